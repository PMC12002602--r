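#' Construct a phenotype plate table
#'
#' One row per carbon source with its substrate class and per-replicate
#' growth calls, as scored from a phenotype microarray.
#'
#' @param source Character vector of unique carbon-source ids.
#' @param class Substrate class per source; one of `amine/amide`,
#'   `amino acid`, `carboxylic acid`, `carbohydrate`, `polymer`, `other`.
#' @param calls Logical matrix, sources x replicates (>= 1 replicate).
#' @return An object of class `plate_table`: a data.frame with columns
#'   `source`, `class`, `rep1..repN`.
#' @export
plate_table <- function(source, class, calls) {
  calls <- as.matrix(calls)
  stopifnot(length(source) == length(class), nrow(calls) == length(source),
            ncol(calls) >= 1L, is.logical(calls))
  if (anyDuplicated(source)) {
    stop("duplicate carbon-source id(s): ",
         paste(unique(source[duplicated(source)]), collapse = ", "))
  }
  bad <- setdiff(unique(class), plate_classes())
  if (length(bad) > 0L) {
    stop("unknown substrate class(es): ", paste(bad, collapse = ", "))
  }
  colnames(calls) <- paste0("rep", seq_len(ncol(calls)))
  out <- data.frame(source = source, class = class, calls,
                    stringsAsFactors = FALSE)
  class(out) <- c("plate_table", "data.frame")
  out
}

#' Registered substrate classes
#' @return Character vector of valid plate substrate classes.
#' @export
plate_classes <- function() {
  c("amine/amide", "amino acid", "carboxylic acid", "carbohydrate",
    "polymer", "other")
}

plate_calls <- function(plate) {
  as.matrix(plate[, grep("^rep[0-9]+$", names(plate)), drop = FALSE])
}

#' Read a phenotype plate from CSV
#'
#' Expected header: `source,class,rep1,...,repN`. Replicate cells accept
#' `0/1`, `TRUE/FALSE`, `T/F`, `+/-` (ASCII or typographic minus).
#'
#' @param path CSV file path.
#' @return A `plate_table`.
#' @export
read_plate <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!all(c("source", "class") %in% names(tab))) {
    stop("plate CSV '", path, "': requires 'source' and 'class' columns")
  }
  rep_cols <- grep("^rep[0-9]+$", names(tab), value = TRUE)
  if (length(rep_cols) == 0L) {
    stop("plate CSV '", path, "': no replicate columns (rep1..repN)")
  }
  calls <- matrix(NA, nrow(tab), length(rep_cols))
  for (j in seq_along(rep_cols)) {
    for (i in seq_len(nrow(tab))) {
      calls[i, j] <- parse_growth_call(tab[[rep_cols[j]]][i], tab$source[i],
                                       rep_cols[j], path)
    }
  }
  plate_table(tab$source, tab$class, calls)
}

parse_growth_call <- function(cell, source, column, path) {
  v <- trimws(cell)
  if (v %in% c("1", "TRUE", "true", "T", "+")) return(TRUE)
  if (v %in% c("0", "FALSE", "false", "F", "-", "−")) return(FALSE)
  stop("plate CSV '", path, "': non-boolean cell '", cell,
       "' at source '", source, "', column ", column)
}

#' Write a phenotype plate to CSV
#' @param plate A `plate_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(plate, path) {
  out <- as.data.frame(plate)
  rep_cols <- grep("^rep[0-9]+$", names(out))
  for (j in rep_cols) out[[j]] <- as.integer(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
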