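#' Read a metabolic model
#'
#' Supported formats: SBML Level 3 Version 1 with the FBC v2 package
#' (`"sbml"`), the package's JSON dialect mirroring the domain types
#' one-to-one (`"json"`), and a TSV reaction table (`"tsv"`, columns
#' `id, equation, lb, ub, gpr, subsystem`). The format is inferred from the
#' file extension when not given.
#'
#' @param path File path.
#' @param format One of `"sbml"`, `"json"`, `"tsv"`; `NULL` = infer.
#' @return A `metabolic_model`.
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||% infer_model_format(path)
  switch(match.arg(format, c("sbml", "json", "tsv")),
         sbml = read_model_sbml(path),
         json = read_model_json(path),
         tsv = read_model_tsv(path))
}

#' Write a metabolic model
#'
#' Output is byte-stable for identical inputs: metabolites, reactions and
#' genes are written in sorted id order.
#'
#' @param model A `metabolic_model`.
#' @param path Output path.
#' @param format One of `"sbml"`, `"json"`, `"tsv"`; `NULL` = infer from
#'   the extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  format <- format %||% infer_model_format(path)
  switch(match.arg(format, c("sbml", "json", "tsv")),
         sbml = write_model_sbml(model, path),
         json = write_model_json(model, path),
         tsv = write_model_tsv(model, path))
  invisible(path)
}

infer_model_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         xml = "sbml", sbml = "sbml",
         json = "json",
         tsv = "tsv", txt = "tsv",
         stop("cannot infer model format from extension '.", ext, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sort_model <- function(model) {
  metabolic_model(
    reactions = unname(model$reactions[order(names(model$reactions))]),
    metabolites = unname(model$metabolites[order(names(model$metabolites))]),
    genes = unname(model$genes[order(names(model$genes))]),
    compartments = model$compartments[order(names(model$compartments))],
    objective = model$objective,
    id = model$id
  )
}

# ---- JSON dialect ------------------------------------------------------

read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("reactions", "metabolites", "objective")) {
    if (is.null(j[[f]])) stop("model JSON '", path, "': missing field '", f, "'")
  }
  mets <- lapply(j$metabolites, function(m) {
    metabolite(m$id, m$name %||% m$id, m$compartment,
               formula = if (!is.null(m$formula)) unlist(m$formula),
               annotations = m$annotations %||% list())
  })
  rxns <- lapply(j$reactions, function(r) {
    reaction(r$id, stoichiometry = unlist(r$stoichiometry),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             name = r$name %||% r$id, gpr = r$gpr %||% "",
             kind = r$kind, annotations = r$annotations %||% list())
  })
  genes <- lapply(j$genes %||% list(), function(g)
    gene(g$id, g$name %||% NA_character_))
  metabolic_model(
    reactions = rxns, metabolites = mets, genes = genes,
    compartments = unlist(j$compartments) %||% default_compartments(),
    objective = j$objective, id = j$id %||% "model"
  )
}

write_model_json <- function(model, path) {
  model <- sort_model(model)
  j <- list(
    id = model$id,
    compartments = as.list(model$compartments),
    objective = model$objective,
    metabolites = lapply(unname(model$metabolites), function(m) {
      out <- list(id = m$id, name = m$name, compartment = m$compartment)
      if (!is.null(m$formula)) out$formula <- as.list(m$formula)
      if (length(m$annotations) > 0L) out$annotations <- m$annotations
      out
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      out <- list(id = r$id, name = r$name,
                  stoichiometry = as.list(r$stoichiometry),
                  lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                  gpr = r$gpr, kind = r$kind)
      if (length(r$annotations) > 0L) out$annotations <- r$annotations
      out
    }),
    genes = lapply(unname(model$genes), function(g)
      list(id = g$id, name = g$name))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# ---- TSV reaction table ------------------------------------------------

write_model_tsv <- function(model, path) {
  model <- sort_model(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# objective: ", model$objective), con)
  writeLines(paste0("# compartments: ",
                    paste(sprintf("%s=%s", names(model$compartments),
                                  model$compartments), collapse = ";")), con)
  writeLines("id\tequation\tlb\tub\tgpr\tsubsystem", con)
  for (r in model$reactions) {
    writeLines(paste(r$id, format_equation(r),
                     format(r$lower_bound, scientific = FALSE),
                     format(r$upper_bound, scientific = FALSE),
                     r$gpr, r$kind, sep = "\t"), con)
  }
  invisible(path)
}

read_model_tsv <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  objective <- sub("^# objective: *", "", grep("^# objective:", header, value = TRUE))
  comp_line <- sub("^# compartments: *", "",
                   grep("^# compartments:", header, value = TRUE))
  compartments <- if (length(comp_line) == 1L) {
    kv <- strsplit(strsplit(comp_line, ";")[[1L]], "=")
    setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  } else default_compartments()
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "equation", "lb", "ub", "gpr")
  if (!all(need %in% names(tab))) {
    stop("model TSV '", path, "': requires columns ",
         paste(need, collapse = ", "))
  }
  rxns <- lapply(seq_len(nrow(tab)), function(i) {
    reaction(tab$id[i], parse_equation(tab$equation[i], tab$id[i]),
             lower_bound = as.numeric(tab$lb[i]),
             upper_bound = as.numeric(tab$ub[i]),
             gpr = tab$gpr[i],
             kind = if ("subsystem" %in% names(tab) && nzchar(tab$subsystem[i]))
               tab$subsystem[i] else NULL)
  })
  metabolic_model(reactions = rxns, compartments = compartments,
                  objective = if (length(objective) == 1L) objective)
}

# "A_c + 2 B_c -> C_c" / "<->"; coefficient defaults to 1
parse_equation <- function(eq, rxn_id) {
  parts <- strsplit(eq, "<->|->", perl = TRUE)[[1L]]
  if (length(parts) > 2L || !grepl("->", eq)) {
    stop("reaction '", rxn_id, "': cannot parse equation '", eq, "'")
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, " \\+ ")[[1L]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9]*\\.?[0-9]+ )?([A-Za-z0-9_.-]+)$", t))[[1L]]
      if (length(m) == 0L) {
        stop("reaction '", rxn_id, "': cannot parse term '", t, "'")
      }
      coef <- if (nzchar(m[2L])) as.numeric(trimws(m[2L])) else 1
      out[m[3L]] <- (if (m[3L] %in% names(out)) out[m[3L]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(parts[1L], -1)
  rhs <- if (length(parts) == 2L) parse_side(parts[2L], +1) else numeric(0)
  both <- intersect(names(lhs), names(rhs))
  s <- c(lhs[setdiff(names(lhs), both)], rhs[setdiff(names(rhs), both)])
  for (b in both) s[b] <- lhs[b] + rhs[b]
  s[s != 0]
}
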