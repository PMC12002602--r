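#' Classify reaction activity across a set of flux solutions
#'
#' Pools flux distributions from feasible simulations (one per carbon
#' source) and partitions the model's reactions by how often each carries
#' flux: `always_active` (active in every solution), `active_at_least_once`
#' (the auxiliary set: active in some but not all), and `never_active`.
#'
#' The auxiliary set is further subdivided at activity-fraction thresholds
#' (default 10%/90%): `near_core` reactions are inactive in at most the
#' lower threshold share of solutions (activity >= 90%), `type_associated`
#' reactions are active in between the thresholds (carbon-source-type
#' related), and `source_specific` reactions are active in at most the lower
#' threshold share (rarely active, carbon-source specific). At exactly the
#' boundary, `near_core` takes precedence, then `source_specific`; the
#' remainder is `type_associated`, so the three always partition the
#' auxiliary set.
#'
#' @param solutions List of `flux_solution` objects over the same reaction
#'   index.
#' @param thresholds Numeric length-2, the lower and upper activity-fraction
#'   thresholds (default `c(0.10, 0.90)`).
#' @param activity_epsilon A reaction is active in a solution when
#'   `|flux| > activity_epsilon`.
#' @return An object of class `activity_profile`: `per_reaction` data frame
#'   (reaction, n_active, fraction_active, class, subclass), `partition`
#'   counts, `auxiliary` counts with percentage shares, `n_solutions`.
#' @export
classify_reaction_activity <- function(solutions, thresholds = c(0.10, 0.90),
                                       activity_epsilon = 1e-6) {
  stopifnot(length(solutions) >= 1L, length(thresholds) == 2L,
            thresholds[1] <= thresholds[2])
  rids <- names(solutions[[1L]]$fluxes)
  for (s in solutions) {
    if (!identical(names(s$fluxes), rids)) {
      stop("solutions are not over the same reaction index")
    }
  }
  n_sol <- length(solutions)
  act <- vapply(solutions, function(s) abs(s$fluxes) > activity_epsilon,
                logical(length(rids)))
  act <- matrix(act, nrow = length(rids))
  n_active <- rowSums(act)
  frac <- n_active / n_sol
  cls <- ifelse(n_active == n_sol, "always_active",
                ifelse(n_active == 0L, "never_active", "active_at_least_once"))
  lo <- thresholds[1]; hi <- thresholds[2]
  sub <- rep(NA_character_, length(rids))
  aux <- cls == "active_at_least_once"
  # inactive fraction <= lo  <=>  activity fraction >= 1 - lo
  sub[aux & frac >= 1 - lo] <- "near_core"
  sub[aux & is.na(sub) & frac <= lo] <- "source_specific"
  sub[aux & is.na(sub)] <- "type_associated"
  per <- data.frame(reaction = rids, n_active = n_active,
                    fraction_active = frac, class = cls, subclass = sub,
                    stringsAsFactors = FALSE)
  partition <- c(always_active = sum(cls == "always_active"),
                 active_at_least_once = sum(aux),
                 never_active = sum(cls == "never_active"))
  aux_counts <- c(near_core = sum(sub == "near_core", na.rm = TRUE),
                  type_associated = sum(sub == "type_associated", na.rm = TRUE),
                  source_specific = sum(sub == "source_specific", na.rm = TRUE))
  aux_share <- if (sum(aux) > 0L) 100 * aux_counts / sum(aux) else
    aux_counts * NA_real_
  structure(
    list(per_reaction = per, partition = partition,
         auxiliary = aux_counts, auxiliary_share_percent = aux_share,
         thresholds = thresholds, n_solutions = n_sol),
    class = "activity_profile"
  )
}

#' @export
print.activity_profile <- function(x, ...) {
  tot <- sum(x$partition)
  cat(sprintf("<activity_profile: %d reactions over %d solutions>\n",
              tot, x$n_solutions))
  for (nm in names(x$partition)) {
    cat(sprintf("  %-22s %5d (%.1f%%)\n", nm, x$partition[[nm]],
                100 * x$partition[[nm]] / tot))
  }
  if (x$partition[["active_at_least_once"]] > 0L) {
    cat("  auxiliary subdivision:\n")
    for (nm in names(x$auxiliary)) {
      cat(sprintf("    %-20s %5d (%.2f%%)\n", nm, x$auxiliary[[nm]],
                  x$auxiliary_share_percent[[nm]]))
    }
  }
  invisible(x)
}

#' Mean number of active reactions per solution
#'
#' @param solutions List of `flux_solution` objects.
#' @param activity_epsilon Activity cutoff on `|flux|`.
#' @return Arithmetic mean of the active-set sizes.
#' @export
mean_active_reactions <- function(solutions, activity_epsilon = 1e-6) {
  stopifnot(length(solutions) >= 1L)
  mean(vapply(solutions, function(s)
    sum(abs(s$fluxes) > activity_epsilon), 0))
}
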