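#' Structural validation of a metabolic model
#'
#' Checks id resolution, bound sanity, GPR parseability and network dead
#' ends. Findings are data, not errors: an empty report means a clean model.
#'
#' An *orphan* metabolite participates in exactly one reaction (a classic
#' dead end); a *dangling* metabolite participates in none.
#'
#' @param model A `metabolic_model`.
#' @return A list of class `validation_report` with components
#'   `dangling_metabolite_ids`, `orphan_metabolite_ids`, `duplicate_ids`,
#'   `unbounded_exchange_ids`, `bound_violations`, `gpr_parse_errors`.
#' @export
validate_model <- function(model) {
  counts <- metabolite_participation(model)
  rt <- model$reactions
  bound_viol <- names(rt)[vapply(rt, function(r) r$lower_bound > r$upper_bound, TRUE)]
  unbounded_ex <- names(rt)[vapply(rt, function(r) {
    r$kind %in% c("exchange", "demand") &&
      (is.infinite(r$lower_bound) || is.infinite(r$upper_bound))
  }, TRUE)]
  gpr_errors <- character(0)
  for (r in rt) {
    ok <- tryCatch({ parse_gpr(r$gpr); TRUE }, error = function(e) FALSE)
    if (!ok) gpr_errors <- c(gpr_errors, r$id)
  }
  structure(
    list(
      dangling_metabolite_ids = names(counts)[counts == 0L],
      orphan_metabolite_ids = names(counts)[counts == 1L],
      duplicate_ids = character(0),  # construction forbids duplicates
      unbounded_exchange_ids = unbounded_ex,
      bound_violations = bound_viol,
      gpr_parse_errors = gpr_errors
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  n <- sum(lengths(x))
  if (n == 0L) {
    cat("<validation_report: clean>\n")
    return(invisible(x))
  }
  cat("<validation_report:", n, "finding(s)>\n")
  for (nm in names(x)) {
    if (length(x[[nm]]) > 0L) {
      cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Is a validation report empty?
#' @param report A `validation_report`.
#' @return `TRUE` iff no findings.
#' @export
is_clean <- function(report) sum(lengths(report)) == 0L

metabolite_participation <- function(model) {
  counts <- setNames(integer(length(model$metabolites)), metabolite_ids(model))
  for (r in model$reactions) {
    ids <- names(r$stoichiometry)
    counts[ids] <- counts[ids] + 1L
  }
  counts
}

#' Strip orphan metabolites to obtain a slim model
#'
#' Removes every metabolite participating in exactly one reaction together
#' with that reaction. With `iterate = TRUE` (default) the removal is
#' repeated to a fixed point, since deleting a reaction can strand further
#' metabolites; the returned model then has no orphan metabolites at all.
#' Gene lists are pruned to genes still referenced by some GPR. The input
#' model is never modified.
#'
#' @param model A `metabolic_model`.
#' @param iterate Iterate removal to a fixed point (default) or apply a
#'   single pass only.
#' @return The slimmed `metabolic_model`.
#' @export
slim_model <- function(model, iterate = TRUE) {
  protected <- c(model$objective,
                 names(model$reactions)[vapply(model$reactions, function(r)
                   r$kind %in% c("exchange", "demand", "biomass"), TRUE)])
  rxns <- model$reactions
  mets <- model$metabolites
  repeat {
    counts <- setNames(integer(length(mets)), names(mets))
    for (r in rxns) counts[names(r$stoichiometry)] <- counts[names(r$stoichiometry)] + 1L
    orphans <- names(counts)[counts == 1L]
    if (length(orphans) == 0L) break
    doomed <- unique(unlist(lapply(rxns, function(r)
      if (any(names(r$stoichiometry) %in% orphans)) r$id else NULL)))
    if (any(doomed %in% protected)) {
      stop("slim_model: refusing to remove protected reaction(s): ",
           paste(intersect(doomed, protected), collapse = ", "),
           " (objective/exchange reactions must be kept)")
    }
    rxns <- rxns[setdiff(names(rxns), doomed)]
    mets <- mets[setdiff(names(mets), orphans)]
    # drop metabolites no longer referenced by any reaction
    referenced <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
    mets <- mets[intersect(names(mets), referenced)]
    if (!iterate) break
  }
  kept_genes <- sort(unique(unlist(lapply(rxns, function(r)
    gpr_genes(parse_gpr(r$gpr))))))
  metabolic_model(
    reactions = unname(rxns),
    metabolites = unname(mets),
    genes = unname(model$genes[intersect(names(model$genes), kept_genes)]),
    compartments = model$compartments,
    objective = model$objective,
    id = paste0(model$id, "-slim")
  )
}
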