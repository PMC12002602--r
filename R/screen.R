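#' Minimal-medium specification
#'
#' Describes which exchange reactions are left unconstrained in a screening
#' simulation. The default free list reflects a minimal medium for an
#' oleaginous soil fungus: phosphate, sulphite, sulphate and ammonium as
#' nutrient exchanges, plus carbon dioxide, oxygen, water and hydrogen ions.
#'
#' @param free_exchange_ids Exchange reaction ids left open in both
#'   directions.
#' @param carbon_exchange_id Exchange id of the carbon source under test
#'   (may be `NA` in a template; filled per source by the screen).
#' @param carbon_uptake_bound Maximal carbon uptake, mmol/gDW/h. The default
#'   10 supports qualitative growth/no-growth screening.
#' @return An object of class `medium_spec`.
#' @export
medium_spec <- function(free_exchange_ids = default_free_exchanges(),
                        carbon_exchange_id = NA_character_,
                        carbon_uptake_bound = 10) {
  stopifnot(carbon_uptake_bound >= 0)
  if (!is.na(carbon_exchange_id) &&
      carbon_exchange_id %in% free_exchange_ids) {
    stop("carbon source '", carbon_exchange_id,
         "' must not be in the free exchange list")
  }
  structure(
    list(free_exchange_ids = free_exchange_ids,
         carbon_exchange_id = carbon_exchange_id,
         carbon_uptake_bound = carbon_uptake_bound),
    class = "medium_spec"
  )
}

#' Default free exchange reactions of the minimal screening medium
#' @return Character vector of exchange reaction ids.
#' @export
default_free_exchanges <- function() {
  c("EX_pi_e", "EX_so3_e", "EX_so4_e", "EX_nh4_e",
    "EX_co2_e", "EX_o2_e", "EX_h2o_e", "EX_h_e")
}

#' Configure a model onto a screening medium
#'
#' Closes uptake through every exchange reaction, then opens the medium's
#' free exchanges in both directions and bounds the carbon exchange's uptake
#' at `carbon_uptake_bound`. Secretion is never closed. The input model is
#' not modified.
#'
#' @param model A `metabolic_model`.
#' @param medium A [medium_spec()] with a concrete `carbon_exchange_id`.
#' @param default_open_bound Magnitude used for opened exchanges.
#' @return The configured `metabolic_model`.
#' @export
configure_medium <- function(model, medium, default_open_bound = 1000) {
  stopifnot(inherits(medium, "medium_spec"))
  rids <- reaction_ids(model)
  is_boundary <- vapply(model$reactions, function(r)
    r$kind %in% c("exchange", "demand"), TRUE)
  carbon <- medium$carbon_exchange_id
  if (is.na(carbon) || !carbon %in% rids || !is_boundary[[carbon]]) {
    stop("no exchange reaction for carbon source '", carbon,
         "' in model (missing transporter/exchange)")
  }
  missing_free <- setdiff(medium$free_exchange_ids, rids)
  if (length(missing_free) > 0L) {
    stop("medium names absent exchange reaction(s): ",
         paste(missing_free, collapse = ", "))
  }
  for (id in rids[is_boundary]) {
    model <- set_bounds(model, id, lower = 0)      # close all uptake
  }
  for (id in medium$free_exchange_ids) {
    model <- set_bounds(model, id, lower = -default_open_bound,
                        upper = default_open_bound)
  }
  set_bounds(model, carbon, lower = -medium$carbon_uptake_bound)
}

#' Majority growth call from plate replicates
#'
#' Phenotype-array replicate data are noisy; a source is scored as
#' assimilated only when growth is observed in at least `min_positive`
#' replicates (two of three in the standard protocol).
#'
#' @param replicate_calls Logical vector of per-replicate growth calls.
#' @param min_positive Minimal number of positive replicates.
#' @return `TRUE`/`FALSE`.
#' @export
biolog_majority_call <- function(replicate_calls, min_positive = 2L) {
  stopifnot(length(replicate_calls) >= 1L, is.logical(replicate_calls))
  sum(replicate_calls) >= min_positive
}

#' Screen carbon sources against a phenotype plate
#'
#' For each plate source: derive the in vitro call by the majority rule, map
#' the source to its exchange reaction, configure the minimal medium, solve
#' (pFBA by default), and call growth in silico. Sources without a mapped
#' exchange reaction are structural in-silico no-growth with reason
#' `"no_exchange"` — the missing-transporter situation.
#'
#' @param model A `metabolic_model`.
#' @param plate A `plate_table`.
#' @param exchange_map Named character vector, source -> exchange reaction
#'   id. Sources absent from the map (or mapped to `NA`) are unmappable.
#' @param medium_template A [medium_spec()]; its carbon slot is filled per
#'   source.
#' @param growth_threshold Growth-call threshold on the objective (1/h).
#' @param min_positive Majority-rule parameter for the plate calls.
#' @param parsimonious Use pFBA flux distributions (default) or raw FBA.
#' @return An object of class `concordance_result`: `per_source` data frame
#'   (source, class, in_vitro, in_silico, mu, reason), `counts` (named:
#'   both_growth, both_no_growth, false_no_growth, false_growth),
#'   `agreement_percent`, and `solutions` (named list of `flux_solution`
#'   for sources with a mapped exchange and feasible medium).
#' @export
screen_carbon_sources <- function(model, plate, exchange_map,
                                  medium_template = medium_spec(),
                                  growth_threshold = 1e-6,
                                  min_positive = 2L,
                                  parsimonious = TRUE) {
  stopifnot(inherits(plate, "plate_table"))
  if (nrow(plate) == 0L) stop("empty plate")
  calls <- plate_calls(plate)
  n <- nrow(plate)
  in_vitro <- vapply(seq_len(n), function(i)
    biolog_majority_call(calls[i, ], min_positive), TRUE)
  in_silico <- logical(n)
  mu <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  solutions <- list()
  for (i in seq_len(n)) {
    src <- plate$source[i]
    ex <- if (src %in% names(exchange_map)) exchange_map[[src]] else NA_character_
    if (is.na(ex) || !ex %in% reaction_ids(model)) {
      in_silico[i] <- FALSE
      reason[i] <- "no_exchange"
      next
    }
    med <- medium_template
    med$carbon_exchange_id <- ex
    conf <- configure_medium(model, med)
    sol <- if (parsimonious) solve_pfba(conf) else solve_fba(conf)
    mu[i] <- if (sol$status == "optimal") sol$objective_value else 0
    in_silico[i] <- growth_call(sol, growth_threshold)
    reason[i] <- if (sol$status == "optimal") "simulated" else sol$status
    if (sol$status == "optimal") solutions[[src]] <- sol
  }
  counts <- c(
    both_growth = sum(in_vitro & in_silico),
    both_no_growth = sum(!in_vitro & !in_silico),
    false_no_growth = sum(in_vitro & !in_silico),
    false_growth = sum(!in_vitro & in_silico)
  )
  structure(
    list(
      per_source = data.frame(
        source = plate$source, class = plate$class,
        in_vitro = in_vitro, in_silico = in_silico,
        mu = mu, reason = reason, stringsAsFactors = FALSE),
      counts = counts,
      agreement_percent = 100 * (counts[["both_growth"]] +
                                   counts[["both_no_growth"]]) / n,
      solutions = solutions
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result: %d sources, agreement %.2f%%>\n",
              nrow(x$per_source), x$agreement_percent))
  print(x$counts)
  invisible(x)
}
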