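#' FSEOF scan: flux scanning based on enforced objective flux
#'
#' Progressively enforces flux through a product reaction (e.g. a linoleate
#' demand) while keeping biomass as the optimisation objective, and records
#' how every reaction's flux responds. Reactions whose flux rises
#' monotonically with the enforced product flux are amplification
#' candidates.
#'
#' Protocol: (1) the maximal product flux `v_prod_max` is computed with the
#' product as objective; (2) `n_steps` enforcement levels are spaced evenly
#' from the baseline product flux (at the unconstrained biomass optimum) to
#' `max_fraction * v_prod_max`; (3) at each level the product's lower bound
#' is fixed and biomass re-optimised (pFBA for deterministic fluxes); (4)
#' each reaction's slope is the least-squares slope of `|flux|` on the
#' enforced level (or the endpoint difference quotient with
#' `slope_method = "endpoint"`). A reaction is reported when its slope is
#' positive, its flux is non-decreasing across levels (within
#' `activity_epsilon`), and it does not change direction; direction-changing
#' reactions are listed separately since "flux increases" is ill-defined
#' across a sign change.
#'
#' @param model A `metabolic_model`, already configured on its medium.
#' @param product_rxn Reaction id of the enforced product (demand) flux.
#' @param biomass_rxn Biomass objective id; defaults to the model objective.
#' @param n_steps Number of enforcement levels.
#' @param max_fraction Top enforcement level as a fraction of the maximal
#'   product flux; below 1 to avoid the often-degenerate extreme vertex.
#' @param slope_method `"regression"` (default) or `"endpoint"`.
#' @param carbon_source Label stored on the records (for aggregation).
#' @param activity_epsilon Activity/monotonicity tolerance.
#' @param growth_threshold Minimal baseline growth for the scan to proceed.
#' @return An object of class `fseof_scan`: `records` data frame
#'   (carbon_source, reaction_id, slope, monotone_increasing, reported),
#'   `levels`, `step_fluxes` (reactions x levels), `v_prod_max`,
#'   `sign_changers`, `reason` (`NA` on success).
#' @export
run_fseof <- function(model, product_rxn, biomass_rxn = model$objective,
                      n_steps = 10L, max_fraction = 0.9,
                      slope_method = c("regression", "endpoint"),
                      carbon_source = NA_character_,
                      activity_epsilon = 1e-6, growth_threshold = 1e-6) {
  slope_method <- match.arg(slope_method)
  rids <- reaction_ids(model)
  stopifnot(product_rxn %in% rids, biomass_rxn %in% rids,
            n_steps >= 2L, max_fraction > 0, max_fraction <= 1)
  empty <- function(reason) {
    structure(list(records = data.frame(
      carbon_source = character(0), reaction_id = character(0),
      slope = numeric(0), monotone_increasing = logical(0),
      reported = logical(0), stringsAsFactors = FALSE),
      levels = numeric(0), step_fluxes = NULL, v_prod_max = NA_real_,
      sign_changers = character(0), reason = reason),
      class = "fseof_scan")
  }
  base <- solve_pfba(model, biomass_rxn, activity_epsilon = activity_epsilon)
  if (base$status != "optimal" || base$objective_value <= growth_threshold) {
    return(empty("no growth on the configured medium"))
  }
  vmax <- solve_fba(model, product_rxn, sense = "max")
  if (vmax$status != "optimal" || vmax$objective_value <= activity_epsilon) {
    return(empty("product unreachable"))
  }
  v_prod_max <- vmax$objective_value
  base_prod <- base$fluxes[[product_rxn]]
  levels <- seq(base_prod, max_fraction * v_prod_max, length.out = n_steps)
  flux_mat <- matrix(NA_real_, length(rids), n_steps,
                     dimnames = list(rids, NULL))
  mu_prev <- Inf
  kept <- logical(n_steps)
  for (k in seq_len(n_steps)) {
    m <- set_bounds(model, product_rxn, lower = levels[k])
    sol <- solve_pfba(m, biomass_rxn, activity_epsilon = activity_epsilon)
    if (sol$status != "optimal") {
      warning("enforcement level ", signif(levels[k], 6),
              " infeasible; step dropped")
      next
    }
    if (sol$objective_value > mu_prev + 1e-6) {
      warning("biomass objective increased along the enforcement grid")
    }
    mu_prev <- sol$objective_value
    flux_mat[, k] <- sol$fluxes
    kept[k] <- TRUE
  }
  if (sum(kept) < 2L) return(empty("fewer than two feasible enforcement steps"))
  levels <- levels[kept]
  flux_mat <- flux_mat[, kept, drop = FALSE]

  nz_sign <- function(v) unique(sign(v[abs(v) > activity_epsilon]))
  sign_change <- vapply(rids, function(r)
    length(nz_sign(flux_mat[r, ])) > 1L, TRUE)
  absf <- abs(flux_mat)
  slope <- vapply(rids, function(r) {
    y <- absf[r, ]
    if (slope_method == "endpoint") {
      (y[length(y)] - y[1L]) / (levels[length(levels)] - levels[1L])
    } else {
      as.numeric(stats::coef(stats::lm.fit(cbind(1, levels), y))[2L])
    }
  }, 0)
  monotone <- vapply(rids, function(r)
    all(diff(absf[r, ]) >= -activity_epsilon), TRUE)
  ever_active <- rowSums(absf > activity_epsilon) > 0L
  reported <- slope > activity_epsilon & monotone & !sign_change & ever_active
  structure(
    list(records = data.frame(
      carbon_source = carbon_source, reaction_id = rids,
      slope = slope, monotone_increasing = monotone,
      reported = reported, row.names = NULL, stringsAsFactors = FALSE),
      levels = levels, step_fluxes = flux_mat, v_prod_max = v_prod_max,
      sign_changers = rids[sign_change], reason = NA_character_),
    class = "fseof_scan"
  )
}

#' @export
print.fseof_scan <- function(x, ...) {
  if (!is.na(x$reason)) {
    cat("<fseof_scan: empty (", x$reason, ")>\n", sep = "")
  } else {
    cat(sprintf("<fseof_scan: %d levels, %d/%d reactions reported>\n",
                length(x$levels), sum(x$records$reported),
                nrow(x$records)))
  }
  invisible(x)
}

#' Aggregate FSEOF scans across carbon sources
#'
#' Pools per-source scan records and retains the reactions that are robust
#' targets: reported with slope above `slope_threshold` in at least
#' `min_sources` sources.
#'
#' @param scans List of `fseof_scan` objects (or a single one), or a
#'   pre-bound data frame of records.
#' @param min_sources Minimal number of sources a reaction must be reported
#'   in.
#' @param slope_threshold Minimal slope for a per-source report to count.
#' @return An object of class `fseof_target_set`: `retained` data frame
#'   (reaction_id, n_sources_reported, mean_slope, max_slope), `slope_long`
#'   long-format slope table (reaction_id, carbon_source, slope) over all
#'   reported reaction-source pairs passing the slope threshold
#'   (heatmap-ready; absent pair = not reported), and the filters used.
#' @export
aggregate_fseof <- function(scans, min_sources = 5L, slope_threshold = 2) {
  records <- if (is.data.frame(scans)) scans
  else {
    if (inherits(scans, "fseof_scan")) scans <- list(scans)
    do.call(rbind, lapply(scans, `[[`, "records"))
  }
  stopifnot(nrow(records) >= 0L,
            all(c("carbon_source", "reaction_id", "slope", "reported")
                %in% names(records)))
  hits <- records[records$reported & records$slope > slope_threshold, ,
                  drop = FALSE]
  hits <- hits[!duplicated(hits[c("carbon_source", "reaction_id")]), ,
               drop = FALSE]
  if (nrow(hits) > 0L) {
    agg <- stats::aggregate(slope ~ reaction_id, data = hits,
                            FUN = function(v) c(n = length(v),
                                                mean = mean(v), max = max(v)))
    retained <- data.frame(
      reaction_id = agg$reaction_id,
      n_sources_reported = as.integer(agg$slope[, "n"]),
      mean_slope = agg$slope[, "mean"],
      max_slope = agg$slope[, "max"],
      stringsAsFactors = FALSE)
    retained <- retained[retained$n_sources_reported >= min_sources, ,
                         drop = FALSE]
    retained <- retained[order(-retained$n_sources_reported,
                               -retained$mean_slope), , drop = FALSE]
    rownames(retained) <- NULL
  } else {
    retained <- data.frame(reaction_id = character(0),
                           n_sources_reported = integer(0),
                           mean_slope = numeric(0), max_slope = numeric(0),
                           stringsAsFactors = FALSE)
  }
  long <- hits[hits$reaction_id %in% retained$reaction_id, , drop = FALSE]
  structure(
    list(retained = retained,
         slope_long = long[order(long$reaction_id, long$carbon_source),
                           c("reaction_id", "carbon_source", "slope")],
         min_sources = min_sources, slope_threshold = slope_threshold,
         n_sources_scanned = length(unique(records$carbon_source))),
    class = "fseof_target_set"
  )
}

#' @export
print.fseof_target_set <- function(x, ...) {
  cat(sprintf(
    "<fseof_target_set: %d retained reaction(s) (>= %d sources, slope > %g) from %d source(s)>\n",
    nrow(x$retained), x$min_sources, x$slope_threshold, x$n_sources_scanned))
  if (nrow(x$retained) > 0L) print(utils::head(x$retained, 10L))
  invisible(x)
}

#' Map retained FSEOF targets to genes through GPR rules
#'
#' @param targets An `fseof_target_set`.
#' @param model The `metabolic_model` the scans were run on.
#' @return The target set extended with: `retained$genes` (list column),
#'   `retained$orphan_gpr` (no gene association), `gene_set` (union over
#'   retained reactions), `orphan_reactions`.
#' @export
map_targets_to_genes <- function(targets, model) {
  stopifnot(inherits(targets, "fseof_target_set"))
  ret <- targets$retained
  genes <- vector("list", nrow(ret))
  for (i in seq_len(nrow(ret))) {
    rid <- ret$reaction_id[i]
    if (!rid %in% reaction_ids(model)) {
      stop("target reaction '", rid, "' not in model")
    }
    genes[[i]] <- gpr_genes(parse_gpr(model$reactions[[rid]]$gpr))
  }
  ret$genes <- genes
  ret$orphan_gpr <- lengths(genes) == 0L
  targets$retained <- ret
  targets$gene_set <- sort(unique(unlist(genes)))
  targets$orphan_reactions <- ret$reaction_id[ret$orphan_gpr]
  targets
}
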