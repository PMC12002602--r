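#' Flux balance analysis
#'
#' Maximises (or minimises) the flux through an objective reaction subject to
#' steady-state mass balance `S v = 0` and the reaction bounds, the standard
#' FBA linear program. Infeasibility and unboundedness are reported through
#' the solution status, never as errors.
#'
#' @param model A `metabolic_model`.
#' @param objective Reaction id to optimise; defaults to the model objective.
#' @param sense `"max"` (default) or `"min"`.
#' @param activity_epsilon Fluxes with absolute value above this are
#'   considered active (mmol/gDW/h).
#' @return A `flux_solution`: list with `status`, `objective_value`, `fluxes`
#'   (named numeric over all reactions), `active_set` and `objective_id`.
#' @export
solve_fba <- function(model, objective = model$objective,
                      sense = c("max", "min"), activity_epsilon = 1e-6) {
  sense <- match.arg(sense)
  rids <- reaction_ids(model)
  if (!objective %in% rids) stop("no reaction '", objective, "' in model")
  S <- dense_stoich(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- as.numeric(rids == objective)
  res <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, sense = sense)
  new_flux_solution(res, rids, objective, activity_epsilon)
}

new_flux_solution <- function(res, rids, objective, activity_epsilon) {
  fluxes <- setNames(res$x, rids)
  structure(
    list(
      status = res$status,
      objective_value = if (res$status == "optimal") res$objective else NA_real_,
      objective_id = objective,
      fluxes = fluxes,
      active_set = if (res$status == "optimal") {
        rids[abs(fluxes) > activity_epsilon]
      } else character(0),
      activity_epsilon = activity_epsilon
    ),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", %s = %.6g, %d active reactions",
                x$objective_id, x$objective_value, length(x$active_set)))
  }
  cat(">\n")
  invisible(x)
}

#' Parsimonious FBA
#'
#' A second linear program fixes the FBA optimum (within `fix_tol`) and
#' minimises the total absolute flux, `sum(|v|)`, via the standard
#' positive/negative flux splitting. LP optima are usually degenerate; the
#' parsimonious solution gives a deterministic, minimal-support flux
#' distribution, which is what reaction-activity pooling across media needs.
#'
#' @inheritParams solve_fba
#' @param fix_tol Absolute slack allowed on the fixed objective value.
#' @return A `flux_solution` with the pFBA flux vector; `objective_value`
#'   is the (fixed) objective flux, not the total.
#' @export
solve_pfba <- function(model, objective = model$objective,
                       activity_epsilon = 1e-6, fix_tol = 1e-9) {
  fba <- solve_fba(model, objective, activity_epsilon = activity_epsilon)
  if (fba$status != "optimal") return(fba)
  rids <- reaction_ids(model)
  S <- dense_stoich(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  n <- length(rids); m <- nrow(S)
  # min sum(|v|) at the fixed optimum. Reactions that cannot go negative
  # contribute |v| = v (cost +1), never-positive ones |v| = -v (cost -1);
  # only sign-mixed reactions are split as v = p - q with p, q >= 0 and a
  # tie row v - p + q = 0, so the LP stays close to the FBA size.
  mixed <- which(lb < 0 & ub > 0)
  k <- length(mixed)
  cost_v <- ifelse(lb >= 0, 1, ifelse(ub <= 0, -1, 0))
  tie <- matrix(0, k, n)
  if (k > 0L) tie[cbind(seq_len(k), mixed)] <- 1
  A <- rbind(
    cbind(S, matrix(0, m, 2L * k)),
    cbind(tie, -diag(1, k), diag(1, k)),
    c(as.numeric(rids == objective), rep(0, 2L * k))
  )
  rhs <- c(rep(0, m + k), fba$objective_value)
  lbs <- c(lb, rep(0, 2L * k))
  ubs <- c(ub, pmax(ub[mixed], 0), pmax(-lb[mixed], 0))
  res <- lp_solve(c(cost_v, rep(1, 2L * k)), A, rhs, lbs, ubs, sense = "min")
  if (res$status != "optimal") {
    warning("pFBA refinement ", res$status, "; returning FBA solution")
    return(fba)
  }
  v <- res$x[seq_len(n)]
  new_flux_solution(list(status = "optimal", objective = fba$objective_value,
                         x = v), rids, objective, activity_epsilon)
}

#' Total absolute flux of a solution
#' @param solution A `flux_solution`.
#' @return `sum(|v|)`, or `NA` if not optimal.
#' @export
total_flux <- function(solution) {
  if (solution$status != "optimal") return(NA_real_)
  sum(abs(solution$fluxes))
}

#' Predict the growth rate on a given carbon source
#'
#' Sets the uptake bound of a carbon exchange reaction (uptake is negative
#' flux by the exchange convention) and maximises the biomass objective.
#'
#' @param model A `metabolic_model`.
#' @param carbon_exchange Exchange reaction id of the carbon source.
#' @param uptake_rate Maximal uptake rate, mmol/gDW/h (non-negative).
#' @param objective Biomass reaction id; defaults to the model objective.
#' @param parsimonious Use pFBA for the returned fluxes (default TRUE).
#' @return A list with `mu` (predicted growth rate, 1/h; 0 when the medium
#'   is infeasible), `status`, and the underlying `solution`.
#' @export
predict_growth_rate <- function(model, carbon_exchange, uptake_rate,
                                objective = model$objective,
                                parsimonious = TRUE) {
  stopifnot(uptake_rate >= 0)
  if (!carbon_exchange %in% reaction_ids(model)) {
    stop("no exchange reaction '", carbon_exchange, "' in model")
  }
  m <- set_bounds(model, carbon_exchange, lower = -uptake_rate)
  sol <- if (parsimonious) solve_pfba(m, objective) else solve_fba(m, objective)
  mu <- if (sol$status == "optimal") sol$objective_value else 0
  list(mu = mu, status = sol$status, solution = sol)
}

#' Qualitative growth call from a flux solution
#'
#' @param solution A `flux_solution` (or a `predict_growth_rate()` result).
#' @param growth_threshold Growth is called iff the optimal objective value
#'   exceeds this (1/h).
#' @return `TRUE`/`FALSE`.
#' @export
growth_call <- function(solution, growth_threshold = 1e-6) {
  if (!is.null(solution$solution)) solution <- solution$solution
  solution$status == "optimal" &&
    is.finite(solution$objective_value) &&
    solution$objective_value > growth_threshold
}
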