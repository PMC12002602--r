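# Independent oracles the FBA engine is checked against.

# Brute-force LP oracle: enumerates every basic solution of
#   max c'v  s.t.  A v = b, lb <= v <= ub   (finite bounds)
# by choosing m basic columns and pinning the rest at a bound. The optimum
# of a bounded feasible LP is attained at such a vertex, so the best
# feasible enumerated objective is the true optimum. Exponential, for tiny
# fixtures only.
enumerate_lp_optimum <- function(obj, A, rhs, lb, ub) {
  A <- as.matrix(A)
  n <- length(obj); m <- nrow(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)), n <= 10)
  best <- -Inf
  feasible <- FALSE
  check <- function(v) {
    if (all(v >= lb - 1e-8) && all(v <= ub + 1e-8) &&
        all(abs(A %*% v - rhs) < 1e-8)) {
      feasible <<- TRUE
      best <<- max(best, sum(obj * v))
    }
  }
  basis_sets <- if (m == 0) list(integer(0)) else
    asplit(utils::combn(n, m), 2)
  for (B in basis_sets) {
    B <- as.integer(B)
    N <- setdiff(seq_len(n), B)
    AB <- A[, B, drop = FALSE]
    if (m > 0 && abs(det(AB)) < 1e-12) next
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(N)))
    if (length(N) == 0) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      at_ub <- as.logical(grid[g, ])
      v[N] <- ifelse(at_ub, ub[N], lb[N])
      if (m > 0) {
        rhs_eff <- rhs - A[, N, drop = FALSE] %*% v[N]
        v[B] <- as.numeric(solve(AB, rhs_eff))
      }
      check(v)
    }
  }
  list(feasible = feasible, objective = if (feasible) best else NA_real_)
}

# Reference FBA through an independent implementation: scipy's HiGHS-based
# linprog, driven over a JSON handshake.
scipy_fba <- function(model, objective = model$objective, sense = "max") {
  lp <- lp_of_model(model, objective)
  cap <- function(v) ifelse(is.finite(v), v, sign(v) * 1e10)
  prob <- list(S = unname(lp$S), obj = lp$obj,
               lb = cap(lp$lb), ub = cap(lp$ub), sense = sense)
  pf <- tempfile(fileext = ".json"); of <- tempfile(fileext = ".json")
  jsonlite::write_json(prob, pf, auto_unbox = TRUE, digits = NA)
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
p = json.load(open(sys.argv[1]))
S = np.array(p["S"], dtype=float)
if S.ndim == 1:
    S = S.reshape(1, -1)
c = np.array(p["obj"], dtype=float)
lb = np.array(p["lb"], dtype=float); ub = np.array(p["ub"], dtype=float)
sgn = -1.0 if p["sense"] == "max" else 1.0
res = linprog(sgn * c, A_eq=S, b_eq=np.zeros(S.shape[0]),
              bounds=list(zip(lb, ub)), method="highs")
status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(res.status, "error")
out = {"status": status,
       "objective": float(sgn * res.fun) if res.status == 0 else None,
       "x": [float(v) for v in res.x] if res.status == 0 else None}
json.dump(out, open(sys.argv[2], "w"))
'
  status <- system2("python", c("-c", shQuote(script), pf, of),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(of)) {
    stop("reference LP run failed: ", paste(status, collapse = "\n"))
  }
  out <- jsonlite::read_json(of, simplifyVector = TRUE)
  if (!is.null(out$x)) names(out$x) <- reaction_ids(model)
  out
}
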