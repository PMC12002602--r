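# Linear-programming core behind FBA/pFBA:
#
#     max/min  c'v   s.t.   A v = b,   lb <= v <= ub
#
# Revised simplex with bounded variables: nonbasic variables rest at a
# finite bound (or 0 when free), the basis inverse is maintained explicitly
# and updated by elementary pivots, and upper bounds are handled in the
# ratio test (including bound flips) rather than as extra rows. Phase 1
# drives signed artificials to zero; Dantzig pricing switches to Bland's
# rule if iterations pile up, which guards against cycling. Problem sizes
# in this package are a few hundred variables at most, so dense algebra is
# appropriate.

#' Solve a bounded linear program
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Constraint matrix (m x n) for the equality system `A v = b`.
#' @param rhs Right-hand side b (length m).
#' @param lb,ub Variable bounds (length n); infinities allowed.
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot/feasibility tolerance.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` (on the original scale) and `x` (length n solution vector;
#'   `NA` unless optimal).
#' @keywords internal
#' @export
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- length(obj); m <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m, length(lb) == n, length(ub) == n)
  bad <- function() list(status = "infeasible", objective = NA_real_,
                         x = rep(NA_real_, n))
  if (any(lb > ub)) return(bad())
  if (m == 0L) {
    # box-only problem: optimum at the bound favoured by each coefficient
    cmin <- if (sense == "max") -obj else obj
    x <- ifelse(cmin > 0, lb, ifelse(cmin < 0, ub,
                                     ifelse(is.finite(lb), lb,
                                            ifelse(is.finite(ub), ub, 0))))
    if (any(!is.finite(x) & abs(cmin) > tol)) {
      return(list(status = "unbounded", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  cmin <- if (sense == "max") -obj else obj
  # artificials: one per row, signed so they start feasible and non-negative
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  r0 <- as.numeric(rhs - A %*% x0)
  sgn <- ifelse(r0 >= 0, 1, -1)
  nt <- n + m
  Afull <- cbind(A, diag(sgn, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))

  st <- list(
    basis = n + seq_len(m),
    Binv = diag(sgn, nrow = m),  # inverse of the artificial basis diag(sgn)
    xB = abs(r0),
    xN = c(x0, rep(0, m)),       # stored values of nonbasic variables
    in_basis = c(rep(FALSE, n), rep(TRUE, m))
  )

  # phase 1
  st <- simplex_run(st, Afull, rhs, lbf, ubf,
                    cost = c(rep(0, n), rep(1, m)), tol = tol)
  if (st$status == "unbounded") return(bad())   # cannot happen, defensive
  art_val <- sum(st$xB[st$basis > n])
  if (art_val > 1e-7) return(bad())
  # pin artificials and optimise the real objective
  ubf[n + seq_len(m)] <- 0
  st$xN[n + seq_len(m)] <- 0
  st$status <- NULL
  st <- simplex_run(st, Afull, rhs, lbf, ubf,
                    cost = c(cmin, rep(0, m)), tol = tol)
  if (st$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  x <- st$xN
  x[st$basis] <- st$xB
  x <- x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# One simplex phase on the current basis; returns the updated state with
# status "optimal" or "unbounded".
simplex_run <- function(st, A, b, lb, ub, cost, tol) {
  m <- nrow(A); nt <- ncol(A)
  basis <- st$basis; Binv <- st$Binv; xB <- st$xB; xN <- st$xN
  in_basis <- st$in_basis
  max_iter <- 1000L + 50L * nt
  bland_after <- max_iter %/% 2L
  refresh <- function() {
    nb <- which(!in_basis)
    rhs_eff <- b - A[, nb, drop = FALSE] %*% xN[nb]
    as.numeric(Binv %*% rhs_eff)
  }
  xB <- refresh()
  for (it in seq_len(max_iter)) {
    if (it %% 64L == 0L) xB <- refresh()
    y <- as.numeric(crossprod(cost[basis], Binv))          # duals
    nb <- which(!in_basis)
    d <- cost[nb] - as.numeric(y %*% A[, nb, drop = FALSE])
    at_lb_ok <- xN[nb] < ub[nb] - tol | !is.finite(ub[nb])
    at_ub_ok <- xN[nb] > lb[nb] + tol | !is.finite(lb[nb])
    up_ok <- d < -tol & at_lb_ok       # increase x_j
    dn_ok <- d > tol & at_ub_ok        # decrease x_j
    if (!any(up_ok) && !any(dn_ok)) {
      return(list(basis = basis, Binv = Binv, xB = xB, xN = xN,
                  in_basis = in_basis, status = "optimal"))
    }
    score <- ifelse(up_ok, -d, ifelse(dn_ok, d, -Inf))
    k <- if (it > bland_after) which(score > tol)[1L] else which.max(score)
    j <- nb[k]
    tdir <- if (up_ok[k]) 1 else -1
    w <- as.numeric(Binv %*% A[, j])
    # ratio test: xB - tdir*theta*w within [lb_B, ub_B]; own bound flip
    tw <- tdir * w
    theta <- Inf; leave <- NA_integer_; leave_to <- NA_real_
    pos <- which(tw > tol)
    if (length(pos) > 0L) {
      rat <- (xB[pos] - lb[basis[pos]]) / tw[pos]
      i <- pos[which.min(rat)]
      if (rat[which.min(rat)] < theta) {
        theta <- max(min(rat), 0); leave <- i; leave_to <- lb[basis[i]]
      }
    }
    neg <- which(tw < -tol)
    if (length(neg) > 0L) {
      rat <- (ub[basis[neg]] - xB[neg]) / (-tw[neg])
      i <- neg[which.min(rat)]
      if (min(rat) < theta) {
        theta <- max(min(rat), 0); leave <- i; leave_to <- ub[basis[i]]
      }
    }
    flip_cap <- if (tdir > 0) ub[j] - xN[j] else xN[j] - lb[j]
    if (is.finite(flip_cap) && flip_cap <= theta) {
      # bound flip: x_j traverses to its other bound, basis unchanged
      xN[j] <- xN[j] + tdir * flip_cap
      xB <- xB - tw * flip_cap
      next
    }
    if (!is.finite(theta)) {
      return(list(basis = basis, Binv = Binv, xB = xB, xN = xN,
                  in_basis = in_basis, status = "unbounded"))
    }
    # pivot: j enters at value xN[j] + tdir*theta, basis[leave] exits
    enter_val <- xN[j] + tdir * theta
    xB <- xB - tw * theta
    old <- basis[leave]
    xN[old] <- leave_to
    in_basis[old] <- FALSE
    in_basis[j] <- TRUE
    basis[leave] <- j
    xB[leave] <- enter_val
    piv <- w[leave]
    Brow <- Binv[leave, ] / piv
    Binv <- Binv - outer(w, Brow)
    Binv[leave, ] <- Brow
  }
  stop("simplex: iteration limit reached (", max_iter, ")")
}
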