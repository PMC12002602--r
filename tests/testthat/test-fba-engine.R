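test_that("FBA finds the bottleneck optimum on the chain model", {
  m <- chain_model(uptake = 10)
  sol <- solve_fba(m)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  # closed medium
  closed <- set_bounds(m, "R1", upper = 0)
  expect_equal(solve_fba(closed)$objective_value, 0)
})

test_that("FBA picks the best-yield route on the branched model", {
  m <- branched_model(uptake = 10, yields = c(0.5, 0.8))
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 8)
  lp <- lp_of_model(m)
  oracle <- enumerate_lp_optimum(lp$obj, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub)
  expect_equal(sol$objective_value, oracle$objective, tolerance = 1e-9)
})

test_that("FBA agrees with brute-force vertex enumeration on small instances", {
  cases <- list(
    chain_model(3.7),
    branched_model(5, c(0.3, 0.9)),
    branched_model(12, c(1.2, 0.7)),
    make_random_feasible_model(n_mets = 4, n_rxns = 7, seed = 5)$model
  )
  for (m in cases) {
    lp <- lp_of_model(m)
    oracle <- enumerate_lp_optimum(lp$obj, lp$S, rep(0, nrow(lp$S)),
                                   lp$lb, lp$ub)
    sol <- solve_fba(m)
    expect_equal(sol$objective_value, oracle$objective, tolerance = 1e-6,
                 info = m$id)
  }
})

test_that("optimal solutions satisfy mass balance and bounds", {
  for (seed in 1:4) {
    m <- make_random_feasible_model(n_mets = 10, n_rxns = 18, seed = seed)$model
    sol <- solve_fba(m)
    expect_equal(sol$status, "optimal")
    S <- as.matrix(stoichiometric_matrix(m))
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-8)
    lb <- vapply(m$reactions, `[[`, 0, "lower_bound")
    ub <- vapply(m$reactions, `[[`, 0, "upper_bound")
    expect_true(all(sol$fluxes >= lb - 1e-8 & sol$fluxes <= ub + 1e-8))
  }
})

test_that("infeasible and unbounded instances are reported as status", {
  m <- chain_model()
  m <- set_bounds(m, "R1", lower = 5, upper = 5)
  m <- set_bounds(m, "R2", lower = 0, upper = 1)  # cannot drain the forced input
  expect_equal(solve_fba(m)$status, "infeasible")

  unb <- metabolic_model(list(
    reaction("F1", c(A_c = 1), lower_bound = -Inf, upper_bound = Inf),
    reaction("F2", c(A_c = -1), lower_bound = -Inf, upper_bound = Inf)
  ), objective = "F2")
  expect_equal(solve_fba(unb)$status, "unbounded")
})

test_that("scaling all bounds scales the optimum; duplicate columns change nothing", {
  m <- branched_model(10, c(0.5, 0.8))
  base <- solve_fba(m)$objective_value
  for (k in c(0.5, 2, 7)) {
    ms <- m
    for (id in reaction_ids(ms)) {
      r <- ms$reactions[[id]]
      ms <- set_bounds(ms, id, lower = r$lower_bound * k,
                       upper = r$upper_bound * k)
    }
    expect_equal(solve_fba(ms)$objective_value, base * k, tolerance = 1e-8)
  }
  dup <- add_reaction(m, reaction("RB_copy", c(S_c = -1, X_c = 0.8),
                                  lower_bound = 0))
  expect_equal(solve_fba(dup)$objective_value, base, tolerance = 1e-9)
})

test_that("pFBA keeps the optimum, minimises total flux, and kills futile cycles", {
  # two parallel equivalent routes: pFBA total equals the single-route total
  par <- metabolic_model(list(
    reaction("UP", c(A_c = 1), lower_bound = 0, upper_bound = 10),
    reaction("P1", c(A_c = -1, B_c = 1), lower_bound = 0),
    reaction("P2", c(A_c = -1, B_c = 1), lower_bound = 0),
    reaction("OUT", c(B_c = -1), lower_bound = 0)
  ), objective = "OUT")
  p <- solve_pfba(par)
  expect_equal(p$objective_value, 10)
  expect_equal(total_flux(p), 30)  # UP + (P1|P2 split) + OUT, never double

  # chain model: unique optimum, pFBA == FBA
  ch <- chain_model()
  expect_equal(solve_pfba(ch)$fluxes, solve_fba(ch)$fluxes, tolerance = 1e-9)

  # zero-gain cycle C1/C2 can spin at FBA optima; pFBA must silence it
  cyc <- metabolic_model(list(
    reaction("UP", c(A_c = 1), lower_bound = 0, upper_bound = 10),
    reaction("C1", c(A_c = -1, B_c = 1), lower_bound = -1000),
    reaction("C2", c(B_c = -1, A_c = 1), lower_bound = -1000),
    reaction("OUT", c(A_c = -1), lower_bound = 0)
  ), objective = "OUT")
  pc <- solve_pfba(cyc)
  expect_equal(pc$objective_value, 10)
  expect_lt(abs(pc$fluxes[["C1"]]), 1e-8)
  expect_lt(abs(pc$fluxes[["C2"]]), 1e-8)
  # independent check: minimal total flux is UP + OUT = 20
  expect_equal(total_flux(pc), 20, tolerance = 1e-8)
})

test_that("pFBA total flux never exceeds the FBA total", {
  for (seed in 1:4) {
    m <- make_random_feasible_model(n_mets = 8, n_rxns = 16, seed = seed)$model
    expect_lte(total_flux(solve_pfba(m)), total_flux(solve_fba(m)) + 1e-8)
  }
})

test_that("growth-rate prediction is linear in the uptake bound", {
  toy <- make_toy_core_model(uptake_bound = 10, yields = c(0.5, 0.8))
  Y <- toy$optimum$best_yield
  for (u in c(0, 1, 2.5, 5, 10)) {
    pred <- predict_growth_rate(toy$model, "EX_glc_e", u)
    expect_equal(pred$mu, u * Y, tolerance = 1e-8)
  }
})

test_that("growth calls respect the threshold and solver status", {
  toy <- make_toy_core_model()
  grown <- predict_growth_rate(toy$model, "EX_glc_e", 10)
  expect_true(growth_call(grown))
  starved <- predict_growth_rate(toy$model, "EX_glc_e", 0)
  expect_equal(starved$mu, 0)
  expect_false(growth_call(starved))
  fake <- structure(list(status = "infeasible", objective_value = NA_real_),
                    class = "flux_solution")
  expect_false(growth_call(fake))
  mu_small <- structure(list(status = "optimal", objective_value = 0.117),
                        class = "flux_solution")
  expect_true(growth_call(mu_small, growth_threshold = 1e-6))
})
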