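scan_toy <- function(coupling, uptake = 10, n_steps = 10) {
  toy <- make_toy_core_model(include_product_branch = TRUE,
                             coupling = coupling, uptake_bound = uptake)
  med <- toy$medium
  med$carbon_exchange_id <- "EX_glc_e"
  conf <- configure_medium(toy$model, med)
  list(toy = toy,
       scan = run_fseof(conf, "DM_product_c", n_steps = n_steps,
                        carbon_source = "glc"))
}

test_that("the product demand scans with slope one and planted couplings are recovered", {
  for (cpl in c(0.5, 1, 2, 5)) {
    s <- scan_toy(cpl)
    rec <- s$scan$records
    expect_equal(rec$slope[rec$reaction_id == "DM_product_c"], 1,
                 tolerance = 1e-6)
    expect_equal(rec$slope[rec$reaction_id == "CARB"], cpl,
                 tolerance = 1e-6)
    expect_true(rec$reported[rec$reaction_id == "CARB"])
    expect_equal(s$scan$v_prod_max, s$toy$optimum$product_max,
                 tolerance = 1e-8)
  }
})

test_that("per-step fluxes match an independent LP at each enforcement level", {
  s <- scan_toy(2)
  conf <- {
    toy <- s$toy
    med <- toy$medium; med$carbon_exchange_id <- "EX_glc_e"
    configure_medium(toy$model, med)
  }
  for (k in seq_along(s$scan$levels)) {
    lvl <- s$scan$levels[k]
    m <- set_bounds(conf, "DM_product_c", lower = lvl)
    lp <- lp_of_model(m)
    oracle <- scipy_fba(m)
    expect_equal(unname(s$scan$step_fluxes["Biomass_reaction_1", k]),
                 oracle$objective, tolerance = 1e-6)
    # the planted coupling holds step by step
    expect_equal(unname(s$scan$step_fluxes["CARB", k]), 2 * lvl,
                 tolerance = 1e-6)
  }
})

test_that("biomass is non-increasing along the enforcement grid and level zero reproduces pFBA", {
  s <- scan_toy(2)
  mu <- s$scan$step_fluxes["Biomass_reaction_1", ]
  expect_true(all(diff(mu) <= 1e-8))
  toy <- s$toy
  med <- toy$medium; med$carbon_exchange_id <- "EX_glc_e"
  conf <- configure_medium(toy$model, med)
  base <- solve_pfba(conf)
  expect_equal(unname(s$scan$step_fluxes[, 1]), unname(base$fluxes),
               tolerance = 1e-7)
})

test_that("inactive reactions are excluded and unreachable products give empty scans", {
  s <- scan_toy(2)
  rec <- s$scan$records
  # the unused low-yield route never carries flux
  expect_false(rec$reported[rec$reaction_id == "ROUTE1"])

  toy <- make_toy_core_model(include_product_branch = TRUE, coupling = 2)
  med <- toy$medium; med$carbon_exchange_id <- "EX_glc_e"
  conf <- configure_medium(toy$model, med)
  blocked <- set_bounds(conf, "PSYN", upper = 0)
  scan <- run_fseof(blocked, "DM_product_c")
  expect_equal(nrow(scan$records), 0)
  expect_match(scan$reason, "unreachable")

  starved <- set_bounds(conf, "EX_glc_e", lower = 0)
  expect_match(run_fseof(starved, "DM_product_c")$reason, "no growth")
})

test_that("aggregation applies both retention filters", {
  rec <- function(src, rxn, slope) {
    data.frame(carbon_source = src, reaction_id = rxn, slope = slope,
               monotone_increasing = TRUE, reported = TRUE,
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    do.call(rbind, lapply(paste0("s", 1:6), rec, rxn = "good", slope = 2.5)),
    do.call(rbind, lapply(paste0("s", 1:4), rec, rxn = "few", slope = 10)),
    do.call(rbind, lapply(paste0("s", 1:6), rec, rxn = "flat", slope = 1.5))
  )
  tg <- aggregate_fseof(records, min_sources = 5, slope_threshold = 2)
  expect_equal(tg$retained$reaction_id, "good")
  expect_equal(tg$retained$n_sources_reported, 6L)
  expect_false("few" %in% tg$slope_long$reaction_id)   # fails min_sources
  expect_false("flat" %in% tg$slope_long$reaction_id)  # fails slope threshold
})

test_that("aggregation is order-invariant and monotone in its filters", {
  toy <- make_toy_core_model(include_product_branch = TRUE, coupling = 3,
                             carbon_sources = paste0("c", 1:6))
  scans <- lapply(paste0("c", 1:6), function(src) {
    med <- toy$medium
    med$carbon_exchange_id <- toy$exchange_map[[src]]
    run_fseof(configure_medium(toy$model, med), "DM_product_c",
              carbon_source = src)
  })
  t1 <- aggregate_fseof(scans, min_sources = 5, slope_threshold = 2)
  t2 <- aggregate_fseof(rev(scans), min_sources = 5, slope_threshold = 2)
  expect_equal(t1$retained, t2$retained)
  # the planted carboxylation-like reaction is reported in every medium
  expect_true("CARB" %in% t1$retained$reaction_id)
  expect_equal(t1$retained$n_sources_reported[
    t1$retained$reaction_id == "CARB"], 6L)
  # tightening either filter can only shrink the retained set
  for (ms in c(5, 6, 7)) {
    for (st in c(2, 2.5, 3.5)) {
      sub <- aggregate_fseof(scans, min_sources = ms, slope_threshold = st)
      expect_true(all(sub$retained$reaction_id %in% t1$retained$reaction_id))
    }
  }
  # re-aggregating the retained long table reproduces the same set
  again <- aggregate_fseof(
    transform(t1$slope_long, monotone_increasing = TRUE, reported = TRUE),
    min_sources = 5, slope_threshold = 2)
  expect_setequal(again$retained$reaction_id, t1$retained$reaction_id)
})

test_that("gene mapping unions GPRs and flags orphan reactions", {
  m <- metabolic_model(list(
    reaction("R1", c(A_c = -1, B_c = 1), lower_bound = 0, gpr = "g1 and g2"),
    reaction("R2", c(B_c = -1, C_c = 1), lower_bound = 0, gpr = "g2 or g3"),
    reaction("T1", c(C_c = -1, C_m = 1), lower_bound = 0, kind = "transport"),
    reaction("BM", c(C_m = -1), lower_bound = 0, kind = "biomass")
  ), objective = "BM")
  rec <- data.frame(
    carbon_source = rep(paste0("s", 1:5), each = 3),
    reaction_id = rep(c("R1", "R2", "T1"), 5),
    slope = 3, monotone_increasing = TRUE, reported = TRUE,
    stringsAsFactors = FALSE)
  tg <- map_targets_to_genes(aggregate_fseof(rec), m)
  expect_setequal(tg$gene_set, c("g1", "g2", "g3"))
  expect_equal(tg$orphan_reactions, "T1")
  expect_true(tg$retained$orphan_gpr[tg$retained$reaction_id == "T1"])
  # brute-force union oracle
  expect_equal(sort(tg$gene_set),
               sort(unique(unlist(lapply(c("R1", "R2"), function(r)
                 gpr_genes(parse_gpr(m$reactions[[r]]$gpr)))))))
})
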