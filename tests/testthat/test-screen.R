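test_that("majority rule requires two positive replicates of three", {
  expect_true(biolog_majority_call(c(TRUE, TRUE, FALSE)))
  expect_true(biolog_majority_call(c(TRUE, TRUE, TRUE)))
  expect_false(biolog_majority_call(c(TRUE, FALSE, FALSE)))
  expect_false(biolog_majority_call(c(FALSE, FALSE, FALSE)))
  expect_true(biolog_majority_call(TRUE, min_positive = 1))
})

test_that("medium configuration opens only the listed exchanges", {
  toy <- make_toy_core_model(carbon_sources = c("glc", "xyl"))
  med <- toy$medium
  med$carbon_exchange_id <- "EX_glc_e"
  conf <- configure_medium(toy$model, med)
  expect_equal(conf$reactions[["EX_glc_e"]]$lower_bound, -10)
  # the other carbon source is closed for uptake, secretion stays open
  expect_equal(conf$reactions[["EX_xyl_e"]]$lower_bound, 0)
  expect_gt(conf$reactions[["EX_xyl_e"]]$upper_bound, 0)
  expect_equal(conf$reactions[["EX_nh4_e"]]$lower_bound, -1000)
  # growth on the configured source, none when it is shut afterwards
  expect_gt(solve_fba(conf)$objective_value, 0)
  shut <- set_bounds(conf, "EX_glc_e", lower = 0)
  expect_equal(solve_fba(shut)$objective_value, 0)
  # the original model is untouched
  expect_equal(toy$model$reactions[["EX_xyl_e"]]$lower_bound, 0)

  med$carbon_exchange_id <- "EX_mystery_e"
  expect_error(configure_medium(toy$model, med), "missing transporter|exchange")
})

test_that("screening recovers a planted confusion structure exactly", {
  toy <- make_toy_core_model(carbon_sources = paste0("c", 1:8))
  planted <- c(both_growth = 5, both_no_growth = 4,
               false_no_growth = 2, false_growth = 3)
  panel <- make_phenotype_panel(toy$model, toy$exchange_map, planted,
                                n_sources = 14, seed = 11)
  res <- screen_carbon_sources(toy$model, panel$plate, panel$exchange_map,
                               medium_template = toy$medium)
  expect_equal(res$counts, planted)
  expect_equal(res$agreement_percent, 100 * 9 / 14)
  expect_equal(sum(res$counts), nrow(panel$plate))
  # per-source categories match the generator's ground truth
  merged <- merge(res$per_source, panel$truth, by = "source")
  expect_equal(merged$in_vitro,
               merged$category %in% c("both_growth", "false_no_growth"))
  expect_equal(merged$in_silico,
               merged$category %in% c("both_growth", "false_growth"))
})

test_that("agreement is invariant under plate row permutation", {
  toy <- make_toy_core_model(carbon_sources = paste0("c", 1:6))
  panel <- make_phenotype_panel(
    toy$model, toy$exchange_map,
    planted = c(both_growth = 4, both_no_growth = 3,
                false_no_growth = 1, false_growth = 2),
    n_sources = 10, seed = 3)
  res1 <- screen_carbon_sources(toy$model, panel$plate, panel$exchange_map,
                                medium_template = toy$medium)
  perm <- panel$plate[sample(nrow(panel$plate)), ]
  class(perm) <- class(panel$plate)
  res2 <- screen_carbon_sources(toy$model, perm, panel$exchange_map,
                                medium_template = toy$medium)
  expect_equal(res2$agreement_percent, res1$agreement_percent)
  expect_equal(res2$counts, res1$counts)
})

test_that("sources without a mapped exchange are structural no-growth", {
  toy <- make_toy_core_model()
  plate <- plate_table(c("glc", "unobtainium"),
                       c("carbohydrate", "other"),
                       matrix(TRUE, 2, 3))
  res <- screen_carbon_sources(toy$model, plate, toy$exchange_map,
                               medium_template = toy$medium)
  row <- res$per_source[res$per_source$source == "unobtainium", ]
  expect_false(row$in_silico)
  expect_equal(row$reason, "no_exchange")
  expect_equal(res$counts[["false_no_growth"]], 1L)
})

test_that("degenerate confusion structures give 100% and 0% agreement", {
  toy <- make_toy_core_model(carbon_sources = paste0("c", 1:10))
  perfect <- make_phenotype_panel(
    toy$model, toy$exchange_map,
    planted = c(both_growth = 10, both_no_growth = 10,
                false_no_growth = 0, false_growth = 0),
    n_sources = 20, seed = 4)
  expect_equal(screen_carbon_sources(toy$model, perfect$plate,
                                     perfect$exchange_map,
                                     medium_template = toy$medium)$agreement_percent,
               100)
  awful <- make_phenotype_panel(
    toy$model, toy$exchange_map,
    planted = c(both_growth = 0, both_no_growth = 0,
                false_no_growth = 5, false_growth = 5),
    n_sources = 10, seed = 5)
  expect_equal(screen_carbon_sources(toy$model, awful$plate,
                                     awful$exchange_map,
                                     medium_template = toy$medium)$agreement_percent,
               0)
  expect_error(screen_carbon_sources(
    toy$model, plate_table(character(0), character(0),
                           matrix(logical(0), 0, 3)),
    toy$exchange_map, medium_template = toy$medium), "replicate|empty")
})
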