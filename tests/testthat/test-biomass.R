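test_that("the published composition validates up to known rounding residuals", {
  comp <- umbelopsis_biomass_composition()
  findings <- validate_composition(comp, tolerance = 1e-9)
  # macromolecule fractions 2.5/5/35/40/17.5 sum exactly to 100%
  expect_false("macromolecules" %in% findings$scope)
  # printed component tables carry small rounding residuals
  expect_true("Protein" %in% findings$scope)
  expect_equal(findings$residual[findings$scope == "Protein"], 0.0009,
               tolerance = 1e-9)
  expect_true("Lipids" %in% findings$scope)
  expect_equal(findings$residual[findings$scope == "Lipids"], 0.002,
               tolerance = 1e-9)
  # a generous tolerance accepts the table as printed
  expect_equal(nrow(validate_composition(comp, tolerance = 0.01)), 0L)
})

test_that("a trivially normalised composition passes strict validation", {
  comp <- biomass_composition(
    macromolecules = c(Protein = 1),
    components = list(Protein = c(Glycine = 1)),
    molecular_weights = c(Glycine = 57.05))
  expect_equal(nrow(validate_composition(comp)), 0L)
})

test_that("coefficients follow the closed form 1000 * f_macro * f_comp / MW", {
  comp <- biomass_composition(
    macromolecules = c(M = 1),
    components = list(M = c(X = 1)),
    molecular_weights = c(X = 100))
  br <- compose_biomass(comp)
  expect_equal(unname(br$component_coefficients["X"]), -10)  # 10 mmol x 100 mg/mmol
  expect_equal(br$mass_mg, 1000, tolerance = 1e-9)

  full <- suppressWarnings(compose_biomass(umbelopsis_biomass_composition()))
  w <- reference_component_weights()
  # leucine drain: renormalised protein share of 35% dry weight
  prot <- umbelopsis_biomass_composition()$components$Protein
  f_leu <- prot[["Leucine"]] / sum(prot)
  expect_equal(unname(full$component_coefficients["Leucine"]),
               -1000 * 0.35 * f_leu / w[["Leucine"]], tolerance = 1e-12)
})

test_that("biomass drains account for exactly one gram of dry weight", {
  br <- suppressWarnings(compose_biomass(umbelopsis_biomass_composition()))
  w <- reference_component_weights()
  # independent summation oracle
  expect_equal(sum(abs(br$component_coefficients) * w[names(br$component_coefficients)]),
               1000, tolerance = 1e-6)
})

test_that("growth-associated maintenance enters at the configured stoichiometry", {
  br <- suppressWarnings(compose_biomass(umbelopsis_biomass_composition(gam_atp = 153)))
  expect_equal(unname(br$coefficients["atp_c"]), -153)
  expect_equal(unname(br$coefficients["h2o_c"]), -153)
  expect_equal(unname(br$coefficients["adp_c"]), 153)
  expect_equal(unname(br$coefficients["pi_c"]), 153)
  expect_equal(br$gam_atp, 153)
})

test_that("scaling weights by k scales coefficients by 1/k; order is irrelevant", {
  comp <- biomass_composition(
    macromolecules = c(A = 0.6, B = 0.4),
    components = list(A = c(x = 0.5, y = 0.5), B = c(z = 1)),
    molecular_weights = c(x = 100, y = 200, z = 50))
  b1 <- compose_biomass(comp)
  comp2 <- comp; comp2$molecular_weights <- comp$molecular_weights * 3
  b2 <- compose_biomass(comp2)
  expect_equal(b2$component_coefficients, b1$component_coefficients / 3)
  expect_equal(b2$mass_mg, 1000, tolerance = 1e-9)

  compP <- biomass_composition(
    macromolecules = rev(comp$macromolecules),
    components = lapply(comp$components, rev)[c("B", "A")],
    molecular_weights = rev(comp$molecular_weights))
  bP <- compose_biomass(compP)
  nm <- names(b1$component_coefficients)
  expect_equal(bP$component_coefficients[nm], b1$component_coefficients[nm])
})

test_that("renormalisation equals composing the exactly-normalised table", {
  raw <- biomass_composition(
    macromolecules = c(A = 0.7, B = 0.3),
    components = list(A = c(x = 0.55, y = 0.46), B = c(z = 1)),  # sums 1.01
    molecular_weights = c(x = 100, y = 200, z = 50))
  exact <- raw
  exact$components$A <- raw$components$A / sum(raw$components$A)
  expect_warning(b_re <- compose_biomass(raw, renormalise = TRUE), "renormalising")
  b_ex <- compose_biomass(exact)
  expect_equal(b_re$component_coefficients, b_ex$component_coefficients)
  expect_error(compose_biomass(raw, renormalise = FALSE), "not normalised")
})

test_that("missing molecular weights are reported by component name", {
  comp <- biomass_composition(
    macromolecules = c(A = 1),
    components = list(A = c(mystery = 1)),
    molecular_weights = c(other = 10))
  expect_error(compose_biomass(comp), "mystery")
})

test_that("the composed reaction slots into a model", {
  br <- suppressWarnings(compose_biomass(umbelopsis_biomass_composition()))
  rxn <- biomass_to_reaction(br)
  expect_s3_class(rxn, "of_reaction")
  expect_equal(rxn$kind, "biomass")
  # the RNA precursor ATP and the GAM ATP share the atp_c species, so the
  # assembled drain is their sum
  expect_equal(unname(rxn$stoichiometry["atp_c"]),
               -153 + br$component_coefficients[["ATP"]])
  expect_equal(unname(rxn$stoichiometry["biomass_c"]), 1)
})
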