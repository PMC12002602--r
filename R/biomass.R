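#' Biomass composition container
#'
#' Describes the macromolecular make-up of one gram of dry biomass: the mass
#' fraction of each macromolecule class, the within-class mass fraction of
#' each component, polymer-residue molecular weights, and the
#' growth-associated maintenance (GAM) ATP cost.
#'
#' @param macromolecules Named numeric vector of dry-weight mass fractions
#'   (must sum to 1).
#' @param components Named list: macromolecule -> named numeric vector of
#'   within-class mass fractions (each must sum to 1).
#' @param molecular_weights Named numeric vector, component -> g/mol.
#'   Polymer-residue weights (monomer minus water) where the component is
#'   polymerised into the macromolecule.
#' @param gam_atp Growth-associated maintenance, mmol ATP hydrolysed per gDW
#'   of biomass formed.
#' @return An object of class `biomass_composition`.
#' @export
biomass_composition <- function(macromolecules, components, molecular_weights,
                                gam_atp = 0) {
  stopifnot(is.numeric(macromolecules), !is.null(names(macromolecules)),
            is.list(components), gam_atp >= 0)
  missing_cls <- setdiff(names(macromolecules), names(components))
  if (length(missing_cls) > 0L) {
    stop("no component breakdown for: ", paste(missing_cls, collapse = ", "))
  }
  structure(
    list(macromolecules = macromolecules, components = components,
         molecular_weights = molecular_weights, gam_atp = gam_atp),
    class = "biomass_composition"
  )
}

#' Validate a biomass composition
#'
#' Checks that the macromolecule fractions and every within-class breakdown
#' sum to one, that weights are positive and GAM non-negative. Findings are
#' returned, not raised.
#'
#' @param composition A `biomass_composition`.
#' @param tolerance Allowed absolute residual on each sum.
#' @return Data frame of findings (`scope`, `residual`, `message`); zero rows
#'   means the composition is exactly normalised.
#' @export
validate_composition <- function(composition, tolerance = 1e-9) {
  findings <- list()
  add <- function(scope, residual, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      scope = scope, residual = residual, message = message,
      stringsAsFactors = FALSE)
  }
  res <- sum(composition$macromolecules) - 1
  if (abs(res) > tolerance) {
    add("macromolecules", res,
        sprintf("macromolecule fractions sum to %.6f, not 1", 1 + res))
  }
  for (cls in names(composition$components)) {
    res <- sum(composition$components[[cls]]) - 1
    if (abs(res) > tolerance) {
      add(cls, res, sprintf("'%s' breakdown sums to %.6f, not 1", cls, 1 + res))
    }
  }
  bad_w <- names(composition$molecular_weights)[composition$molecular_weights <= 0]
  for (w in bad_w) add(w, NA_real_, sprintf("non-positive molecular weight for '%s'", w))
  if (composition$gam_atp < 0) add("gam", NA_real_, "negative GAM")
  if (length(findings) == 0L) {
    data.frame(scope = character(0), residual = numeric(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}

#' Compose a biomass reaction from a composition table
#'
#' Converts mass fractions into molar drain coefficients: a component with
#' within-class fraction `f_comp` of a macromolecule at dry-weight fraction
#' `f_macro` and residue weight `MW` (g/mol) is consumed at
#' `1000 * f_macro * f_comp / MW` mmol per gDW, so that the drains together
#' account for exactly 1000 mg of biomass per gDW. GAM adds
#' `ATP + H2O -> ADP + Pi + H+` at `gam_atp` mmol/gDW.
#'
#' @param composition A `biomass_composition`.
#' @param renormalise If `TRUE` (default), within-class breakdowns and the
#'   macromolecule vector are rescaled to sum exactly to one before
#'   composing (published composition tables often carry rounding residuals
#'   of ~0.1%); a warning reports what was rescaled. If `FALSE`, any residual
#'   beyond `tolerance` is an error.
#' @param tolerance Residual tolerance when `renormalise = FALSE`.
#' @return An object of class `biomass_reaction`: `coefficients` (named,
#'   mmol/gDW, negative = consumed; includes the GAM metabolites),
#'   `component_coefficients` (precursor drains only), `gam_atp`, and
#'   `mass_mg` (the mass-closure check, mg accounted per gDW).
#' @export
compose_biomass <- function(composition, renormalise = TRUE, tolerance = 1e-9) {
  findings <- validate_composition(composition, tolerance)
  sum_findings <- findings[!is.na(findings$residual), , drop = FALSE]
  if (nrow(findings) > nrow(sum_findings)) {
    stop("invalid composition: ",
         paste(findings$message[is.na(findings$residual)], collapse = "; "))
  }
  macro <- composition$macromolecules
  comps <- composition$components
  if (nrow(sum_findings) > 0L) {
    if (!renormalise) {
      stop("composition not normalised (",
           paste(sum_findings$message, collapse = "; "),
           "); pass renormalise = TRUE to rescale")
    }
    warning("renormalising: ", paste(sum_findings$scope, collapse = ", "))
    macro <- macro / sum(macro)
    comps <- lapply(comps, function(v) v / sum(v))
  }
  mw <- composition$molecular_weights
  coef <- numeric(0)
  for (cls in names(macro)) {
    for (comp in names(comps[[cls]])) {
      if (!comp %in% names(mw)) {
        stop("no molecular weight for component '", comp, "'")
      }
      contrib <- -1000 * macro[[cls]] * comps[[cls]][[comp]] / mw[[comp]]
      coef[comp] <- if (comp %in% names(coef)) coef[comp] + contrib else contrib
    }
  }
  mass_mg <- sum(abs(coef) * mw[names(coef)])
  gam <- composition$gam_atp
  gam_coef <- c(atp_c = -gam, h2o_c = -gam, adp_c = gam, pi_c = gam, h_c = gam)
  structure(
    list(coefficients = c(coef, gam_coef),
         component_coefficients = coef,
         gam_atp = gam,
         mass_mg = mass_mg),
    class = "biomass_reaction"
  )
}

#' @export
print.biomass_reaction <- function(x, ...) {
  cat(sprintf("<biomass_reaction: %d precursors, %.6f mg/gDW accounted, GAM %g mmol ATP/gDW>\n",
              length(x$component_coefficients), x$mass_mg, x$gam_atp))
  invisible(x)
}

#' Convert a composed biomass reaction into a model reaction
#'
#' @param br A `biomass_reaction`.
#' @param id Reaction id (default `Biomass_reaction_1`, the conventional
#'   name in fungal reconstructions).
#' @param species_map Optional named character vector mapping component
#'   names to metabolite ids; unmapped components get
#'   `tolower(gsub(" ", "_", name))` plus a `_c` suffix.
#' @return A [reaction()] of kind `biomass` draining the precursors and GAM
#'   metabolites and producing ADP/Pi/H+ plus one unit of a `biomass_c`
#'   pseudo-metabolite.
#' @export
biomass_to_reaction <- function(br, id = "Biomass_reaction_1",
                                species_map = character(0)) {
  stopifnot(inherits(br, "biomass_reaction"))
  nm <- names(br$coefficients)
  ids <- ifelse(nm %in% names(species_map), species_map[nm],
                ifelse(grepl("_c$", nm), nm,
                       paste0(tolower(gsub("[ -]", "_", nm)), "_c")))
  stoich <- setNames(as.numeric(br$coefficients), ids)
  stoich <- tapply(stoich, names(stoich), sum)   # merge collided ids
  stoich <- setNames(as.numeric(stoich), names(stoich))
  stoich["biomass_c"] <- 1
  reaction(id, stoich, lower_bound = 0, upper_bound = 1000, kind = "biomass")
}

#' Published biomass composition of an oleaginous Umbelopsis-type fungus
#'
#' Macromolecular dry-weight fractions and within-class breakdowns as
#' experimentally curated for a lipid-accumulating filamentous fungus: DNA
#' 2.5%, RNA 5%, protein 35%, lipids 40%, carbohydrates 17.5%. Component
#' breakdowns are as printed in the source table; note that the protein
#' entries sum to 100.09%, the lipid entries to 100.2% and the RNA entries
#' to 99.9% — rounding residuals that [compose_biomass()] renormalises by
#' default.
#'
#' @param gam_atp Growth-associated maintenance (mmol ATP/gDW); the curated
#'   value is 153.
#' @param molecular_weights Component weights; defaults to
#'   [reference_component_weights()].
#' @return A `biomass_composition`.
#' @export
umbelopsis_biomass_composition <- function(gam_atp = 153,
                                           molecular_weights = reference_component_weights()) {
  biomass_composition(
    macromolecules = c(DNA = 0.025, RNA = 0.05, Protein = 0.35,
                       Lipids = 0.40, Carbohydrates = 0.175),
    components = list(
      DNA = c(dATP = 0.286, dCTP = 0.224, dGTP = 0.196, dTTP = 0.294),
      RNA = c(ATP = 0.264, CTP = 0.252, GTP = 0.201, UTP = 0.282),
      Protein = c(
        Alanine = 0.076, Arginine = 0.052, Asparagine = 0.047,
        `Aspartic acid` = 0.060, Cysteine = 0.012, Glutamate = 0.064,
        Glutamine = 0.046, Glycine = 0.057, Histidine = 0.024,
        Isoleucine = 0.057, Leucine = 0.088, Lysine = 0.0589,
        Methionine = 0.024, Phenylalanine = 0.037, Proline = 0.051,
        Serine = 0.083, Threonine = 0.059, Tryptophan = 0.012,
        Tyrosine = 0.032, Valine = 0.061),
      Lipids = c(
        Triglycerides = 0.846, Diglycerides = 0.048,
        `Free fatty acids` = 0.048, Sterols = 0.010,
        Phosphatidylethanolamines = 0.007, Phosphatidylcholines = 0.028,
        Phosphatidylinositols = 0.007, Phosphatidylserines = 0.006,
        `Phosphatidic acid` = 0.002),
      Carbohydrates = c(Fucose = 0.237, Glucosamine = 0.429,
                        Galactose = 0.041, Glucose = 0.268, Mannose = 0.025)
    ),
    molecular_weights = molecular_weights,
    gam_atp = gam_atp
  )
}

#' Reference residue molecular weights for biomass components
#'
#' Polymer-residue masses (monomer minus water) for nucleotides, amino acids
#' and sugars, and representative-species masses for lipid classes (e.g.
#' trioleoylglycerol for triglycerides, ergosterol for sterols). These are
#' reasonable defaults shipped as data, not ground truth: callers modelling
#' a specific organism should supply their own table reflecting its acyl
#' chain and sugar composition.
#'
#' @return Named numeric vector, component -> g/mol.
#' @export
reference_component_weights <- function() {
  c(
    # DNA residues (dNMP - H2O)
    dATP = 313.21, dCTP = 289.18, dGTP = 329.21, dTTP = 304.20,
    # RNA residues (NMP - H2O)
    ATP = 329.21, CTP = 305.18, GTP = 345.21, UTP = 306.17,
    # amino-acid residues
    Alanine = 71.08, Arginine = 156.19, Asparagine = 114.10,
    `Aspartic acid` = 115.09, Cysteine = 103.14, Glutamate = 129.12,
    Glutamine = 128.13, Glycine = 57.05, Histidine = 137.14,
    Isoleucine = 113.16, Leucine = 113.16, Lysine = 128.17,
    Methionine = 131.19, Phenylalanine = 147.18, Proline = 97.12,
    Serine = 87.08, Threonine = 101.10, Tryptophan = 186.21,
    Tyrosine = 163.18, Valine = 99.13,
    # lipid classes, representative species
    Triglycerides = 885.43, Diglycerides = 620.99,
    `Free fatty acids` = 280.45, Sterols = 396.65,
    Phosphatidylethanolamines = 744.03, Phosphatidylcholines = 786.11,
    Phosphatidylinositols = 886.56, Phosphatidylserines = 788.00,
    `Phosphatidic acid` = 700.97,
    # carbohydrate residues (sugar - H2O)
    Fucose = 146.14, Glucosamine = 161.16, Galactose = 162.14,
    Glucose = 162.14, Mannose = 162.14
  )
}
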