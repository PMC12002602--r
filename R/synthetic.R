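# Synthetic instances with known ground truth: every stage of the pipeline
# (FBA, screening, activity pooling, FSEOF) can be exercised against
# closed-form expectations without any external model download.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Toy core metabolic network with known optima
#'
#' A small feasible network emulating the glucose-to-lipid core of an
#' oleaginous fungus: carbon sources are taken up and funnelled into a
#' central carbon pool, two routes convert the pool into a biomass precursor
#' at different yields, and biomass formation additionally drains ammonium
#' and phosphate (so the minimal-medium configuration matters).
#'
#' With `include_product_branch = TRUE` the network gains a fatty-acid-like
#' product: a carboxylation-like reaction `CARB` (`cc_c -> mal_c`) feeds a
#' synthesis reaction that consumes `coupling` units of `mal_c` plus one
#' unit of central carbon per unit product, and a demand `DM_product_c`
#' secretes it. The planted FSEOF slope of `CARB` is therefore exactly
#' `coupling`, and the maximal product flux is
#' `uptake_bound / (coupling + 1)`.
#'
#' @param uptake_bound Carbon uptake bound, mmol/gDW/h.
#' @param yields Per-route biomass yields (the best one sets the optimum).
#' @param include_product_branch Add the planted product branch.
#' @param coupling Stoichiometric coupling of the planted reaction to the
#'   product (mol per mol product).
#' @param carbon_sources Character vector of carbon-source names; each gets
#'   an exchange, a transporter and a funnel reaction into the central pool.
#' @return A list: `model` (a `metabolic_model`), `optimum` (closed-form
#'   record: `mu_max`, `best_yield`, `product_max`, `planted_slope`,
#'   `planted_reaction`), `exchange_map` (source -> exchange id), `medium`
#'   (a matching [medium_spec()] template).
#' @export
make_toy_core_model <- function(uptake_bound = 10, yields = c(0.5, 0.8),
                                include_product_branch = FALSE, coupling = 2,
                                carbon_sources = "glc") {
  stopifnot(uptake_bound > 0, all(yields > 0), coupling > 0,
            length(carbon_sources) >= 1L)
  rxns <- list(
    reaction("EX_nh4_e", c(nh4_e = -1), lower_bound = -1000, kind = "exchange"),
    reaction("EX_pi_e", c(pi_e = -1), lower_bound = -1000, kind = "exchange"),
    reaction("T_nh4", c(nh4_e = -1, nh4_c = 1), lower_bound = 0, kind = "transport"),
    reaction("T_pi", c(pi_e = -1, pi_c = 1), lower_bound = 0, kind = "transport")
  )
  for (i in seq_along(yields)) {
    rxns <- c(rxns, list(reaction(
      paste0("ROUTE", i), setNames(c(-1, yields[i]), c("cc_c", "prec_c")),
      lower_bound = 0, gpr = paste0("gR", i, "a and gR", i, "b"))))
  }
  rxns <- c(rxns, list(reaction(
    "Biomass_reaction_1",
    c(prec_c = -1, nh4_c = -0.1, pi_c = -0.02, biomass_c = 1),
    lower_bound = 0, kind = "biomass"),
    reaction("DM_biomass_c", c(biomass_c = -1), lower_bound = 0,
             kind = "demand")))
  for (s in carbon_sources) {
    rxns <- c(rxns, list(
      reaction(paste0("EX_", s, "_e"), setNames(-1, paste0(s, "_e")),
               lower_bound = 0, kind = "exchange"),
      reaction(paste0("T_", s), setNames(c(-1, 1), paste0(s, c("_e", "_c"))),
               lower_bound = 0, kind = "transport",
               gpr = paste0("gT_", s)),
      reaction(paste0("FUNNEL_", s), setNames(c(-1, 1), c(paste0(s, "_c"), "cc_c")),
               lower_bound = 0, gpr = paste0("gF_", s))))
  }
  planted <- NULL
  if (include_product_branch) {
    rxns <- c(rxns, list(
      reaction("CARB", c(cc_c = -1, mal_c = 1), lower_bound = 0,
               gpr = "gACC1 and gACC2"),
      reaction("PSYN", setNames(c(-coupling, -1, 1), c("mal_c", "cc_c", "prod_c")),
               lower_bound = 0, gpr = "gFAS1 or gFAS2"),
      reaction("DM_product_c", c(prod_c = -1), lower_bound = 0,
               kind = "demand")))
    planted <- "CARB"
  }
  model <- metabolic_model(rxns, compartments = default_compartments(),
                           objective = "Biomass_reaction_1", id = "toy_core")
  first_ex <- paste0("EX_", carbon_sources[1L], "_e")
  model <- set_bounds(model, first_ex, lower = -uptake_bound)
  list(
    model = model,
    optimum = list(
      mu_max = uptake_bound * max(yields),
      best_yield = max(yields),
      product_max = if (include_product_branch)
        uptake_bound / (coupling + 1) else NA_real_,
      planted_slope = if (include_product_branch) coupling else NA_real_,
      planted_reaction = planted
    ),
    exchange_map = setNames(paste0("EX_", carbon_sources, "_e"),
                            carbon_sources),
    medium = medium_spec(
      free_exchange_ids = c("EX_nh4_e", "EX_pi_e"),
      carbon_uptake_bound = uptake_bound)
  )
}

#' Random feasible metabolic model
#'
#' Builds a network by laying a guaranteed-feasible backbone pathway from an
#' uptake exchange through every internal metabolite to the biomass
#' reaction (all unit stoichiometry), then adding random internal shortcut
#' reactions until `n_rxns` is reached. Because every reaction is 1:1 in the
#' backbone's carbon currency, the FBA optimum is exactly the uptake bound.
#' Deterministic per seed.
#'
#' @param n_mets Total number of metabolites (>= 2).
#' @param n_rxns Total number of reactions (> `n_mets`; a mass-balanced
#'   growing chain over m metabolites needs m + 1 reactions).
#' @param seed RNG seed.
#' @param uptake_bound Carbon uptake bound.
#' @return A list: `model`, `optimum` (`mu_max = uptake_bound`).
#' @export
make_random_feasible_model <- function(n_mets = 20L, n_rxns = 30L, seed = 1L,
                                       uptake_bound = 10) {
  if (n_mets < 2L) stop("n_mets must be >= 2")
  if (n_rxns < n_mets + 1L) {
    stop("n_rxns must be at least n_mets + 1 (got ", n_rxns, " for ",
         n_mets, " metabolites)")
  }
  with_seed(seed, {
    n_int <- n_mets - 1L                 # src_e plus internal chain mets
    ints <- c("src_c", if (n_int >= 2L) paste0("i", seq_len(n_int - 1L), "_c"))
    rxns <- list(
      reaction("EX_src_e", c(src_e = -1), lower_bound = -uptake_bound,
               kind = "exchange"),
      reaction("T_src", c(src_e = -1, src_c = 1), lower_bound = 0,
               kind = "transport", gpr = "g_t1")
    )
    chain <- ints
    for (k in seq_len(length(chain) - 1L)) {
      rxns <- c(rxns, list(reaction(
        paste0("B", k), setNames(c(-1, 1), chain[k + c(0L, 1L)]),
        lower_bound = 0, gpr = paste0("g_b", k))))
    }
    rxns <- c(rxns, list(reaction(
      "Biomass_reaction_1", setNames(-1, chain[length(chain)]),
      lower_bound = 0, kind = "biomass")))
    n_extra <- n_rxns - length(rxns)
    k <- 0L
    while (k < n_extra) {
      pair <- if (length(ints) >= 2L) sample(ints, 2L) else c("src_e", "src_c")
      k <- k + 1L
      rxns <- c(rxns, list(reaction(
        paste0("X", k), setNames(c(-1, 1), pair), lower_bound = 0,
        gpr = if (stats::runif(1) < 0.5)
          paste0("g_x", k) else paste0("(g_x", k, "a or g_x", k, "b)"))))
    }
    model <- metabolic_model(rxns, compartments = default_compartments(),
                             objective = "Biomass_reaction_1",
                             id = sprintf("random_m%d_r%d_s%d", n_mets, n_rxns, seed))
    list(model = model, optimum = list(mu_max = uptake_bound))
  })
}

#' Phenotype panel with planted confusion structure
#'
#' Generates a plate whose majority calls, screened against `model`, yield
#' exactly the planted 2x2 confusion counts:
#' * `both_growth`: plate-positive sources mapped to model exchanges that
#'   support growth;
#' * `both_no_growth`: plate-negative sources with no exchange in the model;
#' * `false_no_growth`: plate-positive sources with *no* exchange in the
#'   model (the missing-transporter situation);
#' * `false_growth`: plate-negative sources mapped to growth-supporting
#'   exchanges.
#'
#' Replicate noise flips one replicate per affected source but only where
#' it cannot change the majority call, so the planted counts are exact.
#'
#' @param model A `metabolic_model` whose carbon exchanges all support
#'   growth under `medium` (e.g. from [make_toy_core_model()]).
#' @param exchange_map Source -> exchange id map for the model's carbon
#'   sources (growth-capable sources to draw from).
#' @param planted Named integer vector with `both_growth`, `both_no_growth`,
#'   `false_no_growth`, `false_growth`.
#' @param n_sources Total panel size; must equal `sum(planted)`.
#' @param class_mix Named integer vector over [plate_classes()] summing to
#'   `n_sources`; the default is the 95-source split
#'   7/13/15/46/5/9.
#' @param replicates Replicates per source.
#' @param noise_rate Probability that a source's replicate vector carries
#'   one non-pivotal flipped replicate.
#' @param seed RNG seed.
#' @return A list: `plate` (a `plate_table`), `exchange_map` (for the
#'   screen; unmappable sources absent), `truth` (data frame source,
#'   category).
#' @export
make_phenotype_panel <- function(model, exchange_map,
                                 planted = c(both_growth = 41L,
                                             both_no_growth = 36L,
                                             false_no_growth = 8L,
                                             false_growth = 10L),
                                 n_sources = sum(planted),
                                 class_mix = default_class_mix(n_sources),
                                 replicates = 3L, noise_rate = 0.2,
                                 seed = 1L) {
  stopifnot(all(c("both_growth", "both_no_growth", "false_no_growth",
                  "false_growth") %in% names(planted)),
            replicates >= 1L, noise_rate >= 0, noise_rate < 1)
  if (sum(planted) != n_sources) {
    stop("planted counts sum to ", sum(planted), ", not n_sources = ", n_sources)
  }
  if (sum(class_mix) != n_sources) {
    stop("class mix sums to ", sum(class_mix), ", not n_sources = ", n_sources)
  }
  n_growable <- planted[["both_growth"]] + planted[["false_growth"]]
  if (n_growable > length(exchange_map)) {
    stop("planted spec needs ", n_growable,
         " growth-capable sources but the model offers ", length(exchange_map))
  }
  with_seed(seed, {
    growable <- names(exchange_map)[seq_len(n_growable)]
    cat_tp <- growable[seq_len(planted[["both_growth"]])]
    cat_fp <- setdiff(growable, cat_tp)
    n_unmapped <- planted[["both_no_growth"]] + planted[["false_no_growth"]]
    unmapped <- sprintf("u%02d", seq_len(n_unmapped))
    cat_fn <- unmapped[seq_len(planted[["false_no_growth"]])]
    cat_tn <- setdiff(unmapped, cat_fn)
    sources <- c(cat_tp, cat_fp, cat_fn, cat_tn)
    category <- c(rep("both_growth", length(cat_tp)),
                  rep("false_growth", length(cat_fp)),
                  rep("false_no_growth", length(cat_fn)),
                  rep("both_no_growth", length(cat_tn)))
    ord <- sample(length(sources))
    sources <- sources[ord]; category <- category[ord]
    classes <- rep(names(class_mix), class_mix)[seq_along(sources)]
    positive <- category %in% c("both_growth", "false_no_growth")
    calls <- matrix(FALSE, length(sources), replicates)
    for (i in seq_along(sources)) {
      base <- rep(positive[i], replicates)
      if (replicates >= 3L && stats::runif(1) < noise_rate) {
        base[replicates] <- !base[replicates]  # non-pivotal flip
      }
      calls[i, ] <- base
    }
    list(
      plate = plate_table(sources, classes, calls),
      exchange_map = exchange_map[intersect(names(exchange_map),
                                            c(cat_tp, cat_fp))],
      truth = data.frame(source = sources, category = category,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Default substrate-class mix for a phenotype panel
#'
#' For a 95-source panel this is the canonical split 7 amines/amides, 13
#' amino acids, 15 carboxylic acids, 46 carbohydrates, 5 polymers and 9
#' other compounds; other sizes scale proportionally.
#'
#' @param n_sources Panel size.
#' @return Named integer vector over [plate_classes()] summing to
#'   `n_sources`.
#' @export
default_class_mix <- function(n_sources = 95L) {
  base <- c("amine/amide" = 7L, "amino acid" = 13L, "carboxylic acid" = 15L,
            carbohydrate = 46L, polymer = 5L, other = 9L)
  if (n_sources == 95L) return(base)
  scaled <- floor(base * n_sources / 95)
  rem <- n_sources - sum(scaled)
  if (rem > 0L) {
    top <- order(base * n_sources / 95 - scaled, decreasing = TRUE)[seq_len(rem)]
    scaled[top] <- scaled[top] + 1L
  }
  scaled
}
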