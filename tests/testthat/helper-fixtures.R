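# Fixture models built in code.

# linear chain: uptake -> A -> B -> secretion, bottleneck on the uptake
chain_model <- function(uptake = 10) {
  metabolic_model(
    list(
      reaction("R1", c(A_c = 1), lower_bound = 0, upper_bound = uptake,
               kind = "internal"),
      reaction("R2", c(A_c = -1, B_c = 1), lower_bound = 0),
      reaction("R3", c(B_c = -1), lower_bound = 0, kind = "internal")
    ),
    objective = "R3", id = "chain"
  )
}

# two routes of different yield competing for a shared uptake
branched_model <- function(uptake = 10, yields = c(0.5, 0.8)) {
  metabolic_model(
    list(
      reaction("UP", c(S_c = 1), lower_bound = 0, upper_bound = uptake),
      reaction("RA", c(S_c = -1, X_c = yields[1]), lower_bound = 0),
      reaction("RB", c(S_c = -1, X_c = yields[2]), lower_bound = 0),
      reaction("BM", c(X_c = -1), lower_bound = 0)
    ),
    objective = "BM", id = "branched"
  )
}

lp_of_model <- function(model, objective = model$objective) {
  list(
    S = oleoflux:::dense_stoich(model),
    obj = as.numeric(reaction_ids(model) == objective),
    lb = vapply(model$reactions, `[[`, 0, "lower_bound"),
    ub = vapply(model$reactions, `[[`, 0, "upper_bound")
  )
}
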