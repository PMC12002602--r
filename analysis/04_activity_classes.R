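#!/usr/bin/env Rscript
# Pool the flux distributions from the phenotype screen and classify each
# reaction by how often it carries flux: always active (core), active at
# least once (auxiliary), never active. The auxiliary set is subdivided at
# the 10%/90% activity thresholds into near-core, carbon-source-type
# related, and source-specific reactions.

suppressPackageStartupMessages(library(oleoflux))
dir.create("results", showWarnings = FALSE)

toy <- make_toy_core_model(carbon_sources = paste0("c", 1:51))
panel <- make_phenotype_panel(
  toy$model, toy$exchange_map,
  planted = c(both_growth = 41L, both_no_growth = 36L,
              false_no_growth = 8L, false_growth = 10L),
  n_sources = 95, seed = 1)
res <- screen_carbon_sources(toy$model, panel$plate, panel$exchange_map,
                             medium_template = toy$medium)

cat(sprintf("pooling %d feasible solutions\n", length(res$solutions)))
prof <- classify_reaction_activity(res$solutions)
print(prof)
write.table(prof$per_reaction, "results/activity_classes.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# sanity: the partition covers the reaction set, the subdivision the
# auxiliary set
stopifnot(sum(prof$partition) == length(toy$model$reactions),
          sum(prof$auxiliary) == prof$partition[["active_at_least_once"]])
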