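#!/usr/bin/env Rscript
# Screen a 95-source phenotype panel against the toy core model on the
# minimal medium. The panel is generated with the planted confusion
# structure 41 concordant-growth / 36 concordant-no-growth / 8 false-no-
# growth (missing transporter) / 10 false-growth, and the screen must
# recover it, giving 81.05% overall agreement.

suppressPackageStartupMessages(library(oleoflux))
dir.create("results", showWarnings = FALSE)

toy <- make_toy_core_model(carbon_sources = paste0("c", 1:51))
panel <- make_phenotype_panel(
  toy$model, toy$exchange_map,
  planted = c(both_growth = 41L, both_no_growth = 36L,
              false_no_growth = 8L, false_growth = 10L),
  n_sources = 95, seed = 1)
write_plate(panel$plate, "results/phenotype_panel.csv")

res <- screen_carbon_sources(toy$model, panel$plate, panel$exchange_map,
                             medium_template = toy$medium)
print(res)
write.table(res$per_source, "results/concordance.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("\nagreement: %.2f%% over %d sources\n",
            res$agreement_percent, nrow(res$per_source)))
cat(sprintf("mean active reactions per feasible solution: %.1f of %d\n",
            mean_active_reactions(res$solutions),
            length(toy$model$reactions)))
stopifnot(round(res$agreement_percent, 2) == 81.05)
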