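#!/usr/bin/env Rscript
# Simulate the screens the rest of the workflow analyzes:
#   - a MitoSOX respiratory-condition screen with 5% planted knockdown
#     effects (0.5/1/2 reporter-SD) among nulls,
#   - an antioxidant-treated rerun with hit effects halved,
#   - the same population re-screened under glycolytic and basal substrate
#     conditions (shared true effects, independent sorts),
# and write counts, library, design, and ground truth under results/sim/.

suppressPackageStartupMessages(library(sortscreen))

seed <- 20260927L
out <- "results/sim"

cfg <- sim_config(n_genes = 1000L, frac_null = 0.95, guides_per_gene = 10L,
                  n_ntc = 500L, depth = 2e6, n_replicates = 2L,
                  dye = "MitoSOX", condition = "respiratory", seed = seed)

base <- simulate_screen(cfg)
write_sim(base, file.path(out, "mitosox_respiratory"))
hits <- names(base$truth$beta)[base$truth$beta != 0]
writeLines(hits, file.path(out, "planted_hits.txt"))
message(sprintf("base screen: %d guides, %d planted hit genes, %d reads/fraction",
                nrow(base$library), length(hits), cfg$depth))

treated <- simulate_treatment(cfg, rescue_factor = 0.5, hit_mask = hits,
                              treatment = "Trolox_1mM")
write_sim(treated, file.path(out, "mitosox_respiratory_trolox"))
message("treated rerun: planted effects halved (rescue factor 0.5)")

for (cond in c("glycolytic", "basal")) {
  cfg_c <- cfg
  cfg_c$condition <- cond
  # same population (same seed), independent count draws per condition
  sim_c <- sortscreen:::sim_from_population(
    cfg_c, sortscreen:::sim_population(cfg_c),
    count_seed_offset = 1000L * match(cond, c("glycolytic", "basal")))
  write_sim(sim_c, file.path(out, paste0("mitosox_", cond)))
  message("re-screened under ", cond, " substrate condition")
}
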