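#!/usr/bin/env Rscript
# Cross-screen comparisons: substrate-condition correlation matrix,
# regression slope tests against 0 and 1, antioxidant rescue effect over
# the planted hit set, and Dunnett comparisons of hit-class phenotypes
# against the non-targeting-like null genes.

suppressPackageStartupMessages(library(sortscreen))

read_scores <- function(s)
  read.delim(file.path("results/scores", paste0(s, "_gene_scores.tsv")))

base <- read_scores("mitosox_respiratory")
trolox <- read_scores("mitosox_respiratory_trolox")
glyc <- read_scores("mitosox_glycolytic")
basal <- read_scores("mitosox_basal")
hits <- readLines("results/sim/planted_hits.txt")
dir.create("results/compare", showWarnings = FALSE, recursive = TRUE)

## substrate-condition agreement (shared true effects -> high correlation)
joint <- join_screens(list(base, glyc, basal),
                      c("respiratory", "glycolytic", "basal"))
write.table(joint, "results/compare/joint_conditions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cm <- correlation_matrix(joint)
write.table(data.frame(var = rownames(cm$r), cm$r),
            "results/compare/condition_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("r(respiratory, glycolytic) = %.3f (p = %.3g, n = %d)",
                cm$r["respiratory", "glycolytic"],
                cm$p["respiratory", "glycolytic"],
                cm$n["respiratory", "glycolytic"]))

## slope of glycolytic vs respiratory z: near identity for shared effects
st1 <- slope_test(joint$respiratory, joint$glycolytic, b0 = 1)
st0 <- slope_test(joint$respiratory, joint$glycolytic, b0 = 0)
jsonlite::write_json(list(vs_identity = st1, vs_zero = st0),
                     "results/compare/slope_tests.json",
                     auto_unbox = TRUE, digits = NA)
message(sprintf("fitted slope %.3f; F vs b0=1: %.2f (p %.3g); F vs b0=0: %.1f (p %.3g)",
                st1$slope, st1$F, st1$p, st0$F, st0$p))

## antioxidant rescue of the planted hits
re <- rescue_effect(base, trolox, hits, n_boot = 1e4L, seed = 7L)
write.table(re$delta, "results/compare/trolox_delta_z.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("Trolox rescue: mean delta-z over %d hits = %.2f [%.2f, %.2f]",
                re$summary$n_hits, re$summary$mean_delta,
                re$summary$ci_lower, re$summary$ci_upper))

## Dunnett: z of each planted effect-size class vs the null genes
truth <- read.delim("results/sim/mitosox_respiratory/truth_gene.tsv")
z <- setNames(base$z, base$gene)
cls <- ifelse(truth$beta == 0, "null", paste0("beta_", truth$beta))
groups <- split(z[truth$gene], cls)
dn <- dunnett_vs_control(groups, "null", n_mc = 1e5L, seed = 11L)
write.table(dn, "results/compare/dunnett_effect_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Dunnett vs null genes:")
for (i in seq_len(nrow(dn)))
  message(sprintf("  %-10s mean z shift %+.2f, adjusted p %.3g",
                  dn$group[i], dn$estimate[i], dn$p_adj[i]))
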