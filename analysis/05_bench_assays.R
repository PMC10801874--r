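#!/usr/bin/env Rscript
# Bench-assay analytics on synthetic fixtures with known truth:
# rotenone-sensitive complex I activity from A340 kinetic traces,
# blue-native PAGE supercomplex/subcomplex ratios, and 2^-ddCt knockdown
# validation. Inputs are generated here (no instrument data ships with the
# package); true values are printed next to recovered ones.

suppressPackageStartupMessages(library(sortscreen))
dir.create("results/assays", showWarnings = FALSE, recursive = TRUE)
set.seed(91L)

## complex I activity: 45-min traces, readings every 60 s, sigma 1 mAU
true_rates <- c(ntc = 0.010, NDUFA8_kd = 0.003, NDUFS8_kd = 0.004)
tt <- seq(0, 2700, by = 60)
act <- sapply(names(true_rates), function(s) {
  minus <- data.frame(time = tt,
                      a340 = 1.5 - true_rates[[s]] * tt / 60 +
                        rnorm(length(tt), 0, 0.001))
  plus <- data.frame(time = tt,
                     a340 = 1.5 - 0.002 * tt / 60 +
                       rnorm(length(tt), 0, 0.001))
  complex1_activity(minus, plus)$activity
})
write.table(data.frame(sample = names(act),
                       true_activity = true_rates - 0.002,
                       recovered = act),
            "results/assays/complex1_activity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("rotenone-sensitive complex I activity (dA340/min):")
for (s in names(act))
  message(sprintf("  %-10s true %.4f recovered %.4f", s,
                  true_rates[[s]] - 0.002, act[[s]]))

## BN-PAGE band ratios: knockdowns lose supercomplex relative to CI
bands <- data.frame(
  sample_id = rep(c("ntc", "NDUFA8_kd", "NDUFB4_kd"), each = 3),
  band_class = rep(c("supercomplex", "assembled_CI", "subcomplex"), 3),
  intensity = c(30, 30, 6, 10, 32, 7, 14, 30, 6))
br <- bnpage_ratios(bands, "ntc")
write.table(br, "results/assays/bnpage_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("supercomplex/CI ratio normalized to control: ",
        paste(sprintf("%s %.2f", br$sample_id, br$SC_norm), collapse = ", "))

## qPCR knockdown validation: duplicates, ACTB reference
cts <- data.frame(
  sample_id = rep(rep(c("ntc", "NDUFA8_kd"), each = 2), 2),
  gene = rep(c("NDUFA8", "ACTB"), each = 4),
  ct = c(24.1, 24.3, 26.8, 26.6, 17.9, 18.1, 18.0, 18.0),
  replicate = rep(1:2, 4))
f <- ddct_fold(cts, "ntc", reference_gene = "ACTB")
write.table(f, "results/assays/ddct_folds.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("NDUFA8 expression after knockdown: %.2f-fold of control",
                f$fold[f$sample_id == "NDUFA8_kd"]))
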