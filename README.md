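# sortscreen

Scoring and simulation of pooled CRISPRi screens read out by
fluorescence-activated cell sorting (sort-seq), as used to map how gene
knockdowns shift reactive-oxygen-species (ROS) and ATP reporter levels in
the mitochondrial respiratory chain.

In such a screen, cells carrying a CRISPRi sgRNA library are stained with
a reporter dye (e.g. MitoSOX for mitochondrial superoxide, DCFDA for
cytosolic ROS), sorted into the highest and lowest fluorescence quartiles,
and the sorted fractions are sequenced. `sortscreen` turns the reads into
gene-level phenotype calls and provides the downstream comparison
statistics:

- **Guide counting** — exact protospacer matching at a configured offset
  and orientation in FASTQ reads, with a counting report.
- **Phenotypes** — per-guide log2 enrichment in the high vs low fraction,
  ρᵢ = log₂[(cᵢʰ+α)/Σ(cʰ+α)] − log₂[(cᵢˡ+α)/Σ(cˡ+α)], recentred on the
  non-targeting-control (NTC) median per replicate and averaged over
  replicates.
- **Gene scores and z-scores** — signed mean of each gene's 3
  strongest-|ρ| guides, standardized against a *pseudogene* null: random
  NTC subsets scored by the identical rule. A Mann–Whitney guide-agreement
  p-value accompanies each gene.
- **Screen comparisons** — Pearson correlation matrices with t-test
  p-values, extra sum-of-squares F-tests of regression slopes against 0
  or 1, antioxidant rescue effects (Δz with bootstrap CIs), and
  Dunnett-style many-to-one comparisons with a Monte-Carlo max-|t|
  reference.
- **Preranked gene-set enrichment** — weighted Kolmogorov–Smirnov running
  sum with gene-permutation p-values (set sizes 1–500, 1,000 permutations
  by default) over GMT collections.
- **Bench-assay analytics** — rotenone-sensitive complex I activity from
  340 nm kinetic traces, blue-native PAGE supercomplex/subcomplex ratios,
  and 2^−ΔΔCt qPCR fold changes.
- **A generative simulator** — per-cell reporter fluorescence
  N(eᵢβ_g, σ), global quartile gates on the abundance-weighted mixture,
  multinomial sequencing counts, with full ground truth for verification.

## Worked example

Simulate a reference-condition screen (1,000 genes × 10 guides, 500 NTCs,
5% of genes with true effects of 0.5/1/2 reporter-SD, 2×10⁶ reads per
sorted fraction, 2 replicate sorts) and score it:

```r
library(sortscreen)

cfg <- sim_config(seed = 1)            # defaults are the reference design
sim <- simulate_screen(cfg)
gs  <- score_screen(sim$counts, sim$design, sim$library,
                    n_pseudo = 1000, seed = 17)
head(gs[order(-gs$z), c("gene", "score", "z", "p_mw")])
#>         gene    score        z         p_mw
#> 330 gene0330 7.579588 75.59217 6.065183e-08
#> 121 gene0121 7.574088 75.53733 6.065183e-08
#> 556 gene0556 7.509675 74.89509 6.065183e-08
#> 509 gene0509 7.488583 74.68478 6.065183e-08
#> 679 gene0679 7.360147 73.40418 6.065183e-08
#> 775 gene0775 7.322579 73.02960 6.065183e-08
```

The strongest planted effects (β = 2σ: a knockdown shifting reporter
fluorescence by two per-cell SDs) surface with z-scores in the tens —
comparable in character to the extreme hits of a real deep screen — while
the 950 null genes stay standard-normal (here mean z = 0.004, SD = 1.00,
4.4% beyond |z| = 2).

The `analysis/` directory holds the full workflow as numbered drivers —
`01_simulate_screens.R` (base screen, antioxidant-treated rerun, two more
substrate conditions), `02_score_phenotypes.R`, `03_compare_screens.R`,
`04_pathway_enrichment.R`, `05_bench_assays.R` — each writing its tables
under `results/`. Run them in order from the repository root. Example
output from `03`:

```
r(respiratory, glycolytic) = 0.987 (p = 2.23e-308, n = 1000)
Trolox rescue: mean delta-z over 50 hits = -17.55 [-20.55, -14.67]
```

i.e. substrate-independent true effects reproduce as highly correlated
phenotypes across metabolic conditions, and halving the planted effects
("antioxidant treatment") is detected as a large negative shift in hit
z-scores with a bootstrap CI excluding zero.

See `vignettes/sortseq-screen-scoring.Rmd` for the model, parameter
choices, and limitations.

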