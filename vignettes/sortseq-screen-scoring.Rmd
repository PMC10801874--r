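---
title: "Scoring pooled CRISPRi sort-seq screens: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring pooled CRISPRi sort-seq screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortscreen)
```

## The experiment this package models

A pooled CRISPRi screen read out by cell sorting works as follows. A
population of cells, each carrying one sgRNA from a library (targeting
guides plus non-targeting controls, NTCs), is stained with a fluorescent
reporter — for example a ROS-sensitive dye such as MitoSOX or DCFDA, under
a chosen metabolic substrate condition. The sorter collects the cells in
the top and bottom quartiles of reporter fluorescence, the integrated
sgRNA cassettes in each sorted fraction are PCR-amplified and sequenced,
and each guide's read counts in the high versus low fraction reveal whether
its knockdown pushes the reporter up or down.

`sortscreen` implements the full quantitative chain from reads to
gene-level phenotype z-scores, the statistics used to compare screens run
with different dyes, treatments, and substrate conditions, preranked
gene-set enrichment over the resulting gene rankings, the small bench
assays used to follow up individual knockdowns, and a generative simulator
that makes every stage testable against known ground truth.

## From counts to phenotypes

For guide $i$ in one replicate, with raw counts $c^{high}_i$ and
$c^{low}_i$ and pseudocount $\alpha$:

$$\rho_i \;=\; \log_2 \frac{(c^{high}_i + \alpha)\,/\,\sum_j (c^{high}_j + \alpha)}
{(c^{low}_i + \alpha)\,/\,\sum_j (c^{low}_j + \alpha)}$$

- **Pseudocount** $\alpha = 1$ on raw counts (configurable). It keeps
  $\rho$ finite for dropout guides and has negligible influence at the
  read depths of a real screen (hundreds of reads per guide per fraction).
- **Recentring**: the median $\rho$ of the NTC guides is subtracted within
  each replicate (default on), so phenotypes are read relative to the
  no-effect baseline and the NTC median is exactly zero by construction.
- **Replicates** are averaged at the guide level before any gene
  aggregation; per-replicate values are kept alongside.

## Gene scores and the pseudogene null

A gene's score is the signed mean of its `n_strongest = 3` guides with the
largest $|\rho|$ (all guides when it has fewer, flagged via `n_used`).
Selecting by absolute value and averaging with sign keeps antagonistic
guides visible as cancellation rather than inflating the score.

Significance calibration uses *pseudogenes*: random subsets of NTC guide
phenotypes of fixed size (default: the library's modal guides-per-gene —
3 for a compact 1–3-guides/gene library, 10 for a deep one), scored by
exactly the same strongest-`n` rule. The z-score of a gene is its score
standardized by the mean and SD of 1,000 pseudogene scores. Because genes
and pseudogenes pass through the identical selection-biased statistic, the
null distribution of gene z-scores is close to standard normal; the
package's acceptance checks verify mean $\approx 0$, SD $\in [0.85,
1.15]$, and a $|z|>2$ tail near the Gaussian 4.6% on all-null simulations.

A two-sided Mann–Whitney p-value of each gene's guide phenotypes against
the NTC phenotypes accompanies the z-score, quantifying guide agreement;
it is exact for small untied samples (both $n \le 8$) and uses the
tie-corrected normal approximation otherwise.

Two caveats are worth knowing. With a finite NTC pool (say 500 guides)
the empirical null's location carries sampling noise shared by every gene
in a screen, so the *mean* z of a screen can drift by roughly $\pm 0.1$;
this matters only when averaging z across many genes, not for per-gene
inference. Second, pseudogene scores reuse the same NTC pool, so z-scores
within a screen are not strictly independent.

## Comparing screens

- **Joint tables** outer-join gene-score tables across strata; absent
  genes are explicit `NA`, never zero.
- **Correlation matrices** use pairwise-complete Pearson r with two-sided
  t-test p-values, the standard summary for dye-versus-dye or
  condition-versus-condition agreement.
- **Slope tests** compare the least-squares slope of one screen's
  phenotypes on another's against a hypothesized 0 (no relation) or 1
  (identity) by the extra sum-of-squares F-test.
- **Rescue effects** quantify a treatment (e.g. an antioxidant) as
  $\Delta z = z_{treated} - z_{base}$ per gene, summarized over a hit set
  by its mean with a gene-resampling bootstrap CI (10,000 draws). Before
  summarizing, the two z scales are aligned by subtracting the median
  $\Delta z$ over a presumed-null background (default: all shared genes
  outside the hit set). The alignment exists because each screen is
  standardized against its own empirical null: the resulting screen-level
  offset is shared by all genes, so a gene-resampling bootstrap cannot see
  it, and without alignment the CI for a null set's mean is markedly
  anti-conservative. Alignment assumes the treatment leaves the typical
  background gene unmoved; disable it (`align = FALSE`) if that is not
  credible.
- **Dunnett comparisons** of several knockdown classes against a common
  control use pooled-variance t statistics with the family-wise adjusted p
  taken from a Monte-Carlo distribution of the maximum |t| under the null,
  preserving the correlation induced by the shared control. Monte Carlo
  (default $10^5$ draws, seed-reproducible) was chosen over multivariate-t
  quadrature for transparency; agreement with the quadrature answer is
  within the reported precision.

## Preranked enrichment

Gene-set enrichment over a phenotype-ranked list uses the weighted
Kolmogorov–Smirnov running sum: hits advance the sum by
$|s|^{p}/\sum_{hits}|s|^{p}$ (weight $p = 1$ by default), misses retreat
by $1/(N - N_{hits})$, and the enrichment score ES is the extremum.
Significance comes from random same-size gene-set permutations —
appropriate for a preranked analysis where only the ranked vector exists —
with $p = (1 + \#\{|ES_{null}| \ge |ES|\})/(n_{perm}+1)$ and
$NES = ES / \overline{|ES_{null}|}$ over same-sign permutations. Default
set-size bounds 1–500 and 1,000 permutations. Ties in the ranking
statistic keep input order. Across sets, Benjamini–Hochberg q-values are
reported; this is simpler than the NES-binned FDR of some established
implementations and is a documented divergence. The default ranking
statistic is the signed z-score.

## Bench-assay analytics

- **Complex I activity**: NADH absorbs at 340 nm, so complex I activity
  appears as a declining A340 trace; the rotenone-insensitive background
  is removed by subtracting the slope of the +rotenone trace. Slopes are
  least-squares fits over the first 10 minutes of the 45-minute trace by
  default (initial-rate convention; the window is configurable), and
  activity is reported positive, in ΔA340/min.
- **Blue-native PAGE**: band intensities are reduced to
  supercomplex/assembled-CI and subcomplex/assembled-CI ratios, each also
  normalized to the control lane (control ≡ 1 by construction).
- **qPCR knockdown validation**: technical replicates are averaged on the
  Ct scale first (standard practice), then
  $2^{-\Delta\Delta Ct}$ fold changes versus the reference gene and
  control sample.

## The simulator: what it emulates and what it does not

`simulate_screen()` draws, per guide $i$ of gene $g$, a per-cell log2
reporter fluorescence $\mathcal{N}(e_i \beta_g, \sigma)$: $\beta_g$ is the
true knockdown effect (log2 fluorescence units), $e_i \in [0,1]$ the guide
efficacy. Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 1000 | desk-scale version of a genome-subset library |
| `guides_per_gene` | 10 | deep-library design |
| `n_ntc` | 500 | ~5% of guides non-targeting |
| `frac_null` | 0.95 | a minority of knockdowns move the reporter |
| `effect_dist` | 0.5/1/2 × σ | moderate-to-strong effects in reporter-SD units |
| `efficacy_dist` | Beta(5, 1.5) | most guides effective, a tail of weak ones |
| `reporter_sigma` | 1 | working in units of per-cell fluorescence SD |
| `gate_quantiles` | 0.25 / 0.75 | quartile sorting |
| `depth` | 2×10⁶ | ~190 reads/guide/fraction at 10,500 guides |
| `n_replicates` | 2 | replicate sorts |
| `abundance_cv` | 0.3 | log-normal cloning-bottleneck skew |

Gates are *global* population quantiles, as on a sorter: thresholds are
found by root-finding on the abundance-weighted Gaussian-mixture CDF (the
infinite-population limit), per-guide gate probabilities are then Gaussian
tails, and reads per fraction are multinomial with probabilities
proportional to abundance × gate probability. Everything reproduces from
one seed. `simulate_treatment()` reruns the identical population with hit
effects scaled by a rescue factor, re-deriving the gates on the treated
population as the instrument would.

Deliberately not modeled: dye chemistry and probe nonspecificity, growth
and guide dropout during culture, PCR amplification bias beyond the
multinomial, doublets and sorting impurity. Passing tests on simulated
screens therefore validate the statistical chain, not the photochemistry
of any particular reporter.

## Numerical and design notes

- All randomized procedures (pseudogene nulls, permutation tests,
  Monte-Carlo Dunnett, bootstrap, simulator) take explicit seeds and
  restore the caller's RNG state.
- Guide counting is exact substring matching at a configured offset and
  orientation; no mismatch tolerance. This is the conservative default in
  the absence of a stated error model; with protospacers of mixed length,
  the longest match wins deterministically.
- `strongest_mean` breaks |ρ| ties by input position; pseudogene and gene
  scoring share one code path so any such convention cancels in the
  z-score.
- Degenerate inputs fail loudly: all-zero samples, constant NTC
  phenotypes (zero-variance null), gates at 0 or 1, ambiguous libraries
  with duplicated protospacers.
- Recovery benchmarks in the acceptance checks correlate recovered z with
  the identifiable quantity β × mean guide efficacy over the planted
  genes (truth is continuous there; the all-zero null genes would
  contribute only rank noise).
- Problem sizes used in tests and acceptance runs (1,000 genes, depth
  2×10⁶, 1,000 pseudogenes, 10⁴ bootstrap draws) are the package's
  desk-scale reference conditions; they complete in seconds while leaving
  per-guide counting noise realistic.

## Known limitations

- The pseudogene null requires a reasonable NTC pool; with very few NTCs
  (the compact-library regime of ~19) the null's tails are coarse and
  z-scores beyond ~3 should be read qualitatively.
- Mann–Whitney p-values against a shared NTC pool are correlated across
  genes; they rank guide agreement but are not a calibrated family of
  independent tests.
- The simulator's analytic gates assume Gaussian per-guide fluorescence;
  real log-fluorescence distributions have heavier tails, which would
  slightly dilute gate probabilities for strong effects.
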