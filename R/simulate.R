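#' Configuration for the sort-seq screen simulator
#'
#' Describes the generative model of a pooled CRISPRi screen read out by
#' quartile sorting on a fluorescent reporter: each guide knocks down its
#' gene with efficacy `e` in [0, 1]; a cell carrying guide *i* of gene *g*
#' has log2 reporter fluorescence `Normal(e_i * beta_g, sigma)` around the
#' population reference; cells beyond the global gate thresholds (set at
#' population quantiles of the full mixture) are sorted into the high/low
#' fractions and sequenced to a fixed multinomial depth.
#'
#' @param n_genes Number of targeted genes.
#' @param frac_null Fraction of genes with true effect `beta = 0`.
#' @param effect_dist Function(n) drawing non-null effects on the log2
#'   fluorescence scale. Default draws from {0.5, 1, 2} x `reporter_sigma`
#'   (moderate to strong knockdown effects).
#' @param beta Optional explicit per-gene effect vector (length `n_genes`),
#'   overriding `frac_null`/`effect_dist`.
#' @param guides_per_gene Targeting guides per gene.
#' @param n_ntc Non-targeting control guides.
#' @param efficacy_dist Function(n) drawing per-guide knockdown efficacy in
#'   [0, 1]. Default Beta(5, 1.5): most guides effective, some weak.
#' @param n_cells Nominal sorted-population size (the gate thresholds use
#'   the analytic infinite-population mixture; `n_cells` is metadata).
#' @param reporter_sigma Per-cell log2 fluorescence SD around the guide mean.
#' @param gate_quantiles Lower/upper population quantiles defining the sort
#'   gates; default quartiles `c(0.25, 0.75)`.
#' @param depth Sequencing reads per sorted fraction.
#' @param n_replicates Independent replicate sorts.
#' @param abundance_cv Coefficient of variation of log-normal library
#'   abundance skew (cloning bottlenecks).
#' @param dye,condition,treatment Labels recorded in the design.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, frac_null = 0.95,
                       effect_dist = NULL, beta = NULL,
                       guides_per_gene = 10L, n_ntc = 500L,
                       efficacy_dist = function(n) stats::rbeta(n, 5, 1.5),
                       n_cells = 1e6, reporter_sigma = 1,
                       gate_quantiles = c(0.25, 0.75), depth = 2e6,
                       n_replicates = 2L, abundance_cv = 0.3,
                       dye = "MitoSOX", condition = "respiratory",
                       treatment = "none", seed = 1L) {
  if (is.null(effect_dist)) {
    sig <- reporter_sigma
    effect_dist <- function(n) sample(c(0.5, 1, 2) * sig, n, replace = TRUE)
  }
  cfg <- list(n_genes = as.integer(n_genes), frac_null = frac_null,
              effect_dist = effect_dist, beta = beta,
              guides_per_gene = as.integer(guides_per_gene),
              n_ntc = as.integer(n_ntc), efficacy_dist = efficacy_dist,
              n_cells = n_cells, reporter_sigma = reporter_sigma,
              gate_quantiles = gate_quantiles, depth = depth,
              n_replicates = as.integer(n_replicates),
              abundance_cv = abundance_cv, dye = dye, condition = condition,
              treatment = treatment, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L, guides_per_gene >= 1L, n_ntc >= 1L,
              frac_null >= 0, frac_null <= 1, reporter_sigma > 0,
              n_replicates >= 1L, abundance_cv >= 0,
              length(gate_quantiles) == 2L)
    if (depth <= 0) stop("depth must be positive")
    if (!(gate_quantiles[1] >= 0 && gate_quantiles[1] < gate_quantiles[2] &&
          gate_quantiles[2] <= 1) ||
        gate_quantiles[1] == 0 || gate_quantiles[2] == 1)
      stop("gate_quantiles must satisfy 0 < lower < upper < 1 ",
           "(a gate at 0 or 1 captures zero expected cells)")
    if (!is.null(beta) && length(beta) != n_genes)
      stop("beta must have length n_genes")
  })
  class(cfg) <- "sim_config"
  cfg
}

# deterministic population layer: library, effects, efficacies, abundance
sim_population <- function(cfg) {
  with_seed_local(cfg$seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    beta <- cfg$beta
    if (is.null(beta)) {
      beta <- numeric(cfg$n_genes)
      n_eff <- round((1 - cfg$frac_null) * cfg$n_genes)
      if (n_eff > 0) {
        idx <- sample.int(cfg$n_genes, n_eff)
        beta[idx] <- cfg$effect_dist(n_eff)
      }
    }
    names(beta) <- genes
    gid_t <- sprintf("%s_g%02d", rep(genes, each = cfg$guides_per_gene),
                     seq_len(cfg$guides_per_gene))
    gid_n <- sprintf("ntc_%04d", seq_len(cfg$n_ntc))
    lib <- sgrna_library(
      guide_id = c(gid_t, gid_n),
      protospacer = random_protospacers(length(gid_t) + cfg$n_ntc, 19L),
      gene = c(rep(genes, each = cfg$guides_per_gene),
               rep(NA_character_, cfg$n_ntc)),
      sublibrary = "synthetic")
    eff <- c(cfg$efficacy_dist(length(gid_t)), rep(0, cfg$n_ntc))
    names(eff) <- lib$guide_id
    sdlog <- sqrt(log(1 + cfg$abundance_cv^2))
    abun <- stats::rlnorm(nrow(lib), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    abun <- abun / sum(abun)
    names(abun) <- lib$guide_id
    shift <- eff * ifelse(lib$is_ntc, 0, beta[lib$gene])
    shift[is.na(shift)] <- 0
    names(shift) <- lib$guide_id
    list(library = lib, beta = beta, efficacy = eff, abundance = abun,
         shift = shift)
  })
}

random_protospacers <- function(n, len) {
  repeat {
    p <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(p)) return(p)
  }
}

#' Global sort-gate thresholds of a Gaussian-mixture population
#'
#' Solves for the fluorescence cutoffs at the configured population
#' quantiles of the abundance-weighted mixture of per-guide Gaussians
#' (the infinite-cell limit of gating a stained population on the sorter).
#'
#' @param shift Per-guide mean log2 fluorescence shifts.
#' @param weights Per-guide population weights (abundances), summing to 1.
#' @param sigma Per-cell SD.
#' @param gate_quantiles Lower/upper quantiles, e.g. `c(0.25, 0.75)`.
#' @return Numeric length-2 vector `c(lower, upper)` of thresholds.
#' @export
gate_thresholds <- function(shift, weights, sigma,
                            gate_quantiles = c(0.25, 0.75)) {
  weights <- weights / sum(weights)
  cdf <- function(x) sum(weights * stats::pnorm(x, mean = shift, sd = sigma))
  lo <- min(shift) - 10 * sigma
  hi <- max(shift) + 10 * sigma
  vapply(gate_quantiles, function(q)
    stats::uniroot(function(x) cdf(x) - q, c(lo, hi), tol = 1e-10)$root,
    numeric(1))
}

#' Per-guide sort-gate probabilities
#'
#' Gaussian tail probabilities that a cell with mean fluorescence shift
#' `beta_effective` lands beyond the global gate thresholds.
#'
#' @param beta_effective Mean log2 fluorescence shift(s) (`efficacy x beta`).
#' @param sigma Per-cell SD (> 0).
#' @param thresholds Length-2 `c(lower, upper)` from [gate_thresholds()].
#' @return Matrix with columns `p_high`, `p_low`.
#' @export
gate_probability <- function(beta_effective, sigma, thresholds) {
  stopifnot(sigma > 0, length(thresholds) == 2L)
  cbind(p_high = stats::pnorm(thresholds[2], mean = beta_effective,
                              sd = sigma, lower.tail = FALSE),
        p_low = stats::pnorm(thresholds[1], mean = beta_effective,
                             sd = sigma))
}

#' Simulate a pooled sort-seq CRISPRi screen
#'
#' Generates the guide library, per-gene effects and per-guide efficacies,
#' sets global sort gates at the configured quantiles of the full
#' fluorescence mixture, computes per-guide gate probabilities analytically,
#' and draws multinomial read counts per sorted fraction and replicate with
#' probabilities proportional to library abundance x gate probability.
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param count_seed_offset Internal offset separating the count-drawing RNG
#'   stream from the population stream (used by [simulate_treatment()]).
#' @return List with `library` (`sgrna_library`), `counts` (guides x
#'   samples integer matrix), `design` (`screen_design`), and `truth` (list:
#'   per-gene `beta`, per-guide `efficacy`, `abundance`, `p_high`, `p_low`,
#'   gate `thresholds`).
#' @export
simulate_screen <- function(cfg, count_seed_offset = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  pop <- sim_population(cfg)
  sim_from_population(cfg, pop, count_seed_offset)
}

sim_from_population <- function(cfg, pop, count_seed_offset = 0L) {
  thr <- gate_thresholds(pop$shift, pop$abundance, cfg$reporter_sigma,
                         cfg$gate_quantiles)
  gp <- gate_probability(pop$shift, cfg$reporter_sigma, thr)
  if (any(colSums(pop$abundance * gp) <= 0))
    stop("gates capture zero expected cells")
  design <- screen_design(cfg$dye, cfg$condition, cfg$treatment,
                          cfg$n_replicates)
  counts <- matrix(0L, nrow = nrow(pop$library), ncol = nrow(design),
                   dimnames = list(pop$library$guide_id, design$sample_id))
  for (r in seq_len(cfg$n_replicates)) {
    cseed <- (cfg$seed + count_seed_offset + 101L * r) %% .Machine$integer.max
    counts[, design$sample_id[design$replicate == r]] <-
      with_seed_local(cseed, {
        ph <- pop$abundance * gp[, "p_high"]
        pl <- pop$abundance * gp[, "p_low"]
        hi <- stats::rmultinom(1, size = cfg$depth, prob = ph / sum(ph))
        lo <- stats::rmultinom(1, size = cfg$depth, prob = pl / sum(pl))
        m <- cbind(hi, lo)
        hi_first <- design$fraction[design$replicate == r] == "high"
        if (hi_first[1]) m else m[, 2:1]
      })
  }
  truth <- list(beta = pop$beta, efficacy = pop$efficacy,
                abundance = pop$abundance,
                p_high = gp[, "p_high"], p_low = gp[, "p_low"],
                thresholds = thr)
  list(library = pop$library, counts = counts, design = design,
       truth = truth)
}

#' Simulate a treated rerun of a screen
#'
#' Same library, abundances, effects, and efficacies as the base screen from
#' the same `cfg`, but with the true effect of each gene in `hit_mask`
#' multiplied by `rescue_factor` (an antioxidant halving a ROS phenotype has
#' `rescue_factor = 0.5`). Sort gates are re-derived on the treated
#' population, as they would be on the instrument, and counts are drawn
#' from an independent RNG stream.
#'
#' @param cfg The base [sim_config()].
#' @param rescue_factor Multiplier applied to `beta` of masked genes.
#' @param hit_mask Character vector of gene names to rescue.
#' @param treatment Label recorded in the treated design.
#' @return Same structure as [simulate_screen()].
#' @export
simulate_treatment <- function(cfg, rescue_factor, hit_mask,
                               treatment = "Trolox_1mM") {
  stopifnot(inherits(cfg, "sim_config"))
  pop <- sim_population(cfg)
  unknown <- setdiff(hit_mask, names(pop$beta))
  if (length(unknown))
    stop("hit_mask names unknown gene(s): ", paste(unknown, collapse = ", "))
  pop$beta[hit_mask] <- rescue_factor * pop$beta[hit_mask]
  lib <- pop$library
  pop$shift <- pop$efficacy * ifelse(lib$is_ntc, 0, pop$beta[lib$gene])
  pop$shift[is.na(pop$shift)] <- 0
  names(pop$shift) <- lib$guide_id
  cfg2 <- cfg
  cfg2$treatment <- treatment
  sim_from_population(cfg2, pop, count_seed_offset = 50000L)
}

#' Write simulated screen artifacts to a directory
#'
#' Writes `library.tsv`, `counts.tsv`, `design.yaml`, `truth_gene.tsv`, and
#' `truth_guide.tsv`; optionally FASTQ files with each guide's protospacer
#' embedded at a fixed offset, one read per counted read.
#'
#' @param sim Result of [simulate_screen()].
#' @param dir Output directory (created if needed).
#' @param fastq Write per-sample FASTQ files (off by default; they are
#'   large).
#' @param offset 0-based protospacer offset within each synthetic read.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, fastq = FALSE, offset = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(sim$library),
                     file.path(dir, "library.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  yaml::write_yaml(list(samples = split(as.data.frame(sim$design)[
    , c("sample_id", "fraction", "dye", "condition", "treatment",
        "replicate")],
    seq_len(nrow(sim$design)))), file.path(dir, "design.yaml"))
  utils::write.table(
    data.frame(gene = names(sim$truth$beta), beta = sim$truth$beta),
    file.path(dir, "truth_gene.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(guide_id = names(sim$truth$efficacy),
               efficacy = sim$truth$efficacy,
               abundance = sim$truth$abundance,
               p_high = sim$truth$p_high, p_low = sim$truth$p_low),
    file.path(dir, "truth_guide.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (fastq) {
    pad <- paste(rep("A", offset), collapse = "")
    for (s in colnames(sim$counts)) {
      reads <- rep(paste0(pad, sim$library$protospacer), sim$counts[, s])
      con <- gzfile(file.path(dir, paste0("reads_", s, ".fastq.gz")), "w")
      if (length(reads)) {
        writeLines(paste0("@r", seq_along(reads), "\n", reads, "\n+\n",
                          strrep("I", nchar(reads))), con, sep = "\n")
      }
      close(con)
    }
  }
  invisible(dir)
}
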