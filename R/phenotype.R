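#' Guide-level sort-seq phenotypes (log2 high/low enrichment)
#'
#' For each replicate of a single (dye, condition, treatment) stratum the
#' phenotype of guide *i* is the log2 ratio of its read frequency in the
#' high-signal sorted fraction to its frequency in the low-signal fraction,
#' after adding a pseudocount `alpha` to every raw count:
#' \deqn{\rho_i = \log_2\frac{(c^{high}_i+\alpha)/\sum_j(c^{high}_j+\alpha)}
#'                           {(c^{low}_i+\alpha)/\sum_j(c^{low}_j+\alpha)}}
#' With `recenter = TRUE` (default) the median phenotype of the non-targeting
#' control guides is subtracted within each replicate, so the NTC median is
#' exactly zero and knockdown effects are read relative to a no-effect
#' baseline. The combined phenotype is the mean of `rho` across replicates.
#'
#' @param counts Integer matrix, guides x samples (as from [merge_counts()]
#'   or [simulate_screen()]).
#' @param design A `screen_design` covering exactly one stratum (one
#'   dye/condition/treatment combination; any number of replicates).
#' @param library The `sgrna_library`; used to locate NTC guides.
#' @param pseudocount Positive pseudocount `alpha` added to every count.
#' @param recenter Subtract the per-replicate NTC median phenotype.
#' @return An object of class `phenotype_table`: a list with
#'   \describe{
#'     \item{rho}{numeric matrix, guides x replicates, per-replicate phenotypes}
#'     \item{combined}{named numeric vector of per-guide mean phenotypes}
#'     \item{is_ntc}{logical vector aligned with `combined`}
#'     \item{stratum}{list(dye, condition, treatment)}
#'   }
#' @export
sgrna_phenotype <- function(counts, design, library, pseudocount = 1,
                            recenter = TRUE) {
  stopifnot(pseudocount > 0)
  design <- validate_design(as.data.frame(design))
  strat <- unique(design[, c("dye", "condition", "treatment")])
  if (nrow(strat) != 1L)
    stop("sgrna_phenotype expects a single stratum; got ", nrow(strat),
         " (use score_screen for multi-stratum designs)")
  if (!all(design$sample_id %in% colnames(counts)))
    stop("design samples missing from count matrix: ",
         paste(setdiff(design$sample_id, colnames(counts)), collapse = ", "))
  guides <- rownames(counts)
  if (!setequal(guides, library$guide_id))
    stop("count matrix guides do not match library")
  is_ntc <- library$is_ntc[match(guides, library$guide_id)]

  reps <- sort(unique(design$replicate))
  rho <- matrix(NA_real_, nrow = length(guides), ncol = length(reps),
                dimnames = list(guides, paste0("rep", reps)))
  for (k in seq_along(reps)) {
    r <- reps[k]
    hi_id <- design$sample_id[design$replicate == r & design$fraction == "high"]
    lo_id <- design$sample_id[design$replicate == r & design$fraction == "low"]
    if (length(hi_id) != 1L || length(lo_id) != 1L)
      stop("replicate ", r, " lacks a paired high/low sample")
    hi <- counts[, hi_id]
    lo <- counts[, lo_id]
    if (sum(hi) == 0 || sum(lo) == 0)
      stop("all-zero sample in replicate ", r,
           "; check the input counts and pseudocount")
    fh <- (hi + pseudocount) / sum(hi + pseudocount)
    fl <- (lo + pseudocount) / sum(lo + pseudocount)
    v <- log2(fh / fl)
    if (recenter) v <- v - stats::median(v[is_ntc])
    rho[, k] <- v
  }
  structure(list(rho = rho,
                 combined = rowMeans(rho),
                 is_ntc = is_ntc,
                 stratum = as.list(strat)),
            class = "phenotype_table")
}

#' Gene-level phenotype score: average of the strongest guides
#'
#' A gene's score is the signed mean of the combined phenotypes of its
#' `n_strongest` guides with the largest absolute phenotype (all guides when
#' the gene has fewer). Sign conflicts among selected guides are preserved,
#' so antagonistic guides cancel rather than inflate the score.
#'
#' @param pheno A `phenotype_table` from [sgrna_phenotype()].
#' @param library The `sgrna_library`.
#' @param n_strongest Number of top-|rho| guides averaged per gene.
#' @return Data frame with columns `gene`, `score`, `n_guides`, `n_used`;
#'   genes with `n_used < n_strongest` were scored on all their guides.
#' @export
gene_score <- function(pheno, library, n_strongest = 3L) {
  stopifnot(inherits(pheno, "phenotype_table"), n_strongest >= 1L)
  rho <- pheno$combined
  lib <- library[!library$is_ntc, ]
  lib <- lib[lib$guide_id %in% names(rho), ]
  dropped <- setdiff(unique(library$gene[!library$is_ntc]), unique(lib$gene))
  if (length(dropped))
    warning("gene(s) with zero guides in phenotype table excluded: ",
            paste(dropped, collapse = ", "))
  by_gene <- split(rho[lib$guide_id], lib$gene)
  out <- data.frame(
    gene = names(by_gene),
    score = vapply(by_gene, strongest_mean, numeric(1),
                   n_strongest = n_strongest),
    n_guides = lengths(by_gene),
    n_used = pmin(lengths(by_gene), n_strongest),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

# signed mean of the n largest-|x| values; ties broken by position
strongest_mean <- function(x, n_strongest) {
  sel <- order(abs(x), decreasing = TRUE)[seq_len(min(length(x), n_strongest))]
  mean(x[sel])
}

#' Pseudogene null distribution from non-targeting guides
#'
#' Draws `n_pseudo` pseudogenes, each a random subset of `size` NTC guide
#' phenotypes sampled without replacement (pseudogenes drawn independently of
#' one another), and scores each with the same strongest-`n` rule used for
#' real genes. The resulting score distribution is the empirical null used
#' for phenotype z-scores.
#'
#' @param ntc_rho Numeric vector of combined NTC guide phenotypes.
#' @param size Guides per pseudogene (match the library's modal
#'   guides-per-gene).
#' @param n_pseudo Number of pseudogenes (>= 100 enforced).
#' @param n_strongest Same selection parameter as [gene_score()].
#' @param seed Integer seed; the null is fully reproducible from it.
#' @return An object of class `null_model`: list with `pseudo_scores`, `mu`,
#'   `sigma`, `size`, `n_pseudo`, `n_strongest`, `seed`.
#' @export
build_pseudogene_null <- function(ntc_rho, size, n_pseudo = 1000L,
                                  n_strongest = 3L, seed = 17L) {
  ntc_rho <- ntc_rho[is.finite(ntc_rho)]
  if (length(ntc_rho) < size)
    stop("need at least ", size, " NTC guides to build pseudogenes of size ",
         size, " (have ", length(ntc_rho), ")")
  if (n_pseudo < 100L) stop("n_pseudo >= 100 required for a stable null")
  scores <- with_seed_local(seed, {
    vapply(seq_len(n_pseudo), function(i) {
      strongest_mean(sample(ntc_rho, size, replace = FALSE), n_strongest)
    }, numeric(1))
  })
  sigma <- stats::sd(scores)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate null: pseudogene scores have zero variance")
  structure(list(pseudo_scores = scores, mu = mean(scores), sigma = sigma,
                 size = size, n_pseudo = n_pseudo, n_strongest = n_strongest,
                 seed = seed),
            class = "null_model")
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phenotype z-score against the pseudogene null
#'
#' @param score Gene score(s) from [gene_score()].
#' @param null A `null_model` from [build_pseudogene_null()].
#' @return `(score - mu) / sigma`.
#' @export
gene_zscore <- function(score, null) {
  stopifnot(inherits(null, "null_model"))
  (score - null$mu) / null$sigma
}

#' Mann-Whitney guide-agreement p-value
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a gene's guide
#' phenotypes against the NTC guide phenotypes. A low p-value indicates the
#' gene's guides agree on a phenotype shifted away from the null material.
#' The exact distribution is used when both samples have at most 8
#' observations and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param gene_rho Phenotypes of the gene's guides.
#' @param ntc_rho Phenotypes of the NTC guides.
#' @return Two-sided p-value in (0, 1].
#' @export
gene_pvalue_mw <- function(gene_rho, ntc_rho) {
  if (length(gene_rho) < 1L || length(ntc_rho) < 1L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(gene_rho, ntc_rho)) > 0
  use_exact <- !ties && length(gene_rho) <= 8L && length(ntc_rho) <= 8L
  suppressWarnings(
    stats::wilcox.test(gene_rho, ntc_rho, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value)
}

#' Score a sorted screen: counts to gene-level z-scores
#'
#' End-to-end scoring. The design is split into (dye, condition, treatment)
#' strata; within each stratum guide phenotypes are computed per replicate,
#' averaged, aggregated to gene scores, standardized against a pseudogene
#' null built from the stratum's NTC guides, and annotated with Mann-Whitney
#' guide-agreement p-values.
#'
#' @inheritParams sgrna_phenotype
#' @param design A `screen_design`; may span several strata.
#' @param n_strongest Guides averaged per gene (and per pseudogene).
#' @param pseudogene_size Guides per pseudogene; default (`NULL`) uses the
#'   modal number of guides per gene in the library.
#' @param n_pseudo Pseudogenes in the null.
#' @param seed Seed for pseudogene sampling.
#' @return Data frame with one row per gene and stratum: columns `dye`,
#'   `condition`, `treatment`, `gene`, `score`, `z`, `p_mw`, `n_guides`,
#'   `n_used`. Attributes `phenotypes` and `nulls` hold the per-stratum
#'   `phenotype_table` and `null_model` objects (named by stratum).
#' @export
score_screen <- function(counts, design, library, pseudocount = 1,
                         recenter = TRUE, n_strongest = 3L,
                         pseudogene_size = NULL, n_pseudo = 1000L,
                         seed = 17L) {
  design <- validate_design(as.data.frame(design))
  if (is.null(pseudogene_size)) {
    gpg <- table(table(library$gene[!library$is_ntc]))
    pseudogene_size <- as.integer(names(gpg)[which.max(gpg)])
  }
  key <- interaction(design$dye, design$condition, design$treatment,
                     drop = TRUE, sep = "|")
  tables <- list(); phenos <- list(); nulls <- list()
  for (k in levels(key)) {
    sub <- design[key == k, , drop = FALSE]
    ph <- sgrna_phenotype(counts, sub, library, pseudocount = pseudocount,
                          recenter = recenter)
    gs <- gene_score(ph, library, n_strongest = n_strongest)
    null <- build_pseudogene_null(ph$combined[ph$is_ntc],
                                  size = pseudogene_size,
                                  n_pseudo = n_pseudo,
                                  n_strongest = n_strongest, seed = seed)
    gs$z <- gene_zscore(gs$score, null)
    ntc_rho <- ph$combined[ph$is_ntc]
    lib_t <- library[!library$is_ntc, ]
    by_gene <- split(ph$combined[lib_t$guide_id], lib_t$gene)
    gs$p_mw <- vapply(gs$gene, function(g)
      gene_pvalue_mw(by_gene[[g]], ntc_rho), numeric(1))
    gs <- cbind(sub[1, c("dye", "condition", "treatment"), drop = FALSE],
                gs, row.names = NULL)
    tables[[k]] <- gs; phenos[[k]] <- ph; nulls[[k]] <- null
  }
  out <- do.call(rbind, c(tables, list(make.row.names = FALSE)))
  out <- out[, c("dye", "condition", "treatment", "gene", "score", "z",
                 "p_mw", "n_guides", "n_used")]
  attr(out, "phenotypes") <- phenos
  attr(out, "nulls") <- nulls
  out
}

#' Write a gene-score table as TSV
#'
#' @param scores Data frame from [score_screen()].
#' @param path Output path.
#' @export
write_gene_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a null model as JSON
#'
#' @param null A `null_model`.
#' @param path Output path.
#' @export
write_null_model <- function(null, path) {
  jsonlite::write_json(unclass(null), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
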