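#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per tab-separated line, `name <tab> description
#' <tab> member...`. Duplicate members within a set are dropped with a
#' warning; empty member lists and duplicate set names are rejected.
#'
#' @param path GMT file path.
#' @return Object of class `gene_set_collection`: named list of character
#'   vectors, with attribute `source` (the path) and `description` (named
#'   character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": expected name, description, members")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop("malformed GMT line ", i, ": empty member list")
    if (anyDuplicated(members)) {
      warning("set '", f[1], "' has duplicate members; deduplicated")
      members <- unique(members)
    }
    if (f[1] %in% names(sets)) stop("duplicate set name '", f[1], "'")
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(sets, class = "gene_set_collection", source = path,
            description = desc)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
# stats must already be sorted descending; hit_idx are positions in it
gsea_es <- function(stats_sorted, hit_idx, weight_p = 1) {
  N <- length(stats_sorted)
  nh <- length(hit_idx)
  w <- abs(stats_sorted[hit_idx])^weight_p
  sw <- sum(w)
  if (sw == 0) w <- rep(1 / nh, nh) else w <- w / sw
  step <- rep(-1 / (N - nh), N)
  step[hit_idx] <- w # element-wise: w[j] belongs to position hit_idx[j]
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of each gene set in a
#' list of genes ranked by a phenotype statistic. At each hit the running
#' sum increases by `|stat|^weight_p` normalized by the set's total; at each
#' miss it decreases by `1/(N - N_hits)`. The enrichment score (ES) is the
#' extremum of the running sum. Significance comes from random gene-set
#' permutations of the same size; `p = (1 + #{|ES_null| >= |ES|}) /
#' (n_perm + 1)` and `NES = ES / mean(|ES_null| of the same sign)`.
#' Benjamini-Hochberg q-values are attached across sets.
#'
#' @param ranked Data frame with columns `gene`, `stat`, or a named numeric
#'   vector. Ordered descending by `stat`; ties keep input order.
#' @param sets A `gene_set_collection` (or named list of character vectors).
#' @param min_size,max_size Set-size bounds after restricting to ranked
#'   genes.
#' @param n_perm Random permutations per set.
#' @param weight_p Weighting exponent (0 = classic unweighted KS).
#' @param seed RNG seed.
#' @return Data frame: `set`, `size`, `ES`, `NES`, `p`, `q`. Sets with no
#'   ranked member are skipped and listed in attribute `skipped`.
#' @export
preranked_gsea <- function(ranked, sets, min_size = 1L, max_size = 500L,
                           n_perm = 1000L, weight_p = 1, seed = 7L) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene", "stat") %in% names(ranked)))
    genes <- as.character(ranked$gene); stat <- as.numeric(ranked$stat)
  } else {
    genes <- names(ranked); stat <- as.numeric(ranked)
  }
  if (anyDuplicated(genes)) stop("ranked list has duplicate genes")
  ord <- order(stat, decreasing = TRUE) # stable: ties keep input order
  genes <- genes[ord]; stat <- stat[ord]
  N <- length(genes)

  keep <- names(sets)[vapply(sets, function(s) {
    k <- sum(s %in% genes); k >= max(min_size, 1L) && k <= max_size && k < N
  }, logical(1))]
  skipped <- setdiff(names(sets), keep)

  res <- with_seed_local(seed, {
    rows <- lapply(keep, function(nm) {
      hit_idx <- which(genes %in% sets[[nm]])
      k <- length(hit_idx)
      es <- gsea_es(stat, hit_idx, weight_p)
      es_null <- vapply(seq_len(n_perm), function(i)
        gsea_es(stat, sort(sample.int(N, k)), weight_p), numeric(1))
      p <- (1 + sum(abs(es_null) >= abs(es))) / (n_perm + 1)
      same <- es_null[sign(es_null) == sign(es)]
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      data.frame(set = nm, size = k, ES = es, NES = nes, p = p,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  if (is.null(res))
    res <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p = numeric(0))
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Build a ranked gene list from a gene-score table
#'
#' @param scores Gene-score data frame (from [score_screen()]).
#' @param stat Column used as the ranking statistic (default `"z"`).
#' @return Data frame `gene`, `stat` sorted descending, suitable for
#'   [preranked_gsea()].
#' @export
ranked_list <- function(scores, stat = "z") {
  s <- as.data.frame(scores)
  out <- data.frame(gene = s$gene, stat = s[[stat]],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$stat), ]
  out[order(out$stat, decreasing = TRUE), , drop = FALSE]
}
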