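# shared fixtures and independent oracles used across the suite

# regenerate the mini-library composition: 450 guides = 19 NTC + 431
# targeting 219 genes (107 genes x 1 guide, 12 x 2, 100 x 3)
mini_library_df <- function(seed = 101) {
  stopifnot(107 + 12 + 100 == 219, 107 + 24 + 300 == 431)
  genes <- sprintf("GENE%03d", 1:219)
  per_gene <- rep(c(1L, 2L, 3L), c(107L, 12L, 100L))
  gene_col <- rep(genes, per_gene)
  set.seed(seed)
  n <- length(gene_col) + 19L
  proto <- replicate(n, paste(sample(c("A", "C", "G", "T"), 19,
                                     replace = TRUE), collapse = ""))
  while (anyDuplicated(proto)) {
    proto[duplicated(proto)] <- replicate(sum(duplicated(proto)),
      paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE),
            collapse = ""))
  }
  data.frame(
    guide_id = c(sprintf("sg_%03d", seq_along(gene_col)),
                 sprintf("ntc_%02d", 1:19)),
    protospacer = proto,
    gene = c(gene_col, rep("", 19L)),
    stringsAsFactors = FALSE)
}

write_mini_library <- function(path = tempfile(fileext = ".tsv"), ...) {
  write.table(mini_library_df(...), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

# plain-text FASTQ writer for synthetic reads
write_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- as.vector(rbind(paste0("@read", seq_along(reads)), reads, "+",
                           vapply(reads, function(r)
                             strrep("I", nchar(r)), character(1))))
  writeLines(lines, path)
  path
}

# a tiny two-gene library used in several counting tests
toy_library <- function() {
  sgrna_library(
    guide_id = c("g1", "g2", "n1"),
    protospacer = c("ACGTACGTACGTACGTACG", "TTTTCCCCGGGGAAAATTT",
                    "GATCGATCGATCGATCGAT"),
    gene = c("GENEA", "GENEB", NA))
}

# brute-force oracle: best size-k subset by sum of |x|, signed mean
brute_strongest_mean <- function(x, k) {
  k <- min(k, length(x))
  subs <- combn(seq_along(x), k)
  sums <- apply(subs, 2, function(idx) sum(abs(x[idx])))
  best <- subs[, which.max(sums)]
  mean(x[best])
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enumerate_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combs <- combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) {
    a <- vals[idx]; b <- vals[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# step-by-step weighted running-sum ES, written as an explicit walk
walk_gsea_es <- function(stat_sorted, in_set, weight_p = 1) {
  N <- length(stat_sorted)
  nh <- sum(in_set)
  denom_hit <- sum(abs(stat_sorted[in_set])^weight_p)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) run <- run + abs(stat_sorted[i])^weight_p / denom_hit
    else run <- run - 1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# closed-form extra sum-of-squares F-test oracle
closed_form_slope_F <- function(x, y, b0) {
  n <- length(x)
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  rss1 <- sum((y - ahat - bhat * x)^2)
  z <- y - b0 * x
  rss0 <- sum((z - mean(z))^2)
  Fst <- (rss0 - rss1) / (rss1 / (n - 2))
  list(slope = bhat, F = Fst, p = pf(Fst, 1, n - 2, lower.tail = FALSE))
}
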