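#' Join gene-score tables from several screens
#'
#' Outer join on gene. Each input table contributes one phenotype column
#' (its `z` or `score`), named by its label. Genes absent from a screen get
#' `NA`, never 0 — a missing measurement is not a null phenotype.
#'
#' @param tables List of gene-score data frames (from [score_screen()] or
#'   any table with `gene` plus the value column).
#' @param labels Unique character labels, one per table.
#' @param value Which column to carry: `"z"` (default) or `"score"`.
#' @return Data frame `gene` + one numeric column per label, with a
#'   `provenance` attribute recording label -> value column.
#' @export
join_screens <- function(tables, labels, value = c("z", "score")) {
  value <- match.arg(value)
  if (length(tables) != length(labels)) stop("one label per table required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  genes <- character(0)
  cols <- list()
  for (i in seq_along(tables)) {
    t <- as.data.frame(tables[[i]])
    if (!all(c("gene", value) %in% names(t)))
      stop("table '", labels[i], "' lacks gene/", value, " columns")
    if (anyDuplicated(t$gene))
      stop("duplicate gene within table '", labels[i], "': ",
           paste(unique(t$gene[duplicated(t$gene)]), collapse = ", "))
    cols[[labels[i]]] <- stats::setNames(t[[value]], t$gene)
    genes <- union(genes, t$gene)
  }
  genes <- sort(genes)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (lab in labels) out[[lab]] <- unname(cols[[lab]][genes])
  attr(out, "provenance") <- stats::setNames(rep(value, length(labels)), labels)
  out
}

#' Pairwise Pearson correlation matrix with t-test p-values
#'
#' Pairwise-complete Pearson r over the chosen phenotype columns; p-values
#' from the t statistic \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of
#' freedom, two-sided. Exact collinearity is reported at the machine floor
#' rather than p = 0.
#'
#' @param joint Data frame from [join_screens()] (or any gene x phenotype
#'   table).
#' @param vars Columns to correlate; default all non-`gene` numeric columns.
#' @return List of class `correlation_matrix` with matrices `r`, `p`, `n`.
#'   Pairs with fewer than 3 complete observations, or a constant variable,
#'   are `NA` with a warning.
#' @export
correlation_matrix <- function(joint, vars = NULL) {
  if (is.null(vars)) vars <- setdiff(names(joint), "gene")
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- r
  n <- matrix(NA_integer_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- joint[[vars[i]]]; y <- joint[[vars[j]]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- sum(ok)
    if (i == j) {
      if (stats::sd(x[ok]) > 0) { r[i, j] <- 1; p[i, j] <- NA_real_ }
      else warning("variable '", vars[i], "' has zero variance")
      next
    }
    if (sum(ok) < 3L) { warning("fewer than 3 complete pairs for ",
                                vars[i], " vs ", vars[j]); next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero variance in pair ", vars[i], " vs ", vars[j]); next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- max(ct$p.value, .Machine$double.xmin)
  }
  structure(list(r = r, p = p, n = n), class = "correlation_matrix")
}

#' Extra sum-of-squares F-test of a regression slope
#'
#' Fits `y = a + b x` by least squares and compares it with the constrained
#' model fixing the slope at `b0` (intercept free), via
#' \eqn{F = (RSS_0 - RSS_1) / (RSS_1 / (n-2))} on (1, n-2) degrees of
#' freedom. Used to ask whether two screens' phenotypes fall on the identity
#' line (b0 = 1) or are unrelated (b0 = 0).
#'
#' @param x,y Numeric vectors (pairs with `NA` dropped).
#' @param b0 Hypothesized slope, typically 0 or 1.
#' @return List with `slope`, `intercept`, `F`, `p`, `n`, `rss1`, `rss0`.
#'   A perfect fit (RSS1 = 0) reports p at the machine floor unless the free
#'   fit already satisfies b = b0, in which case F = 0 and p = 1.
#' @export
slope_test <- function(x, y, b0 = 0) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("slope_test needs at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("x is constant; slope undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients[2]); a <- unname(fit$coefficients[1])
  rss1 <- sum(fit$residuals^2)
  z <- y - b0 * x
  rss0 <- sum((z - mean(z))^2)
  if (isTRUE(all.equal(b, b0))) return(list(slope = b, intercept = a, F = 0,
                                            p = 1, n = n, rss1 = rss1,
                                            rss0 = rss0))
  if (rss1 <= .Machine$double.eps * rss0) {
    return(list(slope = b, intercept = a, F = Inf,
                p = .Machine$double.xmin, n = n, rss1 = rss1, rss0 = rss0))
  }
  Fstat <- (rss0 - rss1) / (rss1 / (n - 2))
  list(slope = b, intercept = a, F = Fstat,
       p = max(stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
               .Machine$double.xmin),
       n = n, rss1 = rss1, rss0 = rss0)
}

#' Treatment rescue effect on phenotype z-scores
#'
#' For genes scored in a base screen and in a treated screen of the same
#' stratum, the rescue effect is `delta_z = z_treated - z_base`. The summary
#' reports the mean delta over a hit set with a bootstrap confidence
#' interval obtained by resampling genes. An antioxidant that blunts a
#' high-ROS phenotype yields negative delta_z over high-ROS hits.
#'
#' Because each screen is standardized against its own empirical
#' pseudogene null (and its own NTC recentering), the two z scales carry a
#' small screen-level offset that is shared by every gene and therefore
#' invisible to a gene-resampling bootstrap. With `align = TRUE` (default)
#' this nuisance offset is removed before summarizing, by subtracting the
#' median `delta_z` over a background gene set presumed unaffected by the
#' treatment — the cross-screen analogue of the per-replicate NTC-median
#' recentering. The default background is every shared gene outside
#' `hit_set` (falling back to all shared genes when fewer than 30 remain);
#' pass `background` explicitly when summarizing a set that is itself the
#' presumed-null background.
#'
#' @param base,treated Gene-score data frames with `gene` and `z`.
#' @param hit_set Character vector of hit genes to summarize.
#' @param n_boot Bootstrap draws (gene resampling).
#' @param conf Confidence level.
#' @param align Remove the shared cross-screen offset before summarizing.
#' @param background Genes used to estimate the offset; default
#'   `NULL` = shared genes outside `hit_set` (all shared genes if that
#'   complement has fewer than 30 members).
#' @param seed Seed for the bootstrap.
#' @return List with `delta` (data frame gene, z_base, z_treated, delta_z,
#'   offset-aligned when `align = TRUE`),
#'   `summary` (mean_delta, ci_lower, ci_upper, n_hits), `offset` (the
#'   subtracted cross-screen offset, 0 when `align = FALSE`), and
#'   `excluded` (hit genes missing from either screen).
#' @export
rescue_effect <- function(base, treated, hit_set, n_boot = 1e4L,
                          conf = 0.95, align = TRUE, background = NULL,
                          seed = 1L) {
  b <- as.data.frame(base); t <- as.data.frame(treated)
  common <- intersect(b$gene, t$gene)
  delta <- data.frame(gene = common,
                      z_base = b$z[match(common, b$gene)],
                      z_treated = t$z[match(common, t$gene)],
                      stringsAsFactors = FALSE)
  delta$delta_z <- delta$z_treated - delta$z_base
  offset <- 0
  if (align) {
    bg <- if (is.null(background)) {
      comp <- setdiff(common, hit_set)
      if (length(comp) >= 30L) comp else common
    } else intersect(background, common)
    if (!length(bg)) stop("alignment background has no genes in common")
    offset <- stats::median(delta$delta_z[delta$gene %in% bg])
  }
  delta$delta_z <- delta$delta_z - offset
  hits <- intersect(hit_set, common)
  excluded <- setdiff(hit_set, common)
  if (length(hits) == 0L) stop("no hit_set genes present in both screens")
  d <- delta$delta_z[match(hits, delta$gene)]
  boot <- with_seed_local(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(d, length(d), replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
  list(delta = delta,
       summary = list(mean_delta = mean(d), ci_lower = ci[1],
                      ci_upper = ci[2], n_hits = length(hits)),
       offset = offset,
       excluded = excluded)
}

#' Dunnett-style many-to-one comparisons with a Monte-Carlo reference
#'
#' One-way ANOVA layout: each non-control group is compared with the common
#' control by a pooled-variance t statistic; the family-wise adjusted
#' p-value is the Monte-Carlo tail probability of the maximum |t| across
#' comparisons under the null, preserving the correlation induced by the
#' shared control and the pooled variance estimate.
#'
#' @param groups Named list of numeric vectors (one per group, including the
#'   control); each group needs n >= 2.
#' @param control_label Name of the control group.
#' @param n_mc Monte-Carlo draws for the max-|t| null.
#' @param seed Seed; adjusted p-values are reproducible from it.
#' @return Data frame: `group`, `estimate` (mean difference vs control),
#'   `t`, `p_unadj` (two-sided pooled t-test), `p_adj` (Dunnett family-wise).
#' @export
dunnett_vs_control <- function(groups, control_label, n_mc = 1e5L,
                               seed = 1L) {
  if (!control_label %in% names(groups))
    stop("control group '", control_label, "' not found")
  if (length(groups) < 2L) stop("need at least one comparison group")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  k <- length(groups)
  N <- sum(ns)
  df <- N - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  if (s2 <= 0) stop("zero pooled variance")
  others <- setdiff(names(groups), control_label)
  nc <- ns[[control_label]]
  mc_mean <- mean(groups[[control_label]])
  est <- vapply(others, function(g) mean(groups[[g]]) - mc_mean, numeric(1))
  se <- sqrt(s2 * (1 / ns[others] + 1 / nc))
  tstat <- est / se
  p_unadj <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # null max-|t|: group means ~ N(0, s2/n), pooled SD ~ s*sqrt(chi2_df/df)
  maxt <- with_seed_local(seed, {
    zc <- stats::rnorm(n_mc, 0, sqrt(1 / nc))
    s_mc <- sqrt(stats::rchisq(n_mc, df) / df)
    m <- matrix(NA_real_, n_mc, length(others))
    for (j in seq_along(others)) {
      zj <- stats::rnorm(n_mc, 0, sqrt(1 / ns[[others[j]]]))
      m[, j] <- abs(zj - zc) / (s_mc * sqrt(1 / ns[[others[j]]] + 1 / nc))
    }
    apply(m, 1, max)
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), numeric(1))
  p_adj <- pmax(p_adj, 1 / (n_mc + 1))
  data.frame(group = others, estimate = unname(est), t = unname(tstat),
             p_unadj = unname(p_unadj), p_adj = unname(p_adj),
             row.names = NULL, stringsAsFactors = FALSE)
}
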