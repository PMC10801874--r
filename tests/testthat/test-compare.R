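gs_table <- function(genes, z) data.frame(gene = genes, z = z,
                                          stringsAsFactors = FALSE)

test_that("join_screens outer-joins with explicit missing values", {
  a <- gs_table(c("A", "B", "C", "D"), 1:4)
  b <- gs_table(c("A", "B", "C", "E"), 5:8)
  j <- join_screens(list(a, b), c("mito", "cyto"))
  expect_equal(nrow(j), 5L)
  expect_true(is.na(j$mito[j$gene == "E"]))
  expect_true(is.na(j$cyto[j$gene == "D"]))
  expect_false(any(j$cyto[j$gene == "D"] %in% 0))

  # self-join gives two identical columns
  jj <- join_screens(list(a, a), c("x", "y"))
  expect_equal(jj$x, jj$y)

  # column-order independence
  j2 <- join_screens(list(b, a), c("cyto", "mito"))
  expect_equal(j[, c("gene", "mito", "cyto")],
               j2[, c("gene", "mito", "cyto")])

  expect_error(join_screens(list(gs_table(c("A", "A"), 1:2)), "dup"),
               "duplicate gene")
  expect_error(join_screens(list(a, b), c("x", "x")), "unique")
})

test_that("correlation matrix reproduces closed-form Pearson arithmetic", {
  j <- data.frame(gene = c("a", "b", "c"), x = c(1, 2, 3), y = c(1, 3, 2))
  cm <- correlation_matrix(j)
  expect_equal(cm$r["x", "y"], 0.5, tolerance = 1e-12)
  # p from t = r*sqrt((n-2)/(1-r^2)) with n = 3
  t_oracle <- 0.5 * sqrt(1 / 0.75)
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$p["x", "y"], 2 * pt(t_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(cm$n["x", "y"], 3L)
  expect_true(isSymmetric(cm$r))

  # exact collinearity: r = 1, p reported above zero
  j2 <- data.frame(gene = letters[1:4], x = 1:4, y = c(2, 4, 6, 8))
  cm2 <- correlation_matrix(j2)
  expect_equal(cm2$r["x", "y"], 1)
  expect_gt(cm2$p["x", "y"], 0)
})

test_that("correlation is invariant to affine transforms up to sign", {
  set.seed(2)
  j <- data.frame(gene = paste0("g", 1:30), x = rnorm(30), y = rnorm(30))
  r0 <- correlation_matrix(j)$r["x", "y"]
  j$x <- 3 * j$x + 7
  expect_equal(correlation_matrix(j)$r["x", "y"], r0, tolerance = 1e-12)
  j$x <- -j$x
  expect_equal(correlation_matrix(j)$r["x", "y"], -r0, tolerance = 1e-12)
})

test_that("slope_test agrees with the closed-form extra-SS oracle", {
  # identity data: testing b0 = 1 is a perfect constrained fit
  x <- c(0, 1, 2, 3); y <- x
  r <- slope_test(x, y, b0 = 1)
  expect_equal(r$F, 0); expect_equal(r$p, 1)
  # same data against b0 = 0: perfect free fit, p at floor
  r0 <- slope_test(x, y, b0 = 0)
  expect_true(r0$p <= .Machine$double.xmin * 2)

  y2 <- c(0.1, 0.9, 2.2, 2.8)
  fit <- slope_test(x, y2, b0 = 0)
  oracle <- closed_form_slope_F(x, y2, 0)
  # by hand: Sxy = 4.7, Sxx = 5 -> slope 0.94
  expect_equal(fit$slope, 0.94, tolerance = 1e-12)
  expect_equal(fit$F, oracle$F, tolerance = 1e-6 * abs(oracle$F))
  expect_equal(fit$p, oracle$p, tolerance = 1e-6 * oracle$p)
  # oracle cross-check at b0 = 1 too
  o1 <- closed_form_slope_F(x, y2, 1)
  f1 <- slope_test(x, y2, 1)
  expect_equal(f1$F, o1$F, tolerance = 1e-9)

  expect_error(slope_test(1:2, 1:2, 0), "at least 3")
  expect_error(slope_test(rep(1, 5), rnorm(5), 0), "constant")
})

test_that("slope_test p is exactly 1 when the free slope equals b0", {
  set.seed(4)
  x <- rnorm(20); y <- 2.5 * x + 1
  r <- slope_test(x, y, b0 = 2.5)
  expect_equal(r$p, 1)
})

test_that("rescue_effect recovers a planted rescue and spares non-hits", {
  # deterministic toy: treated z = base z for all but hits
  genes <- paste0("g", 1:200)
  set.seed(10)
  zb <- rnorm(200); zt <- zb
  hits <- genes[1:20]
  zt[1:20] <- zb[1:20] - 3
  base <- gs_table(genes, zb); treated <- gs_table(genes, zt)
  re <- rescue_effect(base, treated, hits, n_boot = 2000, seed = 3)
  expect_equal(re$summary$mean_delta, -3, tolerance = 1e-9)
  expect_lt(re$summary$ci_upper, 0)
  re0 <- rescue_effect(base, treated, setdiff(genes, hits),
                       background = setdiff(genes, hits),
                       n_boot = 2000, seed = 3)
  expect_equal(re0$summary$mean_delta, 0, tolerance = 1e-9)

  # identical screens: all deltas zero
  reid <- rescue_effect(base, base, hits, n_boot = 500, seed = 1)
  expect_true(all(reid$delta$delta_z == 0))

  # gene present only in base is excluded and listed
  treated2 <- treated[treated$gene != "g1", ]
  re2 <- rescue_effect(base, treated2, hits, n_boot = 500, seed = 1)
  expect_true("g1" %in% re2$excluded)
  expect_error(rescue_effect(base, treated, "absent_gene"), "no hit_set")
})

test_that("substrate-independent effects yield highly correlated screens", {
  # the same knockdown population sorted twice under different conditions
  # with shared true effects: gene z-scores should agree strongly
  cfg <- sim_config(n_genes = 200, frac_null = 0.8, guides_per_gene = 5,
                    n_ntc = 100, depth = 5e5, n_replicates = 2, seed = 61)
  pop <- sortscreen:::sim_population(cfg)
  s1 <- sortscreen:::sim_from_population(cfg, pop, count_seed_offset = 0L)
  cfg2 <- cfg; cfg2$condition <- "glycolytic"
  s2 <- sortscreen:::sim_from_population(cfg2, pop,
                                         count_seed_offset = 2000L)
  g1 <- score_screen(s1$counts, s1$design, s1$library, n_pseudo = 500,
                     seed = 3)
  g2 <- score_screen(s2$counts, s2$design, s2$library, n_pseudo = 500,
                     seed = 3)
  j <- join_screens(list(g1, g2), c("resp", "glyc"))
  cm <- correlation_matrix(j, c("resp", "glyc"))
  expect_gt(cm$r["resp", "glyc"], 0.9)
})

test_that("dunnett_vs_control: null fixture, t-test reduction, oracle cross-check", {
  set.seed(6)
  g <- list(ctrl = rnorm(10), a = rnorm(10), b = rnorm(10), c = rnorm(10))
  d <- dunnett_vs_control(g, "ctrl", n_mc = 4e4, seed = 2)
  # adjustment is never anti-conservative
  expect_true(all(d$p_adj >= d$p_unadj - 0.01))
  expect_true(all(d$p_adj > 0.05))

  # two groups: adjusted p collapses to the pooled two-sample t-test
  g2 <- list(ctrl = rnorm(12), trt = rnorm(12, 1))
  d2 <- dunnett_vs_control(g2, "ctrl", n_mc = 1e5, seed = 3)
  tt <- t.test(g2$trt, g2$ctrl, var.equal = TRUE)
  expect_lt(abs(d2$p_adj - tt$p.value), 0.005) # Monte-Carlo error only
  expect_equal(d2$t, unname(tt$statistic), tolerance = 1e-10)

  expect_error(dunnett_vs_control(list(ctrl = c(1, 1), a = c(1, 1)), "ctrl"),
               "zero pooled variance")
  expect_error(dunnett_vs_control(g, "nope"), "not found")
})

test_that("dunnett detects a 2-SD shifted group and matches multcomp", {
  hitrate <- replicate(20, {
    g <- c(list(ctrl = rnorm(10)),
           setNames(lapply(1:4, function(i) rnorm(10) + (i == 1) * 2),
                    paste0("grp", 1:4)))
    d <- dunnett_vs_control(g, "ctrl", n_mc = 2e4, seed = 7)
    c(hit = d$p_adj[d$group == "grp1"] < 0.05,
      fp = any(d$p_adj[d$group != "grp1"] < 0.05))
  })
  expect_gte(mean(hitrate["hit", ]), 0.95)
  expect_lt(mean(hitrate["fp", ]), 0.3)

  # independent oracle: multcomp's multivariate-t Dunnett on one fixture
  set.seed(15)
  df <- data.frame(y = c(rnorm(8), rnorm(8, 1.2), rnorm(8, -0.4)),
                   grp = factor(rep(c("ctrl", "a", "b"), each = 8),
                                levels = c("ctrl", "a", "b")))
  fit <- stats::aov(y ~ grp, data = df)
  mc <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")))
  ours <- dunnett_vs_control(split(df$y, df$grp), "ctrl", n_mc = 2e5,
                             seed = 8)
  ref <- as.numeric(mc$test$pvalues)[match(ours$group, c("a", "b"))]
  expect_equal(ours$p_adj, ref, tolerance = 0.02)
})
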