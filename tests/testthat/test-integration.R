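test_that("floored log2 fold change handles zeros and exact powers", {
  expect_equal(log2_fold_change(3.2, 3.2), 0)
  expect_equal(log2_fold_change(0, 0, floor = 0.1), 0)
  expect_equal(log2_fold_change(1, 8), 3)
  expect_error(log2_fold_change(-1, 2), "non-negative")
})

test_that("quintiles partition genes into near-equal deterministic bins", {
  set.seed(81)
  k <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  e <- setNames(rnorm(100), names(k))
  qa <- quintile_expression_analysis(k, e)
  expect_equal(unname(table(qa$membership$quintile)), rep(20L, 5),
               ignore_attr = TRUE)
  expect_setequal(qa$membership$gene_id, names(k))
  # permutation invariance
  perm <- sample(100)
  qb <- quintile_expression_analysis(k[perm], e[perm])
  m1 <- qa$membership[order(qa$membership$gene_id), ]
  m2 <- qb$membership[order(qb$membership$gene_id), ]
  expect_equal(m1$quintile, m2$quintile)
  # membership equals the rank-based oracle (ties by gene id)
  expect_equal(setNames(m1$quintile, m1$gene_id), oracle_quintiles(k))
})

test_that("quintile t-test recovers a planted inverse relation", {
  set.seed(82)
  n <- 500
  k <- setNames(rnorm(n, 0, 1), sprintf("g%03d", 1:n))
  e <- setNames(-0.5 * k + rnorm(n, 0, 0.3), names(k))
  qa <- quintile_expression_analysis(k, e)
  expect_lt(qa$bottom_vs_top_p, 0.01)
  expect_gt(qa$summary$mean_expr_lfc[1], qa$summary$mean_expr_lfc[5])
})

test_that("identical expression changes give t = 0 and p = 1", {
  k <- setNames(1:50, sprintf("g%02d", 1:50))
  e <- setNames(rep(2, 50), names(k))
  qa <- quintile_expression_analysis(k, e)
  expect_true(all(qa$tests$t == 0))
  expect_true(all(qa$tests$p == 1))
  expect_error(quintile_expression_analysis(k[1:4], e[1:4]), "at least 5")
})

test_that("pooled Student t matches stats::t.test away from degeneracy", {
  set.seed(83)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  mine <- student_t_test(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)
  w <- student_t_test(x, y, welch = TRUE)
  expect_equal(w$p.value, t.test(x, y)$p.value)
})

test_that("segmented fit collapses to a line on linear data", {
  set.seed(84)
  x <- runif(50, -2, 2)
  y <- 1 + 0.7 * x
  fit <- segmented_fit(x, y)
  expect_lt(abs(fit$slope_right - fit$slope_left), 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("segmented fit recovers a planted breakpoint at -0.5", {
  set.seed(85)
  n <- 500
  x <- runif(n, -3, 2)
  y <- 0.3 + 0.2 * x + (1.0 - 0.2) * pmax(x + 0.5, 0) + rnorm(n, 0, 0.1)
  fit <- segmented_fit(x, y, psi_init = -0.5)
  expect_lt(abs(fit$psi - (-0.5)), 0.1)
  expect_lt(abs(fit$slope_left - 0.2), 0.2 * 0.2)
  expect_lt(abs(fit$slope_right - 1.0), 0.2 * 1.0)
  # RSS agrees with a dense grid-search oracle to 1e-6 relative
  grid <- seq(quantile(x, 0.05), quantile(x, 0.95), length.out = 2001)
  expect_lt(abs(fit$rss - oracle_grid_rss(x, y, grid)) / fit$rss, 1e-6)
  # far-off start with fallback lands on the same fit
  fit2 <- segmented_fit(x, y, psi_init = 2.0)
  expect_equal(fit2$psi, fit$psi, tolerance = 1e-3)
  expect_equal(fit2$rss, fit$rss, tolerance = 1e-8)
})

test_that("segmented RSS never exceeds the single-line RSS", {
  set.seed(86)
  for (rep in 1:10) {
    x <- rnorm(60)
    y <- rnorm(60) + sample(c(-1, 0, 1), 1) * x
    fit <- segmented_fit(x, y)
    line_rss <- sum(lm.fit(cbind(1, x), y)$residuals^2)
    expect_lte(fit$rss, line_rss + 1e-9)
  }
  expect_error(segmented_fit(rep(1, 20), rnorm(20)), "degenerate")
})

test_that("2-D density grid has the stated shape and integrates to ~1", {
  set.seed(87)
  x <- rnorm(400); y <- rnorm(400, 0, 2)
  dg <- kde2d_grid(x, y)
  expect_equal(dim(dg$z), c(50L, 50L))
  expect_length(dg$levels, 14)
  expect_true(all(dg$z >= 0))
  riemann <- sum(dg$z) * diff(dg$x[1:2]) * diff(dg$y[1:2])
  expect_lt(abs(riemann - 1), 0.05)

  # tight cluster at the origin peaks at the node nearest (0, 0)
  xc <- rnorm(200, 0, 0.01); yc <- rnorm(200, 0, 0.01)
  dgc <- kde2d_grid(xc, yc)
  peak <- which(dgc$z == max(dgc$z), arr.ind = TRUE)
  expect_lt(abs(dgc$x[peak[1]]), 0.05)
  expect_lt(abs(dgc$y[peak[2]]), 0.05)
  expect_error(kde2d_grid(rep(1, 10), rnorm(10)), "variance")
})

test_that("methylation class vs expression join matches a hand tally", {
  assign <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                       gene_id = c("g1", "g1", "g2", "g3", "g4", NA))
  changes <- data.frame(chrom = "chr1",
                        pos = c(10L, 20L, 30L, 40L, 50L, 60L),
                        class = factor(c("gain", "no_change", "gain", "loss",
                                         "no_change", "gain"),
                                       levels = c("gain", "loss",
                                                  "no_change")))
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     fpkm_a = c(1, 2, 4, 0.01),
                     fpkm_b = c(2, 1, 4, 0.02))
  out <- methylation_expression_association(assign, changes, expr)
  # g4 fails the 0.1 FPKM filter; the NA-gene CpG is dropped
  expect_equal(unname(c(out$class_counts)), c(2L, 1L, 1L))
  g1_lfc <- log2(2 / 1)
  expect_equal(out$data$expr_lfc[out$data$pos == 10L], g1_lfc)
  expect_equal(out$data$expr_lfc[out$data$pos == 40L], 0)
})

test_that("association with a single class yields no tests", {
  assign <- data.frame(chrom = "c", pos = c(1L, 2L), gene_id = c("g1", "g2"))
  changes <- data.frame(chrom = "c", pos = c(1L, 2L),
                        class = factor(c("no_change", "no_change"),
                                       levels = c("gain", "loss",
                                                  "no_change")))
  expr <- data.frame(gene_id = c("g1", "g2"), fpkm_a = c(1, 1),
                     fpkm_b = c(2, 3))
  out <- methylation_expression_association(assign, changes, expr)
  expect_null(out$tests)
  # one-member classes are skipped with a notice, not tested
  changes$class[1] <- "gain"
  out2 <- suppressMessages(
    methylation_expression_association(assign, changes, expr))
  expect_null(out2$tests)
  expect_gt(length(out2$skipped), 0)
})
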