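test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(n_prc2_targets = 300, n_genes = 200), "exceed")
  expect_error(sim_config(genotypes = c(wt = 1, bad = 1.5)), "\\[0, 1\\]")
  expect_error(sim_config(mean_coverage = 0), "positive")
  expect_error(sim_config(n_rrbs_replicates = 1), "replicates")
  expect_error(simulate_genome(sim_config(n_genes = 1000,
                                          genome_length = 1e6)),
               "too small")
})

test_that("an identical configuration yields a bit-identical cohort", {
  cfg <- small_cohort_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # a different seed changes the cohort
  c2 <- simulate_cohort(small_cohort_config(seed = 8))
  expect_false(identical(a$cpgs, c2$cpgs))
})

test_that("zero genes produce an empty annotation and no CpGs", {
  g <- simulate_genome(sim_config(n_genes = 0, n_prc2_targets = 0))
  expect_equal(nrow(g$annotation), 0L)
  expect_equal(nrow(g$cpgs), 0L)
})

test_that("CpG density is honored within 5% and genes do not overlap", {
  cfg <- sim_config(seed = 5, n_genes = 200, n_prc2_targets = 60,
                    genome_length = 2e6, cpg_density = 10)
  g <- simulate_genome(cfg)
  # independent recount of emitted positions
  expect_equal(nrow(g$cpgs), length(unique(g$cpgs$pos)))
  expect_true(all(g$cpgs$pos >= 0 & g$cpgs$pos < 2e6))
  expect_lt(abs(nrow(g$cpgs) - 20000) / 20000, 0.05)
  ann <- g$annotation[order(g$annotation$start), ]
  expect_true(all(utils::head(ann$end, -1) <= utils::tail(ann$start, -1)))
  expect_equal(sum(ann$prc2_target), 60L)
})

test_that("retention fraction drives the lost/maintained truth labels", {
  g <- simulate_genome(small_cohort_config(seed = 3))
  # retention 1 reproduces the wild-type K27 region set exactly
  cfg1 <- small_cohort_config(seed = 3, genotypes = c(wt = 1, mut = 1))
  ch1 <- simulate_chromatin(g, cfg1)
  expect_identical(ch1$regions$mut_d0$k27, ch1$regions$wt_d0$k27)
  expect_true(all(ch1$region_truth$status[
    ch1$region_truth$genotype == "mut"] == "maintained"))

  cfg0 <- small_cohort_config(seed = 3, genotypes = c(wt = 1, mut = 0))
  ch0 <- simulate_chromatin(g, cfg0)
  expect_equal(nrow(ch0$regions$mut_d0$k27), 0L)
  expect_true(all(ch0$region_truth$status[
    ch0$region_truth$genotype == "mut"] == "lost"))
})

test_that("retained counts fall in the binomial 99% interval", {
  cfg <- sim_config(seed = 11, n_genes = 450, n_prc2_targets = 400,
                    genome_length = 4e6, cpg_density = 1,
                    genotypes = c(wt = 1, mut = 0.5), reads_per_sample = 1e4)
  g <- simulate_genome(cfg)
  ch <- simulate_chromatin(g, cfg)
  kept <- sum(ch$region_truth$retained[ch$region_truth$genotype == "mut"])
  ci <- qbinom(c(0.005, 0.995), 400, 0.5)
  expect_gte(kept, ci[1])
  expect_lte(kept, ci[2])
})

test_that("methylation gain is planted only at lost-region CpGs", {
  co <- simulate_cohort(small_cohort_config(seed = 13))
  truth <- co$methylation$cpg_truth
  rt <- co$chromatin$region_truth
  lost <- rt$gene_id[rt$genotype == "Suz12GT" & rt$status == "lost"]
  # truth consistency: every gaining CpG lies inside a lost region
  expect_true(all(truth$region_gene[truth$gains_meth_Suz12GT] %in% lost))
  expect_false(any(truth$gains_meth_wt))

  tbl <- co$methylation$table
  gains <- truth$gains_meth_Suz12GT
  d <- meth_percent(tbl, "Suz12GT_d0_r1")[gains] -
    meth_percent(tbl, "wt_d0_r1")[gains]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 15), 4 * se + 0.5)
})

test_that("a zero delta leaves wild type and mutant exchangeable", {
  co <- simulate_cohort(small_cohort_config(seed = 14, meth_gain_delta = 0))
  truth <- co$methylation$cpg_truth
  tbl <- co$methylation$table
  in_reg <- truth$in_k27_region
  d <- meth_percent(tbl, "Suz12GT_d0_r1")[in_reg] -
    meth_percent(tbl, "wt_d0_r1")[in_reg]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 4 * se + 0.2)
})

test_that("replicates share truth and correlate strongly", {
  co <- simulate_cohort(small_cohort_config(seed = 15))
  tbl <- filter_by_coverage(co$methylation$table,
                            c("wt_d0_r1", "wt_d0_r2"))
  r <- cor(meth_percent(tbl, "wt_d0_r1"), meth_percent(tbl, "wt_d0_r2"))
  expect_gt(r, 0.8)
})

test_that("expression couples inversely to H3K27me3 with the planted slope", {
  cfg <- sim_config(seed = 17, n_genes = 500, n_prc2_targets = 500,
                    genome_length = 6e6, cpg_density = 1,
                    reads_per_sample = 1e4, expr_slope = 0.5,
                    expr_noise_sd = 0.1)
  g <- simulate_genome(cfg)
  ch <- simulate_chromatin(g, cfg)
  ex <- simulate_expression(g, ch, cfg)
  expect_true(all(as.matrix(ex$table[-1]) >= 0))
  tw <- ex$truth[ex$truth$genotype == "wt", ]
  dl <- log2(ex$table$fpkm.wt_d5) - log2(ex$table$fpkm.wt_d0)
  fit <- lm(dl ~ I(-tw$k27_lfc_true))
  expect_lt(abs(coef(fit)[2] - 0.5), 0.05)

  # slope 0: target and non-target changes indistinguishable
  cfg0 <- small_cohort_config(seed = 18, expr_slope = 0,
                              derepression_lfc = 0)
  co0 <- simulate_cohort(cfg0)
  d0 <- log2(co0$expression$table$fpkm.wt_d5) -
    log2(co0$expression$table$fpkm.wt_d0)
  tgt <- co0$annotation$prc2_target
  ks <- suppressWarnings(ks.test(d0[tgt], d0[!tgt]))
  expect_gt(ks$p.value, 0.01)
})

test_that("ChIP reads are enriched in regions with graded retention", {
  co <- simulate_cohort(small_cohort_config(seed = 19))
  ann <- co$annotation
  tgt <- ann[ann$prc2_target, ]
  rpm_at_targets <- function(lab) {
    mean(count_tss_window_signal(co$chromatin$reads[[lab]]$k27, tgt)$rpm)
  }
  wt <- rpm_at_targets("wt_d0")
  gt <- rpm_at_targets("Suz12GT_d0")
  nul <- rpm_at_targets("Eednull_d0")
  expect_gt(wt, gt)
  expect_gt(gt, nul)
})
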