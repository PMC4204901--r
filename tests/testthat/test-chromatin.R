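test_that("TSS window RPM follows the reads-per-million definition", {
  ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000L,
                    end = 8000L, strand = "+")
  no_reads <- data.frame(chrom = "chr1", pos = 100L)
  sig <- count_tss_window_signal(no_reads, ann, total_reads = 1e6)
  expect_equal(sig$rpm, 0)

  reads <- data.frame(chrom = "chr1", pos = c(4000L, 4999L, 5000L, 6999L,
                                              6500L, 7000L, 20L))
  sig <- count_tss_window_signal(reads, ann, half_window = 2000,
                                 total_reads = 2e6)
  # window [3000, 7000): 5 reads inside, pos 7000 and 20 outside
  expect_equal(sig$count, 5L)
  expect_equal(sig$rpm, 2.5)
})

test_that("TSS counting equals brute-force interval membership", {
  set.seed(51)
  for (rep in 1:5) {
    ann <- random_annotation(6)
    reads <- data.frame(chrom = sample(c("chr1", "chr2"), 400, TRUE),
                        pos = sample.int(2e5, 400))
    sig <- suppressWarnings(
      count_tss_window_signal(reads, ann, half_window = 1500))
    tss <- gene_tss(ann)
    brute <- vapply(seq_len(nrow(ann)), function(i) {
      sum(reads$chrom == ann$chrom[i] & reads$pos >= tss[i] - 1500 &
            reads$pos < tss[i] + 1500)
    }, 0L)
    expect_equal(sig$count, brute)
  }
})

test_that("RPM is invariant to duplicating reads and doubling the library", {
  set.seed(52)
  ann <- random_annotation(4)
  reads <- data.frame(chrom = "chr1", pos = sample.int(1e5, 300))
  a <- count_tss_window_signal(reads, ann)
  b <- count_tss_window_signal(rbind(reads, reads), ann)
  expect_equal(a$rpm, b$rpm)
})

test_that("metagene profile is strand-oriented and matches per-bin counts", {
  # minus-strand gene, reads only downstream of its TSS (smaller coords)
  ann <- data.frame(gene_id = "g1", chrom = "chr1", start = 10000L,
                    end = 15000L, strand = "-")
  tss <- 14999L
  reads <- data.frame(chrom = "chr1", pos = tss - sample.int(1500, 200))
  prof <- metagene_profile(reads, ann, half_window = 2000, bin = 50)
  left <- sum(prof$rpm[prof$offset < 0])
  right <- sum(prof$rpm[prof$offset >= 0])
  expect_gt(right, 0)
  expect_equal(left, 0)

  # equals brute-force per-bin oracle on a mixed-strand fixture
  set.seed(53)
  ann2 <- random_annotation(5)
  reads2 <- data.frame(chrom = "chr1", pos = sample.int(2e5, 2000, TRUE))
  prof2 <- metagene_profile(reads2, ann2, half_window = 1000, bin = 100)
  tss2 <- gene_tss(ann2)
  acc <- numeric(20)
  for (i in seq_len(nrow(ann2))) for (k in seq_len(nrow(reads2))) {
    off <- if (ann2$strand[i] == "+") reads2$pos[k] - tss2[i]
           else tss2[i] - reads2$pos[k]
    if (off >= -1000 && off < 1000) {
      b <- floor((off + 1000) / 100) + 1
      acc[b] <- acc[b] + 1
    }
  }
  expect_equal(prof2$rpm, acc * 1e6 / nrow(reads2) / nrow(ann2))
})

test_that("strand-flipping the annotation mirrors the metagene profile", {
  set.seed(54)
  ann <- random_annotation(5)
  reads <- data.frame(chrom = "chr1", pos = sample.int(2e5, 1000, TRUE))
  # drop reads whose offset falls exactly on a bin edge for any gene: the
  # half-open bins make edge reads reflect asymmetrically
  tss0 <- gene_tss(ann)
  on_edge <- vapply(reads$pos, function(p)
    any((abs(p - tss0) + 1000) %% 50 == 0), logical(1))
  reads <- reads[!on_edge, , drop = FALSE]
  flipped <- ann
  flipped$strand <- ifelse(ann$strand == "+", "-", "+")
  # flip moves the TSS; anchor both at the same point for the mirror check
  flipped$start <- ifelse(ann$strand == "+", ann$start - 1L, ann$end - 1L)
  flipped$end <- flipped$start + 1L
  anchored <- ann
  anchored$start <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  anchored$end <- anchored$start + 1L
  p1 <- metagene_profile(reads, anchored, half_window = 1000, bin = 50)
  p2 <- metagene_profile(reads, flipped, half_window = 1000, bin = 50)
  expect_equal(p1$rpm, rev(p2$rpm))
})

test_that("region retention is a ratio rule with boundary at >= 0.5", {
  reg <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L, 300L),
                    end = c(50L, 150L, 250L, 350L))
  out <- classify_region_retention(reg, rpm_wt = c(2, 2, 2, 2),
                                   rpm_mut = c(2, 1, 0.99, 0))
  expect_equal(as.character(out$status),
               c("maintained", "maintained", "lost", "lost"))
  expect_warning(
    classify_region_retention(reg[1, ], rpm_wt = 0, rpm_mut = 1),
    "zero wild-type")
})

test_that("retention classification recovers planted truth labels", {
  co <- simulate_cohort(small_cohort_config(seed = 7))
  reg_truth <- co$chromatin$region_truth
  gt <- reg_truth[reg_truth$genotype == "Suz12GT", ]
  reads_wt <- co$chromatin$reads$wt_d0$k27
  reads_mut <- co$chromatin$reads$Suz12GT_d0$k27
  reg <- gt[c("chrom", "start", "end")]
  out <- suppressWarnings(classify_region_retention(
    reg, region_rpm(reads_wt, reg), region_rpm(reads_mut, reg)))
  truth <- gt$status[match(paste(out$start, out$end),
                           paste(gt$start, gt$end))]
  acc <- mean(as.character(out$status) == truth)
  expect_gte(acc, 0.95)
})

test_that("CpG-region overlap respects the half-open convention", {
  cp <- data.frame(chrom = "chr1", pos = c(100L, 199L, 200L, 99L))
  reg <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  out <- overlap_cpgs_with_regions(cp, reg)
  expect_equal(out$pos, c(100L, 199L))  # start included, end excluded

  none <- overlap_cpgs_with_regions(cp, reg[integer(), ])
  expect_equal(nrow(none), 0L)
})

test_that("CpG-region overlap equals the quadratic membership oracle", {
  set.seed(55)
  for (rep in 1:3) {
    cp <- data.frame(chrom = sample(c("chr1", "chr2"), 800, TRUE),
                     pos = sample.int(1e5, 800))
    cp <- cp[order(cp$chrom, cp$pos), ]
    reg <- random_regions(40)
    reg$chrom <- sample(c("chr1", "chr2"), 40, TRUE)
    out <- overlap_cpgs_with_regions(cp, reg)
    hit <- oracle_overlap(cp, reg)
    expect_equal(out$pos, cp$pos[!is.na(hit)])
    expect_equal(out$region_id, hit[!is.na(hit)])
  }
})
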