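# Independent brute-force oracles and random fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the fast implementations.

oracle_summarize <- function(pileup) {
  # per-position loop; minus-strand G evidence folds into pos - 1
  units <- list()
  for (i in seq_len(nrow(pileup))) {
    anchor <- if (pileup$strand[i] == "+") pileup$pos[i] else pileup$pos[i] - 1L
    key <- paste(pileup$chrom[i], anchor)
    if (is.null(units[[key]])) units[[key]] <- c(0L, 0L)
    units[[key]] <- units[[key]] +
      c(pileup$total_reads[i], pileup$meth_reads[i])
  }
  keys <- names(units)
  parts <- strsplit(keys, " ")
  df <- data.frame(chrom = vapply(parts, `[`, "", 1),
                   pos = as.integer(vapply(parts, `[`, "", 2)),
                   cov = vapply(units, `[`, 0L, 1),
                   meth = vapply(units, `[`, 0L, 2))
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  df
}

oracle_filter <- function(x, samples, min_cov) {
  keep <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (s in samples) if (x[[paste0("cov.", s)]][i] < min_cov) ok <- FALSE
    keep[i] <- ok
  }
  which(keep)
}

oracle_bin2d <- function(pa, pb, n_bins) {
  m <- matrix(0L, n_bins, n_bins)
  w <- 100 / n_bins
  for (k in seq_along(pa)) {
    i <- min(floor(pa[k] / w) + 1, n_bins)
    j <- min(floor(pb[k] / w) + 1, n_bins)
    m[i, j] <- m[i, j] + 1L
  }
  m
}

oracle_overlap <- function(cpgs, regions) {
  # quadratic membership: first overlapping region in region order
  hit <- rep(NA_integer_, nrow(cpgs))
  for (i in seq_len(nrow(cpgs))) {
    for (r in seq_len(nrow(regions))) {
      if (cpgs$chrom[i] == regions$chrom[r] &&
          cpgs$pos[i] >= regions$start[r] && cpgs$pos[i] < regions$end[r]) {
        hit[i] <- r
        break
      }
    }
  }
  hit
}

oracle_point_dist <- function(pos, start, end) {
  if (pos >= start && pos < end) 0
  else if (pos < start) start - pos
  else pos - (end - 1)
}

oracle_assign <- function(cpgs, annotation, prc2_targets,
                          body_radius = 4000, neighbor_radius = 1000,
                          prc2_radius = 200000) {
  nearest <- function(pos, chrom, ann) {
    best_d <- Inf; best_g <- NA_character_
    for (j in seq_len(nrow(ann))) {
      if (ann$chrom[j] != chrom) next
      d <- oracle_point_dist(pos, ann$start[j], ann$end[j])
      if (d < best_d || (d == best_d && !is.na(best_g) &&
                         ann$gene_id[j] < best_g)) {
        best_d <- d; best_g <- ann$gene_id[j]
      }
    }
    list(d = best_d, g = best_g)
  }
  ord <- order(cpgs$chrom, cpgs$pos)
  cp <- cpgs[ord, , drop = FALSE]
  n <- nrow(cp)
  gene <- rep(NA_character_, n); rule <- rep("unassigned", n)
  dist <- rep(NA_real_, n)
  # pass 1
  for (i in seq_len(n)) {
    nb <- nearest(cp$pos[i], cp$chrom[i], annotation)
    if (is.finite(nb$d) && nb$d <= body_radius) {
      gene[i] <- nb$g; rule[i] <- "gene_body_4kb"; dist[i] <- nb$d
    }
  }
  # pass 2: inherit only from rule-1 donors, else PRC2 rule
  targets <- annotation[annotation$gene_id %in% prc2_targets, , drop = FALSE]
  for (i in which(rule == "unassigned")) {
    best_d <- Inf; best_g <- NA_character_
    for (j in which(rule == "gene_body_4kb")) {
      if (cp$chrom[j] != cp$chrom[i]) next
      d <- abs(cp$pos[j] - cp$pos[i])
      if (d <= neighbor_radius &&
          (d < best_d || (d == best_d && gene[j] < best_g))) {
        best_d <- d; best_g <- gene[j]
      }
    }
    if (is.finite(best_d)) {
      gene[i] <- best_g; rule[i] <- "neighbor_cpg"; dist[i] <- best_d
    } else {
      np <- nearest(cp$pos[i], cp$chrom[i], targets)
      if (is.finite(np$d) && np$d <= prc2_radius) {
        gene[i] <- np$g; rule[i] <- "nearest_prc2_200kb"; dist[i] <- np$d
      }
    }
  }
  data.frame(chrom = cp$chrom, pos = cp$pos, gene_id = gene, rule = rule,
             distance = dist)
}

oracle_quintiles <- function(k27_lfc, n_quantiles = 5) {
  genes <- names(k27_lfc)
  ord <- order(k27_lfc, genes)
  q <- integer(length(genes))
  for (r in seq_along(ord))
    q[ord[r]] <- ceiling(r * n_quantiles / length(ord))
  stats::setNames(q, genes)
}

oracle_grid_rss <- function(x, y, grid) {
  rss_at <- function(p)
    sum(stats::lm.fit(cbind(1, x, pmax(x - p, 0)), y)$residuals^2)
  rss <- vapply(grid, rss_at, numeric(1))
  b <- which.min(rss)
  # re-enumerate densely inside the winning bracket
  lo <- grid[max(b - 1, 1)]; hi <- grid[min(b + 1, length(grid))]
  fine <- seq(lo, hi, length.out = 4001)
  min(vapply(fine, rss_at, numeric(1)))
}

# fixture builders -----------------------------------------------------------

random_pileup <- function(n_cpg = 50, chroms = c("chrA", "chrB")) {
  pos <- sort(sample.int(10000, n_cpg))
  rows <- list()
  for (k in seq_len(n_cpg)) {
    ch <- sample(chroms, 1)
    tot_p <- sample(0:20, 1)
    if (tot_p > 0)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = pos[k] * 2L, strand = "+",
        meth_reads = sample(0:tot_p, 1), total_reads = tot_p)
    tot_m <- sample(0:20, 1)
    if (tot_m > 0)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = pos[k] * 2L + 1L, strand = "-",
        meth_reads = sample(0:tot_m, 1), total_reads = tot_m)
  }
  do.call(rbind, rows)
}

random_meth_table <- function(n = 40, samples = c("A", "B"),
                              max_cov = 30) {
  pos <- sort(sample.int(1e5, n))
  lst <- lapply(samples, function(s) {
    cov <- sample(0:max_cov, n, replace = TRUE)
    data.frame(chrom = "chr1", pos = pos, cov = cov,
               meth = vapply(cov, function(cc) sample(0:cc, 1), 0L))
  })
  meth_table(stats::setNames(lst, samples))
}

random_annotation <- function(n_genes = 6, span = 1e5, chrom = "chr1") {
  starts <- sort(sample.int(span - 6000, n_genes))
  len <- sample(500:3000, n_genes, replace = TRUE)
  # enforce non-overlap by spacing
  starts <- starts + seq(0, by = 6000, length.out = n_genes)
  data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
             chrom = chrom, start = starts, end = starts + len,
             strand = sample(c("+", "-"), n_genes, replace = TRUE))
}

random_regions <- function(n = 5, span = 1e5, chrom = "chr1") {
  s <- sample.int(span, n)
  data.frame(chrom = chrom, start = s, end = s + sample(200:4000, n, TRUE))
}

small_cohort_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 60, n_prc2_targets = 25,
             genome_length = 1e6, cpg_density = 5,
             reads_per_sample = 2e4, ...)
}
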