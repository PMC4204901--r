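# Readers, writers and the end-to-end orchestrator.
#
# All genomic text I/O follows BED conventions: 0-based half-open
# intervals, tab-separated, no quoting. Writers produce files their paired
# readers accept.

#' Read a BED file
#'
#' Accepts 3+ tab-separated columns (`chrom`, `start`, `end`, optionally
#' `name`, `score`, `strand`). Malformed lines are reported with their
#' line numbers. Records are returned sorted by (chrom, start, end).
#'
#' @param path File path.
#' @return data.frame with `chrom`, `start`, `end` and any optional
#'   columns present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(ncols < 3L)
  if (length(bad) == 0L) {
    start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | start >= end)
  }
  if (length(bad))
    .stopf("malformed BED line(s) in %s: %s", path,
           paste(utils::head(bad, 5), collapse = ", "))
  df <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                   start = start, end = end)
  nc <- min(ncols)
  if (nc >= 4L) df$name <- vapply(parts, `[[`, "", 4L)
  if (nc >= 5L) df$score <- suppressWarnings(
    as.numeric(vapply(parts, `[[`, "", 5L)))
  if (nc >= 6L) {
    df$strand <- vapply(parts, `[[`, "", 6L)
    if (!all(df$strand %in% c("+", "-", ".")))
      .stopf("invalid strand token in %s", path)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write regions or read positions as BED
#'
#' @param x data.frame with `chrom`, `start`, `end` (regions) or `chrom`,
#'   `pos` (points, written as width-1 intervals), plus optional `name`,
#'   `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (!"start" %in% names(x) && "pos" %in% names(x)) {
    x <- data.frame(chrom = x$chrom, start = x$pos, end = x$pos + 1L)
  }
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 6-column annotation BED
#'
#' Columns: chrom, start, end, gene id, score (ignored), strand.
#'
#' @param path File path.
#' @return Annotation data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`), sorted by (chrom, start).
#' @export
read_annotation_bed <- function(path) {
  df <- read_bed(path)
  if (!all(c("name", "strand") %in% names(df)))
    .stopf("annotation BED %s needs 6 columns (name and strand)", path)
  out <- data.frame(gene_id = df$name, chrom = df$chrom, start = df$start,
                    end = df$end, strand = df$strand)
  if (anyDuplicated(out$gene_id)) .stopf("duplicate gene ids in %s", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read / write the wide per-sample methylation TSV
#'
#' The native schema is a header line `chrom pos cov.<sample> meth.<sample>
#' ...` followed by one row per CpG. Round-tripping through
#' [write_methylation_tsv()] and back is the identity.
#'
#' @param path File path.
#' @return A [meth_table()].
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("chrom", "pos") %in% names(df)))
    .stopf("%s: missing chrom/pos columns", path)
  covs <- grep("^cov\\.", names(df), value = TRUE)
  samples <- sub("^cov\\.", "", covs)
  if (length(samples) == 0L) .stopf("%s: no cov.<sample> columns", path)
  miss <- samples[!paste0("meth.", samples) %in% names(df)]
  if (length(miss)) .stopf("%s: missing meth.%s column", path, miss[1])
  for (s in samples)
    if (any(df[[paste0("meth.", s)]] > df[[paste0("cov.", s)]]))
      .stopf("%s: methylated count exceeds coverage (sample %s)", path, s)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "samples") <- samples
  class(df) <- c("meth_table", "data.frame")
  df
}

#' @rdname read_methylation_tsv
#' @param x A `meth_table`.
#' @export
write_methylation_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a bismark-style coverage file as one methylation sample
#'
#' Six tab-separated columns without header: chrom, start (1-based), end,
#' percent methylation, methylated count, unmethylated count. Positions
#' are converted to the package's 0-based convention; counts, not the
#' percent column, are authoritative.
#'
#' @param path File path.
#' @param sample Sample label for the resulting table.
#' @return A single-sample [meth_table()].
#' @export
read_bismark_cov <- function(path, sample = "sample1") {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) .stopf("%s: bismark coverage needs 6 columns", path)
  names(df)[1:6] <- c("chrom", "start", "end", "pct", "nmeth", "nunmeth")
  meth_table(stats::setNames(list(data.frame(
    chrom = df$chrom, pos = df$start - 1L,
    cov = df$nmeth + df$nunmeth, meth = df$nmeth)), sample))
}

#' Read / write expression tables
#'
#' Tab-separated with header: `gene_id` then one FPKM column per sample
#' (`fpkm.<sample>`).
#'
#' @param path File path.
#' @return data.frame `gene_id` + `fpkm.<sample>` columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) .stopf("%s: missing gene_id column", path)
  if (any(as.matrix(df[grep("^fpkm\\.", names(df))]) < 0))
    .stopf("%s: negative FPKM", path)
  df
}

#' @rdname read_expression_tsv
#' @param x Expression data.frame.
#' @export
write_expression_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits annotation BED, per-sample region and read BEDs for both marks,
#' the wide methylation TSV, the expression TSV, and truth TSVs.
#'
#' @param cohort A `prc_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cohort$annotation
  write_bed(data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
                       name = ann$gene_id, score = 0, strand = ann$strand),
            file.path(dir, "annotation.bed"))
  writeLines(cohort$prc2_targets, file.path(dir, "prc2_targets.txt"))
  for (lab in names(cohort$chromatin$reads)) {
    for (mark in c("k27", "k4")) {
      write_bed(cohort$chromatin$reads[[lab]][[mark]],
                file.path(dir, sprintf("reads_%s_%s.bed", mark, lab)))
      write_bed(cohort$chromatin$regions[[lab]][[mark]],
                file.path(dir, sprintf("regions_%s_%s.bed", mark, lab)))
    }
  }
  write_methylation_tsv(cohort$methylation$table,
                        file.path(dir, "methylation.tsv"))
  write_expression_tsv(cohort$expression$table,
                       file.path(dir, "expression.tsv"))
  utils::write.table(cohort$chromatin$region_truth,
                     file.path(dir, "truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$methylation$cpg_truth,
                     file.path(dir, "truth_cpgs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Executes the stages in order — ChIP TSS quantification, bivalency
#' resolution, methylation filtering, the 2-D enrichment matrix against
#' the replicate background, CpG-to-gene assignment, and the
#' methylation/expression integration — comparing `genotype` against wild
#' type at `timepoint`, and writes each stage's tables plus a JSON run
#' manifest (parameters, input checksums) to `outdir`. The pipeline is a
#' pure function of its inputs: rerunning yields byte-identical outputs.
#'
#' @param cohort_dir Directory written by [write_cohort()].
#' @param outdir Output directory.
#' @param genotype Mutant genotype to compare against `wt`.
#' @param timepoint Timepoint label (default "d0").
#' @param params Optional overrides: `min_cov`, `n_bins`, `delta`,
#'   `alpha`, `retention_ratio`, `min_fpkm`, `half_window`.
#' @return Invisible list with the main stage results.
#' @export
run_all <- function(cohort_dir, outdir, genotype = "Suz12GT",
                    timepoint = "d0", params = list()) {
  p <- utils::modifyList(list(min_cov = 10, n_bins = 10, delta = 10,
                              alpha = 5e-7, retention_ratio = 0.5,
                              min_fpkm = 0.1, half_window = 2000), params)
  need <- c("annotation.bed", "prc2_targets.txt", "methylation.tsv",
            "expression.tsv",
            sprintf("reads_k27_%s_%s.bed", c("wt", genotype), timepoint),
            sprintf("regions_k27_wt_%s.bed", timepoint))
  missing <- need[!file.exists(file.path(cohort_dir, need))]
  if (length(missing))
    .stopf("missing input file(s): %s", paste(missing, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  ann <- read_annotation_bed(file.path(cohort_dir, "annotation.bed"))
  prc2 <- readLines(file.path(cohort_dir, "prc2_targets.txt"))
  wt_lab <- paste0("wt_", timepoint)
  mut_lab <- paste0(genotype, "_", timepoint)

  # chip: TSS RPM + region retention
  chip <- stage("chip", {
    r_wt <- read_bed(file.path(cohort_dir,
                               sprintf("reads_k27_%s.bed", wt_lab)))
    r_mut <- read_bed(file.path(cohort_dir,
                                sprintf("reads_k27_%s.bed", mut_lab)))
    reads_wt <- data.frame(chrom = r_wt$chrom, pos = r_wt$start)
    reads_mut <- data.frame(chrom = r_mut$chrom, pos = r_mut$start)
    reg <- read_bed(file.path(cohort_dir,
                              sprintf("regions_k27_%s.bed", wt_lab)))
    sig_wt <- count_tss_window_signal(reads_wt, ann, p$half_window)
    sig_mut <- count_tss_window_signal(reads_mut, ann, p$half_window)
    retention <- classify_region_retention(
      reg, region_rpm(reads_wt, reg), region_rpm(reads_mut, reg),
      retention_ratio = p$retention_ratio)
    list(signal = data.frame(gene_id = sig_wt$gene_id, rpm_wt = sig_wt$rpm,
                             rpm_mut = sig_mut$rpm),
         retention = retention)
  })
  utils::write.table(chip$signal, file.path(outdir, "chip_signal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(chip$retention, file.path(outdir, "region_retention.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # bivalency: wt promoter states d0 vs d5 + resolution
  bivalency <- stage("bivalency", {
    tp <- c("d0", "d5")
    reg_files <- sprintf("regions_%s_wt_%s.bed",
                         rep(c("k27", "k4"), 2), rep(tp, each = 2))
    if (all(file.exists(file.path(cohort_dir, reg_files)))) {
      st <- lapply(tp, function(t) call_promoter_state(
        ann,
        read_bed(file.path(cohort_dir, sprintf("regions_k27_wt_%s.bed", t))),
        read_bed(file.path(cohort_dir, sprintf("regions_k4_wt_%s.bed", t))),
        half_window = p$half_window))
      biv <- st[[1]]$gene_id[st[[1]]$state == "bivalent" |
                               st[[2]]$state == "bivalent"]
      sig <- lapply(tp, function(t) {
        k27 <- read_bed(file.path(cohort_dir,
                                  sprintf("reads_k27_wt_%s.bed", t)))
        k4 <- read_bed(file.path(cohort_dir,
                                 sprintf("reads_k4_wt_%s.bed", t)))
        list(k27 = count_tss_window_signal(
               data.frame(chrom = k27$chrom, pos = k27$start), ann,
               p$half_window),
             k4 = count_tss_window_signal(
               data.frame(chrom = k4$chrom, pos = k4$start), ann,
               p$half_window))
      })
      sg <- data.frame(gene_id = ann$gene_id,
                       k27_d0 = sig[[1]]$k27$rpm, k27_d5 = sig[[2]]$k27$rpm,
                       k4_d0 = sig[[1]]$k4$rpm, k4_d5 = sig[[2]]$k4$rpm)
      calls <- resolve_bivalency(sg[sg$gene_id %in% biv, , drop = FALSE])
      calls
    } else NULL
  })
  if (!is.null(bivalency))
    utils::write.table(bivalency, file.path(outdir, "bivalency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # methylation: filter + matrix + classes (replicate r1 of each sample)
  meth <- stage("methylation", {
    tbl <- read_methylation_tsv(file.path(cohort_dir, "methylation.tsv"))
    a <- paste0(wt_lab, "_r1"); b <- paste0(mut_lab, "_r1")
    tf <- filter_by_coverage(tbl, c(a, b), min_cov = p$min_cov)
    reg <- read_bed(file.path(cohort_dir,
                              sprintf("regions_k27_%s.bed", wt_lab)))
    tf_reg <- overlap_cpgs_with_regions(tf, reg)
    samples <- meth_samples(tbl)
    cells <- unique(sub("_r[0-9]+$", "", samples))
    pairs <- lapply(cells, function(cl) paste0(cl, c("_r1", "_r2")))
    pairs <- Filter(function(pr) all(pr %in% samples), pairs)
    # background on the same site universe as the observed matrix
    tbl_reg <- overlap_cpgs_with_regions(tbl, reg)
    bg <- build_background_model(tbl_reg, pairs, n_bins = p$n_bins,
                                 min_cov = p$min_cov)
    obs <- bin_methylation_2d(tf_reg, a, b, n_bins = p$n_bins)
    enr <- compute_fold_enrichment(obs, bg, alpha = p$alpha)
    changes <- classify_cpg_changes(tf_reg, a, b, delta = p$delta)
    list(filtered = tf, in_region = tf_reg, observed = obs,
         enrichment = enr, changes = changes, sample_a = a, sample_b = b)
  })
  write_methylation_tsv(meth$filtered,
                        file.path(outdir, "methylation_filtered.tsv"))
  for (nm in c("observed", "expected", "fold", "p"))
    utils::write.table(
      if (nm == "observed") meth$enrichment$observed else meth$enrichment[[nm]],
      file.path(outdir, paste0("matrix_", nm, ".tsv")),
      sep = "\t", quote = FALSE)
  utils::write.table(meth$changes, file.path(outdir, "cpg_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # assignment of in-region CpGs to genes
  assign <- stage("assign", {
    assign_all(meth$in_region, ann, prc2_targets = prc2)
  })
  utils::write.table(assign, file.path(outdir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # integration: methylation class vs expression change
  integration <- stage("integrate", {
    expr <- read_expression_tsv(file.path(cohort_dir, "expression.tsv"))
    ex <- data.frame(gene_id = expr$gene_id,
                     fpkm_a = expr[[paste0("fpkm.", wt_lab)]],
                     fpkm_b = expr[[paste0("fpkm.", mut_lab)]])
    methylation_expression_association(assign, meth$changes, ex,
                                       min_fpkm = p$min_fpkm)
  })
  utils::write.table(integration$data,
                     file.path(outdir, "meth_expr_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(integration$tests))
    utils::write.table(integration$tests,
                       file.path(outdir, "meth_expr_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "prcmeth",
    version = as.character(utils::packageVersion("prcmeth")),
    genotype = genotype, timepoint = timepoint, params = p,
    inputs = as.list(tools::md5sum(file.path(cohort_dir, need))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outdir, "run_manifest.json"))
  invisible(list(chip = chip, bivalency = bivalency, methylation = meth,
                 assignments = assign, integration = integration))
}
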