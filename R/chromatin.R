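# ChIP-seq signal quantification: reads-per-million in TSS windows and
# enriched regions, strand-oriented metagene profiles, lost/maintained
# region classification, and CpG-in-region overlap.
#
# Reads are single-base 5' positions (chrom, pos; 0-based). Regions and
# windows are half-open [start, end). Normalization is reads per million
# total mapped reads (RPM).

#' Transcription start sites of an annotation
#'
#' TSS of a plus-strand gene is its `start`; of a minus-strand gene,
#' `end - 1` (0-based).
#'
#' @param annotation data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @return Integer vector of TSS positions, named by gene id.
#' @export
gene_tss <- function(annotation) {
  stopifnot(all(annotation$strand %in% c("+", "-")))
  stats::setNames(ifelse(annotation$strand == "+",
                         annotation$start, annotation$end - 1L),
                  annotation$gene_id)
}

#' RPM in TSS windows
#'
#' Counts read 5' positions inside `[TSS - half_window, TSS + half_window)`
#' per gene and normalizes to reads per million total mapped reads.
#'
#' @param reads data.frame `chrom`, `pos` of read 5' positions.
#' @param annotation Gene annotation (see [gene_tss()]).
#' @param half_window Half window size in bp (default 2000).
#' @param total_reads Library size; defaults to `nrow(reads)`.
#' @return data.frame `gene_id`, `count`, `rpm`.
#' @export
count_tss_window_signal <- function(reads, annotation, half_window = 2000,
                                    total_reads = nrow(reads)) {
  if (total_reads <= 0) .stopf("total mapped reads must be positive")
  tss <- gene_tss(annotation)
  lo <- pmax(tss - half_window, 0L)
  hi <- tss + half_window
  missing_chrom <- !annotation$chrom %in% unique(as.character(reads$chrom))
  if (any(missing_chrom))
    .warnf("%d gene(s) on chromosomes absent from the read set (count 0)",
           sum(missing_chrom))
  win <- GenomicRanges::GRanges(as.character(annotation$chrom),
                                IRanges::IRanges(lo + 1L, hi))
  cnt <- if (nrow(reads) == 0L) integer(length(win))
         else GenomicRanges::countOverlaps(win, .gr_points(reads))
  data.frame(gene_id = annotation$gene_id, count = as.integer(cnt),
             rpm = cnt * 1e6 / total_reads)
}

#' Strand-oriented metagene profile around the TSS
#'
#' Mean RPM per position bin across a gene set, aligned at the TSS with
#' minus-strand genes flipped so that downstream of the TSS is rightward.
#'
#' @inheritParams count_tss_window_signal
#' @param bin Bin width in bp; `2 * half_window` must be a multiple.
#' @return data.frame `offset` (bin start relative to TSS), `rpm`
#'   (mean RPM per bin per gene).
#' @export
metagene_profile <- function(reads, annotation, half_window = 2000, bin = 50,
                             total_reads = nrow(reads)) {
  if (nrow(annotation) == 0L) .stopf("empty gene set")
  n_bins <- 2 * half_window / bin
  if (n_bins != round(n_bins)) .stopf("2*half_window must be a multiple of bin")
  n_bins <- as.integer(n_bins)
  tss <- gene_tss(annotation)
  acc <- numeric(n_bins)
  if (nrow(reads) > 0L) {
    win <- GenomicRanges::GRanges(
      as.character(annotation$chrom),
      IRanges::IRanges(pmax(tss - half_window, 0L) + 1L, tss + half_window))
    hits <- GenomicRanges::findOverlaps(win, .gr_points(reads))
    gi <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    off <- ifelse(annotation$strand[gi] == "+",
                  reads$pos[ri] - tss[gi],
                  tss[gi] - reads$pos[ri])
    keep <- off >= -half_window & off < half_window
    idx <- floor((off[keep] + half_window) / bin) + 1L
    tab <- tabulate(idx, nbins = n_bins)
    acc <- acc + tab
  }
  data.frame(offset = seq(-half_window, half_window - bin, by = bin),
             rpm = acc * 1e6 / total_reads / nrow(annotation))
}

#' RPM within regions
#'
#' @param reads data.frame `chrom`, `pos`.
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param total_reads Library size; defaults to `nrow(reads)`.
#' @return Numeric vector of RPM, one per region.
#' @export
region_rpm <- function(reads, regions, total_reads = nrow(reads)) {
  if (total_reads <= 0) .stopf("total mapped reads must be positive")
  if (nrow(regions) == 0L) return(numeric())
  cnt <- if (nrow(reads) == 0L) integer(nrow(regions))
         else GenomicRanges::countOverlaps(.gr_regions(regions), .gr_points(reads))
  cnt * 1e6 / total_reads
}

#' Classify wild-type enriched regions as maintained or lost in a mutant
#'
#' A region is maintained when the mutant/wild-type RPM ratio is at least
#' `retention_ratio` and the mutant RPM is at least `min_signal`; otherwise
#' it is lost. Regions with zero wild-type RPM (nominally "enriched" yet
#' empty) are dropped with a warning.
#'
#' @param regions data.frame `chrom`, `start`, `end` of wild-type enriched
#'   regions.
#' @param rpm_wt,rpm_mut Region RPM in wild type and mutant (same order as
#'   `regions`; see [region_rpm()]).
#' @param retention_ratio Minimum mutant/wt ratio to call maintained
#'   (default 0.5).
#' @param min_signal Minimum mutant RPM to call maintained (default 0).
#' @return `regions` with added `rpm_wt`, `rpm_mut`, `ratio`, `status`
#'   (factor maintained/lost); dropped regions removed.
#' @export
classify_region_retention <- function(regions, rpm_wt, rpm_mut,
                                      retention_ratio = 0.5, min_signal = 0) {
  stopifnot(length(rpm_wt) == nrow(regions), length(rpm_mut) == nrow(regions))
  drop <- rpm_wt == 0
  if (any(drop))
    .warnf("%d enriched region(s) with zero wild-type RPM dropped", sum(drop))
  out <- regions[!drop, , drop = FALSE]
  w <- rpm_wt[!drop]; m <- rpm_mut[!drop]
  ratio <- m / w
  status <- ifelse(ratio >= retention_ratio & m >= min_signal,
                   "maintained", "lost")
  out$rpm_wt <- w
  out$rpm_mut <- m
  out$ratio <- ratio
  out$status <- factor(status, levels = c("maintained", "lost"))
  rownames(out) <- NULL
  out
}

#' Restrict CpGs to those inside regions
#'
#' A CpG is retained iff its position lies in `[start, end)` of some
#' region; the (first, in region order) overlapping region's index is
#' attached.
#'
#' @param x A `meth_table` (or any data.frame with `chrom`, `pos`).
#' @param regions data.frame `chrom`, `start`, `end`.
#' @return Subset of `x` with an added `region_id` integer column (row
#'   index into `regions`).
#' @export
overlap_cpgs_with_regions <- function(x, regions) {
  if (nrow(regions) == 0L || nrow(x) == 0L) {
    out <- x[integer(), , drop = FALSE]
    out$region_id <- integer()
    return(out)
  }
  hits <- GenomicRanges::findOverlaps(.gr_points(x), .gr_regions(regions),
                                      select = "first")
  keep <- !is.na(hits)
  out <- x[keep, , drop = FALSE]
  out$region_id <- hits[keep]
  attr(out, "samples") <- attr(x, "samples")
  rownames(out) <- NULL
  out
}
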