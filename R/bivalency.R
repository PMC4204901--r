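# Promoter chromatin states (H3K4me3 / H3K27me3) and bivalency resolution
# across differentiation.

#' Call promoter chromatin states from enriched-region sets
#'
#' A mark is present at a gene when any enriched region for that mark
#' overlaps the TSS +/- `half_window` window (half-open). States:
#' `bivalent` (both marks), `k4_only`, `k27_only`, `neither`.
#'
#' @param annotation Gene annotation (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param k27_regions,k4_regions data.frames `chrom`, `start`, `end` of
#'   enriched regions for each mark in one sample.
#' @param half_window TSS window half-size in bp (default 2000).
#' @param genes Optional gene ids to restrict to; unknown ids are an error.
#' @return data.frame `gene_id`, `k27`, `k4` (logical), `state` (factor).
#' @export
call_promoter_state <- function(annotation, k27_regions, k4_regions,
                                half_window = 2000, genes = NULL) {
  if (!is.null(genes)) {
    bad <- setdiff(genes, annotation$gene_id)
    if (length(bad)) .stopf("gene(s) absent from annotation: %s",
                            paste(utils::head(bad, 3), collapse = ", "))
    annotation <- annotation[match(genes, annotation$gene_id), , drop = FALSE]
  }
  tss <- gene_tss(annotation)
  win <- GenomicRanges::GRanges(
    as.character(annotation$chrom),
    IRanges::IRanges(pmax(tss - half_window, 0L) + 1L, tss + half_window))
  has_mark <- function(regions) {
    if (nrow(regions) == 0L) return(rep(FALSE, length(win)))
    GenomicRanges::countOverlaps(win, .gr_regions(regions)) > 0
  }
  k27 <- has_mark(k27_regions)
  k4 <- has_mark(k4_regions)
  state <- ifelse(k27 & k4, "bivalent",
           ifelse(k4, "k4_only", ifelse(k27, "k27_only", "neither")))
  data.frame(gene_id = annotation$gene_id, k27 = k27, k4 = k4,
             state = factor(state, levels = c("bivalent", "k4_only",
                                              "k27_only", "neither")))
}

#' Classify bivalency resolution over differentiation
#'
#' Applies fold-change thresholds to TSS-window signal of the two marks
#' between day 0 and day 5. A gene resolves toward repression when
#' H3K27me3 gains more than `k27_gain_fold` and H3K4me3 drops more than
#' `k4_loss_fold`; it resolves toward activation when H3K27me3 drops more
#' than `k27_loss_fold` and H3K4me3 gains more than `k4_gain_fold`;
#' otherwise it is unresolved. All inequalities are strict ("over
#' x-fold"); the repressed rule is evaluated first (both cannot hold at
#' these thresholds). Signals are floored at `signal_floor` RPM before
#' ratios.
#'
#' @param signal data.frame with columns `gene_id`, `k27_d0`, `k27_d5`,
#'   `k4_d0`, `k4_d5` (TSS-window RPM at the two timepoints).
#' @param k27_gain_fold,k4_loss_fold Thresholds for the repressed call
#'   (defaults 4 and 1.5).
#' @param k27_loss_fold,k4_gain_fold Thresholds for the active call
#'   (defaults 2 and 2).
#' @param signal_floor RPM floor so ratios are defined (default 0.1).
#' @return data.frame `gene_id`, `lfc_k27`, `lfc_k4` (log2 d5/d0),
#'   `class` (factor resolved_repressed / resolved_active / unresolved).
#' @export
resolve_bivalency <- function(signal, k27_gain_fold = 4, k4_loss_fold = 1.5,
                              k27_loss_fold = 2, k4_gain_fold = 2,
                              signal_floor = 0.1) {
  need <- c("gene_id", "k27_d0", "k27_d5", "k4_d0", "k4_d5")
  missing <- setdiff(need, names(signal))
  if (length(missing)) .stopf("missing timepoint column(s): %s",
                              paste(missing, collapse = ", "))
  f <- function(v) pmax(v, signal_floor)
  r27 <- f(signal$k27_d5) / f(signal$k27_d0)
  r4 <- f(signal$k4_d5) / f(signal$k4_d0)
  repressed <- r27 > k27_gain_fold & (1 / r4) > k4_loss_fold
  active <- (1 / r27) > k27_loss_fold & r4 > k4_gain_fold
  class <- ifelse(repressed, "resolved_repressed",
           ifelse(active, "resolved_active", "unresolved"))
  data.frame(gene_id = signal$gene_id,
             lfc_k27 = log2(r27), lfc_k4 = log2(r4),
             class = factor(class, levels = c("resolved_repressed",
                                              "resolved_active",
                                              "unresolved")))
}

#' Tabulate resolution calls, optionally against a second genotype
#'
#' @param calls Output of [resolve_bivalency()].
#' @param secondary_calls Optional second call set (e.g. a mutant) on the
#'   same genes; a class-by-class contingency table is added.
#' @return List with `counts` (named vector per class) and, when
#'   `secondary_calls` is given, `concordance` (primary x secondary table).
#' @export
tabulate_resolution <- function(calls, secondary_calls = NULL) {
  stopifnot(nrow(calls) >= 1L)
  out <- list(counts = table(calls$class))
  if (!is.null(secondary_calls)) {
    idx <- match(calls$gene_id, secondary_calls$gene_id)
    out$concordance <- table(primary = calls$class,
                             secondary = secondary_calls$class[idx])
  }
  out
}
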