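# Per-CpG methylation calling: strand-merged summarization of bisulfite
# pileups, percent-methylation with the 0.01% floor, and coverage filtering.
#
# Coordinate conventions: all positions are 0-based; intervals are half-open
# (BED style). A CpG unit is anchored at the plus-strand C; minus-strand G
# evidence at pos+1 is folded into the same unit.

#' Construct a methylation table
#'
#' A methylation table is a data.frame with columns `chrom`, `pos` and, for
#' each sample `S`, integer columns `cov.S` (read coverage) and `meth.S`
#' (methylation-supporting reads). Sites are sorted by (chrom, pos) and
#' unique. The sample labels are stored in `attr(x, "samples")`.
#'
#' @param sites Named list of per-sample data.frames with columns
#'   `chrom`, `pos`, `cov`, `meth`. Sites absent from a sample get
#'   coverage 0 in that sample.
#' @return A `meth_table` data.frame.
#' @export
meth_table <- function(sites) {
  stopifnot(is.list(sites), length(sites) >= 1L, !is.null(names(sites)))
  for (nm in names(sites)) {
    df <- sites[[nm]]
    if (!all(c("chrom", "pos", "cov", "meth") %in% names(df)))
      .stopf("sample '%s': need columns chrom, pos, cov, meth", nm)
    if (any(df$meth > df$cov))
      .stopf("sample '%s': methylated count exceeds coverage", nm)
    if (any(df$meth < 0 | df$cov < 0))
      .stopf("sample '%s': negative counts", nm)
  }
  keys <- unique(do.call(rbind, lapply(sites, function(d)
    data.frame(chrom = as.character(d$chrom), pos = as.integer(d$pos)))))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  out <- keys
  for (nm in names(sites)) {
    d <- sites[[nm]]
    idx <- match(paste(keys$chrom, keys$pos), paste(d$chrom, d$pos))
    cov <- ifelse(is.na(idx), 0L, as.integer(d$cov[idx]))
    met <- ifelse(is.na(idx), 0L, as.integer(d$meth[idx]))
    out[[paste0("cov.", nm)]] <- cov
    out[[paste0("meth.", nm)]] <- met
  }
  rownames(out) <- NULL
  attr(out, "samples") <- names(sites)
  class(out) <- c("meth_table", "data.frame")
  out
}

#' Sample labels of a methylation table
#' @param x A `meth_table`.
#' @return Character vector of sample labels.
#' @export
meth_samples <- function(x) {
  s <- attr(x, "samples")
  if (is.null(s)) sub("^cov\\.", "", grep("^cov\\.", names(x), value = TRUE))
  else s
}

.check_sample <- function(x, sample) {
  if (!all(paste0(c("cov.", "meth."), rep(sample, each = 2)) %in% names(x)))
    .stopf("unknown sample label '%s'", sample[!paste0("cov.", sample) %in% names(x)][1])
}

#' Summarize a strand-aware bisulfite pileup into CpG units
#'
#' Plus-strand C evidence at position p and minus-strand G evidence at the
#' paired position p+1 are summed into one CpG unit anchored at the
#' plus-strand C. Coverage and methylated counts are the sums over both
#' strands.
#'
#' @param pileup data.frame with columns `chrom`, `pos` (0-based),
#'   `strand` (`+`/`-`), `meth_reads`, `total_reads`.
#' @param sample Sample label used for the output columns.
#' @param merge_strands Merge the two strands of a CpG into one unit
#'   (default TRUE). With FALSE each strand stays its own record at its
#'   own position — an escape hatch for strand-resolved analyses.
#' @return A single-sample [meth_table()].
#' @export
summarize_cpg_methylation <- function(pileup, sample = "sample1",
                                      merge_strands = TRUE) {
  need <- c("chrom", "pos", "strand", "meth_reads", "total_reads")
  if (!all(need %in% names(pileup)))
    .stopf("pileup needs columns %s", paste(need, collapse = ", "))
  if (nrow(pileup) == 0L)
    return(meth_table(stats::setNames(list(
      data.frame(chrom = character(), pos = integer(),
                 cov = integer(), meth = integer())), sample)))
  if (!all(pileup$strand %in% c("+", "-")))
    .stopf("strand tokens must be '+' or '-'")
  if (any(pileup$meth_reads > pileup$total_reads))
    .stopf("methylated reads exceed total reads at a base")
  # anchor: plus-strand C keeps pos, minus-strand G maps to pos - 1
  anchor <- if (merge_strands)
    ifelse(pileup$strand == "+", pileup$pos, pileup$pos - 1L)
  else pileup$pos
  key <- paste(pileup$chrom, anchor)
  cov <- tapply(pileup$total_reads, key, sum)
  met <- tapply(pileup$meth_reads, key, sum)
  parts <- do.call(rbind, strsplit(names(cov), " ", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                   cov = as.integer(cov), meth = as.integer(met))
  meth_table(stats::setNames(list(df), sample))
}

#' Floor percent methylation at 0.01%
#'
#' Fully unmethylated CpGs are reported as 0.01% rather than 0 so that
#' downstream ratio and log arithmetic is defined.
#'
#' @param percent Numeric in \[0, 100\].
#' @return `pmax(percent, 0.01)`.
#' @export
apply_floor <- function(percent) {
  if (any(!is.finite(percent)) || any(percent < 0 | percent > 100))
    .stopf("percent methylation must lie in [0, 100]")
  pmax(percent, 0.01)
}

#' Percent methylation for one sample
#'
#' @param x A `meth_table`.
#' @param sample Sample label.
#' @param floored Apply the 0.01% floor (default TRUE). Raw counts are
#'   always preserved in the table; the floor only affects this derived
#'   value.
#' @return Numeric vector, one value per site (NA where coverage is 0).
#' @export
meth_percent <- function(x, sample, floored = TRUE) {
  .check_sample(x, sample)
  cov <- x[[paste0("cov.", sample)]]
  met <- x[[paste0("meth.", sample)]]
  p <- ifelse(cov > 0, 100 * met / cov, NA_real_)
  if (floored) p[!is.na(p)] <- apply_floor(p[!is.na(p)])
  p
}

#' Filter CpG sites by coverage in every listed sample
#'
#' Retains exactly the sites with coverage >= `min_cov` in each of
#' `samples` (the pairwise-comparison filter: 10x in both samples).
#'
#' @param x A `meth_table`.
#' @param samples Character vector of sample labels; default all samples.
#' @param min_cov Minimum coverage (default 10).
#' @return Filtered `meth_table`.
#' @export
filter_by_coverage <- function(x, samples = meth_samples(x), min_cov = 10) {
  for (s in samples) .check_sample(x, s)
  if (nrow(x) == 0L) return(x)
  keep <- rep(TRUE, nrow(x))
  for (s in samples) keep <- keep & x[[paste0("cov.", s)]] >= min_cov
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- meth_samples(x)
  class(out) <- class(x)
  out
}

#' Low / intermediate / high methylation fractions
#'
#' Fractions of CpGs that are lowly methylated (<= `low` percent),
#' intermediate, or highly methylated (>= `high` percent) in one sample.
#'
#' @param x A coverage-filtered `meth_table`.
#' @param sample Sample label.
#' @param low,high Percent thresholds; defaults 15 and 80. Boundary values
#'   count as low / high respectively.
#' @return Named numeric vector `c(low =, mid =, high =)` summing to 1.
#' @export
global_methylation_distribution <- function(x, sample, low = 15, high = 80) {
  p <- meth_percent(x, sample)
  p <- p[!is.na(p)]
  if (length(p) == 0L)
    .stopf("no covered sites in sample '%s': distribution undefined", sample)
  c(low = mean(p <= low), mid = mean(p > low & p < high),
    high = mean(p >= high))
}
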