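# Pairwise 2-D methylation comparison: binned count matrices, the
# replicate-based background (null) model, per-bin fold enrichment with an
# exact binomial test, and per-CpG change classification.

# Two-sided beta-binomial predictive test: the expected proportion was
# estimated from n_bg background sites, so the null predictive for the
# observed count is beta-binomial with a Jeffreys-smoothed beta posterior
# centred on e. Two-sidedness follows the minimum-likelihood rule used by
# stats::binom.test.
.betabinom_test <- function(o, n, e, n_bg) {
  a <- e * n_bg + 0.5
  b <- (1 - e) * n_bg + 0.5
  k <- 0:n
  logd <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  d <- exp(logd - max(logd))
  sum(d[d <= d[o + 1] * (1 + 1e-7)]) / sum(d)
}

.bin_index <- function(p, n_bins) {
  # left-closed, right-open bins over [0, 100]; last bin closed at 100
  width <- 100 / n_bins
  pmin(floor(p / width) + 1L, n_bins)
}

#' Bin shared CpGs by percent methylation in two samples
#'
#' Each CpG covered in both samples is placed in exactly one (binA, binB)
#' cell of an `n_bins` x `n_bins` grid over \[0, 100\] percent. Bins are
#' left-closed right-open; the last bin is closed at 100. Rows index
#' `sample_a`, columns `sample_b`.
#'
#' @param x A `meth_table`, already coverage-filtered to the shared site
#'   set of the two samples (see [filter_by_coverage()]).
#' @param sample_a,sample_b Sample labels for the two axes.
#' @param n_bins Number of bins per axis (default 10, i.e. 10-point bins).
#' @return List of class `binned_matrix`: `counts` (integer matrix with
#'   dimnames giving bin intervals), `edges`, `samples`, `n` (total CpGs).
#' @export
bin_methylation_2d <- function(x, sample_a, sample_b, n_bins = 10) {
  pa <- meth_percent(x, sample_a)
  pb <- meth_percent(x, sample_b)
  ok <- !is.na(pa) & !is.na(pb)
  if (!any(ok)) .stopf("no CpGs shared between '%s' and '%s'", sample_a, sample_b)
  ia <- .bin_index(pa[ok], n_bins)
  ib <- .bin_index(pb[ok], n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(ia)) counts[ia[k], ib[k]] <- counts[ia[k], ib[k]] + 1L
  edges <- seq(0, 100, length.out = n_bins + 1)
  lab <- sprintf("[%g,%g%s", edges[-length(edges)], edges[-1],
                 c(rep(")", n_bins - 1), "]"))
  dimnames(counts) <- list(lab, lab)
  structure(list(counts = counts, edges = edges,
                 samples = c(sample_a, sample_b), n = sum(ok)),
            class = "binned_matrix")
}

#' Replicate-based background model for the 2-D methylation matrix
#'
#' For each cell type, replicate 1 is binned against replicate 2 on their
#' own shared coverage-passing sites and the count matrix normalized to
#' proportions; the expected-proportion matrix is the unweighted mean of
#' these per-cell-type proportion matrices. Replicate noise thereby defines
#' how much off-diagonal mass is expected in the absence of a real
#' methylation difference.
#'
#' @param x A `meth_table` holding all replicate samples.
#' @param pairs List of length-2 character vectors, one `(rep1, rep2)` pair
#'   per cell type.
#' @param n_bins Bins per axis (default 10).
#' @param min_cov Coverage filter applied per pair (default 10).
#' @return Matrix of expected proportions (sums to 1).
#' @export
build_background_model <- function(x, pairs, n_bins = 10, min_cov = 10) {
  stopifnot(length(pairs) >= 1L)
  mats <- list()
  ns <- integer()
  for (pr in pairs) {
    stopifnot(length(pr) == 2L)
    xf <- filter_by_coverage(x, samples = pr, min_cov = min_cov)
    if (nrow(xf) == 0L) {
      .warnf("replicate pair (%s, %s) shares no sites; excluded", pr[1], pr[2])
      next
    }
    bm <- bin_methylation_2d(xf, pr[1], pr[2], n_bins = n_bins)
    mats[[length(mats) + 1L]] <- bm$counts / bm$n
    ns <- c(ns, bm$n)
  }
  if (length(mats) == 0L) .stopf("all replicate pairs were empty")
  out <- Reduce(`+`, mats) / length(mats)
  # total background size: lets the enrichment test propagate the sampling
  # uncertainty of the expected proportions (beta-binomial predictive test)
  attr(out, "n_background") <- sum(ns)
  out
}

#' Per-bin fold enrichment and significance against the background model
#'
#' Fold enrichment is the observed bin proportion over the expected bin
#' proportion. Significance per bin is a two-sided exact test of the
#' observed count given the total number of binned CpGs and the expected
#' proportion. When the expected matrix carries the size of the background
#' it was estimated from (as [build_background_model()] output does), a
#' beta-binomial predictive test is used so that the sampling uncertainty
#' of the expected proportions is propagated — with a plain binomial test
#' the estimation noise in sparse bins masquerades as signal. A bare
#' expected matrix (known proportions) gets the exact binomial test.
#' Benjamini-Hochberg q-values are reported alongside the raw p-values.
#' Bins with expected 0 and observed 0 are undefined (NA), not 0 or Inf.
#'
#' @param observed A `binned_matrix` (from [bin_methylation_2d()]).
#' @param expected Expected-proportion matrix on the same bin grid
#'   (from [build_background_model()]).
#' @param alpha Significance level for the `significant` flag
#'   (default 5e-7).
#' @return List of class `enrichment_matrix`: `observed` (proportions),
#'   `expected`, `fold`, `p`, `q`, `significant`, `n`, `alpha`.
#' @export
compute_fold_enrichment <- function(observed, expected, alpha = 5e-7) {
  stopifnot(inherits(observed, "binned_matrix"))
  if (!all(dim(expected) == dim(observed$counts)))
    .stopf("bin grid mismatch between observed and expected")
  n <- observed$n
  n_bg <- attr(expected, "n_background")
  obs_p <- observed$counts / n
  fold <- matrix(NA_real_, nrow(obs_p), ncol(obs_p), dimnames = dimnames(obs_p))
  pval <- fold
  for (i in seq_len(nrow(obs_p))) for (j in seq_len(ncol(obs_p))) {
    e <- expected[i, j]; o <- observed$counts[i, j]
    if (e > 0) fold[i, j] <- obs_p[i, j] / e
    else if (o > 0) fold[i, j] <- Inf
    if (e > 0 || o > 0) {
      pval[i, j] <- if (is.null(n_bg)) {
        if (e > 0) stats::binom.test(o, n, p = min(e, 1))$p.value else 0
      } else .betabinom_test(o, n, min(e, 1), n_bg)
    } # e == 0 and o == 0: undefined, stays NA
  }
  q <- pval
  def <- !is.na(pval)
  q[def] <- stats::p.adjust(pval[def], method = "BH")
  structure(list(observed = obs_p, expected = expected, fold = fold,
                 p = pval, q = q, significant = !is.na(pval) & pval < alpha,
                 n = n, alpha = alpha),
            class = "enrichment_matrix")
}

#' Classify per-CpG methylation changes between two samples
#'
#' A CpG gains methylation if percent in `sample_b` exceeds `sample_a` by
#' at least `delta` percentage points, loses if the reverse, otherwise it
#' is unchanged.
#'
#' @param x A `meth_table` filtered to sites covered in both samples.
#' @param sample_a,sample_b Sample labels (change is b relative to a).
#' @param delta Threshold in percentage points (default 10).
#' @return data.frame `chrom`, `pos`, `pct_a`, `pct_b`, `delta`, `class`
#'   (factor gain/loss/no_change).
#' @export
classify_cpg_changes <- function(x, sample_a, sample_b, delta = 10) {
  pa <- meth_percent(x, sample_a)
  pb <- meth_percent(x, sample_b)
  ok <- !is.na(pa) & !is.na(pb)
  d <- pb - pa
  cls <- ifelse(d >= delta, "gain", ifelse(-d >= delta, "loss", "no_change"))
  out <- data.frame(chrom = x$chrom, pos = x$pos, pct_a = pa, pct_b = pb,
                    delta = d,
                    class = factor(cls, levels = c("gain", "loss", "no_change")))
  out[ok, , drop = FALSE]
}
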