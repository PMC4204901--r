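# Internal helpers shared across modules.

# Deterministic 31-bit sub-seed from a master seed and a character key, so
# each simulated sample draws from its own reproducible stream and adding
# samples does not perturb existing ones.
.sub_seed <- function(seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Convert 0-based half-open region data.frame (chrom, start, end) to GRanges.
.gr_regions <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Convert 0-based point positions (chrom, pos) to width-1 GRanges.
.gr_points <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$pos + 1L, width = 1L)
  )
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Pooled-variance two-sided Student t-test
#'
#' Classical Student t-test with pooled variance, two-sided. Unlike
#' [stats::t.test()] it is defined for zero-variance input: when both groups
#' are constant and equal the statistic is 0 (p = 1); when they are constant
#' and different the statistic is infinite (p = 0). Set `welch = TRUE` to
#' delegate to [stats::t.test()] with unequal variances.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param welch Use the Welch unequal-variance test instead.
#' @return List with `statistic`, `df`, `p.value`, `estimate` (mean
#'   difference x - y).
#' @export
student_t_test <- function(x, y, welch = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    .stopf("student_t_test: each group needs >= 2 observations")
  if (welch) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    return(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p.value = ht$p.value, estimate = mean(x) - mean(y)))
  }
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  d <- mean(x) - mean(y)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    t <- d / se
    p <- 2 * stats::pt(-abs(t), df = df)
  }
  list(statistic = t, df = df, p.value = p, estimate = d)
}
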