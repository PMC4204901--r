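# Integration of chromatin, methylation and expression: log2 fold changes
# with a floor, quintile analysis of expression change versus H3K27me3
# change, one-breakpoint segmented regression, 2-D kernel density grids,
# and the methylation-change-class versus expression-change association.

#' Floored log2 fold change
#'
#' `log2(max(b, floor) / max(a, floor))` — the change of `b` relative to
#' `a` with both values floored so the ratio is always defined.
#'
#' @param a,b Non-negative values (FPKM or RPM).
#' @param floor Positive floor (default 0.1, matching the expression
#'   filter used downstream).
#' @return Numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(a, b, floor = 0.1) {
  if (any(a < 0 | b < 0)) .stopf("fold change inputs must be non-negative")
  log2(pmax(b, floor) / pmax(a, floor))
}

#' Quintile analysis of expression change by H3K27me3 change
#'
#' Genes are ranked by their H3K27me3 log2 fold change (ties broken by
#' gene id) and split into five bins of near-equal size (differing by at
#' most one gene). Per-quintile summaries of the expression log2 fold
#' change and pooled-variance two-sided Student t-tests between all
#' quintile pairs are reported.
#'
#' @param k27_lfc Named numeric vector: per-gene log2 fold change in
#'   H3K27me3 signal.
#' @param expr_lfc Named numeric vector: per-gene log2 fold change in
#'   expression. Genes are intersected with `k27_lfc`.
#' @param n_quantiles Number of bins (default 5).
#' @param welch Use Welch instead of pooled-variance t-tests.
#' @return List of class `quintile_analysis`: `membership` (data.frame
#'   `gene_id`, `k27_lfc`, `expr_lfc`, `quintile`), `summary` (per-bin n,
#'   mean, median), `tests` (data.frame of pairwise bins with t and p),
#'   `bottom_vs_top_p`.
#' @export
quintile_expression_analysis <- function(k27_lfc, expr_lfc, n_quantiles = 5,
                                         welch = FALSE) {
  genes <- intersect(names(k27_lfc), names(expr_lfc))
  if (length(genes) < n_quantiles)
    .stopf("need at least %d shared genes", n_quantiles)
  k <- k27_lfc[genes]; e <- expr_lfc[genes]
  ord <- order(k, genes)  # ties by gene id
  q <- integer(length(genes))
  q[ord] <- ceiling(seq_along(ord) * n_quantiles / length(ord))
  membership <- data.frame(gene_id = genes, k27_lfc = unname(k),
                           expr_lfc = unname(e), quintile = q)
  summary <- do.call(rbind, lapply(seq_len(n_quantiles), function(i) {
    v <- e[q == i]
    data.frame(quintile = i, n = length(v), mean_expr_lfc = mean(v),
               median_expr_lfc = stats::median(v))
  }))
  pairs <- utils::combn(n_quantiles, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ht <- student_t_test(e[q == i1], e[q == i2], welch = welch)
    data.frame(quintile_a = i1, quintile_b = i2,
               t = ht$statistic, p = ht$p.value)
  }))
  structure(list(membership = membership, summary = summary, tests = tests,
                 bottom_vs_top_p = tests$p[tests$quintile_a == 1 &
                                             tests$quintile_b == n_quantiles]),
            class = "quintile_analysis")
}

# continuous one-breakpoint fit at fixed psi; returns coef + rss
.broken_fit <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  f <- stats::lm.fit(X, y)
  list(coef = f$coefficients, rss = sum(f$residuals^2))
}

#' One-breakpoint segmented (broken-stick) regression
#'
#' Fits a continuous piecewise-linear least-squares model with a single
#' breakpoint. The breakpoint is found by Muggeo-style iterative
#' linearization starting from `psi_init`; if the iteration fails to
#' converge (or lands outside the search range) a dense grid search with
#' local refinement is used instead, and whichever candidate attains the
#' lowest residual sum of squares is returned. The plain single-line fit
#' is always a candidate, so the reported RSS never exceeds it. The
#' breakpoint search range is the \[5th, 95th\] percentile of `x`, keeping
#' the break away from the boundary.
#'
#' @param x,y Numeric vectors, `length >= 10`.
#' @param psi_init Starting breakpoint (default -0.5).
#' @param max_iter,tol Iteration controls for the linearization.
#' @return List of class `segmented_fit`: `psi`, `intercept`,
#'   `slope_left`, `slope_right`, `rss`, `converged` (did the iterative
#'   path converge), `method` ("iterative", "grid" or "line").
#' @export
segmented_fit <- function(x, y, psi_init = -0.5, max_iter = 50, tol = 1e-8) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) .stopf("segmented fit needs n >= 10")
  if (stats::sd(x) == 0) .stopf("x is degenerate (no spread)")
  rng <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  clamp <- function(p) min(max(p, rng[1]), rng[2])

  # iterative linearization: y ~ x + (x-psi)_+ + gamma * I(x>psi)
  psi <- clamp(psi_init)
  converged <- FALSE
  h <- 1          # step damping; halved on oscillation (no data point
  last_step <- 0  # between the two iterates, so the raw step cycles)
  for (it in seq_len(max_iter)) {
    U <- pmax(x - psi, 0)
    V <- as.numeric(x > psi)
    f <- stats::lm.fit(cbind(1, x, U, V), y)
    beta <- f$coefficients[3]; gamma <- f$coefficients[4]
    if (!is.finite(beta) || !is.finite(gamma) || beta == 0) break
    step <- -gamma / beta
    if (step * last_step < 0 && abs(step) >= 0.999 * abs(last_step))
      h <- h / 2
    last_step <- step
    psi_new <- clamp(psi + h * step)
    if (abs(psi_new - psi) < tol) { psi <- psi_new; converged <- TRUE; break }
    psi <- psi_new
  }
  cand <- list()
  if (is.finite(psi)) {
    bf <- .broken_fit(x, y, psi)
    cand$iterative <- c(list(psi = psi, method = "iterative"), bf)
  }
  # grid search fallback / cross-candidate: coarse grid, fine grid in the
  # winning bracket, then a local optimizer
  grid <- seq(rng[1], rng[2], length.out = 201)
  rss_g <- vapply(grid, function(p) .broken_fit(x, y, p)$rss, numeric(1))
  best <- which.min(rss_g)
  lo <- grid[max(best - 1L, 1L)]; hi <- grid[min(best + 1L, length(grid))]
  fine <- seq(lo, hi, length.out = 201)
  rss_f <- vapply(fine, function(p) .broken_fit(x, y, p)$rss, numeric(1))
  bf <- which.min(rss_f)
  flo <- fine[max(bf - 1L, 1L)]; fhi <- fine[min(bf + 1L, length(fine))]
  opt <- fine[bf]
  if (flo < fhi) {
    om <- stats::optimize(function(p) .broken_fit(x, y, p)$rss, c(flo, fhi),
                          tol = 1e-9)
    if (om$objective < rss_f[bf]) opt <- om$minimum
  }
  bg <- .broken_fit(x, y, opt)
  cand$grid <- c(list(psi = opt, method = "grid"), bg)
  # straight line candidate (slope difference 0)
  lf <- stats::lm.fit(cbind(1, x), y)
  cand$line <- list(psi = clamp(psi_init), method = "line",
                    coef = c(lf$coefficients, 0),
                    rss = sum(lf$residuals^2))
  pick <- cand[[which.min(vapply(cand, `[[`, numeric(1), "rss"))]]
  co <- pick$coef
  structure(list(psi = unname(pick$psi), intercept = unname(co[1]),
                 slope_left = unname(co[2]),
                 slope_right = unname(co[2] + co[3]),
                 rss = pick$rss, converged = converged,
                 method = pick$method),
            class = "segmented_fit")
}

#' Two-dimensional kernel density grid with contour levels
#'
#' Bivariate Gaussian product-kernel density (via [MASS::kde2d()]) with
#' normal-reference bandwidth per axis, evaluated on an `n_grid` x
#' `n_grid` grid, plus `n_levels` equally spaced contour levels between 0
#' and the maximum density. The grid extends one bandwidth beyond the data
#' range on each side so that essentially all density mass falls on the
#' grid (the cell-area-weighted sum of the grid integrates to ~1).
#'
#' @param x,y Numeric vectors (n >= 2, finite).
#' @param n_grid Grid points per axis (default 50).
#' @param n_levels Number of contour levels (default 14).
#' @return List of class `density_grid`: `x`, `y` (grid coordinates),
#'   `z` (density matrix), `levels`.
#' @export
kde2d_grid <- function(x, y, n_grid = 50, n_levels = 14) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) .stopf("need at least 2 finite points")
  hx <- MASS::bandwidth.nrd(x)
  hy <- MASS::bandwidth.nrd(y)
  if (hx == 0 || hy == 0) .stopf("zero variance on an axis")
  lims <- c(range(x) + c(-hx, hx), range(y) + c(-hy, hy))
  d <- MASS::kde2d(x, y, h = c(hx, hy), n = n_grid, lims = lims)
  levels <- seq(0, max(d$z), length.out = n_levels + 1)[-1]
  structure(list(x = d$x, y = d$y, z = d$z, levels = levels),
            class = "density_grid")
}

#' Expression change by methylation-change class
#'
#' Joins per-CpG methylation-change classes to their assigned genes'
#' expression changes. Genes whose maximum FPKM across the two samples is
#' below `min_fpkm` are excluded; the per-class distributions of
#' expression log2 fold change and pairwise pooled Student t-tests between
#' classes are returned. The tests compare per-gene deduplicated values (a
#' gene appears once per class however many of its CpGs carry that class):
#' CpGs of one gene share that gene's expression value, so CpG-level
#' testing would pseudo-replicate it.
#'
#' @param assignments [assign_all()]-style data.frame (`chrom`, `pos`,
#'   `gene_id`).
#' @param changes [classify_cpg_changes()]-style data.frame (`chrom`,
#'   `pos`, `class`).
#' @param expression data.frame `gene_id`, `fpkm_a`, `fpkm_b` (the two
#'   samples being compared).
#' @param min_fpkm Expression filter: keep genes with
#'   `max(fpkm_a, fpkm_b) >= min_fpkm` (default 0.1).
#' @param floor Floor for the log2 ratio (default `min_fpkm`).
#' @param welch Use Welch instead of pooled t-tests.
#' @return List of class `meth_expr_association`: `data` (per retained CpG:
#'   class, gene, expr_lfc), `class_counts`, `tests` (pairwise classes
#'   with t and p; classes with < 2 members are skipped with a notice in
#'   `skipped`).
#' @export
methylation_expression_association <- function(assignments, changes,
                                               expression, min_fpkm = 0.1,
                                               floor = min_fpkm,
                                               welch = FALSE) {
  key <- function(d) paste(d$chrom, d$pos)
  idx <- match(key(changes), key(assignments))
  df <- data.frame(chrom = changes$chrom, pos = changes$pos,
                   class = changes$class,
                   gene_id = assignments$gene_id[idx])
  df <- df[!is.na(df$gene_id), , drop = FALSE]
  keep_gene <- expression$gene_id[pmax(expression$fpkm_a,
                                       expression$fpkm_b) >= min_fpkm]
  df <- df[df$gene_id %in% keep_gene, , drop = FALSE]
  ei <- match(df$gene_id, expression$gene_id)
  df$expr_lfc <- log2_fold_change(expression$fpkm_a[ei],
                                  expression$fpkm_b[ei], floor = floor)
  counts <- table(df$class)
  classes <- names(counts)[counts >= 1]
  tests <- NULL; skipped <- character()
  if (length(classes) >= 2) {
    pairs <- utils::combn(classes, 2)
    rows <- list()
    gene_vals <- function(cl) {
      sub <- df[df$class == cl, , drop = FALSE]
      sub$expr_lfc[!duplicated(sub$gene_id)]
    }
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      va <- gene_vals(a); vb <- gene_vals(b)
      if (length(va) < 2 || length(vb) < 2) {
        skipped <- c(skipped, sprintf("%s vs %s: a class has < 2 members", a, b))
        next
      }
      ht <- student_t_test(va, vb, welch = welch)
      rows[[length(rows) + 1L]] <- data.frame(class_a = a, class_b = b,
                                              t = ht$statistic, p = ht$p.value)
    }
    if (length(rows)) tests <- do.call(rbind, rows)
  }
  if (length(skipped)) message(paste(skipped, collapse = "\n"))
  structure(list(data = df, class_counts = counts, tests = tests,
                 skipped = skipped),
            class = "meth_expr_association")
}
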