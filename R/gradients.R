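# Gradient screens: which genes track an anatomical axis, and what shape
# the trend takes. The screen is a per-gene Spearman rank correlation with
# a fixed classification threshold; trends are either moving-window
# convolutions or penalized-spline (GAM) fits z-scaled for comparison.

#' Filter genes by expression fraction
#'
#' Keeps genes detected (count > 0) in at least `min_fraction` of the
#' cells under consideration; the boundary is inclusive.
#'
#' @param cells A [cell_table()] (already subset to the population of
#'   interest).
#' @param min_fraction Minimum detected fraction (default 0.05).
#' @return Character vector of gene names.
#' @export
expression_fraction_filter <- function(cells, min_fraction = 0.05) {
  if (n_cells(cells) == 0) stop("empty cell subset")
  frac <- Matrix::rowMeans(cells$counts > 0)
  names(frac)[frac >= min_fraction]
}

# Spearman rho with average ranks plus the large-sample t approximation
spearman_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0)
    return(c(rho = NA_real_, p = NA_real_, n = n))
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(c(rho = rho, p = 0, n = n))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Screen genes for axis-correlated expression
#'
#' For every gene, the Spearman rank correlation between its counts and
#' each axis across cells, with a p-value from the large-sample t
#' approximation. Genes are classed `positive` when `rho > threshold`,
#' `negative` when `rho < -threshold`, and `none` otherwise (including
#' zero-variance genes, whose rho is undefined).
#'
#' @param cells A [cell_table()] subset (e.g. one cell type).
#' @param axes Named list of numeric axis vectors (one value per cell),
#'   e.g. `list(crypt_villus = ..., epithelial = ...)`.
#' @param genes Genes to screen (typically from
#'   [expression_fraction_filter()]).
#' @param threshold Classification threshold on rho (default 0.05).
#' @return `data.frame`: `gene`, `axis`, `rho`, `p`, `class`, `n_cells`.
#' @export
axis_correlation_screen <- function(cells, axes, genes, threshold = 0.05) {
  if (n_cells(cells) < 3) stop("need at least 3 cells")
  stopifnot(is.list(axes), !is.null(names(axes)))
  counts <- as.matrix(cells$counts[genes, , drop = FALSE])
  out <- list()
  for (ax in names(axes)) {
    vals <- axes[[ax]]
    stopifnot(length(vals) == n_cells(cells))
    res <- t(apply(counts, 1, spearman_with_p, y = vals))
    cls <- ifelse(is.na(res[, "rho"]), "none",
                  ifelse(res[, "rho"] > threshold, "positive",
                         ifelse(res[, "rho"] < -threshold, "negative",
                                "none")))
    out[[ax]] <- data.frame(gene = genes, axis = ax, rho = res[, "rho"],
                            p = res[, "p"], class = cls,
                            n_cells = as.integer(res[, "n"]),
                            row.names = NULL)
  }
  do.call(rbind, out)
}

#' Convolved expression trend along an axis
#'
#' Cells are sorted by axis value and the gene's counts are averaged over
#' a sliding window of `window` cells. Windows keep a fixed size: at the
#' edges they shift inward rather than shrink, so `window = 1` returns the
#' raw sorted counts and `window = n` a constant curve at the global mean.
#'
#' @param cells A [cell_table()].
#' @param axis Numeric axis values, one per cell.
#' @param gene Gene name.
#' @param window Window size in cells.
#' @return List of class `trend_curve`: `grid` (sorted axis values),
#'   `fitted` (windowed means), `z_fitted` (z-scaled curve), `method`,
#'   `smoothing` (window record).
#' @export
convolved_trend <- function(cells, axis, gene, window) {
  n <- n_cells(cells)
  stopifnot(length(axis) == n, window >= 1, window <= n)
  ord <- order(axis)
  counts <- as.numeric(cells$counts[gene, ])[ord]
  w <- as.integer(window)
  half_lo <- (w - 1L) %/% 2L
  cs <- c(0, cumsum(counts))
  lo <- pmin(pmax(seq_len(n) - half_lo, 1L), n - w + 1L)
  hi <- lo + w - 1L
  fitted <- (cs[hi + 1] - cs[lo]) / w
  new_trend_curve(axis[ord], fitted, "convolution", list(window = w))
}

new_trend_curve <- function(grid, fitted, method, smoothing) {
  s <- sd(fitted)
  z <- if (!is.finite(s) || s == 0) rep(0, length(fitted))
       else (fitted - mean(fitted)) / s
  structure(list(grid = grid, fitted = fitted, z_fitted = z,
                 method = method, smoothing = smoothing),
            class = "trend_curve")
}

#' Penalized-spline (GAM) expression trend along an axis
#'
#' Fits a generalized additive model with a single cubic-regression-spline
#' smooth of the axis to the gene's counts, with the smoothing penalty
#' chosen by generalized cross-validation, then evaluates the fit on a
#' uniform grid and z-scales it so trends of different genes are
#' comparable. Constant counts give a degenerate (all-zero) z-curve.
#'
#' @param cells A [cell_table()].
#' @param axis Numeric axis values, one per cell.
#' @param gene Gene name.
#' @param n_knots Basis dimension of the smooth (default 10).
#' @param grid_n Grid resolution (default 100).
#' @return A `trend_curve` with `method = "additive_model"`.
#' @export
additive_trend <- function(cells, axis, gene, n_knots = 10L,
                           grid_n = 100L) {
  n <- n_cells(cells)
  stopifnot(length(axis) == n)
  if (n < 3 * n_knots)
    stop("need at least ", 3 * n_knots, " cells for ", n_knots, " knots")
  y <- as.numeric(cells$counts[gene, ])
  grid <- seq(min(axis), max(axis), length.out = grid_n)
  if (sd(y) == 0)
    return(new_trend_curve(grid, rep(mean(y), grid_n), "additive_model",
                           list(n_knots = n_knots, sp = NA_real_)))
  df <- data.frame(y = y, axis = axis)
  fit <- mgcv::gam(y ~ s(axis, k = n_knots, bs = "cr"), data = df,
                   method = "GCV.Cp")
  fitted <- as.numeric(predict(fit, newdata = data.frame(axis = grid)))
  new_trend_curve(grid, fitted, "additive_model",
                  list(n_knots = n_knots, sp = fit$sp))
}

#' Rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum tests per gene on log-normalized counts,
#' Benjamini-Hochberg adjusted; genes are ordered by the standardized
#' rank-sum statistic (|z|, largest first) for signature building. Genes
#' constant across both groups get p = 1.
#'
#' @param cells A [cell_table()] containing both groups.
#' @param group_a,group_b Logical or integer indices of the two groups
#'   (each at least 3 cells).
#' @param genes Genes to test (default all).
#' @param n_top Number of top genes to flag (default 15).
#' @return `data.frame` sorted by decreasing `abs_z`: `gene`, `statistic`
#'   (rank-sum W for group A), `z`, `abs_z`, `p`, `p_adj`, `direction`
#'   (`"up_in_a"`/`"up_in_b"`), `top` (logical, first `n_top`).
#' @export
rank_de_genes <- function(cells, group_a, group_b, genes = NULL,
                          n_top = 15L) {
  ia <- if (is.logical(group_a)) which(group_a) else as.integer(group_a)
  ib <- if (is.logical(group_b)) which(group_b) else as.integer(group_b)
  if (length(ia) < 3 || length(ib) < 3)
    stop("both groups need at least 3 cells")
  if (is.null(genes)) genes <- rownames(cells$counts)
  ln <- log_normalize(cells$counts)[genes, , drop = FALSE]
  na <- length(ia); nb <- length(ib)
  res <- t(vapply(genes, function(g) {
    xa <- ln[g, ia]; xb <- ln[g, ib]
    if (sd(c(xa, xb)) == 0)
      return(c(W = na * nb / 2, z = 0, p = 1))
    r <- rank(c(xa, xb))
    W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    # normal approximation with tie correction, for the ordering statistic
    ties <- table(r)
    mu <- na * nb / 2
    sig2 <- na * nb / 12 *
      ((na + nb + 1) - sum(ties^3 - ties) / ((na + nb) * (na + nb - 1)))
    z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
    # exact for small tie-free samples, normal approximation otherwise
    p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
    c(W = W, z = z, p = p)
  }, numeric(3)))
  out <- data.frame(gene = genes, statistic = res[, "W"], z = res[, "z"],
                    abs_z = abs(res[, "z"]), p = res[, "p"],
                    p_adj = p.adjust(res[, "p"], "BH"),
                    direction = ifelse(res[, "z"] >= 0, "up_in_a",
                                       "up_in_b"),
                    row.names = NULL)
  out <- out[order(-out$abs_z, out$p), ]
  out$top <- seq_len(nrow(out)) <= n_top
  out
}
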