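# Immune allocation maps (IMAPs): a 2-D representation placing each cell
# at (crypt-villus value, biexponentially transformed epithelial value),
# with weighted Gaussian kernel densities, manual polygon gates and
# per-gate expression summaries.

#' Biexponential transform
#'
#' The flow-cytometry-style scale applied to clipped epithelial-axis
#' values: `T(v) = asinh(v / w)`. Strictly increasing, odd, linear near
#' zero and logarithmic in the tails; `biexp_inverse()` is its exact
#' inverse.
#'
#' @param values Numeric vector (z-units).
#' @param w Width parameter > 0 (default 0.5 z-units): the scale below
#'   which the transform is effectively linear.
#' @return Transformed values.
#' @export
biexp_transform <- function(values, w = 0.5) {
  if (!is.numeric(w) || length(w) != 1 || w <= 0)
    stop("width parameter w must be a positive scalar")
  asinh(values / w)
}

#' @rdname biexp_transform
#' @export
biexp_inverse <- function(values, w = 0.5) {
  if (w <= 0) stop("width parameter w must be positive")
  sinh(values) * w
}

#' IMAP coordinates for each cell
#'
#' @param axes Axis `data.frame` from [compute_axes()] (needs
#'   `crypt_villus_display` or `crypt_villus`, and `epithelial_clipped`).
#' @param w Biexponential width parameter.
#' @param x_source `"display"` (min-max rescaled crypt-villus, default) or
#'   `"zscore"`.
#' @return `data.frame` with `cell_id`, `imap_x`, `imap_y`.
#' @export
imap_coordinates <- function(axes, w = 0.5,
                             x_source = c("display", "zscore")) {
  x_source <- match.arg(x_source)
  xcol <- if (x_source == "display") "crypt_villus_display"
          else "crypt_villus"
  if (is.null(axes[[xcol]]) || is.null(axes$epithelial_clipped))
    stop("axes are missing required columns")
  data.frame(cell_id = axes$cell_id, imap_x = axes[[xcol]],
             imap_y = biexp_transform(axes$epithelial_clipped, w))
}

#' Weighted two-dimensional Gaussian kernel density
#'
#' A Gaussian product-kernel density over IMAP coordinates with
#' non-negative per-point weights (gene counts or squared signature
#' scores). Weights are normalized to sum to one, so equal weights
#' reproduce the unweighted estimate exactly. The default bandwidth is
#' Scott's rule computed on the weighted cloud, with the effective sample
#' size `1 / sum(w^2)` taking the place of n.
#'
#' @param points Two-column matrix or the `data.frame` from
#'   [imap_coordinates()].
#' @param weights Non-negative weights, one per point (default equal).
#' @param bandwidth `"scott"` or a numeric scalar/length-2 vector of
#'   per-dimension kernel standard deviations.
#' @param gridsize Grid resolution per dimension (default 128).
#' @param expand Fractional margin added around the point cloud for the
#'   evaluation grid.
#' @return List of class `imap_field`: `x`, `y` (grid vectors), `density`
#'   (matrix, rows = x), `point_density` (density at each input point),
#'   `bandwidth`, `weights_normalized`.
#' @export
weighted_kde <- function(points, weights = NULL, bandwidth = "scott",
                         gridsize = 128L, expand = 0.1) {
  if (is.data.frame(points))
    points <- as.matrix(points[, c("imap_x", "imap_y")])
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("one weight per point required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("all weights are zero")
  w <- weights / sum(weights)
  if (identical(bandwidth, "scott")) {
    n_eff <- 1 / sum(w^2)
    mu <- colSums(points * w)
    sdw <- sqrt(colSums(w * sweep(points, 2, mu)^2))
    h <- sdw * n_eff^(-1 / 6)  # Scott's factor, d = 2
  } else {
    h <- rep(as.numeric(bandwidth), length.out = 2)
  }
  if (any(h <= 0)) stop("bandwidth must be positive")
  rngx <- range(points[, 1]); rngy <- range(points[, 2])
  padx <- max(diff(rngx), h[1]) * expand + 3 * h[1]
  pady <- max(diff(rngy), h[2]) * expand + 3 * h[2]
  gx <- seq(rngx[1] - padx, rngx[2] + padx, length.out = gridsize)
  gy <- seq(rngy[1] - pady, rngy[2] + pady, length.out = gridsize)
  # separable kernel: density = Kx diag(w) Ky^T
  kx <- outer(gx, points[, 1], function(a, b) stats::dnorm(a, b, h[1]))
  ky <- outer(gy, points[, 2], function(a, b) stats::dnorm(a, b, h[2]))
  dens <- kx %*% (w * t(ky))
  px <- stats::dnorm(outer(points[, 1], points[, 1], "-"), sd = h[1])
  py <- stats::dnorm(outer(points[, 2], points[, 2], "-"), sd = h[2])
  point_density <- as.numeric((px * py) %*% w)
  structure(list(x = gx, y = gy, density = dens,
                 point_density = point_density, bandwidth = h,
                 weights_normalized = w),
            class = "imap_field")
}

#' Integrate an IMAP density field over its grid
#' @param field An `imap_field` from [weighted_kde()].
#' @return Approximate total mass (trapezoidal; close to 1 when the grid
#'   covers the support).
#' @export
kde_grid_mass <- function(field) {
  dx <- diff(field$x); dy <- diff(field$y)
  d <- field$density
  # trapezoidal rule in both dimensions
  mx <- (d[-1, , drop = FALSE] + d[-nrow(d), , drop = FALSE]) / 2
  m <- (mx[, -1, drop = FALSE] + mx[, -ncol(mx), drop = FALSE]) / 2
  sum(m * outer(dx, dy))
}

#' Define a set of named IMAP gates
#'
#' @param polygons Named list of two-column vertex matrices (simple,
#'   non-self-intersecting polygons in IMAP coordinates). Order encodes
#'   priority: overlapping gates resolve to the earliest listed.
#' @return Object of class `gate_set`.
#' @export
gate_set <- function(polygons) {
  if (is.null(names(polygons)) || any(names(polygons) == ""))
    stop("gates must be named")
  if (anyDuplicated(names(polygons))) stop("gate names must be unique")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    stopifnot(ncol(p) == 2, nrow(p) >= 3)
    if (polygon_self_intersects(p))
      stop("gate polygon is self-intersecting")
    p
  })
  structure(polygons, class = "gate_set")
}

# segment-intersection check over non-adjacent edges
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent around the loop
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read a gate set from labelme-style JSON
#' @param path JSON written by [write_shapes_json()].
#' @return A [gate_set()].
#' @export
read_gates_json <- function(path) gate_set(read_shapes_json(path))

#' Assign each point to an IMAP gate
#'
#' Point-in-polygon with boundary points counted inside; overlaps resolve
#' by gate declaration order; points outside all gates get `"none"`.
#'
#' @param points `data.frame` from [imap_coordinates()] or a two-column
#'   matrix.
#' @param gates A [gate_set()].
#' @return Character vector of gate labels.
#' @export
assign_gates <- function(points, gates) {
  stopifnot(inherits(gates, "gate_set"))
  if (is.data.frame(points))
    points <- as.matrix(points[, c("imap_x", "imap_y")])
  label <- rep("none", nrow(points))
  for (nm in names(gates)) {
    open <- label == "none"
    if (!any(open)) break
    poly <- gates[[nm]]
    hit <- sp::point.in.polygon(points[open, 1], points[open, 2],
                                poly[, 1], poly[, 2]) > 0
    label[which(open)[hit]] <- nm
  }
  label
}

#' Log-normalize counts for expression summaries
#'
#' Counts are scaled per cell to the median total count of the population
#' and `log1p`-transformed.
#'
#' @param counts Genes-by-cells matrix (sparse or dense).
#' @return Dense genes-by-cells matrix of log-normalized expression.
#' @export
log_normalize <- function(counts) {
  tot <- Matrix::colSums(counts)
  target <- median(tot[tot > 0])
  sf <- ifelse(tot > 0, target / tot, 0)
  log1p(as.matrix(counts) %*% Matrix::Diagonal(x = sf)) |> as.matrix()
}

#' Per-gate statistics
#'
#' Cell counts and fractions per gate (the `"none"` bucket included, so
#' fractions sum to 1), and mean log-normalized expression per gate for
#' the requested genes. Empty gates are reported with count 0 and `NA`
#' means.
#'
#' @param cells A [cell_table()].
#' @param labels Gate labels from [assign_gates()], parallel to cells.
#' @param genes Genes to summarize (default none).
#' @param gate_names Gates to report (default: those present in `labels`
#'   plus `"none"`).
#' @return List with `counts` (`data.frame`: gate, n, fraction) and
#'   `means` (gate x gene matrix of mean log-normalized expression).
#' @export
gate_statistics <- function(cells, labels, genes = character(),
                            gate_names = NULL) {
  stopifnot(length(labels) == n_cells(cells))
  if (is.null(gate_names))
    gate_names <- union(setdiff(unique(labels), "none"), "none")
  n <- vapply(gate_names, function(g) sum(labels == g), integer(1))
  out <- data.frame(gate = gate_names, n = n, fraction = n / sum(n))
  means <- NULL
  if (length(genes)) {
    ln <- log_normalize(cells$counts[genes, , drop = FALSE])
    means <- do.call(rbind, lapply(gate_names, function(g) {
      idx <- labels == g
      if (!any(idx)) return(rep(NA_real_, length(genes)))
      rowMeans(ln[, idx, drop = FALSE])
    }))
    dimnames(means) <- list(gate_names, genes)
  }
  list(counts = out, means = means)
}

#' Rank-based signature score per cell
#'
#' Genes are ranked per cell by descending count (average ranks for ties)
#' and ranks are truncated at `r_max`; the score is
#' `1 - (sum(ranks_sig) - n(n+1)/2) / (n * r_max)`, floored at 0, where n
#' is the signature size. A cell expressing its signature genes above all
#' others scores 1; a cell whose signature genes all rank beyond `r_max`
#' scores 0.
#'
#' @param cells A [cell_table()].
#' @param signature Character vector of signature genes (must be in the
#'   panel).
#' @param r_max Rank truncation (default 1500).
#' @return Numeric score in \[0, 1\] per cell.
#' @export
signature_score <- function(cells, signature, r_max = 1500) {
  if (length(signature) == 0) stop("empty signature")
  missing <- setdiff(signature, rownames(cells$counts))
  if (length(missing))
    stop("signature genes absent from panel: ",
         paste(missing, collapse = ", "))
  counts <- as.matrix(cells$counts)
  n_sig <- length(signature)
  sig_rows <- match(signature, rownames(counts))
  apply(counts, 2, function(col) {
    r <- rank(-col, ties.method = "average")
    r <- pmin(r, r_max)
    score <- 1 - (sum(r[sig_rows]) - n_sig * (n_sig + 1) / 2) /
      (n_sig * r_max)
    max(score, 0)
  })
}
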