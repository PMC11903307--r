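# The three anatomical axes. Every cell receives a longitudinal position
# (arc-length fraction along the basal membrane), a crypt-villus position
# (distance above the basal membrane, z-scored within its villus) and an
# epithelial position (relative distance to the epithelium). A
# transcriptional-neighborhood NMF predictor provides crypt-villus values
# for sections where the geometry is unusable.

# Project points onto a polyline: for each point the nearest location on
# any segment, its arc length and the signed offset (positive to the left
# of the directed segment -- above, for a left-to-right basal line).
project_on_polyline <- function(points, polyline) {
  v <- polyline$vertices
  cum <- polyline$cumulative_length
  n_seg <- nrow(v) - 1
  pts <- as.matrix(points)
  best_d2 <- rep(Inf, nrow(pts))
  best_arc <- numeric(nrow(pts))
  best_sign <- numeric(nrow(pts))
  for (s in seq_len(n_seg)) {
    a <- v[s, ]; b <- v[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    cross <- ab[1] * (pts[, 2] - a[2]) - ab[2] * (pts[, 1] - a[1])
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_arc[upd] <- cum[s] + t[upd] * sqrt(len2)
    best_sign[upd] <- sign(cross[upd])
  }
  list(distance = sqrt(best_d2), arc_length = best_arc,
       side = best_sign,
       total_length = cum[length(cum)])
}

#' Longitudinal axis: relative position along the basal membrane
#'
#' Each cell is projected onto the basal-membrane polyline; its
#' longitudinal position is the arc-length fraction (0 at the start vertex,
#' 1 at the end) of the nearest point.
#'
#' @param cells A [cell_table()].
#' @param basal A [polyline_annotation()] of the basal membrane.
#' @return Numeric vector in \[0, 1\], one value per cell.
#' @export
longitudinal_axis <- function(cells, basal) {
  stopifnot(inherits(basal, "polyline"))
  pr <- project_on_polyline(cells$meta[, c("x", "y")], basal)
  pr$arc_length / pr$total_length
}

#' Geometric crypt-villus axis
#'
#' The raw value is the distance from each cell to the basal-membrane
#' polyline, signed positive on the villus side and negative on the
#' muscularis side. Raw values are z-scored among cells sharing a villus
#' label (population standard deviation); a per-sample min-max rescale of
#' the z-scores to \[0, 1\] is provided for display.
#'
#' @param cells A [cell_table()].
#' @param basal Basal-membrane [polyline_annotation()].
#' @param villus_labels Named integer vector `cell_id -> villus_id`; cells
#'   absent from it get `NA` axis values.
#' @param sd_floor Villi whose raw-distance spread falls below this floor
#'   (or that contain a single cell) get all-zero z-scores, with a warning
#'   for singletons.
#' @return `data.frame` with `cell_id`, `crypt_villus_raw` (micrometres,
#'   signed), `crypt_villus` (z-score) and `crypt_villus_display`.
#' @export
crypt_villus_axis_geometric <- function(cells, basal, villus_labels,
                                        sd_floor = 1e-8) {
  pr <- project_on_polyline(cells$meta[, c("x", "y")], basal)
  raw <- pr$distance * ifelse(pr$side == 0, 1, pr$side)
  vid <- villus_labels[cells$meta$cell_id]
  z <- rep(NA_real_, length(raw))
  singletons <- 0L
  for (v in unique(vid[!is.na(vid)])) {
    idx <- which(!is.na(vid) & vid == v)
    if (length(idx) == 1) {
      z[idx] <- 0; singletons <- singletons + 1L
      next
    }
    mu <- mean(raw[idx])
    s <- sqrt(mean((raw[idx] - mu)^2))  # population s.d.
    z[idx] <- if (s < sd_floor) 0 else (raw[idx] - mu) / s
  }
  if (singletons > 0)
    warning(singletons, " villus label(s) with a single cell; z set to 0")
  fin <- z[is.finite(z)]
  display <- if (length(fin) && diff(range(fin)) > 0)
    (z - min(fin)) / diff(range(fin)) else ifelse(is.na(z), NA_real_, 0.5)
  data.frame(cell_id = cells$meta$cell_id, crypt_villus_raw = raw,
             crypt_villus = z, crypt_villus_display = display)
}

# k nearest neighbours among `data` rows for each `query` row, excluding a
# query's own row when `self_idx` maps it into `data`.
knn_indices <- function(data, query, k, self_idx = NULL) {
  k_eff <- min(k + ifelse(is.null(self_idx), 0, 1), nrow(data))
  nn <- RANN::nn2(data, query, k = k_eff)
  idx <- nn$nn.idx; d <- nn$nn.dists
  if (is.null(self_idx)) {
    list(idx = idx[, seq_len(min(k, ncol(idx))), drop = FALSE],
         dists = d[, seq_len(min(k, ncol(d))), drop = FALSE])
  } else {
    out_i <- matrix(0L, nrow(query), min(k, nrow(data) - 1))
    out_d <- matrix(0, nrow(query), ncol(out_i))
    for (r in seq_len(nrow(query))) {
      keep <- if (is.na(self_idx[r])) rep(TRUE, ncol(idx))
              else idx[r, ] != self_idx[r]
      cols <- which(keep)[seq_len(ncol(out_i))]
      out_i[r, ] <- idx[r, cols]
      out_d[r, ] <- d[r, cols]
    }
    list(idx = out_i, dists = out_d)
  }
}

#' Transcriptional neighborhood factors
#'
#' For each cell, transcript counts of its `k` nearest neighbouring cells
#' (optionally restricted to given cell types, e.g. epithelial and stromal
#' neighbourhoods) are summed into a neighborhood matrix, which is then
#' decomposed by non-negative matrix factorization into `n_factors`
#' per-cell loadings. The factorization is seeded and deterministic.
#'
#' @param cells A [cell_table()].
#' @param k Number of nearest neighbours summed (default 10; self
#'   excluded).
#' @param n_factors Latent factor count (default 15).
#' @param restrict_types Optional character vector of cell types eligible
#'   as neighbours.
#' @param seed Seed for the NMF initialization.
#' @return List of class `neighborhood_embedding`: `loadings` (cells x
#'   factors, non-negative), `gene_loadings` (factors x genes),
#'   `neighborhood` (cells x genes summed counts), `mse` (reconstruction
#'   mean squared error), `k`, `restrict_types`.
#' @export
neighborhood_factors <- function(cells, k = 10L, n_factors = 15L,
                                 restrict_types = NULL, seed = 1L) {
  xy <- as.matrix(cells$meta[, c("x", "y")])
  pool <- if (is.null(restrict_types)) seq_len(nrow(xy))
          else which(cells$meta$cell_type %in% restrict_types)
  if (length(pool) < 2) stop("fewer than 2 eligible neighbour cells")
  if (length(pool) <= k) {
    warning("k = ", k, " exceeds available neighbours (", length(pool),
            "); using all")
    k <- length(pool) - 1L
  }
  self_idx <- match(seq_len(nrow(xy)), pool)  # NA when not in pool
  nn <- RANN::nn2(xy[pool, , drop = FALSE], xy, k = min(k + 1, length(pool)))
  counts_t <- Matrix::t(cells$counts)  # cells x genes
  N <- matrix(0, nrow(xy), ncol(counts_t),
              dimnames = list(cells$meta$cell_id, colnames(counts_t)))
  for (r in seq_len(nrow(xy))) {
    nb <- nn$nn.idx[r, ]
    nb <- nb[is.na(self_idx[r]) | nb != self_idx[r]]
    nb <- nb[seq_len(min(k, length(nb)))]
    N[r, ] <- Matrix::colSums(counts_t[pool[nb], , drop = FALSE])
  }
  fit <- RcppML::nmf(N, k = n_factors, seed = seed, verbose = FALSE,
                     tol = 1e-6)
  W <- fit$w %*% diag(fit$d, nrow = length(fit$d))
  rownames(W) <- cells$meta$cell_id
  recon <- W %*% fit$h
  structure(list(loadings = W, gene_loadings = fit$h, neighborhood = N,
                 mse = mean((N - recon)^2), k = k,
                 restrict_types = restrict_types),
            class = "neighborhood_embedding")
}

#' A k-nearest-neighbour regressor over factor space
#'
#' The default supervised map from neighborhood factors to an axis value:
#' deterministic, dependency-light, and honouring the fit/predict contract
#' expected by [crypt_villus_axis_predicted()].
#'
#' @param k Number of training neighbours averaged per prediction.
#' @return A function `f(X, y)` returning a prediction function over new
#'   factor matrices.
#' @export
knn_regressor <- function(k = 25L) {
  function(X, y) {
    X <- as.matrix(X)
    force(y)
    function(newX) {
      nn <- RANN::nn2(X, as.matrix(newX), k = min(k, nrow(X)))
      rowMeans(matrix(y[nn$nn.idx], nrow = nrow(nn$nn.idx)))
    }
  }
}

#' Predicted crypt-villus axis from neighborhood factors
#'
#' Trains a regressor (by default [knn_regressor()]) on labelled cells'
#' factor loadings, predicts the axis for all cells, then smooths each
#' prediction by averaging over its `smoothing_k` spatially nearest cells
#' (the cell itself included, so `smoothing_k = 1` is the identity).
#'
#' @param embedding A `neighborhood_embedding` (or plain loading matrix)
#'   covering all cells to predict.
#' @param coords Two-column matrix of cell centroids (for smoothing),
#'   aligned with the embedding rows.
#' @param train_idx Integer indices of labelled cells.
#' @param train_labels Axis values for `train_idx`.
#' @param smoothing_k Spatial smoothing neighbourhood size (default 150).
#' @param regressor A function `f(X, y) -> predict(newX)`;
#'   default [knn_regressor()].
#' @param holdout_fraction Fraction of labelled cells held out for the
#'   error metrics (default 0.2).
#' @param min_labeled Minimum number of labelled cells required.
#' @param seed Seed for the holdout split.
#' @return List: `prediction` (smoothed, all cells), `prediction_raw`
#'   (unsmoothed), `holdout` (list with `rmse` and `spearman` on held-out
#'   labelled cells).
#' @export
crypt_villus_axis_predicted <- function(embedding, coords, train_idx,
                                        train_labels, smoothing_k = 150L,
                                        regressor = knn_regressor(),
                                        holdout_fraction = 0.2,
                                        min_labeled = 20L, seed = 1L) {
  W <- if (inherits(embedding, "neighborhood_embedding")) embedding$loadings
       else as.matrix(embedding)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(W),
            length(train_idx) == length(train_labels))
  if (length(train_idx) < min_labeled)
    stop("fewer than ", min_labeled, " labelled cells")
  set.seed(seed)
  n_tr <- length(train_idx)
  hold <- sample.int(n_tr, max(1, round(holdout_fraction * n_tr)))
  fit_idx <- setdiff(seq_len(n_tr), hold)
  fit <- regressor(W[train_idx[fit_idx], , drop = FALSE],
                   train_labels[fit_idx])
  hold_pred <- fit(W[train_idx[hold], , drop = FALSE])
  holdout <- list(
    rmse = sqrt(mean((hold_pred - train_labels[hold])^2)),
    spearman = suppressWarnings(
      cor(hold_pred, train_labels[hold], method = "spearman")))
  full_fit <- regressor(W[train_idx, , drop = FALSE], train_labels)
  pred_raw <- full_fit(W)
  smoothing_k <- min(smoothing_k, nrow(coords))
  if (smoothing_k > 1) {
    nn <- RANN::nn2(coords, coords, k = smoothing_k)  # self is nearest
    pred <- rowMeans(matrix(pred_raw[nn$nn.idx], nrow = nrow(coords)))
  } else pred <- pred_raw
  list(prediction = pred, prediction_raw = pred_raw, holdout = holdout)
}

#' Epithelial axis: relative distance to the epithelium
#'
#' For each cell, the mean distance to its `k_epi` nearest epithelial
#' cells is divided by the mean distance to its `k_any` nearest cells of
#' any type (self excluded in both queries). With `k_epi == k_any` the
#' ratio is at least 1, with 1 meaning the cell's immediate neighbourhood
#' is entirely epithelial. Ratios are z-scored over the sample and clipped
#' at `clip_upper`.
#'
#' @param cells A [cell_table()] with `cell_type` metadata.
#' @param epithelial_types Character vector of types counted as
#'   epithelial.
#' @param k_epi,k_any Neighbourhood sizes (defaults 5 and 5).
#' @param clip_upper Upper clip bound in z-units (default 3).
#' @return `data.frame` with `cell_id`, `epithelial_raw` (ratio),
#'   `epithelial` (z-score), `epithelial_clipped`.
#' @export
epithelial_axis <- function(cells,
                            epithelial_types = c("enterocyte", "goblet",
                                                 "progenitor"),
                            k_epi = 5L, k_any = 5L, clip_upper = 3) {
  xy <- as.matrix(cells$meta[, c("x", "y")])
  is_epi <- cells$meta$cell_type %in% epithelial_types
  if (sum(is_epi) < k_epi) stop("fewer than k_epi epithelial cells")
  if (nrow(xy) - 1 < k_any) stop("fewer than k_any cells")
  epi_pool <- which(is_epi)
  self_in_epi <- match(seq_len(nrow(xy)), epi_pool)
  nn_epi <- knn_indices(xy[epi_pool, , drop = FALSE], xy, k_epi,
                        self_idx = self_in_epi)
  nn_any <- knn_indices(xy, xy, k_any, self_idx = seq_len(nrow(xy)))
  num <- rowMeans(nn_epi$dists)
  den <- rowMeans(nn_any$dists)
  if (any(den <= 0)) {
    warning("cells with duplicate coordinates; epsilon floor applied")
    den <- pmax(den, 1e-9)
  }
  raw <- num / den
  z <- (raw - mean(raw)) / sd(raw)
  data.frame(cell_id = cells$meta$cell_id, epithelial_raw = raw,
             epithelial = z, epithelial_clipped = pmin(z, clip_upper))
}

#' Compute all three axes for a sample bundle
#'
#' Convenience wrapper running [longitudinal_axis()],
#' [crypt_villus_axis_geometric()] and [epithelial_axis()] on a bundle
#' with a `basal_membrane` annotation.
#'
#' @param bundle A [sample_bundle()].
#' @param epithelial_types Passed to [epithelial_axis()].
#' @param clip_upper Passed to [epithelial_axis()].
#' @return `data.frame` keyed by `cell_id` with all axis columns.
#' @export
compute_axes <- function(bundle,
                         epithelial_types = c("enterocyte", "goblet",
                                              "progenitor"),
                         clip_upper = 3) {
  basal <- bundle$annotations$basal_membrane
  if (is.null(basal)) stop("bundle lacks a basal_membrane annotation")
  lon <- longitudinal_axis(bundle$cells, basal)
  cv <- crypt_villus_axis_geometric(bundle$cells, basal,
                                    bundle$villus_labels)
  epi <- epithelial_axis(bundle$cells, epithelial_types,
                         clip_upper = clip_upper)
  out <- data.frame(cell_id = bundle$cells$meta$cell_id,
                    longitudinal = lon)
  out <- merge(out, cv, by = "cell_id", sort = FALSE)
  merge(out, epi, by = "cell_id", sort = FALSE)
}
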