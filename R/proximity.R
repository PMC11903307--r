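# Spatial neighbour graphs, the tissue "connectome" (cell-type x
# cell-type interaction scores), nearest-cell-type distances,
# expression-distance correlations and condition-level proximity
# comparison by the two-sample Kolmogorov-Smirnov statistic.

#' Build an undirected spatial neighbour graph over cells
#'
#' @param cells A [cell_table()].
#' @param method `"knn"` (symmetrized k nearest neighbours, default),
#'   `"delaunay"` (Delaunay triangulation; degenerate inputs such as
#'   collinear points fall back to knn with a warning) or `"radius"`
#'   (all pairs within `param` micrometres).
#' @param param Neighbourhood parameter: k for `"knn"` (default 6),
#'   radius in micrometres for `"radius"`.
#' @return An [igraph::graph] whose vertices are cells (named by
#'   `cell_id`, with a `cell_type` attribute when available).
#' @export
spatial_neighbor_graph <- function(cells, method = c("knn", "delaunay",
                                                     "radius"),
                                   param = NULL) {
  method <- match.arg(method)
  xy <- as.matrix(cells$meta[, c("x", "y")])
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 cells")
  edges <- switch(method,
    knn = {
      k <- if (is.null(param)) 6L else as.integer(param)
      nn <- RANN::nn2(xy, xy, k = min(k + 1, n))
      from <- rep(seq_len(n), each = ncol(nn$nn.idx) - 1)
      to <- as.vector(t(nn$nn.idx[, -1, drop = FALSE]))
      cbind(pmin(from, to), pmax(from, to))
    },
    delaunay = {
      tri <- tryCatch(deldir::deldir(xy[, 1], xy[, 2]),
                      error = function(e) NULL)
      if (is.null(tri) || nrow(tri$delsgs) == 0) {
        warning("degenerate layout; falling back to knn")
        return(spatial_neighbor_graph(cells, "knn", param))
      }
      cbind(pmin(tri$delsgs$ind1, tri$delsgs$ind2),
            pmax(tri$delsgs$ind1, tri$delsgs$ind2))
    },
    radius = {
      if (is.null(param)) stop("radius method requires param")
      nn <- RANN::nn2(xy, xy, k = n, searchtype = "radius",
                      radius = param)
      from <- rep(seq_len(n), ncol(nn$nn.idx))
      to <- as.vector(nn$nn.idx)
      keep <- to != 0 & to != from
      cbind(pmin(from[keep], to[keep]), pmax(from[keep], to[keep]))
    })
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::V(g)$name <- cells$meta$cell_id
  if (!is.null(cells$meta$cell_type))
    igraph::V(g)$cell_type <- cells$meta$cell_type
  if (method == "radius" && any(igraph::degree(g) == 0))
    warning("radius leaves isolated cells")
  g
}

#' Cell-type interaction scores from a neighbour graph
#'
#' Raw score(a, b) = number of graph edges joining a cell of type a and a
#' cell of type b (symmetric; within-type edges on the diagonal). When
#' several replicate graphs are given, per-replicate matrices are averaged
#' over the union of types (types absent from a replicate contribute zero
#' rows, with a warning). Two normalizations are returned: max-normalized
#' to \[0, 1\] (for connectome edge display, with edges kept where the
#' normalized score exceeds `threshold`) and row-normalized (rows sum to 1;
#' the heat-map variant).
#'
#' @param graphs A single graph from [spatial_neighbor_graph()] or a list
#'   of replicate graphs (vertices must carry `cell_type`).
#' @param threshold Edge-display threshold on the max-normalized score
#'   (default 0.1).
#' @return List of class `interaction_matrix`: `raw` (averaged counts),
#'   `max_norm`, `row_norm`, `edges` (`data.frame` of type pairs above
#'   threshold), `threshold`, `n_replicates`.
#' @export
interaction_scores <- function(graphs, threshold = 0.1) {
  if (igraph::is_igraph(graphs)) graphs <- list(graphs)
  types <- sort(unique(unlist(lapply(graphs, function(g)
    igraph::V(g)$cell_type))))
  if (!length(types)) stop("graph vertices lack cell_type")
  tally <- function(g) {
    tt <- igraph::V(g)$cell_type
    if (length(setdiff(types, tt)))
      warning("type(s) absent from a replicate: ",
              paste(setdiff(types, tt), collapse = ", "))
    m <- matrix(0, length(types), length(types),
                dimnames = list(types, types))
    el <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(el)) {
      a <- tt[el[, 1]]; b <- tt[el[, 2]]
      for (i in seq_along(a)) {
        m[a[i], b[i]] <- m[a[i], b[i]] + 1
        if (a[i] != b[i]) m[b[i], a[i]] <- m[b[i], a[i]] + 1
      }
    }
    m
  }
  mats <- lapply(graphs, tally)
  raw <- Reduce(`+`, mats) / length(mats)
  max_norm <- if (max(raw) > 0) raw / max(raw) else raw
  rs <- rowSums(raw)
  row_norm <- raw / ifelse(rs > 0, rs, 1)
  idx <- which(max_norm > threshold & upper.tri(max_norm, diag = TRUE),
               arr.ind = TRUE)
  edges <- data.frame(type_a = types[idx[, 1]], type_b = types[idx[, 2]],
                      score = max_norm[idx])
  structure(list(raw = raw, max_norm = max_norm, row_norm = row_norm,
                 edges = edges[order(-edges$score), ],
                 threshold = threshold, n_replicates = length(mats)),
            class = "interaction_matrix")
}

#' Distance from each cell to the nearest cell of each target type
#'
#' Euclidean, self-excluded (a cell's distance to its own type is the
#' distance to the *other* nearest cell of that type). Types absent from
#' the sample give a column of `Inf` with a warning.
#'
#' @param cells A [cell_table()].
#' @param target_types Cell types to measure against (default: all types
#'   present).
#' @return `data.frame` with `cell_id` and one distance column per target
#'   type (micrometres).
#' @export
nearest_type_distances <- function(cells, target_types = NULL) {
  xy <- as.matrix(cells$meta[, c("x", "y")])
  tt <- cells$meta$cell_type
  if (is.null(target_types)) target_types <- sort(unique(tt))
  out <- data.frame(cell_id = cells$meta$cell_id)
  for (ty in target_types) {
    pool <- which(tt == ty)
    if (!length(pool)) {
      warning("type absent from sample: ", ty)
      out[[ty]] <- Inf
      next
    }
    self_idx <- match(seq_len(nrow(xy)), pool)
    if (length(pool) == 1) {
      # the single cell of this type has no self-excluded neighbour
      d <- sqrt((xy[, 1] - xy[pool, 1])^2 + (xy[, 2] - xy[pool, 2])^2)
      d[pool] <- Inf
    } else {
      nn <- knn_indices(xy[pool, , drop = FALSE], xy, k = 1,
                        self_idx = self_idx)
      d <- nn$dists[, 1]
    }
    out[[ty]] <- d
  }
  out
}

#' Correlate a per-cell expression score with nearest-type distances
#'
#' Spearman rank correlation of a score (gene counts or a signature
#' score) against the distance to each target type, computed per sample
#' and averaged. Negative rho means expression is higher when the cell is
#' NEAR that type.
#'
#' @param score Numeric per-cell score.
#' @param distances `data.frame` from [nearest_type_distances()].
#' @param sample_id Per-cell sample labels (single sample if `NULL`).
#' @param min_cells Minimum subset size (default 10).
#' @return `data.frame`: `target_type`, `rho` (mean across samples),
#'   `n_samples`.
#' @export
expression_distance_correlation <- function(score, distances,
                                            sample_id = NULL,
                                            min_cells = 10L) {
  n <- length(score)
  stopifnot(nrow(distances) == n)
  if (is.null(sample_id)) sample_id <- rep("s1", n)
  if (n < min_cells) stop("fewer than ", min_cells, " cells")
  if (sd(score) == 0) {
    warning("zero-variance score; correlations undefined")
    types <- setdiff(names(distances), "cell_id")
    return(data.frame(target_type = types, rho = NA_real_,
                      n_samples = 0L))
  }
  types <- setdiff(names(distances), "cell_id")
  res <- lapply(types, function(ty) {
    rhos <- vapply(unique(sample_id), function(s) {
      idx <- sample_id == s
      d <- distances[[ty]][idx]
      ok <- is.finite(d)
      if (sum(ok) < 3 || sd(score[idx][ok]) == 0) return(NA_real_)
      cor(rank(score[idx][ok]), rank(d[ok]))
    }, numeric(1))
    data.frame(target_type = ty, rho = mean(rhos, na.rm = TRUE),
               n_samples = sum(!is.na(rhos)))
  })
  do.call(rbind, res)
}

#' Compare two proximity distributions by the Kolmogorov-Smirnov statistic
#'
#' Two-sample KS: `D = sup |ECDF_A - ECDF_B|` with the asymptotic
#' p-value; the two distributions are flagged `different` when D exceeds
#' the cutoff (default 0.08).
#'
#' @param distances_a,distances_b Numeric samples (each >= 2 values).
#' @param cutoff_d Similarity cutoff on D (default 0.08).
#' @return List: `D`, `p`, `different` (logical), `n_a`, `n_b`.
#' @export
compare_proximity_distributions <- function(distances_a, distances_b,
                                            cutoff_d = 0.08) {
  a <- distances_a[is.finite(distances_a)]
  b <- distances_b[is.finite(distances_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 finite values")
  kt <- suppressWarnings(ks.test(a, b))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       different = unname(kt$statistic) > cutoff_d,
       n_a = length(a), n_b = length(b))
}
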