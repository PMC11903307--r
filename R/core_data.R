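# Data model: transcript tables, cell tables, polyline annotations,
# sample bundles, and the cell-level preprocessing rules applied before
# any axis or density computation.

#' Construct a cell table
#'
#' A cell table couples a gene-by-cell count matrix with per-cell metadata.
#' It is the central container consumed by every downstream stage.
#'
#' @param counts A matrix or sparse [Matrix::Matrix] with genes in rows and
#'   cells in columns. Entries must be non-negative integers (transcript
#'   counts).
#' @param meta A `data.frame` with one row per cell. Must contain
#'   `cell_id`, `x` and `y` (centroid, micrometres). Optional columns used
#'   downstream: `cell_type`, `cluster`, `sample_id`, `replicate_id`,
#'   `nuclear_count`. `total_count` is always (re)derived from `counts`.
#' @return An object of class `cell_table`: a list with elements `counts`
#'   (dgCMatrix, genes x cells) and `meta` (data.frame, one row per column
#'   of `counts`, in the same order).
#' @examples
#' ct <- cell_table(matrix(1:4, 2, dimnames = list(c("g1", "g2"), NULL)),
#'                  data.frame(cell_id = c("a", "b"), x = c(0, 1), y = c(0, 0)))
#' ct$meta$total_count
#' @export
cell_table <- function(counts, meta) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "dMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  stopifnot(is.data.frame(meta), all(c("cell_id", "x", "y") %in% names(meta)))
  if (ncol(counts) != nrow(meta))
    stop("counts has ", ncol(counts), " cells but meta has ", nrow(meta))
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id in meta")
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  meta$cell_id <- as.character(meta$cell_id)
  colnames(counts) <- meta$cell_id
  meta$total_count <- as.integer(Matrix::colSums(counts))
  if (!is.null(meta$nuclear_count) &&
      any(meta$nuclear_count > meta$total_count))
    stop("nuclear_count exceeds total_count")
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta), class = "cell_table")
}

#' @exportS3Method base::print
print.cell_table <- function(x, ...) {
  cat("cell_table:", ncol(x$counts), "cells x", nrow(x$counts), "genes\n")
  if (!is.null(x$meta$cell_type))
    cat("  cell types:", length(unique(x$meta$cell_type)), "\n")
  invisible(x)
}

#' Number of cells in a cell table
#' @param x A `cell_table`.
#' @return Integer cell count.
#' @export
n_cells <- function(x) ncol(x$counts)

#' Subset a cell table by cell index or predicate
#' @param x A `cell_table`.
#' @param keep Logical or integer index over cells.
#' @return A `cell_table` restricted to the kept cells, order preserved.
#' @export
subset_cells <- function(x, keep) {
  cell_table(x$counts[, keep, drop = FALSE], x$meta[keep, , drop = FALSE])
}

#' Construct a polyline annotation
#'
#' Polylines mark tissue landmarks: the base of the basal membrane (the
#' reference for the longitudinal and crypt--villus axes), villus tops or
#' midlines. Vertex order is meaningful; arc length accumulates along it.
#'
#' @param name Label, e.g. `"basal_membrane"`.
#' @param vertices Two-column numeric matrix of (x, y) vertices,
#'   micrometres; at least two vertices, total length > 0.
#' @return Object of class `polyline` with fields `name`, `vertices`,
#'   `cumulative_length` (micrometres at each vertex, starting at 0).
#' @export
polyline_annotation <- function(name, vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2,
            all(is.finite(vertices)))
  seg <- sqrt(rowSums(diff(vertices)^2))
  cum <- c(0, cumsum(seg))
  if (cum[length(cum)] <= 0) stop("polyline has zero total length")
  structure(list(name = as.character(name), vertices = vertices,
                 cumulative_length = cum), class = "polyline")
}

#' Bundle the inputs describing one profiled sample
#'
#' @param transcripts `data.frame` with columns `x`, `y`, `gene`,
#'   `cell_id` (NA = unassigned), `nuclear` (logical).
#' @param cells A [cell_table()].
#' @param annotations Named list of [polyline_annotation()] objects.
#' @param villus_labels Named integer vector mapping `cell_id` to a villus
#'   id; cells absent from it are not in any villus.
#' @return Object of class `sample_bundle`.
#' @export
sample_bundle <- function(transcripts, cells, annotations = list(),
                          villus_labels = integer()) {
  if (nrow(transcripts)) {
    stopifnot(all(c("x", "y", "gene", "cell_id", "nuclear") %in%
                    names(transcripts)))
    assigned <- transcripts$cell_id[!is.na(transcripts$cell_id)]
    if (!all(assigned %in% cells$meta$cell_id))
      stop("transcripts reference cell_ids absent from the cell table")
  }
  structure(list(transcripts = transcripts, cells = cells,
                 annotations = annotations, villus_labels = villus_labels),
            class = "sample_bundle")
}

# ---------------------------------------------------------------------------
# Preprocessing rules

#' Quality-control filter on per-cell transcript counts
#'
#' Removes cells with fewer than `min_nuclear` nuclear transcripts, fewer
#' than `min_total` total transcripts, or more than `max_total` total
#' transcripts. Removal inequalities are strict, so cells sitting exactly
#' on a threshold are kept.
#'
#' @param cells A [cell_table()] whose `meta` carries `nuclear_count`.
#' @param min_nuclear,min_total,max_total Positive integer thresholds
#'   (defaults 8, 20, 800).
#' @return The filtered `cell_table`, original cell order preserved, with
#'   attribute `qc_report`: a named integer vector of cells removed by each
#'   criterion (a cell can count towards several) and the total removed.
#' @export
qc_filter_cells <- function(cells, min_nuclear = 8L, min_total = 20L,
                            max_total = 800L) {
  if (min_nuclear <= 0 || min_total <= 0 || max_total <= 0)
    stop("thresholds must be positive")
  if (min_total > max_total) stop("min_total exceeds max_total")
  if (is.null(cells$meta$nuclear_count))
    stop("cell table lacks nuclear_count")
  if (n_cells(cells) == 0) {
    warning("empty cell table; nothing to filter")
    attr(cells, "qc_report") <- c(low_nuclear = 0L, low_total = 0L,
                                  high_total = 0L, removed = 0L)
    return(cells)
  }
  nuc <- cells$meta$nuclear_count
  tot <- cells$meta$total_count
  low_nuc <- nuc < min_nuclear
  low_tot <- tot < min_total
  high_tot <- tot > max_total
  keep <- !(low_nuc | low_tot | high_tot)
  out <- subset_cells(cells, keep)
  attr(out, "qc_report") <- c(low_nuclear = sum(low_nuc),
                              low_total = sum(low_tot),
                              high_total = sum(high_tot),
                              removed = sum(!keep))
  out
}

#' Split multi-nucleus segmentations by nearest nucleus centroid
#'
#' Segmentation occasionally merges neighbouring cells into one boundary
#' containing several nuclei. Each transcript of such a cell is reassigned
#' to the sub-cell whose nucleus centroid is nearest (Euclidean); exact
#' ties go to the lower-indexed centroid. Cells with a single centroid are
#' untouched; flagged cells with zero centroids are warned about and left
#' unsplit.
#'
#' @param transcripts `data.frame` with `x`, `y`, `cell_id`.
#' @param nucleus_centroids Named list: `cell_id` -> two-column matrix of
#'   nucleus centroids for cells to split.
#' @param suffix_sep Separator between the parent id and sub-cell index in
#'   the new ids (default `"."`: parent "c1" splits into "c1.1", "c1.2").
#' @return Character vector of new cell assignments, parallel to
#'   `transcripts` rows.
#' @export
split_multinucleus_cells <- function(transcripts, nucleus_centroids,
                                     suffix_sep = ".") {
  assignment <- as.character(transcripts$cell_id)
  for (cid in names(nucleus_centroids)) {
    cen <- as.matrix(nucleus_centroids[[cid]])
    idx <- which(!is.na(assignment) & assignment == cid)
    if (nrow(cen) == 0) {
      warning("cell ", cid, " flagged for splitting but has no centroids")
      next
    }
    if (nrow(cen) < 2 || length(idx) == 0) next
    pts <- cbind(transcripts$x[idx], transcripts$y[idx])
    d2 <- outer(rowSums(pts^2), rowSums(cen^2), "+") - 2 * pts %*% t(cen)
    nearest <- max.col(-d2, ties.method = "first")
    assignment[idx] <- paste0(cid, suffix_sep, nearest)
  }
  assignment
}

#' Aggregate gridded bin counts into cells
#'
#' For array-based platforms profiled on a regular grid of small bins,
#' per-cell counts are the sum over bins belonging to each cell. A bin
#' belongs to the cell whose mask contains the bin centre (so a bin is
#' never double counted even when it touches two masks); bins whose centre
#' falls outside all masks contribute to no cell.
#'
#' @param bin_counts `data.frame` with columns `bin_x`, `bin_y` (bin centre
#'   coordinates), `gene`, `count`.
#' @param cell_masks Named list: `cell_id` -> two-column polygon matrix
#'   (mask boundary, assumed non-overlapping).
#' @param meta Optional `data.frame` of per-cell metadata (must contain
#'   `cell_id`, `x`, `y`); by default centroids are the mean of assigned
#'   bin centres.
#' @return A [cell_table()] over the cells with at least one assigned bin.
#' @export
aggregate_bins_to_cells <- function(bin_counts, cell_masks, meta = NULL) {
  stopifnot(all(c("bin_x", "bin_y", "gene", "count") %in% names(bin_counts)))
  centres <- unique(bin_counts[, c("bin_x", "bin_y")])
  owner <- rep(NA_character_, nrow(centres))
  for (cid in names(cell_masks)) {
    poly <- as.matrix(cell_masks[[cid]])
    unclaimed <- is.na(owner)
    if (!any(unclaimed)) break
    inside <- sp::point.in.polygon(centres$bin_x[unclaimed],
                                   centres$bin_y[unclaimed],
                                   poly[, 1], poly[, 2]) > 0
    owner[which(unclaimed)[inside]] <- cid
  }
  key <- paste(centres$bin_x, centres$bin_y)
  bin_owner <- owner[match(paste(bin_counts$bin_x, bin_counts$bin_y), key)]
  keep <- !is.na(bin_owner)
  if (!any(keep)) stop("no bin falls inside any cell mask")
  agg <- stats::aggregate(count ~ gene + cell, transform(
    bin_counts[keep, , drop = FALSE], cell = bin_owner[keep]), sum)
  genes <- sort(unique(agg$gene))
  cids <- sort(unique(agg$cell))
  counts <- Matrix::sparseMatrix(
    i = match(agg$gene, genes), j = match(agg$cell, cids), x = agg$count,
    dims = c(length(genes), length(cids)),
    dimnames = list(genes, cids))
  if (is.null(meta)) {
    cen <- stats::aggregate(cbind(bin_x, bin_y) ~ cell, transform(
      centres, cell = owner)[!is.na(owner), ], mean)
    meta <- data.frame(cell_id = cen$cell, x = cen$bin_x, y = cen$bin_y)
    meta <- meta[match(cids, meta$cell_id), ]
  } else {
    meta <- meta[match(cids, meta$cell_id), , drop = FALSE]
  }
  cell_table(counts, meta)
}
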