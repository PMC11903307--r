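# Plain-text I/O: transcripts as CSV, cell tables as MatrixMarket + CSV
# metadata, polylines and gates as labelme-style JSON polygons. All
# round-trips are value-identical.

#' Write / read a transcript table (CSV)
#'
#' Columns: `x`, `y`, `gene`, `cell_id` (empty = unassigned), `nuclear`
#' (0/1).
#'
#' @param transcripts Transcript `data.frame`.
#' @param path File path.
#' @return `read_transcripts` returns the `data.frame`;
#'   `write_transcripts` returns `path` invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  out <- transcripts[, c("x", "y", "gene", "cell_id", "nuclear")]
  out$nuclear <- as.integer(out$nuclear)
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_transcripts
#' @export
read_transcripts <- function(path) {
  required <- c("x", "y", "gene", "cell_id", "nuclear")
  header <- names(read.csv(path, nrows = 0))
  missing <- setdiff(required, header)
  if (length(missing))
    stop("transcript CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- read.csv(path, colClasses = c(x = "numeric", y = "numeric",
                                      gene = "character",
                                      cell_id = "character",
                                      nuclear = "integer"))
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | is.na(df$gene) |
                 df$gene == "")
  if (length(bad))
    stop("malformed transcript rows (1-based, excluding header): ",
         paste(head(bad, 10), collapse = ", "))
  df$cell_id[!is.na(df$cell_id) & df$cell_id == ""] <- NA_character_
  df$nuclear <- df$nuclear != 0L
  df
}

#' Write / read a cell table (MatrixMarket counts + CSV metadata)
#'
#' `<stem>.mtx` holds the genes-by-cells sparse counts, `<stem>.genes.txt`
#' the row names, and `<stem>.cells.csv` the per-cell metadata in column
#' order.
#'
#' @param cells A [cell_table()].
#' @param stem Path stem (no extension).
#' @return `read_cell_table` returns the `cell_table`; the writer returns
#'   `stem` invisibly.
#' @export
write_cell_table <- function(cells, stem) {
  Matrix::writeMM(cells$counts, paste0(stem, ".mtx"))
  writeLines(rownames(cells$counts), paste0(stem, ".genes.txt"))
  write.csv(cells$meta, paste0(stem, ".cells.csv"), row.names = FALSE,
            na = "")
  invisible(stem)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(stem) {
  counts <- methods::as(Matrix::readMM(paste0(stem, ".mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(paste0(stem, ".genes.txt"))
  meta <- read.csv(paste0(stem, ".cells.csv"),
                   colClasses = c(cell_id = "character"))
  cell_table(counts, meta)
}

#' Write / read polygon annotations (labelme-style JSON)
#'
#' The schema mirrors labelme exports: a top-level `shapes` array whose
#' entries carry a `label`, a `points` list of `[x, y]` pairs and a
#' `shape_type` of `"linestrip"` (polylines) or `"polygon"` (gates).
#'
#' @param shapes Named list of two-column vertex matrices (for
#'   `write_shapes_json`), or of [polyline_annotation()] objects.
#' @param path File path.
#' @param shape_type `"polygon"` or `"linestrip"`.
#' @return `read_shapes_json` returns a named list of vertex matrices,
#'   with the `shape_type` of each kept as an attribute.
#' @export
write_shapes_json <- function(shapes, path, shape_type = "polygon") {
  entries <- lapply(names(shapes), function(nm) {
    v <- shapes[[nm]]
    if (inherits(v, "polyline")) v <- v$vertices
    list(label = nm,
         points = lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ])),
         shape_type = shape_type)
  })
  jsonlite::write_json(list(shapes = entries), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_shapes_json
#' @export
read_shapes_json <- function(path) {
  parsed <- jsonlite::read_json(path)
  if (is.null(parsed$shapes)) stop("JSON lacks a 'shapes' array")
  out <- list()
  for (sh in parsed$shapes) {
    v <- do.call(rbind, lapply(sh$points, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    attr(v, "shape_type") <- sh$shape_type
    out[[sh$label]] <- v
  }
  out
}

#' Read a polyline annotation file into `polyline` objects
#' @param path labelme-style JSON written by [write_shapes_json()].
#' @return Named list of [polyline_annotation()] objects.
#' @export
read_polylines_json <- function(path) {
  shapes <- read_shapes_json(path)
  lapply(stats::setNames(names(shapes), names(shapes)), function(nm)
    polyline_annotation(nm, shapes[[nm]]))
}

#' Write a whole sample bundle to a directory
#' @param bundle A [sample_bundle()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(bundle$transcripts, file.path(dir, "transcripts.csv"))
  write_cell_table(bundle$cells, file.path(dir, "cells"))
  if (length(bundle$annotations))
    write_shapes_json(bundle$annotations, file.path(dir, "annotations.json"),
                      shape_type = "linestrip")
  if (length(bundle$villus_labels))
    write.csv(data.frame(cell_id = names(bundle$villus_labels),
                         villus_id = as.integer(bundle$villus_labels)),
              file.path(dir, "villus_labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a sample bundle from a directory written by [write_bundle()]
#' @param dir Directory path.
#' @return A [sample_bundle()].
#' @export
read_bundle <- function(dir) {
  transcripts <- read_transcripts(file.path(dir, "transcripts.csv"))
  cells <- read_cell_table(file.path(dir, "cells"))
  ann_path <- file.path(dir, "annotations.json")
  annotations <- if (file.exists(ann_path)) read_polylines_json(ann_path)
                 else list()
  vl_path <- file.path(dir, "villus_labels.csv")
  villus_labels <- integer()
  if (file.exists(vl_path)) {
    vl <- read.csv(vl_path, colClasses = c(cell_id = "character"))
    villus_labels <- stats::setNames(as.integer(vl$villus_id), vl$cell_id)
  }
  sample_bundle(transcripts, cells, annotations, villus_labels)
}
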