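# Shared fixtures, built once per test run and cached. All synthetic; no
# files on disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a full default synthetic sample with perturbations, plus its axes
shared_sample <- function() cached("sample", function() {
  s <- generate_sample(synth_config(seed = 42L),
                       design = default_barcode_design())
  s$axes <- compute_axes(s$bundle)
  s
})

# two replicate samples joined for cross-sample axis prediction
shared_pair <- function() cached("pair", function() {
  sA <- generate_sample(synth_config(seed = 11L), sample_id = "A")
  sB <- generate_sample(synth_config(seed = 22L), sample_id = "B")
  axA <- compute_axes(sA$bundle)
  axB <- compute_axes(sB$bundle)
  meta <- rbind(cbind(sA$bundle$cells$meta, src = "A"),
                cbind(sB$bundle$cells$meta, src = "B"))
  meta$cell_id <- paste0(meta$src, "_", meta$cell_id)
  meta$x[meta$src == "B"] <- meta$x[meta$src == "B"] + 5000
  joint <- cell_table(cbind(sA$bundle$cells$counts,
                            sB$bundle$cells$counts), meta)
  list(sA = sA, sB = sB, axA = axA, axB = axB, joint = joint,
       is_a = meta$src == "A")
})

# a tiny hand-built cell table: 6 cells, 4 genes
toy_cells <- function() {
  counts <- matrix(c(5, 0, 1, 0,
                     0, 3, 0, 2,
                     2, 2, 2, 2,
                     0, 0, 0, 0,
                     7, 1, 0, 0,
                     1, 0, 4, 1),
                   nrow = 4,
                   dimnames = list(c("g1", "g2", "g3", "g4"), NULL))
  meta <- data.frame(cell_id = paste0("c", 1:6),
                     x = c(0, 1, 2, 3, 4, 5), y = c(0, 1, 0, 1, 0, 1),
                     cell_type = c("A", "A", "B", "B", "A", "B"),
                     cluster = "k1",
                     nuclear_count = c(3, 2, 4, 0, 4, 3))
  cell_table(counts, meta)
}

# independent ray-casting point-in-polygon oracle (boundary-inclusive via
# epsilon test on segments)
ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  on_edge <- function(x, y) {
    for (i in seq_len(n)) {
      a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
      cross <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
      if (abs(cross) < 1e-12 &&
          x >= min(a[1], b[1]) - 1e-12 && x <= max(a[1], b[1]) + 1e-12 &&
          y >= min(a[2], b[2]) - 1e-12 && y <= max(a[2], b[2]) + 1e-12)
        return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_edge(x, y)) return(TRUE)
    crossings <- 0L
    for (i in seq_len(n)) {
      a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
      if ((a[2] > y) != (b[2] > y)) {
        xint <- a[1] + (y - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# brute-force k nearest neighbours (self-excluded), returning index matrix
brute_knn <- function(xy, k) {
  n <- nrow(xy)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    d[i] <- Inf
    order(d)[seq_len(k)]
  }, integer(k)))
}
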