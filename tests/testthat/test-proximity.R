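# Spatial graphs, interaction scores, nearest-type distances and
# KS-based proximity comparison.

small_layout <- function(n = 50, types = c("A", "B", "C"), seed = 23) {
  set.seed(seed)
  meta <- data.frame(cell_id = paste0("c", 1:n),
                     x = runif(n, 0, 100), y = runif(n, 0, 100),
                     cell_type = sample(types, n, TRUE),
                     replicate_id = "R1")
  cell_table(matrix(0L, 1, n, dimnames = list("g", NULL)), meta)
}

test_that("knn graph edges equal brute-force k nearest neighbours (symmetrized)", {
  ct <- small_layout()
  g <- spatial_neighbor_graph(ct, "knn", 5)
  el <- igraph::as_edgelist(g, names = FALSE)
  got <- unique(t(apply(el, 1, sort)))
  nn <- brute_knn(as.matrix(ct$meta[, c("x", "y")]), 5)
  pairs <- unique(t(apply(cbind(rep(1:50, each = 5), as.vector(t(nn))),
                          1, sort)))
  expect_setequal(paste(got[, 1], got[, 2]), paste(pairs[, 1], pairs[, 2]))

  # two cells, k = 1: a single edge
  g2 <- spatial_neighbor_graph(subset_cells(ct, 1:2), "knn", 1)
  expect_equal(igraph::ecount(g2), 1)
})

test_that("degenerate delaunay layouts fall back to knn with a warning", {
  ct <- small_layout(3)
  ct$meta$y <- 0  # collinear
  expect_warning(g <- spatial_neighbor_graph(ct, "delaunay"),
                 "degenerate|knn")
  expect_gt(igraph::ecount(g), 0)
  # a proper layout triangulates without warning
  ct2 <- small_layout(20)
  expect_silent(g2 <- spatial_neighbor_graph(ct2, "delaunay"))
  expect_true(igraph::ecount(g2) > 0)
})

test_that("radius graphs connect exactly the pairs within the radius", {
  ct <- small_layout(30)
  r <- 20
  g <- suppressWarnings(spatial_neighbor_graph(ct, "radius", r))
  el <- igraph::as_edgelist(g, names = FALSE)
  d <- as.matrix(dist(ct$meta[, c("x", "y")]))
  expected <- which(d < r & upper.tri(d), arr.ind = TRUE)
  expect_equal(igraph::ecount(g), nrow(expected))
})

test_that("interaction scores tally edges by type pair, symmetric, normalized", {
  # alternating A-B chain: k = 1 connects consecutive cells only
  meta <- data.frame(cell_id = paste0("c", 1:6), x = 1:6, y = 0,
                     cell_type = rep(c("A", "B"), 3))
  ct <- cell_table(matrix(0L, 1, 6, dimnames = list("g", NULL)), meta)
  g <- spatial_neighbor_graph(ct, "knn", 1)
  sc <- interaction_scores(g)
  expect_equal(sc$raw["A", "A"], 0)
  expect_equal(sc$raw["B", "B"], 0)
  expect_equal(sc$max_norm["A", "B"], 1)

  # single type: 1x1 normalized matrix equal to 1
  meta1 <- data.frame(cell_id = paste0("c", 1:4), x = 1:4, y = 0,
                      cell_type = "A")
  ct1 <- cell_table(matrix(0L, 1, 4, dimnames = list("g", NULL)), meta1)
  sc1 <- interaction_scores(spatial_neighbor_graph(ct1, "knn", 1))
  expect_equal(unname(sc1$max_norm[1, 1]), 1)

  # random 3-type layout vs exhaustive edge tally
  ct3 <- small_layout(40)
  g3 <- spatial_neighbor_graph(ct3, "knn", 4)
  sc3 <- interaction_scores(g3)
  el <- igraph::as_edgelist(g3, names = FALSE)
  tt <- ct3$meta$cell_type
  types <- sort(unique(tt))
  oracle <- matrix(0, 3, 3, dimnames = list(types, types))
  for (e in seq_len(nrow(el))) {
    a <- tt[el[e, 1]]; b <- tt[el[e, 2]]
    oracle[a, b] <- oracle[a, b] + 1
    if (a != b) oracle[b, a] <- oracle[b, a] + 1
  }
  expect_equal(sc3$raw, oracle)
  expect_equal(sc3$raw, t(sc3$raw))
  expect_equal(unname(rowSums(sc3$row_norm)), rep(1, 3))
  expect_true(all(sc3$max_norm >= 0 & sc3$max_norm <= 1))
  # edge list honours the threshold
  expect_true(all(sc3$edges$score > sc3$threshold))
})

test_that("replicate averaging covers the type union and warns on absent types", {
  ctA <- small_layout(30, types = c("A", "B"), seed = 1)
  ctB <- small_layout(30, types = c("A", "B", "C"), seed = 2)
  gA <- spatial_neighbor_graph(ctA, "knn", 3)
  gB <- spatial_neighbor_graph(ctB, "knn", 3)
  expect_warning(sc <- interaction_scores(list(gA, gB)), "absent")
  expect_equal(sc$n_replicates, 2L)
  scA <- interaction_scores(gA)
  scB <- interaction_scores(gB)
  expect_equal(sc$raw["A", "B"],
               (scA$raw["A", "B"] + scB$raw["A", "B"]) / 2)
  expect_equal(sc$raw["C", "C"], scB$raw["C", "C"] / 2)
})

test_that("nearest-type distances are Euclidean, self-excluded and match brute force", {
  meta <- data.frame(cell_id = c("p", "q", "r"),
                     x = c(0, 3, 10), y = c(0, 4, 0),
                     cell_type = c("A", "B", "B"))
  ct <- cell_table(matrix(0L, 1, 3, dimnames = list("g", NULL)), meta)
  d <- nearest_type_distances(ct)
  expect_equal(d$B[1], 5)           # 3-4-5 triangle
  expect_equal(d$B[2], sqrt(7^2 + 4^2))  # q's nearest OTHER B is r
  expect_true(is.infinite(nearest_type_distances(
    subset_cells(ct, 1), target_types = "A")$A[1]) |> suppressWarnings())

  # 40-cell toy vs a brute-force all-pairs scan
  ct40 <- small_layout(40)
  got <- nearest_type_distances(ct40)
  dm <- as.matrix(dist(ct40$meta[, c("x", "y")]))
  diag(dm) <- Inf
  for (ty in c("A", "B", "C")) {
    oracle <- apply(dm[, ct40$meta$cell_type == ty, drop = FALSE], 1, min)
    expect_equal(got[[ty]], unname(oracle), tolerance = 1e-10)
  }
  # rigid motion invariance
  ct40b <- ct40
  th <- 0.7
  xy <- as.matrix(ct40$meta[, c("x", "y")])
  rot <- xy %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ct40b$meta$x <- rot[, 1] + 55; ct40b$meta$y <- rot[, 2] - 12
  got2 <- nearest_type_distances(ct40b)
  for (ty in c("A", "B", "C"))
    expect_equal(got2[[ty]], got[[ty]], tolerance = 1e-9)
})

test_that("expression-distance correlation recovers sign conventions and nulls", {
  ct <- small_layout(200, seed = 31)
  dist_tab <- nearest_type_distances(ct)
  # score exactly equal to minus the distance to A: rho = -1
  score <- -dist_tab$A
  res <- expression_distance_correlation(score, dist_tab)
  expect_equal(res$rho[res$target_type == "A"], -1)
  # permuted (geometry-independent) scores rarely exceed |rho| 0.3
  set.seed(77)
  exceed <- vapply(1:300, function(i) {
    r <- expression_distance_correlation(sample(score), dist_tab)
    max(abs(r$rho))
  }, numeric(1))
  expect_lt(mean(exceed > 0.3), 0.02)
  # zero-variance score flagged
  expect_warning(res0 <- expression_distance_correlation(
    rep(1, 200), dist_tab), "zero-variance")
  expect_true(all(is.na(res0$rho)))
})

test_that("a planted epithelial-proximity gene correlates negatively with epithelial distance", {
  s <- shared_sample()
  cd8 <- s$truth$cell_type == "cd8_t"
  sub <- subset_cells(s$bundle$cells, cd8)
  dist_tab <- nearest_type_distances(s$bundle$cells,
                                     target_types = "enterocyte")
  # Itgae has a negative epithelial-axis slope: high near the epithelium
  res <- expression_distance_correlation(
    as.numeric(sub$counts["Itgae", ]), dist_tab[cd8, , drop = FALSE],
    sample_id = sub$meta$sample_id)
  expect_lt(res$rho[res$target_type == "enterocyte"], 0)
})

test_that("KS proximity comparison matches hand-computed statistics", {
  same <- compare_proximity_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_false(same$different)
  disjoint <- compare_proximity_distributions(c(0, 0), c(1, 1))
  expect_equal(disjoint$D, 1)
  expect_true(disjoint$different)
  shift <- compare_proximity_distributions(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(shift$D, 0.25)
  # invariance under a common strictly monotone transform
  shift2 <- compare_proximity_distributions(exp(c(1, 2, 3, 4)),
                                            exp(c(2, 3, 4, 5)))
  expect_equal(shift2$D, shift$D)
  expect_error(compare_proximity_distributions(1, c(1, 2)), "at least 2")
})
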