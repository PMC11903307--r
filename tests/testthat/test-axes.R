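# The three anatomical axes against hand-computed values, brute-force
# oracles and synthetic ground truth.

test_that("longitudinal axis is the arc-length fraction of the nearest polyline point", {
  basal <- polyline_annotation("b", rbind(c(0, 0), c(10, 0)))
  ct <- cell_table(matrix(0L, 1, 2, dimnames = list("g", NULL)),
                   data.frame(cell_id = c("a", "b"), x = c(0, 5),
                              y = c(1, 2)))
  expect_equal(longitudinal_axis(ct, basal), c(0, 0.5))
})

test_that("longitudinal projection matches a dense-sampling oracle on a bent polyline", {
  v <- rbind(c(0, 0), c(10, 0), c(10, 8), c(20, 8))
  basal <- polyline_annotation("b", v)
  set.seed(21)
  n <- 50
  meta <- data.frame(cell_id = paste0("c", 1:n),
                     x = runif(n, -2, 22), y = runif(n, -2, 10))
  ct <- cell_table(matrix(0L, 1, n, dimnames = list("g", NULL)), meta)
  got <- longitudinal_axis(ct, basal)
  # oracle: 1e4 points sampled uniformly in arc length along the line
  total <- basal$cumulative_length[4]
  arc <- seq(0, total, length.out = 1e4)
  pts <- t(vapply(arc, function(a) {
    s <- findInterval(a, basal$cumulative_length, rightmost.closed = TRUE)
    t <- (a - basal$cumulative_length[s]) /
      diff(basal$cumulative_length)[s]
    v[s, ] + t * (v[s + 1, ] - v[s, ])
  }, numeric(2)))
  oracle <- vapply(seq_len(n), function(i) {
    d <- (pts[, 1] - meta$x[i])^2 + (pts[, 2] - meta$y[i])^2
    arc[which.min(d)] / total
  }, numeric(1))
  expect_true(all(abs(got - oracle) < 1e-3))
  # rigid translation leaves values unchanged
  ct2 <- ct; ct2$meta$x <- ct2$meta$x + 100; ct2$meta$y <- ct2$meta$y - 7
  basal2 <- polyline_annotation("b", cbind(v[, 1] + 100, v[, 2] - 7))
  expect_equal(longitudinal_axis(ct2, basal2), got, tolerance = 1e-12)
})

test_that("crypt-villus z-scores use the population s.d. within each villus", {
  basal <- polyline_annotation("b", rbind(c(0, 0), c(10, 0)))
  ct <- cell_table(matrix(0L, 1, 3, dimnames = list("g", NULL)),
                   data.frame(cell_id = c("a", "b", "c"), x = 1:3,
                              y = c(1, 2, 3)))
  vl <- setNames(c(1L, 1L, 1L), c("a", "b", "c"))
  cv <- crypt_villus_axis_geometric(ct, basal, vl)
  expect_equal(cv$crypt_villus_raw, c(1, 2, 3))
  expect_equal(cv$crypt_villus, c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-6)  # {1,2,3}: z = +/-1.2247, 0
  # zero-variance villus maps to zeros
  ct2 <- ct; ct2$meta$y <- c(2, 2, 2)
  cv2 <- crypt_villus_axis_geometric(ct2, basal, vl)
  expect_equal(cv2$crypt_villus, c(0, 0, 0))
  # muscularis side is signed negative
  ct3 <- ct; ct3$meta$y <- c(-1, 1, 2)
  cv3 <- crypt_villus_axis_geometric(ct3, basal, vl)
  expect_equal(cv3$crypt_villus_raw, c(-1, 1, 2))
})

test_that("per-villus z-scores recover ground-truth height on synthetic tissue", {
  s <- shared_sample()
  ax <- s$axes
  tr <- s$truth
  for (v in 1:3) {  # spot-check three villi
    idx <- tr$villus_id == v
    expect_gt(cor(ax$crypt_villus[idx], tr$true_cv[idx],
                  method = "spearman"), 0.95)
    # mean 0, population s.d. 1 within villus
    z <- ax$crypt_villus[idx]
    expect_equal(mean(z), 0, tolerance = 1e-8)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-8)
  }
  expect_true(all(ax$crypt_villus_display >= 0 &
                    ax$crypt_villus_display <= 1))
})

test_that("neighborhood matrix sums the k nearest neighbours' counts", {
  # one-hot counts: with k = 1 each row is the nearest neighbour's row
  counts <- diag(6)
  dimnames(counts) <- list(paste0("g", 1:6), NULL)
  ct <- cell_table(counts, data.frame(cell_id = paste0("c", 1:6),
                                      x = c(0, 1, 3, 6, 10, 15), y = 0,
                                      cell_type = "t"))
  emb <- neighborhood_factors(ct, k = 1L, n_factors = 2L, seed = 1)
  nearest <- c(2, 1, 2, 3, 4, 5)
  expect_equal(unname(emb$neighborhood),
               unname(counts[, nearest] |> t()), ignore_attr = TRUE)
})

test_that("a rank-1 neighborhood factorizes exactly with one factor", {
  # identical counts in every cell make N rank 1
  counts <- matrix(rep(c(4, 1, 0, 2), 30), nrow = 4,
                   dimnames = list(paste0("g", 1:4), NULL))
  set.seed(8)
  ct <- cell_table(counts, data.frame(cell_id = paste0("c", 1:30),
                                      x = runif(30), y = runif(30),
                                      cell_type = "t"))
  emb <- neighborhood_factors(ct, k = 5L, n_factors = 1L, seed = 2)
  rel_err <- sqrt(emb$mse) / mean(emb$neighborhood)
  expect_lt(rel_err, 1e-6)
  expect_true(all(emb$loadings >= 0))
})

test_that("k exceeding the neighbour pool warns and uses all", {
  ct <- cell_table(matrix(1, 1, 4, dimnames = list("g", NULL)),
                   data.frame(cell_id = paste0("c", 1:4),
                              x = 1:4, y = 0, cell_type = "t"))
  expect_warning(emb <- neighborhood_factors(ct, k = 10L, n_factors = 1L),
                 "exceeds")
  expect_equal(emb$k, 3L)
})

test_that("axis prediction memorizes with a 1-NN regressor and smoothing_k = 1 is the identity", {
  set.seed(5)
  W <- matrix(runif(40), 20, 2)
  coords <- matrix(runif(40, 0, 100), 20, 2)
  y <- runif(20)
  pred <- crypt_villus_axis_predicted(W, coords, seq_len(20), y,
                                      smoothing_k = 1L,
                                      regressor = knn_regressor(1L),
                                      min_labeled = 5L, seed = 2)
  expect_equal(pred$prediction, y, tolerance = 1e-12)
  expect_identical(pred$prediction, pred$prediction_raw)
  expect_error(crypt_villus_axis_predicted(W, coords, 1:3, y[1:3],
                                           min_labeled = 5L), "labelled")
})

test_that("cross-sample neighborhood prediction recovers the crypt-villus axis", {
  p <- shared_pair()
  emb <- neighborhood_factors(
    p$joint, k = 10L, n_factors = 15L,
    restrict_types = c("enterocyte", "goblet", "progenitor",
                       "fibroblast", "smooth_muscle"), seed = 3)
  pred <- crypt_villus_axis_predicted(
    emb, p$joint$meta[, c("x", "y")],
    train_idx = which(p$is_a), train_labels = p$axA$crypt_villus,
    smoothing_k = 150L, seed = 5)
  rho <- cor(pred$prediction[!p$is_a], p$sB$truth$true_cv,
             method = "spearman")
  expect_gt(rho, 0.8)
  # geometric and predicted axes agree on the held-out sample
  expect_gt(cor(pred$prediction[!p$is_a], p$axB$crypt_villus,
                method = "spearman"), 0.8)
})

test_that("epithelial-axis ratios equal a brute-force k-NN oracle and are >= 1", {
  set.seed(17)
  n <- 30
  meta <- data.frame(cell_id = paste0("c", 1:n),
                     x = runif(n, 0, 50), y = runif(n, 0, 50),
                     cell_type = sample(c("enterocyte", "cd8_t",
                                          "fibroblast"), n, TRUE))
  ct <- cell_table(matrix(0L, 1, n, dimnames = list("g", NULL)), meta)
  ax <- epithelial_axis(ct, epithelial_types = "enterocyte",
                        k_epi = 5L, k_any = 5L)
  # brute force
  d <- as.matrix(dist(meta[, c("x", "y")]))
  diag(d) <- Inf
  epi_idx <- which(meta$cell_type == "enterocyte")
  oracle <- vapply(seq_len(n), function(i) {
    d_epi <- sort(d[i, epi_idx])[1:5]
    d_any <- sort(d[i, ])[1:5]
    mean(d_epi) / mean(d_any)
  }, numeric(1))
  expect_equal(ax$epithelial_raw, oracle, tolerance = 1e-10)
  expect_true(all(ax$epithelial_raw >= 1))
  expect_true(all(ax$epithelial_clipped <= 3))
})

test_that("on tissue, epithelial cells score lower than lamina propria cells", {
  s <- shared_sample()
  epi <- s$truth$compartment == "epithelial"
  lam <- s$truth$compartment == "lamina"
  expect_lt(mean(s$axes$epithelial[epi]), mean(s$axes$epithelial[lam]))
  expect_true(all(s$axes$epithelial_raw >= 1))
})
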