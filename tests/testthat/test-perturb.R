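# Barcode detection and the four-criterion perturbed-cell caller.

perturb_toy <- function() {
  # genes: markers, contaminant, three barcode channels
  genes <- c("Cd8a", "Cd8b1", "Cd3e", "Muc2", "Muc5ac", "Neurog3",
             "Fer1l6")
  m <- rbind(
    #          boundary   muc2fail  nobarcode  ambiguous  offclust  clean
    Cd8a    = c(2,          5,        5,         4,         5,       6),
    Cd8b1   = c(1,          4,        3,         3,         4,       2),
    Cd3e    = c(0,          2,        2,         2,         2,       3),
    Muc2    = c(1,          2,        0,         0,         1,       0),
    Muc5ac  = c(1,          3,        0,         2,         2,       0),
    Neurog3 = c(0,          0,        0,         2,         0,       4),
    Fer1l6  = c(0,          0,        0,         0,         0,       0))
  meta <- data.frame(cell_id = c("boundary", "muc2fail", "nobarcode",
                                 "ambiguous", "offclust", "clean"),
                     x = 1:6, y = 0,
                     cluster = c("cd8", "cd8", "cd8", "cd8", "goblet",
                                 "cd8"))
  cell_table(m, meta)
}

test_that("barcode detection reads channels with strict-max assignment", {
  ct <- perturb_toy()
  bc <- detect_barcodes(ct, default_barcode_design())
  expect_identical(bc$tentative_sgrna,
                   c("sgCd19", "sgCd19", "none", "ambiguous", "sgCd19",
                     "sgThy1"))
  expect_equal(bc$barcode_total,
               c(1, 3, 0, 4, 2, 4))
  bad <- barcode_design("sgX", "NotInPanel", 7L, "control")
  expect_error(detect_barcodes(ct, bad), "absent")
})

test_that("the caller enforces all four criteria with inclusive boundaries", {
  ct <- perturb_toy()
  calls <- call_perturbed_cells(ct, default_barcode_design(),
                                required_clusters = "cd8")
  by_id <- setNames(calls$called, calls$cell_id)
  # marker sum exactly 3, one barcode, right cluster, Muc2 = 1: called
  expect_true(by_id["boundary"])
  # Muc2 = 2 rejected regardless of barcodes
  expect_false(by_id["muc2fail"])
  # no barcode detected
  expect_false(by_id["nobarcode"])
  # wrong cluster
  expect_false(by_id["offclust"])
  # ambiguous dominant channel is still called but keeps the ambiguous label
  expect_true(by_id["ambiguous"])
  expect_identical(calls$sgrna[calls$cell_id == "ambiguous"], "ambiguous")
  expect_identical(calls$sgrna[calls$cell_id == "clean"], "sgThy1")
  # re-running is bit-identical (pure function)
  calls2 <- call_perturbed_cells(ct, default_barcode_design(),
                                 required_clusters = "cd8")
  expect_identical(calls, calls2)
})

test_that("calls equal an independent re-application of the four rules on tissue", {
  s <- shared_sample()
  cells <- s$bundle$cells
  design <- default_barcode_design()
  calls <- call_perturbed_cells(cells, design,
                                required_clusters = "cd8_t")
  counts <- as.matrix(cells$counts)
  oracle <- vapply(seq_len(n_cells(cells)), function(i) {
    sum(counts[c("Cd8a", "Cd8b1", "Cd3e"), i]) >= 3 &&
      any(counts[design$landing_gene, i] >= 1) &&
      cells$meta$cluster[i] == "cd8_t" &&
      counts["Muc2", i] <= 1
  }, logical(1))
  expect_identical(calls$called, oracle)
})

test_that("decoding achieves perfect precision and oracle-matched recall on synthetic truth", {
  # contamination present: precision still 1 because of the Muc2 rule
  s <- shared_sample()
  calls <- call_perturbed_cells(s$bundle$cells, default_barcode_design(),
                                required_clusters = "cd8_t")
  called <- calls[calls$called, ]
  truth_lab <- s$truth$perturbation[match(called$cell_id, s$truth$cell_id)]
  expect_true(all(called$sgrna == truth_lab))

  # contamination 0: precision = recall = 1 against the filter-passing truth
  cfg <- synth_config(n_villi = 4L, seed = 77L,
                      cells_per_villus = c(epithelial = 60L, lamina = 120L,
                                           muscularis = 30L))
  s0 <- generate_sample(cfg, design = default_barcode_design(),
                        contamination_rate = 0)
  calls0 <- call_perturbed_cells(s0$bundle$cells, default_barcode_design(),
                                 required_clusters = "cd8_t")
  tr0 <- s0$truth
  called0 <- calls0$called
  truly <- !is.na(tr0$perturbation)
  # precision: every called cell is truly perturbed with the right guide
  expect_true(all(tr0$perturbation[called0] ==
                    calls0$sgrna[called0]))
  # recall among true perturbed cells passing the four criteria
  markers <- Matrix::colSums(s0$bundle$cells$counts[
    c("Cd8a", "Cd8b1", "Cd3e"), ])
  muc2 <- as.numeric(s0$bundle$cells$counts["Muc2", ])
  pass <- truly & markers >= 3 & muc2 <= 1
  expect_true(all(called0[pass]))
  expect_equal(sum(called0), sum(pass))
})

test_that("pairwise Welch DE flags a planted shift and nothing under the null", {
  set.seed(55)
  n <- 200
  base <- matrix(rpois(4 * 2 * n, 5), nrow = 4,
                 dimnames = list(c("target", "null1", "null2", "ballast"),
                                 NULL))
  # a high ballast keeps totals (and hence per-cell normalization) stable
  # against the planted shift
  base["ballast", ] <- rpois(2 * n, 100)
  # group B gets a planted shift in `target` of about 2 s.d.
  base["target", (n + 1):(2 * n)] <-
    base["target", (n + 1):(2 * n)] + rpois(n, 2 * sqrt(5))
  bc <- matrix(0L, 2, 2 * n, dimnames = list(c("Muc5ac", "Neurog3"), NULL))
  bc["Muc5ac", 1:n] <- 1L
  bc["Neurog3", (n + 1):(2 * n)] <- 1L
  ct <- cell_table(rbind(base, bc),
                   data.frame(cell_id = paste0("c", 1:(2 * n)),
                              x = 0, y = 0, cluster = "cd8"))
  design <- barcode_design(c("sgA", "sgB"), c("Muc5ac", "Neurog3"),
                           c(7L, 8L), c("control", "experimental"))
  calls <- data.frame(cell_id = ct$meta$cell_id,
                      called = TRUE,
                      sgrna = rep(c("sgA", "sgB"), each = n))
  de <- perturbation_de(ct, calls, genes = c("target", "null1", "null2"))
  expect_lt(de$p_adj[de$gene == "target"], 0.001)
  expect_identical(as.character(de$tier[de$gene == "target"]), "***")
  expect_true(all(de$p_adj[de$gene %in% c("null1", "null2")] > 0.05))

  # identical groups: no significant genes
  ct2 <- cell_table(cbind(rbind(base, bc)[, 1:n], rbind(base, bc)[, 1:n]),
                    data.frame(cell_id = paste0("c", 1:(2 * n)),
                               x = 0, y = 0, cluster = "cd8"))
  de2 <- perturbation_de(ct2, calls, genes = c("target", "null1"))
  expect_true(all(de2$p_adj > 0.05))
})

test_that("gate-stratified DE localizes a gate-specific effect and checks barcode uniformity", {
  set.seed(66)
  n <- 120  # per group per gate
  gate <- rep(c("top", "crypt"), each = 2 * n)
  sg <- rep(rep(c("sgA", "sgB"), each = n), 2)
  target <- rpois(4 * n, 5)
  # effect only in the top gate for sgB
  target[gate == "top" & sg == "sgB"] <-
    target[gate == "top" & sg == "sgB"] + rpois(n, 2 * sqrt(5))
  bc <- matrix(0L, 2, 4 * n, dimnames = list(c("Muc5ac", "Neurog3"), NULL))
  bc["Muc5ac", sg == "sgA"] <- 1L
  bc["Neurog3", sg == "sgB"] <- 1L
  counts <- rbind(target = target, filler = rpois(4 * n, 3), bc)
  ct <- cell_table(counts, data.frame(cell_id = paste0("c", 1:(4 * n)),
                                      x = 0, y = 0, cluster = "cd8"))
  calls <- data.frame(cell_id = ct$meta$cell_id, called = TRUE,
                      sgrna = sg,
                      barcode_total = as.numeric(colSums(bc)))
  cv <- runif(4 * n)
  res <- gate_stratified_de(ct, calls, gate, cv,
                            genes = c("target", "filler"))
  top_p <- res$by_gate$top$p_adj[res$by_gate$top$gene == "target"]
  crypt_p <- res$by_gate$crypt$p_adj[res$by_gate$crypt$gene == "target"]
  expect_lt(top_p, 0.01)
  expect_gt(crypt_p, 0.05)
  # constant barcode totals make the uniformity diagnostic undefined
  expect_true(is.na(res$uniformity_rho))
  # varying barcode totals, independent of the axis: rho near 0
  calls2 <- calls
  set.seed(67)
  calls2$barcode_total <- rpois(4 * n, 2) + 1
  res2 <- gate_stratified_de(ct, calls2, gate, cv,
                             genes = c("target", "filler"))
  expect_lt(abs(res2$uniformity_rho), 0.15)
  # under-sized groups are skipped with a reason
  res3 <- gate_stratified_de(ct, calls, c(rep("tiny", 3),
                                          gate[-(1:3)]), cv,
                             genes = "target")
  expect_true("tiny" %in% res3$skipped$gate)
})
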