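# Synthetic small-intestine generator. Emulates a flattened section of
# rolled gut: a straight basal membrane at y = 0, a muscularis band below
# it, and a row of semi-elliptic villi above it. Epithelial cells sit on
# each villus outline, lamina propria cells fill the interior, crypt
# epithelium sits near the base, and muscularis cells occupy the band.
# Ground-truth anatomical coordinates are exact functions of placement, so
# axis-recovery tests have a noiseless reference.

#' Configuration for the synthetic tissue generator
#'
#' Defaults produce roughly 5,000 cells over 10 villi -- a desk-scale
#' stand-in for one profiled section.
#'
#' @param n_villi Number of villi laid left to right.
#' @param villus_height,villus_width,crypt_depth,muscularis_thickness
#'   Tissue dimensions in micrometres.
#' @param cells_per_villus Named integer vector with compartments
#'   `epithelial`, `lamina`, `muscularis` (muscularis count is per villus
#'   width of band).
#' @param cell_type_frequencies Named list of named numeric vectors, one
#'   per compartment; each must sum to 1.
#' @param gene_models `data.frame` of per-gene log-linear rate models; see
#'   [default_gene_models()].
#' @param noise `"poisson"` (default) or `"negative_binomial"`.
#' @param nb_size Negative-binomial size (dispersion) when
#'   `noise = "negative_binomial"`.
#' @param nuclear_fraction Binomial probability that a transcript is
#'   nuclear.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_villi = 10L,
                         villus_height = 400,
                         villus_width = 120,
                         crypt_depth = 60,
                         muscularis_thickness = 60,
                         cells_per_villus = c(epithelial = 150L,
                                              lamina = 250L,
                                              muscularis = 100L),
                         cell_type_frequencies = default_type_frequencies(),
                         gene_models = default_gene_models(),
                         noise = c("poisson", "negative_binomial"),
                         nb_size = 10,
                         nuclear_fraction = 0.5,
                         seed = 1L) {
  noise <- match.arg(noise)
  dims <- c(n_villi = n_villi, villus_height = villus_height,
            villus_width = villus_width, crypt_depth = crypt_depth,
            muscularis_thickness = muscularis_thickness)
  if (any(dims <= 0)) stop("all dimensions must be positive")
  if (crypt_depth >= villus_height)
    stop("infeasible geometry: crypt_depth must be below villus_height")
  for (cmp in names(cell_type_frequencies)) {
    s <- sum(cell_type_frequencies[[cmp]])
    if (abs(s - 1) > 1e-8)
      stop("cell_type_frequencies for ", cmp, " sum to ", s, ", not 1")
  }
  structure(list(n_villi = as.integer(n_villi),
                 villus_height = villus_height, villus_width = villus_width,
                 crypt_depth = crypt_depth,
                 muscularis_thickness = muscularis_thickness,
                 cells_per_villus = cells_per_villus,
                 cell_type_frequencies = cell_type_frequencies,
                 gene_models = gene_models, noise = noise, nb_size = nb_size,
                 nuclear_fraction = nuclear_fraction,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Default cell-type frequencies per tissue compartment
#' @return Named list of named frequency vectors summing to 1.
#' @export
default_type_frequencies <- function() {
  list(
    epithelial = c(enterocyte = 0.75, goblet = 0.15, progenitor = 0.10),
    lamina = c(cd8_t = 0.30, cd4_t = 0.15, b_cell = 0.20,
               fibroblast = 0.20, dc = 0.15),
    muscularis = c(smooth_muscle = 0.70, fibroblast = 0.20, cd8_t = 0.10))
}

#' Default gene models for the synthetic panel
#'
#' Each gene's expected count is
#' `exp(b0 + b_cv * cv + b_epi * epi + b_long * long)` where `cv` is the
#' true normalized villus height, `epi` the min-max-normalized true
#' epithelial distance and `long` the longitudinal fraction; expression is
#' restricted to the listed cell types (`types = NA` means all). The
#' defaults mirror the biology the package is meant to resolve: cytotoxic
#' effector genes (Gzma/Gzmb/Itgae) rising towards the villus top in CD8 T
#' cells, progenitor genes (Tcf7/Slamf6) rising towards the crypt,
#' enterocyte zonation genes along the crypt-villus axis, chemokines from
#' fibroblasts low in the villus, lineage markers flat, and ten null genes
#' with zero slope everywhere. The three barcode landing genes
#' (Muc5ac/Neurog3/Fer1l6) are in the panel but off (`b0 = -Inf`) until
#' barcodes are injected.
#'
#' @return `data.frame` with columns `gene`, `b0`, `b_cv`, `b_epi`,
#'   `b_long`, `types` (comma-separated or NA for all).
#' @export
default_gene_models <- function() {
  m <- rbind(
    # lineage markers, flat
    c("Epcam",  log(8), 0, 0, 0, "enterocyte,goblet,progenitor"),
    c("Muc2",   log(15), 0, 0, 0, "goblet"),
    c("Cd8a",   log(5), 0, 0, 0, "cd8_t"),
    c("Cd8b1",  log(4), 0, 0, 0, "cd8_t"),
    c("Cd3e",   log(4), 0, 0, 0, "cd8_t,cd4_t"),
    c("Cd4",    log(4), 0, 0, 0, "cd4_t"),
    c("Ms4a1",  log(6), 0, 0, 0, "b_cell"),
    c("Col1a1", log(8), 0, 0, 0, "fibroblast"),
    c("Myh11",  log(8), 0, 0, 0, "smooth_muscle"),
    c("Itgax",  log(4), 0, 0, 0, "dc"),
    c("Cxcr3",  log(3), 0, 0, 0, "cd8_t"),
    # CD8 T cell axis-graded programs
    c("Gzmb",   log(3),  1.0,  0,   0, "cd8_t"),
    c("Gzma",   log(3),  1.0,  0,   0, "cd8_t"),
    c("Itgae",  log(2),  0.8, -0.8, 0, "cd8_t"),
    c("Tcf7",   log(3), -1.0,  0,   0, "cd8_t"),
    c("Slamf6", log(2), -1.0,  0,   0, "cd8_t"),
    c("Klrg1",  log(2), -0.8,  0,   0, "cd8_t"),
    c("Il18r1", log(2), -0.6,  0,   0, "cd8_t"),
    c("Cxcr6",  log(2),  0,   -0.6, 0, "cd8_t"),
    c("Klf2",   log(2), -0.5,  0,   0, "cd8_t"),
    # enterocyte zonation
    c("Alpi",   log(5),  1.0,  0,   0, "enterocyte"),
    c("Ada",    log(3),  1.0,  0,   0, "enterocyte"),
    c("Apoa4",  log(4),  0.8,  0,   0, "enterocyte"),
    c("Reg3b",  log(4), -0.8,  0,   0, "enterocyte"),
    c("Olfm4",  log(4), -1.2,  0,   0, "enterocyte,progenitor"),
    c("Lgr5",   log(4), -1.2,  0,   0, "progenitor"),
    c("Gata4",  log(3),  0,    0,  -1, "enterocyte"),
    # stromal cytokines and chemokines
    c("Cxcl9",  log(2), -1.0,  0,   0, "fibroblast"),
    c("Cxcl10", log(2), -1.0,  0,   0, "fibroblast"),
    c("Il15",   log(2),  0.5,  0,   0, "fibroblast,enterocyte"),
    c("Il7",    log(2),  0.5,  0,   0, "fibroblast"),
    c("Tgfb1",  log(2), -0.5,  0,   0, "fibroblast"),
    # null genes: zero slope by construction
    cbind(sprintf("Null%02d", 1:10), log(2), 0, 0, 0, NA),
    # barcode landing genes, off until injected
    c("Muc5ac", -Inf, 0, 0, 0, NA),
    c("Neurog3", -Inf, 0, 0, 0, NA),
    c("Fer1l6", -Inf, 0, 0, 0, NA))
  data.frame(gene = m[, 1], b0 = as.numeric(m[, 2]),
             b_cv = as.numeric(m[, 3]), b_epi = as.numeric(m[, 4]),
             b_long = as.numeric(m[, 5]), types = m[, 6],
             stringsAsFactors = FALSE)
}

# Dense sample of one villus outline (semi-ellipse), base-left to
# base-right over the top. Used both for epithelial placement and for
# ground-truth epithelial distances.
villus_outline <- function(xc, half_width, height, n = 400) {
  theta <- seq(pi, 0, length.out = n)
  cbind(x = xc + half_width * cos(theta), y = height * sin(theta))
}

point_to_points_min_dist <- function(pts, ref) {
  # min Euclidean distance from each row of pts to the reference cloud
  d2 <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Generate the synthetic tissue geometry and cell placement
#'
#' Lays `n_villi` semi-elliptic villi left to right along a straight basal
#' membrane at y = 0, with a muscularis band below. Epithelial cells are
#' placed on the villus outline (true epithelial distance 0); a share of
#' them near the base represent crypt epithelium. Lamina propria cells are
#' placed inside the villus; muscularis cells in the band. Ground-truth
#' axes are recorded analytically from placement.
#'
#' @param config A [synth_config()].
#' @return List with elements `bundle` (a [sample_bundle()] without counts
#'   yet; its cell table holds a zero count matrix over the panel) and
#'   `truth` (`data.frame`: `cell_id`, `compartment`, `cell_type`,
#'   `villus_id`, `true_long`, `true_cv`, `true_epi` (micrometres),
#'   `true_epi_norm`, `perturbation`). The villus outlines used are kept
#'   in `attr(truth, "outlines")`.
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  W <- config$villus_width; H <- config$villus_height
  nv <- config$n_villi
  half_width <- 0.42 * W
  total_length <- nv * W

  rows <- list(); outlines <- list()
  for (v in seq_len(nv)) {
    xc <- (v - 0.5) * W
    outline <- villus_outline(xc, half_width, H)
    outlines[[v]] <- outline
    n_epi <- config$cells_per_villus[["epithelial"]]
    n_lam <- config$cells_per_villus[["lamina"]]
    n_mus <- config$cells_per_villus[["muscularis"]]

    # epithelial cells on the outline; uniform in arc parameter
    theta <- runif(n_epi, 0, pi)
    epi_xy <- cbind(xc + half_width * cos(theta), H * sin(theta))
    # lamina propria cells inside the villus (rejection-free: shrink to
    # the interior), biased slightly towards the base like real LP density
    u <- runif(n_lam)
    lam_y <- H * u^1.2 * 0.95
    lam_hw <- half_width * sqrt(pmax(1 - (lam_y / H)^2, 0)) * 0.85
    lam_x <- xc + runif(n_lam, -1, 1) * lam_hw
    # muscularis cells in the band below the basal membrane
    mus_x <- runif(n_mus, (v - 1) * W, v * W)
    mus_y <- -runif(n_mus, 0, config$muscularis_thickness)

    xy <- rbind(epi_xy, cbind(lam_x, lam_y), cbind(mus_x, mus_y))
    compartment <- rep(c("epithelial", "lamina", "muscularis"),
                       c(n_epi, n_lam, n_mus))
    # crypt epithelium: epithelial cells below crypt_depth
    types <- character(nrow(xy))
    for (cmp in c("epithelial", "lamina", "muscularis")) {
      idx <- compartment == cmp
      freq <- config$cell_type_frequencies[[cmp]]
      types[idx] <- sample(names(freq), sum(idx), TRUE, prob = freq)
    }
    true_epi <- numeric(nrow(xy))
    true_epi[compartment == "epithelial"] <- 0
    inner <- compartment != "epithelial"
    if (any(inner))
      true_epi[inner] <- point_to_points_min_dist(xy[inner, , drop = FALSE],
                                                  outline)
    rows[[v]] <- data.frame(
      x = xy[, 1], y = xy[, 2], compartment = compartment,
      cell_type = types, villus_id = v,
      true_cv = xy[, 2] / H, true_epi = true_epi)
  }
  truth <- do.call(rbind, rows)
  truth$cell_id <- sprintf("cell_%05d", seq_len(nrow(truth)))
  truth$true_long <- truth$x / total_length
  rng <- range(truth$true_epi)
  truth$true_epi_norm <- (truth$true_epi - rng[1]) / diff(rng)
  truth$perturbation <- NA_character_

  meta <- data.frame(cell_id = truth$cell_id, x = truth$x, y = truth$y,
                     cell_type = truth$cell_type,
                     cluster = truth$cell_type,
                     compartment = truth$compartment,
                     sample_id = "synthetic", replicate_id = "R1",
                     nuclear_count = 0L)
  genes <- config$gene_models$gene
  counts <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                 dims = c(length(genes), nrow(meta)),
                                 dimnames = list(genes, meta$cell_id))
  cells <- cell_table(counts, meta)
  basal <- polyline_annotation(
    "basal_membrane", cbind(seq(0, total_length, by = W), 0))
  bundle <- sample_bundle(
    transcripts = data.frame(x = numeric(), y = numeric(),
                             gene = character(), cell_id = character(),
                             nuclear = logical()),
    cells = cells,
    annotations = list(basal_membrane = basal),
    villus_labels = stats::setNames(truth$villus_id, truth$cell_id))
  truth <- truth[, c("cell_id", "compartment", "cell_type", "villus_id",
                     "true_long", "true_cv", "true_epi", "true_epi_norm",
                     "perturbation")]
  attr(truth, "outlines") <- outlines
  attr(truth, "dims") <- c(height = H, width = W, n_villi = nv,
                           total_length = total_length)
  list(bundle = bundle, truth = truth)
}

#' Draw transcript counts from the per-gene log-linear rate models
#'
#' `count(cell, gene) ~ Poisson(exp(b0 + b_cv*cv + b_epi*epi + b_long*long))`
#' for cells of the gene's eligible types, zero otherwise; the
#' negative-binomial option adds overdispersion at the same mean. Nuclear
#' counts are a binomial draw from each cell's total.
#'
#' @param cells A [cell_table()] (counts are replaced).
#' @param truth Ground-truth `data.frame` from [generate_tissue()].
#' @param gene_models Gene model `data.frame` ([default_gene_models()]).
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param nb_size Negative-binomial size parameter.
#' @param nuclear_fraction Binomial nuclear probability.
#' @param rate_cap Upper bound on the expected count; rates above it are
#'   capped with a warning.
#' @param seed Integer seed.
#' @return The `cell_table` with counts and `nuclear_count` filled in.
#' @export
generate_expression <- function(cells, truth, gene_models,
                                noise = "poisson", nb_size = 10,
                                nuclear_fraction = 0.5, rate_cap = 1e4,
                                seed = 1L) {
  stopifnot(nrow(truth) == n_cells(cells),
            all(truth$cell_id == cells$meta$cell_id))
  set.seed(seed)
  nc <- n_cells(cells)
  type <- cells$meta$cell_type
  counts <- matrix(0L, nrow(gene_models), nc,
                   dimnames = list(gene_models$gene, cells$meta$cell_id))
  capped <- FALSE
  for (g in seq_len(nrow(gene_models))) {
    gm <- gene_models[g, ]
    if (!is.finite(gm$b0)) next
    eligible <- if (is.na(gm$types)) rep(TRUE, nc)
                else type %in% strsplit(gm$types, ",")[[1]]
    if (!any(eligible)) next
    eta <- gm$b0 + gm$b_cv * truth$true_cv[eligible] +
      gm$b_epi * truth$true_epi_norm[eligible] +
      gm$b_long * truth$true_long[eligible]
    rate <- exp(eta)
    if (any(rate > rate_cap)) { rate <- pmin(rate, rate_cap); capped <- TRUE }
    draws <- if (noise == "poisson") rpois(sum(eligible), rate)
             else rnbinom(sum(eligible), size = nb_size, mu = rate)
    counts[g, eligible] <- draws
  }
  if (capped) warning("some expected counts exceeded rate_cap; capped")
  total <- colSums(counts)
  meta <- cells$meta
  meta$nuclear_count <- rbinom(nc, total, nuclear_fraction)
  cell_table(counts, meta)
}

#' Define a pooled-perturbation barcode design
#'
#' Each sgRNA is optically encoded by a pseudogene barcode carrying 7 or 8
#' hybridization sites for one low-expression landing gene of the panel;
#' landing genes must be unique across sgRNAs.
#'
#' @param sgrna Character vector of sgRNA names.
#' @param landing_gene Landing (pseudogene channel) gene per sgRNA.
#' @param sites Integer 7 or 8 per sgRNA.
#' @param role `"control"` or `"experimental"` per sgRNA.
#' @return `data.frame` of class `barcode_design`.
#' @export
barcode_design <- function(sgrna, landing_gene, sites, role) {
  if (anyDuplicated(landing_gene))
    stop("landing genes must be unique across sgRNAs")
  if (!all(sites %in% c(7L, 8L))) stop("sites must be 7 or 8")
  structure(data.frame(sgrna = sgrna, landing_gene = landing_gene,
                       sites = as.integer(sites), role = role,
                       stringsAsFactors = FALSE),
            class = c("barcode_design", "data.frame"))
}

#' The default three-guide design
#'
#' Two control guides (sgCd19, sgThy1) and one experimental guide
#' (sgCxcr3), landing on the three least-expressed panel genes.
#' @return A [barcode_design()].
#' @export
default_barcode_design <- function() {
  barcode_design(sgrna = c("sgCd19", "sgThy1", "sgCxcr3"),
                 landing_gene = c("Muc5ac", "Neurog3", "Fer1l6"),
                 sites = c(7L, 8L, 7L),
                 role = c("control", "control", "experimental"))
}

#' Inject perturbation barcode counts into a synthetic sample
#'
#' A fraction of CD8 T cells is assigned one sgRNA each; the corresponding
#' landing-gene channel receives `1 + Poisson(sites * per_site_rate)`
#' counts, so every perturbed cell is barcode-positive by construction. A
#' configurable fraction of goblet cells receives spurious counts of the
#' contaminant landing gene (bleed-over scenario). Optionally, cells of a
#' given sgRNA are repositioned into an upper villus band (known-direction
#' displacement for gate-enrichment tests); their axis truth is
#' recomputed and, when `gene_models` is supplied, their gradient-gene
#' counts are redrawn at the new position.
#'
#' @param cells A [cell_table()] with counts (after
#'   [generate_expression()]).
#' @param truth Ground-truth `data.frame` (updated and returned).
#' @param design A [barcode_design()].
#' @param fraction Named per-sgRNA fractions of the eligible CD8 T cells
#'   to perturb (default 0.2 each for the default design).
#' @param contamination_rate Fraction of goblet cells receiving spurious
#'   counts of `contaminant_gene`.
#' @param contaminant_gene Landing gene affected by bleed-over (default
#'   `"Fer1l6"`).
#' @param per_site_rate Expected extra barcode counts per hybridization
#'   site.
#' @param target_type Cell type eligible for perturbation.
#' @param shift Optional named list sgRNA -> `c(lo, hi)` band of the
#'   crypt-villus axis into which that guide's cells are resampled.
#' @param gene_models Optional gene models used to redraw counts of
#'   shifted cells.
#' @param seed Integer seed.
#' @return List `cells` (updated `cell_table`) and `truth` (updated, with
#'   `perturbation` labels filled and `contaminated` flag column added).
#' @export
inject_perturbation_barcodes <- function(cells, truth, design,
                                         fraction = NULL,
                                         contamination_rate = 0.05,
                                         contaminant_gene = "Fer1l6",
                                         per_site_rate = 0.3,
                                         target_type = "cd8_t",
                                         shift = NULL, gene_models = NULL,
                                         seed = 1L) {
  stopifnot(inherits(design, "barcode_design"))
  missing_genes <- setdiff(design$landing_gene, rownames(cells$counts))
  if (length(missing_genes))
    stop("landing gene(s) absent from panel: ",
         paste(missing_genes, collapse = ", "))
  set.seed(seed)
  if (is.null(fraction))
    fraction <- stats::setNames(rep(0.2, nrow(design)), design$sgrna)
  counts <- as.matrix(cells$counts)
  meta <- cells$meta
  truth$contaminated <- FALSE

  eligible <- which(meta$cell_type == target_type)
  eligible <- eligible[sample.int(length(eligible))]  # random order
  taken <- 0
  for (i in seq_len(nrow(design))) {
    sg <- design$sgrna[i]
    n_sg <- round(fraction[[sg]] * length(eligible))
    if (n_sg == 0) next
    pick <- eligible[seq(taken + 1, min(taken + n_sg, length(eligible)))]
    taken <- taken + length(pick)
    truth$perturbation[pick] <- sg
    lam <- design$sites[i] * per_site_rate
    counts[design$landing_gene[i], pick] <- 1L + rpois(length(pick), lam)
  }

  # positional displacement with known direction
  if (!is.null(shift)) {
    outlines <- attr(truth, "outlines")
    dims <- attr(truth, "dims")
    for (sg in names(shift)) {
      band <- shift[[sg]]
      idx <- which(!is.na(truth$perturbation) & truth$perturbation == sg)
      if (!length(idx)) next
      H <- dims[["height"]]
      new_cv <- runif(length(idx), band[1], band[2])
      meta$y[idx] <- new_cv * H
      # keep x inside the (narrower) villus at the new height
      v <- truth$villus_id[idx]
      xc <- (v - 0.5) * dims[["width"]]
      hw <- 0.42 * dims[["width"]] * sqrt(pmax(1 - new_cv^2, 0)) * 0.85
      meta$x[idx] <- xc + runif(length(idx), -1, 1) * hw
      truth$true_cv[idx] <- new_cv
      if (!is.null(outlines)) {
        pts <- cbind(meta$x[idx], meta$y[idx])
        d <- vapply(seq_along(idx), function(j)
          point_to_points_min_dist(pts[j, , drop = FALSE],
                                   outlines[[v[j]]]), numeric(1))
        truth$true_epi[idx] <- d
      }
      truth$true_long[idx] <- meta$x[idx] / dims[["total_length"]]
      if (!is.null(gene_models)) {
        # redraw axis-dependent genes at the new position
        grad <- gene_models[is.finite(gene_models$b0) &
                              (gene_models$b_cv != 0 |
                                 gene_models$b_epi != 0 |
                                 gene_models$b_long != 0), ]
        rng <- range(truth$true_epi)
        epi_norm <- (truth$true_epi[idx] - rng[1]) / diff(rng)
        for (g in seq_len(nrow(grad))) {
          gm <- grad[g, ]
          elig <- if (is.na(gm$types)) rep(TRUE, length(idx))
                  else meta$cell_type[idx] %in% strsplit(gm$types, ",")[[1]]
          if (!any(elig)) next
          rate <- exp(gm$b0 + gm$b_cv * truth$true_cv[idx][elig] +
                        gm$b_epi * epi_norm[elig] +
                        gm$b_long * truth$true_long[idx][elig])
          counts[gm$gene, idx[elig]] <- rpois(sum(elig), rate)
        }
      }
    }
  }

  # goblet bleed-over contamination
  goblet <- which(meta$cell_type == "goblet")
  n_cont <- round(contamination_rate * length(goblet))
  if (n_cont > 0) {
    pick <- sample(goblet, n_cont)
    counts[contaminant_gene, pick] <-
      counts[contaminant_gene, pick] + 1L + rpois(n_cont, per_site_rate)
    truth$contaminated[pick] <- TRUE
  }
  list(cells = cell_table(counts, meta), truth = truth)
}

#' Generate a complete synthetic sample
#'
#' Orchestrates [generate_tissue()], [generate_expression()] and (if a
#' design is given) [inject_perturbation_barcodes()] under a single
#' configuration, deriving stage seeds from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param design Optional [barcode_design()]; `NULL` skips perturbation.
#' @param sample_id,replicate_id Labels stamped into the cell metadata.
#' @param ... Passed to [inject_perturbation_barcodes()].
#' @return List `bundle` (complete [sample_bundle()]) and `truth`.
#' @export
generate_sample <- function(config, design = NULL,
                            sample_id = "synthetic", replicate_id = "R1",
                            ...) {
  tis <- generate_tissue(config)
  cells <- generate_expression(tis$bundle$cells, tis$truth,
                               config$gene_models, noise = config$noise,
                               nb_size = config$nb_size,
                               nuclear_fraction = config$nuclear_fraction,
                               seed = config$seed + 1L)
  truth <- tis$truth
  if (!is.null(design)) {
    inj <- inject_perturbation_barcodes(cells, truth, design,
                                        seed = config$seed + 2L, ...)
    cells <- inj$cells
    truth <- inj$truth
  }
  cells$meta$sample_id <- sample_id
  cells$meta$replicate_id <- replicate_id
  bundle <- sample_bundle(tis$bundle$transcripts, cells,
                          tis$bundle$annotations,
                          tis$bundle$villus_labels)
  list(bundle = bundle, truth = truth)
}
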