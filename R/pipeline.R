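# End-to-end pipeline over a synthetic (or loaded) sample: simulate ->
# qc -> axes -> imap -> gradients -> proximity -> perturb, every stage
# writing plain-text artifacts and the configuration snapshot alongside.

#' Default pipeline configuration
#'
#' All numeric defaults are the package-wide reference values: QC
#' thresholds 8/20/800, neighbourhood k = 10 with 15 factors, smoothing
#' over 150 neighbours, epithelial-axis k = 5/5 with clip at +3, rho
#' threshold 0.05, interaction threshold 0.1, marker sum >= 3, at most 1
#' Muc2 transcript, KS cutoff 0.08.
#'
#' @param seed Global seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c(qc = TRUE, axes = TRUE, imap = TRUE, gradients = TRUE,
               proximity = TRUE, perturb = TRUE),
    qc = list(min_nuclear = 8L, min_total = 20L, max_total = 800L),
    axes = list(k_neighborhood = 10L, n_factors = 15L,
                smoothing_k = 150L, k_epi = 5L, k_any = 5L,
                clip_upper = 3,
                epithelial_types = c("enterocyte", "goblet",
                                     "progenitor")),
    imap = list(w = 0.5, gates = NULL),
    gradients = list(min_fraction = 0.05, rho_threshold = 0.05,
                     subset_type = "cd8_t"),
    proximity = list(graph_method = "knn", graph_param = 6L,
                     interaction_threshold = 0.1, ks_cutoff = 0.08),
    perturb = list(marker_genes = c("Cd8a", "Cd8b1", "Cd3e"),
                   marker_min = 3L, contaminant = "Muc2",
                   contaminant_max = 1L,
                   required_clusters = "cd8_t"))
}

#' Default IMAP gates for the synthetic tissue
#'
#' Three rectangular gates in IMAP coordinates (display-rescaled
#' crypt-villus on x): villus top, crypt, and muscularis.
#' @return A [gate_set()].
#' @export
default_gates <- function() {
  gate_set(list(
    top = cbind(c(0.70, 1.01, 1.01, 0.70), c(-3, -3, 3, 3)),
    crypt = cbind(c(0.25, 0.70, 0.70, 0.25), c(-3, -3, 3, 3)),
    muscularis = cbind(c(-0.01, 0.25, 0.25, -0.01), c(-3, -3, 3, 3))))
}

#' Run the full pipeline on a sample bundle
#'
#' Stages run in dependency order; each failure halts with an error named
#' after the stage. Outputs (CSV tables plus a YAML config snapshot and a
#' log) land in `out_dir`. With the same seed and configuration the
#' numeric outputs are byte-identical across runs.
#'
#' @param bundle A [sample_bundle()] (e.g. from [generate_sample()]).
#' @param config Configuration from [default_config()].
#' @param out_dir Output directory, created if needed; `NULL` skips
#'   writing.
#' @param design Optional [barcode_design()] for the perturb stage.
#' @return Named list of per-stage results (also written to `out_dir`).
#' @export
run_pipeline <- function(bundle, config = default_config(),
                         out_dir = NULL, design = NULL) {
  t0 <- Sys.time()
  log_lines <- character()
  note <- function(...) {
    line <- sprintf("[%.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    paste0(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    if (!isTRUE(config$stages[[name]])) return(NULL)
    note("stage ", name, " start")
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    note("stage ", name, " done")
    res
  }
  results <- list()
  emit <- function(name, df) {
    if (!is.null(out_dir))
      write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                row.names = FALSE)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cells <- bundle$cells
  results$qc <- stage("qc", {
    filtered <- qc_filter_cells(cells, config$qc$min_nuclear,
                                config$qc$min_total, config$qc$max_total)
    note("qc kept ", n_cells(filtered), " of ", n_cells(cells), " cells")
    filtered
  })
  if (!is.null(results$qc)) cells <- results$qc
  work <- sample_bundle(bundle$transcripts, cells, bundle$annotations,
                        bundle$villus_labels)

  results$axes <- stage("axes", {
    ax <- compute_axes(work,
                       epithelial_types = config$axes$epithelial_types,
                       clip_upper = config$axes$clip_upper)
    emit("axes", ax)
    ax
  })
  ax <- results$axes

  results$imap <- stage("imap", {
    coords <- imap_coordinates(ax, w = config$imap$w)
    gates <- if (is.null(config$imap$gates)) default_gates()
             else config$imap$gates
    labels <- assign_gates(coords, gates)
    coords$gate <- labels
    emit("imap", coords)
    stats <- gate_statistics(cells, labels)
    emit("gate_counts", stats$counts)
    list(coords = coords, gates = gates, labels = labels,
         stats = stats)
  })

  results$gradients <- stage("gradients", {
    sub_idx <- cells$meta$cell_type == config$gradients$subset_type
    sub <- subset_cells(cells, sub_idx)
    genes <- expression_fraction_filter(sub, config$gradients$min_fraction)
    screen <- axis_correlation_screen(
      sub,
      axes = list(crypt_villus = ax$crypt_villus[sub_idx],
                  epithelial = ax$epithelial[sub_idx],
                  longitudinal = ax$longitudinal[sub_idx]),
      genes = genes, threshold = config$gradients$rho_threshold)
    emit("gradients", screen)
    screen
  })

  results$proximity <- stage("proximity", {
    g <- spatial_neighbor_graph(cells, config$proximity$graph_method,
                                config$proximity$graph_param)
    inter <- interaction_scores(
      g, threshold = config$proximity$interaction_threshold)
    tab <- data.frame(type_a = rep(rownames(inter$raw),
                                   ncol(inter$raw)),
                      type_b = rep(colnames(inter$raw),
                                   each = nrow(inter$raw)),
                      raw = as.vector(inter$raw),
                      max_norm = as.vector(inter$max_norm),
                      row_norm = as.vector(inter$row_norm))
    emit("interactions", tab)
    dist_tab <- nearest_type_distances(cells)
    emit("distances", dist_tab)
    list(graph = g, interactions = inter, distances = dist_tab)
  })

  results$perturb <- stage("perturb", {
    if (is.null(design)) {
      note("no barcode design supplied; perturb stage skipped")
      NULL
    } else {
      calls <- call_perturbed_cells(
        cells, design,
        marker_genes = config$perturb$marker_genes,
        marker_min = config$perturb$marker_min,
        contaminant = config$perturb$contaminant,
        contaminant_max = config$perturb$contaminant_max,
        required_clusters = config$perturb$required_clusters)
      emit("perturb_calls", calls)
      calls
    }
  })

  if (!is.null(out_dir)) {
    cfg <- config
    cfg$imap$gates <- NULL  # polygons snapshotted separately
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  results$log <- log_lines
  results
}
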