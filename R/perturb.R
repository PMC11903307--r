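# Decoding pooled optically encoded CRISPR perturbations. Each sgRNA is
# read out through a pseudogene barcode landing on a low-expression panel
# gene; a cell is called perturbed only when four criteria hold: a CD8
# marker sum at or above threshold, at least one barcode detected,
# membership in a CD8 T cell cluster, and at most one contaminant (Muc2)
# transcript -- the last guarding against goblet-cell bleed-over of the
# Fer1l6 channel.

#' Read barcode channel counts and make tentative sgRNA assignments
#'
#' Counts are taken from the cell-by-gene matrix for each design channel.
#' The tentative sgRNA is the strictly maximal channel with count >= 1;
#' ties across channels give `"ambiguous"`, all-zero gives `"none"`.
#'
#' @param cells A [cell_table()].
#' @param design A [barcode_design()]; all landing genes must be in the
#'   panel.
#' @return `data.frame`: `cell_id`, one count column per sgRNA,
#'   `barcode_total`, `tentative_sgrna`.
#' @export
detect_barcodes <- function(cells, design) {
  stopifnot(inherits(design, "barcode_design"))
  missing <- setdiff(design$landing_gene, rownames(cells$counts))
  if (length(missing))
    stop("landing gene(s) absent from panel: ",
         paste(missing, collapse = ", "))
  ch <- t(as.matrix(cells$counts[design$landing_gene, , drop = FALSE]))
  colnames(ch) <- design$sgrna
  top <- apply(ch, 1, max)
  n_top <- rowSums(ch == top & top > 0)
  tentative <- ifelse(top == 0, "none",
                      ifelse(n_top > 1, "ambiguous",
                             design$sgrna[apply(ch, 1, which.max)]))
  out <- data.frame(cell_id = cells$meta$cell_id, ch,
                    barcode_total = rowSums(ch),
                    tentative_sgrna = tentative, row.names = NULL)
  out
}

#' Call perturbed cells by the four-criterion filter
#'
#' A cell is called perturbed iff (i) the sum of raw counts over the
#' marker genes is at least `marker_min`, (ii) at least one barcode is
#' detected, (iii) its cluster is in `required_clusters`, and (iv) its
#' contaminant-gene count is at most `contaminant_max`. The assigned
#' sgRNA comes from [detect_barcodes()]; called cells with an ambiguous
#' dominant channel keep the `"ambiguous"` label.
#'
#' @param cells A [cell_table()] with `cluster` metadata.
#' @param design A [barcode_design()].
#' @param marker_genes CD8 identity markers (default Cd8a, Cd8b1, Cd3e;
#'   raw counts).
#' @param marker_min Minimum marker sum (default 3).
#' @param contaminant Contaminant gene (default `"Muc2"`).
#' @param contaminant_max Maximum tolerated contaminant count (default 1).
#' @param required_clusters Cluster labels accepted as CD8 T cell
#'   clusters.
#' @return `data.frame` of class `perturb_calls`: `cell_id`, per-channel
#'   counts, `marker_sum`, `muc2` (contaminant count), diagnostics
#'   `pass_markers`, `pass_barcode`, `pass_cluster`, `pass_contaminant`,
#'   `called` (all four), and `sgrna` (assigned label, `NA` when not
#'   called).
#' @export
call_perturbed_cells <- function(cells, design,
                                 marker_genes = c("Cd8a", "Cd8b1", "Cd3e"),
                                 marker_min = 3L,
                                 contaminant = "Muc2",
                                 contaminant_max = 1L,
                                 required_clusters) {
  if (is.null(cells$meta$cluster)) stop("cluster labels are required")
  missing <- setdiff(c(marker_genes, contaminant), rownames(cells$counts))
  if (length(missing))
    stop("gene(s) absent from panel: ", paste(missing, collapse = ", "))
  bc <- detect_barcodes(cells, design)
  marker_sum <- Matrix::colSums(cells$counts[marker_genes, , drop = FALSE])
  muc2 <- as.numeric(cells$counts[contaminant, ])
  pass_markers <- marker_sum >= marker_min
  pass_barcode <- bc$barcode_total >= 1
  pass_cluster <- cells$meta$cluster %in% required_clusters
  pass_contaminant <- muc2 <= contaminant_max
  called <- pass_markers & pass_barcode & pass_cluster & pass_contaminant
  if (!any(called)) warning("no cell passes the perturbation filter")
  out <- data.frame(bc[, setdiff(names(bc), "tentative_sgrna")],
                    marker_sum = as.numeric(marker_sum), muc2 = muc2,
                    pass_markers = pass_markers,
                    pass_barcode = pass_barcode,
                    pass_cluster = pass_cluster,
                    pass_contaminant = pass_contaminant,
                    called = called,
                    sgrna = ifelse(called, bc$tentative_sgrna,
                                   NA_character_),
                    row.names = NULL)
  class(out) <- c("perturb_calls", "data.frame")
  out
}

#' Pairwise differential expression between perturbation groups
#'
#' Welch two-sided t-tests per gene on log-normalized expression for every
#' pair of perturbation groups, Benjamini-Hochberg adjusted within each
#' pairwise comparison, with significance tiers at 0.05 / 0.01 / 0.001.
#' Genes with zero variance in both groups get p = 1.
#'
#' @param cells A [cell_table()].
#' @param calls A `perturb_calls` frame from [call_perturbed_cells()] (or
#'   any frame with `called` and `sgrna`).
#' @param genes Genes to test (default all panel genes).
#' @param min_cells Minimum group size (default 3).
#' @return `data.frame`: `group_a`, `group_b`, `gene`, `mean_a`, `mean_b`,
#'   `t`, `p`, `p_adj`, `tier` (`""`, `"*"`, `"**"`, `"***"`).
#' @export
perturbation_de <- function(cells, calls, genes = NULL, min_cells = 3L) {
  stopifnot(nrow(calls) == n_cells(cells))
  if (is.null(genes)) genes <- rownames(cells$counts)
  groups <- sort(unique(calls$sgrna[calls$called &
                                      !is.na(calls$sgrna) &
                                      calls$sgrna != "ambiguous"]))
  if (length(groups) < 2) stop("need at least 2 perturbation groups")
  ln <- log_normalize(cells$counts)[genes, , drop = FALSE]
  out <- list()
  for (i in seq_len(length(groups) - 1)) {
    for (j in seq(i + 1, length(groups))) {
      ga <- groups[i]; gb <- groups[j]
      ia <- which(calls$called & calls$sgrna == ga)
      ib <- which(calls$called & calls$sgrna == gb)
      if (length(ia) < min_cells || length(ib) < min_cells) next
      res <- t(vapply(genes, function(g) {
        xa <- ln[g, ia]; xb <- ln[g, ib]
        if (sd(xa) == 0 && sd(xb) == 0)
          return(c(mean_a = mean(xa), mean_b = mean(xb), t = 0, p = 1))
        tt <- t.test(xa, xb)  # Welch, two-sided
        c(mean_a = mean(xa), mean_b = mean(xb),
          t = unname(tt$statistic), p = tt$p.value)
      }, numeric(4)))
      p_adj <- p.adjust(res[, "p"], "BH")
      out[[paste(ga, gb)]] <- data.frame(
        group_a = ga, group_b = gb, gene = genes,
        mean_a = res[, "mean_a"], mean_b = res[, "mean_b"],
        t = res[, "t"], p = res[, "p"], p_adj = p_adj,
        tier = cut(p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "")),
        row.names = NULL)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gate-stratified perturbation statistics
#'
#' Runs [perturbation_de()] within each spatial gate (comparisons with a
#' group under `min_cells` are skipped and reported) and computes the
#' barcode-uniformity diagnostic: the Spearman correlation between the
#' detected barcode count of called cells and their crypt-villus axis
#' value, expected near zero when barcode detection is spatially unbiased.
#'
#' @param cells A [cell_table()].
#' @param calls Output of [call_perturbed_cells()].
#' @param gate_labels Per-cell gate labels from [assign_gates()].
#' @param cv_axis Per-cell crypt-villus axis values (for the uniformity
#'   diagnostic).
#' @param genes Genes to test.
#' @param min_cells Minimum per-group size within a gate.
#' @return List: `by_gate` (named list of DE tables), `skipped`
#'   (`data.frame` of gate/reason), `uniformity_rho`.
#' @export
gate_stratified_de <- function(cells, calls, gate_labels, cv_axis,
                               genes = NULL, min_cells = 3L) {
  stopifnot(length(gate_labels) == n_cells(cells),
            length(cv_axis) == n_cells(cells))
  by_gate <- list()
  skipped <- data.frame(gate = character(), reason = character())
  for (g in setdiff(unique(gate_labels), "none")) {
    idx <- which(gate_labels == g)
    sub_cells <- subset_cells(cells, idx)
    sub_calls <- calls[idx, , drop = FALSE]
    tab <- table(sub_calls$sgrna[sub_calls$called])
    if (sum(tab >= min_cells) < 2) {
      skipped <- rbind(skipped, data.frame(
        gate = g, reason = "fewer than 2 groups with enough cells"))
      next
    }
    by_gate[[g]] <- perturbation_de(sub_cells, sub_calls, genes,
                                    min_cells)
  }
  called <- which(calls$called)
  uniformity <- if (length(called) >= 3 &&
                      sd(calls$barcode_total[called]) > 0)
    cor(rank(calls$barcode_total[called]), rank(cv_axis[called]))
  else NA_real_
  list(by_gate = by_gate, skipped = skipped,
       uniformity_rho = uniformity)
}
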