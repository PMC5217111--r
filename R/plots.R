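# Diagnostic plots. Kept deliberately simple: PCA score plot, sample
# distance heat map, and per-gene trajectory lines.

#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_tile geom_text
#'   labs scale_fill_viridis_c theme_minimal
NULL

#' Plot time-point PCA scores
#'
#' PC1 versus PC2 score plot, points labeled and colored by sampling time.
#'
#' @param object An `oxytime_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oxytime_pca <- function(object, ...) {
  vf <- round(100 * object$variance_fraction[1:2], 1)
  ggplot(object$scores,
         aes(x = .data$PC1, y = .data$PC2, color = .data$time_minutes)) +
    geom_point(size = 3) +
    geom_text(aes(label = .data$sample_id), vjust = -1, show.legend = FALSE) +
    labs(x = paste0("PC1 (", vf[1], "%)"), y = paste0("PC2 (", vf[2], "%)"),
         color = "time (min)") +
    theme_minimal()
}

#' Heat map of pairwise sample distances
#'
#' @param dmat Symmetric distance matrix from
#'   [euclidean_distance_matrix()].
#' @return A ggplot.
#' @export
plot_sample_distances <- function(dmat) {
  df <- as_tibble(dmat, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b",
                        values_to = "distance")
  lev <- rownames(dmat)
  df$sample_a <- factor(df$sample_a, levels = lev)
  df$sample_b <- factor(df$sample_b, levels = lev)
  ggplot(df, aes(x = .data$sample_a, y = .data$sample_b,
                 fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "distance") +
    theme_minimal()
}

#' Plot expression trajectories for selected genes
#'
#' Log2 expression relative to the t = 0 sample, one line per gene.
#'
#' @param counts Floored normalized count tibble.
#' @param samples Sample sheet (first time must be 0).
#' @param genes Character vector of gene ids to display.
#' @return A ggplot.
#' @export
plot_gene_trajectories <- function(counts, samples, genes) {
  ratios <- log2_ratio_to_t0(counts, samples)
  unknown <- setdiff(genes, ratios$gene_id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown gene id(s): ", paste(unknown, collapse = ", ")))
  }
  df <- ratios[ratios$gene_id %in% genes, ] |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "log2_ratio") |>
    left_join(samples, by = "sample_id")
  ggplot(df, aes(x = .data$time_minutes, y = .data$log2_ratio,
                 color = .data$gene_id)) +
    geom_line() +
    geom_point() +
    labs(x = "time (min)", y = "log2 fold change vs t = 0", color = NULL) +
    theme_minimal()
}
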