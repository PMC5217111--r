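# End-to-end orchestration: preprocess -> AutoCor + NB trend scans ->
# gate/BH/call -> set arithmetic -> global structure -> optional ESR
# comparison, with a manifest recording every decision in effect so
# published-number comparisons are auditable.

#' Build a pipeline configuration
#'
#' Defaults mirror the study's stated thresholds: floor 20, fold-change
#' gate 2, BH significance at adjusted p <= 0.05, exhaustive permutation
#' mode for 8 time points.
#'
#' @param counts Count tibble or path to a matrix TSV
#'   ([read_matrix_tsv()]).
#' @param samples Sample sheet tibble; ignored when `counts` is a path
#'   (the sidecar is used).
#' @param out_dir Output directory for the report bundle.
#' @param floor Floor value (default 20).
#' @param min_fold_change Fold-change gate (default 2).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @param autocor_mode `"exhaustive"` or `"montecarlo"`.
#' @param autocor_B Monte-Carlo sample size.
#' @param seed Integer seed (Monte-Carlo sampling and any other
#'   randomness).
#' @param universe_size Universe size for expected random overlaps; `NULL`
#'   means "use the number of genes surviving preprocessing", recorded in
#'   the manifest.
#' @param pca_input `"log2_ratio"` or `"log2_counts"`.
#' @param family_ids Optional gene ids to remove as a confounded family.
#' @param esr Optional ESR table (tibble or TSV path) for the overlap
#'   report.
#' @param cluster_max_genes Cap on genes entering UPGMA clustering
#'   (largest fold changes kept), default 2000.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, samples = NULL, out_dir,
                            floor = 20, min_fold_change = 2, alpha = 0.05,
                            autocor_mode = "exhaustive", autocor_B = 1e5,
                            seed = 1L, universe_size = NULL,
                            pca_input = "log2_ratio", family_ids = NULL,
                            esr = NULL, cluster_max_genes = 2000L) {
  structure(list(counts = counts, samples = samples, out_dir = out_dir,
                 floor = floor, min_fold_change = min_fold_change,
                 alpha = alpha, autocor_mode = autocor_mode,
                 autocor_B = autocor_B, seed = seed,
                 universe_size = universe_size, pca_input = pca_input,
                 family_ids = family_ids, esr = esr,
                 cluster_max_genes = cluster_max_genes),
            class = "pipeline_config")
}

#' Run the full time-course analysis pipeline
#'
#' Executes preprocessing, both time-dependence tests, per-method BH
#' calling within the fold-change-gated subset, method combination and
#' Venn arithmetic, PCA, sample distances, UPGMA clustering of the called
#' genes, and (optionally) the ESR overlap. Writes a report bundle to
#' `config$out_dir`; two runs with identical config and seed produce
#' byte-identical files.
#'
#' Files written: `results_autocor.tsv`, `results_nbtrend.tsv`,
#' `calls.tsv`, `venn.json`, `pca_scores.tsv`, `pca_variance.tsv`,
#' `sample_distances.tsv`, `dendrogram.newick`, optionally
#' `esr_overlap.json`, and `manifest.json`.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list with all in-memory results (`preprocess`,
#'   `autocor`, `nbtrend`, `calls`, `venn`, `pca`, `distances`, `cluster`,
#'   `esr_overlap`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(config$counts)) {
    loaded <- read_matrix_tsv(config$counts)
    counts <- loaded$counts
    samples <- loaded$samples
  } else {
    counts <- config$counts
    samples <- config$samples
  }
  set.seed(config$seed)

  pre <- preprocess_counts(counts, samples, family_ids = config$family_ids,
                           floor = config$floor,
                           min_fc = config$min_fold_change)

  ac <- autocor_scan(pre$floored, mode = config$autocor_mode,
                     B = config$autocor_B, seed = config$seed)
  ac$method <- "autocor"
  nb <- nb_trend_scan(pre$raw, pre$samples, scale_factors = pre$scale_factors)
  nb$method <- "nbtrend"

  ac_adj <- gate_and_adjust(select(ac, "gene_id", "p_raw", "method"),
                            pre$fold_changes,
                            min_fc = config$min_fold_change,
                            alpha = config$alpha)
  nb_adj <- gate_and_adjust(select(nb, "gene_id", "p_raw", "method"),
                            pre$fold_changes,
                            min_fc = config$min_fold_change,
                            alpha = config$alpha)
  set_ac <- call_significant(ac_adj, alpha = config$alpha,
                             min_fc = config$min_fold_change)
  set_nb <- call_significant(nb_adj, alpha = config$alpha,
                             min_fc = config$min_fold_change)
  combined <- combine_methods(set_ac, set_nb)
  universe <- config$universe_size %||% nrow(pre$floored)
  vn <- venn(set_ac, set_nb, universe)

  pca <- pca_timepoints(pre$floored, pre$samples, input = config$pca_input)
  dmat <- euclidean_distance_matrix(pre$floored, pre$samples,
                                    input = config$pca_input)

  cluster_genes <- combined
  if (length(cluster_genes) > config$cluster_max_genes) {
    fc <- pre$fold_changes
    fc <- fc[fc$gene_id %in% cluster_genes, ]
    fc <- fc[order(-fc$max_fold_change, fc$gene_id), ]
    cluster_genes <- sort(fc$gene_id[seq_len(config$cluster_max_genes)])
  }
  hc <- NULL
  if (length(cluster_genes) >= 2L) {
    ratios <- log2_ratio_to_t0(pre$floored, pre$samples)
    hc <- average_linkage_cluster(
      ratios[match(cluster_genes, ratios$gene_id), ],
      metric = "uncentered")
  }

  esr_overlap <- NULL
  if (!is.null(config$esr)) {
    esr_tab <- if (is.character(config$esr)) read_esr_table(config$esr) else config$esr
    esr_set <- classify_esr(esr_tab)
    restricted <- intersect(combined, esr_tab$gene_id)
    esr_overlap <- overlap_with_esr(restricted, esr_set, nrow(esr_tab))
  }

  manifest <- list(
    package = "oxytime",
    version = as.character(utils::packageVersion("oxytime")),
    seed = config$seed,
    thresholds = list(floor = config$floor,
                      min_fold_change = config$min_fold_change,
                      alpha = config$alpha),
    universe_size = universe,
    genes_after_qc = nrow(pre$floored),
    genes_gated = length(pre$gated_genes),
    removed_zero = pre$removed_zero,
    removed_family = pre$removed_family,
    decisions = list(
      flooring_order = "normalize_then_floor",
      normalization_target = "mean_of_sample_totals",
      fold_change = "max_over_min_across_all_timepoints",
      pca_input = config$pca_input,
      autocor_identity_permutation_counted = TRUE,
      autocor_tie_tolerance = "1e-9 relative to permutation-invariant denominator",
      autocor_constant_series_p = 1,
      dispersion = "pooled moment estimates smoothed by alpha(mu) = a0 + a1/mu",
      upgma_tie_break = "lexicographically smallest member pair",
      bh = "per method within the fold-change-gated subset"
    )
  )

  # report bundle
  out <- function(f) file.path(config$out_dir, f)
  readr::write_tsv(ac, out("results_autocor.tsv"))
  readr::write_tsv(nb, out("results_nbtrend.tsv"))
  calls <- tibble(gene_id = combined,
                  autocor = combined %in% set_ac,
                  nbtrend = combined %in% set_nb)
  readr::write_tsv(calls, out("calls.tsv"))
  jsonlite::write_json(as.list(vn), out("venn.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(pca$scores, out("pca_scores.tsv"))
  readr::write_tsv(tidy(pca, "variance"), out("pca_variance.tsv"))
  readr::write_tsv(as_tibble(dmat, rownames = "sample_id"),
                   out("sample_distances.tsv"))
  if (!is.null(hc) && requireNamespace("ape", quietly = TRUE)) {
    write_dendrogram_newick(hc, out("dendrogram.newick"))
  }
  if (!is.null(esr_overlap)) {
    jsonlite::write_json(as.list(esr_overlap), out("esr_overlap.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(preprocess = pre, autocor = ac_adj, nbtrend = nb_adj,
                 calls = calls, autocor_set = set_ac, nbtrend_set = set_nb,
                 combined_set = combined, venn = vn, pca = pca,
                 distances = dmat, cluster = hc, esr_overlap = esr_overlap,
                 manifest = manifest))
}
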