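#' Remove genes with zero counts in every sample
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @return List with `counts` (filtered tibble) and `removed` (number of
#'   all-zero gene rows dropped).
#' @export
remove_zero_genes <- function(counts) {
  vals <- count_values(counts)
  keep <- rowSums(vals) > 0
  list(counts = counts[keep, , drop = FALSE], removed = sum(!keep))
}

#' Remove a gene family by explicit id list or id prefix
#'
#' Used to drop families whose near-identical sequences confound read
#' assignment (for the yeast seripauperin family, the 24 *PAU* genes).
#' Requested ids that are absent produce a warning, not an error.
#'
#' @param counts Count tibble.
#' @param ids Character vector of gene ids to remove.
#' @param prefix Alternatively, remove every gene whose id starts with this
#'   prefix. Exactly one of `ids`, `prefix` must be given.
#' @return List with `counts` and `removed` (number of genes dropped).
#' @export
remove_gene_family <- function(counts, ids = NULL, prefix = NULL) {
  if (is.null(ids) == is.null(prefix)) {
    abort("supply exactly one of `ids` or `prefix`")
  }
  if (!is.null(prefix)) {
    drop <- startsWith(counts$gene_id, prefix)
  } else {
    missing <- setdiff(ids, counts$gene_id)
    if (length(missing) > 0L) {
      warn(paste0("gene ids not present in matrix: ",
                  paste(missing, collapse = ", ")))
    }
    drop <- counts$gene_id %in% ids
  }
  list(counts = counts[!drop, , drop = FALSE], removed = sum(drop))
}

#' Per-sample total-count scale factors
#'
#' Factors that equalize the per-sample totals of reads mapping to annotated
#' features: `mean(totals) / total_s` for sample `s`. The mean target keeps
#' normalized values on the raw-count scale; any common target gives the
#' same fold changes.
#'
#' @param counts Count tibble.
#' @return Named numeric vector of positive scale factors, one per sample.
#' @export
sample_scale_factors <- function(counts) {
  totals <- colSums(count_values(counts))
  if (any(totals <= 0)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(names(totals)[totals <= 0], collapse = ", ")))
  }
  mean(totals) / totals
}

#' Total-count normalization
#'
#' Rescales each sample so the total number of reads mapping to annotated
#' features is equal across samples (to the mean of the observed totals).
#'
#' @param counts Count tibble.
#' @return The normalized tibble (same shape; values are reals).
#' @export
total_count_normalize <- function(counts) {
  sf <- sample_scale_factors(counts)
  for (nm in names(sf)) counts[[nm]] <- counts[[nm]] * sf[[nm]]
  counts
}

#' Floor all values at a reliability threshold
#'
#' Counts below the floor are set to the floor (default 20, where the
#' coefficient of variation across time points becomes untrustworthy for
#' low-expression genes). Idempotent and monotone in the floor.
#'
#' @param counts Count tibble (normally normalized first).
#' @param floor Positive floor value, default 20.
#' @return Floored tibble with attribute `"floor"` recording the threshold.
#' @export
floor_values <- function(counts, floor = 20) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  for (nm in setdiff(names(counts), "gene_id")) {
    counts[[nm]] <- pmax(counts[[nm]], floor)
  }
  attr(counts, "floor") <- floor
  counts
}

#' Maximum fold change of one expression series
#'
#' Ratio of the largest to the smallest value over the whole time course
#' (not relative to t = 0). Requires strictly positive values, which
#' flooring guarantees.
#'
#' @param x Numeric vector of positive values in time order.
#' @return `max(x) / min(x)`, a number `>= 1`.
#' @export
max_fold_change <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("max_fold_change needs strictly positive finite values (floor first)")
  }
  max(x) / min(x)
}

#' Per-gene maximum fold changes
#'
#' @param counts Floored count tibble.
#' @return Tibble with columns `gene_id`, `max_fold_change`.
#' @export
gene_fold_changes <- function(counts) {
  vals <- count_values(counts)
  if (any(vals <= 0)) {
    abort("fold changes need strictly positive values (floor first)")
  }
  tibble(gene_id = counts$gene_id,
         max_fold_change = apply(vals, 1L, max) / apply(vals, 1L, min))
}

#' Genes passing the maximum-fold-change gate
#'
#' @param counts Floored count tibble.
#' @param min_fc Inclusive threshold on the maximum fold change, default 2.
#' @return Character vector of gene ids with `max_fold_change >= min_fc`.
#' @export
fold_change_filter <- function(counts, min_fc = 2) {
  fc <- gene_fold_changes(counts)
  fc$gene_id[fc$max_fold_change >= min_fc]
}

#' Log2 expression ratios relative to the time-0 sample
#'
#' @param counts Floored count tibble whose first sample column is the
#'   aerobic t = 0 sample.
#' @param samples Sample sheet; its first (earliest) time must be 0.
#' @return Tibble of the same shape with values `log2(value_t / value_0)`;
#'   the t = 0 column is identically zero.
#' @export
log2_ratio_to_t0 <- function(counts, samples) {
  samples <- validate_sample_sheet(samples)
  samples <- arrange(samples, .data$time_minutes)
  if (samples$time_minutes[1L] != 0) {
    abort("first sample must be at time 0 for t0-relative ratios")
  }
  validate_count_matrix(counts, samples)
  vals <- count_values(counts)
  if (any(vals <= 0)) {
    abort("log2 ratios need strictly positive values (floor first)")
  }
  ratios <- log2(vals / vals[, 1L])
  bind_cols(tibble(gene_id = counts$gene_id), as_tibble(ratios))
}

#' Run the full quality-control and normalization chain
#'
#' Applies, in order: removal of genes with zero counts in all samples,
#' optional removal of a confounded gene family, total-count normalization,
#' and flooring. Fold changes are computed from the floored normalized
#' values. The order (normalize, then floor) reflects that the floor is a
#' reliability threshold on the normalized count scale.
#'
#' @param counts Raw count tibble.
#' @param samples Sample sheet.
#' @param family_ids Optional character vector of gene ids to remove (e.g.
#'   the 24 *PAU* genes).
#' @param floor Floor value, default 20.
#' @param min_fc Fold-change gate for `gated_genes`, default 2.
#' @return A list: `raw` (counts after gene removals), `normalized`,
#'   `floored`, `samples`, `scale_factors`, `fold_changes` (tibble),
#'   `gated_genes` (ids with fold change >= `min_fc`), `removed_zero`,
#'   `removed_family`.
#' @export
preprocess_counts <- function(counts, samples, family_ids = NULL,
                              floor = 20, min_fc = 2) {
  samples <- validate_sample_sheet(samples)
  samples <- arrange(samples, .data$time_minutes)
  validate_count_matrix(counts, samples)
  z <- remove_zero_genes(counts)
  if (!is.null(family_ids)) {
    fam <- remove_gene_family(z$counts, ids = family_ids)
  } else {
    fam <- list(counts = z$counts, removed = 0L)
  }
  sf <- sample_scale_factors(fam$counts)
  normalized <- total_count_normalize(fam$counts)
  floored <- floor_values(normalized, floor = floor)
  fc <- gene_fold_changes(floored)
  list(
    raw = fam$counts,
    normalized = normalized,
    floored = floored,
    samples = samples,
    scale_factors = sf,
    fold_changes = fc,
    gated_genes = fc$gene_id[fc$max_fold_change >= min_fc],
    removed_zero = z$removed,
    removed_family = fam$removed
  )
}
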