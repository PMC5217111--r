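# Environmental stress response (ESR) membership and overlap with the
# oxygen-regulated set. Membership rule: a gene is ESR if it was called by
# the original stress-response compendium, or if it changed more than
# twofold (|log2| > 1, strict) in 10 or more (inclusive) of the 13 stress
# treatments. Missing treatment measurements count as not changed, which
# biases against membership (conservative).

#' Read an ESR response table
#'
#' Expected TSV layout: `gene_id`, `original_call` (0/1), then up to 13
#' numeric log2-response columns; empty cells are missing data.
#'
#' @param path Path to the TSV.
#' @return Tibble with `original_call` as logical.
#' @export
read_esr_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "original_call") %in% names(tab))) {
    abort("ESR table needs columns gene_id, original_call")
  }
  tab$original_call <- as.logical(tab$original_call)
  tab
}

#' Classify genes as ESR members
#'
#' @param esr Tibble: `gene_id`, `original_call` (logical or 0/1), then at
#'   most 13 numeric log2-response columns (one per treatment; `NA` =
#'   missing).
#' @return Sorted character vector of ESR member gene ids.
#' @export
classify_esr <- function(esr) {
  treat_cols <- setdiff(names(esr), c("gene_id", "original_call"))
  if (length(treat_cols) > 13L) {
    abort(paste0("at most 13 treatment columns expected, got ",
                 length(treat_cols)))
  }
  resp <- as.matrix(esr[treat_cols])
  if (length(treat_cols) > 0L && !is.numeric(resp)) {
    abort("treatment columns must be numeric log2 responses")
  }
  changed <- if (length(treat_cols) > 0L) {
    rowSums(abs(resp) > 1, na.rm = TRUE)
  } else {
    rep(0L, nrow(esr))
  }
  member <- as.logical(esr$original_call) | changed >= 10L
  sort(esr$gene_id[member])
}

#' Overlap between the oxygen-regulated set and the ESR
#'
#' The oxygen-regulated set must first be restricted to genes examined in
#' the ESR study (the common universe); counts computed on the restricted
#' universe equal those computed after intersecting both sets with it.
#'
#' @param oxygen_set Character vector of oxygen-regulated gene ids,
#'   restricted to the ESR study universe.
#' @param esr_set Character vector of ESR member gene ids.
#' @param universe_size Size of the common universe (explicit input).
#' @return One-row tibble as in [venn()]; `both` is the observed overlap
#'   and `expected_both` the random expectation. Whether the observed
#'   overlap exceeds or falls short of expectation is a report field, not
#'   an assertion.
#' @export
overlap_with_esr <- function(oxygen_set, esr_set, universe_size) {
  venn(oxygen_set, esr_set, universe_size)
}
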