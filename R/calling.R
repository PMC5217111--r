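#' Benjamini-Hochberg step-up adjustment
#'
#' Classical FDR step-up: sort the m raw p-values ascending, set
#' `adj_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and return in input
#' order. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order; `adj >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Gate on fold change, then adjust within the gated subset
#'
#' The study design: only genes with a maximum fold change of at least
#' `min_fc` over the course enter multiple-testing correction, and BH is
#' applied per method within that subset. Ungated genes keep `p_adj = NA`
#' and are never significant.
#'
#' @param results Per-gene test results: tibble with `gene_id`, `p_raw`,
#'   and a single-valued `method` column.
#' @param fold_changes Tibble with `gene_id`, `max_fold_change`
#'   ([gene_fold_changes()]).
#' @param min_fc Inclusive fold-change gate, default 2.
#' @param alpha Significance level on adjusted p, default 0.05 (inclusive).
#' @return `results` with columns `max_fold_change`, `p_adj`,
#'   `significant` appended.
#' @export
gate_and_adjust <- function(results, fold_changes, min_fc = 2, alpha = 0.05) {
  if (length(unique(results$method)) > 1L) {
    abort("adjust within one method at a time")
  }
  res <- left_join(results, fold_changes, by = "gene_id")
  if (any(is.na(res$max_fold_change))) {
    abort("fold change missing for some tested genes")
  }
  gated <- !is.na(res$p_raw) & res$max_fold_change >= min_fc
  res$p_adj <- NA_real_
  res$p_adj[gated] <- bh_adjust(res$p_raw[gated])
  res$significant <- gated & res$p_adj <= alpha
  res$significant[is.na(res$significant)] <- FALSE
  res
}

#' Call significant genes from adjusted results
#'
#' A gene is called when `p_adj <= alpha` (inclusive at the boundary) and
#' its maximum fold change is at least `min_fc`.
#'
#' @param results Tibble with `gene_id`, `p_adj`, `max_fold_change`, and a
#'   single-valued `method` column.
#' @inheritParams gate_and_adjust
#' @return Sorted character vector of called gene ids.
#' @export
call_significant <- function(results, alpha = 0.05, min_fc = 2) {
  if (nrow(results) == 0L) return(character())
  if (length(unique(results$method)) > 1L) {
    abort("call within one method at a time (adjustment is per method)")
  }
  keep <- !is.na(results$p_adj) & results$p_adj <= alpha &
    results$max_fold_change >= min_fc
  sort(results$gene_id[keep])
}

#' Venn partition of two gene sets with expected random overlap
#'
#' Counts the exclusive and shared members of two sets drawn from a common
#' universe, plus the overlap expected if both sets were uniform random
#' draws of their observed sizes: `|A| * |B| / N`.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_size Size `N` of the common universe; must be supplied
#'   explicitly and be at least as large as either set.
#' @return One-row tibble: `only_a`, `only_b`, `both`, `union`,
#'   `expected_both`.
#' @export
venn <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (universe_size < max(length(set_a), length(set_b))) {
    abort("universe smaller than one of the sets")
  }
  both <- length(intersect(set_a, set_b))
  tibble(
    only_a = length(set_a) - both,
    only_b = length(set_b) - both,
    both = both,
    union = length(union(set_a, set_b)),
    expected_both = length(set_a) * length(set_b) / universe_size
  )
}

#' Union of the gene sets called by the two detection methods
#'
#' @param autocor_set,nbtrend_set Character vectors of called gene ids from
#'   the same universe.
#' @return Sorted character vector (deterministic ordering).
#' @export
combine_methods <- function(autocor_set, nbtrend_set) {
  sort(union(autocor_set, nbtrend_set))
}
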