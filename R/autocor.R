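# AutoCor: exhaustive permutation test on the lag-1 autocorrelation of a
# short expression time series. For n = 8 time points the test compares the
# observed series against all 40,320 orderings; the p-value is the
# proportion of orderings (the original included) whose autocorrelation is
# at least the observed one.

.autocor_cache <- new.env(parent = emptyenv())

EXHAUSTIVE_LIMIT <- 10L

#' Lag-1 sample autocorrelation
#'
#' The textbook biased-denominator estimator
#' `r1 = sum_{t=1}^{n-1} (x_t - xbar)(x_{t+1} - xbar) / sum_t (x_t - xbar)^2`.
#' Invariant under affine maps `a*x + b` (a > 0) and under reversal of the
#' series. For a permutation test only the numerator matters: the multiset
#' of values, hence the mean and denominator, is permutation-invariant.
#'
#' @param x Numeric vector, length >= 3.
#' @return `r1` in `[-1, 1]`, or `NA_real_` for a constant (zero-variance)
#'   series, where the statistic is undefined.
#' @export
lag1_autocorrelation <- function(x) {
  n <- length(x)
  if (n < 3L) abort("lag-1 autocorrelation needs n >= 3")
  if (any(!is.finite(x))) abort("series must be finite")
  c0 <- x - mean(x)
  den <- sum(c0^2)
  if (den == 0) return(NA_real_)
  sum(c0[-n] * c0[-1L]) / den
}

#' Enumerate all orderings of n elements
#'
#' Exhaustive mode of the permutation test; each ordering appears exactly
#' once and the identity is included. Beyond `n = 10` (10! ~ 3.6 million)
#' exhaustive enumeration is refused and Monte-Carlo sampling
#' ([montecarlo_autocor_pvalue()]) should be used instead.
#'
#' @param n Series length, `3 <= n <= 10`.
#' @return List with `n_permutations` (`n!`) and `orderings` (an
#'   `n! x n` integer matrix, one ordering per row).
#' @export
enumerate_permutations <- function(n) {
  n <- as.integer(n)
  if (n < 3L) abort("exhaustive enumeration needs n >= 3")
  if (n > EXHAUSTIVE_LIMIT) {
    abort(paste0("n = ", n, " exceeds the exhaustive limit (", EXHAUSTIVE_LIMIT,
                 "); use Monte-Carlo mode (montecarlo_autocor_pvalue)"))
  }
  list(n_permutations = factorial(n), orderings = all_orderings(n))
}

all_orderings <- function(n) {
  key <- paste0("perm", n)
  if (!is.null(.autocor_cache[[key]])) return(.autocor_cache[[key]])
  out <- matrix(1L, 1L, 1L)
  if (n > 1L) {
    for (k in 2L:n) {
      m <- nrow(out)
      nxt <- matrix(0L, m * k, k)
      for (pos in seq_len(k)) {
        rows <- ((pos - 1L) * m + 1L):(pos * m)
        nxt[rows, pos] <- k
        nxt[rows, -pos] <- out
      }
      out <- nxt
    }
  }
  .autocor_cache[[key]] <- out
  out
}

# Adjacency-pair-count representation of the permutation space: for each
# ordering, how many adjacent positions hold each unordered value pair
# {i, j}. The lag-1 numerator of a centered series c under an ordering is
# then the inner product of these counts with the pair products c_i * c_j,
# turning a per-gene sweep over n! orderings into one matrix product.
adjacency_counts <- function(n) {
  key <- paste0("adj", n)
  if (!is.null(.autocor_cache[[key]])) return(.autocor_cache[[key]])
  P <- all_orderings(n)
  A <- P[, -n, drop = FALSE]
  B <- P[, -1L, drop = FALSE]
  code <- (pmin(A, B) - 1L) * n + pmax(A, B)
  codes <- sort(unique(as.vector(code)))
  M <- matrix(0, nrow(P), length(codes))
  for (k in seq_along(codes)) M[, k] <- rowSums(code == codes[k])
  pairs <- cbind((codes - 1L) %/% n + 1L, (codes - 1L) %% n + 1L)
  res <- list(M = M, pairs = pairs)
  .autocor_cache[[key]] <- res
  res
}

# Exhaustive one-sided p-values for centered series in the columns of X
# (n x G). Ties at machine precision count as >= (tolerance 1e-9 relative
# to the permutation-invariant denominator). Returns r1, p, and the
# numerators used.
exhaustive_pvalues_centered <- function(X, chunk = 200L) {
  n <- nrow(X)
  G <- ncol(X)
  adj <- adjacency_counts(n)
  nperm <- nrow(adj$M)
  den <- colSums(X^2)
  obs <- colSums(X[-1L, , drop = FALSE] * X[-n, , drop = FALSE])
  r1 <- ifelse(den > 0, obs / den, NA_real_)
  p <- rep(1, G)
  live <- which(den > 0)
  tol <- 1e-9 * den
  if (length(live) == 0L) {
    return(list(r1 = r1, p = p, n_permutations = nperm))
  }
  for (start in seq(1L, length(live), by = chunk)) {
    idx <- live[start:min(start + chunk - 1L, length(live))]
    V <- X[adj$pairs[, 1L], idx, drop = FALSE] *
      X[adj$pairs[, 2L], idx, drop = FALSE]
    S <- adj$M %*% V
    ge <- sweep(S, 2L, obs[idx] - tol[idx], ">=")
    p[idx] <- colSums(ge) / nperm
  }
  list(r1 = r1, p = p, n_permutations = nperm)
}

#' Exhaustive permutation p-value for time-dependence of one series
#'
#' One-sided p-value: the proportion of all `n!` orderings of the series
#' whose lag-1 autocorrelation is greater than or equal to the observed one.
#' The identity ordering is part of the enumeration, so `p >= 1/n!`. A
#' constant series carries no evidence of time structure and returns
#' `p = 1` with an undefined (`NA`) statistic.
#'
#' @param x Numeric vector (a gene's normalized counts in time order),
#'   `3 <= length(x) <= 10`.
#' @return One-row tibble: `r1`, `p_raw`, `n_permutations`, `method`
#'   (`"exhaustive"`).
#' @export
exhaustive_autocor_pvalue <- function(x) {
  n <- length(x)
  if (n < 3L) abort("need n >= 3")
  if (n > EXHAUSTIVE_LIMIT) {
    abort(paste0("n = ", n, " exceeds the exhaustive limit; ",
                 "use montecarlo_autocor_pvalue()"))
  }
  if (any(!is.finite(x))) abort("series must be finite")
  res <- exhaustive_pvalues_centered(matrix(x - mean(x), ncol = 1L))
  tibble(r1 = res$r1, p_raw = res$p,
         n_permutations = res$n_permutations, method = "exhaustive")
}

#' Monte-Carlo permutation p-value for time-dependence
#'
#' Samples `B` random orderings and applies the add-one correction
#' `p = (1 + #{r1(permuted) >= r1(observed)}) / (B + 1)`, which keeps the
#' p-value valid and strictly positive. Used when the series is too long
#' for exhaustive enumeration.
#'
#' @param x Numeric vector, length >= 3.
#' @param B Number of sampled orderings, at least 100.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return One-row tibble: `r1`, `p_raw`, `n_permutations` (`B`), `method`
#'   (`"montecarlo"`).
#' @export
montecarlo_autocor_pvalue <- function(x, B = 1e5, seed = 1L) {
  n <- length(x)
  if (n < 3L) abort("need n >= 3")
  if (any(!is.finite(x))) abort("series must be finite")
  B <- as.integer(B)
  if (B < 100L) abort("B must be at least 100")
  c0 <- x - mean(x)
  den <- sum(c0^2)
  if (den == 0) {
    return(tibble(r1 = NA_real_, p_raw = 1, n_permutations = B,
                  method = "montecarlo"))
  }
  obs <- sum(c0[-n] * c0[-1L])
  tol <- 1e-9 * den
  set.seed(seed)
  idx <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
  Xp <- matrix(c0[idx], n, B)
  num <- colSums(Xp[-n, , drop = FALSE] * Xp[-1L, , drop = FALSE])
  tibble(r1 = obs / den, p_raw = (1 + sum(num >= obs - tol)) / (B + 1),
         n_permutations = B, method = "montecarlo")
}

#' Permutation autocorrelation test across a count matrix
#'
#' Runs the AutoCor test gene by gene on normalized (and typically floored)
#' count values in their original time order. With 8 time points the test
#' is exhaustive over all 40,320 orderings.
#'
#' @param counts Normalized count tibble (`gene_id` + time-ordered sample
#'   columns).
#' @param genes Optional character vector restricting the scan; must be a
#'   subset of `counts$gene_id`. Default: all genes.
#' @param mode `"exhaustive"` (series length <= 10) or `"montecarlo"`.
#' @param B Monte-Carlo sample size (only for `mode = "montecarlo"`).
#' @param seed Monte-Carlo seed.
#' @return Tibble with one row per requested gene, in input order:
#'   `gene_id`, `r1`, `p_raw`, `n_permutations`, `method`.
#' @export
autocor_scan <- function(counts, genes = NULL,
                         mode = c("exhaustive", "montecarlo"),
                         B = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  vals <- count_values(counts)
  if (is.null(genes)) genes <- counts$gene_id
  unknown <- setdiff(genes, counts$gene_id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5L), collapse = ", ")))
  }
  if (length(genes) == 0L) {
    return(tibble(gene_id = character(), r1 = double(), p_raw = double(),
                  n_permutations = double(), method = character()))
  }
  X <- t(vals[genes, , drop = FALSE])
  if (mode == "exhaustive") {
    if (nrow(X) > EXHAUSTIVE_LIMIT) {
      abort("series too long for exhaustive mode; use mode = 'montecarlo'")
    }
    X <- sweep(X, 2L, colMeans(X))
    res <- exhaustive_pvalues_centered(X)
    tibble(gene_id = genes, r1 = res$r1, p_raw = res$p,
           n_permutations = res$n_permutations, method = "exhaustive")
  } else {
    rows <- map(seq_along(genes), function(i) {
      montecarlo_autocor_pvalue(X[, i], B = B, seed = seed + i - 1L)
    })
    bind_cols(tibble(gene_id = genes), list_rbind(rows))
  }
}
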