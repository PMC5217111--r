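# Independent oracles and fixture builders. Each oracle is implemented from
# the definition, by a different route than the package code it checks.

# all orderings of 1..n by simple position-insertion recursion (independent
# of the package's enumerator)
naive_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- naive_permutations(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# lag-1 autocorrelation via stats::acf (biased-denominator convention)
acf_r1 <- function(x) {
  as.numeric(stats::acf(x, lag.max = 1, plot = FALSE, demean = TRUE)$acf[2L])
}

# brute-force exhaustive one-sided p: enumerate every ordering, recompute the
# full statistic each time; ties at machine precision count as >=
naive_autocor_p <- function(x) {
  n <- length(x)
  c0 <- x - mean(x)
  den <- sum(c0^2)
  if (den == 0) return(1)
  obs <- acf_r1(x)
  perms <- naive_permutations(n)
  hits <- vapply(perms, function(idx) acf_r1(x[idx]) >= obs - 1e-9, logical(1))
  sum(hits) / length(perms)
}

# BH step-up from the definition: adj_(i) = min_{j >= i} p_(j) * m / j, cap 1
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min((m / (i:m)) * ps[i:m]))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# direct maximization of the NB log-likelihood at fixed dispersion
optim_nb_fit <- function(y, X, offsets, alpha) {
  negll <- function(beta) {
    mu <- pmax(exp(drop(X %*% beta) + offsets), 1e-8)
    if (alpha < 1e-12) {
      -sum(stats::dpois(y, mu, log = TRUE))
    } else {
      -sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
    }
  }
  start <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1L))
  fit <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(beta = fit$par, log_likelihood = -fit$value)
}

# brute-force UPGMA keeping explicit member lists; inter-cluster distance is
# the arithmetic mean over all cross pairs of the ORIGINAL distances
brute_force_upgma_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best) {
          best <- dd
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# count tibble + sample sheet from a genes x times matrix
make_counts <- function(mat, times, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(nrow(mat)))
  ids <- paste0("t", times)
  colnames(mat) <- ids
  list(
    counts = dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                              tibble::as_tibble(mat)),
    samples = tibble::tibble(sample_id = ids, time_minutes = times)
  )
}

HYPOXIA_TIMES <- c(0, 5, 10, 30, 60, 120, 180, 240)

# flat-only truth table for null simulations
flat_truth <- function(n, mu0, alpha) {
  tibble::tibble(
    gene_id = sprintf("null%05d", seq_len(n)), class = "flat",
    mu0 = mu0, fold = 1, direction = "up",
    k = NA_real_, t50 = NA_real_, t_peak = NA_real_, width = NA_real_,
    t_step = NA_real_, alpha = alpha
  )
}
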