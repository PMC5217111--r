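# Quadratic-versus-intercept negative-binomial likelihood-ratio test.
# Full model: log mu = b0 + b1*(t/tmax) + b2*(t/tmax)^2 (+ offset);
# reduced model: log mu = b0 (+ offset). Dispersion is estimated by pooling
# all time points as pseudo-replicates (the design has one replicate per
# time point), then smoothed across genes expressed at similar levels via
# the trend alpha(mu) = a0 + a1/mu.

#' Full and reduced design matrices for the time-course LRT
#'
#' Time is rescaled to `[0, 1]` by its maximum purely for numerical
#' conditioning; the likelihood-ratio statistic is invariant to the
#' rescaling and the quadratic coefficients are reported on the rescaled
#' basis.
#'
#' @param times Numeric vector of sampling times (minutes) with at least 4
#'   distinct values (the full model has 3 parameters).
#' @return List with `times`, `t_max`, `full` (n x 3 matrix: intercept,
#'   `t/t_max`, `(t/t_max)^2`) and `reduced` (n x 1 intercept column).
#' @export
build_designs <- function(times) {
  if (length(unique(times)) < 4L) {
    abort("need >= 4 distinct times to fit a quadratic against an intercept")
  }
  if (any(!is.finite(times)) || any(times < 0)) abort("times must be finite, >= 0")
  t_max <- max(times)
  ts <- times / t_max
  full <- cbind(intercept = 1, t = ts, t2 = ts^2)
  reduced <- cbind(intercept = rep(1, length(times)))
  list(times = times, t_max = t_max, full = full, reduced = reduced)
}

#' Method-of-moments dispersion from pooled time points
#'
#' Treats all time points of one gene as replicates:
#' `alpha_hat = max(0, (s^2 - m) / m^2)` with `m` the sample mean and `s^2`
#' the sample variance. Genes with genuine time trends receive inflated
#' estimates (trend variance is counted as dispersion); the cross-gene
#' trend fit partially corrects this.
#'
#' @param x Positive normalized counts for one gene across time points.
#' @return Nonnegative `alpha_hat`.
#' @export
estimate_dispersion_mom <- function(x) {
  m <- mean(x)
  if (m <= 0) return(0)
  max(0, (var(x) - m) / m^2)
}

#' Fit the mean-dispersion trend alpha(mu) = a0 + a1/mu across genes
#'
#' Ordinary least squares of the gene-wise moment estimates on `1/mean`,
#' restricted to genes with a positive estimate; predictions are clamped at
#' `alpha_min`. With fewer than 20 positive estimates the trend degenerates
#' to the median positive estimate (or `alpha_min` if there is none).
#'
#' @param gene_means Per-gene mean normalized counts.
#' @param alpha_hats Per-gene moment estimates ([estimate_dispersion_mom()]).
#' @param alpha_min Lower clamp for predicted dispersions, default 1e-8.
#' @return List with coefficients `a0`, `a1`, the number of genes used
#'   (`n_used`), and `alpha_fun(mu)` giving the clamped working dispersion.
#' @export
fit_dispersion_trend <- function(gene_means, alpha_hats, alpha_min = 1e-8) {
  stopifnot(length(gene_means) == length(alpha_hats))
  pos <- which(alpha_hats > 0 & gene_means > 0)
  if (length(pos) < 20L) {
    a0 <- if (length(pos) > 0L) median(alpha_hats[pos]) else alpha_min
    a1 <- 0
  } else {
    fit <- lm(a ~ inv_mu, data = data.frame(a = alpha_hats[pos],
                                            inv_mu = 1 / gene_means[pos]))
    a0 <- unname(coef(fit)[1L])
    a1 <- unname(coef(fit)[2L])
  }
  force(alpha_min)
  list(a0 = a0, a1 = a1, n_used = length(pos),
       alpha_fun = function(mu) pmax(alpha_min, a0 + a1 / pmax(mu, 1e-12)))
}

# Negative-binomial log-likelihood at fixed dispersion alpha
# (variance mu + alpha*mu^2; alpha ~ 0 is Poisson).
nb_loglik <- function(y, mu, alpha) {
  mu <- pmax(mu, 1e-8)
  if (alpha < 1e-12) {
    sum(dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
}

#' Fit a negative-binomial GLM with log link at fixed dispersion
#'
#' IRLS fit of `mu_i = exp(design_i . beta + offset_i)` with variance
#' `mu_i + alpha * mu_i^2`. `alpha = 0` degenerates to Poisson regression.
#' Fitted means are floored at 1e-8 when evaluating the log-likelihood so
#' degenerate inputs (e.g. all-zero counts) stay finite; such fits are
#' flagged unconverged by the IRLS machinery.
#'
#' @param y Nonnegative integer counts.
#' @param design Design matrix (rows = observations), with intercept column.
#' @param offsets Per-observation offsets on the log scale (e.g.
#'   `-log(scale_factor)` so fitted means live on the raw-count scale).
#' @param alpha Fixed dispersion, `>= 0`.
#' @return List: `coefficients` (named), `alpha`, `log_likelihood`,
#'   `converged`, `iterations`, `fitted` (mean vector).
#' @export
fit_nb_glm <- function(y, design, offsets = rep(0, length(y)), alpha = 0) {
  if (!is.finite(alpha) || alpha < 0) abort("alpha must be finite and >= 0")
  stopifnot(all(is.finite(offsets)), all(y >= 0))
  fam <- if (alpha < 1e-12) poisson() else MASS::negative.binomial(theta = 1 / alpha)
  fit <- tryCatch(
    suppressWarnings(
      glm.fit(x = design, y = y, offset = offsets, family = fam,
              control = glm.control(epsilon = 1e-10, maxit = 100))
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    beta <- rep(NA_real_, ncol(design))
    names(beta) <- colnames(design)
    return(list(coefficients = beta, alpha = alpha,
                log_likelihood = NA_real_, converged = FALSE,
                iterations = 0L, fitted = rep(NA_real_, length(y))))
  }
  mu <- pmax(fit$fitted.values, 1e-8)
  # fits pinned at the mu floor (e.g. all-zero counts pushing beta0 toward
  # -Inf) are flagged even when IRLS reports convergence
  degenerate <- any(fit$fitted.values <= 1e-8) || isTRUE(fit$boundary)
  list(coefficients = coef(fit), alpha = alpha,
       log_likelihood = nb_loglik(y, mu, alpha),
       converged = isTRUE(fit$converged) && !degenerate,
       iterations = fit$iter, fitted = mu)
}

#' Likelihood-ratio test of nested count models
#'
#' `stat = max(0, 2 * (ll_full - ll_reduced))` referred to the upper tail
#' of the chi-squared distribution with `df` degrees of freedom (2 for
#' quadratic versus intercept). Nested models forbid `ll_full <
#' ll_reduced`; a deficit beyond tolerance marks an optimization failure.
#'
#' @param ll_full,ll_reduced Maximized log-likelihoods of the two fits.
#' @param df Degrees of freedom, default 2.
#' @return List: `lrt_stat`, `df`, `p_raw`, `ok` (FALSE when the full fit
#'   fell below the reduced fit by more than 1e-6).
#' @export
lrt_pvalue <- function(ll_full, ll_reduced, df = 2) {
  raw <- 2 * (ll_full - ll_reduced)
  ok <- is.finite(raw) && raw >= -1e-6
  stat <- max(0, raw)
  list(lrt_stat = stat, df = df,
       p_raw = pchisq(stat, df = df, lower.tail = FALSE), ok = ok)
}

#' Negative-binomial time-trend scan across a count matrix
#'
#' For each gene: working dispersion from the pooled moment estimator
#' smoothed by the cross-gene trend (or supplied directly), full and
#' reduced model fits on the raw counts with offsets `-log(scale_factor)`
#' (so fitted means live on the raw scale while coefficients describe the
#' normalized scale), and the chi-squared(2) likelihood-ratio p-value.
#' Individual gene failures are flagged, never fatal.
#'
#' @param counts Raw count tibble (after gene removals).
#' @param samples Sample sheet (times in minutes).
#' @param scale_factors Named per-sample scale factors
#'   ([sample_scale_factors()]); default recomputed from `counts`.
#' @param genes Optional subset of gene ids; default all.
#' @param dispersion Either `"trend"` (default: moment estimates on
#'   normalized counts, smoothed by [fit_dispersion_trend()]) or a numeric
#'   vector of known dispersions, named by gene id or aligned with `genes`.
#' @return Tibble: `gene_id`, `lrt_stat`, `df`, `p_raw`, `alpha`,
#'   `converged`.
#' @export
nb_trend_scan <- function(counts, samples, scale_factors = NULL,
                          genes = NULL, dispersion = "trend") {
  samples <- validate_sample_sheet(samples)
  samples <- arrange(samples, .data$time_minutes)
  validate_count_matrix(counts, samples)
  if (is.null(scale_factors)) scale_factors <- sample_scale_factors(counts)
  scale_factors <- scale_factors[samples$sample_id]
  if (is.null(genes)) genes <- counts$gene_id
  unknown <- setdiff(genes, counts$gene_id)
  if (length(unknown) > 0L) {
    abort(paste0("unknown gene id(s): ", paste(head(unknown, 5L), collapse = ", ")))
  }
  vals <- count_values(counts)
  norm <- sweep(vals, 2L, scale_factors, `*`)

  if (identical(dispersion, "trend")) {
    means <- rowMeans(norm)
    ahat <- apply(norm, 1L, estimate_dispersion_mom)
    trend <- fit_dispersion_trend(means, ahat)
    alpha <- trend$alpha_fun(means)[match(genes, counts$gene_id)]
  } else if (is.numeric(dispersion)) {
    alpha <- if (!is.null(names(dispersion))) {
      dispersion[genes]
    } else {
      stopifnot(length(dispersion) %in% c(1L, length(genes)))
      rep_len(dispersion, length(genes))
    }
    if (any(is.na(alpha))) abort("dispersion missing for some requested genes")
  } else {
    abort("`dispersion` must be \"trend\" or a numeric vector")
  }

  des <- build_designs(samples$time_minutes)
  offsets <- -log(scale_factors)
  rows <- map(seq_along(genes), function(i) {
    y <- vals[genes[i], ]
    a <- alpha[i]
    if (!is.finite(a) || a < 0) {
      return(tibble(gene_id = genes[i], lrt_stat = NA_real_, df = 2L,
                    p_raw = NA_real_, alpha = a, converged = FALSE))
    }
    full <- fit_nb_glm(y, des$full, offsets, a)
    red <- fit_nb_glm(y, des$reduced, offsets, a)
    if (!is.finite(full$log_likelihood) || !is.finite(red$log_likelihood)) {
      return(tibble(gene_id = genes[i], lrt_stat = NA_real_, df = 2L,
                    p_raw = NA_real_, alpha = a, converged = FALSE))
    }
    lrt <- lrt_pvalue(full$log_likelihood, red$log_likelihood, df = 2)
    tibble(gene_id = genes[i], lrt_stat = lrt$lrt_stat, df = 2L,
           p_raw = lrt$p_raw, alpha = a,
           converged = full$converged && red$converged && lrt$ok)
  })
  list_rbind(rows)
}
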