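test_that("design matrices rescale time to [0, 1] with the right rows", {
  des <- build_designs(HYPOXIA_TIMES)
  expect_equal(dim(des$full), c(8L, 3L))
  expect_equal(unname(des$full[1, ]), c(1, 0, 0))
  expect_equal(unname(des$full[8, ]), c(1, 1, 1))
  expect_equal(dim(des$reduced), c(8L, 1L))
  expect_true(all(des$full[, 1] == 1))
  expect_error(build_designs(c(0, 5)), "4 distinct")
  expect_error(build_designs(c(0, 5, 5, 5, 5)), "4 distinct")
})

test_that("moment dispersion estimator follows its closed form", {
  # m = 100, s^2 = 600 -> (600 - 100) / 100^2 = 0.05
  x <- c(70, 90, 100, 110, 130)
  x <- (x - mean(x)) * sqrt(600 / var(x)) + 100
  expect_equal(estimate_dispersion_mom(x), 0.05, tolerance = 1e-12)
  # Poisson-like: s^2 = m -> 0; constant -> 0
  y <- c(98, 100, 102)
  y <- (y - mean(y)) * sqrt(mean(y) / var(y)) + 100
  expect_equal(estimate_dispersion_mom(y), 0)
  expect_equal(estimate_dispersion_mom(rep(50, 8)), 0)
})

test_that("dispersion trend recovers constant and 1/mu-shaped truths", {
  set.seed(13)
  n <- 2000
  mu <- exp(runif(n, log(10), log(10000)))
  X <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 1 / 0.05), n, 8)
  ahat <- apply(X, 1, estimate_dispersion_mom)
  tr <- fit_dispersion_trend(rowMeans(X), ahat)
  expect_gt(tr$a0, 0.03)
  expect_lt(tr$a0, 0.07)
  # the 1/mu term contributes negligibly at large mu
  expect_lt(abs(tr$alpha_fun(10000) - tr$alpha_fun(1e6)), 0.01)

  # alpha(mu) = 0.01 + 2/mu recovered within 50% at 5000 genes
  n2 <- 5000
  mu2 <- exp(runif(n2, log(10), log(10000)))
  a2 <- 0.01 + 2 / mu2
  X2 <- matrix(rnbinom(n2 * 8, mu = rep(mu2, 8), size = rep(1 / a2, 8)), n2, 8)
  tr2 <- fit_dispersion_trend(rowMeans(X2), apply(X2, 1, estimate_dispersion_mom))
  expect_gt(tr2$a0, 0.005)
  expect_lt(tr2$a0, 0.015)
  expect_gt(tr2$a1, 1)
  expect_lt(tr2$a1, 3)

  # no positive estimates -> clamped constant fallback
  tr3 <- fit_dispersion_trend(c(10, 20, 30), c(0, 0, 0))
  expect_equal(tr3$alpha_fun(100), 1e-8)
})

test_that("NB GLM fit hits the intercept-model closed form and oracles", {
  set.seed(14)
  y <- rpois(8, 40)
  des <- build_designs(HYPOXIA_TIMES)
  o <- rep(0.3, 8)
  for (a in c(0, 0.1)) {
    fit <- fit_nb_glm(y, des$reduced, o, alpha = a)
    expect_true(fit$converged)
    # MLE of the intercept model is the sample mean, for any alpha
    expect_equal(unname(fit$coefficients[1]), log(mean(y)) - 0.3,
                 tolerance = 1e-8)
  }
  # alpha = 0 equals a Poisson regression oracle
  off <- -log(runif(8, 0.8, 1.25))
  pfit <- fit_nb_glm(y, des$full, off, alpha = 0)
  oracle <- stats::glm(y ~ des$full[, 2] + des$full[, 3] + offset(off),
                       family = poisson())
  expect_equal(unname(pfit$coefficients), unname(coef(oracle)),
               tolerance = 1e-6)
  expect_equal(pfit$log_likelihood, as.numeric(stats::logLik(oracle)),
               tolerance = 1e-6)
  # NB likelihood agrees with direct optimization
  yy <- rnbinom(8, mu = exp(3 + seq(0, 1, length.out = 8)), size = 10)
  nfit <- fit_nb_glm(yy, des$full, off, alpha = 0.1)
  ofit <- optim_nb_fit(yy, des$full, off, alpha = 0.1)
  expect_equal(nfit$log_likelihood, ofit$log_likelihood, tolerance = 1e-5)
})

test_that("degenerate all-zero counts are flagged, not fatal", {
  des <- build_designs(HYPOXIA_TIMES)
  fit <- fit_nb_glm(rep(0L, 8), des$reduced, rep(0, 8), alpha = 0.1)
  expect_false(fit$converged)
  expect_true(is.finite(fit$log_likelihood) || is.na(fit$log_likelihood))
})

test_that("LRT p-values match the chi-squared(2) closed form", {
  # for df = 2 the upper tail is exactly exp(-stat/2)
  expect_equal(lrt_pvalue(10, 10)$p_raw, 1)
  expect_equal(lrt_pvalue(10 + 5.991 / 2, 10)$p_raw, exp(-5.991 / 2),
               tolerance = 1e-12)
  expect_equal(round(lrt_pvalue(10 + 5.991 / 2, 10)$p_raw, 4), 0.05)
  expect_equal(round(lrt_pvalue(10 + 13.816 / 2, 10)$p_raw, 4), 0.001)
  # nested models forbid a negative statistic beyond tolerance
  bad <- lrt_pvalue(9, 10)
  expect_false(bad$ok)
  expect_equal(bad$lrt_stat, 0)
})

test_that("LRT is invariant to a common offset shift absorbed by beta0", {
  set.seed(15)
  des <- build_designs(HYPOXIA_TIMES)
  y <- rnbinom(8, mu = 50 * exp(seq(0, 1.5, length.out = 8)), size = 10)
  o1 <- rep(0, 8)
  o2 <- rep(1.7, 8)
  s1 <- lrt_pvalue(fit_nb_glm(y, des$full, o1, 0.1)$log_likelihood,
                   fit_nb_glm(y, des$reduced, o1, 0.1)$log_likelihood)
  s2 <- lrt_pvalue(fit_nb_glm(y, des$full, o2, 0.1)$log_likelihood,
                   fit_nb_glm(y, des$reduced, o2, 0.1)$log_likelihood)
  expect_equal(s1$lrt_stat, s2$lrt_stat, tolerance = 1e-6)
})

test_that("scan power increases with fold change (paired seeds)", {
  # trended genes sit in a flat background so total-count normalization
  # does not absorb their shared trend
  power_at <- function(fold) {
    smooth <- tibble::tibble(
      gene_id = sprintf("s%03d", 1:150), class = "smooth",
      mu0 = 100, fold = fold, direction = "up", k = 0.1, t50 = 45,
      t_peak = NA_real_, width = NA_real_, t_step = NA_real_, alpha = 0.05
    )
    truth <- dplyr::bind_rows(flat_truth(600, mu0 = 100, alpha = 0.05),
                              smooth)
    sim <- simulate_counts(truth, seed = 16)  # same seed: paired draws
    res <- nb_trend_scan(sim$counts, sim$samples, dispersion = 0.05,
                         genes = smooth$gene_id)
    mean(res$p_raw <= 0.05, na.rm = TRUE)
  }
  p2 <- power_at(2)
  p4 <- power_at(4)
  p8 <- power_at(8)
  expect_gte(p4, p2)
  expect_gte(p8, p2)
  expect_gt(p8, 0.5)
})

test_that("a single-time-point spike is caught by the LRT more than AutoCor", {
  # the rapid-induction pattern: flat except one extreme early value
  set.seed(17)
  n <- 80
  base <- matrix(rnbinom(n * 8, mu = 100, size = 1 / 0.02), n, 8)
  base[, 2] <- rnbinom(n, mu = 1600, size = 1 / 0.02)  # 16-fold at 5 min
  cm <- make_counts(base, HYPOXIA_TIMES)
  ac <- autocor_scan(floor_values(cm$counts))
  nb <- nb_trend_scan(cm$counts, cm$samples, dispersion = 0.02)
  expect_gt(mean(nb$p_raw <= 0.05, na.rm = TRUE),
            mean(ac$p_raw <= 0.05))
})

test_that("pooled dispersion is inflated for trended genes (documented caveat)", {
  set.seed(18)
  n <- 200
  flat <- matrix(rnbinom(n * 8, mu = 200, size = 1 / 0.05), n, 8)
  trended <- matrix(
    rnbinom(n * 8, mu = rep(200 * exp(seq(0, 2, length.out = 8)), each = n),
            size = 1 / 0.05), n, 8)
  a_flat <- apply(flat, 1, estimate_dispersion_mom)
  a_trend <- apply(trended, 1, estimate_dispersion_mom)
  expect_gt(mean(a_trend), mean(a_flat))
})

test_that("the scan survives pathological genes and validates ids", {
  set.seed(19)
  mat <- matrix(rpois(5 * 8, 60), 5, 8)
  mat[3, ] <- 0  # degenerate gene must be flagged, not fatal
  cm <- make_counts(mat, HYPOXIA_TIMES)
  res <- nb_trend_scan(cm$counts, cm$samples)
  expect_equal(nrow(res), 5L)
  expect_error(nb_trend_scan(cm$counts, cm$samples, genes = "zzz"),
               "unknown gene")
})
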