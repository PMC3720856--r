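test_that("an intercept-only fit reproduces the sample mean", {
  fit <- fit_species_glm(c(2L, 2L, 2L, 2L))
  expect_equal(unname(fit$fitted), rep(2, 4), tolerance = 1e-8)
  expect_identical(fit$family, "poisson")  # zero variance: fallback
})

test_that("the negative-binomial fit matches MASS::glm.nb", {
  set.seed(10)
  n <- 200
  x <- rnorm(n)
  mu <- exp(1 + 0.7 * x)
  y <- rnbinom(n, size = 1.5, mu = mu)
  ours <- fit_species_glm(y, data.frame(x = x), family = "negbin")
  ref <- MASS::glm.nb(y ~ x)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-4)
  expect_equal(ours$theta, ref$theta, tolerance = 1e-3)
  expect_equal(ours$loglik, as.numeric(stats::logLik(ref)),
               tolerance = 1e-5)
})

test_that("the dispersion fallback separates Poisson from overdispersed data", {
  ## equidispersed data: the dispersion estimate diverges past the cap in
  ## a substantial share of samples (about half; the boundary estimate
  ## theta = Inf has asymptotic probability 1/2 under a true Poisson)
  set.seed(2)
  fams <- replicate(60, {
    y <- rpois(60, 5)
    fit_species_glm(y, data.frame(x = rnorm(60)))$family
  })
  expect_gt(mean(fams == "poisson"), 0.4)
  ## strongly overdispersed data: never falls back
  set.seed(3)
  fams2 <- replicate(30, {
    y <- rnbinom(60, size = 1, mu = 5)
    fit_species_glm(y, data.frame(x = rnorm(60)))$family
  })
  expect_identical(unique(fams2), "negbin")
})

test_that("negative-binomial slope recovery is well calibrated", {
  set.seed(14)
  x <- rnorm(60)
  hits <- 0
  for (r in 1:100) {
    y <- rnbinom(60, size = 1, mu = exp(log(5) + 0.8 * x))
    fit <- fit_species_glm(y, data.frame(x = x))
    ref <- suppressWarnings(MASS::glm.nb(y ~ x))
    se <- sqrt(diag(stats::vcov(ref)))[2]
    if (abs(fit$coefficients[2] - 0.8) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

sim_counts <- function(n, K, beta = 0, seed = 1) {
  set.seed(seed)
  x <- rep(seq(-1, 1, length.out = 7), length.out = n)
  Y <- sapply(seq_len(K), function(k)
    rnbinom(n, size = 2, mu = exp(1.2 + beta * x)))
  colnames(Y) <- paste0("sp", seq_len(K))
  list(Y = Y, pred = data.frame(elevation = x))
}

test_that("a single species reduces to the univariate deviance", {
  d <- sim_counts(21, 1, beta = 1, seed = 5)
  fit <- multivariate_fit(d$Y, d$pred)
  tab <- anova_deviance_resampled(fit, n_resamples = 99, seed = 1)
  ## independent oracle: likelihood-ratio deviance at the same fixed
  ## dispersion via stats::glm with an NB family
  theta <- attr(tab, "theta")[1]
  y <- d$Y[, 1]
  if (is.finite(theta)) {
    full <- stats::glm(y ~ elevation, data = d$pred,
                       family = MASS::negative.binomial(theta))
    null <- stats::glm(y ~ 1, family = MASS::negative.binomial(theta))
  } else {
    full <- stats::glm(y ~ elevation, data = d$pred, family = poisson())
    null <- stats::glm(y ~ 1, family = poisson())
  }
  expect_equal(tab$deviance[1],
               stats::deviance(null) - stats::deviance(full),
               tolerance = 1e-6)
})

test_that("sequential deviance reductions telescope exactly", {
  set.seed(31)
  n <- 21
  pred <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- sapply(1:6, function(k)
    rnbinom(n, size = 2, mu = exp(1 + 0.5 * pred$a - 0.4 * pred$b)))
  colnames(Y) <- paste0("sp", 1:6)
  fit <- multivariate_fit(Y, pred)
  tab <- anova_deviance_resampled(fit, n_resamples = 99, seed = 2)
  dev <- attr(tab, "model_deviances")
  expect_equal(sum(tab$deviance), sum(dev[1, ]) - sum(dev[nrow(dev), ]),
               tolerance = 1e-8)
  ## percent partitioning
  aug <- percent_deviance(tab)
  expect_equal(sum(aug$pct_within_model), 100, tolerance = 1e-6)
  expect_true(all(aug$pct_model_total >= 0 & aug$pct_model_total <= 100))
})

test_that("species order does not change the multivariate statistic", {
  d <- sim_counts(21, 5, beta = 0.8, seed = 9)
  f1 <- multivariate_fit(d$Y, d$pred)
  f2 <- multivariate_fit(d$Y[, 5:1], d$pred)
  t1 <- anova_deviance_resampled(f1, n_resamples = 99, seed = 3)
  t2 <- anova_deviance_resampled(f2, n_resamples = 99, seed = 3)
  expect_equal(t1$deviance, t2$deviance, tolerance = 1e-8)
})

test_that("resampled analysis of deviance is deterministic per seed and detects effects", {
  d <- sim_counts(21, 6, beta = 1.5, seed = 13)
  fit <- multivariate_fit(d$Y, d$pred)
  t1 <- anova_deviance_resampled(fit, n_resamples = 199, seed = 4)
  t2 <- anova_deviance_resampled(fit, n_resamples = 199, seed = 4)
  expect_identical(t1$p_value, t2$p_value)
  expect_lte(t1$p_value[1], 0.01)
  ## row-permutation cross-check agrees on the decision
  t3 <- anova_deviance_resampled(fit, n_resamples = 199,
                                 method = "row-permutation", seed = 5)
  expect_lte(t3$p_value[1], 0.05)
  expect_error(anova_deviance_resampled(fit, n_resamples = 50),
               class = "invalid_argument")
})

test_that("all-zero species are dropped with a warning", {
  d <- sim_counts(21, 3, beta = 0, seed = 6)
  d$Y[, 2] <- 0L
  expect_warning(fit <- multivariate_fit(d$Y, d$pred), "all-zero")
  expect_length(fit$fits, 2)
  expect_error(suppressWarnings(
    multivariate_fit(matrix(0L, 10, 2,
                            dimnames = list(NULL, c("a", "b"))),
                     data.frame(x = rnorm(10)))),
    class = "invalid_argument")
})
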