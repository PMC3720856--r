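test_that("OLS recovers exact relationships and reports full-likelihood AIC", {
  x <- seq(-3, 3, length.out = 20)
  fit <- suppressWarnings(fit_ols(2 + 3 * x, data.frame(x = x)))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$coefficients$estimate[2], 3, tolerance = 1e-10)
  ## constant response: R^2 = 0, slope interval contains 0
  fit0 <- suppressWarnings(fit_ols(rep(5, 20), data.frame(x = x)))
  expect_equal(fit0$r_squared, 0)
  expect_true(fit0$coefficients$lwr[2] <= 0 &&
                fit0$coefficients$upr[2] >= 0)
  ## AIC identical to the standard Gaussian-likelihood value
  set.seed(3)
  y <- 1 + 2 * x + rnorm(20)
  fit2 <- fit_ols(y, data.frame(x = x))
  ref <- stats::AIC(lm(y ~ x))
  expect_equal(fit2$aic, ref, tolerance = 1e-10)
})

test_that("confidence intervals achieve near-nominal coverage", {
  set.seed(11)
  x <- runif(100)
  hits <- 0
  for (r in 1:100) {
    y <- 2 + 3 * x + rnorm(100, 0, 0.1)
    cf <- fit_ols(y, data.frame(x = x))$coefficients
    if (cf$lwr[2] <= 3 && cf$upr[2] >= 3) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("rank-deficient designs fail loudly, naming the culprit", {
  x <- rnorm(20)
  expect_error(fit_ols(rnorm(20), data.frame(a = x, b = 2 * x)),
               regexp = "b", class = "rank_deficient")
  expect_error(fit_ols(rnorm(3), data.frame(a = rnorm(3), b = rnorm(3))),
               class = "not_estimable")
})

test_that("candidate models are exactly the marginality-closed subsets", {
  expect_length(enumerate_candidate_models("a"), 2)
  two <- enumerate_candidate_models(c("a", "b"))
  expect_length(two, 5)
  keys <- vapply(two, function(m) paste(sort(m), collapse = "|"),
                 character(1))
  expect_setequal(keys, c("", "a", "b", "a|b", "a|a:b|b"))
  three <- enumerate_candidate_models(c("a", "b", "c"))
  expect_length(three, 19)
  ## independent construction oracle
  for (mains in list(c("a", "b"), c("a", "b", "c"))) {
    got <- vapply(enumerate_candidate_models(mains),
                  function(m) paste(sort(m), collapse = "|"),
                  character(1))
    want <- vapply(oracle_hierarchical_models(mains),
                   function(m) paste(sort(m), collapse = "|"),
                   character(1))
    expect_setequal(got, want)
  }
  ## capped interaction order
  expect_length(enumerate_candidate_models(c("a", "b", "c"),
                                           max_interaction_order = 1), 8)
  expect_error(enumerate_candidate_models(character(0)),
               class = "invalid_argument")
})

test_that("Akaike weights follow the exponential-difference formula", {
  expect_equal(akaike_weights(c(10, 10, 10, 10)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 3), c(0.731, 0.269))
  w2 <- akaike_weights(c(0, 1000))
  expect_gt(w2[1], 1 - 1e-10)
  expect_error(akaike_weights(c(1, NA)), class = "invalid_argument")
  expect_error(akaike_weights(c(1, Inf)), class = "invalid_argument")
  ## weights always sum to 1
  set.seed(4)
  for (i in 1:10) expect_equal(sum(akaike_weights(rnorm(7, 100, 20))), 1)
})

fake_fit <- function(terms, aic) structure(list(terms = terms, aic = aic),
                                           class = "model_fit")

test_that("importance sums retained weights per term", {
  single <- model_average_importance(list(fake_fit("x", 12)))
  expect_equal(unname(single$importance["x"]), 1)
  ## two equal models, term in one
  aic_equal <- c(10, 10)
  two <- model_average_importance(list(fake_fit(c("x", "z"), 10),
                                       fake_fit("z", 10)))
  expect_equal(unname(two$importance["x"]), 0.5)
  expect_equal(unname(two$importance["z"]), 1)
  ## the 10%-of-max rule: weights (0.90, 0.08, 0.02) keep only the first
  aics <- c(0, 0 - 2 * log(0.08 / 0.90), 0 - 2 * log(0.02 / 0.90))
  fits <- list(fake_fit("x", aics[1]), fake_fit("y", aics[2]),
               fake_fit(c("x", "y"), aics[3]))
  res <- model_average_importance(fits)
  expect_identical(sum(res$retained), 1L)
  expect_equal(unname(res$importance["x"]), 1)
  expect_equal(unname(res$importance["y"]), 0)
  expect_equal(sum(res$weights_retained), 1)
})

test_that("the elevation form is chosen by AIC with ties to linear", {
  set.seed(21)
  d <- data.frame(elevation = rep(seq(-1, 1, length.out = 7), 3),
                  slope = rnorm(21), lai = rnorm(21))
  y_quad <- 5 - 4 * d$elevation^2 + rnorm(21, 0, 0.05)
  expect_identical(select_elevation_form(y_quad, d), "quadratic")
  y_lin <- 1 + 2 * d$elevation + rnorm(21, 0, 0.05)
  expect_identical(select_elevation_form(y_lin, d), "linear")
  ## exact-fit degenerate case: both forms perfect, tie broken to linear
  y_exact <- 1 + 2 * d$elevation
  expect_identical(suppressWarnings(select_elevation_form(y_exact, d)),
                   "linear")
})

test_that("model averaging recovers a dominant elevation effect", {
  set.seed(8)
  d <- data.frame(elevation = rep(seq(1000, 2200, 200), each = 3),
                  slope = rnorm(21, 20, 8),
                  lai = rnorm(21, 4, 0.5))
  y <- 14 - 0.006 * d$elevation + rnorm(21, 0, 0.5)
  res <- trend_model_averaging(y, d)
  expect_gt(res$importance["elevation"], 0.8)
  expect_gt(res$importance["elevation"], res$importance["slope"])
  expect_gt(res$importance["elevation"], res$importance["lai"])
  expect_equal(sum(res$weights_retained), 1, tolerance = 1e-12)
})

test_that("the extremum test classifies parabolas and matches vegan", {
  x <- rep(1:7, each = 3)
  hump <- mos_extremum_test(x, -(x - mean(x))^2)
  expect_identical(hump$conclusion, "hump")
  expect_equal(hump$extremum, mean(x), tolerance = 1e-8)
  ushape <- mos_extremum_test(x, (x - mean(x))^2)
  expect_identical(ushape$conclusion, "u_shape")
  ## numerical agreement with the reference implementation
  set.seed(5)
  y <- -(x - 4)^2 + rnorm(21, 0, 1.5)
  ours <- mos_extremum_test(x, y)
  ref <- vegan::MOStest(x, y)
  expect_equal(ours$extremum, unname(ref$hump["hump"]), tolerance = 1e-8)
  expect_identical(ours$conclusion == "hump",
                   unname(ref$isHump && ref$isBracketed))
  expect_error(mos_extremum_test(1:4, 1:4), class = "invalid_argument")
})

test_that("a linear trend is rarely called a hump", {
  set.seed(99)
  x <- rep(1:7, each = 3)
  calls <- replicate(200, {
    y <- 1 + 0.5 * x + rnorm(21)
    mos_extremum_test(x, y)$conclusion
  })
  expect_lt(mean(calls != "not_supported"), 0.12)
})
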