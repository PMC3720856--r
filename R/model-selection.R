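## Information-theoretic trend modelling -----------------------------------
##
## Gaussian linear models of diversity/biomass responses against
## elevation, slope and LAI; candidate sets enumerated respecting the
## principle of marginality; Akaike weights and model-averaged variable
## importance; Mitchell-Olds & Shaw test for hump/U-shaped relationships.

#' Centre and scale predictor columns
#'
#' Predictors are standardized (z-scores) before polynomial and
#' interaction terms are formed, which keeps the design well conditioned
#' and makes coefficients comparable across terms.
#'
#' @param data data.frame of predictors.
#' @param vars columns to standardize (default all numeric columns).
#' @return data.frame of scaled predictors with attributes `center` and
#'   `scale` for back-transformation.
#' @export
standardize_predictors <- function(data, vars = names(data)) {
  out <- data
  ctr <- scl <- setNames(numeric(length(vars)), vars)
  for (v in vars) {
    ctr[v] <- mean(data[[v]])
    scl[v] <- sd(data[[v]])
    if (scl[v] == 0) scl[v] <- 1
    out[[v]] <- (data[[v]] - ctr[v]) / scl[v]
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

term_parts <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

canonical_term <- function(parts) paste(sort(parts), collapse = ":")

## Expand a set of model terms into design columns. With
## quadratic_elevation, the "elevation" main effect carries both the
## linear and squared (standardized) elevation columns; interactions use
## the linear term only.
term_design <- function(data, terms, quadratic_elevation = FALSE) {
  n <- nrow(data)
  cols <- list()
  for (term in terms) {
    parts <- term_parts(term)
    if (length(parts) == 1L) {
      cols[[term]] <- data[[term]]
      if (quadratic_elevation && term == "elevation")
        cols[["elevation_sq"]] <- data[["elevation"]]^2
    } else {
      cols[[term]] <- Reduce(`*`, lapply(parts, function(p) data[[p]]))
    }
  }
  if (!length(cols)) return(data.frame(row.names = seq_len(n)))
  as.data.frame(cols, optional = TRUE)
}

#' Ordinary least-squares fit with information-theoretic summaries
#'
#' Fits `response ~ design` by OLS and reports coefficient estimates with
#' 95% confidence intervals from the t distribution, residual sum of
#' squares, R-squared, the overall F statistic against the intercept-only
#' model, and AIC computed from the full Gaussian log-likelihood,
#' `AIC = n log(2 pi RSS / n) + n + 2 (k + 1)` where `k` counts the
#' regression coefficients (the +1 is the error variance). Including the
#' Gaussian constant makes the values identical to [stats::AIC()] on an
#' [stats::lm()] fit.
#'
#' @param response numeric response vector.
#' @param design data.frame (or matrix) of term columns; may have zero
#'   columns for the intercept-only model.
#' @param terms optional character vector naming the model's terms (for
#'   bookkeeping in averaging).
#' @param level confidence level for intervals.
#' @return object of class `model_fit`.
#' @export
fit_ols <- function(response, design, terms = colnames(design),
                    level = 0.95) {
  design <- as.data.frame(design)
  if (any(!is.finite(response)) ||
      (ncol(design) && any(!vapply(design, function(col)
        all(is.finite(col)), logical(1)))))
    stop_elevgrad("response and design must be finite",
                  "invalid_argument")
  n <- length(response)
  k <- ncol(design) + 1L
  if (n <= k)
    stop_elevgrad(sprintf(
      "need n > number of coefficients (n = %d, coefficients = %d)",
      n, k), "not_estimable")
  df <- cbind(.response = response, design)
  fit <- lm(.response ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf))
    stop_elevgrad(paste0("rank-deficient design; collinear terms: ",
                         paste(names(cf)[is.na(cf)], collapse = ", ")),
                  "rank_deficient")
  rss <- sum(fit$residuals^2)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  ci <- stats::confint(fit, level = level)
  aic <- n * log(2 * pi * rss / n) + n + 2 * (k + 1)
  f_stat <- if (k > 1L && rss > 0 && tss > rss * (1 + 1e-14)) {
    val <- ((tss - rss) / (k - 1L)) / (rss / (n - k))
    list(value = val, df1 = k - 1L, df2 = n - k,
         p = pf(val, k - 1L, n - k, lower.tail = FALSE))
  } else list(value = NA_real_, df1 = k - 1L, df2 = n - k, p = NA_real_)
  structure(list(
    terms = if (is.null(terms)) character(0) else terms,
    coefficients = data.frame(term = names(cf), estimate = unname(cf),
                              lwr = ci[, 1], upr = ci[, 2],
                              row.names = NULL),
    rss = rss, r_squared = r2, f_statistic = f_stat,
    aic = aic, n = n, k = k, lm = fit), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s\n  n = %d, R^2 = %.3f, AIC = %.2f\n",
              if (length(x$terms)) paste(x$terms, collapse = " + ")
              else "(intercept only)",
              x$n, x$r_squared, x$aic))
  invisible(x)
}

#' Enumerate candidate models respecting marginality
#'
#' Builds the full term lattice (main effects plus interactions up to
#' `max_interaction_order`) and returns every subset closed under the
#' principle of marginality - an interaction appears only together with
#' all of its marginal (lower-order) terms - from the null
#' (intercept-only) model to the maximal model, each exactly once.
#'
#' @param main_effects character vector of main-effect names.
#' @param max_interaction_order highest interaction order to include.
#' @return list of character vectors of model terms; the first element is
#'   `character(0)` (the null model).
#' @export
enumerate_candidate_models <- function(main_effects,
                                       max_interaction_order =
                                         length(main_effects)) {
  if (length(main_effects) < 1)
    stop_elevgrad("need at least one main effect", "invalid_argument")
  m <- length(main_effects)
  ord <- min(max_interaction_order, m)
  terms <- character(0)
  for (k in seq_len(ord)) {
    terms <- c(terms, apply(combn(sort(main_effects), k), 2,
                            paste, collapse = ":"))
  }
  nt <- length(terms)
  if (nt > 20)
    stop_elevgrad("term lattice too large to enumerate",
                  "invalid_argument")
  parts <- lapply(terms, term_parts)
  models <- list()
  for (mask in 0:(2^nt - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(nt) - 1)))
    ok <- TRUE
    for (i in which(inset)) {
      p <- parts[[i]]
      if (length(p) > 1L) {
        margins <- apply(combn(p, length(p) - 1L), 2, canonical_term)
        if (!all(margins %in% terms[inset])) { ok <- FALSE; break }
      }
    }
    if (ok) models[[length(models) + 1L]] <- terms[inset]
  }
  models[order(vapply(models, length, integer(1)))]
}

#' Akaike weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AIC_i - min(AIC)`.
#'
#' @param aics numeric vector of finite AIC values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  if (length(aics) < 1 || any(!is.finite(aics)))
    stop_elevgrad("all AIC values must be finite", "invalid_argument")
  d <- aics - min(aics)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-averaged variable importance
#'
#' Computes Akaike weights over a fitted candidate set, retains the models
#' whose weight exceeds `retain_rule` times the maximum weight (the rule
#' "weight above 10% of the maximum" by default), renormalizes the retained weights to
#' sum to 1, and reports each term's importance as the summed renormalized
#' weight of the retained models containing it.
#'
#' @param fits list of [fit_ols()] objects (each carrying `terms` and
#'   `aic`).
#' @param retain_rule fraction of the maximum weight below which models
#'   are dropped (strictly greater-than retention).
#' @return object of class `averaging_result`: list with `weights` (all
#'   models), `retained` (logical), `weights_retained` (renormalized),
#'   `importance` (named vector) and a summary `table`.
#' @export
model_average_importance <- function(fits, retain_rule = 0.10) {
  if (!length(fits))
    stop_elevgrad("need at least one fitted model", "invalid_argument")
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  w <- akaike_weights(aics)
  retained <- w > retain_rule * max(w)
  wr <- w[retained] / sum(w[retained])
  all_terms <- unique(unlist(lapply(fits, function(f) f$terms)))
  importance <- setNames(numeric(length(all_terms)), all_terms)
  kept <- fits[retained]
  for (term in all_terms) {
    has <- vapply(kept, function(f) term %in% f$terms, logical(1))
    importance[term] <- sum(wr[has])
  }
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "(null)",
      character(1)),
    n_terms = vapply(fits, function(f) length(f$terms), integer(1)),
    aic = aics, delta_aic = aics - min(aics), weight = w,
    retained = retained, stringsAsFactors = FALSE)
  tab <- tab[order(tab$aic), ]
  rownames(tab) <- NULL
  structure(list(weights = w, retained = retained,
                 weights_retained = wr,
                 subset_rule = sprintf("weight > %.2f * max(weight)",
                                       retain_rule),
                 importance = importance, table = tab),
            class = "averaging_result")
}

#' @export
print.averaging_result <- function(x, ...) {
  cat(sprintf("Model averaging over %d models (%d retained; %s)\n",
              length(x$weights), sum(x$retained), x$subset_rule))
  imp <- sort(x$importance, decreasing = TRUE)
  for (i in seq_along(imp))
    cat(sprintf("  %-28s %.3f\n", names(imp)[i], imp[i]))
  invisible(x)
}

#' Choose a linear or quadratic elevation form
#'
#' Fits the maximal candidate model twice - once with a linear elevation
#' term, once adding the squared (standardized) elevation - and returns
#' the form whose maximal model has the lower AIC. Ties break toward the
#' simpler linear form.
#'
#' @param response numeric response vector.
#' @param data data.frame of standardized predictors containing
#'   `elevation` and the other main effects.
#' @param main_effects main-effect names (must include `"elevation"`).
#' @param max_interaction_order highest interaction order in the maximal
#'   model.
#' @return `"linear"` or `"quadratic"`.
#' @export
select_elevation_form <- function(response, data,
                                  main_effects = c("elevation", "slope",
                                                   "lai"),
                                  max_interaction_order =
                                    length(main_effects)) {
  models <- enumerate_candidate_models(main_effects, max_interaction_order)
  maximal <- models[[length(models)]]
  fit_lin <- fit_ols(response, term_design(data, maximal, FALSE),
                     terms = maximal)
  fit_quad <- fit_ols(response, term_design(data, maximal, TRUE),
                      terms = maximal)
  if (fit_quad$aic < fit_lin$aic) "quadratic" else "linear"
}

#' Fit and average a marginality-closed candidate set
#'
#' Convenience wrapper: standardizes predictors, chooses the elevation
#' form by AIC of the maximal model, fits every marginality-closed
#' candidate model (skipping models with more coefficients than the data
#' can estimate), and model-averages with the >10%-of-maximum weight rule.
#'
#' @inheritParams select_elevation_form
#' @param retain_rule passed to [model_average_importance()].
#' @return an `averaging_result` with the chosen `elevation_form`, fitted
#'   models and any skipped model specifications attached.
#' @export
trend_model_averaging <- function(response, data,
                                  main_effects = c("elevation", "slope",
                                                   "lai"),
                                  max_interaction_order =
                                    length(main_effects),
                                  retain_rule = 0.10) {
  ok <- is.finite(response)
  if (!all(ok)) {
    warning(sprintf("dropping %d observation(s) with missing response",
                    sum(!ok)))
    response <- response[ok]
    data <- data[ok, , drop = FALSE]
  }
  sdata <- standardize_predictors(data, main_effects)
  models <- enumerate_candidate_models(main_effects, max_interaction_order)
  ## choose elevation form on the largest model the data can estimate
  estimable <- function(spec, quad) {
    ncol(term_design(sdata, spec, quad)) + 2L < length(response)
  }
  form <- "linear"
  if ("elevation" %in% main_effects) {
    maximal <- models[[length(models)]]
    if (estimable(maximal, TRUE)) {
      form <- select_elevation_form(response, sdata, main_effects,
                                    max_interaction_order)
    }
  }
  quad <- identical(form, "quadratic")
  fits <- list()
  skipped <- list()
  for (spec in models) {
    if (!estimable(spec, quad && "elevation" %in% spec)) {
      skipped[[length(skipped) + 1L]] <- spec
      next
    }
    fits[[length(fits) + 1L]] <-
      fit_ols(response, term_design(sdata, spec,
                                    quad && "elevation" %in% spec),
              terms = spec)
  }
  res <- model_average_importance(fits, retain_rule)
  res$elevation_form <- form
  res$fits <- fits
  res$skipped <- skipped
  res
}

#' Mitchell-Olds & Shaw test for a hump or U shape
#'
#' Fits the quadratic `y ~ x + x^2` (on standardized x for conditioning),
#' locates the extremum `u = -b1 / (2 b2)` in original units, and tests
#' the unconstrained quadratic against the two constrained quadratics
#' whose extremum is pinned at `min(x)` and at `max(x)` (reparameterized
#' as `y ~ a + b2 (x^2 - 2 theta x)`, nested within the quadratic) via F
#' tests. A hump (or U) is supported only when both constrained models
#' are rejected at `level` - i.e. the extremum lies strictly inside the
#' data range - and the curvature sign matches (negative for a hump,
#' positive for a U).
#'
#' @param x predictor vector (>= 3 distinct values, n >= 5).
#' @param y response vector.
#' @param level significance level for the two endpoint tests.
#' @return object of class `mos_test`: list with `extremum`, `curvature`,
#'   `f_low`, `f_high`, `p_low`, `p_high`, `conclusion` (`"hump"`,
#'   `"u_shape"` or `"not_supported"`).
#' @export
mos_extremum_test <- function(x, y, level = 0.05) {
  n <- length(x)
  if (n < 5 || length(unique(x)) < 3)
    stop_elevgrad("need n >= 5 with >= 3 distinct x values",
                  "invalid_argument")
  mx <- mean(x)
  sx <- sd(x)
  if (sx == 0) sx <- 1
  xs <- (x - mx) / sx
  X <- cbind(1, xs, xs^2)
  qf_full <- stats::lm.fit(X, y)
  b <- qf_full$coefficients
  rss_full <- sum(qf_full$residuals^2)
  if (!is.finite(b[3]) || b[3] == 0) {
    return(structure(list(extremum = NA_real_, curvature = 0,
                          f_low = NA_real_, f_high = NA_real_,
                          p_low = NA_real_, p_high = NA_real_,
                          conclusion = "not_supported", level = level),
                     class = "mos_test"))
  }
  u_s <- -b[2] / (2 * b[3])
  extremum <- mx + sx * u_s
  endpoint_test <- function(theta_s) {
    Xc <- cbind(1, xs^2 - 2 * theta_s * xs)
    rss_c <- sum(stats::lm.fit(Xc, y)$residuals^2)
    f <- (rss_c - rss_full) / (rss_full / (n - 3))
    c(f = f, p = pf(f, 1, n - 3, lower.tail = FALSE))
  }
  lo <- endpoint_test((min(x) - mx) / sx)
  hi <- endpoint_test((max(x) - mx) / sx)
  conclusion <- "not_supported"
  if (lo["p"] < level && hi["p"] < level)
    conclusion <- if (b[3] < 0) "hump" else "u_shape"
  structure(list(extremum = unname(extremum),
                 curvature = unname(sign(b[3])),
                 f_low = unname(lo["f"]), f_high = unname(hi["f"]),
                 p_low = unname(lo["p"]), p_high = unname(hi["p"]),
                 conclusion = conclusion, level = level),
            class = "mos_test")
}

#' @export
print.mos_test <- function(x, ...) {
  cat(sprintf(
    "MOS extremum test: %s (extremum at %.4g; p_low = %.3g, p_high = %.3g)\n",
    x$conclusion, x$extremum, x$p_low, x$p_high))
  invisible(x)
}
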