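## Model-based analysis of community composition ---------------------------
##
## Sites x species abundance tables are modelled with one count GLM per
## species (log link; negative binomial with per-species ML dispersion,
## falling back to Poisson when the dispersion estimate diverges, i.e.
## variance ~ mean). Multivariate inference sums per-species deviance
## reductions over sequentially added terms and obtains p-values by a PIT
## residual bootstrap that resamples site rows jointly across species,
## preserving cross-species dependence.

#' Fit a count GLM for one species
#'
#' Log-link GLM fitted by iteratively reweighted least squares. With
#' `family = "auto"` (default) a negative binomial with maximum-likelihood
#' dispersion is used unless the dispersion estimate exceeds `theta_cap`,
#' in which case the Poisson fit is kept (variance approximately equal to
#' the mean).
#'
#' @param counts non-negative integer response vector.
#' @param design data.frame or matrix of predictor columns (intercept
#'   added internally).
#' @param family `"auto"`, `"negbin"` or `"poisson"`.
#' @param theta_cap dispersion (size) cap triggering the Poisson fallback.
#' @param max_iter maximum IRLS iterations.
#' @param tol relative deviance convergence tolerance.
#' @return list with `coefficients`, `fitted`, `theta` (`Inf` for
#'   Poisson), `family`, `deviance`, `loglik`, `converged`.
#' @export
fit_species_glm <- function(counts, design = NULL,
                            family = c("auto", "negbin", "poisson"),
                            theta_cap = 1e6, max_iter = 200, tol = 1e-8) {
  family <- match.arg(family)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_elevgrad("counts must be non-negative integers",
                  "invalid_argument")
  X <- glm_design(design, length(counts))
  if (length(counts) <= ncol(X))
    stop_elevgrad("need more sites than model terms", "invalid_argument")
  fam_code <- match(family, c("auto", "negbin", "poisson"))- 1L
  fit <- cpp_glm_fit(X, as.numeric(counts), fam_code, theta_cap,
                     max_iter, tol)
  names(fit$coefficients) <- colnames(X)
  fit
}

glm_design <- function(design, n) {
  if (is.null(design) || NCOL(design) == 0)
    return(matrix(1, nrow = n, ncol = 1,
                  dimnames = list(NULL, "(Intercept)")))
  design <- as.matrix(design)
  qrX <- qr(cbind(1, design))
  if (qrX$rank < ncol(design) + 1) {
    drop <- setdiff(seq_len(ncol(design) + 1), qrX$pivot[seq_len(qrX$rank)])
    stop_elevgrad(paste0("design is rank deficient; collinear columns: ",
                         paste(colnames(design)[drop - 1], collapse = ", ")),
                  "rank_deficient")
  }
  cbind(`(Intercept)` = 1, design)
}

#' Fit per-species GLMs across a community matrix
#'
#' Assembles one [fit_species_glm()] per species over a shared design.
#' Species with all-zero counts are dropped with a warning.
#'
#' @param matrix sites x species matrix of non-negative integer counts
#'   (ordinal cover classes 0-6 may be used as counts for ground-cover
#'   data, an approximation documented in the package vignette).
#' @param predictors data.frame of site-level predictors.
#' @param terms named list of term blocks added sequentially in the given
#'   order; each element is a character vector of `predictors` columns
#'   (a block enters the analysis of deviance as one term). Defaults to
#'   one block per predictor column.
#' @inheritParams fit_species_glm
#' @return object of class `multi_glm`.
#' @export
multivariate_fit <- function(matrix, predictors,
                             terms = as.list(setNames(names(predictors),
                                                      names(predictors))),
                             family = c("auto", "negbin", "poisson"),
                             theta_cap = 1e6, max_iter = 200,
                             tol = 1e-8) {
  family <- match.arg(family)
  zero <- colSums(matrix) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero species: %s", sum(zero),
                    paste(colnames(matrix)[zero], collapse = ", ")))
    matrix <- matrix[, !zero, drop = FALSE]
  }
  if (ncol(matrix) == 0)
    stop_elevgrad("no species with nonzero counts", "invalid_argument")
  bad <- setdiff(unlist(terms), names(predictors))
  if (length(bad))
    stop_elevgrad(paste0("unknown predictor column(s): ",
                         paste(bad, collapse = ", ")),
                  "invalid_argument")
  ## nested design matrices X_0 (intercept) .. X_T (full)
  designs <- list(glm_design(NULL, nrow(matrix)))
  used <- character(0)
  for (i in seq_along(terms)) {
    used <- c(used, terms[[i]])
    designs[[i + 1L]] <-
      glm_design(as.matrix(predictors[, used, drop = FALSE]),
                 nrow(matrix))
  }
  if (nrow(matrix) <= ncol(designs[[length(designs)]]))
    stop_elevgrad("need more sites than model terms", "invalid_argument")
  fits <- lapply(seq_len(ncol(matrix)), function(k)
    fit_species_glm(matrix[, k], predictors[, used, drop = FALSE],
                    family = family, theta_cap = theta_cap,
                    max_iter = max_iter, tol = tol))
  names(fits) <- colnames(matrix)
  structure(list(fits = fits, Y = matrix, predictors = predictors,
                 terms = terms, designs = designs, family = family,
                 theta_cap = theta_cap, max_iter = max_iter, tol = tol),
            class = "multi_glm")
}

#' @export
print.multi_glm <- function(x, ...) {
  fams <- vapply(x$fits, `[[`, character(1), "family")
  cat(sprintf(
    "Multivariate count GLM: %d species x %d sites; terms: %s\n",
    ncol(x$Y), nrow(x$Y), paste(names(x$terms), collapse = ", ")))
  cat(sprintf("  families: %d negative binomial, %d Poisson fallback\n",
              sum(fams == "negbin"), sum(fams == "poisson")))
  invisible(x)
}

#' Resampled multivariate analysis of deviance
#'
#' Terms are added sequentially in the order of `fit$terms`. The statistic
#' for each term is the summed (over species) deviance reduction when the
#' term enters; per species the dispersion is estimated on the full model
#' and held fixed across the nested sequence so reductions telescope
#' exactly. p-values use the add-one Monte-Carlo convention
#' `(1 + #(null >= observed)) / (1 + n_resamples)` with null datasets
#' synthesized under the null model of each sequential comparison:
#' probability-integral-transform residuals `u ~ U(F(y-1), F(y))` are
#' drawn under the null fit, site rows of the u-matrix are resampled with
#' replacement (method `"pit-trap"`) or jointly permuted
#' (`"row-permutation"`, a cross-check mode), and inverted through the
#' null quantile function.
#'
#' @param fit a [multivariate_fit()] object.
#' @param n_resamples number of bootstrap resamples (>= 99).
#' @param method `"pit-trap"` or `"row-permutation"`.
#' @param seed optional integer seed.
#' @return object of class `deviance_table`: data.frame with one row per
#'   term (`term`, `deviance`, `p_value`) plus attributes with the
#'   per-model deviances.
#' @export
anova_deviance_resampled <- function(fit, n_resamples = 999,
                                     method = c("pit-trap",
                                                "row-permutation"),
                                     seed = NULL) {
  stopifnot(inherits(fit, "multi_glm"))
  method <- match.arg(method)
  if (n_resamples < 99)
    stop_elevgrad("need n_resamples >= 99", "invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  fam_code <- match(fit$family, c("auto", "negbin", "poisson")) - 1L
  res <- cpp_anova_pit(fit$designs, unname(as.matrix(fit$Y)),
                       as.integer(n_resamples),
                       if (method == "pit-trap") 0L else 1L,
                       fam_code, fit$theta_cap, fit$max_iter, fit$tol)
  obs <- res$observed
  p <- vapply(seq_along(obs), function(i)
    (1 + sum(res$null_stats[, i] >= obs[i])) / (1 + n_resamples),
    numeric(1))
  out <- data.frame(term = names(fit$terms), deviance = obs, p_value = p,
                    stringsAsFactors = FALSE)
  attr(out, "model_deviances") <- res$deviances
  attr(out, "theta") <- res$theta
  attr(out, "poisson") <- res$poisson
  attr(out, "n_resamples") <- n_resamples
  attr(out, "method") <- method
  class(out) <- c("deviance_table", "data.frame")
  out
}

#' Percent deviance explained
#'
#' Augments an analysis-of-deviance table with the percentage of the
#' model-explained deviance attributable to each term
#' (`pct_within_model`, summing to 100) and the percentage of the null
#' deviance explained by the full model (`pct_model_total`).
#'
#' @param table a [anova_deviance_resampled()] result.
#' @return the table with columns `pct_within_model` and
#'   `pct_model_total` added.
#' @export
percent_deviance <- function(table) {
  stopifnot(inherits(table, "deviance_table"))
  dev <- attr(table, "model_deviances")
  null_dev <- sum(dev[1, ])
  full_dev <- sum(dev[nrow(dev), ])
  if (null_dev <= 0)
    stop_elevgrad("null deviance is zero; percentages undefined",
                  "undefined_percentage")
  model_red <- null_dev - full_dev
  table$pct_within_model <- if (model_red > 0)
    100 * table$deviance / model_red else rep(NA_real_, nrow(table))
  table$pct_model_total <- 100 * model_red / null_dev
  table
}
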