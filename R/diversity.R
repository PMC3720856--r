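## Fisher's log-series alpha and additive alpha/beta partitioning ----------

#' Fisher's alpha from richness and abundance
#'
#' Solves the log-series defining relation `S = alpha * log(1 + N/alpha)`
#' for its unique positive root. The left-hand side is strictly increasing
#' in alpha with supremum N, so a solution exists exactly when `S < N`; it
#' is bracketed (initial bracket `[1e-6, 1e6]`, upper bound expanded as
#' needed), solved with Brent's method and polished by Newton steps until
#' the re-substitution residual falls below 1e-10.
#'
#' @param s species richness (1 <= s <= n).
#' @param n number of individuals.
#' @return object of class `fisher_alpha`: list with `alpha`, `s`, `n`,
#'   `residual` (absolute defining-equation residual) and `iterations`.
#' @export
#' @examples
#' fisher_alpha(10, 100)
fisher_alpha <- function(s, n) {
  if (!is_count(s) || !is_count(n) || s < 1 || s > n)
    stop_elevgrad("need 1 <= s <= n with s, n integers",
                  "invalid_argument")
  if (s == n)
    stop_elevgrad(
      paste0("S = N (", s, "): alpha*log(1 + N/alpha) < N for every ",
             "finite alpha, no finite solution"),
      "degenerate_diversity")
  f <- function(a) a * log1p(n / a) - s
  lower <- 1e-6
  upper <- 1e6
  it <- 0L
  while (f(upper) < 0 && upper < 1e30) {
    upper <- upper * 10
    it <- it + 1L
  }
  root <- stats::uniroot(f, c(lower, upper), tol = 1e-12)
  a <- root$root
  it <- it + root$iter
  ## Newton polish: f'(a) = log(1 + n/a) - n/(a + n)
  repeat {
    res <- f(a)
    if (abs(res) < 1e-10 || it > 200L) break
    a <- a - res / (log1p(n / a) - n / (a + n))
    it <- it + 1L
  }
  structure(list(alpha = a, s = as.integer(s), n = as.integer(n),
                 residual = abs(f(a)), iterations = it),
            class = "fisher_alpha")
}

#' @export
print.fisher_alpha <- function(x, ...) {
  cat(sprintf("Fisher's alpha = %.4f  (S = %d, N = %d, residual = %.2e)\n",
              x$alpha, x$s, x$n, x$residual))
  invisible(x)
}

#' Convert an ordinal cover class to a pseudo-abundance
#'
#' Maps the seven-point ground-cover scale (0: absent; 1: <1%; 2: 1-4%;
#' 3: 5-24%; 4: 25-49%; 5: 50-74%; 6: 75-100%) to the rounded midpoint
#' percentage of the class interval (0, 1, 3, 15, 37, 62, 88), which is
#' then usable as a pseudo-abundance when computing Fisher's alpha for
#' ground-cover vegetation. The midpoint convention is this package's
#' choice of encoder; the scale itself is the standard field scale.
#'
#' @param cover_class integer vector of classes in `0:6`.
#' @return integer pseudo-abundances.
#' @export
cover_class_to_pseudoabundance <- function(cover_class) {
  if (any(is.na(cover_class)) ||
      !all(cover_class %in% 0:6))
    stop_elevgrad("cover classes must lie in 0..6", "invalid_argument")
  midpoints <- c(0L, 1L, 3L, 15L, 37L, 62L, 88L)
  midpoints[as.integer(cover_class) + 1L]
}

#' Per-plot Fisher's alpha table
#'
#' Computes Fisher's alpha for every row (plot) of a community matrix.
#' Plots with no individuals are excluded with a warning; plots where every
#' individual is a distinct species (S = N) are reported with a degenerate
#' flag and `NA` alpha rather than aborting, so that tiny plots do not stop
#' a pipeline run.
#'
#' @param matrix sites x species matrix of non-negative integer abundances.
#' @return data.frame with columns `site`, `s`, `n`, `alpha`, `residual`,
#'   `degenerate`.
#' @export
plot_alpha_table <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || ncol(matrix) == 0)
    stop_elevgrad("community matrix must be non-empty", "invalid_argument")
  if (any(matrix < 0))
    stop_elevgrad("abundances must be non-negative", "invalid_argument")
  sites <- rownames(matrix)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(matrix)))
  n_i <- rowSums(matrix)
  empty <- n_i == 0
  if (any(empty))
    warning(sprintf("excluding %d plot(s) with no individuals: %s",
                    sum(empty), paste(sites[empty], collapse = ", ")))
  keep <- which(!empty)
  rows <- lapply(keep, function(i) {
    s <- sum(matrix[i, ] > 0)
    n <- sum(matrix[i, ])
    if (s == n) {
      data.frame(site = sites[i], s = s, n = n, alpha = NA_real_,
                 residual = NA_real_, degenerate = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      fa <- fisher_alpha(s, n)
      data.frame(site = sites[i], s = s, n = n, alpha = fa$alpha,
                 residual = fa$residual, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Additive alpha/beta diversity partition for one station
#'
#' Station-level (gamma) diversity is Fisher's alpha computed on the
#' community pooled across the station's plots; beta-diversity is defined
#' additively as the station alpha minus the arithmetic mean of the
#' plot-level alphas. Because Fisher's alpha is a nonlinear index, beta may
#' legitimately be negative (pooling more individuals with no new species
#' lowers alpha).
#'
#' @param plots plots x species abundance matrix restricted to one station.
#' @return object of class `diversity_partition`: list with
#'   `station_alpha`, `mean_plot_alpha`, `beta`, `n_plots` (plots entering
#'   the mean) and `n_degenerate`.
#' @export
additive_beta_partition <- function(plots) {
  if (is.null(dim(plots)) || nrow(plots) < 1)
    stop_elevgrad("need at least one plot", "invalid_argument")
  pooled <- colSums(plots)
  s_pool <- sum(pooled > 0)
  n_pool <- sum(pooled)
  if (n_pool == 0)
    stop_elevgrad("pooled community is empty", "invalid_argument")
  if (s_pool == n_pool)
    stop_elevgrad("pooled community has S = N", "degenerate_diversity")
  station <- fisher_alpha(s_pool, n_pool)
  tab <- suppressWarnings(plot_alpha_table(plots))
  degen <- tab$degenerate
  if (any(degen))
    warning(sprintf("%d degenerate plot(s) excluded from the plot mean",
                    sum(degen)))
  alphas <- tab$alpha[!degen]
  if (!length(alphas))
    stop_elevgrad("every plot is degenerate (S = N): plot-level alpha undefined",
                  "degenerate_diversity")
  mean_plot <- mean(alphas)
  structure(list(station_alpha = station$alpha,
                 mean_plot_alpha = mean_plot,
                 beta = station$alpha - mean_plot,
                 n_plots = length(alphas),
                 n_degenerate = sum(degen)),
            class = "diversity_partition")
}

#' @export
print.diversity_partition <- function(x, ...) {
  cat(sprintf(
    "Diversity partition: station alpha %.3f = mean plot alpha %.3f + beta %.3f (%d plots)\n",
    x$station_alpha, x$mean_plot_alpha, x$beta, x$n_plots))
  invisible(x)
}
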