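// Core numerical routines: log-link Poisson / negative-binomial IRLS with
// per-species maximum-likelihood dispersion, sequential analysis of
// deviance with PIT residual-bootstrap resampling, and the
// independent-swap (checkerboard) null-model chain. All randomness goes
// through R's RNG so set.seed() in R governs every draw.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ETA_MAX = 30.0;

static inline double clampEta(double e) {
  if (e > ETA_MAX) return ETA_MAX;
  if (e < -ETA_MAX) return -ETA_MAX;
  return e;
}

// deviance with family-specific saturated reference; theta ignored for
// Poisson
static double deviance_glm(const arma::vec& y, const arma::vec& mu,
                           double theta, bool poisson) {
  double dev = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    double yj = y[j], mj = mu[j];
    if (poisson) {
      double t = (yj > 0) ? yj * std::log(yj / mj) : 0.0;
      dev += 2.0 * (t - (yj - mj));
    } else {
      double t = (yj > 0) ? yj * std::log(yj / mj) : 0.0;
      dev += 2.0 * (t - (yj + theta) *
                    std::log((yj + theta) / (mj + theta)));
    }
  }
  return dev;
}

static double loglik_glm(const arma::vec& y, const arma::vec& mu,
                         double theta, bool poisson) {
  double ll = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    double yj = y[j], mj = mu[j];
    if (poisson) {
      ll += R::dpois(yj, mj, 1);
    } else {
      ll += R::lgammafn(yj + theta) - R::lgammafn(theta) -
        R::lgammafn(yj + 1.0) + theta * std::log(theta / (theta + mj)) +
        (yj > 0 ? yj * std::log(mj / (theta + mj)) : 0.0);
    }
  }
  return ll;
}

// IRLS for log-link count GLM with fixed dispersion; returns convergence
static bool irls_fit(const arma::mat& X, const arma::vec& y, double theta,
                     bool poisson, arma::vec& beta, arma::vec& mu,
                     int maxit, double tol) {
  arma::uword n = X.n_rows, p = X.n_cols;
  arma::vec eta(n);
  double ybar = arma::mean(y);
  if (ybar <= 0) ybar = 0.5;
  for (arma::uword j = 0; j < n; ++j)
    eta[j] = std::log((y[j] + ybar) / 2.0);
  mu = arma::exp(eta);
  double dev_old = deviance_glm(y, mu, theta, poisson);
  bool converged = false;
  arma::mat XtW(p, n);
  for (int it = 0; it < maxit; ++it) {
    arma::vec w(n), z(n);
    for (arma::uword j = 0; j < n; ++j) {
      double mj = mu[j];
      if (mj < 1e-8) mj = 1e-8;
      w[j] = poisson ? mj : mj / (1.0 + mj / theta);
      z[j] = eta[j] + (y[j] - mj) / mj;
    }
    for (arma::uword c = 0; c < p; ++c)
      XtW.row(c) = (X.col(c) % w).t();
    arma::mat A = XtW * X;
    arma::vec b = XtW * z;
    arma::vec newbeta;
    bool ok = arma::solve(newbeta, A, b, arma::solve_opts::no_approx);
    if (!ok) {
      // fall back to pseudo-inverse for ill-conditioned steps
      newbeta = arma::pinv(A) * b;
    }
    beta = newbeta;
    eta = X * beta;
    for (arma::uword j = 0; j < n; ++j) eta[j] = clampEta(eta[j]);
    mu = arma::exp(eta);
    double dev = deviance_glm(y, mu, theta, poisson);
    if (std::abs(dev - dev_old) / (std::abs(dev) + 0.1) < tol) {
      converged = true;
      break;
    }
    dev_old = dev;
  }
  return converged;
}

static double theta_score(const arma::vec& y, const arma::vec& mu,
                          double th) {
  double score = 0.0;
  for (arma::uword j = 0; j < y.n_elem; ++j) {
    double yj = y[j], mj = mu[j];
    score += R::digamma(th + yj) - R::digamma(th) + std::log(th) +
      1.0 - std::log(th + mj) - (yj + th) / (mj + th);
  }
  return score;
}

// ML estimate of the NB size parameter theta given fitted means
static double theta_ml(const arma::vec& y, const arma::vec& mu,
                       double theta0, double cap, int maxit) {
  // likelihood still increasing at the cap: dispersion diverges
  // (variance <= mean), signal a Poisson fallback
  if (theta_score(y, mu, cap) >= 0) return cap * 2.0;
  double th = theta0;
  if (!(th > 0) || !std::isfinite(th)) th = 1.0;
  if (th > cap) return cap * 2.0;
  for (int it = 0; it < maxit; ++it) {
    double score = 0.0, info = 0.0;
    for (arma::uword j = 0; j < y.n_elem; ++j) {
      double yj = y[j], mj = mu[j];
      score += R::digamma(th + yj) - R::digamma(th) + std::log(th) +
        1.0 - std::log(th + mj) - (yj + th) / (mj + th);
      info += -R::trigamma(th + yj) + R::trigamma(th) - 1.0 / th +
        2.0 / (mj + th) - (yj + th) / ((mj + th) * (mj + th));
    }
    // `info` as accumulated above is already the negative curvature
    if (info <= 0) break;
    double del = score / info;
    th += del;
    if (th > cap) return cap * 2.0;
    if (th <= 0) th = 1e-3;
    if (std::abs(del) < 1e-8 * (th + 1.0)) break;
  }
  return th;
}

// full automatic fit: Poisson start, then NB with ML theta unless the
// dispersion diverges (variance ~ mean), in which case Poisson is kept
struct GlmFit {
  arma::vec beta;
  arma::vec mu;
  double theta;     // Inf for Poisson
  bool poisson;
  bool converged;
  double deviance;
  double loglik;
};

// family: 0 auto, 1 negbin, 2 poisson
static GlmFit fit_species(const arma::mat& X, const arma::vec& y,
                          int family, double theta_cap, int maxit,
                          double tol) {
  GlmFit f;
  f.converged = irls_fit(X, y, 0.0, true, f.beta, f.mu, maxit, tol);
  f.poisson = true;
  f.theta = R_PosInf;
  if (family != 2) {
    // moment start for theta
    double num = 0.0, den = 0.0;
    for (arma::uword j = 0; j < y.n_elem; ++j) {
      num += f.mu[j] * f.mu[j];
      den += (y[j] - f.mu[j]) * (y[j] - f.mu[j]) - f.mu[j];
    }
    double th = (den > 0) ? num / den : theta_cap * 2.0;
    bool diverged = false;
    arma::vec beta = f.beta, mu = f.mu;
    for (int outer = 0; outer < 25; ++outer) {
      th = theta_ml(y, mu, th, theta_cap, 30);
      if (th > theta_cap) { diverged = true; break; }
      double th_old = th;
      irls_fit(X, y, th, false, beta, mu, maxit, tol);
      th = theta_ml(y, mu, th, theta_cap, 30);
      if (th > theta_cap) { diverged = true; break; }
      if (std::abs(th - th_old) < 1e-6 * (th + 1.0)) break;
    }
    if (!diverged && family == 1 && !(th > 0)) th = 1e-3;
    if (!diverged) {
      f.poisson = false;
      f.theta = th;
      f.beta = beta;
      f.mu = mu;
      f.converged = true;
    } else if (family == 1) {
      // NB requested but dispersion diverged: keep a large-theta NB
      f.poisson = false;
      f.theta = theta_cap;
      irls_fit(X, y, f.theta, false, f.beta, f.mu, maxit, tol);
    }
  }
  f.deviance = deviance_glm(y, f.mu, f.theta, f.poisson);
  f.loglik = loglik_glm(y, f.mu, f.theta, f.poisson);
  return f;
}

// [[Rcpp::export]]
List cpp_glm_fit(const arma::mat& X, const arma::vec& y, int family,
                 double theta_cap, int maxit, double tol) {
  GlmFit f = fit_species(X, y, family, theta_cap, maxit, tol);
  return List::create(
    _["coefficients"] = NumericVector(f.beta.begin(), f.beta.end()),
    _["fitted"] = NumericVector(f.mu.begin(), f.mu.end()),
    _["theta"] = f.theta,
    _["family"] = f.poisson ? "poisson" : "negbin",
    _["deviance"] = f.deviance,
    _["loglik"] = f.loglik,
    _["converged"] = f.converged);
}

static inline double cdf_count(double y, double mu, double theta,
                               bool poisson) {
  if (y < 0) return 0.0;
  return poisson ? R::ppois(y, mu, 1, 0)
                 : R::pnbinom_mu(y, theta, mu, 1, 0);
}

static inline double q_count(double u, double mu, double theta,
                             bool poisson) {
  return poisson ? R::qpois(u, mu, 1, 0)
                 : R::qnbinom_mu(u, theta, mu, 1, 0);
}

// Sequential multivariate analysis of deviance with PIT residual
// bootstrap. Xlist holds the nested design matrices X_0 (intercept) ...
// X_T (full); Y is sites x species. Per species the dispersion is
// estimated once on the full model (Poisson fallback past theta_cap) and
// held fixed across the nested sequence so the per-term deviance
// reductions telescope exactly. For each sequential comparison the null
// datasets are synthesized from the smaller model's fit: PIT residuals
// u ~ U(F(y-1), F(y)), site rows resampled jointly across species
// (method 0) or jointly permuted (method 1), then inverted through each
// site's null quantile function.
// [[Rcpp::export]]
List cpp_anova_pit(List Xlist, const arma::mat& Y, int n_resamples,
                   int method, int family, double theta_cap, int maxit,
                   double tol) {
  int n_models = Xlist.size();
  int T = n_models - 1;
  arma::uword n = Y.n_rows, K = Y.n_cols;
  std::vector<arma::mat> X(n_models);
  for (int i = 0; i < n_models; ++i)
    X[i] = as<arma::mat>(Xlist[i]);

  // observed fits
  arma::mat dev(n_models, K);
  arma::vec thetas(K);
  LogicalVector pois(K);
  // store null-model means for every comparison: mus[i] is n x K for X_i
  std::vector<arma::mat> mus(n_models, arma::mat(n, K));
  for (arma::uword k = 0; k < K; ++k) {
    arma::vec y = Y.col(k);
    GlmFit full = fit_species(X[n_models - 1], y, family, theta_cap,
                              maxit, tol);
    thetas[k] = full.theta;
    pois[k] = full.poisson;
    dev(n_models - 1, k) = full.deviance;
    mus[n_models - 1].col(k) = full.mu;
    for (int i = 0; i < n_models - 1; ++i) {
      arma::vec beta, mu;
      irls_fit(X[i], y, full.theta, full.poisson, beta, mu, maxit, tol);
      dev(i, k) = deviance_glm(y, mu, full.theta, full.poisson);
      mus[i].col(k) = mu;
    }
  }
  arma::vec obs(T);
  for (int i = 1; i < n_models; ++i)
    obs[i - 1] = arma::accu(dev.row(i - 1) - dev.row(i));

  // resampling
  arma::mat null_stats(n_resamples, T);
  arma::mat Ystar(n, K);
  std::vector<int> idx(n);
  for (int i = 1; i < n_models; ++i) {
    const arma::mat& mu0 = mus[i - 1];
    // PIT bounds under the comparison's null fit
    arma::mat Flo(n, K), Fhi(n, K);
    for (arma::uword k = 0; k < K; ++k)
      for (arma::uword j = 0; j < n; ++j) {
        Flo(j, k) = cdf_count(Y(j, k) - 1.0, mu0(j, k), thetas[k],
                              pois[k]);
        Fhi(j, k) = cdf_count(Y(j, k), mu0(j, k), thetas[k], pois[k]);
      }
    for (int b = 0; b < n_resamples; ++b) {
      // joint row resample / permutation of the u-matrix
      if (method == 0) {
        for (arma::uword j = 0; j < n; ++j) {
          int r = (int)(unif_rand() * n);
          if (r >= (int)n) r = n - 1;
          idx[j] = r;
        }
      } else {
        for (arma::uword j = 0; j < n; ++j) idx[j] = j;
        for (arma::uword j = n - 1; j > 0; --j) {
          int r = (int)(unif_rand() * (j + 1));
          if (r > (int)j) r = j;
          std::swap(idx[j], idx[r]);
        }
      }
      for (arma::uword k = 0; k < K; ++k)
        for (arma::uword j = 0; j < n; ++j) {
          int s = idx[j];
          double u = Flo(s, k) +
            unif_rand() * (Fhi(s, k) - Flo(s, k));
          if (u < 1e-12) u = 1e-12;
          if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
          Ystar(j, k) = q_count(u, mu0(j, k), thetas[k], pois[k]);
        }
      double stat = 0.0;
      for (arma::uword k = 0; k < K; ++k) {
        arma::vec ys = Ystar.col(k);
        if (arma::accu(ys) <= 0) continue; // degenerate resample column
        GlmFit fu = fit_species(X[i], ys, family, theta_cap, maxit, tol);
        arma::vec beta, mu;
        irls_fit(X[i - 1], ys, fu.theta, fu.poisson, beta, mu, maxit,
                 tol);
        stat += deviance_glm(ys, mu, fu.theta, fu.poisson) - fu.deviance;
      }
      null_stats(b, i - 1) = stat;
    }
  }
  return List::create(
    _["observed"] = NumericVector(obs.begin(), obs.end()),
    _["null_stats"] = wrap(null_stats),
    _["deviances"] = wrap(dev),
    _["theta"] = NumericVector(thetas.begin(), thetas.end()),
    _["poisson"] = pois);
}

// one checkerboard swap attempt; returns true if a swap happened
static inline bool swap_attempt(IntegerMatrix& m, int nr, int nc) {
  int i = (int)(unif_rand() * nr); if (i >= nr) i = nr - 1;
  int j = (int)(unif_rand() * (nr - 1)); if (j >= nr - 1) j = nr - 2;
  if (j >= i) ++j;
  int k = (int)(unif_rand() * nc); if (k >= nc) k = nc - 1;
  int l = (int)(unif_rand() * (nc - 1)); if (l >= nc - 1) l = nc - 2;
  if (l >= k) ++l;
  int a = m(i, k), b = m(i, l), c = m(j, k), d = m(j, l);
  if ((a == 1 && d == 1 && b == 0 && c == 0) ||
      (a == 0 && d == 0 && b == 1 && c == 1)) {
    m(i, k) = 1 - a; m(i, l) = 1 - b; m(j, k) = 1 - c; m(j, l) = 1 - d;
    return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_swap_run(IntegerMatrix presence, double n_attempts) {
  IntegerMatrix m = clone(presence);
  int nr = m.nrow(), nc = m.ncol();
  double swapped = 0;
  if (nr >= 2 && nc >= 2)
    for (double a = 0; a < n_attempts; ++a)
      if (swap_attempt(m, nr, nc)) ++swapped;
  return List::create(_["matrix"] = m, _["n_swapped"] = swapped);
}

// sequential chain: burn-in attempts, then one sample every `thin`
// attempts
// [[Rcpp::export]]
List cpp_swap_samples(IntegerMatrix presence, int n_samples,
                      double burn_in, double thin) {
  IntegerMatrix m = clone(presence);
  int nr = m.nrow(), nc = m.ncol();
  List out(n_samples);
  if (nr < 2 || nc < 2) {
    for (int s = 0; s < n_samples; ++s) out[s] = clone(m);
    return out;
  }
  for (double a = 0; a < burn_in; ++a) swap_attempt(m, nr, nc);
  for (int s = 0; s < n_samples; ++s) {
    for (double a = 0; a < thin; ++a) swap_attempt(m, nr, nc);
    out[s] = clone(m);
  }
  return out;
}
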