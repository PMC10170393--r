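// IRLS fitter for the binomial GLM with complementary log-log link, plus a
// parametric-bootstrap driver for likelihood-ratio statistics across the
// columns of a multivariate binary response. Kept in C++ because the
// resampling inference refits both nested models B times per response
// column.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MU_EPS = 1e-10;   // fitted probabilities clamped to
                                      // [MU_EPS, 1 - MU_EPS]
static const double ETA_LO = -30.0, ETA_HI = 3.0;

static inline double clamp_mu(double m) {
  if (m < MU_EPS) return MU_EPS;
  if (m > 1.0 - MU_EPS) return 1.0 - MU_EPS;
  return m;
}

static double binary_deviance(const vec &y, const vec &mu) {
  double d = 0.0;
  for (uword i = 0; i < y.n_elem; ++i) {
    double m = clamp_mu(mu[i]);
    d += y[i] * std::log(m) + (1.0 - y[i]) * std::log(1.0 - m);
  }
  return -2.0 * d;
}

struct CllFit {
  vec beta;
  vec mu;
  double dev;
  bool converged;
  int iter;
};

// One IRLS fit; tol on the deviance change, 100 iterations max.
// Separated responses (all-0 or all-1) are returned flagged, with the
// clamped empirical mean as the fit, which gives them a near-zero
// deviance contribution in either nested model.
static CllFit irls_cloglog(const vec &y, const mat &X,
                           int maxit = 100, double tol = 1e-8) {
  uword n = X.n_rows, p = X.n_cols;
  CllFit fit;
  double ybar = mean(y);
  if (ybar <= 0.0 || ybar >= 1.0) {
    fit.beta = zeros<vec>(p);
    fit.mu = vec(n, fill::value(clamp_mu(ybar)));
    fit.beta[0] = std::log(-std::log(1.0 - clamp_mu(ybar)));
    fit.dev = binary_deviance(y, fit.mu);
    fit.converged = false;
    fit.iter = 0;
    return fit;
  }

  vec mu(n), eta(n), beta = zeros<vec>(p);
  for (uword i = 0; i < n; ++i) {
    double m0 = (y[i] + 0.5) / 2.0;
    mu[i] = m0;
    eta[i] = std::log(-std::log(1.0 - m0));
  }
  double dev = binary_deviance(y, mu);
  bool conv = false;
  int it = 0;
  for (; it < maxit; ++it) {
    vec w(n), z(n);
    for (uword i = 0; i < n; ++i) {
      double e = std::min(std::max(eta[i], ETA_LO), ETA_HI);
      double dmu = std::exp(e - std::exp(e));       // d mu / d eta
      double m = clamp_mu(mu[i]);
      double v = m * (1.0 - m);
      if (dmu < 1e-12) dmu = 1e-12;
      w[i] = dmu * dmu / v;
      z[i] = e + (y[i] - m) / dmu;
    }
    mat Xw = X.each_col() % w;
    mat A = X.t() * Xw;
    vec b = Xw.t() * z;
    vec beta_new;
    bool ok = solve(beta_new, A, b, solve_opts::no_approx);
    if (!ok) break;

    // step-halving if the deviance fails to decrease
    double step = 1.0;
    vec beta_try, eta_try, mu_try;
    double dev_try = datum::inf;
    for (int h = 0; h < 30; ++h) {
      beta_try = beta + step * (beta_new - beta);
      eta_try = X * beta_try;
      mu_try = vec(eta_try.n_elem);
      for (uword i = 0; i < n; ++i) {
        double e = std::min(std::max(eta_try[i], ETA_LO), ETA_HI);
        mu_try[i] = clamp_mu(-std::expm1(-std::exp(e)));
      }
      dev_try = binary_deviance(y, mu_try);
      if (std::isfinite(dev_try) && dev_try <= dev + 1e-10) break;
      step *= 0.5;
    }
    if (!std::isfinite(dev_try)) break;
    beta = beta_try; eta = eta_try; mu = mu_try;
    if (std::fabs(dev - dev_try) < tol) {
      dev = dev_try;
      conv = true;
      ++it;
      break;
    }
    dev = dev_try;
  }
  fit.beta = beta;
  fit.mu = mu;
  fit.dev = dev;
  fit.converged = conv;
  fit.iter = it;
  return fit;
}

// [[Rcpp::export]]
Rcpp::List cloglog_fit_cpp(const arma::vec &y, const arma::mat &X,
                           int maxit = 100, double tol = 1e-8) {
  CllFit f = irls_cloglog(y, X, maxit, tol);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = f.beta,
      Rcpp::Named("fitted") = f.mu,
      Rcpp::Named("deviance") = f.dev,
      Rcpp::Named("converged") = f.converged,
      Rcpp::Named("iter") = f.iter);
}

// Deviances of one model over every column of a binary response matrix.
// [[Rcpp::export]]
arma::vec many_dev_cpp(const arma::mat &Y, const arma::mat &X) {
  vec out(Y.n_cols);
  for (uword g = 0; g < Y.n_cols; ++g)
    out[g] = irls_cloglog(Y.col(g), X).dev;
  return out;
}

// Parametric bootstrap of per-column LR statistics: simulate each column
// from the reduced model's fitted probabilities (uses R's RNG, so results
// follow set.seed()), refit both nested models, return a B x G matrix of
// deviance differences.
// [[Rcpp::export]]
arma::mat lr_boot_cpp(const arma::mat &mu_reduced, const arma::mat &Xfull,
                      const arma::mat &Xred, int B) {
  uword n = mu_reduced.n_rows, G = mu_reduced.n_cols;
  mat stats(B, G);
  vec y(n);
  Rcpp::RNGScope scope;
  for (int b = 0; b < B; ++b) {
    for (uword g = 0; g < G; ++g) {
      for (uword i = 0; i < n; ++i)
        y[i] = (R::unif_rand() < mu_reduced(i, g)) ? 1.0 : 0.0;
      double devf = irls_cloglog(y, Xfull).dev;
      double devr = irls_cloglog(y, Xred).dev;
      double s = devr - devf;
      stats(b, g) = (s > 0.0) ? s : 0.0;
    }
  }
  return stats;
}
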