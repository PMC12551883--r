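// Numerical kernels for exact ARMA likelihood evaluation.
//
// The hot path during fitting is the concentrated negative log-likelihood
// evaluated thousands of times per series by a quasi-Newton optimizer, so the
// Durbin-Levinson coefficient transform, the stationary (Lyapunov)
// initialization and the Kalman recursions all live here. The filter loop is
// written with plain arrays (no matrix temporaries) and switches to the
// steady-state gain once the state covariance has converged, which makes the
// per-observation cost O(r) for most of a long series.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double F_FLOOR = 1e-12;   // innovation-variance floor
static const double BIG = 1e10;        // penalty for degenerate points

// Durbin-Levinson expansion: partial autocorrelations -> AR coefficients.
// Always maps (-1,1)^p into the causal region.
static arma::vec dl_expand(const arma::vec& xi) {
  const int p = xi.n_elem;
  arma::vec a(p, arma::fill::zeros);
  arma::vec prev(p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    a[i] = xi[i];
    for (int h = 0; h < i; ++h) a[h] = prev[h] - xi[i] * prev[i - 1 - h];
    prev = a;
  }
  return a;
}

// [[Rcpp::export(name = ".dl_expand_cpp")]]
NumericVector dl_expand_cpp(NumericVector xi) {
  arma::vec v(xi.begin(), xi.size());
  return wrap(dl_expand(v));
}

// Stationary state covariance of the companion form (unit innovation
// variance): solves P = T P T' + Q Q' through the r^2 x r^2 linear system.
static bool stationary_P(const std::vector<double>& phi,
                         const std::vector<double>& theta,
                         int r, std::vector<double>& P) {
  arma::mat T(r, r, arma::fill::zeros);
  for (int i = 0; i < (int)phi.size(); ++i) T(i, 0) = phi[i];
  for (int i = 0; i + 1 < r; ++i) T(i, i + 1) = 1.0;
  arma::vec Q(r, arma::fill::zeros);
  Q[0] = 1.0;
  for (int j = 0; j < (int)theta.size(); ++j) Q[j + 1] = theta[j];
  arma::mat Pm;
  if (r == 1) {
    double t = T(0, 0);
    if (std::abs(t) >= 1.0) return false;
    Pm = (Q * Q.t()) / (1.0 - t * t);
  } else {
    arma::mat A = arma::eye(r * r, r * r) - arma::kron(T, T);
    arma::vec vecP;
    if (!arma::solve(vecP, A, arma::vectorise(Q * Q.t()),
                     arma::solve_opts::no_approx) ||
        !vecP.is_finite())
      return false;
    Pm = arma::reshape(vecP, r, r);
    Pm = 0.5 * (Pm + Pm.t());
  }
  P.assign(Pm.begin(), Pm.end());
  return true;
}

// [[Rcpp::export(name = ".stationary_cov_cpp")]]
NumericMatrix stationary_cov_cpp(NumericVector phi, NumericVector theta,
                                 double sigma2) {
  const int p = phi.size(), q = theta.size();
  const int r = std::max(p, q + 1);
  std::vector<double> ph(phi.begin(), phi.end());
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> P;
  if (!stationary_P(ph, th, r, P))
    stop("no stationary solution: model is not causal");
  NumericMatrix out(r, r);
  for (int i = 0; i < r * r; ++i) out[i] = sigma2 * P[i];
  return out;
}

// One pass of the Kalman filter in sigma^2-free units; column-major P.
// Missing values (NaN) contribute prediction steps only. Returns false on
// numerical failure.
static bool kalman_pass(const std::vector<double>& phi,
                        const std::vector<double>& theta,
                        const double* x, int n, double mu,
                        double& sumlogF, double& ssq, int& nobs) {
  const int p = phi.size(), q = theta.size();
  const int r = std::max(p, q + 1);
  std::vector<double> P;
  if (!stationary_P(phi, theta, r, P)) return false;

  std::vector<double> Tfirst(r, 0.0);          // first column of T
  for (int i = 0; i < p; ++i) Tfirst[i] = phi[i];
  std::vector<double> Q(r, 0.0);
  Q[0] = 1.0;
  for (int j = 0; j < q; ++j) Q[j + 1] = theta[j];

  std::vector<double> z(r, 0.0), znew(r), M(r * r), K(r), Prow0(r);
  std::vector<double> Ppred_prev(r * r, -1.0);
  bool steady = false;
  bool has_na = false;
  for (int t = 0; t < n; ++t) if (std::isnan(x[t])) { has_na = true; break; }

  sumlogF = 0.0; ssq = 0.0; nobs = 0;
  double Fs = 0.0;                              // steady-state F
  std::vector<double> Ks(r, 0.0);               // steady-state gain

  for (int t = 0; t < n; ++t) {
    // state prediction: (Tz)_i = phi_{i+1} z_0 + z_{i+1}
    for (int i = 0; i < r; ++i)
      znew[i] = Tfirst[i] * z[0] + (i + 1 < r ? z[i + 1] : 0.0);
    z.swap(znew);

    if (steady) {
      if (std::isnan(x[t])) { steady = false; }   // fall back to full filter
      else {
        double v = x[t] - mu - z[0];
        sumlogF += std::log(Fs);
        ssq += v * v / Fs;
        ++nobs;
        for (int i = 0; i < r; ++i) z[i] += Ks[i] * v;
        continue;
      }
    }

    // covariance prediction: P <- T P T' + Q Q'
    // M = T P  (row i of M = phi_{i+1} * P.row(0) + P.row(i+1))
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < r; ++i)
        M[i + j * r] = Tfirst[i] * P[0 + j * r] +
                       (i + 1 < r ? P[(i + 1) + j * r] : 0.0);
    // P = M T' + QQ'   (column j of P = phi_{j+1} * M.col(0) + M.col(j+1))
    // convergence is judged on successive *predicted* covariances
    double delta = 0.0;
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < r; ++i) {
        double v = Tfirst[j] * M[i + 0 * r] +
                   (j + 1 < r ? M[i + (j + 1) * r] : 0.0) + Q[i] * Q[j];
        delta = std::max(delta, std::abs(v - Ppred_prev[i + j * r]));
        Ppred_prev[i + j * r] = v;
        P[i + j * r] = v;
      }
    const double ptol = 1e-12 * (1.0 + std::abs(P[0]));

    if (std::isnan(x[t])) continue;

    double F = P[0];
    if (F < F_FLOOR) F = F_FLOOR;
    double v = x[t] - mu - z[0];
    sumlogF += std::log(F);
    ssq += v * v / F;
    ++nobs;
    for (int i = 0; i < r; ++i) { K[i] = P[i] / F; Prow0[i] = P[i * r]; }
    for (int i = 0; i < r; ++i) z[i] += K[i] * v;
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < r; ++i)
        P[i + j * r] -= K[i] * Prow0[j];
    // symmetrize
    for (int j = 0; j < r; ++j)
      for (int i = 0; i < j; ++i) {
        double s = 0.5 * (P[i + j * r] + P[j + i * r]);
        P[i + j * r] = P[j + i * r] = s;
      }
    // steady-state switch: covariance recursion has converged and the
    // updated P will keep reproducing itself (no missing data ahead to
    // perturb the recursion pattern)
    if (!has_na && delta < ptol) {
      steady = true;
      Fs = F;
      for (int i = 0; i < r; ++i) Ks[i] = K[i];
    }
  }
  return std::isfinite(sumlogF) && std::isfinite(ssq);
}

// [[Rcpp::export(name = ".kalman_pieces_cpp")]]
List kalman_pieces_cpp(NumericVector phi, NumericVector theta,
                       NumericVector x, double mu) {
  std::vector<double> ph(phi.begin(), phi.end());
  std::vector<double> th(theta.begin(), theta.end());
  double sumlogF, ssq; int nobs;
  if (!kalman_pass(ph, th, x.begin(), x.size(), mu, sumlogF, ssq, nobs))
    return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["sumlogF"] = sumlogF,
                      _["ssq"] = ssq, _["nobs"] = nobs);
}

// Concentrated negative log-likelihood (sigma^2 profiled out, additive
// constant -n/2 (log 2*pi + 1) dropped) as a function of the optimizer
// parameter vector. With transform = true the coefficients are tanh-bounded
// partial autocorrelations expanded through Durbin-Levinson, so every
// iterate is causal and invertible; with transform = false the vector holds
// raw coefficients (used for CSS starts, Hessians and profile refits; the
// AR block must then be causal for the filter to have a stationary start,
// while a non-invertible MA block is allowed).
// par = (ar block [p], ma block [q], mu if include_mean).
// [[Rcpp::export(name = ".arma_obj_cpp")]]
double arma_obj_cpp(NumericVector par, NumericVector x, int p, int q,
                    bool include_mean, bool transform) {
  std::vector<double> phi(p), theta(q);
  if (transform) {
    arma::vec xi_ar(p), xi_ma(q);
    for (int i = 0; i < p; ++i) {
      double u = std::tanh(par[i]);
      xi_ar[i] = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, u));
    }
    for (int j = 0; j < q; ++j) {
      double u = std::tanh(par[p + j]);
      xi_ma[j] = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, u));
    }
    arma::vec ph = dl_expand(xi_ar), th = -dl_expand(xi_ma);
    for (int i = 0; i < p; ++i) phi[i] = ph[i];
    for (int j = 0; j < q; ++j) theta[j] = th[j];
  } else {
    for (int i = 0; i < p; ++i) phi[i] = par[i];
    for (int j = 0; j < q; ++j) theta[j] = par[p + j];
  }
  double mu = include_mean ? par[p + q] : 0.0;
  double sumlogF, ssq; int nobs;
  if (!kalman_pass(phi, theta, x.begin(), x.size(), mu, sumlogF, ssq, nobs))
    return BIG;
  if (nobs == 0 || ssq <= 0.0) return BIG;
  double val = 0.5 * (nobs * std::log(ssq / nobs) + sumlogF);
  return std::isfinite(val) ? val : BIG;
}

// Conditional sum of squares: residual recursion on the de-meaned series with
// pre-sample innovations set to zero; sum over t = p+1, ..., n.
// [[Rcpp::export(name = ".css_cpp")]]
List css_cpp(NumericVector phi, NumericVector theta, NumericVector x,
             double mu) {
  const int p = phi.size(), q = theta.size(), n = x.size();
  std::vector<double> w(n, 0.0);
  double ssq = 0.0;
  for (int t = p; t < n; ++t) {
    double wt = x[t] - mu;
    for (int i = 0; i < p; ++i) wt -= phi[i] * (x[t - 1 - i] - mu);
    for (int j = 0; j < q; ++j)
      if (t - 1 - j >= 0) wt -= theta[j] * w[t - 1 - j];
    w[t] = wt;
    ssq += wt * wt;
  }
  return List::create(_["ssq"] = ssq, _["resid"] = wrap(w));
}

// State-space simulation: z_t = T z_{t-1} + Q w_t, x_t = z_t[0] + mu, from
// supplied innovations w and initial state z0 (drawn in R so that all
// randomness flows through R's RNG).
// [[Rcpp::export(name = ".arma_sim_cpp")]]
NumericVector arma_sim_cpp(NumericVector phi, NumericVector theta,
                           NumericVector w, NumericVector z0, double mu) {
  const int p = phi.size(), q = theta.size();
  const int r = std::max(p, q + 1);
  std::vector<double> Tfirst(r, 0.0), Q(r, 0.0);
  for (int i = 0; i < p; ++i) Tfirst[i] = phi[i];
  Q[0] = 1.0;
  for (int j = 0; j < q; ++j) Q[j + 1] = theta[j];
  std::vector<double> z(z0.begin(), z0.end()), znew(r);
  const int n = w.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < r; ++i)
      znew[i] = Tfirst[i] * z[0] + (i + 1 < r ? z[i + 1] : 0.0) + Q[i] * w[t];
    z.swap(znew);
    out[t] = z[0] + mu;
  }
  return out;
}
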