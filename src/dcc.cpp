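// Quasi-likelihoods and filters for the two-stage DCC estimator.
// Stage 1: univariate GARCH(1,1) per region; stage 2: scalar DCC(1,1)
// with correlation targeting. All recursions are O(T) resp. O(T p^2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BIG = 1e10;

// Conditional-variance filter h_t = omega + alpha x_{t-1}^2 + beta h_{t-1},
// h_1 fixed at `h1` (unconditional warm-up).
// [[Rcpp::export]]
arma::vec garch11_filter_cpp(const arma::vec& x, double omega, double alpha,
                             double beta, double h1) {
  const arma::uword T = x.n_elem;
  arma::vec h(T);
  h(0) = h1;
  for (arma::uword t = 1; t < T; ++t) {
    h(t) = omega + alpha * x(t - 1) * x(t - 1) + beta * h(t - 1);
  }
  return h;
}

// Negative Gaussian quasi-log-likelihood 0.5 * sum(log h_t + x_t^2 / h_t).
// [[Rcpp::export]]
double garch11_negll_cpp(const arma::vec& x, double omega, double alpha,
                         double beta, double h1) {
  if (omega <= 0.0 || alpha < 0.0 || beta < 0.0 || alpha + beta >= 1.0)
    return BIG;
  const arma::uword T = x.n_elem;
  double h = h1, nll = 0.0;
  for (arma::uword t = 0; t < T; ++t) {
    if (t > 0) h = omega + alpha * x(t - 1) * x(t - 1) + beta * h;
    if (h <= 0.0 || !std::isfinite(h)) return BIG;
    nll += 0.5 * (std::log(h) + x(t) * x(t) / h);
  }
  return std::isfinite(nll) ? nll : BIG;
}

// Second-stage negative quasi-log-likelihood for scalar DCC(1,1) with
// correlation targeting: Q_t = (1-a-b) Qbar + a z_{t-1} z_{t-1}' + b Q_{t-1},
// Q_1 = Qbar, R_t = D_t^{-1/2} Q_t D_t^{-1/2}. Contribution per frame is
// 0.5 * (log|R_t| + z_t' R_t^{-1} z_t - z_t' z_t).
// [[Rcpp::export]]
double dcc_negll_cpp(const arma::mat& Z, const arma::mat& Qbar, double a,
                     double b) {
  if (a < 0.0 || b < 0.0 || a + b >= 1.0) return BIG;
  const arma::uword T = Z.n_rows, p = Z.n_cols;
  arma::mat Q = Qbar, R(p, p), L(p, p);
  arma::vec z = Z.row(0).t(), d(p), u(p);
  double nll = 0.0;
  for (arma::uword t = 0; t < T; ++t) {
    if (t > 0) {
      Q = (1.0 - a - b) * Qbar + a * (z * z.t()) + b * Q;
      z = Z.row(t).t();
    }
    d = 1.0 / arma::sqrt(Q.diag());
    R = Q % (d * d.t());
    if (!arma::chol(L, R, "lower")) return BIG;
    double logdet = 2.0 * arma::sum(arma::log(L.diag()));
    u = arma::solve(arma::trimatl(L), z, arma::solve_opts::fast);
    nll += 0.5 * (logdet + arma::dot(u, u) - arma::dot(z, z));
  }
  return std::isfinite(nll) ? nll : BIG;
}

// Framewise correlation matrices R_t implied by (a, b, Qbar); returns a
// p x p x T cube. Same recursion as the likelihood, no smoothing.
// [[Rcpp::export]]
arma::cube dcc_filter_cpp(const arma::mat& Z, const arma::mat& Qbar, double a,
                          double b) {
  const arma::uword T = Z.n_rows, p = Z.n_cols;
  arma::cube Rout(p, p, T);
  arma::mat Q = Qbar;
  arma::vec z = Z.row(0).t(), d(p);
  for (arma::uword t = 0; t < T; ++t) {
    if (t > 0) {
      Q = (1.0 - a - b) * Qbar + a * (z * z.t()) + b * Q;
      z = Z.row(t).t();
    }
    d = 1.0 / arma::sqrt(Q.diag());
    Rout.slice(t) = Q % (d * d.t());
  }
  return Rout;
}

// ---- Bivariate (pairwise) DCC ------------------------------------------
// Specialized closed-form 2x2 likelihood and an in-C++ Nelder-Mead so that
// all p(p-1)/2 pair fits run without R-level overhead.

static double negll_pair(const arma::vec& z1, const arma::vec& z2,
                         double v1, double v2, double r12, double a,
                         double b) {
  if (a < 0.0 || b < 0.0 || a + b >= 1.0) return BIG;
  const arma::uword T = z1.n_elem;
  double q11 = v1, q22 = v2, q12 = r12, nll = 0.0;
  double z1p = z1(0), z2p = z2(0);
  for (arma::uword t = 0; t < T; ++t) {
    if (t > 0) {
      q11 = (1.0 - a - b) * v1 + a * z1p * z1p + b * q11;
      q22 = (1.0 - a - b) * v2 + a * z2p * z2p + b * q22;
      q12 = (1.0 - a - b) * r12 + a * z1p * z2p + b * q12;
      z1p = z1(t); z2p = z2(t);
    }
    double r = q12 / std::sqrt(q11 * q22);
    double om = 1.0 - r * r;
    if (om <= 1e-12) return BIG;
    nll += 0.5 * (std::log(om) +
                  (z1p * z1p + z2p * z2p - 2.0 * r * z1p * z2p) / om -
                  (z1p * z1p + z2p * z2p));
  }
  return std::isfinite(nll) ? nll : BIG;
}

// logistic map shared with the R side: theta -> (a, b), a,b >= 0,
// a + b <= 0.998
static void ab_map(const double* th, double* ab) {
  double m = std::max(0.0, std::max(th[0], th[1]));
  double e0 = std::exp(-m), e1 = std::exp(th[0] - m), e2 = std::exp(th[1] - m);
  double den = e0 + e1 + e2;
  ab[0] = 0.998 * e1 / den;
  ab[1] = 0.998 * e2 / den;
}

// 2-D Nelder-Mead on the transformed parameters.
template <typename F>
static void nm2(F f, double* x, double* fx, double reltol, int maxit) {
  const int n = 2;
  double s[3][2], fv[3];
  for (int i = 0; i < 3; ++i) {
    s[i][0] = x[0]; s[i][1] = x[1];
    if (i > 0) s[i][i - 1] += 0.5;
    fv[i] = f(s[i]);
  }
  for (int it = 0; it < maxit; ++it) {
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    if (std::fabs(fv[hi] - fv[lo]) <
        reltol * (std::fabs(fv[lo]) + reltol)) break;
    double cen[2] = {0, 0};
    for (int i = 0; i < 3; ++i)
      if (i != hi) { cen[0] += s[i][0]; cen[1] += s[i][1]; }
    cen[0] /= n; cen[1] /= n;
    double xr[2] = {cen[0] + (cen[0] - s[hi][0]),
                    cen[1] + (cen[1] - s[hi][1])};
    double fr = f(xr);
    if (fr < fv[lo]) {
      double xe[2] = {cen[0] + 2.0 * (cen[0] - s[hi][0]),
                      cen[1] + 2.0 * (cen[1] - s[hi][1])};
      double fe = f(xe);
      if (fe < fr) { s[hi][0] = xe[0]; s[hi][1] = xe[1]; fv[hi] = fe; }
      else { s[hi][0] = xr[0]; s[hi][1] = xr[1]; fv[hi] = fr; }
    } else if (fr < fv[hi]) {
      s[hi][0] = xr[0]; s[hi][1] = xr[1]; fv[hi] = fr;
    } else {
      double xc[2] = {cen[0] + 0.5 * (s[hi][0] - cen[0]),
                      cen[1] + 0.5 * (s[hi][1] - cen[1])};
      double fc = f(xc);
      if (fc < fv[hi]) { s[hi][0] = xc[0]; s[hi][1] = xc[1]; fv[hi] = fc; }
      else { // shrink toward best
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          s[i][0] = s[lo][0] + 0.5 * (s[i][0] - s[lo][0]);
          s[i][1] = s[lo][1] + 0.5 * (s[i][1] - s[lo][1]);
          fv[i] = f(s[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (fv[i] < fv[lo]) lo = i;
  x[0] = s[lo][0]; x[1] = s[lo][1]; *fx = fv[lo];
}

// Fit bivariate DCC(1,1) for every unordered region pair and assemble the
// framewise correlation stack. `starts` is a k x 2 matrix of (a, b)
// starting values; the best by initial likelihood is optimized.
// [[Rcpp::export]]
Rcpp::List dcc_fit_pairwise_cpp(const arma::mat& Z, const arma::mat& starts,
                                double reltol, int maxit) {
  const arma::uword T = Z.n_rows, p = Z.n_cols;
  arma::mat A(p, p, arma::fill::zeros), B(p, p, arma::fill::zeros),
      NLL(p, p, arma::fill::zeros);
  arma::cube R(p, p, T, arma::fill::ones);
  arma::vec vars(p);
  for (arma::uword j = 0; j < p; ++j)
    vars(j) = arma::var(Z.col(j));
  for (arma::uword i = 0; i < p; ++i)
    for (arma::uword j = i + 1; j < p; ++j) {
      arma::vec z1 = Z.col(i), z2 = Z.col(j);
      double r12 = arma::as_scalar(arma::cor(z1, z2)) *
        std::sqrt(vars(i) * vars(j));
      auto f = [&](const double* th) {
        double ab[2];
        ab_map(th, ab);
        return negll_pair(z1, z2, vars(i), vars(j), r12, ab[0], ab[1]);
      };
      // screen the starts
      arma::uword best = 0;
      double bestv = arma::datum::inf;
      for (arma::uword k = 0; k < starts.n_rows; ++k) {
        double pa = std::max(starts(k, 0) / 0.998, 1e-8);
        double pb = std::max(starts(k, 1) / 0.998, 1e-8);
        double p0 = std::max(1.0 - pa - pb, 1e-8);
        double th[2] = {std::log(pa / p0), std::log(pb / p0)};
        double v = f(th);
        if (v < bestv) { bestv = v; best = k; }
      }
      double pa = std::max(starts(best, 0) / 0.998, 1e-8);
      double pb = std::max(starts(best, 1) / 0.998, 1e-8);
      double p0 = std::max(1.0 - pa - pb, 1e-8);
      double th[2] = {std::log(pa / p0), std::log(pb / p0)};
      double fx;
      nm2(f, th, &fx, reltol, maxit);
      double ab[2];
      ab_map(th, ab);
      A(i, j) = A(j, i) = ab[0];
      B(i, j) = B(j, i) = ab[1];
      NLL(i, j) = NLL(j, i) = fx;
      // filter the pair and fill the stack
      double q11 = vars(i), q22 = vars(j), q12 = r12;
      double z1p = z1(0), z2p = z2(0);
      for (arma::uword t = 0; t < T; ++t) {
        if (t > 0) {
          q11 = (1.0 - ab[0] - ab[1]) * vars(i) + ab[0] * z1p * z1p + ab[1] * q11;
          q22 = (1.0 - ab[0] - ab[1]) * vars(j) + ab[0] * z2p * z2p + ab[1] * q22;
          q12 = (1.0 - ab[0] - ab[1]) * r12 + ab[0] * z1p * z2p + ab[1] * q12;
          z1p = z1(t); z2p = z2(t);
        }
        double r = q12 / std::sqrt(q11 * q22);
        R(i, j, t) = r;
        R(j, i, t) = r;
      }
    }
  return Rcpp::List::create(Rcpp::Named("a") = A, Rcpp::Named("b") = B,
                            Rcpp::Named("negll") = NLL,
                            Rcpp::Named("R") = R);
}

// ---- In-C++ GARCH(1,1) fit ---------------------------------------------
// 3-D Nelder-Mead on (log omega, theta_a, theta_b) with the same logistic
// (alpha, beta) map as the R side.

static double garch_obj(const arma::vec& x, double h1, const double* th) {
  double ab[2];
  ab_map(th + 1, ab);
  const arma::uword T = x.n_elem;
  double omega = std::exp(th[0]);
  if (!(omega > 0.0)) return BIG;
  double h = h1, nll = 0.0;
  for (arma::uword t = 0; t < T; ++t) {
    if (t > 0) h = omega + ab[0] * x(t - 1) * x(t - 1) + ab[1] * h;
    if (h <= 0.0 || !std::isfinite(h)) return BIG;
    nll += 0.5 * (std::log(h) + x(t) * x(t) / h);
  }
  return std::isfinite(nll) ? nll : BIG;
}

// [[Rcpp::export]]
Rcpp::List garch11_fit_cpp(const arma::vec& x, double h1,
                           const arma::vec& theta0, double reltol,
                           int maxit) {
  const int n = 3;
  double s[4][3], fv[4];
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j < n; ++j) s[i][j] = theta0(j);
    if (i > 0) s[i][i - 1] += 0.5;
    fv[i] = garch_obj(x, h1, s[i]);
  }
  int it = 0;
  for (; it < maxit; ++it) {
    int lo = 0, hi = 0, hi2 = 0;
    for (int i = 1; i <= n; ++i) {
      if (fv[i] < fv[lo]) lo = i;
      if (fv[i] > fv[hi]) hi = i;
    }
    for (int i = 0; i <= n; ++i)
      if (i != hi && fv[i] > fv[hi2]) hi2 = i;
    if (std::fabs(fv[hi] - fv[lo]) <
        reltol * (std::fabs(fv[lo]) + reltol)) break;
    double cen[3] = {0, 0, 0};
    for (int i = 0; i <= n; ++i)
      if (i != hi) for (int j = 0; j < n; ++j) cen[j] += s[i][j];
    for (int j = 0; j < n; ++j) cen[j] /= n;
    double xr[3], xe[3], xc[3];
    for (int j = 0; j < n; ++j) xr[j] = cen[j] + (cen[j] - s[hi][j]);
    double fr = garch_obj(x, h1, xr);
    if (fr < fv[lo]) {
      for (int j = 0; j < n; ++j) xe[j] = cen[j] + 2.0 * (cen[j] - s[hi][j]);
      double fe = garch_obj(x, h1, xe);
      if (fe < fr) { std::copy(xe, xe + n, s[hi]); fv[hi] = fe; }
      else { std::copy(xr, xr + n, s[hi]); fv[hi] = fr; }
    } else if (fr < fv[hi2]) {
      std::copy(xr, xr + n, s[hi]); fv[hi] = fr;
    } else {
      for (int j = 0; j < n; ++j) xc[j] = cen[j] + 0.5 * (s[hi][j] - cen[j]);
      double fc = garch_obj(x, h1, xc);
      if (fc < fv[hi]) { std::copy(xc, xc + n, s[hi]); fv[hi] = fc; }
      else {
        int lo2 = lo;
        for (int i = 0; i <= n; ++i) {
          if (i == lo2) continue;
          for (int j = 0; j < n; ++j)
            s[i][j] = s[lo2][j] + 0.5 * (s[i][j] - s[lo2][j]);
          fv[i] = garch_obj(x, h1, s[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i <= n; ++i) if (fv[i] < fv[lo]) lo = i;
  arma::vec theta(3);
  for (int j = 0; j < n; ++j) theta(j) = s[lo][j];
  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("value") = fv[lo],
                            Rcpp::Named("convergence") =
                              (it < maxit) ? 0 : 1);
}
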