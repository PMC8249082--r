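// Core numerics: MVAR least-squares fit, GPDC spectrum, circular-shift
// surrogate null, and the VAR simulation recursion.  Kept in one
// translation unit; everything is deterministic given its inputs (all
// randomness -- surrogate shifts, innovation noise -- is drawn on the R
// side so that set.seed() governs the whole pipeline).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multivariate OLS on the lagged design matrix.
// X: n x D (one column per channel), p: model order.
// On success fills A (D x D x p; A(i,j,r) = weight of channel j at lag r+1
// in the equation of channel i), Sigma (residual covariance with
// denominator n_eff - p*D), gram (Z'Z / n_eff) and resid (n_eff x D).
static bool fit_core(const mat& X, const int p, const bool demean,
                     cube& A, mat& Sigma, mat& gram, mat& resid) {
  const int n = X.n_rows, D = X.n_cols;
  if (n <= p * D + p) return false;
  mat Xc = X;
  if (demean) Xc.each_row() -= mean(X, 0);
  const int neff = n - p;
  mat Z(neff, p * D);
  for (int r = 1; r <= p; ++r)
    Z.cols((r - 1) * D, r * D - 1) = Xc.rows(p - r, n - r - 1);
  mat Y = Xc.rows(p, n - 1);
  mat G = Z.t() * Z;
  mat B;
  bool ok = solve(B, G, Z.t() * Y, solve_opts::no_approx);
  if (!ok) return false;
  resid = Y - Z * B;
  const int dfres = neff - p * D;
  if (dfres <= 0) return false;
  Sigma = (resid.t() * resid) / double(dfres);
  if (Sigma.diag().min() <= 0.0 || !Sigma.is_finite()) return false;
  A.set_size(D, D, p);
  for (int r = 0; r < p; ++r)
    A.slice(r) = B.rows(r * D, (r + 1) * D - 1).t();
  gram = G / double(neff);
  return true;
}

// Squared GPDC: out(i,j,f) = (|Abar_ij(f)|^2/sig2_i) / sum_k |Abar_kj(f)|^2/sig2_k
// with Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs).
static cube gpdc_core(const cube& A, const vec& sigma2, const vec& freqs,
                      const double fs) {
  const int D = A.n_rows, p = A.n_slices, F = freqs.n_elem;
  cube out(D, D, F);
  const vec isig = 1.0 / sigma2;
  for (int fi = 0; fi < F; ++fi) {
    const double w = 2.0 * datum::pi * freqs[fi] / fs;
    cx_mat Abar(D, D, fill::eye);
    for (int r = 0; r < p; ++r) {
      const double c = std::cos(w * (r + 1)), s = std::sin(w * (r + 1));
      Abar -= cx_mat(A.slice(r) * c, A.slice(r) * (-s));
    }
    mat num = square(abs(Abar));
    num.each_col() %= isig;
    rowvec den = sum(num, 0);   // column normalization target
    out.slice(fi) = num.each_row() / den;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_mvar(const arma::mat& X, const int p, const bool demean) {
  cube A;
  mat Sigma, gram, resid;
  const bool ok = fit_core(X, p, demean, A, Sigma, gram, resid);
  if (!ok) return Rcpp::List::create(Rcpp::Named("ok") = false);
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("coeffs") = A,
                            Rcpp::Named("noise_cov") = Sigma,
                            Rcpp::Named("gram") = gram,
                            Rcpp::Named("resid") = resid);
}

// [[Rcpp::export]]
arma::cube cpp_gpdc(const arma::cube& A, const arma::vec& sigma2,
                    const arma::vec& freqs, const double fs) {
  return gpdc_core(A, sigma2, freqs, fs);
}

// Surrogate null for one window.  shifts: S x D integer matrix of circular
// offsets (precomputed in R from the seeded RNG).  Each surrogate shifts
// every channel independently, destroying cross-channel lag structure
// while preserving each autospectrum, then refits and recomputes GPDC.
// Returns the observed squared GPDC, the count of null values >= observed
// per (i, j, f), the number of surrogates that failed to fit, and the
// number used.
// [[Rcpp::export]]
Rcpp::List cpp_surrogate_gpdc(const arma::mat& X, const int p,
                              const arma::vec& freqs, const double fs,
                              const arma::imat& shifts, const bool demean) {
  const int n = X.n_rows, D = X.n_cols, S = shifts.n_rows;
  cube A;
  mat Sigma, gram, resid;
  if (!fit_core(X, p, demean, A, Sigma, gram, resid))
    return Rcpp::List::create(Rcpp::Named("ok") = false);
  cube obs = gpdc_core(A, Sigma.diag(), freqs, fs);
  ucube count(obs.n_rows, obs.n_cols, obs.n_slices, fill::zeros);
  int failed = 0;
  mat Xs(n, D);
  for (int s = 0; s < S; ++s) {
    for (int d = 0; d < D; ++d) {
      const int k = ((shifts(s, d) % n) + n) % n;
      if (k == 0) Xs.col(d) = X.col(d);
      else {
        Xs.col(d).head(k) = X.col(d).tail(k);
        Xs.col(d).tail(n - k) = X.col(d).head(n - k);
      }
    }
    cube As;
    mat Ss, Gs, Es;
    if (!fit_core(Xs, p, demean, As, Ss, Gs, Es)) { ++failed; continue; }
    cube nul = gpdc_core(As, Ss.diag(), freqs, fs);
    count += conv_to<ucube>::from(nul >= obs);
  }
  return Rcpp::List::create(Rcpp::Named("ok") = true,
                            Rcpp::Named("gpdc") = obs,
                            Rcpp::Named("count") = count,
                            Rcpp::Named("n_failed") = failed,
                            Rcpp::Named("n_used") = S - failed);
}

// VAR recursion x(t) = sum_r A_r x(t-r) + e(t).
// noise: n x D innovations; init: p x D presample state, init row 1 is
// x(t-1) at the first generated step (most recent first).  Returns n x D.
// [[Rcpp::export]]
arma::mat cpp_simulate_var(const arma::cube& A, const arma::mat& noise,
                           const arma::mat& init) {
  const int p = A.n_slices, D = A.n_cols, n = noise.n_rows;
  mat full(p + n, D);
  // store chronologically: rows 0..p-1 are x(-p)..x(-1)
  for (int r = 0; r < p; ++r) full.row(p - 1 - r) = init.row(r);
  for (int t = p; t < p + n; ++t) {
    rowvec x = noise.row(t - p);
    for (int r = 0; r < p; ++r)
      x += full.row(t - 1 - r) * A.slice(r).t();
    full.row(t) = x;
  }
  return full.rows(p, p + n - 1);
}
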