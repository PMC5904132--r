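// Time-varying multivariate autoregressive (MVAAR) fitting by Kalman filter
// and adaptive directed transfer function (ADTF) computation.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Kalman/RLS tracking of time-varying VAR coefficients.
// X: nodes x time. State W (n x n*p) is the stacked coefficient matrix so
// that the one-step prediction is W * [x(t-1); ...; x(t-p)]. A single
// covariance P (np x np) is shared across output channels; state noise is a
// random walk scaled by the update coefficient uc (Q = uc * tr(P)/L * I),
// and the scalar measurement variance is tracked as an EWMA of the squared
// prediction error.
// [[Rcpp::export]]
List cpp_kalman_mvaar(const arma::mat& X, int p, double uc) {
  const int n = X.n_rows;
  const int T = X.n_cols;
  const int L = n * p;
  arma::mat W(n, L, arma::fill::zeros);
  arma::mat P(L, L, arma::fill::eye);
  double v = 1.0;
  arma::cube coeffs(n, L, T, arma::fill::zeros);
  arma::mat resid(n, T, arma::fill::zeros);

  for (int t = p; t < T; ++t) {
    arma::vec h(L);
    for (int k = 0; k < p; ++k)
      h.subvec(k * n, k * n + n - 1) = X.col(t - 1 - k);
    P += uc * (arma::trace(P) / L) * arma::eye(L, L);
    arma::vec e = X.col(t) - W * h;
    arma::vec Ph = P * h;
    double denom = arma::dot(h, Ph) + v;
    arma::vec K = Ph / denom;
    W += e * K.t();
    P -= K * Ph.t();
    v = (1.0 - uc) * v + uc * arma::dot(e, e) / n;
    coeffs.slice(t) = W;
    resid.col(t) = e;
  }
  for (int t = 0; t < p && p < T; ++t)
    coeffs.slice(t) = coeffs.slice(p);
  return List::create(_["coeffs"] = coeffs, _["residuals"] = resid);
}

static arma::cx_mat spectral_A(const arma::mat& Wslice, int n, int p,
                               double f, double sfreq) {
  // A(f) = I - sum_k W_k exp(-i 2 pi f k / sfreq); zero-coupling gives I.
  arma::cx_mat A(n, n, arma::fill::eye);
  const std::complex<double> J(0.0, 1.0);
  for (int k = 0; k < p; ++k) {
    std::complex<double> ph =
        std::exp(-J * 2.0 * M_PI * f * double(k + 1) / sfreq);
    A -= arma::conv_to<arma::cx_mat>::from(
             Wslice.cols(k * n, k * n + n - 1)) * ph;
  }
  return A;
}

// Full complex transfer function H(f, t) = A(f, t)^-1.
// coeffs: n x (n*p) x T cube from cpp_kalman_mvaar. Returns a complex vector
// to be reshaped in R as (n, n, nf, T).
// [[Rcpp::export]]
ComplexVector cpp_transfer_function(const arma::cube& coeffs, int p,
                                    const arma::vec& freqs, double sfreq) {
  const int n = coeffs.n_rows;
  const int T = coeffs.n_slices;
  const int nf = freqs.n_elem;
  ComplexVector out((R_xlen_t)n * n * nf * T);
  R_xlen_t pos = 0;
  for (int t = 0; t < T; ++t) {
    for (int fi = 0; fi < nf; ++fi) {
      arma::cx_mat A = spectral_A(coeffs.slice(t), n, p, freqs(fi), sfreq);
      arma::cx_mat H;
      if (!arma::inv(H, A))
        stop("transfer function: singular spectral matrix at f = %f Hz, t = %d",
             freqs(fi), t + 1);
      for (int j = 0; j < n; ++j)
        for (int i = 0; i < n; ++i) {
          std::complex<double> z = H(i, j);
          out[pos + (R_xlen_t)fi * n * n + j * n + i] = Rcomplex{z.real(), z.imag()};
        }
    }
    pos += (R_xlen_t)n * n * nf;
  }
  return out;
}

// Band-integrated normalized ADTF, fused for speed: for each retained time
// point and in-band frequency, H = A^-1, rows (receiver i) of |H|^2 are
// normalized to sum 1, then averaged over the in-band bins.
// Returns an n x n x T cube (theta^2, edge j -> i at [i, j, t]).
// [[Rcpp::export]]
arma::cube cpp_adtf_integrated(const arma::cube& coeffs, int p,
                               const arma::vec& freqs, double sfreq) {
  const int n = coeffs.n_rows;
  const int T = coeffs.n_slices;
  const int nf = freqs.n_elem;
  arma::cube out(n, n, T, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat acc(n, n, arma::fill::zeros);
    for (int fi = 0; fi < nf; ++fi) {
      arma::cx_mat A = spectral_A(coeffs.slice(t), n, p, freqs(fi), sfreq);
      arma::cx_mat H;
      if (!arma::inv(H, A))
        stop("ADTF: singular spectral matrix at f = %f Hz, t = %d",
             freqs(fi), t + 1);
      arma::mat H2 = arma::square(arma::abs(H));
      arma::vec rs = arma::sum(H2, 1);
      for (int i = 0; i < n; ++i) {
        if (rs(i) <= 0.0)
          stop("ADTF: zero transfer-function row at f = %f Hz, t = %d",
               freqs(fi), t + 1);
        H2.row(i) /= rs(i);
      }
      acc += H2;
    }
    out.slice(t) = acc / double(nf);
  }
  return out;
}
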