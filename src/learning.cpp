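// Deterministic-learning core: RBF design matrix and the sequential
// observer/adaptation loop. Kept in compiled code because the weight update
// is inherently sequential (each step depends on the previous observer
// state), so it cannot be vectorised in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gaussian kernels truncated at 3 widths (exact locality: a point farther
// than 3 widths from a center receives exactly zero activation from it).
// [[Rcpp::export(name = ".rbf_design")]]
arma::mat rbf_design(const arma::mat& X, const arma::mat& C, double width) {
  const arma::uword n = X.n_rows, m = C.n_rows;
  arma::mat S(n, m, arma::fill::zeros);
  const double w2 = width * width;
  const double cut2 = 9.0 * w2;
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (arma::uword k = 0; k < X.n_cols; ++k) {
        const double d = X(i, k) - C(j, k);
        d2 += d * d;
      }
      if (d2 <= cut2) S(i, j) = std::exp(-d2 / w2);
    }
  }
  return S;
}

// Discrete-time deterministic learning along a recurrent orbit:
//   xhat(k+1) = xhat(k) - a (xhat(k) - x(k)) + W' S(x(k))
//   W(k+1)    = W(k) - g S(x(k)) (xhat(k) - x(k))' - g sigma W(k)
// with g = gamma (plain gradient) or gamma / (1 + |S|^2) (normalised).
// The orbit is a concatenation of loops of length L; the observer state is
// re-initialised at every loop seam and the artificial seam step (loop end
// to next loop start) is never used as a training target.
// Returns the final weights and their time average over the last epoch.
// [[Rcpp::export(name = ".dl_train")]]
List dl_train(const arma::mat& S, const arma::mat& X, int L, double a,
              double gamma, double sigma, int epochs, bool normalized,
              double weight_cap) {
  const arma::uword n = X.n_rows;
  const arma::uword m = S.n_cols;
  const arma::uword d = X.n_cols;
  if (n < 2) stop("cardiodynamics: need at least 2 orbit points");
  const arma::uword loop_len = (L > 1) ? arma::uword(L) : n;
  arma::mat W(m, d, arma::fill::zeros);
  arma::mat Wsum(m, d, arma::fill::zeros);
  arma::uword wsum_count = 0;
  arma::rowvec xhat = X.row(0);
  for (int e = 0; e < epochs; ++e) {
    for (arma::uword k = 0; k + 1 < n; ++k) {
      if ((k + 1) % loop_len == 0) {  // seam: reset observer, no update
        xhat = X.row(k + 1);
        continue;
      }
      const arma::rowvec s = S.row(k);
      const arma::rowvec err = xhat - X.row(k);
      const double g = normalized ? gamma / (1.0 + arma::dot(s, s)) : gamma;
      xhat = xhat - a * err + s * W;
      // adapt on the posterior (one-step-ahead) error so the regressor and
      // the error it caused are aligned in time
      const arma::rowvec err_post = xhat - X.row(k + 1);
      W -= g * (s.t() * err_post) + (g * sigma) * W;
      if (e == epochs - 1) {
        Wsum += W;
        ++wsum_count;
      }
    }
    if (!W.is_finite() || arma::norm(W, "fro") > weight_cap) {
      stop("cardiodynamics: weight norm diverged; reduce gamma or enable "
           "normalized adaptation");
    }
  }
  if (wsum_count == 0) wsum_count = 1;
  return List::create(_["weights"] = W,
                      _["wbar"] = Wsum / double(wsum_count));
}
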