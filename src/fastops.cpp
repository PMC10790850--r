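// Hot numeric kernel: lagged covariance accumulation for the TRF forward
// model. Everything else stays in R (whose FFT outruns Armadillo's here).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Accumulate X'X and X'y for one segment of the lagged forward model:
// X has one column per lag (env shifted by `lags` samples, zero-padded at
// the segment edges) plus a trailing intercept column; eeg is the
// channels x samples block of the same segment.
// [[Rcpp::export]]
Rcpp::List trf_accumulate_cpp(const arma::vec& env, const arma::mat& eeg,
                              const arma::ivec& lags) {
  const int n = env.n_elem, nl = lags.n_elem;
  arma::mat X(n, nl + 1);
  for (int j = 0; j < nl; ++j) {
    const int l = lags[j];
    for (int t = 0; t < n; ++t) {
      const int s = t - l;
      X(t, j) = (s >= 0 && s < n) ? env[s] : 0.0;
    }
  }
  X.col(nl).ones();
  arma::mat XtX = X.t() * X;
  arma::mat Xty = X.t() * eeg.t();
  return Rcpp::List::create(Rcpp::Named("XtX") = XtX,
                            Rcpp::Named("Xty") = Xty);
}
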