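#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

//' Multiplicative-update non-negative matrix factorisation (single restart)
//'
//' Minimises the Frobenius reconstruction error of \code{V ~ W * H} by Lee-Seung
//' multiplicative updates from the supplied non-negative initialisation.
//' Convergence is declared when the variance-accounted-for (VAF, computed
//' against the uncentred total sum of squares of \code{V}) changes by less than
//' \code{tol} over a 10-iteration block.
//'
//' @param V data matrix (muscles x time points), non-negative.
//' @param W,H initial factor matrices, strictly positive.
//' @param max_iter maximum number of update iterations.
//' @param tol VAF-change convergence tolerance per 10-iteration block.
//' @param eps denominator guard added inside the update rules.
//' @return list with converged factors, the final VAF, iteration count, and a
//'   flag stating whether the objective was non-increasing across all checked
//'   blocks (a property of exact multiplicative updates; violations beyond
//'   numerical noise indicate a defect).
//' @keywords internal
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, double eps) {
  const double sst = accu(square(V));
  double prev_vaf = -datum::inf;
  double prev_obj = datum::inf;
  bool monotone = true;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H <- H .* (W'V) ./ (W'WH + eps)
    H %= (W.t() * V) / (W.t() * W * H + eps);
    // W <- W .* (VH') ./ (WHH' + eps)
    W %= (V * H.t()) / (W * H * H.t() + eps);
    if (it % 10 == 0) {
      const double sse = accu(square(V - W * H));
      if (sse > prev_obj * (1.0 + 1e-9) + 1e-12) monotone = false;
      prev_obj = sse;
      const double vaf = 1.0 - sse / sst;
      if (std::abs(vaf - prev_vaf) < tol) break;
      prev_vaf = vaf;
    }
  }
  const double sse = accu(square(V - W * H));
  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("H") = H,
      Rcpp::Named("vaf") = 1.0 - sse / sst,
      Rcpp::Named("iterations") = std::min(it, max_iter),
      Rcpp::Named("objective_monotone") = monotone);
}
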