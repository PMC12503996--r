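// Fast path for type-1 predictive mean matching: least-squares fit on the
// observed rows, Gaussian coefficient draw (residual variance drawn from
// its scaled chi-square), donor matching on predicted values.  Uses R's
// RNG so results are reproducible under set.seed().  Returns an empty
// vector when the normal equations are (near-)singular; the R wrapper then
// falls back to a pivoted-QR implementation that drops aliased columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector pmm_match_cpp(const arma::vec& y_obs,
                                  const arma::mat& X_obs,
                                  const arma::mat& X_mis,
                                  int donors) {
  const uword n = y_obs.n_elem, p = X_obs.n_cols, m = X_mis.n_rows;
  mat XtX = X_obs.t() * X_obs;
  mat U;
  if (!chol(U, XtX)) return Rcpp::NumericVector(0);
  double rc = rcond(trimatu(U));
  if (!(rc > 1e-12)) return Rcpp::NumericVector(0);

  vec Xty = X_obs.t() * y_obs;
  vec beta = solve(trimatu(U), solve(trimatl(U.t()), Xty));
  vec yhat_obs = X_obs * beta;
  double rss = accu(square(y_obs - yhat_obs));
  double df = std::max(1.0, static_cast<double>(n) - static_cast<double>(p));

  double sigma2_star = rss / R::rchisq(df);
  vec z(p);
  for (uword j = 0; j < p; ++j) z[j] = R::norm_rand();
  vec bstar = beta + std::sqrt(sigma2_star) * solve(trimatu(U), z);
  vec yhat_mis = X_mis * bstar;

  const int k = std::min<int>(donors, n);
  Rcpp::NumericVector out(m);
  std::vector<double> dist(k);
  std::vector<uword> idx(k);
  for (uword i = 0; i < m; ++i) {
    const double target = yhat_mis[i];
    int filled = 0;
    for (uword j = 0; j < n; ++j) {
      double d = std::abs(yhat_obs[j] - target);
      if (filled < k) {
        dist[filled] = d;
        idx[filled] = j;
        ++filled;
        if (filled == k) {  // heapify-lite: track the current worst
          uword w = 0;
          for (int a = 1; a < k; ++a) if (dist[a] > dist[w]) w = a;
          std::swap(dist[w], dist[k - 1]);
          std::swap(idx[w], idx[k - 1]);
        }
      } else if (d < dist[k - 1]) {
        dist[k - 1] = d;
        idx[k - 1] = j;
        uword w = 0;
        for (int a = 1; a < k; ++a) if (dist[a] > dist[w]) w = a;
        std::swap(dist[w], dist[k - 1]);
        std::swap(idx[w], idx[k - 1]);
      }
    }
    int pick = static_cast<int>(R::unif_rand() * filled);
    if (pick >= filled) pick = filled - 1;
    out[i] = y_obs[idx[pick]];
  }
  return out;
}
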