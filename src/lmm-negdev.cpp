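// Profiled negative log-likelihood for the variance-component models.
// Hot path of the optimiser: everything is expressed through q x q
// cross-products (q = random-effect columns), so one evaluation is
// O(q^3) regardless of the number of observations. The surrounding
// bookkeeping (designs, BLUPs, reporting) stays in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// theta: log variance ratios, one per random-effect block
// blocks: 1-based block index per random-effect column
// [[Rcpp::export]]
double lmm_negdev_cpp(const arma::vec& theta,
                      const arma::mat& ZtZ, const arma::mat& ZtX,
                      const arma::vec& Zty, const arma::mat& XtX,
                      const arma::vec& Xty, double yty,
                      int n, const arma::ivec& blocks, bool reml) {
  const double bad = 1e10;
  arma::uword q = ZtZ.n_rows, p = XtX.n_rows;
  arma::vec sg(q);
  for (arma::uword j = 0; j < q; ++j) {
    double th = theta(blocks(j) - 1);
    if (th < -30) th = -30;
    if (th > 15) th = 15;
    sg(j) = std::exp(0.5 * th);
  }
  arma::mat M = ZtZ;
  for (arma::uword i = 0; i < q; ++i)
    for (arma::uword j = 0; j < q; ++j)
      M(i, j) *= sg(i) * sg(j);
  M.diag() += 1.0;
  arma::mat L;
  if (!arma::chol(L, M, "lower")) return bad;
  double logdetV = 2.0 * arma::sum(arma::log(L.diag()));

  arma::mat Bc(q, p + 1);
  Bc.cols(0, p - 1) = ZtX.each_col() % sg;
  Bc.col(p) = Zty % sg;
  arma::mat S = arma::solve(arma::trimatl(L), Bc);

  arma::mat XtViX = XtX - S.cols(0, p - 1).t() * S.cols(0, p - 1);
  arma::vec XtViy = Xty - S.cols(0, p - 1).t() * S.col(p);
  double ytViy = yty - arma::dot(S.col(p), S.col(p));

  arma::mat R;
  if (!arma::chol(R, XtViX)) return bad;
  arma::vec beta = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), XtViy));
  double rss = ytViy - arma::dot(beta, XtViy);
  if (rss < 1e-300) rss = 1e-300;
  double ll;
  if (reml) {
    double sigma2 = rss / (n - (int)p);
    ll = -0.5 * ((n - (int)p) * (std::log(2.0 * M_PI * sigma2) + 1.0) +
                 logdetV + 2.0 * arma::sum(arma::log(R.diag())));
  } else {
    double sigma2 = rss / n;
    ll = -0.5 * (n * (std::log(2.0 * M_PI * sigma2) + 1.0) + logdetV);
  }
  if (!std::isfinite(ll)) return bad;
  return -ll;
}
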