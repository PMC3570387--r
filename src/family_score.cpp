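// Penalized additive-regression family score from precomputed
// cross-products. The R side owns basis construction and caching; these
// routines do the per-family linear algebra, which sits in the innermost
// loops of the greedy parent selection and the structure hill climb.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Score one family given the design-column indices (1-based, into the
// columns of the precomputed Gram matrix G and rows of XtY).
// approx: 0 = BIC on effective df, 1 = ridge-evidence Laplace form.
static double scoreOne(const arma::mat& G, const arma::mat& XtY,
                       const arma::vec& yty, int child,
                       const arma::uvec& idx0, int n, double lambda,
                       int approx) {
  arma::mat Gs = G.submat(idx0, idx0);
  arma::vec b = XtY.col(child - 1);
  arma::vec bs = b.elem(idx0);
  arma::mat A = Gs;
  for (arma::uword k = 1; k < idx0.n_elem; ++k) A(k, k) += lambda;
  arma::mat Ainv;
  if (!arma::inv_sympd(Ainv, A)) {
    if (!arma::inv(Ainv, A)) Rcpp::stop("singular fit in family score");
  }
  arma::vec beta = Ainv * bs;
  double rss = yty(child - 1) - 2.0 * arma::dot(beta, bs) +
               arma::as_scalar(beta.t() * Gs * beta);
  if (rss < 0) rss = 0;
  double sigma2 = rss / n;
  if (sigma2 < 1e-12) sigma2 = 1e-12;
  double logLik = -0.5 * n * (std::log(2.0 * M_PI * sigma2) + 1.0);
  if (approx == 0) {
    double edf = arma::trace(Ainv * Gs);
    return logLik - 0.5 * edf * std::log((double)n);
  }
  double logdet, sign;
  arma::log_det(logdet, sign, A);
  int nPen = idx0.n_elem - 1;
  return logLik - 0.5 * (logdet - nPen * std::log(lambda));
}

// [[Rcpp::export]]
double cppFamilyScore(const arma::mat& G, const arma::mat& XtY,
                      const arma::vec& yty, int child,
                      const arma::ivec& idx, int n, double lambda,
                      int approx) {
  arma::uvec idx0 = arma::conv_to<arma::uvec>::from(idx) - 1;
  return scoreOne(G, XtY, yty, child, idx0, n, lambda, approx);
}

// Score, for one child with current parent design columns `baseIdx`
// (including the intercept column 1), every candidate extension whose
// extra columns are given by the rows of `blockStarts` (start column of
// each candidate parent's basis block) with block width m. Returns one
// score per candidate. Used to refresh a whole gain row at once.
// [[Rcpp::export]]
NumericVector cppScoreAdditions(const arma::mat& G, const arma::mat& XtY,
                                const arma::vec& yty, int child,
                                const arma::ivec& baseIdx,
                                const arma::ivec& blockStarts, int m,
                                int n, double lambda, int approx) {
  int nc = blockStarts.n_elem;
  NumericVector out(nc);
  arma::uvec base0 = arma::conv_to<arma::uvec>::from(baseIdx) - 1;
  for (int c = 0; c < nc; ++c) {
    arma::uvec idx0(base0.n_elem + m);
    idx0.head(base0.n_elem) = base0;
    for (int k = 0; k < m; ++k)
      idx0(base0.n_elem + k) = blockStarts(c) - 1 + k;
    out[c] = scoreOne(G, XtY, yty, child, idx0, n, lambda, approx);
  }
  return out;
}
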