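#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// PLS1 (single numeric response) via NIPALS on mean-centered data.
// Stops early when the residual X'f direction collapses; `used` reports the
// number of components actually extracted.
static void pls1_core(const arma::mat& X, const arma::vec& y, int A,
                      arma::mat& W, arma::mat& P, arma::mat& T, arma::vec& q,
                      arma::rowvec& xm, double& ym, arma::vec& b, int& used) {
  int n = X.n_rows, p = X.n_cols;
  xm = arma::mean(X, 0);
  ym = arma::mean(y);
  arma::mat E = X.each_row() - xm;
  arma::vec f = y - ym;
  W.set_size(p, A); P.set_size(p, A); T.set_size(n, A); q.set_size(A);
  used = 0;
  for (int a = 0; a < A; ++a) {
    arma::vec w = E.t() * f;
    double wn = arma::norm(w);
    if (wn < 1e-12) break;
    w /= wn;
    arma::vec t = E * w;
    double tt = arma::dot(t, t);
    if (tt < 1e-12) break;
    arma::vec pv = E.t() * t / tt;
    double qa = arma::dot(f, t) / tt;
    E -= t * pv.t();
    f -= qa * t;
    W.col(a) = w; P.col(a) = pv; T.col(a) = t; q(a) = qa;
    used = a + 1;
  }
  b.zeros(p);
  if (used > 0) {
    arma::mat Wu = W.cols(0, used - 1), Pu = P.cols(0, used - 1);
    arma::vec qu = q.subvec(0, used - 1);
    b = Wu * arma::solve(Pu.t() * Wu, qu);
  }
}

// [[Rcpp::export]]
List pls1_fit_cpp(const arma::mat& X, const arma::vec& y, int A) {
  arma::mat W, P, T; arma::vec q, b; arma::rowvec xm; double ym; int used;
  pls1_core(X, y, A, W, P, T, q, xm, ym, b, used);
  arma::vec fitted = (X.each_row() - xm) * b + ym;
  return List::create(
    _["b"] = b, _["x_mean"] = xm.t(), _["y_mean"] = ym,
    _["weights"] = (used > 0) ? W.cols(0, used - 1) : W,
    _["loadings"] = (used > 0) ? P.cols(0, used - 1) : P,
    _["scores"] = (used > 0) ? T.cols(0, used - 1) : T,
    _["y_loadings"] = (used > 0) ? q.subvec(0, used - 1) : q,
    _["fitted"] = fitted, _["n_components"] = used);
}

// Coefficient vector only (hot path for Monte-Carlo selection loops).
// [[Rcpp::export]]
List pls1_coef_cpp(const arma::mat& X, const arma::vec& y, int A) {
  arma::mat W, P, T; arma::vec q, b; arma::rowvec xm; double ym; int used;
  pls1_core(X, y, A, W, P, T, q, xm, ym, b, used);
  return List::create(_["b"] = b, _["x_mean"] = xm.t(), _["y_mean"] = ym,
                      _["n_components"] = used);
}

// Held-out predictions for a fixed fold assignment (1-based fold ids).
// [[Rcpp::export]]
arma::vec pls1_cv_pred_cpp(const arma::mat& X, const arma::vec& y, int A,
                           const arma::ivec& fold) {
  int n = X.n_rows;
  arma::vec pred(n, arma::fill::zeros);
  int K = fold.max();
  for (int k = 1; k <= K; ++k) {
    arma::uvec test = arma::find(fold == k);
    if (test.n_elem == 0) continue;
    arma::uvec train = arma::find(fold != k);
    arma::mat W, P, T; arma::vec q, b; arma::rowvec xm; double ym; int used;
    pls1_core(X.rows(train), y.elem(train), A, W, P, T, q, xm, ym, b, used);
    arma::mat Xt = X.rows(test);
    pred.elem(test) = (Xt.each_row() - xm) * b + ym;
  }
  return pred;
}
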