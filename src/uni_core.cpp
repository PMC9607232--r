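// Fused forward/backward pass of the univariate matched-filter CNN:
// Conv1D (valid, stride 1) -> BatchNorm -> tanh -> global max pool ->
// FC -> softmax, with categorical cross-entropy.  One call per minibatch
// keeps the correlation tensors inside compiled code.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// valid-mode sliding correlation of each row of X with each kernel column;
// rows of the result are (example, lag) pairs, example index fastest
static arma::mat conv_valid(const arma::mat& X, const arma::mat& K) {
  const arma::uword B = X.n_rows, NS = X.n_cols, NK = K.n_rows;
  const arma::uword T = NS - NK + 1;
  arma::mat C(B * T, K.n_cols);
  for (arma::uword t = 0; t < T; ++t) {
    C.rows(t * B, t * B + B - 1) = X.cols(t, t + NK - 1) * K;
  }
  return C;
}

// [[Rcpp::export(name = ".cppUniProbs")]]
arma::mat cpp_uni_probs(const arma::mat& X, const arma::mat& K,
                        const arma::vec& g, const arma::vec& b,
                        const arma::vec& rm, const arma::vec& rv,
                        const arma::mat& W, double eps) {
  const arma::uword B = X.n_rows, F = K.n_cols;
  const arma::uword T = X.n_cols - K.n_rows + 1;
  arma::mat C = conv_valid(X, K);
  arma::vec invstd = 1.0 / arma::sqrt(rv + eps);
  arma::mat G(B, F);
  for (arma::uword f = 0; f < F; ++f) {
    const double a = g(f) * invstd(f);
    const double c = b(f) - g(f) * rm(f) * invstd(f);
    arma::vec col = C.col(f);
    for (arma::uword i = 0; i < B; ++i) {
      double best = -arma::datum::inf;
      for (arma::uword t = 0; t < T; ++t) {
        const double v = col(t * B + i);
        if (v > best) best = v;
      }
      // tanh is strictly increasing: pool before the activation
      G(i, f) = std::tanh(a * best + c);
    }
  }
  arma::mat logits = G * W;
  logits.each_col() -= arma::max(logits, 1);
  arma::mat P = arma::exp(logits);
  P.each_col() /= arma::sum(P, 1);
  return P;
}

// [[Rcpp::export(name = ".cppUniStep")]]
List cpp_uni_step(const arma::mat& X, const arma::ivec& y,
                  const arma::mat& K, const arma::vec& g, const arma::vec& b,
                  const arma::mat& W, double eps) {
  const arma::uword B = X.n_rows, NK = K.n_rows, F = K.n_cols;
  const arma::uword T = X.n_cols - NK + 1;
  const arma::uword m = B * T;

  // forward
  arma::mat C = conv_valid(X, K);
  arma::rowvec mu = arma::mean(C, 0);
  arma::rowvec vr = arma::mean(arma::square(C), 0) - arma::square(mu);
  arma::rowvec invstd = 1.0 / arma::sqrt(vr + eps);
  arma::mat Yhat = C.each_row() - mu;
  Yhat.each_row() %= invstd;
  arma::mat A = Yhat.each_row() % g.t();
  A.each_row() += b.t();
  A = arma::tanh(A);
  arma::mat G(B, F);
  arma::umat idx(B, F);
  for (arma::uword f = 0; f < F; ++f) {
    for (arma::uword i = 0; i < B; ++i) {
      double best = -arma::datum::inf;
      arma::uword bt = 0;
      for (arma::uword t = 0; t < T; ++t) {
        const double v = A(t * B + i, f);
        if (v > best) { best = v; bt = t; }
      }
      G(i, f) = best;
      idx(i, f) = bt;
    }
  }
  arma::mat logits = G * W;
  logits.each_col() -= arma::max(logits, 1);
  arma::mat P = arma::exp(logits);
  P.each_col() /= arma::sum(P, 1);

  double loss = 0.0;
  arma::uword correct = 0;
  for (arma::uword i = 0; i < B; ++i) {
    const arma::uword yi = static_cast<arma::uword>(y(i) - 1);
    loss -= std::log(std::max(P(i, yi), 1e-12));
    if (P.row(i).index_max() == yi) ++correct;
  }
  loss /= B;

  // backward
  arma::mat dLogits = P;
  for (arma::uword i = 0; i < B; ++i) {
    dLogits(i, static_cast<arma::uword>(y(i) - 1)) -= 1.0;
  }
  dLogits /= static_cast<double>(B);
  arma::mat dW = G.t() * dLogits;
  arma::mat dG = dLogits * W.t();

  // route through GMP and tanh (sparse), then batch-norm (dense)
  arma::mat dZ(m, F, arma::fill::zeros);
  for (arma::uword f = 0; f < F; ++f) {
    for (arma::uword i = 0; i < B; ++i) {
      const arma::uword r = idx(i, f) * B + i;
      dZ(r, f) = dG(i, f) * (1.0 - A(r, f) * A(r, f));
    }
  }
  arma::rowvec dg = arma::sum(dZ % Yhat, 0);
  arma::rowvec db = arma::sum(dZ, 0);
  arma::mat dYhat = dZ.each_row() % g.t();
  arma::rowvec s1 = arma::sum(dYhat, 0) / static_cast<double>(m);
  arma::rowvec s2 = arma::sum(dYhat % Yhat, 0) / static_cast<double>(m);
  arma::mat dC = dYhat;
  dC.each_row() -= s1;
  dC -= Yhat.each_row() % s2;
  dC.each_row() %= invstd;

  arma::mat dK(NK, F, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    dK += X.cols(t, t + NK - 1).t() * dC.rows(t * B, t * B + B - 1);
  }

  return List::create(
    _["loss"] = loss, _["correct"] = static_cast<int>(correct),
    _["mu"] = arma::vec(mu.t()), _["vr"] = arma::vec(vr.t()),
    _["conv_w"] = dK, _["bn_g"] = arma::vec(dg.t()),
    _["bn_b"] = arma::vec(db.t()), _["fc_w"] = dW);
}
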