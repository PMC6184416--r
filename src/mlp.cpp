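// Loss and gradient of a single-hidden-layer tanh perceptron regressor with
// L2-penalized mean-squared-error loss, for use with a quasi-Newton
// optimizer driving the parameter vector.
//
// Parameter packing: [vec(W) (p*h), b_h (h), v (h), b_o (1)] where W is the
// p x h input->hidden matrix, v the hidden->output weights. Loss is
//   0.5 * mean((yhat - y)^2) + alpha/(2n) * (||W||_F^2 + ||v||^2)
// (biases unpenalized). Gradients come from standard backpropagation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void unpack(const vec& par, int p, int h,
                   mat& W, rowvec& b_h, vec& v, double& b_o) {
  W = reshape(par.subvec(0, p * h - 1), p, h);
  b_h = par.subvec(p * h, p * h + h - 1).t();
  v = par.subvec(p * h + h, p * h + 2 * h - 1);
  b_o = par(p * h + 2 * h);
}

// [[Rcpp::export]]
Rcpp::List mlp_loss_grad(const arma::vec& par, const arma::mat& X,
                         const arma::vec& y, int h, double alpha) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  mat W;
  rowvec b_h;
  vec v;
  double b_o;
  unpack(par, p, h, W, b_h, v, b_o);

  mat Z = tanh(X * W + repmat(b_h, n, 1));
  vec yhat = Z * v + b_o;
  vec r = yhat - y;

  double loss = 0.5 * dot(r, r) / n +
    0.5 * alpha / n * (accu(square(W)) + dot(v, v));

  vec rn = r / n;
  vec g_v = Z.t() * rn + (alpha / n) * v;
  double g_bo = accu(rn);
  mat dZ = (rn * v.t()) % (1.0 - square(Z));
  mat g_W = X.t() * dZ + (alpha / n) * W;
  rowvec g_bh = sum(dZ, 0);

  vec grad(par.n_elem);
  grad.subvec(0, p * h - 1) = vectorise(g_W);
  grad.subvec(p * h, p * h + h - 1) = g_bh.t();
  grad.subvec(p * h + h, p * h + 2 * h - 1) = g_v;
  grad(p * h + 2 * h) = g_bo;

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// [[Rcpp::export]]
arma::vec mlp_forward(const arma::vec& par, const arma::mat& X, int h) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  mat W;
  rowvec b_h;
  vec v;
  double b_o;
  unpack(par, p, h, W, b_h, v, b_o);
  mat Z = tanh(X * W + repmat(b_h, n, 1));
  return Z * v + b_o;
}
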