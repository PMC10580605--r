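// Per-pattern backpropagation with momentum for a small feed-forward
// network: sigmoid hidden layers, linear output, squared-error loss.
// Updates are applied after every training example, in row order, for a
// fixed number of epochs; weights are supplied pre-initialized so the R
// side controls seeding.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::vec& y, List W0, List B0,
                   double lr, double momentum, int epochs) {
  const int nl = W0.size();
  std::vector<arma::mat> W(nl), vW(nl);
  std::vector<arma::vec> B(nl), vB(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = as<arma::mat>(W0[l]);                    // n_in x n_out
    vW[l] = arma::zeros<arma::mat>(W[l].n_rows, W[l].n_cols);
    B[l] = as<arma::vec>(B0[l]);
    vB[l] = arma::zeros<arma::vec>(B[l].n_elem);
  }
  const int n = X.n_rows;
  std::vector<arma::vec> act(nl + 1);
  int diverged_at = -1;
  for (int ep = 0; ep < epochs && diverged_at < 0; ++ep) {
    for (int i = 0; i < n; ++i) {
      act[0] = X.row(i).t();
      for (int l = 0; l < nl; ++l) {
        arma::vec z = W[l].t() * act[l] + B[l];
        act[l + 1] = (l < nl - 1) ? 1.0 / (1.0 + arma::exp(-z))
                                  : z;  // linear output layer
      }
      arma::vec delta = act[nl];
      delta(0) -= y(i);                 // d(SE)/d(output)
      for (int l = nl - 1; l >= 0; --l) {
        arma::mat gW = act[l] * delta.t();
        arma::vec gB = delta;
        if (l > 0) {
          delta = (W[l] * delta) % act[l] % (1.0 - act[l]);
        }
        vW[l] = momentum * vW[l] - lr * gW;
        vB[l] = momentum * vB[l] - lr * gB;
        W[l] += vW[l];
        B[l] += vB[l];
      }
    }
    for (int l = 0; l < nl; ++l) {
      if (!W[l].is_finite() || !B[l].is_finite()) {
        diverged_at = ep + 1;
        break;
      }
    }
  }
  List Wout(nl), Bout(nl);
  for (int l = 0; l < nl; ++l) {
    Wout[l] = W[l];
    Bout[l] = B[l];
  }
  return List::create(_["W"] = Wout, _["B"] = Bout,
                      _["diverged_at"] = diverged_at);
}
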