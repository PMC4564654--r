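// Compiled core of the key-identification perceptron.
//
// The input vector is sparse (at most 186 ones out of 2,232 units), so the
// first affine layer is computed by summing the weight rows of the active
// input units instead of a dense matrix product; the same indices restrict
// the first-layer weight-gradient update. Weight matrices are stored with
// inputs in rows, units in columns (W1: n_in x n1, W2: n1 x n2,
// W3: n2 x n_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec first_layer_input(const arma::mat& W1, const arma::vec& b1,
                                   const IntegerVector& idx) {
  arma::vec h = b1;
  const int L = idx.size();
  for (int i = 0; i < L; ++i) h += W1.row(idx[i] - 1).t();
  return h;
}

// Forward pass for one melody given as 1-based active input indices.
// [[Rcpp::export]]
List cpp_forward(const arma::mat& W1, const arma::vec& b1,
                 const arma::mat& W2, const arma::vec& b2,
                 const arma::mat& W3, const arma::vec& b3,
                 const IntegerVector& idx) {
  arma::vec a1 = arma::tanh(first_layer_input(W1, b1, idx));
  arma::vec a2 = arma::tanh(W2.t() * a1 + b2);
  arma::vec a3 = arma::tanh(W3.t() * a2 + b3);
  return List::create(_["a1"] = a1, _["a2"] = a2, _["a3"] = a3);
}

// Raw output activations for a list of melodies; rows are melodies.
// [[Rcpp::export]]
arma::mat cpp_outputs(const arma::mat& W1, const arma::vec& b1,
                      const arma::mat& W2, const arma::vec& b2,
                      const arma::mat& W3, const arma::vec& b3,
                      const List& melodies) {
  const int n = melodies.size();
  arma::mat out(n, W3.n_cols);
  for (int i = 0; i < n; ++i) {
    IntegerVector idx = melodies[i];
    arma::vec a1 = arma::tanh(first_layer_input(W1, b1, idx));
    arma::vec a2 = arma::tanh(W2.t() * a1 + b2);
    out.row(i) = arma::tanh(W3.t() * a2 + b3).t();
  }
  return out;
}

// Backpropagation gradients of the squared-error loss
// L = 0.5 * sum((a3 - target)^2) for a single item.
// [[Rcpp::export]]
List cpp_gradients(const arma::mat& W1, const arma::vec& b1,
                   const arma::mat& W2, const arma::vec& b2,
                   const arma::mat& W3, const arma::vec& b3,
                   const IntegerVector& idx, const arma::vec& target) {
  arma::vec a1 = arma::tanh(first_layer_input(W1, b1, idx));
  arma::vec a2 = arma::tanh(W2.t() * a1 + b2);
  arma::vec a3 = arma::tanh(W3.t() * a2 + b3);

  arma::vec d3 = (a3 - target) % (1.0 - a3 % a3);
  arma::vec d2 = (W3 * d3) % (1.0 - a2 % a2);
  arma::vec d1 = (W2 * d2) % (1.0 - a1 % a1);

  arma::mat gW1(W1.n_rows, W1.n_cols, arma::fill::zeros);
  for (int i = 0; i < idx.size(); ++i) gW1.row(idx[i] - 1) += d1.t();

  return List::create(
    _["gW1"] = gW1, _["gb1"] = d1,
    _["gW2"] = a1 * d2.t(), _["gb2"] = d2,
    _["gW3"] = a2 * d3.t(), _["gb3"] = d3,
    _["loss"] = 0.5 * arma::accu(arma::square(a3 - target)));
}

// Online (per-item) stochastic gradient descent.
//
// melodies: list of 1-based active-index vectors; key_idx: 1-based output
// unit of the correct key per melody. Presentation order is reshuffled
// every epoch with R's RNG stream (so set.seed() on the R side makes runs
// bit-reproducible). checkpoint_epochs must be sorted increasing, >= 1.
// [[Rcpp::export]]
List cpp_train(arma::mat W1, arma::vec b1,
               arma::mat W2, arma::vec b2,
               arma::mat W3, arma::vec b3,
               const List& melodies, const IntegerVector& key_idx,
               double lr, int n_epochs,
               const IntegerVector& checkpoint_epochs,
               double target_low, double target_high, bool shuffle) {
  const int n = melodies.size();
  const int n_out = W3.n_cols;
  if (n == 0) stop("cannot train on an empty corpus");

  std::vector<IntegerVector> items(n);
  for (int i = 0; i < n; ++i) items[i] = melodies[i];

  arma::mat targets(n_out, n);
  targets.fill(target_low);
  for (int i = 0; i < n; ++i) {
    if (key_idx[i] < 1 || key_idx[i] > n_out) stop("key index out of range");
    targets(key_idx[i] - 1, i) = target_high;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  NumericVector epoch_loss(n_epochs);
  List checkpoints(checkpoint_epochs.size());
  int next_cp = 0;

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    if (shuffle) {
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order[i], order[j]);
      }
    }
    double total = 0.0;
    for (int t = 0; t < n; ++t) {
      const int it = order[t];
      const IntegerVector& idx = items[it];
      arma::vec a1 = arma::tanh(first_layer_input(W1, b1, idx));
      arma::vec a2 = arma::tanh(W2.t() * a1 + b2);
      arma::vec a3 = arma::tanh(W3.t() * a2 + b3);

      arma::vec err = a3 - targets.col(it);
      total += 0.5 * arma::accu(arma::square(err));

      arma::vec d3 = err % (1.0 - a3 % a3);
      arma::vec d2 = (W3 * d3) % (1.0 - a2 % a2);
      arma::vec d1 = (W2 * d2) % (1.0 - a1 % a1);

      W3 -= lr * (a2 * d3.t());
      b3 -= lr * d3;
      W2 -= lr * (a1 * d2.t());
      b2 -= lr * d2;
      b1 -= lr * d1;
      arma::rowvec upd = lr * d1.t();
      for (int i = 0; i < idx.size(); ++i) W1.row(idx[i] - 1) -= upd;
    }
    epoch_loss[epoch - 1] = total / n;
    if (!std::isfinite(total)) {
      stop("training diverged (non-finite loss) at epoch %d", epoch);
    }
    if (next_cp < checkpoint_epochs.size() &&
        epoch == checkpoint_epochs[next_cp]) {
      checkpoints[next_cp] = List::create(
        _["epoch"] = epoch,
        _["W1"] = W1, _["b1"] = b1,
        _["W2"] = W2, _["b2"] = b2,
        _["W3"] = W3, _["b3"] = b3,
        _["training_loss"] = epoch_loss[epoch - 1]);
      ++next_cp;
    }
    if (epoch % 50 == 0) checkUserInterrupt();
  }
  return List::create(_["checkpoints"] = checkpoints,
                      _["epoch_loss"] = epoch_loss);
}
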