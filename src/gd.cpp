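// Bootstrap-averaged full-batch gradient descent with early stopping for a
// single voxel's linear encoding model. The caller supplies standardized
// design rows split into estimation and stopping sets, plus 1-based bootstrap
// row indices (into the estimation set) for every round; all randomness is
// drawn in R so results are reproducible from the R seed alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Loss: L = 0.5 * sum_i (x_i' w + c - y_i)^2 over the bootstrap sample.
// Kernel starts at zero (early stopping then shrinks it toward zero); the
// intercept starts at the bootstrap-sample mean of y. Every eval_every
// iterations the stopping-set MSE is measured and the best snapshot kept;
// descent halts after `patience` consecutive non-improving evaluations.
// [[Rcpp::export(name = ".gd_fit_voxel")]]
List gd_fit_voxel(const arma::mat& X_est, const arma::vec& y_est,
                  const arma::mat& X_stop, const arma::vec& y_stop,
                  const arma::umat& boot_idx, double learning_rate,
                  int max_iters, int eval_every, int patience) {
  const int n_rounds = boot_idx.n_cols;
  const arma::uword q = X_est.n_cols;
  arma::vec w_sum(q, arma::fill::zeros);
  double c_sum = 0.0;
  arma::ivec iters_used(n_rounds);
  arma::vec best_errs(n_rounds);

  for (int r = 0; r < n_rounds; ++r) {
    arma::uvec idx = boot_idx.col(r) - 1;  // to 0-based
    arma::mat Xb = X_est.rows(idx);
    arma::vec yb = y_est.elem(idx);
    const double n_b = static_cast<double>(yb.n_elem);

    arma::vec w(q, arma::fill::zeros);
    double c = arma::mean(yb);

    arma::vec stop_res = X_stop * w + c - y_stop;
    double best_err = arma::dot(stop_res, stop_res) / y_stop.n_elem;
    arma::vec best_w = w;
    double best_c = c;
    int since_best = 0, iter = 0;

    while (iter < max_iters) {
      arma::vec res = Xb * w + c - yb;
      w -= learning_rate * (Xb.t() * res);
      c -= learning_rate * arma::accu(res);
      ++iter;
      if (iter % eval_every == 0) {
        stop_res = X_stop * w + c - y_stop;
        double err = arma::dot(stop_res, stop_res) / y_stop.n_elem;
        if (std::isfinite(err) && err < best_err) {
          best_err = err;
          best_w = w;
          best_c = c;
          since_best = 0;
        } else {
          if (++since_best >= patience) break;
          if (!std::isfinite(err)) break;  // diverged; keep best snapshot
        }
      }
    }
    (void)n_b;
    w_sum += best_w;
    c_sum += best_c;
    iters_used[r] = iter;
    best_errs[r] = best_err;
  }

  return List::create(
      _["kernel"] = w_sum / n_rounds, _["constant"] = c_sum / n_rounds,
      _["iters"] = iters_used, _["stop_mse"] = best_errs);
}
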