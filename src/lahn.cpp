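#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Online anti-Hebbian training.
//
// Response per sample t (columns of Yt, m x T):
//   settled = false: gamma(t) = Q' y(t) + P' gamma(t-1)
//     (literal one-step-lagged recurrence)
//   settled = true:  gamma(t) solves (I - P') gamma = Q' y(t)
//     (steady state of the recurrent dynamics; the lagged recurrence
//      relaxes to this fixed point when its iteration converges, but the
//      fixed point remains well-defined for arbitrarily strong lateral
//      inhibition, where the iteration itself oscillates and diverges)
//
// Updates after each sample:
//   Q(:,i) += etaF * (gamma_i y - gamma_i^2 Q(:,i))   (Oja/Hebbian)
//   P(k,i) -= etaL * gamma_i(t) gamma_k(t-1), k != i  (Stent lateral)
//
// Q is m x n (column i = afferent weights of neuron i); P is n x n with
// P(k,i) the lateral weight from neuron k to neuron i.
// [[Rcpp::export]]
List lahn_train_cpp(const arma::mat& Yt, arma::mat Q, arma::mat P,
                    double etaF, double etaL, double tol, int max_epochs,
                    arma::vec gamma_prev, double guard, bool settled,
                    bool hierarchical) {
  const arma::uword T = Yt.n_cols;
  const arma::uword n = Q.n_cols;
  arma::vec g(n);
  arma::mat A(n, n);
  const arma::mat I = arma::eye(n, n);
  std::vector<double> trace;
  bool converged = false, diverged = false;
  int epochs = 0;

  for (int ep = 0; ep < max_epochs; ++ep) {
    arma::mat Q0 = Q, P0 = P;
    for (arma::uword t = 0; t < T; ++t) {
      const arma::vec y = Yt.col(t);
      if (settled) {
        A = I - P.t();
        bool ok = arma::solve(g, A, Q.t() * y, arma::solve_opts::no_approx);
        if (!ok) { diverged = true; break; }
      } else {
        g = Q.t() * y + P.t() * gamma_prev;
      }
      for (arma::uword i = 0; i < n; ++i) {
        const double gi = g[i];
        Q.col(i) += (etaF * gi) * y - (etaF * gi * gi) * Q.col(i);
      }
      if (etaL != 0.0) {
        P -= etaL * (gamma_prev * g.t());
        P.diag().zeros();
        // hierarchical (Rubner-Tavan) connectivity: neuron i receives
        // lateral input only from neurons k < i; P(k,i) kept for k < i
        if (hierarchical) P = arma::trimatu(P, 1);
      }
      gamma_prev = g;
    }
    epochs = ep + 1;
    if (diverged) break;
    double tr = arma::accu(arma::abs(Q - Q0)) + arma::accu(arma::abs(P - P0));
    trace.push_back(tr);
    if (!Q.is_finite() || !P.is_finite() || arma::abs(Q).max() > guard) {
      diverged = true;
      break;
    }
    if (tr < tol) { converged = true; break; }
  }

  return List::create(_["q"] = Q, _["p"] = P,
                      _["gamma_prev"] = gamma_prev,
                      _["trace"] = trace,
                      _["epochs"] = epochs,
                      _["converged"] = converged,
                      _["diverged"] = diverged);
}

// Evaluation-only pass: activities for a fixed network over an input
// stream, with the same response-mode choice as training.
// Returns T x n activity matrix.
// [[Rcpp::export]]
arma::mat lahn_response_cpp(const arma::mat& Yt, const arma::mat& Q,
                            const arma::mat& P, arma::vec gamma_prev,
                            bool settled) {
  const arma::uword T = Yt.n_cols;
  const arma::uword n = Q.n_cols;
  arma::mat G(T, n);
  arma::vec g(n);
  if (settled) {
    const arma::mat A = arma::eye(n, n) - P.t();
    const arma::mat B = arma::solve(A, Q.t());
    for (arma::uword t = 0; t < T; ++t) {
      g = B * Yt.col(t);
      G.row(t) = g.t();
    }
  } else {
    for (arma::uword t = 0; t < T; ++t) {
      g = Q.t() * Yt.col(t) + P.t() * gamma_prev;
      G.row(t) = g.t();
      gamma_prev = g;
    }
  }
  return G;
}
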