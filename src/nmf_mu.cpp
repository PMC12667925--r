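// Multiplicative-update NMF minimizing the Frobenius error ||V - WH||_F.
// Lee-Seung updates keep the objective non-increasing; iteration stops at
// max_iter or when the relative objective change drops below tol.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, bool trace) {
  const double eps = 1e-12;
  const double vnorm = norm(V, "fro");
  std::vector<double> obj;
  double prev = datum::inf;
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    H %= (W.t() * V) / (W.t() * W * H + eps);
    W %= (V * H.t()) / (W * H * H.t() + eps);
    double err = norm(V - W * H, "fro");
    if (trace) obj.push_back(err);
    iters = it + 1;
    if (std::abs(prev - err) <= tol * std::max(vnorm, 1.0)) { prev = err; break; }
    prev = err;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = prev,
                            Rcpp::Named("trace") = obj,
                            Rcpp::Named("iterations") = iters);
}

// Consensus accumulation: run n_init factorizations from given random inits,
// assign each sample to its argmax H row, and accumulate the co-clustering
// indicator. Initial matrices are supplied from R so seeding stays on the R
// RNG.

// [[Rcpp::export(name = ".nmf_consensus_cpp")]]
arma::mat nmf_consensus_cpp(const arma::mat& V, const Rcpp::List& inits,
                            int max_iter, double tol) {
  const double eps = 1e-12;
  const int n = V.n_cols;
  const double vnorm = norm(V, "fro");
  mat consensus(n, n, fill::zeros);
  int n_init = inits.size();
  for (int r = 0; r < n_init; ++r) {
    Rcpp::List ini = inits[r];
    mat W = Rcpp::as<mat>(ini["W"]);
    mat H = Rcpp::as<mat>(ini["H"]);
    double prev = datum::inf;
    for (int it = 0; it < max_iter; ++it) {
      H %= (W.t() * V) / (W.t() * W * H + eps);
      W %= (V * H.t()) / (W * H * H.t() + eps);
      if ((it + 1) % 10 == 0 || it == max_iter - 1) {
        double err = norm(V - W * H, "fro");
        if (std::abs(prev - err) <= tol * std::max(vnorm, 1.0)) break;
        prev = err;
      }
    }
    uvec lab = index_max(H, 0).t();
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (lab[i] == lab[j]) consensus(i, j) += 1.0;
  }
  consensus /= n_init;
  return consensus;
}
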