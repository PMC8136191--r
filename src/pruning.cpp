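// Felsenstein pruning over sense-codon states with per-pattern
// log-scaling.  Per-branch transition matrices are built here from the
// eigendecomposition of the symmetrized rate matrix of the branch's
// class: P(t) = D^-1 U exp(lambda t) U' D with D = diag(sqrt(pi)).
// Edges must arrive in postorder (children before parents); tip states
// are 1-based codon indices, 0 = missing data (sums over all states).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
double prune_lnL_cpp(const arma::imat& edge,      // nedge x 2, postorder
                     const arma::ivec& class_idx, // per edge, 1-based
                     const arma::vec& lengths,    // per edge
                     const arma::cube& U,         // ncod x ncod x nclass
                     const arma::mat& lambda,     // ncod x nclass
                     const arma::vec& pi,         // ncod
                     const arma::imat& tipstates, // ntip x npat
                     const arma::vec& weights,    // npat
                     const int ntip,
                     const int nnode) {
  const int ncod = pi.n_elem;
  const int npat = tipstates.n_cols;
  const int nedge = edge.n_rows;
  const arma::vec sq = arma::sqrt(pi);
  std::vector<arma::mat> partial(nnode);
  std::vector<bool> seen(nnode, false);
  arma::vec logscale(npat, arma::fill::zeros);
  arma::mat P(ncod, ncod), E(ncod, ncod), contrib(ncod, npat);

  for (int k = 0; k < nedge; ++k) {
    const int parent = edge(k, 0) - 1;
    const int child = edge(k, 1) - 1;
    const int cl = class_idx(k) - 1;
    const arma::vec elt = arma::exp(lambda.col(cl) * lengths(k));
    E = U.slice(cl);
    E.each_row() %= elt.t();
    P = E * U.slice(cl).t();
    P.each_col() /= sq;
    P.each_row() %= sq.t();
    P.clamp(0.0, arma::datum::inf);
    if (child < ntip) {
      for (int p = 0; p < npat; ++p) {
        const int s = tipstates(child, p);
        if (s == 0) {
          contrib.col(p).ones();
        } else {
          contrib.col(p) = P.col(s - 1);
        }
      }
    } else {
      contrib = P * partial[child];
    }
    if (!seen[parent]) {
      partial[parent] = contrib;
      seen[parent] = true;
    } else {
      partial[parent] %= contrib;
      arma::rowvec mx = arma::max(partial[parent], 0);
      for (int p = 0; p < npat; ++p) {
        if (mx(p) > 0 && (mx(p) < 1e-40 || mx(p) > 1e40)) {
          partial[parent].col(p) /= mx(p);
          logscale(p) += std::log(mx(p));
        }
      }
    }
  }

  const int root = ntip;  // root is node ntip+1 (1-based)
  double lnL = 0.0;
  for (int p = 0; p < npat; ++p) {
    const double site_like = arma::dot(pi, partial[root].col(p));
    if (site_like <= 0.0 || !std::isfinite(site_like)) {
      return -std::numeric_limits<double>::infinity();
    }
    lnL += weights(p) * (std::log(site_like) + logscale(p));
  }
  return lnL;
}
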