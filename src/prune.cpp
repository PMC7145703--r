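// Pruning (tree-peeling) likelihood kernel. Postorder edge traversal with
// per-column rescaling; tips enter as transition-matrix column gathers,
// missing states as all-ones partials.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// edge: E x 2 matrix of 1-based node ids (postorder: children first)
// P: list of E transition matrices (nstates x nstates)
// tipstates: ntip x S integer matrix, 1-based states, 0 = missing
// pi: root frequencies; nnode_total: tips + internals; root: root id
// [[Rcpp::export]]
arma::vec cpp_prune_loglik(const arma::imat& edge, const List& P,
                           const arma::imat& tipstates, const arma::vec& pi,
                           const int nnode_total, const int root) {
  const int E = edge.n_rows;
  const int S = tipstates.n_cols;
  const int n = pi.n_elem;
  const int ntip = tipstates.n_rows;
  std::vector<arma::mat> partial(nnode_total + 1);
  std::vector<arma::rowvec> lsc(nnode_total + 1);
  arma::mat M(n, S);
  for (int k = 0; k < E; k++) {
    const int pa = edge(k, 0), ch = edge(k, 1);
    const arma::mat Pm = as<arma::mat>(P[k]);
    arma::rowvec sc;
    if (ch <= ntip) {
      for (int s = 0; s < S; s++) {
        const int st = tipstates(ch - 1, s);
        if (st == 0) M.col(s).ones();
        else M.col(s) = Pm.col(st - 1);
      }
    } else {
      M = Pm * partial[ch];
      sc = lsc[ch];
      partial[ch].reset();
    }
    if (partial[pa].n_elem == 0) {
      partial[pa] = M;
      lsc[pa] = sc.n_elem ? sc : arma::rowvec(S, arma::fill::zeros);
    } else {
      partial[pa] %= M;
      if (sc.n_elem) lsc[pa] += sc;
      arma::rowvec cs = arma::sum(partial[pa], 0);
      cs.transform([](double v) { return v <= 0 ? 1e-300 : v; });
      partial[pa].each_row() /= cs;
      lsc[pa] += arma::log(cs);
    }
  }
  arma::rowvec site = pi.t() * partial[root];
  site.transform([](double v) { return v <= 0 ? 1e-300 : v; });
  return (arma::log(site) + lsc[root]).t();
}

// Batch transition matrices P(t) = V diag(exp(lambda t)) V^-1 for a set of
// branch lengths, from a reversible-generator eigen system.
// [[Rcpp::export]]
List cpp_pmats(const arma::mat& vec, const arma::mat& inv,
               const arma::vec& values, const arma::vec& lengths) {
  const int E = lengths.n_elem;
  List out(E);
  for (int k = 0; k < E; k++) {
    arma::rowvec ex = arma::exp(values.t() * lengths[k]);
    arma::mat P = (vec.each_row() % ex) * inv;
    P.transform([](double v) { return v < 0 ? 0.0 : v; });
    out[k] = P;
  }
  return out;
}
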