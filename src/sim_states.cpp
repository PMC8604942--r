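#include <Rcpp.h>
using namespace Rcpp;

// Sample codon states for every node of a rooted tree, given per-edge,
// per-omega-category cumulative transition probabilities.
//
// edge:      E x 2 matrix of 1-based ape node ids, parents listed before
//            their children (preorder).
// cum_p:     numeric vector of length E * ncat * 61 * 61; for edge e and
//            category k, entry [(e*ncat + k)*3721 + parent*61 + child] is
//            the cumulative probability over child states (0-based indices).
// root_states, site_cat: 0-based codon / category index per site.
//
// Uses R's RNG so results are reproducible under set.seed().
// Returns an (n_nodes x S) matrix of 0-based codon states.
// [[Rcpp::export(name = ".sim_states_c")]]
IntegerMatrix sim_states_c(IntegerMatrix edge, int n_nodes,
                           NumericVector cum_p, int ncat,
                           IntegerVector root_states, IntegerVector site_cat,
                           int root_node) {
  const int S = root_states.size();
  const int E = edge.nrow();
  IntegerMatrix states(n_nodes, S);
  const double *cp = REAL(cum_p);
  for (int i = 0; i < S; ++i) states(root_node - 1, i) = root_states[i];
  for (int e = 0; e < E; ++e) {
    const int parent = edge(e, 0) - 1, child = edge(e, 1) - 1;
    for (int i = 0; i < S; ++i) {
      const int k = site_cat[i];
      const int p = states(parent, i);
      const double *row = cp + (((size_t) e * ncat + k) * 3721) + (size_t) p * 61;
      const double u = unif_rand();
      int c = 0;
      while (c < 60 && row[c] < u) ++c;
      states(child, i) = c;
    }
  }
  return states;
}
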