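// Felsenstein pruning pass for the Mk likelihood.
//
// The per-edge transition matrices are precomputed in R (eigendecomposition
// of Q, shared across edges); this routine only runs the postorder
// conditional-likelihood recursion with per-node rescaling, which dominates
// the optimiser's runtime.

#include <Rcpp.h>
using namespace Rcpp;

// edge: E x 2 (1-based node ids, postorder: children before parents)
// P: E x (k*k) matrix, column (j-1)*k + i holding P_e[i, j] (column-major)
// tip: n_tip x k tip state indicator/ambiguity matrix
// returns: list(root_cond = k-vector (rescaled), logscale = scalar)
// [[Rcpp::export(name = ".mk_prune_cpp")]]
List mk_prune_cpp(IntegerMatrix edge, NumericMatrix P, NumericMatrix tip,
                  int n_node, int root) {
  const int k = tip.ncol();
  const int n_tip = tip.nrow();
  const int E = edge.nrow();
  NumericMatrix cond(n_node, k);
  NumericVector logscale(n_node);
  for (int i = 0; i < n_node; ++i)
    for (int s = 0; s < k; ++s)
      cond(i, s) = (i < n_tip) ? tip(i, s) : 1.0;
  std::vector<double> part(k);
  for (int e = 0; e < E; ++e) {
    const int p = edge(e, 0) - 1;
    const int ch = edge(e, 1) - 1;
    for (int i = 0; i < k; ++i) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += P(e, j * k + i) * cond(ch, j);
      part[i] = acc;
    }
    double m = 0.0;
    for (int i = 0; i < k; ++i) {
      cond(p, i) *= part[i];
      if (cond(p, i) > m) m = cond(p, i);
    }
    if (m <= 0.0) return List::create(Named("root_cond") = R_NilValue,
                                      Named("logscale") = R_NegInf);
    logscale[p] += logscale[ch] + std::log(m);
    logscale[ch] = 0.0;  // consumed
    for (int i = 0; i < k; ++i) cond(p, i) /= m;
  }
  NumericVector rc(k);
  for (int i = 0; i < k; ++i) rc[i] = cond(root - 1, i);
  return List::create(Named("root_cond") = rc,
                      Named("logscale") = logscale[root - 1]);
}
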