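#include <Rcpp.h>
using namespace Rcpp;

// Generalised Sankoff dynamic programme over an arbitrary (possibly
// polytomous) tree given in postorder.  One call scores a batch of
// characters; each character brings its own terminal-cost matrix and
// state-change cost matrix, so unordered (uniform cost), ordered
// (|i-j| cost) and continuous (|x_i-x_j| over the observed candidate
// values) characters all run through the same recursion.
//
// edge:      2-column matrix of 1-based node ids, postorder-sorted
//            (every child row precedes its parent's row); tips are a
//            subset of ids, the root is the parent of the last edge.
// n_nodes:   total number of node ids (array size).
// tip_rows:  per character, an IntegerVector mapping node id -> row of
//            the terminal cost matrix (0 for internal nodes), shared
//            across characters here as tips are common.
// tip_costs: per character, an (n_tip x k_c) matrix of terminal state
//            costs (0 for allowed states, a large penalty otherwise;
//            all-zero rows encode missing data).
// cost_mats: per character, a (k_c x k_c) state-change cost matrix.
//
// Returns the per-character minimum total cost (unweighted steps).

// [[Rcpp::export]]
NumericVector sankoff_scores(IntegerMatrix edge, int n_nodes,
                             IntegerVector tip_row, List tip_costs,
                             List cost_mats) {
  const int n_edge = edge.nrow();
  const int nchar = tip_costs.size();
  NumericVector out(nchar);
  if (n_edge == 0) return out;
  const int root = edge(n_edge - 1, 0) - 1;

  std::vector<double> D;
  for (int c = 0; c < nchar; ++c) {
    NumericMatrix tc = tip_costs[c];
    NumericMatrix cm = cost_mats[c];
    const int k = cm.nrow();
    D.assign((size_t)n_nodes * k, 0.0);
    for (int v = 0; v < n_nodes; ++v) {
      int r = tip_row[v];
      if (r > 0)
        for (int s = 0; s < k; ++s) D[(size_t)v * k + s] = tc(r - 1, s);
    }
    for (int e = 0; e < n_edge; ++e) {
      const int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      const double *dc = &D[(size_t)ch * k];
      double *dp = &D[(size_t)p * k];
      for (int t = 0; t < k; ++t) {
        double best = R_PosInf;
        for (int s = 0; s < k; ++s) {
          double v = cm(t, s) + dc[s];
          if (v < best) best = v;
        }
        dp[t] += best;
      }
    }
    double best = R_PosInf;
    for (int s = 0; s < k; ++s)
      best = std::min(best, D[(size_t)root * k + s]);
    out[c] = best;
  }
  return out;
}

// Down-pass cost vectors for every node of one character: the same
// recursion as sankoff_scores but returning the full table, used by the
// ancestral-state (MPR) machinery in R.
// [[Rcpp::export]]
NumericMatrix sankoff_down(IntegerMatrix edge, int n_nodes,
                           IntegerVector tip_row, NumericMatrix tip_cost,
                           NumericMatrix cost) {
  const int n_edge = edge.nrow();
  const int k = cost.nrow();
  NumericMatrix D(n_nodes, k);
  for (int v = 0; v < n_nodes; ++v) {
    int r = tip_row[v];
    if (r > 0)
      for (int s = 0; s < k; ++s) D(v, s) = tip_cost(r - 1, s);
  }
  for (int e = 0; e < n_edge; ++e) {
    const int p = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    for (int t = 0; t < k; ++t) {
      double best = R_PosInf;
      for (int s = 0; s < k; ++s) {
        double v = cost(t, s) + D(ch, s);
        if (v < best) best = v;
      }
      D(p, t) += best;
    }
  }
  return D;
}
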