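#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

// First-order weighted random walks (node2vec with p = q = 1).
//
// adj / wts: per-node out-neighbour indices (0-based) and positive weights,
// zero-weight edges must already be dropped by the caller.  Per pass the
// start-node order is shuffled; a node with no positive out-edge truncates
// the walk.  All randomness comes from the supplied seed so runs are
// reproducible.
// [[Rcpp::export]]
List random_walks_cpp(List adj, List wts, int n_walks_per_node,
                      int walk_length, int seed) {
  int n = adj.size();
  std::vector<std::vector<int>> nbr(n);
  std::vector<std::vector<double>> cum(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = adj[i];
    NumericVector w = wts[i];
    nbr[i].assign(a.begin(), a.end());
    cum[i].resize(w.size());
    double acc = 0.0;
    for (int j = 0; j < w.size(); ++j) {
      acc += w[j];
      cum[i][j] = acc;
    }
  }

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  List out(static_cast<R_xlen_t>(n) * n_walks_per_node);
  R_xlen_t pos = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<int> walk;
  walk.reserve(walk_length);

  for (int pass = 0; pass < n_walks_per_node; ++pass) {
    // Fisher-Yates shuffle of start nodes
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(order[i], order[d(rng)]);
    }
    for (int s = 0; s < n; ++s) {
      int cur = order[s];
      walk.clear();
      walk.push_back(cur);
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<double>& c = cum[cur];
        if (c.empty() || c.back() <= 0.0) break;  // dead end
        double r = unif(rng) * c.back();
        int lo = 0, hi = static_cast<int>(c.size()) - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (c[mid] < r) lo = mid + 1; else hi = mid;
        }
        cur = nbr[cur][lo];
        walk.push_back(cur);
      }
      out[pos++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}
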