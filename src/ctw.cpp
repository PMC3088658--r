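#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Binary context-tree weighting with Krichevsky-Trofimov node estimators and
// weight 1/2 at internal nodes. Log-domain throughout. Contexts grow only
// along observed paths, so memory is O(distinct contexts), not O(2^depth).

namespace {

struct Tree {
  std::vector<int> child0, child1;
  std::vector<double> a, b;     // counts of 0s / 1s seen at this context
  std::vector<double> lpe, lpw; // log KT estimate, log weighted probability

  int new_node() {
    child0.push_back(-1);
    child1.push_back(-1);
    a.push_back(0.0);
    b.push_back(0.0);
    lpe.push_back(0.0);
    lpw.push_back(0.0);
    return (int)child0.size() - 1;
  }
};

inline double log_sum_exp(double x, double y) {
  if (x < y) std::swap(x, y);
  return x + std::log1p(std::exp(y - x));
}

} // namespace

// [[Rcpp::export]]
List ctw_entropy_cpp(IntegerVector x, int depth) {
  const int n = x.size();
  if (depth < 1) stop("depth must be >= 1");
  if (depth >= n) stop("depth must be smaller than the sequence length");

  for (int i = 0; i < n; ++i) {
    if (x[i] != 0 && x[i] != 1) stop("sequence must be strictly 0/1");
  }

  Tree tr;
  tr.new_node(); // root
  std::vector<int> path(depth + 1);

  // Symbols before index `depth` only provide context.
  int nsym = 0;
  for (int t = depth; t < n; ++t) {
    const int sym = x[t];

    // Walk root -> leaf along the context (most recent symbol first).
    path[0] = 0;
    int node = 0;
    for (int d = 1; d <= depth; ++d) {
      const int bit = x[t - d];
      int nxt = bit ? tr.child1[node] : tr.child0[node];
      if (nxt < 0) {
        nxt = tr.new_node();
        if (bit) tr.child1[node] = nxt; else tr.child0[node] = nxt;
      }
      path[d] = nxt;
      node = nxt;
    }

    // KT update + weighting, leaf back to root.
    for (int d = depth; d >= 0; --d) {
      const int v = path[d];
      const double tot = tr.a[v] + tr.b[v];
      const double lp = sym
        ? std::log((tr.b[v] + 0.5) / (tot + 1.0))
        : std::log((tr.a[v] + 0.5) / (tot + 1.0));
      tr.lpe[v] += lp;
      if (sym) tr.b[v] += 1.0; else tr.a[v] += 1.0;
      if (d == depth) {
        tr.lpw[v] = tr.lpe[v];
      } else {
        const int c0 = tr.child0[v], c1 = tr.child1[v];
        const double lw0 = c0 >= 0 ? tr.lpw[c0] : 0.0;
        const double lw1 = c1 >= 0 ? tr.lpw[c1] : 0.0;
        tr.lpw[v] = std::log(0.5) + log_sum_exp(tr.lpe[v], lw0 + lw1);
      }
    }
    ++nsym;
  }

  const double bits = -tr.lpw[0] / std::log(2.0);
  return List::create(
    _["bits_total"] = bits,
    _["n_symbols"] = nsym,
    _["bits_per_symbol"] = bits / nsym,
    _["n_nodes"] = (int)tr.child0.size());
}
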