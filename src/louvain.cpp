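// Greedy multilevel (Louvain-style) maximisation of a generalized quality
// matrix. The quality of a partition is the sum of matrix entries over all
// within-community (ordered) pairs, including the diagonal. For Markov
// stability the matrix is B(t) = Pi P(t) - pi pi^T (symmetrised), which has
// negative entries, so standard modularity Louvain implementations do not
// apply; the move/aggregate scheme below works for any symmetric matrix.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

// SplitMix64: tiny deterministic RNG, independent of R's RNG stream so that
// optimisation runs are reproducible from an integer seed on any platform.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

void shuffled_order(std::vector<int>& v, SplitMix& rng) {
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(v[i], v[j]);
  }
}

const double kGainTol = 1e-12;

// One pass of greedy single-node moves on the m x m symmetric matrix M
// (column-major, stride m). labels are community ids in [0, m). Returns
// true if any node moved. Ties in gain go to the lowest community index.
bool local_moves(const std::vector<double>& M, int m, std::vector<int>& labels,
                 const std::vector<int>& order) {
  std::vector<double> conn(m);
  std::vector<int> touched;
  touched.reserve(m);
  bool any = false;
  bool moved = true;
  while (moved) {
    moved = false;
    for (int oi = 0; oi < m; ++oi) {
      int v = order[oi];
      touched.clear();
      const double* col = &M[static_cast<size_t>(v) * m];
      for (int u = 0; u < m; ++u) {
        if (u == v) continue;
        int c = labels[u];
        if (conn[c] == 0.0) touched.push_back(c);
        conn[c] += col[u];
      }
      std::sort(touched.begin(), touched.end());
      int cur = labels[v];
      double base = conn[cur];   // 0 if v alone (cur not touched)
      if (std::find(touched.begin(), touched.end(), cur) == touched.end())
        base = 0.0;
      int best = cur;
      double best_gain = 0.0;
      for (size_t ti = 0; ti < touched.size(); ++ti) {
        int c = touched[ti];
        if (c == cur) continue;
        double gain = conn[c] - base;
        if (gain > best_gain + kGainTol) { best_gain = gain; best = c; }
      }
      // moving to an empty (fresh) community == leaving cur: gain -base
      if (-base > best_gain + kGainTol) { best_gain = -base; best = -1; }
      for (size_t ti = 0; ti < touched.size(); ++ti) conn[touched[ti]] = 0.0;
      if (best != cur && best_gain > kGainTol) {
        if (best == -1) {
          // find an unused community id (there is always one since v leaves cur)
          std::vector<char> used(m, 0);
          for (int u = 0; u < m; ++u) used[labels[u]] = 1;
          for (int c = 0; c < m; ++c) if (!used[c]) { best = c; break; }
        }
        labels[v] = best;
        moved = true;
        any = true;
      }
    }
  }
  return any;
}

int compact_labels(std::vector<int>& labels) {
  std::vector<int> map(labels.size(), -1);
  int k = 0;
  for (size_t i = 0; i < labels.size(); ++i) {
    if (map[labels[i]] < 0) map[labels[i]] = k++;
    labels[i] = map[labels[i]];
  }
  return k;
}

}  // namespace

// [[Rcpp::export(rng = false)]]
List louvain_quality(NumericMatrix B, int seed) {
  const int n = B.nrow();
  if (B.ncol() != n) stop("quality matrix must be square");
  SplitMix rng(static_cast<uint64_t>(seed) * 0x2545F4914F6CDD1DULL + 1ULL);

  std::vector<double> M(B.begin(), B.end());
  int m = n;
  std::vector<int> node2meta(n);
  for (int i = 0; i < n; ++i) node2meta[i] = i;

  while (true) {
    std::vector<int> labels(m), order(m);
    for (int i = 0; i < m; ++i) { labels[i] = i; order[i] = i; }
    shuffled_order(order, rng);
    local_moves(M, m, labels, order);
    int k = compact_labels(labels);
    if (k == m) break;  // no coarsening achieved: done
    // aggregate
    std::vector<double> M2(static_cast<size_t>(k) * k, 0.0);
    for (int u = 0; u < m; ++u)
      for (int v = 0; v < m; ++v)
        M2[static_cast<size_t>(labels[u]) * k + labels[v]] +=
            M[static_cast<size_t>(u) * m + v];
    for (int i = 0; i < n; ++i) node2meta[i] = labels[node2meta[i]];
    M.swap(M2);
    m = k;
  }

  // final refinement at single-node resolution so that no single-node move
  // can improve the returned partition
  {
    std::vector<double> Borig(B.begin(), B.end());
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    shuffled_order(order, rng);
    local_moves(Borig, n, node2meta, order);
    compact_labels(node2meta);
  }

  double q = 0.0;
  for (int u = 0; u < n; ++u)
    for (int v = 0; v < n; ++v)
      if (node2meta[u] == node2meta[v]) q += B(u, v);

  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = node2meta[i] + 1;
  return List::create(_["labels"] = lab, _["stability"] = q);
}
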