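#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Maximum-parsimony tree search over unrooted binary topologies, by
// stepwise insertion of taxa (exhaustive enumeration or branch-and-bound;
// the Fitch length of a partial tree never decreases as taxa are added,
// which gives the bound). States are bit codes (A=1, C=2, G=4, T=8) per
// taxon per site pattern; `weights` are pattern multiplicities.
//
// Tree representation: rooted at leaf 0. Node ids: leaves 0..n-1,
// internals n..2n-3. parent/left/right arrays; child0 = the single child
// of the root leaf 0.

struct MPSearch {
  int n, npat;
  const int* states;           // column-major: states[tx + n * pat]
  const int* weights;
  std::vector<int> parent, left, right;
  int child0;
  std::vector<std::vector<int>> setbuf; // per-node state sets
  std::vector<int> active;              // insertable nodes (non-root)
  long best;
  bool exhaustive;
  std::vector<std::string> trees;
  std::vector<std::vector<uint32_t>> splits;
  long n_scored;
  int max_save;

  long fitch_node(int v) {
    // fills setbuf[v], returns weighted changes in subtree of v
    if (v < n) {
      for (int p = 0; p < npat; p++) setbuf[v][p] = states[v + n * p];
      return 0;
    }
    long cost = fitch_node(left[v]) + fitch_node(right[v]);
    const std::vector<int>& a = setbuf[left[v]];
    const std::vector<int>& b = setbuf[right[v]];
    std::vector<int>& o = setbuf[v];
    for (int p = 0; p < npat; p++) {
      int x = a[p] & b[p];
      if (x == 0) { x = a[p] | b[p]; cost += weights[p]; }
      o[p] = x;
    }
    return cost;
  }

  long score() {
    n_scored++;
    long cost = fitch_node(child0);
    const std::vector<int>& a = setbuf[child0];
    for (int p = 0; p < npat; p++) {
      if ((a[p] & states[0 + n * p]) == 0) cost += weights[p];
    }
    return cost;
  }

  void subtree_mask(int v, uint32_t& m) {
    if (v < n) { m |= (1u << v); return; }
    subtree_mask(left[v], m);
    subtree_mask(right[v], m);
  }

  void collect_splits(std::vector<uint32_t>& out) {
    // internal edges: (parent(w), w) with w internal and parent(w) != 0
    for (int w = n; w < 2 * n - 2; w++) {
      if (parent[w] == 0) continue;
      uint32_t m = 0;
      subtree_mask(w, m);
      out.push_back(m); // never contains taxon 0 -> canonical
    }
  }

  std::string newick_node(int v) {
    if (v < n) return std::to_string(v);
    return "(" + newick_node(left[v]) + "," + newick_node(right[v]) + ")";
  }

  void save_tree() {
    if ((int)trees.size() >= max_save) return;
    std::string nw = "(0," + newick_node(left[child0]) + "," +
                     newick_node(right[child0]) + ");";
    trees.push_back(nw);
    std::vector<uint32_t> sp;
    collect_splits(sp);
    splits.push_back(sp);
  }

  void attach(int v, int t, int w) {
    // insert internal w and leaf t on the edge above v
    int u = parent[v];
    if (u == 0) child0 = w;
    else if (left[u] == v) left[u] = w;
    else right[u] = w;
    parent[w] = u;
    left[w] = v;
    right[w] = t;
    parent[v] = w;
    parent[t] = w;
  }

  void detach(int v, int t, int w) {
    int u = parent[w];
    if (u == 0) child0 = v;
    else if (left[u] == w) left[u] = v;
    else right[u] = v;
    parent[v] = u;
    (void)t;
  }

  void rec(int m) {
    if (m == n) {
      long s = score();
      if (s < best) {
        best = s;
        trees.clear();
        splits.clear();
        save_tree();
      } else if (s == best) {
        save_tree();
      }
      return;
    }
    int t = m;
    int w = n + m - 2;
    size_t n_active = active.size();
    for (size_t e = 0; e < n_active; e++) {
      int v = active[e];
      attach(v, t, w);
      bool go = true;
      if (!exhaustive) {
        long ps = score();
        if (ps > best) go = false;
      }
      if (go) {
        active.push_back(t);
        active.push_back(w);
        rec(m + 1);
        active.pop_back();
        active.pop_back();
      }
      detach(v, t, w);
    }
  }
};

// [[Rcpp::export]]
List cpp_mp_search(IntegerMatrix states, IntegerVector weights, bool exhaustive,
                   int max_save, double init_bound) {
  const int n = states.nrow();
  const int npat = states.ncol();
  if (n < 3) stop("need at least 3 taxa");
  if (n > 20) stop("too many taxa for this search");
  MPSearch S;
  S.n = n;
  S.npat = npat;
  std::vector<int> st(n * npat);
  for (int p = 0; p < npat; p++)
    for (int t = 0; t < n; t++) st[t + n * p] = states(t, p);
  std::vector<int> wt(weights.begin(), weights.end());
  S.states = st.data();
  S.weights = wt.data();
  S.parent.assign(2 * n - 2, -1);
  S.left.assign(2 * n - 2, -1);
  S.right.assign(2 * n - 2, -1);
  S.setbuf.assign(2 * n - 2, std::vector<int>(npat));
  S.best = (init_bound == R_PosInf) ? LONG_MAX / 4 : (long)init_bound;
  S.exhaustive = exhaustive;
  S.n_scored = 0;
  S.max_save = max_save;
  // initial 3-taxon star: root leaf 0 -> internal n -> leaves 1, 2
  S.child0 = n;
  S.parent[n] = 0;
  S.left[n] = 1;
  S.right[n] = 2;
  S.parent[1] = n;
  S.parent[2] = n;
  S.active = {1, 2, n};
  if (n == 3) {
    long s = S.score();
    S.best = s;
    S.save_tree();
  } else {
    S.rec(3);
  }
  List spl(S.splits.size());
  for (int i = 0; i < (int)S.splits.size(); i++) {
    IntegerVector v(S.splits[i].size());
    for (int j = 0; j < (int)S.splits[i].size(); j++) v[j] = (int)S.splits[i][j];
    spl[i] = v;
  }
  return List::create(_["score"] = (double)S.best,
                      _["trees"] = wrap(S.trees),
                      _["splits"] = spl,
                      _["n_scored"] = (double)S.n_scored);
}

// Fitch length of one fixed tree given as a postorder edge list
// (each row: parent id, child id; ids 1-based; leaves 1..n in matrix row
// order; root = node after... ). Used by the R-level scorer for speed.
// [[Rcpp::export]]
double cpp_fitch_score(IntegerMatrix states, IntegerVector weights,
                       IntegerMatrix edges, int n_node, int root) {
  const int n = states.nrow();
  const int npat = states.ncol();
  std::vector<std::vector<int>> sets(n_node + 1, std::vector<int>(npat, 0));
  std::vector<bool> init(n_node + 1, false);
  for (int t = 1; t <= n; t++) {
    for (int p = 0; p < npat; p++) sets[t][p] = states(t - 1, p);
    init[t] = true;
  }
  long cost = 0;
  // edges assumed in postorder (children before parents)
  for (int e = 0; e < edges.nrow(); e++) {
    int pa = edges(e, 0), ch = edges(e, 1);
    if (!init[ch]) stop("edges not in postorder");
    if (!init[pa]) {
      sets[pa] = sets[ch];
      init[pa] = true;
    } else {
      for (int p = 0; p < npat; p++) {
        int x = sets[pa][p] & sets[ch][p];
        if (x == 0) { x = sets[pa][p] | sets[ch][p]; cost += weights[p]; }
        sets[pa][p] = x;
      }
    }
  }
  (void)root;
  return (double)cost;
}
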