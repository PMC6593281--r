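#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Dense-adjacency graph used by the null-ensemble hot path. Node count in
// connectome work is a few hundred at most, so an n*n byte matrix is cheap
// and makes edge lookups O(1).
namespace {

struct Graph {
  int n;
  std::vector<std::pair<int, int> > edges; // 0-based
  std::vector<char> adj;

  bool has(int a, int b) const { return adj[(size_t)a * n + b] != 0; }
  void set(int a, int b, char v) {
    adj[(size_t)a * n + b] = v;
    adj[(size_t)b * n + a] = v;
  }
};

Graph build_graph(const IntegerMatrix &e, int n) {
  Graph g;
  g.n = n;
  g.adj.assign((size_t)n * n, 0);
  g.edges.reserve(e.nrow());
  for (int i = 0; i < e.nrow(); ++i) {
    int a = e(i, 0) - 1, b = e(i, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n) stop("edge index out of range");
    if (a == b) stop("self-loop in edge list");
    if (g.has(a, b)) stop("duplicate edge in edge list");
    g.edges.push_back(std::make_pair(a, b));
    g.set(a, b, 1);
  }
  return g;
}

// Maslov-Sneppen double-edge swaps. Uses R's RNG (caller must hold an
// RNGScope, which Rcpp attributes provide) so results obey set.seed().
// Each attempted swap draws two distinct edges and a random orientation;
// proposals that would create a self-loop or multi-edge are discarded and
// retried up to max_tries times, then that swap is skipped.
void ms_rewire(Graph &g, double swaps_per_edge, int max_tries) {
  const int m = (int)g.edges.size();
  if (m < 2) return;
  const long long target = (long long)std::llround(swaps_per_edge * m);
  for (long long s = 0; s < target; ++s) {
    for (int t = 0; t < max_tries; ++t) {
      int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
      int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
      if (i == j) continue;
      int a = g.edges[i].first, b = g.edges[i].second;
      int c = g.edges[j].first, d = g.edges[j].second;
      if (unif_rand() < 0.5) std::swap(c, d);
      // propose (a,b),(c,d) -> (a,d),(c,b)
      if (a == c || a == d || b == c || b == d) continue;
      if (g.has(a, d) || g.has(c, b)) continue;
      g.set(a, b, 0); g.set(c, d, 0);
      g.set(a, d, 1); g.set(c, b, 1);
      g.edges[i] = std::make_pair(a, d);
      g.edges[j] = std::make_pair(c, b);
      break;
    }
  }
}

std::vector<std::vector<int> > neighbor_lists(const Graph &g) {
  std::vector<std::vector<int> > nb(g.n);
  for (size_t i = 0; i < g.edges.size(); ++i) {
    nb[g.edges[i].first].push_back(g.edges[i].second);
    nb[g.edges[i].second].push_back(g.edges[i].first);
  }
  return nb;
}

// Mean binary clustering coefficient; nodes with degree < 2 count as 0.
double clustering_mean(const Graph &g, const std::vector<std::vector<int> > &nb) {
  double acc = 0.0;
  for (int v = 0; v < g.n; ++v) {
    const std::vector<int> &nv = nb[v];
    const int k = (int)nv.size();
    if (k < 2) continue;
    int tri = 0;
    for (int i = 0; i < k; ++i)
      for (int j = i + 1; j < k; ++j)
        if (g.has(nv[i], nv[j])) ++tri;
    acc += 2.0 * tri / ((double)k * (k - 1));
  }
  return acc / g.n;
}

// Characteristic path length over finite pairs only (BFS from every node);
// also counts unordered unreachable pairs.
void path_length(const Graph &g, const std::vector<std::vector<int> > &nb,
                 double &lp, double &n_inf_pairs) {
  const int n = g.n;
  std::vector<int> dist(n), queue(n);
  long long finite_ordered = 0;
  double dist_sum = 0.0;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      const std::vector<int> &nv = nb[v];
      for (size_t i = 0; i < nv.size(); ++i) {
        int w = nv[i];
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          queue[tail++] = w;
        }
      }
    }
    for (int t = 0; t < n; ++t) {
      if (t != s && dist[t] > 0) {
        dist_sum += dist[t];
        ++finite_ordered;
      }
    }
  }
  lp = finite_ordered > 0 ? dist_sum / finite_ordered : NA_REAL;
  n_inf_pairs = ((double)n * (n - 1) - finite_ordered) / 2.0;
}

// Global efficiency of the subgraph induced on one node's neighbours:
// BFS restricted to the neighbour set, mean of 1/d over ordered pairs
// (unreachable pairs contribute 0).
double neighborhood_efficiency(const Graph &g,
                               const std::vector<std::vector<int> > &nb,
                               int v, std::vector<int> &sub_index,
                               std::vector<int> &dist, std::vector<int> &queue) {
  const std::vector<int> &nv = nb[v];
  const int k = (int)nv.size();
  if (k < 2) return 0.0;
  for (int i = 0; i < k; ++i) sub_index[nv[i]] = i;
  double acc = 0.0;
  for (int si = 0; si < k; ++si) {
    std::fill(dist.begin(), dist.begin() + k, -1);
    dist[si] = 0;
    int head = 0, tail = 0;
    queue[tail++] = si;
    while (head < tail) {
      int u = queue[head++];
      const std::vector<int> &nu = nb[nv[u]];
      for (size_t j = 0; j < nu.size(); ++j) {
        if (sub_index[nu[j]] < 0) continue; // outside the neighbourhood
        int w = sub_index[nu[j]];
        if (dist[w] < 0) {
          dist[w] = dist[u] + 1;
          queue[tail++] = w;
        }
      }
    }
    for (int t = 0; t < k; ++t)
      if (t != si && dist[t] > 0) acc += 1.0 / dist[t];
  }
  for (int i = 0; i < k; ++i) sub_index[nv[i]] = -1;
  return acc / ((double)k * (k - 1));
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".ms_rewire_cpp")]]
IntegerMatrix ms_rewire_cpp(IntegerMatrix edges, int n, double swaps_per_edge,
                            int max_tries) {
  Graph g = build_graph(edges, n);
  ms_rewire(g, swaps_per_edge, max_tries);
  IntegerMatrix out((int)g.edges.size(), 2);
  for (int i = 0; i < (int)g.edges.size(); ++i) {
    out(i, 0) = g.edges[i].first + 1;
    out(i, 1) = g.edges[i].second + 1;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cp_lp_cpp")]]
NumericVector cp_lp_cpp(IntegerMatrix edges, int n) {
  Graph g = build_graph(edges, n);
  std::vector<std::vector<int> > nb = neighbor_lists(g);
  double lp, ninf;
  path_length(g, nb, lp, ninf);
  NumericVector out = NumericVector::create(
      _["cp"] = clustering_mean(g, nb), _["lp"] = lp, _["n_inf_pairs"] = ninf);
  return out;
}

// Per-node local efficiency (induced neighbour subgraph definition).
//' @noRd
// [[Rcpp::export(name = ".local_eff_cpp")]]
NumericVector local_eff_cpp(IntegerMatrix edges, int n) {
  Graph g = build_graph(edges, n);
  std::vector<std::vector<int> > nb = neighbor_lists(g);
  std::vector<int> sub_index(n, -1), dist(n), queue(n);
  NumericVector out(n);
  for (int v = 0; v < n; ++v)
    out[v] = neighborhood_efficiency(g, nb, v, sub_index, dist, queue);
  return out;
}

// cp and lp for n_nulls independent degree-preserving rewirings of the same
// input graph: one row per null.
//' @noRd
// [[Rcpp::export(name = ".null_cp_lp_cpp")]]
NumericMatrix null_cp_lp_cpp(IntegerMatrix edges, int n, int n_nulls,
                             double swaps_per_edge, int max_tries) {
  const Graph base = build_graph(edges, n);
  NumericMatrix out(n_nulls, 2);
  colnames(out) = CharacterVector::create("cp", "lp");
  for (int r = 0; r < n_nulls; ++r) {
    Graph g = base;
    ms_rewire(g, swaps_per_edge, max_tries);
    std::vector<std::vector<int> > nb = neighbor_lists(g);
    double lp, ninf;
    path_length(g, nb, lp, ninf);
    out(r, 0) = clustering_mean(g, nb);
    out(r, 1) = lp;
  }
  return out;
}
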