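// Fast core for binary-graph metrics on small undirected graphs (N <= 64).
// Graphs arrive as ranked edge lists (0-based, i < j); prefixes of the list
// give the nested binary networks across the sparsity grid. Node sets are
// held in 64-bit masks so a BFS level is a handful of OR/popcount ops.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

typedef uint64_t mask_t;

inline int popcnt(mask_t x) { return __builtin_popcountll(x); }

struct BitGraph {
  int n;
  mask_t adj[64];
  BitGraph(int n_) : n(n_) {
    if (n_ > 64) stop("graphs with more than 64 nodes are not supported");
    for (int i = 0; i < 64; ++i) adj[i] = 0;
  }
  void add(int a, int b) {
    adj[a] |= (mask_t)1 << b;
    adj[b] |= (mask_t)1 << a;
  }
  void remove(int a, int b) {
    adj[a] &= ~((mask_t)1 << b);
    adj[b] &= ~((mask_t)1 << a);
  }
  bool has(int a, int b) const { return (adj[a] >> b) & 1; }
};

// neighbourhood OR over the set bits of `frontier`
inline mask_t expand(const BitGraph &g, mask_t frontier) {
  mask_t next = 0;
  while (frontier) {
    int v = __builtin_ctzll(frontier);
    frontier &= frontier - 1;
    next |= g.adj[v];
  }
  return next;
}

// Lp over reachable ordered pairs (NA if none), Eglob, unreachable fraction,
// per-node efficiency. One bitset BFS per source.
void path_stats(const BitGraph &g, double &lp, double &eglob, double &unreach,
                double *neff) {
  int n = g.n;
  double dsum = 0.0, invsum = 0.0;
  long nfin = 0, ninf = 0;
  for (int s = 0; s < n; ++s) {
    mask_t visited = (mask_t)1 << s;
    mask_t frontier = visited;
    double inv_s = 0.0;
    int d = 0;
    int reached = 1;
    while (frontier) {
      ++d;
      mask_t next = expand(g, frontier) & ~visited;
      if (!next) break;
      int cnt = popcnt(next);
      dsum += (double)d * cnt;
      inv_s += (double)cnt / d;
      nfin += cnt;
      reached += cnt;
      visited |= next;
      frontier = next;
    }
    ninf += n - reached;
    if (neff) neff[s] = inv_s / (n - 1);
    invsum += inv_s;
  }
  lp = nfin > 0 ? dsum / nfin : NA_REAL;
  eglob = invsum / ((double)n * (n - 1));
  unreach = (double)ninf / ((double)n * (n - 1));
}

// mean clustering coefficient (per-node values optional)
double mean_clustering(const BitGraph &g, double *per_node) {
  double tot = 0.0;
  for (int v = 0; v < g.n; ++v) {
    int deg = popcnt(g.adj[v]);
    double cc = 0.0;
    if (deg >= 2) {
      mask_t nb = g.adj[v];
      long links2 = 0; // each neighbourhood edge counted twice
      mask_t it = nb;
      while (it) {
        int w = __builtin_ctzll(it);
        it &= it - 1;
        links2 += popcnt(g.adj[w] & nb);
      }
      cc = (double)links2 / ((double)deg * (deg - 1));
    }
    if (per_node) per_node[v] = cc;
    tot += cc;
  }
  return tot / g.n;
}

// efficiency of the subgraph induced by mask `sub` (>= 2 nodes assumed
// checked by caller); BFS restricted to the mask
double masked_efficiency(const BitGraph &g, mask_t sub, int m) {
  double tot = 0.0;
  mask_t it = sub;
  while (it) {
    int s = __builtin_ctzll(it);
    it &= it - 1;
    mask_t visited = (mask_t)1 << s;
    mask_t frontier = visited;
    int d = 0;
    while (frontier) {
      ++d;
      mask_t next = expand(g, frontier) & sub & ~visited;
      if (!next) break;
      tot += (double)popcnt(next) / d;
      visited |= next;
      frontier = next;
    }
  }
  return tot / ((double)m * (m - 1));
}

double local_efficiency(const BitGraph &g) {
  double tot = 0.0;
  for (int v = 0; v < g.n; ++v) {
    int m = popcnt(g.adj[v]);
    if (m >= 2) tot += masked_efficiency(g, g.adj[v], m);
  }
  return tot / g.n;
}

// Brandes betweenness (fractional path credit), unordered-pair convention
void brandes(const BitGraph &g, std::vector<double> &cb) {
  int n = g.n;
  cb.assign(n, 0.0);
  std::vector<int> dist(n), stack_;
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  std::queue<int> q;
  for (int s = 0; s < n; ++s) {
    stack_.clear();
    for (int i = 0; i < n; ++i) {
      pred[i].clear();
      sigma[i] = 0.0;
      delta[i] = 0.0;
      dist[i] = -1;
    }
    sigma[s] = 1.0;
    dist[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      stack_.push_back(v);
      mask_t nb = g.adj[v];
      while (nb) {
        int w = __builtin_ctzll(nb);
        nb &= nb - 1;
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int i = (int)stack_.size() - 1; i >= 0; --i) {
      int w = stack_[i];
      for (int v : pred[w]) delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) cb[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) cb[i] *= 0.5;
}

// Maslov-Sneppen double-edge swaps on an edge list; returns accepted count
int rewire_edges(std::vector<std::pair<int, int>> &edges, BitGraph &g,
                 int n_attempts) {
  int K = (int)edges.size();
  if (K < 2) return 0;
  int accepted = 0;
  for (int it = 0; it < n_attempts; ++it) {
    int e1 = (int)(unif_rand() * K);
    int e2 = (int)(unif_rand() * K);
    if (e1 >= K) e1 = K - 1;
    if (e2 >= K) e2 = K - 1;
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,d) and (c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (g.has(a, d) || g.has(c, b)) continue;
    g.remove(a, b);
    g.remove(c, d);
    g.add(a, d);
    g.add(c, b);
    edges[e1] = std::make_pair(std::min(a, d), std::max(a, d));
    edges[e2] = std::make_pair(std::min(c, b), std::max(c, b));
    ++accepted;
  }
  return accepted;
}

BitGraph graph_from_edges(const IntegerMatrix &edges, int n, int k) {
  BitGraph g(n);
  for (int e = 0; e < k; ++e) g.add(edges(e, 0), edges(e, 1));
  return g;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(IntegerMatrix edges, int n) {
  BitGraph g = graph_from_edges(edges, n, edges.nrow());
  NumericMatrix D(n, n);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int s = 0; s < n; ++s) {
    D(s, s) = 0.0;
    mask_t visited = (mask_t)1 << s;
    mask_t frontier = visited;
    int d = 0;
    while (frontier) {
      ++d;
      mask_t next = expand(g, frontier) & ~visited;
      if (!next) break;
      mask_t it = next;
      while (it) {
        int t = __builtin_ctzll(it);
        it &= it - 1;
        D(s, t) = d;
      }
      visited |= next;
      frontier = next;
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericVector cpp_betweenness(IntegerMatrix edges, int n) {
  BitGraph g = graph_from_edges(edges, n, edges.nrow());
  std::vector<double> cb;
  brandes(g, cb);
  return NumericVector(cb.begin(), cb.end());
}

// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix edges, int n) {
  BitGraph g = graph_from_edges(edges, n, edges.nrow());
  NumericVector cc(n);
  mean_clustering(g, cc.begin());
  return cc;
}

// [[Rcpp::export]]
double cpp_local_efficiency(IntegerMatrix edges, int n) {
  BitGraph g = graph_from_edges(edges, n, edges.nrow());
  return local_efficiency(g);
}

// Metrics for each prefix size in kvec of a ranked edge list. Global matrix
// columns: Lp, Eglob, Eloc, Cp, unreachable_frac; nodal matrices are
// n x length(kvec).
// [[Rcpp::export]]
List cpp_grid_metrics(IntegerMatrix edges, int n, IntegerVector kvec,
                      bool want_nodal, bool want_betweenness,
                      bool want_local_eff) {
  int nd = kvec.size();
  NumericMatrix glob(nd, 5);
  colnames(glob) = CharacterVector::create("Lp", "Eglob", "Eloc", "Cp",
                                           "unreachable_frac");
  NumericMatrix neff_m(want_nodal ? n : 0, want_nodal ? nd : 0);
  IntegerMatrix deg_m(want_nodal ? n : 0, want_nodal ? nd : 0);
  NumericMatrix btw_m(want_betweenness ? n : 0, want_betweenness ? nd : 0);

  std::vector<double> neff(n), cb;
  for (int di = 0; di < nd; ++di) {
    int k = kvec[di];
    if (k < 0 || k > edges.nrow()) stop("edge count out of range");
    BitGraph g = graph_from_edges(edges, n, k);
    double lp, eglob, unreach;
    path_stats(g, lp, eglob, unreach, neff.data());
    glob(di, 0) = lp;
    glob(di, 1) = eglob;
    glob(di, 2) = want_local_eff ? local_efficiency(g) : NA_REAL;
    glob(di, 3) = mean_clustering(g, nullptr);
    glob(di, 4) = unreach;
    if (want_nodal) {
      for (int v = 0; v < n; ++v) {
        neff_m(v, di) = neff[v];
        deg_m(v, di) = popcnt(g.adj[v]);
      }
    }
    if (want_betweenness) {
      brandes(g, cb);
      for (int v = 0; v < n; ++v) btw_m(v, di) = cb[v];
    }
  }
  return List::create(_["global"] = glob, _["nodal_efficiency"] = neff_m,
                      _["degree"] = deg_m, _["betweenness"] = btw_m);
}

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, int n, int n_attempts) {
  int K = edges.nrow();
  std::vector<std::pair<int, int>> ev(K);
  BitGraph g(n);
  for (int e = 0; e < K; ++e) {
    ev[e] = std::make_pair(std::min(edges(e, 0), edges(e, 1)),
                           std::max(edges(e, 0), edges(e, 1)));
    g.add(ev[e].first, ev[e].second);
  }
  int acc = rewire_edges(ev, g, n_attempts);
  IntegerMatrix out(K, 2);
  for (int e = 0; e < K; ++e) {
    out(e, 0) = ev[e].first;
    out(e, 1) = ev[e].second;
  }
  return List::create(_["edges"] = out, _["accepted"] = acc);
}

// Mean Cp and Lp over n_null degree-preserving rewired versions of the
// graph; nulls with undefined Lp are excluded and counted.
// [[Rcpp::export]]
List cpp_null_cp_lp(IntegerMatrix edges, int n, int n_null, double swap_mult) {
  int K = edges.nrow();
  std::vector<std::pair<int, int>> base(K);
  for (int e = 0; e < K; ++e)
    base[e] = std::make_pair(std::min(edges(e, 0), edges(e, 1)),
                             std::max(edges(e, 0), edges(e, 1)));
  int n_attempts = (int)(swap_mult * K);
  double cp_sum = 0.0, lp_sum = 0.0;
  int used = 0, undef = 0;
  for (int r = 0; r < n_null; ++r) {
    std::vector<std::pair<int, int>> ev = base;
    BitGraph g(n);
    for (auto &e : ev) g.add(e.first, e.second);
    rewire_edges(ev, g, n_attempts);
    double lp, eglob, unreach;
    path_stats(g, lp, eglob, unreach, nullptr);
    if (ISNA(lp)) {
      ++undef;
      continue;
    }
    cp_sum += mean_clustering(g, nullptr);
    lp_sum += lp;
    ++used;
  }
  return List::create(_["mean_cp"] = used > 0 ? cp_sum / used : NA_REAL,
                      _["mean_lp"] = used > 0 ? lp_sum / used : NA_REAL,
                      _["n_used"] = used, _["n_undefined"] = undef);
}
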