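// Shortest-path kernels for the sociometrics: Brandes' betweenness
// accumulation and per-node BFS eccentricity over unweighted graphs.
// Nodes are 0-based indices; edges arrive as parallel from/to vectors.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static std::vector<std::vector<int>> build_adj(int n, const IntegerVector& from,
                                               const IntegerVector& to) {
  std::vector<std::vector<int>> adj(n);
  for (R_xlen_t k = 0; k < from.size(); ++k) {
    adj[from[k]].push_back(to[k]);
    adj[to[k]].push_back(from[k]);
  }
  return adj;
}

// Raw (unnormalised) betweenness for an undirected unweighted graph,
// with fractional counting over tied shortest paths.
// [[Rcpp::export]]
NumericVector cpp_betweenness_raw(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int>> adj = build_adj(n, from, to);
  NumericVector cb(n);
  std::vector<int> dist(n), queue(n), order(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> preds(n);
  for (int s = 0; s < n; ++s) {
    if (adj[s].empty()) continue;
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) preds[i].clear();
    int head = 0, tail = 0, cnt = 0;
    dist[s] = 0; sigma[s] = 1.0; queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      order[cnt++] = v;
      for (int u : adj[v]) {
        if (dist[u] < 0) { dist[u] = dist[v] + 1; queue[tail++] = u; }
        if (dist[u] == dist[v] + 1) {
          sigma[u] += sigma[v];
          preds[u].push_back(v);
        }
      }
    }
    for (int i = cnt - 1; i >= 0; --i) {
      int v = order[i];
      for (int p : preds[v])
        delta[p] += sigma[p] / sigma[v] * (1.0 + delta[v]);
      if (v != s) cb[v] += delta[v];
    }
  }
  for (int i = 0; i < n; ++i) cb[i] /= 2.0;  // each pair visited from both ends
  return cb;
}

// Max hop distance from each node to any node reachable from it
// (0 for isolated nodes).
// [[Rcpp::export]]
IntegerVector cpp_eccentricity(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int>> adj = build_adj(n, from, to);
  IntegerVector ecc(n);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0, far = 0;
    dist[s] = 0; queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      if (dist[v] > far) far = dist[v];
      for (int u : adj[v])
        if (dist[u] < 0) { dist[u] = dist[v] + 1; queue[tail++] = u; }
    }
    ecc[s] = far;
  }
  return ecc;
}

// Connected-component ids (1-based, in order of first appearance).
// [[Rcpp::export]]
IntegerVector cpp_components(int n, IntegerVector from, IntegerVector to) {
  std::vector<std::vector<int>> adj = build_adj(n, from, to);
  IntegerVector comp(n, NA_INTEGER);
  std::vector<int> queue(n);
  int cid = 0;
  for (int s = 0; s < n; ++s) {
    if (comp[s] != NA_INTEGER) continue;
    ++cid;
    int head = 0, tail = 0;
    comp[s] = cid; queue[tail++] = s;
    while (head < tail) {
      int v = queue[head++];
      for (int u : adj[v])
        if (comp[u] == NA_INTEGER) { comp[u] = cid; queue[tail++] = u; }
    }
  }
  return comp;
}
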