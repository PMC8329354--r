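#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Adjacency matrices are symmetric 0/1 integer matrices with zero diagonal;
// validation happens on the R side.

static std::vector<std::vector<int>> adj_list(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (adj(i, j) != 0) nb[i].push_back(j);
  return nb;
}

// All-pairs BFS distances; -1 marks an unreachable pair.
// [[Rcpp::export(name = ".cpp_distances")]]
IntegerMatrix cpp_distances(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  IntegerMatrix d(n, n);
  std::fill(d.begin(), d.end(), -1);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nb[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    for (int j = 0; j < n; ++j) d(s, j) = dist[j];
  }
  return d;
}

// Per-node clustering coefficient: 2*T_i / (k_i (k_i - 1)), 0 when k_i < 2.
// [[Rcpp::export(name = ".cpp_clustering")]]
NumericVector cpp_clustering(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  NumericVector c(n);
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) { c[i] = 0.0; continue; }
    int tri = 0;
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb[i][a], nb[i][b]) != 0) ++tri;
    c[i] = 2.0 * tri / ((double) k * (k - 1));
  }
  return c;
}

// Per-node local efficiency: global efficiency of the subgraph induced by
// the node's neighbors (the node itself excluded); 0 when < 2 neighbors.
// [[Rcpp::export(name = ".cpp_local_efficiency")]]
NumericVector cpp_local_efficiency(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  NumericVector eloc(n);
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) { eloc[i] = 0.0; continue; }
    // BFS inside the induced subgraph on nb[i]
    std::vector<int> idx(n, -1);
    for (int a = 0; a < k; ++a) idx[nb[i][a]] = a;
    double sum_inv = 0.0;
    std::vector<int> dist(k);
    for (int a = 0; a < k; ++a) {
      std::fill(dist.begin(), dist.end(), -1);
      dist[a] = 0;
      std::queue<int> q;
      q.push(a);
      while (!q.empty()) {
        int v = q.front(); q.pop();
        for (int w : nb[nb[i][v]]) {
          int wi = idx[w];
          if (wi >= 0 && dist[wi] < 0) { dist[wi] = dist[v] + 1; q.push(wi); }
        }
      }
      for (int b = 0; b < k; ++b)
        if (b != a && dist[b] > 0) sum_inv += 1.0 / dist[b];
    }
    eloc[i] = sum_inv / ((double) k * (k - 1));
  }
  return eloc;
}

// Brandes betweenness for unweighted undirected graphs (raw values:
// sum over unordered pairs s<t of sigma_st(v)/sigma_st).
// [[Rcpp::export(name = ".cpp_betweenness")]]
NumericVector cpp_betweenness(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  NumericVector bc(n);
  std::vector<int> dist(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<int> stack;
  stack.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    stack.clear();
    dist[s] = 0; sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      stack.push_back(v);
      for (int w : nb[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    for (int i = (int) stack.size() - 1; i >= 0; --i) {
      int w = stack[i];
      for (int v : pred[w])
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0; // each unordered pair counted twice
  return bc;
}

// Degree-preserving double-edge swaps (Maslov-Sneppen). Performs `attempts`
// proposals; swaps creating self-loops or multi-edges are rejected. Uses R's
// RNG, so results are reproducible under set.seed(). Returns the rewired
// adjacency and the number of accepted swaps.
// [[Rcpp::export(name = ".cpp_rewire")]]
List cpp_rewire(const IntegerMatrix& adj, int attempts) {
  int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<std::pair<int,int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) edges.push_back(std::make_pair(i, j));
  int m = (int) edges.size();
  int accepted = 0;
  if (m >= 2) {
    for (int t = 0; t < attempts; ++t) {
      int e1 = (int) (unif_rand() * m);
      int e2 = (int) (unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int u = edges[e1].first, v = edges[e1].second;
      int x = edges[e2].first, y = edges[e2].second;
      if (unif_rand() < 0.5) std::swap(x, y); // random orientation
      // propose (u,x) and (v,y)
      if (u == x || v == y) continue;          // self-loop
      if (a(u, x) != 0 || a(v, y) != 0) continue; // multi-edge
      a(u, v) = a(v, u) = 0;
      a(x, y) = a(y, x) = 0;
      a(u, x) = a(x, u) = 1;
      a(v, y) = a(y, v) = 1;
      edges[e1] = std::make_pair(std::min(u, x), std::max(u, x));
      edges[e2] = std::make_pair(std::min(v, y), std::max(v, y));
      ++accepted;
    }
  }
  return List::create(_["adjacency"] = a, _["n_swaps"] = accepted);
}

static double mean_clustering(const IntegerMatrix& a) {
  NumericVector c = cpp_clustering(a);
  return mean(c);
}

// Per-node path-length and efficiency statistics in one BFS sweep.
// L follows the reachable-pairs convention (nodes reaching no one are
// excluded from the network mean; NaN nodal value).
// [[Rcpp::export(name = ".cpp_path_stats")]]
List cpp_path_stats(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  NumericVector L_nodal(n), E_nodal(n);
  double L_sum = 0.0; int L_count = 0;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nb[v])
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    double dsum = 0.0, inv = 0.0; int reach = 0;
    for (int j = 0; j < n; ++j) {
      if (j == s) continue;
      if (dist[j] > 0) { dsum += dist[j]; inv += 1.0 / dist[j]; ++reach; }
    }
    E_nodal[s] = (n > 1) ? inv / (n - 1) : 0.0;
    if (reach > 0) {
      L_nodal[s] = dsum / reach;
      L_sum += L_nodal[s];
      ++L_count;
    } else {
      L_nodal[s] = NA_REAL;
    }
  }
  double L = (L_count > 0) ? L_sum / L_count : NA_REAL;
  double E_global = mean(E_nodal);
  return List::create(_["L"] = L, _["L_nodal"] = L_nodal,
                      _["E_global"] = E_global,
                      _["E_nodal"] = E_nodal);
}

static double path_length_only(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int>> nb = adj_list(adj);
  double L_sum = 0.0; int L_count = 0;
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : nb[v])
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
    double dsum = 0.0; int reach = 0;
    for (int j = 0; j < n; ++j)
      if (j != s && dist[j] > 0) { dsum += dist[j]; ++reach; }
    if (reach > 0) { L_sum += dsum / reach; ++L_count; }
  }
  return (L_count > 0) ? L_sum / L_count : NA_REAL;
}

// Bulk random-reference statistics: n_random Maslov-Sneppen rewirings of
// the input, returning each reference's mean clustering and characteristic
// path length plus the accepted-swap counts. Uses R's RNG.
// [[Rcpp::export(name = ".cpp_ref_stats")]]
List cpp_ref_stats(const IntegerMatrix& adj, int n_random, int attempts) {
  NumericVector C(n_random), L(n_random);
  IntegerVector swaps(n_random);
  for (int i = 0; i < n_random; ++i) {
    List rw = cpp_rewire(adj, attempts);
    IntegerMatrix a = rw["adjacency"];
    swaps[i] = as<int>(rw["n_swaps"]);
    C[i] = mean_clustering(a);
    L[i] = path_length_only(a);
  }
  return List::create(_["C_rand"] = C, _["L_rand"] = L,
                      _["n_swaps"] = swaps);
}
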