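#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Build adjacency lists from a symmetric 0/1 matrix (column-major scan).
static std::vector<std::vector<int> > adj_list(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  const int* p = adj.begin();
  std::vector<std::vector<int> > nb(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (p[i + static_cast<size_t>(n) * j] != 0) nb[j].push_back(i);
  return nb;
}

static void bfs(const std::vector<std::vector<int> >& nb, int s,
                std::vector<int>& dist, std::vector<int>& queue) {
  std::fill(dist.begin(), dist.end(), -1);
  dist[s] = 0;
  int head = 0, tail = 0;
  queue[tail++] = s;
  while (head < tail) {
    const int u = queue[head++];
    const int du = dist[u];
    for (size_t k = 0; k < nb[u].size(); ++k) {
      const int v = nb[u][k];
      if (dist[v] < 0) {
        dist[v] = du + 1;
        queue[tail++] = v;
      }
    }
  }
}

// All-pairs unweighted shortest-path distances; unreachable pairs = +Inf.
// [[Rcpp::export(name = ".apsp_bfs")]]
NumericMatrix apsp_bfs(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  std::vector<std::vector<int> > nb = adj_list(adj);
  NumericMatrix D(n, n);
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist, queue);
    for (int v = 0; v < n; ++v)
      D(s, v) = dist[v] < 0 ? R_PosInf : dist[v];
  }
  return D;
}

static double global_eff_lists(const std::vector<std::vector<int> >& nb) {
  const int n = static_cast<int>(nb.size());
  if (n < 2) return 0.0;
  std::vector<int> dist(n), queue(n);
  double acc = 0.0;
  for (int s = 0; s < n; ++s) {
    bfs(nb, s, dist, queue);
    for (int v = 0; v < n; ++v)
      if (v != s && dist[v] > 0) acc += 1.0 / dist[v];
  }
  return acc / (static_cast<double>(n) * (n - 1));
}

// [[Rcpp::export(name = ".global_efficiency_cpp")]]
double global_efficiency_cpp(const IntegerMatrix& adj) {
  return global_eff_lists(adj_list(adj));
}

// Mean over nodes of the global efficiency of each node's
// neighbour-induced subgraph; nodes of degree < 2 contribute 0.
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
double local_efficiency_cpp(const IntegerMatrix& adj) {
  const int n = adj.nrow();
  if (n < 2) return 0.0;
  const int* p = adj.begin();
  std::vector<std::vector<int> > nb = adj_list(adj);
  std::vector<int> pos(n, -1);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    const std::vector<int>& ni = nb[i];
    const int k = static_cast<int>(ni.size());
    if (k < 2) continue;
    for (int a = 0; a < k; ++a) pos[ni[a]] = a;
    std::vector<std::vector<int> > sub(k);
    for (int a = 0; a < k; ++a) {
      const std::vector<int>& na = nb[ni[a]];
      for (size_t t = 0; t < na.size(); ++t)
        if (pos[na[t]] >= 0) sub[a].push_back(pos[na[t]]);
    }
    (void)p;
    acc += global_eff_lists(sub);
    for (int a = 0; a < k; ++a) pos[ni[a]] = -1;
  }
  return acc / n;
}

// Degree-preserving randomization by double edge swaps (Maslov-Sneppen).
// Attempts swaps until n_swaps have been ACCEPTED or max_tries proposals
// have been made; proposals creating self-loops or multi-edges are
// rejected. Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export(name = ".double_edge_swap_cpp")]]
IntegerMatrix double_edge_swap_cpp(const IntegerMatrix& adj, int n_swaps,
                                   int max_tries) {
  const int n = adj.nrow();
  IntegerMatrix A = clone(adj);
  int* pa = A.begin();
  const size_t nn = static_cast<size_t>(n);
  std::vector<int> ei, ej;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < j; ++i)
      if (pa[i + nn * j] != 0) { ei.push_back(i); ej.push_back(j); }
  const int m = static_cast<int>(ei.size());
  if (m < 2) return A;
  int accepted = 0, tries = 0;
  while (accepted < n_swaps && tries < max_tries) {
    ++tries;
    const int pidx = static_cast<int>(unif_rand() * m);
    const int qidx = static_cast<int>(unif_rand() * m);
    if (pidx == qidx) continue;
    int a = ei[pidx], b = ej[pidx], c = ei[qidx], d = ej[qidx];
    // random orientation of the second edge
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed rewiring: (a,b),(c,d) -> (a,d),(c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (pa[a + nn * d] != 0 || pa[c + nn * b] != 0) continue;
    pa[a + nn * b] = pa[b + nn * a] = 0;
    pa[c + nn * d] = pa[d + nn * c] = 0;
    pa[a + nn * d] = pa[d + nn * a] = 1;
    pa[c + nn * b] = pa[b + nn * c] = 1;
    ei[pidx] = a; ej[pidx] = d;
    ei[qidx] = c; ej[qidx] = b;
    ++accepted;
  }
  return A;
}
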