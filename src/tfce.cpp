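#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// TFCE for a non-negative height map on an undirected graph.
// TFCE(v) = sum over h = dh, 2dh, ... <= max(values) of
//           size(component of v at height h)^E * h^H * dh,
// where the component at height h is taken in the subgraph of vertices with
// value >= h. Thresholds are processed in descending order with an
// incremental union-find: vertices activate as h drops below their height,
// so components only ever merge.
// [[Rcpp::export]]
NumericVector tfce_nonneg_cpp(NumericVector values, IntegerMatrix edges,
                              double E, double H, double dh) {
  const int n = values.size();
  NumericVector out(n);
  if (dh <= 0) stop("dh must be > 0");
  double vmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(values[i])) stop("non-finite value in stat map");
    if (values[i] > vmax) vmax = values[i];
  }
  if (vmax < dh) return out;
  const int K = (int)std::floor(vmax / dh + 1e-9);

  // adjacency
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n) stop("edge index out of range");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }

  // vertices sorted by descending height
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  std::vector<int> activated;
  activated.reserve(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  std::size_t next = 0;
  for (int k = K; k >= 1; --k) {
    const double h = k * dh;
    while (next < order.size() && values[order[next]] >= h - 1e-12) {
      const int v = order[next++];
      active[v] = 1;
      csize[v] = 1;
      activated.push_back(v);
      for (int w : adj[v]) {
        if (!active[w]) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    const double hterm = std::pow(h, H) * dh;
    for (int v : activated) {
      out[v] += std::pow((double)csize[uf_find(parent, v)], E) * hterm;
    }
  }
  return out;
}
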