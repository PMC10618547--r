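// Radius-graph construction and radial-burning selection on a cell grid.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <utility>
#include <vector>

using namespace Rcpp;

namespace {
inline int64_t cell_key(int ix, int iy) {
  return (static_cast<int64_t>(ix) << 32) ^
         static_cast<int64_t>(static_cast<uint32_t>(iy));
}
}  // namespace

// Edge list (1-based, i < j, lexicographically sorted) of the euclidean
// threshold graph: d_ij <= r * (1 + tol_rel).
// [[Rcpp::export]]
IntegerMatrix radius_edges_cpp(NumericMatrix coords, double r,
                               double tol_rel) {
  int n = coords.nrow();
  double thr = r * (1.0 + tol_rel);
  double thr2 = thr * thr;
  double cell = std::max(thr, 1e-12);

  std::unordered_map<int64_t, std::vector<int>> cells;
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = static_cast<int>(std::floor(coords(i, 0) / cell));
    cy[i] = static_cast<int>(std::floor(coords(i, 1) / cell));
    cells[cell_key(cx[i], cy[i])].push_back(i);
  }

  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i) {
    double xi = coords(i, 0), yi = coords(i, 1);
    for (int ix = cx[i] - 1; ix <= cx[i] + 1; ++ix) {
      for (int iy = cy[i] - 1; iy <= cy[i] + 1; ++iy) {
        auto it = cells.find(cell_key(ix, iy));
        if (it == cells.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi;
          if (dx * dx + dy * dy <= thr2) edges.emplace_back(i, j);
        }
      }
    }
  }
  std::sort(edges.begin(), edges.end());

  IntegerMatrix out(edges.size(), 2);
  for (size_t k = 0; k < edges.size(); ++k) {
    out(k, 0) = edges[k].first + 1;
    out(k, 1) = edges[k].second + 1;
  }
  return out;
}

// Admission order of radial burning: starting from `start`, repeatedly admit
// the unselected vertex with the smallest priority among those adjacent to
// the selected set.  `priority` is a precomputed total order (1..n, smaller
// admitted first: by radius, then polar angle, then index).  Returns the
// admitted vertices (1-based) in order; shorter than target_n if the
// component of `start` is exhausted first.
// [[Rcpp::export]]
IntegerVector burn_order_cpp(IntegerVector priority, IntegerMatrix edges,
                             int start, int target_n) {
  int n = priority.size();
  std::vector<std::vector<int>> adj(n);
  for (int k = 0; k < edges.nrow(); ++k) {
    int a = edges(k, 0) - 1, b = edges(k, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  std::vector<bool> selected(n, false), queued(n, false);
  typedef std::pair<int, int> pii;  // (priority, vertex)
  std::priority_queue<pii, std::vector<pii>, std::greater<pii>> heap;

  std::vector<int> order;
  order.reserve(target_n);
  int s = start - 1;
  selected[s] = true;
  order.push_back(s + 1);
  for (int nb : adj[s]) {
    if (!queued[nb]) {
      queued[nb] = true;
      heap.push(pii(priority[nb], nb));
    }
  }
  while (static_cast<int>(order.size()) < target_n && !heap.empty()) {
    int v = heap.top().second;
    heap.pop();
    if (selected[v]) continue;
    selected[v] = true;
    order.push_back(v + 1);
    for (int nb : adj[v]) {
      if (!selected[nb] && !queued[nb]) {
        queued[nb] = true;
        heap.push(pii(priority[nb], nb));
      }
    }
  }
  return wrap(order);
}
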