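#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Exact solver for the (balanced or unbalanced) transportation problem on a
// sparse arc list, via successive shortest augmenting paths (SPFA label
// correcting on the residual network). Supplies/demands and arc costs are
// doubles; each augmentation saturates at least one residual arc or source
// node, so termination is finite. Deterministic: arcs are relaxed in input
// order, which fixes tie-breaks.

struct Edge {
  int to;
  double cap;
  double cost;
  int rev; // index of reverse edge in graph[to]
};

// [[Rcpp::export(name = ".mcf_transport")]]
NumericVector mcf_transport(NumericVector supply,
                            NumericVector demand,
                            IntegerVector arc_from,
                            IntegerVector arc_to,
                            NumericVector arc_cost) {
  const int n = supply.size(), m = demand.size(), na = arc_from.size();
  const int S = 0, T = n + m + 1, V = n + m + 2;
  std::vector<std::vector<Edge>> g(V);

  auto add_edge = [&](int u, int v, double cap, double cost) {
    g[u].push_back({v, cap, cost, (int)g[v].size()});
    g[v].push_back({u, 0.0, -cost, (int)g[u].size() - 1});
  };

  for (int i = 0; i < n; ++i) add_edge(S, 1 + i, supply[i], 0.0);
  // remember where each input arc lives so its flow can be read back
  std::vector<int> arc_pos(na);
  for (int k = 0; k < na; ++k) {
    int u = 1 + (arc_from[k] - 1);
    int v = 1 + n + (arc_to[k] - 1);
    arc_pos[k] = (int)g[u].size();
    add_edge(u, v, std::numeric_limits<double>::infinity(), arc_cost[k]);
  }
  for (int j = 0; j < m; ++j) add_edge(1 + n + j, T, demand[j], 0.0);

  const double INF = std::numeric_limits<double>::infinity();
  const double EPS = 1e-12;

  for (;;) {
    // SPFA shortest path S -> T in residual network
    std::vector<double> dist(V, INF);
    std::vector<int> pv(V, -1), pe(V, -1);
    std::vector<char> inq(V, 0);
    std::deque<int> q;
    dist[S] = 0.0;
    q.push_back(S);
    inq[S] = 1;
    while (!q.empty()) {
      int u = q.front();
      q.pop_front();
      inq[u] = 0;
      for (int e = 0; e < (int)g[u].size(); ++e) {
        const Edge &ed = g[u][e];
        if (ed.cap > EPS && dist[u] + ed.cost < dist[ed.to] - EPS) {
          dist[ed.to] = dist[u] + ed.cost;
          pv[ed.to] = u;
          pe[ed.to] = e;
          if (!inq[ed.to]) {
            q.push_back(ed.to);
            inq[ed.to] = 1;
          }
        }
      }
    }
    if (!(dist[T] < INF)) break; // no augmenting path: max flow reached

    double push = INF;
    for (int v = T; v != S; v = pv[v]) push = std::min(push, g[pv[v]][pe[v]].cap);
    if (!(push > EPS)) break;
    for (int v = T; v != S; v = pv[v]) {
      Edge &ed = g[pv[v]][pe[v]];
      ed.cap -= push;
      g[ed.to][ed.rev].cap += push;
    }
  }

  NumericVector flow(na);
  for (int k = 0; k < na; ++k) {
    int u = 1 + (arc_from[k] - 1);
    const Edge &ed = g[u][arc_pos[k]];
    flow[k] = g[ed.to][ed.rev].cap; // reverse capacity == flow pushed
  }
  return flow;
}
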