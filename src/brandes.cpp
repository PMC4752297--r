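#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

// Brandes' single-source accumulation for unweighted graphs, computing
// node and edge betweenness in one pass. Sums run over ordered (s, t)
// pairs; for an undirected graph the caller halves the result.
//
// edges: m x 2 integer matrix of 0-based vertex indices.
// [[Rcpp::export(name = ".brandes_betweenness")]]
List brandes_betweenness(int n, IntegerMatrix edges, bool directed) {
  int m = edges.nrow();

  // adjacency lists of (neighbour, edge id)
  std::vector<std::vector<std::pair<int, int> > > adj(n);
  for (int e = 0; e < m; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    if (u < 0 || u >= n || v < 0 || v >= n)
      stop("edge endpoint out of range");
    adj[u].push_back(std::make_pair(v, e));
    if (!directed) adj[v].push_back(std::make_pair(u, e));
  }

  NumericVector node_bc(n), edge_bc(m);

  std::vector<int> dist(n), stack_order;
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<std::pair<int, int> > > pred(n);
  stack_order.reserve(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    stack_order.clear();

    dist[s] = 0;
    sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front();
      q.pop();
      stack_order.push_back(v);
      for (size_t i = 0; i < adj[v].size(); ++i) {
        int w = adj[v][i].first, eid = adj[v][i].second;
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(std::make_pair(v, eid));
        }
      }
    }

    // dependency accumulation in reverse BFS order
    for (int i = (int)stack_order.size() - 1; i >= 0; --i) {
      int w = stack_order[i];
      for (size_t j = 0; j < pred[w].size(); ++j) {
        int v = pred[w][j].first, eid = pred[w][j].second;
        double c = sigma[v] / sigma[w] * (1.0 + delta[w]);
        edge_bc[eid] += c;
        delta[v] += c;
      }
      if (w != s) node_bc[w] += delta[w];
    }
  }

  return List::create(Named("node") = node_bc, Named("edge") = edge_bc);
}
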