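#include <Rcpp.h>
using namespace Rcpp;

// Sum of geodesic hop counts and number of reachable ordered pairs (u, v),
// u != v, over a directed unweighted graph. Edges are 0-based endpoint
// vectors; breadth-first search from every source.
// [[Rcpp::export]]
NumericVector cpp_geodesic_sums(int n, IntegerVector from, IntegerVector to) {
  int m = from.size();
  std::vector<int> head(n + 1, 0), adj(m);
  for (int e = 0; e < m; ++e) head[from[e] + 1]++;
  for (int i = 0; i < n; ++i) head[i + 1] += head[i];
  std::vector<int> pos(head.begin(), head.end() - 1);
  for (int e = 0; e < m; ++e) adj[pos[from[e]]++] = to[e];

  double total = 0.0, reach = 0.0;
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int qh = 0, qt = 0;
    dist[s] = 0;
    queue[qt++] = s;
    while (qh < qt) {
      int u = queue[qh++];
      for (int k = head[u]; k < head[u + 1]; ++k) {
        int v = adj[k];
        if (dist[v] < 0) {
          dist[v] = dist[u] + 1;
          queue[qt++] = v;
          total += dist[v];
          reach += 1.0;
        }
      }
    }
  }
  return NumericVector::create(total, reach);
}
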