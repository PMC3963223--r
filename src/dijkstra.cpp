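#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
#include <climits>
using namespace Rcpp;

// Deterministic single-source shortest paths on an undirected CSR graph with
// non-negative integer edge weights.
//
// The optimisation key is (total weight, hop count). Among all predecessors
// that realise a node's optimal key, the smallest node index wins, so the
// predecessor tree -- and every path extracted from it -- is invariant to
// edge order and heap internals. Hop counts strictly decrease along
// predecessor chains, which keeps the tree acyclic even across weight-0
// edges (score-1000 interactions), where a pure smallest-id rule could
// produce predecessor cycles.
//
// indptr: length n+1, 0-based offsets into nbr/wt (edges stored both ways).
// nbr:    0-based neighbour indices. wt: non-negative integer weights.
// src:    1-based source node.
// Returns dist (Inf when unreachable), pred (1-based, 0 = none) and hops.
// [[Rcpp::export(name = ".sp_sssp")]]
List sp_sssp(int n, IntegerVector indptr, IntegerVector nbr,
             IntegerVector wt, int src) {
  if (src < 1 || src > n) stop("source index out of range");
  std::vector<long long> dist(n, LLONG_MAX);
  std::vector<int> hop(n, INT_MAX), pred(n, -1);
  typedef std::tuple<long long, int, int> key; // dist, hops, node
  std::priority_queue<key, std::vector<key>, std::greater<key> > pq;
  dist[src - 1] = 0;
  hop[src - 1] = 0;
  pq.push(key(0, 0, src - 1));
  while (!pq.empty()) {
    long long d = std::get<0>(pq.top());
    int h = std::get<1>(pq.top());
    int u = std::get<2>(pq.top());
    pq.pop();
    if (d != dist[u] || h != hop[u]) continue; // stale entry
    for (int e = indptr[u]; e < indptr[u + 1]; ++e) {
      int v = nbr[e];
      long long nd = d + wt[e];
      int nh = h + 1;
      if (nd < dist[v] || (nd == dist[v] && nh < hop[v])) {
        dist[v] = nd;
        hop[v] = nh;
        pred[v] = u;
        pq.push(key(nd, nh, v));
      } else if (nd == dist[v] && nh == hop[v] && u < pred[v]) {
        pred[v] = u;
      }
    }
  }
  NumericVector dout(n);
  IntegerVector pout(n), hout(n);
  for (int i = 0; i < n; ++i) {
    dout[i] = (dist[i] == LLONG_MAX) ? R_PosInf : (double) dist[i];
    pout[i] = pred[i] + 1;
    hout[i] = (hop[i] == INT_MAX) ? NA_INTEGER : hop[i];
  }
  return List::create(_["dist"] = dout, _["pred"] = pout, _["hops"] = hout);
}
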