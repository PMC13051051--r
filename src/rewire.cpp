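#include <Rcpp.h>
#include <unordered_set>
#include <random>
using namespace Rcpp;

// Degree-preserving double-edge swaps on a simple undirected graph.
// Edges come in as a 2-column 1-based integer matrix; weights stay attached
// to their row, so they travel with the edge through the swap. A proposal
// {a,b},{c,d} -> {a,d},{c,b} is rejected when it would create a self-loop or
// duplicate an existing pair, which leaves the distinct-neighbour degree
// sequence exactly invariant. Returns the rewired edge matrix; attribute
// "swaps" reports the number of successful swaps.
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n_nodes,
                               int n_swaps, int seed, double max_try_factor) {
  const int m = edges.nrow();
  IntegerMatrix el = clone(edges);
  std::unordered_set<long long> pairs;
  pairs.reserve(m * 2);
  const long long N = n_nodes + 1LL;
  auto key = [N](int a, int b) {
    return a < b ? (long long)a * N + b : (long long)b * N + a;
  };
  for (int i = 0; i < m; ++i) pairs.insert(key(el(i, 0), el(i, 1)));

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick(0, m - 1);
  std::uniform_int_distribution<int> coin(0, 1);

  long long max_tries = (long long)(max_try_factor * n_swaps) + 100;
  int done = 0;
  for (long long t = 0; t < max_tries && done < n_swaps; ++t) {
    int i = pick(rng), j = pick(rng);
    if (i == j) continue;
    int a = el(i, 0), b = el(i, 1);
    int c = el(j, 0), d = el(j, 1);
    if (coin(rng)) std::swap(c, d);
    // proposed new edges: {a,d}, {c,b}
    if (a == d || c == b) continue;
    long long k1 = key(a, d), k2 = key(c, b);
    if (k1 == k2) continue;
    if (pairs.count(k1) || pairs.count(k2)) continue;
    pairs.erase(key(a, b));
    pairs.erase(key(c, d));
    pairs.insert(k1);
    pairs.insert(k2);
    el(i, 0) = a; el(i, 1) = d;
    el(j, 0) = c; el(j, 1) = b;
    ++done;
  }
  el.attr("swaps") = done;
  return el;
}
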