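#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression and union by size.
// Edges are supplied already sorted by descending weight (ties resolved by
// node-index order in R); ks gives the cumulative number of retained edges at
// each filtration grid point. Returns the connected-component count after the
// first ks[t] edges have been inserted, for each t.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerVector uf_component_counts(IntegerVector edge_i, IntegerVector edge_j,
                                  int n_nodes, IntegerVector ks) {
  const int n_edges = edge_i.size();
  if (edge_j.size() != n_edges)
    stop("edge index vectors differ in length");
  std::vector<int> parent(n_nodes), size(n_nodes, 1);
  for (int v = 0; v < n_nodes; ++v) parent[v] = v;

  IntegerVector out(ks.size());
  int components = n_nodes;
  int e = 0;
  for (int t = 0; t < ks.size(); ++t) {
    int k = ks[t];
    if (k < 0 || k > n_edges) stop("edge count out of range");
    if (k < e) stop("ks must be non-decreasing");
    for (; e < k; ++e) {
      int a = uf_find(parent, edge_i[e] - 1);
      int b = uf_find(parent, edge_j[e] - 1);
      if (a != b) {
        if (size[a] < size[b]) std::swap(a, b);
        parent[b] = a;
        size[a] += size[b];
        --components;
      }
    }
    out[t] = components;
  }
  return out;
}
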