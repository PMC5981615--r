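#include <Rcpp.h>
using namespace Rcpp;

// Average shortest path length over reachable ordered pairs of the graph
// induced by the non-masked vertices, by BFS from every surviving vertex.
// The graph arrives in CSR form: ptr (length n+1, 0-based offsets) and nbr
// (concatenated neighbor lists, 0-based). removed masks deleted vertices.
// Returns NaN when no pair is reachable. For undirected graphs the mean over
// ordered pairs equals the mean over unordered pairs.
// [[Rcpp::export]]
double aplMaskedCpp(const IntegerVector& ptr, const IntegerVector& nbr,
                    const LogicalVector& removed) {
  const int n = ptr.size() - 1;
  const int* p = INTEGER(ptr);
  const int* nb = INTEGER(nbr);
  const int* rm = LOGICAL(removed);
  std::vector<int> dist(n), queue(n);
  double sum = 0.0;
  long long cnt = 0;
  for (int s = 0; s < n; ++s) {
    if (rm[s]) continue;
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    dist[s] = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      int d1 = dist[u] + 1;
      for (int k = p[u]; k < p[u + 1]; ++k) {
        int w = nb[k];
        if (rm[w] || dist[w] >= 0) continue;
        dist[w] = d1;
        sum += d1;
        ++cnt;
        queue[tail++] = w;
      }
    }
  }
  if (cnt == 0) return R_NaN;
  return sum / static_cast<double>(cnt);
}
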