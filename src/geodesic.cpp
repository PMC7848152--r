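#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dijkstra shortest path on the 8-connected pixel graph.
//
// Step cost between adjacent pixels is step_length_mm / w, where
// step_length_mm is pixel_size (axial) or sqrt(2)*pixel_size (diagonal)
// and w is the porosity weight: the destination pixel's porosity
// (weight_mode 0), the mean of the two endpoint porosities
// (weight_mode 1), or 1 for the unweighted tissue-depth map
// (weighted = false). Pixels with porosity below `threshold` are
// removed from the graph entirely. Returns the cost matrix with
// +Inf at unreachable (or blocked) pixels.
// [[Rcpp::export]]
NumericMatrix grid_dijkstra_cpp(NumericMatrix porosity,
                                IntegerVector src_rows,
                                IntegerVector src_cols,
                                double pixel_size,
                                double threshold,
                                bool weighted,
                                int weight_mode) {
  const int nr = porosity.nrow(), nc = porosity.ncol();
  const int n = nr * nc;
  NumericMatrix cost(nr, nc);
  std::fill(cost.begin(), cost.end(), R_PosInf);

  std::vector<bool> open(n);
  for (int k = 0; k < n; ++k) {
    double p = porosity[k];
    open[k] = R_finite(p) && p >= threshold;
  }

  typedef std::pair<double, int> node; // (dist, linear index, column-major)
  std::priority_queue<node, std::vector<node>, std::greater<node> > pq;

  for (int s = 0; s < src_rows.size(); ++s) {
    int idx = (src_cols[s] - 1) * nr + (src_rows[s] - 1);
    if (!open[idx]) stop("inlet lies on a blocked pixel");
    cost[idx] = 0.0;
    pq.push(node(0.0, idx));
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    node top = pq.top();
    pq.pop();
    double d = top.first;
    int idx = top.second;
    if (d > cost[idx]) continue; // stale entry
    int i = idx % nr, j = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int ii = i + dr[k], jj = j + dc[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int jdx = jj * nr + ii;
      if (!open[jdx]) continue;
      double len = (dr[k] != 0 && dc[k] != 0) ? sqrt2 * pixel_size : pixel_size;
      double w = 1.0;
      if (weighted) {
        w = (weight_mode == 1) ? 0.5 * (porosity[idx] + porosity[jdx])
                               : porosity[jdx];
        if (w < threshold) continue; // mean mode can fall below the cutoff
      }
      double nd = d + len / w;
      if (nd < cost[jdx]) {
        cost[jdx] = nd;
        pq.push(node(nd, jdx));
      }
    }
  }
  return cost;
}
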