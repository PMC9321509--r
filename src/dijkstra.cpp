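#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 8-connected cell graph of a resistance
// raster.  Step cost between neighbouring cells i,j is (R_i + R_j)/2 * d,
// d = cellsize for orthogonal moves, cellsize*sqrt(2) for diagonal moves.
// NA resistance cells are impassable.  Pop order is lexicographic by
// (cost, row, col) so results (including predecessors) are deterministic.

struct QNode {
  double cost;
  int row, col;
};
struct QNodeCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    if (a.row != b.row) return a.row > b.row;
    return a.col > b.col;
  }
};

// [[Rcpp::export]]
List cpp_cost_distance(NumericMatrix resist, IntegerMatrix sources,
                       double cellsize) {
  const int nr = resist.nrow(), nc = resist.ncol();
  const double sqrt2 = std::sqrt(2.0);
  NumericMatrix cost(nr, nc);
  IntegerMatrix alloc(nr, nc);
  IntegerMatrix pred(nr, nc);  // 1-based linear index of predecessor, 0 = none
  std::fill(cost.begin(), cost.end(), R_PosInf);
  std::fill(alloc.begin(), alloc.end(), NA_INTEGER);
  std::fill(pred.begin(), pred.end(), 0);

  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (sources(r, c) > 0 && !NumericMatrix::is_na(resist(r, c))) {
        cost(r, c) = 0.0;
        alloc(r, c) = sources(r, c);
        pq.push({0.0, r, c});
      }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    if (nd.cost > cost(nd.row, nd.col)) continue;  // stale entry
    const double rhere = resist(nd.row, nd.col);
    for (int m = 0; m < 8; ++m) {
      const int r2 = nd.row + dr[m], c2 = nd.col + dc[m];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (NumericMatrix::is_na(resist(r2, c2))) continue;
      const double d = (dr[m] != 0 && dc[m] != 0) ? cellsize * sqrt2 : cellsize;
      const double step = 0.5 * (rhere + resist(r2, c2)) * d;
      const double cand = nd.cost + step;
      if (cand < cost(r2, c2)) {
        cost(r2, c2) = cand;
        alloc(r2, c2) = alloc(nd.row, nd.col);
        pred(r2, c2) = nd.row + nr * nd.col + 1;  // column-major, 1-based
        pq.push({cand, r2, c2});
      }
    }
  }

  for (int i = 0; i < nr * nc; ++i)
    if (!R_finite(cost[i])) cost[i] = NA_REAL;

  return List::create(_["cost"] = cost, _["allocation"] = alloc,
                      _["pred"] = pred);
}
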