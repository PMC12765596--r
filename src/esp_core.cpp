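#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Fixed neighbour scan order used everywhere a tie has to break
// deterministically: E, N, W, S, NE, NW, SW, SE.
static const int DR[8] = {0, -1, 0, 1, -1, -1, 1, 1};
static const int DC[8] = {1, 0, -1, 0, 1, -1, -1, 1};

static inline bool in_grid(int r, int c, int nr, int nc) {
  return r >= 0 && r < nr && c >= 0 && c < nc;
}

// Connected-component labelling of a logical mask. Labels are consecutive
// positive integers assigned in row-major first-cell order (row 0 first),
// so the result is deterministic. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix fg, int connectivity) {
  int nr = fg.nrow(), nc = fg.ncol();
  int nnb = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (fg(r, c) != TRUE || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int cr = cur / nc, cc = cur % nc;
        for (int k = 0; k < nnb; ++k) {
          int r2 = cr + DR[k], c2 = cc + DC[k];
          if (!in_grid(r2, c2, nr, nc)) continue;
          if (fg(r2, c2) == TRUE && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return lab;
}

// One-step binary erosion with the box (se = 8) or diamond (se = 4)
// structuring element; cells beyond the raster edge count as background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode(LogicalMatrix fg, int se) {
  int nr = fg.nrow(), nc = fg.ncol();
  int nnb = (se == 8) ? 8 : 4;
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (fg(r, c) != TRUE) { out(r, c) = FALSE; continue; }
      bool keep = true;
      for (int k = 0; k < nnb && keep; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (!in_grid(r2, c2, nr, nc) || fg(r2, c2) != TRUE) keep = false;
      }
      out(r, c) = keep;
    }
  }
  return out;
}

// One-step binary dilation (box or diamond element).
// [[Rcpp::export]]
LogicalMatrix cpp_dilate(LogicalMatrix fg, int se) {
  int nr = fg.nrow(), nc = fg.ncol();
  int nnb = (se == 8) ? 8 : 4;
  LogicalMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      bool on = (fg(r, c) == TRUE);
      for (int k = 0; k < nnb && !on; ++k) {
        int r2 = r + DR[k], c2 = c + DC[k];
        if (in_grid(r2, c2, nr, nc) && fg(r2, c2) == TRUE) on = true;
      }
      out(r, c) = on;
    }
  }
  return out;
}

// Geodesic label dilation: unlabelled cells of `allowed` take the label of
// the first labelled neighbour in scan order, for `steps` sweeps. Used to
// attach boundary-zone cells to their core component. Deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_dilate_labels(IntegerMatrix lab, LogicalMatrix allowed,
                                int steps, int se) {
  int nr = lab.nrow(), nc = lab.ncol();
  int nnb = (se == 8) ? 8 : 4;
  IntegerMatrix cur = clone(lab);
  for (int s = 0; s < steps; ++s) {
    IntegerMatrix nxt = clone(cur);
    bool changed = false;
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (cur(r, c) != 0 || allowed(r, c) != TRUE) continue;
        for (int k = 0; k < nnb; ++k) {
          int r2 = r + DR[k], c2 = c + DC[k];
          if (in_grid(r2, c2, nr, nc) && cur(r2, c2) != 0) {
            nxt(r, c) = cur(r2, c2);
            changed = true;
            break;
          }
        }
      }
    }
    cur = nxt;
    if (!changed) break;
  }
  return cur;
}

struct HeapItem {
  double cost;
  int idx;
};
struct HeapCmp {
  bool operator()(const HeapItem& a, const HeapItem& b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.idx > b.idx;  // equal costs pop in cell-index order
  }
};

// Multi-source Dijkstra over the 8-neighbour lattice. Step cost is
// cell_km * (R(a) + R(b)) / 2, times sqrt(2) for diagonal moves. NA
// resistance cells are impassable. Returns the accumulated-cost grid and a
// backlink grid (scan-order code 1..8 of the predecessor direction, 0 for
// seeds and unreached cells). Ties break by pop order (cost, then cell
// index) and by the fixed neighbour scan order, so results are
// run-to-run deterministic.
// [[Rcpp::export]]
List cpp_cost_distance(NumericMatrix res, LogicalMatrix seed, double cell_km) {
  int nr = res.nrow(), nc = res.ncol(), n = nr * nc;
  NumericMatrix cost(nr, nc);
  IntegerMatrix back(nr, nc);
  std::fill(cost.begin(), cost.end(), R_PosInf);
  std::priority_queue<HeapItem, std::vector<HeapItem>, HeapCmp> pq;
  const double SQRT2 = 1.4142135623730951;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (seed(r, c) == TRUE && !NumericMatrix::is_na(res(r, c))) {
        cost(r, c) = 0.0;
        pq.push({0.0, r * nc + c});
      }
  std::vector<char> done(n, 0);
  while (!pq.empty()) {
    HeapItem top = pq.top(); pq.pop();
    int idx = top.idx;
    if (done[idx]) continue;
    done[idx] = 1;
    int r = idx / nc, c = idx % nc;
    double rc = res(r, c), cc0 = cost(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR[k], c2 = c + DC[k];
      if (!in_grid(r2, c2, nr, nc)) continue;
      double rn = res(r2, c2);
      if (NumericMatrix::is_na(rn)) continue;
      double w = cell_km * 0.5 * (rc + rn);
      if (k >= 4) w *= SQRT2;
      double nd = cc0 + w;
      if (nd < cost(r2, c2)) {
        cost(r2, c2) = nd;
        // backlink points from (r2,c2) to its predecessor (r,c): opposite
        // direction codes pair as E<->W (1,3), N<->S (2,4), NE<->SW (5,7),
        // NW<->SE (6,8)
        static const int OPP[8] = {3, 4, 1, 2, 7, 8, 5, 6};
        back(r2, c2) = OPP[k];
        pq.push({nd, r2 * nc + c2});
      }
    }
  }
  return List::create(_["cost"] = cost, _["backlink"] = back);
}

// D8 flow accumulation by Kahn's topological order. `receiver` holds scan-
// order direction codes 1..8 (cell drains to that neighbour) or 0 for pits.
// Counts are self-inclusive (minimum 1). Errors on a cycle.
// [[Rcpp::export]]
NumericMatrix cpp_flow_accumulation(IntegerMatrix receiver) {
  int nr = receiver.nrow(), nc = receiver.ncol(), n = nr * nc;
  NumericMatrix acc(nr, nc);
  std::fill(acc.begin(), acc.end(), 1.0);
  std::vector<int> indeg(n, 0);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int d = receiver(r, c);
      if (d > 0) {
        int r2 = r + DR[d - 1], c2 = c + DC[d - 1];
        if (in_grid(r2, c2, nr, nc)) indeg[r2 * nc + c2]++;
      }
    }
  std::vector<int> queue;
  queue.reserve(n);
  for (int i = 0; i < n; ++i)
    if (indeg[i] == 0) queue.push_back(i);
  size_t head = 0;
  int processed = 0;
  while (head < queue.size()) {
    int idx = queue[head++];
    ++processed;
    int r = idx / nc, c = idx % nc;
    int d = receiver(r, c);
    if (d > 0) {
      int r2 = r + DR[d - 1], c2 = c + DC[d - 1];
      if (in_grid(r2, c2, nr, nc)) {
        acc(r2, c2) += acc(r, c);
        if (--indeg[r2 * nc + c2] == 0) queue.push_back(r2 * nc + c2);
      }
    }
  }
  if (processed != n)
    stop("cycle detected in flow-direction grid (tie-break violation)");
  return acc;
}
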