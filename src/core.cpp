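#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// 8- or 4-connected component labelling of a logical image by breadth-first
// search. Labels are 1..k in scan order of the first pixel encountered;
// background is 0.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[4] = {-1, 1, 0, 0};
  const int dx4[4] = {0, 0, -1, 1};
  const int n_nb = (connectivity == 4) ? 4 : 8;
  const int* dy = (connectivity == 4) ? dy4 : dy8;
  const int* dx = (connectivity == 4) ? dx4 : dx8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * H);
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % H, pj = p / H;
        for (int k = 0; k < n_nb; ++k) {
          int ni = pi + dy[k], nj = pj + dx[k];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * H);
          }
        }
      }
    }
  }
  return lab;
}

// Geodesic quasi-euclidean distance: shortest path constrained to `region`,
// axial steps cost 1, diagonal steps cost sqrt(2). Dijkstra with a binary
// heap. Pixels outside region or unreachable from any in-region source are
// NA. Distances are in pixel units; callers scale by the pixel size.
// [[Rcpp::export]]
NumericMatrix geodesic_dist_cpp(LogicalMatrix region, LogicalMatrix sources) {
  const int H = region.nrow(), W = region.ncol();
  if (sources.nrow() != H || sources.ncol() != W)
    stop("region and sources must have the same shape");
  NumericMatrix dist(H, W);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  bool any_source = false;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (sources(i, j) && region(i, j)) {
        dist(i, j) = 0.0;
        pq.push(Node(0.0, i + j * H));
        any_source = true;
      }
    }
  }
  if (!any_source) stop("no source pixel lies inside the region");
  const double SQRT2 = std::sqrt(2.0);
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    int p = nd.second;
    int pi = p % H, pj = p / H;
    if (nd.first > dist(pi, pj)) continue;
    for (int k = 0; k < 8; ++k) {
      int ni = pi + dy[k], nj = pj + dx[k];
      if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
      if (!region(ni, nj)) continue;
      double step = (dy[k] != 0 && dx[k] != 0) ? SQRT2 : 1.0;
      double cand = nd.first + step;
      if (cand < dist(ni, nj) - 1e-15) {
        dist(ni, nj) = cand;
        pq.push(Node(cand, ni + nj * H));
      }
    }
  }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (!region(i, j) || !R_finite(dist(i, j)))
        dist(i, j) = NA_REAL;
  return dist;
}

// Per-column median of a frames-by-pixels matrix, ignoring NaN/NA entries.
// Columns with no finite value yield NA.
// [[Rcpp::export]]
NumericVector stack_median_cpp(NumericMatrix x) {
  const int n = x.nrow(), p = x.ncol();
  NumericVector out(p);
  std::vector<double> buf;
  buf.reserve(n);
  for (int j = 0; j < p; ++j) {
    buf.clear();
    for (int i = 0; i < n; ++i) {
      double v = x(i, j);
      if (R_finite(v)) buf.push_back(v);
    }
    if (buf.empty()) {
      out[j] = NA_REAL;
      continue;
    }
    size_t m = buf.size() / 2;
    std::nth_element(buf.begin(), buf.begin() + m, buf.end());
    double hi = buf[m];
    if (buf.size() % 2 == 1) {
      out[j] = hi;
    } else {
      double lo = *std::max_element(buf.begin(), buf.begin() + m);
      out[j] = (lo + hi) / 2.0;
    }
  }
  return out;
}
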