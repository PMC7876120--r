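#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Static 2D kd-tree over a reference point set. Built once per query batch;
// median splits encoded implicitly by index ranges (no node allocation).
// ---------------------------------------------------------------------------

namespace {

struct KDTree {
  const double *x, *y;
  std::vector<int> idx;

  KDTree(const double *x_, const double *y_, int n) : x(x_), y(y_), idx(n) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    build(0, n, 0);
  }

  void build(int lo, int hi, int axis) {
    if (hi - lo <= 1) return;
    int mid = (lo + hi) / 2;
    const double *c = axis == 0 ? x : y;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [c](int a, int b) { return c[a] < c[b]; });
    build(lo, mid, 1 - axis);
    build(mid + 1, hi, 1 - axis);
  }

  // k nearest neighbours of (qx,qy); `skip` excludes one reference index
  // (self-queries), pass -1 to disable. Max-heap keeps current k best.
  void query(double qx, double qy, int k, int skip,
             std::priority_queue<std::pair<double, int> > &heap) const {
    search(0, (int)idx.size(), 0, qx, qy, k, skip, heap);
  }

  void search(int lo, int hi, int axis, double qx, double qy, int k, int skip,
              std::priority_queue<std::pair<double, int> > &heap) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = idx[mid];
    if (p != skip) {
      double dx = x[p] - qx, dy = y[p] - qy, d2 = dx * dx + dy * dy;
      if ((int)heap.size() < k)
        heap.push(std::make_pair(d2, p));
      else if (d2 < heap.top().first) {
        heap.pop();
        heap.push(std::make_pair(d2, p));
      }
    }
    double diff = (axis == 0 ? qx - x[p] : qy - y[p]);
    int l1, h1, l2, h2;
    if (diff < 0) {
      l1 = lo; h1 = mid; l2 = mid + 1; h2 = hi;
    } else {
      l1 = mid + 1; h1 = hi; l2 = lo; h2 = mid;
    }
    search(l1, h1, 1 - axis, qx, qy, k, skip, heap);
    if ((int)heap.size() < k || diff * diff < heap.top().first)
      search(l2, h2, 1 - axis, qx, qy, k, skip, heap);
  }
};

}  // namespace

// Distances (and reference indices, 1-based) of the k nearest reference
// points for each query point. self = TRUE assumes query and reference are
// the same set in the same order and excludes the query point itself.
// Missing neighbours (k exceeds usable reference size) come back as NA.
// [[Rcpp::export]]
List cpp_knn(NumericVector qx, NumericVector qy, NumericVector rx,
             NumericVector ry, int k, bool self) {
  int nq = qx.size(), nr = rx.size();
  if (k < 1) stop("k must be >= 1");
  KDTree tree(rx.begin(), ry.begin(), nr);
  NumericMatrix dist(nq, k);
  IntegerMatrix nbr(nq, k);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  std::fill(nbr.begin(), nbr.end(), NA_INTEGER);
  for (int i = 0; i < nq; ++i) {
    std::priority_queue<std::pair<double, int> > heap;
    tree.query(qx[i], qy[i], k, self ? i : -1, heap);
    int m = (int)heap.size();
    for (int j = m - 1; j >= 0; --j) {
      dist(i, j) = std::sqrt(heap.top().first);
      nbr(i, j) = heap.top().second + 1;
      heap.pop();
    }
  }
  return List::create(_["dist"] = dist, _["index"] = nbr);
}

// ---------------------------------------------------------------------------
// DBSCAN with a uniform-grid fixed-radius neighbourhood index.
// Labels: 0 = noise, 1..K = clusters. minPts counts the point itself.
// Border points join the first core cluster that reaches them in scan order;
// callers sort the input beforehand to pin that order down.
// ---------------------------------------------------------------------------

namespace {

struct Grid {
  double eps, x0, y0;
  int ncx;
  std::unordered_map<long long, std::vector<int> > cells;
  const double *x, *y;
  int n;

  Grid(const double *x_, const double *y_, int n_, double eps_)
      : eps(eps_), x(x_), y(y_), n(n_) {
    double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (x[i] > xmax) xmax = x[i];
    }
    x0 = xmin; y0 = ymin;
    ncx = (int)((xmax - xmin) / eps) + 2;
    for (int i = 0; i < n; ++i) cells[key(i)].push_back(i);
  }
  long long key(int i) const {
    long long cx = (long long)((x[i] - x0) / eps);
    long long cy = (long long)((y[i] - y0) / eps);
    return cy * (long long)(ncx + 1) + cx;
  }
  void neighbours(int i, std::vector<int> &out) const {
    out.clear();
    long long cx = (long long)((x[i] - x0) / eps);
    long long cy = (long long)((y[i] - y0) / eps);
    double e2 = eps * eps;
    for (long long dy = -1; dy <= 1; ++dy)
      for (long long dx = -1; dx <= 1; ++dx) {
        long long k = (cy + dy) * (long long)(ncx + 1) + (cx + dx);
        std::unordered_map<long long, std::vector<int> >::const_iterator it =
            cells.find(k);
        if (it == cells.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          int p = it->second[j];
          double ddx = x[p] - x[i], ddy = y[p] - y[i];
          if (ddx * ddx + ddy * ddy <= e2) out.push_back(p);
        }
      }
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y, double eps,
                         int min_pts) {
  int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  Grid grid(x.begin(), y.begin(), n, eps);
  std::vector<bool> visited(n, false);
  std::vector<int> nb, nb2, seeds;
  int cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    visited[i] = true;
    grid.neighbours(i, nb);
    if ((int)nb.size() < min_pts) continue;  // noise unless claimed later
    ++cluster;
    labels[i] = cluster;
    seeds.assign(nb.begin(), nb.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      int j = seeds[s];
      if (labels[j] == 0) labels[j] = cluster;  // border or reclaimed noise
      if (visited[j]) continue;
      visited[j] = true;
      grid.neighbours(j, nb2);
      if ((int)nb2.size() >= min_pts) {
        labels[j] = cluster;
        seeds.insert(seeds.end(), nb2.begin(), nb2.end());
      }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Two-sample 2D Kolmogorov-Smirnov statistic (Fasano-Franceschini style):
// D is the maximum, over all data points of both samples and the four
// quadrant orientations, of the difference in empirical quadrant fractions.
// Boundary points count toward the quadrant that is closed on both axes
// (lower-left style partition: <= / > on each axis).
// ---------------------------------------------------------------------------

namespace {

inline void quadrant_fracs(const double *x, const double *y, int n, double px,
                           double py, double out[4]) {
  int c[4] = {0, 0, 0, 0};
  for (int i = 0; i < n; ++i) {
    int qx = x[i] > px ? 1 : 0;
    int qy = y[i] > py ? 1 : 0;
    ++c[qx + 2 * qy];
  }
  for (int q = 0; q < 4; ++q) out[q] = (double)c[q] / n;
}

}  // namespace

// [[Rcpp::export]]
double cpp_ks2d(NumericVector ax, NumericVector ay, NumericVector bx,
                NumericVector by) {
  int na = ax.size(), nb = bx.size();
  if (na == 0 || nb == 0) stop("both samples must be non-empty");
  double D = 0.0, fa[4], fb[4];
  for (int i = 0; i < na + nb; ++i) {
    double px = i < na ? ax[i] : bx[i - na];
    double py = i < na ? ay[i] : by[i - na];
    quadrant_fracs(ax.begin(), ay.begin(), na, px, py, fa);
    quadrant_fracs(bx.begin(), by.begin(), nb, px, py, fb);
    for (int q = 0; q < 4; ++q) {
      double d = std::fabs(fa[q] - fb[q]);
      if (d > D) D = d;
    }
  }
  return D;
}

// Nearest-neighbour distances between localizations in consecutive frames,
// used by the NeNA precision estimator. Input must be sorted by frame.
// For every localization in frame f, the distance to the nearest
// localization in frame f+1 (if that frame is occupied) is returned,
// capped at max_radius (pairs beyond the cap are dropped).
// [[Rcpp::export]]
NumericVector cpp_consecutive_nn(NumericVector x, NumericVector y,
                                 IntegerVector frame, double max_radius) {
  int n = x.size();
  std::vector<double> out;
  if (n < 2) return NumericVector(0);
  double cap2 = max_radius * max_radius;
  int i = 0;
  while (i < n) {
    int f = frame[i];
    int j = i;
    while (j < n && frame[j] == f) ++j;       // [i, j) frame f
    if (j < n && frame[j] == f + 1) {
      int k2 = j;
      while (k2 < n && frame[k2] == f + 1) ++k2;  // [j, k2) frame f+1
      for (int a = i; a < j; ++a) {
        double best = R_PosInf;
        for (int b = j; b < k2; ++b) {
          double dx = x[a] - x[b], dy = y[a] - y[b];
          double d2 = dx * dx + dy * dy;
          if (d2 < best) best = d2;
        }
        if (best <= cap2) out.push_back(std::sqrt(best));
      }
    }
    i = j;
  }
  return NumericVector(out.begin(), out.end());
}
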