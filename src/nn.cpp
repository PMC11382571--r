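// Exact 3-d spatial queries used by the cloud-cleanup, metric and ICP code.
// The kd-tree returns results bit-identical to exhaustive search: squared
// distances are accumulated in the same order (dx*dx + dy*dy + dz*dz) with a
// final sqrt, so tests may compare against an O(N*M) oracle with tolerance 0.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <queue>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

namespace {

inline double sq_dist(double ax, double ay, double az,
                      double bx, double by, double bz) {
  const double dx = ax - bx, dy = ay - by, dz = az - bz;
  return dx * dx + dy * dy + dz * dz;
}

class KDTree {
 public:
  explicit KDTree(const NumericMatrix& pts)
      : x_(&pts(0, 0)), y_(&pts(0, 1)), z_(&pts(0, 2)), n_(pts.nrow()) {
    ord_.resize(n_);
    for (int i = 0; i < n_; ++i) ord_[i] = i;
    build(0, n_, 0);
  }

  // Single nearest neighbour; `skip` (or -1) excludes one reference index.
  void nearest(double qx, double qy, double qz, int skip,
               double& best_d2, int& best_i) const {
    best_d2 = R_PosInf;
    best_i = -1;
    nn_rec(0, n_, 0, qx, qy, qz, skip, best_d2, best_i);
  }

  // k nearest neighbours (squared distances), excluding `skip`.
  void knearest(double qx, double qy, double qz, int skip, int k,
                std::vector<double>& d2_out) const {
    std::priority_queue<double> heap;  // max-heap of the k best d2
    knn_rec(0, n_, 0, qx, qy, qz, skip, k, heap);
    d2_out.resize(heap.size());
    for (int i = static_cast<int>(heap.size()) - 1; i >= 0; --i) {
      d2_out[i] = heap.top();
      heap.pop();
    }
  }

 private:
  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    const int mid = (lo + hi) / 2;
    const double* c = axis_ptr(depth % 3);
    std::nth_element(ord_.begin() + lo, ord_.begin() + mid, ord_.begin() + hi,
                     [c](int a, int b) { return c[a] < c[b]; });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  const double* axis_ptr(int axis) const {
    return axis == 0 ? x_ : (axis == 1 ? y_ : z_);
  }

  void nn_rec(int lo, int hi, int depth, double qx, double qy, double qz,
              int skip, double& best_d2, int& best_i) const {
    if (lo >= hi) return;
    const int mid = (lo + hi) / 2;
    const int p = ord_[mid];
    if (p != skip) {
      const double d2 = sq_dist(qx, qy, qz, x_[p], y_[p], z_[p]);
      if (d2 < best_d2 || (d2 == best_d2 && p < best_i)) {
        best_d2 = d2;
        best_i = p;
      }
    }
    const int axis = depth % 3;
    const double qc = axis == 0 ? qx : (axis == 1 ? qy : qz);
    const double diff = qc - axis_ptr(axis)[p];
    const int near_lo = diff < 0 ? lo : mid + 1;
    const int near_hi = diff < 0 ? mid : hi;
    const int far_lo = diff < 0 ? mid + 1 : lo;
    const int far_hi = diff < 0 ? hi : mid;
    nn_rec(near_lo, near_hi, depth + 1, qx, qy, qz, skip, best_d2, best_i);
    if (diff * diff <= best_d2)
      nn_rec(far_lo, far_hi, depth + 1, qx, qy, qz, skip, best_d2, best_i);
  }

  void knn_rec(int lo, int hi, int depth, double qx, double qy, double qz,
               int skip, int k, std::priority_queue<double>& heap) const {
    if (lo >= hi) return;
    const int mid = (lo + hi) / 2;
    const int p = ord_[mid];
    if (p != skip) {
      const double d2 = sq_dist(qx, qy, qz, x_[p], y_[p], z_[p]);
      if (static_cast<int>(heap.size()) < k) {
        heap.push(d2);
      } else if (d2 < heap.top()) {
        heap.pop();
        heap.push(d2);
      }
    }
    const int axis = depth % 3;
    const double qc = axis == 0 ? qx : (axis == 1 ? qy : qz);
    const double diff = qc - axis_ptr(axis)[p];
    const int near_lo = diff < 0 ? lo : mid + 1;
    const int near_hi = diff < 0 ? mid : hi;
    const int far_lo = diff < 0 ? mid + 1 : lo;
    const int far_hi = diff < 0 ? hi : mid;
    knn_rec(near_lo, near_hi, depth + 1, qx, qy, qz, skip, k, heap);
    if (static_cast<int>(heap.size()) < k || diff * diff <= heap.top())
      knn_rec(far_lo, far_hi, depth + 1, qx, qy, qz, skip, k, heap);
  }

  const double* x_;
  const double* y_;
  const double* z_;
  int n_;
  std::vector<int> ord_;
};

inline std::uint64_t cell_key(std::int64_t ix, std::int64_t iy,
                              std::int64_t iz) {
  // Mixing constants from splitmix64; collisions are harmless (a distance
  // check decides membership), they only add candidates.
  std::uint64_t h = static_cast<std::uint64_t>(ix) * 0x9E3779B97F4A7C15ULL;
  h ^= static_cast<std::uint64_t>(iy) * 0xBF58476D1CE4E5B9ULL;
  h ^= static_cast<std::uint64_t>(iz) * 0x94D049BB133111EBULL;
  return h;
}

}  // namespace

// [[Rcpp::export]]
List cpp_nn(NumericMatrix query, NumericMatrix ref) {
  if (ref.nrow() < 1) stop("reference cloud is empty");
  KDTree tree(ref);
  const int n = query.nrow();
  NumericVector dist(n);
  IntegerVector index(n);
  for (int i = 0; i < n; ++i) {
    double d2;
    int j;
    tree.nearest(query(i, 0), query(i, 1), query(i, 2), -1, d2, j);
    dist[i] = std::sqrt(d2);
    index[i] = j + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}

// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("cloud too small for k neighbours");
  KDTree tree(pts);
  NumericVector out(n);
  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    tree.knearest(pts(i, 0), pts(i, 1), pts(i, 2), i, k, d2);
    double s = 0.0;
    for (double v : d2) s += std::sqrt(v);
    out[i] = s / static_cast<double>(d2.size());
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dedupe(NumericMatrix pts, double eps) {
  const int n = pts.nrow();
  LogicalVector keep(n);
  if (eps <= 0.0) stop("eps must be > 0 (exact duplicates handled in R)");
  const double eps2 = eps * eps;
  std::unordered_map<std::uint64_t, std::vector<int>> grid;
  grid.reserve(static_cast<std::size_t>(n) * 2);
  for (int i = 0; i < n; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    const std::int64_t ix = static_cast<std::int64_t>(std::floor(px / eps));
    const std::int64_t iy = static_cast<std::int64_t>(std::floor(py / eps));
    const std::int64_t iz = static_cast<std::int64_t>(std::floor(pz / eps));
    bool ok = true;
    for (std::int64_t dx = -1; dx <= 1 && ok; ++dx)
      for (std::int64_t dy = -1; dy <= 1 && ok; ++dy)
        for (std::int64_t dz = -1; dz <= 1 && ok; ++dz) {
          auto it = grid.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (sq_dist(px, py, pz, pts(j, 0), pts(j, 1), pts(j, 2)) < eps2) {
              ok = false;
              break;
            }
          }
        }
    keep[i] = ok;
    if (ok) grid[cell_key(ix, iy, iz)].push_back(i);
  }
  return keep;
}
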