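#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Minimal 3D kd-tree (median split, cyclic axis) for 1-nearest-neighbour
// queries. Built per call; build is O(M log M), query O(log M) expected,
// which is what the ICP inner loop needs at N up to ~25k points.

namespace {

struct Node {
  int left, right;   // child node indices, -1 if leaf side empty
  int point;         // index into the point array
  int axis;
};

class KDTree3 {
public:
  KDTree3(const NumericMatrix &pts) : n_(pts.nrow()), p_(3 * pts.nrow()) {
    for (int i = 0; i < n_; ++i) {
      p_[3 * i]     = pts(i, 0);
      p_[3 * i + 1] = pts(i, 1);
      p_[3 * i + 2] = pts(i, 2);
    }
    idx_.resize(n_);
    for (int i = 0; i < n_; ++i) idx_[i] = i;
    nodes_.reserve(n_);
    root_ = build(0, n_, 0);
  }

  void nn1(const double *q, int &best, double &best_d2) const {
    best = -1;
    best_d2 = R_PosInf;
    search(root_, q, best, best_d2);
  }

private:
  int n_;
  std::vector<double> p_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;
  int root_;

  int build(int lo, int hi, int depth) {
    if (lo >= hi) return -1;
    int axis = depth % 3;
    int mid = lo + (hi - lo) / 2;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [&](int a, int b) { return p_[3 * a + axis] < p_[3 * b + axis]; });
    Node nd;
    nd.point = idx_[mid];
    nd.axis = axis;
    int self = (int)nodes_.size();
    nodes_.push_back(nd);
    int l = build(lo, mid, depth + 1);
    int r = build(mid + 1, hi, depth + 1);
    nodes_[self].left = l;
    nodes_[self].right = r;
    return self;
  }

  void search(int node, const double *q, int &best, double &best_d2) const {
    if (node < 0) return;
    const Node &nd = nodes_[node];
    const double *pt = &p_[3 * nd.point];
    double dx = q[0] - pt[0], dy = q[1] - pt[1], dz = q[2] - pt[2];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < best_d2) { best_d2 = d2; best = nd.point; }
    double diff = q[nd.axis] - pt[nd.axis];
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    search(near, q, best, best_d2);
    if (diff * diff < best_d2) search(far, q, best, best_d2);
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_nn1")]]
List cpp_nn1(NumericMatrix query, NumericMatrix ref) {
  KDTree3 tree(ref);
  int n = query.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    int best; double d2;
    tree.nn1(q, best, d2);
    idx[i] = best + 1;  // 1-based for R
    dist[i] = std::sqrt(d2);
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
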