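// Kraskov-Stoeckmann-Grassberger (algorithm 1) k-nearest-neighbour mutual
// information, max-norm, plus an all-pairs driver over 3-D residue
// displacement blocks. Estimates are in nats and may be slightly negative
// for independent data; clamping to zero happens at the R level.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// KSG-1 for one pair of marginals.
// X, Y: column-major blocks (n rows), dx/dy columns; strides are the row
// counts of the backing matrices (columns of a block are contiguous).
static double ksg1(const double* X, int ldx, int dx,
                   const double* Y, int ldy, int dy,
                   int n, int k,
                   std::vector<double>& dxv, std::vector<double>& dyv,
                   std::vector<double>& joint) {
  const double INF = std::numeric_limits<double>::infinity();
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double mx = 0.0, my = 0.0;
      for (int c = 0; c < dx; ++c) {
        double d = std::fabs(X[(size_t)c * ldx + j] - X[(size_t)c * ldx + i]);
        if (d > mx) mx = d;
      }
      for (int c = 0; c < dy; ++c) {
        double d = std::fabs(Y[(size_t)c * ldy + j] - Y[(size_t)c * ldy + i]);
        if (d > my) my = d;
      }
      dxv[j] = mx;
      dyv[j] = my;
      joint[j] = mx > my ? mx : my;
    }
    dxv[i] = INF;
    dyv[i] = INF;
    joint[i] = INF;
    // eps_i: kth smallest joint distance among j != i
    std::nth_element(joint.begin(), joint.begin() + (k - 1), joint.end());
    double eps = joint[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (dxv[j] < eps) ++nx;
      if (dyv[j] < eps) ++ny;
    }
    acc += R::digamma((double)nx + 1.0) + R::digamma((double)ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// [[Rcpp::export(name = ".ksg_mi_cpp")]]
double ksg_mi_cpp(NumericMatrix x, NumericMatrix y, int k) {
  int n = x.nrow();
  if (y.nrow() != n) stop("x and y must have the same number of rows");
  if (n < k + 2) stop("need at least k + 2 samples");
  if (k < 1) stop("k must be >= 1");
  std::vector<double> dxv(n), dyv(n), joint(n);
  return ksg1(REAL(x), n, x.ncol(), REAL(y), n, y.ncol(), n, k,
              dxv, dyv, joint);
}

// All-pairs MI over residue blocks of a displacement matrix.
// D: F x (3 * nres), columns grouped per residue (x, y, z).
// Returns the symmetric nres x nres MI matrix (diagonal NA).
// [[Rcpp::export(name = ".ksg_mi_allpairs_cpp")]]
NumericMatrix ksg_mi_allpairs_cpp(NumericMatrix D, int nres, int k) {
  int n = D.nrow();
  if (D.ncol() != 3 * nres) stop("D must have 3 * nres columns");
  if (n < k + 2) stop("need at least k + 2 frames");
  NumericMatrix out(nres, nres);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<double> dxv(n), dyv(n), joint(n);
  const double* base = REAL(D);
  for (int i = 0; i < nres; ++i) {
    for (int j = i + 1; j < nres; ++j) {
      double mi = ksg1(base + (size_t)3 * i * n, n, 3,
                       base + (size_t)3 * j * n, n, 3,
                       n, k, dxv, dyv, joint);
      out(i, j) = mi;
      out(j, i) = mi;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
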