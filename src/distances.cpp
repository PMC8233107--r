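// Pairwise distance kernels: sliced-Wasserstein between persistence
// diagrams and weighted Jaccard between nonnegative weight vectors.
//
// Sliced-Wasserstein (Carriere-style): each diagram is augmented with the
// diagonal projections of the other's points; for each of n_slices fixed
// directions theta in [-pi/2, pi/2) the points are projected, sorted, and
// matched in order with an l1 cost; the distance is the mean over slices.
// Projections of a diagram's own points and of its diagonal projections
// are precomputed and sorted once per slice, so each pair costs only two
// sorted merges.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// per-diagram, per-slice sorted projections of points and of diagonal
// projections
struct SlicedDiagram {
  std::vector<std::vector<double>> pts;   // [slice][point]
  std::vector<std::vector<double>> diag;  // [slice][point]
};

SlicedDiagram slice_diagram(const NumericMatrix& d,
                            const std::vector<double>& ct,
                            const std::vector<double>& st) {
  const int n = d.nrow(), L = static_cast<int>(ct.size());
  SlicedDiagram out;
  out.pts.assign(L, std::vector<double>(n));
  out.diag.assign(L, std::vector<double>(n));
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) {
      double b = d(i, 0), v = d(i, 1), mid = 0.5 * (b + v);
      out.pts[l][i] = b * ct[l] + v * st[l];
      out.diag[l][i] = mid * (ct[l] + st[l]);
    }
    std::sort(out.pts[l].begin(), out.pts[l].end());
    std::sort(out.diag[l].begin(), out.diag[l].end());
  }
  return out;
}

double sw_pair(const SlicedDiagram& a, const SlicedDiagram& b, int L,
               std::vector<double>& u, std::vector<double>& v) {
  double total = 0.0;
  for (int l = 0; l < L; ++l) {
    u.clear();
    v.clear();
    std::merge(a.pts[l].begin(), a.pts[l].end(), b.diag[l].begin(),
               b.diag[l].end(), std::back_inserter(u));
    std::merge(b.pts[l].begin(), b.pts[l].end(), a.diag[l].begin(),
               a.diag[l].end(), std::back_inserter(v));
    double cost = 0.0;
    for (size_t i = 0; i < u.size(); ++i) cost += std::fabs(u[i] - v[i]);
    total += cost;
  }
  return total / L;
}

}  // namespace

// [[Rcpp::export(name = ".sw_cross_cpp")]]
NumericMatrix sw_cross_cpp(List diagsA, List diagsB, int n_slices,
                           bool symmetric) {
  const int L = n_slices;
  std::vector<double> ct(L), st(L);
  for (int l = 0; l < L; ++l) {
    double theta = -M_PI / 2.0 + M_PI * l / L;
    ct[l] = std::cos(theta);
    st[l] = std::sin(theta);
  }
  const int na = diagsA.size(), nb = diagsB.size();
  std::vector<SlicedDiagram> A(na), B;
  for (int i = 0; i < na; ++i)
    A[i] = slice_diagram(as<NumericMatrix>(diagsA[i]), ct, st);
  if (!symmetric) {
    B.resize(nb);
    for (int i = 0; i < nb; ++i)
      B[i] = slice_diagram(as<NumericMatrix>(diagsB[i]), ct, st);
  }
  std::vector<double> u, v;
  if (symmetric) {
    NumericMatrix D(na, na);
    for (int i = 0; i < na; ++i)
      for (int j = i + 1; j < na; ++j) {
        double d = sw_pair(A[i], A[j], L, u, v);
        D(i, j) = d;
        D(j, i) = d;
      }
    return D;
  }
  NumericMatrix D(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) D(i, j) = sw_pair(A[i], B[j], L, u, v);
  return D;
}

// [[Rcpp::export(name = ".jaccard_cross_cpp")]]
NumericMatrix jaccard_cross_cpp(NumericMatrix X, NumericMatrix Y,
                                bool symmetric) {
  const int na = X.nrow(), nb = Y.nrow(), p = X.ncol();
  NumericMatrix D(na, symmetric ? na : nb);
  for (int i = 0; i < na; ++i) {
    int jstart = symmetric ? i + 1 : 0;
    int jend = symmetric ? na : nb;
    for (int j = jstart; j < jend; ++j) {
      double smin = 0.0, smax = 0.0;
      for (int k = 0; k < p; ++k) {
        double a = X(i, k);
        double b = symmetric ? X(j, k) : Y(j, k);
        if (a < b) {
          smin += a;
          smax += b;
        } else {
          smin += b;
          smax += a;
        }
      }
      double d = (smax > 0.0) ? 1.0 - smin / smax : 0.0;
      D(i, j) = d;
      if (symmetric) D(j, i) = d;
    }
  }
  return D;
}
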