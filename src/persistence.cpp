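// Vietoris-Rips persistent homology over a finite metric space,
// homological dimensions 0..max_dim (max_dim <= 2).
//
// Simplices are enumerated up to dimension max_dim + 1 with filtration
// value equal to the diameter (max pairwise distance).  Columns of the
// Z/2 boundary matrix are reduced dimension-by-dimension from the top
// down with the clearing optimisation: a simplex that appears as the
// pivot of a reduced higher-dimensional column is a creator whose own
// column is known to vanish and is skipped.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct Simplex {
  double value;
  int dim;
  std::array<int, 4> v;  // vertices, ascending; unused slots = -1
};

inline std::uint64_t simplex_key(const std::array<int, 4>& v, int dim) {
  std::uint64_t key = 0;
  for (int i = 0; i <= dim; ++i)
    key |= (static_cast<std::uint64_t>(v[i]) + 1) << (16 * i);
  return key;
}

inline double diam3(const NumericMatrix& d, int a, int b, int c) {
  return std::max(d(a, b), std::max(d(a, c), d(b, c)));
}

// xor (symmetric difference) of two ascending index lists
std::vector<int> xor_cols(const std::vector<int>& a,
                          const std::vector<int>& b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  std::set_symmetric_difference(a.begin(), a.end(), b.begin(), b.end(),
                                std::back_inserter(out));
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".vr_persistence_cpp")]]
List vr_persistence_cpp(NumericMatrix dist, int max_dim, double max_radius) {
  const int n = dist.nrow();
  const int dmax = std::min(max_dim + 1, n - 1);

  std::vector<Simplex> simp;
  // vertices
  for (int i = 0; i < n; ++i)
    simp.push_back({0.0, 0, {i, -1, -1, -1}});
  // edges
  if (dmax >= 1)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (dist(i, j) <= max_radius)
          simp.push_back({dist(i, j), 1, {i, j, -1, -1}});
  // triangles
  if (dmax >= 2)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k) {
          double val = diam3(dist, i, j, k);
          if (val <= max_radius) simp.push_back({val, 2, {i, j, k, -1}});
        }
  // tetrahedra
  if (dmax >= 3)
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dij = dist(i, j);
        if (dij > max_radius) continue;
        for (int k = j + 1; k < n; ++k) {
          double dijk = std::max(dij, std::max(dist(i, k), dist(j, k)));
          if (dijk > max_radius) continue;
          for (int l = k + 1; l < n; ++l) {
            double val = std::max(
                dijk, std::max(dist(i, l), std::max(dist(j, l), dist(k, l))));
            if (val <= max_radius) simp.push_back({val, 3, {i, j, k, l}});
          }
        }
      }

  const int m = static_cast<int>(simp.size());
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  // filtration order: value, then dimension, then lexicographic vertices.
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (simp[a].value != simp[b].value) return simp[a].value < simp[b].value;
    if (simp[a].dim != simp[b].dim) return simp[a].dim < simp[b].dim;
    return simp[a].v < simp[b].v;
  });
  std::vector<int> pos(m);  // original index -> filtration position
  for (int i = 0; i < m; ++i) pos[ord[i]] = i;

  // key -> filtration position, for facet lookup
  std::unordered_map<std::uint64_t, int> index;
  index.reserve(m * 2);
  for (int i = 0; i < m; ++i)
    index[simplex_key(simp[ord[i]].v, simp[ord[i]].dim)] = i;

  std::vector<char> cleared(m, 0);
  std::vector<char> killer(m, 0);  // column reduced to nonzero
  // pairs: (dim of class, birth value, death value)
  std::vector<std::array<double, 3>> pairs;
  std::vector<int> deaths_per_dim(4, 0);

  for (int d = dmax; d >= 1; --d) {
    std::unordered_map<int, int> pivot2col;
    std::vector<std::vector<int>> cols;
    for (int fi = 0; fi < m; ++fi) {
      const Simplex& s = simp[ord[fi]];
      if (s.dim != d || cleared[fi]) continue;
      // boundary column: facet positions, ascending
      std::vector<int> col;
      col.reserve(d + 1);
      for (int drop = 0; drop <= d; ++drop) {
        std::array<int, 4> f = {-1, -1, -1, -1};
        int w = 0;
        for (int i = 0; i <= d; ++i)
          if (i != drop) f[w++] = s.v[i];
        col.push_back(index.at(simplex_key(f, d - 1)));
      }
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int piv = col.back();
        auto hit = pivot2col.find(piv);
        if (hit == pivot2col.end()) break;
        col = xor_cols(col, cols[hit->second]);
      }
      if (!col.empty()) {
        int piv = col.back();
        pivot2col[piv] = static_cast<int>(cols.size());
        cols.push_back(col);
        killer[fi] = 1;
        cleared[piv] = 1;
        ++deaths_per_dim[d - 1];
        double birth = simp[ord[piv]].value;
        double death = s.value;
        if (death > birth)
          pairs.push_back({static_cast<double>(d - 1), birth, death});
      }
    }
  }

  // creators per dim = simplices whose column vanished (incl. cleared,
  // incl. all vertices); essential = creators - deaths in that dim.
  std::vector<int> creators(4, 0);
  for (int fi = 0; fi < m; ++fi)
    if (!killer[fi]) ++creators[simp[ord[fi]].dim];

  List out(max_dim + 1);
  for (int k = 0; k <= max_dim; ++k) {
    std::vector<double> births, deaths;
    for (const auto& p : pairs)
      if (static_cast<int>(p[0]) == k) {
        births.push_back(p[1]);
        deaths.push_back(p[2]);
      }
    NumericMatrix pm(static_cast<int>(births.size()), 2);
    for (size_t i = 0; i < births.size(); ++i) {
      pm(i, 0) = births[i];
      pm(i, 1) = deaths[i];
    }
    colnames(pm) = CharacterVector::create("birth", "death");
    int essential = (k <= dmax) ? creators[k] - deaths_per_dim[k] : 0;
    out[k] = List::create(_["dimension"] = k, _["pairs"] = pm,
                          _["essential_count"] = essential);
  }
  return out;
}
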