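#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expanding-ring nearest-analog search on a regular equal-area grid.
//
// For focal cell i, candidate cells j qualify when the future climate
// vector standardized by the FOCAL cell's baseline interannual SD,
// (b_kj - a_ki) / s_ki, has Euclidean norm <= threshold. The search walks
// Chebyshev rings outward; a ring at radius r contains no cell closer than
// r * cell_size, so scanning stops once r * cell_size exceeds the best
// Euclidean distance found (or the search radius). Ties at equal distance
// break by smaller dissimilarity, then by row-major cell index, making the
// result independent of scan order.
//
// a, b, s: per-variable matrices (rows x cols); NA-safe.
// Returns distances (km), 1-based row-major analog index, no-analog flag,
// invalid flag (focal cell unusable: missing climate or zero SD).
// [[Rcpp::export]]
List analog_search_cpp(List a_list, List b_list, List s_list,
                       double cell_size, double threshold, double radius_km) {
  const int K = a_list.size();
  std::vector<NumericMatrix> a(K), b(K), s(K);
  for (int k = 0; k < K; ++k) {
    a[k] = as<NumericMatrix>(a_list[k]);
    b[k] = as<NumericMatrix>(b_list[k]);
    s[k] = as<NumericMatrix>(s_list[k]);
  }
  const int nr = a[0].nrow(), nc = a[0].ncol();
  const double thr2 = threshold * threshold;
  NumericMatrix dist(nr, nc);
  IntegerMatrix analog(nr, nc);
  LogicalMatrix no_analog(nr, nc);
  LogicalMatrix invalid(nr, nc);
  std::fill(dist.begin(), dist.end(), NA_REAL);
  std::fill(analog.begin(), analog.end(), NA_INTEGER);

  const int r_grid = std::max(nr, nc);
  const int r_radius = (int)std::floor(radius_km / cell_size) + 1;
  const int r_max = std::min(r_grid, r_radius);

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      bool bad = false;
      for (int k = 0; k < K; ++k) {
        double av = a[k](i, j), sv = s[k](i, j);
        if (NumericMatrix::is_na(av) || NumericMatrix::is_na(sv) || sv <= 0.0)
          bad = true;
      }
      if (bad) { invalid(i, j) = true; continue; }

      double best_d = R_PosInf, best_dis = R_PosInf;
      int best_idx = -1;

      for (int r = 0; r <= r_max; ++r) {
        if (best_idx >= 0 && r * cell_size > best_d) break;
        if (r * cell_size > radius_km + cell_size) break;
        // ring cells at Chebyshev radius r around (i, j)
        const int ri0 = i - r, ri1 = i + r, rj0 = j - r, rj1 = j + r;
        for (int ci = std::max(ri0, 0); ci <= std::min(ri1, nr - 1); ++ci) {
          const bool edge_row = (ci == ri0 || ci == ri1);
          int cj = std::max(rj0, 0);
          const int cj_end = std::min(rj1, nc - 1);
          for (; cj <= cj_end; ++cj) {
            if (!edge_row && cj != rj0 && cj != rj1) {
              // interior of the ring square: jump to the right edge
              if (rj1 <= cj_end) { cj = rj1 - 1; continue; }
              break;
            }
            const double dr = (double)(ci - i), dc = (double)(cj - j);
            const double d = cell_size * std::sqrt(dr * dr + dc * dc);
            if (d > radius_km) continue;
            double dis2 = 0.0; bool miss = false;
            for (int k = 0; k < K; ++k) {
              const double bv = b[k](ci, cj);
              if (NumericMatrix::is_na(bv)) { miss = true; break; }
              const double z = (bv - a[k](i, j)) / s[k](i, j);
              dis2 += z * z;
            }
            if (miss || dis2 > thr2) continue;
            const int idx = ci * nc + cj;  // row-major, 0-based
            const bool better =
              (d < best_d) ||
              (d == best_d && dis2 < best_dis) ||
              (d == best_d && dis2 == best_dis && idx < best_idx);
            if (better) { best_d = d; best_dis = dis2; best_idx = idx; }
          }
        }
      }
      if (best_idx >= 0) {
        dist(i, j) = best_d;
        analog(i, j) = best_idx + 1;  // 1-based row-major
      } else {
        no_analog(i, j) = true;
      }
    }
  }
  return List::create(_["distance"] = dist, _["analog"] = analog,
                      _["no_analog"] = no_analog, _["invalid"] = invalid);
}
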