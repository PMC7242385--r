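#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterized interaction field on a torus.
//
// Cells are unit squares of side sqrt(cell_area) indexed (i, j),
// 0 <= i < width, 0 <= j < height, with centres at (i + 0.5, j + 0.5) in
// cell units. A cell belongs to a ZOI iff its centre lies strictly inside
// the circle (minimum-image metric, so circles wrap across edges).
//
// For every cell covered by k >= 2 plants, one cell_area of resource is
// divided among the coverers with weights A_i^p (obtained resource, A_c),
// and the cell's stress is shared with weights A_i^q: coverer i bears
// w_q_i of it and is relieved of the rest, so its amelioration gain is
// A_f_i += (1 - w_q_i) * cell_area. Singly covered cells go entirely to
// A_c of the sole plant and contribute nothing to A_f. p or q = +Inf
// means the largest coverer takes the whole resource share / bears the
// whole shared stress (exact ties split equally).

static inline int wrap_idx(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// [[Rcpp::export]]
List zoi_field_cpp(NumericVector x, NumericVector y, NumericVector A,
                   int width, int height, double cell_area,
                   double p, double q) {
  const int n = x.size();
  const double side = std::sqrt(cell_area);
  const double half_span = 0.5 * std::min(width, height);

  NumericVector r_cells(n);
  double A_max = 0.0;
  for (int k = 0; k < n; ++k) {
    if (A[k] < 0) stop("negative ZOI area");
    r_cells[k] = std::sqrt(A[k] / M_PI) / side;
    if (r_cells[k] >= half_span)
      stop("ZOI radius (%.2f cells) reaches half the arena span; "
           "self-overlap on the torus is ill-defined", (double)r_cells[k]);
    if (A[k] > A_max) A_max = A[k];
  }

  const bool p_inf = !R_finite(p) && p > 0;
  const bool q_inf = !R_finite(q) && q > 0;

  // relative weights, normalised by the largest ZOI to avoid overflow
  std::vector<double> wp(n, 1.0), wq(n, 1.0);
  for (int k = 0; k < n; ++k) {
    double rel = (A_max > 0) ? A[k] / A_max : 1.0;
    if (!p_inf) wp[k] = (p == 0.0) ? 1.0 : std::pow(rel, p);
    if (!q_inf) wq[k] = (q == 0.0) ? 1.0 : std::pow(rel, q);
  }

  const int ncell = width * height;
  std::vector<int> cnt(ncell, 0);
  std::vector<double> sum_wp, sum_wq, cell_max;
  std::vector<int> n_at_max;

  // pass 1: coverage counts and per-plant rasterized areas
  NumericVector A_rast(n), A_c(n), A_f(n);
  for (int k = 0; k < n; ++k) {
    const double r = r_cells[k], r2 = r * r;
    const double cx = x[k] / side, cy = y[k] / side; // centre in cell units
    int i0 = (int)std::ceil(cx - r - 0.5), i1 = (int)std::floor(cx + r - 0.5);
    int j0 = (int)std::ceil(cy - r - 0.5), j1 = (int)std::floor(cy + r - 0.5);
    int covered = 0;
    for (int j = j0; j <= j1; ++j) {
      double dy = (j + 0.5) - cy;
      double dy2 = dy * dy;
      if (dy2 >= r2) continue;
      for (int i = i0; i <= i1; ++i) {
        double dx = (i + 0.5) - cx;
        if (dx * dx + dy2 < r2) {
          ++cnt[wrap_idx(i, width) + width * wrap_idx(j, height)];
          ++covered;
        }
      }
    }
    A_rast[k] = covered * cell_area;
  }

  // pass 2: per-cell weight sums (contested cells only matter, but
  // accumulating everywhere is cheaper than branching)
  sum_wp.assign(ncell, 0.0);
  sum_wq.assign(ncell, 0.0);
  if (p_inf || q_inf) {
    cell_max.assign(ncell, -1.0);
    n_at_max.assign(ncell, 0);
  }
  for (int k = 0; k < n; ++k) {
    const double r = r_cells[k], r2 = r * r;
    const double cx = x[k] / side, cy = y[k] / side;
    int i0 = (int)std::ceil(cx - r - 0.5), i1 = (int)std::floor(cx + r - 0.5);
    int j0 = (int)std::ceil(cy - r - 0.5), j1 = (int)std::floor(cy + r - 0.5);
    for (int j = j0; j <= j1; ++j) {
      double dy = (j + 0.5) - cy;
      double dy2 = dy * dy;
      if (dy2 >= r2) continue;
      for (int i = i0; i <= i1; ++i) {
        double dx = (i + 0.5) - cx;
        if (dx * dx + dy2 < r2) {
          int c = wrap_idx(i, width) + width * wrap_idx(j, height);
          if (cnt[c] > 1) {
            sum_wp[c] += wp[k];
            sum_wq[c] += wq[k];
            if (p_inf || q_inf) {
              if (A[k] > cell_max[c]) { cell_max[c] = A[k]; n_at_max[c] = 1; }
              else if (A[k] == cell_max[c]) ++n_at_max[c];
            }
          }
        }
      }
    }
  }

  // pass 3: accumulate per-plant shares
  for (int k = 0; k < n; ++k) {
    const double r = r_cells[k], r2 = r * r;
    const double cx = x[k] / side, cy = y[k] / side;
    int i0 = (int)std::ceil(cx - r - 0.5), i1 = (int)std::floor(cx + r - 0.5);
    int j0 = (int)std::ceil(cy - r - 0.5), j1 = (int)std::floor(cy + r - 0.5);
    double ac = 0.0, af = 0.0;
    for (int j = j0; j <= j1; ++j) {
      double dy = (j + 0.5) - cy;
      double dy2 = dy * dy;
      if (dy2 >= r2) continue;
      for (int i = i0; i <= i1; ++i) {
        double dx = (i + 0.5) - cx;
        if (dx * dx + dy2 < r2) {
          int c = wrap_idx(i, width) + width * wrap_idx(j, height);
          if (cnt[c] == 1) {
            ac += cell_area;
          } else {
            double sc, sf;
            if (p_inf)
              sc = (A[k] == cell_max[c]) ? 1.0 / n_at_max[c] : 0.0;
            else
              sc = (sum_wp[c] > 0) ? wp[k] / sum_wp[c] : 1.0 / cnt[c];
            if (q_inf)
              sf = (A[k] == cell_max[c]) ? 1.0 / n_at_max[c] : 0.0;
            else
              sf = (sum_wq[c] > 0) ? wq[k] / sum_wq[c] : 1.0 / cnt[c];
            ac += cell_area * sc;
            af += cell_area * (1.0 - sf);
          }
        }
      }
    }
    A_c[k] = ac;
    A_f[k] = af;
  }

  return List::create(_["A_rast"] = A_rast, _["A_c"] = A_c, _["A_f"] = A_f);
}
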