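#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Adaptive-partition mutual information between two coordinate blocks.
//
// Points are rank-transformed per coordinate (done here, ties broken by input
// order), so every marginal is uniform on {0, ..., n-1}.  A cell is an axis-
// aligned hyperrectangle in rank space.  At each cell, every (X-coordinate,
// Y-coordinate) pair is scored by the 2x2 chi-square statistic obtained from
// splitting both coordinates at their within-cell medians; the best-scoring
// pair is split into four subcells when the statistic exceeds `crit` (a
// chi-square critical value, Bonferroni-corrected in the R wrapper) and every
// subcell would keep at least `min_cell` points.  Leaves contribute the usual
// plug-in term  (n_c/n) * log(n_c * n / (n_cx * n_cy)),  with n_cx (n_cy) the
// number of all points whose X-block (Y-block) falls inside the cell's X (Y)
// rectangle.  Returns MI in nats.
// ---------------------------------------------------------------------------

namespace {

struct ApWork {
  int n, dx, dy;
  std::vector<int> rx;   // n * dx, column-major ranks
  std::vector<int> ry;   // n * dy
  double crit1;          // chi-square critical value, 4-cell test (df 3)
  double crit2;          // chi-square critical value, 16-cell test (df 15)
  int min_cell;
  double mi;             // accumulator, nats

  int xr(int i, int k) const { return rx[(size_t)k * n + i]; }
  int yr(int i, int k) const { return ry[(size_t)k * n + i]; }
};

// median rank (m/2-th smallest) of cell points along one coordinate
static int cell_split_value(const std::vector<int> &idx,
                            const std::vector<int> &ranks, int n, int coord) {
  std::vector<int> v;
  v.reserve(idx.size());
  for (int i : idx) v.push_back(ranks[(size_t)coord * n + i]);
  size_t mid = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + mid, v.end());
  return v[mid];
}

static void ap_recurse(ApWork &w, std::vector<int> &idx,
                       std::vector<int> &xlo, std::vector<int> &xhi,
                       std::vector<int> &ylo, std::vector<int> &yhi) {
  const int m = (int)idx.size();
  bool split_done = false;
  int best_i = -1, best_j = -1, best_sx = 0, best_sy = 0;

  if (m >= 4 * w.min_cell) {
    double best_chi = -1.0;
    const double e = m / 4.0;
    for (int i = 0; i < w.dx; ++i) {
      if (xhi[i] - xlo[i] < 2) continue;
      int sx = cell_split_value(idx, w.rx, w.n, i);
      if (sx <= xlo[i] || sx >= xhi[i]) continue;
      for (int j = 0; j < w.dy; ++j) {
        if (yhi[j] - ylo[j] < 2) continue;
        int sy = cell_split_value(idx, w.ry, w.n, j);
        if (sy <= ylo[j] || sy >= yhi[j]) continue;
        int c00 = 0, c01 = 0, c10 = 0, c11 = 0;
        for (int t : idx) {
          bool lx = w.xr(t, i) < sx, ly = w.yr(t, j) < sy;
          if (lx && ly) ++c00;
          else if (lx) ++c01;
          else if (ly) ++c10;
          else ++c11;
        }
        double chi = (c00 - e) * (c00 - e) + (c01 - e) * (c01 - e) +
                     (c10 - e) * (c10 - e) + (c11 - e) * (c11 - e);
        chi /= e;
        int cmin = std::min(std::min(c00, c01), std::min(c10, c11));
        if (chi > best_chi && cmin >= w.min_cell) {
          best_chi = chi;
          best_i = i; best_j = j; best_sx = sx; best_sy = sy;
        }
      }
    }
    if (best_chi > w.crit1) {
      split_done = true;
    } else if (best_i >= 0) {
      // two-level look-ahead along the best pair: split each of the four
      // candidate children again at its own medians and test the sixteen
      // counts for uniformity (df 15).  Recovers power the single 4-cell
      // test lacks once cells get small.
      std::vector<int> child[4];
      for (int t : idx) {
        bool lx = w.xr(t, best_i) < best_sx, ly = w.yr(t, best_j) < best_sy;
        child[(lx ? 0 : 2) + (ly ? 0 : 1)].push_back(t);
      }
      double chi2 = 0.0;
      const double e16 = m / 16.0;
      for (int q = 0; q < 4; ++q) {
        int cx = 0, cy = 0;
        if (!child[q].empty()) {
          cx = cell_split_value(child[q], w.rx, w.n, best_i);
          cy = cell_split_value(child[q], w.ry, w.n, best_j);
        }
        int c[4] = {0, 0, 0, 0};
        for (int t : child[q]) {
          bool lx = w.xr(t, best_i) < cx, ly = w.yr(t, best_j) < cy;
          c[(lx ? 0 : 2) + (ly ? 0 : 1)]++;
        }
        for (int r = 0; r < 4; ++r) chi2 += (c[r] - e16) * (c[r] - e16) / e16;
      }
      if (chi2 > w.crit2) split_done = true;
    }
  }

  if (!split_done) {
    // leaf: marginal counts over all n points
    long ncx = 0, ncy = 0;
    for (int t = 0; t < w.n; ++t) {
      bool inx = true, iny = true;
      for (int k = 0; k < w.dx && inx; ++k) {
        int r = w.xr(t, k);
        if (r < xlo[k] || r >= xhi[k]) inx = false;
      }
      for (int k = 0; k < w.dy && iny; ++k) {
        int r = w.yr(t, k);
        if (r < ylo[k] || r >= yhi[k]) iny = false;
      }
      if (inx) ++ncx;
      if (iny) ++ncy;
    }
    if (m > 0 && ncx > 0 && ncy > 0) {
      double p = (double)m / w.n;
      w.mi += p * std::log(((double)m * w.n) / ((double)ncx * (double)ncy));
    }
    return;
  }

  std::vector<int> parts[4];
  for (int t : idx) {
    bool lx = w.xr(t, best_i) < best_sx, ly = w.yr(t, best_j) < best_sy;
    parts[(lx ? 0 : 2) + (ly ? 0 : 1)].push_back(t);
  }
  idx.clear(); idx.shrink_to_fit();

  for (int q = 0; q < 4; ++q) {
    int sx_lo = xlo[best_i], sx_hi = xhi[best_i];
    int sy_lo = ylo[best_j], sy_hi = yhi[best_j];
    if (q < 2) xhi[best_i] = best_sx; else xlo[best_i] = best_sx;
    if (q % 2 == 0) yhi[best_j] = best_sy; else ylo[best_j] = best_sy;
    ap_recurse(w, parts[q], xlo, xhi, ylo, yhi);
    xlo[best_i] = sx_lo; xhi[best_i] = sx_hi;
    ylo[best_j] = sy_lo; yhi[best_j] = sy_hi;
  }
}

static std::vector<int> column_ranks(const NumericMatrix &m) {
  const int n = m.nrow(), d = m.ncol();
  std::vector<int> out((size_t)n * d);
  std::vector<int> ord(n);
  for (int k = 0; k < d; ++k) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    const double *col = &m(0, k);
    std::stable_sort(ord.begin(), ord.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
    for (int r = 0; r < n; ++r) out[(size_t)k * n + ord[r]] = r;
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_ap_mi(NumericMatrix x, NumericMatrix y, double crit1, double crit2,
                 int min_cell) {
  if (x.nrow() != y.nrow()) stop("sample counts differ");
  ApWork w;
  w.n = x.nrow();
  w.dx = x.ncol();
  w.dy = y.ncol();
  w.crit1 = crit1;
  w.crit2 = crit2;
  w.min_cell = min_cell;
  w.mi = 0.0;
  w.rx = column_ranks(x);
  w.ry = column_ranks(y);

  std::vector<int> idx(w.n);
  for (int i = 0; i < w.n; ++i) idx[i] = i;
  std::vector<int> xlo(w.dx, 0), xhi(w.dx, w.n), ylo(w.dy, 0), yhi(w.dy, w.n);
  ap_recurse(w, idx, xlo, xhi, ylo, yhi);
  return w.mi;
}

// ---------------------------------------------------------------------------
// Cao embedding-dimension statistics.
//
// `vecs` holds delay vectors of the maximal dimension D+1 (one per row, most
// recent sample first).  For each d in 1..D the nearest neighbour of each
// point is found in the d-dimensional prefix under the maximum norm (zero
// distances skipped, self-matches excluded) and
//   E(d)  = mean over points of ||v_i - v_nn||_{d+1} / ||v_i - v_nn||_d
//   E*(d) = mean over points of |v_i[d] - v_nn[d]|   (the appended coordinate)
// Returns a 2 x D matrix with rows E and E*.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_cao_e(NumericMatrix vecs) {
  const int n = vecs.nrow();
  const int D = vecs.ncol() - 1;
  if (D < 1) stop("need at least two columns");
  NumericMatrix out(2, D);

  for (int d = 1; d <= D; ++d) {
    double esum = 0.0, essum = 0.0;
    long cnt = 0;
    for (int i = 0; i < n; ++i) {
      double bd = R_PosInf;
      int bj = -1;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double dist = 0.0;
        for (int k = 0; k < d; ++k) {
          double a = std::fabs(vecs(i, k) - vecs(j, k));
          if (a > dist) dist = a;
          if (dist >= bd) break;
        }
        if (dist > 0.0 && dist < bd) { bd = dist; bj = j; }
      }
      if (bj < 0) continue;
      double extra = std::fabs(vecs(i, d) - vecs(bj, d));
      double dd1 = std::max(bd, extra);  // max-norm in d+1 dims
      esum += dd1 / bd;
      essum += extra;
      ++cnt;
    }
    out(0, d - 1) = cnt > 0 ? esum / cnt : NA_REAL;
    out(1, d - 1) = cnt > 0 ? essum / cnt : NA_REAL;
  }
  return out;
}
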