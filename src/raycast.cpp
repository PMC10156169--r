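#include <Rcpp.h>
using namespace Rcpp;

// Bilinear height lookup on a regular lattice. heights(i, j) is the elevation
// at x = x0 + i*cell, y = y0 + j*cell. Returns NA outside the lattice.
static inline double height_at(const NumericMatrix& h, double x0, double y0,
                               double cell, double x, double y) {
  double fx = (x - x0) / cell, fy = (y - y0) / cell;
  int nx = h.nrow(), ny = h.ncol();
  if (fx < 0.0 || fy < 0.0 || fx > nx - 1.0 || fy > ny - 1.0)
    return NA_REAL;
  int i = (int)fx, j = (int)fy;
  if (i >= nx - 1) i = nx - 2;
  if (j >= ny - 1) j = ny - 2;
  double tx = fx - i, ty = fy - j;
  return h(i, j) * (1 - tx) * (1 - ty) + h(i + 1, j) * tx * (1 - ty) +
         h(i, j + 1) * (1 - tx) * ty + h(i + 1, j + 1) * tx * ty;
}

// March rays from a common origin through a heightfield; first surface
// crossing refined by bisection to `tol` meters. Misses (ray leaves the
// lattice or climbs above the terrain for good) return Inf.
// [[Rcpp::export]]
NumericVector raycast_heightfield(NumericVector origin, NumericMatrix dirs,
                                  NumericMatrix heights, double x0, double y0,
                                  double cell, double step, double tol,
                                  double tmax) {
  int m = dirs.nrow();
  NumericVector out(m);
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double hmax = -1e300;
  for (int i = 0; i < heights.nrow(); ++i)
    for (int j = 0; j < heights.ncol(); ++j)
      if (heights(i, j) > hmax) hmax = heights(i, j);

  for (int r = 0; r < m; ++r) {
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    if (NumericVector::is_na(dx)) { out[r] = NA_REAL; continue; }
    double t_prev = 0.0;
    double h0 = height_at(heights, x0, y0, cell, ox, oy);
    double f_prev = NumericVector::is_na(h0) ? 1.0 : (oz - h0);
    double hit = R_PosInf;
    for (double t = step; t <= tmax; t += step) {
      double px = ox + t * dx, py = oy + t * dy, pz = oz + t * dz;
      if (dz >= 0.0 && pz > hmax) break;            // climbing above everything
      double hv = height_at(heights, x0, y0, cell, px, py);
      if (NumericVector::is_na(hv)) break;          // left the lattice
      double f = pz - hv;
      if (f <= 0.0) {
        // bisect [t_prev, t] for the crossing
        double lo = t_prev, hi = t;
        if (f_prev <= 0.0) { hit = t_prev; break; } // started at/below surface
        for (int it = 0; it < 80 && (hi - lo) > tol; ++it) {
          double mid = 0.5 * (lo + hi);
          double hm = height_at(heights, x0, y0, cell,
                                ox + mid * dx, oy + mid * dy);
          double fm = (oz + mid * dz) - hm;
          if (fm <= 0.0) hi = mid; else lo = mid;
        }
        hit = 0.5 * (lo + hi);
        break;
      }
      t_prev = t;
      f_prev = f;
    }
    out[r] = hit;
  }
  return out;
}
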