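#include <Rcpp.h>
using namespace Rcpp;

// Bilinear elevation sample at fractional (row, col); NA outside the grid or
// when any of the four surrounding cells is nodata.
static inline double sample_z(const NumericMatrix &z, double r, double c) {
  int nr = z.nrow(), nc = z.ncol();
  if (r < 0.0 || c < 0.0 || r > nr - 1.0 || c > nc - 1.0) return NA_REAL;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 > nr - 2) r0 = nr - 2;
  if (c0 > nc - 2) c0 = nc - 2;
  if (r0 < 0) r0 = 0;
  if (c0 < 0) c0 = 0;
  double fr = r - r0, fc = c - c0;
  double z00 = z(r0, c0), z01 = z(r0, c0 + 1);
  double z10 = z(r0 + 1, c0), z11 = z(r0 + 1, c0 + 1);
  if (ISNAN(z00) || ISNAN(z01) || ISNAN(z10) || ISNAN(z11)) return NA_REAL;
  return z00 * (1 - fr) * (1 - fc) + z01 * (1 - fr) * fc +
         z10 * fr * (1 - fc) + z11 * fr * fc;
}

// Horizon-angle scan: for every cell and each of n_directions equally spaced
// azimuths (clockwise from north), march along the ray in steps of one cell
// size out to max_radius, sampling elevations bilinearly, and record the
// maximum elevation angle atan((z_p - z_cell)/dist), floored at 0.
// Rays truncate at the grid edge or on entering nodata. Row 0 is the
// northern edge. Returns an (nrow x ncol x n_directions) array in degrees.
// [[Rcpp::export]]
NumericVector horizon_scan_cpp(NumericMatrix z, double cell_size,
                               int n_directions, double max_radius) {
  int nr = z.nrow(), nc = z.ncol();
  int n_steps = (int)std::floor(max_radius / cell_size + 1e-9);
  NumericVector out(Dimension(nr, nc, n_directions));
  std::vector<double> dcol(n_directions), drow(n_directions);
  for (int k = 0; k < n_directions; ++k) {
    double az = 2.0 * M_PI * k / n_directions; // clockwise from north
    dcol[k] = std::sin(az);                    // east component
    drow[k] = -std::cos(az);                   // row index grows southward
  }
  const double rad2deg = 180.0 / M_PI;
  for (int k = 0; k < n_directions; ++k) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double z0 = z(i, j);
        if (ISNAN(z0)) {
          out[i + nr * j + nr * nc * k] = NA_REAL;
          continue;
        }
        double best = 0.0;
        for (int s = 1; s <= n_steps; ++s) {
          double dist = s * cell_size;
          double zp = sample_z(z, i + drow[k] * s, j + dcol[k] * s);
          if (ISNAN(zp)) break;
          double ang = std::atan((zp - z0) / dist);
          if (ang > best) best = ang;
        }
        out[i + nr * j + nr * nc * k] = best * rad2deg;
      }
    }
  }
  return out;
}
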