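#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Conventions shared with the R layer:
//  * 2D images are NumericMatrix with nrow = nx (x index), ncol = ny (y index);
//    the rotation / projection center is the image center ((nx-1)/2, (ny-1)/2).
//  * 3D volumes are column-major arrays dim = (nx, ny, nz); the world
//    coordinate of voxel (i,j,k) (0-based) is origin + (i,j,k) * spacing.
//  * Angles are in radians here; degrees are converted in R.

static inline double bilinear(const NumericMatrix& img, double fx, double fy) {
  const int nx = img.nrow(), ny = img.ncol();
  if (fx < 0.0 || fy < 0.0 || fx > nx - 1.0 || fy > ny - 1.0) return 0.0;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  const double dx = fx - x0, dy = fy - y0;
  return img(x0,     y0)     * (1.0 - dx) * (1.0 - dy)
       + img(x0 + 1, y0)     * dx         * (1.0 - dy)
       + img(x0,     y0 + 1) * (1.0 - dx) * dy
       + img(x0 + 1, y0 + 1) * dx         * dy;
}

// Parallel-beam line integrals of a continuous image (Radon transform).
// Returns n_angles x n_det matrix of integrals in units of value * cm.
// [[Rcpp::export]]
NumericMatrix cpp_radon(const NumericMatrix& img, double px,
                        const NumericVector& angles, int n_det,
                        double det_spacing, double step_frac) {
  const int na = angles.size();
  const int nx = img.nrow(), ny = img.ncol();
  NumericMatrix out(na, n_det);
  const double xc = (nx - 1) / 2.0, yc = (ny - 1) / 2.0;
  const double dc = (n_det - 1) / 2.0;
  const double half = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) * px;
  const double h = step_frac * px;
  const int ns = (int)std::ceil(2.0 * half / h);
  for (int a = 0; a < na; a++) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < n_det; d++) {
      const double t = (d - dc) * det_spacing;
      double acc = 0.0;
      for (int s = 0; s <= ns; s++) {
        const double u = -half + s * h;
        const double wx = t * ct - u * st;
        const double wy = t * st + u * ct;
        acc += bilinear(img, wx / px + xc, wy / px + yc);
      }
      out(a, d) = acc * h;
    }
  }
  return out;
}

// Per-material pathlengths through a label image (nearest-neighbour lookup).
// labels: 1-based material indices (R side), 0/NA treated as empty.
// Returns n_angles x n_det x n_materials array of pathlengths in cm.
// [[Rcpp::export]]
NumericVector cpp_radon_labels(const IntegerMatrix& labels, int n_materials,
                               double px, const NumericVector& angles,
                               int n_det, double det_spacing,
                               double step_frac) {
  const int na = angles.size();
  const int nx = labels.nrow(), ny = labels.ncol();
  NumericVector out(na * n_det * n_materials);
  const double xc = (nx - 1) / 2.0, yc = (ny - 1) / 2.0;
  const double dc = (n_det - 1) / 2.0;
  const double half = 0.5 * std::sqrt((double)nx * nx + (double)ny * ny) * px;
  const double h = step_frac * px;
  const int ns = (int)std::ceil(2.0 * half / h);
  std::vector<double> path((size_t)n_materials);
  for (int a = 0; a < na; a++) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int d = 0; d < n_det; d++) {
      const double t = (d - dc) * det_spacing;
      std::fill(path.begin(), path.end(), 0.0);
      for (int s = 0; s <= ns; s++) {
        const double u = -half + s * h;
        const double fx = (t * ct - u * st) / px + xc;
        const double fy = (t * st + u * ct) / px + yc;
        const int ix = (int)std::lround(fx), iy = (int)std::lround(fy);
        if (ix < 0 || iy < 0 || ix >= nx || iy >= ny) continue;
        const int lab = labels(ix, iy);
        if (lab == NA_INTEGER || lab < 1 || lab > n_materials) continue;
        path[(size_t)lab - 1] += h;
      }
      for (int m = 0; m < n_materials; m++)
        out[a + (size_t)na * d + (size_t)na * n_det * m] = path[(size_t)m];
    }
  }
  out.attr("dim") = IntegerVector::create(na, n_det, n_materials);
  return out;
}

// Back-projection of ramp-filtered projections (n_angles x n_det) onto an
// nx x ny grid with pixel size px. Result must be scaled by pi/n_angles by
// the caller (kept here for clarity of the discretized inversion formula).
// [[Rcpp::export]]
NumericMatrix cpp_backproject(const NumericMatrix& filt,
                              const NumericVector& angles,
                              double det_spacing, int nx, int ny, double px) {
  const int na = angles.size(), nd = filt.ncol();
  NumericMatrix out(nx, ny);
  const double xc = (nx - 1) / 2.0, yc = (ny - 1) / 2.0;
  const double dc = (nd - 1) / 2.0;
  for (int a = 0; a < na; a++) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < ny; j++) {
      const double y = (j - yc) * px;
      for (int i = 0; i < nx; i++) {
        const double x = (i - xc) * px;
        const double u = (x * ct + y * st) / det_spacing + dc;
        if (u < 0.0 || u > nd - 1.0) continue;
        int u0 = (int)std::floor(u);
        if (u0 == nd - 1) u0--;
        const double du = u - u0;
        out(i, j) += filt(a, u0) * (1.0 - du) + filt(a, u0 + 1) * du;
      }
    }
  }
  const double scale = M_PI / na;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) out(i, j) *= scale;
  return out;
}

// Snap fractional indices that are within 1e-9 of an integer onto it, so
// that lattice-preserving transforms (identity, quarter turns on matching
// grids) interpolate with exact 0/1 weights despite rounding in the
// coordinate algebra.
static inline double snap_index(double f) {
  const double r = std::nearbyint(f);
  return std::fabs(f - r) < 1e-9 ? r : f;
}

// Pull-based rigid resampling with tri-linear interpolation.
// The transform maps SOURCE coordinates into the LAB frame:
//   x_lab = R %*% x_src + tr.
// Each target voxel center (lab frame) is pulled back with the inverse and
// sampled from the source; coverage requires every source corner with a
// non-zero interpolation weight to be in-grid and covered (corners with
// weight exactly 0 are not part of the stencil).
// [[Rcpp::export]]
List cpp_resample_rigid(const NumericVector& vals, const LogicalVector& cov,
                        const IntegerVector& dim, const NumericVector& spacing,
                        const NumericVector& origin, const NumericMatrix& R,
                        const NumericVector& tr, const IntegerVector& odim,
                        const NumericVector& ospacing,
                        const NumericVector& oorigin) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  const size_t n_out = (size_t)ox * oy * oz;
  NumericVector ovals(n_out);
  LogicalVector ocov(n_out);
  // inverse of an orthonormal rotation is its transpose
  double Ri[3][3];
  for (int r = 0; r < 3; r++)
    for (int c = 0; c < 3; c++) Ri[r][c] = R(c, r);
  const size_t sxy = (size_t)nx * ny;
  size_t idx = 0;
  for (int k = 0; k < oz; k++) {
    const double wz = oorigin[2] + k * ospacing[2];
    for (int j = 0; j < oy; j++) {
      const double wy = oorigin[1] + j * ospacing[1];
      for (int i = 0; i < ox; i++, idx++) {
        const double wx = oorigin[0] + i * ospacing[0];
        const double dx = wx - tr[0], dy = wy - tr[1], dz = wz - tr[2];
        const double sx0 = Ri[0][0] * dx + Ri[0][1] * dy + Ri[0][2] * dz;
        const double sy0 = Ri[1][0] * dx + Ri[1][1] * dy + Ri[1][2] * dz;
        const double sz0 = Ri[2][0] * dx + Ri[2][1] * dy + Ri[2][2] * dz;
        const double fx = snap_index((sx0 - origin[0]) / spacing[0]);
        const double fy = snap_index((sy0 - origin[1]) / spacing[1]);
        const double fz = snap_index((sz0 - origin[2]) / spacing[2]);
        if (fx < 0.0 || fy < 0.0 || fz < 0.0 ||
            fx > nx - 1.0 || fy > ny - 1.0 || fz > nz - 1.0) {
          ovals[idx] = NA_REAL; ocov[idx] = false; continue;
        }
        int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
            z0 = (int)std::floor(fz);
        if (x0 == nx - 1) x0--;
        if (y0 == ny - 1 && ny > 1) y0--;
        if (z0 == nz - 1 && nz > 1) z0--;
        const int x1 = x0 + 1, y1 = ny > 1 ? y0 + 1 : y0,
                  z1 = nz > 1 ? z0 + 1 : z0;
        const double ax = fx - x0, ay = ny > 1 ? fy - y0 : 0.0,
                     az = nz > 1 ? fz - z0 : 0.0;
        bool all_cov = true;
        double acc = 0.0;
        for (int cz = 0; cz <= 1; cz++) {
          const int zz = cz ? z1 : z0;
          const double wz8 = cz ? az : 1.0 - az;
          for (int cy = 0; cy <= 1; cy++) {
            const int yy = cy ? y1 : y0;
            const double wy8 = cy ? ay : 1.0 - ay;
            for (int cx = 0; cx <= 1; cx++) {
              const double w = (cx ? ax : 1.0 - ax) * wy8 * wz8;
              if (w == 0.0) continue;
              const int xx = cx ? x1 : x0;
              const size_t s = (size_t)xx + (size_t)nx * yy + sxy * zz;
              if (!cov[s]) { all_cov = false; break; }
              acc += w * vals[s];
            }
            if (!all_cov) break;
          }
          if (!all_cov) break;
        }
        if (all_cov) { ovals[idx] = acc; ocov[idx] = true; }
        else { ovals[idx] = NA_REAL; ocov[idx] = false; }
      }
    }
  }
  return List::create(_["values"] = ovals, _["coverage"] = ocov);
}

// Normalized cross-correlation between `fixed` and `moving` sampled at the
// fixed grid translated by each candidate shift (cm, lab frame). Returns one
// NCC value per shift; NA where overlap is empty or degenerate.
// [[Rcpp::export]]
NumericVector cpp_ncc_shifts(const NumericVector& mvals,
                             const LogicalVector& mcov,
                             const IntegerVector& mdim,
                             const NumericVector& mspacing,
                             const NumericVector& morigin,
                             const NumericVector& fvals,
                             const LogicalVector& fcov,
                             const IntegerVector& fdim,
                             const NumericVector& fspacing,
                             const NumericVector& forigin,
                             const NumericMatrix& shifts) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const int fx_n = fdim[0], fy_n = fdim[1], fz_n = fdim[2];
  const size_t sxy = (size_t)nx * ny;
  const int nsh = shifts.nrow();
  NumericVector out(nsh);
  for (int s = 0; s < nsh; s++) {
    const double shx = shifts(s, 0), shy = shifts(s, 1), shz = shifts(s, 2);
    double sum_f = 0, sum_m = 0, sum_ff = 0, sum_mm = 0, sum_fm = 0;
    long n = 0;
    size_t fidx = 0;
    for (int k = 0; k < fz_n; k++) {
      const double wz = forigin[2] + k * fspacing[2] + shz;
      const double fz = (wz - morigin[2]) / mspacing[2];
      for (int j = 0; j < fy_n; j++) {
        const double wy = forigin[1] + j * fspacing[1] + shy;
        const double fy = (wy - morigin[1]) / mspacing[1];
        for (int i = 0; i < fx_n; i++, fidx++) {
          if (!fcov[fidx]) continue;
          const double wx = forigin[0] + i * fspacing[0] + shx;
          const double fxc = snap_index((wx - morigin[0]) / mspacing[0]);
          const double fys = snap_index(fy), fzs = snap_index(fz);
          if (fxc < 0.0 || fys < 0.0 || fzs < 0.0 ||
              fxc > nx - 1.0 || fys > ny - 1.0 || fzs > nz - 1.0) continue;
          int x0 = (int)std::floor(fxc), y0 = (int)std::floor(fys),
              z0 = (int)std::floor(fzs);
          if (x0 == nx - 1) x0--;
          if (y0 == ny - 1 && ny > 1) y0--;
          if (z0 == nz - 1 && nz > 1) z0--;
          const int x1 = x0 + 1, y1 = ny > 1 ? y0 + 1 : y0,
                    z1 = nz > 1 ? z0 + 1 : z0;
          const double ax = fxc - x0, ay = ny > 1 ? fys - y0 : 0.0,
                       az = nz > 1 ? fzs - z0 : 0.0;
          bool ok = true;
          double mv = 0.0;
          for (int cz = 0; cz <= 1 && ok; cz++) {
            const int zz = cz ? z1 : z0;
            const double wz8 = cz ? az : 1.0 - az;
            for (int cy = 0; cy <= 1 && ok; cy++) {
              const int yy = cy ? y1 : y0;
              const double wy8 = cy ? ay : 1.0 - ay;
              for (int cx = 0; cx <= 1 && ok; cx++) {
                const double w = (cx ? ax : 1.0 - ax) * wy8 * wz8;
                if (w == 0.0) continue;
                const int xx = cx ? x1 : x0;
                const size_t si = (size_t)xx + (size_t)nx * yy + sxy * zz;
                if (!mcov[si]) { ok = false; break; }
                mv += w * mvals[si];
              }
            }
          }
          if (!ok) continue;
          const double fv = fvals[fidx];
          sum_f += fv; sum_m += mv;
          sum_ff += fv * fv; sum_mm += mv * mv; sum_fm += fv * mv;
          n++;
        }
      }
    }
    if (n < 2) { out[s] = NA_REAL; continue; }
    const double var_f = sum_ff - sum_f * sum_f / n;
    const double var_m = sum_mm - sum_m * sum_m / n;
    if (var_f <= 0.0 || var_m <= 0.0) { out[s] = NA_REAL; continue; }
    out[s] = (sum_fm - sum_f * sum_m / n) / std::sqrt(var_f * var_m);
  }
  return out;
}

// Per-voxel mean (method = 0) or median (method = 1) over a stack of equally
// shaped volumes, restricted to covered samples.
// [[Rcpp::export]]
List cpp_combine_stack(const List& vols, const List& covs, int method,
                       const NumericVector& weights) {
  const int nv = vols.size();
  std::vector<const double*> vp((size_t)nv);
  std::vector<const int*> cp((size_t)nv);
  R_xlen_t n = 0;
  for (int v = 0; v < nv; v++) {
    NumericVector val = vols[v];
    LogicalVector cv = covs[v];
    vp[(size_t)v] = REAL(val);
    cp[(size_t)v] = LOGICAL(cv);
    n = val.size();
  }
  NumericVector out(n);
  IntegerVector cnt(n);
  std::vector<double> buf((size_t)nv);
  std::vector<double> wbuf((size_t)nv);
  const bool weighted = weights.size() == nv;
  for (R_xlen_t i = 0; i < n; i++) {
    int m = 0;
    for (int v = 0; v < nv; v++) {
      if (cp[(size_t)v][i]) {
        buf[(size_t)m] = vp[(size_t)v][i];
        wbuf[(size_t)m] = weighted ? weights[v] : 1.0;
        m++;
      }
    }
    cnt[i] = m;
    if (m == 0) { out[i] = NA_REAL; continue; }
    if (method == 0) {
      double s = 0.0, w = 0.0;
      for (int v = 0; v < m; v++) { s += buf[(size_t)v] * wbuf[(size_t)v]; w += wbuf[(size_t)v]; }
      out[i] = s / w;
    } else {
      std::sort(buf.begin(), buf.begin() + m);
      out[i] = (m % 2 == 1) ? buf[(size_t)(m / 2)]
                            : 0.5 * (buf[(size_t)(m / 2 - 1)] + buf[(size_t)(m / 2)]);
    }
  }
  return List::create(_["values"] = out, _["n"] = cnt);
}
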