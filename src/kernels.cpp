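#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Volumes are column-major (x fastest), dims (nx, ny, nz).
// Query coordinates are 0-based continuous voxel indices.

static inline R_xlen_t vidx(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static double sample_nearest(const double* v, int nx, int ny, int nz,
                             double qx, double qy, double qz, double fill) {
  int i = (int)std::lround(qx);
  int j = (int)std::lround(qy);
  int k = (int)std::lround(qz);
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return fill;
  return v[vidx(i, j, k, nx, ny)];
}

static double sample_trilinear(const double* v, int nx, int ny, int nz,
                               double qx, double qy, double qz, double fill) {
  if (qx < 0 || qy < 0 || qz < 0 ||
      qx > nx - 1.0 || qy > ny - 1.0 || qz > nz - 1.0)
    return fill;
  int i0 = (int)std::floor(qx), j0 = (int)std::floor(qy), k0 = (int)std::floor(qz);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (nx == 1) i0 = 0;
  if (ny == 1) j0 = 0;
  if (nz == 1) k0 = 0;
  double fx = qx - i0, fy = qy - j0, fz = qz - k0;
  int i1 = (nx == 1) ? i0 : i0 + 1;
  int j1 = (ny == 1) ? j0 : j0 + 1;
  int k1 = (nz == 1) ? k0 : k0 + 1;
  double c000 = v[vidx(i0, j0, k0, nx, ny)], c100 = v[vidx(i1, j0, k0, nx, ny)];
  double c010 = v[vidx(i0, j1, k0, nx, ny)], c110 = v[vidx(i1, j1, k0, nx, ny)];
  double c001 = v[vidx(i0, j0, k1, nx, ny)], c101 = v[vidx(i1, j0, k1, nx, ny)];
  double c011 = v[vidx(i0, j1, k1, nx, ny)], c111 = v[vidx(i1, j1, k1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Central differences in the interior, one-sided at faces, zero on
// degenerate (length-1) axes; scaled by 1/spacing.
static void gradient3_raw(const double* v, int nx, int ny, int nz,
                          double sx, double sy, double sz,
                          double* gx, double* gy, double* gz) {
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        R_xlen_t id = vidx(i, j, k, nx, ny);
        if (nx == 1) {
          gx[id] = 0.0;
        } else if (i == 0) {
          gx[id] = (v[vidx(1, j, k, nx, ny)] - v[id]) / sx;
        } else if (i == nx - 1) {
          gx[id] = (v[id] - v[vidx(nx - 2, j, k, nx, ny)]) / sx;
        } else {
          gx[id] = (v[vidx(i + 1, j, k, nx, ny)] - v[vidx(i - 1, j, k, nx, ny)]) / (2.0 * sx);
        }
        if (ny == 1) {
          gy[id] = 0.0;
        } else if (j == 0) {
          gy[id] = (v[vidx(i, 1, k, nx, ny)] - v[id]) / sy;
        } else if (j == ny - 1) {
          gy[id] = (v[id] - v[vidx(i, ny - 2, k, nx, ny)]) / sy;
        } else {
          gy[id] = (v[vidx(i, j + 1, k, nx, ny)] - v[vidx(i, j - 1, k, nx, ny)]) / (2.0 * sy);
        }
        if (nz == 1) {
          gz[id] = 0.0;
        } else if (k == 0) {
          gz[id] = (v[vidx(i, j, 1, nx, ny)] - v[id]) / sz;
        } else if (k == nz - 1) {
          gz[id] = (v[id] - v[vidx(i, j, nz - 2, nx, ny)]) / sz;
        } else {
          gz[id] = (v[vidx(i, j, k + 1, nx, ny)] - v[vidx(i, j, k - 1, nx, ny)]) / (2.0 * sz);
        }
      }
    }
  }
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= s;
  return k;
}

// Separable Gaussian, kernel truncated at 3*sigma, nearest-edge replication.
static void smooth3_raw(double* v, double* tmp, int nx, int ny, int nz,
                        double sgx, double sgy, double sgz) {
  // x pass: v -> tmp
  {
    std::vector<double> k = gauss_kernel(sgx);
    int r = ((int)k.size() - 1) / 2;
    for (int kz = 0; kz < nz; kz++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          double acc = 0.0;
          for (int t = -r; t <= r; t++) {
            int ii = i + t;
            if (ii < 0) ii = 0;
            if (ii >= nx) ii = nx - 1;
            acc += k[t + r] * v[vidx(ii, j, kz, nx, ny)];
          }
          tmp[vidx(i, j, kz, nx, ny)] = acc;
        }
  }
  // y pass: tmp -> v
  {
    std::vector<double> k = gauss_kernel(sgy);
    int r = ((int)k.size() - 1) / 2;
    for (int kz = 0; kz < nz; kz++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          double acc = 0.0;
          for (int t = -r; t <= r; t++) {
            int jj = j + t;
            if (jj < 0) jj = 0;
            if (jj >= ny) jj = ny - 1;
            acc += k[t + r] * tmp[vidx(i, jj, kz, nx, ny)];
          }
          v[vidx(i, j, kz, nx, ny)] = acc;
        }
  }
  // z pass: v -> tmp, then copy back
  {
    std::vector<double> k = gauss_kernel(sgz);
    int r = ((int)k.size() - 1) / 2;
    for (int kz = 0; kz < nz; kz++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++) {
          double acc = 0.0;
          for (int t = -r; t <= r; t++) {
            int kk = kz + t;
            if (kk < 0) kk = 0;
            if (kk >= nz) kk = nz - 1;
            acc += k[t + r] * v[vidx(i, j, kk, nx, ny)];
          }
          tmp[vidx(i, j, kz, nx, ny)] = acc;
        }
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    for (R_xlen_t id = 0; id < n; id++) v[id] = tmp[id];
  }
}

// [[Rcpp::export]]
NumericVector cpp_sample3(NumericVector vol, IntegerVector dim,
                          NumericMatrix coords, int method, double fill) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double* v = REAL(vol);
  const double* qx = &coords(0, 0);
  const double* qy = &coords(0, 1);
  const double* qz = &coords(0, 2);
  if (method == 0) {
    for (R_xlen_t p = 0; p < n; p++)
      out[p] = sample_nearest(v, nx, ny, nz, qx[p], qy[p], qz[p], fill);
  } else {
    for (R_xlen_t p = 0; p < n; p++)
      out[p] = sample_trilinear(v, nx, ny, nz, qx[p], qy[p], qz[p], fill);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gradient3(NumericVector vol, IntegerVector dim,
                            NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericMatrix g(n, 3);
  gradient3_raw(REAL(vol), nx, ny, nz, spacing[0], spacing[1], spacing[2],
                &g(0, 0), &g(0, 1), &g(0, 2));
  return g;
}

// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(vol);
  std::vector<double> tmp(n);
  smooth3_raw(REAL(out), tmp.data(), nx, ny, nz, sigma[0], sigma[1], sigma[2]);
  return out;
}

// Symmetric-force update, backward-mapping convention:
//   u = (I - I') * [ gS/(|gS|^2 + k^2 (I-I')^2) + gM/(|gM|^2 + k^2 (I-I')^2) ]
// A term whose denominator falls below eps contributes zero.
static void demons_force_raw(const double* s, const double* w,
                             const double* gsx, const double* gsy, const double* gsz,
                             const double* gwx, const double* gwy, const double* gwz,
                             R_xlen_t n, double k, double eps,
                             double* ux, double* uy, double* uz) {
  double k2 = k * k;
  for (R_xlen_t i = 0; i < n; i++) {
    double e = s[i] - w[i];
    double e2 = k2 * e * e;
    double d1 = gsx[i] * gsx[i] + gsy[i] * gsy[i] + gsz[i] * gsz[i] + e2;
    double d2 = gwx[i] * gwx[i] + gwy[i] * gwy[i] + gwz[i] * gwz[i] + e2;
    double a1 = (d1 < eps) ? 0.0 : e / d1;
    double a2 = (d2 < eps) ? 0.0 : e / d2;
    ux[i] = a1 * gsx[i] + a2 * gwx[i];
    uy[i] = a1 * gsy[i] + a2 * gwy[i];
    uz[i] = a1 * gsz[i] + a2 * gwz[i];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_demons_force(NumericVector stat, NumericVector warped,
                               IntegerVector dim, NumericVector spacing,
                               double k, double eps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> gs(3 * n), gw(3 * n);
  gradient3_raw(REAL(stat), nx, ny, nz, spacing[0], spacing[1], spacing[2],
                gs.data(), gs.data() + n, gs.data() + 2 * n);
  gradient3_raw(REAL(warped), nx, ny, nz, spacing[0], spacing[1], spacing[2],
                gw.data(), gw.data() + n, gw.data() + 2 * n);
  NumericMatrix u(n, 3);
  demons_force_raw(REAL(stat), REAL(warped),
                   gs.data(), gs.data() + n, gs.data() + 2 * n,
                   gw.data(), gw.data() + n, gw.data() + 2 * n,
                   n, k, eps, &u(0, 0), &u(0, 1), &u(0, 2));
  return u;
}

// Full single-resolution Demons loop. Returns the displacement field (mm,
// static frame), the per-iteration mean squared intensity difference, the
// iteration count and a convergence flag. Stops when the relative decrease
// of MSD over a 5-iteration window falls below tol, or at max_iter.
// [[Rcpp::export]]
List cpp_demons_run(NumericVector stat, NumericVector moving,
                    IntegerVector dim, NumericVector spacing,
                    double sigma, double k, int max_iter, double tol,
                    double fill, double eps) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double* s = REAL(stat);
  const double* m = REAL(moving);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::vector<double> gs(3 * n);
  gradient3_raw(s, nx, ny, nz, sx, sy, sz,
                gs.data(), gs.data() + n, gs.data() + 2 * n);

  NumericMatrix D(n, 3); // accumulated field, mm
  std::vector<double> w(n), gw(3 * n), u(3 * n), tmp(n);
  std::vector<double> msd_log;
  int iter = 0;
  bool converged = false;
  const int window = 5;

  for (iter = 1; iter <= max_iter; iter++) {
    // warp moving by current field (coords in voxel units)
    R_xlen_t id = 0;
    for (int kz = 0; kz < nz; kz++)
      for (int j = 0; j < ny; j++)
        for (int i = 0; i < nx; i++, id++) {
          double qx = i + D(id, 0) / sx;
          double qy = j + D(id, 1) / sy;
          double qz = kz + D(id, 2) / sz;
          w[id] = sample_trilinear(m, nx, ny, nz, qx, qy, qz, fill);
        }
    double msd = 0.0;
    for (R_xlen_t p = 0; p < n; p++) {
      double e = s[p] - w[p];
      msd += e * e;
    }
    msd /= (double)n;
    msd_log.push_back(msd);

    gradient3_raw(w.data(), nx, ny, nz, sx, sy, sz,
                  gw.data(), gw.data() + n, gw.data() + 2 * n);
    demons_force_raw(s, w.data(),
                     gs.data(), gs.data() + n, gs.data() + 2 * n,
                     gw.data(), gw.data() + n, gw.data() + 2 * n,
                     n, k, eps, u.data(), u.data() + n, u.data() + 2 * n);

    for (R_xlen_t p = 0; p < n; p++) {
      D(p, 0) += u[p];
      D(p, 1) += u[n + p];
      D(p, 2) += u[2 * n + p];
    }
    for (int c = 0; c < 3; c++)
      smooth3_raw(&D(0, c), tmp.data(), nx, ny, nz, sigma, sigma, sigma);

    for (R_xlen_t p = 0; p < 3 * n; p++) {
      if (!R_finite(D(p % n, p / n)))
        stop("non-finite displacement at iteration %d", iter);
    }

    int nl = (int)msd_log.size();
    if (tol > 0 && nl > window) {
      double prev = msd_log[nl - 1 - window];
      if (prev > 0 && (prev - msd) / prev < tol) {
        converged = true;
        break;
      }
    }
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["field"] = D,
                      _["msd"] = NumericVector(msd_log.begin(), msd_log.end()),
                      _["iterations"] = iter,
                      _["converged"] = converged);
}

// Correlation objective for translation search: Pearson correlation between
// the static bone values at the given voxels and the moving image sampled
// at those voxels shifted by t (voxel units). The thresholded images are
// defined only at or above `thresh`, so samples below it - like samples
// outside the moving extent - are excluded from the correlation. Returns
// NA when fewer than min_n valid pairs remain or variance degenerates.
// [[Rcpp::export]]
NumericVector cpp_shift_correlation(NumericVector moving, IntegerVector dim,
                                    NumericMatrix pts, NumericVector svals,
                                    NumericMatrix shifts, int method,
                                    int min_n, double thresh) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* m = REAL(moving);
  R_xlen_t np = pts.nrow();
  int ns = shifts.nrow();
  NumericVector out(ns);
  for (int si = 0; si < ns; si++) {
    double tx = shifts(si, 0), ty = shifts(si, 1), tz = shifts(si, 2);
    double sxm = 0, sym = 0, sxx = 0, syy = 0, sxy = 0;
    R_xlen_t cnt = 0;
    for (R_xlen_t p = 0; p < np; p++) {
      double qx = pts(p, 0) + tx, qy = pts(p, 1) + ty, qz = pts(p, 2) + tz;
      double val;
      if (method == 0) {
        if (qx < -0.5 || qy < -0.5 || qz < -0.5 ||
            qx > nx - 0.5 || qy > ny - 0.5 || qz > nz - 0.5) continue;
        val = sample_nearest(m, nx, ny, nz, qx, qy, qz, 0.0);
      } else {
        if (qx < 0 || qy < 0 || qz < 0 ||
            qx > nx - 1.0 || qy > ny - 1.0 || qz > nz - 1.0) continue;
        val = sample_trilinear(m, nx, ny, nz, qx, qy, qz, 0.0);
      }
      if (val < thresh) continue;
      double x = svals[p];
      sxm += x; sym += val; sxx += x * x; syy += val * val; sxy += x * val;
      cnt++;
    }
    if (cnt < min_n) {
      out[si] = NA_REAL;
      continue;
    }
    double c = (double)cnt;
    double vx = sxx - sxm * sxm / c;
    double vy = syy - sym * sym / c;
    double cov = sxy - sxm * sym / c;
    out[si] = (vx <= 0 || vy <= 0) ? NA_REAL : cov / std::sqrt(vx * vy);
  }
  return out;
}
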