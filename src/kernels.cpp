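#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Keys cubic convolution kernel (a = -0.5), support [-2, 2].
static inline double keys(double x) {
  x = std::fabs(x);
  if (x < 1.0) return 1.0 + x * x * (1.5 * x - 2.5);
  if (x < 2.0) return 2.0 - x * (4.0 - x * (2.5 - 0.5 * x));
  return 0.0;
}

// cubic B-spline kernel beta3, support [-2, 2]
static inline double bspline3(double x) {
  x = std::fabs(x);
  if (x < 1.0) return (4.0 - 6.0 * x * x + 3.0 * x * x * x) / 6.0;
  if (x < 2.0) { const double t = 2.0 - x; return t * t * t / 6.0; }
  return 0.0;
}

static inline double get_vox(const double* v, int nx, int ny, int nz,
                             int i, int j, int k) {
  if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
  return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k)];
}

// Affine resampling of a 3D array about its grid centre.
//
// out[x] = in(M %*% (x - c) + c + off), 1-based voxel coordinates,
// c = floor(dim/2) + 1 (the FFT-centre convention used package-wide).
// interp: 0 = trilinear, 1 = cubic (Keys) convolution. Out-of-grid -> fill.
// [[Rcpp::export(name = ".affine_resample_cpp")]]
NumericVector affine_resample_cpp(NumericVector vol, IntegerVector dim,
                                  NumericMatrix M, NumericVector off,
                                  int interp, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double cx = nx / 2 + 1, cy = ny / 2 + 1, cz = nz / 2 + 1;
  NumericVector out((size_t)nx * ny * nz);
  const double* v = vol.begin();
  double* o = out.begin();
  const double m11 = M(0,0), m12 = M(0,1), m13 = M(0,2);
  const double m21 = M(1,0), m22 = M(1,1), m23 = M(1,2);
  const double m31 = M(2,0), m32 = M(2,1), m33 = M(2,2);
  const double ox = off[0] + cx, oy = off[1] + cy, oz = off[2] + cz;
  size_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double dz = k + 1 - cz;
    for (int j = 0; j < ny; ++j) {
      const double dy = j + 1 - cy;
      const double px0 = m12 * dy + m13 * dz + ox;
      const double py0 = m22 * dy + m23 * dz + oy;
      const double pz0 = m32 * dy + m33 * dz + oz;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double dx = i + 1 - cx;
        const double px = m11 * dx + px0;
        const double py = m21 * dx + py0;
        const double pz = m31 * dx + pz0;
        // convert to 0-based continuous coordinates
        const double x = px - 1.0, y = py - 1.0, z = pz - 1.0;
        if (x < -1.0 || y < -1.0 || z < -1.0 ||
            x > nx || y > ny || z > nz) { o[idx] = fill; continue; }
        if (interp == 0) {
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                    z0 = (int)std::floor(z);
          const double fx = x - x0, fy = y - y0, fz = z - z0;
          double acc = 0.0;
          for (int kk = 0; kk <= 1; ++kk) {
            const double wz = kk ? fz : 1.0 - fz;
            if (wz == 0.0) continue;
            for (int jj = 0; jj <= 1; ++jj) {
              const double wy = jj ? fy : 1.0 - fy;
              if (wy == 0.0) continue;
              for (int ii = 0; ii <= 1; ++ii) {
                const double wx = ii ? fx : 1.0 - fx;
                if (wx == 0.0) continue;
                acc += wx * wy * wz *
                       get_vox(v, nx, ny, nz, x0 + ii, y0 + jj, z0 + kk);
              }
            }
          }
          o[idx] = acc;
        } else if (interp == 2) {
          // input holds cubic B-spline coefficients (see prefilter)
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                    z0 = (int)std::floor(z);
          double acc = 0.0;
          for (int kk = -1; kk <= 2; ++kk) {
            const double wz = bspline3(z - (z0 + kk));
            if (wz == 0.0) continue;
            for (int jj = -1; jj <= 2; ++jj) {
              const double wy = bspline3(y - (y0 + jj));
              if (wy == 0.0) continue;
              const double wyz = wy * wz;
              for (int ii = -1; ii <= 2; ++ii) {
                const double wx = bspline3(x - (x0 + ii));
                if (wx == 0.0) continue;
                acc += wx * wyz *
                       get_vox(v, nx, ny, nz, x0 + ii, y0 + jj, z0 + kk);
              }
            }
          }
          o[idx] = acc;
        } else {
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                    z0 = (int)std::floor(z);
          double acc = 0.0, wsum = 0.0;
          for (int kk = -1; kk <= 2; ++kk) {
            const double wz = keys(z - (z0 + kk));
            if (wz == 0.0) continue;
            for (int jj = -1; jj <= 2; ++jj) {
              const double wy = keys(y - (y0 + jj));
              if (wy == 0.0) continue;
              const double wyz = wy * wz;
              for (int ii = -1; ii <= 2; ++ii) {
                const double wx = keys(x - (x0 + ii));
                if (wx == 0.0) continue;
                acc += wx * wyz *
                       get_vox(v, nx, ny, nz, x0 + ii, y0 + jj, z0 + kk);
                wsum += wx * wyz;
              }
            }
          }
          // Keys weights sum to 1 in the interior; renormalise at borders
          o[idx] = (wsum != 0.0) ? acc / wsum : fill;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Sum of isotropic 3D Gaussians on a grid, truncated at `cutoff` sigma.
// centres: n x 3 matrix of 1-based voxel coordinates; per-point weights.
// Each point contributes `weight` to the sum of grid values (unit DC mass
// in voxel units), amplitude w / ((2*pi)^1.5 sigma^3).
// [[Rcpp::export(name = ".render_gaussians_cpp")]]
NumericVector render_gaussians_cpp(IntegerVector dim, NumericMatrix centres,
                                   NumericVector weights, double sigma,
                                   double cutoff) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  double* o = out.begin();
  const double amp0 = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const double r = cutoff * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int p = 0; p < centres.nrow(); ++p) {
    const double px = centres(p, 0) - 1.0, py = centres(p, 1) - 1.0,
                 pz = centres(p, 2) - 1.0;
    const double amp = amp0 * weights[p];
    const int i0 = std::max(0, (int)std::ceil(px - r)),
              i1 = std::min(nx - 1, (int)std::floor(px + r));
    const int j0 = std::max(0, (int)std::ceil(py - r)),
              j1 = std::min(ny - 1, (int)std::floor(py + r));
    const int k0 = std::max(0, (int)std::ceil(pz - r)),
              k1 = std::min(nz - 1, (int)std::floor(pz + r));
    for (int k = k0; k <= k1; ++k) {
      const double dz2 = (k - pz) * (k - pz);
      for (int j = j0; j <= j1; ++j) {
        const double dyz2 = (j - py) * (j - py) + dz2;
        size_t base = (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
        for (int i = i0; i <= i1; ++i) {
          const double d2 = (i - px) * (i - px) + dyz2;
          if (d2 <= r * r) o[base + i] += amp * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Zero all voxels within `radius` (voxel units) of any point (1-based coords).
// [[Rcpp::export(name = ".zero_near_points_cpp")]]
NumericVector zero_near_points_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix centres, double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double* o = out.begin();
  const double r2 = radius * radius;
  for (int p = 0; p < centres.nrow(); ++p) {
    const double px = centres(p, 0) - 1.0, py = centres(p, 1) - 1.0,
                 pz = centres(p, 2) - 1.0;
    const int i0 = std::max(0, (int)std::ceil(px - radius)),
              i1 = std::min(nx - 1, (int)std::floor(px + radius));
    const int j0 = std::max(0, (int)std::ceil(py - radius)),
              j1 = std::min(ny - 1, (int)std::floor(py + radius));
    const int k0 = std::max(0, (int)std::ceil(pz - radius)),
              k1 = std::min(nz - 1, (int)std::floor(pz + radius));
    for (int k = k0; k <= k1; ++k) {
      const double dz2 = (k - pz) * (k - pz);
      for (int j = j0; j <= j1; ++j) {
        const double dyz2 = (j - py) * (j - py) + dz2;
        size_t base = (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
        for (int i = i0; i <= i1; ++i)
          if ((i - px) * (i - px) + dyz2 <= r2) o[base + i] = 0.0;
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Trilinear sampling at arbitrary 1-based voxel coordinates (n x 3).
// Outside the grid -> 0.
// [[Rcpp::export(name = ".sample_trilinear_cpp")]]
NumericVector sample_trilinear_cpp(NumericVector vol, IntegerVector dim,
                                   NumericMatrix coords) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = vol.begin();
  const int n = coords.nrow();
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    const double x = coords(p, 0) - 1.0, y = coords(p, 1) - 1.0,
                 z = coords(p, 2) - 1.0;
    if (x < -1.0 || y < -1.0 || z < -1.0 || x > nx || y > ny || z > nz) {
      out[p] = 0.0; continue;
    }
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int kk = 0; kk <= 1; ++kk) {
      const double wz = kk ? fz : 1.0 - fz;
      if (wz == 0.0) continue;
      for (int jj = 0; jj <= 1; ++jj) {
        const double wy = jj ? fy : 1.0 - fy;
        if (wy == 0.0) continue;
        for (int ii = 0; ii <= 1; ++ii) {
          const double wx = ii ? fx : 1.0 - fx;
          if (wx == 0.0) continue;
          acc += wx * wy * wz *
                 get_vox(v, nx, ny, nz, x0 + ii, y0 + jj, z0 + kk);
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// Render the Gaussian model map and accumulate, in one pass, the sums
// needed for the CAM (over the model support: model_map > 1e-3 * peak) and
// the overlap fraction (model mass where target > target_contour).
// Returns c(n, sx, sy, sxx, syy, sxy, mass_total, mass_in).
// [[Rcpp::export(name = ".fit_score_cpp")]]
NumericVector fit_score_cpp(NumericVector target, IntegerVector dim,
                            NumericMatrix centres, NumericVector weights,
                            double sigma, double cutoff,
                            double target_contour) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n_vox = (size_t)nx * ny * nz;
  std::vector<double> mm(n_vox, 0.0);
  const double amp0 = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const double r = cutoff * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int p = 0; p < centres.nrow(); ++p) {
    const double px = centres(p, 0) - 1.0, py = centres(p, 1) - 1.0,
                 pz = centres(p, 2) - 1.0;
    const double amp = amp0 * weights[p];
    const int i0 = std::max(0, (int)std::ceil(px - r)),
              i1 = std::min(nx - 1, (int)std::floor(px + r));
    const int j0 = std::max(0, (int)std::ceil(py - r)),
              j1 = std::min(ny - 1, (int)std::floor(py + r));
    const int k0 = std::max(0, (int)std::ceil(pz - r)),
              k1 = std::min(nz - 1, (int)std::floor(pz + r));
    for (int k = k0; k <= k1; ++k) {
      const double dz2 = (k - pz) * (k - pz);
      for (int j = j0; j <= j1; ++j) {
        const double dyz2 = (j - py) * (j - py) + dz2;
        size_t base = (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
        for (int i = i0; i <= i1; ++i) {
          const double d2 = (i - px) * (i - px) + dyz2;
          if (d2 <= r * r) mm[base + i] += amp * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  double mx = 0.0;
  for (size_t i = 0; i < n_vox; ++i) if (mm[i] > mx) mx = mm[i];
  const double contour = 1e-3 * mx;
  const double* t = target.begin();
  double n = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  double mass_total = 0, mass_in = 0;
  for (size_t i = 0; i < n_vox; ++i) {
    const double y = mm[i];
    if (y <= 0.0) continue;
    mass_total += y;
    if (t[i] > target_contour) mass_in += y;
    if (y > contour) {
      n += 1; sx += t[i]; sy += y;
      sxx += t[i] * t[i]; syy += y * y; sxy += t[i] * y;
    }
  }
  return NumericVector::create(n, sx, sy, sxx, syy, sxy, mass_total,
                               mass_in);
}

// In-place cubic B-spline prefilter (Unser's recursive filter, mirror
// boundaries) along one axis.
static void bspline_filter_axis(double* c, int n, int stride) {
  const double z = -0.26794919243112270647;   // sqrt(3) - 2
  const double lambda = 6.0;
  if (n < 2) return;
  // causal initialization: truncated power series with mirror boundary
  int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  if (horizon > n) horizon = n;
  double sum = c[0];
  double zk = z;
  for (int k = 1; k < horizon; ++k) { sum += zk * c[(size_t)k * stride];
                                      zk *= z; }
  c[0] = lambda * sum;
  for (int k = 1; k < n; ++k)
    c[(size_t)k * stride] = lambda * c[(size_t)k * stride] +
                            z * c[(size_t)(k - 1) * stride];
  // anticausal initialization
  c[(size_t)(n - 1) * stride] =
    (z / (z * z - 1.0)) *
    (z * c[(size_t)(n - 2) * stride] + c[(size_t)(n - 1) * stride]);
  for (int k = n - 2; k >= 0; --k)
    c[(size_t)k * stride] = z * (c[(size_t)(k + 1) * stride] -
                                 c[(size_t)k * stride]);
}

// Cubic B-spline coefficients of a 3D array (separable prefilter).
// [[Rcpp::export(name = ".bspline_prefilter_cpp")]]
NumericVector bspline_prefilter_cpp(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out = clone(vol);
  double* c = out.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      bspline_filter_axis(c + (size_t)nx * ((size_t)j + (size_t)ny * k),
                          nx, 1);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i)
      bspline_filter_axis(c + (size_t)i + (size_t)nx * (size_t)ny * k,
                          ny, nx);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      bspline_filter_axis(c + (size_t)i + (size_t)nx * j, nz,
                          nx * ny);
  out.attr("dim") = dim;
  return out;
}
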