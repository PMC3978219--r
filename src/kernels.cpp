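#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Affine resampling of a 3-D volume.
//
// `map` is the 4x4 homogeneous matrix sending 0-based target voxel indices
// to 0-based source voxel indices.  mode 0 = trilinear, 1 = nearest
// neighbour.  Voxels back-projected outside the source grid receive `fill`
// (NA allowed, used by the registration cost to restrict to the overlap).
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src,
                                  IntegerVector src_dim,
                                  IntegerVector out_dim,
                                  NumericMatrix map,
                                  int mode,
                                  double fill) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);

  const double m00 = map(0, 0), m01 = map(0, 1), m02 = map(0, 2), m03 = map(0, 3);
  const double m10 = map(1, 0), m11 = map(1, 1), m12 = map(1, 2), m13 = map(1, 3);
  const double m20 = map(2, 0), m21 = map(2, 1), m22 = map(2, 2), m23 = map(2, 3);

  const double *s = src.begin();
  double *o = out.begin();
  const R_xlen_t sxy = static_cast<R_xlen_t>(sx) * sy;

  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      // incremental evaluation along i
      double px = m01 * j + m02 * k + m03;
      double py = m11 * j + m12 * k + m13;
      double pz = m21 * j + m22 * k + m23;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double x = px + m00 * i;
        const double y = py + m10 * i;
        const double z = pz + m20 * i;
        if (mode == 1) {  // nearest
          const int xi = static_cast<int>(std::floor(x + 0.5));
          const int yi = static_cast<int>(std::floor(y + 0.5));
          const int zi = static_cast<int>(std::floor(z + 0.5));
          if (xi < 0 || yi < 0 || zi < 0 || xi >= sx || yi >= sy || zi >= sz) {
            o[idx] = fill;
          } else {
            o[idx] = s[xi + static_cast<R_xlen_t>(yi) * sx + static_cast<R_xlen_t>(zi) * sxy];
          }
        } else {  // trilinear
          const double xf = std::floor(x), yf = std::floor(y), zf = std::floor(z);
          const int x0 = static_cast<int>(xf), y0 = static_cast<int>(yf), z0 = static_cast<int>(zf);
          if (x0 < 0 || y0 < 0 || z0 < 0 || x0 >= sx - 1 || y0 >= sy - 1 || z0 >= sz - 1) {
            // allow exact upper boundary
            if (x < -1e-9 || y < -1e-9 || z < -1e-9 ||
                x > sx - 1 + 1e-9 || y > sy - 1 + 1e-9 || z > sz - 1 + 1e-9) {
              o[idx] = fill;
              continue;
            }
            const int xc = std::min(std::max(x0, 0), sx - 2);
            const int yc = std::min(std::max(y0, 0), sy - 2);
            const int zc = std::min(std::max(z0, 0), sz - 2);
            const double dx = std::min(std::max(x - xc, 0.0), 1.0);
            const double dy = std::min(std::max(y - yc, 0.0), 1.0);
            const double dz = std::min(std::max(z - zc, 0.0), 1.0);
            const R_xlen_t b = xc + static_cast<R_xlen_t>(yc) * sx + static_cast<R_xlen_t>(zc) * sxy;
            const double c00 = s[b] * (1 - dx) + s[b + 1] * dx;
            const double c10 = s[b + sx] * (1 - dx) + s[b + sx + 1] * dx;
            const double c01 = s[b + sxy] * (1 - dx) + s[b + sxy + 1] * dx;
            const double c11 = s[b + sxy + sx] * (1 - dx) + s[b + sxy + sx + 1] * dx;
            o[idx] = (c00 * (1 - dy) + c10 * dy) * (1 - dz) + (c01 * (1 - dy) + c11 * dy) * dz;
            continue;
          }
          const double dx = x - xf, dy = y - yf, dz = z - zf;
          const R_xlen_t b = x0 + static_cast<R_xlen_t>(y0) * sx + static_cast<R_xlen_t>(z0) * sxy;
          const double c00 = s[b] * (1 - dx) + s[b + 1] * dx;
          const double c10 = s[b + sx] * (1 - dx) + s[b + sx + 1] * dx;
          const double c01 = s[b + sxy] * (1 - dx) + s[b + sxy + 1] * dx;
          const double c11 = s[b + sxy + sx] * (1 - dx) + s[b + sxy + sx + 1] * dx;
          o[idx] = (c00 * (1 - dy) + c10 * dy) * (1 - dz) + (c01 * (1 - dy) + c11 * dy) * dz;
        }
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}

static void blur_axis(std::vector<double> &v, std::vector<double> &tmp,
                      int nx, int ny, int nz, int axis, double sigma) {
  if (sigma <= 0) return;
  const int radius = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  std::vector<double> w(2 * radius + 1);
  for (int r = -radius; r <= radius; ++r)
    w[r + radius] = std::exp(-0.5 * (r * r) / (sigma * sigma));

  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : nxy;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        if (pos > 0) continue;  // handle each line once, from its origin
        R_xlen_t base = i + static_cast<R_xlen_t>(j) * nx + static_cast<R_xlen_t>(k) * nxy;
        for (int p = 0; p < n; ++p) {
          double acc = 0, wsum = 0;
          const int lo = std::max(0, p - radius), hi = std::min(n - 1, p + radius);
          for (int q = lo; q <= hi; ++q) {
            const double wt = w[q - p + radius];
            acc += wt * v[base + static_cast<R_xlen_t>(q) * stride];
            wsum += wt;
          }
          tmp[base + static_cast<R_xlen_t>(p) * stride] = acc / wsum;
        }
      }
    }
  }
  std::swap(v, tmp);
}

// Separable Gaussian blur with per-axis sigma in voxel units.  The kernel is
// renormalised at the grid boundary so the filter conserves signal away from
// hard edges.
// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector img, IntegerVector dim,
                                NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(img.begin(), img.end());
  std::vector<double> tmp(v.size());
  blur_axis(v, tmp, nx, ny, nz, 0, sigma_vox[0]);
  blur_axis(v, tmp, nx, ny, nz, 1, sigma_vox[1]);
  blur_axis(v, tmp, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}
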