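#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Positions outside the grid return `fill`.
static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z, double fill) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1);
  int y1 = std::min(y0 + 1, ny - 1);
  int z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
#define V(i, j, k) v[(i) + nx * ((j) + (size_t)ny * (k))]
  double c00 = V(x0, y0, z0) * (1 - fx) + V(x1, y0, z0) * fx;
  double c10 = V(x0, y1, z0) * (1 - fx) + V(x1, y1, z0) * fx;
  double c01 = V(x0, y0, z1) * (1 - fx) + V(x1, y0, z1) * fx;
  double c11 = V(x0, y1, z1) * (1 - fx) + V(x1, y1, z1) * fx;
#undef V
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Rotation matrix R = Rz(rz) * Ry(ry) * Rx(rx), angles in degrees.
static void rot_matrix(double rx, double ry, double rz, double R[9]) {
  const double d2r = M_PI / 180.0;
  double cx = std::cos(rx * d2r), sx = std::sin(rx * d2r);
  double cy = std::cos(ry * d2r), sy = std::sin(ry * d2r);
  double cz = std::cos(rz * d2r), sz = std::sin(rz * d2r);
  R[0] = cz * cy;  R[1] = cz * sy * sx - sz * cx;  R[2] = cz * sy * cx + sz * sx;
  R[3] = sz * cy;  R[4] = sz * sy * sx + cz * cx;  R[5] = sz * sy * cx - cz * sx;
  R[6] = -sy;      R[7] = cy * sx;                 R[8] = cy * cx;
}

// Resample a 3D volume under a rigid transform.
//
// The transform maps output world coordinates to input world coordinates:
//   x_in = R (x_out - c) + c + t
// with world coordinates = 0-based voxel index * voxel size, c the grid
// centre in mm, t in mm and rotations in degrees (order Rz Ry Rx).
// [[Rcpp::export]]
NumericVector cpp_resample_rigid(NumericVector vol, IntegerVector dims,
                                 NumericVector voxsize, NumericVector rot_deg,
                                 NumericVector trans_mm, double fill = 0.0) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double R[9];
  rot_matrix(rot_deg[0], rot_deg[1], rot_deg[2], R);
  double cx = 0.5 * (nx - 1) * voxsize[0];
  double cy = 0.5 * (ny - 1) * voxsize[1];
  double cz = 0.5 * (nz - 1) * voxsize[2];
  NumericVector out((size_t)nx * ny * nz);
  const double *v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++) {
    double wz = k * voxsize[2] - cz;
    for (int j = 0; j < ny; j++) {
      double wy = j * voxsize[1] - cy;
      for (int i = 0; i < nx; i++, idx++) {
        double wx = i * voxsize[0] - cx;
        double px = R[0] * wx + R[1] * wy + R[2] * wz + cx + trans_mm[0];
        double py = R[3] * wx + R[4] * wy + R[5] * wz + cy + trans_mm[1];
        double pz = R[6] * wx + R[7] * wy + R[8] * wz + cz + trans_mm[2];
        out[idx] = trilinear(v, nx, ny, nz, px / voxsize[0], py / voxsize[1],
                             pz / voxsize[2], fill);
      }
    }
  }
  return out;
}

// Count brain-mask voxels whose transformed position leaves the grid
// (used to refuse transforms that push the head out of the field of view).
// [[Rcpp::export]]
int cpp_count_outside(IntegerVector mask, IntegerVector dims,
                      NumericVector voxsize, NumericVector rot_deg,
                      NumericVector trans_mm) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double R[9];
  rot_matrix(rot_deg[0], rot_deg[1], rot_deg[2], R);
  double cx = 0.5 * (nx - 1) * voxsize[0];
  double cy = 0.5 * (ny - 1) * voxsize[1];
  double cz = 0.5 * (nz - 1) * voxsize[2];
  int outside = 0;
  size_t idx = 0;
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++, idx++) {
        if (!mask[idx]) continue;
        double wx = i * voxsize[0] - cx, wy = j * voxsize[1] - cy,
               wz = k * voxsize[2] - cz;
        double px = (R[0] * wx + R[1] * wy + R[2] * wz + cx + trans_mm[0]) / voxsize[0];
        double py = (R[3] * wx + R[4] * wy + R[5] * wz + cy + trans_mm[1]) / voxsize[1];
        double pz = (R[6] * wx + R[7] * wy + R[8] * wz + cz + trans_mm[2]) / voxsize[2];
        if (px < 0 || py < 0 || pz < 0 || px > nx - 1 || py > ny - 1 || pz > nz - 1)
          outside++;
      }
  return outside;
}

// Separable Gaussian smoothing (voxel units, kernel truncated at 3 sigma,
// edges clamped). Used to precondition volumes for registration.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector vol, IntegerVector dims,
                               double sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int hw = (int)std::ceil(3.0 * sigma_vox);
  std::vector<double> k(2 * hw + 1);
  double ksum = 0.0;
  for (int i = -hw; i <= hw; i++) {
    k[i + hw] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox));
    ksum += k[i + hw];
  }
  for (size_t i = 0; i < k.size(); i++) k[i] /= ksum;

  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(vol.begin(), vol.end()), b(n);
  int dsz[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ax++) {
    int len = dsz[ax];
    size_t st = stride[ax];
    for (size_t base = 0; base < n; base++) {
      // process each line once: base must be the first voxel along ax
      if ((base / st) % len != 0) continue;
      for (int i = 0; i < len; i++) {
        double acc = 0.0;
        for (int j = -hw; j <= hw; j++) {
          int idx = i + j;
          if (idx < 0) idx = 0;
          if (idx >= len) idx = len - 1;
          acc += k[j + hw] * a[base + (size_t)idx * st];
        }
        b[base + (size_t)i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
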