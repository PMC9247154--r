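#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect an out-of-range index back into [0, n) ("mirror" boundary:
// d c b a | a b c d | d c b a). Keeps local means unbiased at the faces.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 3D median filter with a cubic structuring element of side 2*radius + 1.
// vol is a numeric array in R's column-major layout with dims = (nz, ny, nx).
// [[Rcpp::export]]
NumericVector median_filter3d_cpp(NumericVector vol, IntegerVector dims, int radius) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(vol);
  NumericVector out(vol.size());
  const int side = 2 * radius + 1;
  const int m = side * side * side;
  std::vector<double> buf(m);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        int k = 0;
        for (int dx = -radius; dx <= radius; ++dx) {
          const long xx = reflect_idx(x + dx, nx);
          for (int dy = -radius; dy <= radius; ++dy) {
            const long yy = reflect_idx(y + dy, ny);
            const long base = nz * (yy + (long)ny * xx);
            for (int dz = -radius; dz <= radius; ++dz) {
              buf[k++] = vol[reflect_idx(z + dz, nz) + base];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        out[z + (long)nz * (y + (long)ny * x)] = buf[m / 2];
      }
    }
  }
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  int half = (int)std::ceil(4.0 * sigma);
  if (half < 1) half = 1;
  std::vector<double> k(2 * half + 1);
  double s = 0.0;
  for (int i = -half; i <= half; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + half] = v;
    s += v;
  }
  for (auto &v : k) v /= s;
  return k;
}

// Separable 3D Gaussian blur, sigma in voxels per axis (z, y, x order),
// mirror boundary handling.
// [[Rcpp::export]]
NumericVector gaussian_blur3d_cpp(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const long n = (long)nz * ny * nx;
  std::vector<double> a(vol.begin(), vol.end()), b(n);

  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma[axis];
    if (s <= 0) continue;
    std::vector<double> k = gauss_kernel(s);
    const int half = ((int)k.size() - 1) / 2;
    // strides in column-major (z fastest)
    const long strides[3] = {1, (long)nz, (long)nz * ny};
    const int lens[3] = {nz, ny, nx};
    const long stride = strides[axis];
    const int len = lens[axis];
    const int o1 = (axis + 1) % 3, o2 = (axis + 2) % 3;
    for (int i2 = 0; i2 < lens[o2]; ++i2) {
      for (int i1 = 0; i1 < lens[o1]; ++i1) {
        const long base = (long)i1 * strides[o1] + (long)i2 * strides[o2];
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int j = -half; j <= half; ++j) {
            acc += k[j + half] * a[base + (long)reflect_idx(i + j, len) * stride];
          }
          b[base + (long)i * stride] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}
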