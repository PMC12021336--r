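#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

// Direct (exact) nonuniform DFT between a Cartesian image and arbitrary
// k-space locations. Pixel coordinates are integers relative to the matrix
// center (floor(n/2)); k-space coordinates are in cycles per field of view,
// so the phase per pixel is -2*pi*(kx*x + ky*y)/n. Direct summation is the
// reconstruction oracle at demo scale; no gridding kernel is involved.

// [[Rcpp::export]]
ComplexVector cpp_nudft_forward(ComplexMatrix img, NumericVector kx,
                                NumericVector ky) {
  const int n = img.nrow();
  if (img.ncol() != n) stop("image must be square");
  const int ns = kx.size();
  if (ky.size() != ns) stop("kx and ky must have equal length");
  const double c0 = floor(n / 2.0);
  ComplexVector out(ns);
  for (int s = 0; s < ns; ++s) {
    std::complex<double> acc(0.0, 0.0);
    const double fx = -2.0 * M_PI * kx[s] / n;
    const double fy = -2.0 * M_PI * ky[s] / n;
    for (int j = 0; j < n; ++j) {
      const double y = j - c0;
      // phase factor along a column is a geometric progression
      const std::complex<double> stepx(std::cos(fx), std::sin(fx));
      std::complex<double> px(std::cos(fx * (0.0 - c0)), std::sin(fx * (0.0 - c0)));
      const std::complex<double> py(std::cos(fy * y), std::sin(fy * y));
      for (int i = 0; i < n; ++i) {
        const Rcomplex v = img(i, j);
        acc += std::complex<double>(v.r, v.i) * px * py;
        px *= stepx;
      }
    }
    out[s].r = acc.real();
    out[s].i = acc.imag();
  }
  return out;
}

// [[Rcpp::export]]
ComplexMatrix cpp_nudft_adjoint(ComplexVector data, NumericVector kx,
                                NumericVector ky, int n) {
  const int ns = data.size();
  if (kx.size() != ns || ky.size() != ns)
    stop("data, kx and ky must have equal length");
  const double c0 = floor(n / 2.0);
  ComplexMatrix img(n, n);
  std::vector< std::complex<double> > acc(n * n, std::complex<double>(0, 0));
  for (int s = 0; s < ns; ++s) {
    const double fx = 2.0 * M_PI * kx[s] / n;
    const double fy = 2.0 * M_PI * ky[s] / n;
    const std::complex<double> d(data[s].r, data[s].i);
    const std::complex<double> stepx(std::cos(fx), std::sin(fx));
    for (int j = 0; j < n; ++j) {
      const double y = j - c0;
      const std::complex<double> py(std::cos(fy * y), std::sin(fy * y));
      std::complex<double> px(std::cos(fx * (0.0 - c0)), std::sin(fx * (0.0 - c0)));
      const std::complex<double> dj = d * py;
      for (int i = 0; i < n; ++i) {
        acc[i + n * j] += dj * px;
        px *= stepx;
      }
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      img(i, j).r = acc[i + n * j].real();
      img(i, j).i = acc[i + n * j].imag();
    }
  return img;
}
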