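// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)
// and a separable reflective-boundary Gaussian blur. Both operate on plain
// numeric matrices; used by mask morphology and depth smoothing.

#include <Rcpp.h>
using namespace Rcpp;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance to the nearest TRUE pixel of `mask`.
// [[Rcpp::export]]
NumericMatrix sqdist_transform_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e20;
  NumericMatrix g(H, W);
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) f[i] = mask(i, j) ? 0.0 : INF;
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) g(i, j) = d[i];
  }
  NumericMatrix out(H, W);
  for (int i = 0; i < H; ++i) {
    for (int j = 0; j < W; ++j) f[j] = g(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) out(i, j) = d[j];
  }
  return out;
}

// Separable Gaussian blur, reflective (mirror-without-repeat) boundary.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix x, double sigma) {
  const int H = x.nrow(), W = x.ncol();
  if (sigma <= 0) return clone(x);
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double& v : kern) v /= s;
  // symmetric-with-repeat reflection: conserves total mass for any input
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
  };
  NumericMatrix tmp(H, W), out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double acc = 0;
      for (int k = -r; k <= r; ++k) acc += kern[k + r] * x(reflect(i + k, H), j);
      tmp(i, j) = acc;
    }
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double acc = 0;
      for (int k = -r; k <= r; ++k) acc += kern[k + r] * tmp(i, reflect(j + k, W));
      out(i, j) = acc;
    }
  return out;
}

// In-place LeakyReLU on a freshly allocated tensor (safe: callers only pass
// vectors they own), and the fused backward product da *= grad(a).
// [[Rcpp::export]]
void leaky_inplace_cpp(NumericVector x, double slope) {
  double* p = x.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] *= slope;
}

// [[Rcpp::export]]
void leaky_gradmul_cpp(NumericVector da, NumericVector a, double slope) {
  double* d = da.begin();
  const double* p = a.begin();
  const R_xlen_t n = da.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] <= 0) d[i] *= slope;
}
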