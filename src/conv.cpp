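// Minimal 3D convolution / pooling kernels for the dual-branch CNN.
// Layout convention: batch tensors are R arrays dim c(H, W, D, C, B),
// column-major; a 2D branch is the D = 1, kd = 1 special case.
// Weights are K x F matrices with K = kh*kw*kd*C, kernel index
// k = i + kh*(j + kw*(l + kd*c)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int D, int C,
                   int kh, int kw, int kd, arma::mat& col) {
  const int Ho = H - kh + 1, Wo = W - kw + 1, Do = D - kd + 1;
  const int P = Ho * Wo * Do;
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < kd; ++l)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          const int k = i + kh * (j + kw * (l + kd * c));
          double* dst = col.colptr(k);
          for (int d0 = 0; d0 < Do; ++d0)
            for (int w0 = 0; w0 < Wo; ++w0) {
              const double* src =
                x + (size_t)i + (size_t)H * ((w0 + j) + (size_t)W * ((d0 + l) + (size_t)D * c));
              double* dp = dst + (size_t)w0 * Ho + (size_t)d0 * Ho * Wo;
              for (int h0 = 0; h0 < Ho; ++h0) dp[h0] = src[h0];
            }
          (void)P;
        }
}

// [[Rcpp::export]]
NumericVector conv3d_fw_cpp(NumericVector x, IntegerVector xdim,
                            NumericMatrix Wm, NumericVector b) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], B = xdim[4];
  const arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  const int F = Wa.n_cols;
  int kh, kw, kd;
  {
    // kernel dims are implied by K = kh*kw*kd*C; caller passes them via attr
    IntegerVector kdim = Wm.attr("kdim");
    kh = kdim[0]; kw = kdim[1]; kd = kdim[2];
  }
  const int Ho = H - kh + 1, Wo = W - kw + 1, Do = D - kd + 1;
  const int P = Ho * Wo * Do, K = kh * kw * kd * C;
  NumericVector y((size_t)P * F * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, F, B);
  arma::mat col(P, K);
  const size_t xstride = (size_t)H * W * D * C;
  for (int s = 0; s < B; ++s) {
    im2col(x.begin() + s * xstride, H, W, D, C, kh, kw, kd, col);
    arma::mat ys(y.begin() + (size_t)s * P * F, P, F, false, true);
    ys = col * Wa;
    ys.each_row() += arma::rowvec(b.begin(), F);
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw_cpp(NumericVector x, IntegerVector xdim,
                   NumericMatrix Wm, NumericVector dy) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], B = xdim[4];
  const arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  const int F = Wa.n_cols;
  IntegerVector kdim = Wm.attr("kdim");
  const int kh = kdim[0], kw = kdim[1], kd = kdim[2];
  const int Ho = H - kh + 1, Wo = W - kw + 1, Do = D - kd + 1;
  const int P = Ho * Wo * Do, K = kh * kw * kd * C;
  NumericVector dx((size_t)H * W * D * C * B);
  dx.attr("dim") = xdim;
  arma::mat dW(K, F, arma::fill::zeros);
  arma::rowvec db(F, arma::fill::zeros);
  arma::mat col(P, K), dcol(P, K);
  const size_t xstride = (size_t)H * W * D * C;
  for (int s = 0; s < B; ++s) {
    im2col(x.begin() + s * xstride, H, W, D, C, kh, kw, kd, col);
    const arma::mat dys(const_cast<double*>(dy.begin()) + (size_t)s * P * F,
                        P, F, false, true);
    dW += col.t() * dys;
    db += arma::sum(dys, 0);
    dcol = dys * Wa.t();
    // col2im scatter-add
    double* dxs = dx.begin() + s * xstride;
    for (int c = 0; c < C; ++c)
      for (int l = 0; l < kd; ++l)
        for (int j = 0; j < kw; ++j)
          for (int i = 0; i < kh; ++i) {
            const int k = i + kh * (j + kw * (l + kd * c));
            const double* src = dcol.colptr(k);
            for (int d0 = 0; d0 < Do; ++d0)
              for (int w0 = 0; w0 < Wo; ++w0) {
                double* dp =
                  dxs + (size_t)i + (size_t)H * ((w0 + j) + (size_t)W * ((d0 + l) + (size_t)D * c));
                const double* sp = src + (size_t)w0 * Ho + (size_t)d0 * Ho * Wo;
                for (int h0 = 0; h0 < Ho; ++h0) dp[h0] += sp[h0];
              }
          }
  }
  return List::create(_["dx"] = dx,
                      _["dW"] = NumericMatrix(K, F, dW.memptr()),
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Max pooling with stride = pool size, floor division of dims.
// [[Rcpp::export]]
List maxpool_fw_cpp(NumericVector x, IntegerVector xdim, IntegerVector pool) {
  const int H = xdim[0], W = xdim[1], D = xdim[2], C = xdim[3], B = xdim[4];
  const int ph = pool[0], pw = pool[1], pd = pool[2];
  const int Ho = H / ph, Wo = W / pw, Do = D / pd;
  const size_t n = (size_t)Ho * Wo * Do * C * B;
  NumericVector y(n);
  IntegerVector amax(n);  // 0-based linear index into x
  y.attr("dim") = IntegerVector::create(Ho, Wo, Do, C, B);
  size_t o = 0;
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < C; ++c)
      for (int d0 = 0; d0 < Do; ++d0)
        for (int w0 = 0; w0 < Wo; ++w0)
          for (int h0 = 0; h0 < Ho; ++h0) {
            double best = -std::numeric_limits<double>::infinity();
            size_t bi = 0;
            for (int l = 0; l < pd; ++l)
              for (int j = 0; j < pw; ++j)
                for (int i = 0; i < ph; ++i) {
                  const size_t xi = (size_t)(h0 * ph + i) +
                    (size_t)H * ((w0 * pw + j) +
                    (size_t)W * ((d0 * pd + l) +
                    (size_t)D * (c + (size_t)C * s)));
                  const double v = x[xi];
                  if (v > best) { best = v; bi = xi; }
                }
            y[o] = best;
            amax[o] = (int)bi;
            ++o;
          }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_cpp(NumericVector dy, IntegerVector amax,
                             IntegerVector xdim) {
  size_t n = 1;
  for (int i = 0; i < xdim.size(); ++i) n *= (size_t)xdim[i];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[amax[i]] += dy[i];
  return dx;
}
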