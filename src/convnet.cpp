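#include <Rcpp.h>
using namespace Rcpp;

// Minimal 2-D convolution primitives for the correction network.
// Tensor layout is column-major R arrays:
//   activations x: dim (H, W, C, N)
//   kernels    w: dim (kh, kw, Cin, Cout), odd kh/kw, stride 1, zero 'same' pad
// Plain loops; sizes here (<=64x64, <=64 channels) keep this well under a
// second per batch.


// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  int kh = dw[0], kw = dw[1], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch in conv2d_fwd");
  int ph = kh / 2, pw = kw / 2;
  NumericVector y((long)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const double *px = x.begin(), *pw_ = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double *yo = py + (long)H * W * (co + (long)Cout * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          yo[i + (long)H * j] = b[co];
      for (int ci = 0; ci < C; ++ci)
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            double wv = pw_[ki + kh * (kj + kw * (ci + Cin * co))];
            if (wv == 0.0) continue;
            int di = ki - ph, dj = kj - pw;
            int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            const double *xi = px + (long)H * W * (ci + (long)C * n);
            for (int j = j0; j < j1; ++j) {
              const double *xc = xi + (long)H * (j + dj) + di;
              double *yc = yo + (long)H * j;
              for (int i = i0; i < i1; ++i)
                yc[i] += wv * xc[i];
            }
          }
    }
  return y;
}

// gradient w.r.t. input: correlate gy with spatially flipped, transposed w
// [[Rcpp::export]]
NumericVector conv2d_bwd_input(NumericVector gy, NumericVector w) {
  IntegerVector dg = gy.attr("dim"), dw = w.attr("dim");
  int H = dg[0], W = dg[1], Cout = dg[2], N = dg[3];
  int kh = dw[0], kw = dw[1], Cin = dw[2];
  int ph = kh / 2, pw = kw / 2;
  NumericVector gx((long)H * W * Cin * N);
  gx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  const double *pg = gy.begin(), *pw_ = w.begin();
  double *px = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int ci = 0; ci < Cin; ++ci) {
      double *xo = px + (long)H * W * (ci + (long)Cin * n);
      for (int co = 0; co < Cout; ++co)
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            double wv = pw_[ki + kh * (kj + kw * (ci + Cin * co))];
            if (wv == 0.0) continue;
            // y[i] received x[i + di]; so x[i'] receives gy[i' - di]
            int di = ki - ph, dj = kj - pw;
            int i0 = std::max(0, di), i1 = std::min(H, H + di);
            int j0 = std::max(0, dj), j1 = std::min(W, W + dj);
            const double *gi = pg + (long)H * W * (co + (long)Cout * n);
            for (int j = j0; j < j1; ++j) {
              const double *gc = gi + (long)H * (j - dj) - di;
              double *xc = xo + (long)H * j;
              for (int i = i0; i < i1; ++i)
                xc[i] += wv * gc[i];
            }
          }
    }
  return gx;
}

// gradients w.r.t. kernel and bias
// [[Rcpp::export]]
List conv2d_bwd_params(NumericVector x, NumericVector gy,
                       IntegerVector kdim) {
  IntegerVector dx = x.attr("dim"), dg = gy.attr("dim");
  int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  int Cout = dg[2];
  int kh = kdim[0], kw = kdim[1];
  int ph = kh / 2, pw = kw / 2;
  NumericVector gw((long)kh * kw * Cin * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  NumericVector gb(Cout);
  const double *px = x.begin(), *pg = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double *gi = pg + (long)H * W * (co + (long)Cout * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          gb[co] += gi[i + (long)H * j];
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xi = px + (long)H * W * (ci + (long)Cin * n);
        for (int kj = 0; kj < kw; ++kj)
          for (int ki = 0; ki < kh; ++ki) {
            int di = ki - ph, dj = kj - pw;
            int i0 = std::max(0, -di), i1 = std::min(H, H - di);
            int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
            double acc = 0.0;
            for (int j = j0; j < j1; ++j) {
              const double *xc = xi + (long)H * (j + dj) + di;
              const double *gc = gi + (long)H * j;
              for (int i = i0; i < i1; ++i)
                acc += xc[i] * gc[i];
            }
            gw[ki + kh * (kj + kw * (ci + Cin * co))] += acc;
          }
      }
    }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}
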