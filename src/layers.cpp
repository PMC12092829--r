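// GEMM-based building blocks for the scanning U-Net.
//
// All tensors are R arrays in column-major (H, W, C, N) layout: H image rows,
// W image columns, C channels, N batch sections.  Convolution weights for a
// KxK kernel are R arrays (K, K, Cin, Cout), addressed as a (K*K*Cin, Cout)
// matrix; the im2col column order (kh fastest, then kw, then channel) matches
// that flattening.  Only stride-1 same-padding convolutions and 2x2 ops are
// needed by the architecture.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4D (H,W,C,N) array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill the im2col matrix M (N*H*W rows, K*K*Cin cols) from x with zero
// padding.  The valid vertical span is copied contiguously; only the
// padding fringe is handled element-free (zero fill), which keeps the loop
// memcpy-bound rather than branch-bound.
static void im2col(const double* x, int H, int W, int C, int N, int K, int pad,
                   arma::mat& M) {
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (long)n * HW * C;
    const long row0 = (long)n * HW;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + (long)c * HW;
      for (int kw = 0; kw < K; ++kw) {
        for (int kh = 0; kh < K; ++kh) {
          const int col = kh + K * kw + K * K * c;
          double* Mcol = M.colptr(col) + row0;
          const int dh = kh - pad;            // source row offset
          const int i0 = std::max(0, -dh);    // valid output rows [i0, i1)
          const int i1 = std::min(H, H - dh);
          for (int j = 0; j < W; ++j) {
            const int sj = j + kw - pad;
            double* Mj = Mcol + (long)j * H;
            if (sj < 0 || sj >= W) {
              std::fill(Mj, Mj + H, 0.0);
              continue;
            }
            const double* xj = xc + (long)sj * H;
            if (i0 > 0) std::fill(Mj, Mj + i0, 0.0);
            std::copy(xj + i0 + dh, xj + i1 + dh, Mj + i0);
            if (i1 < H) std::fill(Mj + i1, Mj + H, 0.0);
          }
        }
      }
    }
  }
}

// Scatter-accumulate the im2col gradient back onto the padded input grid.
static void col2im(const arma::mat& dM, int H, int W, int C, int N, int K,
                   int pad, double* dx) {
  const long HW = (long)H * W;
  for (int n = 0; n < N; ++n) {
    double* dxn = dx + (long)n * HW * C;
    const long row0 = (long)n * HW;
    for (int c = 0; c < C; ++c) {
      double* dxc = dxn + (long)c * HW;
      for (int kw = 0; kw < K; ++kw) {
        for (int kh = 0; kh < K; ++kh) {
          const int col = kh + K * kw + K * K * c;
          const double* Mcol = dM.colptr(col) + row0;
          const int dh = kh - pad;
          const int i0 = std::max(0, -dh);
          const int i1 = std::min(H, H - dh);
          for (int j = 0; j < W; ++j) {
            const int sj = j + kw - pad;
            if (sj < 0 || sj >= W) continue;
            const double* Mj = Mcol + (long)j * H;
            double* dxj = dxc + (long)sj * H + dh;
            for (int i = i0; i < i1; ++i) dxj[i] += Mj[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericMatrix w, NumericVector b,
                             int K) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int pad = (K - 1) / 2;
  const int Cout = w.ncol();
  if (w.nrow() != K * K * C) stop("weight/input channel mismatch");
  const long HW = (long)H * W;

  arma::mat M((long)N * HW, (long)K * K * C);
  im2col(REAL(x), H, W, C, N, K, pad, M);
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat Y = M * Wm;
  Y.each_row() += arma::rowvec(b.begin(), Cout, false);

  NumericVector y((long)N * HW * Cout);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  double* yp = REAL(y);
  for (int co = 0; co < Cout; ++co) {
    const double* Ycol = Y.colptr(co);
    for (int n = 0; n < N; ++n)
      std::copy(Ycol + (long)n * HW, Ycol + (long)(n + 1) * HW,
                yp + (long)n * HW * Cout + (long)co * HW);
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericMatrix w, NumericVector dy,
                     int K) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int pad = (K - 1) / 2;
  const int Cout = w.ncol();
  const long HW = (long)H * W;

  arma::mat M((long)N * HW, (long)K * K * C);
  im2col(REAL(x), H, W, C, N, K, pad, M);

  arma::mat dY((long)N * HW, Cout);
  const double* dyp = REAL(dy);
  for (int co = 0; co < Cout; ++co) {
    double* Dcol = dY.colptr(co);
    for (int n = 0; n < N; ++n)
      std::copy(dyp + (long)n * HW * Cout + (long)co * HW,
                dyp + (long)n * HW * Cout + (long)(co + 1) * HW,
                Dcol + (long)n * HW);
  }

  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dWm = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * Wm.t();

  NumericVector dx((long)N * HW * C);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im(dM, H, W, C, N, K, pad, REAL(dx));

  NumericMatrix dw(w.nrow(), w.ncol());
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  NumericVector dbv(Cout);
  std::copy(db.begin(), db.end(), dbv.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = dbv);
}

// 2x2 max pooling, stride 2.  Argmax code di + 2*dj recorded for backprop;
// ties resolved by the fixed scan order (0,0),(1,0),(0,1),(1,1).
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 requires even H and W");
  const int Ho = H / 2, Wo = W / 2;
  const long n_out = (long)Ho * Wo * C * N;
  NumericVector y(n_out);
  IntegerVector idx(n_out);
  y.attr("dim") = idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    const double* xc = xp + cn * H * W;
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i, ++o) {
        double best = xc[(2 * i) + (long)(2 * j) * H];
        int code = 0;
        const int offs[4][2] = {{0, 0}, {1, 0}, {0, 1}, {1, 1}};
        for (int k = 1; k < 4; ++k) {
          double v = xc[(2 * i + offs[k][0]) + (long)(2 * j + offs[k][1]) * H];
          if (v > best) { best = v; code = offs[k][0] + 2 * offs[k][1]; }
        }
        yp[o] = best;
        ip[o] = code;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector dy, IntegerVector idx) {
  int d[4];
  IntegerVector dm = dy.attr("dim");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = 2 * Ho, W = 2 * Wo;
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  double* dxp = REAL(dx);
  long o = 0;
  for (long cn = 0; cn < (long)C * N; ++cn) {
    double* dxc = dxp + cn * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i, ++o) {
        const int di = ip[o] % 2, dj = ip[o] / 2;
        dxc[(2 * i + di) + (long)(2 * j + dj) * H] += dyp[o];
      }
  }
  return dx;
}

// Transposed 2x2 convolution, stride 2 ("deconvolution" upsampling).
// Weight layout (2, 2, Cin, Cout); output (2H, 2W, Cout, N).
// [[Rcpp::export(name = ".upconv2_forward")]]
NumericVector upconv2_forward(NumericVector x, NumericVector w,
                              NumericVector b) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 4 || wd[0] != 2 || wd[1] != 2 || wd[2] != C)
    stop("upconv weight must be (2,2,Cin,Cout)");
  const int Cout = wd[3];
  const long HW = (long)H * W;
  NumericVector y((long)4 * HW * Cout * N);
  y.attr("dim") = IntegerVector::create(2 * H, 2 * W, Cout, N);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  const double* wp = REAL(w);

  // gather per-offset weight matrices Wd (Cin x Cout)
  for (int kw = 0; kw < 2; ++kw) {
    for (int kh = 0; kh < 2; ++kh) {
      arma::mat Wd(C, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          Wd(ci, co) = wp[kh + 2 * kw + 4 * ci + (long)4 * C * co];
      for (int n = 0; n < N; ++n) {
        arma::mat Xn(const_cast<double*>(xp) + (long)n * HW * C, HW, C, false);
        arma::mat Yd = Xn * Wd;
        for (int co = 0; co < Cout; ++co) {
          const double* Ycol = Yd.colptr(co);
          double* yc = yp + (long)n * 4 * HW * Cout + (long)co * 4 * HW;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              yc[(2 * i + kh) + (long)(2 * j + kw) * 2 * H] =
                  Ycol[i + (long)j * H] + b[co];
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export(name = ".upconv2_backward")]]
List upconv2_backward(NumericVector x, NumericVector w, NumericVector dy) {
  int d[4]; get_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector wd = w.attr("dim");
  const int Cout = wd[3];
  const long HW = (long)H * W;
  const double* xp = REAL(x);
  const double* wp = REAL(w);
  const double* dyp = REAL(dy);

  NumericVector dx((long)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((long)4 * C * Cout);
  dw.attr("dim") = IntegerVector::create(2, 2, C, Cout);
  NumericVector db(Cout);
  double* dxp = REAL(dx);
  double* dwp = REAL(dw);

  for (int kw = 0; kw < 2; ++kw) {
    for (int kh = 0; kh < 2; ++kh) {
      arma::mat Wd(C, Cout);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          Wd(ci, co) = wp[kh + 2 * kw + 4 * ci + (long)4 * C * co];
      arma::mat dWd(C, Cout, arma::fill::zeros);
      for (int n = 0; n < N; ++n) {
        arma::mat dYd(HW, Cout);
        for (int co = 0; co < Cout; ++co) {
          const double* yc = dyp + (long)n * 4 * HW * Cout + (long)co * 4 * HW;
          double* Dcol = dYd.colptr(co);
          double acc = 0.0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = yc[(2 * i + kh) + (long)(2 * j + kw) * 2 * H];
              Dcol[i + (long)j * H] = g;
              acc += g;
            }
          db[co] += acc;
        }
        arma::mat Xn(const_cast<double*>(xp) + (long)n * HW * C, HW, C, false);
        arma::mat dXn(dxp + (long)n * HW * C, HW, C, false, true);
        dXn += dYd * Wd.t();
        dWd += Xn.t() * dYd;
      }
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < C; ++ci)
          dwp[kh + 2 * kw + 4 * ci + (long)4 * C * co] = dWd(ci, co);
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
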