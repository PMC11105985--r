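// 3x3 same-size convolution with zero padding on (H, W, B, C) feature maps.
// Hot path of the generator: im2col + BLAS dgemm. Layout is R column-major;
// patch columns are ordered (di, dj, ci) to match the (3, 3, C, Cout) kernel.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// fill the im2col matrix P (HWB x 9C), zero-padded shifts of x
static void im2col3(const double *xp, double *P, int H, int W, int B, int C) {
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  const R_xlen_t rows = plane * B;
  R_xlen_t col = 0;
  for (int ci = 0; ci < C; ++ci) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di, ++col) {
        const int oi = di - 1, oj = dj - 1;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        double *__restrict Pc = P + col * rows;
        std::fill(Pc, Pc + rows, 0.0);
        for (int b = 0; b < B; ++b) {
          const double *__restrict xb = xp + plane * (b + static_cast<R_xlen_t>(B) * ci);
          double *__restrict Pb = Pc + plane * b;
          for (int j = j0; j < j1; ++j) {
            const double *__restrict xc = xb + static_cast<R_xlen_t>(j + oj) * H + oi;
            double *__restrict Pj = Pb + static_cast<R_xlen_t>(j) * H;
            for (int i = i0; i < i1; ++i) Pj[i] = xc[i];
          }
        }
      }
    }
  }
}

// scatter-accumulate the im2col gradient back onto the input grid
static void col2im3(const double *dP, double *dx, int H, int W, int B, int C) {
  const R_xlen_t plane = static_cast<R_xlen_t>(H) * W;
  const R_xlen_t rows = plane * B;
  R_xlen_t col = 0;
  for (int ci = 0; ci < C; ++ci) {
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di, ++col) {
        const int oi = di - 1, oj = dj - 1;
        const int i0 = std::max(0, -oi), i1 = std::min(H, H - oi);
        const int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
        const double *__restrict Pc = dP + col * rows;
        for (int b = 0; b < B; ++b) {
          double *__restrict xb = dx + plane * (b + static_cast<R_xlen_t>(B) * ci);
          const double *__restrict Pb = Pc + plane * b;
          for (int j = j0; j < j1; ++j) {
            double *__restrict xc = xb + static_cast<R_xlen_t>(j + oj) * H + oi;
            const double *__restrict Pj = Pb + static_cast<R_xlen_t>(j) * H;
            for (int i = i0; i < i1; ++i) xc[i] += Pj[i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericVector w,
                            int H, int W, int B, int C, int Cout) {
  const int m = H * W * B, k = 9 * C;
  NumericVector y(static_cast<R_xlen_t>(m) * Cout);
  std::vector<double> P(static_cast<R_xlen_t>(m) * k);
  im2col3(x.begin(), P.data(), H, W, B, C);
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &Cout, &k, &one, P.data(), &m,
                  w.begin(), &k, &zero, y.begin(), &m FCONE FCONE);
  y.attr("dim") = IntegerVector::create(H, W, B, Cout);
  return y;
}

// [[Rcpp::export]]
NumericVector conv3_bwd_x_cpp(NumericVector g, NumericVector w,
                              int H, int W, int B, int C, int Cout) {
  const int m = H * W * B, k = 9 * C;
  NumericVector dx(static_cast<R_xlen_t>(m) * C);
  std::vector<double> dP(static_cast<R_xlen_t>(m) * k);
  const double one = 1.0, zero = 0.0;
  // dP = g %*% t(W): (m x Cout) (Cout x k)
  F77_CALL(dgemm)("N", "T", &m, &k, &Cout, &one, g.begin(), &m,
                  w.begin(), &k, &zero, dP.data(), &m FCONE FCONE);
  col2im3(dP.data(), dx.begin(), H, W, B, C);
  dx.attr("dim") = IntegerVector::create(H, W, B, C);
  return dx;
}

// [[Rcpp::export]]
NumericVector conv3_bwd_w_cpp(NumericVector g, NumericVector x,
                              int H, int W, int B, int C, int Cout) {
  const int m = H * W * B, k = 9 * C;
  NumericVector dw(static_cast<R_xlen_t>(k) * Cout);
  std::vector<double> P(static_cast<R_xlen_t>(m) * k);
  im2col3(x.begin(), P.data(), H, W, B, C);
  const double one = 1.0, zero = 0.0;
  // dW = t(P) %*% g: (k x m) (m x Cout)
  F77_CALL(dgemm)("T", "N", &k, &Cout, &m, &one, P.data(), &m,
                  g.begin(), &m, &zero, dw.begin(), &k FCONE FCONE);
  dw.attr("dim") = IntegerVector::create(3, 3, C, Cout);
  return dw;
}
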