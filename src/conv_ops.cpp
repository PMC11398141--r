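// Low-level tensor kernels for the segmentation network.
//
// Feature maps are R arrays with dim c(H, W, N, C): every (n, c) image plane
// is a contiguous H*W block and every channel block (all batch items of one
// channel) is a contiguous H*W*N block.  Convolutions are computed as
// im2col gathers followed by BLAS matrix products; the im2col matrix is laid
// out (H*W*N) x (k*k*Cg) so that both the gather and the GEMM operands are
// contiguous.  A single-precision path exists for training throughput; the
// default double path is used everywhere accuracy is asserted.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector y((R_xlen_t)a * b * c * d);
  y.attr("dim") = IntegerVector::create(a, b, c, d);
  return y;
}

static void get_dim4(const NumericVector &x, int d[4], const char *what) {
  SEXP a = x.attr("dim");
  if (Rf_isNull(a)) stop("%s must be a 4-d array", what);
  IntegerVector dv(a);
  if (dv.size() != 4) stop("%s must be a 4-d array, got %d dims", what, (int)dv.size());
  for (int i = 0; i < 4; ++i) d[i] = dv[i];
}

// ---------------------------------------------------------------------------
// im2col / col2im on the (H, W, N, C) layout
// ---------------------------------------------------------------------------

template <class MAT>
static void im2col_t(const typename MAT::elem_type *x, int H, int W, int N,
                     int Cg, long cin0, int k, int dil, int pad, MAT &Mt) {
  typedef typename MAT::elem_type eT;
  const long HW = (long)H * W, HWN = HW * N;
  Mt.zeros();
  for (int ci = 0; ci < Cg; ++ci) {
    const eT *xc = x + (cin0 + ci) * HWN;
    for (int kj = 0; kj < k; ++kj) {
      const int dw = kj * dil - pad;
      const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
      for (int ki = 0; ki < k; ++ki) {
        const int dh = ki * dil - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        eT *col = Mt.colptr((long)(ci * k + kj) * k + ki);
        if (h1 <= h0 || w1 <= w0) continue;
        for (int n = 0; n < N; ++n) {
          const eT *xn = xc + (long)n * HW;
          eT *cn = col + (long)n * HW;
          for (int w = w0; w < w1; ++w) {
            const eT *src = xn + (long)(w + dw) * H + (h0 + dh);
            std::copy(src, src + (h1 - h0), cn + (long)w * H + h0);
          }
        }
      }
    }
  }
}

template <class MAT>
static void col2im_t(const MAT &Gt, typename MAT::elem_type *gx, int H, int W,
                     int N, int Cg, long cin0, int k, int dil, int pad) {
  typedef typename MAT::elem_type eT;
  const long HW = (long)H * W, HWN = HW * N;
  for (int ci = 0; ci < Cg; ++ci) {
    eT *xc = gx + (cin0 + ci) * HWN;
    for (int kj = 0; kj < k; ++kj) {
      const int dw = kj * dil - pad;
      const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
      for (int ki = 0; ki < k; ++ki) {
        const int dh = ki * dil - pad;
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const eT *col = Gt.colptr((long)(ci * k + kj) * k + ki);
        if (h1 <= h0 || w1 <= w0) continue;
        for (int n = 0; n < N; ++n) {
          eT *xn = xc + (long)n * HW;
          const eT *cn = col + (long)n * HW;
          for (int w = w0; w < w1; ++w) {
            eT *dst = xn + (long)(w + dw) * H + (h0 + dh);
            const eT *src = cn + (long)w * H + h0;
            for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// conv2d, stride 1, optional dilation and channel groups
// ---------------------------------------------------------------------------

template <class MAT, class COL>
static void conv2d_fw_t(const typename MAT::elem_type *x,
                        const typename MAT::elem_type *w,
                        const double *bias, typename MAT::elem_type *y, int H,
                        int W, int N, int Cin, int Cout, int k, int dil,
                        int pad, int groups) {
  typedef typename MAT::elem_type eT;
  const long HWN = (long)H * W * N;
  const int Cg = Cin / groups, CoutG = Cout / groups;
  const long kkC = (long)k * k * Cg;
  const bool pointwise = (k == 1 && groups == 1);
  MAT Mt;
  if (!pointwise) Mt.set_size(HWN, kkC);
  for (int g = 0; g < groups; ++g) {
    const MAT Wm(const_cast<eT *>(w) + (long)g * CoutG * kkC, kkC, CoutG,
                 false, true);
    MAT Yv(y + (long)g * CoutG * HWN, HWN, CoutG, false, true);
    if (pointwise) {
      const MAT Xv(const_cast<eT *>(x), HWN, Cin, false, true);
      Yv = Xv * Wm;
    } else {
      im2col_t(x, H, W, N, Cg, (long)g * Cg, k, dil, pad, Mt);
      Yv = Mt * Wm;
    }
    if (bias) {
      for (int co = 0; co < CoutG; ++co)
        Yv.col(co) += (eT)bias[g * CoutG + co];
    }
  }
}

template <class MAT>
static void conv2d_bw_t(const typename MAT::elem_type *x,
                        const typename MAT::elem_type *w,
                        const typename MAT::elem_type *gy,
                        typename MAT::elem_type *gx,
                        typename MAT::elem_type *gw, double *gb, int H, int W,
                        int N, int Cin, int Cout, int k, int dil, int pad,
                        int groups) {
  typedef typename MAT::elem_type eT;
  const long HWN = (long)H * W * N;
  const int Cg = Cin / groups, CoutG = Cout / groups;
  const long kkC = (long)k * k * Cg;
  const bool pointwise = (k == 1 && groups == 1);
  MAT Mt, Gt;
  if (!pointwise) {
    Mt.set_size(HWN, kkC);
    Gt.set_size(HWN, kkC);
  }
  for (int g = 0; g < groups; ++g) {
    const MAT Wm(const_cast<eT *>(w) + (long)g * CoutG * kkC, kkC, CoutG,
                 false, true);
    const MAT Gy(const_cast<eT *>(gy) + (long)g * CoutG * HWN, HWN, CoutG,
                 false, true);
    MAT Gw(gw + (long)g * CoutG * kkC, kkC, CoutG, false, true);
    if (pointwise) {
      const MAT Xv(const_cast<eT *>(x), HWN, Cin, false, true);
      Gw = Xv.t() * Gy;
      MAT Gxv(gx, HWN, Cin, false, true);
      Gxv += Gy * Wm.t();
    } else {
      im2col_t(x, H, W, N, Cg, (long)g * Cg, k, dil, pad, Mt);
      Gw = Mt.t() * Gy;
      Gt = Gy * Wm.t();
      col2im_t(Gt, gx, H, W, N, Cg, (long)g * Cg, k, dil, pad);
    }
  }
  if (gb) {
    for (int co = 0; co < Cout; ++co) {
      const eT *b = gy + (long)co * HWN;
      double s = 0;
      for (long i = 0; i < HWN; ++i) s += b[i];
      gb[co] = s;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias, int k, int dil,
                                 int pad, int groups, bool single_prec) {
  int xd[4];
  get_dim4(x, xd, "x");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  if (Cin % groups != 0) stop("in_channels %d not divisible by groups %d", Cin, groups);
  const long wlen = w.size();
  const long kkC = (long)k * k * (Cin / groups);
  if (wlen % kkC != 0) stop("weight length inconsistent with kernel/channels");
  const int Cout = (int)(wlen / kkC);
  if (Cout % groups != 0) stop("out_channels %d not divisible by groups %d", Cout, groups);
  const double *bp = NULL;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = REAL(bv); }
  NumericVector y = alloc4(H, W, N, Cout);
  if (!single_prec) {
    conv2d_fw_t<arma::mat, arma::vec>(REAL(x), REAL(w), bp, REAL(y), H, W, N,
                                      Cin, Cout, k, dil, pad, groups);
  } else {
    arma::fvec xf(x.size()), wf(w.size()), yf((long)H * W * N * Cout);
    std::copy(x.begin(), x.end(), xf.begin());
    std::copy(w.begin(), w.end(), wf.begin());
    conv2d_fw_t<arma::fmat, arma::fvec>(xf.memptr(), wf.memptr(), bp,
                                        yf.memptr(), H, W, N, Cin, Cout, k,
                                        dil, pad, groups);
    std::copy(yf.begin(), yf.end(), y.begin());
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         bool has_bias, int k, int dil, int pad, int groups,
                         bool single_prec) {
  int xd[4], gd[4];
  get_dim4(x, xd, "x");
  get_dim4(gy, gd, "gy");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3], Cout = gd[3];
  NumericVector gx = alloc4(H, W, N, Cin);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb;
  double *gbp = NULL;
  if (has_bias) { gb = NumericVector(Cout); gbp = REAL(gb); }
  if (!single_prec) {
    conv2d_bw_t<arma::mat>(REAL(x), REAL(w), REAL(gy), REAL(gx), REAL(gw), gbp,
                           H, W, N, Cin, Cout, k, dil, pad, groups);
  } else {
    arma::fvec xf(x.size()), wf(w.size()), gyf(gy.size());
    arma::fvec gxf(gx.size(), arma::fill::zeros), gwf(gw.size(), arma::fill::zeros);
    std::copy(x.begin(), x.end(), xf.begin());
    std::copy(w.begin(), w.end(), wf.begin());
    std::copy(gy.begin(), gy.end(), gyf.begin());
    conv2d_bw_t<arma::fmat>(xf.memptr(), wf.memptr(), gyf.memptr(),
                            gxf.memptr(), gwf.memptr(), gbp, H, W, N, Cin,
                            Cout, k, dil, pad, groups);
    std::copy(gxf.begin(), gxf.end(), gx.begin());
    std::copy(gwf.begin(), gwf.end(), gw.begin());
  }
  if (has_bias) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// ---------------------------------------------------------------------------
// 2x2 stride-2 transposed convolution (decoder upsampling)
// ---------------------------------------------------------------------------

template <class MAT>
static void convt_fw_t(const typename MAT::elem_type *x,
                       const typename MAT::elem_type *w, const double *bias,
                       typename MAT::elem_type *y, int H, int W, int N,
                       int Cin, int Cout) {
  typedef typename MAT::elem_type eT;
  const long HW = (long)H * W, HWN = HW * N;
  const int H2 = 2 * H, W2 = 2 * W;
  const long HW2 = (long)H2 * W2, HWN2 = HW2 * N;
  const MAT Xv(const_cast<eT *>(x), HWN, Cin, false, true);
  MAT Wtap(Cin, Cout), Ytap(HWN, Cout);
  for (int kj = 0; kj < 2; ++kj)
    for (int ki = 0; ki < 2; ++ki) {
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wtap(ci, co) = w[ki + 2 * kj + 4 * (ci + (long)Cin * co)];
      Ytap = Xv * Wtap;
      for (int co = 0; co < Cout; ++co) {
        const eT b = bias ? (eT)bias[co] : (eT)0;
        const eT *src = Ytap.colptr(co);
        eT *yc = y + (long)co * HWN2;
        for (int n = 0; n < N; ++n)
          for (int ww = 0; ww < W; ++ww) {
            const eT *s = src + (long)n * HW + (long)ww * H;
            eT *d = yc + (long)n * HW2 + (long)(2 * ww + kj) * H2 + ki;
            for (int h = 0; h < H; ++h) d[2 * h] = s[h] + b;
          }
      }
    }
}

template <class MAT>
static void convt_bw_t(const typename MAT::elem_type *x,
                       const typename MAT::elem_type *w,
                       const typename MAT::elem_type *gy,
                       typename MAT::elem_type *gx,
                       typename MAT::elem_type *gw, double *gb, int H, int W,
                       int N, int Cin, int Cout) {
  typedef typename MAT::elem_type eT;
  const long HW = (long)H * W, HWN = HW * N;
  const int H2 = 2 * H, W2 = 2 * W;
  const long HW2 = (long)H2 * W2, HWN2 = HW2 * N;
  const MAT Xv(const_cast<eT *>(x), HWN, Cin, false, true);
  MAT Gxv(gx, HWN, Cin, false, true);
  MAT Wtap(Cin, Cout), Gtap(HWN, Cout), Gwtap(Cin, Cout);
  for (int kj = 0; kj < 2; ++kj)
    for (int ki = 0; ki < 2; ++ki) {
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          Wtap(ci, co) = w[ki + 2 * kj + 4 * (ci + (long)Cin * co)];
      for (int co = 0; co < Cout; ++co) {
        eT *dst = Gtap.colptr(co);
        const eT *gc = gy + (long)co * HWN2;
        for (int n = 0; n < N; ++n)
          for (int ww = 0; ww < W; ++ww) {
            eT *d = dst + (long)n * HW + (long)ww * H;
            const eT *s = gc + (long)n * HW2 + (long)(2 * ww + kj) * H2 + ki;
            for (int h = 0; h < H; ++h) d[h] = s[2 * h];
          }
      }
      Gwtap = Xv.t() * Gtap;
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          gw[ki + 2 * kj + 4 * (ci + (long)Cin * co)] = Gwtap(ci, co);
      Gxv += Gtap * Wtap.t();
    }
  if (gb) {
    for (int co = 0; co < Cout; ++co) {
      const eT *b = gy + (long)co * HWN2;
      double s = 0;
      for (long i = 0; i < HWN2; ++i) s += b[i];
      gb[co] = s;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_convt2x2_forward(NumericVector x, NumericVector w,
                                   Nullable<NumericVector> bias,
                                   bool single_prec) {
  int xd[4];
  get_dim4(x, xd, "x");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  const int Cout = (int)(w.size() / (4L * Cin));
  const double *bp = NULL;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = REAL(bv); }
  NumericVector y = alloc4(2 * H, 2 * W, N, Cout);
  if (!single_prec) {
    convt_fw_t<arma::mat>(REAL(x), REAL(w), bp, REAL(y), H, W, N, Cin, Cout);
  } else {
    arma::fvec xf(x.size()), wf(w.size()), yf(y.size());
    std::copy(x.begin(), x.end(), xf.begin());
    std::copy(w.begin(), w.end(), wf.begin());
    convt_fw_t<arma::fmat>(xf.memptr(), wf.memptr(), bp, yf.memptr(), H, W, N,
                           Cin, Cout);
    std::copy(yf.begin(), yf.end(), y.begin());
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2x2_backward(NumericVector x, NumericVector w, NumericVector gy,
                           bool has_bias, bool single_prec) {
  int xd[4], gd[4];
  get_dim4(x, xd, "x");
  get_dim4(gy, gd, "gy");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3], Cout = gd[3];
  NumericVector gx = alloc4(H, W, N, Cin);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb;
  double *gbp = NULL;
  if (has_bias) { gb = NumericVector(Cout); gbp = REAL(gb); }
  if (!single_prec) {
    convt_bw_t<arma::mat>(REAL(x), REAL(w), REAL(gy), REAL(gx), REAL(gw), gbp,
                          H, W, N, Cin, Cout);
  } else {
    arma::fvec xf(x.size()), wf(w.size()), gyf(gy.size());
    arma::fvec gxf(gx.size(), arma::fill::zeros), gwf(gw.size(), arma::fill::zeros);
    std::copy(x.begin(), x.end(), xf.begin());
    std::copy(w.begin(), w.end(), wf.begin());
    std::copy(gy.begin(), gy.end(), gyf.begin());
    convt_bw_t<arma::fmat>(xf.memptr(), wf.memptr(), gyf.memptr(),
                           gxf.memptr(), gwf.memptr(), gbp, H, W, N, Cin,
                           Cout);
    std::copy(gxf.begin(), gxf.end(), gx.begin());
    std::copy(gwf.begin(), gwf.end(), gw.begin());
  }
  if (has_bias) return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// ---------------------------------------------------------------------------
// 2x2 stride-2 max pooling
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  int xd[4];
  get_dim4(x, xd, "x");
  const int H = xd[0], W = xd[1], N = xd[2], C = xd[3];
  if (H % 2 != 0 || W % 2 != 0)
    stop("max pooling needs even spatial dims, got %d x %d", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, N, C);
  IntegerVector amax(y.size());
  const double *xp = REAL(x);
  double *yp = REAL(y);
  int *ap = INTEGER(amax);
  const long HW = (long)H * W;
  long o = 0;
  for (long p = 0; p < (long)N * C; ++p) {
    const double *plane = xp + p * HW;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const long i00 = (long)(2 * w) * H + 2 * h;
        long best = i00;
        double v = plane[i00];
        if (plane[i00 + 1] > v) { v = plane[i00 + 1]; best = i00 + 1; }
        if (plane[i00 + H] > v) { v = plane[i00 + H]; best = i00 + H; }
        if (plane[i00 + H + 1] > v) { v = plane[i00 + H + 1]; best = i00 + H + 1; }
        yp[o] = v;
        ap[o] = (int)(p * HW + best);
        ++o;
      }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector amax,
                                    IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  double *gp = REAL(gx);
  const double *gyp = REAL(gy);
  const int *ap = INTEGER(amax);
  const long n = gy.size();
  for (long i = 0; i < n; ++i) gp[ap[i]] += gyp[i];
  return gx;
}

// ---------------------------------------------------------------------------
// elementwise activations
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector y, NumericVector gy) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double *yp = REAL(y), *gp = REAL(gy);
  double *op = REAL(gx);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = yp[i] > 0 ? gp[i] : 0.0;
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_elu_forward(NumericVector x, double alpha) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    yp[i] = xp[i] > 0 ? xp[i] : alpha * (std::exp(xp[i]) - 1.0);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_backward(NumericVector y, NumericVector gy, double alpha) {
  NumericVector gx(gy.size());
  gx.attr("dim") = gy.attr("dim");
  const double *yp = REAL(y), *gp = REAL(gy);
  double *op = REAL(gx);
  const R_xlen_t n = gy.size();
  for (R_xlen_t i = 0; i < n; ++i)
    op[i] = yp[i] >= 0 ? gp[i] : gp[i] * (yp[i] + alpha);
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_sigmoid_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = REAL(x);
  double *yp = REAL(y);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = 1.0 / (1.0 + std::exp(-xp[i]));
  return y;
}

// ---------------------------------------------------------------------------
// fused convolution + batch norm + activation unit (the conv1/conv2 blocks)
//
// The convolution is computed as k*k GEMMs on shifted views of a zero-padded
// input buffer (no im2col materialisation, no col2im scatter): contributions
// that fall outside the valid region land in the padding of the padded output
// accumulator and are simply never read. The padded input and the normalised
// pre-activation are cached between forward and backward of a training step,
// and the cache buffers are reused across steps.
// ---------------------------------------------------------------------------

// locally named declarations aliased to the BLAS symbols, so they cannot
// clash with Armadillo's own prototypes
extern "C" {
void rh_dgemm(const char *, const char *, const int *, const int *,
              const int *, const double *, const double *, const int *,
              const double *, const int *, const double *, double *,
              const int *) __asm__("dgemm_");
void rh_sgemm(const char *, const char *, const int *, const int *,
              const int *, const float *, const float *, const int *,
              const float *, const int *, const float *, float *,
              const int *) __asm__("sgemm_");
}

static inline void blas_gemm(char ta, char tb, int m, int n, int k,
                             double alpha, const double *A, int lda,
                             const double *B, int ldb, double beta, double *C,
                             int ldc) {
  rh_dgemm(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}
static inline void blas_gemm(char ta, char tb, int m, int n, int k,
                             float alpha, const float *A, int lda,
                             const float *B, int ldb, float beta, float *C,
                             int ldc) {
  rh_sgemm(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

template <class MAT, class VEC> struct UnitCache {
  VEC xp;          // zero-padded input, (Hp*Wp*N) x Cin  (k > 1)
  VEC xf;          // converted input (kept only when k == 1)
  MAT xhat;        // normalised pre-activation, (HWN) x Cout
  arma::vec mean, inv;
  int H, W, N, Cin, Cout, k, dil, pad, Hp, Wp;
};
typedef UnitCache<arma::fmat, arma::fvec> UnitCacheF;
typedef UnitCache<arma::mat, arma::vec> UnitCacheD;

// copy a compact (H, W, N, C) buffer into the valid region of a padded
// (Hp, Wp, N, C) buffer (which must already be zeroed), or back
template <typename eT, typename sT>
static void pad_copy(const sT *src, eT *dst, int H, int W, int N, int C,
                     int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const long HW = (long)H * W, HpWp = (long)Hp * Wp;
  for (long pc = 0; pc < (long)N * C; ++pc) {
    const sT *sp = src + pc * HW;
    eT *dp = dst + pc * HpWp + p * Hp + p;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) dp[(long)w * Hp + h] = (eT)sp[(long)w * H + h];
  }
}

template <typename eT, typename sT>
static void unpad_copy(const sT *src, eT *dst, int H, int W, int N, int C,
                       int p) {
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const long HW = (long)H * W, HpWp = (long)Hp * Wp;
  for (long pc = 0; pc < (long)N * C; ++pc) {
    const sT *sp = src + pc * HpWp + p * Hp + p;
    eT *dp = dst + pc * HW;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) dp[(long)w * H + h] = (eT)sp[(long)w * Hp + h];
  }
}

// extract tap (ki, kj) of the (k, k, Cin, Cout) weight array as (Cin x Cout)
template <typename eT>
static void tap_weights(const double *w, int k, int Cin, int Cout, int ki,
                        int kj, eT *out) {
  const long kk = (long)k * k;
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      out[ci + (long)Cin * co] = (eT)w[ki + k * kj + kk * (ci + (long)Cin * co)];
}

template <class MAT, class VEC>
static List convunit_fw(NumericVector x, NumericVector w, NumericVector gamma,
                        NumericVector beta, NumericVector rmean,
                        NumericVector rvar, double eps, double momentum,
                        bool training, int act, double alpha, int k, int dil,
                        int pad, bool keep_cache, SEXP cache_in) {
  typedef typename MAT::elem_type eT;
  int xd[4];
  get_dim4(x, xd, "x");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  const long HWN = (long)H * W * N;
  const long kkC = (long)k * k * Cin;
  const int Cout = (int)(w.size() / kkC);
  if (k > 1 && 2 * pad != dil * (k - 1))
    stop("conv unit requires the shape-preserving padding dil*(k-1)/2");

  // reuse the cache buffers across steps to avoid large alloc/free churn
  XPtr<UnitCache<MAT, VEC> > ptr =
      (cache_in != R_NilValue)
          ? XPtr<UnitCache<MAT, VEC> >(cache_in)
          : XPtr<UnitCache<MAT, VEC> >(new UnitCache<MAT, VEC>(), true);
  UnitCache<MAT, VEC> *uc = ptr.get();
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  const long Rp = (long)Hp * Wp * N;
  uc->H = H; uc->W = W; uc->N = N; uc->Cin = Cin; uc->Cout = Cout;
  uc->k = k; uc->dil = dil; uc->pad = pad; uc->Hp = Hp; uc->Wp = Wp;

  MAT Z;               // compact (HWN x Cout) pre-normalisation output
  if (k == 1) {
    uc->xf.set_size(x.size());
    std::copy(x.begin(), x.end(), uc->xf.begin());
    VEC wf(w.size());
    std::copy(w.begin(), w.end(), wf.begin());
    const MAT Xm(uc->xf.memptr(), HWN, Cin, false, true);
    const MAT Wm(wf.memptr(), Cin, Cout, false, true);
    Z = Xm * Wm;
    if (!keep_cache) uc->xf.reset();
  } else {
    uc->xp.set_size(Rp * Cin);
    uc->xp.zeros();
    pad_copy(REAL(x), uc->xp.memptr(), H, W, N, Cin, pad);
    VEC Yp(Rp * Cout, arma::fill::zeros);
    VEC wtap(Cin * (long)Cout);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const long s = (long)(ki * dil - pad) + (long)Hp * (kj * dil - pad);
        const long r0 = s < 0 ? -s : 0;
        const long r1 = s > 0 ? Rp - s : Rp;
        if (r1 <= r0) continue;
        tap_weights(REAL(w), k, Cin, Cout, ki, kj, wtap.memptr());
        blas_gemm('N', 'N', (int)(r1 - r0), Cout, Cin, (eT)1,
                  uc->xp.memptr() + r0 + s, (int)Rp, wtap.memptr(), Cin,
                  (eT)1, Yp.memptr() + r0, (int)Rp);
      }
    }
    Z.set_size(HWN, Cout);
    unpad_copy(Yp.memptr(), Z.memptr(), H, W, N, Cout, pad);
    if (!keep_cache) uc->xp.reset();
  }

  NumericVector y = alloc4(H, W, N, Cout);
  double *yp = REAL(y);
  NumericVector new_rm(Cout), new_rv(Cout);
  arma::vec mean(Cout), inv(Cout);
  if (training) {
    uc->xhat.set_size(HWN, Cout);
  } else {
    uc->xhat.reset();
  }
  const double corr = HWN > 1 ? (double)HWN / (HWN - 1.0) : 1.0;
  for (int c = 0; c < Cout; ++c) {
    eT *zc = Z.colptr(c);
    double mu, va;
    if (training) {
      double s = 0;
      for (long i = 0; i < HWN; ++i) s += zc[i];
      mu = s / HWN;
      double sv = 0;
      for (long i = 0; i < HWN; ++i) {
        const double d = zc[i] - mu;
        sv += d * d;
      }
      va = sv / HWN;
      new_rm[c] = (1 - momentum) * rmean[c] + momentum * mu;
      new_rv[c] = (1 - momentum) * rvar[c] + momentum * va * corr;
    } else {
      mu = rmean[c];
      va = rvar[c];
      new_rm[c] = mu;
      new_rv[c] = va;
    }
    const double iv = 1.0 / std::sqrt(va + eps);
    mean[c] = mu; inv[c] = iv;
    const double g = gamma[c], b = beta[c];
    eT *xh = training ? uc->xhat.colptr(c) : NULL;
    double *yc = yp + (long)c * HWN;
    for (long i = 0; i < HWN; ++i) {
      const double xhi = (zc[i] - mu) * iv;
      if (xh) xh[i] = (eT)xhi;
      double v = g * xhi + b;
      if (act == 1) {
        v = v > 0 ? v : 0;
      } else if (act == 2) {
        v = v > 0 ? v : alpha * (std::exp(v) - 1.0);
      }
      yc[i] = v;
    }
  }
  uc->mean = mean;
  uc->inv = inv;
  return List::create(_["y"] = y, _["cache"] = ptr,
                      _["running_mean"] = new_rm, _["running_var"] = new_rv);
}

// [[Rcpp::export]]
List cpp_convunit_forward(NumericVector x, NumericVector w, NumericVector gamma,
                          NumericVector beta, NumericVector rmean,
                          NumericVector rvar, double eps, double momentum,
                          bool training, int act, double alpha, int k, int dil,
                          int pad, bool keep_cache, bool single_prec,
                          SEXP cache_in) {
  if (single_prec) {
    return convunit_fw<arma::fmat, arma::fvec>(x, w, gamma, beta, rmean, rvar,
                                               eps, momentum, training, act,
                                               alpha, k, dil, pad, keep_cache,
                                               cache_in);
  }
  return convunit_fw<arma::mat, arma::vec>(x, w, gamma, beta, rmean, rvar, eps,
                                           momentum, training, act, alpha, k,
                                           dil, pad, keep_cache, cache_in);
}

template <class MAT, class VEC>
static List convunit_bw(NumericVector y, NumericVector gy, NumericVector w,
                        NumericVector gamma, SEXP cache, int act, double alpha,
                        bool need_gx) {
  typedef typename MAT::elem_type eT;
  XPtr<UnitCache<MAT, VEC> > uc(cache);
  const int H = uc->H, W = uc->W, N = uc->N, Cin = uc->Cin, Cout = uc->Cout;
  const int k = uc->k, dil = uc->dil, pad = uc->pad;
  const int Hp = uc->Hp, Wp = uc->Wp;
  const long HWN = (long)H * W * N;
  const long Rp = (long)Hp * Wp * N;

  MAT G(HWN, Cout);
  const double *gp = REAL(gy), *yp = REAL(y);
  NumericVector ggamma(Cout), gbeta(Cout);
  for (int c = 0; c < Cout; ++c) {
    eT *gc = G.colptr(c);
    const double *gyc = gp + (long)c * HWN;
    const double *yc = yp + (long)c * HWN;
    const eT *xh = uc->xhat.colptr(c);
    // activation gradient
    if (act == 1) {
      for (long i = 0; i < HWN; ++i) gc[i] = yc[i] > 0 ? (eT)gyc[i] : (eT)0;
    } else if (act == 2) {
      for (long i = 0; i < HWN; ++i)
        gc[i] = yc[i] >= 0 ? (eT)gyc[i] : (eT)(gyc[i] * (yc[i] + alpha));
    } else {
      for (long i = 0; i < HWN; ++i) gc[i] = (eT)gyc[i];
    }
    // batch-norm gradient (per channel)
    double sg = 0, sgx = 0;
    for (long i = 0; i < HWN; ++i) {
      sg += gc[i];
      sgx += gc[i] * (double)xh[i];
    }
    ggamma[c] = sgx;
    gbeta[c] = sg;
    const double mg = sg / HWN, mgx = sgx / HWN;
    const double giv = gamma[c] * uc->inv[c];
    for (long i = 0; i < HWN; ++i) {
      gc[i] = (eT)(giv * ((double)gc[i] - mg - (double)xh[i] * mgx));
    }
  }

  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  List out;

  if (k == 1) {
    VEC wf(w.size());
    std::copy(w.begin(), w.end(), wf.begin());
    const MAT Xm(uc->xf.memptr(), HWN, Cin, false, true);
    const MAT Wm(wf.memptr(), Cin, Cout, false, true);
    MAT Gw = Xm.t() * G;
    std::copy(Gw.begin(), Gw.end(), gw.begin());
    if (need_gx) {
      NumericVector gx = alloc4(H, W, N, Cin);
      MAT Gx = G * Wm.t();
      std::copy(Gx.begin(), Gx.end(), REAL(gx));
      out = List::create(_["gx"] = gx, _["gw"] = gw, _["ggamma"] = ggamma,
                         _["gbeta"] = gbeta);
    } else {
      out = List::create(_["gw"] = gw, _["ggamma"] = ggamma,
                         _["gbeta"] = gbeta);
    }
    return out;
  }

  // padded gradient buffer; zero padding makes the shifted-view GEMMs exact
  VEC Gp(Rp * Cout, arma::fill::zeros);
  pad_copy(G.memptr(), Gp.memptr(), H, W, N, Cout, pad);
  VEC wtap(Cin * (long)Cout), gwtap(Cin * (long)Cout);
  VEC gxp;
  if (need_gx) gxp.zeros(Rp * Cin);
  double *gwp = REAL(gw);
  const long kk = (long)k * k;
  for (int kj = 0; kj < k; ++kj) {
    for (int ki = 0; ki < k; ++ki) {
      const long s = (long)(ki * dil - pad) + (long)Hp * (kj * dil - pad);
      const long r0 = s < 0 ? -s : 0;
      const long r1 = s > 0 ? Rp - s : Rp;
      if (r1 <= r0) continue;
      blas_gemm('T', 'N', Cin, Cout, (int)(r1 - r0), (eT)1,
                uc->xp.memptr() + r0 + s, (int)Rp, Gp.memptr() + r0, (int)Rp,
                (eT)0, gwtap.memptr(), Cin);
      for (int co = 0; co < Cout; ++co)
        for (int ci = 0; ci < Cin; ++ci)
          gwp[ki + k * kj + kk * (ci + (long)Cin * co)] =
              (double)gwtap[ci + (long)Cin * co];
      if (need_gx) {
        tap_weights(REAL(w), k, Cin, Cout, ki, kj, wtap.memptr());
        blas_gemm('N', 'T', (int)(r1 - r0), Cin, Cout, (eT)1,
                  Gp.memptr() + r0, (int)Rp, wtap.memptr(), Cin, (eT)1,
                  gxp.memptr() + r0 + s, (int)Rp);
      }
    }
  }
  if (need_gx) {
    NumericVector gx = alloc4(H, W, N, Cin);
    unpad_copy(gxp.memptr(), REAL(gx), H, W, N, Cin, pad);
    out = List::create(_["gx"] = gx, _["gw"] = gw, _["ggamma"] = ggamma,
                       _["gbeta"] = gbeta);
  } else {
    out = List::create(_["gw"] = gw, _["ggamma"] = ggamma,
                       _["gbeta"] = gbeta);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_convunit_backward(NumericVector y, NumericVector gy, NumericVector w,
                           NumericVector gamma, SEXP cache, int act,
                           double alpha, bool need_gx, bool single_prec) {
  if (single_prec) {
    return convunit_bw<arma::fmat, arma::fvec>(y, gy, w, gamma, cache, act,
                                               alpha, need_gx);
  }
  return convunit_bw<arma::mat, arma::vec>(y, gy, w, gamma, cache, act, alpha,
                                           need_gx);
}

// ---------------------------------------------------------------------------
// direct (gather-free) convolution for very small channel counts, e.g. the
// 7x7 spatial-attention convolution on a 2-channel mean/max stack
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv2d_small_forward(NumericVector x, NumericVector w,
                                       Nullable<NumericVector> bias, int k,
                                       int dil, int pad) {
  int xd[4];
  get_dim4(x, xd, "x");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3];
  const long HW = (long)H * W;
  const int Cout = (int)(w.size() / ((long)k * k * Cin));
  NumericVector y = alloc4(H, W, N, Cout);
  double *yp = REAL(y);
  const double *xp = REAL(x), *wp = REAL(w);
  const double *bp = NULL;
  NumericVector bv;
  if (bias.isNotNull()) { bv = bias.get(); bp = REAL(bv); }
  for (int co = 0; co < Cout; ++co) {
    for (int n = 0; n < N; ++n) {
      double *yplane = yp + (long)co * HW * N + (long)n * HW;
      if (bp) {
        for (long i = 0; i < HW; ++i) yplane[i] = bp[co];
      } else {
        std::fill(yplane, yplane + HW, 0.0);
      }
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xplane = xp + (long)ci * HW * N + (long)n * HW;
        for (int kj = 0; kj < k; ++kj) {
          const int dw = kj * dil - pad;
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int ki = 0; ki < k; ++ki) {
            const int dh = ki * dil - pad;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const double wv = wp[ki + k * (kj + k * ((long)ci + Cin * co))];
            if (wv == 0 || h1 <= h0 || w1 <= w0) continue;
            for (int ww = w0; ww < w1; ++ww) {
              const double *src = xplane + (long)(ww + dw) * H + (h0 + dh);
              double *dst = yplane + (long)ww * H + h0;
              for (int h = 0; h < h1 - h0; ++h) dst[h] += wv * src[h];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_small_backward(NumericVector x, NumericVector w,
                               NumericVector gy, bool has_bias, int k, int dil,
                               int pad) {
  int xd[4], gd[4];
  get_dim4(x, xd, "x");
  get_dim4(gy, gd, "gy");
  const int H = xd[0], W = xd[1], N = xd[2], Cin = xd[3], Cout = gd[3];
  const long HW = (long)H * W, HWN = HW * N;
  NumericVector gx = alloc4(H, W, N, Cin);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  const double *xp = REAL(x), *wp = REAL(w), *gp = REAL(gy);
  double *gxp = REAL(gx), *gwp = REAL(gw);
  for (int co = 0; co < Cout; ++co) {
    for (int n = 0; n < N; ++n) {
      const double *gplane = gp + (long)co * HWN + (long)n * HW;
      for (int ci = 0; ci < Cin; ++ci) {
        const double *xplane = xp + (long)ci * HWN + (long)n * HW;
        double *gxplane = gxp + (long)ci * HWN + (long)n * HW;
        for (int kj = 0; kj < k; ++kj) {
          const int dw = kj * dil - pad;
          const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int ki = 0; ki < k; ++ki) {
            const int dh = ki * dil - pad;
            const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            if (h1 <= h0 || w1 <= w0) continue;
            const long widx = ki + k * (kj + k * ((long)ci + Cin * co));
            const double wv = wp[widx];
            double acc = 0;
            for (int ww = w0; ww < w1; ++ww) {
              const double *xs = xplane + (long)(ww + dw) * H + (h0 + dh);
              double *gxs = gxplane + (long)(ww + dw) * H + (h0 + dh);
              const double *gs = gplane + (long)ww * H + h0;
              for (int h = 0; h < h1 - h0; ++h) {
                acc += xs[h] * gs[h];
                gxs[h] += wv * gs[h];
              }
            }
            gwp[widx] += acc;
          }
        }
      }
    }
  }
  if (has_bias) {
    NumericVector gb(Cout);
    for (int co = 0; co < Cout; ++co) {
      const double *b = gp + (long)co * HWN;
      double s = 0;
      for (long i = 0; i < HWN; ++i) s += b[i];
      gb[co] = s;
    }
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// ---------------------------------------------------------------------------
// broadcast scale / blend kernels used by the attention modules
// ---------------------------------------------------------------------------

// y = x * s, s of shape (H, W, N, 1) broadcast over channels
// [[Rcpp::export]]
NumericVector cpp_scale_hwn_forward(NumericVector x, NumericVector s) {
  int xd[4];
  get_dim4(x, xd, "x");
  const long HWN = (long)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = REAL(x), *sp = REAL(s);
  double *yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double *xc = xp + (long)c * HWN;
    double *yc = yp + (long)c * HWN;
    for (long i = 0; i < HWN; ++i) yc[i] = xc[i] * sp[i];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_scale_hwn_backward(NumericVector gy, NumericVector x,
                            NumericVector s) {
  int xd[4];
  get_dim4(x, xd, "x");
  const long HWN = (long)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gs = alloc4(xd[0], xd[1], xd[2], 1);
  const double *gp = REAL(gy), *xp = REAL(x), *sp = REAL(s);
  double *gxp = REAL(gx), *gsp = REAL(gs);
  for (int c = 0; c < C; ++c) {
    const double *gc = gp + (long)c * HWN;
    const double *xc = xp + (long)c * HWN;
    double *gxc = gxp + (long)c * HWN;
    for (long i = 0; i < HWN; ++i) {
      gxc[i] = gc[i] * sp[i];
      gsp[i] += gc[i] * xc[i];
    }
  }
  return List::create(_["gx"] = gx, _["gs"] = gs);
}

// y = x * v, v of shape (1, 1, N, C) broadcast over H, W
// [[Rcpp::export]]
NumericVector cpp_scale_nc_forward(NumericVector x, NumericVector v,
                                   double shift) {
  int xd[4];
  get_dim4(x, xd, "x");
  const long HW = (long)xd[0] * xd[1];
  const int NC = xd[2] * xd[3];
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double *xp = REAL(x), *vp = REAL(v);
  double *yp = REAL(y);
  for (int p = 0; p < NC; ++p) {
    const double f = vp[p] + shift;
    const double *xc = xp + (long)p * HW;
    double *yc = yp + (long)p * HW;
    for (long i = 0; i < HW; ++i) yc[i] = xc[i] * f;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_scale_nc_backward(NumericVector gy, NumericVector x, NumericVector v,
                           double shift) {
  int xd[4];
  get_dim4(x, xd, "x");
  const long HW = (long)xd[0] * xd[1];
  const int NC = xd[2] * xd[3];
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  NumericVector gv = alloc4(1, 1, xd[2], xd[3]);
  const double *gp = REAL(gy), *xp = REAL(x), *vp = REAL(v);
  double *gxp = REAL(gx), *gvp = REAL(gv);
  for (int p = 0; p < NC; ++p) {
    const double f = vp[p] + shift;
    const double *gc = gp + (long)p * HW;
    const double *xc = xp + (long)p * HW;
    double *gxc = gxp + (long)p * HW;
    double acc = 0;
    for (long i = 0; i < HW; ++i) {
      gxc[i] = gc[i] * f;
      acc += gc[i] * xc[i];
    }
    gvp[p] = acc;
  }
  return List::create(_["gx"] = gx, _["gv"] = gv);
}

// out = (1 - g) * fc + g * fs with gate g of shape (H, W, N, 1)
// [[Rcpp::export]]
NumericVector cpp_blend_forward(NumericVector fc, NumericVector fs,
                                NumericVector g) {
  int xd[4];
  get_dim4(fc, xd, "FC");
  const long HWN = (long)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector y(fc.size());
  y.attr("dim") = fc.attr("dim");
  const double *ap = REAL(fc), *bp = REAL(fs), *gp = REAL(g);
  double *yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    const double *ac = ap + (long)c * HWN;
    const double *bc = bp + (long)c * HWN;
    double *yc = yp + (long)c * HWN;
    for (long i = 0; i < HWN; ++i) {
      // exact at the endpoints and exact when fc == fs
      yc[i] = gp[i] == 1.0 ? bc[i] : ac[i] + gp[i] * (bc[i] - ac[i]);
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_blend_backward(NumericVector gy, NumericVector fc, NumericVector fs,
                        NumericVector g) {
  int xd[4];
  get_dim4(fc, xd, "FC");
  const long HWN = (long)xd[0] * xd[1] * xd[2];
  const int C = xd[3];
  NumericVector gfc(fc.size()), gfs(fs.size());
  gfc.attr("dim") = fc.attr("dim");
  gfs.attr("dim") = fs.attr("dim");
  NumericVector gg = alloc4(xd[0], xd[1], xd[2], 1);
  const double *gp = REAL(gy), *ap = REAL(fc), *bp = REAL(fs), *gv = REAL(g);
  double *gap = REAL(gfc), *gbp = REAL(gfs), *ggp = REAL(gg);
  for (int c = 0; c < C; ++c) {
    const double *gc = gp + (long)c * HWN;
    const double *ac = ap + (long)c * HWN;
    const double *bc = bp + (long)c * HWN;
    double *ga = gap + (long)c * HWN;
    double *gb = gbp + (long)c * HWN;
    for (long i = 0; i < HWN; ++i) {
      ga[i] = gc[i] * (1.0 - gv[i]);
      gb[i] = gc[i] * gv[i];
      ggp[i] += gc[i] * (bc[i] - ac[i]);
    }
  }
  return List::create(_["gfc"] = gfc, _["gfs"] = gfs, _["gg"] = gg);
}

// ---------------------------------------------------------------------------
// channel concatenation / split (channel blocks are contiguous)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_cat_channels(NumericVector a, NumericVector b) {
  int ad[4], bd[4];
  get_dim4(a, ad, "a");
  get_dim4(b, bd, "b");
  NumericVector y = alloc4(ad[0], ad[1], ad[2], ad[3] + bd[3]);
  std::copy(a.begin(), a.end(), y.begin());
  std::copy(b.begin(), b.end(), y.begin() + a.size());
  return y;
}

// [[Rcpp::export]]
List cpp_split_channels(NumericVector x, int c1) {
  int xd[4];
  get_dim4(x, xd, "x");
  const R_xlen_t n1 = (R_xlen_t)xd[0] * xd[1] * xd[2] * c1;
  NumericVector a = alloc4(xd[0], xd[1], xd[2], c1);
  NumericVector b = alloc4(xd[0], xd[1], xd[2], xd[3] - c1);
  std::copy(x.begin(), x.begin() + n1, a.begin());
  std::copy(x.begin() + n1, x.end(), b.begin());
  return List::create(_["a"] = a, _["b"] = b);
}

// ---------------------------------------------------------------------------
// Adam with decoupled weight decay; first/second-moment state lives on the
// C++ side and is reused across steps
// ---------------------------------------------------------------------------

struct AdamState {
  std::vector<arma::vec> m, v;
};

// [[Rcpp::export]]
SEXP cpp_adam_init() {
  return XPtr<AdamState>(new AdamState(), true);
}

// [[Rcpp::export]]
List cpp_adam_step(SEXP state, List ws, List gs, LogicalVector decay,
                   double lr, double wd, double beta1, double beta2,
                   double eps, int t) {
  XPtr<AdamState> st(state);
  const size_t P = ws.size();
  if (st->m.size() != P) {
    st->m.assign(P, arma::vec());
    st->v.assign(P, arma::vec());
  }
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  List out(P);
  for (size_t p = 0; p < P; ++p) {
    NumericVector w = ws[p];
    if (Rf_isNull(gs[p])) {
      out[p] = w;
      continue;
    }
    NumericVector g = gs[p];
    const R_xlen_t n = w.size();
    if ((R_xlen_t)st->m[p].n_elem != n) {
      st->m[p].zeros(n);
      st->v[p].zeros(n);
    }
    NumericVector nw(n);
    nw.attr("dim") = w.attr("dim");
    double *mp = st->m[p].memptr(), *vp = st->v[p].memptr();
    const double *wp = REAL(w), *gp = REAL(g);
    double *np = REAL(nw);
    const double dec = decay[p] ? lr * wd : 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      mp[i] = beta1 * mp[i] + (1 - beta1) * gp[i];
      vp[i] = beta2 * vp[i] + (1 - beta2) * gp[i] * gp[i];
      np[i] = wp[i] - lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps) -
              dec * wp[i];
    }
    out[p] = nw;
  }
  return out;
}
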