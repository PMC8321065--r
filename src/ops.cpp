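// Low-level 3D convolution and pooling kernels.
//
// Tensor layout everywhere: channel-first column-major arrays, i.e. an R
// array of dim (C, H, W, D, B) where C varies fastest.  Convolution is
// im2col + BLAS GEMM, chunked over output voxels so the patch matrix never
// exceeds ~256 MB even at full scale (116 input channels on a 61x73x61
// grid).  Weight matrices are (C*KH*KW*KD) x Cout with the patch index
// ordered c fastest, then kh, kw, kd — matching an R array of
// dim (C, KH, KW, KD, Cout) flattened column-major.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline int out_len(int L, int k, int s, int p) {
  return (L + 2 * p - k) / s + 1;
}

// Fill `col` (P x n) with patches for output voxels [o0, o0+n) of sample b.
static void im2col_chunk(const double* x, int C, int H, int W, int D,
                         int KH, int KW, int KD,
                         int SH, int SW, int SD,
                         int PH, int PW, int PD,
                         int OH, int OW, int /*OD*/,
                         int o0, int n, arma::mat& col) {
  const int P = C * KH * KW * KD;
  for (int t = 0; t < n; ++t) {
    int o = o0 + t;
    int oh = o % OH;
    int ow = (o / OH) % OW;
    int od = o / (OH * OW);
    double* dst = col.colptr(t);
    for (int kd = 0; kd < KD; ++kd) {
      int id = od * SD - PD + kd;
      for (int kw = 0; kw < KW; ++kw) {
        int iw = ow * SW - PW + kw;
        for (int kh = 0; kh < KH; ++kh) {
          int ih = oh * SH - PH + kh;
          int p = C * (kh + KH * (kw + KW * kd));
          if (ih < 0 || ih >= H || iw < 0 || iw >= W || id < 0 || id >= D) {
            std::memset(dst + p, 0, sizeof(double) * C);
          } else {
            const double* src = x + (size_t)C * (ih + (size_t)H * (iw + (size_t)W * id));
            std::memcpy(dst + p, src, sizeof(double) * C);
          }
        }
      }
    }
    (void)P;
  }
}

// scatter-add of `col` back into gx (reverse of im2col_chunk)
static void col2im_chunk(double* gx, int C, int H, int W, int D,
                         int KH, int KW, int KD,
                         int SH, int SW, int SD,
                         int PH, int PW, int PD,
                         int OH, int OW, int /*OD*/,
                         int o0, int n, const arma::mat& col) {
  for (int t = 0; t < n; ++t) {
    int o = o0 + t;
    int oh = o % OH;
    int ow = (o / OH) % OW;
    int od = o / (OH * OW);
    const double* src = col.colptr(t);
    for (int kd = 0; kd < KD; ++kd) {
      int id = od * SD - PD + kd;
      if (id < 0 || id >= D) continue;
      for (int kw = 0; kw < KW; ++kw) {
        int iw = ow * SW - PW + kw;
        if (iw < 0 || iw >= W) continue;
        for (int kh = 0; kh < KH; ++kh) {
          int ih = oh * SH - PH + kh;
          if (ih < 0 || ih >= H) continue;
          int p = C * (kh + KH * (kw + KW * kd));
          double* dst = gx + (size_t)C * (ih + (size_t)H * (iw + (size_t)W * id));
          for (int c = 0; c < C; ++c) dst[c] += src[p + c];
        }
      }
    }
  }
}

static int chunk_cols(int P, int total) {
  // cap patch matrix at ~2.4e7 doubles (~190 MB)
  int n = (int)std::max(1.0, 2.4e7 / std::max(P, 1));
  return std::min(n, total);
}

// [[Rcpp::export(name = "cpp_conv3d_forward")]]
NumericVector cpp_conv3d_forward(NumericVector x, IntegerVector xdim,
                                 NumericMatrix wmat, NumericVector bias,
                                 IntegerVector kernel, IntegerVector stride,
                                 IntegerVector pad) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], B = xdim[4];
  const int KH = kernel[0], KW = kernel[1], KD = kernel[2];
  const int SH = stride[0], SW = stride[1], SD = stride[2];
  const int PH = pad[0], PW = pad[1], PD = pad[2];
  const int OH = out_len(H, KH, SH, PH), OW = out_len(W, KW, SW, PW),
            OD = out_len(D, KD, SD, PD);
  if (OH < 1 || OW < 1 || OD < 1)
    stop("convolution output would be empty: input (%d,%d,%d) too small for kernel/stride/padding",
         H, W, D);
  const int P = C * KH * KW * KD;
  const int Cout = wmat.ncol();
  if (wmat.nrow() != P) stop("weight matrix has %d rows, expected %d", wmat.nrow(), P);
  const int nout = OH * OW * OD;
  const bool has_bias = bias.size() == Cout;

  arma::mat Wm(wmat.begin(), P, Cout, false, true);
  NumericVector out((size_t)Cout * nout * B);
  const size_t xstride = (size_t)C * H * W * D;
  const size_t ostride = (size_t)Cout * nout;
  const int nc = chunk_cols(P, nout);
  arma::mat col(P, nc);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + b * xstride;
    double* ob = out.begin() + b * ostride;
    for (int o0 = 0; o0 < nout; o0 += nc) {
      int n = std::min(nc, nout - o0);
      if (n != (int)col.n_cols) col.set_size(P, n);
      im2col_chunk(xb, C, H, W, D, KH, KW, KD, SH, SW, SD, PH, PW, PD,
                   OH, OW, OD, o0, n, col);
      arma::mat om(ob + (size_t)Cout * o0, Cout, n, false, true);
      om = Wm.t() * col;
      if (has_bias)
        om.each_col() += arma::vec(bias.begin(), Cout);
    }
  }
  out.attr("dim") = IntegerVector::create(Cout, OH, OW, OD, B);
  return out;
}

// [[Rcpp::export(name = "cpp_conv3d_backward")]]
List cpp_conv3d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector gout,
                         NumericMatrix wmat, bool has_bias,
                         IntegerVector kernel, IntegerVector stride,
                         IntegerVector pad) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], B = xdim[4];
  const int KH = kernel[0], KW = kernel[1], KD = kernel[2];
  const int SH = stride[0], SW = stride[1], SD = stride[2];
  const int PH = pad[0], PW = pad[1], PD = pad[2];
  const int OH = out_len(H, KH, SH, PH), OW = out_len(W, KW, SW, PW),
            OD = out_len(D, KD, SD, PD);
  const int P = C * KH * KW * KD;
  const int Cout = wmat.ncol();
  const int nout = OH * OW * OD;

  arma::mat Wm(wmat.begin(), P, Cout, false, true);
  arma::mat gW(P, Cout, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  NumericVector gx(x.size());
  const size_t xstride = (size_t)C * H * W * D;
  const size_t ostride = (size_t)Cout * nout;
  const int nc = chunk_cols(P, nout);
  arma::mat col(P, nc);

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + b * xstride;
    double* gxb = gx.begin() + b * xstride;
    for (int o0 = 0; o0 < nout; o0 += nc) {
      int n = std::min(nc, nout - o0);
      if (n != (int)col.n_cols) col.set_size(P, n);
      im2col_chunk(xb, C, H, W, D, KH, KW, KD, SH, SW, SD, PH, PW, PD,
                   OH, OW, OD, o0, n, col);
      arma::mat gm(const_cast<double*>(gout.begin()) + b * ostride + (size_t)Cout * o0,
                   Cout, n, false, true);
      gW += col * gm.t();
      if (has_bias) gb += arma::sum(gm, 1);
      arma::mat gcol = Wm * gm;  // P x n
      col2im_chunk(gxb, C, H, W, D, KH, KW, KD, SH, SW, SD, PH, PW, PD,
                   OH, OW, OD, o0, n, gcol);
    }
  }
  gx.attr("dim") = xdim;
  NumericMatrix gWr(P, Cout);
  std::memcpy(gWr.begin(), gW.memptr(), sizeof(double) * (size_t)P * Cout);
  return List::create(_["gx"] = gx, _["gW"] = gWr,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export(name = "cpp_maxpool3d_forward")]]
List cpp_maxpool3d_forward(NumericVector x, IntegerVector xdim,
                           IntegerVector kernel, IntegerVector stride,
                           IntegerVector pad) {
  const int C = xdim[0], H = xdim[1], W = xdim[2], D = xdim[3], B = xdim[4];
  const int KH = kernel[0], KW = kernel[1], KD = kernel[2];
  const int SH = stride[0], SW = stride[1], SD = stride[2];
  const int PH = pad[0], PW = pad[1], PD = pad[2];
  const int OH = out_len(H, KH, SH, PH), OW = out_len(W, KW, SW, PW),
            OD = out_len(D, KD, SD, PD);
  if (OH < 1 || OW < 1 || OD < 1)
    stop("pooling output would be empty: input (%d,%d,%d) too small", H, W, D);
  const size_t nout = (size_t)C * OH * OW * OD;
  NumericVector out(nout * B);
  IntegerVector idx(nout * B);  // 1-based linear index into x of each max
  const size_t xstride = (size_t)C * H * W * D;

  for (int b = 0; b < B; ++b) {
    const double* xb = x.begin() + b * xstride;
    double* ob = out.begin() + b * nout;
    int* ib = idx.begin() + b * nout;
    for (int od = 0; od < OD; ++od)
      for (int ow = 0; ow < OW; ++ow)
        for (int oh = 0; oh < OH; ++oh)
          for (int c = 0; c < C; ++c) {
            double best = R_NegInf;
            size_t besti = 0;
            for (int kd = 0; kd < KD; ++kd) {
              int id = od * SD - PD + kd;
              if (id < 0 || id >= D) continue;
              for (int kw = 0; kw < KW; ++kw) {
                int iw = ow * SW - PW + kw;
                if (iw < 0 || iw >= W) continue;
                for (int kh = 0; kh < KH; ++kh) {
                  int ih = oh * SH - PH + kh;
                  if (ih < 0 || ih >= H) continue;
                  size_t li = c + (size_t)C * (ih + (size_t)H * (iw + (size_t)W * id));
                  double v = xb[li];
                  if (v > best) { best = v; besti = li; }
                }
              }
            }
            size_t lo = c + (size_t)C * (oh + (size_t)OH * (ow + (size_t)OW * od));
            ob[lo] = best;
            ib[lo] = (int)(besti + b * xstride) + 1;
          }
  }
  out.attr("dim") = IntegerVector::create(C, OH, OW, OD, B);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = "cpp_maxpool3d_backward")]]
NumericVector cpp_maxpool3d_backward(NumericVector gout, IntegerVector idx,
                                     int n_in) {
  NumericVector gx(n_in);
  const R_xlen_t n = gout.size();
  for (R_xlen_t i = 0; i < n; ++i) gx[idx[i] - 1] += gout[i];
  return gx;
}
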