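// Compiled kernels for the network engine: 2-D convolution (stride,
// dilation, TensorFlow-style "same" padding), its gradients, the 2x2
// stride-2 transposed convolution and 2x2 max pooling.
//
// Tensor layout throughout: R arrays with dim = c(N, H, W, C), column
// major, so the linear index of element (n, h, w, c) is
// n + N*(h + H*(w + W*c)).  Weight layout: dim = c(kh, kw, cin, cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void same_pad(int in, int k, int stride, int dilation,
                            int &out, int &pad_beg) {
  int ke = (k - 1) * dilation + 1;
  out = (in + stride - 1) / stride;
  int pad_total = (out - 1) * stride + ke - in;
  if (pad_total < 0) pad_total = 0;
  pad_beg = pad_total / 2;  // extra padding goes to the bottom/right
}

// Gather one sample into an im2col matrix col(K, P) with
// K = kh*kw*cin (ki fastest, then kj, then ci) and P = oh*ow (oy fastest).
static void im2col(const double *x, int n, int N, int H, int W, int C,
                   int kh, int kw, int stride, int dilation,
                   int OH, int OW, int ph, int pw, arma::mat &col) {
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int ox = 0; ox < OW; ++ox) {
          int iw = ox * stride - pw + kj * dilation;
          if (iw < 0 || iw >= W) {
            for (int oy = 0; oy < OH; ++oy)
              col(r, oy + OH * ox) = 0.0;
            continue;
          }
          for (int oy = 0; oy < OH; ++oy) {
            int ih = oy * stride - ph + ki * dilation;
            col(r, oy + OH * ox) =
                (ih < 0 || ih >= H)
                    ? 0.0
                    : x[n + (size_t)N * (ih + (size_t)H * (iw + (size_t)W * ci))];
          }
        }
      }
    }
  }
}

// Scatter-add the im2col gradient back onto the input gradient.
static void col2im(double *gx, const arma::mat &gcol, int n, int N, int H,
                   int W, int C, int kh, int kw, int stride, int dilation,
                   int OH, int OW, int ph, int pw) {
  for (int ci = 0; ci < C; ++ci) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        int r = ki + kh * (kj + kw * ci);
        for (int ox = 0; ox < OW; ++ox) {
          int iw = ox * stride - pw + kj * dilation;
          if (iw < 0 || iw >= W) continue;
          for (int oy = 0; oy < OH; ++oy) {
            int ih = oy * stride - ph + ki * dilation;
            if (ih < 0 || ih >= H) continue;
            gx[n + (size_t)N * (ih + (size_t)H * (iw + (size_t)W * ci))] +=
                gcol(r, oy + OH * ox);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector nn_conv2d(NumericVector x, NumericVector w, NumericVector b,
                        int stride, int dilation) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, cin);
  int OH, OW, ph, pw;
  same_pad(H, kh, stride, dilation, OH, ph);
  same_pad(W, kw, stride, dilation, OW, pw);
  int K = kh * kw * cin, P = OH * OW;

  arma::mat Wm(const_cast<double *>(w.begin()), K, cout, false, true);
  NumericVector out((size_t)N * OH * OW * cout);
  out.attr("dim") = IntegerVector::create(N, OH, OW, cout);
  arma::mat col(K, P);
  const bool has_b = b.size() > 0;

  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), n, N, H, W, C, kh, kw, stride, dilation, OH, OW, ph, pw, col);
    arma::mat om = col.t() * Wm;  // P x cout
    for (int co = 0; co < cout; ++co) {
      double bb = has_b ? b[co] : 0.0;
      for (int p = 0; p < P; ++p) {
        int oy = p % OH, ox = p / OH;
        out[n + (size_t)N * (oy + (size_t)OH * (ox + (size_t)OW * co))] =
            om(p, co) + bb;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List nn_conv2d_backward(NumericVector x, NumericVector w, NumericVector gout,
                        int stride, int dilation, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  int OH, OW, ph, pw;
  same_pad(H, kh, stride, dilation, OH, ph);
  same_pad(W, kw, stride, dilation, OW, pw);
  int K = kh * kw * cin, P = OH * OW;

  arma::mat Wm(const_cast<double *>(w.begin()), K, cout, false, true);
  NumericVector gx((size_t)N * H * W * C);
  gx.attr("dim") = xd;
  NumericVector gw((size_t)K * cout);
  gw.attr("dim") = wd;
  arma::mat Gw(gw.begin(), K, cout, false, true);
  NumericVector gb(has_bias ? cout : 0);

  arma::mat col(K, P), gmat(P, cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < cout; ++co)
      for (int p = 0; p < P; ++p) {
        int oy = p % OH, ox = p / OH;
        gmat(p, co) =
            gout[n + (size_t)N * (oy + (size_t)OH * (ox + (size_t)OW * co))];
      }
    im2col(x.begin(), n, N, H, W, C, kh, kw, stride, dilation, OH, OW, ph, pw, col);
    Gw += col * gmat;                     // K x cout
    arma::mat gcol = Wm * gmat.t();       // K x P
    col2im(gx.begin(), gcol, n, N, H, W, C, kh, kw, stride, dilation, OH, OW,
           ph, pw);
    if (has_bias)
      for (int co = 0; co < cout; ++co) gb[co] += arma::accu(gmat.col(co));
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution: exact spatial doubling, no overlap.
// out(n, 2i+a, 2j+b, co) = sum_ci x(n, i, j, ci) * w(a, b, ci, co) + bias.
// [[Rcpp::export]]
NumericVector nn_conv2d_transpose2(NumericVector x, NumericVector w,
                                   NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int cin = wd[2], cout = wd[3];
  if (cin != C) stop("conv2d_transpose: channel mismatch");
  int OH = 2 * H, OW = 2 * W;
  NumericVector out((size_t)N * OH * OW * cout);
  out.attr("dim") = IntegerVector::create(N, OH, OW, cout);
  const bool has_b = b.size() > 0;

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co)
      for (int ci = 0; ci < C; ++ci)
        for (int bcol = 0; bcol < 2; ++bcol)
          for (int arow = 0; arow < 2; ++arow) {
            double wv = w[arow + 2 * (bcol + 2 * (ci + cin * co))];
            for (int j = 0; j < W; ++j)
              for (int i = 0; i < H; ++i)
                out[n + (size_t)N * ((2 * i + arow) +
                    (size_t)OH * ((2 * j + bcol) + (size_t)OW * co))] +=
                    wv * x[n + (size_t)N * (i + (size_t)H * (j + (size_t)W * ci))];
          }
  if (has_b)
    for (int co = 0; co < cout; ++co)
      for (size_t k = (size_t)N * OH * OW * co; k < (size_t)N * OH * OW * (co + 1); ++k)
        out[k] += b[co];
  return out;
}

// [[Rcpp::export]]
List nn_conv2d_transpose2_backward(NumericVector x, NumericVector w,
                                   NumericVector gout, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  int cin = wd[2], cout = wd[3];
  int OH = 2 * H, OW = 2 * W;
  NumericVector gx((size_t)N * H * W * C);
  gx.attr("dim") = xd;
  NumericVector gw(4 * (size_t)cin * cout);
  gw.attr("dim") = wd;
  NumericVector gb(has_bias ? cout : 0);

  for (int n = 0; n < N; ++n)
    for (int co = 0; co < cout; ++co) {
      for (int ci = 0; ci < C; ++ci)
        for (int bcol = 0; bcol < 2; ++bcol)
          for (int arow = 0; arow < 2; ++arow) {
            double wv = w[arow + 2 * (bcol + 2 * (ci + cin * co))];
            double gwv = 0.0;
            for (int j = 0; j < W; ++j)
              for (int i = 0; i < H; ++i) {
                double g = gout[n + (size_t)N * ((2 * i + arow) +
                           (size_t)OH * ((2 * j + bcol) + (size_t)OW * co))];
                double xv = x[n + (size_t)N * (i + (size_t)H * (j + (size_t)W * ci))];
                gx[n + (size_t)N * (i + (size_t)H * (j + (size_t)W * ci))] += wv * g;
                gwv += xv * g;
              }
            gw[arow + 2 * (bcol + 2 * (ci + cin * co))] += gwv;
          }
      if (has_bias) {
        double acc = 0.0;
        for (int j = 0; j < OW; ++j)
          for (int i = 0; i < OH; ++i)
            acc += gout[n + (size_t)N * (i + (size_t)OH * (j + (size_t)OW * co))];
        gb[co] += acc;
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; requires even H and W.  Returns the pooled map
// and, per output element, the 1-based linear index of the winning input.
// [[Rcpp::export]]
List nn_maxpool2(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int N = xd[0], H = xd[1], W = xd[2], C = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  int OH = H / 2, OW = W / 2;
  NumericVector out((size_t)N * OH * OW * C);
  out.attr("dim") = IntegerVector::create(N, OH, OW, C);
  IntegerVector idx(out.size());
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int ox = 0; ox < OW; ++ox)
        for (int oy = 0; oy < OH; ++oy) {
          double best = R_NegInf;
          size_t besti = 0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              size_t ii = n + (size_t)N * ((2 * oy + a) +
                          (size_t)H * ((2 * ox + b) + (size_t)W * c));
              if (x[ii] > best) { best = x[ii]; besti = ii; }
            }
          size_t oi = n + (size_t)N * (oy + (size_t)OH * (ox + (size_t)OW * c));
          out[oi] = best;
          idx[oi] = (int)(besti + 1);
        }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool2_backward(IntegerVector idx, NumericVector gout,
                                   IntegerVector xdim) {
  size_t nx = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(nx);
  gx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < gout.size(); ++k) gx[idx[k] - 1] += gout[k];
  return gx;
}
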