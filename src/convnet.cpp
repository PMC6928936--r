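// Convolution engine for the super-resolution encoder-decoder.
//
// Tensors are stored column-major as (C, W, T, B): feature channels fastest,
// then electrode axis W, time axis T, batch B.  All arithmetic is single
// precision through BLAS sgemm; the R boundary is double.  A transposed
// convolution is realised as the adjoint of the matching strided convolution,
// so the three primitive passes (forward, backward-data, backward-weights)
// cover every layer type.
//
// For cache locality, output positions are processed per batch element in
// time blocks of roughly 8k columns; the kw kernel-width offsets of one time
// offset are gathered into a single (Cin*kw x block) panel so every sgemm
// has inner dimension Cin*kw.

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>

using namespace Rcpp;

extern "C" void sgemm_(const char *transa, const char *transb,
                       const int *m, const int *n, const int *k,
                       const float *alpha, const float *a, const int *lda,
                       const float *b, const int *ldb,
                       const float *beta, float *c, const int *ldc,
                       size_t, size_t);

static inline void xgemm(char ta, char tb, int m, int n, int k,
                         float alpha, const float *a, int lda,
                         const float *b, int ldb, float beta,
                         float *c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc,
         (size_t)1, (size_t)1);
}

typedef std::vector<float> fvec;

static inline int ceil_div(int a, int b) { return (a + b - 1) / b; }

struct ConvDims {
  int Cin, W, T, B, Cout, kt, kw, s, pw, pt, Wo, To;
};

static ConvDims make_dims(int Cin, int W, int T, int B, int Cout,
                          int kt, int kw, int s) {
  ConvDims d;
  d.Cin = Cin; d.W = W; d.T = T; d.B = B; d.Cout = Cout;
  d.kt = kt; d.kw = kw; d.s = s;
  d.pw = (kw - 1) / 2; d.pt = (kt - 1) / 2;
  d.Wo = ceil_div(W, s); d.To = ceil_div(T, s);
  return d;
}

// Zero-pad one batch element (C,W,T) -> (C, W+2pw, T+2pt)
static void pad_one(const float *x, int C, int W, int T, int pw, int pt,
                    fvec &xp) {
  const int Wp = W + 2 * pw, Tp = T + 2 * pt;
  xp.assign((size_t)C * Wp * Tp, 0.0f);
  for (int t = 0; t < T; ++t)
    for (int w = 0; w < W; ++w)
      std::memcpy(&xp[(size_t)C * ((w + pw) + (size_t)Wp * (t + pt))],
                  &x[(size_t)C * (w + (size_t)W * t)], sizeof(float) * C);
}

// Gather panel for time offset dt and output rows to0..to0+tb-1:
// M is (Cin*kw x Wo*tb); column (wo, ti) stacks the kw width offsets.
// Contiguity: for stride 1 the kw*C floats starting at width offset 0 are
// contiguous in xp; for stride 2 they still are (offsets dw = 0..kw-1 sit at
// consecutive padded-width slots), so a single memcpy of C*kw floats works
// in both cases.
static void gather_panel(const fvec &xp, int C, int Wp,
                         int s, int kw, int dt, int Wo, int to0, int tb,
                         fvec &M) {
  const int rows = C * kw;
  for (int ti = 0; ti < tb; ++ti) {
    const size_t tbase = (size_t)C * Wp * (dt + (size_t)s * (to0 + ti));
    for (int wo = 0; wo < Wo; ++wo)
      std::memcpy(&M[(size_t)rows * (wo + (size_t)Wo * ti)],
                  &xp[tbase + (size_t)C * (size_t)s * wo],
                  sizeof(float) * rows);
  }
}

// Adjoint of gather_panel (scatter-add the panel back).
static void scatter_panel(fvec &xp, int C, int Wp,
                          int s, int kw, int dt, int Wo, int to0, int tb,
                          const fvec &M) {
  const int rows = C * kw;
  for (int ti = 0; ti < tb; ++ti) {
    const size_t tbase = (size_t)C * Wp * (dt + (size_t)s * (to0 + ti));
    for (int wo = 0; wo < Wo; ++wo) {
      const float *col = &M[(size_t)rows * (wo + (size_t)Wo * ti)];
      float *dst = &xp[tbase + (size_t)C * (size_t)s * wo];
      for (int r = 0; r < rows; ++r) dst[r] += col[r];
    }
  }
}

// Kernel panel for time offset dt: (Cin*kw x Cout), row block dw holds
// K[dt, dw, :, co]; kernel stored (kt, kw, Cin, Cout).
static void kernel_panel(const fvec &k, int kt, int kw, int Cin, int Cout,
                         int dt, float *kp) {
  for (int co = 0; co < Cout; ++co)
    for (int dw = 0; dw < kw; ++dw)
      for (int ci = 0; ci < Cin; ++ci)
        kp[(size_t)ci + Cin * ((size_t)dw + kw * (size_t)co)] =
          k[(size_t)dt + kt * ((size_t)dw + kw * ((size_t)ci + (size_t)Cin * co))];
}

static void kernel_panel_store(const float *kp, fvec &k, int kt, int kw,
                               int Cin, int Cout, int dt) {
  for (int co = 0; co < Cout; ++co)
    for (int dw = 0; dw < kw; ++dw)
      for (int ci = 0; ci < Cin; ++ci)
        k[(size_t)dt + kt * ((size_t)dw + kw * ((size_t)ci + (size_t)Cin * co))] =
          kp[(size_t)ci + Cin * ((size_t)dw + kw * (size_t)co)];
}

static int time_block(int Wo, int To) {
  int tb = 8192 / (Wo > 0 ? Wo : 1);
  if (tb < 1) tb = 1;
  if (tb > To) tb = To;
  return tb;
}

static void conv_fwd_core(const fvec &x, const fvec &k, const fvec &bias,
                          const ConvDims &d, fvec &y) {
  const int Wp = d.W + 2 * d.pw, Tp = d.T + 2 * d.pt;
  const int rows = d.Cin * d.kw;
  const int tb = time_block(d.Wo, d.To);
  fvec xp, M((size_t)rows * d.Wo * tb), kp((size_t)rows * d.Cout * d.kt);
  for (int dt = 0; dt < d.kt; ++dt)
    kernel_panel(k, d.kt, d.kw, d.Cin, d.Cout, dt,
                 &kp[(size_t)rows * d.Cout * dt]);
  y.assign((size_t)d.Cout * d.Wo * d.To * d.B, 0.0f);
  const size_t xstride = (size_t)d.Cin * d.W * d.T;
  const size_t ystride = (size_t)d.Cout * d.Wo * d.To;
  (void)Tp;
  for (int b = 0; b < d.B; ++b) {
    pad_one(&x[xstride * b], d.Cin, d.W, d.T, d.pw, d.pt, xp);
    for (int to0 = 0; to0 < d.To; to0 += tb) {
      const int cur = std::min(tb, d.To - to0);
      const int ncol = d.Wo * cur;
      float *yblk = &y[ystride * b + (size_t)d.Cout * d.Wo * to0];
      for (int dt = 0; dt < d.kt; ++dt) {
        gather_panel(xp, d.Cin, Wp, d.s, d.kw, dt, d.Wo, to0, cur, M);
        xgemm('T', 'N', d.Cout, ncol, rows, 1.0f,
              &kp[(size_t)rows * d.Cout * dt], rows,
              M.data(), rows, dt == 0 ? 0.0f : 1.0f, yblk, d.Cout);
      }
      if (!bias.empty())
        for (int j = 0; j < ncol; ++j)
          for (int c = 0; c < d.Cout; ++c)
            yblk[(size_t)d.Cout * j + c] += bias[c];
    }
  }
}

static void conv_bwd_data_core(const fvec &dy, const fvec &k,
                               const ConvDims &d, fvec &dx) {
  const int Wp = d.W + 2 * d.pw, Tp = d.T + 2 * d.pt;
  const int rows = d.Cin * d.kw;
  const int tb = time_block(d.Wo, d.To);
  fvec xp((size_t)d.Cin * Wp * Tp), M((size_t)rows * d.Wo * tb),
       kp((size_t)rows * d.Cout * d.kt);
  for (int dt = 0; dt < d.kt; ++dt)
    kernel_panel(k, d.kt, d.kw, d.Cin, d.Cout, dt,
                 &kp[(size_t)rows * d.Cout * dt]);
  dx.assign((size_t)d.Cin * d.W * d.T * d.B, 0.0f);
  const size_t xstride = (size_t)d.Cin * d.W * d.T;
  const size_t ystride = (size_t)d.Cout * d.Wo * d.To;
  for (int b = 0; b < d.B; ++b) {
    std::fill(xp.begin(), xp.end(), 0.0f);
    for (int to0 = 0; to0 < d.To; to0 += tb) {
      const int cur = std::min(tb, d.To - to0);
      const int ncol = d.Wo * cur;
      const float *dyblk = &dy[ystride * b + (size_t)d.Cout * d.Wo * to0];
      for (int dt = 0; dt < d.kt; ++dt) {
        xgemm('N', 'N', rows, ncol, d.Cout, 1.0f,
              &kp[(size_t)rows * d.Cout * dt], rows,
              dyblk, d.Cout, 0.0f, M.data(), rows);
        scatter_panel(xp, d.Cin, Wp, d.s, d.kw, dt, d.Wo, to0, cur, M);
      }
    }
    // crop padding
    for (int t = 0; t < d.T; ++t)
      for (int w = 0; w < d.W; ++w)
        std::memcpy(&dx[xstride * b + (size_t)d.Cin * (w + (size_t)d.W * t)],
                    &xp[(size_t)d.Cin * ((w + d.pw) + (size_t)Wp * (t + d.pt))],
                    sizeof(float) * d.Cin);
  }
}

static void conv_bwd_weights_core(const fvec &x, const fvec &dy,
                                  const ConvDims &d, fvec &dk, fvec &db) {
  const int Wp = d.W + 2 * d.pw;
  const int rows = d.Cin * d.kw;
  const int tb = time_block(d.Wo, d.To);
  fvec xp, M((size_t)rows * d.Wo * tb), kp((size_t)rows * d.Cout * d.kt, 0.0f);
  db.assign(d.Cout, 0.0f);
  const size_t xstride = (size_t)d.Cin * d.W * d.T;
  const size_t ystride = (size_t)d.Cout * d.Wo * d.To;
  for (int b = 0; b < d.B; ++b) {
    pad_one(&x[xstride * b], d.Cin, d.W, d.T, d.pw, d.pt, xp);
    for (int to0 = 0; to0 < d.To; to0 += tb) {
      const int cur = std::min(tb, d.To - to0);
      const int ncol = d.Wo * cur;
      const float *dyblk = &dy[ystride * b + (size_t)d.Cout * d.Wo * to0];
      for (int dt = 0; dt < d.kt; ++dt) {
        gather_panel(xp, d.Cin, Wp, d.s, d.kw, dt, d.Wo, to0, cur, M);
        xgemm('N', 'T', rows, d.Cout, ncol, 1.0f, M.data(), rows,
              dyblk, d.Cout, 1.0f, &kp[(size_t)rows * d.Cout * dt], rows);
      }
      for (int j = 0; j < ncol; ++j)
        for (int c = 0; c < d.Cout; ++c)
          db[c] += dyblk[(size_t)d.Cout * j + c];
    }
  }
  dk.assign((size_t)d.kt * d.kw * d.Cin * d.Cout, 0.0f);
  for (int dt = 0; dt < d.kt; ++dt)
    kernel_panel_store(&kp[(size_t)rows * d.Cout * dt], dk,
                       d.kt, d.kw, d.Cin, d.Cout, dt);
}

// ---- double <-> float helpers at the R boundary ----

static fvec as_fvec(const NumericVector &v) {
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static NumericVector as_numeric(const fvec &v, IntegerVector dim) {
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i];
  out.attr("dim") = dim;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, IntegerVector xd,
                             NumericVector k, IntegerVector kd,
                             NumericVector bias, int stride) {
  ConvDims d = make_dims(xd[0], xd[1], xd[2], xd[3], kd[3], kd[0], kd[1], stride);
  fvec xf = as_fvec(x), kf = as_fvec(k), bf = as_fvec(bias), y;
  conv_fwd_core(xf, kf, bf, d, y);
  return as_numeric(y, IntegerVector::create(d.Cout, d.Wo, d.To, d.B));
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_bwd_data(NumericVector dy, NumericVector k,
                                  IntegerVector kd, int stride,
                                  IntegerVector in_dim) {
  ConvDims d = make_dims(kd[2], in_dim[1], in_dim[2], in_dim[3], kd[3],
                         kd[0], kd[1], stride);
  fvec dyf = as_fvec(dy), kf = as_fvec(k), dx;
  conv_bwd_data_core(dyf, kf, d, dx);
  return as_numeric(dx, IntegerVector::create(d.Cin, d.W, d.T, d.B));
}

// [[Rcpp::export]]
List cpp_conv2d_bwd_weights(NumericVector x, IntegerVector xd,
                            NumericVector dy, IntegerVector kd, int stride) {
  ConvDims d = make_dims(xd[0], xd[1], xd[2], xd[3], kd[3], kd[0], kd[1], stride);
  fvec xf = as_fvec(x), dyf = as_fvec(dy), dk, db;
  conv_bwd_weights_core(xf, dyf, d, dk, db);
  return List::create(
    _["dk"] = as_numeric(dk, IntegerVector::create(kd[0], kd[1], kd[2], kd[3])),
    _["db"] = as_numeric(db, IntegerVector::create(kd[3])));
}

// Transposed convolution forward: adjoint of the strided convolution that
// maps (out_dim) down to x's spatial size.  The kernel is stored
// (kt, kw, Cout_layer, Cin_layer), i.e. as the kernel of that mirrored
// convolution; kd[2] = Cout_layer is the big (output) side.
// [[Rcpp::export]]
NumericVector cpp_tconv2d_fwd(NumericVector x, IntegerVector xd,
                              NumericVector k, IntegerVector kd,
                              NumericVector bias, int stride,
                              IntegerVector out_dim) {
  ConvDims d = make_dims(kd[2], out_dim[1], out_dim[2], xd[3], kd[3],
                         kd[0], kd[1], stride);
  fvec xf = as_fvec(x), kf = as_fvec(k), bf = as_fvec(bias), y;
  conv_bwd_data_core(xf, kf, d, y);
  const size_t N = (size_t)d.W * d.T * d.B;
  if (bias.size())
    for (size_t j = 0; j < N; ++j) {
      float *yj = &y[(size_t)d.Cin * j];
      for (int c = 0; c < d.Cin; ++c) yj[c] += bf[c];
    }
  return as_numeric(y, IntegerVector::create(d.Cin, d.W, d.T, xd[3]));
}

// ---- whole-network pass ----
//
// layers: integer matrix, one row per layer:
//   col 0: type (0 = conv, 1 = transposed conv)
//   col 1: kt, col 2: kw, col 3: Cin, col 4: Cout, col 5: stride
// weights: list alternating kernel and bias (k1, b1, k2, b2, ...); kernels of
// transposed layers are stored (kt, kw, Cout, Cin) as described above.

struct NetCtx {
  std::vector<fvec> act;     // act[0] = input, act[l] = output of layer l
  std::vector<ConvDims> dims;
};

static void net_forward(const IntegerMatrix &layers, const List &weights,
                        const fvec &x0, int W, int T, int B, NetCtx &ctx) {
  const int L = layers.nrow();
  ctx.act.resize(L + 1);
  ctx.dims.resize(L);
  ctx.act[0] = x0;
  int curC = layers(0, 3), curW = W, curT = T;
  if ((size_t)x0.size() != (size_t)curC * W * T * B)
    stop("input size does not match layer table");
  for (int l = 0; l < L; ++l) {
    const int type = layers(l, 0), kt = layers(l, 1), kw = layers(l, 2),
              Cin = layers(l, 3), Cout = layers(l, 4), s = layers(l, 5);
    if (Cin != curC) stop("layer %d channel mismatch", l + 1);
    fvec kf = as_fvec(weights[2 * l]);
    fvec bf = as_fvec(weights[2 * l + 1]);
    if (type == 0) {
      ConvDims d = make_dims(Cin, curW, curT, B, Cout, kt, kw, s);
      conv_fwd_core(ctx.act[l], kf, bf, d, ctx.act[l + 1]);
      ctx.dims[l] = d;
      curC = Cout; curW = d.Wo; curT = d.To;
    } else {
      const int Wout = curW * s, Tout = curT * s;
      ConvDims d = make_dims(Cout, Wout, Tout, B, Cin, kt, kw, s);
      conv_bwd_data_core(ctx.act[l], kf, d, ctx.act[l + 1]);
      const size_t N = (size_t)Wout * Tout * B;
      for (size_t j = 0; j < N; ++j) {
        float *yj = &ctx.act[l + 1][(size_t)Cout * j];
        for (int c = 0; c < Cout; ++c) yj[c] += bf[c];
      }
      ctx.dims[l] = d;
      curC = Cout; curW = Wout; curT = Tout;
    }
  }
}

static void out_shape(const IntegerMatrix &layers, const NetCtx &ctx,
                      int &outC, int &outW, int &outT) {
  const int L = layers.nrow();
  const ConvDims &dl = ctx.dims[L - 1];
  if (layers(L - 1, 0) == 0) { outC = dl.Cout; outW = dl.Wo; outT = dl.To; }
  else { outC = dl.Cin; outW = dl.W; outT = dl.T; }
}

// [[Rcpp::export]]
NumericVector cpp_srnet_fwd(IntegerMatrix layers, List weights,
                            NumericVector x, IntegerVector xd) {
  fvec x0 = as_fvec(x);
  NetCtx ctx;
  net_forward(layers, weights, x0, xd[1], xd[2], xd[3], ctx);
  int outC, outW, outT;
  out_shape(layers, ctx, outC, outW, outT);
  return as_numeric(ctx.act[layers.nrow()],
                    IntegerVector::create(outC, outW, outT, xd[3]));
}

// Forward + MSE loss + full backward.  Loss and gradients only count time
// samples t < t_valid of the network output (reflection padding of the input
// beyond t_valid carries no loss).
// [[Rcpp::export]]
List cpp_srnet_pass(IntegerMatrix layers, List weights,
                    NumericVector x, IntegerVector xd,
                    NumericVector target, int t_valid,
                    bool want_output) {
  const int L = layers.nrow();
  const int B = xd[3];
  fvec x0 = as_fvec(x);
  NetCtx ctx;
  net_forward(layers, weights, x0, xd[1], xd[2], xd[3], ctx);
  int outC, outW, outT;
  out_shape(layers, ctx, outC, outW, outT);
  if (t_valid < 0 || t_valid > outT) t_valid = outT;
  const size_t n_loss = (size_t)outC * outW * t_valid * B;
  if ((size_t)target.size() != n_loss) stop("target size mismatch");

  fvec dy((size_t)outC * outW * outT * B, 0.0f);
  double loss = 0.0;
  {
    const fvec &yl = ctx.act[L];
    size_t i = 0;
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < t_valid; ++t) {
        const size_t base = (size_t)outC * outW * ((size_t)t + (size_t)outT * b);
        for (int wc = 0; wc < outW * outC; ++wc) {
          const double diff = (double)yl[base + wc] - target[i];
          loss += diff * diff;
          dy[base + wc] = (float)(2.0 * diff / (double)n_loss);
          ++i;
        }
      }
    loss /= (double)n_loss;
  }

  List grads(2 * L);
  fvec cur = dy, nxt, dk, db;
  for (int l = L - 1; l >= 0; --l) {
    const int type = layers(l, 0);
    const ConvDims &d = ctx.dims[l];
    IntegerVector kdim = as<NumericVector>(weights[2 * l]).attr("dim");
    if (type == 0) {
      conv_bwd_weights_core(ctx.act[l], cur, d, dk, db);
      grads[2 * l] = as_numeric(dk, kdim);
      grads[2 * l + 1] = as_numeric(db, IntegerVector::create(d.Cout));
      if (l > 0) {
        fvec kf = as_fvec(weights[2 * l]);
        conv_bwd_data_core(cur, kf, d, nxt);
        cur.swap(nxt);
      }
    } else {
      // transposed layer: mirrored conv maps the big side down to the small
      // side; the weight gradient uses (x := gradient at the big side,
      // dy := the layer input act[l]).
      conv_bwd_weights_core(cur, ctx.act[l], d, dk, db);
      grads[2 * l] = as_numeric(dk, kdim);
      // the transposed layer's bias lives on the big (output) side
      fvec tb(d.Cin, 0.0f);
      const size_t N = (size_t)d.W * d.T * d.B;
      for (size_t j = 0; j < N; ++j) {
        const float *cj = &cur[(size_t)d.Cin * j];
        for (int c = 0; c < d.Cin; ++c) tb[c] += cj[c];
      }
      grads[2 * l + 1] = as_numeric(tb, IntegerVector::create(d.Cin));
      if (l > 0) {
        fvec kf = as_fvec(weights[2 * l]);
        conv_fwd_core(cur, kf, fvec(), d, nxt);
        cur.swap(nxt);
      }
    }
  }

  List out = List::create(_["loss"] = loss, _["grads"] = grads);
  if (want_output) {
    out["y"] = as_numeric(ctx.act[L],
                          IntegerVector::create(outC, outW, outT, B));
  }
  return out;
}
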