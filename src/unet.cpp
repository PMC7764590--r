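// UNet-Mini: a miniature fully-convolutional encoder-decoder for 3-class
// semantic segmentation, with manual backpropagation.
//
//   encoder stage k: conv 3x3 (stride 1, zero pad) -> BN -> ReLU -> maxpool 2x2
//   decoder stage j: x2 nearest upsample -> conv 3x3 -> additive skip -> BN -> ReLU
//   head:            conv 1x1 -> softmax
//
// Encoder widths 16/32/64/64, decoder widths 64/32/16/16.  Skip taps are
// taken post-ReLU, pre-pool; where the encoder is wider than the decoder
// only the leading decoder-width channels are added (parameter free).
// Activations are stored as (H*W x C) matrices, column-major pixel index
// p = row + col*H, so convolution reduces to im2col + one BLAS gemm.
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
// large activation/im2col buffers are allocated and freed once per layer
// per batch; keep them on the heap instead of mmap-ing every time
static const bool malloc_tuned = []() {
  mallopt(M_MMAP_THRESHOLD, 1 << 30);
  mallopt(M_TRIM_THRESHOLD, 1 << 30);
  return true;
}();
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::umat;

static const int ENC_W[4] = {16, 32, 64, 64};
static const int DEC_W[4] = {64, 32, 16, 16};
static const double BN_EPS = 1e-5;
static const double BN_MOM = 0.1;

struct ConvLayer {
  int cin, cout, k;          // k = 3 or 1
  mat W;                     // (cin*k*k) x cout
  rowvec b;
  mat dW;  rowvec db;
  mat mW, vW; rowvec mb, vb; // Adam moments
  void init(int ci, int co, int kk, std::mt19937_64& rng) {
    cin = ci; cout = co; k = kk;
    const int fan = ci * kk * kk;
    std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan));
    W.set_size(fan, co);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng);
    b.zeros(co);
    dW.zeros(fan, co); db.zeros(co);
    mW.zeros(fan, co); vW.zeros(fan, co); mb.zeros(co); vb.zeros(co);
  }
  int nparams() const { return (int)W.n_elem + (int)b.n_elem; }
};

struct BNLayer {
  int c;
  rowvec g, b, dg, db;
  rowvec mg, vg, mb2, vb2;
  rowvec rmean, rvar;        // running statistics (inference)
  rowvec bmean, bvar;        // cached batch statistics (training)
  void init(int cc) {
    c = cc;
    g.ones(c); b.zeros(c); dg.zeros(c); db.zeros(c);
    mg.zeros(c); vg.zeros(c); mb2.zeros(c); vb2.zeros(c);
    rmean.zeros(c); rvar.ones(c);
  }
  int nparams() const { return 2 * c; }
};

static mat im2col3(const mat& a, int H, int W) {
  const int C = (int)a.n_cols;
  mat K(H * W, C * 9, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        const int col = ch * 9 + (di + 1) * 3 + (dj + 1);
        const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        if (r1 <= r0) continue;
        for (int c = c0; c < c1; ++c)
          std::memcpy(K.colptr(col) + (arma::uword)c * H + r0,
                      a.colptr(ch) + (arma::uword)(c + dj) * H + (r0 + di),
                      sizeof(double) * (size_t)(r1 - r0));
      }
  return K;
}

static void col2im3_add(const mat& dK, int H, int W, int C, mat& dX) {
  for (int ch = 0; ch < C; ++ch)
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        const int col = ch * 9 + (di + 1) * 3 + (dj + 1);
        const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        for (int c = c0; c < c1; ++c) {
          double* dst = dX.colptr(ch) + (arma::uword)(c + dj) * H + (r0 + di);
          const double* src = dK.colptr(col) + (arma::uword)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) dst[r] += src[r];
        }
      }
}

static mat pool2(const mat& a, int H, int W, umat& mask) {
  const int H2 = H / 2, W2 = W / 2, C = (int)a.n_cols;
  mat out(H2 * (arma::uword)W2, C);
  mask.set_size(H2 * (arma::uword)W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = a.colptr(ch);
    double* dst = out.colptr(ch);
    arma::uword* msk = mask.colptr(ch);
    for (int c2 = 0; c2 < W2; ++c2) {
      const double* c0 = src + (arma::uword)(2 * c2) * H;
      const double* c1 = c0 + H;
      for (int r2 = 0; r2 < H2; ++r2) {
        const int r = 2 * r2;
        double bv = c0[r]; arma::uword best = (arma::uword)r + (arma::uword)(2 * c2) * H;
        if (c0[r + 1] > bv) { bv = c0[r + 1]; best = (arma::uword)(r + 1) + (arma::uword)(2 * c2) * H; }
        if (c1[r] > bv) { bv = c1[r]; best = (arma::uword)r + (arma::uword)(2 * c2 + 1) * H; }
        if (c1[r + 1] > bv) { bv = c1[r + 1]; best = (arma::uword)(r + 1) + (arma::uword)(2 * c2 + 1) * H; }
        dst[(arma::uword)r2 + (arma::uword)c2 * H2] = bv;
        msk[(arma::uword)r2 + (arma::uword)c2 * H2] = best;
      }
    }
  }
  return out;
}

static mat pool2_back(const mat& g, const umat& mask, int H, int W, int C) {
  mat out(H * (arma::uword)W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    double* dst = out.colptr(ch);
    const double* src = g.colptr(ch);
    const arma::uword* msk = mask.colptr(ch);
    for (arma::uword p = 0; p < g.n_rows; ++p) dst[msk[p]] += src[p];
  }
  return out;
}

static mat up2(const mat& a, int H2, int W2) {
  const int H = 2 * H2, C = (int)a.n_cols;
  mat out(H * (arma::uword)(2 * W2), C);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = a.colptr(ch);
    double* dst = out.colptr(ch);
    for (int c = 0; c < 2 * W2; ++c) {
      const double* sc = src + (arma::uword)(c / 2) * H2;
      double* dc = dst + (arma::uword)c * H;
      for (int r2 = 0; r2 < H2; ++r2) { dc[2 * r2] = sc[r2]; dc[2 * r2 + 1] = sc[r2]; }
    }
  }
  return out;
}

static mat up2_back(const mat& g, int H, int W) {
  const int H2 = H / 2, W2 = W / 2, C = (int)g.n_cols;
  mat out(H2 * (arma::uword)W2, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const double* src = g.colptr(ch);
    double* dst = out.colptr(ch);
    for (int c = 0; c < W; ++c) {
      const double* sc = src + (arma::uword)c * H;
      double* dc = dst + (arma::uword)(c / 2) * H2;
      for (int r2 = 0; r2 < H2; ++r2) dc[r2] += sc[2 * r2] + sc[2 * r2 + 1];
    }
  }
  return out;
}

struct UNet {
  ConvLayer conv[9];  // 0..3 encoder, 4..7 decoder, 8 head 1x1
  BNLayer bn[8];      // 0..3 encoder, 4..7 decoder
  long adam_t;

  explicit UNet(unsigned long seed) : adam_t(0) {
    std::mt19937_64 rng(seed);
    int cin = 1;
    for (int k = 0; k < 4; ++k) { conv[k].init(cin, ENC_W[k], 3, rng); bn[k].init(ENC_W[k]); cin = ENC_W[k]; }
    cin = ENC_W[3];
    for (int j = 0; j < 4; ++j) { conv[4 + j].init(cin, DEC_W[j], 3, rng); bn[4 + j].init(DEC_W[j]); cin = DEC_W[j]; }
    conv[8].init(DEC_W[3], 3, 1, rng);
  }

  int nparams() const {
    int n = 0;
    for (int i = 0; i < 9; ++i) n += conv[i].nparams();
    for (int i = 0; i < 8; ++i) n += bn[i].nparams();
    return n;
  }

  // ---- BN over a batch of per-sample matrices --------------------------
  static void bn_forward_train(BNLayer& L, std::vector<mat>& xs, std::vector<mat>& xhat) {
    const int N = (int)xs.size();
    const double m = (double)N * xs[0].n_rows;
    rowvec s(L.c, arma::fill::zeros), q(L.c, arma::fill::zeros);
    for (int i = 0; i < N; ++i) { s += arma::sum(xs[i], 0); q += arma::sum(arma::square(xs[i]), 0); }
    L.bmean = s / m;
    L.bvar = q / m - arma::square(L.bmean);
    L.bvar.transform([](double v) { return v < 0 ? 0.0 : v; });
    rowvec inv = 1.0 / arma::sqrt(L.bvar + BN_EPS);
    xhat.resize(N);
    for (int i = 0; i < N; ++i) {
      xhat[i] = xs[i];
      xhat[i].each_row() -= L.bmean;
      xhat[i].each_row() %= inv;
      xs[i] = xhat[i];
      xs[i].each_row() %= L.g;
      xs[i].each_row() += L.b;
    }
    L.rmean = (1.0 - BN_MOM) * L.rmean + BN_MOM * L.bmean;
    const double unb = m > 1 ? m / (m - 1.0) : 1.0;
    L.rvar = (1.0 - BN_MOM) * L.rvar + BN_MOM * (L.bvar * unb);
  }

  static void bn_forward_eval(const BNLayer& L, mat& x) {
    rowvec scale = L.g / arma::sqrt(L.rvar + BN_EPS);
    x.each_row() -= L.rmean;
    x.each_row() %= scale;
    x.each_row() += L.b;
  }

  static void bn_backward(BNLayer& L, std::vector<mat>& dy, const std::vector<mat>& xhat) {
    const int N = (int)dy.size();
    const double m = (double)N * dy[0].n_rows;
    rowvec dg(L.c, arma::fill::zeros), db(L.c, arma::fill::zeros);
    for (int i = 0; i < N; ++i) { dg += arma::sum(dy[i] % xhat[i], 0); db += arma::sum(dy[i], 0); }
    L.dg += dg; L.db += db;
    rowvec coef = L.g / arma::sqrt(L.bvar + BN_EPS);
    for (int i = 0; i < N; ++i) {
      mat t = xhat[i];
      t.each_row() %= (dg / m);
      dy[i].each_row() -= db / m;
      dy[i] -= t;
      dy[i].each_row() %= coef;
    }
  }

  // ---- inference forward (running BN stats), one sample ----------------
  mat forward_eval(const mat& x0, int H, int W) const {
    mat x = x0;
    mat taps[4];
    int h = H, w = W;
    umat mask;
    for (int k = 0; k < 4; ++k) {
      mat K = im2col3(x, h, w);
      x = K * conv[k].W;
      x.each_row() += conv[k].b;
      bn_forward_eval(bn[k], x);
      x.transform([](double v) { return v > 0 ? v : 0.0; });
      taps[k] = x;
      x = pool2(x, h, w, mask);
      h /= 2; w /= 2;
    }
    for (int j = 0; j < 4; ++j) {
      x = up2(x, h, w);
      h *= 2; w *= 2;
      mat K = im2col3(x, h, w);
      x = K * conv[4 + j].W;
      x.each_row() += conv[4 + j].b;
      const mat& tap = taps[3 - j];
      x += tap.cols(0, DEC_W[j] - 1);
      bn_forward_eval(bn[4 + j], x);
      x.transform([](double v) { return v > 0 ? v : 0.0; });
    }
    mat logits = x * conv[8].W;
    logits.each_row() += conv[8].b;
    // row-wise softmax
    arma::vec mx = arma::max(logits, 1);
    logits.each_col() -= mx;
    logits = arma::exp(logits);
    arma::vec sums = arma::sum(logits, 1);
    logits.each_col() /= sums;
    return logits;
  }

  void zero_grads() {
    for (int i = 0; i < 9; ++i) { conv[i].dW.zeros(); conv[i].db.zeros(); }
    for (int i = 0; i < 8; ++i) { bn[i].dg.zeros(); bn[i].db.zeros(); }
  }

  // ---- training forward + backward over a mini-batch -------------------
  // imgs: N matrices (H*W x 1); labels: N integer vectors (0 = ignore).
  double backward(const std::vector<mat>& imgs, const std::vector<arma::ivec>& labels,
                  int H, int W) {
    const int N = (int)imgs.size();
    zero_grads();

    std::vector<mat> x(N), taps[4], xhatE[4], pooled[4], outD[4], xhatD[4], probs(N);
    std::vector<umat> pmask[4];
    int hs[5], ws[5];
    hs[0] = H; ws[0] = W;

    // encoder
    for (int i = 0; i < N; ++i) x[i] = imgs[i];
    for (int k = 0; k < 4; ++k) {
      const int h = hs[k], w = ws[k];
      for (int i = 0; i < N; ++i) {
        mat K = im2col3(x[i], h, w);
        x[i] = K * conv[k].W;
        x[i].each_row() += conv[k].b;
      }
      bn_forward_train(bn[k], x, xhatE[k]);
      taps[k].resize(N); pmask[k].resize(N); pooled[k].resize(N);
      for (int i = 0; i < N; ++i) {
        x[i].transform([](double v) { return v > 0 ? v : 0.0; });
        taps[k][i] = x[i];
        x[i] = pool2(x[i], h, w, pmask[k][i]);
        pooled[k][i] = x[i];
      }
      hs[k + 1] = h / 2; ws[k + 1] = w / 2;
    }

    // decoder
    for (int j = 0; j < 4; ++j) {
      const int h2 = hs[4 - j], w2 = ws[4 - j];
      for (int i = 0; i < N; ++i) {
        mat u = up2(x[i], h2, w2);
        mat K = im2col3(u, 2 * h2, 2 * w2);
        x[i] = K * conv[4 + j].W;
        x[i].each_row() += conv[4 + j].b;
        x[i] += taps[3 - j][i].cols(0, DEC_W[j] - 1);
      }
      bn_forward_train(bn[4 + j], x, xhatD[j]);
      outD[j].resize(N);
      for (int i = 0; i < N; ++i) {
        x[i].transform([](double v) { return v > 0 ? v : 0.0; });
        outD[j][i] = x[i];
      }
    }

    // head + softmax cross-entropy (ignore label 0)
    double loss = 0.0;
    long nvalid = 0;
    for (int i = 0; i < N; ++i) {
      mat logits = x[i] * conv[8].W;
      logits.each_row() += conv[8].b;
      arma::vec mx = arma::max(logits, 1);
      logits.each_col() -= mx;
      logits = arma::exp(logits);
      arma::vec sums = arma::sum(logits, 1);
      logits.each_col() /= sums;
      probs[i] = logits;
      const arma::ivec& lab = labels[i];
      for (arma::uword p = 0; p < lab.n_elem; ++p)
        if (lab(p) > 0) {
          loss -= std::log(std::max(probs[i](p, lab(p) - 1), 1e-300));
          ++nvalid;
        }
    }
    if (nvalid == 0) Rcpp::stop("mini-batch has no labeled pixels");
    loss /= (double)nvalid;

    // dlogits
    std::vector<mat> g(N);
    for (int i = 0; i < N; ++i) {
      g[i] = std::move(probs[i]);
      const arma::ivec& lab = labels[i];
      for (arma::uword p = 0; p < lab.n_elem; ++p) {
        if (lab(p) > 0) g[i](p, lab(p) - 1) -= 1.0;
        else g[i].row(p).zeros();
      }
      g[i] /= (double)nvalid;
    }

    // head backward (1x1 conv: im2col is the identity)
    for (int i = 0; i < N; ++i) {
      conv[8].dW += outD[3][i].t() * g[i];
      conv[8].db += arma::sum(g[i], 0);
      g[i] = g[i] * conv[8].W.t();
    }

    // decoder backward, j = 3..0
    std::vector<mat> dtap[4];
    for (int k = 0; k < 4; ++k) {
      dtap[k].resize(N);
      for (int i = 0; i < N; ++i) dtap[k][i].zeros(taps[k][i].n_rows, taps[k][i].n_cols);
    }
    for (int j = 3; j >= 0; --j) {
      const int h2 = hs[4 - j], w2 = ws[4 - j];  // pre-upsample extent
      const int h = 2 * h2, w = 2 * w2;
      for (int i = 0; i < N; ++i) {
        g[i] %= arma::conv_to<mat>::from(outD[j][i] > 0);
        outD[j][i].reset();  // last use of this stage's activation
      }
      bn_backward(bn[4 + j], g, xhatD[j]);
      xhatD[j].clear();
      for (int i = 0; i < N; ++i) {
        // additive skip: leading DEC_W[j] channels of encoder tap 3-j
        dtap[3 - j][i].cols(0, DEC_W[j] - 1) += g[i];
        const mat& src = (j == 0) ? pooled[3][i] : outD[j - 1][i];
        mat u = up2(src, h2, w2);
        mat K = im2col3(u, h, w);
        conv[4 + j].dW += K.t() * g[i];
        conv[4 + j].db += arma::sum(g[i], 0);
        mat dK = g[i] * conv[4 + j].W.t();
        mat du(u.n_rows, u.n_cols, arma::fill::zeros);
        col2im3_add(dK, h, w, (int)u.n_cols, du);
        g[i] = up2_back(du, h, w);
      }
    }

    // encoder backward, k = 3..0 (g holds grad w.r.t. pooled[k])
    for (int k = 3; k >= 0; --k) {
      const int h = hs[k], w = ws[k];
      for (int i = 0; i < N; ++i) {
        g[i] = pool2_back(g[i], pmask[k][i], h, w, (int)taps[k][i].n_cols);
        g[i] += dtap[k][i];
        dtap[k][i].reset();
        g[i] %= arma::conv_to<mat>::from(taps[k][i] > 0);
        taps[k][i].reset();
        pmask[k][i].reset();
      }
      bn_backward(bn[k], g, xhatE[k]);
      xhatE[k].clear();
      for (int i = 0; i < N; ++i) {
        const mat& src = (k == 0) ? imgs[i] : pooled[k - 1][i];
        mat K = im2col3(src, h, w);
        conv[k].dW += K.t() * g[i];
        conv[k].db += arma::sum(g[i], 0);
        if (k > 0) {
          mat dK = g[i] * conv[k].W.t();
          mat dx(src.n_rows, src.n_cols, arma::fill::zeros);
          col2im3_add(dK, h, w, (int)src.n_cols, dx);
          g[i] = dx;
        }
      }
    }
    return loss;
  }

  void step(double lr, bool adam, double b1, double b2, double eps) {
    if (adam) {
      ++adam_t;
      const double c1 = 1.0 - std::pow(b1, (double)adam_t);
      const double c2 = 1.0 - std::pow(b2, (double)adam_t);
      for (int i = 0; i < 9; ++i) {
        ConvLayer& L = conv[i];
        L.mW = b1 * L.mW + (1 - b1) * L.dW; L.vW = b2 * L.vW + (1 - b2) * arma::square(L.dW);
        L.W -= lr * (L.mW / c1) / (arma::sqrt(L.vW / c2) + eps);
        L.mb = b1 * L.mb + (1 - b1) * L.db; L.vb = b2 * L.vb + (1 - b2) * arma::square(L.db);
        L.b -= lr * (L.mb / c1) / (arma::sqrt(L.vb / c2) + eps);
      }
      for (int i = 0; i < 8; ++i) {
        BNLayer& L = bn[i];
        L.mg = b1 * L.mg + (1 - b1) * L.dg; L.vg = b2 * L.vg + (1 - b2) * arma::square(L.dg);
        L.g -= lr * (L.mg / c1) / (arma::sqrt(L.vg / c2) + eps);
        L.mb2 = b1 * L.mb2 + (1 - b1) * L.db; L.vb2 = b2 * L.vb2 + (1 - b2) * arma::square(L.db);
        L.b -= lr * (L.mb2 / c1) / (arma::sqrt(L.vb2 / c2) + eps);
      }
    } else {
      for (int i = 0; i < 9; ++i) { conv[i].W -= lr * conv[i].dW; conv[i].b -= lr * conv[i].db; }
      for (int i = 0; i < 8; ++i) { bn[i].g -= lr * bn[i].dg; bn[i].b -= lr * bn[i].db; }
    }
  }
};

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_unet_create")]]
SEXP cpp_unet_create(int seed) {
  XPtr<UNet> p(new UNet((unsigned long)seed), true);
  return p;
}

// [[Rcpp::export(name = ".cpp_unet_nparams")]]
int cpp_unet_nparams(SEXP ptr) {
  XPtr<UNet> p(ptr);
  return p->nparams();
}

// parameter packing order: conv 1..9 (W column-major, then b), then BN 1..8
// (gamma, beta)
// [[Rcpp::export(name = ".cpp_unet_get_params")]]
NumericVector cpp_unet_get_params(SEXP ptr) {
  XPtr<UNet> p(ptr);
  std::vector<double> out;
  out.reserve(p->nparams());
  for (int i = 0; i < 9; ++i) {
    const ConvLayer& L = p->conv[i];
    out.insert(out.end(), L.W.begin(), L.W.end());
    out.insert(out.end(), L.b.begin(), L.b.end());
  }
  for (int i = 0; i < 8; ++i) {
    const BNLayer& L = p->bn[i];
    out.insert(out.end(), L.g.begin(), L.g.end());
    out.insert(out.end(), L.b.begin(), L.b.end());
  }
  return wrap(out);
}

// [[Rcpp::export(name = ".cpp_unet_set_params")]]
void cpp_unet_set_params(SEXP ptr, const NumericVector& v) {
  XPtr<UNet> p(ptr);
  if ((int)v.size() != p->nparams()) stop("parameter vector has wrong length");
  size_t at = 0;
  for (int i = 0; i < 9; ++i) {
    ConvLayer& L = p->conv[i];
    std::copy(v.begin() + at, v.begin() + at + L.W.n_elem, L.W.begin()); at += L.W.n_elem;
    std::copy(v.begin() + at, v.begin() + at + L.b.n_elem, L.b.begin()); at += L.b.n_elem;
  }
  for (int i = 0; i < 8; ++i) {
    BNLayer& L = p->bn[i];
    std::copy(v.begin() + at, v.begin() + at + L.g.n_elem, L.g.begin()); at += L.g.n_elem;
    std::copy(v.begin() + at, v.begin() + at + L.b.n_elem, L.b.begin()); at += L.b.n_elem;
  }
}

// [[Rcpp::export(name = ".cpp_unet_get_grads")]]
NumericVector cpp_unet_get_grads(SEXP ptr) {
  XPtr<UNet> p(ptr);
  std::vector<double> out;
  out.reserve(p->nparams());
  for (int i = 0; i < 9; ++i) {
    const ConvLayer& L = p->conv[i];
    out.insert(out.end(), L.dW.begin(), L.dW.end());
    out.insert(out.end(), L.db.begin(), L.db.end());
  }
  for (int i = 0; i < 8; ++i) {
    const BNLayer& L = p->bn[i];
    out.insert(out.end(), L.dg.begin(), L.dg.end());
    out.insert(out.end(), L.db.begin(), L.db.end());
  }
  return wrap(out);
}

// running BN statistics, packed mean then var per layer
// [[Rcpp::export(name = ".cpp_unet_get_running")]]
NumericVector cpp_unet_get_running(SEXP ptr) {
  XPtr<UNet> p(ptr);
  std::vector<double> out;
  for (int i = 0; i < 8; ++i) {
    const BNLayer& L = p->bn[i];
    out.insert(out.end(), L.rmean.begin(), L.rmean.end());
    out.insert(out.end(), L.rvar.begin(), L.rvar.end());
  }
  return wrap(out);
}

// [[Rcpp::export(name = ".cpp_unet_set_running")]]
void cpp_unet_set_running(SEXP ptr, const NumericVector& v) {
  XPtr<UNet> p(ptr);
  size_t at = 0;
  for (int i = 0; i < 8; ++i) {
    BNLayer& L = p->bn[i];
    if (at + 2 * L.c > (size_t)v.size()) stop("running-stats vector too short");
    std::copy(v.begin() + at, v.begin() + at + L.c, L.rmean.begin()); at += L.c;
    std::copy(v.begin() + at, v.begin() + at + L.c, L.rvar.begin()); at += L.c;
  }
}

static void check_extent(int H, int W) {
  if (H < 16 || W < 16 || H % 16 != 0 || W % 16 != 0)
    stop("input extent must be a positive multiple of 16 (got %dx%d)", H, W);
}

// imgs: numeric array (H, W, N) in [0,1]; returns probs (H, W, 3, N),
// inference mode (running BN statistics)
// [[Rcpp::export(name = ".cpp_unet_forward")]]
NumericVector cpp_unet_forward(SEXP ptr, const NumericVector& imgs) {
  XPtr<UNet> p(ptr);
  IntegerVector dim = imgs.attr("dim");
  if (dim.size() != 3) stop("imgs must be an H x W x N array");
  const int H = dim[0], W = dim[1], N = dim[2];
  check_extent(H, W);
  const arma::uword HW = (arma::uword)H * W;
  NumericVector out((R_xlen_t)HW * 3 * N);
  out.attr("dim") = IntegerVector::create(H, W, 3, N);
  for (int s = 0; s < N; ++s) {
    mat x0(HW, 1);
    std::copy(imgs.begin() + (size_t)s * HW, imgs.begin() + (size_t)(s + 1) * HW, x0.begin());
    mat probs = p->forward_eval(x0, H, W);
    for (int ch = 0; ch < 3; ++ch)
      std::copy(probs.colptr(ch), probs.colptr(ch) + HW,
                out.begin() + (size_t)s * HW * 3 + (size_t)ch * HW);
  }
  return out;
}

// one training-mode forward+backward pass; gradients stored in the model
// [[Rcpp::export(name = ".cpp_unet_backward")]]
double cpp_unet_backward(SEXP ptr, const NumericVector& imgs, const IntegerVector& labels) {
  XPtr<UNet> p(ptr);
  IntegerVector dim = imgs.attr("dim");
  if (dim.size() != 3) stop("imgs must be an H x W x N array");
  const int H = dim[0], W = dim[1], N = dim[2];
  check_extent(H, W);
  if (labels.size() != imgs.size()) stop("labels must match imgs in extent");
  const arma::uword HW = (arma::uword)H * W;
  std::vector<mat> xs(N);
  std::vector<arma::ivec> labs(N);
  for (int s = 0; s < N; ++s) {
    xs[s].set_size(HW, 1);
    std::copy(imgs.begin() + (size_t)s * HW, imgs.begin() + (size_t)(s + 1) * HW, xs[s].begin());
    labs[s].set_size(HW);
    for (arma::uword q = 0; q < HW; ++q) {
      int l = labels[(size_t)s * HW + q];
      if (l < 0 || l > 3) stop("label codes must be in 0..3");
      labs[s](q) = l;
    }
  }
  return p->backward(xs, labs, H, W);
}

// [[Rcpp::export(name = ".cpp_unet_step")]]
void cpp_unet_step(SEXP ptr, double lr, bool adam, double beta1, double beta2, double eps) {
  XPtr<UNet> p(ptr);
  p->step(lr, adam, beta1, beta2, eps);
}
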