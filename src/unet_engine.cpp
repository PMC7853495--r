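// Native single-precision engine for the encoder / dual-decoder U-Net.
//
// Tensors are stored as arma::fmat with shape (C, H*W*B); column index
// (b*H + y)*W + x, so the C channel values of one pixel are contiguous and
// consecutive x positions are consecutive columns.  Convolutions are im2col
// followed by a single sgemm per layer; all workspaces (im2col buffers,
// activations, gradients) are persistent class members so steady-state
// training performs no allocation.  The RNG (weight init, shuffling,
// dropout) is a private mt19937 seeded at construction: identical seeds give
// bit-identical runs.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>
#include <cmath>

#if defined(__x86_64__) || defined(__SSE2__)
#include <xmmintrin.h>
// Flush subnormal floats to zero inside the heavy numeric entry points:
// adapted weights drive many activations into the subnormal range, where
// hardware arithmetic slows down by an order of magnitude.  The previous
// FP state is restored on scope exit.
struct DenormGuard {
  unsigned int old_csr;
  DenormGuard() : old_csr(_mm_getcsr()) {
    _mm_setcsr(old_csr | 0x8040);   // FTZ (bit 15) | DAZ (bit 6)
  }
  ~DenormGuard() { _mm_setcsr(old_csr); }
};
#else
struct DenormGuard {};
#endif

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvLayer {
  int kh, kw, cin, cout;
  int pad_top, pad_left;     // "same" padding; even kernels pad bottom/right
  bool relu;
  arma::fmat W;              // cout x (kh*kw*cin), column = tap*cin + c
  arma::fvec b;
  arma::fmat mW, vW, dW;     // Adam state + gradient accumulator
  arma::fvec mb, vb, db;
  // persistent per-batch workspaces
  arma::fmat cols;           // im2col of the layer input
  arma::fmat out;            // post-activation output
  arma::fmat dcols, din, Wt; // backward buffers (+ cached transpose)
  int H = 0, Wd = 0, B = 0;

  ConvLayer(int kh_, int kw_, int cin_, int cout_, bool relu_)
    : kh(kh_), kw(kw_), cin(cin_), cout(cout_), relu(relu_) {
    pad_top  = (kh % 2 == 1) ? (kh - 1) / 2 : 0;
    pad_left = (kw % 2 == 1) ? (kw - 1) / 2 : 0;
    W.set_size(cout, kh * kw * cin);
    b.zeros(cout);
    dW.zeros(cout, kh * kw * cin);
    db.zeros(cout);
  }
  size_t n_par() const { return W.n_elem + b.n_elem; }
  void ensure_adam() {
    if (mW.n_elem == 0) {
      mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
      mb.zeros(b.n_elem);           vb.zeros(b.n_elem);
    }
  }
};

// --- im2col / col2im -------------------------------------------------------

// CC is the compile-time channel count (0 = generic); fixed-size copies let
// the compiler emit straight vector moves instead of memcpy calls, which
// matters because these loops run hundreds of thousands of times per batch.
template <int CC>
static void im2col_t(const arma::fmat& A, arma::fmat& K,
                     int Crt, int H, int Wd, int B,
                     int kh, int kw, int pt, int pl) {
  const int C = CC > 0 ? CC : Crt;
  const int ntap = kh * kw;
  K.set_size((size_t)ntap * C, (size_t)H * Wd * B);
  const float* a = A.memptr();
  float* k = K.memptr();
  const size_t colh = (size_t)ntap * C;
  for (int b = 0; b < B; ++b) {
    const size_t boff = (size_t)b * H * Wd;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < Wd; ++x) {
        float* dst = k + (boff + (size_t)y * Wd + x) * colh;
        int t = 0;
        for (int ky = 0; ky < kh; ++ky) {
          const int sy = y + ky - pt;
          for (int kx = 0; kx < kw; ++kx, ++t) {
            const int sx = x + kx - pl;
            float* d = dst + (size_t)t * C;
            if (sy < 0 || sy >= H || sx < 0 || sx >= Wd) {
              for (int c = 0; c < C; ++c) d[c] = 0.f;
            } else {
              const float* s = a + (boff + (size_t)sy * Wd + sx) * C;
              for (int c = 0; c < C; ++c) d[c] = s[c];
            }
          }
        }
      }
    }
  }
}

template <int CC>
static void col2im_add_t(const arma::fmat& K, arma::fmat& dA,
                         int Crt, int H, int Wd, int B,
                         int kh, int kw, int pt, int pl) {
  const int C = CC > 0 ? CC : Crt;
  dA.zeros(C, (size_t)H * Wd * B);
  const float* k = K.memptr();
  float* a = dA.memptr();
  const size_t colh = (size_t)kh * kw * C;
  for (int b = 0; b < B; ++b) {
    const size_t boff = (size_t)b * H * Wd;
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < Wd; ++x) {
        const float* src = k + (boff + (size_t)y * Wd + x) * colh;
        int t = 0;
        for (int ky = 0; ky < kh; ++ky) {
          const int sy = y + ky - pt;
          for (int kx = 0; kx < kw; ++kx, ++t) {
            const int sx = x + kx - pl;
            if (sy < 0 || sy >= H || sx < 0 || sx >= Wd) continue;
            float* d = a + (boff + (size_t)sy * Wd + sx) * C;
            const float* s = src + (size_t)t * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
}

#define DISPATCH_C(FN, CVAL, ...)                 \
  switch (CVAL) {                                 \
    case 1:   FN<1>(__VA_ARGS__); break;          \
    case 2:   FN<2>(__VA_ARGS__); break;          \
    case 16:  FN<16>(__VA_ARGS__); break;         \
    case 32:  FN<32>(__VA_ARGS__); break;         \
    case 64:  FN<64>(__VA_ARGS__); break;         \
    case 128: FN<128>(__VA_ARGS__); break;        \
    case 256: FN<256>(__VA_ARGS__); break;        \
    case 512: FN<512>(__VA_ARGS__); break;        \
    default:  FN<0>(__VA_ARGS__); break;          \
  }

static void im2col(const arma::fmat& A, arma::fmat& K,
                   int C, int H, int Wd, int B,
                   int kh, int kw, int pt, int pl) {
  DISPATCH_C(im2col_t, C, A, K, C, H, Wd, B, kh, kw, pt, pl)
}

static void col2im_add(const arma::fmat& K, arma::fmat& dA,
                       int C, int H, int Wd, int B,
                       int kh, int kw, int pt, int pl) {
  DISPATCH_C(col2im_add_t, C, K, dA, C, H, Wd, B, kh, kw, pt, pl)
}

// --- the network -----------------------------------------------------------

class UNet {
public:
  int insz, base, ndec;        // input H=W, base filters, number of decoders
  float drop_rate;
  static const int depth = 5;
  std::vector<ConvLayer> L;    // canonical ledger order
  int encA[5], encB[5];        // indices into L
  int upL[2][4], decA[2][4], decB[2][4], h3[2], h1[2];
  std::mt19937 rng;
  long adam_t = 0;

  // persistent per-batch intermediates
  arma::fmat pool_out[4];
  arma::Mat<unsigned char> pool_arg[4];
  arma::fmat up_buf[2][4], cat_buf[2][4], uback[2][4];
  arma::fmat drop_mask4, drop_mask5;
  arma::fmat dbottom, mpg[4], dskip[4];

  UNet(int insz_, int base_, int ndec_, double drop_, unsigned int seed)
    : insz(insz_), base(base_), ndec(ndec_), drop_rate((float)drop_), rng(seed) {
    if (insz % 16 != 0)
      stop("input_size must be divisible by 16 (four 2x2 poolings)");
    if (ndec < 1 || ndec > 2) stop("decoder count must be 1 or 2");
    if (base < 1) stop("base_filters must be positive");
    int f[5];
    for (int b = 0; b < 5; ++b) f[b] = base << b;
    auto add = [&](int kh, int kw, int ci, int co, bool relu) {
      L.emplace_back(kh, kw, ci, co, relu);
      return (int)L.size() - 1;
    };
    for (int b = 0; b < 5; ++b) {
      encA[b] = add(3, 3, b == 0 ? 1 : f[b - 1], f[b], true);
      encB[b] = add(3, 3, f[b], f[b], true);
    }
    for (int j = 0; j < ndec; ++j) {
      for (int l = 3; l >= 0; --l) {
        upL[j][l]  = add(2, 2, f[l + 1], f[l], true);
        decA[j][l] = add(3, 3, 2 * f[l], f[l], true);
        decB[j][l] = add(3, 3, f[l], f[l], true);
      }
      h3[j] = add(3, 3, f[0], 2, true);
      h1[j] = add(1, 1, 2, 1, false);   // logits; sigmoid applied in the loss
    }
    init_he();
  }

  // He (truncated-normal) initialization, the convention of the original
  // U-Net's weight scheme (Gaussian with std sqrt(2/N), N = fan-in);
  // truncation at 2 sigma with Keras' variance correction factor
  void init_he() {
    for (auto& ly : L) {
      const double fan_in = (double)ly.kh * ly.kw * ly.cin;
      const double sd = std::sqrt(2.0 / fan_in) / 0.87962566103423978;
      std::normal_distribution<float> N(0.f, (float)sd);
      for (size_t i = 0; i < ly.W.n_elem; ++i) {
        float v = N(rng);
        while (std::fabs(v) > 2.f * sd) v = N(rng);
        ly.W[i] = v;
      }
      ly.b.zeros();
    }
  }

  size_t n_par() const {
    size_t n = 0;
    for (const auto& ly : L) n += ly.n_par();
    return n;
  }

  const arma::fmat& logit(int j) const { return L[h1[j]].out; }

  // --- primitive ops -------------------------------------------------------

  void conv_fwd(ConvLayer& ly, const arma::fmat& in, int H, int Wd, int B) {
    im2col(in, ly.cols, ly.cin, H, Wd, B, ly.kh, ly.kw, ly.pad_top, ly.pad_left);
    ly.out = ly.W * ly.cols;
    const int M = ly.cout;
    float* o = ly.out.memptr();
    const float* bb = ly.b.memptr();
    const size_t nc = ly.out.n_cols;
    if (ly.relu) {
      for (size_t c = 0; c < nc; ++c, o += M)
        for (int m = 0; m < M; ++m) {
          const float v = o[m] + bb[m];
          o[m] = v > 0.f ? v : 0.f;
        }
    } else {
      for (size_t c = 0; c < nc; ++c, o += M)
        for (int m = 0; m < M; ++m) o[m] += bb[m];
    }
    ly.H = H; ly.Wd = Wd; ly.B = B;
  }

  // dout modified in place (relu mask); ly.din receives input gradient
  void conv_bwd(ConvLayer& ly, arma::fmat& dout, bool need_din) {
    if (ly.relu) {
      const float* o = ly.out.memptr();
      float* d = dout.memptr();
      const size_t n = dout.n_elem;
      for (size_t i = 0; i < n; ++i)
        if (o[i] <= 0.f) d[i] = 0.f;
    }
    // each layer is visited exactly once per backward pass, so assignment
    // (gemm straight into dW, no temporary, no prior zeroing) is safe
    ly.dW = dout * ly.cols.t();
    ly.db = arma::sum(dout, 1);
    if (need_din) {
      ly.Wt = ly.W.t();   // explicit transpose: faster sgemm for thin shapes
      ly.dcols = ly.Wt * dout;
      col2im_add(ly.dcols, ly.din, ly.cin, ly.H, ly.Wd, ly.B,
                 ly.kh, ly.kw, ly.pad_top, ly.pad_left);
    }
  }

  static void maxpool_fwd(const arma::fmat& in, arma::fmat& out,
                          arma::Mat<unsigned char>& arg,
                          int C, int H, int Wd, int B) {
    const int Ho = H / 2, Wo = Wd / 2;
    out.set_size(C, (size_t)Ho * Wo * B);
    arg.set_size(C, (size_t)Ho * Wo * B);
    const float* a = in.memptr();
    for (int b = 0; b < B; ++b)
      for (int oy = 0; oy < Ho; ++oy)
        for (int ox = 0; ox < Wo; ++ox) {
          const size_t oc = (size_t)b * Ho * Wo + (size_t)oy * Wo + ox;
          const float* p[4];
          for (int t = 0; t < 4; ++t) {
            const int sy = 2 * oy + t / 2, sx = 2 * ox + t % 2;
            p[t] = a + ((size_t)b * H * Wd + (size_t)sy * Wd + sx) * C;
          }
          float* o = out.colptr(oc);
          unsigned char* g = arg.colptr(oc);
          for (int c = 0; c < C; ++c) {
            int best = 0; float bv = p[0][c];
            for (int t = 1; t < 4; ++t)
              if (p[t][c] > bv) { bv = p[t][c]; best = t; }
            o[c] = bv; g[c] = (unsigned char)best;
          }
        }
  }

  static void maxpool_bwd(const arma::fmat& dout,
                          const arma::Mat<unsigned char>& arg,
                          arma::fmat& din, int C, int H, int Wd, int B) {
    const int Ho = H / 2, Wo = Wd / 2;
    din.zeros(C, (size_t)H * Wd * B);
    float* a = din.memptr();
    for (int b = 0; b < B; ++b)
      for (int oy = 0; oy < Ho; ++oy)
        for (int ox = 0; ox < Wo; ++ox) {
          const size_t oc = (size_t)b * Ho * Wo + (size_t)oy * Wo + ox;
          const float* d = dout.colptr(oc);
          const unsigned char* g = arg.colptr(oc);
          for (int c = 0; c < C; ++c) {
            const int t = g[c];
            const int sy = 2 * oy + t / 2, sx = 2 * ox + t % 2;
            a[((size_t)b * H * Wd + (size_t)sy * Wd + sx) * C + c] += d[c];
          }
        }
  }

  static void upsample_fwd(const arma::fmat& in, arma::fmat& out,
                           int C, int H, int Wd, int B) {
    const int Ho = 2 * H, Wo = 2 * Wd;
    out.set_size(C, (size_t)Ho * Wo * B);
    for (int b = 0; b < B; ++b)
      for (int oy = 0; oy < Ho; ++oy)
        for (int ox = 0; ox < Wo; ++ox) {
          const size_t oc = (size_t)b * Ho * Wo + (size_t)oy * Wo + ox;
          const size_t ic = (size_t)b * H * Wd + (size_t)(oy / 2) * Wd + ox / 2;
          std::memcpy(out.colptr(oc), in.colptr(ic), sizeof(float) * C);
        }
  }

  static void upsample_bwd(const arma::fmat& dout, arma::fmat& din,
                           int C, int H, int Wd, int B) {
    const int Ho = 2 * H, Wo = 2 * Wd;
    din.zeros(C, (size_t)H * Wd * B);
    for (int b = 0; b < B; ++b)
      for (int oy = 0; oy < Ho; ++oy)
        for (int ox = 0; ox < Wo; ++ox) {
          const size_t oc = (size_t)b * Ho * Wo + (size_t)oy * Wo + ox;
          const size_t ic = (size_t)b * H * Wd + (size_t)(oy / 2) * Wd + ox / 2;
          float* d = din.colptr(ic);
          const float* s = dout.colptr(oc);
          for (int c = 0; c < C; ++c) d[c] += s[c];
        }
  }

  void apply_dropout(arma::fmat& x, arma::fmat& m) {
    m.set_size(x.n_rows, x.n_cols);
    std::uniform_real_distribution<float> U(0.f, 1.f);
    const float scale = 1.f / (1.f - drop_rate);
    float* mp = m.memptr();
    float* xp = x.memptr();
    const size_t n = m.n_elem;
    for (size_t i = 0; i < n; ++i) {
      mp[i] = (U(rng) >= drop_rate) ? scale : 0.f;
      xp[i] *= mp[i];
    }
  }

  // --- full forward --------------------------------------------------------

  // X: (1, insz*insz*B).  Leaves logits in L[h1[j]].out.
  void forward(const arma::fmat& X, int B, bool train) {
    int f[5]; for (int b = 0; b < 5; ++b) f[b] = base << b;
    int H = insz;
    const arma::fmat* cur = &X;
    for (int b = 0; b < 5; ++b) {
      conv_fwd(L[encA[b]], *cur, H, H, B);
      conv_fwd(L[encB[b]], L[encA[b]].out, H, H, B);
      arma::fmat& o = L[encB[b]].out;
      if (train && drop_rate > 0.f && (b == 3 || b == 4))
        apply_dropout(o, b == 3 ? drop_mask4 : drop_mask5);
      if (b < 4) {
        maxpool_fwd(o, pool_out[b], pool_arg[b], f[b], H, H, B);
        cur = &pool_out[b];
        H /= 2;
      }
    }
    for (int j = 0; j < ndec; ++j) {
      const arma::fmat* d = &L[encB[4]].out;
      int Hl = insz / 16;
      for (int l = 3; l >= 0; --l) {
        upsample_fwd(*d, up_buf[j][l], f[l + 1], Hl, Hl, B);
        Hl *= 2;
        conv_fwd(L[upL[j][l]], up_buf[j][l], Hl, Hl, B);
        arma::fmat& cat = cat_buf[j][l];
        cat.set_size((size_t)2 * f[l], L[upL[j][l]].out.n_cols);
        cat.rows(0, f[l] - 1) = L[encB[l]].out;
        cat.rows(f[l], 2 * f[l] - 1) = L[upL[j][l]].out;
        conv_fwd(L[decA[j][l]], cat, Hl, Hl, B);
        conv_fwd(L[decB[j][l]], L[decA[j][l]].out, Hl, Hl, B);
        d = &L[decB[j][l]].out;
      }
      conv_fwd(L[h3[j]], *d, insz, insz, B);
      conv_fwd(L[h1[j]], L[h3[j]].out, insz, insz, B);
    }
  }

  // dlogit[j] must hold dL/dlogit for each decoder.
  void backward(int B, arma::fmat dlogit[2]) {
    int f[5]; for (int b = 0; b < 5; ++b) f[b] = base << b;
    for (int j = 0; j < ndec; ++j) {
      conv_bwd(L[h1[j]], dlogit[j], true);
      conv_bwd(L[h3[j]], L[h1[j]].din, true);
      arma::fmat* dd = &L[h3[j]].din;
      int Hl = insz;
      for (int l = 0; l <= 3; ++l) {
        conv_bwd(L[decB[j][l]], *dd, true);
        conv_bwd(L[decA[j][l]], L[decB[j][l]].din, true);
        arma::fmat& dcat = L[decA[j][l]].din;
        if (j == 0) dskip[l] = dcat.rows(0, f[l] - 1);
        else        dskip[l] += dcat.rows(0, f[l] - 1);
        up_buf[j][l] = dcat.rows(f[l], 2 * f[l] - 1);  // reuse as dout buffer
        conv_bwd(L[upL[j][l]], up_buf[j][l], true);
        upsample_bwd(L[upL[j][l]].din, uback[j][l], f[l + 1],
                     Hl / 2, Hl / 2, B);
        dd = &uback[j][l];
        Hl /= 2;
      }
      if (j == 0) dbottom = *dd; else dbottom += *dd;
    }
    // encoder backward
    if (drop_rate > 0.f && drop_mask5.n_elem == dbottom.n_elem)
      dbottom %= drop_mask5;
    arma::fmat* dcur = &dbottom;
    int H = insz / 16;
    for (int b = 4; b >= 0; --b) {
      if (b < 4) {
        maxpool_bwd(*dcur, pool_arg[b], mpg[b], f[b], 2 * H, 2 * H, B);
        H *= 2;
        mpg[b] += dskip[b];
        if (b == 3 && drop_rate > 0.f && drop_mask4.n_elem == mpg[b].n_elem)
          mpg[b] %= drop_mask4;
        dcur = &mpg[b];
      }
      conv_bwd(L[encB[b]], *dcur, true);
      conv_bwd(L[encA[b]], L[encB[b]].din, b > 0);
      dcur = &L[encA[b]].din;
    }
  }

  void zero_grad() { for (auto& ly : L) { ly.dW.zeros(); ly.db.zeros(); } }

  // free the large per-batch workspaces (weights and Adam state are kept);
  // buffers reallocate transparently on the next forward/backward pass
  void release_workspaces() {
    for (auto& ly : L) {
      ly.cols.reset(); ly.out.reset(); ly.dcols.reset(); ly.din.reset();
      ly.Wt.reset(); ly.dW.reset(); ly.db.reset();
      ly.dW.zeros(ly.cout, (size_t)ly.kh * ly.kw * ly.cin);
      ly.db.zeros(ly.cout);
    }
    for (int b = 0; b < 4; ++b) {
      pool_out[b].reset(); pool_arg[b].reset(); mpg[b].reset();
      dskip[b].reset();
    }
    for (int j = 0; j < 2; ++j)
      for (int l = 0; l < 4; ++l) {
        up_buf[j][l].reset(); cat_buf[j][l].reset(); uback[j][l].reset();
      }
    drop_mask4.reset(); drop_mask5.reset(); dbottom.reset();
  }

  void adam_step(float lr, float b1, float b2, float eps) {
    ++adam_t;
    const float c1 = 1.f - std::pow(b1, (float)adam_t);
    const float c2 = 1.f - std::pow(b2, (float)adam_t);
    for (auto& ly : L) {
      ly.ensure_adam();
      auto upd = [&](float* w, const float* g, float* m, float* v, size_t n) {
        for (size_t i = 0; i < n; ++i) {
          const float gi = g[i];
          m[i] = b1 * m[i] + (1.f - b1) * gi;
          v[i] = b2 * v[i] + (1.f - b2) * gi * gi;
          w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
        }
      };
      upd(ly.W.memptr(), ly.dW.memptr(), ly.mW.memptr(), ly.vW.memptr(),
          ly.W.n_elem);
      upd(ly.b.memptr(), ly.db.memptr(), ly.mb.memptr(), ly.vb.memptr(),
          ly.b.n_elem);
    }
  }
};

// --- loss helpers ----------------------------------------------------------

// numerically stable mean BCE from logits; also fills dL/dz = sigmoid(z) - t
static double bce_from_logits(const arma::fmat& z, const arma::fmat& t,
                              arma::fmat* dz) {
  double s = 0.0;
  if (dz) dz->set_size(z.n_rows, z.n_cols);
  const size_t n = z.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const float zi = z[i], ti = t[i];
    s += std::fmax(zi, 0.f) - zi * ti + std::log1p(std::exp(-std::fabs(zi)));
    if (dz) (*dz)[i] = 1.f / (1.f + std::exp(-zi)) - ti;
  }
  return s / (double)n;
}

// --- data marshalling ------------------------------------------------------

// Xf: (npix, n) float, one column per image; copy images idx[from..from+count)
// into a (1, npix*count) row tensor.
static void gather_images(const arma::fmat& Xf, const std::vector<int>& idx,
                          size_t from, size_t count, arma::fmat& out) {
  const size_t npix = Xf.n_rows;
  out.set_size(1, npix * count);
  for (size_t k = 0; k < count; ++k)
    std::memcpy(out.memptr() + k * npix, Xf.colptr(idx[from + k]),
                sizeof(float) * npix);
}

static arma::fmat to_fmat_t(const NumericMatrix& X) {
  // (n, npix) double -> (npix, n) float, one column per image
  arma::fmat out(X.ncol(), X.nrow());
  for (int i = 0; i < X.nrow(); ++i)
    for (int j = 0; j < X.ncol(); ++j)
      out(j, i) = (float)X(i, j);
  return out;
}

// --- exported API ----------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_unet_create(int input_size, int base_filters, int n_decoders,
                     double dropout_rate, int seed) {
  XPtr<UNet> p(new UNet(input_size, base_filters, n_decoders, dropout_rate,
                        (unsigned int)seed), true);
  return p;
}

// [[Rcpp::export]]
double cpp_unet_nparams(SEXP ptr) {
  XPtr<UNet> p(ptr);
  return (double)p->n_par();
}

// [[Rcpp::export]]
DataFrame cpp_unet_layers(SEXP ptr) {
  XPtr<UNet> p(ptr);
  const size_t n = p->L.size();
  IntegerVector kh(n), kw(n), cin(n), cout(n);
  NumericVector np(n);
  for (size_t i = 0; i < n; ++i) {
    kh[i] = p->L[i].kh; kw[i] = p->L[i].kw;
    cin[i] = p->L[i].cin; cout[i] = p->L[i].cout;
    np[i] = (double)p->L[i].n_par();
  }
  return DataFrame::create(_["kh"] = kh, _["kw"] = kw, _["c_in"] = cin,
                           _["c_out"] = cout, _["params"] = np);
}

// [[Rcpp::export]]
NumericVector cpp_unet_get_weights(SEXP ptr) {
  XPtr<UNet> p(ptr);
  NumericVector w((R_xlen_t)p->n_par());
  R_xlen_t k = 0;
  for (auto& ly : p->L) {
    for (size_t i = 0; i < ly.W.n_elem; ++i) w[k++] = ly.W[i];
    for (size_t i = 0; i < ly.b.n_elem; ++i) w[k++] = ly.b[i];
  }
  return w;
}

// [[Rcpp::export]]
void cpp_unet_set_weights(SEXP ptr, NumericVector w) {
  XPtr<UNet> p(ptr);
  if ((size_t)w.size() != p->n_par()) stop("weight vector length mismatch");
  R_xlen_t k = 0;
  for (auto& ly : p->L) {
    for (size_t i = 0; i < ly.W.n_elem; ++i) ly.W[i] = (float)w[k++];
    for (size_t i = 0; i < ly.b.n_elem; ++i) ly.b[i] = (float)w[k++];
  }
}

// [[Rcpp::export]]
List cpp_unet_predict(SEXP ptr, NumericMatrix X, int batch_size) {
  DenormGuard fp_guard;
  XPtr<UNet> p(ptr);
  const int n = X.nrow();
  const size_t npix = (size_t)p->insz * p->insz;
  if ((size_t)X.ncol() != npix) stop("pixel count mismatch");
  arma::fmat Xf = to_fmat_t(X);
  std::vector<int> idx(n); for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<NumericMatrix> outs;
  for (int j = 0; j < p->ndec; ++j) outs.emplace_back(n, (int)npix);
  arma::fmat xb;
  for (int s = 0; s < n; s += batch_size) {
    const int B = std::min(batch_size, n - s);
    gather_images(Xf, idx, s, B, xb);
    p->forward(xb, B, false);
    for (int j = 0; j < p->ndec; ++j) {
      const arma::fmat& z = p->logit(j);
      for (int k = 0; k < B; ++k)
        for (size_t q = 0; q < npix; ++q)
          outs[j](s + k, (int)q) =
            1.0 / (1.0 + std::exp(-(double)z[(size_t)k * npix + q]));
    }
  }
  p->release_workspaces();
  List res;
  for (int j = 0; j < p->ndec; ++j) res.push_back(outs[j]);
  return res;
}

// targets: list with one (n, npix) matrix per decoder; weights: per decoder
// [[Rcpp::export]]
List cpp_unet_eval(SEXP ptr, NumericMatrix X, List targets,
                   NumericVector weights, int batch_size, double threshold) {
  DenormGuard fp_guard;
  XPtr<UNet> p(ptr);
  const int n = X.nrow();
  const size_t npix = (size_t)p->insz * p->insz;
  arma::fmat Xf = to_fmat_t(X);
  std::vector<arma::fmat> Tf;
  for (int j = 0; j < p->ndec; ++j)
    Tf.push_back(to_fmat_t(as<NumericMatrix>(targets[j])));
  std::vector<int> idx(n); for (int i = 0; i < n; ++i) idx[i] = i;
  double loss = 0.0;
  std::vector<double> bce(p->ndec, 0.0), dice(p->ndec, 0.0), acc(p->ndec, 0.0);
  arma::fmat xb, tb;
  const float zthr = (float)std::log(threshold / (1.0 - threshold));
  for (int s = 0; s < n; s += batch_size) {
    const int B = std::min(batch_size, n - s);
    gather_images(Xf, idx, s, B, xb);
    p->forward(xb, B, false);
    for (int j = 0; j < p->ndec; ++j) {
      gather_images(Tf[j], idx, s, B, tb);
      bce[j] += bce_from_logits(p->logit(j), tb, nullptr) * B;
      const arma::fmat& z = p->logit(j);
      for (int k = 0; k < B; ++k) {
        const float* zp = z.memptr() + (size_t)k * npix;
        const float* tp = tb.memptr() + (size_t)k * npix;
        size_t a = 0, bset = 0, o = 0, agree = 0;
        for (size_t q = 0; q < npix; ++q) {
          // logits > zthr  <=>  sigmoid(logit) > threshold
          const bool pa = zp[q] > zthr, tbq = tp[q] > (float)threshold;
          a += pa; bset += tbq; o += (pa && tbq); agree += (pa == tbq);
        }
        dice[j] += (a + bset == 0) ? 1.0 : 2.0 * (double)o / (double)(a + bset);
        acc[j] += (double)agree / (double)npix;
      }
    }
  }
  for (int j = 0; j < p->ndec; ++j) {
    bce[j] /= n; dice[j] /= n; acc[j] /= n;
    loss += weights[j] * bce[j];
  }
  p->release_workspaces();
  return List::create(_["loss"] = loss, _["bce"] = wrap(bce),
                      _["dice"] = wrap(dice), _["accuracy"] = wrap(acc));
}

// Single forward/backward pass; returns the loss and the flattened gradient
// in the same order as cpp_unet_get_weights.  Used by gradient-check tests.
// [[Rcpp::export]]
List cpp_unet_lossgrad(SEXP ptr, NumericMatrix X, List targets,
                       NumericVector weights) {
  DenormGuard fp_guard;
  XPtr<UNet> p(ptr);
  const int B = X.nrow();
  const size_t npix = (size_t)p->insz * p->insz;
  if ((size_t)X.ncol() != npix) stop("pixel count mismatch");
  arma::fmat Xf = to_fmat_t(X);
  std::vector<int> idx(B); for (int i = 0; i < B; ++i) idx[i] = i;
  arma::fmat xb, tb;
  gather_images(Xf, idx, 0, B, xb);
  // gradients are overwritten, not accumulated; no zeroing needed
  p->forward(xb, B, true);
  double loss = 0.0;
  arma::fmat dlog[2];
  for (int j = 0; j < p->ndec; ++j) {
    arma::fmat Tf = to_fmat_t(as<NumericMatrix>(targets[j]));
    gather_images(Tf, idx, 0, B, tb);
    const double lj = bce_from_logits(p->logit(j), tb, &dlog[j]);
    loss += weights[j] * lj;
    dlog[j] *= (float)(weights[j] / (double)tb.n_elem);
  }
  p->backward(B, dlog);
  NumericVector g((R_xlen_t)p->n_par());
  R_xlen_t k = 0;
  for (auto& ly : p->L) {
    for (size_t i = 0; i < ly.dW.n_elem; ++i) g[k++] = ly.dW[i];
    for (size_t i = 0; i < ly.db.n_elem; ++i) g[k++] = ly.db[i];
  }
  return List::create(_["loss"] = loss, _["gradient"] = g);
}

// [[Rcpp::export]]
List cpp_unet_train(SEXP ptr, NumericMatrix X, List targets,
                    NumericMatrix Xval, List val_targets,
                    NumericVector weights, int epochs, int batch_size,
                    double lr, double beta1, double beta2, double adam_eps,
                    int checkpoint_every, double threshold, bool verbose,
                    int validate_every) {
  DenormGuard fp_guard;
  XPtr<UNet> p(ptr);
  const int n = X.nrow();
  const int nval = Xval.nrow();
  const size_t npix = (size_t)p->insz * p->insz;
  if ((size_t)X.ncol() != npix) stop("pixel count mismatch");
  arma::fmat Xf = to_fmat_t(X);
  std::vector<arma::fmat> Tf;
  for (int j = 0; j < p->ndec; ++j)
    Tf.push_back(to_fmat_t(as<NumericMatrix>(targets[j])));

  std::vector<int> idx(n); for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> h_epoch, h_train_loss, h_val_loss;
  std::vector<std::vector<double>> h_val_dice(p->ndec), h_val_acc(p->ndec);
  List checkpoints;

  arma::fmat xb, tb;
  arma::fmat dlog[2];
  for (int ep = 1; ep <= epochs; ++ep) {
    // Fisher-Yates with the engine RNG (deterministic given the seed)
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> U(0, i);
      std::swap(idx[i], idx[U(p->rng)]);
    }
    double ep_loss = 0.0;
    long nb = 0;
    for (int s = 0; s < n; s += batch_size) {
      const int B = std::min(batch_size, n - s);
      gather_images(Xf, idx, s, B, xb);
      // gradients are overwritten, not accumulated; no zeroing needed
      p->forward(xb, B, true);
      double batch_loss = 0.0;
      for (int j = 0; j < p->ndec; ++j) {
        gather_images(Tf[j], idx, s, B, tb);
        const double lj = bce_from_logits(p->logit(j), tb, &dlog[j]);
        batch_loss += weights[j] * lj;
        dlog[j] *= (float)(weights[j] / (double)tb.n_elem);
      }
      p->backward(B, dlog);
      p->adam_step((float)lr, (float)beta1, (float)beta2, (float)adam_eps);
      ep_loss += batch_loss; ++nb;
      if (s == 0) Rcpp::checkUserInterrupt();
    }
    ep_loss /= nb;
    h_epoch.push_back(ep);
    h_train_loss.push_back(ep_loss);
    double vloss = NA_REAL;
    std::vector<double> vdice(p->ndec, NA_REAL), vacc(p->ndec, NA_REAL);
    if (nval > 0 && (validate_every <= 1 || ep % validate_every == 0 ||
                     ep == epochs)) {
      List ev = cpp_unet_eval(ptr, Xval, val_targets, weights, batch_size,
                              threshold);
      vloss = as<double>(ev["loss"]);
      NumericVector d = ev["dice"], a = ev["accuracy"];
      for (int j = 0; j < p->ndec; ++j) { vdice[j] = d[j]; vacc[j] = a[j]; }
    }
    h_val_loss.push_back(vloss);
    for (int j = 0; j < p->ndec; ++j) {
      h_val_dice[j].push_back(vdice[j]);
      h_val_acc[j].push_back(vacc[j]);
    }
    if (checkpoint_every > 0 && ep % checkpoint_every == 0) {
      checkpoints.push_back(List::create(
        _["epoch"] = ep, _["weights"] = cpp_unet_get_weights(ptr),
        _["val_loss"] = vloss, _["val_dice"] = wrap(vdice)));
    }
    if (verbose)
      Rcout << "epoch " << ep << " loss " << ep_loss
            << " val_loss " << vloss << "\n";
  }
  List hist = List::create(
    _["epoch"] = wrap(h_epoch), _["train_loss"] = wrap(h_train_loss),
    _["val_loss"] = wrap(h_val_loss));
  List vd, va;
  for (int j = 0; j < p->ndec; ++j) { vd.push_back(wrap(h_val_dice[j]));
                                      va.push_back(wrap(h_val_acc[j])); }
  p->release_workspaces();
  return List::create(_["history"] = hist, _["val_dice"] = vd,
                      _["val_accuracy"] = va, _["checkpoints"] = checkpoints);
}
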