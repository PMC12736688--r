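// Enhanced time-series transformer for phenology-aware rice mapping.
//
// Implemented from first principles (no deep-learning framework is used):
// forward pass, hand-derived backward pass, and AdamW optimization, all
// templated on the element type -- float for CPU training throughput,
// double for inference and for finite-difference gradient verification.
//
// Architecture (per sample: T timesteps, C feature channels):
//   three-branch feature embedding (affine / two-layer MLP / pairwise
//   feature interactions) -> channel attention -> d_model tokens
//   [+ optional 3D-conv spatio-spectral patch branch, added]
//   + adaptive positional encoding (phenological-stage embedding + learnable
//     projection of sinusoidal DOY features)
//   -> post-LN transformer encoder (n_layers, n_heads, GELU feed-forward)
//   -> phenology attention gate (sigmoid MLP on [token, positional context])
//   -> masked global average pooling -> two-layer MLP head -> softmax.
//
// GELU uses the sigmoid approximation x * sigmoid(1.702 x); the backward
// pass matches it exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <map>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

struct Config {
  int C, d, heads, layers, dff, db, hb, rca, hg, dh, ncls;
  int patch, bands, filt;   // patch branch geometry
  double dropout;
  double brk1, brk2;        // phenological stage bin edges (DOY)
  bool multibranch, adaptive_pos, gate, patchbranch;
  int P2;                   // C*(C+1)/2 pairwise interaction terms
  int dk;                   // d / heads
};

static Config parse_config(const List& cfg) {
  Config c;
  c.C = cfg["n_channels"]; c.d = cfg["d_model"]; c.heads = cfg["n_heads"];
  c.layers = cfg["n_layers"]; c.dff = cfg["d_ff"];
  c.db = cfg["branch_dim"]; c.hb = cfg["branch_hidden"];
  int red = cfg["ca_reduction"];
  c.rca = std::max(2, (3 * c.db) / red);
  c.hg = cfg["gate_hidden"]; c.dh = cfg["head_hidden"];
  c.ncls = cfg["n_classes"];
  c.dropout = cfg["dropout"];
  Rcpp::NumericVector brk = cfg["stage_breaks"];
  c.brk1 = brk[0]; c.brk2 = brk[1];
  c.multibranch = cfg["embed_multibranch"];
  c.adaptive_pos = cfg["pos_adaptive"];
  c.gate = cfg["gate_enabled"];
  c.patchbranch = cfg["use_patch_branch"];
  c.patch = cfg["patch_size"]; c.bands = cfg["n_bands"];
  c.filt = cfg["conv_filters"];
  c.P2 = c.C * (c.C + 1) / 2;
  if (c.d % c.heads != 0) Rcpp::stop("d_model must be divisible by n_heads");
  c.dk = c.d / c.heads;
  return c;
}

struct ParamDef { std::string name; int r, cdim; };

static std::vector<ParamDef> make_layout(const Config& c) {
  std::vector<ParamDef> L;
  auto add = [&](const std::string& n, int r, int cc) { L.push_back({n, r, cc}); };
  if (c.multibranch) {
    add("Wa", c.C, c.db);  add("ba", 1, c.db);
    add("Wb1", c.C, c.hb); add("bb1", 1, c.hb);
    add("Wb2", c.hb, c.db); add("bb2", 1, c.db);
    add("Wc", c.P2, c.db); add("bc", 1, c.db);
    add("Ws1", 3 * c.db, c.rca); add("bs1", 1, c.rca);
    add("Ws2", c.rca, 3 * c.db); add("bs2", 1, 3 * c.db);
    add("We", 3 * c.db, c.d); add("be", 1, c.d);
  } else {
    add("Wlin", c.C, c.d); add("blin", 1, c.d);
  }
  if (c.patchbranch) {
    int ppb = c.patch * c.patch * c.bands;
    add("K1", 27, c.filt); add("bk1", 1, c.filt);
    add("K2", 27 * c.filt, c.filt); add("bk2", 1, c.filt);
    add("Wf", ppb * c.filt, c.d); add("bf", 1, c.d);
  }
  if (c.adaptive_pos) {
    add("Eseason", 3, c.d);
    add("Wp", c.d, c.d); add("bp", 1, c.d);
  }
  for (int l = 0; l < c.layers; ++l) {
    std::string p = "L" + std::to_string(l) + "_";
    add(p + "Wq", c.d, c.d); add(p + "bq", 1, c.d);
    add(p + "Wk", c.d, c.d); add(p + "bk", 1, c.d);
    add(p + "Wv", c.d, c.d); add(p + "bv", 1, c.d);
    add(p + "Wo", c.d, c.d); add(p + "bo", 1, c.d);
    add(p + "g1", 1, c.d);   add(p + "be1", 1, c.d);
    add(p + "Wf1", c.d, c.dff); add(p + "bf1", 1, c.dff);
    add(p + "Wf2", c.dff, c.d); add(p + "bf2", 1, c.d);
    add(p + "g2", 1, c.d);   add(p + "be2", 1, c.d);
  }
  if (c.gate) {
    add("Wg1", 2 * c.d, c.hg); add("bg1", 1, c.hg);
    add("Wg2", c.hg, c.d); add("bg2", 1, c.d);
  }
  add("Wh1", c.d, c.dh); add("bh1", 1, c.dh);
  add("Wh2", c.dh, c.ncls); add("bh2", 1, c.ncls);
  return L;
}

// ---------------------------------------------------------------------------
// parameter pack: named matrices backed by one flat vector ordering
template <typename T>
struct Params {
  std::vector<Mat<T>> M;
  std::map<std::string, int> index;
  const Mat<T>& operator[](const std::string& n) const { return M[index.at(n)]; }
  Mat<T>& operator[](const std::string& n) { return M[index.at(n)]; }
};

template <typename T>
static Params<T> unflatten(const std::vector<ParamDef>& L, const arma::vec& theta) {
  Params<T> P;
  size_t off = 0;
  for (size_t i = 0; i < L.size(); ++i) {
    Mat<T> m(L[i].r, L[i].cdim);
    for (size_t k = 0; k < m.n_elem; ++k) m(k) = (T)theta(off + k);
    P.M.push_back(std::move(m));
    P.index[L[i].name] = (int)i;
    off += (size_t)L[i].r * L[i].cdim;
  }
  if (off != theta.n_elem) Rcpp::stop("parameter vector length mismatch");
  return P;
}

template <typename T>
static arma::vec flatten(const std::vector<ParamDef>& L, const Params<T>& P) {
  size_t tot = 0;
  for (auto& d : L) tot += (size_t)d.r * d.cdim;
  arma::vec out(tot);
  size_t off = 0;
  for (size_t i = 0; i < L.size(); ++i) {
    const Mat<T>& m = P.M[i];
    for (size_t k = 0; k < m.n_elem; ++k) out(off + k) = (double)m(k);
    off += m.n_elem;
  }
  return out;
}

template <typename T>
static Params<T> zeros_like(const Params<T>& P) {
  Params<T> G; G.index = P.index;
  for (auto& m : P.M) G.M.push_back(zeros<Mat<T>>(m.n_rows, m.n_cols));
  return G;
}

// ---------------------------------------------------------------------------
// activations
//
// fexp: element type dispatch onto the libm exponential (expf on the float
// path, which gcc auto-vectorizes through libmvec in the fused loops below)
static inline double fexp(double x) { return std::exp(x); }
static inline float fexp(float x) { return std::exp(x); }

template <typename T> static Mat<T> sigm(const Mat<T>& x) {
  Mat<T> out(x.n_rows, x.n_cols);
  const T* px = x.memptr(); T* po = out.memptr();
  for (size_t k = 0; k < x.n_elem; ++k)
    po[k] = (T)1 / ((T)1 + fexp(-px[k]));
  return out;
}
// gelu(x) = x * sigmoid(1.702 x); returns value, stores the sigmoid for bwd
template <typename T>
static Mat<T> gelu_fwd(const Mat<T>& x, Mat<T>& s) {
  s.set_size(x.n_rows, x.n_cols);
  Mat<T> out(x.n_rows, x.n_cols);
  const T* px = x.memptr(); T* ps = s.memptr(); T* po = out.memptr();
  for (size_t k = 0; k < x.n_elem; ++k) {
    T sv = (T)1 / ((T)1 + fexp((T)-1.702 * px[k]));
    ps[k] = sv; po[k] = px[k] * sv;
  }
  return out;
}
template <typename T>
static Mat<T> gelu_bwd(const Mat<T>& x, const Mat<T>& s, const Mat<T>& dy) {
  Mat<T> out(x.n_rows, x.n_cols);
  const T* px = x.memptr(); const T* ps = s.memptr();
  const T* pd = dy.memptr(); T* po = out.memptr();
  for (size_t k = 0; k < x.n_elem; ++k)
    po[k] = pd[k] * (ps[k] * ((T)1 + (T)1.702 * px[k] * ((T)1 - ps[k])));
  return out;
}

// fast counter-free RNG for dropout masks (xorshift64*); seeded once per
// training run from the user seed, so masks are reproducible
struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  inline double next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return (double)(s >> 11) * 1.1102230246251565e-16;  // 53 bits -> [0, 1)
  }
};

// inverted-dropout multiplier mask (1/keep or 0); identity when p == 0
template <typename T>
static void drop_mask(Mat<T>& m, double p, XRng& rng) {
  T scale = (T)(1.0 / (1.0 - p));
  T* q = m.memptr();
  for (size_t k = 0; k < m.n_elem; ++k) q[k] = (rng.next() < p) ? (T)0 : scale;
}

// sinusoidal DOY features, one row per token
template <typename T>
static Mat<T> doy_sinusoid(const Mat<T>& doys_flat, int d) {
  // doys_flat: (BT x 1)
  Mat<T> out(doys_flat.n_rows, d);
  for (int j = 0; j < d / 2; ++j) {
    double w = std::pow(10000.0, -2.0 * j / d);
    for (size_t i = 0; i < doys_flat.n_rows; ++i) {
      double a = (double)doys_flat(i, 0) * w;
      out(i, 2 * j) = (T)std::sin(a);
      out(i, 2 * j + 1) = (T)std::cos(a);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// caches for one forward pass (kept for the backward pass)
template <typename T>
struct Caches {
  int B, Tn;
  Mat<T> Xb;                       // (BT x C) inputs
  Mat<T> Mb;                       // (B x T) validity
  Col<T> nvalid;                   // per-sample valid count
  // embedding
  Mat<T> A1, preH, sigH, H, B1, Pair, C1, U, S, preZ, sigZ, Z, Wgt, Ug, E;
  // patch branch
  Mat<T> PF;                       // (BT x PPB) raw patches
  std::vector<Mat<T>> cY1, cS1, cG1, cY2, cS2;  // per-token conv caches
  Mat<T> FL, Epatch;
  // positions
  Mat<T> SF, PE;
  std::vector<int> stage;          // per token
  // encoder per layer
  std::vector<Mat<T>> Xin, Qm, Km, Vm, Ctx, MdO, Od,
      xhat1, Y1ln, F1, sigF1, MdF1, Gd, F2, MdF2, xhat2, Y2ln;
  std::vector<Col<T>> istd1, istd2;
  std::vector<std::vector<Mat<T>>> Attn, AttnD;   // [layer][sample*heads]
  Mat<T> Md0, X0;
  // gate
  Mat<T> ctxg, preG1, sigG1, Hg, Gt, Xg;
  // head
  Mat<T> pooled, preHh, sigHh, Hh, MdH, logits, probs;
  // small reusable attention workspaces
  Mat<T> wQh, wKh, wVh, wSc, wAd, wdCh, wdA, wdS;
};

template <typename T>
static void ensure(std::vector<Mat<T>>& v, int n) {
  if ((int)v.size() != n) v.assign(n, Mat<T>());
}
template <typename T>
static void ensure(std::vector<Col<T>>& v, int n) {
  if ((int)v.size() != n) v.assign(n, Col<T>());
}
template <typename T>
static void ensure2(std::vector<std::vector<Mat<T>>>& v, int n, int m) {
  if ((int)v.size() != n) v.assign(n, std::vector<Mat<T>>());
  for (auto& x : v)
    if ((int)x.size() != m) x.assign(m, Mat<T>());
}

template <typename T>
struct Net {
  Config c;
  Params<T> P;

  // im2col for a 3x3x3 kernel over the (patch x patch x bands) volume of
  // one token, `ch` input channels stored as (PPB x ch) matrix `V`.
  // Output: (PPB x 27*ch).
  Mat<T> im2col(const Mat<T>& V, int ch) const {
    int p = c.patch, b = c.bands;
    Mat<T> out(p * p * b, 27 * ch, fill::zeros);
    for (int z = 0; z < b; ++z)
      for (int y = 0; y < p; ++y)
        for (int x = 0; x < p; ++x) {
          int pos = x + p * y + p * p * z;
          int col0 = 0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx >= 0 && xx < p && yy >= 0 && yy < p && zz >= 0 && zz < b) {
                  int src = xx + p * yy + p * p * zz;
                  for (int q = 0; q < ch; ++q)
                    out(pos, col0 + q) = V(src, q);
                }
                col0 += ch;
              }
        }
    return out;
  }

  // scatter-add the im2col gradient back onto the volume
  Mat<T> col2im(const Mat<T>& dCols, int ch) const {
    int p = c.patch, b = c.bands;
    Mat<T> dV(p * p * b, ch, fill::zeros);
    for (int z = 0; z < b; ++z)
      for (int y = 0; y < p; ++y)
        for (int x = 0; x < p; ++x) {
          int pos = x + p * y + p * p * z;
          int col0 = 0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx >= 0 && xx < p && yy >= 0 && yy < p && zz >= 0 && zz < b) {
                  int src = xx + p * yy + p * p * zz;
                  for (int q = 0; q < ch; ++q)
                    dV(src, q) += dCols(pos, col0 + q);
                }
                col0 += ch;
              }
        }
    return dV;
  }

  int stage_of(double doy) const {
    if (doy < c.brk1) return 0;
    if (doy <= c.brk2) return 1;
    return 2;
  }

  // forward pass; dropout only when train && dropout > 0
  void forward(Caches<T>& K, bool train, XRng& rng) const {
    const int B = K.B, Tn = K.Tn, d = c.d;
    const int BT = B * Tn;
    const double p = train ? c.dropout : 0.0;
    const T eps = (T)1e-5;

    K.nvalid = sum(K.Mb, 1);

    // ---- embedding -------------------------------------------------------
    if (c.multibranch) {
      K.A1 = K.Xb * P["Wa"]; K.A1.each_row() += P["ba"];
      K.preH = K.Xb * P["Wb1"]; K.preH.each_row() += P["bb1"];
      K.H = gelu_fwd<T>(K.preH, K.sigH);
      K.B1 = K.H * P["Wb2"]; K.B1.each_row() += P["bb2"];
      K.Pair.set_size(BT, c.P2);
      {
        int q = 0;
        for (int i = 0; i < c.C; ++i)
          for (int j = i; j < c.C; ++j, ++q)
            K.Pair.col(q) = K.Xb.col(i) % K.Xb.col(j);
      }
      K.C1 = K.Pair * P["Wc"]; K.C1.each_row() += P["bc"];
      K.U = join_rows(K.A1, K.B1, K.C1);
      // squeeze: masked mean over time -> channel attention weights
      K.S.set_size(B, 3 * c.db);
      for (int n = 0; n < B; ++n) {
        Row<T> acc(3 * c.db, fill::zeros);
        for (int t = 0; t < Tn; ++t)
          if (K.Mb(n, t) > (T)0.5) acc += K.U.row(n * Tn + t);
        K.S.row(n) = acc / K.nvalid(n);
      }
      K.preZ = K.S * P["Ws1"]; K.preZ.each_row() += P["bs1"];
      K.Z = gelu_fwd<T>(K.preZ, K.sigZ);
      Mat<T> pre2 = K.Z * P["Ws2"]; pre2.each_row() += P["bs2"];
      K.Wgt = sigm<T>(pre2);
      K.Ug = K.U;
      for (int n = 0; n < B; ++n)
        K.Ug.rows(n * Tn, n * Tn + Tn - 1).each_row() %= K.Wgt.row(n);
      K.E = K.Ug * P["We"]; K.E.each_row() += P["be"];
    } else {
      K.E = K.Xb * P["Wlin"]; K.E.each_row() += P["blin"];
    }

    // ---- optional spatio-spectral patch branch ---------------------------
    if (c.patchbranch) {
      int ppb = c.patch * c.patch * c.bands, F = c.filt;
      K.cY1.assign(BT, Mat<T>()); K.cS1.assign(BT, Mat<T>());
      K.cG1.assign(BT, Mat<T>()); K.cY2.assign(BT, Mat<T>());
      K.cS2.assign(BT, Mat<T>());
      K.FL.set_size(BT, ppb * F);
      for (int r = 0; r < BT; ++r) {
        Mat<T> V(ppb, 1);
        for (int k = 0; k < ppb; ++k) V(k, 0) = K.PF(r, k);
        Mat<T> C1m = im2col(V, 1);
        K.cY1[r] = C1m * P["K1"]; K.cY1[r].each_row() += P["bk1"];
        K.cG1[r] = gelu_fwd<T>(K.cY1[r], K.cS1[r]);
        Mat<T> C2m = im2col(K.cG1[r], F);
        K.cY2[r] = C2m * P["K2"]; K.cY2[r].each_row() += P["bk2"];
        Mat<T> G2 = gelu_fwd<T>(K.cY2[r], K.cS2[r]);
        K.FL.row(r) = vectorise(G2, 1);  // row-wise vectorize: (1 x ppb*F)
      }
      K.Epatch = K.FL * P["Wf"]; K.Epatch.each_row() += P["bf"];
      K.E += K.Epatch;
    }

    // ---- positional encoding --------------------------------------------
    // K.SF already holds sinusoid features; stages precomputed in caller
    if (c.adaptive_pos) {
      K.PE = K.SF * P["Wp"]; K.PE.each_row() += P["bp"];
      for (int r = 0; r < BT; ++r) K.PE.row(r) += P["Eseason"].row(K.stage[r]);
    } else {
      K.PE = K.SF;
    }

    K.X0 = K.E + K.PE;
    if (p > 0) {
      K.Md0.set_size(BT, d); drop_mask(K.Md0, p, rng);
      K.X0 %= K.Md0;
    }

    // ---- transformer encoder (post-LN) -----------------------------------
    ensure(K.Xin, c.layers); ensure(K.Qm, c.layers);
    ensure(K.Km, c.layers); ensure(K.Vm, c.layers);
    ensure(K.Ctx, c.layers); ensure(K.MdO, c.layers);
    ensure(K.Od, c.layers);
    ensure(K.xhat1, c.layers); ensure(K.Y1ln, c.layers);
    ensure(K.F1, c.layers); ensure(K.sigF1, c.layers);
    ensure(K.MdF1, c.layers); ensure(K.Gd, c.layers);
    ensure(K.F2, c.layers); ensure(K.MdF2, c.layers);
    ensure(K.xhat2, c.layers); ensure(K.Y2ln, c.layers);
    ensure(K.istd1, c.layers); ensure(K.istd2, c.layers);
    ensure2(K.Attn, c.layers, B * c.heads);
    ensure2(K.AttnD, c.layers, B * c.heads);
    K.wQh.set_size(Tn, c.dk); K.wKh.set_size(Tn, c.dk);
    K.wVh.set_size(Tn, c.dk); K.wSc.set_size(Tn, Tn); K.wAd.set_size(Tn, Tn);

    const T scl = (T)(1.0 / std::sqrt((double)c.dk));
    Mat<T> X = K.X0;
    std::vector<T> kbias(Tn);
    for (int l = 0; l < c.layers; ++l) {
      std::string pr = "L" + std::to_string(l) + "_";
      K.Xin[l] = X;
      Mat<T>& Q = K.Qm[l]; Mat<T>& Km_ = K.Km[l]; Mat<T>& V = K.Vm[l];
      Q = X * P[pr + "Wq"]; Q.each_row() += P[pr + "bq"];
      Km_ = X * P[pr + "Wk"]; Km_.each_row() += P[pr + "bk"];
      V = X * P[pr + "Wv"]; V.each_row() += P[pr + "bv"];
      Mat<T>& Ctx = K.Ctx[l];
      Ctx.set_size(BT, d);
      for (int n = 0; n < B; ++n) {
        for (int t = 0; t < Tn; ++t)
          kbias[t] = (K.Mb(n, t) - (T)1) * (T)1e9;
        int r0 = n * Tn, r1 = n * Tn + Tn - 1;
        for (int h = 0; h < c.heads; ++h) {
          int c0 = h * c.dk, c1 = (h + 1) * c.dk - 1;
          K.wQh = Q.submat(r0, c0, r1, c1);
          K.wKh = Km_.submat(r0, c0, r1, c1);
          K.wVh = V.submat(r0, c0, r1, c1);
          K.wSc = K.wQh * K.wKh.t();
          // row-wise softmax over scaled, key-masked scores
          T* s = K.wSc.memptr();
          for (int i = 0; i < Tn; ++i) {
            T mx = (T)-1e30;
            for (int j = 0; j < Tn; ++j) {
              T v = s[i + j * Tn] * scl + kbias[j];
              s[i + j * Tn] = v;
              if (v > mx) mx = v;
            }
            T sm = 0;
            for (int j = 0; j < Tn; ++j) {
              T e = fexp(s[i + j * Tn] - mx);
              s[i + j * Tn] = e; sm += e;
            }
            T inv = (T)1 / sm;
            for (int j = 0; j < Tn; ++j) s[i + j * Tn] *= inv;
          }
          Mat<T>& A = K.Attn[l][n * c.heads + h];
          A = K.wSc;
          if (p > 0) {
            Mat<T>& Ad = K.AttnD[l][n * c.heads + h];
            Ad.set_size(Tn, Tn);
            T keep = (T)(1.0 / (1.0 - p));
            const T* a = A.memptr(); T* ad = Ad.memptr();
            for (int k2 = 0; k2 < Tn * Tn; ++k2)
              ad[k2] = (rng.next() < p) ? (T)0 : a[k2] * keep;
            Ctx.submat(r0, c0, r1, c1) = Ad * K.wVh;
          } else {
            Ctx.submat(r0, c0, r1, c1) = A * K.wVh;
          }
        }
      }
      Mat<T> O = Ctx * P[pr + "Wo"]; O.each_row() += P[pr + "bo"];
      if (p > 0) {
        K.MdO[l].set_size(BT, d); drop_mask(K.MdO[l], p, rng);
        O %= K.MdO[l];
      }
      K.Od[l] = O;
      // LN1
      Mat<T> R1 = X + O;
      Col<T> mu = mean(R1, 1);
      Mat<T> Cc = R1; Cc.each_col() -= mu;
      Col<T> va = sum(square(Cc), 1) / (T)d;
      K.istd1[l] = 1.0 / sqrt(va + eps);
      Cc.each_col() %= K.istd1[l];
      K.xhat1[l] = Cc;
      Mat<T> Y1 = Cc; Y1.each_row() %= P[pr + "g1"]; Y1.each_row() += P[pr + "be1"];
      K.Y1ln[l] = Y1;
      // feed-forward
      K.F1[l] = Y1 * P[pr + "Wf1"]; K.F1[l].each_row() += P[pr + "bf1"];
      Mat<T> G = gelu_fwd<T>(K.F1[l], K.sigF1[l]);
      if (p > 0) {
        K.MdF1[l].set_size(BT, c.dff); drop_mask(K.MdF1[l], p, rng);
        G %= K.MdF1[l];
      }
      K.Gd[l] = G;
      Mat<T> F2 = G * P[pr + "Wf2"]; F2.each_row() += P[pr + "bf2"];
      if (p > 0) {
        K.MdF2[l].set_size(BT, d); drop_mask(K.MdF2[l], p, rng);
        F2 %= K.MdF2[l];
      }
      K.F2[l] = F2;
      // LN2
      Mat<T> R2 = Y1 + F2;
      Col<T> mu2 = mean(R2, 1);
      Mat<T> C2 = R2; C2.each_col() -= mu2;
      Col<T> va2 = sum(square(C2), 1) / (T)d;
      K.istd2[l] = 1.0 / sqrt(va2 + eps);
      C2.each_col() %= K.istd2[l];
      K.xhat2[l] = C2;
      Mat<T> Y2 = C2; Y2.each_row() %= P[pr + "g2"]; Y2.each_row() += P[pr + "be2"];
      K.Y2ln[l] = Y2;
      X = Y2;
    }

    // ---- phenology gate --------------------------------------------------
    if (c.gate) {
      K.ctxg = join_rows(X, K.PE);
      K.preG1 = K.ctxg * P["Wg1"]; K.preG1.each_row() += P["bg1"];
      K.Hg = gelu_fwd<T>(K.preG1, K.sigG1);
      Mat<T> preG2 = K.Hg * P["Wg2"]; preG2.each_row() += P["bg2"];
      K.Gt = sigm<T>(preG2);
      K.Xg = X % K.Gt;
    } else {
      K.Xg = X;
    }

    // ---- masked pooling + head ------------------------------------------
    K.pooled.set_size(B, d);
    for (int n = 0; n < B; ++n) {
      Row<T> acc(d, fill::zeros);
      for (int t = 0; t < Tn; ++t)
        if (K.Mb(n, t) > (T)0.5) acc += K.Xg.row(n * Tn + t);
      K.pooled.row(n) = acc / K.nvalid(n);
    }
    K.preHh = K.pooled * P["Wh1"]; K.preHh.each_row() += P["bh1"];
    K.Hh = gelu_fwd<T>(K.preHh, K.sigHh);
    if (p > 0) {
      K.MdH.set_size(B, c.dh); drop_mask(K.MdH, p, rng);
      K.Hh %= K.MdH;
    }
    K.logits = K.Hh * P["Wh2"]; K.logits.each_row() += P["bh2"];
    Col<T> mx = max(K.logits, 1);
    Mat<T> ex = K.logits; ex.each_col() -= mx; ex = exp(ex);
    Col<T> sm = sum(ex, 1);
    ex.each_col() /= sm;
    K.probs = ex;
  }

  // mean cross-entropy of the cached forward pass
  double loss(const Caches<T>& K, const ivec& y) const {
    double L = 0;
    for (int n = 0; n < K.B; ++n)
      L -= std::log(std::max((double)K.probs(n, y(n)), 1e-12));
    return L / K.B;
  }

  // backward pass; accumulates into G (assumed zeroed)
  void backward(Caches<T>& K, const ivec& y, Params<T>& G,
                bool train) const {
    const int B = K.B, Tn = K.Tn, d = c.d;
    const int BT = B * Tn;
    const bool p = train && c.dropout > 0;
    const T scl = (T)(1.0 / std::sqrt((double)c.dk));

    // head
    Mat<T> dlog = K.probs;
    for (int n = 0; n < B; ++n) dlog(n, y(n)) -= (T)1;
    dlog /= (T)B;
    G["Wh2"] += K.Hh.t() * dlog;
    G["bh2"] += sum(dlog, 0);
    Mat<T> dHh = dlog * P["Wh2"].t();
    if (p) dHh %= K.MdH;
    Mat<T> dpreHh = gelu_bwd<T>(K.preHh, K.sigHh, dHh);
    G["Wh1"] += K.pooled.t() * dpreHh;
    G["bh1"] += sum(dpreHh, 0);
    Mat<T> dpooled = dpreHh * P["Wh1"].t();

    // un-pool
    Mat<T> dXg(BT, d, fill::zeros);
    for (int n = 0; n < B; ++n) {
      Row<T> g = dpooled.row(n) / K.nvalid(n);
      for (int t = 0; t < Tn; ++t)
        if (K.Mb(n, t) > (T)0.5) dXg.row(n * Tn + t) = g;
    }

    // gate
    Mat<T> dX;                       // grad wrt encoder output
    Mat<T> dPE(BT, d, fill::zeros);  // accumulated positional-encoding grad
    if (c.gate) {
      dX = dXg % K.Gt;
      Mat<T> dGt = dXg % K.Y2ln[c.layers - 1];
      Mat<T> dpre2 = dGt % K.Gt % (1.0 - K.Gt);
      G["Wg2"] += K.Hg.t() * dpre2;
      G["bg2"] += sum(dpre2, 0);
      Mat<T> dHg = dpre2 * P["Wg2"].t();
      Mat<T> dpre1 = gelu_bwd<T>(K.preG1, K.sigG1, dHg);
      G["Wg1"] += K.ctxg.t() * dpre1;
      G["bg1"] += sum(dpre1, 0);
      Mat<T> dctx = dpre1 * P["Wg1"].t();
      dX += dctx.cols(0, d - 1);
      dPE += dctx.cols(d, 2 * d - 1);
    } else {
      dX = dXg;
    }

    // encoder layers, reversed
    for (int l = c.layers - 1; l >= 0; --l) {
      std::string pr = "L" + std::to_string(l) + "_";
      // LN2 backward
      Mat<T> dxhat2 = dX; dxhat2.each_row() %= P[pr + "g2"];
      G[pr + "g2"] += sum(dX % K.xhat2[l], 0);
      G[pr + "be2"] += sum(dX, 0);
      Col<T> m1 = mean(dxhat2, 1);
      Col<T> m2 = mean(dxhat2 % K.xhat2[l], 1);
      Mat<T> dR2 = dxhat2;
      dR2.each_col() -= m1;
      dR2 -= K.xhat2[l].each_col() % m2;
      dR2.each_col() %= K.istd2[l];
      // FFN backward
      Mat<T> dY1 = dR2;                     // residual
      Mat<T> dF2 = dR2;
      if (p) dF2 %= K.MdF2[l];
      G[pr + "Wf2"] += K.Gd[l].t() * dF2;
      G[pr + "bf2"] += sum(dF2, 0);
      Mat<T> dG = dF2 * P[pr + "Wf2"].t();
      if (p) dG %= K.MdF1[l];
      Mat<T> dF1 = gelu_bwd<T>(K.F1[l], K.sigF1[l], dG);
      G[pr + "Wf1"] += K.Y1ln[l].t() * dF1;
      G[pr + "bf1"] += sum(dF1, 0);
      dY1 += dF1 * P[pr + "Wf1"].t();
      // LN1 backward
      Mat<T> dxhat1 = dY1; dxhat1.each_row() %= P[pr + "g1"];
      G[pr + "g1"] += sum(dY1 % K.xhat1[l], 0);
      G[pr + "be1"] += sum(dY1, 0);
      Col<T> n1 = mean(dxhat1, 1);
      Col<T> n2 = mean(dxhat1 % K.xhat1[l], 1);
      Mat<T> dR1 = dxhat1;
      dR1.each_col() -= n1;
      dR1 -= K.xhat1[l].each_col() % n2;
      dR1.each_col() %= K.istd1[l];
      // attention backward
      Mat<T> dXl = dR1;                     // residual to layer input
      Mat<T> dO = dR1;
      if (p) dO %= K.MdO[l];
      G[pr + "Wo"] += K.Ctx[l].t() * dO;
      G[pr + "bo"] += sum(dO, 0);
      Mat<T> dCtx = dO * P[pr + "Wo"].t();
      Mat<T> dQ(BT, d), dK(BT, d), dV(BT, d);
      K.wdCh.set_size(Tn, c.dk); K.wdA.set_size(Tn, Tn);
      K.wdS.set_size(Tn, Tn);
      for (int n = 0; n < B; ++n) {
        int r0 = n * Tn, r1 = n * Tn + Tn - 1;
        for (int h = 0; h < c.heads; ++h) {
          int c0 = h * c.dk, c1 = (h + 1) * c.dk - 1;
          const Mat<T>& A = K.Attn[l][n * c.heads + h];
          const Mat<T>& Ad = p ? K.AttnD[l][n * c.heads + h] : A;
          K.wdCh = dCtx.submat(r0, c0, r1, c1);
          K.wVh = K.Vm[l].submat(r0, c0, r1, c1);
          K.wdA = K.wdCh * K.wVh.t();
          dV.submat(r0, c0, r1, c1) = Ad.t() * K.wdCh;
          // recover the dropout mask from Ad/A, then softmax backward with
          // the score scale folded in
          const T* a = A.memptr(); const T* ad = Ad.memptr();
          T* da = K.wdA.memptr(); T* ds = K.wdS.memptr();
          if (p)
            for (int k2 = 0; k2 < Tn * Tn; ++k2)
              da[k2] = (a[k2] > (T)0) ? da[k2] * (ad[k2] / a[k2]) : (T)0;
          for (int i = 0; i < Tn; ++i) {
            T rs = 0;
            for (int j = 0; j < Tn; ++j) rs += a[i + j * Tn] * da[i + j * Tn];
            for (int j = 0; j < Tn; ++j)
              ds[i + j * Tn] = a[i + j * Tn] * (da[i + j * Tn] - rs) * scl;
          }
          K.wQh = K.Qm[l].submat(r0, c0, r1, c1);
          K.wKh = K.Km[l].submat(r0, c0, r1, c1);
          dQ.submat(r0, c0, r1, c1) = K.wdS * K.wKh;
          dK.submat(r0, c0, r1, c1) = K.wdS.t() * K.wQh;
        }
      }
      G[pr + "Wq"] += K.Xin[l].t() * dQ; G[pr + "bq"] += sum(dQ, 0);
      G[pr + "Wk"] += K.Xin[l].t() * dK; G[pr + "bk"] += sum(dK, 0);
      G[pr + "Wv"] += K.Xin[l].t() * dV; G[pr + "bv"] += sum(dV, 0);
      dXl += dQ * P[pr + "Wq"].t() + dK * P[pr + "Wk"].t() + dV * P[pr + "Wv"].t();
      dX = dXl;
    }

    // embedding dropout
    Mat<T> dX0 = dX;
    if (p) dX0 %= K.Md0;
    Mat<T> dE = dX0;
    dPE += dX0;

    // positional encoding backward
    if (c.adaptive_pos) {
      G["Wp"] += K.SF.t() * dPE;
      G["bp"] += sum(dPE, 0);
      for (int r = 0; r < BT; ++r)
        G["Eseason"].row(K.stage[r]) += dPE.row(r);
    }

    // patch branch backward
    if (c.patchbranch) {
      int ppb = c.patch * c.patch * c.bands, F = c.filt;
      G["Wf"] += K.FL.t() * dE;
      G["bf"] += sum(dE, 0);
      Mat<T> dFL = dE * P["Wf"].t();
      for (int r = 0; r < BT; ++r) {
        Mat<T> dG2(ppb, F);
        for (int k = 0; k < ppb * F; ++k) dG2(k / F, k % F) = dFL(r, k);
        Mat<T> dY2 = gelu_bwd<T>(K.cY2[r], K.cS2[r], dG2);
        Mat<T> C2m = im2col(K.cG1[r], F);
        G["K2"] += C2m.t() * dY2;
        G["bk2"] += sum(dY2, 0);
        Mat<T> dC2 = dY2 * P["K2"].t();
        Mat<T> dG1 = col2im(dC2, F);
        Mat<T> dY1 = gelu_bwd<T>(K.cY1[r], K.cS1[r], dG1);
        Mat<T> V(ppb, 1);
        for (int k = 0; k < ppb; ++k) V(k, 0) = K.PF(r, k);
        Mat<T> C1m = im2col(V, 1);
        G["K1"] += C1m.t() * dY1;
        G["bk1"] += sum(dY1, 0);
      }
    }

    // embedding backward
    if (c.multibranch) {
      G["We"] += K.Ug.t() * dE;
      G["be"] += sum(dE, 0);
      Mat<T> dUg = dE * P["We"].t();
      Mat<T> dU = dUg;
      Mat<T> dWgt(B, 3 * c.db, fill::zeros);
      for (int n = 0; n < B; ++n) {
        int r0 = n * Tn, r1 = n * Tn + Tn - 1;
        dU.rows(r0, r1).each_row() %= K.Wgt.row(n);
        dWgt.row(n) = sum(dUg.rows(r0, r1) % K.U.rows(r0, r1), 0);
      }
      Mat<T> dpre2 = dWgt % K.Wgt % (1.0 - K.Wgt);
      G["Ws2"] += K.Z.t() * dpre2;
      G["bs2"] += sum(dpre2, 0);
      Mat<T> dZ = dpre2 * P["Ws2"].t();
      Mat<T> dpre1 = gelu_bwd<T>(K.preZ, K.sigZ, dZ);
      G["Ws1"] += K.S.t() * dpre1;
      G["bs1"] += sum(dpre1, 0);
      Mat<T> dS_ = dpre1 * P["Ws1"].t();
      for (int n = 0; n < B; ++n) {
        Row<T> g = dS_.row(n) / K.nvalid(n);
        for (int t = 0; t < Tn; ++t)
          if (K.Mb(n, t) > (T)0.5) dU.row(n * Tn + t) += g;
      }
      Mat<T> dA1 = dU.cols(0, c.db - 1);
      Mat<T> dB1 = dU.cols(c.db, 2 * c.db - 1);
      Mat<T> dC1 = dU.cols(2 * c.db, 3 * c.db - 1);
      G["Wa"] += K.Xb.t() * dA1; G["ba"] += sum(dA1, 0);
      G["Wb2"] += K.H.t() * dB1; G["bb2"] += sum(dB1, 0);
      Mat<T> dH = dB1 * P["Wb2"].t();
      Mat<T> dpreH = gelu_bwd<T>(K.preH, K.sigH, dH);
      G["Wb1"] += K.Xb.t() * dpreH; G["bb1"] += sum(dpreH, 0);
      G["Wc"] += K.Pair.t() * dC1; G["bc"] += sum(dC1, 0);
      // (input gradients are not propagated further)
    } else {
      G["Wlin"] += K.Xb.t() * dE;
      G["blin"] += sum(dE, 0);
    }
  }
};

// ---------------------------------------------------------------------------
// batch assembly: copy sample blocks out of the full (N*T x C) matrices
template <typename T>
static void fill_batch(Caches<T>& K, const Mat<T>& X, const Mat<T>& M,
                       const Mat<T>& SFall, const std::vector<int>& stage_all,
                       const Mat<T>* PF, const std::vector<int>& idx, int Tn) {
  int B = (int)idx.size();
  K.B = B; K.Tn = Tn;
  K.Xb.set_size(B * Tn, X.n_cols);
  K.Mb.set_size(B, Tn);
  K.SF.set_size(B * Tn, SFall.n_cols);
  K.stage.resize((size_t)B * Tn);
  if (PF) K.PF.set_size(B * Tn, PF->n_cols);
  for (int n = 0; n < B; ++n) {
    int s = idx[n];
    K.Xb.rows(n * Tn, n * Tn + Tn - 1) = X.rows(s * Tn, s * Tn + Tn - 1);
    K.Mb.row(n) = M.row(s);
    K.SF.rows(n * Tn, n * Tn + Tn - 1) = SFall.rows(s * Tn, s * Tn + Tn - 1);
    for (int t = 0; t < Tn; ++t) K.stage[n * Tn + t] = stage_all[s * Tn + t];
    if (PF) K.PF.rows(n * Tn, n * Tn + Tn - 1) = PF->rows(s * Tn, s * Tn + Tn - 1);
  }
}

template <typename T>
static Mat<T> to_mat(const Rcpp::NumericMatrix& m) {
  Mat<T> out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (T)m(i, j);
  return out;
}

// precompute sinusoid features and stage bins for all tokens
template <typename T>
static void precompute_pos(const Config& c, const Rcpp::NumericMatrix& D,
                           Mat<T>& SF, std::vector<int>& stage) {
  int N = D.nrow(), Tn = D.ncol();
  Mat<T> dflat(N * Tn, 1);
  stage.resize((size_t)N * Tn);
  Net<T> tmp; tmp.c = c;
  for (int n = 0; n < N; ++n)
    for (int t = 0; t < Tn; ++t) {
      double doy = D(n, t);
      if (doy < 1 || doy > 366) Rcpp::stop("DOY out of range [1, 366]");
      dflat(n * Tn + t, 0) = (T)doy;
      stage[(size_t)n * Tn + t] = tmp.stage_of(doy);
    }
  SF = doy_sinusoid<T>(dflat, c.d);
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_param_layout(List cfg) {
  Config c = parse_config(cfg);
  auto L = make_layout(c);
  Rcpp::CharacterVector names(L.size());
  Rcpp::IntegerVector nr(L.size()), nc(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    names[i] = L[i].name; nr[i] = L[i].r; nc[i] = L[i].cdim;
  }
  return List::create(Named("name") = names, Named("nrow") = nr,
                      Named("ncol") = nc);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_init_params(List cfg, int seed) {
  Config c = parse_config(cfg);
  auto L = make_layout(c);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> U(-1.0, 1.0);
  size_t tot = 0;
  for (auto& d : L) tot += (size_t)d.r * d.cdim;
  Rcpp::NumericVector out(tot);
  size_t off = 0;
  for (auto& def : L) {
    size_t n = (size_t)def.r * def.cdim;
    bool is_bias = def.r == 1 && def.name[0] == 'b';
    bool is_gamma = def.name.find("_g1") != std::string::npos ||
                    def.name.find("_g2") != std::string::npos;
    bool is_beta = def.name.find("_be1") != std::string::npos ||
                   def.name.find("_be2") != std::string::npos;
    bool is_season = def.name == "Eseason";
    if (is_gamma) {
      for (size_t k = 0; k < n; ++k) out[off + k] = 1.0;
    } else if (is_bias || is_beta) {
      for (size_t k = 0; k < n; ++k) out[off + k] = 0.0;
    } else if (is_season) {
      for (size_t k = 0; k < n; ++k) out[off + k] = 0.05 * U(rng);
    } else {
      // Xavier uniform
      double lim = std::sqrt(6.0 / (def.r + def.cdim));
      for (size_t k = 0; k < n; ++k) out[off + k] = lim * U(rng);
    }
    off += n;
  }
  return out;
}

template <typename T>
static List forward_impl(const arma::vec& theta, const List& cfg,
                         const Rcpp::NumericMatrix& X,
                         const Rcpp::NumericMatrix& M,
                         const Rcpp::NumericMatrix& D,
                         Rcpp::Nullable<Rcpp::NumericMatrix> Pt,
                         bool intermediates) {
  Config c = parse_config(cfg);
  auto L = make_layout(c);
  Net<T> net; net.c = c; net.P = unflatten<T>(L, theta);
  int N = M.nrow(), Tn = M.ncol();
  if ((int)X.nrow() != N * Tn) Rcpp::stop("feature matrix rows != N * T");
  if ((int)X.ncol() != c.C) Rcpp::stop("feature channels do not match config");
  Mat<T> Xa = to_mat<T>(X), Ma = to_mat<T>(M);
  for (int n = 0; n < N; ++n)
    if (sum(Ma.row(n)) < (T)0.5)
      Rcpp::stop("sample %d has no valid timestep", n + 1);
  Mat<T> SF; std::vector<int> stage;
  precompute_pos<T>(c, D, SF, stage);
  Mat<T> PFa;
  const Mat<T>* PFp = nullptr;
  if (Pt.isNotNull()) {
    PFa = to_mat<T>(Rcpp::NumericMatrix(Pt));
    PFp = &PFa;
  } else if (c.patchbranch) {
    Rcpp::stop("config uses the patch branch but no patches were supplied");
  }
  Caches<T> K;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fill_batch<T>(K, Xa, Ma, SF, stage, PFp, idx, Tn);
  XRng rng(1);
  net.forward(K, false, rng);
  auto wrap = [](const Mat<T>& m) {
    Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
    for (size_t j = 0; j < m.n_cols; ++j)
      for (size_t i = 0; i < m.n_rows; ++i) out(i, j) = (double)m(i, j);
    return out;
  };
  if (!intermediates) return List::create(Named("probs") = wrap(K.probs));
  List out = List::create(
      Named("probs") = wrap(K.probs), Named("embed") = wrap(K.E),
      Named("pos") = wrap(K.PE), Named("encoder") = wrap(K.Y2ln.back()),
      Named("pooled") = wrap(K.pooled), Named("logits") = wrap(K.logits));
  if (c.gate) out["gates"] = wrap(K.Gt);
  if (c.multibranch) {
    out["ca_weights"] = wrap(K.Wgt);
    out["branches"] = List::create(Named("A") = wrap(K.A1),
                                   Named("B") = wrap(K.B1),
                                   Named("C") = wrap(K.C1),
                                   Named("pair") = wrap(K.Pair));
  }
  if (c.patchbranch) out["patch_embed"] = wrap(K.Epatch);
  return out;
}

// [[Rcpp::export]]
List cpp_forward(Rcpp::NumericVector theta, List cfg, Rcpp::NumericMatrix X,
                 Rcpp::NumericMatrix M, Rcpp::NumericMatrix D,
                 Rcpp::Nullable<Rcpp::NumericMatrix> P = R_NilValue,
                 bool intermediates = false) {
  arma::vec th(theta.begin(), theta.size());
  return forward_impl<double>(th, cfg, X, M, D, P, intermediates);
}

// [[Rcpp::export]]
List cpp_loss_grads(Rcpp::NumericVector theta, List cfg, Rcpp::NumericMatrix X,
                    Rcpp::NumericMatrix M, Rcpp::NumericMatrix D,
                    Rcpp::Nullable<Rcpp::NumericMatrix> P,
                    Rcpp::IntegerVector y) {
  arma::vec th(theta.begin(), theta.size());
  Config c = parse_config(cfg);
  auto L = make_layout(c);
  Net<double> net; net.c = c; net.P = unflatten<double>(L, th);
  int N = M.nrow(), Tn = M.ncol();
  Mat<double> Xa = to_mat<double>(X), Ma = to_mat<double>(M);
  Mat<double> SF; std::vector<int> stage;
  precompute_pos<double>(c, D, SF, stage);
  Mat<double> PFa;
  const Mat<double>* PFp = nullptr;
  if (P.isNotNull()) { PFa = to_mat<double>(Rcpp::NumericMatrix(P)); PFp = &PFa; }
  Caches<double> K;
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fill_batch<double>(K, Xa, Ma, SF, stage, PFp, idx, Tn);
  XRng rng(1);
  net.forward(K, false, rng);
  ivec ya(N);
  for (int i = 0; i < N; ++i) ya(i) = y[i];
  double Lv = net.loss(K, ya);
  Params<double> G = zeros_like(net.P);
  net.backward(K, ya, G, false);
  arma::vec gflat = flatten<double>(L, G);
  return List::create(Named("loss") = Lv,
                      Named("grad") = Rcpp::NumericVector(gflat.begin(), gflat.end()));
}

// ---------------------------------------------------------------------------
// training loop with AdamW, gradient clipping and lr scheduling
template <typename T>
static List train_impl(const arma::vec& theta0, const List& cfg,
                       const Rcpp::NumericMatrix& X, const Rcpp::NumericMatrix& M,
                       const Rcpp::NumericMatrix& D,
                       Rcpp::Nullable<Rcpp::NumericMatrix> Pt,
                       const Rcpp::IntegerVector& y, const List& val,
                       const List& tcfg, int seed) {
  Config c = parse_config(cfg);
  auto L = make_layout(c);
  Net<T> net; net.c = c; net.P = unflatten<T>(L, theta0);

  const int N = M.nrow(), Tn = M.ncol();
  const int epochs = tcfg["epochs"];
  const int batch = tcfg["batch_size"];
  const double lr0 = tcfg["lr"];
  const double wd = tcfg["weight_decay"];
  const double clip = tcfg["grad_clip_norm"];
  const std::string sched = Rcpp::as<std::string>(tcfg["scheduler"]);
  const double plateau_factor = tcfg["plateau_factor"];
  const int plateau_patience = tcfg["plateau_patience"];
  const double b1 = 0.9, b2 = 0.999, aeps = 1e-8;

  Mat<T> Xa = to_mat<T>(X), Ma = to_mat<T>(M);
  Mat<T> SF; std::vector<int> stage;
  precompute_pos<T>(c, D, SF, stage);
  Mat<T> PFa; const Mat<T>* PFp = nullptr;
  if (Pt.isNotNull()) { PFa = to_mat<T>(Rcpp::NumericMatrix(Pt)); PFp = &PFa; }
  ivec ya(N);
  for (int i = 0; i < N; ++i) ya(i) = y[i];

  bool has_val = val.size() > 0;
  Mat<T> Xv, Mv, SFv; std::vector<int> stagev; ivec yv;
  Mat<T> PFv; const Mat<T>* PFvp = nullptr;
  int Nv = 0;
  if (has_val) {
    Rcpp::NumericMatrix Xvm = val["X"], Mvm = val["M"], Dvm = val["D"];
    Rcpp::IntegerVector yvm = val["y"];
    Xv = to_mat<T>(Xvm); Mv = to_mat<T>(Mvm);
    precompute_pos<T>(c, Dvm, SFv, stagev);
    Nv = Mvm.nrow();
    yv.set_size(Nv);
    for (int i = 0; i < Nv; ++i) yv(i) = yvm[i];
    if (val.containsElementNamed("P")) {
      Rcpp::NumericMatrix Pv = val["P"];
      PFv = to_mat<T>(Pv); PFvp = &PFv;
    }
  }

  Params<T> Gr = zeros_like(net.P);
  Params<T> Am = zeros_like(net.P), Av = zeros_like(net.P);
  std::mt19937 rng((unsigned)seed);
  XRng drng(0x517CC1B727220A95ULL ^ (uint64_t)(unsigned)seed);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Caches<T> K;
  std::vector<double> h_loss, h_acc, h_vloss, h_vacc, h_lr;
  long clip_count = 0, adam_t = 0;
  double lr = lr0;
  bool diverged = false;
  double best_vloss = 1e300; int plateau_wait = 0;

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    if (sched == "cosine")
      lr = lr0 * 0.5 * (1.0 + std::cos(M_PI * ep / std::max(1, epochs)));
    std::shuffle(order.begin(), order.end(), rng);
    double eploss = 0; long ncorrect = 0; int nb = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int s1 = std::min(N, s0 + batch);
      std::vector<int> idx(order.begin() + s0, order.begin() + s1);
      fill_batch<T>(K, Xa, Ma, SF, stage, PFp, idx, Tn);
      net.forward(K, true, drng);
      ivec yb((int)idx.size());
      for (size_t i = 0; i < idx.size(); ++i) yb(i) = ya(idx[i]);
      double Lv = net.loss(K, yb);
      if (!std::isfinite(Lv)) { diverged = true; break; }
      eploss += Lv * idx.size(); nb += (int)idx.size();
      for (size_t i = 0; i < idx.size(); ++i)
        if ((int)index_max(K.probs.row(i)) == yb(i)) ++ncorrect;
      for (auto& g : Gr.M) g.zeros();
      net.backward(K, yb, Gr, true);
      // global-norm clipping
      double sq = 0;
      for (auto& g : Gr.M) sq += (double)accu(square(g));
      double gn = std::sqrt(sq);
      if (gn > clip) {
        T sclp = (T)(clip / (gn + 1e-12));
        for (auto& g : Gr.M) g *= sclp;
        ++clip_count;
      }
      // AdamW (decoupled weight decay; biases/LN params not decayed)
      ++adam_t;
      double bc1 = 1.0 - std::pow(b1, (double)adam_t);
      double bc2 = 1.0 - std::pow(b2, (double)adam_t);
      const T sb2 = (T)std::sqrt(bc2);
      for (size_t k = 0; k < Gr.M.size(); ++k) {
        Am.M[k] = (T)b1 * Am.M[k] + (T)(1 - b1) * Gr.M[k];
        Av.M[k] = (T)b2 * Av.M[k] + (T)(1 - b2) * square(Gr.M[k]);
        if (L[k].r > 1 && wd > 0)
          net.P.M[k] -= (T)(lr * wd) * net.P.M[k];
        net.P.M[k] -= (T)(lr / bc1) * (Am.M[k] / (sqrt(Av.M[k]) / sb2 + (T)aeps));
      }
    }
    if (diverged) break;
    h_loss.push_back(eploss / std::max(1, nb));
    h_acc.push_back((double)ncorrect / std::max(1, nb));
    h_lr.push_back(lr);
    if (has_val) {
      Caches<T> Kv;
      std::vector<int> iv(Nv);
      for (int i = 0; i < Nv; ++i) iv[i] = i;
      fill_batch<T>(Kv, Xv, Mv, SFv, stagev, PFvp, iv, Tn);
      XRng r2(1);
      net.forward(Kv, false, r2);
      double vl = net.loss(Kv, yv);
      long vc = 0;
      for (int i = 0; i < Nv; ++i)
        if ((int)index_max(Kv.probs.row(i)) == yv(i)) ++vc;
      h_vloss.push_back(vl); h_vacc.push_back((double)vc / Nv);
      if (sched == "plateau") {
        if (vl < best_vloss - 1e-5) { best_vloss = vl; plateau_wait = 0; }
        else if (++plateau_wait >= plateau_patience) {
          lr *= plateau_factor; plateau_wait = 0;
        }
      }
    }
  }

  arma::vec thout = flatten<T>(L, net.P);
  List hist = List::create(Named("loss") = h_loss, Named("acc") = h_acc,
                           Named("lr") = h_lr);
  if (has_val) { hist["val_loss"] = h_vloss; hist["val_acc"] = h_vacc; }
  return List::create(
      Named("theta") = Rcpp::NumericVector(thout.begin(), thout.end()),
      Named("history") = hist, Named("clip_count") = (double)clip_count,
      Named("diverged") = diverged);
}

// [[Rcpp::export]]
List cpp_train(Rcpp::NumericVector theta, List cfg, Rcpp::NumericMatrix X,
               Rcpp::NumericMatrix M, Rcpp::NumericMatrix D,
               Rcpp::Nullable<Rcpp::NumericMatrix> P,
               Rcpp::IntegerVector y, List val, List tcfg, int seed) {
  arma::vec th(theta.begin(), theta.size());
  std::string prec = Rcpp::as<std::string>(tcfg["precision"]);
  if (prec == "double")
    return train_impl<double>(th, cfg, X, M, D, P, y, val, tcfg, seed);
  return train_impl<float>(th, cfg, X, M, D, P, y, val, tcfg, seed);
}
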