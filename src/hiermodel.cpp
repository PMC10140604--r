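// Hierarchical abstraction model: trainable transformer sentence encoder,
// bidirectional GRU across sentences, two-level (sentence -> note -> patient)
// attention, linear softmax classifier. Forward and analytic backward are
// implemented here; the R side owns the optimizer loop and tokenization.
//
// Parameter tensors live in a single flat vector (fixed walk order) so the
// optimizer and checkpoint code can treat the model as one numeric vector.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;

static const double LN_EPS = 1e-5;

struct Cfg {
  int V, d, L, H, F, G, A, C, M;
};

static Cfg get_cfg(const List& cfg) {
  Cfg c;
  c.V = as<int>(cfg["vocab_size"]);
  c.d = as<int>(cfg["emb_dim"]);
  c.L = as<int>(cfg["n_layers"]);
  c.H = as<int>(cfg["n_heads"]);
  c.F = as<int>(cfg["ffn_dim"]);
  c.G = as<int>(cfg["gru_hidden"]);
  c.A = as<int>(cfg["attn_dim"]);
  c.C = as<int>(cfg["n_labels"]);
  c.M = as<int>(cfg["max_tokens"]);
  if (c.d % c.H != 0) stop("emb_dim must be divisible by n_heads");
  return c;
}

struct Layer {
  mat Wq, Wk, Wv, Wo;
  vec bq, bk, bv, bo;
  vec g1, b1;            // layernorm after attention
  mat W1; vec c1;        // FFN in
  mat W2; vec c2;        // FFN out
  vec g2, b2;            // layernorm after FFN
};

struct Gru {
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  vec bz, br, bh;
};

struct Params {
  mat E, Pos;
  std::vector<Layer> layers;
  Gru fw, bw;
  mat Wa; vec ba, ua;
  mat Wn; vec bn, un;
  mat Wc; vec bc;
};

static void allocate(Params& P, const Cfg& c) {
  P.E.set_size(c.V, c.d);
  P.Pos.set_size(c.M + 1, c.d);
  P.layers.resize(c.L);
  for (auto& l : P.layers) {
    l.Wq.set_size(c.d, c.d); l.Wk.set_size(c.d, c.d);
    l.Wv.set_size(c.d, c.d); l.Wo.set_size(c.d, c.d);
    l.bq.set_size(c.d); l.bk.set_size(c.d); l.bv.set_size(c.d); l.bo.set_size(c.d);
    l.g1.set_size(c.d); l.b1.set_size(c.d);
    l.W1.set_size(c.d, c.F); l.c1.set_size(c.F);
    l.W2.set_size(c.F, c.d); l.c2.set_size(c.d);
    l.g2.set_size(c.d); l.b2.set_size(c.d);
  }
  for (Gru* g : {&P.fw, &P.bw}) {
    g->Wz.set_size(c.G, c.d); g->Wr.set_size(c.G, c.d); g->Wh.set_size(c.G, c.d);
    g->Uz.set_size(c.G, c.G); g->Ur.set_size(c.G, c.G); g->Uh.set_size(c.G, c.G);
    g->bz.set_size(c.G); g->br.set_size(c.G); g->bh.set_size(c.G);
  }
  P.Wa.set_size(c.A, 2 * c.G); P.ba.set_size(c.A); P.ua.set_size(c.A);
  P.Wn.set_size(c.A, 2 * c.G); P.bn.set_size(c.A); P.un.set_size(c.A);
  P.Wc.set_size(c.C, 2 * c.G); P.bc.set_size(c.C);
}

template <class F>
static void walk(Params& P, F&& f) {
  f(P.E); f(P.Pos);
  for (auto& l : P.layers) {
    f(l.Wq); f(l.bq); f(l.Wk); f(l.bk); f(l.Wv); f(l.bv); f(l.Wo); f(l.bo);
    f(l.g1); f(l.b1);
    f(l.W1); f(l.c1); f(l.W2); f(l.c2);
    f(l.g2); f(l.b2);
  }
  for (Gru* g : {&P.fw, &P.bw}) {
    f(g->Wz); f(g->Uz); f(g->bz);
    f(g->Wr); f(g->Ur); f(g->br);
    f(g->Wh); f(g->Uh); f(g->bh);
  }
  f(P.Wa); f(P.ba); f(P.ua);
  f(P.Wn); f(P.bn); f(P.un);
  f(P.Wc); f(P.bc);
}

static size_t n_params(const Cfg& c) {
  Params P; allocate(P, c);
  size_t n = 0;
  walk(P, [&](mat& m) { n += m.n_elem; });
  return n;
}

static void unpack(Params& P, const Cfg& c, const NumericVector& flat) {
  allocate(P, c);
  size_t need = n_params(c);
  if ((size_t)flat.size() != need)
    stop("parameter vector has length %d, expected %d", (int)flat.size(), (int)need);
  const double* src = REAL(flat);
  size_t off = 0;
  walk(P, [&](mat& m) {
    std::copy(src + off, src + off + m.n_elem, m.memptr());
    off += m.n_elem;
  });
}

static void pack(Params& P, NumericVector& flat) {
  double* dst = REAL(flat);
  size_t off = 0;
  walk(P, [&](mat& m) {
    std::copy(m.memptr(), m.memptr() + m.n_elem, dst + off);
    off += m.n_elem;
  });
}

static void zero_like(Params& G, const Cfg& c) {
  allocate(G, c);
  walk(G, [](mat& m) { m.zeros(); });
}

// [[Rcpp::export]]
int cppNParams(List cfg) { return (int)n_params(get_cfg(cfg)); }

// Initialization: Xavier-style for projections, N(0, 0.02) embeddings,
// layernorm at identity. Uses the R RNG so set.seed() governs it.
// [[Rcpp::export]]
NumericVector cppInitParams(List cfg) {
  Cfg c = get_cfg(cfg);
  Params P; allocate(P, c);
  P.E.imbue([] { return R::norm_rand() * 0.02; });
  P.Pos.imbue([] { return R::norm_rand() * 0.02; });
  auto xav = [](mat& m) {
    double s = std::sqrt(2.0 / (m.n_rows + m.n_cols));
    m.imbue([s] { return R::norm_rand() * s; });
  };
  for (auto& l : P.layers) {
    xav(l.Wq); xav(l.Wk); xav(l.Wv); xav(l.Wo);
    l.bq.zeros(); l.bk.zeros(); l.bv.zeros(); l.bo.zeros();
    l.g1.ones(); l.b1.zeros();
    xav(l.W1); l.c1.zeros(); xav(l.W2); l.c2.zeros();
    l.g2.ones(); l.b2.zeros();
  }
  for (Gru* g : {&P.fw, &P.bw}) {
    xav(g->Wz); xav(g->Wr); xav(g->Wh);
    xav(g->Uz); xav(g->Ur); xav(g->Uh);
    g->bz.zeros(); g->br.zeros(); g->bh.zeros();
  }
  xav(P.Wa); P.ba.zeros(); P.ua.imbue([] { return R::norm_rand() * 0.1; });
  xav(P.Wn); P.bn.zeros(); P.un.imbue([] { return R::norm_rand() * 0.1; });
  xav(P.Wc); P.bc.zeros();
  NumericVector flat((int)n_params(c));
  pack(P, flat);
  return flat;
}

// ---------------- transformer encoder ----------------

struct EncCache {
  mat X0;                       // embedded input (n x d)
  arma::uvec ids;               // token rows used (incl CLS)
  struct LayerCache {
    mat Xin, Q, K, V, Hcat, R1, X1, pre1, H1, R2, X2;
    cube A;                     // n x n x H attention (softmaxed)
    vec mu1, iv1, mu2, iv2;     // layernorm stats per row
  };
  std::vector<LayerCache> lc;
};

static mat layernorm(const mat& R, const vec& g, const vec& b,
                     vec& mu, vec& iv) {
  int n = R.n_rows, d = R.n_cols;
  mu.set_size(n); iv.set_size(n);
  mat Y(n, d);
  for (int i = 0; i < n; ++i) {
    rowvec r = R.row(i);
    double m = arma::mean(r);
    double v = arma::mean(arma::square(r - m));
    double ivi = 1.0 / std::sqrt(v + LN_EPS);
    mu(i) = m; iv(i) = ivi;
    Y.row(i) = ((r - m) * ivi) % g.t() + b.t();
  }
  return Y;
}

static mat layernorm_back(const mat& dY, const mat& R, const vec& g,
                          const vec& mu, const vec& iv,
                          vec& dg, vec& db) {
  int n = R.n_rows, d = R.n_cols;
  mat dR(n, d);
  for (int i = 0; i < n; ++i) {
    rowvec xc = R.row(i) - mu(i);
    rowvec xhat = xc * iv(i);
    rowvec dy = dY.row(i);
    dg += (dy % xhat).t();
    db += dy.t();
    rowvec dxhat = dy % g.t();
    double s1 = arma::accu(dxhat);
    double s2 = arma::accu(dxhat % xhat);
    dR.row(i) = iv(i) * (dxhat - s1 / d - xhat * s2 / d);
  }
  return dR;
}

// Encode one sentence fragment (token ids, 0-based, CLS prepended here).
// Returns pooled CLS vector; fills cache for backward, and the CLS->token
// attention of the final layer averaged over heads (renormalized without
// the CLS position).
static vec encode_forward(const Params& P, const Cfg& c,
                          const IntegerVector& toks, EncCache& cache,
                          vec* cls_attn) {
  int nt = toks.size();
  if (nt > c.M) stop("sentence fragment longer than max_tokens");
  int n = nt + 1;
  cache.ids.set_size(n);
  cache.ids(0) = 0;  // CLS row of E
  mat X(n, c.d);
  X.row(0) = P.E.row(0) + P.Pos.row(0);
  for (int t = 0; t < nt; ++t) {
    int id = toks[t];
    if (id < 0 || id >= c.V) stop("token id out of range");
    cache.ids(t + 1) = id;
    X.row(t + 1) = P.E.row(id) + P.Pos.row(t + 1);
  }
  cache.X0 = X;
  cache.lc.resize(c.L);
  int dh = c.d / c.H;
  double scale = 1.0 / std::sqrt((double)dh);
  for (int l = 0; l < c.L; ++l) {
    const Layer& ly = P.layers[l];
    auto& lc = cache.lc[l];
    lc.Xin = X;
    lc.Q = X * ly.Wq; lc.Q.each_row() += ly.bq.t();
    lc.K = X * ly.Wk; lc.K.each_row() += ly.bk.t();
    lc.V = X * ly.Wv; lc.V.each_row() += ly.bv.t();
    lc.A.set_size(n, n, c.H);
    lc.Hcat.set_size(n, c.d);
    for (int h = 0; h < c.H; ++h) {
      mat Qh = lc.Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = lc.K.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = lc.V.cols(h * dh, (h + 1) * dh - 1);
      mat S = Qh * Kh.t() * scale;
      for (int i = 0; i < n; ++i) {
        rowvec r = S.row(i);
        r -= r.max();
        rowvec e = arma::exp(r);
        S.row(i) = e / arma::accu(e);
      }
      lc.A.slice(h) = S;
      lc.Hcat.cols(h * dh, (h + 1) * dh - 1) = S * Vh;
    }
    mat O = lc.Hcat * ly.Wo; O.each_row() += ly.bo.t();
    lc.R1 = X + O;
    lc.X1 = layernorm(lc.R1, ly.g1, ly.b1, lc.mu1, lc.iv1);
    lc.pre1 = lc.X1 * ly.W1; lc.pre1.each_row() += ly.c1.t();
    lc.H1 = arma::clamp(lc.pre1, 0.0, arma::datum::inf);
    mat FF = lc.H1 * ly.W2; FF.each_row() += ly.c2.t();
    lc.R2 = lc.X1 + FF;
    lc.X2 = layernorm(lc.R2, ly.g2, ly.b2, lc.mu2, lc.iv2);
    X = lc.X2;
  }
  if (cls_attn) {
    vec a(std::max(n - 1, 0), arma::fill::zeros);
    if (n > 1) {
      const cube& A = cache.lc[c.L - 1].A;
      for (int h = 0; h < c.H; ++h)
        a += A.slice(h).row(0).subvec(1, n - 1).t();
      double s = arma::accu(a);
      if (s > 0) a /= s; else a.fill(1.0 / a.n_elem);
    }
    *cls_attn = a;
  }
  return X.row(0).t();
}

// Backward through the encoder given gradient of the pooled CLS vector.
static void encode_backward(const Params& P, const Cfg& c,
                            const EncCache& cache, const vec& dpooled,
                            Params& Gr) {
  int n = cache.X0.n_rows;
  int dh = c.d / c.H;
  double scale = 1.0 / std::sqrt((double)dh);
  mat dX(n, c.d, arma::fill::zeros);
  dX.row(0) = dpooled.t();
  for (int l = c.L - 1; l >= 0; --l) {
    const Layer& ly = P.layers[l];
    Layer& gl = Gr.layers[l];
    const auto& lc = cache.lc[l];
    // layernorm 2
    mat dR2 = layernorm_back(dX, lc.R2, ly.g2, lc.mu2, lc.iv2, gl.g2, gl.b2);
    mat dX1 = dR2;                      // residual
    mat dFF = dR2;
    gl.c2 += arma::sum(dFF, 0).t();
    gl.W2 += lc.H1.t() * dFF;
    mat dH1 = dFF * ly.W2.t();
    mat dpre1 = dH1 % arma::conv_to<mat>::from(lc.pre1 > 0);
    gl.c1 += arma::sum(dpre1, 0).t();
    gl.W1 += lc.X1.t() * dpre1;
    dX1 += dpre1 * ly.W1.t();
    // layernorm 1
    mat dR1 = layernorm_back(dX1, lc.R1, ly.g1, lc.mu1, lc.iv1, gl.g1, gl.b1);
    mat dXin = dR1;                     // residual
    mat dO = dR1;
    gl.bo += arma::sum(dO, 0).t();
    gl.Wo += lc.Hcat.t() * dO;
    mat dHcat = dO * ly.Wo.t();
    mat dQ(n, c.d, arma::fill::zeros), dK(n, c.d, arma::fill::zeros),
        dV(n, c.d, arma::fill::zeros);
    for (int h = 0; h < c.H; ++h) {
      mat A = lc.A.slice(h);
      mat Qh = lc.Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = lc.K.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = lc.V.cols(h * dh, (h + 1) * dh - 1);
      mat dOh = dHcat.cols(h * dh, (h + 1) * dh - 1);
      mat dA = dOh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = A.t() * dOh;
      // softmax rows backward
      mat dS(n, n);
      for (int i = 0; i < n; ++i) {
        rowvec ai = A.row(i);
        rowvec dai = dA.row(i);
        double dot = arma::accu(ai % dai);
        dS.row(i) = ai % (dai - dot);
      }
      dS *= scale;
      dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh;
      dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh;
    }
    gl.bq += arma::sum(dQ, 0).t(); gl.Wq += lc.Xin.t() * dQ;
    gl.bk += arma::sum(dK, 0).t(); gl.Wk += lc.Xin.t() * dK;
    gl.bv += arma::sum(dV, 0).t(); gl.Wv += lc.Xin.t() * dV;
    dXin += dQ * ly.Wq.t() + dK * ly.Wk.t() + dV * ly.Wv.t();
    dX = dXin;
  }
  for (int i = 0; i < n; ++i) {
    Gr.E.row(cache.ids(i)) += dX.row(i);
    Gr.Pos.row(i) += dX.row(i);
  }
}

// ---------------- GRU ----------------

struct GruCache {
  std::vector<vec> z, r, hh, h;   // per step (h has n entries; h[-1] = 0)
};

static void gru_forward(const Gru& g, const mat& S /* d x n */, GruCache& cc,
                        mat& H /* G x n */) {
  int n = S.n_cols, G = g.bz.n_elem;
  cc.z.resize(n); cc.r.resize(n); cc.hh.resize(n); cc.h.resize(n);
  vec h(G, arma::fill::zeros);
  H.set_size(G, n);
  for (int t = 0; t < n; ++t) {
    vec x = S.col(t);
    vec z = 1.0 / (1.0 + arma::exp(-(g.Wz * x + g.Uz * h + g.bz)));
    vec r = 1.0 / (1.0 + arma::exp(-(g.Wr * x + g.Ur * h + g.br)));
    vec hh = arma::tanh(g.Wh * x + g.Uh * (r % h) + g.bh);
    h = (1.0 - z) % h + z % hh;
    cc.z[t] = z; cc.r[t] = r; cc.hh[t] = hh; cc.h[t] = h;
    H.col(t) = h;
  }
}

static void gru_backward(const Gru& g, const mat& S, const GruCache& cc,
                         const mat& dH /* G x n */, Gru& gg,
                         mat& dS /* d x n */) {
  int n = S.n_cols, G = g.bz.n_elem;
  dS.zeros(S.n_rows, n);
  vec dh(G, arma::fill::zeros);
  for (int t = n - 1; t >= 0; --t) {
    dh += dH.col(t);
    vec hprev = (t == 0) ? vec(G, arma::fill::zeros) : cc.h[t - 1];
    const vec& z = cc.z[t];
    const vec& r = cc.r[t];
    const vec& hh = cc.hh[t];
    vec x = S.col(t);
    vec dz = dh % (hh - hprev);
    vec dhh = dh % z;
    vec dhprev = dh % (1.0 - z);
    vec dahh = dhh % (1.0 - hh % hh);
    gg.Wh += dahh * x.t(); gg.Uh += dahh * (r % hprev).t(); gg.bh += dahh;
    vec drh = g.Uh.t() * dahh;
    vec dr = drh % hprev;
    dhprev += drh % r;
    vec daz = dz % z % (1.0 - z);
    gg.Wz += daz * x.t(); gg.Uz += daz * hprev.t(); gg.bz += daz;
    dhprev += g.Uz.t() * daz;
    vec dar = dr % r % (1.0 - r);
    gg.Wr += dar * x.t(); gg.Ur += dar * hprev.t(); gg.br += dar;
    dhprev += g.Ur.t() * dar;
    dS.col(t) += g.Wz.t() * daz + g.Wr.t() * dar + g.Wh.t() * dahh;
    dh = dhprev;
  }
}

// ---------------- attention pooling ----------------

struct AttnCache {
  mat T;        // tanh(W c + b), A x n
  vec alpha;    // weights (within groups for level 1)
  mat items;    // pooled inputs (2G x n)
};

// softmax over scores within [lo, hi] inclusive
static void softmax_range(vec& s, int lo, int hi) {
  double m = s.subvec(lo, hi).max();
  double tot = 0;
  for (int i = lo; i <= hi; ++i) { s(i) = std::exp(s(i) - m); tot += s(i); }
  for (int i = lo; i <= hi; ++i) s(i) /= tot;
}

// ---------------- full model forward/backward ----------------

struct FwdOut {
  double loss;
  vec probs;
  vec sent_w;        // per fragment, normalized within note
  vec note_w;        // per note
  std::vector<vec> token_attn;
  mat S;             // pooled sentence vectors d x n (post-dropout)
  mat Ctx;           // contextual 2G x n
  vec patient;       // 2G
};

struct FullCache {
  std::vector<EncCache> enc;
  GruCache gf, gb;
  mat Sf;            // d x n sentence vectors fed to GRU
  mat Hf, Hb;        // G x n each
  AttnCache sa, na;
  vec pat_raw;       // before dropout
  vec drop_mask_p;   // 2G (scaled mask) or empty
  mat drop_mask_s;   // d x n or empty
  std::vector<int> note_of;  // fragment -> note index
  int n_notes;
};

static FwdOut model_forward(const Params& P, const Cfg& c,
                            const List& sent_toks, const IntegerVector& note_idx,
                            int label, double dropout, bool training,
                            bool want_attn, FullCache& cache) {
  int n = sent_toks.size();
  if (n == 0) stop("no sentences in window");
  if (note_idx.size() != n) stop("note_idx length mismatch");
  FwdOut out;
  // encode sentences
  cache.enc.resize(n);
  mat S(c.d, n);
  out.token_attn.resize(want_attn ? n : 0);
  for (int i = 0; i < n; ++i) {
    vec attn;
    vec pooled = encode_forward(P, c, sent_toks[i], cache.enc[i],
                                want_attn ? &attn : nullptr);
    if (want_attn) out.token_attn[i] = attn;
    S.col(i) = pooled;
  }
  // dropout on sentence vectors
  if (training && dropout > 0) {
    cache.drop_mask_s.set_size(c.d, n);
    double keep = 1.0 - dropout;
    for (arma::uword k = 0; k < cache.drop_mask_s.n_elem; ++k)
      cache.drop_mask_s(k) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    S = S % cache.drop_mask_s;
  } else cache.drop_mask_s.reset();
  cache.Sf = S;
  // bidirectional GRU
  gru_forward(P.fw, S, cache.gf, cache.Hf);
  mat Srev = arma::fliplr(S);
  mat Hbrev;
  gru_forward(P.bw, Srev, cache.gb, Hbrev);
  cache.Hb = arma::fliplr(Hbrev);
  mat Ctx = arma::join_cols(cache.Hf, cache.Hb);  // 2G x n
  out.Ctx = Ctx;
  // note boundaries
  cache.note_of.assign(note_idx.begin(), note_idx.end());
  int J = 0;
  for (int i = 0; i < n; ++i) {
    if (note_idx[i] != J - 1 && note_idx[i] != J) stop("note_idx must be nondecreasing 0,1,2,...");
    if (note_idx[i] == J) ++J;
  }
  cache.n_notes = J;
  // sentence-level attention within each note
  cache.sa.items = Ctx;
  cache.sa.T = arma::tanh(P.Wa * Ctx + arma::repmat(P.ba, 1, n));
  vec sc = (P.ua.t() * cache.sa.T).t();
  for (int j = 0; j < J; ++j) {
    int lo = -1, hi = -1;
    for (int i = 0; i < n; ++i)
      if (note_idx[i] == j) { if (lo < 0) lo = i; hi = i; }
    softmax_range(sc, lo, hi);
  }
  cache.sa.alpha = sc;
  mat N(2 * c.G, J, arma::fill::zeros);
  for (int i = 0; i < n; ++i) N.col(note_idx[i]) += sc(i) * Ctx.col(i);
  // note-level attention
  cache.na.items = N;
  cache.na.T = arma::tanh(P.Wn * N + arma::repmat(P.bn, 1, J));
  vec nsc = (P.un.t() * cache.na.T).t();
  softmax_range(nsc, 0, J - 1);
  cache.na.alpha = nsc;
  vec pat = N * nsc;
  cache.pat_raw = pat;
  if (training && dropout > 0) {
    cache.drop_mask_p.set_size(2 * c.G);
    double keep = 1.0 - dropout;
    for (arma::uword k = 0; k < cache.drop_mask_p.n_elem; ++k)
      cache.drop_mask_p(k) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
    pat = pat % cache.drop_mask_p;
  } else cache.drop_mask_p.reset();
  // classify
  vec logits = P.Wc * pat + P.bc;
  logits -= logits.max();
  vec ex = arma::exp(logits);
  out.probs = ex / arma::accu(ex);
  out.loss = (label >= 0) ? -std::log(std::max(out.probs(label), 1e-300)) : NA_REAL;
  out.sent_w = sc;
  out.note_w = nsc;
  out.S = S;
  out.patient = pat;
  return out;
}

static void model_backward(const Params& P, const Cfg& c, const FullCache& cache,
                           const FwdOut& out, int label, Params& Gr) {
  int n = cache.Sf.n_cols, J = cache.n_notes;
  // classifier
  vec dlog = out.probs;
  dlog(label) -= 1.0;
  Gr.Wc += dlog * out.patient.t();
  Gr.bc += dlog;
  vec dpat = P.Wc.t() * dlog;
  if (!cache.drop_mask_p.is_empty()) dpat = dpat % cache.drop_mask_p;
  // note-level attention backward
  const mat& N = cache.na.items;
  const vec& beta = cache.na.alpha;
  mat dN(2 * c.G, J, arma::fill::zeros);
  vec dbeta(J);
  for (int j = 0; j < J; ++j) {
    dbeta(j) = arma::dot(N.col(j), dpat);
    dN.col(j) += beta(j) * dpat;
  }
  double bdot = arma::dot(beta, dbeta);
  vec dnsc = beta % (dbeta - bdot);
  // scores f_j = un' tanh(Wn n_j + bn)
  for (int j = 0; j < J; ++j) {
    vec tj = cache.na.T.col(j);
    Gr.un += dnsc(j) * tj;
    vec dt = dnsc(j) * P.un;
    vec da = dt % (1.0 - tj % tj);
    Gr.Wn += da * N.col(j).t();
    Gr.bn += da;
    dN.col(j) += P.Wn.t() * da;
  }
  // sentence-level attention backward
  const mat& Ctx = cache.sa.items;
  const vec& alpha = cache.sa.alpha;
  mat dCtx(2 * c.G, n, arma::fill::zeros);
  vec dalpha(n);
  for (int i = 0; i < n; ++i) {
    int j = cache.note_of[i];
    dalpha(i) = arma::dot(Ctx.col(i), dN.col(j));
    dCtx.col(i) += alpha(i) * dN.col(j);
  }
  vec dsc(n);
  for (int j = 0; j < J; ++j) {
    double dot = 0;
    for (int i = 0; i < n; ++i)
      if (cache.note_of[i] == j) dot += alpha(i) * dalpha(i);
    for (int i = 0; i < n; ++i)
      if (cache.note_of[i] == j) dsc(i) = alpha(i) * (dalpha(i) - dot);
  }
  for (int i = 0; i < n; ++i) {
    vec ti = cache.sa.T.col(i);
    Gr.ua += dsc(i) * ti;
    vec dt = dsc(i) * P.ua;
    vec da = dt % (1.0 - ti % ti);
    Gr.Wa += da * Ctx.col(i).t();
    Gr.ba += da;
    dCtx.col(i) += P.Wa.t() * da;
  }
  // split into fwd/bwd GRU streams
  mat dHf = dCtx.rows(0, c.G - 1);
  mat dHb = dCtx.rows(c.G, 2 * c.G - 1);
  mat dS1, dS2rev;
  gru_backward(P.fw, cache.Sf, cache.gf, dHf, Gr.fw, dS1);
  mat Srev = arma::fliplr(cache.Sf);
  gru_backward(P.bw, Srev, cache.gb, arma::fliplr(dHb), Gr.bw, dS2rev);
  mat dS = dS1 + arma::fliplr(dS2rev);
  if (!cache.drop_mask_s.is_empty()) dS = dS % cache.drop_mask_s;
  // encoder backward per sentence
  for (int i = 0; i < n; ++i)
    encode_backward(P, c, cache.enc[i], dS.col(i), Gr);
}

// Full forward (+ optional backward). sent_toks: list of integer vectors of
// 0-based token ids (no CLS); note_idx: 0-based nondecreasing note index per
// fragment; label: 0-based class index or -1.
// [[Rcpp::export]]
List cppForward(NumericVector params, List cfg, List sent_toks,
                IntegerVector note_idx, int label = -1,
                double dropout = 0.0, bool training = false,
                bool want_grad = false, bool want_attn = false) {
  Cfg c = get_cfg(cfg);
  Params P; unpack(P, c, params);
  FullCache cache;
  FwdOut out = model_forward(P, c, sent_toks, note_idx, label, dropout,
                             training, want_attn, cache);
  List res = List::create(
    _["loss"] = out.loss,
    _["probs"] = NumericVector(out.probs.begin(), out.probs.end()),
    _["sent_w"] = NumericVector(out.sent_w.begin(), out.sent_w.end()),
    _["note_w"] = NumericVector(out.note_w.begin(), out.note_w.end()));
  if (want_attn) {
    List ta(out.token_attn.size());
    for (size_t i = 0; i < out.token_attn.size(); ++i)
      ta[i] = NumericVector(out.token_attn[i].begin(), out.token_attn[i].end());
    res["token_attn"] = ta;
  }
  if (want_grad) {
    if (label < 0) stop("gradient requires a label");
    Params Gr; zero_like(Gr, c);
    model_backward(P, c, cache, out, label, Gr);
    NumericVector flat((int)n_params(c));
    pack(Gr, flat);
    res["grad"] = flat;
  }
  return res;
}

// Encoder only: pooled vector per fragment plus CLS->token attention rows.
// [[Rcpp::export]]
List cppEncode(NumericVector params, List cfg, List sent_toks) {
  Cfg c = get_cfg(cfg);
  Params P; unpack(P, c, params);
  int n = sent_toks.size();
  if (n == 0) stop("no sentences in window");
  NumericMatrix S(c.d, n);
  List ta(n);
  for (int i = 0; i < n; ++i) {
    EncCache cc; vec attn;
    vec pooled = encode_forward(P, c, sent_toks[i], cc, &attn);
    std::copy(pooled.begin(), pooled.end(), S.column(i).begin());
    ta[i] = NumericVector(attn.begin(), attn.end());
  }
  return List::create(_["vectors"] = S, _["token_attn"] = ta);
}

// Bidirectional GRU over externally supplied sentence vectors (d x n).
// [[Rcpp::export]]
NumericMatrix cppContextualize(NumericVector params, List cfg, NumericMatrix svec) {
  Cfg c = get_cfg(cfg);
  Params P; unpack(P, c, params);
  mat S(svec.begin(), svec.nrow(), svec.ncol());
  if ((int)S.n_rows != c.d) stop("sentence vectors must have emb_dim rows");
  GruCache g1, g2; mat Hf, Hbrev;
  gru_forward(P.fw, S, g1, Hf);
  gru_forward(P.bw, arma::fliplr(S), g2, Hbrev);
  mat Ctx = arma::join_cols(Hf, arma::fliplr(Hbrev));
  return NumericMatrix(Ctx.n_rows, Ctx.n_cols, Ctx.memptr());
}

// Two-level attention pooling over contextual vectors (2G x n).
// [[Rcpp::export]]
List cppAggregate(NumericVector params, List cfg, NumericMatrix ctx,
                  IntegerVector note_idx) {
  Cfg c = get_cfg(cfg);
  Params P; unpack(P, c, params);
  mat Ctx(ctx.begin(), ctx.nrow(), ctx.ncol());
  int n = Ctx.n_cols;
  if ((int)Ctx.n_rows != 2 * c.G) stop("contextual vectors must have 2*gru_hidden rows");
  int J = 0;
  for (int i = 0; i < n; ++i) {
    if (note_idx[i] != J - 1 && note_idx[i] != J) stop("note_idx must be nondecreasing 0,1,2,...");
    if (note_idx[i] == J) ++J;
  }
  mat T = arma::tanh(P.Wa * Ctx + arma::repmat(P.ba, 1, n));
  vec sc = (P.ua.t() * T).t();
  for (int j = 0; j < J; ++j) {
    int lo = -1, hi = -1;
    for (int i = 0; i < n; ++i)
      if (note_idx[i] == j) { if (lo < 0) lo = i; hi = i; }
    softmax_range(sc, lo, hi);
  }
  mat N(2 * c.G, J, arma::fill::zeros);
  for (int i = 0; i < n; ++i) N.col(note_idx[i]) += sc(i) * Ctx.col(i);
  mat Tn = arma::tanh(P.Wn * N + arma::repmat(P.bn, 1, J));
  vec nsc = (P.un.t() * Tn).t();
  softmax_range(nsc, 0, J - 1);
  vec pat = N * nsc;
  return List::create(
    _["patient"] = NumericVector(pat.begin(), pat.end()),
    _["sent_w"] = NumericVector(sc.begin(), sc.end()),
    _["note_w"] = NumericVector(nsc.begin(), nsc.end()));
}

// Linear + softmax head on a patient vector.
// [[Rcpp::export]]
NumericVector cppClassify(NumericVector params, List cfg, NumericVector pvec) {
  Cfg c = get_cfg(cfg);
  Params P; unpack(P, c, params);
  vec p(pvec.begin(), pvec.size());
  if ((int)p.n_elem != 2 * c.G) stop("patient vector must have length 2*gru_hidden");
  vec logits = P.Wc * p + P.bc;
  logits -= logits.max();
  vec ex = arma::exp(logits);
  vec probs = ex / arma::accu(ex);
  return NumericVector(probs.begin(), probs.end());
}
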