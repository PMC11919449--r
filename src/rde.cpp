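// Reference-free DNA embedding (RDE) encoder: a pre-LayerNorm Transformer
// with learned absolute positions, masked mean pooling over final-layer
// token states, a linear projection head, and L2 normalization, trained with
// an in-batch-negative contrastive loss on (read, fragment) pairs where
// d(x, y) = 1 - cosine(x, y) and logits are -d/tau.
//
// Forward and backward passes are written out analytically; a numerical
// gradient check in the test suite validates the backward pass end to end
// (in double precision; training and inference default to single precision,
// which roughly doubles BLAS throughput at this model scale).  Sequences are
// padded to the longest in the batch (PAD id 0) and excluded from attention
// (as keys) and from pooling by the length mask.  Dropout (inverted, applied
// to each sublayer output) uses its own seeded generator so that reads and
// fragments receive independent masks and training steps are reproducible.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LN_EPS = 1e-5;

template <typename eT> struct LayerP {
  arma::Col<eT> ln1_g, ln1_b;
  arma::Mat<eT> Wq, Wk, Wv, Wo;
  arma::Col<eT> ln2_g, ln2_b;
  arma::Mat<eT> W1; arma::Col<eT> b1; arma::Mat<eT> W2; arma::Col<eT> b2;
};

template <typename eT> struct RDEP {
  int V, d, L, H, P, maxT, ff;
  arma::Mat<eT> Wemb, Wpos;
  std::vector<LayerP<eT>> layers;
  arma::Col<eT> lnf_g, lnf_b;
  arma::Mat<eT> Wproj; arma::Col<eT> bproj;
};

static long long rde_count(int V, int d, int L, int P, int maxT, int ff) {
  long long per_layer = 2LL * d + 4LL * d * d + 2LL * d +
                        (long long)d * ff + ff + (long long)ff * d + d;
  return (long long)V * d + (long long)maxT * d + (long long)L * per_layer +
         2LL * d + (long long)d * P + P;
}

// Build non-owning armadillo views over a flat parameter (or gradient)
// buffer of the matching element type.
template <typename eT>
static RDEP<eT> make_views(eT *p, const List &cfg) {
  RDEP<eT> m;
  m.V = cfg["vocab_size"]; m.d = cfg["model_width"]; m.L = cfg["n_layers"];
  m.H = cfg["n_heads"]; m.P = cfg["projection_dim"]; m.maxT = cfg["max_tokens"];
  m.ff = cfg["ff_width"];
  eT *q = p;
  auto take_mat = [&q](int r, int c) {
    arma::Mat<eT> v(q, r, c, false, true); q += (long long)r * c; return v;
  };
  auto take_vec = [&q](int n) {
    arma::Col<eT> v(q, n, false, true); q += n; return v;
  };
  m.Wemb = take_mat(m.V, m.d);
  m.Wpos = take_mat(m.maxT, m.d);
  m.layers.reserve(m.L);  // no reallocation: views must keep their aliasing
  for (int l = 0; l < m.L; ++l) {
    LayerP<eT> lp;
    lp.ln1_g = take_vec(m.d); lp.ln1_b = take_vec(m.d);
    lp.Wq = take_mat(m.d, m.d); lp.Wk = take_mat(m.d, m.d);
    lp.Wv = take_mat(m.d, m.d); lp.Wo = take_mat(m.d, m.d);
    lp.ln2_g = take_vec(m.d); lp.ln2_b = take_vec(m.d);
    lp.W1 = take_mat(m.d, m.ff); lp.b1 = take_vec(m.ff);
    lp.W2 = take_mat(m.ff, m.d); lp.b2 = take_vec(m.d);
    m.layers.push_back(std::move(lp));
  }
  m.lnf_g = take_vec(m.d); m.lnf_b = take_vec(m.d);
  m.Wproj = take_mat(m.d, m.P); m.bproj = take_vec(m.P);
  return m;
}

// [[Rcpp::export]]
double rde_param_count_cpp(List cfg) {
  return (double)rde_count(cfg["vocab_size"], cfg["model_width"],
                           cfg["n_layers"], cfg["projection_dim"],
                           cfg["max_tokens"], cfg["ff_width"]);
}

template <typename eT> struct LNCache {
  arma::Mat<eT> xhat;
  arma::Col<eT> isig;
};

template <typename eT>
static arma::Mat<eT> layer_norm(const arma::Mat<eT> &X, const arma::Col<eT> &g,
                                const arma::Col<eT> &b, LNCache<eT> *c) {
  const int d = X.n_cols;
  arma::Col<eT> mu = arma::mean(X, 1);
  arma::Mat<eT> xhat = X.each_col() - mu;
  arma::Col<eT> isig =
      eT(1) / arma::sqrt(arma::sum(xhat % xhat, 1) / d + eT(LN_EPS));
  xhat.each_col() %= isig;
  arma::Mat<eT> Y = xhat;
  Y.each_row() %= g.t();
  Y.each_row() += b.t();
  if (c) { c->xhat = std::move(xhat); c->isig = std::move(isig); }
  return Y;
}

template <typename eT>
static arma::Mat<eT> layer_norm_bwd(const arma::Mat<eT> &dY,
                                    const LNCache<eT> &c,
                                    const arma::Col<eT> &g,
                                    arma::Col<eT> &dg, arma::Col<eT> &db) {
  dg += arma::sum(dY % c.xhat, 0).t();
  db += arma::sum(dY, 0).t();
  arma::Mat<eT> dxhat = dY;
  dxhat.each_row() %= g.t();
  arma::Col<eT> m1 = arma::mean(dxhat, 1);
  arma::Col<eT> m2 = arma::mean(dxhat % c.xhat, 1);
  arma::Mat<eT> dX = dxhat.each_col() - m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.isig;
  return dX;
}

template <typename eT> struct SeqCache {
  int T, len;
  arma::ivec ids;
  struct LayerC {
    arma::Mat<eT> A1, Q, K, V, Ocat, M1, A2, Hpre, M2;
    LNCache<eT> ln1, ln2;
    arma::Cube<eT> Pattn;
  };
  std::vector<LayerC> layers;
  LNCache<eT> lnf;
  arma::Col<eT> pooled, z, e;
  eT znorm;
};

template <typename eT>
static arma::Mat<eT> dropout_mask(int r, int c, double p,
                                  std::mt19937_64 &rng) {
  arma::Mat<eT> M(r, c);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const eT scale = eT(1.0 / (1.0 - p));
  for (int j = 0; j < c; ++j)
    for (int i = 0; i < r; ++i) M(i, j) = U(rng) < p ? eT(0) : scale;
  return M;
}

// Forward one sequence of `T` real tokens (ids 0-based); fills the cache
// when non-null (training also passes dropout rate and its generator).
template <typename eT>
static arma::Col<eT> rde_forward_seq(const RDEP<eT> &m, const int *ids, int T,
                                     SeqCache<eT> *cache, double p,
                                     std::mt19937_64 *rng) {
  const int d = m.d, H = m.H, dh = d / H;
  const eT iscale = eT(1.0 / std::sqrt((double)dh));
  arma::Mat<eT> X(T, d);
  for (int t = 0; t < T; ++t) X.row(t) = m.Wemb.row(ids[t]) + m.Wpos.row(t);
  if (cache) {
    cache->T = T; cache->len = T;
    cache->ids = arma::ivec(T);
    for (int t = 0; t < T; ++t) cache->ids(t) = ids[t];
    cache->layers.resize(m.L);
  }
  for (int l = 0; l < m.L; ++l) {
    typename SeqCache<eT>::LayerC *lc = cache ? &cache->layers[l] : nullptr;
    const LayerP<eT> &lp = m.layers[l];
    arma::Mat<eT> A1 = layer_norm(X, lp.ln1_g, lp.ln1_b,
                                  lc ? &lc->ln1 : nullptr);
    arma::Mat<eT> Q = A1 * lp.Wq, K = A1 * lp.Wk, V = A1 * lp.Wv;
    arma::Mat<eT> Ocat(T, d);
    arma::Cube<eT> Pc;
    if (lc) Pc.set_size(T, T, H);
    for (int h = 0; h < H; ++h) {
      arma::Mat<eT> S = Q.cols(h * dh, (h + 1) * dh - 1) *
                        K.cols(h * dh, (h + 1) * dh - 1).t() * iscale;
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      Ocat.cols(h * dh, (h + 1) * dh - 1) =
          S * V.cols(h * dh, (h + 1) * dh - 1);
      if (lc) Pc.slice(h) = S;
    }
    arma::Mat<eT> O = Ocat * lp.Wo;
    arma::Mat<eT> M1;
    if (p > 0.0 && rng) { M1 = dropout_mask<eT>(T, d, p, *rng); O %= M1; }
    arma::Mat<eT> Xmid = X + O;
    arma::Mat<eT> A2 = layer_norm(Xmid, lp.ln2_g, lp.ln2_b,
                                  lc ? &lc->ln2 : nullptr);
    arma::Mat<eT> Hpre = A2 * lp.W1;
    Hpre.each_row() += lp.b1.t();
    arma::Mat<eT> Ff =
        arma::clamp(Hpre, eT(0), std::numeric_limits<eT>::max()) * lp.W2;
    Ff.each_row() += lp.b2.t();
    arma::Mat<eT> M2;
    if (p > 0.0 && rng) { M2 = dropout_mask<eT>(T, d, p, *rng); Ff %= M2; }
    if (lc) {
      lc->A1 = std::move(A1); lc->Q = std::move(Q); lc->K = std::move(K);
      lc->V = std::move(V); lc->Ocat = std::move(Ocat);
      lc->M1 = std::move(M1); lc->A2 = std::move(A2);
      lc->Hpre = std::move(Hpre); lc->M2 = std::move(M2);
      lc->Pattn = std::move(Pc);
    }
    X = Xmid + Ff;
  }
  arma::Mat<eT> Y = layer_norm(X, m.lnf_g, m.lnf_b,
                               cache ? &cache->lnf : nullptr);
  arma::Col<eT> pooled = arma::sum(Y, 0).t() / eT(T);
  arma::Col<eT> z = m.Wproj.t() * pooled + m.bproj;
  eT zn = std::max(arma::norm(z), eT(1e-12));
  arma::Col<eT> e = z / zn;
  if (cache) {
    cache->pooled = std::move(pooled);
    cache->z = std::move(z); cache->e = e; cache->znorm = zn;
  }
  return e;
}

// Backward one sequence given d(loss)/d(embedding); accumulates into g.
template <typename eT>
static void rde_backward_seq(const RDEP<eT> &m, RDEP<eT> &g,
                             const SeqCache<eT> &c, const arma::Col<eT> &de) {
  const int d = m.d, H = m.H, dh = d / H, T = c.T;
  const eT iscale = eT(1.0 / std::sqrt((double)dh));
  arma::Col<eT> dz = (de - c.e * arma::dot(c.e, de)) / c.znorm;
  g.Wproj += c.pooled * dz.t();
  g.bproj += dz;
  arma::Col<eT> dpooled = m.Wproj * dz;
  arma::Mat<eT> dY(T, d);
  dY.each_row() = dpooled.t() / eT(T);
  arma::Mat<eT> dX = layer_norm_bwd(dY, c.lnf, m.lnf_g, g.lnf_g, g.lnf_b);
  for (int l = m.L - 1; l >= 0; --l) {
    const LayerP<eT> &lp = m.layers[l];
    LayerP<eT> &gl = g.layers[l];
    const typename SeqCache<eT>::LayerC &lc = c.layers[l];
    // feed-forward sublayer
    arma::Mat<eT> dFf = dX;
    if (!lc.M2.is_empty()) dFf %= lc.M2;
    arma::Mat<eT> Hrelu =
        arma::clamp(lc.Hpre, eT(0), std::numeric_limits<eT>::max());
    gl.W2 += Hrelu.t() * dFf;
    gl.b2 += arma::sum(dFf, 0).t();
    arma::Mat<eT> dHpre = (dFf * lp.W2.t()) %
                          arma::conv_to<arma::Mat<eT>>::from(lc.Hpre > eT(0));
    gl.W1 += lc.A2.t() * dHpre;
    gl.b1 += arma::sum(dHpre, 0).t();
    arma::Mat<eT> dA2 = dHpre * lp.W1.t();
    arma::Mat<eT> dXmid =
        dX + layer_norm_bwd(dA2, lc.ln2, lp.ln2_g, gl.ln2_g, gl.ln2_b);
    // attention sublayer
    arma::Mat<eT> dO = dXmid;
    if (!lc.M1.is_empty()) dO %= lc.M1;
    gl.Wo += lc.Ocat.t() * dO;
    arma::Mat<eT> dOcat = dO * lp.Wo.t();
    arma::Mat<eT> dQ(T, d), dK(T, d), dV(T, d);
    for (int h = 0; h < H; ++h) {
      arma::Mat<eT> dOh = dOcat.cols(h * dh, (h + 1) * dh - 1);
      const arma::Mat<eT> &P = lc.Pattn.slice(h);
      arma::Mat<eT> dP = dOh * lc.V.cols(h * dh, (h + 1) * dh - 1).t();
      dV.cols(h * dh, (h + 1) * dh - 1) = P.t() * dOh;
      arma::Col<eT> rs = arma::sum(dP % P, 1);
      arma::Mat<eT> dS = P % (dP.each_col() - rs);
      dQ.cols(h * dh, (h + 1) * dh - 1) =
          dS * lc.K.cols(h * dh, (h + 1) * dh - 1) * iscale;
      dK.cols(h * dh, (h + 1) * dh - 1) =
          dS.t() * lc.Q.cols(h * dh, (h + 1) * dh - 1) * iscale;
    }
    gl.Wq += lc.A1.t() * dQ;
    gl.Wk += lc.A1.t() * dK;
    gl.Wv += lc.A1.t() * dV;
    arma::Mat<eT> dA1 = dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
    dX = dXmid + layer_norm_bwd(dA1, lc.ln1, lp.ln1_g, gl.ln1_g, gl.ln1_b);
  }
  for (int t = 0; t < T; ++t) {
    g.Wemb.row(c.ids(t)) += dX.row(t);
    g.Wpos.row(t) += dX.row(t);
  }
}

template <typename eT>
static NumericMatrix embed_impl(NumericVector params, List cfg,
                                IntegerMatrix ids, IntegerVector lens) {
  std::vector<eT> buf_p(params.begin(), params.end());
  RDEP<eT> m = make_views(buf_p.data(), cfg);
  const int n = ids.nrow();
  NumericMatrix out(n, m.P);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    int T = lens[i];
    if (T < 1) stop("empty token sequence");
    if (T > m.maxT) stop("sequence of %d tokens exceeds max_tokens=%d", T, m.maxT);
    buf.assign(T, 0);
    for (int t = 0; t < T; ++t) buf[t] = ids(i, t);
    arma::Col<eT> e =
        rde_forward_seq<eT>(m, buf.data(), T, nullptr, 0.0, nullptr);
    for (int p = 0; p < m.P; ++p) out(i, p) = (double)e(p);
  }
  return out;
}

// Eval-mode embedding of a padded batch (rows of `ids`, PAD=0 past lens).
// [[Rcpp::export]]
NumericMatrix rde_embed_cpp(NumericVector params, List cfg, IntegerMatrix ids,
                            IntegerVector lens, bool single = true) {
  return single ? embed_impl<float>(params, cfg, ids, lens)
                : embed_impl<double>(params, cfg, ids, lens);
}

template <typename eT>
static List loss_grad_impl(NumericVector params, List cfg,
                           IntegerMatrix read_ids, IntegerVector read_lens,
                           IntegerMatrix frag_ids, IntegerVector frag_lens,
                           double tau, double dropout, int seed,
                           bool want_grad) {
  const int B = read_ids.nrow();
  if (frag_ids.nrow() != B) stop("mismatched batch sizes");
  std::vector<eT> buf_p(params.begin(), params.end());
  RDEP<eT> m = make_views(buf_p.data(), cfg);
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<SeqCache<eT>> cr(B), cf(B);
  arma::Mat<eT> Er(B, m.P), Ef(B, m.P);
  std::vector<int> buf;
  auto fwd = [&](const IntegerMatrix &idm, const IntegerVector &lens, int i,
                 SeqCache<eT> *cc) {
    int T = lens[i];
    if (T < 1) stop("empty token sequence");
    if (T > m.maxT) stop("sequence of %d tokens exceeds max_tokens=%d", T, m.maxT);
    buf.assign(T, 0);
    for (int t = 0; t < T; ++t) buf[t] = idm(i, t);
    return rde_forward_seq<eT>(m, buf.data(), T, cc, dropout, &rng);
  };
  for (int i = 0; i < B; ++i)
    Er.row(i) = fwd(read_ids, read_lens, i, want_grad ? &cr[i] : nullptr).t();
  for (int i = 0; i < B; ++i)
    Ef.row(i) = fwd(frag_ids, frag_lens, i, want_grad ? &cf[i] : nullptr).t();
  // logits_ij = -(1 - <e_r_i, e_f_j>)/tau ; positives on the diagonal
  arma::Mat<eT> logits = (Er * Ef.t() - eT(1)) / eT(tau);
  double loss = 0.0;
  arma::Mat<eT> Pm(B, B);
  for (int i = 0; i < B; ++i) {
    eT mx = logits.row(i).max();
    arma::Row<eT> ex = arma::exp(logits.row(i) - mx);
    eT Z = arma::accu(ex);
    Pm.row(i) = ex / Z;
    loss += -(double)(logits(i, i) - mx - std::log(Z));
  }
  loss /= B;
  double pos_d = 0.0, neg_d = 0.0;
  for (int i = 0; i < B; ++i)
    for (int j = 0; j < B; ++j) {
      double dij = 1.0 - (double)arma::dot(Er.row(i), Ef.row(j));
      if (i == j) pos_d += dij; else neg_d += dij;
    }
  pos_d /= B;
  if (B > 1) neg_d /= (double)B * (B - 1);
  if (!want_grad)
    return List::create(_["loss"] = loss, _["pos_dist"] = pos_d,
                        _["neg_dist"] = neg_d);
  arma::Mat<eT> dlogits = Pm;
  dlogits.diag() -= eT(1);
  dlogits /= eT(B);
  arma::Mat<eT> dEr = dlogits * Ef / eT(tau);
  arma::Mat<eT> dEf = dlogits.t() * Er / eT(tau);
  std::vector<eT> buf_g(buf_p.size(), eT(0));
  RDEP<eT> g = make_views(buf_g.data(), cfg);
  for (int i = 0; i < B; ++i) rde_backward_seq<eT>(m, g, cr[i], dEr.row(i).t());
  for (int i = 0; i < B; ++i) rde_backward_seq<eT>(m, g, cf[i], dEf.row(i).t());
  NumericVector grad((R_xlen_t)params.size());
  for (R_xlen_t k = 0; k < grad.size(); ++k) grad[k] = (double)buf_g[k];
  return List::create(_["loss"] = loss, _["grad"] = grad, _["pos_dist"] = pos_d,
                      _["neg_dist"] = neg_d);
}

// Contrastive loss + full parameter gradient for a batch of (read, fragment)
// pairs.  Row i of read_ids pairs with row i of frag_ids.
// [[Rcpp::export]]
List rde_loss_grad_cpp(NumericVector params, List cfg, IntegerMatrix read_ids,
                       IntegerVector read_lens, IntegerMatrix frag_ids,
                       IntegerVector frag_lens, double tau, double dropout,
                       int seed, bool want_grad = true, bool single = true) {
  if (tau <= 0) stop("temperature must be positive");
  return single ? loss_grad_impl<float>(params, cfg, read_ids, read_lens,
                                        frag_ids, frag_lens, tau, dropout,
                                        seed, want_grad)
                : loss_grad_impl<double>(params, cfg, read_ids, read_lens,
                                         frag_ids, frag_lens, tau, dropout,
                                         seed, want_grad);
}
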