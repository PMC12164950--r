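// Compute kernels for the encoder-decoder transformer: forward,
// backward and decoding steps over a flat parameter vector. The R
// implementation of the same math (R/seq2seq.R) is the reference the
// test suite checks these kernels against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::IntegerVector;
using Rcpp::NumericVector;

static const double LN_EPS = 1e-5;

// ---------------------------------------------------------------------
// Parameter layout. Order mirrors the R constructor exactly:
// emb (V x d), out_W (d x V), out_b (V),
// per encoder layer: Wq Wk Wv Wo (d x d), ln1_g ln1_b (d),
//                    W1 (d x ff), b1 (ff), W2 (ff x d), b2 (d),
//                    ln3_g ln3_b (d)
// per decoder layer: Wq Wk Wv Wo, ln1_g ln1_b, Cq Ck Cv Co,
//                    ln2_g ln2_b, W1 b1 W2 b2, ln3_g ln3_b
// ---------------------------------------------------------------------

struct Dims {
  int V, d, nh, ff, n_enc, n_dec;
};

struct Cursor {
  const double* p;
  double* g;
  size_t off;
  Cursor(const double* p_, double* g_) : p(p_), g(g_), off(0) {}
  mat M(int nr, int nc) {
    mat out(const_cast<double*>(p) + off, nr, nc, false, true);
    off += (size_t)nr * nc;
    return out;
  }
  // gradient view aligned with the most recent parameter view
  mat GM(int nr, int nc, size_t at) {
    return mat(g + at, nr, nc, false, true);
  }
};

// A parameter matrix paired with its gradient accumulator.
struct PG {
  mat W;  // parameter view
  mat G;  // gradient view (may alias a dummy when grads not needed)
};

struct Params {
  mat emb, out_W;
  rowvec out_b;
  mat g_emb, g_out_W;
  rowvec g_out_b;  // views
  std::vector<std::map<std::string, mat>> enc, dec;
  std::vector<std::map<std::string, mat>> genc, gdec;
};

static void take(std::map<std::string, mat>& dst,
                 std::map<std::string, mat>& gdst,
                 const char* name, const double* p, double* g,
                 size_t& off, int nr, int nc) {
  dst[name] = mat(const_cast<double*>(p) + off, nr, nc, false, true);
  gdst[name] = mat(g + off, nr, nc, false, true);
  off += (size_t)nr * nc;
}

static void unpack(const double* p, double* g, const Dims& dm, Params& P) {
  size_t off = 0;
  P.emb = mat(const_cast<double*>(p) + off, dm.V, dm.d, false, true);
  P.g_emb = mat(g + off, dm.V, dm.d, false, true);
  off += (size_t)dm.V * dm.d;
  // encoder-only parameter blocks (n_dec == 0) carry no output head
  if (dm.n_dec > 0) {
    P.out_W = mat(const_cast<double*>(p) + off, dm.d, dm.V, false, true);
    P.g_out_W = mat(g + off, dm.d, dm.V, false, true);
    off += (size_t)dm.d * dm.V;
    P.out_b = rowvec(const_cast<double*>(p) + off, dm.V, false, true);
    P.g_out_b = rowvec(g + off, dm.V, false, true);
    off += dm.V;
  }
  P.enc.resize(dm.n_enc); P.genc.resize(dm.n_enc);
  for (int i = 0; i < dm.n_enc; i++) {
    auto& L = P.enc[i]; auto& G = P.genc[i];
    take(L, G, "Wq", p, g, off, dm.d, dm.d);
    take(L, G, "Wk", p, g, off, dm.d, dm.d);
    take(L, G, "Wv", p, g, off, dm.d, dm.d);
    take(L, G, "Wo", p, g, off, dm.d, dm.d);
    take(L, G, "ln1_g", p, g, off, 1, dm.d);
    take(L, G, "ln1_b", p, g, off, 1, dm.d);
    take(L, G, "W1", p, g, off, dm.d, dm.ff);
    take(L, G, "b1", p, g, off, 1, dm.ff);
    take(L, G, "W2", p, g, off, dm.ff, dm.d);
    take(L, G, "b2", p, g, off, 1, dm.d);
    take(L, G, "ln3_g", p, g, off, 1, dm.d);
    take(L, G, "ln3_b", p, g, off, 1, dm.d);
  }
  P.dec.resize(dm.n_dec); P.gdec.resize(dm.n_dec);
  for (int i = 0; i < dm.n_dec; i++) {
    auto& L = P.dec[i]; auto& G = P.gdec[i];
    take(L, G, "Wq", p, g, off, dm.d, dm.d);
    take(L, G, "Wk", p, g, off, dm.d, dm.d);
    take(L, G, "Wv", p, g, off, dm.d, dm.d);
    take(L, G, "Wo", p, g, off, dm.d, dm.d);
    take(L, G, "ln1_g", p, g, off, 1, dm.d);
    take(L, G, "ln1_b", p, g, off, 1, dm.d);
    take(L, G, "Cq", p, g, off, dm.d, dm.d);
    take(L, G, "Ck", p, g, off, dm.d, dm.d);
    take(L, G, "Cv", p, g, off, dm.d, dm.d);
    take(L, G, "Co", p, g, off, dm.d, dm.d);
    take(L, G, "ln2_g", p, g, off, 1, dm.d);
    take(L, G, "ln2_b", p, g, off, 1, dm.d);
    take(L, G, "W1", p, g, off, dm.d, dm.ff);
    take(L, G, "b1", p, g, off, 1, dm.ff);
    take(L, G, "W2", p, g, off, dm.ff, dm.d);
    take(L, G, "b2", p, g, off, 1, dm.d);
    take(L, G, "ln3_g", p, g, off, 1, dm.d);
    take(L, G, "ln3_b", p, g, off, 1, dm.d);
  }
}

// ---------------------------------------------------------------------
// blocks
// ---------------------------------------------------------------------

struct LnCache { mat Xhat; vec inv; };

static mat ln_fwd(const mat& X, const mat& g1, const mat& b1, LnCache& c) {
  vec mu = mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = mean(square(Xc), 1);
  c.inv = 1.0 / sqrt(v + LN_EPS);
  c.Xhat = Xc.each_col() % c.inv;
  rowvec g = g1.row(0), b = b1.row(0);
  mat Y = c.Xhat.each_row() % g;
  Y.each_row() += b;
  return Y;
}

static mat ln_bwd(const mat& dY, const LnCache& c, const mat& g1,
                  mat& dg, mat& db) {
  rowvec g = g1.row(0);
  mat dXhat = dY.each_row() % g;
  vec m1 = mean(dXhat, 1);
  vec m2 = mean(dXhat % c.Xhat, 1);
  dg += sum(dY % c.Xhat, 0);
  db += sum(dY, 0);
  mat dX = dXhat.each_col() - m1;
  dX -= c.Xhat.each_col() % m2;
  return dX.each_col() % c.inv;
}

struct AttnCache {
  mat Xq, Xkv, Q, K, V, O;
  std::vector<mat> P;
};

static mat attn_fwd(const mat& Xq, const mat& Xkv,
                    const mat& Wq, const mat& Wk, const mat& Wv,
                    const mat& Wo, int nh, bool causal, AttnCache& c) {
  int d = Xq.n_cols, dk = d / nh;
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = Xq * Wq; c.K = Xkv * Wk; c.V = Xkv * Wv;
  c.O.set_size(Xq.n_rows, d);
  c.P.resize(nh);
  double scale = 1.0 / std::sqrt((double)dk);
  for (int h = 0; h < nh; h++) {
    span cs(h * dk, (h + 1) * dk - 1);
    mat S = c.Q.cols(cs) * c.K.cols(cs).t() * scale;
    if (causal) {
      for (uword i = 0; i < S.n_rows; i++)
        for (uword j = i + 1; j < S.n_cols; j++) S(i, j) = -1e30;
    }
    S.each_col() -= max(S, 1);
    S = exp(S);
    S.each_col() /= sum(S, 1);
    c.P[h] = S;
    c.O.cols(cs) = S * c.V.cols(cs);
  }
  return c.O * Wo;
}

static void attn_bwd(const mat& dY, const AttnCache& c,
                     const mat& Wq, const mat& Wk, const mat& Wv,
                     const mat& Wo, int nh,
                     mat& gWq, mat& gWk, mat& gWv, mat& gWo,
                     mat& dXq, mat& dXkv) {
  int d = c.Q.n_cols, dk = d / nh;
  gWo += c.O.t() * dY;
  mat dO = dY * Wo.t();
  mat dQ(c.Q.n_rows, d, fill::zeros);
  mat dK(c.K.n_rows, d, fill::zeros);
  mat dV(c.V.n_rows, d, fill::zeros);
  double scale = 1.0 / std::sqrt((double)dk);
  for (int h = 0; h < nh; h++) {
    span cs(h * dk, (h + 1) * dk - 1);
    const mat& P = c.P[h];
    mat dOh = dO.cols(cs);
    dV.cols(cs) = P.t() * dOh;
    mat dP = dOh * c.V.cols(cs).t();
    mat dS = (P % (dP.each_col() - sum(dP % P, 1))) * scale;
    dQ.cols(cs) = dS * c.K.cols(cs);
    dK.cols(cs) = dS.t() * c.Q.cols(cs);
  }
  gWq += c.Xq.t() * dQ;
  gWk += c.Xkv.t() * dK;
  gWv += c.Xkv.t() * dV;
  dXq += dQ * Wq.t();
  dXkv += dK * Wk.t() + dV * Wv.t();
}

struct FfnCache { mat X, H; umat mask; };

static mat ffn_fwd(const mat& X, const mat& W1, const mat& b1,
                   const mat& W2, const mat& b2, FfnCache& c) {
  c.X = X;
  mat H0 = X * W1;
  H0.each_row() += b1.row(0);
  c.mask = H0 > 0;
  c.H = H0 % conv_to<mat>::from(c.mask);
  mat Y = c.H * W2;
  Y.each_row() += b2.row(0);
  return Y;
}

static mat ffn_bwd(const mat& dY, const FfnCache& c,
                   const mat& W1, const mat& W2,
                   mat& gW1, mat& gb1, mat& gW2, mat& gb2) {
  mat dH = (dY * W2.t()) % conv_to<mat>::from(c.mask);
  gW1 += c.X.t() * dH;
  gb1 += sum(dH, 0);
  gW2 += c.H.t() * dY;
  gb2 += sum(dY, 0);
  return dH * W1.t();
}

// ---------------------------------------------------------------------
// encoder / decoder stacks
// ---------------------------------------------------------------------

struct EncCache {
  std::vector<AttnCache> attn;
  std::vector<LnCache> ln1, ln3;
  std::vector<FfnCache> ffn;
  std::vector<mat> Xin;  // input to each layer
  mat X0;                // embedded input
};

static mat embed(const Params& P, const mat& pos, const IntegerVector& ids,
                 int d) {
  mat X(ids.size(), d);
  double s = std::sqrt((double)d);
  for (int t = 0; t < ids.size(); t++) {
    X.row(t) = P.emb.row(ids[t] - 1) * s + pos.row(t);
  }
  return X;
}

static mat encoder_fwd_cpp(const Params& P, const Dims& dm, const mat& pos,
                           const IntegerVector& src, EncCache& c) {
  mat X = embed(P, pos, src, dm.d);
  c.X0 = X;
  int n = dm.n_enc;
  c.attn.resize(n); c.ln1.resize(n); c.ln3.resize(n);
  c.ffn.resize(n); c.Xin.resize(n);
  for (int i = 0; i < n; i++) {
    const auto& L = P.enc[i];
    c.Xin[i] = X;
    mat A = attn_fwd(X, X, L.at("Wq"), L.at("Wk"), L.at("Wv"), L.at("Wo"),
                     dm.nh, false, c.attn[i]);
    mat X1 = ln_fwd(X + A, L.at("ln1_g"), L.at("ln1_b"), c.ln1[i]);
    mat F = ffn_fwd(X1, L.at("W1"), L.at("b1"), L.at("W2"), L.at("b2"),
                    c.ffn[i]);
    c.ffn[i].X = X1;  // ensure cache holds the ffn input
    X = ln_fwd(X1 + F, L.at("ln3_g"), L.at("ln3_b"), c.ln3[i]);
  }
  return X;
}

static void encoder_bwd_cpp(Params& P, const Dims& dm, const EncCache& c,
                            const IntegerVector& src, mat dX) {
  for (int i = dm.n_enc - 1; i >= 0; i--) {
    const auto& L = P.enc[i];
    auto& G = P.genc[i];
    mat dl3 = ln_bwd(dX, c.ln3[i], L.at("ln3_g"), G.at("ln3_g"), G.at("ln3_b"));
    mat dX1 = ffn_bwd(dl3, c.ffn[i], L.at("W1"), L.at("W2"),
                      G.at("W1"), G.at("b1"), G.at("W2"), G.at("b2"));
    dX1 += dl3;
    mat dA = ln_bwd(dX1, c.ln1[i], L.at("ln1_g"), G.at("ln1_g"), G.at("ln1_b"));
    mat dXq(dA.n_rows, dm.d, fill::zeros), dXkv(dA.n_rows, dm.d, fill::zeros);
    attn_bwd(dA, c.attn[i], L.at("Wq"), L.at("Wk"), L.at("Wv"), L.at("Wo"),
             dm.nh, G.at("Wq"), G.at("Wk"), G.at("Wv"), G.at("Wo"),
             dXq, dXkv);
    dX = dA + dXq + dXkv;
  }
  double s = std::sqrt((double)dm.d);
  for (int t = 0; t < src.size(); t++) {
    P.g_emb.row(src[t] - 1) += dX.row(t) * s;
  }
}

struct DecCache {
  std::vector<AttnCache> attn, cross;
  std::vector<LnCache> ln1, ln2, ln3;
  std::vector<FfnCache> ffn;
  mat Xout;  // decoder final hidden states
};

static mat decoder_fwd_cpp(const Params& P, const Dims& dm, const mat& pos,
                           const mat& enc_out, const IntegerVector& tin,
                           DecCache& c) {
  mat X = embed(P, pos, tin, dm.d);
  int n = dm.n_dec;
  c.attn.resize(n); c.cross.resize(n);
  c.ln1.resize(n); c.ln2.resize(n); c.ln3.resize(n); c.ffn.resize(n);
  for (int i = 0; i < n; i++) {
    const auto& L = P.dec[i];
    mat A = attn_fwd(X, X, L.at("Wq"), L.at("Wk"), L.at("Wv"), L.at("Wo"),
                     dm.nh, true, c.attn[i]);
    mat X1 = ln_fwd(X + A, L.at("ln1_g"), L.at("ln1_b"), c.ln1[i]);
    mat Cx = attn_fwd(X1, enc_out, L.at("Cq"), L.at("Ck"), L.at("Cv"),
                      L.at("Co"), dm.nh, false, c.cross[i]);
    mat X2 = ln_fwd(X1 + Cx, L.at("ln2_g"), L.at("ln2_b"), c.ln2[i]);
    mat F = ffn_fwd(X2, L.at("W1"), L.at("b1"), L.at("W2"), L.at("b2"),
                    c.ffn[i]);
    X = ln_fwd(X2 + F, L.at("ln3_g"), L.at("ln3_b"), c.ln3[i]);
  }
  c.Xout = X;
  mat logits = X * P.out_W;
  logits.each_row() += P.out_b;
  return logits;
}

static mat decoder_bwd_cpp(Params& P, const Dims& dm, const DecCache& c,
                           const IntegerVector& tin, const mat& dLogits) {
  P.g_out_W += c.Xout.t() * dLogits;
  P.g_out_b += sum(dLogits, 0);
  mat dX = dLogits * P.out_W.t();
  mat dEnc;
  for (int i = dm.n_dec - 1; i >= 0; i--) {
    const auto& L = P.dec[i];
    auto& G = P.gdec[i];
    mat dl3 = ln_bwd(dX, c.ln3[i], L.at("ln3_g"), G.at("ln3_g"), G.at("ln3_b"));
    mat dX2 = ffn_bwd(dl3, c.ffn[i], L.at("W1"), L.at("W2"),
                      G.at("W1"), G.at("b1"), G.at("W2"), G.at("b2"));
    dX2 += dl3;
    mat dCx = ln_bwd(dX2, c.ln2[i], L.at("ln2_g"), G.at("ln2_g"), G.at("ln2_b"));
    mat dXq(dCx.n_rows, dm.d, fill::zeros);
    mat dXkv(c.cross[i].Xkv.n_rows, dm.d, fill::zeros);
    attn_bwd(dCx, c.cross[i], L.at("Cq"), L.at("Ck"), L.at("Cv"), L.at("Co"),
             dm.nh, G.at("Cq"), G.at("Ck"), G.at("Cv"), G.at("Co"),
             dXq, dXkv);
    if (dEnc.n_rows == 0) dEnc = dXkv; else dEnc += dXkv;
    mat dX1 = dCx + dXq;
    mat dA = ln_bwd(dX1, c.ln1[i], L.at("ln1_g"), G.at("ln1_g"), G.at("ln1_b"));
    mat dq(dA.n_rows, dm.d, fill::zeros), dkv(dA.n_rows, dm.d, fill::zeros);
    attn_bwd(dA, c.attn[i], L.at("Wq"), L.at("Wk"), L.at("Wv"), L.at("Wo"),
             dm.nh, G.at("Wq"), G.at("Wk"), G.at("Wv"), G.at("Wo"), dq, dkv);
    dX = dA + dq + dkv;
  }
  double s = std::sqrt((double)dm.d);
  for (int t = 0; t < tin.size(); t++) {
    P.g_emb.row(tin[t] - 1) += dX.row(t) * s;
  }
  return dEnc;
}

static Dims make_dims(List dims, int V) {
  Dims dm;
  dm.V = V;
  dm.d = Rcpp::as<int>(dims["d"]);
  dm.nh = Rcpp::as<int>(dims["n_heads"]);
  dm.ff = Rcpp::as<int>(dims["ff"]);
  dm.n_enc = Rcpp::as<int>(dims["n_enc"]);
  dm.n_dec = dims.containsElementNamed("n_dec") ?
    Rcpp::as<int>(dims["n_dec"]) : 0;
  return dm;
}

// ---------------------------------------------------------------------
// exported entry points
// ---------------------------------------------------------------------

// Teacher-forced forward+backward: accumulates gradients of
// sum_t w_t * (-log p(tout_t)) into `gvec` (modified in place) and
// returns the per-token log-probabilities.
// [[Rcpp::export]]
NumericVector cpp_policy_grad(NumericVector pvec, NumericVector gvec,
                              List dims, int V, const arma::mat& pos,
                              IntegerVector src, IntegerVector tin,
                              IntegerVector tout, NumericVector w) {
  Dims dm = make_dims(dims, V);
  Params P;
  unpack(pvec.begin(), gvec.begin(), dm, P);
  EncCache ec;
  DecCache dc;
  mat enc_out = encoder_fwd_cpp(P, dm, pos, src, ec);
  mat logits = decoder_fwd_cpp(P, dm, pos, enc_out, tin, dc);
  logits.each_col() -= max(logits, 1);
  mat Pm = exp(logits);
  Pm.each_col() /= sum(Pm, 1);
  int L = tout.size();
  NumericVector logp(L);
  mat dLogits = Pm;
  for (int t = 0; t < L; t++) {
    double wt = (w.size() == 1) ? w[0] : w[t];
    logp[t] = std::log(Pm(t, tout[t] - 1) + 1e-12);
    dLogits.row(t) *= wt;
    dLogits(t, tout[t] - 1) -= wt;
  }
  mat dEnc = decoder_bwd_cpp(P, dm, dc, tin, dLogits);
  encoder_bwd_cpp(P, dm, ec, src, dEnc);
  return logp;
}

// Teacher-forced per-token log-probabilities (no gradients).
// [[Rcpp::export]]
NumericVector cpp_policy_logp(NumericVector pvec, List dims, int V,
                              const arma::mat& pos, IntegerVector src,
                              IntegerVector tin, IntegerVector tout) {
  Dims dm = make_dims(dims, V);
  std::vector<double> dummy(pvec.size(), 0.0);
  Params P;
  unpack(pvec.begin(), dummy.data(), dm, P);
  EncCache ec;
  DecCache dc;
  mat enc_out = encoder_fwd_cpp(P, dm, pos, src, ec);
  mat logits = decoder_fwd_cpp(P, dm, pos, enc_out, tin, dc);
  logits.each_col() -= max(logits, 1);
  mat Pm = exp(logits);
  Pm.each_col() /= sum(Pm, 1);
  NumericVector logp(tout.size());
  for (int t = 0; t < tout.size(); t++) {
    logp[t] = std::log(Pm(t, tout[t] - 1) + 1e-12);
  }
  return logp;
}

// Encoder output for a source sequence (decoding entry point).
// [[Rcpp::export]]
arma::mat cpp_encode(NumericVector pvec, List dims, int V,
                     const arma::mat& pos, IntegerVector src) {
  Dims dm = make_dims(dims, V);
  std::vector<double> dummy(pvec.size(), 0.0);
  Params P;
  unpack(pvec.begin(), dummy.data(), dm, P);
  EncCache ec;
  return encoder_fwd_cpp(P, dm, pos, src, ec);
}

// Log-probabilities of the next token given the decoder prefix.
// [[Rcpp::export]]
NumericVector cpp_next_logp(NumericVector pvec, List dims, int V,
                            const arma::mat& pos, const arma::mat& enc_out,
                            IntegerVector tin) {
  Dims dm = make_dims(dims, V);
  std::vector<double> dummy(pvec.size(), 0.0);
  Params P;
  unpack(pvec.begin(), dummy.data(), dm, P);
  DecCache dc;
  mat logits = decoder_fwd_cpp(P, dm, pos, enc_out, tin, dc);
  rowvec last = logits.row(logits.n_rows - 1);
  last -= last.max();
  last -= std::log(accu(exp(last)));
  return NumericVector(last.begin(), last.end());
}

// Pooled encoder state for fingerprints/state: the fingerprint is the
// mean of the hidden states at the 1-based positions in `pool_idx`.
// [[Rcpp::export]]
NumericVector cpp_encode_pool(NumericVector pvec, List dims, int V,
                              const arma::mat& pos, IntegerVector src,
                              IntegerVector pool_idx) {
  Dims dm = make_dims(dims, V);
  std::vector<double> dummy(pvec.size(), 0.0);
  Params P;
  unpack(pvec.begin(), dummy.data(), dm, P);
  EncCache ec;
  mat out = encoder_fwd_cpp(P, dm, pos, src, ec);
  rowvec pooled(dm.d, fill::zeros);
  for (int k = 0; k < pool_idx.size(); k++) pooled += out.row(pool_idx[k] - 1);
  pooled /= pool_idx.size();
  return NumericVector(pooled.begin(), pooled.end());
}

// Encoder-only backward from a pooled-state gradient (classification
// tuning): accumulates into gvec, returns the pooled forward state.
// [[Rcpp::export]]
NumericVector cpp_encoder_pool_grad(NumericVector pvec, NumericVector gvec,
                                    List dims, int V, const arma::mat& pos,
                                    IntegerVector src, NumericVector dpool,
                                    IntegerVector pool_idx) {
  Dims dm = make_dims(dims, V);
  Params P;
  unpack(pvec.begin(), gvec.begin(), dm, P);
  EncCache ec;
  mat out = encoder_fwd_cpp(P, dm, pos, src, ec);
  mat dOut(out.n_rows, dm.d, fill::zeros);
  rowvec dp(dpool.begin(), dm.d);
  for (int k = 0; k < pool_idx.size(); k++) {
    dOut.row(pool_idx[k] - 1) += dp / pool_idx.size();
  }
  encoder_bwd_cpp(P, dm, ec, src, dOut);
  rowvec pooled(dm.d, fill::zeros);
  for (int k = 0; k < pool_idx.size(); k++) pooled += out.row(pool_idx[k] - 1);
  pooled /= pool_idx.size();
  return NumericVector(pooled.begin(), pooled.end());
}
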