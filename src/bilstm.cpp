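// Minimal BiLSTM binary classifier: trainable embedding -> BiLSTM ->
// dense ReLU -> dense sigmoid, trained with Adam on binary cross-entropy.
// Implemented directly (no framework is available at build time) with
// batched, mask-aware forward/backward passes. Single-threaded and
// deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

struct AdamState {
  mat m, v;
  void init(const mat &p) {
    m.zeros(p.n_rows, p.n_cols);
    v.zeros(p.n_rows, p.n_cols);
  }
};

struct Params {
  mat E;                    // D x V (transposed from the R-side V x D)
  mat Wf, Uf, Wb, Ub;       // 4H x D, 4H x H per direction
  vec bf, bb;               // 4H
  mat W1;                   // U x 2H
  vec b1;                   // U
  mat W2;                   // 1 x U
  double b2;
  int D, H, U, V;
};

static Params unpack(const List &params) {
  Params p;
  mat E = as<mat>(params["E"]);
  p.E = E.t();
  p.Wf = as<mat>(params["Wf"]); p.Uf = as<mat>(params["Uf"]);
  p.bf = as<vec>(params["bf"]);
  p.Wb = as<mat>(params["Wb"]); p.Ub = as<mat>(params["Ub"]);
  p.bb = as<vec>(params["bb"]);
  p.W1 = as<mat>(params["W1"]); p.b1 = as<vec>(params["b1"]);
  p.W2 = as<mat>(params["W2"]); p.b2 = as<vec>(params["b2"])(0);
  p.D = p.E.n_rows; p.V = p.E.n_cols;
  p.H = p.Uf.n_cols; p.U = p.W1.n_rows;
  return p;
}

static List pack(const Params &p) {
  return List::create(
      _["E"] = wrap(mat(p.E.t())), _["Wf"] = wrap(p.Wf), _["Uf"] = wrap(p.Uf),
      _["bf"] = wrap(p.bf), _["Wb"] = wrap(p.Wb), _["Ub"] = wrap(p.Ub),
      _["bb"] = wrap(p.bb), _["W1"] = wrap(p.W1), _["b1"] = wrap(p.b1),
      _["W2"] = wrap(p.W2), _["b2"] = wrap(vec{p.b2}));
}

struct DirCache {
  cube G;   // gates (i,f,g,o) 4H x B x T, post-activation
  cube C;   // cell states H x B x T
  cube Hs;  // hidden states H x B x T
};

// Run one LSTM direction over the (already direction-ordered) token ids.
// ids: T x B, 0 = padding. Returns final hidden state (H x B).
static mat lstm_forward(const Params &p, const mat &W, const mat &U,
                        const vec &b, const arma::imat &ids,
                        DirCache *cache) {
  const int T = ids.n_rows, B = ids.n_cols, H = p.H;
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  if (cache) {
    cache->G.set_size(4 * H, B, T);
    cache->C.set_size(H, B, T);
    cache->Hs.set_size(H, B, T);
  }
  mat X(p.D, B);
  for (int t = 0; t < T; ++t) {
    X.zeros();
    for (int bcol = 0; bcol < B; ++bcol)
      if (ids(t, bcol) > 0) X.col(bcol) = p.E.col(ids(t, bcol) - 1);
    mat Z = W * X + U * h;
    Z.each_col() += b;
    mat gi = 1.0 / (1.0 + arma::exp(-Z.rows(0, H - 1)));
    mat gf = 1.0 / (1.0 + arma::exp(-Z.rows(H, 2 * H - 1)));
    mat gg = arma::tanh(Z.rows(2 * H, 3 * H - 1));
    mat go = 1.0 / (1.0 + arma::exp(-Z.rows(3 * H, 4 * H - 1)));
    mat c_new = gf % c + gi % gg;
    mat h_new = go % arma::tanh(c_new);
    for (int bcol = 0; bcol < B; ++bcol) {
      if (ids(t, bcol) == 0) {           // masked: carry state
        c_new.col(bcol) = c.col(bcol);
        h_new.col(bcol) = h.col(bcol);
      }
    }
    if (cache) {
      cache->G.slice(t).rows(0, H - 1) = gi;
      cache->G.slice(t).rows(H, 2 * H - 1) = gf;
      cache->G.slice(t).rows(2 * H, 3 * H - 1) = gg;
      cache->G.slice(t).rows(3 * H, 4 * H - 1) = go;
      cache->C.slice(t) = c_new;
      cache->Hs.slice(t) = h_new;
    }
    c = c_new;
    h = h_new;
  }
  return h;
}

// Backward pass for one direction; accumulates parameter gradients and
// the embedding gradient (dE, D x V).
static void lstm_backward(const Params &p, const mat &W, const mat &U,
                          const arma::imat &ids, const DirCache &cache,
                          const mat &dh_final, mat &gW, mat &gU, vec &gb,
                          mat &gE) {
  const int T = ids.n_rows, B = ids.n_cols, H = p.H;
  mat dh = dh_final;                 // gradient w.r.t. h_t
  mat dc(H, B, arma::fill::zeros);
  mat X(p.D, B);
  for (int t = T - 1; t >= 0; --t) {
    const mat &gi = cache.G.slice(t).rows(0, H - 1);
    const mat &gf = cache.G.slice(t).rows(H, 2 * H - 1);
    const mat &gg = cache.G.slice(t).rows(2 * H, 3 * H - 1);
    const mat &go = cache.G.slice(t).rows(3 * H, 4 * H - 1);
    mat c_prev = t > 0 ? mat(cache.C.slice(t - 1)) : mat(H, B, arma::fill::zeros);
    mat h_prev = t > 0 ? mat(cache.Hs.slice(t - 1)) : mat(H, B, arma::fill::zeros);
    arma::rowvec msk(B);
    for (int bcol = 0; bcol < B; ++bcol) msk(bcol) = ids(t, bcol) > 0 ? 1.0 : 0.0;
    mat m = arma::repmat(msk, H, 1);

    mat tanhc = arma::tanh(cache.C.slice(t));
    mat dh_eff = dh % m;
    mat dc_eff = dc % m + dh_eff % go % (1.0 - tanhc % tanhc);
    mat d_o = dh_eff % tanhc;
    mat d_i = dc_eff % gg;
    mat d_f = dc_eff % c_prev;
    mat d_g = dc_eff % gi;
    mat dZ(4 * H, B);
    dZ.rows(0, H - 1) = d_i % gi % (1.0 - gi);
    dZ.rows(H, 2 * H - 1) = d_f % gf % (1.0 - gf);
    dZ.rows(2 * H, 3 * H - 1) = d_g % (1.0 - gg % gg);
    dZ.rows(3 * H, 4 * H - 1) = d_o % go % (1.0 - go);

    X.zeros();
    for (int bcol = 0; bcol < B; ++bcol)
      if (ids(t, bcol) > 0) X.col(bcol) = p.E.col(ids(t, bcol) - 1);
    gW += dZ * X.t();
    gU += dZ * h_prev.t();
    gb += arma::sum(dZ, 1);
    mat dX = W.t() * dZ;
    for (int bcol = 0; bcol < B; ++bcol)
      if (ids(t, bcol) > 0) gE.col(ids(t, bcol) - 1) += dX.col(bcol);

    dh = U.t() * dZ + dh % (1.0 - m);
    dc = dc_eff % gf + dc % (1.0 - m);
  }
}

// Assemble direction-ordered id matrices for a batch of sequences.
static void batch_ids(const std::vector<std::vector<int>> &seqs,
                      const std::vector<int> &batch, arma::imat &fwd,
                      arma::imat &bwd) {
  int B = batch.size(), T = 1;
  for (int b : batch) T = std::max<int>(T, seqs[b].size());
  fwd.zeros(T, B);
  bwd.zeros(T, B);
  for (int k = 0; k < B; ++k) {
    const std::vector<int> &s = seqs[batch[k]];
    for (size_t t = 0; t < s.size(); ++t) {
      fwd(t, k) = s[t];
      bwd(t, k) = s[s.size() - 1 - t];
    }
  }
}

static std::vector<std::vector<int>> convert_seqs(const List &seqs) {
  std::vector<std::vector<int>> out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector s = seqs[i];
    out[i] = std::vector<int>(s.begin(), s.end());
  }
  return out;
}

// Forward pass for a batch; fills prob (B) and dense activations a1 (U x B).
static void model_forward(const Params &p, const arma::imat &fwd,
                          const arma::imat &bwd, DirCache *cf, DirCache *cb,
                          mat &rep, mat &a1, arma::rowvec &prob) {
  mat hf = lstm_forward(p, p.Wf, p.Uf, p.bf, fwd, cf);
  mat hb = lstm_forward(p, p.Wb, p.Ub, p.bb, bwd, cb);
  rep = arma::join_cols(hf, hb);
  mat z1 = p.W1 * rep;
  z1.each_col() += p.b1;
  a1 = arma::clamp(z1, 0.0, arma::datum::inf);
  arma::rowvec z2 = p.W2 * a1 + p.b2;
  prob = 1.0 / (1.0 + arma::exp(-z2));
}

// [[Rcpp::export(name = ".bilstm_train")]]
List bilstm_train_cpp(List params, List seqs_r, NumericVector labels,
                      double lr, int batch_size, int epochs, int seed) {
  Params p = unpack(params);
  std::vector<std::vector<int>> seqs = convert_seqs(seqs_r);
  const int n = seqs.size();
  std::mt19937_64 rng(static_cast<uint64_t>(seed));

  // Adam state: E handled lazily (per-column), the rest densely.
  AdamState sE, sWf, sUf, sbf, sWb, sUb, sbb, sW1, sb1, sW2, sb2;
  sE.init(p.E); sWf.init(p.Wf); sUf.init(p.Uf);
  mat bf_m(p.bf.n_elem, 1, arma::fill::zeros), bf_v = bf_m;
  sWb.init(p.Wb); sUb.init(p.Ub);
  mat bb_m = bf_m, bb_v = bf_m;
  sW1.init(p.W1);
  mat b1_m(p.b1.n_elem, 1, arma::fill::zeros), b1_v = b1_m;
  sW2.init(p.W2);
  double b2_m = 0, b2_v = 0;

  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-7;
  long step = 0;

  mat gE(p.D, p.V);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with the private rng
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif01(rng) * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int off = 0; off < n; off += batch_size) {
      int B = std::min(batch_size, n - off);
      std::vector<int> batch(order.begin() + off, order.begin() + off + B);
      arma::imat fwd, bwd;
      batch_ids(seqs, batch, fwd, bwd);
      DirCache cf, cb;
      mat rep, a1;
      arma::rowvec prob;
      model_forward(p, fwd, bwd, &cf, &cb, rep, a1, prob);

      arma::rowvec y(B);
      for (int k = 0; k < B; ++k) y(k) = labels[batch[k]];
      arma::rowvec dz2 = (prob - y) / B;

      mat gW2 = dz2 * a1.t();                    // 1 x U
      double gb2 = arma::accu(dz2);
      mat da1 = p.W2.t() * dz2;                  // U x B
      mat dz1 = da1 % arma::conv_to<mat>::from(a1 > 0.0);
      mat gW1 = dz1 * rep.t();
      vec gb1 = arma::sum(dz1, 1);
      mat drep = p.W1.t() * dz1;                 // 2H x B

      mat gWf(p.Wf.n_rows, p.Wf.n_cols, arma::fill::zeros);
      mat gUf(p.Uf.n_rows, p.Uf.n_cols, arma::fill::zeros);
      vec gbf(p.bf.n_elem, arma::fill::zeros);
      mat gWb = gWf, gUb = gUf;
      vec gbb = gbf;
      gE.zeros();
      lstm_backward(p, p.Wf, p.Uf, fwd, cf, drep.rows(0, p.H - 1),
                    gWf, gUf, gbf, gE);
      lstm_backward(p, p.Wb, p.Ub, bwd, cb, drep.rows(p.H, 2 * p.H - 1),
                    gWb, gUb, gbb, gE);

      ++step;
      double bc1 = 1.0 - std::pow(beta1, step);
      double bc2 = 1.0 - std::pow(beta2, step);
      auto adam = [&](mat &w, mat &m, mat &v, const mat &g) {
        m = beta1 * m + (1 - beta1) * g;
        v = beta2 * v + (1 - beta2) * (g % g);
        w -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
      };
      adam(p.Wf, sWf.m, sWf.v, gWf);
      adam(p.Uf, sUf.m, sUf.v, gUf);
      adam(p.Wb, sWb.m, sWb.v, gWb);
      adam(p.Ub, sUb.m, sUb.v, gUb);
      adam(p.W1, sW1.m, sW1.v, gW1);
      adam(p.W2, sW2.m, sW2.v, gW2);
      {
        mat g(gbf);
        bf_m = beta1 * bf_m + (1 - beta1) * g;
        bf_v = beta2 * bf_v + (1 - beta2) * (g % g);
        p.bf -= lr * (bf_m / bc1) / (arma::sqrt(bf_v / bc2) + eps);
      }
      {
        mat g(gbb);
        bb_m = beta1 * bb_m + (1 - beta1) * g;
        bb_v = beta2 * bb_v + (1 - beta2) * (g % g);
        p.bb -= lr * (bb_m / bc1) / (arma::sqrt(bb_v / bc2) + eps);
      }
      {
        mat g(gb1);
        b1_m = beta1 * b1_m + (1 - beta1) * g;
        b1_v = beta2 * b1_v + (1 - beta2) * (g % g);
        p.b1 -= lr * (b1_m / bc1) / (arma::sqrt(b1_v / bc2) + eps);
      }
      {
        b2_m = beta1 * b2_m + (1 - beta1) * gb2;
        b2_v = beta2 * b2_v + (1 - beta2) * gb2 * gb2;
        p.b2 -= lr * (b2_m / bc1) / (std::sqrt(b2_v / bc2) + eps);
      }
      // lazy Adam on touched embedding columns
      std::vector<int> touched;
      for (int t = 0; t < (int)fwd.n_rows; ++t)
        for (int k = 0; k < B; ++k)
          if (fwd(t, k) > 0) touched.push_back(fwd(t, k) - 1);
      std::sort(touched.begin(), touched.end());
      touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
      for (int cidx : touched) {
        vec g = gE.col(cidx);
        sE.m.col(cidx) = beta1 * sE.m.col(cidx) + (1 - beta1) * g;
        sE.v.col(cidx) = beta2 * sE.v.col(cidx) + (1 - beta2) * (g % g);
        p.E.col(cidx) -= lr * (sE.m.col(cidx) / bc1) /
                         (arma::sqrt(sE.v.col(cidx) / bc2) + eps);
      }
    }
  }
  return pack(p);
}

// [[Rcpp::export(name = ".bilstm_forward")]]
List bilstm_forward_cpp(List params, List seqs_r, int batch_size) {
  Params p = unpack(params);
  std::vector<std::vector<int>> seqs = convert_seqs(seqs_r);
  const int n = seqs.size();
  NumericVector prob_out(n);
  NumericMatrix a1_out(n, p.U);
  for (int off = 0; off < n; off += batch_size) {
    int B = std::min(batch_size, n - off);
    std::vector<int> batch(B);
    for (int k = 0; k < B; ++k) batch[k] = off + k;
    arma::imat fwd, bwd;
    batch_ids(seqs, batch, fwd, bwd);
    mat rep, a1;
    arma::rowvec prob;
    model_forward(p, fwd, bwd, nullptr, nullptr, rep, a1, prob);
    for (int k = 0; k < B; ++k) {
      prob_out[off + k] = prob(k);
      for (int u = 0; u < p.U; ++u) a1_out(off + k, u) = a1(u, k);
    }
  }
  return List::create(_["prob"] = prob_out, _["dense"] = a1_out);
}
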