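// Two-layer stacked LSTM classifier for fixed-length univariate series:
// LSTM -> dropout -> LSTM -> dropout -> dense softmax, trained with Adam on
// categorical cross-entropy. Written against Armadillo; no external deep
// learning framework is assumed.
//
// Parameter layout (list order matters, see PARAM_NAMES):
//   Wx1 (1 x 4H), Wh1 (H x 4H), b1 (1 x 4H),
//   Wx2 (H x 4H), Wh2 (H x 4H), b2 (1 x 4H),
//   Wy  (H x K),  by  (1 x K)
// Gate blocks in the 4H axis: [input | forget | cell | output].

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int N_PARAMS = 8;

struct LstmParams {
  mat Wx1, Wh1, b1, Wx2, Wh2, b2, Wy, by;
  int H() const { return Wh1.n_rows; }
  int K() const { return Wy.n_cols; }
};

static LstmParams unpack(const Rcpp::List& p) {
  LstmParams P;
  P.Wx1 = Rcpp::as<mat>(p["Wx1"]); P.Wh1 = Rcpp::as<mat>(p["Wh1"]);
  P.b1 = Rcpp::as<mat>(p["b1"]);
  P.Wx2 = Rcpp::as<mat>(p["Wx2"]); P.Wh2 = Rcpp::as<mat>(p["Wh2"]);
  P.b2 = Rcpp::as<mat>(p["b2"]);
  P.Wy = Rcpp::as<mat>(p["Wy"]); P.by = Rcpp::as<mat>(p["by"]);
  return P;
}

static Rcpp::List pack(const LstmParams& P) {
  return Rcpp::List::create(
      Rcpp::Named("Wx1") = P.Wx1, Rcpp::Named("Wh1") = P.Wh1,
      Rcpp::Named("b1") = P.b1,
      Rcpp::Named("Wx2") = P.Wx2, Rcpp::Named("Wh2") = P.Wh2,
      Rcpp::Named("b2") = P.b2,
      Rcpp::Named("Wy") = P.Wy, Rcpp::Named("by") = P.by);
}

static mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// per-layer forward cache for BPTT
struct LayerCache {
  cube i, f, g, o, c, tc, h;  // B x H x L each
};

// forward one LSTM layer over all timesteps; X_t supplied via callback
template <typename GetX>
static void layer_forward(const mat& Wx, const mat& Wh, const mat& b,
                          int B, int L, GetX getx, LayerCache& cc) {
  int H = Wh.n_rows;
  cc.i.set_size(B, H, L); cc.f.set_size(B, H, L); cc.g.set_size(B, H, L);
  cc.o.set_size(B, H, L); cc.c.set_size(B, H, L); cc.tc.set_size(B, H, L);
  cc.h.set_size(B, H, L);
  mat h_prev(B, H, fill::zeros), c_prev(B, H, fill::zeros);
  for (int t = 0; t < L; ++t) {
    mat Z = getx(t) * Wx + h_prev * Wh;
    Z.each_row() += b.row(0);
    mat gi = sigm(Z.cols(0, H - 1));
    mat gf = sigm(Z.cols(H, 2 * H - 1));
    mat gg = tanh(Z.cols(2 * H, 3 * H - 1));
    mat go = sigm(Z.cols(3 * H, 4 * H - 1));
    mat c_t = gf % c_prev + gi % gg;
    mat tc = tanh(c_t);
    mat h_t = go % tc;
    cc.i.slice(t) = gi; cc.f.slice(t) = gf; cc.g.slice(t) = gg;
    cc.o.slice(t) = go; cc.c.slice(t) = c_t; cc.tc.slice(t) = tc;
    cc.h.slice(t) = h_t;
    h_prev = h_t; c_prev = c_t;
  }
}

// backward one layer; dh_top(t) = gradient flowing into h_t from above.
// Returns per-timestep input gradients through dx callback.
template <typename GetX, typename DhTop, typename PutDx>
static void layer_backward(const mat& Wx, const mat& Wh,
                           const LayerCache& cc, int B, int L,
                           GetX getx, DhTop dh_top, PutDx put_dx,
                           mat& dWx, mat& dWh, mat& db) {
  int H = Wh.n_rows;
  dWx.zeros(Wx.n_rows, Wx.n_cols);
  dWh.zeros(Wh.n_rows, Wh.n_cols);
  db.zeros(1, 4 * H);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    mat dh = dh_top(t) + dh_next;
    const mat& gi = cc.i.slice(t); const mat& gf = cc.f.slice(t);
    const mat& gg = cc.g.slice(t); const mat& go = cc.o.slice(t);
    const mat& tc = cc.tc.slice(t);
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    mat c_prev = (t > 0) ? cc.c.slice(t - 1) : mat(B, H, fill::zeros);
    mat dZ(B, 4 * H);
    dZ.cols(0, H - 1)         = (dc % gg) % gi % (1.0 - gi);
    dZ.cols(H, 2 * H - 1)     = (dc % c_prev) % gf % (1.0 - gf);
    dZ.cols(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dZ.cols(3 * H, 4 * H - 1) = (dh % tc) % go % (1.0 - go);
    mat h_prev = (t > 0) ? cc.h.slice(t - 1) : mat(B, H, fill::zeros);
    dWx += getx(t).t() * dZ;
    dWh += h_prev.t() * dZ;
    db += sum(dZ, 0);
    dh_next = dZ * Wh.t();
    dc_next = dc % gf;
    put_dx(t, dZ * Wx.t());
  }
}

static mat softmax_rows(mat logits) {
  logits.each_col() -= max(logits, 1);
  mat e = exp(logits);
  e.each_col() /= sum(e, 1);
  return e;
}

// forward + loss + gradients for one batch. Dropout masks (inverted
// dropout, already scaled) are applied to layer-1 outputs per timestep and
// to the final layer-2 state; empty masks mean no dropout.
static double batch_grad(const LstmParams& P, const mat& X,
                         const uvec& y, const cube& mask1, const mat& mask2,
                         LstmParams& G) {
  int B = X.n_rows, L = X.n_cols, H = P.H(), K = P.K();
  bool drop = mask2.n_elem > 0;

  LayerCache c1, c2;
  layer_forward(P.Wx1, P.Wh1, P.b1, B, L,
                [&](int t) { return mat(X.col(t)); }, c1);
  // layer-2 inputs: dropped layer-1 outputs
  cube x2(B, H, L);
  for (int t = 0; t < L; ++t)
    x2.slice(t) = drop ? mat(c1.h.slice(t) % mask1.slice(t))
                       : c1.h.slice(t);
  layer_forward(P.Wx2, P.Wh2, P.b2, B, L,
                [&](int t) { return x2.slice(t); }, c2);
  mat h_top = c2.h.slice(L - 1);
  if (drop) h_top = h_top % mask2;
  mat logits = h_top * P.Wy;
  logits.each_row() += P.by.row(0);
  mat probs = softmax_rows(logits);

  double loss = 0.0;
  mat dlogits = probs;
  for (int b = 0; b < B; ++b) {
    double p = std::max(probs(b, y(b)), 1e-12);
    loss -= std::log(p);
    dlogits(b, y(b)) -= 1.0;
  }
  loss /= B;
  dlogits /= B;

  G.Wy = h_top.t() * dlogits;
  G.by = sum(dlogits, 0);
  mat dh_last = dlogits * P.Wy.t();
  if (drop) dh_last = dh_last % mask2;

  // layer 2 backward; collect gradients w.r.t. its inputs
  cube dx2(B, H, L, fill::zeros);
  layer_backward(P.Wx2, P.Wh2, c2, B, L,
                 [&](int t) { return x2.slice(t); },
                 [&](int t) {
                   return (t == L - 1) ? dh_last : mat(B, H, fill::zeros);
                 },
                 [&](int t, const mat& dx) { dx2.slice(t) = dx; },
                 G.Wx2, G.Wh2, G.b2);
  // through layer-1 dropout
  if (drop) for (int t = 0; t < L; ++t) dx2.slice(t) %= mask1.slice(t);

  layer_backward(P.Wx1, P.Wh1, c1, B, L,
                 [&](int t) { return mat(X.col(t)); },
                 [&](int t) { return dx2.slice(t); },
                 [&](int, const mat&) {},
                 G.Wx1, G.Wh1, G.b1);
  return loss;
}

static mat glorot(int r, int c, std::mt19937& eng) {
  double s = std::sqrt(6.0 / (r + c));
  std::uniform_real_distribution<double> U(-s, s);
  mat m(r, c);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = U(eng);
  return m;
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_init(int hidden, int n_class, int seed) {
  std::mt19937 eng(static_cast<unsigned>(seed));
  LstmParams P;
  int H = hidden;
  P.Wx1 = glorot(1, 4 * H, eng); P.Wh1 = glorot(H, 4 * H, eng);
  P.b1 = mat(1, 4 * H, fill::zeros);
  P.b1.cols(H, 2 * H - 1).fill(1.0);  // forget-gate bias at 1
  P.Wx2 = glorot(H, 4 * H, eng); P.Wh2 = glorot(H, 4 * H, eng);
  P.b2 = mat(1, 4 * H, fill::zeros);
  P.b2.cols(H, 2 * H - 1).fill(1.0);
  P.Wy = glorot(H, n_class, eng); P.by = mat(1, n_class, fill::zeros);
  return pack(P);
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_loss_grad(Rcpp::List params, arma::mat X,
                              arma::uvec y) {
  LstmParams P = unpack(params), G;
  cube m1; mat m2;  // empty: dropout off (used by gradient-check tests)
  double loss = batch_grad(P, X, y, m1, m2, G);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = pack(G));
}

// [[Rcpp::export]]
arma::mat cpp_lstm_predict(Rcpp::List params, arma::mat X) {
  LstmParams P = unpack(params);
  int B = X.n_rows, L = X.n_cols;
  LayerCache c1, c2;
  layer_forward(P.Wx1, P.Wh1, P.b1, B, L,
                [&](int t) { return mat(X.col(t)); }, c1);
  layer_forward(P.Wx2, P.Wh2, P.b2, B, L,
                [&](int t) { return c1.h.slice(t); }, c2);
  mat logits = c2.h.slice(L - 1) * P.Wy;
  logits.each_row() += P.by.row(0);
  return softmax_rows(logits);
}

struct AdamState {
  std::vector<mat> m, v;
  long step = 0;
};

static void adam_update(std::vector<mat*>& par, std::vector<mat*>& grad,
                        AdamState& st, double lr, double decay) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  if (st.m.empty()) {
    for (auto* p : par) {
      st.m.push_back(mat(p->n_rows, p->n_cols, fill::zeros));
      st.v.push_back(mat(p->n_rows, p->n_cols, fill::zeros));
    }
  }
  st.step++;
  double lr_t = lr / (1.0 + decay * st.step);
  double bc1 = 1.0 - std::pow(b1, (double)st.step);
  double bc2 = 1.0 - std::pow(b2, (double)st.step);
  for (size_t k = 0; k < par.size(); ++k) {
    st.m[k] = b1 * st.m[k] + (1.0 - b1) * (*grad[k]);
    st.v[k] = b2 * st.v[k] + (1.0 - b2) * square(*grad[k]);
    *par[k] -= lr_t * (st.m[k] / bc1) / (sqrt(st.v[k] / bc2) + eps);
  }
}

static std::vector<mat*> param_ptrs(LstmParams& P) {
  return {&P.Wx1, &P.Wh1, &P.b1, &P.Wx2, &P.Wh2, &P.b2, &P.Wy, &P.by};
}

// [[Rcpp::export]]
Rcpp::List cpp_lstm_train(Rcpp::List params, arma::mat X, arma::uvec y,
                          int epochs, int batch_size, double lr,
                          double decay, double dropout, int seed) {
  LstmParams P = unpack(params);
  int S = X.n_rows, H = P.H();
  std::mt19937 eng(static_cast<unsigned>(seed) ^ 0x9e3779b9u);
  std::uniform_real_distribution<double> U01(0.0, 1.0);
  AdamState adam;
  std::vector<double> loss_hist, acc_hist;
  std::vector<int> order(S);
  for (int i = 0; i < S; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), eng);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < S; start += batch_size) {
      int end = std::min(start + batch_size, S);
      int B = end - start;
      mat Xb(B, X.n_cols);
      uvec yb(B);
      for (int b = 0; b < B; ++b) {
        Xb.row(b) = X.row(order[start + b]);
        yb(b) = y(order[start + b]);
      }
      cube mask1; mat mask2;
      if (dropout > 0.0) {
        double keep = 1.0 - dropout;
        mask1.set_size(B, H, X.n_cols);
        for (uword e = 0; e < mask1.n_elem; ++e)
          mask1(e) = (U01(eng) < keep) ? 1.0 / keep : 0.0;
        mask2.set_size(B, H);
        for (uword e = 0; e < mask2.n_elem; ++e)
          mask2(e) = (U01(eng) < keep) ? 1.0 / keep : 0.0;
      }
      LstmParams G;
      ep_loss += batch_grad(P, Xb, yb, mask1, mask2, G);
      n_batches++;
      std::vector<mat*> pp = param_ptrs(P), gp = param_ptrs(G);
      adam_update(pp, gp, adam, lr, decay);
    }
    loss_hist.push_back(ep_loss / n_batches);
    // training accuracy in inference mode (dropout off)
    mat probs = cpp_lstm_predict(pack(P), X);
    uvec pred = index_max(probs, 1);
    acc_hist.push_back((double)accu(pred == y) / S);
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = pack(P),
      Rcpp::Named("loss") = loss_hist,
      Rcpp::Named("accuracy") = acc_hist);
}
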