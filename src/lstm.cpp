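// Numeric core of the two-layer LSTM: full-sequence forward and
// backpropagation-through-time for one layer. Gate order in the fused
// weight matrices is [input | forget | cell | output]. The R wrappers in
// R/models.R stack layers and add the affine head.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Extract the (batch x channels) matrix at time t from a (b, L, C) array.
static mat at_time(const cube& x, uword t) {
  mat out(x.n_rows, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c) out.col(c) = x.slice(c).col(t);
  return out;
}

static void set_time(cube& x, uword t, const mat& v) {
  for (uword c = 0; c < x.n_slices; ++c) x.slice(c).col(t) = v.col(c);
}

// [[Rcpp::export(name = "lstm_layer_forward")]]
Rcpp::List lstm_layer_forward(const arma::cube& X, const arma::mat& Wi,
                              const arma::mat& Wh, const arma::vec& b) {
  const uword bsz = X.n_rows, L = X.n_cols;
  const uword h = Wh.n_rows;
  cube H(bsz, L, h, fill::zeros);
  // gate/state caches as (bsz, h, L) cubes: slice t is the (b x h) matrix
  cube I(bsz, h, L), F(bsz, h, L), G(bsz, h, L), O(bsz, h, L),
      C(bsz, h, L), TC(bsz, h, L);
  mat hprev(bsz, h, fill::zeros), cprev(bsz, h, fill::zeros);
  rowvec br = b.t();
  for (uword t = 0; t < L; ++t) {
    mat z = at_time(X, t) * Wi + hprev * Wh;
    z.each_row() += br;
    mat ig = sigm(z.cols(0, h - 1));
    mat fg = sigm(z.cols(h, 2 * h - 1));
    mat gg = tanh(z.cols(2 * h, 3 * h - 1));
    mat og = sigm(z.cols(3 * h, 4 * h - 1));
    mat c = fg % cprev + ig % gg;
    mat tc = tanh(c);
    mat hh = og % tc;
    I.slice(t) = ig; F.slice(t) = fg; G.slice(t) = gg; O.slice(t) = og;
    C.slice(t) = c; TC.slice(t) = tc;
    set_time(H, t, hh);
    hprev = hh; cprev = c;
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("I") = I, Rcpp::Named("F") = F,
      Rcpp::Named("G") = G, Rcpp::Named("O") = O, Rcpp::Named("C") = C,
      Rcpp::Named("TC") = TC);
}

// [[Rcpp::export(name = "lstm_layer_backward")]]
Rcpp::List lstm_layer_backward(const arma::cube& X, const arma::mat& Wi,
                               const arma::mat& Wh, const Rcpp::List& cache,
                               const arma::cube& dH) {
  const cube H = cache["H"], I = cache["I"], F = cache["F"], G = cache["G"],
             O = cache["O"], C = cache["C"], TC = cache["TC"];
  const uword bsz = X.n_rows, L = X.n_cols, cin = X.n_slices;
  const uword h = Wh.n_rows;
  cube dX(bsz, L, cin, fill::zeros);
  mat dWi(cin, 4 * h, fill::zeros), dWh(h, 4 * h, fill::zeros);
  rowvec db(4 * h, fill::zeros);
  mat dh_next(bsz, h, fill::zeros), dc_next(bsz, h, fill::zeros);
  for (uword tt = L; tt-- > 0;) {
    mat dh = at_time(dH, tt) + dh_next;
    const mat& ig = I.slice(tt);
    const mat& fg = F.slice(tt);
    const mat& gg = G.slice(tt);
    const mat& og = O.slice(tt);
    const mat& tc = TC.slice(tt);
    mat dc = dh % og % (1.0 - tc % tc) + dc_next;
    mat cprev = (tt > 0) ? C.slice(tt - 1) : mat(bsz, h, fill::zeros);
    mat dz(bsz, 4 * h);
    dz.cols(0, h - 1) = dc % gg % ig % (1.0 - ig);
    dz.cols(h, 2 * h - 1) = dc % cprev % fg % (1.0 - fg);
    dz.cols(2 * h, 3 * h - 1) = dc % ig % (1.0 - gg % gg);
    dz.cols(3 * h, 4 * h - 1) = dh % tc % og % (1.0 - og);
    mat xt = at_time(X, tt);
    dWi += xt.t() * dz;
    if (tt > 0) {
      mat hprev = at_time(H, tt - 1);
      dWh += hprev.t() * dz;
    }
    db += sum(dz, 0);
    set_time(dX, tt, dz * Wi.t());
    dh_next = dz * Wh.t();
    dc_next = dc % fg;
  }
  return Rcpp::List::create(
      Rcpp::Named("dX") = dX, Rcpp::Named("dWi") = dWi,
      Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = vec(db.t()));
}

// Fused full-network pass for the stacked LSTM + affine head: forward,
// RMSE loss and complete backward in one call, keeping all per-timestep
// caches in C++. Layers come as a list of (Wi, Wh, b) with b = bi + bh.

struct LayerCache {
  std::vector<mat> I, F, G, O, C, TC, Hs;
};

static void run_layer(const std::vector<mat>& X, const mat& Wi, const mat& Wh,
                      const rowvec& br, LayerCache& lc) {
  const uword L = X.size();
  const uword bsz = X[0].n_rows, h = Wh.n_rows;
  mat hprev(bsz, h, fill::zeros), cprev(bsz, h, fill::zeros);
  lc.I.resize(L); lc.F.resize(L); lc.G.resize(L); lc.O.resize(L);
  lc.C.resize(L); lc.TC.resize(L); lc.Hs.resize(L);
  for (uword t = 0; t < L; ++t) {
    mat z = X[t] * Wi + hprev * Wh;
    z.each_row() += br;
    lc.I[t] = sigm(z.cols(0, h - 1));
    lc.F[t] = sigm(z.cols(h, 2 * h - 1));
    lc.G[t] = tanh(z.cols(2 * h, 3 * h - 1));
    lc.O[t] = sigm(z.cols(3 * h, 4 * h - 1));
    lc.C[t] = lc.F[t] % cprev + lc.I[t] % lc.G[t];
    lc.TC[t] = tanh(lc.C[t]);
    lc.Hs[t] = lc.O[t] % lc.TC[t];
    hprev = lc.Hs[t]; cprev = lc.C[t];
  }
}

// [[Rcpp::export(name = "lstm_net_cpp")]]
Rcpp::List lstm_net_cpp(const arma::mat& Xin, const Rcpp::List& layers,
                        const arma::mat& Whead, const double bhead,
                        const Rcpp::Nullable<Rcpp::NumericVector>& target) {
  const uword bsz = Xin.n_rows, L = Xin.n_cols;
  const uword nlay = layers.size();
  std::vector<std::vector<mat>> inputs(nlay + 1);
  inputs[0].resize(L);
  for (uword t = 0; t < L; ++t) inputs[0][t] = Xin.col(t);
  std::vector<LayerCache> caches(nlay);
  std::vector<mat> Wis(nlay), Whs(nlay);
  for (uword li = 0; li < nlay; ++li) {
    Rcpp::List lay = layers[li];
    Wis[li] = Rcpp::as<mat>(lay["Wi"]);
    Whs[li] = Rcpp::as<mat>(lay["Wh"]);
    rowvec br = Rcpp::as<rowvec>(lay["b"]);
    run_layer(inputs[li], Wis[li], Whs[li], br, caches[li]);
    inputs[li + 1] = caches[li].Hs;
  }
  const mat& hl = inputs[nlay][L - 1];
  vec yhat = hl * Whead + bhead;
  if (target.isNull()) {
    return Rcpp::List::create(Rcpp::Named("yhat") = yhat);
  }
  vec y = Rcpp::as<vec>(target.get());
  vec err = yhat - y;
  double loss = std::sqrt(mean(err % err));
  vec dy = (loss > 0) ? vec(err / (double(bsz) * loss)) : err;
  // head gradients
  mat dWhead = hl.t() * dy;
  double dbhead = sum(dy);
  std::vector<mat> dH(L);
  const uword htop = Whs[nlay - 1].n_rows;
  for (uword t = 0; t < L; ++t) dH[t] = mat(bsz, htop, fill::zeros);
  dH[L - 1] = dy * Whead.t();
  Rcpp::List lgrads(nlay);
  for (uword li = nlay; li-- > 0;) {
    const LayerCache& lc = caches[li];
    const std::vector<mat>& X = inputs[li];
    const uword h = Whs[li].n_rows, cin = X[0].n_cols;
    mat dWi(cin, 4 * h, fill::zeros), dWh(h, 4 * h, fill::zeros);
    rowvec db(4 * h, fill::zeros);
    mat dh_next(bsz, h, fill::zeros), dc_next(bsz, h, fill::zeros);
    std::vector<mat> dX(L);
    for (uword tt = L; tt-- > 0;) {
      mat dh = dH[tt] + dh_next;
      mat dc = dh % lc.O[tt] % (1.0 - lc.TC[tt] % lc.TC[tt]) + dc_next;
      mat cprev = (tt > 0) ? lc.C[tt - 1] : mat(bsz, h, fill::zeros);
      mat dz(bsz, 4 * h);
      dz.cols(0, h - 1) = dc % lc.G[tt] % lc.I[tt] % (1.0 - lc.I[tt]);
      dz.cols(h, 2 * h - 1) = dc % cprev % lc.F[tt] % (1.0 - lc.F[tt]);
      dz.cols(2 * h, 3 * h - 1) = dc % lc.I[tt] % (1.0 - lc.G[tt] % lc.G[tt]);
      dz.cols(3 * h, 4 * h - 1) = dh % lc.TC[tt] % lc.O[tt] % (1.0 - lc.O[tt]);
      dWi += X[tt].t() * dz;
      if (tt > 0) dWh += lc.Hs[tt - 1].t() * dz;
      db += sum(dz, 0);
      dX[tt] = dz * Wis[li].t();
      dh_next = dz * Whs[li].t();
      dc_next = dc % lc.F[tt];
    }
    lgrads[li] = Rcpp::List::create(Rcpp::Named("dWi") = dWi,
                                    Rcpp::Named("dWh") = dWh,
                                    Rcpp::Named("db") = vec(db.t()));
    if (li > 0) dH = dX;
  }
  return Rcpp::List::create(
      Rcpp::Named("yhat") = yhat, Rcpp::Named("loss") = loss,
      Rcpp::Named("layers") = lgrads,
      Rcpp::Named("dWhead") = dWhead, Rcpp::Named("dbhead") = dbhead);
}
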