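// LSTM sequence kernels: the per-timestep recurrences are the hot path of
// training and are kept in C++; all surrounding tensor plumbing stays in R.
// Forward returns its gate caches behind an external pointer so nothing but
// the hidden states is copied back into R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct LstmCache {
  cube X;                      // (input, T, B)
  cube I, F, G, O, TC, HP, CP; // gate states, (hidden, B, T) keyed by t
};

// X: (input, T, B). Returns hidden states H (hidden, T, B) and a cache
// pointer for the matching backward call.
// [[Rcpp::export(name = ".lstm_fwd_cpp")]]
List lstm_fwd_cpp(const arma::mat& Wx, const arma::mat& Wh, const arma::vec& b,
                  const arma::cube& X, bool reverse, bool want_cache) {
  const int in = X.n_rows, T = X.n_cols, B = X.n_slices;
  const int h = Wh.n_cols;
  LstmCache* cc = new LstmCache();
  if (want_cache) {
    cc->X = X;
    cc->I.set_size(h, B, T); cc->F.set_size(h, B, T); cc->G.set_size(h, B, T);
    cc->O.set_size(h, B, T); cc->TC.set_size(h, B, T);
    cc->HP.set_size(h, B, T); cc->CP.set_size(h, B, T);
  }
  cube H(h, T, B, arma::fill::zeros);
  mat hs(h, B, arma::fill::zeros), cs(h, B, arma::fill::zeros);
  mat x(in, B);
  const double* Xp = X.memptr();
  double* Hp = H.memptr();
  for (int step = 0; step < T; ++step) {
    const int t = reverse ? (T - 1 - step) : step;
    for (int bb = 0; bb < B; ++bb)
      std::memcpy(x.colptr(bb), Xp + (size_t)bb * in * T + (size_t)t * in,
                  in * sizeof(double));
    mat Gm = Wx * x + Wh * hs;
    Gm.each_col() += b;
    mat gi = sigm(Gm.rows(0, h - 1));
    mat gf = sigm(Gm.rows(h, 2 * h - 1));
    mat gg = arma::tanh(Gm.rows(2 * h, 3 * h - 1));
    mat go = sigm(Gm.rows(3 * h, 4 * h - 1));
    if (want_cache) {
      cc->HP.slice(t) = hs;
      cc->CP.slice(t) = cs;
    }
    cs = gf % cs + gi % gg;
    mat tc = arma::tanh(cs);
    hs = go % tc;
    if (want_cache) {
      cc->I.slice(t) = gi; cc->F.slice(t) = gf; cc->G.slice(t) = gg;
      cc->O.slice(t) = go; cc->TC.slice(t) = tc;
    }
    for (int bb = 0; bb < B; ++bb)
      std::memcpy(Hp + (size_t)bb * h * T + (size_t)t * h, hs.colptr(bb),
                  h * sizeof(double));
  }
  XPtr<LstmCache> ptr(cc, true);
  return List::create(_["H"] = H, _["cache"] = ptr);
}

// Backpropagation through time. dH: (hidden, T, B) upstream gradients.
// [[Rcpp::export(name = ".lstm_bwd_cpp")]]
List lstm_bwd_cpp(const arma::mat& Wx, const arma::mat& Wh, SEXP cache,
                  const arma::cube& dH, bool reverse) {
  XPtr<LstmCache> cc(cache);
  const int in = cc->X.n_rows, T = cc->X.n_cols, B = cc->X.n_slices;
  const int h = Wh.n_cols;
  mat dWx(arma::size(Wx), arma::fill::zeros);
  mat dWh(arma::size(Wh), arma::fill::zeros);
  vec db(4 * h, arma::fill::zeros);
  cube dX(in, T, B, arma::fill::zeros);
  mat dh_next(h, B, arma::fill::zeros), dc_next(h, B, arma::fill::zeros);
  mat x(in, B), dh(h, B), dG(4 * h, B);
  const double* Xp = cc->X.memptr();
  const double* dHp = dH.memptr();
  double* dXp = dX.memptr();
  for (int step = T - 1; step >= 0; --step) {
    const int t = reverse ? (T - 1 - step) : step;
    for (int bb = 0; bb < B; ++bb) {
      std::memcpy(x.colptr(bb), Xp + (size_t)bb * in * T + (size_t)t * in,
                  in * sizeof(double));
      std::memcpy(dh.colptr(bb), dHp + (size_t)bb * h * T + (size_t)t * h,
                  h * sizeof(double));
    }
    dh += dh_next;
    const mat& gi = cc->I.slice(t);
    const mat& gf = cc->F.slice(t);
    const mat& gg = cc->G.slice(t);
    const mat& go = cc->O.slice(t);
    const mat& tc = cc->TC.slice(t);
    mat ddo = dh % tc;
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    dG.rows(0, h - 1) = (dc % gg) % gi % (1.0 - gi);
    dG.rows(h, 2 * h - 1) = (dc % cc->CP.slice(t)) % gf % (1.0 - gf);
    dG.rows(2 * h, 3 * h - 1) = (dc % gi) % (1.0 - gg % gg);
    dG.rows(3 * h, 4 * h - 1) = ddo % go % (1.0 - go);
    dc_next = dc % gf;
    dWx += dG * x.t();
    dWh += dG * cc->HP.slice(t).t();
    db += arma::sum(dG, 1);
    mat dx = Wx.t() * dG;
    for (int bb = 0; bb < B; ++bb)
      std::memcpy(dXp + (size_t)bb * in * T + (size_t)t * in, dx.colptr(bb),
                  in * sizeof(double));
    dh_next = Wh.t() * dG;
  }
  // release the cache eagerly: R's GC cannot see this memory and a training
  // loop would otherwise accumulate caches until a collection happens
  cc->X.reset(); cc->I.reset(); cc->F.reset(); cc->G.reset();
  cc->O.reset(); cc->TC.reset(); cc->HP.reset(); cc->CP.reset();
  return List::create(_["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db,
                      _["dX"] = dX);
}
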