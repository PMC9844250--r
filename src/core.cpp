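// Compiled inner loops of the connectivity network: the per-timestep LSTM
// recurrences (which cannot be vectorized over time in R) and the
// per-timepoint self-attention, batched over subjects.  The temporal
// attention MLP, classifier head and loss stay in R where they are cheap.
//
// Layouts (0-based here; S subjects, N nodes, T timepoints, M = S*N):
//   - sequence index m = s*N + i; scalar inputs X2 are M x T;
//   - "big" matrices stack rows r = t*M + s*N + i (node fastest, then
//     subject, then time);
//   - the group g = t*S + s indexes one (subject, timepoint); flattened
//     connectivity Wflat is ST x N^2 with column j*N + i holding W_t[i, j]
//     (column-major N x N), W[i, j] = attention of query i on key j.
// Gate order in 4H blocks: input, forget, candidate, output.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static inline mat sigm(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

static void lstm_fwd(const mat &X2, const rowvec &Wi, const mat &Wh,
                     const rowvec &bias, bool reverse, cube &Hout, cube &Cout,
                     cube &Gates) {
  const uword M = X2.n_rows, T = X2.n_cols, H = Wh.n_rows;
  Hout.set_size(M, H, T);
  Cout.set_size(M, H, T);
  Gates.set_size(M, 4 * H, T);
  mat hprev(M, H, fill::zeros), cprev(M, H, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    const uword t = reverse ? (T - 1 - k) : k;
    mat pre = X2.col(t) * Wi + hprev * Wh;
    pre.each_row() += bias;
    mat &G = Gates.slice(t);
    G.cols(0, 2 * H - 1) = sigm(pre.cols(0, 2 * H - 1));       // i, f
    G.cols(2 * H, 3 * H - 1) = tanh(pre.cols(2 * H, 3 * H - 1)); // g
    G.cols(3 * H, 4 * H - 1) = sigm(pre.cols(3 * H, 4 * H - 1)); // o
    Cout.slice(t) = G.cols(H, 2 * H - 1) % cprev +
                    G.cols(0, H - 1) % G.cols(2 * H, 3 * H - 1);
    Hout.slice(t) = G.cols(3 * H, 4 * H - 1) % tanh(Cout.slice(t));
    hprev = Hout.slice(t);
    cprev = Cout.slice(t);
  }
}

static void lstm_bwd(const cube &dH, const mat &X2, const cube &C,
                     const cube &Gates, const cube &Hout, const mat &Wh,
                     bool reverse, rowvec &dWi, mat &dWh, rowvec &db) {
  const uword M = X2.n_rows, T = X2.n_cols, H = Wh.n_rows;
  dWi.zeros(4 * H);
  db.zeros(4 * H);
  dWh.zeros(H, 4 * H);
  mat dh_carry(M, H, fill::zeros), dc_carry(M, H, fill::zeros);
  const mat WhT = Wh.t();
  for (uword k = T; k-- > 0;) {
    const uword t = reverse ? (T - 1 - k) : k;
    const bool first = (k == 0);
    const uword tprev = reverse ? (t + 1) : (t - 1);
    const mat &G = Gates.slice(t);
    const auto gi = G.cols(0, H - 1);
    const auto gf = G.cols(H, 2 * H - 1);
    const auto gg = G.cols(2 * H, 3 * H - 1);
    const auto go = G.cols(3 * H, 4 * H - 1);
    const mat tc = tanh(C.slice(t));
    const mat dh = dH.slice(t) + dh_carry;
    const mat do_ = dh % tc;
    const mat dc = dc_carry + dh % go % (1.0 - tc % tc);
    mat dA(M, 4 * H);
    dA.cols(0, H - 1) = (dc % gg) % gi % (1.0 - gi);
    if (first)
      dA.cols(H, 2 * H - 1).zeros();
    else
      dA.cols(H, 2 * H - 1) = (dc % C.slice(tprev)) % gf % (1.0 - gf);
    dA.cols(2 * H, 3 * H - 1) = (dc % gi) % (1.0 - gg % gg);
    dA.cols(3 * H, 4 * H - 1) = do_ % go % (1.0 - go);
    dc_carry = dc % gf;
    dWi += X2.col(t).t() * dA;
    if (!first)
      dWh += Hout.slice(tprev).t() * dA;
    db += sum(dA, 0);
    dh_carry = dA * WhT;
  }
}

// Exported single-purpose wrappers (used by the per-subject operations).

// [[Rcpp::export]]
List lstm_forward_cpp(const arma::mat &X2, const arma::rowvec &Wi,
                      const arma::mat &Wh, const arma::rowvec &bias,
                      bool reverse) {
  cube H, C, G;
  lstm_fwd(X2, Wi, Wh, bias, reverse, H, C, G);
  return List::create(Named("H") = H, Named("C") = C, Named("Gates") = G);
}

// [[Rcpp::export]]
List lstm_backward_cpp(const arma::cube &dH, const arma::mat &X2,
                       const arma::cube &C, const arma::cube &Gates,
                       const arma::cube &Hout, const arma::mat &Wh,
                       bool reverse) {
  rowvec dWi, db;
  mat dWh;
  lstm_bwd(dH, X2, C, Gates, Hout, Wh, reverse, dWi, dWh, db);
  return List::create(Named("dWi") = dWi, Named("dWh") = dWh,
                      Named("db") = db);
}

struct FwdCache {
  mat X2;
  cube Hf, Cf, Gf, Hb, Cb, Gb;
  mat Emb;                    // MT x 2H
  std::vector<mat> Q, K, Wh;  // per head
  uword S, N, T, H;
  double scale;
};

// Full batched forward through encoder + self-attention.  Returns the
// flattened connectivity (ST x N^2) and, when a backward pass will follow,
// an external pointer to the cache.
// [[Rcpp::export]]
List core_forward_cpp(const arma::mat &X2, const arma::rowvec &fWi,
                      const arma::mat &fWh, const arma::rowvec &fb,
                      const arma::rowvec &bWi, const arma::mat &bWh,
                      const arma::rowvec &bb, const Rcpp::List &Wq_list,
                      const Rcpp::List &Wk_list, int S_, int N_,
                      double scale, bool want_cache) {
  FwdCache *ca = new FwdCache();
  ca->X2 = X2;
  const uword M = X2.n_rows, T = X2.n_cols, H = fWh.n_rows;
  const uword S = (uword)S_, N = (uword)N_;
  const uword ST = S * T, MT = M * T;
  ca->S = S; ca->N = N; ca->T = T; ca->H = H; ca->scale = scale;
  lstm_fwd(X2, fWi, fWh, fb, false, ca->Hf, ca->Cf, ca->Gf);
  lstm_fwd(X2, bWi, bWh, bb, true, ca->Hb, ca->Cb, ca->Gb);
  mat &Emb = ca->Emb;
  Emb.set_size(MT, 2 * H);
  for (uword t = 0; t < T; ++t) {
    Emb.rows(t * M, t * M + M - 1).cols(0, H - 1) = ca->Hf.slice(t);
    Emb.rows(t * M, t * M + M - 1).cols(H, 2 * H - 1) = ca->Hb.slice(t);
  }
  const int nh = Wq_list.size();
  mat W(MT, N, fill::zeros);
  for (int h = 0; h < nh; ++h) {
    const mat Wq = Rcpp::as<mat>(Wq_list[h]);
    const mat Wk = Rcpp::as<mat>(Wk_list[h]);
    mat Q = Emb * Wq;
    mat K = Emb * Wk;
    mat Wh_(MT, N);
    for (uword g = 0; g < ST; ++g) {
      const uword r0 = g * N, r1 = g * N + N - 1;
      mat Sg = Q.rows(r0, r1) * K.rows(r0, r1).t() * scale;
      // row-wise softmax
      Sg.each_col() -= max(Sg, 1);
      Sg = exp(Sg);
      Sg.each_col() /= sum(Sg, 1);
      Wh_.rows(r0, r1) = Sg;
    }
    W += Wh_;
    if (want_cache) {
      ca->Q.push_back(std::move(Q));
      ca->K.push_back(std::move(K));
      ca->Wh.push_back(std::move(Wh_));
    }
  }
  W /= (double)nh;
  // Wflat: row g = t*S + s, col j*N + i  <-  W(t*M + s*N + i, j)
  mat Wflat(ST, N * N);
  for (uword t = 0; t < T; ++t)
    for (uword s = 0; s < S; ++s) {
      const uword g = t * S + s, r0 = t * M + s * N;
      for (uword j = 0; j < N; ++j)
        for (uword i = 0; i < N; ++i)
          Wflat(g, j * N + i) = W(r0 + i, j);
    }
  if (!want_cache) {
    delete ca;
    return List::create(Named("Wflat") = Wflat);
  }
  Rcpp::XPtr<FwdCache> ptr(ca, true);
  return List::create(Named("Wflat") = Wflat, Named("cache") = ptr);
}

// Backward from the gradient on the flattened connectivity down to all
// encoder and attention parameter gradients.  Frees the cache.
// [[Rcpp::export]]
List core_backward_cpp(SEXP cache_sexp, const arma::mat &dWflat,
                       const Rcpp::List &Wq_list, const Rcpp::List &Wk_list,
                       const arma::mat &fWh, const arma::mat &bWh) {
  Rcpp::XPtr<FwdCache> ptr(cache_sexp);
  FwdCache *ca = ptr.get();
  if (ca == nullptr || ca->Emb.n_elem == 0)
    Rcpp::stop("attention cache already consumed");
  const uword S = ca->S, N = ca->N, T = ca->T, H = ca->H;
  const uword M = S * N, ST = S * T, MT = M * T;
  const int nh = Wq_list.size();
  // dW in row-major layout from dWflat
  mat dW(MT, N);
  for (uword t = 0; t < T; ++t)
    for (uword s = 0; s < S; ++s) {
      const uword g = t * S + s, r0 = t * M + s * N;
      for (uword j = 0; j < N; ++j)
        for (uword i = 0; i < N; ++i)
          dW(r0 + i, j) = dWflat(g, j * N + i);
    }
  mat dEmb(MT, 2 * H, fill::zeros);
  List gWq(nh), gWk(nh);
  for (int h = 0; h < nh; ++h) {
    const mat Wq = Rcpp::as<mat>(Wq_list[h]);
    const mat Wk = Rcpp::as<mat>(Wk_list[h]);
    const mat &Q = ca->Q[h];
    const mat &K = ca->K[h];
    const mat &Wh_ = ca->Wh[h];
    const uword d = Q.n_cols;
    mat dQ(MT, d), dK(MT, d);
    for (uword g = 0; g < ST; ++g) {
      const uword r0 = g * N, r1 = g * N + N - 1;
      mat dWg = dW.rows(r0, r1) / (double)nh;
      const mat &Wg_ = Wh_.rows(r0, r1);
      colvec rs = sum(dWg % Wg_, 1);
      mat dS = (Wg_ % (dWg.each_col() - rs)) * ca->scale;
      dQ.rows(r0, r1) = dS * K.rows(r0, r1);
      dK.rows(r0, r1) = dS.t() * Q.rows(r0, r1);
    }
    gWq[h] = ca->Emb.t() * dQ;
    gWk[h] = ca->Emb.t() * dK;
    dEmb += dQ * Wq.t() + dK * Wk.t();
  }
  cube dHf(M, H, T), dHb(M, H, T);
  for (uword t = 0; t < T; ++t) {
    dHf.slice(t) = dEmb.rows(t * M, t * M + M - 1).cols(0, H - 1);
    dHb.slice(t) = dEmb.rows(t * M, t * M + M - 1).cols(H, 2 * H - 1);
  }
  rowvec f_dWi, f_db, b_dWi, b_db;
  mat f_dWh, b_dWh;
  lstm_bwd(dHf, ca->X2, ca->Cf, ca->Gf, ca->Hf, fWh, false, f_dWi, f_dWh,
           f_db);
  lstm_bwd(dHb, ca->X2, ca->Cb, ca->Gb, ca->Hb, bWh, true, b_dWi, b_dWh,
           b_db);
  List out = List::create(
      Named("f_dWi") = f_dWi, Named("f_dWh") = f_dWh, Named("f_db") = f_db,
      Named("b_dWi") = b_dWi, Named("b_dWh") = b_dWh, Named("b_db") = b_db,
      Named("dWq") = gWq, Named("dWk") = gWk);
  // free the large buffers now; the finalizer deletes the struct at GC
  ca->X2.reset();
  ca->Emb.reset();
  ca->Hf.reset(); ca->Cf.reset(); ca->Gf.reset();
  ca->Hb.reset(); ca->Cb.reset(); ca->Gb.reset();
  ca->Q.clear(); ca->K.clear(); ca->Wh.clear();
  return out;
}
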