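// Sequence LSTM kernels used by the bi-directional recurrent regressor.
//
// Layout conventions:
//   X    : cube (I, B, T)  -- input features, batch, time
//   mask : mat  (B, T)     -- 1 for a real frame, 0 for right padding; at a
//                             masked step the hidden and cell states are
//                             carried through unchanged, so padded frames
//                             contribute nothing to states or gradients.
//   W    : mat (4H, I), U : mat (4H, H), b : vec (4H)
//   reverse = true processes the sequence back-to-front (the backward
//   direction of a bi-directional layer); outputs stay aligned with the
//   original time axis.
// Gate order within the 4H block: input (i), forget (f), candidate (g,
// tanh), output (o).
//
// Hot loops are written against raw column pointers with preallocated
// workspaces and in-place BLAS accumulation: these kernels run hundreds of
// thousands of times per training run and temporaries dominate otherwise.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }
// tanh via exp: measurably faster than std::tanh on this libm, exact at the
// saturation limits (exp overflow/underflow give +/-1).
static inline double fast_tanh(double x) { return 1.0 - 2.0 / (1.0 + std::exp(2.0 * x)); }

// C += A (m x k) * B (k x n), in place
static inline void gemm_acc(const double* A, const double* Bm, double* C,
                            int m, int k, int n) {
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, A, &m, Bm, &k, &one, C, &m
                  FCONE FCONE);
}

// [[Rcpp::export(name = ".lstm_forward")]]
Rcpp::List lstm_forward(const arma::cube& X, const arma::mat& mask,
                        const arma::mat& W, const arma::mat& U,
                        const arma::vec& b, const bool reverse = false) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = U.n_cols;
  if (W.n_rows != 4 * H || W.n_cols != I)
    Rcpp::stop("weight dimensions inconsistent with input");

  // Input projection for all timesteps in one GEMM.
  const mat Xf(const_cast<double*>(X.memptr()), I, B * T, false, true);
  mat Ain = W * Xf;                       // (4H, B*T)
  Ain.each_col() += b;

  cube Hc(H, B, T);                       // masked hidden states
  cube Cc(H, B, T);                       // masked cell states
  cube G(4 * H, B, T);                    // activated gates
  cube Chat(H, B, T);                     // unmasked candidate cell values

  mat a(4 * H, B);
  const mat zeros_state(H, B, fill::zeros);
  for (uword k = 0; k < T; ++k) {
    const uword t = reverse ? (T - 1 - k) : k;
    const bool first = (k == 0);
    const uword tprev = reverse ? t + 1 : t - 1;
    const double* hprev = first ? zeros_state.memptr() : Hc.slice_memptr(tprev);
    const double* cprev = first ? zeros_state.memptr() : Cc.slice_memptr(tprev);
    // a = Ain[, block t] + U * hprev
    std::memcpy(a.memptr(), Ain.colptr(t * B), sizeof(double) * 4 * H * B);
    gemm_acc(U.memptr(), hprev, a.memptr(), 4 * H, H, B);

    double* Gt = G.slice_memptr(t);
    double* Ct = Cc.slice_memptr(t);
    double* Ht = Hc.slice_memptr(t);
    double* Cht = Chat.slice_memptr(t);
    for (uword col = 0; col < B; ++col) {
      const double m = mask(col, t);
      const double* ac = a.colptr(col);
      const double* hp = hprev + col * H;
      const double* cp = cprev + col * H;
      double* gcol = Gt + col * 4 * H;
      double* ccol = Ct + col * H;
      double* hcol = Ht + col * H;
      double* chcol = Cht + col * H;
      for (uword h = 0; h < H; ++h) {
        const double gi = sig(ac[h]);
        const double gf = sig(ac[H + h]);
        const double gg = fast_tanh(ac[2 * H + h]);
        const double go = sig(ac[3 * H + h]);
        const double cn = gf * cp[h] + gi * gg;
        const double hn = go * fast_tanh(cn);
        gcol[h] = gi; gcol[H + h] = gf; gcol[2 * H + h] = gg; gcol[3 * H + h] = go;
        chcol[h] = cn;
        ccol[h] = m * cn + (1.0 - m) * cp[h];
        hcol[h] = m * hn + (1.0 - m) * hp[h];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("H") = Hc, Rcpp::Named("C") = Cc,
                            Rcpp::Named("G") = G, Rcpp::Named("Chat") = Chat);
}

// Backpropagation through time for the forward pass above.  dH is the
// gradient of the loss with respect to the (masked) hidden-state sequence.
// [[Rcpp::export(name = ".lstm_backward")]]
Rcpp::List lstm_backward(const arma::cube& X, const arma::mat& mask,
                         const arma::mat& W, const arma::mat& U,
                         const Rcpp::List& cache, const arma::cube& dH,
                         const bool reverse = false) {
  const uword I = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = U.n_cols;
  const cube& Hc = cache["H"];
  const cube& Cc = cache["C"];
  const cube& G = cache["G"];
  const cube& Chat = cache["Chat"];

  cube dA(4 * H, B, T);                   // pre-activation gradients
  const mat Ut = U.t();
  const mat zeros_state(H, B, fill::zeros);

  mat dh_carry(H, B, fill::zeros), dc_carry(H, B, fill::zeros);
  // iterate in reverse processing order: last-processed step first
  for (uword k = T; k-- > 0;) {
    const uword t = reverse ? (T - 1 - k) : k;
    const bool first = (k == 0);          // first step in processing order
    const uword tprev = reverse ? t + 1 : t - 1;
    const double* cprev = first ? zeros_state.memptr() : Cc.slice_memptr(tprev);
    const double* Gt = G.slice_memptr(t);
    const double* Cht = Chat.slice_memptr(t);
    const double* dHt = dH.slice_memptr(t);
    double* dAt = dA.slice_memptr(t);

    for (uword col = 0; col < B; ++col) {
      const double m = mask(col, t);
      const double* gcol = Gt + col * 4 * H;
      const double* chcol = Cht + col * H;
      const double* cp = cprev + col * H;
      const double* dhext = dHt + col * H;
      double* dhc = dh_carry.colptr(col);
      double* dcc = dc_carry.colptr(col);
      double* dac = dAt + col * 4 * H;
      for (uword h = 0; h < H; ++h) {
        const double gi = gcol[h], gf = gcol[H + h], gg = gcol[2 * H + h],
                     go = gcol[3 * H + h];
        const double tc = fast_tanh(chcol[h]);
        const double dh = dhext[h] + dhc[h];
        const double dc = dcc[h];
        const double dhnew = m * dh;
        const double dcnew = m * dc + dhnew * go * (1.0 - tc * tc);
        const double di = dcnew * gg;
        const double dg = dcnew * gi;
        const double df = dcnew * cp[h];
        const double do_ = dhnew * tc;
        dac[h] = di * gi * (1.0 - gi);
        dac[H + h] = df * gf * (1.0 - gf);
        dac[2 * H + h] = dg * (1.0 - gg * gg);
        dac[3 * H + h] = do_ * go * (1.0 - go);
        // carry to the processing-order predecessor
        dhc[h] = (1.0 - m) * dh;
        dcc[h] = (1.0 - m) * dc + dcnew * gf;
      }
    }
    gemm_acc(Ut.memptr(), dAt, dh_carry.memptr(), H, 4 * H, B);
  }

  // Weight gradients in single GEMMs over the flattened time axis.
  const mat Xf(const_cast<double*>(X.memptr()), I, B * T, false, true);
  const mat dAf(dA.memptr(), 4 * H, B * T, false, true);
  mat dW = dAf * Xf.t();
  vec db = sum(dAf, 1);
  // previous-hidden states in processing order (zero at the start slice)
  cube Hprev(H, B, T, fill::zeros);
  if (T > 1) {
    if (reverse)
      std::memcpy(Hprev.memptr(), Hc.slice_memptr(1),
                  sizeof(double) * H * B * (T - 1));
    else
      std::memcpy(Hprev.slice_memptr(1), Hc.memptr(),
                  sizeof(double) * H * B * (T - 1));
  }
  const mat Hprevf(Hprev.memptr(), H, B * T, false, true);
  mat dU = dAf * Hprevf.t();
  mat dXf = W.t() * dAf;
  cube dX(dXf.memptr(), I, B, T);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("dU") = dU, Rcpp::Named("db") = db);
}
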