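// LSTM inner loops of the ConvLSTM classifier.  The memory layout mirrors
// the R code: activations are (B*T) x C matrices with rows ordered
// batch-fastest, time-slower; LSTM gate order is [input, forget, cell,
// output].  Keeping the stepwise recurrences in C++ fuses the many small
// elementwise operations that dominate the recurrent passes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// full LSTM layer forward; returns the per-step caches needed by backward
// [[Rcpp::export(name = ".cppLstmForward")]]
Rcpp::List cppLstmForward(const arma::mat& A, int B, int Tn,
                          const arma::mat& Wx, const arma::mat& Wh,
                          const arma::vec& b) {
  const int L = Wh.n_cols / 4;
  mat H(B * Tn, L), C(B * Tn, L), I(B * Tn, L), F(B * Tn, L),
      G(B * Tn, L), O(B * Tn, L), TC(B * Tn, L);
  mat h(B, L, fill::zeros), c(B, L, fill::zeros);
  const mat Xproj = A * Wx;
  const rowvec bt = b.t();
  for (int t = 0; t < Tn; ++t) {
    const int r0 = t * B, r1 = t * B + B - 1;
    mat Gt = Xproj.rows(r0, r1) + h * Wh;
    Gt.each_row() += bt;
    const mat gi = sigmoid(Gt.cols(0, L - 1));
    const mat gf = sigmoid(Gt.cols(L, 2 * L - 1));
    const mat gc = tanh(Gt.cols(2 * L, 3 * L - 1));
    const mat go = sigmoid(Gt.cols(3 * L, 4 * L - 1));
    C.rows(r0, r1) = c;                    // c_{t-1}
    c = gf % c + gi % gc;
    const mat tc = tanh(c);
    h = go % tc;
    I.rows(r0, r1) = gi; F.rows(r0, r1) = gf;
    G.rows(r0, r1) = gc; O.rows(r0, r1) = go;
    TC.rows(r0, r1) = tc; H.rows(r0, r1) = h;
  }
  return Rcpp::List::create(
    Rcpp::Named("out") = H, Rcpp::Named("i") = I, Rcpp::Named("f") = F,
    Rcpp::Named("g") = G, Rcpp::Named("o") = O, Rcpp::Named("tc") = TC,
    Rcpp::Named("cPrev") = C);
}

// full LSTM layer backward given dH (gradient w.r.t. every step's output)
// [[Rcpp::export(name = ".cppLstmBackward")]]
Rcpp::List cppLstmBackward(const arma::mat& A, const arma::mat& H,
                           const arma::mat& I, const arma::mat& F,
                           const arma::mat& G, const arma::mat& O,
                           const arma::mat& TC, const arma::mat& Cprev,
                           const arma::mat& Wx, const arma::mat& Wh,
                           const arma::mat& dH, int B, int Tn) {
  const int L = Wh.n_cols / 4;
  mat dGall(B * Tn, 4 * L);
  mat dhNext(B, L, fill::zeros), dcNext(B, L, fill::zeros);
  const mat WhT = Wh.t();
  for (int t = Tn - 1; t >= 0; --t) {
    const int r0 = t * B, r1 = t * B + B - 1;
    const mat dh = dH.rows(r0, r1) + dhNext;
    const mat tc = TC.rows(r0, r1), o = O.rows(r0, r1);
    const mat dc = dcNext + dh % o % (1.0 - tc % tc);
    const mat gi = I.rows(r0, r1), gf = F.rows(r0, r1),
              gc = G.rows(r0, r1), cp = Cprev.rows(r0, r1);
    mat dG(B, 4 * L);
    dG.cols(0, L - 1) = (dc % gc) % gi % (1.0 - gi);
    dG.cols(L, 2 * L - 1) = (dc % cp) % gf % (1.0 - gf);
    dG.cols(2 * L, 3 * L - 1) = (dc % gi) % (1.0 - gc % gc);
    dG.cols(3 * L, 4 * L - 1) = (dh % tc) % o % (1.0 - o);
    dcNext = dc % gf;
    dGall.rows(r0, r1) = dG;
    dhNext = dG * WhT;
  }
  mat Hprev(B * Tn, L, fill::zeros);
  if (Tn > 1) Hprev.rows(B, B * Tn - 1) = H.rows(0, B * (Tn - 1) - 1);
  const vec db = sum(dGall, 0).t();
  return Rcpp::List::create(
    Rcpp::Named("dWx") = A.t() * dGall,
    Rcpp::Named("dWh") = Hprev.t() * dGall,
    Rcpp::Named("db") = Rcpp::NumericVector(db.begin(), db.end()),
    Rcpp::Named("dA") = dGall * Wx.t());
}

// im2col gather without SEXP copies: A is (B*Tin) x Cin, result is
// (B*Tout) x (k*Cin) with columns ordered kernel-offset fastest
// [[Rcpp::export(name = ".cppIm2col")]]
Rcpp::NumericMatrix cppIm2col(const Rcpp::NumericMatrix& A, int B, int Tin,
                              int k) {
  const int Cin = A.ncol();
  const int Tout = Tin - k + 1;
  const int nOut = B * Tout;
  Rcpp::NumericMatrix out(nOut, k * Cin);
  const double* a = A.begin();
  double* o = out.begin();
  for (int c = 0; c < Cin; ++c)
    for (int tau = 0; tau < k; ++tau)
      std::copy(a + c * (B * Tin) + tau * B,
                a + c * (B * Tin) + tau * B + nOut,
                o + (c * k + tau) * nOut);
  return out;
}

// scatter-add the patch gradient back onto the input layout
// [[Rcpp::export(name = ".cppCol2im")]]
Rcpp::NumericMatrix cppCol2im(const Rcpp::NumericMatrix& dXcol, int B,
                              int Tin, int Cin, int k) {
  const int Tout = Tin - k + 1;
  const int nOut = B * Tout;
  Rcpp::NumericMatrix dA(B * Tin, Cin);
  const double* d = dXcol.begin();
  double* o = dA.begin();
  for (int c = 0; c < Cin; ++c)
    for (int tau = 0; tau < k; ++tau) {
      const double* src = d + (c * k + tau) * nOut;
      double* dst = o + c * (B * Tin) + tau * B;
      for (int i = 0; i < nOut; ++i) dst[i] += src[i];
    }
  return dA;
}

// fused bias + ReLU: Z = max(Xcol W + b, 0) with negativity mask
// [[Rcpp::export(name = ".cppBiasRelu")]]
Rcpp::List cppBiasRelu(Rcpp::NumericMatrix Z, const Rcpp::NumericVector& b) {
  const int n = Z.nrow(), m = Z.ncol();
  Rcpp::LogicalMatrix neg(n, m);
  double* z = Z.begin();
  int* ng = neg.begin();
  for (int j = 0; j < m; ++j) {
    const double bj = b[j];
    for (int i = 0; i < n; ++i) {
      double v = z[j * n + i] + bj;
      if (v < 0) { z[j * n + i] = 0; ng[j * n + i] = 1; }
      else { z[j * n + i] = v; ng[j * n + i] = 0; }
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = Z, Rcpp::Named("neg") = neg);
}

// in-place SGD-with-momentum update on one parameter array:
// v <- mu v + g;  p <- p - lr v.  p and v are modified in place, so the
// training loop allocates nothing per step; callers must pass uniquely
// referenced arrays.
// [[Rcpp::export(name = ".cppSgdUpdate")]]
void cppSgdUpdate(Rcpp::NumericVector p, Rcpp::NumericVector v,
                  const Rcpp::NumericVector& g, double lr, double mu) {
  const R_xlen_t n = p.size();
  double* pp = p.begin();
  double* pv = v.begin();
  const double* pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pv[i] = mu * pv[i] + pg[i];
    pp[i] -= lr * pv[i];
  }
}
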