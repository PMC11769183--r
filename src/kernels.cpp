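// Hot inner loops of the neural-network engine: im2col gather / col2im
// scatter for the convolutions, the ELU nonlinearity, and the LSTM
// recurrence. Large dense products stay in R where they hit BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X: (B x M). idx: (P x K), 1-based column indices into X; an index of 0
// denotes an out-of-range (zero-padding) tap and yields zeros.
// Returns (B*P x K) with out[b + B*p, k] = X(b, idx(p, k) - 1).
// [[Rcpp::export]]
NumericMatrix cpp_gather_cols(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int B = X.nrow(), P = idx.nrow(), K = idx.ncol();
  NumericMatrix out(B * P, K);
  const double* xp = X.begin();
  double* op = out.begin();
  for (int k = 0; k < K; ++k) {
    double* ocol = op + (R_xlen_t)k * B * P;
    for (int p = 0; p < P; ++p) {
      const int j = idx(p, k);
      if (j == 0) continue;                 // NumericMatrix zero-initializes
      const double* xcol = xp + (R_xlen_t)(j - 1) * B;
      std::copy(xcol, xcol + B, ocol + (R_xlen_t)p * B);
    }
  }
  return out;
}

// Reverse of cpp_gather_cols: accumulate dcols (B*P x K) back into (B x M);
// zero indices (padding taps) are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_scatter_cols(const NumericMatrix& dcols, const IntegerMatrix& idx,
                               int M) {
  const int P = idx.nrow(), K = idx.ncol();
  const int B = dcols.nrow() / P;
  NumericMatrix out(B, M);
  const double* dp = dcols.begin();
  double* op = out.begin();
  for (int k = 0; k < K; ++k) {
    const double* dcol = dp + (R_xlen_t)k * B * P;
    for (int p = 0; p < P; ++p) {
      const int j = idx(p, k);
      if (j == 0) continue;
      double* ocol = op + (R_xlen_t)(j - 1) * B;
      const double* src = dcol + (R_xlen_t)p * B;
      for (int b = 0; b < B; ++b) ocol[b] += src[b];
    }
  }
  return out;
}

// Fused bias add + ELU over the (rows x C_out) output of a convolution GEMM.
// [[Rcpp::export]]
NumericMatrix cpp_bias_elu(const NumericMatrix& Y, const NumericVector& b) {
  const int n = Y.nrow(), C = Y.ncol();
  NumericMatrix out(n, C);
  for (int c = 0; c < C; ++c) {
    const double bc = b[c];
    const double* yc = Y.begin() + (R_xlen_t)c * n;
    double* oc = out.begin() + (R_xlen_t)c * n;
    for (int i = 0; i < n; ++i) {
      const double v = yc[i] + bc;
      oc[i] = v > 0 ? v : std::expm1(v);
    }
  }
  return out;
}

// ELU backward given only the activation output y (y > 0 iff input > 0).
// [[Rcpp::export]]
NumericVector cpp_elu_bwd_y(const NumericVector& y, const NumericVector& dout) {
  NumericVector d(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) {
    d[i] = y[i] > 0 ? dout[i] : dout[i] * (y[i] + 1.0);
  }
  d.attr("dim") = dout.attr("dim");
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_elu_fwd(const NumericVector& x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    y[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_elu_bwd(const NumericVector& x, const NumericVector& y,
                          const NumericVector& dout) {
  NumericVector d(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    d[i] = x[i] > 0 ? dout[i] : dout[i] * (y[i] + 1.0);
  }
  d.attr("dim") = dout.attr("dim");
  return d;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// LSTM forward recurrence. XW: (B, T, 4H) array of precomputed input
// projections; Wh: (H x 4H); b: length 4H. Gate order i, f, g, o.
// Returns the hidden sequence and every cached quantity the backward pass
// needs.
// [[Rcpp::export]]
List cpp_lstm_fwd(const NumericVector& XW, const NumericMatrix& Wh,
                  const NumericVector& b, int B, int Tn, int H) {
  const int G = 4 * H;
  arma::mat WhM(const_cast<double*>(Wh.begin()), H, G, false, true);
  NumericVector hs(B * Tn * H), Hprev(B * Tn * H), CS(B * Tn * H), TC(B * Tn * H);
  NumericVector GI(B * Tn * H), GF(B * Tn * H), GG(B * Tn * H), GO(B * Tn * H);
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat A(B, G);
  const double* xw = XW.begin();
  for (int t = 0; t < Tn; ++t) {
    A = h * WhM;
    // add input projection slice and bias; XW element (b, t, j) at b + B*t + B*Tn*j
    for (int j = 0; j < G; ++j) {
      const double* src = xw + (R_xlen_t)B * t + (R_xlen_t)B * Tn * j;
      double bj = b[j];
      double* acol = A.colptr(j);
      for (int bb = 0; bb < B; ++bb) acol[bb] += src[bb] + bj;
    }
    for (int j = 0; j < H; ++j) {
      const R_xlen_t off = (R_xlen_t)B * t + (R_xlen_t)B * Tn * j;
      double* gi = GI.begin() + off; double* gf = GF.begin() + off;
      double* gg = GG.begin() + off; double* go = GO.begin() + off;
      double* cs = CS.begin() + off; double* tc = TC.begin() + off;
      double* hp = Hprev.begin() + off; double* hso = hs.begin() + off;
      const double* ai = A.colptr(j); const double* af = A.colptr(H + j);
      const double* ag = A.colptr(2 * H + j); const double* ao = A.colptr(3 * H + j);
      double* hcol = h.colptr(j); double* ccol = c.colptr(j);
      for (int bb = 0; bb < B; ++bb) {
        double i_ = sigmoid(ai[bb]);
        double f_ = sigmoid(af[bb]);
        double g_ = std::tanh(ag[bb]);
        double o_ = sigmoid(ao[bb]);
        hp[bb] = hcol[bb];
        cs[bb] = ccol[bb];
        double cnew = f_ * ccol[bb] + i_ * g_;
        double tcv = std::tanh(cnew);
        ccol[bb] = cnew;
        hcol[bb] = o_ * tcv;
        hso[bb] = hcol[bb];
        gi[bb] = i_; gf[bb] = f_; gg[bb] = g_; go[bb] = o_; tc[bb] = tcv;
      }
    }
  }
  auto dims = IntegerVector::create(B, Tn, H);
  hs.attr("dim") = dims; Hprev.attr("dim") = dims; CS.attr("dim") = dims;
  TC.attr("dim") = dims; GI.attr("dim") = dims; GF.attr("dim") = dims;
  GG.attr("dim") = dims; GO.attr("dim") = dims;
  return List::create(_["hs"] = hs, _["Hprev"] = Hprev, _["CS"] = CS,
                      _["TC"] = TC, _["GI"] = GI, _["GF"] = GF,
                      _["GG"] = GG, _["GO"] = GO);
}

// LSTM backward recurrence. Returns dA over all timesteps (B, T, 4H); the
// caller turns it into parameter/input gradients with three BLAS products.
// [[Rcpp::export]]
NumericVector cpp_lstm_bwd(const NumericVector& dhs, const NumericMatrix& Wh,
                           const NumericVector& GI, const NumericVector& GF,
                           const NumericVector& GG, const NumericVector& GO,
                           const NumericVector& CS, const NumericVector& TC,
                           int B, int Tn, int H) {
  const int G = 4 * H;
  arma::mat WhT(const_cast<double*>(Wh.begin()), H, G, false, true);
  NumericVector dA_all(B * Tn * G);
  arma::mat dh(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
  arma::mat dA(B, G);
  for (int t = Tn - 1; t >= 0; --t) {
    for (int j = 0; j < H; ++j) {
      const R_xlen_t off = (R_xlen_t)B * t + (R_xlen_t)B * Tn * j;
      const double* gi = GI.begin() + off; const double* gf = GF.begin() + off;
      const double* gg = GG.begin() + off; const double* go = GO.begin() + off;
      const double* cs = CS.begin() + off; const double* tc = TC.begin() + off;
      const double* dhsp = dhs.begin() + off;
      double* dhcol = dh.colptr(j); double* dccol = dc.colptr(j);
      double* dai = dA.colptr(j); double* daf = dA.colptr(H + j);
      double* dag = dA.colptr(2 * H + j); double* dao = dA.colptr(3 * H + j);
      for (int bb = 0; bb < B; ++bb) {
        double dht = dhsp[bb] + dhcol[bb];
        double do_ = dht * tc[bb];
        double dct = dccol[bb] + dht * go[bb] * (1.0 - tc[bb] * tc[bb]);
        dai[bb] = (dct * gg[bb]) * gi[bb] * (1.0 - gi[bb]);
        daf[bb] = (dct * cs[bb]) * gf[bb] * (1.0 - gf[bb]);
        dag[bb] = (dct * gi[bb]) * (1.0 - gg[bb] * gg[bb]);
        dao[bb] = do_ * go[bb] * (1.0 - go[bb]);
        dccol[bb] = dct * gf[bb];
      }
    }
    dh = dA * WhT.t();
    for (int j = 0; j < G; ++j) {
      double* dst = dA_all.begin() + (R_xlen_t)B * t + (R_xlen_t)B * Tn * j;
      const double* src = dA.colptr(j);
      std::copy(src, src + B, dst);
    }
  }
  dA_all.attr("dim") = IntegerVector::create(B, Tn, G);
  return dA_all;
}
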