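// Hot numeric kernels for the 1-D CNN: same-padded convolution (im2col
// packing + BLAS matrix multiply) and non-overlapping max pooling, forward
// and backward. Tensors are R arrays (batch, width, channels) mapped onto
// arma::cube (rows, cols, slices).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pack A (B, Wd, Cin) into S (B*Wd, k*Cin): S[(w*B + b), (c*k + kk)] =
// A(b, w + kk - pl, c), zero outside. Columns of A are contiguous, so each
// (c, kk) pair is a single contiguous block copy.
static arma::mat im2col(const arma::cube& A, const int k) {
  const int B = A.n_rows, Wd = A.n_cols, Cin = A.n_slices;
  const int pl = (k - 1) / 2;
  arma::mat S(B * Wd, k * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    const arma::mat& Ac = A.slice(c);
    for (int kk = 0; kk < k; ++kk) {
      const int shift = kk - pl;
      const int lo = std::max(0, -shift);
      const int hi = std::min(Wd, Wd - shift);
      if (lo >= hi) continue;
      std::memcpy(S.colptr(c * k + kk) + lo * B,
                  Ac.colptr(lo + shift),
                  sizeof(double) * B * (hi - lo));
    }
  }
  return S;
}

// W3 (k, Cin, Cout) flattened to (k*Cin, Cout) with rows ordered (c*k + kk).
static arma::mat flattenW(const arma::cube& W3) {
  const int k = W3.n_rows, Cin = W3.n_cols, Cout = W3.n_slices;
  arma::mat Wm(k * Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kk = 0; kk < k; ++kk)
        Wm(c * k + kk, o) = W3(kk, c, o);
  return Wm;
}

// [[Rcpp::export(.conv1dForwardC)]]
arma::cube conv1dForwardC(const arma::cube& A, const arma::cube& W3,
                          const arma::vec& b) {
  const int B = A.n_rows, Wd = A.n_cols;
  const int k = W3.n_rows, Cout = W3.n_slices;
  arma::mat out2 = im2col(A, k) * flattenW(W3);
  out2.each_row() += b.t();
  arma::cube out(B, Wd, Cout);
  std::memcpy(out.memptr(), out2.memptr(), sizeof(double) * out2.n_elem);
  return out;
}

// [[Rcpp::export(.conv1dBackwardC)]]
List conv1dBackwardC(const arma::cube& A, const arma::cube& W3,
                     const arma::cube& dOut) {
  const int B = A.n_rows, Wd = A.n_cols, Cin = A.n_slices;
  const int k = W3.n_rows, Cout = W3.n_slices;
  const int pl = (k - 1) / 2;
  const arma::mat dOut2(const_cast<double*>(dOut.memptr()), B * Wd, Cout,
                        false, true);
  arma::mat S = im2col(A, k);
  arma::mat dW2 = S.t() * dOut2;               // (k*Cin, Cout)
  arma::mat dS = dOut2 * flattenW(W3).t();     // (B*Wd, k*Cin)
  arma::cube dW(k, Cin, Cout);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kk = 0; kk < k; ++kk)
        dW(kk, c, o) = dW2(c * k + kk, o);
  arma::vec db = arma::sum(dOut2, 0).t();
  // scatter-add dS blocks back onto the input grid (reverse of im2col)
  arma::cube dA(B, Wd, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    arma::mat& dAc = dA.slice(c);
    for (int kk = 0; kk < k; ++kk) {
      const int shift = kk - pl;
      const int lo = std::max(0, -shift);
      const int hi = std::min(Wd, Wd - shift);
      if (lo >= hi) continue;
      const arma::mat blk(const_cast<double*>(dS.colptr(c * k + kk)) + lo * B,
                          B, hi - lo, false, true);
      dAc.cols(lo + shift, hi - 1 + shift) += blk;
    }
  }
  return List::create(_["dA"] = dA, _["dW"] = dW, _["db"] = db);
}

// Non-overlapping max pool of window p along width; remainder columns are
// dropped. Returns the pooled cube and 1-based argmax offsets for routing
// gradients back.
// [[Rcpp::export(.poolForwardC)]]
List poolForwardC(const arma::cube& A, const int p) {
  const int B = A.n_rows, Wd = A.n_cols, C = A.n_slices;
  const int Wo = Wd / p;
  arma::cube out(B, Wo, C);
  arma::icube arg(B, Wo, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Ac = A.slice(c);
    arma::mat& Oc = out.slice(c);
    for (int j = 0; j < Wo; ++j) {
      const int base = j * p;
      for (int b = 0; b < B; ++b) {
        double mx = Ac(b, base);
        int am = 1;
        for (int q = 1; q < p; ++q) {
          const double v = Ac(b, base + q);
          if (v > mx) { mx = v; am = q + 1; }
        }
        Oc(b, j) = mx;
        arg(b, j, c) = am;
      }
    }
  }
  return List::create(_["out"] = out, _["arg"] = arg);
}

// [[Rcpp::export(.poolBackwardC)]]
arma::cube poolBackwardC(const arma::icube& arg, const arma::cube& dOut,
                         const int inWidth, const int p) {
  const int B = dOut.n_rows, Wo = dOut.n_cols, C = dOut.n_slices;
  arma::cube dA(B, inWidth, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& dOc = dOut.slice(c);
    arma::mat& dAc = dA.slice(c);
    for (int j = 0; j < Wo; ++j) {
      const int base = j * p;
      for (int b = 0; b < B; ++b)
        dAc(b, base + arg(b, j, c) - 1) = dOc(b, j);
    }
  }
  return dA;
}
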