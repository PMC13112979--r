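// Windowed multi-head self-attention inner loops. The R layer prepares the
// window-gathered qkv matrix, the relative-position bias and the additive
// attention mask; these kernels run the per-(window, sample, head) matrix
// products that dominate training time.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// qkvW: (nb*wsz2) x 3C, blocks of wsz2 rows ordered sample-fastest within
// window; bias: wsz2 x wsz2 x nh; mask: wsz2 x wsz2 x nw (or empty cube);
// returns the attention output rows (nb*wsz2 x C) and the softmax
// matrices A (wsz2 x wsz2 x (nh*nb)) needed for the backward pass.
// [[Rcpp::export(name = ".attnCoreForward")]]
List attnCoreForward(const arma::mat& qkvW, const arma::cube& bias,
                     const arma::cube& mask, int wsz2, int nh, int hd,
                     int N, double scale) {
  const int C = nh * hd;
  const int nb = qkvW.n_rows / wsz2;
  const bool hasMask = mask.n_elem > 0;
  arma::mat O(qkvW.n_rows, C, arma::fill::zeros);
  arma::cube A(wsz2, wsz2, nh * nb);
  for (int b = 0; b < nb; ++b) {
    const int r0 = b * wsz2;
    const int w = b / N;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * hd;
      arma::mat Q = qkvW.submat(r0, c0, r0 + wsz2 - 1, c0 + hd - 1);
      arma::mat K = qkvW.submat(r0, C + c0, r0 + wsz2 - 1, C + c0 + hd - 1);
      arma::mat V = qkvW.submat(r0, 2 * C + c0, r0 + wsz2 - 1,
                                2 * C + c0 + hd - 1);
      arma::mat S = Q * K.t() * scale + bias.slice(h);
      if (hasMask) S += mask.slice(w);
      // row-wise softmax
      arma::vec mx = arma::max(S, 1);
      S.each_col() -= mx;
      S = arma::exp(S);
      arma::vec rs = arma::sum(S, 1);
      S.each_col() /= rs;
      A.slice((size_t)b * nh + h) = S;
      O.submat(r0, c0, r0 + wsz2 - 1, c0 + hd - 1) = S * V;
    }
  }
  return List::create(_["O"] = O, _["A"] = A);
}

// Backward of the core: given dO (nb*wsz2 x C), the gathered qkvW and the
// stored softmax cube A, produce dqkvW and the accumulated bias gradient.
// [[Rcpp::export(name = ".attnCoreBackward")]]
List attnCoreBackward(const arma::mat& dO, const arma::mat& qkvW,
                      const arma::cube& A, int wsz2, int nh, int hd,
                      int N, double scale) {
  const int C = nh * hd;
  const int nb = dO.n_rows / wsz2;
  arma::mat dqkvW(dO.n_rows, 3 * C, arma::fill::zeros);
  arma::cube dBias(wsz2, wsz2, nh, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const int r0 = b * wsz2;
    for (int h = 0; h < nh; ++h) {
      const int c0 = h * hd;
      arma::mat Q = qkvW.submat(r0, c0, r0 + wsz2 - 1, c0 + hd - 1);
      arma::mat K = qkvW.submat(r0, C + c0, r0 + wsz2 - 1, C + c0 + hd - 1);
      arma::mat V = qkvW.submat(r0, 2 * C + c0, r0 + wsz2 - 1,
                                2 * C + c0 + hd - 1);
      const arma::mat& Ab = A.slice((size_t)b * nh + h);
      arma::mat dOb = dO.submat(r0, c0, r0 + wsz2 - 1, c0 + hd - 1);
      arma::mat dV = Ab.t() * dOb;
      arma::mat dA = dOb * V.t();
      arma::vec rowDot = arma::sum(Ab % dA, 1);
      dA.each_col() -= rowDot;
      arma::mat dS = Ab % dA;
      dBias.slice(h) += dS;
      dqkvW.submat(r0, c0, r0 + wsz2 - 1, c0 + hd - 1) = dS * K * scale;
      dqkvW.submat(r0, C + c0, r0 + wsz2 - 1, C + c0 + hd - 1) =
        dS.t() * Q * scale;
      dqkvW.submat(r0, 2 * C + c0, r0 + wsz2 - 1, 2 * C + c0 + hd - 1) = dV;
    }
  }
  return List::create(_["dqkvW"] = dqkvW, _["dBias"] = dBias);
}
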