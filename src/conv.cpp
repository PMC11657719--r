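// im2col convolution kernels. The batch layout matches the R side:
// feature maps are (npos * channels) x B matrices, spatial index fastest
// within a channel. idx is the precomputed patch x npos gather table of
// 1-based input rows (0 = zero padding).
//
// The im2col matrix (patch x npos*B) is by far the largest object in the
// training loop (hundreds of MB at batch 512), so it lives in grow-only
// scratch buffers that are reused across calls instead of being
// allocated per batch; the backward pass recomputes it from the cached
// layer input rather than keeping it alive between calls.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static std::vector<double> buf_m, buf_dyc, buf_dm;

static arma::mat borrow(std::vector<double>& buf, const arma::uword nr,
                        const arma::uword nc) {
  if (buf.size() < nr * nc) buf.resize(nr * nc);
  return arma::mat(buf.data(), nr, nc, false, true);
}

static void im2col(const arma::mat& X, const IntegerMatrix& idx,
                   arma::mat& M) {
  const int patch = idx.nrow(), npos = idx.ncol(), B = X.n_cols;
  for (int s = 0; s < B; ++s) {
    const double* xc = X.colptr(s);
    for (int p = 0; p < npos; ++p) {
      double* mc = M.colptr((arma::uword)s * npos + p);
      const int* ic = &idx(0, p);
      for (int r = 0; r < patch; ++r) {
        const int id = ic[r];
        mc[r] = id > 0 ? xc[id - 1] : 0.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".conv_fwd_cpp")]]
NumericMatrix conv_fwd_cpp(const arma::mat& X, const arma::mat& W,
                           const arma::vec& b, const IntegerMatrix& idx) {
  const int patch = idx.nrow(), npos = idx.ncol();
  const int B = X.n_cols, cout = W.n_rows;
  arma::mat M = borrow(buf_m, patch, (arma::uword)npos * B);
  im2col(X, idx, M);
  arma::mat Yc = W * M;  // cout x (npos*B)
  NumericMatrix Y((arma::uword)npos * cout, B);
  for (int s = 0; s < B; ++s) {
    double* yc = &Y(0, s);
    for (int p = 0; p < npos; ++p) {
      const double* src = Yc.colptr((arma::uword)s * npos + p);
      for (int c = 0; c < cout; ++c) yc[(arma::uword)c * npos + p] = src[c] + b[c];
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv_bwd_cpp")]]
List conv_bwd_cpp(const arma::mat& dY, const arma::mat& W,
                  const arma::mat& Xin, const IntegerMatrix& idx,
                  const bool need_dx) {
  const int patch = idx.nrow(), npos = idx.ncol();
  const int B = dY.n_cols, cout = W.n_rows;
  arma::mat M = borrow(buf_m, patch, (arma::uword)npos * B);
  im2col(Xin, idx, M);
  arma::mat dYc = borrow(buf_dyc, cout, (arma::uword)npos * B);
  for (int s = 0; s < B; ++s) {
    const double* dyc = dY.colptr(s);
    for (int p = 0; p < npos; ++p) {
      double* dst = dYc.colptr((arma::uword)s * npos + p);
      for (int c = 0; c < cout; ++c) dst[c] = dyc[(arma::uword)c * npos + p];
    }
  }
  arma::mat dW = dYc * M.t();
  arma::vec db = arma::sum(dYc, 1);
  arma::mat dX;
  if (need_dx) {
    arma::mat dM = borrow(buf_dm, patch, (arma::uword)npos * B);
    dM = W.t() * dYc;
    dX.zeros(Xin.n_rows, B);
    for (int s = 0; s < B; ++s) {
      double* dxc = dX.colptr(s);
      for (int p = 0; p < npos; ++p) {
        const double* dmc = dM.colptr((arma::uword)s * npos + p);
        const int* ic = &idx(0, p);
        for (int r = 0; r < patch; ++r) {
          const int id = ic[r];
          if (id > 0) dxc[id - 1] += dmc[r];
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
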