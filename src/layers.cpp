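// Fused batch normalization, in-place Adam, and FCGR counting kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Batch norm over (npos * ch) x B maps, population statistics per
// channel. In training mode returns the normalized activations and the
// caches needed for the backward pass, plus updated running statistics.

// [[Rcpp::export(name = ".bn_fwd_cpp")]]
List bn_fwd_cpp(const arma::mat& X, const arma::vec& gamma,
                const arma::vec& beta, const int npos, const int ch,
                const arma::vec& run_mean, const arma::vec& run_var,
                const bool train, const double momentum, const double eps) {
  const int B = X.n_cols;
  const double m = (double)npos * B;
  arma::vec mu(ch), var(ch);
  if (train) {
    arma::vec s1(ch, arma::fill::zeros), s2(ch, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      const double* xc = X.colptr(s);
      for (int c = 0; c < ch; ++c) {
        double a1 = 0.0, a2 = 0.0;
        const double* base = xc + (arma::uword)c * npos;
        for (int p = 0; p < npos; ++p) { a1 += base[p]; a2 += base[p] * base[p]; }
        s1[c] += a1; s2[c] += a2;
      }
    }
    mu = s1 / m;
    var = s2 / m - mu % mu;
    var.transform([](double x) { return x > 0.0 ? x : 0.0; });
  } else {
    mu = run_mean;
    var = run_var;
  }
  arma::vec inv_sd = 1.0 / arma::sqrt(var + eps);
  arma::mat Y(X.n_rows, B);
  arma::mat xhat;
  if (train) xhat.set_size(X.n_rows, B);
  for (int s = 0; s < B; ++s) {
    const double* xc = X.colptr(s);
    double* yc = Y.colptr(s);
    double* hc = train ? xhat.colptr(s) : nullptr;
    for (int c = 0; c < ch; ++c) {
      const double mc = mu[c], ic = inv_sd[c], gc = gamma[c], bc = beta[c];
      const arma::uword off = (arma::uword)c * npos;
      for (int p = 0; p < npos; ++p) {
        const double h = (xc[off + p] - mc) * ic;
        if (train) hc[off + p] = h;
        yc[off + p] = gc * h + bc;
      }
    }
  }
  if (train) {
    arma::vec nrm = (1.0 - momentum) * run_mean + momentum * mu;
    arma::vec nrv = (1.0 - momentum) * run_var + momentum * var;
    return List::create(_["Y"] = Y, _["xhat"] = xhat, _["inv_sd"] = inv_sd,
                        _["run_mean"] = nrm, _["run_var"] = nrv);
  }
  return List::create(_["Y"] = Y);
}

// [[Rcpp::export(name = ".bn_bwd_cpp")]]
List bn_bwd_cpp(const arma::mat& dY, const arma::mat& xhat,
                const arma::vec& inv_sd, const arma::vec& gamma,
                const int npos, const int ch) {
  const int B = dY.n_cols;
  const double m = (double)npos * B;
  arma::vec s1(ch, arma::fill::zeros), s2(ch, arma::fill::zeros);
  arma::vec dgamma(ch, arma::fill::zeros), dbeta(ch, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const double* dyc = dY.colptr(s);
    const double* hc = xhat.colptr(s);
    for (int c = 0; c < ch; ++c) {
      const arma::uword off = (arma::uword)c * npos;
      double a1 = 0.0, a2 = 0.0;
      for (int p = 0; p < npos; ++p) {
        a1 += dyc[off + p];
        a2 += dyc[off + p] * hc[off + p];
      }
      s1[c] += a1; s2[c] += a2;
    }
  }
  dbeta = s1;
  dgamma = s2;
  arma::mat dX(dY.n_rows, B);
  for (int s = 0; s < B; ++s) {
    const double* dyc = dY.colptr(s);
    const double* hc = xhat.colptr(s);
    double* dxc = dX.colptr(s);
    for (int c = 0; c < ch; ++c) {
      const double gc = gamma[c], ic = inv_sd[c];
      const double t1 = s1[c] / m, t2 = s2[c] / m;
      const arma::uword off = (arma::uword)c * npos;
      for (int p = 0; p < npos; ++p)
        dxc[off + p] = ic * (gc * dyc[off + p] - gc * t1 - gc * t2 * hc[off + p]);
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// In-place Adam update: params, m and v are modified directly (they are
// owned exclusively by the training loop).

// [[Rcpp::export(name = ".adam_step_cpp")]]
void adam_step_cpp(List params, List grads, List m, List v, const int t,
                   const double lr, const double wd, const double beta1,
                   const double beta2, const double eps) {
  const double bc1 = 1.0 - std::pow(beta1, t);
  const double bc2 = 1.0 - std::pow(beta2, t);
  for (int k = 0; k < params.size(); ++k) {
    NumericVector p = params[k];
    NumericVector g = grads[k];
    NumericVector mk = m[k];
    NumericVector vk = v[k];
    const R_xlen_t n = p.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = g[i] + wd * p[i];
      mk[i] = beta1 * mk[i] + (1.0 - beta1) * gi;
      vk[i] = beta2 * vk[i] + (1.0 - beta2) * gi * gi;
      p[i] -= lr * (mk[i] / bc1) / (std::sqrt(vk[i] / bc2) + eps);
    }
  }
}

// FCGR sliding-window counter. Returns the 2^k x 2^k count grid
// (column-major, row 0 = top of the image) and the number of windows
// counted; windows containing non-ACGT characters are skipped.

// [[Rcpp::export(name = ".fcgr_counts_cpp")]]
List fcgr_counts_cpp(const std::string& seq, const int k) {
  const int side = 1 << k;
  const int n = (int)seq.size();
  IntegerMatrix grid(side, side);
  int counted = 0;
  int col = 0, rowbits = 0, run = 0;  // run = current stretch of valid bases
  const int mask = side - 1;
  for (int i = 0; i < n; ++i) {
    int xb, yb, valid = 1;
    switch (seq[i]) {
      case 'A': case 'a': xb = 0; yb = 0; break;
      case 'C': case 'c': xb = 0; yb = 1; break;
      case 'G': case 'g': xb = 1; yb = 1; break;
      case 'T': case 't': xb = 1; yb = 0; break;
      default: xb = 0; yb = 0; valid = 0;
    }
    // the j-th character of a window contributes bit j-1; sliding the
    // window shifts previous bits down
    col = (col >> 1) | (xb << (k - 1));
    rowbits = (rowbits >> 1) | (yb << (k - 1));
    run = valid ? run + 1 : 0;
    if (run >= k) {
      const int row = mask - rowbits;
      grid(row, col) += 1;
      ++counted;
    }
  }
  return List::create(_["grid"] = grid, _["counted"] = counted);
}

// Substitution mutation with 2:1 transition:transversion weighting.
// Draws one uniform per position from the R RNG (matching the vectorized
// draw order, so results are reproducible under set.seed), leaving
// non-ACGT positions untouched.

// [[Rcpp::export(name = ".mutate_cpp")]]
std::string mutate_cpp(const std::string& seq, const double mu) {
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string out = seq;
  const int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    const double u = unif_rand();
    int code;
    switch (seq[i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default: continue;
    }
    if (u < mu) out[i] = BASES[(code + 2) % 4];                  // transition
    else if (u < 1.25 * mu) out[i] = BASES[(code + 1) % 4];      // transversion
    else if (u < 1.5 * mu) out[i] = BASES[(code + 3) % 4];       // transversion
  }
  return out;
}
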