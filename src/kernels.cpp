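// Hot numerical kernels for the 3D CNN.
//
// Layout contract (shared with R/nn.R): a sample volume is the column-major
// flattening of array(D, H, W, C) — voxel-fastest, channels blocked — and a
// batch is a matrix with one sample per column. im2col patch matrices are
// (fan x nout*B) with the output-position index fastest within a sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// gather im2col patches: off = patch-element offsets (0-based) into the
// padded sample, base = per-output-position base offsets (0-based)
// [[Rcpp::export]]
arma::mat cpp_im2col(const arma::mat& xp, const arma::ivec& off,
                     const arma::ivec& base) {
  const arma::uword fan = off.n_elem, nout = base.n_elem, B = xp.n_cols;
  arma::mat P(fan, nout * B);
  for (arma::uword b = 0; b < B; ++b) {
    const double* col = xp.colptr(b);
    for (arma::uword o = 0; o < nout; ++o) {
      double* dst = P.colptr(o + nout * b);
      const double* src = col + base[o];
      for (arma::uword e = 0; e < fan; ++e) dst[e] = src[off[e]];
    }
  }
  return P;
}

// scatter-accumulate col2im: inverse of cpp_im2col
// [[Rcpp::export]]
arma::mat cpp_col2im(const arma::mat& dP, const arma::ivec& off,
                     const arma::ivec& base, int npad) {
  const arma::uword fan = off.n_elem, nout = base.n_elem;
  const arma::uword B = dP.n_cols / nout;
  arma::mat dxp(npad, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    double* col = dxp.colptr(b);
    for (arma::uword o = 0; o < nout; ++o) {
      const double* src = dP.colptr(o + nout * b);
      double* dst = col + base[o];
      for (arma::uword e = 0; e < fan; ++e) dst[off[e]] += src[e];
    }
  }
  return dxp;
}

// (cout x nout*B) conv GEMM result -> (nout*cout x B) voxel-fastest layout
// [[Rcpp::export]]
arma::mat cpp_chw_to_hwc(const arma::mat& y, int nout_, int B_) {
  const arma::uword cout = y.n_rows, nout = nout_, B = B_;
  arma::mat out(nout * cout, B);
  for (arma::uword b = 0; b < B; ++b) {
    double* dst = out.colptr(b);
    for (arma::uword o = 0; o < nout; ++o) {
      const double* src = y.colptr(o + nout * b);
      for (arma::uword c = 0; c < cout; ++c) dst[o + c * nout] = src[c];
    }
  }
  return out;
}

// inverse of cpp_chw_to_hwc for the backward pass
// [[Rcpp::export]]
arma::mat cpp_hwc_to_chw(const arma::mat& dy, int nout_, int cout_) {
  const arma::uword nout = nout_, cout = cout_, B = dy.n_cols;
  arma::mat out(cout, nout * B);
  for (arma::uword b = 0; b < B; ++b) {
    const double* src = dy.colptr(b);
    for (arma::uword o = 0; o < nout; ++o) {
      double* dst = out.colptr(o + nout * b);
      for (arma::uword c = 0; c < cout; ++c) dst[c] = src[o + c * nout];
    }
  }
  return out;
}

// patches for output positions [o0, o1) of sample b into a preallocated
// buffer (fan x (o1 - o0))
static inline void im2col_chunk(const arma::mat& xp, const arma::ivec& off,
                                const arma::ivec& base, arma::uword b,
                                arma::uword o0, arma::uword o1,
                                arma::mat& P) {
  const arma::uword fan = off.n_elem;
  const double* col = xp.colptr(b);
  for (arma::uword o = o0; o < o1; ++o) {
    double* dst = P.colptr(o - o0);
    const double* src = col + base[o];
    for (arma::uword e = 0; e < fan; ++e) dst[e] = src[off[e]];
  }
}

// cache-blocked chunk width so the patch buffer stays near L2
static inline arma::uword conv_chunk(arma::uword fan) {
  arma::uword c = 262144 / (fan + 1);
  return c < 64 ? 64 : c;
}

// conv forward: blocked im2col + GEMM + layout transform; the patch matrix
// is never materialized whole, so memory stays bounded at any input size
// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& xp, const arma::mat& W,
                       const arma::vec& bias, const arma::ivec& off,
                       const arma::ivec& base) {
  const arma::uword fan = off.n_elem, nout = base.n_elem, B = xp.n_cols;
  const arma::uword cout = W.n_rows;
  const arma::uword chunk = conv_chunk(fan);
  arma::mat P(fan, std::min<arma::uword>(chunk, nout));
  arma::mat out(nout * cout, B);
  for (arma::uword b = 0; b < B; ++b) {
    double* dst = out.colptr(b);
    for (arma::uword o0 = 0; o0 < nout; o0 += chunk) {
      const arma::uword o1 = std::min(o0 + chunk, nout);
      im2col_chunk(xp, off, base, b, o0, o1, P);
      arma::mat y = W * P.cols(0, o1 - o0 - 1);
      y.each_col() += bias;
      for (arma::uword o = o0; o < o1; ++o) {
        const double* src = y.colptr(o - o0);
        for (arma::uword c = 0; c < cout; ++c) dst[o + c * nout] = src[c];
      }
    }
  }
  return out;
}

// conv backward: recomputes patch chunks from the cached layer input
// (cheaper than holding the full patch matrix), accumulating dW/db and,
// when needed, the padded input gradient
// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& xp, const arma::mat& dy,
                  const arma::mat& W, const arma::ivec& off,
                  const arma::ivec& base, bool need_dx) {
  const arma::uword fan = off.n_elem, nout = base.n_elem, B = xp.n_cols;
  const arma::uword cout = W.n_rows;
  const arma::uword chunk = conv_chunk(fan);
  arma::mat P(fan, std::min<arma::uword>(chunk, nout));
  arma::mat dyt(cout, std::min<arma::uword>(chunk, nout));
  arma::mat dW(cout, fan, arma::fill::zeros);
  arma::vec db(cout, arma::fill::zeros);
  arma::mat dxp;
  if (need_dx) dxp.zeros(xp.n_rows, B);
  for (arma::uword b = 0; b < B; ++b) {
    const double* dcol = dy.colptr(b);
    for (arma::uword o0 = 0; o0 < nout; o0 += chunk) {
      const arma::uword o1 = std::min(o0 + chunk, nout);
      const arma::uword w = o1 - o0;
      im2col_chunk(xp, off, base, b, o0, o1, P);
      for (arma::uword o = o0; o < o1; ++o) {
        double* dst = dyt.colptr(o - o0);
        for (arma::uword c = 0; c < cout; ++c) dst[c] = dcol[o + c * nout];
      }
      dW += dyt.cols(0, w - 1) * P.cols(0, w - 1).t();
      db += arma::sum(dyt.cols(0, w - 1), 1);
      if (need_dx) {
        arma::mat dP = W.t() * dyt.cols(0, w - 1);
        double* xcol = dxp.colptr(b);
        for (arma::uword o = o0; o < o1; ++o) {
          const double* src = dP.colptr(o - o0);
          double* dst = xcol + base[o];
          for (arma::uword e = 0; e < fan; ++e) dst[off[e]] += src[e];
        }
      }
    }
  }
  if (!need_dx) {
    return List::create(Named("dW") = dW, Named("db") = db);
  }
  return List::create(Named("dW") = dW, Named("db") = db,
                      Named("dxp") = dxp);
}

// max-pool forward over precomputed window offsets; returns pooled values
// and 1-based argmax element index within each window
// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& x, const arma::ivec& off,
                     const arma::ivec& base) {
  const arma::uword k3 = off.n_elem, nc = base.n_elem, B = x.n_cols;
  arma::mat y(nc, B);
  arma::imat wm(nc, B);
  for (arma::uword b = 0; b < B; ++b) {
    const double* col = x.colptr(b);
    for (arma::uword o = 0; o < nc; ++o) {
      const double* src = col + base[o];
      double best = src[off[0]];
      arma::uword arg = 0;
      for (arma::uword e = 1; e < k3; ++e) {
        const double v = src[off[e]];
        if (v > best) { best = v; arg = e; }
      }
      y(o, b) = best;
      wm(o, b) = static_cast<int>(arg) + 1;
    }
  }
  return List::create(Named("y") = y, Named("wm") = wm);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dy, const arma::imat& wm,
                          const arma::ivec& off, const arma::ivec& base,
                          int n_in) {
  const arma::uword nc = base.n_elem, B = dy.n_cols;
  arma::mat dx(n_in, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    double* col = dx.colptr(b);
    for (arma::uword o = 0; o < nc; ++o) {
      col[base[o] + off[wm(o, b) - 1]] += dy(o, b);
    }
  }
  return dx;
}

// global max over the first `nvox` stride of each channel block
// [[Rcpp::export]]
List cpp_globalmax_fwd(const arma::mat& x, int nvox_, int chans_) {
  const arma::uword nvox = nvox_, chans = chans_, B = x.n_cols;
  arma::mat y(chans, B);
  arma::imat wm(chans, B);
  for (arma::uword b = 0; b < B; ++b) {
    const double* col = x.colptr(b);
    for (arma::uword c = 0; c < chans; ++c) {
      const double* src = col + c * nvox;
      double best = src[0];
      arma::uword arg = 0;
      for (arma::uword v = 1; v < nvox; ++v) {
        if (src[v] > best) { best = src[v]; arg = v; }
      }
      y(c, b) = best;
      wm(c, b) = static_cast<int>(arg) + 1;
    }
  }
  return List::create(Named("y") = y, Named("wm") = wm);
}

// [[Rcpp::export]]
arma::mat cpp_globalmax_bwd(const arma::mat& dy, const arma::imat& wm,
                            int nvox_, int chans_) {
  const arma::uword nvox = nvox_, chans = chans_, B = dy.n_cols;
  arma::mat dx(nvox * chans, B, arma::fill::zeros);
  for (arma::uword b = 0; b < B; ++b) {
    double* col = dx.colptr(b);
    for (arma::uword c = 0; c < chans; ++c) {
      col[c * nvox + wm(c, b) - 1] = dy(c, b);
    }
  }
  return dx;
}
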