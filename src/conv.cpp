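// 2-D convolution primitives and the fused custom-WDSR forward/backward.
//
// Layout: an activation is stored as an (L*D) x C matrix whose column c is
// the vectorised L x D channel c (lateral lines L are the fast index).
// Kernels arrive flattened as (k*k*Cin) x Cout matrices so the convolution
// reduces to im2col + GEMM. Zero padding, stride 1, odd kernel size =>
// same-size outputs, which the masked loss relies on.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Unfold x ((L*D) x C) into an (L*D) x (k*k*C) matrix whose row p holds the
// zero-padded k x k receptive field of output position p. Output position is
// the fast (row) index so every copy below is contiguous.
template <typename MT>
static MT im2col_pad_t(const MT& x, const int k, const int L, const int D) {
  typedef typename MT::elem_type T;
  const int C = x.n_cols;
  const int p = (k - 1) / 2;
  MT cols(L * D, k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const T* xc = x.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        T* col = cols.colptr(c * k * k + dj * k + di);
        // output (i,j) reads input (i + di - p, j + dj - p)
        const int i0 = std::max(0, p - di);
        const int i1 = std::min(L, L + p - di);
        const int j0 = std::max(0, p - dj);
        const int j1 = std::min(D, D + p - dj);
        for (int j = j0; j < j1; ++j) {
          const T* src = xc + (size_t)(j + dj - p) * L + (i0 + di - p);
          std::copy(src, src + (i1 - i0), col + (size_t)j * L + i0);
        }
      }
    }
  }
  return cols;
}

// Scatter-add the unfolded matrix back onto an (L*D) x C activation
// (adjoint of im2col_pad); used for input gradients.
template <typename MT>
static MT col2im_pad_t(const MT& cols, const int k, const int L, const int D,
                       const int C) {
  typedef typename MT::elem_type T;
  const int p = (k - 1) / 2;
  MT x(L * D, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    T* xc = x.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const T* col = cols.colptr(c * k * k + dj * k + di);
        const int i0 = std::max(0, p - di);
        const int i1 = std::min(L, L + p - di);
        const int j0 = std::max(0, p - dj);
        const int j1 = std::min(D, D + p - dj);
        for (int j = j0; j < j1; ++j) {
          T* dst = xc + (size_t)(j + dj - p) * L + (i0 + di - p);
          const T* src = col + (size_t)j * L + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return x;
}

// Forward convolution on an L x D x C cube: y(.,.,o) = sum_c W[.,.,c,o] *
// x(.,.,c) + b[o] with W flattened to (k*k*Cin) x Cout. Exported for tests
// and generic use; the training loop uses the fused path below.
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& W,
                      const arma::vec& b, const int k) {
  const int L = x.n_rows, D = x.n_cols, C = x.n_slices;
  const mat xm((double*)x.memptr(), L * D, C, false);
  mat y = im2col_pad_t(xm, k, L, D) * W;  // (L*D) x Cout
  y.each_row() += b.t();
  return cube(y.memptr(), L, D, W.n_cols);
}

// Backward pass of conv2d_fwd: given upstream gradient gy (L x D x Cout),
// return gradients w.r.t. input, flattened weights and bias.
// [[Rcpp::export]]
Rcpp::List conv2d_bwd(const arma::cube& x, const arma::mat& W,
                      const arma::cube& gy, const int k) {
  const int L = x.n_rows, D = x.n_cols, C = x.n_slices;
  const mat xm((double*)x.memptr(), L * D, C, false);
  const mat gym((double*)gy.memptr(), L * D, gy.n_slices, false);
  mat cols = im2col_pad_t(xm, k, L, D);
  mat gW = cols.t() * gym;                          // (k*k*Cin) x Cout
  vec gb = sum(gym, 0).t();
  mat gxm = col2im_pad_t(mat(gym * W.t()), k, L, D, C);  // (L*D) x Cin
  cube gx(gxm.memptr(), L, D, C);
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                            Rcpp::Named("gb") = gb);
}

// ---------------------------------------------------------------------------
// Fused custom-WDSR pass.
//
// Canonical parameter order (effective, already weight-normalised, weights):
//   0                  head conv, 1 -> nf, kernel k
//   1 + 2*i            block i expand conv, nf -> nf*expansion, kernel k
//   2 + 2*i            block i contract conv, nf*expansion -> nf, kernel k
//   1 + 2*nblocks      tail conv, nf -> 1, kernel k
//   2 + 2*nblocks      global skip conv, 1 -> 1, kernel skip_k
//
// x0: normalised input (image - mean), vectorised L*D.
// y:  target on the original [0,1] scale, vectorised, only used when
//     loss_mask has entries; mean restores the output scale (denorm).
// loss_mask: per-pixel 0/1 weights (1 = pixel contributes to the loss).
//
// Returns yhat (denormalised prediction), the masked logarithmic loss
// sum(mask * log((|y - yhat| + eps) / kloss)), and, when want_grad, the
// gradients of that loss w.r.t. every effective weight matrix and bias.
// Internal arithmetic is single precision (the usual choice for training
// convolutional networks); inputs and outputs are double.
// [[Rcpp::export]]
Rcpp::List wdsr_pass(const arma::vec& x0, const int L, const int D,
                     const Rcpp::List& W, const Rcpp::List& b,
                     const Rcpp::IntegerVector& ksize, const int nblocks,
                     const double mean_shift, const arma::vec& y,
                     const arma::vec& loss_mask, const double eps,
                     const double kloss, const bool want_grad) {
  const int nconv = 3 + 2 * nblocks;
  std::vector<fmat> Wm(nconv);
  std::vector<frowvec> bv(nconv);
  for (int i = 0; i < nconv; ++i) {
    Wm[i] = conv_to<fmat>::from(Rcpp::as<mat>(W[i]));
    bv[i] = conv_to<frowvec>::from(Rcpp::as<rowvec>(b[i]));
  }
  const int k = ksize[0], sk = ksize[nconv - 1];
  const int tail = 1 + 2 * nblocks, skip = 2 + 2 * nblocks;

  const fmat x0m = conv_to<fmat>::from(x0);
  // forward, caching what the backward pass reuses
  fmat cols0 = im2col_pad_t(x0m, k, L, D);
  fmat h = cols0 * Wm[0];
  h.each_row() += bv[0];
  std::vector<fmat> cols1(nblocks), cols2(nblocks), relu_mask;
  if (want_grad) relu_mask.resize(nblocks);
  for (int i = 0; i < nblocks; ++i) {
    cols1[i] = im2col_pad_t(h, k, L, D);
    fmat t1 = cols1[i] * Wm[1 + 2 * i];
    t1.each_row() += bv[1 + 2 * i];
    if (want_grad) relu_mask[i] = conv_to<fmat>::from(t1 > 0.0f);
    t1.clamp(0.0f, std::numeric_limits<float>::max());
    cols2[i] = im2col_pad_t(t1, k, L, D);
    fmat t2 = cols2[i] * Wm[2 + 2 * i];
    t2.each_row() += bv[2 + 2 * i];
    h += t2;
  }
  fmat colsT = im2col_pad_t(h, k, L, D);
  fmat body = colsT * Wm[tail];
  body += bv[tail](0);
  fmat colsS = im2col_pad_t(x0m, sk, L, D);
  fmat yhatf = body + colsS * Wm[skip] + bv[skip](0) + (float)mean_shift;

  // masked logarithmic loss and its gradient w.r.t. yhat (double for the
  // reduction so the reported loss is stable)
  vec yhat = conv_to<vec>::from(yhatf.col(0));
  vec e = yhat - y;
  vec ae = abs(e) + eps;
  double loss = dot(loss_mask, log(ae / kloss));
  Rcpp::List out =
      Rcpp::List::create(Rcpp::Named("yhat") = yhat, Rcpp::Named("loss") = loss);
  if (!want_grad) return out;

  fmat gy(L * D, 1);
  gy.col(0) = conv_to<fvec>::from(loss_mask % sign(e) / ae);

  Rcpp::List gW(nconv), gb(nconv);
  // skip and tail branches both receive gy
  gW[skip] = Rcpp::wrap(conv_to<mat>::from(fmat(colsS.t() * gy)));
  gb[skip] = Rcpp::wrap(conv_to<vec>::from(fvec(sum(gy, 0).t())));
  gW[tail] = Rcpp::wrap(conv_to<mat>::from(fmat(colsT.t() * gy)));
  gb[tail] = Rcpp::wrap(conv_to<vec>::from(fvec(sum(gy, 0).t())));
  fmat gh =
      col2im_pad_t(fmat(gy * Wm[tail].t()), k, L, D, Wm[tail].n_rows / (k * k));
  for (int i = nblocks - 1; i >= 0; --i) {
    // h_out = h_in + contract(relu(expand(h_in)))
    const fmat& gt2 = gh;
    gW[2 + 2 * i] = Rcpp::wrap(conv_to<mat>::from(fmat(cols2[i].t() * gt2)));
    gb[2 + 2 * i] = Rcpp::wrap(conv_to<vec>::from(fvec(sum(gt2, 0).t())));
    fmat gt1 = col2im_pad_t(fmat(gt2 * Wm[2 + 2 * i].t()), k, L, D,
                            Wm[2 + 2 * i].n_rows / (k * k));
    gt1 %= relu_mask[i];
    gW[1 + 2 * i] = Rcpp::wrap(conv_to<mat>::from(fmat(cols1[i].t() * gt1)));
    gb[1 + 2 * i] = Rcpp::wrap(conv_to<vec>::from(fvec(sum(gt1, 0).t())));
    gh += col2im_pad_t(fmat(gt1 * Wm[1 + 2 * i].t()), k, L, D,
                       Wm[1 + 2 * i].n_rows / (k * k));
  }
  gW[0] = Rcpp::wrap(conv_to<mat>::from(fmat(cols0.t() * gh)));
  gb[0] = Rcpp::wrap(conv_to<vec>::from(fvec(sum(gh, 0).t())));
  out["gW"] = gW;
  out["gb"] = gb;
  return out;
}
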