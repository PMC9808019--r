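// Compact convolutional backbone for the MIL patch classifier.
//
// Layout conventions shared with the R wrappers (R/backbone.R):
//  - a batch of n images with C channels of size H x W travels as an
//    arma::cube of dims (H, W, C*n); sample i occupies slices [i*C, (i+1)*C)
//    and slice order within a sample is channel order. This matches
//    array(t(X), c(H, W, C*n)) for an n x (H*W*C) R matrix whose rows are
//    column-major flattened (H, W, C) arrays.
//  - conv weights are (9*Cin) x Cout matrices; row index = cin*9 +
//    (dy+1)*3 + (dx+1) for kernel offsets dy, dx in {-1, 0, 1}.
//  - all convolutions are 3x3, stride 1, zero padding 1 (shape preserving);
//    optional 2x2 max pooling (stride 2) follows a conv+ReLU block.
//
// Gradients are exact (verified against finite differences in the test
// suite); no randomness lives on the C++ side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// im2col for one sample: (H, W, C) cube -> (H*W) x (9*C) matrix.
static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& P = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const int col = c * 9 + (dy + 1) * 3 + (dx + 1);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(W, W - dx);
        if (y1 <= y0 || x1 <= x0) continue;
        mat shifted(H, W, fill::zeros);
        shifted.submat(y0, x0, y1 - 1, x1 - 1) =
            P.submat(y0 + dy, x0 + dx, y1 - 1 + dy, x1 - 1 + dx);
        out.col(col) = vectorise(shifted);
      }
    }
  }
  return out;
}

// adjoint of im2col3: scatter-add column gradients back onto the input.
static cube col2im3(const mat& dcols, int H, int W, int C) {
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        const int col = c * 9 + (dy + 1) * 3 + (dx_ + 1);
        const int y0 = std::max(0, -dy), y1 = std::min(H, H - dy);
        const int x0 = std::max(0, -dx_), x1 = std::min(W, W - dx_);
        if (y1 <= y0 || x1 <= x0) continue;
        mat dshift = reshape(dcols.col(col), H, W);
        dx.slice(c).submat(y0 + dy, x0 + dx_, y1 - 1 + dy, x1 - 1 + dx_) +=
            dshift.submat(y0, x0, y1 - 1, x1 - 1);
      }
    }
  }
  return dx;
}

// Runs the convolutional stack and global average pooling; the linear head
// (with feature normalisation) lives on the R side.
// [[Rcpp::export]]
List cnn_forward_cpp(const arma::cube& x, const List& conv_w,
                     const List& conv_b, const Rcpp::LogicalVector& pool,
                     int n_channels_in, bool want_cache) {
  const int L = conv_w.size();
  const int n = x.n_slices / n_channels_in;

  cube cur = x;
  int cin = n_channels_in;
  List inputs(L), relu_out(L), pool_idx(L);

  for (int l = 0; l < L; ++l) {
    const mat W = Rcpp::as<mat>(conv_w[l]);
    const vec b = Rcpp::as<vec>(conv_b[l]);
    const int cout = W.n_cols;
    const int H = cur.n_rows, Wd = cur.n_cols;
    if (want_cache) inputs[l] = cur;

    cube out(H, Wd, cout * n);
    // stack im2col blocks for all samples, then a single GEMM per layer
    mat M_all(n * H * Wd, 9 * cin);
    for (int i = 0; i < n; ++i)
      M_all.rows(i * H * Wd, (i + 1) * H * Wd - 1) =
          im2col3(cur.slices(i * cin, (i + 1) * cin - 1));
    mat O_all = M_all * W; // (n*H*W) x cout
    O_all.each_row() += b.t();
    for (int i = 0; i < n; ++i)
      for (int f = 0; f < cout; ++f)
        out.slice(i * cout + f) =
            reshape(O_all.col(f).subvec(i * H * Wd, (i + 1) * H * Wd - 1), H, Wd);
    out.transform([](double v) { return v > 0.0 ? v : 0.0; });  // ReLU
    if (want_cache) relu_out[l] = out;

    if (pool[l]) {
      const int Hp = H / 2, Wp = Wd / 2;
      cube pooled(Hp, Wp, cout * n);
      cube idx(Hp, Wp, cout * n);  // local argmax in {0,1,2,3} (col-major 2x2)
      for (unsigned s = 0; s < out.n_slices; ++s) {
        const mat& S = out.slice(s);
        for (int xx = 0; xx < Wp; ++xx) {
          for (int yy = 0; yy < Hp; ++yy) {
            double v00 = S(2 * yy, 2 * xx), v10 = S(2 * yy + 1, 2 * xx);
            double v01 = S(2 * yy, 2 * xx + 1), v11 = S(2 * yy + 1, 2 * xx + 1);
            double best = v00; int bi = 0;
            if (v10 > best) { best = v10; bi = 1; }
            if (v01 > best) { best = v01; bi = 2; }
            if (v11 > best) { best = v11; bi = 3; }
            pooled(yy, xx, s) = best;
            idx(yy, xx, s) = bi;
          }
        }
      }
      if (want_cache) pool_idx[l] = idx;
      cur = pooled;
    } else {
      cur = out;
    }
    cin = cout;
  }

  // global average pool -> feats (n x C_last)
  const int cl = cin, Hf = cur.n_rows, Wf = cur.n_cols;
  mat feats(n, cl);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < cl; ++c)
      feats(i, c) = accu(cur.slice(i * cl + c)) / double(Hf * Wf);

  List cache;
  if (want_cache) {
    cache = List::create(Named("inputs") = inputs, Named("relu_out") = relu_out,
                         Named("pool_idx") = pool_idx, Named("gap_in") = cur,
                         Named("n") = n, Named("cin") = n_channels_in);
  }
  return List::create(Named("feats") = feats, Named("cache") = cache);
}

// Backpropagates from gradients w.r.t. the pooled features through the
// convolutional stack.
// [[Rcpp::export]]
List cnn_backward_cpp(const List& conv_w, const Rcpp::LogicalVector& pool,
                      const List& cache, const arma::mat& dfeats) {
  const int L = conv_w.size();
  const List inputs = cache["inputs"];
  const List relu_out = cache["relu_out"];
  const List pool_idx = cache["pool_idx"];
  const cube gap_in = Rcpp::as<cube>(cache["gap_in"]);
  const int n = Rcpp::as<int>(cache["n"]);
  const int cin0 = Rcpp::as<int>(cache["cin"]);

  const int cl = gap_in.n_slices / n, Hf = gap_in.n_rows, Wf = gap_in.n_cols;
  cube dcur(Hf, Wf, gap_in.n_slices);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < cl; ++c)
      dcur.slice(i * cl + c).fill(dfeats(i, c) / double(Hf * Wf));

  List d_conv_w(L), d_conv_b(L);
  for (int l = L - 1; l >= 0; --l) {
    const mat W = Rcpp::as<mat>(conv_w[l]);
    const int cout = W.n_cols;
    const int cin = (l == 0) ? cin0 : Rcpp::as<mat>(conv_w[l - 1]).n_cols;
    const cube relu = Rcpp::as<cube>(relu_out[l]);
    const int H = relu.n_rows, Wd = relu.n_cols;

    cube dout(H, Wd, relu.n_slices, fill::zeros);
    if (pool[l]) {
      const cube idx = Rcpp::as<cube>(pool_idx[l]);
      const int Hp = dcur.n_rows, Wp = dcur.n_cols;
      for (unsigned s = 0; s < dout.n_slices; ++s)
        for (int xx = 0; xx < Wp; ++xx)
          for (int yy = 0; yy < Hp; ++yy) {
            const int bi = int(idx(yy, xx, s));
            dout(2 * yy + (bi % 2), 2 * xx + (bi / 2), s) += dcur(yy, xx, s);
          }
    } else {
      dout = dcur;
    }
    // ReLU mask
    for (unsigned s = 0; s < dout.n_slices; ++s)
      dout.slice(s) %= conv_to<mat>::from(relu.slice(s) > 0.0);

    const cube in = Rcpp::as<cube>(inputs[l]);
    cube din(in.n_rows, in.n_cols, in.n_slices);
    mat M_all(n * H * Wd, 9 * cin);
    mat dO_all(n * H * Wd, cout);
    for (int i = 0; i < n; ++i) {
      M_all.rows(i * H * Wd, (i + 1) * H * Wd - 1) =
          im2col3(in.slices(i * cin, (i + 1) * cin - 1));
      for (int f = 0; f < cout; ++f)
        dO_all.col(f).subvec(i * H * Wd, (i + 1) * H * Wd - 1) =
            vectorise(dout.slice(i * cout + f));
    }
    mat dW = M_all.t() * dO_all;
    vec db = sum(dO_all, 0).t();
    mat dM_all = dO_all * W.t();
    for (int i = 0; i < n; ++i) {
      cube dsub = col2im3(dM_all.rows(i * H * Wd, (i + 1) * H * Wd - 1),
                          in.n_rows, in.n_cols, cin);
      for (int c = 0; c < cin; ++c) din.slice(i * cin + c) = dsub.slice(c);
    }
    d_conv_w[l] = dW;
    d_conv_b[l] = db;
    dcur = din;
  }

  return List::create(Named("conv_w") = d_conv_w, Named("conv_b") = d_conv_b,
                      Named("dinput") = dcur);
}
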