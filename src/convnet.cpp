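// Compiled kernels for the small cleansing-score CNN:
//   conv 3x3 (same padding) -> ReLU -> 2x2 max pool, three blocks
//   (channels taken from the weight shapes), global average pooling,
//   dense 5-way head. Forward and batch-averaged gradients.
// Convolutions are im2col + GEMM in single precision; everything is
// deterministic (no threading, no RNG).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

// im2col for a 3x3 kernel, zero padding 1, stride 1: (H,W,C) -> (9C, HW)
fmat im2col3(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat col(9 * C, H * W, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const fmat& plane = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword r = c * 9 + (uword)((dy + 1) * 3 + (dx + 1));
        int i0 = std::max(0, -dy), i1 = std::min((int)H, (int)H - dy);
        int j0 = std::max(0, -dx), j1 = std::min((int)W, (int)W - dx);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            col(r, (uword)(j * (int)H + i)) =
              plane((uword)(i + dy), (uword)(j + dx));
      }
    }
  }
  return col;
}

// adjoint of im2col3: scatter (9C, HW) gradients back to (H,W,C)
void col2im3(const fmat& col, fcube& gx) {
  const uword H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  gx.zeros();
  for (uword c = 0; c < C; ++c) {
    fmat& plane = gx.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword r = c * 9 + (uword)((dy + 1) * 3 + (dx + 1));
        int i0 = std::max(0, -dy), i1 = std::min((int)H, (int)H - dy);
        int j0 = std::max(0, -dx), j1 = std::min((int)W, (int)W - dx);
        for (int j = j0; j < j1; ++j)
          for (int i = i0; i < i1; ++i)
            plane((uword)(i + dy), (uword)(j + dx)) +=
              col(r, (uword)(j * (int)H + i));
      }
    }
  }
}

// 2x2 max pool, stride 2; argmax linear index (into the input plane)
// recorded for the backward pass. First maximum wins on ties.
fcube maxpool2(const fcube& x, ucube& idx) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fcube out(H / 2, W / 2, C);
  idx.set_size(H / 2, W / 2, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W / 2; ++j)
      for (uword i = 0; i < H / 2; ++i) {
        uword bi = 2 * i, bj = 2 * j, best = bj * H + bi;
        float v = x(bi, bj, c);
        if (x(bi + 1, bj, c) > v) { v = x(bi + 1, bj, c); best = bj * H + bi + 1; }
        if (x(bi, bj + 1, c) > v) { v = x(bi, bj + 1, c); best = (bj + 1) * H + bi; }
        if (x(bi + 1, bj + 1, c) > v) { v = x(bi + 1, bj + 1, c); best = (bj + 1) * H + bi + 1; }
        out(i, j, c) = v;
        idx(i, j, c) = best;
      }
  return out;
}

struct Block {
  fmat col;    // im2col of the block input
  fmat z;      // post-ReLU activations (C_out x HW)
  fcube a;     // z reshaped to (H, W, C_out)
  fcube p;     // pooled output
  ucube pi;    // pool argmax
};

// one conv -> ReLU -> pool block
fcube block_fwd(const fcube& in, const fmat& W, const fvec& b, Block& cc) {
  const uword H = in.n_rows, Wd = in.n_cols, Cout = W.n_rows;
  cc.col = im2col3(in);
  cc.z = W * cc.col;
  cc.z.each_col() += b;
  cc.z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  cc.a.set_size(H, Wd, Cout);
  for (uword c = 0; c < Cout; ++c)
    cc.a.slice(c) = reshape(cc.z.row(c), H, Wd);
  cc.p = maxpool2(cc.a, cc.pi);
  return cc.p;
}

// backward through pool -> ReLU -> conv; returns gradient w.r.t. the
// block input and accumulates dW, db.
fcube block_bwd(const fcube& dp, const Block& cc, const fmat& W,
                fmat& dW, fvec& db, uword Hin, uword Win, uword Cin) {
  const uword Cout = W.n_rows, H = cc.a.n_rows, Wd = cc.a.n_cols;
  fmat dz(Cout, H * Wd, fill::zeros);
  for (uword c = 0; c < Cout; ++c)
    for (uword j = 0; j < Wd / 2; ++j)
      for (uword i = 0; i < H / 2; ++i) {
        uword k = cc.pi(i, j, c);
        if (cc.a.slice(c)(k) > 0.0f) dz(c, k) += dp(i, j, c);
      }
  dW += dz * cc.col.t();
  db += sum(dz, 1);
  fmat dcol = W.t() * dz;
  fcube din(Hin, Win, Cin);
  col2im3(dcol, din);
  return din;
}

struct Params {
  fmat W1, W2, W3, Wd;
  fvec b1, b2, b3, bd;
};

Params unpack(const Rcpp::List& params) {
  Params p;
  p.W1 = conv_to<fmat>::from(Rcpp::as<mat>(params["W1"]));
  p.b1 = conv_to<fvec>::from(Rcpp::as<vec>(params["b1"]));
  p.W2 = conv_to<fmat>::from(Rcpp::as<mat>(params["W2"]));
  p.b2 = conv_to<fvec>::from(Rcpp::as<vec>(params["b2"]));
  p.W3 = conv_to<fmat>::from(Rcpp::as<mat>(params["W3"]));
  p.b3 = conv_to<fvec>::from(Rcpp::as<vec>(params["b3"]));
  p.Wd = conv_to<fmat>::from(Rcpp::as<mat>(params["Wd"]));
  p.bd = conv_to<fvec>::from(Rcpp::as<vec>(params["bd"]));
  return p;
}

}  // namespace

// Forward (and optionally backward) pass over a batch.
// x: H x W x C x B array of channel stacks; y: 5 x B soft targets (may
// be empty when only probabilities are needed). Returns softmax
// probabilities, mean cross-entropy loss, and batch-averaged gradients.
// [[Rcpp::export(name = ".cnn_pass")]]
Rcpp::List cnn_pass(Rcpp::List params, Rcpp::NumericVector x,
                    Rcpp::NumericMatrix y, bool want_grad) {
  Rcpp::IntegerVector xd = x.attr("dim");
  if (xd.size() != 4) Rcpp::stop("x must be a 4-d array (H, W, C, B)");
  const uword H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  if (H % 8 != 0 || W % 8 != 0)
    Rcpp::stop("frame side must be divisible by 8");
  Params pp = unpack(params);
  if (pp.W1.n_cols != 9 * C) Rcpp::stop("input channel count does not match model");
  const uword C1 = pp.W1.n_rows, C2 = pp.W2.n_rows, C3 = pp.W3.n_rows;
  const bool have_y = y.nrow() == 5 && (uword)y.ncol() == B;
  if (want_grad && !have_y) Rcpp::stop("gradients need 5 x B targets");

  fmat gW1(size(pp.W1), fill::zeros), gW2(size(pp.W2), fill::zeros),
       gW3(size(pp.W3), fill::zeros), gWd(size(pp.Wd), fill::zeros);
  fvec gb1(C1, fill::zeros), gb2(C2, fill::zeros), gb3(C3, fill::zeros),
       gbd(5, fill::zeros);
  Rcpp::NumericMatrix probs(5, B);
  double loss = 0.0;
  const double* xptr = x.begin();
  const uword plane = H * W, per = plane * C;

  for (uword s = 0; s < B; ++s) {
    fcube x0(H, W, C);
    for (uword c = 0; c < C; ++c)
      for (uword k = 0; k < plane; ++k)
        x0.slice(c)(k) = (float)xptr[s * per + c * plane + k];

    Block c1, c2, c3;
    fcube p1 = block_fwd(x0, pp.W1, pp.b1, c1);
    fcube p2 = block_fwd(p1, pp.W2, pp.b2, c2);
    fcube p3 = block_fwd(p2, pp.W3, pp.b3, c3);
    const float npool = (float)(p3.n_rows * p3.n_cols);
    fvec feat(C3);
    for (uword c = 0; c < C3; ++c) feat(c) = accu(p3.slice(c)) / npool;
    fvec logits = pp.Wd * feat + pp.bd;
    fvec pr = exp(logits - logits.max());
    pr /= accu(pr);
    for (uword k = 0; k < 5; ++k) probs(k, s) = pr(k);

    if (have_y) {
      for (uword k = 0; k < 5; ++k)
        if (y(k, s) > 0)
          loss -= y(k, s) * std::log(std::max(pr(k), 1e-12f));
    }
    if (!want_grad) continue;

    fvec dl = pr;
    for (uword k = 0; k < 5; ++k) dl(k) -= (float)y(k, s);
    gWd += dl * feat.t();
    gbd += dl;
    fvec dfeat = pp.Wd.t() * dl;
    fcube dp3(p3.n_rows, p3.n_cols, C3);
    for (uword c = 0; c < C3; ++c) dp3.slice(c).fill(dfeat(c) / npool);
    fcube dp2 = block_bwd(dp3, c3, pp.W3, gW3, gb3, p2.n_rows, p2.n_cols, C2);
    fcube dp1 = block_bwd(dp2, c2, pp.W2, gW2, gb2, p1.n_rows, p1.n_cols, C1);
    fcube dx  = block_bwd(dp1, c1, pp.W1, gW1, gb1, H, W, C);
    (void)dx;
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("probs") = probs,
    Rcpp::Named("loss") = have_y ? loss / (double)B : NA_REAL
  );
  if (want_grad) {
    const float inv = 1.0f / (float)B;
    out["grads"] = Rcpp::List::create(
      Rcpp::Named("W1") = conv_to<mat>::from(gW1 * inv),
      Rcpp::Named("b1") = conv_to<vec>::from(gb1 * inv),
      Rcpp::Named("W2") = conv_to<mat>::from(gW2 * inv),
      Rcpp::Named("b2") = conv_to<vec>::from(gb2 * inv),
      Rcpp::Named("W3") = conv_to<mat>::from(gW3 * inv),
      Rcpp::Named("b3") = conv_to<vec>::from(gb3 * inv),
      Rcpp::Named("Wd") = conv_to<mat>::from(gWd * inv),
      Rcpp::Named("bd") = conv_to<vec>::from(gbd * inv)
    );
  }
  return out;
}
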