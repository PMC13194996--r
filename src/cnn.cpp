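// 1-D convolutional speech-state classifier: forward, backward, Adam loop.
// Architecture is fixed (stem k15/s4/32; three conv blocks k7/k5/k5 with
// out channels 64/128/256, max-pool stride 2 and dropout after each pool;
// global average pooling; single logit). Convolutions use "same" padding;
// all heavy lifting is im2col + BLAS GEMM in double precision.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <algorithm>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

namespace {

struct Params {
  mat W0; vec b0;    // stem: (32, C*15)
  mat W1; vec b1;    // block1: (64, 32*7)
  mat W2; vec b2;    // block2: (128, 64*5)
  mat W3; vec b3;    // block3: (256, 128*5)
  vec w4; double b4; // head: (256)
};

Params params_from_list(const List& p) {
  Params q;
  q.W0 = Rcpp::as<mat>(p["W0"]); q.b0 = Rcpp::as<vec>(p["b0"]);
  q.W1 = Rcpp::as<mat>(p["W1"]); q.b1 = Rcpp::as<vec>(p["b1"]);
  q.W2 = Rcpp::as<mat>(p["W2"]); q.b2 = Rcpp::as<vec>(p["b2"]);
  q.W3 = Rcpp::as<mat>(p["W3"]); q.b3 = Rcpp::as<vec>(p["b3"]);
  q.w4 = Rcpp::as<vec>(p["w4"]); q.b4 = Rcpp::as<double>(p["b4"]);
  return q;
}

List params_to_list(const Params& q) {
  return List::create(
    Named("W0") = q.W0, Named("b0") = q.b0,
    Named("W1") = q.W1, Named("b1") = q.b1,
    Named("W2") = q.W2, Named("b2") = q.b2,
    Named("W3") = q.W3, Named("b3") = q.b3,
    Named("w4") = q.w4, Named("b4") = q.b4);
}

// Temporal lengths through the network for an input of T samples.
// The same-padded stride-4 stem gives ceil(T/4); each kernel-2/stride-2
// pool gives floor(L/2).
void length_trace_(int T, int& L0, int& L1, int& L2, int& L3) {
  L0 = (T + 3) / 4;
  L1 = L0 / 2;
  L2 = L1 / 2;
  L3 = L2 / 2;
}

mat relu(const mat& Z) {
  mat A = Z;
  A.elem(find(A < 0)).zeros();
  return A;
}

// Gather a same-padded 1-D convolution input into column form.
// A is (Cin, Lin*B), column index b*Lin + t; result (Cin*k, Lout*B).
mat im2col(const mat& A, int Cin, int Lin, int B, int k, int stride,
           int pad_l, int Lout) {
  mat M(Cin * k, (uword)Lout * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lout; ++l) {
      const uword col = (uword)b * Lout + l;
      for (int j = 0; j < k; ++j) {
        const int t = l * stride + j - pad_l;
        if (t >= 0 && t < Lin)
          M.submat(j * Cin, col, (j + 1) * Cin - 1, col) =
            A.col((uword)b * Lin + t);
      }
    }
  return M;
}

// Scatter-add of im2col gradients back onto the input.
mat col2im(const mat& dM, int Cin, int Lin, int B, int k, int stride,
           int pad_l, int Lout) {
  mat dA(Cin, (uword)Lin * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lout; ++l) {
      const uword col = (uword)b * Lout + l;
      for (int j = 0; j < k; ++j) {
        const int t = l * stride + j - pad_l;
        if (t >= 0 && t < Lin)
          dA.col((uword)b * Lin + t) +=
            dM.submat(j * Cin, col, (j + 1) * Cin - 1, col);
      }
    }
  return dA;
}

// Max-pool kernel 2 stride 2 over the temporal axis of (Cc, Lin*B); an odd
// trailing position is dropped. Records the argmax for the backward pass.
mat maxpool_forward(const mat& A, int Cc, int Lin, int B, int Lout,
                    umat& argfirst) {
  mat P(Cc, (uword)Lout * B);
  argfirst.set_size(Cc, (uword)Lout * B);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lout; ++l) {
      const uword c1 = (uword)b * Lin + 2 * l;
      const uword out = (uword)b * Lout + l;
      for (int c = 0; c < Cc; ++c) {
        const double a1 = A(c, c1), a2 = A(c, c1 + 1);
        const bool first = a1 >= a2;  // ties resolve to the earlier sample
        P(c, out) = first ? a1 : a2;
        argfirst(c, out) = first ? 1u : 0u;
      }
    }
  return P;
}

mat maxpool_backward(const mat& dP, const umat& argfirst, int Cc, int Lin,
                     int B, int Lout) {
  mat dA(Cc, (uword)Lin * B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int l = 0; l < Lout; ++l) {
      const uword c1 = (uword)b * Lin + 2 * l;
      const uword out = (uword)b * Lout + l;
      for (int c = 0; c < Cc; ++c)
        dA(c, argfirst(c, out) ? c1 : c1 + 1) += dP(c, out);
    }
  return dA;
}

struct FwdCache {
  mat M0, M1, M2, M3;      // im2col matrices
  mat Z0, Z1, Z2, Z3;      // pre-activations
  mat P1, P2, P3;          // post pool (+ dropout) activations
  umat m1, m2, m3;         // pool argmax flags
  mat d1, d2, d3;          // dropout masks (empty in eval mode)
  mat H;                   // pooled features (256, B)
  vec logits;
  int C, T, B, L0, L1, L2, L3, pad0;
};

// Full forward pass. X arrives as (C, T*B) with column index b*T + t.
void forward(const Params& p, const mat& X, int C, int T, int B,
             bool training, double dropout, std::mt19937_64* rng,
             FwdCache& f, bool keep_cache) {
  length_trace_(T, f.L0, f.L1, f.L2, f.L3);
  if (f.L3 < 1)
    stop("input of %d samples is too short for the pooling cascade", T);
  f.C = C; f.T = T; f.B = B;
  f.pad0 = ((f.L0 - 1) * 4 + 15 - T) / 2;

  std::uniform_real_distribution<double> unif(0.0, 1.0);
  auto make_drop = [&](mat& mask, uword nr, uword nc) {
    mask.set_size(nr, nc);
    const double keep = 1.0 - dropout;
    for (uword j = 0; j < nc; ++j)
      for (uword i = 0; i < nr; ++i)
        mask(i, j) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
  };

  mat M0 = im2col(X, C, T, B, 15, 4, f.pad0, f.L0);
  mat Z0 = p.W0 * M0; Z0.each_col() += p.b0;
  mat A1 = relu(Z0);

  mat M1 = im2col(A1, 32, f.L0, B, 7, 1, 3, f.L0);
  mat Z1 = p.W1 * M1; Z1.each_col() += p.b1;
  mat A2 = relu(Z1);
  mat P1 = maxpool_forward(A2, 64, f.L0, B, f.L1, f.m1);
  if (training && dropout > 0) { make_drop(f.d1, P1.n_rows, P1.n_cols); P1 %= f.d1; }

  mat M2 = im2col(P1, 64, f.L1, B, 5, 1, 2, f.L1);
  mat Z2 = p.W2 * M2; Z2.each_col() += p.b2;
  mat A3 = relu(Z2);
  mat P2 = maxpool_forward(A3, 128, f.L1, B, f.L2, f.m2);
  if (training && dropout > 0) { make_drop(f.d2, P2.n_rows, P2.n_cols); P2 %= f.d2; }

  mat M3 = im2col(P2, 128, f.L2, B, 5, 1, 2, f.L2);
  mat Z3 = p.W3 * M3; Z3.each_col() += p.b3;
  mat A4 = relu(Z3);
  mat P3 = maxpool_forward(A4, 256, f.L2, B, f.L3, f.m3);
  if (training && dropout > 0) { make_drop(f.d3, P3.n_rows, P3.n_cols); P3 %= f.d3; }

  f.H.set_size(256, B);
  for (int b = 0; b < B; ++b)
    f.H.col(b) = mean(P3.cols((uword)b * f.L3, (uword)(b + 1) * f.L3 - 1), 1);
  f.logits = f.H.t() * p.w4 + p.b4;

  if (keep_cache) {
    f.M0 = std::move(M0); f.M1 = std::move(M1);
    f.M2 = std::move(M2); f.M3 = std::move(M3);
    f.Z0 = std::move(Z0); f.Z1 = std::move(Z1);
    f.Z2 = std::move(Z2); f.Z3 = std::move(Z3);
    f.P1 = std::move(P1); f.P2 = std::move(P2); f.P3 = std::move(P3);
  }
}

// Numerically stable binary cross-entropy with logits.
vec bce_losses(const vec& z, const vec& y) {
  vec zp = z; zp.elem(find(zp < 0)).zeros();
  return zp - z % y + log(1.0 + exp(-abs(z)));
}

struct Grads {
  Params g;
  mat dX;  // (C, T*B), filled only on request
};

// Backward pass. `scale` multiplies the per-sample dlogit (1/B for a mean
// loss, 1 for per-sample losses as used by the saliency map).
void backward(const Params& p, const FwdCache& f, const vec& y, double scale,
              bool want_input_grad, bool training, Grads& out) {
  const int B = f.B;
  vec dz = (1.0 / (1.0 + exp(-f.logits)) - y) * scale;

  out.g.w4 = f.H * dz;
  out.g.b4 = accu(dz);
  mat dH = p.w4 * dz.t();              // (256, B)

  mat dP3(256, (uword)f.L3 * B);
  for (int b = 0; b < B; ++b)
    dP3.cols((uword)b * f.L3, (uword)(b + 1) * f.L3 - 1) =
      repmat(dH.col(b) / f.L3, 1, f.L3);
  if (training && !f.d3.is_empty()) dP3 %= f.d3;

  mat dA4 = maxpool_backward(dP3, f.m3, 256, f.L2, B, f.L3);
  dA4 %= conv_to<mat>::from(f.Z3 > 0);
  out.g.W3 = dA4 * f.M3.t();
  out.g.b3 = sum(dA4, 1);
  mat dP2 = col2im(p.W3.t() * dA4, 128, f.L2, B, 5, 1, 2, f.L2);
  if (training && !f.d2.is_empty()) dP2 %= f.d2;

  mat dA3 = maxpool_backward(dP2, f.m2, 128, f.L1, B, f.L2);
  dA3 %= conv_to<mat>::from(f.Z2 > 0);
  out.g.W2 = dA3 * f.M2.t();
  out.g.b2 = sum(dA3, 1);
  mat dP1 = col2im(p.W2.t() * dA3, 64, f.L1, B, 5, 1, 2, f.L1);
  if (training && !f.d1.is_empty()) dP1 %= f.d1;

  mat dA2 = maxpool_backward(dP1, f.m1, 64, f.L0, B, f.L1);
  dA2 %= conv_to<mat>::from(f.Z1 > 0);
  out.g.W1 = dA2 * f.M1.t();
  out.g.b1 = sum(dA2, 1);
  mat dA1 = col2im(p.W1.t() * dA2, 32, f.L0, B, 7, 1, 3, f.L0);

  dA1 %= conv_to<mat>::from(f.Z0 > 0);
  out.g.W0 = dA1 * f.M0.t();
  out.g.b0 = sum(dA1, 1);
  if (want_input_grad)
    out.dX = col2im(p.W0.t() * dA1, f.C, f.T, B, 15, 4, f.pad0, f.L0);
}

// Reshape an R (C, T, B) cube into the internal (C, T*B) layout.
mat cube_to_wide(const cube& X) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  mat A(C, T * B);
  for (uword b = 0; b < B; ++b) A.cols(b * T, (b + 1) * T - 1) = X.slice(b);
  return A;
}

struct AdamState {
  Params m, v;
  int t = 0;
  explicit AdamState(const Params& p) {
    auto zero_like = [](const mat& x) { return mat(x.n_rows, x.n_cols, fill::zeros); };
    m.W0 = zero_like(p.W0); m.b0 = vec(p.b0.n_elem, fill::zeros);
    m.W1 = zero_like(p.W1); m.b1 = vec(p.b1.n_elem, fill::zeros);
    m.W2 = zero_like(p.W2); m.b2 = vec(p.b2.n_elem, fill::zeros);
    m.W3 = zero_like(p.W3); m.b3 = vec(p.b3.n_elem, fill::zeros);
    m.w4 = vec(p.w4.n_elem, fill::zeros); m.b4 = 0.0;
    v = m;
  }
};

template <typename M>
void adam_update_one(M& theta, const M& grad, M& m, M& v, double lr,
                     double b1, double b2, double eps, double wd, int t) {
  M g = grad + wd * theta;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
  theta -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

void adam_update_scalar(double& theta, double grad, double& m, double& v,
                        double lr, double b1, double b2, double eps,
                        double wd, int t) {
  const double g = grad + wd * theta;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * g * g;
  const double bc1 = 1 - std::pow(b1, t), bc2 = 1 - std::pow(b2, t);
  theta -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
}

void adam_step(Params& p, const Params& g, AdamState& s, double lr,
               double b1, double b2, double eps, double wd) {
  ++s.t;
  adam_update_one(p.W0, g.W0, s.m.W0, s.v.W0, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.b0, g.b0, s.m.b0, s.v.b0, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.W1, g.W1, s.m.W1, s.v.W1, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.b1, g.b1, s.m.b1, s.v.b1, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.W2, g.W2, s.m.W2, s.v.W2, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.b2, g.b2, s.m.b2, s.v.b2, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.W3, g.W3, s.m.W3, s.v.W3, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.b3, g.b3, s.m.b3, s.v.b3, lr, b1, b2, eps, wd, s.t);
  adam_update_one(p.w4, g.w4, s.m.w4, s.v.w4, lr, b1, b2, eps, wd, s.t);
  adam_update_scalar(p.b4, g.b4, s.m.b4, s.v.b4, lr, b1, b2, eps, wd, s.t);
}

// Evaluation-mode loss and accuracy over a dataset, in chunks.
void eval_dataset(const Params& p, const cube& X, const vec& y, int chunk,
                  double& loss, double& acc) {
  const int C = X.n_rows, T = X.n_cols, n = X.n_slices;
  double lsum = 0; int ncorrect = 0;
  for (int start = 0; start < n; start += chunk) {
    const int end = std::min(n - 1, start + chunk - 1);
    const int B = end - start + 1;
    mat A(C, (uword)T * B);
    for (int b = 0; b < B; ++b)
      A.cols((uword)b * T, (uword)(b + 1) * T - 1) = X.slice(start + b);
    FwdCache f;
    forward(p, A, C, T, B, false, 0.0, nullptr, f, false);
    vec ysub = y.subvec(start, end);
    lsum += accu(bce_losses(f.logits, ysub));
    ncorrect += accu((f.logits >= 0) == (ysub >= 0.5));
  }
  loss = lsum / n;
  acc = (double)ncorrect / n;
}

} // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector cnn_length_trace(int T) {
  int L0, L1, L2, L3;
  length_trace_(T, L0, L1, L2, L3);
  return Rcpp::IntegerVector::create(L0, L1, L2, L3);
}

// He-normal initialization of all weights, seeded and platform-stable.
// [[Rcpp::export]]
List cnn_init_params(int C, int seed) {
  if (C < 1) stop("channel count must be >= 1");
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  auto he = [&](int rows, int cols, int fan_in) {
    mat W(rows, cols);
    const double sd = std::sqrt(2.0 / fan_in);
    for (uword j = 0; j < W.n_cols; ++j)
      for (uword i = 0; i < W.n_rows; ++i) W(i, j) = sd * gauss(rng);
    return W;
  };
  Params p;
  p.W0 = he(32, C * 15, C * 15);   p.b0 = vec(32, fill::zeros);
  p.W1 = he(64, 32 * 7, 32 * 7);   p.b1 = vec(64, fill::zeros);
  p.W2 = he(128, 64 * 5, 64 * 5);  p.b2 = vec(128, fill::zeros);
  p.W3 = he(256, 128 * 5, 128 * 5); p.b3 = vec(256, fill::zeros);
  p.w4 = he(256, 1, 256).col(0);   p.b4 = 0.0;
  return params_to_list(p);
}

// Evaluation-mode class probabilities for a (C, T, B) batch.
// [[Rcpp::export]]
arma::vec cnn_forward_prob(List params, arma::cube X, int chunk = 512) {
  Params p = params_from_list(params);
  const int C = X.n_rows, T = X.n_cols, n = X.n_slices;
  if ((int)p.W0.n_cols != C * 15)
    stop("model was built for %d channels, got %d", (int)p.W0.n_cols / 15, C);
  vec out(n);
  for (int start = 0; start < n; start += chunk) {
    const int end = std::min(n - 1, start + chunk - 1);
    const int B = end - start + 1;
    mat A(C, (uword)T * B);
    for (int b = 0; b < B; ++b)
      A.cols((uword)b * T, (uword)(b + 1) * T - 1) = X.slice(start + b);
    FwdCache f;
    forward(p, A, C, T, B, false, 0.0, nullptr, f, false);
    out.subvec(start, end) = 1.0 / (1.0 + exp(-f.logits));
  }
  return out;
}

// Mean (or per-sample) evaluation-mode BCE loss; the finite-difference
// oracle in the test-suite drives this.
// [[Rcpp::export]]
Rcpp::NumericVector cnn_loss(List params, arma::cube X, arma::vec y,
                             std::string reduction = "mean") {
  Params p = params_from_list(params);
  mat A = cube_to_wide(X);
  FwdCache f;
  forward(p, A, X.n_rows, X.n_cols, X.n_slices, false, 0.0, nullptr, f, false);
  vec losses = bce_losses(f.logits, y);
  if (reduction == "mean")
    return Rcpp::NumericVector::create(mean(losses));
  return Rcpp::wrap(losses);
}

// Gradient of the *per-sample* loss with respect to the input, (C, T, B).
// Each slice receives the gradient of its own segment's loss (evaluation
// mode, dropout off), as required by the saliency map.
// [[Rcpp::export]]
arma::cube cnn_input_grad(List params, arma::cube X, arma::vec y) {
  Params p = params_from_list(params);
  const int C = X.n_rows, T = X.n_cols, n = X.n_slices;
  cube out(C, T, n);
  const int chunk = 256;
  for (int start = 0; start < n; start += chunk) {
    const int end = std::min(n - 1, start + chunk - 1);
    const int B = end - start + 1;
    mat A(C, (uword)T * B);
    for (int b = 0; b < B; ++b)
      A.cols((uword)b * T, (uword)(b + 1) * T - 1) = X.slice(start + b);
    FwdCache f;
    forward(p, A, C, T, B, false, 0.0, nullptr, f, true);
    Grads g;
    backward(p, f, y.subvec(start, end), 1.0, true, false, g);
    for (int b = 0; b < B; ++b)
      out.slice(start + b) = g.dX.cols((uword)b * T, (uword)(b + 1) * T - 1);
  }
  return out;
}

// Parameter gradients of the mean loss (evaluation mode); used by the
// finite-difference gradient checks.
// [[Rcpp::export]]
List cnn_param_grad(List params, arma::cube X, arma::vec y) {
  Params p = params_from_list(params);
  mat A = cube_to_wide(X);
  FwdCache f;
  forward(p, A, X.n_rows, X.n_cols, X.n_slices, false, 0.0, nullptr, f, true);
  Grads g;
  backward(p, f, y, 1.0 / X.n_slices, false, false, g);
  return params_to_list(g.g);
}

// Mini-batch Adam training with cosine learning-rate decay and early
// stopping on validation loss. Returns the best-validation parameters and
// a per-epoch history.
// [[Rcpp::export]]
List cnn_train(List params, arma::cube X, arma::vec y,
               arma::cube Xval, arma::vec yval,
               int epochs, double lr0, double beta1, double beta2,
               double eps, double weight_decay, int batch_size,
               double dropout, int patience, int seed,
               bool cosine = true) {
  Params p = params_from_list(params);
  const int C = X.n_rows, T = X.n_cols, n = X.n_slices;
  if ((int)y.n_elem != n) stop("label/segment count mismatch");
  if (n < 1 || (int)Xval.n_slices < 1) stop("empty training or validation set");

  std::mt19937_64 rng((uint64_t)seed);
  AdamState adam(p);
  Params best = p;
  double best_val = datum::inf;
  int best_epoch = 0, stall = 0, rows = 0;
  mat history(epochs, 6, fill::zeros);

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int e = 0; e < epochs; ++e) {
    const double lr = cosine
      ? 0.5 * lr0 * (1.0 + std::cos(M_PI * (double)e / epochs))
      : lr0;
    std::shuffle(idx.begin(), idx.end(), rng);
    double lsum = 0; int ncorrect = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(n - 1, start + batch_size - 1);
      const int B = end - start + 1;
      mat A(C, (uword)T * B);
      vec yb(B);
      for (int b = 0; b < B; ++b) {
        A.cols((uword)b * T, (uword)(b + 1) * T - 1) = X.slice(idx[start + b]);
        yb(b) = y(idx[start + b]);
      }
      FwdCache f;
      forward(p, A, C, T, B, true, dropout, &rng, f, true);
      if (!f.logits.is_finite()) stop("training diverged: non-finite loss");
      lsum += accu(bce_losses(f.logits, yb));
      ncorrect += accu((f.logits >= 0) == (yb >= 0.5));
      Grads g;
      backward(p, f, yb, 1.0 / B, false, true, g);
      adam_step(p, g.g, adam, lr, beta1, beta2, eps, weight_decay);
    }
    double vloss, vacc;
    eval_dataset(p, Xval, yval, 512, vloss, vacc);
    if (!std::isfinite(vloss)) stop("training diverged: non-finite loss");
    history(rows, 0) = e + 1;
    history(rows, 1) = lr;
    history(rows, 2) = lsum / n;
    history(rows, 3) = (double)ncorrect / n;
    history(rows, 4) = vloss;
    history(rows, 5) = vacc;
    ++rows;
    if (vloss < best_val - 1e-12) {
      best_val = vloss; best = p; best_epoch = e + 1; stall = 0;
    } else if (++stall >= patience) break;
  }

  return List::create(
    Named("params") = params_to_list(best),
    Named("history") = history.rows(0, rows - 1),
    Named("best_epoch") = best_epoch,
    Named("epochs_run") = rows);
}
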