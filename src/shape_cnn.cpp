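// Codon-context shape model: a small 1-D convolutional network over codon
// tokens. Tokens are 0..63 (codons, lexicographic over A<C<G<T) plus 64 as
// the pad token for positions outside the CDS. The first layer is a
// convolution over one-hot token vectors, implemented as a gather-sum over an
// embedding-style weight table. Two further valid convolutions, then a head
// combining the center-position features with the window-mean features, a
// fully connected hidden layer, and a scalar log-shape output which is
// exponentiated so predictions are strictly positive.
//
// All convolutions are "valid": a training window carries
// window + 3*(kernel-1) tokens so that the final feature map has exactly
// `window` positions. Whole-transcript sliding prediction pads the token
// sequence and runs the identical stack, making batched training windows and
// sliding evaluation bit-identical.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::cube;

static const int N_TOKENS = 65;  // 64 codons + pad
static const double LOG_CLIP = -18.420680743952367;  // log(1e-8)

struct Params {
  mat W1, W2, W3, W4;   // (k*65 x F), (k*F x F), (k*F x F), (2F x H)
  vec b1, b2, b3, b4;
  vec W5;               // (H)
  double b5;
  int kernel, n_filters, hidden;
};

static Params params_from_list(const List& w) {
  Params p;
  p.W1 = as<mat>(w["W1"]); p.b1 = as<vec>(w["b1"]);
  p.W2 = as<mat>(w["W2"]); p.b2 = as<vec>(w["b2"]);
  p.W3 = as<mat>(w["W3"]); p.b3 = as<vec>(w["b3"]);
  p.W4 = as<mat>(w["W4"]); p.b4 = as<vec>(w["b4"]);
  p.W5 = as<vec>(w["W5"]); p.b5 = as<double>(w["b5"]);
  p.kernel = as<int>(w["kernel"]);
  p.n_filters = as<int>(w["n_filters"]);
  p.hidden = as<int>(w["hidden"]);
  return p;
}

static List params_to_list(const Params& p) {
  return List::create(
    _["W1"] = p.W1, _["b1"] = p.b1, _["W2"] = p.W2, _["b2"] = p.b2,
    _["W3"] = p.W3, _["b3"] = p.b3, _["W4"] = p.W4, _["b4"] = p.b4,
    _["W5"] = p.W5, _["b5"] = p.b5,
    _["kernel"] = p.kernel, _["n_filters"] = p.n_filters,
    _["hidden"] = p.hidden);
}

// one-hot convolution: tokens (length P_in) -> out (P_in-k+1 x F), ReLU
static mat conv1_forward(const int* tok, int P_in, const Params& p) {
  int k = p.kernel, F = p.n_filters;
  int P = P_in - k + 1;
  mat out(P, F);
  out.each_row() = p.b1.t();
  for (int pos = 0; pos < P; ++pos)
    for (int j = 0; j < k; ++j)
      out.row(pos) += p.W1.row(j * N_TOKENS + tok[pos + j]);
  out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return out;
}

// im2col for a valid 1-D convolution: A (P x F) -> C (P-k+1 x k*F)
static mat im2col(const mat& A, int k) {
  int P = A.n_rows - k + 1, F = A.n_cols;
  mat C(P, k * F);
  for (int j = 0; j < k; ++j)
    C.cols(j * F, (j + 1) * F - 1) = A.rows(j, j + P - 1);
  return C;
}

static mat conv_forward(const mat& A, const mat& W, const vec& b, int k) {
  mat out = im2col(A, k) * W;
  out.each_row() += b.t();
  out.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return out;
}

// forward pass for one window sample; returns prediction and (optionally)
// keeps intermediates for backprop
struct Acts {
  mat A1, A2, A3;      // feature maps
  vec feat;            // 2F
  vec h;               // hidden (post-ReLU)
  double z;            // log-shape output
};

static Acts forward_sample(const int* tok, int ctx, const Params& p) {
  Acts a;
  int k = p.kernel, F = p.n_filters;
  a.A1 = conv1_forward(tok, ctx, p);
  a.A2 = conv_forward(a.A1, p.W2, p.b2, k);
  a.A3 = conv_forward(a.A2, p.W3, p.b3, k);
  int W = a.A3.n_rows;                 // = window
  int c = (W - 1) / 2;
  a.feat.set_size(2 * F);
  a.feat.subvec(0, F - 1) = a.A3.row(c).t();
  a.feat.subvec(F, 2 * F - 1) = arma::mean(a.A3, 0).t();
  vec pre = p.W4.t() * a.feat + p.b4;
  a.h = arma::clamp(pre, 0.0, arma::datum::inf);
  a.z = arma::dot(p.W5, a.h) + p.b5;
  return a;
}

struct Grads {
  mat W1, W2, W3, W4;
  vec b1, b2, b3, b4, W5;
  double b5;
  void zero_like(const Params& p) {
    W1.zeros(arma::size(p.W1)); W2.zeros(arma::size(p.W2));
    W3.zeros(arma::size(p.W3)); W4.zeros(arma::size(p.W4));
    b1.zeros(p.b1.n_elem); b2.zeros(p.b2.n_elem); b3.zeros(p.b3.n_elem);
    b4.zeros(p.b4.n_elem); W5.zeros(p.W5.n_elem); b5 = 0.0;
  }
};

// backprop one sample given dL/dz; accumulates into g
static void backward_sample(const int* tok, int ctx, const Params& p,
                            const Acts& a, double dz, Grads& g) {
  int k = p.kernel, F = p.n_filters;
  // head
  g.W5 += dz * a.h;
  g.b5 += dz;
  vec dh = dz * p.W5;
  dh.elem(arma::find(a.h <= 0.0)).zeros();
  g.W4 += a.feat * dh.t();
  g.b4 += dh;
  vec dfeat = p.W4 * dh;
  // pooling
  int W = a.A3.n_rows, c = (W - 1) / 2;
  mat dA3(W, F, arma::fill::zeros);
  dA3.each_row() += (dfeat.subvec(F, 2 * F - 1) / (double)W).t();
  dA3.row(c) += dfeat.subvec(0, F - 1).t();
  // conv3
  dA3.elem(arma::find(a.A3 <= 0.0)).zeros();
  mat C3 = im2col(a.A2, k);
  g.W3 += C3.t() * dA3;
  g.b3 += arma::sum(dA3, 0).t();
  mat dC3 = dA3 * p.W3.t();
  mat dA2(a.A2.n_rows, F, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    dA2.rows(j, j + W - 1) += dC3.cols(j * F, (j + 1) * F - 1);
  // conv2
  dA2.elem(arma::find(a.A2 <= 0.0)).zeros();
  mat C2 = im2col(a.A1, k);
  g.W2 += C2.t() * dA2;
  g.b2 += arma::sum(dA2, 0).t();
  mat dC2 = dA2 * p.W2.t();
  int P2 = a.A2.n_rows;
  mat dA1(a.A1.n_rows, F, arma::fill::zeros);
  for (int j = 0; j < k; ++j)
    dA1.rows(j, j + P2 - 1) += dC2.cols(j * F, (j + 1) * F - 1);
  // conv1 (one-hot gather)
  dA1.elem(arma::find(a.A1 <= 0.0)).zeros();
  int P1 = a.A1.n_rows;
  for (int pos = 0; pos < P1; ++pos) {
    for (int j = 0; j < k; ++j)
      g.W1.row(j * N_TOKENS + tok[pos + j]) += dA1.row(pos);
  }
  g.b1 += arma::sum(dA1, 0).t();
}

struct AdamState {
  Grads m, v;
  double b1t = 1.0, b2t = 1.0;
};

static void adam_update_mat(mat& w, const mat& g, mat& m, mat& v,
                            double lr, double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
}
static void adam_update_vec(vec& w, const vec& g, vec& m, vec& v,
                            double lr, double c1, double c2) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
}

static void adam_step(Params& p, const Grads& g, AdamState& s, double lr) {
  s.b1t *= 0.9; s.b2t *= 0.999;
  double c1 = 1.0 - s.b1t, c2 = 1.0 - s.b2t;
  adam_update_mat(p.W1, g.W1, s.m.W1, s.v.W1, lr, c1, c2);
  adam_update_mat(p.W2, g.W2, s.m.W2, s.v.W2, lr, c1, c2);
  adam_update_mat(p.W3, g.W3, s.m.W3, s.v.W3, lr, c1, c2);
  adam_update_mat(p.W4, g.W4, s.m.W4, s.v.W4, lr, c1, c2);
  adam_update_vec(p.b1, g.b1, s.m.b1, s.v.b1, lr, c1, c2);
  adam_update_vec(p.b2, g.b2, s.m.b2, s.v.b2, lr, c1, c2);
  adam_update_vec(p.b3, g.b3, s.m.b3, s.v.b3, lr, c1, c2);
  adam_update_vec(p.b4, g.b4, s.m.b4, s.v.b4, lr, c1, c2);
  adam_update_vec(p.W5, g.W5, s.m.W5, s.v.W5, lr, c1, c2);
  s.m.b5 = 0.9 * s.m.b5 + 0.1 * g.b5;
  s.v.b5 = 0.999 * s.v.b5 + 0.001 * g.b5 * g.b5;
  p.b5 -= lr * (s.m.b5 / c1) / (std::sqrt(s.v.b5 / c2) + 1e-8);
}

static double clipped_log(double y) {
  return std::log(std::max(1e-8, y));
}

// mean squared log-difference loss over a set of samples (forward only)
static double eval_loss(const IntegerMatrix& X, const NumericVector& logy,
                        const std::vector<int>& idx, const Params& p) {
  int ctx = X.ncol();
  std::vector<int> tok(ctx);
  double s = 0.0;
  for (int i : idx) {
    for (int j = 0; j < ctx; ++j) tok[j] = X(i, j);
    Acts a = forward_sample(tok.data(), ctx, p);
    double lp = std::max(a.z, LOG_CLIP);
    double d = lp - logy[i];
    s += d * d;
  }
  return s / idx.size();
}

// [[Rcpp::export]]
List cpp_shape_train(IntegerMatrix X, NumericVector y, IntegerMatrix Xval,
                     NumericVector yval, int n_filters,
                     int kernel, int hidden, int epochs, double lr,
                     int batch, double val_frac, int seed) {
  int n = X.nrow(), ctx = X.ncol();
  if (n < 2) stop("need at least 2 training samples");
  int window = ctx - 3 * (kernel - 1);
  if (window < 1 || window % 2 == 0)
    stop("context width %d incompatible with kernel %d", ctx, kernel);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < ctx; ++j)
      if (X(i, j) < 0 || X(i, j) >= N_TOKENS) stop("token out of range");

  std::mt19937 rng(seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  Params p;
  p.kernel = kernel; p.n_filters = n_filters; p.hidden = hidden;
  auto he = [&](int rows, int cols, double fan_in) {
    mat w(rows, cols);
    double s = std::sqrt(2.0 / fan_in);
    for (arma::uword i = 0; i < w.n_elem; ++i) w(i) = s * nd(rng);
    return w;
  };
  int F = n_filters;
  p.W1 = he(kernel * N_TOKENS, F, kernel);          // one-hot: fan-in = kernel
  p.W2 = he(kernel * F, F, kernel * F);
  p.W3 = he(kernel * F, F, kernel * F);
  p.W4 = he(2 * F, hidden, 2 * F);
  p.W5 = vec(hidden);
  for (int i = 0; i < hidden; ++i) p.W5[i] = std::sqrt(2.0 / hidden) * nd(rng);
  p.b1.zeros(F); p.b2.zeros(F); p.b3.zeros(F); p.b4.zeros(hidden);
  p.b5 = 0.0;

  NumericVector logy(n);
  for (int i = 0; i < n; ++i) logy[i] = clipped_log(y[i]);

  // validation set: explicit held-out samples when provided (so resampled
  // duplicates of a training point can never leak into validation),
  // otherwise a fixed random split of the training matrix
  bool ext_val = Xval.nrow() > 0;
  NumericVector logyv(Xval.nrow());
  for (int i = 0; i < Xval.nrow(); ++i) logyv[i] = clipped_log(yval[i]);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  int n_val = ext_val ? Xval.nrow() : (int)std::floor(val_frac * n);
  std::vector<int> val_idx, train_idx;
  if (ext_val) {
    train_idx = perm;
    val_idx.resize(n_val);
    for (int i = 0; i < n_val; ++i) val_idx[i] = i;
  } else {
    val_idx.assign(perm.begin(), perm.begin() + n_val);
    train_idx.assign(perm.begin() + n_val, perm.end());
  }
  if (train_idx.empty()) stop("validation split leaves no training samples");

  AdamState adam;
  adam.m.zero_like(p); adam.v.zero_like(p);
  Grads g;
  std::vector<int> tok(ctx);
  std::vector<double> train_hist, val_hist;
  Params best = p;
  double prev_val = R_PosInf;
  int epochs_run = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(train_idx.begin(), train_idx.end(), rng);
    double ep_loss = 0.0;
    int n_train = train_idx.size();
    for (int start = 0; start < n_train; start += batch) {
      int end = std::min(start + batch, n_train);
      int bs = end - start;
      g.zero_like(p);
      double batch_loss = 0.0;
      for (int b = start; b < end; ++b) {
        int i = train_idx[b];
        for (int j = 0; j < ctx; ++j) tok[j] = X(i, j);
        Acts a = forward_sample(tok.data(), ctx, p);
        double lp = std::max(a.z, LOG_CLIP);
        double d = lp - logy[i];
        batch_loss += d * d;
        double dz = (a.z > LOG_CLIP) ? 2.0 * d / bs : 0.0;
        backward_sample(tok.data(), ctx, p, a, dz, g);
      }
      adam_step(p, g, adam, lr);
      ep_loss += batch_loss;
      if ((start / batch) % 16 == 0) Rcpp::checkUserInterrupt();
    }
    ep_loss /= n_train;
    train_hist.push_back(ep_loss);
    epochs_run = ep + 1;
    if (n_val > 0) {
      double vl = ext_val ? eval_loss(Xval, logyv, val_idx, p)
                          : eval_loss(X, logy, val_idx, p);
      val_hist.push_back(vl);
      if (!std::isfinite(vl) || !std::isfinite(ep_loss))
        stop("shape model training diverged (non-finite loss)");
      if (vl > prev_val) {  // early stop: keep previous epoch's weights
        p = best;
        break;
      }
      prev_val = vl;
      best = p;
    } else {
      if (!std::isfinite(ep_loss))
        stop("shape model training diverged (non-finite loss)");
      best = p;
    }
  }

  List out = params_to_list(p);
  out["train_loss"] = wrap(train_hist);
  out["val_loss"] = wrap(val_hist);
  out["epochs_run"] = epochs_run;
  out["window"] = window;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_shape_predict_windows(List w, IntegerMatrix X) {
  Params p = params_from_list(w);
  int n = X.nrow(), ctx = X.ncol();
  std::vector<int> tok(ctx);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < ctx; ++j) {
      int t = X(i, j);
      if (t < 0 || t >= N_TOKENS) stop("token out of range");
      tok[j] = t;
    }
    Acts a = forward_sample(tok.data(), ctx, p);
    out[i] = std::exp(a.z);
  }
  return out;
}

// Sliding whole-CDS prediction: pad the token sequence so that every codon's
// receptive field matches a training window exactly, run the conv stack once,
// then read out center features and running window means.
// [[Rcpp::export]]
NumericVector cpp_shape_predict_seq(List w, IntegerVector tokens, int window) {
  Params p = params_from_list(w);
  int k = p.kernel, F = p.n_filters;
  int L = tokens.size();
  if (L < 1) stop("empty codon sequence");
  int ctx = window + 3 * (k - 1);
  int half = (ctx - 1) / 2;
  std::vector<int> tok(L + 2 * half, 64);  // pad token
  for (int i = 0; i < L; ++i) {
    int t = tokens[i];
    if (t < 0 || t >= N_TOKENS) stop("token out of range");
    tok[half + i] = t;
  }
  mat A1 = conv1_forward(tok.data(), (int)tok.size(), p);
  mat A2 = conv_forward(A1, p.W2, p.b2, k);
  mat A3 = conv_forward(A2, p.W3, p.b3, k);  // rows: L + window - 1
  // prefix sums over rows for O(1) window means
  mat cs = arma::cumsum(A3, 0);
  int c_off = (window - 1) / 2;
  NumericVector out(L);
  vec feat(2 * F);
  for (int c = 0; c < L; ++c) {
    feat.subvec(0, F - 1) = A3.row(c + c_off).t();
    vec tot = cs.row(c + window - 1).t();
    if (c > 0) tot -= cs.row(c - 1).t();
    feat.subvec(F, 2 * F - 1) = tot / (double)window;
    vec h = arma::clamp(p.W4.t() * feat + p.b4, 0.0, arma::datum::inf);
    out[c] = std::exp(arma::dot(p.W5, h) + p.b5);
  }
  return out;
}
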