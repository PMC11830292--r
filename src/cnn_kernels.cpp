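// Compute kernels for the 1-D CNN: im2col convolutions, batch norm,
// max pooling, dropout, dense layers, and the full forward/backward pass.
// Single precision throughout (the working precision of CNN training);
// parameters cross the R boundary as doubles. Hot loops are written
// column-contiguous (Armadillo is column-major) so they vectorize.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
// Denormal activations stall the FPU by ~50x; flush them to zero while the
// kernels run (they are far below any meaningful signal level here).
struct FlushDenormals {
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(saved); }
};
#else
struct FlushDenormals {};
#endif

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

typedef arma::Mat<unsigned char> umat8;

static fmat as_fmat(SEXP x) {
  NumericMatrix m(x);
  arma::mat d(m.begin(), m.nrow(), m.ncol(), false);
  return arma::conv_to<fmat>::from(d);
}

static fvec as_fvec(SEXP x) {
  NumericVector v(x);
  arma::vec d(v.begin(), v.size(), false);
  return arma::conv_to<fvec>::from(d);
}

static NumericMatrix wrap_fmat(const fmat& x) {
  arma::mat d = arma::conv_to<arma::mat>::from(x);
  return wrap(d);
}

static NumericVector wrap_fvec(const fvec& x) {
  arma::vec d = arma::conv_to<arma::vec>::from(x);
  return wrap(d);
}

// xorshift32: cheap deterministic stream for dropout masks.
struct XorShift32 {
  uint32_t s;
  explicit XorShift32(uint32_t seed) : s(seed ? seed : 0x9e3779b9u) {}
  float unif() {
    s ^= s << 13; s ^= s >> 17; s ^= s << 5;
    return (s >> 8) * (1.0f / 16777216.0f);
  }
};

struct NetConfig {
  int kernel, pool, head; // head: 0 = softmax2, 1 = sigmoid1
  float conv_dropout, dense_dropout, bn_eps, bn_momentum;
};

static NetConfig read_config(const List& config) {
  NetConfig c;
  c.kernel = as<int>(config["kernel_size"]);
  c.pool = as<int>(config["pool_size"]);
  c.head = as<std::string>(config["head"]) == "sigmoid1" ? 1 : 0;
  c.conv_dropout = as<double>(config["conv_dropout"]);
  c.dense_dropout = as<double>(config["dense_dropout"]);
  c.bn_eps = 1e-5f;
  c.bn_momentum = 0.9f;
  return c;
}

// Same-padding 1-D convolution as k offset GEMMs on shifted column views
// (columns are grouped per sample; patches never cross a sample boundary).
// W is (F x C*k) with taps ordered channel-fastest; A is (C x T*B).
static fmat conv_fwd(const fmat& W, const fmat& A, int k, int T, int B) {
  const int C = A.n_rows;
  const int pad_l = (k - 1) / 2;
  fmat Z(W.n_rows, A.n_cols, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const fmat Wj = W.cols((size_t)j * C, (size_t)(j + 1) * C - 1);
    const int shift = j - pad_l; // output t draws on input t + shift
    if (shift == 0) { Z += Wj * A; continue; }
    for (int b = 0; b < B; ++b) {
      const size_t off = (size_t)b * T;
      if (shift < 0)
        Z.cols(off - shift, off + T - 1) += Wj * A.cols(off, off + T - 1 + shift);
      else
        Z.cols(off, off + T - 1 - shift) += Wj * A.cols(off + shift, off + T - 1);
    }
  }
  return Z;
}

// Weight gradient of the same convolution: dW_j = dZ_valid * A_shifted^T.
static fmat conv_dW(const fmat& dZ, const fmat& A, int k, int T, int B) {
  const int C = A.n_rows;
  const int pad_l = (k - 1) / 2;
  fmat dW(dZ.n_rows, (size_t)C * k, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    fmat acc(dZ.n_rows, C, arma::fill::zeros);
    const int shift = j - pad_l;
    if (shift == 0) {
      acc = dZ * A.t();
    } else {
      for (int b = 0; b < B; ++b) {
        const size_t off = (size_t)b * T;
        if (shift < 0)
          acc += dZ.cols(off - shift, off + T - 1) * A.cols(off, off + T - 1 + shift).t();
        else
          acc += dZ.cols(off, off + T - 1 - shift) * A.cols(off + shift, off + T - 1).t();
      }
    }
    dW.cols((size_t)j * C, (size_t)(j + 1) * C - 1) = acc;
  }
  return dW;
}

// Input gradient: scatter each tap back with the opposite shift.
static fmat conv_dA(const fmat& W, const fmat& dZ, int k, int T, int B, int C) {
  const int pad_l = (k - 1) / 2;
  fmat dA(C, dZ.n_cols, arma::fill::zeros);
  for (int j = 0; j < k; ++j) {
    const fmat Wjt = W.cols((size_t)j * C, (size_t)(j + 1) * C - 1).t();
    const int shift = j - pad_l;
    if (shift == 0) { dA += Wjt * dZ; continue; }
    for (int b = 0; b < B; ++b) {
      const size_t off = (size_t)b * T;
      if (shift < 0)
        dA.cols(off, off + T - 1 + shift) += Wjt * dZ.cols(off - shift, off + T - 1);
      else
        dA.cols(off + shift, off + T - 1) += Wjt * dZ.cols(off, off + T - 1 - shift);
    }
  }
  return dA;
}

static fmat maxpool_fwd(const fmat& A, int P, int T, int B, umat8& idx) {
  const int F = A.n_rows, To = T / P;
  fmat out(F, (size_t)To * B);
  idx.set_size(F, (size_t)To * B);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < To; ++t) {
      const size_t oc = (size_t)b * To + t;
      const size_t ic0 = (size_t)b * T + (size_t)t * P;
      float* po = out.colptr(oc);
      unsigned char* pi = idx.colptr(oc);
      std::copy(A.colptr(ic0), A.colptr(ic0) + F, po);
      std::fill(pi, pi + F, (unsigned char)0);
      for (int j = 1; j < P; ++j) {
        const float* pa = A.colptr(ic0 + j);
        for (int f = 0; f < F; ++f)
          if (pa[f] > po[f]) { po[f] = pa[f]; pi[f] = (unsigned char)j; }
      }
    }
  }
  return out;
}

static fmat maxpool_bwd(const fmat& dout, const umat8& idx, int P, int T, int B) {
  const int F = dout.n_rows, To = T / P;
  fmat dA(F, (size_t)T * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < To; ++t) {
      const size_t oc = (size_t)b * To + t;
      const size_t ic0 = (size_t)b * T + (size_t)t * P;
      const float* pd = dout.colptr(oc);
      const unsigned char* pi = idx.colptr(oc);
      for (int f = 0; f < F; ++f) dA(f, ic0 + pi[f]) = pd[f];
    }
  }
  return dA;
}

static void dropout_fwd(fmat& A, float rate, XorShift32& gen, umat8& mask) {
  mask.set_size(A.n_rows, A.n_cols);
  if (rate <= 0.0f) { mask.fill(1); return; }
  const float scale = 1.0f / (1.0f - rate);
  float* a = A.memptr();
  unsigned char* m = mask.memptr();
  for (size_t i = 0; i < A.n_elem; ++i) {
    if (gen.unif() < rate) { m[i] = 0; a[i] = 0.0f; }
    else { m[i] = 1; a[i] *= scale; }
  }
}

static void dropout_bwd(fmat& dA, const umat8& mask, float rate) {
  if (rate <= 0.0f) return;
  const float scale = 1.0f / (1.0f - rate);
  float* d = dA.memptr();
  const unsigned char* m = mask.memptr();
  for (size_t i = 0; i < dA.n_elem; ++i) d[i] = m[i] ? d[i] * scale : 0.0f;
}

// Per-channel (row) mean and variance, accumulated column-contiguously in
// double to avoid catastrophic cancellation at single precision.
static void row_stats(const fmat& Z, fvec& mu, fvec& var) {
  const int F = Z.n_rows;
  arma::vec s(F, arma::fill::zeros), s2(F, arma::fill::zeros);
  for (size_t j = 0; j < Z.n_cols; ++j) {
    const float* p = Z.colptr(j);
    for (int f = 0; f < F; ++f) { s[f] += p[f]; s2[f] += (double)p[f] * p[f]; }
  }
  const double N = (double)Z.n_cols;
  mu.set_size(F); var.set_size(F);
  for (int f = 0; f < F; ++f) {
    mu[f] = (float)(s[f] / N);
    var[f] = (float)std::max(s2[f] / N - (s[f] / N) * (s[f] / N), 0.0);
  }
}

// ReLU(gamma * xhat + beta) in one column-contiguous pass.
static fmat bn_scale_relu(const fmat& xhat, const fvec& gamma, const fvec& beta) {
  const int F = xhat.n_rows;
  fmat act(F, xhat.n_cols, arma::fill::none);
  const float* g = gamma.memptr();
  const float* be = beta.memptr();
  for (size_t j = 0; j < xhat.n_cols; ++j) {
    const float* x = xhat.colptr(j);
    float* a = act.colptr(j);
    for (int f = 0; f < F; ++f) {
      const float v = g[f] * x[f] + be[f];
      a[f] = v > 0.0f ? v : 0.0f;
    }
  }
  return act;
}

struct ConvParams {
  fmat W; fvec b, gamma, beta, rmean, rvar;
};

struct Caches {
  std::vector<fmat> input;     // conv input per block (reused in backward)
  std::vector<fmat> xhat;      // BN-normalized pre-activation
  std::vector<fvec> invstd;
  std::vector<umat8> pool_idx;
  std::vector<umat8> drop_mask;
  std::vector<int> T_in;       // time length entering each block
  fmat flat, dense_h;          // flatten output; dense post-ReLU pre-dropout
  umat8 dense_drop;
  fmat head_in;                // dense output after dropout
};

// Shared forward pass. training = true uses batch statistics, applies
// dropout, fills caches and updates running BN statistics.
static fmat net_forward(const std::vector<ConvParams>& conv,
                        const fmat& Wd, const fvec& bd,
                        const fmat& Wh, const fvec& bh,
                        const NetConfig& cfg, const fmat& X,
                        bool training, XorShift32& gen,
                        Caches* cache,
                        std::vector<fvec>* new_rmean,
                        std::vector<fvec>* new_rvar) {
  const int B = X.n_cols;
  const int L = conv.size();
  fmat A = X; // treat input as 1 channel: (1 x input_len*B)
  A.reshape(1, X.n_elem);
  int T = X.n_rows;
  if (cache) {
    cache->input.reserve(L); cache->xhat.reserve(L); cache->invstd.reserve(L);
    cache->pool_idx.reserve(L); cache->drop_mask.reserve(L); cache->T_in.reserve(L);
  }
  for (int l = 0; l < L; ++l) {
    if (cache) cache->T_in.push_back(T);
    fmat Z = conv_fwd(conv[l].W, A, cfg.kernel, T, B);
    Z.each_col() += conv[l].b;
    if (cache) cache->input.push_back(std::move(A));
    const int F = Z.n_rows;
    fvec mu(F), var(F), invstd(F);
    if (training) {
      row_stats(Z, mu, var);
      if (new_rmean) {
        (*new_rmean)[l] = cfg.bn_momentum * conv[l].rmean + (1.0f - cfg.bn_momentum) * mu;
        (*new_rvar)[l] = cfg.bn_momentum * conv[l].rvar + (1.0f - cfg.bn_momentum) * var;
      }
    } else {
      mu = conv[l].rmean;
      var = conv[l].rvar;
    }
    for (int f = 0; f < F; ++f) invstd[f] = 1.0f / std::sqrt(var[f] + cfg.bn_eps);
    fmat xhat = std::move(Z);
    xhat.each_col() -= mu;
    xhat.each_col() %= invstd;
    fmat act = bn_scale_relu(xhat, conv[l].gamma, conv[l].beta);
    if (cache) { cache->xhat.push_back(std::move(xhat)); cache->invstd.push_back(invstd); }
    umat8 pidx;
    fmat pooled = maxpool_fwd(act, cfg.pool, T, B, pidx);
    T /= cfg.pool;
    umat8 dmask;
    if (training) dropout_fwd(pooled, cfg.conv_dropout, gen, dmask);
    if (cache) { cache->pool_idx.push_back(std::move(pidx)); cache->drop_mask.push_back(std::move(dmask)); }
    A = std::move(pooled);
  }
  // flatten: per-sample column-major (channel fastest) vectorization
  const int C_last = A.n_rows;
  fmat flat(C_last * T, B);
  for (int b = 0; b < B; ++b)
    std::copy(A.colptr((size_t)b * T), A.colptr((size_t)b * T) + (size_t)C_last * T,
              flat.colptr(b));
  if (cache) cache->flat = flat;
  fmat h = Wd * flat;
  h.each_col() += bd;
  float* hp = h.memptr();
  for (size_t i = 0; i < h.n_elem; ++i) hp[i] = hp[i] > 0.0f ? hp[i] : 0.0f;
  if (cache) cache->dense_h = h;
  umat8 ddrop;
  if (training) dropout_fwd(h, cfg.dense_dropout, gen, ddrop);
  if (cache) { cache->dense_drop = std::move(ddrop); cache->head_in = h; }
  fmat logits = Wh * h;
  logits.each_col() += bh;
  fmat probs;
  if (cfg.head == 0) { // softmax over the rows of each column
    probs = logits;
    for (int b = 0; b < B; ++b) {
      fvec z = probs.col(b);
      z -= z.max();
      fvec e = arma::exp(z);
      probs.col(b) = e / arma::accu(e);
    }
  } else {
    probs = 1.0f / (1.0f + arma::exp(-logits));
  }
  return probs;
}

static std::vector<ConvParams> read_conv(const List& params) {
  List convL = params["conv"];
  std::vector<ConvParams> conv(convL.size());
  for (int l = 0; l < convL.size(); ++l) {
    List pl = convL[l];
    conv[l].W = as_fmat(pl["W"]);
    conv[l].b = as_fvec(pl["b"]);
    conv[l].gamma = as_fvec(pl["gamma"]);
    conv[l].beta = as_fvec(pl["beta"]);
    conv[l].rmean = as_fvec(pl["rmean"]);
    conv[l].rvar = as_fvec(pl["rvar"]);
  }
  return conv;
}

// Batch-statistics pass for BN re-estimation: propagate a batch in
// training-mode normalization (no dropout) and return each layer's batch
// mean and variance, so running statistics can be set to their average
// after training instead of a lagging exponential estimate.
// [[Rcpp::export(name = ".cnn_bn_stats_cpp")]]
List cnn_bn_stats_cpp(List params, List config, NumericMatrix X) {
  FlushDenormals ftz;
  NetConfig cfg = read_config(config);
  cfg.conv_dropout = 0.0f;
  cfg.dense_dropout = 0.0f;
  std::vector<ConvParams> conv = read_conv(params);
  const int L = conv.size();
  List dense = params["dense"], head = params["head"];
  fmat Wd = as_fmat(dense["W"]), Wh = as_fmat(head["W"]);
  fvec bd = as_fvec(dense["b"]), bh = as_fvec(head["b"]);
  fmat Xf = as_fmat(X);
  const int B = Xf.n_cols;
  fmat A = Xf;
  A.reshape(1, Xf.n_elem);
  int T = Xf.n_rows;
  List means(L), vars(L);
  XorShift32 gen(1u);
  for (int l = 0; l < L; ++l) {
    fmat Z = conv_fwd(conv[l].W, A, cfg.kernel, T, B);
    Z.each_col() += conv[l].b;
    const int F = Z.n_rows;
    fvec mu(F), var(F), invstd(F);
    row_stats(Z, mu, var);
    means[l] = wrap_fvec(mu);
    vars[l] = wrap_fvec(var);
    for (int f = 0; f < F; ++f) invstd[f] = 1.0f / std::sqrt(var[f] + cfg.bn_eps);
    fmat xhat = std::move(Z);
    xhat.each_col() -= mu;
    xhat.each_col() %= invstd;
    fmat act = bn_scale_relu(xhat, conv[l].gamma, conv[l].beta);
    umat8 pidx;
    A = maxpool_fwd(act, cfg.pool, T, B, pidx);
    T /= cfg.pool;
  }
  return List::create(_["mean"] = means, _["var"] = vars);
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
NumericMatrix cnn_forward_cpp(List params, List config, NumericMatrix X) {
  FlushDenormals ftz;
  NetConfig cfg = read_config(config);
  std::vector<ConvParams> conv = read_conv(params);
  List dense = params["dense"], head = params["head"];
  fmat Wd = as_fmat(dense["W"]), Wh = as_fmat(head["W"]);
  fvec bd = as_fvec(dense["b"]), bh = as_fvec(head["b"]);
  fmat Xf = as_fmat(X);
  XorShift32 gen(1u);
  fmat probs = net_forward(conv, Wd, bd, Wh, bh, cfg, Xf, false, gen,
                           nullptr, nullptr, nullptr);
  return wrap_fmat(probs);
}

// One training step: forward with batch statistics + dropout, cross-entropy
// loss, full backward pass. Returns gradients, updated running BN stats,
// the loss and the training-mode probabilities.
// [[Rcpp::export(name = ".cnn_train_batch_cpp")]]
List cnn_train_batch_cpp(List params, List config, NumericMatrix X,
                         NumericMatrix Y, int rng_seed) {
  FlushDenormals ftz;
  NetConfig cfg = read_config(config);
  std::vector<ConvParams> conv = read_conv(params);
  const int L = conv.size();
  List dense = params["dense"], head = params["head"];
  fmat Wd = as_fmat(dense["W"]), Wh = as_fmat(head["W"]);
  fvec bd = as_fvec(dense["b"]), bh = as_fvec(head["b"]);
  fmat Xf = as_fmat(X), Yf = as_fmat(Y); // Y: n_out x B one-hot / binary
  const int B = Xf.n_cols;

  XorShift32 gen((uint32_t)rng_seed);
  Caches cache;
  std::vector<fvec> new_rmean(L), new_rvar(L);
  fmat probs = net_forward(conv, Wd, bd, Wh, bh, cfg, Xf, true, gen,
                           &cache, &new_rmean, &new_rvar);

  const float eps = 1e-7f;
  double loss = 0.0;
  fmat dlogits(probs.n_rows, B);
  if (cfg.head == 0) {
    for (int b = 0; b < B; ++b)
      for (arma::uword i = 0; i < probs.n_rows; ++i)
        loss -= Yf(i, b) * std::log(std::max(probs(i, b), eps));
  } else {
    for (int b = 0; b < B; ++b) {
      const float p = std::min(std::max(probs(0, b), eps), 1.0f - eps);
      loss -= Yf(0, b) * std::log(p) + (1.0f - Yf(0, b)) * std::log(1.0f - p);
    }
  }
  loss /= B;
  dlogits = (probs - Yf) / (float)B;

  // head
  fmat dWh = dlogits * cache.head_in.t();
  fvec dbh = arma::sum(dlogits, 1);
  fmat dh = Wh.t() * dlogits;
  dropout_bwd(dh, cache.dense_drop, cfg.dense_dropout);
  {
    float* d = dh.memptr();
    const float* hh = cache.dense_h.memptr();
    for (size_t i = 0; i < dh.n_elem; ++i) if (hh[i] <= 0.0f) d[i] = 0.0f;
  }
  fmat dWd = dh * cache.flat.t();
  fvec dbd = arma::sum(dh, 1);
  fmat dflat = Wd.t() * dh;

  // un-flatten
  int T = cache.T_in[L - 1] / cfg.pool;
  const int C_last = conv[L - 1].W.n_rows;
  fmat dA(C_last, (size_t)T * B);
  for (int b = 0; b < B; ++b)
    std::copy(dflat.colptr(b), dflat.colptr(b) + (size_t)C_last * T,
              dA.colptr((size_t)b * T));

  List conv_grads(L);
  for (int l = L - 1; l >= 0; --l) {
    const int Tl = cache.T_in[l]; // time length entering block l
    dropout_bwd(dA, cache.drop_mask[l], cfg.conv_dropout);
    fmat dact = maxpool_bwd(dA, cache.pool_idx[l], cfg.pool, Tl, B);
    const fmat& xhat = cache.xhat[l];
    const int F = xhat.n_rows;
    const float* g = conv[l].gamma.memptr();
    const float* be = conv[l].beta.memptr();
    // pass 1: ReLU mask from the sign of the BN output, plus the dgamma /
    // dbeta accumulations (double accumulators; column-contiguous)
    arma::vec dgamma_d(F, arma::fill::zeros), dbeta_d(F, arma::fill::zeros);
    for (size_t j = 0; j < xhat.n_cols; ++j) {
      const float* xc = xhat.colptr(j);
      float* dc = dact.colptr(j);
      for (int f = 0; f < F; ++f) {
        if (g[f] * xc[f] + be[f] <= 0.0f) dc[f] = 0.0f;
        dgamma_d[f] += (double)dc[f] * xc[f];
        dbeta_d[f] += dc[f];
      }
    }
    fvec dgamma = arma::conv_to<fvec>::from(dgamma_d);
    fvec dbeta = arma::conv_to<fvec>::from(dbeta_d);
    // pass 2: dZ in place. With dxhat = gamma * dact, the column sums of
    // dxhat and dxhat*xhat are gamma*dbeta and gamma*dgamma respectively.
    const float N = (float)xhat.n_cols;
    fvec s1 = conv[l].gamma % dbeta;
    fvec s2 = conv[l].gamma % dgamma;
    fvec scale = cache.invstd[l] / N;
    for (size_t j = 0; j < xhat.n_cols; ++j) {
      const float* xc = xhat.colptr(j);
      float* dc = dact.colptr(j);
      for (int f = 0; f < F; ++f)
        dc[f] = scale[f] * (N * g[f] * dc[f] - s1[f] - xc[f] * s2[f]);
    }
    fmat& dZ = dact;
    // conv backward against the cached block input
    fmat dW = conv_dW(dZ, cache.input[l], cfg.kernel, Tl, B);
    fvec db = arma::sum(dZ, 1);
    if (l > 0)
      dA = conv_dA(conv[l].W, dZ, cfg.kernel, Tl, B, cache.input[l].n_rows);
    conv_grads[l] = List::create(_["W"] = wrap_fmat(dW), _["b"] = wrap_fvec(db),
                                 _["gamma"] = wrap_fvec(dgamma),
                                 _["beta"] = wrap_fvec(dbeta));
  }

  List rmeans(L), rvars(L);
  for (int l = 0; l < L; ++l) {
    rmeans[l] = wrap_fvec(new_rmean[l]);
    rvars[l] = wrap_fvec(new_rvar[l]);
  }
  return List::create(
    _["loss"] = loss,
    _["probs"] = wrap_fmat(probs),
    _["grads"] = List::create(
      _["conv"] = conv_grads,
      _["dense"] = List::create(_["W"] = wrap_fmat(dWd), _["b"] = wrap_fvec(dbd)),
      _["head"] = List::create(_["W"] = wrap_fmat(dWh), _["b"] = wrap_fvec(dbh))),
    _["rmean"] = rmeans, _["rvar"] = rvars);
}
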