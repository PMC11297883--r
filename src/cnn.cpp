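// Sequential CNN engine for square single-channel inputs:
//   [conv kxk 'same' + ReLU + maxpool 2x2 stride 2 (floor)] * n_blocks
//   -> global max pool -> dropout -> dense + ReLU -> batchnorm
//   -> dense softmax
// Forward, exact backward (for Adam training with per-sample loss weights)
// and Grad-CAM gradients w.r.t. the final conv activation. Feature maps are
// held as (H*W x C) matrices, column-major over pixels (i + H*j).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

struct ConvLayer {
  mat W;     // (k*k*Cin x Cout), column c = kernel for output channel c
  vec b;     // (Cout)
  int k;
};

struct Net {
  std::vector<ConvLayer> conv;
  mat W1; vec b1;          // dense: (units x nfeat)
  vec gamma, beta;         // batchnorm over units
  mat W2; vec b2;          // softmax dense: (K x units)
  double bn_eps = 1e-5;
};

static Net unpack(const List& weights) {
  Net net;
  List convs = weights["conv"];
  for (int l = 0; l < convs.size(); ++l) {
    List cl = convs[l];
    NumericVector Wv = cl["W"];
    IntegerVector d = Wv.attr("dim");           // (k, k, Cin, Cout)
    ConvLayer layer;
    layer.k = d[0];
    layer.W = mat(Wv.begin(), d[0] * d[1] * d[2], d[3]);
    layer.b = as<vec>(cl["b"]);
    net.conv.push_back(layer);
  }
  net.W1 = as<mat>(weights["W1"]);  net.b1 = as<vec>(weights["b1"]);
  net.gamma = as<vec>(weights["gamma"]); net.beta = as<vec>(weights["beta"]);
  net.W2 = as<mat>(weights["W2"]);  net.b2 = as<vec>(weights["b2"]);
  return net;
}

// patches laid out (H*W x k*k*C): column (di + k*dj + k*k*c) holds the
// (di,dj)-shifted copy of input channel c, so inner loops touch memory
// contiguously and the convolution is a single GEMM: z = cols * W.
static void im2col(const mat& in, int H, int W, int k, mat& cols) {
  const int C = in.n_cols, pad = k / 2;
  cols.zeros((uword)H * W, (uword)k * k * C);
  for (int c = 0; c < C; ++c) {
    const double* src = in.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = cols.colptr(di + k * dj + (uword)k * k * c);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H, H + pad - di);
          const double* s = src + (uword)H * jj + di - pad;
          double* d = dst + (uword)H * j;
          for (int i = i0; i < i1; ++i) d[i] = s[i];
        }
      }
    }
  }
}

static void col2im(const mat& dcols, int H, int W, int C, int k, mat& din) {
  const int pad = k / 2;
  din.zeros((uword)H * W, C);
  for (int c = 0; c < C; ++c) {
    double* dst = din.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* src = dcols.colptr(di + k * dj + (uword)k * k * c);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pad;
          if (jj < 0 || jj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H, H + pad - di);
          double* d = dst + (uword)H * jj + di - pad;
          const double* s = src + (uword)H * j;
          for (int i = i0; i < i1; ++i) d[i] += s[i];
        }
      }
    }
  }
}

// max pool 2x2 stride 2, floor division of odd sizes (trailing row/col dropped)
static void maxpool(const mat& in, int H, int W, mat& out, arma::umat& idx,
                    int& Ho, int& Wo) {
  const int C = in.n_cols;
  Ho = H / 2; Wo = W / 2;
  out.set_size((uword)Ho * Wo, C);
  idx.set_size((uword)Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const double* src = in.colptr(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const uword p00 = (2 * i) + (uword)H * (2 * j);
        const uword cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        uword best = cand[0];
        for (int q = 1; q < 4; ++q) if (src[cand[q]] > src[best]) best = cand[q];
        out(i + (uword)Ho * j, c) = src[best];
        idx(i + (uword)Ho * j, c) = best;
      }
    }
  }
}

struct Cache {
  std::vector<mat> input;      // input map of each conv layer (HW x Cin)
  std::vector<mat> act;        // post-ReLU conv output (HW x Cout)
  std::vector<mat> pooled;     // post-pool map
  std::vector<arma::umat> pidx;
  std::vector<int> H, W;       // spatial size at conv layer input
  arma::uvec gmp_idx;          // argmax pixel per channel of last pooled map
};

// conv stack forward for one sample; returns global-max-pooled features
static vec conv_forward(const mat& x, const Net& net, Cache* cache) {
  int H = (int)std::lround(std::sqrt((double)x.n_rows));
  mat cur = x;                 // (HW x 1)
  int W = (int)(x.n_rows / H);
  mat cols;
  for (size_t l = 0; l < net.conv.size(); ++l) {
    const ConvLayer& cl = net.conv[l];
    im2col(cur, H, W, cl.k, cols);
    mat z = cols * cl.W;
    z.each_row() += cl.b.t();
    z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    mat pooled; arma::umat pidx; int Ho, Wo;
    maxpool(z, H, W, pooled, pidx, Ho, Wo);
    if (cache) {
      cache->input.push_back(cur); cache->act.push_back(z);
      cache->pooled.push_back(pooled); cache->pidx.push_back(pidx);
      cache->H.push_back(H); cache->W.push_back(W);
    }
    cur = pooled; H = Ho; W = Wo;
  }
  const int C = cur.n_cols;
  vec feat(C);
  arma::uvec gidx(C);
  for (int c = 0; c < C; ++c) {
    uword im;
    feat(c) = cur.col(c).max(im);
    gidx(c) = im;
  }
  if (cache) cache->gmp_idx = gidx;
  return feat;
}

// backward through the conv stack for one sample, from d(features)
static void conv_backward(const Cache& cache, const Net& net, const vec& dfeat,
                          std::vector<mat>& dW, std::vector<vec>& db) {
  const int L = (int)net.conv.size();
  // gradient w.r.t. last pooled map
  mat dcur(cache.pooled[L - 1].n_rows, cache.pooled[L - 1].n_cols,
           arma::fill::zeros);
  for (uword c = 0; c < dcur.n_cols; ++c)
    dcur(cache.gmp_idx(c), c) = dfeat(c);
  mat cols, dcols;
  for (int l = L - 1; l >= 0; --l) {
    const ConvLayer& cl = net.conv[l];
    const int H = cache.H[l], W = cache.W[l];
    // unpool
    mat dz((uword)H * W, cache.act[l].n_cols, arma::fill::zeros);
    const arma::umat& pidx = cache.pidx[l];
    for (uword c = 0; c < dcur.n_cols; ++c)
      for (uword p = 0; p < dcur.n_rows; ++p)
        dz(pidx(p, c), c) += dcur(p, c);
    // ReLU mask, in place
    {
      const double* a = cache.act[l].memptr();
      double* g = dz.memptr();
      const uword nn = dz.n_elem;
      for (uword q = 0; q < nn; ++q) if (a[q] <= 0.0) g[q] = 0.0;
    }
    im2col(cache.input[l], H, W, cl.k, cols);
    dW[l] += cols.t() * dz;
    db[l] += arma::sum(dz, 0).t();
    if (l > 0) {
      dcols = dz * cl.W.t();
      col2im(dcols, H, W, cache.input[l].n_cols, cl.k, dcur);
    }
  }
}

struct HeadOut {
  mat P, Pd, Z1, A1, xhat, Y, logits, probs;
  vec mu, var;
};

static void head_forward(const mat& P, const Net& net, const mat& drop_mask,
                         bool training, const vec& run_mean,
                         const vec& run_var, HeadOut& h) {
  const int N = P.n_cols;
  h.P = P;
  h.Pd = P % drop_mask;
  h.Z1 = net.W1 * h.Pd;
  h.Z1.each_col() += net.b1;
  h.A1 = h.Z1;
  h.A1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  if (training) {
    h.mu = arma::mean(h.A1, 1);
    h.var = arma::mean(arma::square(h.A1.each_col() - h.mu), 1);
  } else {
    h.mu = run_mean; h.var = run_var;
  }
  vec denom = arma::sqrt(h.var + net.bn_eps);
  h.xhat = (h.A1.each_col() - h.mu);
  h.xhat.each_col() /= denom;
  h.Y = h.xhat.each_col() % net.gamma;
  h.Y.each_col() += net.beta;
  h.logits = net.W2 * h.Y;
  h.logits.each_col() += net.b2;
  h.probs = h.logits;
  for (int i = 0; i < N; ++i) {
    vec c = h.logits.col(i);
    c -= c.max();
    vec e = arma::exp(c);
    h.probs.col(i) = e / arma::accu(e);
  }
}

// [[Rcpp::export]]
List cnn_batch(const arma::cube& X, const arma::ivec& y, const List& weights,
               const arma::vec& run_mean, const arma::vec& run_var,
               const arma::mat& drop_mask, const arma::vec& sample_w,
               bool training, bool want_grad) {
  Net net = unpack(weights);
  const int N = X.n_slices;
  const uword HW = X.n_rows * X.n_cols;
  const int nfeat = net.conv.back().b.n_elem;
  mat P(nfeat, N);
  std::vector<Cache> caches(want_grad ? N : 0);
  for (int i = 0; i < N; ++i) {
    mat xi(const_cast<double*>(X.slice(i).memptr()), HW, 1, false);
    P.col(i) = conv_forward(xi, net, want_grad ? &caches[i] : nullptr);
  }
  HeadOut h;
  head_forward(P, net, drop_mask, training, run_mean, run_var, h);
  double loss = 0.0;
  for (int i = 0; i < N; ++i)
    loss += -sample_w(i) * std::log(std::max(h.probs(y(i), i), 1e-300));
  loss /= N;
  List out = List::create(_["loss"] = loss,
                          _["probs"] = h.probs,
                          _["bn_mean"] = h.mu, _["bn_var"] = h.var);
  if (!want_grad) return out;

  // head backward
  mat dZ2 = h.probs;
  for (int i = 0; i < N; ++i) {
    dZ2(y(i), i) -= 1.0;
    dZ2.col(i) *= sample_w(i) / N;
  }
  mat dW2 = dZ2 * h.Y.t();
  vec db2 = arma::sum(dZ2, 1);
  mat dY = net.W2.t() * dZ2;
  vec dgamma = arma::sum(dY % h.xhat, 1);
  vec dbeta = arma::sum(dY, 1);
  mat dxhat = dY.each_col() % net.gamma;
  vec denom = arma::sqrt(h.var + net.bn_eps);
  mat dA1;
  if (training) {
    mat xc = h.A1.each_col() - h.mu;
    vec dvar = arma::sum(dxhat % xc, 1) % (-0.5 * arma::pow(h.var + net.bn_eps, -1.5));
    vec dmu = -arma::sum(dxhat, 1) / denom +
              dvar % (-2.0 * arma::mean(xc, 1));
    dA1 = dxhat.each_col() / denom;
    dA1 += (xc.each_col() % (2.0 * dvar / N));
    dA1.each_col() += dmu / N;
  } else {
    dA1 = dxhat.each_col() / denom;
  }
  mat dZ1 = dA1 % arma::conv_to<mat>::from(h.Z1 > 0.0);
  mat dW1 = dZ1 * h.Pd.t();
  vec db1 = arma::sum(dZ1, 1);
  mat dP = (net.W1.t() * dZ1) % drop_mask;

  // conv backward per sample
  std::vector<mat> dW(net.conv.size());
  std::vector<vec> db(net.conv.size());
  for (size_t l = 0; l < net.conv.size(); ++l) {
    dW[l].zeros(net.conv[l].W.n_rows, net.conv[l].W.n_cols);
    db[l].zeros(net.conv[l].b.n_elem);
  }
  for (int i = 0; i < N; ++i)
    conv_backward(caches[i], net, dP.col(i), dW, db);

  List conv_grads(net.conv.size());
  List convs = weights["conv"];
  for (size_t l = 0; l < net.conv.size(); ++l) {
    List cl = convs[l];
    NumericVector Wv = cl["W"];
    NumericVector g(Wv.size());
    std::copy(dW[l].begin(), dW[l].end(), g.begin());
    g.attr("dim") = Wv.attr("dim");
    conv_grads[l] = List::create(_["W"] = g, _["b"] = db[l]);
  }
  out["grads"] = List::create(_["conv"] = conv_grads,
                              _["W1"] = dW1, _["b1"] = db1,
                              _["gamma"] = dgamma, _["beta"] = dbeta,
                              _["W2"] = dW2, _["b2"] = db2);
  return out;
}

// [[Rcpp::export]]
arma::mat cnn_predict_probs(const arma::cube& X, const List& weights,
                            const arma::vec& run_mean, const arma::vec& run_var) {
  Net net = unpack(weights);
  const int N = X.n_slices;
  const uword HW = X.n_rows * X.n_cols;
  const int nfeat = net.conv.back().b.n_elem;
  mat P(nfeat, N);
  for (int i = 0; i < N; ++i) {
    mat xi(const_cast<double*>(X.slice(i).memptr()), HW, 1, false);
    P.col(i) = conv_forward(xi, net, nullptr);
  }
  HeadOut h;
  mat mask(nfeat, N, arma::fill::ones);
  head_forward(P, net, mask, false, run_mean, run_var, h);
  return h.probs;
}

// Grad-CAM ingredients: final conv layer activation A (post-ReLU, before its
// pool) and d(logit_target)/dA, both as H x W x C cubes. Eval mode
// (running batchnorm statistics, no dropout).
// [[Rcpp::export]]
List cnn_gradcam_raw(const arma::mat& x, const List& weights,
                     const arma::vec& run_mean, const arma::vec& run_var,
                     int target) {
  Net net = unpack(weights);
  const uword HW = x.n_rows * x.n_cols;
  mat xi(const_cast<double*>(x.memptr()), HW, 1, false);
  Cache cache;
  vec feat = conv_forward(xi, net, &cache);
  const int nfeat = feat.n_elem;
  HeadOut h;
  mat mask(nfeat, 1, arma::fill::ones);
  head_forward(feat, net, mask, false, run_mean, run_var, h);
  // backward from logit 'target' (pre-softmax score)
  vec dZ2(net.b2.n_elem, arma::fill::zeros);
  dZ2(target) = 1.0;
  vec dY = net.W2.t() * dZ2;
  vec denom = arma::sqrt(run_var + net.bn_eps);
  vec dA1 = (dY % net.gamma) / denom;
  vec dZ1 = dA1 % arma::conv_to<vec>::from(h.Z1.col(0) > 0.0);
  vec dP = net.W1.t() * dZ1;
  const int L = (int)net.conv.size();
  // through global max pool to last pooled map
  mat dpool(cache.pooled[L - 1].n_rows, cache.pooled[L - 1].n_cols,
            arma::fill::zeros);
  for (uword c = 0; c < dpool.n_cols; ++c)
    dpool(cache.gmp_idx(c), c) = dP(c);
  // through the last max pool to the conv activation
  const int H = cache.H[L - 1], W = cache.W[L - 1];
  const int C = cache.act[L - 1].n_cols;
  mat dA((uword)H * W, C, arma::fill::zeros);
  const arma::umat& pidx = cache.pidx[L - 1];
  for (uword c = 0; c < dpool.n_cols; ++c)
    for (uword p = 0; p < dpool.n_rows; ++p)
      dA(pidx(p, c), c) += dpool(p, c);
  arma::cube A(H, W, C), G(H, W, C);
  for (int c = 0; c < C; ++c) {
    A.slice(c) = arma::reshape(cache.act[L - 1].col(c), H, W);
    G.slice(c) = arma::reshape(dA.col(c), H, W);
  }
  return List::create(_["A"] = A, _["dA"] = G,
                      _["probs"] = h.probs.col(0),
                      _["logits"] = h.logits.col(0));
}

// Partial forward: from a supplied final-conv activation (post-ReLU cube)
// through the last pool, global max pool and the head, to the logits.
// Used as an independent finite-difference oracle for the Grad-CAM
// gradients.
// [[Rcpp::export]]
arma::vec cnn_logits_from_conv(const arma::cube& A, const List& weights,
                               const arma::vec& run_mean,
                               const arma::vec& run_var) {
  Net net = unpack(weights);
  const int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  mat act((uword)H * W, C);
  for (int c = 0; c < C; ++c)
    act.col(c) = arma::vectorise(A.slice(c));
  mat pooled; arma::umat pidx; int Ho, Wo;
  maxpool(act, H, W, pooled, pidx, Ho, Wo);
  vec feat(C);
  for (int c = 0; c < C; ++c) feat(c) = pooled.col(c).max();
  HeadOut h;
  mat mask(C, 1, arma::fill::ones);
  head_forward(feat, net, mask, false, run_mean, run_var, h);
  return h.logits.col(0);
}
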