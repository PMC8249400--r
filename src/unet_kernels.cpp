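// Fast float32 backend for the package's U-Net.
//
// Mirrors the pure-R reference implementation exactly (same architecture,
// same tensor layout, same batch-norm semantics); the whole forward +
// backward pass of one mini-batch runs in a single call so all
// intermediate activations stay in single precision inside C++.
//
// Tensor layout: a batch of N images of H x W pixels with C channels is an
// arma::fmat with N*H*W rows (sample-major, then row-major pixels) and C
// columns. Convolutions are im2col gathers followed by one sgemm.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::frowvec;
using arma::uword;

typedef arma::Mat<unsigned char> bmat;

static inline int row_index(int n, int i, int j, int H, int W) {
  // 0-based row for sample n, pixel (i, j), all 0-based
  return (n * H + i) * W + j;
}

// 3x3 same-padding im2col: output (R x 9C), offset-major column blocks in
// the order di = -1..1 (outer), dj = -1..1 (inner)
static fmat im2col3(const fmat& X, int H, int W, int N) {
  const int C = X.n_cols;
  fmat out(X.n_rows, 9 * C, arma::fill::zeros);
  int o = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj, ++o) {
      const int js = std::max(0, -dj), je = std::min(W, W - dj); // dest j range
      const int len = je - js;
      if (len <= 0) continue;
      for (int c = 0; c < C; ++c) {
        const float* src = X.colptr(c);
        float* dst = out.colptr(o * C + c);
        for (int n = 0; n < N; ++n) {
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            std::memcpy(dst + row_index(n, i, js, H, W),
                        src + row_index(n, si, js + dj, H, W),
                        len * sizeof(float));
          }
        }
      }
    }
  }
  return out;
}

// adjoint of im2col3: accumulate (R x 9C) gradients back onto (R x C)
static fmat col2im3(const fmat& dXcol, int H, int W, int N, int C) {
  fmat dX(dXcol.n_rows, C, arma::fill::zeros);
  int o = 0;
  for (int di = -1; di <= 1; ++di) {
    for (int dj = -1; dj <= 1; ++dj, ++o) {
      const int js = std::max(0, -dj), je = std::min(W, W - dj);
      const int len = je - js;
      if (len <= 0) continue;
      for (int c = 0; c < C; ++c) {
        const float* src = dXcol.colptr(o * C + c);
        float* dst = dX.colptr(c);
        for (int n = 0; n < N; ++n) {
          for (int i = 0; i < H; ++i) {
            const int si = i + di;
            if (si < 0 || si >= H) continue;
            const float* s = src + row_index(n, i, js, H, W);
            float* d = dst + row_index(n, si, js + dj, H, W);
            for (int t = 0; t < len; ++t) d[t] += s[t];
          }
        }
      }
    }
  }
  return dX;
}

struct ConvCache {
  fmat Xcol;     // im2col of the layer input (reused for the weight grad)
  fmat xhat;     // normalized pre-activation
  frowvec inv_sd;
  bmat mask;     // ReLU mask
  int H, W, N;
};

struct Net {
  List params;   // R-side doubles, read-only
  List stats;    // running BN moments (updated on training passes)
  double bn_momentum, bn_eps;
  bool training;
  std::map<std::string, ConvCache> cache;
  std::map<std::string, fmat> extra;   // upconv inputs, dropout mask, out input
  List grads;

  fmat P(const std::string& nm) {
    return arma::conv_to<fmat>::from(as<arma::mat>(params[nm]));
  }
  frowvec V(const std::string& nm, List& from) {
    return arma::conv_to<frowvec>::from(as<arma::rowvec>(from[nm]));
  }

  fmat conv_bn_relu_fwd(const fmat& X, const std::string& nm,
                        int H, int W, int N) {
    fmat W9 = P(nm + ".W");
    frowvec gamma = V(nm + ".gamma", params), beta = V(nm + ".beta", params);
    fmat Xcol = im2col3(X, H, W, N);
    fmat Y = Xcol * W9;
    const int C = Y.n_cols;
    frowvec mu(C), inv_sd(C);
    fmat xhat;
    if (training) {
      mu = arma::mean(Y, 0);
      Y.each_row() -= mu;
      frowvec v = arma::mean(arma::square(Y), 0);   // population variance
      inv_sd = 1.0f / arma::sqrt(v + (float)bn_eps);
      xhat = std::move(Y);
      xhat.each_row() %= inv_sd;
      arma::rowvec rm = as<arma::rowvec>(stats[nm + ".mean"]);
      arma::rowvec rv = as<arma::rowvec>(stats[nm + ".var"]);
      rm = (1 - bn_momentum) * rm + bn_momentum * arma::conv_to<arma::rowvec>::from(mu);
      rv = (1 - bn_momentum) * rv + bn_momentum * arma::conv_to<arma::rowvec>::from(v);
      stats[nm + ".mean"] = NumericVector(rm.begin(), rm.end());
      stats[nm + ".var"] = NumericVector(rv.begin(), rv.end());
    } else {
      mu = V(nm + ".mean", stats);
      frowvec v = V(nm + ".var", stats);
      inv_sd = 1.0f / arma::sqrt(v + (float)bn_eps);
      xhat = std::move(Y);
      xhat.each_row() -= mu;
      xhat.each_row() %= inv_sd;
    }
    fmat out = xhat;
    out.each_row() %= gamma;
    out.each_row() += beta;
    bmat mask(out.n_rows, out.n_cols);
    float* po = out.memptr();
    unsigned char* pm = mask.memptr();
    const size_t nel = out.n_elem;
    for (size_t t = 0; t < nel; ++t) {
      if (po[t] > 0.0f) pm[t] = 1;
      else { pm[t] = 0; po[t] = 0.0f; }
    }
    if (training) {
      ConvCache cc;
      cc.Xcol = std::move(Xcol); cc.xhat = std::move(xhat); cc.inv_sd = inv_sd;
      cc.mask = std::move(mask); cc.H = H; cc.W = W; cc.N = N;
      cache[nm] = std::move(cc);
    }
    return out;
  }

  fmat conv_bn_relu_bwd(fmat dOut, const std::string& nm) {
    ConvCache& cc = cache[nm];
    fmat W9 = P(nm + ".W");
    frowvec gamma = V(nm + ".gamma", params);
    // ReLU
    float* pd = dOut.memptr();
    const unsigned char* pm = cc.mask.memptr();
    for (size_t t = 0; t < dOut.n_elem; ++t) if (!pm[t]) pd[t] = 0.0f;
    // BN
    frowvec dgamma = arma::sum(dOut % cc.xhat, 0);
    frowvec dbeta = arma::sum(dOut, 0);
    fmat dxhat = dOut;
    dxhat.each_row() %= gamma;
    frowvec m1 = arma::mean(dxhat, 0);
    frowvec m2 = arma::mean(dxhat % cc.xhat, 0);
    fmat dConv = dxhat;
    dConv.each_row() -= m1;
    dConv -= cc.xhat.each_row() % m2;
    dConv.each_row() %= cc.inv_sd;
    // conv
    fmat dW = cc.Xcol.t() * dConv;
    fmat dXcol = dConv * W9.t();
    fmat dX = col2im3(dXcol, cc.H, cc.W, cc.N, cc.Xcol.n_cols / 9);
    cc.Xcol.reset();
    grads[nm + ".W"] = arma::conv_to<arma::mat>::from(dW);
    grads[nm + ".gamma"] = NumericVector(dgamma.begin(), dgamma.end());
    grads[nm + ".beta"] = NumericVector(dbeta.begin(), dbeta.end());
    return dX;
  }
};

// 2x2 max pooling; winner codes 1..4 in position order (1,1),(1,2),(2,1),(2,2)
static fmat maxpool_fwd(const fmat& X, int H, int W, int N, bmat& winner) {
  const int C = X.n_cols, h = H / 2, w = W / 2;
  fmat out(N * h * w, C);
  winner.set_size(N * h * w, C);
  for (int c = 0; c < C; ++c) {
    const float* src = X.colptr(c);
    float* dst = out.colptr(c);
    unsigned char* wn = winner.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int io = 0; io < h; ++io) {
        for (int jo = 0; jo < w; ++jo) {
          const int q = row_index(n, io, jo, h, w);
          float best = src[row_index(n, 2 * io, 2 * jo, H, W)];
          int bk = 1, k = 1;
          for (int a = 0; a < 2; ++a) {
            for (int b = 0; b < 2; ++b, ++k) {
              if (k == 1) continue;
              const float v = src[row_index(n, 2 * io + a, 2 * jo + b, H, W)];
              if (v > best) { best = v; bk = k; }
            }
          }
          dst[q] = best; wn[q] = (unsigned char)bk;
        }
      }
    }
  }
  return out;
}

static fmat maxpool_bwd(const fmat& dY, const bmat& winner,
                        int H, int W, int N) {
  const int C = dY.n_cols, h = H / 2, w = W / 2;
  fmat dX(N * H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* src = dY.colptr(c);
    const unsigned char* wn = winner.colptr(c);
    float* dst = dX.colptr(c);
    for (int n = 0; n < N; ++n) {
      for (int io = 0; io < h; ++io) {
        for (int jo = 0; jo < w; ++jo) {
          const int q = row_index(n, io, jo, h, w);
          const int k = wn[q] - 1;
          const int a = k / 2, b = k % 2;
          dst[row_index(n, 2 * io + a, 2 * jo + b, H, W)] += src[q];
        }
      }
    }
  }
  return dX;
}

// 2x2 stride-2 transposed convolution; Z column blocks ordered as the
// output positions (1,1),(1,2),(2,1),(2,2)
static fmat upconv_scatter(const fmat& Z, int h, int w, int N, int cout) {
  fmat out(N * 4 * h * w, cout);
  const int H = 2 * h, W = 2 * w;
  for (int k = 0; k < 4; ++k) {
    const int a = k / 2, b = k % 2;
    for (int c = 0; c < cout; ++c) {
      const float* src = Z.colptr(k * cout + c);
      float* dst = out.colptr(c);
      for (int n = 0; n < N; ++n)
        for (int io = 0; io < h; ++io)
          for (int jo = 0; jo < w; ++jo)
            dst[row_index(n, 2 * io + a, 2 * jo + b, H, W)] =
              src[row_index(n, io, jo, h, w)];
    }
  }
  return out;
}

static fmat upconv_gather(const fmat& dOut, int h, int w, int N, int cout) {
  fmat dZ(N * h * w, 4 * cout);
  const int H = 2 * h, W = 2 * w;
  for (int k = 0; k < 4; ++k) {
    const int a = k / 2, b = k % 2;
    for (int c = 0; c < cout; ++c) {
      const float* src = dOut.colptr(c);
      float* dst = dZ.colptr(k * cout + c);
      for (int n = 0; n < N; ++n)
        for (int io = 0; io < h; ++io)
          for (int jo = 0; jo < w; ++jo)
            dst[row_index(n, io, jo, h, w)] =
              src[row_index(n, 2 * io + a, 2 * jo + b, H, W)];
    }
  }
  return dZ;
}

static void check_divisible(int H, int W, int depth) {
  const int d = 1 << depth;
  if (H % d != 0 || W % d != 0) {
    stop("input %d x %d not divisible by 2^depth = %d; the encoder cannot pool it",
         H, W, d);
  }
}

// full forward pass; fills net caches when training
static fmat forward_net(Net& net, const fmat& X0, int H, int W, int N,
                        int depth, int base_filters, double dropout_rate,
                        const NumericVector& dropout_u,
                        std::vector<fmat>& skips, std::vector<bmat>& winners) {
  fmat X = X0;
  int curH = H, curW = W;
  skips.resize(depth + 1);
  winners.resize(depth + 1);
  for (int l = 1; l <= depth; ++l) {
    char nm[16];
    snprintf(nm, sizeof(nm), "enc%da", l);
    X = net.conv_bn_relu_fwd(X, nm, curH, curW, N);
    snprintf(nm, sizeof(nm), "enc%db", l);
    X = net.conv_bn_relu_fwd(X, nm, curH, curW, N);
    skips[l] = X;
    bmat wn;
    X = maxpool_fwd(X, curH, curW, N, wn);
    winners[l] = std::move(wn);
    curH /= 2; curW /= 2;
  }
  X = net.conv_bn_relu_fwd(X, "bota", curH, curW, N);
  X = net.conv_bn_relu_fwd(X, "botb", curH, curW, N);
  if (net.training && dropout_rate > 0) {
    const float keep = 1.0f - (float)dropout_rate;
    fmat dmask(X.n_rows, X.n_cols);
    if ((int)dropout_u.size() < (int)X.n_elem) {
      stop("dropout noise vector too short");
    }
    float* pm = dmask.memptr();
    for (size_t t = 0; t < X.n_elem; ++t) {
      pm[t] = (dropout_u[t] < keep) ? 1.0f / keep : 0.0f;
    }
    X %= dmask;
    net.extra["dropout"] = std::move(dmask);
  }
  for (int l = depth; l >= 1; --l) {
    char nm[16];
    const int fl = base_filters << (l - 1);
    snprintf(nm, sizeof(nm), "up%d.W", l);
    fmat Wu = net.P(nm);
    snprintf(nm, sizeof(nm), "up%d.b", l);
    frowvec bu = net.V(nm, net.params);
    if (net.training) {
      char key[16];
      snprintf(key, sizeof(key), "upin%d", l);
      net.extra[key] = X;
    }
    fmat up = upconv_scatter(X * Wu, curH, curW, N, fl);
    up.each_row() += bu;
    curH *= 2; curW *= 2;
    X = arma::join_rows(up, skips[l]);
    snprintf(nm, sizeof(nm), "dec%da", l);
    X = net.conv_bn_relu_fwd(X, nm, curH, curW, N);
    snprintf(nm, sizeof(nm), "dec%db", l);
    X = net.conv_bn_relu_fwd(X, nm, curH, curW, N);
  }
  if (net.training) net.extra["outin"] = X;
  fmat logits = X * net.P("out.W");
  logits.each_row() += net.V("out.b", net.params);
  return logits;
}

//' @noRd
// [[Rcpp::export(name = "cpp_unet_train_batch")]]
List cpp_unet_train_batch(List params, List stats, NumericVector x,
                          IntegerVector y, int H, int W, int N,
                          int depth, int base_filters, double dropout_rate,
                          NumericVector dropout_u,
                          double bn_momentum, double bn_eps) {
  check_divisible(H, W, depth);
  const int R = N * H * W;
  if ((int)x.size() != R || (int)y.size() != R) stop("batch size mismatch");
  fmat X(R, 1);
  for (int t = 0; t < R; ++t) X(t, 0) = (float)x[t];

  Net net;
  net.params = params; net.stats = clone(stats);
  net.bn_momentum = bn_momentum; net.bn_eps = bn_eps;
  net.training = true;
  net.grads = List::create();

  std::vector<fmat> skips; std::vector<bmat> winners;
  fmat logits = forward_net(net, X, H, W, N, depth, base_filters,
                            dropout_rate, dropout_u, skips, winners);

  // softmax cross-entropy over two classes
  double loss = 0; int correct = 0;
  fmat dlogits(R, 2);
  for (int t = 0; t < R; ++t) {
    const float m = std::max(logits(t, 0), logits(t, 1));
    const float e0 = std::exp(logits(t, 0) - m), e1 = std::exp(logits(t, 1) - m);
    const float s = e0 + e1;
    const float p0 = e0 / s, p1 = e1 / s;
    const int cls = y[t] - 1;            // labels 1..2
    loss -= std::log((double)(cls == 0 ? p0 : p1) + 1e-12);
    if ((p1 >= p0 ? 1 : 0) == cls) ++correct;
    dlogits(t, 0) = (p0 - (cls == 0 ? 1.0f : 0.0f)) / R;
    dlogits(t, 1) = (p1 - (cls == 1 ? 1.0f : 0.0f)) / R;
  }
  loss /= R;

  // backward
  fmat Xout = net.extra["outin"];
  fmat dW_out = Xout.t() * dlogits;
  net.grads["out.W"] = arma::conv_to<arma::mat>::from(dW_out);
  {
    frowvec db = arma::sum(dlogits, 0);
    net.grads["out.b"] = NumericVector(db.begin(), db.end());
  }
  fmat dX = dlogits * net.P("out.W").t();

  int curH = H, curW = W;
  for (int l = 1; l <= depth; ++l) {
    char nm[16];
    const int fl = base_filters << (l - 1);
    snprintf(nm, sizeof(nm), "dec%db", l);
    dX = net.conv_bn_relu_bwd(dX, nm);
    snprintf(nm, sizeof(nm), "dec%da", l);
    dX = net.conv_bn_relu_bwd(dX, nm);
    fmat dup = dX.cols(0, fl - 1);
    skips[l] = dX.cols(fl, 2 * fl - 1);  // reuse as skip gradient store
    char key[16];
    snprintf(key, sizeof(key), "upin%d", l);
    fmat Xin = net.extra[key];
    fmat dZ = upconv_gather(dup, curH / 2, curW / 2, N, fl);
    snprintf(nm, sizeof(nm), "up%d.W", l);
    net.grads[nm] = arma::conv_to<arma::mat>::from(fmat(Xin.t() * dZ));
    snprintf(nm, sizeof(nm), "up%d.b", l);
    {
      frowvec db = arma::sum(dup, 0);
      net.grads[nm] = NumericVector(db.begin(), db.end());
    }
    char wnm[16];
    snprintf(wnm, sizeof(wnm), "up%d.W", l);
    dX = dZ * net.P(wnm).t();
    curH /= 2; curW /= 2;
  }
  if (net.extra.count("dropout")) dX %= net.extra["dropout"];
  dX = net.conv_bn_relu_bwd(dX, "botb");
  dX = net.conv_bn_relu_bwd(dX, "bota");
  for (int l = depth; l >= 1; --l) {
    dX = maxpool_bwd(dX, winners[l], curH * 2, curW * 2, N);
    dX += skips[l];
    char nm[16];
    snprintf(nm, sizeof(nm), "enc%db", l);
    dX = net.conv_bn_relu_bwd(dX, nm);
    snprintf(nm, sizeof(nm), "enc%da", l);
    dX = net.conv_bn_relu_bwd(dX, nm);
    curH *= 2; curW *= 2;
  }

  return List::create(_["loss"] = loss,
                      _["accuracy"] = (double)correct / R,
                      _["grads"] = net.grads,
                      _["stats"] = net.stats);
}

//' @noRd
// [[Rcpp::export(name = "cpp_unet_predict")]]
NumericVector cpp_unet_predict(List params, List stats, NumericVector x,
                               int H, int W, int N, int depth,
                               int base_filters, double bn_eps) {
  check_divisible(H, W, depth);
  const int R = N * H * W;
  if ((int)x.size() != R) stop("input size mismatch");
  fmat X(R, 1);
  for (int t = 0; t < R; ++t) X(t, 0) = (float)x[t];
  Net net;
  net.params = params; net.stats = stats;
  net.bn_momentum = 0; net.bn_eps = bn_eps;
  net.training = false;
  std::vector<fmat> skips; std::vector<bmat> winners;
  fmat logits = forward_net(net, X, H, W, N, depth, base_filters,
                            0.0, NumericVector(0), skips, winners);
  NumericVector out(R);
  for (int t = 0; t < R; ++t) {
    const float m = std::max(logits(t, 0), logits(t, 1));
    const float e0 = std::exp(logits(t, 0) - m), e1 = std::exp(logits(t, 1) - m);
    out[t] = (double)(e1 / (e0 + e1));
  }
  return out;
}
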