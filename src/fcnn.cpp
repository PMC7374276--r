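// Fully convolutional counting network: forward, backward and prediction.
//
// Feature maps are stored as N x C matrices (N = H*W pixels, column-major
// pixel index n = col*H + row, matching R's matrix vectorisation), so each
// channel can be viewed as an H x W matrix without copying. A k x k
// convolution is computed as k^2 shifted GEMMs: for each kernel offset the
// shifted input is gathered into a small reusable buffer and multiplied by
// the corresponding weight block. This keeps the working set cache-sized
// (no materialised im2col matrix) while all arithmetic still runs through
// BLAS. All convolutions are stride-1 with zero same-padding, which
// preserves the spatial extent — a requirement of the sum/k^2 count rule.
// Batch normalisation operates per channel over the spatial positions of
// the single input (batch size 1), deterministically at training and
// inference time alike.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double BN_EPS = 1e-5;

// T = X shifted by (dr, dc) with zero fill: T[(r,c), ch] = X[(r+dr, c+dc), ch]
static void shift_extract(const arma::mat& X, arma::mat& T, int H, int W,
                          int dr, int dc) {
  const int C = X.n_cols;
  const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
  const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
  T.zeros();
  if (r1 <= r0 || c1 <= c0) return;
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat src(const_cast<double*>(X.colptr(ch)), H, W, false);
    arma::mat dst(T.colptr(ch), H, W, false, true);
    dst.submat(r0, c0, r1 - 1, c1 - 1) =
        src.submat(r0 + dr, c0 + dc, r1 - 1 + dr, c1 - 1 + dc);
  }
}

// dX[(r+dr, c+dc), ch] += dT[(r,c), ch]  (adjoint of shift_extract)
static void shift_scatter_add(arma::mat& dX, const arma::mat& dT, int H,
                              int W, int dr, int dc) {
  const int C = dX.n_cols;
  const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
  const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
  if (r1 <= r0 || c1 <= c0) return;
  for (int ch = 0; ch < C; ++ch) {
    const arma::mat g(const_cast<double*>(dT.colptr(ch)), H, W, false);
    arma::mat x(dX.colptr(ch), H, W, false, true);
    x.submat(r0 + dr, c0 + dc, r1 - 1 + dr, c1 - 1 + dc) +=
        g.submat(r0, c0, r1 - 1, c1 - 1);
  }
}

// same-padding convolution: Y = sum_o shift_o(X) * W_block(o)
// W is (k*k*cin) x cout; offset order matches blocks of cin rows
static arma::mat conv_forward(const arma::mat& X, const arma::mat& Wm,
                              int H, int W, int k) {
  const int cin = X.n_cols, cout = Wm.n_cols, p = (k - 1) / 2;
  if (k == 1) return X * Wm;
  arma::mat Y(X.n_rows, cout, arma::fill::zeros);
  arma::mat T(X.n_rows, cin);
  int o = 0;
  for (int dc = -p; dc <= p; ++dc)
    for (int dr = -p; dr <= p; ++dr, ++o) {
      shift_extract(X, T, H, W, dr, dc);
      Y += T * Wm.rows((size_t)o * cin, (size_t)(o + 1) * cin - 1);
    }
  return Y;
}

// gradients of a same-padding convolution given dZ (= dL/dY)
static arma::mat conv_backward(const arma::mat& X, const arma::mat& Wm,
                               const arma::mat& dZ, int H, int W, int k,
                               arma::mat& dW) {
  const int cin = X.n_cols, p = (k - 1) / 2;
  dW.set_size(arma::size(Wm));
  if (k == 1) {
    dW = X.t() * dZ;
    return dZ * Wm.t();
  }
  arma::mat dX(X.n_rows, cin, arma::fill::zeros);
  arma::mat T(X.n_rows, cin);
  int o = 0;
  for (int dc = -p; dc <= p; ++dc)
    for (int dr = -p; dr <= p; ++dr, ++o) {
      shift_extract(X, T, H, W, dr, dc);
      const arma::span rows((size_t)o * cin, (size_t)(o + 1) * cin - 1);
      dW(rows, arma::span::all) = T.t() * dZ;
      shift_scatter_add(dX, dZ * Wm.rows((size_t)o * cin,
                                         (size_t)(o + 1) * cin - 1).t(),
                        H, W, dr, dc);
    }
  return dX;
}

// spatial batch-norm forward; returns normalised x_hat and writes y in place
struct BnCache { arma::mat xhat; arma::rowvec inv_std, mu, var; };

static BnCache bn_forward(arma::mat& Z, const arma::rowvec& gamma,
                          const arma::rowvec& beta) {
  BnCache c;
  const arma::rowvec mu = arma::mean(Z, 0);
  const arma::rowvec var = arma::var(Z, 1, 0);  // population variance
  c.mu = mu;
  c.var = var;
  c.inv_std = 1.0 / arma::sqrt(var + BN_EPS);
  Z.each_row() -= mu;
  Z.each_row() %= c.inv_std;
  c.xhat = Z;
  Z.each_row() %= gamma;
  Z.each_row() += beta;
  return c;
}

static arma::mat bn_backward(const arma::mat& dZ2, const BnCache& c,
                             const arma::rowvec& gamma, arma::rowvec& dgamma,
                             arma::rowvec& dbeta) {
  const double N = (double)dZ2.n_rows;
  dgamma = arma::sum(dZ2 % c.xhat, 0);
  dbeta = arma::sum(dZ2, 0);
  arma::mat dxhat = dZ2;
  dxhat.each_row() %= gamma;
  const arma::rowvec m1 = arma::sum(dxhat, 0) / N;
  const arma::rowvec m2 = arma::sum(dxhat % c.xhat, 0) / N;
  arma::mat dZ = dxhat;
  dZ.each_row() -= m1;
  dZ -= c.xhat.each_row() % m2;
  dZ.each_row() %= c.inv_std;
  return dZ;
}

// inference-mode batch-norm with frozen running statistics
static void bn_forward_frozen(arma::mat& Z, const arma::rowvec& gamma,
                              const arma::rowvec& beta,
                              const arma::rowvec& mu,
                              const arma::rowvec& var) {
  const arma::rowvec inv_std = 1.0 / arma::sqrt(var + BN_EPS);
  Z.each_row() -= mu;
  Z.each_row() %= inv_std;
  Z.each_row() %= gamma;
  Z.each_row() += beta;
}

struct LayerCache {
  arma::mat in;   // layer input activation
  BnCache bn;
  arma::umat relu_mask;
};

// One network evaluation. `layers` is a list of lists with fields
//   type ("conv"/"incep"), k, cin, cout, bn, relu   (conv)
//   cin, out1, out3                                  (incep; bn+relu fixed)
// `params` is the flat parameter list (see R/fcnn_model.R for the layout).
// When `bn_state` is non-null the batch-norm layers use those frozen
// running statistics (inference mode, strictly local receptive field);
// otherwise they normalise by the statistics of the current input
// (training mode) and the caches record them.
static arma::mat forward_pass(const List& layers, const List& params,
                              const arma::mat& x0, int H, int W,
                              std::vector<LayerCache>* caches,
                              const List* bn_state) {
  arma::mat act = x0;
  int pi = 0, bi = 0;
  for (int li = 0; li < layers.size(); ++li) {
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    LayerCache cache;
    if (caches) cache.in = act;
    if (type == "conv") {
      const int k = as<int>(ly["k"]);
      const bool bn = as<bool>(ly["bn"]), relu = as<bool>(ly["relu"]);
      const arma::mat Wm = as<arma::mat>(params[pi++]);
      const arma::rowvec b = as<arma::rowvec>(params[pi++]);
      arma::mat Z = conv_forward(act, Wm, H, W, k);
      Z.each_row() += b;
      if (bn) {
        const arma::rowvec gamma = as<arma::rowvec>(params[pi++]);
        const arma::rowvec beta = as<arma::rowvec>(params[pi++]);
        if (bn_state) {
          List st = (*bn_state)[bi++];
          bn_forward_frozen(Z, gamma, beta, as<arma::rowvec>(st["mean"]),
                            as<arma::rowvec>(st["var"]));
        } else {
          cache.bn = bn_forward(Z, gamma, beta);
          ++bi;
        }
      }
      if (relu) {
        cache.relu_mask = (Z > 0);
        Z.elem(arma::find(cache.relu_mask == 0)).zeros();
      }
      act = Z;
    } else {  // inception: parallel 1x1 and 3x3, concat, BN, ReLU
      const arma::mat W1 = as<arma::mat>(params[pi++]);
      const arma::rowvec b1 = as<arma::rowvec>(params[pi++]);
      const arma::mat W3 = as<arma::mat>(params[pi++]);
      const arma::rowvec b3 = as<arma::rowvec>(params[pi++]);
      const arma::rowvec gamma = as<arma::rowvec>(params[pi++]);
      const arma::rowvec beta = as<arma::rowvec>(params[pi++]);
      arma::mat Z1 = act * W1;
      Z1.each_row() += b1;
      arma::mat Z3 = conv_forward(act, W3, H, W, 3);
      Z3.each_row() += b3;
      arma::mat Z = arma::join_rows(Z1, Z3);
      if (bn_state) {
        List st = (*bn_state)[bi++];
        bn_forward_frozen(Z, gamma, beta, as<arma::rowvec>(st["mean"]),
                          as<arma::rowvec>(st["var"]));
      } else {
        cache.bn = bn_forward(Z, gamma, beta);
        ++bi;
      }
      cache.relu_mask = (Z > 0);
      Z.elem(arma::find(cache.relu_mask == 0)).zeros();
      act = Z;
    }
    if (caches) (*caches)[li] = std::move(cache);
  }
  return act;
}

// [[Rcpp::export(name = ".cpp_fcnn_predict")]]
NumericVector cpp_fcnn_predict(List layers, List params, NumericMatrix x,
                               int H, int W,
                               Nullable<List> bn_state = R_NilValue) {
  const arma::mat x0(x.begin(), x.nrow(), x.ncol());
  List st;
  const List* stp = nullptr;
  if (bn_state.isNotNull()) { st = bn_state.get(); stp = &st; }
  arma::mat out = forward_pass(layers, params, x0, H, W, nullptr, stp);
  return wrap(arma::vec(out.col(0)));
}

// Loss = mean pixel error (L1 or L2) + count_weight * (count error)^2,
// where the count error is the summed map difference over kernel_area.
// The count term directly penalises the integral bias that a per-pixel
// loss is nearly blind to (a one-cell bias spread over a tile moves each
// pixel by ~1e-1), and makes validation-based model selection sensitive
// to exactly the quantity the method reports.
// [[Rcpp::export(name = ".cpp_fcnn_loss")]]
double cpp_fcnn_loss(List layers, List params, NumericMatrix x,
                     NumericVector target, int H, int W,
                     std::string loss_type,
                     Nullable<List> bn_state = R_NilValue,
                     double count_weight = 0, double kernel_area = 1) {
  const arma::mat x0(x.begin(), x.nrow(), x.ncol());
  List st;
  const List* stp = nullptr;
  if (bn_state.isNotNull()) { st = bn_state.get(); stp = &st; }
  arma::mat out = forward_pass(layers, params, x0, H, W, nullptr, stp);
  const arma::vec t(target.begin(), target.size());
  const arma::vec d = out.col(0) - t;
  double loss = (loss_type == "l2") ? arma::mean(arma::square(d))
                                    : arma::mean(arma::abs(d));
  if (count_weight > 0) {
    const double cerr = arma::accu(d) / kernel_area;
    loss += count_weight * cerr * cerr;
  }
  return loss;
}

// Forward + backward for one training example; returns the loss and the
// gradient list in the same flat order as `params`.
// [[Rcpp::export(name = ".cpp_fcnn_grad")]]
List cpp_fcnn_grad(List layers, List params, NumericMatrix x,
                   NumericVector target, int H, int W,
                   std::string loss_type,
                   double count_weight = 0, double kernel_area = 1) {
  const arma::mat x0(x.begin(), x.nrow(), x.ncol());
  const int L = layers.size();
  std::vector<LayerCache> caches(L);
  arma::mat out = forward_pass(layers, params, x0, H, W, &caches, nullptr);

  const arma::vec t(target.begin(), target.size());
  const arma::vec d = out.col(0) - t;
  const double N = (double)d.n_elem;
  double loss;
  arma::mat dAct(d.n_elem, 1);
  if (loss_type == "l2") {
    loss = arma::mean(arma::square(d));
    dAct.col(0) = 2.0 * d / N;
  } else {
    loss = arma::mean(arma::abs(d));
    dAct.col(0) = arma::sign(d) / N;
  }
  if (count_weight > 0) {
    const double cerr = arma::accu(d) / kernel_area;
    loss += count_weight * cerr * cerr;
    dAct.col(0) += count_weight * 2.0 * cerr / kernel_area;
  }

  // parameter offsets per layer
  std::vector<int> offs(L);
  int pi = 0;
  for (int li = 0; li < L; ++li) {
    offs[li] = pi;
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    if (type == "conv")
      pi += 2 + (as<bool>(ly["bn"]) ? 2 : 0);
    else
      pi += 6;
  }
  List grads(pi);

  for (int li = L - 1; li >= 0; --li) {
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    LayerCache& c = caches[li];
    int o = offs[li];
    if (type == "conv") {
      const int k = as<int>(ly["k"]);
      const bool bn = as<bool>(ly["bn"]), relu = as<bool>(ly["relu"]);
      const arma::mat Wm = as<arma::mat>(params[o]);
      if (relu) dAct.elem(arma::find(c.relu_mask == 0)).zeros();
      arma::mat dZ;
      if (bn) {
        const arma::rowvec gamma = as<arma::rowvec>(params[o + 2]);
        arma::rowvec dgamma, dbeta;
        dZ = bn_backward(dAct, c.bn, gamma, dgamma, dbeta);
        grads[o + 2] = wrap(dgamma);
        grads[o + 3] = wrap(dbeta);
      } else {
        dZ = dAct;
      }
      grads[o + 1] = wrap(arma::rowvec(arma::sum(dZ, 0)));
      arma::mat dW;
      dAct = conv_backward(c.in, Wm, dZ, H, W, k, dW);
      grads[o] = wrap(dW);
    } else {
      const int out1 = as<int>(ly["out1"]);
      const arma::mat W1 = as<arma::mat>(params[o]);
      const arma::mat W3 = as<arma::mat>(params[o + 2]);
      const arma::rowvec gamma = as<arma::rowvec>(params[o + 4]);
      dAct.elem(arma::find(c.relu_mask == 0)).zeros();
      arma::rowvec dgamma, dbeta;
      arma::mat dZ = bn_backward(dAct, c.bn, gamma, dgamma, dbeta);
      grads[o + 4] = wrap(dgamma);
      grads[o + 5] = wrap(dbeta);
      arma::mat dZ1 = dZ.cols(0, out1 - 1);
      arma::mat dZ3 = dZ.cols(out1, dZ.n_cols - 1);
      grads[o] = wrap(arma::mat(c.in.t() * dZ1));
      grads[o + 1] = wrap(arma::rowvec(arma::sum(dZ1, 0)));
      arma::mat dW3;
      arma::mat dX3 = conv_backward(c.in, W3, dZ3, H, W, 3, dW3);
      grads[o + 2] = wrap(dW3);
      grads[o + 3] = wrap(arma::rowvec(arma::sum(dZ3, 0)));
      dAct = dZ1 * W1.t() + dX3;
    }
  }
  // batch statistics of every BN layer, in layer order, for running-stat
  // updates on the R side
  List bn_batch;
  for (int li = 0; li < L; ++li) {
    List ly = layers[li];
    std::string type = as<std::string>(ly["type"]);
    const bool has_bn = (type == "incep") || as<bool>(ly["bn"]);
    if (has_bn)
      bn_batch.push_back(List::create(Named("mean") = wrap(caches[li].bn.mu),
                                      Named("var") = wrap(caches[li].bn.var)));
  }
  return List::create(Named("loss") = loss, Named("grads") = grads,
                      Named("bn_batch") = bn_batch);
}
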