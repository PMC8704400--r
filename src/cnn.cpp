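// Single-precision 1D CNN engine: im2col + GEMM convolutions, max
// pooling, global average pooling, dense layers, softmax
// cross-entropy, Adam. Layers arrive from R as a list of lists; the
// training loop runs entirely in C++ so the per-batch cost is GEMM
// bound. Deterministic given the seed (single-threaded shuffling,
// fixed accumulation order).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

enum LayerKind { CONV, MAXPOOL, GAP, FLATTEN, DENSE };

struct Layer {
  LayerKind kind = CONV;
  fmat W;          // conv: Cout x (k*Cin); dense: out x in
  fvec b;
  int kernel = 3;  // conv only (odd)
  int pool = 2;    // maxpool only
  bool relu = true;
  bool trainable = true;
  // caches (per forward pass)
  fmat cols;       // conv: im2col of input
  fmat a_in;       // dense: input activations
  fmat a_out;      // post-activation output (relu mask)
  umat argmax;     // maxpool selector (0/1)
  int L_in = 0, L_out = 0;
  // gradients and Adam state
  fmat dW, mW, vW;
  fvec db, mb, vb;
};

static std::vector<Layer> parse_layers(const List& layers) {
  std::vector<Layer> net;
  for (int i = 0; i < layers.size(); ++i) {
    List ll = layers[i];
    std::string kind = as<std::string>(ll["kind"]);
    Layer lay;
    if (kind == "conv") {
      lay.kind = CONV;
      lay.W = as<fmat>(wrap(as<NumericMatrix>(ll["W"])));
      lay.b = arma::conv_to<fvec>::from(as<arma::vec>(ll["b"]));
      lay.kernel = as<int>(ll["kernel"]);
      if (lay.kernel % 2 == 0) stop("conv kernel must be odd");
    } else if (kind == "maxpool") {
      lay.kind = MAXPOOL;
      lay.pool = as<int>(ll["size"]);
      if (lay.pool != 2) stop("only pool size 2 is supported");
    } else if (kind == "gap") {
      lay.kind = GAP;
    } else if (kind == "flatten") {
      lay.kind = FLATTEN;
    } else if (kind == "dense") {
      lay.kind = DENSE;
      lay.W = as<fmat>(wrap(as<NumericMatrix>(ll["W"])));
      lay.b = arma::conv_to<fvec>::from(as<arma::vec>(ll["b"]));
      lay.relu = as<std::string>(ll["activation"]) == "relu";
    } else {
      stop("unknown layer kind: " + kind);
    }
    if (ll.containsElementNamed("trainable"))
      lay.trainable = as<bool>(ll["trainable"]);
    net.push_back(std::move(lay));
  }
  return net;
}

// Gather a batch into (C x L*B) channel-major activation blocks.
static fmat gather_batch(const NumericVector& X, int L, int C,
                         const std::vector<int>& idx) {
  const int B = (int)idx.size();
  fmat A(C, (size_t)L * B);
  const double* px = X.begin();
  for (int b = 0; b < B; ++b) {
    const double* ps = px + (size_t)idx[b] * L * C;
    for (int c = 0; c < C; ++c)
      for (int l = 0; l < L; ++l)
        A(c, (size_t)b * L + l) = (float)ps[l + (size_t)L * c];
  }
  return A;
}

static void im2col(const fmat& A, int L, int B, int k, fmat& cols) {
  const int C = A.n_rows, pad = (k - 1) / 2;
  cols.zeros((size_t)k * C, (size_t)L * B);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * L;
    for (int j = 0; j < k; ++j) {
      const int d = j - pad;            // input offset for tap j
      const int l0 = std::max(0, -d), l1 = std::min(L, L - d);
      if (l1 <= l0) continue;
      cols.submat(j * C, off + l0, (j + 1) * C - 1, off + l1 - 1) =
        A.cols(off + l0 + d, off + l1 - 1 + d);
    }
  }
}

static void col2im(const fmat& dcols, int L, int B, int k, int C,
                   fmat& dA) {
  const int pad = (k - 1) / 2;
  dA.zeros(C, (size_t)L * B);
  for (int b = 0; b < B; ++b) {
    const size_t off = (size_t)b * L;
    for (int j = 0; j < k; ++j) {
      const int d = j - pad;
      const int l0 = std::max(0, -d), l1 = std::min(L, L - d);
      if (l1 <= l0) continue;
      dA.cols(off + l0 + d, off + l1 - 1 + d) +=
        dcols.submat(j * C, off + l0, (j + 1) * C - 1, off + l1 - 1);
    }
  }
}

// Forward through all layers; returns logits (n_out x B).
static fmat forward(std::vector<Layer>& net, fmat A, int L, int B,
                    bool keep) {
  for (auto& lay : net) {
    switch (lay.kind) {
    case CONV: {
      lay.L_in = L; lay.L_out = L;
      fmat cols;
      im2col(A, L, B, lay.kernel, cols);
      fmat Z = lay.W * cols;
      Z.each_col() += lay.b;
      Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      if (keep) { lay.cols = std::move(cols); lay.a_out = Z; }
      A = std::move(Z);
      break;
    }
    case MAXPOOL: {
      lay.L_in = L;
      const int Lo = L / 2;
      lay.L_out = Lo;
      const int C = A.n_rows;
      fmat O(C, (size_t)Lo * B);
      umat am(C, (size_t)Lo * B);
      for (int b = 0; b < B; ++b) {
        for (int l = 0; l < Lo; ++l) {
          const size_t c0 = (size_t)b * L + 2 * l;
          const size_t co = (size_t)b * Lo + l;
          for (int c = 0; c < C; ++c) {
            const float v0 = A(c, c0), v1 = A(c, c0 + 1);
            if (v0 >= v1) { O(c, co) = v0; am(c, co) = 0; }
            else          { O(c, co) = v1; am(c, co) = 1; }
          }
        }
      }
      if (keep) lay.argmax = std::move(am);
      A = std::move(O);
      L = Lo;
      break;
    }
    case GAP: {
      lay.L_in = L; lay.L_out = 1;
      const int C = A.n_rows;
      fmat O(C, B);
      for (int b = 0; b < B; ++b)
        O.col(b) = arma::mean(A.cols((size_t)b * L,
                                     (size_t)b * L + L - 1), 1);
      A = std::move(O);
      L = 1;
      break;
    }
    case FLATTEN: {
      lay.L_in = L; lay.L_out = 1;
      const int C = A.n_rows;
      fmat O((size_t)C * L, B);
      for (int b = 0; b < B; ++b)
        O.col(b) = arma::vectorise(A.cols((size_t)b * L,
                                          (size_t)b * L + L - 1));
      A = std::move(O);
      L = 1;
      break;
    }
    case DENSE: {
      lay.L_in = 1; lay.L_out = 1;
      if (keep) lay.a_in = A;
      fmat Z = lay.W * A;
      Z.each_col() += lay.b;
      if (lay.relu)
        Z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      if (keep) lay.a_out = Z;
      A = std::move(Z);
      break;
    }
    }
  }
  return A;
}

static fmat softmax_cols(fmat Z) {
  for (arma::uword j = 0; j < Z.n_cols; ++j) {
    fvec c = Z.col(j);
    c -= c.max();
    c = arma::exp(c);
    Z.col(j) = c / arma::accu(c);
  }
  return Z;
}

// Backward from dLogits; fills lay.dW / lay.db for trainable layers.
static void backward(std::vector<Layer>& net, fmat dA, int B) {
  for (int i = (int)net.size() - 1; i >= 0; --i) {
    Layer& lay = net[i];
    switch (lay.kind) {
    case DENSE: {
      if (lay.relu) {
        const float* po = lay.a_out.memptr();
        float* pd = dA.memptr();
        const size_t n = dA.n_elem;
        for (size_t e = 0; e < n; ++e) if (po[e] <= 0.0f) pd[e] = 0.0f;
      }
      lay.dW = dA * lay.a_in.t();
      lay.db = arma::sum(dA, 1);
      dA = lay.W.t() * dA;
      lay.a_in.reset();
      break;
    }
    case FLATTEN: {
      const int L = lay.L_in;
      const int C = dA.n_rows / L;
      fmat O(C, (size_t)L * B);
      for (int b = 0; b < B; ++b) {
        fvec v = dA.col(b);
        O.cols((size_t)b * L, (size_t)b * L + L - 1) =
          arma::reshape(v, C, L);
      }
      dA = std::move(O);
      break;
    }
    case GAP: {
      const int L = lay.L_in;
      const int C = dA.n_rows;
      fmat O(C, (size_t)L * B);
      for (int b = 0; b < B; ++b) {
        fvec g = dA.col(b) / (float)L;
        for (int l = 0; l < L; ++l) O.col((size_t)b * L + l) = g;
      }
      dA = std::move(O);
      break;
    }
    case MAXPOOL: {
      const int L = lay.L_in, Lo = lay.L_out;
      const int C = dA.n_rows;
      fmat O(C, (size_t)L * B, arma::fill::zeros);
      for (int b = 0; b < B; ++b)
        for (int l = 0; l < Lo; ++l) {
          const size_t co = (size_t)b * Lo + l;
          const size_t c0 = (size_t)b * L + 2 * l;
          for (int c = 0; c < C; ++c)
            O(c, c0 + lay.argmax(c, co)) = dA(c, co);
        }
      dA = std::move(O);
      break;
    }
    case CONV: {
      {
        const float* po = lay.a_out.memptr();
        float* pd = dA.memptr();
        const size_t n = dA.n_elem;
        for (size_t e = 0; e < n; ++e) if (po[e] <= 0.0f) pd[e] = 0.0f;
      }
      lay.dW = dA * lay.cols.t();
      lay.db = arma::sum(dA, 1);
      if (i > 0) {
        fmat dcols = lay.W.t() * dA;
        const int Cin = lay.W.n_cols / lay.kernel;
        fmat dX;
        col2im(dcols, lay.L_in, B, lay.kernel, Cin, dX);
        dA = std::move(dX);
      }
      lay.cols.reset();
      lay.a_out.reset();
      break;
    }
    }
  }
}

static List export_layers(const List& layers,
                          const std::vector<Layer>& net) {
  List out = clone(layers);
  for (size_t i = 0; i < net.size(); ++i) {
    if (net[i].kind == CONV || net[i].kind == DENSE) {
      List ll = out[i];
      ll["W"] = wrap(arma::conv_to<arma::mat>::from(net[i].W));
      ll["b"] = wrap(arma::conv_to<arma::vec>::from(net[i].b));
      out[i] = ll;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_cnn_train(List layers, NumericVector X, IntegerVector y,
                   int n_classes, int epochs, int batch_size,
                   double lr, int seed, bool shuffle = true,
                   double beta1 = 0.9, double beta2 = 0.999,
                   double adam_eps = 1e-8) {
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 3) stop("X must be a (length, channels, n) array");
  const int L = dims[0], C = dims[1], N = dims[2];
  if (y.size() != N) stop("label length mismatch");
  std::vector<Layer> net = parse_layers(layers);
  for (auto& lay : net)
    if (lay.kind == CONV || lay.kind == DENSE) {
      lay.mW.zeros(lay.W.n_rows, lay.W.n_cols);
      lay.vW.zeros(lay.W.n_rows, lay.W.n_cols);
      lay.mb.zeros(lay.b.n_elem);
      lay.vb.zeros(lay.b.n_elem);
    }
  std::mt19937 gen((unsigned)seed);
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  NumericVector loss_hist(epochs);
  long t = 0;
  const float f1 = (float)beta1, f2 = (float)beta2;
  const float feps = (float)adam_eps;
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) std::shuffle(ord.begin(), ord.end(), gen);
    double ep_loss = 0.0;
    int n_batch = 0;
    for (int s = 0; s < N; s += batch_size) {
      const int B = std::min(batch_size, N - s);
      std::vector<int> idx(ord.begin() + s, ord.begin() + s + B);
      fmat A = gather_batch(X, L, C, idx);
      fmat logits = forward(net, std::move(A), L, B, true);
      fmat P = softmax_cols(logits);
      double loss = 0.0;
      for (int b = 0; b < B; ++b)
        loss -= std::log(std::max(P(y[idx[b]], b), 1e-12f));
      loss /= B;
      ep_loss += loss;
      ++n_batch;
      // dLogits = (P - onehot)/B
      for (int b = 0; b < B; ++b) P(y[idx[b]], b) -= 1.0f;
      P /= (float)B;
      backward(net, std::move(P), B);
      ++t;
      const float bc1 = 1.0f - std::pow(f1, (float)t);
      const float bc2 = 1.0f - std::pow(f2, (float)t);
      const float alpha = (float)lr * std::sqrt(bc2) / bc1;
      for (auto& lay : net) {
        if ((lay.kind != CONV && lay.kind != DENSE) || !lay.trainable)
          continue;
        lay.mW = f1 * lay.mW + (1.0f - f1) * lay.dW;
        lay.vW = f2 * lay.vW + (1.0f - f2) * arma::square(lay.dW);
        lay.W -= alpha * lay.mW / (arma::sqrt(lay.vW) + feps);
        lay.mb = f1 * lay.mb + (1.0f - f1) * lay.db;
        lay.vb = f2 * lay.vb + (1.0f - f2) * arma::square(lay.db);
        lay.b -= alpha * lay.mb / (arma::sqrt(lay.vb) + feps);
      }
    }
    loss_hist[ep] = ep_loss / n_batch;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["layers"] = export_layers(layers, net),
                      _["loss"] = loss_hist);
}

// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(List layers, NumericVector X,
                              int batch_size = 256) {
  IntegerVector dims = X.attr("dim");
  if (dims.size() != 3) stop("X must be a (length, channels, n) array");
  const int L = dims[0], C = dims[1], N = dims[2];
  std::vector<Layer> net = parse_layers(layers);
  NumericMatrix out;
  bool first = true;
  for (int s = 0; s < N; s += batch_size) {
    const int B = std::min(batch_size, N - s);
    std::vector<int> idx(B);
    for (int b = 0; b < B; ++b) idx[b] = s + b;
    fmat A = gather_batch(X, L, C, idx);
    fmat P = softmax_cols(forward(net, std::move(A), L, B, false));
    if (first) { out = NumericMatrix(N, P.n_rows); first = false; }
    for (int b = 0; b < B; ++b)
      for (arma::uword k = 0; k < P.n_rows; ++k)
        out(s + b, k) = P(k, b);
  }
  return out;
}

// Analytic loss and gradients on one fixed batch (for gradient
// checking and unit tests; not used in training).
// [[Rcpp::export]]
List cpp_cnn_grad(List layers, NumericVector X, IntegerVector y,
                  int n_classes) {
  IntegerVector dims = X.attr("dim");
  const int L = dims[0], C = dims[1], N = dims[2];
  std::vector<Layer> net = parse_layers(layers);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  fmat A = gather_batch(X, L, C, idx);
  fmat P = softmax_cols(forward(net, std::move(A), L, N, true));
  double loss = 0.0;
  for (int b = 0; b < N; ++b)
    loss -= std::log(std::max(P(y[b], b), 1e-12f));
  loss /= N;
  for (int b = 0; b < N; ++b) P(y[b], b) -= 1.0f;
  P /= (float)N;
  backward(net, std::move(P), N);
  List grads(layers.size());
  for (size_t i = 0; i < net.size(); ++i) {
    if (net[i].kind == CONV || net[i].kind == DENSE) {
      grads[i] = List::create(
        _["dW"] = wrap(arma::conv_to<arma::mat>::from(net[i].dW)),
        _["db"] = wrap(arma::conv_to<arma::vec>::from(net[i].db)));
    }
  }
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
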