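// 1D convolutional network for metapixel spectra: forward/backward passes,
// Adam training loop, and input-gradient computation for integrated
// gradients. Single precision + im2col/BLAS; all randomness (init, batch
// order, dropout) comes from a caller-supplied seed, so runs are
// reproducible bit-for-bit in a fixed environment.
//
// Activations are held as (channels, length * batch) matrices throughout:
// a window of kernel columns inside one item is contiguous in that layout,
// so im2col is a straight memcpy per output position, kernel-1/stride-1
// layers need no im2col at all, and the flatten before the head is a free
// reinterpretation.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using arma::fmat;
using arma::fvec;

namespace {

struct NetSpec {
  std::vector<int> F, K, S;   // filters, kernel, stride per conv layer
  std::vector<int> Lout;      // output length per conv layer
  int C0, L0, ncls;
  int nconv() const { return (int)F.size(); }
  int flat_dim() const { return F.back() * Lout.back(); }
  bool unit(int l) const { return K[l] == 1 && S[l] == 1; }
  int Cin(int l) const { return l == 0 ? C0 : F[l - 1]; }
  int Lin(int l) const { return l == 0 ? L0 : Lout[l - 1]; }
};

// the training loop recycles multi-MB activation buffers every minibatch;
// keeping them on the heap (instead of mmap-backed, returned to the kernel
// on free) avoids repeated page-fault zeroing
void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
    done = true;
  }
#endif
}

NetSpec make_spec(const Rcpp::IntegerMatrix& layers, int C0, int L0, int ncls) {
  NetSpec s;
  s.C0 = C0; s.L0 = L0; s.ncls = ncls;
  int L = L0;
  for (int i = 0; i < layers.nrow(); ++i) {
    int f = layers(i, 0), k = layers(i, 1), st = layers(i, 2);
    if (f < 1 || k < 1 || st < 1) Rcpp::stop("invalid layer spec at layer %d", i + 1);
    if (L < k) Rcpp::stop("input length %d shorter than kernel %d at layer %d", L, k, i + 1);
    int lo = (L - k) / st + 1;
    s.F.push_back(f); s.K.push_back(k); s.S.push_back(st); s.Lout.push_back(lo);
    L = lo;
  }
  return s;
}

struct Net {
  NetSpec spec;
  std::vector<fmat> W;   // (F x C_in*K)
  std::vector<fvec> b;
  fmat fcW;              // (ncls x flat)
  fvec fcb;
};

Net net_from_r(const Rcpp::List& weights, const Rcpp::IntegerMatrix& layers,
               int C0, int L0, int ncls) {
  Net net;
  net.spec = make_spec(layers, C0, L0, ncls);
  int n = net.spec.nconv();
  for (int l = 0; l < n; ++l) {
    arma::mat W = weights["W" + std::to_string(l + 1)];
    arma::vec b = weights["b" + std::to_string(l + 1)];
    net.W.push_back(arma::conv_to<fmat>::from(W));
    net.b.push_back(arma::conv_to<fvec>::from(b));
  }
  arma::mat fw = weights["fcW"];
  arma::vec fb = weights["fcb"];
  net.fcW = arma::conv_to<fmat>::from(fw);
  net.fcb = arma::conv_to<fvec>::from(fb);
  return net;
}

Rcpp::List net_to_r(const Net& net) {
  Rcpp::List out;
  for (int l = 0; l < net.spec.nconv(); ++l) {
    out["W" + std::to_string(l + 1)] =
      Rcpp::wrap(arma::conv_to<arma::mat>::from(net.W[l]));
    out["b" + std::to_string(l + 1)] =
      Rcpp::wrap(arma::conv_to<arma::vec>::from(net.b[l]));
  }
  out["fcW"] = Rcpp::wrap(arma::conv_to<arma::mat>::from(net.fcW));
  out["fcb"] = Rcpp::wrap(arma::conv_to<arma::vec>::from(net.fcb));
  return out;
}

// A is (C, Lin*B); output (C*k, Lout*B); kernel windows are contiguous
fmat im2col(const fmat& A, int C, int Lin, int k, int s, int Lout, int B) {
  fmat out(C * k, (size_t)Lout * B);
  const size_t bytes = sizeof(float) * C * k;
  for (int bb = 0; bb < B; ++bb) {
    for (int t = 0; t < Lout; ++t) {
      std::memcpy(out.colptr((size_t)bb * Lout + t),
                  A.colptr((size_t)bb * Lin + (size_t)t * s), bytes);
    }
  }
  return out;
}

void col2im_add(fmat& dA, const fmat& dcol, int C, int Lin, int k, int s,
                int Lout, int B) {
  const int n = C * k;
  for (int bb = 0; bb < B; ++bb) {
    for (int t = 0; t < Lout; ++t) {
      const float* src = dcol.colptr((size_t)bb * Lout + t);
      float* dst = dA.colptr((size_t)bb * Lin + (size_t)t * s);
      for (int j = 0; j < n; ++j) dst[j] += src[j];
    }
  }
}

struct FwdCache {
  int B = 0;
  std::vector<fmat> acts;    // acts[0] = input, acts[l+1] = output of conv l
  std::vector<fmat> cols;    // im2col buffers (empty for kernel-1 layers)
  fmat flat;                 // flattened (masked) features entering the head
  fmat mask;                 // dropout mask (empty in eval mode)
  fmat logits;               // (ncls x B)
};

// ReLU after every conv layer except the last
void forward(const Net& net, const fmat& X, int B, FwdCache& c,
             bool train, double dropout, std::mt19937_64* gen) {
  const NetSpec& sp = net.spec;
  c.B = B;
  c.acts.assign(1, X);
  c.cols.assign(sp.nconv(), fmat());
  for (int l = 0; l < sp.nconv(); ++l) {
    const fmat* src = &c.acts[l];
    if (!sp.unit(l)) {
      c.cols[l] = im2col(c.acts[l], sp.Cin(l), sp.Lin(l), sp.K[l], sp.S[l],
                         sp.Lout[l], B);
      src = &c.cols[l];
    }
    fmat Y = net.W[l] * (*src);
    Y.each_col() += net.b[l];
    if (l < sp.nconv() - 1) {
      float* p = Y.memptr();
      const size_t n = Y.n_elem;
      for (size_t j = 0; j < n; ++j) if (p[j] < 0.0f) p[j] = 0.0f;
    }
    c.acts.push_back(std::move(Y));
  }
  // (F, Lout*B) and (F*Lout, B) share the same linear layout
  c.flat = fmat(c.acts.back().memptr(), sp.flat_dim(), B);
  if (train && dropout > 0) {
    const float q = 1.0f - (float)dropout;
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    c.mask.set_size(sp.flat_dim(), B);
    for (arma::uword j = 0; j < c.mask.n_elem; ++j) {
      c.mask(j) = unif(*gen) < q ? 1.0f / q : 0.0f;
    }
    c.flat %= c.mask;
  } else {
    c.mask.reset();
  }
  c.logits = net.fcW * c.flat;
  c.logits.each_col() += net.fcb;
}

fmat softmax_cols(const fmat& logits) {
  fmat p = logits;
  for (arma::uword j = 0; j < p.n_cols; ++j) {
    fvec col = p.col(j);
    col -= col.max();
    col = arma::exp(col);
    p.col(j) = col / arma::accu(col);
  }
  return p;
}

struct Grads {
  std::vector<fmat> dW;
  std::vector<fvec> db;
  fmat dfcW;
  fvec dfcb;
};

// backprop from dlogits; fills parameter grads (if g != nullptr) and
// returns gradient w.r.t. the input matrix (if want_dx)
fmat backward(const Net& net, const FwdCache& c, const fmat& dlogits,
              Grads* g, bool want_dx) {
  const NetSpec& sp = net.spec;
  const int B = c.B;
  if (g) {
    g->dfcW = dlogits * c.flat.t();
    g->dfcb = arma::sum(dlogits, 1);
    g->dW.resize(sp.nconv());
    g->db.resize(sp.nconv());
  }
  fmat dflat = net.fcW.t() * dlogits;
  if (!c.mask.is_empty()) dflat %= c.mask;
  // reinterpret (flat, B) as (F, Lout*B)
  fmat dY(dflat.memptr(), sp.F.back(), (size_t)sp.Lout.back() * B);
  for (int l = sp.nconv() - 1; l >= 0; --l) {
    if (l < sp.nconv() - 1) {
      // ReLU derivative via the stored post-activation
      const float* a = c.acts[l + 1].memptr();
      float* p = dY.memptr();
      const size_t n = dY.n_elem;
      for (size_t j = 0; j < n; ++j) if (a[j] <= 0.0f) p[j] = 0.0f;
    }
    if (g) {
      const fmat& src = sp.unit(l) ? c.acts[l] : c.cols[l];
      g->dW[l] = dY * src.t();
      g->db[l] = arma::sum(dY, 1);
    }
    if (l == 0 && !want_dx) return fmat();
    if (sp.unit(l)) {
      dY = net.W[l].t() * dY;           // col2im is the identity here
    } else {
      fmat dcol = net.W[l].t() * dY;
      fmat dprev(sp.Cin(l), (size_t)sp.Lin(l) * B, arma::fill::zeros);
      col2im_add(dprev, dcol, sp.Cin(l), sp.Lin(l), sp.K[l], sp.S[l],
                 sp.Lout[l], B);
      dY = std::move(dprev);
    }
  }
  return dY;
}

struct Adam {
  std::vector<fmat> mW, vW;
  std::vector<fmat> mb, vb;    // stored as column matrices
  fmat mfcW, vfcW, mfcb, vfcb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const Net& net) {
    for (int l = 0; l < net.spec.nconv(); ++l) {
      mW.push_back(fmat(arma::size(net.W[l]), arma::fill::zeros));
      vW.push_back(fmat(arma::size(net.W[l]), arma::fill::zeros));
      mb.push_back(fmat(net.b[l].n_elem, 1, arma::fill::zeros));
      vb.push_back(fmat(net.b[l].n_elem, 1, arma::fill::zeros));
    }
    mfcW.zeros(arma::size(net.fcW)); vfcW.zeros(arma::size(net.fcW));
    mfcb.zeros(net.fcb.n_elem, 1);   vfcb.zeros(net.fcb.n_elem, 1);
  }

  void upd(fmat& w, fmat& m, fmat& v, const fmat& gr, double lr) {
    m = (float)b1 * m + (float)(1 - b1) * gr;
    v = (float)b2 * v + (float)(1 - b2) * arma::square(gr);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= (float)(lr / c1) * (m / (arma::sqrt(v / (float)c2) + (float)eps));
  }

  void step(Net& net, const Grads& g, double lr) {
    ++t;
    for (int l = 0; l < net.spec.nconv(); ++l) {
      upd(net.W[l], mW[l], vW[l], g.dW[l], lr);
      fmat bl(net.b[l].memptr(), net.b[l].n_elem, 1);
      fmat gb(const_cast<float*>(g.db[l].memptr()), g.db[l].n_elem, 1);
      upd(bl, mb[l], vb[l], gb, lr);
      net.b[l] = bl.col(0);
    }
    upd(net.fcW, mfcW, vfcW, g.dfcW, lr);
    fmat fb(net.fcb.memptr(), net.fcb.n_elem, 1);
    fmat gfb(const_cast<float*>(g.dfcb.memptr()), g.dfcb.n_elem, 1);
    upd(fb, mfcb, vfcb, gfb, lr);
    net.fcb = fb.col(0);
  }
};

// input (C, L, n) array -> (C, L*n) float matrix, plus n
fmat mat_from_r(const Rcpp::NumericVector& x, int& n_items) {
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) Rcpp::stop("input must be a 3-d array (channels x length x items)");
  n_items = dim[2];
  arma::mat xm(x.begin(), (size_t)dim[0], (size_t)dim[1] * dim[2]);
  return arma::conv_to<fmat>::from(xm);
}

Rcpp::NumericVector grad_to_r(const fmat& dX, int C, int L, int B) {
  Rcpp::NumericVector res(dX.n_elem);
  const float* p = dX.memptr();
  for (arma::uword j = 0; j < dX.n_elem; ++j) res[j] = (double)p[j];
  res.attr("dim") = Rcpp::IntegerVector::create(C, L, B);
  return res;
}

}  // namespace

// He-uniform initialization of all weights, deterministic in `seed`
// [[Rcpp::export]]
Rcpp::List cpp_cnn_init(Rcpp::IntegerMatrix layers, int n_channels,
                        int input_length, int n_classes, int seed) {
  NetSpec sp = make_spec(layers, n_channels, input_length, n_classes);
  std::mt19937_64 gen((uint64_t)seed);
  auto he_mat = [&](int rows, int fan_in) {
    float lim = std::sqrt(6.0f / (float)fan_in);
    std::uniform_real_distribution<float> unif(-lim, lim);
    fmat W(rows, fan_in);
    for (arma::uword j = 0; j < W.n_elem; ++j) W(j) = unif(gen);
    return W;
  };
  Net net;
  net.spec = sp;
  for (int l = 0; l < sp.nconv(); ++l) {
    net.W.push_back(he_mat(sp.F[l], sp.Cin(l) * sp.K[l]));
    net.b.push_back(fvec(sp.F[l], arma::fill::zeros));
  }
  net.fcW = he_mat(n_classes, sp.flat_dim());
  net.fcb = fvec(n_classes, arma::fill::zeros);
  return net_to_r(net);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List weights, Rcpp::IntegerMatrix layers,
                         Rcpp::NumericVector x, Rcpp::IntegerVector y,
                         int n_classes, int epochs, int batch_size,
                         double lr, double dropout, int seed) {
  tune_allocator();
  int N = 0;
  fmat X = mat_from_r(x, N);
  if (N < 1) Rcpp::stop("empty training set");
  if ((int)y.size() != N) Rcpp::stop("label/input size mismatch");
  const int C0 = X.n_rows, L0 = X.n_cols / N;
  Net net = net_from_r(weights, layers, C0, L0, n_classes);
  Adam opt; opt.init(net);
  std::mt19937_64 gen((uint64_t)seed + 0x9e3779b97f4a7c15ULL);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  Rcpp::NumericVector ep_loss(epochs), ep_acc(epochs);
  FwdCache c;
  Grads g;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double loss_sum = 0; int correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      int B = std::min(batch_size, N - start);
      fmat Xb(C0, (size_t)L0 * B);
      for (int i = 0; i < B; ++i) {
        std::memcpy(Xb.colptr((size_t)L0 * i),
                    X.colptr((size_t)L0 * idx[start + i]),
                    sizeof(float) * C0 * L0);
      }
      forward(net, Xb, B, c, true, dropout, &gen);
      fmat P = softmax_cols(c.logits);
      fmat dlog = P;
      for (int i = 0; i < B; ++i) {
        int lab = y[idx[start + i]];
        float p = std::max(P(lab, i), 1e-12f);
        loss_sum -= std::log(p);
        if (P.col(i).index_max() == (arma::uword)lab) ++correct;
        dlog(lab, i) -= 1.0f;
      }
      dlog /= (float)B;
      if (!std::isfinite(loss_sum)) {
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
      }
      backward(net, c, dlog, &g, false);
      opt.step(net, g, lr);
    }
    ep_loss[e] = loss_sum / N;
    ep_acc[e] = (double)correct / N;
    if (!std::isfinite(ep_loss[e])) {
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", e + 1);
    }
    if (e % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("weights") = net_to_r(net),
                            Rcpp::Named("loss") = ep_loss,
                            Rcpp::Named("train_acc") = ep_acc);
}

// eval-mode forward pass; returns items x classes matrices
// [[Rcpp::export]]
Rcpp::List cpp_cnn_forward(Rcpp::List weights, Rcpp::IntegerMatrix layers,
                           Rcpp::NumericVector x, int n_classes) {
  int N = 0;
  fmat X = mat_from_r(x, N);
  Net net = net_from_r(weights, layers, X.n_rows, X.n_cols / N, n_classes);
  FwdCache c;
  forward(net, X, N, c, false, 0.0, nullptr);
  fmat P = softmax_cols(c.logits);
  return Rcpp::List::create(
    Rcpp::Named("logits") = Rcpp::wrap(arma::conv_to<arma::mat>::from(c.logits.t())),
    Rcpp::Named("probs") = Rcpp::wrap(arma::conv_to<arma::mat>::from(P.t())));
}

// gradient of the pre-softmax score of `target` w.r.t. each input feature
// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_input_grad(Rcpp::List weights,
                                       Rcpp::IntegerMatrix layers,
                                       Rcpp::NumericVector x,
                                       Rcpp::IntegerVector target,
                                       int n_classes) {
  int N = 0;
  fmat X = mat_from_r(x, N);
  if ((int)target.size() != N) Rcpp::stop("target length must match item count");
  const int C0 = X.n_rows, L0 = X.n_cols / N;
  Net net = net_from_r(weights, layers, C0, L0, n_classes);
  FwdCache c;
  forward(net, X, N, c, false, 0.0, nullptr);
  fmat dlog(n_classes, N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) dlog(target[i], i) = 1.0f;
  fmat dX = backward(net, c, dlog, nullptr, true);
  if (!dX.is_finite()) Rcpp::stop("non-finite input gradients");
  return grad_to_r(dX, C0, L0, N);
}

// mean over the k = 1..n_steps midpoint-Riemann path points of the input
// gradient at ((k - 1/2)/n) * x; multiplying by x in R gives the IG
// attributions. The midpoint rule keeps the completeness residual an order
// of magnitude below the one-sided endpoint sums at equal step counts.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn_ig_mean_grad(Rcpp::List weights,
                                         Rcpp::IntegerMatrix layers,
                                         Rcpp::NumericVector x,
                                         Rcpp::IntegerVector target,
                                         int n_classes, int n_steps) {
  tune_allocator();
  if (n_steps < 2) Rcpp::stop("n_steps must be >= 2");
  int N = 0;
  fmat X = mat_from_r(x, N);
  if ((int)target.size() != N) Rcpp::stop("target length must match item count");
  const int C0 = X.n_rows, L0 = X.n_cols / N;
  Net net = net_from_r(weights, layers, C0, L0, n_classes);
  fmat dlog(n_classes, N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) dlog(target[i], i) = 1.0f;
  arma::mat acc(C0, (size_t)L0 * N, arma::fill::zeros);
  FwdCache c;
  for (int k = 1; k <= n_steps; ++k) {
    float alpha = ((float)k - 0.5f) / (float)n_steps;
    fmat Xs = X * alpha;
    forward(net, Xs, N, c, false, 0.0, nullptr);
    fmat dX = backward(net, c, dlog, nullptr, true);
    acc += arma::conv_to<arma::mat>::from(dX);
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  acc /= (double)n_steps;
  Rcpp::NumericVector res(acc.begin(), acc.end());
  res.attr("dim") = Rcpp::IntegerVector::create(C0, L0, N);
  return res;
}
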