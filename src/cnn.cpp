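// Convolutional network for rumble/noise snippet classification.
//
// The architecture is fixed: three convolutional blocks (2x conv 32@5x5,
// 2x conv 64@3x3, 2x conv 128@5x5), each followed by 2x2 max-pooling and
// 25% dropout, then a dense 128-unit ReLU layer with 40% dropout and a
// 2-class softmax head. Convolutions use "same" zero padding so the three
// poolings fit the 115-pixel input height. Training uses RMSprop on the
// sparse categorical cross-entropy.
//
// Implemented via im2col + GEMM (single-threaded BLAS). The compute path is
// templated on the scalar type: float for training/inference, double for
// the numerical gradient check. All randomness (weight initialization,
// shuffling, dropout) comes from one std::mt19937 stream seeded from R, so
// runs are bit-reproducible on one machine.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int N_CONV = 6;
static const int CONV_K[N_CONV]    = {5, 5, 3, 3, 5, 5};
static const int CONV_CIN[N_CONV]  = {3, 32, 32, 64, 64, 128};
static const int CONV_COUT[N_CONV] = {32, 32, 64, 64, 128, 128};
static const double DROP_CONV = 0.25;
static const double DROP_DENSE = 0.40;
static const int N_DENSE_HIDDEN = 128;
static const int N_CLASSES = 2;

template <typename T>
struct Params {
  std::vector<Mat<T>> Wc;  // conv weights, Cout x (k*k*Cin)
  std::vector<Col<T>> bc;  // conv biases
  Mat<T> W1; Col<T> b1;    // dense hidden
  Mat<T> W2; Col<T> b2;    // output
};

// ---------------------------------------------------------------------------
// im2col / col2im with "same" zero padding (odd k).
// Feature maps are stored pixel-major: X is (H*W x C), pixel index
// p = h + H*w. A kernel offset (dy, dx) is then a single linear shift of a
// channel column, so im2col is a contiguous memcpy per (offset, channel)
// followed by zeroing the rows that crossed the vertical image border.

template <typename T>
static void im2col(const Mat<T>& X, int H, int W, int k, Mat<T>& col) {
  const int C = X.n_cols, P = k / 2, HW = H * W;
  col.set_size(HW, C * k * k);
  for (int dx = -P; dx <= P; ++dx) {
    for (int dy = -P; dy <= P; ++dy) {
      const int o = dy + H * dx;  // source = dest + o
      for (int c = 0; c < C; ++c) {
        const int j = ((dy + P) * k + (dx + P)) * C + c;
        T* dst = col.colptr(j);
        const T* src = X.colptr(c);
        const int d0 = std::max(0, -o), d1 = HW - std::max(0, o);
        if (d0 > 0) std::fill(dst, dst + d0, T(0));
        if (d1 < HW) std::fill(dst + std::max(d0, d1), dst + HW, T(0));
        if (d1 > d0) std::copy(src + d0 + o, src + d1 + o, dst + d0);
        // zero rows whose source row crossed the vertical border
        if (dy > 0) {
          for (int w = 0; w < W; ++w) {
            const int p = H - dy + H * w;
            std::fill(dst + p, dst + std::min(HW, p + dy), T(0));
          }
        } else if (dy < 0) {
          for (int w = 0; w < W; ++w) {
            const int p = H * w;
            std::fill(dst + p, dst + p - dy, T(0));
          }
        }
      }
    }
  }
}

template <typename T>
static void col2im(const Mat<T>& col, int H, int W, int C, int k, Mat<T>& X) {
  const int P = k / 2, HW = H * W;
  X.zeros(HW, C);
  for (int dx = -P; dx <= P; ++dx) {
    for (int dy = -P; dy <= P; ++dy) {
      const int o = dy + H * dx;
      for (int c = 0; c < C; ++c) {
        const int j = ((dy + P) * k + (dx + P)) * C + c;
        const T* src = col.colptr(j);
        T* dst = X.colptr(c);
        // accumulate dst[p + o] += src[p] where valid (border rows in src
        // were zeroed on the forward pass and contribute nothing; the
        // corresponding gradient rows are handled identically here)
        const int d0 = std::max(0, -o), d1 = HW - std::max(0, o);
        if (dy == 0) {
          for (int p = d0; p < d1; ++p) dst[p + o] += src[p];
        } else {
          for (int w = 0; w < W; ++w) {
            int p_lo = H * w + std::max(0, -dy);
            int p_hi = H * w + H - std::max(0, dy);
            p_lo = std::max(p_lo, d0);
            p_hi = std::min(p_hi, d1);
            for (int p = p_lo; p < p_hi; ++p) dst[p + o] += src[p];
          }
        }
      }
    }
  }
}

// 2x2 max pooling, stride 2, floor semantics; records argmax input pixels.
template <typename T>
static void maxpool(const Mat<T>& X, int H, int W, Mat<T>& Y, umat& idx) {
  const int C = X.n_cols, H2 = H / 2, W2 = W / 2;
  Y.set_size(H2 * W2, C);
  idx.set_size(H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const T* x = X.colptr(c);
    T* y = Y.colptr(c);
    uword* ix = idx.colptr(c);
    for (int w = 0; w < W2; ++w) {
      for (int h = 0; h < H2; ++h) {
        const int p00 = 2 * h + H * 2 * w;
        const int cand[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        T best = x[cand[0]]; int bi = cand[0];
        for (int j = 1; j < 4; ++j)
          if (x[cand[j]] > best) { best = x[cand[j]]; bi = cand[j]; }
        y[h + H2 * w] = best;
        ix[h + H2 * w] = bi;
      }
    }
  }
}

template <typename T>
static void unpool(const Mat<T>& dY, const umat& idx, int HW, Mat<T>& dX) {
  dX.zeros(HW, dY.n_cols);
  for (uword c = 0; c < dY.n_cols; ++c) {
    const T* dy = dY.colptr(c);
    const uword* ix = idx.colptr(c);
    T* dx = dX.colptr(c);
    for (uword p = 0; p < dY.n_rows; ++p) dx[ix[p]] += dy[p];
  }
}

// ---------------------------------------------------------------------------

struct Shape {
  int H0, W0;
  int H[4], W[4];  // spatial dims at block inputs / after pools
  int flat;
  Shape(int h, int w) : H0(h), W0(w) {
    H[0] = h; W[0] = w;
    for (int b = 1; b <= 3; ++b) { H[b] = H[b - 1] / 2; W[b] = W[b - 1] / 2; }
    flat = H[3] * W[3] * CONV_COUT[5];
  }
};

template <typename T>
struct Cache {
  Mat<T> a0, a1, a2, p1d, a3, a4, p2d, a5, a6, p3d;
  Mat<T> m1, m2, m3;  // dropout masks (already scaled by 1/keep)
  umat i1, i2, i3;
  std::vector<Mat<T>> cols;  // per-conv im2col buffers kept for backward
  Cache() : cols(N_CONV) {}
};

template <typename T>
static void conv_forward(const Mat<T>& Win, const Col<T>& b, const Mat<T>& X,
                         int H, int W, int k, Mat<T>& buf, Mat<T>& Y,
                         bool relu = true) {
  im2col(X, H, W, k, buf);
  Y = buf * Win.t();           // (HW x kkC) * (kkC x F)
  Y.each_row() += b.t();
  if (relu) Y.transform([](T v) { return v > T(0) ? v : T(0); });
}

// Backward through one conv+relu using the im2col buffer kept from the
// forward pass: given dY (post-relu grad already masked by the caller),
// accumulate dW/db and produce dX.
template <typename T>
static void conv_backward(const Mat<T>& Win, const Mat<T>& col_fwd, int H,
                          int W, int Cin, int k, const Mat<T>& dY,
                          Mat<T>& dW, Col<T>& db, Mat<T>& dX) {
  dW += dY.t() * col_fwd;
  db += sum(dY, 0).t();
  Mat<T> dcol = dY * Win;      // (HW x F) * (F x kkC)
  col2im(dcol, H, W, Cin, k, dX);
}

// zero the gradient wherever the forward activation was clipped
template <typename T>
static void relu_backward(Mat<T>& d, const Mat<T>& post) {
  const T* a = post.memptr();
  T* p = d.memptr();
  for (uword i = 0; i < d.n_elem; ++i)
    if (a[i] <= T(0)) p[i] = T(0);
}

// Forward one image through the convolutional trunk. `train` controls
// dropout; masks are drawn from `rng`.
// `keep_cols = true` retains each conv layer's im2col matrix in the cache
// for reuse by the backward pass (memory is reused across images).
template <typename T>
static void trunk_forward(const Params<T>& P, const Shape& S, Cache<T>& c,
                          bool train, std::mt19937& rng, Mat<T>& buf,
                          bool keep_cols = false) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  auto dropout = [&](Mat<T>& X, Mat<T>& mask, double rate) {
    if (!train) return;
    const T scale = T(1.0 / (1.0 - rate));
    mask.set_size(X.n_rows, X.n_cols);
    for (uword i = 0; i < X.n_elem; ++i)
      mask(i) = U(rng) < rate ? T(0) : scale;
    X %= mask;
  };
  auto cbuf = [&](int i) -> Mat<T>& { return keep_cols ? c.cols[i] : buf; };
  conv_forward(P.Wc[0], P.bc[0], c.a0, S.H[0], S.W[0], CONV_K[0], cbuf(0),
               c.a1);
  conv_forward(P.Wc[1], P.bc[1], c.a1, S.H[0], S.W[0], CONV_K[1], cbuf(1),
               c.a2);
  maxpool(c.a2, S.H[0], S.W[0], c.p1d, c.i1);
  dropout(c.p1d, c.m1, DROP_CONV);
  conv_forward(P.Wc[2], P.bc[2], c.p1d, S.H[1], S.W[1], CONV_K[2], cbuf(2),
               c.a3);
  conv_forward(P.Wc[3], P.bc[3], c.a3, S.H[1], S.W[1], CONV_K[3], cbuf(3),
               c.a4);
  maxpool(c.a4, S.H[1], S.W[1], c.p2d, c.i2);
  dropout(c.p2d, c.m2, DROP_CONV);
  conv_forward(P.Wc[4], P.bc[4], c.p2d, S.H[2], S.W[2], CONV_K[4], cbuf(4),
               c.a5);
  conv_forward(P.Wc[5], P.bc[5], c.a5, S.H[2], S.W[2], CONV_K[5], cbuf(5),
               c.a6);
  maxpool(c.a6, S.H[2], S.W[2], c.p3d, c.i3);
  dropout(c.p3d, c.m3, DROP_CONV);
}

template <typename T>
static void trunk_backward(const Params<T>& P, const Shape& S, Cache<T>& c,
                           const Mat<T>& dflat_col, Params<T>& G,
                           bool train) {
  Mat<T> dp3 = reshape(dflat_col, S.H[3] * S.W[3], CONV_COUT[5]);
  if (train) dp3 %= c.m3;
  Mat<T> d6, d5, dp2, d4, d3, dp1, d2, d1, d0;
  unpool(dp3, c.i3, S.H[2] * S.W[2], d6);
  relu_backward(d6, c.a6);
  conv_backward(P.Wc[5], c.cols[5], S.H[2], S.W[2], CONV_CIN[5], CONV_K[5],
                d6, G.Wc[5], G.bc[5], d5);
  relu_backward(d5, c.a5);
  conv_backward(P.Wc[4], c.cols[4], S.H[2], S.W[2], CONV_CIN[4], CONV_K[4],
                d5, G.Wc[4], G.bc[4], dp2);
  if (train) dp2 %= c.m2;
  unpool(dp2, c.i2, S.H[1] * S.W[1], d4);
  relu_backward(d4, c.a4);
  conv_backward(P.Wc[3], c.cols[3], S.H[1], S.W[1], CONV_CIN[3], CONV_K[3],
                d4, G.Wc[3], G.bc[3], d3);
  relu_backward(d3, c.a3);
  conv_backward(P.Wc[2], c.cols[2], S.H[1], S.W[1], CONV_CIN[2], CONV_K[2],
                d3, G.Wc[2], G.bc[2], dp1);
  if (train) dp1 %= c.m1;
  unpool(dp1, c.i1, S.H[0] * S.W[0], d2);
  relu_backward(d2, c.a2);
  conv_backward(P.Wc[1], c.cols[1], S.H[0], S.W[0], CONV_CIN[1], CONV_K[1],
                d2, G.Wc[1], G.bc[1], d1);
  relu_backward(d1, c.a1);
  conv_backward(P.Wc[0], c.cols[0], S.H[0], S.W[0], CONV_CIN[0], CONV_K[0],
                d1, G.Wc[0], G.bc[0], d0);
}

// ---------------------------------------------------------------------------
// Parameter plumbing between R lists and Params<T>.

template <typename T>
static Params<T> params_from_list(const Rcpp::List& L) {
  Params<T> P;
  Rcpp::List wc = L["conv_w"], bc = L["conv_b"];
  for (int i = 0; i < N_CONV; ++i) {
    Rcpp::NumericMatrix w = wc[i];
    Rcpp::NumericVector b = bc[i];
    P.Wc.push_back(conv_to<Mat<T>>::from(
        mat(w.begin(), w.nrow(), w.ncol(), false)));
    P.bc.push_back(conv_to<Col<T>>::from(vec(b.begin(), b.size(), false)));
  }
  Rcpp::NumericMatrix w1 = L["dense1_w"], w2 = L["dense2_w"];
  Rcpp::NumericVector b1 = L["dense1_b"], b2 = L["dense2_b"];
  P.W1 = conv_to<Mat<T>>::from(mat(w1.begin(), w1.nrow(), w1.ncol(), false));
  P.b1 = conv_to<Col<T>>::from(vec(b1.begin(), b1.size(), false));
  P.W2 = conv_to<Mat<T>>::from(mat(w2.begin(), w2.nrow(), w2.ncol(), false));
  P.b2 = conv_to<Col<T>>::from(vec(b2.begin(), b2.size(), false));
  return P;
}

template <typename T>
static Rcpp::List params_to_list(const Params<T>& P) {
  Rcpp::List wc(N_CONV), bc(N_CONV);
  for (int i = 0; i < N_CONV; ++i) {
    wc[i] = Rcpp::wrap(conv_to<mat>::from(P.Wc[i]));
    bc[i] = Rcpp::wrap(conv_to<vec>::from(P.bc[i]));
  }
  return Rcpp::List::create(
      Rcpp::Named("conv_w") = wc, Rcpp::Named("conv_b") = bc,
      Rcpp::Named("dense1_w") = Rcpp::wrap(conv_to<mat>::from(P.W1)),
      Rcpp::Named("dense1_b") = Rcpp::wrap(conv_to<vec>::from(P.b1)),
      Rcpp::Named("dense2_w") = Rcpp::wrap(conv_to<mat>::from(P.W2)),
      Rcpp::Named("dense2_b") = Rcpp::wrap(conv_to<vec>::from(P.b2)));
}

// Decode image i from packed raw pixels (H x W x C per image, values 0-255)
// into a (C x H*W) matrix scaled to [0, 1].
template <typename T>
static void decode_image(const Rcpp::RawVector& X, int i, int H, int W, int C,
                         Mat<T>& a0) {
  const R_xlen_t off = (R_xlen_t)i * H * W * C;
  a0.set_size(H * W, C);
  const Rbyte* p = &X[off];
  for (int c = 0; c < C; ++c) {
    T* dst = a0.colptr(c);
    for (int px = 0; px < H * W; ++px)
      dst[px] = T(p[px + (R_xlen_t)c * H * W]) / T(255);
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_init(int height, int width, int channels, int seed) {
  std::mt19937 rng((uint32_t)seed);
  Shape S(height, width);
  Params<double> P;
  auto glorot = [&](int rows, int cols, int fan_in, int fan_out) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    std::uniform_real_distribution<double> U(-lim, lim);
    mat W(rows, cols);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = U(rng);
    return W;
  };
  for (int i = 0; i < N_CONV; ++i) {
    const int k = CONV_K[i], cin = CONV_CIN[i], cout = CONV_COUT[i];
    P.Wc.push_back(glorot(cout, k * k * cin, k * k * cin, k * k * cout));
    P.bc.push_back(vec(cout, fill::zeros));
  }
  P.W1 = glorot(N_DENSE_HIDDEN, S.flat, S.flat, N_DENSE_HIDDEN);
  P.b1 = vec(N_DENSE_HIDDEN, fill::zeros);
  P.W2 = glorot(N_CLASSES, N_DENSE_HIDDEN, N_DENSE_HIDDEN, N_CLASSES);
  P.b2 = vec(N_CLASSES, fill::zeros);
  return params_to_list(P);
}

template <typename T>
static Mat<T> softmax_cols(Mat<T> Z) {
  for (uword j = 0; j < Z.n_cols; ++j) {
    Col<T> z = Z.col(j);
    z -= z.max();
    z = exp(z);
    Z.col(j) = z / accu(z);
  }
  return Z;
}

// Forward a set of images (no dropout); returns class probabilities
// (N_CLASSES x n) and optionally accumulates loss/accuracy against labels.
template <typename T>
static Mat<T> forward_eval(const Params<T>& P, const Shape& S,
                           const Rcpp::RawVector& X, int n) {
  Mat<T> probs(N_CLASSES, n);
  Cache<T> c;
  Mat<T> buf;
  std::mt19937 dummy(0);
  for (int i = 0; i < n; ++i) {
    decode_image(X, i, S.H0, S.W0, CONV_CIN[0], c.a0);
    trunk_forward(P, S, c, false, dummy, buf);
    Col<T> flat = vectorise(c.p3d);
    Col<T> z1 = P.W1 * flat + P.b1;
    z1.transform([](T v) { return v > T(0) ? v : T(0); });
    Col<T> z2 = P.W2 * z1 + P.b2;
    probs.col(i) = softmax_cols(Mat<T>(z2));
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return probs;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_cnn_predict(Rcpp::List weights, Rcpp::RawVector X,
                                    int n, int height, int width) {
  Params<float> P = params_from_list<float>(weights);
  Shape S(height, width);
  Mat<float> probs = forward_eval(P, S, X, n);
  mat out = conv_to<mat>::from(probs.t());
  return Rcpp::wrap(out);
}

template <typename T>
static void zero_like(const Params<T>& P, Params<T>& G) {
  G.Wc.clear(); G.bc.clear();
  for (int i = 0; i < N_CONV; ++i) {
    G.Wc.push_back(Mat<T>(P.Wc[i].n_rows, P.Wc[i].n_cols, fill::zeros));
    G.bc.push_back(Col<T>(P.bc[i].n_elem, fill::zeros));
  }
  G.W1.zeros(P.W1.n_rows, P.W1.n_cols); G.b1.zeros(P.b1.n_elem);
  G.W2.zeros(P.W2.n_rows, P.W2.n_cols); G.b2.zeros(P.b2.n_elem);
}

// One forward+backward pass over a batch; returns (sum loss, n correct)
// and fills gradient G (mean over batch). Images are processed one at a
// time, forward and backward back-to-back, so each conv layer's im2col
// matrix is built once and reused; batch gradients are accumulated as the
// mean of per-image gradients, which is identical to a jointly computed
// batch gradient for this loss.
template <typename T>
static std::pair<double, int> batch_grad(const Params<T>& P, const Shape& S,
                                         const Rcpp::RawVector& X,
                                         const std::vector<int>& idx,
                                         const Rcpp::IntegerVector& y,
                                         bool train, std::mt19937& rng,
                                         Params<T>& G, Cache<T>& c) {
  const int nb = (int)idx.size();
  zero_like(P, G);
  Mat<T> buf;
  double loss = 0;
  int correct = 0;
  std::uniform_real_distribution<double> U(0.0, 1.0);
  for (int j = 0; j < nb; ++j) {
    decode_image(X, idx[j], S.H0, S.W0, CONV_CIN[0], c.a0);
    trunk_forward(P, S, c, train, rng, buf, true);
    Col<T> flat = vectorise(c.p3d);
    Col<T> z1 = P.W1 * flat + P.b1;
    Col<T> a1 = z1;
    a1.transform([](T v) { return v > T(0) ? v : T(0); });
    Col<T> m4;
    Col<T> a1d = a1;
    if (train) {
      const T scale = T(1.0 / (1.0 - DROP_DENSE));
      m4.set_size(a1.n_elem);
      for (uword i = 0; i < m4.n_elem; ++i)
        m4(i) = U(rng) < DROP_DENSE ? T(0) : scale;
      a1d %= m4;
    }
    Col<T> z2 = P.W2 * a1d + P.b2;
    Col<T> probs = softmax_cols(Mat<T>(z2));
    const int lab = y[idx[j]];
    loss += -std::log(std::max((double)probs(lab), 1e-12));
    if ((int)probs.index_max() == lab) ++correct;
    Col<T> dz2 = probs;
    dz2(lab) -= T(1);
    dz2 /= T(nb);  // batch-mean factor carried through the whole backward
    G.W2 += dz2 * a1d.t();
    G.b2 += dz2;
    Col<T> da1 = P.W2.t() * dz2;
    if (train) da1 %= m4;
    for (uword i = 0; i < da1.n_elem; ++i)
      if (a1(i) <= T(0)) da1(i) = T(0);
    G.W1 += da1 * flat.t();
    G.b1 += da1;
    Col<T> dflat = P.W1.t() * da1;
    trunk_backward(P, S, c, Mat<T>(dflat), G, train);
  }
  return {loss, correct};
}

template <typename T>
struct RmsState { std::vector<Mat<T>> vWc; std::vector<Col<T>> vbc;
                  Mat<T> vW1; Col<T> vb1; Mat<T> vW2; Col<T> vb2; };

template <typename T>
static void rms_update(Params<T>& P, const Params<T>& G, RmsState<T>& V,
                       T lr, T rho, T eps) {
  auto upd = [&](Mat<T>& w, const Mat<T>& g, Mat<T>& v) {
    v = rho * v + (T(1) - rho) * square(g);
    w -= lr * g / (sqrt(v) + eps);
  };
  auto updc = [&](Col<T>& w, const Col<T>& g, Col<T>& v) {
    v = rho * v + (T(1) - rho) * square(g);
    w -= lr * g / (sqrt(v) + eps);
  };
  for (int i = 0; i < N_CONV; ++i) {
    upd(P.Wc[i], G.Wc[i], V.vWc[i]);
    updc(P.bc[i], G.bc[i], V.vbc[i]);
  }
  upd(P.W1, G.W1, V.vW1); updc(P.b1, G.b1, V.vb1);
  upd(P.W2, G.W2, V.vW2); updc(P.b2, G.b2, V.vb2);
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List weights, Rcpp::RawVector X,
                         Rcpp::IntegerVector y, int n, Rcpp::RawVector Xval,
                         Rcpp::IntegerVector yval, int nval, int height,
                         int width, double lr, double rho, double eps,
                         int batch_size, int max_epochs, int patience,
                         double converge_loss, int seed, bool verbose) {
  typedef float T;
  Params<T> P = params_from_list<T>(weights);
  Shape S(height, width);
  std::mt19937 rng((uint32_t)seed);
  RmsState<T> V;
  {
    Params<T> Z; zero_like(P, Z);
    V.vWc = Z.Wc; V.vbc = Z.bc; V.vW1 = Z.W1; V.vb1 = Z.b1;
    V.vW2 = Z.W2; V.vb2 = Z.b2;
  }
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  Params<T> G;
  Cache<T> cache;
  Params<T> best = P;
  double best_val = std::numeric_limits<double>::infinity();
  int since_best = 0;
  std::vector<double> h_tl, h_ta, h_vl, h_va;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double tr_loss = 0; int tr_correct = 0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      std::vector<int> idx(order.begin() + b0,
                           order.begin() + std::min(n, b0 + batch_size));
      auto res = batch_grad(P, S, X, idx, y, true, rng, G, cache);
      if (!std::isfinite(res.first))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", epoch + 1);
      tr_loss += res.first;
      tr_correct += res.second;
      rms_update(P, G, V, T(lr), T(rho), T(eps));
      Rcpp::checkUserInterrupt();
    }
    Mat<T> pv = forward_eval(P, S, Xval, nval);
    double v_loss = 0; int v_correct = 0;
    for (int i = 0; i < nval; ++i) {
      v_loss += -std::log(std::max((double)pv(yval[i], i), 1e-12));
      if ((int)pv.col(i).index_max() == yval[i]) ++v_correct;
    }
    v_loss /= nval;
    const double v_acc = (double)v_correct / nval;
    h_tl.push_back(tr_loss / n);
    h_ta.push_back((double)tr_correct / n);
    h_vl.push_back(v_loss);
    h_va.push_back(v_acc);
    if (verbose)
      Rcpp::Rcout << "epoch " << (epoch + 1) << ": train_loss="
                  << tr_loss / n << " train_acc=" << (double)tr_correct / n
                  << " val_loss=" << v_loss << " val_acc=" << v_acc
                  << std::endl;
    if (v_loss < best_val - 1e-6) {
      best_val = v_loss; best = P; since_best = 0;
    } else {
      ++since_best;
    }
    if (v_acc >= 1.0 && v_loss < converge_loss) break;
    if (since_best >= patience) break;
  }
  Rcpp::NumericMatrix hist(h_tl.size(), 4);
  for (size_t i = 0; i < h_tl.size(); ++i) {
    hist(i, 0) = h_tl[i]; hist(i, 1) = h_ta[i];
    hist(i, 2) = h_vl[i]; hist(i, 3) = h_va[i];
  }
  colnames(hist) = Rcpp::CharacterVector::create("train_loss", "train_acc",
                                                 "val_loss", "val_acc");
  return Rcpp::List::create(Rcpp::Named("weights") = params_to_list(best),
                            Rcpp::Named("history") = hist);
}

// ---------------------------------------------------------------------------
// Double-precision loss and numerical gradient check (dropout disabled).

template <typename T>
static double full_loss(const Params<T>& P, const Shape& S,
                        const Rcpp::RawVector& X,
                        const Rcpp::IntegerVector& y, int n) {
  Mat<T> probs = forward_eval(P, S, X, n);
  double loss = 0;
  for (int i = 0; i < n; ++i)
    loss += -std::log(std::max((double)probs(y[i], i), 1e-300));
  return loss / n;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_gradcheck(Rcpp::List weights, Rcpp::RawVector X,
                             Rcpp::IntegerVector y, int n, int height,
                             int width, Rcpp::IntegerVector tensor,
                             Rcpp::IntegerVector index, double h) {
  typedef double T;
  Params<T> P = params_from_list<T>(weights);
  Shape S(height, width);
  std::mt19937 rng(0);
  Params<T> G;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Cache<T> cache;
  batch_grad(P, S, X, idx, y, false, rng, G, cache);
  auto tensor_ref = [&](Params<T>& Q, int t) -> T* {
    if (t < N_CONV) return Q.Wc[t].memptr();
    if (t < 2 * N_CONV) return Q.bc[t - N_CONV].memptr();
    switch (t - 2 * N_CONV) {
      case 0: return Q.W1.memptr();
      case 1: return Q.b1.memptr();
      case 2: return Q.W2.memptr();
      default: return Q.b2.memptr();
    }
  };
  const int m = tensor.size();
  Rcpp::NumericVector analytic(m), numeric(m);
  for (int j = 0; j < m; ++j) {
    analytic[j] = tensor_ref(G, tensor[j])[index[j]];
    T* w = tensor_ref(P, tensor[j]) + index[j];
    const T w0 = *w;
    *w = w0 + h;
    const double lp = full_loss(P, S, X, y, n);
    *w = w0 - h;
    const double lm = full_loss(P, S, X, y, n);
    *w = w0;
    numeric[j] = (lp - lm) / (2 * h);
  }
  return Rcpp::List::create(Rcpp::Named("analytic") = analytic,
                            Rcpp::Named("numeric") = numeric);
}
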