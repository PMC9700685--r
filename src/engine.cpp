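// Minimal layer-graph engine for small encoder-decoder segmentation networks.
//
// Tensors are stored channel-first as arma::Mat<T> of shape [C, H*W*N] with
// column index h + H*(w + W*n); spatial convolutions are computed as k*k
// shifted GEMMs so the heavy lifting lands in BLAS, while the memory-bound
// ops (depth-wise convolution, batch norm, pooling, bilinear resampling)
// are fused single-pass raw loops. All activation and gradient buffers are
// persistent across steps to avoid allocation churn. The graph is a flat
// list of nodes emitted in topological order by the R side, which also
// fixes every node's output shape. Backward passes are hand-derived per
// op; Adam with decoupled weight decay updates the parameters in place.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
#include <chrono>
#include <map>

using namespace Rcpp;

// vectorizable exp: range reduction + degree-5 polynomial + exponent bit
// trick; relative error ~1e-7, ample for single-precision training. The
// double instantiation keeps std::exp (used for gradient checks).
static inline float fast_exp(float x) {
  x = x < -87.0f ? -87.0f : (x > 87.0f ? 87.0f : x);
  float t = x * 1.44269504088896341f;
  int32_t ki = (int32_t)t;
  ki -= (t < (float)ki);                   // branchless floor
  float r = x - (float)ki * 0.693147180559945f;
  float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.1666666667f +
            r * (0.0416666667f + r * (0.008333333f + r * 0.0013888889f)))));
  int32_t bits = (ki + 127) << 23;
  float pw;
  std::memcpy(&pw, &bits, sizeof(float));
  return p * pw;
}
static inline double fast_exp(double x) { return std::exp(x); }

template <typename T>
static void sigmoid_kernel(const T* a, T* s, size_t n) {
  for (size_t i = 0; i < n; ++i) s[i] = (T)1 / ((T)1 + fast_exp(-a[i]));
}

// swish forward: s = sigmoid(a), out = a * s
template <typename T>
static void swish_fwd_kernel(const T* a, T* s, T* out, size_t n) {
  for (size_t i = 0; i < n; ++i) {
    T si = (T)1 / ((T)1 + fast_exp(-a[i]));
    s[i] = si; out[i] = a[i] * si;
  }
}

// swish backward: g += dy * s * (1 + a * (1 - s))
template <typename T>
static void swish_bwd_kernel(const T* a, const T* s, const T* dy, T* g, size_t n) {
  for (size_t i = 0; i < n; ++i)
    g[i] += dy[i] * s[i] * ((T)1 + a[i] * ((T)1 - s[i]));
}

// fused batch-norm + swish transform: z = a*scale + shift (per channel),
// s = sigmoid(z), out = z*s, optionally caching s for backward
template <typename T>
static void bnsw_transform(const T* a, const T* sc, const T* sh,
                           T* out, T* aux, int C, size_t ncols, bool save_aux) {
  for (size_t j = 0; j < ncols; ++j) {
    const T* ac = a + j * C;
    T* oc = out + j * C;
    T* xc = aux + j * C;
    for (int c = 0; c < C; ++c) {
      T z = ac[c] * sc[c] + sh[c];
      T s = (T)1 / ((T)1 + fast_exp(-z));
      oc[c] = z * s;
      if (save_aux) xc[c] = s;
    }
  }
}

#ifdef __SSE2__
#include <emmintrin.h>

static inline __m128 exp4(__m128 x) {
  const __m128 lo = _mm_set1_ps(-87.0f), hi = _mm_set1_ps(87.0f);
  x = _mm_min_ps(hi, _mm_max_ps(lo, x));
  __m128 t = _mm_mul_ps(x, _mm_set1_ps(1.44269504088896341f));
  __m128i ki = _mm_cvttps_epi32(t);
  __m128 kf = _mm_cvtepi32_ps(ki);
  // floor adjustment for negative t
  __m128i adj = _mm_srli_epi32(_mm_castps_si128(_mm_cmplt_ps(t, kf)), 31);
  ki = _mm_sub_epi32(ki, adj);
  kf = _mm_cvtepi32_ps(ki);
  __m128 r = _mm_sub_ps(x, _mm_mul_ps(kf, _mm_set1_ps(0.693147180559945f)));
  __m128 p = _mm_set1_ps(0.0013888889f);
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(0.008333333f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(0.0416666667f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(0.1666666667f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(0.5f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f));
  p = _mm_add_ps(_mm_mul_ps(p, r), _mm_set1_ps(1.0f));
  __m128i bits = _mm_slli_epi32(_mm_add_epi32(ki, _mm_set1_epi32(127)), 23);
  return _mm_mul_ps(p, _mm_castsi128_ps(bits));
}

static inline __m128 sigmoid4(__m128 a) {
  __m128 e = exp4(_mm_sub_ps(_mm_setzero_ps(), a));
  return _mm_div_ps(_mm_set1_ps(1.0f), _mm_add_ps(_mm_set1_ps(1.0f), e));
}

template <>
void sigmoid_kernel<float>(const float* a, float* s, size_t n) {
  size_t i = 0;
  for (; i + 4 <= n; i += 4)
    _mm_storeu_ps(s + i, sigmoid4(_mm_loadu_ps(a + i)));
  for (; i < n; ++i) s[i] = 1.0f / (1.0f + fast_exp(-a[i]));
}

template <>
void swish_fwd_kernel<float>(const float* a, float* s, float* out, size_t n) {
  size_t i = 0;
  for (; i + 4 <= n; i += 4) {
    __m128 av = _mm_loadu_ps(a + i);
    __m128 sv = sigmoid4(av);
    _mm_storeu_ps(s + i, sv);
    _mm_storeu_ps(out + i, _mm_mul_ps(av, sv));
  }
  for (; i < n; ++i) {
    float si = 1.0f / (1.0f + fast_exp(-a[i]));
    s[i] = si; out[i] = a[i] * si;
  }
}

template <>
void bnsw_transform<float>(const float* a, const float* sc, const float* sh,
                           float* out, float* aux, int C, size_t ncols,
                           bool save_aux) {
  for (size_t j = 0; j < ncols; ++j) {
    const float* ac = a + j * C;
    float* oc = out + j * C;
    float* xc = aux + j * C;
    int c = 0;
    for (; c + 4 <= C; c += 4) {
      __m128 z = _mm_add_ps(_mm_mul_ps(_mm_loadu_ps(ac + c), _mm_loadu_ps(sc + c)),
                            _mm_loadu_ps(sh + c));
      __m128 s = sigmoid4(z);
      _mm_storeu_ps(oc + c, _mm_mul_ps(z, s));
      if (save_aux) _mm_storeu_ps(xc + c, s);
    }
    for (; c < C; ++c) {
      float z = ac[c] * sc[c] + sh[c];
      float s = 1.0f / (1.0f + fast_exp(-z));
      oc[c] = z * s;
      if (save_aux) xc[c] = s;
    }
  }
}

template <>
void swish_bwd_kernel<float>(const float* a, const float* s, const float* dy,
                             float* g, size_t n) {
  const __m128 one = _mm_set1_ps(1.0f);
  size_t i = 0;
  for (; i + 4 <= n; i += 4) {
    __m128 av = _mm_loadu_ps(a + i), sv = _mm_loadu_ps(s + i);
    __m128 d = _mm_mul_ps(_mm_loadu_ps(dy + i),
               _mm_mul_ps(sv, _mm_add_ps(one,
                 _mm_mul_ps(av, _mm_sub_ps(one, sv)))));
    _mm_storeu_ps(g + i, _mm_add_ps(_mm_loadu_ps(g + i), d));
  }
  for (; i < n; ++i)
    g[i] += dy[i] * s[i] * (1.0f + a[i] * (1.0f - s[i]));
}
#endif

// simple size-keyed buffer pool so short-lived gradient buffers are reused
// instead of repeatedly mapped and unmapped
template <typename T>
struct BufPool {
  std::map<size_t, std::vector<arma::Mat<T>*>> free_;
  arma::Mat<T>* acquire(arma::uword r, arma::uword c) {
    size_t key = (size_t)r * c;
    auto& v = free_[key];
    arma::Mat<T>* m;
    if (!v.empty()) { m = v.back(); v.pop_back(); }
    else m = new arma::Mat<T>(r, c);
    if (m->n_rows != r || m->n_cols != c) m->set_size(r, c);  // same n_elem: no realloc
    return m;
  }
  void release(arma::Mat<T>* m) { if (m) free_[m->n_elem].push_back(m); }
  ~BufPool() { for (auto& kv : free_) for (auto* m : kv.second) delete m; }
};

template <typename T>
struct Node {
  std::string op;
  int in1 = -1, in2 = -1;          // 0-based input node indices
  int k = 0, cin = 0, cout = 0;
  bool bias = false;
  int H = 0, W = 0, C = 0;         // output shape

  arma::Mat<T> Wt;                 // conv: [cout, cin*k*k]; dwconv: [C, k*k]
  arma::Col<T> b, gamma, beta, rmean, rvar;

  arma::Mat<T> mW, vW;             // Adam state
  arma::Col<T> mb, vb, mg, vg, mbe, vbe;

  arma::Mat<T> out;
  arma::Mat<T>* g = nullptr;       // pooled gradient buffer, live only in backward
  arma::Mat<T> aux;                // swish: cached sigmoid; conv k>1: shift scratch
  arma::Col<T> mu, istd;           // batch-norm cache
  std::vector<unsigned char> amax; // maxpool argmax in {0,1,2,3}

  arma::Mat<T> dW;
  arma::Col<T> db, dgamma, dbeta;
};

// copy X shifted by (dy,dx) into 'out' (zero padding), both [C, H*W*N]
template <typename T>
static void shift_copy(const arma::Mat<T>& X, arma::Mat<T>& out,
                       int H, int W, int N, int dy, int dx) {
  if (out.n_rows != X.n_rows || out.n_cols != X.n_cols)
    out.set_size(X.n_rows, X.n_cols);
  out.zeros();
  int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);   // dest h range [h0,h1)
  int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
  if (h1 <= h0 || w1 <= w0) return;
  for (int n = 0; n < N; ++n)
    for (int w = w0; w < w1; ++w) {
      int dst = h0 + H * (w + W * n);
      int src = (h0 + dy) + H * ((w + dx) + W * n);
      std::memcpy(out.colptr(dst), X.colptr(src),
                  sizeof(T) * X.n_rows * (h1 - h0));
    }
}

// accumulate src into acc with destination shifted by (dy,dx)
template <typename T>
static void shift_scatter(const arma::Mat<T>& src, arma::Mat<T>& acc,
                          int H, int W, int N, int dy, int dx) {
  int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);   // src h range
  int w0 = std::max(0, -dx), w1 = std::min(W, W - dx);
  if (h1 <= h0 || w1 <= w0) return;
  arma::uword C = src.n_rows;
  for (int n = 0; n < N; ++n)
    for (int w = w0; w < w1; ++w) {
      const T* s = src.colptr(h0 + H * (w + W * n));
      T* d = acc.colptr((h0 + dy) + H * ((w + dx) + W * n));
      arma::uword len = C * (h1 - h0);
      for (arma::uword i = 0; i < len; ++i) d[i] += s[i];
    }
}

// 1-D bilinear 2x upsampling taps (align_corners = false, edge clamped)
static void up_taps(int Hin, int i, int& i0, int& i1, double& w0, double& w1) {
  double s = (i + 0.5) / 2.0 - 0.5;
  double fl = std::floor(s);
  double fr = s - fl;
  i0 = std::max(0, std::min(Hin - 1, (int)fl));
  i1 = std::max(0, std::min(Hin - 1, (int)fl + 1));
  w0 = 1.0 - fr; w1 = fr;
}

template <typename T>
class Engine {
 public:
  std::vector<Node<T>> nodes;
  int N = 0;
  long adam_t = 0;
  T bn_eps = (T)1e-3, bn_momentum = (T)0.9;
  BufPool<T> pool;
  std::map<std::string, double> prof;
  bool profiling = false;

  struct OpTimer {
    Engine* e; std::string op; std::chrono::steady_clock::time_point t0;
    OpTimer(Engine* e_, std::string op_) : e(e_), op(std::move(op_)) {
      if (e->profiling) t0 = std::chrono::steady_clock::now();
    }
    ~OpTimer() {
      if (e->profiling)
        e->prof[op] += std::chrono::duration<double>(
          std::chrono::steady_clock::now() - t0).count();
    }
  };

  explicit Engine(List graph) {
    int n = graph.size();
    nodes.resize(n);
    for (int i = 0; i < n; ++i) {
      List g = graph[i];
      Node<T>& nd = nodes[i];
      nd.op = as<std::string>(g["op"]);
      IntegerVector in = g["in"];
      if (in.size() > 0) nd.in1 = in[0] - 1;
      if (in.size() > 1) nd.in2 = in[1] - 1;
      nd.k = as<int>(g["k"]); nd.cin = as<int>(g["cin"]); nd.cout = as<int>(g["cout"]);
      nd.bias = as<bool>(g["bias"]);
      nd.H = as<int>(g["H"]); nd.W = as<int>(g["W"]); nd.C = as<int>(g["C"]);
      if (nd.op == "conv") {
        nd.Wt.zeros(nd.cout, (arma::uword)nd.cin * nd.k * nd.k);
        if (nd.bias) nd.b.zeros(nd.cout);
      } else if (nd.op == "dwconv") {
        nd.Wt.zeros(nd.C, (arma::uword)nd.k * nd.k);
        if (nd.bias) nd.b.zeros(nd.C);
      } else if (nd.op == "bn" || nd.op == "bnswish") {
        nd.gamma.ones(nd.C); nd.beta.zeros(nd.C);
        nd.rmean.zeros(nd.C); nd.rvar.ones(nd.C);
      }
    }
  }

  void init(int seed) {
    std::mt19937 rng((unsigned)seed);
    std::normal_distribution<double> nrm(0.0, 1.0);
    for (auto& nd : nodes) {
      if (nd.op == "conv") {
        double sd = std::sqrt(2.0 / (double)(nd.cin * nd.k * nd.k));
        for (arma::uword j = 0; j < nd.Wt.n_elem; ++j) nd.Wt(j) = (T)(sd * nrm(rng));
        if (nd.bias) nd.b.zeros();
      } else if (nd.op == "dwconv") {
        double sd = std::sqrt(2.0 / (double)(nd.k * nd.k));
        for (arma::uword j = 0; j < nd.Wt.n_elem; ++j) nd.Wt(j) = (T)(sd * nrm(rng));
        if (nd.bias) nd.b.zeros();
      } else if (nd.op == "bn" || nd.op == "bnswish") {
        nd.gamma.ones(); nd.beta.zeros(); nd.rmean.zeros(); nd.rvar.ones();
      }
      nd.mW.reset(); nd.vW.reset(); nd.mb.reset(); nd.vb.reset();
      nd.mg.reset(); nd.vg.reset(); nd.mbe.reset(); nd.vbe.reset();
    }
    adam_t = 0;
  }

  long nparams() const {
    long p = 0;
    for (const auto& nd : nodes)
      p += nd.Wt.n_elem + nd.b.n_elem + nd.gamma.n_elem + nd.beta.n_elem;
    return p;
  }

  static void resize_to(arma::Mat<T>& m, arma::uword r, arma::uword c) {
    if (m.n_rows != r || m.n_cols != c) m.set_size(r, c);
  }

  void forward(const arma::Mat<T>& X, int batch, bool train) {
    N = batch;
    for (size_t i = 0; i < nodes.size(); ++i) {
      Node<T>& nd = nodes[i];
      arma::uword cols = (arma::uword)nd.H * nd.W * N;
      if (nd.op == "input") { nd.out = X; continue; }
      OpTimer tm(this, nd.op);
      const arma::Mat<T>& A = nodes[nd.in1].out;
      const Node<T>& na = nodes[nd.in1];
      resize_to(nd.out, nd.C, cols);

      if (nd.op == "conv") {
        if (nd.k == 1) {
          nd.out = nd.Wt * A;
        } else {
          nd.out.zeros();
          int p = (nd.k - 1) / 2, o = 0;
          for (int dx = -p; dx <= p; ++dx)
            for (int dy = -p; dy <= p; ++dy, ++o) {
              shift_copy(A, nd.aux, nd.H, nd.W, N, dy, dx);
              nd.out += nd.Wt.cols((arma::uword)o * nd.cin,
                                   (arma::uword)(o + 1) * nd.cin - 1) * nd.aux;
            }
        }
        if (nd.bias) nd.out.each_col() += nd.b;
      } else if (nd.op == "dwconv") {
        int C = nd.C, H = nd.H, W = nd.W, p = (nd.k - 1) / 2;
        const T* bp = nd.bias ? nd.b.memptr() : nullptr;
        const T* srcbase[49]; const T* wv[49]; int dys[49];
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < W; ++w) {
            int nt = 0, o = 0;
            for (int dx = -p; dx <= p; ++dx)
              for (int dy = -p; dy <= p; ++dy, ++o)
                if (w + dx >= 0 && w + dx < W) {
                  srcbase[nt] = A.colptr((arma::uword)H * ((w + dx) + (arma::uword)W * n));
                  wv[nt] = nd.Wt.colptr(o);
                  dys[nt] = dy; ++nt;
                }
            T* dst = nd.out.colptr((arma::uword)H * (w + (arma::uword)W * n));
            for (int h = 0; h < H; ++h) {
              T* d = dst + (size_t)h * C;
              if (bp) std::memcpy(d, bp, sizeof(T) * C);
              else std::memset(d, 0, sizeof(T) * C);
              for (int t = 0; t < nt; ++t) {
                int hs = h + dys[t];
                if (hs < 0 || hs >= H) continue;
                const T* s = srcbase[t] + (size_t)hs * C;
                const T* ww = wv[t];
                for (int c = 0; c < C; ++c) d[c] += s[c] * ww[c];
              }
            }
          }
      } else if (nd.op == "bn") {
        int C = nd.C;
        arma::uword m = A.n_cols;
        if (train) {
          nd.mu.zeros(C);
          arma::Col<T> sq(C, arma::fill::zeros);
          T* mup = nd.mu.memptr(); T* sqp = sq.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j);
            for (int c = 0; c < C; ++c) { mup[c] += a[c]; sqp[c] += a[c] * a[c]; }
          }
          nd.mu /= (T)m;
          arma::Col<T> var = sq / (T)m - arma::square(nd.mu);
          var = arma::clamp(var, (T)0, std::numeric_limits<T>::max());
          nd.istd = 1.0 / arma::sqrt(var + bn_eps);
          nd.rmean = bn_momentum * nd.rmean + (1 - bn_momentum) * nd.mu;
          nd.rvar  = bn_momentum * nd.rvar  + (1 - bn_momentum) * var;
          arma::Col<T> scale = nd.istd % nd.gamma;
          arma::Col<T> shift = nd.beta - nd.mu % scale;
          const T* sc = scale.memptr(); const T* sh = shift.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j); T* y = nd.out.colptr(j);
            for (int c = 0; c < C; ++c) y[c] = a[c] * sc[c] + sh[c];
          }
        } else {
          arma::Col<T> scale = nd.gamma / arma::sqrt(nd.rvar + bn_eps);
          arma::Col<T> shift = nd.beta - nd.rmean % scale;
          const T* sc = scale.memptr(); const T* sh = shift.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j); T* y = nd.out.colptr(j);
            for (int c = 0; c < C; ++c) y[c] = a[c] * sc[c] + sh[c];
          }
        }
      } else if (nd.op == "swish") {
        resize_to(nd.aux, nd.C, cols);          // cache sigmoid for backward
        swish_fwd_kernel(A.memptr(), nd.aux.memptr(), nd.out.memptr(), A.n_elem);
      } else if (nd.op == "bnswish") {
        int C = nd.C;
        arma::uword m = A.n_cols;
        arma::Col<T> scale(C), shift(C);
        if (train) {
          nd.mu.zeros(C);
          arma::Col<T> sq(C, arma::fill::zeros);
          T* mup = nd.mu.memptr(); T* sqp = sq.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j);
            for (int c = 0; c < C; ++c) { mup[c] += a[c]; sqp[c] += a[c] * a[c]; }
          }
          nd.mu /= (T)m;
          arma::Col<T> var = sq / (T)m - arma::square(nd.mu);
          var = arma::clamp(var, (T)0, std::numeric_limits<T>::max());
          nd.istd = 1.0 / arma::sqrt(var + bn_eps);
          nd.rmean = bn_momentum * nd.rmean + (1 - bn_momentum) * nd.mu;
          nd.rvar  = bn_momentum * nd.rvar  + (1 - bn_momentum) * var;
          scale = nd.istd % nd.gamma;
          shift = nd.beta - nd.mu % scale;
          resize_to(nd.aux, nd.C, cols);
          bnsw_transform(A.memptr(), scale.memptr(), shift.memptr(),
                         nd.out.memptr(), nd.aux.memptr(), C, m, true);
        } else {
          scale = nd.gamma / arma::sqrt(nd.rvar + bn_eps);
          shift = nd.beta - nd.rmean % scale;
          bnsw_transform(A.memptr(), scale.memptr(), shift.memptr(),
                         nd.out.memptr(), (T*)nullptr, C, m, false);
        }
      } else if (nd.op == "sigmoid") {
        sigmoid_kernel(A.memptr(), nd.out.memptr(), A.n_elem);
      } else if (nd.op == "gap") {
        arma::uword hw = (arma::uword)na.H * na.W;
        for (int n = 0; n < N; ++n)
          nd.out.col(n) = arma::mean(A.cols(n * hw, (n + 1) * hw - 1), 1);
      } else if (nd.op == "chanscale") {
        const arma::Mat<T>& G = nodes[nd.in2].out;   // [C, N]
        arma::uword hw = (arma::uword)nd.H * nd.W;
        int C = nd.C;
        for (int n = 0; n < N; ++n) {
          const T* gv = G.colptr(n);
          for (arma::uword j = n * hw; j < (n + 1) * hw; ++j) {
            const T* a = A.colptr(j); T* y = nd.out.colptr(j);
            for (int c = 0; c < C; ++c) y[c] = a[c] * gv[c];
          }
        }
      } else if (nd.op == "mul") {
        nd.out = A % nodes[nd.in2].out;
      } else if (nd.op == "add") {
        nd.out = A + nodes[nd.in2].out;
      } else if (nd.op == "concat") {
        const arma::Mat<T>& B = nodes[nd.in2].out;
        arma::uword c1 = A.n_rows, c2 = B.n_rows;
        for (arma::uword j = 0; j < cols; ++j) {
          T* y = nd.out.colptr(j);
          std::memcpy(y, A.colptr(j), sizeof(T) * c1);
          std::memcpy(y + c1, B.colptr(j), sizeof(T) * c2);
        }
      } else if (nd.op == "maxpool") {
        int Hi = na.H, Wi = na.W, C = nd.C;
        nd.amax.assign((size_t)C * cols, 0);
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < nd.W; ++w)
            for (int h = 0; h < nd.H; ++h) {
              arma::uword dst = h + (arma::uword)nd.H * (w + (arma::uword)nd.W * n);
              const T* s0 = A.colptr(2 * h     + Hi * (2 * w     + (arma::uword)Wi * n));
              const T* s1 = A.colptr(2 * h + 1 + Hi * (2 * w     + (arma::uword)Wi * n));
              const T* s2 = A.colptr(2 * h     + Hi * (2 * w + 1 + (arma::uword)Wi * n));
              const T* s3 = A.colptr(2 * h + 1 + Hi * (2 * w + 1 + (arma::uword)Wi * n));
              T* y = nd.out.colptr(dst);
              unsigned char* am = nd.amax.data() + (size_t)C * dst;
              for (int c = 0; c < C; ++c) {
                T v = s0[c]; unsigned char a = 0;
                if (s1[c] > v) { v = s1[c]; a = 1; }
                if (s2[c] > v) { v = s2[c]; a = 2; }
                if (s3[c] > v) { v = s3[c]; a = 3; }
                y[c] = v; am[c] = a;
              }
            }
      } else if (nd.op == "upsample") {
        int Hi = na.H, Wi = na.W, C = nd.C;
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < nd.W; ++w) {
            int j0, j1; double u0, u1;
            up_taps(Wi, w, j0, j1, u0, u1);
            for (int h = 0; h < nd.H; ++h) {
              int i0, i1; double v0, v1;
              up_taps(Hi, h, i0, i1, v0, v1);
              const T* s00 = A.colptr(i0 + Hi * (j0 + (arma::uword)Wi * n));
              const T* s10 = A.colptr(i1 + Hi * (j0 + (arma::uword)Wi * n));
              const T* s01 = A.colptr(i0 + Hi * (j1 + (arma::uword)Wi * n));
              const T* s11 = A.colptr(i1 + Hi * (j1 + (arma::uword)Wi * n));
              T* y = nd.out.colptr(h + (arma::uword)nd.H * (w + (arma::uword)nd.W * n));
              T a00 = (T)(v0 * u0), a10 = (T)(v1 * u0), a01 = (T)(v0 * u1), a11 = (T)(v1 * u1);
              for (int c = 0; c < C; ++c)
                y[c] = a00 * s00[c] + a10 * s10[c] + a01 * s01[c] + a11 * s11[c];
            }
          }
      } else {
        stop("unknown op: " + nd.op);
      }
    }
  }

  // backward from a seed gradient placed on node 'seed_at' (0-based);
  // assumes forward(train = true) was just run. Gradient buffers come from
  // a size-keyed pool and are returned as soon as a node is processed.
  void backward(int seed_at, const arma::Mat<T>& seed) {
    auto ensure = [&](int j) {
      Node<T>& m = nodes[j];
      if (!m.g) {
        m.g = pool.acquire(m.C, (arma::uword)m.H * m.W * N);
        m.g->zeros();
      }
    };
    ensure(seed_at);
    *nodes[seed_at].g = seed;
    for (int i = seed_at; i >= 0; --i) {
      Node<T>& nd = nodes[i];
      if (!nd.g) continue;
      if (nd.op == "input") { pool.release(nd.g); nd.g = nullptr; continue; }
      OpTimer tm(this, nd.op + "_bw");
      arma::Mat<T>& dY = *nd.g;
      Node<T>& na = nodes[nd.in1];

      if (nd.op == "conv") {
        ensure(nd.in1);
        const arma::Mat<T>& A = na.out;
        if (nd.bias) nd.db = arma::sum(dY, 1);
        if (nd.k == 1) {
          nd.dW = dY * A.t();
          (*na.g) += nd.Wt.t() * dY;
        } else {
          resize_to(nd.dW, nd.Wt.n_rows, nd.Wt.n_cols);
          int p = (nd.k - 1) / 2, o = 0;
          arma::Mat<T> tmp;
          for (int dx = -p; dx <= p; ++dx)
            for (int dy = -p; dy <= p; ++dy, ++o) {
              shift_copy(A, nd.aux, nd.H, nd.W, N, dy, dx);
              nd.dW.cols((arma::uword)o * nd.cin, (arma::uword)(o + 1) * nd.cin - 1) =
                dY * nd.aux.t();
              tmp = nd.Wt.cols((arma::uword)o * nd.cin,
                               (arma::uword)(o + 1) * nd.cin - 1).t() * dY;
              shift_scatter(tmp, (*na.g), nd.H, nd.W, N, dy, dx);
            }
        }
      } else if (nd.op == "dwconv") {
        ensure(nd.in1);
        const arma::Mat<T>& A = na.out;
        if (nd.bias) nd.db = arma::sum(dY, 1);
        resize_to(nd.dW, nd.Wt.n_rows, nd.Wt.n_cols);
        nd.dW.zeros();
        int C = nd.C, H = nd.H, W = nd.W, p = (nd.k - 1) / 2;
        const T* dybase[49]; const T* wv[49]; T* dwv[49]; int dys[49];
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < W; ++w) {
            int nt = 0, o = 0;
            for (int dx = -p; dx <= p; ++dx)
              for (int dy = -p; dy <= p; ++dy, ++o)
                if (w - dx >= 0 && w - dx < W) {
                  dybase[nt] = dY.colptr((arma::uword)H * ((w - dx) + (arma::uword)W * n));
                  wv[nt] = nd.Wt.colptr(o);
                  dwv[nt] = nd.dW.colptr(o);
                  dys[nt] = dy; ++nt;
                }
            const T* abase = A.colptr((arma::uword)H * (w + (arma::uword)W * n));
            T* gbase = (*na.g).colptr((arma::uword)H * (w + (arma::uword)W * n));
            for (int h = 0; h < H; ++h) {
              const T* ac = abase + (size_t)h * C;
              T* gc = gbase + (size_t)h * C;
              for (int t = 0; t < nt; ++t) {
                int hd = h - dys[t];
                if (hd < 0 || hd >= H) continue;
                const T* dyc = dybase[t] + (size_t)hd * C;
                const T* ww = wv[t]; T* dw = dwv[t];
                for (int c = 0; c < C; ++c) {
                  gc[c] += ww[c] * dyc[c];
                  dw[c] += ac[c] * dyc[c];
                }
              }
            }
          }
      } else if (nd.op == "bn") {
        ensure(nd.in1);
        const arma::Mat<T>& A = na.out;
        int C = nd.C;
        arma::uword m = A.n_cols;
        arma::Col<T> sdy(C, arma::fill::zeros), sdyx(C, arma::fill::zeros);
        {
          T* p1 = sdy.memptr(); T* p2 = sdyx.memptr();
          const T* mup = nd.mu.memptr(); const T* isp = nd.istd.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j); const T* d = dY.colptr(j);
            for (int c = 0; c < C; ++c) {
              p1[c] += d[c];
              p2[c] += d[c] * (a[c] - mup[c]) * isp[c];
            }
          }
        }
        nd.dgamma = sdyx; nd.dbeta = sdy;
        // dX = gamma*istd/m * (m*dY - sum(dY) - xhat*sum(dY*xhat))
        arma::Col<T> k1 = nd.gamma % nd.istd;                    // * dY
        arma::Col<T> k2 = k1 % sdyx % nd.istd / (T)m;            // * (A - mu)
        arma::Col<T> k0 = (T)-1 / (T)m * k1 % sdy + k2 % nd.mu;  // constant
        {
          const T* q0 = k0.memptr(); const T* q1 = k1.memptr(); const T* q2 = k2.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j); const T* d = dY.colptr(j);
            T* g = (*na.g).colptr(j);
            for (int c = 0; c < C; ++c)
              g[c] += q1[c] * d[c] - q2[c] * a[c] + q0[c];
          }
        }
      } else if (nd.op == "swish") {
        ensure(nd.in1);
        swish_bwd_kernel(na.out.memptr(), nd.aux.memptr(), dY.memptr(),
                         (*na.g).memptr(), dY.n_elem);
      } else if (nd.op == "bnswish") {
        ensure(nd.in1);
        const arma::Mat<T>& A = na.out;
        int C = nd.C;
        arma::uword m = A.n_cols;
        arma::Col<T> scale = nd.istd % nd.gamma;
        arma::Col<T> shift = nd.beta - nd.mu % scale;
        arma::Col<T> sdz(C, arma::fill::zeros), sdzx(C, arma::fill::zeros);
        {
          // pass 1: dz = dY * s * (1 + z(1-s)); overwrite aux (s) with dz
          const T* scp = scale.memptr(); const T* shp = shift.memptr();
          const T* mup = nd.mu.memptr(); const T* isp = nd.istd.memptr();
          T* p1 = sdz.memptr(); T* p2 = sdzx.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j); const T* d = dY.colptr(j);
            T* x = nd.aux.colptr(j);
            for (int c = 0; c < C; ++c) {
              T z = a[c] * scp[c] + shp[c];
              T s = x[c];
              T dz = d[c] * s * ((T)1 + z * ((T)1 - s));
              x[c] = dz;
              p1[c] += dz;
              p2[c] += dz * (a[c] - mup[c]) * isp[c];
            }
          }
        }
        nd.dgamma = sdzx; nd.dbeta = sdz;
        arma::Col<T> k1 = nd.gamma % nd.istd;
        arma::Col<T> k2 = k1 % sdzx % nd.istd / (T)m;
        arma::Col<T> k0 = (T)-1 / (T)m * k1 % sdz + k2 % nd.mu;
        {
          // pass 2: dX += k1*dz - k2*a + k0
          const T* q0 = k0.memptr(); const T* q1 = k1.memptr(); const T* q2 = k2.memptr();
          for (arma::uword j = 0; j < m; ++j) {
            const T* a = A.colptr(j); const T* x = nd.aux.colptr(j);
            T* gp = (*na.g).colptr(j);
            for (int c = 0; c < C; ++c)
              gp[c] += q1[c] * x[c] - q2[c] * a[c] + q0[c];
          }
        }
      } else if (nd.op == "sigmoid") {
        ensure(nd.in1);
        (*na.g) += dY % nd.out % (1.0 - nd.out);
      } else if (nd.op == "gap") {
        ensure(nd.in1);
        arma::uword hw = (arma::uword)na.H * na.W;
        for (int n = 0; n < N; ++n)
          (*na.g).cols(n * hw, (n + 1) * hw - 1).each_col() += dY.col(n) / (T)hw;
      } else if (nd.op == "chanscale") {
        Node<T>& ng = nodes[nd.in2];
        ensure(nd.in1); ensure(nd.in2);
        const arma::Mat<T>& A = na.out;
        const arma::Mat<T>& G = ng.out;
        arma::uword hw = (arma::uword)nd.H * nd.W;
        int C = nd.C;
        for (int n = 0; n < N; ++n) {
          const T* gv = G.colptr(n);
          T* gg = (*ng.g).colptr(n);
          for (arma::uword j = n * hw; j < (n + 1) * hw; ++j) {
            const T* a = A.colptr(j); const T* d = dY.colptr(j);
            T* ga = (*na.g).colptr(j);
            for (int c = 0; c < C; ++c) {
              gg[c] += d[c] * a[c];
              ga[c] += d[c] * gv[c];
            }
          }
        }
      } else if (nd.op == "mul") {
        Node<T>& nb = nodes[nd.in2];
        ensure(nd.in1); ensure(nd.in2);
        (*na.g) += dY % nb.out;
        (*nb.g) += dY % na.out;
      } else if (nd.op == "add") {
        Node<T>& nb = nodes[nd.in2];
        ensure(nd.in1); ensure(nd.in2);
        (*na.g) += dY;
        (*nb.g) += dY;
      } else if (nd.op == "concat") {
        Node<T>& nb = nodes[nd.in2];
        ensure(nd.in1); ensure(nd.in2);
        (*na.g) += dY.rows(0, na.C - 1);
        (*nb.g) += dY.rows(na.C, nd.C - 1);
      } else if (nd.op == "maxpool") {
        ensure(nd.in1);
        int Hi = na.H, Wi = na.W, C = nd.C;
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < nd.W; ++w)
            for (int h = 0; h < nd.H; ++h) {
              arma::uword src = h + (arma::uword)nd.H * (w + (arma::uword)nd.W * n);
              const T* d = dY.colptr(src);
              const unsigned char* am = nd.amax.data() + (size_t)C * src;
              for (int c = 0; c < C; ++c) {
                int hh = 2 * h + (am[c] & 1), ww = 2 * w + (am[c] >> 1);
                (*na.g)(c, hh + Hi * (ww + (arma::uword)Wi * n)) += d[c];
              }
            }
      } else if (nd.op == "upsample") {
        ensure(nd.in1);
        int Hi = na.H, Wi = na.W, C = nd.C;
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < nd.W; ++w) {
            int j0, j1; double u0, u1;
            up_taps(Wi, w, j0, j1, u0, u1);
            for (int h = 0; h < nd.H; ++h) {
              int i0, i1; double v0, v1;
              up_taps(Hi, h, i0, i1, v0, v1);
              const T* d = dY.colptr(h + (arma::uword)nd.H * (w + (arma::uword)nd.W * n));
              T* g00 = (*na.g).colptr(i0 + Hi * (j0 + (arma::uword)Wi * n));
              T* g10 = (*na.g).colptr(i1 + Hi * (j0 + (arma::uword)Wi * n));
              T* g01 = (*na.g).colptr(i0 + Hi * (j1 + (arma::uword)Wi * n));
              T* g11 = (*na.g).colptr(i1 + Hi * (j1 + (arma::uword)Wi * n));
              T a00 = (T)(v0 * u0), a10 = (T)(v1 * u0), a01 = (T)(v0 * u1), a11 = (T)(v1 * u1);
              for (int c = 0; c < C; ++c) {
                g00[c] += a00 * d[c]; g10[c] += a10 * d[c];
                g01[c] += a01 * d[c]; g11[c] += a11 * d[c];
              }
            }
          }
      }
      pool.release(nd.g);
      nd.g = nullptr;
    }
  }

  void adam_step(double lr, double b1, double b2, double eps, double wd) {
    ++adam_t;
    double c1 = 1.0 - std::pow(b1, (double)adam_t);
    double c2 = 1.0 - std::pow(b2, (double)adam_t);
    auto upd = [&](arma::Mat<T>& w, arma::Mat<T>& g, arma::Mat<T>& m, arma::Mat<T>& v, bool decay) {
      if (w.n_elem == 0 || g.n_elem == 0) return;
      if (m.n_elem == 0) { m.zeros(arma::size(w)); v.zeros(arma::size(w)); }
      const T tb1 = (T)b1, tb2 = (T)b2;
      T* wp = w.memptr(); T* gp = g.memptr(); T* mp = m.memptr(); T* vp = v.memptr();
      for (arma::uword j = 0; j < w.n_elem; ++j) {
        mp[j] = tb1 * mp[j] + (1 - tb1) * gp[j];
        vp[j] = tb2 * vp[j] + (1 - tb2) * gp[j] * gp[j];
        T step = (T)((mp[j] / c1) / (std::sqrt(vp[j] / c2) + eps));
        if (decay) step += (T)wd * wp[j];
        wp[j] -= (T)lr * step;
      }
    };
    auto updc = [&](arma::Col<T>& w, arma::Col<T>& g, arma::Col<T>& m, arma::Col<T>& v, bool decay) {
      if (w.n_elem == 0 || g.n_elem == 0) return;
      if (m.n_elem == 0) { m.zeros(arma::size(w)); v.zeros(arma::size(w)); }
      arma::Mat<T> wm(w.memptr(), w.n_elem, 1, false, true);
      arma::Mat<T> gm(g.memptr(), g.n_elem, 1, false, true);
      arma::Mat<T> mm(m.memptr(), m.n_elem, 1, false, true);
      arma::Mat<T> vm(v.memptr(), v.n_elem, 1, false, true);
      upd(wm, gm, mm, vm, decay);
    };
    for (auto& nd : nodes) {
      upd(nd.Wt, nd.dW, nd.mW, nd.vW, true);
      updc(nd.b, nd.db, nd.mb, nd.vb, false);
      updc(nd.gamma, nd.dgamma, nd.mg, nd.vg, false);
      updc(nd.beta, nd.dbeta, nd.mbe, nd.vbe, false);
    }
  }
};

// ---------------------------------------------------------------------------
// R interface

template <typename T>
static arma::Mat<T> r_to_tensor(const NumericVector& x, int H, int W, int C, int N) {
  // R array [H, W, C, N] -> engine [C, H*W*N]
  arma::Mat<T> out((arma::uword)C, (arma::uword)H * W * N);
  const double* p = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        const double* src = p + (size_t)H * (w + (size_t)W * (c + (size_t)C * n));
        for (int h = 0; h < H; ++h)
          out(c, h + (size_t)H * (w + (size_t)W * n)) = (T)src[h];
      }
  return out;
}

template <typename T>
static NumericVector tensor_to_r(const arma::Mat<T>& m, int H, int W, int C, int N) {
  NumericVector out((R_xlen_t)H * W * C * N);
  double* p = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w) {
        double* dst = p + (size_t)H * (w + (size_t)W * (c + (size_t)C * n));
        for (int h = 0; h < H; ++h)
          dst[h] = (double)m(c, h + (size_t)H * (w + (size_t)W * n));
      }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

struct EngineHandle {
  Engine<float>* ef = nullptr;
  Engine<double>* ed = nullptr;
  ~EngineHandle() { delete ef; delete ed; }
};

static EngineHandle* get_handle(SEXP ptr) {
  Rcpp::XPtr<EngineHandle> xp(ptr);
  EngineHandle* h = xp.get();
  if (h == nullptr) stop("invalid engine pointer");
  return h;
}

// [[Rcpp::export]]
SEXP eng_create(List graph, std::string precision) {
  EngineHandle* h = new EngineHandle();
  if (precision == "single") h->ef = new Engine<float>(graph);
  else h->ed = new Engine<double>(graph);
  Rcpp::XPtr<EngineHandle> xp(h, true);
  return xp;
}

// [[Rcpp::export]]
void eng_init(SEXP ptr, int seed) {
  EngineHandle* h = get_handle(ptr);
  if (h->ef) h->ef->init(seed); else h->ed->init(seed);
}

// [[Rcpp::export]]
double eng_nparams(SEXP ptr) {
  EngineHandle* h = get_handle(ptr);
  return (double)(h->ef ? h->ef->nparams() : h->ed->nparams());
}

template <typename T>
static NumericVector forward_impl(Engine<T>* e, NumericVector x, bool train) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::Mat<T> X = r_to_tensor<T>(x, H, W, C, N);
  e->forward(X, N, train);
  Node<T>& last = e->nodes.back();
  return tensor_to_r(last.out, last.H, last.W, last.C, N);
}

// [[Rcpp::export]]
NumericVector eng_forward(SEXP ptr, NumericVector x, bool train) {
  EngineHandle* h = get_handle(ptr);
  return h->ef ? forward_impl(h->ef, x, train) : forward_impl(h->ed, x, train);
}

template <typename T>
static double bce_of(const arma::Mat<T>& P, const arma::Mat<T>& Tt) {
  double eps = 1e-7, s = 0;
  for (arma::uword i = 0; i < P.n_elem; ++i) {
    double p = std::min(1.0 - eps, std::max(eps, (double)P(i)));
    s += (double)Tt(i) * std::log(p) + (1.0 - (double)Tt(i)) * std::log(1.0 - p);
  }
  return -s / (double)P.n_elem;
}

// train/val tensors arrive as [H,W,C,N] arrays; returns [epochs, 2] losses
template <typename T>
static NumericMatrix train_impl(Engine<T>* e, NumericVector x, NumericVector y,
                                int epochs, int batch, double lr, double b1, double b2,
                                double eps, double wd, int seed,
                                Nullable<NumericVector> valx, Nullable<NumericVector> valy) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::Mat<T> X = r_to_tensor<T>(x, H, W, C, N);
  arma::Mat<T> Y = r_to_tensor<T>(y, H, W, 1, N);
  arma::Mat<T> VX, VY; int NV = 0;
  if (valx.isNotNull()) {
    NumericVector vx(valx), vy(valy);
    IntegerVector dv = vx.attr("dim");
    NV = dv[3];
    VX = r_to_tensor<T>(vx, H, W, C, NV);
    VY = r_to_tensor<T>(vy, H, W, 1, NV);
  }
  arma::uword hw = (arma::uword)H * W;
  int seed_node = (int)e->nodes.size() - 2;   // node feeding the final sigmoid
  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  NumericMatrix log(epochs, 2);
  arma::Mat<T> xb, yb, seed_g;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double tot = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int nb = std::min(batch, N - s0);
      xb.set_size(X.n_rows, hw * nb);
      yb.set_size(1, hw * nb);
      for (int j = 0; j < nb; ++j) {
        xb.cols(j * hw, (j + 1) * hw - 1) =
          X.cols((arma::uword)idx[s0 + j] * hw, (arma::uword)(idx[s0 + j] + 1) * hw - 1);
        yb.cols(j * hw, (j + 1) * hw - 1) =
          Y.cols((arma::uword)idx[s0 + j] * hw, (arma::uword)(idx[s0 + j] + 1) * hw - 1);
      }
      e->forward(xb, nb, true);
      const arma::Mat<T>& P = e->nodes.back().out;
      double L = bce_of(P, yb);
      if (!std::isfinite(L)) stop("training diverged: non-finite loss");
      tot += L * nb;
      seed_g = (P - yb) / (T)P.n_elem;   // fused sigmoid + BCE gradient
      e->backward(seed_node, seed_g);
      e->adam_step(lr, b1, b2, eps, wd);
    }
    log(ep, 0) = tot / N;
    if (NV > 0) {
      double vt = 0;
      for (int s0 = 0; s0 < NV; s0 += batch) {
        int nb = std::min(batch, NV - s0);
        xb = VX.cols((arma::uword)s0 * hw, (arma::uword)(s0 + nb) * hw - 1);
        yb = VY.cols((arma::uword)s0 * hw, (arma::uword)(s0 + nb) * hw - 1);
        e->forward(xb, nb, false);
        vt += bce_of(e->nodes.back().out, yb) * nb;
      }
      log(ep, 1) = vt / NV;
    } else {
      log(ep, 1) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return log;
}

// [[Rcpp::export]]
NumericMatrix eng_train(SEXP ptr, NumericVector x, NumericVector y,
                        int epochs, int batch, double lr, double b1, double b2,
                        double eps, double wd, int seed,
                        Nullable<NumericVector> valx = R_NilValue,
                        Nullable<NumericVector> valy = R_NilValue) {
  EngineHandle* h = get_handle(ptr);
  return h->ef ? train_impl(h->ef, x, y, epochs, batch, lr, b1, b2, eps, wd, seed, valx, valy)
               : train_impl(h->ed, x, y, epochs, batch, lr, b1, b2, eps, wd, seed, valx, valy);
}

template <typename T>
static List weights_impl(Engine<T>* e) {
  List out(e->nodes.size());
  for (size_t i = 0; i < e->nodes.size(); ++i) {
    Node<T>& nd = e->nodes[i];
    out[i] = List::create(
      _["W"] = nd.Wt.n_elem ? wrap(arma::conv_to<arma::mat>::from(nd.Wt)) : R_NilValue,
      _["b"] = nd.b.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.b)) : R_NilValue,
      _["gamma"] = nd.gamma.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.gamma)) : R_NilValue,
      _["beta"] = nd.beta.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.beta)) : R_NilValue,
      _["rmean"] = nd.rmean.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.rmean)) : R_NilValue,
      _["rvar"] = nd.rvar.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.rvar)) : R_NilValue);
  }
  return out;
}

template <typename T>
static void set_weights_impl(Engine<T>* e, List w) {
  if ((size_t)w.size() != e->nodes.size()) stop("weight list length mismatch");
  for (size_t i = 0; i < e->nodes.size(); ++i) {
    List wi = w[i];
    Node<T>& nd = e->nodes[i];
    if (nd.Wt.n_elem) {
      arma::mat m = as<arma::mat>(wi["W"]);
      if (m.n_rows != nd.Wt.n_rows || m.n_cols != nd.Wt.n_cols)
        stop("weight shape mismatch at node %d", (int)i + 1);
      nd.Wt = arma::conv_to<arma::Mat<T>>::from(m);
    }
    if (nd.b.n_elem) nd.b = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(wi["b"]));
    if (nd.gamma.n_elem) {
      nd.gamma = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(wi["gamma"]));
      nd.beta  = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(wi["beta"]));
      nd.rmean = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(wi["rmean"]));
      nd.rvar  = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(wi["rvar"]));
    }
  }
}

// [[Rcpp::export]]
List eng_weights(SEXP ptr) {
  EngineHandle* h = get_handle(ptr);
  return h->ef ? weights_impl(h->ef) : weights_impl(h->ed);
}

// [[Rcpp::export]]
void eng_set_weights(SEXP ptr, List w) {
  EngineHandle* h = get_handle(ptr);
  if (h->ef) set_weights_impl(h->ef, w); else set_weights_impl(h->ed, w);
}

template <typename T>
static double loss_impl(Engine<T>* e, NumericVector x, NumericVector y, bool train) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::Mat<T> X = r_to_tensor<T>(x, H, W, C, N);
  arma::Mat<T> Y = r_to_tensor<T>(y, H, W, 1, N);
  e->forward(X, N, train);
  return bce_of(e->nodes.back().out, Y);
}

// [[Rcpp::export]]
double eng_loss(SEXP ptr, NumericVector x, NumericVector y, bool train = false) {
  EngineHandle* h = get_handle(ptr);
  return h->ef ? loss_impl(h->ef, x, y, train) : loss_impl(h->ed, x, y, train);
}

template <typename T>
static List grad_impl(Engine<T>* e, NumericVector x, NumericVector y) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::Mat<T> X = r_to_tensor<T>(x, H, W, C, N);
  arma::Mat<T> Y = r_to_tensor<T>(y, H, W, 1, N);
  e->forward(X, N, true);
  const arma::Mat<T>& P = e->nodes.back().out;
  arma::Mat<T> seed_g = (P - Y) / (T)P.n_elem;
  e->backward((int)e->nodes.size() - 2, seed_g);
  List out(e->nodes.size());
  for (size_t i = 0; i < e->nodes.size(); ++i) {
    Node<T>& nd = e->nodes[i];
    out[i] = List::create(
      _["dW"] = nd.dW.n_elem ? wrap(arma::conv_to<arma::mat>::from(nd.dW)) : R_NilValue,
      _["db"] = nd.db.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.db)) : R_NilValue,
      _["dgamma"] = nd.dgamma.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.dgamma)) : R_NilValue,
      _["dbeta"] = nd.dbeta.n_elem ? wrap(arma::conv_to<arma::vec>::from(nd.dbeta)) : R_NilValue);
  }
  return out;
}

// [[Rcpp::export]]
List eng_grad(SEXP ptr, NumericVector x, NumericVector y) {
  EngineHandle* h = get_handle(ptr);
  return h->ef ? grad_impl(h->ef, x, y) : grad_impl(h->ed, x, y);
}

template <typename T>
static NumericVector profile_impl(Engine<T>* e, NumericVector x, NumericVector y, int reps) {
  IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], N = d[3];
  arma::Mat<T> X = r_to_tensor<T>(x, H, W, C, N);
  arma::Mat<T> Y = r_to_tensor<T>(y, H, W, 1, N);
  e->prof.clear();
  e->profiling = true;
  for (int r = 0; r < reps; ++r) {
    e->forward(X, N, true);
    const arma::Mat<T>& P = e->nodes.back().out;
    arma::Mat<T> seed_g = (P - Y) / (T)P.n_elem;
    e->backward((int)e->nodes.size() - 2, seed_g);
    e->adam_step(1e-3, 0.99, 0.999, 1e-7, 5e-4);
  }
  e->profiling = false;
  NumericVector out(e->prof.size());
  CharacterVector nm(e->prof.size());
  int i = 0;
  for (auto& kv : e->prof) { nm[i] = kv.first; out[i] = kv.second; ++i; }
  out.attr("names") = nm;
  return out;
}

// per-op cumulative wall time over 'reps' full training steps (dev tool)
// [[Rcpp::export]]
NumericVector eng_profile(SEXP ptr, NumericVector x, NumericVector y, int reps = 1) {
  EngineHandle* h = get_handle(ptr);
  return h->ef ? profile_impl(h->ef, x, y, reps) : profile_impl(h->ed, x, y, reps);
}
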