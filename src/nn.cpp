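// Minimal float32 CNN engine: MobileNetV2 encoder + U-Net decoder variants,
// im2col+GEMM convolutions, manual backprop, Adam. Single-threaded, CPU.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <memory>
#include <random>
#include <chrono>
#include <map>
static std::map<std::string,double> g_tim;
struct TimerG { std::string k; std::chrono::high_resolution_clock::time_point t0; TimerG(const char* k_):k(k_),t0(std::chrono::high_resolution_clock::now()){} ~TimerG(){ g_tim[k]+=std::chrono::duration<double>(std::chrono::high_resolution_clock::now()-t0).count(); } };

using arma::fmat;
using arma::frowvec;

// Activation tensor: (N*H*W) x C, pixel row-major (p = y*W + x), images in
// consecutive row blocks.
struct Tensor {
  fmat a;
  int N = 0, H = 0, W = 0, C = 0;
  void set(int N_, int H_, int W_, int C_) {
    N = N_; H = H_; W = W_; C = C_;
    a.set_size((size_t)N * H * W, C);
  }
  size_t rows() const { return (size_t)N * H * W; }
};

struct Param {
  fmat w, g, m, v;
  void init(int r, int c) {
    w.set_size(r, c);
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

struct Net;

struct Layer {
  std::vector<int> in;
  Tensor out, gout;
  virtual void forward(Net& net, bool train) = 0;
  virtual void backward(Net& net) = 0;
  virtual std::vector<Param*> params() { return {}; }
  virtual std::vector<fmat*> buffers() { return {}; }  // non-trained state (BN running stats)
  // drop activation/workspace memory (weights and state are kept); the next
  // forward pass re-allocates as needed
  virtual void release() { out.a.reset(); gout.a.reset(); }
  virtual ~Layer() {}
};

struct Net {
  std::vector<std::unique_ptr<Layer>> nodes;
  std::mt19937 rng;
  long adam_t = 0;
  Tensor& T(int i) { return nodes[i]->out; }
  Tensor& G(int i) { return nodes[i]->gout; }
  // gradient accumulator for node i's output, allocated and zeroed on first
  // use in a backward pass (tensors are freed as soon as a node's backward
  // has consumed them, keeping the peak footprint near the forward size)
  fmat& gacc(int i) {
    Tensor& o = nodes[i]->out;
    Tensor& g = nodes[i]->gout;
    if (g.a.n_rows != o.rows() || g.a.n_cols != (arma::uword)o.C) {
      g.set(o.N, o.H, o.W, o.C);
      g.a.zeros();
    }
    return g.a;
  }
  int add(Layer* l) { nodes.emplace_back(l); return (int)nodes.size() - 1; }
  std::vector<Param*> all_params() {
    std::vector<Param*> ps;
    for (auto& n : nodes) for (auto* p : n->params()) ps.push_back(p);
    return ps;
  }
  std::vector<fmat*> all_buffers() {
    std::vector<fmat*> bs;
    for (auto& n : nodes) for (auto* b : n->buffers()) bs.push_back(b);
    return bs;
  }
  void fill_he(fmat& w, int fan_in) {
    std::normal_distribution<float> d(0.f, std::sqrt(2.0f / fan_in));
    for (auto& x : w) x = d(rng);
  }
};

static inline int out_dim(int H, int s) { return (H + s - 1) / s; }
static inline int pad_before(int H, int H2, int k, int s) {
  int tot = (H2 - 1) * s + k - H;
  if (tot < 0) tot = 0;
  return tot / 2;
}

struct Input : Layer {
  void forward(Net&, bool) override {}
  void backward(Net&) override {}
};

// 3x3 convolution, 'same' padding, via im2col + GEMM.
struct Conv3 : Layer {
  int stride, cin, cout;
  bool bias;
  Param W, B;
  fmat colbuf, dcolbuf;
  Conv3(int in_, int cin_, int cout_, int stride_, bool bias_, Net& net) {
    in = {in_}; cin = cin_; cout = cout_; stride = stride_; bias = bias_;
    W.init(cin * 9, cout);
    net.fill_he(W.w, cin * 9);
    if (bias) { B.init(1, cout); B.w.zeros(); }
  }
  std::vector<Param*> params() override {
    if (bias) return {&W, &B};
    return {&W};
  }
  void release() override {
    out.a.reset(); gout.a.reset(); colbuf.reset(); dcolbuf.reset();
  }
  void im2col(const fmat& A, size_t off, int H, int Wd, int H2, int W2, int pT, int pL) {
    for (int c = 0; c < cin; c++) {
      const float* src = A.colptr(c) + off;
      for (int ky = 0; ky < 3; ky++) for (int kx = 0; kx < 3; kx++) {
        float* dst = colbuf.colptr((size_t)c * 9 + ky * 3 + kx);
        // valid ox range: 0 <= ox*stride + kx - pL < Wd
        int ox0 = std::max(0, (pL - kx + stride - 1) / stride);
        int ox1 = std::min(W2, (Wd - 1 - kx + pL) / stride + 1);
        for (int oy = 0; oy < H2; oy++) {
          int iy = oy * stride + ky - pT;
          float* d = dst + (size_t)oy * W2;
          if (iy < 0 || iy >= H) { std::fill(d, d + W2, 0.f); continue; }
          const float* s = src + (size_t)iy * Wd + kx - pL;
          for (int ox = 0; ox < ox0; ox++) d[ox] = 0.f;
          if (stride == 1) {
            std::copy(s + ox0, s + ox1, d + ox0);
          } else {
            for (int ox = ox0; ox < ox1; ox++) d[ox] = s[(size_t)ox * stride];
          }
          for (int ox = ox1; ox < W2; ox++) d[ox] = 0.f;
        }
      }
    }
  }
  void col2im_add(fmat& GA, size_t off, int H, int Wd, int H2, int W2, int pT, int pL,
                  const fmat& dcol) {
    for (int c = 0; c < cin; c++) {
      float* dst = GA.colptr(c) + off;
      for (int ky = 0; ky < 3; ky++) for (int kx = 0; kx < 3; kx++) {
        const float* src = dcol.colptr((size_t)c * 9 + ky * 3 + kx);
        int ox0 = std::max(0, (pL - kx + stride - 1) / stride);
        int ox1 = std::min(W2, (Wd - 1 - kx + pL) / stride + 1);
        for (int oy = 0; oy < H2; oy++) {
          int iy = oy * stride + ky - pT;
          if (iy < 0 || iy >= H) continue;
          const float* s = src + (size_t)oy * W2;
          float* d = dst + (size_t)iy * Wd + kx - pL;
          if (stride == 1) {
            for (int ox = ox0; ox < ox1; ox++) d[ox] += s[ox];
          } else {
            for (int ox = ox0; ox < ox1; ox++) d[(size_t)ox * stride] += s[ox];
          }
        }
      }
    }
  }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    int H = X.H, Wd = X.W;
    int H2 = out_dim(H, stride), W2 = out_dim(Wd, stride);
    int pT = pad_before(H, H2, 3, stride), pL = pad_before(Wd, W2, 3, stride);
    out.set(X.N, H2, W2, cout);
    colbuf.set_size((size_t)H2 * W2, (size_t)cin * 9);
    for (int n = 0; n < X.N; n++) {
      im2col(X.a, (size_t)n * H * Wd, H, Wd, H2, W2, pT, pL);
      out.a.rows((size_t)n * H2 * W2, (size_t)(n + 1) * H2 * W2 - 1) = colbuf * W.w;
    }
    if (bias) out.a.each_row() += B.w.row(0);
  }
  void backward(Net& net) override {
    Tensor& X = net.T(in[0]);
    fmat& GX = net.gacc(in[0]);
    int H = X.H, Wd = X.W, H2 = out.H, W2 = out.W;
    int pT = pad_before(H, H2, 3, stride), pL = pad_before(Wd, W2, 3, stride);
    if (bias) B.g += arma::sum(gout.a, 0);
    colbuf.set_size((size_t)H2 * W2, (size_t)cin * 9);
    dcolbuf.set_size((size_t)H2 * W2, (size_t)cin * 9);
    for (int n = 0; n < X.N; n++) {
      im2col(X.a, (size_t)n * H * Wd, H, Wd, H2, W2, pT, pL);
      const auto gblock =
        gout.a.rows((size_t)n * H2 * W2, (size_t)(n + 1) * H2 * W2 - 1);
      W.g += colbuf.t() * gblock;
      dcolbuf = gblock * W.w.t();
      col2im_add(GX, (size_t)n * H * Wd, H, Wd, H2, W2, pT, pL, dcolbuf);
    }
    colbuf.reset();
    dcolbuf.reset();
  }
};

// 1x1 convolution (== dense over channels); also used as the final dense layer.
struct Conv1 : Layer {
  int cin, cout;
  bool bias;
  Param W, B;
  Conv1(int in_, int cin_, int cout_, bool bias_, Net& net) {
    in = {in_}; cin = cin_; cout = cout_; bias = bias_;
    W.init(cin, cout);
    net.fill_he(W.w, cin);
    if (bias) { B.init(1, cout); B.w.zeros(); }
  }
  std::vector<Param*> params() override {
    if (bias) return {&W, &B};
    return {&W};
  }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    out.set(X.N, X.H, X.W, cout);
    out.a = X.a * W.w;
    if (bias) out.a.each_row() += B.w.row(0);
  }
  void backward(Net& net) override {
    Tensor& X = net.T(in[0]);
    W.g += X.a.t() * gout.a;
    if (bias) B.g += arma::sum(gout.a, 0);
    net.gacc(in[0]) += gout.a * W.w.t();
  }
};

// 3x3 depthwise convolution, 'same' padding.
struct DW3 : Layer {
  int stride, c;
  Param W;  // 9 x C
  DW3(int in_, int c_, int stride_, Net& net) {
    in = {in_}; c = c_; stride = stride_;
    W.init(9, c);
    net.fill_he(W.w, 9);
  }
  std::vector<Param*> params() override { return {&W}; }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    int H = X.H, Wd = X.W;
    int H2 = out_dim(H, stride), W2 = out_dim(Wd, stride);
    int pT = pad_before(H, H2, 3, stride), pL = pad_before(Wd, W2, 3, stride);
    out.set(X.N, H2, W2, c);
    for (int n = 0; n < X.N; n++) {
      for (int ch = 0; ch < c; ch++) {
        const float* src = X.a.colptr(ch) + (size_t)n * H * Wd;
        float* dst = out.a.colptr(ch) + (size_t)n * H2 * W2;
        const float* w = W.w.colptr(ch);
        for (int oy = 0; oy < H2; oy++) {
          float* drow = dst + (size_t)oy * W2;
          int iy0 = oy * stride - pT;
          bool y_interior = iy0 >= 0 && iy0 + 2 < H;
          if (stride == 1 && y_interior) {
            // interior rows, stride 1: branch-free across the row body
            const float* r0 = src + (size_t)iy0 * Wd;
            const float* r1 = r0 + Wd;
            const float* r2 = r1 + Wd;
            int ox0 = std::max(0, pL);
            int ox1 = std::min(W2, Wd + pL - 2);
            const float *p0 = r0 - pL, *p1 = r1 - pL, *p2 = r2 - pL;
            for (int ox = ox0; ox < ox1; ox++) {
              drow[ox] = w[0] * p0[ox] + w[1] * p0[ox + 1] + w[2] * p0[ox + 2] +
                         w[3] * p1[ox] + w[4] * p1[ox + 1] + w[5] * p1[ox + 2] +
                         w[6] * p2[ox] + w[7] * p2[ox + 1] + w[8] * p2[ox + 2];
            }
            // border columns use the general (zero-padded) rule
            for (int ox = 0; ox < ox0; ox++) drow[ox] = dw_at(src, H, Wd, oy, ox, pT, pL, w);
            for (int ox = ox1; ox < W2; ox++) drow[ox] = dw_at(src, H, Wd, oy, ox, pT, pL, w);
          } else {
            for (int ox = 0; ox < W2; ox++)
              drow[ox] = dw_at(src, H, Wd, oy, ox, pT, pL, w);
          }
        }
      }
    }
  }
  inline float dw_at(const float* src, int H, int Wd, int oy, int ox, int pT,
                     int pL, const float* w) {
    float acc = 0.f;
    for (int ky = 0; ky < 3; ky++) {
      int iy = oy * stride + ky - pT;
      if (iy < 0 || iy >= H) continue;
      const float* s = src + (size_t)iy * Wd;
      for (int kx = 0; kx < 3; kx++) {
        int ix = ox * stride + kx - pL;
        if (ix >= 0 && ix < Wd) acc += w[ky * 3 + kx] * s[ix];
      }
    }
    return acc;
  }
  void backward(Net& net) override {
    Tensor& X = net.T(in[0]);
    fmat& GX = net.gacc(in[0]);
    int H = X.H, Wd = X.W, H2 = out.H, W2 = out.W;
    int pT = pad_before(H, H2, 3, stride), pL = pad_before(Wd, W2, 3, stride);
    for (int n = 0; n < X.N; n++) {
      for (int ch = 0; ch < c; ch++) {
        const float* src = X.a.colptr(ch) + (size_t)n * H * Wd;
        float* gsrc = GX.colptr(ch) + (size_t)n * H * Wd;
        const float* go = gout.a.colptr(ch) + (size_t)n * H2 * W2;
        const float* w = W.w.colptr(ch);
        float* gw = W.g.colptr(ch);
        for (int oy = 0; oy < H2; oy++) {
          for (int ox = 0; ox < W2; ox++) {
            float g = go[(size_t)oy * W2 + ox];
            if (g == 0.f) continue;
            for (int ky = 0; ky < 3; ky++) {
              int iy = oy * stride + ky - pT;
              if (iy < 0 || iy >= H) continue;
              for (int kx = 0; kx < 3; kx++) {
                int ix = ox * stride + kx - pL;
                if (ix < 0 || ix >= Wd) continue;
                gw[ky * 3 + kx] += g * src[(size_t)iy * Wd + ix];
                gsrc[(size_t)iy * Wd + ix] += g * w[ky * 3 + kx];
              }
            }
          }
        }
      }
    }
  }
};

// Batch normalization over batch x spatial, per channel.
struct BN : Layer {
  int c;
  Param Ga, Be;
  fmat rm, rv;           // running mean / var, 1 x C
  frowvec bm, bistd;     // batch statistics from the last training forward
  float eps = 1e-3f, mom = 0.1f;
  BN(int in_, int c_) {
    in = {in_}; c = c_;
    Ga.init(1, c); Ga.w.ones();
    Be.init(1, c); Be.w.zeros();
    rm.zeros(1, c); rv.ones(1, c);
  }
  std::vector<Param*> params() override { return {&Ga, &Be}; }
  std::vector<fmat*> buffers() override { return {&rm, &rv}; }
  void forward(Net& net, bool train) override {
    Tensor& X = net.T(in[0]);
    out.set(X.N, X.H, X.W, c);
    size_t Nr = X.rows();
    if (train) {
      bm.set_size(c); bistd.set_size(c);
      for (int ch = 0; ch < c; ch++) {
        const float* x = X.a.colptr(ch);
        double s = 0, s2 = 0;
        for (size_t i = 0; i < Nr; i++) { s += x[i]; s2 += (double)x[i] * x[i]; }
        double m = s / Nr, var = s2 / Nr - m * m;
        if (var < 0) var = 0;
        bm[ch] = (float)m;
        bistd[ch] = 1.0f / std::sqrt((float)var + eps);
        rm(0, ch) = (1 - mom) * rm(0, ch) + mom * (float)m;
        rv(0, ch) = (1 - mom) * rv(0, ch) + mom * (float)var;
        float g = Ga.w(0, ch), b = Be.w(0, ch), mu = bm[ch], is = bistd[ch];
        float* y = out.a.colptr(ch);
        for (size_t i = 0; i < Nr; i++) y[i] = g * (x[i] - mu) * is + b;
      }
    } else {
      for (int ch = 0; ch < c; ch++) {
        const float* x = X.a.colptr(ch);
        float is = 1.0f / std::sqrt(rv(0, ch) + eps);
        float g = Ga.w(0, ch), b = Be.w(0, ch), mu = rm(0, ch);
        float* y = out.a.colptr(ch);
        for (size_t i = 0; i < Nr; i++) y[i] = g * (x[i] - mu) * is + b;
      }
    }
  }
  void backward(Net& net) override {
    // training-mode backward (batch statistics)
    Tensor& X = net.T(in[0]);
    fmat& GX = net.gacc(in[0]);
    size_t Nr = X.rows();
    for (int ch = 0; ch < c; ch++) {
      const float* x = X.a.colptr(ch);
      const float* go = gout.a.colptr(ch);
      float mu = bm[ch], is = bistd[ch], g = Ga.w(0, ch);
      double sdy = 0, sdyx = 0;
      for (size_t i = 0; i < Nr; i++) {
        float xh = (x[i] - mu) * is;
        sdy += go[i];
        sdyx += (double)go[i] * xh;
      }
      Ga.g(0, ch) += (float)sdyx;
      Be.g(0, ch) += (float)sdy;
      float k1 = (float)(sdy / Nr), k2 = (float)(sdyx / Nr);
      float gis = g * is;
      float* gx = GX.colptr(ch);
      for (size_t i = 0; i < Nr; i++) {
        float xh = (x[i] - mu) * is;
        gx[i] += gis * (go[i] - k1 - xh * k2);
      }
    }
  }
};

// Clipped ReLU; cap = 6 for MobileNetV2 blocks, large cap gives plain ReLU.
struct ReLUcap : Layer {
  float cap;
  ReLUcap(int in_, float cap_) { in = {in_}; cap = cap_; }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    out.set(X.N, X.H, X.W, X.C);
    const float* x = X.a.memptr();
    float* y = out.a.memptr();
    size_t n = X.a.n_elem;
    for (size_t i = 0; i < n; i++)
      y[i] = std::min(std::max(x[i], 0.f), cap);
  }
  void backward(Net& net) override {
    float* gx = net.gacc(in[0]).memptr();
    const float* y = out.a.memptr();
    const float* go = gout.a.memptr();
    size_t n = out.a.n_elem;
    for (size_t i = 0; i < n; i++)
      gx[i] += (y[i] > 0.f && y[i] < cap) ? go[i] : 0.f;
  }
};

struct SigmoidL : Layer {
  SigmoidL(int in_) { in = {in_}; }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    out.set(X.N, X.H, X.W, X.C);
    const float* x = X.a.memptr();
    float* y = out.a.memptr();
    size_t n = X.a.n_elem;
    for (size_t i = 0; i < n; i++) y[i] = 1.0f / (1.0f + std::exp(-x[i]));
  }
  void backward(Net& net) override {
    float* gx = net.gacc(in[0]).memptr();
    const float* y = out.a.memptr();
    const float* go = gout.a.memptr();
    size_t n = out.a.n_elem;
    for (size_t i = 0; i < n; i++) gx[i] += go[i] * y[i] * (1.0f - y[i]);
  }
};

struct AddL : Layer {
  AddL(int a, int b) { in = {a, b}; }
  void forward(Net& net, bool) override {
    Tensor& A = net.T(in[0]);
    out.set(A.N, A.H, A.W, A.C);
    out.a = A.a + net.T(in[1]).a;
  }
  void backward(Net& net) override {
    net.gacc(in[0]) += gout.a;
    net.gacc(in[1]) += gout.a;
  }
};

struct ConcatC : Layer {
  ConcatC(int a, int b) { in = {a, b}; }
  void forward(Net& net, bool) override {
    Tensor& A = net.T(in[0]);
    Tensor& B = net.T(in[1]);
    out.set(A.N, A.H, A.W, A.C + B.C);
    out.a.cols(0, A.C - 1) = A.a;
    out.a.cols(A.C, A.C + B.C - 1) = B.a;
  }
  void backward(Net& net) override {
    Tensor& A = net.T(in[0]);
    Tensor& B = net.T(in[1]);
    net.gacc(in[0]) += gout.a.cols(0, A.C - 1);
    net.gacc(in[1]) += gout.a.cols(A.C, A.C + B.C - 1);
  }
};

// Nearest-neighbour x2 upsampling.
struct Up2 : Layer {
  Up2(int in_) { in = {in_}; }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    int H = X.H, Wd = X.W, H2 = 2 * H, W2 = 2 * Wd;
    out.set(X.N, H2, W2, X.C);
    for (int c = 0; c < X.C; c++) {
      for (int n = 0; n < X.N; n++) {
        const float* s = X.a.colptr(c) + (size_t)n * H * Wd;
        float* d = out.a.colptr(c) + (size_t)n * H2 * W2;
        for (int y = 0; y < H2; y++) {
          const float* sr = s + (size_t)(y / 2) * Wd;
          float* dr = d + (size_t)y * W2;
          for (int x = 0; x < W2; x++) dr[x] = sr[x / 2];
        }
      }
    }
  }
  void backward(Net& net) override {
    Tensor& X = net.T(in[0]);
    fmat& GX = net.gacc(in[0]);
    int H = X.H, Wd = X.W, H2 = 2 * H, W2 = 2 * Wd;
    for (int c = 0; c < X.C; c++) {
      for (int n = 0; n < X.N; n++) {
        float* gs = GX.colptr(c) + (size_t)n * H * Wd;
        const float* gd = gout.a.colptr(c) + (size_t)n * H2 * W2;
        for (int y = 0; y < H2; y++) {
          float* gr = gs + (size_t)(y / 2) * Wd;
          const float* dr = gd + (size_t)y * W2;
          for (int x = 0; x < W2; x++) gr[x / 2] += dr[x];
        }
      }
    }
  }
};

struct GAP : Layer {
  GAP(int in_) { in = {in_}; }
  void forward(Net& net, bool) override {
    Tensor& X = net.T(in[0]);
    size_t hw = (size_t)X.H * X.W;
    out.set(X.N, 1, 1, X.C);
    for (int n = 0; n < X.N; n++)
      out.a.row(n) = arma::mean(X.a.rows((size_t)n * hw, (size_t)(n + 1) * hw - 1), 0);
  }
  void backward(Net& net) override {
    Tensor& X = net.T(in[0]);
    fmat& GX = net.gacc(in[0]);
    size_t hw = (size_t)X.H * X.W;
    for (int n = 0; n < X.N; n++)
      GX.rows((size_t)n * hw, (size_t)(n + 1) * hw - 1).each_row() +=
        gout.a.row(n) / (float)hw;
  }
};

// ---------------------------------------------------------------------------
// Graph builders

static int make_div(double v, int divisor = 8) {
  int nv = (int)(v + divisor / 2.0) / divisor * divisor;
  if (nv < divisor) nv = divisor;
  if (nv < 0.9 * v) nv += divisor;
  return nv;
}

struct NetHandle {
  Net net;
  std::string variant;
  int input_size = 224;
  double width = 1.0;
  int out_node = -1;
  int out_channels = 0;
};

static int conv_bn_act(Net& net, int in, int cin, int cout, int stride, float cap) {
  int x = net.add(new Conv3(in, cin, cout, stride, false, net));
  x = net.add(new BN(x, cout));
  return net.add(new ReLUcap(x, cap));
}

static int inv_residual(Net& net, int in, int cin, int cout, int stride, int t) {
  int x = in;
  int cexp = cin * t;
  if (t != 1) {
    x = net.add(new Conv1(x, cin, cexp, false, net));
    x = net.add(new BN(x, cexp));
    x = net.add(new ReLUcap(x, 6.f));
  }
  x = net.add(new DW3(x, cexp, stride, net));
  x = net.add(new BN(x, cexp));
  x = net.add(new ReLUcap(x, 6.f));
  x = net.add(new Conv1(x, cexp, cout, false, net));
  x = net.add(new BN(x, cout));
  if (stride == 1 && cin == cout) x = net.add(new AddL(x, in));
  return x;
}

// MobileNetV2 encoder. Returns bottleneck node; taps filled with the last
// node at output strides 2, 4, 8, 16 and the tap channel counts.
static int build_encoder(Net& net, int in, double w,
                         std::vector<int>& taps, std::vector<int>& tapc,
                         int& cbot) {
  // (t, c, n, s) inverted-residual schedule; 17 blocks in total.
  const int T[7] = {1, 6, 6, 6, 6, 6, 6};
  const int C[7] = {16, 24, 32, 64, 96, 160, 320};
  const int Nrep[7] = {1, 2, 3, 4, 3, 3, 1};
  const int S[7] = {1, 2, 2, 2, 1, 2, 1};
  int c0 = make_div(32 * w);
  int x = conv_bn_act(net, in, 3, c0, 2, 6.f);
  int cin = c0;
  int stride_now = 2;
  taps.assign(4, -1); tapc.assign(4, 0);
  auto record = [&](int node, int ch) {
    int idx = -1;
    if (stride_now == 2) idx = 0;
    else if (stride_now == 4) idx = 1;
    else if (stride_now == 8) idx = 2;
    else if (stride_now == 16) idx = 3;
    if (idx >= 0) { taps[idx] = node; tapc[idx] = ch; }
  };
  record(x, c0);
  for (int g = 0; g < 7; g++) {
    int cout = make_div(C[g] * w);
    for (int r = 0; r < Nrep[g]; r++) {
      int s = (r == 0) ? S[g] : 1;
      if (s == 2) stride_now *= 2;
      x = inv_residual(net, x, cin, cout, s, T[g]);
      cin = cout;
      record(x, cout);
    }
  }
  cbot = cin;
  return x;
}

static int dec_block(Net& net, int x, int cx, int skip, int cskip, int cout) {
  x = net.add(new Up2(x));
  x = net.add(new ConcatC(x, skip));
  x = conv_bn_act(net, x, cx + cskip, cout, 1, 1e30f);
  x = conv_bn_act(net, x, cout, cout, 1, 1e30f);
  return x;
}

// [[Rcpp::export(name = ".net_build")]]
SEXP net_build(std::string variant, int input_size, double width, int out_channels,
               int seed) {
  if (input_size % 32 != 0) Rcpp::stop("input_size must be divisible by 32");
  NetHandle* h = new NetHandle();
  h->variant = variant;
  h->input_size = input_size;
  h->width = width;
  h->out_channels = out_channels;
  Net& net = h->net;
  net.rng.seed((unsigned)seed);
  int x0 = net.add(new Input());
  std::vector<int> taps, tapc;
  int cbot = 0;
  int bot = build_encoder(net, x0, width, taps, tapc, cbot);
  if (variant == "heatmap" || variant == "segmentation") {
    int d1 = make_div(256 * width), d2 = make_div(128 * width),
        d3 = make_div(64 * width), d4 = make_div(32 * width),
        dh = make_div(16 * width);
    int x = dec_block(net, bot, cbot, taps[3], tapc[3], d1);
    x = dec_block(net, x, d1, taps[2], tapc[2], d2);
    x = dec_block(net, x, d2, taps[1], tapc[1], d3);
    x = dec_block(net, x, d3, taps[0], tapc[0], d4);
    // head: upsample to input resolution, three convs, last sigmoid-activated
    x = net.add(new Up2(x));
    x = net.add(new Conv3(x, d4, dh, 1, true, net));
    x = net.add(new ReLUcap(x, 1e30f));
    x = net.add(new Conv3(x, dh, dh, 1, true, net));
    x = net.add(new ReLUcap(x, 1e30f));
    int head = net.add(new Conv3(x, dh, out_channels, 1, true, net));
    // start the sigmoid output near the (mostly zero) target background
    static_cast<Conv3*>(net.nodes[head].get())->B.w.fill(-3.0f);
    x = net.add(new SigmoidL(head));
    h->out_node = x;
  } else if (variant == "direct") {
    int ds = make_div(256 * width);
    // two separable convolutions (depthwise + pointwise), then GAP + dense
    int x = net.add(new DW3(bot, cbot, 1, net));
    x = net.add(new Conv1(x, cbot, ds, true, net));
    x = net.add(new ReLUcap(x, 1e30f));
    x = net.add(new DW3(x, ds, 1, net));
    x = net.add(new Conv1(x, ds, ds, true, net));
    x = net.add(new ReLUcap(x, 1e30f));
    x = net.add(new GAP(x));
    x = net.add(new Conv1(x, ds, out_channels, true, net));
    x = net.add(new SigmoidL(x));
    h->out_node = x;
  } else {
    delete h;
    Rcpp::stop("unknown variant");
  }
  return Rcpp::XPtr<NetHandle>(h, true);
}

// ---------------------------------------------------------------------------
// R <-> tensor conversion. R arrays are [H, W, C, N] column-major.

static Tensor r2t(const Rcpp::NumericVector& x) {
  Rcpp::IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d.size() > 2 ? d[2] : 1, N = d.size() > 3 ? d[3] : 1;
  Tensor t;
  t.set(N, H, W, C);
  const double* p = x.begin();
  for (int n = 0; n < N; n++)
    for (int c = 0; c < C; c++) {
      float* col = t.a.colptr(c) + (size_t)n * H * W;
      const double* src = p + (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; w++)
        for (int hh = 0; hh < H; hh++)
          col[(size_t)hh * W + w] = (float)src[hh + (size_t)H * w];
    }
  return t;
}

static Rcpp::NumericVector t2r(const Tensor& t) {
  Rcpp::NumericVector x((size_t)t.H * t.W * t.C * t.N);
  x.attr("dim") = Rcpp::IntegerVector::create(t.H, t.W, t.C, t.N);
  double* p = x.begin();
  for (int n = 0; n < t.N; n++)
    for (int c = 0; c < t.C; c++) {
      const float* col = t.a.colptr(c) + (size_t)n * t.H * t.W;
      double* dst = p + (size_t)t.H * t.W * (c + (size_t)t.C * n);
      for (int w = 0; w < t.W; w++)
        for (int hh = 0; hh < t.H; hh++)
          dst[hh + (size_t)t.H * w] = col[(size_t)hh * t.W + w];
    }
  return x;
}

// ---------------------------------------------------------------------------
// Losses: return value and write gradient wrt the network output.

static double loss_and_grad(const fmat& P, const fmat& Tg, const std::string& type,
                            const arma::vec& w, fmat& G) {
  size_t R = P.n_rows, C = P.n_cols;
  G.zeros(R, C);
  if (type == "wmse") {
    double L = 0;
    for (size_t c = 0; c < C; c++) {
      const float* p = P.colptr(c);
      const float* t = Tg.colptr(c);
      float* g = G.colptr(c);
      double wc = w.n_elem == C ? w[c] : 1.0, s = 0;
      for (size_t i = 0; i < R; i++) {
        double d = (double)p[i] - t[i];
        s += d * d;
        g[i] = (float)(2.0 * wc * d / R);
      }
      L += wc * s / R;
    }
    return L;
  }
  if (type == "mse") {
    double s = 0;
    size_t n = R * C;
    const float* p = P.memptr();
    const float* t = Tg.memptr();
    float* g = G.memptr();
    for (size_t i = 0; i < n; i++) {
      double d = (double)p[i] - t[i];
      s += d * d;
      g[i] = (float)(2.0 * d / n);
    }
    return s / n;
  }
  if (type == "wl1") {
    // w = (threshold, w_hi, w_lo)
    double thr = w[0], whi = w[1], wlo = w[2], s = 0;
    size_t n = R * C;
    const float* p = P.memptr();
    const float* t = Tg.memptr();
    float* g = G.memptr();
    for (size_t i = 0; i < n; i++) {
      double d = (double)p[i] - t[i];
      double ww = t[i] >= thr ? whi : wlo;
      s += ww * std::fabs(d);
      g[i] = (float)(ww * (d > 0 ? 1.0 : (d < 0 ? -1.0 : 0.0)) / n);
    }
    return s / n;
  }
  if (type == "dice") {
    const double eps = 1e-7;
    double sp = 0, st = 0, spt = 0;
    size_t n = R * C;
    const float* p = P.memptr();
    const float* t = Tg.memptr();
    for (size_t i = 0; i < n; i++) { sp += p[i]; st += t[i]; spt += (double)p[i] * t[i]; }
    double den = sp + st + eps;
    double L = 1.0 - 2.0 * spt / den;
    float* g = G.memptr();
    for (size_t i = 0; i < n; i++)
      g[i] = (float)(-2.0 * (t[i] * den - spt) / (den * den));
    return L;
  }
  Rcpp::stop("unknown loss");
}

static void run_forward(NetHandle* h, Tensor&& x, bool train) {
  Net& net = h->net;
  net.nodes[0]->out = std::move(x);
  for (size_t i = 1; i < net.nodes.size(); i++) { TimerG t((std::string("f_")+typeid(*net.nodes[i]).name()).c_str()); net.nodes[i]->forward(net, train); }
}

static void run_backward(NetHandle* h, const fmat& seed) {
  Net& net = h->net;
  { TimerG t("zero"); for (auto* p : net.all_params()) p->g.zeros(); }
  net.nodes[h->out_node]->gout.a = seed;
  for (int i = (int)net.nodes.size() - 1; i >= 1; i--) {
    TimerG t((std::string("b_")+typeid(*net.nodes[i]).name()).c_str());
    net.nodes[i]->backward(net);
    // this node's activation and gradient are no longer needed: every
    // consumer (higher index) has already run its backward
    net.nodes[i]->out.a.reset();
    net.nodes[i]->gout.a.reset();
  }
  net.nodes[0]->gout.a.reset();
}

static void adam_step(Net& net, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  net.adam_t++;
  double bc1 = 1.0 - std::pow(b1, (double)net.adam_t);
  double bc2 = 1.0 - std::pow(b2, (double)net.adam_t);
  for (auto* p : net.all_params()) {
    float* w = p->w.memptr();
    float* g = p->g.memptr();
    float* m = p->m.memptr();
    float* v = p->v.memptr();
    size_t n = p->w.n_elem;
    for (size_t i = 0; i < n; i++) {
      m[i] = (float)(b1 * m[i] + (1 - b1) * g[i]);
      v[i] = (float)(b2 * v[i] + (1 - b2) * (double)g[i] * g[i]);
      double mh = m[i] / bc1, vh = v[i] / bc2;
      w[i] -= (float)(lr * mh / (std::sqrt(vh) + eps));
    }
  }
}

// [[Rcpp::export(name = ".net_step")]]
double net_step(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericVector y,
                std::string loss, arma::vec lossw, double lr, bool update) {
  Rcpp::XPtr<NetHandle> h(ptr);
  run_forward(h, r2t(x), true);
  Tensor& outT = h->net.T(h->out_node);
  Tensor yt = r2t(y);
  if (yt.a.n_rows != outT.a.n_rows || yt.a.n_cols != outT.a.n_cols)
    Rcpp::stop("target shape does not match network output");
  fmat G;
  double L = loss_and_grad(outT.a, yt.a, loss, lossw, G);
  if (!std::isfinite(L)) Rcpp::stop("non-finite training loss");
  run_backward(h, G);
  if (update) adam_step(h->net, lr);
  return L;
}

// [[Rcpp::export(name = ".net_eval_loss")]]
double net_eval_loss(SEXP ptr, Rcpp::NumericVector x, Rcpp::NumericVector y,
                     std::string loss, arma::vec lossw) {
  Rcpp::XPtr<NetHandle> h(ptr);
  run_forward(h, r2t(x), false);
  Tensor& outT = h->net.T(h->out_node);
  Tensor yt = r2t(y);
  if (yt.a.n_rows != outT.a.n_rows || yt.a.n_cols != outT.a.n_cols)
    Rcpp::stop("target shape does not match network output");
  fmat G;
  return loss_and_grad(outT.a, yt.a, loss, lossw, G);
}

// [[Rcpp::export(name = ".net_forward")]]
Rcpp::NumericVector net_forward(SEXP ptr, Rcpp::NumericVector x, bool train = false) {
  Rcpp::XPtr<NetHandle> h(ptr);
  run_forward(h, r2t(x), train);
  return t2r(h->net.T(h->out_node));
}

// [[Rcpp::export(name = ".net_param_count")]]
double net_param_count(SEXP ptr) {
  Rcpp::XPtr<NetHandle> h(ptr);
  double n = 0;
  for (auto* p : h->net.all_params()) n += p->w.n_elem;
  return n;
}

// [[Rcpp::export(name = ".net_get_state")]]
Rcpp::List net_get_state(SEXP ptr) {
  Rcpp::XPtr<NetHandle> h(ptr);
  auto ps = h->net.all_params();
  auto bs = h->net.all_buffers();
  Rcpp::List w(ps.size()), b(bs.size());
  for (size_t i = 0; i < ps.size(); i++) {
    Rcpp::NumericMatrix m(ps[i]->w.n_rows, ps[i]->w.n_cols);
    for (size_t j = 0; j < ps[i]->w.n_elem; j++) m[j] = ps[i]->w[j];
    w[i] = m;
  }
  for (size_t i = 0; i < bs.size(); i++) {
    Rcpp::NumericMatrix m(bs[i]->n_rows, bs[i]->n_cols);
    for (size_t j = 0; j < bs[i]->n_elem; j++) m[j] = (*bs[i])[j];
    b[i] = m;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = w, Rcpp::Named("buffers") = b);
}

// [[Rcpp::export(name = ".net_set_state")]]
void net_set_state(SEXP ptr, Rcpp::List state) {
  Rcpp::XPtr<NetHandle> h(ptr);
  auto ps = h->net.all_params();
  auto bs = h->net.all_buffers();
  Rcpp::List w = state["weights"], b = state["buffers"];
  if ((size_t)w.size() != ps.size() || (size_t)b.size() != bs.size())
    Rcpp::stop("state does not match network");
  for (size_t i = 0; i < ps.size(); i++) {
    Rcpp::NumericMatrix m = w[i];
    if ((size_t)m.size() != ps[i]->w.n_elem) Rcpp::stop("weight shape mismatch");
    for (size_t j = 0; j < ps[i]->w.n_elem; j++) ps[i]->w[j] = (float)m[j];
  }
  for (size_t i = 0; i < bs.size(); i++) {
    Rcpp::NumericMatrix m = b[i];
    for (size_t j = 0; j < bs[i]->n_elem; j++) (*bs[i])[j] = (float)m[j];
  }
}

// [[Rcpp::export(name = ".net_get_grads")]]
Rcpp::List net_get_grads(SEXP ptr) {
  Rcpp::XPtr<NetHandle> h(ptr);
  auto ps = h->net.all_params();
  Rcpp::List g(ps.size());
  for (size_t i = 0; i < ps.size(); i++) {
    Rcpp::NumericMatrix m(ps[i]->g.n_rows, ps[i]->g.n_cols);
    for (size_t j = 0; j < ps[i]->g.n_elem; j++) m[j] = ps[i]->g[j];
    g[i] = m;
  }
  return g;
}

static Param* checked_param(SEXP ptr, int param, int elem) {
  Rcpp::XPtr<NetHandle> h(ptr);
  auto ps = h->net.all_params();
  if (param < 1 || (size_t)param > ps.size()) Rcpp::stop("parameter block out of range");
  if (elem < 1 || (size_t)elem > ps[param - 1]->w.n_elem)
    Rcpp::stop("parameter element out of range");
  return ps[param - 1];
}

// [[Rcpp::export(name = ".net_set_param_elem")]]
void net_set_param_elem(SEXP ptr, int param, int elem, double value) {
  checked_param(ptr, param, elem)->w[elem - 1] = (float)value;
}

// [[Rcpp::export(name = ".net_get_param_elem")]]
double net_get_param_elem(SEXP ptr, int param, int elem) {
  return checked_param(ptr, param, elem)->w[elem - 1];
}

// [[Rcpp::export(name = ".net_release_activations")]]
void net_release_activations(SEXP ptr) {
  Rcpp::XPtr<NetHandle> h(ptr);
  for (auto& nd : h->net.nodes) nd->release();
}

// [[Rcpp::export(name = ".net_ptr_valid")]]
bool net_ptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// [[Rcpp::export(name = ".net_info")]]
Rcpp::List net_info(SEXP ptr) {
  Rcpp::XPtr<NetHandle> h(ptr);
  return Rcpp::List::create(
    Rcpp::Named("variant") = h->variant,
    Rcpp::Named("input_size") = h->input_size,
    Rcpp::Named("width") = h->width,
    Rcpp::Named("out_channels") = h->out_channels,
    Rcpp::Named("n_layers") = (int)h->net.nodes.size(),
    Rcpp::Named("n_params") = net_param_count(ptr));
}

// [[Rcpp::export(name = ".net_timings")]]
Rcpp::List net_timings() {
  Rcpp::List l;
  for (auto& kv : g_tim) l[kv.first] = kv.second;
  g_tim.clear();
  return l;
}
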