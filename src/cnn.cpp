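// Minimal single-precision CNN training engine: 3x3 same-padding
// convolutions (ReLU), 2x2 max pooling, dense layers, Adam, with
// softmax cross-entropy or mean-squared-error losses and on-the-fly
// flip augmentation.  Convolution is im2col + GEMM (BLAS sgemm via
// Armadillo).  All randomness comes from a std::mt19937 seeded by the
// caller; execution is single-threaded and deterministic.
//
// Data layout: one image per column, flattened exactly like an R array
// of dim c(H, W, C): index = c*H*W + x*H + y.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace Rcpp;

enum { L_CONV = 1, L_POOL = 2, L_DENSE = 3, L_HEAD = 4 };

struct LayerDef {
  int kind;
  int cin, cout;    // channels (or flat dims for dense/head)
  int hin, win;     // spatial dims of the input
  int hout, wout;
  int widx;         // index into the weight list, -1 for pooling
};

static std::vector<LayerDef> parse_arch(List arch) {
  const int in_c = as<int>(arch["channels"]);
  const int in_side = as<int>(arch["side"]);
  List ls = arch["layers"];
  std::vector<LayerDef> defs;
  int c = in_c, h = in_side, w = in_side, widx = 0;
  for (R_xlen_t i = 0; i < ls.size(); ++i) {
    List L = ls[i];
    const int kind = as<int>(L["kind"]);
    LayerDef d;
    d.kind = kind; d.cin = c; d.hin = h; d.win = w; d.widx = -1;
    if (kind == L_CONV) {
      d.cout = as<int>(L["out"]); d.hout = h; d.wout = w;
      d.widx = widx++; c = d.cout;
    } else if (kind == L_POOL) {
      d.cout = c; d.hout = h / 2; d.wout = w / 2;
      h = d.hout; w = d.wout;
    } else {  // dense / head: implicit flatten
      d.cin = c * h * w; d.cout = as<int>(L["out"]);
      d.hin = 1; d.win = 1; d.hout = 1; d.wout = 1;
      d.widx = widx++; c = d.cout; h = 1; w = 1;
    }
    defs.push_back(d);
  }
  return defs;
}

// He-normal initialization.
// [[Rcpp::export]]
List cpp_cnn_init(List arch, int seed) {
  std::vector<LayerDef> defs = parse_arch(arch);
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::normal_distribution<double> N(0.0, 1.0);
  List out;
  for (size_t i = 0; i < defs.size(); ++i) {
    if (defs[i].widx < 0) continue;
    const int fan_in = defs[i].kind == L_CONV ? defs[i].cin * 9 : defs[i].cin;
    const int fan_out = defs[i].cout;
    const double sd = std::sqrt(2.0 / fan_in);
    NumericMatrix W(fan_out, fan_in);
    for (R_xlen_t j = 0; j < W.size(); ++j) W[j] = sd * N(rng);
    NumericVector b(fan_out);
    out.push_back(List::create(_["W"] = W, _["b"] = b));
  }
  return out;
}

// --- im2col / col2im (3x3, pad 1, stride 1), batched ----------------------
// col: (H*W*B) x (C*9); for image n, rows [n*HW, (n+1)*HW).  Column
// (c*9 + (dx+1)*3 + (dy+1)) holds the plane shifted by (dx, dy), zero
// outside.  Plane index p = x*H + y.
static void im2col_block(const float* x, int C, int H, int W,
                         arma::fmat& col, size_t row0) {
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c) {
    const float* plane = x + c * HW;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        float* dst = col.colptr(c * 9 + (dx + 1) * 3 + (dy + 1)) + row0;
        for (int xc = 0; xc < W; ++xc) {
          const int sx = xc + dx;
          float* d = dst + static_cast<size_t>(xc) * H;
          if (sx < 0 || sx >= W) {
            std::fill(d, d + H, 0.0f);
            continue;
          }
          const float* s = plane + static_cast<size_t>(sx) * H;
          const int y0 = dy < 0 ? 1 : 0;
          const int y1 = dy > 0 ? H - 1 : H;
          if (y0 > 0) d[0] = 0.0f;
          if (y1 < H) d[H - 1] = 0.0f;
          for (int y = y0; y < y1; ++y) d[y] = s[y + dy];
        }
      }
    }
  }
}

static void col2im_add_block(const arma::fmat& dcol, size_t row0,
                             int C, int H, int W, float* dx) {
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c) {
    float* plane = dx + c * HW;
    for (int dxo = -1; dxo <= 1; ++dxo) {
      for (int dyo = -1; dyo <= 1; ++dyo) {
        const float* src = dcol.colptr(c * 9 + (dxo + 1) * 3 + (dyo + 1)) + row0;
        for (int xc = 0; xc < W; ++xc) {
          const int sx = xc + dxo;
          if (sx < 0 || sx >= W) continue;
          const float* s = src + static_cast<size_t>(xc) * H;
          float* p = plane + static_cast<size_t>(sx) * H;
          const int y0 = dyo < 0 ? 1 : 0;
          const int y1 = dyo > 0 ? H - 1 : H;
          for (int y = y0; y < y1; ++y) p[y + dyo] += s[y];
        }
      }
    }
  }
}

// zero the gradient wherever the (post-ReLU) activation was clipped
static void relu_mask(arma::fmat& grad, const arma::fmat& act) {
  const float* a = act.memptr();
  float* g = grad.memptr();
  const size_t n = grad.n_elem;
  for (size_t i = 0; i < n; ++i)
    if (a[i] <= 0.0f) g[i] = 0.0f;
}

struct Net {
  std::vector<LayerDef> defs;
  std::vector<arma::fmat> W;    // dense: (out x in); conv: transposed (cin*9 x cout)
  std::vector<arma::fvec> b;
  std::vector<arma::fmat> act;  // per-layer outputs (post-ReLU), features x batch
  std::vector<arma::umat> poolidx;
  int in_dim;

  void load(List arch, List weights) {
    defs = parse_arch(arch);
    in_dim = as<int>(arch["channels"]) * as<int>(arch["side"]) * as<int>(arch["side"]);
    W.clear(); b.clear();
    for (size_t i = 0; i < defs.size(); ++i) {
      if (defs[i].widx < 0) continue;
      List lw = weights[defs[i].widx];
      NumericMatrix Wr = lw["W"];
      NumericVector br = lw["b"];
      arma::fmat Wf(Wr.nrow(), Wr.ncol());
      for (R_xlen_t j = 0; j < Wr.size(); ++j) Wf[j] = static_cast<float>(Wr[j]);
      if (defs[i].kind == L_CONV) Wf = Wf.t();  // store (cin*9 x cout)
      W.push_back(Wf);
      arma::fvec bf(br.size());
      for (R_xlen_t j = 0; j < br.size(); ++j) bf[j] = static_cast<float>(br[j]);
      b.push_back(bf);
    }
  }

  // forward a batch; caches activations when `train` is true
  arma::fmat forward(const arma::fmat& X, bool train, int upto = -1) {
    const int B = X.n_cols;
    const int nl = upto < 0 ? (int)defs.size() : upto;
    arma::fmat cur = X;
    if (train) { act.assign(defs.size(), arma::fmat()); poolidx.assign(defs.size(), arma::umat()); }
    for (int li = 0; li < nl; ++li) {
      const LayerDef& d = defs[li];
      if (d.kind == L_CONV) {
        const size_t HW = static_cast<size_t>(d.hin) * d.win;
        arma::fmat col(HW * B, d.cin * 9);
        for (int n = 0; n < B; ++n)
          im2col_block(cur.colptr(n), d.cin, d.hin, d.win, col, n * HW);
        arma::fmat y = col * W[d.widx];               // (HW*B x cout)
        y.each_row() += b[d.widx].t();
        arma::fmat out(HW * d.cout, B);
        for (int n = 0; n < B; ++n)
          for (int c = 0; c < d.cout; ++c)
            std::copy(y.colptr(c) + n * HW, y.colptr(c) + (n + 1) * HW,
                      out.colptr(n) + c * HW);
        out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        if (train) act[li] = out;
        cur = std::move(out);
      } else if (d.kind == L_POOL) {
        const int Ho = d.hout, Wo = d.wout, Hi = d.hin, Wi = d.win;
        const size_t HWo = static_cast<size_t>(Ho) * Wo;
        arma::fmat out(HWo * d.cout, B);
        arma::umat idx;
        if (train) idx.set_size(HWo * d.cout, B);
        for (int n = 0; n < B; ++n) {
          const float* in = cur.colptr(n);
          float* o = out.colptr(n);
          for (int c = 0; c < d.cout; ++c) {
            const float* plane = in + static_cast<size_t>(c) * Hi * Wi;
            for (int xo = 0; xo < Wo; ++xo) {
              for (int yo = 0; yo < Ho; ++yo) {
                size_t best = static_cast<size_t>(2 * xo) * Hi + 2 * yo;
                float bv = plane[best];
                const int cand_x[3] = {2 * xo, 2 * xo + 1, 2 * xo};
                for (int dx = 0; dx < 2; ++dx) {
                  for (int dy = 0; dy < 2; ++dy) {
                    const size_t p = static_cast<size_t>(2 * xo + dx) * Hi + 2 * yo + dy;
                    if (plane[p] > bv) { bv = plane[p]; best = p; }
                  }
                }
                (void)cand_x;
                const size_t po = static_cast<size_t>(c) * HWo + static_cast<size_t>(xo) * Ho + yo;
                o[po] = bv;
                if (train) idx(po, n) = static_cast<size_t>(c) * Hi * Wi + best;
              }
            }
          }
        }
        if (train) { poolidx[li] = std::move(idx); act[li] = out; }
        cur = std::move(out);
      } else {  // dense / head
        arma::fmat out = W[d.widx] * cur;
        out.each_col() += b[d.widx];
        if (d.kind == L_DENSE)
          out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
        if (train) act[li] = out;
        cur = std::move(out);
      }
    }
    return cur;
  }

  // backward from head gradient; fills dW/db (same shapes as W/b)
  void backward(const arma::fmat& X, const arma::fmat& dout,
                std::vector<arma::fmat>& dW, std::vector<arma::fvec>& db) {
    const int B = X.n_cols;
    dW.resize(W.size()); db.resize(b.size());
    for (size_t i = 0; i < W.size(); ++i) {
      dW[i].zeros(W[i].n_rows, W[i].n_cols);
      db[i].zeros(b[i].n_elem);
    }
    arma::fmat grad = dout;
    for (int li = (int)defs.size() - 1; li >= 0; --li) {
      const LayerDef& d = defs[li];
      const arma::fmat& input = li == 0 ? X : act[li - 1];
      if (d.kind == L_HEAD || d.kind == L_DENSE) {
        if (d.kind == L_DENSE) relu_mask(grad, act[li]);
        dW[d.widx] += grad * input.t();
        db[d.widx] += arma::sum(grad, 1);
        if (li > 0) grad = W[d.widx].t() * grad;
      } else if (d.kind == L_POOL) {
        const size_t in_sz = static_cast<size_t>(d.cin) * d.hin * d.win;
        arma::fmat g(in_sz, B, arma::fill::zeros);
        for (int n = 0; n < B; ++n) {
          const float* gp = grad.colptr(n);
          float* op = g.colptr(n);
          const arma::uword* ip = poolidx[li].colptr(n);
          const size_t m = poolidx[li].n_rows;
          for (size_t j = 0; j < m; ++j) op[ip[j]] += gp[j];
        }
        grad = std::move(g);
      } else {  // conv
        relu_mask(grad, act[li]);
        const size_t HW = static_cast<size_t>(d.hin) * d.win;
        const bool need_dx = li > 0;
        // gather the gradient into (HW*B x cout) layout
        arma::fmat gy(HW * B, d.cout);
        for (int n = 0; n < B; ++n)
          for (int c = 0; c < d.cout; ++c)
            std::copy(grad.colptr(n) + c * HW, grad.colptr(n) + (c + 1) * HW,
                      gy.colptr(c) + n * HW);
        arma::fmat col(HW * B, d.cin * 9);
        for (int n = 0; n < B; ++n)
          im2col_block(input.colptr(n), d.cin, d.hin, d.win, col, n * HW);
        dW[d.widx] += col.t() * gy;         // (cin*9 x cout)
        db[d.widx] += arma::sum(gy, 0).t();
        if (need_dx) {
          arma::fmat dcol = gy * W[d.widx].t();     // (HW*B x cin*9)
          arma::fmat g(static_cast<size_t>(d.cin) * HW, B, arma::fill::zeros);
          for (int n = 0; n < B; ++n)
            col2im_add_block(dcol, n * HW, d.cin, d.hin, d.win, g.colptr(n));
          grad = std::move(g);
        }
      }
    }
  }
};

// copy image column `src` into `dst`, flipping horizontally/vertically
static void copy_flip(const float* src, float* dst, int C, int H, int W,
                      bool hflip, bool vflip) {
  const size_t HW = static_cast<size_t>(H) * W;
  for (int c = 0; c < C; ++c) {
    const float* sp = src + c * HW;
    float* dp = dst + c * HW;
    for (int x = 0; x < W; ++x) {
      const int sx = hflip ? W - 1 - x : x;
      const float* scol = sp + static_cast<size_t>(sx) * H;
      float* dcol = dp + static_cast<size_t>(x) * H;
      if (!vflip) std::copy(scol, scol + H, dcol);
      else for (int y = 0; y < H; ++y) dcol[y] = scol[H - 1 - y];
    }
  }
}

static double loss_and_grad(const arma::fmat& out, const std::vector<double>& y,
                            const std::vector<int>& idx, size_t off, int B,
                            int task, arma::fmat& dout) {
  dout.set_size(out.n_rows, B);
  double loss = 0.0;
  if (task == 0) {  // MSE, single output
    for (int n = 0; n < B; ++n) {
      const double t = y[idx[off + n]];
      const double r = out(0, n) - t;
      loss += r * r;
      dout(0, n) = static_cast<float>(2.0 * r / B);
    }
    loss /= B;
  } else {          // softmax cross-entropy
    const int K = out.n_rows;
    for (int n = 0; n < B; ++n) {
      const int t = static_cast<int>(y[idx[off + n]]);
      float mx = out(0, n);
      for (int k2 = 1; k2 < K; ++k2) mx = std::max(mx, out(k2, n));
      double Z = 0.0;
      for (int k2 = 0; k2 < K; ++k2) Z += std::exp(static_cast<double>(out(k2, n)) - mx);
      for (int k2 = 0; k2 < K; ++k2) {
        const double p = std::exp(static_cast<double>(out(k2, n)) - mx) / Z;
        dout(k2, n) = static_cast<float>((p - (k2 == t ? 1.0 : 0.0)) / B);
        if (k2 == t) loss += -(static_cast<double>(out(k2, n)) - mx - std::log(Z));
      }
    }
    loss /= B;
  }
  return loss;
}

static List weights_to_r(const Net& net) {
  List out;
  for (size_t i = 0; i < net.defs.size(); ++i) {
    if (net.defs[i].widx < 0) continue;
    const int wi = net.defs[i].widx;
    arma::fmat Wf = net.defs[i].kind == L_CONV ? net.W[wi].t() : net.W[wi];
    NumericMatrix Wr(Wf.n_rows, Wf.n_cols);
    for (size_t j = 0; j < Wf.n_elem; ++j) Wr[j] = Wf[j];
    NumericVector br(net.b[wi].n_elem);
    for (size_t j = 0; j < net.b[wi].n_elem; ++j) br[j] = net.b[wi][j];
    out.push_back(List::create(_["W"] = Wr, _["b"] = br));
  }
  return out;
}

// Train with Adam.  task: 0 = regression (MSE), 1 = classification (CE).
// train_idx/test_idx are 1-based indices into the columns of X.
// [[Rcpp::export]]
List cpp_cnn_train(List arch, List weights, NumericMatrix X, NumericVector y,
                   IntegerVector train_idx, IntegerVector test_idx,
                   int task, List cfg) {
  Net net;
  net.load(arch, weights);
  const int batch = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["learning_rate"]);
  const int epochs = as<int>(cfg["epochs"]);
  const int seed = as<int>(cfg["seed"]);
  const bool hflip = as<bool>(cfg["hflip"]);
  const bool vflip = as<bool>(cfg["vflip"]);

  const int d = X.nrow();
  arma::fmat Xf(d, X.ncol());
  for (R_xlen_t j = 0; j < X.size(); ++j) Xf[j] = static_cast<float>(X[j]);
  std::vector<double> yv(y.begin(), y.end());

  // image geometry for flipping
  const int C = as<int>(arch["channels"]);
  const int side = as<int>(arch["side"]);

  std::vector<int> tr(train_idx.size());
  for (size_t i = 0; i < tr.size(); ++i) tr[i] = train_idx[i] - 1;

  std::mt19937 rng(static_cast<uint32_t>(seed) * 2654435761u + 97u);
  std::uniform_int_distribution<int> coin(0, 1);

  // Adam state
  std::vector<arma::fmat> mW(net.W.size()), vW(net.W.size());
  std::vector<arma::fvec> mb(net.b.size()), vb(net.b.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    mW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    vW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    mb[i].zeros(net.b[i].n_elem);
    vb[i].zeros(net.b[i].n_elem);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  NumericVector epoch_loss(epochs);
  std::vector<arma::fmat> dW;
  std::vector<arma::fvec> db;
  arma::fmat Xb, dout;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(tr.begin(), tr.end(), rng);
    double acc_loss = 0.0;
    long acc_n = 0;
    for (size_t off = 0; off < tr.size(); off += batch) {
      const int B = std::min<size_t>(batch, tr.size() - off);
      Xb.set_size(d, B);
      for (int n = 0; n < B; ++n) {
        const bool hf = hflip && coin(rng) == 1;
        const bool vf = vflip && coin(rng) == 1;
        if (hf || vf)
          copy_flip(Xf.colptr(tr[off + n]), Xb.colptr(n), C, side, side, hf, vf);
        else
          std::copy(Xf.colptr(tr[off + n]), Xf.colptr(tr[off + n]) + d, Xb.colptr(n));
      }
      arma::fmat out = net.forward(Xb, true);
      const double loss = loss_and_grad(out, yv, tr, off, B, task, dout);
      acc_loss += loss * B;
      acc_n += B;
      net.backward(Xb, dout, dW, db);
      ++step;
      const double corr = lr * std::sqrt(1.0 - std::pow(b2, step)) / (1.0 - std::pow(b1, step));
      for (size_t i = 0; i < net.W.size(); ++i) {
        mW[i] = b1 * mW[i] + (1.0 - b1) * dW[i];
        vW[i] = b2 * vW[i] + (1.0 - b2) * arma::square(dW[i]);
        net.W[i] -= corr * mW[i] / (arma::sqrt(vW[i]) + eps);
        mb[i] = b1 * mb[i] + (1.0 - b1) * db[i];
        vb[i] = b2 * vb[i] + (1.0 - b2) * arma::square(db[i]);
        net.b[i] -= corr * mb[i] / (arma::sqrt(vb[i]) + eps);
      }
    }
    epoch_loss[ep] = acc_loss / acc_n;
    Rcpp::checkUserInterrupt();
  }

  // evaluation-mode losses (no augmentation) on the train and test parts
  auto eval_loss = [&](const IntegerVector& idx) -> double {
    if (idx.size() == 0) return NA_REAL;
    std::vector<int> iv(idx.size());
    for (size_t i = 0; i < iv.size(); ++i) iv[i] = idx[i] - 1;
    double acc = 0.0;
    const int chunk = 64;
    for (size_t off = 0; off < iv.size(); off += chunk) {
      const int B = std::min<size_t>(chunk, iv.size() - off);
      arma::fmat Xc(d, B);
      for (int n = 0; n < B; ++n)
        Xc.col(n) = Xf.col(iv[off + n]);
      arma::fmat out = net.forward(Xc, false);
      arma::fmat dummy;
      acc += loss_and_grad(out, yv, iv, off, B, task, dummy) * B;
    }
    return acc / iv.size();
  };

  const double final_train = eval_loss(train_idx);
  const double final_test = eval_loss(test_idx);

  return List::create(_["weights"] = weights_to_r(net),
                      _["epoch_loss"] = epoch_loss,
                      _["final_train_loss"] = final_train,
                      _["final_test_loss"] = final_test);
}

// Forward pass in evaluation mode.  If drop_head, stop before the last
// layer (feature extraction from the headless backbone).
// [[Rcpp::export]]
NumericMatrix cpp_cnn_forward(List arch, List weights, NumericMatrix X,
                              bool drop_head) {
  Net net;
  net.load(arch, weights);
  const int nl = drop_head ? (int)net.defs.size() - 1 : (int)net.defs.size();
  const int d = X.nrow();
  const int N = X.ncol();
  // keep the largest per-layer im2col buffer under ~256 MB
  size_t colmax = 1;
  for (size_t i = 0; i < net.defs.size(); ++i)
    if (net.defs[i].kind == L_CONV) {
      const size_t e = static_cast<size_t>(net.defs[i].hin) * net.defs[i].win *
                       net.defs[i].cin * 9;
      if (e > colmax) colmax = e;
    }
  int chunk = (int)std::min<size_t>(64, std::max<size_t>(1, (268435456 / 4) / colmax));
  NumericMatrix out;
  for (int off = 0; off < N; off += chunk) {
    const int B = std::min(chunk, N - off);
    arma::fmat Xc(d, B);
    for (int n = 0; n < B; ++n)
      for (int j = 0; j < d; ++j)
        Xc(j, n) = static_cast<float>(X(j, off + n));
    arma::fmat y = net.forward(Xc, false, nl);
    if (off == 0) out = NumericMatrix(y.n_rows, N);
    for (size_t n = 0; n < y.n_cols; ++n)
      for (size_t j = 0; j < y.n_rows; ++j)
        out(j, off + n) = y(j, n);
  }
  return out;
}
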