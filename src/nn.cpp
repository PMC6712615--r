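// Minimal CNN compute kernels: im2col/GEMM convolution (with dilation),
// max/average pooling, batch normalisation and PReLU.  Activations are
// laid out as one column per sample, rows ordered h-fastest, then w, then
// channel (an H x W x C array flattened column-major).  Convolution
// weights are (k*k*Cin) x Cout with rows ordered kh-fastest, then kw,
// then input channel.
//
// Convolutions compute in single precision (the GEMM dominates run time);
// the memory-bound elementwise kernels stay in double.  The im2col
// expansion built in the forward pass is cached behind an external
// pointer and reused by the backward pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;

static fmat as_fmat(const NumericMatrix& x) {
  fmat out(x.nrow(), x.ncol());
  const double* src = x.begin();
  float* dst = out.memptr();
  const size_t n = (size_t)x.nrow() * x.ncol();
  for (size_t i = 0; i < n; ++i) dst[i] = (float)src[i];
  return out;
}

static NumericMatrix as_rmat(const fmat& x) {
  NumericMatrix out(x.n_rows, x.n_cols);
  const float* src = x.memptr();
  double* dst = out.begin();
  const size_t n = x.n_elem;
  for (size_t i = 0; i < n; ++i) dst[i] = (double)src[i];
  return out;
}

// Fill columns [col0, col0 + OH*OW) of `out` with the im2col expansion of
// one sample.  Column index = oh + OH*ow; row index = kh + k*(kw + k*c).
static void im2col_one(const float* a, int H, int W, int C,
                       int k, int dil, int stride, int pad,
                       int OH, int OW, fmat& out, size_t col0) {
  for (int c = 0; c < C; ++c) {
    const float* ac = a + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pad + kw * dil;
          float* dst = out.colptr(col0 + (size_t)OH * ow);
          const size_t nr = out.n_rows;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < OH; ++oh) dst[r + nr * oh] = 0.0f;
            continue;
          }
          const float* src = ac + (size_t)iw * H;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pad + kh * dil;
            dst[r + nr * oh] = (ih >= 0 && ih < H) ? src[ih] : 0.0f;
          }
        }
      }
    }
  }
}

// Scatter-add the col2im inverse of im2col_one.
static void col2im_one(const fmat& cols, size_t col0, int H, int W, int C,
                       int k, int dil, int stride, int pad,
                       int OH, int OW, float* a) {
  for (int c = 0; c < C; ++c) {
    float* ac = a + (size_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int r = kh + k * (kw + k * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int iw = ow * stride - pad + kw * dil;
          if (iw < 0 || iw >= W) continue;
          const float* src = cols.colptr(col0 + (size_t)OH * ow);
          const size_t nr = cols.n_rows;
          float* dst = ac + (size_t)iw * H;
          for (int oh = 0; oh < OH; ++oh) {
            const int ih = oh * stride - pad + kh * dil;
            if (ih >= 0 && ih < H) dst[ih] += src[r + nr * oh];
          }
        }
      }
    }
  }
}

static int out_extent(int H, int k, int dil, int stride, int pad) {
  const int eff = (k - 1) * dil + 1;
  return (H + 2 * pad - eff) / stride + 1;
}

// Returns list(Y, cols) where cols is an external pointer to the cached
// im2col matrix (NULL unless keep_cols).
// [[Rcpp::export]]
List cpp_conv_fwd(NumericMatrix X, int H, int W, int C,
                  NumericMatrix Wt, NumericVector b,
                  int k, int dil, int stride, int pad, bool keep_cols) {
  const int N = X.ncol();
  const int OH = out_extent(H, k, dil, stride, pad);
  const int OW = out_extent(W, k, dil, stride, pad);
  const int Cout = Wt.ncol();
  const size_t ohow = (size_t)OH * OW;
  fmat Xf = as_fmat(X);
  fmat Wf = as_fmat(Wt);
  fvec bf(Cout);
  for (int j = 0; j < Cout; ++j) bf[j] = (float)b[j];

  fmat* cols = new fmat(Wf.n_rows, ohow * N);
  for (int n = 0; n < N; ++n)
    im2col_one(Xf.colptr(n), H, W, C, k, dil, stride, pad, OH, OW,
               *cols, (size_t)n * ohow);
  fmat Ym = Wf.t() * (*cols);         // Cout x (OH*OW*N)
  Ym.each_col() += bf;

  fmat Y(ohow * Cout, N);
  for (int n = 0; n < N; ++n) {
    fmat blk = Ym.cols(n * ohow, (n + 1) * ohow - 1); // Cout x OH*OW
    Y.col(n) = arma::vectorise(blk.t());
  }
  SEXP ptr = R_NilValue;
  if (keep_cols) {
    XPtr<fmat> xp(cols, true);
    ptr = xp;
  } else {
    delete cols;
  }
  return List::create(_["Y"] = as_rmat(Y), _["cols"] = ptr);
}

// [[Rcpp::export]]
List cpp_conv_bwd(SEXP colsPtr, NumericMatrix dY, int H, int W, int C,
                  NumericMatrix Wt, int k, int dil, int stride, int pad) {
  XPtr<fmat> cols(colsPtr);
  const int N = dY.ncol();
  const int OH = out_extent(H, k, dil, stride, pad);
  const int OW = out_extent(W, k, dil, stride, pad);
  const int Cout = Wt.ncol();
  const size_t ohow = (size_t)OH * OW;
  fmat Wf = as_fmat(Wt);
  fmat dYf = as_fmat(dY);

  // permute dY back to Cout x (OH*OW*N)
  fmat dYm(Cout, ohow * N);
  for (int n = 0; n < N; ++n) {
    fmat blk(dYf.colptr(n), ohow, Cout, false, true);
    dYm.cols(n * ohow, (n + 1) * ohow - 1) = blk.t();
  }

  fmat dW = (*cols) * dYm.t();        // (k*k*C) x Cout
  fvec db = arma::sum(dYm, 1);
  fmat dcols = Wf * dYm;              // (k*k*C) x (OH*OW*N)

  fmat dX((size_t)H * W * C, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    col2im_one(dcols, (size_t)n * ohow, H, W, C, k, dil, stride, pad,
               OH, OW, dX.colptr(n));

  NumericVector dbv(Cout);
  for (int j = 0; j < Cout; ++j) dbv[j] = (double)db[j];
  return List::create(_["dX"] = as_rmat(dX), _["dW"] = as_rmat(dW),
                      _["db"] = dbv);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericMatrix X, int H, int W, int C, int s) {
  const int N = X.ncol();
  const int OH = H / s, OW = W / s;
  NumericMatrix Y((size_t)OH * OW * C, N);
  IntegerMatrix idx((size_t)OH * OW * C, N); // 0-based source row
  for (int n = 0; n < N; ++n) {
    const double* x = &X(0, n);
    double* y = &Y(0, n);
    int* id = &idx(0, n);
    for (int c = 0; c < C; ++c) {
      const size_t coff = (size_t)c * H * W;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double best = -INFINITY; size_t bi = 0;
          for (int dw = 0; dw < s; ++dw) {
            for (int dh = 0; dh < s; ++dh) {
              const size_t r = coff + (size_t)(ow * s + dw) * H + oh * s + dh;
              if (x[r] > best) { best = x[r]; bi = r; }
            }
          }
          const size_t ro = (size_t)c * OH * OW + (size_t)ow * OH + oh;
          y[ro] = best;
          id[ro] = (int)bi;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(NumericMatrix dY, IntegerMatrix idx, int nrowX) {
  const int N = dY.ncol();
  const int nr = dY.nrow();
  NumericMatrix dX(nrowX, N);
  for (int n = 0; n < N; ++n) {
    const double* g = &dY(0, n);
    const int* id = &idx(0, n);
    double* out = &dX(0, n);
    for (int r = 0; r < nr; ++r) out[id[r]] += g[r];
  }
  return dX;
}

// Non-overlapping average pooling, kernel = stride (sh x sw covers the
// whole extent for a global pool).
// [[Rcpp::export]]
NumericMatrix cpp_avgpool_fwd(NumericMatrix X, int H, int W, int C,
                              int sh, int sw) {
  const int N = X.ncol();
  const int OH = H / sh, OW = W / sw;
  const double inv = 1.0 / ((double)sh * sw);
  NumericMatrix Y((size_t)OH * OW * C, N);
  for (int n = 0; n < N; ++n) {
    const double* x = &X(0, n);
    double* y = &Y(0, n);
    for (int c = 0; c < C; ++c) {
      const size_t coff = (size_t)c * H * W;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double acc = 0.0;
          for (int dw = 0; dw < sw; ++dw)
            for (int dh = 0; dh < sh; ++dh)
              acc += x[coff + (size_t)(ow * sw + dw) * H + oh * sh + dh];
          y[(size_t)c * OH * OW + (size_t)ow * OH + oh] = acc * inv;
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix cpp_avgpool_bwd(NumericMatrix dY, int H, int W, int C,
                              int sh, int sw) {
  const int N = dY.ncol();
  const int OH = H / sh, OW = W / sw;
  const double inv = 1.0 / ((double)sh * sw);
  NumericMatrix dX((size_t)H * W * C, N);
  for (int n = 0; n < N; ++n) {
    const double* g = &dY(0, n);
    double* out = &dX(0, n);
    for (int c = 0; c < C; ++c) {
      const size_t coff = (size_t)c * H * W;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          const double gv = g[(size_t)c * OH * OW + (size_t)ow * OH + oh] * inv;
          for (int dw = 0; dw < sw; ++dw)
            for (int dh = 0; dh < sh; ++dh)
              out[coff + (size_t)(ow * sw + dw) * H + oh * sh + dh] += gv;
        }
      }
    }
  }
  return dX;
}

// Batch normalisation over (spatial x batch) per channel.
// training: returns batch mu/invstd and updated running stats.
// [[Rcpp::export]]
List cpp_bn_fwd(NumericMatrix X, int hw, int C,
                NumericVector gamma, NumericVector beta,
                NumericVector rmean, NumericVector rvar,
                bool training, double eps, double momentum) {
  const int N = X.ncol();
  NumericVector mu(C), invstd(C), nmean(C), nvar(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* x = &X(0, n) + (size_t)c * hw;
        for (int i = 0; i < hw; ++i) { s += x[i]; s2 += x[i] * x[i]; }
      }
      const double m = (double)hw * N;
      const double mean = s / m;
      double v = s2 / m - mean * mean;
      if (v < 0) v = 0;
      mu[c] = mean;
      invstd[c] = 1.0 / std::sqrt(v + eps);
      nmean[c] = momentum * rmean[c] + (1 - momentum) * mean;
      nvar[c] = momentum * rvar[c] + (1 - momentum) * v;
    }
  } else {
    for (int c = 0; c < C; ++c) {
      mu[c] = rmean[c];
      invstd[c] = 1.0 / std::sqrt(rvar[c] + eps);
      nmean[c] = rmean[c];
      nvar[c] = rvar[c];
    }
  }
  NumericMatrix Y(X.nrow(), N);
  for (int n = 0; n < N; ++n) {
    const double* x = &X(0, n);
    double* y = &Y(0, n);
    for (int c = 0; c < C; ++c) {
      const double m = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
      const size_t off = (size_t)c * hw;
      for (int i = 0; i < hw; ++i)
        y[off + i] = (x[off + i] - m) * is * g + b;
    }
  }
  return List::create(_["Y"] = Y, _["mu"] = mu, _["invstd"] = invstd,
                      _["mean"] = nmean, _["var"] = nvar);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericMatrix X, NumericMatrix dY, int hw, int C,
                NumericVector gamma, NumericVector mu, NumericVector invstd,
                bool batch_stats) {
  const int N = X.ncol();
  const double m = (double)hw * N;
  NumericVector dgamma(C), dbeta(C);
  NumericMatrix dX(X.nrow(), N);
  for (int c = 0; c < C; ++c) {
    const size_t off = (size_t)c * hw;
    const double mc = mu[c], is = invstd[c], g = gamma[c];
    double s1 = 0.0, s2 = 0.0, db = 0.0, dg = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* x = &X(0, n) + off;
      const double* gy = &dY(0, n) + off;
      for (int i = 0; i < hw; ++i) {
        const double xh = (x[i] - mc) * is;
        db += gy[i];
        dg += gy[i] * xh;
        s1 += gy[i];
        s2 += gy[i] * xh;
      }
    }
    dgamma[c] = dg; dbeta[c] = db;
    s1 *= g; s2 *= g;
    for (int n = 0; n < N; ++n) {
      const double* x = &X(0, n) + off;
      const double* gy = &dY(0, n) + off;
      double* out = &dX(0, n) + off;
      if (batch_stats) {
        for (int i = 0; i < hw; ++i) {
          const double xh = (x[i] - mc) * is;
          out[i] = (is / m) * (m * g * gy[i] - s1 - xh * s2);
        }
      } else {
        for (int i = 0; i < hw; ++i) out[i] = g * gy[i] * is;
      }
    }
  }
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// PReLU with one slope per channel.
// [[Rcpp::export]]
NumericMatrix cpp_prelu_fwd(NumericMatrix X, int hw, int C,
                            NumericVector a) {
  const int N = X.ncol();
  NumericMatrix Y(X.nrow(), N);
  for (int n = 0; n < N; ++n) {
    const double* x = &X(0, n);
    double* y = &Y(0, n);
    for (int c = 0; c < C; ++c) {
      const double ac = a[c];
      const size_t off = (size_t)c * hw;
      for (int i = 0; i < hw; ++i) {
        const double v = x[off + i];
        y[off + i] = v > 0 ? v : ac * v;
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_prelu_bwd(NumericMatrix X, NumericMatrix dY, int hw, int C,
                   NumericVector a) {
  const int N = X.ncol();
  NumericVector da(C);
  NumericMatrix dX(X.nrow(), N);
  for (int c = 0; c < C; ++c) {
    const double ac = a[c];
    const size_t off = (size_t)c * hw;
    double dac = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* x = &X(0, n) + off;
      const double* gy = &dY(0, n) + off;
      double* out = &dX(0, n) + off;
      for (int i = 0; i < hw; ++i) {
        if (x[i] > 0) out[i] = gy[i];
        else { out[i] = ac * gy[i]; dac += gy[i] * x[i]; }
      }
    }
    da[c] = dac;
  }
  return List::create(_["dX"] = dX, _["da"] = da);
}

// ---------------------------------------------------------------------------
// Fast path: whole-epoch training loop and batched prediction in C++ with
// float workspaces.  The per-layer kernels above remain the reference
// implementation used by the R-orchestrated path (gradient checks); this
// section reimplements the same arithmetic with no per-layer R round trips.

namespace {

struct GNode {
  int kind;  // 1 conv, 2 maxpool, 3 avgpool, 4 fc, 5 bn, 6 prelu, 7 concat
  int hin, win, cin, hout, wout, cout;
  int k, dil, stride, pad, kh, kw, infeat;
  std::vector<int> inputs;  // node ids, 0 = network input
};

struct Net {
  std::vector<GNode> nodes;
  // per-node float parameters (empty when unused)
  std::vector<fmat> W;
  std::vector<fvec> b, gamma, beta, aslope, rmean, rvar;
  // momentum buffers
  std::vector<fmat> vW;
  std::vector<fvec> vb, vgamma, vbeta, va;
  std::vector<double> bnsteps;
};

std::vector<GNode> parse_nodes(List nodesList) {
  std::vector<GNode> nodes(nodesList.size());
  for (int i = 0; i < nodesList.size(); ++i) {
    List nd = nodesList[i];
    IntegerVector g = nd["geom"];
    IntegerVector in = nd["inputs"];
    GNode& n = nodes[i];
    n.kind = g[0]; n.hin = g[1]; n.win = g[2]; n.cin = g[3];
    n.hout = g[4]; n.wout = g[5]; n.cout = g[6];
    n.k = g[7]; n.dil = g[8]; n.stride = g[9]; n.pad = g[10];
    n.kh = g[11]; n.kw = g[12]; n.infeat = g[13];
    n.inputs.assign(in.begin(), in.end());
  }
  return nodes;
}

fvec as_fvec(SEXP x) {
  NumericVector v(x);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

void load_params(Net& net, List params, List velocity, List state) {
  const int n = net.nodes.size();
  net.W.resize(n); net.b.resize(n); net.gamma.resize(n); net.beta.resize(n);
  net.aslope.resize(n); net.rmean.resize(n); net.rvar.resize(n);
  net.vW.resize(n); net.vb.resize(n); net.vgamma.resize(n);
  net.vbeta.resize(n); net.va.resize(n);
  net.bnsteps.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (Rf_isNull(params[i])) continue;
    List p = params[i];
    List v = Rf_isNull(velocity[i]) ? List() : List(velocity[i]);
    const int kind = net.nodes[i].kind;
    if (kind == 1 || kind == 4) {
      net.W[i] = as_fmat(as<NumericMatrix>(p["W"]));
      net.b[i] = as_fvec(p["b"]);
      net.vW[i] = v.containsElementNamed("W")
        ? as_fmat(as<NumericMatrix>(v["W"]))
        : fmat(net.W[i].n_rows, net.W[i].n_cols, arma::fill::zeros);
      net.vb[i] = v.containsElementNamed("b")
        ? as_fvec(v["b"]) : fvec(net.b[i].n_elem, arma::fill::zeros);
    } else if (kind == 5) {
      net.gamma[i] = as_fvec(p["gamma"]);
      net.beta[i] = as_fvec(p["beta"]);
      net.vgamma[i] = v.containsElementNamed("gamma")
        ? as_fvec(v["gamma"]) : fvec(net.gamma[i].n_elem, arma::fill::zeros);
      net.vbeta[i] = v.containsElementNamed("beta")
        ? as_fvec(v["beta"]) : fvec(net.beta[i].n_elem, arma::fill::zeros);
      List st = state[i];
      net.rmean[i] = as_fvec(st["mean"]);
      net.rvar[i] = as_fvec(st["var"]);
      net.bnsteps[i] = st.containsElementNamed("steps")
        ? as<double>(st["steps"]) : 0.0;
    } else if (kind == 6) {
      net.aslope[i] = as_fvec(p["a"]);
      net.va[i] = v.containsElementNamed("a")
        ? as_fvec(v["a"]) : fvec(net.aslope[i].n_elem, arma::fill::zeros);
    }
  }
}

NumericVector rvec(const fvec& x) {
  NumericVector out(x.n_elem);
  for (size_t i = 0; i < x.n_elem; ++i) out[i] = (double)x[i];
  return out;
}

void store_params(const Net& net, List params, List velocity, List state) {
  for (size_t i = 0; i < net.nodes.size(); ++i) {
    if (Rf_isNull(params[i])) continue;
    const int kind = net.nodes[i].kind;
    if (kind == 1 || kind == 4) {
      params[i] = List::create(_["W"] = as_rmat(net.W[i]),
                               _["b"] = rvec(net.b[i]));
      velocity[i] = List::create(_["W"] = as_rmat(net.vW[i]),
                                 _["b"] = rvec(net.vb[i]));
    } else if (kind == 5) {
      params[i] = List::create(_["gamma"] = rvec(net.gamma[i]),
                               _["beta"] = rvec(net.beta[i]));
      velocity[i] = List::create(_["gamma"] = rvec(net.vgamma[i]),
                                 _["beta"] = rvec(net.vbeta[i]));
      state[i] = List::create(_["mean"] = rvec(net.rmean[i]),
                              _["var"] = rvec(net.rvar[i]),
                              _["steps"] = net.bnsteps[i]);
    } else if (kind == 6) {
      params[i] = List::create(_["a"] = rvec(net.aslope[i]));
      velocity[i] = List::create(_["a"] = rvec(net.va[i]));
    }
  }
}

// forward one batch; acts[0] must hold the input.  When training, im2col
// caches, bn stats and maxpool argmaxes are stored for the backward pass.
struct Workspace {
  std::vector<fmat> acts, cols;
  std::vector<arma::umat> poolidx;
  std::vector<fvec> bn_mu, bn_invstd;
};

void net_forward(Net& net, Workspace& ws, bool training,
                 double eps, double bn_mom) {
  const int n = net.nodes.size();
  ws.acts.resize(n + 1); ws.cols.resize(n);
  ws.poolidx.resize(n); ws.bn_mu.resize(n); ws.bn_invstd.resize(n);
  const int N = ws.acts[0].n_cols;
  for (int i = 0; i < n; ++i) {
    GNode& nd = net.nodes[i];
    fmat& out = ws.acts[i + 1];
    const fmat& A = ws.acts[nd.inputs[0]];
    const int hw = nd.hin * nd.win;
    switch (nd.kind) {
    case 1: {  // conv (shared with atrous / 1x1 / via geometry)
      const int OH = nd.hout, OW = nd.wout;
      const size_t ohow = (size_t)OH * OW;
      fmat& cols = ws.cols[i];
      cols.set_size(net.W[i].n_rows, ohow * N);
      for (int s = 0; s < N; ++s)
        im2col_one(A.colptr(s), nd.hin, nd.win, nd.cin, nd.k, nd.dil,
                   nd.stride, nd.pad, OH, OW, cols, (size_t)s * ohow);
      fmat Ym = net.W[i].t() * cols;
      Ym.each_col() += net.b[i];
      out.set_size(ohow * nd.cout, N);
      for (int s = 0; s < N; ++s) {
        fmat blk = Ym.cols(s * ohow, (s + 1) * ohow - 1);
        out.col(s) = arma::vectorise(blk.t());
      }
      if (!training) cols.reset();
      break;
    }
    case 2: {  // max pool
      const int s0 = nd.k, OH = nd.hout, OW = nd.wout;
      out.set_size((size_t)OH * OW * nd.cin, N);
      ws.poolidx[i].set_size(out.n_rows, N);
      for (int s = 0; s < N; ++s) {
        const float* x = A.colptr(s);
        float* y = out.colptr(s);
        arma::uword* id = ws.poolidx[i].colptr(s);
        for (int c = 0; c < nd.cin; ++c) {
          const size_t coff = (size_t)c * nd.hin * nd.win;
          for (int ow = 0; ow < OW; ++ow)
            for (int oh = 0; oh < OH; ++oh) {
              float best = -INFINITY; size_t bi = 0;
              for (int dw = 0; dw < s0; ++dw)
                for (int dh = 0; dh < s0; ++dh) {
                  const size_t r = coff + (size_t)(ow * s0 + dw) * nd.hin
                    + oh * s0 + dh;
                  if (x[r] > best) { best = x[r]; bi = r; }
                }
              const size_t ro = (size_t)c * OH * OW + (size_t)ow * OH + oh;
              y[ro] = best; id[ro] = bi;
            }
        }
      }
      break;
    }
    case 3: {  // avg pool (kh x kw, stride = kernel)
      const int OH = nd.hout, OW = nd.wout;
      const float inv = 1.0f / ((float)nd.kh * nd.kw);
      out.set_size((size_t)OH * OW * nd.cin, N);
      for (int s = 0; s < N; ++s) {
        const float* x = A.colptr(s);
        float* y = out.colptr(s);
        for (int c = 0; c < nd.cin; ++c) {
          const size_t coff = (size_t)c * nd.hin * nd.win;
          for (int ow = 0; ow < OW; ++ow)
            for (int oh = 0; oh < OH; ++oh) {
              float acc = 0.0f;
              for (int dw = 0; dw < nd.kw; ++dw)
                for (int dh = 0; dh < nd.kh; ++dh)
                  acc += x[coff + (size_t)(ow * nd.kw + dw) * nd.hin
                           + oh * nd.kh + dh];
              y[(size_t)c * OH * OW + (size_t)ow * OH + oh] = acc * inv;
            }
        }
      }
      break;
    }
    case 4:  // fully connected
      out = net.W[i] * A;
      out.each_col() += net.b[i];
      break;
    case 5: {  // batch norm
      fvec mu(nd.cin), invstd(nd.cin);
      if (training) {
        // cumulative average until the exponential momentum takes over,
        // so short trainings have unbiased running statistics
        const double mom = std::min(bn_mom,
                                    net.bnsteps[i] / (net.bnsteps[i] + 1.0));
        net.bnsteps[i] += 1.0;
        for (int c = 0; c < nd.cin; ++c) {
          double s = 0.0, s2 = 0.0;
          for (int sN = 0; sN < N; ++sN) {
            const float* x = A.colptr(sN) + (size_t)c * hw;
            for (int j = 0; j < hw; ++j) { s += x[j]; s2 += x[j] * (double)x[j]; }
          }
          const double m = (double)hw * N;
          const double mean = s / m;
          double v = s2 / m - mean * mean;
          if (v < 0) v = 0;
          mu[c] = (float)mean;
          invstd[c] = (float)(1.0 / std::sqrt(v + eps));
          net.rmean[i][c] = (float)(mom * net.rmean[i][c] + (1 - mom) * mean);
          net.rvar[i][c] = (float)(mom * net.rvar[i][c] + (1 - mom) * v);
        }
      } else {
        for (int c = 0; c < nd.cin; ++c) {
          mu[c] = net.rmean[i][c];
          invstd[c] = (float)(1.0 / std::sqrt((double)net.rvar[i][c] + eps));
        }
      }
      out.set_size(A.n_rows, N);
      for (int s = 0; s < N; ++s) {
        const float* x = A.colptr(s);
        float* y = out.colptr(s);
        for (int c = 0; c < nd.cin; ++c) {
          const float m0 = mu[c], is = invstd[c];
          const float g = net.gamma[i][c], b0 = net.beta[i][c];
          const size_t off = (size_t)c * hw;
          for (int j = 0; j < hw; ++j)
            y[off + j] = (x[off + j] - m0) * is * g + b0;
        }
      }
      ws.bn_mu[i] = mu; ws.bn_invstd[i] = invstd;
      break;
    }
    case 6: {  // prelu
      out.set_size(A.n_rows, N);
      for (int s = 0; s < N; ++s) {
        const float* x = A.colptr(s);
        float* y = out.colptr(s);
        for (int c = 0; c < nd.cin; ++c) {
          const float ac = net.aslope[i][c];
          const size_t off = (size_t)c * hw;
          for (int j = 0; j < hw; ++j) {
            const float v = x[off + j];
            y[off + j] = v > 0 ? v : ac * v;
          }
        }
      }
      break;
    }
    case 7: {  // concat along channels (= stacked rows)
      size_t rows = 0;
      for (int in : nd.inputs) rows += ws.acts[in].n_rows;
      out.set_size(rows, N);
      size_t off = 0;
      for (int in : nd.inputs) {
        out.rows(off, off + ws.acts[in].n_rows - 1) = ws.acts[in];
        off += ws.acts[in].n_rows;
      }
      break;
    }
    }
  }
}

// backward + SGD update for one batch; dOut is the loss gradient wrt the
// final activation.
void net_backward_update(Net& net, Workspace& ws, const fmat& dOut,
                         float lr, float momentum) {
  const int n = net.nodes.size();
  std::vector<fmat> gacc(n + 1);
  gacc[n] = dOut;
  const int N = dOut.n_cols;
  auto add_grad = [&](int slot, fmat&& g) {
    if (gacc[slot].n_elem == 0) gacc[slot] = std::move(g);
    else gacc[slot] += g;
  };
  for (int i = n - 1; i >= 0; --i) {
    GNode& nd = net.nodes[i];
    fmat dY = std::move(gacc[i + 1]);
    if (dY.n_elem == 0) continue;
    const fmat& A = ws.acts[nd.inputs[0]];
    const int hw = nd.hin * nd.win;
    const bool need_dx = nd.inputs[0] != 0 || nd.kind == 7;
    switch (nd.kind) {
    case 1: {
      const int OH = nd.hout, OW = nd.wout;
      const size_t ohow = (size_t)OH * OW;
      fmat dYm(nd.cout, ohow * N);
      for (int s = 0; s < N; ++s) {
        fmat blk(const_cast<float*>(dY.colptr(s)), ohow, nd.cout, false, true);
        dYm.cols(s * ohow, (s + 1) * ohow - 1) = blk.t();
      }
      fmat dW = ws.cols[i] * dYm.t();
      fvec db = arma::sum(dYm, 1);
      if (need_dx && nd.inputs[0] != 0) {
        fmat dcols = net.W[i] * dYm;
        fmat dX((size_t)nd.hin * nd.win * nd.cin, N, arma::fill::zeros);
        for (int s = 0; s < N; ++s)
          col2im_one(dcols, (size_t)s * ohow, nd.hin, nd.win, nd.cin,
                     nd.k, nd.dil, nd.stride, nd.pad, OH, OW, dX.colptr(s));
        add_grad(nd.inputs[0], std::move(dX));
      }
      net.vW[i] = momentum * net.vW[i] - lr * dW;
      net.W[i] += net.vW[i];
      net.vb[i] = momentum * net.vb[i] - lr * db;
      net.b[i] += net.vb[i];
      ws.cols[i].reset();
      break;
    }
    case 2: {
      if (!need_dx || nd.inputs[0] == 0) break;
      fmat dX((size_t)hw * nd.cin, N, arma::fill::zeros);
      for (int s = 0; s < N; ++s) {
        const float* g = dY.colptr(s);
        const arma::uword* id = ws.poolidx[i].colptr(s);
        float* out = dX.colptr(s);
        for (size_t r = 0; r < dY.n_rows; ++r) out[id[r]] += g[r];
      }
      add_grad(nd.inputs[0], std::move(dX));
      break;
    }
    case 3: {
      if (!need_dx || nd.inputs[0] == 0) break;
      const int OH = nd.hout, OW = nd.wout;
      const float inv = 1.0f / ((float)nd.kh * nd.kw);
      fmat dX((size_t)hw * nd.cin, N, arma::fill::zeros);
      for (int s = 0; s < N; ++s) {
        const float* g = dY.colptr(s);
        float* out = dX.colptr(s);
        for (int c = 0; c < nd.cin; ++c) {
          const size_t coff = (size_t)c * nd.hin * nd.win;
          for (int ow = 0; ow < OW; ++ow)
            for (int oh = 0; oh < OH; ++oh) {
              const float gv = g[(size_t)c * OH * OW + (size_t)ow * OH + oh] * inv;
              for (int dw = 0; dw < nd.kw; ++dw)
                for (int dh = 0; dh < nd.kh; ++dh)
                  out[coff + (size_t)(ow * nd.kw + dw) * nd.hin
                      + oh * nd.kh + dh] += gv;
            }
        }
      }
      add_grad(nd.inputs[0], std::move(dX));
      break;
    }
    case 4: {
      fmat dW = dY * A.t();
      fvec db = arma::sum(dY, 1);
      if (need_dx && nd.inputs[0] != 0)
        add_grad(nd.inputs[0], net.W[i].t() * dY);
      net.vW[i] = momentum * net.vW[i] - lr * dW;
      net.W[i] += net.vW[i];
      net.vb[i] = momentum * net.vb[i] - lr * db;
      net.b[i] += net.vb[i];
      break;
    }
    case 5: {
      const fvec& mu = ws.bn_mu[i];
      const fvec& invstd = ws.bn_invstd[i];
      const double m = (double)hw * N;
      fvec dgamma(nd.cin), dbeta(nd.cin);
      fmat dX(A.n_rows, N);
      for (int c = 0; c < nd.cin; ++c) {
        const size_t off = (size_t)c * hw;
        const float mc = mu[c], is = invstd[c], g = net.gamma[i][c];
        double s1 = 0.0, s2 = 0.0;
        for (int s = 0; s < N; ++s) {
          const float* x = A.colptr(s) + off;
          const float* gy = dY.colptr(s) + off;
          for (int j = 0; j < hw; ++j) {
            const float xh = (x[j] - mc) * is;
            s1 += gy[j];
            s2 += gy[j] * (double)xh;
          }
        }
        dgamma[c] = (float)s2; dbeta[c] = (float)s1;
        const double gs1 = s1 * g, gs2 = s2 * g;
        for (int s = 0; s < N; ++s) {
          const float* x = A.colptr(s) + off;
          const float* gy = dY.colptr(s) + off;
          float* out = dX.colptr(s) + off;
          for (int j = 0; j < hw; ++j) {
            const float xh = (x[j] - mc) * is;
            out[j] = (float)((is / m) * (m * g * gy[j] - gs1 - xh * gs2));
          }
        }
      }
      if (need_dx && nd.inputs[0] != 0) add_grad(nd.inputs[0], std::move(dX));
      net.vgamma[i] = momentum * net.vgamma[i] - lr * dgamma;
      net.gamma[i] += net.vgamma[i];
      net.vbeta[i] = momentum * net.vbeta[i] - lr * dbeta;
      net.beta[i] += net.vbeta[i];
      break;
    }
    case 6: {
      fvec da(nd.cin, arma::fill::zeros);
      fmat dX(A.n_rows, N);
      for (int c = 0; c < nd.cin; ++c) {
        const float ac = net.aslope[i][c];
        const size_t off = (size_t)c * hw;
        double dac = 0.0;
        for (int s = 0; s < N; ++s) {
          const float* x = A.colptr(s) + off;
          const float* gy = dY.colptr(s) + off;
          float* out = dX.colptr(s) + off;
          for (int j = 0; j < hw; ++j) {
            if (x[j] > 0) out[j] = gy[j];
            else { out[j] = ac * gy[j]; dac += gy[j] * (double)x[j]; }
          }
        }
        da[c] = (float)dac;
      }
      if (need_dx && nd.inputs[0] != 0) add_grad(nd.inputs[0], std::move(dX));
      net.va[i] = momentum * net.va[i] - lr * da;
      net.aslope[i] += net.va[i];
      break;
    }
    case 7: {
      size_t off = 0;
      for (int in : nd.inputs) {
        const size_t rows = ws.acts[in].n_rows;
        if (in != 0)
          add_grad(in, dY.rows(off, off + rows - 1));
        off += rows;
      }
      break;
    }
    }
  }
}

}  // namespace

// One training epoch of mini-batch SGD.  `order` is the 0-based shuffled
// sample order; params/velocity/state are modified copies returned to R.
// [[Rcpp::export]]
List cpp_run_epoch(List nodesList, List params, List velocity, List state,
                   NumericMatrix X, IntegerVector labels,
                   IntegerVector order, int batch_size, double lr,
                   double momentum, int n_classes,
                   double eps, double bn_mom) {
  Net net;
  net.nodes = parse_nodes(nodesList);
  load_params(net, params, velocity, state);
  const int n = order.size();
  Workspace ws;
  double loss_sum = 0.0;
  for (int start = 0; start < n; start += batch_size) {
    const int nb = std::min(batch_size, n - start);
    ws.acts.resize(net.nodes.size() + 1);
    ws.acts[0].set_size(X.nrow(), nb);
    for (int j = 0; j < nb; ++j) {
      const double* src = &X(0, order[start + j]);
      float* dst = ws.acts[0].colptr(j);
      for (int r = 0; r < X.nrow(); ++r) dst[r] = (float)src[r];
    }
    net_forward(net, ws, true, eps, bn_mom);
    // softmax loss and gradient
    const fmat& out = ws.acts.back();
    fmat dOut(out.n_rows, nb);
    double bl = 0.0;
    for (int j = 0; j < nb; ++j) {
      const float* f = out.colptr(j);
      float mx = f[0];
      for (int c = 1; c < n_classes; ++c) mx = std::max(mx, f[c]);
      double z = 0.0;
      for (int c = 0; c < n_classes; ++c) z += std::exp((double)f[c] - mx);
      const double lse = std::log(z);
      const int y = labels[order[start + j]];
      bl += lse - ((double)f[y] - mx);
      float* d = dOut.colptr(j);
      for (int c = 0; c < n_classes; ++c)
        d[c] = (float)((std::exp((double)f[c] - mx) / z - (c == y ? 1.0 : 0.0)) / nb);
    }
    loss_sum += bl;
    net_backward_update(net, ws, dOut, (float)lr, (float)momentum);
  }
  store_params(net, params, velocity, state);
  return List::create(_["params"] = params, _["velocity"] = velocity,
                      _["state"] = state, _["loss"] = loss_sum / n);
}

// Batched class-probability prediction (eval mode).
// [[Rcpp::export]]
NumericMatrix cpp_predict_probs(List nodesList, List params, List state,
                                NumericMatrix X, int batch_size,
                                int n_classes, double eps) {
  Net net;
  net.nodes = parse_nodes(nodesList);
  List dummyv(params.size());
  load_params(net, params, dummyv, state);
  const int n = X.ncol();
  NumericMatrix probs(n, n_classes);
  Workspace ws;
  for (int start = 0; start < n; start += batch_size) {
    const int nb = std::min(batch_size, n - start);
    ws.acts.resize(net.nodes.size() + 1);
    ws.acts[0].set_size(X.nrow(), nb);
    for (int j = 0; j < nb; ++j) {
      const double* src = &X(0, start + j);
      float* dst = ws.acts[0].colptr(j);
      for (int r = 0; r < X.nrow(); ++r) dst[r] = (float)src[r];
    }
    net_forward(net, ws, false, eps, 0.9);
    const fmat& out = ws.acts.back();
    for (int j = 0; j < nb; ++j) {
      const float* f = out.colptr(j);
      float mx = f[0];
      for (int c = 1; c < n_classes; ++c) mx = std::max(mx, f[c]);
      double z = 0.0;
      for (int c = 0; c < n_classes; ++c) z += std::exp((double)f[c] - mx);
      for (int c = 0; c < n_classes; ++c)
        probs(start + j, c) = std::exp((double)f[c] - mx) / z;
    }
  }
  return probs;
}

// Forward-only pass in training mode that refreshes batch-norm running
// statistics at the current weights (weights are not touched).  Used to
// recalibrate eval-mode normalisation after an epoch of fast weight
// movement.
// [[Rcpp::export]]
List cpp_update_stats(List nodesList, List params, List state,
                      NumericMatrix X, int batch_size,
                      double eps, double bn_mom) {
  Net net;
  net.nodes = parse_nodes(nodesList);
  List dummyv(params.size());
  load_params(net, params, dummyv, state);
  const int n = X.ncol();
  Workspace ws;
  for (int start = 0; start < n; start += batch_size) {
    const int nb = std::min(batch_size, n - start);
    ws.acts.resize(net.nodes.size() + 1);
    ws.acts[0].set_size(X.nrow(), nb);
    for (int j = 0; j < nb; ++j) {
      const double* src = &X(0, start + j);
      float* dst = ws.acts[0].colptr(j);
      for (int r = 0; r < X.nrow(); ++r) dst[r] = (float)src[r];
    }
    net_forward(net, ws, true, eps, bn_mom);
  }
  store_params(net, params, dummyv, state);
  return List::create(_["state"] = state);
}
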