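// Dense 3D conv-net engine for the two-stage lesion segmentation model.
//
// Activations are (n_voxels x n_channels) matrices; voxels are linearised
// column-major, x fastest: row = x + dx*(y + dy*z), matching R's array
// layout. Convolutions are 3x3x3, zero-padded by 1. Two execution paths:
// narrow layers (small Cin*Cout, large spatial extent) run as direct
// nested loops to avoid the 27x im2col memory blow-up; wide layers (the
// coarse-scale trunks) run as im2col + BLAS GEMM. Batches are vectors of
// items so stage-2 boxes of different sizes can share batch-normalisation
// statistics.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double BN_EPS = 1e-5;

struct Dims {
  int x, y, z;
  long n() const { return (long)x * y * z; }
};

static Dims dims_of(SEXP a) {
  IntegerVector d = Rf_getAttrib(a, R_DimSymbol);
  if (d.size() < 3) stop("expected a 3D array");
  Dims out;
  out.x = d[0]; out.y = d[1]; out.z = d[2];
  return out;
}

static mat as_feat(SEXP a) {
  IntegerVector d = Rf_getAttrib(a, R_DimSymbol);
  NumericVector v(a);
  long n; int C;
  if (d.size() == 3) { n = (long)d[0] * d[1] * d[2]; C = 1; }
  else if (d.size() == 4) { n = (long)d[0] * d[1] * d[2]; C = d[3]; }
  else stop("expected a 3D or 4D array");
  mat out(n, C);
  std::copy(v.begin(), v.end(), out.memptr());
  return out;
}

static NumericVector feat_to_r(const mat& f, Dims d) {
  NumericVector out(f.n_elem);
  std::copy(f.begin(), f.end(), out.begin());
  if (f.n_cols == 1) out.attr("dim") = IntegerVector::create(d.x, d.y, d.z);
  else out.attr("dim") = IntegerVector::create(d.x, d.y, d.z, (int)f.n_cols);
  return out;
}

struct Batch {
  std::vector<mat> a;
  std::vector<Dims> d;
  size_t size() const { return a.size(); }
  long rows() const { long r = 0; for (auto& m : a) r += m.n_rows; return r; }
};

// ---------------------------------------------------------------------------
// Convolution kernels

static Dims conv_out_dims(Dims d, int stride) {
  Dims o;
  o.x = (d.x - 1) / stride + 1;
  o.y = (d.y - 1) / stride + 1;
  o.z = (d.z - 1) / stride + 1;
  return o;
}

// weight row index for input channel ci and kernel offset k (0..26)
static inline int wrow(int ci, int k) { return ci * 27 + k; }

// direct loops only pay off for narrow stride-1 convolutions over large
// spatial extents; strided convolutions have small outputs and vectorise
// poorly, so they go through im2col + GEMM
static bool conv_direct(int Cin, int Cout, int stride) {
  return stride == 1 && Cin * Cout <= 192;
}

static void im2col(const mat& X, Dims d, int stride, mat& col, Dims od) {
  int Cin = X.n_cols;
  col.zeros(od.n(), 27 * Cin);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = X.colptr(c);
    for (int k = 0; k < 27; ++k) {
      int ox = k % 3 - 1, oy = (k / 3) % 3 - 1, oz = k / 9 - 1;
      double* cc = col.colptr(wrow(c, k));
      for (int z = 0; z < od.z; ++z) {
        int iz = z * stride + oz;
        if (iz < 0 || iz >= d.z) continue;
        for (int y = 0; y < od.y; ++y) {
          int iy = y * stride + oy;
          if (iy < 0 || iy >= d.y) continue;
          long ob = ((long)z * od.y + y) * od.x;
          long ib = ((long)iz * d.y + iy) * d.x;
          int x0 = 0, x1 = od.x;
          while (x0 < od.x && (x0 * stride + ox) < 0) ++x0;
          while (x1 > x0 && ((x1 - 1) * stride + ox) >= d.x) --x1;
          for (int x = x0; x < x1; ++x)
            cc[ob + x] = xc[ib + (long)x * stride + ox];
        }
      }
    }
  }
}

static void col2im_add(const mat& col, Dims d, int stride, Dims od, mat& dX) {
  int Cin = dX.n_cols;
  for (int c = 0; c < Cin; ++c) {
    double* xc = dX.colptr(c);
    for (int k = 0; k < 27; ++k) {
      int ox = k % 3 - 1, oy = (k / 3) % 3 - 1, oz = k / 9 - 1;
      const double* cc = col.colptr(wrow(c, k));
      for (int z = 0; z < od.z; ++z) {
        int iz = z * stride + oz;
        if (iz < 0 || iz >= d.z) continue;
        for (int y = 0; y < od.y; ++y) {
          int iy = y * stride + oy;
          if (iy < 0 || iy >= d.y) continue;
          long ob = ((long)z * od.y + y) * od.x;
          long ib = ((long)iz * d.y + iy) * d.x;
          int x0 = 0, x1 = od.x;
          while (x0 < od.x && (x0 * stride + ox) < 0) ++x0;
          while (x1 > x0 && ((x1 - 1) * stride + ox) >= d.x) --x1;
          for (int x = x0; x < x1; ++x)
            xc[ib + (long)x * stride + ox] += cc[ob + x];
        }
      }
    }
  }
}

static void conv3_fwd(const mat& X, Dims d, const mat& W, int stride,
                      mat& Y, Dims& od) {
  od = conv_out_dims(d, stride);
  int Cin = X.n_cols, Cout = W.n_cols;
  if (!conv_direct(Cin, Cout, stride)) {
    mat col;
    im2col(X, d, stride, col, od);
    Y = col * W;
    return;
  }
  Y.zeros(od.n(), Cout);
  for (int k = 0; k < 27; ++k) {
    int ox = k % 3 - 1, oy = (k / 3) % 3 - 1, oz = k / 9 - 1;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = X.colptr(ci);
      for (int z = 0; z < od.z; ++z) {
        int iz = z * stride + oz;
        if (iz < 0 || iz >= d.z) continue;
        for (int y = 0; y < od.y; ++y) {
          int iy = y * stride + oy;
          if (iy < 0 || iy >= d.y) continue;
          long ob = ((long)z * od.y + y) * od.x;
          long ib = ((long)iz * d.y + iy) * d.x + ox;
          int x0 = 0, x1 = od.x;
          while (x0 < od.x && (x0 * stride + ox) < 0) ++x0;
          while (x1 > x0 && ((x1 - 1) * stride + ox) >= d.x) --x1;
          for (int co = 0; co < Cout; ++co) {
            const double w = W(wrow(ci, k), co);
            double* __restrict__ yc = Y.colptr(co) + ob;
            const double* __restrict__ xl = xc + ib;
            for (int x = x0; x < x1; ++x) yc[x] += w * xl[x];
          }
        }
      }
    }
  }
}

static void conv3_bwd(const mat& X, Dims d, const mat& W, int stride,
                      const mat& dY, Dims od, mat& dW, mat& dX,
                      bool want_dx) {
  int Cin = X.n_cols, Cout = W.n_cols;
  dW.zeros(W.n_rows, W.n_cols);
  if (want_dx) dX.zeros(X.n_rows, X.n_cols);
  if (!conv_direct(Cin, Cout, stride)) {
    mat col;
    im2col(X, d, stride, col, od);
    dW = col.t() * dY;
    if (want_dx) {
      mat dcol = dY * W.t();
      col2im_add(dcol, d, stride, od, dX);
    }
    return;
  }
  for (int k = 0; k < 27; ++k) {
    int ox = k % 3 - 1, oy = (k / 3) % 3 - 1, oz = k / 9 - 1;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = X.colptr(ci);
      double* dxc = want_dx ? dX.colptr(ci) : nullptr;
      for (int z = 0; z < od.z; ++z) {
        int iz = z * stride + oz;
        if (iz < 0 || iz >= d.z) continue;
        for (int y = 0; y < od.y; ++y) {
          int iy = y * stride + oy;
          if (iy < 0 || iy >= d.y) continue;
          long ob = ((long)z * od.y + y) * od.x;
          long ib = ((long)iz * d.y + iy) * d.x + ox;
          int x0 = 0, x1 = od.x;
          while (x0 < od.x && (x0 * stride + ox) < 0) ++x0;
          while (x1 > x0 && ((x1 - 1) * stride + ox) >= d.x) --x1;
          for (int co = 0; co < Cout; ++co) {
            const double w = W(wrow(ci, k), co);
            const double* __restrict__ dyc = dY.colptr(co) + ob;
            const double* __restrict__ xl = xc + ib;
            double acc = 0;
            for (int x = x0; x < x1; ++x) acc += xl[x] * dyc[x];
            if (dxc) {
              double* __restrict__ dxl = dxc + ib;
              for (int x = x0; x < x1; ++x) dxl[x] += w * dyc[x];
            }
            dW(wrow(ci, k), co) += acc;
          }
        }
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Fused conv + batch-norm + optional ReLU unit
//
// Caches the layer input (for the convolution backward) and the normalised
// activations xhat (for the batch-norm backward); the ReLU mask is derived
// from g*xhat + b on the fly, so no mask is stored.

struct CBR {
  mat W; vec g, b, rm, rv;
  int stride = 1;
  bool relu = true;
  // caches
  Batch in;
  std::vector<mat> xhat;
  std::vector<Dims> od;
  vec invstd;
  long N = 0;
  bool eval_mode = false;
  // grads
  mat dW; vec dg, db;

  void fwd(const Batch& x, Batch& y, bool training, double mom, bool keep) {
    size_t B = x.size();
    if (keep) in = x;
    y.a.resize(B); y.d.resize(B);
    od.resize(B);
    int C = W.n_cols;
    for (size_t i = 0; i < B; ++i)
      conv3_fwd(x.a[i], x.d[i], W, stride, y.a[i], od[i]);
    for (size_t i = 0; i < B; ++i) y.d[i] = od[i];
    eval_mode = !training;
    if (training) {
      N = 0;
      for (auto& m : y.a) N += m.n_rows;
      vec s(C, arma::fill::zeros), s2(C, arma::fill::zeros);
      for (auto& m : y.a) {
        s += arma::sum(m, 0).t();
        s2 += arma::sum(arma::square(m), 0).t();
      }
      vec mean = s / (double)N;
      vec var = s2 / (double)N - arma::square(mean);
      var.transform([](double v) { return v < 0 ? 0.0 : v; });
      invstd = 1.0 / arma::sqrt(var + BN_EPS);
      rm = (1.0 - mom) * rm + mom * mean;
      rv = (1.0 - mom) * rv + mom * var;
      if (keep) xhat.resize(B);
      for (size_t i = 0; i < B; ++i) {
        for (int c = 0; c < C; ++c)
          y.a[i].col(c) = (y.a[i].col(c) - mean[c]) * invstd[c];
        if (keep) xhat[i] = y.a[i];
        for (int c = 0; c < C; ++c) {
          y.a[i].col(c) = g[c] * y.a[i].col(c) + b[c];
          if (relu) {
            double* p = y.a[i].colptr(c);
            for (long r = 0; r < (long)y.a[i].n_rows; ++r)
              if (p[r] < 0) p[r] = 0;
          }
        }
      }
    } else {
      vec is = 1.0 / arma::sqrt(rv + BN_EPS);
      for (size_t i = 0; i < B; ++i) {
        for (int c = 0; c < C; ++c) {
          y.a[i].col(c) = g[c] * (y.a[i].col(c) - rm[c]) * is[c] + b[c];
          if (relu) {
            double* p = y.a[i].colptr(c);
            for (long r = 0; r < (long)y.a[i].n_rows; ++r)
              if (p[r] < 0) p[r] = 0;
          }
        }
      }
    }
  }

  // dy is consumed (modified in place); dx gets the input gradient
  void bwd(Batch& dy, Batch& dx, bool want_dx = true) {
    size_t B = dy.size();
    int C = W.n_cols;
    // ReLU: zero gradients where the unit was inactive (g*xhat + b <= 0)
    if (relu) {
      for (size_t i = 0; i < B; ++i)
        for (int c = 0; c < C; ++c) {
          const double* xh = xhat[i].colptr(c);
          double* dyc = dy.a[i].colptr(c);
          double gc = g[c], bc = b[c];
          for (long r = 0; r < (long)dy.a[i].n_rows; ++r)
            if (gc * xh[r] + bc <= 0) dyc[r] = 0;
        }
    }
    // batch-norm backward (training statistics)
    dg.zeros(C); db.zeros(C);
    vec sdy(C, arma::fill::zeros), sdyx(C, arma::fill::zeros);
    for (size_t i = 0; i < B; ++i) {
      sdy += arma::sum(dy.a[i], 0).t();
      sdyx += arma::sum(dy.a[i] % xhat[i], 0).t();
    }
    dg = sdyx; db = sdy;
    for (size_t i = 0; i < B; ++i)
      for (int c = 0; c < C; ++c)
        dy.a[i].col(c) = g[c] * invstd[c] *
          (dy.a[i].col(c) - sdy[c] / (double)N -
           xhat[i].col(c) * (sdyx[c] / (double)N));
    // convolution backward
    dx.a.resize(B); dx.d.resize(B);
    dW.zeros(W.n_rows, W.n_cols);
    mat dWi;
    for (size_t i = 0; i < B; ++i) {
      dx.d[i] = in.d[i];
      conv3_bwd(in.a[i], in.d[i], W, stride, dy.a[i], od[i], dWi, dx.a[i],
                want_dx);
      dW += dWi;
    }
  }
};

// ResBlock: conv-BN-ReLU, conv-BN, + identity, ReLU after the addition
struct ResBlock {
  CBR u1, u2;
  Batch in, preact;  // preact = bn2-out + identity (pre final ReLU)

  void fwd(const Batch& x, Batch& y, bool training, double mom, bool keep) {
    if (keep) in = x;
    Batch h;
    u1.fwd(x, h, training, mom, keep);
    u2.relu = false;
    u2.fwd(h, y, training, mom, keep);
    for (size_t i = 0; i < y.size(); ++i) y.a[i] += x.a[i];
    if (keep) preact = y;
    for (size_t i = 0; i < y.size(); ++i)
      y.a[i].transform([](double v) { return v > 0 ? v : 0.0; });
  }
  void bwd(Batch& dy, Batch& dx) {
    size_t B = dy.size();
    for (size_t i = 0; i < B; ++i) {
      const double* pa = preact.a[i].memptr();
      double* dyc = dy.a[i].memptr();
      for (long r = 0; r < (long)dy.a[i].n_elem; ++r)
        if (pa[r] <= 0) dyc[r] = 0;
    }
    Batch ds = dy;    // identity branch gradient
    Batch dh, dxc;
    u2.bwd(dy, dh);
    u1.bwd(dh, dxc);
    dx.a.resize(B); dx.d = dxc.d;
    for (size_t i = 0; i < B; ++i) dx.a[i] = dxc.a[i] + ds.a[i];
  }
};

// 1x1x1 conv head with bias
struct Conv1 {
  mat W; vec b;
  mat dW; vec db;
  Batch in;
  void fwd(const Batch& x, Batch& y, bool keep) {
    if (keep) in = x;
    y.a.resize(x.size()); y.d = x.d;
    for (size_t i = 0; i < x.size(); ++i) {
      y.a[i] = x.a[i] * W;
      y.a[i].each_row() += b.t();
    }
  }
  void bwd(const Batch& dy, Batch& dx) {
    dW.zeros(W.n_rows, W.n_cols); db.zeros(W.n_cols);
    dx.a.resize(dy.size()); dx.d = dy.d;
    for (size_t i = 0; i < dy.size(); ++i) {
      dW += in.a[i].t() * dy.a[i];
      db += arma::sum(dy.a[i], 0).t();
      dx.a[i] = dy.a[i] * W.t();
    }
  }
};

// nearest-neighbour x2 upsampling
static void up2_fwd(const mat& x, Dims d, mat& y, Dims& od) {
  od.x = d.x * 2; od.y = d.y * 2; od.z = d.z * 2;
  int C = x.n_cols;
  y.set_size(od.n(), C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (int z = 0; z < od.z; ++z)
      for (int yy = 0; yy < od.y; ++yy) {
        long ob = ((long)z * od.y + yy) * od.x;
        long ib = ((long)(z / 2) * d.y + yy / 2) * d.x;
        for (int xx = 0; xx < od.x; ++xx)
          yc[ob + xx] = xc[ib + xx / 2];
      }
  }
}

static void up2_bwd(const mat& dy, Dims od, mat& dx, Dims d) {
  int C = dy.n_cols;
  dx.zeros((long)d.x * d.y * d.z, C);
  for (int c = 0; c < C; ++c) {
    const double* yc = dy.colptr(c);
    double* xc = dx.colptr(c);
    for (int z = 0; z < od.z; ++z)
      for (int yy = 0; yy < od.y; ++yy) {
        long ob = ((long)z * od.y + yy) * od.x;
        long ib = ((long)(z / 2) * d.y + yy / 2) * d.x;
        for (int xx = 0; xx < od.x; ++xx)
          xc[ib + xx / 2] += yc[ob + xx];
      }
  }
}

// ---------------------------------------------------------------------------
// Parameter plumbing

static mat get_mat(List p, const std::string& nm) {
  if (!p.containsElementNamed(nm.c_str())) stop("missing parameter: " + nm);
  NumericMatrix m = p[nm];
  mat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.memptr());
  return out;
}
static vec get_vec(List p, const std::string& nm) {
  if (!p.containsElementNamed(nm.c_str())) stop("missing parameter: " + nm);
  NumericVector v = p[nm];
  return vec(v.begin(), v.size());
}
static NumericMatrix r_mat(const mat& m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}
static NumericVector r_vec(const vec& v) {
  return NumericVector(v.begin(), v.end());
}

static void load_cbr(List p, const std::string& pre, CBR& u, int stride) {
  u.W = get_mat(p, pre + "_W");
  u.stride = stride;
  u.g = get_vec(p, pre + "_g");  u.b = get_vec(p, pre + "_b");
  u.rm = get_vec(p, pre + "_rm"); u.rv = get_vec(p, pre + "_rv");
}
static void load_res(List p, const std::string& pre, ResBlock& r) {
  r.u1.W = get_mat(p, pre + "_W1"); r.u1.stride = 1;
  r.u1.g = get_vec(p, pre + "_g1"); r.u1.b = get_vec(p, pre + "_b1");
  r.u1.rm = get_vec(p, pre + "_rm1"); r.u1.rv = get_vec(p, pre + "_rv1");
  r.u2.W = get_mat(p, pre + "_W2"); r.u2.stride = 1;
  r.u2.g = get_vec(p, pre + "_g2"); r.u2.b = get_vec(p, pre + "_b2");
  r.u2.rm = get_vec(p, pre + "_rm2"); r.u2.rv = get_vec(p, pre + "_rv2");
}
static void dump_cbr(List& g, List& s, const std::string& pre, CBR& u) {
  g[pre + "_W"] = r_mat(u.dW);
  g[pre + "_g"] = r_vec(u.dg);
  g[pre + "_b"] = r_vec(u.db);
  s[pre + "_rm"] = r_vec(u.rm);
  s[pre + "_rv"] = r_vec(u.rv);
}
static void dump_res(List& g, List& s, const std::string& pre, ResBlock& r) {
  g[pre + "_W1"] = r_mat(r.u1.dW);
  g[pre + "_g1"] = r_vec(r.u1.dg);
  g[pre + "_b1"] = r_vec(r.u1.db);
  g[pre + "_W2"] = r_mat(r.u2.dW);
  g[pre + "_g2"] = r_vec(r.u2.dg);
  g[pre + "_b2"] = r_vec(r.u2.db);
  s[pre + "_rm1"] = r_vec(r.u1.rm);
  s[pre + "_rv1"] = r_vec(r.u1.rv);
  s[pre + "_rm2"] = r_vec(r.u2.rm);
  s[pre + "_rv2"] = r_vec(r.u2.rv);
}

// ---------------------------------------------------------------------------
// Stage 1: stem (x2) -> strided conv (x4) -> strided conv (x8) ->
// ResBlocks -> 1x1x1 head.

struct Stage1 {
  CBR stem, down1, down2;
  std::vector<ResBlock> res;
  Conv1 head;

  void load(List p) {
    load_cbr(p, "s1_stem", stem, 1);
    load_cbr(p, "s1_down1", down1, 2);
    load_cbr(p, "s1_down2", down2, 2);
    int R = 0;
    while (p.containsElementNamed(("s1_res" + std::to_string(R) + "_W1").c_str())) ++R;
    res.resize(R);
    for (int r = 0; r < R; ++r) load_res(p, "s1_res" + std::to_string(r), res[r]);
    head.W = get_mat(p, "s1_head_W");
    head.b = get_vec(p, "s1_head_b");
  }

  void fwd(const Batch& x2in, Batch& logits, Batch& f2, Batch& f4, Batch& f8,
           bool training, double mom, bool keep) {
    stem.fwd(x2in, f2, training, mom, keep);
    down1.fwd(f2, f4, training, mom, keep);
    down2.fwd(f4, f8, training, mom, keep);
    for (auto& r : res) { Batch t; r.fwd(f8, t, training, mom, keep); f8 = t; }
    head.fwd(f8, logits, keep);
  }

  void bwd(Batch& dlogits) {
    Batch d1, d2;
    head.bwd(dlogits, d1);
    for (int r = (int)res.size() - 1; r >= 0; --r) {
      res[r].bwd(d1, d2); d1 = d2;
    }
    down2.bwd(d1, d2);
    down1.bwd(d2, d1);
    stem.bwd(d1, d2, false);   // no gradient wrt the raw input needed
  }

  void dump(List& g, List& s) {
    dump_cbr(g, s, "s1_stem", stem);
    dump_cbr(g, s, "s1_down1", down1);
    dump_cbr(g, s, "s1_down2", down2);
    for (size_t r = 0; r < res.size(); ++r)
      dump_res(g, s, "s1_res" + std::to_string(r), res[r]);
    g["s1_head_W"] = r_mat(head.dW);
    g["s1_head_b"] = r_vec(head.db);
  }
};

// Stage 2 decoder: trunk at x8 (conv + ResBlocks), then upsample / concat /
// conv through x4, x2 and full resolution (raw image skip), 1x1x1 head.

struct Stage2 {
  CBR g8, d4, d2, df;
  std::vector<ResBlock> res;
  Conv1 head;
  bool use_image;
  int c_up4, c_up2, c_upf;
  std::vector<Dims> dims8, dims4, dims2;

  void load(List p, bool use_img) {
    use_image = use_img;
    load_cbr(p, "s2_g8", g8, 1);
    int R = 0;
    while (p.containsElementNamed(("s2_res" + std::to_string(R) + "_W1").c_str())) ++R;
    res.resize(R);
    for (int r = 0; r < R; ++r) load_res(p, "s2_res" + std::to_string(r), res[r]);
    load_cbr(p, "s2_d4", d4, 1);
    load_cbr(p, "s2_d2", d2, 1);
    load_cbr(p, "s2_df", df, 1);
    head.W = get_mat(p, "s2_head_W");
    head.b = get_vec(p, "s2_head_b");
  }

  void fwd(const Batch& f8, const Batch& f4, const Batch& f2, const Batch& img,
           Batch& logits, bool training, double mom, bool keep) {
    size_t B = f8.size();
    Batch h8;
    g8.fwd(f8, h8, training, mom, keep);
    for (auto& r : res) { Batch t; r.fwd(h8, t, training, mom, keep); h8 = t; }
    dims8 = h8.d;
    c_up4 = h8.a[0].n_cols;

    Batch j4; j4.a.resize(B); j4.d.resize(B);
    for (size_t i = 0; i < B; ++i) {
      mat u; Dims odu;
      up2_fwd(h8.a[i], h8.d[i], u, odu);
      j4.a[i] = arma::join_rows(u, f4.a[i]);
      j4.d[i] = odu;
    }
    Batch h4;
    d4.fwd(j4, h4, training, mom, keep);
    dims4 = h4.d;
    c_up2 = h4.a[0].n_cols;

    Batch j2; j2.a.resize(B); j2.d.resize(B);
    for (size_t i = 0; i < B; ++i) {
      mat u; Dims odu;
      up2_fwd(h4.a[i], h4.d[i], u, odu);
      j2.a[i] = arma::join_rows(u, f2.a[i]);
      j2.d[i] = odu;
    }
    Batch h2;
    d2.fwd(j2, h2, training, mom, keep);
    dims2 = h2.d;
    c_upf = h2.a[0].n_cols;

    Batch jf; jf.a.resize(B); jf.d.resize(B);
    for (size_t i = 0; i < B; ++i) {
      mat u; Dims odu;
      up2_fwd(h2.a[i], h2.d[i], u, odu);
      if (use_image) jf.a[i] = arma::join_rows(u, img.a[i]);
      else jf.a[i] = std::move(u);
      jf.d[i] = odu;
    }
    Batch hf;
    df.fwd(jf, hf, training, mom, keep);
    head.fwd(hf, logits, keep);
  }

  void bwd(Batch& dlogits) {
    size_t B = dlogits.size();
    Batch dhf, djf;
    head.bwd(dlogits, dhf);
    df.bwd(dhf, djf);
    Batch dh2; dh2.a.resize(B); dh2.d = dims2;
    for (size_t i = 0; i < B; ++i) {
      mat du = djf.a[i].cols(0, c_upf - 1);
      up2_bwd(du, djf.d[i], dh2.a[i], dims2[i]);
    }
    Batch dj2;
    d2.bwd(dh2, dj2);
    Batch dh4; dh4.a.resize(B); dh4.d = dims4;
    for (size_t i = 0; i < B; ++i) {
      mat du = dj2.a[i].cols(0, c_up2 - 1);
      up2_bwd(du, dj2.d[i], dh4.a[i], dims4[i]);
    }
    Batch dj4;
    d4.bwd(dh4, dj4);
    Batch dh8; dh8.a.resize(B); dh8.d = dims8;
    for (size_t i = 0; i < B; ++i) {
      mat du = dj4.a[i].cols(0, c_up4 - 1);
      up2_bwd(du, dj4.d[i], dh8.a[i], dims8[i]);
    }
    Batch d2b;
    for (int r = (int)res.size() - 1; r >= 0; --r) {
      res[r].bwd(dh8, d2b); dh8 = d2b;
    }
    Batch dump_;
    g8.bwd(dh8, dump_, false);  // frozen pyramid: input gradient discarded
  }

  void dump(List& g, List& s) {
    dump_cbr(g, s, "s2_g8", g8);
    for (size_t r = 0; r < res.size(); ++r)
      dump_res(g, s, "s2_res" + std::to_string(r), res[r]);
    dump_cbr(g, s, "s2_d4", d4);
    dump_cbr(g, s, "s2_d2", d2);
    dump_cbr(g, s, "s2_df", df);
    g["s2_head_W"] = r_mat(head.dW);
    g["s2_head_b"] = r_vec(head.db);
  }
};

// ---------------------------------------------------------------------------
// Pooling / smoothing / labelling utilities

static void avgpool2(const mat& x, Dims d, mat& y, Dims& od) {
  od.x = (d.x + 1) / 2; od.y = (d.y + 1) / 2; od.z = (d.z + 1) / 2;
  int C = x.n_cols;
  y.set_size(od.n(), C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.colptr(c);
    double* yc = y.colptr(c);
    for (int z = 0; z < od.z; ++z)
      for (int yy = 0; yy < od.y; ++yy)
        for (int xx = 0; xx < od.x; ++xx) {
          double s = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int ix = std::min(2 * xx + dx, d.x - 1);
                int iy = std::min(2 * yy + dy, d.y - 1);
                int iz = std::min(2 * z + dz, d.z - 1);
                s += xc[((long)iz * d.y + iy) * d.x + ix];
              }
          yc[((long)z * od.y + yy) * od.x + xx] = s / 8.0;
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2(NumericVector arr) {
  Dims d = dims_of(arr);
  mat x(arr.begin(), d.n(), 1, false);
  mat y; Dims od;
  avgpool2(x, d, y, od);
  return feat_to_r(y, od);
}

// block maximum with kernel k and zero padding (partial blocks: maximum of
// the available voxels, floored at 0)
// [[Rcpp::export]]
NumericVector cpp_block_max(NumericVector arr, int k, double threshold) {
  Dims d = dims_of(arr);
  Dims od; od.x = (d.x + k - 1) / k; od.y = (d.y + k - 1) / k;
  od.z = (d.z + k - 1) / k;
  NumericVector out(od.n());
  const double* x = arr.begin();
  double* y = out.begin();
  std::fill(y, y + out.size(), 0.0);
  for (int z = 0; z < d.z; ++z)
    for (int yy = 0; yy < d.y; ++yy)
      for (int xx = 0; xx < d.x; ++xx) {
        double v = x[((long)z * d.y + yy) * d.x + xx];
        if (threshold > 0) v = (v >= threshold) ? 1.0 : 0.0;
        long o = ((long)(z / k) * od.y + yy / k) * od.x + xx / k;
        if (v > y[o]) y[o] = v;
      }
  out.attr("dim") = IntegerVector::create(od.x, od.y, od.z);
  return out;
}

// separable Gaussian smoothing; sigma per axis in voxels (kernel truncated
// at 3 sigma and renormalised at the edges)
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3(NumericVector arr, NumericVector sigma) {
  Dims d = dims_of(arr);
  std::vector<double> buf(arr.begin(), arr.end());
  std::vector<double> tmp(buf.size());
  int dims[3] = { d.x, d.y, d.z };
  long strides[3] = { 1, (long)d.x, (long)d.x * d.y };
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    for (int i = -r; i <= r; ++i) kern[i + r] = std::exp(-0.5 * i * i / (s * s));
    int n = dims[ax];
    long st = strides[ax];
    int oa = (ax + 1) % 3, ob = (ax + 2) % 3;
    for (int ib = 0; ib < dims[ob]; ++ib)
      for (int ia = 0; ia < dims[oa]; ++ia) {
        long base = (long)ia * strides[oa] + (long)ib * strides[ob];
        for (int i = 0; i < n; ++i) {
          double acc = 0, wsum = 0;
          int j0 = std::max(0, i - r), j1 = std::min(n - 1, i + r);
          for (int j = j0; j <= j1; ++j) {
            double w = kern[j - i + r];
            acc += w * buf[base + (long)j * st];
            wsum += w;
          }
          tmp[base + (long)i * st] = acc / wsum;
        }
      }
    buf.swap(tmp);
  }
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = IntegerVector::create(d.x, d.y, d.z);
  return out;
}

// connected components by flood fill (connectivity 6/18/26)
// [[Rcpp::export]]
IntegerVector cpp_conn_comp(LogicalVector binArr, int connectivity) {
  Dims d = dims_of(binArr);
  long n = d.n();
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<std::array<int, 3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.push_back({ dx, dy, dz });
      }
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; ++s) {
    if (!binArr[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back(); stack.pop_back();
      int x = v % d.x, y = (v / d.x) % d.y, z = v / ((long)d.x * d.y);
      for (auto& o : nb) {
        int ix = x + o[0], iy = y + o[1], iz = z + o[2];
        if (ix < 0 || ix >= d.x || iy < 0 || iy >= d.y || iz < 0 || iz >= d.z)
          continue;
        long w = ((long)iz * d.y + iy) * d.x + ix;
        if (binArr[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(d.x, d.y, d.z);
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Exported forward / training steps

static Batch batch_from_list(List xs) {
  Batch b;
  b.a.resize(xs.size()); b.d.resize(xs.size());
  for (int i = 0; i < xs.size(); ++i) {
    SEXP e = xs[i];
    b.a[i] = as_feat(e);
    b.d[i] = dims_of(e);
  }
  return b;
}

static void sigmoid_inplace(mat& m) {
  m.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
}

// Stage-1 training/eval step over a batch of full-resolution patches.
// [[Rcpp::export]]
List cpp_stage1_batch(List params, List xs, List ts, double pos_weight,
                      bool training, bool want_grad, double bn_momentum) {
  Stage1 net;
  net.load(params);
  Batch raw = batch_from_list(xs);
  Batch x2; x2.a.resize(raw.size()); x2.d.resize(raw.size());
  for (size_t i = 0; i < raw.size(); ++i)
    avgpool2(raw.a[i], raw.d[i], x2.a[i], x2.d[i]);
  Batch logits, f2, f4, f8;
  net.fwd(x2, logits, f2, f4, f8, training, bn_momentum, want_grad);

  Batch tgt = batch_from_list(ts);
  long N = 0;
  for (auto& m : logits.a) N += m.n_rows;
  double loss = 0;
  Batch dlog; dlog.a.resize(logits.size()); dlog.d = logits.d;
  for (size_t i = 0; i < logits.size(); ++i) {
    if (tgt.a[i].n_rows != logits.a[i].n_rows)
      stop("target shape does not match the low-resolution grid");
    mat p = logits.a[i];
    sigmoid_inplace(p);
    mat pc = arma::clamp(p, 1e-7, 1.0 - 1e-7);
    const mat& t = tgt.a[i];
    loss += arma::accu(-pos_weight * t % arma::log(pc)
                       - (1.0 - t) % arma::log(1.0 - pc));
    if (want_grad)
      dlog.a[i] = (-pos_weight * t % (1.0 - p) + (1.0 - t) % p) / (double)N;
  }
  loss /= (double)N;

  List out;
  out["loss"] = loss;
  if (want_grad) {
    net.bwd(dlog);
    List g, s;
    net.dump(g, s);
    out["grads"] = g;
    out["bn_stats"] = s;
  }
  return out;
}

// Single-volume stage-1 forward (eval mode); returns the coarse probability
// map and the retained feature pyramid.
// [[Rcpp::export]]
List cpp_stage1_forward(List params, NumericVector x) {
  Stage1 net;
  net.load(params);
  Batch raw; raw.a.push_back(as_feat(x)); raw.d.push_back(dims_of(x));
  Batch x2; x2.a.resize(1); x2.d.resize(1);
  avgpool2(raw.a[0], raw.d[0], x2.a[0], x2.d[0]);
  Batch logits, f2, f4, f8;
  net.fwd(x2, logits, f2, f4, f8, false, 0.0, false);
  mat p = logits.a[0];
  sigmoid_inplace(p);
  return List::create(
    _["prob"] = feat_to_r(p, logits.d[0]),
    _["f2"] = feat_to_r(f2.a[0], f2.d[0]),
    _["f4"] = feat_to_r(f4.a[0], f4.d[0]),
    _["f8"] = feat_to_r(f8.a[0], f8.d[0]));
}

// Batched stage-1 eval forward: probabilities and pyramid features for a
// list of equally-important patches (used during stage-2 training, where
// the frozen first stage scores every patch of the batch).
// [[Rcpp::export]]
List cpp_stage1_forward_batch(List params, List xs) {
  Stage1 net;
  net.load(params);
  Batch raw = batch_from_list(xs);
  Batch x2; x2.a.resize(raw.size()); x2.d.resize(raw.size());
  for (size_t i = 0; i < raw.size(); ++i)
    avgpool2(raw.a[i], raw.d[i], x2.a[i], x2.d[i]);
  Batch logits, f2, f4, f8;
  net.fwd(x2, logits, f2, f4, f8, false, 0.0, false);
  List out(raw.size());
  for (size_t i = 0; i < raw.size(); ++i) {
    mat p = logits.a[i];
    sigmoid_inplace(p);
    out[i] = List::create(
      _["prob"] = feat_to_r(p, logits.d[i]),
      _["f2"] = feat_to_r(f2.a[i], f2.d[i]),
      _["f4"] = feat_to_r(f4.a[i], f4.d[i]),
      _["f8"] = feat_to_r(f8.a[i], f8.d[i]));
  }
  return out;
}

// Single-box stage-2 forward (eval mode). Crops are 4D (x,y,z,channel)
// arrays; img is 3D (ignored when use_image is FALSE).
// [[Rcpp::export]]
NumericVector cpp_stage2_forward(List params, NumericVector f8,
                                 NumericVector f4, NumericVector f2,
                                 NumericVector img, bool use_image) {
  Stage2 net;
  net.load(params, use_image);
  Batch b8, b4, b2, bi;
  b8.a.push_back(as_feat(f8)); b8.d.push_back(dims_of(f8));
  b4.a.push_back(as_feat(f4)); b4.d.push_back(dims_of(f4));
  b2.a.push_back(as_feat(f2)); b2.d.push_back(dims_of(f2));
  if (use_image) { bi.a.push_back(as_feat(img)); bi.d.push_back(dims_of(img)); }
  Batch logits;
  net.fwd(b8, b4, b2, bi, logits, false, 0.0, false);
  mat p = logits.a[0];
  sigmoid_inplace(p);
  return feat_to_r(p, logits.d[0]);
}

// Stage-2 training step. `boxes` lists every proposed box in the batch:
// list(f8, f4, f2, img, patch, off) with `patch` the 1-based owning patch
// and `off` the 0-based full-resolution offset of the box inside it. Dice
// loss is computed per patch on the zero-initialised assembled prediction
// (last writer wins in overlaps) and averaged; gradients flow only to
// stage-2 parameters.
// [[Rcpp::export]]
List cpp_stage2_batch(List params, List boxes, List gts, double eps,
                      bool want_grad, double bn_momentum) {
  int nbox = boxes.size();
  int npatch = gts.size();
  Batch b8, b4, b2, bi;
  std::vector<int> patch_of(nbox);
  std::vector<std::array<int, 3>> off(nbox);
  bool use_image = true;
  for (int i = 0; i < nbox; ++i) {
    List bx = boxes[i];
    b8.a.push_back(as_feat(bx["f8"])); b8.d.push_back(dims_of(bx["f8"]));
    b4.a.push_back(as_feat(bx["f4"])); b4.d.push_back(dims_of(bx["f4"]));
    b2.a.push_back(as_feat(bx["f2"])); b2.d.push_back(dims_of(bx["f2"]));
    if (bx.containsElementNamed("img") && !Rf_isNull(bx["img"])) {
      bi.a.push_back(as_feat(bx["img"])); bi.d.push_back(dims_of(bx["img"]));
    } else use_image = false;
    patch_of[i] = as<int>(bx["patch"]) - 1;
    IntegerVector o = bx["off"];
    off[i] = { o[0], o[1], o[2] };
  }

  Stage2 net;
  net.load(params, use_image);
  Batch logits;
  std::vector<mat> probs(nbox);
  if (nbox > 0) {
    net.fwd(b8, b4, b2, bi, logits, true, bn_momentum, want_grad);
    for (int i = 0; i < nbox; ++i) {
      probs[i] = logits.a[i];
      sigmoid_inplace(probs[i]);
    }
  }

  std::vector<Dims> pd(npatch);
  std::vector<vec> pred(npatch);
  std::vector<arma::ivec> writer(npatch);
  for (int pI = 0; pI < npatch; ++pI) {
    pd[pI] = dims_of(gts[pI]);
    pred[pI].zeros(pd[pI].n());
    writer[pI] = arma::ivec(pd[pI].n(), arma::fill::value(-1));
  }
  for (int i = 0; i < nbox; ++i) {
    int pI = patch_of[i];
    Dims bd = logits.d[i];
    Dims Pd = pd[pI];
    const double* src = probs[i].colptr(0);
    for (int z = 0; z < bd.z; ++z)
      for (int y = 0; y < bd.y; ++y)
        for (int x = 0; x < bd.x; ++x) {
          int gx = off[i][0] + x, gy = off[i][1] + y, gz = off[i][2] + z;
          if (gx >= Pd.x || gy >= Pd.y || gz >= Pd.z) continue;
          long gi = ((long)gz * Pd.y + gy) * Pd.x + gx;
          pred[pI][gi] = src[((long)z * bd.y + y) * bd.x + x];
          writer[pI][gi] = i;
        }
  }

  double loss = 0;
  std::vector<vec> dpred(npatch);
  for (int pI = 0; pI < npatch; ++pI) {
    mat tm = as_feat(gts[pI]);
    vec t(tm.colptr(0), pd[pI].n());
    double sp = arma::accu(pred[pI]);
    double st = arma::accu(t);
    double spt = arma::dot(pred[pI], t);
    double S = sp + st + eps, T2 = 2.0 * spt + eps;
    loss += 1.0 - T2 / S;
    if (want_grad)
      dpred[pI] = (-(2.0 * t * S - T2) / (S * S)) / (double)npatch;
  }
  loss /= (double)npatch;

  List out;
  out["loss"] = loss;
  out["n_boxes"] = nbox;
  if (want_grad && nbox > 0) {
    Batch dlog; dlog.a.resize(nbox); dlog.d = logits.d;
    for (int i = 0; i < nbox; ++i)
      dlog.a[i].zeros(logits.a[i].n_rows, 1);
    for (int pI = 0; pI < npatch; ++pI) {
      Dims Pd = pd[pI];
      for (long gi = 0; gi < (long)Pd.n(); ++gi) {
        int i = writer[pI][gi];
        if (i < 0) continue;
        int gx = gi % Pd.x, gy = (gi / Pd.x) % Pd.y,
            gz = gi / ((long)Pd.x * Pd.y);
        Dims bd = dlog.d[i];
        long bi2 = ((long)(gz - off[i][2]) * bd.y + (gy - off[i][1])) * bd.x
                   + (gx - off[i][0]);
        double p = pred[pI][gi];
        dlog.a[i](bi2, 0) = dpred[pI][gi] * p * (1.0 - p);
      }
    }
    net.bwd(dlog);
    List g, s;
    net.dump(g, s);
    out["grads"] = g;
    out["bn_stats"] = s;
  }
  return out;
}
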