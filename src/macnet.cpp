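// Fast forward/backward/training engine for the attention-enhanced shallow
// ConvNet.  Single precision internally (BLAS throughput); the R-level
// reference operations are double precision and the two paths are
// cross-checked in the test suite.
//
// Internal layout is time-major ("transposed") so that every convolution
// becomes a contiguous-memcpy im2col plus one GEMM, and the CBAM spatial
// gate is a shifted-accumulation convolution:
//  - per-sample features live in (C*Tc) x F matrices whose rows are pixels
//    r = c*Tc + t (time fastest) and whose columns are feature maps;
//  - viewing such a matrix as Tc x (C*F) is a zero-copy reshape, which
//    turns the (C, 1) spatial convolution into a single GEMM;
//  - parameter matrices keep the same shapes and index conventions as the
//    R reference implementations in R/model.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uword;

namespace {

struct Config {
  int C, T, M, F1, k1, ratio, k2, F2, pool, stride, pooled;
  double dropout, log_eps;
  int branch;              // 0, 1, 2
  bool square, value_proj, use_tconv, use_sconv, bn_affine;
  int Tc, f_in, f_out, c2, feat_dim, cbam_h;
};

Config parse_cfg(const List& cfg) {
  Config c;
  c.C = as<int>(cfg["C"]); c.T = as<int>(cfg["T"]);
  c.M = as<int>(cfg["n_classes"]);
  c.F1 = as<int>(cfg["n_temporal_filters"]);
  c.k1 = as<int>(cfg["temporal_kernel"]);
  c.ratio = as<int>(cfg["cbam_ratio"]);
  c.k2 = as<int>(cfg["spatial_attention_kernel"]);
  c.F2 = as<int>(cfg["n_spatial_filters"]);
  c.pool = as<int>(cfg["pool_kernel"]);
  c.stride = as<int>(cfg["pool_stride"]);
  c.pooled = as<int>(cfg["pooled"]);
  c.dropout = as<double>(cfg["dropout_p"]);
  c.log_eps = as<double>(cfg["safe_log_eps"]);
  std::string br = as<std::string>(cfg["branch"]);
  c.branch = (br == "II") ? 2 : (br == "I" ? 1 : 0);
  c.square = as<bool>(cfg["square_before_pool"]);
  c.value_proj = as<bool>(cfg["value_projection"]);
  c.use_tconv = as<bool>(cfg["temporal_conv"]);
  c.use_sconv = as<bool>(cfg["spatial_conv"]);
  c.bn_affine = as<bool>(cfg["bn_affine"]);
  c.Tc = c.use_tconv ? c.T - c.k1 + 1 : c.T;
  c.f_in = c.use_tconv ? c.F1 : 1;
  c.f_out = c.use_sconv ? c.F2 : c.f_in;
  c.c2 = c.use_sconv ? 1 : c.C;
  c.feat_dim = c.f_out * c.c2 * c.pooled;
  c.cbam_h = c.F1 / c.ratio;
  return c;
}

struct Params {
  fmat Wq, Wk, Wv, tc_w, tc_b, ca_w0, ca_b0, ca_w1, ca_b1, sa_w, sa_b,
       sc_w, sc_b, bn_gamma, bn_beta, cl_w, cl_b;
  std::vector<fmat*> all;      // canonical order
  std::vector<std::string> names;

  void collect(const Config& c) {
    all.clear(); names.clear();
    auto add = [&](fmat& m, const char* n) { all.push_back(&m); names.push_back(n); };
    if (c.branch >= 1) {
      add(Wq, "Wq"); add(Wk, "Wk");
      if (c.value_proj) add(Wv, "Wv");
    }
    if (c.use_tconv) { add(tc_w, "tc_w"); add(tc_b, "tc_b"); }
    if (c.branch == 2) {
      add(ca_w0, "ca_w0"); add(ca_b0, "ca_b0");
      add(ca_w1, "ca_w1"); add(ca_b1, "ca_b1");
      add(sa_w, "sa_w"); add(sa_b, "sa_b");
    }
    if (c.use_sconv) { add(sc_w, "sc_w"); add(sc_b, "sc_b"); }
    if (c.bn_affine) { add(bn_gamma, "bn_gamma"); add(bn_beta, "bn_beta"); }
    add(cl_w, "cl_w"); add(cl_b, "cl_b");
  }
};

fmat to_fmat(SEXP s) {
  if (Rf_isMatrix(s)) {
    NumericMatrix m(s);
    fmat out(m.nrow(), m.ncol());
    for (int j = 0; j < m.ncol(); ++j)
      for (int i = 0; i < m.nrow(); ++i)
        out(i, j) = static_cast<float>(m(i, j));
    return out;
  }
  NumericVector v(s);
  fmat out(v.size(), 1);
  for (int i = 0; i < v.size(); ++i) out(i, 0) = static_cast<float>(v[i]);
  return out;
}

Params parse_params(const List& pl, const Config& c) {
  Params p;
  p.collect(c);
  for (size_t i = 0; i < p.all.size(); ++i) {
    if (!pl.containsElementNamed(p.names[i].c_str()))
      stop("missing parameter `%s`", p.names[i]);
    *p.all[i] = to_fmat(pl[p.names[i]]);
  }
  return p;
}

List params_to_list(const Params& p) {
  List out;
  for (size_t i = 0; i < p.all.size(); ++i) {
    const fmat& m = *p.all[i];
    NumericMatrix r(m.n_rows, m.n_cols);
    for (uword j = 0; j < m.n_cols; ++j)
      for (uword k = 0; k < m.n_rows; ++k)
        r(k, j) = m(k, j);
    out[p.names[i]] = r;
  }
  return out;
}

// Spatial-conv weight (F2 x F1*C, column m*C + c) reordered into the GEMM
// operand B (C*F1 x F2, row c + C*m).
fmat sconv_B(const fmat& sc_w, int C, int f_in) {
  fmat B(C * f_in, sc_w.n_rows);
  for (uword f2 = 0; f2 < sc_w.n_rows; ++f2)
    for (int m = 0; m < f_in; ++m)
      for (int ch = 0; ch < C; ++ch)
        B(ch + C * m, f2) = sc_w(f2, m * C + ch);
  return B;
}

void sconv_B_back(fmat& g_sc_w, const fmat& dB, int C, int f_in) {
  for (uword f2 = 0; f2 < g_sc_w.n_rows; ++f2)
    for (int m = 0; m < f_in; ++m)
      for (int ch = 0; ch < C; ++ch)
        g_sc_w(f2, m * C + ch) += dB(ch + C * m, f2);
}

// Same-padded k x k convolution of a 2-channel image by shifted
// accumulation.  Images and output are Tc x C matrices (rows = time = the
// kernel's column axis j; cols = channel = the kernel's row axis i).
// Kernel weights w(0, d*k*k + i*k + j), d = 0 avg-channel, d = 1 max.
void sa_conv_forward(const fmat& img_a, const fmat& img_m, const fmat& w,
                     float b, int k, fmat& out) {
  int Tc = img_a.n_rows, C = img_a.n_cols, pad = (k - 1) / 2;
  out.set_size(Tc, C);
  out.fill(b);
  for (int d = 0; d < 2; ++d) {
    const fmat& img = d == 0 ? img_a : img_m;
    for (int i = 0; i < k; ++i) {
      int dc = i - pad;
      int c0 = std::max(0, -dc), c1 = std::min(C, C - dc);
      if (c0 >= c1) continue;
      for (int j = 0; j < k; ++j) {
        float wij = w(0, d * k * k + i * k + j);
        if (wij == 0.0f) continue;
        int dt = j - pad;
        int t0 = std::max(0, -dt), t1 = std::min(Tc, Tc - dt);
        if (t0 >= t1) continue;
        out.submat(t0, c0, t1 - 1, c1 - 1) +=
          wij * img.submat(t0 + dt, c0 + dc, t1 - 1 + dt, c1 - 1 + dc);
      }
    }
  }
}

// Backward of sa_conv_forward: given d(out), accumulate kernel/bias grads
// and the gradients of the two input images.
void sa_conv_backward(const fmat& img_a, const fmat& img_m, const fmat& w,
                      int k, const fmat& dout, fmat& g_w, float& g_b,
                      fmat& dimg_a, fmat& dimg_m) {
  int Tc = img_a.n_rows, C = img_a.n_cols, pad = (k - 1) / 2;
  dimg_a.zeros(Tc, C);
  dimg_m.zeros(Tc, C);
  g_b += arma::accu(dout);
  for (int d = 0; d < 2; ++d) {
    const fmat& img = d == 0 ? img_a : img_m;
    fmat& dimg = d == 0 ? dimg_a : dimg_m;
    for (int i = 0; i < k; ++i) {
      int dc = i - pad;
      int c0 = std::max(0, -dc), c1 = std::min(C, C - dc);
      if (c0 >= c1) continue;
      for (int j = 0; j < k; ++j) {
        int dt = j - pad;
        int t0 = std::max(0, -dt), t1 = std::min(Tc, Tc - dt);
        if (t0 >= t1) continue;
        g_w(0, d * k * k + i * k + j) += arma::accu(
          dout.submat(t0, c0, t1 - 1, c1 - 1) %
          img.submat(t0 + dt, c0 + dc, t1 - 1 + dt, c1 - 1 + dc));
        dimg.submat(t0 + dt, c0 + dc, t1 - 1 + dt, c1 - 1 + dc) +=
          w(0, d * k * k + i * k + j) * dout.submat(t0, c0, t1 - 1, c1 - 1);
      }
    }
  }
}

// Per-sample forward cache (time-major layouts).
struct Cache {
  fmat Xt, Q, K, V, A, Yt;         // attention; Yt = refined input (T x C)
  fmat Gt;                          // temporal-conv output (C*Tc) x F1
  fvec avg, mx, za, ha, zm, hm, Mc;
  arma::uvec mx_idx;                // per-map argmax pixel of Gt
  fvec cm, cx, Ms;                  // per-pixel descriptors / gate
  arma::uvec cx_idx;                // per-pixel argmax map of Fpt
  fmat G2t;                         // CBAM output (or copy of Gt)
  fmat Ut;                          // head input (c2*Tc) x f_out
  fmat xhat;                        // post-BN
  fmat pooled, mask, zfeat;         // (c2*P) x f_out
};

struct BatchCache {
  std::vector<Cache> s;
  fvec mu, invstd;                  // per output map
  fmat logits, probs;               // M x N
};

// Contiguous im2col for the temporal convolution:
// Mcol(c*Tc + t, j) = Yt(t + j, c); every (c, j) pair is one memcpy.
void tconv_im2col(const fmat& Yt, int k1, int Tc, fmat& Mcol) {
  int C = Yt.n_cols;
  Mcol.set_size(C * Tc, k1);
  for (int j = 0; j < k1; ++j) {
    float* dst = Mcol.colptr(j);
    for (int ch = 0; ch < C; ++ch)
      std::memcpy(dst + ch * Tc, Yt.colptr(ch) + j, Tc * sizeof(float));
  }
}

void forward_batch(const Config& c, const Params& p,
                   const std::vector<fmat>& X, bool training,
                   fvec& run_mean, fvec& run_var, std::mt19937& rng,
                   BatchCache& bc) {
  int N = X.size();
  int HW = c.C * c.Tc;
  int head_rows = c.c2 * c.Tc;
  bc.s.assign(N, Cache());
  const float invsqd = 1.0f / std::sqrt((float)c.C);
  fmat B;
  if (c.use_sconv) B = sconv_B(p.sc_w, c.C, c.f_in);
  frowvec mc_row;

  // accumulate BN statistics on the fly
  fvec bn_sum(c.f_out, arma::fill::zeros);
  fvec bn_sumsq(c.f_out, arma::fill::zeros);

  for (int n = 0; n < N; ++n) {
    Cache& cc = bc.s[n];
    // ---- temporal attention ----
    if (c.branch >= 1) {
      cc.Xt = X[n].t();
      cc.Q = cc.Xt * p.Wq.t();
      cc.K = cc.Xt * p.Wk.t();
      cc.V = c.value_proj ? fmat(cc.Xt * p.Wv.t()) : cc.Xt;
      fmat S = (cc.Q * cc.K.t()) * invsqd;
      S.each_col() -= arma::max(S, 1);
      cc.A = arma::exp(S);
      cc.A.each_col() /= arma::sum(cc.A, 1);
      cc.Yt = cc.Xt + cc.A * cc.V;
    } else {
      cc.Yt = X[n].t();
    }
    // ---- temporal convolution ----
    if (c.use_tconv) {
      fmat Mcol;
      tconv_im2col(cc.Yt, c.k1, c.Tc, Mcol);
      cc.Gt = Mcol * p.tc_w.t();           // (C*Tc) x F1
      cc.Gt.each_row() += p.tc_b.col(0).t();
    } else {
      cc.Gt.set_size(HW, 1);
      for (int ch = 0; ch < c.C; ++ch)
        std::memcpy(cc.Gt.colptr(0) + ch * c.T, cc.Yt.colptr(ch),
                    c.T * sizeof(float));
    }
    // ---- CBAM with residual skip ----
    if (c.branch == 2) {
      cc.avg = arma::mean(cc.Gt, 0).t();
      cc.mx.set_size(c.F1);
      cc.mx_idx.set_size(c.F1);
      for (int m = 0; m < c.F1; ++m) {
        cc.mx_idx[m] = cc.Gt.col(m).index_max();
        cc.mx[m] = cc.Gt(cc.mx_idx[m], m);
      }
      cc.za = p.ca_w0 * cc.avg + p.ca_b0.col(0);
      cc.ha = arma::clamp(cc.za, 0.0f, arma::datum::inf);
      cc.zm = p.ca_w0 * cc.mx + p.ca_b0.col(0);
      cc.hm = arma::clamp(cc.zm, 0.0f, arma::datum::inf);
      fvec sgate = p.ca_w1 * cc.ha + p.ca_w1 * cc.hm + 2.0f * p.ca_b1.col(0);
      cc.Mc = 1.0f / (1.0f + arma::exp(-sgate));
      mc_row = cc.Mc.t();
      fmat Fpt = cc.Gt;
      Fpt.each_row() %= mc_row;
      cc.cm = arma::mean(Fpt, 1);
      cc.cx = Fpt.col(0);
      cc.cx_idx.zeros(HW);
      for (int m = 1; m < c.F1; ++m) {
        const float* col = Fpt.colptr(m);
        float* best = cc.cx.memptr();
        for (int r = 0; r < HW; ++r)
          if (col[r] > best[r]) { best[r] = col[r]; cc.cx_idx[r] = m; }
      }
      // spatial gate: 7x7 conv over the (avg, max) descriptor images
      fmat img_a(cc.cm.memptr(), c.Tc, c.C, false, true);
      fmat img_m(cc.cx.memptr(), c.Tc, c.C, false, true);
      fmat logit;
      sa_conv_forward(img_a, img_m, p.sa_w, p.sa_b(0, 0), c.k2, logit);
      cc.Ms = 1.0f / (1.0f + arma::exp(-arma::vectorise(logit)));
      cc.G2t = Fpt;
      cc.G2t.each_col() %= cc.Ms;
      cc.G2t += cc.Gt;
    } else {
      cc.G2t = cc.Gt;
    }
    // ---- spatial convolution ----
    if (c.use_sconv) {
      fmat W2(cc.G2t.memptr(), c.Tc, c.C * c.f_in, false, true);
      cc.Ut = W2 * B;                      // Tc x F2
      cc.Ut.each_row() += p.sc_b.col(0).t();
    } else {
      cc.Ut = cc.G2t;                      // (C*Tc) x f_in
    }
    bn_sum += arma::sum(cc.Ut, 0).t();
    bn_sumsq += arma::sum(cc.Ut % cc.Ut, 0).t();
  }

  // ---- batch normalization over the whole batch ----
  const float bn_eps = 1e-5f;
  float count = (float)head_rows * N;
  if (training) {
    bc.mu = bn_sum / count;
    fvec v = bn_sumsq / count - bc.mu % bc.mu;
    v = arma::clamp(v, 0.0f, arma::datum::inf);
    bc.invstd = 1.0f / arma::sqrt(v + bn_eps);
    const float mom = 0.1f;
    run_mean = (1.0f - mom) * run_mean + mom * bc.mu;
    run_var = (1.0f - mom) * run_var + mom * v;
  } else {
    bc.mu = run_mean;
    bc.invstd = 1.0f / arma::sqrt(run_var + bn_eps);
  }
  frowvec mu_row = bc.mu.t(), invstd_row = bc.invstd.t();

  // ---- head: square, pool, dropout, safe log, classifier ----
  bc.logits.set_size(c.M, N);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const float keep = 1.0f - (float)c.dropout;
  for (int n = 0; n < N; ++n) {
    Cache& cc = bc.s[n];
    cc.xhat = cc.Ut;
    cc.xhat.each_row() -= mu_row;
    cc.xhat.each_row() %= invstd_row;
    fmat y2 = cc.xhat;
    if (c.bn_affine) {
      y2.each_row() %= p.bn_gamma.col(0).t();
      y2.each_row() += p.bn_beta.col(0).t();
    }
    if (c.square) y2 %= y2;
    cc.pooled.set_size(c.c2 * c.pooled, c.f_out);
    for (int ch = 0; ch < c.c2; ++ch)
      for (int j = 0; j < c.pooled; ++j) {
        int r0 = ch * c.Tc + j * c.stride;
        cc.pooled.row(ch * c.pooled + j) =
          arma::mean(y2.rows(r0, r0 + c.pool - 1), 0);
      }
    if (training && c.dropout > 0) {
      cc.mask.set_size(c.c2 * c.pooled, c.f_out);
      for (uword i = 0; i < cc.mask.n_elem; ++i)
        cc.mask(i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
      cc.pooled %= cc.mask;
    }
    cc.zfeat = arma::log(arma::clamp(cc.pooled, (float)c.log_eps,
                                     arma::datum::inf));
    fvec flat(c.feat_dim);
    for (int f = 0; f < c.f_out; ++f)
      for (int q = 0; q < c.c2 * c.pooled; ++q)
        flat[f * c.c2 * c.pooled + q] = cc.zfeat(q, f);
    bc.logits.col(n) = p.cl_w * flat + p.cl_b.col(0);
  }
  bc.probs = bc.logits;
  bc.probs.each_row() -= arma::max(bc.probs, 0);
  bc.probs = arma::exp(bc.probs);
  bc.probs.each_row() /= arma::sum(bc.probs, 0);
}

// Backward; fills grads (same structure as Params).  y: 0-based labels.
double backward_batch(const Config& c, const Params& p,
                      const std::vector<fmat>& X, const arma::ivec& y,
                      BatchCache& bc, Params& g) {
  int N = X.size();
  int HW = c.C * c.Tc;
  const float invsqd = 1.0f / std::sqrt((float)c.C);

  double loss = 0.0;
  fmat dlogits = bc.probs;   // M x N
  for (int n = 0; n < N; ++n) {
    loss -= std::log(std::max((double)bc.probs(y[n], n), 1e-12));
    dlogits(y[n], n) -= 1.0f;
  }
  loss /= N;
  dlogits /= (float)N;

  for (auto* m : g.all) m->zeros();

  fmat B, dB;
  if (c.use_sconv) {
    B = sconv_B(p.sc_w, c.C, c.f_in);
    dB.zeros(B.n_rows, B.n_cols);
  }
  frowvec gamma_row, beta_row;
  if (c.bn_affine) {
    gamma_row = p.bn_gamma.col(0).t();
    beta_row = p.bn_beta.col(0).t();
  }
  frowvec invstd_row = bc.invstd.t();

  // BN backward needs batch-wide means of dxhat and dxhat*xhat; first pass
  // computes per-slice head backward down to dxhat.
  std::vector<fmat> dxhat(N);
  fvec sum_d(c.f_out, arma::fill::zeros), sum_dx(c.f_out, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    Cache& cc = bc.s[n];
    fvec flat(c.feat_dim);
    for (int f = 0; f < c.f_out; ++f)
      for (int q = 0; q < c.c2 * c.pooled; ++q)
        flat[f * c.c2 * c.pooled + q] = cc.zfeat(q, f);
    g.cl_w += dlogits.col(n) * flat.t();
    g.cl_b.col(0) += dlogits.col(n);
    fvec dflat = p.cl_w.t() * dlogits.col(n);
    fmat dpool(c.c2 * c.pooled, c.f_out);
    for (int f = 0; f < c.f_out; ++f)
      for (int q = 0; q < c.c2 * c.pooled; ++q)
        dpool(q, f) = cc.pooled(q, f) > (float)c.log_eps
          ? dflat[f * c.c2 * c.pooled + q] / cc.pooled(q, f) : 0.0f;
    if (cc.mask.n_elem) dpool %= cc.mask;
    fmat dy2(c.c2 * c.Tc, c.f_out, arma::fill::zeros);
    for (int ch = 0; ch < c.c2; ++ch)
      for (int j = 0; j < c.pooled; ++j) {
        int r0 = ch * c.Tc + j * c.stride;
        dy2.rows(r0, r0 + c.pool - 1).each_row() +=
          dpool.row(ch * c.pooled + j) / (float)c.pool;
      }
    if (c.square) {
      fmat y2 = cc.xhat;
      if (c.bn_affine) {
        y2.each_row() %= gamma_row;
        y2.each_row() += beta_row;
      }
      dy2 %= 2.0f * y2;
    }
    if (c.bn_affine) {
      g.bn_gamma.col(0) += arma::sum(dy2 % cc.xhat, 0).t();
      g.bn_beta.col(0) += arma::sum(dy2, 0).t();
      dy2.each_row() %= gamma_row;
    }
    sum_d += arma::sum(dy2, 0).t();
    sum_dx += arma::sum(dy2 % cc.xhat, 0).t();
    dxhat[n] = std::move(dy2);
  }
  float count = (float)(c.c2 * c.Tc) * N;
  frowvec mean_d = (sum_d / count).t();
  frowvec mean_dx = (sum_dx / count).t();

  for (int n = 0; n < N; ++n) {
    Cache& cc = bc.s[n];
    // BN backward (batch statistics)
    fmat dU = dxhat[n];
    dU.each_row() -= mean_d;
    fmat tmp = cc.xhat;
    tmp.each_row() %= mean_dx;
    dU -= tmp;
    dU.each_row() %= invstd_row;

    fmat dG2t;
    if (c.use_sconv) {
      fmat W2(cc.G2t.memptr(), c.Tc, c.C * c.f_in, false, true);
      dB += W2.t() * dU;
      g.sc_b.col(0) += arma::sum(dU, 0).t();
      fmat dW2 = dU * B.t();               // Tc x (C*f_in)
      dG2t = fmat(dW2.memptr(), HW, c.f_in);  // zero-copy reinterpret
    } else {
      dG2t = dU;
    }

    fmat dGt;
    if (c.branch == 2) {
      frowvec mc_row = cc.Mc.t();
      fmat Fpt = cc.Gt;
      Fpt.each_row() %= mc_row;            // recompute channel-gated maps
      dGt = dG2t;                          // skip connection
      // spatial gate backward
      fvec dMs = arma::sum(dG2t % Fpt, 1);
      fmat dFpt = dG2t;
      dFpt.each_col() %= cc.Ms;
      fvec dl = dMs % cc.Ms % (1.0f - cc.Ms);
      fmat img_a(cc.cm.memptr(), c.Tc, c.C, false, true);
      fmat img_m(cc.cx.memptr(), c.Tc, c.C, false, true);
      fmat dlogit(dl.memptr(), c.Tc, c.C, false, true);
      fmat dimg_a, dimg_m;
      float gb = 0.0f;
      sa_conv_backward(img_a, img_m, p.sa_w, c.k2, dlogit, g.sa_w, gb,
                       dimg_a, dimg_m);
      g.sa_b(0, 0) += gb;
      fvec dcm(dimg_a.memptr(), HW);
      fvec dcx(dimg_m.memptr(), HW);
      dFpt.each_col() += dcm / (float)c.F1;
      for (int r = 0; r < HW; ++r) dFpt(r, cc.cx_idx[r]) += dcx[r];
      // channel gate backward
      fvec dMc = arma::sum(dFpt % cc.Gt, 0).t();
      fmat dG_fp = dFpt;
      dG_fp.each_row() %= mc_row;
      dGt += dG_fp;
      fvec ds = dMc % cc.Mc % (1.0f - cc.Mc);
      g.ca_w1 += ds * cc.ha.t() + ds * cc.hm.t();
      g.ca_b1.col(0) += 2.0f * ds;
      fvec dha = p.ca_w1.t() * ds;
      fvec dza = dha % arma::conv_to<fvec>::from(cc.za > 0);
      fvec dzm = dha % arma::conv_to<fvec>::from(cc.zm > 0);
      g.ca_w0 += dza * cc.avg.t() + dzm * cc.mx.t();
      g.ca_b0.col(0) += dza + dzm;
      fvec davg = p.ca_w0.t() * dza;
      fvec dmx = p.ca_w0.t() * dzm;
      dGt.each_row() += (davg / (float)HW).t();
      for (int m = 0; m < c.F1; ++m) dGt(cc.mx_idx[m], m) += dmx[m];
    } else {
      dGt = dG2t;
    }

    // temporal conv backward
    fmat dYt;
    if (c.use_tconv) {
      fmat Mcol;
      tconv_im2col(cc.Yt, c.k1, c.Tc, Mcol);
      g.tc_w += dGt.t() * Mcol;
      g.tc_b.col(0) += arma::sum(dGt, 0).t();
      fmat dMcol = dGt * p.tc_w;           // (C*Tc) x k1
      dYt.zeros(c.T, c.C);
      for (int j = 0; j < c.k1; ++j) {
        const float* src = dMcol.colptr(j);
        for (int ch = 0; ch < c.C; ++ch) {
          float* dst = dYt.colptr(ch) + j;
          const float* s2 = src + ch * c.Tc;
          for (int t = 0; t < c.Tc; ++t) dst[t] += s2[t];
        }
      }
    } else {
      dYt.set_size(c.T, c.C);
      for (int ch = 0; ch < c.C; ++ch)
        std::memcpy(dYt.colptr(ch), dGt.colptr(0) + ch * c.T,
                    c.T * sizeof(float));
    }

    // attention backward (parameter gradients only; input grads unused)
    if (c.branch >= 1) {
      fmat dA = dYt * cc.V.t();
      fmat dV = cc.A.t() * dYt;
      fmat dS = dA;
      for (uword r = 0; r < dS.n_rows; ++r) {
        float dot = arma::dot(dA.row(r), cc.A.row(r));
        dS.row(r) = (dA.row(r) - dot) % cc.A.row(r);
      }
      fmat dQ = (dS * cc.K) * invsqd;
      fmat dK = (dS.t() * cc.Q) * invsqd;
      g.Wq += dQ.t() * cc.Xt;
      g.Wk += dK.t() * cc.Xt;
      if (c.value_proj) g.Wv += dV.t() * cc.Xt;
    }
  }
  if (c.use_sconv) sconv_B_back(g.sc_w, dB, c.C, c.f_in);
  return loss;
}

std::vector<fmat> slices_from_R(const NumericVector& x, int C, int T) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3 || dim[1] != C || dim[2] != T)
    stop("input array must be N x C x T matching the configuration");
  int N = dim[0];
  std::vector<fmat> out(N, fmat(C, T));
  for (int t = 0; t < T; ++t)
    for (int ch = 0; ch < C; ++ch)
      for (int n = 0; n < N; ++n)
        out[n](ch, t) = (float)x[n + (R_xlen_t)N * (ch + (R_xlen_t)C * t)];
  return out;
}

fvec bn_vec(const List& bn, const char* nm, int f_out) {
  NumericVector v = bn[nm];
  if ((int)v.size() != f_out) stop("bn `%s` has wrong length", nm);
  fvec out(f_out);
  for (int i = 0; i < f_out; ++i) out[i] = (float)v[i];
  return out;
}

List bn_to_list(const fvec& mean, const fvec& var) {
  return List::create(Named("mean") = NumericVector(mean.begin(), mean.end()),
                      Named("var") = NumericVector(var.begin(), var.end()));
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forward(List params, List cfg, NumericVector x, List bn) {
  Config c = parse_cfg(cfg);
  Params p = parse_params(params, c);
  std::vector<fmat> X = slices_from_R(x, c.C, c.T);
  fvec rm = bn_vec(bn, "mean", c.f_out), rv = bn_vec(bn, "var", c.f_out);
  std::mt19937 rng(0);
  BatchCache bc;
  forward_batch(c, p, X, false, rm, rv, rng, bc);
  NumericMatrix out(X.size(), c.M);
  for (size_t n = 0; n < X.size(); ++n)
    for (int m = 0; m < c.M; ++m) out(n, m) = bc.logits(m, n);
  return out;
}

// [[Rcpp::export]]
List cpp_grads(List params, List cfg, NumericVector x, IntegerVector y,
               List bn, bool training = true) {
  Config c = parse_cfg(cfg);
  Params p = parse_params(params, c);
  std::vector<fmat> X = slices_from_R(x, c.C, c.T);
  fvec rm = bn_vec(bn, "mean", c.f_out), rv = bn_vec(bn, "var", c.f_out);
  std::mt19937 rng(12345);
  BatchCache bc;
  Config c2 = c;
  c2.dropout = 0.0;                     // deterministic gradients
  forward_batch(c2, p, X, training, rm, rv, rng, bc);
  arma::ivec yy(X.size());
  for (size_t n = 0; n < X.size(); ++n) yy[n] = y[n];
  Params g;
  g.collect(c);
  for (size_t i = 0; i < g.all.size(); ++i)
    g.all[i]->set_size(p.all[i]->n_rows, p.all[i]->n_cols);
  double loss = backward_batch(c2, p, X, yy, bc, g);
  List out = params_to_list(g);
  out.attr("loss") = loss;
  return out;
}

// [[Rcpp::export]]
List cpp_train(List params, List cfg, NumericVector x, IntegerVector y,
               List tcfg, List bn) {
  Config c = parse_cfg(cfg);
  Params p = parse_params(params, c);
  std::vector<fmat> X = slices_from_R(x, c.C, c.T);
  int N = X.size();
  if ((int)y.size() != N) stop("labels must match the sample count");

  double lr = as<double>(tcfg["lr"]);
  int epochs = as<int>(tcfg["epochs"]);
  int batch = as<int>(tcfg["batch_size"]);
  double ema_decay = as<double>(tcfg["ema_decay"]);
  int seed = as<int>(tcfg["seed"]);
  bool cosine = as<bool>(tcfg["cosine"]);

  fvec rm = bn_vec(bn, "mean", c.f_out), rv = bn_vec(bn, "var", c.f_out);
  std::mt19937 rng(seed);

  size_t np = p.all.size();
  std::vector<fmat> m(np), v(np), ema(np);
  for (size_t i = 0; i < np; ++i) {
    m[i].zeros(p.all[i]->n_rows, p.all[i]->n_cols);
    v[i].zeros(p.all[i]->n_rows, p.all[i]->n_cols);
    ema[i].zeros(p.all[i]->n_rows, p.all[i]->n_cols);
  }
  Params g;
  g.collect(c);
  for (size_t i = 0; i < np; ++i)
    g.all[i]->set_size(p.all[i]->n_rows, p.all[i]->n_cols);

  const float b1 = 0.9f, b2 = 0.999f, adam_eps = 1e-8f;
  long step = 0;
  NumericVector history(epochs);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int e = 0; e < epochs; ++e) {
    float lr_e = cosine
      ? (float)(0.5 * lr * (1.0 + std::cos(M_PI * (double)e / epochs)))
      : (float)lr;
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < N; start += batch) {
      int nb = std::min(batch, N - start);
      std::vector<fmat> Xb(nb);
      arma::ivec yb(nb);
      for (int i = 0; i < nb; ++i) {
        Xb[i] = X[order[start + i]];
        yb[i] = y[order[start + i]];
      }
      BatchCache bc;
      forward_batch(c, p, Xb, true, rm, rv, rng, bc);
      double loss = backward_batch(c, p, Xb, yb, bc, g);
      if (!std::isfinite(loss))
        stop("training diverged: non-finite loss at epoch %d", e + 1);
      ++step;
      float bc1 = 1.0f - std::pow(b1, (float)step);
      float bc2 = 1.0f - std::pow(b2, (float)step);
      for (size_t i = 0; i < np; ++i) {
        m[i] = b1 * m[i] + (1.0f - b1) * (*g.all[i]);
        v[i] = b2 * v[i] + (1.0f - b2) * arma::square(*g.all[i]);
        *p.all[i] -= lr_e * (m[i] / bc1) /
          (arma::sqrt(v[i] / bc2) + adam_eps);
        ema[i] = (float)ema_decay * ema[i] +
          (1.0f - (float)ema_decay) * (*p.all[i]);
      }
      epoch_loss += loss;
      ++n_batches;
    }
    history[e] = epoch_loss / std::max(n_batches, 1);
    if (e % 8 == 0) Rcpp::checkUserInterrupt();
  }

  // bias-corrected EMA (zero-debias): ema / (1 - decay^step)
  Params pe;
  pe.collect(c);
  double corr = 1.0 - std::pow(ema_decay, (double)step);
  if (corr <= 0) corr = 1.0;
  for (size_t i = 0; i < np; ++i)
    *pe.all[i] = ema[i] / (float)corr;

  return List::create(
    Named("params") = params_to_list(p),
    Named("ema") = params_to_list(pe),
    Named("bn") = bn_to_list(rm, rv),
    Named("history") = history);
}
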