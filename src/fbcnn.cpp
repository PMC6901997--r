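// Core numerical routines for the multiscale filter-bank CNN.
//
// Layout conventions (all column-major, doubles):
//   input batch  X : cube (C, T, B)          one EEG trial per slice
//   temporal out Y : cube (FT4, C*T, B)      column index ct = c + C*t, so a
//                                            slice viewed as a (FT4*C x T)
//                                            matrix is the input of the
//                                            spatial convolution for free
//   spatial  out Z : cube (FS, T, B)
//   pooled   out P : cube (FS, L, B)         L = floor((T-pool)/stride)+1
//
// Batch norm uses batch statistics in the training step and running
// statistics at inference; running stats follow the usual
// new = (1-mom)*old + mom*batch convention with unbiased batch variance.

#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

struct Net {
  int C, T, FT, nb, FT4, FS, NC, pool, stride, L;
  double bn_eps, bn_mom, p_floor;
  std::vector<int> ker;
  std::vector<mat> Wt;
  vec g1, b1, g2, b2, bc;
  mat Ws, Wc;
  vec m1, v1, m2, v2;
};

static Net unpack(const List& par, const List& buf, const List& cfg) {
  Net n;
  n.C = as<int>(cfg["C"]);     n.T = as<int>(cfg["T"]);
  n.FT = as<int>(cfg["F_T"]);  n.FS = as<int>(cfg["F_S"]);
  n.NC = as<int>(cfg["N_C"]);
  n.pool = as<int>(cfg["pool_length"]);
  n.stride = as<int>(cfg["pool_stride"]);
  n.bn_eps = as<double>(cfg["bn_eps"]);
  n.bn_mom = as<double>(cfg["bn_momentum"]);
  n.p_floor = as<double>(cfg["power_floor"]);
  IntegerVector k = cfg["temporal_kernel_lengths"];
  n.nb = k.size();
  for (int i = 0; i < n.nb; ++i) n.ker.push_back(k[i]);
  n.FT4 = n.nb * n.FT;
  n.L = (n.T - n.pool) / n.stride + 1;
  List Wt = par["Wt"];
  for (int i = 0; i < n.nb; ++i) n.Wt.push_back(as<mat>(Wt[i]));
  n.g1 = as<vec>(par["g1"]); n.b1 = as<vec>(par["b1"]);
  n.Ws = as<mat>(par["Ws"]);
  n.g2 = as<vec>(par["g2"]); n.b2 = as<vec>(par["b2"]);
  n.Wc = as<mat>(par["Wc"]); n.bc = as<vec>(par["bc"]);
  n.m1 = as<vec>(buf["m1"]); n.v1 = as<vec>(buf["v1"]);
  n.m2 = as<vec>(buf["m2"]); n.v2 = as<vec>(buf["v2"]);
  return n;
}

// im2col along time with "same" zero padding: column j holds the input
// shifted so that out(t) = sum_j W(j) * col_j(t); pad_left = floor((k-1)/2).
static mat xcol_same(const mat& X, int k) {
  const int C = X.n_rows, T = X.n_cols, CT = C * T;
  const int pl = (k - 1) / 2;
  mat Xp(C, T + k - 1, fill::zeros);
  Xp.cols(pl, pl + T - 1) = X;
  mat out(CT, k);
  for (int j = 0; j < k; ++j)
    std::memcpy(out.colptr(j), Xp.colptr(j), sizeof(double) * CT);
  return out;
}

// the im2col of the longest kernel contains every shorter kernel's columns:
// kernel k with pad (k-1)/2 needs shifts -(k-1)/2 .. k-1-(k-1)/2, a
// contiguous column range of the widest one
static int kernel_max(const Net& n) {
  return *std::max_element(n.ker.begin(), n.ker.end());
}

// temporal filter bank for one trial, written into a (FT4 x C*T) slice
static void temporal_forward(const Net& n, const mat& Xb, double* ys) {
  const int CT = n.C * n.T;
  const int kmax = kernel_max(n), plK = (kmax - 1) / 2;
  mat xc = xcol_same(Xb, kmax);
  mat Ys(ys, n.FT4, CT, false, true);
  for (int i = 0; i < n.nb; ++i) {
    const int k = n.ker[i], off = plK - (k - 1) / 2;
    mat G = xc.cols(off, off + k - 1) * n.Wt[i].t();   // (CT x FT)
    Ys.rows(i * n.FT, (i + 1) * n.FT - 1) = G.t();
  }
}

// square -> average pool forward for one slice: P(s,l) = mean_t z(s,t)^2
static void pool_forward(const Net& n, const mat& Zb, mat& Pb) {
  for (int l = 0; l < n.L; ++l) {
    const int t0 = l * n.stride;
    vec acc(n.FS, fill::zeros);
    for (int t = t0; t < t0 + n.pool; ++t) acc += square(Zb.col(t));
    Pb.col(l) = acc / n.pool;
  }
}

// [[Rcpp::export]]
List cpp_fbcnn_step(const arma::cube& X, const arma::ivec& y,
                    List par, List buf, List cfg, double dropout_p) {
  Net n = unpack(par, buf, cfg);
  const int B = X.n_slices, CT = n.C * n.T;
  const size_t N1 = (size_t)CT * B, N2 = (size_t)n.T * B;

  cube Y(n.FT4, CT, B);
  for (int b = 0; b < B; ++b)
    temporal_forward(n, X.slice(b), Y.slice_memptr(b));

  // batch norm 1 over (c, t, b) per feature map
  mat Ym(Y.memptr(), n.FT4, N1, false, true);
  vec mu1 = mean(Ym, 1);
  vec var1 = mean(square(Ym), 1) - square(mu1);
  var1.transform([](double v) { return v < 0 ? 0 : v; });
  vec istd1 = 1.0 / sqrt(var1 + n.bn_eps);

  cube Ybn(n.FT4, CT, B);
  {
    mat Bm(Ybn.memptr(), n.FT4, N1, false, true);
    vec a = n.g1 % istd1, c = n.b1 - n.g1 % istd1 % mu1;
    const double* src = Ym.memptr(); double* dst = Bm.memptr();
    for (size_t j = 0; j < N1; ++j) {
      const double* av = a.memptr(); const double* cv = c.memptr();
      for (int f = 0; f < n.FT4; ++f) *dst++ = av[f] * (*src++) + cv[f];
    }
  }

  // spatial convolution: slice viewed as (FT4*C x T)
  const int R = n.FT4 * n.C;
  cube Z(n.FS, n.T, B);
  for (int b = 0; b < B; ++b) {
    mat Yb(Ybn.slice_memptr(b), R, n.T, false, true);
    Z.slice(b) = n.Ws * Yb;
  }

  // batch norm 2 over (t, b) per spatial filter
  mat Zm(Z.memptr(), n.FS, N2, false, true);
  vec mu2 = mean(Zm, 1);
  vec var2 = mean(square(Zm), 1) - square(mu2);
  var2.transform([](double v) { return v < 0 ? 0 : v; });
  vec istd2 = 1.0 / sqrt(var2 + n.bn_eps);
  cube Zbn(n.FS, n.T, B);
  {
    mat Bm(Zbn.memptr(), n.FS, N2, false, true);
    Bm = Zm;
    Bm.each_col() -= mu2;
    Bm.each_col() %= (n.g2 % istd2);
    Bm.each_col() += n.b2;
  }

  // square -> average pool -> log (floored) -> inverted dropout
  cube P(n.FS, n.L, B), D(n.FS, n.L, B), mask(n.FS, n.L, B);
  const double keep = 1.0 - dropout_p;
  for (int b = 0; b < B; ++b) {
    mat Pb(n.FS, n.L);
    pool_forward(n, Zbn.slice(b), Pb);
    P.slice(b) = Pb;
    for (int l = 0; l < n.L; ++l)
      for (int s = 0; s < n.FS; ++s) {
        double m = (dropout_p > 0 && R::unif_rand() < dropout_p) ? 0.0 : 1.0 / keep;
        mask(s, l, b) = m;
        D(s, l, b) = m * std::log(std::max(Pb(s, l), n.p_floor));
      }
  }

  // classifier + log-softmax + mean NLL
  mat Dm(D.memptr(), n.FS * n.L, B, false, true);
  mat logits = n.Wc * Dm;
  logits.each_col() += n.bc;
  mat lp(n.NC, B);
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    vec col = logits.col(b);
    double mx = col.max();
    double lse = mx + std::log(accu(exp(col - mx)));
    lp.col(b) = col - lse;
    loss -= lp(y(b), b);
  }
  loss /= B;

  // ---- backward ----
  mat dlogits = exp(lp);
  for (int b = 0; b < B; ++b) dlogits(y(b), b) -= 1.0;
  dlogits /= B;

  mat gWc = dlogits * Dm.t();
  vec gbc = sum(dlogits, 1);
  mat dD = n.Wc.t() * dlogits;           // (FS*L x B)

  // dropout, log, pool-of-squares backward -> dZbn (reuse storage of Zbn? keep)
  cube dZ(n.FS, n.T, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < n.L; ++l) {
      const int t0 = l * n.stride;
      for (int s = 0; s < n.FS; ++s) {
        double p = P(s, l, b);
        double dlogp = dD((size_t)l * n.FS + s, b) * mask(s, l, b);
        double dp = (p > n.p_floor) ? dlogp / p : 0.0;
        if (dp != 0.0) {
          const double c2 = 2.0 * dp / n.pool;
          for (int t = t0; t < t0 + n.pool; ++t)
            dZ(s, t, b) += c2 * Zbn(s, t, b);
        }
      }
    }
  }

  // batch norm 2 backward (input Z, output Zbn); overwrite dZ with dZpre
  mat dZm(dZ.memptr(), n.FS, N2, false, true);
  vec Sdy2 = sum(dZm, 1);
  vec Sdyx2(n.FS, fill::zeros);
  {
    const double* zp = Zm.memptr(); const double* dp_ = dZm.memptr();
    for (size_t j = 0; j < N2; ++j)
      for (int s = 0; s < n.FS; ++s) {
        double xh = (*zp++ - mu2(s)) * istd2(s);
        Sdyx2(s) += (*dp_++) * xh;
      }
  }
  vec gg2 = Sdyx2, gb2 = Sdy2;
  {
    double* dp_ = dZm.memptr(); const double* zp = Zm.memptr();
    vec a = n.g2;
    vec c1 = (n.g2 % Sdy2) / (double)N2;
    vec c2 = (n.g2 % Sdyx2) / (double)N2;
    for (size_t j = 0; j < N2; ++j)
      for (int s = 0; s < n.FS; ++s) {
        double xh = (*zp++ - mu2(s)) * istd2(s);
        *dp_ = istd2(s) * (a(s) * (*dp_) - c1(s) - xh * c2(s));
        ++dp_;
      }
  }

  // spatial conv backward; reuse Ybn as dYbn storage
  mat gWs(n.FS, R, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat Yb(Ybn.slice_memptr(b), R, n.T, false, true);
    gWs += dZ.slice(b) * Yb.t();
    Yb = n.Ws.t() * dZ.slice(b);
  }

  // batch norm 1 backward; Ybn now holds dYbn, Y holds pre-norm input
  mat dBm(Ybn.memptr(), n.FT4, N1, false, true);
  vec Sdy1 = sum(dBm, 1);
  vec Sdyx1(n.FT4, fill::zeros);
  {
    const double* yp = Ym.memptr(); const double* dp_ = dBm.memptr();
    for (size_t j = 0; j < N1; ++j)
      for (int f = 0; f < n.FT4; ++f) {
        double xh = (*yp++ - mu1(f)) * istd1(f);
        Sdyx1(f) += (*dp_++) * xh;
      }
  }
  vec gg1 = Sdyx1, gb1 = Sdy1;
  {
    double* dp_ = dBm.memptr(); const double* yp = Ym.memptr();
    vec a = n.g1;
    vec c1 = (n.g1 % Sdy1) / (double)N1;
    vec c2 = (n.g1 % Sdyx1) / (double)N1;
    for (size_t j = 0; j < N1; ++j)
      for (int f = 0; f < n.FT4; ++f) {
        double xh = (*yp++ - mu1(f)) * istd1(f);
        *dp_ = istd1(f) * (a(f) * (*dp_) - c1(f) - xh * c2(f));
        ++dp_;
      }
  }

  // temporal conv backward: per-branch row block against the shared im2col
  std::vector<mat> gWt;
  for (int i = 0; i < n.nb; ++i) gWt.push_back(mat(n.FT, n.ker[i], fill::zeros));
  const int kmax = kernel_max(n), plK = (kmax - 1) / 2;
  for (int b = 0; b < B; ++b) {
    mat dYs(Ybn.slice_memptr(b), n.FT4, CT, false, true);
    mat xc = xcol_same(X.slice(b), kmax);
    for (int i = 0; i < n.nb; ++i) {
      const int k = n.ker[i], off = plK - (k - 1) / 2;
      mat G = dYs.rows(i * n.FT, (i + 1) * n.FT - 1);   // (FT x CT)
      gWt[i] += G * xc.cols(off, off + k - 1);
    }
  }

  // running statistics (unbiased batch variance)
  double ub1 = (double)N1 / std::max<double>(1.0, (double)N1 - 1);
  double ub2 = (double)N2 / std::max<double>(1.0, (double)N2 - 1);
  vec m1n = (1 - n.bn_mom) * n.m1 + n.bn_mom * mu1;
  vec v1n = (1 - n.bn_mom) * n.v1 + n.bn_mom * (var1 * ub1);
  vec m2n = (1 - n.bn_mom) * n.m2 + n.bn_mom * mu2;
  vec v2n = (1 - n.bn_mom) * n.v2 + n.bn_mom * (var2 * ub2);

  List gWtL(n.nb);
  for (int i = 0; i < n.nb; ++i) gWtL[i] = gWt[i];
  return List::create(
    _["loss"] = loss,
    _["logp"] = lp.t(),
    _["grads"] = List::create(_["Wt"] = gWtL, _["g1"] = gg1, _["b1"] = gb1,
                              _["Ws"] = gWs, _["g2"] = gg2, _["b2"] = gb2,
                              _["Wc"] = gWc, _["bc"] = gbc),
    _["buffers"] = List::create(_["m1"] = m1n, _["v1"] = v1n,
                                _["m2"] = m2n, _["v2"] = v2n));
}

// [[Rcpp::export]]
List cpp_fbcnn_infer(const arma::cube& X, List par, List buf, List cfg,
                     bool acts = false) {
  Net n = unpack(par, buf, cfg);
  const int B = X.n_slices, CT = n.C * n.T, R = n.FT4 * n.C;
  vec istd1 = 1.0 / sqrt(n.v1 + n.bn_eps);
  vec istd2 = 1.0 / sqrt(n.v2 + n.bn_eps);
  vec a1 = n.g1 % istd1, c1 = n.b1 - a1 % n.m1;
  vec a2 = n.g2 % istd2, c2 = n.b2 - a2 % n.m2;
  mat lp(n.NC, B);
  List act_out;
  for (int b = 0; b < B; ++b) {
    cube Y(n.FT4, CT, 1);
    temporal_forward(n, X.slice(b), Y.slice_memptr(0));
    mat Ybn(n.FT4, CT);
    {
      const double* src = Y.memptr(); double* dst = Ybn.memptr();
      for (int j = 0; j < CT; ++j)
        for (int f = 0; f < n.FT4; ++f) *dst++ = a1(f) * (*src++) + c1(f);
    }
    mat Yb(Ybn.memptr(), R, n.T, false, true);
    mat Z = n.Ws * Yb;
    mat Zbn = Z;
    Zbn.each_col() %= a2;
    Zbn.each_col() += c2;
    mat P(n.FS, n.L);
    pool_forward(n, Zbn, P);
    mat logP = log(clamp(P, n.p_floor, datum::inf));
    vec d(logP.memptr(), n.FS * n.L);
    vec logits = n.Wc * d + n.bc;
    double mx = logits.max();
    double lse = mx + std::log(accu(exp(logits - mx)));
    lp.col(b) = logits - lse;
    if (acts && b == 0)
      act_out = List::create(_["temporal"] = mat(Y.slice_memptr(0), n.FT4, CT),
                             _["temporal_bn"] = Ybn,
                             _["spatial"] = Z, _["spatial_bn"] = Zbn,
                             _["pooled"] = P, _["log_pooled"] = logP);
  }
  if (acts) return List::create(_["logp"] = lp.t(), _["acts"] = act_out);
  return List::create(_["logp"] = lp.t());
}
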