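// Compact convolutional networks for multichannel EEG windows.
//
// Two variants share one trunk and differ only in the first learnable
// layer, which is the experimental contrast of interest:
//   * spatial-first: layer 1 is a full-channel spatial convolution
//     (kernel spanning all input channels, temporal extent 1), so the
//     network learns spatial filters before any temporal filtering;
//   * temporal-first ("standard"): layer 1 is a depthwise temporal
//     convolution (spatial extent 1), so no cross-channel mixing happens
//     in layer 1.
// Trunk: two temporal convolution blocks (convolution, batch
// normalization, ELU, average pooling, dropout), flatten, dense softmax.
// Training: minibatch Adam on categorical cross-entropy with
// early stopping on validation accuracy.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Arch {
  int type;            // 0 = spatial-first, 1 = temporal-first (depthwise)
  int dw_trunk;        // 1 = trunk convolutions are per-map (no mixing)
  int C, T, K;
  int F1, L1;          // layer-1 maps and temporal kernel length
  int F2, L2, F3, L3;  // trunk conv maps / kernel lengths
  int p1, p2, p3;      // average-pool widths
  double dropout;
  int T1, T2, T3, feat;
};

static Arch arch_from_list(const Rcpp::List& a) {
  Arch r;
  r.type = a["type"]; r.C = a["channels"]; r.T = a["samples"]; r.K = a["n_classes"];
  r.dw_trunk = a["dw_trunk"];
  r.F1 = a["F1"]; r.L1 = a["L1"];
  r.F2 = a["F2"]; r.L2 = a["L2"]; r.F3 = a["F3"]; r.L3 = a["L3"];
  r.p1 = a["p1"]; r.p2 = a["p2"]; r.p3 = a["p3"];
  r.dropout = a["dropout"];
  if (r.dw_trunk && (r.F2 != r.F1 || r.F3 != r.F1))
    Rcpp::stop("a per-map trunk keeps the map count: F2 = F3 = F1");
  r.T1 = r.T / r.p1; r.T2 = r.T1 / r.p2; r.T3 = r.T2 / r.p3;
  r.feat = r.F3 * r.T3;
  if (r.T3 < 1) Rcpp::stop("pooling exhausts the time axis");
  if (r.type == 1 && r.F1 % r.C != 0)
    Rcpp::stop("depthwise layer 1 needs F1 to be a multiple of channels");
  return r;
}

struct Net {
  mat W1;              // spatial: F1 x C; depthwise: F1 x L1
  vec b1, g1, be1, rm1, rv1;
  cube W2;             // F1 x L2 x F2
  vec b2, g2, be2, rm2, rv2;
  cube W3;             // F2 x L3 x F3
  vec b3, g3, be3, rm3, rv3;
  mat Wd;              // K x feat
  vec bd;
};

static Net net_zero(const Arch& a) {
  Net n;
  n.W1 = (a.type == 0) ? mat(a.F1, a.C, fill::zeros) : mat(a.F1, a.L1, fill::zeros);
  n.b1 = vec(a.F1, fill::zeros); n.g1 = n.b1; n.be1 = n.b1; n.rm1 = n.b1; n.rv1 = n.b1;
  n.W2 = cube(a.dw_trunk ? 1 : a.F1, a.L2, a.F2, fill::zeros);
  n.b2 = vec(a.F2, fill::zeros); n.g2 = n.b2; n.be2 = n.b2; n.rm2 = n.b2; n.rv2 = n.b2;
  n.W3 = cube(a.dw_trunk ? 1 : a.F2, a.L3, a.F3, fill::zeros);
  n.b3 = vec(a.F3, fill::zeros); n.g3 = n.b3; n.be3 = n.b3; n.rm3 = n.b3; n.rv3 = n.b3;
  n.Wd = mat(a.K, a.feat, fill::zeros);
  n.bd = vec(a.K, fill::zeros);
  return n;
}

static void net_init(Net& n, const Arch& a, std::mt19937& rng) {
  std::normal_distribution<double> N01(0.0, 1.0);
  auto fill_norm = [&](mat& M, double sdv) { for (uword i = 0; i < M.n_elem; ++i) M(i) = sdv * N01(rng); };
  auto fill_cube = [&](cube& Cb, double sdv) { for (uword i = 0; i < Cb.n_elem; ++i) Cb(i) = sdv * N01(rng); };
  n = net_zero(a);
  fill_norm(n.W1, std::sqrt(2.0 / (a.type == 0 ? a.C : a.L1)));
  fill_cube(n.W2, std::sqrt(2.0 / ((a.dw_trunk ? 1 : a.F1) * a.L2)));
  fill_cube(n.W3, std::sqrt(2.0 / ((a.dw_trunk ? 1 : a.F2) * a.L3)));
  fill_norm(n.Wd, std::sqrt(2.0 / a.feat));
  n.g1.ones(); n.g2.ones(); n.g3.ones();
  n.rv1.ones(); n.rv2.ones(); n.rv3.ones();
}

static Rcpp::List net_to_list(const Net& n) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = n.W1, Rcpp::Named("b1") = n.b1,
    Rcpp::Named("g1") = n.g1, Rcpp::Named("be1") = n.be1,
    Rcpp::Named("rm1") = n.rm1, Rcpp::Named("rv1") = n.rv1,
    Rcpp::Named("W2") = n.W2, Rcpp::Named("b2") = n.b2,
    Rcpp::Named("g2") = n.g2, Rcpp::Named("be2") = n.be2,
    Rcpp::Named("rm2") = n.rm2, Rcpp::Named("rv2") = n.rv2,
    Rcpp::Named("W3") = n.W3, Rcpp::Named("b3") = n.b3,
    Rcpp::Named("g3") = n.g3, Rcpp::Named("be3") = n.be3,
    Rcpp::Named("rm3") = n.rm3, Rcpp::Named("rv3") = n.rv3,
    Rcpp::Named("Wd") = n.Wd, Rcpp::Named("bd") = n.bd);
}

static Net net_from_list(const Rcpp::List& p) {
  Net n;
  n.W1 = Rcpp::as<mat>(p["W1"]); n.b1 = Rcpp::as<vec>(p["b1"]);
  n.g1 = Rcpp::as<vec>(p["g1"]); n.be1 = Rcpp::as<vec>(p["be1"]);
  n.rm1 = Rcpp::as<vec>(p["rm1"]); n.rv1 = Rcpp::as<vec>(p["rv1"]);
  n.W2 = Rcpp::as<cube>(p["W2"]); n.b2 = Rcpp::as<vec>(p["b2"]);
  n.g2 = Rcpp::as<vec>(p["g2"]); n.be2 = Rcpp::as<vec>(p["be2"]);
  n.rm2 = Rcpp::as<vec>(p["rm2"]); n.rv2 = Rcpp::as<vec>(p["rv2"]);
  n.W3 = Rcpp::as<cube>(p["W3"]); n.b3 = Rcpp::as<vec>(p["b3"]);
  n.g3 = Rcpp::as<vec>(p["g3"]); n.be3 = Rcpp::as<vec>(p["be3"]);
  n.rm3 = Rcpp::as<vec>(p["rm3"]); n.rv3 = Rcpp::as<vec>(p["rv3"]);
  n.Wd = Rcpp::as<mat>(p["Wd"]); n.bd = Rcpp::as<vec>(p["bd"]);
  return n;
}

// ---- primitive layers ------------------------------------------------

// full-mixing temporal convolution with "same" padding
static mat conv_full(const mat& x, const cube& K, const vec& b) {
  const int Min = x.n_rows, T = x.n_cols, L = K.n_cols, Mout = K.n_slices;
  const int off = L / 2;
  mat y(Mout, T);
  for (int f = 0; f < Mout; ++f) {
    rowvec acc(T, fill::value(b(f)));
    for (int m = 0; m < Min; ++m) {
      const rowvec xr = x.row(m);
      for (int u = 0; u < L; ++u) {
        int t1 = std::max(0, off - u), t2 = std::min(T - 1, T - 1 + off - u);
        if (t1 > t2) continue;
        acc.subvec(t1, t2) += K(m, u, f) * xr.subvec(t1 + u - off, t2 + u - off);
      }
    }
    y.row(f) = acc;
  }
  return y;
}

static void conv_full_bw(const mat& x, const cube& K, const mat& dy,
                         mat& dx, cube& dK, vec& db) {
  const int Min = x.n_rows, T = x.n_cols, L = K.n_cols, Mout = K.n_slices;
  const int off = L / 2;
  for (int f = 0; f < Mout; ++f) {
    db(f) += accu(dy.row(f));
    for (int m = 0; m < Min; ++m) {
      for (int u = 0; u < L; ++u) {
        int t1 = std::max(0, off - u), t2 = std::min(T - 1, T - 1 + off - u);
        if (t1 > t2) continue;
        dK(m, u, f) += dot(dy.row(f).subvec(t1, t2),
                           x.row(m).subvec(t1 + u - off, t2 + u - off));
        dx.row(m).subvec(t1 + u - off, t2 + u - off) += K(m, u, f) * dy.row(f).subvec(t1, t2);
      }
    }
  }
}

// depthwise temporal convolution: map j reads input channel j / k only
static mat conv_dw(const mat& x, const mat& W, const vec& b, int k) {
  const int T = x.n_cols, F1 = W.n_rows, L = W.n_cols;
  const int off = L / 2;
  mat y(F1, T);
  for (int j = 0; j < F1; ++j) {
    const int c = j / k;
    rowvec acc(T, fill::value(b(j)));
    const rowvec xr = x.row(c);
    for (int u = 0; u < L; ++u) {
      int t1 = std::max(0, off - u), t2 = std::min(T - 1, T - 1 + off - u);
      if (t1 > t2) continue;
      acc.subvec(t1, t2) += W(j, u) * xr.subvec(t1 + u - off, t2 + u - off);
    }
    y.row(j) = acc;
  }
  return y;
}

static void conv_dw_bw(const mat& x, const mat& W, const mat& dy, int k,
                       mat& dx, mat& dW, vec& db) {
  const int T = x.n_cols, F1 = W.n_rows, L = W.n_cols;
  const int off = L / 2;
  for (int j = 0; j < F1; ++j) {
    const int c = j / k;
    db(j) += accu(dy.row(j));
    for (int u = 0; u < L; ++u) {
      int t1 = std::max(0, off - u), t2 = std::min(T - 1, T - 1 + off - u);
      if (t1 > t2) continue;
      dW(j, u) += dot(dy.row(j).subvec(t1, t2),
                      x.row(c).subvec(t1 + u - off, t2 + u - off));
      dx.row(c).subvec(t1 + u - off, t2 + u - off) += W(j, u) * dy.row(j).subvec(t1, t2);
    }
  }
}

// per-map temporal convolution (no cross-map mixing): kernel slice m
// filters map m only
static mat conv_pm(const mat& x, const cube& K, const vec& b) {
  const int M = x.n_rows, T = x.n_cols, L = K.n_cols;
  const int off = L / 2;
  mat y(M, T);
  for (int m = 0; m < M; ++m) {
    rowvec acc(T, fill::value(b(m)));
    for (int u = 0; u < L; ++u) {
      int t1 = std::max(0, off - u), t2 = std::min(T - 1, T - 1 + off - u);
      if (t1 > t2) continue;
      acc.subvec(t1, t2) += K(0, u, m) * x.row(m).subvec(t1 + u - off, t2 + u - off);
    }
    y.row(m) = acc;
  }
  return y;
}

static void conv_pm_bw(const mat& x, const cube& K, const mat& dy,
                       mat& dx, cube& dK, vec& db) {
  const int T = x.n_cols, L = K.n_cols, M = x.n_rows;
  const int off = L / 2;
  for (int m = 0; m < M; ++m) {
    db(m) += accu(dy.row(m));
    for (int u = 0; u < L; ++u) {
      int t1 = std::max(0, off - u), t2 = std::min(T - 1, T - 1 + off - u);
      if (t1 > t2) continue;
      dK(0, u, m) += dot(dy.row(m).subvec(t1, t2),
                         x.row(m).subvec(t1 + u - off, t2 + u - off));
      dx.row(m).subvec(t1 + u - off, t2 + u - off) += K(0, u, m) * dy.row(m).subvec(t1, t2);
    }
  }
}

static cube avg_pool(const cube& x, int p) {
  const int M = x.n_rows, T = x.n_cols, B = x.n_slices, To = T / p;
  cube y(M, To, B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < To; ++t)
      y.slice(b).col(t) = mean(x.slice(b).cols(t * p, t * p + p - 1), 1);
  return y;
}

static cube avg_pool_bw(const cube& dy, int p, int T) {
  const int M = dy.n_rows, To = dy.n_cols, B = dy.n_slices;
  cube dx(M, T, B, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < To; ++t)
      for (int i = 0; i < p; ++i)
        dx.slice(b).col(t * p + i) = dy.slice(b).col(t) / p;
  return dx;
}

static cube elu(const cube& x) {
  cube y = x;
  y.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  return y;
}

static cube elu_bw(const cube& y, const cube& dy) {
  cube dx = dy;
  for (uword i = 0; i < y.n_elem; ++i)
    if (y(i) <= 0) dx(i) *= (y(i) + 1.0);
  return dx;
}

struct BnCache { vec mu, var; cube xhat; };

static const double BN_EPS = 1e-5;

// batch norm per map over (time, batch); updates running stats in training
static cube bn_forward(const cube& x, const vec& g, const vec& be,
                       vec& rm, vec& rv, bool training, BnCache* cache) {
  const int M = x.n_rows, T = x.n_cols, B = x.n_slices;
  cube y(M, T, B);
  vec mu(M), var(M);
  if (training) {
    for (int m = 0; m < M; ++m) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const rowvec r = x.slice(b).row(m);
        s += accu(r); s2 += dot(r, r);
      }
      const double n = double(T) * B;
      mu(m) = s / n;
      var(m) = std::max(0.0, s2 / n - mu(m) * mu(m));
    }
    rm = 0.9 * rm + 0.1 * mu;
    rv = 0.9 * rv + 0.1 * var;
  } else { mu = rm; var = rv; }
  cube xhat(M, T, B);
  for (int b = 0; b < B; ++b)
    for (int m = 0; m < M; ++m)
      xhat.slice(b).row(m) = (x.slice(b).row(m) - mu(m)) / std::sqrt(var(m) + BN_EPS);
  for (int b = 0; b < B; ++b)
    for (int m = 0; m < M; ++m)
      y.slice(b).row(m) = g(m) * xhat.slice(b).row(m) + be(m);
  if (cache) { cache->mu = mu; cache->var = var; cache->xhat = xhat; }
  return y;
}

static cube bn_backward(const BnCache& c, const vec& g, const cube& dy,
                        vec& dg, vec& dbe) {
  const int M = dy.n_rows, T = dy.n_cols, B = dy.n_slices;
  const double n = double(T) * B;
  cube dx(M, T, B);
  for (int m = 0; m < M; ++m) {
    double sum_dy = 0, sum_dyxh = 0;
    for (int b = 0; b < B; ++b) {
      sum_dy += accu(dy.slice(b).row(m));
      sum_dyxh += dot(dy.slice(b).row(m), c.xhat.slice(b).row(m));
    }
    dg(m) += sum_dyxh;
    dbe(m) += sum_dy;
    const double isd = 1.0 / std::sqrt(c.var(m) + BN_EPS);
    for (int b = 0; b < B; ++b) {
      dx.slice(b).row(m) = (g(m) * isd / n) *
        (n * dy.slice(b).row(m) - sum_dy - c.xhat.slice(b).row(m) * sum_dyxh);
    }
  }
  return dx;
}

// ---- full forward / backward on a batch ------------------------------

struct Cache {
  cube X;                       // input batch C x T x B
  cube Z1, A1, P1;              // layer 1
  cube Z2, A2, P2, M2;          // block 2 (+ dropout mask)
  cube Z3, A3, P3, M3;          // block 3
  mat F;                        // feat x B
  mat probs;                    // K x B
  BnCache bn1, bn2, bn3;
};

static mat softmax_cols(mat logits) {
  logits.each_row() -= max(logits, 0);
  mat e = exp(logits);
  e.each_row() /= sum(e, 0);
  return e;
}

static void forward(const Net& n, Net* mut, const Arch& a, const cube& X,
                    bool training, std::mt19937* rng, Cache* c) {
  const int B = X.n_slices;
  Net& rs = mut ? *mut : const_cast<Net&>(n);   // running stats live here
  cube Z1(a.F1, a.T, B);
  for (int b = 0; b < B; ++b)
    Z1.slice(b) = (a.type == 0)
      ? (n.W1 * X.slice(b)).eval() + repmat(n.b1, 1, a.T)
      : conv_dw(X.slice(b), n.W1, n.b1, a.F1 / a.C);
  BnCache bc1;
  cube N1 = bn_forward(Z1, n.g1, n.be1, rs.rm1, rs.rv1, training, &bc1);
  cube A1 = elu(N1);
  cube P1 = avg_pool(A1, a.p1);

  cube Z2(a.F2, a.T1, B);
  for (int b = 0; b < B; ++b)
    Z2.slice(b) = a.dw_trunk ? conv_pm(P1.slice(b), n.W2, n.b2)
                             : conv_full(P1.slice(b), n.W2, n.b2);
  BnCache bc2;
  cube N2 = bn_forward(Z2, n.g2, n.be2, rs.rm2, rs.rv2, training, &bc2);
  cube A2 = elu(N2);
  cube P2 = avg_pool(A2, a.p2);
  cube M2;
  if (training && a.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    M2.set_size(size(P2));
    for (uword i = 0; i < M2.n_elem; ++i)
      M2(i) = (U(*rng) < a.dropout) ? 0.0 : 1.0 / (1.0 - a.dropout);
    P2 %= M2;
  }

  cube Z3(a.F3, a.T2, B);
  for (int b = 0; b < B; ++b)
    Z3.slice(b) = a.dw_trunk ? conv_pm(P2.slice(b), n.W3, n.b3)
                             : conv_full(P2.slice(b), n.W3, n.b3);
  BnCache bc3;
  cube N3 = bn_forward(Z3, n.g3, n.be3, rs.rm3, rs.rv3, training, &bc3);
  cube A3 = elu(N3);
  cube P3 = avg_pool(A3, a.p3);
  cube M3;
  if (training && a.dropout > 0) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    M3.set_size(size(P3));
    for (uword i = 0; i < M3.n_elem; ++i)
      M3(i) = (U(*rng) < a.dropout) ? 0.0 : 1.0 / (1.0 - a.dropout);
    P3 %= M3;
  }

  mat F(a.feat, B);
  for (int b = 0; b < B; ++b) F.col(b) = vectorise(P3.slice(b));
  mat logits = n.Wd * F;
  logits.each_col() += n.bd;
  mat probs = softmax_cols(logits);

  if (c) {
    c->X = X; c->Z1 = Z1; c->A1 = A1; c->P1 = P1;
    c->Z2 = Z2; c->A2 = A2; c->P2 = P2; c->M2 = M2;
    c->Z3 = Z3; c->A3 = A3; c->P3 = P3; c->M3 = M3;
    c->F = F; c->probs = probs;
    c->bn1 = bc1; c->bn2 = bc2; c->bn3 = bc3;
  }
}

static double backward(const Net& n, const Arch& a, const Cache& c,
                       const ivec& y, Net& g) {
  const int B = c.X.n_slices;
  // loss and dlogits
  double loss = 0;
  mat dlog = c.probs;
  for (int b = 0; b < B; ++b) {
    loss -= std::log(std::max(c.probs(y(b), b), 1e-12));
    dlog(y(b), b) -= 1.0;
  }
  loss /= B;
  dlog /= B;

  g.Wd += dlog * c.F.t();
  g.bd += sum(dlog, 1);
  mat dF = n.Wd.t() * dlog;

  cube dP3(a.F3, a.T3, B);
  for (int b = 0; b < B; ++b)
    dP3.slice(b) = reshape(dF.col(b), a.F3, a.T3);
  if (!c.M3.is_empty()) dP3 %= c.M3;
  cube dA3 = avg_pool_bw(dP3, a.p3, a.T2);
  cube dN3 = elu_bw(c.A3, dA3);
  cube dZ3 = bn_backward(c.bn3, n.g3, dN3, g.g3, g.be3);
  cube dP2(a.F2, a.T2, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat dx(a.F2, a.T2, fill::zeros);
    if (a.dw_trunk) conv_pm_bw(c.P2.slice(b), n.W3, dZ3.slice(b), dx, g.W3, g.b3);
    else conv_full_bw(c.P2.slice(b), n.W3, dZ3.slice(b), dx, g.W3, g.b3);
    dP2.slice(b) = dx;
  }
  if (!c.M2.is_empty()) dP2 %= c.M2;
  cube dA2 = avg_pool_bw(dP2, a.p2, c.A2.n_cols);
  cube dN2 = elu_bw(c.A2, dA2);
  cube dZ2 = bn_backward(c.bn2, n.g2, dN2, g.g2, g.be2);
  cube dP1(a.F1, a.T1, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat dx(a.F1, a.T1, fill::zeros);
    if (a.dw_trunk) conv_pm_bw(c.P1.slice(b), n.W2, dZ2.slice(b), dx, g.W2, g.b2);
    else conv_full_bw(c.P1.slice(b), n.W2, dZ2.slice(b), dx, g.W2, g.b2);
    dP1.slice(b) = dx;
  }
  cube dA1 = avg_pool_bw(dP1, a.p1, c.A1.n_cols);
  cube dN1 = elu_bw(c.A1, dA1);
  cube dZ1 = bn_backward(c.bn1, n.g1, dN1, g.g1, g.be1);
  for (int b = 0; b < B; ++b) {
    if (a.type == 0) {
      g.W1 += dZ1.slice(b) * c.X.slice(b).t();
      g.b1 += sum(dZ1.slice(b), 1);
    } else {
      mat dx(a.C, a.T, fill::zeros);
      conv_dw_bw(c.X.slice(b), n.W1, dZ1.slice(b), a.F1 / a.C, dx, g.W1, g.b1);
    }
  }
  return loss;
}

// ---- Adam ------------------------------------------------------------

struct Adam {
  Net m, v;
  double lr, b1, b2, eps;
  long t;
  Adam(const Arch& a, double lr_) : m(net_zero(a)), v(net_zero(a)),
    lr(lr_), b1(0.9), b2(0.999), eps(1e-8), t(0) {}
  template <class M>
  void upd(M& p, M& g, M& mm, M& vv, double bc1, double bc2) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    p -= lr * (mm / bc1) / (sqrt(vv / bc2) + eps);
    g.zeros();
  }
  void step(Net& p, Net& g) {
    ++t;
    double bc1 = 1 - std::pow(b1, (double)t), bc2 = 1 - std::pow(b2, (double)t);
    upd(p.W1, g.W1, m.W1, v.W1, bc1, bc2);
    upd(p.b1, g.b1, m.b1, v.b1, bc1, bc2);
    upd(p.g1, g.g1, m.g1, v.g1, bc1, bc2);
    upd(p.be1, g.be1, m.be1, v.be1, bc1, bc2);
    upd(p.W2, g.W2, m.W2, v.W2, bc1, bc2);
    upd(p.b2, g.b2, m.b2, v.b2, bc1, bc2);
    upd(p.g2, g.g2, m.g2, v.g2, bc1, bc2);
    upd(p.be2, g.be2, m.be2, v.be2, bc1, bc2);
    upd(p.W3, g.W3, m.W3, v.W3, bc1, bc2);
    upd(p.b3, g.b3, m.b3, v.b3, bc1, bc2);
    upd(p.g3, g.g3, m.g3, v.g3, bc1, bc2);
    upd(p.be3, g.be3, m.be3, v.be3, bc1, bc2);
    upd(p.Wd, g.Wd, m.Wd, v.Wd, bc1, bc2);
    upd(p.bd, g.bd, m.bd, v.bd, bc1, bc2);
  }
};

static mat predict_probs(const Net& n, const Arch& a, const cube& X) {
  Cache c;
  Net tmp = n;   // running stats untouched in eval mode
  forward(n, &tmp, a, X, false, nullptr, &c);
  return c.probs;
}

static double accuracy(const mat& probs, const ivec& y) {
  int ok = 0;
  for (uword b = 0; b < probs.n_cols; ++b) {
    uword am = index_max(probs.col(b));
    if ((int)am == y(b)) ++ok;
  }
  return double(ok) / probs.n_cols;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::cube& Xtr, const arma::ivec& ytr,
                         const arma::cube& Xval, const arma::ivec& yval,
                         const Rcpp::List& arch, const Rcpp::List& hyper,
                         int seed) {
  Arch a = arch_from_list(arch);
  const double lr = hyper["lr"];
  const int batch = hyper["batch"];
  const int max_epochs = hyper["max_epochs"];
  const int patience = hyper["patience"];

  std::mt19937 rng(seed);
  Net net;
  net_init(net, a, rng);
  Net grads = net_zero(a);
  Adam opt(a, lr);

  const int N = Xtr.n_slices;
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  double best_acc = -1.0;
  int best_epoch = 0;
  Net best = net;
  std::vector<double> hist;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int s0 = 0; s0 < N; s0 += batch) {
      const int B = std::min(batch, N - s0);
      cube Xb(a.C, a.T, B);
      ivec yb(B);
      for (int b = 0; b < B; ++b) {
        Xb.slice(b) = Xtr.slice(order[s0 + b]);
        yb(b) = ytr(order[s0 + b]);
      }
      Cache c;
      forward(net, &net, a, Xb, true, &rng, &c);
      backward(net, a, c, yb, grads);
      opt.step(net, grads);
    }
    const double va = accuracy(predict_probs(net, a, Xval), yval);
    hist.push_back(va);
    if (va > best_acc + 1e-12) { best_acc = va; best_epoch = epoch; best = net; }
    if (epoch - best_epoch >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = net_to_list(best),
    Rcpp::Named("history") = hist,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_acc") = best_acc);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(const Rcpp::List& params, const Rcpp::List& arch,
                          const arma::cube& X) {
  Arch a = arch_from_list(arch);
  Net n = net_from_list(params);
  return predict_probs(n, a, X);
}

// Loss and analytic gradients in training mode without dropout; used by
// the finite-difference gradient check in the test suite.
// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(const Rcpp::List& params, const Rcpp::List& arch,
                             const arma::cube& X, const arma::ivec& y) {
  Arch a = arch_from_list(arch);
  a.dropout = 0.0;
  Net n = net_from_list(params);
  Net run = n;                 // scratch running stats
  Cache c;
  forward(n, &run, a, X, true, nullptr, &c);
  Net g = net_zero(a);
  double loss = backward(n, a, c, y, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = net_to_list(g));
}

// [[Rcpp::export]]
double cnn_loss_cpp(const Rcpp::List& params, const Rcpp::List& arch,
                    const arma::cube& X, const arma::ivec& y) {
  Arch a = arch_from_list(arch);
  a.dropout = 0.0;
  Net n = net_from_list(params);
  Net run = n;
  Cache c;
  forward(n, &run, a, X, true, nullptr, &c);
  double loss = 0;
  for (uword b = 0; b < X.n_slices; ++b)
    loss -= std::log(std::max(c.probs(y(b), b), 1e-12));
  return loss / X.n_slices;
}
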