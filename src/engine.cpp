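// Compiled core: surrogate 4-basin potential, analytic descriptor map,
// MLP collective-variable evaluation with input Jacobian, OPES kernel
// bias, and the overdamped-Langevin integrator that ties them together.
// All randomness goes through R's RNG so seeds set in R are honoured.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Surrogate potential
//
// Coons-patch blend of four 1-D edge profiles over the unit square, plus a
// central product bump that penalises the diagonal PRE<->POST crossing.
// Edge profiles f(t) = E_start + (E_end - E_start)*s(t) + b*phi(t) where
// s is the quintic smootherstep (C2 when clamped) and phi(t) = 16 t^2 (1-t)^2
// is a polynomial bump: zero value/slope at t = 0, 1, peak 1 at t = 1/2, and
// quartic growth outside [0, 1] which confines the dynamics.
// ---------------------------------------------------------------------------

static inline double sstep(double t) {
  if (t <= 0.0) return 0.0;
  if (t >= 1.0) return 1.0;
  return t * t * t * (10.0 + t * (-15.0 + 6.0 * t));
}
static inline double dsstep(double t) {
  if (t <= 0.0 || t >= 1.0) return 0.0;
  double u = t * (1.0 - t);
  return 30.0 * u * u;
}
static inline double bump(double t) {
  double u = t * (1.0 - t);
  return 16.0 * u * u;
}
static inline double dbump(double t) {
  return 32.0 * t * (1.0 - t) * (1.0 - 2.0 * t);
}

struct SurrogatePars {
  // basin energies: PRE, INT1, INT2, POST
  double E0, E1, E2, E3;
  // bump amplitudes: A = PRE-INT1 edge (x2=0), B = INT2-POST edge (x2=1),
  // C = PRE-INT2 edge (x1=0), D = INT1-POST edge (x1=1)
  double bA, bB, bC, bD;
  double cdiag;
};

static SurrogatePars as_surrogate(const List& pars) {
  SurrogatePars p;
  NumericVector E = pars["basin_energies"];
  NumericVector b = pars["bumps"];
  p.E0 = E[0]; p.E1 = E[1]; p.E2 = E[2]; p.E3 = E[3];
  p.bA = b[0]; p.bB = b[1]; p.bC = b[2]; p.bD = b[3];
  p.cdiag = as<double>(pars["diagonal_penalty"]);
  return p;
}

static inline void edge_profile(double t, double e0, double e1, double b,
                                double& f, double& df) {
  f = e0 + (e1 - e0) * sstep(t) + b * bump(t);
  df = (e1 - e0) * dsstep(t) + b * dbump(t);
}

static inline void surrogate_energy(const SurrogatePars& p, double x1, double x2,
                                    double& V, double& g1, double& g2) {
  double fA, dfA, fB, dfB, fC, dfC, fD, dfD;
  edge_profile(x1, p.E0, p.E1, p.bA, fA, dfA);
  edge_profile(x1, p.E2, p.E3, p.bB, fB, dfB);
  edge_profile(x2, p.E0, p.E2, p.bC, fC, dfC);
  edge_profile(x2, p.E1, p.E3, p.bD, fD, dfD);
  double w1 = sstep(x1), w2 = sstep(x2);
  double dw1 = dsstep(x1), dw2 = dsstep(x2);
  double bilin = (1 - w1) * (1 - w2) * p.E0 + w1 * (1 - w2) * p.E1 +
                 (1 - w1) * w2 * p.E2 + w1 * w2 * p.E3;
  V = (1 - w2) * fA + w2 * fB + (1 - w1) * fC + w1 * fD - bilin +
      p.cdiag * bump(x1) * bump(x2);
  g1 = (1 - w2) * dfA + w2 * dfB + dw1 * (fD - fC) -
       dw1 * ((1 - w2) * (p.E1 - p.E0) + w2 * (p.E3 - p.E2)) +
       p.cdiag * dbump(x1) * bump(x2);
  g2 = dw2 * (fB - fA) + (1 - w1) * dfC + w1 * dfD -
       dw2 * ((1 - w1) * (p.E2 - p.E0) + w1 * (p.E3 - p.E1)) +
       p.cdiag * bump(x1) * dbump(x2);
}

// [[Rcpp::export]]
List cpp_potential(List pars, NumericMatrix X) {
  SurrogatePars p = as_surrogate(pars);
  int n = X.nrow();
  NumericVector V(n);
  NumericMatrix G(n, 2);
  for (int i = 0; i < n; ++i) {
    double v, g1, g2;
    surrogate_energy(p, X(i, 0), X(i, 1), v, g1, g2);
    V[i] = v; G(i, 0) = g1; G(i, 1) = g2;
  }
  return List::create(_["energy"] = V, _["gradient"] = G);
}

// ---------------------------------------------------------------------------
// Descriptor map: column j responds to one latent axis through a logistic
// switch  d_j(x) = base_j + amp_j * plogis((x_axis - 0.5) / tau_j).
// Matrix `desc` columns: axis (1 or 2), base, amp, tau.
// ---------------------------------------------------------------------------

struct CVSpec {
  int type;                      // 0 = linear map of latent, 1 = descriptor MLP
  int ncv;
  // type 0
  std::vector<double> P;         // 2 x ncv projection, column-major
  // type 1
  int ndesc;
  std::vector<int> axis;
  std::vector<double> base, amp, tau, mu, sd;
  std::vector<NumericMatrix> W;  // layer weights, (in x out)
  std::vector<NumericVector> b;
  int act;                       // 1 = relu, 2 = shifted softplus
  int head;                      // 0 = identity, 1 = lda (w, lorentz, affine)
  std::vector<double> head_w;
  double lorentz, affA, affB;
  // work buffers
  std::vector<std::vector<double> > h;    // post-activation per layer
  std::vector<std::vector<double> > pre;  // pre-activation per layer
  std::vector<double> d, z, delta0, delta1;
};

static inline double act_f(int act, double x) {
  if (act == 1) return x > 0.0 ? x : 0.0;
  // shifted softplus: log(1 + e^x) - log 2, numerically stable
  double m = x > 0.0 ? x : 0.0;
  return m + std::log1p(std::exp(x > 0.0 ? -x : x)) - 0.6931471805599453;
}
static inline double act_df(int act, double x) {
  if (act == 1) return x > 0.0 ? 1.0 : 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

static CVSpec as_cvspec(const List& spec) {
  CVSpec c;
  c.type = as<int>(spec["type"]);
  c.ncv = as<int>(spec["ncv"]);
  if (c.type == 0) {
    NumericMatrix P = spec["P"];
    c.P.assign(P.begin(), P.end());
    return c;
  }
  NumericMatrix desc = spec["desc"];
  c.ndesc = desc.nrow();
  c.axis.resize(c.ndesc); c.base.resize(c.ndesc);
  c.amp.resize(c.ndesc); c.tau.resize(c.ndesc);
  for (int j = 0; j < c.ndesc; ++j) {
    c.axis[j] = (int)desc(j, 0); c.base[j] = desc(j, 1);
    c.amp[j] = desc(j, 2); c.tau[j] = desc(j, 3);
  }
  NumericVector mu = spec["mu"], sd = spec["sd"];
  c.mu.assign(mu.begin(), mu.end());
  c.sd.assign(sd.begin(), sd.end());
  List Ws = spec["W"], bs = spec["b"];
  for (int l = 0; l < Ws.size(); ++l) {
    c.W.push_back(as<NumericMatrix>(Ws[l]));
    c.b.push_back(as<NumericVector>(bs[l]));
  }
  c.act = as<int>(spec["act"]);
  c.head = as<int>(spec["head"]);
  if (c.head == 1) {
    NumericVector w = spec["head_w"];
    c.head_w.assign(w.begin(), w.end());
    c.lorentz = as<double>(spec["lorentz"]);
    c.affA = as<double>(spec["affine_a"]);
    c.affB = as<double>(spec["affine_b"]);
  }
  int L = c.W.size();
  c.h.resize(L + 1); c.pre.resize(L);
  c.h[0].resize(c.ndesc);
  for (int l = 0; l < L; ++l) {
    c.pre[l].resize(c.W[l].ncol());
    c.h[l + 1].resize(c.W[l].ncol());
  }
  c.d.resize(c.ndesc); c.z.resize(c.ndesc);
  int wmax = c.ndesc;
  for (int l = 0; l < L; ++l) wmax = std::max(wmax, (int)c.W[l].ncol());
  c.delta0.resize(wmax); c.delta1.resize(wmax);
  return c;
}

// evaluate CV s(x) and Jacobian J[d][k] = ds_k / dx_d  (d = 0,1)
static void cv_eval(CVSpec& c, const double* x, double* s, double* J) {
  if (c.type == 0) {
    for (int k = 0; k < c.ncv; ++k) {
      s[k] = c.P[2 * k] * x[0] + c.P[2 * k + 1] * x[1];
      J[k] = c.P[2 * k]; J[c.ncv + k] = c.P[2 * k + 1];
    }
    return;
  }
  int L = c.W.size();
  // descriptors + standardization; dz/dx stored per column (single axis each)
  std::vector<double>& dzdx = c.d;  // reuse buffer: derivative wrt its axis
  for (int j = 0; j < c.ndesc; ++j) {
    double u = (x[c.axis[j] - 1] - 0.5) / c.tau[j];
    double sig = 1.0 / (1.0 + std::exp(-u));
    double dj = c.base[j] + c.amp[j] * sig;
    c.z[j] = (dj - c.mu[j]) / c.sd[j];
    dzdx[j] = c.amp[j] * sig * (1.0 - sig) / (c.tau[j] * c.sd[j]);
    c.h[0][j] = c.z[j];
  }
  // forward
  for (int l = 0; l < L; ++l) {
    const NumericMatrix& W = c.W[l];
    int nin = W.nrow(), nout = W.ncol();
    for (int o = 0; o < nout; ++o) {
      double acc = c.b[l][o];
      const double* wcol = &W(0, o);
      const double* hin = &c.h[l][0];
      for (int i = 0; i < nin; ++i) acc += hin[i] * wcol[i];
      c.pre[l][o] = acc;
      c.h[l + 1][o] = (l == L - 1) ? acc : act_f(c.act, acc);
    }
  }
  // head + per-output reverse pass for the Jacobian
  int nout_net = c.W[L - 1].ncol();
  double dhead = 1.0;
  if (c.head == 1) {
    double u = 0.0;
    for (int j = 0; j < nout_net; ++j) u += c.head_w[j] * c.h[L][j];
    double uhat = c.affA * u + c.affB;
    s[0] = c.lorentz * std::atan(uhat / c.lorentz);
    dhead = c.affA / (1.0 + (uhat / c.lorentz) * (uhat / c.lorentz));
  } else {
    for (int k = 0; k < c.ncv; ++k) s[k] = c.h[L][k];
  }
  for (int k = 0; k < c.ncv; ++k) {
    std::vector<double>& cur = c.delta0;
    std::vector<double>& nxt = c.delta1;
    if (c.head == 1) {
      for (int j = 0; j < nout_net; ++j) cur[j] = dhead * c.head_w[j];
    } else {
      for (int j = 0; j < nout_net; ++j) cur[j] = (j == k) ? 1.0 : 0.0;
    }
    for (int l = L - 1; l >= 0; --l) {
      const NumericMatrix& W = c.W[l];
      int nin = W.nrow(), nout = W.ncol();
      for (int i = 0; i < nin; ++i) {
        double acc = 0.0;
        const double* wrow = &W(i, 0);
        // W is column-major (in x out): stride nin between outputs
        for (int o = 0; o < nout; ++o) acc += wrow[(size_t)o * nin] * cur[o];
        nxt[i] = (l > 0) ? acc * act_df(c.act, c.pre[l - 1][i]) : acc;
      }
      std::swap(cur, nxt);
    }
    double j0 = 0.0, j1 = 0.0;
    for (int j = 0; j < c.ndesc; ++j) {
      if (c.axis[j] == 1) j0 += cur[j] * dzdx[j];
      else j1 += cur[j] * dzdx[j];
    }
    J[k] = j0; J[c.ncv + k] = j1;
  }
}

// [[Rcpp::export]]
List cpp_eval_cv(List spec, NumericMatrix X) {
  CVSpec c = as_cvspec(spec);
  int n = X.nrow();
  NumericMatrix S(n, c.ncv), J1(n, c.ncv), J2(n, c.ncv);
  std::vector<double> s(c.ncv), J(2 * c.ncv);
  for (int i = 0; i < n; ++i) {
    double x[2] = { X(i, 0), X(i, 1) };
    cv_eval(c, x, &s[0], &J[0]);
    for (int k = 0; k < c.ncv; ++k) {
      S(i, k) = s[k]; J1(i, k) = J[k]; J2(i, k) = J[c.ncv + k];
    }
  }
  return List::create(_["cv"] = S, _["J1"] = J1, _["J2"] = J2);
}

// ---------------------------------------------------------------------------
// OPES bias: weighted Gaussian kernel density with well-tempered target.
//   p(s)  = sum_k h_k G(s; c_k, sig_k) / sum_k h_k
//   V(s)  = pref * log(p(s)/Z + eps)
// standard variant: pref = (1 - 1/gamma)/beta, deposit weight e^{beta V};
// explore variant:  pref = (gamma - 1)/beta,   deposit weight 1
// Z is the mean of p over deposited kernel centers.
// ---------------------------------------------------------------------------

struct OPES {
  int ncv, variant;
  double beta, gamma, barrier, eps, pref, stride, merge_thresh, cutoff2;
  double sigma_min_frac;
  std::vector<double> sigma0;
  std::vector<double> cen, sig, hgt;   // kernels: cen/sig are K x ncv flat
  std::vector<double> pc;              // unnormalized density at each center
  double sum_h, sum_w, sum_w2;
  long n_dep;
  double max_bias_seen, min_bias_seen;
  int n_merged;

  int K() const { return (int)hgt.size(); }

  double kval(int k, const double* s) const {
    double q = 0.0, norm = 1.0;
    for (int d = 0; d < ncv; ++d) {
      double dd = (s[d] - cen[(size_t)k * ncv + d]) / sig[(size_t)k * ncv + d];
      q += dd * dd;
      norm *= sig[(size_t)k * ncv + d] * 2.5066282746310002;  // sqrt(2*pi)
    }
    if (q > cutoff2) return 0.0;
    return std::exp(-0.5 * q) / norm;
  }

  // unnormalized density and gradient
  double uprob(const double* s, double* grad) const {
    double p = 0.0;
    if (grad) for (int d = 0; d < ncv; ++d) grad[d] = 0.0;
    for (int k = 0; k < K(); ++k) {
      double q = 0.0, norm = 1.0;
      double dd[2];
      for (int d = 0; d < ncv; ++d) {
        dd[d] = (s[d] - cen[(size_t)k * ncv + d]) / sig[(size_t)k * ncv + d];
        q += dd[d] * dd[d];
        norm *= sig[(size_t)k * ncv + d] * 2.5066282746310002;
      }
      if (q > cutoff2) continue;
      double g = hgt[k] * std::exp(-0.5 * q) / norm;
      p += g;
      if (grad)
        for (int d = 0; d < ncv; ++d)
          grad[d] -= g * dd[d] / sig[(size_t)k * ncv + d];
    }
    return p;
  }

  // normalization: the running maximum of the density estimate (evaluated
  // at kernel centers), so the bias is <= ~0 with floor pref*log(eps);
  // this realizes the BARRIER cap on the deposited bias range
  double Z() const {
    if (K() == 0 || sum_h <= 0.0) return 1.0;
    double m = 0.0;
    for (size_t j = 0; j < pc.size(); ++j) if (pc[j] > m) m = pc[j];
    return std::max(m / sum_h, 1e-300);
  }

  double bias(const double* s, double* grad) const {
    if (K() == 0) {
      if (grad) for (int d = 0; d < ncv; ++d) grad[d] = 0.0;
      return 0.0;
    }
    double gp[2] = {0.0, 0.0};
    double p = uprob(s, grad ? gp : (double*)0) / sum_h;
    double z = Z();
    double arg = p / z + eps;
    double v = pref * std::log(arg);
    if (grad) {
      double fac = pref / (arg * z * sum_h);
      for (int d = 0; d < ncv; ++d) grad[d] = fac * gp[d];
    }
    return v;
  }

  void recompute_pc() {
    pc.assign(K(), 0.0);
    for (int j = 0; j < K(); ++j) {
      double p = 0.0;
      for (int k = 0; k < K(); ++k) p += hgt[k] * kval(k, &cen[(size_t)j * ncv]);
      pc[j] = p;
    }
  }

  void deposit(const double* s) {
    double w;
    if (variant == 1) w = 1.0;
    else {
      double v = bias(s, (double*)0);
      w = std::exp(std::min(beta * v, 700.0));
    }
    n_dep++;
    sum_w += w; sum_w2 += w * w;
    double neff = sum_w * sum_w / std::max(sum_w2, 1e-300);
    double shrink = std::pow(neff * (ncv + 2.0) / 4.0, -1.0 / (ncv + 4.0));
    std::vector<double> sg(ncv);
    for (int d = 0; d < ncv; ++d)
      sg[d] = std::max(sigma0[d] * shrink, sigma0[d] * sigma_min_frac);
    // merge with nearest kernel if closer than merge_thresh bandwidths
    int best = -1; double bestq = merge_thresh * merge_thresh;
    for (int k = 0; k < K(); ++k) {
      double q = 0.0;
      for (int d = 0; d < ncv; ++d) {
        double dd = (s[d] - cen[(size_t)k * ncv + d]) / sig[(size_t)k * ncv + d];
        q += dd * dd;
      }
      if (q < bestq) { bestq = q; best = k; }
    }
    if (best >= 0) {
      n_merged++;
      // remove the old kernel's contribution to the center densities, then
      // add back the merged one
      for (int j = 0; j < K(); ++j)
        pc[j] -= hgt[best] * kval(best, &cen[(size_t)j * ncv]);
      double h1 = hgt[best], h2 = w, hn = h1 + h2;
      for (int d = 0; d < ncv; ++d) {
        double c1 = cen[(size_t)best * ncv + d], s1 = sig[(size_t)best * ncv + d];
        double cn = (h1 * c1 + h2 * s[d]) / hn;
        double m2 = (h1 * (s1 * s1 + c1 * c1) + h2 * (sg[d] * sg[d] + s[d] * s[d])) / hn;
        cen[(size_t)best * ncv + d] = cn;
        sig[(size_t)best * ncv + d] = std::sqrt(std::max(m2 - cn * cn, 1e-16));
      }
      hgt[best] = hn;
      sum_h += w;
      for (int j = 0; j < K(); ++j)
        pc[j] += hgt[best] * kval(best, &cen[(size_t)j * ncv]);
      // the merged kernel moved: refresh its own density entry exactly
      double p = 0.0;
      for (int k = 0; k < K(); ++k) p += hgt[k] * kval(k, &cen[(size_t)best * ncv]);
      pc[best] = p;
    } else {
      int Kold = K();
      for (int d = 0; d < ncv; ++d) { cen.push_back(s[d]); sig.push_back(sg[d]); }
      hgt.push_back(w);
      sum_h += w;
      for (int j = 0; j < Kold; ++j)
        pc[j] += w * kval(Kold, &cen[(size_t)j * ncv]);
      double pnew = 0.0;
      for (int k = 0; k <= Kold; ++k) pnew += hgt[k] * kval(k, s);
      pc.push_back(pnew);
    }
    if (n_dep % 256 == 0) recompute_pc();  // guard against drift
  }
};

static OPES as_opes(const List& o) {
  OPES b;
  b.ncv = as<int>(o["ncv"]);
  b.variant = as<int>(o["variant"]);
  b.beta = as<double>(o["beta"]);
  b.gamma = as<double>(o["gamma"]);
  b.barrier = as<double>(o["barrier"]);
  b.eps = as<double>(o["epsilon"]);
  b.pref = (b.variant == 1) ? (b.gamma - 1.0) / b.beta
                            : (1.0 - 1.0 / b.gamma) / b.beta;
  if (b.gamma <= 1.0) b.pref = 0.0;
  b.merge_thresh = as<double>(o["merge_threshold"]);
  b.cutoff2 = as<double>(o["cutoff_sd"]); b.cutoff2 *= b.cutoff2;
  b.sigma_min_frac = as<double>(o["sigma_min_frac"]);
  NumericVector s0 = o["sigma0"];
  b.sigma0.assign(s0.begin(), s0.end());
  b.sum_h = b.sum_w = b.sum_w2 = 0.0;
  b.n_dep = 0; b.n_merged = 0;
  b.max_bias_seen = -std::numeric_limits<double>::infinity();
  b.min_bias_seen = std::numeric_limits<double>::infinity();
  if (o.containsElementNamed("kernels") && !Rf_isNull(o["kernels"])) {
    List kl = o["kernels"];
    NumericMatrix cen = kl["center"], sig = kl["sigma"];
    NumericVector h = kl["height"];
    for (int k = 0; k < h.size(); ++k) {
      for (int d = 0; d < b.ncv; ++d) {
        b.cen.push_back(cen(k, d)); b.sig.push_back(sig(k, d));
      }
      b.hgt.push_back(h[k]); b.sum_h += h[k];
      b.sum_w += h[k]; b.sum_w2 += h[k] * h[k];
    }
    b.n_dep = h.size();
    b.recompute_pc();
  }
  return b;
}

static List opes_kernels(const OPES& b) {
  int K = b.K();
  NumericMatrix cen(K, b.ncv), sig(K, b.ncv);
  NumericVector h(K);
  for (int k = 0; k < K; ++k) {
    for (int d = 0; d < b.ncv; ++d) {
      cen(k, d) = b.cen[(size_t)k * b.ncv + d];
      sig(k, d) = b.sig[(size_t)k * b.ncv + d];
    }
    h[k] = b.hgt[k];
  }
  return List::create(_["center"] = cen, _["sigma"] = sig, _["height"] = h);
}

// [[Rcpp::export]]
List cpp_eval_bias(List opes, NumericMatrix S) {
  OPES b = as_opes(opes);
  int n = S.nrow();
  NumericVector V(n);
  NumericMatrix G(n, b.ncv);
  std::vector<double> s(b.ncv), g(b.ncv);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < b.ncv; ++d) s[d] = S(i, d);
    V[i] = b.bias(&s[0], &g[0]);
    for (int d = 0; d < b.ncv; ++d) G(i, d) = g[d];
  }
  return List::create(_["energy"] = V, _["gradient"] = G,
                      _["Z"] = b.Z(), _["sum_height"] = b.sum_h);
}

// [[Rcpp::export]]
List cpp_update_bias(List opes, NumericMatrix S) {
  OPES b = as_opes(opes);
  std::vector<double> s(b.ncv);
  for (int i = 0; i < S.nrow(); ++i) {
    for (int d = 0; d < b.ncv; ++d) s[d] = S(i, d);
    b.deposit(&s[0]);
  }
  return List::create(_["kernels"] = opes_kernels(b),
                      _["n_deposited"] = (double)b.n_dep,
                      _["n_merged"] = b.n_merged);
}

// ---------------------------------------------------------------------------
// Walls: one-sided quadratic (or general power) restraints per CV dimension.
// walls list: matrix (ncv x 5): lo, hi, k_lo, k_hi, exponent. NA limit = off.
// ---------------------------------------------------------------------------

static double wall_eval(const NumericMatrix& w, const double* s, double* grad) {
  double e = 0.0;
  for (int d = 0; d < w.nrow(); ++d) {
    double lo = w(d, 0), hi = w(d, 1), klo = w(d, 2), khi = w(d, 3), ex = w(d, 4);
    if (grad) grad[d] = 0.0;
    if (!ISNA(lo) && s[d] < lo) {
      double u = lo - s[d];
      e += klo * std::pow(u, ex);
      if (grad) grad[d] += -klo * ex * std::pow(u, ex - 1.0);
    }
    if (!ISNA(hi) && s[d] > hi) {
      double u = s[d] - hi;
      e += khi * std::pow(u, ex);
      if (grad) grad[d] += khi * ex * std::pow(u, ex - 1.0);
    }
  }
  return e;
}

// [[Rcpp::export]]
List cpp_wall_energy(NumericMatrix walls, NumericMatrix S) {
  int n = S.nrow(), ncv = walls.nrow();
  NumericVector E(n);
  NumericMatrix G(n, ncv);
  std::vector<double> s(ncv), g(ncv);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < ncv; ++d) s[d] = S(i, d);
    E[i] = wall_eval(walls, &s[0], &g[0]);
    for (int d = 0; d < ncv; ++d) G(i, d) = g[d];
  }
  return List::create(_["energy"] = E, _["gradient"] = G);
}

// ---------------------------------------------------------------------------
// Overdamped Langevin engine (Euler-Maruyama), optionally biased through a
// CV model with OPES + walls. Records every `record_stride` steps.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List pars, NumericVector x0, int n_steps, double dt, double kT,
             double friction, int record_stride,
             Nullable<List> cv_spec, Nullable<List> opes_pars,
             Nullable<NumericMatrix> walls,
             int bias_stride, bool freeze_bias, double max_step) {
  SurrogatePars p = as_surrogate(pars);
  bool has_cv = cv_spec.isNotNull();
  CVSpec cv;
  if (has_cv) cv = as_cvspec(List(cv_spec));
  bool has_opes = opes_pars.isNotNull();
  OPES ob;
  if (has_opes) ob = as_opes(List(opes_pars));
  bool has_walls = walls.isNotNull();
  NumericMatrix wm;
  if (has_walls) wm = NumericMatrix(walls);

  int ncv = has_cv ? cv.ncv : 0;
  int nrec = n_steps / record_stride;
  NumericMatrix X(nrec, 2), S(nrec, std::max(ncv, 1));
  NumericVector Vb(nrec), Tm(nrec);
  double x[2] = { x0[0], x0[1] };
  std::vector<double> s(std::max(ncv, 1)), J(2 * std::max(ncv, 1)),
      gb(std::max(ncv, 1)), gw(std::max(ncv, 1));
  double noise_amp = std::sqrt(2.0 * kT * dt / friction);
  long n_clamped = 0;
  int irec = 0;

  RNGScope rng;
  for (int step = 0; step < n_steps; ++step) {
    double V, g1, g2;
    surrogate_energy(p, x[0], x[1], V, g1, g2);
    double f[2] = { -g1, -g2 };
    double vbias = 0.0;
    if (has_cv) {
      cv_eval(cv, x, &s[0], &J[0]);
      if (has_opes) {
        vbias = ob.bias(&s[0], &gb[0]);
        if (vbias > ob.max_bias_seen) ob.max_bias_seen = vbias;
        if (vbias < ob.min_bias_seen) ob.min_bias_seen = vbias;
        for (int k = 0; k < ncv; ++k) {
          f[0] -= gb[k] * J[k];
          f[1] -= gb[k] * J[ncv + k];
        }
      }
      if (has_walls) {
        wall_eval(wm, &s[0], &gw[0]);
        for (int k = 0; k < ncv; ++k) {
          f[0] -= gw[k] * J[k];
          f[1] -= gw[k] * J[ncv + k];
        }
      }
    }
    for (int d = 0; d < 2; ++d) {
      double disp = dt * f[d] / friction + noise_amp * norm_rand();
      if (disp > max_step) { disp = max_step; n_clamped++; }
      else if (disp < -max_step) { disp = -max_step; n_clamped++; }
      x[d] += disp;
    }
    if (!std::isfinite(x[0]) || !std::isfinite(x[1]))
      stop("integration diverged at step %d", step + 1);
    if (has_opes && !freeze_bias && ((step + 1) % bias_stride == 0)) {
      if (has_cv) cv_eval(cv, x, &s[0], &J[0]);
      ob.deposit(&s[0]);
    }
    if ((step + 1) % record_stride == 0) {
      Tm[irec] = (step + 1) * dt;
      X(irec, 0) = x[0]; X(irec, 1) = x[1];
      if (has_cv) {
        cv_eval(cv, x, &s[0], &J[0]);
        for (int k = 0; k < ncv; ++k) S(irec, k) = s[k];
        Vb[irec] = has_opes ? ob.bias(&s[0], (double*)0) : 0.0;
      }
      irec++;
    }
  }
  List out = List::create(
      _["time"] = Tm, _["X"] = X,
      _["cv"] = has_cv ? S : NumericMatrix(0, 0),
      _["bias"] = Vb, _["n_clamped"] = (double)n_clamped);
  if (has_opes) {
    out["kernels"] = opes_kernels(ob);
    out["max_bias"] = ob.max_bias_seen;
    out["min_bias"] = ob.min_bias_seen;
    out["n_merged"] = ob.n_merged;
    out["n_deposited"] = (double)ob.n_dep;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small 1-D sampler for closed-form oracle tests: harmonic or tilted quartic
// double well, with an optional static bias given on a grid (linear interp).
// potential codes: 0 -> 0.5*k*x^2 ; 1 -> h*(x^2-1)^2 + tilt*x
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sim1d(int pot, NumericVector pp, double x0, int n_steps, double dt,
               double kT, int record_stride,
               Nullable<NumericVector> bias_grid_x,
               Nullable<NumericVector> bias_grid_v) {
  bool has_bias = bias_grid_x.isNotNull();
  NumericVector bx, bv;
  if (has_bias) { bx = NumericVector(bias_grid_x); bv = NumericVector(bias_grid_v); }
  int nb = has_bias ? bx.size() : 0;
  double bx0 = has_bias ? bx[0] : 0.0;
  double bdx = has_bias ? (bx[1] - bx[0]) : 1.0;
  int nrec = n_steps / record_stride;
  NumericVector X(nrec);
  double x = x0, amp = std::sqrt(2.0 * kT * dt);
  int irec = 0;
  RNGScope rng;
  for (int step = 0; step < n_steps; ++step) {
    double f;
    if (pot == 0) f = -pp[0] * x;
    else f = -(4.0 * pp[0] * x * (x * x - 1.0) + pp[1]);
    if (has_bias) {
      double u = (x - bx0) / bdx;
      int i = (int)std::floor(u);
      if (i >= 0 && i < nb - 1) f -= (bv[i + 1] - bv[i]) / bdx;
    }
    x += dt * f + amp * norm_rand();
    if (!std::isfinite(x)) stop("integration diverged at step %d", step + 1);
    if ((step + 1) % record_stride == 0) X[irec++] = x;
  }
  return List::create(_["x"] = X);
}
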