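// Hierarchical resource-rational planning model: log posterior, gradient,
// and a multinomial No-U-Turn sampler with dual-averaging step-size and
// diagonal mass-matrix adaptation.
//
// Parameterization (unconstrained vector theta):
//   [0..3]   hyper-means mu for U_outcome, C_plan, C_info, U_leisure
//   [4..7]   cut points: kappa1 = theta[4], kappa_k = kappa_{k-1} + exp(theta[3+k])
//   [8]      log shared C_info (only when variant == shared_Cinfo)
//   then one block per subject, log-scale positives:
//            log U_outcome, log C_plan, (log C_info), log U_leisure,
//            (log s_gain, log s_loss)
// Subject parameters carry properly normalized truncated-normal priors
// (lower bound 0): normal log-density minus log Phi(mu/sd), plus the
// log-Jacobian of exp().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log1pexp_(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double sig_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log P(y = k | eta, kappa) for ordered logistic with K = 5 and gradients
// d/deta, d/dkappa_lower, d/dkappa_upper. Lower/upper indices are set in
// the caller; this returns the three partials by reference.
static double ordlogit_lpmf_grad(int y, double eta, const double* kap,
                                 double& d_eta, double& d_klo, double& d_khi,
                                 int& ilo, int& ihi) {
  d_eta = 0.0; d_klo = 0.0; d_khi = 0.0; ilo = -1; ihi = -1;
  if (y == 1) {
    double b = kap[0] - eta;
    double lp = -log1pexp_(-b);
    double smb = sig_(-b);
    d_eta = -smb; d_khi = smb; ihi = 0;
    return lp;
  }
  if (y == 5) {
    double a = kap[3] - eta;
    double lp = -log1pexp_(a);
    double sa = sig_(a);
    d_eta = sa; d_klo = -sa; ilo = 3;
    return lp;
  }
  int lo = y - 2, hi = y - 1;          // 0-based cut indices
  double a = kap[lo] - eta, b = kap[hi] - eta;   // a < b
  // log(sigma(b) - sigma(a)), numerically stable
  double lP = -a - log1pexp_(-a) - log1pexp_(-b) + std::log1p(-std::exp(a - b));
  double lda = -log1pexp_(-a) - log1pexp_(a);    // log sigma'(a)
  double ldb = -log1pexp_(-b) - log1pexp_(b);
  double ra = std::exp(lda - lP), rb = std::exp(ldb - lP);
  d_eta = ra - rb; d_klo = -ra; d_khi = rb; ilo = lo; ihi = hi;
  return lP;
}

class HierModel {
public:
  arma::ivec subj, y, gain;     // per trial
  arma::vec p, crank;
  int n_subj, n_trials;
  bool scaling, shared_ci;
  double mu_prior_sd, subj_sd, scale_mean, scale_sd, kappa_sd;
  int blk;                      // per-subject block size
  int off_subj;                 // offset of first subject block

  HierModel(List data, bool scaling_, bool shared_ci_, List priors)
      : scaling(scaling_), shared_ci(shared_ci_) {
    subj = as<arma::ivec>(data["subj"]);      // 0-based
    y = as<arma::ivec>(data["y"]);
    gain = as<arma::ivec>(data["gain"]);
    p = as<arma::vec>(data["p"]);
    crank = as<arma::vec>(data["crank"]);
    n_subj = as<int>(data["n_subj"]);
    n_trials = subj.n_elem;
    mu_prior_sd = as<double>(priors["mu_prior_sd"]);
    subj_sd = as<double>(priors["subj_sd"]);
    scale_mean = as<double>(priors["scale_mean"]);
    scale_sd = as<double>(priors["scale_sd"]);
    kappa_sd = as<double>(priors["kappa_sd"]);
    blk = 3 + (shared_ci ? 0 : 1) + (scaling ? 2 : 0);
    off_subj = 8 + (shared_ci ? 1 : 0);
  }

  int dim() const { return off_subj + n_subj * blk; }

  // indices within a subject block
  int i_uo() const { return 0; }
  int i_cp() const { return 1; }
  int i_ci() const { return 2; }                 // only if !shared_ci
  int i_ul() const { return shared_ci ? 2 : 3; }
  int i_sg() const { return (shared_ci ? 3 : 4); }
  int i_sl() const { return (shared_ci ? 4 : 5); }

  double logp_grad(const arma::vec& th, arma::vec& g) const {
    const double l2pi = 0.5 * std::log(2.0 * M_PI);
    g.zeros(dim());
    double lp = 0.0;

    // hyper-mean priors
    for (int k = 0; k < 4; ++k) {
      double m = th[k];
      lp += -0.5 * m * m / (mu_prior_sd * mu_prior_sd) - std::log(mu_prior_sd) - l2pi;
      g[k] += -m / (mu_prior_sd * mu_prior_sd);
    }

    // cut points
    double kap[4];
    kap[0] = th[4];
    for (int k = 1; k < 4; ++k) kap[k] = kap[k - 1] + std::exp(th[4 + k]);
    double gkap[4] = {0, 0, 0, 0};
    for (int k = 0; k < 4; ++k) {
      lp += -0.5 * kap[k] * kap[k] / (kappa_sd * kappa_sd) - std::log(kappa_sd) - l2pi;
      gkap[k] += -kap[k] / (kappa_sd * kappa_sd);
    }
    lp += th[5] + th[6] + th[7];   // log-Jacobian of the increments

    // subject parameters on the natural scale
    arma::vec Uo(n_subj), Cp(n_subj), Ul(n_subj), Ci(n_subj), Sg(n_subj), Sl(n_subj);
    double xc = 0.0;
    if (shared_ci) xc = std::exp(th[8]);
    for (int j = 0; j < n_subj; ++j) {
      int o = off_subj + j * blk;
      Uo[j] = std::exp(th[o + i_uo()]);
      Cp[j] = std::exp(th[o + i_cp()]);
      Ul[j] = std::exp(th[o + i_ul()]);
      Ci[j] = shared_ci ? xc : std::exp(th[o + i_ci()]);
      Sg[j] = scaling ? std::exp(th[o + i_sg()]) : 1.0;
      Sl[j] = scaling ? std::exp(th[o + i_sl()]) : 1.0;
    }

    // priors: x ~ N(mu, subj_sd) with lower=0 device (no renormalization),
    // plus log-Jacobian y of x = exp(y)
    double v = subj_sd * subj_sd;
    arma::vec gUo(n_subj, arma::fill::zeros), gCp(n_subj, arma::fill::zeros),
        gUl(n_subj, arma::fill::zeros), gCi(n_subj, arma::fill::zeros),
        gSg(n_subj, arma::fill::zeros), gSl(n_subj, arma::fill::zeros);
    double gxc = 0.0;
    for (int j = 0; j < n_subj; ++j) {
      double du = Uo[j] - th[0], dc = Cp[j] - th[1], dl = Ul[j] - th[3];
      lp += -0.5 * (du * du + dc * dc + dl * dl) / v
            - 3.0 * (std::log(subj_sd) + l2pi);
      gUo[j] += -du / v; g[0] += du / v;
      gCp[j] += -dc / v; g[1] += dc / v;
      gUl[j] += -dl / v; g[3] += dl / v;
      if (!shared_ci) {
        double di = Ci[j] - th[2];
        lp += -0.5 * di * di / v - std::log(subj_sd) - l2pi;
        gCi[j] += -di / v; g[2] += di / v;
      }
      if (scaling) {
        double dg = Sg[j] - scale_mean, ds = Sl[j] - scale_mean;
        double vs = scale_sd * scale_sd;
        lp += -0.5 * (dg * dg + ds * ds) / vs - 2.0 * (std::log(scale_sd) + l2pi);
        gSg[j] += -dg / vs; gSl[j] += -ds / vs;
      }
    }
    if (shared_ci) {
      double di = xc - th[2];
      lp += -0.5 * di * di / v - std::log(subj_sd) - l2pi;
      gxc += -di / v; g[2] += di / v;
    }
    // truncated-normal normalization: -log Phi(mu/sd) per draw, with its
    // mu-gradient -phi(mu/sd)/(sd Phi(mu/sd))
    {
      int counts[4] = {n_subj, n_subj, shared_ci ? 1 : n_subj, n_subj};
      for (int k = 0; k < 4; ++k) {
        double zz = th[k] / subj_sd;
        double lphi = ::Rf_pnorm5(zz, 0.0, 1.0, 1, 1);
        lp -= counts[k] * lphi;
        g[k] -= counts[k] *
          std::exp(::Rf_dnorm4(zz, 0.0, 1.0, 1) - lphi) / subj_sd;
      }
      if (scaling) {
        double lphis = ::Rf_pnorm5(scale_mean / scale_sd, 0.0, 1.0, 1, 1);
        lp -= 2.0 * n_subj * lphis;   // constant: scale prior mean is fixed
      }
    }
    // log-Jacobians
    for (int j = 0; j < n_subj; ++j) {
      int o = off_subj + j * blk;
      lp += th[o + i_uo()] + th[o + i_cp()] + th[o + i_ul()];
      if (!shared_ci) lp += th[o + i_ci()];
      if (scaling) lp += th[o + i_sg()] + th[o + i_sl()];
    }
    if (shared_ci) lp += th[8];

    // likelihood
    for (int t = 0; t < n_trials; ++t) {
      int j = subj[t];
      double s = gain[t] ? Sg[j] : Sl[j];
      double up = p[t] * s * Uo[j] - Cp[j];
      double ui = p[t] * (s * Uo[j] - Cp[j]) - Ci[j] * crank[t];
      bool plan = up >= Ul[j];
      double eta = ui - (plan ? up : Ul[j]);
      double de, dlo, dhi; int ilo, ihi;
      lp += ordlogit_lpmf_grad((int)y[t], eta, kap, de, dlo, dhi, ilo, ihi);
      if (ilo >= 0) gkap[ilo] += dlo;
      if (ihi >= 0) gkap[ihi] += dhi;
      double pl = plan ? 1.0 : 0.0;
      gUo[j] += de * p[t] * s * (1.0 - pl);
      gCp[j] += de * (pl - p[t]);
      gCi[j] += de * (-crank[t]);
      gUl[j] += de * (pl - 1.0);
      if (scaling) {
        double dS = de * p[t] * Uo[j] * (1.0 - pl);
        if (gain[t]) gSg[j] += dS; else gSl[j] += dS;
      }
    }
    if (shared_ci) { gxc += arma::accu(gCi); }

    // chain rule x = exp(y): dl/dy = dl/dx * x + 1 (Jacobian already in lp)
    for (int j = 0; j < n_subj; ++j) {
      int o = off_subj + j * blk;
      g[o + i_uo()] += gUo[j] * Uo[j] + 1.0;
      g[o + i_cp()] += gCp[j] * Cp[j] + 1.0;
      g[o + i_ul()] += gUl[j] * Ul[j] + 1.0;
      if (!shared_ci) g[o + i_ci()] += gCi[j] * Ci[j] + 1.0;
      if (scaling) {
        g[o + i_sg()] += gSg[j] * Sg[j] + 1.0;
        g[o + i_sl()] += gSl[j] * Sl[j] + 1.0;
      }
    }
    if (shared_ci) g[8] += gxc * xc + 1.0;

    // cut-point chain rule
    g[4] += gkap[0] + gkap[1] + gkap[2] + gkap[3];
    g[5] += (gkap[1] + gkap[2] + gkap[3]) * std::exp(th[5]) + 1.0;
    g[6] += (gkap[2] + gkap[3]) * std::exp(th[6]) + 1.0;
    g[7] += gkap[3] * std::exp(th[7]) + 1.0;
    return lp;
  }
};

// ---------------------------------------------------------------------------
// NUTS

struct PSPoint {
  arma::vec q, r, g;
  double logp;
};

struct NutsCtx {
  const HierModel* model;
  arma::vec minv;            // inverse metric (posterior variances)
  double eps;
  double joint0;
  double sum_alpha;
  int n_alpha;
  bool divergent;
  int n_grad;
};

static double joint_(const PSPoint& z, const arma::vec& minv) {
  return z.logp - 0.5 * arma::dot(minv % z.r, z.r);
}

static void leapfrog_(NutsCtx& c, PSPoint& z, double direction) {
  double e = direction * c.eps;
  z.r += 0.5 * e * z.g;
  z.q += e * (c.minv % z.r);
  z.logp = c.model->logp_grad(z.q, z.g);
  z.r += 0.5 * e * z.g;
  c.n_grad++;
}

static bool no_uturn_(const arma::vec& qm, const arma::vec& rm,
                      const arma::vec& qp, const arma::vec& rp,
                      const arma::vec& minv) {
  arma::vec dq = qp - qm;
  return arma::dot(dq, minv % rm) >= 0.0 && arma::dot(dq, minv % rp) >= 0.0;
}

struct TreeOut {
  PSPoint zm, zp;       // boundary states
  arma::vec qprop;
  double logw;          // logsumexp of (joint - joint0) over leaves
  bool ok;
};

static double logsumexp2_(double a, double b) {
  double m = std::max(a, b);
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static TreeOut build_tree_(NutsCtx& c, PSPoint z, int depth, double direction) {
  TreeOut out;
  if (depth == 0) {
    leapfrog_(c, z, direction);
    double j = joint_(z, c.minv);
    double dh = j - c.joint0;
    if (!std::isfinite(dh)) dh = -1e10;
    if (dh < -1000.0) { c.divergent = true; out.ok = false; out.logw = -1e10; out.zm = z; out.zp = z; out.qprop = z.q;
      c.sum_alpha += 0.0; c.n_alpha += 1; return out; }
    c.sum_alpha += std::min(1.0, std::exp(dh));
    c.n_alpha += 1;
    out.zm = z; out.zp = z; out.qprop = z.q; out.logw = dh; out.ok = true;
    return out;
  }
  TreeOut first = build_tree_(c, z, depth - 1, direction);
  if (!first.ok) return first;
  PSPoint edge = (direction > 0) ? first.zp : first.zm;
  TreeOut second = build_tree_(c, edge, depth - 1, direction);
  TreeOut out2;
  out2.ok = false;
  if (!second.ok) { out2 = second; return out2; }
  double logw = logsumexp2_(first.logw, second.logw);
  arma::vec qprop = first.qprop;
  if (std::log(::unif_rand()) < second.logw - logw) qprop = second.qprop;
  out2.zm = (direction > 0) ? first.zm : second.zm;
  out2.zp = (direction > 0) ? second.zp : first.zp;
  out2.qprop = qprop;
  out2.logw = logw;
  out2.ok = no_uturn_(out2.zm.q, out2.zm.r, out2.zp.q, out2.zp.r, c.minv);
  return out2;
}

// one NUTS transition; returns new position and updates ctx diagnostics
static arma::vec nuts_once_(NutsCtx& c, const arma::vec& q0, int max_depth,
                            int& treedepth) {
  int d = q0.n_elem;
  PSPoint z;
  z.q = q0;
  z.g.set_size(d);
  z.logp = c.model->logp_grad(z.q, z.g);
  c.n_grad++;
  z.r.set_size(d);
  for (int i = 0; i < d; ++i) z.r[i] = ::norm_rand() / std::sqrt(c.minv[i]);
  c.joint0 = joint_(z, c.minv);
  c.divergent = false;
  c.sum_alpha = 0.0; c.n_alpha = 0;

  PSPoint zm = z, zp = z;
  arma::vec qsel = z.q;
  double logw = 0.0;     // weight of the initial point: joint - joint0 = 0
  treedepth = 0;
  for (int depth = 0; depth < max_depth; ++depth) {
    double direction = (::unif_rand() < 0.5) ? -1.0 : 1.0;
    TreeOut t = build_tree_(c, (direction > 0) ? zp : zm, depth, direction);
    if (c.divergent) break;
    if (!t.ok) break;
    // biased progressive sampling toward the new subtree
    if (std::log(::unif_rand()) < t.logw - logw) qsel = t.qprop;
    logw = logsumexp2_(logw, t.logw);
    if (direction > 0) zp = t.zp; else zm = t.zm;
    treedepth = depth + 1;
    if (!no_uturn_(zm.q, zm.r, zp.q, zp.r, c.minv)) break;
  }
  return qsel;
}

// [[Rcpp::export]]
List nuts_chain(List data, bool scaling, bool shared_ci, List priors,
                int iter, int warmup, double init_radius, int max_depth,
                double target_accept) {
  HierModel model(data, scaling, shared_ci, priors);
  int d = model.dim();

  NutsCtx c;
  c.model = &model;
  c.minv = arma::vec(d, arma::fill::ones);
  c.n_grad = 0;

  arma::vec q(d);
  for (int i = 0; i < d; ++i) q[i] = (2.0 * ::unif_rand() - 1.0) * init_radius;

  // crude step-size initialization: scale until acceptance crosses 0.5
  {
    PSPoint z; z.q = q; z.g.set_size(d);
    z.logp = model.logp_grad(z.q, z.g);
    z.r.set_size(d);
    for (int i = 0; i < d; ++i) z.r[i] = ::norm_rand();
    double j0 = joint_(z, c.minv);
    c.eps = 0.1;
    for (int tries = 0; tries < 50; ++tries) {
      PSPoint zt = z;
      leapfrog_(c, zt, 1.0);
      double dh = joint_(zt, c.minv) - j0;
      if (!std::isfinite(dh)) dh = -1e10;
      if (dh > std::log(0.5)) { c.eps *= 2.0; }
      else { c.eps *= 0.5; if (dh > std::log(0.25)) break; }
      if (c.eps < 1e-8 || c.eps > 1e4) break;
    }
  }

  // dual averaging state
  double mu_da = std::log(10.0 * c.eps), log_eps_bar = 0.0, hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kap_da = 0.75;
  int da_count = 0;

  // mass adaptation windows (Stan-like)
  int init_buf = std::min(75, (int)(0.15 * warmup));
  int term_buf = std::min(50, (int)(0.10 * warmup));
  int window = 25;
  int win_start = init_buf;
  int win_end = std::min(win_start + window, warmup - term_buf);
  arma::vec wm(d, arma::fill::zeros), wm2(d, arma::fill::zeros);
  int wn = 0;

  int n_keep = iter - warmup;
  arma::mat draws(n_keep, d);
  IntegerVector divergences(n_keep);
  IntegerVector depths(n_keep);
  NumericVector accepts(n_keep);
  int warm_div = 0;

  for (int it = 0; it < iter; ++it) {
    int treedepth = 0;
    q = nuts_once_(c, q, max_depth, treedepth);
    double alpha = (c.n_alpha > 0) ? c.sum_alpha / c.n_alpha : 0.0;

    if (it < warmup) {
      if (c.divergent) warm_div++;
      // dual averaging
      da_count++;
      double frac = 1.0 / (da_count + t0);
      hbar = (1.0 - frac) * hbar + frac * (target_accept - alpha);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma * hbar;
      double w = std::pow((double)da_count, -kap_da);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      c.eps = std::exp(log_eps);

      // variance accumulation in slow windows
      if (it >= win_start && it < win_end) {
        wn++;
        arma::vec dq = q - wm;
        wm += dq / wn;
        wm2 += dq % (q - wm);
        if (it == win_end - 1) {
          if (wn > 2) {
            arma::vec var = wm2 / (wn - 1);
            c.minv = var * ((double)wn / (wn + 5.0)) + 1e-3 * (5.0 / (wn + 5.0));
          }
          wm.zeros(); wm2.zeros(); wn = 0;
          window *= 2;
          win_start = win_end;
          win_end = std::min(win_start + window, warmup - term_buf);
          if (warmup - term_buf - win_end < 2 * window) win_end = warmup - term_buf;
          // restart step-size adaptation around current eps
          mu_da = std::log(10.0 * c.eps);
          hbar = 0.0; da_count = 0; log_eps_bar = std::log(c.eps);
        }
      }
      if (it == warmup - 1) c.eps = std::exp(log_eps_bar);
    } else {
      int k = it - warmup;
      draws.row(k) = q.t();
      divergences[k] = c.divergent ? 1 : 0;
      depths[k] = treedepth;
      accepts[k] = alpha;
    }
  }

  return List::create(_["draws"] = draws,
                      _["divergent"] = divergences,
                      _["treedepth"] = depths,
                      _["accept_stat"] = accepts,
                      _["step_size"] = c.eps,
                      _["inv_metric"] = c.minv,
                      _["warmup_divergences"] = warm_div,
                      _["n_grad"] = c.n_grad);
}

// [[Rcpp::export]]
List hier_logp_grad(NumericVector theta, List data, bool scaling,
                    bool shared_ci, List priors) {
  HierModel model(data, scaling, shared_ci, priors);
  arma::vec th = as<arma::vec>(theta);
  arma::vec g(model.dim());
  double lp = model.logp_grad(th, g);
  return List::create(_["logp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// [[Rcpp::export]]
int hier_dim(List data, bool scaling, bool shared_ci, List priors) {
  HierModel model(data, scaling, shared_ci, priors);
  return model.dim();
}
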