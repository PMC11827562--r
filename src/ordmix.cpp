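// Random-intercept cumulative-logit (mixed-effects ordered logistic) model:
// negative log-likelihood and gradient, marginalizing the subject intercept
// b_j ~ N(0, sigma^2) by Gauss-Hermite quadrature.
//
// theta = [cut1, log-increments (K-2), beta (p), log_sigma]

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log1pexp2_(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// ordered logistic log-pmf with K categories and gradient wrt eta and cuts
static double olp_(int y, double eta, const arma::vec& kap, int K,
                   double& d_eta, arma::vec& d_kap) {
  if (y == 1) {
    double b = kap[0] - eta;
    double smb = 1.0 / (1.0 + std::exp(b));   // sigma(-b)
    d_eta = -smb; d_kap[0] += 0.0;            // caller applies weights; set below
    d_kap[0] = smb;
    return -log1pexp2_(-b);
  }
  if (y == K) {
    double a = kap[K - 2] - eta;
    double sa = 1.0 / (1.0 + std::exp(-a));
    d_eta = sa; d_kap[K - 2] = -sa;
    return -log1pexp2_(a);
  }
  int lo = y - 2, hi = y - 1;
  double a = kap[lo] - eta, b = kap[hi] - eta;
  double lP = -a - log1pexp2_(-a) - log1pexp2_(-b) + std::log1p(-std::exp(a - b));
  double lda = -log1pexp2_(-a) - log1pexp2_(a);
  double ldb = -log1pexp2_(-b) - log1pexp2_(b);
  double ra = std::exp(lda - lP), rb = std::exp(ldb - lP);
  d_eta = ra - rb; d_kap[lo] = -ra; d_kap[hi] = rb;
  return lP;
}

// [[Rcpp::export]]
List ordmix_nll_grad(NumericVector theta, IntegerVector y, NumericMatrix X,
                     IntegerVector subj, int n_subj, int K,
                     NumericVector gh_nodes, NumericVector gh_weights) {
  int n = y.size(), p = X.ncol(), Q = gh_nodes.size();
  int ncut = K - 1;
  arma::vec th = as<arma::vec>(theta);
  arma::vec kap(ncut);
  kap[0] = th[0];
  for (int k = 1; k < ncut; ++k) kap[k] = kap[k - 1] + std::exp(th[k]);
  arma::vec beta = th.subvec(ncut, ncut + p - 1);
  double lsig = th[ncut + p];
  double sigma = std::exp(lsig);

  arma::mat Xa = as<arma::mat>(X);
  arma::vec eta0 = Xa * beta;

  // log w~_q = log(w_q / sqrt(pi)); offset b_q = sqrt(2) * sigma * x_q
  arma::vec lw(Q), bq(Q);
  for (int q = 0; q < Q; ++q) {
    lw[q] = std::log(gh_weights[q]) - 0.5 * std::log(M_PI);
    bq[q] = M_SQRT2 * sigma * gh_nodes[q];
  }

  // pass 1: per-subject per-node conditional log-likelihoods
  arma::mat ll(n_subj, Q, arma::fill::zeros);
  arma::vec dkap_dummy(ncut, arma::fill::zeros);
  for (int t = 0; t < n; ++t) {
    int j = subj[t];
    for (int q = 0; q < Q; ++q) {
      double de;
      dkap_dummy.zeros();
      ll(j, q) += olp_(y[t], eta0[t] + bq[q], kap, K, de, dkap_dummy);
    }
  }
  double nll = 0.0;
  arma::mat alpha(n_subj, Q);
  for (int j = 0; j < n_subj; ++j) {
    double m = ll(j, 0) + lw[0];
    for (int q = 1; q < Q; ++q) m = std::max(m, ll(j, q) + lw[q]);
    double s = 0.0;
    for (int q = 0; q < Q; ++q) s += std::exp(ll(j, q) + lw[q] - m);
    double lj = m + std::log(s);
    nll -= lj;
    for (int q = 0; q < Q; ++q) alpha(j, q) = std::exp(ll(j, q) + lw[q] - lj);
  }

  // pass 2: gradient
  arma::vec gkap(ncut, arma::fill::zeros), gbeta(p, arma::fill::zeros);
  double glsig = 0.0;
  arma::vec dkap(ncut);
  for (int t = 0; t < n; ++t) {
    int j = subj[t];
    for (int q = 0; q < Q; ++q) {
      double a = alpha(j, q);
      if (a < 1e-14) continue;
      double de;
      dkap.zeros();
      olp_(y[t], eta0[t] + bq[q], kap, K, de, dkap);
      gkap += a * dkap;
      for (int c = 0; c < p; ++c) gbeta[c] += a * de * Xa(t, c);
      glsig += a * de * bq[q];   // d eta/d log sigma = sqrt2 * x_q * sigma = bq
    }
  }

  // chain rule for cut increments; negate for NLL
  arma::vec g(th.n_elem, arma::fill::zeros);
  for (int k = 0; k < ncut; ++k) {
    double acc = 0.0;
    for (int m = k; m < ncut; ++m) acc += gkap[m];
    g[k] = (k == 0) ? acc : acc * std::exp(th[k]);
  }
  for (int c = 0; c < p; ++c) g[ncut + c] = gbeta[c];
  g[ncut + p] = glsig;
  g = -g;
  return List::create(_["nll"] = nll,
                      _["grad"] = NumericVector(g.begin(), g.end()));
}
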