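// Hamiltonian Monte Carlo for the dyadic Beta regression with two
// multi-membership random intercepts (individuals and samples of each dyad).
//
// Likelihood: y_d ~ Beta(mu_d * phi, (1 - mu_d) * phi)
//   logit(mu_d) = x_d' beta + u[a_d] + u[b_d] + w[sa_d] + w[sb_d]
// Centred parameterisation (dyadic data strongly informs each group
// effect, so centred mixes better than non-centred here).
// Unconstrained parameter vector theta:
//   [ beta (p) | u (n_u) | w (n_w) | log sigma_u | log sigma_w | log phi ]
// (sigma blocks are present only when the corresponding n_* > 0).
//
// Priors: beta_j ~ N(0, prior_beta_sd^2); z ~ N(0, 1);
//         sigma ~ half-Student-t(df, 0, scale); phi ~ Gamma(shape, rate).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// fast digamma: upward recurrence to x >= 8, then asymptotic series
static inline double digamma_fast(double x) {
  double acc = 0.0;
  while (x < 8.0) { acc -= 1.0 / x; x += 1.0; }
  const double inv = 1.0 / x, inv2 = inv * inv;
  return acc + std::log(x) - 0.5 * inv -
    inv2 * (1.0 / 12.0 - inv2 * (1.0 / 120.0 - inv2 / 252.0));
}

struct BmmData {
  NumericVector y, ly, l1my, lity;  // y, log y, log(1-y), logit y
  NumericMatrix X;                  // n x p, includes intercept
  NumericMatrix Rinv;               // p x p: beta = Rinv * theta_beta
  bool use_rinv;
  std::vector<double> Xr;           // row-major copy of X for locality
  IntegerVector ia, ib, sa, sb;     // 0-based group indices (-1 = unused)
  int n, p, n_u, n_w;
  // prior hyperparameters
  double beta_sd, sig_df, sig_scale, phi_shape, phi_rate;
  // layout
  int off_zu, off_zw, i_lsu, i_lsw, i_lphi, npar;
};

static BmmData make_data(const List& data, const List& prior) {
  BmmData d;
  d.y = data["y"];
  d.X = as<NumericMatrix>(data["X"]);
  d.use_rinv = data.containsElementNamed("Rinv");
  if (d.use_rinv) d.Rinv = as<NumericMatrix>(data["Rinv"]);
  d.ia = data["ia"]; d.ib = data["ib"];
  d.sa = data["sa"]; d.sb = data["sb"];
  d.n_u = as<int>(data["n_u"]);
  d.n_w = as<int>(data["n_w"]);
  d.n = d.y.size();
  d.p = d.X.ncol();
  d.ly = NumericVector(d.n); d.l1my = NumericVector(d.n);
  d.lity = NumericVector(d.n);
  for (int i = 0; i < d.n; ++i) {
    d.ly[i] = std::log(d.y[i]);
    d.l1my[i] = std::log1p(-d.y[i]);
    d.lity[i] = d.ly[i] - d.l1my[i];
  }
  d.Xr.resize((size_t)d.n * d.p);
  for (int i = 0; i < d.n; ++i)
    for (int j = 0; j < d.p; ++j) d.Xr[(size_t)i * d.p + j] = d.X(i, j);
  d.beta_sd = as<double>(prior["beta_sd"]);
  d.sig_df = as<double>(prior["sigma_df"]);
  d.sig_scale = as<double>(prior["sigma_scale"]);
  d.phi_shape = as<double>(prior["phi_shape"]);
  d.phi_rate = as<double>(prior["phi_rate"]);
  d.off_zu = d.p;
  d.off_zw = d.p + d.n_u;
  int k = d.p + d.n_u + d.n_w;
  d.i_lsu = (d.n_u > 0) ? k++ : -1;
  d.i_lsw = (d.n_w > 0) ? k++ : -1;
  d.i_lphi = k++;
  d.npar = k;
  return d;
}

// log half-Student-t(df, scale) density of sigma plus log-Jacobian (sigma =
// exp(ls)); constant terms dropped
static inline double lp_half_t(double ls, double df, double scale) {
  double s = std::exp(ls);
  double q = 1.0 + (s * s) / (df * scale * scale);
  return -0.5 * (df + 1.0) * std::log(q) + ls;
}
static inline double dlp_half_t(double ls, double df, double scale) {
  double s = std::exp(ls);
  double q = 1.0 + (s * s) / (df * scale * scale);
  // d/dls = dlogp/dsigma * sigma + 1
  return -(df + 1.0) * (s * s) / (df * scale * scale * q) + 1.0;
}

static double log_post(const BmmData& d, const NumericVector& th,
                       bool& ok) {
  ok = true;
  const double su = (d.i_lsu >= 0) ? std::exp(th[d.i_lsu]) : 0.0;
  const double sw = (d.i_lsw >= 0) ? std::exp(th[d.i_lsw]) : 0.0;
  const double phi = std::exp(th[d.i_lphi]);
  if (!R_finite(phi) || phi <= 0) { ok = false; return -INFINITY; }
  const double lg_phi = std::lgamma(phi);
  double ll = 0.0;
  for (int i = 0; i < d.n; ++i) {
    const double* xi = &d.Xr[(size_t)i * d.p];
    double eta = 0.0;
    for (int j = 0; j < d.p; ++j) eta += xi[j] * th[j];
    if (d.n_u > 0) eta += th[d.off_zu + d.ia[i]] + th[d.off_zu + d.ib[i]];
    if (d.n_w > 0) eta += th[d.off_zw + d.sa[i]] + th[d.off_zw + d.sb[i]];
    const double mu = 1.0 / (1.0 + std::exp(-eta));
    const double a = mu * phi, b = (1.0 - mu) * phi;
    if (a <= 0 || b <= 0) { ok = false; return -INFINITY; }
    ll += lg_phi - std::lgamma(a) - std::lgamma(b) +
      (a - 1.0) * d.ly[i] + (b - 1.0) * d.l1my[i];
  }
  // priors (the Normal prior is on beta = Rinv * theta when the design
  // was QR-reparameterised)
  double lp = 0.0;
  if (d.use_rinv) {
    for (int r = 0; r < d.p; ++r) {
      double beta_r = 0.0;
      for (int j = 0; j < d.p; ++j) beta_r += d.Rinv(r, j) * th[j];
      lp -= 0.5 * beta_r * beta_r / (d.beta_sd * d.beta_sd);
    }
  } else {
    for (int j = 0; j < d.p; ++j) lp -= 0.5 * th[j] * th[j] / (d.beta_sd * d.beta_sd);
  }
  if (d.n_u > 0) {
    const double inv2 = 1.0 / (2.0 * su * su);
    for (int k = 0; k < d.n_u; ++k)
      lp -= th[d.off_zu + k] * th[d.off_zu + k] * inv2;
    lp -= d.n_u * th[d.i_lsu];
  }
  if (d.n_w > 0) {
    const double inv2 = 1.0 / (2.0 * sw * sw);
    for (int k = 0; k < d.n_w; ++k)
      lp -= th[d.off_zw + k] * th[d.off_zw + k] * inv2;
    lp -= d.n_w * th[d.i_lsw];
  }
  if (d.i_lsu >= 0) lp += lp_half_t(th[d.i_lsu], d.sig_df, d.sig_scale);
  if (d.i_lsw >= 0) lp += lp_half_t(th[d.i_lsw], d.sig_df, d.sig_scale);
  lp += d.phi_shape * th[d.i_lphi] - d.phi_rate * phi;  // Gamma + Jacobian
  double out = ll + lp;
  if (!R_finite(out)) { ok = false; return -INFINITY; }
  return out;
}

static void grad_log_post(const BmmData& d, const NumericVector& th,
                          NumericVector& g, bool& ok) {
  ok = true;
  std::fill(g.begin(), g.end(), 0.0);
  const double su = (d.i_lsu >= 0) ? std::exp(th[d.i_lsu]) : 0.0;
  const double sw = (d.i_lsw >= 0) ? std::exp(th[d.i_lsw]) : 0.0;
  const double phi = std::exp(th[d.i_lphi]);
  if (!R_finite(phi) || phi <= 0) { ok = false; return; }
  const double dig_phi = digamma_fast(phi);
  double dphi = 0.0;
  for (int i = 0; i < d.n; ++i) {
    const double* xi = &d.Xr[(size_t)i * d.p];
    double eta = 0.0;
    for (int j = 0; j < d.p; ++j) eta += xi[j] * th[j];
    if (d.n_u > 0) eta += th[d.off_zu + d.ia[i]] + th[d.off_zu + d.ib[i]];
    if (d.n_w > 0) eta += th[d.off_zw + d.sa[i]] + th[d.off_zw + d.sb[i]];
    const double mu = 1.0 / (1.0 + std::exp(-eta));
    const double a = mu * phi, b = (1.0 - mu) * phi;
    if (a <= 0 || b <= 0) { ok = false; return; }
    const double dig_a = digamma_fast(a), dig_b = digamma_fast(b);
    const double geta = phi * mu * (1.0 - mu) * (d.lity[i] - dig_a + dig_b);
    for (int j = 0; j < d.p; ++j) g[j] += geta * xi[j];
    if (d.n_u > 0) {
      g[d.off_zu + d.ia[i]] += geta;
      g[d.off_zu + d.ib[i]] += geta;
    }
    if (d.n_w > 0) {
      g[d.off_zw + d.sa[i]] += geta;
      g[d.off_zw + d.sb[i]] += geta;
    }
    dphi += dig_phi - mu * dig_a - (1.0 - mu) * dig_b +
      mu * d.ly[i] + (1.0 - mu) * d.l1my[i];
  }
  g[d.i_lphi] += phi * dphi;
  // priors
  if (d.use_rinv) {
    for (int r = 0; r < d.p; ++r) {
      double beta_r = 0.0;
      for (int j = 0; j < d.p; ++j) beta_r += d.Rinv(r, j) * th[j];
      const double s = beta_r / (d.beta_sd * d.beta_sd);
      for (int j = 0; j < d.p; ++j) g[j] -= d.Rinv(r, j) * s;
    }
  } else {
    for (int j = 0; j < d.p; ++j) g[j] -= th[j] / (d.beta_sd * d.beta_sd);
  }
  if (d.n_u > 0) {
    const double inv2 = 1.0 / (su * su);
    double ssq = 0.0;
    for (int k = 0; k < d.n_u; ++k) {
      g[d.off_zu + k] -= th[d.off_zu + k] * inv2;
      ssq += th[d.off_zu + k] * th[d.off_zu + k];
    }
    g[d.i_lsu] += ssq * inv2 - d.n_u;
  }
  if (d.n_w > 0) {
    const double inv2 = 1.0 / (sw * sw);
    double ssq = 0.0;
    for (int k = 0; k < d.n_w; ++k) {
      g[d.off_zw + k] -= th[d.off_zw + k] * inv2;
      ssq += th[d.off_zw + k] * th[d.off_zw + k];
    }
    g[d.i_lsw] += ssq * inv2 - d.n_w;
  }
  if (d.i_lsu >= 0) g[d.i_lsu] += dlp_half_t(th[d.i_lsu], d.sig_df, d.sig_scale);
  if (d.i_lsw >= 0) g[d.i_lsw] += dlp_half_t(th[d.i_lsw], d.sig_df, d.sig_scale);
  g[d.i_lphi] += d.phi_shape - d.phi_rate * phi;
  for (int j = 0; j < d.npar; ++j) {
    if (!R_finite(g[j])) { ok = false; return; }
  }
}

// [[Rcpp::export(name = ".bmm_logpost")]]
double bmm_logpost(List data, List prior, NumericVector theta) {
  BmmData d = make_data(data, prior);
  if (theta.size() != d.npar) stop("theta has wrong length");
  bool ok;
  return log_post(d, theta, ok);
}

// [[Rcpp::export(name = ".bmm_grad")]]
NumericVector bmm_grad(List data, List prior, NumericVector theta) {
  BmmData d = make_data(data, prior);
  if (theta.size() != d.npar) stop("theta has wrong length");
  NumericVector g(d.npar);
  bool ok;
  grad_log_post(d, theta, g, ok);
  return g;
}

// one HMC transition; returns new log posterior, updates theta in place
static double hmc_step(const BmmData& d, NumericVector& th, double lp0,
                       double eps, int L, const NumericVector& inv_mass,
                       double& accept_prob) {
  const int K = d.npar;
  NumericVector p(K), th1 = clone(th), g(K);
  double kin0 = 0.0;
  for (int j = 0; j < K; ++j) {
    p[j] = R::norm_rand() / std::sqrt(inv_mass[j]);
    kin0 += 0.5 * p[j] * p[j] * inv_mass[j];
  }
  bool ok;
  grad_log_post(d, th1, g, ok);
  if (!ok) { accept_prob = 0.0; return lp0; }
  // leapfrog
  for (int l = 0; l < L; ++l) {
    for (int j = 0; j < K; ++j) p[j] += 0.5 * eps * g[j];
    for (int j = 0; j < K; ++j) th1[j] += eps * inv_mass[j] * p[j];
    grad_log_post(d, th1, g, ok);
    if (!ok) { accept_prob = 0.0; return lp0; }
    for (int j = 0; j < K; ++j) p[j] += 0.5 * eps * g[j];
  }
  double lp1 = log_post(d, th1, ok);
  if (!ok) { accept_prob = 0.0; return lp0; }
  double kin1 = 0.0;
  for (int j = 0; j < K; ++j) kin1 += 0.5 * p[j] * p[j] * inv_mass[j];
  double logr = (lp1 - kin1) - (lp0 - kin0);
  accept_prob = (logr >= 0) ? 1.0 : std::exp(logr);
  if (R::unif_rand() < accept_prob) {
    th = th1;
    return lp1;
  }
  return lp0;
}

// [[Rcpp::export(name = ".bmm_sample")]]
List bmm_sample(List data, List prior, NumericVector init, int chains,
                int warmup, int iter, int max_leapfrog, double adapt_delta,
                double init_jitter) {
  BmmData d = make_data(data, prior);
  if (init.size() != d.npar) stop("init has wrong length");
  RNGScope scope;
  NumericMatrix draws(iter * chains, d.npar);
  IntegerVector chain_id(iter * chains);
  NumericVector accept(chains), step_size(chains);

  for (int c = 0; c < chains; ++c) {
    NumericVector th = clone(init);
    for (int j = 0; j < d.npar; ++j) th[j] += init_jitter * R::norm_rand();
    NumericVector inv_mass(d.npar, 1.0);
    bool ok;
    double lp = log_post(d, th, ok);
    if (!ok) stop("non-finite log posterior at initial values");

    // dual averaging (Hoffman & Gelman 2014 defaults)
    double eps = 0.1 / std::pow((double)d.npar, 0.25);
    double mu_da = std::log(10.0 * eps), log_eps_bar = 0.0, Hbar = 0.0;
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    int adapt_count = 0;

    // variance accumulation window for the diagonal mass matrix
    const int win_lo = warmup / 4, win_hi = (3 * warmup) / 4;
    NumericVector m1(d.npar, 0.0), m2(d.npar, 0.0);
    int nacc = 0;

    for (int t = 0; t < warmup; ++t) {
      int L = (int)std::ceil(max_leapfrog * (0.8 + 0.2 * R::unif_rand()));
      double ap;
      lp = hmc_step(d, th, lp, eps, L, inv_mass, ap);
      ++adapt_count;
      Hbar += (1.0 / (adapt_count + t0)) *
        ((adapt_delta - ap) - Hbar);
      double log_eps = mu_da - std::sqrt((double)adapt_count) / gamma * Hbar;
      double w = std::pow((double)adapt_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (t >= win_lo && t < win_hi) {
        ++nacc;
        for (int j = 0; j < d.npar; ++j) {
          double del = th[j] - m1[j];
          m1[j] += del / nacc;
          m2[j] += del * (th[j] - m1[j]);
        }
      }
      if (t == win_hi - 1 && nacc > 10) {
        for (int j = 0; j < d.npar; ++j) {
          double v = m2[j] / (nacc - 1);
          inv_mass[j] = (v > 1e-10) ? v : 1e-10;
        }
        // restart step-size adaptation under the new metric
        eps = std::exp(log_eps_bar);
        mu_da = std::log(10.0 * eps);
        Hbar = 0.0; log_eps_bar = 0.0; adapt_count = 0;
      }
    }
    eps = std::exp(log_eps_bar);
    if (!R_finite(eps) || eps <= 0) eps = 0.01;
    step_size[c] = eps;

    double acc_sum = 0.0;
    for (int t = 0; t < iter; ++t) {
      int L = (int)std::ceil(max_leapfrog * (0.8 + 0.2 * R::unif_rand()));
      double ap;
      lp = hmc_step(d, th, lp, eps, L, inv_mass, ap);
      acc_sum += ap;
      int row = c * iter + t;
      for (int j = 0; j < d.npar; ++j) draws(row, j) = th[j];
      chain_id[row] = c + 1;
    }
    accept[c] = acc_sum / iter;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["accept"] = accept, _["step_size"] = step_size);
}
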