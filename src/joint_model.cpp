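// Joint Bayesian model for one ordinal (cumulative proportional-odds,
// exceedance parameterization) plus d-1 binary outcomes, with hierarchical
// shrinkage of the treatment main effect and A-by-X interactions across
// outcomes, sampled by a hand-written No-U-Turn sampler.
//
// Unconstrained parameter layout (length depends on hier):
//   [0, L-1)              u        ordinal intercepts: tau_1 = u_0,
//                                  tau_y = tau_{y-1} - exp(u_y)  (y >= 2)
//   [L-1, L-1 + d-1)      tau_bin  binary-outcome intercepts (free)
//   next d*p              m        covariate main effects, outcome-major
//   next d*(p+1)          z | b    hier: standardized coefficients z_{k,j};
//                                  flat: b_{k,j} directly (j = 0 is the
//                                  treatment main effect)
//   hier only, next p+1   beta_star pooled effects
//   hier only, next p+1   log_sigma log of shrinkage SDs sigma_{beta_j}
//
// b_{k,j} = beta_star_j + sigma_j * z_{k,j} (non-centered).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double log_logistic(double z) {
  // log G(z), numerically stable
  return (z < 0.0) ? z - std::log1p(std::exp(z)) : -std::log1p(std::exp(-z));
}
static inline double logistic(double z) {
  return (z < 0.0) ? std::exp(z) / (1.0 + std::exp(z)) : 1.0 / (1.0 + std::exp(-z));
}
static inline double log_dlogistic(double z) {
  // log g(z) = log G(z) + log G(-z)
  return log_logistic(z) + log_logistic(-z);
}

struct JointModel {
  arma::mat X;        // n x p
  arma::vec A;        // n, 0/1
  arma::ivec yord;    // n, 0..L-1
  arma::imat Ybin;    // n x (d-1)
  int n, p, d, L;
  bool hier;
  bool centered = false;  // hierarchical block parameterization
  double m_scale, b_scale, bstar_scale, sigma_mean, t_df, t_scale;
  double lik_scale;   // 0 disables the likelihood (prior sampling)

  int off_taub, off_m, off_b, off_star, off_ls, npar;

  void set_offsets() {
    off_taub = L - 1;
    off_m = off_taub + (d - 1);
    off_b = off_m + d * p;
    off_star = off_b + d * (p + 1);
    off_ls = off_star + (p + 1);
    npar = hier ? (off_ls + (p + 1)) : off_star;
  }

  double t_lpdf(double x) const {
    // Student-t(df, 0, scale), constants dropped
    return -0.5 * (t_df + 1.0) * std::log1p(x * x / (t_df * t_scale * t_scale));
  }
  double t_grad(double x) const {
    return -(t_df + 1.0) * x / (t_df * t_scale * t_scale + x * x);
  }

  // log posterior density (unnormalized, on the unconstrained scale,
  // including transform Jacobians) and its gradient.
  double logpost_grad(const arma::vec& q, arma::vec& grad) const {
    grad.zeros(npar);
    arma::vec tau(L - 1);
    tau(0) = q(0);
    for (int y = 1; y < L - 1; ++y) tau(y) = tau(y - 1) - std::exp(q(y));

    // coefficient block
    arma::mat b(d, p + 1);
    arma::vec sigma, bstar;
    if (hier) {
      bstar = q.subvec(off_star, off_star + p);
      sigma = arma::exp(q.subvec(off_ls, off_ls + p));
      for (int k = 0; k < d; ++k)
        for (int j = 0; j <= p; ++j)
          b(k, j) = centered ? q(off_b + k * (p + 1) + j)
                             : bstar(j) + sigma(j) * q(off_b + k * (p + 1) + j);
    } else {
      for (int k = 0; k < d; ++k)
        for (int j = 0; j <= p; ++j)
          b(k, j) = q(off_b + k * (p + 1) + j);
    }

    double lp = 0.0;
    arma::vec gtau(L - 1, arma::fill::zeros);
    arma::mat gb(d, p + 1, arma::fill::zeros);  // wrt b on natural scale

    for (int k = 0; k < d; ++k) {
      arma::vec mk(p);
      for (int j = 0; j < p; ++j) mk(j) = q(off_m + k * p + j);
      arma::vec bint(p);
      for (int j = 0; j < p; ++j) bint(j) = b(k, j + 1);
      arma::vec theta = X * mk + A % (b(k, 0) + X * bint);

      arma::vec dtheta(n, arma::fill::zeros);
      if (k == 0) {
        // ordinal multinomial likelihood via exceedance increments;
        // arithmetic fast path with a log-stable fallback for far tails
        for (int i = 0; i < n; ++i) {
          int y = yord(i);
          double th = theta(i), lpi, dth;
          if (y == 0) {
            double clo = tau(0) + th;
            double Glo = logistic(clo);
            lpi = log_logistic(-clo);       // log(1 - G)
            dth = -Glo;                     // -g/(1-G)
            gtau(0) -= lik_scale * Glo;
          } else if (y == L - 1) {
            double chi = tau(L - 2) + th;
            double Ghi = logistic(chi);
            lpi = log_logistic(chi);
            dth = 1.0 - Ghi;                // g/G
            gtau(L - 2) += lik_scale * (1.0 - Ghi);
          } else {
            double chi = tau(y - 1) + th;   // upper threshold (larger)
            double clo = tau(y) + th;
            double Ghi = logistic(chi), Glo = logistic(clo);
            double pdiff = Ghi - Glo;
            double rhi, rlo;
            if (pdiff > 1e-12) {
              lpi = std::log(pdiff);
              rhi = Ghi * (1.0 - Ghi) / pdiff;
              rlo = Glo * (1.0 - Glo) / pdiff;
            } else {
              lpi = log_logistic(clo) + log_logistic(-chi) +
                    std::log(std::expm1(chi - clo));
              rhi = std::exp(log_dlogistic(chi) - lpi);
              rlo = std::exp(log_dlogistic(clo) - lpi);
            }
            dth = rhi - rlo;
            gtau(y - 1) += lik_scale * rhi;
            gtau(y) -= lik_scale * rlo;
          }
          lp += lik_scale * lpi;
          dtheta(i) = lik_scale * dth;
        }
      } else {
        double tb = q(off_taub + k - 1);
        for (int i = 0; i < n; ++i) {
          double eta = tb + theta(i);
          int y = Ybin(i, k - 1);
          double G, l1mG;  // logistic(eta), log(1 - logistic(eta))
          if (eta < 0) {
            double e = std::exp(eta);
            G = e / (1.0 + e);
            l1mG = -std::log1p(e);
          } else {
            double e = std::exp(-eta);
            G = 1.0 / (1.0 + e);
            l1mG = -eta - std::log1p(e);
          }
          lp += lik_scale * (y * eta + l1mG);
          dtheta(i) = lik_scale * (y - G);
        }
        grad(off_taub + k - 1) += arma::accu(dtheta);
      }

      // chain rule theta -> (m_k, b_k)
      arma::vec gm = X.t() * dtheta;
      for (int j = 0; j < p; ++j) grad(off_m + k * p + j) += gm(j);
      arma::vec w = A % dtheta;
      gb(k, 0) += arma::accu(w);
      arma::vec gbi = X.t() * w;
      for (int j = 0; j < p; ++j) gb(k, j + 1) += gbi(j);
    }

    // ---- priors ----
    // covariate main effects: Normal(0, m_scale)
    for (int k = 0; k < d; ++k)
      for (int j = 0; j < p; ++j) {
        double v = q(off_m + k * p + j);
        lp += -0.5 * v * v / (m_scale * m_scale);
        grad(off_m + k * p + j) += -v / (m_scale * m_scale);
      }

    // intercept priors (Student-t on the constrained tau values)
    for (int y = 0; y < L - 1; ++y) {
      lp += t_lpdf(tau(y));
      gtau(y) += t_grad(tau(y));
    }
    for (int k = 1; k < d; ++k) {
      double tb = q(off_taub + k - 1);
      lp += t_lpdf(tb);
      grad(off_taub + k - 1) += t_grad(tb);
    }

    // coefficient block priors + chain rule for b
    if (hier) {
      for (int j = 0; j <= p; ++j) {
        double s2 = sigma(j) * sigma(j);
        double gsum = 0.0, gzsum = 0.0;
        for (int k = 0; k < d; ++k) {
          double v = q(off_b + k * (p + 1) + j);
          if (centered) {
            double dev = v - bstar(j);            // b ~ N(bstar, sigma)
            lp += -0.5 * dev * dev / s2 - q(off_ls + j);
            grad(off_b + k * (p + 1) + j) += gb(k, j) - dev / s2;
            gsum += dev / s2;
            gzsum += -1.0 + dev * dev / s2;
          } else {
            lp += -0.5 * v * v;                   // z ~ N(0,1)
            grad(off_b + k * (p + 1) + j) += sigma(j) * gb(k, j) - v;
            gsum += gb(k, j);
            gzsum += sigma(j) * v * gb(k, j);
          }
        }
        double bs = bstar(j);
        lp += -0.5 * bs * bs / (bstar_scale * bstar_scale);
        grad(off_star + j) += gsum - bs / (bstar_scale * bstar_scale);
        // sigma_j ~ Exponential(mean sigma_mean), log transform Jacobian
        lp += -sigma(j) / sigma_mean + q(off_ls + j);
        grad(off_ls + j) += gzsum - sigma(j) / sigma_mean + 1.0;
      }
    } else {
      for (int k = 0; k < d; ++k)
        for (int j = 0; j <= p; ++j) {
          double v = b(k, j);
          lp += -0.5 * v * v / (b_scale * b_scale);
          grad(off_b + k * (p + 1) + j) += gb(k, j) - v / (b_scale * b_scale);
        }
    }

    // ordinal intercept transform: Jacobian + chain rule tau -> u
    double csum = 0.0;
    for (int y = L - 2; y >= 1; --y) {
      csum += gtau(y);
      grad(y) += -std::exp(q(y)) * csum + 1.0;  // +1 = d/du of Jacobian u_y
      lp += q(y);
    }
    grad(0) += csum + gtau(0);

    if (!std::isfinite(lp)) lp = -arma::datum::inf;
    return lp;
  }
};

// ---------------- NUTS ----------------

struct Tree {
  arma::vec q_minus, r_minus, g_minus, q_plus, r_plus, g_plus, q_prop, g_prop;
  double lp_minus, lp_plus, lp_prop;
  int n_valid;
  bool ok;          // no divergence, no U-turn inside
  bool divergent;
  double sum_alpha;
  int n_alpha;
};

struct Sampler {
  const JointModel& model;
  arma::vec inv_mass;   // diagonal of M^{-1} (diagonal metric)
  bool dense = false;
  arma::mat Sigma;      // dense M^{-1}
  arma::mat Lsig;       // lower Cholesky of Sigma
  double eps;
  double max_delta = 1000.0;

  Sampler(const JointModel& m) : model(m) {}

  arma::vec metric_times(const arma::vec& r) const {
    return dense ? arma::vec(Sigma * r) : arma::vec(inv_mass % r);
  }

  arma::vec draw_momentum() const {
    int npar = model.npar;
    arma::vec xi(npar);
    for (int i = 0; i < npar; ++i) xi(i) = norm_rand();
    if (dense) {
      // r ~ N(0, Sigma^{-1}): solve L^T r = xi
      return arma::solve(arma::trimatu(Lsig.t()), xi);
    }
    return xi / arma::sqrt(inv_mass);
  }

  double kinetic(const arma::vec& r) const {
    return 0.5 * arma::dot(r, metric_times(r));
  }

  void leapfrog(arma::vec& q, arma::vec& r, arma::vec& g, double& lp,
                double direction) const {
    double e = direction * eps;
    r += 0.5 * e * g;
    q += e * metric_times(r);
    lp = model.logpost_grad(q, g);
    r += 0.5 * e * g;
  }

  bool no_uturn(const arma::vec& q_minus, const arma::vec& q_plus,
                const arma::vec& r_minus, const arma::vec& r_plus) const {
    arma::vec dq = q_plus - q_minus;
    return arma::dot(dq, metric_times(r_minus)) >= 0.0 &&
           arma::dot(dq, metric_times(r_plus)) >= 0.0;
  }

  Tree build_tree(const arma::vec& q, const arma::vec& r, const arma::vec& g,
                  double lp, double logu, int v, int j, double H0) const {
    Tree t;
    if (j == 0) {
      arma::vec q1 = q, r1 = r, g1 = g;
      double lp1 = lp;
      leapfrog(q1, r1, g1, lp1, (double)v);
      double H = lp1 - kinetic(r1);
      t.q_minus = t.q_plus = t.q_prop = q1;
      t.r_minus = t.r_plus = r1;
      t.g_minus = t.g_plus = t.g_prop = g1;
      t.lp_minus = t.lp_plus = t.lp_prop = lp1;
      t.n_valid = (logu <= H) ? 1 : 0;
      t.divergent = !(logu < H + max_delta) || !std::isfinite(H);
      t.ok = !t.divergent;
      double a = std::exp(std::min(0.0, H - H0));
      t.sum_alpha = std::isfinite(a) ? a : 0.0;
      t.n_alpha = 1;
      return t;
    }
    Tree left = build_tree(q, r, g, lp, logu, v, j - 1, H0);
    if (!left.ok) return left;
    Tree right;
    if (v == -1)
      right = build_tree(left.q_minus, left.r_minus, left.g_minus,
                         left.lp_minus, logu, v, j - 1, H0);
    else
      right = build_tree(left.q_plus, left.r_plus, left.g_plus,
                         left.lp_plus, logu, v, j - 1, H0);
    Tree t2;
    if (v == -1) {
      t2.q_minus = right.q_minus; t2.r_minus = right.r_minus;
      t2.g_minus = right.g_minus; t2.lp_minus = right.lp_minus;
      t2.q_plus = left.q_plus; t2.r_plus = left.r_plus;
      t2.g_plus = left.g_plus; t2.lp_plus = left.lp_plus;
    } else {
      t2.q_minus = left.q_minus; t2.r_minus = left.r_minus;
      t2.g_minus = left.g_minus; t2.lp_minus = left.lp_minus;
      t2.q_plus = right.q_plus; t2.r_plus = right.r_plus;
      t2.g_plus = right.g_plus; t2.lp_plus = right.lp_plus;
    }
    t2.n_valid = left.n_valid + right.n_valid;
    t2.sum_alpha = left.sum_alpha + right.sum_alpha;
    t2.n_alpha = left.n_alpha + right.n_alpha;
    t2.divergent = right.divergent;
    if (right.n_valid > 0 &&
        unif_rand() < (double)right.n_valid / std::max(1, t2.n_valid)) {
      t2.q_prop = right.q_prop; t2.g_prop = right.g_prop;
      t2.lp_prop = right.lp_prop;
    } else {
      t2.q_prop = left.q_prop; t2.g_prop = left.g_prop;
      t2.lp_prop = left.lp_prop;
    }
    t2.ok = right.ok && !t2.divergent &&
            no_uturn(t2.q_minus, t2.q_plus, t2.r_minus, t2.r_plus);
    return t2;
  }
};

static double find_initial_eps(Sampler& s, const arma::vec& q0,
                               const arma::vec& g0, double lp0) {
  arma::vec r = s.draw_momentum();
  double H0 = lp0 - s.kinetic(r);
  s.eps = 1.0;
  arma::vec q = q0, g = g0, r1 = r;
  double lp = lp0;
  s.leapfrog(q, r1, g, lp, 1.0);
  double H = lp - s.kinetic(r1);
  if (!std::isfinite(H)) { s.eps = 0.1; return s.eps; }
  double a = (H - H0 > std::log(0.5)) ? 1.0 : -1.0;
  for (int it = 0; it < 50; ++it) {
    q = q0; g = g0; r1 = r; lp = lp0;
    s.leapfrog(q, r1, g, lp, 1.0);
    H = lp - s.kinetic(r1);
    double dH = std::isfinite(H) ? H - H0 : -arma::datum::inf;
    if (a * dH <= a * std::log(0.5)) break;
    s.eps *= std::pow(2.0, a);
  }
  return s.eps;
}

inline bool no_uturn_outer(const Sampler& s, const Tree& t);

// Run one chain.  Expects the R RNG to be seeded by the caller.
// [[Rcpp::export]]
List nuts_chain_cpp(const arma::mat& X, const arma::vec& A,
                    const arma::ivec& yord, const arma::imat& Ybin,
                    int L, bool hier, List prior, double lik_scale,
                    int warmup, int iter, double target_accept,
                    int max_treedepth, const arma::vec& init,
                    bool dense_mass = true, bool centered = false) {
  JointModel m;
  m.X = X; m.A = A; m.yord = yord; m.Ybin = Ybin;
  m.n = X.n_rows; m.p = X.n_cols; m.d = 1 + Ybin.n_cols; m.L = L;
  m.hier = hier;
  m.centered = centered;
  m.m_scale = as<double>(prior["m_scale"]);
  m.b_scale = as<double>(prior["b_scale"]);
  m.bstar_scale = as<double>(prior["bstar_scale"]);
  m.sigma_mean = as<double>(prior["sigma_mean"]);
  m.t_df = as<double>(prior["t_df"]);
  m.t_scale = as<double>(prior["t_scale"]);
  m.lik_scale = lik_scale;
  m.set_offsets();
  int npar = m.npar;
  if ((int)init.n_elem != npar) stop("init has wrong length");

  Sampler s(m);
  s.inv_mass = arma::vec(npar, arma::fill::ones);

  arma::vec q = init, g(npar);
  double lp = m.logpost_grad(q, g);
  if (!std::isfinite(lp)) stop("non-finite log density at initial values");

  // dual averaging state
  find_initial_eps(s, q, g, lp);
  double mu = std::log(10.0 * s.eps), log_ebar = std::log(s.eps);
  double Hbar = 0.0;
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_m = 0;

  // Stan-style windowed mass adaptation (dense or diagonal metric)
  int init_buffer = 75, term_buffer = 50, base_window = 25;
  bool adapt_mass = warmup >= init_buffer + term_buffer + base_window;
  int window_end = adapt_mass ? init_buffer + base_window : -1;
  int window_size = base_window;
  arma::vec welford_m(npar, arma::fill::zeros);
  arma::mat welford_S(npar, npar, arma::fill::zeros);
  int welford_n = 0;

  arma::mat draws(iter, npar);
  arma::vec lp_out(iter);
  IntegerVector divergent(iter), treedepth(iter);
  NumericVector accept_stat(iter), stepsizes(iter);
  int div_warmup = 0;

  int total = warmup + iter;
  for (int it = 0; it < total; ++it) {
    arma::vec r = s.draw_momentum();
    double H0 = lp - s.kinetic(r);
    double logu = H0 - exp_rand();

    Tree t;
    t.q_minus = t.q_plus = t.q_prop = q;
    t.r_minus = t.r_plus = r;
    t.g_minus = t.g_plus = t.g_prop = g;
    t.lp_minus = t.lp_plus = t.lp_prop = lp;
    t.n_valid = 1;
    t.ok = true; t.divergent = false;
    t.sum_alpha = 0.0; t.n_alpha = 0;

    int depth = 0;
    bool div_this = false;
    double sum_alpha = 0.0;
    int n_alpha = 0;
    while (t.ok && depth < max_treedepth) {
      int v = (unif_rand() < 0.5) ? -1 : 1;
      Tree sub;
      if (v == -1)
        sub = s.build_tree(t.q_minus, t.r_minus, t.g_minus, t.lp_minus, logu,
                           v, depth, H0);
      else
        sub = s.build_tree(t.q_plus, t.r_plus, t.g_plus, t.lp_plus, logu,
                           v, depth, H0);
      sum_alpha += sub.sum_alpha;
      n_alpha += sub.n_alpha;
      if (sub.divergent) div_this = true;
      if (sub.ok && sub.n_valid > 0 &&
          unif_rand() < (double)sub.n_valid / std::max(1, t.n_valid)) {
        t.q_prop = sub.q_prop; t.g_prop = sub.g_prop; t.lp_prop = sub.lp_prop;
      }
      if (v == -1) {
        t.q_minus = sub.q_minus; t.r_minus = sub.r_minus;
        t.g_minus = sub.g_minus; t.lp_minus = sub.lp_minus;
      } else {
        t.q_plus = sub.q_plus; t.r_plus = sub.r_plus;
        t.g_plus = sub.g_plus; t.lp_plus = sub.lp_plus;
      }
      t.n_valid += sub.n_valid;
      t.ok = sub.ok && no_uturn_outer(s, t);
      ++depth;
    }
    q = t.q_prop; g = t.g_prop; lp = t.lp_prop;
    double alpha = (n_alpha > 0) ? sum_alpha / n_alpha : 0.0;

    if (it < warmup) {
      if (div_this) ++div_warmup;
      // dual averaging
      ++da_m;
      Hbar = (1.0 - 1.0 / (da_m + t0)) * Hbar +
             (target_accept - alpha) / (da_m + t0);
      double log_eps = mu - std::sqrt((double)da_m) / gamma * Hbar;
      s.eps = std::exp(log_eps);
      double w = std::pow((double)da_m, -kappa);
      log_ebar = w * log_eps + (1.0 - w) * log_ebar;

      if (adapt_mass && it >= init_buffer && it < warmup - term_buffer) {
        ++welford_n;
        arma::vec delta = q - welford_m;
        welford_m += delta / welford_n;
        welford_S += delta * (q - welford_m).t();
        if (it + 1 == window_end) {
          if (welford_n > 1) {
            double w = welford_n / (welford_n + 5.0);
            double reg = 1e-3 * (5.0 / (welford_n + 5.0));
            arma::mat cov = welford_S / (welford_n - 1.0);
            if (dense_mass) {
              arma::mat Sig = w * cov + reg * arma::eye(npar, npar);
              arma::mat Lc;
              if (arma::chol(Lc, Sig, "lower")) {
                s.Sigma = Sig; s.Lsig = Lc; s.dense = true;
              } else {
                s.inv_mass = w * cov.diag() + reg; s.dense = false;
              }
            } else {
              s.inv_mass = w * cov.diag() + reg;
            }
          }
          welford_m.zeros(); welford_S.zeros(); welford_n = 0;
          // restart step-size adaptation around the current value
          find_initial_eps(s, q, g, lp);
          mu = std::log(10.0 * s.eps);
          log_ebar = std::log(s.eps);
          Hbar = 0.0; da_m = 0;
          window_size *= 2;
          window_end = it + 1 + window_size;
          if (window_end + window_size + term_buffer > warmup)
            window_end = warmup - term_buffer;
        }
      }
      if (it == warmup - 1) s.eps = std::exp(log_ebar);
    } else {
      int k = it - warmup;
      draws.row(k) = q.t();
      lp_out(k) = lp;
      divergent[k] = div_this ? 1 : 0;
      treedepth[k] = depth;
      accept_stat[k] = alpha;
      stepsizes[k] = s.eps;
    }
  }

  return List::create(
      _["draws"] = draws, _["lp"] = lp_out, _["divergent"] = divergent,
      _["treedepth"] = treedepth, _["accept_stat"] = accept_stat,
      _["stepsize"] = s.eps, _["divergent_warmup"] = div_warmup,
      _["inv_mass"] = s.dense ? arma::vec(s.Sigma.diag()) : s.inv_mass);
}

// helper used above (defined after to keep the loop readable)
inline bool no_uturn_outer(const Sampler& s, const Tree& t) {
  return s.no_uturn(t.q_minus, t.q_plus, t.r_minus, t.r_plus);
}

// Log posterior and gradient on the unconstrained scale (for tests).
// [[Rcpp::export]]
List logpost_grad_cpp(const arma::vec& q, const arma::mat& X,
                      const arma::vec& A, const arma::ivec& yord,
                      const arma::imat& Ybin, int L, bool hier, List prior,
                      double lik_scale, bool centered = false) {
  JointModel m;
  m.X = X; m.A = A; m.yord = yord; m.Ybin = Ybin;
  m.n = X.n_rows; m.p = X.n_cols; m.d = 1 + Ybin.n_cols; m.L = L;
  m.hier = hier;
  m.centered = centered;
  m.m_scale = as<double>(prior["m_scale"]);
  m.b_scale = as<double>(prior["b_scale"]);
  m.bstar_scale = as<double>(prior["bstar_scale"]);
  m.sigma_mean = as<double>(prior["sigma_mean"]);
  m.t_df = as<double>(prior["t_df"]);
  m.t_scale = as<double>(prior["t_scale"]);
  m.lik_scale = lik_scale;
  m.set_offsets();
  if ((int)q.n_elem != m.npar) stop("parameter vector has wrong length");
  arma::vec g(m.npar);
  double lp = m.logpost_grad(q, g);
  return List::create(_["lp"] = lp, _["grad"] = g);
}
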