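// Fast path for the hierarchical adaptive forgetting variational filter.
// Mirrors the R reference implementation step for step (same finite
// difference constants, same sweep order) so the two engines agree to
// numerical precision.

#include <Rcpp.h>
using namespace Rcpp;

static const double H_AB = 1e-5;  // relative FD step in Beta shapes

struct Nig {
  double mu, kappa, alpha, beta;
};
struct Bb {
  double a, b;
};

static inline Nig weighted_prior(const Nig &p, const Nig &p0, double w) {
  Nig r;
  r.kappa = w * p.kappa + (1 - w) * p0.kappa;
  r.mu = (w * p.kappa * p.mu + (1 - w) * p0.kappa * p0.mu) / r.kappa;
  r.alpha = w * p.alpha + (1 - w) * p0.alpha;
  r.beta = w * p.beta + (1 - w) * p0.beta +
           0.5 * (w * p.kappa * (p.mu - r.mu) * (p.mu - r.mu) +
                  (1 - w) * p0.kappa * (p0.mu - r.mu) * (p0.mu - r.mu));
  return r;
}

static inline Nig nig_update(const Nig &p, const Nig &p0, double w, double x) {
  Nig r;
  r.kappa = w * p.kappa + (1 - w) * p0.kappa + 1.0;
  r.mu = (w * p.kappa * p.mu + (1 - w) * p0.kappa * p0.mu + x) / r.kappa;
  r.alpha = w * p.alpha + (1 - w) * p0.alpha + 0.5;
  r.beta = w * p.beta + (1 - w) * p0.beta +
           0.5 * (w * p.kappa * (r.mu - p.mu) * (r.mu - p.mu) +
                  (1 - w) * p0.kappa * (r.mu - p0.mu) * (r.mu - p0.mu) +
                  (x - r.mu) * (x - r.mu));
  return r;
}

static inline double nig_part(const Nig &t) {
  return R::lgammafn(t.alpha) - t.alpha * std::log(t.beta) -
         0.5 * std::log(t.kappa);
}

static inline double nig_logz(const Nig &p, const Nig &p0, double w) {
  Nig h = weighted_prior(p, p0, w);
  return nig_part(h) - w * nig_part(p) - (1 - w) * nig_part(p0);
}

// analytic d^2 log Z / dw^2 (second derivative of the log-partition along
// the straight line in natural-parameter space)
static inline double logz_d2(const Nig &p, const Nig &p0, double w) {
  double da = p.alpha - p0.alpha;
  double dk = p.kappa - p0.kappa;
  double d1 = (p.beta + p.kappa * p.mu * p.mu / 2) -
              (p0.beta + p0.kappa * p0.mu * p0.mu / 2);
  double d2n = p.kappa * p.mu - p0.kappa * p0.mu;
  double kap = w * p.kappa + (1 - w) * p0.kappa;
  double alp = w * p.alpha + (1 - w) * p0.alpha;
  double n1 = w * (p.beta + p.kappa * p.mu * p.mu / 2) +
              (1 - w) * (p0.beta + p0.kappa * p0.mu * p0.mu / 2);
  double n2 = w * p.kappa * p.mu + (1 - w) * p0.kappa * p0.mu;
  double bet = n1 - n2 * n2 / (2 * kap);
  double b1 = d1 - n2 * d2n / kap + n2 * n2 * dk / (2 * kap * kap);
  double b2 = -(d2n * d2n / kap - 2 * n2 * d2n * dk / (kap * kap) +
                n2 * n2 * dk * dk / (kap * kap * kap));
  return R::trigamma(alp) * da * da - 2 * da * b1 / bet -
         alp * (b2 * bet - b1 * b1) / (bet * bet) +
         dk * dk / (2 * kap * kap);
}

static inline double elogz_taylor(const Nig &p, const Nig &p0, double a,
                                  double b) {
  double s = a + b;
  double w = a / s;
  double v = a * b / (s * s * (s + 1));
  return nig_logz(p, p0, w) + 0.5 * v * logz_d2(p, p0, w);
}

static inline double lbeta_(double a, double b) { return R::lbeta(a, b); }

static inline double beta_logz(const Bb &p, const Bb &p0, double w) {
  double ah = w * p.a + (1 - w) * p0.a;
  double bh = w * p.b + (1 - w) * p0.b;
  return lbeta_(ah, bh) - w * lbeta_(p.a, p.b) - (1 - w) * lbeta_(p0.a, p0.b);
}

static inline double beta_logz_d2(const Bb &p, const Bb &p0, double w) {
  double da = p.a - p0.a;
  double db = p.b - p0.b;
  double ah = w * p.a + (1 - w) * p0.a;
  double bh = w * p.b + (1 - w) * p0.b;
  return R::trigamma(ah) * da * da + R::trigamma(bh) * db * db -
         R::trigamma(ah + bh) * (da + db) * (da + db);
}

static inline double beta_elogz_taylor(const Bb &p, const Bb &p0, double a,
                                       double b) {
  double s = a + b;
  double w = a / s;
  double v = a * b / (s * s * (s + 1));
  return beta_logz(p, p0, w) + 0.5 * v * beta_logz_d2(p, p0, w);
}

// E_q[log NIG(z|th)] under q = NIG(t)
static inline double e_log_nig(const Nig &t, const Nig &th) {
  double el2 = std::log(t.beta) - R::digamma(t.alpha);
  double einv = t.alpha / t.beta;
  double equad = einv * (t.mu - th.mu) * (t.mu - th.mu) + 1.0 / t.kappa;
  return 0.5 * std::log(th.kappa / (2 * M_PI)) +
         th.alpha * std::log(th.beta) - R::lgammafn(th.alpha) -
         (th.alpha + 1.5) * el2 - th.beta * einv - 0.5 * th.kappa * equad;
}

static inline double e_log_lik_norm(const Nig &t, double x) {
  double el2 = std::log(t.beta) - R::digamma(t.alpha);
  return -0.5 * std::log(2 * M_PI) - 0.5 * el2 -
         0.5 * ((t.alpha / t.beta) * (x - t.mu) * (x - t.mu) + 1.0 / t.kappa);
}

static inline double e_log_beta(const Bb &q, const Bb &sh) {
  double d = R::digamma(q.a + q.b);
  return (sh.a - 1) * (R::digamma(q.a) - d) +
         (sh.b - 1) * (R::digamma(q.b) - d) - lbeta_(sh.a, sh.b);
}

static inline double beta_entropy(const Bb &q) {
  return lbeta_(q.a, q.b) - (q.a - 1) * R::digamma(q.a) -
         (q.b - 1) * R::digamma(q.b) +
         (q.a + q.b - 2) * R::digamma(q.a + q.b);
}

// expected log-joint terms depending on q(w) (entropy excluded)
struct SwCtx {
  const Nig *tp, *t0;
  double delta, ca, cb;
};

static inline double S_w(const SwCtx &c, double a, double b) {
  double w = a / (a + b);
  double d = R::digamma(a + b);
  return w * c.delta - elogz_taylor(*c.tp, *c.t0, a, b) +
         c.ca * (R::digamma(a) - d) + c.cb * (R::digamma(b) - d);
}

struct SbCtx {
  const Bb *pp, *p0;
  double xw, ca, cb;
};

static inline double S_b(const SbCtx &c, double a, double b) {
  double w = a / (a + b);
  double d = R::digamma(a + b);
  return w * c.xw - beta_elogz_taylor(*c.pp, *c.p0, a, b) +
         c.ca * (R::digamma(a) - d) + c.cb * (R::digamma(b) - d);
}

// smooth positivity guard (matches the R reference implementation): keeps
// the trajectory continuous in the prior parameters, unlike a hard
// reject-and-keep branch
static const double GUARD_EPS = 1e-3;
static const double GUARD_K = 50.0;
static inline double softplus_(double x) {
  return x > 30 ? x : std::log1p(std::exp(std::min(x, 30.0)));
}
static inline double ncvmp_guard(double x) {
  return GUARD_EPS + softplus_(GUARD_K * (x - GUARD_EPS)) / GUARD_K;
}

// generic damped NCVMP step; S evaluated through fn(ctx, a, b)
template <typename Ctx, double (*fn)(const Ctx &, double, double)>
static inline Bb ncvmp_step(const Ctx &ctx, const Bb &old, double damping) {
  double a = old.a, b = old.b;
  double ha = H_AB * std::max(1.0, a);
  double hb = H_AB * std::max(1.0, b);
  double ga = (fn(ctx, a + ha, b) - fn(ctx, a - ha, b)) / (2 * ha);
  double gb = (fn(ctx, a, b + hb) - fn(ctx, a, b - hb)) / (2 * hb);
  double tab = R::trigamma(a + b);
  double c11 = R::trigamma(a) - tab, c22 = R::trigamma(b) - tab;
  double det = c11 * c22 - tab * tab;
  if (det <= 0 || !R_FINITE(det)) return old;
  double la = (c22 * ga + tab * gb) / det;
  double lb = (tab * ga + c11 * gb) / det;
  double na = la + 1, nb = lb + 1;
  if (!R_FINITE(na) || !R_FINITE(nb)) return old;
  na = ncvmp_guard(na);
  nb = ncvmp_guard(nb);
  Bb out;
  out.a = (1 - damping) * a + damping * na;
  out.b = (1 - damping) * b + damping * nb;
  return out;
}

static inline double trial_elbo(const Nig &tj, const Bb &pj, const Bb &bj,
                                const Nig &tp, const Bb &pp, const Bb &bp,
                                const Nig &t0, const Bb &p0, const Bb &b0,
                                double x) {
  double w = pj.a / (pj.a + pj.b);
  double bh = bj.a / (bj.a + bj.b);
  return e_log_lik_norm(tj, x) + w * e_log_nig(tj, tp) +
         (1 - w) * e_log_nig(tj, t0) - elogz_taylor(tp, t0, pj.a, pj.b) +
         bh * e_log_beta(pj, pp) + (1 - bh) * e_log_beta(pj, p0) -
         beta_elogz_taylor(pp, p0, bj.a, bj.b) + e_log_beta(bj, bp) -
         e_log_nig(tj, tj) + beta_entropy(pj) + beta_entropy(bj);
}

struct UpdateResult {
  Nig theta;
  Bb phi, beta2;
  double elbo;
  int iter;
};

static UpdateResult update1(const Nig &tp, const Bb &pp, const Bb &bp,
                            const Nig &t0, const Bb &p0, const Bb &b0,
                            double x, double tol, int max_iter,
                            double damping) {
  double bh0 = bp.a / (bp.a + bp.b);
  Bb pj;
  pj.a = bh0 * pp.a + (1 - bh0) * p0.a;
  pj.b = bh0 * pp.b + (1 - bh0) * p0.b;
  Bb bj = bp;
  Nig tj = tp;
  double elbo_old = R_NegInf, elbo = NA_REAL;
  int it = 0;
  while (it < max_iter) {
    ++it;
    double w = pj.a / (pj.a + pj.b);
    tj = nig_update(tp, t0, w, x);
    SwCtx cw;
    cw.tp = &tp;
    cw.t0 = &t0;
    cw.delta = e_log_nig(tj, tp) - e_log_nig(tj, t0);
    double bh = bj.a / (bj.a + bj.b);
    cw.ca = bh * pp.a + (1 - bh) * p0.a - 1;
    cw.cb = bh * pp.b + (1 - bh) * p0.b - 1;
    pj = ncvmp_step<SwCtx, S_w>(cw, pj, damping);
    SbCtx cb;
    cb.pp = &pp;
    cb.p0 = &p0;
    cb.xw = e_log_beta(pj, pp) - e_log_beta(pj, p0);
    cb.ca = bp.a - 1;
    cb.cb = bp.b - 1;
    bj = ncvmp_step<SbCtx, S_b>(cb, bj, damping);
    elbo = trial_elbo(tj, pj, bj, tp, pp, bp, t0, p0, b0, x);
    if (tol > 0 && R_FINITE(elbo) && std::fabs(elbo - elbo_old) < tol) break;
    elbo_old = elbo;
  }
  UpdateResult r;
  r.theta = tj;
  r.phi = pj;
  r.beta2 = bj;
  r.elbo = elbo;
  r.iter = it;
  return r;
}

// [[Rcpp::export]]
NumericMatrix hafvf_filter_cpp(NumericVector x, NumericVector theta0,
                               NumericVector phi0, NumericVector beta0,
                               double tol, int max_iter, double damping) {
  int n = x.size();
  Nig t0 = {theta0[0], theta0[1], theta0[2], theta0[3]};
  Bb p0 = {phi0[0], phi0[1]};
  Bb b0 = {beta0[0], beta0[1]};
  Nig tp = t0;
  Bb pp = p0, bp = b0;
  NumericMatrix out(n, 10);
  colnames(out) = CharacterVector::create("mu", "kappa", "alpha", "beta",
                                          "phi_a", "phi_b", "beta_a",
                                          "beta_b", "elbo", "n_iter");
  for (int j = 0; j < n; ++j) {
    UpdateResult r = update1(tp, pp, bp, t0, p0, b0, x[j], tol, max_iter,
                             damping);
    out(j, 0) = r.theta.mu;
    out(j, 1) = r.theta.kappa;
    out(j, 2) = r.theta.alpha;
    out(j, 3) = r.theta.beta;
    out(j, 4) = r.phi.a;
    out(j, 5) = r.phi.b;
    out(j, 6) = r.beta2.a;
    out(j, 7) = r.beta2.b;
    out(j, 8) = r.elbo;
    out(j, 9) = r.iter;
    tp = r.theta;
    pp = r.phi;
    bp = r.beta2;
  }
  return out;
}

// single-trial update on raw parameter vectors (used by session/MDP loops)
// [[Rcpp::export]]
NumericVector hafvf_update1_cpp(NumericVector theta_prev, NumericVector phi_prev,
                                NumericVector beta_prev, NumericVector theta0,
                                NumericVector phi0, NumericVector beta0,
                                double x, double tol, int max_iter,
                                double damping) {
  Nig tp = {theta_prev[0], theta_prev[1], theta_prev[2], theta_prev[3]};
  Bb pp = {phi_prev[0], phi_prev[1]};
  Bb bp = {beta_prev[0], beta_prev[1]};
  Nig t0 = {theta0[0], theta0[1], theta0[2], theta0[3]};
  Bb p0 = {phi0[0], phi0[1]};
  Bb b0 = {beta0[0], beta0[1]};
  UpdateResult r = update1(tp, pp, bp, t0, p0, b0, x, tol, max_iter, damping);
  return NumericVector::create(r.theta.mu, r.theta.kappa, r.theta.alpha,
                               r.theta.beta, r.phi.a, r.phi.b, r.beta2.a,
                               r.beta2.b, r.elbo, (double)r.iter);
}

// standardized first-passage density at the lower bound (zero drift, unit
// diffusion, bounds (0, 1) after time scaling); small/large-time series
// with the usual switch on required series length
// [[Rcpp::export]]
NumericVector wfpt_f0_cpp(NumericVector u, NumericVector w,
                          double err = 1e-10) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = u[i];
    double wi = w[w.size() == 1 ? 0 : i];
    if (!(t > 0)) {
      out[i] = 0.0;
      continue;
    }
    double ks = 2 + std::sqrt(std::max(
        0.0, -2 * t * std::log(2 * err * std::sqrt(2 * M_PI * t))));
    ks = std::max(ks, std::sqrt(t) + 1);
    double kl = std::sqrt(std::max(
        0.0, -2 * std::log(M_PI * t * err) / (M_PI * M_PI * t)));
    kl = std::max(kl, 1 / (M_PI * std::sqrt(t)));
    double f = 0;
    if (ks < kl) {
      int K = (int)std::ceil(ks);
      for (int k = -(K - 1) / 2; k <= (int)std::ceil((K - 1) / 2.0); ++k) {
        double z = wi + 2 * k;
        f += z * std::exp(-z * z / (2 * t));
      }
      f /= std::sqrt(2 * M_PI * t * t * t);
    } else {
      int K = (int)std::ceil(kl);
      for (int k = 1; k <= K; ++k) {
        f += k * std::exp(-k * k * M_PI * M_PI * t / 2) *
             std::sin(k * M_PI * wi);
      }
      f *= M_PI;
    }
    out[i] = f;
  }
  return out;
}

// Euler-discretized race between two absorbing bounds at 0 and zeta.
// Returns choice (1 = upper), rt in seconds (excluding non-decision time)
// and a censoring flag. Uses R's RNG so set.seed() applies.
// [[Rcpp::export]]
NumericMatrix euler_race_cpp(int n, NumericVector xi, NumericVector s2,
                             double zeta, double z0, double dt,
                             double max_steps) {
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("choice", "rt", "censored");
  RNGScope scope;
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double drift = xi[xi.size() == 1 ? 0 : i];
    double sd = std::sqrt(s2[s2.size() == 1 ? 0 : i]);
    double z = z0;
    double steps = 0;
    int choice = 0, censored = 0;
    double s2dt = sd * sd * dt;
    while (true) {
      steps += 1;
      double znew = z + dt * drift + sdt * sd * norm_rand();
      if (znew >= zeta) {
        choice = 1;
        z = znew;
        break;
      }
      if (znew <= 0) {
        choice = 2;
        z = znew;
        break;
      }
      // Brownian-bridge correction: the path may have touched a bound
      // within the step even though both endpoints are interior.
      double p_lo = std::exp(-2.0 * z * znew / s2dt);
      double p_hi = std::exp(-2.0 * (zeta - z) * (zeta - znew) / s2dt);
      double u = unif_rand();
      if (u < p_lo) {
        choice = 2;
        z = znew;
        break;
      }
      if (u < p_lo + p_hi) {
        choice = 1;
        z = znew;
        break;
      }
      z = znew;
      if (steps >= max_steps) {
        censored = 1;
        choice = (z >= z0) ? 1 : 2;
        break;
      }
    }
    out(i, 0) = choice;
    out(i, 1) = steps * dt;
    out(i, 2) = censored;
  }
  return out;
}
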