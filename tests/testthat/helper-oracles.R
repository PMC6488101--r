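## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## textbook NIG conjugate update of a single observation
oracle_nig_update <- function(mu, kappa, alpha, beta, x) {
  kap1 <- kappa + 1
  list(mu = (kappa * mu + x) / kap1,
       kappa = kap1,
       alpha = alpha + 0.5,
       beta = beta + kappa * (x - mu)^2 / (2 * (kappa + 1)))
}

## textbook NIG batch update of n observations via sufficient statistics
oracle_nig_batch <- function(mu, kappa, alpha, beta, xs) {
  n <- length(xs)
  xb <- mean(xs)
  ss <- sum((xs - xb)^2)
  kap1 <- kappa + n
  list(mu = (kappa * mu + n * xb) / kap1,
       kappa = kap1,
       alpha = alpha + n / 2,
       beta = beta + 0.5 * ss + kappa * n * (xb - mu)^2 / (2 * kap1))
}

## pure-R Wiener first-passage density at the lower bound (long series,
## independent of the package's small/large-time switch)
oracle_wiener_lower <- function(t, xi, s2, zeta, z0, K = 400) {
  sig <- sqrt(s2)
  v <- xi / sig
  a <- zeta / sig
  w <- z0 / zeta
  u <- t / a^2
  k <- seq_len(K)
  f0 <- pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
  if (u < 0.5) {  # small-time form is more accurate there
    kk <- -200:200
    f0 <- sum((w + 2 * kk) * exp(-(w + 2 * kk)^2 / (2 * u))) /
      sqrt(2 * pi * u^3)
  }
  f0 / a^2 * exp(-v * a * w - v^2 * t / 2)
}

## numeric CDF of the conditional RT distribution on a fine grid
oracle_rt_cdf <- function(choice, xi, s2, ddm, tmax = 60, n = 40000) {
  ts <- seq(1e-6, tmax, length.out = n)
  f <- exp(wiener_log_density(ts + ddm$tau, choice, xi, s2, ddm))
  cdf <- cumsum(c(0, diff(ts)) * f)
  cdf <- cdf / cdf[n]
  stats::approxfun(ts + ddm$tau, cdf, yleft = 0, yright = 1)
}

## exact P(mu1 > mu2) for two NIG posteriors by 2-d quadrature over the
## two inverse-gamma variances and the closed-form normal difference
oracle_qs_probability <- function(p1, p2, n_gl = 48) {
  gl <- pracma::gaussLegendre(n_gl, 0, 1)
  s1 <- 1 / stats::qgamma(gl$x, p1$alpha, rate = p1$beta)
  s2 <- 1 / stats::qgamma(gl$x, p2$alpha, rate = p2$beta)
  acc <- 0
  for (i in seq_len(n_gl)) {
    sd_d <- sqrt(s1[i] / p1$kappa + s2 / p2$kappa)
    acc <- acc + gl$w[i] *
      sum(gl$w * stats::pnorm((p1$mu - p2$mu) / sd_d))
  }
  acc / sum(gl$w)^1  # weights on (0,1) sum to 1
}

## quadrature log-marginal of one (choice, rt) trial under the NIGDM prior
oracle_trial_logmarginal <- function(rt, choice, omega, ddm, n_s = 24,
                                     n_xi = 48) {
  gl <- pracma::gaussLegendre(n_s, 0, 1)
  glx <- pracma::gaussLegendre(n_xi, -1, 1)
  s1 <- 1 / stats::qgamma(gl$x, omega$q1_alpha, rate = omega$q1_beta)
  s2 <- 1 / stats::qgamma(gl$x, omega$q2_alpha, rate = omega$q2_beta)
  mu_d <- omega$q1_mu - omega$q2_mu
  total <- 0
  for (i in seq_len(n_s)) {
    for (j in seq_len(n_s)) {
      v_xi <- s1[i] / omega$q1_kappa + s2[j] / omega$q2_kappa
      sd_xi <- sqrt(v_xi)
      xi_nodes <- mu_d + 6 * sd_xi * glx$x
      dens <- exp(wiener_log_density(rt, choice, xi_nodes, s1[i] + s2[j],
                                     ddm)) *
        stats::dnorm(xi_nodes, mu_d, sd_xi)
      total <- total + gl$w[i] * gl$w[j] * sum(glx$w * 6 * sd_xi * dens)
    }
  }
  log(total / (sum(gl$w)^2))
}
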