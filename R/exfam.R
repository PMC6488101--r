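#' Normal-Inverse-Gamma belief over a reward distribution
#'
#' Container for the conjugate posterior (or prior) of a normally distributed
#' reward with unknown mean and variance. The joint law is
#' \eqn{\mu_z \sim N(\mu, \sigma^2/\kappa)}, \eqn{\sigma^2 \sim
#' IG(\alpha, \beta)}. `kappa` plays the role of a pseudo-observation count
#' for the mean (the agent's *effective memory*), `alpha`/`beta` summarise
#' the evidence about the reward variance.
#'
#' @param mu Expected reward mean (real).
#' @param kappa Pseudo-observation count for the mean, in trials (> 0).
#' @param alpha Inverse-gamma shape (> 0).
#' @param beta Inverse-gamma rate, in squared reward units (> 0).
#' @return An object of class `nig_posterior`.
#' @examples
#' nig_posterior(0, 1, 1, 1)
#' @export
nig_posterior <- function(mu, kappa, alpha, beta) {
  stopifnot(
    is.numeric(mu), is.numeric(kappa), is.numeric(alpha), is.numeric(beta),
    length(mu) == 1L, length(kappa) == 1L, length(alpha) == 1L,
    length(beta) == 1L
  )
  if (!all(is.finite(c(mu, kappa, alpha, beta)))) {
    stop("nig_posterior parameters must be finite", call. = FALSE)
  }
  if (kappa <= 0 || alpha <= 0 || beta <= 0) {
    stop("kappa, alpha and beta must be strictly positive", call. = FALSE)
  }
  structure(list(mu = mu, kappa = kappa, alpha = alpha, beta = beta),
            class = "nig_posterior")
}

#' @export
print.nig_posterior <- function(x, ...) {
  cat(sprintf("<nig_posterior mu=%.4g kappa=%.4g alpha=%.4g beta=%.4g>\n",
              x$mu, x$kappa, x$alpha, x$beta))
  invisible(x)
}

#' Beta belief over a forgetting factor
#'
#' A `Beta(a, b)` distribution used for the first-level forgetting factor
#' `w` (weight of the previous posterior against the naive prior) and for
#' the second-level factor `b` (weight of the previous `w`-posterior against
#' the fixed `w`-prior).
#'
#' @param a,b Strictly positive shape parameters.
#' @return An object of class `beta_belief`.
#' @examples
#' beta_belief(4.5, 0.5) # strong prior belief in a stable environment
#' @export
beta_belief <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L)
  if (!all(is.finite(c(a, b))) || a <= 0 || b <= 0) {
    stop("beta_belief shapes must be finite and strictly positive",
         call. = FALSE)
  }
  structure(list(a = a, b = b), class = "beta_belief")
}

#' @export
print.beta_belief <- function(x, ...) {
  cat(sprintf("<beta_belief a=%.4g b=%.4g mean=%.4g>\n",
              x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' @export
mean.beta_belief <- function(x, ...) x$a / (x$a + x$b)

#' @rdname beta_belief
#' @param x Object to test.
#' @export
is_beta_belief <- function(x) inherits(x, "beta_belief")

beta_var <- function(phi) {
  s <- phi$a + phi$b
  phi$a * phi$b / (s^2 * (s + 1))
}

## ---------------------------------------------------------------------------
## Log-partition functions (moment parameterization). The base-measure
## constant 0.5*log(2*pi) cancels in every mixture normalizer and is omitted.

nig_log_partition <- function(theta) {
  lgamma(theta$alpha) - theta$alpha * log(theta$beta) - 0.5 * log(theta$kappa)
}

beta_log_partition <- function(phi) lbeta(phi$a, phi$b)

## ---------------------------------------------------------------------------

#' Forgetting-weighted mixture prior of a NIG belief
#'
#' Combines the previous posterior and the naive prior with exponential
#' weights `w_hat` and `1 - w_hat`. The combination is performed in
#' natural-parameter space, where the normalized mixture is again a NIG
#' distribution; expressed in moments, `kappa` and `alpha` combine linearly,
#' the mean combines through `kappa * mu`, and `beta` picks up a
#' mean-dispersion term.
#'
#' @param theta_prev [nig_posterior()] carried over from the previous trial.
#' @param theta0 Naive prior [nig_posterior()].
#' @param w_hat Expected forgetting factor in `[0, 1]`; 1 keeps the previous
#'   posterior, 0 resets to the naive prior.
#' @return The weighted prior as a [nig_posterior()].
#' @examples
#' weighted_prior(nig_posterior(1, 4, 2, 2), nig_posterior(0, 0.1, 1, 1), 0.5)
#' @export
weighted_prior <- function(theta_prev, theta0, w_hat) {
  stopifnot(inherits(theta_prev, "nig_posterior"),
            inherits(theta0, "nig_posterior"))
  if (!is.finite(w_hat) || w_hat < 0 || w_hat > 1) {
    stop("w_hat must lie in [0, 1]", call. = FALSE)
  }
  p <- weighted_prior_num(
    theta_prev$mu, theta_prev$kappa, theta_prev$alpha, theta_prev$beta,
    theta0$mu, theta0$kappa, theta0$alpha, theta0$beta, w_hat
  )
  nig_posterior(p[1], p[2], p[3], p[4])
}

## hot-path version on raw numerics: returns c(mu, kappa, alpha, beta)
weighted_prior_num <- function(mup, kp, ap, bp, mu0, k0, a0, b0, w) {
  kap <- w * kp + (1 - w) * k0
  mu  <- (w * kp * mup + (1 - w) * k0 * mu0) / kap
  alp <- w * ap + (1 - w) * a0
  bet <- w * bp + (1 - w) * b0 +
    0.5 * (w * kp * (mup - mu)^2 + (1 - w) * k0 * (mu0 - mu)^2)
  c(mu, kap, alp, bet)
}

#' Conjugate NIG update under the forgetting-weighted prior
#'
#' One-observation Bayesian update of the weighted mixture prior formed from
#' `theta_prev` and `theta0` with weight `w_hat`. With `w_hat = 1` this is
#' the textbook NIG conjugate update; with `w_hat = 0` it is memoryless.
#'
#' @inheritParams weighted_prior
#' @param x Observed reward (finite real).
#' @return Updated [nig_posterior()].
#' @examples
#' nig_update(nig_posterior(0, 1, 1, 1), nig_posterior(0, 1, 1, 1), 1, 2)
#' @export
nig_update <- function(theta_prev, theta0, w_hat, x) {
  stopifnot(inherits(theta_prev, "nig_posterior"),
            inherits(theta0, "nig_posterior"))
  if (!is.finite(x)) stop("observation x must be finite", call. = FALSE)
  if (!is.finite(w_hat) || w_hat < 0 || w_hat > 1) {
    stop("w_hat must lie in [0, 1]", call. = FALSE)
  }
  p <- nig_update_num(
    theta_prev$mu, theta_prev$kappa, theta_prev$alpha, theta_prev$beta,
    theta0$mu, theta0$kappa, theta0$alpha, theta0$beta, w_hat, x
  )
  nig_posterior(p[1], p[2], p[3], p[4])
}

nig_update_num <- function(mup, kp, ap, bp, mu0, k0, a0, b0, w, x) {
  kap <- w * kp + (1 - w) * k0 + 1
  mu  <- (w * kp * mup + (1 - w) * k0 * mu0 + x) / kap
  alp <- w * ap + (1 - w) * a0 + 0.5
  bet <- w * bp + (1 - w) * b0 +
    0.5 * (w * kp * (mu - mup)^2 + (1 - w) * k0 * (mu - mu0)^2 + (x - mu)^2)
  c(mu, kap, alp, bet)
}

#' Log normalizing constant of the exponential mixture prior
#'
#' Evaluates \eqn{\log Z(w) = \log \int p(z \mid \theta_{prev})^w
#' p(z \mid \theta_0)^{1-w} dz} for two NIG components. Because both
#' components share the same base measure, the integral reduces to a
#' difference of log-partition functions evaluated at the weighted natural
#' parameters: \eqn{\log Z = A(\hat\vartheta) - w A(\theta_{prev}) - (1-w)
#' A(\theta_0)}. The function is smooth in `w` on `(0, 1)` and vanishes at
#' the endpoints and whenever the two components coincide.
#'
#' @inheritParams weighted_prior
#' @param w Mixture weight in `[0, 1]`.
#' @return Log normalizer (scalar).
#' @export
mixture_log_normalizer <- function(theta_prev, theta0, w) {
  stopifnot(inherits(theta_prev, "nig_posterior"),
            inherits(theta0, "nig_posterior"))
  if (!is.finite(w) || w < 0 || w > 1) {
    stop("w must lie in [0, 1]", call. = FALSE)
  }
  nig_logz_num(theta_prev$mu, theta_prev$kappa, theta_prev$alpha,
               theta_prev$beta, theta0$mu, theta0$kappa, theta0$alpha,
               theta0$beta, w)
}

nig_logz_num <- function(mup, kp, ap, bp, mu0, k0, a0, b0, w) {
  p <- weighted_prior_num(mup, kp, ap, bp, mu0, k0, a0, b0, w)
  if (p[2] <= 0 || p[3] <= 0 || p[4] <= 0) {
    stop("invalid mixture: weighted parameters do not define a proper NIG",
         call. = FALSE)
  }
  (lgamma(p[3]) - p[3] * log(p[4]) - 0.5 * log(p[2])) -
    w       * (lgamma(ap) - ap * log(bp) - 0.5 * log(kp)) -
    (1 - w) * (lgamma(a0) - a0 * log(b0) - 0.5 * log(k0))
}

## Beta-level analogue: log Z(b) for the mixture of two Beta components.
beta_logz_num <- function(aprev, bprev, a0, b0, w) {
  ah <- w * aprev + (1 - w) * a0
  bh <- w * bprev + (1 - w) * b0
  lbeta(ah, bh) - w * lbeta(aprev, bprev) - (1 - w) * lbeta(a0, b0)
}

#' Posterior-predictive law of a NIG belief
#'
#' The predictive distribution of the next reward is a Student-t with
#' location `mu`, squared scale `beta * (kappa + 1) / (alpha * kappa)` and
#' `2 * alpha` degrees of freedom. The predictive variance is finite only
#' when `alpha > 1`.
#'
#' @param theta A [nig_posterior()].
#' @return A list with elements `location`, `scale2`, `scale` and `df`.
#' @examples
#' nig_predictive(nig_posterior(0, 1, 1, 1)) # scale2 = 2, df = 2
#' @export
nig_predictive <- function(theta) {
  stopifnot(inherits(theta, "nig_posterior"))
  scale2 <- theta$beta * (theta$kappa + 1) / (theta$alpha * theta$kappa)
  list(location = theta$mu, scale2 = scale2, scale = sqrt(scale2),
       df = 2 * theta$alpha)
}

#' Constant-forgetting Beta-Bernoulli filter
#'
#' Didactic fixed-forgetting filter for a binary reward stream: the success
#' and failure counts are decayed geometrically towards the naive prior
#' before each update. With `w = 1` the posterior mean follows the running
#' mean (learning rate `1/j`); with `w < 1` the total evidence `a + b`
#' converges to the *efficient memory* `1 / (1 - w)` (plus the prior mass).
#'
#' @param rewards Vector of 0/1 outcomes.
#' @param w Forgetting factor in `[0, 1]`.
#' @param prior Numeric length-2 vector `c(a0, b0)` of non-negative prior
#'   counts (the memoryless limit `c(0, 0)` is allowed here).
#' @return A tibble with one row per trial: `trial`, `reward`, `a`, `b` and
#'   the posterior mean `rho`.
#' @examples
#' beta_bernoulli_filter(c(1, 1, 0), w = 1, prior = c(0, 0))
#' @export
beta_bernoulli_filter <- function(rewards, w = 1, prior = c(1, 1)) {
  stopifnot(all(rewards %in% c(0, 1)), length(prior) == 2L, all(prior >= 0))
  if (!is.finite(w) || w < 0 || w > 1) {
    stop("w must lie in [0, 1]", call. = FALSE)
  }
  n <- length(rewards)
  a <- numeric(n)
  b <- numeric(n)
  va <- 0
  vb <- 0
  for (j in seq_len(n)) {
    va <- w * va + rewards[j]
    vb <- w * vb + (1 - rewards[j])
    a[j] <- prior[1] + va
    b[j] <- prior[2] + vb
  }
  tibble::tibble(trial = seq_len(n), reward = rewards, a = a, b = b,
                 rho = a / (a + b))
}

## ---------------------------------------------------------------------------
## Expected log-densities and entropies used by the variational machinery.
## All take moment-parameterized beliefs.

## E_q[log N(x | mu_z, sigma^2)] under q = NIG(theta)
e_log_lik_norm <- function(theta, x) {
  el2 <- log(theta$beta) - digamma(theta$alpha)
  -0.5 * log(2 * pi) - 0.5 * el2 -
    0.5 * ((theta$alpha / theta$beta) * (x - theta$mu)^2 + 1 / theta$kappa)
}

## E_q[log NIG(z | th)] under q = NIG(theta)
e_log_nig <- function(theta, th) {
  el2 <- log(theta$beta) - digamma(theta$alpha)
  einv <- theta$alpha / theta$beta
  equad <- einv * (theta$mu - th$mu)^2 + 1 / theta$kappa
  0.5 * log(th$kappa / (2 * pi)) + th$alpha * log(th$beta) -
    lgamma(th$alpha) - (th$alpha + 1.5) * el2 - th$beta * einv -
    0.5 * th$kappa * equad
}

nig_entropy <- function(theta) -e_log_nig(theta, theta)

## E_q[log Beta(w | sh)] under q = Beta(phi)
e_log_beta <- function(phi, sh) {
  d <- digamma(phi$a + phi$b)
  (sh$a - 1) * (digamma(phi$a) - d) + (sh$b - 1) * (digamma(phi$b) - d) -
    lbeta(sh$a, sh$b)
}

beta_entropy <- function(phi) {
  lbeta(phi$a, phi$b) - (phi$a - 1) * digamma(phi$a) -
    (phi$b - 1) * digamma(phi$b) +
    (phi$a + phi$b - 2) * digamma(phi$a + phi$b)
}
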