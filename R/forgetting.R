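#' Joint state of the two forgetting-factor posteriors
#'
#' Bundles the Beta posterior `phi` over the first-level forgetting factor
#' `w`, the Beta posterior `beta2` over the second-level factor `b`, and the
#' beliefs carried over from the previous trial, which act as the mixture
#' components of the current priors.
#'
#' @param phi,beta2 Current [beta_belief()]s for `w` and `b`.
#' @param phi_prev,beta2_prev Previous-trial posteriors (default: the current
#'   ones, appropriate before the first observation).
#' @return An object of class `forgetting_state` with derived fields `w_hat`
#'   and `b_hat` (posterior means).
#' @export
forgetting_state <- function(phi, beta2, phi_prev = phi, beta2_prev = beta2) {
  stopifnot(is_beta_belief(phi), is_beta_belief(beta2),
            is_beta_belief(phi_prev), is_beta_belief(beta2_prev))
  structure(list(
    phi = phi, beta2 = beta2,
    phi_prev = phi_prev, beta2_prev = beta2_prev,
    w_hat = phi$a / (phi$a + phi$b),
    b_hat = beta2$a / (beta2$a + beta2$b)
  ), class = "forgetting_state")
}

## step size shared with the compiled filter so the two paths agree exactly
.H_AB <- 1e-5   # relative finite-difference step in Beta shape parameters

## d^2 log Z / dw^2, analytic. log Z(w) = A(natural mix) - w A_prev -
## (1-w) A_0, so the second derivative is that of the log-partition along
## the straight line in natural-parameter space. Writing n1 = beta +
## kappa mu^2 / 2 and n2 = kappa mu (both linear in w):
## A = lgamma(alpha) - alpha log(beta) - log(kappa)/2 with
## beta = n1 - n2^2 / (2 kappa).
logz_d2_num <- function(mup, kp, ap, bp, mu0, k0, a0, b0, w) {
  da <- ap - a0
  dk <- kp - k0
  d1 <- (bp + kp * mup^2 / 2) - (b0 + k0 * mu0^2 / 2)
  d2n <- kp * mup - k0 * mu0
  kap <- w * kp + (1 - w) * k0
  alp <- w * ap + (1 - w) * a0
  n1 <- w * (bp + kp * mup^2 / 2) + (1 - w) * (b0 + k0 * mu0^2 / 2)
  n2 <- w * kp * mup + (1 - w) * k0 * mu0
  bet <- n1 - n2^2 / (2 * kap)
  b1 <- d1 - n2 * d2n / kap + n2^2 * dk / (2 * kap^2)
  b2 <- -(d2n^2 / kap - 2 * n2 * d2n * dk / kap^2 + n2^2 * dk^2 / kap^3)
  trigamma(alp) * da^2 - 2 * da * b1 / bet -
    alp * (b2 * bet - b1^2) / bet^2 + dk^2 / (2 * kap^2)
}

beta_logz_d2_num <- function(aprev, bprev, a0, b0, w) {
  da <- aprev - a0
  db <- bprev - b0
  ah <- w * aprev + (1 - w) * a0
  bh <- w * bprev + (1 - w) * b0
  trigamma(ah) * da^2 + trigamma(bh) * db^2 - trigamma(ah + bh) * (da + db)^2
}

#' Taylor approximation of the expected mixture log-normalizer
#'
#' Approximates \eqn{E_{q(w)}[\log Z(w)]} by a second-order Taylor expansion
#' around the posterior mean \eqn{\hat w}: \eqn{\log Z(\hat w) + \tfrac12
#' Var[w] \, \partial^2_w \log Z(\hat w)}. The first-order term vanishes by
#' construction. Exact (zero) when the two mixture components coincide.
#'
#' @param phi [beta_belief()] posterior over `w`.
#' @inheritParams weighted_prior
#' @return Scalar approximation of the expected log-normalizer.
#' @export
expected_log_normalizer_taylor <- function(phi, theta_prev, theta0) {
  stopifnot(is_beta_belief(phi))
  elogz_taylor_num(theta_prev$mu, theta_prev$kappa, theta_prev$alpha,
                   theta_prev$beta, theta0$mu, theta0$kappa, theta0$alpha,
                   theta0$beta, phi$a, phi$b)
}

elogz_taylor_num <- function(mup, kp, ap, bp, mu0, k0, a0, b0, pa, pb) {
  w <- pa / (pa + pb)
  v <- pa * pb / ((pa + pb)^2 * (pa + pb + 1))
  nig_logz_num(mup, kp, ap, bp, mu0, k0, a0, b0, w) +
    0.5 * v * logz_d2_num(mup, kp, ap, bp, mu0, k0, a0, b0, w)
}

beta_elogz_taylor_num <- function(aprev, bprev, a0, b0, pa, pb) {
  w <- pa / (pa + pb)
  v <- pa * pb / ((pa + pb)^2 * (pa + pb + 1))
  beta_logz_num(aprev, bprev, a0, b0, w) +
    0.5 * v * beta_logz_d2_num(aprev, bprev, a0, b0, w)
}

## ---------------------------------------------------------------------------
## NCVMP machinery. For a Beta factor with natural parameters
## lambda = (a - 1, b - 1) and sufficient statistics (log w, log(1 - w)),
## the fixed-point update is lambda* = Cov_q(T)^{-1} grad_lambda S, where
## S(a, b) is the expected log-joint as a function of the factor's own
## parameters (entropy excluded). Terms linear in the mean parameters
## reproduce conjugate updates exactly.

ncvmp_propose <- function(a, b, S) {
  ha <- .H_AB * max(1, a)
  hb <- .H_AB * max(1, b)
  ga <- (S(a + ha, b) - S(a - ha, b)) / (2 * ha)
  gb <- (S(a, b + hb) - S(a, b - hb)) / (2 * hb)
  tab <- trigamma(a + b)
  cov_t <- matrix(c(trigamma(a) - tab, -tab, -tab, trigamma(b) - tab), 2, 2)
  lam <- solve(cov_t, c(ga, gb))
  c(lam[1] + 1, lam[2] + 1)
}

## smooth positivity guard: maps any real proposal into (eps, Inf) while
## leaving admissible values essentially untouched. A hard reject-and-keep
## branch would make the filter trajectory discontinuous in the prior
## parameters, which breaks the differentiability the MAP/Laplace fitting
## machinery relies on.
.GUARD_EPS <- 1e-3
.GUARD_K <- 50
ncvmp_guard <- function(x) {
  .GUARD_EPS + softplus(.GUARD_K * (x - .GUARD_EPS)) / .GUARD_K
}

ncvmp_damped_step <- function(phi_old, S, damping) {
  prop <- tryCatch(ncvmp_propose(phi_old$a, phi_old$b, S),
                   error = function(e) c(NA_real_, NA_real_))
  if (!all(is.finite(prop))) {
    warning("NCVMP proposal is not finite; keeping previous parameters",
            call. = FALSE)
    return(phi_old)
  }
  prop <- ncvmp_guard(prop)
  beta_belief((1 - damping) * phi_old$a + damping * prop[1],
              (1 - damping) * phi_old$b + damping * prop[2])
}

#' NCVMP update of the first-level forgetting posterior
#'
#' One (damped) non-conjugate variational message-passing step for the Beta
#' posterior over `w`. The message combines the evidence that the previous
#' posterior explains the current belief about the reward distribution
#' better (or worse) than the naive prior, the Taylor-approximated expected
#' mixture log-normalizer, and the second-level-weighted Beta prior over `w`.
#'
#' @param state A [forgetting_state()]; `state$phi` is the current posterior,
#'   `state$phi_prev` the previous-trial posterior and `state$beta2` supplies
#'   the second-level weight `b_hat`.
#' @param theta_prev,theta0 Previous posterior and naive prior of the reward
#'   belief ([nig_posterior()]).
#' @param theta_j Current variational posterior of the reward belief.
#' @param priors List with element `phi0`, the naive [beta_belief()] prior
#'   over `w` (an [agent_priors()] object works).
#' @param damping Step size in `(0, 1]`; 1 is an undamped NCVMP step.
#' @return Updated [beta_belief()] for `w`.
#' @export
ncvmp_step_w <- function(state, theta_prev, theta0, theta_j, priors,
                         damping = 0.8) {
  stopifnot(inherits(state, "forgetting_state"))
  phi0 <- priors$phi0
  delta <- e_log_nig(theta_j, theta_prev) - e_log_nig(theta_j, theta0)
  bh <- state$b_hat
  ca <- bh * state$phi_prev$a + (1 - bh) * phi0$a - 1
  cb <- bh * state$phi_prev$b + (1 - bh) * phi0$b - 1
  tp <- theta_prev
  t0 <- theta0
  S <- function(a, b) {
    w <- a / (a + b)
    d <- digamma(a + b)
    w * delta -
      elogz_taylor_num(tp$mu, tp$kappa, tp$alpha, tp$beta,
                       t0$mu, t0$kappa, t0$alpha, t0$beta, a, b) +
      ca * (digamma(a) - d) + cb * (digamma(b) - d)
  }
  ncvmp_damped_step(state$phi, S, damping)
}

#' NCVMP update of the second-level forgetting posterior
#'
#' Same machinery as [ncvmp_step_w()], one level up: `b` weights the
#' previous `w`-posterior against the fixed `w`-prior. Its own prior is the
#' previous `b`-posterior (the top level carries no further forgetting).
#'
#' @param state A [forgetting_state()]; `state$phi` must hold the *current*
#'   posterior over `w`.
#' @param phi_prev,phi0 Previous `w`-posterior and fixed `w`-prior
#'   ([beta_belief()]).
#' @param beta_prior Previous-trial posterior over `b` ([beta_belief()]).
#' @param damping Step size in `(0, 1]`.
#' @return Updated [beta_belief()] for `b`.
#' @export
ncvmp_step_b <- function(state, phi_prev, phi0, beta_prior, damping = 0.8) {
  stopifnot(inherits(state, "forgetting_state"))
  xw <- e_log_beta(state$phi, phi_prev) - e_log_beta(state$phi, phi0)
  ca <- beta_prior$a - 1
  cb <- beta_prior$b - 1
  S <- function(a, b) {
    w <- a / (a + b)
    d <- digamma(a + b)
    w * xw -
      beta_elogz_taylor_num(phi_prev$a, phi_prev$b, phi0$a, phi0$b, a, b) +
      ca * (digamma(a) - d) + cb * (digamma(b) - d)
  }
  ncvmp_damped_step(state$beta2, S, damping)
}

#' Efficient memory of a forgetting belief
#'
#' The efficient memory is the expected value of `1 / (1 - w)` under the
#' Beta posterior over the forgetting factor: the asymptotic bound on the
#' number of trials the agent can keep in memory. It is
#' `(a + b - 1) / (b - 1)` when `b > 1` and undefined otherwise, in which
#' case the first-order Taylor fallback `1 / (1 - E[w])` is returned.
#'
#' @param phi A [beta_belief()].
#' @return The efficient memory (in trials), with attribute `exact` saying
#'   whether the exact expectation (`TRUE`) or the Taylor fallback (`FALSE`)
#'   was used.
#' @examples
#' efficient_memory(beta_belief(9, 2))    # exact: 10
#' efficient_memory(beta_belief(4.5, 0.5)) # Taylor: 10
#' @export
efficient_memory <- function(phi) {
  stopifnot(is_beta_belief(phi))
  if (phi$b > 1) {
    structure((phi$a + phi$b - 1) / (phi$b - 1), exact = TRUE)
  } else {
    structure((phi$a + phi$b) / phi$b, exact = FALSE)
  }
}
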