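#' Prior configuration of a hierarchical adaptive forgetting agent
#'
#' @param theta0 Naive [nig_posterior()] prior over each state-action reward
#'   distribution.
#' @param phi0 [beta_belief()] prior over the first-level forgetting factor
#'   `w` (stability of the reward belief).
#' @param beta0 [beta_belief()] prior over the second-level factor `b`
#'   (stability of the `w`-belief).
#' @param gamma0 Optional [beta_belief()] prior over the temporal-discount
#'   factor; required only for multi-stage (TD) agents.
#' @param pi0 Policy-prior concentration (> 0) used to smooth next-state
#'   action frequencies when computing state values under TD learning.
#' @return An object of class `agent_priors`.
#' @examples
#' agent_priors(nig_posterior(0, 0.1, 1, 1),
#'              beta_belief(4.5, 0.5), beta_belief(0.5, 4.5))
#' @export
agent_priors <- function(theta0, phi0, beta0, gamma0 = NULL, pi0 = 5) {
  stopifnot(inherits(theta0, "nig_posterior"), is_beta_belief(phi0),
            is_beta_belief(beta0), is.null(gamma0) || is_beta_belief(gamma0),
            pi0 > 0)
  structure(list(theta0 = theta0, phi0 = phi0, beta0 = beta0,
                 gamma0 = gamma0, pi0 = pi0),
            class = "agent_priors")
}

#' Canonical long/short memory prior profiles
#'
#' The four limit-case agents used throughout the flexibility simulations,
#' labelled by expected memory at the first and second level (L = long,
#' S = short): `Beta(4.5, 0.5)` encodes a prior expected forgetting factor
#' of 0.9 (long memory), `Beta(0.5, 4.5)` of 0.1 (short memory). The reward
#' prior is diffuse: `mu0 = 0`, `kappa0 = 0.1`, `alpha0 = 1`, `beta0 = 1`.
#'
#' @param profile One of `"LL"`, `"SL"`, `"LS"`, `"SS"`; the first letter is
#'   the first-level memory, the second letter the second-level memory.
#' @return An [agent_priors()] object.
#' @examples
#' flexibility_priors("LS")
#' @export
flexibility_priors <- function(profile = c("LL", "SL", "LS", "SS")) {
  profile <- match.arg(profile)
  long <- c(4.5, 0.5)
  short <- c(0.5, 4.5)
  lv1 <- if (substr(profile, 1, 1) == "L") long else short
  lv2 <- if (substr(profile, 2, 2) == "L") long else short
  agent_priors(theta0 = nig_posterior(0, 0.1, 1, 1),
               phi0 = beta_belief(lv1[1], lv1[2]),
               beta0 = beta_belief(lv2[1], lv2[2]))
}

#' Initial agent state for a single observation stream
#'
#' @param priors An [agent_priors()] object.
#' @return An object of class `hafvf_state` holding the current variational
#'   posteriors (`theta`, `phi`, `beta2`), the previous-trial posteriors
#'   (initially the priors themselves), the lag since the last observation
#'   and the last per-trial evidence lower bound.
#' @export
new_agent_state <- function(priors) {
  stopifnot(inherits(priors, "agent_priors"))
  structure(list(
    theta = priors$theta0, phi = priors$phi0, beta2 = priors$beta0,
    theta_prev = priors$theta0, phi_prev = priors$phi0,
    beta2_prev = priors$beta0,
    lag = 0L, elbo = NA_real_, converged = NA, n_iter = 0L
  ), class = "hafvf_state")
}

mix_beta <- function(prev, prior, w) {
  beta_belief(w * prev$a + (1 - w) * prior$a,
              w * prev$b + (1 - w) * prior$b)
}

#' One coordinate-ascent trial update of the hierarchical filter
#'
#' Performs the per-trial variational sweep: conjugate update of the reward
#' belief under the current expected forgetting factor, then damped NCVMP
#' updates of the two forgetting posteriors, iterated until the per-trial
#' evidence lower bound changes by less than `tol` (or `max_iter` sweeps).
#' The update is fully deterministic.
#'
#' @param state An `hafvf_state` (see [new_agent_state()]).
#' @param x Observed reward for this trial (finite real).
#' @param priors An [agent_priors()] object.
#' @param tol Absolute ELBO-change convergence tolerance; `tol = 0` runs
#'   exactly `max_iter` sweeps (smooth objective for numerical
#'   differentiation).
#' @param max_iter Sweep cap; non-convergence returns the best iterate with
#'   `converged = FALSE`.
#' @param damping NCVMP damping factor in `(0, 1]`.
#' @return The updated `hafvf_state`; fields `elbo`, `converged`, `n_iter`
#'   describe the sweep.
#' @export
hafvf_trial_update <- function(state, x, priors, tol = 1e-3, max_iter = 50L,
                               damping = 0.8) {
  stopifnot(inherits(state, "hafvf_state"), inherits(priors, "agent_priors"))
  if (!is.finite(x)) stop("observation must be finite", call. = FALSE)
  theta_prev <- state$theta
  phi_prev <- state$phi
  beta_prev <- state$beta2

  bh <- beta_prev$a / (beta_prev$a + beta_prev$b)
  phi_j <- mix_beta(phi_prev, priors$phi0, bh)
  beta_j <- beta_prev
  theta_j <- theta_prev
  elbo_old <- -Inf
  elbo <- NA_real_
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w_hat <- phi_j$a / (phi_j$a + phi_j$b)
    theta_j <- nig_update(theta_prev, priors$theta0, w_hat, x)
    fstate <- forgetting_state(phi_j, beta_j, phi_prev, beta_prev)
    phi_j <- ncvmp_step_w(fstate, theta_prev, priors$theta0, theta_j,
                          priors, damping)
    fstate <- forgetting_state(phi_j, beta_j, phi_prev, beta_prev)
    beta_j <- ncvmp_step_b(fstate, phi_prev, priors$phi0, beta_prev, damping)
    elbo <- trial_elbo_num(theta_j, phi_j, beta_j, theta_prev, phi_prev,
                           beta_prev, priors, x)
    if (tol > 0 && is.finite(elbo) && abs(elbo - elbo_old) < tol) {
      converged <- TRUE
      break
    }
    elbo_old <- elbo
  }
  structure(list(
    theta = theta_j, phi = phi_j, beta2 = beta_j,
    theta_prev = theta_prev, phi_prev = phi_prev, beta2_prev = beta_prev,
    lag = 0L, elbo = elbo, converged = converged, n_iter = it
  ), class = "hafvf_state")
}

trial_elbo_num <- function(theta_j, phi_j, beta_j, theta_prev, phi_prev,
                           beta_prev, priors, x) {
  w_hat <- phi_j$a / (phi_j$a + phi_j$b)
  b_hat <- beta_j$a / (beta_j$a + beta_j$b)
  e_log_lik_norm(theta_j, x) +
    w_hat * e_log_nig(theta_j, theta_prev) +
    (1 - w_hat) * e_log_nig(theta_j, priors$theta0) -
    expected_log_normalizer_taylor(phi_j, theta_prev, priors$theta0) +
    b_hat * e_log_beta(phi_j, phi_prev) +
    (1 - b_hat) * e_log_beta(phi_j, priors$phi0) -
    beta_elogz_taylor_num(phi_prev$a, phi_prev$b, priors$phi0$a,
                          priors$phi0$b, beta_j$a, beta_j$b) +
    e_log_beta(beta_j, beta_prev) +
    nig_entropy(theta_j) + beta_entropy(phi_j) + beta_entropy(beta_j)
}

#' Per-trial evidence lower bound of a converged state
#'
#' Evaluates the variational lower bound on the log predictive density of
#' the trial's observation: expected log-likelihood, forgetting-weighted
#' prior cross-entropies at all three levels (with the Taylor-approximated
#' expected mixture log-normalizers), and the entropies of the three
#' variational factors.
#'
#' @param state An `hafvf_state` whose `theta`/`phi`/`beta2` are the
#'   current-trial posteriors and whose `*_prev` fields hold the previous
#'   trial's posteriors.
#' @param x The trial's observation.
#' @param priors An [agent_priors()] object.
#' @return The per-trial ELBO (nats).
#' @export
trial_elbo <- function(state, x, priors) {
  stopifnot(inherits(state, "hafvf_state"), inherits(priors, "agent_priors"))
  trial_elbo_num(state$theta, state$phi, state$beta2, state$theta_prev,
                 state$phi_prev, state$beta2_prev, priors, x)
}

#' Lag-adjusted forgetting-weighted prior
#'
#' When an action has not been observed for `lag` trials, the influence of
#' its last posterior decays geometrically: the mixture weight becomes
#' `w_hat ^ lag`.
#'
#' @inheritParams weighted_prior
#' @param lag Number of trials since the last observation (>= 0; 0 is the
#'   identity with the standard path).
#' @return The lag-adjusted weighted prior as a [nig_posterior()].
#' @export
delayed_prior <- function(theta_prev, theta0, w_hat, lag) {
  stopifnot(lag >= 0, lag == round(lag))
  weighted_prior(theta_prev, theta0, w_hat^lag)
}

#' Counterfactual (continuous) update of an unobserved action
#'
#' Updates the belief about an action that was *not* selected this trial by
#' replacing the missing observation with its expected value and the squared
#' residual with its expectation under the current belief. The posterior
#' mean therefore stays exactly at the trial's weighted-prior mean, while
#' the belief relaxes towards the naive prior at a rate set by the expected
#' forgetting factor; over many consecutive non-selections the variance of
#' the mean grows back towards its prior level, encouraging re-exploration.
#' The forgetting posterior is propagated through its own weighted prior
#' (there is no stability evidence without an observation).
#'
#' @param state The unchosen action's `hafvf_state`.
#' @param priors An [agent_priors()] object.
#' @return The updated `hafvf_state` with `lag` incremented.
#' @export
continuous_counterfactual_update <- function(state, priors) {
  stopifnot(inherits(state, "hafvf_state"), inherits(priors, "agent_priors"))
  theta_prev <- state$theta
  phi_prev <- state$phi
  beta_prev <- state$beta2
  bh <- beta_prev$a / (beta_prev$a + beta_prev$b)
  phi_j <- mix_beta(phi_prev, priors$phi0, bh)
  w_hat <- phi_j$a / (phi_j$a + phi_j$b)
  th <- weighted_prior(theta_prev, priors$theta0, w_hat)
  esq <- (th$beta / th$alpha) * (1 + 1 / th$kappa)
  theta_j <- nig_posterior(th$mu, th$kappa + 1, th$alpha + 0.5,
                           th$beta + 0.5 * esq)
  structure(list(
    theta = theta_j, phi = phi_j, beta2 = beta_prev,
    theta_prev = theta_prev, phi_prev = phi_prev, beta2_prev = beta_prev,
    lag = state$lag + 1L, elbo = NA_real_, converged = NA, n_iter = 0L
  ), class = "hafvf_state")
}

#' Run the hierarchical adaptive forgetting filter over a reward stream
#'
#' Applies [hafvf_trial_update()] sequentially to a univariate observation
#' stream and returns the full per-trial trace of the variational
#' posteriors, forgetting factors, memory diagnostics and evidence lower
#' bound.
#'
#' @param x Numeric vector of observations (e.g. rewards).
#' @param priors An [agent_priors()] object.
#' @inheritParams hafvf_trial_update
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation); both produce the same trace to numerical precision.
#' @return A tibble of class `hafvf_trace` with one row per trial: posterior
#'   parameters (`mu`, `kappa`, `alpha`, `beta`), forgetting posteriors
#'   (`phi_a` ... `beta_b`), their means (`w_hat`, `b_hat`), the efficient
#'   memories at both levels and the per-trial `elbo`.
#' @examples
#' tr <- hafvf_filter(rnorm(50, 2), flexibility_priors("LL"))
#' mean(tr$elbo)
#' @export
hafvf_filter <- function(x, priors, tol = 1e-3, max_iter = 50L,
                         damping = 0.8, engine = c("cpp", "r")) {
  stopifnot(is.numeric(x), all(is.finite(x)),
            inherits(priors, "agent_priors"))
  engine <- match.arg(engine)
  if (engine == "cpp") {
    m <- hafvf_filter_cpp(
      as.numeric(x),
      c(priors$theta0$mu, priors$theta0$kappa, priors$theta0$alpha,
        priors$theta0$beta),
      c(priors$phi0$a, priors$phi0$b),
      c(priors$beta0$a, priors$beta0$b),
      tol, as.integer(max_iter), damping
    )
    tr <- tibble::as_tibble(as.data.frame(m))
  } else {
    st <- new_agent_state(priors)
    n <- length(x)
    out <- vector("list", n)
    for (j in seq_len(n)) {
      st <- hafvf_trial_update(st, x[j], priors, tol, max_iter, damping)
      out[[j]] <- c(
        mu = st$theta$mu, kappa = st$theta$kappa, alpha = st$theta$alpha,
        beta = st$theta$beta, phi_a = st$phi$a, phi_b = st$phi$b,
        beta_a = st$beta2$a, beta_b = st$beta2$b, elbo = st$elbo,
        n_iter = as.numeric(st$n_iter)
      )
    }
    tr <- tibble::as_tibble(as.data.frame(do.call(rbind, out)))
  }
  tr <- dplyr::mutate(
    tr,
    trial = dplyr::row_number(), x = as.numeric(x),
    w_hat = .data$phi_a / (.data$phi_a + .data$phi_b),
    b_hat = .data$beta_a / (.data$beta_a + .data$beta_b),
    eff_mem_w = ifelse(.data$phi_b > 1,
                       (.data$phi_a + .data$phi_b - 1) / (.data$phi_b - 1),
                       (.data$phi_a + .data$phi_b) / .data$phi_b),
    eff_mem_b = ifelse(.data$beta_b > 1,
                       (.data$beta_a + .data$beta_b - 1) / (.data$beta_b - 1),
                       (.data$beta_a + .data$beta_b) / .data$beta_b),
    .before = 1L
  )
  tr <- dplyr::relocate(tr, "trial", "x")
  class(tr) <- c("hafvf_trace", class(tr))
  attr(tr, "priors") <- priors
  tr
}

#' @export
print.hafvf_trace <- function(x, ...) {
  cat(sprintf(
    "# hafvf_trace: %d trials, mean ELBO %.4f, final w_hat %.3f b_hat %.3f\n",
    nrow(x), mean(x$elbo), x$w_hat[nrow(x)], x$b_hat[nrow(x)]))
  NextMethod()
}
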