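#' Drift-diffusion (race) parameters of a decision maker
#'
#' @param zeta Decision threshold (> 0); the race runs between absorbing
#'   bounds at 0 and `zeta`.
#' @param z0 Start point in `(0, zeta)`; default `zeta / 2` (unbiased).
#' @param tau Non-decision time in seconds (>= 0).
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(2)
#' @export
ddm_params <- function(zeta, z0 = zeta / 2, tau = 0) {
  stopifnot(is.numeric(zeta), is.numeric(z0), is.numeric(tau))
  if (!is.finite(zeta) || zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  if (!is.finite(z0) || z0 <= 0 || z0 >= zeta) {
    stop("z0 must lie strictly between 0 and zeta", call. = FALSE)
  }
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  structure(list(zeta = zeta, z0 = z0, tau = tau), class = "ddm_params")
}

#' Sample trial-wise drift and diffusion noise from two reward beliefs
#'
#' Draws action-value parameters from the two Normal-Inverse-Gamma
#' posteriors (`sigma_i^2 ~ IG(alpha_i, beta_i)`, `mu_i ~ N(mu_i,
#' sigma_i^2 / kappa_i)`) and returns the induced accumulator drift
#' `xi = mu_1 - mu_2` and diffusion variance `s2 = sigma_1^2 + sigma_2^2`,
#' one pair per trial.
#'
#' @param post1,post2 [nig_posterior()]s of the two candidate actions.
#' @param n Number of trials to draw.
#' @return A tibble with columns `xi` and `s2`.
#' @export
sample_action_params <- function(post1, post2, n = 1) {
  stopifnot(inherits(post1, "nig_posterior"), inherits(post2, "nig_posterior"))
  s1 <- 1 / stats::rgamma(n, shape = post1$alpha, rate = post1$beta)
  s2 <- 1 / stats::rgamma(n, shape = post2$alpha, rate = post2$beta)
  m1 <- stats::rnorm(n, post1$mu, sqrt(s1 / post1$kappa))
  m2 <- stats::rnorm(n, post2$mu, sqrt(s2 / post2$kappa))
  tibble::tibble(xi = m1 - m2, s2 = s1 + s2)
}

#' Analytic absorption probability of the race
#'
#' Probability that a Wiener process with drift `xi` and diffusion variance
#' `s2`, started at `z0` between absorbing bounds 0 and `zeta`, is absorbed
#' at the upper bound (choice 1):
#' \deqn{P = \frac{1 - e^{-2 \xi z_0 / s^2}}{1 - e^{-2 \xi \zeta / s^2}}}
#' with the continuous limit `z0 / zeta` at `xi = 0`. Overflow-guarded for
#' large drifts.
#'
#' @param xi Drift (vectorized).
#' @param s2 Diffusion variance (> 0, vectorized).
#' @param ddm A [ddm_params()] object.
#' @return Upper-bound absorption probability in `[0, 1]`.
#' @examples
#' ddm_hit_probability(1, 1, ddm_params(2)) # (1 - e^-2) / (1 - e^-4)
#' @export
ddm_hit_probability <- function(xi, s2, ddm) {
  stopifnot(inherits(ddm, "ddm_params"), all(s2 > 0))
  a <- 2 * xi * ddm$z0 / s2
  b <- 2 * xi * ddm$zeta / s2
  p <- ifelse(
    abs(b) < 1e-9,
    ddm$z0 / ddm$zeta + xi * ddm$z0 * (ddm$zeta - ddm$z0) / (2 * s2) /
      (ddm$zeta / 2),  # first-order expansion around xi = 0
    ifelse(b > 0,
           expm1(-a) / expm1(-b),
           # xi < 0: multiply through by exp(b) to avoid overflow
           (exp(b - a) - exp(b)) / (1 - exp(b))))
  pmin(pmax(p, 0), 1)
}

#' Simulate one decision by Euler discretization of the race
#'
#' Forward-simulates `dx = xi dt + sqrt(dt) s eps` from `z0` until a bound
#' is crossed. Intended for illustration and cross-checks; likelihood
#' computations always use the analytic first-passage density
#' ([wiener_log_density()]).
#'
#' @param drift A list or one-row data frame with elements `xi` and `s2`
#'   (e.g. one row of [sample_action_params()]).
#' @param ddm A [ddm_params()] object.
#' @param dt Euler step in seconds.
#' @param max_steps Guard on the path length; crossing it returns
#'   `censored = TRUE`.
#' @return A list with `choice` (1 = upper bound), `rt` (seconds, including
#'   the non-decision time) and `censored`.
#' @export
simulate_trial <- function(drift, ddm, dt = 1e-3, max_steps = 1e6) {
  stopifnot(inherits(ddm, "ddm_params"), dt > 0)
  m <- euler_race_cpp(1L, as.numeric(drift$xi), as.numeric(drift$s2),
                      ddm$zeta, ddm$z0, dt, max_steps)
  list(choice = as.integer(m[1, 1]), rt = m[1, 2] + ddm$tau,
       censored = m[1, 3] > 0)
}

#' Simulate many race trials (vectorized Euler paths)
#'
#' @inheritParams simulate_trial
#' @param n Number of trials.
#' @param xi,s2 Drift and diffusion variance (scalars or length-`n`).
#' @return A tibble with `choice`, `rt` (including `tau`) and `censored`.
#' @export
simulate_trials <- function(n, xi, s2, ddm, dt = 1e-3, max_steps = 1e6) {
  stopifnot(inherits(ddm, "ddm_params"), dt > 0)
  m <- euler_race_cpp(as.integer(n), as.numeric(xi), as.numeric(s2),
                      ddm$zeta, ddm$z0, dt, max_steps)
  tibble::tibble(choice = as.integer(m[, 1]), rt = m[, 2] + ddm$tau,
                 censored = m[, 3] > 0)
}

#' Marginal choice probability of the diffusion actor
#'
#' Monte-Carlo average of the analytic absorption probability over
#' trial-wise parameter draws from the two posteriors: the probability that
#' the actor selects action 1 on a random trial.
#'
#' @inheritParams sample_action_params
#' @param ddm A [ddm_params()] object.
#' @param n_mc Number of Monte-Carlo draws (a warning is issued below 100).
#' @return Scalar choice probability.
#' @export
choice_probability_marginal <- function(post1, post2, ddm, n_mc = 10000) {
  if (n_mc < 100) {
    warning("n_mc < 100 gives a noisy estimate", call. = FALSE)
  }
  d <- sample_action_params(post1, post2, n_mc)
  mean(ddm_hit_probability(d$xi, d$s2, ddm))
}

#' Q-sampling (Thompson) choice probability
#'
#' Monte-Carlo estimate of `P(mu_1 > mu_2)` under the two NIG posteriors:
#' the probability that action 1 has the larger sampled action value. The
#' diffusion actor converges to this rule as the threshold grows.
#'
#' @inheritParams sample_action_params
#' @param n_mc Number of Monte-Carlo draws.
#' @return Scalar probability.
#' @export
qs_probability <- function(post1, post2, n_mc = 10000) {
  d <- sample_action_params(post1, post2, n_mc)
  mean(d$xi > 0)
}

## ---------------------------------------------------------------------------
## First-passage density of the Wiener process (standardized form; both the
## small-time and large-time series, with the switch of Navarro & Fuss 2009).

## density of absorption at the LOWER bound at scaled time u = t / a^2 for a
## zero-drift unit-diffusion process with bounds (0, a), relative start w;
## small/large-time series with the usual switch, evaluated in compiled code
wfpt_f0 <- function(u, w, err = 1e-10) {
  n <- length(u)
  wfpt_f0_cpp(as.numeric(u), rep_len(as.numeric(w), n), err)
}

#' Log first-passage density of the decision process
#'
#' Analytic Wiener first-passage density at the chosen bound, evaluated at
#' `rt - tau`, for drift `xi`, diffusion variance `s2`, bounds `(0, zeta)`
#' and start point `z0`. This is the defective density of the observed
#' `(choice, rt)` pair: integrating it over `rt` recovers the absorption
#' probability of that bound.
#'
#' @param rt Reaction times in seconds (vectorized); values `<= tau` get
#'   `-Inf`.
#' @param choice 1 (upper bound) or 2 (lower bound), vectorized.
#' @param xi,s2 Drift and diffusion variance.
#' @param ddm A [ddm_params()] object.
#' @return Log density values.
#' @export
wiener_log_density <- function(rt, choice, xi, s2, ddm) {
  stopifnot(inherits(ddm, "ddm_params"), all(s2 > 0),
            all(choice %in% c(1, 2)))
  n <- max(length(rt), length(choice), length(xi), length(s2))
  rt <- rep_len(rt, n)
  choice <- rep_len(choice, n)
  xi <- rep_len(xi, n)
  s2 <- rep_len(s2, n)
  sig <- sqrt(s2)
  v <- xi / sig
  a <- ddm$zeta / sig
  w <- ddm$z0 / ddm$zeta
  ## choice 1 = upper bound: reflect
  v <- ifelse(choice == 1, -v, v)
  wrel <- ifelse(choice == 1, 1 - w, w)
  t <- rt - ddm$tau
  ok <- t > 0
  out <- rep(-Inf, n)
  if (any(ok)) {
    tt <- t[ok]
    u <- tt / a[ok]^2
    f0 <- wfpt_f0(u, wrel[ok])
    out[ok] <- log(pmax(f0, 1e-300)) - 2 * log(a[ok]) -
      v[ok] * a[ok] * wrel[ok] - v[ok]^2 * tt / 2
  }
  out
}

## inverse-CDF sampler for (choice, rt): exact in distribution up to the
## grid resolution of the conditional CDF; used for bulk data generation.
rwiener_inv <- function(n, xi, s2, ddm, grid_n = 2048) {
  p_up <- ddm_hit_probability(xi, s2, ddm)
  choice <- ifelse(stats::runif(n) < p_up, 1L, 2L)
  rt <- numeric(n)
  for (ch in c(1L, 2L)) {
    idx <- which(choice == ch)
    if (!length(idx)) next
    pb <- if (ch == 1L) p_up else 1 - p_up
    ## locate an upper time limit covering ~all mass
    tmax <- 1
    repeat {
      ts <- seq(1e-5, tmax, length.out = grid_n)
      f <- exp(wiener_log_density(ts + ddm$tau, ch, xi, s2, ddm))
      cdf <- cumsum(f) * (ts[2] - ts[1])
      if (cdf[grid_n] > 0.999 * pb || tmax > 4096) break
      tmax <- tmax * 2
    }
    q <- stats::runif(length(idx), 0, cdf[grid_n])
    rt[idx] <- ts[pmax(1L, findInterval(q, cdf) + 1L)] + ddm$tau
  }
  tibble::tibble(choice = choice, rt = rt)
}

#' Speed-accuracy policy surface of the diffusion actor
#'
#' Evaluates marginal accuracy (probability of choosing the higher-valued
#' action) and mean decision time on a grid of reward-variance (`beta_j`)
#' and effective-memory (`kappa_j`) values, for two actions with opposite
#' means. Mean decision time uses the analytic expected first-passage time
#' averaged over posterior draws.
#'
#' @param mu Posterior means of the two actions (length 2).
#' @param alpha Shared inverse-gamma shape.
#' @param beta_grid,kappa_grid Grids of `beta_j` and `kappa_j` values.
#' @param ddm A [ddm_params()] object.
#' @param n_mc Monte-Carlo draws per grid cell.
#' @return A tibble with columns `beta_j`, `kappa_j`, `accuracy`, `mean_rt`.
#' @export
policy_surface <- function(mu = c(1, -1), alpha = 3,
                           beta_grid = seq(0.5, 4, length.out = 5),
                           kappa_grid = seq(0.5, 4, length.out = 5),
                           ddm = ddm_params(2), n_mc = 4000) {
  grid <- tidyr::expand_grid(beta_j = beta_grid, kappa_j = kappa_grid)
  res <- purrr::pmap_dfr(grid, function(beta_j, kappa_j) {
    p1 <- nig_posterior(mu[1], kappa_j, alpha, beta_j)
    p2 <- nig_posterior(mu[2], kappa_j, alpha, beta_j)
    d <- sample_action_params(p1, p2, n_mc)
    pu <- ddm_hit_probability(d$xi, d$s2, ddm)
    et <- mean_fpt(d$xi, d$s2, ddm)
    tibble::tibble(accuracy = mean(ifelse(mu[1] >= mu[2], pu, 1 - pu)),
                   mean_rt = mean(et) + ddm$tau)
  })
  dplyr::bind_cols(grid, res)
}

## expected first-passage time (unconditional on bound), by Wald's identity
mean_fpt <- function(xi, s2, ddm) {
  pu <- ddm_hit_probability(xi, s2, ddm)
  ifelse(abs(xi) < 1e-9,
         ddm$z0 * (ddm$zeta - ddm$z0) / s2,
         (ddm$zeta * pu - ddm$z0) / xi)
}
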