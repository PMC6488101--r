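#' Simulate a two-armed bandit session with the actor-critic agent
#'
#' Alternates decision and learning on each trial: the actor draws
#' trial-wise drift and noise from the two current reward posteriors and
#' races them to a bound (choice + reaction time); the critic then updates
#' the chosen action's belief with the observed reward and applies the
#' continuous counterfactual update to the unchosen action.
#'
#' @param schedule A tibble with one row per trial and columns `mean1`,
#'   `mean2` (reward means of the two actions) and optionally `sd1`, `sd2`
#'   (default 1).
#' @param priors An [agent_priors()] object.
#' @param ddm A [ddm_params()] object.
#' @param seed Optional integer seed; recorded in the manifest.
#' @param dt Euler step used to simulate the race.
#' @param counterfactual `"continuous"` (default) or `"none"`.
#' @param tol,max_iter,damping Critic convergence controls.
#' @return A tibble of class `hafvf_session`: per-trial `choice`, `rt`,
#'   `reward`, both actions' posterior means, the chosen action's
#'   forgetting diagnostics and per-trial ELBO. The attribute `manifest`
#'   records seed and configuration.
#' @export
run_session <- function(schedule, priors, ddm, seed = NULL, dt = 1e-3,
                        counterfactual = c("continuous", "none"),
                        tol = 1e-3, max_iter = 50L, damping = 0.8) {
  stopifnot(inherits(priors, "agent_priors"), inherits(ddm, "ddm_params"))
  counterfactual <- match.arg(counterfactual)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule$sd1)) schedule$sd1 <- 1
  if (is.null(schedule$sd2)) schedule$sd2 <- 1
  n <- nrow(schedule)
  t0 <- c(priors$theta0$mu, priors$theta0$kappa, priors$theta0$alpha,
          priors$theta0$beta)
  p0 <- c(priors$phi0$a, priors$phi0$b)
  b0 <- c(priors$beta0$a, priors$beta0$b)
  ## raw numeric belief blocks per action: theta(4), phi(2), beta(2)
  bel <- list(c(t0, p0, b0), c(t0, p0, b0))
  out <- matrix(NA_real_, n, 11)
  colnames(out) <- c("choice", "rt", "reward", "mu1", "mu2", "kappa1",
                     "kappa2", "w_hat", "b_hat", "elbo", "censored")
  for (j in seq_len(n)) {
    q1 <- bel[[1]]
    q2 <- bel[[2]]
    s1 <- 1 / stats::rgamma(1, q1[3], rate = q1[4])
    s2 <- 1 / stats::rgamma(1, q2[3], rate = q2[4])
    m1 <- stats::rnorm(1, q1[1], sqrt(s1 / q1[2]))
    m2 <- stats::rnorm(1, q2[1], sqrt(s2 / q2[2]))
    race <- euler_race_cpp(1L, m1 - m2, s1 + s2, ddm$zeta, ddm$z0, dt, 1e6)
    ch <- as.integer(race[1, 1])
    rt <- race[1, 2] + ddm$tau
    mu_r <- if (ch == 1L) schedule$mean1[j] else schedule$mean2[j]
    sd_r <- if (ch == 1L) schedule$sd1[j] else schedule$sd2[j]
    r <- stats::rnorm(1, mu_r, sd_r)
    qc <- bel[[ch]]
    up <- hafvf_update1_cpp(qc[1:4], qc[5:6], qc[7:8], t0, p0, b0, r,
                            tol, as.integer(max_iter), damping)
    bel[[ch]] <- up[1:8]
    if (counterfactual == "continuous") {
      other <- 3L - ch
      bel[[other]] <- counterfactual_num(bel[[other]], t0, p0)
    }
    out[j, ] <- c(ch, rt, r, bel[[1]][1], bel[[2]][1], bel[[1]][2],
                  bel[[2]][2], up[5] / (up[5] + up[6]),
                  up[7] / (up[7] + up[8]), up[9], race[1, 3])
  }
  res <- dplyr::mutate(tibble::as_tibble(as.data.frame(out)),
                       trial = dplyr::row_number(), .before = 1L)
  res$choice <- as.integer(res$choice)
  class(res) <- c("hafvf_session", class(res))
  attr(res, "manifest") <- list(
    seed = seed, dt = dt, counterfactual = counterfactual,
    priors = priors, ddm = ddm, tol = tol, max_iter = max_iter,
    damping = damping, schedule_hash = sum(schedule$mean1 * seq_len(n)) +
      sum(schedule$mean2), package_version = as.character(
        utils::packageVersion("hafvf"))
  )
  res
}

## continuous counterfactual update on a raw numeric belief block
counterfactual_num <- function(q, t0, p0) {
  bh <- q[7] / (q[7] + q[8])
  pa <- bh * q[5] + (1 - bh) * p0[1]
  pb <- bh * q[6] + (1 - bh) * p0[2]
  w <- pa / (pa + pb)
  th <- weighted_prior_num(q[1], q[2], q[3], q[4], t0[1], t0[2], t0[3],
                           t0[4], w)
  esq <- (th[4] / th[3]) * (1 + 1 / th[2])
  c(th[1], th[2] + 1, th[3] + 0.5, th[4] + 0.5 * esq, pa, pb, q[7], q[8])
}
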