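#' Piecewise-stationary Gaussian signal specification
#'
#' @param segments A tibble/data frame with columns `length` (trials, >= 1),
#'   `mean` and `sd` (> 0), one row per stationary segment.
#' @param seed Integer seed making the realization reproducible.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(segments, seed = 1L) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("length", "mean", "sd") %in% names(segments)),
            all(segments$length >= 1), all(segments$sd > 0))
  structure(list(segments = segments, seed = as.integer(seed)),
            class = "signal_spec")
}

#' Realize a signal specification
#'
#' @param spec A [signal_spec()].
#' @return A tibble with columns `trial`, `segment`, `r`.
#' @export
gen_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  set.seed(spec$seed)
  seg <- spec$segments
  r <- unlist(purrr::pmap(seg, function(length, mean, sd) {
    stats::rnorm(length, mean, sd)
  }))
  tibble::tibble(trial = seq_along(r),
                 segment = rep(seq_len(nrow(seg)), seg$length), r = r)
}

#' Noisy square-wave benchmark signal
#'
#' Two periods of 200 trials alternating between `N(1, 0.33)` and
#' `N(-1, 0.33)` (400 trials). With `include_test = TRUE`, a further
#' 1200-trial block at level 5 is appended, used to probe generalization to
#' an unseen contingency change.
#'
#' @param seed Integer seed.
#' @param include_test Append the 1200-trial test block?
#' @return A tibble with `trial`, `segment`, `r`.
#' @export
gen_square_wave <- function(seed = 1L, include_test = FALSE) {
  seg <- tibble::tibble(length = rep(100L, 4L),
                        mean = c(1, -1, 1, -1), sd = 0.33)
  if (include_test) {
    seg <- dplyr::bind_rows(seg,
                            tibble::tibble(length = 1200L, mean = 5,
                                           sd = 0.33))
  }
  gen_signal(signal_spec(seg, seed))
}

#' Contingency-change learning stream
#'
#' A stationary Gaussian stream (`mean = 3`, `sd = 1`) followed by an
#' abrupt change to `mean = -3` after either a long (900-trial) or short
#' (100-trial) training phase; 1000 trials in total.
#'
#' @param training `"long"` (900 pre-change trials) or `"short"` (100).
#' @param seed Integer seed.
#' @param total Total session length.
#' @return A tibble with `trial`, `segment`, `r` and attribute
#'   `change_point` (index of the first post-change trial).
#' @export
gen_cc_experiment <- function(training = c("long", "short"), seed = 1L,
                              total = 1000L) {
  training <- match.arg(training)
  n_pre <- if (training == "long") 900L else 100L
  stopifnot(total > n_pre)
  out <- gen_signal(signal_spec(tibble::tibble(
    length = c(n_pre, total - n_pre), mean = c(3, -3), sd = 1), seed))
  attr(out, "change_point") <- n_pre + 1L
  out
}

#' Isolated-outlier learning stream
#'
#' A stationary `N(3, 1)` stream of 1000 trials in which the observation
#' immediately after the training phase is replaced by the unexpected value
#' -3. Differs from the matching stationary stream in exactly one trial.
#'
#' @inheritParams gen_cc_experiment
#' @return A tibble with `trial`, `segment`, `r` and attribute
#'   `outlier_trial`.
#' @export
gen_outlier_experiment <- function(training = c("long", "short"), seed = 1L,
                                   total = 1000L) {
  training <- match.arg(training)
  n_pre <- if (training == "long") 900L else 100L
  stopifnot(total > n_pre)
  out <- gen_signal(signal_spec(tibble::tibble(length = total, mean = 3,
                                               sd = 1), seed))
  out$r[n_pre + 1L] <- -3
  attr(out, "outlier_trial") <- n_pre + 1L
  out
}

#' Flexibility simulation study: average ELBO per agent and dataset
#'
#' Runs the four long/short memory agents ([flexibility_priors()]) on the
#' contingency-change experiment (abrupt mean reversal after long or short
#' training) and the isolated-outlier experiment (single unexpected
#' observation), and reports the session-average per-trial evidence lower
#' bound as a model-fit score. Dataset 1 uses the long training, dataset 2
#' the short training.
#'
#' @param seeds Integer vector of signal seeds (one session per seed).
#' @param agents Character vector of agent profiles.
#' @return A tibble with columns `agent`, `experiment` (1 = contingency
#'   change, 2 = isolated outlier), `dataset` (1 = long training,
#'   2 = short), `seed`, `mean_elbo`.
#' @examples
#' \donttest{
#' run_flexibility_experiments(seeds = 1:3)
#' }
#' @export
run_flexibility_experiments <- function(seeds = 1:20,
                                        agents = c("LL", "SL", "LS", "SS")) {
  grid <- tidyr::expand_grid(agent = agents, experiment = 1:2,
                             dataset = 1:2, seed = seeds)
  purrr::pmap_dfr(grid, function(agent, experiment, dataset, seed) {
    training <- if (dataset == 1L) "long" else "short"
    sig <- if (experiment == 1L) {
      gen_cc_experiment(training, seed)
    } else {
      gen_outlier_experiment(training, seed)
    }
    tr <- hafvf_filter(sig$r, flexibility_priors(agent))
    tibble::tibble(agent = agent, experiment = experiment,
                   dataset = dataset, seed = seed,
                   mean_elbo = mean(tr$elbo))
  })
}

#' Summarise a flexibility study into the agent x dataset score table
#'
#' @param results Output of [run_flexibility_experiments()].
#' @return A tibble with one row per experiment x dataset and one column
#'   per agent (seed-averaged mean ELBO), plus the winning agent.
#' @export
summarise_flexibility <- function(results) {
  wide <- results |>
    dplyr::group_by(.data$experiment, .data$dataset, .data$agent) |>
    dplyr::summarise(mean_elbo = mean(.data$mean_elbo), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "agent", values_from = "mean_elbo")
  agents <- setdiff(names(wide), c("experiment", "dataset"))
  wide$winner <- agents[max.col(as.matrix(wide[agents]))]
  wide
}

#' Reward schedule of the two-armed bandit fitting study
#'
#' Action 1 pays `N(0, 1)` for 500 trials, then `N(+2, 1)` for 100 trials,
#' then `N(-2, 1)`. Action 2 follows the reversed-order, opposite-sign
#' schedule (`+2` for 400 trials, `-2` for 100, then `0`), so the combined
#' session has contingency changes at trials 400, 500 and 600.
#'
#' @param n_trials Session length.
#' @return A tibble with `trial`, `mean1`, `mean2`, `sd1`, `sd2`.
#' @export
bandit_schedule <- function(n_trials = 1000L) {
  trial <- seq_len(n_trials)
  m1 <- ifelse(trial <= 500, 0, ifelse(trial <= 600, 2, -2))
  m2 <- ifelse(trial <= 400, 2, ifelse(trial <= 500, -2, 0))
  tibble::tibble(trial = trial, mean1 = m1, mean2 = m2, sd1 = 1, sd2 = 1)
}

#' Generate a population of bandit subjects around a reference configuration
#'
#' Subject-level parameters (reward prior, forgetting priors, threshold,
#' start-point bias, non-decision time) are scattered around a reference
#' near-optimal configuration in the unbounded parameter space with a
#' covariance matrix drawn from an inverse-Wishart distribution with 10
#' degrees of freedom and scale `diag(1, ..., 1, 0.1)` (the last entry
#' keeps the threshold variability small). Each subject is simulated on the
#' bandit schedule; subjects with accuracy below 70% (fraction of choices
#' of the currently better action while the means differ) are rejected and
#' re-sampled.
#'
#' @param n_subjects Number of accepted subjects to return.
#' @param n_trials Trials per subject.
#' @param seed Integer seed.
#' @param center Named numeric vector of reference parameters in the
#'   unbounded space; see [bandit_center()].
#' @param max_tries Resampling guard.
#' @return A list with `subjects` (tibble of parameters, one row per
#'   accepted subject, including realized `accuracy`), `sessions` (list of
#'   session tibbles) and `schedule`.
#' @export
gen_bandit_study <- function(n_subjects = 64L, n_trials = 1000L, seed = 1L,
                             center = bandit_center(),
                             max_tries = 20L * n_subjects) {
  set.seed(seed)
  sched <- bandit_schedule(n_trials)
  d <- length(center)
  scale_mat <- diag(c(rep(1, d - 1), 0.1))
  ## inverse-Wishart draw: Sigma ~ IW(Psi, nu) <=> Sigma^-1 ~ W(nu, Psi^-1);
  ## nu = d + 2 makes E[Sigma] = Psi
  nu <- d + 2
  sigma <- solve(stats::rWishart(1, df = nu, Sigma = solve(scale_mat))[, , 1])
  ch <- chol(sigma)
  subjects <- vector("list", n_subjects)
  sessions <- vector("list", n_subjects)
  acc <- 0L
  tries <- 0L
  while (acc < n_subjects && tries < max_tries) {
    tries <- tries + 1L
    u <- center + drop(t(ch) %*% stats::rnorm(d))
    pars <- bandit_unpack(u)
    ses <- run_session(sched, pars$priors, pars$ddm)
    better <- ifelse(sched$mean1 > sched$mean2, 1L,
                     ifelse(sched$mean2 > sched$mean1, 2L, NA_integer_))
    ok <- !is.na(better)
    accuracy <- mean(ses$choice[ok] == better[ok])
    if (accuracy >= 0.7) {
      acc <- acc + 1L
      subjects[[acc]] <- tibble::tibble(
        subject = acc, !!!stats::setNames(as.list(u), names(center)),
        accuracy = accuracy)
      sessions[[acc]] <- ses
    }
  }
  if (acc < n_subjects) {
    stop("could not generate enough subjects above the accuracy floor",
         call. = FALSE)
  }
  list(subjects = dplyr::bind_rows(subjects[seq_len(acc)]),
       sessions = sessions[seq_len(acc)], schedule = sched)
}

#' Reference bandit-subject configuration (unbounded space)
#'
#' Positive-domain parameters are stored through the inverse softplus; the
#' start point is stored as a bias on the logit of `z0 / zeta`.
#'
#' @return Named numeric vector.
#' @export
bandit_center <- function() {
  c(mu0 = 0,
    kappa0 = inv_softplus(0.5), alpha0 = inv_softplus(1.5),
    beta0 = inv_softplus(1.5),
    phi_a = inv_softplus(4.5), phi_b = inv_softplus(0.5),
    bet_a = inv_softplus(2), bet_b = inv_softplus(1),
    tau = inv_softplus(0.3), nu = 0,
    zeta = inv_softplus(2))
}

## map an unbounded subject vector to agent priors + ddm parameters
bandit_unpack <- function(u) {
  zeta <- softplus(u[["zeta"]])
  z0 <- zeta * stats::plogis(u[["nu"]])
  list(
    priors = agent_priors(
      theta0 = nig_posterior(u[["mu0"]], softplus(u[["kappa0"]]),
                             softplus(u[["alpha0"]]), softplus(u[["beta0"]])),
      phi0 = beta_belief(softplus(u[["phi_a"]]), softplus(u[["phi_b"]])),
      beta0 = beta_belief(softplus(u[["bet_a"]]), softplus(u[["bet_b"]]))),
    ddm = ddm_params(zeta, z0, softplus(u[["tau"]]))
  )
}
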