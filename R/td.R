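#' Five-state Markov decision processes for the multi-stage experiments
#'
#' Two similar 5-state MDPs with left/right actions. Each action has a 90%
#' probability of leading to its intended target state; the remaining 10%
#' is spread evenly over the other four states. A reward of 5 is delivered
#' on each arrival in the rewarded state. The experiments run the first MDP
#' (rewarded state 5) for the first half of the session and then switch:
#' experiment `"i"` moves the reward to state 2 (deep change: the optimal
#' policy flips from left in 3-4-5 to right in 1-4-2), experiment `"ii"`
#' keeps it at state 5 under the second MDP's transitions (shallow change:
#' left in state 3 stays on the rewarded path).
#'
#' @param phase `"pre"` (first MDP) or `"post"` (second MDP).
#' @param experiment `"i"` or `"ii"` (only affects the post-change rewarded
#'   state).
#' @return A list with `n_states`, `intended` (5 x 2 matrix of intended
#'   target states, columns = left/right), `rewarded_state`, `reward` and
#'   `intended_transition_prob`.
#' @export
mdp_spec <- function(phase = c("pre", "post"), experiment = c("i", "ii")) {
  phase <- match.arg(phase)
  experiment <- match.arg(experiment)
  if (phase == "pre") {
    intended <- cbind(L = c(3L, 1L, 4L, 5L, 5L), R = c(2L, 2L, 1L, 1L, 4L))
    rewarded <- 5L
  } else {
    intended <- cbind(L = c(3L, 1L, 5L, 1L, 5L), R = c(2L, 2L, 4L, 2L, 4L))
    rewarded <- if (experiment == "i") 2L else 5L
  }
  list(n_states = 5L, intended = intended, rewarded_state = rewarded,
       reward = 5, intended_transition_prob = 0.9)
}

mdp_transition <- function(spec, s, a) {
  if (stats::runif(1) < spec$intended_transition_prob) {
    spec$intended[s, a]
  } else {
    sample(setdiff(seq_len(spec$n_states), spec$intended[s, a]), 1L)
  }
}

#' Initial state of a temporal-difference learning agent
#'
#' One hierarchical forgetting belief per state-action, a Beta belief over
#' the discount factor, and visit counts for the policy-prior-smoothed
#' state values.
#'
#' @param priors An [agent_priors()] with a non-null `gamma0`.
#' @param n_states,n_actions Dimensions of the task.
#' @return An object of class `td_agent_state`.
#' @export
new_td_agent <- function(priors, n_states = 5L, n_actions = 2L) {
  stopifnot(inherits(priors, "agent_priors"), !is.null(priors$gamma0))
  t0 <- c(priors$theta0$mu, priors$theta0$kappa, priors$theta0$alpha,
          priors$theta0$beta)
  p0 <- c(priors$phi0$a, priors$phi0$b)
  b0 <- c(priors$beta0$a, priors$beta0$b)
  bel <- array(rep(c(t0, p0, b0), each = n_states * n_actions),
               dim = c(n_states, n_actions, 8))
  structure(list(
    bel = bel, lag = matrix(0L, n_states, n_actions),
    counts = matrix(0, n_states, n_actions),
    gamma = priors$gamma0, n_states = n_states, n_actions = n_actions
  ), class = "td_agent_state")
}

## policy-prior (Dirichlet pi0) smoothed state value
td_state_value <- function(agent, s, pi0) {
  p <- (agent$counts[s, ] + pi0) / (sum(agent$counts[s, ]) +
                                      agent$n_actions * pi0)
  sum(p * agent$bel[s, , 1])
}

#' Temporal-difference update of the agent
#'
#' The chosen state-action's belief is updated with the bootstrapped
#' observation r + E(gamma) * V(next state), where V is the
#' policy-prior-weighted mean over the next state's action posteriors. The
#' Beta belief over the discount factor is then updated by NCVMP against
#' the expected log-likelihood of that observation, with a forgetting
#' weight inherited from the chosen action's first-level forgetting factor
#' (so a drop of `w` pulls the discount belief back to its prior).
#' Beliefs about state-actions not selected for `n` trials re-enter through
#' the lag-adjusted weighted prior (`w^n`, delayed updating).
#'
#' @param agent A `td_agent_state`.
#' @param s,a,r,s_next Trial data: state, action (1 = left, 2 = right),
#'   reward, next state (`NA` for a terminal transition, which triggers a
#'   pure reward update).
#' @param priors An [agent_priors()].
#' @param tol,max_iter,damping Critic convergence controls.
#' @return The updated `td_agent_state` with fields `last_elbo`,
#'   `last_what` describing the update.
#' @export
td_update <- function(agent, s, a, r, s_next, priors, tol = 1e-3,
                      max_iter = 50L, damping = 0.8) {
  stopifnot(inherits(agent, "td_agent_state"))
  t0 <- c(priors$theta0$mu, priors$theta0$kappa, priors$theta0$alpha,
          priors$theta0$beta)
  p0 <- c(priors$phi0$a, priors$phi0$b)
  b0 <- c(priors$beta0$a, priors$beta0$b)
  g <- agent$gamma
  g_hat <- g$a / (g$a + g$b)
  v_next <- if (is.na(s_next)) 0 else td_state_value(agent, s_next,
                                                     priors$pi0)
  x_eff <- r + g_hat * v_next

  q <- agent$bel[s, a, ]
  ## delayed updating: discount the previous posterior by w^lag
  lag <- max(1L, agent$lag[s, a] + 1L)
  if (lag > 1L) {
    pa <- q[5] / (q[5] + q[6])
    om <- pa^(lag - 1L)  # extra decay beyond the standard one-step path
    th <- weighted_prior_num(q[1], q[2], q[3], q[4], t0[1], t0[2], t0[3],
                             t0[4], om)
    q[1:4] <- th
  }
  up <- hafvf_update1_cpp(q[1:4], q[5:6], q[7:8], t0, p0, b0, x_eff,
                          tol, as.integer(max_iter), damping)
  agent$bel[s, a, ] <- up[1:8]
  w_hat <- up[5] / (up[5] + up[6])

  ## discount-factor update (only when a next state exists)
  if (!is.na(s_next) && v_next != 0) {
    einv <- up[3] / up[4]
    mu_j <- up[1]
    ca <- w_hat * g$a + (1 - w_hat) * priors$gamma0$a - 1
    cb <- w_hat * g$b + (1 - w_hat) * priors$gamma0$b - 1
    S <- function(ga, gb) {
      gh <- ga / (ga + gb)
      vg <- ga * gb / ((ga + gb)^2 * (ga + gb + 1))
      d <- digamma(ga + gb)
      -0.5 * einv * ((r + gh * v_next - mu_j)^2 + vg * v_next^2) +
        ca * (digamma(ga) - d) + cb * (digamma(gb) - d)
    }
    agent$gamma <- ncvmp_damped_step(g, S, damping)
  }

  agent$counts[s, a] <- agent$counts[s, a] + 1
  agent$lag <- agent$lag + 1L
  agent$lag[s, a] <- 0L
  agent$last_elbo <- up[9]
  agent$last_what <- w_hat
  agent
}

#' Run the multi-stage (TD) simulation study
#'
#' Simulates agents on the two-phase 5-state MDP task: the first MDP for
#' the first half of the session, an abrupt switch to the second MDP at the
#' midpoint. Agents select actions through the diffusion actor applied to
#' the bootstrapped action values and learn by [td_update()].
#'
#' @param experiment `"i"` (deep change) or `"ii"` (shallow change).
#' @param n_agents Number of simulated agents.
#' @param n_trials Session length (change point at `n_trials / 2`).
#' @param priors An [agent_priors()] with `gamma0`; the default follows the
#'   multi-stage study configuration (`mu0 = 0`, `kappa0 = 0.5`,
#'   `alpha0 = 3`, `beta0 = 0.5`, flat forgetting priors, discount prior
#'   `Beta(9, 1)`, `pi0 = 5`).
#' @param ddm A [ddm_params()] for the action race.
#' @param seed Integer seed.
#' @param dt Euler step of the race.
#' @return A tibble with one row per agent x trial: `state`, `action`,
#'   `reward`, `rt`, `w_hat` (chosen action), `e_gamma`, `phase`.
#' @export
run_mdp_experiment <- function(experiment = c("i", "ii"), n_agents = 64L,
                               n_trials = 1000L,
                               priors = mdp_priors(),
                               ddm = ddm_params(2, 1, 0.3), seed = 1L,
                               dt = 1e-3) {
  experiment <- match.arg(experiment)
  set.seed(seed)
  half <- n_trials %/% 2L
  pre <- mdp_spec("pre", experiment)
  post <- mdp_spec("post", experiment)
  res <- vector("list", n_agents)
  for (ag in seq_len(n_agents)) {
    agent <- new_td_agent(priors)
    s <- sample.int(5L, 1L)
    out <- matrix(NA_real_, n_trials, 7)
    for (j in seq_len(n_trials)) {
      spec <- if (j <= half) pre else post
      g_hat <- agent$gamma$a / (agent$gamma$a + agent$gamma$b)
      ## bootstrapped action values: E[r] + E[gamma] V(intended target)
      qv <- vapply(1:2, function(a) {
        agent$bel[s, a, 1] +
          g_hat * td_state_value(agent, spec$intended[s, a], priors$pi0)
      }, numeric(1))
      ## race between the two bootstrapped values using each action's
      ## posterior uncertainty
      sig <- vapply(1:2, function(a) {
        1 / stats::rgamma(1, agent$bel[s, a, 3], rate = agent$bel[s, a, 4])
      }, numeric(1))
      mtilde <- stats::rnorm(2, qv, sqrt(sig / agent$bel[s, , 2]))
      race <- euler_race_cpp(1L, mtilde[1] - mtilde[2], sum(sig),
                             ddm$zeta, ddm$z0, dt, 1e6)
      a <- as.integer(race[1, 1])
      rt <- race[1, 2] + ddm$tau
      s_next <- mdp_transition(spec, s, a)
      r <- if (s_next == spec$rewarded_state) spec$reward else 0
      agent <- td_update(agent, s, a, r, s_next, priors)
      out[j, ] <- c(s, a, r, rt, agent$last_what, g_hat,
                    as.numeric(j <= half))
      s <- s_next
    }
    res[[ag]] <- tibble::tibble(
      agent = ag, trial = seq_len(n_trials), state = as.integer(out[, 1]),
      action = as.integer(out[, 2]), reward = out[, 3], rt = out[, 4],
      w_hat = out[, 5], e_gamma = out[, 6],
      phase = ifelse(out[, 7] > 0, "pre", "post")
    )
  }
  dplyr::bind_rows(res)
}

#' Default priors of the multi-stage study
#'
#' @return An [agent_priors()] with the multi-stage configuration.
#' @export
mdp_priors <- function() {
  agent_priors(theta0 = nig_posterior(0, 0.5, 3, 0.5),
               phi0 = beta_belief(1, 1), beta0 = beta_belief(1, 1),
               gamma0 = beta_belief(9, 1), pi0 = 5)
}
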