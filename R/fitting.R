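#' Softplus transform and its log-Jacobian
#'
#' `softplus(x) = log(1 + exp(x))` maps the real line onto the positive
#' half-line with a bounded gradient (unlike the exponential map), which
#' regularizes MAP optimisation of positive-domain parameters. The
#' log-Jacobian of the transform is `-log(1 + exp(-x))`; it is added to the
#' variational bound for transformed latent variances (not for transformed
#' hyperparameters, which are optimized, not integrated).
#'
#' @param x Real vector (unbounded scale).
#' @param y Positive vector (natural scale).
#' @return `softplus` and `inv_softplus` return the transformed vector;
#'   `softplus_log_jacobian` returns `log |d softplus(x) / dx|`.
#' @examples
#' softplus_log_jacobian(0)  # -log(2)
#' @export
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' @rdname softplus
#' @export
inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, y + log(-expm1(-pmin(y, 30))))
}

#' @rdname softplus
#' @export
softplus_log_jacobian <- function(x) ifelse(x < -30, x, -log1p(exp(-pmax(x, -30))))

## ---------------------------------------------------------------------------

#' Deterministic forward filter over a choice-reward session
#'
#' Runs the critic over an observed two-action session: on each trial the
#' chosen action's belief receives the hierarchical trial update with the
#' observed reward and the unchosen action receives the continuous
#' counterfactual update. Returns the *pre-decision* beliefs of both
#' actions on every trial (the state the actor acted from), plus the
#' post-update diagnostics. The trajectory is a deterministic, smooth
#' function of the prior parameters, so its outputs can be differentiated
#' numerically.
#'
#' @param data A tibble with columns `choice` (1/2) and `reward`, ordered
#'   by trial.
#' @param priors An [agent_priors()] object.
#' @param tol,max_iter,damping Critic convergence controls.
#' @return A tibble with one row per trial: `q1_mu ... q1_beta`,
#'   `q2_mu ... q2_beta` (pre-decision NIG parameters), `w_hat`, `b_hat`
#'   and `elbo` of the chosen action's update.
#' @export
forward_filter <- function(data, priors, tol = 1e-3, max_iter = 50L,
                           damping = 0.8) {
  stopifnot(all(c("choice", "reward") %in% names(data)),
            inherits(priors, "agent_priors"))
  n <- nrow(data)
  t0 <- c(priors$theta0$mu, priors$theta0$kappa, priors$theta0$alpha,
          priors$theta0$beta)
  p0 <- c(priors$phi0$a, priors$phi0$b)
  b0 <- c(priors$beta0$a, priors$beta0$b)
  bel <- list(c(t0, p0, b0), c(t0, p0, b0))
  out <- matrix(NA_real_, n, 11)
  for (j in seq_len(n)) {
    out[j, 1:8] <- c(bel[[1]][1:4], bel[[2]][1:4])
    ch <- data$choice[j]
    qc <- bel[[ch]]
    up <- hafvf_update1_cpp(qc[1:4], qc[5:6], qc[7:8], t0, p0, b0,
                            data$reward[j], tol, as.integer(max_iter),
                            damping)
    bel[[ch]] <- up[1:8]
    bel[[3L - ch]] <- counterfactual_num(bel[[3L - ch]], t0, p0)
    out[j, 9:11] <- c(up[5] / (up[5] + up[6]), up[7] / (up[7] + up[8]),
                      up[9])
  }
  colnames(out) <- c("q1_mu", "q1_kappa", "q1_alpha", "q1_beta",
                     "q2_mu", "q2_kappa", "q2_alpha", "q2_beta",
                     "w_hat", "b_hat", "elbo")
  dplyr::mutate(tibble::as_tibble(as.data.frame(out)),
                trial = dplyr::row_number(), .before = 1L)
}

## unbounded <-> natural parameterization of agent priors (8 parameters)
priors_to_unbounded <- function(priors) {
  c(mu0 = priors$theta0$mu,
    kappa0 = inv_softplus(priors$theta0$kappa),
    alpha0 = inv_softplus(priors$theta0$alpha),
    beta0 = inv_softplus(priors$theta0$beta),
    phi_a = inv_softplus(priors$phi0$a),
    phi_b = inv_softplus(priors$phi0$b),
    bet_a = inv_softplus(priors$beta0$a),
    bet_b = inv_softplus(priors$beta0$b))
}

unbounded_to_priors <- function(u) {
  agent_priors(
    theta0 = nig_posterior(u[[1]], softplus(u[[2]]), softplus(u[[3]]),
                           softplus(u[[4]])),
    phi0 = beta_belief(softplus(u[[5]]), softplus(u[[6]])),
    beta0 = beta_belief(softplus(u[[7]]), softplus(u[[8]])))
}

#' Gradient of a forward-filter functional w.r.t. the unbounded priors
#'
#' Richardson-extrapolated central-difference gradient of a scalar
#' functional of the critic trajectory (by default the session-total
#' evidence lower bound) in the unbounded prior parameterization. The
#' two-level extrapolation `(4 g(h/2) - g(h)) / 3` with a moderately large
#' base step keeps the estimate above the filter's internal
#' finite-difference noise floor while cancelling the leading truncation
#' error.
#'
#' @param u Named unbounded parameter vector (mu0 raw, softplus transform
#'   for the positive-domain parameters).
#' @param x Observation stream (numeric vector).
#' @param fn Functional mapping a filter trace to a scalar; default sums
#'   the per-trial ELBO.
#' @param sweeps Fixed sweep count per trial (smooth filtering mode).
#' @param h Base finite-difference step.
#' @return Gradient vector, same length as `u`.
#' @export
forward_filter_grad <- function(u, x, fn = function(tr) sum(tr$elbo),
                                sweeps = 4L, h = 2e-4) {
  f <- function(v) fn(hafvf_filter(x, unbounded_to_priors(v), tol = 0,
                                   max_iter = sweeps))
  u <- as.numeric(u)
  vapply(seq_along(u), function(i) {
    e <- replace(numeric(length(u)), i, 1)
    g1 <- (f(u + h * e) - f(u - h * e)) / (2 * h)
    g2 <- (f(u + h / 2 * e) - f(u - h / 2 * e)) / h
    (4 * g2 - g1) / 3
  }, numeric(1))
}

## ---------------------------------------------------------------------------
## Amortized inference network: one hidden layer mapping per-trial data and
## critic state to a Gaussian posterior over the trial latents
## chi = (xi, u1, u2), u_i the inverse-softplus of the action noise
## variances.

#' Initialize an amortized inference network
#'
#' A single-hidden-layer perceptron (tanh) mapping the 9 per-trial features
#' `(rt, choice sign, mu1 - mu2, kappa1, kappa2, alpha1, alpha2, beta1,
#' beta2)` to the mean vector and lower-triangular Cholesky factor of a
#' 3-dimensional Gaussian over the trial latents.
#'
#' @param n_hidden Hidden-layer width.
#' @param seed Integer seed for the weight initialization.
#' @param init_scale Standard deviation of the initial weights.
#' @return An object of class `inference_net`.
#' @export
new_inference_net <- function(n_hidden = 32L, seed = 1L, init_scale = 0.1) {
  set.seed(seed)
  n_in <- 9L
  n_out <- 9L
  structure(list(
    W1 = matrix(stats::rnorm(n_in * n_hidden, 0, init_scale / sqrt(n_in)),
                n_in, n_hidden),
    b1 = numeric(n_hidden),
    W2 = matrix(stats::rnorm(n_hidden * n_out, 0,
                             init_scale / sqrt(n_hidden)),
                n_hidden, n_out),
    b2 = numeric(n_out)
  ), class = "inference_net")
}

net_features <- function(data, omega) {
  cbind(data$rt, ifelse(data$choice == 1, 1, -1),
        omega$q1_mu - omega$q2_mu, omega$q1_kappa, omega$q2_kappa,
        omega$q1_alpha, omega$q2_alpha, omega$q1_beta, omega$q2_beta)
}

net_forward <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2, net$b1, "+"))
  O <- sweep(H %*% net$W2, 2, net$b2, "+")
  list(H = H, O = O)
}

## gradients of the network weights given dL/dO (n x 9)
net_backprop <- function(net, X, H, dO) {
  dH <- (dO %*% t(net$W2)) * (1 - H^2)
  list(W1 = t(X) %*% dH, b1 = colSums(dH),
       W2 = t(H) %*% dO, b2 = colSums(dO))
}

## unpack network outputs into q(chi) parameters
net_unpack <- function(O) {
  list(mu = O[, 1:3, drop = FALSE],
       ld = softplus(O[, 4:6, drop = FALSE]) + 1e-4,
       lo = O[, 7:9, drop = FALSE])  # L21, L31, L32
}

## log inverse-gamma density
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

## per-trial reparameterized bound for all trials at once.
## eps: n x 3 x n_mc array of standard normal draws.
## Returns list(value = per-trial bound vector, and if grad = TRUE the
## gradient w.r.t. the 9 network outputs (n x 9) and the ddm parameters).
bound_all <- function(data, omega, ddm, net_out, eps, grad = FALSE,
                      h_ddm = 1e-4) {
  n <- nrow(data)
  n_mc <- dim(eps)[3]
  P <- net_unpack(net_out$O)
  acc <- numeric(n)
  dO <- if (grad) matrix(0, n, 9) else NULL
  g_ddm <- c(zeta = 0, z0 = 0, tau = 0)

  mu_d <- omega$q1_mu - omega$q2_mu

  logjoint_chi <- function(xi, u1, u2, dd) {
    s1 <- softplus(u1)
    s2 <- softplus(u2)
    lw <- wiener_log_density(data$rt, data$choice, xi, s1 + s2, dd)
    lw[!is.finite(lw)] <- -1e4
    lp_xi <- stats::dnorm(xi, mu_d,
                          sqrt(s1 / omega$q1_kappa + s2 / omega$q2_kappa),
                          log = TRUE)
    lp_s <- dinvgamma_log(s1, omega$q1_alpha, omega$q1_beta) +
      dinvgamma_log(s2, omega$q2_alpha, omega$q2_beta) +
      softplus_log_jacobian(u1) + softplus_log_jacobian(u2)
    lw + lp_xi + lp_s
  }

  for (m in seq_len(n_mc)) {
    e <- eps[, , m, drop = FALSE]
    dim(e) <- c(n, 3)
    xi <- P$mu[, 1] + P$ld[, 1] * e[, 1]
    u1 <- P$mu[, 2] + P$lo[, 1] * e[, 1] + P$ld[, 2] * e[, 2]
    u2 <- P$mu[, 3] + P$lo[, 2] * e[, 1] + P$lo[, 3] * e[, 2] +
      P$ld[, 3] * e[, 3]
    lj <- logjoint_chi(xi, u1, u2, ddm)
    acc <- acc + lj / n_mc
    if (grad) {
      h <- 1e-4
      gxi <- (logjoint_chi(xi + h, u1, u2, ddm) -
                logjoint_chi(xi - h, u1, u2, ddm)) / (2 * h)
      gu1 <- (logjoint_chi(xi, u1 + h, u2, ddm) -
                logjoint_chi(xi, u1 - h, u2, ddm)) / (2 * h)
      gu2 <- (logjoint_chi(xi, u1, u2 + h, ddm) -
                logjoint_chi(xi, u1, u2 - h, ddm)) / (2 * h)
      ## chain rule chi = mu + L eps, ld = softplus(o_{4:6})
      dO[, 1] <- dO[, 1] + gxi / n_mc
      dO[, 2] <- dO[, 2] + gu1 / n_mc
      dO[, 3] <- dO[, 3] + gu2 / n_mc
      dO[, 4] <- dO[, 4] + gxi * e[, 1] / n_mc
      dO[, 5] <- dO[, 5] + gu1 * e[, 2] / n_mc
      dO[, 6] <- dO[, 6] + gu2 * e[, 3] / n_mc
      dO[, 7] <- dO[, 7] + gu1 * e[, 1] / n_mc
      dO[, 8] <- dO[, 8] + gu2 * e[, 1] / n_mc
      dO[, 9] <- dO[, 9] + gu2 * e[, 2] / n_mc
      ## ddm parameter gradients by central differences on the Wiener term
      for (pn in c("zeta", "z0", "tau")) {
        dp <- ddm
        dp[[pn]] <- dp[[pn]] + h_ddm
        dm <- ddm
        dm[[pn]] <- dm[[pn]] - h_ddm
        if (pn == "zeta") {
          ## keep the relative start point fixed when zeta moves
          dp$z0 <- ddm$z0 * dp$zeta / ddm$zeta
          dm$z0 <- ddm$z0 * dm$zeta / ddm$zeta
        }
        lwp <- wiener_log_density(data$rt, data$choice, xi,
                                  softplus(u1) + softplus(u2), dp)
        lwm <- wiener_log_density(data$rt, data$choice, xi,
                                  softplus(u1) + softplus(u2), dm)
        lwp[!is.finite(lwp)] <- -1e4
        lwm[!is.finite(lwm)] <- -1e4
        g_ddm[[pn]] <- g_ddm[[pn]] +
          sum(lwp - lwm) / (2 * h_ddm) / n_mc
      }
    }
  }
  ## entropy of q (does not depend on eps): 3/2 log(2 pi e) + sum log ld
  ent <- 1.5 * log(2 * pi * exp(1)) + rowSums(log(P$ld))
  value <- acc + ent
  if (grad) {
    ## d entropy / d ld = 1 / ld, through softplus
    sig <- stats::plogis(net_out$O[, 4:6, drop = FALSE])
    dO[, 4:6] <- (dO[, 4:6] + 1 / P$ld) * sig
    ## means and off-diagonals pass through unchanged (identity link)
    list(value = value, dO = dO, g_ddm = g_ddm)
  } else {
    list(value = value)
  }
}

#' Variational lower bound on the log-likelihood of one trial
#'
#' Reparameterized Monte-Carlo estimate of
#' `E_q[log Wiener(y | chi) + log p(chi | Omega_j) - log q(chi | y)]`, with
#' the softplus log-Jacobian corrections for the transformed latent
#' variances. An unbiased lower bound on the marginal log-density of the
#' trial's `(choice, rt)` pair in expectation.
#'
#' @param y One-row tibble (or list) with `rt` and `choice`.
#' @param omega One-row tibble with the pre-decision beliefs
#'   (`q1_mu ... q2_beta`, as returned by [forward_filter()]).
#' @param ddm A [ddm_params()] object.
#' @param net An [new_inference_net()] object.
#' @param n_mc Number of Monte-Carlo samples.
#' @return Scalar bound value (nats).
#' @export
trial_bound <- function(y, omega, ddm, net, n_mc = 8L) {
  y <- tibble::as_tibble(y)
  omega <- tibble::as_tibble(omega)
  eps <- array(stats::rnorm(3 * n_mc), dim = c(1, 3, n_mc))
  out <- bound_all(y, omega, ddm, net_forward(net, net_features(y, omega)),
                   eps, grad = FALSE)
  out$value[1]
}

## pretrain the network to match the prior moments of chi (cheap
## least-squares warm start so the variational posterior begins close to
## the per-trial prior rather than at an arbitrary point)
net_pretrain <- function(net, X, omega, n_iter = 200L, lr = 0.05) {
  e_s1 <- omega$q1_beta / pmax(omega$q1_alpha - 1, 0.5)
  e_s2 <- omega$q2_beta / pmax(omega$q2_alpha - 1, 0.5)
  targ_mu <- cbind(omega$q1_mu - omega$q2_mu, inv_softplus(e_s1),
                   inv_softplus(e_s2))
  targ_sd <- cbind(sqrt(e_s1 / omega$q1_kappa + e_s2 / omega$q2_kappa),
                   1 / sqrt(pmax(omega$q1_alpha, 1)),
                   1 / sqrt(pmax(omega$q2_alpha, 1)))
  targ <- cbind(targ_mu, inv_softplus(pmax(targ_sd, 1e-3)),
                matrix(0, nrow(X), 3))
  ms <- vs <- lapply(net[c("W1", "b1", "W2", "b2")], function(p) p * 0)
  for (i in seq_len(n_iter)) {
    fw <- net_forward(net, X)
    dO <- 2 * (fw$O - targ) / nrow(X)
    gr <- net_backprop(net, X, fw$H, dO)
    for (nm in names(gr)) {
      ms[[nm]] <- 0.9 * ms[[nm]] + 0.1 * gr[[nm]]
      vs[[nm]] <- 0.99 * vs[[nm]] + 0.01 * gr[[nm]]^2
      net[[nm]] <- net[[nm]] - lr * ms[[nm]] / (sqrt(vs[[nm]]) + 1e-8)
    }
  }
  net
}

#' MAP fit of the actor parameters to choice/reaction-time data
#'
#' Fits per-subject diffusion parameters (threshold, start-point bias and
#' non-decision time) and a shared amortized inference network by
#' stochastic gradient ascent on the sum of per-trial variational bounds,
#' with an L2 penalty (standard normal prior) on all parameters in the
#' unbounded space. Optimisation uses Adam (step size 0.005, beta1 = 0.9,
#' beta2 = 0.99) with the step size divided by `ceiling(i / 1000)` and an
#' annealing jitter with variance `1 / i` added to the parameters at each
#' iteration. The critic trajectory of each subject is computed once from
#' `priors` (it does not depend on the actor parameters).
#'
#' @param sessions A list of session tibbles, each with columns `choice`,
#'   `reward`, `rt`.
#' @param priors An [agent_priors()] used for the critic forward pass
#'   (shared across subjects).
#' @param n_iter Number of Adam iterations.
#' @param n_mc Monte-Carlo samples per trial and iteration.
#' @param n_hidden Hidden units of the inference network.
#' @param seed Integer seed (controls initialization, annealing and the
#'   reparameterization noise).
#' @param init Optional list with starting values `zeta`, `z0_rel`, `tau`
#'   (shared across subjects).
#' @param verbose Print progress every 100 iterations.
#' @return An object of class `hafvf_map_fit`: tibble `subjects` with the
#'   fitted `zeta`, `z0`, `tau` per subject, the shared `net`, the loss
#'   trace and the final bound.
#' @export
map_fit <- function(sessions, priors, n_iter = 300L, n_mc = 8L,
                    n_hidden = 32L, seed = 1L, init = NULL,
                    verbose = FALSE) {
  stopifnot(is.list(sessions), length(sessions) >= 1L)
  set.seed(seed)
  ns <- length(sessions)
  ## per-subject critic pass and features (fixed during optimisation)
  omegas <- lapply(sessions, forward_filter, priors = priors)
  feats <- Map(function(d, o) net_features(d, o), sessions, omegas)
  net <- new_inference_net(n_hidden, seed = seed + 1L)
  net <- net_pretrain(net, do.call(rbind, feats),
                      dplyr::bind_rows(omegas))
  rt_min <- vapply(sessions, function(d) min(d$rt), numeric(1))
  if (is.null(init)) init <- list(zeta = 2, z0_rel = 0.5, tau = 0.25)
  ## unbounded per-subject parameters: zeta_u, nu (logit start bias), tau_u
  par <- cbind(rep(inv_softplus(init$zeta), ns),
               rep(stats::qlogis(init$z0_rel), ns),
               stats::qlogis(pmin(init$tau / (0.98 * rt_min), 0.9)))
  colnames(par) <- c("zeta_u", "nu", "tau_u")
  adam_m <- list(par = par * 0,
                 net = lapply(net[c("W1", "b1", "W2", "b2")],
                              function(p) p * 0))
  adam_v <- adam_m
  loss_trace <- numeric(n_iter)
  b1 <- 0.9
  b2 <- 0.99
  unpack_ddm <- function(p, k) {
    zeta <- softplus(p[k, 1])
    ddm_params(zeta, zeta * stats::plogis(p[k, 2]),
               stats::plogis(p[k, 3]) * 0.98 * rt_min[k])
  }
  for (i in seq_len(n_iter)) {
    jit_sd <- 1 / sqrt(i)
    par_j <- par + stats::rnorm(length(par), 0, jit_sd)
    net_j <- net
    for (nm in c("W1", "b1", "W2", "b2")) {
      net_j[[nm]] <- net_j[[nm]] +
        stats::rnorm(length(net_j[[nm]]), 0, jit_sd * 0.1)
    }
    total <- 0
    g_par <- par * 0
    g_net <- lapply(net[c("W1", "b1", "W2", "b2")], function(p) p * 0)
    for (k in seq_len(ns)) {
      d <- sessions[[k]]
      om <- omegas[[k]]
      dd <- unpack_ddm(par_j, k)
      fw <- net_forward(net_j, feats[[k]])
      eps <- array(stats::rnorm(nrow(d) * 3 * n_mc),
                   dim = c(nrow(d), 3, n_mc))
      out <- bound_all(d, om, dd, fw, eps, grad = TRUE)
      total <- total + sum(out$value)
      gb <- net_backprop(net_j, feats[[k]], fw$H, out$dO)
      for (nm in names(g_net)) g_net[[nm]] <- g_net[[nm]] + gb[[nm]]
      ## chain ddm gradients into the unbounded parameterization
      zeta <- dd$zeta
      dz_du <- stats::plogis(par_j[k, 1])          # d zeta / d zeta_u
      z0rel <- stats::plogis(par_j[k, 2])
      ## g_ddm["zeta"] is taken at fixed relative start point, so it
      ## already includes the induced shift of z0
      g_par[k, 1] <- out$g_ddm[["zeta"]] * dz_du
      g_par[k, 2] <- out$g_ddm[["z0"]] * zeta * z0rel * (1 - z0rel)
      g_par[k, 3] <- out$g_ddm[["tau"]] * 0.98 * rt_min[k] *
        stats::plogis(par_j[k, 3]) * (1 - stats::plogis(par_j[k, 3]))
    }
    ## L2 prior on all parameters in the unbounded space
    total <- total - 0.5 * (sum(par_j^2) +
                              sum(vapply(c("W1", "b1", "W2", "b2"),
                                         function(nm) sum(net_j[[nm]]^2),
                                         numeric(1))))
    g_par <- g_par - par_j
    for (nm in names(g_net)) g_net[[nm]] <- g_net[[nm]] - net_j[[nm]]
    loss_trace[i] <- total
    lr <- 0.005 / ceiling(i / 1000)
    adam_m$par <- b1 * adam_m$par + (1 - b1) * g_par
    adam_v$par <- b2 * adam_v$par + (1 - b2) * g_par^2
    par <- par + lr * (adam_m$par / (1 - b1^i)) /
      (sqrt(adam_v$par / (1 - b2^i)) + 1e-8)
    for (nm in names(g_net)) {
      adam_m$net[[nm]] <- b1 * adam_m$net[[nm]] + (1 - b1) * g_net[[nm]]
      adam_v$net[[nm]] <- b2 * adam_v$net[[nm]] + (1 - b2) * g_net[[nm]]^2
      net[[nm]] <- net[[nm]] + lr * (adam_m$net[[nm]] / (1 - b1^i)) /
        (sqrt(adam_v$net[[nm]] / (1 - b2^i)) + 1e-8)
    }
    if (verbose && i %% 100 == 0) {
      message(sprintf("iter %d  bound %.2f", i, total))
    }
    if (!is.finite(total)) {
      stop("map_fit diverged (non-finite objective)", call. = FALSE)
    }
  }
  subjects <- purrr::map_dfr(seq_len(ns), function(k) {
    dd <- unpack_ddm(par, k)
    tibble::tibble(subject = k, zeta = dd$zeta, z0 = dd$z0, tau = dd$tau,
                   z0_rel = dd$z0 / dd$zeta)
  })
  structure(list(subjects = subjects, par_unbounded = par, net = net,
                 loss_trace = loss_trace,
                 final_bound = loss_trace[n_iter], priors = priors,
                 seed = seed),
            class = "hafvf_map_fit")
}

#' @export
print.hafvf_map_fit <- function(x, ...) {
  cat(sprintf("<hafvf_map_fit: %d subjects, final bound %.2f>\n",
              nrow(x$subjects), x$final_bound))
  print(x$subjects)
  invisible(x)
}

## ---------------------------------------------------------------------------

#' MAP fit of the hierarchical filter to a univariate signal
#'
#' Finds the posterior mode of the eight prior parameters (reward prior
#' `mu0, kappa0, alpha0, beta0` and the two Beta forgetting priors) under a
#' standard normal hyperprior in the unbounded space (inverse-softplus
#' transform for positive-domain parameters), using the session-total
#' per-trial evidence lower bound as the log-likelihood of the signal. The
#' quadratic (Laplace) approximation of the log model evidence is computed
#' at the mode.
#'
#' @param x Numeric observation stream.
#' @param init Starting point in the unbounded space (default: zero
#'   vector, i.e. the hyperprior mode).
#' @param compute_evidence Also compute the Laplace evidence?
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return An object of class `hafvf_map`: unbounded and natural parameter
#'   estimates, the log-joint at the mode, the Laplace `evidence`, and
#'   convergence diagnostics.
#' @export
fit_signal_map <- function(x, init = NULL,
                           compute_evidence = TRUE,
                           control = list(maxit = 500), sweeps = 4L) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  if (is.null(init)) init <- numeric(8)
  ## fixed number of coordinate-ascent sweeps per trial (tol = 0) keeps the
  ## objective smooth so numerical gradients and Hessians are reliable
  logjoint <- function(u) {
    pr <- tryCatch(unbounded_to_priors(u), error = function(e) NULL)
    if (is.null(pr)) return(-1e10)
    tr <- hafvf_filter(x, pr, tol = 0, max_iter = sweeps)
    lj <- sum(tr$elbo) + sum(stats::dnorm(u, 0, 1, log = TRUE))
    if (!is.finite(lj)) -1e10 else lj
  }
  opt <- stats::optim(init, function(u) -logjoint(u), method = "BFGS",
                      control = control)
  ## polish: restart BFGS from the incumbent until it stops improving
  ## (quasi-Newton restarts recover from stale curvature estimates)
  for (k in 1:4) {
    opt2 <- stats::optim(opt$par, function(u) -logjoint(u),
                         method = "BFGS", control = control)
    if (opt2$value > opt$value - 1e-6) {
      opt <- if (opt2$value < opt$value) opt2 else opt
      break
    }
    opt <- opt2
  }
  u <- opt$par
  names(u) <- c("mu0", "kappa0", "alpha0", "beta0", "phi_a", "phi_b",
                "bet_a", "bet_b")
  res <- list(par_unbounded = u, priors = unbounded_to_priors(u),
              logjoint = -opt$value, convergence = opt$convergence,
              n_trials = length(x))
  if (compute_evidence) {
    ev <- laplace_log_evidence(logjoint, u)
    res$evidence <- ev$evidence
    res$hessian <- ev$hessian
  }
  structure(res, class = "hafvf_map")
}

#' @export
print.hafvf_map <- function(x, ...) {
  cat(sprintf("<hafvf_map: %d trials, log-joint %.2f%s>\n", x$n_trials,
              x$logjoint,
              if (!is.null(x$evidence)) {
                sprintf(", Laplace evidence %.2f", x$evidence)
              } else ""))
  th <- x$priors$theta0
  cat(sprintf("  theta0: mu=%.3f kappa=%.3f alpha=%.3f beta=%.3f\n",
              th$mu, th$kappa, th$alpha, th$beta))
  cat(sprintf("  phi0: Beta(%.3f, %.3f)  beta0: Beta(%.3f, %.3f)\n",
              x$priors$phi0$a, x$priors$phi0$b, x$priors$beta0$a,
              x$priors$beta0$b))
  invisible(x)
}

#' Laplace (quadratic) approximation of the log model evidence
#'
#' Evaluates `logjoint(mode) + (M/2) log(2 pi) - 1/2 log det(-H)` with `H`
#' the Hessian of the log-joint at the mode, computed by central
#' differences. A Hessian that is not negative definite signals a saddle
#' point or non-convergence and raises an error.
#'
#' @param logjoint Function of the unbounded parameter vector returning the
#'   log-joint density (log-likelihood plus log-prior).
#' @param mode Parameter vector at (or near) the interior optimum.
#' @param h Finite-difference step.
#' @return A list with `evidence`, `hessian` and `logjoint` at the mode.
#' @export
laplace_log_evidence <- function(logjoint, mode, h = 1e-3) {
  m <- length(mode)
  f0 <- logjoint(mode)
  H <- matrix(NA_real_, m, m)
  fp <- numeric(m)
  fm <- numeric(m)
  for (i in seq_len(m)) {
    ei <- replace(numeric(m), i, h)
    fp[i] <- logjoint(mode + ei)
    fm[i] <- logjoint(mode - ei)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h^2
  }
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        ei <- replace(numeric(m), i, h)
        ej <- replace(numeric(m), j, h)
        fpp <- logjoint(mode + ei + ej)
        fmm <- logjoint(mode - ei - ej)
        H[i, j] <- H[j, i] <-
          (fpp - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + fmm) / (2 * h^2)
      }
    }
  }
  ev <- eigen(-H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("Hessian of the log-joint is not negative definite at the mode ",
         "(saddle point or non-convergence)", call. = FALSE)
  }
  list(evidence = f0 + (m / 2) * log(2 * pi) - 0.5 * sum(log(ev)),
       hessian = H, logjoint = f0)
}

## ---------------------------------------------------------------------------

#' Parameter-recovery study for the diffusion actor
#'
#' Simulates subjects with known diffusion parameters on the two-armed
#' bandit, fits them with [map_fit()], and reports true versus recovered
#' values.
#'
#' @param n_subjects,n_trials Study size.
#' @param seed Integer seed.
#' @param priors Critic priors used both to simulate and to fit.
#' @param n_iter Adam iterations for the fit.
#' @return A list with `subjects` (tibble of true and recovered `zeta`,
#'   `z0_rel`, `tau` with one row per subject) and the `fit` object.
#' @export
recover_ddm_study <- function(n_subjects = 8L, n_trials = 300L, seed = 1L,
                              priors = flexibility_priors("LL"),
                              n_iter = 600L) {
  set.seed(seed)
  truth <- tibble::tibble(
    subject = seq_len(n_subjects),
    zeta = exp(stats::rnorm(n_subjects, log(2), 0.35)),
    z0_rel = stats::plogis(stats::rnorm(n_subjects, 0, 0.5)),
    tau = 0.3 * exp(stats::rnorm(n_subjects, 0, 0.25)))
  sched <- bandit_schedule(n_trials)
  sessions <- lapply(seq_len(n_subjects), function(k) {
    run_session(sched, priors,
                ddm_params(truth$zeta[k], truth$zeta[k] * truth$z0_rel[k],
                           truth$tau[k]))
  })
  fit <- map_fit(sessions, priors, n_iter = n_iter, seed = seed + 1L)
  subjects <- dplyr::left_join(
    truth,
    dplyr::rename(fit$subjects, zeta_hat = "zeta", z0_rel_hat = "z0_rel",
                  tau_hat = "tau", z0_hat = "z0"),
    by = "subject")
  list(subjects = subjects, fit = fit)
}
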