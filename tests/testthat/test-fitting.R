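test_that("softplus pair and log-Jacobian evaluate correctly", {
  expect_equal(softplus_log_jacobian(0), -log(2))
  expect_equal(softplus_log_jacobian(-1), -log(1 + exp(1)))
  expect_equal(softplus_log_jacobian(50), 0, tolerance = 1e-12)
  x <- seq(-20, 20, by = 0.5)
  expect_equal(inv_softplus(softplus(x)), x, tolerance = 1e-8)
  ## the Jacobian is the derivative of the transform
  h <- 1e-6
  expect_equal(exp(softplus_log_jacobian(0.7)),
               (softplus(0.7 + h) - softplus(0.7 - h)) / (2 * h),
               tolerance = 1e-6)
})

test_that("forward filter is reproducible and its gradients match central differences", {
  set.seed(81)
  sched <- bandit_schedule(60)
  ses <- run_session(sched, flexibility_priors("LL"), ddm_params(2, 1, 0.2),
                     seed = 5)
  a <- forward_filter(ses, flexibility_priors("LL"))
  b <- forward_filter(ses, flexibility_priors("LL"))
  expect_identical(as.data.frame(a), as.data.frame(b))
  ## Richardson gradient vs plain central differences (h = 1e-5) of the
  ## session-total ELBO in the unbounded prior space
  u <- hafvf:::priors_to_unbounded(flexibility_priors("LL"))
  x <- ses$reward[1:50]
  last_elbo <- function(tr) tr$elbo[nrow(tr)]
  g <- forward_filter_grad(u, x, fn = last_elbo)
  f <- function(v) last_elbo(hafvf_filter(x, hafvf:::unbounded_to_priors(v),
                                          tol = 0, max_iter = 4))
  for (i in seq_along(u)) {
    e <- replace(numeric(8), i, 1e-5)
    fd <- (f(u + e) - f(u - e)) / 2e-5
    expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-2), 1e-3,
              label = paste("relative gradient error,", names(u)[i]))
  }
})

test_that("forward filter of 50 two-action trials runs quickly", {
  sched <- bandit_schedule(50)
  ses <- run_session(sched, flexibility_priors("LL"), ddm_params(2), seed = 6)
  t0 <- Sys.time()
  forward_filter(ses, flexibility_priors("LL"))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
})

test_that("a tight posterior with a matched variational family attains the marginal", {
  ## sharply concentrated beliefs: the trial marginal is close to a point
  ## evaluation, and a matched Gaussian q should reach it within 0.05 nat
  omega <- tibble::tibble(q1_mu = 1, q1_kappa = 400, q1_alpha = 300,
                          q1_beta = 300, q2_mu = -1, q2_kappa = 400,
                          q2_alpha = 300, q2_beta = 300)
  dd <- ddm_params(2, 1, 0.1)
  y <- tibble::tibble(rt = 0.6, choice = 1)
  ## matched q built by hand: mean at the prior mode, prior spread
  net <- new_inference_net(n_hidden = 4, seed = 1)
  net$W2[] <- 0
  e_s <- 300 / 299  # E[sigma^2] under IG(300, 300)
  sd_s2 <- 300 / (299 * sqrt(298))          # sd of sigma^2
  sd_u <- sd_s2 / (1 - exp(-e_s))           # through the inverse softplus
  net$b2 <- c(2, inv_softplus(e_s), inv_softplus(e_s),
              inv_softplus(sqrt(2 * e_s / 400)),
              inv_softplus(sd_u), inv_softplus(sd_u),
              0, 0, 0)
  set.seed(91)
  bounds <- replicate(40, trial_bound(y, omega, dd, net, n_mc = 16))
  quad <- oracle_trial_logmarginal(y$rt, y$choice, omega, dd)
  expect_lt(abs(mean(bounds) - quad), 0.05)
})

test_that("the trial bound never exceeds the quadrature log-marginal", {
  set.seed(92)
  dd <- ddm_params(2, 1, 0.1)
  net <- new_inference_net(n_hidden = 8, seed = 3)
  n_viol <- 0
  for (k in 1:20) {
    omega <- tibble::tibble(
      q1_mu = rnorm(1), q1_kappa = runif(1, 1, 10),
      q1_alpha = runif(1, 2, 8), q1_beta = runif(1, 1, 6),
      q2_mu = rnorm(1), q2_kappa = runif(1, 1, 10),
      q2_alpha = runif(1, 2, 8), q2_beta = runif(1, 1, 6))
    y <- tibble::tibble(rt = runif(1, 0.3, 2), choice = sample(1:2, 1))
    bs <- replicate(30, trial_bound(y, omega, dd, net, n_mc = 8))
    quad <- oracle_trial_logmarginal(y$rt, y$choice, omega, dd)
    ## allow 2 MC standard errors on the bound estimate
    if (mean(bs) > quad + 2 * sd(bs) / sqrt(length(bs)) + 0.02) {
      n_viol <- n_viol + 1
    }
  }
  expect_equal(n_viol, 0)
})

test_that("collapsing the variational scale below the optimum lowers the bound", {
  omega <- tibble::tibble(q1_mu = 0.5, q1_kappa = 5, q1_alpha = 4,
                          q1_beta = 3, q2_mu = -0.5, q2_kappa = 5,
                          q2_alpha = 4, q2_beta = 3)
  dd <- ddm_params(2, 1, 0.1)
  y <- tibble::tibble(rt = 0.8, choice = 1)
  base <- new_inference_net(n_hidden = 4, seed = 2)
  base$W2[] <- 0
  base$b2 <- c(1, inv_softplus(0.9), inv_softplus(0.9),
               inv_softplus(0.5), inv_softplus(0.3), inv_softplus(0.3),
               0, 0, 0)
  tight <- base
  tight$b2[4:6] <- inv_softplus(c(0.01, 0.01, 0.01))
  set.seed(93)
  b1 <- mean(replicate(30, trial_bound(y, omega, dd, base, n_mc = 16)))
  set.seed(93)
  b2 <- mean(replicate(30, trial_bound(y, omega, dd, tight, n_mc = 16)))
  expect_lt(b2, b1)
})

test_that("Laplace evidence is exact for a Gaussian log-joint and penalizes irrelevant parameters", {
  ## exactly quadratic log-joint: evidence equals the closed form
  A <- matrix(c(2, 0.5, 0.5, 1.5), 2, 2)
  m <- c(0.3, -0.7)
  cst <- -1.234
  f <- function(u) cst - 0.5 * drop(t(u - m) %*% A %*% (u - m))
  ev <- laplace_log_evidence(f, m)
  expect_equal(ev$evidence, cst + log(2 * pi) - 0.5 *
                 determinant(A)$modulus[1], tolerance = 1e-6)
  ## adding a parameter with a standard normal prior and a single
  ## normalized observation at zero lowers the evidence (Occam direction):
  ## the exact drop is log N(0 | 0, 2)
  f2 <- function(u) f(u[1:2]) - 0.5 * u[3]^2 -
    0.5 * u[3]^2 - log(2 * pi)
  ev2 <- laplace_log_evidence(f2, c(m, 0))
  expect_lt(ev2$evidence, ev$evidence)
  expect_equal(ev2$evidence - ev$evidence, dnorm(0, 0, sqrt(2), log = TRUE),
               tolerance = 1e-6)
  ## a saddle is rejected
  expect_error(laplace_log_evidence(function(u) u[1]^2 - u[2]^2, c(0, 0)),
               "negative definite")
})

test_that("map_fit is reproducible under identical seeds", {
  ## identical seeds reproduce the loss trace exactly
  ses <- lapply(1:2, function(k) run_session(bandit_schedule(60),
                                             flexibility_priors("LL"),
                                             ddm_params(2, 1, 0.2),
                                             seed = k))
  f1 <- map_fit(ses, flexibility_priors("LL"), n_iter = 20, seed = 5)
  f2 <- map_fit(ses, flexibility_priors("LL"), n_iter = 20, seed = 5)
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("signal MAP fit finds an interior mode with finite evidence", {
  sig <- gen_square_wave(seed = 2)
  fit <- fit_signal_map(sig$r[1:200], control = list(maxit = 200))
  expect_true(is.finite(fit$logjoint))
  expect_true(is.finite(fit$evidence))
  expect_lt(fit$evidence, fit$logjoint + 8 / 2 * log(2 * pi))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 8)
})
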