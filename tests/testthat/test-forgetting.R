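test_that("Taylor expected log-normalizer matches Gauss-Legendre quadrature", {
  tp <- nig_posterior(2.2, 6, 3.5, 4)
  t0 <- nig_posterior(0, 0.1, 1, 1)
  ## identical components: exactly zero for any belief
  expect_equal(expected_log_normalizer_taylor(beta_belief(2, 3), tp, tp), 0,
               tolerance = 1e-10)
  ## point-mass limit: tends to log Z at the mean
  phi_tight <- beta_belief(9000, 1000)
  expect_equal(expected_log_normalizer_taylor(phi_tight, tp, t0),
               mixture_log_normalizer(tp, t0, 0.9), tolerance = 1e-3)
  ## moderate-variance beliefs: within 5% of the quadrature value
  gl <- pracma::gaussLegendre(120, 0, 1)
  for (sh in list(c(18, 2), c(40, 12), c(8, 20))) {
    phi <- beta_belief(sh[1], sh[2])
    v <- phi$a * phi$b / ((phi$a + phi$b)^2 * (phi$a + phi$b + 1))
    expect_lt(v, 0.02)
    quad <- sum(gl$w * dbeta(gl$x, sh[1], sh[2]) *
                  vapply(gl$x, function(w)
                    mixture_log_normalizer(tp, t0, w), numeric(1)))
    expect_equal(expected_log_normalizer_taylor(phi, tp, t0), quad,
                 tolerance = abs(quad) * 0.05)
  }
})

test_that("undamped NCVMP fixed point sits at the ELBO grid optimum", {
  ## 5-trial toy stream; the oracle is a brute-force grid search over the
  ## Beta parameters of q(w), maximizing the same per-trial variational
  ## objective the step optimizes
  set.seed(11)
  x <- rnorm(5, 1.5, 0.7)
  pr <- flexibility_priors("LL")
  st <- new_agent_state(pr)
  for (j in 1:4) st <- hafvf_trial_update(st, x[j], pr)
  tp <- st$theta; pp <- st$phi; bb <- st$beta2
  bh <- bb$a / (bb$a + bb$b)
  ## converge the joint (theta, phi) fixed point, undamped
  phi <- beta_belief(bh * pp$a + (1 - bh) * pr$phi0$a,
                     bh * pp$b + (1 - bh) * pr$phi0$b)
  th <- tp
  for (k in 1:200) {
    w <- phi$a / (phi$a + phi$b)
    th <- nig_update(tp, pr$theta0, w, x[5])
    fs <- forgetting_state(phi, bb, pp, bb)
    phi <- ncvmp_step_w(fs, tp, pr$theta0, th, pr, damping = 1)
  }
  ## oracle objective: E[w]-weighted prior terms + Taylor E[log Z] + prior
  ## + entropy, maximized on a 50 x 50 log-spaced grid
  delta <- hafvf:::e_log_nig(th, tp) - hafvf:::e_log_nig(th, pr$theta0)
  ca <- bh * pp$a + (1 - bh) * pr$phi0$a
  cb <- bh * pp$b + (1 - bh) * pr$phi0$b
  obj <- function(a, b) {
    (a / (a + b)) * delta -
      expected_log_normalizer_taylor(beta_belief(a, b), tp, pr$theta0) +
      hafvf:::e_log_beta(beta_belief(a, b), beta_belief(ca, cb)) +
      hafvf:::beta_entropy(beta_belief(a, b))
  }
  as <- exp(seq(log(0.5), log(60), length.out = 50))
  bs <- exp(seq(log(0.05), log(8), length.out = 50))
  vals <- outer(as, bs, Vectorize(obj))
  ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  ## the fixed point lies within one grid cell of the argmax
  ratio_a <- phi$a / as[ix[1]]
  ratio_b <- phi$b / bs[ix[2]]
  step_a <- as[2] / as[1]
  step_b <- bs[2] / bs[1]
  expect_lt(abs(log(ratio_a)), log(step_a) * 1.5)
  expect_lt(abs(log(ratio_b)), log(step_b) * 1.5)
  ## and its objective value is not worse than the grid optimum
  expect_gt(obj(phi$a, phi$b), max(vals) - 1e-3)
})

test_that("NCVMP step degenerates to the conjugate prior pull when the likelihood is flat", {
  ## second level with identical previous posterior and prior: any b is
  ## admissible; the step returns the prior-pulled value
  pr <- flexibility_priors("LL")
  phi0 <- pr$phi0
  st <- forgetting_state(phi0, pr$beta0, phi0, pr$beta0)
  got <- ncvmp_step_b(st, phi0, phi0, pr$beta0, damping = 1)
  expect_equal(got$a, pr$beta0$a, tolerance = 1e-6)
  expect_equal(got$b, pr$beta0$b, tolerance = 1e-6)
  ## extremely concentrated prior dominates the posterior
  conc <- beta_belief(5000, 5000)
  st2 <- forgetting_state(beta_belief(4.5, 0.5), conc,
                          beta_belief(4.5, 0.5), conc)
  got2 <- ncvmp_step_b(st2, beta_belief(2, 1), beta_belief(4.5, 0.5),
                       conc, damping = 1)
  expect_equal(got2$a / (got2$a + got2$b), 0.5, tolerance = 0.01)
})

test_that("expected forgetting factors grow under stability and drop at an outlier", {
  set.seed(5)
  x <- rnorm(300, 3, 1)
  tr <- hafvf_filter(x, flexibility_priors("SL"))
  ## data consistently at the predictive mean: w_hat rises over trials
  expect_gt(tr$w_hat[300], tr$w_hat[5] + 0.2)
  ## single extreme outlier after training under a long-memory prior
  x2 <- c(rnorm(200, 3, 1), -6)
  tr2 <- hafvf_filter(x2, flexibility_priors("LL"))
  expect_lt(tr2$w_hat[201], tr2$w_hat[200])
  ## w_hat and b_hat always remain in (0, 1)
  for (t in list(tr, tr2)) {
    expect_true(all(t$w_hat > 0 & t$w_hat < 1))
    expect_true(all(t$b_hat > 0 & t$b_hat < 1))
  }
})

test_that("efficient memory uses the exact form when defined and the Taylor fallback otherwise", {
  e1 <- efficient_memory(beta_belief(9, 2))
  expect_equal(as.numeric(e1), 10)
  expect_true(attr(e1, "exact"))
  e2 <- efficient_memory(beta_belief(4.5, 0.5))
  expect_equal(as.numeric(e2), 10)
  expect_false(attr(e2, "exact"))
  e3 <- efficient_memory(beta_belief(1, 1))
  expect_equal(as.numeric(e3), 2)
  ## exact expectation check by Monte Carlo where defined
  set.seed(1)
  w <- rbeta(2e5, 9, 2)
  expect_equal(as.numeric(e1), mean(1 / (1 - w)), tolerance = 0.05)
})

test_that("effective memory is bounded by the efficient memory in stationary streams", {
  ## kappa_j tracks a geometric average of past forgetting factors, so the
  ## long-term bound uses the running maximum of the efficient memory
  ## (kappa_j <= kappa0 + max_{i<=j} eff_mem_i + 1, provable by induction
  ## on the update recursion)
  set.seed(9)
  for (profile in c("LL", "LS", "SL")) {
    pr <- flexibility_priors(profile)
    tr <- hafvf_filter(rnorm(400, 2, 1), pr)
    bound <- pr$theta0$kappa + cummax(tr$eff_mem_w) + 1
    expect_true(all(tr$kappa <= bound + 1e-8),
                label = paste("memory bound for", profile))
  }
})
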