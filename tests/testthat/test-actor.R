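test_that("absorption probability matches the closed form and its limits", {
  dd <- ddm_params(2, 1, 0)
  expect_equal(ddm_hit_probability(1, 1, dd),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(ddm_hit_probability(0, 1, dd), 0.5, tolerance = 1e-9)
  expect_equal(ddm_hit_probability(0, 1, ddm_params(2, 0.5, 0)), 0.25,
               tolerance = 1e-6)
  expect_equal(ddm_hit_probability(1e4, 1, dd), 1)
  expect_equal(ddm_hit_probability(-1e4, 1, dd), 0)
  ## continuity across the small-drift switch
  expect_equal(ddm_hit_probability(1e-10, 1, dd),
               ddm_hit_probability(1e-8, 1, dd), tolerance = 1e-6)
})

test_that("sampled drift moments match the analytic values", {
  p1 <- nig_posterior(1.2, 3, 4, 5)
  p2 <- nig_posterior(0.4, 2, 3, 2)
  set.seed(21)
  n <- 1e5
  d <- sample_action_params(p1, p2, n)
  e_xi <- p1$mu - p2$mu
  v_xi <- (p1$beta / (p1$alpha - 1)) / p1$kappa +
    (p2$beta / (p2$alpha - 1)) / p2$kappa
  expect_equal(mean(d$xi), e_xi, tolerance = 3 * sqrt(v_xi / n) / abs(e_xi))
  expect_equal(var(d$xi), v_xi, tolerance = 0.05)
  ## symmetry: identical posteriors give mean-zero drift
  d2 <- sample_action_params(p1, p1, n)
  expect_lt(abs(mean(d2$xi)), 4 * sd(d2$xi) / sqrt(n))
  ## concentration limit degenerates to the mean difference
  c1 <- nig_posterior(2, 1e8, 1e8, 1e8)
  c2 <- nig_posterior(1, 1e8, 1e8, 1e8)
  d3 <- sample_action_params(c1, c2, 100)
  expect_equal(d3$xi, rep(1, 100), tolerance = 1e-3)
})

test_that("Euler race frequencies match the analytic absorption probability on a grid", {
  dd <- ddm_params(2, 1, 0.1)
  set.seed(31)
  for (xi in c(-0.8, 0, 0.9)) {
    for (s2 in c(0.5, 1, 2.5)) {
      n <- 4000
      sim <- simulate_trials(n, xi, s2, dd, dt = 1e-3)
      p <- ddm_hit_probability(xi, s2, dd)
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(sim$choice == 1) - p), 3 * se + 0.005)
      expect_true(all(sim$rt >= dd$tau))
    }
  }
})

test_that("the first-passage density normalizes to the absorption probability and matches an independent series", {
  dd <- ddm_params(2, 0.8, 0)
  for (xi in c(-0.5, 0.7)) {
    for (ch in 1:2) {
      ii <- integrate(function(t) exp(wiener_log_density(t, ch, xi, 1.3, dd)),
                      1e-8, 100, subdivisions = 4000L, rel.tol = 1e-9)$value
      p <- ddm_hit_probability(xi, 1.3, dd)
      expect_equal(ii, if (ch == 1) p else 1 - p, tolerance = 1e-5)
    }
  }
  ## pointwise agreement with the long-series oracle (lower bound density)
  for (t in c(0.1, 0.5, 1.5, 4)) {
    got <- exp(wiener_log_density(t, 2, 0.4, 0.9, dd))
    want <- oracle_wiener_lower(t, 0.4, 0.9, dd$zeta, dd$z0)
    expect_equal(got, want, tolerance = 1e-8)
  }
  ## symmetric start: upper and lower densities are identical at xi = 0
  dds <- ddm_params(2, 1, 0)
  ts <- c(0.2, 0.7, 2)
  expect_equal(wiener_log_density(ts, 1, 0, 1, dds),
               wiener_log_density(ts, 2, 0, 1, dds), tolerance = 1e-10)
  ## rt below the non-decision time has zero density
  expect_identical(wiener_log_density(0.2, 1, 0.5, 1, ddm_params(2, 1, 0.3)),
                   -Inf)
})

test_that("Q-sampling probability matches the quadrature oracle", {
  p1 <- nig_posterior(0.8, 4, 3, 2.5)
  p2 <- nig_posterior(0.2, 2, 4, 3)
  set.seed(41)
  got <- qs_probability(p1, p2, n_mc = 2e5)
  want <- oracle_qs_probability(p1, p2)
  expect_equal(got, want, tolerance = 0.005)
  expect_equal(qs_probability(p1, p1, n_mc = 2e5), 0.5, tolerance = 0.01)
  ## degenerate separation
  d1 <- nig_posterior(5, 1e7, 1e7, 1e7)
  d2 <- nig_posterior(-5, 1e7, 1e7, 1e7)
  expect_equal(qs_probability(d1, d2, n_mc = 1000), 1)
})

test_that("marginal race choice probability approaches Q-sampling as the threshold grows", {
  p1 <- nig_posterior(0.9, 3, 3, 2)
  p2 <- nig_posterior(0.1, 3, 3, 2)
  set.seed(51)
  qs <- oracle_qs_probability(p1, p2)
  gaps <- vapply(c(0.5, 2, 8, 32), function(z) {
    set.seed(52)
    abs(choice_probability_marginal(p1, p2, ddm_params(z), n_mc = 4e4) - qs)
  }, numeric(1))
  expect_true(all(diff(gaps) <= 0.005))
  expect_lt(gaps[4], 0.01)
  ## symmetric posteriors stay at one half at any threshold
  set.seed(53)
  expect_equal(choice_probability_marginal(p1, p1, ddm_params(2),
                                           n_mc = 4e4), 0.5,
               tolerance = 0.01)
  ## a clearly dominant arm is chosen nearly surely at a high threshold
  t1 <- nig_posterior(2, 50, 40, 10)
  t2 <- nig_posterior(0, 50, 40, 10)
  set.seed(54)
  expect_gte(choice_probability_marginal(t1, t2, ddm_params(8), n_mc = 2e4),
             0.99)
  expect_warning(choice_probability_marginal(p1, p2, ddm_params(2),
                                             n_mc = 50), "n_mc")
})

test_that("choice probability is invariant to a common shift of the means", {
  p1 <- nig_posterior(0.7, 3, 3, 2)
  p2 <- nig_posterior(-0.2, 4, 2.5, 2)
  dd <- ddm_params(2)
  set.seed(61)
  a <- choice_probability_marginal(p1, p2, dd, n_mc = 4e4)
  s1 <- nig_posterior(p1$mu + 5, 3, 3, 2)
  s2 <- nig_posterior(p2$mu + 5, 4, 2.5, 2)
  set.seed(61)
  b <- choice_probability_marginal(s1, s2, dd, n_mc = 4e4)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("speed and accuracy vary with reward noise and effective memory as expected", {
  set.seed(71)
  surf <- policy_surface(mu = c(1, -1), alpha = 3,
                         beta_grid = seq(0.5, 4, length.out = 5),
                         kappa_grid = seq(0.5, 4, length.out = 5),
                         ddm = ddm_params(2), n_mc = 3000)
  ## accuracy decreases with reward noise (beta_j) and increases with
  ## effective memory (kappa_j); mean decision time decreases with noise
  for (k in unique(surf$kappa_j)) {
    sub <- surf[surf$kappa_j == k, ]
    sub <- sub[order(sub$beta_j), ]
    expect_lt(sub$accuracy[5], sub$accuracy[1])
    expect_lt(sub$mean_rt[5], sub$mean_rt[1])
  }
  for (b in unique(surf$beta_j)) {
    sub <- surf[surf$beta_j == b, ]
    sub <- sub[order(sub$kappa_j), ]
    expect_gt(sub$accuracy[5], sub$accuracy[1])
  }
})

test_that("ddm parameter validation rejects impossible geometries", {
  expect_error(ddm_params(-1), "zeta")
  expect_error(ddm_params(2, 2.5), "z0")
  expect_error(ddm_params(2, 1, -0.1), "tau")
})
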