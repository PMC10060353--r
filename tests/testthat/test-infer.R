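free <- interaction_params(D_e = 0, a = 1)

test_that("squared displacement from the first observation is exact", {
  inc <- rbind(c(3, 4), c(0, 0))
  obs <- obs_from_increments(inc, dt = 1)
  expect_equal(msd_lag(obs, 1, 0), 0)
  expect_equal(msd_lag(obs, 1, 1), 25)
  expect_equal(msd_lag(obs, 1, 2), 25)
  expect_error(msd_lag(obs, 1, 0.5), "not one of the observation times")
})

test_that("MSD estimator is the per-increment maximum-likelihood estimate", {
  expect_equal(msd_estimate(obs_from_increments(matrix(0, 3, 2)), 1), 0)
  obs <- obs_from_increments(rbind(c(3, 4)), dt = 1)
  expect_equal(msd_estimate(obs, 1), 12.5)   # 25 / (2 * 1 * 1)
  # dt enters the denominator
  obs2 <- obs_from_increments(rbind(c(3, 4)), dt = 5)
  expect_equal(msd_estimate(obs2, 1), 2.5)
})

test_that("with interactions off the higher-order MLE equals the MSD estimate", {
  cfg <- experiment_config(25, 0.05, free, duration = 3000,
                           obs_interval = 300, h = 300, boundary = FALSE,
                           seed = 43)
  obs <- simulate_system(cfg)
  for (i in c(1, 7, 25))
    expect_equal(mle_sigma_hom(obs, i, free), msd_estimate(obs, i),
                 tolerance = 1e-13)
  # and the two posteriors coincide
  ph <- posterior_update(obs, 3, c(0, 0), free, "hom")
  pm <- posterior_update(obs, 3, c(0, 0), free, "msd")
  expect_equal(ph$alpha, pm$alpha)
  expect_equal(ph$beta, pm$beta, tolerance = 1e-13)
})

test_that("zero-interaction log-likelihood equals the iid Gaussian-increment
           log-likelihood", {
  cfg <- experiment_config(5, 0.03, free, duration = 1500,
                           obs_interval = 300, h = 300, boundary = FALSE,
                           seed = 47)
  obs <- simulate_system(cfg)
  sigma <- 0.025; dt <- 300
  inc <- obs$positions[2, -1, ] - obs$positions[2, -6, ]
  direct <- sum(dnorm(inc, 0, sigma * sqrt(dt), log = TRUE))
  expect_equal(hom_loglik(obs, 2, sigma, free), direct, tolerance = 1e-12)
})

test_that("the log-likelihood is maximised at the closed-form MLE", {
  cfg <- experiment_preset("exp0", N = 12, duration = 3600,
                           obs_interval = 300, h = 60, seed = 53)
  obs <- simulate_system(cfg)
  p <- cfg$interaction
  s2 <- mle_sigma_hom(obs, 4, p)
  opt <- optimize(function(s) hom_loglik(obs, 4, s, p),
                  interval = sqrt(s2) * c(0.2, 5), maximum = TRUE,
                  tol = 1e-12)
  expect_equal(opt$maximum^2, s2, tolerance = 1e-8)
})

test_that("log-likelihood in the precision has the Gamma shape K log(tau) - beta tau", {
  cfg <- experiment_preset("exp0", N = 8, duration = 2400,
                           obs_interval = 300, h = 60, seed = 59)
  obs <- simulate_system(cfg)
  p <- cfg$interaction
  K <- 8
  post <- posterior_update(obs, 2, c(0, 0), p, "hom")
  taus <- seq(2000, 30000, length.out = 9)
  ll <- vapply(taus, function(tau) hom_loglik(obs, 2, tau^-0.5, p),
               numeric(1))
  shape <- K * log(taus) - post$beta * taus
  expect_equal(diff(ll), diff(shape), tolerance = 1e-8)
})

test_that("conjugate update: shape grows by K, batch equals sequential,
           MLE equals beta/K", {
  cfg <- experiment_preset("exp0", N = 10, duration = 3000,
                           obs_interval = 300, h = 60, seed = 61)
  obs <- simulate_system(cfg)
  p <- cfg$interaction
  K <- n_int <- 10
  post <- posterior_update(obs, 6, c(0, 0), p, "hom")
  expect_identical(post$alpha, 10)
  expect_equal(mle_sigma_hom(obs, 6, p), post$beta / K, tolerance = 1e-13)
  # informative prior shifts both parameters additively
  post2 <- posterior_update(obs, 6, c(2, 5), p, "hom")
  expect_equal(post2$alpha, post$alpha + 2)
  expect_equal(post2$beta, post$beta + 5, tolerance = 1e-12)
  # sequential one-interval updates reproduce the batch result exactly
  pr <- c(0, 0)
  for (k in 1:K) {
    sub <- observation_set(obs$times[k:(k + 1)],
                           obs$positions[, k:(k + 1), , drop = FALSE])
    pk <- posterior_update(sub, 6, pr, p, "hom")
    pr <- c(pk$alpha, pk$beta)
  }
  expect_equal(pr[1], post$alpha)
  expect_equal(pr[2], post$beta, tolerance = 1e-12)
})

test_that("single unit residual with identity normalised covariance gives beta = 1/2 each dimension", {
  # increment (1,1) over dt = 1 with no drift: quad = 2, beta = 1
  obs <- obs_from_increments(rbind(c(1, 1)), dt = 1)
  post <- posterior_update(obs, 1, c(0, 0), free, "hom")
  expect_equal(post$beta, 1)
  expect_identical(post$alpha, 1)
})

test_that("MSD estimator is unbiased for free Brownian motion", {
  # one simulated population of 200 independent walkers, K = 100
  cfg <- experiment_config(200, 0.02, free, duration = 100 * 300,
                           obs_interval = 300, h = 300, boundary = FALSE,
                           seed = 67)
  obs <- simulate_system(cfg)
  ratio <- vapply(1:200, function(i) msd_estimate(obs, i), numeric(1)) /
    0.02^2
  expect_gt(mean(ratio), 0.97)
  expect_lt(mean(ratio), 1.03)
})

test_that("higher-order recovery is sharp when observations approach the
           integration step", {
  # dense interacting population, 15-s observations: the drift linearisation
  # holds within each interval and the population-mean mode lands on truth
  cfg <- experiment_preset("exp3", N = 128L, duration = 7200,
                           obs_interval = 15, seed = 303)
  obs <- simulate_system(cfg)
  fit <- fit_diffusivity(obs, "hom")
  expect_lt(abs(mean(fit$estimates$sigma_mode) / exp(-9 / 2) - 1), 0.02)
})

test_that("scaled posterior rate follows the chi-square law on Brownian data", {
  # 2 beta_K / sigma^2 ~ chi^2 with 2K degrees of freedom
  K <- 10
  cfg <- experiment_config(200, 0.015, free, duration = K * 300,
                           obs_interval = 300, h = 300, boundary = FALSE,
                           seed = 71)
  obs <- simulate_system(cfg)
  stat <- vapply(1:200, function(i)
    2 * posterior_update(obs, i, c(0, 0), free, "msd")$beta / 0.015^2,
    numeric(1))
  expect_gt(ks.test(stat, pchisq, df = 2 * K)$p.value, 0.01)
})
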