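test_that("Euler-Maruyama transition has linear mean and isotropic covariance", {
  td <- euler_transition(c(2, 3), c(0, 0), sigma = 0.01, dt = 300)
  expect_equal(td$mean, c(2, 3))
  expect_equal(td$cov, 3e-2 * diag(2))
  td2 <- euler_transition(c(0, 0), c(0.001, 0), sigma = 0.01, dt = 100)
  expect_equal(td2$mean, c(0.1, 0))
  expect_identical(td2$cov[1, 2], 0)
  expect_identical(td2$cov[1, 1], td2$cov[2, 2])
  expect_error(euler_transition(c(0, 0), c(0, 0), 0.01, dt = 0), "dt")
})

test_that("higher-order transition reduces to Euler-Maruyama at zero Jacobian", {
  td_e <- euler_transition(c(1, 2), c(1e-4, -2e-4), 0.02, 600)
  td_h <- hom_transition(c(1, 2), c(1e-4, -2e-4), matrix(0, 2, 2), 0.02, 600)
  expect_identical(td_h$cov, td_e$cov)
  expect_identical(td_h$mean, td_e$mean)
})

test_that("higher-order covariance matches the direct matrix-product oracle", {
  A <- matrix(c(-0.1, 0.05, 0.05, -0.2), 2)
  td <- hom_transition(c(0, 0), c(0, 0), A, sigma = 0.01, dt = 300)
  expect_equal(td$cov, oracle_hom_cov(A, 0.01, 300), tolerance = 1e-12)
  expect_true(isSymmetric(td$cov))
  expect_true(all(eigen(td$cov, symmetric = TRUE)$values > 0))
})

test_that("covariance scales as sigma^2 and normalized_cov is sigma-free", {
  A <- matrix(c(0.3, -0.1, -0.1, 0.05), 2)
  t1 <- hom_transition(c(0, 0), c(0, 0), A, sigma = 0.01, dt = 60)
  t2 <- hom_transition(c(0, 0), c(0, 0), A, sigma = 0.05, dt = 60)
  expect_equal(t2$cov, 25 * t1$cov, tolerance = 1e-14)
  expect_identical(t1$normalized_cov, t2$normalized_cov)
  expect_equal(t1$cov, 0.01^2 * t1$normalized_cov)
})

test_that("closed-form trace, determinant and eigenvalue match direct algebra", {
  set.seed(41)
  for (rep in 1:200) {
    a <- runif(3, -1, 1)
    A <- matrix(c(a[1], a[3], a[3], a[2]), 2)
    dt <- runif(1, 1e-3, 3600)
    sigma <- runif(1, 1e-4, 1)
    S <- oracle_hom_cov(A, sigma, dt)
    inv <- hom_cov_invariants(A, sigma, dt)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(inv[["trace"]], sum(diag(S)), tolerance = 1e-10)
    expect_equal(inv[["det"]], det(S), tolerance = 1e-10)
    expect_equal(inv[["lambda_min"]], min(ev), tolerance = 1e-10)
    expect_gt(inv[["lambda_min"]], 0)
  }
})

test_that("isotropic case gives lambda_min = sigma^2 dt", {
  expect_equal(lambda_min_closed_form(matrix(0, 2, 2), 0.05, 60),
               0.05^2 * 60)
})

test_that("eigenvalue discriminant is non-negative for any symmetric Jacobian", {
  set.seed(42)
  for (rep in 1:200) {
    a <- runif(3, -5, 5)
    A <- matrix(c(a[1], a[3], a[3], a[2]), 2)
    inv <- hom_cov_invariants(A, runif(1, 0.001, 1), runif(1, 0.001, 100))
    expect_gte(inv[["trace"]]^2 - 4 * inv[["det"]], -1e-8 * inv[["trace"]]^2)
    expect_gt(inv[["lambda_min"]], 0)
  }
})

test_that("asymmetric Jacobians warn (transition) or error (closed form)", {
  A <- matrix(c(0, 0.2, -0.2, 0), 2)
  expect_warning(hom_transition(c(0, 0), c(0, 0), A, 0.01, 10),
                 "asymmetric")
  expect_error(hom_cov_invariants(A, 0.01, 10), "symmetric")
  # round-off asymmetry passes silently
  A2 <- matrix(c(0.1, 0.05, 0.05 + 1e-12, 0.1), 2)
  expect_silent(hom_transition(c(0, 0), c(0, 0), A2, 0.01, 10))
})

test_that("(Z1, Z2) sampler reproduces the joint law of the Wiener increment
           and its time integral", {
  z <- sample_z1_z2(dt = 1, n = 1e5, seed = 31)
  n <- 1e5
  se_v1 <- 1 * sqrt(2 / (n - 1))
  se_v2 <- (1 / 3) * sqrt(2 / (n - 1))
  se_cov <- sqrt((1 * 1 / 3 + 0.25) / (n - 1))
  for (d in 1:2) {
    expect_lt(abs(var(z$z1[, d]) - 1), 3 * se_v1)
    expect_lt(abs(var(z$z2[, d]) - 1 / 3), 3 * se_v2)
    expect_lt(abs(cov(z$z1[, d], z$z2[, d]) - 0.5), 3 * se_cov)
  }
  # correlation sqrt(3)/2 regardless of dt
  for (dt in c(0.1, 1, 300)) {
    z <- sample_z1_z2(dt, 2e4, seed = 32)
    expect_equal(cor(z$z1[, 1], z$z2[, 1]), sqrt(3) / 2, tolerance = 0.02)
  }
  # reproducible under seed, and the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  z1 <- sample_z1_z2(1, 10, seed = 5)
  z2 <- sample_z1_z2(1, 10, seed = 5)
  expect_identical(z1, z2)
  set.seed(99); expect_identical(rnorm(1), before)
})

test_that("propagating with sampled (Z1, Z2) reproduces the higher-order law", {
  A <- matrix(c(-0.004, 0.001, 0.001, -0.002), 2)
  x <- c(5, 7); a <- c(2e-4, -1e-4); sigma <- 0.02; dt <- 120
  n <- 1e5
  z <- sample_z1_z2(dt, n, seed = 33)
  prop <- matrix(rep(x + a * dt, each = n), n, 2) +
    sigma * z$z1 + sigma * t(A %*% t(z$z2))
  td <- hom_transition(x, a, A, sigma, dt)
  se_mean <- sqrt(diag(td$cov) / n)
  expect_lt(max(abs(colMeans(prop) - td$mean) / se_mean), 3)
  emp <- cov(prop)
  se_var <- diag(td$cov) * sqrt(2 / (n - 1))
  expect_lt(max(abs(diag(emp) - diag(td$cov)) / se_var), 3)
  se_cov <- sqrt((td$cov[1, 1] * td$cov[2, 2] + td$cov[1, 2]^2) / (n - 1))
  expect_lt(abs(emp[1, 2] - td$cov[1, 2]) / se_cov, 3)
})
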