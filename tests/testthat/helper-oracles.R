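# Independent oracles used across the suite.

# Scalar pair potential, written out directly (independent of the C++ path).
oracle_potential <- function(r, D_e, a, r0 = 1, phi = "exp") {
  q <- if (phi == "exp") exp(-a * (r - r0)) else (r0 / r)^a
  D_e * (1 - q)^2 - D_e
}

# Total potential energy of a configuration, via the scalar oracle.
oracle_energy <- function(pos, params) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    e <- e + oracle_potential(sqrt(sum((pos[i, ] - pos[j, ])^2)),
                              params$D_e, params$a, params$r0, params$phi)
  e
}

# Central-finite-difference gradient of the total energy wrt particle i.
fd_drift <- function(pos, i, params, h = 1e-6) {
  g <- numeric(2)
  for (d in 1:2) {
    p1 <- p2 <- pos
    p1[i, d] <- p1[i, d] + h
    p2[i, d] <- p2[i, d] - h
    g[d] <- (oracle_energy(p1, params) - oracle_energy(p2, params)) / (2 * h)
  }
  -g
}

# Central-finite-difference Jacobian of drift() wrt particle i's coordinates.
fd_jacobian <- function(pos, i, params, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (d in 1:2) {
    p1 <- p2 <- pos
    p1[i, d] <- p1[i, d] + h
    p2[i, d] <- p2[i, d] - h
    J[, d] <- (drift(particle_state(p1), i, params) -
                 drift(particle_state(p2), i, params)) / (2 * h)
  }
  J
}

# Independent matrix-arithmetic construction of the higher-order covariance.
oracle_hom_cov <- function(A, sigma, dt) {
  S1 <- sigma * sqrt(dt) * (diag(2) + dt / 2 * A)
  S2 <- sigma * dt^1.5 / sqrt(12) * A
  t(S1) %*% S1 + t(S2) %*% S2
}

# Build an observation set directly from a matrix of increments for one
# particle (times 0, dt, 2*dt, ...), bypassing the simulator.
obs_from_increments <- function(inc, dt = 1, x0 = c(0, 0)) {
  k1 <- nrow(inc) + 1L
  path <- rbind(x0, x0 + apply(inc, 2, cumsum))
  pos <- array(0, c(1, k1, 2))
  pos[1, , ] <- path
  observation_set(times = seq(0, by = dt, length.out = k1), positions = pos)
}

# Random non-degenerate particle configuration.
random_config <- function(n, spread = 4, min_dist = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    pos <- matrix(runif(2 * n) * spread, n, 2)
    if (n == 1 || min(dist(pos)) > min_dist) return(pos)
  }
}
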