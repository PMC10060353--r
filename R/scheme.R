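# Gaussian transition densities for one particle over one
# inter-observation interval.  Both schemes share the mean
#   m = x + a * dt
# and differ in the covariance:
#   Euler-Maruyama:  S = sigma^2 dt I
#   higher-order:    S = S1' S1 + S2' S2,
#                    S1 = sigma sqrt(dt) (I + dt/2 A),
#                    S2 = sigma dt^{3/2} / sqrt(12) A,
# where A is the drift Jacobian at the start of the interval.  sigma enters
# only as a scalar multiplier, so the sigma-free normalised covariance
# Sbar = S / sigma^2 is always computed first; the conjugacy machinery
# never rebuilds covariances per sigma value.

SYM_TOL <- 1e-9

new_transition_density <- function(mean, normalized_cov, sigma, dt) {
  structure(list(mean = as.numeric(mean),
                 cov = sigma^2 * normalized_cov,
                 normalized_cov = normalized_cov,
                 sigma = sigma, dt = dt),
            class = "transition_density")
}

#' @export
print.transition_density <- function(x, ...) {
  cat("Gaussian transition density (dt =", x$dt, "s)\n")
  cat("  mean:", format(x$mean), "\n")
  cat("  cov:\n")
  print(x$cov)
  invisible(x)
}

check_scheme_inputs <- function(x, drift, sigma, dt) {
  stopifnot(is.numeric(x), length(x) == 2L, all(is.finite(x)),
            is.numeric(drift), length(drift) == 2L, all(is.finite(drift)),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma),
            sigma > 0)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive finite scalar")
}

#' Euler-Maruyama transition density
#'
#' First-order Gaussian approximation of the particle position after a time
#' step `dt`: mean `x + drift * dt`, isotropic covariance
#' \eqn{\sigma^2 \Delta t\, I}. The drift is frozen at its value at the start
#' of the interval and its spatial variation is ignored entirely.
#'
#' @param x Observed position at the start of the interval (2-vector).
#' @param drift Drift vector at the start of the interval (2-vector).
#' @param sigma Diffusion parameter (cell diameters / sqrt(s)), > 0.
#' @param dt Interval length (s), > 0.
#' @return A `transition_density` with fields `mean`, `cov` and the
#'   sigma-free `normalized_cov`.
#' @export
euler_transition <- function(x, drift, sigma, dt) {
  check_scheme_inputs(x, drift, sigma, dt)
  new_transition_density(x + drift * dt, dt * diag(2), sigma, dt)
}

#' Higher-order transition density
#'
#' Gaussian approximation whose covariance accounts for the variation of
#' the drift within the interval through the drift Jacobian `jac`:
#' \deqn{S = S_1^T S_1 + S_2^T S_2, \quad
#'   S_1 = \sigma\sqrt{\Delta t}\,(I + \tfrac{\Delta t}{2} A), \quad
#'   S_2 = \sigma\frac{\Delta t^{3/2}}{\sqrt{12}} A.}
#' For symmetric `A` (always the case for potential-derived drifts) the
#' result is guaranteed symmetric positive-definite, so the density is
#' proper for every `dt` and `sigma`. With `jac = 0` the density reduces
#' exactly to [euler_transition()].
#'
#' Asymmetric `jac` beyond round-off (`max|A - A'| > 1e-9`) falls outside
#' the positive-definiteness guarantee; a warning is issued and the
#' covariance is checked numerically, with non-positive-definite results
#' rejected rather than repaired.
#'
#' @inheritParams euler_transition
#' @param jac Drift Jacobian at the start of the interval (2 x 2 matrix).
#' @return A `transition_density`.
#' @export
hom_transition <- function(x, drift, jac, sigma, dt) {
  check_scheme_inputs(x, drift, sigma, dt)
  jac <- as.matrix(jac)
  stopifnot(all(dim(jac) == c(2L, 2L)), all(is.finite(jac)))
  asym <- max(abs(jac - t(jac)))
  sbar <- normalized_hom_cov(jac, dt)
  if (asym > SYM_TOL) {
    warning("asymmetric Jacobian (max|A - A'| = ", format(asym),
            "): positive-definiteness is not guaranteed, checking numerically")
    ev <- eigen(sbar, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("degenerate covariance: higher-order covariance not positive ",
           "definite for the supplied asymmetric Jacobian")
  }
  new_transition_density(x + drift * dt, sbar, sigma, dt)
}

# sigma-free covariance Sbar = dt (I + dt/2 A)'(I + dt/2 A) + dt^3/12 A'A
normalized_hom_cov <- function(jac, dt) {
  b <- diag(2) + (dt / 2) * jac
  dt * crossprod(b) + (dt^3 / 12) * crossprod(jac)
}

#' Closed-form invariants of the higher-order covariance
#'
#' Trace, determinant and smallest eigenvalue of the higher-order
#' covariance, from the closed-form expressions in the entries of a
#' symmetric Jacobian (no matrix products or eigendecompositions). The
#' discriminant \eqn{\mathrm{Tr}^2 - 4\det} is a sum of squares, so the
#' eigenvalues are always real, and the determinant is strictly positive:
#' the smallest eigenvalue is positive for every symmetric `jac`, which is
#' what makes the transition density proper.
#'
#' @param jac Symmetric 2 x 2 drift Jacobian.
#' @param sigma Diffusion parameter, > 0.
#' @param dt Interval length (s), > 0.
#' @return Named numeric vector with elements `trace`, `det`, `lambda_min`.
#' @export
hom_cov_invariants <- function(jac, sigma, dt) {
  jac <- as.matrix(jac)
  stopifnot(all(dim(jac) == c(2L, 2L)), all(is.finite(jac)),
            is.numeric(sigma), sigma > 0, is.numeric(dt), dt > 0)
  if (max(abs(jac - t(jac))) > SYM_TOL)
    stop("closed-form eigenvalue expressions require a symmetric Jacobian")
  a11 <- dt * jac[1, 1]; a22 <- dt * jac[2, 2]; a12 <- dt * jac[1, 2]
  s2t <- sigma^2 * dt
  tr <- (s2t / 3) * (3 / 2 + (3 / 2 + a11)^2 + (3 / 2 + a22)^2 + 2 * a12^2)
  det <- (s2t^2 / 9) *
    ((3 / 4 + (3 / 2 + a11)^2 + a12^2) * (3 / 4 + (3 / 2 + a22)^2 + a12^2) -
       ((3 + a11 + a22) * a12)^2)
  disc <- tr^2 - 4 * det
  # sum-of-squares identity for the discriminant; clamp round-off
  disc <- max(disc, 0)
  c(trace = tr, det = det, lambda_min = (tr - sqrt(disc)) / 2)
}

#' Smallest eigenvalue of the higher-order covariance, closed form
#'
#' Convenience wrapper around [hom_cov_invariants()]; positive for every
#' symmetric Jacobian, every `dt > 0` and every `sigma > 0`.
#'
#' @inheritParams hom_cov_invariants
#' @return The smallest eigenvalue (cell diameters^2).
#' @export
lambda_min_closed_form <- function(jac, sigma, dt) {
  unname(hom_cov_invariants(jac, sigma, dt)["lambda_min"])
}

#' Sample the Wiener increment and its time integral
#'
#' Draws `n` pairs of the 2-D Wiener increment \eqn{Z_1 = W(t_k+\Delta t) -
#' W(t_k)} and its pathwise time integral \eqn{Z_2 = \int W\,ds} over an
#' interval of length `dt`, per spatial dimension independently:
#' \deqn{Z_1 = \sqrt{\Delta t}\, U_1, \qquad
#'   Z_2 = \frac{\Delta t^{3/2}}{2}\left(U_1 + \frac{U_2}{\sqrt 3}\right)}
#' with \eqn{U_1, U_2} independent standard normals, which reproduces the
#' joint law \eqn{\mathrm{Var}(Z_1) = \Delta t},
#' \eqn{\mathrm{Var}(Z_2) = \Delta t^3/3},
#' \eqn{\mathrm{Cov}(Z_1, Z_2) = \Delta t^2/2}.
#'
#' @param dt Interval length (s), > 0.
#' @param n Number of pairs, >= 1.
#' @param seed Optional integer; when given, the draw is made under this
#'   seed and the caller's RNG state is restored afterwards.
#' @return A list with `n x 2` matrices `z1` and `z2` (columns are the two
#'   spatial dimensions).
#' @export
sample_z1_z2 <- function(dt, n, seed = NULL) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  u1 <- matrix(rnorm(2 * n), n, 2)
  u2 <- matrix(rnorm(2 * n), n, 2)
  list(z1 = sqrt(dt) * u1,
       z2 = (dt^1.5 / 2) * (u1 + u2 / sqrt(3)))
}
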