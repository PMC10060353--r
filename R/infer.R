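# Per-particle diffusivity inference.  Everything is built on the K x N
# matrix of per-interval quadratic forms
#   q_ik = (x_{i,k+1} - m_ik)' Sbar_ik^{-1} (x_{i,k+1} - m_ik)
# where, for the higher-order method, m_ik and the sigma-free covariance
# Sbar_ik come from the transition density evaluated at the full
# population snapshot at t_k, and for the MSD method m_ik = x_ik and
# Sbar_ik = dt I.  The log-likelihood, the Gamma conjugate update and the
# maximum-likelihood estimate are all linear functionals of these forms.

# Quadratic forms and log|Sbar| for all particles and intervals.
# Returns list(quad = K x N, logdet = K x N).
increment_quadforms <- function(obs, interaction, method = c("hom", "msd")) {
  method <- match.arg(method)
  n <- n_particles(obs)
  k <- n_intervals(obs)
  dt <- obs_dt(obs)
  quad <- logdet <- matrix(0, k, n)
  if (method == "msd") {
    for (kk in seq_len(k)) {
      d <- obs$positions[, kk + 1, , drop = FALSE] -
        obs$positions[, kk, , drop = FALSE]
      quad[kk, ] <- (d[, 1, 1]^2 + d[, 1, 2]^2) / dt
      logdet[kk, ] <- 2 * log(dt)
    }
    return(list(quad = quad, logdet = logdet))
  }
  stopifnot(inherits(interaction, "interaction_params"))
  for (kk in seq_len(k)) {
    snap <- obs$positions[, kk, ]
    if (is.null(dim(snap))) snap <- matrix(snap, 1)
    dj <- drift_jacobian_all(snap, interaction)
    a11 <- dj$jac[, 1]; a12 <- dj$jac[, 2]
    a21 <- dj$jac[, 3]; a22 <- dj$jac[, 4]
    # Sbar = dt B'B + dt^3/12 A'A,  B = I + dt/2 A
    b11 <- 1 + dt / 2 * a11; b12 <- dt / 2 * a12
    b21 <- dt / 2 * a21;     b22 <- 1 + dt / 2 * a22
    s11 <- dt * (b11^2 + b21^2)       + dt^3 / 12 * (a11^2 + a21^2)
    s12 <- dt * (b11 * b12 + b21 * b22) +
      dt^3 / 12 * (a11 * a12 + a21 * a22)
    s22 <- dt * (b12^2 + b22^2)       + dt^3 / 12 * (a12^2 + a22^2)
    det <- s11 * s22 - s12^2
    if (any(det < 1e-300))
      stop("degenerate covariance at interval ", kk,
           ": |Sbar| below 1e-300")
    r1 <- obs$positions[, kk + 1, 1] - (snap[, 1] + dj$drift[, 1] * dt)
    r2 <- obs$positions[, kk + 1, 2] - (snap[, 2] + dj$drift[, 2] * dt)
    quad[kk, ] <- (s22 * r1^2 - 2 * s12 * r1 * r2 + s11 * r2^2) / det
    logdet[kk, ] <- log(det)
  }
  list(quad = quad, logdet = logdet)
}

check_particle_index <- function(obs, i) {
  stopifnot(inherits(obs, "observation_set"), is.numeric(i),
            length(i) == 1L, i >= 1, i <= n_particles(obs))
}

#' Squared displacement from the first observation
#'
#' The per-particle term of the classic mean-square-displacement curve:
#' the squared distance between particle `i`'s position at time `T` and
#' its first observed position. Averaging over particles gives the
#' population MSD at lag `T`, which for free Brownian motion in two
#' dimensions equals \eqn{2\sigma^2 T}.
#'
#' @param obs An [observation_set()].
#' @param i Particle index (1-based).
#' @param T An observation time (s).
#' @return Squared displacement (cell diameters^2).
#' @export
msd_lag <- function(obs, i, T) {
  check_particle_index(obs, i)
  k <- which(abs(obs$times - T) <= 1e-9)
  if (length(k) != 1L)
    stop("T = ", T, " is not one of the observation times")
  sum((obs$positions[i, k, ] - obs$positions[i, 1, ])^2)
}

#' MSD maximum-likelihood estimate of sigma^2
#'
#' The increment-based estimator
#' \deqn{\hat\sigma^2 = \frac{1}{2K\Delta t}\sum_{k=0}^{K-1}
#'   \|x_{i(k+1)} - x_{ik}\|^2,}
#' the maximum-likelihood estimate of \eqn{\sigma^2} under the free
#' Brownian increment model (isotropic Gaussian increments with
#' per-dimension variance \eqn{\sigma^2\Delta t}). Unbiased for
#' non-interacting particles; systematically biased low under crowding,
#' where neighbour forces suppress net displacement.
#'
#' @inheritParams msd_lag
#' @return Estimate of sigma^2 (cell diameters^2 / s).
#' @export
msd_estimate <- function(obs, i) {
  check_particle_index(obs, i)
  d <- obs$positions[i, -1, , drop = FALSE] -
    obs$positions[i, -(n_intervals(obs) + 1), , drop = FALSE]
  sum(d^2) / (2 * n_intervals(obs) * obs_dt(obs))
}

#' Log-likelihood under the higher-order transition density
#'
#' Sum over intervals of the log-density of the next observation of
#' particle `i` under the higher-order Gaussian transition evaluated at
#' the observed population snapshot at the interval start (standard 2-D
#' Gaussian normalisation). As a function of the precision
#' \eqn{\tau = \sigma^{-2}} the log-likelihood has the Gamma shape
#' \eqn{K\log\tau - \beta\tau + \mathrm{const}}, which is what yields the
#' conjugate posterior of [posterior_update()].
#'
#' @inheritParams msd_lag
#' @param sigma Diffusion parameter at which to evaluate, > 0.
#' @param interaction An [interaction_params()] describing the known drift
#'   model.
#' @return The log-likelihood (a scalar).
#' @export
hom_loglik <- function(obs, i, sigma, interaction) {
  check_particle_index(obs, i)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  qf <- increment_quadforms(obs, interaction, "hom")
  k <- n_intervals(obs)
  sum(-log(2 * pi) - 2 * log(sigma) - 0.5 * qf$logdet[, i]) -
    sum(qf$quad[, i]) / (2 * sigma^2)
}

#' Gamma conjugate posterior update for the precision
#'
#' The precision \eqn{\tau_i = \sigma_i^{-2}} of particle `i` has a Gamma
#' conjugate posterior under either transition model: with prior
#' \eqn{\mathrm{Gamma}(\alpha_0, \beta_0)} (the improper
#' \eqn{\alpha_0 = \beta_0 = 0} is allowed),
#' \deqn{\alpha_K = \alpha_0 + K, \qquad
#'   \beta_K = \beta_0 + \tfrac12 \sum_k
#'   (x_{i(k+1)} - m_{ik})^T \bar S_{ik}^{-1} (x_{i(k+1)} - m_{ik}).}
#' For `method = "msd"` the free-Brownian assumption is used
#' (\eqn{m_{ik} = x_{ik}}, \eqn{\bar S_{ik} = \Delta t\, I}), giving the
#' "MSD posterior"; for `method = "hom"` the higher-order mean and
#' normalised covariance are used.
#'
#' @inheritParams hom_loglik
#' @param prior Length-2 numeric `c(alpha, beta)`, both >= 0.
#' @param method `"hom"` or `"msd"`.
#' @return A `gamma_posterior` object (fields `alpha`, `beta`).
#' @export
posterior_update <- function(obs, i, prior = c(0, 0), interaction = NULL,
                             method = c("hom", "msd")) {
  method <- match.arg(method)
  check_particle_index(obs, i)
  prior <- as.numeric(prior)
  stopifnot(length(prior) == 2L, all(prior >= 0), all(is.finite(prior)))
  qf <- increment_quadforms(obs, interaction, method)
  gamma_posterior(prior[1] + n_intervals(obs),
                  prior[2] + sum(qf$quad[, i]) / 2)
}

#' @rdname posterior_update
#' @param alpha,beta Shape and rate of a Gamma distribution on the
#'   precision, both >= 0.
#' @export
gamma_posterior <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "gamma_posterior")
}

#' @export
print.gamma_posterior <- function(x, ...) {
  cat(sprintf("Gamma posterior on the precision: alpha = %g, beta = %g\n",
              x$alpha, x$beta))
  if (x$alpha > 1)
    cat(sprintf("  posterior-mode sigma = %g\n",
                sqrt(x$beta / (x$alpha - 1))))
  else cat("  improper or mode-undefined (alpha <= 1)\n")
  invisible(x)
}

#' Maximum-likelihood estimate of sigma^2, higher-order model
#'
#' \deqn{\hat\sigma_i^2 = \frac{1}{2K}\sum_k
#'   (x_{i(k+1)} - m_{ik})^T \bar S_{ik}^{-1} (x_{i(k+1)} - m_{ik}),}
#' which equals \eqn{\beta_K / K} under the improper prior. With the
#' interaction switched off (zero drift) it reduces exactly to
#' [msd_estimate()].
#'
#' @inheritParams hom_loglik
#' @return Estimate of sigma^2 (cell diameters^2 / s).
#' @export
mle_sigma_hom <- function(obs, i, interaction) {
  check_particle_index(obs, i)
  qf <- increment_quadforms(obs, interaction, "hom")
  sum(qf$quad[, i]) / (2 * n_intervals(obs))
}

#' Diffusion coefficient from sigma^2
#'
#' Converts the diffusion parameter convention used throughout the package
#' (per-dimension increment variance \eqn{\sigma^2\Delta t}) to the
#' physicist's diffusion coefficient \eqn{D = \sigma^2 / 2}.
#'
#' @param sigma2 sigma^2 value(s) (cell diameters^2 / s).
#' @return D in cell diameters^2 / s.
#' @export
sigma2_to_D <- function(sigma2) sigma2 / 2
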