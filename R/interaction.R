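#' Pairwise interaction parameters
#'
#' Defines the attractive-repulsive pair potential
#' \deqn{U(r) = D_e\left[1 - \left(\frac{\varphi(r)}{\varphi(r_0)}\right)^a\right]^2 - D_e}
#' with decay function \eqn{\varphi(r) = e^{-r}} (`phi = "exp"`, the Morse
#' potential) or \eqn{\varphi(r) = 1/r} (`phi = "reciprocal"`, a
#' Lennard-Jones-shaped potential). The potential has its single minimum
#' \eqn{U(r_0) = -D_e} at the equilibrium distance `r0` and decays to 0 as
#' \eqn{r \to \infty}.
#'
#' Lengths are measured in average cell diameters, so `r0 = 1` in all the
#' shipped experiment presets.
#'
#' @param D_e Well depth (energy units), > 0; 0 switches interactions off.
#' @param a Well steepness (dimensionless), > 0.
#' @param r0 Equilibrium pair distance (cell diameters), > 0.
#' @param phi Decay function, `"exp"` (Morse) or `"reciprocal"`
#'   (Lennard-Jones shape).
#' @param eps Minimum pair distance (cell diameters) below which a
#'   configuration is rejected as degenerate: the gradient and Hessian of
#'   the potential diverge as particles coincide.
#'
#' @return An object of class `interaction_params`.
#' @examples
#' p <- interaction_params(D_e = 0.00021, a = 3.5)
#' potential_value(1, p)    # -D_e at the equilibrium distance
#' @export
interaction_params <- function(D_e, a, r0 = 1, phi = c("exp", "reciprocal"),
                               eps = 1e-8) {
  phi <- match.arg(phi)
  stopifnot(is.numeric(D_e), length(D_e) == 1L, is.finite(D_e), D_e >= 0,
            is.numeric(a), length(a) == 1L, is.finite(a), a > 0,
            is.numeric(r0), length(r0) == 1L, is.finite(r0), r0 > 0,
            is.numeric(eps), length(eps) == 1L, eps > 0)
  structure(list(D_e = D_e, a = a, r0 = r0, phi = phi, eps = eps),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  kind <- if (x$phi == "exp") "Morse (exponential decay)" else
    "Lennard-Jones shape (reciprocal decay)"
  cat("Pair potential:", kind, "\n")
  cat(sprintf("  well depth D_e = %g, steepness a = %g, equilibrium r0 = %g\n",
              x$D_e, x$a, x$r0))
  invisible(x)
}

phi_code <- function(params) if (params$phi == "exp") 0L else 1L

#' Particle configuration
#'
#' A snapshot of `N` particle positions in the plane at one time.
#'
#' @param positions Numeric `N x 2` matrix of coordinates (cell diameters).
#' @param time Time of the snapshot (seconds).
#' @return An object of class `particle_state`.
#' @export
particle_state <- function(positions, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 1L)
    stop("`positions` must be an N x 2 matrix with N >= 1")
  if (!all(is.finite(positions)))
    stop("non-finite coordinates in `positions`")
  structure(list(positions = positions, time = time),
            class = "particle_state")
}

#' Pair potential value
#'
#' @param r Pair distance (cell diameters). `r = 0` is allowed for the
#'   exponential decay (the potential stays finite) and rejected for the
#'   reciprocal decay.
#' @param params An [interaction_params()] object.
#' @return The potential energy `U(r)`.
#' @export
potential_value <- function(r, params) {
  stopifnot(inherits(params, "interaction_params"))
  if (!all(is.finite(r)) || any(r < 0))
    stop("`r` must be finite and non-negative")
  if (params$phi == "reciprocal" && any(r == 0))
    stop("r = 0 is outside the domain of the reciprocal decay function")
  vapply(r, cpp_potential, numeric(1), De = params$D_e, a = params$a,
         r0 = params$r0, phi_kind = phi_code(params))
}

#' Drift vector of one particle
#'
#' The deterministic velocity of particle `i`, the negative gradient of the
#' summed pair potential with respect to that particle's coordinates:
#' \deqn{a_i = -\sum_{j \ne i} \nabla_{x_i} U(\|x_i - x_j\|).}
#' Pairwise forces are equal and opposite, so the drifts sum to zero over
#' the population.
#'
#' @param state A [particle_state()].
#' @param i Particle index (1-based); `NULL` returns the full `N x 2` drift
#'   matrix.
#' @param params An [interaction_params()].
#' @return A length-2 numeric vector (cell diameters / s), or an `N x 2`
#'   matrix when `i` is `NULL`.
#' @export
drift <- function(state, i = NULL, params) {
  stopifnot(inherits(state, "particle_state"),
            inherits(params, "interaction_params"))
  d <- cpp_drift_all(state$positions, params$D_e, params$a, params$r0,
                     phi_code(params), params$eps)
  if (is.null(i)) return(d)
  stopifnot(i >= 1, i <= nrow(d))
  d[i, ]
}

#' Drift Jacobian of one particle
#'
#' The matrix of partial derivatives of particle `i`'s drift with respect
#' to its own coordinates,
#' \deqn{A_i = -\sum_{j \ne i} \mathrm{Hessian}\, U(\|x_i - x_j\|),}
#' symmetric by construction (it is a sum of Hessians of a scalar
#' potential). This is the matrix the higher-order transition density
#' consumes.
#'
#' @inheritParams drift
#' @return A `2 x 2` symmetric matrix (1/s), or a list of length `N` of
#'   such matrices when `i` is `NULL`.
#' @export
jacobian <- function(state, i = NULL, params) {
  stopifnot(inherits(state, "particle_state"),
            inherits(params, "interaction_params"))
  dj <- cpp_drift_jac_all(state$positions, params$D_e, params$a, params$r0,
                          phi_code(params), params$eps)
  to_mat <- function(row) matrix(row, 2, 2, byrow = TRUE)
  if (is.null(i))
    return(lapply(seq_len(nrow(dj$jac)), function(k) to_mat(dj$jac[k, ])))
  stopifnot(i >= 1, i <= nrow(dj$jac))
  to_mat(dj$jac[i, ])
}

# Drift and Jacobians for all particles in one pass; internal workhorse for
# the likelihood computations.
drift_jacobian_all <- function(positions, params) {
  cpp_drift_jac_all(positions, params$D_e, params$a, params$r0,
                    phi_code(params), params$eps)
}

#' Total interaction energy
#'
#' Sum of the pair potential over all unordered pairs; used for sanity
#' checks of the deterministic (gradient-flow) limit.
#'
#' @inheritParams drift
#' @return A scalar energy.
#' @export
total_energy <- function(state, params) {
  stopifnot(inherits(state, "particle_state"),
            inherits(params, "interaction_params"))
  cpp_total_energy(state$positions, params$D_e, params$a, params$r0,
                   phi_code(params), params$eps)
}
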