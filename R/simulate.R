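#' Experiment configuration
#'
#' Full design of one in-silico cell-migration experiment: `N` particles
#' seeded uniformly in a centred `box_inner` x `box_inner` square, confined
#' by reflecting walls to `[0, box_outer]^2`, integrated by Euler-Maruyama
#' steps of size `h` for `duration` seconds, and observed every
#' `obs_interval` seconds starting at t = 0.
#'
#' @param N Particle count, >= 1.
#' @param sigma Per-particle diffusion parameter(s)
#'   (cell diameters / sqrt(s)); a scalar is broadcast to all particles.
#' @param interaction An [interaction_params()] object.
#' @param duration Total simulated time (s); must cover at least one
#'   observation interval.
#' @param obs_interval Time between observations (s); must be a multiple
#'   of `h`.
#' @param h Integration step (s), default 1.
#' @param box_inner Side of the seeding square (cell diameters), default 40.
#' @param box_outer Side of the confinement square (cell diameters),
#'   default 50.
#' @param boundary Keep the reflecting walls? Setting `FALSE` simulates in
#'   free space (useful for pure-Brownian checks).
#' @param seed RNG seed for the run.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(N, sigma, interaction, duration,
                              obs_interval, h = 1, box_inner = 40,
                              box_outer = 50, boundary = TRUE, seed = 1L) {
  stopifnot(inherits(interaction, "interaction_params"),
            is.numeric(N), length(N) == 1L, N >= 1,
            is.numeric(h), h > 0, is.numeric(obs_interval),
            obs_interval >= h, is.numeric(duration),
            duration >= obs_interval,
            is.numeric(box_inner), is.numeric(box_outer),
            box_inner > 0, box_inner <= box_outer,
            is.logical(boundary), length(boundary) == 1L)
  if (abs(obs_interval / h - round(obs_interval / h)) > 1e-9)
    stop("`obs_interval` must be an integer multiple of `h`")
  N <- as.integer(N)
  sigma <- as.numeric(sigma)
  if (length(sigma) == 1L) sigma <- rep(sigma, N)
  if (length(sigma) != N) stop("`sigma` must be a scalar or length-N vector")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("all `sigma` must be finite and > 0")
  structure(list(N = N, sigma = sigma, interaction = interaction,
                 duration = duration, obs_interval = obs_interval, h = h,
                 box_inner = box_inner, box_outer = box_outer,
                 boundary = boundary, seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment: N = %d, duration = %g s, observed every %g s (K = %d)\n",
              x$N, x$duration, x$obs_interval,
              floor(x$duration / x$obs_interval)))
  cat(sprintf("  integration step h = %g s, box %g in %g, boundary: %s, seed %d\n",
              x$h, x$box_inner, x$box_outer,
              if (x$boundary) "reflecting" else "none", x$seed))
  cat(sprintf("  sigma: %s\n", if (length(unique(x$sigma)) == 1L)
    format(x$sigma[1]) else sprintf("per-particle, mean %g", mean(x$sigma))))
  print(x$interaction)
  invisible(x)
}

#' Shipped experiment designs
#'
#' The five simulation designs used throughout: `exp0` has well depth
#' `D_e = 0.0004`, steepness `a = 4`, `sigma = 0.01` and `N = 100`;
#' `exp1`..`exp4` share `D_e = 0.00021`, `a = 3.5`,
#' `sigma = exp(-9/2)` and have `N = 2^(5+n)` (64, 128, 256, 512)
#' particles. All use the Morse potential with `r0 = 1`, `h = 1` s,
#' a 40 x 40 seeding square inside 50 x 50 reflecting walls, and default
#' to two simulated days observed every 5 minutes.
#'
#' @param name One of `"exp0"`, `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`.
#' @param ... Overrides passed to [experiment_config()] (commonly
#'   `duration`, `obs_interval`, `N`, `seed` for scaled-down runs).
#' @return An `experiment_config`.
#' @examples
#' cfg <- experiment_preset("exp3", duration = 14400, seed = 7)
#' cfg$N
#' @export
experiment_preset <- function(name, ...) {
  presets <- list(
    exp0 = list(D_e = 0.0004, a = 4, sigma = 1e-2, N = 100L),
    exp1 = list(D_e = 0.00021, a = 3.5, sigma = exp(-9 / 2), N = 64L),
    exp2 = list(D_e = 0.00021, a = 3.5, sigma = exp(-9 / 2), N = 128L),
    exp3 = list(D_e = 0.00021, a = 3.5, sigma = exp(-9 / 2), N = 256L),
    exp4 = list(D_e = 0.00021, a = 3.5, sigma = exp(-9 / 2), N = 512L))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; choose one of ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  args <- list(N = p$N, sigma = p$sigma,
               interaction = interaction_params(D_e = p$D_e, a = p$a,
                                                r0 = 1, phi = "exp"),
               duration = 172800, obs_interval = 300, h = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(experiment_config, args)
}

#' Seed initial particle positions
#'
#' Draws `N` positions i.i.d. uniform on the inner seeding square, centred
#' inside the confinement box (offset `(box_outer - box_inner)/2` from the
#' walls). Uses the current RNG state; [simulate_system()] seeds the RNG
#' from the config before calling this.
#'
#' @param config An [experiment_config()].
#' @return A [particle_state()] at time 0.
#' @export
seed_positions <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  off <- (config$box_outer - config$box_inner) / 2
  particle_state(matrix(off + runif(2 * config$N) * config$box_inner,
                        config$N, 2), time = 0)
}

#' Observation set
#'
#' Container for `N` particles observed at `K + 1` equally spaced times.
#'
#' @param times Strictly increasing, equally spaced observation times (s).
#' @param positions `N x (K+1) x 2` array of coordinates (cell diameters).
#' @param sigma_true Optional ground-truth sigma vector (synthetic data).
#' @param ids Optional integer particle ids (0-based, as in trajectory
#'   files); defaults to `0:(N-1)`.
#' @param config Optional `experiment_config` provenance.
#' @return An object of class `observation_set`.
#' @export
observation_set <- function(times, positions, sigma_true = NULL,
                            ids = NULL, config = NULL) {
  stopifnot(is.array(positions), length(dim(positions)) == 3L,
            dim(positions)[3] == 2L)
  n <- dim(positions)[1]
  k1 <- dim(positions)[2]
  if (length(times) != k1) stop("length(times) must match dim(positions)[2]")
  if (k1 < 2L) stop("at least two observation times are required (K >= 1)")
  dts <- diff(times)
  if (any(dts <= 0) || max(abs(dts - dts[1])) > 1e-9 * max(dts[1], 1))
    stop("observation times must be strictly increasing and equally spaced")
  if (!all(is.finite(positions))) stop("non-finite positions")
  if (is.null(ids)) ids <- 0:(n - 1)
  stopifnot(length(ids) == n)
  if (!is.null(sigma_true)) {
    sigma_true <- as.numeric(sigma_true)
    if (length(sigma_true) == 1L) sigma_true <- rep(sigma_true, n)
    stopifnot(length(sigma_true) == n)
  }
  structure(list(times = as.numeric(times), positions = positions,
                 sigma_true = sigma_true, ids = as.integer(ids),
                 config = config),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  n <- dim(x$positions)[1]
  k <- dim(x$positions)[2] - 1L
  cat(sprintf("Observation set: %d particles, %d intervals of %g s (%.2f h total)\n",
              n, k, diff(x$times)[1], (x$times[k + 1] - x$times[1]) / 3600))
  if (!is.null(x$sigma_true))
    cat("  ground-truth sigma attached (synthetic data)\n")
  invisible(x)
}

n_particles <- function(obs) dim(obs$positions)[1]
n_intervals <- function(obs) dim(obs$positions)[2] - 1L
obs_dt <- function(obs) diff(obs$times)[1]

#' Forward-simulate an interacting particle system
#'
#' Brownian-dynamics (Euler-Maruyama) integration of the interacting SDE
#' system at fine step `h`: each step applies drift from the pair potential
#' plus isotropic Gaussian noise `sigma * sqrt(h)`, then folds coordinates
#' back into `[0, box_outer]^2` (reflecting walls) when the boundary is
#' active. Positions are recorded every `obs_interval` seconds, starting
#' at t = 0, and the ground-truth sigma vector is attached. The run is
#' fully reproducible from `config$seed`: one seeded generator drives both
#' the initial seeding and the per-step noise, drawn in fixed particle
#' order.
#'
#' @param config An [experiment_config()].
#' @param state Optional initial [particle_state()]; by default positions
#'   are drawn by [seed_positions()].
#' @return An [observation_set()] with `sigma_true` and `config` attached.
#' @examples
#' cfg <- experiment_preset("exp0", duration = 1800, obs_interval = 300,
#'                          h = 60, seed = 42)
#' obs <- simulate_system(cfg)
#' obs
#' @export
simulate_system <- function(config, state = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  if (is.null(state)) state <- seed_positions(config)
  stopifnot(inherits(state, "particle_state"),
            nrow(state$positions) == config$N)
  record_every <- as.integer(round(config$obs_interval / config$h))
  k <- floor(config$duration / config$obs_interval)
  n_steps <- as.integer(k * record_every)
  p <- config$interaction
  pos <- cpp_simulate(state$positions, config$sigma, p$D_e, p$a, p$r0,
                      phi_code(p), config$h, n_steps, record_every,
                      if (config$boundary) config$box_outer else -1,
                      p$eps)
  observation_set(times = seq(0, by = config$obs_interval, length.out = k + 1),
                  positions = pos, sigma_true = config$sigma,
                  config = config)
}
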