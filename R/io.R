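# Trajectory and estimate tables.  Trajectories travel as plain CSV with
# header `particle_id,t,x,y` (0-based ids, seconds, cell diameters), one
# row per particle per observation time; numbers are written at full
# double precision so write -> read round-trips are lossless well below
# 1e-12 relative.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write trajectories to CSV
#'
#' @param obs An [observation_set()].
#' @param path Output file path.
#' @param manifest Also write `<path>.manifest.json`-style run metadata?
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(obs, path, manifest = FALSE) {
  stopifnot(inherits(obs, "observation_set"))
  n <- n_particles(obs)
  k1 <- n_intervals(obs) + 1L
  df <- data.frame(
    particle_id = rep(obs$ids, each = k1),
    t = fmt_num(rep(obs$times, times = n)),
    x = fmt_num(as.vector(t(obs$positions[, , 1]))),
    y = fmt_num(as.vector(t(obs$positions[, , 2]))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (manifest) write_manifest(paste0(path, ".manifest"), outputs = path)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' Reads a `particle_id,t,x,y` table and validates it into an
#' [observation_set()]: every particle must be observed on the same
#' strictly increasing, equally spaced time grid, with no duplicate
#' (particle, time) pairs and no non-finite values. Malformed input is
#' rejected with an error naming the offending particle or row.
#'
#' @param path CSV file path.
#' @return An [observation_set()].
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, colClasses = "numeric")
  if (nrow(df) == 0L) stop("empty trajectory file: ", path)
  need <- c("particle_id", "t", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ","))
  if (!all(is.finite(as.matrix(df[need]))))
    stop("non-finite values in trajectory file (first bad row: ",
         which(!is.finite(rowSums(df[need])))[1], ")")
  ids <- sort(unique(df$particle_id))
  times <- sort(unique(df$t))
  if (nrow(df) != length(ids) * length(times) ||
      anyDuplicated(df[c("particle_id", "t")]) > 0) {
    counts <- table(df$particle_id)
    bad <- names(counts)[counts != length(times)][1]
    stop("ragged or duplicated time grid (particle ",
         if (is.na(bad) || is.null(bad)) "unknown" else bad,
         " does not match the common time vector)")
  }
  n <- length(ids)
  k1 <- length(times)
  df <- df[order(match(df$particle_id, ids), df$t), ]
  pos <- array(0, c(n, k1, 2))
  pos[, , 1] <- matrix(df$x, n, k1, byrow = TRUE)
  pos[, , 2] <- matrix(df$y, n, k1, byrow = TRUE)
  observation_set(times = times, positions = pos, ids = ids)
}

#' Write per-particle estimates to CSV
#'
#' @param fit A `diff_fit`, or a data frame shaped like its `estimates`
#'   component.
#' @param path Output file path.
#' @return `path`, invisibly. Rows are ordered by (particle_id, method);
#'   header is exactly `particle_id,method,alpha,beta,sigma2_mle,sigma_mode`.
#' @export
write_estimates <- function(fit, path) {
  est <- if (inherits(fit, "diff_fit")) fit$estimates else as.data.frame(fit)
  need <- c("particle_id", "method", "alpha", "beta", "sigma2_mle",
            "sigma_mode")
  if (nrow(est) == 0L) stop("no estimate records to write")
  if (!all(need %in% names(est)))
    stop("estimate records need columns ", paste(need, collapse = ","))
  est <- est[order(est$particle_id, est$method), need]
  for (col in c("alpha", "beta", "sigma2_mle", "sigma_mode"))
    est[[col]] <- fmt_num(est[[col]])
  write.csv(est, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an estimates CSV
#'
#' @param path CSV written by [write_estimates()].
#' @return A data frame.
#' @export
read_estimates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, colClasses = c(particle_id = "integer",
                                method = "character"))
}

#' Write a run manifest
#'
#' Plain key-value text file recording the package version, timestamp,
#' seed, config echo and MD5 digests of input/output files, so that every
#' command-line run is traceable.
#'
#' @param path Output path.
#' @param config Optional `experiment_config` to echo.
#' @param seed Optional seed to record.
#' @param inputs,outputs Optional file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seed = NULL,
                           inputs = character(), outputs = character()) {
  lines <- c(
    paste0("crowddiff_version: ", as.character(packageVersion("crowddiff"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (!is.null(seed)) lines <- c(lines, paste0("seed: ", seed))
  if (!is.null(config)) {
    p <- config$interaction
    lines <- c(lines, "config:",
               sprintf("  N: %d", config$N),
               sprintf("  box_inner: %g", config$box_inner),
               sprintf("  box_outer: %g", config$box_outer),
               sprintf("  h: %g", config$h),
               sprintf("  duration: %g", config$duration),
               sprintf("  obs_interval: %g", config$obs_interval),
               sprintf("  seed: %d", config$seed),
               sprintf("  sigma: %s", paste(fmt_num(unique(config$sigma)),
                                            collapse = " ")),
               "interaction:",
               sprintf("  D_e: %g", p$D_e), sprintf("  a: %g", p$a),
               sprintf("  r0: %g", p$r0), sprintf("  phi: %s", p$phi))
  }
  digest <- function(fs, tag)
    if (length(fs)) sprintf("%s: %s %s", tag, basename(fs),
                            unname(tools::md5sum(fs)))
  lines <- c(lines, digest(inputs, "input"), digest(outputs, "output"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a key-value config file
#'
#' Parses the flat `key: value` format written by [write_manifest()] /
#' used by the command-line interface, with `simulation` and
#' `interaction` blocks, into an [experiment_config()].
#'
#' @param path Config file path.
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) next
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = ":"))
    if (nzchar(val)) kv[[key]] <- val
  }
  num <- function(key, default = NULL) {
    if (!is.null(kv[[key]])) as.numeric(strsplit(kv[[key]], "\\s+")[[1]])
    else if (!is.null(default)) default
    else stop("config is missing required key '", key, "'")
  }
  experiment_config(
    N = num("N"), sigma = num("sigma"),
    interaction = interaction_params(
      D_e = num("D_e"), a = num("a"), r0 = num("r0", 1),
      phi = if (!is.null(kv$phi)) kv$phi else "exp"),
    duration = num("duration"), obs_interval = num("obs_interval"),
    h = num("h", 1), box_inner = num("box_inner", 40),
    box_outer = num("box_outer", 50), seed = num("seed", 1))
}
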