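#' Motility parameters for the biased persistent random walk
#'
#' Bundles the four intrinsic motility properties of a cell: persistence
#' time \code{tau} (mean time between direction changes, minutes),
#' migration speed \code{s} (um/min), migration bias \code{b} in
#' \eqn{[0, 1]} (0 = purely Brownian, 1 = deterministic motion along the
#' preferred direction), and the preferred direction \code{d} (a unit
#' 2-vector; inside tumor simulations it is set at run time to the
#' normalized oxygen gradient).
#'
#' @param tau persistence time, minutes (> 0)
#' @param s migration speed, um/min (>= 0)
#' @param b migration bias, dimensionless in [0, 1]
#' @param d preferred direction, numeric length-2; normalized internally.
#'   A zero vector is allowed and means "no preferred direction".
#' @return an object of class \code{motility_params}
#' @export
motility_params <- function(tau = 15, s = 0.28, b = 0.1791, d = c(1, 0)) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be a single positive number (minutes)")
  if (!is.numeric(s) || length(s) != 1L || s < 0)
    stop("`s` must be a single non-negative number (um/min)")
  if (!is.numeric(b) || length(b) != 1L || b < 0 || b > 1)
    stop("`b` must lie in [0, 1]")
  if (!is.numeric(d) || length(d) != 2L || anyNA(d))
    stop("`d` must be a numeric 2-vector")
  nd <- sqrt(sum(d^2))
  if (nd > 0) d <- d / nd
  structure(list(tau = tau, s = s, b = b, d = d), class = "motility_params")
}

#' @export
print.motility_params <- function(x, ...) {
  cat(sprintf(
    "motility_params: tau = %g min, s = %g um/min, b = %g, d = (%.3f, %.3f)\n",
    x$tau, x$s, x$b, x$d[1], x$d[2]))
  invisible(x)
}

#' Update a migration direction by the persistent biased turning rule
#'
#' With probability \code{dt / tau} the direction is re-drawn as
#' \code{normalize((1 - b) * xi + b * d)}, where \code{xi} is a uniformly
#' distributed random unit vector; otherwise it is returned unchanged.
#' An exactly cancelling draw (zero resultant) re-draws \code{xi}.
#'
#' @param current_dir unit 2-vector, the current direction
#' @param params a [motility_params()] object
#' @param dt time step, minutes; must not exceed \code{params$tau}
#' @return a unit 2-vector
#' @export
update_direction <- function(current_dir, params, dt) {
  stopifnot(inherits(params, "motility_params"))
  if (dt > params$tau) stop("`dt` must not exceed the persistence time tau")
  if (params$b < 0 || params$b > 1) stop("bias must lie in [0, 1]")
  if (stats::runif(1) >= dt / params$tau) return(current_dir)
  repeat {
    th <- stats::runif(1, 0, 2 * pi)
    v <- (1 - params$b) * c(cos(th), sin(th)) + params$b * params$d
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Simulate independent cell tracks under the biased persistent random walk
#'
#' Cells are seeded at a common origin and move independently (no
#' mechanics, no field coupling) with a fixed preferred direction.
#' Direction turns occur with probability \code{dt / tau} per mechanics
#' step; between turns the motion is a straight line at the cell's speed,
#' which the integrator exploits by advancing exactly between turn events
#' (the turn-event gaps are drawn as geometric step counts, identical in
#' law to the per-step Bernoulli rule).  Positions are sampled on the
#' requested grid.
#'
#' @param params a [motility_params()] object (shared by all cells unless
#'   \code{speeds} is given)
#' @param n_cells number of cells
#' @param duration total tracking time, minutes
#' @param sample_interval sampling interval, minutes; must divide
#'   \code{duration}
#' @param dt mechanics step, minutes (default 0.1)
#' @param speeds optional per-cell speed vector overriding \code{params$s}
#' @return a \code{track_cohort}: list with \code{time_min} (length m + 1
#'   grid including t = 0) and \code{n_cells x (m + 1)} matrices \code{x},
#'   \code{y} in um
#' @export
simulate_tracks <- function(params, n_cells, duration, sample_interval,
                            dt = 0.1, speeds = NULL) {
  stopifnot(inherits(params, "motility_params"))
  if (n_cells < 1) stop("`n_cells` must be at least 1")
  if (duration <= 0 || sample_interval <= 0)
    stop("invalid track spec: duration and sample_interval must be positive")
  m <- duration / sample_interval
  if (abs(m - round(m)) > 1e-9)
    stop("`sample_interval` must divide `duration`")
  m <- as.integer(round(m))
  sps <- sample_interval / dt
  if (abs(sps - round(sps)) > 1e-9)
    stop("`dt` must divide `sample_interval`")
  if (is.null(speeds)) speeds <- rep(params$s, n_cells)
  if (length(speeds) != n_cells) stop("`speeds` must have length n_cells")
  tr <- bprw_tracks_cpp(speeds, params$b, params$d[1], params$d[2],
                        params$tau, dt, as.integer(round(sps)), m)
  structure(list(time_min = seq(0, duration, by = sample_interval),
                 x = tr$x, y = tr$y),
            class = "track_cohort")
}

#' @export
print.track_cohort <- function(x, ...) {
  cat(sprintf("track_cohort: %d cells, %d samples (t = 0..%g min)\n",
              nrow(x$x), length(x$time_min), max(x$time_min)))
  invisible(x)
}

#' Per-timepoint displacement statistics of a track cohort
#'
#' For every point of the shared time grid, the mean and standard
#' deviation of the distance from the origin across cells.  This is the
#' observable used to calibrate migration bias and speed.
#'
#' @param cohort a \code{track_cohort}
#' @return data frame with columns \code{t_min}, \code{mean_disp_um},
#'   \code{sd_disp_um}
#' @export
displacement_series <- function(cohort) {
  stopifnot(inherits(cohort, "track_cohort"))
  if (nrow(cohort$x) < 1) stop("empty cohort")
  d <- sqrt((cohort$x - cohort$x[, 1])^2 + (cohort$y - cohort$y[, 1])^2)
  sd_d <- if (nrow(d) > 1) apply(d, 2, stats::sd) else rep(0, ncol(d))
  data.frame(t_min = cohort$time_min,
             mean_disp_um = colMeans(d),
             sd_disp_um = sd_d)
}
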