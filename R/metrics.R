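#' Movement onset time
#'
#' First sample at which the Euclidean distance from the start-dot center
#' reaches 2.25 cm.
#'
#' @param traj A `reach_trajectory` tibble (see [simulate_trial()]).
#' @param threshold Onset distance, m.
#' @return Onset time in ms, or `NA` (never crossed: a failed trial).
#' @export
detect_onset <- function(traj, threshold = 0.0225) {
  d <- sqrt(traj$x_m^2 + traj$y_m^2)
  # tolerance absorbs rounding when a sample lands exactly on the radius
  i <- which(d >= threshold - 1e-12)[1]
  if (is.na(i)) NA_real_ else traj$t_ms[i]
}

#' Movement end time
#'
#' First sample at which the distance to the target center falls to 0.75 cm.
#'
#' @param traj A `reach_trajectory` tibble.
#' @param threshold End distance, m.
#' @param target Target center, m.
#' @return End time in ms, or `NA` (never reached: a failed trial).
#' @export
detect_end <- function(traj, threshold = 0.0075, target = c(0, 0.15)) {
  d <- sqrt((traj$x_m - target[1])^2 + (traj$y_m - target[2])^2)
  i <- which(d <= threshold + 1e-12)[1]
  if (is.na(i)) NA_real_ else traj$t_ms[i]
}

peak_velocity_index <- function(traj) {
  speed <- sqrt(traj$vx^2 + traj$vy^2)
  which.max(speed)   # earliest sample on ties
}

#' Directional error at peak velocity
#'
#' Signed angle between the vector from the movement-onset position to the
#' target and the vector from the onset position to the position at peak
#' velocity; clockwise (rightward) deviations are positive.
#'
#' @param traj A `reach_trajectory` tibble.
#' @param onset Onset time in ms (see [detect_onset()]).
#' @param target Target center, m.
#' @return Angle in degrees.
#' @export
directional_error <- function(traj, onset, target = c(0, 0.15)) {
  i0 <- match(onset, traj$t_ms)
  if (is.na(i0)) abort("`onset` is not a sample time of this trajectory")
  ip <- peak_velocity_index(traj)
  p0 <- c(traj$x_m[i0], traj$y_m[i0])
  v1 <- target - p0
  v2 <- c(traj$x_m[ip], traj$y_m[ip]) - p0
  if (sqrt(sum(v2^2)) == 0)
    abort("position at peak velocity coincides with the onset position")
  # cross > 0 means v2 counterclockwise of v1; clockwise positive, so negate
  -atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)) * 180 / pi
}

#' Normalized wall force at peak velocity
#'
#' Force the hand exerts on the channel wall at the moment of peak speed,
#' divided by the peak speed (N.s/m). Defined only for channel trials;
#' compensation of the clockwise field reads out negative.
#'
#' @param traj A `reach_trajectory` tibble from an EC or IEC trial.
#' @param min_peak_speed Floor below which the readout is unreliable, m/s.
#' @return Force at peak velocity, N.s/m; `NA` for non-channel trials or when
#'   peak speed is below the floor.
#' @export
force_at_peak_velocity <- function(traj, min_peak_speed = 0.05) {
  ip <- peak_velocity_index(traj)
  w <- traj$wall_force_n[ip]
  if (is.na(w)) return(NA_real_)
  sp <- sqrt(traj$vx[ip]^2 + traj$vy[ip]^2)
  if (sp < min_peak_speed) return(NA_real_)
  w / sp
}

#' Classify trial success from movement time
#'
#' A trial is successful when the movement time falls inside the instructed
#' window (350-450 ms, endpoints inclusive).
#'
#' @param movement_time_ms Movement time(s), ms; `NA` (failed trial) is FALSE.
#' @param window Inclusive window, ms.
#' @return Logical vector.
#' @export
classify_success <- function(movement_time_ms, window = c(350, 450)) {
  !is.na(movement_time_ms) &
    movement_time_ms >= window[1] & movement_time_ms <= window[2]
}

#' Extract all per-trial metrics from a trajectory
#'
#' @param traj A `reach_trajectory` tibble.
#' @param success_window_ms Inclusive success window, ms.
#' @return One-row tibble: `movement_time_ms`, `peak_velocity`, `t_peak_ms`,
#'   `directional_error_deg`, `force_at_pv`, `success`, `failure_flag`.
#' @export
trial_metrics <- function(traj, success_window_ms = c(350, 450)) {
  onset <- detect_onset(traj)
  endt <- detect_end(traj)
  failed <- isTRUE(attr(traj, "failed")) || is.na(onset) || is.na(endt)
  ip <- peak_velocity_index(traj)
  pv <- sqrt(traj$vx[ip]^2 + traj$vy[ip]^2)
  mt <- if (failed) NA_real_ else endt - onset
  de <- if (failed) NA_real_ else directional_error(traj, onset)
  tibble::tibble(
    movement_time_ms = mt,
    peak_velocity = pv,
    t_peak_ms = traj$t_ms[ip],
    directional_error_deg = de,
    force_at_pv = force_at_peak_velocity(traj),
    success = classify_success(mt, success_window_ms),
    failure_flag = failed
  )
}
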