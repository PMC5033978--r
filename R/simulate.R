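#' Clockwise velocity-dependent curl-field force
#'
#' `(Fx, Fy) = (g * vy, -g * vx)`: force is perpendicular to the velocity,
#' with magnitude `g * |v|`, rotated clockwise (a forward reach is pushed
#' rightward).
#'
#' @param vx,vy Hand velocity components, m/s (vectorized).
#' @param g_field Curl gain, N.s/m.
#' @return Tibble with columns `fx`, `fy` (N).
#' @export
#' @examples
#' curl_force(0, 0.5)        # 7.5 N rightward
curl_force <- function(vx, vy, g_field = 15) {
  stopifnot(all(is.finite(vx)), all(is.finite(vy)))
  tibble::tibble(fx = g_field * vy, fy = -g_field * vx)
}

#' Error-clamp channel restoring force
#'
#' Lateral force the spring-damper channel applies to the hand:
#' `-(stiffness * x + damping * vx)`. The wall force recorded in a
#' trajectory is its negation (the force the hand exerts on the wall).
#'
#' @param lateral_pos Lateral displacement from the channel centerline, m.
#' @param lateral_vel Lateral velocity, m/s.
#' @param stiffness Spring stiffness, N/m.
#' @param damping Damping, N.s/m.
#' @return Numeric force on the hand, N (vectorized).
#' @export
#' @examples
#' channel_force(0.001, 0.01)   # -5.3 N
channel_force <- function(lateral_pos, lateral_vel, stiffness = 5000,
                          damping = 30) {
  -(stiffness * lateral_pos + damping * lateral_vel)
}

#' Lateral position of the augmented-error cursor
#'
#' The augmented cursor follows the hand on the forward axis while its lateral
#' position traces the circular arc through the start, the point `max_dev` to
#' the left of the midpoint, and the target; maximal deviation (1 cm by
#' default) occurs mid-reach, endpoints map to zero.
#'
#' @param y_hand Forward hand position, m, in `[0, reach_len]` (values outside
#'   are clamped to the nearest endpoint, where the offset is 0).
#' @param max_dev Maximal leftward deviation, m.
#' @param reach_len Reach length, m.
#' @return Cursor lateral position, m (leftward negative; vectorized).
#' @export
#' @examples
#' augmented_cursor_x(0.075)   # -0.01
augmented_cursor_x <- function(y_hand, max_dev = 0.01, reach_len = 0.15) {
  y <- pmin(pmax(y_hand, 0), reach_len)
  # circle through (0,0), (-max_dev, L/2), (0, L): center at y = L/2 and
  # x = xc = ((L/2)^2 - max_dev^2) / (2 * max_dev) > 0 (to the right of the
  # straight path for max_dev < L/2), so the arc bulges left.
  L <- reach_len
  xc <- ((L / 2)^2 - max_dev^2) / (2 * max_dev)
  r <- sqrt(xc^2 + (L / 2)^2)
  xc - sqrt(pmax(r^2 - (y - L / 2)^2, 0))
}

#' Minimum-jerk reference trajectory
#'
#' Position, velocity and acceleration of the classic fifth-order polynomial
#' reach profile from 0 to `dist` over `duration_ms`, held at the endpoint
#' afterwards.
#'
#' @param t_ms Times, ms.
#' @param dist Reach distance, m.
#' @param duration_ms Movement duration, ms.
#' @return Tibble with columns `pos` (m), `vel` (m/s), `acc` (m/s^2).
#' @keywords internal
min_jerk <- function(t_ms, dist = 0.15, duration_ms = 765) {
  tau <- pmin(pmax(t_ms / duration_ms, 0), 1)
  Ts <- duration_ms / 1000
  tibble::tibble(
    pos = dist * (10 * tau^3 - 15 * tau^4 + 6 * tau^5),
    vel = dist / Ts * (30 * tau^2 - 60 * tau^3 + 30 * tau^4),
    acc = dist / Ts^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
  )
}

#' Simulate a single reaching trial at 1 kHz
#'
#' Point-mass hand tracking a minimum-jerk reference with a PD controller plus
#' feedforward of the reference acceleration. The learner contributes an
#' anticipatory lateral force `-z * g_field * vy` (compensation of the
#' expected clockwise curl). The environment depends on the trial phase:
#' null/familiarization trials apply no force, force-field trials the curl
#' field, and (interspersed) error-clamp trials the stiff channel, in which
#' lateral tracking is ceded to the channel and the net anticipatory push is
#' absorbed by the wall — so the recorded wall force at peak velocity reads
#' out `-z * g_field * vy`.
#'
#' @param z Compensation state expressed this trial (fraction of the field).
#' @param phase One of `"FAM"`, `"N"`, `"FF"`, `"EC"`, `"IEC"`.
#' @param physics A [physics_params()].
#' @param control A [control_params()].
#' @param motor_noise_sd White noise SD on the commanded lateral force, N
#'   (0 for a noiseless trial).
#' @param duration_ms Reference duration for this trial, ms (defaults to the
#'   controller's calibrated value; jitter it per trial upstream).
#' @return Tibble of class `reach_trajectory` with columns `t_ms`, `x_m`,
#'   `y_m`, `vx`, `vy`, `fx_env`, `fy_env`, `wall_force_n` (NA outside channel
#'   trials); attributes `phase` and `failed` (TRUE if the target was not
#'   acquired before timeout).
#' @export
simulate_trial <- function(z, phase, physics = physics_params(),
                           control = control_params(),
                           motor_noise_sd = 0, duration_ms = NULL) {
  stopifnot(is.finite(z), phase %in% c("FAM", "N", "FF", "EC", "IEC"))
  dt <- control$dt_ms / 1000
  L <- physics$reach_len
  dur <- duration_ms %||% control$ref_duration_ms
  n_max <- ceiling(control$timeout_ms / control$dt_ms)
  channel <- phase %in% c("EC", "IEC")
  curl <- phase == "FF"

  t_ms <- seq(0, by = control$dt_ms, length.out = n_max + 1)
  ref <- min_jerk(t_ms, dist = L, duration_ms = dur)
  noise <- if (motor_noise_sd > 0) rnorm(n_max + 1, 0, motor_noise_sd) else numeric(n_max + 1)

  x <- y <- vx <- vy <- fxe <- fye <- wall <- numeric(n_max + 1)
  m <- physics$mass; kp <- control$kp; kd <- control$kd
  g <- physics$g_field; K <- physics$stiffness; D <- physics$damping
  xi <- 0; yi <- 0; vxi <- 0; vyi <- 0
  end_i <- n_max + 1; acquired <- FALSE
  for (i in seq_len(n_max + 1)) {
    # environment force
    if (channel) {
      fx_env <- channel_force(xi, vxi, K, D); fy_env <- 0
    } else if (curl) {
      fx_env <- g * vyi; fy_env <- -g * vxi
    } else {
      fx_env <- 0; fy_env <- 0
    }
    # controller: feedforward reference acceleration + PD tracking; lateral
    # tracking is released inside the channel
    fy_ctl <- m * ref$acc[i] + kp * (ref$pos[i] - yi) + kd * (ref$vel[i] - vyi)
    fx_ctl <- if (channel) 0 else kp * (0 - xi) + kd * (0 - vxi)
    # learned anticipatory compensation of the expected field
    fx_ff <- -z * g * vyi + noise[i]

    x[i] <- xi; y[i] <- yi; vx[i] <- vxi; vy[i] <- vyi
    fxe[i] <- fx_env; fye[i] <- fy_env
    wall[i] <- if (channel) -fx_env else NA_real_

    if (sqrt(xi^2 + (yi - L)^2) <= 0.0075) { end_i <- i; acquired <- TRUE; break }

    ax <- (fx_env + fx_ctl + fx_ff) / m
    ay <- (fy_env + fy_ctl) / m
    vxi <- vxi + ax * dt; vyi <- vyi + ay * dt
    xi <- xi + vxi * dt;  yi <- yi + vyi * dt
  }
  keep <- seq_len(min(end_i, n_max + 1))
  out <- tibble::tibble(t_ms = t_ms[keep], x_m = x[keep], y_m = y[keep],
                        vx = vx[keep], vy = vy[keep],
                        fx_env = fxe[keep], fy_env = fye[keep],
                        wall_force_n = wall[keep])
  structure(out, class = c("reach_trajectory", class(out)),
            phase = phase, failed = !acquired)
}

#' Visual error experienced by the learner on one trial
#'
#' On field/null trials the error is the measured lateral deviation at peak
#' velocity normalized by reach length (rightward positive: under-compensation
#' of the clockwise field yields a positive, adaptation-driving error). On
#' clamp trials the hand runs straight, so the only error available is the
#' mismatch between the trajectory the adapted motor system predicts and the
#' visual feedback — a mismatch that grows with the adaptation state itself.
#' The arc conveys no direction (error 0); the veridical cursor yields the
#' decay-driving prediction error `-z * clamp_error_scale`; the augmented
#' cursor adds its own leftward offset on top, so its error is nonzero even
#' for an unadapted learner.
#'
#' @param phase Trial phase.
#' @param feedback Feedback condition (`"arc"`, `"cursor"`, `"augmented"`).
#' @param z Current total compensation state.
#' @param params A [learner_params()].
#' @param lateral_dev_norm Measured lateral deviation at peak velocity
#'   normalized by reach length (trajectory tier); `NULL` in the fast tier,
#'   where field/null deviations are predicted as `(field - z) * d_field`.
#' @param aug_offset_norm Augmented-cursor offset magnitude at peak velocity,
#'   normalized by reach length (defaults to 1 cm mid-reach / 15 cm).
#' @return Signed unitless error.
#' @export
experienced_error <- function(phase, feedback, z, params = learner_params(),
                              lateral_dev_norm = NULL,
                              aug_offset_norm = 0.01 / 0.15) {
  if (phase %in% c("EC", "IEC")) {
    gain <- unname(params$clamp_error_gain[[feedback]])
    if (gain == 0) return(0)
    pred <- z * params$clamp_error_scale
    if (feedback == "augmented") pred <- pred + aug_offset_norm
    return(-gain * pred)
  }
  if (!is.null(lateral_dev_norm)) return(lateral_dev_norm)
  field <- as.numeric(phase == "FF")
  (field - z) * params$d_field
}

#' Two-state learner update
#'
#' `z_i <- retention_i * z_i + learn_i * error (+ state noise)` for the fast
#' and slow states. The behavioral compensation is `z = z_fast + z_slow`,
#' clipped to `[-0.5, 1.5]`.
#'
#' @param state List with `z_fast` and `z_slow`.
#' @param error Signed experienced error (see [experienced_error()]).
#' @param params A [learner_params()].
#' @param noisy Add Gaussian state noise (`state_noise_sd`) to each state.
#' @return Updated state list.
#' @export
#' @examples
#' update_state(list(z_fast = 0.1, z_slow = 0.4), error = 0,
#'              params = learner_params(state_noise_sd = 0))
update_state <- function(state, error, params = learner_params(),
                         noisy = FALSE) {
  ns <- if (noisy && params$state_noise_sd > 0) rnorm(2, 0, params$state_noise_sd) else c(0, 0)
  zf <- params$retention_fast * state$z_fast + params$learn_fast * error + ns[1]
  zs <- params$retention_slow * state$z_slow + params$learn_slow * error + ns[2]
  tot <- zf + zs
  if (tot > 1.5 || tot < -0.5) {           # clip total, preserving the ratio
    scale <- max(min(tot, 1.5), -0.5) / tot
    zf <- zf * scale; zs <- zs * scale
  }
  list(z_fast = zf, z_slow = zs)
}
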