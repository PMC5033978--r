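# Fraction of a minimum-jerk reach spent between the onset threshold
# (2.25 cm from start) and the end threshold (0.75 cm short of the target):
# movement time = fraction * reference duration.
mt_fraction <- function(reach_len = 0.15, onset_m = 0.0225, end_m = 0.0075) {
  s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  lo <- stats::uniroot(function(t) s(t) - onset_m / reach_len, c(0, 1), tol = 1e-12)$root
  hi <- stats::uniroot(function(t) s(t) - (1 - end_m / reach_len), c(0, 1), tol = 1e-12)$root
  hi - lo
}

derive_seed <- function(seed, salt) {
  (as.double(seed) * 1000003 + salt * 7919) %% 2147483629 + 1
}

jitter_participants <- function(n, learner, cohort) {
  rf <- pmin(learner$retention_fast + rnorm(n, 0, cohort$jitter_retention), 0.985)
  rs <- pmin(learner$retention_slow + rnorm(n, 0, cohort$jitter_retention / 2), 0.9995)
  rs <- pmax(rs, rf + 0.005)           # keep fast < slow
  lf <- learner$learn_fast * exp(rnorm(n, 0, cohort$jitter_learn) - cohort$jitter_learn^2 / 2)
  ls <- learner$learn_slow * exp(rnorm(n, 0, cohort$jitter_learn) - cohort$jitter_learn^2 / 2)
  ls <- pmin(ls, lf * 0.9)             # keep slow gain below fast gain
  df <- learner$d_field * exp(rnorm(n, 0, cohort$jitter_d_field) - cohort$jitter_d_field^2 / 2)
  cs <- learner$clamp_error_scale * exp(rnorm(n, 0, cohort$jitter_learn) - cohort$jitter_learn^2 / 2)
  tibble::tibble(retention_fast = rf, retention_slow = rs,
                 learn_fast = lf, learn_slow = ls, d_field = df,
                 clamp_error_scale = cs)
}

simulate_group_fast <- function(schedule, feedback, config, group_seed) {
  set.seed(as.integer(group_seed))
  n <- config$cohort$n_per_group
  l <- config$learner; g <- config$physics$g_field
  pars <- jitter_participants(n, l, config$cohort)
  gain <- unname(l$clamp_error_gain[[feedback]])
  aug_offset <- if (feedback == "augmented")
    abs(augmented_cursor_x(config$physics$reach_len / 2)) / config$physics$reach_len else 0
  mt_mean <- mt_fraction(config$physics$reach_len) * config$control$ref_duration_ms
  mt_sd <- config$control$duration_jitter * mt_mean
  pv_mean <- 1.875 * config$physics$reach_len / (config$control$ref_duration_ms / 1000)

  zf <- rep(0, n); zs <- rep(0, n)
  n_tr <- nrow(schedule)
  fpv <- matrix(NA_real_, n_tr, n)
  de <- matrix(NA_real_, n_tr, n)
  zmat <- matrix(NA_real_, n_tr, n)
  phase <- schedule$phase
  # noise scale on the executed deviation, expressed in compensation units
  exec_sd <- l$fpv_noise_sd / g
  for (i in seq_len(n_tr)) {
    z <- zf + zs
    zmat[i, ] <- z
    ch <- phase[i] %in% c("EC", "IEC")
    if (ch) {
      fpv[i, ] <- -g * z + rnorm(n, 0, l$fpv_noise_sd)
      err <- if (gain == 0) rep(0, n) else -gain * (z * pars$clamp_error_scale + aug_offset)
    } else {
      field <- as.numeric(phase[i] == "FF")
      dev <- (field - z) * pars$d_field + rnorm(n, 0, exec_sd * l$d_field)
      de[i, ] <- atan2(dev * config$physics$reach_len, config$physics$reach_len / 2) * 180 / pi
      err <- dev
    }
    ns <- if (l$state_noise_sd > 0) rnorm(2 * n, 0, l$state_noise_sd) else numeric(2 * n)
    zf <- pars$retention_fast * zf + pars$learn_fast * err + ns[seq_len(n)]
    zs <- pars$retention_slow * zs + pars$learn_slow * err + ns[n + seq_len(n)]
    tot <- zf + zs
    over <- tot > 1.5 | tot < -0.5
    if (any(over)) {
      sc <- pmax(pmin(tot[over], 1.5), -0.5) / tot[over]
      zf[over] <- zf[over] * sc; zs[over] <- zs[over] * sc
    }
  }
  mt <- matrix(rnorm(n_tr * n, mt_mean, mt_sd), n_tr, n)
  pv <- matrix(rnorm(n_tr * n, pv_mean, 0.03), n_tr, n)
  purrr::map_dfr(seq_len(n), function(j) {
    dplyr::mutate(
      schedule[, c("global_index", "phase", "block_label", "within_block_index")],
      participant = sprintf("%s_%02d", feedback, j),
      group = feedback, feedback = feedback,
      movement_time_ms = mt[, j],
      peak_velocity = pv[, j],
      directional_error_deg = de[, j],
      force_at_pv = fpv[, j],
      z_state = zmat[, j],
      success = classify_success(mt[, j], config$analysis$success_window_ms),
      failure_flag = FALSE)
  })
}

simulate_group_trajectory <- function(schedule, feedback, config, group_seed,
                                      keep_trajectories = FALSE) {
  set.seed(as.integer(group_seed))
  n <- config$cohort$n_per_group
  l <- config$learner; phy <- config$physics; ctl <- config$control
  pars <- jitter_participants(n, l, config$cohort)
  rows <- vector("list", n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  for (j in seq_len(n)) {
    pj <- learner_params(
      retention_fast = pars$retention_fast[j], retention_slow = pars$retention_slow[j],
      learn_fast = pars$learn_fast[j], learn_slow = pars$learn_slow[j],
      clamp_error_gain = l$clamp_error_gain, d_field = pars$d_field[j],
      clamp_error_scale = pars$clamp_error_scale[j],
      state_noise_sd = l$state_noise_sd, fpv_noise_sd = l$fpv_noise_sd,
      motor_noise_sd = l$motor_noise_sd)
    state <- list(z_fast = 0, z_slow = 0)
    recs <- vector("list", nrow(schedule))
    tlist <- if (keep_trajectories) vector("list", nrow(schedule)) else NULL
    for (i in seq_len(nrow(schedule))) {
      ph <- schedule$phase[i]
      z <- state$z_fast + state$z_slow
      dur <- ctl$ref_duration_ms * exp(rnorm(1, 0, ctl$duration_jitter) -
                                         ctl$duration_jitter^2 / 2)
      # per-trial execution noise on the expressed compensation, scaled so the
      # force-at-peak-velocity readout varies with SD ~ fpv_noise_sd
      z_expr <- z + rnorm(1, 0, l$fpv_noise_sd / phy$g_field)
      traj <- simulate_trial(z_expr, ph, physics = phy,
                             control = ctl, motor_noise_sd = l$motor_noise_sd,
                             duration_ms = dur)
      m <- trial_metrics(traj, config$analysis$success_window_ms)
      ip <- peak_velocity_index(traj)
      dev_norm <- traj$x_m[ip] / phy$reach_len
      err <- experienced_error(ph, feedback, z, pj,
                               lateral_dev_norm = if (ph %in% c("EC", "IEC")) NULL else dev_norm)
      state <- update_state(state, err, pj, noisy = TRUE)
      recs[[i]] <- dplyr::mutate(m, z_state = z)
      if (keep_trajectories) tlist[[i]] <- traj
    }
    rows[[j]] <- dplyr::bind_cols(
      schedule[, c("global_index", "phase", "block_label", "within_block_index")],
      tibble::tibble(participant = sprintf("%s_%02d", feedback, j),
                     group = feedback, feedback = feedback),
      dplyr::bind_rows(recs))
    if (keep_trajectories) trajs[[j]] <- tlist
  }
  out <- dplyr::bind_rows(rows)
  if (keep_trajectories) attr(out, "trajectories") <- trajs
  out
}

#' Simulate a full cohort
#'
#' Generates one group of participants per feedback condition, all following
#' the same trial schedule, with per-participant parameter jitter and a
#' deterministic RNG stream derived from `(seed, group)`. Two fidelity tiers
#' share the learner: `"fast"` generates the per-trial metrics directly from
#' the learner state plus noise; `"trajectory"` integrates every reach at
#' 1 kHz through the point-mass model and extracts the metrics from the
#' simulated paths.
#'
#' @param config A [default_config()].
#' @param seed Master seed for all noise (schedules use `schedule_seed`, so
#'   changing `seed` changes noise realizations but not the trial plan).
#' @param mode `"fast"` or `"trajectory"`.
#' @param schedule_seed Seed for IEC placement in the schedule.
#' @param keep_trajectories In trajectory mode, attach the simulated
#'   trajectories as an attribute (memory-heavy; small runs only).
#' @return Tibble with one row per trial per participant: schedule columns,
#'   `participant`, `group`, `feedback`, the per-trial metrics
#'   (`movement_time_ms`, `peak_velocity`, `directional_error_deg`,
#'   `force_at_pv`, `success`, `failure_flag`), and the latent `z_state`
#'   (available only because the cohort is simulated).
#' @export
#' @examples
#' cfg <- default_config(cohort = cohort_params(n_per_group = 2))
#' tab <- simulate_cohort(cfg, seed = 1)
#' dplyr::count(tab, group)
simulate_cohort <- function(config = default_config(), seed = 1,
                            mode = c("fast", "trajectory"),
                            schedule_seed = 1, keep_trajectories = FALSE) {
  mode <- match.arg(mode)
  viol <- validate_config(config)
  if (nrow(viol) > 0)
    abort(paste0("invalid configuration: ",
                 paste(viol$key, viol$rule, sep = " - ", collapse = "; ")))
  schedule <- build_schedule(config$protocol, seed = schedule_seed)
  groups <- config$cohort$groups
  out <- purrr::map_dfr(seq_along(groups), function(gi) {
    fun <- if (mode == "fast") simulate_group_fast else simulate_group_trajectory
    gseed <- derive_seed(seed, gi)
    if (mode == "fast") fun(schedule, groups[gi], config, gseed)
    else fun(schedule, groups[gi], config, gseed, keep_trajectories)
  })
  attr(out, "config_digest") <- config_digest(unclass(config))
  attr(out, "seed") <- seed
  out
}
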