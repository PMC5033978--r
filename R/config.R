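#' Protocol configuration
#'
#' Trial counts for the alternating force-field / error-clamp design:
#' a familiarization period, a baseline null block (N1, with interspersed
#' error-clamp probes), ten force-field blocks each followed by an
#' assessment error-clamp block (the last one deferred until after washout),
#' a null washout block (N2), and a final recall error-clamp block (EC10).
#'
#' The defaults reproduce the published totals: 192 familiarization trials,
#' then 617 trials in 22 blocks — N1 = 66 null + 6 interspersed clamps,
#' 10 x (18 force-field + 2 interspersed clamps), 10 x 30 error-clamp
#' trials, and a 45-trial washout.
#'
#' @param fam_trials Familiarization (null-field) trials before the main run.
#' @param n1_null,n1_iec Null trials and interspersed error-clamp trials in N1.
#' @param n_ff_blocks Number of force-field blocks.
#' @param ff_trials,ff_iec Force-field trials and interspersed clamps per FF block.
#' @param n_ec_blocks Number of assessment error-clamp blocks.
#' @param ec_trials Error-clamp trials per EC block.
#' @param n2_null Null washout trials (no interspersed clamps by default).
#' @param iec_lead_in Earliest within-block position at which an interspersed
#'   clamp may appear; the first `iec_lead_in - 1` trials of a host block are
#'   always field/null trials so block-entry behavior is field-driven.
#' @return A list of class `protocol_config`.
#' @export
#' @examples
#' cfg <- protocol_config()
#' protocol_total(cfg)  # 617
protocol_config <- function(fam_trials = 192,
                            n1_null = 66, n1_iec = 6,
                            n_ff_blocks = 10, ff_trials = 18, ff_iec = 2,
                            n_ec_blocks = 10, ec_trials = 30,
                            n2_null = 45,
                            iec_lead_in = 4) {
  cfg <- list(
    fam_trials = as.integer(fam_trials),
    n1_null = as.integer(n1_null), n1_iec = as.integer(n1_iec),
    n_ff_blocks = as.integer(n_ff_blocks),
    ff_trials = as.integer(ff_trials), ff_iec = as.integer(ff_iec),
    n_ec_blocks = as.integer(n_ec_blocks), ec_trials = as.integer(ec_trials),
    n2_null = as.integer(n2_null),
    iec_lead_in = as.integer(iec_lead_in)
  )
  structure(cfg, class = c("protocol_config", "list"))
}

#' Total number of post-familiarization trials implied by a protocol config
#' @param config A [protocol_config()].
#' @return Integer trial count.
#' @export
protocol_total <- function(config) {
  with(config,
       n1_null + n1_iec +
         n_ff_blocks * (ff_trials + ff_iec) +
         n_ec_blocks * ec_trials +
         n2_null)
}

#' Physics parameters: curl field and error-clamp channel
#'
#' @param g_field Curl-field gain in N.s/m; the field force is
#'   `(Fx, Fy) = (g * vy, -g * vx)`, a clockwise curl.
#' @param stiffness Channel spring stiffness, N/m.
#' @param damping Channel damping, N.s/m.
#' @param mass Point-mass of hand plus handle, kg.
#' @param reach_len Reach distance, m (start dot to target dot center).
#' @return A list of class `physics_params`.
#' @export
physics_params <- function(g_field = 15, stiffness = 5000, damping = 30,
                           mass = 1, reach_len = 0.15) {
  stopifnot(g_field > 0, stiffness >= 0, damping >= 0, mass > 0, reach_len > 0)
  structure(list(g_field = g_field, stiffness = stiffness, damping = damping,
                 mass = mass, reach_len = reach_len),
            class = c("physics_params", "list"))
}

#' Two-state learner parameters
#'
#' The learner keeps a fast and a slow compensation state; their sum `z` is
#' the fraction of the curl field compensated (z = 1 means full compensation).
#' Each trial: `z_i <- retention_i * z_i + learn_i * error + state noise`.
#' During error-clamp trials the error available to the learner depends on the
#' visual feedback condition: the arc conveys no directional information
#' (gain 0); the veridical straight cursor conveys a prediction error that
#' grows with the adaptation state itself (`-z * clamp_error_scale`), because
#' an adapted motor system predicts a curved trajectory that the clamped,
#' straight feedback contradicts; the augmented cursor adds the offset of its
#' leftward-curved path on top of that.
#'
#' @param retention_fast,retention_slow Per-trial retention factors, in (0, 1);
#'   fast < slow.
#' @param learn_fast,learn_slow Error gains; fast > slow.
#' @param clamp_error_gain Named numeric vector mapping feedback condition
#'   (`arc`, `cursor`, `augmented`) to the visual error gain during clamp trials.
#' @param d_field Typical field-driven lateral deviation at peak velocity for an
#'   unadapted learner, normalized by reach length (unitless). Sets the scale of
#'   the error signal in the fast (metric-level) tier; the trajectory tier
#'   measures it from the simulated path.
#' @param clamp_error_scale Normalized prediction-error magnitude per unit of
#'   compensation state during clamp trials with trajectory feedback: the
#'   visual error is `-z * clamp_error_scale` (cursor) with the curved-cursor
#'   offset added for augmented feedback. Calibrated so the within-block
#'   unlearning of the cursor condition is markedly faster than the arc
#'   condition's passive (retention-only) decay, of the order of the published
#'   group decay rates.
#' @param state_noise_sd Per-trial SD of the additive state noise (unitless).
#' @param fpv_noise_sd Trial-to-trial SD of the force-at-peak-velocity readout,
#'   N.s/m (execution + measurement noise).
#' @param motor_noise_sd White force noise on the commanded lateral force in the
#'   trajectory tier, N.
#' @return A list of class `learner_params`.
#' @export
learner_params <- function(retention_fast = 0.92, retention_slow = 0.996,
                           learn_fast = 0.08, learn_slow = 0.01,
                           clamp_error_gain = c(arc = 0, cursor = 1, augmented = 1),
                           d_field = 0.12,
                           clamp_error_scale = 2,
                           state_noise_sd = 0.005,
                           fpv_noise_sd = 1.4,
                           motor_noise_sd = 0.5) {
  stopifnot(retention_fast < retention_slow,
            retention_fast > 0, retention_slow < 1,
            learn_fast > learn_slow,
            all(c("arc", "cursor", "augmented") %in% names(clamp_error_gain)))
  structure(list(retention_fast = retention_fast, retention_slow = retention_slow,
                 learn_fast = learn_fast, learn_slow = learn_slow,
                 clamp_error_gain = clamp_error_gain,
                 d_field = d_field,
                 clamp_error_scale = clamp_error_scale,
                 state_noise_sd = state_noise_sd,
                 fpv_noise_sd = fpv_noise_sd,
                 motor_noise_sd = motor_noise_sd),
            class = c("learner_params", "list"))
}

#' Reach controller parameters (trajectory tier)
#'
#' The hand tracks a minimum-jerk reference with a PD controller plus exact
#' feedforward of the reference acceleration. `ref_duration_ms` is calibrated
#' so that the measured Movement Time (onset at 2.25 cm from the start center
#' to arrival within 0.75 cm of the target center) is ~400 ms, the middle of
#' the instructed 400 +/- 50 ms window: those thresholds span only ~52% of a
#' minimum-jerk profile.
#'
#' @param kp,kd PD gains, N/m and N.s/m.
#' @param ref_duration_ms Minimum-jerk reference duration, ms.
#' @param duration_jitter Fractional SD of the per-trial reference duration
#'   (drives the movement-time distribution; 0.12 gives MT SD ~ 48 ms so the
#'   350-450 ms window is hit with probability ~0.70).
#' @param timeout_ms Trial timeout, ms.
#' @param dt_ms Integration/sampling step, ms (1 kHz).
#' @return A list of class `control_params`.
#' @export
control_params <- function(kp = 300, kd = 35, ref_duration_ms = 765,
                           duration_jitter = 0.12, timeout_ms = 1200,
                           dt_ms = 1) {
  stopifnot(kp > 0, kd >= 0, ref_duration_ms > 0, duration_jitter >= 0,
            timeout_ms >= ref_duration_ms, dt_ms > 0)
  structure(list(kp = kp, kd = kd, ref_duration_ms = ref_duration_ms,
                 duration_jitter = duration_jitter, timeout_ms = timeout_ms,
                 dt_ms = dt_ms),
            class = c("control_params", "list"))
}

#' Cohort-level configuration
#'
#' @param n_per_group Participants per feedback group.
#' @param groups Feedback conditions simulated (one cohort group each).
#' @param jitter_retention Additive SD of between-participant jitter on the
#'   retention factors (clipped below 1).
#' @param jitter_learn Fractional SD of between-participant jitter on the
#'   learning gains.
#' @param jitter_d_field Fractional SD of between-participant jitter on d_field.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 15,
                          groups = c("arc", "cursor", "augmented"),
                          jitter_retention = 0.005,
                          jitter_learn = 0.15,
                          jitter_d_field = 0.10) {
  stopifnot(n_per_group >= 1, length(groups) >= 1,
            all(groups %in% c("arc", "cursor", "augmented")))
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 jitter_retention = jitter_retention,
                 jitter_learn = jitter_learn,
                 jitter_d_field = jitter_d_field),
            class = c("cohort_params", "list"))
}

#' Analysis parameters for the decay-rate procedure
#'
#' @param subsample_k Subset size of the exhaustive subsampling bootstrap.
#' @param ec_blocks Labels of the error-clamp blocks averaged into the
#'   per-participant 30-trial decay series.
#' @param bin_size Trials per bin for block-entry/block-end summaries.
#' @param tail `"absolute"` compares permutation |differences| against the
#'   |mean bootstrap difference| (two-sided); `"greater"` is the literal
#'   one-sided rule.
#' @param b_bounds Decay-rate search interval for the exponential fit.
#' @param success_window_ms Inclusive movement-time window counted as a
#'   successful trial, ms.
#' @return A list of class `analysis_params`.
#' @export
analysis_params <- function(subsample_k = 12,
                            ec_blocks = paste0("EC", 1:9),
                            bin_size = 6,
                            tail = c("absolute", "greater"),
                            b_bounds = c(-5, 0.5),
                            success_window_ms = c(350, 450)) {
  tail <- match.arg(tail)
  stopifnot(subsample_k >= 1, bin_size >= 1, length(b_bounds) == 2,
            b_bounds[1] < b_bounds[2], length(success_window_ms) == 2)
  structure(list(subsample_k = as.integer(subsample_k), ec_blocks = ec_blocks,
                 bin_size = as.integer(bin_size), tail = tail,
                 b_bounds = b_bounds, success_window_ms = success_window_ms),
            class = c("analysis_params", "list"))
}

#' Full run configuration
#'
#' Bundles the protocol, physics, learner, controller, cohort and analysis
#' sections. Every default reproduces the printed protocol constants
#' (617 trials / 22 blocks / 30 per EC block / 18 FF per block / 192
#' familiarization; field gain 15 N.s/m; channel 5000 N/m and 30 N.s/m;
#' success window 350-450 ms; onset/end thresholds 2.25 / 0.75 cm; 1 cm
#' maximal cursor deviation).
#'
#' @param protocol,physics,learner,control,cohort,analysis Section objects;
#'   see the corresponding constructors.
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' validate_config(cfg)   # empty tibble: no violations
default_config <- function(protocol = protocol_config(),
                           physics = physics_params(),
                           learner = learner_params(),
                           control = control_params(),
                           cohort = cohort_params(),
                           analysis = analysis_params()) {
  structure(list(protocol = protocol, physics = physics, learner = learner,
                 control = control, cohort = cohort, analysis = analysis),
            class = c("run_config", "list"))
}

#' Validate a run configuration
#'
#' Checks every section invariant and returns one row per violation; an empty
#' tibble means the configuration is valid.
#'
#' @param config A [default_config()]-style list (possibly hand-edited).
#' @return Tibble with columns `key` and `rule`.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(key, rule) tibble::tibble(key = key, rule = rule)
  p <- config$protocol
  counts <- unlist(p[c("fam_trials", "n1_null", "n1_iec", "n_ff_blocks",
                       "ff_trials", "ff_iec", "n_ec_blocks", "ec_trials",
                       "n2_null")])
  if (any(counts < 0) || any(counts != round(counts)))
    v <- c(v, list(bad("protocol", "all trial counts must be non-negative integers")))
  if (p$n1_iec > 0 && p$n1_null + p$n1_iec < p$iec_lead_in)
    v <- c(v, list(bad("protocol.n1_iec", "host block shorter than the IEC lead-in")))
  if (p$ff_iec >= p$ff_trials + p$ff_iec && p$ff_iec > 0)
    v <- c(v, list(bad("protocol.ff_iec", "IEC count must be below host block length")))
  ph <- config$physics
  if (ph$g_field <= 0)
    v <- c(v, list(bad("physics.g_field", "curl gain must be > 0")))
  if (ph$stiffness < 0)
    v <- c(v, list(bad("physics.stiffness", "channel stiffness must be >= 0")))
  if (ph$damping < 0)
    v <- c(v, list(bad("physics.damping", "channel damping must be >= 0")))
  l <- config$learner
  if (!(l$retention_fast < l$retention_slow))
    v <- c(v, list(bad("learner.retention", "retention_fast must be < retention_slow")))
  if (!(l$learn_fast > l$learn_slow))
    v <- c(v, list(bad("learner.learn", "learn_fast must be > learn_slow")))
  if (any(!c("arc", "cursor", "augmented") %in% names(l$clamp_error_gain)))
    v <- c(v, list(bad("learner.clamp_error_gain", "must name arc, cursor and augmented")))
  a <- config$analysis
  n <- config$cohort$n_per_group
  if (a$subsample_k > n)
    v <- c(v, list(bad("analysis.subsample_k", "subset size exceeds group size")))
  if (a$success_window_ms[1] >= a$success_window_ms[2])
    v <- c(v, list(bad("analysis.success_window_ms", "window must be increasing")))
  if (length(v) == 0) return(tibble::tibble(key = character(), rule = character()))
  dplyr::bind_rows(v)
}

#' Stable digest of a configuration
#'
#' Rolling polynomial hash of the canonical `key: value` serialization; used
#' to tag schedules and report bundles with the configuration that generated
#' them.
#'
#' @param config Any nested list of atomic values.
#' @return An 8-character hex token.
#' @export
config_digest <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  canon <- paste(names(flat), vapply(flat, format, character(1), digits = 15),
                 sep = ": ", collapse = "\n")
  bytes <- utf8ToInt(canon)
  # polynomial rolling hash mod the Mersenne prime 2^31 - 1 (stable across
  # platforms; doubles hold intermediates exactly below 2^53)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read / write a configuration as YAML
#'
#' @param config A `run_config` list.
#' @param path File path.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  # named vectors become YAML maps (yaml drops names of atomic vectors)
  as_yamlable <- function(x) if (length(x) > 1 && !is.null(names(x))) as.list(x) else x
  yaml::write_yaml(lapply(config, function(s) lapply(unclass(s), as_yamlable)),
                   path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sec in names(cfg)) {
    if (!is.null(raw[[sec]])) {
      upd <- lapply(raw[[sec]], function(x) {
        # YAML sequences/maps of scalars come back as lists; flatten them
        if (is.list(x) && all(vapply(x, function(e)
          is.atomic(e) && length(e) == 1, logical(1)))) unlist(x) else x
      })
      cfg[[sec]] <- modifyList(cfg[[sec]], upd)
    }
  }
  cfg
}
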