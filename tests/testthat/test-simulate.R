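test_that("curl force follows F = Bv for the clockwise field", {
  expect_equal(unlist(curl_force(0, 0)), c(fx = 0, fy = 0))
  expect_equal(unlist(curl_force(0, 0.5, g_field = 15)), c(fx = 7.5, fy = 0))
  expect_equal(unlist(curl_force(0.1, 0, g_field = 15)), c(fx = 0, fy = -1.5))
})

test_that("curl force is orthogonal to velocity with magnitude g|v|", {
  withr::with_seed(11, {
    vx <- rnorm(1000); vy <- rnorm(1000)
  })
  f <- curl_force(vx, vy, g_field = 15)
  expect_lt(max(abs(f$fx * vx + f$fy * vy)), 1e-12)
  expect_equal(sqrt(f$fx^2 + f$fy^2), 15 * sqrt(vx^2 + vy^2), tolerance = 1e-12)
})

test_that("channel restoring force matches the spring-damper law", {
  expect_equal(channel_force(0, 0), 0)
  expect_equal(channel_force(0.001, 0.01), -5.3)
  expect_equal(channel_force(-0.001, 0), 5)
})

test_that("augmented cursor arc passes through its anchor points", {
  expect_equal(augmented_cursor_x(0), 0)
  expect_equal(augmented_cursor_x(0.075), -0.01)
  expect_equal(augmented_cursor_x(0.15), 0, tolerance = 1e-12)
  # out-of-range forward positions clamp to the endpoint value
  expect_equal(augmented_cursor_x(-0.02), 0)
  expect_equal(augmented_cursor_x(0.2), 0, tolerance = 1e-12)
  # bulges left everywhere in between
  expect_true(all(augmented_cursor_x(seq(0.01, 0.14, by = 0.01)) < 0))
})

test_that("unadapted reach in the curl field deviates rightward", {
  tr <- simulate_trial(0, "FF")
  expect_gt(max(tr$x_m), 0.005)
  expect_false(attr(tr, "failed"))
})

test_that("channel wall force reads out the compensation state", {
  # nothing to compensate: wall force stays near zero
  tr0 <- simulate_trial(0, "EC")
  expect_lt(max(abs(tr0$wall_force_n)), 0.2)
  # z = 0.5: normalized wall force at peak velocity ~ -z * g within 5%
  tr <- simulate_trial(0.5, "EC")
  fpv <- force_at_peak_velocity(tr)
  expect_lt(abs(fpv - (-0.5 * 15)) / (0.5 * 15), 0.05)
  # channel confinement: lateral excursion under 3 mm even at high z
  trh <- simulate_trial(0.9, "EC")
  expect_lt(max(abs(trh$x_m)), 0.003)
})

test_that("two-state update follows the retention + error-gain recursion", {
  p <- learner_params(state_noise_sd = 0)
  st <- update_state(list(z_fast = 0.1, z_slow = 0.4), error = 0, params = p)
  expect_equal(st$z_fast, 0.092)
  expect_equal(st$z_slow, 0.3984)
})

test_that("clamp-trial errors depend on feedback as designed", {
  p <- learner_params(state_noise_sd = 0)
  # arc: no trajectory feedback, no error
  expect_equal(experienced_error("EC", "arc", z = 0.3, params = p), 0)
  # cursor: decay-driving error proportional to the state
  e_cur <- experienced_error("EC", "cursor", z = 0.3, params = p)
  expect_equal(e_cur, -0.3 * p$clamp_error_scale)
  # augmented: strictly larger error magnitude at equal state
  e_aug <- experienced_error("EC", "augmented", z = 0.3, params = p)
  expect_lt(e_aug, e_cur)
  # arc feedback: repeated clamp trials decay by retention only
  st <- list(z_fast = 0.05, z_slow = 0.2)
  st2 <- update_state(st, experienced_error("EC", "arc", 0.25, p), p)
  expect_equal(st2$z_fast, p$retention_fast * 0.05)
  expect_equal(st2$z_slow, p$retention_slow * 0.2)
})

test_that("cursor feedback drives z monotonically toward zero without noise", {
  p <- learner_params(state_noise_sd = 0)
  st <- list(z_fast = 0.06, z_slow = 0.18)
  zs <- numeric(30)
  for (i in 1:30) {
    z <- st$z_fast + st$z_slow
    zs[i] <- z
    st <- update_state(st, experienced_error("EC", "cursor", z, p), p)
  }
  expect_true(all(diff(zs) < 0))
  expect_true(all(zs > 0))
})

test_that("larger clamp error gain produces faster within-block decline", {
  run_block <- function(gain) {
    p <- learner_params(state_noise_sd = 0,
                        clamp_error_gain = c(arc = 0, cursor = gain,
                                             augmented = 2))
    st <- list(z_fast = 0.06, z_slow = 0.18)
    for (i in 1:30)
      st <- update_state(st, experienced_error("EC", "cursor",
                                               st$z_fast + st$z_slow, p), p)
    st$z_fast + st$z_slow
  }
  finals <- vapply(c(0, 0.5, 1, 1.5), run_block, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("cohorts have the configured composition and are reproducible", {
  cfg <- small_config(n_per_group = 3)
  tab1 <- simulate_cohort(cfg, seed = 5)
  expect_equal(nrow(tab1), 3 * 3 * 809)
  expect_equal(as.integer(table(tab1$group)), rep(3L * 809L, 3))
  expect_equal(dplyr::n_distinct(tab1$participant), 9)
  # same seed: byte-identical table
  tab2 <- simulate_cohort(cfg, seed = 5)
  expect_identical(tab1, tab2)
  # different seed: same schedule, different noise
  tab3 <- simulate_cohort(cfg, seed = 6)
  expect_equal(tab1[, c("global_index", "phase", "block_label")],
               tab3[, c("global_index", "phase", "block_label")],
               ignore_attr = TRUE)
  expect_false(identical(tab1$force_at_pv, tab3$force_at_pv))
})

test_that("the trajectory tier agrees with the fast tier on the readout", {
  cfg <- default_config(
    cohort = cohort_params(n_per_group = 2, groups = "cursor",
                           jitter_retention = 0, jitter_learn = 0,
                           jitter_d_field = 0),
    learner = learner_params(fpv_noise_sd = 0.3, motor_noise_sd = 0.2,
                             state_noise_sd = 0.002),
    analysis = analysis_params(subsample_k = 1))
  # truncated protocol keeps the runtime modest
  cfg$protocol <- protocol_config(fam_trials = 5, n1_null = 12, n1_iec = 2,
                                  n_ff_blocks = 2, ff_trials = 30, ff_iec = 2,
                                  n_ec_blocks = 2, ec_trials = 12, n2_null = 8)
  tab <- simulate_cohort(cfg, seed = 2, mode = "trajectory")
  expect_equal(nrow(tab), 2 * (5 + protocol_total(cfg$protocol)))
  ec <- dplyr::filter(tab, phase %in% c("EC", "IEC"), !failure_flag)
  # simulated wall readout tracks the latent state with slope ~ -g and
  # residual spread set by the configured execution noise
  fit <- stats::lm(force_at_pv ~ z_state, data = ec)
  expect_gt(stats::cor(ec$force_at_pv, -15 * ec$z_state), 0.7)
  expect_lt(abs(stats::coef(fit)[["z_state"]] + 15) / 15, 0.2)
  expect_lt(stats::sd(stats::resid(fit)), 3 * 0.3)
  ff <- dplyr::filter(tab, phase == "FF", !failure_flag)
  # adaptation reduces the rightward deviation over force-field trials
  expect_lt(stats::cor(ff$directional_error_deg, ff$z_state), 0)
})
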