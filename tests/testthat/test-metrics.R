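test_that("onset and end thresholds reproduce the ramp solution", {
  tr <- ramp_trajectory()
  # 0.15 * t / 400 = 0.0225  =>  t = 60;  = 0.1425  =>  t = 380
  expect_equal(detect_onset(tr), 60)
  expect_equal(detect_end(tr), 380)
  m <- trial_metrics(tr)
  expect_equal(m$movement_time_ms, 320)
  expect_false(m$failure_flag)
})

test_that("threshold edge cases are flagged or clamped", {
  # stationary hand: onset never crossed
  still <- ramp_trajectory()
  still$y_m <- 0; still$vy <- 0
  expect_true(is.na(detect_onset(still)))
  expect_true(trial_metrics(still)$failure_flag)
  # trajectory starting beyond the onset radius: onset at the first sample
  far <- ramp_trajectory()
  far$y_m <- far$y_m + 0.05
  expect_equal(detect_onset(far), 0)
  # stopping 1 cm short of the target: end never crossed
  short <- ramp_trajectory(t_end = 350)
  expect_true(is.na(detect_end(short)))
  expect_true(trial_metrics(short)$failure_flag)
})

test_that("directional error is the signed angle at peak velocity", {
  # onset (0,0), target (0,0.15), peak-velocity position (0.01, 0.07):
  # rightward (clockwise) deviation of atan(1/7) = +8.13 degrees
  mk <- function(px) {
    tr <- ramp_trajectory(t_end = 100)
    tr$x_m <- seq(0, px, length.out = nrow(tr))
    tr$y_m <- seq(0, 0.07, length.out = nrow(tr))
    # put peak speed at the last sample
    tr$vx <- 0; tr$vy <- 0.3; tr$vy[nrow(tr)] <- 0.5
    tr
  }
  expect_equal(directional_error(mk(0.01), onset = 0),
               atan(1 / 7) * 180 / pi, tolerance = 1e-10)
  expect_equal(directional_error(mk(0), onset = 0), 0)
  expect_equal(directional_error(mk(-0.01), onset = 0),
               -atan(1 / 7) * 180 / pi, tolerance = 1e-10)
})

test_that("directional error is antisymmetric under x-mirroring", {
  tr <- simulate_trial(0, "FF")
  onset <- detect_onset(tr)
  mirrored <- tr
  mirrored$x_m <- -tr$x_m; mirrored$vx <- -tr$vx
  expect_equal(directional_error(mirrored, onset),
               -directional_error(tr, onset), tolerance = 1e-10)
})

test_that("force at peak velocity normalizes by peak speed", {
  tr <- ramp_trajectory(wall = -3)     # constant vy = 0.375, wall -3 N
  # peak speed 0.375 m/s everywhere (first sample wins the tie)
  expect_equal(force_at_peak_velocity(tr), -3 / 0.375)
  tr0 <- ramp_trajectory(wall = 0)
  expect_equal(force_at_peak_velocity(tr0), 0)
  # non-channel trial: no wall force, readout absent
  expect_true(is.na(force_at_peak_velocity(ramp_trajectory())))
  # peak speed below the floor: unreliable, absent
  slow <- ramp_trajectory(wall = -3)
  slow$vx <- 0; slow$vy <- 0.01
  expect_true(is.na(force_at_peak_velocity(slow)))
})

test_that("success window is 350-450 ms inclusive", {
  expect_true(classify_success(400))
  expect_false(classify_success(320))
  expect_true(classify_success(350))
  expect_true(classify_success(450))
  expect_false(classify_success(451))
  expect_false(classify_success(NA_real_))
})

test_that("onset < peak velocity time <= end on simulated trials", {
  withr::with_seed(9, {
    for (ph in c("N", "FF", "EC")) {
      tr <- simulate_trial(0.3, ph, motor_noise_sd = 0.5,
                           duration_ms = 765 * runif(1, 0.9, 1.1))
      m <- trial_metrics(tr)
      expect_false(m$failure_flag)
      expect_lt(detect_onset(tr), m$t_peak_ms)
      expect_lte(m$t_peak_ms, detect_end(tr))
    }
  })
})

test_that("metrics are pure functions of the trajectory", {
  tr <- simulate_trial(0.4, "EC")
  expect_identical(trial_metrics(tr), trial_metrics(tr))
})
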