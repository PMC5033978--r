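test_that("per-participant EC series averages positions across blocks", {
  blocks <- paste0("EC", 1:9)
  mk_records <- function(values_by_block) {
    purrr::imap_dfr(values_by_block, function(v, bl)
      tibble::tibble(participant = "p1", group = "arc", phase = "EC",
                     block_label = bl, within_block_index = seq_along(v),
                     force_at_pv = v, failure_flag = FALSE))
  }
  # identical blocks: the mean is the block itself
  rec <- mk_records(setNames(rep(list(1:30), 9), blocks))
  expect_equal(ec_series(rec)$force, as.numeric(1:30))
  # blocks cancelling pairwise plus one zero block: all-zero series
  vals <- c(rep(list(1:30, -(1:30)), 4), list(rep(0, 30)))
  rec0 <- mk_records(setNames(vals, blocks))
  expect_equal(ec_series(rec0)$force, rep(0, 30))
  # brute-force oracle on randomized block values
  withr::with_seed(4, {
    vals <- replicate(9, rnorm(30), simplify = FALSE)
  })
  recr <- mk_records(setNames(vals, blocks))
  manual <- sapply(1:30, function(k) mean(sapply(vals, `[`, k)))
  expect_equal(ec_series(recr)$force, manual)
})

test_that("missing blocks and imputation are handled explicitly", {
  blocks <- paste0("EC", 1:9)
  rec <- purrr::map_dfr(blocks, function(bl)
    tibble::tibble(participant = "p1", group = "arc", phase = "EC",
                   block_label = bl, within_block_index = 1:30,
                   force_at_pv = rnorm(30), failure_flag = FALSE))
  expect_error(ec_series(dplyr::filter(rec, block_label != "EC4")),
               "p1/EC4")
  # failed trial: imputed as the same-position mean of the other blocks
  rec2 <- rec
  i <- which(rec2$block_label == "EC3" & rec2$within_block_index == 7)
  rec2$failure_flag[i] <- TRUE
  s <- ec_series(rec2)
  others <- rec$force_at_pv[rec$within_block_index == 7 &
                              rec$block_label != "EC3"]
  expect_equal(s$force[s$position == 7], mean(others))
  expect_equal(attr(s, "n_imputed"), 1L)
})

test_that("exponential fit recovers noiseless generating parameters", {
  f <- fit_exponential(exp_series(2, -0.3, 1))
  expect_equal(c(f$a, f$b, f$c), c(2, -0.3, 1), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_true(f$converged)
  expect_equal(f$initial_state, f$a + f$c)
  # the published cursor-group rate used as generator input
  f2 <- fit_exponential(exp_series(-5, -0.26, 1))
  expect_lt(abs(f2$b + 0.26), 1e-6)
})

test_that("constant series is degenerate but well-defined", {
  f <- fit_exponential(rep(4, 30))
  expect_equal(f$a, 0)
  expect_equal(f$c, 4)
  expect_false(f$converged)
  expect_lte(f$r2, 1)
})

test_that("fit agrees with an independent Levenberg-Marquardt route", {
  skip_if_not_installed("minpack.lm")
  withr::with_seed(21, {
    y <- exp_series(-4, -0.2, -1) + rnorm(30, 0, 0.3)
  })
  ours <- fit_exponential(y)
  x <- 1:30
  ref <- minpack.lm::nlsLM(y ~ a * exp(b * x) + c,
                           start = list(a = ours$a * 1.3, b = ours$b * 0.7,
                                        c = ours$c + 0.5))
  est <- coef(ref)
  expect_equal(ours$a, unname(est["a"]), tolerance = 1e-5)
  expect_equal(ours$b, unname(est["b"]), tolerance = 1e-5)
  expect_equal(ours$c, unname(est["c"]), tolerance = 1e-5)
  # our profiled residual is at least as small
  expect_lte(ours$ss_res, sum(residuals(ref)^2) + 1e-10)
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_exponential(exp_series(2, -0.3, 1))
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate[td$term == "initial_state"], 3, tolerance = 1e-7)
  gl <- glance(f)
  expect_named(gl, c("r.squared", "ss_res", "n", "converged"))
})

test_that("subset enumeration is exhaustive and lexicographic", {
  expect_equal(nrow(enumerate_subsamples(4, 3)), 4)
  expect_equal(nrow(enumerate_subsamples(15, 12)), 455)
  expect_equal(enumerate_subsamples(5, 5), matrix(1:5, 1))
  expect_error(enumerate_subsamples(3, 4), "exceed")
  # spot-check against the independent recursive generator
  got <- enumerate_subsamples(6, 3)
  oracle <- recursive_subsets(6, 3)
  expect_equal(nrow(got), length(oracle))
  expect_equal(lapply(seq_len(nrow(got)), function(i) got[i, ]), oracle)
})

test_that("subsample fits behave on degenerate group structures", {
  base <- exp_series(-3, -0.2, -0.5)
  m <- matrix(rep(base, each = 15), nrow = 15)
  fits <- subsample_fits(m, k = 12)
  expect_equal(nrow(fits), 455)
  expect_equal(unique(round(fits$b, 10)), -0.2)
  expect_equal(unique(round(fits$a, 10)), -3)
  # k = n: the single subset is the grand average
  f1 <- subsample_fits(m, k = 15)
  expect_equal(nrow(f1), 1)
  grand <- fit_exponential(colMeans(m))
  expect_equal(unname(f1$b), grand$b, tolerance = 1e-10)
})

test_that("mean subset rate tracks the grand-average rate on noisy data", {
  withr::with_seed(31, {
    m <- synth_group(15, a = -3, b = -0.2, c = -0.5, sd_noise = 0.2)
  })
  fits <- subsample_fits(m, k = 12)
  grand <- fit_exponential(colMeans(m))
  expect_lt(abs(mean(fits$b) - grand$b), 0.02)
})

test_that("permutation differences are exchangeable-null centered", {
  base <- exp_series(-3, -0.2, -0.5)
  m <- matrix(rep(base, each = 12), nrow = 12)
  # identical pooled series: any relabeling gives exactly zero differences
  withr::with_seed(7, {
    d <- permutation_difference(m, m)
  })
  expect_equal(unname(d), c(0, 0, 0))
  # determinism under a fixed seed
  withr::with_seed(3, {
    ma <- synth_group(12, -3, -0.2, -0.5)
    mb <- synth_group(12, -3, -0.2, -0.5)
  })
  d1 <- withr::with_seed(5, permutation_difference(ma, mb))
  d2 <- withr::with_seed(5, permutation_difference(ma, mb))
  expect_identical(d1, d2)
  # null generator: permutation distribution of the rate difference is
  # centered at zero within Monte-Carlo error
  withr::with_seed(13, {
    ga <- synth_group(15, -3, -0.2, -0.5)
    gb <- synth_group(15, -3, -0.2, -0.5)
  })
  cmp <- compare_decay(series_tbl_from_matrices(ga, gb), "A", "B", seed = 17)
  mc_err <- 3 * stats::sd(cmp$perm$b) / sqrt(nrow(cmp$perm))
  expect_lt(abs(mean(cmp$perm$b)), mc_err)
})

test_that("comparing a group against its copy is null by construction", {
  withr::with_seed(23, {
    ga <- synth_group(15, -3, -0.2, -0.5)
  })
  cmp <- compare_decay(series_tbl_from_matrices(ga, ga), "A", "B", seed = 2)
  expect_equal(unname(cmp$mean_diff), c(0, 0, 0), tolerance = 1e-12)
  expect_true(all(cmp$p > 0.9))
  expect_equal(cmp$n_iter, 455)
  # p values are proportions over the iteration count
  expect_true(all(abs(cmp$p * 455 - round(cmp$p * 455)) < 1e-9))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})

test_that("the published arc/cursor rates are distinguished by the procedure", {
  # groups generated at the two printed decay rates with modest noise
  withr::with_seed(41, {
    ga <- synth_group(15, a = -2.5, b = -0.08, c = -1.5, sd_noise = 0.15,
                      sd_b = 0.02)
    gb <- synth_group(15, a = -2.5, b = -0.26, c = -0.7, sd_noise = 0.15,
                      sd_b = 0.02)
  })
  cmp <- compare_decay(series_tbl_from_matrices(ga, gb), "A", "B", seed = 8)
  expect_lt(cmp$p[["b"]], 0.05)
  # signs: arc minus cursor rate difference is positive (arc less negative)
  expect_gt(cmp$mean_diff[["b"]], 0)
})

test_that("one-sided rule is available as the configurable alternative", {
  withr::with_seed(51, {
    ga <- synth_group(12, -3, -0.1, -1)
    gb <- synth_group(12, -3, -0.3, -0.5)
  })
  tb <- series_tbl_from_matrices(ga, gb)
  two <- compare_decay(tb, "A", "B", k = 10, seed = 3, tail = "absolute")
  one <- compare_decay(tb, "A", "B", k = 10, seed = 3, tail = "greater")
  expect_identical(two$mean_diff, one$mean_diff)
  expect_false(identical(two$p, one$p))
})
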