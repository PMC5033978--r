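# Independent oracles and fixture builders used across the suite.

# Brute-force recursive subset generator (lexicographic), independent of the
# implementation's enumeration.
recursive_subsets <- function(n, k, start = 1) {
  if (k == 0) return(list(integer(0)))
  if (start > n) return(list())
  out <- list()
  for (i in start:n) {
    for (rest in recursive_subsets(n, k - 1, i + 1)) {
      out[[length(out) + 1]] <- c(i, rest)
    }
  }
  out
}

# Noiseless single-exponential series.
exp_series <- function(a, b, c, n = 30) a * exp(b * seq_len(n)) + c

# Minimal hand-built trajectory: straight ramp y(t) = 0.15 * t / 400 m at
# constant velocity, sampled at 1 kHz. `wall` optionally sets a constant
# wall force (channel trial).
ramp_trajectory <- function(t_end = 420, wall = NA_real_) {
  t_ms <- seq(0, t_end)
  out <- tibble::tibble(
    t_ms = t_ms,
    x_m = 0, y_m = 0.15 * t_ms / 400,
    vx = 0, vy = 0.15 / 0.4,
    fx_env = 0, fy_env = 0,
    wall_force_n = wall)
  structure(out, class = c("reach_trajectory", class(out)),
            phase = if (is.na(wall)) "N" else "EC", failed = FALSE)
}

# Small cohort configuration for quick pipeline tests.
small_config <- function(n_per_group = 5, groups = c("arc", "cursor", "augmented")) {
  default_config(
    cohort = cohort_params(n_per_group = n_per_group, groups = groups),
    analysis = analysis_params(subsample_k = n_per_group - 1))
}

# Synthetic group of decay series with participant-level variability around
# generating parameters (a, b, c).
synth_group <- function(n = 15, a, b, c, len = 30, sd_noise = 0.15,
                        sd_b = 0.02) {
  t(sapply(seq_len(n), function(i) {
    bi <- b + rnorm(1, 0, sd_b)
    a * exp(bi * seq_len(len)) + c + rnorm(len, 0, sd_noise)
  }))
}

# Matrix -> ec_series-shaped tibble for two groups.
series_tbl_from_matrices <- function(ma, mb, ga = "A", gb = "B") {
  as_tbl <- function(m, g) {
    purrr::map_dfr(seq_len(nrow(m)), function(i)
      tibble::tibble(participant = sprintf("%s_%02d", g, i), group = g,
                     position = seq_len(ncol(m)), force = m[i, ]))
  }
  dplyr::bind_rows(as_tbl(ma, ga), as_tbl(mb, gb))
}
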