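# Profiled least squares for y = a * exp(b x) + c: for fixed b the problem is
# linear in (a, c) and solved in closed form; b is located on a deterministic
# coarse grid, refined by Brent search, then the full 3-parameter problem is
# polished with damped Gauss-Newton. Deterministic throughout.
.exp_linpars <- function(y, E) {
  n <- length(y)
  Se <- sum(E); See <- sum(E * E); Sy <- sum(y); Sey <- sum(E * y)
  den <- n * See - Se * Se
  if (!is.finite(den) || abs(den) < 1e-300 * (1 + See * n))
    return(c(a = 0, c = mean(y)))
  a <- (n * Sey - Se * Sy) / den
  c(a = a, c = (Sy - a * Se) / n)
}

.exp_ss <- function(b, y, x) {
  E <- exp(b * x)
  if (any(!is.finite(E))) return(Inf)
  p <- .exp_linpars(y, E)
  sum((y - p[1] * E - p[2])^2)
}

.fit_exp_core <- function(y, x, b_bounds = c(-5, 0.5), grid_n = 61L) {
  n <- length(y)
  sy_tot <- sum((y - mean(y))^2)
  if (sy_tot < 1e-12 * (1 + mean(y)^2)) {   # constant series: b unidentifiable
    return(list(a = 0, b = 0, c = mean(y), ss_res = sum((y - mean(y))^2),
                ss_tot = sy_tot, r2 = 1, converged = FALSE))
  }
  grid <- seq(b_bounds[1], b_bounds[2], length.out = grid_n)
  Em <- exp(outer(x, grid))                  # n x grid_n
  Se <- colSums(Em); See <- colSums(Em * Em)
  Sy <- sum(y); Sey <- colSums(Em * y)
  den <- n * See - Se * Se
  a_g <- ifelse(abs(den) < 1e-300, 0, (n * Sey - Se * Sy) / den)
  c_g <- (Sy - a_g * Se) / n
  ss_g <- colSums((y - sweep(Em, 2, a_g, "*") - matrix(c_g, n, grid_n, byrow = TRUE))^2)
  i <- which.min(ss_g)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, grid_n)]
  b <- if (lo < hi)
    optimize(.exp_ss, c(lo, hi), y = y, x = x, tol = 1e-10)$minimum
  else grid[i]
  E <- exp(b * x); p <- .exp_linpars(y, E)
  theta <- c(p[["a"]], b, p[["c"]])
  ss <- sum((y - theta[1] * E - theta[3])^2)
  # Gauss-Newton polish with Levenberg damping
  lambda <- 1e-8; converged <- FALSE
  for (it in seq_len(60)) {
    E <- exp(theta[2] * x)
    r <- y - theta[1] * E - theta[3]
    J <- cbind(E, theta[1] * x * E, 1)
    A <- crossprod(J) + lambda * diag(3)
    step <- tryCatch(solve(A, crossprod(J, r)), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta + as.numeric(step)
    cand[2] <- min(max(cand[2], b_bounds[1]), b_bounds[2])
    Ec <- exp(cand[2] * x)
    ss_new <- sum((y - cand[1] * Ec - cand[3])^2)
    if (is.finite(ss_new) && ss_new <= ss) {
      improved <- (ss - ss_new) <= 1e-10 * (1 + ss)
      theta <- cand; ss <- ss_new
      lambda <- max(lambda / 4, 1e-12)
      if (improved) { converged <- TRUE; break }
    } else {
      lambda <- lambda * 8
      if (lambda > 1e6) break
    }
  }
  list(a = theta[1], b = theta[2], c = theta[3], ss_res = ss, ss_tot = sy_tot,
       r2 = 1 - ss / sy_tot, converged = converged)
}

#' Fit a single-exponential decay model
#'
#' Least-squares fit of `y = a * exp(b * x) + c` to an error-clamp series.
#' The linear parameters (a, c) are profiled out exactly for any candidate
#' decay rate b, which is located on a deterministic grid over `b_bounds`,
#' refined by Brent search and a damped Gauss-Newton polish — so the result
#' is deterministic and recovers noiseless model data to machine precision.
#' `x` is the 1-based trial position within the series.
#'
#' @param y Numeric series (force at peak velocity, N.s/m; typically the
#'   30-trial average across the nine post-adaptation error-clamp blocks).
#' @param x Trial positions (default `1:length(y)`).
#' @param b_bounds Search interval for the decay rate b.
#' @return An object of class `decay_fit`: a list with `a` (amplitude), `b`
#'   (decay rate per trial), `c` (asymptote), `initial_state` (`a + c`),
#'   `r2`, `converged`, `ss_res`, `n`, and the data. A constant series is
#'   degenerate: `a = 0`, `c = mean(y)`, `b` pinned at 0 with
#'   `converged = FALSE`.
#' @export
#' @examples
#' x <- 1:30
#' f <- fit_exponential(2 * exp(-0.3 * x) + 1)
#' tidy(f)
fit_exponential <- function(y, x = seq_along(y), b_bounds = c(-5, 0.5)) {
  stopifnot(length(y) == length(x), all(is.finite(y)), all(is.finite(x)))
  if (length(y) < 4) abort("at least 4 points are required to fit a + b + c")
  core <- .fit_exp_core(as.numeric(y), as.numeric(x), b_bounds)
  structure(c(core,
              list(initial_state = core$a + core$c, n = length(y),
                   x = as.numeric(x), y = as.numeric(y))),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Single-exponential decay fit: y = a*exp(b*x) + c\n")
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g  (initial state a+c = %.4g)\n",
              x$a, x$b, x$c, x$initial_state))
  cat(sprintf("  r^2 = %.4f on %d points; converged: %s\n",
              x$r2, x$n, x$converged))
  invisible(x)
}

#' @rdname fit_exponential
#' @param object,... A `decay_fit`; further arguments are ignored.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "initial_state"),
                 estimate = c(x$a, x$b, x$c, x$initial_state))
}

#' @rdname fit_exponential
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, ss_res = x$ss_res, n = x$n,
                 converged = x$converged)
}

#' @export
predict.decay_fit <- function(object, x = object$x, ...) {
  object$a * exp(object$b * x) + object$c
}

#' Per-participant error-clamp decay series
#'
#' For each participant, averages the force at peak velocity at each
#' within-block trial position across the listed error-clamp blocks,
#' producing the 30-point series the exponential model is fitted to.
#' Missing or failed trials are imputed with the mean of the same
#' within-block position across the remaining blocks; the number of imputed
#' values is recorded in the `n_imputed` attribute.
#'
#' @param records Trial table (see [simulate_cohort()] or the CSV interface);
#'   must contain `participant`, `group`, `phase`, `block_label`,
#'   `within_block_index`, `force_at_pv`.
#' @param blocks Block labels to average over (default EC1-EC9).
#' @return Tibble with columns `participant`, `group`, `position`, `force`.
#' @export
ec_series <- function(records, blocks = paste0("EC", 1:9)) {
  ec <- dplyr::filter(records, .data$phase == "EC",
                      .data$block_label %in% blocks)
  have <- ec |> dplyr::distinct(.data$participant, .data$block_label)
  miss <- tidyr::expand_grid(participant = unique(records$participant),
                             block_label = blocks) |>
    dplyr::anti_join(have, by = c("participant", "block_label"))
  if (nrow(miss) > 0)
    abort(sprintf("missing EC block(s): %s",
                  paste(miss$participant, miss$block_label, sep = "/",
                        collapse = ", ")))
  n_imputed <- sum(is.na(ec$force_at_pv) | ec$failure_flag)
  out <- ec |>
    dplyr::mutate(force_at_pv = ifelse(.data$failure_flag, NA_real_,
                                       .data$force_at_pv)) |>
    dplyr::group_by(.data$participant, .data$group,
                    position = .data$within_block_index) |>
    dplyr::summarise(force = mean(.data$force_at_pv, na.rm = TRUE),
                     .groups = "drop")
  if (any(!is.finite(out$force)))
    abort("a within-block position has no usable trials in any block")
  attr(out, "n_imputed") <- n_imputed
  out
}

# participants x positions matrix for one group
series_matrix <- function(series, group = NULL) {
  s <- if (is.null(group)) series else dplyr::filter(series, .data$group == !!group)
  wide <- tidyr::pivot_wider(s[, c("participant", "position", "force")],
                             names_from = "position", values_from = "force")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$participant
  m[, order(as.integer(colnames(m))), drop = FALSE]
}

#' Enumerate all size-k subsets
#'
#' All `choose(n, k)` distinct subsets of `1:n`, in lexicographic order, with
#' no randomness — the exhaustive enumeration underlying the subsampling
#' bootstrap (455 subsets for 12 of 15 participants).
#'
#' @param n Group size.
#' @param k Subset size.
#' @return Integer matrix with one row per subset, `k` columns.
#' @export
#' @examples
#' nrow(enumerate_subsamples(15, 12))  # 455
enumerate_subsamples <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k > n) abort("`k` must not exceed `n`")
  if (k < 1) abort("`k` must be at least 1")
  t(combn(n, k))
}

#' Exponential fits over all subsamples of a group
#'
#' For every enumerated subset of `k` participants, averages the member
#' series pointwise and fits the single-exponential decay model to the
#' average; rows follow the enumeration order of [enumerate_subsamples()].
#'
#' @param series Either the tibble returned by [ec_series()] (optionally
#'   filtered to one group) or a participants x positions numeric matrix.
#' @param k Subset size (default 12).
#' @param subsets Optional subset matrix (rows of participant indices); by
#'   default all `choose(n, k)` subsets.
#' @param b_bounds Decay-rate search interval.
#' @return Tibble with `subset_id`, `a`, `b`, `c`, `initial_state`, `r2`,
#'   `converged`.
#' @export
subsample_fits <- function(series, k = 12, subsets = NULL,
                           b_bounds = c(-5, 0.5)) {
  m <- if (is.matrix(series)) series else series_matrix(series)
  if (is.null(subsets)) subsets <- enumerate_subsamples(nrow(m), k)
  x <- seq_len(ncol(m))
  fits <- vapply(seq_len(nrow(subsets)), function(i) {
    f <- .fit_exp_core(colMeans(m[subsets[i, ], , drop = FALSE]), x, b_bounds)
    c(f$a, f$b, f$c, f$r2, as.numeric(f$converged))
  }, numeric(5))
  tibble::tibble(subset_id = seq_len(ncol(fits)),
                 a = fits[1, ], b = fits[2, ], c = fits[3, ],
                 initial_state = fits[1, ] + fits[3, ],
                 r2 = fits[4, ], converged = fits[5, ] == 1)
}

#' One permutation difference for a pooled pair of subsets
#'
#' Randomly relabels the pooled participants of one bootstrap iteration into
#' two pseudo-groups of the original sizes, fits the average series of each,
#' and returns the parameter differences (A minus B). Uses the current RNG
#' state.
#'
#' @param series_a,series_b Numeric matrices (participants x positions) of
#'   the two selected subsets.
#' @param b_bounds Decay-rate search interval.
#' @return Named numeric vector with `initial_state`, `b`, `c` differences.
#' @export
permutation_difference <- function(series_a, series_b, b_bounds = c(-5, 0.5)) {
  pool <- rbind(series_a, series_b)
  na <- nrow(series_a)
  idx <- sample.int(nrow(pool))
  x <- seq_len(ncol(pool))
  fa <- .fit_exp_core(colMeans(pool[idx[seq_len(na)], , drop = FALSE]), x, b_bounds)
  fb <- .fit_exp_core(colMeans(pool[idx[-seq_len(na)], , drop = FALSE]), x, b_bounds)
  c(initial_state = (fa$a + fa$c) - (fb$a + fb$c),
    b = fa$b - fb$b, c = fa$c - fb$c)
}

#' Compare decay parameters between two groups
#'
#' The full decay-rate comparison procedure: enumerate all `choose(n, k)`
#' subsets of each group (455 for 12 of 15), pair subset i of group A with
#' subset i of group B, fit the single-exponential model to each subset's
#' average 30-trial series, and take per-iteration parameter differences
#' (bootstrap distribution). On each iteration, the 24 selected participants
#' are additionally relabeled at random into two pseudo-groups and refitted
#' (permutation distribution). The p-value per parameter is the proportion of
#' permutation differences larger than the mean bootstrap difference —
#' compared on absolute values by default (`tail = "absolute"`), or literally
#' one-sided with `tail = "greater"`.
#'
#' @param series The [ec_series()] tibble covering both groups.
#' @param group_a,group_b Group labels to compare (differences are A minus B).
#' @param k Subset size (default 12).
#' @param seed Seed for the permutation relabelings (and subset thinning).
#' @param max_subsets Optionally run only this many iterations, sampled
#'   without replacement from the enumerated subsets (for replicated
#'   calibration studies); `NULL` runs all.
#' @param tail `"absolute"` or `"greater"`.
#' @param b_bounds Decay-rate search interval.
#' @return Object of class `decay_comparison`: a list with the pair, subset
#'   bookkeeping, per-iteration `boot` and `perm` difference tibbles,
#'   `mean_diff`, and `p` (each over `initial_state`, `b`, `c`).
#' @export
compare_decay <- function(series, group_a, group_b, k = 12, seed = 1,
                          max_subsets = NULL, tail = c("absolute", "greater"),
                          b_bounds = c(-5, 0.5)) {
  tail <- match.arg(tail)
  ma <- series_matrix(series, group_a)
  mb <- series_matrix(series, group_b)
  if (ncol(ma) != ncol(mb)) abort("both groups must share the series length")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sa <- enumerate_subsamples(nrow(ma), k)
  sb <- enumerate_subsamples(nrow(mb), k)
  n_iter <- min(nrow(sa), nrow(sb))
  iter_idx <- seq_len(n_iter)
  if (!is.null(max_subsets) && max_subsets < n_iter)
    iter_idx <- sort(sample.int(n_iter, max_subsets))
  x <- seq_len(ncol(ma))
  boot <- matrix(NA_real_, length(iter_idx), 3,
                 dimnames = list(NULL, c("initial_state", "b", "c")))
  perm <- boot
  for (ii in seq_along(iter_idx)) {
    i <- iter_idx[ii]
    suba <- ma[sa[i, ], , drop = FALSE]
    subb <- mb[sb[i, ], , drop = FALSE]
    fa <- .fit_exp_core(colMeans(suba), x, b_bounds)
    fb <- .fit_exp_core(colMeans(subb), x, b_bounds)
    boot[ii, ] <- c((fa$a + fa$c) - (fb$a + fb$c), fa$b - fb$b, fa$c - fb$c)
    perm[ii, ] <- permutation_difference(suba, subb, b_bounds)
  }
  mean_diff <- colMeans(boot)
  p <- if (tail == "absolute")
    colMeans(abs(perm) > matrix(abs(mean_diff), nrow(perm), 3, byrow = TRUE))
  else
    colMeans(perm > matrix(mean_diff, nrow(perm), 3, byrow = TRUE))
  structure(list(pair = c(group_a, group_b), k = k,
                 n_subsets_a = nrow(sa), n_subsets_b = nrow(sb),
                 n_iter = length(iter_idx), tail = tail, seed = seed,
                 boot = tibble::as_tibble(boot), perm = tibble::as_tibble(perm),
                 mean_diff = mean_diff, p = p),
            class = "decay_comparison")
}

#' @export
print.decay_comparison <- function(x, ...) {
  cat(sprintf("Decay comparison: %s vs %s (%d iterations, k = %d, %s tail)\n",
              x$pair[1], x$pair[2], x$n_iter, x$k, x$tail))
  print(tidy(x))
  invisible(x)
}

#' @rdname compare_decay
#' @param x A `decay_comparison`; `...` ignored.
#' @exportS3Method generics::tidy
tidy.decay_comparison <- function(x, ...) {
  tibble::tibble(parameter = names(x$mean_diff),
                 mean_diff = unname(x$mean_diff),
                 p = unname(x$p))
}

#' @rdname compare_decay
#' @param object A `decay_comparison`.
#' @exportS3Method generics::glance
glance.decay_comparison <- function(x, ...) {
  tibble::tibble(group_a = x$pair[1], group_b = x$pair[2], k = x$k,
                 n_iter = x$n_iter, tail = x$tail)
}

#' Full decay analysis over all group pairs
#'
#' Builds the per-participant series, the per-group subsample fit
#' distributions, and every pairwise group comparison.
#'
#' @param records Trial table (see [simulate_cohort()]).
#' @param k Subset size.
#' @param seed Seed passed to each comparison (offset per pair).
#' @param blocks Error-clamp blocks averaged into the series.
#' @param max_subsets,tail,b_bounds Passed to [compare_decay()].
#' @return List with `series`, `group_fits` (tibble with a `group` column),
#'   and `comparisons` (named list of `decay_comparison`).
#' @export
decay_analysis <- function(records, k = 12, seed = 1,
                           blocks = paste0("EC", 1:9), max_subsets = NULL,
                           tail = "absolute", b_bounds = c(-5, 0.5)) {
  series <- ec_series(records, blocks)
  groups <- unique(series$group)
  group_fits <- purrr::map_dfr(groups, function(g) {
    dplyr::mutate(subsample_fits(series_matrix(series, g), k = k,
                                 b_bounds = b_bounds),
                  group = g, .before = 1)
  })
  pairs <- combn(groups, 2, simplify = FALSE)
  comparisons <- purrr::map(seq_along(pairs), function(i) {
    compare_decay(series, pairs[[i]][1], pairs[[i]][2], k = k,
                  seed = derive_seed(seed, i), max_subsets = max_subsets,
                  tail = tail, b_bounds = b_bounds)
  })
  names(comparisons) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  list(series = series, group_fits = group_fits, comparisons = comparisons)
}
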