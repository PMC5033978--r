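#' Mean of the first or last bin of a block
#'
#' @param values Metric values in within-block trial order.
#' @param bin_size Trials per bin (6 for block entry/end summaries, 3 for the
#'   initial-three-trials summary).
#' @param which `"first"` or `"last"`.
#' @return Mean of the selected bin.
#' @export
#' @examples
#' block_bins(1:30, 6, "first")  # 3.5
block_bins <- function(values, bin_size = 6, which = c("first", "last")) {
  which <- match.arg(which)
  values <- values[!is.na(values)]
  if (length(values) < bin_size)
    abort(sprintf("block has %d usable trials, need at least %d",
                  length(values), bin_size))
  if (which == "first") mean(values[seq_len(bin_size)])
  else mean(values[seq.int(length(values) - bin_size + 1, length(values))])
}

#' Within-block probability of success
#'
#' Successful trials divided by non-failed trials.
#'
#' @param success Logical vector of per-trial success.
#' @param failure_flag Logical vector marking failed trials (excluded).
#' @return Proportion in `[0, 1]`.
#' @export
success_probability <- function(success, failure_flag = rep(FALSE, length(success))) {
  keep <- !failure_flag & !is.na(success)
  if (!any(keep)) abort("no non-failed trials in this block")
  mean(success[keep])
}

#' Within-block exploratory variance
#'
#' Unbiased (n - 1) sample variance of a metric within one block; used as the
#' index of exploratory behavior for the directional angle in force-field
#' blocks and the force at peak velocity in error-clamp blocks.
#'
#' @param x Metric values within the block.
#' @return Sample variance.
#' @export
exploratory_variance <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) abort("at least 2 usable trials are required")
  var(x)
}

#' Per-participant block summaries
#'
#' Descriptive quantities per participant and block: means of the directional
#' error (signed and absolute, field/null trials only — interspersed clamp
#' trials are channel trials and are excluded), movement time, and force at
#' peak velocity (channel trials only); first/last six-trial bin means and
#' the initial three-trial mean of the block's primary metric; the
#' within-block probability of success; and the within-block variances of the
#' directional error and the force at peak velocity.
#'
#' @param records Trial table (see [simulate_cohort()]).
#' @param bin_size Trials per bin for the entry/end summaries.
#' @return Tibble with one row per participant x block, in block order.
#' @export
summarize_blocks <- function(records, bin_size = 6) {
  safe <- function(f, x, ...) if (sum(!is.na(x)) >= 1) tryCatch(f(x, ...), error = function(e) NA_real_) else NA_real_
  records |>
    dplyr::filter(!.data$failure_flag) |>
    dplyr::arrange(.data$participant, .data$global_index) |>
    dplyr::group_by(.data$participant, .data$group, .data$block_label) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_directional_error = mean(.data$directional_error_deg[
        !.data$phase %in% c("EC", "IEC")], na.rm = TRUE),
      mean_abs_directional_error = mean(abs(.data$directional_error_deg[
        !.data$phase %in% c("EC", "IEC")]), na.rm = TRUE),
      mean_movement_time = mean(.data$movement_time_ms, na.rm = TRUE),
      mean_force_at_pv = mean(.data$force_at_pv, na.rm = TRUE),
      de_first_bin = safe(block_bins, .data$directional_error_deg[
        !.data$phase %in% c("EC", "IEC")], bin_size, "first"),
      de_last_bin = safe(block_bins, .data$directional_error_deg[
        !.data$phase %in% c("EC", "IEC")], bin_size, "last"),
      fpv_first_bin = safe(block_bins, .data$force_at_pv, bin_size, "first"),
      fpv_last_bin = safe(block_bins, .data$force_at_pv, bin_size, "last"),
      fpv_first3 = safe(block_bins, .data$force_at_pv, 3, "first"),
      p_success = success_probability(.data$success),
      var_directional_error = safe(exploratory_variance,
                                   .data$directional_error_deg[
                                     !.data$phase %in% c("EC", "IEC")]),
      var_force_at_pv = safe(exploratory_variance, .data$force_at_pv),
      .groups = "drop")
}

#' Group-level block summaries
#'
#' Averages the per-participant block summaries within each group (each
#' quantity is computed per participant first, then averaged).
#'
#' @param block_summaries Output of [summarize_blocks()].
#' @return Tibble with one row per group x block.
#' @export
group_block_summary <- function(block_summaries) {
  block_summaries |>
    dplyr::group_by(.data$group, .data$block_label) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_participants = dplyr::n(), .groups = "drop")
}

#' Long-format export of block summaries
#'
#' Tidy long table (`group`, `participant`, `block_label`, `measure`,
#' `value`) for direct ingestion by external statistics software.
#'
#' @param block_summaries Output of [summarize_blocks()].
#' @return Long tibble.
#' @export
summary_long <- function(block_summaries) {
  tidyr::pivot_longer(block_summaries,
                      cols = -c("participant", "group", "block_label"),
                      names_to = "measure", values_to = "value")
}
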