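#' Run the full pipeline: simulate, extract, summarize, fit, compare
#'
#' Executes the end-to-end analysis: cohort simulation, per-trial metrics,
#' block summaries, per-participant decay series, subsample fit
#' distributions, and every pairwise group comparison (three for the default
#' three-condition cohort). With `out_dir` set, the report bundle is also
#' written to disk: trial table, block summaries (wide and long), subsample
#' fits, comparison samples and a JSON fit report, plus the configuration
#' echo and a run log.
#'
#' @param config A [default_config()].
#' @param seed Master seed.
#' @param mode Cohort fidelity tier: `"fast"` (metric-level) or
#'   `"trajectory"` (full 1 kHz simulation).
#' @param out_dir Optional output directory (created if missing).
#' @param max_subsets Optionally thin the bootstrap iterations (see
#'   [compare_decay()]).
#' @return (Invisibly) a list: `records`, `block_summaries`, `group_summary`,
#'   `analysis` (see [decay_analysis()]), `fit_report`, `config`, `seed`.
#' @export
#' @examples
#' \donttest{
#' cfg <- default_config(cohort = cohort_params(n_per_group = 5))
#' res <- run_pipeline(cfg, seed = 1, max_subsets = 5)
#' res$fit_report$comparisons
#' }
run_pipeline <- function(config = default_config(), seed = 1,
                         mode = c("fast", "trajectory"), out_dir = NULL,
                         max_subsets = NULL) {
  mode <- match.arg(mode)
  viol <- validate_config(config)
  if (nrow(viol) > 0)
    abort(paste0("stage config: invalid configuration: ",
                 paste(viol$key, viol$rule, sep = " - ", collapse = "; ")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage %s: %s", name, conditionMessage(e))))
  }
  records <- stage("simulate", simulate_cohort(config, seed = seed, mode = mode))
  block_summaries <- stage("summaries", summarize_blocks(records,
                                                         config$analysis$bin_size))
  group_summary <- stage("summaries", group_block_summary(block_summaries))
  analysis <- stage("decayfit", decay_analysis(
    records, k = config$analysis$subsample_k, seed = seed,
    blocks = config$analysis$ec_blocks, max_subsets = max_subsets,
    tail = config$analysis$tail, b_bounds = config$analysis$b_bounds))

  group_stats <- analysis$group_fits |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(c("a", "b", "c", "initial_state"),
                                   list(mean = mean, sd = sd)),
                     r2_min = min(.data$r2), r2_mean = mean(.data$r2),
                     n_subsets = dplyr::n(), .groups = "drop")
  comparisons <- purrr::map_dfr(analysis$comparisons, function(cmp) {
    dplyr::mutate(tidy(cmp), pair = paste(cmp$pair, collapse = " vs "),
                  n_iter = cmp$n_iter, .before = 1)
  })
  fit_report <- list(groups = group_stats, comparisons = comparisons,
                     n_imputed = attr(analysis$series, "n_imputed") %||% 0L)

  out <- list(records = records, block_summaries = block_summaries,
              group_summary = group_summary, analysis = analysis,
              fit_report = fit_report, config = config, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(records, file.path(out_dir, "trials.csv"))
    readr::write_csv(block_summaries, file.path(out_dir, "block_summaries.csv"))
    readr::write_csv(summary_long(block_summaries),
                     file.path(out_dir, "block_summaries_long.csv"))
    readr::write_csv(analysis$group_fits, file.path(out_dir, "subsample_fits.csv"))
    readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
    samples <- purrr::imap_dfr(analysis$comparisons, function(cmp, nm) {
      dplyr::bind_rows(dplyr::mutate(cmp$boot, kind = "bootstrap"),
                       dplyr::mutate(cmp$perm, kind = "permutation")) |>
        dplyr::mutate(pair = nm, .before = 1)
    })
    readr::write_csv(samples, file.path(out_dir, "difference_samples.csv"))
    jsonlite::write_json(
      list(groups = group_stats, comparisons = comparisons,
           n_imputed = fit_report$n_imputed,
           config_digest = config_digest(unclass(config)), seed = seed),
      file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(c(sprintf("clampdecay %s", as.character(utils::packageVersion("clampdecay"))),
                 sprintf("seed: %d", as.integer(seed)),
                 sprintf("mode: %s", mode),
                 sprintf("config_digest: %s", config_digest(unclass(config))),
                 sprintf("R: %s", R.version.string)),
               file.path(out_dir, "run_log.txt"))
  }
  invisible(out)
}
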