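#' Place interspersed error-clamp trials within a host block
#'
#' Draws the within-block positions of the IEC probes for one null-field or
#' force-field block. Positions are unique, sorted, and never in the first
#' `lead_in - 1` trials of the block, so that behavior at block entry is
#' driven by the field. Uses the current RNG state: seed upstream for
#' reproducibility.
#'
#' @param host_block_length Total trials in the host block (field + IEC).
#' @param n_iec Number of interspersed error-clamp trials.
#' @param lead_in Earliest admissible position (default 4).
#' @return Sorted integer vector of within-block positions.
#' @export
#' @examples
#' set.seed(1); place_iec(20, 2)
place_iec <- function(host_block_length, n_iec, lead_in = 4) {
  host_block_length <- as.integer(host_block_length)
  n_iec <- as.integer(n_iec)
  if (n_iec == 0) return(integer(0))
  if (n_iec >= host_block_length)
    abort("`n_iec` must be smaller than `host_block_length`.")
  slots <- seq.int(lead_in, host_block_length)
  if (n_iec > length(slots))
    abort(sprintf("cannot place %d IEC trials in %d admissible positions",
                  n_iec, length(slots)))
  sort(sample(slots, n_iec))
}

block_phases <- function(base_phase, n_base, iec_pos) {
  len <- n_base + length(iec_pos)
  ph <- rep(base_phase, len)
  ph[iec_pos] <- "IEC"
  ph
}

#' Build the default trial schedule
#'
#' Assembles the full experiment plan: familiarization, baseline null block
#' N1 (with interspersed error-clamp probes), alternating force-field and
#' assessment error-clamp blocks (FF1, EC1, ..., FF9, EC9, FF10), a null
#' washout block N2, and the recall probe EC10 immediately after washout.
#'
#' @param config A [protocol_config()].
#' @param seed Integer seed controlling IEC placement (the only randomness).
#' @param expected_total Optional check: if supplied and the configured counts
#'   do not sum to it (post-familiarization), construction fails with an error
#'   naming the discrepancy.
#' @return A tibble of class `ec_schedule` with columns `global_index`
#'   (1-based over all trials including familiarization), `phase` (one of
#'   FAM, N, FF, EC, IEC), `block_label`, `within_block_index`; attribute
#'   `config_digest` identifies the generating configuration.
#' @export
#' @examples
#' sched <- build_schedule(protocol_config(), seed = 1)
#' sum(sched$phase != "FAM")  # 617
build_schedule <- function(config = protocol_config(), seed = 1L,
                           expected_total = NULL) {
  p <- config
  if (!is.null(expected_total)) {
    tot <- protocol_total(p)
    if (tot != expected_total)
      abort(sprintf(
        "configured counts sum to %d post-familiarization trials, not the expected %d",
        tot, as.integer(expected_total)))
  }
  if (p$n_ff_blocks != p$n_ec_blocks)
    abort("the alternating design requires equal numbers of FF and EC blocks")
  if (p$n_ff_blocks < 1) abort("at least one FF/EC block pair is required")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  blocks <- list(
    list(label = "FAM", phases = rep("FAM", p$fam_trials)),
    list(label = "N1",
         phases = block_phases("N", p$n1_null,
                               place_iec(p$n1_null + p$n1_iec, p$n1_iec,
                                         p$iec_lead_in)))
  )
  K <- p$n_ff_blocks
  ff_block <- function(i) {
    list(label = paste0("FF", i),
         phases = block_phases("FF", p$ff_trials,
                               place_iec(p$ff_trials + p$ff_iec, p$ff_iec,
                                         p$iec_lead_in)))
  }
  ec_block <- function(i) {
    list(label = paste0("EC", i), phases = rep("EC", p$ec_trials))
  }
  for (i in seq_len(K - 1)) blocks <- c(blocks, list(ff_block(i), ec_block(i)))
  blocks <- c(blocks,
              list(ff_block(K),
                   list(label = "N2", phases = rep("N", p$n2_null)),
                   ec_block(K)))

  sched <- purrr::map_dfr(blocks, function(b) {
    tibble::tibble(phase = b$phases,
                   block_label = b$label,
                   within_block_index = seq_along(b$phases))
  })
  sched <- dplyr::mutate(sched, global_index = dplyr::row_number(),
                         .before = 1)
  structure(sched,
            class = c("ec_schedule", class(tibble::tibble()))) -> out
  attr(out, "config_digest") <- config_digest(c(unclass(p), seed = seed))
  out
}

# Save/restore the global RNG state so schedule building does not perturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Validate a schedule against the design invariants
#'
#' @param schedule An `ec_schedule` tibble.
#' @param config The [protocol_config()] it should satisfy.
#' @return Tibble with one row per violated rule (empty when valid).
#' @export
validate_schedule <- function(schedule, config = protocol_config()) {
  v <- list()
  bad <- function(rule) tibble::tibble(rule = rule)
  main <- dplyr::filter(schedule, .data$phase != "FAM")
  if (nrow(main) != protocol_total(config))
    v <- c(v, list(bad(sprintf("post-familiarization trial count %d != %d",
                               nrow(main), protocol_total(config)))))
  n_blocks <- dplyr::n_distinct(main$block_label)
  if (n_blocks != 2 + config$n_ff_blocks + config$n_ec_blocks)
    v <- c(v, list(bad(sprintf("block count %d != %d", n_blocks,
                               2 + config$n_ff_blocks + config$n_ec_blocks))))
  ec_lens <- main |>
    dplyr::filter(grepl("^EC", .data$block_label)) |>
    dplyr::count(.data$block_label)
  if (any(ec_lens$n != config$ec_trials))
    v <- c(v, list(bad("EC block length differs from the configured count")))
  host <- dplyr::filter(schedule, .data$phase == "IEC")
  if (nrow(host) > 0 && any(grepl("^EC", host$block_label)))
    v <- c(v, list(bad("IEC trials must lie inside N or FF blocks")))
  ec_out <- dplyr::filter(schedule, .data$phase == "EC",
                          !grepl("^EC", .data$block_label))
  if (nrow(ec_out) > 0)
    v <- c(v, list(bad("EC trials must lie inside EC blocks")))
  contig <- schedule |>
    dplyr::group_by(.data$block_label) |>
    dplyr::summarise(ok = all(.data$within_block_index == dplyr::row_number()))
  if (!all(contig$ok))
    v <- c(v, list(bad("within_block_index must be contiguous from 1")))
  if (length(v) == 0) return(tibble::tibble(rule = character()))
  dplyr::bind_rows(v)
}

#' Read / write a schedule as CSV
#'
#' Columns: `global_index`, `phase`, `block_label`, `within_block_index`.
#'
#' @param schedule An `ec_schedule` tibble.
#' @param path File path.
#' @return `read_schedule()` returns the schedule tibble; `write_schedule()`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule[, c("global_index", "phase", "block_label",
                                "within_block_index")], path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    global_index = readr::col_integer(),
    phase = readr::col_character(),
    block_label = readr::col_character(),
    within_block_index = readr::col_integer()))
  attr(out, "spec") <- NULL
  attr(out, "problems") <- NULL
  structure(out, class = c("ec_schedule", class(tibble::tibble())))
}
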