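#' Grating stimulus parameter sets
#'
#' The four drifting-grating protocols used to probe spatial frequency,
#' temporal frequency, contrast, and direction tuning. Each set varies one
#' stimulus axis while holding the others at standard values (0.03 c/deg,
#' 1 Hz, 0.98 contrast, 0 deg unless it is the varied axis).
#'
#' @format A named list; each element describes one set: the varied axis, the
#'   condition values, repeats per condition, and trial duration in seconds.
#' @export
grating_sets <- list(
  spatial = list(
    varying = "sf_cpd",
    sf_cpd = c(0.02, 0.03, 0.04, 0.06, 0.08, 0.12, 0.16, 0.32, 0.64, 0.96),
    tf_hz = 1, contrast = 0.98, direction_deg = 0,
    n_repeats = 6L, duration_s = 7
  ),
  temporal = list(
    varying = "tf_hz",
    sf_cpd = 0.03,
    tf_hz = c(0.3, 0.4, 0.6, 1.2, 1.6, 2.4, 3.2, 4.8, 6.4, 9.6),
    contrast = 0.98, direction_deg = 0,
    n_repeats = 4L, duration_s = 14
  ),
  contrast = list(
    varying = "contrast",
    sf_cpd = 0.03, tf_hz = 1,
    contrast = c(0.10, 0.20, 0.39, 0.58, 0.78, 0.98),
    direction_deg = 0,
    n_repeats = 10L, duration_s = 7
  ),
  direction = list(
    varying = "direction_deg",
    sf_cpd = 0.03, tf_hz = 1, contrast = 0.98,
    direction_deg = seq(0, 315, by = 45),
    n_repeats = 6L, duration_s = 7
  )
)

protocol_tibble <- function(trials) {
  # lay trials out on a single timeline: 1 s blank, stimulus, 1 s blank
  trials <- dplyr::mutate(trials, trial_index = dplyr::row_number())
  slot <- trials$pre_blank_s + trials$duration_s + trials$post_blank_s
  onset <- cumsum(dplyr::lag(slot, default = 0)) + trials$pre_blank_s
  trials$t_start_s <- onset
  trials$t_end_s <- onset + trials$duration_s
  dplyr::relocate(trials, "trial_index")
}

#' Build a drifting-grating protocol
#'
#' Expands one of the standard grating sets ([grating_sets]) into a
#' trial-by-trial presentation schedule: every condition repeated its
#' prescribed number of times, the whole trial list pseudorandomly permuted
#' under `seed`, and a 1 s blank screen attached before and after each trial.
#'
#' @param set_name One of `"spatial"`, `"temporal"`, `"contrast"`,
#'   `"direction"`.
#' @param seed Integer seed for the presentation order.
#' @param n_repeats Optional override of the repeats per condition (for
#'   desk-scale runs); default is the set's standard count.
#' @param duration_s Optional override of the individual trial duration.
#' @return A tibble with one row per trial: `trial_index`, `condition_id`,
#'   `kind`, `sf_cpd`, `tf_hz`, `contrast`, `direction_deg`, `duration_s`,
#'   `pre_blank_s`, `post_blank_s`, `t_start_s`, `t_end_s`. Attributes
#'   `set_name`, `varying`, `seed` identify the protocol.
#' @examples
#' p <- grating_protocol("spatial", seed = 1)
#' nrow(p) # 60 trials: 10 spatial frequencies x 6 repeats
#' @export
grating_protocol <- function(set_name, seed = 1L, n_repeats = NULL,
                             duration_s = NULL) {
  if (!is.character(set_name) || length(set_name) != 1L ||
      !set_name %in% names(grating_sets)) {
    abort(paste0("unknown grating set; use one of: ",
                 paste(names(grating_sets), collapse = ", ")))
  }
  set <- grating_sets[[set_name]]
  if (!is.null(n_repeats)) set$n_repeats <- as.integer(n_repeats)
  if (!is.null(duration_s)) set$duration_s <- duration_s
  stopifnot(set$n_repeats >= 1L, set$duration_s > 0)

  conds <- tidyr::expand_grid(
    sf_cpd = set$sf_cpd, tf_hz = set$tf_hz,
    contrast = set$contrast, direction_deg = set$direction_deg
  )
  conds$condition_id <- sprintf("%s_%02d", set_name, seq_len(nrow(conds)))
  trials <- tidyr::uncount(conds, weights = set$n_repeats)
  trials <- dplyr::group_by(trials, .data$condition_id)
  trials <- dplyr::mutate(trials, repeat_index = dplyr::row_number())
  trials <- dplyr::ungroup(trials)

  ord <- with_seed(seed, sample.int(nrow(trials)))
  trials <- trials[ord, ]
  trials$kind <- "grating"
  trials$duration_s <- set$duration_s
  trials$pre_blank_s <- 1
  trials$post_blank_s <- 1
  out <- protocol_tibble(dplyr::select(
    trials, "condition_id", "kind", "sf_cpd", "tf_hz", "contrast",
    "direction_deg", "repeat_index", "duration_s", "pre_blank_s",
    "post_blank_s"
  ))
  attr(out, "set_name") <- set_name
  attr(out, "varying") <- set$varying
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Build a full-field flicker protocol
#'
#' Alternating full-field black and white epochs of 600 ms each, starting
#' with white, used to separate transient from sustained response profiles.
#' `n_repeats` counts individual 600 ms epochs (the standard session uses
#' 800: 400 white and 400 black, interleaved).
#'
#' @param n_repeats Total number of 600 ms epochs (>= 1).
#' @param epoch_s Epoch duration in seconds (default 0.6).
#' @return A tibble with one row per epoch: `trial_index`, `condition_id`
#'   (`flicker_white`/`flicker_black`), `kind`, `duration_s`, `t_start_s`,
#'   `t_end_s`. Epochs abut with no inter-epoch blank.
#' @export
flicker_protocol <- function(n_repeats = 800L, epoch_s = 0.6) {
  n_repeats <- as.integer(n_repeats)
  if (is.na(n_repeats) || n_repeats < 1L) {
    abort("n_repeats must be a positive integer")
  }
  stopifnot(epoch_s > 0)
  kind <- rep(c("flicker_white", "flicker_black"), length.out = n_repeats)
  out <- tibble::tibble(
    trial_index = seq_len(n_repeats),
    condition_id = kind,
    kind = kind,
    sf_cpd = NA_real_, tf_hz = NA_real_,
    contrast = 1, direction_deg = NA_real_,
    repeat_index = as.integer(stats::ave(seq_len(n_repeats), kind,
                                         FUN = seq_along)),
    duration_s = epoch_s,
    pre_blank_s = 0, post_blank_s = 0,
    t_start_s = (seq_len(n_repeats) - 1) * epoch_s,
    t_end_s = seq_len(n_repeats) * epoch_s
  )
  attr(out, "set_name") <- "flicker"
  attr(out, "epoch_s") <- epoch_s
  out
}
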