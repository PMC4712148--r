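#' Direction and orientation selectivity indices (vector sum)
#'
#' From spontaneous-subtracted mean rates `F(theta)` at 8 evenly spaced
#' directions:
#' `DSI = |sum F(theta) e^(i theta)| / sum F(theta)` and
#' `OSI = |sum F(theta) e^(2 i theta)| / sum F(theta)` (theta in radians),
#' with the preferred direction/orientation given by the phase of the same
#' sums. Negative spontaneous-subtracted rates are clipped to 0 before the
#' sums, since negative weights make the normalizer ill-defined. Units with
#' DSI > 0.33 are direction selective; OSI > 0.6, orientation selective
#' (strict inequalities).
#'
#' @param rates Mean rates per direction, spontaneous-subtracted, spikes/s.
#' @param directions_deg Stimulus directions, degrees; default
#'   `seq(0, 315, by = 45)`.
#' @param dsi_threshold,osi_threshold Classification thresholds.
#' @return A one-row tibble: `dsi`, `osi`, `preferred_direction_deg`,
#'   `preferred_orientation_deg`, `ds_flag`, `os_flag`, `flagged`.
#' @examples
#' compute_dsi_osi(c(10, 0, 0, 0, 5, 0, 0, 0)) # opponent case: DSI 1/3
#' @export
compute_dsi_osi <- function(rates, directions_deg = seq(0, 315, by = 45),
                            dsi_threshold = 0.33, osi_threshold = 0.6) {
  stopifnot(length(rates) == length(directions_deg))
  if (length(directions_deg) != 8 ||
      any(abs(diff(sort(directions_deg %% 360))) - 45 > 1e-9)) {
    warn("directions are not 8 evenly spaced angles; indices computed anyway")
  }
  f <- pmax(0, rates)
  tot <- sum(f)
  if (tot <= 0) {
    return(tibble::tibble(dsi = NA_real_, osi = NA_real_,
                          preferred_direction_deg = NA_real_,
                          preferred_orientation_deg = NA_real_,
                          ds_flag = NA, os_flag = NA, flagged = TRUE))
  }
  th <- directions_deg * pi / 180
  v1 <- sum(f * exp(1i * th)) / tot
  v2 <- sum(f * exp(2i * th)) / tot
  tibble::tibble(
    dsi = Mod(v1),
    osi = Mod(v2),
    preferred_direction_deg = (Arg(v1) * 180 / pi) %% 360,
    preferred_orientation_deg = ((Arg(v2) * 180 / pi) / 2) %% 180,
    ds_flag = Mod(v1) > dsi_threshold,
    os_flag = Mod(v2) > osi_threshold,
    flagged = FALSE
  )
}

#' F1/F0 response linearity
#'
#' Builds the cycle-averaged firing rate over the grating's drift period,
#' then takes `F0` as the mean rate minus the spontaneous rate and `F1` as
#' the amplitude of the Fourier component at the drift frequency, in the
#' peak-sinusoid-amplitude convention (`2 |DFT_1| / N`), under which a
#' raised-cosine rate has F1/F0 exactly 1. The spontaneous rate shifts only
#' the DC term, so it is subtracted from F0 alone. Units with ratio > 1 are
#' classified linear.
#'
#' @param spikes Spike tibble; `spike_time_s` relative to stimulus onset.
#'   Only spikes in `[0, n_cycles/drift_tf)` per trial are used.
#' @param drift_tf_hz Grating drift (temporal) frequency, Hz.
#' @param duration_s Stimulus duration per trial, seconds; must hold an
#'   integer number of cycles.
#' @param spont_rate Spontaneous rate, spikes/s.
#' @param bin_s Cycle histogram bin width, seconds (default 1 ms).
#' @return A one-row tibble: `f0`, `f1`, `ratio`, `linear_flag`, `flagged`.
#' @export
compute_f1f0 <- function(spikes, drift_tf_hz, duration_s,
                         spont_rate = 0, bin_s = 0.001) {
  period <- 1 / drift_tf_hz
  n_cycles <- duration_s / period
  if (abs(n_cycles - round(n_cycles)) > 1e-6) {
    abort("trial duration must hold an integer number of drift cycles")
  }
  n_cycles <- round(n_cycles)
  n_trials <- length(unique(spikes$trial_index))
  st <- spikes$spike_time_s
  st <- st[st >= 0 & st < duration_s]

  n_bins <- max(8L, round(period / bin_s))
  phase <- (st %% period) / period
  counts <- tabulate(pmin(n_bins, floor(phase * n_bins) + 1L), n_bins)
  denom <- n_trials * n_cycles * (period / n_bins)
  rate <- counts / denom

  f0 <- mean(rate) - spont_rate
  dft <- fft(rate)
  f1 <- 2 * Mod(dft[2]) / n_bins
  if (f0 <= 0) {
    return(tibble::tibble(f0 = f0, f1 = f1, ratio = NA_real_,
                          linear_flag = NA, flagged = TRUE))
  }
  ratio <- f1 / f0
  tibble::tibble(f0 = f0, f1 = f1, ratio = ratio,
                 linear_flag = ratio > 1, flagged = FALSE)
}

#' Transient/sustained index from flicker responses
#'
#' PSTH over the 600 ms epochs of the unit's preferred polarity (by default
#' the flicker color with the higher mean rate): the index is the mean rate
#' in the first 50 ms divided by the mean rate over the remaining epoch.
#' Index above 1 is transient; 1 or below is sustained ("fell below 1" read
#' as sustained at the boundary). A zero denominator with a nonzero
#' numerator gives `Inf`, transient, flagged.
#'
#' @param spikes Spike tibble from a flicker protocol; `spike_time_s`
#'   relative to each epoch's onset, `condition_id` in
#'   `flicker_white`/`flicker_black`.
#' @param epoch_s Epoch duration, seconds (default 0.6).
#' @param onset_window_s Early window, seconds (default 0.05).
#' @param preferred Which epochs to use: `"auto"`, `"flicker_white"`, or
#'   `"flicker_black"`.
#' @param latency_s Response-onset latency offset added to both windows
#'   (default 0).
#' @return A one-row tibble: `ts_index`, `early_rate`, `late_rate`,
#'   `temporal_class`, `preferred_epoch`, `flagged`.
#' @export
compute_ts_index <- function(spikes, epoch_s = 0.6, onset_window_s = 0.05,
                             preferred = c("auto", "flicker_white",
                                           "flicker_black"),
                             latency_s = 0) {
  preferred <- match.arg(preferred)
  stopifnot(nrow(spikes) >= 0)
  if (preferred == "auto") {
    by_kind <- dplyr::count(spikes, .data$condition_id)
    if (nrow(by_kind) == 0) abort("no flicker spikes supplied")
    preferred <- by_kind$condition_id[which.max(by_kind$n)]
  }
  sp <- spikes[spikes$condition_id == preferred, ]
  n_epochs <- length(unique(sp$trial_index))
  if (n_epochs == 0) abort("no epochs of the preferred flicker polarity")
  st <- sp$spike_time_s - latency_s
  early_n <- sum(st >= 0 & st < onset_window_s)
  late_n <- sum(st >= onset_window_s & st < epoch_s)
  early_rate <- early_n / (n_epochs * onset_window_s)
  late_rate <- late_n / (n_epochs * (epoch_s - onset_window_s))

  if (late_rate == 0 && early_rate > 0) {
    idx <- Inf; flagged <- TRUE
  } else if (late_rate == 0) {
    idx <- NA_real_; flagged <- TRUE
  } else {
    idx <- early_rate / late_rate; flagged <- FALSE
  }
  tibble::tibble(
    ts_index = idx, early_rate = early_rate, late_rate = late_rate,
    temporal_class = dplyr::case_when(
      is.na(idx) ~ NA_character_,
      idx > 1 ~ "transient",
      TRUE ~ "sustained"
    ),
    preferred_epoch = preferred,
    flagged = flagged
  )
}

#' Spontaneous and evoked firing rates
#'
#' Spontaneous rate is the mean rate over grey/blank periods (the 1 s blanks
#' flanking grating trials); evoked rate is the maximum over all grating
#' conditions of the trial-mean rate during the stimulus window. The evoked
#' rate is reported as-is even when no condition drives the unit above its
#' spontaneous rate.
#'
#' @param spikes Spike tibble aligned to a grating protocol.
#' @param protocol The matching [grating_protocol()] tibble (or a list of
#'   protocols with matching spike tibbles: pass `more` as a list of
#'   `list(spikes, protocol)` pairs to pool).
#' @param more Optional list of additional `list(spikes, protocol)` pairs;
#'   evoked is maximized and spontaneous pooled across all of them.
#' @return A one-row tibble: `spont_rate`, `evoked_rate`,
#'   `evoked_condition_id`.
#' @export
compute_spontaneous_evoked <- function(spikes, protocol, more = list()) {
  pairs <- c(list(list(spikes = spikes, protocol = protocol)),
             more)
  blank_time <- 0; blank_n <- 0
  best <- tibble::tibble(rate = -Inf, condition_id = NA_character_)
  for (pr in pairs) {
    sp <- pr$spikes; pt <- pr$protocol
    for (i in seq_len(nrow(pt))) {
      tr <- pt[i, ]
      st <- sp$spike_time_s[sp$trial_index == tr$trial_index]
      blank_n <- blank_n + sum(st < 0 | st >= tr$duration_s)
      blank_time <- blank_time + tr$pre_blank_s + tr$post_blank_s
    }
    per_cond <- dplyr::summarise(
      dplyr::group_by(
        purrr::map_dfr(seq_len(nrow(pt)), function(i) {
          tr <- pt[i, ]
          st <- sp$spike_time_s[sp$trial_index == tr$trial_index]
          tibble::tibble(condition_id = tr$condition_id,
                         rate = sum(st >= 0 & st < tr$duration_s) /
                           tr$duration_s)
        }),
        .data$condition_id),
      rate = mean(.data$rate), .groups = "drop")
    cand <- per_cond[which.max(per_cond$rate), ]
    if (nrow(cand) == 1 && cand$rate > best$rate) {
      best <- tibble::tibble(rate = cand$rate,
                             condition_id = cand$condition_id)
    }
  }
  tibble::tibble(
    spont_rate = if (blank_time > 0) blank_n / blank_time else NA_real_,
    evoked_rate = if (is.finite(best$rate)) best$rate else 0,
    evoked_condition_id = best$condition_id
  )
}
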