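#' Default analysis configuration
#'
#' All classification thresholds at their standard values: 95%
#' variance-explained inclusion gate, DSI > 0.33 for direction selectivity,
#' OSI > 0.6 for orientation selectivity, F1/F0 > 1 for linearity,
#' transient/sustained index > 1 for transient, radius ratio within
#' \[0.7, 1.3\] for circular receptive fields, STA lags scanned over
#' 0-300 ms.
#'
#' @param ... Named overrides of individual entries.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    ve_threshold = 0.95,
    dsi_threshold = 0.33,
    osi_threshold = 0.6,
    f1f0_threshold = 1,
    ts_threshold = 1,
    circularity_bounds = c(0.7, 1.3),
    lag_window_s = c(0, 0.3)
  )
  utils::modifyList(cfg, list(...))
}

na_row <- function(...) tibble::tibble(...)

#' Characterize one unit from its spike trains
#'
#' Runs the full per-unit battery: STA receptive field with 2D Gaussian fit,
#' polarity and circularity; DoG spatial-frequency fit with preferred/cutoff
#' frequency; two-half-Gaussian temporal-frequency fit with low50/high50/
#' bandwidth; hyperbolic contrast fit with contrast gain and C50; DSI/OSI;
#' F1/F0 at the tested spatial frequency closest to the preferred one;
#' transient/sustained index; spontaneous and evoked rates. Fits failing the
#' variance-explained gate are excluded (their derived metrics set to NA)
#' but the unit is retained for the non-parametric axes.
#'
#' @param spikes Spike tibble for one unit, with a `protocol` column naming
#'   the stimulus set (`spatial`, `temporal`, `contrast`, `direction`,
#'   `flicker`, `movie`).
#' @param protocols Named list of protocol tibbles matching the `protocol`
#'   values present.
#' @param movie Optional `noise_movie` for the receptive-field stage; when
#'   missing, the RF stage is skipped with a warning.
#' @param config A [default_config()] list.
#' @return A one-row tibble of per-unit metrics and classifications.
#' @export
characterize_unit <- function(spikes, protocols, movie = NULL,
                              config = default_config()) {
  uid <- unique(spikes$unit_id)
  stopifnot(length(uid) == 1)
  get_sp <- function(kind) spikes[spikes$protocol == kind, ]
  out <- tibble::tibble(unit_id = uid)

  # --- receptive field ----------------------------------------------------
  rf_sp <- get_sp("movie")
  if (!is.null(movie) && nrow(rf_sp) > 0) {
    sta <- compute_sta(rf_sp, movie, lag_window = config$lag_window_s)
    g2 <- fit_gaussian2d(sta)
    pol <- classify_polarity(g2)
    circ <- classify_circularity(g2, config$circularity_bounds)
    out <- dplyr::bind_cols(out, tibble::tibble(
      rf_n_spikes = sta$n_spikes, rf_lag_s = sta$best_lag_s,
      rf_amp = g2$amp, rf_xc = g2$xc, rf_yc = g2$yc,
      rf_sx = g2$sx, rf_sy = g2$sy, rf_ve = g2$variance_explained,
      polarity = pol$polarity,
      radius_ratio = circ$radius_ratio, circularity = circ$circularity,
      mean_radius_deg = circ$mean_radius_deg))
  } else {
    if (is.null(movie) && nrow(rf_sp) > 0) {
      warn(sprintf("%s: movie unavailable, receptive-field stage skipped", uid))
    }
    out <- dplyr::bind_cols(out, tibble::tibble(
      rf_n_spikes = NA_integer_, rf_lag_s = NA_real_, rf_amp = NA_real_,
      rf_xc = NA_real_, rf_yc = NA_real_, rf_sx = NA_real_, rf_sy = NA_real_,
      rf_ve = NA_real_, polarity = NA_character_, radius_ratio = NA_real_,
      circularity = NA_character_, mean_radius_deg = NA_real_))
  }

  # --- spatial frequency --------------------------------------------------
  sf_sp <- get_sp("spatial")
  sf_fit <- NULL
  if (nrow(sf_sp) > 0 && "spatial" %in% names(protocols)) {
    sf_curve <- build_tuning_curve(sf_sp, protocols$spatial)
    sf_fit <- fit_dog(sf_curve)
    inc <- fit_quality_gate(sf_fit, config$ve_threshold) == "include"
    met <- if (inc) derive_sf_metrics(sf_fit) else {
      tibble::tibble(preferred_sf_cpd = NA_real_, cutoff_sf_cpd = NA_real_,
                     sf_class = NA_character_)
    }
    out <- dplyr::bind_cols(out, tibble::tibble(
      sf_ve = sf_fit$variance_explained, sf_included = inc), met)
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      sf_ve = NA_real_, sf_included = FALSE, preferred_sf_cpd = NA_real_,
      cutoff_sf_cpd = NA_real_, sf_class = NA_character_))
  }

  # --- linearity (F1/F0 at the SF nearest the preferred one) --------------
  if (nrow(sf_sp) > 0 && "spatial" %in% names(protocols)) {
    prot <- protocols$spatial
    sfs <- sort(unique(prot$sf_cpd))
    target <- out$preferred_sf_cpd
    if (is.na(target)) {
      curve <- build_tuning_curve(sf_sp, prot)
      target <- curve$value[which.max(curve$mean_rate)]
    }
    sf_use <- sfs[which.min(abs(sfs - target))]
    cond_ids <- unique(prot$condition_id[prot$sf_cpd == sf_use])
    tr <- prot[prot$condition_id %in% cond_ids, ]
    sp_use <- sf_sp[sf_sp$condition_id %in% cond_ids, ]
    spont_here <- attr(build_tuning_curve(sf_sp, prot), "spont_rate")
    lin <- compute_f1f0(sp_use, drift_tf_hz = tr$tf_hz[1],
                        duration_s = tr$duration_s[1],
                        spont_rate = spont_here)
    out <- dplyr::bind_cols(out, tibble::tibble(
      f0 = lin$f0, f1 = lin$f1, f1f0 = lin$ratio,
      linearity = dplyr::case_when(
        is.na(lin$ratio) ~ NA_character_,
        lin$ratio > config$f1f0_threshold ~ "linear",
        TRUE ~ "nonlinear"),
      f1f0_sf_cpd = sf_use))
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      f0 = NA_real_, f1 = NA_real_, f1f0 = NA_real_,
      linearity = NA_character_, f1f0_sf_cpd = NA_real_))
  }

  # --- temporal frequency -------------------------------------------------
  tf_sp <- get_sp("temporal")
  if (nrow(tf_sp) > 0 && "temporal" %in% names(protocols)) {
    tf_curve <- build_tuning_curve(tf_sp, protocols$temporal)
    tf_fit <- fit_two_half_gaussian(tf_curve)
    inc <- fit_quality_gate(tf_fit, config$ve_threshold) == "include"
    met <- if (inc) derive_tf_metrics(tf_fit) else {
      tibble::tibble(preferred_tf_hz = NA_real_, low50_hz = NA_real_,
                     high50_hz = NA_real_, bandwidth_hz = NA_real_,
                     tf_class = NA_character_)
    }
    out <- dplyr::bind_cols(out, tibble::tibble(
      tf_ve = tf_fit$variance_explained, tf_included = inc), met)
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      tf_ve = NA_real_, tf_included = FALSE, preferred_tf_hz = NA_real_,
      low50_hz = NA_real_, high50_hz = NA_real_, bandwidth_hz = NA_real_,
      tf_class = NA_character_))
  }

  # --- contrast -----------------------------------------------------------
  cr_sp <- get_sp("contrast")
  if (nrow(cr_sp) > 0 && "contrast" %in% names(protocols)) {
    cr_curve <- build_tuning_curve(cr_sp, protocols$contrast)
    cr_fit <- fit_hyperbolic(cr_curve)
    inc <- fit_quality_gate(cr_fit, config$ve_threshold) == "include"
    met <- if (inc) derive_contrast_metrics(cr_fit) else {
      tibble::tibble(contrast_gain = NA_real_, c50 = NA_real_,
                     c20 = NA_real_)
    }
    out <- dplyr::bind_cols(out, tibble::tibble(
      cr_ve = cr_fit$variance_explained, cr_included = inc), met)
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      cr_ve = NA_real_, cr_included = FALSE, contrast_gain = NA_real_,
      c50 = NA_real_, c20 = NA_real_))
  }

  # --- direction/orientation ---------------------------------------------
  dir_sp <- get_sp("direction")
  if (nrow(dir_sp) > 0 && "direction" %in% names(protocols)) {
    dir_curve <- build_tuning_curve(dir_sp, protocols$direction)
    spont_dir <- attr(dir_curve, "spont_rate")
    sel <- compute_dsi_osi(dir_curve$mean_rate - spont_dir,
                           dir_curve$value,
                           config$dsi_threshold, config$osi_threshold)
    out <- dplyr::bind_cols(out, tibble::tibble(
      dsi = sel$dsi, osi = sel$osi,
      preferred_direction_deg = sel$preferred_direction_deg,
      preferred_orientation_deg = sel$preferred_orientation_deg,
      ds_flag = sel$ds_flag, os_flag = sel$os_flag))
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      dsi = NA_real_, osi = NA_real_, preferred_direction_deg = NA_real_,
      preferred_orientation_deg = NA_real_, ds_flag = NA, os_flag = NA))
  }

  # --- transient/sustained ------------------------------------------------
  fl_sp <- get_sp("flicker")
  if (nrow(fl_sp) > 0) {
    epoch_s <- if ("flicker" %in% names(protocols)) {
      attr(protocols$flicker, "epoch_s") %||% 0.6
    } else 0.6
    ts <- compute_ts_index(fl_sp, epoch_s = epoch_s)
    out <- dplyr::bind_cols(out, tibble::tibble(
      ts_index = ts$ts_index, temporal_class = ts$temporal_class))
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      ts_index = NA_real_, temporal_class = NA_character_))
  }

  # --- spontaneous / evoked ----------------------------------------------
  grating_kinds <- intersect(c("spatial", "temporal", "contrast", "direction"),
                             names(protocols))
  grating_kinds <- grating_kinds[vapply(grating_kinds, function(k) {
    nrow(get_sp(k)) > 0
  }, logical(1))]
  if (length(grating_kinds) > 0) {
    pairs <- lapply(grating_kinds, function(k) {
      list(spikes = get_sp(k), protocol = protocols[[k]])
    })
    se <- compute_spontaneous_evoked(pairs[[1]]$spikes, pairs[[1]]$protocol,
                                     more = pairs[-1])
    out <- dplyr::bind_cols(out, tibble::tibble(
      spont_rate = se$spont_rate, evoked_rate = se$evoked_rate))
  } else {
    out <- dplyr::bind_cols(out, tibble::tibble(
      spont_rate = NA_real_, evoked_rate = NA_real_))
  }
  out
}

#' Characterize every unit in a spike table
#'
#' @param spikes Spike tibble for many units (columns `unit_id`, `protocol`,
#'   `condition_id`, `trial_index`, `spike_time_s`).
#' @param protocols Named list of protocol tibbles.
#' @param movie Optional `noise_movie`.
#' @param config A [default_config()] list.
#' @param truth Optional ground-truth tibble from [sample_population()];
#'   when given, its class labels are joined in with a `true_` prefix.
#' @return A tibble with one row per unit (a "cell report" table).
#' @export
characterize_population <- function(spikes, protocols, movie = NULL,
                                    config = default_config(),
                                    truth = NULL) {
  reports <- spikes |>
    dplyr::group_split(.data$unit_id) |>
    purrr::map(characterize_unit, protocols = protocols, movie = movie,
               config = config) |>
    dplyr::bind_rows()
  if (!is.null(truth) && nrow(truth) > 0) {
    lab <- dplyr::select(
      truth, "unit_id",
      true_polarity = "polarity", true_linearity = "linearity",
      true_temporal_class = "temporal_profile", true_selectivity = "selectivity")
    reports <- dplyr::left_join(reports, lab, by = "unit_id")
  }
  reports
}

frac_tbl <- function(x, axis) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(tibble::tibble())
  tb <- table(x)
  tibble::tibble(axis = axis, level = names(tb),
                 count = as.integer(tb),
                 fraction = as.numeric(tb) / sum(tb))
}

#' Population summary tables from per-unit reports
#'
#' Counts and fractions for every classification axis (polarity,
#' circularity, pass-band classes, linearity, transient/sustained, DS/OS),
#' distribution summaries of the continuous metrics (via
#' [summarize_values()]), and — when ground-truth labels are present —
#' per-axis confusion matrices and agreement fractions. Units whose fits
#' were excluded remain counted on the axes that do not need those fits.
#'
#' @param reports Tibble from [characterize_population()].
#' @return A list of tibbles: `classification`, `metrics`, `agreement`
#'   (NULL without ground truth), `confusion` (ditto), `n_units`.
#' @export
build_population_table <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  cls <- dplyr::bind_rows(
    frac_tbl(reports$polarity, "polarity"),
    frac_tbl(reports$circularity, "circularity"),
    frac_tbl(reports$sf_class, "sf_class"),
    frac_tbl(reports$tf_class, "tf_class"),
    frac_tbl(reports$linearity, "linearity"),
    frac_tbl(reports$temporal_class, "temporal_class"),
    frac_tbl(ifelse(reports$ds_flag, "ds", "non_ds"), "direction_selective"),
    frac_tbl(ifelse(reports$os_flag, "os", "non_os"), "orientation_selective")
  )
  metric_cols <- c("mean_radius_deg", "spont_rate", "evoked_rate",
                   "preferred_sf_cpd", "cutoff_sf_cpd", "preferred_tf_hz",
                   "low50_hz", "high50_hz", "bandwidth_hz", "contrast_gain",
                   "c50", "f1f0", "dsi", "osi", "ts_index")
  metric_cols <- intersect(metric_cols, names(reports))
  metrics <- purrr::map_dfr(metric_cols, function(cn) {
    s <- summarize_values(reports[[cn]])
    dplyr::bind_cols(tibble::tibble(metric = cn),
                     dplyr::select(s, -"values"))
  })

  agreement <- NULL; confusion <- NULL
  if ("true_polarity" %in% names(reports)) {
    ax <- list(
      polarity = c("polarity", "true_polarity"),
      linearity = c("linearity", "true_linearity"),
      temporal_class = c("temporal_class", "true_temporal_class")
    )
    confusion <- purrr::map_dfr(names(ax), function(nm) {
      est <- reports[[ax[[nm]][1]]]; tru <- reports[[ax[[nm]][2]]]
      ok <- !is.na(est) & !is.na(tru)
      if (!any(ok)) return(tibble::tibble())
      tb <- as.data.frame(table(estimated = est[ok], truth = tru[ok]))
      dplyr::bind_cols(tibble::tibble(axis = nm), tb)
    })
    sel_est <- dplyr::case_when(
      reports$ds_flag ~ "ds",
      reports$os_flag ~ "os",
      is.na(reports$ds_flag) ~ NA_character_,
      TRUE ~ "none")
    ok_sel <- !is.na(sel_est) & !is.na(reports$true_selectivity)
    agreement <- tibble::tibble(
      axis = c("polarity", "linearity", "temporal_class", "selectivity"),
      agreement = c(
        agree_frac(reports$polarity, reports$true_polarity),
        agree_frac(reports$linearity, reports$true_linearity),
        agree_frac(reports$temporal_class, reports$true_temporal_class),
        if (any(ok_sel)) mean(sel_est[ok_sel] == reports$true_selectivity[ok_sel])
        else NA_real_
      )
    )
  }
  list(classification = cls, metrics = metrics, agreement = agreement,
       confusion = confusion, n_units = nrow(reports))
}

agree_frac <- function(est, tru) {
  ok <- !is.na(est) & !is.na(tru)
  if (!any(ok)) return(NA_real_)
  mean(est[ok] == tru[ok])
}
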