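#' Tuning-family primitives
#'
#' The four parametric response families used both by the generator (forward
#' model) and by the fitting module:
#' * `dog_curve()`: difference-of-Gaussians spatial-frequency tuning
#'   `R(v) = b + (kc - b) (exp(-(pi rc v)^2) - ks exp(-(pi rs v)^2))`;
#' * `two_half_gaussian_curve()`: temporal-frequency tuning, a Gaussian with
#'   independent low- and high-side baselines
#'   `R(w) = b1|b2 + (a - b1|b2) exp(-((p - w)/s)^2)`;
#' * `hyperbolic_curve()`: Naka-Rushton contrast response
#'   `R(c) = b + (Rmax - b) c^n / (c^n + h^n)`;
#' * `gaussian2d_surface()`: the 2D spatial receptive-field profile
#'   `A exp(-((x - xc)^2 / (2 sx^2) + (y - yc)^2 / (2 sy^2)))`.
#'
#' @param v,w,cc,x,y Abscissae (c/deg, Hz, contrast fraction, degrees).
#' @param b,kc,ks,rc,rs DoG parameters: baseline, centre amplitude, relative
#'   surround strength, centre and surround radii (deg).
#' @param b1,b2,a,p,s Two-half-Gaussian parameters: low/high baselines, peak
#'   amplitude, peak frequency (Hz), width (Hz).
#' @param rmax,h,n Hyperbolic parameters: maximum rate, semi-saturation
#'   contrast, exponent.
#' @param amp,xc,yc,sx,sy 2D Gaussian parameters: signed amplitude, centre
#'   (deg), radii (deg).
#' @return Numeric vector (or matrix for `gaussian2d_surface`) of the family
#'   evaluated at the abscissae.
#' @name tuning-families
NULL

#' @rdname tuning-families
#' @export
dog_curve <- function(v, b, kc, ks, rc, rs) {
  b + (kc - b) * (exp(-(pi * rc * v)^2) - ks * exp(-(pi * rs * v)^2))
}

#' @rdname tuning-families
#' @export
two_half_gaussian_curve <- function(w, b1, b2, a, p, s) {
  base <- ifelse(w < p, b1, b2)
  base + (a - base) * exp(-((p - w) / s)^2)
}

#' @rdname tuning-families
#' @export
hyperbolic_curve <- function(cc, b, rmax, h, n) {
  b + (rmax - b) * cc^n / (cc^n + h^n)
}

#' @rdname tuning-families
#' @export
gaussian2d_surface <- function(x, y, amp, xc, yc, sx, sy) {
  amp * exp(-(outer(rep(1, length(y)), (x - xc)^2 / (2 * sx^2)) +
                outer((y - yc)^2 / (2 * sy^2), rep(1, length(x)))))
}

# --- direction tuning ------------------------------------------------------

# multiplicative direction gain, peak 1 at the preferred angle
direction_gain <- function(theta_deg, pref_deg, kappa, mode = c("ds", "os")) {
  mode <- match.arg(mode)
  th <- (theta_deg - pref_deg) * pi / 180
  if (mode == "ds") exp(kappa * (cos(th) - 1)) else exp(kappa * (cos(2 * th) - 1))
}

# DSI/OSI of the noise-free 8-direction response for a given concentration;
# depends on where the preferred direction falls relative to the 45 deg
# sampling grid, so the preferred direction is part of the mapping
index_for_kappa <- function(kappa, mode, pref_deg = 0) {
  dirs <- seq(0, 315, by = 45)
  g <- direction_gain(dirs, pref_deg, kappa, mode)
  k <- if (mode == "ds") 1 else 2
  Mod(sum(g * exp(1i * k * dirs * pi / 180))) / sum(g)
}

# invert index_for_kappa (monotone in kappa) for a target DSI or OSI
kappa_for_index <- function(target, mode = c("ds", "os"), pref_deg = 0) {
  mode <- match.arg(mode)
  stopifnot(target >= 0, target < 1)
  if (target <= 1e-8) return(0)
  lim <- index_for_kappa(80, mode, pref_deg)
  if (target >= lim) {
    abort(sprintf(
      "target index %.3f unreachable at preferred direction %.1f deg (max %.3f on the 45 deg grid)",
      target, pref_deg, lim))
  }
  uniroot(function(k) index_for_kappa(k, mode, pref_deg) - target,
          c(1e-6, 80), tol = 1e-9)$root
}

# --- ground-truth population ----------------------------------------------

#' Sample a ground-truth LNP model-neuron population
#'
#' Draws `n` linear-nonlinear-Poisson model neurons whose spatial receptive
#' field, spatial/temporal/contrast tuning, direction tuning, response
#' linearity, and flicker adaptation are all governed by the same parametric
#' families the analysis modules fit, so every downstream estimate has a
#' known recovery target. Default parameter ranges are centred on typical
#' mouse-LGN population values (receptive-field radii near 6.5 deg,
#' preferred temporal frequencies near 3.2 Hz, C50 near 0.5, spontaneous
#' rates near 2 spikes/s).
#'
#' @param n Number of neurons.
#' @param seed Integer seed.
#' @param class_mix Named list of class fractions: `on` (ON polarity),
#'   `linear`, `transient`, `ds`, `os`. DS/OS are mutually exclusive;
#'   remaining mass is non-selective.
#' @param rf_extent_deg Half-width of the region receptive-field centres are
#'   scattered over (centred on 0), degrees.
#' @param snr One of `"high"` or `"paper"`: `"high"` narrows evoked-rate and
#'   spontaneous ranges to well-separated values for recovery experiments.
#' @return A tibble with one row per neuron and all generator parameters,
#'   plus the ground-truth class labels (`polarity`, `linearity`,
#'   `temporal_profile`, `selectivity`).
#' @export
sample_population <- function(n, seed = 1L,
                              class_mix = list(on = 0.5, linear = 0.95,
                                               transient = 0.95,
                                               ds = 0.05, os = 0.02),
                              rf_extent_deg = 12, snr = c("high", "paper")) {
  snr <- match.arg(snr)
  stopifnot(n >= 0)
  if (n == 0) return(tibble::tibble())
  mix <- utils::modifyList(list(on = 0.5, linear = 0.95, transient = 0.95,
                                ds = 0.05, os = 0.02), class_mix)
  if (mix$ds + mix$os > 1) abort("ds + os fractions must not exceed 1")

  with_seed(seed, {
    # deterministic label assignment: first ceil(frac*n) get the label, then
    # shuffled, so small populations still contain every requested class
    take <- function(frac) {
      k <- round(frac * n)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    }
    on <- take(mix$on)
    linear <- take(mix$linear)
    transient <- take(mix$transient)
    n_ds <- round(mix$ds * n); n_os <- round(mix$os * n)
    sel <- sample(c(rep("ds", n_ds), rep("os", n_os),
                    rep("none", n - n_ds - n_os)))

    radius <- runif(n, 4, 9)             # mean RF radius, deg (median ~6.5)
    ratio <- runif(n, 0.85, 1.18)        # sx/sy, circular by construction
    sx <- radius * sqrt(ratio)
    sy <- radius / sqrt(ratio)
    spont <- if (snr == "high") runif(n, 1, 3) else rexp_trunc(n, 2, 0.2, 10)
    r_evoked <- if (snr == "high") runif(n, 20, 40) else runif(n, 5, 35)

    rc <- runif(n, 2.2, 4)               # DoG centre radius, deg
    rs <- rc * runif(n, 3.5, 6)
    ks <- runif(n, 0.65, 0.92)

    # preferred TF and width drawn jointly so the standard 1 Hz probe still
    # drives the cell (low50 medians near 1.4 Hz imply substantial response
    # at 1 Hz); a nonzero low-side baseline fraction adds the same guarantee
    tf_p <- runif(n, 2.2, 4.5)           # preferred TF, Hz
    tf_s_lo <- pmax(1.6, (tf_p - 1) / 1.2)
    tf_s <- tf_s_lo + runif(n, 0, pmax(0.2, 3.0 - tf_s_lo))
    tf_b1 <- runif(n, 0.05, 0.2)         # fraction of peak amplitude
    tf_b2 <- runif(n, 0, 0.15)           # fraction of peak amplitude

    cr_h <- runif(n, 0.35, 0.65)
    cr_n <- runif(n, 1.8, 3.5)

    dsi_target <- ifelse(sel == "ds", runif(n, 0.6, 0.8), runif(n, 0.02, 0.08))
    osi_target <- ifelse(sel == "os", runif(n, 0.8, 0.9), NA_real_)
    # selective cells prefer directions near the 0 deg axis used by the
    # fixed-direction protocols, so all their response axes stay measurable
    # (and, for OS cells, the discrete 45 deg sampling grid does not cap the
    # attainable OSI); non-selective cells (kappa ~ 0) can point anywhere
    pref_dir <- ifelse(sel == "none",
                       runif(n, 0, 360),
                       runif(n, -10, 10) %% 360)
    kappa <- vapply(seq_len(n), function(i) {
      if (sel[i] == "os") kappa_for_index(osi_target[i], "os", pref_dir[i])
      else kappa_for_index(dsi_target[i], "ds", pref_dir[i])
    }, numeric(1))

    tibble::tibble(
      unit_id = sprintf("unit_%03d", seq_len(n)),
      polarity = ifelse(on, "ON", "OFF"),
      linearity = ifelse(linear, "linear", "nonlinear"),
      temporal_profile = ifelse(transient, "transient", "sustained"),
      selectivity = sel,
      rf_amp = ifelse(on, 1, -1),
      rf_xc = runif(n, -rf_extent_deg, rf_extent_deg),
      rf_yc = runif(n, -rf_extent_deg, rf_extent_deg),
      rf_sx = sx, rf_sy = sy,
      sf_rc = rc, sf_rs = rs, sf_ks = ks,
      tf_b1 = tf_b1, tf_b2 = tf_b2, tf_p = tf_p, tf_s = tf_s,
      cr_h = cr_h, cr_n = cr_n,
      dir_pref = pref_dir, dir_kappa = kappa,
      dir_mode = ifelse(sel == "os", "os", "ds"),
      dsi_target = ifelse(sel == "os", NA_real_, dsi_target),
      osi_target = osi_target,
      mod_depth = ifelse(linear, 2, 0),
      adaptation_tau = ifelse(transient, runif(n, 0.01, 0.025),
                              runif(n, 0.04, 0.06)),
      sustained_frac = ifelse(transient, runif(n, 0, 0.15),
                              runif(n, 1.1, 1.25)),
      spont_rate = spont,
      r_evoked = r_evoked,
      movie_drive_sd = r_evoked / 2
    )
  })
}

rexp_trunc <- function(n, rate_mean, lo, hi) {
  pmin(pmax(stats::rexp(n, 1 / rate_mean), lo), hi)
}

# --- forward model ---------------------------------------------------------

# peak-normalized tuning factors for one neuron (a one-row tibble or list)
norm_sf_gain <- function(nrn, v) {
  d <- exp(-(pi * nrn$sf_rc * v)^2) - nrn$sf_ks * exp(-(pi * nrn$sf_rs * v)^2)
  vg <- seq(0, 1.2, length.out = 2048)
  dmax <- max(exp(-(pi * nrn$sf_rc * vg)^2) -
                nrn$sf_ks * exp(-(pi * nrn$sf_rs * vg)^2))
  pmax(0, d) / dmax
}

norm_tf_gain <- function(nrn, w) {
  two_half_gaussian_curve(w, nrn$tf_b1, nrn$tf_b2, 1, nrn$tf_p, nrn$tf_s)
}

norm_contrast_gain <- function(nrn, cc) {
  cc^nrn$cr_n / (cc^nrn$cr_n + nrn$cr_h^nrn$cr_n)
}

#' Noise-free firing rate of a model neuron for a grating condition
#'
#' The grating drive is separable:
#' `rate(t) = spont + r_evoked * Gsf(v) * Gtf(w) * Gc(c) * Gdir(theta) * M(t)`
#' with each tuning factor normalized to peak 1 and
#' `M(t) = max(0, 1 + m cos(2 pi w t - phi))` rescaled to unit mean.
#' `m = mod_depth`: `m = 1` gives a raised-cosine rate whose F1/F0 is exactly
#' 1; `m > 1` gives a rectified, strongly modulated rate (F1/F0 > 1,
#' "linear" cells); `m = 0` gives an unmodulated rate (F1/F0 = 0,
#' "nonlinear" cells). Rates are rectified at 0.
#'
#' @param neuron One row of [sample_population()] (tibble or list).
#' @param condition A list or one-row tibble with `sf_cpd`, `tf_hz`,
#'   `contrast`, `direction_deg`.
#' @param t Time points within the trial, seconds from stimulus onset.
#' @param phase Temporal phase offset phi, radians.
#' @return Numeric vector of rates, spikes/s.
#' @export
expected_grating_rate <- function(neuron, condition, t, phase = 0) {
  nrn <- as.list(neuron)
  amp <- nrn$r_evoked *
    norm_sf_gain(nrn, condition$sf_cpd) *
    norm_tf_gain(nrn, condition$tf_hz) *
    norm_contrast_gain(nrn, condition$contrast) *
    direction_gain(condition$direction_deg, nrn$dir_pref, nrn$dir_kappa,
                   nrn$dir_mode %||% "ds")
  m <- nrn$mod_depth %||% 1
  if (m > 0) {
    mod <- pmax(0, 1 + m * cos(2 * pi * condition$tf_hz * t - phase))
    # renormalize to unit mean over a cycle so amp is the mean evoked rate
    mod <- mod / mean_rectified_cosine(m)
  } else {
    mod <- rep(1, length(t))
  }
  pmax(0, nrn$spont_rate + amp * mod)
}

# mean over a cycle of max(0, 1 + m cos x)
mean_rectified_cosine <- function(m) {
  if (m <= 1) return(1)
  x0 <- acos(-1 / m)
  (x0 + m * sin(x0)) / pi
}

# --- Poisson sampling ------------------------------------------------------

# inhomogeneous Poisson spike times on [0, t_max] by thinning, 1 ms ceiling
sample_inhomogeneous_poisson <- function(rate_fn, t_max, rate_max) {
  if (rate_max <= 0 || t_max <= 0) return(numeric(0))
  n <- rpois(1, rate_max * t_max)
  if (n == 0) return(numeric(0))
  tt <- sort(runif(n, 0, t_max))
  keep <- runif(n) < rate_fn(tt) / rate_max
  tt[keep]
}

#' Simulate spike trains for a grating protocol
#'
#' Inhomogeneous Poisson sampling (thinning) of [expected_grating_rate()]
#' for every trial of a protocol; pre/post blank periods are driven by the
#' spontaneous rate alone. Spike times are reported relative to stimulus
#' onset, so blanks occupy `[-pre_blank, 0)` and `[duration, duration +
#' post_blank)`.
#'
#' @param neuron One row of [sample_population()].
#' @param protocol A [grating_protocol()] tibble.
#' @param seed Integer seed.
#' @return A tibble of spikes: `unit_id`, `condition_id`, `trial_index`,
#'   `spike_time_s`.
#' @export
simulate_trials <- function(neuron, protocol, seed = 1L) {
  nrn <- as.list(neuron)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(protocol)), function(i) {
      tr <- protocol[i, ]
      cond <- list(sf_cpd = tr$sf_cpd, tf_hz = tr$tf_hz,
                   contrast = tr$contrast, direction_deg = tr$direction_deg)
      rmax <- nrn$spont_rate + nrn$r_evoked *
        max(1e-9, (1 + (nrn$mod_depth %||% 1)) /
              mean_rectified_cosine(nrn$mod_depth %||% 1)) + 1
      stim <- sample_inhomogeneous_poisson(
        function(t) expected_grating_rate(nrn, cond, t),
        tr$duration_s, rmax)
      blank_pre <- sample_inhomogeneous_poisson(
        function(t) rep(nrn$spont_rate, length(t)),
        tr$pre_blank_s, max(nrn$spont_rate, 1e-9)) - tr$pre_blank_s
      blank_post <- sample_inhomogeneous_poisson(
        function(t) rep(nrn$spont_rate, length(t)),
        tr$post_blank_s, max(nrn$spont_rate, 1e-9)) + tr$duration_s
      st <- sort(c(blank_pre, stim, blank_post))
      if (length(st) == 0) return(NULL)
      tibble::tibble(
        unit_id = nrn$unit_id %||% "unit_001",
        condition_id = tr$condition_id,
        trial_index = tr$trial_index,
        spike_time_s = st
      )
    })
    dplyr::bind_rows(rows)
  })
}

# biphasic temporal kernel (difference of exponentials), unit peak,
# evaluated at lag seconds
biphasic_kernel <- function(lag_s, peak_s = 0.05) {
  tau1 <- peak_s / 2
  tau2 <- peak_s
  k <- (lag_s / tau1) * exp(-lag_s / tau1) - 0.5 * (lag_s / tau2) * exp(-lag_s / tau2)
  k[lag_s < 0] <- 0
  k / max(k)
}

#' Simulate a model neuron's response to a noise movie
#'
#' LNP cascade: the movie (as deviation from mid-grey) is projected onto the
#' neuron's signed 2D Gaussian receptive field, convolved with a biphasic
#' temporal kernel, scaled to a target drive standard deviation, rectified
#' around the spontaneous rate, and sampled as an inhomogeneous Poisson
#' process frame by frame.
#'
#' @param neuron One row of [sample_population()].
#' @param movie A `noise_movie`.
#' @param seed Integer seed.
#' @param kernel_peak_s Latency of the temporal kernel peak, seconds.
#' @param drive_sd Target standard deviation of the filtered drive in
#'   spikes/s; default is the neuron's `movie_drive_sd` (zero gives a
#'   homogeneous Poisson process at the spontaneous rate).
#' @return A spike tibble as in [simulate_trials()], with `condition_id`
#'   `"movie"` and spike times relative to movie start.
#' @export
simulate_movie_response <- function(neuron, movie, seed = 1L,
                                    kernel_peak_s = 0.05, drive_sd = NULL) {
  stopifnot(inherits(movie, "noise_movie"))
  nrn <- as.list(neuron)
  dp <- attr(movie, "deg_per_pixel")
  fr <- attr(movie, "frame_rate_hz")
  d <- dim(movie); nt <- d[1]; ny <- d[2]; nx <- d[3]
  drive_sd <- drive_sd %||% nrn$movie_drive_sd %||% 6

  x <- (seq_len(nx) - (nx + 1) / 2) * dp
  y <- (seq_len(ny) - (ny + 1) / 2) * dp
  rf <- gaussian2d_surface(x, y, nrn$rf_amp, nrn$rf_xc, nrn$rf_yc,
                           nrn$rf_sx, nrn$rf_sy)
  if (max(abs(nrn$rf_xc), abs(nrn$rf_yc)) >
        max(abs(range(x)), abs(range(y)))) {
    abort("receptive-field centre lies outside the movie extent")
  }

  fr_mat <- matrix(movie, nrow = nt) - 0.5   # nt x (ny*nx), column-major y,x
  s_t <- as.numeric(fr_mat %*% as.numeric(rf))
  lags <- seq_len(min(nt, as.integer(round(0.3 * fr)) + 1L)) - 1L
  kern <- biphasic_kernel(lags / fr, kernel_peak_s)
  drive <- stats::filter(s_t, kern, method = "convolution", sides = 1)
  drive[is.na(drive)] <- 0
  drive <- as.numeric(drive)
  sdd <- sd(drive)
  if (drive_sd > 0 && sdd > 0) {
    drive <- drive * (drive_sd / sdd)
  } else {
    drive <- rep(0, nt)
  }
  rate <- pmax(0, nrn$spont_rate + drive)

  with_seed(seed, {
    counts <- rpois(nt, rate / fr)
    idx <- rep.int(seq_len(nt), counts)
    st <- (idx - 1) / fr + runif(length(idx)) / fr
    tibble::tibble(
      unit_id = nrn$unit_id %||% "unit_001",
      condition_id = "movie",
      trial_index = 1L,
      spike_time_s = sort(st)
    )
  })
}

#' Simulate a model neuron's response to the flicker protocol
#'
#' Step response with exponential adaptation: within each epoch of the
#' neuron's preferred polarity (white for ON, black for OFF) the rate is
#' `spont + step * (sustained_frac + (1 - sustained_frac) exp(-t / tau))`;
#' non-preferred epochs are driven by the spontaneous rate alone.
#' `sustained_frac` below 1 gives an onset transient, 1 a flat response, and
#' slightly above 1 a sustained response with a shallow onset dip.
#'
#' @param neuron One row of [sample_population()].
#' @param protocol A [flicker_protocol()] tibble.
#' @param seed Integer seed.
#' @param step_rate Step amplitude in spikes/s; default `r_evoked`.
#' @return A spike tibble; spike times relative to each epoch's onset.
#' @export
simulate_flicker_response <- function(neuron, protocol, seed = 1L,
                                      step_rate = NULL) {
  nrn <- as.list(neuron)
  step <- step_rate %||% nrn$r_evoked %||% 20
  pref <- if ((nrn$polarity %||% "ON") == "ON") "flicker_white" else "flicker_black"
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(protocol)), function(i) {
      tr <- protocol[i, ]
      if (tr$condition_id == pref) {
        sf <- nrn$sustained_frac %||% 0
        tau <- nrn$adaptation_tau %||% 0.02
        rate_fn <- function(t) {
          pmax(0, nrn$spont_rate + step * (sf + (1 - sf) * exp(-t / tau)))
        }
        rmax <- nrn$spont_rate + step * max(1, sf) + 1
      } else {
        rate_fn <- function(t) rep(nrn$spont_rate, length(t))
        rmax <- max(nrn$spont_rate, 1e-9)
      }
      st <- sample_inhomogeneous_poisson(rate_fn, tr$duration_s, rmax)
      if (length(st) == 0) return(NULL)
      tibble::tibble(
        unit_id = nrn$unit_id %||% "unit_001",
        condition_id = tr$condition_id,
        trial_index = tr$trial_index,
        spike_time_s = st
      )
    })
    dplyr::bind_rows(rows)
  })
}
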