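#' Specify a contrast-modulated spatiotemporal noise movie
#'
#' The receptive-field mapping stimulus is band-limited noise built in the
#' Fourier domain: the spatial amplitude spectrum falls off as
#' `A(f) ~ 1/(f + fc)` with `fc = 0.05` c/deg and a hard cutoff at
#' 0.16 c/deg, the temporal spectrum is flat with a sharp low-pass cutoff at
#' 10 Hz, and every frame is multiplied by a slow (0.1 Hz) sinusoidal
#' contrast envelope to prevent response adaptation.
#'
#' @param n_x,n_y Frame size in pixels.
#' @param deg_per_pixel Degrees of visual angle per pixel.
#' @param frame_rate_hz Frame rate in Hz.
#' @param fc_cpd Spatial corner frequency of the 1/(f+fc) drop-off, c/deg.
#' @param spatial_cutoff_cpd Hard spatial cutoff, c/deg.
#' @param temporal_cutoff_hz Hard temporal low-pass cutoff, Hz.
#' @param modulation_hz Contrast-envelope frequency, Hz.
#' @param movie_duration_s Duration of one movie block, seconds.
#' @param grey_duration_s Duration of the grey block preceding each movie
#'   block, seconds.
#' @param n_sessions Number of grey+movie blocks in a full session.
#' @param seed Integer seed for the random spectrum phases.
#' @return A list of class `noise_movie_spec`.
#' @export
noise_movie_spec <- function(n_x = 64L, n_y = 64L, deg_per_pixel = 1,
                             frame_rate_hz = 30, fc_cpd = 0.05,
                             spatial_cutoff_cpd = 0.16,
                             temporal_cutoff_hz = 10, modulation_hz = 0.1,
                             movie_duration_s = 300, grey_duration_s = 300,
                             n_sessions = 4L, seed = 1L) {
  spec <- list(
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    deg_per_pixel = deg_per_pixel, frame_rate_hz = frame_rate_hz,
    fc_cpd = fc_cpd, spatial_cutoff_cpd = spatial_cutoff_cpd,
    temporal_cutoff_hz = temporal_cutoff_hz, modulation_hz = modulation_hz,
    movie_duration_s = movie_duration_s, grey_duration_s = grey_duration_s,
    n_sessions = as.integer(n_sessions), seed = as.integer(seed)
  )
  if (spec$fc_cpd <= 0 || spec$spatial_cutoff_cpd <= spec$fc_cpd) {
    abort("need spatial_cutoff_cpd > fc_cpd > 0")
  }
  nyq_s <- 0.5 / spec$deg_per_pixel
  nyq_t <- spec$frame_rate_hz / 2
  if (spec$spatial_cutoff_cpd > nyq_s) {
    abort(sprintf("spatial cutoff %.3g c/deg exceeds Nyquist %.3g c/deg",
                  spec$spatial_cutoff_cpd, nyq_s))
  }
  if (spec$temporal_cutoff_hz >= nyq_t) {
    abort(sprintf("temporal cutoff %.3g Hz must be below Nyquist %.3g Hz",
                  spec$temporal_cutoff_hz, nyq_t))
  }
  if (spec$modulation_hz <= 0 || spec$modulation_hz > spec$temporal_cutoff_hz / 10) {
    abort("modulation_hz must be positive and well below the temporal cutoff")
  }
  stopifnot(spec$movie_duration_s > 0, spec$grey_duration_s >= 0,
            spec$n_sessions >= 1L)
  structure(spec, class = "noise_movie_spec")
}

#' Generate one band-limited noise movie block
#'
#' Draws a white Gaussian random field, shapes its 3D Fourier amplitude to
#' the target spectrum (spatially `1/(f + fc)` radially, zero beyond the
#' spatial cutoff; temporally flat, zero beyond the temporal cutoff; DC
#' forced to zero), inverse-transforms it (the FFT of a real field is
#' Hermitian, so the output is exactly real), scales the zero-mean noise so
#' that 3 RMS spans the [0, 1] intensity range around mid-grey 0.5, applies
#' the sinusoidal contrast envelope `E(t) = 0.5 (1 - cos(2 pi m t))`, and
#' clips any residual out-of-range values. The clipped fraction is recorded
#' in the `clip_fraction` attribute.
#'
#' @param spec A [noise_movie_spec()].
#' @param envelope Apply the contrast envelope (default `TRUE`).
#' @return A `noise_movie` object: a 3D array (time x y x x) of intensities
#'   in `[0, 1]` with attributes `deg_per_pixel`, `frame_rate_hz`,
#'   `timestamps_s`, `spec`, `clip_fraction`.
#' @export
generate_noise_movie <- function(spec, envelope = TRUE) {
  stopifnot(inherits(spec, "noise_movie_spec"))
  nt <- as.integer(round(spec$movie_duration_s * spec$frame_rate_hz))
  ny <- spec$n_y; nx <- spec$n_x
  stopifnot(nt >= 2L)

  ft <- fft_freq(nt, d = 1 / spec$frame_rate_hz)
  fx <- fft_freq(nx, d = spec$deg_per_pixel)
  fy <- fft_freq(ny, d = spec$deg_per_pixel)
  fs <- sqrt(outer(fy^2, fx^2, `+`)) # spatial frequency magnitude, c/deg

  amp_s <- 1 / (fs + spec$fc_cpd)
  amp_s[fs > spec$spatial_cutoff_cpd] <- 0
  amp_t <- as.numeric(abs(ft) <= spec$temporal_cutoff_hz)

  white <- with_seed(spec$seed, array(rnorm(nt * ny * nx), dim = c(nt, ny, nx)))
  spec3 <- fft(white)
  # separable amplitude mask; DC zero so the mean is exactly mid-grey
  mask <- outer(amp_t, amp_s)
  dim(mask) <- c(nt, ny, nx)
  mask[1, 1, 1] <- 0
  noise <- Re(fft(spec3 * mask, inverse = TRUE)) / (nt * ny * nx)

  scale <- (0.5 / 3) / sd(as.numeric(noise))
  noise <- noise * scale
  if (envelope) {
    t_s <- (seq_len(nt) - 1) / spec$frame_rate_hz
    env <- 0.5 * (1 - cos(2 * pi * spec$modulation_hz * t_s))
    noise <- noise * env
  }
  frames <- noise + 0.5
  clip_fraction <- mean(frames < 0 | frames > 1)
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1

  structure(
    frames,
    class = c("noise_movie", "array"),
    deg_per_pixel = spec$deg_per_pixel,
    frame_rate_hz = spec$frame_rate_hz,
    timestamps_s = (seq_len(nt) - 1) / spec$frame_rate_hz,
    spec = spec,
    clip_fraction = clip_fraction
  )
}

#' Assemble a full mapping session (grey blocks + movie blocks)
#'
#' A session is `n_sessions` repeats of a grey (mid-luminance) block followed
#' by a movie block; at the standard scale 4 x (5 min grey + 5 min movie)
#' = 40 min. The same movie block is reused across sessions, as when a single
#' pre-rendered movie file is replayed.
#'
#' @param spec A [noise_movie_spec()].
#' @return A `noise_movie` object covering the full session, with an
#'   attribute `block_table`: a tibble of block kinds and start/end times.
#' @export
assemble_movie_session <- function(spec) {
  stopifnot(inherits(spec, "noise_movie_spec"))
  if (spec$n_sessions < 1L) abort("n_sessions must be >= 1")
  movie <- generate_noise_movie(spec)
  fr <- spec$frame_rate_hz
  n_grey <- as.integer(round(spec$grey_duration_s * fr))
  nt_m <- dim(movie)[1]
  block <- vector("list", 2L * spec$n_sessions)
  kinds <- character(0); starts <- numeric(0)
  t0 <- 0
  rows <- list()
  for (s in seq_len(spec$n_sessions)) {
    rows[[2 * s - 1]] <- tibble::tibble(
      block = "grey", session = s, t_start_s = t0,
      t_end_s = t0 + n_grey / fr)
    t0 <- t0 + n_grey / fr
    rows[[2 * s]] <- tibble::tibble(
      block = "movie", session = s, t_start_s = t0,
      t_end_s = t0 + nt_m / fr)
    t0 <- t0 + nt_m / fr
  }
  block_table <- dplyr::bind_rows(rows)

  nt_total <- spec$n_sessions * (n_grey + nt_m)
  frames <- array(0.5, dim = c(nt_total, spec$n_y, spec$n_x))
  for (s in seq_len(spec$n_sessions)) {
    off <- (s - 1L) * (n_grey + nt_m) + n_grey
    frames[off + seq_len(nt_m), , ] <- movie
  }
  structure(
    frames,
    class = c("noise_movie", "array"),
    deg_per_pixel = spec$deg_per_pixel,
    frame_rate_hz = fr,
    timestamps_s = (seq_len(nt_total) - 1) / fr,
    spec = spec,
    clip_fraction = attr(movie, "clip_fraction"),
    block_table = block_table
  )
}

#' Radially averaged spatial amplitude spectrum of a movie
#'
#' Averages the 2D amplitude spectrum over frames (weighted toward frames
#' with appreciable contrast so the envelope's near-zero frames do not
#' dilute the estimate), then averages amplitudes in thin annuli of spatial
#' frequency.
#'
#' @param movie A `noise_movie`.
#' @param n_frames Number of frames to sample (default 200, evenly spaced).
#' @return A tibble with `f_cpd` (annulus centre) and `amplitude`.
#' @export
movie_radial_spectrum <- function(movie, n_frames = 200L) {
  stopifnot(inherits(movie, "noise_movie"))
  d <- dim(movie); nt <- d[1]; ny <- d[2]; nx <- d[3]
  dp <- attr(movie, "deg_per_pixel")
  idx <- unique(round(seq(1, nt, length.out = min(n_frames, nt))))
  # keep the upper half of sampled frames by RMS contrast
  rms <- vapply(idx, function(i) sd(as.numeric(movie[i, , ])), numeric(1))
  idx <- idx[rms >= median(rms)]
  acc <- matrix(0, ny, nx)
  for (i in idx) acc <- acc + Mod(fft(movie[i, , ] - mean(movie[i, , ])))
  acc <- acc / length(idx)
  fs <- sqrt(outer(fft_freq(ny, dp)^2, fft_freq(nx, dp)^2, `+`))
  nyq <- 0.5 / dp
  breaks <- seq(0, nyq, length.out = 33)
  bin <- cut(as.numeric(fs), breaks, include.lowest = TRUE)
  tibble::tibble(
    f_cpd = (head(breaks, -1) + tail(breaks, -1)) / 2,
    amplitude = as.numeric(tapply(as.numeric(acc), bin, mean))
  )
}

#' Fit the 1/(f+fc) spectral model to a movie's spatial spectrum
#'
#' Least-squares fit of `k / (f + fc)` to the frame-averaged amplitude
#' spectrum, cell by Fourier cell inside the pass band (per-cell fitting
#' avoids the binning bias a radially averaged spectrum suffers where the
#' curve is steep); used to verify that a generated movie has the intended
#' spatial statistics.
#'
#' @param movie A `noise_movie`.
#' @param n_frames Frames sampled for the spectrum estimate.
#' @return A list with elements `fc_cpd` and `k`.
#' @export
fit_radial_spectrum <- function(movie, n_frames = 200L) {
  spec <- attr(movie, "spec")
  d <- dim(movie); nt <- d[1]; ny <- d[2]; nx <- d[3]
  dp <- attr(movie, "deg_per_pixel")
  idx <- unique(round(seq(1, nt, length.out = min(n_frames, nt))))
  rms <- vapply(idx, function(i) sd(as.numeric(movie[i, , ])), numeric(1))
  idx <- idx[rms >= median(rms)]
  acc <- matrix(0, ny, nx)
  for (i in idx) acc <- acc + Mod(fft(movie[i, , ] - mean(movie[i, , ])))
  acc <- acc / length(idx)
  fs <- sqrt(outer(fft_freq(ny, dp)^2, fft_freq(nx, dp)^2, `+`))
  band <- fs > 0 & fs < spec$spatial_cutoff_cpd
  f <- as.numeric(fs[band]); a <- as.numeric(acc[band])
  obj <- function(fc) {
    pred <- 1 / (f + fc)
    k <- sum(pred * a) / sum(pred^2)
    sum((a - k * pred)^2)
  }
  fc <- optimize(obj, c(1e-4, 1))$minimum
  pred <- 1 / (f + fc)
  list(fc_cpd = fc, k = sum(pred * a) / sum(pred^2))
}
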