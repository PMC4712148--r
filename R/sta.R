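#' Spike-triggered average receptive-field map
#'
#' For each lag on the frame grid inside `lag_window`, averages the movie
#' frame preceding every spike by that lag (as deviation from mid-grey
#' 0.5) and returns the map at the lag with the largest absolute peak.
#' Spikes earlier than the longest lag after movie start are excluded.
#'
#' Because the mapping movie is spatially correlated (its amplitude spectrum
#' falls as `1/(f + fc)`), the raw STA is the receptive field blurred by the
#' stimulus autocorrelation. When the movie carries its generating spec and
#' `whiten = TRUE`, the map is decorrelated in the Fourier domain by a
#' regularized inverse of the known stimulus power spectrum inside the pass
#' band (classical inverse-correlation / Wiener correction), which removes
#' the blur without fitting anything.
#'
#' After decorrelation the map is smoothed with a Gaussian of known width
#' (`smooth_sigma_px`) to suppress the amplified per-pixel noise; because
#' the smoothing kernel is known exactly, [fit_gaussian2d()] removes its
#' contribution from the fitted radii in quadrature, so the smoothing costs
#' no bias in the reported receptive-field size.
#'
#' @param spikes Spike tibble with `spike_time_s` on the movie timebase.
#' @param movie A `noise_movie`.
#' @param lag_window Numeric length-2, seconds; lags scanned at frame
#'   resolution (default `c(0, 0.3)`).
#' @param whiten Apply the spectral decorrelation (default `TRUE` when the
#'   movie has a spec attached).
#' @param lambda Tikhonov regularization for the decorrelation, as a
#'   fraction of the peak stimulus power.
#' @param smooth_sigma_px Gaussian smoothing width in pixels applied after
#'   decorrelation (default 3 when whitening, 0 otherwise).
#' @return An `rf_map` object: list with `map` (y by x matrix, signed),
#'   `deg_per_pixel`, `best_lag_s`, `lag_profile` (tibble of lag vs peak
#'   |amplitude|), `n_spikes`, `smooth_sigma_deg`.
#' @export
compute_sta <- function(spikes, movie, lag_window = c(0, 0.3),
                        whiten = !is.null(attr(movie, "spec")),
                        lambda = 0.05,
                        smooth_sigma_px = if (isTRUE(whiten)) 3 else 0) {
  stopifnot(inherits(movie, "noise_movie"), length(lag_window) == 2L,
            lag_window[2] >= lag_window[1])
  fr <- attr(movie, "frame_rate_hz")
  dp <- attr(movie, "deg_per_pixel")
  d <- dim(movie); nt <- d[1]; ny <- d[2]; nx <- d[3]

  st <- spikes$spike_time_s
  lag_frames <- seq(floor(lag_window[1] * fr), ceiling(lag_window[2] * fr))
  lag_frames <- lag_frames[lag_frames >= 0]
  max_lag <- max(lag_frames)
  st <- st[st >= (max_lag + 1) / fr & st < nt / fr]
  if (length(st) == 0) abort("no usable spikes within the movie timebase")
  sp_frame <- floor(st * fr) + 1L   # frame on screen at spike time

  fr_mat <- matrix(movie, nrow = nt) - 0.5
  maps <- lapply(lag_frames, function(l) {
    idx <- sp_frame - l
    colMeans(fr_mat[idx, , drop = FALSE])
  })
  peak <- vapply(maps, function(m) max(abs(m)), numeric(1))
  best <- which.max(peak)
  map <- matrix(maps[[best]], ny, nx)

  if (isTRUE(whiten)) {
    spec <- attr(movie, "spec")
    if (is.null(spec)) abort("whitening requested but the movie has no spec")
    fs <- sqrt(outer(fft_freq(ny, dp)^2, fft_freq(nx, dp)^2, `+`))
    amp <- 1 / (fs + spec$fc_cpd)
    amp[fs > spec$spatial_cutoff_cpd] <- 0
    pw <- amp^2
    filt <- pw / (pw^2 + (lambda * max(pw))^2)  # ~1/pw in band, 0 outside
    filt[pw == 0] <- 0
    wmap <- Re(fft(fft(map) * filt, inverse = TRUE)) / (ny * nx)
    # keep the raw map's amplitude scale at the peak for interpretability
    sc <- max(abs(map)) / max(abs(wmap))
    map <- wmap * sc
  }
  if (smooth_sigma_px > 0) {
    fpx <- outer(fft_freq(ny)^2, fft_freq(nx)^2, `+`)
    g <- exp(-2 * pi^2 * smooth_sigma_px^2 * fpx)
    map <- Re(fft(fft(map) * g, inverse = TRUE)) / (ny * nx)
  }

  structure(
    list(
      map = map,
      deg_per_pixel = dp,
      best_lag_s = lag_frames[best] / fr,
      lag_profile = tibble::tibble(lag_s = lag_frames / fr,
                                   peak_amplitude = peak),
      n_spikes = length(st),
      whitened = isTRUE(whiten),
      smooth_sigma_deg = smooth_sigma_px * dp
    ),
    class = "rf_map"
  )
}

#' @export
print.rf_map <- function(x, ...) {
  cat(sprintf(
    "<rf_map> %d x %d px (%.3g deg/px), lag %.0f ms, %d spikes%s\n",
    nrow(x$map), ncol(x$map), x$deg_per_pixel, 1000 * x$best_lag_s,
    x$n_spikes, if (x$whitened) ", decorrelated" else ""))
  invisible(x)
}

# pixel-centre coordinates (deg) of a map, centred on the grid
map_coords <- function(map, dp) {
  ny <- nrow(map); nx <- ncol(map)
  list(x = (seq_len(nx) - (nx + 1) / 2) * dp,
       y = (seq_len(ny) - (ny + 1) / 2) * dp)
}

#' Fit a 2D Gaussian to a receptive-field map
#'
#' Bounded Levenberg-Marquardt least squares of
#' `A exp(-((x - xc)^2 / (2 sx^2) + (y - yc)^2 / (2 sy^2))) + c0`, where the
#' additive offset `c0` is a free nuisance term initialized at the map's
#' median (it absorbs residual grey-level bias and is not reported). `A`
#' carries the sign of the map's extremum. Initialized at the extremum with
#' moment-based radii plus jittered restarts; the best residual wins.
#'
#' @param rf An `rf_map`, or a plain matrix (then `deg_per_pixel` must be
#'   given).
#' @param deg_per_pixel Degree calibration when `rf` is a matrix.
#' @param n_starts Number of jittered restarts (default 5).
#' @return A `gauss2d_fit`: list with `amp`, `xc`, `yc`, `sx`, `sy`,
#'   `variance_explained`, `converged`, `flagged`, `n_pixels`.
#' @export
fit_gaussian2d <- function(rf, deg_per_pixel = NULL, n_starts = 5L) {
  smooth_deg <- 0
  if (inherits(rf, "rf_map")) {
    map <- rf$map; dp <- rf$deg_per_pixel
    smooth_deg <- rf$smooth_sigma_deg %||% 0
  } else {
    map <- as.matrix(rf); dp <- deg_per_pixel
    if (is.null(dp)) abort("deg_per_pixel required for a bare matrix")
  }
  if (!all(is.finite(map))) abort("map contains non-finite values")
  med <- median(map)
  z <- map - med
  if (max(abs(z)) == 0) abort("map has no nonzero extremum")
  co <- map_coords(map, dp)
  X <- outer(rep(1, nrow(map)), co$x)
  Y <- outer(co$y, rep(1, ncol(map)))

  ext <- which(abs(z) == max(abs(z)), arr.ind = TRUE)[1, ]
  a0 <- z[ext[1], ext[2]]
  x0 <- co$x[ext[2]]; y0 <- co$y[ext[1]]
  # moment-based radius guess from pixels with the extremum's sign
  w <- pmax(0, z * sign(a0))
  sx0 <- sqrt(sum(w * (X - x0)^2) / sum(w))
  sy0 <- sqrt(sum(w * (Y - y0)^2) / sum(w))
  sx0 <- max(sx0, dp); sy0 <- max(sy0, dp)

  resid_fn <- function(par) {
    pred <- par[1] * exp(-((X - par[2])^2 / (2 * par[5]^2) +
                             (Y - par[3])^2 / (2 * par[4]^2))) + par[6]
    as.numeric(pred - z)
  }
  span_x <- diff(range(co$x)); span_y <- diff(range(co$y))
  amax <- max(abs(z))
  lower <- c(-4 * amax, min(co$x) - span_x / 2, min(co$y) - span_y / 2,
             dp / 4, dp / 4, -amax)
  upper <- c(4 * amax, max(co$x) + span_x / 2, max(co$y) + span_y / 2,
             2 * span_y, 2 * span_x, amax)

  starts <- list(c(a0, x0, y0, sy0, sx0, 0))
  jit <- with_seed(20201L, lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
    c(a0 * runif(1, 0.6, 1.4),
      x0 + runif(1, -2, 2) * dp, y0 + runif(1, -2, 2) * dp,
      sy0 * runif(1, 0.5, 2), sx0 * runif(1, 0.5, 2), 0)
  }))
  starts <- c(starts, jit)

  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower + 1e-9), upper - 1e-9)
    ft <- tryCatch(
      minpack.lm::nls.lm(p0, lower, upper, resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ft)) next
    rss <- sum(ft$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = ft, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(amp = NA_real_, xc = NA_real_, yc = NA_real_,
                          sx = NA_real_, sy = NA_real_,
                          variance_explained = NA_real_, converged = FALSE,
                          flagged = TRUE, n_pixels = length(z)),
                     class = "gauss2d_fit"))
  }
  par <- best$fit$par
  ve <- 1 - best$rss / sum((z - mean(z))^2)
  # remove the map's declared smoothing from the radii (in quadrature)
  deblur <- function(s) sqrt(max(s^2 - smooth_deg^2, (dp / 4)^2))
  structure(
    list(amp = par[1], xc = par[2], yc = par[3],
         sy = deblur(abs(par[4])), sx = deblur(abs(par[5])),
         variance_explained = max(0, min(1, ve)),
         converged = best$fit$info %in% 1:4,
         flagged = !(best$fit$info %in% 1:4),
         n_pixels = length(z)),
    class = "gauss2d_fit"
  )
}

#' @export
print.gauss2d_fit <- function(x, ...) {
  cat(sprintf(
    "<gauss2d_fit> A=%.3g at (%.2f, %.2f) deg, radii (sx=%.2f, sy=%.2f) deg, VE=%.3f\n",
    x$amp, x$xc, x$yc, x$sx, x$sy, x$variance_explained))
  invisible(x)
}

#' @rdname tidy-geniculate
#' @method tidy gauss2d_fit
#' @export
tidy.gauss2d_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amp", "xc", "yc", "sx", "sy"),
    estimate = c(x$amp, x$xc, x$yc, x$sx, x$sy)
  )
}

#' @rdname glance-geniculate
#' @method glance gauss2d_fit
#' @export
glance.gauss2d_fit <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 converged = x$converged, flagged = x$flagged,
                 n_pixels = x$n_pixels)
}

#' Classify receptive-field polarity from a 2D Gaussian fit
#'
#' ON if the fitted amplitude is positive (centre excited by luminance
#' increments), OFF if negative; exactly zero amplitude is indeterminate.
#'
#' @param fit A `gauss2d_fit`.
#' @return A one-row tibble with `polarity` (`"ON"`, `"OFF"`, or `NA`) and
#'   `flagged`.
#' @export
classify_polarity <- function(fit) {
  amp <- if (inherits(fit, "gauss2d_fit")) fit$amp else fit
  pol <- dplyr::case_when(
    is.na(amp) | amp == 0 ~ NA_character_,
    amp > 0 ~ "ON",
    TRUE ~ "OFF"
  )
  tibble::tibble(polarity = pol, flagged = is.na(pol))
}

#' Classify receptive-field circularity
#'
#' The radius ratio is horizontal over vertical (`sx / sy`); fields with
#' ratio in the closed interval \[0.7, 1.3\] are circular, and for those the
#' absolute radius is reported as the mean of the two radii.
#'
#' @param fit A `gauss2d_fit` (or anything with `sx`, `sy`).
#' @param bounds Length-2 inclusive circularity bounds (default
#'   `c(0.7, 1.3)`).
#' @return A one-row tibble: `radius_ratio`, `circularity`
#'   (`"circular"`/`"non_circular"`), `mean_radius_deg` (NA when
#'   non-circular).
#' @export
classify_circularity <- function(fit, bounds = c(0.7, 1.3)) {
  stopifnot(fit$sx > 0, fit$sy > 0)
  ratio <- fit$sx / fit$sy
  circ <- ratio >= bounds[1] & ratio <= bounds[2]
  tibble::tibble(
    radius_ratio = ratio,
    circularity = ifelse(circ, "circular", "non_circular"),
    mean_radius_deg = ifelse(circ, (fit$sx + fit$sy) / 2, NA_real_)
  )
}
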