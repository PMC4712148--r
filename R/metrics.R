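#' Derived spatial-frequency metrics
#'
#' From a DoG fit: the preferred spatial frequency is where the fitted curve
#' peaks over `v > 0` (located numerically by golden-section refinement of a
#' dense grid); the cutoff is the smallest frequency above the peak at which
#' the baseline-subtracted response falls to 1% of its baseline-subtracted
#' peak (bisection). A unit is low-pass if the fitted peak lies at or below
#' the lowest tested frequency, high-pass at or above the highest, band-pass
#' otherwise.
#'
#' @param fit A `dog_fit`.
#' @param tested_range Length-2 numeric, the lowest and highest tested
#'   spatial frequencies (default: range of the fitted curve's abscissae).
#' @return A one-row tibble: `preferred_sf_cpd`, `cutoff_sf_cpd`,
#'   `sf_class`.
#' @export
derive_sf_metrics <- function(fit, tested_range = NULL) {
  stopifnot(inherits(fit, "dog_fit"))
  if (isTRUE(fit$flagged)) {
    return(tibble::tibble(preferred_sf_cpd = NA_real_,
                          cutoff_sf_cpd = NA_real_, sf_class = NA_character_))
  }
  tested_range <- tested_range %||% range(fit$curve$value)
  f <- function(v) dog_curve(v, fit$b, fit$kc, fit$ks, fit$rc, fit$rs)
  v_hi <- max(tested_range[2] * 4, 2 / (pi * fit$rc))
  grid <- seq(0, v_hi, length.out = 4096)
  i <- which.max(f(grid))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  pref <- if (i == 1) 0 else optimize(f, c(lo, hi), maximum = TRUE)$maximum

  sf_class <- if (pref <= tested_range[1]) {
    "low_pass"
  } else if (pref >= tested_range[2]) {
    "high_pass"
  } else {
    "band_pass"
  }

  peak_amp <- f(max(pref, 1e-12)) - fit$b
  cutoff <- NA_real_
  if (peak_amp > 0) {
    g <- function(v) (f(v) - fit$b) - 0.01 * peak_amp
    v_end <- v_hi
    while (g(v_end) > 0 && v_end < 1e4) v_end <- v_end * 2
    if (g(v_end) <= 0) {
      cutoff <- uniroot(g, c(max(pref, 1e-12), v_end), tol = 1e-10)$root
    }
  }
  tibble::tibble(preferred_sf_cpd = pref, cutoff_sf_cpd = cutoff,
                 sf_class = sf_class)
}

#' Derived temporal-frequency metrics
#'
#' From a two-half-Gaussian fit: `low50` and `high50` are the frequencies at
#' which the fitted curve passes through half of its peak amplitude
#' (`R = a/2`, absolute scale) on the low and high side of the peak `p`;
#' the bandwidth is their difference. A side whose baseline exceeds `a/2`
#' never reaches half-maximum and that bound is undefined, which also forces
#' the pass-band class (`low_pass` when low50 is undefined, `high_pass` when
#' high50 is undefined). Otherwise the class follows the peak position
#' against the tested range, as for spatial frequency.
#'
#' @param fit A `tf_fit`.
#' @param tested_range Length-2 numeric, lowest and highest tested temporal
#'   frequencies.
#' @return A one-row tibble: `preferred_tf_hz`, `low50_hz`, `high50_hz`,
#'   `bandwidth_hz`, `tf_class`.
#' @export
derive_tf_metrics <- function(fit, tested_range = NULL) {
  stopifnot(inherits(fit, "tf_fit"))
  if (isTRUE(fit$flagged)) {
    return(tibble::tibble(preferred_tf_hz = NA_real_, low50_hz = NA_real_,
                          high50_hz = NA_real_, bandwidth_hz = NA_real_,
                          tf_class = NA_character_))
  }
  tested_range <- tested_range %||% range(fit$curve$value)
  half <- fit$a / 2
  # closed form: b + (a - b) exp(-z^2) = a/2  =>  z = sqrt(log((a-b)/(a/2-b)))
  side50 <- function(b) {
    if (half <= b) return(NA_real_)
    sqrt(log((fit$a - b) / (half - b)))
  }
  z1 <- side50(fit$b1); z2 <- side50(fit$b2)
  low50 <- if (is.na(z1)) NA_real_ else fit$p - fit$s * z1
  high50 <- if (is.na(z2)) NA_real_ else fit$p + fit$s * z2
  if (!is.na(low50) && low50 < 0) low50 <- 0

  tf_class <- if (is.na(low50) || fit$p <= tested_range[1]) {
    "low_pass"
  } else if (is.na(high50) || fit$p >= tested_range[2]) {
    "high_pass"
  } else {
    "band_pass"
  }
  tibble::tibble(
    preferred_tf_hz = fit$p,
    low50_hz = low50, high50_hz = high50,
    bandwidth_hz = if (is.na(low50) || is.na(high50)) NA_real_ else high50 - low50,
    tf_class = tf_class
  )
}

#' Derived contrast-response metrics
#'
#' From a hyperbolic fit: `c20` is the contrast at which the
#' baseline-subtracted response reaches 20% of its baseline-subtracted value
#' at full contrast, and the contrast gain is the slope `dR/dc` of the
#' fitted curve at `c20` (analytic derivative). `C50` is the contrast at
#' which the baseline-subtracted response reaches 50% of its full-contrast
#' value. Both have closed forms in the Naka-Rushton parameters.
#'
#' @param fit A `crf_fit`.
#' @return A one-row tibble: `contrast_gain` (spikes/s per unit contrast),
#'   `c50`, `c20`.
#' @export
derive_contrast_metrics <- function(fit) {
  stopifnot(inherits(fit, "crf_fit"))
  empty <- tibble::tibble(contrast_gain = NA_real_, c50 = NA_real_,
                          c20 = NA_real_)
  if (isTRUE(fit$flagged)) return(empty)
  b <- fit$b; rmax <- fit$rmax; h <- fit$h; n <- fit$n
  r1 <- hyperbolic_curve(1, b, rmax, h, n)
  if (r1 <= b) return(empty)
  # baseline-subtracted response fraction q of full-contrast value:
  # c^n/(c^n + h^n) = q / (1 + h^n)  =>  c^n = q h^n / (1 + h^n - q)
  level_c <- function(q) {
    qq <- q / (1 + h^n)
    (qq * h^n / (1 - qq))^(1 / n)
  }
  c50 <- level_c(0.5)
  c20 <- level_c(0.2)
  gain <- (rmax - b) * n * c20^(n - 1) * h^n / (c20^n + h^n)^2
  tibble::tibble(contrast_gain = gain, c50 = c50, c20 = c20)
}
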