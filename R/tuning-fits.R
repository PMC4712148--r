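#' Build a tuning curve from trial spikes
#'
#' Trial firing rate is spike count over the stimulus window divided by the
#' stimulus duration; the curve holds the mean and SEM over repeats per
#' value of the varied axis. The spontaneous rate is estimated from the
#' blank periods flanking every trial.
#'
#' @param spikes Spike tibble (`condition_id`, `trial_index`,
#'   `spike_time_s` relative to stimulus onset).
#' @param protocol A [grating_protocol()] tibble.
#' @param varying Column name of the varied axis; default the protocol's
#'   `varying` attribute.
#' @return A `tuning_curve`: tibble with `value`, `mean_rate`, `sem_rate`,
#'   `n_repeats`, and attributes `varying`, `spont_rate`, `spont_sem`.
#' @export
build_tuning_curve <- function(spikes, protocol, varying = NULL) {
  varying <- varying %||% attr(protocol, "varying")
  if (is.null(varying) || !varying %in% names(protocol)) {
    abort("cannot determine the varied axis; pass `varying`")
  }
  unknown <- setdiff(unique(spikes$condition_id),
                     c(unique(protocol$condition_id), NA))
  if (length(unknown) > 0) {
    abort(paste("spikes reference conditions absent from the protocol:",
                paste(unknown, collapse = ", ")))
  }
  trials <- dplyr::select(protocol, "condition_id", "trial_index",
                          value = dplyr::all_of(varying), "duration_s",
                          "pre_blank_s", "post_blank_s")
  per_trial <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    st <- spikes$spike_time_s[spikes$trial_index == tr$trial_index]
    n_stim <- sum(st >= 0 & st < tr$duration_s)
    n_blank <- sum(st < 0 | st >= tr$duration_s)
    tibble::tibble(
      condition_id = tr$condition_id, trial_index = tr$trial_index,
      value = tr$value,
      rate = n_stim / tr$duration_s,
      blank_rate = n_blank / (tr$pre_blank_s + tr$post_blank_s)
    )
  })
  curve <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$value),
    mean_rate = mean(.data$rate),
    sem_rate = if (dplyr::n() > 1) sd(.data$rate) / sqrt(dplyr::n()) else 0,
    n_repeats = dplyr::n(),
    .groups = "drop"
  )
  curve <- dplyr::arrange(curve, .data$value)
  blank_ok <- is.finite(per_trial$blank_rate)
  attr(curve, "varying") <- varying
  attr(curve, "spont_rate") <- if (any(blank_ok)) {
    mean(per_trial$blank_rate[blank_ok])
  } else NA_real_
  attr(curve, "spont_sem") <- if (sum(blank_ok) > 1) {
    sd(per_trial$blank_rate[blank_ok]) / sqrt(sum(blank_ok))
  } else 0
  class(curve) <- c("tuning_curve", class(curve))
  curve
}

# --- shared fitting machinery ---------------------------------------------

flat_curve <- function(y) var(y) == 0 || sd(y) < 1e-12 * (abs(mean(y)) + 1)

ve_of <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  max(0, min(1, 1 - sum((obs - pred)^2) / sst))
}

multistart_lm <- function(resid_fn, starts, lower, upper, maxiter = 300) {
  best <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower + 1e-10), upper - 1e-10)
    ft <- tryCatch(
      minpack.lm::nls.lm(p0, lower, upper, resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ft)) next
    rss <- sum(ft$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = ft, rss = rss)
  }
  best
}

no_fit <- function(cls, terms, curve) {
  structure(
    c(setNames(as.list(rep(NA_real_, length(terms))), terms),
      list(variance_explained = NA_real_, converged = FALSE, flagged = TRUE,
           curve = curve)),
    class = c(cls, "tuning_fit")
  )
}

new_tuning_fit <- function(cls, pars, ve, converged, curve) {
  structure(
    c(as.list(pars),
      list(variance_explained = ve, converged = converged,
           flagged = !converged, curve = curve)),
    class = c(cls, "tuning_fit")
  )
}

#' @export
print.tuning_fit <- function(x, ...) {
  terms <- setdiff(names(x), c("variance_explained", "converged", "flagged",
                               "curve"))
  vals <- paste(sprintf("%s=%.4g", terms, unlist(x[terms])), collapse = ", ")
  cat(sprintf("<%s> %s; VE=%.4f%s\n", class(x)[1], vals,
              x$variance_explained, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Tidy methods for geniculate fit objects
#'
#' `tidy()` returns the fitted parameters as a `term`/`estimate` tibble.
#'
#' @param x A fit object.
#' @param ... Unused.
#' @name tidy-geniculate
NULL

#' Glance methods for geniculate fit objects
#'
#' `glance()` returns a one-row tibble of fit quality: variance explained,
#' convergence, and the inclusion flag.
#'
#' @param x A fit object.
#' @param ... Unused.
#' @name glance-geniculate
NULL

#' @rdname tidy-geniculate
#' @method tidy tuning_fit
#' @export
tidy.tuning_fit <- function(x, ...) {
  terms <- setdiff(names(x), c("variance_explained", "converged", "flagged",
                               "curve"))
  tibble::tibble(term = terms, estimate = as.numeric(unlist(x[terms])))
}

#' @rdname glance-geniculate
#' @method glance tuning_fit
#' @export
glance.tuning_fit <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 converged = x$converged, flagged = x$flagged,
                 included = fit_quality_gate(x) == "include")
}

#' Evaluate a fitted tuning curve at new abscissae
#'
#' @param object A `tuning_fit`.
#' @param newdata Numeric abscissae (defaults to a dense grid over the data
#'   range).
#' @param ... Unused.
#' @return Numeric vector of fitted rates.
#' @export
predict.tuning_fit <- function(object, newdata = NULL, ...) {
  x <- object
  if (is.null(newdata)) {
    rng <- range(x$curve$value)
    newdata <- seq(rng[1], rng[2], length.out = 512)
  }
  switch(class(x)[1],
    dog_fit = dog_curve(newdata, x$b, x$kc, x$ks, x$rc, x$rs),
    tf_fit = two_half_gaussian_curve(newdata, x$b1, x$b2, x$a, x$p, x$s),
    crf_fit = hyperbolic_curve(newdata, x$b, x$rmax, x$h, x$n),
    abort("unknown fit class")
  )
}

# --- DoG spatial-frequency fit --------------------------------------------

#' Fit a difference-of-Gaussians spatial-frequency tuning curve
#'
#' Bounded least squares of
#' `R(v) = b + (kc - b)(exp(-(pi rc v)^2) - ks exp(-(pi rs v)^2))` with
#' `rs > rc > 0` (enforced by fitting `log(rs/rc)`) and `ks >= 0`.
#' Variance explained is `1 - SSres/SStot`. A flat (zero-variance) curve
#' returns a flagged no-fit.
#'
#' @param curve A `tuning_curve` (or tibble with `value`, `mean_rate`).
#' @param n_starts Jittered multi-starts (default 10).
#' @return A `dog_fit` with parameters `b`, `kc`, `ks`, `rc`, `rs`.
#' @export
fit_dog <- function(curve, n_starts = 10L) {
  v <- curve$value; y <- curve$mean_rate
  if (length(v) < 5) abort("need at least 5 spatial frequencies")
  terms <- c("b", "kc", "ks", "rc", "rs")
  if (flat_curve(y)) return(no_fit("dog_fit", terms, curve))

  # parameters: b, kc, ks, rc, log_ratio (rs = rc * exp(log_ratio))
  resid_fn <- function(par) {
    rs <- par[4] * exp(par[5])
    dog_curve(v, par[1], par[2], par[3], par[4], rs) - y
  }
  rng <- max(y) - min(y)
  lower <- c(0, 0, 0, 1e-3, 1e-3)
  upper <- c(max(y) + rng, 3 * max(y) + 1, 5, 100, 6)
  base0 <- c(min(y), max(y), 0.8, 1 / (pi * max(v[which.max(y)], 0.03)), log(4))
  starts <- c(list(base0), with_seed(40411L, lapply(seq_len(n_starts - 1), function(i) {
    c(min(y) * runif(1, 0, 1.5), max(y) * runif(1, 0.5, 2),
      runif(1, 0.1, 1.2), runif(1, 0.5, 8), log(runif(1, 1.5, 8)))
  })))
  best <- multistart_lm(resid_fn, starts, lower, upper)
  if (is.null(best)) return(no_fit("dog_fit", terms, curve))
  p <- best$fit$par
  pars <- c(b = p[1], kc = p[2], ks = p[3], rc = p[4], rs = p[4] * exp(p[5]))
  ve <- ve_of(y, dog_curve(v, pars["b"], pars["kc"], pars["ks"],
                           pars["rc"], pars["rs"]))
  new_tuning_fit("dog_fit", pars, ve, best$fit$info %in% 1:4, curve)
}

#' Fit a two-half-Gaussian temporal-frequency tuning curve
#'
#' Piecewise Gaussian continuous at the peak: baseline `b1` below the peak
#' frequency `p`, `b2` above, common amplitude `a` and width `s`.
#'
#' @inheritParams fit_dog
#' @return A `tf_fit` with parameters `b1`, `b2`, `a`, `p`, `s`.
#' @export
fit_two_half_gaussian <- function(curve, n_starts = 10L) {
  w <- curve$value; y <- curve$mean_rate
  if (length(w) < 5) abort("need at least 5 temporal frequencies")
  terms <- c("b1", "b2", "a", "p", "s")
  if (flat_curve(y)) return(no_fit("tf_fit", terms, curve))

  resid_fn <- function(par) {
    two_half_gaussian_curve(w, par[1], par[2], par[3], par[4], par[5]) - y
  }
  rng <- diff(range(w))
  lower <- c(0, 0, 1e-6, min(w) / 4, rng / 100)
  upper <- c(max(y) + 1, max(y) + 1, 3 * max(y) + 1, max(w) * 4, 4 * rng)
  base0 <- c(min(y), min(y), max(y), w[which.max(y)], rng / 3)
  starts <- c(list(base0), with_seed(50511L, lapply(seq_len(n_starts - 1), function(i) {
    c(min(y) * runif(1, 0, 1.5), min(y) * runif(1, 0, 1.5),
      max(y) * runif(1, 0.5, 2),
      runif(1, min(w), max(w)), rng * runif(1, 0.05, 1))
  })))
  best <- multistart_lm(resid_fn, starts, lower, upper)
  if (is.null(best)) return(no_fit("tf_fit", terms, curve))
  p <- best$fit$par
  pars <- c(b1 = p[1], b2 = p[2], a = p[3], p = p[4], s = p[5])
  ve <- ve_of(y, two_half_gaussian_curve(w, p[1], p[2], p[3], p[4], p[5]))
  converged <- best$fit$info %in% 1:4 && pars["a"] >= max(pars["b1"], pars["b2"])
  new_tuning_fit("tf_fit", pars, ve, converged, curve)
}

#' Fit a hyperbolic (Naka-Rushton) contrast-response function
#'
#' `R(c) = b + (Rmax - b) c^n / (c^n + h^n)` with bounds `n` in (0, 10\] and
#' `h` in (0, 1.5\].
#'
#' @inheritParams fit_dog
#' @return A `crf_fit` with parameters `b`, `rmax`, `h`, `n`.
#' @export
fit_hyperbolic <- function(curve, n_starts = 10L) {
  cc <- curve$value; y <- curve$mean_rate
  if (length(cc) < 4) abort("need at least 4 contrast levels")
  terms <- c("b", "rmax", "h", "n")
  if (flat_curve(y)) return(no_fit("crf_fit", terms, curve))

  resid_fn <- function(par) {
    hyperbolic_curve(cc, par[1], par[2], par[3], par[4]) - y
  }
  lower <- c(0, 1e-6, 1e-3, 1e-3)
  upper <- c(max(y) + 1, 5 * max(y) + 1, 1.5, 10)
  base0 <- c(min(y), max(y), 0.5, 2)
  starts <- c(list(base0), with_seed(60611L, lapply(seq_len(n_starts - 1), function(i) {
    c(min(y) * runif(1, 0, 1.5), max(y) * runif(1, 0.5, 3),
      runif(1, 0.05, 1.4), runif(1, 0.3, 8))
  })))
  best <- multistart_lm(resid_fn, starts, lower, upper)
  if (is.null(best)) return(no_fit("crf_fit", terms, curve))
  p <- best$fit$par
  pars <- c(b = p[1], rmax = p[2], h = p[3], n = p[4])
  ve <- ve_of(y, hyperbolic_curve(cc, p[1], p[2], p[3], p[4]))
  new_tuning_fit("crf_fit", pars, ve, best$fit$info %in% 1:4, curve)
}

#' Fit-quality inclusion gate
#'
#' A unit's fit is included in population analyses only when it explains at
#' least 95% of the response variance (inclusive boundary).
#'
#' @param fit A `tuning_fit` (or a plain VE number).
#' @param threshold Variance-explained threshold, default 0.95.
#' @return `"include"` or `"exclude"`.
#' @export
fit_quality_gate <- function(fit, threshold = 0.95) {
  ve <- if (inherits(fit, "tuning_fit") || is.list(fit)) {
    fit$variance_explained
  } else {
    fit
  }
  if (is.null(ve) || is.na(ve)) return("exclude")
  if (isTRUE(fit$flagged)) return("exclude")
  if (ve >= threshold) "include" else "exclude"
}
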