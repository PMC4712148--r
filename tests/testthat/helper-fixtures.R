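# shared fixtures and independent oracles, built in code at test time

# minimal grating-like protocol: one condition repeated n times
toy_protocol <- function(n_trials = 6, duration_s = 7, value = 0.03,
                         varying = "sf_cpd") {
  p <- tibble::tibble(
    trial_index = seq_len(n_trials),
    condition_id = "c1",
    kind = "grating",
    sf_cpd = if (varying == "sf_cpd") value else 0.03,
    tf_hz = if (varying == "tf_hz") value else 1,
    contrast = if (varying == "contrast") value else 0.98,
    direction_deg = if (varying == "direction_deg") value else 0,
    repeat_index = seq_len(n_trials),
    duration_s = duration_s,
    pre_blank_s = 1, post_blank_s = 1
  )
  slot <- p$pre_blank_s + p$duration_s + p$post_blank_s
  p$t_start_s <- cumsum(dplyr::lag(slot, default = 0)) + p$pre_blank_s
  p$t_end_s <- p$t_start_s + p$duration_s
  attr(p, "varying") <- varying
  p
}

# spikes tibble from a list of per-trial spike-time vectors
toy_spikes <- function(times_by_trial, condition_id = "c1",
                       unit_id = "unit_001") {
  empty <- tibble::tibble(unit_id = character(), condition_id = character(),
                          trial_index = integer(), spike_time_s = numeric())
  dplyr::bind_rows(empty, lapply(seq_along(times_by_trial), function(i) {
    st <- times_by_trial[[i]]
    if (length(st) == 0) return(NULL)
    tibble::tibble(unit_id = unit_id, condition_id = condition_id,
                   trial_index = i, spike_time_s = sort(st))
  }))
}

# independent inhomogeneous-Poisson sampler (thinning), used as a spike
# source for estimator checks; deliberately separate from the package's
rate_spikes <- function(rate_fn, t_max, rate_max, n_trials = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_trials), function(i) {
    n <- rpois(1, rate_max * t_max)
    tt <- sort(runif(n, 0, t_max))
    tt[runif(n) < rate_fn(tt) / rate_max]
  })
}

# exhaustive-enumeration two-sided Mann-Whitney p for small samples, no ties
mw_exact_p_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  idx <- utils::combn(n + m, n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(idx, 2, function(ii) {
    sum(rank(pooled)[ii]) - n * (n + 1) / 2
  })
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Kruskal-Wallis H from the rank formula, no tie correction
kw_h_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  ri <- split(r, rep(seq_along(groups), lengths(groups)))
  12 / (n * (n + 1)) * sum(vapply(ri, function(rr) {
    sum(rr)^2 / length(rr)
  }, numeric(1))) - 3 * (n + 1)
}

# small shared movie for spectrum tests (cached across tests in one run)
.test_env <- new.env(parent = emptyenv())
spectrum_movie <- function() {
  if (is.null(.test_env$movie)) {
    spec <- noise_movie_spec(n_x = 64, n_y = 64,
                             movie_duration_s = 512 / 30,
                             grey_duration_s = 0, n_sessions = 1L,
                             seed = 7L)
    .test_env$movie <- generate_noise_movie(spec)
  }
  .test_env$movie
}
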