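test_that("population sampling is seeded, labelled, and respects the class mix", {
  a <- sample_population(24, seed = 7)
  b <- sample_population(24, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 24)
  expect_equal(nrow(sample_population(0, seed = 1)), 0)
  expect_true(all(a$sf_rs > a$sf_rc), TRUE)
  expect_true(all(a$rf_sx > 0 & a$rf_sy > 0 & a$spont_rate >= 0))

  all_ds <- sample_population(10, seed = 3,
                              class_mix = list(ds = 1.0, os = 0))
  expect_true(all(all_ds$selectivity == "ds"))
  expect_true(all(all_ds$dsi_target >= 0.5))
})

test_that("grating drive obeys the separable forward-model identities", {
  nrn <- as.list(sample_population(1, seed = 5)[1, ])
  tt <- seq(0, 1 - 1e-4, by = 1e-4)

  # zero contrast leaves only the spontaneous rate
  r0 <- expected_grating_rate(nrn, list(sf_cpd = 0.03, tf_hz = 1,
                                        contrast = 0, direction_deg = 0), tt)
  expect_equal(r0, rep(nrn$spont_rate, length(tt)))

  # raised-cosine modulation (depth 1): F1/F0 of the evoked rate is 1
  nrn$mod_depth <- 1; nrn$spont_rate <- 0
  r1 <- expected_grating_rate(nrn, list(sf_cpd = 0.03, tf_hz = 1,
                                        contrast = 0.98, direction_deg = 0), tt)
  f0 <- mean(r1)
  f1 <- 2 * Mod(mean(r1 * exp(-2i * pi * tt)))
  expect_equal(f1 / f0, 1, tolerance = 1e-6)

  # unmodulated drive: F1 vanishes
  nrn$mod_depth <- 0
  r2 <- expected_grating_rate(nrn, list(sf_cpd = 0.03, tf_hz = 1,
                                        contrast = 0.98, direction_deg = 0), tt)
  expect_lt(2 * Mod(mean(r2 * exp(-2i * pi * tt))) / mean(r2), 1e-9)
  expect_true(all(r1 >= 0) && all(r2 >= 0))
})

test_that("trial simulation is Poisson with the model mean and seeded", {
  nrn <- sample_population(1, seed = 2)[1, ]
  nrn$r_evoked <- 0
  nrn$spont_rate <- 10
  prot <- toy_protocol(n_trials = 300, duration_s = 2)
  sp <- simulate_trials(nrn, prot, seed = 9)
  counts <- vapply(seq_len(300), function(i) {
    st <- sp$spike_time_s[sp$trial_index == i]
    sum(st >= 0 & st < 2)
  }, numeric(1))
  mu <- mean(counts)
  expect_lt(abs(mu - 20), 3 * sqrt(20 / 300))
  fano <- var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / 300))
  expect_identical(sp, simulate_trials(nrn, prot, seed = 9))
  # blanks carry only spontaneous spikes, inside their windows
  expect_true(all(sp$spike_time_s >= -1 & sp$spike_time_s < 3))

  nrn$spont_rate <- 0
  expect_equal(nrow(simulate_trials(nrn, prot, seed = 1)), 0)
})

test_that("noise-free tuning curves refit to the generating parameters", {
  pop <- sample_population(5, seed = 31)
  sfs <- grating_sets$spatial$sf_cpd
  tfs <- grating_sets$temporal$tf_hz
  ccs <- grating_sets$contrast$contrast
  for (i in seq_len(nrow(pop))) {
    nrn <- as.list(pop[i, ])
    # unmodulated drive isolates the tuning families: the temporal protocol's
    # trial length is not an integer cycle count at every drift frequency, so
    # a modulated rate's trial mean carries a small truncation distortion
    nrn$mod_depth <- 0
    mean_rate_at <- function(cond) {
      tt <- seq(0, 7 - 5e-5, by = 1e-4)
      mean(expected_grating_rate(nrn, cond, tt))
    }
    sf_y <- vapply(sfs, function(v) {
      mean_rate_at(list(sf_cpd = v, tf_hz = 1, contrast = 0.98,
                        direction_deg = 0))
    }, numeric(1))
    fd <- fit_dog(tibble::tibble(value = sfs, mean_rate = sf_y))
    expect_lt(abs(fd$rc / nrn$sf_rc - 1), 1e-4)
    expect_lt(abs(fd$rs / nrn$sf_rs - 1), 1e-4)
    expect_lt(abs(fd$ks / nrn$sf_ks - 1), 1e-4)

    tf_y <- vapply(tfs, function(w) {
      mean_rate_at(list(sf_cpd = 0.03, tf_hz = w, contrast = 0.98,
                        direction_deg = 0))
    }, numeric(1))
    ftf <- fit_two_half_gaussian(tibble::tibble(value = tfs, mean_rate = tf_y))
    expect_lt(abs(ftf$p / nrn$tf_p - 1), 1e-4)
    expect_lt(abs(ftf$s / nrn$tf_s - 1), 1e-4)

    cr_y <- vapply(ccs, function(cc) {
      mean_rate_at(list(sf_cpd = 0.03, tf_hz = 1, contrast = cc,
                        direction_deg = 0))
    }, numeric(1))
    fcr <- fit_hyperbolic(tibble::tibble(value = ccs, mean_rate = cr_y))
    expect_lt(abs(fcr$h / nrn$cr_h - 1), 1e-3)
    expect_lt(abs(fcr$n / nrn$cr_n - 1), 1e-3)
  }
})

test_that("flicker simulation locks to the preferred polarity and adapts", {
  prot <- flicker_protocol(200)
  nrn <- sample_population(1, seed = 8)[1, ]
  nrn$polarity <- "ON"; nrn$spont_rate <- 1; nrn$r_evoked <- 30

  # polarity lock: a sustained ON cell fires overwhelmingly in white epochs
  nrn$adaptation_tau <- 0.02; nrn$sustained_frac <- 1
  spl <- simulate_flicker_response(nrn, prot, seed = 5)
  expect_gt(sum(spl$condition_id == "flicker_white"),
            5 * sum(spl$condition_id == "flicker_black"))

  nrn$adaptation_tau <- 0.01; nrn$sustained_frac <- 0
  sp <- simulate_flicker_response(nrn, prot, seed = 2)
  ts <- compute_ts_index(sp)
  expect_gt(ts$ts_index, 2)
  expect_identical(ts$temporal_class, "transient")
  expect_identical(ts$preferred_epoch, "flicker_white")

  # no adaptation: flat step response, index near 1
  nrn$sustained_frac <- 1
  sp2 <- simulate_flicker_response(nrn, prot, seed = 3)
  ts2 <- compute_ts_index(sp2)
  expect_lt(abs(ts2$ts_index - 1), 0.25)

  nrn$polarity <- "OFF"
  sp3 <- simulate_flicker_response(nrn, prot, seed = 4)
  expect_gt(sum(sp3$condition_id == "flicker_black"),
            sum(sp3$condition_id == "flicker_white"))
})

test_that("movie response is an LNP cascade with seeded Poisson output", {
  spec <- noise_movie_spec(n_x = 32, n_y = 32, movie_duration_s = 30,
                           grey_duration_s = 0, n_sessions = 1L, seed = 12L)
  m <- generate_noise_movie(spec)
  nrn <- sample_population(1, seed = 14, rf_extent_deg = 5)[1, ]
  sp <- simulate_movie_response(nrn, m, seed = 6)
  expect_identical(sp, simulate_movie_response(nrn, m, seed = 6))
  # zero gain: homogeneous Poisson at the spontaneous rate
  sp0 <- simulate_movie_response(nrn, m, seed = 6, drive_sd = 0)
  expect_lt(abs(nrow(sp0) / 30 - nrn$spont_rate),
            4 * sqrt(nrn$spont_rate * 30) / 30)
  # RF centre outside the movie extent is rejected
  nrn$rf_xc <- 100
  expect_error(simulate_movie_response(nrn, m, seed = 1), "outside")
})
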