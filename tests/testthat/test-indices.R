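dirs8 <- seq(0, 315, by = 45)

test_that("DSI/OSI vector-sum identities", {
  # single-direction responder
  r <- compute_dsi_osi(c(10, 0, 0, 0, 0, 0, 0, 0), dirs8)
  expect_equal(r$dsi, 1)
  expect_equal(r$osi, 1)
  expect_equal(r$preferred_direction_deg, 0)
  expect_true(r$ds_flag && r$os_flag)

  # uniform response cancels completely
  r2 <- compute_dsi_osi(rep(7, 8), dirs8)
  expect_equal(r2$dsi, 0, tolerance = 1e-12)
  expect_equal(r2$osi, 0, tolerance = 1e-12)
  expect_false(r2$ds_flag || r2$os_flag)

  # opponent case: 10 vs 5 gives DSI = 1/3, OSI = 1
  r3 <- compute_dsi_osi(c(10, 0, 0, 0, 5, 0, 0, 0), dirs8)
  expect_equal(r3$dsi, 1 / 3, tolerance = 1e-12)
  expect_equal(r3$osi, 1, tolerance = 1e-12)
  expect_true(r3$ds_flag) # 0.333... exceeds the 0.33 threshold
  # the threshold itself is strict: an index exactly at it is not selective
  r4 <- compute_dsi_osi(c(10, 0, 0, 0, 5, 0, 0, 0), dirs8,
                        dsi_threshold = 1 / 3)
  expect_false(r4$ds_flag)

  # all-zero response is flagged
  r0 <- compute_dsi_osi(rep(0, 8), dirs8)
  expect_true(r0$flagged)
  expect_true(is.na(r0$dsi))
})

test_that("indices are bounded, scale-invariant, and rotation-equivariant", {
  set.seed(11)
  for (i in 1:50) {
    f <- runif(8, 0, 20)
    r <- compute_dsi_osi(f, dirs8)
    expect_gte(r$dsi, 0); expect_lte(r$dsi, 1)
    expect_gte(r$osi, 0); expect_lte(r$osi, 1)
    r2 <- compute_dsi_osi(2 * f, dirs8)
    expect_equal(r2$dsi, r$dsi, tolerance = 1e-12)
    expect_equal(r2$osi, r$osi, tolerance = 1e-12)
    # rotate stimulus directions by 90 deg
    k <- 2
    rot <- compute_dsi_osi(f[c((8 - k + 1):8, 1:(8 - k))], dirs8)
    expect_equal(rot$dsi, r$dsi, tolerance = 1e-9)
    expect_equal(rot$osi, r$osi, tolerance = 1e-9)
    expect_equal((rot$preferred_direction_deg - r$preferred_direction_deg) %% 360,
                 90, tolerance = 1e-6)
  }
})

test_that("negative spontaneous-subtracted rates are clipped before Eq-style sums", {
  r <- compute_dsi_osi(c(10, -3, -3, -3, 5, -3, -3, -3), dirs8)
  expect_equal(r$dsi, 1 / 3, tolerance = 1e-12)
})

test_that("F1/F0 matches analytic Fourier ratios of known rate profiles", {
  period <- 1
  # raised cosine r(t) = r0 (1 + cos 2 pi t): ratio exactly 1
  rfun <- function(t) 40 * (1 + cos(2 * pi * t))
  tr <- rate_spikes(rfun, t_max = 50, rate_max = 81, n_trials = 60, seed = 3)
  sp <- toy_spikes(tr)
  res <- compute_f1f0(sp, drift_tf_hz = 1, duration_s = 50, spont_rate = 0)
  expect_lt(abs(res$ratio - 1), 0.02)

  # constant rate: ratio ~ 0
  tr2 <- rate_spikes(function(t) rep(40, length(t)), 50, 41, 60, seed = 4)
  res2 <- compute_f1f0(toy_spikes(tr2), 1, 50, 0)
  expect_lt(res2$ratio, 0.02)

  # half-wave rectified cosine: ratio = pi/2
  rfun3 <- function(t) 80 * pmax(0, cos(2 * pi * t))
  tr3 <- rate_spikes(rfun3, 50, 81, 60, seed = 5)
  res3 <- compute_f1f0(toy_spikes(tr3), 1, 50, 0)
  expect_lt(abs(res3$ratio - pi / 2) / (pi / 2), 0.02)
})

test_that("spontaneous rate shifts only F0 and gates the ratio", {
  rfun <- function(t) 5 + 20 * (1 + cos(2 * pi * t))
  tr <- rate_spikes(rfun, 40, 46, 40, seed = 6)
  sp <- toy_spikes(tr)
  res <- compute_f1f0(sp, 1, 40, spont_rate = 5)
  expect_lt(abs(res$ratio - 1), 0.05)
  # spontaneous above the mean rate: undefined ratio, flagged
  res2 <- compute_f1f0(sp, 1, 40, spont_rate = 60)
  expect_true(res2$flagged)
  expect_true(is.na(res2$ratio))
  # non-integer cycle count is rejected
  expect_error(compute_f1f0(sp, 1, 40.3, 0), "integer number")
})

test_that("doubling every rate leaves F1/F0 unchanged", {
  rfun <- function(t) 30 * pmax(0, 1 + 1.5 * cos(2 * pi * t))
  tr <- rate_spikes(rfun, 60, 80, 30, seed = 8)
  tr2 <- rate_spikes(function(t) 2 * rfun(t), 60, 160, 30, seed = 9)
  r1 <- compute_f1f0(toy_spikes(tr), 1, 60, 0)
  r2 <- compute_f1f0(toy_spikes(tr2), 1, 60, 0)
  expect_lt(abs(r1$ratio - r2$ratio), 0.03)
})

test_that("transient/sustained index is the 50 ms / remainder rate ratio", {
  # 20 epochs: 20 early spikes (rate 20/s in 0-50 ms), 55 late spikes
  # (rate 5/s in 50-600 ms) -> index 4.0 exactly
  early <- rep(seq_len(20), each = 1)
  sp <- dplyr::bind_rows(
    tibble::tibble(unit_id = "u", condition_id = "flicker_white",
                   trial_index = rep(1:20, each = 1),
                   spike_time_s = runif(20, 0, 0.05)),
    tibble::tibble(unit_id = "u", condition_id = "flicker_white",
                   trial_index = rep(1:20, length.out = 55),
                   spike_time_s = runif(55, 0.05, 0.6))
  )
  r <- compute_ts_index(sp, preferred = "flicker_white")
  expect_equal(r$ts_index, 4.0, tolerance = 1e-12)
  expect_identical(r$temporal_class, "transient")

  # constant rate: index 1, boundary classified sustained
  spc <- tibble::tibble(unit_id = "u", condition_id = "flicker_white",
                        trial_index = rep(1:10, each = 12),
                        spike_time_s = rep(seq(0.025, 0.575, by = 0.05), 10))
  rc <- compute_ts_index(spc, preferred = "flicker_white")
  expect_equal(rc$ts_index, 1.0, tolerance = 1e-9)
  expect_identical(rc$temporal_class, "sustained")

  # silent late window: infinite index, transient, flagged
  sp_inf <- tibble::tibble(unit_id = "u", condition_id = "flicker_white",
                           trial_index = 1:5,
                           spike_time_s = rep(0.01, 5))
  ri <- compute_ts_index(sp_inf, preferred = "flicker_white")
  expect_identical(ri$ts_index, Inf)
  expect_true(ri$flagged)
  expect_identical(ri$temporal_class, "transient")
})

test_that("spontaneous comes from blanks and evoked from the best grating", {
  prot <- toy_protocol(n_trials = 4, duration_s = 7)
  sp <- toy_spikes(lapply(1:4, function(i) {
    c(runif(2, -1, 0), seq(0.05, 6.95, length.out = 51), runif(2, 7, 8))
  }))
  se <- compute_spontaneous_evoked(sp, prot)
  expect_equal(se$spont_rate, 2, tolerance = 1e-9)
  expect_equal(se$evoked_rate, 51 / 7, tolerance = 1e-9)
  expect_identical(se$evoked_condition_id, "c1")

  # zero spikes everywhere
  se0 <- compute_spontaneous_evoked(sp[0, ], prot)
  expect_equal(se0$spont_rate, 0)
  expect_equal(se0$evoked_rate, 0)
})
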