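test_that("single-spike STA reproduces the triggering frame exactly", {
  spec <- noise_movie_spec(n_x = 16, n_y = 16, movie_duration_s = 4,
                           grey_duration_s = 0, n_sessions = 1L, seed = 21L)
  m <- generate_noise_movie(spec)
  fr <- attr(m, "frame_rate_hz")
  # one spike during frame 60; at lag 0 the STA is that frame minus mid-grey
  sp <- tibble::tibble(unit_id = "u", condition_id = "movie",
                       trial_index = 1L, spike_time_s = 59.5 / fr)
  sta <- compute_sta(sp, m, lag_window = c(0, 0), whiten = FALSE,
                     smooth_sigma_px = 0)
  expect_equal(sta$map, m[60, , ] - 0.5, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sta$n_spikes, 1L)

  # no usable spikes
  sp2 <- tibble::tibble(unit_id = "u", condition_id = "movie",
                        trial_index = 1L, spike_time_s = 1e6)
  expect_error(compute_sta(sp2, m), "no usable spikes")
})

test_that("STA is linear: merged trains give the count-weighted mean map", {
  spec <- noise_movie_spec(n_x = 16, n_y = 16, movie_duration_s = 20,
                           grey_duration_s = 0, n_sessions = 1L, seed = 22L)
  m <- generate_noise_movie(spec)
  set.seed(1)
  t1 <- runif(40, 1, 19); t2 <- runif(25, 1, 19)
  mk <- function(tt) tibble::tibble(unit_id = "u", condition_id = "movie",
                                    trial_index = 1L, spike_time_s = sort(tt))
  s1 <- compute_sta(mk(t1), m, lag_window = c(0, 0), whiten = FALSE,
                    smooth_sigma_px = 0)
  s2 <- compute_sta(mk(t2), m, lag_window = c(0, 0), whiten = FALSE,
                    smooth_sigma_px = 0)
  s12 <- compute_sta(mk(c(t1, t2)), m, lag_window = c(0, 0), whiten = FALSE,
                     smooth_sigma_px = 0)
  w <- c(s1$n_spikes, s2$n_spikes)
  expect_equal(s12$map, (w[1] * s1$map + w[2] * s2$map) / sum(w),
               tolerance = 1e-12)
})

test_that("stimulus-independent spikes leave the STA at the CLT noise floor", {
  spec <- noise_movie_spec(n_x = 32, n_y = 32, movie_duration_s = 240,
                           grey_duration_s = 0, n_sessions = 1L, seed = 23L)
  m <- generate_noise_movie(spec)
  set.seed(42)
  n_spk <- 800
  sp <- tibble::tibble(unit_id = "u", condition_id = "movie",
                       trial_index = 1L,
                       spike_time_s = sort(runif(n_spk, 1, 239)))
  sta <- compute_sta(sp, m, lag_window = c(0, 0), whiten = FALSE,
                     smooth_sigma_px = 0)
  frame_rms <- sd(as.numeric(m - 0.5))
  expect_lt(max(abs(sta$map)), 4 * frame_rms / sqrt(sta$n_spikes))
})

test_that("2D Gaussian fit recovers a rendered field and its symmetries", {
  x <- seq(-20, 20, by = 1)
  z <- gaussian2d_surface(x, x, 1, 10, -5, 6, 6)
  g <- fit_gaussian2d(z, deg_per_pixel = 1)
  expect_lt(abs(g$amp - 1), 1e-3)
  expect_lt(abs(g$xc - 10), 1e-3)
  expect_lt(abs(g$yc - (-5)), 1e-3)
  expect_lt(abs(g$sx - 6), 1e-3)
  expect_lt(abs(g$sy - 6), 1e-3)
  expect_gte(g$variance_explained, 0.999)

  # sign symmetry: negated map gives the same fit with negated amplitude
  g2 <- fit_gaussian2d(-z, deg_per_pixel = 1)
  expect_lt(abs(g2$amp + g$amp), 1e-6)
  expect_lt(abs(g2$sx - g$sx), 1e-6)

  expect_error(fit_gaussian2d(matrix(0, 8, 8), deg_per_pixel = 1),
               "no nonzero extremum")

  td <- tidy(g)
  expect_identical(td$term, c("amp", "xc", "yc", "sx", "sy"))
  expect_true(glance(g)$converged)
})

test_that("anisotropic fields recover both radii", {
  x <- seq(-24, 24, by = 1)
  z <- gaussian2d_surface(x, x, -2, 0, 3, 9, 5)
  g <- fit_gaussian2d(z, deg_per_pixel = 1)
  expect_lt(abs(g$sx - 9), 1e-3)
  expect_lt(abs(g$sy - 5), 1e-3)
  expect_lt(g$amp, 0)
})

test_that("polarity follows the fitted amplitude sign", {
  expect_identical(classify_polarity(list(amp = 2))$polarity, "ON")
  expect_identical(classify_polarity(list(amp = -2))$polarity, "OFF")
  z <- classify_polarity(list(amp = 0))
  expect_true(is.na(z$polarity) && z$flagged)
})

test_that("circularity rule uses the inclusive 0.7-1.3 ratio band", {
  mk <- function(sx, sy) list(sx = sx, sy = sy)
  r <- classify_circularity(mk(6, 6))
  expect_equal(r$radius_ratio, 1)
  expect_identical(r$circularity, "circular")
  expect_equal(r$mean_radius_deg, 6)

  r2 <- classify_circularity(mk(9, 6))
  expect_equal(r2$radius_ratio, 1.5)
  expect_identical(r2$circularity, "non_circular")
  expect_true(is.na(r2$mean_radius_deg))

  r3 <- classify_circularity(mk(4.2, 6))
  expect_equal(r3$radius_ratio, 0.7)
  expect_identical(r3$circularity, "circular")
  r4 <- classify_circularity(mk(7.8, 6))
  expect_equal(r4$radius_ratio, 1.3)
  expect_identical(r4$circularity, "circular")
})

test_that("simulated LNP neurons round-trip through the STA stage", {
  spec <- noise_movie_spec(movie_duration_s = 150, grey_duration_s = 0,
                           n_sessions = 1L, seed = 24L)
  m <- generate_noise_movie(spec)
  pop <- sample_population(2, seed = 33, rf_extent_deg = 8)
  pop$polarity <- c("ON", "OFF")
  pop$rf_amp <- c(1, -1)
  x <- (1:64) - 32.5
  for (i in 1:2) {
    nrn <- pop[i, ]
    sp <- simulate_movie_response(nrn, m, seed = 50 + i)
    sta <- compute_sta(sp, m)
    rf <- gaussian2d_surface(x, x, nrn$rf_amp, nrn$rf_xc, nrn$rf_yc,
                             nrn$rf_sx, nrn$rf_sy)
    expect_gt(cor(as.numeric(sta$map), as.numeric(rf)), 0.8)
    g <- fit_gaussian2d(sta)
    expect_identical(classify_polarity(g)$polarity, nrn$polarity)
    expect_lt(abs(g$xc - nrn$rf_xc), 1.5)
    expect_lt(abs(g$yc - nrn$rf_yc), 1.5)
  }
})

test_that("shifting a neuron's field shifts the fitted centre equivariantly", {
  spec <- noise_movie_spec(movie_duration_s = 150, grey_duration_s = 0,
                           n_sessions = 1L, seed = 25L)
  m <- generate_noise_movie(spec)
  nrn <- sample_population(1, seed = 44, rf_extent_deg = 4)[1, ]
  g1 <- fit_gaussian2d(compute_sta(simulate_movie_response(nrn, m, seed = 9),
                                   m))
  nrn$rf_xc <- nrn$rf_xc + 6
  nrn$rf_yc <- nrn$rf_yc - 4
  g2 <- fit_gaussian2d(compute_sta(simulate_movie_response(nrn, m, seed = 9),
                                   m))
  expect_lt(abs((g2$xc - g1$xc) - 6), 1)
  expect_lt(abs((g2$yc - g1$yc) - (-4)), 1)
})
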