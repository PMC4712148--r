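test_that("tuning curves average trial rates and attach spontaneous rates", {
  prot <- toy_protocol(n_trials = 6, duration_s = 7)
  counts <- c(70, 63, 77, 70, 63, 77)
  sp <- toy_spikes(lapply(counts, function(n) seq(0.01, 6.99, length.out = n)))
  cv <- build_tuning_curve(sp, prot)
  expect_equal(cv$mean_rate, 10.0)
  expect_equal(cv$n_repeats, 6L)
  # no blank spikes: spontaneous rate zero
  expect_equal(attr(cv, "spont_rate"), 0)

  # empty trials give zero rate and zero SEM
  sp0 <- toy_spikes(list(numeric(0)))[0, ]
  cv0 <- build_tuning_curve(sp0, toy_protocol(n_trials = 3))
  expect_equal(cv0$mean_rate, 0)
  expect_equal(cv0$sem_rate, 0)

  # unknown conditions are rejected by name
  bad <- toy_spikes(list(c(1, 2)), condition_id = "zzz")
  expect_error(build_tuning_curve(bad, prot), "zzz")
})

test_that("blank-period spikes define the spontaneous rate", {
  prot <- toy_protocol(n_trials = 4, duration_s = 7)
  sp <- toy_spikes(lapply(1:4, function(i) {
    c(runif(4, -1, 0), runif(70, 0, 7), runif(4, 7, 8))
  }))
  cv <- build_tuning_curve(sp, prot)
  expect_equal(attr(cv, "spont_rate"), 4, tolerance = 1e-9)
})

test_that("all three families refit their own noise-free renders", {
  set.seed(77)
  sfs <- grating_sets$spatial$sf_cpd
  for (i in 1:10) {
    b <- runif(1, 0, 4); kc <- b + runif(1, 8, 30)
    ks <- runif(1, 0.3, 0.95); rc <- runif(1, 1.5, 4)
    rs <- rc * runif(1, 2.5, 6)
    y <- dog_curve(sfs, b, kc, ks, rc, rs)
    f <- fit_dog(tibble::tibble(value = sfs, mean_rate = y))
    expect_gte(f$variance_explained, 0.999)
    for (nm in c("b", "kc", "ks", "rc", "rs")) {
      truth <- get(nm)
      expect_lt(abs(f[[nm]] - truth) / max(abs(truth), 1e-6), 1e-3)
    }
  }
  tfs <- grating_sets$temporal$tf_hz
  for (i in 1:10) {
    a <- runif(1, 8, 30); b1 <- runif(1, 0, 0.3) * a; b2 <- runif(1, 0, 0.3) * a
    p <- runif(1, 1.5, 5); s <- runif(1, 1.2, 3)
    y <- two_half_gaussian_curve(tfs, b1, b2, a, p, s)
    f <- fit_two_half_gaussian(tibble::tibble(value = tfs, mean_rate = y))
    expect_gte(f$variance_explained, 0.999)
    for (nm in c("b1", "b2", "a", "p", "s")) {
      expect_lt(abs(f[[nm]] - get(nm)) / max(abs(get(nm)), 1e-2), 2e-3)
    }
  }
  ccs <- grating_sets$contrast$contrast
  for (i in 1:10) {
    b <- runif(1, 0, 3); rmax <- b + runif(1, 6, 25)
    h <- runif(1, 0.2, 0.8); n <- runif(1, 1.2, 4)
    y <- hyperbolic_curve(ccs, b, rmax, h, n)
    f <- fit_hyperbolic(tibble::tibble(value = ccs, mean_rate = y))
    expect_gte(f$variance_explained, 0.999)
    for (nm in c("b", "rmax", "h", "n")) {
      expect_lt(abs(f[[nm]] - get(nm)) / max(abs(get(nm)), 1e-2), 2e-3)
    }
  }
})

test_that("flat curves are flagged instead of fitted", {
  flat <- tibble::tibble(value = grating_sets$spatial$sf_cpd, mean_rate = 5)
  expect_true(fit_dog(flat)$flagged)
  flat_tf <- tibble::tibble(value = grating_sets$temporal$tf_hz, mean_rate = 3)
  expect_true(fit_two_half_gaussian(flat_tf)$flagged)
  flat_cr <- tibble::tibble(value = grating_sets$contrast$contrast,
                            mean_rate = 2)
  expect_true(fit_hyperbolic(flat_cr)$flagged)
  expect_identical(fit_quality_gate(fit_dog(flat)), "exclude")
})

test_that("noisy curves still localize parameters within 15% (median)", {
  set.seed(101)
  sfs <- grating_sets$spatial$sf_cpd
  err_rc <- err_rs <- numeric(20)
  for (i in 1:20) {
    y <- dog_curve(sfs, 1, 21, 0.85, 2.5, 10) + rnorm(length(sfs), 0, 1)
    f <- fit_dog(tibble::tibble(value = sfs, mean_rate = y))
    expect_lt(f$variance_explained, 1)
    err_rc[i] <- abs(f$rc / 2.5 - 1)
    err_rs[i] <- abs(f$rs / 10 - 1)
  }
  expect_lt(median(err_rc), 0.15)
  expect_lt(median(err_rs), 0.15)
})

test_that("fits are equivariant under uniform rate rescaling", {
  sfs <- grating_sets$spatial$sf_cpd
  y <- dog_curve(sfs, 1.5, 20, 0.8, 2.5, 9)
  f1 <- fit_dog(tibble::tibble(value = sfs, mean_rate = y))
  f2 <- fit_dog(tibble::tibble(value = sfs, mean_rate = 3 * y))
  expect_lt(abs(f2$b / f1$b - 3), 1e-6)
  expect_lt(abs(f2$kc / f1$kc - 3), 1e-6)
  expect_lt(abs(f2$ks - f1$ks), 1e-6)
  expect_lt(abs(f2$rc - f1$rc), 1e-6)
  expect_lt(abs(f2$rs - f1$rs), 1e-6)

  ccs <- grating_sets$contrast$contrast
  yc <- hyperbolic_curve(ccs, 1, 12, 0.45, 2.2)
  g1 <- fit_hyperbolic(tibble::tibble(value = ccs, mean_rate = yc))
  g2 <- fit_hyperbolic(tibble::tibble(value = ccs, mean_rate = 2 * yc))
  expect_lt(abs(g2$h - g1$h), 1e-6)
  expect_lt(abs(g2$n - g1$n), 1e-6)
})

test_that("fitted contrast curves are non-decreasing in contrast", {
  set.seed(55)
  ccs <- grating_sets$contrast$contrast
  for (i in 1:10) {
    y <- hyperbolic_curve(ccs, runif(1, 0, 2), runif(1, 8, 25),
                          runif(1, 0.2, 0.9), runif(1, 1, 4)) +
      rnorm(length(ccs), 0, 0.5)
    f <- fit_hyperbolic(tibble::tibble(value = ccs, mean_rate = y))
    if (f$flagged) next
    grid <- predict(f, seq(0, 1, length.out = 512))
    expect_true(all(diff(grid) >= -1e-9))
  }
})

test_that("variance-explained gate is inclusive at its threshold", {
  expect_identical(fit_quality_gate(list(variance_explained = 0.96,
                                         flagged = FALSE)), "include")
  expect_identical(fit_quality_gate(list(variance_explained = 0.95,
                                         flagged = FALSE)), "include")
  expect_identical(fit_quality_gate(list(variance_explained = 0.80,
                                         flagged = FALSE)), "exclude")
  expect_identical(fit_quality_gate(list(variance_explained = NA_real_,
                                         flagged = TRUE)), "exclude")
})

test_that("tidy and glance expose parameters and fit quality", {
  sfs <- grating_sets$spatial$sf_cpd
  f <- fit_dog(tibble::tibble(value = sfs,
                              mean_rate = dog_curve(sfs, 0, 20, 0.9, 2, 10)))
  td <- tidy(f)
  expect_identical(td$term, c("b", "kc", "ks", "rc", "rs"))
  gl <- glance(f)
  expect_true(gl$included)
  expect_gte(gl$variance_explained, 0.999)
})
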