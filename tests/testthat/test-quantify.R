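test_that("noiseless round trip recovers amplitudes to high precision", {
  sp <- simulate_spectrum(ff = 10, snr = Inf)
  fit <- fit_spectrum(sp)
  truth <- sp$truth$amplitudes0 * exp(-30 / default_basis()$t2)
  expect_equal(setNames(fit$amplitude, fit$name), truth[fit$name],
               tolerance = 1e-6)
  prof <- quantify_spectrum(sp)
  expect_equal(prof$ff, 10, tolerance = 1e-6)
  expect_equal(prof$f_si, 0.85, tolerance = 1e-6)
  expect_equal(prof$f_ui, 0.05, tolerance = 1e-6)
  expect_equal(prof$f_pui, 0.02, tolerance = 1e-6)
})

test_that("noisy amplitudes are recovered without material bias", {
  # Monte-Carlo calibration at snr = 50: mean recovered amplitude within
  # 3 standard errors of truth for the major signals
  seeds <- 1:100
  fits <- lapply(seeds, function(s) {
    f <- fit_spectrum(simulate_spectrum(ff = 15, snr = 50, seed = s))
    setNames(f$amplitude, f$name)
  })
  sp <- simulate_spectrum(ff = 15, snr = Inf)
  truth <- sp$truth$amplitudes0 * exp(-30 / default_basis()$t2)
  for (sig in c("Lip13", "Water")) {
    vals <- vapply(fits, `[[`, numeric(1), sig)
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - truth[[sig]]), 3 * se + 1e-9)
  }
})

test_that("T2 estimation matches closed forms and flags degeneracy", {
  # two exact points from A = 100, T2 = 60
  est <- estimate_t2(c(30, 90), c(100 * exp(-30 / 60), 100 * exp(-90 / 60)))
  expect_equal(est$t2, 60, tolerance = 1e-6)
  expect_equal(est$a0, 100, tolerance = 1e-6)

  # noiseless six-echo water series recovers 27 ms
  tes <- c(30, 50, 68, 135, 180, 270)
  series <- simulate_te_series(ff = 10, snr = Inf)
  water <- vapply(series, function(s) {
    f <- fit_spectrum(s); f$amplitude[f$name == "Water"]
  }, numeric(1))
  expect_equal(estimate_t2(tes, water)$t2, 27, tolerance = 1e-4)

  # constant amplitudes: no decay, flagged non-physical
  flat <- estimate_t2(tes, rep(5, 6))
  expect_identical(flat$t2, Inf)
  expect_false(flat$physical)

  # non-positive amplitudes dropped with warning; < 2 usable points fail
  expect_warning(estimate_t2(c(30, 60, 90), c(10, -1, 2)), "dropped")
  expect_error(suppressWarnings(estimate_t2(c(30, 60), c(10, -1))),
               "at least two")
})

test_that("T2 correction is the exact TE = 0 extrapolation", {
  expect_equal(t2_correct(100, 0, 60), 100)
  expect_equal(t2_correct(100, 30, 60), 100 * exp(0.5))
  expect_equal(t2_correct(100, 30, 27), 100 * exp(30 / 27))
  # multiplicative, order preserving, factor >= 1
  expect_equal(t2_correct(7 * 3, 40, 50), 7 * t2_correct(3, 40, 50))
  x <- c(1, 2, 5)
  expect_true(all(diff(t2_correct(x, 25, 60)) > 0))
  expect_true(all(t2_correct(x, 25, 60) >= x))
})

test_that("fat fraction arithmetic and monotonicity", {
  expect_equal(compute_ff(0, 5), 0)
  expect_equal(compute_ff(7, 7), 50)
  expect_equal(compute_ff(10, 90), 10)
  expect_error(compute_ff(0, 0), "both zero")
  # strictly increasing in lipid, decreasing in water
  expect_true(all(diff(compute_ff(c(1, 2, 3), 10)) > 0))
  expect_true(all(diff(compute_ff(5, c(10, 20, 30))) < 0))
})

test_that("hydrogen fractions follow the published definitions", {
  amps <- c(Lip09 = 0.1, Lip13 = 0.6, Lip16 = 0.1, Lip21 = 0.08,
            Lip24 = 0.05, Lip28 = 0.04, Lip53 = 0.03)
  fr <- compute_fractions(amps)
  expect_equal(fr$f_si, 0.85)
  expect_equal(fr$f_ui, 0.08)
  expect_equal(fr$f_pui, 0.04)
  # no unsaturation
  amps0 <- amps; amps0[c("Lip21", "Lip28")] <- 0
  fr0 <- compute_fractions(amps0)
  expect_equal(fr0$f_ui, 0)
  expect_equal(fr0$f_pui, 0)
  expect_error(compute_fractions(amps * 0), "zero")
})

test_that("closure identity and fraction ordering hold on random amplitudes", {
  set.seed(202)
  for (i in 1:200) {
    a <- setNames(runif(7), c("Lip09", "Lip13", "Lip16", "Lip21", "Lip24",
                              "Lip28", "Lip53"))
    fr <- compute_fractions(a)
    D <- sum(a)
    expect_equal(fr$f_si + (a[["Lip21"]] + a[["Lip28"]] + a[["Lip53"]]) / D,
                 1, tolerance = 1e-12)
    expect_gte(fr$f_ui, fr$f_pui)
  }
})

test_that("TE-series quantification estimates T2 and falls back when unstable", {
  series <- simulate_te_series(ff = 15, snr = 5000, seed = 2)
  prof <- quantify_te_series(series)
  expect_equal(prof$t2_water, 27, tolerance = 0.05)
  expect_equal(prof$t2_lipids, 60, tolerance = 0.1)
  expect_match(prof$t2_source, "estimated")
  expect_equal(prof$ff, 15, tolerance = 0.5)
  # demand an unattainable precision: the fixed fallback is used
  noisy <- simulate_te_series(ff = 2, snr = 12, seed = 5)
  prof2 <- quantify_te_series(noisy, max_rel_se = 1e-9)
  expect_identical(prof2$t2_water, 27)
  expect_identical(prof2$t2_lipids, 60)
  expect_match(prof2$t2_source, "fixed")
})

test_that("cohort-scale orderings match the calibrated biology", {
  cohort <- simulate_cohort(seed = 5)
  med <- tapply(cohort$ff, cohort$group, median)
  expect_true(med[["NoS"]] < med[["MASLD"]] && med[["MASLD"]] < med[["MASH"]])
  fui <- tapply(cohort$f_ui, cohort$group, median)
  expect_gt(fui[["NoS"]], fui[["MASH"]])
})
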