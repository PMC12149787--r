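test_that("cohort generation reproduces configured group sizes and is seeded", {
  cohort <- simulate_cohort(cohort_config(), seed = 7)
  expect_equal(as.vector(table(cohort$group)), c(90, 20, 17))
  expect_equal(nrow(cohort), 127)
  expect_identical(cohort, simulate_cohort(cohort_config(), seed = 7))
  expect_false(identical(cohort, simulate_cohort(cohort_config(), seed = 8)))
  # all configured variables present and positive
  cfg <- cohort_config()
  expect_true(all(cfg$variables %in% names(cohort)))
  expect_true(all(as.matrix(cohort[cfg$variables]) > 0))
})

test_that("marginals converge to the configured medians and quartiles", {
  vars <- unique(default_summaries()$variable)
  identity_dep <- diag(length(vars))
  dimnames(identity_dep) <- list(vars, vars)
  cfg <- cohort_config(n_per_group = c(NoS = 100, MASLD = 100, MASH = 10000),
                       dependence = identity_dep)
  cohort <- simulate_cohort(cfg, seed = 11)
  mash <- cohort[cohort$group == "MASH", ]
  # MASH fat-fraction median within 5% of the calibrated 14.81
  expect_lt(abs(median(mash$ff) - 14.81) / 14.81, 0.05)
  expect_lt(abs(quantile(mash$ff, 0.25) - 9.38) / 9.38, 0.08)
  expect_lt(abs(quantile(mash$ff, 0.75) - 25.31) / 25.31, 0.08)
  # a truncated-normal variable too
  expect_lt(abs(median(mash$quicki) - 0.31), 0.01)
})

test_that("Gaussian copula induces the configured rank correlation", {
  cfg <- cohort_config(n_per_group = c(NoS = 10, MASLD = 10, MASH = 10000))
  cohort <- simulate_cohort(cfg, seed = 3)
  mash <- cohort[cohort$group == "MASH", ]
  target <- cfg$dependence["ff", "insulinemia"]
  expect_lt(abs(cor(mash$ff, mash$insulinemia, method = "spearman") - target),
            0.05)
  target_neg <- cfg$dependence["ff", "f_ui"]
  expect_lt(abs(cor(mash$ff, mash$f_ui, method = "spearman") - target_neg),
            0.05)
})

test_that("invalid configurations are rejected with diagnostics", {
  s <- default_summaries()
  s$q3[s$variable == "ff" & s$group == "MASH"] <- 1  # below median
  expect_error(cohort_config(summaries = s), "quartile order")

  vars <- unique(default_summaries()$variable)
  R <- diag(length(vars)); dimnames(R) <- list(vars, vars)
  R[1, 2] <- R[2, 1] <- 0.9; R[1, 3] <- R[3, 1] <- 0.9
  R[2, 3] <- R[3, 2] <- -0.9
  expect_error(cohort_config(dependence = R), "positive semi-definite")

  R2 <- diag(length(vars)); dimnames(R2) <- list(vars, vars)
  R2[1, 2] <- 0.5  # asymmetric
  expect_error(cohort_config(dependence = R2), "symmetric")
})

test_that("zero-fat spectra contain the water line only", {
  sp <- simulate_spectrum(ff = 0, snr = Inf)
  amps <- sp$truth$amplitudes0
  expect_equal(unname(amps[setdiff(names(amps), "Water")]),
               rep(0, length(amps) - 1))
  fit <- fit_spectrum(sp)
  expect_lt(max(fit$amplitude[fit$name != "Water"]), 1e-8)
  expect_equal(fit$amplitude[fit$name == "Water"],
               100 * exp(-30 / 27), tolerance = 1e-8)
})

test_that("infeasible hydrogen-fraction targets are rejected", {
  expect_error(simulate_spectrum(10, c(f_si = 0.9, f_ui = 0.2, f_pui = 0.0)),
               "infeasible")
  expect_error(simulate_spectrum(10, c(f_si = 0.8, f_ui = 0.02, f_pui = 0.05)),
               "f_pui")
})

test_that("lipid-to-water raw amplitude ratio grows with TE (T2 lipids > water)", {
  ratio_at <- function(te) {
    sp <- simulate_spectrum(10, te = te, snr = Inf)
    f <- fit_spectrum(sp)
    a <- setNames(f$amplitude, f$name)
    sum(a[c("Lip09", "Lip13", "Lip16", "Lip21", "Lip24", "Lip28", "Lip53")]) /
      a[["Water"]]
  }
  r30 <- ratio_at(30); r270 <- ratio_at(270)
  expect_gt(r270, r30)
  # closed form: ratio multiplies by exp(-240/60)/exp(-240/27)
  expect_equal(r270 / r30, exp(-240 / 60) / exp(-240 / 27), tolerance = 1e-6)
})

test_that("TE series has six echoes with exact water decay when noiseless", {
  series <- simulate_te_series(ff = 5, snr = Inf)
  expect_length(series, 6)
  tes <- unname(vapply(series, function(s) s$te, numeric(1)))
  expect_equal(tes, c(30, 50, 68, 135, 180, 270))
  water <- unname(vapply(series, function(s) {
    f <- fit_spectrum(s); f$amplitude[f$name == "Water"]
  }, numeric(1)))
  expect_equal(water, 100 * exp(-tes / 27), tolerance = 1e-6)
  # seeded reproducibility of the noisy series
  s1 <- simulate_te_series(ff = 5, snr = 80, seed = 4)
  s2 <- simulate_te_series(ff = 5, snr = 80, seed = 4)
  expect_identical(s1, s2)
})
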