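test_that("toy ROC: AUC, curve endpoints and Youden tie-break", {
  scores <- c(3, 5, 1, 4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(scores, labels), 0.75)
  expect_equal(auc_pairs(scores, labels), 0.75)

  curve <- roc_curve(scores, labels)
  expect_equal(roc_auc_trapezoid(curve), 0.75)
  # two thresholds tie at J = 50; the more sensitive (lower) cut is returned
  opt <- youden_optimal(curve)
  expect_equal(opt$youden, 50)
  expect_equal(opt$cutoff, 2)
  expect_true(opt$tie)

  # perfect separation passes through (100, 100) and gives Youden 100
  psep <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(psep$sensitivity == 100 & psep$specificity == 100))
  expect_equal(attr(psep, "auc"), 1)
  expect_equal(youden_optimal(psep)$youden, 100)

  # all scores identical: degenerate curve, AUC 0.5
  flat <- roc_curve(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(flat, "auc"), 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both")
})

test_that("trapezoidal and pair-counting AUC agree exactly, ties included", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- sample(0:9, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    curve <- roc_curve(scores, labels)
    a_rank <- roc_auc(scores, labels, direction = ">")
    expect_equal(roc_auc_trapezoid(curve), max(a_rank, 1 - a_rank),
                 tolerance = 1e-12)
    expect_equal(a_rank, auc_pairs(scores, labels), tolerance = 1e-12)
    # complement identity
    expect_equal(roc_auc(-scores, labels, direction = ">"), 1 - a_rank,
                 tolerance = 1e-12)
    # Youden maximum equals brute-force maximum over curve points
    expect_equal(youden_optimal(curve)$youden,
                 max(curve$sensitivity + curve$specificity - 100))
  }
})

test_that("rank AUC matches the pROC reference on tied data", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- sample(1:6, 60, replace = TRUE)
  labels <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels, direction = ">"), ref,
               tolerance = 1e-12)
})

test_that("screening applies the AUC retention rule and reports n", {
  cohort <- toy_cohort()
  cohort$insulinemia <- cohort$ff + rnorm(nrow(cohort), sd = 6)
  cohort$insulinemia[1:3] <- NA
  scr <- screen_variables(cohort, c("ff", "insulinemia", "noise"),
                          contrast = contrast_mash_vs_nos())
  expect_s3_class(scr, "mashdx_screen")
  expect_equal(scr$variable[1], "ff")  # sorted by AUC descending
  expect_equal(scr$auc[scr$variable == "ff"], 1)
  expect_false(scr$retained[scr$variable == "noise"])
  expect_equal(scr$n_neg[scr$variable == "insulinemia"], 27)  # NAs dropped
  # auc_min = 0 retains everything measurable
  scr0 <- screen_variables(cohort, c("ff", "noise"), auc_min = 0)
  expect_true(all(scr0$retained))
  expect_error(screen_variables(cohort, "absent"), "not present")
})

test_that("direction is chosen so AUC >= 0.5 and recorded in the cutoff", {
  cohort <- toy_cohort()
  cohort$quicki_like <- -cohort$ff  # lower values indicate disease
  scr <- screen_variables(cohort, c("ff", "quicki_like"))
  expect_equal(scr$direction[scr$variable == "ff"], ">")
  expect_equal(scr$direction[scr$variable == "quicki_like"], "<")
  expect_equal(scr$auc[scr$variable == "ff"],
               scr$auc[scr$variable == "quicki_like"])
})

test_that("calibrated cohort: ff has the top AUC of the standard contrasts", {
  cohort <- simulate_cohort(seed = 2)
  vars <- c("ff", "insulinemia", "elastography", "quicki", "bmi", "waist",
            "age", "ast")
  scr <- screen_variables(cohort, vars)
  expect_equal(scr$variable[1], "ff")
  expect_gt(scr$auc[1], 0.9)
  # the four standard contrasts all run
  for (ctr in list(contrast_mash_vs_rest(), contrast_mash_vs_nos(),
                   contrast_mash_vs_masld(), contrast_masld_vs_nos())) {
    s <- screen_variables(cohort, "ff", contrast = ctr)
    expect_true(is.finite(s$auc))
  }
})
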