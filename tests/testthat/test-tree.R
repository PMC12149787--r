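test_that("G2 statistic matches closed forms and the log-likelihood oracle", {
  even <- g2_statistic(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$g2, 0)
  expect_equal(even$logworth, 0)

  diag20 <- g2_statistic(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag20$g2, 40 * log(2), tolerance = 1e-12)

  # a split whose G2 sits exactly at the 5% chi-square point has LogWorth 1.3010
  synthetic_g2 <- qchisq(0.95, df = 1)
  lw_p05 <- -pchisq(synthetic_g2, 1, lower.tail = FALSE, log.p = TRUE) / log(10)
  expect_equal(lw_p05, 1.30103, tolerance = 1e-5)

  # empty margin: no evidence
  expect_equal(g2_statistic(matrix(c(0, 0, 3, 7), 2))$g2, 0)
  expect_equal(g2_statistic(matrix(c(0, 0, 3, 7), 2))$p, 1)

  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (sum(tab) == 0) next
    got <- g2_statistic(tab)
    expect_equal(got$g2, g2_loglik_oracle(tab), tolerance = 1e-9)
    expect_equal(got$logworth, -log10(got$p), tolerance = 1e-9)
    # Pearson option agrees with chisq.test without continuity correction
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      ref <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      expect_equal(g2_statistic(tab, "pearson")$g2, unname(ref),
                   tolerance = 1e-9)
    }
  }
})

test_that("best_split scans midpoints and agrees with a brute-force oracle", {
  d <- tibble::tibble(x = c(1, 2, 3, 10, 11, 12),
                      mash = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  bs <- best_split(d, "x")
  expect_equal(bs$threshold, 6.5)
  expect_equal(bs$g2, g2_loglik_oracle(matrix(c(3, 0, 0, 3), 2)),
               tolerance = 1e-9)

  # oracle: enumerate every midpoint with g2_statistic
  set.seed(8)
  for (i in 1:20) {
    x <- round(rnorm(40), 1)
    y <- runif(40) < plogis(x)
    if (!any(y) || all(y)) next
    d <- tibble::tibble(x = x, mash = y)
    v <- sort(unique(x))
    mids <- (v[-1] + v[-length(v)]) / 2
    g2s <- vapply(mids, function(t) {
      g2_statistic(table(factor(x <= t, c(TRUE, FALSE)),
                         factor(y, c(TRUE, FALSE))))$g2
    }, numeric(1))
    bs <- best_split(d, "x")
    expect_equal(bs$g2, max(g2s), tolerance = 1e-9)
    expect_equal(bs$threshold, mids[which.max(g2s)])
  }

  # constant variable: no candidate split
  expect_equal(nrow(best_split(tibble::tibble(x = rep(1, 6),
                                              mash = rep(c(TRUE, FALSE), 3)),
                               "x")), 0)
})

test_that("tree growth respects pruning, node size and depth controls", {
  cohort <- toy_cohort()
  tree <- grow_tree(cohort, c("ff", "noise"))
  g <- glance(tree)
  expect_equal(g$root_variable, "ff")
  expect_equal(g$n_splits, 1)  # noise cannot earn a second split
  leaves <- tree$nodes[tree$nodes$leaf, ]
  expect_equal(sort(leaves$prob), c(0, 1))

  # children's class counts sum to the parent's
  for (i in which(!tree$nodes$leaf)) {
    nd <- tree$nodes[i, ]
    kids <- tree$nodes[tree$nodes$id %in% c(nd$left, nd$right), ]
    expect_equal(sum(kids$n_pos), nd$n_pos)
    expect_equal(sum(kids$n_neg), nd$n_neg)
  }

  # single-class data: root leaf
  one <- cohort[!cohort$mash, ]
  t1 <- grow_tree(one, "ff")
  expect_equal(nrow(t1$nodes), 1)
  expect_true(t1$nodes$leaf[1])

  # infinite pruning threshold: root leaf regardless of signal
  t2 <- grow_tree(cohort, "ff", min_logworth = Inf)
  expect_equal(nrow(t2$nodes), 1)

  # every retained split clears the LogWorth floor
  co <- simulate_cohort(seed = 9)
  t3 <- grow_tree(co, c("ff", "insulinemia", "elastography", "quicki"))
  expect_true(all(t3$nodes$logworth[!t3$nodes$leaf] >= 1.3))
  expect_true(all(t3$nodes$depth <= 4))

  # monotone pruning: relaxing min_logworth keeps previously retained splits
  strict <- grow_tree(co, c("ff", "insulinemia"), min_logworth = 3)
  loose <- grow_tree(co, c("ff", "insulinemia"), min_logworth = 1.3)
  strict_splits <- strict$nodes[!strict$nodes$leaf,
                                c("split_variable", "threshold")]
  loose_splits <- loose$nodes[!loose$nodes$leaf,
                              c("split_variable", "threshold")]
  expect_true(nrow(dplyr::anti_join(strict_splits, loose_splits,
                                    by = c("split_variable",
                                           "threshold"))) == 0)
})

test_that("prediction routes by threshold with the <= boundary rule", {
  cohort <- toy_cohort()
  tree <- grow_tree(cohort, "ff")
  thr <- tree$nodes$threshold[1]
  p <- predict(tree, tibble::tibble(ff = c(thr, thr + 1e-9, 20, 1)))
  expect_equal(p$prob, c(0, 1, 1, 0))     # boundary goes to the <= side
  expect_equal(p$class, c(FALSE, TRUE, TRUE, FALSE))
  # missing value on path routes to the larger child and is flagged
  pm <- predict(tree, tibble::tibble(ff = NA_real_))
  expect_true(pm$imputed_route)
  expect_equal(pm$prob, 0)  # larger child is the non-MASH side (30 vs 10)
  # leaf probabilities are empirical proportions
  mixed <- tibble::tibble(
    ff = c(rep(1, 2), rep(10, 8), rep(1, 18), rep(10, 2)),
    mash = rep(c(TRUE, FALSE), c(10, 20))
  )
  tmix <- grow_tree(mixed, "ff", min_node = 2)
  pr <- predict(tmix, tibble::tibble(ff = 10))
  expect_equal(pr$prob, 0.8)
})

test_that("column contributions are G2 shares summing to one", {
  cohort <- toy_cohort()
  single <- column_contributions(grow_tree(cohort, c("ff", "noise")))
  expect_equal(single$variable, "ff")
  expect_equal(single$contribution, 1)

  co <- simulate_cohort(seed = 21)
  cc <- column_contributions(grow_tree(co, c("ff", "insulinemia",
                                             "elastography", "quicki")))
  expect_equal(sum(cc$contribution), 1, tolerance = 1e-12)
  expect_true(all(cc$contribution >= 0))
  expect_equal(cc$variable[1], "ff")

  none <- grow_tree(cohort, "ff", min_logworth = Inf)
  expect_equal(nrow(column_contributions(none)), 0)
})

test_that("cross-validation is stratified, seeded and exact on separable data", {
  cohort <- toy_cohort()
  cv <- cross_validate(cohort, "ff", k = 5, seed = 3)
  expect_equal(cv$means$sensitivity, c(1, 1))
  expect_equal(cv$means$specificity, c(1, 1))
  expect_identical(cv$folds, cross_validate(cohort, "ff", k = 5, seed = 3)$folds)
  # means are the arithmetic means of the folds
  tr <- cv$folds[cv$folds$part == "training", ]
  expect_equal(mean(tr$auc), cv$means$auc[cv$means$part == "training"])

  co <- simulate_cohort(seed = 17)
  cv2 <- cross_validate(co, c("ff", "insulinemia"), k = 6, seed = 4)
  expect_true(all(cv2$folds$sensitivity >= 0 & cv2$folds$sensitivity <= 1))
  # minority positive class: training sensitivity below training specificity
  m <- cv2$means
  expect_lt(m$sensitivity[m$part == "training"],
            m$specificity[m$part == "training"])
})
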