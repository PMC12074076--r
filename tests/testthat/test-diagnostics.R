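test_that("the ROC curve contains its endpoints and is monotone", {
  roc <- roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_true(any(roc$sens == 1 & roc$spec == 0))
  expect_true(any(roc$sens == 0 & roc$spec == 1))
  # a threshold between the classes separates perfectly
  expect_true(any(roc$sens == 1 & roc$spec == 1))
  # tie case: all values identical leaves only the degenerate points
  roc2 <- roc_curve(rep(3, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(nrow(roc2), 2)
  expect_setequal(roc2$sens, c(0, 1))
  # monotonicity on random data, against explicit counting
  set.seed(101)
  for (rep in 1:5) {
    v <- round(rnorm(20, 3, 1), 1)
    lb <- rbinom(20, 1, 0.4)
    if (sum(lb) %in% c(0, 20)) next
    roc <- roc_curve(v, lb)
    expect_true(all(diff(roc$sens) <= 1e-12))
    expect_true(all(diff(roc$spec) >= -1e-12))
    for (i in seq_len(nrow(roc))) {
      expect_equal(roc$sens[i], sum(v[lb == 1] >= roc$threshold[i]) / sum(lb))
    }
  }
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both cases and controls")
})

test_that("AUC equals the brute-force pair statistic and the trapezoid area", {
  expect_equal(auc(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    v <- round(rnorm(n, 3, 1), sample(0:2, 1)) # induce ties sometimes
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) %in% c(0, n)) next
    a <- auc(v, lb)
    expect_equal(a, auc_brute(v, lb == 1), tolerance = 1e-12)
    expect_equal(a, roc_auc_trapezoid(roc_curve(v, lb)), tolerance = 1e-12)
    # anti-symmetry under sign flip (midranks make ties cancel)
    expect_equal(a + auc(-v, lb), 1, tolerance = 1e-12)
  }
  # shuffled labels on many values: near-null AUC
  set.seed(5)
  v <- rnorm(2000)
  lb <- rbinom(2000, 1, 0.5)
  expect_lt(abs(auc(v, lb) - 0.5), 0.05)
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  v <- round(rnorm(40, 3, 1), 1)
  lb <- rbinom(40, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(lb, v,
                                                         direction = "<"))))
  expect_equal(auc(v, lb), ref, tolerance = 1e-12)
})

test_that("the optimal cut-point matches exhaustive search with documented tie-breaks", {
  # separable case: the midpoint of the gap, at the perfect corner
  cp <- optimal_cutpoint(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1)))
  expect_equal(cp$cutoff, 2.5)
  expect_equal(cp$sens, 1)
  expect_equal(cp$spec, 1)
  set.seed(303)
  for (rep in 1:30) {
    n <- sample(c(8, 12, 50, 200), 1)
    v <- round(rnorm(n, 3.4, 0.7), sample(1:2, 1))
    lb <- rbinom(n, 1, 0.45)
    if (sum(lb) %in% c(0, n)) next
    got <- optimal_cutpoint(roc_curve(v, lb))
    want <- cutpoint_brute(v, lb == 1)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$sens, want$sens)
    expect_equal(got$spec, want$spec)
    # optimality: no candidate threshold does better
    d2 <- (1 - got$sens)^2 + (1 - got$spec)^2
    expect_lte(d2, want$d2 + 1e-15)
  }
  # symmetric overlap: returned point is at least as close as every candidate
  v <- c(1, 2, 3, 1.5, 2.5, 3.5)
  lb <- c(0, 0, 0, 1, 1, 1)
  got <- optimal_cutpoint(roc_curve(v, lb))
  roc <- roc_curve(v, lb)
  expect_true(all((1 - got$sens)^2 + (1 - got$spec)^2 <=
                    (1 - roc$sens)^2 + (1 - roc$spec)^2 + 1e-15))
})

test_that("confusion metrics use >= cutoff and report undefined ratios as NA", {
  # cases at 5, 7, 8, 9; cutoff 7 -> TP=3, FP=1, FN=1, TN=5
  cm <- confusion_metrics(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
                          c(0, 0, 0, 0, 1, 0, 1, 1, 1, 0), 7)
  expect_equal(cm$tp, 3)
  expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 5)
  expect_equal(cm$sens, 0.75)
  expect_equal(cm$spec, 5 / 6)
  expect_equal(cm$ppv, 0.75)
  expect_equal(cm$npv, 5 / 6)
  expect_error(confusion_metrics(1:4, c(0, 0, 1, 1), Inf), "is.finite")
  # everything predicted positive
  cm2 <- confusion_metrics(1:6, c(0, 0, 0, 1, 1, 1), 0)
  expect_equal(cm2$sens, 1)
  expect_equal(cm2$spec, 0)
  expect_true(is.na(cm2$npv))
})

test_that("prevalence-weighted accuracy reproduces the worked example", {
  acc <- accuracy_from_rates(0.86, 0.93, 14, 15)
  expect_equal(acc, (0.86 * 14 + 0.93 * 15) / 29)
  expect_equal(round(acc, 1), 0.9)
})

test_that("the two-means sample size formula behaves as expected", {
  ss <- sample_size_two_means(0.59, 0.56, 0.58, alpha = 0.05, power = 0.80,
                              dropout = 0.10)
  expect_equal(ss$n_per_group, 15L)
  expect_equal(ss$n_recruited, 17L)
  # doubling the difference divides n by about four
  ss2 <- sample_size_two_means(1.18, 0.56, 0.58)
  expect_lte(ss2$n_per_group, ceiling(ss$n_per_group / 4) + 1)
  # no drop-out: recruit exactly n
  ss3 <- sample_size_two_means(0.59, 0.56, 0.58, dropout = 0)
  expect_equal(ss3$n_recruited, ss3$n_per_group)
  expect_error(sample_size_two_means(0, 0.5, 0.5), "non-zero")
})

test_that("diagnose_groups evaluates all six pairwise contrasts", {
  pm <- simulate_patient_means(default_group_params(), 30, seed = 3)
  pm$patient_id <- seq_len(nrow(pm))
  d <- diagnose_groups(pm)
  expect_equal(nrow(d), 6)
  expect_equal(d$reference[1], "CG")
  expect_equal(d$case_group[6], "OSCCG")
  expect_true(all(d$auc >= 0 & d$auc <= 1))
  expect_true(all(d$accuracy >= 0 & d$accuracy <= 1, na.rm = TRUE))
})
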