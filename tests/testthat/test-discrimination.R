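test_that("AUC handles perfect separation, ties and mixed ordering", {
  expect_equal(roc_auc(c(1, 2), c(3, 4), direction = "lower")$auc, 1)
  r_tied <- roc_auc(c(5, 5), c(5, 5, 5))
  expect_equal(r_tied$auc, 0.5)
  expect_true(r_tied$degenerate)
  # 4-pair instance: (1,2) ok, (1,4) ok, (3,4) ok, (3,2) not -> 0.75
  expect_equal(roc_auc(c(1, 3), c(2, 4), direction = "lower")$auc, 0.75)
  expect_equal(roc_auc(c(1, 3), c(2, 4), direction = "lower")$auc,
               auc_pairs(c(1, 3), c(2, 4), "lower"))
  expect_error(roc_auc(numeric(0), 1:3), "nonempty")
})

test_that("pair counting, trapezoid, and rank-sum U agree on random tied instances", {
  set.seed(42)
  for (i in 1:100) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    cases <- sample(1:8, n1, replace = TRUE)
    controls <- sample(1:8, n0, replace = TRUE)
    dir <- sample(c("lower", "higher"), 1)
    curve <- roc_auc(cases, controls, direction = dir)
    expect_equal(curve$auc, auc_pairs(cases, controls, dir))
    expect_equal(curve$auc, auc_trapezoid(curve))
    u <- mann_whitney(cases, controls)$u
    auc_higher <- if (dir == "higher") curve$auc else 1 - curve$auc
    expect_equal(auc_higher, u / (n1 * n0))
  }
})

test_that("reversing the direction reflects the AUC about one half", {
  set.seed(7)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  expect_equal(roc_auc(x, y, "lower")$auc, 1 - roc_auc(x, y, "higher")$auc)
})

test_that("auto orientation picks the median-concordant direction; default stays fixed", {
  set.seed(23)
  cases <- rnorm(30, 1); controls <- rnorm(30)   # cases sit higher
  r_auto <- roc_auc(cases, controls, "auto")
  expect_identical(r_auto$direction, "higher")
  expect_equal(r_auto$auc, roc_auc(cases, controls, "higher")$auc)
  # the fixed default does not flip and duly reports a sub-0.5 AUC
  expect_lt(roc_auc(cases, controls, "lower")$auc, 0.5)
})

test_that("curve endpoints span (0,1) and (1,0) in ROC space", {
  r <- roc_auc(rnorm(10), rnorm(10))
  cv <- r$curve
  expect_true(any(cv$sensitivity == 0 & cv$specificity == 1))
  expect_true(any(cv$sensitivity == 1 & cv$specificity == 0))
  expect_true(all(cv$sensitivity >= 0 & cv$sensitivity <= 1))
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
})

test_that("the Youden cut-point equals exhaustive search on small instances", {
  expect_equal(optimal_cutpoint(roc_auc(c(1, 2), c(3, 4), "lower"))$threshold, 2.5)
  expect_equal(optimal_cutpoint(roc_auc(c(1, 2), c(3, 4), "lower"))$j, 1)
  set.seed(11)
  for (i in 1:50) {
    n1 <- sample(2:10, 1); n0 <- sample(2:10, 1)
    cases <- round(rnorm(n1, 0, 2), 1)
    controls <- round(rnorm(n0, 1, 2), 1)
    curve <- roc_auc(cases, controls, "lower")
    oc <- optimal_cutpoint(curve)
    expect_equal(oc$j, best_j_exhaustive(cases, controls, "lower"))
  }
})

test_that("a degenerate curve returns the lowest candidate with a flag", {
  oc <- optimal_cutpoint(roc_auc(rep(2, 4), rep(2, 6)))
  expect_identical(oc$threshold, -Inf)
  expect_equal(oc$j, 0)
  expect_true(oc$degenerate)
})

test_that("confusion metrics follow the stated definitions", {
  # published female counts: 53/73 toxicity and 20/33 non-toxicity correct
  f <- cutpoint_metrics(tp = 53, fn = 20, tn = 20, fp = 13)
  expect_equal(round(f$accuracy, 2), 0.69)
  expect_equal(round(f$sensitivity, 2), 0.73)
  expect_equal(round(f$specificity, 2), 0.61)
  # published male counts: 23/47 and 39/50
  m <- cutpoint_metrics(tp = 23, fn = 24, tn = 39, fp = 11)
  expect_equal(round(m$accuracy, 2), 0.64)
  expect_equal(round(m$sensitivity, 2), 0.49)
  expect_equal(round(m$specificity, 2), 0.78)
})

test_that("threshold evaluation respects the boundary rule and count invariants", {
  cases <- c(1, 2, 3); controls <- c(3, 4)
  # value >= threshold goes to the higher (non-DLT) class; 3 sits on the boundary
  ev <- evaluate_cutpoint(cases, controls, threshold = 3, direction = "lower")
  expect_equal(ev$tp, 2); expect_equal(ev$fn, 1)
  expect_equal(ev$tn, 2); expect_equal(ev$fp, 0)
  expect_equal(ev$tp + ev$fn, length(cases))
  expect_equal(ev$tn + ev$fp, length(controls))
  # perfect classification
  p <- evaluate_cutpoint(c(1, 2), c(3, 4), 2.5, "lower")
  expect_equal(c(p$accuracy, p$sensitivity, p$specificity), c(1, 1, 1))
  # threshold below every value: all predicted into the higher class
  lo <- evaluate_cutpoint(c(1, 2), c(3, 4), 0, "lower")
  expect_equal(lo$sensitivity, 0); expect_equal(lo$specificity, 1)
  expect_error(evaluate_cutpoint(1:3, 4:6, Inf), "finite")
})

test_that("DeLong interval matches an independent implementation", {
  set.seed(19)
  cases <- rnorm(35, 1); controls <- rnorm(45)
  r <- roc_auc(cases, controls, direction = "higher")
  ref <- pROC::roc(controls = controls, cases = cases,
                   direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
  expect_equal(r$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(r$ci_high, ci[3], tolerance = 1e-6)
})

test_that("DeLong interval covers the true binormal AUC at near-nominal rate", {
  set.seed(3)
  true_auc <- pnorm(1 / sqrt(2))
  hits <- 0L
  for (i in 1:500) {
    r <- roc_auc(rnorm(40, 1), rnorm(40), direction = "higher")
    if (r$ci_low <= true_auc && true_auc <= r$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.90)
})

test_that("published fixed cut-offs classify per sex and error when one is missing", {
  spec <- separation_cohort_spec(delta = c(smi_cm2_m2 = 1),
                                 n = c(F = 400L, M = 400L),
                                 prevalence = c(F = 0.5, M = 0.5), seed = 13)
  sim <- generate_cohort(spec)
  res <- threshold_classifier(sim$cohort, "smi_cm2_m2",
                              cutoffs = c(F = -0.5, M = -0.5))
  expect_identical(res$sex, c("F", "M"))
  expect_true(all(res$tp + res$fn ==
                    table(sim$cohort$sex, sim$cohort$dlt)[, "1"]))
  # independence oracle: expected accuracy from the known stratum normals
  prev <- 0.5; t <- -0.5
  exp_acc <- prev * pnorm(t, -1, 1) + (1 - prev) * (1 - pnorm(t, 0, 1))
  expect_lt(abs(res$accuracy[1] - exp_acc), 0.1)
  expect_error(threshold_classifier(sim$cohort, "smi_cm2_m2",
                                    cutoffs = c(F = -0.5)), "sex 'M'")
})

test_that("the full per-measurement report flags BSA-beating variables and degenerates", {
  spec <- separation_cohort_spec(delta = c(sm_volume_cm3 = 1.2),
                                 n = c(F = 120L), prevalence = c(F = 0.5),
                                 seed = 9)
  sim <- generate_cohort(spec)
  cohort <- sim$cohort
  cohort$sat_density_3d_hu <- 0  # constant measurement -> degenerate ROC
  rep_ <- evaluate_all(cohort)
  expect_identical(unique(rep_$sex), "F")
  top <- rep_[which.max(rep_$auc), ]
  expect_identical(top$variable, "sm_volume_cm3")
  expect_true(top$exceeds_bsa)
  cst <- rep_[rep_$variable == "sat_density_3d_hu", ]
  expect_equal(cst$auc, 0.5)
  expect_true(cst$degenerate)
  bsa_row <- rep_[rep_$variable == "bsa", ]
  expect_false(bsa_row$exceeds_bsa)
})
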