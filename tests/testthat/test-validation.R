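test_that("ROC handles the worked small cohorts and degenerate scores", {
  out <- c(1, 1, 0, 0)
  r1 <- roc_analysis(out, c(1, 2, 7, 8))
  expect_equal(r1$auc, 1.0)
  expect_equal(r1$youden_j, 1.0)
  r2 <- roc_analysis(out, c(1, 7, 2, 8))
  expect_equal(r2$auc, 0.75)
  # a constant score has no discrimination
  expect_equal(roc_analysis(out, rep(5, 4))$auc, 0.5)
  expect_error(roc_analysis(c(1, 1), c(1, 2)), "both outcome classes")
})

test_that("trapezoid AUC equals brute-force concordance on random cohorts", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    outcome <- rbinom(n, 1, runif(1, 0.15, 0.5))
    if (length(unique(outcome)) < 2) outcome[1:2] <- c(0, 1)
    score <- sample(0:8, n, replace = TRUE)  # heavy ties, like the real score
    r <- roc_analysis(outcome, score)
    expect_equal(r$auc, brute_force_concordance(outcome, score),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a simulated cohort", {
  skip_if_not_installed("pROC")
  coh <- simulate_cohort(tss_cohort_config(n = 586, rho = suite_rho, seed = 8))
  r <- roc_analysis(coh$outcome, coh$tss_total)
  ref <- pROC::auc(pROC::roc(coh$outcome, coh$tss_total, direction = ">",
                             quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("confusion metrics satisfy their accounting identity at every cutoff", {
  expect_equal(confusion_metrics(c(1, 0), c(3, 6), 8),
               list(sensitivity = 1, specificity = 0, accuracy = 0.5,
                    tp = 1, fp = 1, tn = 0, fn = 0))
  cm_low <- confusion_metrics(c(1, 0), c(3, 6), -1)
  expect_equal(cm_low$sensitivity, 0)
  expect_equal(cm_low$specificity, 1)
  set.seed(17)
  outcome <- rbinom(300, 1, 0.2)
  score <- sample(0:8, 300, replace = TRUE)
  n_pos <- sum(outcome)
  n_neg <- sum(1 - outcome)
  for (cut in -1:8) {
    cm <- confusion_metrics(outcome, score, cut)
    expect_equal(cm$accuracy,
                 (cm$sensitivity * n_pos + cm$specificity * n_neg) / 300)
  }
})

test_that("Hosmer-Lemeshow is calibrated under the null and detects gross miscalibration", {
  set.seed(23)
  null_p <- power_p <- numeric(100)
  for (i in 1:100) {
    n <- 5000
    x <- sample(0:8, n, replace = TRUE, prob = dbinom(0:8, 8, 0.7))
    p_true <- plogis(0.68 - 0.6 * x)
    y <- rbinom(n, 1, p_true)
    d <- data.frame(y = y, x = x)
    fit <- tss_fit(y ~ x, d)
    null_p[i] <- hosmer_lemeshow(fit)$p_value
    # grossly miscalibrated probabilities: square the fitted values
    power_p[i] <- hosmer_lemeshow(y, prob = fitted(fit)^2)$p_value
  }
  expect_gte(mean(null_p > 0.05), 0.90)
  expect_gte(mean(power_p < 0.05), 0.90)
})

test_that("Hosmer-Lemeshow degenerate groupings raise errors and exact fits score zero", {
  y <- rep(c(0, 1), 50)
  expect_error(hosmer_lemeshow(y, prob = rep(0.5, 100)), "distinct predicted")
  expect_error(hosmer_lemeshow(y, prob = runif(100), groups = 1), "at least 2 groups")
  # observed rate equal to mean prediction in every group -> statistic 0
  prob <- rep(c(0.2, 0.5, 0.8), each = 10)
  yy <- c(rep(c(1, 0), c(2, 8)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(8, 2)))
  hl <- hosmer_lemeshow(yy, prob = prob, groups = 3)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_gte(hl$statistic, 0)
})

test_that("fit statistics reduce to their closed-form limits", {
  coh <- simulate_cohort(tss_cohort_config(n = 2000, rho = suite_rho, seed = 41))
  fit <- tss_fit(outcome ~ tss_total, coh)
  fs <- fit_statistics(fit)
  expect_equal(fs$mcfadden_r2,
               1 - fit$log_likelihood / fit$null_log_likelihood)
  expect_equal(fs$lr_statistic,
               2 * (fit$log_likelihood - fit$null_log_likelihood))
  expect_true(fs$mcfadden_r2 >= 0 && fs$mcfadden_r2 < 1)
  # no-effect covariate: R2 near zero, LR p not extreme
  set.seed(5)
  d0 <- data.frame(y = rbinom(2000, 1, 0.3), x = rnorm(2000))
  fs0 <- fit_statistics(tss_fit(y ~ x, d0))
  expect_lt(fs0$mcfadden_r2, 0.01)
  # relabeling the outcome flips the coefficients but fixes McFadden R2
  coh2 <- coh
  coh2$outcome <- 1 - coh2$outcome
  fit2 <- tss_fit(outcome ~ tss_total, coh2)
  expect_equal(unname(coef(fit2)), -unname(coef(fit)), tolerance = 1e-6)
  expect_equal(fit_statistics(fit2)$mcfadden_r2, fs$mcfadden_r2,
               tolerance = 1e-8)
})

test_that("VIF is 1 for orthogonal covariates and flags perfect collinearity", {
  x1 <- rep(c(-1, 1), each = 20)
  x2 <- rep(c(-1, 1), times = 20)
  d <- data.frame(a = x1, b = x2)
  expect_equal(unname(vif(d, c("a", "b"))), c(1, 1), tolerance = 1e-12)
  d$c <- d$a
  w <- capture_warnings(v <- vif(d, c("a", "b", "c")))
  expect_true(any(grepl("collinear", w)))
  expect_true(any(is.infinite(v)))
  d$z <- 1
  expect_error(vif(d, c("a", "z")), "zero variance")
  # correlated sub-scores from the calibrated generator stay below 5
  coh <- simulate_cohort(tss_cohort_config(n = 2000, rho = suite_rho, seed = 19))
  vs <- vif(coh, c("tad_score", "quadrant_score", "ap_alignment_score",
                   "lateral_alignment_score", "mcs_score", "acs_score"))
  expect_true(all(vs >= 1))
  expect_true(all(vs < 5))
})

test_that("group comparison matches the Mann-Whitney and chi-square oracles", {
  d <- data.frame(outcome = c(1, 1, 0, 0), v = c(1, 2, 3, 4))
  gc <- group_compare(d, "v")
  expect_equal(gc$statistic, 0)  # complete separation: U = 0
  expect_named(gc$summary["complication", ],
               c("n", "mean", "sd", "min", "max", "median"))
  # null behaviour: identical distributions rarely rejected
  set.seed(71)
  pvals <- replicate(100, {
    dd <- data.frame(outcome = rbinom(200, 1, 0.3), v = rnorm(200))
    group_compare(dd, "v")$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.90)
  # categorical route with a zero expected cell flag
  dc <- data.frame(outcome = rep(c(0, 1), each = 30),
                   g = c(rep("a", 30), rep(c("a", "b"), 15)))
  gcc <- group_compare(dc, "g", kind = "categorical")
  expect_true(gcc$low_expected || gcc$p_value <= 1)
  expect_equal(gcc$kind, "categorical")
})

test_that("group score separation reaches the published significance at the published effect", {
  pvals <- vapply(1:40, function(i) {
    coh <- simulate_cohort(tss_cohort_config(n = 586, rho = suite_rho,
                                             seed = 500 + i))
    group_compare(coh, "tss_total")$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.001), 0.95)
})

test_that("two-proportion z-test reproduces the published quadrant contrasts", {
  eq <- proportion_z_test(10, 50, 20, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  # superior-posterior: 25% of 48 vs 4.6% of 538
  expect_lt(proportion_z_test(12, 48, 25, 538)$p_value, 0.001)
  # centre-centre: 18.8% of 48 vs 35.5% of 538
  p_cc <- proportion_z_test(9, 48, 191, 538)$p_value
  expect_lt(p_cc, 0.05)
  expect_equal(p_cc, 0.019, tolerance = 0.002)
  expect_error(proportion_z_test(60, 50, 1, 10), "\\[0, n\\]")
  # agrees with the unconditional chi-square version
  ref <- suppressWarnings(prop.test(c(12, 25), c(48, 538), correct = FALSE))
  expect_equal(proportion_z_test(12, 48, 25, 538)$p_value, ref$p.value,
               tolerance = 1e-10)
})

test_that("Spearman correlation handles exact monotone and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_correlation(x, x)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  expect_error(spearman_correlation(x, rep(1, 6)), "constant")
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
  # ACS score vs outcome on the calibrated generator: weak negative
  rhos <- vapply(1:40, function(i) {
    coh <- simulate_cohort(tss_cohort_config(n = 586, rho = suite_rho,
                                             seed = 700 + i))
    spearman_correlation(coh$acs_score, coh$outcome)$rho
  }, numeric(1))
  expect_true(all(rhos < 0))
  med <- median(abs(rhos))
  expect_gt(med, 0.15)
  expect_lt(med, 0.45)
})

test_that("per-score calibration tracks the generating model", {
  coh <- simulate_cohort(tss_cohort_config(n = 5000, mode = "model_based",
                                           rho = suite_rho, seed = 99))
  fit <- tss_fit(outcome ~ tss_total, coh)
  cal <- calibration_by_score(coh, fit)
  expect_equal(cal$score, 0:8)
  expect_true(all(diff(cal$predicted) < 0))  # monotone in score
  big <- cal[cal$present & cal$n >= 20, ]
  expect_lt(mean(abs(big$observed - big$predicted)), 0.05)
  # absent levels are flagged, not fabricated
  sub <- coh[coh$tss_total != 0, ]
  cal2 <- calibration_by_score(sub, fit)
  expect_false(cal2$present[cal2$score == 0])
  expect_true(is.na(cal2$observed[cal2$score == 0]))
})

test_that("the one-call validation assembles a coherent report", {
  coh <- simulate_cohort(tss_cohort_config(n = 586, rho = suite_rho, seed = 123))
  v <- tss_validate(coh)
  expect_s3_class(v, "tss_validation")
  expect_output(print(v), "AUC")
  expect_equal(v$n, 586)
  expect_equal(v$roc$auc, brute_force_concordance(coh$outcome, coh$tss_total),
               tolerance = 1e-12)
  rep <- as_report(v)
  expect_equal(rep$roc$auc, v$roc$auc)
  expect_equal(rep$cohort$n, 586)
  expect_equal(nrow(rep$calibration), 9)
})

test_that("McFadden R2 on calibrated synthetic cohorts brackets the published value", {
  r2 <- vapply(1:40, function(i) {
    coh <- simulate_cohort(tss_cohort_config(n = 586, mode = "model_based",
                                             rho = suite_rho, seed = 900 + i))
    fit_statistics(tss_fit(outcome ~ tss_total, coh))$mcfadden_r2
  }, numeric(1))
  expect_gte(median(r2), 0.10)
  expect_lte(median(r2), 0.25)
})
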