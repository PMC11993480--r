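test_that("trinary moment matching solves the two-moment system exactly", {
  p <- moment_match_trinary(0.79, 0.92)
  expect_equal(unname(p), c(0.55025, 0.10950, 0.34025), tolerance = 1e-12)
  expect_equal(unname(moment_match_trinary(2, 0)), c(0, 0, 1))
  expect_equal(unname(moment_match_trinary(1, 0)), c(0, 1, 0))
  # the reconstructed moments are exact for feasible inputs
  set.seed(13)
  for (i in 1:20) {
    m <- runif(1, 0.3, 1.7)
    s <- runif(1, sqrt(max(0, m - m^2 / 1)) * 0, 0.4) + 0.5  # keep feasible-ish
    pr <- tryCatch(moment_match_trinary(m, s), error = function(e) NULL)
    if (is.null(pr)) next
    k <- 0:2
    expect_equal(sum(pr * k), m, tolerance = 1e-9)
    expect_equal(sqrt(sum(pr * k^2) - m^2), s, tolerance = 1e-9)
  }
  expect_error(moment_match_trinary(0.1, 1.5), "infeasible")
  expect_error(moment_match_trinary(1, 1.1), "infeasible")
})

test_that("Bernoulli margins report the implied SD for cross-checking", {
  b <- bernoulli_margin(0.42)
  expect_equal(b$p, 0.42)
  expect_equal(b$implied_sd, sqrt(0.42 * 0.58))
  expect_equal(bernoulli_margin(0.42)$implied_sd, 0.50, tolerance = 0.015)
  expect_equal(bernoulli_margin(0.9)$implied_sd, 0.30, tolerance = 0.01)
  expect_equal(bernoulli_margin(0)$implied_sd, 0)
  expect_error(bernoulli_margin(1.2), "\\[0, 1\\]")
})

test_that("the published margins demand positive correlation and calibration finds it", {
  m <- tss_study_margins()
  # independence falls well short of the published total-score SD
  var_ind <- sum(vapply(m$complication, function(ms) ms[["sd"]]^2, numeric(1)))
  expect_equal(sqrt(var_ind), 1.52, tolerance = 0.01)
  expect_lt(sqrt(var_ind), 2.22)
  # suite_rho was calibrated in the helper; both are proper correlations
  expect_true(all(suite_rho > 0 & suite_rho < 1))
  # degenerate target below independence returns zero with a warning
  expect_warning(r0 <- calibrate_rho(m$complication, 1.0, n = 2e4, seed = 1),
                 "independence")
  expect_equal(r0, 0)
  expect_error(calibrate_rho(m$complication, 5, n = 2e4, seed = 1),
               "unreachable")
})

test_that("simulated total-score SD is non-decreasing in rho and hits its target", {
  sds <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(rho) {
    coh <- simulate_cohort(tss_cohort_config(n = 20000, prevalence = 0.999,
                                             rho = c(rho, rho), seed = 42))
    sd(coh$tss_total[coh$outcome == 1])
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  # calibrated rho reproduces the published group SDs
  coh <- simulate_cohort(tss_cohort_config(n = 100000, rho = suite_rho, seed = 7))
  expect_equal(sd(coh$tss_total[coh$outcome == 1]), 2.22, tolerance = 0.08)
  expect_equal(sd(coh$tss_total[coh$outcome == 0]), 1.56, tolerance = 0.06)
})

test_that("generated sub-scores reproduce the published group margins", {
  coh <- simulate_cohort(tss_cohort_config(n = 100000, rho = suite_rho, seed = 11))
  m <- tss_study_margins()
  cols <- c(tad = "tad_score", quadrant = "quadrant_score",
            ap_alignment = "ap_alignment_score",
            lateral_alignment = "lateral_alignment_score",
            mcs = "mcs_score", acs = "acs_score")
  for (g in c(1, 0)) {
    gm <- if (g == 1) m$complication else m$none
    sub <- coh[coh$outcome == g, ]
    for (nm in names(cols)) {
      expect_equal(mean(sub[[cols[nm]]]), unname(gm[[nm]]["mean"]),
                   tolerance = 0.02)
    }
  }
  # totals sum the sub-scores and stay on 0..8 without truncation
  expect_equal(coh$tss_total,
               as.integer(rowSums(coh[, unname(cols)])))
  expect_true(all(coh$tss_total >= 0 & coh$tss_total <= 8))
})

test_that("back-filled raw measurements re-score to the generated sub-scores", {
  coh <- simulate_cohort(tss_cohort_config(n = 2000, rho = suite_rho, seed = 29))
  rescored <- tss_score(coh[, c("tad_mm", "quadrant_ap", "quadrant_lat",
                                "cda_diff_deg", "lateral_angulation_deg",
                                "mcs", "acs")])
  expect_identical(rescored$tad_score, coh$tad_score)
  expect_identical(rescored$quadrant_score, coh$quadrant_score)
  expect_identical(rescored$ap_alignment_score, coh$ap_alignment_score)
  expect_identical(rescored$lateral_alignment_score, coh$lateral_alignment_score)
  expect_identical(rescored$mcs_score, coh$mcs_score)
  expect_identical(rescored$acs_score, coh$acs_score)
  expect_identical(rescored$tss_total, coh$tss_total)
})

test_that("the complication count stays in its binomial envelope", {
  coh <- simulate_cohort(tss_cohort_config(n = 586, rho = suite_rho, seed = 37))
  bounds <- qbinom(c(0.005, 0.995), 586, 48 / 586)
  expect_gte(sum(coh$outcome), bounds[1])
  expect_lte(sum(coh$outcome), bounds[2])
})

test_that("model-based generation approaches the published prevalence", {
  coh <- simulate_cohort(tss_cohort_config(n = 100000, mode = "model_based",
                                           rho = suite_rho, seed = 53))
  expect_equal(mean(coh$outcome), 48 / 586, tolerance = 0.25)
  expect_lt(abs(mean(coh$outcome) - 48 / 586), 0.02)
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- tss_cohort_config(n = 300, rho = suite_rho, seed = 8)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(a, f1)
  write_cohort(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the derived intercept matches its closed form and the risk bands", {
  b0 <- derive_model_intercept(0.248, 3, -0.597)
  expect_equal(b0, qlogis(0.248) + 3 * 0.597, tolerance = 1e-12)
  expect_equal(derive_model_intercept(0.5, 0, -2), 0)
  expect_error(derive_model_intercept(0, 3, -0.597), "strictly between")
  p5 <- predicted_probability(5, b0, -0.597)
  p6 <- predicted_probability(6, b0, -0.597)
  expect_equal(p5, 0.091, tolerance = 0.005)
  expect_equal(p6, 0.052, tolerance = 0.005)
})
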