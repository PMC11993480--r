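# Independent oracles and shared fixtures for the test suite.

# Brute-force tie-corrected concordance probability: over all
# (event, non-event) pairs, the fraction in which the event has the lower
# score, counting ties as one half. This is the Mann-Whitney reading of
# the AUC for a score in which lower values indicate higher risk.
brute_force_concordance <- function(outcome, score) {
  s1 <- score[outcome == 1]
  s0 <- score[outcome == 0]
  total <- 0
  for (a in s1) {
    for (b in s0) {
      total <- total + (a < b) + 0.5 * (a == b)
    }
  }
  total / (length(s1) * length(s0))
}

# Copula correlations used throughout the suite where a calibrated default
# is needed without re-running the bisection in every test. Calibrated
# once here (deterministically) at suite start-up.
suite_rho <- local({
  m <- tss_study_margins()
  c(calibrate_rho(m$complication, 2.22, seed = 101),
    calibrate_rho(m$none, 1.56, seed = 202))
})

# A small complete measurement record meeting every scoring target.
perfect_record <- function() {
  data.frame(tad_mm = 20, quadrant_ap = "centre", quadrant_lat = "centre",
             cda_diff_deg = 0, lateral_angulation_deg = 10,
             mcs = "positive", acs = "positive",
             stringsAsFactors = FALSE)
}

# Random complete measurement records for property tests.
random_records <- function(n) {
  data.frame(
    tad_mm = runif(n, 5, 45),
    quadrant_ap = sample(c("superior", "centre", "inferior"), n, replace = TRUE),
    quadrant_lat = sample(c("anterior", "centre", "posterior"), n, replace = TRUE),
    cda_diff_deg = runif(n, -25, 25),
    lateral_angulation_deg = runif(n, 0, 35),
    mcs = sample(c("negative", "neutral", "positive"), n, replace = TRUE),
    acs = sample(c("negative", "neutral", "positive"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
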