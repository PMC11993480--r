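# Synthetic cohort generator calibrated to the published group summaries.
#
# The study cohort itself is not deposited, so the generator reproduces its
# statistical structure: per-group sub-score margins (moment-matched to the
# published means/SDs), an equicorrelated Gaussian copula per group
# calibrated so the simulated total-score SD matches the published group
# SDs, and raw measurements back-filled consistently with each sub-score so
# that re-scoring a generated record reproduces its sub-scores exactly.

#' Published per-group sub-score margins
#'
#' Mean and SD of each of the six sub-scores in the complication and
#' non-complication groups of the development cohort (n = 48 / 538). These
#' are the generator's default margins.
#'
#' @return Nested list: `$complication` and `$none`, each a list of
#'   `c(mean, sd)` for `tad`, `quadrant`, `ap_alignment`,
#'   `lateral_alignment`, `mcs`, `acs`.
#' @export
tss_study_margins <- function() {
  list(
    complication = list(
      tad = c(mean = 0.79, sd = 0.92),
      quadrant = c(mean = 0.98, sd = 0.79),
      ap_alignment = c(mean = 0.42, sd = 0.50),
      lateral_alignment = c(mean = 0.90, sd = 0.31),
      mcs = c(mean = 0.42, sd = 0.50),
      acs = c(mean = 0.56, sd = 0.50)),
    none = list(
      tad = c(mean = 1.41, sd = 0.85),
      quadrant = c(mean = 1.56, sd = 0.60),
      ap_alignment = c(mean = 0.57, sd = 0.50),
      lateral_alignment = c(mean = 0.98, sd = 0.13),
      mcs = c(mean = 0.70, sd = 0.46),
      acs = c(mean = 0.91, sd = 0.29)))
}

#' Published per-group raw-measurement summaries
#'
#' Group means/SDs of the raw radiographic measurements and the published
#' lag-screw quadrant frequencies, used to back-fill raw measurement
#' columns consistently with the generated sub-scores. The four published
#' quadrant frequencies are taken as-is; the unlisted remainder is spread
#' uniformly over the other five quadrant combinations.
#'
#' @return Nested list: `$complication` and `$none`, each with `tad`,
#'   `cda_diff`, `lateral_angulation` as `c(mean, sd)` and
#'   `quadrant_freq` as a named probability vector over the nine
#'   `"ap:lat"` combinations.
#' @export
tss_study_raw_defaults <- function() {
  list(
    complication = list(
      tad = c(mean = 31.09, sd = 11.22),
      cda_diff = c(mean = -5.27, sd = 9.8),
      lateral_angulation = c(mean = 11.58, sd = 6.70),
      quadrant_freq = quadrant_freq_table(sa = 0.063, sp = 0.25,
                                          cc = 0.188, ic = 0.104)),
    none = list(
      tad = c(mean = 23.66, sd = 9.46),
      cda_diff = c(mean = -1.23, sd = 6.05),
      lateral_angulation = c(mean = 8.81, sd = 4.95),
      quadrant_freq = quadrant_freq_table(sa = 0.011, sp = 0.046,
                                          cc = 0.355, ic = 0.262)))
}

.quadrant_combos <- c("superior:anterior", "superior:centre",
                      "superior:posterior", "centre:anterior",
                      "centre:centre", "centre:posterior",
                      "inferior:anterior", "inferior:centre",
                      "inferior:posterior")

quadrant_freq_table <- function(sa, sp, cc, ic) {
  freq <- stats::setNames(rep(0, 9L), .quadrant_combos)
  freq["superior:anterior"] <- sa
  freq["superior:posterior"] <- sp
  freq["centre:centre"] <- cc
  freq["inferior:centre"] <- ic
  rest <- setdiff(.quadrant_combos,
                  c("superior:anterior", "superior:posterior",
                    "centre:centre", "inferior:centre"))
  freq[rest] <- (1 - sa - sp - cc - ic) / length(rest)
  freq
}

#' Moment-matched probabilities on the support \{0, 1, 2\}
#'
#' Solves `p1 + 2 p2 = mean` and `p1 + 4 p2 = sd^2 + mean^2` for the
#' unique distribution on \{0, 1, 2\} with exactly the requested first two
#' moments. Infeasible moment pairs (any probability outside `[0, 1]`)
#' raise an error reporting the violated bound.
#'
#' @param mean,sd Target mean (in `[0, 2]`) and SD.
#' @return Numeric vector `c(p0, p1, p2)`.
#' @examples
#' moment_match_trinary(0.79, 0.92)  # c(0.5503, 0.1095, 0.3402)
#' @export
moment_match_trinary <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  m2 <- sd^2 + mean^2
  p2 <- (m2 - mean) / 2
  p1 <- mean - 2 * p2
  p0 <- 1 - p1 - p2
  p <- c(p0 = p0, p1 = p1, p2 = p2)
  tol <- 1e-9
  if (any(p < -tol) || any(p > 1 + tol)) {
    bad <- which(p < -tol | p > 1 + tol)[1]
    stop(sprintf(
      "infeasible moments (mean %.4g, sd %.4g): %s = %.4g outside [0, 1]",
      mean, sd, names(p)[bad], p[bad]))
  }
  p <- pmin(pmax(p, 0), 1)
  p / sum(p)
}

#' Bernoulli margin from a published mean
#'
#' For a binary sub-score the published mean determines the distribution;
#' the implied SD `sqrt(p (1 - p))` is returned so it can be cross-checked
#' against the published SD.
#'
#' @param mean Target mean in `[0, 1]`.
#' @return List with `p` and `implied_sd`.
#' @export
bernoulli_margin <- function(mean) {
  if (!is.numeric(mean) || mean < 0 || mean > 1) {
    stop("mean must lie in [0, 1]")
  }
  list(p = mean, implied_sd = sqrt(mean * (1 - mean)))
}

# Probability vectors (support 0..k) for one group's six margins.
margin_probs <- function(group_margins) {
  list(
    tad = moment_match_trinary(group_margins$tad["mean"],
                               group_margins$tad["sd"]),
    quadrant = moment_match_trinary(group_margins$quadrant["mean"],
                                    group_margins$quadrant["sd"]),
    ap_alignment = binary_probs(group_margins$ap_alignment["mean"]),
    lateral_alignment = binary_probs(group_margins$lateral_alignment["mean"]),
    mcs = binary_probs(group_margins$mcs["mean"]),
    acs = binary_probs(group_margins$acs["mean"]))
}

binary_probs <- function(mean) {
  p <- bernoulli_margin(unname(mean))$p
  c(1 - p, p)
}

# Equicorrelated Gaussian copula draw thresholded through each margin's
# inverse CDF. Returns an n x 6 integer matrix of sub-scores.
sample_subscores <- function(n, probs, rho) {
  stopifnot(rho >= 0, rho < 1)
  if (n == 0L) {
    return(matrix(integer(0), 0L, length(probs),
                  dimnames = list(NULL, names(probs))))
  }
  z0 <- stats::rnorm(n)
  out <- vapply(probs, function(p) {
    cum <- cumsum(p)[-length(p)]
    th <- stats::qnorm(pmin(pmax(cum, 1e-15), 1 - 1e-15))
    z <- sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
    findInterval(z, th)
  }, integer(n))
  if (n == 1L) out <- matrix(out, 1L, dimnames = list(NULL, names(probs)))
  out
}

#' Calibrate the copula correlation to a target total-score SD
#'
#' The published tables give only marginal sub-score moments; under
#' independence the total-score SD they imply falls short of the published
#' group SDs, so the margins must be positively correlated. This finds the
#' equicorrelated Gaussian-copula correlation whose simulated total-score
#' SD matches the target, by bisection with common random numbers (the
#' simulated SD is monotone in `rho`).
#'
#' @param margins One group's margins, as in `tss_study_margins()$none`.
#' @param target_sd Target SD of the total score.
#' @param n Monte Carlo sample size per bisection step (default 1e5).
#' @param tol Acceptable absolute SD mismatch (default 0.05).
#' @param seed Seed for the common-random-number draws.
#' @return The calibrated correlation in `[0, 1)`. If the independence SD
#'   already reaches the target, 0 is returned with a warning; if the
#'   target is unreachable even as `rho -> 1`, an error is raised.
#' @export
calibrate_rho <- function(margins, target_sd, n = 1e5, tol = 0.05, seed = 1) {
  probs <- margin_probs(margins)
  var_ind <- sum(vapply(probs, function(p) {
    k <- seq_along(p) - 1
    sum(p * k^2) - sum(p * k)^2
  }, numeric(1)))
  if (sqrt(var_ind) >= target_sd) {
    warning("independence already meets or exceeds the target SD; returning rho = 0")
    return(0)
  }
  sim_sd <- function(rho) {
    set.seed(seed)
    stats::sd(rowSums(sample_subscores(n, probs, rho)))
  }
  hi <- 0.999
  if (sim_sd(hi) < target_sd - tol) {
    stop("calibration failure: target total-score SD unreachable as rho -> 1")
  }
  lo <- 0
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    s <- sim_sd(mid)
    if (abs(s - target_sd) < tol / 2 || (hi - lo) < 1e-4) break
    if (s < target_sd) lo <- mid else hi <- mid
  }
  rho <- (lo + hi) / 2
  if (abs(sim_sd(rho) - target_sd) > tol) {
    stop("calibration failure: could not match the target SD within tolerance")
  }
  rho
}

#' Logistic intercept from a published probability anchor
#'
#' The published model reports only the slope; the intercept is recovered
#' from the probability threshold at its corresponding score:
#' `beta0 = logit(p) - beta1 * score`.
#'
#' @param anchor_probability Probability in `(0, 1)` (published Youden
#'   threshold 0.248).
#' @param anchor_score Score at which that probability is attained
#'   (published: 3 points).
#' @param beta1 Per-point log-odds slope (published: -0.597).
#' @return The implied intercept `beta0`.
#' @examples
#' derive_model_intercept(0.248, 3, -0.597)  # 0.6817
#' @export
derive_model_intercept <- function(anchor_probability, anchor_score, beta1) {
  if (anchor_probability <= 0 || anchor_probability >= 1) {
    stop("anchor_probability must lie strictly between 0 and 1")
  }
  stats::qlogis(anchor_probability) - beta1 * anchor_score
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the development cohort's published structure:
#' n = 586, prevalence 48/586, the published per-group sub-score margins
#' and raw-measurement summaries, copula correlations calibrated to the
#' published total-score SDs (2.22 complication / 1.56 non-complication),
#' and the published logistic slope with the anchor-derived intercept.
#'
#' @param n Cohort size.
#' @param prevalence Complication probability in `(0, 1)`.
#' @param mode `"distribution_matched"` (outcome first, then group-specific
#'   sub-scores) or `"model_based"` (score mixture first, then outcome from
#'   the logistic model).
#' @param margins Per-group sub-score margins (see [tss_study_margins()]).
#' @param total_sd Length-2 target total-score SDs,
#'   `c(complication, none)`, used to calibrate `rho` when it is `NULL`.
#' @param rho `NULL` (calibrate at generation time) or length-2 copula
#'   correlations `c(complication, none)`.
#' @param beta1 Logistic slope for `model_based` mode.
#' @param beta0 Logistic intercept; `NULL` derives it from `anchor`.
#' @param anchor `list(probability, score)` anchor for the intercept.
#' @param raw Per-group raw-measurement summaries (see
#'   [tss_study_raw_defaults()]).
#' @param seed Integer seed driving all generation randomness.
#' @return Object of class `tss_cohort_config`.
#' @export
tss_cohort_config <- function(n = 586, prevalence = 48 / 586,
                              mode = c("distribution_matched", "model_based"),
                              margins = tss_study_margins(),
                              total_sd = c(complication = 2.22, none = 1.56),
                              rho = NULL, beta1 = -0.597, beta0 = NULL,
                              anchor = list(probability = 0.248, score = 3),
                              raw = tss_study_raw_defaults(), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1, prevalence > 0, prevalence < 1, length(total_sd) == 2L)
  if (!is.null(rho)) {
    stopifnot(length(rho) == 2L, all(rho >= 0), all(rho < 1))
  }
  structure(list(n = as.integer(n), prevalence = prevalence, mode = mode,
                 margins = margins, total_sd = total_sd, rho = rho,
                 beta1 = beta1, beta0 = beta0, anchor = anchor, raw = raw,
                 seed = as.integer(seed)),
            class = "tss_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort with the configured statistical structure. In
#' `distribution_matched` mode the outcome is Bernoulli(prevalence) and,
#' given the outcome group, the six sub-scores come from that group's
#' equicorrelated Gaussian copula thresholded through the moment-matched
#' margins. In `model_based` mode a latent group drawn at the prevalence
#' supplies the sub-scores and the outcome is then drawn from the logistic
#' model at the resulting total. Raw measurement columns (TAD, quadrant
#' bands, CDA difference, lateral angulation, cortical support categories)
#' are back-filled from the group's published summaries restricted to the
#' region each sub-score implies, so re-scoring a generated record with
#' [tss_score()] reproduces its sub-scores exactly.
#'
#' Generation is deterministic given the config (including the seed).
#'
#' @param config A [tss_cohort_config()].
#' @return Data frame with columns `id`, `outcome`, the six sub-scores,
#'   `tss_total`, and the raw measurement columns `tad_mm`,
#'   `quadrant_ap`, `quadrant_lat`, `cda_diff_deg`,
#'   `lateral_angulation_deg`, `mcs`, `acs`. The fully resolved config
#'   (calibrated `rho`, derived `beta0`) is attached as attribute
#'   `"config"`.
#' @examples
#' cohort <- simulate_cohort(tss_cohort_config(n = 200, seed = 7, rho = c(0.4, 0.2)))
#' table(cohort$outcome)
#' @export
simulate_cohort <- function(config = tss_cohort_config()) {
  stopifnot(inherits(config, "tss_cohort_config"))
  if (is.null(config$rho)) {
    sub_seed <- function(off) {
      as.integer((as.numeric(config$seed) + off) %% 2147483647)
    }
    config$rho <- c(
      calibrate_rho(config$margins$complication, config$total_sd[[1]],
                    seed = sub_seed(101)),
      calibrate_rho(config$margins$none, config$total_sd[[2]],
                    seed = sub_seed(202)))
  }
  if (is.null(config$beta0)) {
    config$beta0 <- derive_model_intercept(config$anchor$probability,
                                           config$anchor$score, config$beta1)
  }
  set.seed(config$seed)
  n <- config$n
  probs <- list(complication = margin_probs(config$margins$complication),
                none = margin_probs(config$margins$none))

  if (config$mode == "distribution_matched") {
    outcome <- stats::rbinom(n, 1L, config$prevalence)
    group <- outcome
  } else {
    group <- stats::rbinom(n, 1L, config$prevalence)
  }

  scores <- matrix(NA_integer_, n, 6L,
                   dimnames = list(NULL, names(probs$complication)))
  for (g in c(1L, 0L)) {
    idx <- which(group == g)
    gp <- if (g == 1L) probs$complication else probs$none
    gr <- if (g == 1L) config$rho[[1]] else config$rho[[2]]
    scores[idx, ] <- sample_subscores(length(idx), gp, gr)
  }
  total <- rowSums(scores)

  if (config$mode == "model_based") {
    outcome <- stats::rbinom(n, 1L, stats::plogis(config$beta0 +
                                                    config$beta1 * total))
  }

  raw <- backfill_raw(scores, group, config$raw)
  out <- data.frame(id = seq_len(n), outcome = outcome,
                    tad_score = scores[, "tad"],
                    quadrant_score = scores[, "quadrant"],
                    ap_alignment_score = scores[, "ap_alignment"],
                    lateral_alignment_score = scores[, "lateral_alignment"],
                    mcs_score = scores[, "mcs"],
                    acs_score = scores[, "acs"],
                    tss_total = as.integer(total))
  out <- cbind(out, raw)
  attr(out, "config") <- config
  out
}

# Raw measurements consistent with each sub-score, drawn from the group's
# published summaries truncated to the region the score implies.
backfill_raw <- function(scores, group, raw) {
  n <- nrow(scores)
  tad_mm <- cda <- ang <- numeric(n)
  qap <- qlat <- mcs <- acs <- character(n)
  for (g in c(1L, 0L)) {
    idx <- which(group == g)
    if (!length(idx)) next
    pr <- if (g == 1L) raw$complication else raw$none

    tad_mm[idx] <- sample_banded_normal(
      scores[idx, "tad"], pr$tad["mean"], pr$tad["sd"],
      bands = list(`0` = c(30, Inf), `1` = c(25, 30), `2` = c(0, 25)))
    ang[idx] <- sample_banded_normal(
      scores[idx, "lateral_alignment"], pr$lateral_angulation["mean"],
      pr$lateral_angulation["sd"],
      bands = list(`0` = c(20, Inf), `1` = c(0, 20)))
    cda[idx] <- sample_union_normal(
      scores[idx, "ap_alignment"], pr$cda_diff["mean"], pr$cda_diff["sd"],
      regions = list(`0` = rbind(c(-Inf, 0), c(10, Inf)),
                     `1` = rbind(c(0, 10))))

    q <- sample_quadrants(scores[idx, "quadrant"], pr$quadrant_freq)
    qap[idx] <- q$ap
    qlat[idx] <- q$lat
    mcs[idx] <- sample_cortical(scores[idx, "mcs"])
    acs[idx] <- sample_cortical(scores[idx, "acs"])
  }
  data.frame(tad_mm = tad_mm, quadrant_ap = qap, quadrant_lat = qlat,
             cda_diff_deg = cda, lateral_angulation_deg = ang,
             mcs = mcs, acs = acs)
}

# Truncated normal via inverse-CDF, one contiguous band per score value.
sample_banded_normal <- function(score, mean, sd, bands) {
  out <- numeric(length(score))
  for (s in names(bands)) {
    idx <- which(score == as.integer(s))
    if (!length(idx)) next
    b <- bands[[s]]
    out[idx] <- rtrunc_norm(length(idx), mean, sd, b[1], b[2])
  }
  out
}

# Truncated normal on a union of disjoint intervals (rows of `regions`).
sample_union_normal <- function(score, mean, sd, regions) {
  out <- numeric(length(score))
  for (s in names(regions)) {
    idx <- which(score == as.integer(s))
    if (!length(idx)) next
    reg <- regions[[s]]
    mass <- stats::pnorm(reg[, 2], mean, sd) - stats::pnorm(reg[, 1], mean, sd)
    mass <- pmax(mass, 1e-12)
    pick <- sample.int(nrow(reg), length(idx), replace = TRUE,
                       prob = mass / sum(mass))
    out[idx] <- vapply(seq_along(idx), function(i) {
      rtrunc_norm(1L, mean, sd, reg[pick[i], 1], reg[pick[i], 2])
    }, numeric(1))
  }
  out
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    # essentially no mass in the band: fall back to the nearer edge
    edge <- if (is.finite(lo)) lo else hi
    return(rep(edge + if (is.finite(hi)) (hi - lo) / 2 else 0, n))
  }
  x <- stats::qnorm(stats::runif(n, plo, phi), mean, sd)
  if (is.finite(hi)) x <- pmin(x, hi - 1e-9)
  if (is.finite(lo)) x <- pmax(x, lo)
  x
}

sample_quadrants <- function(score, freq) {
  combo_score <- score_quadrant(
    sub(":.*", "", .quadrant_combos), sub(".*:", "", .quadrant_combos))
  out <- character(length(score))
  for (s in 0:2) {
    idx <- which(score == s)
    if (!length(idx)) next
    combos <- .quadrant_combos[combo_score == s]
    w <- freq[combos]
    w <- pmax(w, 1e-12)
    out[idx] <- sample(combos, length(idx), replace = TRUE, prob = w / sum(w))
  }
  list(ap = sub(":.*", "", out), lat = sub(".*:", "", out))
}

sample_cortical <- function(score) {
  out <- rep("negative", length(score))
  idx <- which(score == 1L)
  if (length(idx)) {
    out[idx] <- sample(c("neutral", "positive"), length(idx), replace = TRUE)
  }
  out
}
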