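# The targeted surgical score: six sub-scores, 0-8 total, risk bands.

.band_ap <- c("superior", "centre", "inferior")
.band_lat <- c("anterior", "centre", "posterior")
.cortical_levels <- c("negative", "neutral", "positive")
.risk_levels <- c("very_low", "low", "moderate", "high")

#' Tip-apex distance sub-score (0-2 points)
#'
#' Target `< 25` mm scores 2, acceptable `[25, 30)` mm scores 1,
#' undesirable `>= 30` mm scores 0. The band edges follow the classical
#' cutout thresholds: risk is markedly decreased below 25 mm and markedly
#' increased at 30 mm and above, so 25 mm falls in the acceptable band and
#' 30 mm in the undesirable one.
#'
#' @param tad Tip-apex distance in mm (vectorised, non-negative).
#' @return Integer points in `{0, 1, 2}`.
#' @export
score_tad <- function(tad) {
  check_nonneg(tad, "tad")
  as.integer(ifelse(tad < 25, 2L, ifelse(tad < 30, 1L, 0L)))
}

#' Lag-screw quadrant sub-score (0-2 points)
#'
#' Centre-centre and inferior-centre placements score 2; superior-anterior
#' and superior-posterior placements score 0; the remaining five
#' combinations score 1.
#'
#' @param ap_band Character vector in `c("superior", "centre", "inferior")`.
#' @param lat_band Character vector in `c("anterior", "centre", "posterior")`.
#' @return Integer points in `{0, 1, 2}`.
#' @export
score_quadrant <- function(ap_band, lat_band) {
  check_levels(ap_band, .band_ap, "ap_band")
  check_levels(lat_band, .band_lat, "lat_band")
  target <- (ap_band == "centre" | ap_band == "inferior") & lat_band == "centre"
  undesirable <- ap_band == "superior" & lat_band != "centre"
  out <- ifelse(target, 2L, ifelse(undesirable, 0L, 1L))
  out[is.na(ap_band) | is.na(lat_band)] <- NA_integer_
  as.integer(out)
}

#' AP alignment sub-score (0-1 point)
#'
#' Neutral or mild valgus alignment (collo-diaphyseal angle difference in
#' `[0, 10)` degrees, fractured minus intact) scores 1; any varus or
#' `>= 10` degrees valgus scores 0. An optional varus neutrality tolerance
#' admits small negative differences (e.g. measurement error) into the
#' favourable window; the default is strict (0 degrees).
#'
#' @param cda_diff Signed angle difference in degrees (vectorised).
#' @param varus_tolerance Non-negative tolerance in degrees; differences
#'   down to `-varus_tolerance` still score 1.
#' @return Integer points in `{0, 1}`.
#' @export
score_ap_alignment <- function(cda_diff, varus_tolerance = 0) {
  stopifnot(is.numeric(cda_diff), length(varus_tolerance) == 1L,
            varus_tolerance >= 0)
  as.integer(cda_diff >= -varus_tolerance & cda_diff < 10)
}

#' Lateral alignment sub-score (0-1 point)
#'
#' Angulation between the proximal fragment axis and the diaphyseal axis on
#' the lateral film below 20 degrees scores 1; 20 degrees and above scores
#' 0. The angulation is an absolute magnitude.
#'
#' @param angulation Lateral angulation in degrees (vectorised,
#'   non-negative).
#' @return Integer points in `{0, 1}`.
#' @export
score_lateral_alignment <- function(angulation) {
  check_nonneg(angulation, "angulation")
  as.integer(angulation < 20)
}

#' Cortical support sub-score (0-1 point)
#'
#' Neutral or positive medial (AP) / anterior (lateral) cortical support
#' scores 1; negative support scores 0.
#'
#' @param category Character vector in
#'   `c("negative", "neutral", "positive")`.
#' @return Integer points in `{0, 1}`.
#' @export
score_cortical <- function(category) {
  check_levels(category, .cortical_levels, "cortical support category")
  out <- as.integer(category %in% c("neutral", "positive"))
  out[is.na(category)] <- NA_integer_
  out
}

#' Clinical risk band for a total score
#'
#' Totals 7-8 map to very low predicted complication risk (< 5%), 5-6 to
#' low (5-10%), 2-4 to moderate (10-50%) and 0-1 to high (> 50%).
#'
#' @param total Integer total score in `0:8` (vectorised).
#' @return Factor with levels `very_low < low < moderate < high`.
#' @export
assign_risk_band <- function(total) {
  bad <- !is.na(total) & (total < 0 | total > 8 | total != round(total))
  if (any(bad)) stop("total score must be an integer in 0..8")
  band <- ifelse(total >= 7, "very_low",
                 ifelse(total >= 5, "low",
                        ifelse(total >= 2, "moderate", "high")))
  factor(band, levels = .risk_levels)
}

#' Model-predicted complication probability for a total score
#'
#' Evaluates the logistic curve `1 / (1 + exp(-(beta0 + beta1 * total)))`.
#' With a negative slope the probability decreases strictly in the score
#' and equals 0.5 at `total = -beta0 / beta1`.
#'
#' @param total Total score (vectorised, `0:8` for the published model, but
#'   any numeric is accepted).
#' @param beta0 Logit intercept.
#' @param beta1 Per-point log-odds slope.
#' @return Probability in `(0, 1)`.
#' @seealso [derive_model_intercept()] for the published anchor-based
#'   intercept.
#' @export
predicted_probability <- function(total, beta0, beta1) {
  stats::plogis(beta0 + beta1 * total)
}

#' Score a cohort of radiographic measurements
#'
#' Applies the six scoring rules to a measurement table and appends the
#' sub-score columns, the total score, the clinical risk band and
#' (optionally) a model-predicted complication probability. Required input
#' columns: `tad_mm`, `quadrant_ap`, `quadrant_lat`, `cda_diff_deg`,
#' `lateral_angulation_deg`, `mcs`, `acs`. Rows with missing measurements
#' are scored partially and flagged via the `incomplete` column rather
#' than imputed.
#'
#' @param data Data frame of per-hip measurements (one row per hip).
#' @param varus_tolerance Passed to [score_ap_alignment()].
#' @param model Optional `list(beta0 = , beta1 = )`; when supplied, a
#'   `predicted_probability` column is added.
#' @return The input data frame with columns `tad_score`,
#'   `quadrant_score`, `ap_alignment_score`, `lateral_alignment_score`,
#'   `mcs_score`, `acs_score`, `tss_total`, `risk_band`, `incomplete`
#'   (and `predicted_probability` when `model` is given) appended.
#' @examples
#' rec <- data.frame(tad_mm = 20, quadrant_ap = "centre",
#'                   quadrant_lat = "centre", cda_diff_deg = 0,
#'                   lateral_angulation_deg = 10, mcs = "positive",
#'                   acs = "positive")
#' tss_score(rec)$tss_total  # 8
#' @export
tss_score <- function(data, varus_tolerance = 0, model = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("tad_mm", "quadrant_ap", "quadrant_lat", "cda_diff_deg",
                "lateral_angulation_deg", "mcs", "acs")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing measurement column(s): ", paste(missing_cols, collapse = ", "))
  }
  sub <- data.frame(
    tad_score = score_tad(data$tad_mm),
    quadrant_score = score_quadrant(as.character(data$quadrant_ap),
                                    as.character(data$quadrant_lat)),
    ap_alignment_score = score_ap_alignment(data$cda_diff_deg, varus_tolerance),
    lateral_alignment_score = score_lateral_alignment(data$lateral_angulation_deg),
    mcs_score = score_cortical(as.character(data$mcs)),
    acs_score = score_cortical(as.character(data$acs)))
  total <- rowSums(sub)
  out <- cbind(data, sub)
  out$tss_total <- as.integer(total)
  out$risk_band <- assign_risk_band(out$tss_total)
  out$incomplete <- is.na(total)
  if (!is.null(model)) {
    stopifnot(is.list(model), all(c("beta0", "beta1") %in% names(model)))
    out$predicted_probability <- predicted_probability(out$tss_total,
                                                       model$beta0, model$beta1)
  }
  out
}

check_levels <- function(x, levels, name) {
  if (is.factor(x)) x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("unknown %s: %s (expected one of %s)", name,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")))
  }
  invisible(x)
}
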