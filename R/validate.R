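# One-call validation of a scored cohort, mirroring the published analysis.

#' Validate the targeted surgical score on a cohort
#'
#' Runs the full validation pipeline on a scored cohort: logistic fit of
#' the outcome on the total score with odds ratios, ROC/AUC with the
#' Youden cutoff mapped back to a score threshold, confusion metrics at
#' that cutoff, Hosmer-Lemeshow calibration, McFadden pseudo R-squared and
#' likelihood-ratio test, the between-group Mann-Whitney comparison of the
#' score, and the per-score-level observed/predicted calibration table.
#'
#' @param data Data frame with at least the outcome and total-score
#'   columns (e.g. from [simulate_cohort()] or [tss_score()] joined with
#'   outcomes).
#' @param score_col,outcome_col Column names (defaults `"tss_total"`,
#'   `"outcome"`).
#' @param hl_groups Requested Hosmer-Lemeshow groups (default 10; tied
#'   quantiles collapse automatically for discrete scores).
#' @param conf_level Wald confidence level (default 0.95).
#' @param cutoff Optional score cutoff overriding the Youden choice.
#' @return Object of class `tss_validation` with components `fit`, `roc`,
#'   `cutoff`, `confusion`, `hosmer_lemeshow`, `fit_statistics`,
#'   `group_comparison`, `calibration`, `n`, `prevalence`.
#' @examples
#' cohort <- simulate_cohort(tss_cohort_config(n = 400, seed = 1, rho = c(0.4, 0.2)))
#' v <- tss_validate(cohort)
#' print(v)
#' @export
tss_validate <- function(data, score_col = "tss_total",
                         outcome_col = "outcome", hl_groups = 10,
                         conf_level = 0.95, cutoff = NULL) {
  stopifnot(is.data.frame(data), score_col %in% names(data),
            outcome_col %in% names(data))
  keep <- !is.na(data[[score_col]]) & !is.na(data[[outcome_col]])
  data <- data[keep, , drop = FALSE]
  outcome <- data[[outcome_col]]
  score <- data[[score_col]]
  check_outcome(outcome)

  fit <- tss_fit(stats::reformulate(score_col, outcome_col), data,
                 conf_level = conf_level)
  roc <- roc_analysis(outcome, score, fit)
  cutoff <- if (is.null(cutoff)) roc$youden_cutoff else cutoff
  structure(
    list(fit = fit,
         roc = roc,
         cutoff = cutoff,
         confusion = confusion_metrics(outcome, score, cutoff),
         hosmer_lemeshow = hosmer_lemeshow(fit, groups = hl_groups),
         fit_statistics = fit_statistics(fit),
         group_comparison = group_compare(data, score_col, outcome_col,
                                          kind = "continuous"),
         calibration = calibration_by_score(data, fit, score_col, outcome_col),
         n = length(outcome),
         prevalence = mean(outcome)),
    class = "tss_validation")
}

#' @export
print.tss_validation <- function(x, ...) {
  or <- odds_ratio(x$fit)
  sl <- or[or$term != "(Intercept)", ][1, ]
  cat("Targeted surgical score validation\n")
  cat(sprintf("  n = %d, complications = %d (%.1f%%)\n", x$n,
              round(x$n * x$prevalence), 100 * x$prevalence))
  cat(sprintf("  Per-point beta = %.3f (SE %.3f), OR = %.3f [%.3f-%.3f]\n",
              sl$beta, sl$se, sl$or, sl$or_low, sl$or_high))
  cat(sprintf("  AUC = %.3f; Youden cutoff: score <= %g\n", x$roc$auc,
              x$cutoff))
  cat(sprintf("  Sensitivity %.1f%%, specificity %.1f%%, accuracy %.2f%%\n",
              100 * x$confusion$sensitivity, 100 * x$confusion$specificity,
              100 * x$confusion$accuracy))
  cat(sprintf("  Hosmer-Lemeshow p = %.3f (df %d); McFadden R2 = %.3f; LR p = %.3g\n",
              x$hosmer_lemeshow$p_value, x$hosmer_lemeshow$df,
              x$fit_statistics$mcfadden_r2, x$fit_statistics$lr_p))
  cat(sprintf("  Mann-Whitney U = %g, p = %.3g\n",
              x$group_comparison$statistic, x$group_comparison$p_value))
  invisible(x)
}

#' @export
summary.tss_validation <- function(object, ...) {
  print(object)
  cat("\nCalibration by score level:\n")
  print(object$calibration, digits = 4)
  invisible(object)
}

#' @export
plot.tss_validation <- function(x, which = c("calibration", "roc"), ...) {
  which <- match.arg(which)
  if (which == "roc") return(plot(x$roc, ...))
  cal <- x$calibration[x$calibration$present, ]
  plot(cal$score, 100 * cal$observed, type = "b", pch = 16,
       xlab = "Total score", ylab = "Complication rate (%)", ...)
  graphics::lines(x$calibration$score, 100 * x$calibration$predicted,
                  type = "b", pch = 1, lty = 2)
  graphics::legend("topright", legend = c("observed", "predicted"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Flatten a validation result into a plain report list
#'
#' Produces a nested list of named scalars and small tables suitable for
#' serialisation with [write_report()].
#'
#' @param x A `tss_validation` object.
#' @return A list with elements `model`, `roc`, `diagnostics`,
#'   `group_comparison`, `calibration`, `cohort`.
#' @export
as_report <- function(x) {
  stopifnot(inherits(x, "tss_validation"))
  or <- odds_ratio(x$fit)
  list(
    cohort = list(n = x$n, prevalence = x$prevalence),
    model = list(
      terms = or$term, beta = or$beta, se = or$se,
      ci_low = unname(x$fit$ci[, "lower"]),
      ci_high = unname(x$fit$ci[, "upper"]),
      odds_ratio = or$or, or_low = or$or_low, or_high = or$or_high,
      p_values = unname(x$fit$p_values),
      log_likelihood = x$fit$log_likelihood,
      null_log_likelihood = x$fit$null_log_likelihood,
      converged = x$fit$converged),
    roc = list(auc = x$roc$auc, youden_j = x$roc$youden_j,
               cutoff = x$cutoff,
               threshold_probability = x$roc$threshold_probability,
               sensitivity = x$confusion$sensitivity,
               specificity = x$confusion$specificity,
               accuracy = x$confusion$accuracy),
    diagnostics = list(
      hl_statistic = x$hosmer_lemeshow$statistic,
      hl_df = x$hosmer_lemeshow$df,
      hl_p = x$hosmer_lemeshow$p_value,
      mcfadden_r2 = x$fit_statistics$mcfadden_r2,
      lr_statistic = x$fit_statistics$lr_statistic,
      lr_p = x$fit_statistics$lr_p),
    group_comparison = list(
      mann_whitney_u = x$group_comparison$statistic,
      p_value = x$group_comparison$p_value),
    calibration = x$calibration)
}
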