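# Validation statistics: discrimination, calibration, group comparisons.

#' Empirical ROC analysis of a risk score
#'
#' Builds the empirical ROC curve of a score for which *lower* values
#' indicate higher complication risk (as for the total targeted surgical
#' score): at each distinct threshold `t` a positive call is `score <= t`.
#' The area under the curve is computed by the trapezoid rule, which on the
#' empirical curve equals the tie-corrected Mann-Whitney concordance
#' probability. The operating threshold is chosen by Youden's J
#' (sensitivity + specificity - 1), ties broken towards the more sensitive
#' (higher score) cutoff so the result is deterministic on discrete scores.
#'
#' When a single-covariate [tss_fit()] is supplied, the probability
#' threshold corresponding to the Youden cutoff is reported; because the
#' fitted probability is strictly monotone in the score, ranking by score
#' and by predicted probability give identical curves.
#'
#' @param outcome Binary vector (1 = complication), both classes present.
#' @param score Numeric score vector, lower = higher risk.
#' @param fit Optional [tss_fit()] of the outcome on this score alone.
#' @return Object of class `tss_roc`: `points` (threshold, fpr, tpr),
#'   `auc`, `youden_j`, `youden_cutoff` (score units),
#'   `threshold_probability` (if `fit` given), and `sensitivity`,
#'   `specificity`, `accuracy` at the cutoff.
#' @export
roc_analysis <- function(outcome, score, fit = NULL) {
  check_outcome(outcome)
  stopifnot(is.numeric(score), length(score) == length(outcome))
  s1 <- score[outcome == 1]
  s0 <- score[outcome == 0]
  th <- sort(unique(score))
  tpr <- vapply(th, function(t) mean(s1 <= t), numeric(1))
  fpr <- vapply(th, function(t) mean(s0 <= t), numeric(1))
  pts <- data.frame(threshold = c(-Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  k <- nrow(pts)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-k]) / 2)

  j <- tpr + (1 - fpr) - 1
  cutoff <- max(th[j == max(j)])
  cm <- confusion_metrics(outcome, score, cutoff)

  thr_prob <- NULL
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "tss_fit"))
    if (length(fit$coefficients) != 2L) {
      stop("fit must be a single-covariate model of the score")
    }
    thr_prob <- unname(stats::plogis(fit$coefficients[1] +
                                       fit$coefficients[2] * cutoff))
  }
  structure(list(points = pts, auc = auc, youden_j = max(j),
                 youden_cutoff = cutoff, threshold_probability = thr_prob,
                 sensitivity = cm$sensitivity, specificity = cm$specificity,
                 accuracy = cm$accuracy,
                 n_pos = length(s1), n_neg = length(s0)),
            class = "tss_roc")
}

#' @export
print.tss_roc <- function(x, ...) {
  cat("ROC analysis (", x$n_pos, " events / ", x$n_neg, " non-events)\n",
      sep = "")
  cat("AUC:", round(x$auc, 4), "\n")
  cat("Youden cutoff: score <=", x$youden_cutoff,
      " (J =", round(x$youden_j, 4), ")\n")
  if (!is.null(x$threshold_probability)) {
    cat("Probability threshold at cutoff:",
        round(x$threshold_probability, 4), "\n")
  }
  cat(sprintf("Sensitivity %.1f%%, specificity %.1f%%, accuracy %.2f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' @export
plot.tss_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Confusion-matrix metrics at a score cutoff
#'
#' A positive (high-risk) call is `score <= cutoff`. Accuracy satisfies
#' the identity `(sensitivity * n_pos + specificity * n_neg) / n`.
#'
#' @param outcome Binary vector (1 = complication).
#' @param score Numeric score, lower = higher risk.
#' @param cutoff Score cutoff for a positive call.
#' @return List with `sensitivity`, `specificity`, `accuracy`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_metrics <- function(outcome, score, cutoff) {
  check_outcome(outcome)
  pos_call <- score <= cutoff
  tp <- sum(pos_call & outcome == 1)
  fn <- sum(!pos_call & outcome == 1)
  tn <- sum(!pos_call & outcome == 0)
  fp <- sum(pos_call & outcome == 0)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(outcome),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients by predicted probability (deciles of risk by default;
#' quantile breaks that coincide because the predictor is discrete are
#' collapsed, so a single-score model is effectively grouped by score
#' level) and compares observed and expected event counts with the
#' chi-square statistic `sum (O - E)^2 / (n_g * pi_g * (1 - pi_g))` on
#' `groups - 2` degrees of freedom.
#'
#' @param fit A converged [tss_fit()], or a binary outcome vector when
#'   `prob` is supplied directly.
#' @param prob Predicted probabilities matching `fit` as an outcome
#'   vector; ignored when `fit` is a `tss_fit`.
#' @param groups Requested number of risk groups (default 10).
#' @return List with `statistic`, `df`, `p_value`, and a per-group
#'   `table` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(fit, prob = NULL, groups = 10) {
  if (inherits(fit, "tss_fit")) {
    if (!fit$converged) stop("model did not converge")
    outcome <- fit$glm$y
    prob <- stats::fitted(fit$glm)
  } else {
    outcome <- fit
    check_outcome(outcome)
    stopifnot(is.numeric(prob), length(prob) == length(outcome))
  }
  if (groups < 2) stop("at least 2 groups are required")
  if (length(unique(prob)) < 3L) {
    stop("fewer than 3 distinct predicted probabilities; reduce `groups` or refit")
  }
  breaks <- unique(stats::quantile(prob, probs = seq(0, 1, length.out = groups + 1)))
  if (length(breaks) < 3L) stop("could not form at least 2 risk groups")
  grp <- cut(prob, breaks = breaks, include.lowest = TRUE)
  n_g <- tapply(outcome, grp, length)
  keep <- !is.na(n_g) & n_g > 0
  o_g <- tapply(outcome, grp, sum)[keep]
  e_g <- tapply(prob, grp, sum)[keep]
  n_g <- n_g[keep]
  pi_g <- e_g / n_g
  denom <- n_g * pi_g * (1 - pi_g)
  term <- ifelse(denom > 0, (o_g - e_g)^2 / denom,
                 ifelse(abs(o_g - e_g) < 1e-12, 0, Inf))
  stat <- sum(term)
  df <- max(length(n_g) - 2L, 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(group = names(n_g), n = as.integer(n_g),
                          observed = as.integer(o_g),
                          expected = as.numeric(e_g), row.names = NULL))
}

#' Model fit statistics: McFadden pseudo R-squared and likelihood ratio
#'
#' McFadden's R2 is `1 - ll_model / ll_null`; the likelihood-ratio
#' statistic is `2 * (ll_model - ll_null)` on as many degrees of freedom
#' as there are non-intercept covariates.
#'
#' @param fit A converged [tss_fit()].
#' @return List with `mcfadden_r2`, `lr_statistic`, `lr_df`, `lr_p`.
#' @export
fit_statistics <- function(fit) {
  stopifnot(inherits(fit, "tss_fit"))
  if (!fit$converged) stop("model did not converge")
  r2 <- 1 - fit$log_likelihood / fit$null_log_likelihood
  lr <- 2 * (fit$log_likelihood - fit$null_log_likelihood)
  df <- length(fit$coefficients) - 1L
  list(mcfadden_r2 = r2, lr_statistic = lr, lr_df = df,
       lr_p = stats::pchisq(lr, df, lower.tail = FALSE))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of covariate `j` on the remaining covariates. Values near 1
#' indicate no collinearity; the conventional concern threshold is 5.
#' Perfectly collinear covariates are reported as `Inf` with a warning.
#'
#' @param data Data frame holding the covariates.
#' @param covariates Character vector of at least two column names; each
#'   column must be numeric with non-zero variance.
#' @return Named numeric vector of VIFs (all `>= 1`).
#' @export
vif <- function(data, covariates) {
  stopifnot(is.data.frame(data), is.character(covariates),
            length(covariates) >= 2L)
  X <- data[covariates]
  for (nm in covariates) {
    if (!is.numeric(X[[nm]])) stop(sprintf("covariate %s is not numeric", nm))
    if (stats::var(X[[nm]]) == 0) {
      stop(sprintf("covariate %s has zero variance", nm))
    }
  }
  out <- vapply(covariates, function(nm) {
    r2 <- suppressWarnings(
      summary(stats::lm(stats::reformulate(setdiff(covariates, nm), nm),
                        data = X))$r.squared)
    if (1 - r2 < 1e-10) {
      warning(sprintf("covariate %s is perfectly collinear (singular)", nm))
      return(Inf)
    }
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- covariates
  out
}

#' Compare a variable between complication and non-complication groups
#'
#' Continuous variables are compared with the Mann-Whitney U test (normal
#' approximation with continuity and tie correction); categorical
#' variables with Pearson's chi-square on the outcome-by-level table. The
#' per-group descriptive summary (mean, SD, min, max, median for
#' continuous; counts for categorical) accompanies the test.
#'
#' @param data Data frame with the outcome and the variable.
#' @param column Name of the variable to compare.
#' @param outcome_col Name of the binary outcome column (default
#'   `"outcome"`).
#' @param kind `"continuous"`, `"categorical"`, or `"auto"` (numeric
#'   columns are treated as continuous).
#' @return List with `kind`, `statistic` (U for continuous, X-squared for
#'   categorical), `p_value`, `summary`, and `low_expected` (chi-square
#'   reliability flag).
#' @export
group_compare <- function(data, column, outcome_col = "outcome",
                          kind = c("auto", "continuous", "categorical")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(data), column %in% names(data),
            outcome_col %in% names(data))
  outcome <- data[[outcome_col]]
  check_outcome(outcome)
  x <- data[[column]]
  if (kind == "auto") kind <- if (is.numeric(x)) "continuous" else "categorical"
  if (kind == "continuous") {
    g1 <- x[outcome == 1]
    g0 <- x[outcome == 0]
    ht <- suppressWarnings(stats::wilcox.test(g1, g0, correct = TRUE,
                                              exact = FALSE))
    summ <- t(vapply(list(complication = g1, none = g0), function(v) {
      c(n = length(v), mean = mean(v), sd = stats::sd(v), min = min(v),
        max = max(v), median = stats::median(v))
    }, numeric(6)))
    list(kind = kind, statistic = unname(ht$statistic), p_value = ht$p.value,
         summary = summ, low_expected = NA)
  } else {
    tab <- table(outcome, x)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(kind = kind, statistic = unname(ht$statistic), p_value = ht$p.value,
         summary = tab, low_expected = any(ht$expected < 5))
  }
}

#' Two-proportion z-test (pooled, two-sided)
#'
#' @param k1,n1 Events and size in the first group.
#' @param k2,n2 Events and size in the second group.
#' @return List with `z`, `p_value`, and the two sample proportions.
#' @export
proportion_z_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("event counts must lie in [0, n]")
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = if (se == 0) 1 else 2 * stats::pnorm(-abs(z)),
       p1 = p1, p2 = p2)
}

#' Spearman rank correlation with tie-averaged ranks
#'
#' @param x,y Numeric vectors of equal length (`>= 3`), neither constant.
#' @return List with `rho` and `p_value` (asymptotic t approximation).
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3L) stop("at least 3 observations are required")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation is undefined for a constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Observed versus model-predicted complication rates by score level
#'
#' For every score level 0-8, reports the number of patients, the observed
#' complication fraction, and the model-predicted probability at that
#' level. Levels absent from the cohort are flagged (`present = FALSE`)
#' with `NA` observed rates, never fabricated.
#'
#' @param data Data frame with the score and outcome columns.
#' @param fit Converged single-covariate [tss_fit()] of outcome on score.
#' @param score_col,outcome_col Column names (defaults `"tss_total"`,
#'   `"outcome"`).
#' @return Data frame with columns `score`, `n`, `observed`, `predicted`,
#'   `present`.
#' @export
calibration_by_score <- function(data, fit, score_col = "tss_total",
                                 outcome_col = "outcome") {
  stopifnot(inherits(fit, "tss_fit"), score_col %in% names(data),
            outcome_col %in% names(data))
  if (!fit$converged) stop("model did not converge")
  if (length(fit$coefficients) != 2L) {
    stop("fit must be a single-covariate model of the score")
  }
  score <- data[[score_col]]
  outcome <- data[[outcome_col]]
  levels <- 0:8
  out <- do.call(rbind, lapply(levels, function(s) {
    idx <- !is.na(score) & score == s
    n <- sum(idx)
    data.frame(score = s, n = n,
               observed = if (n > 0) mean(outcome[idx]) else NA_real_,
               predicted = unname(stats::plogis(fit$coefficients[1] +
                                                  fit$coefficients[2] * s)),
               present = n > 0)
  }))
  rownames(out) <- NULL
  out
}

check_outcome <- function(outcome) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(outcome)) < 2L) {
    stop("both outcome classes must be present")
  }
  invisible(outcome)
}
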