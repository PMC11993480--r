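# Logistic complication model: the package's central fitting function.

#' Fit a logistic complication model
#'
#' Fits a binary logistic regression of a mechanical-complication outcome
#' on one or more covariates (typically the total score, or the six
#' sub-scores for a multivariable analysis) by maximum likelihood, and
#' carries the inference the score validation needs: standard errors from
#' the observed information, Wald confidence intervals, odds ratios with
#' exponentiated intervals, and model/null log-likelihoods.
#'
#' The design matrix is checked for full rank before fitting and the fit is
#' checked for (quasi-)complete separation afterwards; both conditions
#' raise informative errors instead of returning unstable estimates.
#'
#' @param formula Model formula, e.g. `outcome ~ tss_total`.
#' @param data Data frame containing the outcome (coded 0/1, both classes
#'   present) and covariates.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return An object of class `tss_fit` with components `coefficients`,
#'   `se`, `ci` (matrix with `lower`/`upper`), `odds_ratios`, `or_ci`,
#'   `log_likelihood`, `null_log_likelihood`, `converged`, `n_iterations`,
#'   `n`, and the underlying `glm` object.
#' @examples
#' cohort <- simulate_cohort(tss_cohort_config(n = 400, seed = 1, rho = c(0.4, 0.2)))
#' fit <- tss_fit(outcome ~ tss_total, cohort)
#' summary(fit)
#' @export
tss_fit <- function(formula, data, conf_level = 0.95) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data),
            conf_level > 0, conf_level < 1)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("outcome must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: covariates are collinear or constant")
  }

  sep_warning <- FALSE
  g <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  huge_coef <- max(abs(stats::coef(g))) > 10
  if ((sep_warning && huge_coef) || (huge_coef && g$deviance < 1e-6)) {
    stop("perfect separation: the outcome is completely determined by the covariates")
  }

  est <- stats::coef(g)
  se <- sqrt(diag(stats::vcov(g)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = est - z * se, upper = est + z * se)
  g0 <- stats::glm(y ~ 1, family = stats::binomial())

  structure(
    list(coefficients = est,
         se = se,
         ci = ci,
         odds_ratios = exp(est),
         or_ci = exp(ci),
         p_values = summary(g)$coefficients[, 4],
         log_likelihood = as.numeric(stats::logLik(g)),
         null_log_likelihood = as.numeric(stats::logLik(g0)),
         converged = g$converged,
         n_iterations = g$iter,
         conf_level = conf_level,
         n = length(y),
         formula = formula,
         glm = g,
         call = match.call()),
    class = "tss_fit")
}

#' Odds ratios with confidence intervals from a fitted model
#'
#' @param fit A [tss_fit()] object (must have converged).
#' @return Data frame with one row per coefficient: `beta`, `se`, odds
#'   ratio `or`, and the exponentiated Wald interval `or_low`, `or_high`.
#' @export
odds_ratio <- function(fit) {
  stopifnot(inherits(fit, "tss_fit"))
  if (!fit$converged) stop("model did not converge")
  data.frame(term = names(fit$coefficients),
             beta = unname(fit$coefficients),
             se = unname(fit$se),
             or = unname(fit$odds_ratios),
             or_low = unname(fit$or_ci[, "lower"]),
             or_high = unname(fit$or_ci[, "upper"]),
             row.names = NULL)
}

#' @export
print.tss_fit <- function(x, ...) {
  cat("Logistic complication model (", x$n, " patients)\n", sep = "")
  cat("Call: ", deparse(x$formula), "\n\n")
  print(round(x$coefficients, 4))
  cat("\nLog-likelihood:", format(x$log_likelihood, digits = 6),
      " (null:", format(x$null_log_likelihood, digits = 6), ")\n")
  invisible(x)
}

#' @export
summary.tss_fit <- function(object, ...) {
  tab <- cbind(beta = object$coefficients,
               se = object$se,
               ci_low = object$ci[, "lower"],
               ci_high = object$ci[, "upper"],
               or = object$odds_ratios,
               or_low = object$or_ci[, "lower"],
               or_high = object$or_ci[, "upper"],
               p = object$p_values)
  structure(list(table = tab, n = object$n, formula = object$formula,
                 log_likelihood = object$log_likelihood,
                 null_log_likelihood = object$null_log_likelihood,
                 conf_level = object$conf_level),
            class = "summary.tss_fit")
}

#' @export
print.summary.tss_fit <- function(x, ...) {
  cat("Logistic complication model: ", deparse(x$formula),
      "  (n = ", x$n, ")\n\n", sep = "")
  print(round(x$table, 4))
  r2 <- 1 - x$log_likelihood / x$null_log_likelihood
  cat("\nMcFadden R2:", round(r2, 4), "\n")
  invisible(x)
}

#' @export
coef.tss_fit <- function(object, ...) object$coefficients

#' @export
vcov.tss_fit <- function(object, ...) stats::vcov(object$glm)

#' @export
logLik.tss_fit <- function(object, ...) stats::logLik(object$glm)

#' @export
nobs.tss_fit <- function(object, ...) object$n

#' @export
confint.tss_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.tss_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  stats::predict(object$glm, newdata = newdata, type = type)
}

#' @export
fitted.tss_fit <- function(object, ...) stats::fitted(object$glm)

#' @export
residuals.tss_fit <- function(object, type = c("deviance", "pearson", "response"),
                              ...) {
  stats::residuals(object$glm, type = match.arg(type))
}

#' @export
simulate.tss_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fitted(object$glm)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
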