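# Tabular I/O with row-level validation and deterministic report output.

.subscore_cols <- c("tad_score", "quadrant_score", "ap_alignment_score",
                    "lateral_alignment_score", "mcs_score", "acs_score")

#' Read a cohort CSV with row-level validation
#'
#' Reads a comma-separated, UTF-8, header-required cohort table. Rows that
#' violate the invariants of whatever validated columns they carry are
#' rejected with a reason (outcome not 0/1, sub-score outside its domain,
#' `tss_total` inconsistent with the sub-scores); unknown columns are
#' carried through untouched. Counts of accepted and rejected rows are
#' reported via `message()`, and the rejected rows (with row numbers and
#' reasons) are attached as attribute `"rejected"`.
#'
#' @param path Path to the CSV file.
#' @param required Character vector of columns that must be present.
#' @return Data frame of accepted rows.
#' @export
read_cohort <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("empty input: ", path)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }

  reasons <- rep(NA_character_, nrow(data))
  flag <- function(bad, why) {
    bad <- which(bad & is.na(reasons))
    reasons[bad] <<- why
  }
  if ("outcome" %in% names(data)) {
    flag(!(data$outcome %in% c(0, 1)), "outcome not 0/1")
  }
  for (col in intersect(.subscore_cols, names(data))) {
    top <- if (col %in% c("tad_score", "quadrant_score")) 2L else 1L
    v <- data[[col]]
    flag(!is.na(v) & !(v %in% 0:top),
         sprintf("%s outside 0..%d", col, top))
  }
  if (all(c(.subscore_cols, "tss_total") %in% names(data))) {
    total <- rowSums(data[.subscore_cols])
    flag(!is.na(total) & !is.na(data$tss_total) & total != data$tss_total,
         "inconsistent total")
  }

  rejected <- which(!is.na(reasons))
  message(sprintf("read_cohort: accepted %d of %d rows (%d rejected)",
                  nrow(data) - length(rejected), nrow(data), length(rejected)))
  rej_df <- data.frame(row = rejected, reason = reasons[rejected])
  if (length(rejected)) {
    for (i in seq_len(nrow(rej_df))) {
      message(sprintf("  row %d rejected: %s", rej_df$row[i], rej_df$reason[i]))
    }
    data <- data[-rejected, , drop = FALSE]
  }
  attr(data, "rejected") <- rej_df
  data
}

#' Write a cohort CSV
#'
#' Plain deterministic CSV output (comma-separated, `.` decimal, header,
#' no row names).
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a validation report
#'
#' Serialises a validation result deterministically. JSON output rounds
#' floats to a fixed number of significant digits (default 4) and
#' round-trips losslessly through [jsonlite::fromJSON]; text output is the
#' human-readable summary; CSV output is the per-score calibration table.
#'
#' @param results A `tss_validation` object or the list from
#'   [as_report()].
#' @param path Output path.
#' @param format `"json"`, `"text"`, or `"csv"`.
#' @param digits Significant digits for JSON/text floats.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, format = c("json", "text", "csv"),
                         digits = 4) {
  format <- match.arg(format)
  report <- if (inherits(results, "tss_validation")) as_report(results) else results
  if (format == "json") {
    jsonlite::write_json(round_recursive(report, digits), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", null = "null")
  } else if (format == "csv") {
    if (is.null(report$calibration)) stop("report carries no calibration table")
    utils::write.csv(round_recursive(report$calibration, digits), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    writeLines(format_report_text(report, digits), path)
  }
  invisible(path)
}

round_recursive <- function(x, digits) {
  if (is.list(x) && !is.data.frame(x)) {
    return(lapply(x, round_recursive, digits = digits))
  }
  if (is.data.frame(x)) {
    x[] <- lapply(x, function(col) if (is.double(col)) signif(col, digits) else col)
    return(x)
  }
  if (is.double(x)) signif(x, digits) else x
}

format_report_text <- function(report, digits = 4) {
  fmt <- function(x) format(signif(x, digits), trim = TRUE)
  lines <- c("Targeted surgical score validation report", "")
  if (!is.null(report$cohort)) {
    lines <- c(lines, sprintf("n = %d, prevalence = %s", report$cohort$n,
                              fmt(report$cohort$prevalence)))
  }
  if (!is.null(report$model)) {
    m <- report$model
    for (i in seq_along(m$terms)) {
      lines <- c(lines, sprintf(
        "%s: beta %s (SE %s, CI %s to %s), OR %s [%s-%s], p %s",
        m$terms[i], fmt(m$beta[i]), fmt(m$se[i]), fmt(m$ci_low[i]),
        fmt(m$ci_high[i]), fmt(m$odds_ratio[i]), fmt(m$or_low[i]),
        fmt(m$or_high[i]), fmt(m$p_values[i])))
    }
  }
  if (!is.null(report$roc)) {
    r <- report$roc
    lines <- c(lines, sprintf(
      "AUC %s; cutoff <= %s; sens %s, spec %s, acc %s",
      fmt(r$auc), fmt(r$cutoff), fmt(r$sensitivity), fmt(r$specificity),
      fmt(r$accuracy)))
  }
  if (!is.null(report$diagnostics)) {
    d <- report$diagnostics
    lines <- c(lines, sprintf(
      "HL statistic %s (df %d, p %s); McFadden R2 %s; LR p %s",
      fmt(d$hl_statistic), d$hl_df, fmt(d$hl_p), fmt(d$mcfadden_r2),
      fmt(d$lr_p)))
  }
  if (!is.null(report$calibration)) {
    cal <- report$calibration
    lines <- c(lines, "", "score,n,observed,predicted,present")
    lines <- c(lines, vapply(seq_len(nrow(cal)), function(i) {
      paste(cal$score[i], cal$n[i], fmt(cal$observed[i]),
            fmt(cal$predicted[i]), cal$present[i], sep = ",")
    }, character(1)))
  }
  lines
}
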