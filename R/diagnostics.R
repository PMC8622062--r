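#' Classify a survival probability against the rewarming threshold
#'
#' The triage rule is inclusive: a patient is classified positive (rewarm)
#' when the predicted survival probability is at least the threshold,
#' compared on unrounded values. (A 9.928% probability is negative at the
#' 10% threshold even though it displays as 10% after rounding.)
#'
#' @param probability Predicted survival probabilities in `[0,1]`.
#' @param threshold Decision threshold in `(0,1)`; default 0.10, the
#'   suggested criterion to initiate ECLS rewarming.
#'
#' @return Character vector `"positive"`/`"negative"` (`NA` stays `NA`).
#' @export
#'
#' @examples
#' classify_rewarm(c(0.0992, 0.10, 0.147))
classify_rewarm <- function(probability, threshold = 0.10) {
  .check_threshold(threshold)
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    abort("`probability` must lie in [0, 1].")
  }
  if_else(probability >= threshold, "positive", "negative")
}

.check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single probability strictly inside (0, 1).")
  }
}

# outcome vectors may arrive as survived/died tokens, logicals or 0/1;
# returns logical (TRUE = survived) preserving NA
.as_survived <- function(outcome) {
  if (is.logical(outcome)) return(outcome)
  if (is.numeric(outcome)) {
    if (any(!outcome %in% c(0, 1, NA))) abort("Numeric outcomes must be 0/1.")
    return(outcome == 1)
  }
  o <- tolower(as.character(outcome))
  bad <- !(o %in% c("survived", "died") | is.na(o))
  if (any(bad)) {
    abort(paste0("Unrecognised outcome value(s): ",
                 paste(unique(o[bad]), collapse = ", "),
                 ". Use 'survived'/'died'."))
  }
  o == "survived"
}

#' Cross-classify predictions and outcomes at a threshold
#'
#' Counts true/false positives and negatives for the rewarming rule
#' (positive = probability >= threshold; a positive prediction asserts
#' survival). Records with missing outcome are excluded from the counts and
#' reported in the `n_missing_outcome` tally.
#'
#' @param data A data frame (typically the output of [hope_score()]).
#' @param threshold Decision threshold in `(0,1)`.
#' @param probability,outcome Columns holding the predicted probability and
#'   the observed outcome (`"survived"`/`"died"`, logical, or 0/1). Defaults
#'   `hope_probability` and `outcome`.
#'
#' @return An object of class `hope_confusion`: counts `tp`, `fp`, `tn`,
#'   `fn`, the `threshold`, `n` (records with known outcome) and
#'   `n_missing_outcome`. `tidy()` turns it into a one-row tibble.
#' @export
#'
#' @examples
#' dead <- tibble::tibble(
#'   hope_probability = c(0.007, 0.034, 0.036, 0.147, 0.336, 0.439, 0.553, 0.814),
#'   outcome = "died"
#' )
#' confusion_table(dead, threshold = 0.10)  # tn = 3, fp = 5
confusion_table <- function(data, threshold = 0.10,
                            probability = hope_probability, outcome = outcome) {
  .check_threshold(threshold)
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  p <- eval_tidy(enquo(probability), data)
  y <- eval_tidy(enquo(outcome), data)
  if (length(p) != length(y)) abort("probability and outcome have different lengths.")
  surv <- .as_survived(y)
  known <- !is.na(surv) & !is.na(p)
  p <- p[known]; surv <- surv[known]
  pos <- p >= threshold
  structure(
    list(
      tp = sum(pos & surv), fp = sum(pos & !surv),
      tn = sum(!pos & !surv), fn = sum(!pos & surv),
      threshold = threshold,
      n = length(p),
      n_missing_outcome = sum(!known)
    ),
    class = "hope_confusion"
  )
}

#' Assemble a confusion object from known counts
#'
#' For working from published tables where only the four counts are
#' reported.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @param threshold Decision threshold the counts refer to.
#' @return A `hope_confusion` object.
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, threshold = 0.10) {
  .check_threshold(threshold)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be nonnegative integers.")
  }
  structure(c(as.list(counts),
              list(threshold = threshold, n = sum(counts),
                   n_missing_outcome = 0L)),
            class = "hope_confusion")
}

#' @export
print.hope_confusion <- function(x, ...) {
  cat(sprintf("Confusion table at threshold %s (positive = rewarm)\n",
              format_percent(x$threshold)))
  cat(sprintf("  tp=%d fp=%d tn=%d fn=%d  (n=%d known outcomes, %d missing)\n",
              x$tp, x$fp, x$tn, x$fn, x$n, x$n_missing_outcome))
  invisible(x)
}

#' @export
tidy.hope_confusion <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
         threshold = x$threshold, n = x$n,
         n_missing_outcome = x$n_missing_outcome)
}

#' Wilson score interval for a binomial proportion
#'
#' The score-based interval, stable at small n and extreme proportions,
#' used for every proportion this package reports.
#'
#' @param successes Number of successes (vectorised).
#' @param n Number of trials, at least 1.
#' @param conf.level Confidence level in `(0,1)`; default 0.95.
#'
#' @return A tibble with `successes`, `n`, `estimate`, `conf.low`,
#'   `conf.high`; bounds always in `[0,1]`.
#' @export
#'
#' @examples
#' wilson_interval(3, 8)   # 14-69% at integer rounding
#' wilson_interval(3, 4)   # 30-95%
wilson_interval <- function(successes, n, conf.level = 0.95) {
  if (!is.numeric(conf.level) || length(conf.level) != 1L ||
      conf.level <= 0 || conf.level >= 1) {
    abort("`conf.level` must be in (0, 1).")
  }
  k <- length(successes)
  if (length(n) == 1L) n <- rep(n, k)
  if (length(n) != k) abort("`successes` and `n` lengths differ.")
  if (any(n < 1) || any(successes < 0) || any(successes > n) ||
      any(successes != round(successes)) || any(n != round(n))) {
    abort("Require integer 0 <= successes <= n and n >= 1.")
  }
  z <- qnorm(1 - (1 - conf.level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  tibble(successes = as.integer(successes), n = as.integer(n),
         estimate = phat,
         conf.low = pmax(0, centre - half),
         conf.high = pmin(1, centre + half))
}

#' Diagnostic performance report with Wilson intervals
#'
#' Computes the six triage metrics from a confusion table: sensitivity
#' (criterion fulfilled among survivors), specificity (criterion not
#' fulfilled among non-survivors), positive and negative predictive values,
#' and the false-positive and false-negative percentages over all patients.
#' A metric whose denominator is zero is reported as undefined (`NA`
#' estimate, `note = "undefined"`), never as 0.
#'
#' @param table A `hope_confusion` object from [confusion_table()] or
#'   [confusion_from_counts()].
#' @param conf.level Confidence level for the Wilson intervals.
#'
#' @return A tibble of class `hope_diagnostics` with one row per metric:
#'   `metric`, `numerator`, `denominator`, `estimate`, `conf.low`,
#'   `conf.high`, `display` (e.g. `"61/62 = 98% (91-100%)"`) and `note`.
#' @export
#'
#' @examples
#' diagnostic_report(confusion_from_counts(tp = 61, fp = 5, tn = 3, fn = 1))
diagnostic_report <- function(table, conf.level = 0.95) {
  if (!inherits(table, "hope_confusion")) {
    abort("`table` must be a hope_confusion object.")
  }
  total <- table$n
  spec_tbl <- tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv",
               "fp_fraction", "fn_fraction"),
    numerator = c(table$tp, table$tn, table$tp, table$tn, table$fp, table$fn),
    denominator = c(table$tp + table$fn, table$tn + table$fp,
                    table$tp + table$fp, table$tn + table$fn, total, total)
  )
  rows <- purrr::pmap(spec_tbl, function(metric, numerator, denominator) {
    if (denominator == 0) {
      tibble(metric = metric, numerator = numerator, denominator = denominator,
             estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
             display = sprintf("%s undefined (empty denominator)", metric),
             note = "undefined")
    } else {
      w <- wilson_interval(numerator, denominator, conf.level)
      tibble(metric = metric, numerator = numerator, denominator = denominator,
             estimate = w$estimate, conf.low = w$conf.low, conf.high = w$conf.high,
             display = sprintf("%d/%d = %s (%.0f%%-%.0f%%)", numerator, denominator,
                               format_percent(w$estimate),
                               percent_round(w$conf.low), percent_round(w$conf.high)),
             note = "")
    }
  })
  out <- bind_rows(rows)
  attr(out, "threshold") <- table$threshold
  attr(out, "conf.level") <- conf.level
  class(out) <- c("hope_diagnostics", class(out))
  out
}

#' @export
print.hope_diagnostics <- function(x, ...) {
  cat(sprintf("Diagnostic performance at HOPE probability >= %s (%.0f%% CI, Wilson)\n",
              format_percent(attr(x, "threshold")),
              100 * attr(x, "conf.level")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %s\n", x$metric[i], x$display[i]))
  }
  invisible(x)
}
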