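#' Calibration-in-the-large of predicted survival probabilities
#'
#' Compares the mean predicted survival probability with the observed
#' survival rate — the dissociation this pipeline exists to expose: an
#' outcome-dependent selection of cases inflates the observed rate far above
#' the mean prediction while leaving within-class ranking (the AUC) intact.
#' Per-outcome-class mean predictions are reported together with a
#' rank-based (Mann-Whitney) p-value for the between-class location shift,
#' and a nonparametric bootstrap interval for the observed-minus-predicted
#' gap.
#'
#' @param data A data frame (typically the output of [hope_score()]).
#' @param probability,outcome Columns with predicted probability and
#'   observed outcome; defaults `hope_probability` and `outcome`. Records
#'   with missing outcome are dropped (and counted).
#' @param conf.level Level of the bootstrap interval for the gap.
#' @param boot_n Bootstrap resamples for the gap interval; 0 disables it.
#' @param boot_seed Seed for the bootstrap resampling.
#' @param recalibrate If `TRUE`, additionally fits the logistic
#'   recalibration model `outcome ~ logit(p)` and reports its intercept and
#'   slope (1 and 0 mean perfect weak calibration). Off by default;
#'   calibration-in-the-large is the primary measure.
#'
#' @return An object of class `hope_calibration` with `mean_predicted`,
#'   `observed_rate`, `gap` (observed - predicted) and its bootstrap bounds,
#'   `group_means` (tibble by outcome class), `range` of predictions,
#'   `comparison_p` (two-sided Mann-Whitney with continuity correction),
#'   counts, and optionally `recalibration`. `glance()` flattens the
#'   headline numbers; `tidy()` returns the group means.
#' @export
#'
#' @examples
#' d <- tibble::tibble(
#'   hope_probability = c(0.007, 0.034, 0.036, 0.147, 0.336, 0.439, 0.553, 0.814),
#'   outcome = "died"
#' )
#' calibration_summary(d, boot_n = 0)$group_means
calibration_summary <- function(data, probability = hope_probability,
                                outcome = outcome, conf.level = 0.95,
                                boot_n = 2000, boot_seed = 1L,
                                recalibrate = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  p <- eval_tidy(enquo(probability), data)
  y <- eval_tidy(enquo(outcome), data)
  surv <- .as_survived(y)
  keep <- !is.na(surv) & !is.na(p)
  n_missing <- sum(!keep)
  p <- p[keep]; surv <- surv[keep]
  if (length(p) == 0L) abort("No records with a known outcome.")

  group_means <- tibble(outcome = c("survived", "died"),
                        n = c(sum(surv), sum(!surv)),
                        mean_predicted = c(
                          if (sum(surv)) mean(p[surv]) else NA_real_,
                          if (sum(!surv)) mean(p[!surv]) else NA_real_
                        ))

  comparison_p <- if (all(surv) || all(!surv)) NA_real_ else {
    suppressWarnings(
      wilcox.test(p[surv], p[!surv], alternative = "two.sided",
                  correct = TRUE, exact = FALSE)$p.value
    )
  }

  gap <- mean(surv) - mean(p)
  gap_ci <- c(NA_real_, NA_real_)
  if (boot_n > 0) {
    boots <- withr_seed(boot_seed, {
      vapply(seq_len(boot_n), function(i) {
        idx <- sample.int(length(p), replace = TRUE)
        mean(surv[idx]) - mean(p[idx])
      }, numeric(1))
    })
    alpha <- 1 - conf.level
    gap_ci <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }

  recal <- NULL
  if (isTRUE(recalibrate)) {
    fit <- glm(surv ~ qlogis(p), family = binomial())
    recal <- tibble(term = c("intercept", "slope"),
                    estimate = unname(stats::coef(fit)))
  }

  structure(
    list(mean_predicted = mean(p), observed_rate = mean(surv), gap = gap,
         gap_conf.low = gap_ci[1], gap_conf.high = gap_ci[2],
         conf.level = conf.level,
         group_means = group_means,
         range = c(min(p), max(p)),
         comparison_p = comparison_p,
         n = length(p), n_missing_outcome = n_missing,
         recalibration = recal),
    class = "hope_calibration"
  )
}

#' @export
print.hope_calibration <- function(x, ...) {
  cat(sprintf("Calibration-in-the-large (n = %d with known outcome)\n", x$n))
  cat(sprintf("  mean predicted survival  %s\n", format_percent(x$mean_predicted)))
  cat(sprintf("  observed survival        %s\n", format_percent(x$observed_rate)))
  gap_ci <- if (is.na(x$gap_conf.low)) "" else {
    sprintf(" (%d%% CI %+.3f to %+.3f)", round(100 * x$conf.level),
            x$gap_conf.low, x$gap_conf.high)
  }
  cat(sprintf("  gap (observed - mean predicted)  %+.3f%s\n", x$gap, gap_ci))
  cat(sprintf("  group means: survivors %s, non-survivors %s (Mann-Whitney p = %s)\n",
              format_percent(x$group_means$mean_predicted[1]),
              format_percent(x$group_means$mean_predicted[2]),
              format.pval(x$comparison_p, digits = 2)))
  cat(sprintf("  prediction range %s to %s\n",
              format_percent(x$range[1], 1), format_percent(x$range[2], 1)))
  if (!is.null(x$recalibration)) {
    cat(sprintf("  logistic recalibration: intercept %+.3f, slope %.3f\n",
                x$recalibration$estimate[1], x$recalibration$estimate[2]))
  }
  invisible(x)
}

#' @export
glance.hope_calibration <- function(x, ...) {
  tibble(mean_predicted = x$mean_predicted, observed_rate = x$observed_rate,
         gap = x$gap, gap_conf.low = x$gap_conf.low,
         gap_conf.high = x$gap_conf.high,
         mean_predicted_survivors = x$group_means$mean_predicted[1],
         mean_predicted_nonsurvivors = x$group_means$mean_predicted[2],
         comparison_p = x$comparison_p,
         min_predicted = x$range[1], max_predicted = x$range[2],
         n = x$n, n_missing_outcome = x$n_missing_outcome)
}

#' @export
tidy.hope_calibration <- function(x, ...) x$group_means

#' @export
autoplot.hope_calibration <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    abort("Supply the scored data frame used to build the summary via `data`.")
  }
  surv <- .as_survived(data$outcome)
  df <- tibble(probability = data$hope_probability,
               outcome = if_else(surv, "survived", "died"))
  df <- df[!is.na(df$outcome) & !is.na(df$probability), ]
  ggplot(df, aes(x = .data$outcome, y = .data$probability,
                 colour = .data$outcome)) +
    geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    stat_summary(fun = mean, geom = "point", shape = 95, size = 12,
                 colour = "black") +
    labs(x = NULL, y = "HOPE survival probability",
         title = "Predicted survival probability by observed outcome",
         subtitle = "black bar = group mean") +
    theme_minimal()
}

#' Sensitivity of the survival probability to the asphyxia classification
#'
#' When the mechanism is uncertain (immersion with the head above water
#' versus submersion), the asphyxia flag alone shifts the log-odds by the
#' asphyxia coefficient. This computes both scenario probabilities for each
#' record; guidance for unclear scenarios is to choose the variant giving
#' the patient the highest survival probability, so the non-asphyxial value
#' is labelled as the recommended when-in-doubt choice.
#'
#' @param data A data frame of patient records as for [hope_score()]; the
#'   `mechanism`/`asphyxia` columns may be anything — both scenarios are
#'   forced.
#' @param coefficients A [hope_coefficients()] set.
#'
#' @return A tibble with `id` (when present), `probability_asphyxia`,
#'   `probability_non_asphyxia`, `logit_shift` (their log-odds difference,
#'   equal to minus the asphyxia coefficient) and `recommended`
#'   (`"non_asphyxial"`).
#' @export
#'
#' @examples
#' rec <- tibble::tibble(age = 44, sex = "female", mechanism = "submersion",
#'                       temperature_c = 20.1, potassium_mmol_l = 4.3,
#'                       cpr_min = 150)
#' asphyxia_sensitivity(rec)
asphyxia_sensitivity <- function(data, coefficients = hope_coefficients()) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- as_tibble(data)
  if (!"mechanism" %in% names(data)) data$mechanism <- NA_character_
  a <- hope_score(mutate(data, asphyxia = TRUE, mechanism = NULL),
                  coefficients = coefficients, on_invalid = "error")
  na <- hope_score(mutate(data, asphyxia = FALSE, mechanism = NULL),
                   coefficients = coefficients, on_invalid = "error")
  out <- tibble(
    probability_asphyxia = a$hope_probability,
    probability_non_asphyxia = na$hope_probability,
    logit_shift = na$hope_score - a$hope_score,
    recommended = "non_asphyxial"
  )
  if ("id" %in% names(data)) out <- bind_cols(tibble(id = data$id), out)
  out
}

#' Shift a survival probability across the asphyxia classification
#'
#' Converts a probability computed under one mechanism class to the other by
#' moving the log-odds by the asphyxia coefficient (1.95 by default):
#' a 16% asphyxial (submersion) probability becomes 57% non-asphyxial
#' (immersion). Useful when only the probability, not the full record, is
#' available.
#'
#' @param probability Survival probability in `(0,1)`.
#' @param to `"non_asphyxial"` (adds the penalty back) or `"asphyxial"`
#'   (applies it).
#' @param coefficients A [hope_coefficients()] set (its `asphyxia` entry is
#'   used).
#'
#' @return The shifted probability.
#' @export
#'
#' @examples
#' shift_asphyxia(0.16)              # ~0.57
#' shift_asphyxia(0.57, "asphyxial") # back down
shift_asphyxia <- function(probability, to = c("non_asphyxial", "asphyxial"),
                           coefficients = hope_coefficients()) {
  to <- match.arg(to)
  if (any(probability <= 0 | probability >= 1, na.rm = TRUE)) {
    abort("`probability` must lie strictly inside (0, 1).")
  }
  delta <- abs(coefficients$asphyxia)
  plogis(qlogis(probability) + if (to == "non_asphyxial") delta else -delta)
}
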