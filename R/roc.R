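#' ROC curve and AUC for predicted survival probabilities
#'
#' Discrimination of the score: the AUC is the Mann-Whitney concordance
#' probability that a randomly chosen survivor receives a higher predicted
#' probability than a randomly chosen non-survivor, with ties counting one
#' half. The point estimate and the 95% interval come from `pROC` (DeLong
#' variance, the conventional default); when either outcome class has fewer
#' than two members the DeLong variance is degenerate and a seeded
#' stratified bootstrap is used instead, with the interval labelled
#' accordingly. The curve is built from every distinct predicted value used
#' as a threshold.
#'
#' @param data A data frame (typically the output of [hope_score()]).
#' @param probability,outcome Columns with predicted probability and
#'   observed outcome; defaults `hope_probability` and `outcome`.
#' @param conf.level Confidence level; default 0.95.
#' @param boot_n Bootstrap resamples for the fallback interval.
#' @param boot_seed Seed for the fallback bootstrap (ignored otherwise).
#'
#' @return An object of class `hope_roc`: `auc`, `conf.low`, `conf.high`,
#'   `ci_method` (`"delong"` or `"bootstrap"`), `curve` (tibble of
#'   `threshold`, `fpr`, `tpr` from (0,0) to (1,1)), and the class sizes.
#'   `glance()` gives a one-row summary, `tidy()` the curve,
#'   `ggplot2::autoplot()` the standard ROC plot.
#' @export
#'
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(hope_probability = runif(40),
#'                     outcome = ifelse(runif(40) < hope_probability,
#'                                      "survived", "died"))
#' glance(roc_auc(d))
roc_auc <- function(data, probability = hope_probability, outcome = outcome,
                    conf.level = 0.95, boot_n = 2000, boot_seed = 1L) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  p <- eval_tidy(enquo(probability), data)
  y <- eval_tidy(enquo(outcome), data)
  surv <- .as_survived(y)
  keep <- !is.na(surv) & !is.na(p)
  p <- p[keep]; surv <- surv[keep]
  n1 <- sum(surv); n0 <- sum(!surv)
  if (n1 == 0L || n0 == 0L) {
    abort(sprintf("Both outcome classes are required; no %s in the data.",
                  if (n1 == 0L) "survivors" else "non-survivors"))
  }

  roc <- pROC::roc(response = surv, predictor = p,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc))

  if (min(n1, n0) >= 2L) {
    ci <- as.numeric(pROC::ci.auc(roc, conf.level = conf.level, method = "delong"))
    ci_method <- "delong"
    ci_low <- ci[1]; ci_high <- ci[3]
  } else {
    # single-member class: DeLong variance degenerates, fall back to a
    # seeded outcome-stratified bootstrap
    boots <- withr_seed(boot_seed, {
      vapply(seq_len(boot_n), function(i) {
        i1 <- sample(which(surv), n1, replace = TRUE)
        i0 <- sample(which(!surv), n0, replace = TRUE)
        .auc_concordance(p[i1], p[i0])
      }, numeric(1))
    })
    alpha <- 1 - conf.level
    qs <- quantile(boots, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
    ci_method <- "bootstrap"
    ci_low <- qs[1]; ci_high <- qs[2]
  }

  structure(
    list(auc = auc, conf.low = ci_low, conf.high = ci_high,
         conf.level = conf.level, ci_method = ci_method,
         curve = .roc_curve(p, surv), n_survivors = n1, n_nonsurvivors = n0),
    class = "hope_roc"
  )
}

# rank-free concordance used only by the bootstrap fallback
.auc_concordance <- function(p_pos, p_neg) {
  g <- expand.grid(pos = p_pos, neg = p_neg)
  mean((g$pos > g$neg) + 0.5 * (g$pos == g$neg))
}

# (fpr, tpr) at every distinct predicted value, inclusive rule p >= t
.roc_curve <- function(p, surv) {
  th <- sort(unique(p), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(p[surv] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(p[!surv] >= t), numeric(1))
  tibble(threshold = c(Inf, th, -Inf),
         fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

# evaluate an expression under a temporary, restorable RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' @export
print.hope_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f, %s); %d survivors, %d non-survivors\n",
              x$auc, round(100 * x$conf.level), x$conf.low, x$conf.high,
              x$ci_method, x$n_survivors, x$n_nonsurvivors))
  invisible(x)
}

#' @export
glance.hope_roc <- function(x, ...) {
  tibble(auc = x$auc, conf.low = x$conf.low, conf.high = x$conf.high,
         conf.level = x$conf.level, ci_method = x$ci_method,
         n_survivors = x$n_survivors, n_nonsurvivors = x$n_nonsurvivors)
}

#' @export
tidy.hope_roc <- function(x, ...) x$curve

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_abline geom_point
#'   labs theme_minimal coord_equal geom_segment geom_jitter
#'   position_jitter stat_summary annotate
#' @export
ggplot2::autoplot

#' @export
autoplot.hope_roc <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(intercept = 0, slope = 1, linetype = "dashed", colour = "grey60") +
    geom_step(linewidth = 0.8) +
    coord_equal() +
    labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve, AUC = %.2f (%d%% CI %.2f-%.2f)",
                      object$auc, round(100 * object$conf.level),
                      object$conf.low, object$conf.high)
    ) +
    theme_minimal()
}
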