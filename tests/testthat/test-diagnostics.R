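test_that("the rewarming rule is inclusive and compares unrounded values", {
  expect_identical(classify_rewarm(c(0.0992, 0.10, 0.147)),
                   c("negative", "positive", "positive"))
  # 9.928% displays as 9.9% or rounds to 10% but stays below the threshold
  expect_identical(classify_rewarm(0.09928038), "negative")
  expect_identical(classify_rewarm(NA_real_), NA_character_)
  expect_error(classify_rewarm(0.5, threshold = 0), "threshold")
  expect_error(classify_rewarm(1.2), "0, 1")
})

test_that("confusion counts reproduce the published non-survivor accounting", {
  ct <- confusion_table(nonsurvivor_frame(), threshold = 0.10)
  expect_equal(ct$tn, 3)
  expect_equal(ct$fp, 5)
  expect_equal(ct$tp + ct$fn, 0)
  expect_equal(ct$n, 8)
})

test_that("confusion handles empty input, missing outcomes and ties", {
  empty <- tibble::tibble(hope_probability = numeric(), outcome = character())
  ct <- confusion_table(empty)
  expect_equal(unlist(ct[c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 0, tn = 0, fn = 0))

  d <- tibble::tibble(hope_probability = c(0.5, 0.2, 0.05),
                      outcome = c("survived", NA, "died"))
  ct2 <- confusion_table(d)
  expect_equal(ct2$n, 2)
  expect_equal(ct2$n_missing_outcome, 1)

  tie <- tibble::tibble(hope_probability = 0.10, outcome = "died")
  expect_equal(confusion_table(tie)$fp, 1)  # p == threshold is positive
})

test_that("confusion counts match an independent per-element recount", {
  set.seed(101)
  d <- tibble::tibble(hope_probability = round(runif(50), 2),
                      outcome = sample(c("survived", "died"), 50, TRUE))
  ct <- confusion_table(d, threshold = 0.3)
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(50)) {
    pos <- d$hope_probability[i] >= 0.3
    surv <- d$outcome[i] == "survived"
    if (pos && surv) tp <- tp + 1
    if (pos && !surv) fp <- fp + 1
    if (!pos && !surv) tn <- tn + 1
    if (!pos && surv) fn <- fn + 1
  }
  expect_equal(tidy(ct)[, c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn))
})

test_that("Wilson intervals reproduce the published table bounds", {
  w38 <- wilson_interval(3, 8)
  expect_equal(w38$conf.low, 0.13685, tolerance = 1e-4)
  expect_equal(w38$conf.high, 0.69425, tolerance = 1e-4)
  expect_equal(percent_round(w38$conf.low), 14)
  expect_equal(percent_round(w38$conf.high), 69)
  w34 <- wilson_interval(3, 4)
  expect_equal(percent_round(w34$conf.low), 30)
  expect_equal(percent_round(w34$conf.high), 95)
})

test_that("Wilson intervals agree with the score-test inversion in prop.test", {
  for (n in c(1, 4, 8, 20, 70)) {
    for (k in unique(c(0, 1, floor(n / 2), n))) {
      w <- wilson_interval(k, n)
      ref <- suppressWarnings(prop.test(k, n, correct = FALSE)$conf.int)
      expect_equal(c(w$conf.low, w$conf.high), as.numeric(ref),
                   tolerance = 1e-9)
    }
  }
  expect_equal(wilson_interval(0, 10)$conf.low, 0)
  expect_equal(wilson_interval(10, 10)$conf.high, 1)
  expect_error(wilson_interval(3, 0), "n >= 1")
  expect_error(wilson_interval(5, 4), "successes")
})

test_that("Wilson coverage matches its exact binomial coverage", {
  n <- 20; p <- 0.3
  # exact coverage by enumeration of all binomial outcomes
  w <- wilson_interval(0:n, n)
  covers <- w$conf.low <= p & p <= w$conf.high
  exact_coverage <- sum(dbinom(0:n, n, p)[covers])
  set.seed(55)
  k <- rbinom(10000, n, p)
  empirical <- mean(covers[k + 1])
  mc_err <- 3 * sqrt(exact_coverage * (1 - exact_coverage) / 10000)
  expect_lt(abs(empirical - exact_coverage), mc_err)
})

test_that("the diagnostic report reproduces the published metrics", {
  rep <- diagnostic_report(confusion_from_counts(tp = 61, fp = 5, tn = 3, fn = 1))
  est <- setNames(rep$estimate, rep$metric)
  expect_equal(est[["sensitivity"]], 61 / 62)
  expect_equal(est[["specificity"]], 3 / 8)
  expect_equal(est[["ppv"]], 61 / 66)
  expect_equal(est[["npv"]], 3 / 4)
  expect_equal(est[["fp_fraction"]], 5 / 70)
  expect_equal(est[["fn_fraction"]], 1 / 70)
  disp <- setNames(rep$display, rep$metric)
  expect_identical(disp[["sensitivity"]], "61/62 = 98% (91%-100%)")
  expect_identical(disp[["specificity"]], "3/8 = 38% (14%-69%)")
  expect_identical(disp[["npv"]], "3/4 = 75% (30%-95%)")
  # every interval contains its point estimate
  expect_true(all(rep$conf.low <= rep$estimate & rep$estimate <= rep$conf.high))
})

test_that("zero-denominator metrics are reported undefined, never zero", {
  rep <- diagnostic_report(confusion_from_counts(tp = 10, fp = 0, tn = 0, fn = 0))
  est <- setNames(rep$estimate, rep$metric)
  note <- setNames(rep$note, rep$metric)
  expect_equal(est[["sensitivity"]], 1)
  expect_true(is.na(est[["specificity"]]))
  expect_identical(note[["specificity"]], "undefined")
  expect_true(is.na(est[["npv"]]))
})

test_that("report metrics equal hand-computed ratios on random tables", {
  set.seed(77)
  for (i in 1:20) {
    cts <- as.list(setNames(sample(0:30, 4, TRUE), c("tp", "fp", "tn", "fn")))
    rep <- do.call(confusion_from_counts, cts) |> diagnostic_report()
    est <- setNames(rep$estimate, rep$metric)
    total <- with(cts, tp + fp + tn + fn)
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    expect_equal(est[["sensitivity"]], with(cts, ratio(tp, tp + fn)))
    expect_equal(est[["specificity"]], with(cts, ratio(tn, tn + fp)))
    expect_equal(est[["ppv"]], with(cts, ratio(tp, tp + fp)))
    expect_equal(est[["npv"]], with(cts, ratio(tn, tn + fn)))
    expect_equal(est[["fp_fraction"]], ratio(cts$fp, total))
    expect_equal(est[["fn_fraction"]], ratio(cts$fn, total))
  }
})

test_that("AUC equals brute-force pairwise concordance on small cohorts", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(8:30, 1)
    p <- round(runif(n), 1)  # coarse grid forces ties
    surv <- runif(n) < 0.6
    if (!any(surv) || all(surv)) next
    d <- tibble::tibble(hope_probability = p,
                        outcome = ifelse(surv, "survived", "died"))
    r <- roc_auc(d)
    expect_equal(r$auc, auc_pairwise(p, surv), tolerance = 1e-12)
  }
})

test_that("AUC hits the degenerate anchors", {
  sep <- tibble::tibble(hope_probability = c(0.9, 0.8, 0.2, 0.1),
                        outcome = c("survived", "survived", "died", "died"))
  expect_equal(suppressWarnings(roc_auc(sep))$auc, 1.0)
  ties <- tibble::tibble(hope_probability = rep(0.4, 10),
                         outcome = rep(c("survived", "died"), 5))
  expect_equal(roc_auc(ties)$auc, 0.5)
  one_class <- tibble::tibble(hope_probability = runif(5), outcome = "survived")
  expect_error(roc_auc(one_class), "non-survivors")
})

test_that("the ROC curve is a valid trapezoid decomposition of the AUC", {
  set.seed(31)
  d <- tibble::tibble(hope_probability = round(runif(60), 2),
                      outcome = sample(c("survived", "died"), 60, TRUE,
                                       prob = c(0.7, 0.3)))
  r <- roc_auc(d)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(tail(r$curve$fpr, 1), 1); expect_equal(tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_lt(abs(trapezoid_area(r$curve$fpr, r$curve$tpr) - r$auc), 1e-10)
})

test_that("the DeLong interval contains the point AUC", {
  set.seed(13)
  d <- tibble::tibble(hope_probability = runif(40),
                      outcome = sample(c("survived", "died"), 40, TRUE))
  g <- glance(roc_auc(d))
  expect_identical(g$ci_method, "delong")
  expect_lte(g$conf.low, g$auc)
  expect_gte(g$conf.high, g$auc)
})

test_that("a single-member class falls back to a seeded bootstrap interval", {
  d <- tibble::tibble(hope_probability = c(0.05, runif(20, 0.2, 0.9)),
                      outcome = c("died", rep("survived", 20)))
  r1 <- roc_auc(d, boot_n = 500, boot_seed = 9)
  r2 <- roc_auc(d, boot_n = 500, boot_seed = 9)
  expect_identical(r1$ci_method, "bootstrap")
  expect_identical(c(r1$conf.low, r1$conf.high), c(r2$conf.low, r2$conf.high))
})

test_that("sensitivity falls and specificity rises as the threshold rises", {
  set.seed(17)
  d <- tibble::tibble(hope_probability = runif(80),
                      outcome = sample(c("survived", "died"), 80, TRUE))
  ths <- seq(0.05, 0.95, by = 0.05)
  sens <- spec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    ct <- confusion_table(d, threshold = ths[i])
    sens[i] <- ct$tp / (ct$tp + ct$fn)
    spec[i] <- ct$tn / (ct$tn + ct$fp)
  }
  expect_true(all(diff(sens) <= 0))
  expect_true(all(diff(spec) >= 0))
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(23)
  d <- tibble::tibble(hope_probability = runif(50),
                      outcome = sample(c("survived", "died"), 50, TRUE))
  a1 <- roc_auc(d)$auc
  a2 <- roc_auc(dplyr::mutate(d, hope_probability = plogis(3 * qlogis(hope_probability) + 1)))$auc
  a3 <- roc_auc(dplyr::mutate(d, hope_probability = hope_probability^3))$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})
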