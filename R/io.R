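#' Read a cohort of patient records from delimited text
#'
#' Reads the canonical cohort layout (header row; columns `id`, `age`,
#' `sex`, `mechanism`, `temperature_c`, `potassium_mmol_l`, `cpr_min` and
#' optionally `asphyxia`, `outcome`, `cpc`; lowercase tokens; empty fields
#' for missing values; UTF-8). Column order is free and unknown columns
#' pass through. Rows failing validation (nonpositive potassium or CPR,
#' unknown sex/mechanism/outcome tokens) are dropped from the result and
#' collected, with their line numbers, in the `problems` attribute; a
#' warning summarises them.
#'
#' @param path File to read.
#' @param delim Field delimiter, default comma.
#'
#' @return A tibble of valid records. Attribute `problems` is a tibble
#'   (`row`, `column`, `message`) of rejected rows (data rows, header
#'   excluded).
#' @export
read_cohort <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE, trim_ws = TRUE)
  required <- c("age", "sex", "temperature_c", "potassium_mmol_l", "cpr_min")
  missing_cols <- setdiff(required, names(data))
  if (!any(c("mechanism", "asphyxia") %in% names(data))) {
    missing_cols <- c(missing_cols, "mechanism (or asphyxia)")
  }
  if (length(missing_cols)) {
    abort(paste0("Missing mandatory column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c("age", "temperature_c", "potassium_mmol_l", "cpr_min"),
                        names(data))) {
    data[[col]] <- as.numeric(data[[col]])
  }
  if ("cpc" %in% names(data)) data$cpc <- as.integer(data$cpc)

  problems <- list()
  note <- function(rows, column, message) {
    for (r in rows) problems[[length(problems) + 1L]] <<-
        tibble(row = r, column = column, message = message)
  }
  bad <- rep(FALSE, nrow(data))
  chk <- function(cond, column, message) {
    cond[is.na(cond)] <- FALSE
    note(which(cond), column, message)
    bad <<- bad | cond
  }
  chk(!is.na(data$potassium_mmol_l) & data$potassium_mmol_l <= 0,
      "potassium_mmol_l", "must be > 0")
  chk(!is.na(data$cpr_min) & data$cpr_min <= 0, "cpr_min", "must be > 0")
  chk(!is.na(data$age) & data$age < 0, "age", "must be nonnegative")
  sx <- tolower(as.character(data$sex))
  chk(!is.na(sx) & !sx %in% c("male", "female"), "sex",
      "unknown token (use male/female)")
  if ("mechanism" %in% names(data)) {
    mech <- as.character(data$mechanism)
    chk(!is.na(mech) & !mech %in% names(.mechanisms), "mechanism",
        paste0("unknown token (use ",
               paste(names(.mechanisms), collapse = "/"), ")"))
  }
  if ("outcome" %in% names(data)) {
    oc <- tolower(as.character(data$outcome))
    chk(!is.na(oc) & !oc %in% c("survived", "died"), "outcome",
        "unknown token (use survived/died)")
  }

  problems <- if (length(problems)) bind_rows(problems) else {
    tibble(row = integer(), column = character(), message = character())
  }
  if (any(bad)) {
    warn(sprintf("%d row(s) of %s failed validation and were dropped (see attr(., 'problems')).",
                 sum(bad), path))
  }
  out <- data[!bad, , drop = FALSE]
  attr(out, "problems") <- problems
  out
}

#' Write a cohort table as delimited text
#'
#' Full-precision serialisation of the canonical layout; probabilities are
#' never rounded on disk (display rounding is confined to report fields).
#'
#' @param data Cohort tibble.
#' @param path Output file.
#' @param delim Field delimiter, default comma.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim, na = "")
  invisible(data)
}

#' Descriptive cohort summary with survivor/non-survivor comparison
#'
#' Median and range for the continuous covariates and counts with
#' percentages for the categorical ones, split by outcome when available,
#' in the shape of a study characteristics table. Group comparisons use the
#' standard routines — Mann-Whitney (`wilcox.test`) for continuous and
#' Fisher's exact test for categorical variables; a comparison is reported
#' as `NA` (undefined) when a variable has a single level or an outcome
#' class is absent.
#'
#' @param cohort A nonempty cohort tibble.
#'
#' @return An object of class `hope_cohort_summary`: tibbles `continuous`
#'   (`variable`, `median`, `min`, `max`, per-group medians, `p_value`) and
#'   `categorical` (`variable`, `level`, `n`, `percent`, per-group counts,
#'   `p_value`), plus `n` and the survivor count.
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort("`cohort` must be a nonempty data frame.")
  }
  surv <- if ("outcome" %in% names(cohort)) .as_survived(cohort$outcome) else {
    rep(NA, nrow(cohort))
  }
  two_groups <- sum(surv %in% TRUE) > 0 && sum(surv %in% FALSE) > 0

  cont_vars <- intersect(
    c("age", "temperature_c", "potassium_mmol_l", "cpr_min",
      "hope_probability"),
    names(cohort)
  )
  continuous <- bind_rows(lapply(cont_vars, function(v) {
    x <- cohort[[v]]
    p <- if (two_groups && length(unique(stats::na.omit(x))) > 1) {
      suppressWarnings(wilcox.test(x[surv %in% TRUE], x[surv %in% FALSE],
                                   exact = FALSE)$p.value)
    } else NA_real_
    tibble(
      variable = v,
      median = median(x, na.rm = TRUE),
      min = suppressWarnings(min(x, na.rm = TRUE)),
      max = suppressWarnings(max(x, na.rm = TRUE)),
      median_survivors = if (two_groups) median(x[surv %in% TRUE], na.rm = TRUE) else NA_real_,
      median_nonsurvivors = if (two_groups) median(x[surv %in% FALSE], na.rm = TRUE) else NA_real_,
      p_value = p
    )
  }))

  cat_vars <- intersect(c("sex", "mechanism", "asphyxia", "outcome"), names(cohort))
  categorical <- bind_rows(lapply(cat_vars, function(v) {
    x <- as.character(cohort[[v]])
    tab <- table(x, useNA = "no")
    p <- NA_real_
    if (v != "outcome" && two_groups && length(tab) > 1) {
      ct <- table(x, surv)
      p <- tryCatch(fisher.test(ct)$p.value, error = function(e) NA_real_)
    }
    tibble(
      variable = v, level = names(tab), n = as.integer(tab),
      percent = 100 * as.integer(tab) / sum(tab),
      n_survivors = if (two_groups) {
        vapply(names(tab), function(l) sum(x == l & surv %in% TRUE, na.rm = TRUE),
               integer(1))
      } else NA_integer_,
      n_nonsurvivors = if (two_groups) {
        vapply(names(tab), function(l) sum(x == l & surv %in% FALSE, na.rm = TRUE),
               integer(1))
      } else NA_integer_,
      p_value = p
    )
  }))

  structure(list(continuous = continuous, categorical = categorical,
                 n = nrow(cohort),
                 n_survivors = sum(surv %in% TRUE),
                 n_nonsurvivors = sum(surv %in% FALSE)),
            class = "hope_cohort_summary")
}

#' @export
print.hope_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: n = %d (%d survivors, %d non-survivors)\n\n",
              x$n, x$n_survivors, x$n_nonsurvivors))
  cat("Continuous variables (median [range]):\n")
  print(as.data.frame(x$continuous), row.names = FALSE, digits = 3)
  cat("\nCategorical variables:\n")
  print(as.data.frame(x$categorical), row.names = FALSE, digits = 3)
  invisible(x)
}

#' In-publication reference fixtures
#'
#' The handful of individual-level values the validation publication
#' prints, usable as ground truth in examples and tests: the pediatric
#' false-negative case (a 6-year-old boy, submersion, 17 degrees C,
#' potassium 7.6 mmol/L, 95 min of CPR, who survived with full recovery and
#' a predicted survival of 9.9%), the eight non-survivor predicted
#' probabilities, and the confusion counts of the 10% rule on the 70-patient
#' cohort.
#'
#' @return A list: `pediatric_case` (one-row cohort tibble),
#'   `non_survivor_probabilities` (length-8 numeric, probability scale) and
#'   `table2_counts` (list `tp`, `fp`, `tn`, `fn`).
#' @export
#'
#' @examples
#' hope_score(hope_fixtures()$pediatric_case)$hope_probability
hope_fixtures <- function() {
  list(
    pediatric_case = tibble(
      id = "pediatric_boy", age = 6, sex = "male", mechanism = "submersion",
      temperature_c = 17, potassium_mmol_l = 7.6, cpr_min = 95,
      outcome = "survived", cpc = 1L
    ),
    non_survivor_probabilities =
      c(0.007, 0.034, 0.036, 0.147, 0.336, 0.439, 0.553, 0.814),
    table2_counts = list(tp = 61L, fp = 5L, tn = 3L, fn = 1L)
  )
}

#' Write the reference fixtures as delimited files
#'
#' @param dir Directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- hope_fixtures()
  p1 <- file.path(dir, "pediatric_case.csv")
  write_cohort(fx$pediatric_case, p1)
  p2 <- file.path(dir, "non_survivor_probabilities.csv")
  readr::write_csv(tibble(hope_probability = fx$non_survivor_probabilities,
                          outcome = "died"), p2)
  invisible(c(p1, p2))
}
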