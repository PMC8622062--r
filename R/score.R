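#' Evaluate the HOPE linear predictor
#'
#' Low-level vectorised evaluation of the score's linear combination on the
#' log-odds scale. No range checks are applied beyond the domain of the
#' logarithms; most users want [hope_score()], which validates a cohort
#' table and returns probabilities with warnings.
#'
#' @param male Logical or 0/1: patient is male.
#' @param asphyxia Logical or 0/1: asphyxia-related mechanism (see
#'   [classify_mechanism()]).
#' @param age Age in years.
#' @param temperature Core temperature at admission, degrees Celsius.
#' @param potassium Serum potassium, mmol/L; must be positive.
#' @param cpr CPR duration in minutes, CPR start to ECLS start; must be
#'   positive.
#' @param coefficients A [hope_coefficients()] set.
#'
#' @return Numeric vector of log-odds of survival. Apply [stats::plogis()]
#'   for the survival probability.
#' @export
#'
#' @examples
#' plogis(hope_linear_score(male = TRUE, asphyxia = TRUE, age = 6,
#'                          temperature = 17, potassium = 7.6, cpr = 95))
hope_linear_score <- function(male, asphyxia, age, temperature, potassium, cpr,
                              coefficients = hope_coefficients()) {
  stopifnot(inherits(coefficients, "hope_coefficients"))
  if (any(potassium <= 0, na.rm = TRUE) || any(cpr <= 0, na.rm = TRUE)) {
    abort("`potassium` and `cpr` must be positive (base-2 logarithms are taken).")
  }
  coefficients$intercept +
    coefficients$male * as.numeric(male) +
    coefficients$asphyxia * as.numeric(asphyxia) +
    coefficients$age * age +
    coefficients$log2_potassium * log2(potassium) +
    coefficients$log2_cpr * log2(cpr) +
    coefficients$temperature * temperature +
    coefficients$temperature_squared * temperature^2
}

# observed covariate ranges of the source cohort; values outside them are
# scored but flagged
.observed_ranges <- list(
  age               = c(1, 95),
  temperature_c     = c(13.5, 28.9),
  potassium_mmol_l  = c(2.4, 16.1),
  cpr_min           = c(20, 307)
)

#' Score a cohort with the HOPE survival model
#'
#' Adds the HOPE log-odds score and survival probability to a cohort table.
#' Expects the canonical columns `age`, `sex` (`"male"`/`"female"`),
#' `mechanism` (see [hope_mechanisms()]) and/or `asphyxia`, `temperature_c`,
#' `potassium_mmol_l`, `cpr_min`; an `id` column is used in messages when
#' present. Any other columns pass through untouched.
#'
#' Rows with a missing or inadmissible covariate are not scored: with
#' `on_invalid = "warn"` (the default, the fail-soft batch contract) they
#' receive `NA` results and the reason in `hope_warnings`, and one R warning
#' summarises the failures; with `on_invalid = "error"` the first problem
#' aborts, naming the offending field and row. Covariates outside the ranges
#' observed in the source cohort, temperatures above 32 degrees C (the
#' hypothermic-cardiac-arrest study criterion) and pediatric ages (< 18 y,
#' where guidelines advise expert consultation over the score) are scored
#' but annotated in `hope_warnings` — study-level exclusions are the
#' pipeline's job, not the formula's.
#'
#' @param data A data frame of patient records, one row per patient.
#' @param coefficients A [hope_coefficients()] set.
#' @param add_30min_ids Ids of records whose `cpr_min` is only CPR-to-admission;
#'   30 minutes are added for the admission-to-ECLS interval and the row is
#'   flagged in a `cpr_imputed` column. Explicit and per record, never silent.
#' @param on_invalid `"warn"` (fail-soft) or `"error"` (reject on the first
#'   invalid record).
#'
#' @return The input as a tibble with columns `hope_score` (log-odds),
#'   `hope_probability` (in (0,1), full precision) and `hope_warnings`
#'   (semicolon-separated annotations, `""` when clean), plus `cpr_imputed`
#'   when `add_30min_ids` is used. A `metadata` attribute records the
#'   coefficient set, whether it was modified, and the package version.
#' @export
#'
#' @examples
#' boy <- tibble::tibble(id = "case1", age = 6, sex = "male",
#'                       mechanism = "submersion", temperature_c = 17,
#'                       potassium_mmol_l = 7.6, cpr_min = 95)
#' hope_score(boy)$hope_probability  # 0.0993
hope_score <- function(data, coefficients = hope_coefficients(),
                       add_30min_ids = NULL,
                       on_invalid = c("warn", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (!is.data.frame(data)) abort("`data` must be a data frame of patient records.")
  data <- as_tibble(data)
  n <- nrow(data)

  required <- c("age", "sex", "temperature_c", "potassium_mmol_l", "cpr_min")
  have_mech <- "mechanism" %in% names(data)
  have_asph <- "asphyxia" %in% names(data)
  missing_cols <- setdiff(required, names(data))
  if (!have_mech && !have_asph) missing_cols <- c(missing_cols, "mechanism (or asphyxia)")
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }

  if (n == 0L) {
    warn("Empty cohort: nothing to score.")
    out <- mutate(data, hope_score = numeric(0), hope_probability = numeric(0),
                  hope_warnings = character(0))
    return(.with_metadata(out, coefficients))
  }

  ids <- if ("id" %in% names(data)) as.character(data$id) else as.character(seq_len(n))

  if (!is.null(add_30min_ids)) {
    hit <- ids %in% as.character(add_30min_ids)
    unmatched <- setdiff(as.character(add_30min_ids), ids)
    if (length(unmatched)) {
      abort(paste0("add_30min_ids not found in cohort: ",
                   paste(unmatched, collapse = ", ")))
    }
    data$cpr_min <- data$cpr_min + 30 * hit
    data$cpr_imputed <- hit
  }

  mech <- if (have_mech) as.character(data$mechanism) else rep(NA_character_, n)
  mech_known <- is.na(mech) | mech %in% names(.mechanisms)
  mech_asph <- rep(NA, n)
  mech_asph[mech_known] <- unname(.mechanisms[mech[mech_known]])

  asph <- if (have_asph) as.logical(data$asphyxia) else mech_asph
  # the flag must agree with the mechanism's class when both are given
  conflict <- have_asph & have_mech & !is.na(asph) & !is.na(mech_asph) & (asph != mech_asph)
  asph[is.na(asph)] <- mech_asph[is.na(asph)]

  sex <- tolower(as.character(data$sex))
  sex_ok <- is.na(sex) | sex %in% c("male", "female")
  male <- sex == "male"

  # per-row validity: every covariate present and in the formula's domain
  invalid_msgs <- vector("list", n)
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    for (i in which(cond)) invalid_msgs[[i]] <<- c(invalid_msgs[[i]], msg)
  }
  flag(is.na(data$age), "missing age")
  flag(is.na(sex), "missing sex")
  flag(!sex_ok, "invalid sex (use 'male'/'female')")
  flag(is.na(data$temperature_c), "missing temperature_c")
  flag(is.na(data$potassium_mmol_l), "missing potassium_mmol_l")
  flag(is.na(data$cpr_min), "missing cpr_min")
  flag(!mech_known, "unknown mechanism")
  flag(is.na(asph) & mech_known, "missing mechanism (or asphyxia)")
  flag(conflict, "asphyxia flag contradicts mechanism class")
  flag(!is.na(data$potassium_mmol_l) & data$potassium_mmol_l <= 0,
       "potassium_mmol_l must be > 0")
  flag(!is.na(data$cpr_min) & data$cpr_min <= 0, "cpr_min must be > 0")

  invalid <- lengths(invalid_msgs) > 0L
  if (any(invalid) && on_invalid == "error") {
    i <- which(invalid)[1L]
    abort(sprintf("Record '%s': %s.", ids[i],
                  paste(invalid_msgs[[i]], collapse = "; ")))
  }

  score <- rep(NA_real_, n)
  ok <- !invalid
  if (any(ok)) {
    score[ok] <- hope_linear_score(
      male = male[ok], asphyxia = asph[ok], age = data$age[ok],
      temperature = data$temperature_c[ok],
      potassium = data$potassium_mmol_l[ok], cpr = data$cpr_min[ok],
      coefficients = coefficients
    )
  }

  notes <- .range_notes(data, ok)
  if ("cpr_imputed" %in% names(data)) {
    notes[data$cpr_imputed] <- lapply(notes[data$cpr_imputed], c,
                                      "cpr_min includes +30 min imputed admission-to-ECLS interval")
  }
  all_notes <- purrr::map2(invalid_msgs, notes, function(inv, rng) {
    if (length(inv)) paste0("invalid: ", inv) else rng
  })

  if (any(invalid)) {
    warn(sprintf("%d of %d record(s) could not be scored (see hope_warnings): %s",
                 sum(invalid), n,
                 paste(utils::head(ids[invalid], 5), collapse = ", ")))
  }

  out <- mutate(data,
                hope_score = score,
                hope_probability = plogis(score),
                hope_warnings = purrr::map_chr(all_notes, paste, collapse = "; "))
  .with_metadata(out, coefficients)
}

.range_notes <- function(data, ok) {
  n <- nrow(data)
  notes <- vector("list", n)
  add <- function(cond, msg) {
    cond <- cond & ok
    cond[is.na(cond)] <- FALSE
    for (i in which(cond)) notes[[i]] <<- c(notes[[i]], msg)
  }
  add(data$temperature_c > 32,
      "temperature > 32 C: above the hypothermic cardiac arrest criterion; interpret with caution")
  for (v in names(.observed_ranges)) {
    r <- .observed_ranges[[v]]
    add(data[[v]] < r[1] | data[[v]] > r[2],
        sprintf("%s outside observed range %g-%g", v, r[1], r[2]))
  }
  add(data$age < 18,
      "pediatric patient (< 18 y): guidelines recommend expert consultation rather than the score")
  notes
}

.with_metadata <- function(out, coefficients) {
  attr(out, "metadata") <- list(
    coefficients = unclass(coefficients),
    coefficients_modified = isTRUE(attr(coefficients, "modified")),
    package_version = as.character(utils::packageVersion("hopeval"))
  )
  out
}

#' Round and format probabilities as percentages
#'
#' Rounding is half away from zero (so 37.5% prints as 38%), matching the
#' reporting convention used throughout the validation tables; the
#' underlying probabilities are always kept at full precision and rounding
#' is presentation-only.
#'
#' @param p Probabilities in `[0,1]`.
#' @param digits Decimal places of the percentage: 0 (default report style),
#'   1 or 2.
#' @return `format_percent()` returns characters like `"38%"`;
#'   `percent_round()` the numeric percentage.
#' @export
#'
#' @examples
#' format_percent(c(0.375, 0.09928), digits = 0)
format_percent <- function(p, digits = 0) {
  paste0(formatC(percent_round(p, digits), format = "f", digits = digits), "%")
}

#' @rdname format_percent
#' @export
percent_round <- function(p, digits = 0) {
  x <- 100 * p
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
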