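#' HOPE score coefficients
#'
#' The fixed log-odds coefficients of the HOPE survival model. The linear
#' predictor is
#'
#' \deqn{2.44 - 1.55\,\mathrm{male} - 1.95\,\mathrm{asphyxia} - 0.0191\,\mathrm{age}
#'   - 2.07\log_2 K - 0.573\log_2 \mathrm{CPR} + 0.937\,T - 0.0247\,T^2}
#'
#' with age in years, serum potassium \eqn{K} in mmol/L, CPR duration in
#' minutes (CPR start to ECLS start) and core temperature \eqn{T} in degrees
#' Celsius; both logarithms are base 2. The survival probability is the
#' inverse logit of this score. The coefficients are constants of the
#' published model and are never refit here; overriding any of them marks the
#' set as modified, and that flag is carried into scoring metadata.
#'
#' @param ... Named overrides of individual coefficients (an explicit user
#'   act; the result is flagged as modified). Valid names are
#'   `intercept`, `male`, `asphyxia`, `age`, `log2_potassium`, `log2_cpr`,
#'   `temperature`, `temperature_squared`.
#'
#' @return A named list of class `hope_coefficients` with a logical
#'   `modified` attribute.
#' @export
#'
#' @examples
#' hope_coefficients()
hope_coefficients <- function(...) {
  coefs <- list(
    intercept           =  2.44,
    male                = -1.55,
    asphyxia            = -1.95,
    age                 = -0.0191,
    log2_potassium      = -2.07,
    log2_cpr            = -0.573,
    temperature         =  0.937,
    temperature_squared = -0.0247
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(coefs))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      abort(paste0(
        "Unknown coefficient name(s): ",
        paste(if (length(bad)) bad else "<unnamed>", collapse = ", ")
      ))
    }
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        abort(sprintf("Coefficient '%s' must be a single finite number.", nm))
      }
      coefs[[nm]] <- as.numeric(v)
    }
  }
  structure(coefs,
            class = "hope_coefficients",
            modified = length(overrides) > 0L)
}

#' @export
print.hope_coefficients <- function(x, ...) {
  cat("HOPE score coefficients (log-odds scale)",
      if (isTRUE(attr(x, "modified"))) " [MODIFIED]" else "", "\n", sep = "")
  for (nm in names(x)) cat(sprintf("  %-20s %+.4f\n", nm, x[[nm]]))
  invisible(x)
}

# canonical mechanism vocabulary and its asphyxia classification
.mechanisms <- c(
  exposure              = FALSE,
  immersion             = FALSE,
  other_non_asphyxial   = FALSE,
  submersion            = TRUE,
  avalanche_head_buried = TRUE,
  other_asphyxial       = TRUE
)

#' Mechanisms of hypothermia recognised by the scorer
#'
#' @return A tibble with the canonical mechanism tokens and their asphyxia
#'   classification. Submersion and avalanche with burial of the head are
#'   asphyxia-related; cold exposure (outdoor or indoor) and immersion
#'   (head above water) are not.
#' @export
hope_mechanisms <- function() {
  tibble(mechanism = names(.mechanisms), asphyxia = unname(.mechanisms))
}

#' Classify a mechanism of hypothermia as asphyxia-related
#'
#' Submersion and avalanche with the head buried under snow involve airway
#' compromise and carry the model's asphyxia penalty; exposure to cold and
#' immersion (head above water) do not.
#'
#' @param mechanism Character vector of mechanism tokens; see
#'   [hope_mechanisms()] for the vocabulary. `NA` passes through as `NA`.
#'
#' @return Logical vector: `TRUE` for asphyxia-related mechanisms.
#' @export
#'
#' @examples
#' classify_mechanism(c("submersion", "immersion", "exposure"))
classify_mechanism <- function(mechanism) {
  mechanism <- as.character(mechanism)
  known <- mechanism %in% names(.mechanisms) | is.na(mechanism)
  if (!all(known)) {
    abort(paste0(
      "Unknown mechanism value(s): ",
      paste(unique(mechanism[!known]), collapse = ", "),
      ". Valid values: ", paste(names(.mechanisms), collapse = ", "), "."
    ))
  }
  unname(.mechanisms[mechanism])
}

#' Impute CPR duration when only the pre-admission time is known
#'
#' When a report gives CPR duration only up to hospital admission and not to
#' the start of extracorporeal support, 30 minutes are added for the
#' admission-to-ECLS interval. The returned vector carries an `imputed`
#' attribute so the provenance of the value is never silent; in a cohort
#' table use the `add_30min_ids` argument of [hope_score()] instead, which
#' records the flag in a column.
#'
#' @param cpr_before_admission CPR duration in minutes from CPR start to
#'   hospital admission; must be positive.
#'
#' @return `cpr_before_admission + 30`, with attribute `imputed = TRUE`.
#' @export
#'
#' @examples
#' impute_cpr_from_admission(65)  # 95 min
impute_cpr_from_admission <- function(cpr_before_admission) {
  if (!is.numeric(cpr_before_admission) || any(!is.finite(cpr_before_admission)) ||
      any(cpr_before_admission <= 0)) {
    abort("`cpr_before_admission` must be positive and finite (minutes of CPR).")
  }
  structure(cpr_before_admission + 30, imputed = TRUE)
}
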