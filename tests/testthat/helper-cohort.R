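# shared generators and independent oracles

# random but valid patient records, intentionally independent of
# sample_cohort(): plain uniform draws over generous covariate ranges
random_records <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("r%04d", seq_len(n)),
    age = runif(n, 0.5, 100),
    sex = sample(c("male", "female"), n, replace = TRUE),
    mechanism = sample(c("exposure", "immersion", "submersion",
                         "avalanche_head_buried", "other_asphyxial",
                         "other_non_asphyxial"), n, replace = TRUE),
    temperature_c = runif(n, 10, 34),
    potassium_mmol_l = runif(n, 0.5, 17),
    cpr_min = runif(n, 5, 350)
  )
}

# brute-force Mann-Whitney concordance: every survivor/non-survivor pair,
# ties count one half
auc_pairwise <- function(p, survived) {
  pos <- p[survived]
  neg <- p[!survived]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# trapezoidal area under an (fpr, tpr) polyline
trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

scored_pediatric_case <- function() {
  suppressWarnings(hope_score(hope_fixtures()$pediatric_case))
}

nonsurvivor_frame <- function() {
  tibble::tibble(
    hope_probability = hope_fixtures()$non_survivor_probabilities,
    outcome = "died"
  )
}
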