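#' Configure the synthetic discharge-record generator
#'
#' Builds a validated configuration for [simulate_dataset()]. The defaults
#' emulate a province-scale discharge census: ~1.38 million admissions across
#' 252 institutions of mixed types, from which the modelling cohort
#' (inpatient, aged 65 and over, genitourinary N00--N99 diagnosis) comes out
#' at roughly six thousand admissions. Expenditure is log-normal conditional
#' on the eight encounter factors, with length of stay the dominant driver,
#' then institution type, then insurance type.
#'
#' @param n_records Number of admissions to generate.
#' @param n_institutions Number of institutions the records are spread over.
#' @param effect_sizes Named numeric vector: standardized contribution of each
#'   of the eight factors to log(curative income) of inpatient records. Names
#'   must be exactly `length_of_stay`, `institution_type`, `insurance_type`,
#'   `surgery`, `gender`, `institution_level`, `age`, `admission_season`.
#' @param noise_sd Residual standard deviation on the log scale.
#' @param genitourinary_fraction Fraction of records carrying N00--N99 codes.
#' @param elderly_fraction Fraction of records aged 65 and over.
#' @param preventive_fraction Fraction of records flagged as preventive
#'   services (excluded from curative apportionment).
#' @param interaction_strength Coefficient of an optional
#'   length-of-stay x institution-type interaction on the log scale; 0
#'   (default) keeps the ground truth additive.
#' @param insurance_levels Labels of the insurance scheme categorical
#'   (at least 3 levels).
#' @param seed Integer seed; the same configuration reproduces the dataset
#'   bit for bit.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_records = 500, n_institutions = 10, seed = 1)
#' dat <- simulate_dataset(cfg)
#' dat$records
sim_config <- function(n_records = 1377681L,
                       n_institutions = 252L,
                       effect_sizes = c(
                         length_of_stay = 0.55, institution_type = 0.38,
                         insurance_type = 0.29, surgery = 0.23,
                         gender = 0.21, institution_level = 0.19,
                         age = 0.03, admission_season = 0.05
                       ),
                       noise_sd = 0.5,
                       genitourinary_fraction = 0.05,
                       elderly_fraction = 0.25,
                       preventive_fraction = 0.03,
                       interaction_strength = 0,
                       insurance_levels = c(
                         "urban_employee", "urban_resident",
                         "rural_cooperative", "self_pay"
                       ),
                       seed = 1L) {
  check_scalar_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
      abort(sprintf("`%s` must be a positive integer (got %s).", name,
                    paste(format(x), collapse = ", ")),
            class = "cceann_config_error")
    }
  }
  check_fraction <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a single value in [0, 1].", name),
            class = "cceann_config_error")
    }
  }
  check_scalar_count(n_records, "n_records")
  check_scalar_count(n_institutions, "n_institutions")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || is.na(noise_sd) ||
      noise_sd < 0) {
    abort("`noise_sd` must be a single nonnegative number.",
          class = "cceann_config_error")
  }
  check_fraction(genitourinary_fraction, "genitourinary_fraction")
  check_fraction(elderly_fraction, "elderly_fraction")
  check_fraction(preventive_fraction, "preventive_fraction")
  if (is.null(names(effect_sizes)) ||
      !setequal(names(effect_sizes), MODEL_FACTORS) ||
      length(effect_sizes) != length(MODEL_FACTORS) ||
      anyNA(effect_sizes)) {
    abort(paste0("`effect_sizes` must be a named numeric vector over exactly ",
                 "the eight model factors: ",
                 paste(MODEL_FACTORS, collapse = ", "), "."),
          class = "cceann_config_error")
  }
  if (length(insurance_levels) < 3 || anyDuplicated(insurance_levels)) {
    abort("`insurance_levels` must hold at least 3 distinct labels.",
          class = "cceann_config_error")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.", class = "cceann_config_error")
  }
  structure(
    list(
      n_records = as.integer(n_records),
      n_institutions = as.integer(n_institutions),
      effect_sizes = effect_sizes[MODEL_FACTORS],
      noise_sd = noise_sd,
      genitourinary_fraction = genitourinary_fraction,
      elderly_fraction = elderly_fraction,
      preventive_fraction = preventive_fraction,
      interaction_strength = interaction_strength,
      insurance_levels = as.character(insurance_levels),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Read a generator configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effect_sizes)) {
    raw$effect_sizes <- unlist(raw$effect_sizes)
  }
  do.call(sim_config, raw)
}

# Institution-type mix and per-type admission volume / care-setting profile.
# Counts are fractions of n_institutions; `volume` is the relative expected
# number of admissions per institution of that type; `p_outpatient` the
# per-record probability of an outpatient encounter.
institution_profile <- function() {
  tibble(
    institution_type = INSTITUTION_TYPES,
    type_share  = c(0.14, 0.06, 0.04, 0.48, 0.08, 0.20),
    volume      = c(20, 4, 1.5, 1.2, 0.3, 0.15),
    p_outpatient = c(0.55, 0.60, 0.60, 0.90, 0.98, 1.00)
  )
}

# Ordinal cost scores used by the ground-truth linear model on the log scale.
# Higher score = costlier category; the generator standardizes these before
# applying the configured effect sizes.
factor_scores <- list(
  institution_type = c(
    general_hospital = 5, tcm_hospital = 4, special_hospital = 3.5,
    basic_medical = 2, public_health = 1, ambulatory = 0.5
  ),
  institution_level = c(tertiary = 3, secondary = 2, primary = 1),
  admission_season = c(spring = 1, summer = 0.5, autumn = 1.5, winter = 2)
)

# Standardize a numeric vector; all-constant vectors map to 0 so a factor
# with no variation contributes nothing rather than NaN.
std0 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate discharge records, institution ledgers and a population table
#'
#' Generates a complete synthetic input set for the CCE pipeline with known
#' ground truth. For inpatient records, log(curative income) is
#' `intercept + sum_f effect_sizes[f] * x_f + N(0, noise_sd)` where `x_f` is
#' the standardized encoded factor; outpatient encounters get a separate,
#' much smaller income intercept and always `length_of_stay = 0`. Each
#' institution's yearbook total `ST_INC` is its sampled curative income
#' inflated by a fixed factor (the non-sampled remainder), `ST_ALL` is a
#' fixed share of `ST_INC` plus a base allowance, and `S_P_ALL` scales
#' `ST_ALL` by the institution's sampled preventive income share.
#'
#' @param config A [sim_config()].
#' @return A list with class `cce_simulation`: `records` (one row per
#'   admission), `ledgers` (one row per institution), `population`
#'   (thousands of persons per age band), and `truth` (the generator
#'   parameters for parameter-recovery tests).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be built with sim_config().",
          class = "cceann_config_error")
  }
  n <- config$n_records
  set.seed(config$seed)

  prof <- institution_profile()
  n_per_type <- round(prof$type_share * config$n_institutions)
  # rounding may drift off the requested count; settle the difference on the
  # most numerous type
  n_per_type[4] <- n_per_type[4] + config$n_institutions - sum(n_per_type)
  inst <- tibble(
    institution_id = sprintf("H%04d", seq_len(config$n_institutions)),
    institution_type = rep(prof$institution_type, n_per_type)
  )
  level_for_type <- function(type) {
    switch(type,
      general_hospital = sample(INSTITUTION_LEVELS, 1, prob = c(0.4, 0.5, 0.1)),
      tcm_hospital = ,
      special_hospital = sample(INSTITUTION_LEVELS, 1, prob = c(0.1, 0.7, 0.2)),
      "primary"
    )
  }
  inst$institution_level <- vapply(inst$institution_type, level_for_type, "")
  inst <- dplyr::left_join(inst, prof, by = "institution_type")

  idx <- sample.int(nrow(inst), n, replace = TRUE, prob = inst$volume)
  rec <- tibble(
    record_id = sprintf("R%08d", seq_len(n)),
    institution_id = inst$institution_id[idx],
    institution_type = inst$institution_type[idx],
    institution_level = inst$institution_level[idx]
  )
  rec$setting <- ifelse(runif(n) < inst$p_outpatient[idx], "outpatient",
                        "inpatient")
  inpat <- rec$setting == "inpatient"

  # demographics: elderly_fraction aged >= 65, the rest split 15:64 vs 0:14
  u <- runif(n)
  elderly <- u < config$elderly_fraction
  child <- u > 1 - 0.12 * (1 - config$elderly_fraction) / 0.88
  rec$age <- integer(n)
  rec$age[elderly] <- 65L + stats::rgeom(sum(elderly), 1 / 9)
  rec$age[child] <- sample(0:14, sum(child), TRUE)
  mid <- !elderly & !child
  rec$age[mid] <- sample(15:64, sum(mid), TRUE)
  rec$gender <- sample(c("male", "female"), n, TRUE)
  rec$insurance_type <- sample(config$insurance_levels, n, TRUE,
                               prob = insurance_probs(length(config$insurance_levels)))
  rec$admission_season <- sample(SEASONS, n, TRUE)
  rec$surgery <- ifelse(inpat, runif(n) < 0.35, runif(n) < 0.02)
  rec$length_of_stay <- ifelse(inpat,
                               1L + stats::rnbinom(n, size = 3, mu = 8), 0L)
  rec$icd10 <- random_icd10(n, config$genitourinary_fraction)
  rec$is_preventive <- runif(n) < config$preventive_fraction

  # ground-truth log-linear income model (inpatient only)
  es <- config$effect_sizes
  x_los <- std0(rec$length_of_stay[inpat])
  x_type <- std0(factor_scores$institution_type[rec$institution_type[inpat]])
  eta <- log(7000) +
    es[["length_of_stay"]] * x_los +
    es[["institution_type"]] * x_type +
    es[["insurance_type"]] * std0(match(rec$insurance_type[inpat],
                                        config$insurance_levels)) +
    es[["surgery"]] * std0(as.numeric(rec$surgery[inpat])) +
    es[["gender"]] * std0(as.numeric(rec$gender[inpat] == "male")) +
    es[["institution_level"]] *
      std0(factor_scores$institution_level[rec$institution_level[inpat]]) +
    es[["age"]] * std0(rec$age[inpat]) +
    es[["admission_season"]] *
      std0(factor_scores$admission_season[rec$admission_season[inpat]]) +
    config$interaction_strength * x_los * x_type
  income <- numeric(n)
  income[inpat] <- exp(eta + rnorm(sum(inpat), 0, config$noise_sd))
  # outpatient intercept calibrated so the outpatient share of total CCE
  # lands near one fifth, the share provincial accounting reports
  income[!inpat] <- exp(log(1500) + rnorm(sum(!inpat), 0, config$noise_sd))
  rec$curative_income <- income

  ledgers <- make_ledgers(rec, inst)
  out <- list(
    records = rec[, c("record_id", "age", "gender", "icd10", "institution_id",
                      "institution_type", "institution_level",
                      "insurance_type", "admission_season", "surgery",
                      "length_of_stay", "setting", "curative_income",
                      "is_preventive")],
    ledgers = ledgers,
    population = default_population(),
    truth = list(effect_sizes = es, noise_sd = config$noise_sd,
                 config = config)
  )
  class(out) <- "cce_simulation"
  out
}

# decaying enrollment shares for however many insurance levels are configured
insurance_probs <- function(k) {
  p <- c(0.35, 0.30, 0.25, 0.10)
  if (k <= 4) return(p[seq_len(k)] / sum(p[seq_len(k)]))
  p <- c(p, rep(0.05, k - 4))
  p / sum(p)
}

# ICD-10 three-character codes: a configured share in N00-N99, the remainder
# drawn from a plausible chapter mix dominated by circulatory/respiratory/
# neoplastic disease. Numeric parts stay inside each letter's valid chapter
# range so every generated code classifies cleanly.
random_icd10 <- function(n, gu_fraction) {
  gu <- runif(n) < gu_fraction
  codes <- character(n)
  codes[gu] <- sprintf("N%02d", sample(0:99, sum(gu), TRUE))
  mix <- list(  # letter, max valid two-digit part, sampling weight
    I = c(99, 22), J = c(99, 14), C = c(97, 12), E = c(90, 9), K = c(93, 8),
    M = c(99, 7), A = c(99, 4), B = c(99, 3), G = c(99, 4), H = c(95, 3),
    L = c(99, 2), R = c(99, 5), S = c(99, 4), T = c(98, 2), D = c(48, 2),
    F = c(99, 3)
  )
  w <- vapply(mix, `[`, 0, 2)
  n_other <- sum(!gu)
  letters_drawn <- sample(names(mix), n_other, TRUE, prob = w / sum(w))
  maxes <- vapply(mix, `[`, 0, 1)[letters_drawn]
  codes[!gu] <- paste0(letters_drawn,
                       sprintf("%02d", floor(runif(n_other) * (maxes + 1))))
  codes
}

# Yearbook totals per institution. The 1.25 income inflation models the
# non-sampled remainder of each institution's year; 0.18 is the subsidy share
# of curative income and 2e5 RMB a base allowance so that institutions with
# no sampled curative activity still carry an allowance (exercising the
# unallocated bucket downstream).
make_ledgers <- function(records, inst) {
  sampled <- records |>
    dplyr::group_by(.data$institution_id) |>
    dplyr::summarise(
      a = sum(.data$curative_income),
      a_p = sum(.data$curative_income[.data$is_preventive]),
      .groups = "drop"
    )
  inst |>
    dplyr::select("institution_id", "institution_type") |>
    dplyr::left_join(sampled, by = "institution_id") |>
    dplyr::mutate(
      a = dplyr::coalesce(.data$a, 0),
      a_p = dplyr::coalesce(.data$a_p, 0),
      ST_INC = 1.25 * .data$a,
      ST_ALL = 0.18 * .data$ST_INC + 2e5,
      S_P_ALL = .data$ST_ALL *
        dplyr::if_else(.data$a > 0, .data$a_p / .data$a, 0)
    ) |>
    dplyr::select("institution_id", "institution_type", "ST_INC", "ST_ALL",
                  "S_P_ALL")
}

#' Default provincial population table
#'
#' Thousands of persons in the three reporting age bands, at the scale of a
#' mid-size Chinese province.
#'
#' @return A tibble with `age_group` and `population` (thousands).
#' @export
default_population <- function() {
  tibble(
    age_group = AGE_BANDS,
    population = c(4469.10, 32837.40, 5135.50)
  )
}

#' @export
print.cce_simulation <- function(x, ...) {
  cat(sprintf(
    "<cce_simulation> %d records, %d institutions, %d inpatient\n",
    nrow(x$records), nrow(x$ledgers),
    sum(x$records$setting == "inpatient")
  ))
  invisible(x)
}
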