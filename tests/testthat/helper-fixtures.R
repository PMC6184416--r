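# Shared fixtures and independent oracles for the test suite.

# A small, fully valid record set built by hand (no generator involved), for
# accounting and reporting unit tests.
tiny_records <- function() {
  tibble::tibble(
    record_id = sprintf("R%02d", 1:6),
    age = c(70L, 80L, 30L, 66L, 10L, 72L),
    gender = c("male", "female", "male", "female", "male", "female"),
    icd10 = c("N18", "N20", "I10", "N39", "J06", "C61"),
    institution_id = c("H1", "H1", "H1", "H2", "H2", "H2"),
    institution_type = c(rep("general_hospital", 3), rep("basic_medical", 3)),
    institution_level = c(rep("tertiary", 3), rep("primary", 3)),
    insurance_type = c("urban_employee", "urban_resident", "self_pay",
                       "urban_employee", "rural_cooperative", "self_pay"),
    admission_season = c("winter", "spring", "summer", "autumn", "winter",
                         "spring"),
    surgery = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    length_of_stay = c(10L, 5L, 0L, 7L, 0L, 12L),
    setting = c("inpatient", "inpatient", "outpatient", "inpatient",
                "outpatient", "inpatient"),
    curative_income = c(5000, 3000, 400, 2500, 150, 6000),
    is_preventive = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
}

tiny_ledgers <- function() {
  tibble::tibble(
    institution_id = c("H1", "H2"),
    institution_type = c("general_hospital", "basic_medical"),
    ST_INC = c(12000, 10000),
    ST_ALL = c(2000, 1500),
    S_P_ALL = c(200, 100)
  )
}

# Literal loop transcription of the Garson connection-weight formula,
# independent of the vectorized implementation.
garson_oracle <- function(W, v) {
  p <- nrow(W)
  h <- ncol(W)
  q <- numeric(p)
  for (i in seq_len(p)) {
    for (k in seq_len(h)) {
      denom <- 0
      for (j in seq_len(p)) denom <- denom + abs(W[j, k])
      if (denom > 0) q[i] <- q[i] + (abs(W[i, k]) / denom) * abs(v[k])
    }
  }
  q / sum(q)
}

# A generator config for fast model-level tests: cohort of ~1500 elderly
# genitourinary inpatient admissions with a dominant length-of-stay effect.
recovery_config <- function(seed, n_records = 4000) {
  sim_config(
    n_records = n_records, n_institutions = 40,
    effect_sizes = c(
      length_of_stay = 0.8, institution_type = 0.2, insurance_type = 0.15,
      surgery = 0.1, gender = 0.1, institution_level = 0.1,
      age = 0.05, admission_season = 0.05
    ),
    elderly_fraction = 1, genitourinary_fraction = 1, seed = seed
  )
}

cohort_matrix <- function(cfg, ...) {
  sim <- simulate_dataset(cfg)
  encode_factors(model_cohort(exclude_invalid(sim$records)$records), ...)
}
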