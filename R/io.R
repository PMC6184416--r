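#' Read and write discharge records
#'
#' Records travel as UTF-8 comma-delimited files with a header row; columns
#' are the `DischargeRecord` fields in a fixed order. `read_records()`
#' validates every row and reports offending row numbers (1-based, excluding
#' the header) rather than silently coercing.
#'
#' @param records A tibble of discharge records.
#' @param path File path.
#' @return `read_records()` returns a validated tibble; `write_records()`
#'   returns `path` invisibly.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  readr::write_csv(records[, RECORD_COLUMNS], path)
  invisible(path)
}

RECORD_COLUMNS <- c(
  "record_id", "age", "gender", "icd10", "institution_id",
  "institution_type", "institution_level", "insurance_type",
  "admission_season", "surgery", "length_of_stay", "setting",
  "curative_income", "is_preventive"
)

ICD10_PATTERN <- "^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$"

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      record_id = readr::col_character(),
      age = readr::col_integer(),
      gender = readr::col_character(),
      icd10 = readr::col_character(),
      institution_id = readr::col_character(),
      institution_type = readr::col_character(),
      institution_level = readr::col_character(),
      insurance_type = readr::col_character(),
      admission_season = readr::col_character(),
      surgery = readr::col_logical(),
      length_of_stay = readr::col_integer(),
      setting = readr::col_character(),
      curative_income = readr::col_double(),
      is_preventive = readr::col_logical()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(RECORD_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Records file is missing mandatory column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "cceann_format_error")
  }
  df <- as_tibble(df[, RECORD_COLUMNS])
  if (nrow(df) == 0) return(df)
  validate_records(df)
  df
}

validate_records <- function(df) {
  bad_rows <- function(lgl) which(is.na(lgl) | !lgl)
  problems <- list(
    `missing field` = bad_rows(stats::complete.cases(df)),
    `malformed ICD-10 code` = setdiff(
      bad_rows(grepl(ICD10_PATTERN, df$icd10)),
      bad_rows(!is.na(df$icd10))
    ),
    `outpatient with nonzero length of stay` = which(
      df$setting == "outpatient" & df$length_of_stay != 0
    ),
    `inpatient with length of stay < 1` = which(
      df$setting == "inpatient" & df$length_of_stay < 1
    ),
    `negative curative income` = which(df$curative_income < 0)
  )
  problems <- problems[vapply(problems, length, 0L) > 0]
  if (length(problems) > 0) {
    msg <- vapply(names(problems), function(nm) {
      rows <- problems[[nm]]
      shown <- paste(head(rows, 10), collapse = ", ")
      if (length(rows) > 10) shown <- paste0(shown, ", ...")
      sprintf("%s at row(s) %s", nm, shown)
    }, "")
    abort(paste0("Invalid records: ", paste(msg, collapse = "; "), "."),
          class = "cceann_validation_error")
  }
  invisible(df)
}

#' Read and write institution ledgers
#'
#' A ledger holds one institution's yearbook totals: `ST_INC` (total curative
#' income), `ST_ALL` (total basic expenditure allowance) and `S_P_ALL`
#' (preventive-service allowance, `0 <= S_P_ALL <= ST_ALL`).
#'
#' @param ledgers A tibble of ledgers.
#' @param path File path.
#' @export
write_ledgers <- function(ledgers, path) {
  readr::write_csv(ledgers[, LEDGER_COLUMNS], path)
  invisible(path)
}

LEDGER_COLUMNS <- c("institution_id", "institution_type", "ST_INC", "ST_ALL",
                    "S_P_ALL")

#' @rdname write_ledgers
#' @export
read_ledgers <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    institution_id = readr::col_character(),
    institution_type = readr::col_character(),
    ST_INC = readr::col_double(),
    ST_ALL = readr::col_double(),
    S_P_ALL = readr::col_double()
  ), progress = FALSE)
  missing_cols <- setdiff(LEDGER_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Ledger file is missing mandatory column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "cceann_format_error")
  }
  validate_ledgers(as_tibble(df[, LEDGER_COLUMNS]))
}

validate_ledgers <- function(ledgers) {
  bad <- which(ledgers$S_P_ALL > ledgers$ST_ALL | ledgers$S_P_ALL < 0 |
                 ledgers$ST_INC < 0 | ledgers$ST_ALL < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Ledger invariant 0 <= S_P_ALL <= ST_ALL (and nonnegative totals) violated at row(s) %s.",
      paste(head(bad, 10), collapse = ", ")
    ), class = "cceann_validation_error")
  }
  ledgers
}

#' Read and write the population table
#'
#' @param population A tibble with `age_group` (`0-14`, `15-64`, `65+`) and
#'   `population` in thousands of persons.
#' @param path File path.
#' @export
write_population <- function(population, path) {
  readr::write_csv(population[, c("age_group", "population")], path)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    age_group = readr::col_character(),
    population = readr::col_double()
  ), progress = FALSE)
  if (!setequal(df$age_group, AGE_BANDS) || nrow(df) != 3 ||
      any(df$population <= 0)) {
    abort("Population table must hold exactly one positive row per age band.",
          class = "cceann_validation_error")
  }
  as_tibble(df)
}

#' Write a full simulated dataset to a directory
#'
#' Writes `records.csv`, `ledgers.csv` and `population.csv`.
#'
#' @param sim A `cce_simulation` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "cce_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_records(sim$records, file.path(dir, "records.csv"))
  write_ledgers(sim$ledgers, file.path(dir, "ledgers.csv"))
  write_population(sim$population, file.path(dir, "population.csv"))
  invisible(dir)
}
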