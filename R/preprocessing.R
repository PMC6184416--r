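#' Exclude invalid discharge records
#'
#' Drops records the expenditure model cannot use: any missing mandatory
#' field, an inpatient stay below one day, an outpatient stay above zero,
#' a malformed ICD-10 code, or negative billed income. The exclusion report
#' counts removals by reason (a record failing several checks is counted
#' under the first that caught it).
#'
#' @param records A tibble of discharge records.
#' @return A list with `records` (clean tibble) and `report`
#'   (tibble of `reason`, `n`).
#' @export
exclude_invalid <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  flag <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, label, reason)
  }
  reason <- flag(!stats::complete.cases(records[, RECORD_COLUMNS]),
                 "missing_field")
  reason <- flag(!grepl(ICD10_PATTERN, records$icd10), "malformed_icd10")
  reason <- flag(records$setting == "inpatient" & records$length_of_stay < 1,
                 "nonpositive_inpatient_stay")
  reason <- flag(records$setting == "outpatient" & records$length_of_stay != 0,
                 "outpatient_with_stay")
  reason <- flag(records$curative_income < 0, "negative_income")

  clean <- records[is.na(reason), ]
  if (nrow(clean) == 0) {
    abort("All records were excluded; nothing left to analyze.",
          class = "cceann_empty_dataset_error")
  }
  report <- tibble(reason = reason[!is.na(reason)]) |>
    dplyr::count(.data$reason, name = "n")
  list(records = clean, report = report)
}

#' Standardize a numeric vector (z-score)
#'
#' Centers to mean 0 and scales to standard deviation 1, using the sample
#' (n-1) standard deviation.
#'
#' @param x Numeric vector, length at least 2, non-constant.
#' @return Standardized vector with `mean 0`, `sd 1` (tolerance 1e-8).
#' @export
zscore <- function(x) {
  if (length(x) < 2) {
    abort("`zscore()` needs at least 2 values.",
          class = "cceann_validation_error")
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Constant column: standard deviation is zero, z-score undefined.",
          class = "cceann_constant_column_error")
  }
  (x - mean(x)) / s
}

#' Select the modelling cohort
#'
#' The influencing-factor model is fitted on hospitalization expenditure of
#' elderly genitourinary admissions: inpatient setting, age at least
#' `min_age`, ICD-10 N00--N99, not preventive.
#'
#' @param records Clean discharge records.
#' @param min_age Lower age bound (default 65).
#' @return The subset tibble.
#' @export
model_cohort <- function(records, min_age = 65) {
  records |>
    dplyr::filter(.data$setting == "inpatient",
                  .data$age >= min_age,
                  is_genitourinary(.data$icd10),
                  !.data$is_preventive)
}

#' Encode the eight model factors into a numeric design matrix
#'
#' Continuous factors (`length_of_stay`, `age`) are z-scored; categoricals
#' are either mapped to their level index and z-scored
#' (`scheme = "ordinal"`, the default: exactly one standardized column per
#' factor) or expanded to one indicator column per observed level
#' (`scheme = "one_hot"`). The outcome is `log(curative_income)` by default,
#' matching the right-skewed cost distribution, or raw RMB with
#' `outcome = "raw"`.
#'
#' Ordinal is the default because the downstream Garson sensitivity
#' analysis compares importances *across* factors: summing dummy-column
#' importances hands a multi-level categorical several columns' worth of
#' weight magnitude (a multiplicity bias that can outrank a genuinely
#' dominant continuous driver), whereas one standardized column per factor
#' keeps the eight factors on an equal footing. One-hot remains available
#' for pure prediction, where the bias is irrelevant.
#'
#' Standardization statistics (and, under one-hot, the level sets) are
#' learned from the rows in `train_idx` when supplied and applied unchanged
#' to all rows, so no test-set information leaks into the encoding. A level
#' observed outside the training rows is an error, never a silent column.
#'
#' @param records Clean discharge records (the modelling cohort).
#' @param scheme `"one_hot"` or `"ordinal"`.
#' @param outcome `"log"` or `"raw"` hospitalization expenditure.
#' @param train_idx Optional integer indices of the training rows used to
#'   learn encoding statistics; default all rows.
#' @return An object of class `model_matrix`: list with `X` (n x p numeric
#'   matrix), `y`, `feature_map` (tibble `column`, `factor`), `n`, `p`.
#' @export
encode_factors <- function(records, scheme = c("ordinal", "one_hot"),
                           outcome = c("log", "raw"), train_idx = NULL) {
  scheme <- match.arg(scheme)
  outcome <- match.arg(outcome)
  if (is.null(train_idx)) train_idx <- seq_len(nrow(records))
  if (nrow(records) < 2) {
    abort("Need at least 2 records to encode.",
          class = "cceann_validation_error")
  }

  source_values <- list(
    length_of_stay = records$length_of_stay,
    institution_type = records$institution_type,
    insurance_type = records$insurance_type,
    surgery = as.numeric(records$surgery),
    gender = records$gender,
    institution_level = records$institution_level,
    age = records$age,
    admission_season = records$admission_season
  )
  continuous <- c("length_of_stay", "age", "surgery")

  cols <- list()
  map <- list()
  for (f in MODEL_FACTORS) {
    v <- source_values[[f]]
    if (f %in% continuous) {
      z <- scale_by_train(as.numeric(v), train_idx, f)
      if (is.null(z)) next
      cols[[f]] <- z
      map[[f]] <- tibble(column = f, factor = f)
    } else if (scheme == "ordinal") {
      # rank levels by their mean training-set outcome so the index scale
      # has ordinal meaning (alphabetical order would force the network to
      # fit an arbitrary zig-zag, inflating its weight magnitudes)
      mean_y <- tapply(log(records$curative_income[train_idx]),
                       v[train_idx], mean)
      levels_tr <- names(sort(mean_y))
      check_unseen(v, levels_tr, f)
      z <- scale_by_train(match(v, levels_tr), train_idx, f)
      if (is.null(z)) next
      cols[[f]] <- z
      map[[f]] <- tibble(column = f, factor = f)
    } else {
      levels_tr <- sort(unique(v[train_idx]))
      check_unseen(v, levels_tr, f)
      if (length(levels_tr) == 1) {
        warn(sprintf("Factor '%s' is constant on the training rows; dropped.",
                     f))
        next
      }
      for (lev in levels_tr) {
        nm <- paste0(f, ".", lev)
        cols[[nm]] <- as.numeric(v == lev)
        map[[nm]] <- tibble(column = nm, factor = f)
      }
    }
  }
  X <- do.call(cbind, cols)
  y <- if (outcome == "log") log(records$curative_income) else
    records$curative_income
  if (any(!is.finite(y))) {
    abort("Outcome is not finite for every record (zero income under log?).",
          class = "cceann_validation_error")
  }
  structure(
    list(X = X, y = y, feature_map = dplyr::bind_rows(map),
         n = nrow(X), p = ncol(X), scheme = scheme, outcome = outcome),
    class = "model_matrix"
  )
}

# NULL (with a warning) for constant columns: they carry no information and
# would standardize to NaN, so they are dropped, never silently kept.
scale_by_train <- function(v, train_idx, f) {
  m <- mean(v[train_idx])
  s <- sd(v[train_idx])
  if (!is.finite(s) || s == 0) {
    warn(sprintf("Factor '%s' is constant on the training rows; dropped.", f))
    return(NULL)
  }
  (v - m) / s
}

check_unseen <- function(v, levels_tr, f) {
  unseen <- setdiff(unique(v), levels_tr)
  if (length(unseen) > 0) {
    abort(sprintf("Factor '%s' has level(s) unseen in training rows: %s.",
                  f, paste(unseen, collapse = ", ")),
          class = "cceann_unknown_category_error")
  }
}

#' @export
print.model_matrix <- function(x, ...) {
  cat(sprintf("<model_matrix> n = %d, p = %d (%s encoding, %s outcome)\n",
              x$n, x$p, x$scheme, x$outcome))
  invisible(x)
}

#' Train/test and cross-validation split plan
#'
#' Holds out `round(test_frac * n)` rows as the test set and partitions the
#' remaining training rows into `k` folds whose sizes differ by at most one.
#' Deterministic given `seed`.
#'
#' @param n Number of rows (at least 20).
#' @param seed Integer seed.
#' @param test_frac Held-out fraction (default 0.10).
#' @param k Number of cross-validation folds (default 5).
#' @return An object of class `split_plan`: list with `train_idx`,
#'   `test_idx`, `cv_folds` (list of `k` index vectors), `seed`.
#' @export
make_splits <- function(n, seed, test_frac = 0.1, k = 5) {
  if (n < 20 || n < 2 * k) {
    abort(sprintf("n = %d is too small to split into a test set and %d folds.",
                  n, k), class = "cceann_validation_error")
  }
  set.seed(seed)
  test_idx <- sort(sample.int(n, round(test_frac * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  fold_of <- sample(rep(seq_len(k), length.out = length(train_idx)))
  structure(
    list(
      train_idx = train_idx,
      test_idx = test_idx,
      cv_folds = split(train_idx, fold_of),
      seed = as.integer(seed)
    ),
    class = "split_plan"
  )
}
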