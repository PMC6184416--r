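#' Per-patient sharing coefficient
#'
#' The SHA2011 apportionment splits an institution's yearbook totals onto its
#' sampled patients in proportion to billed curative income, after removing
#' preventive activity from the denominator: `a_i / (a - a_p)` where `a_i` is
#' the patient's curative income, `a` the institution's total sampled
#' curative income and `a_p` the income of records flagged preventive.
#'
#' @param a_i Per-record curative income (vectorized), RMB.
#' @param a Institution total sampled curative income, RMB.
#' @param a_p Institution sampled preventive curative income, RMB.
#' @return Sharing coefficients in `[0, 1]`; over an institution's
#'   non-preventive records they sum to 1.
#' @export
#' @examples
#' sharing_coefficient(100, 1000, 0)   # 0.1
#' sharing_coefficient(50, 1050, 50)   # 0.05
sharing_coefficient <- function(a_i, a, a_p = 0) {
  if (any(a_p < 0) || any(a_i < 0)) {
    abort("Curative income must be nonnegative.",
          class = "cceann_validation_error")
  }
  if (any(a <= a_p)) {
    abort(paste0("Degenerate institution: total sampled income does not ",
                 "exceed its preventive share (a <= a_p); the sharing ",
                 "coefficient is undefined."),
          class = "cceann_degenerate_institution_error")
  }
  a_i / (a - a_p)
}

# per-institution sampled totals a and a_p
sampled_totals <- function(records) {
  records |>
    dplyr::group_by(.data$institution_id) |>
    dplyr::summarise(
      a = sum(.data$curative_income),
      a_p = sum(.data$curative_income[.data$is_preventive]),
      .groups = "drop"
    )
}

#' Apportion yearbook totals onto individual admissions
#'
#' For each institution, splits curative income `ST_INC` (net of its
#' preventive share, taken as `ST_INC * a_p / a`) and basic expenditure
#' allowance `ST_ALL - S_P_ALL` over the institution's non-preventive sampled
#' records by the sharing coefficient `a_i / (a - a_p)`. Preventive records
#' receive zero. Each record's curative care expenditure (CCE) is the sum of
#' its income and allowance shares.
#'
#' Institutions whose ledger carries totals but which have no sampled
#' non-preventive curative income cannot be apportioned; their
#' `ST_ALL - S_P_ALL` (and net `ST_INC`) goes to an explicit unallocated
#' bucket returned as the `"unallocated"` attribute, never silently dropped.
#'
#' @param records Discharge records (one institution or many).
#' @param ledgers Institution ledgers matching `records$institution_id`.
#' @param setting_strata If `TRUE`, apportionment runs separately within the
#'   outpatient and inpatient stratum of each institution (the yearbook total
#'   is first split across strata by their sampled income shares).
#' @return A tibble with `record_id`, `allocated_income`,
#'   `allocated_allowance` and `cce`, in the input record order, with
#'   attribute `"unallocated"` (tibble of institution-level remainders).
#' @export
allocate_cce <- function(records, ledgers, setting_strata = FALSE) {
  validate_ledgers(ledgers)
  unknown <- setdiff(unique(records$institution_id), ledgers$institution_id)
  if (length(unknown) > 0) {
    abort(sprintf("No ledger for institution(s): %s.",
                  paste(head(unknown, 5), collapse = ", ")),
          class = "cceann_lookup_error")
  }
  if (setting_strata) {
    sampled_ids <- unique(records$institution_id)
    zero_led <- ledgers[!ledgers$institution_id %in% sampled_ids, ]
    parts <- split(records, records$setting)
    alloc <- purrr::map(parts, function(part) {
      led <- scale_ledger_to_stratum(ledgers, records, part$setting[1])
      allocate_cce(part, led, setting_strata = FALSE)
    })
    out <- dplyr::bind_rows(alloc)
    out <- out[match(records$record_id, out$record_id), ]
    zero_unalloc <- dplyr::transmute(
      zero_led, institution_id = .data$institution_id,
      unallocated = .data$ST_INC + .data$ST_ALL - .data$S_P_ALL
    )
    attr(out, "unallocated") <- dplyr::bind_rows(
      c(unname(purrr::map(alloc, attr, "unallocated")), list(zero_unalloc))
    )
    return(out)
  }

  totals <- sampled_totals(records)
  df <- records |>
    dplyr::select("record_id", "institution_id", "curative_income",
                  "is_preventive") |>
    dplyr::left_join(totals, by = "institution_id") |>
    dplyr::left_join(ledgers, by = "institution_id")

  ok <- df$a > df$a_p
  coef <- numeric(nrow(df))
  coef[ok] <- df$curative_income[ok] / (df$a[ok] - df$a_p[ok])
  coef[df$is_preventive] <- 0

  alloc_income <- ifelse(ok, df$ST_INC * (1 - df$a_p / df$a), 0) * coef
  alloc_allow <- ifelse(ok, df$ST_ALL - df$S_P_ALL, 0) * coef

  allocated_ids <- unique(df$institution_id[ok & !df$is_preventive])
  unallocated <- ledgers |>
    dplyr::filter(!.data$institution_id %in% allocated_ids) |>
    dplyr::mutate(unallocated = .data$ST_INC + .data$ST_ALL - .data$S_P_ALL) |>
    dplyr::select("institution_id", "unallocated")

  out <- tibble(
    record_id = df$record_id,
    allocated_income = alloc_income,
    allocated_allowance = alloc_allow,
    cce = alloc_income + alloc_allow
  )
  attr(out, "unallocated") <- unallocated
  out
}

# Split each ledger's totals across care settings in proportion to sampled
# income, so within-stratum apportionment still conserves the yearbook total.
scale_ledger_to_stratum <- function(ledgers, records, setting) {
  shares <- records |>
    dplyr::group_by(.data$institution_id) |>
    dplyr::summarise(
      share = sum(.data$curative_income[.data$setting == !!setting]) /
        sum(.data$curative_income),
      .groups = "drop"
    )
  ledgers |>
    dplyr::inner_join(shares, by = "institution_id") |>
    dplyr::mutate(
      share = dplyr::coalesce(.data$share, 0),
      ST_INC = .data$ST_INC * .data$share,
      ST_ALL = .data$ST_ALL * .data$share,
      S_P_ALL = .data$S_P_ALL * .data$share
    ) |>
    dplyr::select(-"share")
}

#' Apportioned income / allowance for one institution
#'
#' Convenience wrappers around [allocate_cce()] returning a single numeric
#' vector aligned with `records`.
#'
#' @inheritParams allocate_cce
#' @return Numeric vector of per-record shares, RMB.
#' @export
allocate_income <- function(records, ledgers) {
  allocate_cce(records, ledgers)$allocated_income
}

#' @rdname allocate_income
#' @export
allocate_allowance <- function(records, ledgers) {
  allocate_cce(records, ledgers)$allocated_allowance
}

#' Aggregate CCE along a reporting dimension
#'
#' @param allocations Result of [allocate_cce()].
#' @param records The matching discharge records (to supply grouping fields).
#' @param by Name of a record field to group by, or `NULL` for the grand
#'   total. Derived dimensions `age_band`, `icd10_chapter` and `gbd_group`
#'   are also accepted.
#' @param gbd_map Mapping table for `by = "gbd_group"`; see [default_gbd_map()].
#' @return A tibble `(group, cce)` sorted by descending expenditure, plus a
#'   `(group = "total")` grand-total row accessible via [sum()] of the column.
#' @export
total_cce <- function(allocations, records, by = NULL,
                      gbd_map = default_gbd_map()) {
  df <- dplyr::inner_join(allocations, records, by = "record_id")
  if (is.null(by)) {
    return(tibble(group = "total", cce = sum(df$cce)))
  }
  derived <- c("age_band", "icd10_chapter", "gbd_group")
  valid <- c(setdiff(names(records), "record_id"), derived)
  if (!by %in% valid) {
    abort(sprintf("Unknown dimension '%s'. Valid dimensions: %s.", by,
                  paste(valid, collapse = ", ")),
          class = "cceann_usage_error")
  }
  df$group <- switch(by,
    age_band = age_band(df$age),
    icd10_chapter = icd10_chapter(df$icd10),
    gbd_group = gbd_group(df$icd10, gbd_map),
    df[[by]]
  )
  df |>
    dplyr::group_by(group = .data$group) |>
    dplyr::summarise(cce = sum(.data$cce), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$cce))
}
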