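#' Expenditure shares over a complete partition
#'
#' Adds `proportion` (percent of the column total) to a grouped expenditure
#' table. Full precision is kept; rounding happens only at serialization.
#'
#' @param table Tibble with a grouping column and `expenditure`.
#' @param expenditure Column name holding expenditures (default
#'   `"expenditure"`).
#' @return The table with a `proportion` column (percent, sums to 100).
#' @export
#' @examples
#' proportion_table(tibble::tibble(
#'   age_group = c("0-14", "15-64", "65+"),
#'   expenditure = c(4.57, 46.45, 22.82)
#' ))
proportion_table <- function(table, expenditure = "expenditure") {
  e <- table[[expenditure]]
  if (any(e < 0) || sum(e) == 0) {
    abort("Expenditures must be nonnegative with a positive total.",
          class = "cceann_validation_error")
  }
  dplyr::mutate(table, proportion = 100 * e / sum(e))
}

#' Per-capita expenditure
#'
#' @param expenditure Expenditure in RMB.
#' @param population Population in thousands of persons.
#' @return RMB per person: `expenditure / (population * 1000)`.
#' @export
#' @examples
#' per_capita(979.14e6, 5135.50) # elderly genitourinary CCE per person
per_capita <- function(expenditure, population) {
  if (any(population <= 0)) {
    abort("`population` must be positive (thousands of persons).",
          class = "cceann_validation_error")
  }
  expenditure / (population * 1000)
}

#' Outpatient/inpatient split of CCE by group
#'
#' @param allocations Result of [allocate_cce()].
#' @param records Matching discharge records carrying `setting`.
#' @param by Record field to group by (e.g. `"institution_type"`).
#' @return Tibble with `group`, `cce`, `outpatient_pct`, `inpatient_pct`
#'   (the two percentages sum to 100 within each group).
#' @export
setting_split <- function(allocations, records, by = "institution_type") {
  df <- dplyr::inner_join(allocations, records, by = "record_id")
  if (anyNA(df$setting) || !all(df$setting %in% c("outpatient", "inpatient"))) {
    abort("Every allocation must be labeled outpatient or inpatient.",
          class = "cceann_validation_error")
  }
  df |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::summarise(
      outpatient_cce = sum(.data$cce[.data$setting == "outpatient"]),
      cce = sum(.data$cce),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      outpatient_pct = 100 * .data$outpatient_cce / .data$cce,
      inpatient_pct = 100 - .data$outpatient_pct
    ) |>
    dplyr::select("group", "cce", "outpatient_pct", "inpatient_pct") |>
    dplyr::arrange(dplyr::desc(.data$cce))
}

#' Combine group rows of a setting-split table into its total row
#'
#' The overall outpatient share is the CCE-weighted mean of the group
#' shares: `sum(cce_g * outpatient_pct_g) / sum(cce_g)`.
#'
#' @param table Tibble with `cce` and `outpatient_pct` per group.
#' @return One-row tibble with total `cce`, `outpatient_pct`,
#'   `inpatient_pct`.
#' @export
#' @examples
#' setting_total(tibble::tibble(
#'   cce = c(216.78, 15.53, 0.77, 0.10),
#'   outpatient_pct = c(16.23, 63.67, 96.64, 100.00)
#' ))
setting_total <- function(table) {
  tot <- sum(table$cce)
  out <- sum(table$cce * table$outpatient_pct) / tot
  tibble(cce = tot, outpatient_pct = out, inpatient_pct = 100 - out)
}

# group x setting contingency of CCE, the single array both GBD table
# styles derive from
cce_contingency <- function(allocations, records, group) {
  dplyr::inner_join(allocations, records, by = "record_id") |>
    dplyr::group_by(group = {{ group }}, setting = .data$setting) |>
    dplyr::summarise(cce = sum(.data$cce), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "setting", values_from = "cce",
                       values_fill = 0) |>
    (\(d) {
      for (col in c("outpatient", "inpatient"))
        if (!col %in% names(d)) d[[col]] <- 0
      d
    })()
}

#' GBD broad-group expenditure shares in two normalizations
#'
#' From one group-by-setting contingency array, derives the two standard
#' presentations: `share_of_total` normalizes each column over groups (each
#' column sums to 100: a group's share of all expenditure, of outpatient
#' expenditure, of inpatient expenditure), and `within_group` normalizes the
#' outpatient/inpatient split within each group row (each row sums to 100).
#' Each table reproduces the other's marginals.
#'
#' @param allocations Result of [allocate_cce()].
#' @param records Matching discharge records.
#' @param gbd_map Mapping table, see [default_gbd_map()].
#' @return List of tibbles `share_of_total` and `within_group`.
#' @export
gbd_tables <- function(allocations, records, gbd_map = default_gbd_map()) {
  cont <- cce_contingency(allocations, records,
                          gbd_group(.data$icd10, gbd_map))
  total <- cont$outpatient + cont$inpatient
  list(
    share_of_total = tibble(
      group = cont$group,
      total_pct = 100 * total / sum(total),
      outpatient_pct = 100 * cont$outpatient / sum(cont$outpatient),
      inpatient_pct = 100 * cont$inpatient / sum(cont$inpatient)
    ),
    within_group = tibble(
      group = cont$group,
      total_pct = 100 * total / sum(total),
      outpatient_pct = 100 * cont$outpatient / total,
      inpatient_pct = 100 * cont$inpatient / total
    )
  )
}

#' Render the full set of dimensional expenditure tables
#'
#' Produces the standard reporting battery from per-record allocations:
#' GBD broad-group shares (both normalizations), institution-type table with
#' outpatient/inpatient split, age-band table with per-capita expenditure,
#' ICD-10 chapter table, and the genitourinary-by-age table (proportions
#' taken against each age band's all-cause expenditure). Optionally writes
#' each table as CSV (rounded to 2 decimals, with a units header line) plus
#' a JSON manifest.
#'
#' @param allocations Result of [allocate_cce()].
#' @param records Matching discharge records.
#' @param population Population table (thousands per age band), needed for
#'   per-capita columns.
#' @param gbd_map Mapping table, see [default_gbd_map()].
#' @param dir Optional output directory for CSV serialization.
#' @param units `"million"` or `"billion"` RMB for serialized expenditures.
#' @return Named list of tibbles (invisibly the directory when `dir` is
#'   given via the `"dir"` attribute).
#' @export
render_tables <- function(allocations, records, population = NULL,
                          gbd_map = default_gbd_map(), dir = NULL,
                          units = c("million", "billion")) {
  units <- match.arg(units)
  df <- dplyr::inner_join(allocations, records, by = "record_id")

  gbd <- gbd_tables(allocations, records, gbd_map)

  institution <- setting_split(allocations, records, by = "institution_type")

  age <- df |>
    dplyr::group_by(age_group = age_band(.data$age)) |>
    dplyr::summarise(expenditure = sum(.data$cce), .groups = "drop") |>
    proportion_table()
  if (!is.null(population)) {
    age <- age |>
      dplyr::left_join(population, by = "age_group") |>
      dplyr::mutate(per_capita = per_capita(.data$expenditure,
                                            .data$population))
  }

  chapter <- df |>
    dplyr::group_by(chapter = icd10_chapter(.data$icd10)) |>
    dplyr::summarise(expenditure = sum(.data$cce), .groups = "drop") |>
    proportion_table() |>
    dplyr::arrange(dplyr::desc(.data$expenditure))

  gu <- df[is_genitourinary(df$icd10), ]
  if (nrow(gu) == 0) {
    warn("No genitourinary (N00-N99) records; emitting an empty table.")
    gu_age <- tibble(age_group = character(), expenditure = numeric(),
                     proportion = numeric())
  } else {
    all_age <- df |>
      dplyr::group_by(age_group = age_band(.data$age)) |>
      dplyr::summarise(total = sum(.data$cce), .groups = "drop")
    gu_age <- gu |>
      dplyr::group_by(age_group = age_band(.data$age)) |>
      dplyr::summarise(expenditure = sum(.data$cce), .groups = "drop") |>
      dplyr::left_join(all_age, by = "age_group") |>
      dplyr::mutate(proportion = 100 * .data$expenditure / .data$total) |>
      dplyr::select(-"total")
    if (!is.null(population)) {
      gu_age <- gu_age |>
        dplyr::left_join(population, by = "age_group") |>
        dplyr::mutate(per_capita = per_capita(.data$expenditure,
                                              .data$population))
    }
  }

  tables <- list(
    gbd_share_of_total = gbd$share_of_total,
    gbd_within_group = gbd$within_group,
    institution = institution,
    age_group = age,
    icd10_chapter = chapter,
    genitourinary_age = gu_age
  )
  if (!is.null(dir)) {
    write_table_set(tables, dir, units)
    attr(tables, "dir") <- dir
  }
  tables
}

# serialize: expenditure converted to the requested unit, everything rounded
# to 2 decimals, one "# units:" comment line above the header, plus a JSON
# manifest of what was written
write_table_set <- function(tables, dir, units) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  div <- c(million = 1e6, billion = 1e9)[[units]]
  manifest <- purrr::imap(tables, function(tab, nm) {
    out <- tab
    for (col in intersect(c("expenditure", "cce"), names(out))) {
      out[[col]] <- out[[col]] / div
    }
    out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                            \(x) round(x, 2)))
    path <- file.path(dir, paste0(nm, ".csv"))
    writeLines(sprintf("# units: %s RMB", units), path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE)
    list(file = basename(path), rows = nrow(out), units = units)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
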