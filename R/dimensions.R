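# ICD-10 chapter boundaries (three-character categories). D and H chapters
# split mid-letter; S00-T98 and V01-Y98 span letters. Lexicographic
# comparison on the normalized 3-character code is order-correct.
ICD10_CHAPTERS <- tibble::tibble(
  start = c("A00", "C00", "D50", "E00", "F00", "G00", "H00", "H60", "I00",
            "J00", "K00", "L00", "M00", "N00", "O00", "P00", "Q00", "R00",
            "S00", "V01", "Z00", "U00"),
  end   = c("B99", "D48", "D89", "E90", "F99", "G99", "H59", "H95", "I99",
            "J99", "K93", "L99", "M99", "N99", "O99", "P96", "Q99", "R99",
            "T98", "Y98", "Z99", "U99"),
  chapter = c(
    "Certain infectious and parasitic diseases",
    "Neoplasms",
    "Diseases of the blood and blood-forming organs and certain disorders involving the immune mechanism",
    "Endocrine, nutritional and metabolic diseases",
    "Mental and behavioural disorders",
    "Diseases of the nervous system",
    "Diseases of the eye and adnexa",
    "Diseases of the ear and mastoid process",
    "Diseases of the circulatory system",
    "Diseases of the respiratory system",
    "Diseases of the digestive system",
    "Diseases of the skin and subcutaneous tissue",
    "Diseases of the musculoskeletal system and connective tissue",
    "Diseases of the genitourinary system",
    "Pregnancy, childbirth and the puerperium",
    "Certain conditions originating in the perinatal period",
    "Congenital malformations, deformations and chromosomal abnormalities",
    "Symptoms, signs and abnormal clinical and laboratory findings, not elsewhere classified",
    "Injury, poisoning and certain other consequences of external causes",
    "External causes of morbidity and mortality",
    "Factors influencing health status and contact with health services",
    "Codes for special purposes"
  )
)

# normalize "N18.5" -> "N18"; error on anything not ICD-10-shaped
normalize_icd10 <- function(code) {
  ok <- !is.na(code) & grepl(ICD10_PATTERN, code)
  if (any(!ok)) {
    abort(sprintf("Malformed ICD-10 code(s): %s.",
                  paste(head(unique(code[!ok]), 5), collapse = ", ")),
          class = "cceann_validation_error")
  }
  substr(code, 1, 3)
}

match_ranges <- function(code3, start, end) {
  # for each code, the index of the (first) range containing it, NA if none
  hit <- rep(NA_integer_, length(code3))
  for (i in seq_along(start)) {
    sel <- is.na(hit) & code3 >= start[i] & code3 <= end[i]
    hit[sel] <- i
  }
  hit
}

#' ICD-10 chapter of a diagnosis code
#'
#' @param code Character vector of ICD-10 codes (three-character category,
#'   optional decimal subdivision, e.g. `"N18"` or `"N18.5"`).
#' @return Character vector of standard chapter titles; N00--N99 codes map to
#'   `"Diseases of the genitourinary system"`.
#' @export
#' @examples
#' icd10_chapter(c("N18", "I10"))
icd10_chapter <- function(code) {
  code3 <- normalize_icd10(code)
  hit <- match_ranges(code3, ICD10_CHAPTERS$start, ICD10_CHAPTERS$end)
  # syntactically valid codes between chapter blocks (e.g. D49) are
  # unclassifiable in strict ICD-10; report them explicitly
  out <- ICD10_CHAPTERS$chapter[hit]
  out[is.na(hit)] <- "Unassigned"
  out
}

#' Is a code a genitourinary-system diagnosis (N00--N99)?
#'
#' @inheritParams icd10_chapter
#' @return Logical vector.
#' @export
is_genitourinary <- function(code) {
  startsWith(normalize_icd10(code), "N")
}

#' Default ICD-10 to GBD broad-cause mapping
#'
#' The bundled table follows the classical Global Burden of Disease broad
#' grouping: Group I (communicable, maternal, perinatal and nutritional)
#' covers A00--B99, nutritional anaemias and deficiencies, meningitis and
#' the maternal/perinatal chapters; Group III (injuries) covers S00--T98 and
#' the external-cause chapter; ill-defined symptoms (R00--R99) and
#' special-purpose codes fall to `other_unclassified`; the remaining disease
#' chapters are Group II (non-communicable diseases). It ships as an
#' editable CSV (`range_start`, `range_end`, `group`) so the grouping is
#' auditable data, not code.
#'
#' @param path Optional path to a replacement CSV in the same layout.
#' @return A tibble of ordered, disjoint code ranges.
#' @export
default_gbd_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gbd_map.csv", package = "cceann")
  }
  map <- readr::read_csv(path, col_types = readr::cols(
    range_start = readr::col_character(),
    range_end = readr::col_character(),
    group = readr::col_character()
  ), progress = FALSE)
  bad_group <- setdiff(unique(map$group), GBD_GROUPS)
  if (length(bad_group) > 0) {
    abort(sprintf("Unknown GBD group label(s): %s.",
                  paste(bad_group, collapse = ", ")),
          class = "cceann_validation_error")
  }
  map <- dplyr::arrange(map, .data$range_start)
  overlap <- map$range_start[-1] <= map$range_end[-nrow(map)]
  if (any(overlap)) {
    abort("GBD mapping ranges overlap after normalization.",
          class = "cceann_validation_error")
  }
  map
}

GBD_GROUPS <- c("group_I_infectious_maternal_perinatal", "group_II_ncd",
                "group_III_injury", "other_unclassified")

#' GBD broad cause group of a diagnosis code
#'
#' Codes falling outside every mapped range are returned as
#' `other_unclassified` (never an error) with a warning naming them.
#'
#' @inheritParams icd10_chapter
#' @param map Mapping table, by default [default_gbd_map()].
#' @return Character vector over the four broad-group labels.
#' @export
#' @examples
#' gbd_group(c("A15", "I10", "V01", "R50"))
gbd_group <- function(code, map = default_gbd_map()) {
  code3 <- normalize_icd10(code)
  hit <- match_ranges(code3, map$range_start, map$range_end)
  out <- map$group[hit]
  if (anyNA(hit)) {
    warn(sprintf("ICD-10 code(s) outside the GBD map, classed as other: %s.",
                 paste(head(unique(code3[is.na(hit)]), 5), collapse = ", ")))
    out[is.na(hit)] <- "other_unclassified"
  }
  out
}

#' Reporting age band
#'
#' Partitions nonnegative integer ages into the three reporting bands:
#' 0--14, 15--64 and 65-and-over.
#'
#' @param age Integer vector of ages in years.
#' @return Character vector over `"0-14"`, `"15-64"`, `"65+"`.
#' @export
#' @examples
#' age_band(c(0, 14, 15, 64, 65, 90))
age_band <- function(age) {
  if (any(is.na(age)) || any(age < 0) || any(age != floor(age))) {
    abort("`age` must be nonnegative whole years.",
          class = "cceann_validation_error")
  }
  dplyr::case_when(
    age <= 14 ~ AGE_BANDS[1],
    age <= 64 ~ AGE_BANDS[2],
    TRUE ~ AGE_BANDS[3]
  )
}
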