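# Charlson comorbidity index and named comorbidity flags over a look-back
# window anchored either at the index MM diagnosis or at first-LOT start.

#' The eight named comorbidity flags
#' @return character vector of condition names.
#' @export
comorbidity_conditions <- function() {
  c("cardiac_arrhythmia", "congestive_heart_failure",
    "hypertension_complicated", "hypertension_simple", "hepatic_disease",
    "pulmonary_circulation_disorders", "renal_impairment", "valvular_disease")
}

# Conditions folded into the single cardiovascular covariate used by the
# subsequent-treatment models.
cardiovascular_components <- function() {
  c("cardiac_arrhythmia", "congestive_heart_failure",
    "hypertension_complicated", "valvular_disease")
}

#' Diagnosis code map
#'
#' Maps diagnosis codes to the named comorbidity conditions and to Charlson
#' categories with the classic 17-category weights (1/2/3/6). The map is a
#' data file: alternative code dialects are supplied by pointing `path` at a
#' CSV with columns `code,condition,charlson_category,weight`.
#'
#' @param path optional CSV path; defaults to the map shipped with the
#'   package (synthetic `DX_*` codes used by the claims generator).
#' @return tibble with columns `code`, `condition`, `charlson_category`,
#'   `weight`.
#' @export
default_code_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "code_map.csv", package = "mmlot")
  map <- readr::read_csv(
    path,
    col_types = readr::cols(
      code = readr::col_character(),
      condition = readr::col_character(),
      charlson_category = readr::col_character(),
      weight = readr::col_integer()
    )
  )
  if (any(!is.na(map$weight) & map$weight < 1)) {
    config_error("code_map", "Charlson weights must be >= 1")
  }
  map
}

# severe form suppresses the mild form for the same patient
flag_hierarchy <- function() {
  tibble::tibble(severe = "hypertension_complicated",
                 mild = "hypertension_simple")
}

charlson_hierarchy <- function() {
  tibble::tribble(
    ~severe,                          ~mild,
    "diabetes_with_complications",    "diabetes",
    "moderate_severe_liver_disease",  "mild_liver_disease",
    "metastatic_solid_tumor",         "malignancy"
  )
}

apply_hierarchy <- function(df, key, hierarchy) {
  for (i in seq_len(nrow(hierarchy))) {
    sup <- df |>
      dplyr::filter(.data[[key]] == hierarchy$severe[i]) |>
      dplyr::distinct(.data$patient_id)
    df <- df |>
      dplyr::anti_join(
        dplyr::mutate(sup, !!key := hierarchy$mild[i]),
        by = c("patient_id", key)
      )
  }
  df
}

#' Comorbidity profiles over a look-back window
#'
#' For each patient, flags each named comorbidity as present when at least
#' one mapped diagnosis event falls in `[anchor - window_days, anchor - 1]`,
#' applies hierarchical suppression (complicated hypertension suppresses
#' simple hypertension), derives the cardiovascular composite (arrhythmia OR
#' congestive heart failure OR complicated hypertension OR valvular
#' disease), and computes the Charlson Comorbidity Index as the sum of
#' weights over distinct in-window Charlson categories (each category
#' counted once; severe forms suppress their mild counterparts). The index
#' MM diagnosis code is excluded from the score by default so that every
#' cohort member does not carry the malignancy weight by construction.
#'
#' @param diagnoses tibble of diagnosis events (`patient_id`, `date`,
#'   `code`).
#' @param anchors tibble with `patient_id` and `anchor_date` (one row per
#'   patient); both the index-diagnosis and the first-LOT-start anchors are
#'   first-class, so callers pass whichever the table at hand requires.
#' @param window_days look-back window length in days (default 180).
#' @param code_map a [default_code_map()] tibble.
#' @param exclude_codes codes excluded from the CCI (default the index MM
#'   code `DX_MM`); flags are unaffected.
#' @return tibble with one row per anchor patient: logical flag columns,
#'   `cardiovascular_composite`, and integer `cci_score`. Unmapped in-window
#'   codes are ignored and counted in the `unmapped_codes` attribute.
#' @export
comorbidity_profiles <- function(diagnoses, anchors, window_days = 180,
                                 code_map = default_code_map(),
                                 exclude_codes = "DX_MM") {
  stopifnot(all(c("patient_id", "anchor_date") %in% names(anchors)))
  anchors <- dplyr::mutate(anchors, anchor_date = as_date_safe(.data$anchor_date))
  ev <- diagnoses |>
    dplyr::mutate(date = as_date_safe(.data$date)) |>
    dplyr::inner_join(anchors, by = "patient_id") |>
    dplyr::filter(.data$date >= .data$anchor_date - window_days,
                  .data$date <= .data$anchor_date - 1)
  n_unmapped <- sum(!ev$code %in% code_map$code)
  ev <- dplyr::inner_join(ev, code_map, by = "code")

  flags_long <- ev |>
    dplyr::filter(!is.na(.data$condition)) |>
    dplyr::distinct(.data$patient_id, .data$condition) |>
    apply_hierarchy("condition", flag_hierarchy())

  flags <- tidyr::expand_grid(patient_id = anchors$patient_id,
                              condition = comorbidity_conditions()) |>
    dplyr::left_join(dplyr::mutate(flags_long, present = TRUE),
                     by = c("patient_id", "condition")) |>
    dplyr::mutate(present = !is.na(.data$present)) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "present")

  cci <- ev |>
    dplyr::filter(!is.na(.data$charlson_category),
                  !.data$code %in% exclude_codes) |>
    dplyr::distinct(.data$patient_id, .data$charlson_category, .data$weight) |>
    apply_hierarchy("charlson_category", charlson_hierarchy()) |>
    dplyr::summarise(cci_score = sum(.data$weight), .by = "patient_id")

  out <- flags |>
    dplyr::left_join(cci, by = "patient_id") |>
    dplyr::mutate(
      cci_score = as.integer(dplyr::coalesce(.data$cci_score, 0L)),
      cardiovascular_composite =
        rowSums(dplyr::pick(dplyr::all_of(cardiovascular_components()))) > 0
    )
  attr(out, "unmapped_codes") <- n_unmapped
  out
}

#' Comorbidity flags for a single anchor date
#'
#' Single-patient convenience wrapper around [comorbidity_profiles()].
#'
#' @param diagnoses diagnosis events for one patient (or more; all rows are
#'   treated as one patient's history).
#' @param anchor_date the window anchor.
#' @inheritParams comorbidity_profiles
#' @return one-row profile tibble.
#' @export
comorbidity_flags <- function(diagnoses, anchor_date, window_days = 180,
                              code_map = default_code_map(),
                              exclude_codes = "DX_MM") {
  pid <- if (nrow(diagnoses) > 0) diagnoses$patient_id[1] else "patient"
  diagnoses$patient_id <- pid
  comorbidity_profiles(
    diagnoses,
    tibble::tibble(patient_id = pid, anchor_date = as_date_safe(anchor_date)),
    window_days = window_days, code_map = code_map,
    exclude_codes = exclude_codes
  )
}

#' Charlson Comorbidity Index for a single anchor date
#'
#' @inheritParams comorbidity_flags
#' @return non-negative integer score.
#' @export
cci_score <- function(diagnoses, anchor_date, window_days = 180,
                      code_map = default_code_map(),
                      exclude_codes = "DX_MM") {
  comorbidity_flags(diagnoses, anchor_date, window_days, code_map,
                    exclude_codes)$cci_score
}
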