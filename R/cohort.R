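# Study inclusion/exclusion rules, follow-up windows, transplant strata.

#' Cohort construction rules
#'
#' @param index_floor_date earliest admissible index MM diagnosis date.
#' @param lookback_days required continuous coverage before index.
#' @param coverage_gap_days permissible gap between coverage intervals when
#'   assessing continuous eligibility (default 0; 30- or 45-day bridging is
#'   a common claims convention and can be configured here).
#' @param prior_malignancy_codes diagnosis codes whose presence in the
#'   look-back year excludes the patient.
#' @param mm_codes diagnosis codes identifying multiple myeloma; the first
#'   such event is the index diagnosis.
#' @return a `cohort_rules` list.
#' @export
cohort_rules <- function(index_floor_date = "2007-01-01",
                         lookback_days = 365,
                         coverage_gap_days = 0,
                         prior_malignancy_codes = "DX_PRIOR_MAL",
                         mm_codes = "DX_MM") {
  structure(list(
    index_floor_date = as_date_safe(index_floor_date),
    lookback_days = lookback_days,
    coverage_gap_days = coverage_gap_days,
    prior_malignancy_codes = prior_malignancy_codes,
    mm_codes = mm_codes
  ), class = "cohort_rules")
}

index_dates <- function(diagnoses, mm_codes) {
  diagnoses |>
    dplyr::filter(.data$code %in% mm_codes) |>
    dplyr::mutate(date = as_date_safe(.data$date)) |>
    dplyr::summarise(index_date = min_date(.data$date), .by = "patient_id")
}

#' Follow-up windows per patient
#'
#' For claims-type sources, follow-up ends with continuous insurance
#' eligibility: the end of the merged coverage interval (medical and
#' pharmacy each, bridged by at most `coverage_gap_days`) that contains the
#' index date, taking the earlier of the two kinds. For EMR-type sources,
#' follow-up ends on the last date of observed activity (any diagnosis,
#' claim or procedure). Death truncates follow-up when earlier. Patients
#' without both coverage kinds active at index have `eligible_at_index =
#' FALSE` and no follow-up window (they fail the coverage criterion).
#'
#' @param population an `mm_population`.
#' @param rules a [cohort_rules()] object.
#' @return tibble: `patient_id`, `index_date`, `source_kind`, `death_date`,
#'   `eligible_at_index`, `lookback_ok`, `followup_end`.
#' @export
followup_ends <- function(population, rules = cohort_rules()) {
  idx <- index_dates(population$diagnoses, rules$mm_codes)
  pts <- population$patients |>
    dplyr::select("patient_id", "source_kind", "death_date")
  base <- dplyr::left_join(idx, pts, by = "patient_id") |>
    dplyr::mutate(source_kind = dplyr::coalesce(.data$source_kind, "claims"))

  cov <- population$coverage |>
    dplyr::mutate(start = as_date_safe(.data$start),
                  end = as_date_safe(.data$end)) |>
    merge_spans(c("patient_id", "kind"), gap = rules$coverage_gap_days) |>
    dplyr::inner_join(idx, by = "patient_id") |>
    dplyr::filter(.data$start <= .data$index_date,
                  .data$end >= .data$index_date) |>
    dplyr::summarise(cov_start = max(.data$start), cov_end = min(.data$end),
                     n_kinds = dplyr::n_distinct(.data$kind),
                     .by = "patient_id")

  activity <- dplyr::bind_rows(
    dplyr::select(population$diagnoses, "patient_id", "date"),
    dplyr::select(population$drug_claims, "patient_id", "date"),
    dplyr::select(population$procedures, "patient_id", "date")
  ) |>
    dplyr::mutate(date = as_date_safe(.data$date)) |>
    dplyr::summarise(last_activity = suppressWarnings(max(.data$date)),
                     .by = "patient_id")

  base |>
    dplyr::left_join(cov, by = "patient_id") |>
    dplyr::left_join(activity, by = "patient_id") |>
    dplyr::mutate(
      eligible_at_index = !is.na(.data$n_kinds) & .data$n_kinds == 2,
      lookback_ok = .data$eligible_at_index &
        .data$cov_start <= .data$index_date - rules$lookback_days,
      raw_end = dplyr::if_else(.data$source_kind == "emr",
                               .data$last_activity, .data$cov_end),
      followup_end = dplyr::if_else(
        .data$eligible_at_index | .data$source_kind == "emr",
        pmin(.data$raw_end, .data$death_date, na.rm = TRUE),
        as.Date(NA)
      )
    ) |>
    dplyr::select("patient_id", "index_date", "source_kind", "death_date",
                  "eligible_at_index", "lookback_ok", "followup_end")
}

#' Follow-up end for a single patient
#'
#' @param population an `mm_population`.
#' @param patient_id one patient identifier.
#' @inheritParams followup_ends
#' @return a `Date` (NA when the patient is ineligible at index).
#' @export
determine_followup_end <- function(population, patient_id,
                                   rules = cohort_rules()) {
  fu <- followup_ends(population, rules)
  fu$followup_end[match(patient_id, fu$patient_id)]
}

#' Follow-up months from first-LOT start
#'
#' `(followup_end - start) / 30.4375`, the convention used for the
#' follow-up sensitivity subsets.
#'
#' @param first_lot_start,followup_end dates.
#' @return numeric months.
#' @export
followup_months <- function(first_lot_start, followup_end) {
  months_between(first_lot_start, followup_end)
}

age_category_levels <- function() c("<65", "65-74", "75-84", ">=85")

cut_age <- function(age) {
  cut(age, breaks = c(-Inf, 64, 74, 84, Inf),
      labels = age_category_levels())
}

#' Apply the study inclusion criteria
#'
#' Applies, in order: (0) demographics on file for a patient with an MM
#' claim; (1) index MM diagnosis on/after the floor date; (2) known sex;
#' (3) medical and pharmacy coverage active on the index date; (4) at
#' least `lookback_days` of continuous coverage before index; (5) no
#' prior-malignancy diagnosis in the look-back year; (6) at least one line
#' of therapy. A filter log records the patient count before, excluded at,
#' and after each criterion.
#'
#' @param population an `mm_population`.
#' @param lines optional precomputed [build_lots()] table; computed with
#'   `lot_rules` if omitted.
#' @param rules a [cohort_rules()] object.
#' @param lot_rules a [lot_rules()] object, used when `lines` is NULL.
#' @return a tibble of cohort members (`patient_id`,
#'   `index_diagnosis_date`, `age_at_diagnosis`, `age_category`, `sex`,
#'   `race`, `transplant_status`, `death_date`, `followup_end`,
#'   `first_lot_start`, `followup_months_from_first_lot`, `n_lines`, and
#'   per-criterion `flag_*` columns) with the filter log attached as the
#'   `filter_log` attribute (see [filter_log()]).
#' @export
build_cohort <- function(population, lines = NULL, rules = cohort_rules(),
                         lot_rules = mmlot::lot_rules()) {
  for (nm in names(population_table_specs())) {
    if (is.null(population[[nm]])) {
      rlang::abort(sprintf("population is missing required table `%s`", nm),
                   class = "mmlot_missing_input")
    }
  }
  fu <- followup_ends(population, rules)
  if (is.null(lines)) {
    lines <- build_lots(population, rules = lot_rules,
                        followups = dplyr::filter(fu, !is.na(.data$followup_end)))
  }
  pts <- population$patients
  prior_mal <- population$diagnoses |>
    dplyr::filter(.data$code %in% rules$prior_malignancy_codes) |>
    dplyr::mutate(date = as_date_safe(.data$date))
  line_counts <- dplyr::summarise(lines, n_lines = dplyr::n(),
                                  first_lot_start = min_date(.data$start),
                                  .by = "patient_id")
  asct <- population$procedures |>
    dplyr::filter(.data$kind == "ASCT") |>
    dplyr::summarise(asct_date = min_date(as_date_safe(.data$date)),
                     .by = "patient_id")

  cand <- fu |>
    dplyr::left_join(dplyr::select(pts, "patient_id", "birth_year", "sex",
                                   "race"),
                     by = "patient_id") |>
    dplyr::left_join(line_counts, by = "patient_id") |>
    dplyr::left_join(asct, by = "patient_id") |>
    dplyr::left_join(
      prior_mal |>
        dplyr::inner_join(fu[, c("patient_id", "index_date")],
                          by = "patient_id") |>
        dplyr::filter(.data$date >= .data$index_date - rules$lookback_days,
                      .data$date <= .data$index_date - 1) |>
        dplyr::distinct(.data$patient_id) |>
        dplyr::mutate(has_prior_mal = TRUE),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      flag_demographics = .data$patient_id %in% pts$patient_id &
        !is.na(.data$birth_year),
      flag_index_date = .data$index_date >= rules$index_floor_date,
      flag_known_sex = !is.na(.data$sex) & .data$sex %in% c("male", "female"),
      flag_coverage_at_index = .data$eligible_at_index,
      flag_lookback = .data$lookback_ok,
      flag_no_prior_malignancy = is.na(.data$has_prior_mal),
      flag_received_lot = !is.na(.data$n_lines) & .data$n_lines >= 1
    )

  steps <- c(
    demographics_on_file = "flag_demographics",
    index_on_or_after_floor = "flag_index_date",
    known_sex = "flag_known_sex",
    coverage_at_index = "flag_coverage_at_index",
    continuous_lookback = "flag_lookback",
    no_prior_malignancy = "flag_no_prior_malignancy",
    received_lot = "flag_received_lot"
  )
  log <- vector("list", length(steps))
  keep <- cand
  for (i in seq_along(steps)) {
    n_before <- nrow(keep)
    pass <- keep[[steps[i]]]
    keep <- keep[pass, ]
    log[[i]] <- tibble::tibble(
      criterion = names(steps)[i], n_before = n_before,
      n_excluded = n_before - nrow(keep), n_after = nrow(keep)
    )
  }
  flog <- dplyr::bind_rows(log)

  members <- keep |>
    dplyr::mutate(
      age_at_diagnosis = as.integer(format(.data$index_date, "%Y")) -
        .data$birth_year,
      age_category = cut_age(.data$age_at_diagnosis),
      transplant_status = dplyr::if_else(
        !is.na(.data$asct_date) & .data$asct_date >= .data$index_date &
          .data$asct_date <= .data$followup_end,
        "transplant", "non_transplant"),
      followup_months_from_first_lot =
        followup_months(.data$first_lot_start, .data$followup_end)
    ) |>
    dplyr::select("patient_id", index_diagnosis_date = "index_date",
                  "age_at_diagnosis", "age_category", "sex", "race",
                  "transplant_status", "death_date", "followup_end",
                  "first_lot_start", "followup_months_from_first_lot",
                  "n_lines", dplyr::starts_with("flag_"))
  attr(members, "filter_log") <- flog
  class(members) <- c("mm_cohort", class(members))
  members
}

#' Retrieve the filter log of a cohort
#'
#' @param cohort output of [build_cohort()].
#' @return tibble with columns `criterion`, `n_before`, `n_excluded`,
#'   `n_after`; `n_after` of each step equals `n_before` of the next.
#' @export
filter_log <- function(cohort) {
  attr(cohort, "filter_log")
}
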