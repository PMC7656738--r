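# Configuration for the synthetic claims generator.

# Log-normal line-duration parameters (months) chosen so the per-line mean
# and median match the published attrition-table duration summaries:
# meanlog = log(median), sdlog = sqrt(2 * log(mean / median)).
default_duration_model <- function() {
  tab <- tibble::tribble(
    ~stratum,         ~lot, ~mean_months, ~median_months,
    "non_transplant",  1L,   6.9,          3.6,
    "non_transplant",  2L,   7.5,          4.1,
    "non_transplant",  3L,   6.5,          3.7,
    "non_transplant",  4L,   5.7,          3.4,
    "non_transplant",  5L,   5.5,          3.2,
    "transplant",      1L,   6.3,          4.2,
    "transplant",      2L,   6.1,          2.7,
    "transplant",      3L,   7.4,          3.6,
    "transplant",      4L,   6.6,          3.4,
    "transplant",      5L,   5.6,          3.3
  )
  dplyr::mutate(tab,
    meanlog = log(.data$median_months),
    sdlog = sqrt(2 * log(.data$mean_months / .data$median_months))
  )
}

# Comorbidity prevalences per stratum (probability a patient carries the
# condition; planted as diagnosis events in the 180 days before index).
default_comorbidity_prevalence <- function() {
  tibble::tribble(
    ~condition,                         ~code,               ~non_transplant, ~transplant,
    "cardiac_arrhythmia",               "DX_ARRHYTHMIA",      0.196,           0.106,
    "congestive_heart_failure",         "DX_CHF",             0.135,           0.042,
    "hypertension_complicated",         "DX_HTN_COMP",        0.169,           0.094,
    "hypertension_simple",              "DX_HTN_SIMPLE",      0.530,           0.476,
    "hepatic_disease",                  "DX_HEPATIC",         0.044,           0.055,
    "pulmonary_circulation_disorders",  "DX_PULM_CIRC",       0.047,           0.020,
    "renal_impairment",                 "DX_RENAL",           0.241,           0.170,
    "valvular_disease",                 "DX_VALVULAR",        0.102,           0.057,
    "diabetes",                         "DX_DIABETES",        0.200,           0.120,
    "chronic_pulmonary_disease",        "DX_COPD",            0.150,           0.080
  )
}

default_regimen_mix <- function() {
  list(
    non_transplant = c(Vd = 0.20, Rd = 0.19, VRd = 0.12, `V/alkylator` = 0.10,
                       V = 0.08, R = 0.06, T = 0.03, other = 0.22),
    transplant     = c(Vd = 0.12, Rd = 0.10, VRd = 0.33, `V/alkylator` = 0.29,
                       V = 0.04, R = 0.03, T = 0.01, other = 0.08)
  )
}

#' Synthetic-population configuration
#'
#' Generative parameters for [simulate_population()]. Defaults emulate the
#' study conditions of the source cohorts: index diagnoses on/after
#' 2007-01-01, an ~11% transplant fraction, per-line continuation and death
#' probabilities matching the published attrition table, log-normal line
#' durations matched to published mean/median months per line, regimen
#' mixes resembling published frontline patterns, and comorbidity
#' prevalences resembling the published baseline tables.
#'
#' A patient's journey is drawn line by line: at line `k` the patient
#' continues to line `k + 1` with the stratum's continuation probability,
#' dies with the death probability, and otherwise remains alive in
#' follow-up with no further treatment. Continuation and death must sum to
#' at most 1 at every line.
#'
#' @param n_patients number of patients to generate.
#' @param index_date_range two dates bounding the index MM diagnosis.
#' @param p_transplant probability of the transplant stratum.
#' @param continuation named list (`non_transplant`, `transplant`) of
#'   per-line continuation probabilities; the last element is reused for
#'   lines beyond its length, and `max_lines` caps journey length.
#' @param death named list of per-line death probabilities (same shape).
#' @param duration_model tibble (`stratum`, `lot`, `meanlog`, `sdlog`) of
#'   log-normal duration parameters in months; the `lot = 5` row is reused
#'   for later lines.
#' @param gap_model between-line treatment-free gap: `min_days` (kept above
#'   the 60-day discontinuation rule so planted lines are recoverable) plus
#'   an exponential tail with mean `mean_extra_days`.
#' @param regimen_mix named list of per-stratum categorical distributions
#'   over regimen categories (must each sum to 1).
#' @param comorbidity_prevalence tibble (`condition`, `code`,
#'   `non_transplant`, `transplant`) of per-stratum prevalences.
#' @param coverage_censor_rate per-year hazard of eligibility loss applied
#'   on top of the journey draws; 0 (default) disables extra truncation —
#'   loss to follow-up is already absorbed in the non-continuation mass.
#' @param p_frontline_induction probability that a transplant patient's
#'   ASCT follows an observed frontline induction line; the remainder
#'   receive ASCT before any observed treatment.
#' @param p_consolidation probability (among frontline-induction patients)
#'   of a consolidation segment: same-regimen treatment resuming within 4
#'   months of ASCT and persisting at least a month after it.
#' @param p_violation fraction of patients given protocol-violating claim
#'   streams (a deliberate >= 60-day intra-line gap) to exercise the LOT
#'   engine; 0 by default so planted journeys are exactly recoverable.
#' @param p_emr fraction of patients drawn from an EMR-like source whose
#'   follow-up ends at last observed activity rather than at eligibility
#'   end.
#' @param prior_malignancy_rate fraction with a non-MM malignancy code in
#'   the look-back year (excluded by the cohort filter); 0 by default.
#' @param sex_male,age_model,race_mix demographic models per stratum.
#' @param treatment_delay_days range of days from index diagnosis to first
#'   treatment.
#' @param asct_delay_days range of days from induction end to ASCT.
#' @param death_window_days death occurs within this many days after the
#'   last line ends.
#' @param coverage_tail_days range of coverage days retained after the last
#'   journey event for patients alive in follow-up.
#' @param lookback_extra_days range of additional coverage days before the
#'   mandatory 365-day look-back.
#' @param max_lines hard cap on journey length.
#' @param max_asct_per_patient cap on ASCT events (default 1).
#' @param seed integer seed; identical seed and config yield byte-identical
#'   tables.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 1000,
                       index_date_range = c("2007-01-01", "2016-12-31"),
                       p_transplant = 2763 / 24825,
                       continuation = list(
                         non_transplant = c(0.431, 0.545, 0.573, 0.574, 0.580),
                         transplant     = c(0.790, 0.692, 0.631, 0.648, 0.629)
                       ),
                       death = list(
                         non_transplant = c(0.129, 0.122, 0.123, 0.123, 0.123),
                         transplant     = c(0.013, 0.027, 0.042, 0.063, 0.079)
                       ),
                       duration_model = default_duration_model(),
                       gap_model = list(min_days = 61, mean_extra_days = 30),
                       regimen_mix = default_regimen_mix(),
                       comorbidity_prevalence = default_comorbidity_prevalence(),
                       coverage_censor_rate = 0,
                       p_frontline_induction = 0.609,
                       p_consolidation = 0.111,
                       p_violation = 0,
                       p_emr = 0,
                       prior_malignancy_rate = 0,
                       sex_male = c(non_transplant = 0.503, transplant = 0.563),
                       age_model = list(
                         non_transplant = c(mean = 72, sd = 10),
                         transplant     = c(mean = 64, sd = 8)
                       ),
                       race_mix = c(white = 0.55, black = 0.12, asian = 0.02,
                                    hispanic = 0.02, other_unknown = 0.29),
                       treatment_delay_days = c(0, 60),
                       asct_delay_days = c(14, 60),
                       death_window_days = 90,
                       coverage_tail_days = c(90, 720),
                       lookback_extra_days = c(0, 720),
                       max_lines = 8,
                       max_asct_per_patient = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      is.na(cfg$n_patients) || cfg$n_patients < 0) {
    config_error("n_patients", "must be a single non-negative count")
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  rng <- as_date_safe(cfg$index_date_range)
  if (length(rng) != 2 || anyNA(rng) || rng[1] > rng[2]) {
    config_error("index_date_range", "must be an ordered pair of dates")
  }
  cfg$index_date_range <- rng
  for (f in c("p_transplant", "coverage_censor_rate", "p_frontline_induction",
              "p_consolidation", "p_violation", "p_emr",
              "prior_malignancy_rate")) {
    assert_prob(cfg[[f]], f)
  }
  assert_prob(cfg$sex_male, "sex_male")
  assert_simplex(cfg$race_mix, "race_mix")
  for (s in c("non_transplant", "transplant")) {
    pc <- cfg$continuation[[s]]
    pd <- cfg$death[[s]]
    assert_prob(pc, paste0("continuation$", s))
    assert_prob(pd, paste0("death$", s))
    if (length(pc) != length(pd)) {
      config_error(paste0("death$", s),
                   "must have the same length as the continuation vector")
    }
    if (any(pc + pd > 1 + 1e-12)) {
      config_error(paste0("continuation$", s),
                   "continuation + death must be <= 1 at every line")
    }
    assert_simplex(cfg$regimen_mix[[s]], paste0("regimen_mix$", s))
    unknown <- setdiff(names(cfg$regimen_mix[[s]]),
                       names(regimen_category_agents()))
    if (length(unknown) > 0) {
      config_error(paste0("regimen_mix$", s),
                   paste("unknown regimen categories:",
                         paste(unknown, collapse = ", ")))
    }
  }
  need <- c("stratum", "lot", "meanlog", "sdlog")
  if (!all(need %in% names(cfg$duration_model))) {
    config_error("duration_model",
                 paste("must contain columns", paste(need, collapse = ", ")))
  }
  assert_prob(cfg$comorbidity_prevalence$non_transplant,
              "comorbidity_prevalence$non_transplant")
  assert_prob(cfg$comorbidity_prevalence$transplant,
              "comorbidity_prevalence$transplant")
  if (cfg$gap_model$min_days < 0 || cfg$gap_model$mean_extra_days < 0) {
    config_error("gap_model", "day counts must be >= 0")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    config_error("seed", "must be a single integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  index window:", format(x$index_date_range[1]), "to",
      format(x$index_date_range[2]), "\n")
  cat("  p_transplant:", signif(x$p_transplant, 4), "\n")
  cat("  continuation (non-transplant):",
      paste(x$continuation$non_transplant, collapse = ", "), "\n")
  cat("  continuation (transplant):    ",
      paste(x$continuation$transplant, collapse = ", "), "\n")
  invisible(x)
}
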