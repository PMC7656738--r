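# Per-line attrition/disposition table and duration summaries.

#' Classify disposition at a given line
#'
#' A patient who reached line `k` is classified `subsequent_treatment` if a
#' line `k + 1` exists; otherwise `death` if the death date lies within
#' follow-up; otherwise `no_subsequent_treatment`. A patient who starts
#' line `k + 1` and later dies counts as `subsequent_treatment` at line `k`
#' (a transition, not a terminal state), so the three outcomes partition
#' each line's cohort.
#'
#' @param cohort a [build_cohort()] tibble (needs `n_lines`, `death_date`,
#'   `followup_end`).
#' @param k line number.
#' @return tibble `patient_id`, `lot_number`, `outcome` for members who
#'   reached line `k`.
#' @export
classify_disposition <- function(cohort, k) {
  cohort |>
    dplyr::filter(.data$n_lines >= k) |>
    dplyr::mutate(
      lot_number = as.integer(k),
      outcome = dplyr::case_when(
        .data$n_lines >= k + 1 ~ "subsequent_treatment",
        !is.na(.data$death_date) &
          .data$death_date <= .data$followup_end ~ "death",
        TRUE ~ "no_subsequent_treatment"
      )
    ) |>
    dplyr::select("patient_id", "lot_number", "outcome")
}

#' Mean, SD and median of line durations
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator; NA for a
#' single value) and median (midpoint convention for even n).
#'
#' @param durations numeric vector of durations in months.
#' @return one-row tibble `n`, `duration_mean`, `duration_sd`,
#'   `duration_median`; zero rows for empty input.
#' @export
duration_summary <- function(durations) {
  if (length(durations) == 0) {
    return(tibble::tibble(n = integer(), duration_mean = numeric(),
                          duration_sd = numeric(),
                          duration_median = numeric()))
  }
  tibble::tibble(
    n = length(durations),
    duration_mean = mean(durations),
    duration_sd = if (length(durations) > 1) stats::sd(durations) else NA_real_,
    duration_median = stats::median(durations)
  )
}

#' Attrition percentages from a vector of per-line frequencies
#'
#' `attrition_pct` at line k is `100 * (1 - n_k / n_(k-1))` -- the fraction
#' of the previous line's cohort with no record of line k.
#'
#' @param counts per-line cohort sizes, line 1 first.
#' @return tibble `lot_number`, `n`, `attrition_pct` (NA for line 1).
#' @export
attrition_from_counts <- function(counts) {
  k <- seq_along(counts)
  tibble::tibble(
    lot_number = k,
    n = counts,
    attrition_pct = c(NA_real_, 100 * (1 - counts[-1] / counts[-length(counts)]))
  )
}

#' Attrition/disposition table by line and transplant stratum
#'
#' For lines 1 to `max_lot` within each stratum: cohort size, attrition
#' percent relative to the previous line, disposition counts and percents
#' (deaths / no subsequent treatment in follow-up / subsequent treatment,
#' which partition the line's cohort), and the duration mean, SD and
#' median in months. Values are unrounded; rounding is applied only by
#' [format_attrition_table()].
#'
#' @param cohort a [build_cohort()] tibble.
#' @param lines a [build_lots()] (or [segment_lines()]) tibble.
#' @param max_lot deepest line reported (default 5).
#' @return tibble of class `mm_attrition` with one row per stratum and
#'   line.
#' @export
attrition_table <- function(cohort, lines, max_lot = 5) {
  lines <- dplyr::inner_join(
    lines,
    dplyr::select(cohort, "patient_id",
                  stratum = "transplant_status"),
    by = "patient_id"
  )
  strata <- c("non_transplant", "transplant")
  rows <- list()
  for (s in strata) {
    mem <- dplyr::filter(cohort, .data$transplant_status == s)
    for (k in seq_len(max_lot)) {
      at_k <- dplyr::filter(mem, .data$n_lines >= k)
      n_k <- nrow(at_k)
      disp <- classify_disposition(mem, k)
      n_prev <- nrow(dplyr::filter(mem, .data$n_lines >= k - 1))
      dur <- lines |>
        dplyr::filter(.data$stratum == s, .data$lot_number == k) |>
        dplyr::pull("duration_months")
      ds <- duration_summary(dur)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stratum = s,
        lot_number = as.integer(k),
        n = n_k,
        attrition_pct = if (k == 1 || n_prev == 0) NA_real_ else
          100 * (1 - n_k / n_prev),
        deaths_n = sum(disp$outcome == "death"),
        no_subsequent_n = sum(disp$outcome == "no_subsequent_treatment"),
        subsequent_n = sum(disp$outcome == "subsequent_treatment"),
        deaths_pct = pct(sum(disp$outcome == "death"), n_k),
        no_subsequent_pct = pct(sum(disp$outcome == "no_subsequent_treatment"),
                                n_k),
        subsequent_pct = pct(sum(disp$outcome == "subsequent_treatment"), n_k),
        duration_mean = if (nrow(ds)) ds$duration_mean else NA_real_,
        duration_sd = if (nrow(ds)) ds$duration_sd else NA_real_,
        duration_median = if (nrow(ds)) ds$duration_median else NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mm_attrition", class(out))
  out
}

#' Render an attrition table for publication
#'
#' One-decimal rounding (half away from zero, the convention used in
#' printed tables), `n (%)` disposition columns and a
#' `mean +/- SD (median)` duration column. Counts inside the suppression
#' range of `policy` are masked along with their percentages.
#'
#' @param att an [attrition_table()] result.
#' @param policy optional [suppression_policy()]; `NULL` disables masking.
#' @return tibble of presentation strings.
#' @export
format_attrition_table <- function(att, policy = NULL) {
  mask <- function(n) {
    !is.null(policy) & n >= policy$suppress_range[1] &
      n <= policy$suppress_range[2]
  }
  fmt_np <- function(n, p) {
    ifelse(mask(n), policy$replacement_token,
           sprintf("%d (%.1f)", n, round_half_up(p, 1)))
  }
  att |>
    dplyr::mutate(
      frequency = .data$n,
      attrition = ifelse(is.na(.data$attrition_pct), "-",
                         sprintf("%.1f", round_half_up(.data$attrition_pct, 1))),
      deaths = fmt_np(.data$deaths_n, .data$deaths_pct),
      no_subsequent = fmt_np(.data$no_subsequent_n, .data$no_subsequent_pct),
      subsequent = fmt_np(.data$subsequent_n, .data$subsequent_pct),
      duration = ifelse(
        is.na(.data$duration_mean), "-",
        sprintf("%.1f ± %s (%s)",
                round_half_up(.data$duration_mean, 1),
                ifelse(is.na(.data$duration_sd), "-",
                       sprintf("%.1f", round_half_up(.data$duration_sd, 1))),
                ifelse(is.na(.data$duration_median), "-",
                       sprintf("%.1f", round_half_up(.data$duration_median, 1))))
      )
    ) |>
    dplyr::select("stratum", "lot_number", "frequency", "attrition",
                  "deaths", "no_subsequent", "subsequent", "duration")
}
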