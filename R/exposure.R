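# Exposure-interval construction: claims + days supply -> per-agent
# continuous exposure spans.

#' Line-of-therapy segmentation rules
#'
#' The configurable rule set driving [build_exposure_intervals()],
#' [segment_lines()] and [attach_transplant_phases()].
#'
#' @param discontinuation_gap_days a regimen agent discontinued for at
#'   least this many days ends the line (default 60).
#' @param regimen_formation_window_days agents whose first exposure begins
#'   within this many days of the line start join the line's regimen
#'   (default 60; set to 0 for the literal new-agent rule, under which any
#'   staggered combination start opens a new line).
#' @param line_end_mode `"any_agent_discontinued"` (default: the first
#'   regimen agent to lapse ends the line) or `"all_agents_discontinued"`
#'   (the line survives partial de-escalation and ends only when every
#'   regimen agent has lapsed).
#' @param steroid_agents agent codes exempted by the steroid rule.
#' @param steroids_trigger_new_line if `FALSE` (default), a steroid starting
#'   after the formation window neither ends the current line nor starts a
#'   new one; steroids starting within the window still count in the
#'   regimen agent set.
#' @param consolidation_window_days post-ASCT treatment must begin within
#'   this many days of ASCT to qualify as consolidation (default 122, i.e.
#'   4 months at 30.5 days/month).
#' @param consolidation_min_duration_days consolidation must persist at
#'   least this many days after ASCT (default 30).
#' @param administration_default_supply_days exposure days attached to a
#'   parenteral administration claim that carries no supply (default 7).
#' @param merge_gap_days covered spans of one agent separated by at most
#'   this many uncovered days merge into one exposure interval (default 0:
#'   only overlapping or abutting spans merge).
#' @return a validated `lot_rules` list.
#' @export
lot_rules <- function(discontinuation_gap_days = 60,
                      regimen_formation_window_days = 60,
                      line_end_mode = c("any_agent_discontinued",
                                        "all_agents_discontinued"),
                      steroid_agents = mmlot::steroid_agents(),
                      steroids_trigger_new_line = FALSE,
                      consolidation_window_days = 122,
                      consolidation_min_duration_days = 30,
                      administration_default_supply_days = 7,
                      merge_gap_days = 0) {
  rules <- list(
    discontinuation_gap_days = discontinuation_gap_days,
    regimen_formation_window_days = regimen_formation_window_days,
    line_end_mode = match.arg(line_end_mode),
    steroid_agents = steroid_agents,
    steroids_trigger_new_line = isTRUE(steroids_trigger_new_line),
    consolidation_window_days = consolidation_window_days,
    consolidation_min_duration_days = consolidation_min_duration_days,
    administration_default_supply_days = administration_default_supply_days,
    merge_gap_days = merge_gap_days
  )
  days <- c("discontinuation_gap_days", "regimen_formation_window_days",
            "consolidation_window_days", "consolidation_min_duration_days",
            "administration_default_supply_days", "merge_gap_days")
  for (f in days) {
    v <- rules[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      config_error(f, "must be a single day count >= 0")
    }
  }
  structure(rules, class = "lot_rules")
}

# Generic span union used for both drug exposure and coverage intervals:
# within each group, spans separated by <= gap uncovered days merge.
merge_spans <- function(df, group_cols, gap = 0) {
  df |>
    dplyr::mutate(.s = as.numeric(.data$start), .e = as.numeric(.data$end)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(group_cols)), .data$.s, .data$.e) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(
      .prev_end = dplyr::lag(cummax(.data$.e)),
      .new = is.na(.data$.prev_end) | (.data$.s - .data$.prev_end - 1) > gap,
      .grp = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$.grp, .add = TRUE) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select(-".grp")
}

#' Build per-agent exposure intervals from drug claims
#'
#' Each claim covers `[date, date + days_supply - 1]`; a parenteral claim
#' with missing supply covers the configured administration cycle.
#' Overlapping or abutting covered spans of the same agent (uncovered gap
#' at most `merge_gap_days`) merge into a single exposure interval, so the
#' resulting intervals per patient and agent are non-overlapping and
#' separated by more than `merge_gap_days` days.
#'
#' Claims naming an agent absent from the dictionary are skipped with a
#' warning; the skip count is attached as the `skipped_unknown_agents`
#' attribute.
#'
#' @param drug_claims tibble with `patient_id`, `date`, `agent`,
#'   `days_supply` (and optionally `route`).
#' @param rules a [lot_rules()] object.
#' @param dict an [agent_dictionary()] tibble.
#' @return tibble of exposure intervals: `patient_id`, `agent`, `start`,
#'   `end` (last covered day).
#' @export
build_exposure_intervals <- function(drug_claims, rules = lot_rules(),
                                     dict = agent_dictionary()) {
  unknown <- !drug_claims$agent %in% dict$agent
  if (any(unknown)) {
    rlang::warn(sprintf("skipped %d claim(s) with unknown agent(s): %s",
                        sum(unknown),
                        paste(unique(drug_claims$agent[unknown]),
                              collapse = ", ")))
    drug_claims <- drug_claims[!unknown, ]
  }
  if (nrow(drug_claims) == 0) {
    out <- tibble::tibble(patient_id = character(), agent = character(),
                          start = as.Date(character()),
                          end = as.Date(character()))
    attr(out, "skipped_unknown_agents") <- sum(unknown)
    return(out)
  }
  supply <- drug_claims$days_supply
  if (!"days_supply" %in% names(drug_claims)) supply <- rep(NA_integer_, nrow(drug_claims))
  supply <- ifelse(is.na(supply),
                   rules$administration_default_supply_days, supply)
  if (any(supply < 1)) rlang::abort("days_supply must be >= 1")
  iv <- drug_claims |>
    dplyr::mutate(date = as_date_safe(.data$date),
                  start = .data$date,
                  end = .data$date + supply - 1) |>
    merge_spans(c("patient_id", "agent"), gap = rules$merge_gap_days)
  attr(iv, "skipped_unknown_agents") <- sum(unknown)
  iv
}
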