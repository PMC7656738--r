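# Line-of-therapy segmentation: gap rule, new-agent rule, steroid
# exemption, and post-ASCT phase annotation with consolidation folding.

#' Treatment-line duration in months
#'
#' Day span divided by 30.4375, with a 1-day floor so that a line starting
#' and ending on the same day has a 1-day (0.03-month) duration. Rounding
#' happens only at presentation.
#'
#' @param start,end line start and end dates.
#' @return numeric months.
#' @export
lot_duration_months <- function(start, end) {
  pmax(1, as.numeric(as_date_safe(end) - as_date_safe(start))) / DAYS_PER_MONTH
}

# Merge one agent's claim covers (numeric day scale, already sorted by d)
# into maximal intervals with uncovered gaps <= merge_gap.
merge_claim_covers <- function(d, e, merge_gap) {
  run_end <- cummax(e)
  new_iv <- c(TRUE, d[-1] - run_end[-length(run_end)] - 1 > merge_gap)
  grp <- cumsum(new_iv)
  list(s = d[new_iv], e = as.numeric(tapply(e, grp, max)))
}

# Segment one patient's claims (numeric day scale).
# cl: data.frame(agent, d, e) sorted by d, where [d, e] is the span a
# single claim covers; fu/death numeric (death may be Inf).
segment_patient_days <- function(cl, fu_end, death, rules) {
  hard_end <- min(fu_end, death)
  cl <- cl[cl$d <= hard_end, , drop = FALSE]
  if (nrow(cl) == 0) return(NULL)
  cl$e <- pmin(cl$e, hard_end)
  W <- rules$regimen_formation_window_days
  G <- rules$discontinuation_gap_days
  exempt <- if (rules$steroids_trigger_new_line) character() else rules$steroid_agents

  starts <- ends <- numeric(0)
  regimens <- list()
  reasons <- character(0)
  prev_end <- -Inf
  repeat {
    keep <- cl$d > prev_end
    if (!any(keep)) break
    rem <- cl[keep, , drop = FALSE]
    s <- min(rem$d)
    # every remaining claim is > prev_end and >= s, so regimen membership
    # is "has a claim within the formation window of the line start"
    regimen <- unique(rem$agent[rem$d <= s + W])

    trig <- rem$d[!(rem$agent %in% regimen) & !(rem$agent %in% exempt)]
    new_end <- if (length(trig)) min(trig) - 1 else Inf

    agent_lapse_end <- vapply(regimen, function(a) {
      ia <- rem[rem$agent == a, , drop = FALSE]
      iv <- merge_claim_covers(ia$d, ia$e, rules$merge_gap_days)
      k <- length(iv$s)
      for (j in seq_len(k)) {
        lapse <- if (j < k) iv$s[j + 1] - iv$e[j] - 1 else hard_end - iv$e[j]
        if (lapse >= G) return(iv$e[j])
      }
      Inf
    }, numeric(1))
    gap_end <- if (rules$line_end_mode == "any_agent_discontinued") {
      min(agent_lapse_end)
    } else {
      # all-agents mode: the line ends only once every regimen agent has
      # lapsed; the end day is the latest last-covered day among them
      if (all(is.finite(agent_lapse_end))) max(agent_lapse_end) else Inf
    }

    nat_end <- max(rem$e)
    line_end <- min(new_end, gap_end, nat_end)
    reason <- if (is.finite(new_end) && new_end <= min(gap_end, nat_end)) {
      "new_agent"
    } else if (is.finite(gap_end) && gap_end <= nat_end) {
      "gap"
    } else if (is.finite(death) && nat_end >= death) {
      "death"
    } else {
      "followup_end"
    }

    starts <- c(starts, s)
    ends <- c(ends, line_end)
    regimens <- c(regimens, list(sort(regimen)))
    reasons <- c(reasons, reason)
    prev_end <- line_end
  }
  list(start = starts, end = ends, regimen = regimens, reason = reasons)
}

#' Segment drug claims into lines of therapy
#'
#' A line starts at the earliest claim (administration) date; agents with a
#' claim within the regimen-formation window of the line start join the
#' line's regimen. The line ends at the earliest of: (a) the day before an
#' agent outside the regimen (and not exempted by the steroid rule) first
#' starts after the formation window (`end_reason = "new_agent"`); (b) the
#' last covered day of the first regimen agent whose exposure -- merged
#' claim coverage per [build_exposure_intervals()] -- lapses for at least
#' the discontinuation gap while follow-up continues
#' (`end_reason = "gap"`); (c) follow-up end or death, with the end date
#' clipped accordingly. Ties between a gap and a new-agent event on the
#' same end day resolve to `new_agent`. The next line starts at the next
#' claim after the line end, so an agent whose coverage straddles a line
#' boundary re-enters the next line through its next administration.
#'
#' @param drug_claims tibble with `patient_id`, `date`, `agent`,
#'   `days_supply`; a missing supply covers the configured administration
#'   cycle.
#' @param followups tibble with `patient_id`, `followup_end`, and
#'   optionally `death_date` (from [followup_ends()]); patients without a
#'   row are dropped with a warning.
#' @param rules a [lot_rules()] object.
#' @param dict an [agent_dictionary()] tibble (unknown agents are skipped
#'   with a warning).
#' @return tibble of lines: `patient_id`, `lot_number`, `start`, `end`,
#'   `regimen_agents` (list-column), `agents` (semicolon-joined, sorted),
#'   `duration_months`, `end_reason`.
#' @export
segment_lines <- function(drug_claims, followups, rules = lot_rules(),
                          dict = agent_dictionary()) {
  empty <- tibble::tibble(
    patient_id = character(), lot_number = integer(),
    start = as.Date(character()), end = as.Date(character()),
    regimen_agents = list(), agents = character(),
    duration_months = numeric(), end_reason = character()
  )
  unknown <- !drug_claims$agent %in% dict$agent
  if (any(unknown)) {
    rlang::warn(sprintf("skipped %d claim(s) with unknown agent(s)",
                        sum(unknown)))
    drug_claims <- drug_claims[!unknown, ]
  }
  if (nrow(drug_claims) == 0) return(empty)
  if (!"death_date" %in% names(followups)) followups$death_date <- as.Date(NA)
  miss <- setdiff(unique(drug_claims$patient_id), followups$patient_id)
  if (length(miss) > 0) {
    rlang::warn(sprintf(
      "%d patient(s) with exposures but no follow-up window were dropped",
      length(miss)))
    drug_claims <- drug_claims[!drug_claims$patient_id %in% miss, ]
    if (nrow(drug_claims) == 0) return(empty)
  }

  supply <- drug_claims$days_supply
  supply <- ifelse(is.na(supply),
                   rules$administration_default_supply_days, supply)
  if (any(supply < 1)) rlang::abort("days_supply must be >= 1")
  iv <- drug_claims |>
    dplyr::mutate(d = as.numeric(as_date_safe(.data$date)),
                  e = .data$d + supply - 1) |>
    dplyr::arrange(.data$patient_id, .data$d, .data$agent)
  fu <- followups |>
    dplyr::mutate(fu = as.numeric(as_date_safe(.data$followup_end)),
                  dd = ifelse(is.na(.data$death_date), Inf,
                              as.numeric(as_date_safe(.data$death_date))))
  fu_map <- stats::setNames(fu$fu, fu$patient_id)
  dd_map <- stats::setNames(fu$dd, fu$patient_id)

  by_patient <- split(as.data.frame(iv[, c("agent", "d", "e")]),
                      iv$patient_id)
  pids <- names(by_patient)
  res <- lapply(pids, function(pid) {
    segment_patient_days(by_patient[[pid]], fu_map[[pid]],
                         dd_map[[pid]], rules)
  })
  keep <- !vapply(res, is.null, logical(1))
  res <- res[keep]
  if (length(res) == 0) return(empty)
  n_per <- vapply(res, function(x) length(x$start), integer(1))
  out <- tibble::tibble(
    patient_id = rep(pids[keep], n_per),
    lot_number = sequence(n_per),
    start = as.Date(unlist(lapply(res, `[[`, "start")),
                    origin = "1970-01-01"),
    end = as.Date(unlist(lapply(res, `[[`, "end")), origin = "1970-01-01"),
    regimen_agents = do.call(c, lapply(res, `[[`, "regimen")),
    end_reason = unlist(lapply(res, `[[`, "reason"))
  )
  out |>
    dplyr::mutate(
      agents = vapply(.data$regimen_agents, paste, character(1),
                      collapse = ";"),
      duration_months = lot_duration_months(.data$start, .data$end)
    ) |>
    dplyr::relocate("agents", "duration_months", .after = "regimen_agents")
}

#' Annotate transplant phases and fold consolidation into the first line
#'
#' For each patient with an ASCT event, the line active at (or most
#' recently before) the first ASCT is labelled induction. A post-ASCT
#' treatment segment is folded into that line as consolidation -- rather
#' than opening a new line -- iff it starts within the consolidation window
#' of ASCT, persists at least the minimum consolidation duration after
#' ASCT, and its agent set equals or is a superset of the induction
#' regimen. An induction line whose own exposures continue past ASCT for at
#' least the minimum duration likewise carries `consolidation_present`.
#' Post-ASCT treatment failing any condition starts the next line; a
#' patient whose last treatment-related event is the ASCT itself remains
#' single-line.
#'
#' @param lines output of [segment_lines()].
#' @param procedures tibble of procedure events (`patient_id`, `date`,
#'   `kind`); only `kind == "ASCT"` rows are used, first ASCT per patient.
#' @param rules a [lot_rules()] object.
#' @return `lines` with logical columns `induction` and
#'   `consolidation_present` added, consolidation segments folded, and
#'   `lot_number` renumbered.
#' @export
attach_transplant_phases <- function(lines, procedures, rules = lot_rules()) {
  lines$induction <- FALSE
  lines$consolidation_present <- FALSE
  asct <- procedures |>
    dplyr::filter(.data$kind == "ASCT") |>
    dplyr::mutate(date = as_date_safe(.data$date)) |>
    dplyr::summarise(asct_date = min_date(.data$date), .by = "patient_id")
  asct <- asct[asct$patient_id %in% lines$patient_id, ]
  if (nrow(asct) == 0) return(lines)

  win <- rules$consolidation_window_days
  mindur <- rules$consolidation_min_duration_days
  n_pre_exposure <- 0L
  pieces <- split(lines, lines$patient_id)
  for (r in seq_len(nrow(asct))) {
    pid <- asct$patient_id[r]
    a <- asct$asct_date[r]
    ls <- pieces[[pid]]
    ls <- ls[order(ls$lot_number), ]
    cand <- which(ls$start <= a)
    if (length(cand) == 0) {
      n_pre_exposure <- n_pre_exposure + 1L
      next
    }
    i <- max(cand)
    ls$induction[i] <- TRUE
    if (ls$end[i] >= a + mindur) {
      # the induction line itself continues past ASCT
      ls$consolidation_present[i] <- TRUE
    } else if (i < nrow(ls)) {
      j <- i + 1L
      if (ls$start[j] <= a + win && ls$end[j] >= a + mindur &&
          all(ls$regimen_agents[[i]] %in% ls$regimen_agents[[j]])) {
        ls$end[i] <- ls$end[j]
        ls$end_reason[i] <- ls$end_reason[j]
        ls$consolidation_present[i] <- TRUE
        ls <- ls[-j, ]
        ls$lot_number <- seq_len(nrow(ls))
      }
    }
    pieces[[pid]] <- ls
  }
  if (n_pre_exposure > 0) {
    rlang::warn(sprintf(
      "ASCT precedes any drug exposure for %d patient(s); ignored for phase labelling",
      n_pre_exposure))
  }
  out <- dplyr::bind_rows(pieces)
  out$duration_months <- lot_duration_months(out$start, out$end)
  dplyr::arrange(out, .data$patient_id, .data$lot_number)
}

#' Build annotated lines of therapy for a whole population
#'
#' Convenience wrapper chaining [followup_ends()], [segment_lines()],
#' [attach_transplant_phases()] and [classify_regimen()].
#'
#' @param population an `mm_population`.
#' @param rules a [lot_rules()] object.
#' @param followups optional precomputed [followup_ends()] table.
#' @param regimen_rules rule list for [classify_regimen()].
#' @return annotated lines tibble with a `regimen_category` column.
#' @export
build_lots <- function(population, rules = lot_rules(), followups = NULL,
                       regimen_rules = mmlot::regimen_rules()) {
  followups <- followups %||% followup_ends(population)
  lines <- segment_lines(population$drug_claims, followups, rules)
  lines <- attach_transplant_phases(lines, population$procedures, rules)
  if (nrow(lines) == 0) {
    lines$regimen_category <- character()
    return(lines)
  }
  lines$regimen_category <-
    classify_regimen(lines$regimen_agents, rules = regimen_rules)$label
  lines
}
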