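# Seeded synthetic claims generator. Journeys are drawn line by line from
# the configured continuation/death probabilities; claims are then emitted
# at refill cadence so that the LOT engine can recover the planted lines
# exactly when no protocol violations are requested.

run_seeded <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        suppressWarnings(rm(".Random.seed", envir = globalenv()))
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

runif_range <- function(n, range) {
  round(stats::runif(n, range[1], range[2]))
}

empty_population <- function(config = NULL) {
  pop <- list(
    patients = tibble::tibble(
      patient_id = character(), birth_year = integer(),
      sex = character(), race = character(),
      death_date = as.Date(character()), source_kind = character()
    ),
    diagnoses = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      code = character()
    ),
    drug_claims = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      agent = character(), days_supply = integer(), route = character()
    ),
    procedures = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      kind = character()
    ),
    coverage = tibble::tibble(
      patient_id = character(), start = as.Date(character()),
      end = as.Date(character()), kind = character()
    )
  )
  structure(pop, class = c("mm_population", "list"), config = config)
}

prob_at_line <- function(vecs, stratum, k) {
  vapply(stratum, function(s) {
    v <- vecs[[s]]
    v[min(k, length(v))]
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a synthetic claims population
#'
#' Draws `n_patients` patient journeys under the configured per-line
#' continuation and death probabilities, realizes each treatment line as
#' drug claims at refill cadence (oral agents every 30 days with a 30-day
#' supply; parenteral agents as weekly administrations), plants comorbidity
#' diagnosis events uniformly in the 180-day pre-index window, emits ASCT
#' procedure events for the transplant stratum (after a frontline induction
#' line for most, before observed treatment for the remainder), optional
#' same-regimen consolidation segments after ASCT, death dates shortly
#' after the final line for patients drawn to die, and medical plus
#' pharmacy coverage intervals spanning the look-back year through the end
#' of follow-up.
#'
#' Between-line treatment-free gaps are kept above the 60-day
#' discontinuation threshold so the planted journey is recoverable by the
#' LOT engine; setting `p_violation > 0` deliberately injects rule-breaking
#' claim streams (intra-line gaps of more than 60 days and late add-on
#' agents) to exercise the engine.
#'
#' Identical seed and config produce byte-identical tables.
#'
#' @param config a [sim_config()] object.
#' @return an `mm_population`: a named list of five tibbles (`patients`,
#'   `diagnoses`, `drug_claims`, `procedures`, `coverage`) with the
#'   resolved config attached as an attribute. The attribute
#'   `journey_truth` carries the planted per-patient line count, stratum,
#'   and outcome for oracle-style tests.
#' @export
simulate_population <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  if (config$n_patients == 0) return(empty_population(config))
  run_seeded(config$seed, build_population_impl(config))
}

#' @rdname simulate_population
#' @export
generate_population <- simulate_population

build_population_impl <- function(config) {
  n <- config$n_patients
  dict <- agent_dictionary()
  cat_agents <- regimen_category_agents()

  # --- demographics -------------------------------------------------------
  patient_id <- sprintf("MM%09d", sample.int(999999999L, n))
  stratum <- ifelse(stats::runif(n) < config$p_transplant,
                    "transplant", "non_transplant")
  rng <- config$index_date_range
  index_date <- rng[1] + sample.int(as.integer(rng[2] - rng[1]) + 1L, n,
                                    replace = TRUE) - 1L
  age <- numeric(n)
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    m <- config$age_model[[s]]
    draw <- round(stats::rnorm(length(idx), m[["mean"]], m[["sd"]]))
    while (any(bad <- draw < 20 | draw > 100)) {
      draw[bad] <- round(stats::rnorm(sum(bad), m[["mean"]], m[["sd"]]))
    }
    age[idx] <- draw
  }
  sex <- ifelse(stats::runif(n) < config$sex_male[stratum], "male", "female")
  race <- sample(names(config$race_mix), n, replace = TRUE,
                 prob = config$race_mix)
  source_kind <- ifelse(stats::runif(n) < config$p_emr, "emr", "claims")

  # --- journey draws ------------------------------------------------------
  n_lines <- rep(1L, n)
  died <- rep(FALSE, n)
  active <- rep(TRUE, n)
  for (k in seq_len(config$max_lines - 1L)) {
    idx <- which(active)
    if (length(idx) == 0) break
    u <- stats::runif(length(idx))
    pc <- prob_at_line(config$continuation, stratum[idx], k)
    pd <- prob_at_line(config$death, stratum[idx], k)
    cont <- u < pc
    die <- !cont & u < pc + pd
    n_lines[idx[cont]] <- k + 1L
    died[idx[die]] <- TRUE
    active[] <- FALSE
    active[idx[cont]] <- TRUE
  }

  # --- per-line table -----------------------------------------------------
  pidx <- rep(seq_len(n), n_lines)
  lot <- sequence(n_lines)
  nl <- length(pidx)
  line_stratum <- stratum[pidx]
  category <- character(nl)
  for (s in unique(line_stratum)) {
    rows <- which(line_stratum == s)
    mix <- config$regimen_mix[[s]]
    category[rows] <- sample(names(mix), length(rows), replace = TRUE,
                             prob = mix)
  }
  dm <- config$duration_model
  key <- match(
    paste(line_stratum, pmin(lot, max(dm$lot))),
    paste(dm$stratum, dm$lot)
  )
  months <- stats::rlnorm(nl, dm$meanlog[key], dm$sdlog[key])
  dur_days <- pmax(7, round(months * DAYS_PER_MONTH))

  has_parenteral <- vapply(cat_agents, function(a) {
    any(dict$route[match(a, dict$agent)] == "parenteral")
  }, logical(1))
  has_oral <- vapply(cat_agents, function(a) {
    any(dict$route[match(a, dict$agent)] == "oral")
  }, logical(1))
  par_supply <- dict$default_supply_days[match("bortezomib", dict$agent)]
  realized_len <- pmax(
    ifelse(has_parenteral[category],
           ceiling(dur_days / par_supply) * par_supply, 0),
    ifelse(has_oral[category], ceiling(dur_days / 30) * 30, 0)
  )

  gap_extra <- if (config$gap_model$mean_extra_days > 0) {
    round(stats::rexp(nl, 1 / config$gap_model$mean_extra_days))
  } else {
    rep(0, nl)
  }
  gap <- config$gap_model$min_days + gap_extra

  # --- transplant machinery (drawn before chaining; applied inside it) ----
  is_tx <- stratum == "transplant"
  has_ind <- is_tx & stats::runif(n) < config$p_frontline_induction
  has_cons <- has_ind & stats::runif(n) < config$p_consolidation
  delay1 <- runif_range(n, config$treatment_delay_days)
  # pre-treatment ASCT patients need room for an ASCT strictly before the
  # first claim
  delay1[is_tx & !has_ind] <- delay1[is_tx & !has_ind] + 36L
  asct_delay <- runif_range(n, config$asct_delay_days)
  cons_start_delay <- runif_range(n, c(21, 90))
  cons_dur <- runif_range(n, c(30, 90))

  # --- chain start/end offsets line by line -------------------------------
  start_off <- integer(nl)
  end_off <- integer(nl)
  asct_off <- rep(NA_integer_, n)
  cons_start_off <- rep(NA_integer_, n)
  cons_end_off <- rep(NA_integer_, n)
  cons_category <- rep(NA_character_, n)
  for (k in seq_len(max(lot))) {
    rows <- which(lot == k)
    pats <- pidx[rows]
    if (k == 1) {
      start_off[rows] <- delay1[pats]
    } else {
      prev_end <- end_off[rows - 1L]
      base <- prev_end
      ci <- has_cons[pats] & k == 2
      base[ci] <- pmax(base[ci], cons_end_off[pats[ci]])
      s <- base + gap[rows]
      ai <- has_ind[pats] & k == 2
      s[ai] <- pmax(s[ai], asct_off[pats[ai]] + 123L)
      start_off[rows] <- s
    }
    end_off[rows] <- start_off[rows] + realized_len[rows] - 1L
    if (k == 1) {
      p1 <- pats
      asct_off[p1[has_ind[p1]]] <-
        end_off[rows][has_ind[p1]] + asct_delay[p1[has_ind[p1]]]
      asct_off[p1[is_tx[p1] & !has_ind[p1]]] <-
        pmax(1L, delay1[p1[is_tx[p1] & !has_ind[p1]]] -
               runif_range(sum(is_tx[p1] & !has_ind[p1]), c(5, 30)))
      cc <- p1[has_cons[p1]]
      if (length(cc) > 0) {
        cons_category[cc] <- category[rows][has_cons[p1]]
        cons_start_off[cc] <- asct_off[cc] + cons_start_delay[cc]
        cl <- pmax(
          ifelse(has_parenteral[cons_category[cc]],
                 ceiling(cons_dur[cc] / par_supply) * par_supply, 0),
          ifelse(has_oral[cons_category[cc]],
                 ceiling(cons_dur[cc] / 30) * 30, 0)
        )
        cons_end_off[cc] <- cons_start_off[cc] + as.integer(cl) - 1L
      }
    }
  }

  journey_end <- vapply(split(end_off, pidx), max, numeric(1))
  journey_end <- pmax(journey_end,
                      ifelse(is.na(cons_end_off), -Inf, cons_end_off),
                      ifelse(is.na(asct_off), -Inf, asct_off))
  death_off <- rep(NA_integer_, n)
  death_off[died] <- as.integer(journey_end[died]) +
    sample.int(config$death_window_days, sum(died), replace = TRUE)

  # --- claims -------------------------------------------------------------
  seg <- tibble::tibble(
    pidx = c(pidx, which(has_cons)),
    start = c(start_off, cons_start_off[has_cons]),
    dur = c(dur_days, cons_dur[has_cons]),
    category = c(category, cons_category[has_cons])
  )
  agents_per_cat <- cat_agents[seg$category]
  n_agents <- lengths(agents_per_cat)
  claims <- tibble::tibble(
    pidx = rep(seg$pidx, n_agents),
    start = rep(seg$start, n_agents),
    dur = rep(seg$dur, n_agents),
    agent = unlist(agents_per_cat, use.names = FALSE)
  )
  di <- match(claims$agent, dict$agent)
  claims$days_supply <- dict$default_supply_days[di]
  claims$route <- dict$route[di]
  n_claims <- ceiling(claims$dur / claims$days_supply)
  claims <- claims[rep(seq_len(nrow(claims)), n_claims), ]
  claims$off <- claims$start + (sequence(n_claims) - 1L) * claims$days_supply

  # protocol violations: an intra-line >= 60-day hole (odd violators) or a
  # late add-on agent after the regimen-formation window (even violators)
  viol <- which(stats::runif(n) < config$p_violation)
  if (length(viol) > 0) {
    hole <- viol[seq_along(viol) %% 2L == 1L]
    addon <- setdiff(viol, hole)
    if (length(hole) > 0) {
      h0 <- delay1[hole] + 40L
      keep <- !(claims$pidx %in% hole &
                  claims$off >= h0[match(claims$pidx, hole)] &
                  claims$off <= h0[match(claims$pidx, hole)] + 70L)
      keep[is.na(keep)] <- TRUE
      claims <- claims[keep, ]
    }
    if (length(addon) > 0) {
      extra <- tibble::tibble(
        pidx = addon, start = NA_integer_, dur = NA_integer_,
        agent = "pomalidomide",
        days_supply = 30L, route = "oral",
        off = delay1[addon] + 75L
      )
      claims <- dplyr::bind_rows(claims, extra)
    }
  }

  drug_claims <- tibble::tibble(
    patient_id = patient_id[claims$pidx],
    date = index_date[claims$pidx] + claims$off,
    agent = claims$agent,
    days_supply = as.integer(claims$days_supply),
    route = claims$route
  )

  # --- diagnoses ----------------------------------------------------------
  diagnoses <- tibble::tibble(
    patient_id = patient_id, date = index_date, code = "DX_MM"
  )
  prev <- config$comorbidity_prevalence
  for (i in seq_len(nrow(prev))) {
    p <- ifelse(stratum == "transplant", prev$transplant[i],
                prev$non_transplant[i])
    hit <- which(stats::runif(n) < p)
    if (length(hit) > 0) {
      diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
        patient_id = patient_id[hit],
        date = index_date[hit] - sample.int(180L, length(hit), replace = TRUE),
        code = prev$code[i]
      ))
    }
  }
  if (config$prior_malignancy_rate > 0) {
    hit <- which(stats::runif(n) < config$prior_malignancy_rate)
    if (length(hit) > 0) {
      diagnoses <- dplyr::bind_rows(diagnoses, tibble::tibble(
        patient_id = patient_id[hit],
        date = index_date[hit] - sample.int(365L, length(hit), replace = TRUE),
        code = "DX_PRIOR_MAL"
      ))
    }
  }

  # --- procedures ---------------------------------------------------------
  tx_idx <- which(!is.na(asct_off))
  procedures <- tibble::tibble(
    patient_id = patient_id[tx_idx],
    date = index_date[tx_idx] + asct_off[tx_idx],
    kind = "ASCT"
  )
  oth <- which(stats::runif(n) < 0.2)
  if (length(oth) > 0) {
    procedures <- dplyr::bind_rows(procedures, tibble::tibble(
      patient_id = patient_id[oth],
      date = index_date[oth] + sample.int(180L, length(oth), replace = TRUE) - 1L,
      kind = "other"
    ))
  }

  # --- coverage and censoring --------------------------------------------
  cov_start_off <- -365L - runif_range(n, config$lookback_extra_days)
  cov_end_off <- as.integer(journey_end) +
    runif_range(n, config$coverage_tail_days)
  cov_end_off[died] <- pmax(cov_end_off[died], death_off[died] + 30L)
  if (config$coverage_censor_rate > 0) {
    censor_off <- round(stats::rexp(n, config$coverage_censor_rate / 365))
    cov_end_off <- pmin(cov_end_off, censor_off)
    cov_end_off <- pmax(cov_end_off, 1L)
    cov_end_date <- index_date + cov_end_off
    drug_claims <- dplyr::filter(
      drug_claims,
      .data$date <= cov_end_date[match(.data$patient_id, patient_id)]
    )
    procedures <- dplyr::filter(
      procedures,
      .data$date <= cov_end_date[match(.data$patient_id, patient_id)]
    )
  }
  coverage <- tibble::tibble(
    patient_id = rep(patient_id, 2),
    start = rep(index_date + cov_start_off, 2),
    end = rep(index_date + cov_end_off, 2),
    kind = rep(c("medical", "pharmacy"), each = n)
  )

  patients <- tibble::tibble(
    patient_id = patient_id,
    birth_year = as.integer(format(index_date, "%Y")) - as.integer(age),
    sex = sex, race = race,
    death_date = index_date + death_off,
    source_kind = source_kind
  )

  # events never postdate death
  if (any(died)) {
    dd <- patients$death_date[match(drug_claims$patient_id, patient_id)]
    drug_claims <- dplyr::filter(drug_claims,
                                 is.na(dd) | .data$date <= dd)
    dd <- patients$death_date[match(procedures$patient_id, patient_id)]
    procedures <- dplyr::filter(procedures, is.na(dd) | .data$date <= dd)
  }

  pop <- list(
    patients = dplyr::arrange(patients, .data$patient_id),
    diagnoses = dplyr::arrange(diagnoses, .data$patient_id, .data$date,
                               .data$code),
    drug_claims = dplyr::arrange(drug_claims, .data$patient_id, .data$date,
                                 .data$agent),
    procedures = dplyr::arrange(procedures, .data$patient_id, .data$date,
                                .data$kind),
    coverage = dplyr::arrange(coverage, .data$patient_id, .data$kind)
  )
  truth <- tibble::tibble(
    patient_id = patient_id, stratum = stratum, n_lines = n_lines,
    died = died, frontline_induction = has_ind, consolidation = has_cons,
    index_date = index_date
  ) |> dplyr::arrange(.data$patient_id)
  structure(pop, class = c("mm_population", "list"),
            config = config, journey_truth = truth)
}

#' @export
print.mm_population <- function(x, ...) {
  cat("<mm_population>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %8d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
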