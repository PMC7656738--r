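# Independent oracles used across the suite.

# ---- day-mask line-segmentation oracle -------------------------------------
# Literal re-implementation of the segmentation rules on boolean day masks,
# structurally independent of the interval-based engine. Days are integer
# offsets from 0; returns a data.frame of lines in day offsets.
oracle_segment_days <- function(claims, fu_end, death = Inf,
                                W = 60, G = 60, merge_gap = 0,
                                steroids = c("dexamethasone", "prednisone"),
                                steroids_trigger = FALSE) {
  hard <- min(fu_end, death)
  claims <- claims[claims$day <= hard, , drop = FALSE]
  if (nrow(claims) == 0) return(NULL)
  # boolean coverage mask over days 0..hard for one agent's claims
  agent_mask <- function(cl) {
    m <- rep(FALSE, hard + 1L)
    for (i in seq_len(nrow(cl))) {
      d0 <- cl$day[i]
      d1 <- min(cl$day[i] + cl$supply[i] - 1L, hard)
      m[(d0:d1) + 1L] <- TRUE
    }
    if (merge_gap > 0) {
      cov <- which(m)
      if (length(cov) > 1) {
        for (i in seq_len(length(cov) - 1L)) {
          if (cov[i + 1L] - cov[i] > 1L &&
              cov[i + 1L] - cov[i] - 1L <= merge_gap) {
            m[(cov[i] + 1L):(cov[i + 1L] - 1L)] <- TRUE
          }
        }
      }
    }
    m
  }
  lines <- list()
  prev_end <- -1
  repeat {
    rem <- claims[claims$day > prev_end, , drop = FALSE]
    if (nrow(rem) == 0) break
    s <- min(rem$day)
    regimen <- sort(unique(rem$agent[rem$day <= s + W]))
    trig <- rem$day[!(rem$agent %in% regimen) &
                      (steroids_trigger | !(rem$agent %in% steroids))]
    new_t <- if (length(trig)) min(trig) else Inf
    gap_ends <- vapply(regimen, function(a) {
      m <- agent_mask(rem[rem$agent == a, , drop = FALSE])
      st <- which(m & !c(FALSE, m[-length(m)])) - 1L
      en <- which(m & !c(m[-1], FALSE)) - 1L
      for (j in seq_along(st)) {
        lapse <- if (j < length(st)) st[j + 1] - en[j] - 1 else hard - en[j]
        if (lapse >= G) return(en[j])
      }
      Inf
    }, numeric(1))
    gap_end <- if (length(gap_ends)) min(gap_ends) else Inf
    nat_end <- max(pmin(rem$day + rem$supply - 1, hard))
    line_end <- min(new_t - 1, gap_end, nat_end)
    reason <- if (is.finite(new_t) && new_t - 1 <= min(gap_end, nat_end)) {
      "new_agent"
    } else if (is.finite(gap_end) && gap_end <= nat_end) {
      "gap"
    } else if (is.finite(death) && nat_end >= death) {
      "death"
    } else {
      "followup_end"
    }
    lines[[length(lines) + 1L]] <- data.frame(
      start = s, end = line_end,
      agents = paste(regimen, collapse = ";"),
      end_reason = reason, stringsAsFactors = FALSE
    )
    prev_end <- line_end
  }
  do.call(rbind, lines)
}

# Random small claim stream (day offsets) for oracle-equivalence fuzzing.
random_claim_stream <- function(max_agents = 4, horizon = 900) {
  pool <- c("bortezomib", "lenalidomide", "dexamethasone", "thalidomide",
            "cyclophosphamide", "carfilzomib")
  agents <- sample(pool, sample.int(max_agents, 1))
  do.call(rbind, lapply(agents, function(a) {
    k <- sample.int(6, 1)
    data.frame(agent = a,
               day = sort(sample.int(horizon, k)),
               supply = sample(c(7L, 14L, 30L), k, replace = TRUE))
  }))
}

# Run the installed engine on a day-offset claim stream and return lines in
# day offsets for comparison with the oracle.
engine_segment_days <- function(claims, fu_end, death = Inf,
                                rules = mmlot::lot_rules()) {
  origin <- as.Date("2012-01-01")
  dc <- tibble::tibble(
    patient_id = "P1",
    date = origin + claims$day,
    agent = claims$agent,
    days_supply = as.integer(claims$supply),
    route = "oral"
  )
  fus <- tibble::tibble(
    patient_id = "P1",
    followup_end = origin + fu_end,
    death_date = if (is.finite(death)) origin + death else as.Date(NA)
  )
  ln <- mmlot::segment_lines(dc, fus, rules)
  if (nrow(ln) == 0) return(NULL)
  data.frame(start = as.numeric(ln$start - origin),
             end = as.numeric(ln$end - origin),
             agents = ln$agents, end_reason = ln$end_reason,
             stringsAsFactors = FALSE)
}

# ---- suppression back-solver oracle ----------------------------------------
# All ways to write total as an ordered sum of k integers each >= 1.
enumerate_compositions <- function(total, k) {
  if (k == 1) return(matrix(total, ncol = 1))
  out <- list()
  for (v in seq_len(total - k + 1)) {
    rest <- enumerate_compositions(total - v, k - 1)
    out[[v]] <- cbind(v, rest)
  }
  do.call(rbind, out)
}

# TRUE if any suppressed cell in the masked row has a unique feasible value
# given the published margin and the knowledge that masked counts are >= 1.
row_back_solvable <- function(values, suppressed, margin_suppressed) {
  if (margin_suppressed || !any(suppressed)) return(FALSE)
  hidden_total <- sum(values[suppressed])
  h <- sum(suppressed)
  if (hidden_total < h) return(TRUE) # shouldn't happen; treat as broken
  sols <- enumerate_compositions(hidden_total, h)
  any(vapply(seq_len(ncol(sols)),
             function(j) length(unique(sols[, j])) == 1, logical(1)))
}
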