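origin <- as.Date("2012-01-01")

claims_tbl <- function(days, agents, supply = 30L) {
  tibble::tibble(patient_id = "P1", date = origin + days, agent = agents,
                 days_supply = as.integer(supply), route = "oral")
}

fu_tbl <- function(end_day, death_day = NA) {
  tibble::tibble(patient_id = "P1", followup_end = origin + end_day,
                 death_date = if (is.na(death_day)) as.Date(NA) else
                   origin + death_day)
}

test_that("abutting and gapped claims merge into the right exposure intervals", {
  iv <- build_exposure_intervals(claims_tbl(c(0, 30), "lenalidomide"))
  expect_equal(nrow(iv), 1)
  expect_equal(as.numeric(iv$start - origin), 0)
  expect_equal(as.numeric(iv$end - origin), 59)

  iv <- build_exposure_intervals(claims_tbl(c(0, 100), "lenalidomide"))
  expect_equal(as.numeric(iv$start - origin), c(0, 100))
  expect_equal(as.numeric(iv$end - origin), c(29, 129))
})

test_that("exposure intervals equal a brute-force day-coverage mask", {
  set.seed(11)
  for (i in 1:25) {
    days <- sort(sample.int(300, 5))
    cl <- claims_tbl(days, "bortezomib", supply = 7L)
    iv <- build_exposure_intervals(cl)
    # independent bitmask
    mask <- rep(FALSE, 400)
    for (d in days) mask[(d:(d + 6)) + 1] <- TRUE
    st <- which(mask & !c(FALSE, mask[-length(mask)])) - 1
    en <- which(mask & !c(mask[-1], FALSE)) - 1
    expect_equal(as.numeric(iv$start - origin), st)
    expect_equal(as.numeric(iv$end - origin), en)
  }
})

test_that("unknown agents are skipped with a warning and counted", {
  cl <- dplyr::bind_rows(claims_tbl(0, "lenalidomide"),
                         claims_tbl(5, "unobtainium"))
  expect_warning(iv <- build_exposure_intervals(cl), "unknown agent")
  expect_equal(nrow(iv), 1)
  expect_equal(attr(iv, "skipped_unknown_agents"), 1)
})

test_that("a single continuously exposed agent yields one line", {
  cl <- claims_tbl(seq(0, 180, by = 30), "bortezomib")
  ln <- segment_lines(cl, fu_tbl(400))
  expect_equal(nrow(ln), 1)
  expect_equal(ln$agents, "bortezomib")
  expect_equal(ln$end_reason, "gap") # exposure lapses 60+ days before follow-up end
  cl2 <- claims_tbl(seq(0, 180, by = 30), "bortezomib")
  ln2 <- segment_lines(cl2, fu_tbl(220))
  expect_equal(ln2$end_reason, "followup_end")
})

test_that("formation window joins staggered starts; later starts open a new line", {
  base <- claims_tbl(seq(0, 150, by = 30), "bortezomib")
  joined <- dplyr::bind_rows(base, claims_tbl(c(20, 50, 80), "lenalidomide"))
  ln <- segment_lines(joined, fu_tbl(400))
  # lenalidomide (day 20 < 60-day window) joins the frontline regimen;
  # once it is discontinued >= 60 days the line ends and the continuing
  # bortezomib opens the next line
  expect_equal(ln$agents[1], "bortezomib;lenalidomide")
  expect_equal(as.numeric(ln$end[1] - origin), 109) # lenalidomide last covered day
  expect_equal(ln$end_reason[1], "gap")
  expect_equal(ln$agents[2], "bortezomib")

  late <- dplyr::bind_rows(base, claims_tbl(c(90, 120), "lenalidomide"))
  ln <- segment_lines(late, fu_tbl(400))
  # lenalidomide arriving after the window ends line 1 the day before
  expect_equal(ln$agents[1], "bortezomib")
  expect_equal(as.numeric(ln$end[1] - origin), 89)
  expect_equal(as.numeric(ln$start[2] - origin), 90)
  expect_equal(ln$end_reason[1], "new_agent")
  expect_equal(ln$agents[2], "bortezomib;lenalidomide")
})

test_that("all-agents mode survives partial de-escalation", {
  cl <- dplyr::bind_rows(claims_tbl(seq(0, 150, by = 30), "bortezomib"),
                         claims_tbl(c(20, 50, 80), "lenalidomide"))
  ln <- segment_lines(cl, fu_tbl(400),
                      lot_rules(line_end_mode = "all_agents_discontinued"))
  expect_equal(nrow(ln), 1)
  expect_equal(ln$agents, "bortezomib;lenalidomide")
  expect_equal(as.numeric(ln$end - origin), 179)
})

test_that("a 60-day discontinuation ends the line at the last covered day", {
  cl <- claims_tbl(c(0, 30, 150), "lenalidomide")
  ln <- segment_lines(cl, fu_tbl(400))
  expect_equal(nrow(ln), 2)
  expect_equal(as.numeric(ln$end[1] - origin), 59)
  expect_equal(as.numeric(ln$start[2] - origin), 150)
  expect_equal(ln$end_reason[1], "gap")
})

test_that("steroids starting late neither end nor start a line by default", {
  cl <- dplyr::bind_rows(
    claims_tbl(seq(0, 150, by = 30), "lenalidomide"),
    claims_tbl(c(100, 130), "dexamethasone")
  )
  ln <- segment_lines(cl, fu_tbl(400))
  expect_equal(nrow(ln), 1)
  expect_equal(ln$agents, "lenalidomide")
  # but with the steroid trigger on, dexamethasone opens a new line
  ln2 <- segment_lines(cl, fu_tbl(400),
                       lot_rules(steroids_trigger_new_line = TRUE))
  expect_equal(nrow(ln2), 2)
  # a steroid starting within the window joins the regimen either way
  cl3 <- dplyr::bind_rows(claims_tbl(seq(0, 150, by = 30), "lenalidomide"),
                          claims_tbl(c(10, 40), "dexamethasone"))
  ln3 <- segment_lines(cl3, fu_tbl(400))
  expect_equal(ln3$agents[1], "dexamethasone;lenalidomide")
})

test_that("literal mode (window 0) fragments staggered combination starts", {
  cl <- dplyr::bind_rows(claims_tbl(seq(0, 150, by = 30), "bortezomib"),
                         claims_tbl(c(20, 50), "lenalidomide"))
  ln <- segment_lines(cl, fu_tbl(400),
                      lot_rules(regimen_formation_window_days = 0))
  expect_gte(nrow(ln), 2)
  expect_equal(as.numeric(ln$end[1] - origin), 19)
  expect_equal(ln$end_reason[1], "new_agent")
})

test_that("death clips the line end", {
  cl <- claims_tbl(seq(0, 180, by = 30), "lenalidomide")
  ln <- segment_lines(cl, fu_tbl(400, death_day = 95))
  expect_equal(nrow(ln), 1)
  expect_equal(as.numeric(ln$end - origin), 95)
  expect_equal(ln$end_reason, "death")
})

test_that("duration conversion lands on the published scale", {
  d0 <- as.Date("2012-01-01")
  expect_equal(round(lot_duration_months(d0, d0), 2), 0.03)
  expect_equal(round(lot_duration_months(d0, d0 + 110), 1), 3.6)
  expect_equal(round(lot_duration_months(d0, d0 + 365), 2), 11.99)
})

test_that("segmentation agrees with the day-mask oracle on random streams", {
  set.seed(202)
  n_mismatch <- 0
  for (i in 1:200) {
    cl <- random_claim_stream()
    fu <- 900 + sample.int(200, 1)
    death <- if (stats::runif(1) < 0.2) sample.int(900, 1) + 100 else Inf
    eng <- engine_segment_days(cl, fu, death)
    ora <- oracle_segment_days(cl, fu, death)
    if (is.null(eng) && is.null(ora)) next
    same <- !is.null(eng) && !is.null(ora) &&
      nrow(eng) == nrow(ora) &&
      all(eng$start == ora$start) && all(eng$end == ora$end) &&
      all(eng$agents == ora$agents) && all(eng$end_reason == ora$end_reason)
    if (!same) n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})

test_that("a longer discontinuation gap never yields more lines", {
  set.seed(303)
  for (i in 1:40) {
    cl <- random_claim_stream()
    fu <- 1000
    n_lines <- vapply(c(30, 60, 90, 150), function(g) {
      res <- engine_segment_days(cl, fu,
                                 rules = lot_rules(discontinuation_gap_days = g))
      if (is.null(res)) 0 else nrow(res)
    }, numeric(1))
    expect_true(all(diff(n_lines) <= 0))
  }
})

test_that("line spans partition exposure starts", {
  set.seed(404)
  for (i in 1:40) {
    cl <- random_claim_stream()
    eng <- engine_segment_days(cl, 1000)
    # lines are ordered and non-overlapping: end(k) < start(k+1)
    if (nrow(eng) > 1) {
      expect_true(all(eng$end[-nrow(eng)] < eng$start[-1]))
    }
    # every line start is an actual claim day
    expect_true(all(eng$start %in% cl$day))
  }
})
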