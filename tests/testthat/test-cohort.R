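test_that("follow-up ends at eligibility end, last activity, or death", {
  # claims source: end of the coverage interval containing index
  pop <- fixture_patient(id = "A",
                        index = as.Date("2010-06-01"),
                        cov_start = as.Date("2010-01-01") - 400,
                        cov_end = as.Date("2013-06-30"))
  fu <- followup_ends(pop)
  expect_equal(fu$followup_end, as.Date("2013-06-30"))

  # EMR source: last date of observed activity
  pop <- fixture_patient(id = "B", source_kind = "emr",
                        index = as.Date("2014-06-01"),
                        treat_start = as.Date("2014-07-01"), n_claims = 3L)
  pop$procedures <- dplyr::bind_rows(pop$procedures, tibble::tibble(
    patient_id = "B", date = as.Date("2015-02-10"), kind = "other"))
  fu <- followup_ends(pop)
  expect_equal(fu$followup_end, as.Date("2015-02-10"))

  # death inside coverage truncates follow-up
  pop <- fixture_patient(id = "C", index = as.Date("2010-06-01"),
                        cov_end = as.Date("2013-06-30"),
                        death = as.Date("2012-01-01"))
  fu <- followup_ends(pop)
  expect_equal(fu$followup_end, as.Date("2012-01-01"))
})

test_that("follow-up months use the 30.4375-day month", {
  d0 <- as.Date("2010-01-01")
  expect_equal(followup_months(d0, d0), 0)
  expect_equal(round(followup_months(d0, d0 + 365), 2), 11.99)
  expect_equal(round(followup_months(d0, as.Date("2011-07-01")), 2), 17.94)
})

test_that("boundary dates and prior malignancy exclude at the right criteria", {
  pop <- fixture_patient(id = "OK")
  pop <- fixture_patient(pop, id = "EARLY", index = as.Date("2006-12-31"))
  pop <- fixture_patient(pop, id = "PRIOR",
                        extra_dx = tibble::tibble(
                          date = as.Date("2012-06-01") - 100,
                          code = "DX_PRIOR_MAL"))
  cohort <- build_cohort(pop)
  log <- filter_log(cohort)
  expect_equal(log$n_excluded[log$criterion == "index_on_or_after_floor"], 1)
  expect_equal(log$n_excluded[log$criterion == "no_prior_malignancy"], 1)
  expect_equal(sort(cohort$patient_id), "OK")
  # the floor date itself is admissible
  pop2 <- fixture_patient(id = "FLOOR", index = as.Date("2007-01-01"),
                         cov_start = as.Date("2005-01-01"))
  expect_equal(build_cohort(pop2)$patient_id, "FLOOR")
})

test_that("hand-planted violations of each criterion are logged exactly", {
  pop <- empty_pop_tables()
  for (i in 1:8) pop <- fixture_patient(pop, id = sprintf("CLEAN%02d", i))
  # 2 early index
  for (i in 1:2) pop <- fixture_patient(pop, id = paste0("EARLY", i),
                                        index = as.Date("2005-03-01"))
  # 1 unknown sex
  pop <- fixture_patient(pop, id = "NOSEX", sex = "unknown")
  # 2 no pharmacy coverage at index
  for (i in 1:2) {
    pop <- fixture_patient(pop, id = paste0("NOCOV", i))
    pop$coverage <- dplyr::filter(pop$coverage,
      !(.data$patient_id == paste0("NOCOV", i) & .data$kind == "pharmacy"))
  }
  # 1 short look-back
  pop <- fixture_patient(pop, id = "SHORTLB",
                         cov_start = as.Date("2012-06-01") - 100)
  # 2 prior malignancy in look-back year
  for (i in 1:2) pop <- fixture_patient(pop, id = paste0("PRIOR", i),
    extra_dx = tibble::tibble(date = as.Date("2012-06-01") - 200,
                              code = "DX_PRIOR_MAL"))
  # 1 never treated
  pop <- fixture_patient(pop, id = "NOTX", n_claims = 0L)
  # the two coverage-ineligible patients have claims but no follow-up window
  expect_warning(cohort <- build_cohort(pop), "no follow-up window")
  log <- filter_log(cohort)
  expect_equal(log$n_excluded,
               c(0, 2, 1, 2, 1, 2, 1))
  expect_equal(log$n_after[nrow(log)], 8)
  expect_equal(nrow(cohort), 8)
  # chain identity: n_after of step i equals n_before of step i + 1
  expect_equal(log$n_after[-nrow(log)], log$n_before[-1])
  expect_true(all(diff(log$n_after) <= 0))
})

test_that("included members re-pass every criterion (idempotence)", {
  pop <- simulate_population(sim_config(n_patients = 150, seed = 21,
                                        prior_malignancy_rate = 0.1))
  cohort <- suppressWarnings(build_cohort(pop))
  flags <- dplyr::select(cohort, dplyr::starts_with("flag_"))
  expect_true(all(as.matrix(flags)))
  expect_true(all(cohort$index_diagnosis_date >= as.Date("2007-01-01")))
  expect_true(all(cohort$followup_end >= cohort$index_diagnosis_date))
})

test_that("transplant status reflects ASCT within follow-up", {
  pop <- fixture_patient(id = "TX")
  pop$procedures <- dplyr::bind_rows(pop$procedures, tibble::tibble(
    patient_id = "TX", date = as.Date("2012-12-01"), kind = "ASCT"))
  pop <- fixture_patient(pop, id = "NOTX")
  cohort <- build_cohort(pop)
  expect_equal(cohort$transplant_status[cohort$patient_id == "TX"],
               "transplant")
  expect_equal(cohort$transplant_status[cohort$patient_id == "NOTX"],
               "non_transplant")
})

test_that("a coverage bridge rule tolerates configured gaps", {
  pop <- fixture_patient(id = "GAP")
  # split the coverage into two spans with a 20-day hole before index
  pop$coverage <- tibble::tibble(
    patient_id = "GAP",
    start = c(as.Date("2010-01-01"), as.Date("2011-08-21"),
              as.Date("2010-01-01"), as.Date("2011-08-21")),
    end = c(as.Date("2011-08-01"), as.Date("2014-01-01"),
            as.Date("2011-08-01"), as.Date("2014-01-01")),
    kind = rep(c("medical", "pharmacy"), each = 2)
  )
  strict <- build_cohort(pop)
  expect_equal(nrow(strict), 0) # look-back broken under a 0-day bridge
  bridged <- build_cohort(pop, rules = cohort_rules(coverage_gap_days = 30))
  expect_equal(bridged$patient_id, "GAP")
})
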