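anchor <- as.Date("2013-03-01")

dx <- function(offsets, codes, id = "P1") {
  tibble::tibble(patient_id = id, date = anchor - offsets, code = codes)
}

test_that("an empty window gives all-false flags and a zero score", {
  prof <- comorbidity_flags(dx(numeric(0), character(0)), anchor)
  expect_true(all(!unlist(prof[comorbidity_conditions()])))
  expect_equal(prof$cci_score, 0L)
  expect_false(prof$cardiovascular_composite)
})

test_that("the 180-day window boundary is inclusive on the far edge only", {
  expect_false(comorbidity_flags(dx(200, "DX_CHF"),
                                 anchor)$congestive_heart_failure)
  expect_false(comorbidity_flags(dx(181, "DX_CHF"),
                                 anchor)$congestive_heart_failure)
  expect_true(comorbidity_flags(dx(180, "DX_CHF"),
                                anchor)$congestive_heart_failure)
  expect_true(comorbidity_flags(dx(1, "DX_CHF"),
                                anchor)$congestive_heart_failure)
  # the anchor day itself is outside the look-back
  expect_false(comorbidity_flags(dx(0, "DX_CHF"),
                                 anchor)$congestive_heart_failure)
})

test_that("the cardiovascular composite is the OR of its four components", {
  prof <- comorbidity_flags(dx(c(30, 60), c("DX_ARRHYTHMIA", "DX_VALVULAR")),
                            anchor)
  expect_true(prof$cardiovascular_composite)
  prof2 <- comorbidity_flags(dx(30, "DX_RENAL"), anchor)
  expect_false(prof2$cardiovascular_composite)
  prof3 <- comorbidity_flags(dx(30, "DX_HTN_COMP"), anchor)
  expect_true(prof3$cardiovascular_composite)
})

test_that("complicated hypertension suppresses simple hypertension", {
  prof <- comorbidity_flags(dx(c(20, 40), c("DX_HTN_COMP", "DX_HTN_SIMPLE")),
                            anchor)
  expect_true(prof$hypertension_complicated)
  expect_false(prof$hypertension_simple)
})

test_that("CCI sums configured weights over distinct categories", {
  # one weight-1 (CHF) and one weight-2 (renal) category
  expect_equal(cci_score(dx(c(10, 20), c("DX_CHF", "DX_RENAL")), anchor), 3L)
  # repeated events in one category count once
  expect_equal(cci_score(dx(c(10, 20, 30), rep("DX_CHF", 3)), anchor), 1L)
  # severe liver suppresses mild liver
  expect_equal(cci_score(dx(c(10, 20), c("DX_HEPATIC", "DX_LIVER_SEVERE")),
                         anchor), 3L)
  # the index MM code is excluded from the score by default
  expect_equal(cci_score(dx(10, "DX_MM"), anchor), 0L)
  expect_equal(cci_score(dx(10, "DX_MM"), anchor, exclude_codes = character()),
               2L)
})

test_that("CCI agrees with a brute-force set-union oracle", {
  map <- default_code_map()
  charlson <- dplyr::filter(map, !is.na(.data$charlson_category),
                            .data$code != "DX_MM")
  set.seed(99)
  for (i in 1:10) {
    codes <- sample(charlson$code, sample.int(8, 1), replace = TRUE)
    offsets <- sample.int(180, length(codes), replace = TRUE)
    got <- cci_score(dx(offsets, codes), anchor)
    # oracle: distinct categories, hierarchy by hand, sum weights
    cats <- unique(charlson$charlson_category[match(codes, charlson$code)])
    for (pair in list(c("diabetes_with_complications", "diabetes"),
                      c("moderate_severe_liver_disease", "mild_liver_disease"),
                      c("metastatic_solid_tumor", "malignancy"))) {
      if (all(pair %in% cats)) cats <- setdiff(cats, pair[2])
    }
    w <- charlson$weight[match(cats, charlson$charlson_category)]
    expect_equal(got, as.integer(sum(w)))
  }
})

test_that("adding events never lowers the score or clears a flag", {
  set.seed(123)
  map <- default_code_map()
  pool <- setdiff(map$code, c("DX_MM", "DX_PRIOR_MAL",
                              "DX_HTN_SIMPLE", "DX_DIABETES",
                              "DX_HEPATIC"))
  for (i in 1:10) {
    codes <- sample(pool, 4, replace = TRUE)
    off <- sample.int(180, 4, replace = TRUE)
    base <- comorbidity_flags(dx(off[1:3], codes[1:3]), anchor)
    more <- comorbidity_flags(dx(off, codes), anchor)
    expect_gte(more$cci_score, base$cci_score)
    for (cn in comorbidity_conditions()) {
      if (base[[cn]]) expect_true(more[[cn]])
    }
  }
})

test_that("profiles are equivariant under a common time shift", {
  events <- dx(c(15, 90, 170), c("DX_CHF", "DX_RENAL", "DX_COPD"))
  p0 <- comorbidity_flags(events, anchor)
  shifted <- dplyr::mutate(events, date = .data$date + 500)
  p1 <- comorbidity_flags(shifted, anchor + 500)
  expect_equal(p0, p1)
})

test_that("both window anchors are supported for a whole cohort", {
  diagnoses <- dplyr::bind_rows(dx(40, "DX_CHF", id = "P1"),
                                dx(100, "DX_RENAL", id = "P2"))
  anchors <- tibble::tibble(patient_id = c("P1", "P2"),
                            anchor_date = c(anchor, anchor + 70))
  prof <- comorbidity_profiles(diagnoses, anchors)
  expect_equal(nrow(prof), 2)
  expect_true(prof$congestive_heart_failure[prof$patient_id == "P1"])
  expect_true(prof$renal_impairment[prof$patient_id == "P2"])
})
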