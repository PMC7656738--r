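test_that("identical groups give p = 1 for the mean comparison", {
  d <- tibble::tibble(grp = rep(c("a", "b"), each = 20),
                      x = rep(rnorm(20, 5), 2))
  res <- compare_groups(d, "grp")
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("the 2x2 chi-squared statistic matches hand-computed expected counts", {
  d <- tibble::tibble(
    grp = rep(c("g1", "g2"), each = 30),
    trait = c(rep(c("yes", "no"), c(10, 20)), rep(c("yes", "no"), c(20, 10)))
  )
  res <- compare_groups(d, "grp")
  expect_equal(unname(res$statistic), 20 / 3, tolerance = 1e-9)
  expect_equal(res$type, "categorical")
})

test_that("a single-stratum MH test reduces to the ordinary chi-squared", {
  set.seed(42)
  d <- tibble::tibble(
    grp = sample(c("a", "b"), 200, replace = TRUE),
    trait = sample(c("x", "y"), 200, replace = TRUE),
    stratum = "all"
  )
  plain <- compare_groups(d, "grp", vars = "trait")
  one <- compare_groups(d, "grp", vars = "trait", strata = "stratum")
  expect_equal(unname(one$statistic), unname(plain$statistic),
               tolerance = 1e-12)
  # with two genuine strata the stratified CMH statistic is used
  d$stratum <- rep(c("s1", "s2"), 100)
  mh <- compare_groups(d, "grp", vars = "trait", strata = "stratum")
  expect_match(mh$method, "Mantel-Haenszel")
  expect_false(isTRUE(all.equal(unname(mh$statistic),
                                unname(plain$statistic))))
})

test_that("a 2-SD mean shift at n=500/arm is detected in almost every replicate", {
  set.seed(7)
  hits <- 0
  for (i in 1:100) {
    d <- tibble::tibble(grp = rep(c("a", "b"), each = 500),
                        x = c(rnorm(500), rnorm(500, 2)))
    p <- compare_groups(d, "grp")$p_value
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("zero-variance continuous variables are skipped with a notice", {
  d <- tibble::tibble(grp = rep(c("a", "b"), each = 5), x = 1)
  res <- compare_groups(d, "grp")
  expect_match(res$note, "zero variance")
  expect_true(is.na(res$p_value))
})

sim_logit_frame <- function(n, beta1 = 0, beta2 = log(0.5), b0 = 0.3) {
  x1 <- stats::rbinom(n, 1, 0.5)
  x2 <- stats::rbinom(n, 1, 0.5)
  eta <- b0 + beta1 * x1 + beta2 * x2
  tibble::tibble(
    received_subsequent = stats::runif(n) < stats::plogis(eta),
    followup_months = 60,
    x1 = x1, x2 = x2
  )
}

test_that("null and true odds ratios are recovered at n = 10,000", {
  set.seed(2024)
  d <- sim_logit_frame(10000)
  fit <- fit_subsequent_treatment_model(d, covariates = c("x1", "x2"))
  td <- tidy(fit)
  expect_gt(td$odds_ratio[td$term == "x1"], 0.9)
  expect_lt(td$odds_ratio[td$term == "x1"], 1.1)
  expect_gt(td$odds_ratio[td$term == "x2"], 0.45)
  expect_lt(td$odds_ratio[td$term == "x2"], 0.56)
  expect_false(fit$separation)
  expect_true(all(td$conf_low <= td$odds_ratio & td$odds_ratio <= td$conf_high))
})

test_that("estimates concentrate around truth as n grows", {
  set.seed(31)
  err <- vapply(c(2000, 20000), function(n) {
    # average over replicates: concentration holds in expectation, not on
    # every single draw
    mean(vapply(1:5, function(i) {
      d <- sim_logit_frame(n)
      td <- tidy(fit_subsequent_treatment_model(d,
                                                covariates = c("x1", "x2")))
      abs(log(td$odds_ratio[td$term == "x2"]) - log(0.5))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.08)
  expect_lt(err[1], 0.25)
})

test_that("follow-up subsets nest and strictly reduce n", {
  set.seed(5)
  d <- sim_logit_frame(2000)
  d$followup_months <- stats::runif(2000, 0, 40)
  fits <- lapply(c("overall", "6+", "12+", "24+"), function(s)
    fit_subsequent_treatment_model(d, subset = s, covariates = c("x1", "x2")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  expect_true(all(diff(ns) < 0))
  expect_equal(ns[1], 2000)
})

test_that("separation is flagged rather than reported as a huge estimate", {
  d <- tibble::tibble(
    received_subsequent = rep(c(TRUE, FALSE), each = 50),
    followup_months = 60,
    x1 = rep(c(1, 0), each = 50)
  )
  fit <- suppressWarnings(
    fit_subsequent_treatment_model(d, covariates = "x1"))
  expect_true(fit$separation)
  expect_true(all(tidy(fit)$separation_flag))
  expect_false(glance(fit)$separation == FALSE)
})

test_that("a degenerate outcome subset raises a classed error", {
  d <- tibble::tibble(received_subsequent = rep(TRUE, 20),
                      followup_months = 60, x1 = rbinom(20, 1, 0.5))
  expect_error(fit_subsequent_treatment_model(d, covariates = "x1"),
               class = "mmlot_degenerate_outcome")
})

test_that("the end-to-end model frame fits across strata and subsets", {
  pop <- simulate_population(sim_config(n_patients = 2500, seed = 17))
  lines <- suppressWarnings(build_lots(pop))
  cohort <- build_cohort(pop, lines = lines)
  prof <- comorbidity_profiles(
    pop$diagnoses,
    dplyr::select(cohort, patient_id, anchor_date = index_diagnosis_date))
  mf <- build_model_frame(cohort, prof)
  res <- subsequent_treatment_models(mf, strata = "non_transplant",
                                     subsets = c("overall", "6+"))
  expect_true(all(c("stratum", "subset", "term", "odds_ratio",
                    "conf_low", "conf_high", "p_value") %in% names(res)))
  expect_true(all(res$conf_low <= res$odds_ratio))
  expect_true(all(res$odds_ratio <= res$conf_high))
  # reference levels carry no rows
  expect_false(any(grepl("65-74", res$term)))
})
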