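# Group comparisons (chi-squared / t-tests) and logistic models of
# receiving a subsequent line of therapy.

#' Compare characteristics between two groups
#'
#' For each categorical characteristic, a chi-squared test of association
#' with the grouping (uncorrected Pearson with a single stratum; the
#' Mantel-Haenszel / Cochran-Mantel-Haenszel statistic when a
#' stratification variable is supplied). For each continuous
#' characteristic, a two-sample t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance test). Zero-variance
#' continuous variables are skipped with a notice in the `note` column.
#'
#' @param data tibble of characteristics, one row per patient.
#' @param group name of a two-level grouping column (e.g. only-1-LOT vs
#'   more-than-1-LOT).
#' @param vars character vector of characteristic columns to test;
#'   defaults to every column except `group` and `strata`.
#' @param strata optional name of a stratification column for the
#'   Mantel-Haenszel tests.
#' @param var_equal pooled-variance t-tests if `TRUE`.
#' @return tidy tibble: `variable`, `type`, `statistic`, `df`, `p_value`,
#'   `n_1`, `n_2`, `method`, `note`.
#' @export
compare_groups <- function(data, group, vars = NULL, strata = NULL,
                           var_equal = FALSE) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) {
    rlang::abort("`group` must have exactly two levels with data on both sides")
  }
  if (any(table(g) == 0)) rlang::abort("both groups must be nonempty")
  vars <- vars %||% setdiff(names(data), c(group, strata))
  z <- if (!is.null(strata)) factor(data[[strata]])

  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    n1 <- sum(!is.na(x) & g == levels(g)[1])
    n2 <- sum(!is.na(x) & g == levels(g)[2])
    base <- tibble::tibble(variable = v, n_1 = n1, n_2 = n2,
                           note = NA_character_)
    if (is.numeric(x)) {
      if (stats::sd(x, na.rm = TRUE) == 0 || anyNA(stats::sd(x, na.rm = TRUE))) {
        return(dplyr::mutate(base, type = "continuous",
                             statistic = NA_real_, df = NA_real_,
                             p_value = NA_real_,
                             method = "t-test",
                             note = "skipped: zero variance"))
      }
      tt <- stats::t.test(x ~ g, var.equal = var_equal)
      dplyr::mutate(base, type = "continuous",
                    statistic = unname(tt$statistic),
                    df = unname(tt$parameter), p_value = tt$p.value,
                    method = tt$method)
    } else {
      xf <- factor(x)
      if (is.null(z) || nlevels(z) < 2) {
        # single stratum: the general-association statistic reduces to the
        # ordinary (uncorrected) Pearson chi-squared
        ct <- suppressWarnings(stats::chisq.test(table(g, xf),
                                                 correct = FALSE))
      } else {
        ct <- stats::mantelhaen.test(table(xf, g, z), correct = FALSE)
      }
      dplyr::mutate(base, type = "categorical",
                    statistic = unname(ct$statistic),
                    df = unname(ct$parameter), p_value = ct$p.value,
                    method = ct$method)
    }
  })
}

default_model_covariates <- function() {
  c("age_category", "sex", "cardiovascular_composite", "hepatic_disease",
    "pulmonary_circulation_disorders", "renal_impairment")
}

subset_thresholds <- function() {
  c(overall = 0, `6+` = 6, `12+` = 12, `24+` = 24)
}

#' Assemble the modelling frame
#'
#' Joins cohort members with their comorbidity profiles and derives the
#' binary outcome (received a second line or beyond), the age category
#' with 65-74 as the reference level, and follow-up months from first-LOT
#' start used by the sensitivity subsets.
#'
#' @param cohort a [build_cohort()] tibble.
#' @param profiles a [comorbidity_profiles()] tibble.
#' @return tibble ready for [fit_subsequent_treatment_model()].
#' @export
build_model_frame <- function(cohort, profiles) {
  cohort |>
    dplyr::inner_join(profiles, by = "patient_id") |>
    dplyr::mutate(
      received_subsequent = .data$n_lines >= 2,
      age_category = stats::relevel(factor(.data$age_category,
                                           levels = age_category_levels()),
                                    ref = "65-74"),
      sex = factor(.data$sex, levels = c("female", "male")),
      followup_months = .data$followup_months_from_first_lot
    ) |>
    dplyr::select("patient_id", "transplant_status", "received_subsequent",
                  "followup_months", dplyr::all_of(default_model_covariates()))
}

#' Logistic model of receiving a subsequent line of therapy
#'
#' Maximum-likelihood logistic regression of the binary outcome (received
#' a second or later line) on age category (reference 65-74), sex (male
#' vs female), the cardiovascular composite, liver disease, pulmonary
#' circulation disorders and renal impairment, optionally restricted to a
#' follow-up sensitivity subset (patients with at least 6, 12 or 24
#' months of follow-up from first-LOT start). Odds ratios carry Wald 95%
#' confidence intervals and p-values. The fit is deterministic given the
#' data (IRLS convergence tolerance 1e-8, up to 50 iterations). Complete
#' or quasi-complete separation is detected (absurd coefficient magnitude
#' or standard error) and flagged rather than silently reported as an
#' infinite estimate.
#'
#' @param features a [build_model_frame()] tibble (or any tibble with
#'   `received_subsequent`, `followup_months` and the covariates).
#' @param subset one of `"overall"`, `"6+"`, `"12+"`, `"24+"`.
#' @param covariates covariate column names.
#' @return an object of class `mmlot_fit`; see [tidy.mmlot_fit()] and
#'   [glance.mmlot_fit()].
#' @export
fit_subsequent_treatment_model <- function(features,
                                           subset = c("overall", "6+",
                                                      "12+", "24+"),
                                           covariates =
                                             default_model_covariates()) {
  subset <- match.arg(subset)
  thr <- subset_thresholds()[[subset]]
  dat <- dplyr::filter(features, .data$followup_months >= thr)
  y <- dat$received_subsequent
  if (length(unique(y[!is.na(y)])) < 2) {
    rlang::abort("outcome must have both classes in the subset",
                 class = "mmlot_degenerate_outcome")
  }
  covariates <- covariates[covariates %in% names(dat)]
  keep <- vapply(covariates,
                 function(v) length(unique(dat[[v]])) > 1, logical(1))
  form <- stats::reformulate(covariates[keep],
                             response = "received_subsequent")
  fit <- stats::glm(form, data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  co <- summary(fit)$coefficients
  separation <- !fit$converged ||
    any(abs(co[, "Estimate"]) > 15) || any(co[, "Std. Error"] > 10)
  structure(list(fit = fit, subset = subset, n = nrow(dat),
                 n_events = sum(dat$received_subsequent),
                 separation = separation,
                 dropped_covariates = covariates[!keep]),
            class = "mmlot_fit")
}

#' @export
print.mmlot_fit <- function(x, ...) {
  cat(sprintf("<mmlot_fit> subset %s: n = %d, events = %d%s\n",
              x$subset, x$n, x$n_events,
              if (x$separation) " [separation flagged]" else ""))
  print(tidy(x))
  invisible(x)
}

#' Tidy a subsequent-treatment model
#'
#' Broom-style coefficient table: odds ratios with Wald 95% confidence
#' intervals and p-values per non-reference term (the intercept is
#' omitted).
#'
#' @param x an `mmlot_fit`.
#' @param ... unused.
#' @return tibble: `term`, `estimate` (log-odds), `std_error`,
#'   `odds_ratio`, `conf_low`, `conf_high`, `p_value`, `separation_flag`.
#' @method tidy mmlot_fit
#' @export
tidy.mmlot_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  zcrit <- stats::qnorm(0.975)
  out <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    odds_ratio = exp(co[, "Estimate"]),
    conf_low = exp(co[, "Estimate"] - zcrit * co[, "Std. Error"]),
    conf_high = exp(co[, "Estimate"] + zcrit * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"],
    separation_flag = x$separation
  )
  dplyr::filter(out, .data$term != "(Intercept)")
}

#' Model-level summary
#'
#' @param x an `mmlot_fit`.
#' @param ... unused.
#' @return one-row tibble: subset, n, events, convergence and separation
#'   flags, deviance and AIC.
#' @method glance mmlot_fit
#' @export
glance.mmlot_fit <- function(x, ...) {
  tibble::tibble(
    subset = x$subset, n = x$n, n_events = x$n_events,
    converged = x$fit$converged, separation = x$separation,
    null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}

#' Fit the subsequent-treatment model across follow-up subsets
#'
#' Fits the model overall and within the 6+, 12+ and 24+ month follow-up
#' sensitivity subsets, per transplant stratum, and binds the tidied
#' coefficient tables. Subset sizes are nested: each threshold can only
#' shrink the analysis set.
#'
#' @param features a [build_model_frame()] tibble.
#' @param strata strata to fit (default both).
#' @param subsets follow-up subsets to fit.
#' @return tidy tibble with `stratum` and `subset` columns; subsets in
#'   which the outcome is degenerate are skipped with a message.
#' @export
subsequent_treatment_models <- function(features,
                                        strata = c("non_transplant",
                                                   "transplant"),
                                        subsets = c("overall", "6+", "12+",
                                                    "24+")) {
  grid <- tidyr::expand_grid(stratum = strata, subset = subsets)
  purrr::pmap_dfr(grid, function(stratum, subset) {
    dat <- dplyr::filter(features, .data$transplant_status == stratum)
    res <- tryCatch(
      fit_subsequent_treatment_model(dat, subset = subset),
      mmlot_degenerate_outcome = function(e) NULL
    )
    if (is.null(res)) {
      message(sprintf("skipping %s / %s: outcome degenerate", stratum, subset))
      return(tibble::tibble())
    }
    dplyr::mutate(tidy(res), stratum = stratum, subset = subset,
                  n = res$n, .before = 1)
  })
}
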