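# End-to-end pipeline: simulate -> cohort -> lot -> comorbidity ->
# attrition -> inference -> report bundle.

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()], either built in code or read
#' from a YAML/JSON file with sections `simulate` (arguments to
#' [sim_config()]), `cohort` ([cohort_rules()]), `lot_rules`
#' ([lot_rules()]), `suppression` ([suppression_policy()]) and `attrition`
#' (`max_lot`).
#'
#' @param path optional YAML or JSON file; entries override the defaults.
#' @param ... named sections overriding the file/defaults, e.g.
#'   `simulate = list(n_patients = 2000)`.
#' @return a named list of resolved sections.
#' @export
pipeline_config <- function(path = NULL, ...) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      rlang::abort(sprintf("config file `%s` does not exist", path),
                   class = "mmlot_missing_input")
    }
    user <- if (grepl("[.]json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
  }
  dots <- list(...)
  for (nm in names(dots)) {
    user[[nm]] <- utils::modifyList(user[[nm]] %||% list(), dots[[nm]])
  }
  list(
    simulate = user$simulate %||% list(),
    cohort = user$cohort %||% list(),
    lot_rules = user$lot_rules %||% list(),
    suppression = user$suppression %||% list(),
    attrition = utils::modifyList(list(max_lot = 5),
                                  user$attrition %||% list())
  )
}

demographics_counts <- function(cohort, profiles) {
  feats <- dplyr::inner_join(
    dplyr::select(cohort, "patient_id", "transplant_status", "age_category",
                  "sex", "n_lines"),
    profiles, by = "patient_id"
  ) |>
    dplyr::mutate(grp = ifelse(.data$n_lines >= 2, "more_than_1_lot",
                               "only_1_lot"))
  chars <- c(paste0("age_", age_category_levels()), "male",
             comorbidity_conditions())
  rows <- list()
  for (s in c("non_transplant", "transplant")) {
    d <- dplyr::filter(feats, .data$transplant_status == s)
    for (ch in chars) {
      hit <- if (startsWith(ch, "age_")) {
        d$age_category == sub("^age_", "", ch)
      } else if (ch == "male") {
        d$sex == "male"
      } else {
        d[[ch]]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stratum = s, characteristic = ch,
        only_1_lot = sum(hit & d$grp == "only_1_lot"),
        more_than_1_lot = sum(hit & d$grp == "more_than_1_lot")
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> follow-up -> exposure/LOT construction ->
#' cohort filters -> comorbidity profiling -> attrition table ->
#' group comparisons and logistic models -> suppressed report tables, and
#' writes every output plus a JSON manifest, the resolved configuration
#' and a run log to `out_dir`. Identical seed and configuration produce an
#' identical bundle.
#'
#' @param config a [pipeline_config()] list (or a path passed to it).
#' @param out_dir output directory (created if needed).
#' @param seed overrides the simulation seed.
#' @param simulate if `TRUE` (default) generate the population; otherwise
#'   read claim tables from `claims_dir`.
#' @param claims_dir directory of claim tables when `simulate = FALSE`.
#' @return invisibly, a list with every intermediate product (population,
#'   followups, lines, cohort, profiles, attrition, comparisons, models,
#'   demographics) and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = NULL, simulate = TRUE, claims_dir = NULL) {
  if (is.character(config)) config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    note("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      note("stage %s: FAILED (%s)", name, conditionMessage(e))
      writeLines(log_lines, log_path)
      rlang::abort(sprintf("pipeline stage `%s` failed: %s", name,
                           conditionMessage(e)),
                   class = "mmlot_stage_error", parent = e)
    })
    note("stage %s: ok", name)
    out
  }

  scfg <- do.call(sim_config, config$simulate)
  if (!is.null(seed)) scfg$seed <- as.integer(seed)
  note("seed: %d", scfg$seed)

  pop <- if (simulate) {
    stage("simulate", simulate_population(scfg))
  } else {
    if (is.null(claims_dir) || !dir.exists(claims_dir)) {
      rlang::abort(sprintf("claims directory `%s` does not exist",
                           claims_dir %||% "<missing>"),
                   class = "mmlot_missing_input")
    }
    stage("load", read_claims_tables(claims_dir))
  }
  if (simulate) {
    stage("write_tables",
          write_claims_tables(pop, file.path(out_dir, "claims")))
  }

  crules <- do.call(cohort_rules, config$cohort)
  lrules <- do.call(lot_rules, config$lot_rules)
  policy <- do.call(suppression_policy, config$suppression)

  fus <- stage("followup", followup_ends(pop, crules))
  lines <- stage("lot", build_lots(
    pop, rules = lrules,
    followups = dplyr::filter(fus, !is.na(.data$followup_end))))
  cohort <- stage("cohort", build_cohort(pop, lines = lines, rules = crules))
  lines <- dplyr::semi_join(lines, cohort, by = "patient_id")

  prof_lot <- stage("comorbidity_first_lot", comorbidity_profiles(
    pop$diagnoses,
    dplyr::select(cohort, "patient_id", anchor_date = "first_lot_start")))
  prof_idx <- stage("comorbidity_index", comorbidity_profiles(
    pop$diagnoses,
    dplyr::select(cohort, "patient_id",
                  anchor_date = "index_diagnosis_date")))

  att <- stage("attrition",
               attrition_table(cohort, lines,
                               max_lot = config$attrition$max_lot))
  att_fmt <- format_attrition_table(att, policy = policy)

  demo <- stage("demographics", demographics_counts(cohort, prof_lot))
  sup <- suppress_small_cells(
    as.matrix(demo[, c("only_1_lot", "more_than_1_lot")]), policy)
  demo_out <- demo
  demo_out$only_1_lot <- sup$masked[, 1]
  demo_out$more_than_1_lot <- sup$masked[, 2]
  demo_out$margin_suppressed <- sup$margin_suppressed

  cmp <- stage("compare_groups", {
    feats <- dplyr::inner_join(
      dplyr::select(cohort, "patient_id", "transplant_status",
                    "age_at_diagnosis", "n_lines"),
      prof_lot, by = "patient_id") |>
      dplyr::mutate(grp = .data$n_lines >= 2)
    purrr::map_dfr(c("non_transplant", "transplant"), function(s) {
      d <- dplyr::filter(feats, .data$transplant_status == s)
      if (length(unique(d$grp)) < 2) return(tibble::tibble())
      compare_groups(
        dplyr::select(d, "grp", "age_at_diagnosis", "cci_score",
                      dplyr::all_of(comorbidity_conditions())),
        group = "grp") |>
        dplyr::mutate(stratum = s, .before = 1)
    })
  })

  models <- stage("inference", {
    mf <- build_model_frame(cohort, prof_idx)
    subsequent_treatment_models(mf)
  })

  lines_out <- dplyr::select(lines, -"regimen_agents")
  outputs <- list(
    filter_log = filter_log(cohort),
    cohort = tibble::as_tibble(cohort),
    lines = lines_out,
    attrition = att,
    attrition_formatted = att_fmt,
    demographics = demo_out,
    comparisons = cmp,
    model_results = models
  )
  files <- character()
  for (nm in names(outputs)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(outputs[[nm]], path, na = "")
    files <- c(files, basename(path))
  }
  jsonlite::write_json(serialize_config(scfg),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mmlot")),
    seed = scfg$seed,
    n_patients = nrow(pop$patients),
    n_cohort = nrow(cohort),
    files = c(files, "resolved_config.json", "run_log.txt")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, log_path)

  invisible(c(list(population = pop, followups = fus,
                   profiles_first_lot = prof_lot,
                   profiles_index = prof_idx, manifest = manifest),
              outputs))
}
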