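# Hand-built tiny populations for cohort/comorbidity tests.

empty_pop_tables <- function() {
  list(
    patients = tibble::tibble(patient_id = character(),
                              birth_year = integer(), sex = character(),
                              race = character(),
                              death_date = as.Date(character()),
                              source_kind = character()),
    diagnoses = tibble::tibble(patient_id = character(),
                               date = as.Date(character()),
                               code = character()),
    drug_claims = tibble::tibble(patient_id = character(),
                                 date = as.Date(character()),
                                 agent = character(),
                                 days_supply = integer(),
                                 route = character()),
    procedures = tibble::tibble(patient_id = character(),
                                date = as.Date(character()),
                                kind = character()),
    coverage = tibble::tibble(patient_id = character(),
                              start = as.Date(character()),
                              end = as.Date(character()),
                              kind = character())
  )
}

# One eligible patient: index MM dx, full coverage, one treated line.
fixture_patient <- function(pop = empty_pop_tables(), id,
                            index = as.Date("2012-06-01"),
                            birth_year = 1945L, sex = "male",
                            race = "white", death = as.Date(NA),
                            source_kind = "claims",
                            cov_start = index - 800,
                            cov_end = index + 1000,
                            treat_start = index + 10,
                            n_claims = 6L, agent = "lenalidomide",
                            extra_dx = NULL, mm_dx = TRUE) {
  pop$patients <- dplyr::bind_rows(pop$patients, tibble::tibble(
    patient_id = id, birth_year = birth_year, sex = sex, race = race,
    death_date = death, source_kind = source_kind))
  if (mm_dx) {
    pop$diagnoses <- dplyr::bind_rows(pop$diagnoses, tibble::tibble(
      patient_id = id, date = index, code = "DX_MM"))
  }
  if (!is.null(extra_dx)) {
    extra_dx$patient_id <- id
    pop$diagnoses <- dplyr::bind_rows(pop$diagnoses, extra_dx)
  }
  if (n_claims > 0) {
    pop$drug_claims <- dplyr::bind_rows(pop$drug_claims, tibble::tibble(
      patient_id = id, date = treat_start + 30 * (seq_len(n_claims) - 1),
      agent = agent, days_supply = 30L, route = "oral"))
  }
  pop$coverage <- dplyr::bind_rows(pop$coverage, tibble::tibble(
    patient_id = id, start = cov_start, end = cov_end,
    kind = c("medical", "pharmacy")))
  structure(pop, class = c("mm_population", "list"))
}
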