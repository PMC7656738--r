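# Anti-myeloma agent dictionary and regimen-category rules.

#' Anti-myeloma agent dictionary
#'
#' Canonical agent codes with route of administration, the default days of
#' exposure that a single claim confers (oral dispensings carry a 30-day
#' supply; parenteral administrations carry the administration-cycle length,
#' 7 days by default, because claims record administration dates rather than
#' supply), and drug-class membership used by the regimen classifier
#' (alkylating agents) and the line-segmentation steroid rule.
#'
#' @param parenteral_supply_days default exposure days attached to a
#'   parenteral administration claim.
#' @return a tibble with columns `agent`, `route`, `default_supply_days`,
#'   `class`.
#' @export
agent_dictionary <- function(parenteral_supply_days = 7) {
  tibble::tribble(
    ~agent,             ~route,       ~class,
    "bortezomib",       "parenteral", "proteasome_inhibitor",
    "carfilzomib",      "parenteral", "proteasome_inhibitor",
    "daratumumab",      "parenteral", "monoclonal_antibody",
    "bendamustine",     "parenteral", "alkylator",
    "lenalidomide",     "oral",       "imid",
    "thalidomide",      "oral",       "imid",
    "pomalidomide",     "oral",       "imid",
    "cyclophosphamide", "oral",       "alkylator",
    "melphalan",        "oral",       "alkylator",
    "dexamethasone",    "oral",       "steroid",
    "prednisone",       "oral",       "steroid"
  ) |>
    dplyr::mutate(
      default_supply_days = ifelse(.data$route == "oral", 30L,
                                   as.integer(parenteral_supply_days))
    )
}

# Agent subsets used by classification and segmentation rules.
alkylator_agents <- function(dict = agent_dictionary()) {
  dict$agent[dict$class == "alkylator"]
}

#' Steroid agents
#'
#' Steroids are ubiquitous co-medication; under the default segmentation
#' rules a steroid starting after the regimen-formation window neither ends
#' the current line nor starts a new one.
#'
#' @param dict an [agent_dictionary()] tibble.
#' @return character vector of steroid agent codes.
#' @export
steroid_agents <- function(dict = agent_dictionary()) {
  dict$agent[dict$class == "steroid"]
}

#' Frontline regimen classification rules
#'
#' The ordered, first-match rule list mapping a line's agent set to a
#' presentation category: Vd (bortezomib/dexamethasone), Rd
#' (lenalidomide/dexamethasone), VRd (the triplet), V/alkylator (bortezomib
#' plus an alkylating agent, with or without dexamethasone), V, R, T
#' single-agent categories, and a residual `other` bucket (which absorbs,
#' e.g., Td, VR, and triplets carrying an extra novel agent). The rule list
#' is data, not code: rows can be reordered or replaced, and
#' [classify_regimen()] applies whatever list it is given.
#'
#' Each row matches when the agent set contains every agent in `required`
#' (a `+`-separated list; the token `ALKYLATOR` matches any one alkylating
#' agent) and contains nothing outside `required` plus `allowed_extra`.
#'
#' @param path optional path to a CSV with columns
#'   `label,required,allowed_extra`; defaults to the rule file shipped with
#'   the package.
#' @return a tibble of ordered rules.
#' @export
regimen_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "regimen_rules.csv", package = "mmlot")
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = character()) |>
    dplyr::mutate(rule_id = dplyr::row_number())
}

split_agents <- function(x) {
  if (is.na(x) || x == "") character() else strsplit(x, "+", fixed = TRUE)[[1]]
}

rule_matches <- function(agents, required, allowed_extra,
                         alkylators = alkylator_agents()) {
  req <- split_agents(required)
  extra <- split_agents(allowed_extra)
  wants_alk <- "ALKYLATOR" %in% req
  req <- setdiff(req, "ALKYLATOR")
  if (!all(req %in% agents)) return(FALSE)
  if (wants_alk && !any(agents %in% alkylators)) return(FALSE)
  allowed <- c(req, extra, if (wants_alk) alkylators)
  all(agents %in% allowed)
}

#' Classify a regimen agent set
#'
#' Applies the ordered rule list and returns the label of the first matching
#' rule; an agent set matching no rule is `other`. Classification is
#' deterministic and invariant to the order in which agents are listed.
#' Agents absent from the dictionary are tolerated (they simply fail every
#' specific rule, yielding `other`) with a warning.
#'
#' @param agents character vector of canonical agent codes (one regimen), or
#'   a list of such vectors.
#' @param rules a [regimen_rules()] tibble.
#' @param dict an [agent_dictionary()] tibble.
#' @return for a single agent vector, a tibble with `label` and
#'   `matched_rule`; for a list, one row per element.
#' @export
#' @examples
#' classify_regimen(c("dexamethasone", "bortezomib"))$label # "Vd"
classify_regimen <- function(agents, rules = regimen_rules(),
                             dict = agent_dictionary()) {
  if (!is.list(agents)) agents <- list(agents)
  alks <- alkylator_agents(dict)
  unknown <- setdiff(unique(unlist(agents)), dict$agent)
  if (length(unknown) > 0) {
    rlang::warn(sprintf("unknown agent(s) %s classified under `other`",
                        paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(agents, function(set) {
    stopifnot(length(set) > 0)
    set <- unique(set)
    for (i in seq_len(nrow(rules))) {
      if (rule_matches(set, rules$required[i], rules$allowed_extra[i], alks)) {
        return(tibble::tibble(label = rules$label[i],
                              matched_rule = paste0("rule_", rules$rule_id[i])))
      }
    }
    tibble::tibble(label = "other", matched_rule = "fallback")
  })
}

# Agent sets used by the synthetic generator to realize each regimen
# category as concrete drug claims.
regimen_category_agents <- function() {
  list(
    Vd            = c("bortezomib", "dexamethasone"),
    Rd            = c("lenalidomide", "dexamethasone"),
    VRd           = c("bortezomib", "lenalidomide", "dexamethasone"),
    `V/alkylator` = c("bortezomib", "cyclophosphamide", "dexamethasone"),
    V             = "bortezomib",
    R             = "lenalidomide",
    T             = "thalidomide",
    other         = c("thalidomide", "dexamethasone")
  )
}
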