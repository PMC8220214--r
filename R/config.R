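# Configuration: a single nested list (class cua_config) mirrors the YAML
# run file.  Loading validates every section up front and reports ALL
# schema violations, not just the first.

.num_or_null <- function(x) if (is.null(x) || all(is.na(x))) NULL else x

.as_pair <- function(x) {
  if (is.list(x)) x <- unlist(x)
  as.numeric(x)
}

# --- builders: config section -> validated domain object -----------------

build_cohort_spec <- function(cc) {
  cohort_spec(
    n_patients = cc$n_patients,
    age = .as_pair(cc$age), duration = .as_pair(cc$duration),
    hba1c = .as_pair(cc$hba1c), bmi = .as_pair(cc$bmi),
    sbp = .as_pair(cc$sbp), dbp = .as_pair(cc$dbp),
    tc = .as_pair(cc$tc), hdl = .as_pair(cc$hdl),
    ldl = .as_pair(cc$ldl), tg = .as_pair(cc$tg),
    egfr = .as_pair(cc$egfr),
    female = cc$female,
    race = unlist(cc$race),
    smoking_current = cc$smoking_current,
    history = unlist(cc$history))
}

build_profile <- function(pc) {
  treatment_profile(
    label = pc$label,
    deltas = lapply(pc$deltas, .as_pair),
    annual_drug_cost = pc$annual_drug_cost,
    treatment_time = pc$treatment_time,
    post_treatment_annual_cost = pc$post_treatment_annual_cost,
    lipid_delta_unit = pc$lipid_delta_unit %||% "percent",
    post_treatment_effect = pc$post_treatment_effect %||% "hold")
}

build_cost_table <- function(cc) {
  events <- lapply(cc$events, function(e) {
    list(fatal = if (is.null(e$fatal)) NA else e$fatal,
         nonfatal = e$nonfatal, subsequent = e$subsequent)
  })
  cost_table(management = cc$management, events = events)
}

build_utility_table <- function(uc) {
  utility_table(initial = uc$initial, events = uc$events)
}

build_econ_settings <- function(ec) {
  econ_settings(discount_rate = ec$discount_rate %||% 0.05,
                wtp = ec$wtp,
                wtp_3x = .num_or_null(ec$wtp_3x),
                currency = ec$currency %||% "USD",
                cny_per_usd = ec$cny_per_usd %||% 6.8)
}

build_sim_settings <- function(sc, seed) {
  sim_settings(horizon_years = sc$horizon,
               seed = seed,
               event_order = if (is.null(sc$event_order)) .events
                             else unlist(sc$event_order))
}

build_equations <- function(qc, dir = NULL) {
  f <- qc$file
  if (is.null(f) || !nzchar(f)) return(synthetic_risk_equations())
  if (!file.exists(f) && !is.null(dir)) f <- file.path(dir, qc$file)
  read_risk_equations(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build all domain objects from a run configuration
#'
#' @param config a `cua_config` nested list ([default_config()] or
#'   [load_config()]).
#' @return list with `spec`, `profiles` (intervention/comparator),
#'   `equations`, `costs`, `utilities`, `econ`, `sim`.
#' @export
build_inputs <- function(config) {
  list(spec = build_cohort_spec(config$cohort),
       profiles = list(
         intervention = build_profile(config$profiles$intervention),
         comparator = build_profile(config$profiles$comparator)),
       equations = build_equations(config$equations %||% list(file = NULL),
                                   attr(config, "dir")),
       costs = build_cost_table(config$costs),
       utilities = build_utility_table(config$utilities),
       econ = build_econ_settings(config$econ),
       sim = build_sim_settings(config$sim, config$seed %||% 1))
}

#' Validate a run configuration
#'
#' Checks that every required section is present and that each section
#' builds a valid domain object; returns the full list of violations
#' (empty when valid) rather than failing at the first.
#'
#' @param config a nested list.
#' @return character vector of violation messages (with key paths).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  need <- c("cohort", "profiles", "costs", "utilities", "econ", "sim")
  for (s in need) {
    if (is.null(config[[s]])) errs <- c(errs, paste0(s, ": section missing"))
  }
  if (!is.null(config$profiles)) {
    for (p in c("intervention", "comparator")) {
      if (is.null(config$profiles[[p]])) {
        errs <- c(errs, paste0("profiles.", p, ": section missing"))
      }
    }
  }
  if (length(errs)) return(errs)
  try_build <- function(section, fn) {
    tryCatch({ fn(); character(0) },
             error = function(e) paste0(section, ": ",
                                        conditionMessage(e)))
  }
  c(try_build("cohort", function() build_cohort_spec(config$cohort)),
    try_build("profiles.intervention",
              function() build_profile(config$profiles$intervention)),
    try_build("profiles.comparator",
              function() build_profile(config$profiles$comparator)),
    try_build("equations",
              function() build_equations(config$equations %||%
                                           list(file = NULL),
                                         attr(config, "dir"))),
    try_build("costs", function() build_cost_table(config$costs)),
    try_build("utilities",
              function() build_utility_table(config$utilities)),
    try_build("econ",
              function() suppressMessages(
                build_econ_settings(config$econ))),
    try_build("sim",
              function() build_sim_settings(config$sim,
                                            config$seed %||% 1)))
}

#' Load and validate a YAML run configuration
#'
#' Reads the nested key-value run file, validates every section, and fails
#' with the complete list of schema violations if any.  Relative equation
#' file paths resolve against the config file's directory.
#'
#' @param path YAML file path.
#' @return a validated `cua_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config <- yaml::read_yaml(path)
  class(config) <- c("cua_config", "list")
  attr(config, "dir") <- dirname(normalizePath(path))
  errs <- validate_config(config)
  if (length(errs)) {
    stop("config validation failed:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  config
}

#' Write a run configuration to YAML
#'
#' @param config a `cua_config` list.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  x <- config
  attributes(x) <- list(names = names(x))
  yaml::write_yaml(x, path)
  invisible(path)
}
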