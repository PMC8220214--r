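# Shipped base-case inputs: the published cohort summary statistics,
# 52-week treatment-effect profiles, complication cost/utility tables,
# thresholds — and a synthetic stand-in risk-equation set.

#' Default baseline cohort specification
#'
#' The published simulation cohort: mean (SD) age 56 (10.3) years, diabetes
#' duration 7 (5.9) years, HbA1c 8.2 (1.0)%, BMI 32.8 (6.7) kg/m^2, SBP
#' 131.41 (14.6) / DBP 80.01 (9.5) mmHg, TC 4.75 (1.09), HDL 1.20 (0.30),
#' LDL 2.64 (0.88), TG 2.12 (1.55) mmol/L, eGFR 97.35 (15.34); 48% female,
#' 14.22% current smokers; history proportions MI 4%, angina 2%, PVD 1%,
#' renal complications 0.5%, microalbuminuria 0.5% (both reported only as
#' "under 1%"; encoded as the 0.5% midpoint), background retinopathy 8%.
#'
#' @param n_patients cohort size per arm (default 1000).
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(n_patients = 1000) {
  cohort_spec(
    n_patients = n_patients,
    age = c(56, 10.3), duration = c(7, 5.9), hba1c = c(8.2, 1.0),
    bmi = c(32.8, 6.7), sbp = c(131.41, 14.6), dbp = c(80.01, 9.5),
    tc = c(4.75, 1.09), hdl = c(1.20, 0.30), ldl = c(2.64, 0.88),
    tg = c(2.12, 1.55), egfr = c(97.35, 15.34),
    female = 0.48,
    race = c(white = 0.77, black = 0.0684, asian = 0.14,
             amerindian = 0.0025, other = 0.0191),
    smoking_current = 0.1422,
    history = c(mi = 0.04, angina = 0.02, pvd = 0.01, renal = 0.005,
                microalbuminuria = 0.005, retinopathy = 0.08))
}

#' Default treatment profiles
#'
#' 52-week mean (SD) changes from baseline for the once-weekly semaglutide
#' and once-daily empagliflozin arms.  HbA1c (%), SBP/DBP (mmHg), BMI
#' (kg/m^2) and eGFR (ml/min/1.73m^2) deltas are absolute; lipid deltas are
#' interpreted as percent change from baseline (the published magnitudes,
#' e.g. TC -6.15, are implausible as mmol/L shifts — the chosen unit
#' interpretation is recorded on the profile and switchable).  Both arms
#' default to the comparator's annual drug cost ($558.2/year), a 5-year
#' treatment time, and a post-treatment basal-insulin cost equal to the
#' comparator-era annual therapy cost (configurable; the published analysis
#' does not state it).
#'
#' @param intervention_price,comparator_price annual drug costs.
#' @param treatment_time years on treatment before the basal-insulin switch.
#' @param insulin_cost annual post-treatment therapy cost.
#' @return list with elements `intervention` and `comparator`.
#' @export
default_profiles <- function(intervention_price = 558.2,
                             comparator_price = 558.2,
                             treatment_time = 5,
                             insulin_cost = 558.2) {
  list(
    intervention = treatment_profile(
      label = "semaglutide",
      deltas = list(hba1c = c(-1.44, 0.03), sbp = c(-4.11, 0.36),
                    dbp = c(-1.27, 0.23), tc = c(-6.15, 0.90),
                    hdl = c(1.53, 0.22), ldl = c(-2.48, 0.77),
                    tg = c(-31.16, 3.36), bmi = c(-1.92, 0.06),
                    egfr = c(0.15, 0.23)),
      annual_drug_cost = intervention_price,
      treatment_time = treatment_time,
      post_treatment_annual_cost = insulin_cost,
      lipid_delta_unit = "percent"),
    comparator = treatment_profile(
      label = "empagliflozin",
      deltas = list(hba1c = c(-0.83, 0.05), sbp = c(-4.48, 0.56),
                    dbp = c(-2.39, 0.37), tc = c(4.14, 1.39),
                    hdl = c(2.63, 0.34), ldl = c(4.18, 1.19),
                    tg = c(-15.13, 5.17), bmi = c(-1.32, 0.09),
                    egfr = c(-0.06, 0.37)),
      annual_drug_cost = comparator_price,
      treatment_time = treatment_time,
      post_treatment_annual_cost = insulin_cost,
      lipid_delta_unit = "percent"))
}

#' Default complication cost table (2019 USD)
#'
#' Event-year (fatal / non-fatal) and subsequent-year costs per
#' complication, plus the $1,427.10 annual management cost in the absence
#' of complications.  Blindness and ulcer have no fatal-cost variant.
#'
#' @return a [cost_table()].
#' @export
default_cost_table <- function() {
  cost_table(
    management = 1427.10,
    events = list(
      ihd        = list(fatal = 0,       nonfatal = 6293.30,  subsequent = 1123.51),
      mi         = list(fatal = 7855.14, nonfatal = 7855.14,  subsequent = 484.52),
      chf        = list(fatal = 3033.73, nonfatal = 3033.73,  subsequent = 1604.12),
      stroke     = list(fatal = 2266.31, nonfatal = 3059.07,  subsequent = 539.32),
      amputation = list(fatal = 4434.60, nonfatal = 4434.60,  subsequent = 4316.66),
      blindness  = list(fatal = NA,      nonfatal = 2361.49,  subsequent = 1747.01),
      renal      = list(fatal = 0,       nonfatal = 14685.91, subsequent = 14685.91),
      ulcer      = list(fatal = NA,      nonfatal = 2310.00,  subsequent = 813.01)))
}

#' Default health-utility table
#'
#' Initial utility 0.876 without complications; per-event decrements
#' (positive magnitudes) in the event year and subsequent years.
#'
#' @return a [utility_table()].
#' @export
default_utility_table <- function() {
  utility_table(
    initial = 0.876,
    events = list(
      ihd        = list(event = 0.090, subsequent = 0.090),
      mi         = list(event = 0.055, subsequent = 0.236),
      chf        = list(event = 0.236, subsequent = 0.236),
      stroke     = list(event = 0.164, subsequent = 0.326),
      amputation = list(event = 0.380, subsequent = 0.380),
      blindness  = list(event = 0.157, subsequent = 0.157),
      renal      = list(event = 0.400, subsequent = 0.400),
      ulcer      = list(event = 0.059, subsequent = 0.059)))
}

#' Synthetic stand-in risk-equation set
#'
#' A complete, internally consistent equation set with plausible magnitudes:
#' all-cause mortality rising steeply with attained age (Gompertz),
#' HbA1c-sensitive coronary/MI hazards, duration-driven retinopathy
#' progression (Weibull), eGFR-protective renal failure.  These are NOT
#' published UKPDS 82 estimates (which are not reproduced here); absolute
#' life-expectancy, QALY and cost magnitudes produced with this set are
#' illustrative only.  Substantive analyses should supply a coefficient
#' file via [read_risk_equations()].
#'
#' @return a [risk_equations()] set.
#' @export
synthetic_risk_equations <- function() {
  risk_equations(list(
    risk_equation("ihd", "logistic",
                  c(intercept = -8.8, hba1c = 0.25, age = 0.035,
                    sbp = 0.005, female = -0.2)),
    risk_equation("mi", "cloglog",
                  c(intercept = -9.5, hba1c = 0.30, age = 0.04,
                    smoker = 0.4, hist_mi = 0.8), recurrent = TRUE),
    risk_equation("chf", "cloglog",
                  c(intercept = -10.5, age = 0.07, bmi = 0.04)),
    risk_equation("stroke", "cloglog",
                  c(intercept = -10.0, age = 0.055, sbp = 0.012,
                    hba1c = 0.12), recurrent = TRUE),
    risk_equation("amputation", "logistic",
                  c(intercept = -9.5, hba1c = 0.35, duration = 0.03,
                    hist_pvd = 1.0)),
    risk_equation("blindness", "weibull",
                  c(intercept = -8.0, hba1c = 0.20, hist_retinopathy = 0.7),
                  shape = 1.4),
    risk_equation("renal", "logistic",
                  c(intercept = -4.2, egfr = -0.03, duration = 0.04,
                    hist_microalbuminuria = 1.2, hist_renal = 1.0)),
    risk_equation("ulcer", "logistic",
                  c(intercept = -7.8, hba1c = 0.15, hist_pvd = 0.8,
                    duration = 0.02), recurrent = TRUE),
    risk_equation("death", "gompertz",
                  c(intercept = -9.8, age = 0.088, hba1c = 0.06,
                    hist_mi = 0.3, prior_mi = 0.4, prior_stroke = 0.4,
                    prior_chf = 0.5, prior_renal = 0.9))))
}

#' Default nested run configuration
#'
#' The complete base-case configuration as a plain nested list (the same
#' shape [load_config()] reads from YAML): cohort summary statistics, the
#' two arm profiles at equal annual drug cost ($558.2/year), cost/utility
#' tables, thresholds (lambda = $10,425.29/QALY), 5% discounting over a
#' 40-year horizon, and the synthetic risk-equation set (referenced as
#' `equations$file = NULL`, meaning [synthetic_risk_equations()]).
#'
#' @param n_patients cohort size per arm.
#' @param seed master seed.
#' @return a nested list of class `cua_config`.
#' @export
default_config <- function(n_patients = 1000, seed = 1) {
  cfg <- list(
    seed = seed,
    cohort = list(
      n_patients = n_patients,
      age = c(56, 10.3), duration = c(7, 5.9), hba1c = c(8.2, 1.0),
      bmi = c(32.8, 6.7), sbp = c(131.41, 14.6), dbp = c(80.01, 9.5),
      tc = c(4.75, 1.09), hdl = c(1.20, 0.30), ldl = c(2.64, 0.88),
      tg = c(2.12, 1.55), egfr = c(97.35, 15.34),
      female = 0.48,
      race = list(white = 0.77, black = 0.0684, asian = 0.14,
                  amerindian = 0.0025, other = 0.0191),
      smoking_current = 0.1422,
      history = list(mi = 0.04, angina = 0.02, pvd = 0.01, renal = 0.005,
                     microalbuminuria = 0.005, retinopathy = 0.08)),
    profiles = list(
      intervention = list(
        label = "semaglutide", annual_drug_cost = 558.2,
        treatment_time = 5, post_treatment_annual_cost = 558.2,
        lipid_delta_unit = "percent", post_treatment_effect = "hold",
        deltas = list(hba1c = c(-1.44, 0.03), sbp = c(-4.11, 0.36),
                      dbp = c(-1.27, 0.23), tc = c(-6.15, 0.90),
                      hdl = c(1.53, 0.22), ldl = c(-2.48, 0.77),
                      tg = c(-31.16, 3.36), bmi = c(-1.92, 0.06),
                      egfr = c(0.15, 0.23))),
      comparator = list(
        label = "empagliflozin", annual_drug_cost = 558.2,
        treatment_time = 5, post_treatment_annual_cost = 558.2,
        lipid_delta_unit = "percent", post_treatment_effect = "hold",
        deltas = list(hba1c = c(-0.83, 0.05), sbp = c(-4.48, 0.56),
                      dbp = c(-2.39, 0.37), tc = c(4.14, 1.39),
                      hdl = c(2.63, 0.34), ldl = c(4.18, 1.19),
                      tg = c(-15.13, 5.17), bmi = c(-1.32, 0.09),
                      egfr = c(-0.06, 0.37)))),
    equations = list(file = NULL),
    costs = list(
      management = 1427.10,
      events = list(
        ihd        = list(fatal = 0,       nonfatal = 6293.30,  subsequent = 1123.51),
        mi         = list(fatal = 7855.14, nonfatal = 7855.14,  subsequent = 484.52),
        chf        = list(fatal = 3033.73, nonfatal = 3033.73,  subsequent = 1604.12),
        stroke     = list(fatal = 2266.31, nonfatal = 3059.07,  subsequent = 539.32),
        amputation = list(fatal = 4434.60, nonfatal = 4434.60,  subsequent = 4316.66),
        blindness  = list(fatal = NA,      nonfatal = 2361.49,  subsequent = 1747.01),
        renal      = list(fatal = 0,       nonfatal = 14685.91, subsequent = 14685.91),
        ulcer      = list(fatal = NA,      nonfatal = 2310.00,  subsequent = 813.01))),
    utilities = list(
      initial = 0.876,
      events = list(
        ihd        = list(event = 0.090, subsequent = 0.090),
        mi         = list(event = 0.055, subsequent = 0.236),
        chf        = list(event = 0.236, subsequent = 0.236),
        stroke     = list(event = 0.164, subsequent = 0.326),
        amputation = list(event = 0.380, subsequent = 0.380),
        blindness  = list(event = 0.157, subsequent = 0.157),
        renal      = list(event = 0.400, subsequent = 0.400),
        ulcer      = list(event = 0.059, subsequent = 0.059))),
    econ = list(discount_rate = 0.05, wtp = 10425.29, wtp_3x = NULL,
                currency = "USD", cny_per_usd = 6.8),
    sim = list(horizon = 40,
               event_order = c("ihd", "mi", "chf", "stroke", "amputation",
                               "blindness", "renal", "ulcer")))
  class(cfg) <- c("cua_config", "list")
  cfg
}
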