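# Baseline cohort synthesis: generate patient-level records whose sample
# moments match published summary statistics (means/SDs for continuous risk
# factors, proportions for binary traits), and attach per-arm treatment
# profiles for common-random-numbers comparison.

# Continuous baseline variables, in fixed sampling order, with hard
# physiological floors.  Truncation is at mean +/- 4 SD intersected with the
# floor, so impossible values (negative lipids, HbA1c below the assay range)
# can never be drawn.
.cont_vars <- c("age", "duration", "hba1c", "bmi", "sbp", "dbp",
                "tc", "hdl", "ldl", "tg", "egfr")
.cont_floors <- c(age = 18, duration = 0, hba1c = 3, bmi = 10, sbp = 50,
                  dbp = 30, tc = 0.05, hdl = 0.05, ldl = 0.05, tg = 0.05,
                  egfr = 1)
.hist_flags <- c("mi", "angina", "pvd", "renal", "microalbuminuria",
                 "retinopathy")

#' Baseline cohort specification
#'
#' Summary statistics from which a synthetic patient-level cohort is drawn:
#' mean/SD pairs for the continuous risk factors, and proportions for sex,
#' race, smoking and pre-existing event history.  Continuous units: age and
#' diabetes duration in years, HbA1c in %, BMI in kg/m^2, SBP/DBP in mmHg,
#' lipids (TC, HDL, LDL, TG) in mmol/L, eGFR in ml/min/1.73m^2.
#'
#' @param n_patients number of patients to simulate per arm.
#' @param age,duration,hba1c,bmi,sbp,dbp,tc,hdl,ldl,tg,egfr numeric
#'   `c(mean, sd)` pairs.
#' @param female proportion female in `[0, 1]`.
#' @param race named numeric vector of race proportions summing to at most 1;
#'   any remainder is assigned to a catch-all `"other"` category.  Race is
#'   carried through as a categorical tag for risk-equation files that
#'   consume it; the shipped synthetic equations do not.
#' @param smoking_current proportion of current smokers.
#' @param history named proportions of pre-existing events, names among
#'   `mi`, `angina`, `pvd`, `renal`, `microalbuminuria`, `retinopathy`.
#' @return an object of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the shipped base-case values,
#'   [sample_cohort()] to draw patients.
#' @export
cohort_spec <- function(n_patients,
                        age, duration, hba1c, bmi, sbp, dbp,
                        tc, hdl, ldl, tg, egfr,
                        female, race, smoking_current, history) {
  v <- new_validator()
  v$check(is_number(n_patients) && n_patients >= 1, "n_patients",
          "must be a single number >= 1")
  cont <- list(age = age, duration = duration, hba1c = hba1c, bmi = bmi,
               sbp = sbp, dbp = dbp, tc = tc, hdl = hdl, ldl = ldl,
               tg = tg, egfr = egfr)
  for (nm in names(cont)) {
    x <- cont[[nm]]
    ok <- is.numeric(x) && length(x) == 2L && all(is.finite(x)) && x[2] >= 0
    v$check(ok, nm, "must be c(mean, sd) with sd >= 0")
    if (ok) cont[[nm]] <- c(mean = unname(x[1]), sd = unname(x[2]))
  }
  v$check(is_prob(female), "female", "must be a proportion in [0, 1]")
  v$check(is.numeric(race) && length(names(race)) == length(race) &&
            all(race >= 0) && sum(race) <= 1 + 1e-9, "race",
          "must be named non-negative proportions summing to <= 1")
  v$check(is_prob(smoking_current), "smoking_current",
          "must be a proportion in [0, 1]")
  v$check(is.numeric(history) && all(.hist_flags %in% names(history)) &&
            all(history >= 0 & history <= 1), "history",
          paste("must be proportions in [0, 1] named:",
                paste(.hist_flags, collapse = ", ")))
  v$stop_if_any("cohort_spec")

  race <- race[race > 0 | names(race) == "other"]
  rem <- 1 - sum(race)
  if (rem > 1e-9) {
    race[["other"]] <- if (is.na(race["other"])) rem else race[["other"]] + rem
  }
  structure(list(n_patients = as.integer(n_patients),
                 continuous = cont,
                 female = female, race = race / sum(race),
                 smoking_current = smoking_current,
                 history = history[.hist_flags]),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Baseline cohort specification:", x$n_patients, "patients\n")
  m <- vapply(x$continuous, `[[`, numeric(1), "mean")
  s <- vapply(x$continuous, `[[`, numeric(1), "sd")
  print(round(data.frame(mean = m, sd = s), 3))
  cat("female:", x$female, " smoking (current):", x$smoking_current, "\n")
  cat("history:", paste(names(x$history), signif(x$history, 3),
                        sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Treatment arm profile
#'
#' One arm's 52-week effect deltas (mean and SD) on the modifiable risk
#' factors, its annual drug acquisition cost, treatment duration, and the
#' annual cost of the basal-insulin therapy assumed to follow treatment.
#'
#' Glycaemic/pressure/weight/renal deltas (`hba1c`, `sbp`, `dbp`, `bmi`,
#' `egfr`) are absolute changes in the variable's units.  Lipid deltas
#' (`tc`, `hdl`, `ldl`, `tg`) are interpreted according to
#' `lipid_delta_unit`: `"percent"` (default) applies them as percent change
#' from baseline, `"absolute"` as mmol/L shifts.
#'
#' @param label arm name.
#' @param deltas named list of `c(mean, sd)` effect deltas; any subset of
#'   `hba1c, sbp, dbp, tc, hdl, ldl, tg, bmi, egfr`.
#' @param annual_drug_cost annual drug acquisition cost (currency/year).
#' @param treatment_time on-treatment duration in years (then switch to
#'   basal insulin).
#' @param post_treatment_annual_cost annual cost of post-switch therapy.
#' @param lipid_delta_unit `"percent"` or `"absolute"`.
#' @param post_treatment_effect `"hold"` keeps the treatment deltas in force
#'   after the switch; `"revert"` removes them.
#' @return an object of class `treatment_profile`.
#' @export
treatment_profile <- function(label, deltas = list(),
                              annual_drug_cost,
                              treatment_time = 5,
                              post_treatment_annual_cost = annual_drug_cost,
                              lipid_delta_unit = c("percent", "absolute"),
                              post_treatment_effect = c("hold", "revert")) {
  lipid_delta_unit <- match.arg(lipid_delta_unit)
  post_treatment_effect <- match.arg(post_treatment_effect)
  v <- new_validator()
  v$check(is.character(label) && length(label) == 1L, "label",
          "must be a single string")
  v$check(is_number(annual_drug_cost) && annual_drug_cost >= 0,
          "annual_drug_cost", "must be a single number >= 0")
  v$check(is_number(treatment_time) && treatment_time >= 0,
          "treatment_time", "must be a single number >= 0")
  v$check(is_number(post_treatment_annual_cost) &&
            post_treatment_annual_cost >= 0,
          "post_treatment_annual_cost", "must be a single number >= 0")
  allowed <- setdiff(.cont_vars, c("age", "duration"))
  for (nm in names(deltas)) {
    v$check(nm %in% allowed, paste0("deltas.", nm),
            paste("unknown risk factor; allowed:",
                  paste(allowed, collapse = ", ")))
    x <- deltas[[nm]]
    ok <- is.numeric(x) && length(x) %in% 1:2 && all(is.finite(x))
    v$check(ok, paste0("deltas.", nm), "must be c(mean) or c(mean, sd)")
    if (ok) deltas[[nm]] <- c(mean = unname(x[1]),
                              sd = if (length(x) == 2L) unname(x[2]) else 0)
  }
  v$stop_if_any("treatment_profile")
  structure(list(label = label, deltas = deltas,
                 annual_drug_cost = annual_drug_cost,
                 treatment_time = treatment_time,
                 post_treatment_annual_cost = post_treatment_annual_cost,
                 lipid_delta_unit = lipid_delta_unit,
                 post_treatment_effect = post_treatment_effect),
            class = "treatment_profile")
}

#' @export
print.treatment_profile <- function(x, ...) {
  cat("Treatment profile:", x$label, "\n")
  cat("  annual drug cost:", x$annual_drug_cost,
      " treatment time:", x$treatment_time, "y",
      " post-treatment cost:", x$post_treatment_annual_cost, "\n")
  if (length(x$deltas)) {
    d <- vapply(x$deltas, `[[`, numeric(1), "mean")
    cat("  deltas:", paste(names(d), d, sep = "=", collapse = " "),
        sprintf("(lipids as %s)\n", x$lipid_delta_unit))
  }
  invisible(x)
}

#' Draw a synthetic patient-level cohort
#'
#' Samples `spec$n_patients` baseline records.  Continuous risk factors are
#' drawn from normal distributions truncated at mean +/- 4 SD and at hard
#' physiological floors (e.g. HbA1c >= 3%, eGFR >= 1, BMI >= 10); the
#' underlying normal parameters are calibrated so that the truncated
#' distribution reproduces the specified mean and SD (a noticeable
#' correction only where a floor sits close to the mean, e.g. diabetes
#' duration).  Binary traits are Bernoulli with the specified proportions;
#' race is categorical.  Sampling is fully determined by `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed master integer seed; the baseline stream is derived from it.
#' @return a `data.frame` of class `cohort`, one row per patient, columns
#'   `id`, the continuous variables, `female`, `race`, `smoker`, and the
#'   `hist_*` flags (0/1).
#' @export
sample_cohort <- function(spec, seed) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  stopifnot(is_number(seed))
  n <- spec$n_patients
  set.seed(derive_seed(seed, "baseline"))
  cols <- list(id = seq_len(n))
  for (nm in .cont_vars) {
    p <- spec$continuous[[nm]]
    lo <- max(p["mean"] - 4 * p["sd"], .cont_floors[[nm]])
    hi <- max(p["mean"] + 4 * p["sd"], lo)
    if (p[["sd"]] > 0) {
      # calibrate the underlying normal so the truncated draw recovers the
      # published mean/SD despite the physiological floor
      par <- .match_truncnorm(p[["mean"]], p[["sd"]], lo, hi)
      cols[[nm]] <- rtruncnorm(n, par[["mu"]], par[["sigma"]], lo, hi)
    } else {
      cols[[nm]] <- rtruncnorm(n, p[["mean"]], 0, lo, hi)
    }
  }
  cols$female <- as.integer(stats::runif(n) < spec$female)
  cols$race <- sample(names(spec$race), n, replace = TRUE, prob = spec$race)
  cols$smoker <- as.integer(stats::runif(n) < spec$smoking_current)
  for (nm in .hist_flags) {
    cols[[paste0("hist_", nm)]] <-
      as.integer(stats::runif(n) < spec$history[[nm]])
  }
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Pair two treatment arms over one baseline cohort
#'
#' Both arms reference the same patients and, downstream, the same
#' per-patient random streams; only the treatment profile differs, so any
#' outcome difference is attributable to the profiles (common random
#' numbers).
#'
#' @param cohort a `cohort` from [sample_cohort()].
#' @param profile_a,profile_b [treatment_profile()]s for the intervention
#'   and comparator arm.
#' @return an object of class `paired_arms`.
#' @export
make_paired_arms <- function(cohort, profile_a, profile_b) {
  stopifnot(inherits(cohort, "cohort"),
            inherits(profile_a, "treatment_profile"),
            inherits(profile_b, "treatment_profile"))
  structure(list(cohort = cohort,
                 intervention = profile_a,
                 comparator = profile_b),
            class = "paired_arms")
}

#' Write / read a cohort as CSV
#'
#' One row per patient.  Columns: `id`; continuous baselines
#' `age, duration, hba1c, bmi, sbp, dbp, tc, hdl, ldl, tg, egfr`
#' (units as in [cohort_spec()]); `female`, `smoker` and `hist_*` as 0/1;
#' `race` as a category label.
#'
#' @param cohort a `cohort` data frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "data.frame"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", .cont_vars, "female", "race", "smoker",
            paste0("hist_", .hist_flags))
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop("cohort CSV missing columns: ", paste(miss, collapse = ", "))
  }
  class(out) <- c("cohort", "data.frame")
  out
}
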