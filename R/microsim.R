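# Annual-cycle semi-Markov patient-level simulation.  Each patient-year-event
# combination consumes one uniform draw from a stream keyed only by
# (master seed, patient id), with a fixed canonical layout, so two arms or
# two price points with identical risk dynamics replay identical histories
# (common random numbers).

.max_horizon <- 70L
.draw_events <- c(.events, "death")  # canonical uniform-layout order

#' Simulation settings
#'
#' @param horizon_years time horizon in annual cycles (1..70).
#' @param seed master integer seed driving every stream in the run.
#' @param event_order within-year evaluation order; a permutation of the
#'   eight complication events.  Death is always evaluated last.
#' @return an object of class `sim_settings`.
#' @export
sim_settings <- function(horizon_years = 40, seed = 1,
                         event_order = .events) {
  v <- new_validator()
  v$check(is_number(horizon_years) && horizon_years >= 1 &&
            horizon_years <= .max_horizon, "horizon_years",
          "must be in [1, 70]")
  v$check(is_number(seed), "seed", "must be a single number")
  v$check(is.character(event_order) && setequal(event_order, .events) &&
            !anyDuplicated(event_order), "event_order",
          paste("must be a permutation of:", paste(.events, collapse = ", ")))
  v$stop_if_any("sim_settings")
  structure(list(horizon = as.integer(horizon_years),
                 cycle_length = 1L,
                 seed = as.integer(seed),
                 event_order = event_order),
            class = "sim_settings")
}

# One patient's uniform draws: rows = years 1..70, columns = canonical
# events (8 complications then death).  Depends only on (seed, patient id),
# never on horizon or evaluation order.
.patient_uniforms <- function(seed, patient_id) {
  set.seed(derive_seed(seed, "events", patient_id))
  matrix(stats::runif(.max_horizon * length(.draw_events)),
         nrow = .max_horizon, ncol = length(.draw_events),
         dimnames = list(NULL, .draw_events))
}

# Uniform array for a cohort: n x 70 x 9.
.cohort_uniforms <- function(seed, ids) {
  n <- length(ids)
  U <- array(NA_real_, dim = c(n, .max_horizon, length(.draw_events)),
             dimnames = list(NULL, NULL, .draw_events))
  for (i in seq_len(n)) U[i, , ] <- .patient_uniforms(seed, ids[[i]])
  U
}

# Numeric state matrix from a cohort data frame: continuous baselines,
# binary traits, race dummies, and prior_* simulated-event flags (init 0).
.state_matrix <- function(cohort) {
  n <- nrow(cohort)
  base_cols <- c(.cont_vars, "female", "smoker", paste0("hist_", .hist_flags))
  m <- as.matrix(as.data.frame(cohort)[, base_cols])
  races <- sort(unique(cohort$race))
  rd <- vapply(races, function(r) as.numeric(cohort$race == r), numeric(n))
  if (n == 1L) rd <- matrix(rd, nrow = 1)
  colnames(rd) <- paste0("race_", races)
  pr <- matrix(0, n, length(.events),
               dimnames = list(NULL, paste0("prior_", .events)))
  cbind(m, rd, pr)
}

# Core vectorized loop shared by simulate_arm()/simulate_patient().
.simulate_impl <- function(state0, profile, equations, settings, U,
                           rules = trajectory_rule()) {
  n <- nrow(state0)
  H <- settings$horizon
  ev_idx <- match(settings$event_order, .events)
  inc <- array(FALSE, dim = c(n, H, length(.events)),
               dimnames = list(NULL, NULL, .events))
  first_year <- matrix(NA_integer_, n, length(.events),
                       dimnames = list(NULL, .events))
  death_year <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  state <- state0
  for (y in seq_len(H)) {
    state <- .update_state(state, y, profile, rules)
    occ_year <- matrix(FALSE, n, length(.events))
    for (e in ev_idx) {
      ev <- .events[[e]]
      eq <- equations[[ev]]
      if (is.null(eq)) next  # event not modelled by this equation set
      eligible <- alive & (eq$recurrent | is.na(first_year[, e]))
      if (!any(eligible)) next
      p <- .risk_prob(eq, state)
      occ <- eligible & (U[, y, ev] < p)
      if (any(occ)) {
        occ_year[, e] <- occ
        inc[occ, y, e] <- TRUE
        newf <- occ & is.na(first_year[, e])
        first_year[newf, e] <- y
      }
    }
    pd <- .risk_prob(equations[["death"]], state)
    dead <- alive & (U[, y, "death"] < pd)
    death_year[dead] <- y
    alive <- alive & !dead
    # simulated events feed next year's state as prior_* flags
    for (e in seq_along(.events)) {
      if (any(occ_year[, e])) {
        cn <- paste0("prior_", .events[[e]])
        state[, cn] <- pmax(state[, cn], as.numeric(occ_year[, e]))
      }
    }
    if (!any(alive)) break
  }
  structure(list(inc = inc, first_year = first_year,
                 death_year = death_year,
                 le = ifelse(is.na(death_year), H, death_year),
                 n = n, horizon = H,
                 arm = profile$label,
                 settings = settings),
            class = "arm_history")
}

#' Simulate one treatment arm
#'
#' Runs the annual-cycle simulation for every patient in the cohort: each
#' year, risk factors are updated (treatment deltas in force during years
#' 1..`treatment_time`), the complication events are evaluated in the
#' configured order as conditionally independent Bernoulli draws given the
#' state, then all-cause death; a patient dying in year t still accrues that
#' year's events.  Histories are a pure function of (cohort, risk-relevant
#' profile fields, equations, settings, seed): economic fields such as
#' `annual_drug_cost` never enter.
#'
#' @param cohort a `cohort` from [sample_cohort()].
#' @param profile a [treatment_profile()].
#' @param equations a [risk_equations()] set.
#' @param settings a [sim_settings()].
#' @param rules a [trajectory_rule()].
#' @param uniforms optional precomputed uniform array from an earlier run
#'   with the same seed and cohort (performance cache; contents are
#'   identical to what would be regenerated).
#' @return an object of class `arm_history`: per-patient event incidence,
#'   first-occurrence years, death years and life-years lived.
#' @export
simulate_arm <- function(cohort, profile, equations, settings,
                         rules = trajectory_rule(), uniforms = NULL) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort) >= 1,
            inherits(profile, "treatment_profile"),
            inherits(equations, "risk_equations"),
            inherits(settings, "sim_settings"))
  if (is.null(uniforms)) uniforms <- .cohort_uniforms(settings$seed, cohort$id)
  .simulate_impl(.state_matrix(cohort), profile, equations, settings,
                 uniforms, rules)
}

#' Simulate a single patient
#'
#' Scalar counterpart of [simulate_arm()] for one baseline record, using the
#' same per-patient stream keyed by (seed, patient id).
#'
#' @param patient a one-row `cohort` data frame.
#' @inheritParams simulate_arm
#' @param stream optional 70 x 9 uniform matrix (rows = years, columns =
#'   the eight events then death) overriding the derived stream.
#' @return a list with `events` (data.frame: year, event, fatal),
#'   `death_year` (NA if alive at horizon) and `le` (life-years lived).
#' @export
simulate_patient <- function(patient, profile, equations, settings,
                             rules = trajectory_rule(), stream = NULL) {
  stopifnot(inherits(patient, "data.frame"), nrow(patient) == 1L)
  if (!inherits(patient, "cohort")) class(patient) <- c("cohort", class(patient))
  if (is.null(stream)) stream <- .patient_uniforms(settings$seed, patient$id)
  U <- array(stream, dim = c(1L, dim(stream)),
             dimnames = list(NULL, NULL, colnames(stream)))
  h <- .simulate_impl(.state_matrix(patient), profile, equations, settings,
                      U, rules)
  history_events(h, 1L)
}

#' Extract one patient's event history in long format
#'
#' @param history an `arm_history`.
#' @param i patient index.
#' @return as [simulate_patient()].
#' @export
history_events <- function(history, i) {
  stopifnot(inherits(history, "arm_history"))
  hits <- which(history$inc[i, , , drop = FALSE], arr.ind = TRUE)
  d <- data.frame(year = as.integer(hits[, 2]),
                  event = .events[hits[, 3]],
                  stringsAsFactors = FALSE)
  d <- d[order(d$year, match(d$event, .events)), , drop = FALSE]
  dy <- history$death_year[[i]]
  d$fatal <- !is.na(dy) & d$year == dy
  rownames(d) <- NULL
  list(events = d, death_year = dy, le = history$le[[i]])
}

#' @export
print.arm_history <- function(x, ...) {
  cat("Arm history:", x$arm, "-", x$n, "patients,", x$horizon, "years\n")
  cat("  deaths within horizon:", sum(!is.na(x$death_year)),
      " mean life-years:", round(mean(x$le), 2), "\n")
  cat("  events per patient:",
      round(sum(x$inc) / x$n, 3), "\n")
  invisible(x)
}

#' Export event histories as long-format CSV
#'
#' Columns: `patient_id`, `year`, `event` (complication name or `death`),
#' `fatal` (TRUE when a complication co-occurs with death in the same year).
#'
#' @param history an `arm_history`.
#' @param path file path.
#' @export
write_event_history_csv <- function(history, path) {
  stopifnot(inherits(history, "arm_history"))
  rows <- lapply(seq_len(history$n), function(i) {
    h <- history_events(history, i)
    d <- h$events
    if (!is.na(h$death_year)) {
      d <- rbind(d, data.frame(year = h$death_year, event = "death",
                               fatal = TRUE))
    }
    if (nrow(d)) cbind(patient_id = i, d) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = integer(0), year = integer(0),
                      event = character(0), fatal = logical(0))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
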