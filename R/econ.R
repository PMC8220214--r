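# Economic accrual and cost-utility comparison: convert event histories
# into discounted costs and QALYs, summarize arms, and classify the
# incremental cost-utility ratio against willingness-to-pay thresholds.

#' Complication cost table
#'
#' Per-event costs at the time of the event (fatal vs non-fatal, chosen by
#' whether the event co-occurs with death in that year) and in each
#' subsequent year, plus the annual management cost in the absence of
#' complications.  A missing (`NA`) fatal cost means the event has no fatal
#' variant and the non-fatal cost is always used.  All costs are in the
#' configured currency (2019 USD in the shipped tables).
#'
#' @param management annual diabetes management cost, accrued every alive
#'   year and booked in the complication-cost bucket.
#' @param events named list (one entry per event) of lists with elements
#'   `fatal` (may be `NA`), `nonfatal`, `subsequent`, all `>= 0`.
#' @return an object of class `cost_table`.
#' @export
cost_table <- function(management, events) {
  v <- new_validator()
  v$check(is_number(management) && management >= 0, "management",
          "must be a single number >= 0")
  for (nm in names(events)) {
    e <- events[[nm]]
    for (f in c("fatal", "nonfatal", "subsequent")) {
      x <- e[[f]]
      ok <- (f == "fatal" && length(x) == 1L && is.na(x)) ||
        (is_number(x) && x >= 0)
      v$check(ok, paste0("events.", nm, ".", f),
              "must be a single number >= 0 (fatal may be NA)")
    }
  }
  v$stop_if_any("cost_table")
  structure(list(management = management, events = events),
            class = "cost_table")
}

#' Health-utility table
#'
#' Baseline utility without complications and per-event utility decrements
#' (entered as positive magnitudes) applied in the event's year and in
#' subsequent years.  Decrements combine additively across complications;
#' per-year utility is floored at 0.
#'
#' @param initial initial utility in (0, 1].
#' @param events named list of lists with elements `event` (event-year
#'   decrement) and `subsequent`, both `>= 0`.
#' @return an object of class `utility_table`.
#' @export
utility_table <- function(initial, events) {
  v <- new_validator()
  v$check(is_number(initial) && initial > 0 && initial <= 1, "initial",
          "must be in (0, 1]")
  for (nm in names(events)) {
    for (f in c("event", "subsequent")) {
      x <- events[[nm]][[f]]
      v$check(is_number(x) && x >= 0, paste0("events.", nm, ".", f),
              "must be a single number >= 0")
    }
  }
  v$stop_if_any("utility_table")
  structure(list(initial = initial, events = events),
            class = "utility_table")
}

#' Economic settings
#'
#' Discount rate, willingness-to-pay (WTP) thresholds and currency notes.
#' The primary threshold `wtp` (lambda, currency/QALY) marks "very cost
#' effective"; its multiple `wtp_3x` (3 lambda) marks "cost effective".
#' When `wtp_3x` is supplied and differs from `3 * wtp` by no more than
#' rounding (0.05), the supplied value is kept and a note is emitted.
#'
#' @param discount_rate annual discount rate for costs and utilities
#'   (default 0.05).
#' @param wtp WTP threshold lambda (currency/QALY).
#' @param wtp_3x optional explicit 3-lambda threshold; default `3 * wtp`.
#' @param currency currency tag carried through outputs.
#' @param cny_per_usd conversion note (CNY per USD) for provenance.
#' @return an object of class `econ_settings`.
#' @export
econ_settings <- function(discount_rate = 0.05, wtp = 10425.29,
                          wtp_3x = NULL, currency = "USD",
                          cny_per_usd = 6.8) {
  v <- new_validator()
  v$check(is_number(discount_rate) && discount_rate >= 0, "discount_rate",
          "must be a single number >= 0")
  v$check(is_number(wtp) && wtp > 0, "wtp", "must be a single number > 0")
  derived <- if (is_number(wtp)) 3 * wtp else NA_real_
  note <- NULL
  if (is.null(wtp_3x)) {
    wtp_3x <- derived
  } else {
    v$check(is_number(wtp_3x) && wtp_3x > 0, "wtp_3x",
            "must be a single number > 0")
    if (is_number(wtp_3x) && is.finite(derived) &&
        abs(wtp_3x - derived) > 1e-9) {
      if (abs(wtp_3x - derived) <= 0.05) {
        note <- sprintf(paste("supplied 3x threshold %.2f differs from",
                              "derived %.2f by rounding; keeping supplied"),
                        wtp_3x, derived)
        message("econ_settings: ", note)
      } else {
        v$check(FALSE, "wtp_3x",
                sprintf("inconsistent with 3 * wtp (%.2f vs %.2f)",
                        wtp_3x, derived))
      }
    }
  }
  v$stop_if_any("econ_settings")
  structure(list(discount_rate = discount_rate, wtp = wtp, wtp_3x = wtp_3x,
                 wtp_3x_derived = derived, rounding_note = note,
                 currency = currency, cny_per_usd = cny_per_usd),
            class = "econ_settings")
}

# --- accrual -------------------------------------------------------------

# Vectorized accrual over an arm_history.  Returns one row per patient:
# life-years (undiscounted), QALY (discounted), discounted on-treatment and
# post-treatment person-years, and the cost components.  `price` overrides
# the profile's annual drug cost (used by the price search; NULL = profile).
.accrue_arm <- function(history, costs, utilities, profile, econ,
                        price = NULL) {
  stopifnot(inherits(history, "arm_history"), inherits(costs, "cost_table"),
            inherits(utilities, "utility_table"),
            inherits(profile, "treatment_profile"),
            inherits(econ, "econ_settings"))
  if (is.null(price)) price <- profile$annual_drug_cost
  if (price < 0) stop("annual drug price must be >= 0")
  n <- history$n
  H <- history$horizon
  seen <- .events[apply(history$inc, 3, any)]
  missc <- setdiff(seen, names(costs$events))
  missu <- setdiff(seen, names(utilities$events))
  if (length(missc) || length(missu)) {
    stop("events present in histories but absent from tables: ",
         paste(unique(c(missc, missu)), collapse = ", "))
  }
  disc <- discount_factors(H, econ$discount_rate)
  yrs <- matrix(seq_len(H), n, H, byrow = TRUE)
  le <- history$le
  alive <- yrs <= matrix(le, n, H)           # year counts while alive
  dmat <- !is.na(history$death_year) &
    yrs == matrix(ifelse(is.na(history$death_year), 0L,
                         history$death_year), n, H)
  uy <- matrix(utilities$initial, n, H)
  cy <- matrix(costs$management, n, H)       # management accrues every alive year
  for (e in seen) {
    occ <- history$inc[, , e]
    if (n == 1L) occ <- matrix(occ, 1L, H)
    fy <- history$first_year[, e]
    after <- !is.na(fy) & yrs > matrix(ifelse(is.na(fy), H + 1L, fy), n, H)
    after_only <- after & !occ
    ut <- utilities$events[[e]]
    uy <- uy - occ * ut$event - after_only * ut$subsequent
    ct <- costs$events[[e]]
    fatal_cost <- if (is.na(ct$fatal)) ct$nonfatal else ct$fatal
    ev_cost <- ifelse(dmat & occ, fatal_cost, ct$nonfatal)
    cy <- cy + occ * ev_cost + after_only * ct$subsequent
  }
  uy <- pmax(uy, 0)
  qaly <- as.vector((uy * alive) %*% disc)
  complication_cost <- as.vector((cy * alive) %*% disc)
  tt <- floor(profile$treatment_time)
  on_tx <- alive & yrs <= tt
  post_tx <- alive & yrs > tt
  disc_tx_years <- as.vector(on_tx %*% disc)
  disc_post_years <- as.vector(post_tx %*% disc)
  therapy_cost <- price * disc_tx_years +
    profile$post_treatment_annual_cost * disc_post_years
  out <- data.frame(
    id = seq_len(n), le = le, qaly = qaly,
    therapy_cost = therapy_cost,
    complication_cost = complication_cost,
    total_cost = therapy_cost + complication_cost,
    disc_tx_years = disc_tx_years,
    disc_post_years = disc_post_years)
  attr(out, "price") <- price
  attr(out, "arm") <- history$arm
  class(out) <- c("patient_econ", "data.frame")
  out
}

#' Accrue discounted economics for one patient history
#'
#' Per year t (t = 1 is undiscounted; later years weighted by
#' `(1+r)^-(t-1)`): utility is `max(0, initial - sum of active decrements)`
#' with the event-year decrement in an event's occurrence year and the
#' subsequent-year decrement thereafter, additively across complications;
#' costs are therapy (annual drug cost while on treatment, post-treatment
#' therapy cost after), management, event-year complication costs (fatal
#' variant when the event co-occurs with death) and subsequent-year costs of
#' prior events.  Nothing accrues after death; the death year itself accrues
#' in full (annual accounting, no half-cycle correction).
#'
#' @param history a single-patient history from [simulate_patient()] or
#'   [history_events()].
#' @param costs a [cost_table()].
#' @param utilities a [utility_table()].
#' @param profile the arm's [treatment_profile()].
#' @param econ an [econ_settings()].
#' @param horizon time horizon in years (defaults to the history's).
#' @return one-row data.frame: `le`, `qaly`, `therapy_cost`,
#'   `complication_cost`, `total_cost` and discounted person-year splits.
#' @export
accrue_patient_economics <- function(history, costs, utilities, profile,
                                     econ, horizon = history$horizon) {
  stopifnot(is.list(history), !is.null(history$le))
  if (is.null(horizon)) stop("horizon must be supplied for this history")
  H <- as.integer(horizon)
  inc <- array(FALSE, dim = c(1L, H, length(.events)),
               dimnames = list(NULL, NULL, .events))
  fy <- matrix(NA_integer_, 1L, length(.events),
               dimnames = list(NULL, .events))
  ev <- history$events
  if (!is.null(ev) && nrow(ev)) {
    bad <- setdiff(unique(ev$event), .events)
    if (length(bad)) {
      stop("unknown events in history: ", paste(bad, collapse = ", "))
    }
    for (k in seq_len(nrow(ev))) {
      inc[1L, ev$year[[k]], ev$event[[k]]] <- TRUE
    }
    for (e in unique(ev$event)) fy[1L, e] <- min(ev$year[ev$event == e])
  }
  h <- structure(list(inc = inc, first_year = fy,
                      death_year = history$death_year,
                      le = history$le, n = 1L, horizon = H,
                      arm = profile$label),
                 class = "arm_history")
  out <- .accrue_arm(h, costs, utilities, profile, econ)
  out[, setdiff(names(out), "id")]
}

#' Summarize per-patient economics into an arm outcome
#'
#' Means over patients with 95% confidence intervals from a normal
#' approximation on the patient-level distribution.  Total cost is exactly
#' the sum of the therapy and complication components.
#'
#' @param pe a `patient_econ` data frame from the accrual step.
#' @return an object of class `arm_outcome` with fields `le` (undiscounted
#'   life-years), `qaly` (discounted), `therapy_cost`, `complication_cost`,
#'   `total_cost`, each with a `ci` attribute row, plus `n`.
#' @export
summarize_arm <- function(pe) {
  stopifnot(inherits(pe, "data.frame"), nrow(pe) >= 1)
  fields <- c("le", "qaly", "therapy_cost", "complication_cost",
              "total_cost")
  n <- nrow(pe)
  est <- vapply(fields, function(f) mean(pe[[f]]), numeric(1))
  se <- vapply(fields, function(f) {
    if (n > 1L) stats::sd(pe[[f]]) / sqrt(n) else 0
  }, numeric(1))
  z <- stats::qnorm(0.975)
  ci <- rbind(lower = est - z * se, upper = est + z * se)
  structure(c(as.list(est),
              list(ci = ci, n = n,
                   arm = attr(pe, "arm"),
                   price = attr(pe, "price"),
                   mean_disc_tx_years = mean(pe$disc_tx_years))),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, digits = 2, ...) {
  cat("Arm outcome", if (!is.null(x$arm)) paste0("(", x$arm, ")"),
      "- n =", x$n, "\n")
  f <- c("le", "qaly", "therapy_cost", "complication_cost", "total_cost")
  m <- cbind(mean = unlist(x[f]), t(x$ci))
  print(round(m, digits))
  invisible(x)
}

# ICUR classification: a step function with breakpoints exactly at the
# lambda and 3*lambda thresholds.
.classify <- function(dq, dc, wtp, wtp3) {
  if (dq == 0 && dc == 0) return("equivalent")
  if (dq >= 0 && dc <= 0) return("dominant")
  if (dq <= 0 && dc >= 0) return("dominated")
  icur <- dc / dq
  if (dq > 0) {
    if (icur < wtp) "very-cost-effective"
    else if (icur <= wtp3) "cost-effective"
    else "not-worthwhile"
  } else {
    # southwest quadrant: savings per QALY forgone must beat 3*lambda
    if (icur > wtp3) "cost-effective" else "not-worthwhile"
  }
}

#' Compare two arm outcomes (incremental cost-utility)
#'
#' Computes `dQALY = a$qaly - b$qaly`, `dCost = a$total_cost -
#' b$total_cost`, the incremental cost-utility ratio `ICUR = dCost / dQALY`
#' (exact when both increments are nonzero), and the willingness-to-pay
#' classification: `dominant` (no ratio reported), `very-cost-effective`
#' (ICUR < lambda), `cost-effective` (lambda <= ICUR <= 3 lambda),
#' `not-worthwhile` (ICUR > 3 lambda), or `dominated`.  With `dQALY = 0`
#' and nonzero `dCost` the ICUR is undefined (`NA`) and classification
#' follows the cost sign.
#'
#' @param a,b [summarize_arm()] outcomes for intervention and comparator.
#' @param econ an [econ_settings()] carrying the thresholds.
#' @return an object of class `cua_result`.
#' @export
compare_arms <- function(a, b, econ) {
  stopifnot(inherits(a, "arm_outcome"), inherits(b, "arm_outcome"),
            inherits(econ, "econ_settings"))
  dq <- a$qaly - b$qaly
  dc <- a$total_cost - b$total_cost
  dle <- a$le - b$le
  icur <- if (dq != 0) dc / dq else NA_real_
  cls <- .classify(dq, dc, econ$wtp, econ$wtp_3x)
  structure(list(delta_qaly = dq, delta_cost = dc, delta_le = dle,
                 icur = icur, classification = cls,
                 dominant = identical(cls, "dominant"),
                 wtp = econ$wtp, wtp_3x = econ$wtp_3x,
                 currency = econ$currency,
                 intervention = a, comparator = b),
            class = "cua_result")
}

#' @export
print.cua_result <- function(x, ...) {
  cat("Incremental cost-utility result\n")
  cat(sprintf("  dQALY = %.4f, dCost = %.2f %s, dLE = %.4f\n",
              x$delta_qaly, x$delta_cost, x$currency, x$delta_le))
  if (x$dominant || is.na(x$icur)) {
    cat("  ICUR: - (", x$classification, ")\n", sep = "")
  } else {
    cat(sprintf("  ICUR = %.2f %s/QALY (%s; lambda = %.2f, 3 lambda = %.2f)\n",
                x$icur, x$currency, x$classification, x$wtp, x$wtp_3x))
  }
  invisible(x)
}
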