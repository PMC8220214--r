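# Risk engine: annual complication/death probabilities from patient state
# via configurable equation sets, plus risk-factor trajectory updates
# (treatment effects, drift, post-treatment switch).

.events <- c("ihd", "mi", "chf", "stroke", "amputation", "blindness",
             "renal", "ulcer")
.event_recurrent_default <- c(ihd = FALSE, mi = TRUE, chf = FALSE,
                              stroke = TRUE, amputation = FALSE,
                              blindness = FALSE, renal = FALSE, ulcer = TRUE)
.forms <- c("logistic", "cloglog", "weibull", "gompertz")

#' Single risk equation
#'
#' Maps a patient state to an annual event probability.  Functional forms:
#' \describe{
#'   \item{logistic}{p = 1 / (1 + exp(-lp))}
#'   \item{cloglog}{p = 1 - exp(-exp(lp)) (complementary log-log; constant
#'     within-year hazard exp(lp))}
#'   \item{gompertz}{p = 1 - exp(-exp(lp)); the linear predictor is expected
#'     to carry an age slope, giving a Gompertz hazard in attained age}
#'   \item{weibull}{p = 1 - exp(-exp(lp) * (d^shape - (d-1)^shape)) with d =
#'     diabetes duration (floored at 1): a Weibull cumulative-hazard
#'     increment in duration}
#' }
#' The linear predictor is `coef["intercept"] + sum(coef[k] * state[[k]])`
#' over the remaining coefficient names, each of which must resolve to a
#' patient-state field (baseline variables, `female`, `smoker`, `hist_*`,
#' `prior_*` event flags, or `race_*` dummies).
#'
#' @param event event name.
#' @param form one of `"logistic"`, `"cloglog"`, `"weibull"`, `"gompertz"`.
#' @param coef named numeric coefficients including `"intercept"`.
#' @param recurrent can the event repeat after its first occurrence?
#' @param shape Weibull shape (required iff `form == "weibull"`).
#' @return an object of class `risk_equation`.
#' @export
risk_equation <- function(event, form, coef, recurrent = FALSE,
                          shape = NULL) {
  v <- new_validator()
  v$check(is.character(event) && length(event) == 1L, "event",
          "must be a single string")
  v$check(form %in% .forms, paste0(event, ".form"),
          paste("must be one of:", paste(.forms, collapse = ", ")))
  v$check(is.numeric(coef) && length(coef) >= 1L &&
            "intercept" %in% names(coef) && all(is.finite(coef)),
          paste0(event, ".coef"),
          "must be finite named numerics including 'intercept'")
  if (identical(form, "weibull")) {
    v$check(is_number(shape) && shape > 0, paste0(event, ".shape"),
            "weibull form requires a single shape > 0")
  }
  v$stop_if_any("risk_equation")
  structure(list(event = event, form = form, coef = coef,
                 recurrent = isTRUE(recurrent), shape = shape),
            class = "risk_equation")
}

#' Risk equation set
#'
#' A named collection of [risk_equation()]s covering the modelled
#' complications plus all-cause death.  The shipped set
#' ([synthetic_risk_equations()]) is a synthetic stand-in with plausible
#' magnitudes, not published UKPDS estimates; substantive use should load a
#' coefficient file via [read_risk_equations()].
#'
#' @param ... [risk_equation()] objects (or a single list of them).
#' @return an object of class `risk_equations` (named list).
#' @export
risk_equations <- function(...) {
  eqs <- list(...)
  if (length(eqs) == 1L && !inherits(eqs[[1]], "risk_equation")) {
    eqs <- eqs[[1]]
  }
  v <- new_validator()
  for (e in eqs) {
    v$check(inherits(e, "risk_equation"), "equations",
            "all elements must be risk_equation objects")
  }
  v$stop_if_any("risk_equations")
  names(eqs) <- vapply(eqs, `[[`, character(1), "event")
  v$check(!anyDuplicated(names(eqs)), "equations", "duplicate event names")
  v$check("death" %in% names(eqs), "equations",
          "must include a 'death' equation")
  v$stop_if_any("risk_equations")
  structure(eqs, class = "risk_equations")
}

#' @export
print.risk_equations <- function(x, ...) {
  cat("Risk equation set:", length(x), "equations\n")
  for (e in x) {
    cat(sprintf("  %-10s %-8s %s covariates: %s\n", e$event, e$form,
                if (e$recurrent) "recurrent " else "first-only",
                paste(setdiff(names(e$coef), "intercept"), collapse = ", ")))
  }
  invisible(x)
}

# Linear predictor over a state matrix; errors name the missing covariate
# and the event (configuration error surface of the spec).
.risk_lp <- function(eq, state) {
  lp <- rep(eq$coef[["intercept"]], nrow(state))
  for (cv in setdiff(names(eq$coef), "intercept")) {
    if (!cv %in% colnames(state)) {
      stop("risk equation '", eq$event, "': covariate '", cv,
           "' not found in patient state", call. = FALSE)
    }
    lp <- lp + eq$coef[[cv]] * state[, cv]
  }
  lp
}

# Vectorized probability for one event over a state matrix.
.risk_prob <- function(eq, state) {
  lp <- .risk_lp(eq, state)
  p <- switch(eq$form,
    logistic = stats::plogis(lp),
    cloglog = ,
    gompertz = 1 - exp(-exp(lp)),
    weibull = {
      d <- pmax(state[, "duration"], 1)
      1 - exp(-exp(lp) * (d^eq$shape - (d - 1)^eq$shape))
    })
  pmin(pmax(p, 0), 1)
}

#' Annual event probability for one patient
#'
#' Evaluates one risk equation on a patient's current state.  For a
#' non-recurrent event that is already in the patient's simulated history
#' (`prior_<event>` flag set) the probability is 0.  Evaluation is pure:
#' repeated calls on a frozen state return identical values.
#'
#' @param state a one-row patient state (list or data.frame row) holding
#'   every covariate the equation references, plus optional `prior_*` flags.
#' @param event event name present in `equations`.
#' @param equations a [risk_equations()] set.
#' @return probability in `[0, 1]`.
#' @export
annual_event_probability <- function(state, event, equations) {
  stopifnot(inherits(equations, "risk_equations"))
  if (!event %in% names(equations)) {
    stop("event '", event, "' not defined in the risk equation set")
  }
  eq <- equations[[event]]
  st <- as.list(state)
  prior <- paste0("prior_", event)
  if (!eq$recurrent && isTRUE(st[[prior]] >= 1)) return(0)
  num <- st[vapply(st, function(x) is.numeric(x) || is.logical(x),
                   logical(1))]
  m <- matrix(as.numeric(unlist(num)), nrow = 1,
              dimnames = list(NULL, names(num)))
  as.numeric(.risk_prob(eq, m))
}

# --- equation file format ------------------------------------------------

#' Read / write a risk-equation coefficient file
#'
#' Plain-text format, one block per event separated by blank lines; `#`
#' starts a comment.  Within a block:
#' \preformatted{
#' event mi
#' form cloglog
#' recurrent yes
#' coef intercept -9.5
#' coef hba1c 0.30
#' }
#' `shape <value>` is required for `form weibull`.  Schema violations are
#' reported with their line numbers.
#'
#' @param path file path.
#' @return a [risk_equations()] set.
#' @export
read_risk_equations <- function(path) {
  if (!file.exists(path)) stop("equation file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", raw)
  lines <- trimws(lines)
  v <- new_validator()
  blocks <- list(); cur <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur$fields)) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) { flush(); next }
    toks <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- toks[[1]]
    if (identical(key, "event")) flush()
    if (is.null(cur)) cur <- list(start = i, fields = list())
    at <- function(msg) paste0("line ", i, ": ", msg)
    if (identical(key, "event")) {
      if (length(toks) != 2L) v$check(FALSE, path, at("expected: event <name>"))
      else cur$fields$event <- toks[[2]]
    } else if (identical(key, "form")) {
      if (length(toks) != 2L || !toks[[2]] %in% .forms) {
        v$check(FALSE, path, at(paste("form must be one of:",
                                      paste(.forms, collapse = ", "))))
      } else cur$fields$form <- toks[[2]]
    } else if (identical(key, "recurrent")) {
      if (length(toks) != 2L || !toks[[2]] %in% c("yes", "no")) {
        v$check(FALSE, path, at("recurrent must be 'yes' or 'no'"))
      } else cur$fields$recurrent <- identical(toks[[2]], "yes")
    } else if (identical(key, "shape")) {
      val <- suppressWarnings(as.numeric(toks[[2]]))
      if (length(toks) != 2L || is.na(val)) {
        v$check(FALSE, path, at("expected: shape <number>"))
      } else cur$fields$shape <- val
    } else if (identical(key, "coef")) {
      val <- if (length(toks) == 3L) {
        suppressWarnings(as.numeric(toks[[3]]))
      } else NA_real_
      if (is.na(val)) v$check(FALSE, path, at("expected: coef <name> <number>"))
      else cur$fields$coef[[toks[[2]]]] <- val
    } else {
      v$check(FALSE, path, at(paste0("unknown directive '", key, "'")))
    }
  }
  flush()
  v$stop_if_any("risk equation file")
  eqs <- lapply(blocks, function(b) {
    f <- b$fields
    for (need in c("event", "form", "coef")) {
      v$check(!is.null(f[[need]]),
              path, paste0("block at line ", b$start, ": missing '", need, "'"))
    }
    if (length(v$errors())) return(NULL)
    tryCatch(
      risk_equation(f$event, f$form, unlist(f$coef),
                    recurrent = isTRUE(f$recurrent), shape = f$shape),
      error = function(e) {
        v$check(FALSE, path,
                paste0("block at line ", b$start, ": ", conditionMessage(e)))
        NULL
      })
  })
  v$stop_if_any("risk equation file")
  risk_equations(eqs)
}

#' @rdname read_risk_equations
#' @param equations a [risk_equations()] set to serialize.
#' @export
write_risk_equations <- function(equations, path) {
  stopifnot(inherits(equations, "risk_equations"))
  out <- character(0)
  for (e in equations) {
    out <- c(out,
             paste("event", e$event),
             paste("form", e$form),
             paste("recurrent", if (e$recurrent) "yes" else "no"),
             if (!is.null(e$shape)) paste("shape", format(e$shape, digits = 15)),
             paste("coef", names(e$coef), format(e$coef, digits = 15,
                                                 trim = TRUE, scientific = FALSE)),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

# --- risk-factor trajectories -------------------------------------------

#' Risk-factor trajectory rule
#'
#' Governs how risk factors evolve between cycles: annual drift after year 1
#' (units/year per factor, default 0), physiological floors, and whether
#' treatment deltas revert at the end of treatment (`NULL` defers to the
#' profile's `post_treatment_effect`).
#'
#' @param drift named numeric annual drifts (units/year), e.g.
#'   `c(hba1c = 0.1)`.
#' @param floors named physiological floors; defaults to the package floors.
#' @param reversion `NULL`, `"hold"` or `"revert"`.
#' @return an object of class `trajectory_rule`.
#' @export
trajectory_rule <- function(drift = numeric(0), floors = .cont_floors,
                            reversion = NULL) {
  stopifnot(is.numeric(drift), all(is.finite(drift)) || !length(drift))
  if (!is.null(reversion)) reversion <- match.arg(reversion, c("hold", "revert"))
  structure(list(drift = drift, floors = floors, reversion = reversion),
            class = "trajectory_rule")
}

.lipids <- c("tc", "hdl", "ldl", "tg")

# Apply an arm's mean deltas to a state matrix (year-1 shift).
.apply_deltas <- function(state, profile, undo = FALSE) {
  for (nm in names(profile$deltas)) {
    d <- profile$deltas[[nm]][["mean"]]
    if (nm %in% .lipids && identical(profile$lipid_delta_unit, "percent")) {
      fac <- 1 + d / 100
      state[, nm] <- if (undo) state[, nm] / fac else state[, nm] * fac
    } else {
      state[, nm] <- state[, nm] + (if (undo) -d else d)
    }
  }
  state
}

.apply_floors <- function(state, floors) {
  for (nm in intersect(names(floors), colnames(state))) {
    state[, nm] <- pmax(state[, nm], floors[[nm]])
  }
  state
}

# Vectorized cycle update: transforms the state in force during year
# (cycle_year - 1) into the state in force during cycle_year.
.update_state <- function(state, cycle_year, profile, rules) {
  if (cycle_year == 1L) {
    state <- .apply_deltas(state, profile)
  } else {
    state[, "age"] <- state[, "age"] + 1
    state[, "duration"] <- state[, "duration"] + 1
    for (nm in names(rules$drift)) {
      state[, nm] <- state[, nm] + rules$drift[[nm]]
    }
    rev <- if (is.null(rules$reversion)) profile$post_treatment_effect
           else rules$reversion
    if (identical(rev, "revert") &&
        cycle_year == floor(profile$treatment_time) + 1L) {
      state <- .apply_deltas(state, profile, undo = TRUE)
    }
  }
  .apply_floors(state, rules$floors)
}

#' Advance one patient's risk factors by one annual cycle
#'
#' Cycle 1 applies the arm's treatment deltas as a one-time shift (held
#' constant while on treatment).  Later cycles advance age and diabetes
#' duration by 1 year, apply any configured drift, and at the cycle after
#' `treatment_time` remove the deltas if the reversion rule is `"revert"`
#' (default `"hold"` keeps them).  Values are clamped at physiological
#' floors.
#'
#' @param state one patient's state (named list or one-row data.frame).
#' @param cycle_year cycle index (1 = first simulated year).
#' @param profile a [treatment_profile()].
#' @param rules a [trajectory_rule()].
#' @return the updated state, same shape as the input.
#' @export
update_risk_factors <- function(state, cycle_year, profile,
                                rules = trajectory_rule()) {
  stopifnot(cycle_year >= 1, inherits(profile, "treatment_profile"))
  st <- as.list(state)
  num <- names(st)[vapply(st, is.numeric, logical(1))]
  m <- matrix(as.numeric(unlist(st[num])), nrow = 1,
              dimnames = list(NULL, num))
  m <- .update_state(m, as.integer(cycle_year), profile, rules)
  for (nm in num) st[[nm]] <- as.numeric(m[, nm])
  st
}
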