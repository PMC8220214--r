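# Shared fixtures: scaled-down configurations, constant-probability
# equation sets, hand-crafted economic outcomes, and an independent
# straight-line reimplementation of the simulation loop used as an oracle.

small_config <- function(n = 50, seed = 7, horizon = 40) {
  cfg <- default_config(n_patients = n, seed = seed)
  cfg$sim$horizon <- horizon
  cfg
}

# Equation set with state-independent probabilities (logistic intercepts).
# p outside (0, 1) is encoded with an extreme finite intercept.
const_equations <- function(p_event = 0.05, p_death = 0.02) {
  int <- function(p) {
    if (p <= 0) -50 else if (p >= 1) 50 else qlogis(p)
  }
  ev <- lapply(dmcua:::.events, function(e) {
    risk_equation(e, "logistic", c(intercept = int(p_event)),
                  recurrent = dmcua:::.event_recurrent_default[[e]])
  })
  risk_equations(c(ev, list(
    risk_equation("death", "logistic", c(intercept = int(p_death))))))
}

# Craft an arm outcome with exact component values (one synthetic patient).
mk_outcome <- function(qaly, therapy, complication, le = 40, price = NA,
                       disc_tx = 0, arm = "arm") {
  pe <- data.frame(id = 1, le = le, qaly = qaly, therapy_cost = therapy,
                   complication_cost = complication,
                   total_cost = therapy + complication,
                   disc_tx_years = disc_tx, disc_post_years = 0)
  attr(pe, "price") <- price
  attr(pe, "arm") <- arm
  class(pe) <- c("patient_econ", "data.frame")
  summarize_arm(pe)
}

# Minimal synthetic context for the price search: dCost(p) = a + b * p with
# dQALY fixed, built from two one-patient arms.  Comparator price p0.
mk_affine_fit <- function(a, b, delta_qaly, comparator_total = 10000,
                          p0 = 558.2, econ = suppressMessages(econ_settings())) {
  pe_c <- data.frame(id = 1, le = 40, qaly = 10,
                     therapy_cost = comparator_total / 2,
                     complication_cost = comparator_total / 2,
                     total_cost = comparator_total,
                     disc_tx_years = 0, disc_post_years = 0)
  attr(pe_c, "price") <- p0
  attr(pe_c, "arm") <- "comparator"
  class(pe_c) <- c("patient_econ", "data.frame")
  # intervention at reference price 0: therapy = 0, total = a + comp_total
  pe_i <- data.frame(id = 1, le = 40, qaly = 10 + delta_qaly,
                     therapy_cost = 0,
                     complication_cost = a + comparator_total,
                     total_cost = a + comparator_total,
                     disc_tx_years = b, disc_post_years = 0)
  attr(pe_i, "price") <- 0
  attr(pe_i, "arm") <- "intervention"
  class(pe_i) <- c("patient_econ", "data.frame")
  oi <- summarize_arm(pe_i)
  oc <- summarize_arm(pe_c)
  structure(list(patients = list(intervention = pe_i, comparator = pe_c),
                 outcomes = list(intervention = oi, comparator = oc),
                 inputs = list(econ = econ),
                 result = compare_arms(oi, oc, econ)),
            class = "cua")
}

# Independent straight-line reimplementation of the annual-cycle loop,
# scalar throughout; shares only the uniform streams and the coefficient
# values with the package implementation.
oracle_simulate <- function(cohort, profile, equations, settings) {
  events <- dmcua:::.events
  floors <- dmcua:::.cont_floors
  lipids <- c("tc", "hdl", "ldl", "tg")
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    u <- dmcua:::.patient_uniforms(settings$seed, cohort$id[[i]])
    st <- as.list(as.data.frame(cohort)[i, ])
    for (e in events) st[[paste0("prior_", e)]] <- 0
    had <- setNames(rep(FALSE, length(events)), events)
    rec <- list()
    death_year <- NA_integer_
    for (y in seq_len(settings$horizon)) {
      # risk-factor update
      if (y == 1) {
        for (nm in names(profile$deltas)) {
          d <- profile$deltas[[nm]][["mean"]]
          if (nm %in% lipids &&
              identical(profile$lipid_delta_unit, "percent")) {
            st[[nm]] <- st[[nm]] * (1 + d / 100)
          } else st[[nm]] <- st[[nm]] + d
        }
      } else {
        st$age <- st$age + 1
        st$duration <- st$duration + 1
        if (identical(profile$post_treatment_effect, "revert") &&
            y == floor(profile$treatment_time) + 1) {
          for (nm in names(profile$deltas)) {
            d <- profile$deltas[[nm]][["mean"]]
            if (nm %in% lipids &&
                identical(profile$lipid_delta_unit, "percent")) {
              st[[nm]] <- st[[nm]] / (1 + d / 100)
            } else st[[nm]] <- st[[nm]] - d
          }
        }
      }
      for (nm in names(floors)) {
        if (!is.null(st[[nm]])) st[[nm]] <- max(st[[nm]], floors[[nm]])
      }
      lp_of <- function(eq) {
        lp <- eq$coef[["intercept"]]
        for (cv in setdiff(names(eq$coef), "intercept")) {
          lp <- lp + eq$coef[[cv]] * st[[cv]]
        }
        lp
      }
      p_of <- function(eq) {
        lp <- lp_of(eq)
        switch(eq$form,
               logistic = 1 / (1 + exp(-lp)),
               cloglog = ,
               gompertz = 1 - exp(-exp(lp)),
               weibull = {
                 d <- max(st$duration, 1)
                 1 - exp(-exp(lp) * (d^eq$shape - (d - 1)^eq$shape))
               })
      }
      occurred <- character(0)
      for (ev in settings$event_order) {
        eq <- equations[[ev]]
        if (!eq$recurrent && had[[ev]]) next
        if (u[y, ev] < p_of(eq)) {
          rec[[length(rec) + 1L]] <- list(year = y, event = ev)
          occurred <- c(occurred, ev)
        }
      }
      died <- u[y, "death"] < p_of(equations[["death"]])
      for (ev in occurred) {
        had[[ev]] <- TRUE
        st[[paste0("prior_", ev)]] <- 1
      }
      if (died) {
        death_year <- y
        break
      }
    }
    ev_df <- if (length(rec)) {
      data.frame(year = vapply(rec, `[[`, numeric(1), "year"),
                 event = vapply(rec, `[[`, character(1), "event"),
                 stringsAsFactors = FALSE)
    } else data.frame(year = integer(0), event = character(0))
    out[[i]] <- list(events = ev_df, death_year = death_year,
                     le = if (is.na(death_year)) settings$horizon
                          else death_year)
  }
  out
}
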