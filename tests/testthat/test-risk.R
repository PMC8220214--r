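# Risk engine: functional forms, recurrence, trajectories, file format.

state_at <- function(...) {
  st <- list(age = 56, duration = 7, hba1c = 8.2, bmi = 32.8, sbp = 131.41,
             dbp = 80.01, tc = 4.75, hdl = 1.2, ldl = 2.64, tg = 2.12,
             egfr = 97.35, female = 0, smoker = 0,
             hist_mi = 0, hist_angina = 0, hist_pvd = 0, hist_renal = 0,
             hist_microalbuminuria = 0, hist_retinopathy = 0,
             prior_mi = 0, prior_stroke = 0, prior_chf = 0, prior_renal = 0)
  utils::modifyList(st, list(...))
}

test_that("logistic form returns 1/2 at zero linear predictor", {
  eq <- risk_equations(list(
    risk_equation("mi", "logistic", c(intercept = 0)),
    risk_equation("death", "logistic", c(intercept = -5))))
  expect_identical(annual_event_probability(state_at(), "mi", eq), 0.5)
})

test_that("complementary log-log matches direct arithmetic evaluation", {
  # lp = -2 through intercept alone
  eq <- risk_equations(list(
    risk_equation("stroke", "cloglog", c(intercept = -2), recurrent = TRUE),
    risk_equation("death", "logistic", c(intercept = -5))))
  expect_equal(annual_event_probability(state_at(), "stroke", eq),
               1 - exp(-exp(-2)), tolerance = 1e-12)
  # lp assembled from covariates
  eq2 <- risk_equations(list(
    risk_equation("stroke", "cloglog",
                  c(intercept = -10, age = 0.05, hba1c = 0.2),
                  recurrent = TRUE),
    risk_equation("death", "logistic", c(intercept = -5))))
  lp <- -10 + 0.05 * 56 + 0.2 * 8.2
  expect_equal(annual_event_probability(state_at(), "stroke", eq2),
               1 - exp(-exp(lp)), tolerance = 1e-12)
})

test_that("weibull-in-duration form matches its cumulative-hazard increment", {
  eq <- risk_equations(list(
    risk_equation("blindness", "weibull", c(intercept = -6), shape = 1.4),
    risk_equation("death", "logistic", c(intercept = -5))))
  d <- 7
  expect_equal(annual_event_probability(state_at(), "blindness", eq),
               1 - exp(-exp(-6) * (d^1.4 - (d - 1)^1.4)), tolerance = 1e-12)
})

test_that("non-recurrent events with a prior occurrence have probability 0", {
  eq <- risk_equations(list(
    risk_equation("chf", "logistic", c(intercept = 0)),
    risk_equation("mi", "logistic", c(intercept = 0), recurrent = TRUE),
    risk_equation("death", "logistic", c(intercept = -5))))
  st <- state_at()
  st$prior_chf <- 1
  st$prior_mi <- 1
  expect_identical(annual_event_probability(st, "chf", eq), 0)
  expect_identical(annual_event_probability(st, "mi", eq), 0.5)
})

test_that("missing covariates raise errors naming covariate and event", {
  eq <- risk_equations(list(
    risk_equation("mi", "logistic", c(intercept = 0, nonexistent = 1)),
    risk_equation("death", "logistic", c(intercept = -5))))
  expect_error(annual_event_probability(state_at(), "mi", eq),
               "'mi'.*'nonexistent'")
  expect_error(annual_event_probability(state_at(), "ulcer", eq),
               "not defined")
})

test_that("probabilities are monotone in a positively-weighted covariate", {
  eqs <- synthetic_risk_equations()
  st <- state_at()
  for (ev in c("ihd", "mi", "stroke")) {
    p0 <- annual_event_probability(st, ev, eqs)
    st_hi <- utils::modifyList(st, list(hba1c = st$hba1c + 1))
    expect_gt(annual_event_probability(st_hi, ev, eqs), p0)
  }
  # repeated evaluation on a frozen state is pure
  p1 <- annual_event_probability(st, "death", eqs)
  p2 <- annual_event_probability(st, "death", eqs)
  expect_identical(p1, p2)
  expect_true(p1 >= 0 && p1 <= 1)
})

test_that("year-1 update applies treatment deltas once", {
  pr <- default_profiles()$intervention
  st <- update_risk_factors(state_at(), 1, pr)
  expect_equal(st$hba1c, 8.2 - 1.44, tolerance = 1e-12)
  expect_equal(st$sbp, 131.41 - 4.11, tolerance = 1e-12)
  expect_equal(st$bmi, 32.8 - 1.92, tolerance = 1e-12)
  # lipids move as percent changes
  expect_equal(st$tc, 4.75 * (1 - 6.15 / 100), tolerance = 1e-12)
  expect_equal(st$hdl, 1.2 * (1 + 1.53 / 100), tolerance = 1e-12)
  # age does not advance in cycle 1 (baseline year)
  expect_equal(st$age, 56)
})

test_that("zero-delta, zero-drift trajectories only advance age and duration", {
  pr <- treatment_profile("null", deltas = list(), annual_drug_cost = 0)
  st <- state_at()
  for (y in 1:5) st <- update_risk_factors(st, y, pr)
  expect_equal(st$age, 56 + 4)
  expect_equal(st$duration, 7 + 4)
  expect_equal(st$hba1c, 8.2)
  expect_equal(st$tc, 4.75)
})

test_that("reversion returns risk factors to the counterfactual drift path", {
  pr <- treatment_profile("rev", deltas = list(hba1c = c(-1.44, 0)),
                          annual_drug_cost = 0, treatment_time = 5,
                          post_treatment_effect = "revert")
  rules <- trajectory_rule(drift = c(hba1c = 0.1))
  # hand-simulated 7-year trajectory
  st <- state_at()
  traj <- numeric(7)
  for (y in 1:7) {
    st <- update_risk_factors(st, y, pr, rules)
    traj[y] <- st$hba1c
  }
  expect_equal(traj[1], 8.2 - 1.44, tolerance = 1e-12)
  expect_equal(traj[5], 8.2 - 1.44 + 0.4, tolerance = 1e-12)
  # year 6: drift applies, then the delta is removed -> counterfactual path
  expect_equal(traj[6], 8.2 + 0.5, tolerance = 1e-12)
  expect_equal(traj[7], 8.2 + 0.6, tolerance = 1e-12)
  # under "hold" the delta persists
  pr_h <- treatment_profile("hold", deltas = list(hba1c = c(-1.44, 0)),
                            annual_drug_cost = 0, treatment_time = 5,
                            post_treatment_effect = "hold")
  st <- state_at()
  for (y in 1:7) st <- update_risk_factors(st, y, pr_h, rules)
  expect_equal(st$hba1c, 8.2 - 1.44 + 0.6, tolerance = 1e-12)
})

test_that("trajectory floors prevent physiologically impossible values", {
  pr <- treatment_profile("big", deltas = list(hba1c = c(-9, 0)),
                          annual_drug_cost = 0)
  st <- update_risk_factors(state_at(), 1, pr)
  expect_equal(st$hba1c, dmcua:::.cont_floors[["hba1c"]])
})

test_that("equation files round-trip and validate with line-level errors", {
  eqs <- synthetic_risk_equations()
  f <- tempfile(fileext = ".txt")
  write_risk_equations(eqs, f)
  back <- read_risk_equations(f)
  expect_equal(names(back), names(eqs))
  for (nm in names(eqs)) {
    expect_equal(back[[nm]]$coef, eqs[[nm]]$coef, tolerance = 1e-12)
    expect_identical(back[[nm]]$form, eqs[[nm]]$form)
    expect_identical(back[[nm]]$recurrent, eqs[[nm]]$recurrent)
  }
  # malformed content is reported with line numbers, all errors at once
  bad <- tempfile(fileext = ".txt")
  writeLines(c("event mi", "form banana", "coef intercept x", "",
               "event death", "form logistic", "coef intercept -5"), bad)
  err <- tryCatch(read_risk_equations(bad), error = conditionMessage)
  expect_match(err, "line 2")
  expect_match(err, "line 3")
  # a block missing its form is caught
  bad2 <- tempfile(fileext = ".txt")
  writeLines(c("event mi", "coef intercept -2", "", "event death",
               "form logistic", "coef intercept -5"), bad2)
  expect_error(read_risk_equations(bad2), "missing 'form'")
  # weibull without shape is rejected
  bad3 <- tempfile(fileext = ".txt")
  writeLines(c("event blindness", "form weibull", "coef intercept -2", "",
               "event death", "form logistic", "coef intercept -5"), bad3)
  expect_error(read_risk_equations(bad3), "shape")
})

test_that("the shipped equation file parses to the synthetic set", {
  f <- system.file("extdata", "risk_equations_synthetic.txt",
                   package = "dmcua")
  expect_true(nzchar(f))
  eqs <- read_risk_equations(f)
  ref <- synthetic_risk_equations()
  expect_equal(names(eqs), names(ref))
  expect_equal(eqs$death$coef, ref$death$coef, tolerance = 1e-12)
})
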