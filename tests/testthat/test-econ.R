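# Economic accrual: closed-form limits, published-table accounting
# identities, additivity, discounting, classification.

no_event_history <- function(le = 40, death_year = NA_integer_,
                             horizon = 40) {
  list(events = data.frame(year = integer(0), event = character(0),
                           fatal = logical(0)),
       death_year = death_year, le = le, horizon = horizon)
}

base_tables <- function() {
  list(costs = default_cost_table(), utils = default_utility_table(),
       profile = default_profiles()$intervention)
}

test_that("an event-free 40-year life at r = 0 yields QALY 35.04 and LE 40", {
  tb <- base_tables()
  econ0 <- suppressMessages(econ_settings(discount_rate = 0))
  pe <- accrue_patient_economics(no_event_history(), tb$costs, tb$utils,
                                 tb$profile, econ0)
  expect_equal(pe$qaly, 0.876 * 40, tolerance = 1e-12)
  expect_equal(pe$le, 40)
})

test_that("event-free accruals match geometric-series annuity closed forms", {
  tb <- base_tables()
  for (r in c(0, 0.05, 0.08)) {
    econ <- suppressMessages(econ_settings(discount_rate = r))
    pe <- accrue_patient_economics(no_event_history(), tb$costs, tb$utils,
                                   tb$profile, econ)
    ann40 <- sum((1 + r)^-(0:39))
    ann5 <- sum((1 + r)^-(0:4))
    expect_equal(pe$complication_cost, 1427.10 * ann40,
                 tolerance = 1e-9)
    expect_equal(pe$qaly, 0.876 * ann40, tolerance = 1e-9)
    expect_equal(pe$therapy_cost,
                 558.2 * ann5 + 558.2 * (ann40 - ann5), tolerance = 1e-9)
    expect_equal(pe$total_cost, pe$therapy_cost + pe$complication_cost,
                 tolerance = 1e-12)
  }
})

test_that("a single non-fatal MI accrues the published event and follow-up values", {
  tb <- base_tables()
  econ <- suppressMessages(econ_settings(discount_rate = 0))
  hist <- list(events = data.frame(year = 3L, event = "mi", fatal = FALSE),
               death_year = NA_integer_, le = 40, horizon = 40)
  pe <- accrue_patient_economics(hist, tb$costs, tb$utils, tb$profile, econ)
  ref <- accrue_patient_economics(no_event_history(), tb$costs, tb$utils,
                                  tb$profile, econ)
  # year 3 adds the 7,855.14 event cost; years 4..40 add 484.52 each
  expect_equal(pe$complication_cost - ref$complication_cost,
               7855.14 + 37 * 484.52, tolerance = 1e-9)
  # year-3 utility loses 0.055; each later year loses 0.236
  expect_equal(ref$qaly - pe$qaly, 0.055 + 37 * 0.236, tolerance = 1e-9)
})

test_that("death co-occurrence selects the fatal cost variant", {
  tb <- base_tables()
  econ <- suppressMessages(econ_settings(discount_rate = 0))
  fatal <- list(events = data.frame(year = 5L, event = "stroke",
                                    fatal = TRUE),
                death_year = 5L, le = 5, horizon = 40)
  nonfatal <- list(events = data.frame(year = 5L, event = "stroke",
                                       fatal = FALSE),
                   death_year = NA_integer_, le = 5, horizon = 40)
  # same 5 alive years in both; only the event-year cost differs
  nonfatal_censored <- nonfatal
  nonfatal_censored$death_year <- 6L
  nonfatal_censored$le <- 6
  pe_f <- accrue_patient_economics(fatal, tb$costs, tb$utils, tb$profile,
                                   econ)
  expect_equal(pe_f$complication_cost, 5 * 1427.10 + 2266.31,
               tolerance = 1e-9)
  # blindness has no fatal variant: the non-fatal cost applies at death too
  blind <- list(events = data.frame(year = 2L, event = "blindness",
                                    fatal = TRUE),
                death_year = 2L, le = 2, horizon = 40)
  pe_b <- accrue_patient_economics(blind, tb$costs, tb$utils, tb$profile,
                                   econ)
  expect_equal(pe_b$complication_cost, 2 * 1427.10 + 2361.49,
               tolerance = 1e-9)
  # nothing accrues after death
  expect_equal(pe_f$le, 5)
  expect_equal(pe_f$qaly, 5 * 0.876 - 0.164, tolerance = 1e-9)
})

test_that("stacked decrements floor per-year utility at zero", {
  tb <- base_tables()
  econ <- suppressMessages(econ_settings(discount_rate = 0))
  hist <- list(events = data.frame(year = c(1L, 1L, 2L),
                                   event = c("renal", "amputation",
                                             "stroke"),
                                   fatal = FALSE),
               death_year = 3L, le = 3, horizon = 40)
  pe <- accrue_patient_economics(hist, tb$costs, tb$utils, tb$profile,
                                 econ)
  # year 1: 0.876 - (0.400 + 0.380) = 0.096; year 2:
  # 0.876 - (0.400 + 0.380 + 0.164) < 0 -> floored at 0; year 3:
  # 0.876 - (0.400 + 0.380 + 0.326) < 0 -> floored at 0
  expect_equal(pe$qaly, 0.096, tolerance = 1e-9)
  expect_gte(pe$qaly, 0)
})

test_that("increasing the discount rate strictly shrinks positive streams", {
  tb <- base_tables()
  q <- vapply(c(0, 0.03, 0.05, 0.08), function(r) {
    econ <- suppressMessages(econ_settings(discount_rate = r))
    accrue_patient_economics(no_event_history(), tb$costs, tb$utils,
                             tb$profile, econ)$qaly
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("unknown history events raise a configuration error", {
  tb <- base_tables()
  econ <- suppressMessages(econ_settings())
  hist <- list(events = data.frame(year = 1L, event = "gout",
                                   fatal = FALSE),
               death_year = NA_integer_, le = 40, horizon = 40)
  expect_error(accrue_patient_economics(hist, tb$costs, tb$utils,
                                        tb$profile, econ),
               "gout")
})

test_that("arm summaries: degenerate and zero-width confidence intervals", {
  o1 <- mk_outcome(qaly = 11, therapy = 3000, complication = 20000)
  expect_equal(o1$total_cost, 23000)
  expect_equal(unname(o1$ci["lower", "qaly"]), 11)
  expect_equal(unname(o1$ci["upper", "qaly"]), 11)
  # identical patients -> zero-width CIs
  pe <- data.frame(id = 1:5, le = 40, qaly = 11, therapy_cost = 3000,
                   complication_cost = 20000, total_cost = 23000,
                   disc_tx_years = 4, disc_post_years = 10)
  class(pe) <- c("patient_econ", "data.frame")
  o5 <- summarize_arm(pe)
  expect_equal(unname(o5$ci["upper", "total_cost"] -
                        o5$ci["lower", "total_cost"]), 0)
})

test_that("published incremental pairs reproduce their printed ICURs", {
  econ <- suppressMessages(econ_settings(wtp = 10425.29, wtp_3x = 31275.88))
  # arm totals chosen so the increments equal the printed (dCost, dQALY)
  a3 <- mk_outcome(qaly = 11.1068, therapy = 0,
                   complication = 24360.948 + 2946.177869)
  al <- mk_outcome(qaly = 11.1068, therapy = 0,
                   complication = 24360.948 + 982.0576956)
  b <- mk_outcome(qaly = 11.1068 - 0.0942, therapy = 0,
                  complication = 24360.948)
  r3 <- compare_arms(a3, b, econ)
  rl <- compare_arms(al, b, econ)
  expect_equal(r3$icur, r3$delta_cost / r3$delta_qaly)
  expect_equal(r3$icur, 31275.77355, tolerance = 1e-7)
  expect_equal(rl$icur, 10425.24093, tolerance = 1e-7)
  expect_identical(rl$classification, "very-cost-effective")
  expect_identical(r3$classification, "cost-effective")
})

test_that("dominance is reported instead of a ratio", {
  econ <- suppressMessages(econ_settings())
  a <- mk_outcome(qaly = 11.11, therapy = 3665.96, complication = 20692.53)
  b <- mk_outcome(qaly = 11.01, therapy = 3699.32, complication = 20661.62)
  expect_equal(a$total_cost, 24358.49, tolerance = 1e-9)
  expect_equal(b$total_cost, 24360.95 - 0.01, tolerance = 1e-9)
  r <- compare_arms(a, b, econ)
  expect_true(r$dominant)
  expect_identical(r$classification, "dominant")
  expect_output(print(r), "ICUR: -")
})

test_that("classification is a step function with breakpoints at the thresholds", {
  econ <- suppressMessages(econ_settings(wtp = 10000))
  cls_at <- function(icur) {
    a <- mk_outcome(qaly = 11, therapy = 0, complication = 20000 + icur)
    b <- mk_outcome(qaly = 10, therapy = 0, complication = 20000)
    compare_arms(a, b, econ)$classification
  }
  eps <- 1e-6
  expect_identical(cls_at(10000 - eps), "very-cost-effective")
  expect_identical(cls_at(10000 + eps), "cost-effective")
  expect_identical(cls_at(30000 - eps), "cost-effective")
  expect_identical(cls_at(30000 + eps), "not-worthwhile")
})

test_that("zero-QALY increments classify by cost sign with undefined ICUR", {
  econ <- suppressMessages(econ_settings())
  a <- mk_outcome(qaly = 10, therapy = 0, complication = 21000)
  b <- mk_outcome(qaly = 10, therapy = 0, complication = 20000)
  r <- compare_arms(a, b, econ)
  expect_true(is.na(r$icur))
  expect_identical(r$classification, "dominated")
  r2 <- compare_arms(b, a, econ)
  expect_identical(r2$classification, "dominant")
})

test_that("total cost additivity is exact for every simulated patient", {
  fit <- cua(small_config(n = 120, seed = 30))
  for (arm in c("intervention", "comparator")) {
    pe <- fit$patients[[arm]]
    expect_identical(pe$total_cost, pe$therapy_cost + pe$complication_cost)
    expect_true(all(pe$qaly <= pe$le + 1e-12))
    expect_true(all(pe$qaly >= 0))
  }
  o <- fit$outcomes$intervention
  expect_equal(o$total_cost, o$therapy_cost + o$complication_cost,
               tolerance = 1e-12)
})
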