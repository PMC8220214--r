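# Sensitivity analyses: tornado rows, PSA against analytic oracles,
# scenario accounting identities.

test_that("published parameter rows carry the stated ranges", {
  pars <- default_owsa_parameters()
  expect_length(pars, 20)
  nm <- vapply(pars, `[[`, character(1), "name")
  ihd <- pars[[which(nm == "IHD per-year cost")]]
  expect_equal(c(ihd$baseline, ihd$low, ihd$high),
               c(1123.51, 898.808, 1348.212))
  dr <- pars[[which(nm == "discount rate")]]
  expect_equal(c(dr$low, dr$high), c(0.03, 0.08))
  for (p in pars) expect_true(p$low <= p$baseline && p$baseline <= p$high)
  expect_error(owsa_parameter("x", 1, 2, 3, "a.b"), "low <= baseline")
})

test_that("a degenerate parameter yields a zero-width tornado bar", {
  fit <- cua(small_config(n = 60, seed = 41), intervention_price = 1200)
  par0 <- owsa_parameter("frozen management cost", 1427.10, 1427.10,
                         1427.10, "costs.management")
  ow <- owsa(fit, parameters = list(par0))
  expect_equal(ow$rows$width, 0)
  expect_equal(ow$rows$icur_low, ow$rows$icur_high)
  expect_equal(ow$rows$icur_low, fit$result$icur, tolerance = 1e-9)
})

test_that("one-way rows perturb exactly one input and sort by width", {
  fit <- cua(small_config(n = 150, seed = 42), intervention_price = 1200)
  pars <- list(
    owsa_parameter("IHD per-year cost", 1123.51, 898.808, 1348.212,
                   "costs.events.ihd.subsequent"),
    owsa_parameter("initial utility", 0.876, 0.78, 0.92,
                   "utilities.initial"),
    owsa_parameter("discount rate", 0.05, 0.03, 0.08,
                   "econ.discount_rate"))
  ow <- owsa(fit, parameters = pars)
  expect_equal(nrow(ow$rows), 3)
  expect_true(all(diff(ow$rows$width) <= 0))
  expect_true(all(ow$rows$width >= 0))
  # a lower initial utility shrinks dQALY, raising the ICUR
  iu <- ow$rows[ow$rows$parameter == "initial utility", ]
  expect_gt(iu$icur_low, fit$result$icur)
})

test_that("treatment time drives dCost monotonically via direct accounting", {
  cfg <- small_config(n = 150, seed = 43)
  cfg$profiles$intervention$annual_drug_cost <- 1200
  dcost_at_tt <- function(tt) {
    c2 <- cfg
    c2$profiles$intervention$treatment_time <- tt
    c2$profiles$comparator$treatment_time <- tt
    cua(c2)$result$delta_cost
  }
  d4 <- dcost_at_tt(4); d5 <- dcost_at_tt(5); d6 <- dcost_at_tt(6)
  # the intervention price premium (1200 - 558.2) accrues one extra
  # discounted on-treatment year per added treatment year
  expect_true(d4 < d5 && d5 < d6)
})

test_that("the discount-rate bar is widest among purely economic rows (fixture)", {
  fit <- cua(default_config(n_patients = 1000, seed = 1))
  pl <- find_price(fit, "lambda")
  fitl <- cua(default_config(n_patients = 1000, seed = 1),
              intervention_price = pl$price)
  ow <- owsa(fitl)
  rows <- ow$rows
  econ_rows <- rows[!rows$parameter %in% c("treatment time",
                                           "time horizon"), ]
  expect_identical(econ_rows$parameter[[1]], "discount rate")
})

test_that("point-mass distributions reproduce the deterministic run exactly", {
  fit <- cua(small_config(n = 80, seed = 44), intervention_price = 1000)
  dists <- list(
    psa_distribution("management cost", "costs.management",
                     function() 1427.10),
    psa_distribution("initial utility", "utilities.initial",
                     function() 0.876))
  pr <- psa(fit, n = 8, distributions = dists)
  expect_true(all(pr$draws$delta_qaly == fit$result$delta_qaly))
  expect_true(all(pr$draws$delta_cost == fit$result$delta_cost))
  expect_true(pr$prob_cost_effective %in% c(0, 1))
})

test_that("toy two-parameter PSA matches its analytic cost-effectiveness probability", {
  fit <- cua(small_config(n = 100, seed = 45), intervention_price = 1000)
  econ <- fit$inputs$econ
  dq <- fit$result$delta_qaly
  inv <- affine_price_inversion(fit, "lambda", prices = c(0, 2000))
  b_i <- inv$b
  b_c <- fit$outcomes$comparator$mean_disc_tx_years
  # two sampled prices: intervention ~ N(1000, 150), comparator ~ N(558.2, 80)
  dists <- list(
    psa_distribution("intervention price",
                     "profiles.intervention.annual_drug_cost",
                     function() rnorm(1, 1000, 150)),
    psa_distribution("comparator price",
                     "profiles.comparator.annual_drug_cost",
                     function() rnorm(1, 558.2, 80)))
  n <- 300
  pr <- psa(fit, n = n, distributions = dists, wtp = econ$wtp)
  # dCost = a0 + b_i (p - 1000) - b_c (q - 558.2); CE iff dCost <= wtp * dq
  a0 <- fit$result$delta_cost
  mu <- a0
  sdv <- sqrt((b_i * 150)^2 + (b_c * 80)^2)
  p_true <- pnorm((econ$wtp * dq - mu) / sdv)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(pr$prob_cost_effective - p_true), 3 * se + 1e-9)
  # PSA is deterministic given its seed
  pr2 <- psa(fit, n = 20, distributions = dists)
  pr3 <- psa(fit, n = 20, distributions = dists)
  expect_identical(pr2$draws, pr3$draws)
})

test_that("default PSA distributions cover costs, utilities and effects", {
  cfg <- small_config(n = 20, seed = 46)
  dists <- default_psa_distributions(cfg)
  nm <- vapply(dists, `[[`, character(1), "name")
  expect_true("mi per-year cost" %in% nm)
  expect_true("initial utility" %in% nm)
  expect_true(any(grepl("intervention hba1c delta", nm)))
  # samplers respect their support
  set.seed(1)
  for (d in dists) {
    v <- replicate(20, d$sample())
    if (grepl("cost", d$name)) expect_true(all(v >= 0))
    if (grepl("disutility", d$name)) expect_true(all(v >= 0 & v <= 2))
    if (identical(d$name, "initial utility")) {
      expect_true(all(v > 0 & v < 1))
    }
  }
})

test_that("scenario multiplier 1 is the identity; 0.8 moves exactly the drug component", {
  fit <- cua(small_config(n = 120, seed = 47), intervention_price = 900)
  s1 <- scenario(fit, multiplier = 1)
  expect_equal(s1$delta_cost, fit$result$delta_cost, tolerance = 1e-12)
  expect_equal(s1$delta_qaly, fit$result$delta_qaly, tolerance = 1e-12)
  s08 <- scenario(fit, multiplier = 0.8)
  drug_component <- 558.2 *
    mean(fit$patients$comparator$disc_tx_years)
  expect_equal(fit$outcomes$comparator$total_cost -
                 s08$comparator$total_cost,
               0.2 * drug_component, tolerance = 1e-9)
  # the intervention arm is untouched
  expect_equal(s08$intervention$total_cost,
               fit$outcomes$intervention$total_cost, tolerance = 1e-12)
  expect_equal(s08$delta_qaly, fit$result$delta_qaly, tolerance = 1e-12)
})
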