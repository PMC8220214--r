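# Sensitivity analyses over the fitted context: one-way (tornado) analysis
# on the published parameter ranges, probabilistic sensitivity analysis
# (second-order Monte Carlo), and scenario analysis on the comparator
# price.  All re-runs share the master seed's random streams, so parameter
# changes -- not sampling noise -- drive the differences.

#' One-way sensitivity-analysis parameter
#'
#' A named input with baseline/low/high values and the configuration
#' path(s) it perturbs (several paths move together when one published
#' number feeds multiple config keys, e.g. a disutility applied in both the
#' event year and subsequent years).
#'
#' @param name display name.
#' @param baseline,low,high values with `low <= baseline <= high`.
#' @param paths character vector of dotted config paths.
#' @return an object of class `owsa_parameter`.
#' @export
owsa_parameter <- function(name, baseline, low, high, paths) {
  v <- new_validator()
  v$check(is.character(name) && length(name) == 1L, "name",
          "must be a single string")
  v$check(is_number(baseline) && is_number(low) && is_number(high),
          name, "baseline/low/high must be single numbers")
  v$check(low <= baseline && baseline <= high, name,
          "requires low <= baseline <= high")
  v$check(is.character(paths) && length(paths) >= 1L, name,
          "paths must be a character vector")
  v$stop_if_any("owsa_parameter")
  structure(list(name = name, baseline = baseline, low = low, high = high,
                 paths = paths), class = "owsa_parameter")
}

#' Published one-way sensitivity-analysis parameter set
#'
#' The 20 tabulated rows: discount rate 5% [3%, 8%], initial utility 0.876
#' [0.78, 0.92], treatment time 5 [4, 6] years, horizon 40 [30, 50] years,
#' the eight per-year complication costs, and the eight complication
#' disutilities.  Costs and disutilities without reported 95% CIs carry
#' +/-20% and +/-10% ranges respectively.
#'
#' @return list of [owsa_parameter()]s.
#' @export
default_owsa_parameters <- function() {
  ue <- function(ev, both) {
    if (both) paste0("utilities.events.", ev, c(".event", ".subsequent"))
    else paste0("utilities.events.", ev, ".subsequent")
  }
  ce <- function(ev) paste0("costs.events.", ev, ".subsequent")
  list(
    owsa_parameter("discount rate", 0.05, 0.03, 0.08, "econ.discount_rate"),
    owsa_parameter("initial utility", 0.876, 0.78, 0.92, "utilities.initial"),
    owsa_parameter("treatment time", 5, 4, 6,
                   c("profiles.intervention.treatment_time",
                     "profiles.comparator.treatment_time")),
    owsa_parameter("time horizon", 40, 30, 50, "sim.horizon"),
    owsa_parameter("IHD per-year cost", 1123.51, 898.808, 1348.212, ce("ihd")),
    owsa_parameter("MI per-year cost", 484.52, 307.06, 661.99, ce("mi")),
    owsa_parameter("CHF per-year cost", 1604.12, 1334.83, 2800.64, ce("chf")),
    owsa_parameter("stroke per-year cost", 539.32, 474.42, 880.95,
                   ce("stroke")),
    owsa_parameter("blindness per-year cost", 1747.01, 1521.87, 1972.03,
                   ce("blindness")),
    owsa_parameter("ESRD per-year cost", 14685.91, 13994.99, 15500.9,
                   ce("renal")),
    owsa_parameter("amputation per-year cost", 4316.66, 0, 7669.32,
                   ce("amputation")),
    owsa_parameter("ulcer per-year cost", 813.01, 650.408, 975.612,
                   ce("ulcer")),
    owsa_parameter("IHD disutility", 0.09, 0.081, 0.099, ue("ihd", TRUE)),
    owsa_parameter("MI disutility", 0.236, 0.026, 0.446, ue("mi", FALSE)),
    owsa_parameter("CHF disutility", 0.236, 0.026, 0.446, ue("chf", TRUE)),
    owsa_parameter("stroke disutility", 0.326, 0.036, 0.616,
                   ue("stroke", FALSE)),
    owsa_parameter("blindness disutility", 0.157, 0.007, 0.307,
                   ue("blindness", TRUE)),
    owsa_parameter("ESRD disutility", 0.4, 0.19, 0.61, ue("renal", TRUE)),
    owsa_parameter("amputation disutility", 0.38, 0.204, 0.496,
                   ue("amputation", TRUE)),
    owsa_parameter("ulcer disutility", 0.059, 0.0531, 0.0649,
                   ue("ulcer", TRUE)))
}

# Sections whose perturbation can change event histories; anything else
# only moves the economic accrual and may reuse the frozen histories.
.sim_relevant <- function(paths) {
  any(grepl("^(cohort|sim|equations|profiles)\\.", paths) |
        paths %in% c("seed", "cohort", "sim", "equations", "profiles"))
}

# Run one perturbed configuration and return the ICUR summary at the
# context's intervention price.
.perturbed_icur <- function(fit, paths, values) {
  cfg <- fit$config
  for (k in seq_along(paths)) cfg <- set_config_path(cfg, paths[[k]],
                                                     values[[k]])
  run <- .run_config(cfg, cache = fit$cache)
  r <- run$result
  list(icur = r$icur, classification = r$classification,
       delta_qaly = r$delta_qaly, delta_cost = r$delta_cost)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the frozen-seed pipeline with exactly one parameter at its low
#' and then its high value, recording the ICUR at each end.  Rows are
#' sorted by descending bar width `|ICUR_high - ICUR_low|`.  When a
#' perturbation makes the intervention dominant (no ratio defined) the bar
#' endpoint is recorded as 0 and flagged.
#'
#' @param fit a [cua()] fit; its intervention price is held fixed.
#' @param parameters list of [owsa_parameter()]s
#'   (default [default_owsa_parameters()]).
#' @return an object of class `owsa`: a data.frame `rows` plus the baseline
#'   ICUR.
#' @export
owsa <- function(fit, parameters = default_owsa_parameters()) {
  stopifnot(inherits(fit, "cua"))
  for (p in parameters) stopifnot(inherits(p, "owsa_parameter"))
  one <- function(p, value) {
    r <- .perturbed_icur(fit, p$paths, rep(list(value), length(p$paths)))
    dom <- identical(r$classification, "dominant") || !is.finite(r$icur)
    list(icur = if (dom) 0 else r$icur, dominant = dom)
  }
  rows <- lapply(parameters, function(p) {
    lo <- one(p, p$low)
    hi <- one(p, p$high)
    data.frame(parameter = p$name, baseline = p$baseline,
               low = p$low, high = p$high,
               icur_low = lo$icur, icur_high = hi$icur,
               dominant_low = lo$dominant, dominant_high = hi$dominant,
               width = abs(hi$icur - lo$icur))
  })
  d <- do.call(rbind, rows)
  d <- d[order(-d$width), , drop = FALSE]
  rownames(d) <- NULL
  structure(list(rows = d, base_icur = fit$result$icur,
                 price = fit$outcomes$intervention$price,
                 wtp = fit$inputs$econ$wtp,
                 wtp_3x = fit$inputs$econ$wtp_3x),
            class = "owsa")
}

#' @export
print.owsa <- function(x, ...) {
  cat(sprintf("One-way sensitivity analysis at price %.2f (base ICUR %s)\n",
              x$price, if (is.finite(x$base_icur %||% NA_real_))
                sprintf("%.2f", x$base_icur) else "- (dominance)"))
  d <- x$rows
  d[c("icur_low", "icur_high", "width")] <-
    lapply(d[c("icur_low", "icur_high", "width")], round, 1)
  print(d[c("parameter", "low", "high", "icur_low", "icur_high", "width")],
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.owsa <- function(x, n_top = nrow(x$rows), ...) {
  d <- x$rows[seq_len(min(n_top, nrow(x$rows))), , drop = FALSE]
  d <- d[rev(seq_len(nrow(d))), ]
  lo <- pmin(d$icur_low, d$icur_high)
  hi <- pmax(d$icur_low, d$icur_high)
  mid <- x$base_icur
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(lo, hi, mid)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICUR", ylab = "", main = "Tornado diagram")
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi,
                 seq_len(nrow(d)) + 0.35, col = "steelblue")
  graphics::abline(v = mid, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

# --- probabilistic sensitivity analysis ---------------------------------

#' Distribution assignment for one PSA input
#'
#' @param name display name.
#' @param paths config paths receiving the sampled value.
#' @param sample function of no arguments returning one draw (called under
#'   the iteration's seed).
#' @param kind `"scalar"` replaces the config value; `"pair_mean"` replaces
#'   the mean of a `c(mean, sd)` pair (treatment-effect deltas).
#' @return an object of class `psa_distribution`.
#' @export
psa_distribution <- function(name, paths, sample,
                             kind = c("scalar", "pair_mean")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), is.character(paths), is.function(sample))
  structure(list(name = name, paths = paths, sample = sample, kind = kind),
            class = "psa_distribution")
}

.gamma_sampler <- function(mean, sd) {
  if (sd <= 0 || mean <= 0) return(function() mean)
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  function() stats::rgamma(1, shape = shape, rate = rate)
}

# Beta scaled to [0, 2 * mean]: symmetric, mean preserved.
.scaled_beta_sampler <- function(mean, sd) {
  if (sd <= 0 || mean <= 0) return(function() mean)
  sb <- min(sd / (2 * mean), 0.28)  # keep alpha > 0.5
  alpha <- 1 / (8 * sb^2) - 0.5
  function() 2 * mean * stats::rbeta(1, alpha, alpha)
}

.beta_sampler <- function(mean, sd) {
  if (sd <= 0) return(function() mean)
  v <- sd^2
  a <- mean * (mean * (1 - mean) / v - 1)
  b <- (1 - mean) * (mean * (1 - mean) / v - 1)
  function() stats::rbeta(1, a, b)
}

#' Default PSA distribution assignments
#'
#' Second-order distributions for the inputs the published analysis
#' subjects to uncertainty: per-year complication costs ~ Gamma (mean at
#' baseline; SD from the reported range where one exists, otherwise 20% of
#' the mean), utility decrements ~ Beta scaled to `[0, 2 x baseline]` (SD
#' from the reported range, otherwise 10% of the baseline), initial
#' utility ~ Beta, and treatment-effect deltas ~ Normal with their
#' reported SDs.  All assignments are plain data and freely overridable.
#'
#' @param config the run configuration being sampled.
#' @param include character subset of `c("costs", "utilities", "effects")`.
#' @return list of [psa_distribution()]s.
#' @export
default_psa_distributions <- function(config,
                                      include = c("costs", "utilities",
                                                  "effects")) {
  pars <- default_owsa_parameters()
  names(pars) <- vapply(pars, `[[`, character(1), "name")
  disp <- c(ihd = "IHD", mi = "MI", chf = "CHF", stroke = "stroke",
            blindness = "blindness", renal = "ESRD",
            amputation = "amputation", ulcer = "ulcer")
  out <- list()
  if ("costs" %in% include) {
    ci_based <- c("mi", "chf", "stroke", "blindness", "renal", "amputation")
    for (ev in .events) {
      base <- get_config_path(config, paste0("costs.events.", ev,
                                             ".subsequent"))
      row <- pars[[paste(disp[[ev]], "per-year cost")]]
      sd <- if (ev %in% ci_based && !is.null(row)) {
        (row$high - row$low) / (2 * stats::qnorm(0.975))
      } else 0.2 * base
      out[[length(out) + 1L]] <- psa_distribution(
        paste0(ev, " per-year cost"),
        paste0("costs.events.", ev, ".subsequent"),
        .gamma_sampler(base, sd))
    }
  }
  if ("utilities" %in% include) {
    u0 <- get_config_path(config, "utilities.initial")
    out[[length(out) + 1L]] <- psa_distribution(
      "initial utility", "utilities.initial",
      .beta_sampler(u0, (0.92 - 0.78) / (2 * stats::qnorm(0.975))))
    ci_based <- c("mi", "chf", "stroke", "blindness", "renal", "amputation")
    for (ev in .events) {
      base <- get_config_path(config, paste0("utilities.events.", ev,
                                             ".subsequent"))
      row <- pars[[paste(disp[[ev]], "disutility")]]
      sd <- if (ev %in% ci_based && !is.null(row)) {
        (row$high - row$low) / (2 * stats::qnorm(0.975))
      } else 0.1 * base
      evt <- get_config_path(config, paste0("utilities.events.", ev,
                                            ".event"))
      paths <- paste0("utilities.events.", ev,
                      if (isTRUE(all.equal(evt, base))) {
                        c(".event", ".subsequent")
                      } else ".subsequent")
      out[[length(out) + 1L]] <- psa_distribution(
        paste0(ev, " disutility"), paths,
        .scaled_beta_sampler(base, sd))
    }
  }
  if ("effects" %in% include) {
    for (arm in c("intervention", "comparator")) {
      deltas <- get_config_path(config, paste0("profiles.", arm, ".deltas"))
      for (nm in names(deltas)) {
        pair <- .as_pair(deltas[[nm]])
        m <- pair[1]; s <- if (length(pair) > 1L) pair[2] else 0
        out[[length(out) + 1L]] <- psa_distribution(
          paste(arm, nm, "delta"),
          paste0("profiles.", arm, ".deltas.", nm),
          local({ m0 <- m; s0 <- s
                  function() stats::rnorm(1, m0, s0) }),
          kind = "pair_mean")
      }
    }
  }
  out
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' For each iteration, samples every assigned input from its distribution,
#' re-runs the full pipeline (simulation + accrual) at the sampled
#' parameter vector under the frozen master-seed event streams, and records
#' the incremental result.  The probability of cost-effectiveness is the
#' fraction of draws whose incremental net monetary benefit at the chosen
#' willingness-to-pay is non-negative (`wtp * dQALY - dCost >= 0`);
#' dominant draws count as cost-effective.
#'
#' @param fit a [cua()] fit.
#' @param n number of Monte Carlo iterations (published setting: 1000).
#' @param distributions list of [psa_distribution()]s (default
#'   [default_psa_distributions()]).
#' @param wtp willingness-to-pay threshold for the cost-effectiveness flag
#'   (default the context's lambda).
#' @param seed seed for the parameter draws (default the fit's master
#'   seed); every draw is reproducible from it.
#' @return an object of class `psa`: `draws` data.frame (iteration,
#'   sampled parameters, `delta_qaly`, `delta_cost`, `icur`, `below_wtp`),
#'   `prob_cost_effective`, `wtp`, `n`.
#' @export
psa <- function(fit, n = 1000, distributions = NULL, wtp = NULL,
                seed = NULL) {
  stopifnot(inherits(fit, "cua"), is_number(n), n >= 1)
  if (is.null(distributions)) {
    distributions <- default_psa_distributions(fit$config)
  }
  for (d in distributions) stopifnot(inherits(d, "psa_distribution"))
  if (is.null(wtp)) wtp <- fit$inputs$econ$wtp
  if (is.null(seed)) seed <- fit$config$seed %||% 1
  dn <- vapply(distributions, `[[`, character(1), "name")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, "psa", i))
    cfg <- fit$config
    vals <- numeric(length(distributions))
    for (k in seq_along(distributions)) {
      d <- distributions[[k]]
      v <- d$sample()
      vals[[k]] <- v
      for (pt in d$paths) {
        if (identical(d$kind, "pair_mean")) {
          old <- .as_pair(get_config_path(cfg, pt))
          cfg <- set_config_path(cfg, pt,
                                 c(v, if (length(old) > 1L) old[2] else 0))
        } else {
          cfg <- set_config_path(cfg, pt, v)
        }
      }
    }
    run <- .run_config(cfg, cache = fit$cache)
    r <- run$result
    rows[[i]] <- c(iteration = i, stats::setNames(vals, dn),
                   delta_qaly = r$delta_qaly, delta_cost = r$delta_cost,
                   icur = if (is.na(r$icur)) NA_real_ else r$icur,
                   below_wtp = as.numeric(wtp * r$delta_qaly -
                                            r$delta_cost >= 0))
  }
  draws <- as.data.frame(do.call(rbind, rows))
  draws$below_wtp <- draws$below_wtp > 0
  structure(list(draws = draws,
                 prob_cost_effective = mean(draws$below_wtp),
                 wtp = wtp, n = as.integer(n), seed = seed,
                 price = fit$outcomes$intervention$price),
            class = "psa")
}

#' @export
print.psa <- function(x, ...) {
  cat(sprintf(paste("Probabilistic sensitivity analysis: %d iterations at",
                    "price %.2f\n"), x$n, x$price))
  cat(sprintf("  P(cost-effective at WTP %.2f) = %.3f\n",
              x$wtp, x$prob_cost_effective))
  cat(sprintf("  dQALY mean %.4f, dCost mean %.2f\n",
              mean(x$draws$delta_qaly), mean(x$draws$delta_cost)))
  invisible(x)
}

#' @export
plot.psa <- function(x, ...) {
  d <- x$draws
  graphics::plot(d$delta_qaly, d$delta_cost,
                 pch = 16, cex = 0.5,
                 col = ifelse(d$below_wtp, "steelblue", "firebrick"),
                 xlab = "Incremental QALYs", ylab = "Incremental cost",
                 main = "Cost-effectiveness plane")
  graphics::abline(0, x$wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  invisible(x)
}

#' Scenario analysis: re-price the comparator's drug component
#'
#' Multiplies the comparator arm's annual drug acquisition cost (the drug
#' component of therapy cost only; post-treatment therapy and complication
#' costs are untouched) and recomputes the comparison under the same
#' histories.  The comparator's total falls by exactly
#' `(1 - multiplier) x (discounted drug-cost component)`.
#'
#' @param fit a [cua()] fit.
#' @param multiplier positive price multiplier (published scenario: 0.8).
#' @param intervention_price optional intervention annual price for the
#'   comparison (default the fitted price).
#' @return a `cua_result` with an added `comparator_total` field.
#' @export
scenario <- function(fit, multiplier = 0.8, intervention_price = NULL) {
  stopifnot(inherits(fit, "cua"), is_number(multiplier), multiplier > 0)
  pe <- fit$patients$comparator
  p0 <- attr(pe, "price")
  pe$therapy_cost <- pe$therapy_cost +
    (multiplier - 1) * p0 * pe$disc_tx_years
  pe$total_cost <- pe$therapy_cost + pe$complication_cost
  attr(pe, "price") <- multiplier * p0
  oc <- summarize_arm(pe)
  oi <- if (is.null(intervention_price)) fit$outcomes$intervention
        else summarize_arm(.repriced_intervention(fit, intervention_price))
  res <- compare_arms(oi, oc, fit$inputs$econ)
  res$multiplier <- multiplier
  res
}
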