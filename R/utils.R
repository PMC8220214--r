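# Internal utilities: deterministic seed derivation, truncated-normal
# sampling, validation accumulation, discounting, config-path access.

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' All randomness in the package flows from a single master seed.  Sub-streams
#' (baseline sampling, per-patient event draws, PSA iterations) are keyed by
#' mixing the master seed with integer/character labels through a small
#' modular hash, so that e.g. two arms or two price points reuse identical
#' per-patient draws.
#'
#' @param ... integers or character labels to mix into the seed.
#' @return an integer in [0, 2^31 - 2] suitable for [set.seed()].
#' @keywords internal
derive_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "")) else as.numeric(x)
  }), use.names = FALSE)
  h <- 11
  for (p in parts) {
    # exact in double precision: |h| < 2^31, 69069 * 2^31 < 2^53
    h <- (h * 69069 + p + 1) %% 2147483647
  }
  # second mixing pass decorrelates nearby labels
  h <- (h * 69069 + 12345) %% 2147483647
  as.integer(h)
}

#' Truncated-normal sampling via inverse CDF
#'
#' Draws from Normal(mean, sd) truncated to [lo, hi].  Degenerate sd = 0
#' returns the mean (clamped to the interval).
#'
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  # guard against numerically exceeding the bounds in extreme tails
  pmin(pmax(x, lo), hi)
}

# Mean and SD of Normal(mu, sigma) truncated to [lo, hi].
.truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z <= 0) return(c(mean = mu, sd = 0))
  d <- (stats::dnorm(a) - stats::dnorm(b)) / Z
  m <- mu + sigma * d
  av <- if (is.finite(a)) a * stats::dnorm(a) else 0
  bv <- if (is.finite(b)) b * stats::dnorm(b) else 0
  v <- sigma^2 * (1 + (av - bv) / Z - d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying normal parameters whose [lo, hi]-truncation has the target
# mean and SD (so published summary statistics are recovered despite hard
# physiological floors).  Falls back to the naive parameters when the
# truncation probability is negligible or matching is infeasible.
.match_truncnorm <- function(mean, sd, lo, hi) {
  mm <- .truncnorm_moments(mean, sd, lo, hi)
  if (abs(mm[["mean"]] - mean) < 1e-4 * sd &&
        abs(mm[["sd"]] - sd) < 1e-4 * sd) {
    return(c(mu = mean, sigma = sd))
  }
  obj <- function(par) {
    m <- .truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (m[["mean"]] - mean)^2 / sd^2 + (m[["sd"]] - sd)^2 / sd^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(maxit = 500, reltol = 1e-14))
  if (!is.finite(fit$value) || fit$value > 1e-6) {
    # infeasible target (floor too close to the mean for the requested
    # SD); keep the best-effort parameters anyway
    fit2 <- stats::optim(fit$par, obj,
                         control = list(maxit = 500, reltol = 1e-14))
    if (fit2$value < fit$value) fit <- fit2
  }
  c(mu = fit$par[[1]], sigma = exp(fit$par[[2]]))
}

# Validation accumulator: collect all violations, then fail once with the
# full list (spec: report every schema violation, not just the first).
new_validator <- function() {
  errs <- character(0)
  list(
    check = function(ok, path, msg) {
      if (!isTRUE(ok)) errs[[length(errs) + 1L]] <<- paste0(path, ": ", msg)
      invisible(isTRUE(ok))
    },
    errors = function() errs,
    stop_if_any = function(context) {
      if (length(errs)) {
        stop(context, " validation failed:\n  - ",
             paste(errs, collapse = "\n  - "), call. = FALSE)
      }
      invisible(TRUE)
    }
  )
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
is_prob <- function(x) is_number(x) && x >= 0 && x <= 1

#' Discount factors for annual cycles
#'
#' First cycle undiscounted (exponent 0), end-of-year accrual thereafter:
#' cycle t in 1..horizon gets weight (1 + r)^-(t - 1).
#'
#' @param horizon number of annual cycles.
#' @param rate annual discount rate (>= 0).
#' @return numeric vector of length `horizon`.
#' @export
discount_factors <- function(horizon, rate) {
  stopifnot(is_number(rate), rate >= 0, horizon >= 1)
  (1 + rate)^-(seq_len(horizon) - 1)
}

# --- nested config path access ------------------------------------------

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Read a value from a nested configuration list by dotted path
#' @param config a nested list.
#' @param path dotted key path, e.g. `"costs.events.mi.subsequent"`.
#' @export
get_config_path <- function(config, path) {
  keys <- split_path(path)
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("config path not found: ", path, " (missing '", k, "')",
           call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' Set a value in a nested configuration list by dotted path
#'
#' Used by the one-way and probabilistic sensitivity analyses to perturb a
#' single input while leaving the rest of the configuration untouched.  The
#' path must already exist (perturbations never invent new keys).
#'
#' @inheritParams get_config_path
#' @param value replacement value.
#' @export
set_config_path <- function(config, path, value) {
  keys <- split_path(path)
  get_config_path(config, path)  # errors if absent
  rec <- function(node, keys) {
    k <- keys[[1]]
    if (length(keys) == 1L) node[[k]] <- value
    else node[[k]] <- rec(node[[k]], keys[-1])
    node
  }
  rec(config, keys)
}

# Rolling polynomial hash of a character scalar, for run manifests.
text_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h1 <- 17; h2 <- 5381
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 131 + b) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}
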