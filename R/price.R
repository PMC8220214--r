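# Value-based price exploration: re-price the intervention arm's therapy
# stream over frozen histories (common random numbers), giving an
# incremental cost that is exactly affine in the annual price, and invert
# the ICUR against a willingness-to-pay target by binary search (with a
# closed-form affine inversion as cross-check).

# Per-patient intervention economics at an arbitrary annual price.  Only
# the on-treatment drug component moves; histories and QALYs are untouched.
.repriced_intervention <- function(fit, price) {
  if (!is_number(price) || price < 0) {
    stop("annual price must be a single number >= 0")
  }
  pe <- fit$patients$intervention
  base_price <- attr(pe, "price")
  pe$therapy_cost <- pe$therapy_cost + (price - base_price) * pe$disc_tx_years
  pe$total_cost <- pe$therapy_cost + pe$complication_cost
  attr(pe, "price") <- price
  pe
}

#' Incremental cost-utility result at a given intervention price
#'
#' Uses the fitted context's frozen histories: the intervention arm's
#' therapy stream is re-priced while event histories, QALYs and the
#' comparator arm are unchanged, so `dQALY` is identical across all prices
#' and `dCost(price)` is exactly affine with slope equal to the mean
#' discounted on-treatment person-years.
#'
#' @param fit a [cua()] fit (the frozen simulation context).
#' @param price annual intervention drug cost (>= 0).
#' @return a [compare_arms()] `cua_result`.
#' @export
icur_at_price <- function(fit, price) {
  stopifnot(inherits(fit, "cua"))
  oi <- summarize_arm(.repriced_intervention(fit, price))
  compare_arms(oi, fit$outcomes$comparator, fit$inputs$econ)
}

.resolve_target <- function(target, econ) {
  if (is.character(target)) {
    lab <- match.arg(target, c("lambda", "3lambda"))
    list(label = lab,
         value = if (identical(lab, "lambda")) econ$wtp else econ$wtp_3x)
  } else {
    stopifnot(is_number(target), target > 0)
    list(label = format(target), value = target)
  }
}

#' Closed-form affine inversion of the price--ICUR relationship
#'
#' Fits `dCost(p) = a + b p` exactly from two price evaluations (the
#' relationship is affine under common random numbers) and returns the
#' price at which `dCost(p) / dQALY` equals the target.  Exposed as an
#' independent cross-check of [find_price()]'s bisection.
#'
#' @param fit a [cua()] fit.
#' @param target `"lambda"`, `"3lambda"`, or a numeric willingness-to-pay
#'   (currency/QALY).
#' @param prices two distinct probe prices used to identify the line.
#' @return list with `price`, `a` (intercept), `b` (slope = mean
#'   discounted on-treatment person-years), `delta_qaly`, `target`.
#' @export
affine_price_inversion <- function(fit, target = "lambda",
                                   prices = c(0, 1000)) {
  stopifnot(inherits(fit, "cua"), length(prices) == 2L,
            prices[1] != prices[2])
  tg <- .resolve_target(target, fit$inputs$econ)
  dq <- fit$result$delta_qaly
  if (dq <= 0) stop("delta QALY must be positive to invert the ICUR")
  d1 <- icur_at_price(fit, prices[1])$delta_cost
  d2 <- icur_at_price(fit, prices[2])$delta_cost
  b <- (d2 - d1) / (prices[2] - prices[1])
  a <- d1 - b * prices[1]
  list(price = (tg$value * dq - a) / b, a = a, b = b,
       delta_qaly = dq, target = tg$value)
}

#' Find the intervention price meeting a willingness-to-pay target
#'
#' Bisection on the annual intervention price: starting from the midpoint
#' of the bracket, the ICUR at the midpoint is compared with the target and
#' the half-interval that cannot contain the solution is discarded, until
#' the achieved ICUR is within `tolerance` of the target.  The bracket is
#' checked first; where the intervention dominates at the lower bound (no
#' ratio defined) the bracket test falls back to the sign of
#' `dCost - target * dQALY`, which is monotone in price.
#'
#' @param fit a [cua()] fit (frozen context; re-running with the same seed
#'   is bit-identical).
#' @param target `"lambda"`, `"3lambda"`, or a numeric currency/QALY value.
#' @param bounds search bracket for the annual price; default spans the
#'   comparator price to four times it.
#' @param tolerance convergence criterion on `|ICUR - target|`
#'   (currency/QALY, default $1).
#' @param max_iter hard iteration cap.
#' @return an object of class `price_search_result`: `price`, `icur`,
#'   `converged`, `iterations`, and a `trace` data.frame of the bracket,
#'   midpoint and ICUR per iteration.
#' @export
find_price <- function(fit, target = "lambda", bounds = NULL,
                       tolerance = 1, max_iter = 60) {
  stopifnot(inherits(fit, "cua"), is_number(tolerance), tolerance > 0)
  econ <- fit$inputs$econ
  tg <- .resolve_target(target, econ)
  dq <- fit$result$delta_qaly
  if (dq <= 0) {
    stop("delta QALY is not positive; the ICUR cannot be inverted ",
         "against a positive willingness-to-pay target")
  }
  p0 <- fit$outcomes$comparator$price
  if (is.null(bounds)) bounds <- c(p0, 4 * p0)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2], bounds[1] >= 0)
  # monotone surrogate g(p) = dCost(p) - target * dQALY; g = 0 at solution
  g <- function(p) icur_at_price(fit, p)$delta_cost - tg$value * dq
  g_lo <- g(bounds[1]); g_hi <- g(bounds[2])
  icur_of <- function(gv) gv / dq + tg$value
  if (g_lo > 0 || g_hi < 0) {
    stop(sprintf(paste("target %.2f not bracketed by bounds [%.2f, %.2f]:",
                       "endpoint ICURs are %.2f and %.2f"),
                 tg$value, bounds[1], bounds[2],
                 icur_of(g_lo), icur_of(g_hi)))
  }
  lo <- bounds[1]; hi <- bounds[2]
  trace <- vector("list", max_iter)
  converged <- FALSE
  mid <- NA_real_; icur_mid <- NA_real_
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    res <- icur_at_price(fit, mid)
    icur_mid <- if (res$delta_qaly > 0) res$delta_cost / res$delta_qaly
                else NA_real_
    trace[[k]] <- data.frame(iteration = k, lower = lo, upper = hi,
                             price = mid, delta_cost = res$delta_cost,
                             icur = icur_mid)
    if (is.finite(icur_mid) && abs(icur_mid - tg$value) <= tolerance) {
      converged <- TRUE
      break
    }
    if (res$delta_cost - tg$value * dq > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-10) break
  }
  structure(list(target_label = tg$label, target = tg$value,
                 price = mid, icur = icur_mid,
                 delta_qaly = dq,
                 delta_cost = icur_mid * dq,
                 converged = converged,
                 iterations = sum(!vapply(trace, is.null, logical(1))),
                 tolerance = tolerance, bounds = bounds,
                 trace = do.call(rbind, trace[!vapply(trace, is.null,
                                                      logical(1))]),
                 currency = econ$currency),
            class = "price_search_result")
}

#' @export
print.price_search_result <- function(x, ...) {
  cat("Price search: target", x$target_label, "=",
      sprintf("%.2f %s/QALY", x$target, x$currency), "\n")
  cat(sprintf("  price C* = %.2f %s/year after %d iterations (%s)\n",
              x$price, x$currency, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  achieved ICUR = %.2f (dQALY = %.4f, dCost = %.2f)\n",
              x$icur, x$delta_qaly, x$delta_cost))
  invisible(x)
}

#' Export a price-search result (and its iteration trace) as CSV
#'
#' @param result a `price_search_result`.
#' @param path CSV path for the one-row summary.
#' @param trace_path optional CSV path for the iteration trace.
#' @export
write_price_search_csv <- function(result, path, trace_path = NULL) {
  stopifnot(inherits(result, "price_search_result"))
  utils::write.csv(
    data.frame(target_label = result$target_label, target = result$target,
               price = result$price, icur = result$icur,
               delta_qaly = result$delta_qaly,
               delta_cost = result$delta_cost,
               converged = result$converged,
               iterations = result$iterations,
               currency = result$currency),
    path, row.names = FALSE)
  if (!is.null(trace_path)) {
    utils::write.csv(result$trace, trace_path, row.names = FALSE)
  }
  invisible(path)
}
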