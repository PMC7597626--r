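#' Integrate the fitted diurnal curve over a time window
#'
#' Cumulative gas exchange over part of the day is the time integral of
#' the instantaneous rate. The curve
#' \eqn{\exp(\omega \ln t - \eta/t + \psi)} has no elementary
#' antiderivative, so the integral is computed by a composite
#' quadrature rule on an evenly spaced grid: Simpson's rule by default
#' (the interval count is rounded up to the next even number), or the
#' trapezoid rule. Results are in response-unit hours, e.g.
#' \eqn{\mu mol\ CO_2\ m^{-2} s^{-1} \cdot h} for net photosynthesis.
#'
#' The window must start after midnight (`t_start > 0`): the curve is
#' singular at `t = 0`, so "since dawn" totals use the first
#' measurement hour (07:00 by convention) as the lower limit.
#'
#' @param params A [model_params()] object.
#' @param t_start,t_end Window limits in decimal hours,
#'   `0 < t_start < t_end`.
#' @param step Target grid spacing in hours (default 0.1).
#' @param rule `"simpson"` (default) or `"trapezoid"`.
#' @return The integral, a single number.
#' @examples
#' # constant curve integrates to the window width
#' integrate_response(model_params(0, 0, 0), 6, 18) # 12
#' @export
integrate_response <- function(params, t_start, t_end, step = 0.1,
                               rule = c("simpson", "trapezoid")) {
  check_params(params)
  rule <- match.arg(rule)
  if (!is.numeric(t_start) || t_start <= 0) {
    stop("t_start must be > 0: the curve is singular at t = 0", call. = FALSE)
  }
  if (!is.numeric(t_end) || t_end <= t_start) {
    stop("t_end must exceed t_start", call. = FALSE)
  }
  if (!is.numeric(step) || step <= 0) {
    stop("step must be a positive number of hours", call. = FALSE)
  }

  n <- max(1L, as.integer(ceiling((t_end - t_start) / step)))
  if (rule == "simpson" && n %% 2L == 1L) n <- n + 1L
  x <- seq(t_start, t_end, length.out = n + 1L)
  y <- evaluate_response(params, x)
  h <- (t_end - t_start) / n

  if (rule == "trapezoid") {
    h * (sum(y) - (y[1L] + y[n + 1L]) / 2)
  } else {
    odd  <- y[seq(2L, n, by = 2L)]                       # interior odd nodes
    even <- if (n >= 4L) y[seq(3L, n - 1L, by = 2L)] else numeric(0)
    h / 3 * (y[1L] + y[n + 1L] + 4 * sum(odd) + 2 * sum(even))
  }
}

#' Running cumulative response along a time grid
#'
#' Integrates the curve piecewise between consecutive grid times and
#' accumulates, so `cumulative[k]` approximates the integral from
#' `grid[1]` to `grid[k]`. The integrand is positive, hence the running
#' values are nondecreasing and the last equals the total over the
#' grid span.
#'
#' @inheritParams integrate_response
#' @param grid Strictly increasing times, all `> 0` (hours).
#' @return Object of class `"cumulative_result"`: list with `grid`,
#'   `cumulative` (same length, starting at 0), and `daily_total`.
#' @export
cumulative_curve <- function(params, grid, step = 0.1,
                             rule = c("simpson", "trapezoid")) {
  check_params(params)
  rule <- match.arg(rule)
  check_time(grid)
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least two times",
         call. = FALSE)
  }
  pieces <- vapply(seq_len(length(grid) - 1L), function(i) {
    integrate_response(params, grid[i], grid[i + 1L], step = step, rule = rule)
  }, numeric(1))
  structure(list(grid = grid,
                 cumulative = c(0, cumsum(pieces)),
                 daily_total = sum(pieces)),
            class = "cumulative_result")
}

#' Share of the daily response achieved by a cutoff time
#'
#' Ratio of the integral over `[t_start, cutoff]` to the integral over
#' the full window `[t_start, t_end]`; e.g. the fraction of daily
#' carbon assimilation already fixed by noon. Always in (0, 1] since
#' the integrand is positive.
#'
#' @inheritParams integrate_response
#' @param cutoff Cutoff time, `t_start < cutoff <= t_end`.
#' @param window Length-2 numeric, `c(t_start, t_end)`; defaults to the
#'   07:00-17:00 measurement day.
#' @return Fraction in (0, 1].
#' @export
fraction_achieved_by <- function(params, cutoff, window = c(7, 17),
                                 step = 0.1,
                                 rule = c("simpson", "trapezoid")) {
  rule <- match.arg(rule)
  if (length(window) != 2L || !(window[1] < window[2])) {
    stop("window must be c(t_start, t_end) with t_start < t_end",
         call. = FALSE)
  }
  if (!(cutoff > window[1] && cutoff <= window[2])) {
    stop("cutoff must lie inside the window: t_start < cutoff <= t_end",
         call. = FALSE)
  }
  num <- integrate_response(params, window[1], cutoff, step = step, rule = rule)
  den <- integrate_response(params, window[1], window[2], step = step,
                            rule = rule)
  num / den
}

#' Daily total of a fitted response
#'
#' Convenience wrapper: integrates the (fitted) curve over the
#' photoperiod window with the default quadrature settings. Accepts
#' either a [fit_diurnal()] result or bare [model_params()].
#'
#' @param fit A `"diurnal_fit"` object or a [model_params()] object.
#' @inheritParams integrate_response
#' @param window Length-2 numeric window, default `c(7, 17)`.
#' @return The daily total in response-unit hours.
#' @export
daily_total <- function(fit, window = c(7, 17), step = 0.1,
                        rule = c("simpson", "trapezoid")) {
  rule <- match.arg(rule)
  params <- if (inherits(fit, "diurnal_fit")) fit$params else fit
  if (length(window) != 2L || any(window <= 0) || any(window >= 24)) {
    stop("window must lie within (0, 24) hours", call. = FALSE)
  }
  integrate_response(params, window[1], window[2], step = step, rule = rule)
}
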