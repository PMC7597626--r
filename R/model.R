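#' Parameters of the diurnal gas-exchange curve
#'
#' Container for the three constants of the log-linear diurnal response
#' model
#' \deqn{p(t) = \exp(\omega \ln t - \eta / t + \psi),}
#' the closed-form solution of the rate law
#' \eqn{dp/dt = p (\omega/t + \eta/t^2)}. Time \eqn{t} is in decimal
#' clock hours since local midnight (07:00 is `t = 7`), which keeps
#' every daytime measurement strictly positive; the curve is singular
#' at `t = 0` and is never evaluated there.
#'
#' With `omega < 0` and `eta > 0` the curve rises from early morning to
#' an interior maximum at `t = -eta/omega` and declines afterwards --
#' the typical unimodal diurnal course of net photosynthesis, stomatal
#' conductance and transpiration. Other sign combinations give
#' monotone curves and are permitted, but [peak_time()] is only defined
#' for the unimodal case.
#'
#' @param omega Dimensionless coefficient of \eqn{\ln t}. Negative for
#'   a diurnal (rise-then-fall) curve.
#' @param eta Coefficient of \eqn{1/t}, in hours. Positive for a
#'   diurnal curve.
#' @param psi Dimensionless log-scale intercept; `exp(psi)` carries the
#'   amplitude (and the units) of the response.
#' @return An object of class `"model_params"`: a list with elements
#'   `omega`, `eta`, `psi`.
#' @seealso [evaluate_response()], [response_rate()], [peak_time()],
#'   [fit_diurnal()]
#' @examples
#' p <- model_params(omega = -2, eta = 18, psi = 9.8)
#' peak_time(p) # 9, i.e. 09:00
#' evaluate_response(p, t = c(7, 9, 11))
#' @export
model_params <- function(omega, eta, psi) {
  stopifnot(is.numeric(omega), length(omega) == 1L,
            is.numeric(eta),   length(eta)   == 1L,
            is.numeric(psi),   length(psi)   == 1L)
  if (!all(is.finite(c(omega, eta, psi)))) {
    stop("model parameters omega, eta, psi must all be finite", call. = FALSE)
  }
  structure(list(omega = as.numeric(omega),
                 eta   = as.numeric(eta),
                 psi   = as.numeric(psi)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Diurnal response curve p(t) = exp(%.4g ln t - %.4g/t + %.4g)\n",
              x$omega, x$eta, x$psi))
  if (x$omega < 0 && x$eta > 0) {
    cat(sprintf("  unimodal; interior peak at t = %.3f h\n", -x$eta / x$omega))
  } else {
    cat("  monotone on t > 0 (no interior peak)\n")
  }
  invisible(x)
}

# shared domain check: the model is undefined at t = 0 and meaningless
# for negative clock time
check_time <- function(t) {
  if (!is.numeric(t) || length(t) < 1L) {
    stop("t must be a numeric vector of clock hours", call. = FALSE)
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop("t must be > 0: the diurnal curve exp(omega ln t - eta/t + psi) ",
         "is singular at t = 0 and undefined for t <= 0",
         call. = FALSE)
  }
  invisible(t)
}

check_params <- function(params) {
  if (!inherits(params, "model_params")) {
    stop("params must be a model_params object (see model_params())",
         call. = FALSE)
  }
  invisible(params)
}

#' Evaluate the diurnal response curve
#'
#' Computes \eqn{p(t) = \exp(\omega \ln t - \eta/t + \psi)} at clock
#' times `t` (decimal hours since midnight). The result is strictly
#' positive for any finite parameters, which is what makes the model
#' fit gas-exchange rates on the log scale.
#'
#' @param params A [model_params()] object.
#' @param t Numeric vector of times, all `> 0` (hours).
#' @return Numeric vector of responses, same units as the fitted data.
#' @export
evaluate_response <- function(params, t) {
  check_params(params)
  check_time(t)
  exp(params$omega * log(t) - params$eta / t + params$psi)
}

#' Instantaneous rate of change of the diurnal curve
#'
#' The model's rate law: \eqn{dp/dt = p(t)\,(\omega/t + \eta/t^2)}.
#' Positive while the response is still climbing, zero at the peak
#' (`t = -eta/omega` when `omega < 0, eta > 0`), negative during the
#' afternoon decline.
#'
#' @inheritParams evaluate_response
#' @return Numeric vector of rates, response units per hour.
#' @export
response_rate <- function(params, t) {
  check_params(params)
  check_time(t)
  evaluate_response(params, t) * (params$omega / t + params$eta / t^2)
}

#' Time of the diurnal maximum
#'
#' Solves \eqn{dp/dt = 0} for the unimodal case: the rate
#' \eqn{p (\omega/t + \eta/t^2)} vanishes at \eqn{t^* = -\eta/\omega},
#' which is a maximum exactly when `omega < 0` and `eta > 0`.
#'
#' @param params A [model_params()] object with `omega < 0`, `eta > 0`.
#' @return The peak time in decimal hours.
#' @export
peak_time <- function(params) {
  check_params(params)
  if (!(params$omega < 0 && params$eta > 0)) {
    stop("no interior peak: a diurnal maximum on t > 0 requires ",
         "omega < 0 and eta > 0", call. = FALSE)
  }
  -params$eta / params$omega
}
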