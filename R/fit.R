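#' Fit the diurnal curve to one observed series
#'
#' Estimates (`omega`, `eta`, `psi`) by ordinary least squares on the
#' log scale: \eqn{\ln p} is exactly linear in \eqn{(\ln t, -1/t, 1)},
#' so the fit is closed-form and deterministic, with no starting
#' values. Goodness of fit is then assessed on the original scale,
#' where instruments report: `r` is the Pearson correlation between
#' observed and back-transformed fitted values, and `S` the residual
#' standard error \eqn{\sqrt{\sum(obs - fit)^2 / (n - 3)}}.
#'
#' Nonpositive observations cannot enter a log fit; they are excluded
#' with a warning rather than shifted, to avoid inventing an offset.
#' An optional Gauss-Newton refinement (`refine = TRUE`) re-minimises
#' the sum of squared errors on the original scale starting from the
#' log-scale solution; it is off by default because the log-scale
#' estimator is exact whenever the data follow the model with
#' multiplicative error.
#'
#' @param t Numeric vector of measurement times, decimal hours, `> 0`.
#' @param value Numeric vector of observed responses, same length.
#' @param refine Logical; if `TRUE`, polish the estimate by
#'   Gauss-Newton ([stats::nls()]) on the original scale.
#' @return An object of class `"diurnal_fit"`: list with `params`
#'   ([model_params()]), `n` (points used), `r`, `S`, `window`
#'   (`c(t_min, t_max)`), and `refined`.
#' @examples
#' tr <- c(7, 9, 11, 13, 15, 17)
#' y <- evaluate_response(model_params(-2, 18, 3), tr)
#' fit_diurnal(tr, y) # recovers (-2, 18, 3) exactly, r = 1, S = 0
#' @export
fit_diurnal <- function(t, value, refine = FALSE) {
  if (length(t) != length(value)) {
    stop("t and value must have the same length", call. = FALSE)
  }
  ok <- is.finite(value) & value > 0
  if (any(!ok)) {
    warning(sprintf(
      "excluding %d nonpositive or non-finite observation(s) from the log-scale fit",
      sum(!ok)), call. = FALSE)
    t <- t[ok]
    value <- value[ok]
  }
  if (length(value) < 3L) {
    stop("insufficient data: at least 3 positive observations are needed ",
         "to fit (omega, eta, psi)", call. = FALSE)
  }
  check_time(t)
  if (length(unique(t)) < 3L) {
    stop("insufficient data: at least 3 distinct measurement times are ",
         "needed (the design is singular otherwise)", call. = FALSE)
  }

  lt  <- log(t)
  nit <- -1 / t
  ols <- stats::lm(log(value) ~ lt + nit)
  cf  <- stats::coef(ols)
  if (anyNA(cf)) {
    stop("singular design: times do not separate ln t and 1/t", call. = FALSE)
  }
  params <- model_params(omega = cf[["lt"]],
                         eta   = cf[["nit"]],
                         psi   = cf[["(Intercept)"]])

  if (isTRUE(refine)) {
    start <- list(omega = params$omega, eta = params$eta, psi = params$psi)
    nl <- tryCatch(
      stats::nls(value ~ exp(omega * log(t) - eta / t + psi),
                 start = start,
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      cf2 <- stats::coef(nl)
      params <- model_params(cf2[["omega"]], cf2[["eta"]], cf2[["psi"]])
    } else {
      warning("Gauss-Newton refinement failed to converge; ",
              "returning the log-scale estimate", call. = FALSE)
    }
  }

  pred <- evaluate_response(params, t)
  n <- length(value)
  structure(list(
    params  = params,
    n       = n,
    r       = goodness_r(value, pred),
    S       = if (n > 3L) goodness_S(value, pred, k = 3L) else NA_real_,
    window  = range(t),
    refined = isTRUE(refine)
  ), class = "diurnal_fit")
}

#' @export
print.diurnal_fit <- function(x, ...) {
  cat(sprintf(
    "Diurnal fit (n = %d, window %.1f-%.1f h)%s\n",
    x$n, x$window[1], x$window[2],
    if (x$refined) ", Gauss-Newton refined" else ""))
  print(x$params)
  cat(sprintf("  r = %.4f, S = %s\n", x$r,
              if (is.na(x$S)) "NA (n = 3)" else sprintf("%.4f", x$S)))
  invisible(x)
}

#' Pearson correlation between observed and fitted values
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2),
#'   each with nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
goodness_r <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("observed and predicted must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("undefined correlation: a sequence has zero variance", call. = FALSE)
  }
  stats::cor(observed, predicted)
}

#' Residual standard error on the original scale
#'
#' \eqn{S = \sqrt{\sum (obs - pred)^2 / (n - k)}} with `k` the number
#' of fitted constants (3 for this model).
#'
#' @inheritParams goodness_r
#' @param k Number of estimated parameters (default 3).
#' @return Nonnegative standard error, in response units.
#' @export
goodness_S <- function(observed, predicted, k = 3L) {
  n <- length(observed)
  if (length(predicted) != n) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (n <= k) {
    stop(sprintf("no residual degrees of freedom: n = %d <= k = %d", n, k),
         call. = FALSE)
  }
  sqrt(sum((observed - predicted)^2) / (n - k))
}

#' Fit every treatment cell of a measurement table
#'
#' Fits the diurnal curve independently to each water band x Si dose x
#' response kind cell of a long-format measurement table, pooling
#' replicates as individual points (set `aggregate = "means"` to fit
#' per-time replicate means instead). Cells whose data violate the fit
#' preconditions are reported with the failure reason in the `note`
#' column rather than silently dropped, so the output always has one
#' row per requested cell.
#'
#' @param table A measurement data frame with columns `water_band`,
#'   `si_dose_mg_per_L`, `replicate`, `time_h`, `response_kind`,
#'   `value`, `units` (see [read_measurements()]).
#' @param kinds Response kinds to fit (default: all present).
#' @param aggregate `"pool"` (default) or `"means"`.
#' @param refine Passed to [fit_diurnal()].
#' @return A data frame with one row per cell: `water_band`,
#'   `si_dose_mg_per_L`, `response_kind`, `omega`, `eta`, `psi`, `n`,
#'   `r`, `S`, `note` (`NA` for clean fits; the error or warning text
#'   otherwise).
#' @export
fit_all <- function(table, kinds = NULL, aggregate = c("pool", "means"),
                    refine = FALSE) {
  validate_measurements(table)
  aggregate <- match.arg(aggregate)
  if (is.null(kinds)) kinds <- unique(table$response_kind)
  table <- table[table$response_kind %in% kinds, , drop = FALSE]
  if (nrow(table) == 0L) {
    stop("empty measurement table: nothing to fit", call. = FALSE)
  }

  cells <- unique(table[, c("water_band", "si_dose_mg_per_L", "response_kind")])
  cells <- cells[order(match(cells$water_band, unique(table$water_band)),
                       cells$si_dose_mg_per_L,
                       match(cells$response_kind, kinds)), , drop = FALSE]

  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- table[table$water_band == cell$water_band &
                   table$si_dose_mg_per_L == cell$si_dose_mg_per_L &
                   table$response_kind == cell$response_kind, , drop = FALSE]
    if (aggregate == "means") {
      agg <- stats::aggregate(value ~ time_h, data = sub, FUN = mean)
      tt <- agg$time_h; vv <- agg$value
    } else {
      tt <- sub$time_h; vv <- sub$value
    }
    notes <- character(0)
    fit <- withCallingHandlers(
      tryCatch(fit_diurnal(tt, vv, refine = refine),
               error = function(e) {
                 notes <<- c(notes, conditionMessage(e))
                 NULL
               }),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    base <- data.frame(water_band = cell$water_band,
                       si_dose_mg_per_L = cell$si_dose_mg_per_L,
                       response_kind = cell$response_kind,
                       stringsAsFactors = FALSE)
    if (is.null(fit)) {
      cbind(base, data.frame(omega = NA_real_, eta = NA_real_, psi = NA_real_,
                             n = NA_integer_, r = NA_real_, S = NA_real_,
                             note = paste(notes, collapse = "; ")))
    } else {
      cbind(base, data.frame(omega = fit$params$omega, eta = fit$params$eta,
                             psi = fit$params$psi, n = fit$n,
                             r = fit$r, S = fit$S,
                             note = if (length(notes)) {
                               paste(notes, collapse = "; ")
                             } else NA_character_))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
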