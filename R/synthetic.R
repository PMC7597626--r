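# Synthetic factorial drought x silicon gas-exchange experiment.

#' Soil-moisture bands and silicon doses of the factorial design
#'
#' `water_bands()` returns the four soil-moisture treatments as
#' percent-of-field-capacity ranges, from well-watered control to
#' severe stress; `si_doses()` returns the four silicon irrigation
#' doses in mg L-1.
#'
#' @return Character vector of bands / numeric vector of doses.
#' @export
water_bands <- function() c("100-95", "80-75", "55-50", "35-30")

#' @rdname water_bands
#' @export
si_doses <- function() c(0, 100, 300, 500)

response_kinds <- function() c("PN", "GS", "E")

response_units <- function(kind) {
  c(PN = "umol CO2 m-2 s-1",
    GS = "mmol H2O m-2 s-1",
    E  = "mmol H2O m-2 s-1")[kind]
}

#' Treatment design of the simulated experiment
#'
#' Describes which factorial cells to simulate and the diurnal
#' sampling schedule. Defaults reproduce the full experiment: four
#' soil-moisture bands x four Si doses, five replicate plants, gas
#' exchange measured every 2 h from 07:00 to 17:00.
#'
#' @param water_band Subset of [water_bands()].
#' @param si_dose Subset of [si_doses()], mg L-1.
#' @param replicates Number of replicate plants per cell (>= 1).
#' @param sample_times Strictly increasing clock hours, all > 0.
#' @return Object of class `"treatment_design"`.
#' @export
treatment_design <- function(water_band = water_bands(),
                             si_dose = si_doses(),
                             replicates = 5L,
                             sample_times = c(7, 9, 11, 13, 15, 17)) {
  if (!all(water_band %in% water_bands())) {
    stop("unknown water band; expected a subset of: ",
         paste(water_bands(), collapse = ", "), call. = FALSE)
  }
  if (!all(si_dose %in% si_doses())) {
    stop("unknown Si dose; expected a subset of: ",
         paste(si_doses(), collapse = ", "), call. = FALSE)
  }
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (any(sample_times <= 0) || any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing and > 0", call. = FALSE)
  }
  structure(list(water_band = water_band, si_dose = si_dose,
                 replicates = as.integer(replicates),
                 sample_times = sample_times),
            class = "treatment_design")
}

#' Settings of the synthetic gas-exchange generator
#'
#' Holds everything the simulator needs: the RNG seed, the
#' multiplicative (lognormal) measurement noise, the base diurnal
#' curve per response kind, and the treatment effects. Treatments act
#' purely on amplitude -- each cell's curve is the base curve with
#' `psi` shifted by the log of its water and Si multipliers -- so the
#' peak time is identical across treatments, as observed in the field
#' (all responses peak near 09:00 regardless of stress).
#'
#' Default multipliers encode the qualitative treatment structure:
#' water multipliers fall monotonically with stress severity (1, 0.79,
#' 0.60, 0.46 -- the severe value chosen so that severe-band daily
#' totals are about 46% of control), and Si multipliers rank 300 > 500
#' > 100 > 0 mg L-1 (1.10, 1.06, 1.03, 1), the intermediate dose being
#' the most effective. They are calibration knobs, not ground truth.
#'
#' @param seed Integer RNG seed.
#' @param noise_sigma_ln Standard deviation of the log-scale
#'   measurement noise (default 0.05, i.e. ~5% multiplicative error).
#' @param base_params Named list of [model_params()], one per response
#'   kind (`PN`, `GS`, `E`). Defaults peak at 09:00 with realistic
#'   amplitudes (~30 umol m-2 s-1 for PN).
#' @param water_multipliers Named numeric, one per water band, control
#'   = 1, strictly decreasing with stress.
#' @param si_multipliers Named numeric, one per Si dose, 0-dose = 1,
#'   ranked 300 > 500 > 100 > 0.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    seed = 1L,
    noise_sigma_ln = 0.05,
    base_params = list(
      PN = model_params(-6, 54, log(30)  + 6 * log(9) + 6),
      GS = model_params(-6, 54, log(200) + 6 * log(9) + 6),
      E  = model_params(-6, 54, log(4)   + 6 * log(9) + 6)),
    water_multipliers = c("100-95" = 1, "80-75" = 0.79,
                          "55-50" = 0.60, "35-30" = 0.46),
    si_multipliers = c("0" = 1, "100" = 1.03, "300" = 1.10, "500" = 1.06)) {
  if (noise_sigma_ln < 0) stop("noise_sigma_ln must be >= 0", call. = FALSE)
  if (!all(response_kinds() %in% names(base_params))) {
    stop("base_params needs entries PN, GS and E", call. = FALSE)
  }
  lapply(base_params[response_kinds()], check_params)
  if (!setequal(names(water_multipliers), water_bands())) {
    stop("water_multipliers must be named by the four water bands",
         call. = FALSE)
  }
  wm <- water_multipliers[water_bands()]
  if (wm[["100-95"]] != 1 || any(diff(wm) >= 0)) {
    stop("water multipliers must start at 1 for the control band and ",
         "decrease strictly with stress severity", call. = FALSE)
  }
  if (!setequal(names(si_multipliers), as.character(si_doses()))) {
    stop("si_multipliers must be named by the four Si doses", call. = FALSE)
  }
  sm <- si_multipliers
  if (sm[["0"]] != 1 ||
      !(sm[["300"]] > sm[["500"]] && sm[["500"]] > sm[["100"]] &&
        sm[["100"]] > sm[["0"]])) {
    stop("si multipliers must have 0-dose = 1 and rank 300 > 500 > 100 > 0",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 noise_sigma_ln = noise_sigma_ln,
                 base_params = base_params[response_kinds()],
                 water_multipliers = wm,
                 si_multipliers = sm),
            class = "synthetic_config")
}

#' True curve parameters for one treatment cell
#'
#' Returns the generating [model_params()] for a water band x Si dose
#' x response kind combination: the base parameters with `psi` shifted
#' by `log(water_multiplier * si_multiplier)`. Because the shift acts
#' only on the amplitude, peak time and curve shape are shared by all
#' treatments, and every time integral of the cell's curve scales by
#' exactly the product of its multipliers.
#'
#' @param water_band One of [water_bands()].
#' @param si_dose One of [si_doses()].
#' @param config A [synthetic_config()].
#' @param kind `"PN"`, `"GS"` or `"E"`.
#' @return A [model_params()] object.
#' @export
true_params_for <- function(water_band, si_dose, config, kind = "PN") {
  stopifnot(inherits(config, "synthetic_config"))
  if (!water_band %in% water_bands()) {
    stop("unknown water band: ", water_band, call. = FALSE)
  }
  if (!si_dose %in% si_doses()) {
    stop("unknown Si dose: ", si_dose, call. = FALSE)
  }
  if (!kind %in% response_kinds()) {
    stop("unknown response kind: ", kind, call. = FALSE)
  }
  base <- config$base_params[[kind]]
  mult <- config$water_multipliers[[water_band]] *
    config$si_multipliers[[as.character(si_dose)]]
  model_params(base$omega, base$eta, base$psi + log(mult))
}

#' Simulate a factorial diurnal gas-exchange experiment
#'
#' Draws one noisy measurement for every treatment cell x replicate x
#' sample time x response kind. Each value is the cell's true curve
#' evaluated at the sample time, multiplied by lognormal measurement
#' noise `exp(e)`, `e ~ N(0, noise_sigma_ln^2)` -- gas-exchange errors
#' scale with the signal, and multiplicative noise keeps every value
#' positive for the log-scale fit. Output is deterministic given the
#' config seed.
#'
#' @param design A [treatment_design()].
#' @param config A [synthetic_config()].
#' @return A long-format measurement data frame with columns
#'   `water_band`, `si_dose_mg_per_L`, `replicate`, `time_h`,
#'   `response_kind`, `value`, `units`.
#' @examples
#' tab <- generate_gas_exchange(
#'   treatment_design(water_band = "100-95", si_dose = 0),
#'   synthetic_config(seed = 42))
#' head(tab)
#' @export
generate_gas_exchange <- function(design = treatment_design(),
                                  config = synthetic_config()) {
  stopifnot(inherits(design, "treatment_design"),
            inherits(config, "synthetic_config"))
  grid <- expand.grid(
    time_h = design$sample_times,
    replicate = seq_len(design$replicates),
    response_kind = response_kinds(),
    si_dose_mg_per_L = design$si_dose,
    water_band = design$water_band,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  mu <- numeric(nrow(grid))
  for (band in design$water_band) {
    for (dose in design$si_dose) {
      for (kind in response_kinds()) {
        sel <- grid$water_band == band &
          grid$si_dose_mg_per_L == dose &
          grid$response_kind == kind
        tp <- true_params_for(band, dose, config, kind)
        mu[sel] <- evaluate_response(tp, grid$time_h[sel])
      }
    }
  }

  set.seed(config$seed)
  eps <- stats::rnorm(nrow(grid), mean = 0, sd = config$noise_sigma_ln)
  out <- data.frame(
    water_band = grid$water_band,
    si_dose_mg_per_L = grid$si_dose_mg_per_L,
    replicate = grid$replicate,
    time_h = grid$time_h,
    response_kind = grid$response_kind,
    value = mu * exp(eps),
    units = unname(response_units(grid$response_kind)),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$water_band, water_bands()), out$si_dose_mg_per_L,
                   match(out$response_kind, response_kinds()), out$replicate,
                   out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}
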