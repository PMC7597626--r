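# Diurnal microclimate profiles for the synthetic experiment.
#
# The shapes are smooth piecewise half-cosine curves pinned to the
# measurement-day anchors: PPFD zero at 05:00 and 19:00 with a
# 11:00-15:00 plateau; RH 88% at 06:00 declining to a 15:00 minimum and
# recovering to 36% by 17:00; air temperature peaking 13:00-15:00 with
# a sunset value above the sunrise value; ambient CO2 highest in the
# early morning, lowest over midday, rising again after 15:00. Only
# the RH and PPFD anchors are pinned to reported values; the PPFD, Ta
# and Ca magnitudes are realistic defaults for a subtropical cloudless
# day and are configurable.

ppfd_profile <- function(t, ppfd_max = 1800, sunrise = 5,
                         plateau = c(11, 15), sunset = 19) {
  rise <- ppfd_max * (1 - cos(pi * (t - sunrise) / (plateau[1] - sunrise))) / 2
  fall <- ppfd_max * (1 - cos(pi * (sunset - t) / (sunset - plateau[2]))) / 2
  out <- ifelse(t <= sunrise | t >= sunset, 0,
                ifelse(t < plateau[1], rise,
                       ifelse(t <= plateau[2], ppfd_max, fall)))
  pmax(out, 0)
}

rh_profile <- function(t, rh_morning = 88, rh_min = 32, rh_evening = 36,
                       t_morning = 6, t_min = 15, t_evening = 17) {
  decline <- rh_min + (rh_morning - rh_min) *
    (1 + cos(pi * (t - t_morning) / (t_min - t_morning))) / 2
  # half-cosine recovery reaches rh_evening exactly at t_evening,
  # then drifts up gently toward the next morning
  recover <- rh_min + (rh_evening - rh_min) *
    (1 - cos(pi * pmin(t - t_min, t_evening - t_min) /
               (t_evening - t_min))) / 2
  late <- recover + 1.5 * pmax(t - t_evening, 0)
  out <- ifelse(t <= t_morning, rh_morning,
                ifelse(t <= t_min, decline, late))
  pmin(pmax(out, 0), 100)
}

ta_profile <- function(t, ta_min = 24, ta_max = 36, ta_sunset = 30,
                       sunrise = 5, t_peak = 14, sunset = 19) {
  rise <- ta_min + (ta_max - ta_min) *
    (1 - cos(pi * (t - sunrise) / (t_peak - sunrise))) / 2
  fall <- ta_max - (ta_max - ta_sunset) *
    (1 - cos(pi * pmin(t - t_peak, sunset - t_peak) /
               (sunset - t_peak))) / 2
  ifelse(t <= sunrise, ta_min, ifelse(t <= t_peak, rise, fall))
}

ca_profile <- function(t, ca_max = 420, ca_min = 380, ca_evening = 405,
                       t_drop = 6, t_low = c(12, 15), t_recover = 19) {
  drop <- ca_min + (ca_max - ca_min) *
    (1 + cos(pi * (t - t_drop) / (t_low[1] - t_drop))) / 2
  rise <- ca_min + (ca_evening - ca_min) *
    (1 - cos(pi * pmin(t - t_low[2], t_recover - t_low[2]) /
               (t_recover - t_low[2]))) / 2
  ifelse(t <= t_drop, ca_max,
         ifelse(t < t_low[1], drop,
                ifelse(t <= t_low[2], ca_min, rise)))
}

#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Saturation vapor pressure by the Tetens approximation,
#' \eqn{e_s = 0.6108 \exp(17.27\,T_a / (T_a + 237.3))} kPa, multiplied
#' by the saturation shortfall `1 - rh/100`. Zero at 100% humidity and
#' strictly increasing in temperature at fixed humidity below
#' saturation.
#'
#' @param ta Air temperature, degrees C.
#' @param rh Relative humidity, percent, in \[0, 100\].
#' @return VPD in kPa.
#' @export
vpd_from <- function(ta, rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    stop("rh must lie in [0, 100] percent", call. = FALSE)
  }
  es <- 0.6108 * exp(17.27 * ta / (ta + 237.3))
  es * (1 - rh / 100)
}

#' Generate a diurnal microclimate profile
#'
#' Builds the measurement-day climate series that accompanies a
#' synthetic gas-exchange experiment: photosynthetic photon flux
#' density (PPFD), air temperature (Ta), relative humidity (RH),
#' ambient CO2 (Ca) and vapor pressure deficit (VPD, derived from Ta
#' and RH via [vpd_from()]). The profiles are deterministic smooth
#' curves; see the package vignette for the anchor points they honour.
#'
#' @param times Numeric vector of clock hours (default every half hour
#'   from 05:00 to 19:00).
#' @param ppfd_max Midday PPFD plateau, umol m-2 s-1.
#' @param ta_range `c(min, max, sunset)` air temperatures, degrees C.
#' @param ca_range `c(max, min, evening)` ambient CO2, umol mol-1.
#' @param rh_min Minimum relative humidity (at 15:00), percent.
#' @return Data frame with columns `time_h`, `ppfd`, `ta`, `rh`, `ca`,
#'   `vpd`.
#' @examples
#' cl <- generate_climate(times = c(5, 6, 12, 17))
#' cl$rh[cl$time_h == 6]  # 88
#' cl$rh[cl$time_h == 17] # 36
#' @export
generate_climate <- function(times = seq(5, 19, by = 0.5),
                             ppfd_max = 1800,
                             ta_range = c(24, 36, 30),
                             ca_range = c(420, 380, 405),
                             rh_min = 32) {
  if (any(!is.finite(times)) || any(times < 0) || any(times > 24)) {
    stop("times must be clock hours in [0, 24]", call. = FALSE)
  }
  ta <- ta_profile(times, ta_min = ta_range[1], ta_max = ta_range[2],
                   ta_sunset = ta_range[3])
  rh <- rh_profile(times, rh_min = rh_min)
  data.frame(
    time_h = times,
    ppfd = ppfd_profile(times, ppfd_max = ppfd_max),
    ta = ta,
    rh = rh,
    ca = ca_profile(times, ca_max = ca_range[1], ca_min = ca_range[2],
                    ca_evening = ca_range[3]),
    vpd = vpd_from(ta, rh)
  )
}
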