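# Synthetic factorial experiment and its microclimate.

test_that("climate profiles honour the measurement-day anchors", {
  cl <- generate_climate(times = c(5, 6, 15, 17, 19))
  expect_equal(cl$rh[cl$time_h == 6], 88)
  expect_equal(cl$rh[cl$time_h == 17], 36)
  expect_equal(cl$ppfd[cl$time_h == 5], 0)
  expect_equal(cl$ppfd[cl$time_h == 19], 0)
})

test_that("climate curves have the right diurnal shapes", {
  cl <- generate_climate(times = seq(5, 19, by = 0.25))
  expect_true(all(cl$ppfd >= 0))
  expect_true(all(cl$rh >= 0 & cl$rh <= 100))
  expect_true(all(cl$vpd >= 0))
  # RH falls from morning to its 15:00 minimum, then recovers to 17:00
  rh_fall <- cl$rh[cl$time_h >= 6 & cl$time_h <= 15]
  rh_rise <- cl$rh[cl$time_h >= 15 & cl$time_h <= 17]
  expect_true(all(diff(rh_fall) <= 0))
  expect_true(all(diff(rh_rise) >= 0))
  expect_equal(cl$time_h[which.min(cl$rh)], 15)
  # PPFD plateau spans late morning to mid-afternoon
  expect_equal(max(cl$ppfd), cl$ppfd[cl$time_h == 13])
  expect_equal(cl$ppfd[cl$time_h == 11], cl$ppfd[cl$time_h == 15])
  # temperature peaks mid-afternoon; sunset warmer than sunrise
  expect_true(cl$time_h[which.max(cl$ta)] %in% seq(13, 15, 0.25))
  expect_gt(cl$ta[cl$time_h == 19], cl$ta[cl$time_h == 5])
  # CO2 highest in the early morning, lowest midday, rising after 15:00
  expect_equal(which.max(cl$ca), 1L)
  expect_true(cl$time_h[which.min(cl$ca)] >= 12 &&
                cl$time_h[which.min(cl$ca)] <= 15)
  ca_late <- cl$ca[cl$time_h >= 15]
  expect_true(all(diff(ca_late) >= 0))
})

test_that("vpd_from implements the Tetens saturation deficit", {
  expect_equal(vpd_from(31.7, 100), 0)
  expect_equal(vpd_from(25, 50),
               0.5 * 0.6108 * exp(17.27 * 25 / (25 + 237.3)))
  # strictly increasing in temperature below saturation
  ta <- seq(10, 40, by = 1)
  expect_true(all(diff(vpd_from(ta, 60)) > 0))
  expect_error(vpd_from(25, 101), "\\[0, 100\\]")
  expect_error(vpd_from(25, -5), "\\[0, 100\\]")
})

test_that("config validation enforces the treatment-effect orderings", {
  expect_error(synthetic_config(noise_sigma_ln = -0.1), ">= 0")
  expect_error(
    synthetic_config(water_multipliers = c("100-95" = 0.9, "80-75" = 0.79,
                                           "55-50" = 0.60, "35-30" = 0.46)),
    "control band")
  expect_error(
    synthetic_config(water_multipliers = c("100-95" = 1, "80-75" = 0.5,
                                           "55-50" = 0.60, "35-30" = 0.46)),
    "decrease")
  expect_error(
    synthetic_config(si_multipliers = c("0" = 1, "100" = 1.2,
                                        "300" = 1.1, "500" = 1.06)),
    "rank")
  expect_error(treatment_design(water_band = "90-85"), "unknown water band")
  expect_error(treatment_design(replicates = 0), "replicates")
  expect_error(treatment_design(sample_times = c(9, 7)), "increasing")
})

test_that("treatment effects scale amplitude only, preserving the peak", {
  cfg <- synthetic_config()
  base <- cfg$base_params$PN
  ctrl <- true_params_for("100-95", 0, cfg, "PN")
  expect_equal(ctrl, base)
  severe <- true_params_for("35-30", 0, cfg, "PN")
  # integral scales by exactly the water multiplier (0.46)
  expect_equal(daily_total(severe) / daily_total(ctrl), 0.46,
               tolerance = 1e-12)
  for (band in water_bands()) {
    for (dose in si_doses()) {
      expect_equal(peak_time(true_params_for(band, dose, cfg, "PN")),
                   peak_time(base))
    }
  }
  expect_error(true_params_for("100-95", 0, cfg, "WUE"), "kind")
})

test_that("noise-free generation reproduces the model exactly and seeds reproduce", {
  cfg0 <- synthetic_config(seed = 21, noise_sigma_ln = 0)
  des <- treatment_design(water_band = c("100-95", "35-30"), si_dose = c(0, 300))
  tab <- generate_gas_exchange(des, cfg0)
  expect_equal(nrow(tab), 2 * 2 * 5 * 6 * 3)
  i <- which(tab$water_band == "35-30" & tab$si_dose_mg_per_L == 300 &
               tab$response_kind == "GS" & tab$replicate == 4 &
               tab$time_h == 13)
  tp <- true_params_for("35-30", 300, cfg0, "GS")
  expect_equal(tab$value[i], evaluate_response(tp, 13))

  cfg <- synthetic_config(seed = 22, noise_sigma_ln = 0.05)
  expect_identical(generate_gas_exchange(des, cfg),
                   generate_gas_exchange(des, cfg))
})

test_that("lognormal noise has the expected multiplicative mean", {
  cfg <- synthetic_config(seed = 23, noise_sigma_ln = 0.2)
  des <- treatment_design(water_band = "100-95", si_dose = 0,
                          replicates = 10000, sample_times = 9)
  tab <- generate_gas_exchange(des, cfg)
  pn <- tab$value[tab$response_kind == "PN"]
  mu <- evaluate_response(cfg$base_params$PN, 9)
  # E[mu * exp(eps)] = mu * exp(sigma^2 / 2) for lognormal noise
  expect_equal(mean(pn) / (mu * exp(0.2^2 / 2)), 1, tolerance = 0.01)
})

test_that("expected responses preserve the drought and silicon orderings", {
  cfg <- synthetic_config(noise_sigma_ln = 0)
  for (kind in c("PN", "GS", "E")) {
    for (t in measurement_hours) {
      # more stress, lower response (at fixed dose)
      v_band <- vapply(water_bands(), function(b) {
        evaluate_response(true_params_for(b, 0, cfg, kind), t)
      }, numeric(1))
      expect_true(all(diff(v_band) < 0))
      # within a band: Si300 > Si500 > Si100 > Si0
      v_si <- vapply(c(300, 500, 100, 0), function(d) {
        evaluate_response(true_params_for("55-50", d, cfg, kind), t)
      }, numeric(1))
      expect_true(all(diff(v_si) < 0))
    }
  }
})

test_that("the default factorial round-trips through the fit with high r", {
  cfg <- synthetic_config()  # default seed, sigma_ln = 0.05
  fits <- fit_all(generate_gas_exchange(treatment_design(), cfg))
  expect_equal(nrow(fits), 48L)
  expect_true(all(fits$r > 0.9))
})
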