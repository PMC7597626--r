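# Log-linear estimator, goodness-of-fit statistics, per-cell fitting.

test_that("noiseless model data is recovered to machine precision", {
  s <- noiseless_series(model_params(-2, 18, 3))
  fit <- fit_diurnal(s$t, s$value)
  expect_equal(fit$params$omega, -2, tolerance = 1e-12)
  expect_equal(fit$params$eta, 18, tolerance = 1e-12)
  expect_equal(fit$params$psi, 3, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$S, 0, tolerance = 1e-10)
  expect_equal(fit$n, 6L)
  expect_equal(fit$window, c(7, 17))
})

test_that("estimator equals the direct normal-equation solution", {
  set.seed(404)
  for (i in 1:10) {
    p <- random_unimodal_params()
    s <- noisy_series(p, sigma = 0.1)
    fit <- fit_diurnal(s$t, s$value)
    oracle <- normal_equation_fit(s$t, s$value)
    expect_equal(fit$params$psi, unname(oracle["psi"]), tolerance = 1e-10)
    expect_equal(fit$params$omega, unname(oracle["omega"]), tolerance = 1e-10)
    expect_equal(fit$params$eta, unname(oracle["eta"]), tolerance = 1e-10)
  }
})

test_that("goodness_r follows the product-moment definition", {
  expect_equal(goodness_r(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(goodness_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # definitional covariance / (sd * sd) oracle, spelled out
  x <- c(1, 2, 4); y <- c(1, 2, 3)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(goodness_r(x, y), oracle)
  expect_error(goodness_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(goodness_r(1, 1), "length")
})

test_that("goodness_S is the residual standard error with df = n - k", {
  expect_equal(goodness_S(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  # SSE = 4 on 1 residual degree of freedom -> S = 2, by hand
  expect_equal(goodness_S(c(1, 2, 3, 4), c(1, 2, 3, 2), k = 3), 2)
  expect_error(goodness_S(c(1, 2, 3), c(1, 2, 3), k = 3),
               "degrees of freedom")
})

test_that("nonpositive observations are excluded with a warning, not shifted", {
  p <- model_params(-2, 18, 3)
  s <- noiseless_series(p)
  v <- s$value
  v[2] <- -v[2]
  expect_warning(fit <- fit_diurnal(s$t, v), "excluding 1 nonpositive")
  expect_equal(fit$n, 5L)
  # remaining points still lie exactly on the curve
  expect_equal(fit$params$omega, -2, tolerance = 1e-10)
  # too few survivors is an error, not a silent fit
  expect_warning(
    expect_error(fit_diurnal(s$t, -abs(v)), "insufficient data"),
    "nonpositive")
})

test_that("degenerate designs are rejected", {
  expect_error(fit_diurnal(c(7, 9), c(1, 2)), "insufficient data")
  expect_error(fit_diurnal(c(9, 9, 9, 9), c(1, 2, 3, 4)),
               "distinct measurement times")
})

test_that("pooled identical replicates fit identically to one replicate", {
  p <- model_params(-3, 24, 2)
  s <- noiseless_series(p)
  single <- fit_diurnal(s$t, s$value)
  pooled <- fit_diurnal(rep(s$t, 3), rep(s$value, 3))
  expect_equal(pooled$params$omega, single$params$omega, tolerance = 1e-12)
  expect_equal(pooled$params$eta, single$params$eta, tolerance = 1e-12)
  expect_equal(pooled$params$psi, single$params$psi, tolerance = 1e-12)
})

test_that("Gauss-Newton refinement does not worsen the original-scale SSE", {
  set.seed(505)
  p <- model_params(-6, 54, 5)
  s <- noisy_series(p, sigma = 0.15, replicates = 3)
  ols <- fit_diurnal(s$t, s$value)
  ref <- fit_diurnal(s$t, s$value, refine = TRUE)
  sse <- function(f) {
    sum((s$value - evaluate_response(f$params, s$t))^2)
  }
  expect_true(ref$refined)
  expect_lte(sse(ref), sse(ols) * (1 + 1e-8))
})

test_that("fit_all recovers every cell of a noiseless factorial exactly", {
  cfg <- synthetic_config(seed = 11, noise_sigma_ln = 0)
  tab <- generate_gas_exchange(treatment_design(), cfg)
  fits <- fit_all(tab)
  expect_equal(nrow(fits), 4 * 4 * 3)
  expect_true(all(is.na(fits$note)))
  for (i in seq_len(nrow(fits))) {
    tp <- true_params_for(fits$water_band[i], fits$si_dose_mg_per_L[i],
                          cfg, fits$response_kind[i])
    expect_equal(fits$omega[i], tp$omega, tolerance = 1e-8)
    expect_equal(fits$eta[i], tp$eta, tolerance = 1e-8)
    expect_equal(fits$psi[i], tp$psi, tolerance = 1e-8)
  }
  expect_true(all(abs(fits$r - 1) < 1e-10))
})

test_that("fit_all flags a corrupt cell with a reason and fits the rest", {
  cfg <- synthetic_config(seed = 12, noise_sigma_ln = 0)
  tab <- generate_gas_exchange(treatment_design(), cfg)
  bad <- tab$water_band == "55-50" & tab$si_dose_mg_per_L == 100 &
    tab$response_kind == "E"
  tab$value[bad] <- -abs(tab$value[bad])
  fits <- fit_all(tab)
  flagged <- fits[fits$water_band == "55-50" & fits$si_dose_mg_per_L == 100 &
                    fits$response_kind == "E", ]
  expect_equal(nrow(flagged), 1L)
  expect_true(is.na(flagged$omega))
  expect_match(flagged$note, "insufficient data")
  expect_equal(sum(!is.na(fits$omega)), 47L)
})

test_that("fitting per-time replicate means matches pooling on noiseless data", {
  cfg <- synthetic_config(seed = 13, noise_sigma_ln = 0)
  tab <- generate_gas_exchange(
    treatment_design(water_band = "100-95", si_dose = 0), cfg)
  pool <- fit_all(tab, kinds = "PN")
  means <- fit_all(tab, kinds = "PN", aggregate = "means")
  expect_equal(means$omega, pool$omega, tolerance = 1e-10)
  expect_equal(means$n, 6L)
})
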