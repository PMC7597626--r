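# Shared test helpers: random unimodal parameter draws and noiseless
# series generated directly from the closed-form curve.

random_unimodal_params <- function() {
  omega <- stats::runif(1, -6, -0.5)
  peak <- stats::runif(1, 6, 14)          # interior peak within the day
  model_params(omega = omega, eta = -omega * peak,
               psi = stats::runif(1, -1, 5))
}

measurement_hours <- c(7, 9, 11, 13, 15, 17)

noiseless_series <- function(params, t = measurement_hours) {
  list(t = t, value = evaluate_response(params, t))
}

noisy_series <- function(params, sigma, replicates = 1,
                         t = measurement_hours) {
  tt <- rep(t, times = replicates)
  mu <- evaluate_response(params, tt)
  list(t = tt, value = mu * exp(stats::rnorm(length(tt), 0, sigma)))
}

# direct solution of the 3x3 normal equations for the log-linear fit;
# independent of the lm-based path in fit_diurnal
normal_equation_fit <- function(t, value) {
  X <- cbind(1, log(t), -1 / t)
  beta <- solve(crossprod(X), crossprod(X, log(value)))
  c(psi = beta[1], omega = beta[2], eta = beta[3])
}
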