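# Independent straight-line oracles kept deliberately separate from the
# package implementation: each re-derives its quantity in one pass of
# plain arithmetic so it can arbitrate the package's answers.

# CO2 mass-balance chain written as bare formulas (concentrations in
# g m^-3). Returns all intermediate quantities.
oracle_mass_balance <- function(m, p, y, n_cows, t_in,
                                co2_in, co2_out, c_in, c_out) {
  qt <- 5.6 * m^0.75 + 1.6e-5 * p^3 + 22 * y
  cf <- 4e-5 * (20 - t_in)^3 + 1
  qcor <- qt * cf
  p_co2 <- 0.299 * qcor
  q <- p_co2 * n_cows / (co2_in - co2_out)
  et <- q * (c_in - c_out)
  e <- et * 500 / (n_cows * m)
  list(qt = qt, cf = cf, qcor = qcor, p_co2 = p_co2, q = q, et = et, e = e)
}

# Textbook regression metrics.
oracle_metrics <- function(targets, predictions) {
  r <- targets - predictions
  n <- length(r)
  list(
    R = stats::cor(targets, predictions),
    R2 = stats::cor(targets, predictions)^2,
    MSE = sum(r^2) / n,
    RMSE = sqrt(sum(r^2) / n),
    MAE = sum(abs(r)) / n,
    SD = sqrt(sum((r - mean(r))^2) / n)
  )
}

# Central finite-difference Jacobian of the network output w.r.t. all
# parameters; reference for the analytic backpropagated Jacobian.
oracle_numeric_jacobian <- function(model, x, h = 1e-6) {
  w <- barngas:::mlp_flatten(model)
  out <- matrix(NA_real_, nrow(x), length(w))
  for (k in seq_along(w)) {
    wp <- w; wp[k] <- wp[k] + h
    wm <- w; wm[k] <- wm[k] - h
    out[, k] <- (mlp_forward(barngas:::mlp_unflatten(model, wp), x) -
                   mlp_forward(barngas:::mlp_unflatten(model, wm), x)) / (2 * h)
  }
  out
}

# Small noiseless study shared by several tests.
noiseless_study <- function(n_records = 48, seed = 7) {
  gen_study(generator_config(n_records = n_records, seed = seed,
                             snr = Inf, noise_amplitude = 1))
}

herd_of <- function(study) {
  cfg <- study$config
  herd_state(cfg$n_cows, cfg$mean_mass, cfg$days_insemination, cfg$milk_yield)
}
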