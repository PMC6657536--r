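# Independent oracles used across tests.

# Dense normal-equations ridge solution on the raw truncated power basis:
# (C'C + lambda D)^{-1} C'y with D penalizing only the truncated block.
ridge_oracle <- function(times, y, spec, lambda) {
  B <- truncated_basis(times, spec, 0)
  C <- cbind(B$X, B$Z)
  D <- diag(c(rep(0, spec$degree + 1L), rep(1, length(spec$knots))))
  drop(solve(crossprod(C) + lambda * D, crossprod(C, y)))
}

# Central finite difference of a curve prediction.
fd_deriv <- function(fit, grid, h = 1e-4, order = 1) {
  f <- function(g, m) suppressWarnings(predict_curve(fit, g, m)$estimate)
  if (order == 1) (f(grid + h, 0) - f(grid - h, 0)) / (2 * h)
  else (f(grid + h, 1) - f(grid - h, 1)) / (2 * h)
}

# Standard noisy saturating-trace fixture.
saturating_fit <- function(A = 80, k = 1.5, noise_sd = 0.5, n_points = 400,
                           seed = 42, ...) {
  tr <- simulate_curve(curve_params("saturating", A = A, k = k,
                                    noise_sd = noise_sd,
                                    n_points = n_points), seed = seed)
  fit_penalized_spline(tr, ...)
}

# Two-group five-dose design with saturating base curves.
nano_fixture <- function(np_amplitude, noise_sd = 1, n_points = 200,
                         seed = 1) {
  des <- dose_design(c(0.2, 0.4, 0.8, 1.2, 1.36),
                     np_amplitude = np_amplitude, np_rate = 2,
                     replicates = 1)
  amps <- c(20, 35, 50, 65, 80)
  pars <- setNames(lapply(seq_along(amps), function(i)
    curve_params("saturating", A = amps[i], k = 0.6 + 0.35 * i,
                 noise_sd = noise_sd, n_points = n_points)),
    as.character(des$doses))
  list(design = des, params = pars,
       data = simulate_dataset(des, pars, seed = seed))
}
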