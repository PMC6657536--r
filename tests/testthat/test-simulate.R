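# Synthetic aggregometry generator: curve families, noise model, dose designs.

test_that("identical seeds reproduce traces bit for bit; noiseless output is
           seed-independent", {
  p <- curve_params("staircase", noise_sd = 2, n_points = 120)
  expect_identical(simulate_curve(p, seed = 7), simulate_curve(p, seed = 7))
  expect_false(identical(simulate_curve(p, seed = 7),
                         simulate_curve(p, seed = 8)))
  p0 <- curve_params("rise_decay", noise_sd = 0, n_points = 50)
  expect_identical(simulate_curve(p0, seed = 1), simulate_curve(p0, seed = 99))
})

test_that("simulating does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_curve(curve_params("saturating"), seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("saturating family approaches its amplitude asymptote", {
  p <- curve_params("saturating", A = 80, k = 1.5, noise_sd = 0,
                    duration = 30, n_points = 500)
  tr <- simulate_curve(p)
  expect_equal(tail(tr$aggregation, 1), 80, tolerance = 1e-8)
  # strictly increasing until the exponential term underflows
  expect_true(all(diff(head(tr$aggregation, 250)) > 0))
  expect_true(all(diff(tr$aggregation) >= 0))
})

test_that("rise_decay peaks at the closed-form biexponential argmax", {
  # t* = log(lambda1/lambda2) / (lambda1 - lambda2), checked by grid search
  p <- curve_params("rise_decay", A = 30, lambda1 = 3, lambda2 = 0.4,
                    noise_sd = 0, n_points = 70001)
  tr <- simulate_curve(p)
  tstar <- log(3 / 0.4) / (3 - 0.4)
  expect_equal(tr$time[which.max(tr$aggregation)], tstar, tolerance = 1e-3)
  expect_equal(max(tr$aggregation), 30, tolerance = 1e-6)
  expect_lt(tail(tr$aggregation, 1), 30)  # rises then falls
})

test_that("invalid families and parameters are rejected by name", {
  expect_error(curve_params("sigmoidal"), "unknown curve family: 'sigmoidal'")
  expect_error(curve_params("saturating", noise_sd = -1), "noise_sd")
  expect_error(curve_params("rise_decay", lambda1 = 0.3, lambda2 = 0.4),
               "lambda1")
  expect_error(curve_params("staircase", transitions = c(1, 9)),
               "transition")
  expect_error(curve_params("saturating", A = 120), "'A'")
})

test_that("empirical noise sd matches the configured level", {
  p <- curve_params("saturating", noise_sd = 2, duration = 7,
                    n_points = 20000)
  tr <- simulate_curve(p, seed = 11)
  noiseless <- simulate_curve(curve_params("saturating", noise_sd = 0,
                                           duration = 7, n_points = 20000))
  resid <- tr$aggregation - noiseless$aggregation
  expect_lt(abs(sd(resid) - 2) / 2, 0.05)
  expect_lt(abs(mean(resid)), 0.1)
})

test_that("AR(1) noise keeps its stationary sd and autocorrelation", {
  p <- curve_params("saturating", noise_sd = 2, ar_rho = 0.6,
                    n_points = 20000)
  resid <- simulate_curve(p, seed = 3)$aggregation -
    simulate_curve(curve_params("saturating", noise_sd = 0,
                                n_points = 20000))$aggregation
  expect_lt(abs(sd(resid) - 2) / 2, 0.05)
  expect_lt(abs(cor(resid[-1], resid[-20000]) - 0.6), 0.05)
})

test_that("dataset layout: one trace per (dose, group, replicate)", {
  doses <- c(0.2, 0.4, 0.6, 0.8, 1.2, 1.32, 1.36)
  des <- dose_design(doses, groups = "agonist_only", replicates = 1)
  pars <- setNames(lapply(seq_along(doses), function(i)
    curve_params("saturating", A = 10 * i, noise_sd = 0, n_points = 100)),
    as.character(doses))
  dat <- simulate_dataset(des, pars, seed = 1)
  expect_equal(nrow(dat), 700)
  expect_identical(names(dat), c("subject_id", "dose", "group", "time_min",
                                 "aggregation_pct"))
  # strictly increasing noiseless final values under monotone amplitudes
  finals <- vapply(split(dat, dat$dose),
                   function(d) tail(d$aggregation_pct, 1), numeric(1))
  expect_true(all(diff(finals[order(as.numeric(names(finals)))]) > 0))
})

test_that("zero nanoparticle offset makes both groups identical before
           noise", {
  des <- dose_design(c(0.4, 1.2), np_amplitude = 0, replicates = 1)
  pars <- setNames(lapply(c(30, 70), function(a)
    curve_params("saturating", A = a, noise_sd = 0, n_points = 50)),
    c("0.4", "1.2"))
  dat <- simulate_dataset(des, pars)
  ag <- dat[dat$group == "agonist_only", ]
  np <- dat[dat$group == "agonist_plus_np", ]
  expect_equal(ag$aggregation_pct, np$aggregation_pct)
})

test_that("the nanoparticle offset is additive on the noiseless signal", {
  des <- dose_design(c(0.4), np_amplitude = 15, np_rate = 2, replicates = 1)
  pars <- list(`0.4` = curve_params("saturating", A = 40, noise_sd = 0,
                                    n_points = 80))
  dat <- simulate_dataset(des, pars)
  ag <- dat[dat$group == "agonist_only", ]
  np <- dat[dat$group == "agonist_plus_np", ]
  expect_equal(np$aggregation_pct - ag$aggregation_pct,
               15 * (1 - exp(-2 * ag$time_min)))
})

test_that("missing dose parameters are rejected naming the dose", {
  des <- dose_design(c(0.4, 1.2))
  pars <- list(`0.4` = curve_params("saturating"))
  expect_error(simulate_dataset(des, pars), "1.2")
})

test_that("dose designs validate their invariants", {
  expect_error(dose_design(c(1, 1)), "strictly increasing")
  expect_error(dose_design(1, groups = "placebo"), "placebo")
  expect_error(dose_design(1, np_amplitude = -3), "np_amplitude")
  expect_error(dose_design(1, replicates = 0), "replicates")
})

test_that("phase-law traces follow the exact linear-ODE solution", {
  tr <- simulate_from_phase_law(120, -1.5, y0 = 0, n_points = 200)
  expect_equal(tr$aggregation, 80 * (1 - exp(-1.5 * tr$time)),
               tolerance = 1e-12)
  # fixed point -gamma0/gamma1 reached in the long run
  long <- simulate_from_phase_law(120, -1.5, duration = 40, n_points = 100)
  expect_equal(tail(long$aggregation, 1), 80, tolerance = 1e-8)
  expect_error(simulate_from_phase_law(120, 0), "gamma1")
})

test_that("closed-form phase-law solution matches brute-force integration", {
  skip_if_not_installed("deSolve")
  sol <- deSolve::ode(c(y = 5), seq(0, 7, length.out = 201),
                      function(t, y, p) list(120 - 1.5 * y[1]), NULL,
                      method = "ode45", atol = 1e-10, rtol = 1e-10)
  tr <- simulate_from_phase_law(120, -1.5, y0 = 5, n_points = 201)
  expect_lt(max(abs(sol[, "y"] - tr$aggregation)), 1e-6)
})
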