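# Truncated power basis, penalized LMM fitting, BLUP prediction and bands.

test_that("truncated basis entries follow the power rule at all orders", {
  s1 <- spline_spec(1, knots = 0.5)
  tb <- function(...) suppressWarnings(truncated_basis(...))
  expect_equal(unname(tb(0.75, s1, 0)$Z[1, 1]), 0.25)
  s5 <- spline_spec(5, knots = 0)
  expect_equal(unname(tb(2, s5, 1)$Z[1, 1]), 5 * 2^4)   # 80
  expect_equal(unname(tb(2, s5, 2)$Z[1, 1]), 20 * 2^3)  # 160
  # value 0 at and below the knot (continuous limit at t = kappa)
  expect_equal(unname(tb(c(-1, 0), s5, 0)$Z[, 1]), c(0, 0))
  # polynomial block holds exact derivatives of t^j
  B <- tb(c(1.5), spline_spec(3, knots = 0.1), 2)
  expect_equal(B$X[1, ], c(0, 0, 2, 6 * 1.5), ignore_attr = TRUE)
})

test_that("basis rejects unsupported derivative orders and warns on outside
           knots", {
  sp <- spline_spec(5, knots = 0.5)
  expect_error(truncated_basis(1, sp, 3), "deriv_order")
  expect_error(truncated_basis(1, spline_spec(1, 0.5), 1), "deriv_order")
  expect_warning(truncated_basis(seq(0, 1, 0.1), spline_spec(5, 2)),
                 "outside")
})

test_that("knot rules: auto count, interior quantiles, monotonicity", {
  sp <- default_knots(seq(0, 7, length.out = 400))
  expect_length(sp$knots, 35)  # min(100, 35)
  sp12 <- default_knots(1:12)
  expect_equal(sp12$knots, unname(quantile(1:12, c(0.25, 0.5, 0.75))))
  expect_error(spline_spec(5, knots = c(2, 1)), "strictly increasing")
  expect_error(default_knots(1:4, K = 10), "distinct times")
})

test_that("a noiseless linear signal is reproduced and its random
           coefficients shrink to zero", {
  tt <- seq(0, 7, length.out = 100)
  fit <- fit_penalized_spline(tt, 2 + 3 * tt, knots = 5)
  expect_lt(max(abs(fit$fitted - (2 + 3 * tt))), 1e-8)
  expect_lt(max(abs(fit$u)), 1e-6)
})

test_that("BLUP at fixed lambda equals the dense generalized-ridge oracle", {
  set.seed(101)
  for (p in c(2L, 3L, 5L)) {
    n <- 50L
    tt <- sort(runif(n, 0, 1.5))
    y <- 20 * sin(3 * tt) + rnorm(n)
    sp <- default_knots(tt, K = 3, degree = p)
    for (lam in c(1e-3, 0.5, 10)) {
      fit <- fit_penalized_spline(tt, y, spec = sp, lambda = lam)
      oracle <- ridge_oracle(tt, y, sp, lam)
      expect_lt(max(abs(c(fit$beta, fit$u) - oracle)) / max(abs(oracle)),
                1e-8)
      # fitted values equal the design applied to the coefficients exactly
      B <- truncated_basis(tt, sp, 0)
      expect_equal(fit$fitted,
                   drop(cbind(B$X, B$Z) %*% c(fit$beta, fit$u)),
                   tolerance = 1e-10)
    }
  }
})

test_that("lambda limits: OLS on the full basis as lambda -> 0 and the
           degree-p polynomial fit as lambda -> Inf", {
  set.seed(7)
  tt <- sort(runif(60, 0, 2))
  y <- 30 * tt * exp(-tt) + rnorm(60, 0, 0.5)
  sp <- default_knots(tt, K = 3, degree = 3)
  B <- truncated_basis(tt, sp, 0)
  f_lo <- fit_penalized_spline(tt, y, spec = sp, lambda = 1e-10)
  ols <- lm.fit(cbind(B$X, B$Z), y)
  expect_lt(max(abs(f_lo$fitted - ols$fitted.values)), 1e-5)
  f_hi <- fit_penalized_spline(tt, y, spec = sp, lambda = 1e10)
  pol <- lm.fit(B$X, y)
  expect_lt(max(abs(f_hi$fitted - pol$fitted.values)), 1e-5)
})

test_that("REML fit agrees with nlme::lme on the same mixed model", {
  skip_if_not_installed("nlme")
  set.seed(21)
  n <- 150L
  tt <- sort(runif(n, 0, 1))
  y <- 50 * (1 - exp(-3 * tt)) + rnorm(n, 0, 1)
  sp <- default_knots(tt, K = 8, degree = 3)
  fit <- fit_penalized_spline(tt, y, spec = sp)
  B <- truncated_basis(tt, sp, 0)
  df <- data.frame(y = y, g = factor(rep(1, n)))
  df$X <- B$X
  df$Z <- B$Z
  lfit <- nlme::lme(y ~ X - 1, random = list(g = nlme::pdIdent(~ Z - 1)),
                    data = df, method = "REML")
  expect_equal(as.numeric(fitted(lfit)), fit$fitted, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(lfit$sigma^2, fit$sigma2_eps, tolerance = 1e-3)
  expect_equal(as.numeric(nlme::VarCorr(lfit)[1, 1]), fit$sigma2_u,
               tolerance = 1e-3)
})

test_that("REML recovers a smooth truth from noisy data (RMSE < 1)", {
  tt <- seq(0, 7, length.out = 400)
  truth <- 40 * sin(2 * pi * tt / 7)
  set.seed(5)
  y <- truth + rnorm(400, 0, 1)
  fit <- fit_penalized_spline(tt, y)
  expect_lt(sqrt(mean((fit$fitted - truth)^2)), 1)
})

test_that("near-polynomial data drives the random-coefficient variance to
           the boundary and the fit stays valid", {
  set.seed(9)
  tt <- seq(0, 7, length.out = 120)
  y <- 5 + 2 * tt + rnorm(120, 0, 1)
  fit <- fit_penalized_spline(tt, y, degree = 2, knots = 4)
  expect_true(fit$boundary || fit$sigma2_u < 1e-6 * fit$sigma2_eps)
  expect_gt(fit$sigma2_eps, 0)
})

test_that("curve, velocity and acceleration are continuous across knots", {
  fit <- saturating_fit(noise_sd = 1, seed = 13)
  eps <- 1e-8
  for (m in 0:2) {
    lo <- predict_curve(fit, fit$spec$knots - eps, m)$estimate
    hi <- predict_curve(fit, fit$spec$knots + eps, m)$estimate
    scale <- max(abs(predict_curve(fit, deriv_order = m)$estimate))
    expect_lt(max(abs(hi - lo)), 1e-6 * scale)
  }
})

test_that("prediction consistency: order 0 at training times equals stored
           fitted values; constant response has zero derivative", {
  fit <- saturating_fit(noise_sd = 0.5, seed = 3)
  pr <- predict_curve(fit, sort(unique(fit$times)), 0)
  expect_equal(pr$estimate, fit$fitted[order(fit$times)], tolerance = 1e-10)
  tt <- seq(0, 7, length.out = 100)
  fc <- fit_penalized_spline(tt, rep(42, 100), knots = 5)
  expect_lt(max(abs(predict_curve(fc, tt, 1)$estimate)), 1e-8)
})

test_that("derivative estimates match central finite differences", {
  fit <- saturating_fit(noise_sd = 0.5, seed = 17)
  g <- seq(0.3, 6.7, length.out = 50)
  v <- predict_curve(fit, g, 1)$estimate
  a <- predict_curve(fit, g, 2)$estimate
  expect_lt(max(abs(v - fd_deriv(fit, g, order = 1))) / max(abs(v)), 1e-4)
  expect_lt(max(abs(a - fd_deriv(fit, g, order = 2))) / max(abs(a)), 1e-4)
})

test_that("bands are symmetric, ordered and widen with the level", {
  fit <- saturating_fit(seed = 29)
  pr95 <- predict_curve(fit, level = 0.95)
  pr99 <- predict_curve(fit, level = 0.99)
  expect_true(all(pr95$lower <= pr95$estimate & pr95$estimate <= pr95$upper))
  expect_true(all(pr95$se > 0))
  expect_true(all(pr99$upper - pr99$lower > pr95$upper - pr95$lower))
  expect_equal(pr95$upper - pr95$estimate, pr95$estimate - pr95$lower)
})

test_that("degenerate inputs are rejected informatively", {
  expect_error(fit_penalized_spline(1:50, c(NA, rnorm(49))), "non-finite")
  expect_error(fit_penalized_spline(1:10, rnorm(10), degree = 5, knots = 4),
               "observations")
  expect_warning(predict_curve(saturating_fit(seed = 1), c(-1, 3)),
                 "extrapolat")
})
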