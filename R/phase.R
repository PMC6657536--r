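# Phase-plane reconstruction: regress the BLUP-predicted velocity on the
# BLUP-predicted aggregation to read off an empirical law dy/dt = F(y),
# either linear (F(y) = gamma0 + gamma1 y) or a smooth penalized-spline law,
# then locate steady states F(y*) = 0 and classify their local stability.

#' Extract phase-plane points from a fitted trace
#'
#' Pairs the order-0 and order-1 predictions of a penalized-spline fit at
#' identical times, giving the (aggregation, velocity) point cloud on which
#' the phase-law regressions operate. Because spline derivative estimates are
#' least reliable at the ends of the time range, a fraction `trim` of the time
#' span is dropped at each end by default.
#'
#' @param fit A [fit_penalized_spline()] object.
#' @param grid Evaluation times; default the sorted unique training times.
#' @param trim Fraction of the time span trimmed from each end (default 0.05).
#' @return Data frame with columns `time`, `aggregation` (fitted level,
#'   percent) and `velocity` (percent/min).
#' @export
phase_points <- function(fit, grid = NULL, trim = 0.05) {
  stopifnot(inherits(fit, "penalized_spline_fit"))
  .assert_number(trim, "trim", lower = 0, upper = 0.49)
  if (is.null(grid)) grid <- sort(unique(fit$times))
  grid <- as.numeric(grid)
  if (!length(grid)) stop("'grid' must be non-empty")
  if (trim > 0) {
    rng <- range(grid)
    span <- diff(rng)
    grid <- grid[grid >= rng[1L] + trim * span & grid <= rng[2L] - trim * span]
    if (!length(grid)) stop("trimming removed every grid point")
  }
  data.frame(time = grid,
             aggregation = predict_curve(fit, grid, 0)$estimate,
             velocity = predict_curve(fit, grid, 1)$estimate)
}

#' Fit the linear phase law dy/dt = gamma0 + gamma1 y
#'
#' Ordinary least squares of predicted velocity on predicted aggregation.
#' Reported standard errors are naive: they ignore both that the points are
#' themselves estimates and their serial correlation along the trace. The
#' adjusted R-squared uses the one-predictor formula
#' \eqn{1 - (1 - R^2)(n - 1)/(n - 2)}; the raw value can be negative for a
#' non-informative fit, so a zero-clipped copy is reported alongside it, the
#' convention used when tabulating fits across dose levels.
#'
#' @param points Data frame from [phase_points()] (columns `aggregation`,
#'   `velocity`).
#' @return Object of class `phase_linear_fit` with `gamma0`, `gamma1`, their
#'   standard errors, residual variance `tau2`, `adj_r2_raw`, `adj_r2`
#'   (clipped at 0) and `n`.
#' @export
fit_linear_phase <- function(points) {
  if (!all(c("aggregation", "velocity") %in% names(points)))
    stop("'points' must have columns 'aggregation' and 'velocity'")
  yhat <- as.numeric(points$aggregation)
  v <- as.numeric(points$velocity)
  n <- length(yhat)
  if (n < 3L) stop("need at least 3 phase points")
  if (var(yhat) == 0)
    stop("predicted aggregation is constant; the phase law is unidentifiable")
  m <- lm(v ~ yhat)
  sm <- summary(m)
  r2 <- sm$r.squared
  adj_raw <- 1 - (1 - r2) * (n - 1) / (n - 2)
  structure(list(gamma0 = unname(coef(m)[1L]),
                 gamma1 = unname(coef(m)[2L]),
                 se_gamma0 = sm$coefficients[1L, 2L],
                 se_gamma1 = sm$coefficients[2L, 2L],
                 tau2 = sm$sigma^2,
                 r2 = r2, adj_r2_raw = adj_raw, adj_r2 = max(0, adj_raw),
                 n = n, model = m,
                 range = range(yhat)),
            class = "phase_linear_fit")
}

#' @export
print.phase_linear_fit <- function(x, ...) {
  cat("Linear phase law dy/dt = gamma0 + gamma1 * y\n")
  cat(sprintf("  gamma0 = %.4g (SE %.3g), gamma1 = %.4g (SE %.3g)\n",
              x$gamma0, x$se_gamma0, x$gamma1, x$se_gamma1))
  cat(sprintf("  adj. R^2 = %.3f (raw %.3f), tau^2 = %.4g, n = %d\n",
              x$adj_r2, x$adj_r2_raw, x$tau2, x$n))
  if (x$gamma1 < 0)
    cat(sprintf("  stable steady state at y* = %.4g\n", -x$gamma0 / x$gamma1))
  invisible(x)
}

#' Fit a smooth phase law dy/dt = gamma0 + g(y)
#'
#' Drops the linearity assumption: the velocity is regressed on the predicted
#' aggregation with a penalized truncated-power spline over the aggregation
#' axis (the same LMM/BLUP machinery as the time-domain smoother), so the law
#' \eqn{F(y) = \gamma_0 + g(y)} is estimated without a presumed shape. Knots
#' default to quantiles of the observed aggregation values with
#' `K = min(floor(n/4), 20)`, degree 5 for consistency with the curve model.
#'
#' @param points Data frame from [phase_points()].
#' @param spec Optional [spline_spec()] over the aggregation axis.
#' @param degree Basis degree for the default spec.
#' @param tolerance Steady-state residual tolerance passed to
#'   [find_steady_states()].
#' @return Object of class `phase_smooth_fit`: the underlying
#'   `penalized_spline_fit` (`$fit`), `gamma0` (the basis intercept),
#'   observed aggregation `range`, and `steady_states` (data frame from
#'   [find_steady_states()]).
#' @export
fit_smooth_phase <- function(points, spec = NULL, degree = 5,
                             tolerance = 1e-6) {
  if (!all(c("aggregation", "velocity") %in% names(points)))
    stop("'points' must have columns 'aggregation' and 'velocity'")
  yhat <- as.numeric(points$aggregation)
  v <- as.numeric(points$velocity)
  n <- length(yhat)
  if (is.null(spec)) {
    K <- min(n %/% 4L, 20L)
    spec <- default_knots(yhat, K = max(K, 1L), degree = degree)
  }
  dim1 <- spec$degree + 1L + length(spec$knots)
  if (n < dim1 + 2L)
    stop("need at least ", dim1 + 2L,
         " phase points for this basis (got ", n, ")")
  fit <- fit_penalized_spline(yhat, v, spec = spec)
  out <- structure(list(fit = fit, gamma0 = fit$beta[1L],
                        range = range(yhat), n = n,
                        tolerance = tolerance),
                   class = "phase_smooth_fit")
  out$steady_states <- find_steady_states(out, tolerance = tolerance)
  out
}

#' @export
print.phase_smooth_fit <- function(x, ...) {
  cat("Smooth phase law dy/dt = gamma0 + g(y), penalized spline over y\n")
  cat("  ", x$n, " points over y in [", signif(x$range[1L], 4), ", ",
      signif(x$range[2L], 4), "]\n", sep = "")
  ss <- x$steady_states
  if (nrow(ss))
    for (i in seq_len(nrow(ss)))
      cat(sprintf("  steady state y* = %.4g (%s)\n",
                  ss$y_star[i], ss$stability[i]))
  else cat("  no steady state inside the observed range\n")
  invisible(x)
}

#' Evaluate a fitted smooth phase law
#'
#' @param law A [fit_smooth_phase()] object.
#' @param y Aggregation levels at which to evaluate the law.
#' @param level Band level.
#' @return A `curve_estimate` data frame (column `time` holds the
#'   aggregation level).
#' @export
predict_phase_law <- function(law, y, level = 0.95) {
  stopifnot(inherits(law, "phase_smooth_fit"))
  suppressWarnings(predict_curve(law$fit, y, 0, level = level))
}

#' Locate steady states of a fitted phase law and classify their stability
#'
#' For the linear law the unique root is \eqn{y^* = -\gamma_0/\gamma_1},
#' stable iff \eqn{\gamma_1 < 0} (with \eqn{\gamma_1 = 0} there is no finite
#' steady state and an empty table is returned, flagged via
#' `attr(, "no_finite_fixed_point")`). For the smooth law the fitted
#' \eqn{F(y)} is scanned for sign changes on a dense grid over the observed
#' aggregation range — widened by a fraction `extend` at each end, because a
#' trajectory relaxing towards its steady state approaches it from one side,
#' leaving the root just beyond the largest fitted value — and each bracket
#' is refined by bisection until \eqn{|F(y^*)|} is below `tolerance`;
#' stability
#' comes from the sign of the numerically differentiated law at the root —
#' negative slope means perturbations decay (stable) — and roots where the
#' slope magnitude is below `tolerance` are flagged `indeterminate`.
#'
#' @param law A `phase_linear_fit` or `phase_smooth_fit`.
#' @param tolerance Residual tolerance \eqn{|F(y^*)| <} `tolerance` and the
#'   slope-magnitude threshold for the `indeterminate` flag.
#' @param interval Search interval for the smooth law; default the observed
#'   aggregation range widened by `extend` at each end.
#' @param n_grid Scan grid size.
#' @param extend Fractional widening of the default search interval.
#' @return Data frame with columns `y_star`, `velocity` (residual
#'   \eqn{F(y^*)}), `slope` (\eqn{F'(y^*)}) and `stability`
#'   (`"stable"`, `"unstable"` or `"indeterminate"`).
#' @export
find_steady_states <- function(law, tolerance = 1e-6, interval = NULL,
                               n_grid = 2001, extend = 0.05) {
  UseMethod("find_steady_states")
}

.empty_steady_states <- function() {
  data.frame(y_star = numeric(0), velocity = numeric(0),
             slope = numeric(0), stability = character(0))
}

#' @rdname find_steady_states
#' @export
find_steady_states.phase_linear_fit <- function(law, tolerance = 1e-6,
                                                interval = NULL,
                                                n_grid = 2001,
                                                extend = 0.05) {
  if (law$gamma1 == 0) {
    out <- .empty_steady_states()
    attr(out, "no_finite_fixed_point") <- TRUE
    return(out)
  }
  ystar <- -law$gamma0 / law$gamma1
  data.frame(y_star = ystar, velocity = 0, slope = law$gamma1,
             stability = if (law$gamma1 < 0) "stable" else "unstable")
}

#' @rdname find_steady_states
#' @export
find_steady_states.phase_smooth_fit <- function(law, tolerance = 1e-6,
                                                interval = NULL,
                                                n_grid = 2001,
                                                extend = 0.05) {
  .assert_number(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  .assert_number(extend, "extend", lower = 0)
  if (is.null(interval))
    interval <- law$range + c(-1, 1) * extend * diff(law$range)
  F_of <- function(y)
    suppressWarnings(predict_curve(law$fit, y, 0)$estimate)
  yy <- seq(interval[1L], interval[2L], length.out = n_grid)
  vv <- F_of(yy)
  roots <- numeric(0)
  exact <- which(vv == 0)
  roots <- c(roots, yy[exact])
  sgn <- sign(vv)
  cross <- which(sgn[-1L] * sgn[-n_grid] < 0)
  for (i in cross) {
    r <- uniroot(F_of, lower = yy[i], upper = yy[i + 1L],
                 tol = .Machine$double.eps^0.75, maxiter = 2000L)
    roots <- c(roots, r$root)
  }
  roots <- sort(unique(roots))
  if (!length(roots)) return(.empty_steady_states())
  # merge near-duplicates from adjacent brackets
  keep <- c(TRUE, diff(roots) > diff(interval) / n_grid)
  roots <- roots[keep]
  h <- max(diff(interval) * 1e-5, 1e-8)
  res <- lapply(roots, function(y0) {
    f0 <- F_of(y0)
    if (abs(f0) >= tolerance) return(NULL)  # grazing near-zero, not a root
    sl <- (F_of(y0 + h) - F_of(y0 - h)) / (2 * h)
    data.frame(y_star = y0, velocity = f0, slope = sl,
               stability = if (abs(sl) < tolerance) "indeterminate"
               else if (sl < 0) "stable" else "unstable")
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  if (!length(res)) return(.empty_steady_states())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
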