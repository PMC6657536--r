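#' Truncated power-basis specification
#'
#' Defines the spline basis \deqn{f(t) = \sum_{j=0}^{p} \beta_j t^j +
#' \sum_{k=1}^{K} u_k (t - \kappa_k)_+^p} used throughout the package, where
#' \eqn{(x)_+^p = x^p} for \eqn{x > 0} and 0 otherwise (and 0 at \eqn{x = 0},
#' the continuous limit). Degree 5 is the default so that the estimated curve
#' and its first two derivatives are smooth across knots.
#'
#' @param degree Polynomial degree `p >= 1` (default 5).
#' @param knots Strictly increasing knot locations (minutes).
#' @param knot_rule How the knots were chosen; bookkeeping only.
#' @return An object of class `spline_spec`.
#' @seealso [default_knots()], [truncated_basis()]
#' @export
spline_spec <- function(degree = 5, knots,
                        knot_rule = c("explicit", "quantile", "equal_spaced")) {
  knot_rule <- match.arg(knot_rule)
  .assert_number(degree, "degree", lower = 1)
  if (length(knots) < 1L || anyNA(knots) || !is.numeric(knots))
    stop("'knots' must be a non-empty numeric vector")
  if (is.unsorted(knots, strictly = TRUE))
    stop("'knots' must be strictly increasing")
  structure(list(degree = as.integer(degree), knots = as.numeric(knots),
                 knot_rule = knot_rule),
            class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Truncated power spline basis: degree ", x$degree, ", ",
      length(x$knots), " knots (", x$knot_rule, ")\n", sep = "")
  invisible(x)
}

#' Default knot placement
#'
#' Places `K` knots at the interior quantiles (probabilities
#' \eqn{1/(K+1), \dots, K/(K+1)}) of the distinct observed times. The
#' automatic rule `K = min(floor(n_distinct / 4), 35)` follows common
#' penalized-spline practice of using ample knots and letting the penalty do
#' the smoothing.
#'
#' @param times Observed times (duplicates allowed).
#' @param K Number of knots, or `"auto"`.
#' @param degree Degree stored in the returned spec.
#' @return A [spline_spec()] with `knot_rule = "quantile"`.
#' @export
default_knots <- function(times, K = "auto", degree = 5) {
  ut <- sort(unique(as.numeric(times[is.finite(times)])))
  nd <- length(ut)
  if (identical(K, "auto")) K <- min(nd %/% 4L, 35L)
  .assert_number(K, "K", lower = 1)
  K <- as.integer(K)
  if (nd < K + 2L)
    stop("need at least K + 2 = ", K + 2L, " distinct times, got ", nd)
  kn <- unname(quantile(ut, probs = seq_len(K) / (K + 1), type = 7))
  kn <- unique(kn)
  kn <- kn[kn > ut[1L] & kn < ut[nd]]
  if (!length(kn)) stop("knot placement degenerated; too few distinct times")
  spline_spec(degree = degree, knots = kn, knot_rule = "quantile")
}

#' Evaluate the truncated power basis and its derivatives
#'
#' Returns the design blocks of the basis at the requested derivative order
#' `m`: the polynomial block has columns \eqn{d^m t^j / dt^m = j!/(j-m)!\,
#' t^{j-m}} for \eqn{j \ge m} (zero columns for \eqn{j < m}, keeping the
#' coefficient layout identical across orders), and the truncated block has
#' columns \eqn{p!/(p-m)!\,(t-\kappa_k)_+^{p-m}} — the exact calculus
#' derivative of \eqn{(t-\kappa_k)_+^p}, with value 0 at \eqn{t \le \kappa_k}.
#'
#' @param times Evaluation times.
#' @param spec A [spline_spec()].
#' @param deriv_order 0 (curve), 1 (velocity) or 2 (acceleration).
#' @return A list with matrices `X` (`length(times)` by `degree + 1`) and `Z`
#'   (`length(times)` by `K`).
#' @export
truncated_basis <- function(times, spec, deriv_order = 0) {
  stopifnot(inherits(spec, "spline_spec"))
  if (!deriv_order %in% 0:2)
    stop("'deriv_order' must be 0, 1 or 2")
  p <- spec$degree
  if (deriv_order > p - 1)
    stop("'deriv_order' must be <= degree - 1 for a continuous result")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    stop("'times' must be finite")
  rng <- range(times)
  if (any(spec$knots < rng[1L] | spec$knots > rng[2L]))
    warning("some knots lie outside the range of 'times'")
  m <- deriv_order
  X <- matrix(0, length(times), p + 1L)
  for (j in 0:p)
    if (j >= m)
      X[, j + 1L] <- (factorial(j) / factorial(j - m)) * times^(j - m)
  dt <- outer(times, spec$knots, "-")
  Z <- (factorial(p) / factorial(p - m)) * pmax(dt, 0)^(p - m)
  colnames(X) <- paste0("t^", 0:p)
  colnames(Z) <- paste0("knot", seq_along(spec$knots))
  list(X = X, Z = Z)
}

# ---------------------------------------------------------------------------
# Ridge / linear-mixed-model solver.
#
# Model: y = X beta + Z u + eps, u ~ N(0, sigma_u^2 I_K), eps ~ N(0,
# sigma_eps^2 I_n). With lambda = sigma_eps^2 / sigma_u^2 the BLUP of
# (beta, u) solves the ridge system (C'C + lambda D) theta = C'y, C = [X Z],
# D penalizing only the Z block. The REML (or ML) criterion is profiled down
# to a 1-D search over log(lambda) using the Woodbury identity, so each
# evaluation costs one K x K Cholesky regardless of n.
# ---------------------------------------------------------------------------
.ridge_lmm_fit <- function(X, Z, y, lambda = NULL,
                           method = c("REML", "ML"),
                           loglam_bounds = c(-30, 30)) {
  method <- match.arg(method)
  X <- as.matrix(X); Z <- as.matrix(Z); y <- as.numeric(y)
  n <- length(y); px <- ncol(X); K <- ncol(Z)
  if (nrow(X) != n || nrow(Z) != n) stop("design/response dimension mismatch")
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite response values")
  if (n < px + K + 2L && is.null(lambda))
    stop("need at least ", px + K + 2L,
         " observations for this basis (got ", n, ")")

  XtX <- crossprod(X); ZtZ <- crossprod(Z)
  ZtX <- crossprod(Z, X); Xty <- drop(crossprod(X, y))
  Zty <- drop(crossprod(Z, y)); yty <- sum(y * y)
  qfloor <- max(yty, 1) * .Machine$double.eps^2

  profile_parts <- function(lam) {
    A <- ZtZ
    diag(A) <- diag(A) + lam
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    AiR <- backsolve(cA, forwardsolve(t(cA), cbind(ZtX, Zty)))
    Ai_ZtX <- AiR[, seq_len(px), drop = FALSE]
    Ai_Zty <- AiR[, px + 1L]
    XtMX <- XtX - crossprod(ZtX, Ai_ZtX)
    XtMX <- (XtMX + t(XtMX)) / 2
    XtMy <- Xty - drop(crossprod(ZtX, Ai_Zty))
    yMy <- yty - sum(Zty * Ai_Zty)
    cX <- tryCatch(chol(XtMX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    b <- backsolve(cX, forwardsolve(t(cX), XtMy))
    Q <- max(yMy - sum(XtMy * b), qfloor)
    list(Q = Q,
         logdetA = 2 * sum(log(diag(cA))),
         logdetXtMX = 2 * sum(log(diag(cX))))
  }

  criterion <- function(loglam) {
    pp <- profile_parts(exp(loglam))
    if (is.null(pp)) return(.Machine$double.xmax)
    ld <- pp$logdetA - K * loglam
    if (method == "REML")
      (n - px) * log(pp$Q) + ld + pp$logdetXtMX
    else
      n * log(pp$Q) + ld
  }

  boundary <- FALSE
  if (is.null(lambda)) {
    opt <- optimize(criterion, interval = loglam_bounds, tol = 1e-8)
    loglam <- opt$minimum
    if (loglam > loglam_bounds[2L] - 0.5) boundary <- TRUE
    if (loglam < loglam_bounds[1L] + 0.5) boundary <- TRUE
    lambda <- exp(loglam)
    crit_value <- opt$objective
    if (!is.finite(crit_value))
      stop("variance-component estimation failed to converge: criterion ",
           "non-finite at log(lambda) = ", signif(loglam, 4))
  } else {
    .assert_number(lambda, "lambda", lower = 0, strict_lower = TRUE)
    crit_value <- criterion(log(lambda))
  }

  pp <- profile_parts(lambda)
  if (is.null(pp))
    stop("penalized normal equations are singular at lambda = ",
         signif(lambda, 4))
  dfres <- if (method == "REML") n - px else n
  sigma2_eps <- pp$Q / dfres
  sigma2_u <- sigma2_eps / lambda

  CtC <- rbind(cbind(XtX, t(ZtX)), cbind(ZtX, ZtZ))
  idxZ <- px + seq_len(K)
  diag(CtC)[idxZ] <- diag(CtC)[idxZ] + lambda
  cC <- tryCatch(chol(CtC), error = function(e)
    stop("penalized normal equations are singular; increase lambda or ",
         "reduce the basis"))
  theta <- backsolve(cC, forwardsolve(t(cC), c(Xty, Zty)))
  cov_unscaled <- chol2inv(cC)
  fitted <- drop(X %*% theta[seq_len(px)] + Z %*% theta[idxZ])

  list(beta = theta[seq_len(px)], u = theta[idxZ], theta = theta,
       lambda = lambda, sigma2_eps = sigma2_eps, sigma2_u = sigma2_u,
       cov = sigma2_eps * cov_unscaled, fitted = fitted, n = n,
       method = method, criterion = crit_value, boundary = boundary)
}

# Extract (times, response) from the accepted input shapes.
.as_trace <- function(times, response) {
  if (is.data.frame(times) && missing(response)) {
    df <- times
    tc <- intersect(c("time_min", "time"), names(df))
    yc <- intersect(c("aggregation_pct", "aggregation", "response"), names(df))
    if (!length(tc) || !length(yc))
      stop("data frame input must have time ('time' or 'time_min') and ",
           "response ('aggregation' or 'aggregation_pct') columns")
    return(list(times = as.numeric(df[[tc[1L]]]),
                y = as.numeric(df[[yc[1L]]])))
  }
  list(times = as.numeric(times), y = as.numeric(response))
}

#' Fit a penalized spline by its linear-mixed-model formulation
#'
#' Smooths a single-condition set of traces \eqn{y_i(t) = f(t) + \epsilon_{it}}
#' with the truncated power basis of [spline_spec()], treating the truncated
#' coefficients \eqn{u_k} as random effects with variance \eqn{\sigma_u^2}.
#' The smoothing parameter \eqn{\lambda = \sigma_\epsilon^2/\sigma_u^2} is
#' estimated by REML (profiled to a one-dimensional search; ML available), and
#' the coefficients are the BLUP solution of the mixed-model equations —
#' equivalently the generalized-ridge solution \eqn{(C'C + \lambda D)^{-1}
#' C'y} with the penalty on the truncated block only. Multiple traces of the
#' same condition may be pooled; duplicate times are treated as replicate
#' observations.
#'
#' Basis columns are computed on internally rescaled time \eqn{t/s} (with `s`
#' the largest observed time) for numerical conditioning — raw degree-5
#' powers of minutes are ill-conditioned — and all reported coefficients,
#' variances and covariances are mapped back exactly to the raw
#' parameterization (the map is diagonal because rescaling has no intercept
#' shift).
#'
#' @param times Observation times (minutes), or a data frame with
#'   `time`/`time_min` and `aggregation`/`aggregation_pct` columns.
#' @param response Percent-aggregation values (omit for data-frame input).
#' @param spec Optional [spline_spec()]; by default [default_knots()] with the
#'   given `degree` and `knots` rule.
#' @param degree,knots Used to build the default spec: degree of the basis and
#'   knot count (or `"auto"`).
#' @param method Variance-component estimation: `"REML"` (default) or `"ML"`.
#' @param lambda Optional fixed smoothing parameter (raw-time scale); when
#'   supplied no variance-component estimation is done.
#' @return An object of class `penalized_spline_fit` with components `beta`
#'   (fixed polynomial coefficients, raw scale), `u` (predicted truncated
#'   coefficients), `sigma2_u`, `sigma2_eps`, `lambda`, `cov` (joint
#'   covariance of the coefficient error, raw scale), `fitted`, `spec`,
#'   `boundary` (TRUE when \eqn{\hat\sigma_u^2} hit the boundary at 0, i.e.
#'   the fit is effectively a degree-p polynomial).
#' @seealso [predict_curve()]
#' @export
#' @examples
#' tr <- simulate_curve(curve_params("saturating", noise_sd = 1), seed = 3)
#' fit <- fit_penalized_spline(tr)
#' fit
fit_penalized_spline <- function(times, response, spec = NULL, degree = 5,
                                 knots = "auto", method = c("REML", "ML"),
                                 lambda = NULL) {
  method <- match.arg(method)
  tr <- .as_trace(times, response)
  tt <- tr$times; y <- tr$y
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite response values")
  if (anyNA(tt) || any(!is.finite(tt))) stop("non-finite time values")
  if (is.null(spec)) spec <- default_knots(tt, K = knots, degree = degree)
  stopifnot(inherits(spec, "spline_spec"))
  p <- spec$degree
  K <- length(spec$knots)
  if (length(y) < p + K + 2L)
    stop("need at least degree + K + 2 = ", p + K + 2L, " observations")

  s <- max(abs(tt))
  if (s == 0) s <- 1
  spec_s <- spline_spec(p, spec$knots / s, knot_rule = spec$knot_rule)
  B <- truncated_basis(tt / s, spec_s, 0)
  lam_s <- if (is.null(lambda)) NULL else lambda / s^(2 * p)
  fit <- .ridge_lmm_fit(B$X, B$Z, y, lambda = lam_s, method = method)

  # Diagonal back-map to raw time: t^j = s^j (t/s)^j, (t-k)_+^p = s^p (...)^p.
  S <- c(s^(0:p), rep(s^p, K))
  structure(list(
    spec = spec, degree = p,
    beta = fit$beta / S[seq_len(p + 1L)],
    u = fit$u / S[p + 1L + seq_len(K)],
    sigma2_u = fit$sigma2_u / s^(2 * p),
    sigma2_eps = fit$sigma2_eps,
    lambda = fit$lambda * s^(2 * p),
    cov = fit$cov / tcrossprod(S),
    fitted = fit$fitted,
    times = tt, response = y,
    time_range = range(tt),
    scale = s,
    theta_scaled = fit$theta, cov_scaled = fit$cov, spec_scaled = spec_s,
    method = method, boundary = fit$boundary, n = fit$n),
    class = "penalized_spline_fit")
}

#' @export
print.penalized_spline_fit <- function(x, ...) {
  cat("Penalized truncated-power spline fit (", x$method, ")\n", sep = "")
  cat("  degree ", x$degree, ", ", length(x$spec$knots), " knots, n = ",
      x$n, "\n", sep = "")
  cat("  sigma_eps = ", signif(sqrt(x$sigma2_eps), 4),
      ", sigma_u = ", signif(sqrt(x$sigma2_u), 4),
      ", lambda = ", signif(x$lambda, 4), "\n", sep = "")
  if (x$boundary)
    cat("  note: sigma_u^2 at boundary; fit is effectively a degree-",
        x$degree, " polynomial\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted curve or its derivatives with confidence bands
#'
#' Applies the derivative basis to the BLUP coefficients: order 0 gives the
#' estimated aggregation curve, order 1 the velocity and order 2 the
#' acceleration. Pointwise standard errors come from the joint coefficient
#' covariance through the same linear map, and bands are symmetric normal
#' quantile bands at the stated level, conditional on the estimated variance
#' components (plug-in bands; smoothing-parameter uncertainty is ignored).
#'
#' @param fit A [fit_penalized_spline()] object.
#' @param grid Evaluation times; defaults to the sorted unique training times.
#' @param deriv_order 0, 1 or 2.
#' @param level Confidence level of the pointwise band.
#' @return A `curve_estimate`: a data frame with columns `time`, `estimate`,
#'   `se`, `lower`, `upper` and attributes `deriv_order` and `level`.
#' @export
predict_curve <- function(fit, grid = NULL, deriv_order = 0, level = 0.95) {
  stopifnot(inherits(fit, "penalized_spline_fit"))
  if (!deriv_order %in% 0:2) stop("'deriv_order' must be 0, 1 or 2")
  .assert_number(level, "level", lower = 0, upper = 1, strict_lower = TRUE)
  if (is.null(grid)) grid <- sort(unique(fit$times))
  grid <- as.numeric(grid)
  if (!length(grid)) stop("'grid' must be non-empty")
  if (any(grid < fit$time_range[1L]) || any(grid > fit$time_range[2L]))
    warning("grid extends outside the training time range; extrapolating")

  s <- fit$scale
  B <- suppressWarnings(
    truncated_basis(grid / s, fit$spec_scaled, deriv_order))
  C <- cbind(B$X, B$Z)
  est <- drop(C %*% fit$theta_scaled) / s^deriv_order
  se <- sqrt(pmax(rowSums((C %*% fit$cov_scaled) * C), 0)) / s^deriv_order
  zq <- qnorm((1 + level) / 2)
  out <- data.frame(time = grid, estimate = est, se = se,
                    lower = est - zq * se, upper = est + zq * se)
  attr(out, "deriv_order") <- deriv_order
  attr(out, "level") <- level
  class(out) <- c("curve_estimate", "data.frame")
  out
}
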