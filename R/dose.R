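# Multi-condition functional dose model:
#   y_dj = f_1(t_j) + sum_{d>=2} I_d f_d(t_j) + eps_dj
# with every f_d a truncated power-basis penalized spline sharing one set of
# knots and one smoothing variance, fitted jointly as a single mixed model.

# Validate a long-format dataset and return it with a condition index.
.prepare_conditions <- function(dataset) {
  req <- c("dose", "group", "time_min", "aggregation_pct")
  miss <- setdiff(req, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(dataset$group),
                 c("agonist_only", "agonist_plus_np"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  # Condition order follows the ten-level layout: agonist-only doses ascending
  # first, then agonist+NP doses ascending; d = 1 is the reference.
  conds <- unique(dataset[, c("group", "dose")])
  conds <- conds[order(match(conds$group,
                             c("agonist_only", "agonist_plus_np")),
                       conds$dose), , drop = FALSE]
  conds$d <- seq_len(nrow(conds))
  conds$label <- paste0(conds$group, ":", conds$dose)
  rownames(conds) <- NULL
  idx <- match(paste0(dataset$group, ":", dataset$dose), conds$label)
  list(conditions = conds, index = idx)
}

#' Fit the joint multi-dose functional model
#'
#' Fits the indicator-deviation model in which condition 1 (the lowest
#' agonist-only dose) has mean curve \eqn{f_1(t)} and every other condition
#' `d` deviates from it by its own smooth curve \eqn{f_d(t)}, so the
#' condition-`d` mean is \eqn{l_d(t) = f_1(t) + f_d(t)}. All curves are
#' degree-`degree` truncated power splines sharing one knot set (placed from
#' the pooled times) and one smoothing variance \eqn{\sigma_u^2}; the
#' residual variance \eqn{\sigma_\epsilon^2} is shared across conditions.
#' Sharing knots makes any between-condition contrast an exact linear map of
#' the joint coefficient vector, so contrast standard errors follow from one
#' covariance matrix.
#'
#' @param dataset Long-format data frame with columns `dose`, `group`
#'   (`"agonist_only"` / `"agonist_plus_np"`), `time_min`, `aggregation_pct`
#'   (the [simulate_dataset()] schema; `subject_id` is ignored — traces within
#'   a condition are pooled).
#' @param spec Optional shared [spline_spec()]; default [default_knots()] on
#'   the pooled times.
#' @param degree,knots Default-spec construction as in
#'   [fit_penalized_spline()].
#' @param method `"REML"` or `"ML"`.
#' @param lambda Optional fixed smoothing parameter (raw-time scale).
#' @return An object of class `dose_model_fit`; see [predict_condition()] and
#'   [estimate_nano_effect()].
#' @export
fit_dose_model <- function(dataset, spec = NULL, degree = 5, knots = "auto",
                           method = c("REML", "ML"), lambda = NULL) {
  method <- match.arg(method)
  pc <- .prepare_conditions(dataset)
  conds <- pc$conditions
  D <- nrow(conds)
  tt <- as.numeric(dataset$time_min)
  y <- as.numeric(dataset$aggregation_pct)
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite response values")
  if (is.null(spec)) spec <- default_knots(tt, K = knots, degree = degree)
  p <- spec$degree
  K <- length(spec$knots)
  dim1 <- p + 1L + K
  nc <- tabulate(pc$index, D)
  small <- which(nc < dim1)
  if (length(small))
    stop("condition(s) with fewer observations than the basis dimension (",
         dim1, "): ", paste(conds$label[small], collapse = ", "))

  s <- max(abs(tt)); if (s == 0) s <- 1
  spec_s <- spline_spec(p, spec$knots / s, knot_rule = spec$knot_rule)
  B <- truncated_basis(tt / s, spec_s, 0)

  # Fixed block: baseline polynomial + indicator-masked deviation polynomials.
  # Random block: baseline + deviation truncated blocks, one shared variance.
  X <- matrix(0, length(y), (p + 1L) * D)
  Z <- matrix(0, length(y), K * D)
  X[, seq_len(p + 1L)] <- B$X
  Z[, seq_len(K)] <- B$Z
  for (d in seq_len(D)[-1L]) {
    rows <- pc$index == d
    X[rows, (d - 1L) * (p + 1L) + seq_len(p + 1L)] <- B$X[rows, ]
    Z[rows, (d - 1L) * K + seq_len(K)] <- B$Z[rows, ]
  }

  lam_s <- if (is.null(lambda)) NULL else lambda / s^(2 * p)
  fit <- .ridge_lmm_fit(X, Z, y, lambda = lam_s, method = method)

  structure(list(
    conditions = conds, spec = spec, degree = p, K = K,
    sigma2_eps = fit$sigma2_eps,
    sigma2_u = fit$sigma2_u / s^(2 * p),
    lambda = fit$lambda * s^(2 * p),
    fitted = fit$fitted, n = fit$n,
    times = tt, response = y, cond_index = pc$index,
    time_range = range(tt), scale = s,
    theta_scaled = fit$theta, cov_scaled = fit$cov, spec_scaled = spec_s,
    method = method, boundary = fit$boundary),
    class = "dose_model_fit")
}

#' @export
print.dose_model_fit <- function(x, ...) {
  cat("Joint dose model: ", nrow(x$conditions), " conditions, degree ",
      x$degree, ", ", x$K, " shared knots, n = ", x$n, "\n", sep = "")
  cat("  reference (d = 1): ", x$conditions$label[1L], "\n", sep = "")
  cat("  sigma_eps = ", signif(sqrt(x$sigma2_eps), 4), ", lambda = ",
      signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

# Match a condition given a label "group:dose", a d index, or (dose, group).
.match_condition <- function(fit, cond) {
  conds <- fit$conditions
  if (is.numeric(cond) && length(cond) == 1L && cond %in% conds$d)
    return(as.integer(cond))
  d <- match(as.character(cond), conds$label)
  if (is.na(d))
    stop("unknown condition '", cond, "'; available: ",
         paste(conds$label, collapse = ", "))
  d
}

# Coefficient-selector matrix (scaled space) for condition d at `grid`,
# derivative order m: rows map the joint theta to l_d^{(m)}(grid).
.condition_rows <- function(fit, d, grid, deriv_order = 0) {
  s <- fit$scale
  B <- suppressWarnings(
    truncated_basis(grid / s, fit$spec_scaled, deriv_order))
  p1 <- fit$degree + 1L; K <- fit$K; D <- nrow(fit$conditions)
  M <- matrix(0, length(grid), p1 * D + K * D)
  M[, seq_len(p1)] <- B$X
  M[, p1 * D + seq_len(K)] <- B$Z
  if (d > 1L) {
    M[, (d - 1L) * p1 + seq_len(p1)] <- B$X
    M[, p1 * D + (d - 1L) * K + seq_len(K)] <- B$Z
  }
  M
}

#' Evaluate one condition's fitted curve from the joint dose model
#'
#' @param fit A [fit_dose_model()] object.
#' @param condition Condition label `"group:dose"` (see
#'   `fit$conditions$label`) or its integer index `d`.
#' @param grid Evaluation times; default the condition's observed times.
#' @param deriv_order 0, 1 or 2.
#' @param level Band level.
#' @return A `curve_estimate` data frame as in [predict_curve()].
#' @export
predict_condition <- function(fit, condition, grid = NULL, deriv_order = 0,
                              level = 0.95) {
  stopifnot(inherits(fit, "dose_model_fit"))
  if (!deriv_order %in% 0:2) stop("'deriv_order' must be 0, 1 or 2")
  d <- .match_condition(fit, condition)
  if (is.null(grid))
    grid <- sort(unique(fit$times[fit$cond_index == d]))
  grid <- as.numeric(grid)
  if (!length(grid)) stop("'grid' must be non-empty")
  M <- .condition_rows(fit, d, grid, deriv_order)
  sm <- fit$scale^deriv_order
  est <- drop(M %*% fit$theta_scaled) / sm
  se <- sqrt(pmax(rowSums((M %*% fit$cov_scaled) * M), 0)) / sm
  zq <- qnorm((1 + level) / 2)
  out <- data.frame(time = grid, estimate = est, se = se,
                    lower = est - zq * se, upper = est + zq * se)
  attr(out, "deriv_order") <- deriv_order
  attr(out, "level") <- level
  class(out) <- c("curve_estimate", "data.frame")
  out
}

#' Estimate the nanoparticle effect by paired condition contrasts
#'
#' For each paired dose level `s` computes the contrast curve
#' \deqn{\hat h_s(t) = \hat l_{np(s)}(t) - \hat l_{ag(s)}(t),} the fitted
#' agonist-plus-nanoparticle curve minus the fitted agonist-only curve at the
#' same dose, and the overall effect curve as the arithmetic mean of the
#' per-dose contrasts (an exact identity, not a refit). Pointwise standard
#' errors are propagated from the joint coefficient covariance; because the
#' baseline curve cancels in every contrast, the contrasts are invariant to
#' the choice of reference condition.
#'
#' @param fit A [fit_dose_model()] object containing both groups.
#' @param pairing Optional data frame with columns `agonist` and `np` holding
#'   condition labels to contrast, one row per dose level `s`; by default all
#'   doses present in both groups are paired in ascending order.
#' @param grid Evaluation times; default the sorted unique pooled times.
#' @param level Level for the pointwise bands on the contrasts.
#' @return An object of class `nano_effect`: list with `grid`, `doses`,
#'   matrices `effect` and `se` (times by dose levels), vectors `overall` and
#'   `overall_se`, and `level`. `as.data.frame()` gives the long CSV-ready
#'   form.
#' @export
estimate_nano_effect <- function(fit, pairing = NULL, grid = NULL,
                                 level = 0.95) {
  stopifnot(inherits(fit, "dose_model_fit"))
  conds <- fit$conditions
  if (is.null(pairing)) {
    ag <- conds[conds$group == "agonist_only", ]
    np <- conds[conds$group == "agonist_plus_np", ]
    shared <- intersect(ag$dose, np$dose)
    if (!length(shared))
      stop("no dose level is present in both groups; supply 'pairing'")
    shared <- sort(shared)
    pairing <- data.frame(
      agonist = paste0("agonist_only:", shared),
      np = paste0("agonist_plus_np:", shared))
  }
  if (!all(c("agonist", "np") %in% names(pairing)))
    stop("'pairing' must have columns 'agonist' and 'np'")
  if (is.null(grid)) grid <- sort(unique(fit$times))
  grid <- as.numeric(grid)

  S <- nrow(pairing)
  eff <- se <- matrix(NA_real_, length(grid), S)
  doses <- numeric(S)
  Msum <- NULL
  for (s in seq_len(S)) {
    da <- .match_condition(fit, pairing$agonist[s])
    dn <- .match_condition(fit, pairing$np[s])
    doses[s] <- conds$dose[da]
    Mc <- .condition_rows(fit, dn, grid, 0) -
      .condition_rows(fit, da, grid, 0)
    eff[, s] <- drop(Mc %*% fit$theta_scaled)
    se[, s] <- sqrt(pmax(rowSums((Mc %*% fit$cov_scaled) * Mc), 0))
    Msum <- if (is.null(Msum)) Mc else Msum + Mc
  }
  Mbar <- Msum / S
  overall <- rowMeans(eff)
  overall_se <- sqrt(pmax(rowSums((Mbar %*% fit$cov_scaled) * Mbar), 0))

  structure(list(grid = grid, doses = doses, pairing = pairing,
                 effect = eff, se = se, overall = overall,
                 overall_se = overall_se, level = level),
            class = "nano_effect")
}

#' @export
print.nano_effect <- function(x, ...) {
  cat("Nanoparticle effect: ", length(x$doses), " paired dose level(s), ",
      length(x$grid), " grid points\n", sep = "")
  cat("  mean overall effect: ", signif(mean(x$overall), 4),
      " percent aggregation\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.nano_effect <- function(x, ...) {
  S <- length(x$doses)
  per <- data.frame(
    dose = rep(as.character(x$doses), each = length(x$grid)),
    time = rep(x$grid, S),
    estimate = as.vector(x$effect),
    se = as.vector(x$se))
  overall <- data.frame(dose = "overall", time = x$grid,
                        estimate = x$overall, se = x$overall_se)
  rbind(per, overall)
}
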