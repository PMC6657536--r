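#' Parameters for a synthetic aggregation curve family
#'
#' Defines the noiseless signal \eqn{f(t)} and the observation-noise level of a
#' synthetic optical-aggregometry trace, modelled as \eqn{y(t) = f(t) +
#' \epsilon_t} with independent (optionally AR(1)) Gaussian noise. Five curve
#' families cover the kinetic shapes seen in ADP-induced platelet aggregation:
#'
#' \describe{
#'   \item{`saturating`}{\eqn{f(t) = A(1 - e^{-kt})}: monotone rise to a
#'     plateau, the high-dose shape.}
#'   \item{`rise_decay`}{a biexponential \eqn{A\,(e^{-\lambda_2 t} -
#'     e^{-\lambda_1 t})} rescaled so its peak equals `A`: initial aggregation
#'     followed by de-aggregation, the low-dose shape. Requires
#'     \eqn{\lambda_1 > \lambda_2}; the peak sits at
#'     \eqn{t^* = \log(\lambda_1/\lambda_2)/(\lambda_1 - \lambda_2)}.}
#'   \item{`staircase`}{a sum of logistic steps plus an exponentially damped
#'     sinusoid: plateau/staircase traces with interim fluctuations. Built from
#'     smooth components so that all derivatives exist everywhere.}
#'   \item{`linear_ode`}{the solution of \eqn{dy/dt = \gamma_0 + \gamma_1 y}
#'     from `y0` (see [simulate_from_phase_law()]).}
#'   \item{`logistic_ode`}{the solution of \eqn{dy/dt = r\,y(1 - y/capacity)}
#'     from `y0 > 0`: autocatalytic, sigmoidal aggregation.}
#' }
#'
#' @param family Curve family, one of `"saturating"`, `"rise_decay"`,
#'   `"staircase"`, `"linear_ode"`, `"logistic_ode"`.
#' @param A Amplitude in percent aggregation, in \[0, 100\] (`saturating`,
#'   `rise_decay`).
#' @param k Rate constant (per minute) of the saturating family.
#' @param lambda1,lambda2 Fast and slow rate constants (per minute) of the
#'   rise--decay family; `lambda1 > lambda2 > 0`.
#' @param plateaus Step heights (percent) of the staircase family; their sum is
#'   the final plateau and must lie in \[0, 100\].
#' @param transitions Step midpoints (minutes), strictly inside `(0, duration)`,
#'   same length as `plateaus`.
#' @param steepness Logistic steepness (per minute) of the staircase steps.
#' @param wiggle_amp,wiggle_decay,wiggle_freq Amplitude (percent), exponential
#'   damping rate (per minute) and frequency (cycles per minute) of the damped
#'   oscillation superimposed on the staircase.
#' @param gamma0,gamma1,y0 Intercept (percent/min), slope (1/min, nonzero) and
#'   initial value (percent) of the `linear_ode` family.
#' @param r,capacity Growth rate (per minute) and carrying capacity (percent)
#'   of the `logistic_ode` family; for this family `y0 > 0`.
#' @param noise_sd Standard deviation of the additive observation noise
#'   (percent aggregation), `>= 0`.
#' @param duration Trace duration in minutes (aggregometer runs last roughly
#'   6--7 minutes; default 7).
#' @param n_points Number of equally spaced sampling times over
#'   `[0, duration]`, `>= 2`.
#' @param ar_rho Optional AR(1) coefficient of the noise, in `(-1, 1)`;
#'   default 0 (independent noise).
#'
#' @return An object of class `curve_params`.
#' @seealso [simulate_curve()], [simulate_dataset()]
#' @export
#' @examples
#' p <- curve_params("saturating", A = 80, k = 1.5, noise_sd = 1)
#' head(simulate_curve(p, seed = 1))
curve_params <- function(family = c("saturating", "rise_decay", "staircase",
                                    "linear_ode", "logistic_ode"),
                         A = 80, k = 1.5,
                         lambda1 = 3, lambda2 = 0.4,
                         plateaus = c(35, 45), transitions = c(1, 3),
                         steepness = 4, wiggle_amp = 3, wiggle_decay = 1,
                         wiggle_freq = 1.5,
                         gamma0 = 120, gamma1 = -1.5, y0 = 0,
                         r = 0.8, capacity = 70,
                         noise_sd = 1, duration = 7, n_points = 400,
                         ar_rho = 0) {
  if (is.character(family) && length(family) == 1L &&
      !family %in% c("saturating", "rise_decay", "staircase", "linear_ode",
                     "logistic_ode"))
    stop("unknown curve family: '", family, "'")
  family <- match.arg(family)
  .assert_number(noise_sd, "noise_sd", lower = 0)
  .assert_number(duration, "duration", lower = 0, strict_lower = TRUE)
  .assert_number(n_points, "n_points", lower = 2)
  .assert_number(ar_rho, "ar_rho", lower = -1, upper = 1)

  switch(family,
    saturating = {
      .assert_number(A, "A", lower = 0, upper = 100)
      .assert_number(k, "k", lower = 0, strict_lower = TRUE)
    },
    rise_decay = {
      .assert_number(A, "A", lower = 0, upper = 100)
      .assert_number(lambda1, "lambda1", lower = 0, strict_lower = TRUE)
      .assert_number(lambda2, "lambda2", lower = 0, strict_lower = TRUE)
      if (lambda1 <= lambda2) stop("'lambda1' must exceed 'lambda2'")
    },
    staircase = {
      if (length(plateaus) != length(transitions) || length(plateaus) < 1L)
        stop("'plateaus' and 'transitions' must have equal positive length")
      if (any(plateaus < 0) || sum(plateaus) > 100)
        stop("staircase plateau levels must be >= 0 and sum to <= 100")
      if (any(transitions <= 0) || any(transitions >= duration))
        stop("staircase transition times must lie strictly inside (0, duration)")
      .assert_number(steepness, "steepness", lower = 0, strict_lower = TRUE)
      .assert_number(wiggle_amp, "wiggle_amp", lower = 0)
    },
    linear_ode = {
      if (gamma1 == 0) stop("'gamma1' must be nonzero for the linear_ode family")
    },
    logistic_ode = {
      .assert_number(r, "r", lower = 0, strict_lower = TRUE)
      .assert_number(capacity, "capacity", lower = 0, strict_lower = TRUE)
      .assert_number(y0, "y0", lower = 0, strict_lower = TRUE)
    })

  structure(list(family = family, A = A, k = k, lambda1 = lambda1,
                 lambda2 = lambda2, plateaus = plateaus,
                 transitions = transitions, steepness = steepness,
                 wiggle_amp = wiggle_amp, wiggle_decay = wiggle_decay,
                 wiggle_freq = wiggle_freq, gamma0 = gamma0, gamma1 = gamma1,
                 y0 = y0, r = r, capacity = capacity, noise_sd = noise_sd,
                 duration = duration, n_points = n_points, ar_rho = ar_rho),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat("Synthetic aggregation curve: family '", x$family, "', ",
      x$n_points, " points over [0, ", x$duration, "] min, noise sd ",
      x$noise_sd, "\n", sep = "")
  invisible(x)
}

# Noiseless signal f(t) of a curve_params object, as a vectorized function.
signal_function <- function(params) {
  stopifnot(inherits(params, "curve_params"))
  switch(params$family,
    saturating = function(t) params$A * (1 - exp(-params$k * t)),
    rise_decay = {
      l1 <- params$lambda1; l2 <- params$lambda2
      tstar <- log(l1 / l2) / (l1 - l2)
      peak <- exp(-l2 * tstar) - exp(-l1 * tstar)
      function(t) params$A * (exp(-l2 * t) - exp(-l1 * t)) / peak
    },
    staircase = function(t) {
      f <- rep(0, length(t))
      for (i in seq_along(params$plateaus))
        f <- f + params$plateaus[i] *
          plogis(params$steepness * (t - params$transitions[i]))
      f + params$wiggle_amp * exp(-params$wiggle_decay * t) *
        sin(2 * pi * params$wiggle_freq * t)
    },
    linear_ode = {
      ystar <- -params$gamma0 / params$gamma1
      function(t) ystar + (params$y0 - ystar) * exp(params$gamma1 * t)
    },
    logistic_ode = function(t) {
      params$capacity /
        (1 + (params$capacity - params$y0) / params$y0 * exp(-params$r * t))
    })
}

#' Simulate a single aggregometry trace
#'
#' Draws one percent-aggregation time course \eqn{y(t_l) = f(t_l) +
#' \epsilon_l} on an equally spaced grid of `n_points` times over
#' `[0, duration]`, with `f` the noiseless signal of the chosen curve family
#' and independent (or AR(1)) Gaussian noise of standard deviation
#' `noise_sd`. Values are deliberately not clipped to \[0, 100\]: clipping
#' would break the additive-noise model the spline estimators assume.
#'
#' @param params A [curve_params()] object.
#' @param seed Optional integer seed; identical `(params, seed)` reproduce the
#'   trace bit for bit, and the caller's RNG stream is left untouched.
#' @return A data frame with columns `time` (minutes) and `aggregation`
#'   (percent).
#' @export
simulate_curve <- function(params, seed = NULL) {
  if (!inherits(params, "curve_params"))
    stop("'params' must be a curve_params object")
  tt <- seq(0, params$duration, length.out = params$n_points)
  f <- signal_function(params)(tt)
  eps <- with_seed(seed,
                   .sim_noise(params$n_points, params$noise_sd, params$ar_rho))
  data.frame(time = tt, aggregation = f + eps)
}

#' Simulate a trace from a linear phase law
#'
#' Generates a trace whose noiseless signal is the exact solution of the linear
#' differential equation \eqn{dy/dt = \gamma_0 + \gamma_1 y}, namely
#' \deqn{y(t) = -\gamma_0/\gamma_1 + (y_0 + \gamma_0/\gamma_1)
#'   e^{\gamma_1 t},}
#' the closed form used as an oracle for phase-plane reconstruction. With
#' \eqn{\gamma_1 < 0} the trajectory relaxes to the stable steady state
#' \eqn{y^* = -\gamma_0/\gamma_1}.
#'
#' @param gamma0 Intercept of the phase law (percent per minute).
#' @param gamma1 Slope of the phase law (1/min); must be nonzero.
#' @param y0 Initial aggregation (percent).
#' @param duration,n_points Grid definition as in [curve_params()].
#' @param noise_sd Additive Gaussian noise sd (percent).
#' @param seed Optional integer seed.
#' @return A data frame with columns `time` and `aggregation`.
#' @export
#' @examples
#' tr <- simulate_from_phase_law(120, -1.5, n_points = 50, seed = 1)
#' tail(tr, 2)  # approaches the fixed point 80
simulate_from_phase_law <- function(gamma0, gamma1, y0 = 0, duration = 7,
                                    n_points = 400, noise_sd = 0,
                                    seed = NULL) {
  if (!is.numeric(gamma1) || length(gamma1) != 1L || gamma1 == 0)
    stop("'gamma1' must be nonzero; for gamma1 = 0 use the saturating or ",
         "linear curve families")
  p <- curve_params("linear_ode", gamma0 = gamma0, gamma1 = gamma1, y0 = y0,
                    noise_sd = noise_sd, duration = duration,
                    n_points = n_points)
  simulate_curve(p, seed = seed)
}

#' Dose--group design for a synthetic aggregometry experiment
#'
#' Describes the layout of a multi-dose experiment: an increasing ladder of
#' agonist (ADP) doses, one or both treatment groups (agonist only, agonist
#' plus nanoparticles), the additive nanoparticle enhancement and the number
#' of replicate traces per condition. The nanoparticle effect is an additive
#' smooth offset on the signal scale,
#' \eqn{h(t) = a\,(1 - e^{-r t})} for onset 0, or a logistic ramp
#' \eqn{a / (1 + e^{-r (t - onset)})} for a positive onset minute.
#'
#' @param doses Strictly increasing numeric dose labels.
#' @param groups Subset of `c("agonist_only", "agonist_plus_np")`.
#' @param np_amplitude Asymptotic nanoparticle enhancement (percent), `>= 0`.
#' @param np_rate Rate constant (per minute) of the enhancement ramp.
#' @param np_onset Onset minute of the enhancement; 0 means active from t = 0.
#' @param replicates Traces per (dose, group) cell, `>= 1`.
#' @return An object of class `dose_design`.
#' @export
dose_design <- function(doses,
                        groups = c("agonist_only", "agonist_plus_np"),
                        np_amplitude = 0, np_rate = 2, np_onset = 0,
                        replicates = 1) {
  if (length(doses) < 1L || any(diff(doses) <= 0))
    stop("'doses' must be strictly increasing")
  bad <- setdiff(groups, c("agonist_only", "agonist_plus_np"))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "))
  .assert_number(np_amplitude, "np_amplitude", lower = 0)
  .assert_number(np_rate, "np_rate", lower = 0, strict_lower = TRUE)
  .assert_number(np_onset, "np_onset", lower = 0)
  .assert_number(replicates, "replicates", lower = 1)
  structure(list(doses = doses, groups = groups, np_amplitude = np_amplitude,
                 np_rate = np_rate, np_onset = np_onset,
                 replicates = as.integer(replicates)),
            class = "dose_design")
}

# The additive nanoparticle offset h(t) of a design, vectorized over t.
np_offset <- function(design, t) {
  a <- design$np_amplitude
  if (a == 0) return(rep(0, length(t)))
  if (design$np_onset == 0) a * (1 - exp(-design$np_rate * t))
  else a * plogis(design$np_rate * (t - design$np_onset))
}

#' Simulate a full multi-dose aggregometry dataset
#'
#' Generates one trace per (dose, group, replicate) cell of a [dose_design()].
#' Traces in the `agonist_plus_np` group share the agonist-only noiseless
#' signal of their dose plus the design's smooth nanoparticle offset, with
#' noise added afterwards, so the group contrast of noiseless signals equals
#' the configured offset exactly.
#'
#' @param design A [dose_design()].
#' @param params_by_dose Named list mapping each dose label (via
#'   `as.character(dose)`) to a [curve_params()] object. Every trace in a cell
#'   uses its dose's parameters; `noise_sd`, `duration` and `n_points` are
#'   taken from these objects.
#' @param seed Optional integer seed for the whole dataset.
#' @return A long-format data frame with columns `subject_id`, `dose`,
#'   `group`, `time_min`, `aggregation_pct` — the schema consumed by
#'   [fit_penalized_spline()] and [fit_dose_model()] and written by
#'   [write_aggregation_dataset()].
#' @export
#' @examples
#' des <- dose_design(c(0.4, 1.2), replicates = 1, np_amplitude = 10)
#' pars <- lapply(c(`0.4` = 30, `1.2` = 70), function(a)
#'   curve_params("saturating", A = a, noise_sd = 0, n_points = 20))
#' dat <- simulate_dataset(des, pars, seed = 1)
#' table(dat$dose, dat$group)
simulate_dataset <- function(design, params_by_dose, seed = NULL) {
  if (!inherits(design, "dose_design"))
    stop("'design' must be a dose_design object")
  keys <- as.character(design$doses)
  missing_d <- keys[!keys %in% names(params_by_dose)]
  if (length(missing_d))
    stop("no curve parameters supplied for dose(s): ",
         paste(missing_d, collapse = ", "))
  for (k in keys)
    if (!inherits(params_by_dose[[k]], "curve_params"))
      stop("'params_by_dose[[\"", k, "\"]]' is not a curve_params object")

  with_seed(seed, {
    out <- vector("list",
                  length(keys) * length(design$groups) * design$replicates)
    i <- 0L; sid <- 0L
    for (k in seq_along(keys)) {
      p <- params_by_dose[[keys[k]]]
      tt <- seq(0, p$duration, length.out = p$n_points)
      f0 <- signal_function(p)(tt)
      for (g in design$groups) {
        f <- if (g == "agonist_plus_np") f0 + np_offset(design, tt) else f0
        for (rep_i in seq_len(design$replicates)) {
          i <- i + 1L; sid <- sid + 1L
          eps <- .sim_noise(p$n_points, p$noise_sd, p$ar_rho)
          out[[i]] <- data.frame(
            subject_id = sprintf("s%03d", sid),
            dose = design$doses[k],
            group = g,
            time_min = tt,
            aggregation_pct = f + eps)
        }
      }
    }
    do.call(rbind, out)
  })
}
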