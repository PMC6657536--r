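# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs `code` untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.assert_number <- function(x, name, lower = -Inf, upper = Inf,
                           strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (strict_lower && x <= lower)
    stop("'", name, "' must be > ", lower)
  if (!strict_lower && x < lower)
    stop("'", name, "' must be >= ", lower)
  if (x > upper)
    stop("'", name, "' must be <= ", upper)
  invisible(x)
}

# Gaussian noise, optionally AR(1) with stationary marginal sd `sd`.
.sim_noise <- function(n, sd, ar_rho = 0) {
  if (sd < 0) stop("'noise_sd' must be >= 0")
  if (sd == 0) return(rep(0, n))
  z <- rnorm(n)
  if (ar_rho == 0) return(sd * z)
  if (abs(ar_rho) >= 1) stop("'ar_rho' must lie in (-1, 1)")
  e <- numeric(n)
  e[1L] <- sd * z[1L]
  innov <- sd * sqrt(1 - ar_rho^2)
  for (i in seq_len(n)[-1L]) e[i] <- ar_rho * e[i - 1L] + innov * z[i]
  e
}
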