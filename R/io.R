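# Long-format CSV interchange (RFC-4180, UTF-8, "." decimal separator) and
# the end-to-end pipeline driver.

.dataset_columns <- c("subject_id", "dose", "group", "time_min",
                      "aggregation_pct")

#' Validate a long-format aggregation dataset
#'
#' Checks the documented schema (`subject_id`, `dose`, `group`, `time_min`,
#' `aggregation_pct`), coerces numeric columns, verifies group labels, sorts
#' non-monotone trace times with a warning, errors on non-finite responses,
#' and warns (without rejecting) when aggregation values fall outside
#' \[-20, 120\] percent — additive noise can legitimately push observations
#' somewhat outside \[0, 100\].
#'
#' @param dataset A data frame.
#' @return The validated (possibly re-sorted) data frame.
#' @export
validate_aggregation_dataset <- function(dataset) {
  miss <- setdiff(.dataset_columns, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  for (cn in c("time_min", "aggregation_pct")) {
    v <- dataset[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("unparseable numeric in column '", cn, "' at row ", bad[1L])
      dataset[[cn]] <- vn
    }
  }
  if (anyNA(dataset$aggregation_pct) ||
      any(!is.finite(dataset$aggregation_pct)))
    stop("'aggregation_pct' contains non-finite values")
  if (anyNA(dataset$time_min) || any(!is.finite(dataset$time_min)) ||
      any(dataset$time_min < 0))
    stop("'time_min' must be finite and >= 0")
  bad <- setdiff(unique(dataset$group), c("agonist_only", "agonist_plus_np"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (any(dataset$aggregation_pct < -20 | dataset$aggregation_pct > 120))
    warning("aggregation_pct values outside [-20, 120] percent")

  key <- interaction(dataset$subject_id, dataset$dose, dataset$group,
                     drop = TRUE)
  unsorted <- vapply(split(dataset$time_min, key),
                     function(tt) is.unsorted(tt, strictly = TRUE),
                     logical(1L))
  if (any(unsorted)) {
    warning("non-monotone trace times in ", sum(unsorted),
            " trace(s); sorting")
    dataset <- dataset[order(key, dataset$time_min), , drop = FALSE]
    rownames(dataset) <- NULL
  }
  dataset
}

#' Read an aggregation dataset from CSV
#'
#' @param path Path to a CSV with the [validate_aggregation_dataset()] schema.
#' @return A validated data frame.
#' @export
read_aggregation_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse '", path, "': ",
                                           conditionMessage(e)))
  if (nrow(dat) == 0L) stop("dataset is empty: ", path)
  validate_aggregation_dataset(dat)
}

#' Write an aggregation dataset to CSV
#'
#' @param dataset Data frame with the documented schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_aggregation_dataset <- function(dataset, path) {
  miss <- setdiff(.dataset_columns, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  write.csv(dataset[, .dataset_columns], path, row.names = FALSE)
  invisible(path)
}

# Build a dose_design + per-dose curve_params pair from a plain config list
# (the YAML/CLI surface of the simulator).
.simulation_from_config <- function(sim) {
  doses <- sim$doses
  if (is.null(doses)) stop("simulate config needs 'doses'")
  design <- dose_design(
    doses = doses,
    groups = sim$groups %||% c("agonist_only", "agonist_plus_np"),
    np_amplitude = sim$np_amplitude %||% 0,
    np_rate = sim$np_rate %||% 2,
    np_onset = sim$np_onset %||% 0,
    replicates = sim$replicates %||% 1)
  amp <- sim$amplitudes %||% seq(20, 90, length.out = length(doses))
  if (length(amp) != length(doses))
    stop("'amplitudes' must match 'doses' in length")
  rate <- sim$rates %||% seq(0.8, 2.5, length.out = length(doses))
  if (length(rate) == 1L) rate <- rep(rate, length(doses))
  params <- setNames(lapply(seq_along(doses), function(i)
    curve_params(sim$family %||% "saturating",
                 A = amp[i], k = rate[i],
                 noise_sd = sim$noise_sd %||% 1,
                 duration = sim$duration %||% 7,
                 n_points = sim$n_points %||% 400)),
    as.character(doses))
  list(design = design, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_estimate <- function(est, path) {
  write.csv(as.data.frame(est)[, c("time", "estimate", "se", "lower",
                                   "upper")], path, row.names = FALSE)
  path
}

#' Run the full aggregometry analysis pipeline
#'
#' Orchestrates the stages end to end: load (or simulate) the dataset, fit a
#' penalized spline per condition and export curve / velocity / acceleration
#' estimates, fit the joint dose model, estimate the nanoparticle effect when
#' both groups are present, fit the linear and smooth phase laws per
#' condition with steady-state analysis, and write a machine-readable
#' manifest. All outputs are CSV (plus the manifest JSON); rerunning with the
#' same config and seed reproduces byte-identical CSVs.
#'
#' @param config Either a list or a path to a YAML/JSON file. Recognised
#'   fields: `input` (CSV path) or `simulate` (list with `doses`, optional
#'   `amplitudes`, `rates`, `family`, `noise_sd`, `np_amplitude`, `np_rate`,
#'   `replicates`, `duration`, `n_points`, `groups`); `spline` (list with
#'   `degree`, `knots`); `phase` (list with `trim`, `tolerance`); `seed`;
#'   `outdir`.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Seed (overrides `config$seed`).
#' @return Invisibly, the manifest list (stages, settings, output files).
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a file path")
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  seed <- seed %||% config$seed
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  degree <- config$spline$degree %||% 5
  knots <- config$spline$knots %||% "auto"
  trim <- config$phase$trim %||% 0.05
  tolerance <- config$phase$tolerance %||% 1e-6

  stages <- c("load", "condition_fits", "dose_model", "nano_effect", "phase")
  manifest <- list(
    package = "plateletfda",
    version = as.character(packageVersion("plateletfda")),
    seed = seed,
    settings = list(degree = degree, knots = knots, trim = trim,
                    tolerance = tolerance),
    stages = setNames(as.list(rep("pending", length(stages))), stages),
    files = character(0))
  fail <- function(stage, e) {
    manifest$stages[[stage]] <- paste0("failed: ", conditionMessage(e))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  add_file <- function(p) manifest$files <<- c(manifest$files, basename(p))

  # -- load -----------------------------------------------------------------
  dat <- tryCatch({
    if (!is.null(config$input)) {
      read_aggregation_dataset(config$input)
    } else if (!is.null(config$simulate)) {
      sc <- .simulation_from_config(config$simulate)
      d <- simulate_dataset(sc$design, sc$params, seed = seed)
      write_aggregation_dataset(d, file.path(outdir, "data.csv"))
      add_file("data.csv")
      d
    } else stop("config needs either 'input' or 'simulate'")
  }, error = function(e) fail("load", e))
  manifest$stages$load <- "completed"

  pc <- .prepare_conditions(dat)
  conds <- pc$conditions
  if (!is.null(config$conditions)) {
    absent <- setdiff(config$conditions, conds$label)
    if (length(absent))
      fail("load", simpleError(paste0("condition(s) not in the data: ",
                                      paste(absent, collapse = ", "))))
  }

  # -- per-condition spline fits + derivative estimates ---------------------
  fits <- tryCatch({
    fits <- list()
    for (i in seq_len(nrow(conds))) {
      rows <- pc$index == i
      f <- fit_penalized_spline(dat$time_min[rows],
                                dat$aggregation_pct[rows],
                                degree = degree, knots = knots)
      slug <- gsub("[^A-Za-z0-9._-]", "_", conds$label[i])
      for (m in 0:2) {
        nm <- c("curve", "velocity", "acceleration")[m + 1L]
        pth <- file.path(outdir, sprintf("fit_%s_%s.csv", slug, nm))
        .write_estimate(predict_curve(f, deriv_order = m), pth)
        add_file(pth)
      }
      fits[[conds$label[i]]] <- f
    }
    fits
  }, error = function(e) fail("condition_fits", e))
  manifest$stages$condition_fits <- "completed"

  # -- joint dose model -----------------------------------------------------
  dm <- tryCatch({
    dm <- fit_dose_model(dat, degree = degree, knots = knots)
    long <- do.call(rbind, lapply(seq_len(nrow(conds)), function(d) {
      est <- predict_condition(dm, d)
      cbind(condition = conds$label[d], as.data.frame(est))
    }))
    pth <- file.path(outdir, "dose_model_fitted.csv")
    write.csv(long, pth, row.names = FALSE)
    add_file(pth)
    dm
  }, error = function(e) fail("dose_model", e))
  manifest$stages$dose_model <- "completed"

  # -- nanoparticle effect --------------------------------------------------
  manifest$stages$nano_effect <- tryCatch({
    if (length(unique(conds$group)) == 2L) {
      eff <- estimate_nano_effect(dm)
      pth <- file.path(outdir, "nano_effect.csv")
      write.csv(as.data.frame(eff), pth, row.names = FALSE)
      add_file(pth)
      "completed"
    } else "skipped: single group"
  }, error = function(e) fail("nano_effect", e))

  # -- phase-plane models ---------------------------------------------------
  tryCatch({
    lin <- do.call(rbind, lapply(names(fits), function(lb) {
      pts <- phase_points(fits[[lb]], trim = trim)
      pl <- fit_linear_phase(pts)
      ss <- find_steady_states(pl)
      data.frame(condition = lb, gamma0 = pl$gamma0,
                 se_gamma0 = pl$se_gamma0, gamma1 = pl$gamma1,
                 se_gamma1 = pl$se_gamma1, tau2 = pl$tau2,
                 adj_r2_raw = pl$adj_r2_raw, adj_r2 = pl$adj_r2, n = pl$n,
                 fixed_point = if (nrow(ss)) ss$y_star else NA_real_,
                 stability = if (nrow(ss)) ss$stability else "none")
    }))
    pth <- file.path(outdir, "phase_linear.csv")
    write.csv(lin, pth, row.names = FALSE)
    add_file(pth)

    sm <- do.call(rbind, lapply(names(fits), function(lb) {
      pts <- phase_points(fits[[lb]], trim = trim)
      ps <- fit_smooth_phase(pts, tolerance = tolerance)
      ss <- ps$steady_states
      if (!nrow(ss))
        data.frame(condition = lb, y_star = NA_real_, velocity = NA_real_,
                   slope = NA_real_, stability = "none")
      else cbind(condition = lb, ss)
    }))
    pth <- file.path(outdir, "phase_smooth_steady_states.csv")
    write.csv(sm, pth, row.names = FALSE)
    add_file(pth)
  }, error = function(e) fail("phase", e))
  manifest$stages$phase <- "completed"

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
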