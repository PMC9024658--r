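## On-disk formats.  Canonical units are SI (m, T, A, V) and are recorded in
## a header/metadata field of every file; readers validate schema and units
## and raise distinct errors for missing columns, unit mismatches and
## non-finite values.

MEAS_UNITS <- "m,T,A"

#' Write / read a coil field measurement table (CSV)
#'
#' Columns: \code{coil_id, x, y, z, Bx, By, Bz, current} for triaxial data,
#' or \code{coil_id, x, y, z, value, nx, ny, nz, current} for single-axis
#' (projected) data.  A leading comment line records the units.
#'
#' @param meas a \code{\link{field_measurements}} object.
#' @param path file path.
#' @return \code{read_measurements_csv} returns a
#'   \code{field_measurements}; the writer returns \code{path} invisibly.
#' @export
write_measurements_csv <- function(meas, path) {
  stopifnot(inherits(meas, "field_measurements"))
  if (is.null(meas$projections)) {
    df <- data.frame(coil_id = meas$coil_id, meas$positions,
                     meas$values * meas$current, current = meas$current)
    names(df) <- c("coil_id", "x", "y", "z", "Bx", "By", "Bz", "current")
  } else {
    df <- data.frame(coil_id = meas$coil_id, meas$positions,
                     value = meas$values * meas$current, meas$projections,
                     current = meas$current)
    names(df) <- c("coil_id", "x", "y", "z", "value", "nx", "ny", "nz",
                   "current")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coilcal measurements; units=%s", MEAS_UNITS), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    u <- sub(".*units=", "", first)
    if (u != MEAS_UNITS)
      stop(sprintf("unit mismatch: file declares '%s', expected '%s'",
                   u, MEAS_UNITS), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  need_pos <- c("coil_id", "x", "y", "z", "current")
  miss <- setdiff(need_pos, names(df))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  triax <- all(c("Bx", "By", "Bz") %in% names(df))
  if (!triax && !all(c("value", "nx", "ny", "nz") %in% names(df)))
    stop("missing column(s): Bx,By,Bz (triaxial) or value,nx,ny,nz (projected)",
         call. = FALSE)
  num <- df[setdiff(names(df), "coil_id")]
  if (!all(vapply(num, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite values in measurement table", call. = FALSE)
  cur <- unique(df$current)
  if (length(cur) != 1L)
    stop("mixed currents in one measurement table", call. = FALSE)
  if (triax) {
    field_measurements(as.matrix(df[c("x", "y", "z")]),
                       as.matrix(df[c("Bx", "By", "Bz")]),
                       current = cur, coil_id = df$coil_id[1L])
  } else {
    field_measurements(as.matrix(df[c("x", "y", "z")]), df$value,
                       current = cur, coil_id = df$coil_id[1L],
                       projections = as.matrix(df[c("nx", "ny", "nz")]))
  }
}

#' Write / read a coil model set (JSON)
#'
#' Serializes the shared basis (origin, lmax, normalization tag, units) and
#' the per-coil coefficient vectors.
#'
#' @param set a \code{\link{coil_model_set}}.
#' @param path file path.
#' @return the reader returns a \code{coil_model_set}; the writer returns
#'   \code{path} invisibly.
#' @export
write_models_json <- function(set, path) {
  stopifnot(inherits(set, "coil_model_set"))
  obj <- list(
    format = "coilcal_vsh_models",
    units = list(origin = "m", coeffs = "T"),
    origin = set$origin, lmax = set$lmax, R0 = set$R0,
    normalization_tag = set$models[[1L]]$normalization,
    validity_radius = if (is.finite(set$validity_radius))
      set$validity_radius else NULL,
    coils = lapply(seq_along(set$models), function(i)
      list(coil_id = colnames(set$B)[i], coeffs = set$models[[i]]$coeffs))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "coilcal_vsh_models")
    stop("not a coilcal VSH model file", call. = FALSE)
  vr <- obj$validity_radius
  ids <- obj$coils$coil_id
  co <- obj$coils$coeffs
  if (is.null(ids)) {                       # non-simplified fallback
    ids <- vapply(obj$coils, `[[`, character(1), "coil_id")
    co <- lapply(obj$coils, function(c) as.numeric(c$coeffs))
  }
  models <- lapply(seq_along(ids), function(i)
    vsh_model(if (is.list(co)) co[[i]] else co[i, ], obj$lmax,
              as.numeric(obj$origin), obj$R0,
              validity_radius = vr, coil_id = ids[i]))
  coil_model_set(models)
}

#' Write / read sensor parameters (JSON)
#'
#' @param sensors list of \code{\link{sensor_parameters}}.
#' @param path file path.
#' @return the reader returns a list of \code{sensor_parameters}; the
#'   writer returns \code{path} invisibly.
#' @export
write_sensors_json <- function(sensors, path) {
  obj <- list(
    format = "coilcal_sensors",
    units = list(gain = "V/T", position = "m"),
    sensors = lapply(sensors, function(s)
      list(channel = s$channel_id, gain_V_per_T = s$gain,
           position_m = s$position, orientation = s$orientation))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensors_json
#' @export
read_sensors_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "coilcal_sensors")
    stop("not a coilcal sensor parameter file", call. = FALSE)
  lapply(obj$sensors, function(s)
    sensor_parameters(s$gain_V_per_T, unlist(s$position_m),
                      unlist(s$orientation),
                      channel_id = s$channel))
}

#' Run the calibration pipeline from a configuration
#'
#' Configuration fields (list, or path to a YAML/JSON file): \code{seed},
#' \code{mode} ("fluxgate" or "opm"), \code{lmax}, \code{fine_tune},
#' \code{out_dir} (optional: artifacts are written there).  Executes the
#' full staged pipeline on the bundled synthetic scenario and logs each
#' stage.
#'
#' @param config list or file path.
#' @param quiet suppress progress messages.
#' @return the \code{\link{run_calibration_pipeline}} result, invisibly
#'   when artifacts are written.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mode <- if (is.null(config$mode)) "fluxgate" else config$mode
  lmax <- if (is.null(config$lmax)) 5L else as.integer(config$lmax)
  fine_tune <- if (is.null(config$fine_tune)) TRUE else
    isTRUE(config$fine_tune)
  log_msg <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[coilcal %s] %s", stage,
                                sprintf(fmt, ...)))
  }
  log_msg("config", "seed=%d mode=%s lmax=%d fine_tune=%s",
          seed, mode, lmax, fine_tune)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }
  scenario <- run_stage("simulate", default_shield_scenario(seed, mode))
  models <- run_stage("fit-fields", fit_scenario_models(scenario, lmax))
  log_msg("fit-fields", "%d coils, worst NRMSE %.3g%%",
          length(models$set), 100 * max(models$nrmse))
  run <- run_stage("calibrate",
                   run_calibration_pipeline(scenario, models = models,
                                            lmax = lmax,
                                            fine_tune = fine_tune,
                                            seed = seed))
  log_msg("calibrate", "RMS errors: %.3f mm / %.3f deg / %.3f %%",
          rms_calibration_errors(run)[1], rms_calibration_errors(run)[2],
          rms_calibration_errors(run)[3])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_models_json(models$set, file.path(config$out_dir, "models.json"))
    write_sensors_json(lapply(run$calibrations, `[[`, "estimate"),
                       file.path(config$out_dir, "sensors.json"))
    utils::write.csv(run$errors, file.path(config$out_dir, "errors.csv"),
                     row.names = FALSE)
    log_msg("write", "artifacts in %s", config$out_dir)
    return(invisible(run))
  }
  run
}
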