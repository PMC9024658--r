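#' Map and model the scenario coil fields
#'
#' Computes the Biot-Savart field of every usable coil at the scenario's
#' mapping positions (noiseless, per unit current) and fits a VSH model to
#' each, with a common origin at the centroid of the mapping positions.
#'
#' @param scenario a \code{\link{default_shield_scenario}} result.
#' @param lmax expansion degree (default 5: 35 components).
#' @param R0 reference-sphere radius of the basis normalization (m).
#' @return list with \code{set} (a \code{\link{coil_model_set}} over the
#'   usable coils), \code{measurements} (list of
#'   \code{\link{field_measurements}}), \code{nrmse} (per-coil fit NRMSE)
#'   and \code{max_field_per_amp} (per-coil max field norm over the mapping
#'   points, T/A).
#' @export
fit_scenario_models <- function(scenario, lmax = 5, R0 = 0.1) {
  stopifnot(inherits(scenario, "shield_scenario"))
  pts <- scenario$mapping_points
  origin <- colMeans(pts)
  meas <- list()
  models <- list()
  maxf <- numeric(0)
  for (k in scenario$usable) {
    B <- biot_savart_field(scenario$coils[[k]], scenario$mapping_current,
                           pts)
    m <- field_measurements(pts, B, current = scenario$mapping_current,
                            coil_id = scenario$coils[[k]]$coil_id)
    meas[[length(meas) + 1L]] <- m
    models[[length(models) + 1L]] <- fit_vsh(m, lmax = lmax,
                                             origin = origin, R0 = R0)
    maxf <- c(maxf, max(row_norms(B)) / scenario$mapping_current)
  }
  list(set = coil_model_set(models), measurements = meas,
       nrmse = vapply(models, function(m) m$nrmse, numeric(1)),
       max_field_per_amp = maxf, usable = scenario$usable)
}

#' Synthesize the eight low-order harmonic excitations
#'
#' For each degree/order with l <= 2 (three homogeneous components, five
#' first-order gradients), computes the coil currents approximating that
#' VSH component via \code{\link{currents_for_harmonic}} and scales them so
#' the true (Biot-Savart) superposed field reaches the scenario's maximum
#' amplitude over the mapping region.
#'
#' @param models result of \code{\link{fit_scenario_models}}.
#' @param scenario the matching scenario.
#' @return list of excitations: \code{l}, \code{m}, \code{currents}
#'   (full-length coil current vector, A), \code{model} (fitted
#'   \code{vsh_model} of the superposed field).
#' @export
harmonic_excitations <- function(models, scenario) {
  set <- models$set
  out <- list()
  for (l in seq_len(min(2L, set$lmax))) for (m in -l:l) {
    tgt <- harmonic_target(l, m, set$lmax)
    i_use <- currents_for_harmonic(set, tgt)
    full <- numeric(length(scenario$coils))
    full[models$usable] <- i_use
    B <- scenario_field(scenario$coils, full, scenario$mapping_points)
    sc <- scenario$b_max / max(row_norms(B))
    full <- full * sc
    out[[length(out) + 1L]] <- list(
      l = l, m = m, currents = full,
      model = superpose_models(set, as.numeric(i_use) * sc))
  }
  out
}

#' End-to-end synthetic calibration run
#'
#' Full pipeline on synthetic ground truth: map the coil fields (noiseless)
#' and fit VSH models; synthesize the eight homogeneous/gradient
#' excitations; simulate the channels' lock-in time series for the harmonic
#' and individual-coil excitations (Biot-Savart truth plus sensor noise);
#' extract in-phase amplitudes; run the staged calibration per channel; and
#' score the estimates against the known true parameters.
#'
#' @param scenario a \code{\link{default_shield_scenario}} result.
#' @param channels true \code{\link{sensor_parameters}} to calibrate
#'   (default the scenario's fluxgate channels).
#' @param models optional precomputed \code{\link{fit_scenario_models}}
#'   result (reusable across noise seeds: the mapping is noiseless).
#' @param lmax expansion degree.
#' @param fine_tune run the optional mid-pipeline refinement stage.
#' @param seed noise seed (default the scenario seed).
#' @return object of class \code{calibration_run}: \code{calibrations}
#'   (per-channel \code{sensor_calibration}), \code{errors} (data.frame
#'   with per-channel position/orientation/gain errors, final stage),
#'   \code{stage_errors} (same per stage), \code{models}, \code{harmonics}.
#' @export
run_calibration_pipeline <- function(scenario,
                                     channels = scenario$channels,
                                     models = NULL, lmax = 5,
                                     fine_tune = TRUE,
                                     seed = scenario$seed) {
  if (is.null(models)) models <- fit_scenario_models(scenario, lmax)
  harm <- harmonic_excitations(models, scenario)

  plan <- lapply(harm, function(h) list(currents = h$currents))
  for (j in seq_along(models$usable)) {
    cur <- numeric(length(scenario$coils))
    cur[models$usable[j]] <- scenario$b_max / models$max_field_per_amp[j]
    plan[[length(plan) + 1L]] <- list(currents = cur)
  }
  series <- simulate_responses(scenario, plan, channels = channels,
                               seed = seed)
  amps <- vapply(series, function(v)
    lockin_amplitude(v, scenario$f0, scenario$fs)$in_phase,
    numeric(length(channels)))

  nh <- length(harm)
  hmodels <- lapply(harm, `[[`, "model")
  hdeg <- vapply(harm, `[[`, integer(1), "l")
  # individual responses correspond to unit "current scale" of the
  # per-unit-current models: rescale to response per ampere of each coil
  icur <- vapply((nh + 1):length(plan), function(j)
    sum(plan[[j]]$currents), numeric(1))

  cals <- vector("list", length(channels))
  for (c in seq_along(channels)) {
    y_ind <- amps[c, (nh + 1):length(plan)] / icur
    cals[[c]] <- calibrate_sensor(
      models$set, harmonic_models = hmodels,
      harmonic_responses = amps[c, seq_len(nh)],
      individual_responses = y_ind, harmonic_degrees = hdeg,
      fine_tune = fine_tune,
      channel_id = channels[[c]]$channel_id)
  }

  stage_names <- names(cals[[1L]]$stages)
  stage_errors <- lapply(stage_names, function(sn) {
    do.call(rbind, lapply(seq_along(channels), function(c)
      one_channel_errors(cals[[c]]$stages[[sn]]$params, channels[[c]])))
  })
  names(stage_errors) <- stage_names
  errors <- stage_errors$final

  structure(list(calibrations = cals, errors = errors,
                 stage_errors = stage_errors, models = models,
                 harmonics = harm, scenario = scenario, seed = seed),
            class = "calibration_run")
}

## Per-channel error triple against the true parameters
one_channel_errors <- function(est, truth) {
  data.frame(
    channel = if (is.null(truth$channel_id)) NA_character_
              else truth$channel_id,
    position_error_m = sqrt(sum((est$position - truth$position)^2)),
    orientation_error_deg = angle_deg(est$orientation, truth$orientation),
    gain_error_rel = abs(est$gain - truth$gain) / truth$gain,
    stringsAsFactors = FALSE)
}

#' @export
print.calibration_run <- function(x, ...) {
  e <- x$errors
  cat(sprintf("Calibration run: %d channels (seed %d)\n", nrow(e), x$seed))
  cat(sprintf("  RMS position error    : %.3f mm\n",
              1e3 * sqrt(mean(e$position_error_m^2))))
  cat(sprintf("  RMS orientation error : %.3f deg\n",
              sqrt(mean(e$orientation_error_deg^2))))
  cat(sprintf("  RMS gain error        : %.3f %%\n",
              100 * sqrt(mean(e$gain_error_rel^2))))
  invisible(x)
}

#' RMS error summary of one or more calibration runs
#'
#' @param runs a \code{calibration_run} or list of them (e.g. over noise
#'   seeds).
#' @return named vector: RMS position error (mm), RMS orientation error
#'   (deg), RMS gain error (percent), pooled over all channels and runs.
#' @export
rms_calibration_errors <- function(runs) {
  if (inherits(runs, "calibration_run")) runs <- list(runs)
  e <- do.call(rbind, lapply(runs, `[[`, "errors"))
  c(position_mm = 1e3 * sqrt(mean(e$position_error_m^2)),
    orientation_deg = sqrt(mean(e$orientation_error_deg^2)),
    gain_pct = 100 * sqrt(mean(e$gain_error_rel^2)))
}

#' End-to-end synthetic phantom localization run
#'
#' Calibrates the synthetic 48-channel OPM array in joint dual-axis mode
#' (the two tangential channels of each OPM share one position), then
#' localizes the phantom's nine magnetic dipoles: amplitudes are
#' forward-simulated through the TRUE sensor parameters (plus lock-in
#' noise), channels are screened with the correlation mask, and dipoles are
#' fitted with the CALIBRATED parameters by grid search plus refinement.
#'
#' @param seed integer seed for the scenario, array and noise.
#' @param scenario optional precomputed OPM-mode scenario.
#' @param array optional precomputed \code{\link{default_opm_array}}.
#' @param models optional precomputed \code{\link{fit_scenario_models}}.
#' @param grid_spec dipole search box, see \code{\link{fit_dipole}}.
#' @return object of class \code{phantom_run}: \code{dipole_errors} (m),
#'   \code{fits}, \code{calibration_errors}, \code{cad_comparison}
#'   (Umeyama-aligned distances of calibrated vs true positions),
#'   \code{sensors_est}.
#' @export
run_phantom_pipeline <- function(seed = 1, scenario = NULL, array = NULL,
                                 models = NULL,
                                 grid_spec = list(
                                   lower = c(-0.06, -0.06, 0),
                                   upper = c(0.06, 0.06, 0.06),
                                   spacing = 0.005)) {
  if (is.null(scenario)) scenario <- default_shield_scenario(seed, "opm")
  if (is.null(array)) array <- default_opm_array(seed)
  if (is.null(models)) models <- fit_scenario_models(scenario)
  harm <- harmonic_excitations(models, scenario)

  true_x <- array$bx_channels
  true_y <- array$by_channels
  all_true <- c(true_x, true_y)

  plan <- lapply(harm, function(h) list(currents = h$currents))
  for (j in seq_along(models$usable)) {
    cur <- numeric(length(scenario$coils))
    cur[models$usable[j]] <- scenario$b_max / models$max_field_per_amp[j]
    plan[[length(plan) + 1L]] <- list(currents = cur)
  }
  series <- simulate_responses(scenario, plan, channels = all_true,
                               seed = seed)
  amps <- vapply(series, function(v)
    lockin_amplitude(v, scenario$f0, scenario$fs)$in_phase,
    numeric(length(all_true)))
  nh <- length(harm)
  hmodels <- lapply(harm, `[[`, "model")
  hdeg <- vapply(harm, `[[`, integer(1), "l")
  icur <- vapply((nh + 1):length(plan), function(j)
    sum(plan[[j]]$currents), numeric(1))

  n_pairs <- length(true_x)
  est <- vector("list", 2L * n_pairs)
  for (p in seq_len(n_pairs)) {
    init <- lapply(c(p, n_pairs + p), function(c) {
      hom <- which(hdeg == 1L)
      grd <- which(hdeg == 2L)
      H <- t(vapply(hmodels[hom], uniform_part, numeric(3)))
      lin <- linear_gain_orientation(H, amps[c, hom])
      Gt <- lapply(hmodels[grd], gradient_part)
      HG <- t(vapply(hmodels[grd], uniform_part, numeric(3)))
      r <- linear_position(Gt, HG, amps[c, grd], lin$gvec)
      params_from_gvec(lin$gvec, r + models$set$origin,
                       all_true[[c]]$channel_id)
    })
    jt <- refine_sensor_joint(init[[1L]], init[[2L]], models$set,
                              amps[p, (nh + 1):length(plan)] / icur,
                              amps[n_pairs + p,
                                   (nh + 1):length(plan)] / icur)
    est[[p]] <- jt$x
    est[[n_pairs + p]] <- jt$y
  }

  cal_err <- do.call(rbind, lapply(seq_along(all_true), function(c)
    one_channel_errors(est[[c]], all_true[[c]])))

  pos_est <- t(vapply(est, function(s) s$position, numeric(3)))
  pos_true <- t(vapply(all_true, function(s) s$position, numeric(3)))
  um <- umeyama_rigid(pos_est, pos_true)
  cad <- position_errors(um$transform(pos_est), pos_true)

  # phantom localization through the calibrated array
  fs <- scenario$fs
  f0 <- scenario$f0
  n <- round(scenario$duration * fs)
  tt <- (0:(n - 1L)) / fs
  carrier <- sin(2 * pi * f0 * tt)
  gains <- vapply(all_true, function(s) s$gain, numeric(1))
  fits <- vector("list", length(array$dipoles))
  derr <- numeric(length(array$dipoles))
  with_seed(seed + 1L, {
    for (d in seq_along(array$dipoles)) {
      dip <- array$dipoles[[d]]
      amp_true <- forward_amplitudes(dip, all_true)
      v <- outer(amp_true, carrier) +
        matrix(stats::rnorm(length(amp_true) * n,
                            sd = gains * scenario$noise_density *
                              sqrt(fs / 2)), length(amp_true), n)
      mask <- correlation_mask(v, carrier, threshold = 0.9, f0 = f0,
                               fs = fs)
      y <- lockin_amplitude(v, f0, fs)$in_phase
      fits[[d]] <- fit_dipole(y, est, mask = mask, grid_spec = grid_spec)
      derr[d] <- sqrt(sum((fits[[d]]$dipole$position - dip$position)^2))
    }
  })

  structure(list(dipole_errors = derr, fits = fits,
                 calibration_errors = cal_err, cad_comparison = cad,
                 sensors_est = est, array = array, scenario = scenario,
                 seed = seed),
            class = "phantom_run")
}

#' @export
print.phantom_run <- function(x, ...) {
  cat(sprintf("Phantom run (seed %d): %d dipoles\n", x$seed,
              length(x$dipole_errors)))
  cat(sprintf("  average dipole position error : %.2f mm (range %.2f-%.2f)\n",
              1e3 * mean(x$dipole_errors), 1e3 * min(x$dipole_errors),
              1e3 * max(x$dipole_errors)))
  cat(sprintf("  array vs truth (aligned)      : mean %.2f mm\n",
              1e3 * x$cad_comparison$mean))
  invisible(x)
}
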