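# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

# Default fluxgate scenario with its fitted coil models (mapping is
# noiseless, so the models are reusable across noise seeds).
cached_shield <- function() {
  if (is.null(.fixtures$shield)) {
    sc <- default_shield_scenario(seed = 42, mode = "fluxgate")
    .fixtures$shield <- list(scenario = sc,
                             models = fit_scenario_models(sc))
  }
  .fixtures$shield
}

# A square test coil 0.6 m from a 0.2 m sampling region, with a fixed
# generic point cloud inside the region.
square_loop_fixture <- function() {
  if (is.null(.fixtures$square)) {
    coil <- rectangular_coil(center = c(0.6, 0, 0), u = c(0, 1, 0),
                             v = c(0, 0, 1), width = 0.5, height = 0.5,
                             coil_id = "sq")
    pts <- with_fixed_rng(7, matrix(runif(108 * 3, -0.1, 0.1), 108, 3))
    B <- biot_savart_field(coil, 1, pts)
    .fixtures$square <- list(coil = coil, points = pts,
                             meas = field_measurements(pts, B, current = 1,
                                                       coil_id = "sq"))
  }
  .fixtures$square
}

# Deterministic RNG scope for fixtures/tests
with_fixed_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_unit_seeded <- function(seed) with_fixed_rng(seed, random_unit())

angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca))) * 180 / pi
}

perturb_params <- function(p, dpos = 3e-3, dgain = 0.03) {
  sensor_parameters(p$gain * (1 + dgain), p$position + dpos * c(1, -1, 1),
                    p$orientation + c(0.03, 0.02, -0.01), p$channel_id)
}

# Coil model set whose fields are exactly degree <= 2: three mostly-uniform
# and five mostly-gradient excitation models with random coefficients.
degree2_excitations <- function(seed = 11) {
  with_fixed_rng(seed, {
    models <- list()
    degrees <- c(1, 1, 1, 2, 2, 2, 2, 2)
    for (k in seq_along(degrees)) {
      co <- numeric(8)
      if (degrees[k] == 1) {
        co[1:3] <- rnorm(3, sd = 1e-8)
      } else {
        co[4:8] <- rnorm(5, sd = 1e-8)
      }
      models[[k]] <- vsh_model(co, lmax = 2, origin = c(0, 0, 0),
                               coil_id = sprintf("exc%d", k))
    }
    list(models = models, degrees = degrees,
         set = coil_model_set(models))
  })
}

# Noiseless responses of a sensor to a list of vsh models (the sensor
# forward model: gain * B(r) . n)
responses_of <- function(models, params) {
  vapply(models, function(m)
    params$gain * sum(predict(m, matrix(params$position, 1)) *
                        params$orientation), numeric(1))
}
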