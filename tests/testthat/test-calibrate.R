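# Linear and nonlinear estimation of sensor gain, orientation, position.

test_that("orthogonal uniform fields recover gain and orientation exactly", {
  g_true <- 1.3e5
  n_true <- c(0.6, -0.48, 0.64)
  n_true <- n_true / sqrt(sum(n_true^2))
  B0 <- 1e-8
  H <- B0 * diag(3)
  bH <- g_true * as.numeric(H %*% n_true)
  lin <- linear_gain_orientation(H, bH)
  expect_equal(lin$gain, g_true)
  expect_equal(lin$orientation, n_true)
  # random well-conditioned uniform set, synthesized responses
  H2 <- with_fixed_rng(41, matrix(rnorm(15, sd = 1e-8), 5, 3))
  bH2 <- as.numeric(H2 %*% (g_true * n_true))
  lin2 <- linear_gain_orientation(H2, bH2)
  expect_equal(lin2$gvec, g_true * n_true, tolerance = 1e-10)
  # two collinear fields cannot resolve the orientation
  expect_error(linear_gain_orientation(rbind(c(1, 0, 0), c(2, 0, 0),
                                             c(3, 0, 0)) * 1e-8,
                                       c(1, 2, 3)),
               "rank")
})

test_that("gradient responses place the sensor; degenerate sets fail", {
  gvec <- 1e5 * c(0.2, -0.4, 0.89)
  r_true <- c(0.013, -0.021, 0.04)
  Gt <- with_fixed_rng(42, lapply(1:5, function(i) {
    A <- matrix(rnorm(9), 3)
    S <- (A + t(A)) / 2
    (S - diag(3) * sum(diag(S)) / 3) * 1e-8
  }))
  HG <- with_fixed_rng(43, matrix(rnorm(15, sd = 1e-9), 5, 3))
  bG <- vapply(1:5, function(i)
    sum(gvec * (HG[i, ] + Gt[[i]] %*% r_true)), numeric(1))
  expect_equal(linear_position(Gt, HG, bG, gvec), r_true,
               tolerance = 1e-10)
  # sensor at the origin of pure-gradient fields
  b0 <- as.numeric(HG %*% gvec)
  expect_equal(linear_position(Gt, HG, b0, gvec), c(0, 0, 0),
               tolerance = 1e-10)
  # only diagonal gradients: transverse gradient missing, rank error
  Gd <- list(diag(c(1, -0.5, -0.5)) * 1e-8, diag(c(-0.5, 1, -0.5)) * 1e-8,
             diag(c(-0.5, -0.5, 1)) * 1e-8)
  bGd <- vapply(Gd, function(G) sum(gvec * (G %*% r_true)), numeric(1))
  expect_error(linear_position(Gd, matrix(0, 3, 3), bGd, gvec),
               "transverse")
})

test_that("the SSE objective matches brute-force accumulation", {
  d2 <- degree2_excitations()
  truth <- sensor_parameters(1e5, c(0.01, 0.02, -0.01), c(0, 0.6, 0.8),
                             "toy")
  y <- responses_of(d2$models, truth)
  expect_equal(sse_objective(truth, d2$set, y), 0, tolerance = 1e-30)
  # 3-coil toy with wrong parameters: term-by-term hand sum
  off <- sensor_parameters(1.1e5, c(0.012, 0.02, -0.01), c(0, 0.55, 0.83))
  models3 <- d2$models[1:3]
  set3 <- coil_model_set(models3)
  y3 <- y[1:3]
  hand <- 0
  for (i in 1:3) {
    pred <- off$gain * sum(predict(models3[[i]],
                                   rbind(off$position)) * off$orientation)
    hand <- hand + (y3[i] - pred)^2
  }
  expect_equal(sse_objective(off, set3, y3), hand, tolerance = 1e-12)
  # moving 1 mm off the noiseless optimum strictly increases the objective
  shifted <- sensor_parameters(truth$gain, truth$position + c(1e-3, 0, 0),
                               truth$orientation)
  expect_gt(sse_objective(shifted, d2$set, y), 0)
})

test_that("with exact degree-2 fields the linear stage alone is exact", {
  d2 <- degree2_excitations()
  truth <- sensor_parameters(0.9e5, c(-0.015, 0.025, 0.03),
                             random_unit_seeded(44), "exact")
  y <- responses_of(d2$models, truth)
  cal <- calibrate_sensor(d2$set, harmonic_models = d2$models,
                          harmonic_responses = y,
                          individual_responses = y,
                          harmonic_degrees = d2$degrees,
                          fine_tune = FALSE)
  lin <- cal$stages$linear$params
  expect_equal(lin$gain, truth$gain, tolerance = 1e-9)
  expect_equal(lin$position, truth$position, tolerance = 1e-9)
  expect_equal(lin$orientation, truth$orientation, tolerance = 1e-9)
})

test_that("refinement never worsens the objective and fixes a perturbed start", {
  d2 <- degree2_excitations()
  truth <- sensor_parameters(1e5, c(0.01, -0.01, 0.02),
                             random_unit_seeded(45))
  y <- responses_of(d2$models, truth)
  # starting at the truth with noiseless data stays at zero
  r0 <- refine_sensor(truth, d2$set, y)
  expect_equal(attr(r0, "sse"), 0, tolerance = 1e-25)
  expect_equal(r0$position, truth$position, tolerance = 1e-8)
  # perturbed start converges back
  start <- sensor_parameters(1.05e5, truth$position + c(3e-3, -2e-3, 1e-3),
                             truth$orientation + c(0.05, 0, 0))
  r1 <- refine_sensor(start, d2$set, y)
  expect_lte(attr(r1, "sse"), sse_objective(start, d2$set, y))
  expect_equal(r1$position, truth$position, tolerance = 1e-5)
  expect_equal(r1$gain, truth$gain, tolerance = 1e-5)
})

test_that("joint dual-axis refinement shares one exact position", {
  d2 <- degree2_excitations()
  pos <- c(0.005, 0.015, -0.02)
  tx <- sensor_parameters(1e9, pos, c(1, 0.05, 0), "x")
  ty <- sensor_parameters(1.04e9, pos, c(-0.03, 1, 0.02), "y")
  yx <- responses_of(d2$models, tx)
  yy <- responses_of(d2$models, ty)
  sx <- sensor_parameters(tx$gain * 1.02, pos + c(2e-3, 0, -1e-3),
                          tx$orientation)
  sy <- sensor_parameters(ty$gain * 0.97, pos + c(-1e-3, 1e-3, 0),
                          ty$orientation)
  jt <- refine_sensor_joint(sx, sy, d2$set, yx, yy)
  expect_identical(jt$x$position, jt$y$position)   # shared by construction
  expect_equal(jt$x$position, pos, tolerance = 1e-6)
  expect_equal(jt$x$gain, tx$gain, tolerance = 1e-6)
  expect_equal(jt$y$orientation, ty$orientation, tolerance = 1e-6)
})

test_that("full pipeline is exact on noiseless synthetic data, stagewise", {
  sh <- cached_shield()
  set <- sh$models$set
  truth <- sensor_parameters(1e5, c(0.02, -0.03, 0.04),
                             random_unit_seeded(46), "noiseless")
  harm <- harmonic_excitations(sh$models, sh$scenario)
  hmodels <- lapply(harm, `[[`, "model")
  yh <- responses_of(hmodels, truth)
  yi <- responses_of(set$models, truth)
  cal <- calibrate_sensor(set, harmonic_models = hmodels,
                          harmonic_responses = yh,
                          individual_responses = yi,
                          harmonic_degrees = vapply(harm, `[[`,
                                                    integer(1), "l"))
  sses <- vapply(cal$stages, `[[`, numeric(1), "sse")
  expect_true(all(diff(sses) <= 1e-12 * (sses[1] + 1e-300)))
  expect_equal(cal$estimate$position, truth$position, tolerance = 1e-7)
  expect_equal(cal$estimate$gain, truth$gain, tolerance = 1e-7)
  expect_lt(angle_between(cal$estimate$orientation, truth$orientation),
            1e-5)
})

test_that("estimates are invariant to basis normalization and coil order", {
  sh <- cached_shield()
  sc <- sh$scenario
  truth <- sensor_parameters(1e5, c(0.01, 0.02, 0.03),
                             random_unit_seeded(47))
  # refit all coil models on a different reference sphere (rescales every
  # basis component): estimates must not move
  cal_for <- function(models) {
    harm <- harmonic_excitations(models, sc)
    hmodels <- lapply(harm, `[[`, "model")
    calibrate_sensor(models$set, harmonic_models = hmodels,
                     harmonic_responses = responses_of(hmodels, truth),
                     individual_responses = responses_of(models$set$models,
                                                         truth),
                     harmonic_degrees = vapply(harm, `[[`, integer(1),
                                               "l"),
                     fine_tune = FALSE)$estimate
  }
  a <- cal_for(sh$models)
  models_b <- fit_scenario_models(sc, R0 = 0.05)
  b <- cal_for(models_b)
  expect_equal(a$gain, b$gain, tolerance = 1e-8)
  expect_equal(a$position, b$position, tolerance = 1e-8)
  expect_equal(a$orientation, b$orientation, tolerance = 1e-8)
  # permuting the coil order leaves the estimate unchanged
  perm <- rev(seq_along(sh$models$set))
  set_p <- coil_model_set(sh$models$set$models[perm])
  yi <- responses_of(sh$models$set$models, truth)
  r1 <- refine_sensor(perturb_params(truth), sh$models$set, yi)
  r2 <- refine_sensor(perturb_params(truth), set_p, yi[perm])
  expect_equal(r1$position, r2$position, tolerance = 1e-8)
  expect_equal(r1$gain, r2$gain, tolerance = 1e-8)
})

test_that("missing harmonic responses fall back to a user init", {
  d2 <- degree2_excitations()
  truth <- sensor_parameters(1e5, c(0.01, 0, 0.01), c(0, 1, 0))
  y <- responses_of(d2$models, truth)
  init <- sensor_parameters(0.95e5, c(0.013, 0.001, 0.012), c(0.05, 1, 0))
  cal <- calibrate_sensor(d2$set, individual_responses = y, init = init)
  expect_equal(cal$estimate$position, truth$position, tolerance = 1e-5)
  expect_error(calibrate_sensor(d2$set, individual_responses = y),
               "init")
})
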