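# Biot-Savart ground truth, synthetic scenarios, lock-in detection.

test_that("segment Biot-Savart matches loop closed forms", {
  mu0 <- 4e-7 * pi
  # square loop, side a: |B| at the center = 2 sqrt(2) mu0 I / (pi a)
  a <- 0.4; I <- 2
  sq <- rectangular_coil(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), a, a)
  Bc <- biot_savart_field(sq, I, rbind(c(0, 0, 1e-6)))
  expect_equal(sqrt(sum(Bc^2)), 2 * sqrt(2) * mu0 * I / (pi * a),
               tolerance = 1e-6)
  # circular loop radius R: |B| at the center = mu0 I / (2 R)
  R <- 0.3
  ci <- circular_coil(c(0, 0, 0), c(0, 0, 1), R, n_segments = 128)
  Bc2 <- biot_savart_field(ci, I, rbind(c(0, 0, 1e-6)))
  expect_equal(sqrt(sum(Bc2^2)), mu0 * I / (2 * R), tolerance = 1e-4)
  # far field converges to the dipole of moment I * area * normal
  far <- with_fixed_rng(61, {
    d <- matrix(rnorm(15), 5); 8 * d / sqrt(rowSums(d^2))
  })
  Bf <- biot_savart_field(ci, I, far)
  Bd <- dipole_field(dipole_source(c(0, 0, 0), c(0, 0, I * pi * R^2)), far)
  expect_lt(max(sqrt(rowSums((Bf - Bd)^2)) / sqrt(rowSums(Bd^2))), 0.01)
  # turns multiply the field
  ci2 <- circular_coil(c(0, 0, 0), c(0, 0, 1), R, n_segments = 128,
                       turns = 3)
  expect_equal(biot_savart_field(ci2, I, far), 3 * Bf)
  expect_error(biot_savart_field(sq, I, rbind(c(a / 2, 0, 0))), "segment")
})

test_that("the default shield scenario reproduces the mapping design", {
  sc <- default_shield_scenario(seed = 3)
  expect_length(sc$coils, 18L)
  expect_length(sc$usable, 17L)                 # one broken connector
  expect_equal(nrow(sc$mapping_points), 108L)   # 324 scalar measurements
  expect_length(sc$channels, 18L)               # 6 triads x 3 channels
  # triad channels are spaced 2 cm along the probe axis and orthogonal
  p <- t(vapply(sc$channels[1:3], function(s) s$position, numeric(3)))
  expect_equal(sqrt(sum((p[2, ] - p[1, ])^2)), 0.02, tolerance = 1e-12)
  o <- t(vapply(sc$channels[1:3], function(s) s$orientation, numeric(3)))
  expect_equal(o %*% t(o), diag(3), tolerance = 1e-10)
  # determinism: identical scenario from the same seed
  sc2 <- default_shield_scenario(seed = 3)
  expect_identical(sc, sc2)
  expect_false(identical(sc$channels,
                         default_shield_scenario(seed = 4)$channels))
  # the design matrix of the mapping has 324 rows and full rank at lmax 5
  S <- vsh_design_matrix(sc$mapping_points, 5,
                         colMeans(sc$mapping_points))
  expect_equal(nrow(S), 324L)
  expect_equal(qr(S)$rank, 35L)
})

test_that("fitted shield-coil spectra are dominated by low degrees", {
  sh <- cached_shield()
  for (k in c(1, 9, 17)) {
    sp <- vsh_spectrum(sh$models$set$models[[k]])
    dt <- tapply(sp$beta_sq, sp$l, sum)
    expect_gt(dt[["1"]] + dt[["2"]], 0.9 * sum(dt))
  }
})

test_that("the OPM array has 48 channels at 24 shared positions", {
  arr <- default_opm_array(seed = 6)
  expect_length(arr$bx_channels, 24L)
  expect_length(arr$by_channels, 24L)
  px <- t(vapply(arr$bx_channels, function(s) s$position, numeric(3)))
  py <- t(vapply(arr$by_channels, function(s) s$position, numeric(3)))
  expect_identical(px, py)                      # paired tangential axes
  expect_equal(nrow(unique(round(px, 10))), 24L)
  for (s in c(arr$bx_channels, arr$by_channels))
    expect_equal(sum(s$orientation^2), 1, tolerance = 1e-12)
  expect_length(arr$dipoles, 9L)
  # dipole standoff 3-6 cm from the nearest channel
  for (d in arr$dipoles) {
    dist <- min(sqrt(rowSums(sweep(px, 2, d$position)^2)))
    expect_gt(dist, 0.025)
    expect_lt(dist, 0.075)
    expect_equal(sqrt(sum(d$moment^2)), 1.4e-7, tolerance = 1e-12)
  }
  # field-referred forward amplitudes: tens to hundreds of pT across the
  # 3-6 cm standoffs (nominal 1 V/nT gain)
  amps <- vapply(arr$dipoles, function(d)
    max(abs(forward_amplitudes(d, c(arr$bx_channels, arr$by_channels)))) /
      1e9, numeric(1))
  expect_true(all(amps > 30e-12 & amps < 3000e-12))
  expect_identical(arr, default_opm_array(seed = 6))
})

test_that("simulated responses are sinusoids with calibrated noise", {
  sc <- default_shield_scenario(seed = 7)
  plan <- list(list(currents = c(1e-3, numeric(17))))
  # zero noise: an exact sinusoid with the predicted amplitude
  ser0 <- simulate_responses(sc, plan, channels = sc$channels[1:2],
                             noise_density = 0)
  v <- ser0[[1]]
  ch <- sc$channels[[1]]
  B <- biot_savart_field(sc$coils[[1]], 1e-3, rbind(ch$position))
  amp <- ch$gain * sum(B * ch$orientation)
  tt <- (0:(ncol(v) - 1)) / sc$fs
  expect_equal(v[1, ], amp * sin(2 * pi * sc$f0 * tt), tolerance = 1e-12)
  # same seed, same series
  s1 <- simulate_responses(sc, plan, channels = sc$channels[1:2], seed = 9)
  s2 <- simulate_responses(sc, plan, channels = sc$channels[1:2], seed = 9)
  expect_identical(s1, s2)
  # noise-only variance matches density^2 * fs / 2 (field-referred)
  plan_long <- list(list(currents = numeric(18), duration = 100))
  sn <- simulate_responses(sc, plan_long, channels = sc$channels[1])
  v_field <- sn[[1]][1, ] / sc$channels[[1]]$gain
  expect_equal(var(v_field), sc$noise_density^2 * sc$fs / 2,
               tolerance = 0.05)
})

test_that("lock-in detection recovers sinusoid amplitudes", {
  fs <- 1000; f0 <- 20
  tt <- (0:(fs - 1)) / fs
  A <- 3.7e-4
  la <- lockin_amplitude(A * sin(2 * pi * f0 * tt), f0, fs)
  expect_equal(la$in_phase, A, tolerance = 1e-12)
  expect_equal(la$amplitude, A, tolerance = 1e-12)
  # DC offsets do not leak into the amplitude
  la2 <- lockin_amplitude(A * sin(2 * pi * f0 * tt) + 0.5, f0, fs)
  expect_equal(la2$in_phase, A, tolerance = 1e-10)
  # negative (anti-phase) amplitudes keep their sign
  la3 <- lockin_amplitude(-A * sin(2 * pi * f0 * tt), f0, fs)
  expect_equal(la3$in_phase, -A, tolerance = 1e-12)
  expect_error(lockin_amplitude(rnorm(100), 20, 30), "fs")
  # white-noise amplitude error has sd ~ sigma sqrt(2/N)
  sigma <- 1e-3
  n <- length(tt)
  errs <- with_fixed_rng(62, vapply(1:300, function(i)
    lockin_amplitude(rnorm(n, sd = sigma), f0, fs)$in_phase, numeric(1)))
  expect_equal(sd(errs), sigma * sqrt(2 / n), tolerance = 0.15)
})
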