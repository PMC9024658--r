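#' Coil geometry as closed polyline loops
#'
#' @param loops list of K x 3 vertex matrices (m); each polyline must be
#'   closed (first vertex equals last) with at least 3 distinct vertices.
#' @param turns integer number of turns (multiplies the field).
#' @param coil_id label.
#' @return object of class \code{coil_geometry}.
#' @export
coil_geometry <- function(loops, turns = 1L, coil_id = "coil") {
  if (is.matrix(loops)) loops <- list(loops)
  loops <- lapply(loops, as_points, name = "loop")
  for (lp in loops) {
    if (nrow(lp) < 4L || max(abs(lp[1L, ] - lp[nrow(lp), ])) > 1e-12)
      stop("each loop must be closed (first = last vertex, >= 3 distinct vertices)",
           call. = FALSE)
  }
  structure(list(coil_id = coil_id, loops = loops,
                 turns = as.integer(turns)),
            class = "coil_geometry")
}

#' Planar rectangular coil
#'
#' @param center 3-vector (m).
#' @param u,v orthogonal in-plane unit vectors (width / height directions).
#' @param width,height side lengths (m).
#' @param turns,coil_id see \code{\link{coil_geometry}}.
#' @return a \code{coil_geometry} with one 5-vertex closed loop.
#' @export
rectangular_coil <- function(center, u, v, width, height, turns = 1L,
                             coil_id = "rect") {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  hw <- width / 2
  hh <- height / 2
  verts <- rbind(center + hw * u + hh * v, center - hw * u + hh * v,
                 center - hw * u - hh * v, center + hw * u - hh * v,
                 center + hw * u + hh * v)
  coil_geometry(verts, turns, coil_id)
}

#' Circular coil approximated by a regular polygon
#'
#' @param center 3-vector (m).
#' @param normal coil axis direction.
#' @param radius loop radius (m).
#' @param n_segments polygon order (default 64).
#' @param turns,coil_id see \code{\link{coil_geometry}}.
#' @return a \code{coil_geometry}.
#' @export
circular_coil <- function(center, normal, radius, n_segments = 64L,
                          turns = 1L, coil_id = "circ") {
  normal <- normal / sqrt(sum(normal^2))
  a <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- a - sum(a * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = n_segments + 1L)
  # polygon inscribed so that the enclosed area matches the circle's
  r_eff <- radius * sqrt(2 * pi / (n_segments * sin(2 * pi / n_segments)))
  verts <- sweep(r_eff * (outer(cos(th), e1) + outer(sin(th), e2)),
                 2L, center, FUN = "+")
  coil_geometry(verts, turns, coil_id)
}

#' Biot-Savart field of a polyline coil
#'
#' Exact analytic field of each straight finite segment, summed over all
#' segments and turns:
#' \code{B = mu0 I/(4 pi) (|r1| + |r2|) (r1 x r2) /
#' (|r1||r2| (|r1||r2| + r1 . r2))} for a segment with end-point vectors
#' r1, r2 from the field point.
#'
#' @param coil a \code{\link{coil_geometry}}.
#' @param current applied current (A).
#' @param points M x 3 field points (m); none may lie within \code{eps} of
#'   any segment.
#' @param eps minimum point-to-segment distance (m), default 1 mm.
#' @return M x 3 matrix of field vectors (T).
#' @export
biot_savart_field <- function(coil, current, points, eps = 1e-3) {
  stopifnot(inherits(coil, "coil_geometry"))
  points <- as_points(points)
  M <- nrow(points)
  B <- matrix(0, M, 3L)
  for (lp in coil$loops) {
    for (s in seq_len(nrow(lp) - 1L)) {
      a <- lp[s, ]
      b <- lp[s + 1L, ]
      r1 <- sweep(points, 2L, a)
      r2 <- sweep(points, 2L, b)
      n1 <- row_norms(r1)
      n2 <- row_norms(r2)
      # point-to-segment distance check
      L <- b - a
      L2 <- sum(L^2)
      t0 <- pmin(1, pmax(0, (r1 %*% L) / L2))
      dseg <- row_norms(r1 - outer(as.numeric(t0), L))
      if (any(dseg < eps))
        stop(sprintf("field point within %g m of a coil segment", eps),
             call. = FALSE)
      cr <- cbind(r1[, 2] * r2[, 3] - r1[, 3] * r2[, 2],
                  r1[, 3] * r2[, 1] - r1[, 1] * r2[, 3],
                  r1[, 1] * r2[, 2] - r1[, 2] * r2[, 1])
      dot <- rowSums(r1 * r2)
      denom <- n1 * n2 * (n1 * n2 + dot)
      B <- B + cr * ((n1 + n2) / denom)
    }
  }
  B * (MU0 * current * coil$turns / (4 * pi))
}

## Field at `points` of all scenario coils driven with `currents` (A)
scenario_field <- function(coils, currents, points, eps = 1e-3) {
  B <- matrix(0, nrow(points), 3L)
  for (k in seq_along(coils)) {
    if (currents[k] != 0)
      B <- B + biot_savart_field(coils[[k]], currents[k], points, eps)
  }
  B
}

## Orthonormal frame with third axis along `axis` and a roll angle
frame_about <- function(axis, roll = 0) {
  w <- axis / sqrt(sum(axis^2))
  a <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- a - sum(a * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  u2 <- cos(roll) * u + sin(roll) * v
  v2 <- -sin(roll) * u + cos(roll) * v
  rbind(u2, v2, w)
}

#' Default synthetic shield-coil scenario
#'
#' A person-sized cylindrical coil form carrying 16 rectangular coils (two
#' rings of eight, 0.5 m tall, on a 0.45 m radius form) and 2 circular end
#' coils (0.40 m radius), surrounding a helmet-sized sensor region.  One
#' rectangular coil is marked broken (17 usable).  The field-mapping design
#' is a 6 x 6 x 3 grid of 108 triaxial positions (324 scalar measurements)
#' covering the sensor region.  Six triaxial fluxgate placements (18
#' single-axis channels, 2 cm channel spacing along the probe axis, nominal
#' gain 0.1 V/uT with 0.1 percent scatter) are drawn inside the region with
#' seed-dependent jitter.
#'
#' @param seed integer seed controlling placement jitter and downstream
#'   noise; fixed seed gives byte-identical scenarios.
#' @param mode \code{"fluxgate"} (12.5 nT max excitation field, amplitude
#'   SNR 1900) or \code{"opm"} (0.5 nT, SNR 1e4).
#' @return list of class \code{shield_scenario}: \code{coils},
#'   \code{usable} (indices), \code{mapping_points},
#'   \code{mapping_current}, \code{channels} (18 true
#'   \code{\link{sensor_parameters}}), \code{b_max}, \code{snr},
#'   \code{noise_density} (T/sqrt(Hz)), \code{f0}, \code{fs},
#'   \code{duration}, \code{seed}.
#' @export
default_shield_scenario <- function(seed = 1, mode = c("fluxgate", "opm")) {
  mode <- match.arg(mode)
  Rform <- 0.45
  coils <- list()
  k <- 0L
  for (ring_z in c(-0.28, 0.28)) {
    for (j in 0:7) {
      k <- k + 1L
      phi <- 2 * pi * j / 8 + (ring_z > 0) * pi / 8
      c0 <- c(Rform * cos(phi), Rform * sin(phi), ring_z)
      u <- c(-sin(phi), cos(phi), 0)
      coils[[k]] <- rectangular_coil(c0, u, c(0, 0, 1), 0.45, 0.5,
                                     coil_id = sprintf("rect%02d", k))
    }
  }
  coils[[17L]] <- circular_coil(c(0, 0, -0.65), c(0, 0, 1), 0.40,
                                coil_id = "circ_bottom")
  coils[[18L]] <- circular_coil(c(0, 0, 0.65), c(0, 0, 1), 0.40,
                                coil_id = "circ_top")
  broken <- 7L
  usable <- setdiff(seq_len(18L), broken)

  g <- expand.grid(x = seq(-0.10, 0.10, length.out = 6),
                   y = seq(-0.10, 0.10, length.out = 6),
                   z = seq(-0.05, 0.11, length.out = 3))
  mapping <- as.matrix(g)

  channels <- with_seed(seed, {
    chans <- list()
    base_dirs <- rbind(c(0, 0, 1), c(1, 1, 1), c(-1, 1, 1),
                       c(1, -1, 1), c(-1, -1, 1), c(0, 1, -1))
    for (p in 1:6) {
      centre <- c(0.04 * cos(2 * pi * p / 6), 0.04 * sin(2 * pi * p / 6),
                  0.03) + stats::runif(3, -0.015, 0.015)
      ax <- base_dirs[p, ] + stats::rnorm(3, sd = 0.2)
      Fr <- frame_about(ax, roll = stats::runif(1, 0, 2 * pi))
      for (ch in 1:3) {
        pos <- centre + (ch - 2) * 0.02 * Fr[3, ]
        gain <- 1e5 * (1 + stats::runif(1, -1e-3, 1e-3))
        chans[[length(chans) + 1L]] <-
          sensor_parameters(gain, pos, Fr[ch, ],
                            channel_id = sprintf("fg%02d_%d", p, ch))
      }
    }
    chans
  })

  b_max <- if (mode == "fluxgate") 12.5e-9 else 0.5e-9
  snr <- if (mode == "fluxgate") 1900 else 1e4
  duration <- 1
  structure(
    list(coils = coils, usable = usable, broken = broken,
         mapping_points = mapping, mapping_current = 0.0133,
         channels = channels, mode = mode, b_max = b_max, snr = snr,
         noise_density = b_max * sqrt(duration) / snr,
         f0 = 20, fs = 1000, duration = duration, seed = seed),
    class = "shield_scenario"
  )
}

#' Default synthetic 48-channel OPM array with phantom dipoles
#'
#' Six 4-channel sensors (24 channel positions on a 0.09 m helmet-like
#' spherical cap, 2 x 2 channel grids with 1.8 cm pitch) measuring two
#' tangential components each: 48 channels.  Gains scatter 5 percent about
#' 1 V/nT; the two tangential orientations are perturbed by a configurable
#' angle scatter (default 2 degrees), so they are not exactly orthogonal.
#' Nine phantom dipoles (|m| = 140 nAm^2, near-tangential moments) sit 3-6
#' cm below the array.
#'
#' @param seed integer seed; fixed seed gives identical arrays.
#' @param ori_scatter_deg orientation perturbation scatter (degrees).
#' @return list with \code{bx_channels}, \code{by_channels} (24 true
#'   \code{\link{sensor_parameters}} each, matched by index),
#'   \code{dipoles} (9 \code{\link{dipole_source}}), \code{seed}.
#' @export
default_opm_array <- function(seed = 1, ori_scatter_deg = 2) {
  with_seed(seed, {
    Rcap <- 0.09
    dirs <- rbind(
      cbind(sin(pi / 10) * cos(2 * pi * (0:2) / 3),
            sin(pi / 10) * sin(2 * pi * (0:2) / 3), cos(pi / 10)),
      cbind(sin(2 * pi / 9) * cos(2 * pi * (0:2) / 3 + pi / 3),
            sin(2 * pi / 9) * sin(2 * pi * (0:2) / 3 + pi / 3),
            cos(2 * pi / 9)))
    bx <- list()
    by <- list()
    sca <- ori_scatter_deg * pi / 180
    for (s in 1:6) {
      w <- dirs[s, ]
      Fr <- frame_about(w, roll = stats::runif(1, 0, 2 * pi))
      centre <- Rcap * w
      for (cx in c(-1, 1)) for (cy in c(-1, 1)) {
        pos <- centre + 0.009 * cx * Fr[1, ] + 0.009 * cy * Fr[2, ] +
          stats::rnorm(3, sd = 5e-4)
        ox <- Fr[1, ] + stats::rnorm(3, sd = sca)
        oy <- Fr[2, ] + stats::rnorm(3, sd = sca)
        id <- sprintf("opm%d_%d%d", s, (cx + 1) / 2, (cy + 1) / 2)
        bx[[length(bx) + 1L]] <- sensor_parameters(
          1e9 * (1 + stats::runif(1, -0.05, 0.05)), pos, ox,
          channel_id = paste0(id, "_x"))
        by[[length(by) + 1L]] <- sensor_parameters(
          1e9 * (1 + stats::runif(1, -0.05, 0.05)), pos, oy,
          channel_id = paste0(id, "_y"))
      }
    }
    dip <- list()
    radii <- rep(c(0.030, 0.045, 0.060), each = 3L)
    for (d in 1:9) {
      th <- stats::runif(1, 0, pi / 3)
      ph <- 2 * pi * d / 9 + stats::runif(1, -0.2, 0.2)
      w <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      Fr <- frame_about(w, roll = stats::runif(1, 0, 2 * pi))
      mdir <- Fr[1, ] + stats::rnorm(3, sd = 0.15)
      mdir <- mdir / sqrt(sum(mdir^2))
      dip[[d]] <- dipole_source(radii[d] * w, 1.4e-7 * mdir)
    }
    list(bx_channels = bx, by_channels = by, dipoles = dip, seed = seed)
  })
}

#' Simulate lock-in-ready sensor time series
#'
#' Each excitation block drives the scenario coils with a current vector
#' modulated by a sinusoid at the excitation frequency; every channel
#' records \code{v(t) = gain (B(t) . n) + noise}, with white Gaussian noise
#' of the scenario's field-referred density (per-sample variance
#' \code{density^2 fs / 2}, scaled by the gain).
#'
#' @param scenario a \code{\link{default_shield_scenario}} result.
#' @param plan list of blocks, each a list with \code{currents} (length
#'   18 A-vector over the scenario coils) and optional \code{duration} (s).
#' @param channels list of \code{\link{sensor_parameters}}; default the
#'   scenario's fluxgate channels.
#' @param seed RNG seed for the noise (default the scenario seed).
#' @param noise_density field-referred noise density (T/sqrt(Hz)); default
#'   the scenario's.
#' @return list of blocks, each an n_channels x n_samples matrix (V), with
#'   attribute \code{reference} (the unit excitation waveform).
#' @export
simulate_responses <- function(scenario, plan,
                               channels = scenario$channels,
                               seed = scenario$seed,
                               noise_density = scenario$noise_density) {
  stopifnot(inherits(scenario, "shield_scenario"))
  pos <- t(vapply(channels, function(s) s$position, numeric(3)))
  ori <- t(vapply(channels, function(s) s$orientation, numeric(3)))
  gains <- vapply(channels, function(s) s$gain, numeric(1))
  fs <- scenario$fs
  f0 <- scenario$f0
  with_seed(seed, {
    lapply(plan, function(block) {
      stopifnot(length(block$currents) == length(scenario$coils))
      dur <- if (is.null(block$duration)) scenario$duration
             else block$duration
      n <- round(dur * fs)
      tt <- (0:(n - 1L)) / fs
      carrier <- sin(2 * pi * f0 * tt)
      B <- scenario_field(scenario$coils, block$currents, pos)
      amp <- gains * rowSums(B * ori)               # V at unit carrier
      sd_t <- gains * noise_density * sqrt(fs / 2)
      v <- outer(amp, carrier) +
        matrix(stats::rnorm(length(amp) * n, sd = sd_t),
               length(amp), n)
      attr(v, "reference") <- carrier
      v
    })
  })
}

#' Lock-in amplitude extraction
#'
#' Demodulates a series at the reference frequency over an integer number of
#' periods (enforced by truncation): \code{z = 2/N sum v(t) exp(-i 2 pi f0
#' t)}.  For \code{v = A sin(2 pi f0 t)} the in-phase component equals A
#' exactly; a DC offset does not affect the result.
#'
#' @param series numeric vector, or matrix with one series per row.
#' @param f0 reference frequency (Hz).
#' @param fs sampling rate (Hz); must exceed \code{2 f0}.
#' @param duration optional analysis length (s), truncated to whole periods.
#' @return list with \code{amplitude} (magnitude, V), \code{in_phase}
#'   (signed amplitude relative to the sine reference), \code{quadrature},
#'   \code{phase} (rad).
#' @export
lockin_amplitude <- function(series, f0, fs, duration = NULL) {
  if (fs <= 2 * f0)
    stop("'fs' must exceed twice the reference frequency", call. = FALSE)
  if (is.vector(series)) series <- matrix(series, nrow = 1L)
  n_avail <- ncol(series)
  n_req <- if (is.null(duration)) n_avail else min(n_avail,
                                                   round(duration * fs))
  per <- fs / f0
  n <- floor(n_req / per) * per
  if (n < per) stop("series shorter than one reference period",
                    call. = FALSE)
  n <- round(n)
  tt <- (0:(n - 1L)) / fs
  e <- exp(-1i * 2 * pi * f0 * tt)
  z <- 2 / n * (series[, seq_len(n), drop = FALSE] %*% e)
  z <- as.complex(z)
  # v = A sin(wt) -> z = -iA: in-phase (sine) component is -Im(z)
  list(amplitude = Mod(z), in_phase = -Im(z), quadrature = Re(z),
       phase = Arg(z))
}
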