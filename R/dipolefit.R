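#' Magnetic point-dipole source
#'
#' @param position 3-vector (m).
#' @param moment 3-vector magnetic moment (A m^2).
#' @return object of class \code{dipole_source}.
#' @export
dipole_source <- function(position, moment) {
  stopifnot(length(position) == 3L, all(is.finite(position)),
            length(moment) == 3L, all(is.finite(moment)))
  structure(list(position = as.numeric(position),
                 moment = as.numeric(moment)),
            class = "dipole_source")
}

#' @export
print.dipole_source <- function(x, ...) {
  cat(sprintf("Magnetic dipole at (%.1f, %.1f, %.1f) mm, |m| = %.3g nAm^2\n",
              1e3 * x$position[1], 1e3 * x$position[2], 1e3 * x$position[3],
              1e9 * sqrt(sum(x$moment^2))))
  invisible(x)
}

## mu0/(4 pi d^3) (3 rhat rhat' - I): lead matrix mapping moment -> field at
## each point; points relative to the dipole position.  M x 3 x 3 as a list.
dipole_lead <- function(position, points, eps = 1e-3) {
  rel <- sweep(points, 2L, position)
  d <- row_norms(rel)
  if (any(d < eps))
    stop(sprintf("point within %g m of the dipole position", eps),
         call. = FALSE)
  list(rel = rel, d = d)
}

#' Field of a magnetic point dipole
#'
#' Free-space point-dipole formula
#' \code{B = mu0/(4 pi) (3 (m . rhat) rhat - m) / d^3}.
#'
#' @param dipole a \code{\link{dipole_source}}.
#' @param points M x 3 field points (m); none may lie within \code{eps} of
#'   the dipole.
#' @param eps singularity guard distance (m), default 1 mm.
#' @return M x 3 matrix of field vectors (T).
#' @export
dipole_field <- function(dipole, points, eps = 1e-3) {
  stopifnot(inherits(dipole, "dipole_source"))
  points <- as_points(points)
  ld <- dipole_lead(dipole$position, points, eps)
  rhat <- ld$rel / ld$d
  mdotr <- as.numeric(rhat %*% dipole$moment)
  k <- MU0 / (4 * pi * ld$d^3)
  k * (3 * mdotr * rhat -
         matrix(dipole$moment, nrow(points), 3L, byrow = TRUE))
}

#' Channel amplitudes of a dipole through calibrated sensors
#'
#' \code{amplitude_c = gain_c * B(r_c) . n_c} for each channel.
#'
#' @param dipole a \code{\link{dipole_source}}.
#' @param sensors list of \code{\link{sensor_parameters}}.
#' @param eps singularity guard distance (m).
#' @return numeric vector of amplitudes (V), one per channel.
#' @export
forward_amplitudes <- function(dipole, sensors, eps = 1e-3) {
  pos <- t(vapply(sensors, function(s) s$position, numeric(3)))
  B <- dipole_field(dipole, pos, eps)
  ori <- t(vapply(sensors, function(s) s$orientation, numeric(3)))
  gains <- vapply(sensors, function(s) s$gain, numeric(1))
  gains * rowSums(B * ori)
}

## Amplitudes are linear in the moment: N x 3 matrix L with amp = L %*% m
moment_lead_matrix <- function(position, sensors, eps = 1e-3) {
  pos <- t(vapply(sensors, function(s) s$position, numeric(3)))
  ld <- dipole_lead(position, pos, eps)
  rhat <- ld$rel / ld$d
  k <- MU0 / (4 * pi * ld$d^3)
  ori <- t(vapply(sensors, function(s) s$orientation, numeric(3)))
  gains <- vapply(sensors, function(s) s$gain, numeric(1))
  ndotr <- rowSums(ori * rhat)
  # row c: gain_c * k_c * (3 (n_c . rhat_c) rhat_c - n_c)
  (gains * k) * (3 * ndotr * rhat - ori)
}

#' Latency-adjusted correlation channel mask
#'
#' Per channel, the maximum normalized correlation with the reference
#' waveform over integer-sample lags within plus/minus one reference period;
#' channels below \code{threshold} are rejected (as unreliable, e.g. due to
#' phase offsets).
#'
#' @param channel_series M x T matrix (channels in rows) or numeric vector.
#' @param reference length-T reference time series (e.g. the excitation
#'   current waveform).
#' @param threshold correlation threshold (default 0.9).
#' @param f0,fs reference frequency and sampling rate (Hz); the lag window
#'   is one period, \code{fs/f0} samples.
#' @return logical mask (TRUE = keep), with attribute \code{correlation}.
#' @export
correlation_mask <- function(channel_series, reference, threshold = 0.9,
                             f0 = 20, fs = 1000) {
  if (is.vector(channel_series))
    channel_series <- matrix(channel_series, nrow = 1L)
  Tn <- ncol(channel_series)
  stopifnot(length(reference) == Tn)
  if (stats::sd(reference) == 0)
    stop("reference has zero variance", call. = FALSE)
  P <- max(1L, round(fs / f0))
  lags <- -P:P
  cors <- apply(channel_series, 1L, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    best <- -Inf
    for (k in lags) {
      if (k >= 0) {
        a <- x[(1L + k):Tn]
        b <- reference[1L:(Tn - k)]
      } else {
        a <- x[1L:(Tn + k)]
        b <- reference[(1L - k):Tn]
      }
      best <- max(best, abs(stats::cor(a, b)))
    }
    best
  })
  mask <- !is.na(cors) & cors >= threshold
  if (any(is.na(cors)))
    warning(sprintf("%d zero-variance channel(s) rejected", sum(is.na(cors))),
            call. = FALSE)
  attr(mask, "correlation") <- cors
  mask
}

#' Localize a magnetic dipole from channel amplitudes
#'
#' Two-stage fit: (1) grid search over candidate positions in a bounding
#' box, solving the moment linearly at each node (amplitudes are linear in
#' the moment) and scoring the residual; (2) derivative-free (Nelder-Mead)
#' refinement of the position from the best node, with the moment re-solved
#' linearly at every evaluation (separable least squares).  Residual ties in
#' the grid stage are broken by the first index.
#'
#' @param amplitudes per-channel amplitudes (V).
#' @param sensors list of \code{\link{sensor_parameters}} (all channels).
#' @param mask optional logical keep-mask (e.g. from
#'   \code{\link{correlation_mask}}); at least 6 channels must survive.
#' @param grid_spec list with \code{lower}, \code{upper} (3-vectors, m) and
#'   \code{spacing} (m, default 0.005) defining the search box.
#' @param eps singularity guard distance (m).
#' @param reltol,maxit refinement optimizer settings.
#' @return list with \code{dipole} (a \code{\link{dipole_source}}),
#'   \code{residual} (relative residual norm), \code{grid_residual},
#'   \code{n_channels}.
#' @export
fit_dipole <- function(amplitudes, sensors, mask = NULL,
                       grid_spec = list(lower = c(-0.06, -0.06, 0),
                                        upper = c(0.06, 0.06, 0.06),
                                        spacing = 0.005),
                       eps = 1e-3, reltol = 1e-10, maxit = 2000) {
  amplitudes <- as.numeric(amplitudes)
  stopifnot(length(amplitudes) == length(sensors))
  if (is.null(mask)) mask <- rep(TRUE, length(amplitudes))
  y <- amplitudes[mask]
  sens <- sensors[mask]
  if (length(y) < 6L)
    stop("at least 6 unmasked channels are needed to fit 6 dipole parameters",
         call. = FALSE)
  ynorm2 <- sum(y^2)
  if (ynorm2 == 0) stop("all amplitudes are zero", call. = FALSE)

  # precomputed channel geometry for the (hot) per-node moment solve
  spos_f <- t(vapply(sens, function(s) s$position, numeric(3)))
  ori_f <- t(vapply(sens, function(s) s$orientation, numeric(3)))
  gk <- vapply(sens, function(s) s$gain, numeric(1)) * MU0 / (4 * pi)

  solve_at <- function(pos) {
    rel <- spos_f - matrix(pos, nrow(spos_f), 3L, byrow = TRUE)
    d <- sqrt(rowSums(rel^2))
    if (any(d < eps)) return(list(res2 = Inf, m = c(0, 0, 0)))
    rhat <- rel / d
    L <- (gk / d^3) * (3 * rowSums(ori_f * rhat) * rhat - ori_f)
    m <- tryCatch(qr.solve(L, y), error = function(e) NULL)
    if (is.null(m)) return(list(res2 = Inf, m = c(0, 0, 0)))
    list(res2 = sum((y - as.numeric(L %*% m))^2), m = m)
  }

  sp <- if (is.null(grid_spec$spacing)) 0.005 else grid_spec$spacing
  gx <- seq(grid_spec$lower[1], grid_spec$upper[1], by = sp)
  gy <- seq(grid_spec$lower[2], grid_spec$upper[2], by = sp)
  gz <- seq(grid_spec$lower[3], grid_spec$upper[3], by = sp)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))

  best_i <- 0L
  best_res2 <- Inf
  for (i in seq_len(nrow(grid))) {
    s <- solve_at(grid[i, ])
    if (s$res2 < best_res2) {          # strict: first minimum wins ties
      best_res2 <- s$res2
      best_i <- i
    }
  }
  if (best_i == 0L)
    stop("no admissible grid node (all within the singularity guard)",
         call. = FALSE)
  p0 <- grid[best_i, ]

  fn <- function(p) {
    v <- solve_at(p)$res2
    if (is.finite(v)) v else ynorm2 * 1e6
  }
  op <- stats::optim(p0, fn, method = "Nelder-Mead",
                     control = list(reltol = reltol, maxit = maxit,
                                    parscale = rep(sp, 3L)))
  pos <- if (op$value <= best_res2) op$par else p0
  fin <- solve_at(pos)
  list(dipole = dipole_source(pos, fin$m),
       residual = sqrt(fin$res2 / ynorm2),
       grid_residual = sqrt(best_res2 / ynorm2),
       n_channels = length(y))
}
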