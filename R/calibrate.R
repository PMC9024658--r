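#' Sensor parameters: gain, position, orientation
#'
#' @param gain sensor gain (V/T), positive.
#' @param position 3-vector (m), in the frame of the coil models.
#' @param orientation 3-vector; normalized to unit length (must be nonzero).
#' @param channel_id optional label.
#' @return object of class \code{sensor_parameters}.
#' @export
sensor_parameters <- function(gain, position, orientation,
                              channel_id = NULL) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain), gain > 0,
            length(position) == 3L, all(is.finite(position)),
            length(orientation) == 3L, all(is.finite(orientation)))
  nn <- sqrt(sum(orientation^2))
  if (nn == 0) stop("'orientation' must be nonzero", call. = FALSE)
  structure(
    list(gain = as.numeric(gain), position = as.numeric(position),
         orientation = as.numeric(orientation) / nn,
         channel_id = channel_id),
    class = "sensor_parameters"
  )
}

#' @export
print.sensor_parameters <- function(x, ...) {
  cat(sprintf("Sensor%s: gain %.6g V/T\n",
              if (!is.null(x$channel_id)) paste0(" [", x$channel_id, "]")
              else "", x$gain))
  cat(sprintf("  position    : (%.2f, %.2f, %.2f) mm\n",
              1e3 * x$position[1], 1e3 * x$position[2], 1e3 * x$position[3]))
  cat(sprintf("  orientation : (%.4f, %.4f, %.4f)\n",
              x$orientation[1], x$orientation[2], x$orientation[3]))
  invisible(x)
}

## gain * orientation <-> parameter conversions
gvec_of <- function(params) params$gain * params$orientation

params_from_gvec <- function(gvec, position, channel_id = NULL) {
  sensor_parameters(sqrt(sum(gvec^2)), position, gvec, channel_id)
}

#' Linear gain and orientation estimate from homogeneous-field responses
#'
#' Solves \code{gvec = pinv(H) \%*\% bH}, where row i of H is the uniform
#' field of the i-th homogeneous excitation and bH are the sensor response
#' amplitudes.  The gain is the norm of the solution and the orientation its
#' direction: uniform fields encode gain and orientation but carry no
#' position information.
#'
#' @param H N_H x 3 matrix of uniform field vectors (T).
#' @param bH length N_H response amplitudes (V).
#' @param rtol pseudo-inverse relative cutoff.
#' @return list with \code{gvec} (V/T 3-vector), \code{gain},
#'   \code{orientation}.
#' @export
linear_gain_orientation <- function(H, bH, rtol = 1e-10) {
  H <- as.matrix(H)
  if (ncol(H) != 3L) stop("'H' must have 3 columns", call. = FALSE)
  if (nrow(H) < 3L)
    stop("at least 3 homogeneous-field responses are required",
         call. = FALSE)
  if (length(bH) != nrow(H))
    stop("'bH' must have one entry per row of 'H'", call. = FALSE)
  ps <- pinv_svd(H, rtol)
  if (ps$rank < 3L)
    stop(sprintf(
      "uniform-field matrix has rank %d < 3: orientation unresolvable (fields collinear/coplanar)",
      ps$rank), call. = FALSE)
  gvec <- as.numeric(ps$pinv %*% bH)
  list(gvec = gvec, gain = sqrt(sum(gvec^2)),
       orientation = gvec / sqrt(sum(gvec^2)))
}

#' Linear position estimate from gradient-field responses
#'
#' First-order model of the i-th gradient excitation:
#' \code{b_i = gvec . (u_i + G_i (r - origin))}, with u_i its uniform part
#' and G_i its gradient tensor at the expansion origin.  Stacking rows
#' \code{t(gvec) \%*\% G_i} into a matrix G gives the linear system
#' \code{r = pinv(G) \%*\% (bG - HG \%*\% gvec)} for the position relative
#' to the origin.
#'
#' @param gradient_tensors list of 3 x 3 gradient tensors (T/m).
#' @param HG N_G x 3 matrix of the excitations' uniform parts (T).
#' @param bG length N_G response amplitudes (V).
#' @param gvec gain-times-orientation vector from
#'   \code{\link{linear_gain_orientation}}.
#' @param rtol pseudo-inverse relative cutoff.
#' @return position 3-vector (m) relative to the expansion origin.
#' @export
linear_position <- function(gradient_tensors, HG, bG, gvec, rtol = 1e-10) {
  stopifnot(is.list(gradient_tensors))
  NG <- length(gradient_tensors)
  if (NG < 3L)
    stop("at least 3 gradient-field responses are required", call. = FALSE)
  HG <- as.matrix(HG)
  stopifnot(nrow(HG) == NG, ncol(HG) == 3L, length(bG) == NG,
            length(gvec) == 3L)
  G <- t(vapply(gradient_tensors, function(Gi) as.numeric(gvec %*% Gi),
                numeric(3)))
  ps <- pinv_svd(G, rtol)
  if (ps$rank < 3L)
    stop(sprintf(
      "gradient matrix has rank %d < 3: position unresolvable (e.g. only diagonal gradients available; a transverse gradient is needed)",
      ps$rank), call. = FALSE)
  as.numeric(ps$pinv %*% (bG - as.numeric(HG %*% gvec)))
}

## Fields of all coils in `set` at one position: 3 x N matrix (T/A)
model_amplitudes <- function(set, position) {
  tab <- vsh_basis_tables(set$lmax, set$R0)
  rel <- matrix(position - set$origin, 1L)
  F <- eval_basis_fields(rel, tab)
  rbind(F$Bx %*% set$B, F$By %*% set$B, F$Bz %*% set$B)
}

#' Sum-of-squared-errors calibration objective
#'
#' \code{sum_i (y_i - gain * B_i(r) . n)^2} over the coil models, the
#' quantity minimized by the nonlinear refinement stages.
#'
#' @param params a \code{\link{sensor_parameters}} object.
#' @param models a \code{\link{coil_model_set}}.
#' @param responses numeric vector of response amplitudes (V), one per coil
#'   model (column of the set).
#' @return scalar SSE (V^2).
#' @export
sse_objective <- function(params, models, responses) {
  stopifnot(inherits(params, "sensor_parameters"),
            inherits(models, "coil_model_set"))
  responses <- as.numeric(responses)
  if (length(responses) != ncol(models$B))
    stop("one response per coil model is required", call. = FALSE)
  pred <- as.numeric(gvec_of(params) %*% model_amplitudes(models,
                                                          params$position))
  sum((responses - pred)^2)
}

## Shared Nelder-Mead driver: minimizes fn over x0 with restarts until the
## relative improvement stalls.  Returns list(x, value, convergence).
nm_minimize <- function(fn, x0, parscale, reltol = 1e-10, maxit = 5000,
                        restarts = 2L) {
  best <- list(par = x0, value = fn(x0), convergence = 0L)
  for (k in seq_len(restarts + 1L)) {
    op <- stats::optim(best$par, fn, method = "Nelder-Mead",
                       control = list(reltol = reltol, maxit = maxit,
                                      parscale = parscale))
    improved <- op$value < best$value
    stalled <- best$value - op$value <= reltol * (abs(best$value) + reltol)
    if (improved) best <- op
    if (stalled) break
  }
  best
}

#' Nonlinear refinement of sensor parameters
#'
#' Derivative-free (Nelder-Mead simplex) minimization of the SSE objective
#' over the 6-vector (gvec, position); gain and orientation are extracted
#' from gvec afterwards, which avoids an explicit unit-norm constraint.
#' Never returns parameters worse than the initial ones.
#'
#' @param init initial \code{\link{sensor_parameters}} (e.g. from the linear
#'   stage).
#' @param models a \code{\link{coil_model_set}} of the excitation fields.
#' @param responses response amplitudes (V), one per model.
#' @param reltol relative objective convergence tolerance.
#' @param maxit maximum simplex iterations per start.
#' @param restarts number of simplex restarts from the incumbent.
#' @return refined \code{sensor_parameters} with attributes \code{sse} and
#'   \code{convergence} (0 = converged, 1 = iteration limit).
#' @export
refine_sensor <- function(init, models, responses, reltol = 1e-10,
                          maxit = 5000, restarts = 2L) {
  stopifnot(inherits(init, "sensor_parameters"))
  responses <- as.numeric(responses)
  g0 <- gvec_of(init)
  fn <- function(x) {
    pred <- as.numeric(x[1:3] %*% model_amplitudes(models, x[4:6]))
    sum((responses - pred)^2)
  }
  parscale <- c(rep(0.05 * sqrt(sum(g0^2)), 3L), rep(0.005, 3L))
  op <- nm_minimize(fn, c(g0, init$position), parscale, reltol, maxit,
                    restarts)
  out <- params_from_gvec(op$par[1:3], op$par[4:6], init$channel_id)
  vr <- models$validity_radius
  if (is.finite(vr) &&
      sqrt(sum((out$position - models$origin)^2)) > vr)
    warning("refined position lies outside the coil-model validity sphere",
            call. = FALSE)
  attr(out, "sse") <- op$value
  attr(out, "convergence") <- op$convergence
  out
}

#' Joint dual-axis refinement sharing one position
#'
#' Refines two channels measuring different field components at the same
#' physical location (e.g. the two tangential OPM axes) by minimizing the
#' summed SSE over the 9-vector (position, gvec_x, gvec_y); the returned
#' pair shares the position exactly.
#'
#' @param init_x,init_y initial \code{\link{sensor_parameters}} per channel.
#' @param models a \code{\link{coil_model_set}}.
#' @param responses_x,responses_y response amplitudes (V) per channel.
#' @param reltol,maxit,restarts as in \code{\link{refine_sensor}}.
#' @return list of two \code{sensor_parameters} (\code{x}, \code{y}) with
#'   identical positions, plus attribute \code{sse}.
#' @export
refine_sensor_joint <- function(init_x, init_y, models, responses_x,
                                responses_y, reltol = 1e-10, maxit = 5000,
                                restarts = 2L) {
  stopifnot(inherits(init_x, "sensor_parameters"),
            inherits(init_y, "sensor_parameters"))
  responses_x <- as.numeric(responses_x)
  responses_y <- as.numeric(responses_y)
  gx0 <- gvec_of(init_x)
  gy0 <- gvec_of(init_y)
  r0 <- (init_x$position + init_y$position) / 2
  fn <- function(x) {
    A <- model_amplitudes(models, x[1:3])
    sum((responses_x - as.numeric(x[4:6] %*% A))^2) +
      sum((responses_y - as.numeric(x[7:9] %*% A))^2)
  }
  parscale <- c(rep(0.005, 3L), rep(0.05 * sqrt(sum(gx0^2)), 3L),
                rep(0.05 * sqrt(sum(gy0^2)), 3L))
  op <- nm_minimize(fn, c(r0, gx0, gy0), parscale, reltol, maxit, restarts)
  out <- list(
    x = params_from_gvec(op$par[4:6], op$par[1:3], init_x$channel_id),
    y = params_from_gvec(op$par[7:9], op$par[1:3], init_y$channel_id)
  )
  attr(out, "sse") <- op$value
  attr(out, "convergence") <- op$convergence
  out
}

## Classify harmonic excitations by dominant degree of their VSH energy
dominant_degree <- function(model) {
  sp <- vsh_spectrum(model)
  agg <- tapply(sp$beta_sq, sp$l, sum)
  as.integer(names(agg)[which.max(agg)])
}

#' Full sensor calibration pipeline
#'
#' Runs the staged estimation of one channel's gain, position and
#' orientation: (1) linear initialization from the responses to the
#' (approximately) homogeneous and first-order-gradient excitations, using
#' uniform/gradient parts extracted from their fitted VSH models; (2)
#' optional fine-tune by SSE minimization against the full VSH models of
#' those same excitations; (3) final SSE minimization against the
#' individual-coil responses and full models.
#'
#' @param models \code{\link{coil_model_set}} of the N individual coils.
#' @param harmonic_models list of \code{vsh_model}s of the superposed
#'   excitations (the fields actually produced by the synthesized currents).
#' @param harmonic_responses response amplitudes (V) to those excitations.
#' @param individual_responses response amplitudes (V) to the N individual
#'   coils.
#' @param harmonic_degrees optional integer vector (1 = homogeneous, 2 =
#'   gradient) classifying the excitations; by default each is classified by
#'   the dominant degree of its VSH energy.
#' @param fine_tune run stage 2 (default TRUE).
#' @param init optional \code{sensor_parameters} used instead of the linear
#'   stage when harmonic responses are missing.
#' @param channel_id label for the result.
#' @param reltol,maxit,restarts optimizer settings, see
#'   \code{\link{refine_sensor}}.
#' @return object of class \code{sensor_calibration}: element
#'   \code{estimate} (final \code{sensor_parameters}) and \code{stages}, a
#'   list of per-stage parameters with the SSE against the individual-coil
#'   responses evaluated at each stage.
#' @export
calibrate_sensor <- function(models, harmonic_models = NULL,
                             harmonic_responses = NULL,
                             individual_responses, harmonic_degrees = NULL,
                             fine_tune = TRUE, init = NULL,
                             channel_id = NULL, reltol = 1e-10,
                             maxit = 5000, restarts = 2L) {
  stopifnot(inherits(models, "coil_model_set"))
  individual_responses <- as.numeric(individual_responses)
  stages <- list()
  common_sse <- function(p) sse_objective(p, models, individual_responses)

  if (!is.null(harmonic_models) && !is.null(harmonic_responses)) {
    stopifnot(length(harmonic_models) == length(harmonic_responses))
    if (is.null(harmonic_degrees))
      harmonic_degrees <- vapply(harmonic_models, dominant_degree,
                                 integer(1))
    hom <- which(harmonic_degrees == 1L)
    grd <- which(harmonic_degrees == 2L)
    H <- t(vapply(harmonic_models[hom], uniform_part, numeric(3)))
    lin <- linear_gain_orientation(H, harmonic_responses[hom])
    Gt <- lapply(harmonic_models[grd], gradient_part)
    HG <- t(vapply(harmonic_models[grd], uniform_part, numeric(3)))
    r_rel <- linear_position(Gt, HG, harmonic_responses[grd], lin$gvec)
    p0 <- params_from_gvec(lin$gvec, r_rel + models$origin, channel_id)
    stages$linear <- list(params = p0, sse = common_sse(p0))

    if (fine_tune) {
      hset <- coil_model_set(harmonic_models)
      p1 <- refine_sensor(p0, hset, harmonic_responses, reltol, maxit,
                          restarts)
      stages$fine_tune <- list(params = p1, sse = common_sse(p1),
                               stage_sse = attr(p1, "sse"))
      p0 <- p1
    }
  } else if (!is.null(init)) {
    stopifnot(inherits(init, "sensor_parameters"))
    p0 <- init
    stages$user_init <- list(params = p0, sse = common_sse(p0))
  } else {
    stop("either harmonic responses or an explicit 'init' must be supplied",
         call. = FALSE)
  }

  pf <- refine_sensor(p0, models, individual_responses, reltol, maxit,
                      restarts)
  stages$final <- list(params = pf, sse = common_sse(pf),
                       stage_sse = attr(pf, "sse"))

  structure(list(estimate = pf, stages = stages, channel_id = channel_id),
            class = "sensor_calibration")
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf("Sensor calibration%s (%d stage(s)):\n",
              if (!is.null(x$channel_id)) paste0(" [", x$channel_id, "]")
              else "", length(x$stages)))
  for (nm in names(x$stages))
    cat(sprintf("  %-10s SSE = %.6g V^2\n", nm, x$stages[[nm]]$sse))
  print(x$estimate)
  invisible(x)
}

#' @export
coef.sensor_calibration <- function(object, ...) {
  p <- object$estimate
  c(gain = p$gain, x = p$position[1], y = p$position[2], z = p$position[3],
    nx = p$orientation[1], ny = p$orientation[2], nz = p$orientation[3])
}

#' @export
summary.sensor_calibration <- function(object, ...) {
  s <- data.frame(
    stage = names(object$stages),
    gain = vapply(object$stages, function(s) s$params$gain, numeric(1)),
    sse = vapply(object$stages, function(s) s$sse, numeric(1)),
    row.names = NULL
  )
  structure(list(table = s, estimate = object$estimate),
            class = "summary.sensor_calibration")
}

#' @export
print.summary.sensor_calibration <- function(x, ...) {
  print(x$table)
  print(x$estimate)
  invisible(x)
}
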