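#' Coil field measurement set
#'
#' Container for the discrete field samples of one coil: positions, field
#' values (triaxial vectors, or single-axis projections with their unit
#' measurement directions), and the applied current.  Fields are stored per
#' unit current (T/A) on ingestion so models scale linearly between the
#' fluxgate (~10 nT) and OPM (<1 nT) excitation regimes.
#'
#' @param positions M x 3 matrix (m).
#' @param values M x 3 field vectors, or length-M scalars (T) when
#'   \code{projections} is given.
#' @param current applied current amplitude (A); values are divided by it.
#' @param coil_id label.
#' @param projections optional M x 3 unit measurement directions for
#'   single-axis data.
#' @return object of class \code{field_measurements}.
#' @export
field_measurements <- function(positions, values, current = 1,
                               coil_id = "coil", projections = NULL) {
  positions <- as_points(positions)
  if (!is.numeric(current) || length(current) != 1L || !is.finite(current) ||
      current == 0)
    stop("'current' must be a single nonzero number", call. = FALSE)
  if (is.null(projections)) {
    values <- as_points(values, "values")
    if (nrow(values) != nrow(positions))
      stop("'values' must have one row per position", call. = FALSE)
  } else {
    values <- as.numeric(values)
    if (length(values) != nrow(positions))
      stop("'values' must have one entry per position", call. = FALSE)
    if (!all(is.finite(values)))
      stop("'values' contains non-finite entries", call. = FALSE)
    projections <- as_points(projections, "projections")
    if (any(abs(row_norms(projections) - 1) > 1e-6))
      stop("'projections' rows must be unit-norm", call. = FALSE)
  }
  structure(
    list(coil_id = coil_id, positions = positions,
         values = values / current, projections = projections,
         current = current),
    class = "field_measurements"
  )
}

#' @export
print.field_measurements <- function(x, ...) {
  kind <- if (is.null(x$projections)) "triaxial" else "single-axis"
  cat(sprintf("Field measurements [%s]: %d %s points (%d scalar values)\n",
              x$coil_id, nrow(x$positions), kind,
              if (is.null(x$projections)) 3L * nrow(x$positions)
              else length(x$values)))
  invisible(x)
}

## Stack measurement values in the row order of the design matrix
stacked_values <- function(meas) {
  if (is.null(meas$projections)) as.numeric(t(meas$values)) else meas$values
}

#' Fit VSH coefficients to coil field measurements
#'
#' Least-squares fit of the interior VSH expansion to discrete field samples
#' via an SVD pseudo-inverse of the design matrix.  The default expansion
#' origin is the centroid of the measurement positions, which places the
#' zero crossings of the gradient components inside the sampled volume.
#'
#' @param meas a \code{\link{field_measurements}} object.
#' @param lmax maximum degree (default 5, i.e. 35 components).
#' @param origin expansion origin; \code{NULL} (default) uses the centroid
#'   of the measurement positions.
#' @param R0 reference-sphere radius of the basis normalization (m).
#' @param rtol relative singular-value cutoff of the pseudo-inverse.
#' @return a \code{vsh_fit} (inherits \code{vsh_model}) with elements
#'   \code{nrmse}, \code{rank}, \code{rank_deficient}, \code{fitted},
#'   \code{residuals}.
#' @export
fit_vsh <- function(meas, lmax = 5, origin = NULL, R0 = 0.1, rtol = 1e-10) {
  stopifnot(inherits(meas, "field_measurements"))
  if (is.null(origin)) origin <- colMeans(meas$positions)
  S <- vsh_design_matrix(meas$positions, lmax, origin,
                         projections = meas$projections, R0 = R0)
  y <- stacked_values(meas)
  C <- as.integer(lmax) * (as.integer(lmax) + 2L)
  if (nrow(S) < C)
    warning(sprintf("under-determined fit: %d rows for %d coefficients",
                    nrow(S), C), call. = FALSE)
  ps <- pinv_svd(S, rtol)
  if (ps$rank < C)
    warning(sprintf("rank-deficient design matrix: rank %d < %d",
                    ps$rank, C), call. = FALSE)
  beta <- as.numeric(ps$pinv %*% y)
  fitted <- as.numeric(S %*% beta)
  res <- y - fitted
  vr <- max(row_norms(sweep(meas$positions, 2L, origin)))
  out <- vsh_model(beta, lmax, origin, R0, validity_radius = vr,
                   coil_id = meas$coil_id)
  out$rank <- ps$rank
  out$rank_deficient <- ps$rank < C
  out$cond <- ps$cond
  out$fitted <- fitted
  out$residuals <- res
  out$nrmse <- sqrt(mean(res^2)) / sqrt(mean(y^2))
  class(out) <- c("vsh_fit", "vsh_model")
  out
}

#' @export
print.vsh_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  fit     : NRMSE %.3g%%, rank %d%s\n", 100 * x$nrmse, x$rank,
              if (x$rank_deficient) " (RANK-DEFICIENT)" else ""))
  invisible(x)
}

#' @export
residuals.vsh_fit <- function(object, ...) object$residuals

#' Normalized RMS error of a VSH model against measurements
#'
#' RMS of (prediction - measurement) over all scalar components, divided by
#' the RMS of the measurements.
#'
#' @param model a \code{vsh_model}.
#' @param meas a \code{\link{field_measurements}} object (values per unit
#'   current).
#' @return scalar NRMSE (dimensionless; multiply by 100 for percent).
#' @export
normalized_rms_error <- function(model, meas) {
  stopifnot(inherits(model, "vsh_model"),
            inherits(meas, "field_measurements"))
  y <- stacked_values(meas)
  if (all(y == 0)) stop("all-zero measurements: NRMSE undefined",
                        call. = FALSE)
  B <- predict(model, meas$positions)
  pred <- if (is.null(meas$projections)) as.numeric(t(B))
          else rowSums(B * meas$projections)
  sqrt(mean((pred - y)^2)) / sqrt(mean(y^2))
}

#' Bundle per-coil VSH models sharing one basis
#'
#' @param models list of \code{vsh_model} objects with identical origin,
#'   lmax, R0 and normalization.
#' @return object of class \code{coil_model_set} with the C x N coefficient
#'   matrix \code{B} (column per coil).
#' @export
coil_model_set <- function(models) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "vsh_model")))
  ref <- models[[1L]]
  for (m in models) {
    if (m$lmax != ref$lmax || m$R0 != ref$R0 ||
        max(abs(m$origin - ref$origin)) > 1e-12)
      stop("all models must share origin, lmax and normalization",
           call. = FALSE)
  }
  B <- vapply(models, function(m) m$coeffs, numeric(length(ref$coeffs)))
  ids <- vapply(seq_along(models), function(i) {
    id <- models[[i]]$coil_id
    if (is.null(id)) sprintf("coil%02d", i) else as.character(id)
  }, character(1))
  colnames(B) <- ids
  structure(
    list(models = models, B = B, lmax = ref$lmax, origin = ref$origin,
         R0 = ref$R0,
         validity_radius = suppressWarnings(
           min(Inf, unlist(lapply(models, function(m) m$validity_radius))))),
    class = "coil_model_set"
  )
}

#' @export
print.coil_model_set <- function(x, ...) {
  cat(sprintf("Coil model set: %d coils, lmax = %d (%d components), origin (%.3g, %.3g, %.3g) m\n",
              ncol(x$B), x$lmax, nrow(x$B),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
length.coil_model_set <- function(x) ncol(x$B)

#' Superpose coil models with given currents
#'
#' Linear combination of the per-coil fields: the returned model has
#' coefficients \code{B \%*\% currents} (coil fields are stored per unit
#' current).
#'
#' @param set a \code{\link{coil_model_set}}.
#' @param currents length-N current vector (A).
#' @return a \code{vsh_model} of the superposed field.
#' @export
superpose_models <- function(set, currents) {
  stopifnot(inherits(set, "coil_model_set"))
  currents <- as.numeric(currents)
  if (length(currents) != ncol(set$B))
    stop(sprintf("'currents' must have length %d", ncol(set$B)),
         call. = FALSE)
  vsh_model(as.numeric(set$B %*% currents), set$lmax, set$origin, set$R0,
            validity_radius = if (is.finite(set$validity_radius))
              set$validity_radius else NULL,
            coil_id = "superposition")
}
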