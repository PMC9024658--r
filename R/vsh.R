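#' Vector-spherical-harmonic design matrix
#'
#' Evaluates the interior VSH basis fields (gradients of real solid
#' harmonics) for degrees 1..\code{lmax} at a set of points, as a design
#' matrix suitable for least-squares coefficient fitting.  Degree 1 spans the
#' three homogeneous field components, degree 2 the five first-order
#' gradients; degrees 1..lmax span \code{lmax*(lmax+2)} components
#' (35 for lmax = 5).
#'
#' Column ordering is degree-major: l ascending, m = -l..l within each
#' degree.  With triaxial sampling the matrix has \code{3*M} rows ordered
#' point-major (rows 3i-2, 3i-1, 3i are the x, y, z components at point i);
#' with \code{projections} given it has \code{M} rows, row i being the basis
#' fields projected on the unit vector \code{projections[i, ]}.
#'
#' @param points M x 3 matrix of positions (m).
#' @param lmax maximum degree (>= 1).
#' @param origin 3-vector, expansion origin (m).
#' @param projections optional M x 3 matrix of unit measurement directions;
#'   if given, single-axis (projected) rows are produced.
#' @param R0 reference-sphere radius (m) of the unit-RMS basis normalization.
#' @return the design matrix, with attributes \code{lm} (C x 2 degree/order
#'   table), \code{lmax}, \code{origin}, \code{R0}.
#' @export
vsh_design_matrix <- function(points, lmax, origin = c(0, 0, 0),
                              projections = NULL, R0 = 0.1) {
  points <- as_points(points)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("'origin' must be a finite 3-vector", call. = FALSE)
  if (!is.numeric(lmax) || length(lmax) != 1L || lmax < 1)
    stop("'lmax' must be an integer >= 1", call. = FALSE)
  lmax <- as.integer(lmax)
  tab <- vsh_basis_tables(lmax, R0)
  rel <- sweep(points, 2L, origin)
  F <- eval_basis_fields(rel, tab)
  M <- nrow(points)
  if (is.null(projections)) {
    S <- matrix(0, 3L * M, tab$C)
    S[seq(1L, 3L * M, by = 3L), ] <- F$Bx
    S[seq(2L, 3L * M, by = 3L), ] <- F$By
    S[seq(3L, 3L * M, by = 3L), ] <- F$Bz
  } else {
    projections <- as_points(projections, "projections")
    if (nrow(projections) != M)
      stop("'projections' must have one row per point", call. = FALSE)
    if (any(abs(row_norms(projections) - 1) > 1e-6))
      stop("'projections' rows must be unit-norm", call. = FALSE)
    S <- projections[, 1] * F$Bx + projections[, 2] * F$By +
      projections[, 3] * F$Bz
  }
  structure(S, lm = tab$lm, lmax = lmax, origin = as.numeric(origin), R0 = R0)
}

#' Construct a VSH field model
#'
#' A \code{vsh_model} represents one continuous, source-free magnetic field
#' as a coefficient vector over the interior VSH basis (see
#' \code{\link{vsh_design_matrix}} for the basis conventions).
#'
#' @param coeffs length \code{lmax*(lmax+2)} coefficient vector (T per basis
#'   unit).
#' @param lmax maximum degree.
#' @param origin expansion origin (m).
#' @param R0 reference-sphere radius of the basis normalization (m).
#' @param validity_radius radius (m) within which the expansion is trusted;
#'   evaluation beyond it warns.  \code{NULL} disables the check.
#' @param coil_id optional label.
#' @return an object of class \code{vsh_model}.
#' @export
vsh_model <- function(coeffs, lmax, origin = c(0, 0, 0), R0 = 0.1,
                      validity_radius = NULL, coil_id = NULL) {
  lmax <- as.integer(lmax)
  C <- lmax * (lmax + 2L)
  coeffs <- as.numeric(coeffs)
  if (length(coeffs) != C)
    stop(sprintf("'coeffs' must have length %d for lmax = %d", C, lmax),
         call. = FALSE)
  structure(
    list(coeffs = coeffs, lmax = lmax, origin = as.numeric(origin), R0 = R0,
         normalization = sprintf("rms1@%gm", R0),
         validity_radius = validity_radius, coil_id = coil_id),
    class = "vsh_model"
  )
}

#' @export
coef.vsh_model <- function(object, ...) {
  tab <- vsh_basis_tables(object$lmax, object$R0)
  stats::setNames(object$coeffs,
                  sprintf("l%d,m%+d", tab$lm[, 1], tab$lm[, 2]))
}

#' @export
print.vsh_model <- function(x, ...) {
  cat(sprintf("VSH field model%s: lmax = %d (%d components)\n",
              if (!is.null(x$coil_id)) paste0(" [", x$coil_id, "]") else "",
              x$lmax, length(x$coeffs)))
  cat(sprintf("  origin  : (%.4g, %.4g, %.4g) m\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  basis   : unit-RMS on %g m sphere; ordering l asc, m = -l..l\n",
              x$R0))
  u <- uniform_part(x) * 1e9
  cat(sprintf("  uniform : (%.4g, %.4g, %.4g) nT\n", u[1], u[2], u[3]))
  invisible(x)
}

#' Evaluate a VSH field model
#'
#' @param object a \code{vsh_model}.
#' @param points M x 3 positions (m).
#' @param ... unused.
#' @return M x 3 matrix of field vectors (T).
#' @export
predict.vsh_model <- function(object, points, ...) {
  points <- as_points(points)
  if (!is.null(object$validity_radius)) {
    r <- row_norms(sweep(points, 2L, object$origin))
    if (any(r > object$validity_radius))
      warning(sprintf("%d point(s) outside the validity radius (%g m)",
                      sum(r > object$validity_radius),
                      object$validity_radius), call. = FALSE)
  }
  tab <- vsh_basis_tables(object$lmax, object$R0)
  rel <- sweep(points, 2L, object$origin)
  F <- eval_basis_fields(rel, tab)
  cbind(F$Bx %*% object$coeffs, F$By %*% object$coeffs,
        F$Bz %*% object$coeffs)
}

#' Truncate a VSH model to a lower maximum degree
#'
#' @param model a \code{vsh_model}.
#' @param lmax new (smaller or equal) maximum degree.
#' @return a \code{vsh_model} keeping only coefficients with l <= lmax.
#' @export
truncate_vsh <- function(model, lmax) {
  stopifnot(inherits(model, "vsh_model"), lmax >= 1, lmax <= model$lmax)
  lmax <- as.integer(lmax)
  C <- lmax * (lmax + 2L)
  vsh_model(model$coeffs[seq_len(C)], lmax, model$origin, model$R0,
            model$validity_radius, model$coil_id)
}

#' Homogeneous (uniform) part of a VSH model
#'
#' The spatially constant field contributed by the degree-1 coefficients.
#'
#' @param model a \code{vsh_model}.
#' @return field 3-vector (T).
#' @export
uniform_part <- function(model) {
  stopifnot(inherits(model, "vsh_model"))
  m1 <- truncate_vsh(model, 1L)
  m1$validity_radius <- NULL
  as.numeric(predict(m1, matrix(model$origin, 1L)))
}

#' First-order gradient part of a VSH model
#'
#' The gradient tensor G, with \code{G[j, k]} = dB_j/dx_k at the expansion
#' origin, contributed by the degree-2 coefficients.  Symmetric and traceless
#' (Maxwell's equations in a source-free region).
#'
#' @param model a \code{vsh_model} with \code{lmax >= 2}.
#' @return 3 x 3 gradient tensor (T/m).
#' @export
gradient_part <- function(model) {
  stopifnot(inherits(model, "vsh_model"))
  if (model$lmax < 2L)
    stop("gradient_part() requires lmax >= 2", call. = FALSE)
  C1 <- 3L
  C2 <- 8L
  co <- numeric(C2)
  co[(C1 + 1L):C2] <- model$coeffs[(C1 + 1L):C2]
  m2 <- vsh_model(co, 2L, model$origin, model$R0)
  # degree-2 fields are exactly linear in position, so unit offsets give the
  # exact Jacobian
  P <- sweep(diag(3), 2, 0) + matrix(model$origin, 3, 3, byrow = TRUE)
  t(predict(m2, P))
}

#' VSH spectrum of a field model
#'
#' Squared coefficients per (l, m) component plus per-degree totals; the sum
#' over the table equals the squared norm of the coefficient vector.
#'
#' @param model a \code{vsh_model}.
#' @return data.frame with columns \code{l}, \code{m}, \code{beta},
#'   \code{beta_sq}, \code{degree_total} (sum of \code{beta_sq} over the
#'   degree, repeated within it).
#' @export
vsh_spectrum <- function(model) {
  stopifnot(inherits(model, "vsh_model"))
  tab <- vsh_basis_tables(model$lmax, model$R0)
  b2 <- model$coeffs^2
  dtot <- tapply(b2, tab$lm[, 1], sum)
  data.frame(l = tab$lm[, 1], m = tab$lm[, 2], beta = model$coeffs,
             beta_sq = b2,
             degree_total = as.numeric(dtot[as.character(tab$lm[, 1])]))
}
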