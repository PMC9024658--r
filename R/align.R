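#' Closed-form rigid (Umeyama) alignment of corresponding point sets
#'
#' Least-squares estimate of the rotation, translation (and optionally a
#' global scale) mapping \code{source} onto \code{target}:
#' \code{target ~ scale * R \%*\% source + t}.  The rotation is constrained
#' to be proper (determinant +1); reflections are never returned.
#' Correspondence is by row index.
#'
#' @param source,target M x 3 matrices (M >= 3, non-collinear).
#' @param with_scale estimate a global scale (default FALSE: unit scale).
#' @return list with \code{rotation} (3 x 3), \code{translation}
#'   (3-vector), \code{scale}, \code{transform} (function mapping M x 3
#'   points), and \code{rmsd} after alignment.
#' @export
umeyama_rigid <- function(source, target, with_scale = FALSE) {
  source <- as_points(source, "source")
  target <- as_points(target, "target")
  if (nrow(source) != nrow(target))
    stop("'source' and 'target' must have the same number of points",
         call. = FALSE)
  M <- nrow(source)
  if (M < 3L) stop("at least 3 correspondences are required", call. = FALSE)
  mu_s <- colMeans(source)
  mu_t <- colMeans(target)
  xs <- sweep(source, 2L, mu_s)
  xt <- sweep(target, 2L, mu_t)
  Sigma <- crossprod(xt, xs) / M
  sv <- svd(Sigma)
  if (sum(sv$d > 1e-12 * max(sv$d)) < 2L)
    stop("degenerate (collinear) point configuration", call. = FALSE)
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  scale <- if (with_scale) sum(sv$d * diag(S)) / (sum(xs^2) / M) else 1
  t0 <- mu_t - scale * as.numeric(R %*% mu_s)
  transform <- function(p) {
    p <- as_points(p)
    sweep(scale * p %*% t(R), 2L, t0, FUN = "+")
  }
  aligned <- transform(source)
  list(rotation = R, translation = t0, scale = scale, transform = transform,
       rmsd = sqrt(mean(rowSums((aligned - target)^2))))
}

#' Per-point distances and summary statistics between point sets
#'
#' Euclidean distances between corresponding rows (apply
#' \code{\link{umeyama_rigid}} first if the sets live in different frames).
#'
#' @param aligned_source,target M x 3 matrices with matched rows.
#' @return list with \code{distances} (m), \code{mean}, \code{rms},
#'   \code{range}.
#' @export
position_errors <- function(aligned_source, target) {
  aligned_source <- as_points(aligned_source, "aligned_source")
  target <- as_points(target, "target")
  if (nrow(aligned_source) != nrow(target))
    stop("point counts differ", call. = FALSE)
  d <- row_norms(aligned_source - target)
  list(distances = d, mean = mean(d), rms = sqrt(mean(d^2)),
       range = range(d))
}
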