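#' @keywords internal
"_PACKAGE"

## Physical constant: permeability of free space [T m / A]
MU0 <- 4e-7 * pi

#' Moore-Penrose pseudo-inverse with relative singular-value cutoff
#'
#' Singular values below `rtol` times the largest are treated as zero.
#'
#' @param A numeric matrix.
#' @param rtol relative cutoff (default 1e-10).
#' @return list with `pinv` (the pseudo-inverse), `rank` (numerical rank) and
#'   `cond` (ratio of largest to smallest retained singular value).
#' @keywords internal
pinv_svd <- function(A, rtol = 1e-10) {
  A <- as.matrix(A)
  sv <- svd(A)
  keep <- sv$d > rtol * max(sv$d, 0)
  r <- sum(keep)
  if (r == 0L) {
    return(list(pinv = t(A) * 0, rank = 0L, cond = Inf))
  }
  dinv <- numeric(length(sv$d))
  dinv[keep] <- 1 / sv$d[keep]
  list(
    pinv = sv$v %*% (dinv * t(sv$u)),
    rank = r,
    cond = max(sv$d[keep]) / min(sv$d[keep])
  )
}

## Row-wise Euclidean norms of a matrix
row_norms <- function(x) sqrt(rowSums(x^2))

## Coerce to an M x 3 numeric matrix of finite coordinates
as_points <- function(points, name = "points") {
  points <- as.matrix(points)
  if (is.vector(points)) points <- matrix(points, nrow = 1L)
  if (ncol(points) != 3L)
    stop(sprintf("'%s' must have 3 columns", name), call. = FALSE)
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  points
}

## Evaluate a function with a temporary RNG state seeded from `seed`,
## restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Angle in degrees between unit (or general nonzero) vectors
angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  ca <- max(-1, min(1, ca))
  acos(ca) * 180 / pi
}
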