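#' Target coefficient vector for one VSH component
#'
#' Convenience constructor: a coefficient vector that is zero except for one
#' unit entry at degree \code{l}, order \code{m}.
#'
#' @param l,m degree and order of the requested component.
#' @param lmax maximum degree of the basis (sets the vector length).
#' @param amplitude coefficient value (T), default 1.
#' @return length \code{lmax*(lmax+2)} numeric vector.
#' @export
harmonic_target <- function(l, m, lmax, amplitude = 1) {
  stopifnot(l >= 1, l <= lmax, abs(m) <= l)
  C <- as.integer(lmax) * (as.integer(lmax) + 2L)
  v <- numeric(C)
  # degree-major ordering: degrees 1..l-1 occupy (l-1)(l+1) slots
  v[(l - 1L) * (l + 1L) + (m + l + 1L)] <- amplitude
  v
}

#' Coil currents approximating a target VSH coefficient vector
#'
#' Minimum-norm least-squares currents \code{i = pinv(B) \%*\% target} such
#' that the superposed coil field approximates the requested harmonic
#' content.  When the achieved-to-requested ratio of a requested component
#' falls below \code{warn_ratio}, a warning reports that the coil
#' arrangement cannot produce it well.
#'
#' @param set a \code{\link{coil_model_set}}.
#' @param target length-C coefficient vector (e.g. from
#'   \code{\link{harmonic_target}}).
#' @param warn_ratio achievability warning threshold (default 0.5).
#' @param rtol pseudo-inverse relative cutoff.
#' @return length-N current vector (A), with attribute \code{achieved}
#'   (the coefficient vector actually produced).
#' @export
currents_for_harmonic <- function(set, target, warn_ratio = 0.5,
                                  rtol = 1e-10) {
  stopifnot(inherits(set, "coil_model_set"))
  target <- as.numeric(target)
  if (length(target) != nrow(set$B))
    stop(sprintf("'target' must have length %d", nrow(set$B)), call. = FALSE)
  i <- as.numeric(pinv_svd(set$B, rtol)$pinv %*% target)
  achieved <- as.numeric(set$B %*% i)
  # achievability is only meaningful for components that carry real weight
  tmax <- max(abs(target))
  req <- if (tmax > 0) which(abs(target) >= 1e-3 * tmax) else integer(0)
  if (length(req)) {
    ratio <- achieved[req] / target[req]
    if (any(ratio < warn_ratio))
      warning(sprintf(
        "requested component(s) achieved at ratio %s < %g: coil arrangement may not span them",
        paste(sprintf("%.2f", ratio[ratio < warn_ratio]), collapse = ", "),
        warn_ratio), call. = FALSE)
  }
  structure(i, achieved = achieved)
}

#' Diagnostics of a coil arrangement for harmonic synthesis
#'
#' Reports the condition number and numerical rank of the coefficient matrix
#' B (optionally restricted to degrees <= \code{degree_cutoff}), and the
#' achieved-to-requested ratio for every single-component target in the
#' restricted range.  A low restricted rank reveals, e.g., that a three-axis
#' Helmholtz-like set spans only two of the three diagonal gradients.
#'
#' @param set a \code{\link{coil_model_set}}.
#' @param degree_cutoff optional maximum degree of the rows to consider
#'   (e.g. 2 for the homogeneous + first-order-gradient subspace).
#' @param rtol pseudo-inverse relative cutoff.
#' @return list with \code{condition_number}, \code{rank}, \code{n_rows},
#'   \code{n_coils}, and data.frame \code{achievability} (l, m, ratio).
#' @export
synthesis_diagnostics <- function(set, degree_cutoff = NULL, rtol = 1e-10) {
  stopifnot(inherits(set, "coil_model_set"))
  tab <- vsh_basis_tables(set$lmax, set$R0)
  rows <- seq_len(nrow(set$B))
  if (!is.null(degree_cutoff))
    rows <- which(tab$lm[, 1] <= degree_cutoff)
  Bsub <- set$B[rows, , drop = FALSE]
  sv <- svd(Bsub)$d
  r <- sum(sv > rtol * max(sv))
  cond <- if (r > 0) max(sv) / min(sv[sv > rtol * max(sv)]) else Inf
  Bpinv <- pinv_svd(set$B, rtol)$pinv
  ach <- vapply(rows, function(k) {
    tgt <- numeric(nrow(set$B))
    tgt[k] <- 1
    (set$B %*% (Bpinv %*% tgt))[k]
  }, numeric(1))
  list(condition_number = cond, rank = r, n_rows = length(rows),
       n_coils = ncol(set$B),
       achievability = data.frame(l = tab$lm[rows, 1], m = tab$lm[rows, 2],
                                  ratio = ach))
}
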