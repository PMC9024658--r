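## Internal construction of the interior vector-spherical-harmonic basis.
##
## Each basis field is the gradient of a real regular solid harmonic,
## w_lm = grad(r^l Y_lm(theta, phi)), which is automatically divergence- and
## curl-free inside any source-free sphere.  Degree l = 1 gives the three
## homogeneous (uniform) fields, l = 2 the five independent first-order
## gradients, and so on; degree l contributes 2l+1 components, so degrees
## 1..lmax span lmax*(lmax+2) components (35 for lmax = 5).
##
## Conventions (fixed package-wide): real spherical harmonics Y_lm,
## orthonormal on the unit sphere, no Condon-Shortley phase; theta is the
## polar angle from +z, phi the azimuth from +x; component ordering is
## l ascending, m = -l..l within each degree.  Each basis field is scaled to
## unit RMS magnitude over a reference sphere of radius `R0` (default 0.1 m),
## so coefficients carry tesla.
##
## Internally each solid harmonic r^l Y_lm -- a homogeneous polynomial of
## degree l -- is expanded exactly in the monomial basis (solved once per
## lmax by projection at generic sample points and cached); gradients then
## follow from monomial calculus, which is exact everywhere including on the
## z-axis where spherical-component formulas are singular.

.basis_cache <- new.env(parent = emptyenv())

## Exponent triples (a, b, c), a+b+c = d, for all monomials of degree d
monomial_exponents <- function(d) {
  out <- list()
  for (a in d:0) for (b in (d - a):0) {
    out[[length(out) + 1L]] <- c(a, b, d - a - b)
  }
  do.call(rbind, out)
}

## Monomial design matrix: M x nrow(E), column j = x^E[j,1] y^E[j,2] z^E[j,3]
monomial_matrix <- function(points, E) {
  M <- nrow(points)
  out <- matrix(1, M, nrow(E))
  for (j in seq_len(nrow(E))) {
    e <- E[j, ]
    v <- rep(1, M)
    if (e[1] > 0) v <- v * points[, 1]^e[1]
    if (e[2] > 0) v <- v * points[, 2]^e[2]
    if (e[3] > 0) v <- v * points[, 3]^e[3]
    out[, j] <- v
  }
  out
}

## Real orthonormal spherical harmonics Y_lm (m = -l..l) at given angles,
## no Condon-Shortley phase.  Returns a length(theta) x (2l+1) matrix.
real_sph_harm <- function(l, theta, phi) {
  ct <- cos(theta)
  P <- pracma::legendre(l, ct)              # rows m = 0..l, CS phase included
  if (is.vector(P)) P <- matrix(P, nrow = l + 1L)
  out <- matrix(0, length(theta), 2L * l + 1L)
  for (m in 0:l) {
    Nlm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
    Plm <- (-1)^m * P[m + 1L, ]             # strip Condon-Shortley
    if (m == 0L) {
      out[, l + 1L] <- Nlm * Plm
    } else {
      out[, l + 1L + m] <- sqrt(2) * Nlm * Plm * cos(m * phi)
      out[, l + 1L - m] <- sqrt(2) * Nlm * Plm * sin(m * phi)
    }
  }
  out
}

## Deterministic generic sample points (no RNG): golden-spiral directions at
## staggered radii; used to solve for the monomial coefficients exactly.
generic_points <- function(n) {
  i <- seq_len(n)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(rho * cos(ga * i), rho * sin(ga * i), z)
  dirs * (0.6 + 0.8 * ((i * 7) %% n) / n)
}

## Monomial coefficients of the homogeneous polynomial r^l Y_lm for all m.
## Returns nrow(E_l) x (2l+1) matrix; exact up to round-off.
solid_harmonic_coefs <- function(l) {
  E <- monomial_exponents(l)
  D <- nrow(E)
  pts <- generic_points(2L * D + 8L)
  r <- row_norms(pts)
  theta <- acos(pmin(1, pmax(-1, pts[, 3] / r)))
  phi <- atan2(pts[, 2], pts[, 1])
  f <- r^l * real_sph_harm(l, theta, phi)
  V <- monomial_matrix(pts, E)
  coefs <- qr.solve(qr(V), f)
  resid <- max(abs(V %*% coefs - f))
  stopifnot(resid < 1e-9 * max(abs(f)))
  coefs
}

## Build (and cache) the monomial tables of the full VSH basis for degrees
## 1..lmax: exponents E over degrees 0..lmax-1 and, per Cartesian component,
## an nmono x C coefficient matrix of the basis fields.
vsh_basis_tables <- function(lmax, R0 = 0.1) {
  key <- sprintf("l%d_R%.8g", lmax, R0)
  if (!is.null(.basis_cache[[key]])) return(.basis_cache[[key]])
  stopifnot(lmax >= 1)

  E <- do.call(rbind, lapply(0:(lmax - 1L), monomial_exponents))
  mono_key <- function(e) paste(e, collapse = ",")
  idx <- new.env(parent = emptyenv())
  for (j in seq_len(nrow(E))) assign(mono_key(E[j, ]), j, envir = idx)

  C <- lmax * (lmax + 2L)
  Wx <- matrix(0, nrow(E), C)
  Wy <- matrix(0, nrow(E), C)
  Wz <- matrix(0, nrow(E), C)
  lm <- matrix(0L, C, 2L)

  col <- 0L
  for (l in 1:lmax) {
    El <- monomial_exponents(l)
    Ql <- solid_harmonic_coefs(l)           # potential coefficients
    # unit-RMS scaling on the reference sphere:
    # mean |grad(r^l Y_lm)|^2 over sphere radius R0 = R0^(2l-2) l(2l+1)/(4pi)
    scale <- 1 / (R0^(l - 1) * sqrt(l * (2 * l + 1) / (4 * pi)))
    for (m in -l:l) {
      col <- col + 1L
      lm[col, ] <- c(l, m)
      q <- Ql[, l + 1L + m]
      for (j in seq_len(nrow(El))) {
        e <- El[j, ]
        if (e[1] > 0) {
          t <- get(mono_key(c(e[1] - 1L, e[2], e[3])), envir = idx)
          Wx[t, col] <- Wx[t, col] + scale * q[j] * e[1]
        }
        if (e[2] > 0) {
          t <- get(mono_key(c(e[1], e[2] - 1L, e[3])), envir = idx)
          Wy[t, col] <- Wy[t, col] + scale * q[j] * e[2]
        }
        if (e[3] > 0) {
          t <- get(mono_key(c(e[1], e[2], e[3] - 1L)), envir = idx)
          Wz[t, col] <- Wz[t, col] + scale * q[j] * e[3]
        }
      }
    }
  }

  out <- list(lmax = lmax, R0 = R0, E = E, Wx = Wx, Wy = Wy, Wz = Wz,
              lm = lm, C = C)
  .basis_cache[[key]] <- out
  out
}

## Evaluate all C basis fields at M points (relative coordinates already
## shifted by the expansion origin).  Returns list of M x C matrices Bx/By/Bz.
eval_basis_fields <- function(rel_points, tables) {
  P <- monomial_matrix(rel_points, tables$E)
  list(Bx = P %*% tables$Wx, By = P %*% tables$Wy, Bz = P %*% tables$Wz)
}
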