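# The VSH basis: dimensionality, Maxwell constraints, low-order extraction.

test_that("basis dimensions and ordering follow the degree structure", {
  pts <- with_fixed_rng(1, matrix(runif(108 * 3, -0.1, 0.1), 108, 3))
  S <- vsh_design_matrix(pts, lmax = 5)
  expect_equal(dim(S), c(324L, 35L))   # 108 triaxial points, 35 components
  lm <- attr(S, "lm")
  expect_equal(lm[, 1], rep(1:5, times = 2 * (1:5) + 1))
  expect_equal(sum(lm[, 1] <= 2), 8L)  # uniform + first-order gradients
  # triaxial sampling at well-spread points gives a full-rank basis
  expect_lt(max(svd(S)$d) / min(svd(S)$d), 1e6)
})

test_that("degree-1 basis fields are spatially constant", {
  pts <- with_fixed_rng(2, matrix(runif(30, -0.2, 0.2), 10, 3))
  S <- vsh_design_matrix(pts, lmax = 1)
  expect_equal(ncol(S), 3L)
  blk1 <- S[1:3, ]
  for (i in 2:10) expect_equal(S[(3 * i - 2):(3 * i), ], blk1)
})

test_that("every basis field is divergence- and curl-free (finite differences)", {
  tab_pts <- with_fixed_rng(3, matrix(runif(60, -0.08, 0.08), 20, 3))
  h <- 1e-4 * 0.1                      # step: 1e-4 of the region scale
  S0 <- function(p) matrix(vsh_design_matrix(rbind(p), lmax = 5), 3, 35)
  for (i in seq_len(nrow(tab_pts))) {
    p <- tab_pts[i, ]
    J <- array(0, c(3, 3, 35))
    for (k in 1:3) {
      e <- numeric(3); e[k] <- h
      J[, k, ] <- (S0(p + e) - S0(p - e)) / (2 * h)
    }
    scale <- max(abs(S0(p))) / 0.1    # field scale per length
    div <- abs(J[1, 1, ] + J[2, 2, ] + J[3, 3, ])
    curl <- pmax(abs(J[3, 2, ] - J[2, 3, ]), abs(J[1, 3, ] - J[3, 1, ]),
                 abs(J[2, 1, ] - J[1, 2, ]))
    expect_lt(max(div) / scale, 1e-6)
    expect_lt(max(curl) / scale, 1e-6)
  }
})

test_that("model evaluation is the term-by-term coefficient sum", {
  co <- with_fixed_rng(4, rnorm(35))
  m <- vsh_model(co, 5, origin = c(0.01, -0.02, 0.005))
  pts <- with_fixed_rng(5, matrix(runif(15, -0.05, 0.05), 5, 3))
  pred <- predict(m, pts)
  # brute-force accumulation, one basis column at a time
  acc <- matrix(0, 5, 3)
  for (j in 1:35) {
    ej <- numeric(35); ej[j] <- 1
    mj <- vsh_model(ej, 5, origin = m$origin)
    acc <- acc + co[j] * predict(mj, pts)
  }
  expect_equal(pred, acc, tolerance = 1e-12)
  # zero coefficients give a zero field
  expect_equal(predict(vsh_model(numeric(35), 5), pts), matrix(0, 5, 3))
  # degree-1-only model is uniform
  m1 <- vsh_model(c(rnorm(3), numeric(32)), 5)
  two <- predict(m1, rbind(c(0.05, 0, 0), c(-0.03, 0.07, 0.01)))
  expect_equal(two[1, ], two[2, ])
})

test_that("uniform part extracts the homogeneous field", {
  co <- numeric(35); co[4:8] <- 1       # degree-2 only
  expect_equal(uniform_part(vsh_model(co, 5)), c(0, 0, 0))
  # forward-then-fit round trip of a constant 1 nT z-field
  pts <- with_fixed_rng(6, matrix(runif(90, -0.1, 0.1), 30, 3))
  B <- matrix(rep(c(0, 0, 1e-9), each = 30), 30, 3)
  fit <- fit_vsh(field_measurements(pts, B), lmax = 3)
  expect_equal(uniform_part(fit), c(0, 0, 1e-9), tolerance = 1e-9)
  # consistency with evaluating the degree-1 truncation at the origin
  m <- vsh_model(with_fixed_rng(8, rnorm(35)), 5, origin = c(0, 0.01, 0))
  expect_equal(uniform_part(m),
               as.numeric(predict(truncate_vsh(m, 1),
                                  rbind(m$origin))))
})

test_that("gradient part is the symmetric traceless Jacobian at the origin", {
  co <- numeric(35); co[1:3] <- rnorm(3)
  expect_equal(gradient_part(vsh_model(co, 5)), matrix(0, 3, 3))
  m <- vsh_model(with_fixed_rng(9, rnorm(35)), 5, origin = c(0.01, 0, -0.01))
  G <- gradient_part(m)
  expect_equal(G, t(G), tolerance = 1e-12)
  expect_lt(abs(sum(diag(G))), 1e-12 * norm(G, "F"))
  # matches central finite differences of the degree-2 truncation
  m2 <- truncate_vsh(m, 2)
  h <- 1e-5
  Gfd <- matrix(0, 3, 3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    Gfd[, k] <- (predict(m2, rbind(m$origin + e)) -
                   predict(m2, rbind(m$origin - e))) / (2 * h)
  }
  expect_equal(G, Gfd, tolerance = 1e-6)
  expect_error(gradient_part(vsh_model(rnorm(3), 1)), "lmax >= 2")
})

test_that("pure transverse-gradient field is recovered in the gradient tensor", {
  # B = (G z, 0, G x): symmetric traceless, curl- and divergence-free
  Gv <- 2e-8
  pts <- with_fixed_rng(10, matrix(runif(120, -0.1, 0.1), 40, 3))
  B <- cbind(Gv * pts[, 3], 0, Gv * pts[, 1])
  fit <- fit_vsh(field_measurements(pts, B), lmax = 3,
                 origin = c(0, 0, 0))
  Gt <- gradient_part(fit)
  expect_equal(Gt, rbind(c(0, 0, Gv), c(0, 0, 0), c(Gv, 0, 0)),
               tolerance = 1e-6)
})

test_that("spectrum sums to the coefficient energy and flags dominant degrees", {
  co <- numeric(35); co[17] <- 3       # one l=3 entry
  sp <- vsh_spectrum(vsh_model(co, 5))
  expect_equal(sum(sp$beta_sq), 9)
  expect_equal(sp$beta_sq[17], 9)
  m <- vsh_model(with_fixed_rng(11, rnorm(35)), 5)
  sp <- vsh_spectrum(m)
  expect_equal(sum(sp$beta_sq), sum(m$coeffs^2))
  expect_equal(unique(sp$degree_total),
               as.numeric(tapply(sp$beta_sq, sp$l, sum)))
  # a far coil's energy is concentrated at low degrees
  fit <- fit_vsh(square_loop_fixture()$meas, lmax = 5)
  d <- vsh_spectrum(fit)
  dt <- tapply(d$beta_sq, d$l, sum)
  expect_gt(dt[["1"]], dt[["2"]])
  expect_gt(dt[["2"]], dt[["3"]])
})

test_that("invalid basis inputs are rejected", {
  expect_error(vsh_design_matrix(matrix(c(1, NA, 0), 1), 2), "non-finite")
  expect_error(vsh_design_matrix(matrix(0, 1, 3), 0), "lmax")
  expect_error(vsh_design_matrix(matrix(0.05, 1, 3), 2,
                                 projections = matrix(c(1, 1, 0), 1)),
               "unit-norm")
  expect_error(vsh_model(numeric(10), 5), "length 35")
})
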