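test_that("diabatic matrix reproduces direct substitution and the origin", {
  m <- lvc_model(omega = c(1, 1), E_vert = c(0, 1),
                 kappa = rbind(c(0.5, 0), c(-0.5, 0)), lam = c(0, 0.2))
  expect_equal(diabatic_matrix(m, c(1, 1)),
               matrix(c(1.5, 0.2, 0.2, 1.5), 2))
  expect_equal(diabatic_matrix(m, c(0, 0)), diag(c(0, 1)))
  expect_error(diabatic_matrix(m, c(1, 2, 3)), "length")
})

test_that("diabatic matrix agrees with a loop-based re-summation oracle", {
  for (seed in 1:5) {
    m <- random_lvc_model(n_modes = 3, n_states = 3, seed = seed)
    set.seed(seed + 100)
    q <- stats::runif(3, -2, 2)
    expect_lt(max(abs(diabatic_matrix(m, q) - loop_diabatic(m, q))), 1e-12)
  }
})

test_that("adiabatic energies match the 2x2 closed form and a dense eigensolver", {
  m2 <- random_lvc_model(2, 2, seed = 3)
  q <- c(0.4, -0.7)
  W <- diabatic_matrix(m2, q)
  wbar <- (W[1, 1] + W[2, 2]) / 2
  r <- sqrt(((W[1, 1] - W[2, 2]) / 2)^2 + W[1, 2]^2)
  expect_equal(adiabatic_surface(m2, q)$energies, c(wbar - r, wbar + r),
               tolerance = 1e-12)

  m3 <- random_lvc_model(2, 3, seed = 5)
  q <- c(-0.3, 1.1)
  ad <- adiabatic_surface(m3, q)
  e <- eigen(diabatic_matrix(m3, q), symmetric = TRUE)
  expect_lt(max(abs(ad$energies - sort(e$values))), 1e-10)
  # orthonormality
  expect_lt(max(abs(crossprod(ad$vectors) - diag(3))), 1e-10)
})

test_that("states are degenerate on the seam (conical intersection)", {
  m <- make_model("sloped_ci")
  # seam on the q2 = 0 axis: W11 = W22 and W12 = 0
  root <- uniroot(function(q1) {
    W <- diabatic_matrix(m, c(q1, 0)); W[1, 1] - W[2, 2]
  }, c(0.1, 6))$root
  e <- adiabatic_surface(m, c(root, 0))$energies
  expect_lt(abs(e[2] - e[1]), 1e-9)
})

test_that("trace is invariant under the adiabatic transform", {
  m <- random_lvc_model(3, 4, seed = 11)
  set.seed(42)
  for (i in 1:20) {
    q <- stats::runif(3, -2, 2)
    expect_lt(abs(sum(adiabatic_surface(m, q)$energies) -
                    sum(diag(diabatic_matrix(m, q)))), 1e-12)
  }
})

test_that("adiabatic gradient: uncoupled closed form, finite differences, stationarity", {
  # uncoupled single state: gradient is omega*q + kappa
  m1 <- lvc_model(omega = c(0.7, 1.3), E_vert = 0.2,
                  kappa = matrix(c(0.4, -0.1), 1))
  q <- c(0.5, -1.2)
  expect_equal(adiabatic_gradient(m1, q, 1), m1$omega * q + c(0.4, -0.1),
               tolerance = 1e-12)
  # at the minimum the gradient vanishes
  qmin <- -c(0.4, -0.1) / m1$omega
  expect_lt(max(abs(adiabatic_gradient(m1, qmin, 1))), 1e-12)

  # finite-difference oracle on a coupled random model
  m <- random_lvc_model(3, 3, seed = 8)
  q <- c(0.3, -0.2, 0.5)
  for (J in 1:3) {
    g <- adiabatic_gradient(m, q, J)
    gfd <- vapply(1:3, function(i) {
      h <- 1e-5; qp <- q; qm <- q
      qp[i] <- q[i] + h; qm[i] <- q[i] - h
      (adiabatic_surface(m, qp)$energies[J] -
         adiabatic_surface(m, qm)$energies[J]) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - gfd)), 1e-6)
  }
})

test_that("nonadiabatic coupling vector: antisymmetry, finite differences, divergence", {
  m <- random_lvc_model(3, 3, seed = 13)
  q <- c(0.2, 0.6, -0.4)
  d12 <- nac_vector(m, q, 1, 2)
  expect_equal(d12, -nac_vector(m, q, 2, 1), tolerance = 1e-12)

  # finite difference of gauge-fixed eigenvectors: <c_I(q) | d c_J / d q>
  ad0 <- adiabatic_surface(m, q)
  dfd <- vapply(1:3, function(i) {
    h <- 1e-6; qp <- q; qp[i] <- q[i] + h; qm <- q; qm[i] <- q[i] - h
    vp <- adiabatic_surface(m, qp, gauge_ref = ad0$vectors)$vectors
    vm <- adiabatic_surface(m, qm, gauge_ref = ad0$vectors)$vectors
    sum(ad0$vectors[, 1] * (vp[, 2] - vm[, 2])) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(d12 - dfd)), 1e-5)

  # magnitude grows monotonically approaching the intersection along a ray
  mci <- make_model("sloped_ci")
  root <- uniroot(function(q1) {
    W <- diabatic_matrix(mci, c(q1, 0)); W[1, 1] - W[2, 2]
  }, c(0.1, 6))$root
  q2s <- c(1.0, 0.7, 0.4, 0.2, 0.1)
  mags <- vapply(q2s, function(q2)
    sqrt(sum(nac_vector(mci, c(root, q2), 1, 2)^2)), numeric(1))
  expect_true(all(diff(mags) > 0))
  # exactly at the degeneracy: refuses with a degeneracy condition
  expect_error(nac_vector(mci, c(root, 0), 1, 2), class = "aimsim_degeneracy")
})

test_that("eigenvector continuity holds along a trajectory after sign fixing", {
  m <- make_model("sloped_ci")
  qs <- cbind(seq(0, 3, length.out = 60), seq(0.8, -0.4, length.out = 60))
  prev <- NULL
  for (i in seq_len(nrow(qs))) {
    ad <- adiabatic_surface(m, qs[i, ], gauge_ref = prev)
    if (!is.null(prev))
      expect_true(all(colSums(prev * ad$vectors) >= 0))
    prev <- ad$vectors
  }
})

test_that("model files round-trip through the text format", {
  m <- make_model("sloped_ci")
  path <- tempfile(fileext = ".json")
  write_lvc_model(m, path)
  m2 <- read_lvc_model(path)
  expect_equal(m2$omega, m$omega)
  expect_equal(m2$kappa, m$kappa)
  expect_equal(m2$lam, m$lam)
  expect_equal(m2$E_vert, m$E_vert)
  q <- c(0.3, -0.5)
  expect_equal(diabatic_matrix(m2, q), diabatic_matrix(m, q))
  unlink(path)
})

test_that("constructor rejects inconsistent inputs", {
  expect_error(lvc_model(omega = c(1, -1), E_vert = c(0, 1)), "positive")
  expect_error(lvc_model(omega = 1, E_vert = c(0, 1),
                         lam = array(c(0, 1, 2, 0), c(2, 2, 1))),
               "symmetric")
})
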