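test_that("overlap: normalisation, displaced closed form, Hermiticity", {
  pr <- random_tbf_pair(3, seed = 1)
  a <- pr[[1]]; b <- pr[[2]]
  expect_equal(overlap(a, a), 1 + 0i, tolerance = 1e-13)
  expect_equal(overlap(a, b), Conj(overlap(b, a)), tolerance = 1e-13)
  expect_lte(abs(overlap(a, b)), 1)

  # equal widths, zero momenta, displaced by d in one coordinate
  u <- tbf(1, R = c(0, 0), P = c(0, 0), alpha = 0.8)
  v <- tbf(1, R = c(1.3, 0), P = c(0, 0), alpha = 0.8)
  expect_equal(overlap(u, v), exp(-0.8 * 1.3^2 / 2) + 0i, tolerance = 1e-12)
})

test_that("closed-form matrix elements match adaptive quadrature on 100+ random pairs", {
  worst <- c(overlap = 0, deriv = 0, kin = 0)
  for (i in 1:104) {
    dim <- (i %% 4) + 1
    pr <- random_tbf_pair(dim, seed = 1000 + i)
    a <- pr[[1]]; b <- pr[[2]]
    worst["overlap"] <- max(worst["overlap"],
                            abs(overlap(a, b) - quad_overlap(a, b)))
    rho <- (i %% dim) + 1
    worst["deriv"] <- max(worst["deriv"],
                          abs(derivative_element(a, b, rho) -
                                quad_element(a, b, "d", rho)))
    masses <- seq_len(dim) + 0.5
    kin_q <- 0
    for (r in seq_len(dim))
      kin_q <- kin_q + quad_element(a, b, "d2", r) / (2 * masses[r])
    worst["kin"] <- max(worst["kin"],
                        abs(kinetic_element(a, b, masses) - kin_q))
  }
  expect_lt(worst["overlap"], 1e-8)
  expect_lt(worst["deriv"], 1e-8)
  expect_lt(worst["kin"], 1e-8)
})

test_that("derivative element: momentum expectation and parity", {
  pr <- random_tbf_pair(2, seed = 5)
  a <- pr[[1]]
  for (rho in 1:2)
    expect_equal(derivative_element(a, a, rho),
                 complex(imaginary = a$P[rho]), tolerance = 1e-12)
  # zero-momentum identical-width pair: purely real, antisymmetric in a<->b
  u <- tbf(1, R = c(0.2, -0.4), P = c(0, 0), alpha = 0.9)
  v <- tbf(1, R = c(-0.5, 0.3), P = c(0, 0), alpha = 0.9)
  d_uv <- derivative_element(u, v, 1)
  expect_lt(abs(Im(d_uv)), 1e-13)
  expect_equal(d_uv, -derivative_element(v, u, 1), tolerance = 1e-12)
})

test_that("kinetic element: diagonal closed form, mass linearity, Hermiticity", {
  pr <- random_tbf_pair(3, seed = 9)
  a <- pr[[1]]; b <- pr[[2]]
  masses <- c(1, 2, 3)
  expect_equal(kinetic_element(a, a, masses),
               sum((a$P^2 + a$alpha) / (2 * masses)) + 0i, tolerance = 1e-12)
  expect_equal(kinetic_element(a, b, 2 * masses),
               kinetic_element(a, b, masses) / 2, tolerance = 1e-12)
  expect_equal(kinetic_element(a, b, masses),
               Conj(kinetic_element(b, a, masses)), tolerance = 1e-12)
})

test_that("time-derivative element: norm conservation, phase-only motion, finite differences", {
  pr <- random_tbf_pair(2, seed = 21)
  a <- pr[[1]]; b <- pr[[2]]
  dyn_a <- list(dR = c(0.3, -0.2), dP = c(0.1, 0.4), dgamma = 0.7)
  expect_lt(abs(2 * Re(sdot_element(a, a, dyn_a))), 1e-13)

  # ket at rest: only the phase moves
  rest <- list(dR = c(0, 0), dP = c(0, 0), dgamma = 1.3)
  expect_equal(sdot_element(a, b, rest), 1i * 1.3 * overlap(a, b),
               tolerance = 1e-12)

  # central finite difference through the ket parameters
  dyn <- list(dR = c(0.25, -0.45), dP = c(-0.15, 0.35), dgamma = 0.6)
  delta <- 1e-4
  shift <- function(s) {
    bb <- b
    bb$R <- b$R + s * dyn$dR; bb$P <- b$P + s * dyn$dP
    bb$gamma <- b$gamma + s * dyn$dgamma
    bb
  }
  fd <- (overlap(a, shift(delta)) - overlap(a, shift(-delta))) / (2 * delta)
  expect_lt(abs(sdot_element(a, b, dyn) - fd), 1e-6)
})

test_that("centroid: midpoint, idempotence, and the product-density argmax", {
  u <- tbf(1, R = c(1, -2), P = c(0, 0), alpha = 0.7)
  v <- tbf(1, R = c(3, 4), P = c(0, 0), alpha = 0.7)
  expect_equal(centroid(u, v), c(2, 1))
  expect_equal(centroid(u, u), u$R)

  w <- tbf(1, R = c(0.5, 1.5), P = c(0.2, -0.3), alpha = c(0.4, 2.5))
  z <- tbf(1, R = c(2.0, -1.0), P = c(-0.1, 0.6), alpha = c(1.8, 0.6))
  cen <- centroid(w, z)
  # independent numerical argmax of |chi_w * chi_z| (log scale for conditioning)
  obj <- function(q) -log(abs(tbf_value(w, q) * tbf_value(z, q)))
  opt <- optim(c(1, 0), obj, method = "BFGS", control = list(reltol = 1e-14))
  expect_lt(max(abs(cen - opt$par)), 1e-5)
})

test_that("overlap decays monotonically with separation for equal-width pairs", {
  seps <- seq(0, 4, by = 0.5)
  ovs <- vapply(seps, function(d) {
    abs(overlap(tbf(1, 0, 0, 0.5), tbf(1, d, 0, 0.5)))
  }, numeric(1))
  expect_true(all(diff(ovs) <= 0))
})

test_that("TBF constructor validates widths and dimensions", {
  expect_error(tbf(1, R = c(0, 0), P = c(0, 0), alpha = c(0.5, -1)),
               "positive")
  expect_error(tbf(1, R = c(0, 0), P = 0, alpha = 0.5), "same length")
})
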