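p_noscreen <- sim_params(olapthresh = 0)

test_that("single-TBF matrices: unit overlap, kinetic + potential energy", {
  m <- make_model("sloped_ci")
  x <- tbf(2, R = c(0.5, -0.2), P = c(0.3, 0.1), alpha = 0.5)
  set <- coupled_set(list(x), complex(real = 1))
  mats <- assemble_matrices(set, m, p_noscreen)
  expect_equal(mats$S, matrix(1 + 0i, 1, 1), tolerance = 1e-13)
  Eexp <- kinetic_element(x, x, 1 / m$omega) +
    adiabatic_surface(m, x$R)$energies[2]
  expect_equal(mats$H[1, 1], Eexp, tolerance = 1e-12)
  expect_equal(mats$n_pot_evals, 1L)
})

test_that("overlap screening zeroes couplings but keeps S exact", {
  m <- make_model("sloped_ci")
  far <- coupled_set(list(tbf(2, c(-2, 0), c(0, 0), 0.5, id = "a"),
                          tbf(2, c(2.5, 0.5), c(0.4, 0), 0.5, id = "b")),
                     c(1, 0) / 1)
  ov <- abs(overlap(far$tbfs[[1]], far$tbfs[[2]]))
  p_hi <- sim_params(olapthresh = ov * 1.5)
  mats <- assemble_matrices(far, m, p_hi)
  expect_identical(mats$H[1, 2], 0i)
  expect_identical(mats$Sdot[1, 2], 0i)
  expect_equal(mats$S[1, 2], overlap(far$tbfs[[1]], far$tbfs[[2]]),
               tolerance = 1e-12)
  # olapthresh = 0 reproduces the unscreened result bit for bit
  m0 <- assemble_matrices(far, m, sim_params(olapthresh = 0))
  m_tiny <- assemble_matrices(far, m, sim_params(olapthresh = 1e-300))
  expect_identical(m0$H, m_tiny$H)
  expect_identical(m0$Sdot, m_tiny$Sdot)
})

test_that("SPA0 potential term is near-exact on a slowly varying surface", {
  # quasi-linear potential: tiny harmonic curvature + linear slope
  m <- lvc_model(omega = 0.01, E_vert = 0.5, kappa = matrix(0.3, 1, 1))
  a <- tbf(1, R = 0.35, P = 0.20, alpha = 0.5, id = "a")
  b <- tbf(1, R = 0.05, P = 0.17, alpha = 0.5, id = "b")
  set <- coupled_set(list(a, b), c(1, 0))
  mats <- assemble_matrices(set, m, p_noscreen)
  spa0_pot <- mats$H[1, 2] - kinetic_element(a, b, 1 / m$omega)
  # quadrature of <a | E(q) | b>
  Eq <- function(q) adiabatic_surface(m, q)$energies[1]
  f <- function(x) vapply(x, function(q) Conj(tbf_value(a, q)) * Eq(q) *
                            tbf_value(b, q), complex(1))
  exact <- integrate(function(x) Re(f(x)), -Inf, Inf, rel.tol = 1e-10)$value +
    1i * integrate(function(x) Im(f(x)), -Inf, Inf, rel.tol = 1e-10)$value
  expect_lt(abs(spa0_pot - exact) / abs(exact), 0.01)
})

test_that("regularised inverse: identity, rank deficiency, dense-solver agreement", {
  expect_equal(regularized_inverse(diag(3) + 0i, 1e-4), diag(3) + 0i,
               tolerance = 1e-12)
  # [[1,1],[1,1]]: eigenvalues 2 and 0; pseudo-inverse on the retained space
  S1 <- matrix(1 + 0i, 2, 2)
  pinv <- regularized_inverse(S1, 1e-4)
  expect_equal(pinv, matrix(0.25 + 0i, 2, 2), tolerance = 1e-12)
  # well-conditioned Hermitian: matches solve()
  set.seed(4)
  A <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4)
  S <- A %*% t(Conj(A)) + 2 * diag(4)
  expect_lt(max(abs(regularized_inverse(S, 1e-6) - solve(S))), 1e-10)
  # fully degenerate basis errors out
  expect_error(regularized_inverse(S1 * 0, 1e-4), "no eigenvalue")
})

test_that("amplitude propagation: invariances and the matrix-exponential oracle", {
  set.seed(12)
  n <- 3
  A <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n)
  S <- A %*% t(Conj(A)) / n + diag(n)
  H <- (A + t(Conj(A))) / 2
  Sd <- (A - t(Conj(A))) / 5
  C0 <- c(1, 0.3 + 0.2i, -0.1i); C0 <- C0 / sqrt(sum(abs(C0)^2))
  z <- matrix(0i, n, n)

  # H = 0, Sdot = 0: C unchanged
  mats0 <- list(S = S, Sdot = z, H = z)
  expect_equal(propagate_coefficients(C0, mats0, mats0, 0.3, 1e-8), C0,
               tolerance = 1e-12)

  # frozen matrices: matches exp(-i S^-1 (H - i Sdot) dt) C
  mats <- list(S = S, Sdot = Sd, H = H)
  got <- propagate_coefficients(C0, mats, mats, 0.05, 1e-10, n_sub = 8L)
  want <- frozen_propagator(C0, S, Sd, H, 0.05)
  expect_lt(max(abs(got - want)), 1e-8)

  # 100 frozen-matrix steps stay on the oracle to 1e-6
  C <- C0
  for (i in 1:100) C <- propagate_coefficients(C, mats, mats, 0.05, 1e-10)
  expect_lt(max(abs(C - frozen_propagator(C0, S, Sd, H, 5))), 1e-6)

  # single TBF: pure phase evolution, |C| constant to 1e-12
  m2 <- list(S = matrix(1 + 0i), Sdot = matrix(0i), H = matrix(0.7 + 0i))
  c2 <- 1 + 0i
  for (i in 1:50) c2 <- propagate_coefficients(c2, m2, m2, 0.02, 1e-8)
  expect_lt(abs(abs(c2) - 1), 1e-12)
  expect_lt(abs(c2 - exp(-1i * 0.7 * 1)), 1e-10)
})

test_that("Mulliken populations: orthogonal limit, resolution of S, loop oracle", {
  set <- make_set_1d(4, spread = 8)       # widely separated: S ~ identity
  mats_S <- diag(4) + 0i
  for (k in 1:4)
    expect_equal(mulliken_population(set, mats_S, k), abs(set$C[k])^2,
                 tolerance = 1e-12)

  set2 <- make_set_1d(5, spread = 0.8, seed = 3)
  S <- matrix(0i, 5, 5)
  for (i in 1:5) for (j in 1:5)
    S[i, j] <- overlap(set2$tbfs[[i]], set2$tbfs[[j]])
  # brute-force double loop
  for (k in 1:5) {
    nk <- 0
    for (kp in 1:5)
      nk <- nk + Re(Conj(set2$C[kp]) * S[kp, k] * set2$C[k])
    expect_equal(mulliken_population(set2, S, k), nk, tolerance = 1e-12)
  }
  # populations resolve the total norm
  total <- sum(vapply(1:5, function(k) mulliken_population(set2, S, k),
                      numeric(1)))
  expect_equal(total, set_norm(set2$C, S), tolerance = 1e-12)
  expect_equal(state_population(set2, S, 1L), total, tolerance = 1e-12)
  expect_equal(state_population(set2, S, 2L), 0)
})

test_that("assembled Hamiltonian is Hermitian and norm is conserved in coupled dynamics", {
  m <- make_model("sloped_ci")
  set <- coupled_set(list(tbf(2, c(1.8, 0.4), c(1.2, 0.1), 0.5, id = "u"),
                          tbf(1, c(1.7, 0.5), c(1.5, 0.2), 0.5, id = "v")),
                     c(1, 0))
  mats <- assemble_matrices(set, m, p_noscreen)
  expect_lt(max(abs(mats$H - t(Conj(mats$H)))), 1e-12)
  # cross-state blocks of S and Sdot vanish (electronic orthogonality)
  expect_identical(mats$S[1, 2], 0i)
  expect_identical(mats$Sdot[1, 2], 0i)

  # norm conservation over 1000 frozen-geometry amplitude steps
  C <- set$C
  for (i in 1:1000)
    C <- propagate_coefficients(C, mats, mats, 0.02, 1e-10)
  expect_lt(abs(set_norm(C, mats$S) - set_norm(set$C, mats$S)), 1e-6)
})
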