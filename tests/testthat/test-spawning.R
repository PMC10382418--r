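m_ci <- make_model("sloped_ci")

test_that("coupling magnitude: construction, symmetry, finite-difference norm", {
  # far from the intersection the indicator is small
  far <- tbf(2, R = c(-3, 0.2), P = c(0, 0), alpha = 0.5)
  expect_lt(coupling_magnitude(far, m_ci, 1L),
            coupling_magnitude(tbf(2, c(2, 0.3), c(0, 0), 0.5), m_ci, 1L))

  # mirror symmetry of the model in the coupling mode
  q2 <- 0.6
  a <- tbf(2, R = c(1.5, q2), P = c(0, 0), alpha = 0.5)
  b <- tbf(2, R = c(1.5, -q2), P = c(0, 0), alpha = 0.5)
  expect_equal(coupling_magnitude(a, m_ci, 1L),
               coupling_magnitude(b, m_ci, 1L), tolerance = 1e-12)

  # matches the norm of the finite-difference coupling vector
  q <- c(1.7, 0.5)
  x <- tbf(2, R = q, P = c(0, 0), alpha = 0.5)
  ad0 <- adiabatic_surface(m_ci, q)
  dfd <- vapply(1:2, function(i) {
    h <- 1e-6; qp <- q; qp[i] <- q[i] + h; qm <- q; qm[i] <- q[i] - h
    vp <- adiabatic_surface(m_ci, qp, gauge_ref = ad0$vectors)$vectors
    vm <- adiabatic_surface(m_ci, qm, gauge_ref = ad0$vectors)$vectors
    sum(ad0$vectors[, 2] * (vp[, 1] - vm[, 1])) / (2 * h)
  }, numeric(1))
  expect_lt(abs(coupling_magnitude(x, m_ci, 1L) - sqrt(sum(dfd^2))), 1e-5)
})

test_that("spawning-mode entry requires both coupling and population", {
  p <- sim_params(csthresh = 0.5, poptospawn = 0.01)
  weak <- tbf(2, R = c(-3, 0.1), P = c(0, 0), alpha = 0.5, id = "w")
  strong <- tbf(2, R = c(1.9, 0.25), P = c(1, 0), alpha = 0.5, id = "s")
  stopifnot(coupling_magnitude(strong, m_ci, 1L) > 0.5)

  set1 <- coupled_set(list(weak), complex(real = 1))
  S1 <- matrix(1 + 0i, 1, 1)
  chk <- check_entry(weak, set1, S1, m_ci, p, 1L)
  expect_false(chk$enter)
  expect_equal(chk$reason, "coupling")

  # population below poptospawn: skip with reason "population"
  set2 <- coupled_set(list(strong, weak), c(sqrt(0.005), sqrt(0.995)))
  S2 <- diag(2) + 0i
  chk2 <- check_entry(strong, set2, S2, m_ci, p, 1L)
  expect_false(chk2$enter)
  expect_equal(chk2$reason, "population")

  set3 <- coupled_set(list(strong), complex(real = 1))
  expect_true(check_entry(strong, set3, S1, m_ci, p, 1L)$enter)
})

test_that("child momentum rescaling conserves classical energy or rejects", {
  R <- c(1.9, 0.4); P <- c(1.5, 0.2)
  E_tot <- sum(P^2 * m_ci$omega / 2) + adiabatic_surface(m_ci, R)$energies[2]
  nv <- nac_vector(m_ci, R, 2, 1)
  Pc <- aimsim:::rescale_momentum(P, m_ci, E_tot, R, 1L, nv)
  E_child <- sum(Pc^2 * m_ci$omega / 2) +
    adiabatic_surface(m_ci, R)$energies[1]
  expect_equal(E_child, E_tot, tolerance = 1e-10)
  # the adjustment is along the coupling vector
  dP <- Pc - P
  expect_lt(abs(dP[1] * nv[2] - dP[2] * nv[1]), 1e-10)

  # spawning upward with too little energy is classically forbidden
  E_low <- adiabatic_surface(m_ci, R)$energies[1] + 1e-3
  expect_null(aimsim:::rescale_momentum(c(0.05, 0.02), m_ci, E_low, R, 2L, nv))
})

test_that("overlap acceptance tests implement both roles of omax", {
  p <- sim_params(omax = 0.6)
  parent <- tbf(2, R = c(0, 0), P = c(1, 0), alpha = 0.5, id = "p")
  near <- tbf(1, R = c(0.05, 0), P = c(1.1, 0), alpha = 0.5, id = "c")
  # child identical to an existing TBF: redundant
  existing <- near; existing$state <- 1L; existing$id <- "e"
  res <- omax_tests(near, parent, near, list(existing), p)
  expect_false(res$accept)
  expect_equal(res$reason, "redundant")

  # parent overlap just under threshold: rejected with reason parent-overlap
  d_for <- function(d) tbf(1, R = c(d, 0), P = c(1, 0), alpha = 0.5, id = "c2")
  # |overlap| = exp(-alpha d^2 / 2); choose overlap ~ 0.59
  d59 <- sqrt(-2 * log(0.59) / 0.5)
  res2 <- omax_tests(d_for(d59), parent, d_for(d59), list(), p)
  expect_false(res2$accept)
  expect_equal(res2$reason, "parent-overlap")

  # clean accept: strong parent overlap, empty swarm
  res3 <- omax_tests(near, parent, near, list(), p)
  expect_true(res3$accept)

  # split thresholds reproduce the single-parameter behaviour when equal
  p_split <- sim_params(omax = 0.6, omax_parent = 0.6, omax_swarm = 0.6)
  for (d in c(0.3, d59, 1.5)) {
    r1 <- omax_tests(d_for(d), parent, d_for(d), list(existing), p)
    r2 <- omax_tests(d_for(d), parent, d_for(d), list(existing), p_split)
    expect_identical(r1$accept, r2$accept)
  }
})

test_that("spawning mode finds the indicator maximum and yields a valid child", {
  p <- sim_params()
  # parent heading into the intersection region on the upper state
  parent <- tbf(2, R = c(0.8, 0.45), P = c(1.2, -0.1), alpha = 0.5, id = "par")
  set <- coupled_set(list(parent), complex(real = 1))
  sp <- run_spawning_mode(parent, set, m_ci, p, 1L, t_entry = 3.0)
  expect_true(sp$event$accepted)
  expect_gte(sp$event$t_max, sp$event$t_entry)
  child <- sp$child
  expect_equal(child$state, 1L)
  expect_equal(child$parent_id, "par")
  expect_equal(child$birth_time, 3.0)
  # child accepted means parent-child overlap at the spawning geometry
  # exceeded omax; indicator at the located maximum exceeds the threshold
  expect_gte(sp$event$indicator, p$csthresh)

  # classical back-then-forward propagation is reversible
  back <- propagate_tbf(propagate_tbf(parent, m_ci, 0.025), m_ci, -0.025)
  expect_lt(max(abs(back$R - parent$R)), 1e-10)
  expect_lt(max(abs(back$P - parent$P)), 1e-10)
})

test_that("monotonically decreasing indicator puts the maximum at entry", {
  p <- sim_params(csthresh = 1e-4, spawn_cap = 8L)
  # parent moving away from the intersection: indicator decays from entry
  parent <- tbf(2, R = c(-1.5, 0.3), P = c(-2, 0), alpha = 0.5, id = "awy")
  set <- coupled_set(list(parent), complex(real = 1))
  sp <- run_spawning_mode(parent, set, m_ci, p, 1L, t_entry = 1.0)
  expect_equal(sp$event$t_max, 1.0, tolerance = 1e-12)
})

test_that("accepted spawns grow the set by one and leave the norm unchanged", {
  p <- sim_params(t_final = 12)
  ic <- list(R0 = c(0.2, 0.6), P0 = c(0.1, -0.2))
  r <- run_ic(ic, m_ci, p)
  acc <- r$spawn_log[r$spawn_log$accepted, ]
  expect_gte(nrow(acc), 1)
  # n_tbfs trace increments by exactly 1 at each accepted spawn
  jumps <- diff(r$n_tbfs)
  expect_true(all(jumps >= 0))
  expect_equal(sum(jumps), nrow(acc))
  # norm continuity across spawns: child enters with zero coefficient
  for (te in acc$t_entry) {
    i <- which.min(abs(r$times - te))
    if (i > 1 && i < length(r$norm))
      expect_lt(abs(r$norm[i + 1] - r$norm[i - 1]), 5e-4)
  }
})

test_that("a threshold above the global indicator maximum suppresses spawning", {
  p <- sim_params(csthresh = 1e6, t_final = 8)
  r <- run_ic(list(R0 = c(0.3, 0.4), P0 = c(0, 0)), m_ci, p)
  expect_equal(nrow(r$spawn_log), 0L)
  expect_equal(max(abs(r$populations[, 2] - 1)), 0, tolerance = 1e-9)
})
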