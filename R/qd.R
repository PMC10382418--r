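#' Coordinate grid for quantum dynamics
#'
#' Rectangular grid, one axis per mode.  The kinetic propagator uses the
#' discrete Fourier transform, so the grid is periodic; the ranges must be
#' wide enough that the wavepacket never reaches the boundary (checked
#' during propagation).
#'
#' @param ranges list (or 2-vector for one mode) of \code{c(min, max)} per
#'   mode.
#' @param n points per mode (recycled).
#' @return object of class \code{qd_grid} with axes, spacings, and
#'   wavenumber axes.
#' @export
qd_grid <- function(ranges, n = 256L) {
  if (is.numeric(ranges) && length(ranges) == 2L) ranges <- list(ranges)
  n <- rep_len(as.integer(n), length(ranges))
  axes <- lapply(seq_along(ranges), function(i) {
    r <- ranges[[i]]
    seq(r[1], r[2], length.out = n[i] + 1L)[seq_len(n[i])]  # periodic
  })
  dx <- vapply(seq_along(axes), function(i) axes[[i]][2] - axes[[i]][1],
               numeric(1))
  kaxes <- lapply(seq_along(axes), function(i) {
    ni <- n[i]
    2 * pi / (ni * dx[i]) * c(0:(ni %/% 2 - 1L), -(ni - ni %/% 2):-1L)
  })
  structure(list(axes = axes, n = n, dx = dx, kaxes = kaxes,
                 n_modes = length(axes)), class = "qd_grid")
}

grid_volume_element <- function(grid) prod(grid$dx)

# outer product of per-mode vectors -> full-grid array
grid_outer <- function(vecs) {
  out <- vecs[[1L]]
  if (length(vecs) > 1L)
    for (i in 2:length(vecs)) out <- outer(out, vecs[[i]])
  array(out, dim = vapply(vecs, length, integer(1)))
}

#' Multi-state grid wavefunction
#'
#' Complex amplitude arrays, one per diabatic state, on a \code{qd_grid}.
#' \code{qd_gaussian} initialises a normalised Gaussian wavepacket
#' \eqn{\prod_\rho (2\alpha_\rho/\pi)^{1/4} e^{-\alpha_\rho (q_\rho-R_\rho)^2
#' + i P_\rho (q_\rho - R_\rho)}} on one state.
#'
#' @param grid a \code{qd_grid}.
#' @param n_states number of electronic states.
#' @param R,P centre position and momentum.
#' @param alpha per-mode widths.
#' @param state the populated diabatic/adiabatic state index.
#' @return object of class \code{grid_wavefunction}: list of state arrays
#'   plus the grid and time.
#' @export
qd_gaussian <- function(grid, n_states, R, P, alpha, state = 1L) {
  R <- rep_len(R, grid$n_modes); P <- rep_len(P, grid$n_modes)
  alpha <- rep_len(alpha, grid$n_modes)
  g1 <- lapply(seq_len(grid$n_modes), function(i) {
    x <- grid$axes[[i]]
    (2 * alpha[i] / pi)^0.25 *
      exp(-alpha[i] * (x - R[i])^2 + 1i * P[i] * (x - R[i]))
  })
  psi <- vector("list", n_states)
  zero <- array(0i, dim = grid$n)
  for (m in seq_len(n_states)) psi[[m]] <- zero
  psi[[state]] <- grid_outer(g1)
  structure(list(psi = psi, grid = grid, t = 0), class = "grid_wavefunction")
}

#' Total norm of a grid wavefunction
#' @param wf a \code{grid_wavefunction}.
#' @return scalar (Riemann sum).
#' @export
qd_norm <- function(wf) {
  sum(vapply(wf$psi, function(a) sum(abs(a)^2), numeric(1))) *
    grid_volume_element(wf$grid)
}

# precompute pointwise diabatic eigen-decompositions over the whole grid;
# returns list(vals = list per state of arrays, vecs = M x M x npts matrix)
grid_eigensystem <- function(model, grid) {
  M <- model$n_states
  qs <- grid$axes
  npts <- prod(grid$n)
  idx <- arrayInd(seq_len(npts), .dim = grid$n)
  vals <- matrix(0, npts, M)
  vecs <- array(0, c(M, M, npts))
  if (M == 2L) {
    # vectorised closed form
    Q <- sapply(seq_len(grid$n_modes), function(i) qs[[i]][idx[, i]])
    Q <- matrix(Q, npts, grid$n_modes)
    harm <- as.numeric(Q^2 %*% (model$omega / 2))
    d1 <- model$E_vert[1] + as.numeric(Q %*% model$kappa[1, ]) + harm
    d2 <- model$E_vert[2] + as.numeric(Q %*% model$kappa[2, ]) + harm
    off <- as.numeric(Q %*% model$lam[1, 2, ]) + model$lam0[1, 2]
    m <- (d1 + d2) / 2; dd <- (d1 - d2) / 2; r <- sqrt(dd^2 + off^2)
    vals[, 1] <- m - r; vals[, 2] <- m + r
    tiny <- abs(off) < 1e-14
    v2a <- off; v2b <- r - dd
    nrm2 <- sqrt(v2a^2 + v2b^2)
    v1a <- (r - dd) / pmax(nrm2, 1e-300); v1b <- -off / pmax(nrm2, 1e-300)
    v2a <- v2a / pmax(nrm2, 1e-300); v2b <- v2b / pmax(nrm2, 1e-300)
    # uncoupled points: identity (or swap if diabat 1 above diabat 2)
    swap <- tiny & (dd > 0)
    keepid <- tiny & !swap
    v1a[keepid] <- 1; v1b[keepid] <- 0; v2a[keepid] <- 0; v2b[keepid] <- 1
    v1a[swap] <- 0; v1b[swap] <- 1; v2a[swap] <- 1; v2b[swap] <- 0
    vecs[1, 1, ] <- v1a; vecs[2, 1, ] <- v1b
    vecs[1, 2, ] <- v2a; vecs[2, 2, ] <- v2b
  } else {
    for (p in seq_len(npts)) {
      q <- vapply(seq_len(grid$n_modes), function(i) qs[[i]][idx[p, i]],
                  numeric(1))
      ad <- adiabatic_surface(model, q)
      vals[p, ] <- ad$energies
      vecs[, , p] <- ad$vectors
    }
  }
  list(vals = vals, vecs = vecs, npts = npts)
}

#' Split-operator propagation of a grid wavefunction
#'
#' Strang splitting: half-step in the diabatic potential matrix (pointwise
#' matrix exponential through the precomputed eigen-decomposition), full
#' kinetic step in momentum space (FFT), half potential step.  Strictly
#' norm-conserving.  Errors out if probability reaches the grid boundary.
#'
#' @param wf a \code{grid_wavefunction}.
#' @param model an \code{lvc_model} (defines the diabatic potential).
#' @param dt time step (atomic time units).
#' @param n_steps number of steps.
#' @param record optional function \code{f(wf, step)} called after every
#'   step whose results are collected and returned.
#' @param boundary_tol maximum admissible boundary amplitude density.
#' @return the propagated \code{grid_wavefunction}; if \code{record} is
#'   supplied, a list with \code{wf} and \code{records}.
#' @export
propagate_split_operator <- function(wf, model, dt, n_steps, record = NULL,
                                     boundary_tol = 1e-8) {
  grid <- wf$grid
  M <- length(wf$psi)
  es <- grid_eigensystem(model, grid)
  dims <- grid$n
  # half-step potential propagator, per pair of states (M small)
  ph <- exp(-1i * (dt / 2) * es$vals)            # npts x M
  U <- vector("list", M * M)                     # U[[i + (j-1)M]] arrays
  for (i in seq_len(M)) for (j in seq_len(M)) {
    acc <- 0i
    for (m in seq_len(M))
      acc <- acc + es$vecs[i, m, ] * ph[, m] * es$vecs[j, m, ]
    U[[i + (j - 1L) * M]] <- array(acc, dim = dims)
  }
  # kinetic phase: exp(-i dt sum_rho omega_rho k^2 / 2)
  kin <- grid_outer(lapply(seq_len(grid$n_modes), function(i)
    exp(-1i * dt * model$omega[i] * grid$kaxes[[i]]^2 / 2)))
  if (grid$n_modes == 1L) kin <- array(kin, dim = dims)

  apply_pot_half <- function(psi) {
    out <- vector("list", M)
    for (i in seq_len(M)) {
      acc <- array(0i, dim = dims)
      for (j in seq_len(M)) acc <- acc + U[[i + (j - 1L) * M]] * psi[[j]]
      out[[i]] <- acc
    }
    out
  }
  npts <- prod(dims)
  records <- if (!is.null(record)) vector("list", n_steps) else NULL
  psi <- wf$psi
  for (s in seq_len(n_steps)) {
    psi <- apply_pot_half(psi)
    for (m in seq_len(M)) {
      pk <- stats::fft(psi[[m]]) * kin
      psi[[m]] <- stats::fft(pk, inverse = TRUE) / npts
    }
    psi <- apply_pot_half(psi)
    wf$psi <- psi
    wf$t <- wf$t + dt
    if (!is.null(record)) records[[s]] <- record(wf, s)
  }
  # boundary check: probability density on the outermost grid planes
  bmax <- 0
  for (i in seq_len(grid$n_modes)) {
    for (m in seq_len(M)) {
      sl <- slice.index(psi[[m]], i)
      bmax <- max(bmax, max(abs(psi[[m]][sl == 1 | sl == dims[i]])^2))
    }
  }
  if (bmax > boundary_tol)
    stop(sprintf(paste0("wavepacket reached the grid boundary (density ",
                        "%.2e > %.0e); enlarge the grid ranges"),
                 bmax, boundary_tol))
  if (!is.null(record)) return(list(wf = wf, records = records))
  wf
}

#' Adiabatic state populations of a grid wavefunction
#'
#' Rotates the diabatic spinor into the adiabatic basis pointwise and
#' integrates the per-component density.
#'
#' @param wf a \code{grid_wavefunction}.
#' @param model an \code{lvc_model}.
#' @return numeric vector of per-adiabatic-state populations (sums to the
#'   total norm).
#' @export
adiabatic_populations <- function(wf, model) {
  es <- grid_eigensystem(model, wf$grid)
  M <- length(wf$psi)
  psi_flat <- vapply(wf$psi, as.vector, complex(es$npts))
  psi_flat <- matrix(psi_flat, es$npts, M)
  pops <- numeric(M)
  for (J in seq_len(M)) {
    amp <- complex(es$npts)
    for (m in seq_len(M)) amp <- amp + es$vecs[m, J, ] * psi_flat[, m]
    pops[J] <- sum(abs(amp)^2)
  }
  pops * grid_volume_element(wf$grid)
}

#' Position expectation value of a grid wavefunction
#'
#' @param wf a \code{grid_wavefunction}.
#' @return numeric vector \eqn{\langle q \rangle} over modes (summed over
#'   states, normalised).
#' @export
qd_position_expectation <- function(wf) {
  grid <- wf$grid
  dens <- nuclear_density(wf)
  dV <- grid_volume_element(grid)
  nrm <- sum(dens) * dV
  vapply(seq_len(grid$n_modes), function(i) {
    qi <- grid$axes[[i]][slice.index(dens, i)]
    sum(qi * dens) * dV / nrm
  }, numeric(1))
}

#' Nuclear density
#'
#' For a grid wavefunction: the state-summed density \eqn{\sum_m
#' |\psi_m|^2}.  For an AIMS coupled set: the per-state coherent sums
#' \eqn{|\sum_{k \in J} C_k \chi_k|^2} evaluated on the grid and summed
#' over states.
#'
#' @param x a \code{grid_wavefunction} or a \code{coupled_set}.
#' @param grid a \code{qd_grid} (required for a coupled set).
#' @param ... unused.
#' @return real array on the grid.
#' @export
nuclear_density <- function(x, grid = NULL, ...) UseMethod("nuclear_density")

#' @export
nuclear_density.grid_wavefunction <- function(x, grid = NULL, ...) {
  out <- abs(x$psi[[1L]])^2
  if (length(x$psi) > 1L)
    for (m in 2:length(x$psi)) out <- out + abs(x$psi[[m]])^2
  out
}

# evaluate one TBF on the grid
tbf_on_grid <- function(x, grid) {
  g1 <- lapply(seq_len(grid$n_modes), function(i) {
    q <- grid$axes[[i]]
    (2 * x$alpha[i] / pi)^0.25 *
      exp(-x$alpha[i] * (q - x$R[i])^2 + 1i * x$P[i] * (q - x$R[i]))
  })
  grid_outer(g1) * exp(1i * x$gamma)
}

#' @export
nuclear_density.coupled_set <- function(x, grid = NULL, ...) {
  if (is.null(grid)) stop("a qd_grid is required for a coupled set")
  states <- set_states(x)
  out <- array(0, dim = grid$n)
  for (J in unique(states)) {
    amp <- array(0i, dim = grid$n)
    for (k in which(states == J))
      amp <- amp + x$C[k] * tbf_on_grid(x$tbfs[[k]], grid)
    out <- out + abs(amp)^2
  }
  out
}

#' Exact quantum-dynamics reference run
#'
#' Propagates an initial Gaussian wavepacket (matching the AIMS initial
#' TBF at the Franck-Condon point) with the split-operator scheme and
#' records adiabatic populations on an output grid, producing the same
#' trace schema as an AIMS run for direct comparison.
#'
#' @param model an \code{lvc_model}.
#' @param grid a \code{qd_grid}.
#' @param dt QD time step.
#' @param t_final end time.
#' @param R0,P0 initial wavepacket centre (defaults: Franck-Condon point at
#'   rest).
#' @param alpha widths (default: ground-state widths 1/2).
#' @param initial_state initially populated adiabatic state.
#' @param n_record number of output times.
#' @param boundary_tol maximum admissible probability density on the grid
#'   boundary.  Adiabatic-state preparation imprints a conical kink on the
#'   diabatic components at the intersection whose Fourier tail decays only
#'   algebraically, so intersection models need a looser tolerance than the
#'   default (the packet itself stays far from the boundary).
#' @return object of class \code{qd_run} with \code{times},
#'   \code{populations} (adiabatic), \code{norm}, and the final
#'   wavefunction.
#' @export
qd_run <- function(model, grid, dt, t_final, R0 = 0, P0 = 0, alpha = 0.5,
                   initial_state = 2L, n_record = 200L, boundary_tol = 1e-8) {
  wf <- qd_gaussian(grid, model$n_states, R0, P0, alpha,
                    state = initial_state)
  # rotate the initial diabatic spinor so the packet starts on one
  # *adiabatic* state: psi_dia_m = V[m, J] * packet
  es <- grid_eigensystem(model, grid)
  packet <- as.vector(wf$psi[[initial_state]])
  for (m in seq_len(model$n_states))
    wf$psi[[m]] <- array(es$vecs[m, initial_state, ] * packet, dim = grid$n)
  n_steps <- ceiling(t_final / dt)
  every <- max(1L, floor(n_steps / n_record))
  res <- propagate_split_operator(wf, model, dt, n_steps,
                                  boundary_tol = boundary_tol,
                                  record = function(w, s) {
                                    if (s %% every == 0L || s == n_steps)
                                      c(w$t, adiabatic_populations(w, model),
                                        qd_norm(w))
                                    else NULL
                                  })
  recs <- do.call(rbind, Filter(Negate(is.null), res$records))
  M <- model$n_states
  structure(list(times = c(0, recs[, 1]),
                 populations = rbind(
                   replace(numeric(M), initial_state, 1), recs[, 2:(M + 1)]),
                 norm = c(1, recs[, M + 2]),
                 wf = res$wf, dt = dt), class = "qd_run")
}

#' @export
print.qd_run <- function(x, ...) {
  cat(sprintf("QD reference run to t = %.2f atu (dt = %g)\n",
              max(x$times), x$dt))
  cat("  final adiabatic populations:",
      format(x$populations[nrow(x$populations), ], digits = 4), "\n")
  invisible(x)
}

#' @export
plot.qd_run <- function(x, ...) {
  graphics::matplot(x$times, x$populations, type = "l", lty = 2,
                    xlab = "time (atu)", ylab = "adiabatic population", ...)
  invisible(x)
}
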