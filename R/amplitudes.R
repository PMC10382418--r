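#' Simulation parameters
#'
#' User-facing thresholds and settings of an AIMS run, named after their
#' FMS90 counterparts where one exists.
#'
#' @param timestep base nuclear time step (atomic time units).
#' @param t_final propagation end time (atomic time units).
#' @param csthresh nonadiabatic-coupling magnitude (per coordinate unit)
#'   above which a TBF enters the spawning mode.
#' @param poptospawn minimum Mulliken population of a TBF for it to be
#'   allowed to spawn.
#' @param omax overlap threshold of the spawning tests: the child must
#'   overlap its parent by at least \code{omax} at the spawning geometry and
#'   must not overlap any other existing TBF by more than \code{omax} once
#'   backpropagated.  \code{omax_parent}/\code{omax_swarm} split the single
#'   threshold into its two roles.
#' @param olapthresh overlap-screening threshold: Hamiltonian and
#'   time-derivative couplings are only computed for TBF pairs whose
#'   absolute overlap exceeds it.
#' @param regthresh eigenvalue threshold for the regularised inversion of
#'   the overlap matrix.
#' @param widths per-coordinate TBF width vector, or \code{NULL} to match
#'   the vibrational ground state of the model (\eqn{\alpha_i = 1/2} in
#'   dimensionless modes).
#' @param n_ic number of initial conditions for an ensemble.
#' @param seed RNG seed for Wigner sampling.
#' @param initial_state electronic state populated at t = 0 (adiabatic
#'   index, ascending energy).
#' @param factor time-step reduction factor inside coupling regions.
#' @param dt_min_frac minimum admissible step, as a fraction of
#'   \code{timestep}.
#' @param norm_tol,energy_tol per-step drift tolerances for step rejection.
#' @param spawn_cap maximum duration of a spawning mode, in base steps.
#' @param n_sub minimum number of RK4 substeps per nuclear step for the
#'   amplitude equations (substep length at most \code{timestep}/4).
#' @param omax_parent,omax_swarm optional split thresholds; default to
#'   \code{omax}.
#' @param hermitize Hermitize the assembled Hamiltonian matrix (the SPA0
#'   coupling block is not automatically Hermitian); disabling this is only
#'   useful for diagnostics.
#' @return object of class \code{sim_params}.
#' @export
sim_params <- function(timestep = 0.1, t_final = 30, csthresh = 0.5,
                       poptospawn = 0.001, omax = 0.6, olapthresh = 0.001,
                       regthresh = 1e-4, widths = NULL, n_ic = 100L,
                       seed = 1L, initial_state = 2L, factor = 4,
                       dt_min_frac = 1 / 64, norm_tol = 1e-4,
                       energy_tol = 1e-4, spawn_cap = 100L, n_sub = 4L,
                       omax_parent = omax, omax_swarm = omax,
                       hermitize = TRUE) {
  stopifnot(timestep > 0, t_final > 0, csthresh >= 0, poptospawn >= 0,
            omax >= 0, omax <= 1, olapthresh >= 0, olapthresh <= 1,
            regthresh >= 0, n_ic >= 1, factor > 1)
  structure(list(timestep = timestep, t_final = t_final, csthresh = csthresh,
                 poptospawn = poptospawn, omax = omax,
                 omax_parent = omax_parent, omax_swarm = omax_swarm,
                 olapthresh = olapthresh, regthresh = regthresh,
                 widths = widths, n_ic = as.integer(n_ic),
                 seed = as.integer(seed),
                 initial_state = as.integer(initial_state), factor = factor,
                 dt_min_frac = dt_min_frac, norm_tol = norm_tol,
                 energy_tol = energy_tol, spawn_cap = as.integer(spawn_cap),
                 n_sub = as.integer(n_sub), hermitize = hermitize),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("AIMS simulation parameters:\n")
  for (nm in c("timestep", "t_final", "csthresh", "poptospawn", "omax",
               "olapthresh", "regthresh", "n_ic", "seed", "initial_state"))
    cat(sprintf("  %-13s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Coupled set of TBFs
#'
#' An ordered collection of TBFs descending from one ancestor, together
#' with the complex amplitude vector.  All TBFs share a common time.
#'
#' @param tbfs list of \code{tbf} objects.
#' @param C complex amplitude vector aligned with \code{tbfs}.
#' @param t current time (atomic time units).
#' @return object of class \code{coupled_set}.
#' @export
coupled_set <- function(tbfs, C, t = 0) {
  if (length(tbfs) != length(C)) stop("C must align with tbfs")
  structure(list(tbfs = tbfs, C = as.complex(C), t = t),
            class = "coupled_set")
}

set_states <- function(set) vapply(set$tbfs, `[[`, integer(1), "state")

# floored NAC evaluation for matrix assembly: near a degeneracy the gap in
# the denominator is clamped at `floor` (sign preserved) instead of raising
nac_vector_floored <- function(model, q, I, J, floor = 1e-8) {
  ep_nac_floored(model, q, eval_point(model, q), I, J, floor)
}

#' Assemble the overlap, time-derivative and Hamiltonian matrices
#'
#' Builds S, \eqn{\dot S} and H (under the zeroth-order saddle-point
#' approximation) for a coupled set.  Same-state pairs receive the nuclear
#' kinetic element plus the adiabatic energy at the pair centroid times the
#' overlap; different-state pairs receive the first-order nonadiabatic
#' coupling term \eqn{-\sum_\rho (1/M_\rho)\, d_{IJ,\rho}(\bar R_{kk'})
#' \langle\chi_k|\partial_\rho|\chi_{k'}\rangle}; second-order couplings
#' are omitted.  Pairs whose absolute overlap falls below
#' \code{olapthresh} have their H and \eqn{\dot S} couplings set to zero
#' (S itself is kept exact).  H is Hermitized after assembly unless
#' \code{params$hermitize} is \code{FALSE}.
#'
#' @param set a \code{coupled_set}.
#' @param model an \code{lvc_model}.
#' @param params a \code{sim_params}.
#' @param gauge optional environment caching, per TBF pair, the adiabatic
#'   eigenvectors of the previous evaluation at that pair's centroid.  The
#'   eigenvector sign at each new evaluation is chosen to maximise overlap
#'   with the cached one, keeping the sign of the nonadiabatic coupling --
#'   and hence of the cross-state Hamiltonian elements -- continuous in
#'   time along the pair's path.  Without it the gauge is fixed pointwise
#'   (largest component positive), which flips sign across the seam and
#'   makes the two halves of a crossing's transfer integral cancel.
#' @return list with complex matrices \code{S}, \code{Sdot}, \code{H}, the
#'   full cross-state overlap magnitudes \code{S_nuc}, the number of
#'   model-potential (centroid) evaluations \code{n_pot_evals}, and a
#'   logical \code{degeneracy_clamped}.
#' @export
assemble_matrices <- function(set, model, params, gauge = NULL) {
  tbfs <- set$tbfs
  N <- length(tbfs)
  nm <- model$n_modes
  states <- set_states(set)
  Rm <- vapply(tbfs, `[[`, numeric(nm), "R")      # nm x N (nm>1) or vector
  Pm <- vapply(tbfs, `[[`, numeric(nm), "P")
  Am <- vapply(tbfs, `[[`, numeric(nm), "alpha")
  Rm <- matrix(Rm, nm, N); Pm <- matrix(Pm, nm, N); Am <- matrix(Am, nm, N)
  gam <- vapply(tbfs, `[[`, numeric(1), "gamma")

  if (model$n_states == 2L) {
    ev <- ev2_cols(model, Rm)
    dRm <- Pm * model$omega
    dPm <- -ev2_gradient(model, ev, states)
    EJ <- ev$E1; EJ[states == 2L] <- ev$E2[states == 2L]
    dgam <- colSums(Pm * Pm * model$omega) / 2 - EJ
  } else {
    dyn <- lapply(tbfs, tbf_dynamics, model = model)
    dRm <- matrix(vapply(dyn, `[[`, numeric(nm), "dR"), nm, N)
    dPm <- matrix(vapply(dyn, `[[`, numeric(nm), "dP"), nm, N)
    dgam <- vapply(dyn, `[[`, numeric(1), "dgamma")
  }

  ones <- rep(1, N)
  S_nuc <- matrix(1 + 0i, N, N)       # product of 1-D overlaps, no phase
  kin_ratio <- matrix(0i, N, N)
  sdot_ratio <- matrix(0i, N, N)
  deriv_arr <- array(0i, c(nm, N, N))
  for (r in seq_len(nm)) {
    aa <- outer(Am[r, ], ones); ab <- outer(ones, Am[r, ])
    Ra <- outer(Rm[r, ], ones); Rb <- outer(ones, Rm[r, ])
    Pa <- outer(Pm[r, ], ones); Pb <- outer(ones, Pm[r, ])
    c2 <- aa + ab
    c1 <- 2 * aa * Ra + 2 * ab * Rb + 1i * (Pb - Pa)
    c0 <- -aa * Ra^2 - ab * Rb^2 + 1i * (Pa * Ra - Pb * Rb)
    S_nuc <- S_nuc * ((2 * aa / pi)^0.25 * (2 * ab / pi)^0.25 *
                        sqrt(pi / c2) * exp(c0 + c1^2 / (4 * c2)))
    mu1 <- c1 / (2 * c2)
    mu2 <- mu1^2 + 1 / (2 * c2)
    kin_ratio <- kin_ratio + (model$omega[r] / 2) *
      -(4 * ab^2 * (mu2 - 2 * Rb * mu1 + Rb^2) -
          4i * ab * Pb * (mu1 - Rb) - (Pb^2 + 2 * ab))
    deriv_arr[r, , ] <- -2 * ab * (mu1 - Rb) + 1i * Pb
    dRb <- outer(ones, dRm[r, ]); dPb <- outer(ones, dPm[r, ])
    sdot_ratio <- sdot_ratio + dRb * (2 * ab * (mu1 - Rb) - 1i * Pb) +
      dPb * 1i * (mu1 - Rb)
  }
  phase <- outer(exp(-1i * gam), exp(1i * gam))
  S_full <- S_nuc * phase
  same <- outer(states, states, `==`)

  S <- S_full * same
  Sdot <- S_full * (sdot_ratio + 1i * outer(ones, dgam)) * same
  H <- matrix(0i, N, N)

  absS <- abs(S_full)
  clamped <- FALSE
  # unordered pair list surviving the overlap screen (diagonal always kept)
  ij <- which(upper.tri(absS, diag = TRUE) &
                (absS >= params$olapthresh | diag(N) > 0), arr.ind = TRUE)
  n_evals <- nrow(ij)
  cen <- (Am[, ij[, 1], drop = FALSE] * Rm[, ij[, 1], drop = FALSE] +
            Am[, ij[, 2], drop = FALSE] * Rm[, ij[, 2], drop = FALSE]) /
    (Am[, ij[, 1], drop = FALSE] + Am[, ij[, 2], drop = FALSE])
  ids <- vapply(tbfs, `[[`, character(1), "id")
  if (model$n_states == 2L) {
    evc <- ev2_cols(model, cen)
    nacc <- ev2_nac12(model, evc)
    for (p in seq_len(n_evals)) {
      i <- ij[p, 1L]; j <- ij[p, 2L]
      if (states[i] == states[j]) {
        EJ <- if (states[i] == 1L) evc$E1[p] else evc$E2[p]
        H[i, j] <- (kin_ratio[i, j] + EJ) * S_full[i, j]
        if (j > i) H[j, i] <- (kin_ratio[j, i] + EJ) * S_full[j, i]
      } else {
        d12 <- nacc$d[, p]                    # d for states (1 -> 2)
        clamped <- clamped || nacc$clamped[p]
        if (!is.null(gauge)) {
          key <- paste0(ids[i], "|", ids[j])
          vc <- c(evc$v11[p], evc$v21[p], evc$v12[p], evc$v22[p])
          prev <- gauge[[key]]
          if (!is.null(prev)) {
            s1 <- sign(vc[1L] * prev[1L] + vc[2L] * prev[2L])
            s2 <- sign(vc[3L] * prev[3L] + vc[4L] * prev[4L])
            if (s1 == 0) s1 <- 1
            if (s2 == 0) s2 <- 1
            if (s1 < 0) vc[1:2] <- -vc[1:2]
            if (s2 < 0) vc[3:4] <- -vc[3:4]
            d12 <- d12 * (s1 * s2)
          }
          gauge[[key]] <- vc
        }
        sgn_ij <- if (states[i] == 1L) 1 else -1
        H[i, j] <- -sum(model$omega * (sgn_ij * d12) * deriv_arr[, i, j]) *
          S_full[i, j]
        H[j, i] <- -sum(model$omega * (-sgn_ij * d12) * deriv_arr[, j, i]) *
          S_full[j, i]
      }
    }
  } else {
    for (p in seq_len(n_evals)) {
      i <- ij[p, 1L]; j <- ij[p, 2L]
      ep <- eval_point(model, cen[, p])
      if (states[i] == states[j]) {
        EJ <- ep$E[states[i]]
        H[i, j] <- (kin_ratio[i, j] + EJ) * S_full[i, j]
        if (j > i) H[j, i] <- (kin_ratio[j, i] + EJ) * S_full[j, i]
      } else {
        if (!is.null(gauge)) {
          key <- paste0(ids[i], "|", ids[j])
          V <- matrix(ep$V, model$n_states)
          prev <- gauge[[key]]
          if (!is.null(prev)) {
            for (cl in seq_len(ncol(V))) {
              s <- sign(sum(V[, cl] * prev[, cl]))
              if (s < 0) V[, cl] <- -V[, cl]
            }
          }
          gauge[[key]] <- V
          ep$V <- V
        }
        nv <- ep_nac_floored(model, cen[, p], ep, states[i], states[j])
        clamped <- clamped || nv$clamped
        H[i, j] <- -sum(model$omega * nv$d * deriv_arr[, i, j]) * S_full[i, j]
        H[j, i] <- -sum(model$omega * (-nv$d) * deriv_arr[, j, i]) *
          S_full[j, i]
      }
    }
  }
  # screening of Sdot couplings (S kept exact; H already skipped above)
  if (params$olapthresh > 0) {
    off <- !diag(N) & absS < params$olapthresh
    Sdot[off] <- 0i
  }
  if (isTRUE(params$hermitize)) H <- (H + Conj(t(H))) / 2
  list(S = S, Sdot = Sdot, H = H, S_nuc = absS, n_pot_evals = n_evals,
       degeneracy_clamped = clamped)
}

#' Regularised inverse of the overlap matrix
#'
#' Eigendecomposition-based pseudo-inverse: eigenvalues of the Hermitian
#' overlap matrix below \code{regthresh} are discarded and the inverse is
#' formed on the retained subspace.
#'
#' @param S Hermitian (complex) matrix.
#' @param regthresh eigenvalue retention threshold.
#' @return complex matrix of the same dimension.
#' @export
regularized_inverse <- function(S, regthresh) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values >= regthresh
  if (!any(keep))
    stop("overlap matrix has no eigenvalue above the regularisation ",
         "threshold (degenerate basis)")
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(Conj(V)) / e$values[keep])
}

amp_deriv <- function(C, S, Sdot, H, regthresh) {
  -1i * (regularized_inverse(S, regthresh) %*% ((H - 1i * Sdot) %*% C))
}

#' Propagate the complex amplitudes over one nuclear step
#'
#' Integrates \eqn{dC/dt = -i S^{-1} (H - i\dot S) C} across one nuclear
#' time step with a fixed-step 4th-order Runge-Kutta scheme, linearly
#' interpolating S, \eqn{\dot S} and H between the step endpoints.  The
#' substep length never exceeds a quarter of the nuclear step.
#'
#' @param C complex amplitude vector at the start of the step.
#' @param mats0,mats1 matrix sets (as returned by
#'   \code{\link{assemble_matrices}}) at the step start and end.
#' @param dt nuclear step length.
#' @param regthresh regularisation threshold for the overlap inversion.
#' @param n_sub minimum number of RK4 substeps (at least 4).
#' @return the amplitude vector at the end of the step.
#' @export
propagate_coefficients <- function(C, mats0, mats1, dt, regthresh,
                                   n_sub = 4L) {
  n_sub <- max(4L, as.integer(n_sub))
  h <- dt / n_sub
  # interpolation nodes k/(2 n_sub): each substep uses nodes 2k-2, 2k-1, 2k;
  # the regularised inverse is computed once per node
  n_nodes <- 2L * n_sub + 1L
  nodes <- lapply(seq_len(n_nodes) - 1L, function(k) {
    x <- k / (2 * n_sub)
    S <- mats0$S + x * (mats1$S - mats0$S)
    list(A = regularized_inverse(S, regthresh) %*%
           ((mats0$H + x * (mats1$H - mats0$H)) -
              1i * (mats0$Sdot + x * (mats1$Sdot - mats0$Sdot))))
  })
  dC <- function(C, node) -1i * (node$A %*% C)
  C <- as.complex(C)
  for (k in seq_len(n_sub)) {
    m0 <- nodes[[2L * k - 1L]]; mm <- nodes[[2L * k]]; m1 <- nodes[[2L * k + 1L]]
    k1 <- dC(C, m0)
    k2 <- dC(C + h / 2 * k1, mm)
    k3 <- dC(C + h / 2 * k2, mm)
    k4 <- dC(C + h * k3, m1)
    C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  as.vector(C)
}

#' Total norm of a coupled set
#'
#' \eqn{\Re(C^\dagger S C)}; equals 1 at initialisation and is conserved by
#' exact propagation.
#'
#' @param C complex amplitude vector.
#' @param S overlap matrix.
#' @return scalar in \eqn{[0, 1]} (up to integration error).
#' @export
set_norm <- function(C, S) {
  Re((t(Conj(C)) %*% S %*% C)[1L, 1L])
}

#' Mulliken population of one TBF
#'
#' \eqn{n_k = \sum_{k'} \Re\{C_{k'}^* S_{k'k} C_k\}} restricted to
#' same-state partners: the symmetric attribution of shared overlap weight.
#' Gates spawning through \code{poptospawn}.
#'
#' @param set a \code{coupled_set}.
#' @param S same-state overlap matrix of the set.
#' @param k TBF index.
#' @return real number.
#' @export
mulliken_population <- function(set, S, k) {
  sum(Re(Conj(set$C) * S[, k] * set$C[k]))
}

#' Per-state population of a coupled set
#'
#' Sum of the Mulliken populations of all TBFs on state \code{J}.
#'
#' @inheritParams mulliken_population
#' @param J electronic state index.
#' @return real number.
#' @export
state_population <- function(set, S, J) {
  ks <- which(set_states(set) == J)
  if (!length(ks)) return(0)
  sum(vapply(ks, function(k) mulliken_population(set, S, k), numeric(1)))
}

#' Electronic-structure evaluation count per step
#'
#' The number of centroid evaluations required by the Hamiltonian matrix of
#' an N-TBF set without overlap screening: \eqn{N(N+1)/2}.
#'
#' @param n_tbfs number of TBFs.
#' @return integer.
#' @export
nes_count <- function(n_tbfs) {
  as.integer(n_tbfs * (n_tbfs + 1) / 2)
}
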