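#' Classical equations of motion of a TBF centre
#'
#' Time derivatives of the centre coordinates, momenta and semiclassical
#' phase of a TBF evolving on its adiabatic surface: \eqn{\dot{\bar R} =
#' \bar P / M}, \eqn{\dot{\bar P} = -\nabla E_J(\bar R)}, and
#' \eqn{\dot\gamma = T - V} (the classical Lagrangian, the standard frozen
#' Gaussian phase convention; any constant offset cancels in observables
#' through the amplitude equations).
#'
#' @param x a \code{tbf}.
#' @param model an \code{lvc_model}.
#' @return list with \code{dR}, \code{dP}, \code{dgamma}.
#' @export
tbf_dynamics <- function(x, model) {
  ep <- eval_point(model, x$R)
  grad <- ep_gradient(model, x$R, ep, x$state)
  Tkin <- sum(x$P^2 * model$omega / 2)   # 1/(2M) = omega/2
  list(dR = x$P * model$omega, dP = -grad, dgamma = Tkin - ep$E[x$state])
}

#' Classical energy of a TBF centre
#'
#' Kinetic energy of the centre plus the adiabatic potential at the centre.
#' Conserved along single-surface Verlet propagation (up to the integrator's
#' bounded oscillatory error).
#'
#' @inheritParams tbf_dynamics
#' @return scalar energy (Hartree).
#' @export
tbf_energy <- function(x, model) {
  sum(x$P^2 * model$omega / 2) + eval_point(model, x$R)$E[x$state]
}

#' Velocity-Verlet step for a TBF centre
#'
#' Advances \eqn{(\bar R, \bar P)} by one time-reversible velocity-Verlet
#' step on the TBF's adiabatic surface, with per-mode masses
#' \eqn{M_i = 1/\omega_i}.  The phase is not touched; see
#' \code{\link{phase_step}} and \code{\link{propagate_tbf}}.
#'
#' @inheritParams tbf_dynamics
#' @param dt time step (atomic time units), positive or negative (negative
#'   steps propagate backwards in time).
#' @return the updated \code{tbf}.
#' @export
verlet_step <- function(x, model, dt) {
  if (dt == 0) stop("dt must be nonzero")
  J <- x$state
  f0 <- -ep_gradient(model, x$R, eval_point(model, x$R), J)
  P_half <- x$P + 0.5 * dt * f0
  R_new <- x$R + dt * P_half * model$omega
  f1 <- -ep_gradient(model, R_new, eval_point(model, R_new), J)
  x$P <- P_half + 0.5 * dt * f1
  x$R <- R_new
  x
}

#' Semiclassical phase step
#'
#' Accumulates \eqn{\gamma \leftarrow \gamma + \Delta t\, (T - V)} with the
#' kinetic energy at the Verlet half-step momentum and the potential
#' averaged over the step endpoints (second-order accurate, time
#' symmetric, consistent with the centre propagation).
#'
#' @inheritParams verlet_step
#' @return the updated phase (scalar).
#' @export
phase_step <- function(x, model, dt) {
  J <- x$state
  ep0 <- eval_point(model, x$R)
  P_half <- x$P - 0.5 * dt * ep_gradient(model, x$R, ep0, J)
  R_new <- x$R + dt * P_half * model$omega
  ep1 <- eval_point(model, R_new)
  Tkin <- sum(P_half^2 * model$omega / 2)
  x$gamma + dt * (Tkin - (ep0$E[J] + ep1$E[J]) / 2)
}

#' Combined classical step: centre + phase
#'
#' @inheritParams verlet_step
#' @return the updated \code{tbf} with centre and phase advanced by \code{dt}.
#' @export
propagate_tbf <- function(x, model, dt) {
  J <- x$state
  ep0 <- eval_point(model, x$R)
  P_half <- x$P - 0.5 * dt * ep_gradient(model, x$R, ep0, J)
  R_new <- x$R + dt * P_half * model$omega
  ep1 <- eval_point(model, R_new)
  x$P <- P_half - 0.5 * dt * ep_gradient(model, R_new, ep1, J)
  x$R <- R_new
  x$gamma <- x$gamma + dt * (sum(P_half^2 * model$omega / 2) -
                               (ep0$E[J] + ep1$E[J]) / 2)
  x
}

# vectorised combined step for a list of TBFs (column-parallel over TBFs on
# the two-state fast path; falls back to per-TBF stepping otherwise)
propagate_tbfs <- function(tbfs, model, dt) {
  if (model$n_states != 2L || length(tbfs) == 1L) {
    out <- lapply(tbfs, propagate_tbf, model = model, dt = dt)
    attr(out, "energy0") <- vapply(tbfs, tbf_energy, numeric(1), model = model)
    attr(out, "energy1") <- vapply(out, tbf_energy, numeric(1), model = model)
    return(out)
  }
  nm <- model$n_modes
  om <- model$omega
  N <- length(tbfs)
  Q <- matrix(vapply(tbfs, `[[`, numeric(nm), "R"), nm, N)
  P <- matrix(vapply(tbfs, `[[`, numeric(nm), "P"), nm, N)
  J <- vapply(tbfs, `[[`, integer(1), "state")
  up <- J == 2L
  ev0 <- ev2_cols(model, Q)
  P_half <- P - 0.5 * dt * ev2_gradient(model, ev0, J)
  R_new <- Q + dt * P_half * om
  ev1 <- ev2_cols(model, R_new)
  P_new <- P_half - 0.5 * dt * ev2_gradient(model, ev1, J)
  E0 <- ev0$E1; E0[up] <- ev0$E2[up]
  E1 <- ev1$E1; E1[up] <- ev1$E2[up]
  dgam <- dt * (colSums(P_half * P_half * om) / 2 - (E0 + E1) / 2)
  for (k in seq_len(N)) {
    tbfs[[k]]$R <- R_new[, k]
    tbfs[[k]]$P <- P_new[, k]
    tbfs[[k]]$gamma <- tbfs[[k]]$gamma + dgam[k]
  }
  # classical centre energies at both endpoints (step-rejection test)
  attr(tbfs, "energy0") <- colSums(P * P * om) / 2 + E0
  attr(tbfs, "energy1") <- colSums(P_new * P_new * om) / 2 + E1
  tbfs
}

# classical centre energies of every TBF in a list (vectorised when 2-state)
tbf_energies <- function(tbfs, model) {
  if (model$n_states != 2L)
    return(vapply(tbfs, tbf_energy, numeric(1), model = model))
  nm <- model$n_modes
  N <- length(tbfs)
  Q <- matrix(vapply(tbfs, `[[`, numeric(nm), "R"), nm, N)
  P <- matrix(vapply(tbfs, `[[`, numeric(nm), "P"), nm, N)
  J <- vapply(tbfs, `[[`, integer(1), "state")
  ev <- ev2_cols(model, Q)
  colSums(P * P * model$omega) / 2 + ifelse(J == 1L, ev$E1, ev$E2)
}

# coupling magnitudes |d_(J,other)| for every TBF in a list (2-state path)
coupling_magnitudes <- function(tbfs, model) {
  if (model$n_states != 2L)
    return(vapply(tbfs, function(x)
      coupling_magnitude(x, model, if (x$state == 1L) 2L else 1L),
      numeric(1)))
  nm <- model$n_modes
  Q <- matrix(vapply(tbfs, `[[`, numeric(nm), "R"), nm, length(tbfs))
  ev <- ev2_cols(model, Q)
  d <- ev2_nac12(model, ev)$d
  sqrt(colSums(matrix(d * d, nm)))
}

#' Adaptive time-step controller
#'
#' Holds the base nuclear time step and the rules for reducing it: a fixed
#' reduction factor inside regions of sizable nonadiabatic coupling (and
#' throughout the spawning mode), and step halving upon rejection of an
#' integration step (norm or total-energy drift beyond tolerance) down to a
#' minimum step below which the dynamics aborts.
#'
#' @param dt_base base time step (atomic time units); the FMS90 name is
#'   \code{timestep}.
#' @param factor reduction factor applied in coupling regions (default 4).
#' @param dt_min minimum admissible step; a required step below this aborts
#'   the run.
#' @param norm_tol per-step norm-drift tolerance for step rejection.
#' @param energy_tol per-step total-energy drift tolerance (Hartree).
#' @return object of class \code{step_controller}.
#' @export
step_controller <- function(dt_base, factor = 4, dt_min = dt_base / 64,
                            norm_tol = 1e-4, energy_tol = 1e-4) {
  if (dt_min >= dt_base) stop("dt_min must be smaller than dt_base")
  if (factor <= 1) stop("reduction factor must exceed 1")
  structure(list(dt_base = dt_base, factor = factor, dt_min = dt_min,
                 norm_tol = norm_tol, energy_tol = energy_tol),
            class = "step_controller")
}

#' Choose the next integration time step
#'
#' Returns the base step away from coupling regions, the reduced step
#' (\code{dt_base/factor}) when any TBF pair is in a strong-coupling region
#' or a spawning mode is active, and half the previous step after a
#' rejection; signals an abort (with the tripped tolerance as diagnostic)
#' when the required step falls below \code{dt_min}.
#'
#' @param controller a \code{step_controller}.
#' @param context list with logicals \code{in_coupling_region},
#'   \code{last_step_accepted}, and numerics \code{last_dt},
#'   \code{norm_drift}, \code{energy_drift}.
#' @return list with \code{dt}, logical \code{abort}, and \code{reason}
#'   (\code{NULL} unless aborting).
#' @export
adapt_step <- function(controller, context) {
  ctx <- utils::modifyList(list(in_coupling_region = FALSE,
                                last_step_accepted = TRUE,
                                last_dt = controller$dt_base,
                                norm_drift = 0, energy_drift = 0), context)
  if (!isTRUE(ctx$last_step_accepted)) {
    dt <- ctx$last_dt / 2
    if (dt < controller$dt_min) {
      reason <- if (ctx$norm_drift > controller$norm_tol)
        sprintf("norm drift %.3e exceeds tolerance %.3e at the minimum step",
                ctx$norm_drift, controller$norm_tol)
      else
        sprintf("energy drift %.3e exceeds tolerance %.3e at the minimum step",
                ctx$energy_drift, controller$energy_tol)
      return(list(dt = NA_real_, abort = TRUE, reason = reason))
    }
    return(list(dt = dt, abort = FALSE, reason = NULL))
  }
  if (isTRUE(ctx$in_coupling_region))
    return(list(dt = controller$dt_base / controller$factor,
                abort = FALSE, reason = NULL))
  list(dt = controller$dt_base, abort = FALSE, reason = NULL)
}
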