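#' Nonadiabaticity indicator of a TBF
#'
#' Euclidean norm of the nonadiabatic coupling vector between the TBF's
#' state and another state, evaluated at the TBF centre.  This magnitude is
#' compared against \code{csthresh} to trigger the spawning mode.
#'
#' @param x a \code{tbf}.
#' @param model an \code{lvc_model}.
#' @param J_other the coupled electronic state (distinct from the TBF's).
#' @return nonnegative scalar (per coordinate unit).
#' @export
coupling_magnitude <- function(x, model, J_other) {
  if (J_other == x$state) stop("J_other must differ from the TBF's state")
  nv <- ep_nac_floored(model, x$R, eval_point(model, x$R), x$state, J_other)
  sqrt(sum(nv$d^2))
}

#' Spawning-mode entry check
#'
#' A TBF enters the spawning mode towards \code{J_other} iff its
#' nonadiabaticity indicator exceeds \code{csthresh} and its Mulliken
#' population is at least \code{poptospawn}.
#'
#' @inheritParams coupling_magnitude
#' @param set the \code{coupled_set} containing \code{x}.
#' @param S current same-state overlap matrix of the set.
#' @param params a \code{sim_params}.
#' @return list with logical \code{enter} and character \code{reason}
#'   (\code{"coupling"} or \code{"population"} when skipping, \code{NA}
#'   when entering).
#' @export
check_entry <- function(x, set, S, model, params, J_other) {
  mag <- coupling_magnitude(x, model, J_other)
  if (mag <= params$csthresh)
    return(list(enter = FALSE, reason = "coupling", indicator = mag))
  k <- match(x$id, vapply(set$tbfs, `[[`, character(1), "id"))
  pop <- mulliken_population(set, S, k)
  if (pop < params$poptospawn)
    return(list(enter = FALSE, reason = "population", indicator = mag))
  list(enter = TRUE, reason = NA_character_, indicator = mag)
}

# momentum of the child TBF: the parent momentum adjusted along the unit
# nonadiabatic coupling vector so that the classical total energy is
# conserved on the target surface; NULL if classically forbidden
rescale_momentum <- function(P, model, E_total, R, target_state, nac_dir) {
  nrm <- sqrt(sum(nac_dir^2))
  dhat <- if (nrm > 0) nac_dir / nrm else rep(1 / sqrt(length(P)), length(P))
  E_new <- adiabatic_surface(model, R)$energies[target_state]
  K_target <- E_total - E_new
  w <- model$omega / 2                    # 1/(2M)
  a <- sum(w * dhat^2)
  b <- 2 * sum(w * P * dhat)
  c0 <- sum(w * P^2) - K_target
  disc <- b^2 - 4 * a * c0
  if (disc < 0) return(NULL)
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  P + roots[which.min(abs(roots))] * dhat
}

#' Overlap acceptance tests for a candidate child TBF
#'
#' The two roles of the \code{omax} threshold: (i) the child must overlap
#' its parent by at least \code{omax_parent} at the spawning geometry, and
#' (ii) once backpropagated to the spawning-mode entry time it must not be
#' redundant, i.e. its maximum absolute overlap with any other existing TBF
#' must not exceed \code{omax_swarm}.  Both default to the single
#' \code{omax} value.
#'
#' @param child_at_spawn,parent_at_spawn TBFs at the spawning geometry.
#' @param child_at_entry the child backpropagated to the entry time.
#' @param swarm list of the other existing TBFs (parent excluded) at the
#'   entry time.
#' @param params a \code{sim_params} (uses \code{omax_parent},
#'   \code{omax_swarm}).
#' @return list with logical \code{accept} and \code{reason}
#'   (\code{"parent-overlap"} or \code{"redundant"} on rejection).
#' @export
omax_tests <- function(child_at_spawn, parent_at_spawn, child_at_entry,
                       swarm, params) {
  ov_parent <- abs(overlap(child_at_spawn, parent_at_spawn))
  if (ov_parent < params$omax_parent)
    return(list(accept = FALSE, reason = "parent-overlap",
                parent_overlap = ov_parent))
  ov_swarm <- 0
  for (other in swarm)
    ov_swarm <- max(ov_swarm, abs(overlap(child_at_entry, other)))
  if (ov_swarm > params$omax_swarm)
    return(list(accept = FALSE, reason = "redundant",
                parent_overlap = ov_parent, swarm_overlap = ov_swarm))
  list(accept = TRUE, reason = NA_character_, parent_overlap = ov_parent,
       swarm_overlap = ov_swarm)
}

#' Run the spawning mode for one parent TBF
#'
#' Implements the forward search and child creation: the amplitudes are
#' frozen by the caller; a clone of the parent is propagated classically on
#' its own surface with the reduced time step until a three-point local
#' maximum of the nonadiabaticity indicator is found (or the duration cap
#' is reached, in which case the spawn happens at the cap and is flagged).
#' A child TBF is created there on the coupled state with zero amplitude
#' and its momentum rescaled along the coupling vector to conserve the
#' parent's classical energy; it is backpropagated to the entry time and
#' subjected to the \code{omax} tests.
#'
#' @param parent the parent \code{tbf} at the spawning-mode entry time.
#' @param set the \code{coupled_set} at the entry time.
#' @param model an \code{lvc_model}.
#' @param params a \code{sim_params}.
#' @param J_other the coupled state to spawn onto.
#' @param t_entry entry time of the spawning mode (atomic time units).
#' @return list with \code{event} (a one-row data frame: the spawn log
#'   record) and \code{child} (a \code{tbf}, or \code{NULL} if rejected).
#' @export
run_spawning_mode <- function(parent, set, model, params, J_other, t_entry) {
  dt_s <- params$timestep / params$factor
  cap <- params$spawn_cap * params$factor
  clone <- parent
  ind <- coupling_magnitude(clone, model, J_other)
  traj <- list(clone)
  inds <- ind
  at_cap <- FALSE
  i_max <- NA_integer_
  for (s in seq_len(cap)) {
    clone <- propagate_tbf(clone, model, dt_s)
    traj[[s + 1L]] <- clone
    inds[s + 1L] <- coupling_magnitude(clone, model, J_other)
    if (s >= 2L && inds[s] > inds[s - 1L] && inds[s] > inds[s + 1L]) {
      i_max <- s  # three-point local maximum on the reduced time grid
      break
    }
    if (inds[s + 1L] < params$csthresh) {
      # left the coupling region without an interior maximum: the maximum
      # sits on the boundary (typically the entry point itself)
      i_max <- which.max(inds)
      break
    }
  }
  if (is.na(i_max)) {               # duration cap hit, indicator still high
    i_max <- which.max(inds)
    at_cap <- i_max == length(inds)
  }
  t_max <- t_entry + (i_max - 1L) * dt_s
  at_max <- traj[[i_max]]

  event <- data.frame(parent_id = parent$id, child_id = NA_character_,
                      source_state = parent$state, target_state = J_other,
                      t_entry = t_entry, t_max = t_max,
                      indicator = inds[i_max], accepted = FALSE,
                      rejection_reason = NA_character_,
                      at_cap = at_cap, stringsAsFactors = FALSE)

  nv <- nac_vector_floored(model, at_max$R, parent$state, J_other)
  P_child <- rescale_momentum(at_max$P, model, tbf_energy(at_max, model),
                              at_max$R, J_other, nv$d)
  if (is.null(P_child)) {
    event$rejection_reason <- "forbidden"
    return(list(event = event, child = NULL))
  }
  child <- tbf(state = J_other, R = at_max$R, P = P_child,
               alpha = at_max$alpha, gamma = at_max$gamma,
               parent_id = parent$id, birth_time = t_entry)
  # backpropagate the child to the entry time on its own surface
  child_entry <- child
  for (s in seq_len(i_max - 1L))
    child_entry <- propagate_tbf(child_entry, model, -dt_s)

  ids <- vapply(set$tbfs, `[[`, character(1), "id")
  swarm <- set$tbfs[ids != parent$id]
  chk <- omax_tests(child, at_max, child_entry, swarm, params)
  if (!chk$accept) {
    event$rejection_reason <- chk$reason
    return(list(event = event, child = NULL))
  }
  event$child_id <- child_entry$id
  event$accepted <- TRUE
  list(event = event, child = child_entry)
}
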