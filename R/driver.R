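#' Wigner sampling of initial conditions
#'
#' Samples phase-space points from the Wigner quasi-distribution of the
#' ground vibrational state of the uncoupled harmonic modes, centred at the
#' Franck-Condon point: in dimensionless coordinates each mode contributes
#' independent \eqn{q \sim N(0, 1/2)} and \eqn{p \sim N(0, 1/2)}
#' (variances).  Deterministic under a fixed seed.
#'
#' @param model an \code{lvc_model}.
#' @param n number of initial conditions.
#' @param seed RNG seed.
#' @return list of initial conditions, each a list with \code{R0},
#'   \code{P0}, \code{weight} and \code{index}.
#' @export
wigner_sample <- function(model, n, seed) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sd0 <- sqrt(1 / 2)
  lapply(seq_len(n), function(i) {
    list(R0 = stats::rnorm(model$n_modes, 0, sd0),
         P0 = stats::rnorm(model$n_modes, 0, sd0),
         weight = 1, index = i)
  })
}

default_widths <- function(model, params) {
  if (is.null(params$widths)) rep(1 / 2, model$n_modes)
  else rep_len(params$widths, model$n_modes)
}

#' Run AIMS dynamics from a single initial condition
#'
#' One ancestor TBF is placed at the sampled phase-space point with unit
#' amplitude on the initial electronic state.  The time loop joins
#' classical propagation of all TBF centres (velocity Verlet + phase),
#' matrix assembly under SPA0, RK4 amplitude propagation with the
#' regularised overlap inverse, adaptive time stepping (reduced step in
#' coupling regions, halving on norm/energy drift rejection), and the
#' spawning algorithm.
#'
#' @param ic initial condition (list with \code{R0}, \code{P0}), e.g. one
#'   element of \code{\link{wigner_sample}}.
#' @param model an \code{lvc_model}.
#' @param params a \code{sim_params}.
#' @return object of class \code{aims_run}: the population trace on the
#'   base-step grid (\code{times}, \code{populations}, \code{norm},
#'   \code{n_tbfs}, \code{n_es}), the spawn-event log, the final coupled
#'   set, and an \code{aborted} flag.
#' @export
run_ic <- function(ic, model, params) {
  dtb <- params$timestep
  n_steps <- ceiling(params$t_final / dtb)
  widths <- default_widths(model, params)
  anc <- tbf(state = params$initial_state, R = ic$R0, P = ic$P0,
             alpha = widths, gamma = 0, id = "tbf-1", birth_time = 0)
  set <- coupled_set(list(anc), complex(real = 1), t = 0)
  ctrl <- step_controller(dtb, factor = params$factor,
                          dt_min = dtb * params$dt_min_frac,
                          norm_tol = params$norm_tol,
                          energy_tol = params$energy_tol)
  gauge <- new.env(parent = emptyenv())  # per-pair eigenvector continuity
  mats <- assemble_matrices(set, model, params, gauge)
  n_states <- model$n_states

  times <- numeric(n_steps + 1L)
  pops <- matrix(0, n_steps + 1L, n_states)
  norms <- numeric(n_steps + 1L)
  ntbfs <- integer(n_steps + 1L)
  nes <- integer(n_steps + 1L)
  record <- function(i) {
    times[i] <<- set$t
    pops[i, ] <<- vapply(seq_len(n_states), function(J)
      state_population(set, mats$S, J), numeric(1))
    norms[i] <<- set_norm(set$C, mats$S)
    ntbfs[i] <<- length(set$tbfs)
    nes[i] <<- mats$n_pot_evals
  }
  record(1L)

  spawn_log <- list()
  blocked <- new.env(parent = emptyenv())   # "<id>:<state>" -> TRUE
  aborted <- FALSE
  abort_reason <- NULL
  next_id <- 2L

  # advance the whole coupled set by dt; returns list(set, mats, ok).
  # rejection tests: coupled-set norm drift and the largest per-TBF
  # classical energy drift over the step (both shrink with the step size,
  # so halving can cure them)
  try_step <- function(set, mats, dt) {
    tbfs2 <- propagate_tbfs(set$tbfs, model, dt)
    e0 <- attr(tbfs2, "energy0")
    set2 <- coupled_set(tbfs2, set$C, t = set$t + dt)
    mats2 <- assemble_matrices(set2, model, params, gauge)
    C2 <- propagate_coefficients(set$C, mats, mats2, dt, params$regthresh,
                                 params$n_sub)
    set2$C <- C2
    drift_n <- abs(set_norm(C2, mats2$S) - set_norm(set$C, mats$S))
    drift_e <- max(abs(attr(tbfs2, "energy1") - e0))
    ok <- drift_n <= ctrl$norm_tol && drift_e <= ctrl$energy_tol
    list(set = set2, mats = mats2, ok = ok, norm_drift = drift_n,
         energy_drift = drift_e)
  }

  # advance by dt with recursive halving on rejection
  advance <- function(set, mats, dt) {
    st <- try_step(set, mats, dt)
    if (st$ok) return(st)
    nxt <- adapt_step(ctrl, list(last_step_accepted = FALSE, last_dt = dt,
                                 norm_drift = st$norm_drift,
                                 energy_drift = st$energy_drift))
    if (nxt$abort) return(list(abort = TRUE, reason = nxt$reason))
    h1 <- advance(set, mats, nxt$dt)
    if (isTRUE(h1$abort)) return(h1)
    h2 <- advance(h1$set, h1$mats, nxt$dt)
    if (isTRUE(h2$abort)) return(h2)
    h2
  }

  other_states <- function(J) setdiff(seq_len(n_states), J)

  for (step in seq_len(n_steps)) {
    # coupling-region flag: any live TBF within half the spawning threshold
    in_coupling <- FALSE
    if (n_states == 2L) {
      in_coupling <- any(coupling_magnitudes(set$tbfs, model) >
                           params$csthresh / 2)
    } else if (n_states > 1L) {
      for (x in set$tbfs) {
        for (Jo in other_states(x$state)) {
          if (coupling_magnitude(x, model, Jo) > params$csthresh / 2) {
            in_coupling <- TRUE; break
          }
        }
        if (in_coupling) break
      }
    }
    dt_use <- adapt_step(ctrl, list(in_coupling_region = in_coupling))$dt
    n_rep <- round(dtb / dt_use)
    for (rep_i in seq_len(n_rep)) {
      st <- advance(set, mats, dt_use)
      if (isTRUE(st$abort)) {
        aborted <- TRUE; abort_reason <- st$reason
        break
      }
      set <- st$set; mats <- st$mats
    }
    if (aborted) break

    # spawning checks at the end of the base step
    if (n_states > 1L) {
      for (k in seq_along(set$tbfs)) {
        x <- set$tbfs[[k]]
        for (Jo in other_states(x$state)) {
          key <- paste0(x$id, ":", Jo)
          mag <- coupling_magnitude(x, model, Jo)
          if (isTRUE(blocked[[key]])) {
            if (mag < params$csthresh) rm(list = key, envir = blocked)
            next
          }
          chk <- check_entry(x, set, mats$S, model, params, Jo)
          if (!chk$enter) next
          blocked[[key]] <- TRUE   # one spawning mode per coupling region
          sp <- run_spawning_mode(x, set, model, params, Jo, set$t)
          spawn_log[[length(spawn_log) + 1L]] <- sp$event
          if (!is.null(sp$child)) {
            child <- sp$child
            child$id <- sprintf("tbf-%d", next_id); next_id <- next_id + 1L
            # a child is born inside the coupling region: block its own
            # back-spawn toward the source state until it leaves the region
            blocked[[paste0(child$id, ":", x$state)]] <- TRUE
            set$tbfs[[length(set$tbfs) + 1L]] <- child
            set$C <- c(set$C, 0i)
            mats <- assemble_matrices(set, model, params, gauge)
          }
        }
      }
    }
    record(step + 1L)
  }

  keep <- seq_len(if (aborted) step else n_steps + 1L)
  log_df <- if (length(spawn_log)) do.call(rbind, spawn_log) else
    data.frame(parent_id = character(), child_id = character(),
               source_state = integer(), target_state = integer(),
               t_entry = numeric(), t_max = numeric(), indicator = numeric(),
               accepted = logical(), rejection_reason = character(),
               at_cap = logical(), stringsAsFactors = FALSE)
  structure(list(times = times[keep], populations = pops[keep, , drop = FALSE],
                 norm = norms[keep], n_tbfs = ntbfs[keep], n_es = nes[keep],
                 spawn_log = log_df, set = set, params = params,
                 aborted = aborted, abort_reason = abort_reason,
                 ic = ic), class = "aims_run")
}

#' @export
print.aims_run <- function(x, ...) {
  cat(sprintf("AIMS run: %d TBFs at t = %.3f atu%s\n", length(x$set$tbfs),
              max(x$times), if (x$aborted) " (ABORTED)" else ""))
  cat(sprintf("  spawn events: %d attempted, %d accepted\n",
              nrow(x$spawn_log), sum(x$spawn_log$accepted)))
  pf <- x$populations[nrow(x$populations), ]
  cat("  final populations:", format(pf, digits = 4), "\n")
  cat("  final norm:", format(x$norm[length(x$norm)], digits = 6), "\n")
  invisible(x)
}

#' Run a full AIMS ensemble
#'
#' Samples \code{n_ic} Wigner initial conditions, runs one independent
#' coupled set per initial condition (independent first-generation
#' approximation), and averages the population traces incoherently with
#' equal weights.  Aborted runs are excluded from the average and reported.
#'
#' @param model an \code{lvc_model}.
#' @param params a \code{sim_params} (supplies \code{n_ic} and \code{seed}
#'   unless overridden).
#' @param n_ic,seed optional overrides of the corresponding params fields.
#' @param ics optional pre-sampled list of initial conditions (takes
#'   precedence over Wigner sampling); the paired-IC mechanism of
#'   parameter sweeps.
#' @param keep_runs keep the individual \code{aims_run} objects.
#' @return object of class \code{aims_ensemble} with the averaged trace and
#'   (optionally) the per-IC runs.
#' @export
aims_ensemble <- function(model, params, n_ic = params$n_ic,
                          seed = params$seed, ics = NULL, keep_runs = FALSE) {
  if (is.null(ics)) ics <- wigner_sample(model, n_ic, seed)
  runs <- lapply(ics, run_ic, model = model, params = params)
  ok <- !vapply(runs, `[[`, logical(1), "aborted")
  if (!any(ok)) stop("all runs aborted")
  avg <- ensemble_average(runs[ok])
  structure(list(times = avg$times, populations = avg$populations,
                 norm = avg$norm, n_aborted = sum(!ok),
                 n_ic = length(ics), params = params,
                 mean_spawns = mean(vapply(runs[ok], function(r)
                   sum(r$spawn_log$accepted), numeric(1))),
                 runs = if (keep_runs) runs else NULL),
            class = "aims_ensemble")
}

#' Incoherent ensemble average of population traces
#'
#' Equal-weight arithmetic mean of per-state populations over runs (the
#' observable average under the independent first-generation
#' approximation).  Traces on different grids are linearly interpolated
#' onto the first run's grid.
#'
#' @param traces list of \code{aims_run} objects (or anything with
#'   \code{times}, \code{populations}, \code{norm}).
#' @return list with \code{times}, \code{populations}, \code{norm}.
#' @export
ensemble_average <- function(traces) {
  stopifnot(length(traces) >= 1)
  grid <- traces[[1L]]$times
  n_states <- ncol(traces[[1L]]$populations)
  acc <- matrix(0, length(grid), n_states)
  nrm <- numeric(length(grid))
  for (tr in traces) {
    if (isTRUE(all.equal(tr$times, grid))) {
      acc <- acc + tr$populations
      nrm <- nrm + tr$norm
    } else {
      for (J in seq_len(n_states))
        acc[, J] <- acc[, J] +
          stats::approx(tr$times, tr$populations[, J], xout = grid,
                        rule = 2)$y
      nrm <- nrm + stats::approx(tr$times, tr$norm, xout = grid, rule = 2)$y
    }
  }
  list(times = grid, populations = acc / length(traces),
       norm = nrm / length(traces))
}

#' @export
print.aims_ensemble <- function(x, ...) {
  cat(sprintf("AIMS ensemble: %d ICs (%d aborted), t up to %.2f atu\n",
              x$n_ic, x$n_aborted, max(x$times)))
  cat("  mean accepted spawns per IC:", format(x$mean_spawns, digits = 3), "\n")
  cat("  final mean populations:",
      format(x$populations[nrow(x$populations), ], digits = 4), "\n")
  invisible(x)
}

#' Plot a population trace
#'
#' @param x an \code{aims_run} or \code{aims_ensemble}.
#' @param ... passed to \code{matplot}.
#' @export
plot.aims_ensemble <- function(x, ...) {
  graphics::matplot(x$times, x$populations, type = "l", lty = 1,
                    xlab = "time (atu)", ylab = "adiabatic population", ...)
  graphics::legend("right", legend = paste("state", seq_len(ncol(x$populations))),
                   col = seq_len(ncol(x$populations)), lty = 1, bty = "n")
  invisible(x)
}

#' @export
plot.aims_run <- plot.aims_ensemble

#' Write a population trace to TSV
#'
#' Columns: time, one column per state population, norm, n_tbfs, n_es.
#'
#' @param x an \code{aims_run} (or \code{aims_ensemble}; the TBF counters
#'   are omitted when absent).
#' @param path output file.
#' @export
write_trace <- function(x, path) {
  df <- data.frame(time = x$times)
  for (J in seq_len(ncol(x$populations)))
    df[[paste0("pop_state", J)]] <- x$populations[, J]
  df$norm <- x$norm
  if (!is.null(x$n_tbfs)) { df$n_tbfs <- x$n_tbfs; df$n_es <- x$n_es }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
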