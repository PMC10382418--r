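#' Signed relative deviation of a population trace
#'
#' \eqn{(P(t) - P_{ref}(t)) / P_{ref}(t)} at every output time where the
#' reference population is at least \code{floor}; other times are dropped
#' (the relative deviation is ill-defined when the reference population
#' vanishes).
#'
#' @param pop,pop_ref population series on a common time grid.
#' @param floor minimum reference population (default 0.01).
#' @return numeric vector of deviations (possibly shorter than the input).
#' @export
signed_relative_deviation <- function(pop, pop_ref, floor = 0.01) {
  if (length(pop) != length(pop_ref))
    stop("population series must share a common grid")
  keep <- pop_ref >= floor
  (pop[keep] - pop_ref[keep]) / pop_ref[keep]
}

#' Gaussian kernel density estimate with Scott's bandwidth
#'
#' Univariate Gaussian-kernel density with the Scott rule
#' \eqn{h = \hat\sigma\, n^{-1/5}}.  The estimated probability density
#' function (EPDF) integrates to 1 on its evaluation grid.
#'
#' @param samples numeric vector, \code{n >= 2}, with nonzero spread.
#' @param n_grid number of evaluation points.
#' @param cut grid extension beyond the sample range, in bandwidths.
#' @return list with \code{x}, \code{y}, \code{bw}, \code{n}.
#' @export
kde_scott <- function(samples, n_grid = 512L, cut = 4) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("need at least two samples")
  s <- stats::sd(samples)
  if (s == 0) stop("samples have zero variance; no density to estimate")
  bw <- s * n^(-1 / 5)
  d <- stats::density(samples, bw = bw, kernel = "gaussian", n = n_grid,
                      from = min(samples) - cut * bw,
                      to = max(samples) + cut * bw)
  list(x = d$x, y = d$y, bw = bw, n = n)
}

#' Integrated absolute nuclear-density deviation
#'
#' \eqn{\int |\rho_{AIMS}(q, t) - \rho_{ref}(q, t)|\, dq} per output time
#' (Riemann sum on the common grid).  Bounded by 2 for unit-norm densities.
#'
#' @param dens,dens_ref lists (over output times) of density arrays on a
#'   common \code{qd_grid}, or single arrays.
#' @param grid the common \code{qd_grid}.
#' @return numeric vector (one value per time).
#' @export
density_deviation <- function(dens, dens_ref, grid) {
  if (!is.list(dens)) dens <- list(dens)
  if (!is.list(dens_ref)) dens_ref <- list(dens_ref)
  if (length(dens) != length(dens_ref))
    stop("density series have different lengths")
  dV <- grid_volume_element(grid)
  vapply(seq_along(dens), function(i) {
    if (!identical(dim(dens[[i]]), dim(dens_ref[[i]])))
      stop("density grids do not match")
    sum(abs(dens[[i]] - dens_ref[[i]])) * dV
  }, numeric(1))
}

sweepable_params <- c("timestep", "csthresh", "poptospawn", "omax",
                      "olapthresh", "regthresh", "widths")

apply_sweep_value <- function(params, name, value) {
  if (name == "widths") {
    # swept value is a common multiplicative factor on the widths
    base <- if (is.null(params$widths)) 1 / 2 else params$widths
    params$widths <- base * value
  } else if (name == "omax") {
    params$omax <- params$omax_parent <- params$omax_swarm <- value
  } else if (name == "timestep") {
    # keep the ratio of base step to rejection minimum
    params$timestep <- value
  } else {
    params[[name]] <- value
  }
  params
}

#' One-at-a-time parameter sweep
#'
#' Runs a full AIMS ensemble for each value of one parameter, holding all
#' others at their reference values and reusing the same Wigner initial
#' conditions (strictly paired sweeps: the reference value reproduces the
#' reference trace exactly).  The signed relative deviations of the
#' excited-state population from the reference, pooled over all time steps
#' and parameter values, are summarised by a Scott-rule kernel density
#' estimate.  The most extreme swept value (largest |log10(value/ref)|, or
#' largest absolute difference if either is zero) is excluded from the
#' pooled EPDF by default.
#'
#' @param param_name one of \code{timestep}, \code{csthresh},
#'   \code{poptospawn}, \code{omax}, \code{olapthresh}, \code{regthresh},
#'   \code{widths} (for \code{widths} the values are multiplicative factors
#'   on the reference widths).
#' @param values numeric vector of parameter values to sweep.
#' @param base_params reference \code{sim_params}.
#' @param model an \code{lvc_model}.
#' @param n_ic,seed ensemble size and seed (shared across values).
#' @param excited_state state whose population is monitored (default: the
#'   initial state of \code{base_params}).
#' @param floor reference-population floor for the relative deviation.
#' @param exclude_extreme drop the most extreme swept value from the
#'   pooled EPDF.
#' @param reference optional precomputed reference \code{aims_ensemble}.
#' @return object of class \code{aims_sweep}: per-value traces and
#'   deviation series, the pooled deviations, and the EPDF.
#' @export
aims_sweep <- function(param_name, values, base_params, model,
                       n_ic = base_params$n_ic, seed = base_params$seed,
                       excited_state = base_params$initial_state,
                       floor = 0.01, exclude_extreme = TRUE,
                       reference = NULL) {
  if (!param_name %in% sweepable_params)
    stop("unknown parameter '", param_name, "'; valid names: ",
         paste(sweepable_params, collapse = ", "))
  ics <- wigner_sample(model, n_ic, seed)
  if (is.null(reference))
    reference <- aims_ensemble(model, base_params, ics = ics)
  ref_pop <- reference$populations[, excited_state]

  ref_value <- if (param_name == "widths") 1 else base_params[[param_name]]
  per_value <- lapply(values, function(v) {
    p <- apply_sweep_value(base_params, param_name, v)
    ens <- aims_ensemble(model, p, ics = ics)
    dev <- signed_relative_deviation(ens$populations[, excited_state],
                                     ref_pop, floor)
    list(value = v, ensemble = ens, deviation = dev)
  })

  extremity <- vapply(values, function(v) {
    if (ref_value > 0 && v > 0) abs(log10(v / ref_value)) else abs(v - ref_value)
  }, numeric(1))
  pool_idx <- seq_along(values)
  excluded <- NULL
  if (exclude_extreme && length(values) > 1L) {
    excluded <- which.max(extremity)
    pool_idx <- setdiff(pool_idx, excluded)
  }
  pooled <- unlist(lapply(per_value[pool_idx], `[[`, "deviation"))
  epdf <- if (length(pooled) >= 2L && stats::sd(pooled) > 0)
    kde_scott(pooled) else NULL
  structure(list(param_name = param_name, values = values,
                 ref_value = ref_value, reference = reference,
                 results = per_value, pooled_deviations = pooled,
                 excluded_value = if (!is.null(excluded)) values[excluded],
                 epdf = epdf, excited_state = excited_state, floor = floor),
            class = "aims_sweep")
}

#' @export
print.aims_sweep <- function(x, ...) {
  cat(sprintf("AIMS one-at-a-time sweep of '%s' (reference %g)\n",
              x$param_name, x$ref_value))
  for (r in x$results) {
    fin <- r$ensemble$populations[nrow(r$ensemble$populations),
                                  x$excited_state]
    cat(sprintf("  %-10g final excited population %.4f\n", r$value, fin))
  }
  if (!is.null(x$excluded_value))
    cat("  excluded from EPDF (most extreme):", x$excluded_value, "\n")
  if (!is.null(x$epdf))
    cat(sprintf("  pooled deviations: n = %d, EPDF bandwidth %.4g\n",
                length(x$pooled_deviations), x$epdf$bw))
  invisible(x)
}

#' @export
plot.aims_sweep <- function(x, ...) {
  if (is.null(x$epdf)) stop("sweep has no EPDF (degenerate deviations)")
  graphics::plot(x$epdf$x, x$epdf$y, type = "l",
                 xlab = "signed relative deviation",
                 ylab = "estimated probability density",
                 main = paste("EPDF:", x$param_name), ...)
  invisible(x)
}

#' Write a sweep EPDF table
#'
#' @param x an \code{aims_sweep}.
#' @param path output TSV path.
#' @export
write_epdf <- function(x, path) {
  if (is.null(x$epdf)) stop("sweep has no EPDF")
  utils::write.table(data.frame(deviation = x$epdf$x, density = x$epdf$y),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
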