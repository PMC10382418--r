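#' Built-in toy model Hamiltonians
#'
#' Deterministic generators for the model Hamiltonians used throughout the
#' package's tests and examples:
#' \describe{
#'   \item{\code{uncoupled_harmonic}}{one mode, one or two uncoupled
#'     harmonic states; the exact-limit regime where a single frozen
#'     Gaussian is exact.}
#'   \item{\code{flat_rabi}}{two states with zero intrastate coupling and a
#'     constant interstate coupling: the nuclear motion factorises and the
#'     state populations undergo textbook Rabi oscillations.}
#'   \item{\code{sloped_ci}}{the shipped two-mode, two-state conical
#'     intersection model: one tuning mode with same-sign surface slopes at
#'     the seam (a sloped intersection) and one coupling mode, with the
#'     intersection energetically below the Franck-Condon point.  This is a
#'     configurable stand-in of standard linear vibronic coupling form, not
#'     a published molecular parameter set.}
#' }
#'
#' @param kind one of \code{"uncoupled_harmonic"}, \code{"flat_rabi"},
#'   \code{"sloped_ci"}.
#' @param n_states for \code{uncoupled_harmonic}: 1 or 2 states.
#' @param coupling for \code{flat_rabi}: the constant coupling (Hartree).
#' @param gap for \code{flat_rabi}: the diabatic energy gap (Hartree).
#' @return an \code{lvc_model}.
#' @export
make_model <- function(kind = c("uncoupled_harmonic", "flat_rabi",
                                "sloped_ci"),
                       n_states = 1L, coupling = 0.1, gap = 0) {
  kind <- match.arg(kind)
  switch(kind,
    uncoupled_harmonic = lvc_model(omega = 1,
                                   E_vert = if (n_states == 1L) 0 else c(0, 1)),
    flat_rabi = lvc_model(omega = 1, E_vert = c(0, gap), lam0 = coupling),
    sloped_ci = lvc_model(omega = c(0.30, 0.18), E_vert = c(0, 0.60),
                          kappa = rbind(c(-0.20, 0), c(-0.50, 0)),
                          lam = c(0, 0.35))
  )
}

#' Random LVC model (oracle-test input)
#'
#' A dense random model for brute-force oracle comparisons: frequencies in
#' [0.5, 2], vertical energies in [0, 2], couplings in [-0.5, 0.5].
#' Deterministic under a fixed seed.
#'
#' @param n_modes,n_states dimensions.
#' @param seed RNG seed.
#' @return an \code{lvc_model}.
#' @export
random_lvc_model <- function(n_modes, n_states, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lam <- array(0, c(n_states, n_states, n_modes))
  for (i in seq_len(n_modes)) {
    m <- matrix(stats::runif(n_states^2, -0.5, 0.5), n_states)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    lam[, , i] <- m
  }
  lvc_model(omega = stats::runif(n_modes, 0.5, 2),
            E_vert = stats::runif(n_states, 0, 2),
            kappa = matrix(stats::runif(n_states * n_modes, -0.5, 0.5),
                           n_states),
            lam = lam)
}

#' Random TBF pair (oracle-test input)
#'
#' Two normalised TBFs with widths in [0.2, 5], centres and momenta in
#' [-3, 3] and phases in [0, 2*pi), deterministic under a fixed seed;
#' exercises both near-orthogonal and strongly overlapping regimes.
#'
#' @param dim dimensionality (number of coordinates).
#' @param seed RNG seed.
#' @param states electronic state labels of the pair.
#' @return list of two \code{tbf} objects.
#' @export
random_tbf_pair <- function(dim, seed, states = c(1L, 1L)) {
  stopifnot(dim >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mk <- function(st) tbf(state = st,
                         R = stats::runif(dim, -3, 3),
                         P = stats::runif(dim, -3, 3),
                         alpha = stats::runif(dim, 0.2, 5),
                         gamma = stats::runif(1, 0, 2 * pi))
  list(mk(states[1L]), mk(states[2L]))
}
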