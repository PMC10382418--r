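#' Linear vibronic coupling (LVC) model Hamiltonian
#'
#' Constructs an analytic diabatic model Hamiltonian of linear vibronic
#' coupling form in dimensionless normal-mode coordinates.  The diabatic
#' potential matrix is
#' \deqn{W_{AA}(q) = E_A + \sum_i \kappa_{A,i} q_i + \sum_i \frac{\omega_i}{2} q_i^2,
#'       \qquad W_{AB}(q) = \sum_i \lambda_{AB,i} q_i \; (A \neq B),}
#' with a shared harmonic diagonal.  The kinetic energy is
#' \eqn{\sum_i (\omega_i/2) p_i^2}, i.e. each mode carries an effective mass
#' \eqn{1/\omega_i}, so the vibrational ground state of an uncoupled surface
#' is a unit-exponent Gaussian \eqn{\exp(-q_i^2/2)} and the matching frozen
#' Gaussian width is \eqn{\alpha_i = 1/2}.
#'
#' @param omega numeric vector of per-mode harmonic frequencies (Hartree),
#'   all positive.
#' @param E_vert numeric vector of per-state vertical energies (Hartree).
#' @param kappa matrix (n_states x n_modes) of linear intrastate couplings
#'   (Hartree); defaults to zeros.
#' @param lam array (n_states x n_states x n_modes) of linear interstate
#'   couplings (Hartree), symmetric in its first two indices and zero on the
#'   diagonal; a single n_modes vector is accepted for two-state models.
#' @param lam0 optional constant (coordinate-independent) interstate
#'   coupling matrix (Hartree), symmetric with zero diagonal; a scalar is
#'   accepted for two-state models.  Zero by default; nonzero values serve
#'   flat two-level test models (Rabi oscillations) that the strictly
#'   linear coupling cannot express.
#' @return An object of class \code{lvc_model}.
#' @examples
#' m <- lvc_model(omega = c(1, 1), E_vert = c(0, 1),
#'                kappa = rbind(c(0.5, 0), c(-0.5, 0)),
#'                lam = c(0, 0.2))
#' diabatic_matrix(m, c(1, 1))
#' @export
lvc_model <- function(omega, E_vert, kappa = NULL, lam = NULL, lam0 = NULL) {
  omega <- as.numeric(omega)
  E_vert <- as.numeric(E_vert)
  n_modes <- length(omega)
  n_states <- length(E_vert)
  if (n_modes < 1L) stop("need at least one mode")
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("all omega must be positive")
  if (is.null(kappa)) kappa <- matrix(0, n_states, n_modes)
  kappa <- matrix(as.numeric(kappa), n_states, n_modes)
  if (is.null(lam)) {
    lam <- array(0, c(n_states, n_states, n_modes))
  } else if (is.vector(lam) && n_states == 2L) {
    v <- as.numeric(lam)
    if (length(v) != n_modes) stop("lam vector must have length n_modes")
    lam <- array(0, c(2L, 2L, n_modes))
    lam[1L, 2L, ] <- v
    lam[2L, 1L, ] <- v
  }
  lam <- array(as.numeric(lam), c(n_states, n_states, n_modes))
  for (i in seq_len(n_modes)) {
    li <- lam[, , i]
    if (max(abs(li - t(li))) > 1e-12) stop("lam must be symmetric in the state indices")
    if (any(abs(diag(matrix(li, n_states))) > 0)) stop("lam diagonal must be zero")
  }
  if (is.null(lam0)) {
    lam0 <- matrix(0, n_states, n_states)
  } else if (length(lam0) == 1L && n_states == 2L) {
    lam0 <- matrix(c(0, lam0, lam0, 0), 2L)
  } else {
    lam0 <- matrix(as.numeric(lam0), n_states, n_states)
    if (max(abs(lam0 - t(lam0))) > 1e-12 || any(abs(diag(lam0)) > 0))
      stop("lam0 must be symmetric with zero diagonal")
  }
  out <- list(
    n_modes = n_modes, n_states = n_states,
    omega = omega, E_vert = E_vert, kappa = kappa, lam = lam, lam0 = lam0,
    eff_mass = 1 / omega
  )
  if (n_states == 2L) {      # precomputed pieces for the fast 2-state path
    out$lam12 <- lam[1L, 2L, ]
    out$lam0_12 <- lam0[1L, 2L]
    out$kap1 <- kappa[1L, ]
    out$kap2 <- kappa[2L, ]
  }
  structure(out, class = "lvc_model")
}

#' @export
print.lvc_model <- function(x, ...) {
  cat("LVC model:", x$n_modes, "mode(s),", x$n_states, "state(s)\n")
  cat("  omega  (Ha):", format(x$omega, digits = 4), "\n")
  cat("  E_vert (Ha):", format(x$E_vert, digits = 4), "\n")
  nz <- sum(x$kappa != 0)
  cat("  ", nz, "nonzero kappa,", sum(x$lam != 0) / 2, "nonzero interstate coupling(s)\n")
  invisible(x)
}

check_q <- function(model, q) {
  q <- as.numeric(q)
  if (length(q) != model$n_modes)
    stop("coordinate vector has length ", length(q), ", model has ",
         model$n_modes, " modes")
  q
}

#' Diabatic potential matrix of an LVC model
#'
#' @param model an \code{lvc_model}.
#' @param q mode-coordinate vector (length \code{n_modes}).
#' @return real symmetric n_states x n_states matrix (Hartree).
#' @export
diabatic_matrix <- function(model, q) {
  q <- check_q(model, q)
  ns <- model$n_states
  harm <- sum(model$omega / 2 * q^2)
  W <- matrix(0, ns, ns)
  diag(W) <- model$E_vert + as.numeric(model$kappa %*% q) + harm
  for (i in seq_len(model$n_modes))
    W <- W + model$lam[, , i] * q[i]
  W + model$lam0
}

# per-mode derivative dW/dq_i; returns n_states x n_states matrix
diabatic_gradient_matrix <- function(model, q, i) {
  W <- matrix(model$lam[, , i], model$n_states)
  diag(W) <- model$kappa[, i] + model$omega[i] * q[i]
  W
}

#' Adiabatic energies and eigenvectors of an LVC model
#'
#' Diagonalises the diabatic matrix at \code{q}.  Energies are returned in
#' ascending order.  The eigenvector gauge is fixed: each column's sign is
#' chosen so that its overlap with the corresponding column of
#' \code{gauge_ref} is non-negative; without a reference, the component of
#' largest magnitude is made positive.
#'
#' @inheritParams diabatic_matrix
#' @param gauge_ref optional eigenvector matrix from a previous (nearby)
#'   evaluation used to fix the sign continuity along a trajectory.
#' @return list with \code{energies} (ascending) and \code{vectors}
#'   (orthonormal columns).
#' @export
adiabatic_surface <- function(model, q, gauge_ref = NULL) {
  W <- diabatic_matrix(model, q)
  if (model$n_states == 2L) {
    # closed-form 2x2 symmetric eigenproblem (hot path of the propagators)
    m <- (W[1, 1] + W[2, 2]) / 2; d <- (W[1, 1] - W[2, 2]) / 2; c <- W[1, 2]
    r <- sqrt(d^2 + c^2)
    vals <- c(m - r, m + r)
    if (abs(c) < 1e-14) {
      vecs <- if (d <= 0) diag(2) else matrix(c(0, 1, 1, 0), 2)
    } else {
      v2 <- c(c, r - d); v1 <- c(r - d, -c)
      vecs <- cbind(v1 / sqrt(sum(v1^2)), v2 / sqrt(sum(v2^2)))
    }
  } else {
    e <- eigen(W, symmetric = TRUE)
    idx <- order(e$values)
    vals <- e$values[idx]
    vecs <- e$vectors[, idx, drop = FALSE]
  }
  for (j in seq_len(ncol(vecs))) {
    s <- if (is.null(gauge_ref)) {
      sign(vecs[which.max(abs(vecs[, j])), j])
    } else {
      s0 <- sign(sum(gauge_ref[, j] * vecs[, j]))
      if (s0 == 0) 1 else s0
    }
    if (s < 0) vecs[, j] <- -vecs[, j]
  }
  list(energies = vals, vectors = vecs)
}

#' Gradient of an adiabatic surface
#'
#' Hellmann-Feynman gradient \eqn{c_J^\top (\partial W/\partial q_i) c_J} of
#' adiabatic state \code{J} at \code{q}.
#'
#' @inheritParams diabatic_matrix
#' @param J electronic state index (1-based, ascending energy order).
#' @return numeric vector of length \code{n_modes} (Hartree per coordinate).
#' @export
adiabatic_gradient <- function(model, q, J) {
  q <- check_q(model, q)
  if (J < 1L || J > model$n_states) stop("state index out of range")
  ad <- adiabatic_surface(model, q)
  cJ <- ad$vectors[, J]
  vapply(seq_len(model$n_modes), function(i) {
    as.numeric(cJ %*% diabatic_gradient_matrix(model, q, i) %*% cJ)
  }, numeric(1))
}

#' Nonadiabatic coupling vector between two adiabatic states
#'
#' First-order derivative coupling
#' \eqn{d_{IJ,i} = c_I^\top (\partial W/\partial q_i) c_J / (E_J - E_I)}.
#' Near a degeneracy the formula diverges; if the adiabatic gap falls below
#' \code{floor} an error of class \code{aimsim_degeneracy} is raised.
#'
#' @inheritParams adiabatic_gradient
#' @param I,J distinct state indices.
#' @param floor minimum adiabatic gap (Hartree) below which the evaluation
#'   refuses to return a (numerically overflowing) vector.
#' @return numeric vector of length \code{n_modes} (inverse coordinate units).
#' @export
nac_vector <- function(model, q, I, J, floor = 1e-8) {
  q <- check_q(model, q)
  if (I == J) stop("nonadiabatic coupling requires two distinct states")
  ad <- adiabatic_surface(model, q)
  gap <- ad$energies[J] - ad$energies[I]
  if (abs(gap) < floor) {
    cond <- structure(class = c("aimsim_degeneracy", "error", "condition"),
                      list(message = sprintf(
                        "adiabatic states %d and %d degenerate at this geometry (gap %.3e Ha)",
                        I, J, abs(gap)), call = sys.call(-1)))
    stop(cond)
  }
  cI <- ad$vectors[, I]; cJ <- ad$vectors[, J]
  vapply(seq_len(model$n_modes), function(i) {
    as.numeric(cI %*% diabatic_gradient_matrix(model, q, i) %*% cJ)
  }, numeric(1)) / gap
}

#' Write / read LVC model files
#'
#' Plain-text key/value + array serialisation of an \code{lvc_model}
#' (YAML).  Units are Hartree / atomic units throughout; the file carries a
#' \code{schema} version field.
#'
#' @param model an \code{lvc_model}.
#' @param path file path.
#' @return \code{read_lvc_model} returns an \code{lvc_model}.
#' @export
write_lvc_model <- function(model, path) {
  obj <- list(schema = "aimsim-lvc-1",
              n_modes = model$n_modes, n_states = model$n_states,
              omega = model$omega, E_vert = model$E_vert,
              kappa = as.vector(model$kappa), lam = as.vector(model$lam),
              lam0 = as.vector(model$lam0))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_lvc_model
#' @export
read_lvc_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  if (!identical(obj$schema, "aimsim-lvc-1"))
    stop("unrecognised model file schema: ", obj$schema)
  lvc_model(omega = obj$omega, E_vert = obj$E_vert,
            kappa = matrix(obj$kappa, obj$n_states, obj$n_modes),
            lam = array(obj$lam, c(obj$n_states, obj$n_states, obj$n_modes)),
            lam0 = if (!is.null(obj$lam0))
              matrix(obj$lam0, obj$n_states, obj$n_states))
}
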