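#' Trajectory basis function (frozen Gaussian)
#'
#' A normalised multidimensional frozen Gaussian
#' \deqn{\chi(R) = e^{i\gamma} \prod_\rho (2\alpha_\rho/\pi)^{1/4}
#'   \exp[-\alpha_\rho (R_\rho-\bar R_\rho)^2
#'        + i \bar P_\rho (R_\rho-\bar R_\rho)]}
#' whose centre \eqn{(\bar R, \bar P)} follows a classical trajectory on one
#' adiabatic electronic surface and which carries a semiclassical phase
#' \eqn{\gamma}.
#'
#' @param state electronic state index (1-based).
#' @param R,P centre position and momentum vectors (atomic units).
#' @param alpha per-coordinate width vector (positive, atomic units).
#' @param gamma semiclassical phase (radians).
#' @param id unique token (auto-generated if missing).
#' @param parent_id id of the parent TBF, or \code{NA} for an ancestor.
#' @param birth_time time of creation (atomic time units).
#' @return object of class \code{tbf}.
#' @export
tbf <- function(state, R, P, alpha, gamma = 0, id = NULL,
                parent_id = NA_character_, birth_time = 0) {
  R <- as.numeric(R); P <- as.numeric(P)
  alpha <- rep_len(as.numeric(alpha), length(R))
  if (length(P) != length(R)) stop("R and P must have the same length")
  if (any(alpha <= 0)) stop("all widths must be positive")
  if (is.null(id)) id <- sprintf("tbf-%08x", sample.int(.Machine$integer.max, 1L))
  structure(list(id = id, state = as.integer(state), R = R, P = P,
                 alpha = alpha, gamma = as.numeric(gamma),
                 parent_id = parent_id, birth_time = birth_time),
            class = "tbf")
}

#' @export
print.tbf <- function(x, ...) {
  cat(sprintf("TBF %s on state %d (dim %d)\n", x$id, x$state, length(x$R)))
  cat("  R:", format(x$R, digits = 4), "\n")
  cat("  P:", format(x$P, digits = 4), "\n")
  cat("  alpha:", format(x$alpha, digits = 4), " gamma:",
      format(x$gamma, digits = 4), "\n")
  invisible(x)
}

# --- per-coordinate Gaussian moment kernels -------------------------------
#
# All bra-ket integrals reduce to moments of exp(-c2 x^2 + c1 x + c0) with
#   c2 = a_a + a_b
#   c1 = 2 a_a R_a + 2 a_b R_b + i (P_b - P_a)
#   c0 = -a_a R_a^2 - a_b R_b^2 + i (P_a R_a - P_b R_b)
# and normalisation (2 a_a/pi)^(1/4) (2 a_b/pi)^(1/4).  The helpers operate
# elementwise so the callers can pass matrices (vectorised pair assembly).

gauss1d_overlap <- function(aa, Ra, Pa, ab, Rb, Pb) {
  c2 <- aa + ab
  c1 <- 2 * aa * Ra + 2 * ab * Rb + 1i * (Pb - Pa)
  c0 <- -aa * Ra^2 - ab * Rb^2 + 1i * (Pa * Ra - Pb * Rb)
  (2 * aa / pi)^0.25 * (2 * ab / pi)^0.25 *
    sqrt(pi / c2) * exp(c0 + c1^2 / (4 * c2))
}

# first-moment ratio <x>/<1> of the pair kernel
gauss1d_mu1 <- function(aa, Ra, Pa, ab, Rb, Pb) {
  (2 * aa * Ra + 2 * ab * Rb + 1i * (Pb - Pa)) / (2 * (aa + ab))
}

# ratio <a|d/dx|b> / <a|b> for one coordinate (ket-side quantities)
gauss1d_deriv_ratio <- function(aa, Ra, Pa, ab, Rb, Pb) {
  mu1 <- gauss1d_mu1(aa, Ra, Pa, ab, Rb, Pb)
  -2 * ab * (mu1 - Rb) + 1i * Pb
}

# ratio <a|-d^2/dx^2|b> / <a|b> for one coordinate
gauss1d_kin_ratio <- function(aa, Ra, Pa, ab, Rb, Pb) {
  c2 <- aa + ab
  mu1 <- gauss1d_mu1(aa, Ra, Pa, ab, Rb, Pb)
  mu2 <- mu1^2 + 1 / (2 * c2)
  -(4 * ab^2 * (mu2 - 2 * Rb * mu1 + Rb^2) -
      4i * ab * Pb * (mu1 - Rb) - (Pb^2 + 2 * ab))
}

check_pair <- function(a, b) {
  if (length(a$R) != length(b$R))
    stop("TBFs have different dimensionality")
}

#' Overlap between two TBFs
#'
#' Closed-form complex overlap \eqn{\langle\chi_a|\chi_b\rangle}, the product
#' of per-coordinate 1-D Gaussian overlaps times the relative phase factor
#' \eqn{e^{i(\gamma_b-\gamma_a)}}.  Its modulus never exceeds 1.
#'
#' @param a,b TBFs of equal dimensionality.
#' @return complex scalar.
#' @export
overlap <- function(a, b) {
  check_pair(a, b)
  prod(gauss1d_overlap(a$alpha, a$R, a$P, b$alpha, b$R, b$P)) *
    exp(1i * (b$gamma - a$gamma))
}

#' Matrix element of the coordinate derivative between two TBFs
#'
#' \eqn{\langle\chi_a|\partial/\partial R_\rho|\chi_b\rangle} in closed form.
#'
#' @inheritParams overlap
#' @param rho coordinate index.
#' @return complex scalar.
#' @export
derivative_element <- function(a, b, rho) {
  check_pair(a, b)
  if (rho < 1L || rho > length(a$R)) stop("coordinate index out of range")
  overlap(a, b) *
    gauss1d_deriv_ratio(a$alpha[rho], a$R[rho], a$P[rho],
                        b$alpha[rho], b$R[rho], b$P[rho])
}

#' Nuclear kinetic-energy matrix element between two TBFs
#'
#' \eqn{\langle\chi_a|\hat T_n|\chi_b\rangle
#'   = \sum_\rho \frac{1}{2M_\rho}
#'     \langle\chi_a|-\partial^2/\partial R_\rho^2|\chi_b\rangle}
#' in closed form.
#'
#' @inheritParams overlap
#' @param masses per-coordinate masses (atomic units), positive.
#' @return complex scalar.
#' @export
kinetic_element <- function(a, b, masses) {
  check_pair(a, b)
  masses <- rep_len(as.numeric(masses), length(a$R))
  if (any(masses <= 0)) stop("masses must be positive")
  ratios <- gauss1d_kin_ratio(a$alpha, a$R, a$P, b$alpha, b$R, b$P)
  overlap(a, b) * sum(ratios / (2 * masses))
}

#' Time-derivative overlap element between two TBFs
#'
#' \eqn{\langle\chi_a|\partial\chi_b/\partial t\rangle} by the chain rule
#' through the ket's centre coordinates, momenta and phase.
#'
#' @inheritParams overlap
#' @param b_dynamics list with components \code{dR}, \code{dP} (vectors) and
#'   \code{dgamma} (scalar): the time derivatives of the ket TBF's centre
#'   from its classical equations of motion.
#' @return complex scalar.
#' @export
sdot_element <- function(a, b, b_dynamics) {
  check_pair(a, b)
  mu1 <- gauss1d_mu1(a$alpha, a$R, a$P, b$alpha, b$R, b$P)
  dR_part <- 2 * b$alpha * (mu1 - b$R) - 1i * b$P     # d/d Rbar ratio
  dP_part <- 1i * (mu1 - b$R)                          # d/d Pbar ratio
  overlap(a, b) * (sum(b_dynamics$dR * dR_part + b_dynamics$dP * dP_part) +
                     1i * b_dynamics$dgamma)
}

#' Centroid of a TBF pair
#'
#' The position where the product density \eqn{|\chi_a \chi_b|} peaks: the
#' width-weighted mean of the two centres, per coordinate.  This is the
#' evaluation point of electronic-structure quantities under the
#' zeroth-order saddle-point approximation.
#'
#' @inheritParams overlap
#' @return numeric position vector.
#' @export
centroid <- function(a, b) {
  check_pair(a, b)
  (a$alpha * a$R + b$alpha * b$R) / (a$alpha + b$alpha)
}
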