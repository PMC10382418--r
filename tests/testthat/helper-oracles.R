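# Numerical oracles used across the suite.  All are independent of the
# closed forms they check: quadrature on the raw Gaussian definition,
# finite differences, dense linear algebra.

# evaluate one 1-D Gaussian factor of a TBF (no phase factor)
g1d <- function(q, R, P, alpha) {
  (2 * alpha / pi)^0.25 * exp(-alpha * (q - R)^2 + 1i * P * (q - R))
}

# full TBF value at a point (vector q), with phase
tbf_value <- function(x, q) {
  prod(g1d(q, x$R, x$P, x$alpha)) * exp(1i * x$gamma)
}

# <a | op_rho | b> by per-coordinate adaptive quadrature, where op is the
# identity, d/dq, or -d^2/dq^2 acting on the ket in coordinate `rho`
quad_element <- function(a, b, op = c("1", "d", "d2"), rho = 1L) {
  op <- match.arg(op)
  n <- length(a$R)
  cplx_int <- function(f) {
    re <- stats::integrate(function(x) Re(f(x)), -Inf, Inf,
                           rel.tol = 1e-12, abs.tol = 1e-13)$value
    im <- stats::integrate(function(x) Im(f(x)), -Inf, Inf,
                           rel.tol = 1e-12, abs.tol = 1e-13)$value
    complex(real = re, imaginary = im)
  }
  out <- exp(1i * (b$gamma - a$gamma))
  for (k in seq_len(n)) {
    ak <- a$alpha[k]; bk <- b$alpha[k]
    fk <- if (k == rho && op == "d") {
      function(x) Conj(g1d(x, a$R[k], a$P[k], ak)) *
        (-2 * bk * (x - b$R[k]) + 1i * b$P[k]) * g1d(x, b$R[k], b$P[k], bk)
    } else if (k == rho && op == "d2") {
      function(x) Conj(g1d(x, a$R[k], a$P[k], ak)) *
        -((-2 * bk * (x - b$R[k]) + 1i * b$P[k])^2 - 2 * bk) *
        g1d(x, b$R[k], b$P[k], bk)
    } else {
      function(x) Conj(g1d(x, a$R[k], a$P[k], ak)) *
        g1d(x, b$R[k], b$P[k], bk)
    }
    out <- out * cplx_int(fk)
  }
  out
}

# overlap by quadrature
quad_overlap <- function(a, b) quad_element(a, b, "1")

# loop-based diabatic matrix (independent re-summation)
loop_diabatic <- function(model, q) {
  ns <- model$n_states
  W <- matrix(0, ns, ns)
  for (A in seq_len(ns)) {
    W[A, A] <- model$E_vert[A]
    for (i in seq_len(model$n_modes))
      W[A, A] <- W[A, A] + model$kappa[A, i] * q[i] +
        model$omega[i] / 2 * q[i]^2
    for (B in seq_len(ns)) if (B != A) {
      for (i in seq_len(model$n_modes))
        W[A, B] <- W[A, B] + model$lam[A, B, i] * q[i]
      W[A, B] <- W[A, B] + model$lam0[A, B]
    }
  }
  W
}

# matrix exponential via dense eigendecomposition (general complex matrix)
expm_eig <- function(A) {
  e <- eigen(A)
  e$vectors %*% diag(exp(e$values), nrow(A)) %*% solve(e$vectors)
}

# frozen-matrix amplitude propagator oracle: C(t) = exp(-i S^-1 (H - i Sdot) t) C
frozen_propagator <- function(C, S, Sdot, H, t) {
  A <- -1i * solve(S) %*% (H - 1i * Sdot)
  as.vector(expm_eig(A * t) %*% C)
}

# simple deterministic coupled-set fixture: n same-state TBFs in 1-D
make_set_1d <- function(n, state = 1L, spread = 1.2, seed = 7) {
  set.seed(seed)
  tbfs <- lapply(seq_len(n), function(k)
    tbf(state = state, R = (k - (n + 1) / 2) * spread,
        P = stats::runif(1, -0.5, 0.5), alpha = 0.5,
        gamma = stats::runif(1, 0, 2 * pi), id = paste0("f", k)))
  C <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  coupled_set(tbfs, C / sqrt(sum(abs(C)^2)))
}
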