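# Internal lean evaluation of the electronic structure at one geometry.
#
# The generic operations (adiabatic_surface, adiabatic_gradient, nac_vector)
# allocate matrices per call; the propagators evaluate the surfaces millions
# of times, so the two-state case (all shipped models) gets a fused
# closed-form path with no matrix construction.  Returns:
#   E     adiabatic energies, ascending
#   V     2 x 2 (or n x n) eigenvector matrix, gauge: largest component > 0
#   dW11, dW22, dW12  per-mode derivatives of the diabatic entries (2-state
#                     path only; dW12 is the constant lam12)
eval_point <- function(model, q) {
  if (model$n_states == 2L) {
    om <- model$omega
    h <- sum(om * q * q) * 0.5
    d1 <- model$E_vert[1L] + sum(model$kap1 * q) + h
    d2 <- model$E_vert[2L] + sum(model$kap2 * q) + h
    off <- sum(model$lam12 * q) + model$lam0_12
    m <- (d1 + d2) * 0.5; dd <- (d1 - d2) * 0.5
    r <- sqrt(dd * dd + off * off)
    if (abs(off) < 1e-14) {
      V <- if (dd <= 0) c(1, 0, 0, 1) else c(0, 1, 1, 0)
    } else {
      t1 <- r - dd
      nrm <- sqrt(t1 * t1 + off * off)
      V <- c(t1 / nrm, -off / nrm, off / nrm, t1 / nrm)
      # gauge: largest-|component| positive, per column
      if (abs(V[1L]) >= abs(V[2L])) { if (V[1L] < 0) V[1:2] <- -V[1:2] }
      else if (V[2L] < 0) V[1:2] <- -V[1:2]
      if (abs(V[3L]) >= abs(V[4L])) { if (V[3L] < 0) V[3:4] <- -V[3:4] }
      else if (V[4L] < 0) V[3:4] <- -V[3:4]
    }
    oq <- om * q
    list(E = c(m - r, m + r), V = V,
         dW11 = model$kap1 + oq, dW22 = model$kap2 + oq, dW12 = model$lam12)
  } else {
    ad <- adiabatic_surface(model, q)
    list(E = ad$energies, V = ad$vectors)
  }
}

# Column-vectorised two-state evaluation: Q is n_modes x K.  Returns
# adiabatic energies (length-K vectors), flattened eigenvector components
# (v11, v21 = lower state; v12, v22 = upper state), the gap, and the
# per-mode diabatic derivative rows needed for gradients and couplings.
ev2_cols <- function(model, Q) {
  om <- model$omega
  Q <- matrix(Q, model$n_modes)
  h <- 0.5 * colSums(om * Q * Q)
  d1 <- model$E_vert[1L] + colSums(model$kap1 * Q) + h
  d2 <- model$E_vert[2L] + colSums(model$kap2 * Q) + h
  off <- colSums(model$lam12 * Q) + model$lam0_12
  m <- (d1 + d2) * 0.5; dd <- (d1 - d2) * 0.5
  r <- sqrt(dd * dd + off * off)
  t1 <- r - dd
  nrm <- sqrt(t1 * t1 + off * off)
  bad <- nrm < 1e-14              # uncoupled columns: diabatic eigenvectors
  nrm[bad] <- 1
  v11 <- t1 / nrm; v21 <- -off / nrm
  v12 <- off / nrm; v22 <- t1 / nrm
  if (any(bad)) {
    swap <- bad & (dd > 0)
    keep <- bad & !swap
    v11[keep] <- 1; v21[keep] <- 0; v12[keep] <- 0; v22[keep] <- 1
    v11[swap] <- 0; v21[swap] <- 1; v12[swap] <- 1; v22[swap] <- 0
  }
  # gauge: largest-|component| positive, per column
  s1 <- ifelse(abs(v11) >= abs(v21), sign(v11), sign(v21))
  s2 <- ifelse(abs(v12) >= abs(v22), sign(v12), sign(v22))
  s1[s1 == 0] <- 1; s2[s2 == 0] <- 1
  v11 <- v11 * s1; v21 <- v21 * s1
  v12 <- v12 * s2; v22 <- v22 * s2
  list(E1 = m - r, E2 = m + r, gap = 2 * r,
       v11 = v11, v21 = v21, v12 = v12, v22 = v22,
       dW11 = model$kap1 + om * Q, dW22 = model$kap2 + om * Q)
}

# per-column adiabatic gradients for a vector of states J (length K)
ev2_gradient <- function(model, ev, J) {
  up <- J == 2L
  c1 <- ev$v11; c1[up] <- ev$v12[up]
  c2 <- ev$v21; c2[up] <- ev$v22[up]
  nm <- nrow(ev$dW11)
  ev$dW11 * rep(c1 * c1, each = nm) + ev$dW22 * rep(c2 * c2, each = nm) +
    model$lam12 * rep(2 * c1 * c2, each = nm)
}

# per-column 1->2 coupling vectors with floored gap (n_modes x K)
ev2_nac12 <- function(model, ev, floor = 1e-8) {
  nm <- nrow(ev$dW11)
  num <- ev$dW11 * rep(ev$v11 * ev$v12, each = nm) +
    ev$dW22 * rep(ev$v21 * ev$v22, each = nm) +
    model$lam12 * rep(ev$v11 * ev$v22 + ev$v21 * ev$v12, each = nm)
  gap_f <- pmax(ev$gap, floor)
  list(d = num / rep(gap_f, each = nm), clamped = ev$gap < floor)
}

# adiabatic gradient of state J from an eval_point result (2-state fast path)
ep_gradient <- function(model, q, ep, J) {
  if (model$n_states == 2L) {
    c1 <- ep$V[2L * J - 1L]; c2 <- ep$V[2L * J]
    c1 * c1 * ep$dW11 + c2 * c2 * ep$dW22 + 2 * c1 * c2 * ep$dW12
  } else {
    cJ <- ep$V[, J]
    vapply(seq_len(model$n_modes), function(i) {
      as.numeric(cJ %*% diabatic_gradient_matrix(model, q, i) %*% cJ)
    }, numeric(1))
  }
}

# NAC vector with floored gap from an eval_point result
ep_nac_floored <- function(model, q, ep, I, J, floor = 1e-8) {
  gap <- ep$E[J] - ep$E[I]
  gap_f <- sign(gap + (gap == 0)) * max(abs(gap), floor)
  if (model$n_states == 2L) {
    a1 <- ep$V[2L * I - 1L]; a2 <- ep$V[2L * I]
    b1 <- ep$V[2L * J - 1L]; b2 <- ep$V[2L * J]
    num <- a1 * b1 * ep$dW11 + a2 * b2 * ep$dW22 +
      (a1 * b2 + a2 * b1) * ep$dW12
  } else {
    cI <- ep$V[, I]; cJ <- ep$V[, J]
    num <- vapply(seq_len(model$n_modes), function(i) {
      as.numeric(cI %*% diabatic_gradient_matrix(model, q, i) %*% cJ)
    }, numeric(1))
  }
  list(d = num / gap_f, clamped = abs(gap) < floor)
}
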