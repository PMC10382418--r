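---
title: "Multiple spawning dynamics on vibronic coupling models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple spawning dynamics on vibronic coupling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aimsim)
```

## The model and the method

`aimsim` propagates coupled electron–nuclear dynamics for analytic
linear vibronic coupling (LVC) Hamiltonians.  In dimensionless normal
modes the diabatic potential matrix is

$$ W_{AA}(q) = E_A + \sum_i \kappa_{A,i} q_i + \sum_i \tfrac{\omega_i}{2} q_i^2,
   \qquad W_{AB}(q) = \lambda^{(0)}_{AB} + \sum_i \lambda_{AB,i} q_i , $$

with kinetic energy $\sum_i (\omega_i/2)\, p_i^2$, i.e. each mode carries
effective mass $1/\omega_i$.  In this convention the vibrational ground
state of an uncoupled surface is $\exp(-q^2/2)$, so the matching frozen
Gaussian width is $\alpha_i = 1/2$ and the Wigner distribution of the
ground state is a product of normals with variance $1/2$ in both $q$ and
$p$.  The constant term $\lambda^{(0)}$ is an extension used only by flat
two-level test models (Rabi oscillations); it is zero in all conical
intersection models.

The nuclear wavefunction on each electronic state is expanded in
trajectory basis functions (TBFs): normalised frozen Gaussians whose
centres follow classical trajectories (velocity Verlet) on single
adiabatic surfaces and which carry a semiclassical phase $\gamma$ with
$\dot\gamma = T - V$, the classical Lagrangian.  Any constant offset in
this convention cancels in observables through the amplitude equations;
the choice makes a single TBF's amplitude exactly stationary
($H - i\dot S = 0$ for a one-member set), which the test suite asserts.

The amplitudes obey $\dot C = -i\, S^{-1} (H - i\dot S)\, C$.  Overlap
and kinetic elements are analytic; same-state potential elements and
cross-state first-order nonadiabatic couplings are evaluated under the
zeroth-order saddle-point approximation (SPA0): the electronic quantity
is taken at the centroid (width-weighted midpoint) of the pair and
multiplied by the analytic Gaussian element.  Second-order nonadiabatic
couplings are omitted.  The assembled $H$ is Hermitized,
$H \leftarrow (H + H^\dagger)/2$; the analytic cross blocks are already
Hermitian for a real coupling vector, so this guards only against the
independent per-pair centroid evaluations drifting apart.

New TBFs enter through the spawning algorithm: each TBF monitors the
magnitude of the nonadiabatic coupling vector at its centre; above
`csthresh` (and with Mulliken population at least `poptospawn`) the
amplitudes are frozen, a clone of the parent runs forward with the
reduced step until a three-point local maximum of the indicator (or the
duration cap of 100 base steps), a child is created there on the coupled
state with zero amplitude and with the parent's momentum adjusted along
the coupling direction so classical energy is conserved (if that is
impossible the spawn is "forbidden"), the child is backpropagated to the
entry time, and the `omax` tests decide acceptance: the child must
overlap its parent by at least `omax` at the spawning geometry, and must
not overlap any other existing TBF by more than `omax` at the entry
time.  Re-entry into the spawning mode is blocked until the indicator
falls back below `csthresh`, so each coupling-region passage spawns at
most one child per parent and state.

Ancestor TBFs drawn from the Wigner distribution form independent
coupled sets (the independent first-generation approximation); their
population traces are averaged with equal weights.  Runs that abort in
the adaptive stepper are excluded from the average and counted.

## Eigenvector gauge

The adiabatic eigenvectors of a 2×2 diabatic matrix are defined only up
to sign, and the sign of the nonadiabatic coupling vector inherits that
gauge.  A pointwise convention (largest component positive) flips sign
across the seam, which reverses the cross-state Hamiltonian element in
the middle of a crossing and makes the two halves of the transfer
integral cancel — the population transfer then collapses to a few
percent of the exact value.  `assemble_matrices` therefore keeps a
per-TBF-pair cache of the previous eigenvectors at that pair's centroid
and chooses each new sign to maximise the overlap with the cached one
(first evaluation: largest component positive).  This makes the coupling
continuous in time along each pair's path.  A closed loop around the
conical intersection still accumulates the geometric sign change — a
known limitation of adiabatic frozen-Gaussian dynamics that this package
shares.

## Adaptive time stepping

The base nuclear step (`timestep`, default 0.1 atu for the shipped
model) is reduced by `factor` (default 4) whenever any TBF's coupling
magnitude exceeds `csthresh/2` or a spawning mode is active.  After each
step two rejection tests run: total-norm drift above `norm_tol` (1e-4)
and, as the energy test, the largest per-TBF *classical* energy drift
above `energy_tol` (1e-4 Ha).  The classical energy is what the Verlet
integrator controls and its error shrinks with the step, so halving
converges; the quantum expectation $\langle H \rangle$ under SPA0 has a
small step-size-independent drift (the centroid moves and the
approximation error changes), which would make rejection loops
non-terminating.  On rejection the step is halved until accepted or
until it falls below `dt_min` (`timestep`/64), at which point the run
aborts with the tripped tolerance as diagnostic.  The amplitude
equations are integrated with classical RK4 using at least four substeps
per nuclear step and linear interpolation of $S$, $\dot S$, $H$ across
the step; the regularised inverse (eigenvalues of $S$ below `regthresh`
discarded) is computed once per interpolation node.

## The shipped model and reference parameters

`make_model("sloped_ci")` is a two-mode, two-state LVC model:
$\omega = (0.30, 0.18)$ Ha, $E = (0, 0.60)$ Ha,
$\kappa_1 = (-0.20, 0)$, $\kappa_2 = (-0.50, 0)$,
$\lambda = (0, 0.35)$ Ha.  The conical intersection sits at
$q = (2, 0)$ at energy 0.2 Ha, 0.4 Ha below the Franck–Condon point, and
both surface slopes along the tuning mode have the same sign at the
seam (a sloped topography, favouring recrossing).  The parameters were
chosen so the first seam passage is of intermediate Landau–Zener
character — roughly half the amplitude crosses diabatically — which is
the regime adaptive spawning targets; a much weaker coupling makes the
adiabatic populations swing fully and coherently (a nearly diabatic
passage that a one-child-per-passage basis cannot follow), a much
stronger one suppresses transfer altogether.  This is a stand-in of
standard LVC form, not a published molecular parameter set.

Reference simulation parameters (the `sim_params()` defaults):
`timestep` 0.1 atu (0.025 reduced), `t_final` 30 atu (about three tuning
periods, enough for the initial decay and the first recrossings),
`csthresh` 0.5, `poptospawn` 0.001, `omax` 0.6, `olapthresh` 0.001,
`regthresh` 1e-4, widths 1/2 per mode, 100 initial conditions.  The
threshold values follow the published reference choices for a
two-dimensional cation model where one exists (`poptospawn`, `omax`,
`olapthresh`, `regthresh`); `csthresh` is set between the background
coupling magnitude along excited-state trajectories (≈ 0.25 at the
Franck–Condon point) and the seam peaks (≫ 1), so that passages are
detected individually and the re-entry block releases between them.

## What the exact reference shows, and what passing tests mean

The split-operator grid propagator (Strang splitting, Fourier kinetic
step, pointwise diabatic matrix exponential, 160 points per mode over
roughly ±10, `dt` 0.02) is converged at the 1e-3 level for the shipped
model — refining grid and step leaves the trace unchanged at that scale —
and conserves norm to 1e-10.  Starting the grid wavepacket on the upper
*adiabatic* state imprints a conical kink on the diabatic components at
the intersection; its Fourier tail decays only algebraically and shows
up as a harmless ~1e-6 background density on the grid boundary, which is
why intersection runs use a looser `boundary_tol` than the default
1e-8.

Against this reference, the 100-IC AIMS ensemble reproduces the final
excited-state population to about 0.03 absolute, with the largest
pointwise deviation (≈ 0.16) at the elbow of the decay near t = 10 atu,
where the exact wavepacket completes its first-passage transfer faster
than the incoherently averaged, one-child-per-passage basis.  The
synthetic Wigner ensemble emulates the quantum initial state exactly in
distribution; what it does not emulate is inter-ancestor coherence,
which the independent first-generation approximation discards by
construction.  Passing tests therefore demonstrate the method's
behaviour on smooth low-dimensional LVC models, not on-the-fly molecular
dynamics: there are no conical-intersection seams of higher dimension,
no anharmonicity, and no electronic-structure noise here.

## Numerical choices and degenerate inputs

* Degeneracy floor for coupling vectors: inside matrix assembly the
  adiabatic gap in the denominator is clamped at 1e-8 Ha (sign
  preserved) and the event is flagged; the user-facing `nac_vector`
  raises a classed error instead of returning an overflowing vector.
* The conservation demonstrations run where their bounds are
  diagnostic: classical energy on a smooth single surface at the reduced
  reference step (drift < 1e-6 Ha over 1e4 steps; trajectories that
  skirt the cone tip see the Verlet error rise to ~1e-5 there), and
  amplitude norm for a coupled two-TBF set at `dt` 0.01 with exact
  $\dot S$, Hermitized $H$ and no regularisation truncation
  (drift < 1e-6 over 1e3 steps).
* Screening (`olapthresh`) zeroes only $H$ and $\dot S$ couplings; $S$
  is kept exact to preserve positive semidefiniteness.  With
  `olapthresh = 0` the screened path reproduces the unscreened result
  bit for bit, and the per-step count of centroid evaluations equals
  $N(N+1)/2$.
* `regthresh` is an absolute eigenvalue threshold on the unit-diagonal
  overlap matrix, matching the conventional 1e-4 default.
* Ties and boundary cases in the spawning mode: a monotonically
  decreasing indicator places the spawn at the entry point; an indicator
  still rising at the duration cap spawns at the cap and flags the
  event; children inherit the parent's widths and phase.
* The `timestep` sweep multiplies base and reduced steps together,
  mirroring how the adaptive scheme is used in practice.

## Sensitivity layer

`aims_sweep` varies one parameter at a time with shared (paired) Wigner
initial conditions, so the reference value reproduces the reference
trace exactly.  Deviations are signed relative differences of the
excited-state population, defined only where the reference population is
at least 0.01 (division floor), pooled over output times and swept
values, with the most extreme value per parameter (largest
$|\log_{10}(v/v_{\rm ref})|$) excluded by default.  The pooled sample is
summarised by a Gaussian-kernel density with Scott's bandwidth
$\hat\sigma n^{-1/5}$.  At the shipped scale the qualitative ordering
matches the expectation that the spawning threshold and the TBF widths
matter most: multiplying `csthresh` by 10 or 100 progressively traps
population in the excited state; `poptospawn` = 0.5 traps it; halving
the widths slows and doubling them speeds the mid-time depopulation;
while `olapthresh` up to 0.1 and `regthresh` between 1e-5 and 1e-3 leave
the trace essentially unchanged.

## Known limitations

* Geometric-phase effects around the intersection are not represented
  (adiabatic representation with sign-continuous but single-valued
  per-pair gauges).
* SPA0 misestimates couplings whose length scale is shorter than the
  pair overlap — near-seam centroids in strongly diabatic passages; the
  adaptive step contains but does not remove this error.
* The grid reference is limited to few-mode models (memory and
  pointwise eigensystem cost grow with the full grid).
* Exact (non-SPA0) integrals exist only as test oracles, not as a
  production path.
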