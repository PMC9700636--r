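---
title: "Methods: large-deviation and information geometry of jump processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: large-deviation and information geometry of jump processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumpgeom)
```

## The model class

`jumpgeom` treats Markov jump processes on the non-negative integer lattice:
`D` species with counts `n = (n_1, ..., n_D)`, and reactions
`y_r -> ybar_r` firing with mass-action propensity
`k_r * prod_i n_i! / (n_i - y_ri)!` (proportional sampling of reactant
tuples). The probability distribution evolves under the master equation
`d rho / dt = T rho`, with the continuous-time generator `T` having
non-negative off-diagonal jump rates and columns summing to zero — the
convention under which `exp(tT)` is a stochastic semigroup. (A transition
*kernel* over a finite step has columns summing to one; the generator of its
time derivative must sum to zero, and that is the form built here.)

Everything else in the package derives from the moment/cumulant generating
function of `rho`,

$$\psi(\theta) = \log \sum_n \rho_n e^{\theta \cdot n},$$

which ties three strands together:

1. **Exponential families.** Tilting `rho` by `e^{theta n - psi}` sweeps out
   an exponential family; `grad psi` is the tilted mean, `Hess psi` the
   Fisher metric `g`, the third derivative the Amari–Chentsov cubic tensor,
   and the Legendre transform `psi*(n)` the large-deviation function whose
   Bregman divergence is a Kullback–Leibler divergence.
2. **Importance sampling.** The tilted distribution is the variance-optimal
   proposal for tail queries `P(n > nbar)`; the reweighted indicator
   `exp(psi - theta n) I{n > nbar}` is unbiased, bounded by the Chernoff
   factor `exp(psi - theta nbar)`, and the optimal tilt is the Legendre
   maximizer `theta(nbar)` with bound `exp(-psi*(nbar))`.
3. **Hamiltonian dynamics.** Acting on generating functions, the generator
   becomes the Liouville function `L(phid, phi)` — a polynomial for
   mass-action kinetics — and at leading exponential order the CGF evolves
   along stationary paths of the Hamiltonian system
   `dtheta/dt = dL/dn`, `dn/dt = -dL/dtheta`, with final-time tilt
   `phid_T = z` and the initial condition supplied by the gradient of the
   initial CGF. Liouville's theorem then makes a phase-space density
   (`exp` of the stationary-path CGF) and the tangent inner product
   `delta theta . delta n` invariants of motion, even though the underlying
   process is dissipative: contraction of base distributions is exactly
   compensated by expansion of likelihood-ratio sensitivity. That balance is
   the substance of the adjoint (`eta`) coordinates and the flat
   coherent-state connection implemented here.

## The two-state system as verification surface

For `N` independent walkers hopping `a <-> b` with rates `k+`, `k-`, every
quantity has a closed form, so the package uses this system to verify its
generic machinery end to end. In descaled time (`dtau/dt = k+ + k-`) and
offset coordinates (`nu`-type variables in `(-1/2, 1/2)`, zero at a
symmetric 50/50 split):

- steady state `nu_ss = (k+ - k-) / (2 (k+ + k-))`;
- base offset `nu_bar(tau) - nu_ss = (nu_bar0 - nu_ss) e^{-tau}` relaxes
  forward, tilt offset `nu_under(tau) - nu_ss = (nu_underT - nu_ss)
  e^{tau - T}` grows toward its imposed final value;
- overlap parameter
  `Lambda = (nu_bar0 - nu_ss)(nu_underT - nu_ss) / (1/4 - nu_ss^2)`,
  conserved density `PhiHat0 = (1 + Lambda e^{-T})^{-1}`, invariant CGF per
  walker `psi/N = -log PhiHat0`;
- Fisher eigenvalue `dnu/dtheta` in two forms (a product over the base and
  tilt measure factors times `PhiHat0^2`, and `1/4 - nu^2` in additive
  exponential coordinates) whose equality is asserted at every evaluation;
- the conserved volume `∫ dv du PhiHat0^2` over the image of a rectangle of
  boundary data, in the fully descaled coordinates `u, v`.

Because the hopping dynamics is linear, a binomial distribution stays
binomial, and the stationary-path (saddle) CGF equals the exact lattice CGF
*identically*, not just to leading order; the test suite asserts this
equality to 1e-10 per walker for `N` in {50, 100, 200} rather than a
finite-size convergence rate, which would be comparing machine noise.
Likewise `psi*(N nu)/N` for binomials is exactly `N`-independent, so the
large-deviation-scaling checks on the binomial ladder assert the differences
sit at the noise floor.

## Numerical choices

- **Truncation.** Lattices are truncated at user-specified `max_counts`.
  Propensities of jumps that would leave the box are removed from the
  generator — keeping columns summing to zero, hence probability conserved
  *within* the box — and accumulated per source state in a `lost_rate`
  attribute so truncation error is visible rather than silently reflected.
  Base-distribution constructors track the probability mass lost to
  truncation (`lost_mass` attribute). Default Poisson truncation is the mean
  plus ten standard deviations.
- **Enumeration.** States are enumerated row-major over the species index
  (species 1 slowest), so flat indices are reproducible; conserved sectors
  (e.g. fixed total `N`) are selected *before* the generator is built, which
  is also how degenerate steady-state problems are made well-posed.
- **Evolution.** Dense `Matrix::expm` up to 2000 states; `deSolve::lsoda`
  with `rtol 1e-10 / atol 1e-12` above. Steady states come from an SVD null
  space with a relative threshold of `1e-8`; a multi-dimensional null space
  raises an error naming the sector issue.
- **Moments.** All CGF, mean, Fisher, cubic-tensor and divergence
  computations are exact lattice sums (log-sum-exp stabilized); finite
  differences appear only as cross-checks in the tests (central, step
  `1e-4`).
- **Legendre transform.** Damped Newton on the concave dual with gradient
  tolerance `1e-9`, using the Fisher pseudo-inverse with eigenvalue
  threshold `1e-10` so conserved-quantity flat directions are projected out;
  the degenerate subspace is returned explicitly. Targets outside the
  reachable mean range, or off the conserved sector, raise "unreachable
  mean" errors.
- **Sampling.** Inverse-CDF on the truncated lattice with a mandatory
  integer seed; the caller's RNG state is saved and restored. Tail queries
  are one-dimensional by construction (multi-species distributions are first
  reduced by `dist_marginal`); the strict convention `n > nbar` is the
  default for tail estimation and the non-strict `n >= nbar` for the
  tail-ratio parameter-difference estimator, and each report names the
  convention used.
- **Boundary-value problem.** Single shooting on the initial tilt with
  damped Newton (finite-difference Jacobian, step `1e-7`), integration by
  `deSolve` `ode45` at `rtol 1e-10`; the initial guess
  `theta_0 = log(z) e^{-lambda T}` uses the slowest mean-field relaxation
  rate `lambda` at the steady state. The action is accumulated as an
  auxiliary ODE state, and the saddle CGF is `psi_0(theta_0) - S`.
  Backward sweeps (tangent transport) integrate in reversed time via the
  substitution `s = T - t`. Shooting failure after bounded damping raises an
  error reporting the boundary residual; for multistable systems only the
  single branch found by shooting is reported.
- **Second derivatives of `L`.** Analytic throughout: mass-action Liouville
  functions are polynomial in the coherent-state chart and
  exponential-polynomial in the number-potential chart, so the variational
  (monodromy, tangent-transport) equations use exact coefficients.
- **Volume quadrature.** Tensor-product Gauss–Legendre (order 48 per axis)
  over the mapped boundary rectangle. Because the trajectory laws scale the
  two axes by `e^{tau-T}` and `e^{-tau}` while the density depends only on
  the invariant product `u v`, the integral is conserved to quadrature
  precision, and the reported residual is a genuine end-to-end check of the
  construction.

## Monodromy conventions

The monodromy determinant on the dynamical (nonzero Fisher eigenvalue)
subspace equals 1 in any chart — that is Liouville's theorem and is what
`liouville_volume_check` asserts. Its *eigenvalues* are chart-dependent: in
the number-potential chart along a tilted trajectory the local growth rate is
`k+ e^w + k- e^{-w}` (with `w` the tilt difference), which integrates to
slightly more than `T` off the steady state, while in the descaled boundary
coordinates `(v, u)` of the two-state closed form the rates are exactly
`±1`, giving eigenvalues `e^{+T}` and `e^{-T}`. `two_state_monodromy`
computes the latter by finite differences of the closed-form laws; the pure
exponential eigenvalues should be expected in that chart, not in `(theta, n)`.

## What the synthetic test conditions do and do not show

All inputs are synthetic: Poisson and binomial bases, the two-state network,
and small nonlinear birth/annihilation models. These exercise every code
path — conserved sectors, degenerate Fisher directions, nonlinear Hamiltonian
flows, truncation loss — under conditions where independent oracles (closed
forms, exact lattice sums, brute-force boundary perturbation) exist. They do
not probe: severely multimodal or multistable landscapes (shooting finds one
branch and says so), lattices too large for exact summation (where only the
sampling layer applies), time-dependent rate coefficients (the adjoint
transform explicitly rejects them, since the descaling reference would
acquire a time derivative), or heavy-tailed base distributions outside the
exponential-family setting. The tail-ratio estimator of a parameter
difference is a leading-exponential construction: at `N = 200` and thresholds
at the midpoint of the two arm means plus 0.5 and 1.5 standard deviations, a
planted log-odds difference of 0.2 is recovered with a systematic bias of
roughly a fifth of its value (verified against exact binomial tails), which
tightens as `N` grows; thresholds anchored to a single arm sit noticeably
further off. Threshold placement is therefore user-supplied, never chosen
automatically.

## Problem sizes used in the checks

Desk scale throughout, chosen so every oracle is exact: lattices up to a few
thousand states; binomial ladders `N` in {20, 40, 80, 160}; boundary-value
problems on 2–4 phase-space dimensions with 300-point output grids;
`1e5`–`1e6` Monte Carlo draws for the stochastic estimator checks; 200-seed
replicate studies for unbiasedness. The conserved-volume and
density-extrema computations use 48-node Gauss–Legendre quadrature and an
801-point grid per axis respectively.
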