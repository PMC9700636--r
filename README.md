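# jumpgeom

Large-deviation and information geometry of Markov jump processes on
non-negative integer lattices.

## What it is for

Stochastic population processes — chemical reaction networks with mass-action
kinetics, hopping walkers, birth–death systems — evolve probability
distributions ρ(n) over integer counts under a master equation
dρ/dt = T ρ. Their rare-event structure is carried by the cumulant generating
function (CGF)

    ψ(θ) = log Σ_n ρ_n e^{θ·n},

whose gradient is the tilted mean n(θ), whose Hessian is the Fisher
information metric g(θ), and whose Legendre transform ψ*(n) is the
large-deviation (rate) function. Exponentially tilted distributions
ρ̃_n = ρ_n e^{θ·n − ψ} are simultaneously the importance distributions of
variance-optimal rare-event sampling and the coordinates of an exponential
family, so one machinery serves statistics and geometry at once.

`jumpgeom` is for researchers who want to compute with this machinery
directly:

- **Master-equation layer** — build sparse generators on truncated lattices
  (with conserved-sector restriction and explicit truncation-loss tracking),
  evolve distributions by matrix exponential or stiff ODE integration, solve
  steady states.
- **Information geometry** — exact-summation CGFs, tilting, Legendre-dual
  large-deviation functions, Fisher metrics with degenerate
  (conserved-quantity) directions handled by pseudo-inverse, Amari–Chentsov
  cubic tensors, Bregman/KL divergences.
- **Importance sampling** — exact tail probabilities, unbiased tilted
  estimators `h̃ = e^{ψ−θn} I{n > n̄}` with Chernoff bound `e^{ψ−θn̄}` and its
  variance analogue, the variance-optimal tilt θ(n̄) with bound `e^{−ψ*(n̄)}`,
  and a tail-ratio estimator of differences in exponential parameters between
  two bases.
- **Doi–Peliti stationary paths** — the Liouville (Hamiltonian) function
  ℒ(φ†, φ) of any mass-action network with exact derivatives in both the
  coherent-state and number-potential charts, shooting solutions of the
  two-point boundary problem (final tilt φ†_T = z, initial CGF gradient),
  Hamilton–Jacobi residuals, tangent-field transport with its conserved
  inner product δθ·δn, Liouville-theorem diagnostics (zero phase-space
  divergence, unit monodromy determinant), and adjoint (η) coordinates that
  exchange the roles of base distribution and likelihood ratio.
- **Two-state closed forms** — for N walkers hopping `a ⇌ b` every quantity
  above is available in closed form: the overlap parameter Λ, the conserved
  density Φ̂₀ = (1 + Λe^{−T})⁻¹ with invariant CGF ψ/N = −log Φ̂₀, exponential
  trajectory laws for the base and tilt offsets (ν̄, ν̲), the Fisher
  eigenvalue in both its product and additive-coordinate forms, the conserved
  phase-space volume ∫ dv du Φ̂₀², and the flat coherent-state connection
  whose ±1 transport eigenvalues balance dynamics against inference.

## Worked example

```r
library(jumpgeom)

## Two-state system: k+ = 2/3, k- = 1/3 so nu_ss = 1/6, descaled tau = t
p  <- two_state_params(k_plus = 2/3, k_minus = 1/3)
b  <- two_state_boundary(nu_bar0 = -1/4, nu_underT = -1/6, T = 3)
ph <- phi0_and_invariant_cgf(p, b)
#> Lambda = 0.625  PhiHat0 = 0.969822  psi/N = 0.030643

## conserved phase-space volume of a boundary rectangle, five times in [0,3]
vol <- two_state_volume(p, -1/6 + c(-0.075, 0.075),
                        -1/4 + c(-0.05, 0.05), T = 3)
#> conserved volume integral: 0.0031610422 (max deviation 4.34e-19)

## rare-event estimation for a Poisson(2) count exceeding 5
rho   <- dist_poisson(2, max_counts = 60)
exact_tail(rho, 5)                        # 0.0165636
theta <- optimal_tilt(rho, 5)             # 0.916291 = log(5/2)
attr(theta, "ldf_bound")                  # 0.205676 = e^{-psi*(5)}
tilted_estimate(rho, 5, as.numeric(theta), n_samples = 1e5, seed = 7)
#> Tilted tail estimate: 0.0166165 (se 9.19e-05, n = 100000,
#>                                  theta = 0.916291, strict n > nbar)
#>   Chernoff bound 0.205676, variance bound 0.00313238, seed 7
```

The tilted estimator lands within one standard error of the exact tail with
a sample variance about 19 times smaller than naive Monte Carlo at the same
sample size.

Λ = 0.625 is the overlap of the initial base offset (ν̄₀ = −1/4) and final
tilt offset (ν̲_T = −1/6) with the steady state (𝛎 = 1/6); Φ̂₀² is the
density conserved along stationary trajectories, and ψ/N = −log Φ̂₀ is the
value of the CGF per walker that the whole stationary path maintains.

A command-line wrapper over the same functions is installed at
`system.file("cli", "jumpgeom", package = "jumpgeom")`, with subcommands
`evolve`, `cgf`, `ldf`, `tilt-estimate`, `stationary-path`, `two-state`, and
`fixture`; every stochastic subcommand requires `--seed` and every run writes
a manifest echoing its parameters.

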