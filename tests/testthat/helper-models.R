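# Shared model builders. The canonical two-state example uses k+ = 2/3,
# k- = 1/3 so that k+ + k- = 1 and descaled time tau equals physical time;
# the steady-state offset is nu_ss = 1/6 and the reference boundary data are
# nu_bar0 = -1/4, nu_underT = -1/6, T = 3.

two_state_spec <- function(k_plus = 2/3, k_minus = 1/3) {
  jump_process(c("a", "b"), list(
    list(reactants = c(a = 1), products = c(b = 1), rate = k_plus),
    list(reactants = c(b = 1), products = c(a = 1), rate = k_minus)),
    name = "two-state hopping")
}

birth_death_spec <- function(b = 1, d = 1) {
  jump_process("a", list(
    list(reactants = NULL, products = c(a = 1), rate = b),
    list(reactants = c(a = 1), products = NULL, rate = d)),
    name = "birth-death")
}

ref_params <- function() two_state_params(2/3, 1/3)

ref_boundary <- function() two_state_boundary(-1/4, -1/6, 3)

# final-time generating-function argument z = (z_a, z_b) that imposes the
# tilt offset nu_underT while fixing the conserved component (z nu_ss sum = 1)
ref_z <- function(p = ref_params(), b = ref_boundary()) {
  phidT <- (b$nu_underT - p$nu_ss) / (0.25 - p$nu_ss^2)
  PhiT <- 1 - p$nu_ss * phidT
  c(PhiT - phidT / 2, PhiT + phidT / 2)
}

# memoized reference BVP solution (several test files reuse it)
ref_traj <- local({
  cache <- new.env(parent = emptyenv())
  function(N = 1, n_steps = 300) {
    key <- paste0("N", N, "_", n_steps)
    if (is.null(cache[[key]])) {
      b <- ref_boundary()
      psi0 <- cgf_multinomial(N, c(0.5 - b$nu_bar0, 0.5 + b$nu_bar0))
      L <- build_liouville(two_state_spec())
      cache[[key]] <- solve_bvp(L, psi0, ref_z(), b$T, n_steps = n_steps)
    }
    cache[[key]]
  }
})

# evolved two-state base distribution: binomial form is preserved with
# nu_b(t) relaxing exponentially toward the steady state
evolved_two_state <- function(N, nu_b0, t, p = ref_params()) {
  dist_two_state(N, p$nu_b + (nu_b0 - p$nu_b) * exp(-p$tau_rate * t))
}
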