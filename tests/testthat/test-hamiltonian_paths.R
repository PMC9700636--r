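# Liouville functions and stationary-path dynamics: construction, Hamiltonian
# structure, boundary-value solves against the two-state closed forms,
# Hamilton-Jacobi and Liouville-theorem diagnostics, tangent transport,
# adjoint coordinates.

nonlinear_spec <- function() {
  # birth plus pairwise annihilation: a genuinely nonlinear Hamiltonian flow
  jump_process("a", list(
    list(reactants = NULL, products = c(a = 1), rate = 5),
    list(reactants = c(a = 2), products = NULL, rate = 0.1)),
    name = "birth-annihilation")
}

test_that("Liouville function matches closed forms and conserves probability", {
  L <- build_liouville(two_state_spec(2, 1))
  set.seed(1)
  for (rep in 1:5) {
    phid <- exp(runif(2, -0.5, 0.5))
    phi <- runif(2, 0.2, 2)
    ref <- 2 * (phid[1] - phid[2]) * phi[1] + 1 * (phid[2] - phid[1]) * phi[2]
    expect_equal(L$cs(phid, phi), ref, tolerance = 1e-12)
    expect_equal(L$cs(c(1, 1), phi), 0, tolerance = 1e-14)
  }

  # birth-death: L = b (1 - phid) + d (phid - 1) phi
  Lbd <- build_liouville(birth_death_spec(1.3, 0.6))
  for (rep in 1:5) {
    phid <- exp(runif(1, -1, 1))
    phi <- runif(1, 0.1, 3)
    expect_equal(Lbd$cs(phid, phi),
                 1.3 * (1 - phid) + 0.6 * (phid - 1) * phi,
                 tolerance = 1e-12)
  }

  # any spec: L(phid = 1, .) = 0, and charts agree under the log transform
  Lnl <- build_liouville(nonlinear_spec())
  for (rep in 1:5) {
    phi <- runif(1, 0.5, 10)
    expect_equal(Lnl$cs(1, phi), 0, tolerance = 1e-12)
    th <- runif(1, -0.4, 0.4)
    n <- runif(1, 1, 20)
    expect_equal(Lnl$np(th, n), Lnl$cs(exp(th), exp(-th) * n),
                 tolerance = 1e-10)
  }
})

test_that("analytic Liouville gradients match finite differences", {
  set.seed(2)
  for (L in list(build_liouville(two_state_spec(2, 1)),
                 build_liouville(nonlinear_spec()))) {
    D <- L$D
    for (rep in 1:3) {
      th <- runif(D, -0.4, 0.4)
      n <- runif(D, 2, 10)
      g <- L$grad_np(th, n)
      H <- L$hess_np(th, n)
      h <- 1e-6
      for (i in seq_len(D)) {
        e <- numeric(D); e[i] <- h
        expect_equal(g$dtheta[i],
                     (L$np(th + e, n) - L$np(th - e, n)) / (2 * h),
                     tolerance = 1e-6)
        expect_equal(g$dn[i],
                     (L$np(th, n + e) - L$np(th, n - e)) / (2 * h),
                     tolerance = 1e-6)
        # mixed second derivatives against FD of the analytic gradient
        expect_equal(H$Htn[i, ],
                     (L$grad_np(th + e, n)$dn - L$grad_np(th - e, n)$dn) /
                       (2 * h), tolerance = 1e-5, ignore_attr = TRUE)
      }
      gc <- L$grad_cs(exp(th), exp(-th) * n)
      for (i in seq_len(D)) {
        e <- numeric(D); e[i] <- h
        expect_equal(gc$dphid[i],
                     (L$cs(exp(th) + e, exp(-th) * n) -
                        L$cs(exp(th) - e, exp(-th) * n)) / (2 * h),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("the zero-tilt section is the mass-action rate equation", {
  L <- build_liouville(two_state_spec())
  p <- ref_params()
  n <- c(0.7, 0.3)
  v <- stationary_path_ode(L, list(theta = c(0, 0), n = n))
  expect_equal(v$dtheta, c(0, 0), tolerance = 1e-14)
  # dnu/dtau = nu_ss - nu for the difference coordinate nu = (n_b - n_a)/2
  nu <- (n[2] - n[1]) / 2
  expect_equal((v$dn[2] - v$dn[1]) / 2, p$nu_ss - nu, tolerance = 1e-12)
  expect_equal(sum(v$dn), 0, tolerance = 1e-14)  # total number conserved
})

test_that("the phase velocity satisfies the symplectic condition", {
  set.seed(3)
  for (L in list(build_liouville(two_state_spec(2, 1)),
                 build_liouville(nonlinear_spec()))) {
    D <- L$D
    for (rep in 1:3) {
      th <- runif(D, -0.3, 0.3)
      n <- runif(D, 2, 8)
      h <- 1e-6
      for (i in seq_len(D)) for (j in seq_len(D)) {
        ei <- numeric(D); ei[i] <- h
        ej <- numeric(D); ej[j] <- h
        dthdot_dth <- (stationary_path_ode(L, list(theta = th + ej, n = n))$dtheta[i] -
                       stationary_path_ode(L, list(theta = th - ej, n = n))$dtheta[i]) / (2 * h)
        dndot_dn <- (stationary_path_ode(L, list(theta = th, n = n + ei))$dn[j] -
                     stationary_path_ode(L, list(theta = th, n = n - ei))$dn[j]) / (2 * h)
        expect_lt(abs(dthdot_dth + dndot_dn), 1e-6)
      }
    }
  }
})

test_that("z = 1 with the steady-state CGF is a fixed point", {
  L <- build_liouville(two_state_spec())
  p <- ref_params()
  psi0 <- cgf_multinomial(1, c(p$nu_a, p$nu_b))
  traj <- solve_bvp(L, psi0, c(1, 1), 2, n_steps = 100)
  expect_lt(max(abs(traj$theta)), 1e-9)
  expect_lt(max(abs(sweep(traj$n, 2, c(p$nu_a, p$nu_b)))), 1e-9)
  expect_lt(max(abs(traj$L_values)), 1e-12)
  expect_lt(abs(traj$psi_T), 1e-9)
})

test_that("the BVP solution matches the two-state closed-form laws", {
  traj <- ref_traj()
  p <- ref_params()
  b <- ref_boundary()
  cf <- two_state_trajectories(p, b, traj$time)
  nu_bar_num <- 0.5 * (traj$phi[, 2] - traj$phi[, 1]) /
    (traj$phi[, 2] + traj$phi[, 1])
  den <- traj$phid[, 2] * p$nu_b + traj$phid[, 1] * p$nu_a
  nu_under_num <- 0.5 * (traj$phid[, 2] * p$nu_b -
                           traj$phid[, 1] * p$nu_a) / den
  expect_lt(max(abs(nu_bar_num - cf$nu_bar)), 1e-6)
  expect_lt(max(abs(nu_under_num - cf$nu_under)), 1e-6)
  # the saddle CGF equals the invariant closed form
  expect_equal(traj$psi_T, phi0_and_invariant_cgf(p, b)$psi_per_N,
               tolerance = 1e-9)
})

test_that("Liouville value is conserved along solved trajectories", {
  expect_lt(ref_traj()$diagnostics$L_drift, 1e-8)
  Lnl <- build_liouville(nonlinear_spec())
  trajnl <- solve_bvp(Lnl, cgf_poisson(3), z = 1.4, T = 1.2, n_steps = 200)
  expect_lt(trajnl$diagnostics$L_drift, 1e-8)
  # Lagrangian duality: L_lagr(ndot, n) + L(theta, n) = theta . ndot, with
  # d L_lagr / d ndot = theta, checked by perturbing the trajectory point
  i <- 101
  th <- trajnl$theta[i, ]; n <- trajnl$n[i, ]
  ndot_of <- function(th) -Lnl$grad_np(th, n)$dtheta
  theta_of_ndot <- function(target) {
    f <- function(x) ndot_of(x) - target
    x <- th
    for (k in 1:50) {
      J <- (f(x + 1e-7) - f(x - 1e-7)) / 2e-7
      x <- x - f(x) / J
      if (abs(f(x)) < 1e-12) break
    }
    x
  }
  Llag <- function(ndot) {
    x <- theta_of_ndot(ndot)
    sum(x * ndot) + Lnl$np(x, n)
  }
  nd <- ndot_of(th)
  # Lagrange-Hamilton duality: L_lagr(ndot, n) = theta . ndot + L(theta, n)
  expect_equal(Llag(nd), sum(th * nd) + Lnl$np(th, n), tolerance = 1e-8)
  h <- 1e-5
  expect_equal((Llag(nd + h) - Llag(nd - h)) / (2 * h), th,
               tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("Hamilton-Jacobi equation holds with second-order FD scaling", {
  N <- 100
  traj <- ref_traj(N)
  L <- build_liouville(two_state_spec())
  evolve_fn <- function(t) evolved_two_state(N, 0.25, t)
  hj1 <- hamilton_jacobi_residual(traj, L, evolve_fn, dt = 1e-3)
  expect_lt(hj1$max_residual, 1e-3)
  expect_lt(hj1$max_theta_mismatch, 1e-8)
  # residual is finite-difference limited: halving dt quarters it
  hj2 <- hamilton_jacobi_residual(traj, L, evolve_fn, dt = 2e-3)
  ratio <- hj2$max_residual / hj1$max_residual
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
  # a steady-state trajectory has zero residual
  p <- ref_params()
  trajss <- solve_bvp(L, cgf_multinomial(N, c(p$nu_a, p$nu_b)),
                      c(1, 1), 2, n_steps = 100)
  hjss <- hamilton_jacobi_residual(trajss, L,
                                   function(t) dist_two_state(N, p$nu_b),
                                   dt = 1e-3)
  expect_lt(hjss$max_residual, 1e-6)
})

test_that("tangent fields transport with a conserved inner product", {
  traj <- ref_traj(100)
  L <- build_liouville(two_state_spec())

  tg0 <- propagate_tangents(traj, L, dtheta_T = c(0, 0), dn_0 = c(1, -1))
  expect_lt(max(abs(tg0$dtheta)), 1e-14)
  expect_lt(max(abs(tg0$inner_product)), 1e-14)

  tg <- propagate_tangents(traj, L, dtheta_T = c(0.01, -0.01),
                           dn_0 = c(0.5, -0.5))
  expect_lt(max(abs(tg$inner_product - tg$inner_product[1])), 1e-6)
})

test_that("transported differentials agree with brute-force BVP perturbation", {
  p <- ref_params()
  b <- ref_boundary()
  L <- build_liouville(two_state_spec())
  N <- 100
  traj <- ref_traj(N)
  h <- 1e-4

  # perturb the final tilt: z -> z e^{h dtheta_T}
  dth_dir <- c(1, -1)
  zp <- ref_z() * exp(h * dth_dir)
  zm <- ref_z() * exp(-h * dth_dir)
  psi0 <- cgf_multinomial(N, c(0.5 - b$nu_bar0, 0.5 + b$nu_bar0))
  tp <- solve_bvp(L, psi0, zp, b$T, n_steps = 300)
  tm <- solve_bvp(L, psi0, zm, b$T, n_steps = 300)
  dtheta_fd <- (tp$theta - tm$theta) / (2 * h)

  # perturb the initial base mean: nu_bar0 -> nu_bar0 +- h (dn through psi0)
  psip <- cgf_multinomial(N, c(0.5 - (b$nu_bar0 + h), 0.5 + b$nu_bar0 + h))
  psim <- cgf_multinomial(N, c(0.5 - (b$nu_bar0 - h), 0.5 + b$nu_bar0 - h))
  np_ <- solve_bvp(L, psip, ref_z(), b$T, n_steps = 300)
  nm_ <- solve_bvp(L, psim, ref_z(), b$T, n_steps = 300)
  dn_fd <- (np_$n - nm_$n) / (2 * h)

  tg <- propagate_tangents(traj, L, dtheta_T = dth_dir, dn_0 = dn_fd[1, ])
  # the product of the transported differentials equals the brute-force one
  ip_fd <- rowSums(dtheta_fd * dn_fd)
  expect_lt(max(abs(tg$inner_product - ip_fd)), 1e-5 * abs(ip_fd[1]) + 1e-5)
  expect_lt(max(abs(tg$dtheta - dtheta_fd)), 1e-5)
})

test_that("phase volume is conserved: zero divergence, unit monodromy", {
  traj <- ref_traj()
  L <- build_liouville(two_state_spec())
  lv <- liouville_volume_check(traj, L, basis = matrix(c(1, -1) / sqrt(2)))
  expect_lt(lv$max_divergence, 1e-6)
  expect_equal(lv$det, 1, tolerance = 1e-5)
  # eigenvalues form a reciprocal pair (unit product)
  expect_equal(prod(Re(lv$eigenvalues)), 1, tolerance = 1e-5)

  Lnl <- build_liouville(nonlinear_spec())
  trajnl <- solve_bvp(Lnl, cgf_poisson(3), z = 1.4, T = 1.2, n_steps = 200)
  lvnl <- liouville_volume_check(trajnl, Lnl, basis = matrix(1))
  expect_lt(lvnl$max_divergence, 1e-6)
  expect_equal(lvnl$det, 1, tolerance = 1e-5)
})

test_that("the split stationary-path CGF is time-invariant", {
  Lnl <- build_liouville(nonlinear_spec())
  trajnl <- solve_bvp(Lnl, cgf_poisson(3), z = 1.4, T = 1.2, n_steps = 200)
  expect_gt(abs(trajnl$action), 1e-3)  # non-trivial action for this model
  w <- wigner_split_invariance(trajnl, Lnl)
  expect_lt(w$max_deviation, 1e-8)
  w2 <- wigner_split_invariance(ref_traj(), build_liouville(two_state_spec()))
  expect_lt(w2$max_deviation, 1e-8)
})

test_that("adjoint coordinates exchange base and tilt consistently", {
  traj <- ref_traj()
  L <- build_liouville(two_state_spec())
  ad <- adjoint_transform(traj, L)
  expect_lt(ad$diagnostics$max_identity_defect, 1e-10)  # theta + eta = log(n/n_ss)
  expect_lt(ad$diagnostics$max_Ltilde_defect, 1e-10)
  expect_lt(ad$diagnostics$max_hamilton_defect, 1e-6)
  # nu_bar from the descaled base field equals the closed-form law
  p <- ref_params()
  cf <- two_state_trajectories(p, ref_boundary(), traj$time)
  nu_bar_phi <- 0.5 * (traj$phi[, 2] - traj$phi[, 1]) /
    (traj$phi[, 2] + traj$phi[, 1])
  expect_lt(max(abs(nu_bar_phi - cf$nu_bar)), 1e-6)

  # at the steady state the adjoint fields are trivial
  psi0 <- cgf_multinomial(1, c(p$nu_a, p$nu_b))
  trajss <- solve_bvp(L, psi0, c(1, 1), 1.5, n_steps = 60)
  adss <- adjoint_transform(trajss, L)
  expect_lt(max(abs(adss$varphi - 1)), 1e-8)
  expect_lt(max(abs(adss$eta)), 1e-8)
})
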