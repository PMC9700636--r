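# Doi-Peliti large-deviation dynamics: the Liouville (Hamiltonian) function of
# a mass-action jump process, stationary-path two-point boundary-value
# problems, Liouville-theorem / Hamilton-Jacobi diagnostics, tangent-field
# transport, and adjoint (eta) coordinates.

# componentwise power products with 0^0 = 1, and their derivatives
prodpow <- function(x, e) prod(x^e)

dprodpow <- function(x, e) {
  g <- numeric(length(x))
  for (i in which(e > 0))
    g[i] <- e[i] * prod(x^(e - (seq_along(e) == i)))
  g
}

d2prodpow <- function(x, e) {
  D <- length(x)
  H <- matrix(0, D, D)
  for (i in which(e > 0)) for (j in which(e > 0)) {
    ee <- e
    ee[i] <- ee[i] - 1L
    if (ee[j] == 0) next
    f <- e[i] * ee[j]
    ee[j] <- ee[j] - 1L
    H[i, j] <- f * prod(x^ee)
  }
  H
}

#' Liouville (Hamiltonian) function of a mass-action jump process
#'
#' Builds the phase-space function
#' `L(phid, phi) = sum_r k_r (prod_i phid_i^y_ri - prod_i phid_i^ybar_ri)
#' prod_i phi_i^y_ri` representing the generator of the process acting on
#' generating functions, together with its number-potential form
#' `L(theta, n)` under `phid = exp(theta)`, `phi = exp(-theta) n`, and exact
#' first and second derivatives in both charts. Probability conservation is
#' the identity `L(phid = 1, phi) = 0`: zero tilt is a flat direction.
#'
#' @param spec a [jump_process()].
#' @return object of class `liouville`: list of closures `cs` / `grad_cs`
#'   (coherent-state value and gradients), `np` / `grad_np` / `hess_np`
#'   (number-potential value, gradients and second derivatives), plus the
#'   stoichiometric data.
#' @export
build_liouville <- function(spec) {
  k <- spec$rate
  Y <- unname(spec$reactants)
  Yb <- unname(spec$products)
  Dm <- Yb - Y                       # net stoichiometric change per reaction
  R <- length(k)
  D <- ncol(Y)

  cs <- function(phid, phi) {
    s <- 0
    for (r in seq_len(R))
      s <- s + k[r] * (prodpow(phid, Y[r, ]) - prodpow(phid, Yb[r, ])) *
        prodpow(phi, Y[r, ])
    s
  }
  grad_cs <- function(phid, phi) {
    gd <- gp <- numeric(D)
    for (r in seq_len(R)) {
      mphi <- prodpow(phi, Y[r, ])
      gd <- gd + k[r] * (dprodpow(phid, Y[r, ]) - dprodpow(phid, Yb[r, ])) *
        mphi
      gp <- gp + k[r] * (prodpow(phid, Y[r, ]) - prodpow(phid, Yb[r, ])) *
        dprodpow(phi, Y[r, ])
    }
    list(dphid = gd, dphi = gp)
  }

  # number-potential chart: L(theta, n) = sum_r k_r (1 - e^{theta.d_r}) n^y_r
  np <- function(theta, n) {
    s <- 0
    for (r in seq_len(R))
      s <- s + k[r] * (1 - exp(sum(theta * Dm[r, ]))) * prodpow(n, Y[r, ])
    s
  }
  grad_np <- function(theta, n) {
    gt <- gn <- numeric(D)
    for (r in seq_len(R)) {
      er <- exp(sum(theta * Dm[r, ]))
      m <- prodpow(n, Y[r, ])
      gt <- gt - k[r] * Dm[r, ] * er * m
      gn <- gn + k[r] * (1 - er) * dprodpow(n, Y[r, ])
    }
    list(dtheta = gt, dn = gn)
  }
  hess_np <- function(theta, n) {
    Htt <- Htn <- Hnn <- matrix(0, D, D)
    for (r in seq_len(R)) {
      er <- exp(sum(theta * Dm[r, ]))
      m <- prodpow(n, Y[r, ])
      dm <- dprodpow(n, Y[r, ])
      Htt <- Htt - k[r] * er * m * tcrossprod(Dm[r, ])
      Htn <- Htn - k[r] * er * tcrossprod(Dm[r, ], dm)
      Hnn <- Hnn + k[r] * (1 - er) * d2prodpow(n, Y[r, ])
    }
    list(Htt = Htt, Htn = Htn, Hnn = Hnn)  # Htn[i,j] = d2L/dtheta_i dn_j
  }

  structure(list(cs = cs, grad_cs = grad_cs, np = np, grad_np = grad_np,
                 hess_np = hess_np, rate = k, reactants = Y, products = Yb,
                 net = Dm, species = spec$species, D = D),
            class = "liouville")
}

#' @export
print.liouville <- function(x, ...) {
  cat("Liouville function of a", length(x$rate), "reaction,", x$D,
      "species mass-action process\n")
  invisible(x)
}

#' Hamiltonian phase velocity of the stationary-path equations
#'
#' In the number-potential chart, `dtheta/dt = dL/dn`, `dn/dt = -dL/dtheta`;
#' in the coherent-state chart, `dphid/dt = dL/dphi`, `dphi/dt = -dL/dphid`.
#' The two charts agree under `phid = exp(theta)`, `phi = exp(-theta) n`.
#' The zero-tilt section `theta = 0` reproduces the deterministic mass-action
#' rate equation.
#'
#' @param L a [build_liouville()] object.
#' @param state list with `theta`,`n` (chart "np") or `phid`,`phi` ("cs").
#' @param chart coordinate chart.
#' @return list of velocity components in the requested chart.
#' @export
stationary_path_ode <- function(L, state, chart = c("np", "cs")) {
  chart <- match.arg(chart)
  if (chart == "np") {
    g <- L$grad_np(state$theta, state$n)
    list(dtheta = g$dn, dn = -g$dtheta)
  } else {
    g <- L$grad_cs(state$phid, state$phi)
    list(dphid = g$dphi, dphi = -g$dphid)
  }
}

# ---- initial-CGF objects ----------------------------------------------------

#' Initial cumulant generating functions for boundary-value problems
#'
#' `cgf_poisson` is the CGF of a product-Poisson distribution with the given
#' means; `cgf_multinomial` that of `N` walkers multinomially distributed
#' with occupancies `nu`; `cgf_from_dist` wraps an explicit lattice
#' distribution (exact summation).
#'
#' @param means Poisson mean vector.
#' @param N walker count.
#' @param nu occupancy vector summing to 1.
#' @param rho a [lattice_dist()].
#' @return object of class `cgf_fn`: list with closures `fn(theta)` and
#'   `grad(theta)`.
#' @export
cgf_poisson <- function(means) {
  structure(list(fn = function(theta) sum(means * (exp(theta) - 1)),
                 grad = function(theta) means * exp(theta)),
            class = "cgf_fn")
}

#' @rdname cgf_poisson
#' @export
cgf_multinomial <- function(N, nu) {
  stopifnot(abs(sum(nu) - 1) < 1e-12)
  structure(list(fn = function(theta) N * log(sum(nu * exp(theta))),
                 grad = function(theta) {
                   w <- nu * exp(theta)
                   N * w / sum(w)
                 }),
            class = "cgf_fn")
}

#' @rdname cgf_poisson
#' @export
cgf_from_dist <- function(rho) {
  structure(list(fn = function(theta) cgf_and_mean(rho, theta)$psi,
                 grad = function(theta) cgf_and_mean(rho, theta)$mean),
            class = "cgf_fn")
}

# mean-field steady state: integrate dn/dt = -dL/dtheta|_{theta=0}
mean_field_steady <- function(L, n0, t_end = 200, rtol = 1e-12) {
  f <- function(t, y, p) list(-L$grad_np(numeric(L$D), y)$dtheta)
  out <- deSolve::ode(y = n0, times = c(0, t_end), func = f, parms = NULL,
                      rtol = rtol, atol = 1e-12)
  drop(out[nrow(out), -1])
}

# slowest nonzero relaxation rate of the mean-field Jacobian at n_ss
slowest_rate <- function(L, n_ss, tol = 1e-9) {
  D <- L$D
  J <- matrix(0, D, D)
  th0 <- numeric(D)
  for (j in seq_len(D)) {
    ep <- em <- n_ss
    h <- 1e-6 * max(1, abs(n_ss[j]))
    ep[j] <- ep[j] + h
    em[j] <- em[j] - h
    J[, j] <- (-L$grad_np(th0, ep)$dtheta + L$grad_np(th0, em)$dtheta) /
      (2 * h)
  }
  lam <- abs(Re(eigen(J, only.values = TRUE)$values))
  lam <- lam[lam > tol]
  if (!length(lam)) 1 else min(lam)
}

#' Solve the stationary-path boundary-value problem
#'
#' Single shooting on the unknown initial tilt `theta_0`: Hamilton's
#' equations are integrated forward from `(theta_0, n_0 = grad psi_0(theta_0))`
#' and `theta_0` is Newton-iterated until the final coherent-state field
#' matches the imposed tilt, `phid_T = z` (equivalently `theta_T = log z`),
#' to within `tol`. The action `S = int (-dtheta/dt . n + L) dt` is
#' accumulated as an auxiliary ODE state, and the final-time CGF value along
#' the saddle is `psi_T = psi_0(theta_0) - S`. The initial Newton guess is
#' `theta_0 = log(z) exp(-lambda T)` with `lambda` the slowest mean-field
#' relaxation rate at the steady state.
#'
#' @param L a [build_liouville()] object.
#' @param psi0 initial CGF, a `cgf_fn` (see [cgf_poisson()]).
#' @param z final-time generating-function argument, a positive vector of
#'   length `D`.
#' @param T time horizon (must be positive).
#' @param n_steps number of output grid intervals.
#' @param tol shooting tolerance on `max |phid_T - z|`.
#' @param max_iter Newton iteration cap (with bounded damped restarts).
#' @return object of class `phase_trajectory`: list with `time`, matrices
#'   `theta`, `n`, `phid`, `phi` (rows = time points), `L_values`,
#'   `action_cum` (cumulative action), `action`, `psi0_value`, `psi_T`, and
#'   `diagnostics` (Liouville drift, shooting residual).
#' @export
solve_bvp <- function(L, psi0, z, T, n_steps = 400, tol = 1e-8,
                      max_iter = 60) {
  stopifnot(T > 0, all(z > 0), length(z) == L$D)
  D <- L$D
  times <- seq(0, T, length.out = n_steps + 1)
  integrate_from <- function(theta0) {
    y0 <- c(theta0, psi0$grad(theta0), 0)
    f <- function(t, y, p) {
      th <- y[1:D]; n <- y[(D + 1):(2 * D)]
      g <- L$grad_np(th, n)
      dth <- g$dn; dn <- -g$dtheta
      list(c(dth, dn, -sum(dth * n) + L$np(th, n)))
    }
    deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                 method = "ode45", rtol = 1e-10, atol = 1e-10)
  }
  target <- log(z)
  resid <- function(theta0) {
    out <- integrate_from(theta0)
    out[nrow(out), 2:(D + 1)] - target
  }
  n_ss <- mean_field_steady(L, psi0$grad(numeric(D)))
  lam <- slowest_rate(L, n_ss)
  theta0 <- target * exp(-lam * T)
  r <- resid(theta0)
  it <- 0
  while (max(abs(r)) > 1e-12 && it < max_iter) {
    it <- it + 1
    J <- matrix(0, D, D)
    for (j in seq_len(D)) {
      e <- numeric(D); e[j] <- 1e-7
      J[, j] <- (resid(theta0 + e) - r) / 1e-7
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) step <- -drop(MASS_ginv(J) %*% r)
    lamd <- 1
    repeat {
      r_new <- resid(theta0 + lamd * step)
      if (all(is.finite(r_new)) &&
          (max(abs(r_new)) < max(abs(r)) || lamd < 1e-4)) break
      lamd <- lamd / 2
    }
    theta0 <- theta0 + lamd * step
    r <- r_new
  }
  if (max(abs(exp(target + r) - z)) > tol)
    stop(sprintf("shooting failed to converge: residual %.3e on phid_T",
                 max(abs(exp(target + r) - z))))
  out <- integrate_from(theta0)
  th <- out[, 2:(D + 1), drop = FALSE]
  n <- out[, (D + 2):(2 * D + 1), drop = FALSE]
  Scum <- out[, 2 * D + 2]
  phid <- exp(th)
  phi <- exp(-th) * n
  Lval <- vapply(seq_along(times), function(i) L$np(th[i, ], n[i, ]),
                 numeric(1))
  psi0v <- psi0$fn(th[1, ])
  structure(list(time = times, theta = th, n = n, phid = phid, phi = phi,
                 L_values = Lval, action_cum = Scum,
                 action = Scum[length(Scum)], psi0_value = psi0v,
                 psi_T = psi0v - Scum[length(Scum)],
                 diagnostics = list(
                   L_drift = max(abs(Lval - Lval[1])),
                   shooting_residual = max(abs(exp(target + r) - z)),
                   newton_iterations = it)),
            class = "phase_trajectory")
}

# minimal pseudo-inverse fallback for near-singular shooting Jacobians
MASS_ginv <- function(A, tol = 1e-12) {
  s <- svd(A)
  nz <- s$d > tol * max(s$d)
  s$v[, nz, drop = FALSE] %*% (t(s$u[, nz, drop = FALSE]) / s$d[nz])
}

#' @export
print.phase_trajectory <- function(x, ...) {
  cat(sprintf(
    "Stationary-path trajectory: D = %d, T = %g, %d time points\n",
    ncol(x$theta), max(x$time), length(x$time)))
  cat(sprintf("  action S = %.8g, psi_T = %.8g\n", x$action, x$psi_T))
  cat(sprintf("  Liouville drift %.3e, shooting residual %.3e\n",
              x$diagnostics$L_drift, x$diagnostics$shooting_residual))
  invisible(x)
}

#' Write a trajectory as CSV
#' @param traj a `phase_trajectory`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  D <- ncol(traj$theta)
  df <- data.frame(t = traj$time)
  for (i in seq_len(D)) df[[paste0("theta_", i)]] <- traj$theta[, i]
  for (i in seq_len(D)) df[[paste0("n_", i)]] <- traj$n[, i]
  for (i in seq_len(D)) df[[paste0("phi_dag_", i)]] <- traj$phid[, i]
  for (i in seq_len(D)) df[[paste0("phi_", i)]] <- traj$phi[, i]
  df$L_value <- traj$L_values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

traj_interp <- function(traj) {
  D <- ncol(traj$theta)
  list(theta = lapply(seq_len(D), function(i)
         stats::splinefun(traj$time, traj$theta[, i])),
       n = lapply(seq_len(D), function(i)
         stats::splinefun(traj$time, traj$n[, i])))
}

traj_point <- function(ip, t, D) {
  list(theta = vapply(seq_len(D), function(i) ip$theta[[i]](t), numeric(1)),
       n = vapply(seq_len(D), function(i) ip$n[[i]](t), numeric(1)))
}

#' Hamilton-Jacobi residual of a solved trajectory
#'
#' The large-deviation function of the evolving distribution satisfies
#' `d psi*/d n = theta` and `d psi*/d t = L(d psi*/d n, n)` along stationary
#' paths. Given a function `evolve_fn(t)` returning the evolved base
#' distribution as a [lattice_dist()], this computes, on a set of interior
#' times, the Legendre transform of the evolved CGF at the trajectory's
#' `n(t)`, a central finite-difference time derivative with step `dt`, and
#' reports the maximum absolute residual of the Hamilton-Jacobi equation
#' together with the pointwise check of `theta(n)` against the trajectory
#' tilt (compared on the non-degenerate Fisher subspace).
#'
#' @param traj a `phase_trajectory`.
#' @param L the [build_liouville()] object that generated it.
#' @param evolve_fn function of time returning a [lattice_dist()].
#' @param times interior evaluation times (default 5 interior grid points).
#' @param dt finite-difference step for the time derivative.
#' @return list with `max_residual`, `max_theta_mismatch`, and a `table` of
#'   pointwise values.
#' @export
hamilton_jacobi_residual <- function(traj, L, evolve_fn, times = NULL,
                                     dt = 1e-3) {
  D <- ncol(traj$theta)
  Tend <- max(traj$time)
  if (is.null(times))
    times <- seq(Tend / 6, Tend * 5 / 6, length.out = 5)
  ip <- traj_interp(traj)
  rows <- lapply(times, function(t) {
    pt <- traj_point(ip, t, D)
    lp <- legendre_ldf(evolve_fn(t), pt$n)
    proj <- function(v) {
      dg <- lp$degenerate
      if (ncol(dg)) v - dg %*% crossprod(dg, v) else v
    }
    th_mis <- max(abs(proj(lp$theta_of_n - pt$theta)))
    sp <- legendre_ldf(evolve_fn(t + dt), pt$n)$psi_star
    sm <- legendre_ldf(evolve_fn(t - dt), pt$n)$psi_star
    dpsidt <- (sp - sm) / (2 * dt)
    lv <- L$np(lp$theta_of_n, pt$n)
    c(t = t, dpsi_dt = dpsidt, L_value = lv, residual = abs(dpsidt - lv),
      theta_mismatch = th_mis)
  })
  tab <- do.call(rbind, rows)
  list(max_residual = max(tab[, "residual"]),
       max_theta_mismatch = max(tab[, "theta_mismatch"]),
       table = as.data.frame(tab))
}

#' Transport tangent fields along a stationary trajectory
#'
#' Integrates the linearized (variational) transport laws
#' `d/dt delta_theta_j = delta_theta_i d2L/dtheta_i dn_j` (backward from its
#' final condition) and `d/dt delta_n_i = -delta_n_j d2L/dn_j dtheta_i`
#' (forward from its initial condition), and reports the inner product
#' `delta_theta . delta_n` per time point, which is conserved along the
#' trajectory. `dn_0` is the initial displacement of the base distribution in
#' mixture coordinates (`delta n = g delta eta` for a displacement
#' `delta eta` of the base exponential parameter).
#'
#' @param traj a `phase_trajectory`.
#' @param L the generating [build_liouville()] object.
#' @param dtheta_T final-time tilt displacement (length `D`).
#' @param dn_0 initial base-distribution displacement (length `D`).
#' @return object of class `tangent_fields`: list with `time`, matrices
#'   `dtheta`, `dn`, and `inner_product` per time point.
#' @export
propagate_tangents <- function(traj, L, dtheta_T, dn_0) {
  D <- ncol(traj$theta)
  ip <- traj_interp(traj)
  M <- function(t) {
    pt <- traj_point(ip, t, D)
    L$hess_np(pt$theta, pt$n)$Htn   # [i,j] = d2L/dtheta_i dn_j
  }
  times <- traj$time
  Tend <- max(times)
  # backward sweep via s = T - t so the integrator runs forward in s
  back <- deSolve::ode(y = as.numeric(dtheta_T), times = Tend - rev(times),
                       func = function(s, y, p)
                         list(drop(-t(M(Tend - s)) %*% y)),
                       parms = NULL, method = "ode45",
                       rtol = 1e-10, atol = 1e-12)
  dtheta <- back[nrow(back):1, -1, drop = FALSE]
  fwd <- deSolve::ode(y = as.numeric(dn_0), times = times,
                      func = function(t, y, p) list(drop(-M(t) %*% y)),
                      parms = NULL, method = "ode45",
                      rtol = 1e-10, atol = 1e-12)
  dn <- fwd[, -1, drop = FALSE]
  structure(list(time = times, dtheta = dtheta, dn = dn,
                 inner_product = rowSums(dtheta * dn)),
            class = "tangent_fields")
}

#' Liouville-theorem diagnostics for a solved trajectory
#'
#' Checks (a) that the phase-space divergence of the Hamiltonian vector field
#' vanishes at sampled trajectory points (pairwise cancellation of
#' `d phid_dot/d phid` and `d phi_dot/d phi`), and (b) that the monodromy
#' matrix (linearized time-`T` map) restricted to a non-degenerate
#' perturbation subspace has determinant 1. Conserved-quantity directions
#' (zero Fisher eigenvalues) must be excluded from the basis.
#'
#' @param traj a `phase_trajectory`.
#' @param L the generating [build_liouville()] object.
#' @param basis D x k matrix whose columns span the dynamical
#'   (nonzero-Fisher-eigenvalue) directions.
#' @param n_div_points number of trajectory points at which the divergence is
#'   sampled.
#' @return list with `max_divergence`, `monodromy` (2k x 2k), `det`,
#'   `eigenvalues`.
#' @export
liouville_volume_check <- function(traj, L, basis, n_div_points = 9) {
  D <- ncol(traj$theta)
  basis <- as.matrix(basis)
  k <- ncol(basis)
  ip <- traj_interp(traj)
  Tend <- max(traj$time)
  # (a) divergence of the coherent-state Hamiltonian field, central FD
  div_at <- function(t) {
    pt <- traj_point(ip, t, D)
    phid <- exp(pt$theta)
    phi <- exp(-pt$theta) * pt$n
    h <- 1e-6
    s <- 0
    for (i in seq_len(D)) {
      ep <- em <- phid
      ep[i] <- ep[i] + h; em[i] <- em[i] - h
      s <- s + (L$grad_cs(ep, phi)$dphi[i] -
                  L$grad_cs(em, phi)$dphi[i]) / (2 * h)
      ep <- em <- phi
      ep[i] <- ep[i] + h; em[i] <- em[i] - h
      s <- s - (L$grad_cs(phid, ep)$dphid[i] -
                  L$grad_cs(phid, em)$dphid[i]) / (2 * h)
    }
    s
  }
  divs <- vapply(seq(0, Tend, length.out = n_div_points), div_at, numeric(1))
  # (b) monodromy of the full variational system, restricted to the basis
  vf <- function(t, y, p) {
    pt <- traj_point(ip, t, D)
    H <- L$hess_np(pt$theta, pt$n)
    dth <- y[1:D]; dn <- y[(D + 1):(2 * D)]
    # linearization of (theta_dot, n_dot) = (dL/dn, -dL/dtheta)
    ddth <- drop(t(H$Htn) %*% dth + H$Hnn %*% dn)
    ddn <- drop(-H$Htt %*% dth - H$Htn %*% dn)
    list(c(ddth, ddn))
  }
  cols <- vector("list", 2 * k)
  for (j in seq_len(k)) {
    cols[[j]] <- c(basis[, j], numeric(D))
    cols[[k + j]] <- c(numeric(D), basis[, j])
  }
  Mono <- matrix(0, 2 * k, 2 * k)
  Bproj <- rbind(cbind(basis, matrix(0, D, k)),
                 cbind(matrix(0, D, k), basis))
  for (j in seq_len(2 * k)) {
    out <- deSolve::ode(y = cols[[j]], times = c(0, Tend), func = vf,
                        parms = NULL, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    yT <- out[nrow(out), -1]
    Mono[, j] <- drop(crossprod(Bproj, yT) /
                        colSums(Bproj^2))
  }
  structure(list(max_divergence = max(abs(divs)), monodromy = Mono,
                 det = det(Mono), eigenvalues = eigen(Mono)$values),
            class = "liouville_volume_check")
}

#' Time-invariance of the split stationary-path CGF
#'
#' Along a stationary path the phase-space density (Wigner function) at the
#' saddle equals `exp(psi_T)` no matter where the trajectory is split:
#' `psi_0(theta_0) - S(0,t) - S(t,T) = psi_T` for every interior `t`, where
#' the head action comes from the stored trajectory and the tail action is
#' recomputed by independently re-integrating Hamilton's equations from the
#' split point. The spread of the split values over `t` is the reported
#' invariance defect.
#'
#' @param traj a `phase_trajectory`.
#' @param L the generating [build_liouville()] object.
#' @param times interior split times (default 5 interior grid points).
#' @return list with `values` (split CGF per time) and `max_deviation`.
#' @export
wigner_split_invariance <- function(traj, L, times = NULL) {
  D <- ncol(traj$theta)
  Tend <- max(traj$time)
  if (is.null(times))
    times <- seq(Tend / 6, Tend * 5 / 6, length.out = 5)
  Scum <- stats::splinefun(traj$time, traj$action_cum)
  ip <- traj_interp(traj)
  vals <- vapply(times, function(t) {
    pt <- traj_point(ip, t, D)
    f <- function(tt, y, p) {
      th <- y[1:D]; n <- y[(D + 1):(2 * D)]
      g <- L$grad_np(th, n)
      list(c(g$dn, -g$dtheta, -sum(g$dn * n) + L$np(th, n)))
    }
    out <- deSolve::ode(y = c(pt$theta, pt$n, 0), times = c(t, Tend),
                        func = f, parms = NULL, method = "ode45",
                        rtol = 1e-10, atol = 1e-12)
    S_tail <- out[nrow(out), 2 * D + 2]
    traj$psi0_value - Scum(t) - S_tail
  }, numeric(1))
  list(values = vals, max_deviation = max(abs(vals - traj$psi_T)))
}

#' Adjoint (descaled) coordinates along a trajectory
#'
#' Rescales the coherent-state fields by the mean-field steady state `n_ss`
#' (`varphid = phid * n_ss`, `varphi = phi / n_ss`) and introduces the
#' adjoint exponential coordinate `eta = log(varphi)`, exchanging the roles
#' of coordinate and response fields. For time-independent generators the
#' modified Liouville function equals the original pointwise
#' (`Ltilde(n, eta) = L(theta, n)`), and `theta + eta = log(n / n_ss)`
#' componentwise. The returned diagnostics verify the identity chain and
#' that the eta-chart Hamiltonian equations `eta_dot = -dLtilde/dn`,
#' `n_dot = dLtilde/deta` reproduce the transformed trajectory velocities.
#'
#' @param traj a `phase_trajectory`.
#' @param L the generating [build_liouville()] object (time-independent; the
#'   interface accepts constant rate coefficients only).
#' @param n_ss optional steady-state mean; computed from the mean-field flow
#'   started at the trajectory's initial `n` if omitted.
#' @return object of class `adjoint_coords`: list with `time`, matrices
#'   `varphid`, `varphi`, `eta`, `n_ss`, and `diagnostics`
#'   (`max_identity_defect` for `theta + eta - log(n/n_ss)`,
#'   `max_Ltilde_defect`, `max_hamilton_defect`).
#' @export
adjoint_transform <- function(traj, L, n_ss = NULL) {
  D <- ncol(traj$theta)
  if (is.null(n_ss)) n_ss <- mean_field_steady(L, traj$n[1, ])
  varphid <- sweep(traj$phid, 2, n_ss, `*`)
  varphi <- sweep(traj$phi, 2, n_ss, `/`)
  eta <- log(varphi)
  ident <- traj$theta + eta - log(sweep(traj$n, 2, n_ss, `/`))
  Ltilde <- function(n, et) L$np(log(n / n_ss) - et, n)
  lt_defect <- max(abs(vapply(seq_along(traj$time), function(i)
    Ltilde(traj$n[i, ], eta[i, ]) - traj$L_values[i], numeric(1))))
  # eta-chart Hamilton equations vs chain-rule velocities, by central FD
  ham_defect <- 0
  h <- 1e-5
  idx <- unique(round(seq(1, length(traj$time), length.out = 9)))
  for (i in idx) {
    n <- traj$n[i, ]; et <- eta[i, ]; th <- traj$theta[i, ]
    g <- L$grad_np(th, n)
    ndot <- -g$dtheta
    etadot <- ndot / n - g$dn            # chain rule through eta = log(n/n_ss) - theta
    for (j in seq_len(D)) {
      ep <- em <- et
      ep[j] <- ep[j] + h; em[j] <- em[j] - h
      dLt_deta <- (Ltilde(n, ep) - Ltilde(n, em)) / (2 * h)
      ham_defect <- max(ham_defect, abs(ndot[j] - dLt_deta))
      np_ <- nm_ <- n
      np_[j] <- np_[j] + h; nm_[j] <- nm_[j] - h
      dLt_dn <- (Ltilde(np_, et) - Ltilde(nm_, et)) / (2 * h)
      ham_defect <- max(ham_defect, abs(etadot[j] + dLt_dn))
    }
  }
  structure(list(time = traj$time, varphid = varphid, varphi = varphi,
                 eta = eta, n_ss = n_ss,
                 diagnostics = list(max_identity_defect = max(abs(ident)),
                                    max_Ltilde_defect = lt_defect,
                                    max_hamilton_defect = ham_defect)),
            class = "adjoint_coords")
}
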