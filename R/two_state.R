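# Closed forms for the two-state linear hopping system a <-> b with N
# independent walkers: overlap parameter, conserved density, exponential
# trajectory laws, Fisher eigenvalue in two forms, the conserved phase-space
# volume integral, the coherent-state Hessian defect, and the flat
# coherent-state connection. Everything is expressed in descaled time tau
# (d tau / dt = k_plus + k_minus); conversion to physical time happens only
# at the I/O boundary.

#' Parameters of the two-state linear system
#'
#' `N` independent walkers hop between states `a` and `b` with rates
#' `k_plus` (a to b) and `k_minus` (b to a). Derived quantities: occupancies
#' `nu_b = k_plus / (k_plus + k_minus)`, `nu_a = 1 - nu_b`, the steady-state
#' offset coordinate `nu_ss = (nu_b - nu_a) / 2` in `(-1/2, 1/2)`, the
#' descaled-time rate `dtau/dt = k_plus + k_minus`, and the steady-state tilt
#' references `theta_ss = log(nu_b/nu_a)` and
#' `h_ss = log(1/4 - nu_ss^2) / 2`.
#'
#' @param k_plus,k_minus positive hopping rates.
#' @param N walker count.
#' @return object of class `two_state_params`.
#' @export
two_state_params <- function(k_plus, k_minus, N = 1L) {
  stopifnot(k_plus > 0, k_minus > 0, N >= 1)
  nu_b <- k_plus / (k_plus + k_minus)
  nu_a <- 1 - nu_b
  nu_ss <- (nu_b - nu_a) / 2
  structure(list(k_plus = k_plus, k_minus = k_minus, N = as.integer(N),
                 nu_b = nu_b, nu_a = nu_a, nu_ss = nu_ss,
                 tau_rate = k_plus + k_minus,
                 theta_ss = log(nu_b / nu_a),
                 h_ss = 0.5 * log(0.25 - nu_ss^2)),
            class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf(
    "Two-state system: k+ = %g, k- = %g, N = %d (nu_ss = %.6g, dtau/dt = %g)\n",
    x$k_plus, x$k_minus, x$N, x$nu_ss, x$tau_rate))
  invisible(x)
}

#' Boundary data for the two-state stationary path
#'
#' @param nu_bar0 initial base-distribution mean offset, in `(-1/2, 1/2)`.
#' @param nu_underT final tilt offset, in `(-1/2, 1/2)`.
#' @param T horizon in descaled time tau.
#' @return object of class `two_state_boundary`.
#' @export
two_state_boundary <- function(nu_bar0, nu_underT, T) {
  stopifnot(abs(nu_bar0) < 0.5, abs(nu_underT) < 0.5, T > 0)
  structure(list(nu_bar0 = nu_bar0, nu_underT = nu_underT, T = T),
            class = "two_state_boundary")
}

#' Overlap parameter between initial and final data
#'
#' `Lambda = (nu_bar0 - nu_ss)(nu_underT - nu_ss) / (1/4 - nu_ss^2)`, the
#' single combination of boundary data on which the conserved density
#' depends. Symmetric under swapping the two boundary offsets.
#'
#' @param params a [two_state_params()].
#' @param boundary a [two_state_boundary()].
#' @export
overlap_lambda <- function(params, boundary) {
  v <- params$nu_ss
  (boundary$nu_bar0 - v) * (boundary$nu_underT - v) / (0.25 - v^2)
}

#' Conserved density and invariant CGF per walker
#'
#' `PhiHat0 = 1 / (1 + Lambda exp(-T))` and `psi/N = -log(PhiHat0)`. The
#' bracket form `psi/N = log[(nu_under_a/nu_ss_a) nu_bar_a +
#' (nu_under_b/nu_ss_b) nu_bar_b]`, evaluated from the propagated
#' trajectories at any tau, is asserted equal within `1e-12`.
#'
#' @inheritParams overlap_lambda
#' @return list with `Lambda`, `PhiHat0`, `psi_per_N`, and
#'   `bracket_deviation` (max deviation of the bracket form over tau).
#' @export
phi0_and_invariant_cgf <- function(params, boundary) {
  Lam <- overlap_lambda(params, boundary)
  denom <- 1 + Lam * exp(-boundary$T)
  if (denom <= 0)
    stop("1 + Lambda exp(-T) <= 0: boundary data outside the admissible domain")
  phi0 <- 1 / denom
  psiN <- -log(phi0)
  taus <- seq(0, boundary$T, length.out = 9)
  tr <- two_state_trajectories(params, boundary, taus)
  bracket <- log((0.5 - tr$nu_under) / params$nu_a * (0.5 - tr$nu_bar) +
                 (0.5 + tr$nu_under) / params$nu_b * (0.5 + tr$nu_bar))
  dev <- max(abs(bracket - psiN))
  if (dev > 1e-12)
    warning(sprintf("bracket form of psi/N deviates by %.2e", dev))
  list(Lambda = Lam, PhiHat0 = phi0, psi_per_N = psiN,
       bracket_deviation = dev)
}

#' Closed-form stationary-path trajectories of the two-state system
#'
#' The base-mean offset relaxes forward, `nu_bar(tau) - nu_ss =
#' (nu_bar0 - nu_ss) exp(-tau)`, and the tilt offset grows toward its final
#' condition, `nu_under(tau) - nu_ss = (nu_underT - nu_ss) exp(tau - T)`.
#' The importance-distribution mean `nu(tau)` follows from the additive
#' exponential-family form `nu = tanh((theta + eta + theta_ss)/2) / 2`, with
#' `theta(tau)` and `eta(tau)` recovered by inverting
#' `nu_under = tanh((theta + theta_ss)/2)/2` and
#' `nu_bar = tanh((eta + theta_ss)/2)/2`.
#'
#' @inheritParams overlap_lambda
#' @param tau_grid times in `[0, T]` (descaled).
#' @return data.frame with columns `tau`, `nu_bar`, `nu_under`, `nu`,
#'   `theta`, `eta`, `u`, `v`.
#' @export
two_state_trajectories <- function(params, boundary, tau_grid) {
  # the exponential laws extend smoothly outside [0, T]; slight excursions
  # (e.g. finite-difference stencils at the endpoints) are permitted
  v <- params$nu_ss
  s <- sqrt(0.25 - v^2)
  nu_bar <- v + (boundary$nu_bar0 - v) * exp(-tau_grid)
  nu_under <- v + (boundary$nu_underT - v) * exp(tau_grid - boundary$T)
  theta <- 2 * atanh(2 * nu_under) - params$theta_ss
  eta <- 2 * atanh(2 * nu_bar) - params$theta_ss
  nu <- 0.5 * tanh((theta + eta + params$theta_ss) / 2)
  data.frame(tau = tau_grid, nu_bar = nu_bar, nu_under = nu_under, nu = nu,
             theta = theta, eta = eta,
             u = (nu_bar - v) / s, v = (nu_under - v) / s)
}

#' Fisher-metric eigenvalue of the two-state system, in both closed forms
#'
#' The nonzero eigenvalue of `g/N` is computed both as
#' `(1/4 - nu_under^2)(1/4 - nu_bar^2)/(1/4 - nu_ss^2) * PhiHat0^2` (with
#' `PhiHat0 = 1/(1 + u v)` evaluated pointwise from the descaled coordinates)
#' and as `1/4 - nu^2` in the additive exponential-family coordinates; the
#' two are asserted equal within `1e-10`. The full 2 x 2 metric
#' `g/N = eigenvalue * (1,-1)(1,-1)^T / 2`-type rank-1 form carries its zero
#' eigenvalue in the conserved `(1,1)` direction.
#'
#' @param params a [two_state_params()].
#' @param nu_under,nu_bar tilt and base offsets at the evaluation point.
#' @return list with `eigenvalue`, `form_uv` (product form), `form_additive`
#'   (`1/4 - nu^2`), `PhiHat0_point`, `metric` (2 x 2 matrix `g/N` in the
#'   `(a, b)` basis), `zero_direction`.
#' @export
two_state_fisher_eigenvalue <- function(params, nu_under, nu_bar) {
  vss <- params$nu_ss
  s2 <- 0.25 - vss^2
  u <- (nu_bar - vss) / sqrt(s2)
  v <- (nu_under - vss) / sqrt(s2)
  phi0 <- 1 / (1 + u * v)
  form_uv <- (0.25 - nu_under^2) * (0.25 - nu_bar^2) / s2 * phi0^2
  theta <- 2 * atanh(2 * nu_under) - params$theta_ss
  eta <- 2 * atanh(2 * nu_bar) - params$theta_ss
  nu <- 0.5 * tanh((theta + eta + params$theta_ss) / 2)
  form_additive <- 0.25 - nu^2
  if (abs(form_uv - form_additive) > 1e-10)
    warning(sprintf("Fisher eigenvalue forms disagree by %.2e",
                    abs(form_uv - form_additive)))
  list(eigenvalue = form_uv, form_uv = form_uv,
       form_additive = form_additive, nu = nu, PhiHat0_point = phi0,
       metric = form_uv * tcrossprod(c(1, -1)) / 2,
       zero_direction = c(1, 1) / sqrt(2))
}

#' Conserved phase-space volume integral of a boundary rectangle
#'
#' Maps a rectangle of boundary data `(nu_underT, nu_bar0)` through the
#' stationary-path laws to each time in `tau_grid`, and evaluates
#' `int dv du PhiHat0^2` over the image in the fully descaled coordinates
#' `u, v` by tensor-product Gauss-Legendre quadrature. Liouville's theorem
#' makes the integral tau-independent; the maximum deviation across the grid
#' is reported.
#'
#' @param params a [two_state_params()].
#' @param nu_underT_range,nu_bar0_range numeric length-2 intervals of
#'   boundary data.
#' @param T horizon (descaled time).
#' @param tau_grid evaluation times in `[0, T]`.
#' @param n_quad quadrature order per axis.
#' @return list with `tau`, `integral` (per tau), `max_deviation`.
#' @export
two_state_volume <- function(params, nu_underT_range, nu_bar0_range, T,
                             tau_grid = seq(0, T, length.out = 5),
                             n_quad = 48) {
  vss <- params$nu_ss
  s <- sqrt(0.25 - vss^2)
  gq <- gauss_legendre(n_quad)
  # boundary-data nodes (tensor product), mapped through the trajectory laws
  vT <- (nu_underT_range - vss) / s   # descaled final tilt interval
  u0 <- (nu_bar0_range - vss) / s     # descaled initial base interval
  nodes_v <- (vT[2] - vT[1]) / 2 * gq$x + mean(vT)
  w_v <- (vT[2] - vT[1]) / 2 * gq$w
  nodes_u <- (u0[2] - u0[1]) / 2 * gq$x + mean(u0)
  w_u <- (u0[2] - u0[1]) / 2 * gq$w
  integral <- vapply(tau_grid, function(tau) {
    v_tau <- nodes_v * exp(tau - T)    # v(tau) = v_T e^{tau-T}
    u_tau <- nodes_u * exp(-tau)       # u(tau) = u_0 e^{-tau}
    wv <- w_v * exp(tau - T)
    wu <- w_u * exp(-tau)
    dens <- outer(v_tau, u_tau, function(vv, uu) (1 + uu * vv)^(-2))
    drop(wv %*% dens %*% wu)
  }, numeric(1))
  list(tau = tau_grid, integral = integral,
       max_deviation = max(integral) - min(integral))
}

gauss_legendre <- function(n) {
  # Golub-Welsch: nodes/weights on [-1, 1]
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

#' Coherent-state Hessian defect of the two-state system
#'
#' The Hessian of the CGF in coherent-state (z-affine) coordinates fails to
#' define a dual metric: along the z-affine contour it evaluates to
#' `-(nu - nu_under)^2` per unit `(delta theta)^2`, negative-semidefinite and
#' degenerate whenever `nu = nu_under` (which holds for all tilts when the
#' base starts at the steady state). The decomposition into intrinsic Fisher
#' term, extrinsic-curvature term `(1/4 + nu_under^2)`, and advection
#' `2 nu_under nu` is assembled independently and asserted to reproduce the
#' defect within `1e-10`.
#'
#' @inheritParams two_state_fisher_eigenvalue
#' @return list with `defect`, `fisher_term`, `extrinsic_term`,
#'   `advection_term`, `decomposition_residual`.
#' @export
coherent_hessian_defect <- function(params, nu_under, nu_bar) {
  fe <- two_state_fisher_eigenvalue(params, nu_under, nu_bar)
  defect <- -(fe$nu - nu_under)^2
  fisher_term <- fe$eigenvalue
  extrinsic_term <- 0.25 + nu_under^2
  advection_term <- 2 * nu_under * fe$nu
  assembled <- fisher_term + advection_term - extrinsic_term
  res <- abs(assembled - defect)
  if (res > 1e-10)
    warning(sprintf("Hessian-defect decomposition residual %.2e", res))
  list(defect = defect, fisher_term = fisher_term,
       extrinsic_term = extrinsic_term, advection_term = advection_term,
       decomposition_residual = res)
}

#' Covariant derivatives in the flat coherent-state connection
#'
#' The connection that is affine-flat in the coherent-state fields has, for
#' the two-state system's dynamical coordinate, coefficients
#' `Gamma_theta = -2 nu_under` and `Gamma_eta = -2 nu_bar` (obtained from the
#' coordinate-transform formula between exponential and z-affine
#' coordinates). With them, the covariant part of the transported tilt field
#' satisfies `(d/dtau) delta_theta + theta_dot Gamma_theta delta_theta =
#' +delta_theta`, and the base field the mirror law with eigenvalue `-1`.
#' Grouping the metric transport with these laws, the two bracket factors are
#' `(+1 + v_dot d/dv log PhiHat0^2)` and `(-1 + u_dot d/du log PhiHat0^2)`;
#' their sum must vanish, expressing conservation of the Fisher inner
#' product.
#'
#' @inheritParams overlap_lambda
#' @param tau evaluation time in `[0, T]`.
#' @return list with `Gamma_theta`, `Gamma_eta`, `bracket_theta`,
#'   `bracket_eta`, `bracket_sum`, `susceptibility_theta`,
#'   `susceptibility_eta`, `transport_eigenvalues`, and
#'   `transport_residuals` (defect of the covariant transport laws for
#'   `delta theta` and `delta eta`, checked by finite differences of the
#'   closed-form trajectories).
#' @export
two_state_covariant_derivatives <- function(params, boundary, tau) {
  tr <- two_state_trajectories(params, boundary, tau)
  u <- tr$u
  v <- tr$v
  udot <- -u
  vdot <- v
  dlog_dv <- -2 * u / (1 + u * v)   # d/dv log PhiHat0^2
  dlog_du <- -2 * v / (1 + u * v)
  sus_theta <- vdot * dlog_dv
  sus_eta <- udot * dlog_du
  bracket_theta <- 1 + sus_theta
  bracket_eta <- -1 + sus_eta
  # covariant transport check by finite differences of the closed forms
  h <- 1e-6
  dth_of <- function(tt) {
    trh <- two_state_trajectories(params, boundary, tt)
    # delta theta from a unit displacement of nu_underT
    exp(tt - boundary$T) / (0.25 - trh$nu_under^2)
  }
  deta_of <- function(tt) {
    trh <- two_state_trajectories(params, boundary, tt)
    exp(-tt) / (0.25 - trh$nu_bar^2)
  }
  ddth <- (dth_of(tau + h) - dth_of(tau - h)) / (2 * h)
  ddeta <- (deta_of(tau + h) - deta_of(tau - h)) / (2 * h)
  thetadot <- (tr$nu_under - params$nu_ss) / (0.25 - tr$nu_under^2)
  etadot <- -(tr$nu_bar - params$nu_ss) / (0.25 - tr$nu_bar^2)
  Gamma_theta <- -2 * tr$nu_under
  Gamma_eta <- -2 * tr$nu_bar
  res_theta <- abs(ddth + thetadot * Gamma_theta * dth_of(tau) - dth_of(tau))
  res_eta <- abs(ddeta + etadot * Gamma_eta * deta_of(tau) + deta_of(tau))
  list(Gamma_theta = Gamma_theta, Gamma_eta = Gamma_eta,
       bracket_theta = bracket_theta, bracket_eta = bracket_eta,
       bracket_sum = bracket_theta + bracket_eta,
       susceptibility_theta = sus_theta, susceptibility_eta = sus_eta,
       transport_eigenvalues = c(theta = 1, eta = -1),
       transport_residuals = c(theta = res_theta, eta = res_eta))
}

#' Monodromy of the two-state stationary-path flow in descaled coordinates
#'
#' The linearized time-`T` map of the boundary data in the fully descaled
#' coordinates `(v, u)` (tilt and base displacements), computed by central
#' finite differences of the closed-form trajectory laws. The tilt direction
#' grows as `e^{T}` and the base direction contracts as `e^{-T}`; the
#' determinant is 1, Liouville's theorem in the coordinates where the
#' dynamical eigenvalues are pure exponentials.
#'
#' @inheritParams overlap_lambda
#' @param step finite-difference step on the boundary data.
#' @return list with `monodromy` (2 x 2, rows/cols ordered `(v, u)`),
#'   `eigenvalues`, `det`.
#' @export
two_state_monodromy <- function(params, boundary, step = 1e-6) {
  ends <- function(nuT, nu0) {
    bb <- two_state_boundary(nu0, nuT, boundary$T)
    tr <- two_state_trajectories(params, bb, c(0, boundary$T))
    # (v, u) at tau = 0 and tau = T
    list(start = c(tr$v[1], tr$u[1]), end = c(tr$v[2], tr$u[2]))
  }
  base <- ends(boundary$nu_underT, boundary$nu_bar0)
  cols <- matrix(0, 2, 2)
  ins <- matrix(0, 2, 2)
  pert <- list(c(step, 0), c(0, step))
  for (j in 1:2) {
    pl <- ends(boundary$nu_underT + pert[[j]][1],
               boundary$nu_bar0 + pert[[j]][2])
    mi <- ends(boundary$nu_underT - pert[[j]][1],
               boundary$nu_bar0 - pert[[j]][2])
    cols[, j] <- (pl$end - mi$end) / (2 * step)
    ins[, j] <- (pl$start - mi$start) / (2 * step)
  }
  M <- cols %*% solve(ins)
  list(monodromy = M, eigenvalues = eigen(M)$values, det = det(M))
}

#' Squared conserved density over the physical coordinate square
#'
#' Evaluates `PhiHat0^2 = (1 + Lambda exp(-T))^{-2}` on a grid of boundary
#' data `(nu_underT, nu_bar0)` over the full physical square
#' `[-1/2, 1/2]^2` (the maximal range of the nu-type coordinates), the
#' grayscale density of the base plane of the conserved-volume construction.
#'
#' @param params a [two_state_params()].
#' @param T horizon (descaled time).
#' @param n_grid grid points per axis.
#' @return list with `nu_underT`, `nu_bar0` (grid axes), `density` (matrix),
#'   `min`, `max`.
#' @export
two_state_density_extrema <- function(params, T, n_grid = 401) {
  ax <- seq(-0.5, 0.5, length.out = n_grid)
  vss <- params$nu_ss
  dens <- outer(ax, ax, function(nuT, nu0)
    (1 + (nu0 - vss) * (nuT - vss) / (0.25 - vss^2) * exp(-T))^(-2))
  list(nu_underT = ax, nu_bar0 = ax, density = dens,
       min = min(dens), max = max(dens))
}
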