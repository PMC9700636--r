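# Exponential families over a lattice base distribution: CGF, tilting,
# Legendre-dual large-deviation function, Fisher metric, cubic tensor,
# Bregman divergence. All moments are exact sums over the truncated lattice;
# finite differences appear only in cross-checks.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

tilted_logweights <- function(rho, theta) {
  drop(rho$states %*% theta) + log(rho$probs)
}

#' Cumulant generating function, tilted mean and Fisher metric
#'
#' For a base distribution `rho` on the lattice and tilt coordinate `theta`
#' (with `z_i = exp(theta_i)`), computes the CGF
#' `psi(theta) = log sum_n rho_n exp(theta . n)`, the mean of `n` under the
#' tilted distribution, and the Fisher metric `g` as the tilted covariance
#' (equal to the Hessian of `psi`). All quantities are exact lattice sums.
#'
#' @param rho a [lattice_dist()].
#' @param theta numeric tilt vector of length `D`.
#' @return object of class `tilted_point`: list with `theta`, `psi`, `mean`,
#'   `fisher`.
#' @export
cgf_and_mean <- function(rho, theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == ncol(rho$states), all(is.finite(theta)))
  lw <- tilted_logweights(rho, theta)
  keep <- is.finite(lw)
  psi <- logsumexp(lw[keep])
  tp <- numeric(length(lw))
  tp[keep] <- exp(lw[keep] - psi)
  m <- drop(crossprod(rho$states, tp))
  Sc <- sweep(rho$states, 2, m)
  g <- crossprod(Sc, Sc * tp)
  structure(list(theta = theta, psi = psi, mean = m, fisher = g),
            class = "tilted_point")
}

#' @export
print.tilted_point <- function(x, ...) {
  cat("Tilted point on exponential family\n")
  cat("  theta:", paste(signif(x$theta, 6), collapse = ", "), "\n")
  cat("  psi:  ", signif(x$psi, 8), "\n")
  cat("  mean: ", paste(signif(x$mean, 6), collapse = ", "), "\n")
  cat("  Fisher eigenvalues:",
      paste(signif(eigen(x$fisher, symmetric = TRUE,
                         only.values = TRUE)$values, 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Exponentially tilt a lattice distribution
#'
#' Returns the importance distribution
#' `rho~_n = rho_n exp(theta . n - psi(theta))`.
#'
#' @inheritParams cgf_and_mean
#' @return a [lattice_dist()].
#' @export
tilt <- function(rho, theta) {
  lw <- tilted_logweights(rho, as.numeric(theta))
  psi <- logsumexp(lw[is.finite(lw)])
  p <- ifelse(is.finite(lw), exp(lw - psi), 0)
  lattice_dist(rho$states, p, species = rho$species,
               lost_mass = attr(rho, "lost_mass"))
}

# Moore-Penrose pseudo-inverse with reported degenerate subspace.
fisher_pinv <- function(g, eig_tol = 1e-10) {
  e <- eigen(g, symmetric = TRUE)
  scale <- max(abs(e$values), 1)
  nz <- e$values > eig_tol * scale
  ginv <- e$vectors[, nz, drop = FALSE] %*%
    (t(e$vectors[, nz, drop = FALSE]) / e$values[nz])
  list(pinv = ginv, values = e$values, vectors = e$vectors, nonzero = nz)
}

#' Legendre transform to the large-deviation function
#'
#' Solves the concave maximization `psi*(n) = max_theta [theta . n -
#' psi(theta)]` by damped Newton iteration (gradient tolerance `grad_tol`),
#' using the Fisher pseudo-inverse so that flat (conserved-quantity)
#' directions of the CGF are handled. `psi*` is the large-deviation function;
#' its gradient is the inverse coordinate map `theta(n)` and its Hessian the
#' inverse Fisher metric.
#'
#' @param rho a [lattice_dist()].
#' @param n target mean vector, strictly inside the reachable mean range of
#'   `rho` (componentwise between the min and max supported lattice values;
#'   conserved directions must match exactly).
#' @param grad_tol convergence tolerance on the projected gradient.
#' @param eig_tol relative eigenvalue threshold declaring a Fisher direction
#'   degenerate.
#' @param max_iter Newton iteration cap.
#' @return object of class `legendre_pair`: list with `n`, `psi_star`,
#'   `theta_of_n`, `inverse_metric`, `fisher`, `degenerate` (basis of the
#'   zero-eigenvalue subspace, possibly 0 columns).
#' @export
legendre_ldf <- function(rho, n, grad_tol = 1e-9, eig_tol = 1e-10,
                         max_iter = 200) {
  n <- as.numeric(n)
  D <- ncol(rho$states)
  stopifnot(length(n) == D)
  supp <- rho$probs > 0
  lo <- apply(rho$states[supp, , drop = FALSE], 2, min)
  hi <- apply(rho$states[supp, , drop = FALSE], 2, max)
  free <- hi > lo
  if (any(n[free] <= lo[free]) || any(n[free] >= hi[free]) ||
      any(abs(n[!free] - lo[!free]) > 1e-9))
    stop("unreachable mean: n must lie strictly inside the support range")
  theta <- numeric(D)
  obj <- function(th) sum(th * n) - cgf_and_mean(rho, th)$psi
  f <- obj(theta)
  for (it in seq_len(max_iter)) {
    tp <- cgf_and_mean(rho, theta)
    grad <- n - tp$mean
    fp <- fisher_pinv(tp$fisher, eig_tol)
    pgrad <- drop(fp$vectors[, fp$nonzero, drop = FALSE] %*%
                    crossprod(fp$vectors[, fp$nonzero, drop = FALSE], grad))
    if (max(abs(pgrad)) < grad_tol) break
    step <- drop(fp$pinv %*% grad)
    lam <- 1
    repeat {  # damping: backtrack until the concave objective improves
      f_new <- obj(theta + lam * step)
      if (is.finite(f_new) && f_new >= f - 1e-15) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    theta <- theta + lam * step
    f <- obj(theta)
  }
  tp <- cgf_and_mean(rho, theta)
  fp <- fisher_pinv(tp$fisher, eig_tol)
  if (max(abs(n - tp$mean)) > 1e-6 * max(1, max(abs(n))))
    stop("unreachable mean: target lies off the conserved sector of rho")
  structure(list(n = n, psi_star = sum(theta * n) - tp$psi,
                 theta_of_n = theta, inverse_metric = fp$pinv,
                 fisher = tp$fisher,
                 degenerate = fp$vectors[, !fp$nonzero, drop = FALSE]),
            class = "legendre_pair")
}

#' @export
print.legendre_pair <- function(x, ...) {
  cat("Legendre pair (large-deviation function)\n")
  cat("  n:       ", paste(signif(x$n, 6), collapse = ", "), "\n")
  cat("  psi*(n): ", signif(x$psi_star, 8), "\n")
  cat("  theta(n):", paste(signif(x$theta_of_n, 6), collapse = ", "), "\n")
  if (ncol(x$degenerate))
    cat("  degenerate Fisher directions:", ncol(x$degenerate), "\n")
  invisible(x)
}

#' Amari-Chentsov cubic tensor
#'
#' The totally symmetric third derivative of the CGF,
#' `T_kij = d^3 psi / d theta_k d theta_i d theta_j`, computed as the exact
#' third central moment of the tilted distribution. In exponential
#' coordinates the dually-flat connection pair is `Gamma = 0` and
#' `Gamma* = T`.
#'
#' @inheritParams cgf_and_mean
#' @return object of class `connection_data`: list with `cubic_tensor`
#'   (D x D x D array), `gamma_flat` (zero array), `gamma_dual` (equal to the
#'   cubic tensor).
#' @export
cubic_tensor <- function(rho, theta) {
  tp <- cgf_and_mean(rho, theta)
  td <- tilt(rho, theta)
  D <- ncol(rho$states)
  Sc <- sweep(td$states, 2, tp$mean)
  Tarr <- array(0, dim = c(D, D, D))
  for (k in seq_len(D)) {
    wk <- td$probs * Sc[, k]
    Tarr[k, , ] <- crossprod(Sc, Sc * wk)
  }
  structure(list(cubic_tensor = Tarr,
                 gamma_flat = array(0, dim = c(D, D, D)),
                 gamma_dual = Tarr),
            class = "connection_data")
}

#' Bregman divergence of the CGF between two tilts
#'
#' `D_psi(theta : eta) = psi(theta) + psi*(n(eta)) - n(eta) . theta`, the
#' Bregman divergence of the CGF, which equals the Kullback-Leibler divergence
#' `KL(rho_eta || rho_theta)` of the eta-tilt from the theta-tilt. The direct
#' lattice KL sum is returned in the `kl` attribute as a cross-check.
#'
#' @param rho base [lattice_dist()].
#' @param theta,eta tilt vectors.
#' @return the divergence (numeric), with attribute `kl`.
#' @export
psi_divergence <- function(rho, theta, eta) {
  a <- cgf_and_mean(rho, theta)
  b <- cgf_and_mean(rho, eta)
  div <- a$psi - b$psi - sum((theta - eta) * b$mean)
  pt <- tilt(rho, theta)$probs
  pe <- tilt(rho, eta)$probs
  pos <- pe > 0
  kl <- sum(pe[pos] * (log(pe[pos]) - log(pt[pos])))
  attr(div, "kl") <- kl
  div
}

#' Sensitivity of the tilted mean to the base-distribution parameter
#'
#' For a differentiable family of base distributions `rho(n0)` (Poisson or
#' binomial families), computes the mixed inner product
#' `< d/d theta_i , d/d n0_j > = d n_i(theta, n0) / d n0_j` by central finite
#' differences. At `theta = 0` this is the identity for a mean-parametrized
#' family.
#'
#' @param family function mapping a mean vector `n0` to a [lattice_dist()].
#' @param n0 base mean vector.
#' @param theta tilt at which the sensitivity is evaluated.
#' @param step finite-difference step.
#' @return D x D matrix with entries `d n_i / d n0_j`.
#' @export
pythagorean_sensitivity <- function(family, n0, theta, step = 1e-4) {
  n0 <- as.numeric(n0)
  D <- length(n0)
  out <- matrix(0, D, D)
  for (j in seq_len(D)) {
    ep <- em <- n0
    ep[j] <- ep[j] + step
    em[j] <- em[j] - step
    mp <- cgf_and_mean(family(ep), theta)$mean
    mm <- cgf_and_mean(family(em), theta)$mean
    out[, j] <- (mp - mm) / (2 * step)
  }
  out
}
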