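#' Define a Markov jump process with mass-action kinetics
#'
#' A jump process on the non-negative integer lattice is specified by `D`
#' species and a set of reactions, each with integer reactant and product
#' stoichiometries and a positive rate constant. Propensities follow
#' proportional sampling (the microphysics underlying mass-action rate laws):
#' reaction `r` fires from state `n` at rate
#' `k_r * prod_i n_i! / (n_i - y_ri)!`, where `y_r` is the reactant
#' stoichiometry vector.
#'
#' @param species character vector of species names (length `D >= 1`).
#' @param reactions list of reactions; each a list with elements `reactants`
#'   and `products` (named integer vectors over species; missing species count
#'   as 0) and `rate` (positive rate constant, per unit time).
#' @param name optional model name.
#' @return An object of class `jump_process` with elements `species`,
#'   `reactants` and `products` (R x D integer matrices), `rate` (length-R
#'   numeric), and `name`.
#' @examples
#' two_state <- jump_process(
#'   species = c("a", "b"),
#'   reactions = list(
#'     list(reactants = c(a = 1), products = c(b = 1), rate = 2),
#'     list(reactants = c(b = 1), products = c(a = 1), rate = 1)
#'   ),
#'   name = "two-state hopping"
#' )
#' @export
jump_process <- function(species, reactions, name = "jump process") {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species))
  D <- length(species)
  R <- length(reactions)
  stoich <- function(x) {
    v <- integer(D)
    names(v) <- species
    if (length(x)) {
      if (is.null(names(x)) || !all(names(x) %in% species))
        stop("reaction stoichiometries must be named by species")
      v[names(x)] <- as.integer(x)
    }
    if (any(v < 0)) stop("stoichiometries must be non-negative integers")
    v
  }
  Y <- matrix(0L, R, D, dimnames = list(NULL, species))
  Ybar <- Y
  rate <- numeric(R)
  for (r in seq_len(R)) {
    rx <- reactions[[r]]
    Y[r, ] <- stoich(rx$reactants)
    Ybar[r, ] <- stoich(rx$products)
    if (is.null(rx$rate) || !is.finite(rx$rate) || rx$rate <= 0)
      stop("each reaction needs a positive finite rate constant")
    rate[r] <- rx$rate
  }
  structure(list(species = species, reactants = Y, products = Ybar,
                 rate = rate, name = name),
            class = "jump_process")
}

#' @export
print.jump_process <- function(x, ...) {
  cat("Jump process:", x$name, "\n")
  cat(" ", length(x$species), "species:",
      paste(x$species, collapse = ", "), "\n")
  for (r in seq_along(x$rate)) {
    side <- function(v) {
      nz <- which(v > 0)
      if (!length(nz)) return("0")
      paste(ifelse(v[nz] > 1, paste0(v[nz], " "), ""), x$species[nz],
            sep = "", collapse = " + ")
    }
    cat(sprintf("  %s -> %s   rate %g\n",
                side(x$reactants[r, ]), side(x$products[r, ]), x$rate[r]))
  }
  invisible(x)
}

#' Read / write a jump-process model as JSON
#'
#' The schema is
#' `{"name": str, "species": [str], "reactions": [{"reactants": {species:
#' int}, "products": {species: int}, "rate": float}]}`.
#'
#' @param path file path.
#' @param spec a `jump_process`.
#' @return `read_jump_process` returns a `jump_process`;
#'   `write_jump_process` returns `path` invisibly.
#' @export
read_jump_process <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$species) || is.null(j$reactions))
    stop("malformed model JSON: needs 'species' and 'reactions'")
  reactions <- lapply(j$reactions, function(r) {
    list(reactants = unlist(r$reactants), products = unlist(r$products),
         rate = as.numeric(r$rate))
  })
  jump_process(unlist(j$species), reactions,
               name = if (is.null(j$name)) "jump process" else j$name)
}

#' @rdname read_jump_process
#' @export
write_jump_process <- function(spec, path) {
  reactions <- lapply(seq_along(spec$rate), function(r) {
    list(reactants = as.list(spec$reactants[r, ][spec$reactants[r, ] > 0]),
         products = as.list(spec$products[r, ][spec$products[r, ] > 0]),
         rate = spec$rate[r])
  })
  jsonlite::write_json(list(name = spec$name, species = spec$species,
                            reactions = reactions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- truncated lattice ------------------------------------------------------

#' Truncate the integer lattice
#'
#' States are enumerated row-major over the species index: species 1 varies
#' slowest, species `D` fastest, each `n_i` running `0..max_counts[i]`. The
#' enumeration is fixed so flat indices are reproducible across runs.
#'
#' @param max_counts integer vector of inclusive upper bounds per species.
#' @return object of class `lattice_truncation`.
#' @export
lattice_truncation <- function(max_counts) {
  max_counts <- as.integer(max_counts)
  stopifnot(length(max_counts) >= 1L, all(max_counts >= 1L))
  structure(list(max_counts = max_counts), class = "lattice_truncation")
}

#' Enumerate lattice states
#'
#' @param trunc a `lattice_truncation`.
#' @param sector optional conserved-quantity sector: a list
#'   `list(weights = w, value = c)` restricting enumeration to states with
#'   `sum(w * n) == c`. Order within the sector follows the full row-major
#'   enumeration.
#' @return integer matrix, one row per state.
#' @export
lattice_states <- function(trunc, sector = NULL) {
  m <- trunc$max_counts
  D <- length(m)
  grids <- lapply(rev(m), function(k) 0:k)
  S <- as.matrix(rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  dimnames(S) <- NULL
  S <- matrix(as.integer(S), nrow = nrow(S))
  if (!is.null(sector)) {
    keep <- drop(S %*% sector$weights) == sector$value
    if (!any(keep)) stop("sector restriction leaves no lattice states")
    S <- S[keep, , drop = FALSE]
  }
  S
}

# ---- lattice distributions --------------------------------------------------

#' Probability distribution on a truncated integer lattice
#'
#' @param states integer matrix, one row per lattice state (columns are
#'   species).
#' @param probs non-negative weights, one per state; normalized internally.
#'   Mass removed by normalization (e.g. leaked past a truncation boundary)
#'   is recorded in the `lost_mass` attribute.
#' @param species optional species names.
#' @param lost_mass probability mass lost to truncation, tracked for
#'   diagnostics.
#' @return object of class `lattice_dist` with elements `states`, `probs`,
#'   `species`.
#' @export
lattice_dist <- function(states, probs, species = NULL, lost_mass = 0) {
  states <- as.matrix(states)
  stopifnot(nrow(states) == length(probs), all(probs >= 0))
  s <- sum(probs)
  if (s <= 0) stop("distribution has no mass")
  if (is.null(species)) {
    species <- colnames(states)
    if (is.null(species)) species <- paste0("n", seq_len(ncol(states)))
  }
  structure(list(states = states, probs = probs / s, species = species),
            lost_mass = lost_mass, class = "lattice_dist")
}

#' @export
print.lattice_dist <- function(x, ...) {
  cat(sprintf("Lattice distribution: %d states, %d species (%s)\n",
              nrow(x$states), ncol(x$states),
              paste(x$species, collapse = ", ")))
  m <- dist_mean(x)
  cat("  mean:", paste(signif(m, 6), collapse = ", "), "\n")
  lm <- attr(x, "lost_mass")
  if (!is.null(lm) && lm > 0)
    cat("  truncation lost mass:", signif(lm, 3), "\n")
  invisible(x)
}

#' Moments of a lattice distribution
#' @param rho a `lattice_dist`.
#' @return `dist_mean`: mean vector; `dist_cov`: covariance matrix.
#' @export
dist_mean <- function(rho) drop(crossprod(rho$states, rho$probs))

#' @rdname dist_mean
#' @export
dist_cov <- function(rho) {
  m <- dist_mean(rho)
  Sc <- sweep(rho$states, 2, m)
  crossprod(Sc, Sc * rho$probs)
}

#' Standard base distributions on the truncated lattice
#'
#' `dist_poisson` builds a product of independent Poisson marginals truncated
#' at `max_counts` (leaked tail mass is tracked). `dist_binomial` builds the
#' one-species binomial on counts `0..N`. `dist_two_state` builds the
#' two-species binomial on the conserved shell `n_a + n_b = N`, with
#' `n_b ~ Binomial(N, nu_b)`.
#'
#' @param means Poisson mean vector.
#' @param max_counts truncation bounds (defaults to means + 10 sd, at least
#'   20).
#' @param N total walker count.
#' @param prob,nu_b success probability / occupancy of species `b`.
#' @param species species names.
#' @return a `lattice_dist`.
#' @export
dist_poisson <- function(means, max_counts = NULL, species = NULL) {
  D <- length(means)
  stopifnot(all(means > 0))
  if (is.null(max_counts))
    max_counts <- pmax(20, ceiling(means + 10 * sqrt(means)))
  trunc <- lattice_truncation(max_counts)
  S <- lattice_states(trunc)
  logp <- rowSums(vapply(seq_len(D), function(i)
    stats::dpois(S[, i], means[i], log = TRUE), numeric(nrow(S))))
  p <- exp(logp)
  lattice_dist(S, p, species = species, lost_mass = 1 - sum(p))
}

#' @rdname dist_poisson
#' @export
dist_binomial <- function(N, prob, species = "n") {
  S <- matrix(0:N, ncol = 1)
  lattice_dist(S, stats::dbinom(0:N, N, prob), species = species)
}

#' @rdname dist_poisson
#' @export
dist_two_state <- function(N, nu_b, species = c("a", "b")) {
  nb <- N:0   # row-major sector order: n_a ascending
  S <- matrix(as.integer(c(N - nb, nb)), ncol = 2)
  lattice_dist(S, stats::dbinom(nb, N, nu_b), species = species)
}

#' Marginalize a lattice distribution along a linear combination of species
#'
#' Tail queries and the importance-sampling operations are one-dimensional;
#' multi-species distributions are reduced to a declared species or linear
#' combination `sum(weights * n)` first.
#'
#' @param rho a `lattice_dist`.
#' @param weights numeric vector of length `D` (e.g. a unit vector to pick one
#'   species).
#' @return a one-species `lattice_dist` on the distinct values of the linear
#'   combination.
#' @export
dist_marginal <- function(rho, weights) {
  v <- drop(rho$states %*% weights)
  agg <- rowsum(rho$probs, v)
  vals <- as.numeric(rownames(agg))
  lattice_dist(matrix(vals, ncol = 1), drop(agg), species = "m",
               lost_mass = attr(rho, "lost_mass"))
}

#' Read / write lattice distributions as CSV
#'
#' Columns are `n_1 .. n_D` (named by species) followed by `prob`.
#'
#' @param rho a `lattice_dist`.
#' @param path file path.
#' @export
write_dist_csv <- function(rho, path) {
  df <- as.data.frame(rho$states)
  names(df) <- rho$species
  df$prob <- rho$probs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot("prob" %in% names(df))
  sp <- setdiff(names(df), "prob")
  lattice_dist(as.matrix(df[sp]), df$prob, species = sp)
}

# ---- generator --------------------------------------------------------------

#' Build the master-equation generator on a truncated lattice
#'
#' Assembles the continuous-time generator `T` of the master equation
#' `d rho / dt = T rho` as a sparse matrix over the flat state enumeration.
#' Off-diagonal entries are mass-action propensities for jumps
#' `n -> n - y_r + ybar_r`; every column sums to zero (probability
#' conservation). Propensities of jumps that would leave the truncated lattice
#' are dropped from the generator and accumulated per source state in the
#' `lost_rate` attribute, so truncation error is visible rather than silently
#' reflected.
#'
#' @param spec a `jump_process`.
#' @param trunc a `lattice_truncation`.
#' @param sector optional conserved-sector restriction as in
#'   [lattice_states()].
#' @return a `dgCMatrix` generator with attributes `states` (the enumeration)
#'   and `lost_rate`.
#' @export
build_generator <- function(spec, trunc, sector = NULL) {
  D <- length(spec$species)
  if (length(trunc$max_counts) != D)
    stop("truncation dimension does not match species count")
  if (any(apply(spec$reactants, 1, function(y) any(y > trunc$max_counts))))
    stop("truncation too small: some reactant stoichiometry fits nowhere")
  S <- lattice_states(trunc, sector)
  ns <- nrow(S)
  key <- apply(S, 1, paste, collapse = ",")
  idx <- stats::setNames(seq_len(ns), key)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  lost <- numeric(ns)
  for (r in seq_along(spec$rate)) {
    y <- spec$reactants[r, ]
    d <- spec$products[r, ] - y
    feas <- which(colSums(t(S) >= y) == D)
    if (!length(feas)) next
    # falling-factorial propensity k * prod n_i!/(n_i-y_i)!
    a <- rep(spec$rate[r], length(feas))
    for (i in which(y > 0)) {
      ni <- S[feas, i]
      for (k in 0:(y[i] - 1L)) a <- a * (ni - k)
    }
    tgt <- S[feas, , drop = FALSE] + rep(d, each = length(feas))
    tkey <- apply(tgt, 1, paste, collapse = ",")
    hit <- idx[tkey]
    inside <- !is.na(hit) &
      !apply(tgt > rep(trunc$max_counts, each = nrow(tgt)), 1, any)
    if (any(!inside)) lost[feas[!inside]] <- lost[feas[!inside]] + a[!inside]
    if (any(inside)) {
      ii <- c(ii, hit[inside], feas[inside])
      jj <- c(jj, feas[inside], feas[inside])
      xx <- c(xx, a[inside], -a[inside])
    }
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, ns))
  attr(G, "states") <- S
  attr(G, "lost_rate") <- lost
  attr(G, "species") <- spec$species
  G
}

#' Evolve a lattice distribution under the master equation
#'
#' Computes `exp(t T) rho0`: by dense matrix exponential for state spaces up
#' to 2000 states, and by implicit ODE integration (lsoda) above that.
#'
#' @param gen generator from [build_generator()].
#' @param rho0 initial `lattice_dist` on the same enumeration.
#' @param t non-negative time.
#' @return evolved `lattice_dist`.
#' @export
evolve_distribution <- function(gen, rho0, t) {
  if (t < 0) stop("t must be non-negative")
  S <- attr(gen, "states")
  if (nrow(S) != nrow(rho0$states) ||
      any(S != rho0$states))
    stop("rho0 is not on the generator's state enumeration")
  if (t == 0) return(rho0)
  ns <- nrow(S)
  if (ns <= 2000) {
    p <- drop(as.matrix(Matrix::expm(gen * t)) %*% rho0$probs)
  } else {
    deriv <- function(tt, y, parms) list(drop(gen %*% y))
    out <- deSolve::ode(y = rho0$probs, times = c(0, t), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    p <- out[nrow(out), -1]
  }
  if (abs(sum(p) - 1) > 1e-9)
    warning("mass not conserved within 1e-9 during evolution")
  p[p < 0] <- 0
  lattice_dist(S, p, species = attr(gen, "species"),
               lost_mass = attr(rho0, "lost_mass"))
}

#' Steady state of a generator
#'
#' Returns the normalized null vector of the generator. Errors if the null
#' space is not one-dimensional (multiple conserved sectors): restrict the
#' lattice to a sector with the `sector` argument of [build_generator()]
#' first.
#'
#' @param gen generator from [build_generator()].
#' @param tol relative singular-value threshold for null-space dimension.
#' @return a `lattice_dist`.
#' @export
steady_state <- function(gen, tol = 1e-8) {
  A <- as.matrix(gen)
  sv <- svd(A)
  small <- sv$d < tol * max(sv$d, 1)
  if (sum(small) == 0) stop("generator has no null vector at tolerance")
  if (sum(small) > 1)
    stop("degenerate null space: generator has multiple conserved sectors; ",
         "restrict to a sector before building the generator")
  v <- sv$v[, which(small)]
  v <- v * sign(sum(v))
  if (any(v < -1e-10)) stop("null vector is not a probability distribution")
  v[v < 0] <- 0
  rho <- lattice_dist(attr(gen, "states"), v, species = attr(gen, "species"))
  res <- max(abs(drop(gen %*% rho$probs)))
  if (res > 1e-10)
    warning(sprintf("steady-state residual %.2e exceeds 1e-10", res))
  rho
}
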