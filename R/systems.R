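# Potential-energy models, the target canonical density, and exact (or
# Metropolis-exact) equilibrium sampling for toy systems.
#
# Built-in systems:
#   double_well  U(x) = x^6 + 2 cos(5 (x + 1)), 1D; defaults beta = 1, m = 10
#   quartic      U(x) = x^4, 1D; defaults beta = 1, m = 1
#   quartic_nd   U(x) = sum_i x_i^4, separable n-D
#   lj_cluster   5-particle Lennard-Jones cluster (eps = sigma = 1) with a
#                harmonic restraint (k/2) sum |r_i|^2 to the origin
#
# All energies returned to the user are reduced: u(x) = beta * U(x),
# t(v) = beta * v' M v / 2, h = u + t.

.builtin_systems <- list(
  double_well = list(code = 1L, dimension = 1L, mass = 10, beta = 1,
                     params = numeric(0)),
  quartic     = list(code = 0L, dimension = 1L, mass = 1, beta = 1,
                     params = numeric(0)),
  quartic_nd  = list(code = 0L, dimension = NA_integer_, mass = 1, beta = 1,
                     params = numeric(0)),
  lj_cluster  = list(code = 2L, dimension = 15L, mass = 1, beta = 1,
                     params = c(k = 1))
)

#' Define a Langevin system (potential + masses + inverse temperature)
#'
#' A system bundles a potential-energy model `U(x)`, a diagonal mass matrix
#' and an inverse temperature `beta`, and exposes the reduced potential
#' `u(x) = beta U(x)`, reduced kinetic energy `t(v) = beta v'Mv/2` and the
#' canonical target `pi(x, v) \\propto e^{-u(x)} e^{-t(v)}`.
#'
#' @param name one of `"double_well"`, `"quartic"`, `"quartic_nd"`,
#'   `"lj_cluster"`, or `"custom"` (then supply `potential` and `gradient`).
#' @param beta inverse temperature (reduced units); default is the built-in
#'   system's study value (1 for all built-ins).
#' @param masses per-degree-of-freedom masses (recycled to the dimension);
#'   default is the built-in system's study value (10 for the double well,
#'   1 otherwise).
#' @param dimension number of degrees of freedom; required for
#'   `"quartic_nd"` and `"custom"`.
#' @param params named numeric parameters of the potential (`k`, the
#'   restraint constant, for `"lj_cluster"`).
#' @param potential,gradient for `name = "custom"`: R functions taking a
#'   position vector and returning `U(x)` (scalar) and `\\nabla U(x)`
#'   (vector).
#' @param domain optional declared bounded support `c(lo, hi)` for 1D
#'   systems; required for potentials whose density does not decay (e.g. a
#'   free particle), where "equilibrium" means the canonical density
#'   restricted to this interval.
#' @return an object of class `langevin_system`.
#' @examples
#' sys <- langevin_system("double_well")
#' potential_energy(sys, -1)   # u(-1) = 1 + 2 cos(0) = 3
#' @export
langevin_system <- function(name = c("double_well", "quartic", "quartic_nd",
                                     "lj_cluster", "custom"),
                            beta = NULL, masses = NULL, dimension = NULL,
                            params = NULL, potential = NULL, gradient = NULL,
                            domain = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(potential) || is.null(gradient) || is.null(dimension))
      stop("custom systems need `potential`, `gradient` and `dimension`")
    code <- -1L
    def <- list(mass = 1, beta = 1, params = numeric(0))
  } else {
    def <- .builtin_systems[[name]]
    code <- def$code
    if (is.null(dimension)) dimension <- def$dimension
    if (name %in% c("double_well", "quartic") && dimension != 1L)
      stop(name, " is one-dimensional")
    if (is.na(dimension))
      stop("quartic_nd needs an explicit `dimension`")
  }
  dimension <- as.integer(dimension)
  if (dimension < 1L) stop("dimension must be >= 1")
  if (is.null(beta)) beta <- def$beta
  if (beta <= 0) stop("beta must be > 0")
  if (is.null(masses)) masses <- def$mass
  masses <- rep_len(as.numeric(masses), dimension)
  if (any(masses <= 0)) stop("all masses must be > 0")
  p <- def$params
  if (!is.null(params)) {
    params <- unlist(params)
    p[names(params)] <- params
  }
  structure(list(name = name, code = code, dimension = dimension,
                 beta = as.numeric(beta), masses = masses,
                 params = as.numeric(p), param_names = names(p),
                 potential_fn = potential, gradient_fn = gradient,
                 domain = domain),
            class = "langevin_system")
}

#' @export
print.langevin_system <- function(x, ...) {
  cat(sprintf("<langevin_system> %s  (dimension %d, beta = %g)\n",
              x$name, x$dimension, x$beta))
  cat("  masses:", paste(signif(unique(x$masses), 4), collapse = ", "), "\n")
  if (length(x$params))
    cat("  params:", paste(x$param_names, signif(x$params, 4), sep = " = ",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Instantiate a system from a config block
#'
#' Accepts a list of the form
#' `list(system = list(name = "double_well", beta = 1, masses = 10))`
#' (or the inner list directly), as parsed from a JSON/TOML-style config.
#'
#' @param config list with fields `name` and optionally `beta`, `masses`,
#'   `dimension`, `params`.
#' @return a [langevin_system()].
#' @export
system_from_config <- function(config) {
  if (!is.null(config$system)) config <- config$system
  langevin_system(name = config$name, beta = config$beta,
                  masses = config$masses, dimension = config$dimension,
                  params = config$params)
}

check_position <- function(system, x) {
  x <- as.numeric(x)
  if (length(x) != system$dimension)
    stop("position has length ", length(x), ", expected ", system$dimension)
  if (!all(is.finite(x))) stop("non-finite position")
  x
}

#' Reduced potential energy u(x) = beta U(x)
#'
#' @param system a [langevin_system()].
#' @param x position vector of the system's dimension.
#' @return reduced (unitless) potential energy.
#' @export
potential_energy <- function(system, x) {
  x <- check_position(system, x)
  system$beta * cpp_potential(system$code, system$params, x,
                              system$potential_fn)
}

#' Force -grad U(x)
#'
#' Returns the negative gradient of the (unreduced) potential; division by
#' the mass happens inside the V substep.
#'
#' @inheritParams potential_energy
#' @return force vector.
#' @export
force <- function(system, x) {
  x <- check_position(system, x)
  -cpp_gradient(system$code, system$params, x, system$gradient_fn)
}

#' Reduced kinetic energy t(v) = beta v'Mv/2
#'
#' @param system a [langevin_system()].
#' @param v velocity vector.
#' @return reduced kinetic energy.
#' @export
kinetic_energy <- function(system, v) {
  v <- as.numeric(v)
  if (length(v) != system$dimension)
    stop("velocity has length ", length(v), ", expected ", system$dimension)
  0.5 * system$beta * sum(system$masses * v^2)
}

#' Reduced Hamiltonian h(z) = u(x) + t(v)
#'
#' @inheritParams potential_energy
#' @param v velocity vector.
#' @return reduced total energy of the phase point.
#' @export
reduced_hamiltonian <- function(system, x, v) {
  potential_energy(system, x) + kinetic_energy(system, v)
}

# Vectorized reduced potential over a grid (1D systems), used by the
# quadrature routines.  Falls back to a loop for custom potentials.
u_grid_1d <- function(system, xs) {
  b <- system$beta
  switch(as.character(system$code),
         "0" = b * xs^4,
         "1" = b * (xs^6 + 2 * cos(5 * (xs + 1))),
         vapply(xs, function(x)
           b * cpp_potential(system$code, system$params, x,
                             system$potential_fn), numeric(1)))
}

# Auto-select a bounded domain [-L, L] so that the neglected tail mass of
# pi_x is < 1e-12 (relative to the density maximum).
default_domain_1d <- function(system) {
  if (!is.null(system$domain)) return(sort(as.numeric(system$domain))[1:2])
  L <- 1
  repeat {
    xs <- seq(-L, L, length.out = 2001)
    u <- u_grid_1d(system, xs)
    umin <- min(u)
    if (u[1] - umin > 40 && u[length(u)] - umin > 40) break  # e^-40 < 1e-17
    L <- L * 1.5
    if (L > 1e4) stop("failed to bound the support of the density")
  }
  c(-L, L)
}

#' Exact configuration-space density on a 1D grid by quadrature
#'
#' Computes the per-bin mass of the equilibrium marginal
#' `pi_x(x) \\propto e^{-beta U(x)}` by trapezoidal quadrature on a fine
#' sub-grid within every bin, normalized to sum to 1.
#'
#' @param system a 1D [langevin_system()].
#' @param edges strictly increasing bin edges covering the support (the
#'   neglected tail mass outside the grid is renormalized away).
#' @param subdivisions quadrature points per bin (default 1e4).
#' @return object of class `density_grid_1d` with fields `edges` and
#'   `masses`.
#' @export
equilibrium_density_1d <- function(system, edges, subdivisions = 1e4) {
  if (system$dimension != 1L) stop("requires a 1D system")
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  nb <- length(edges) - 1L
  masses <- numeric(nb)
  for (b in seq_len(nb)) {
    xs <- seq(edges[b], edges[b + 1], length.out = subdivisions)
    f <- exp(-u_grid_1d(system, xs))
    masses[b] <- sum((f[-1] + f[-length(f)]) / 2 * diff(xs))
  }
  tot <- sum(masses)
  if (tot <= 0) stop("zero total mass on the supplied grid")
  # refinement check: double the sub-grid on the heaviest bin
  bmax <- which.max(masses)
  xs2 <- seq(edges[bmax], edges[bmax + 1], length.out = 2L * subdivisions)
  f2 <- exp(-u_grid_1d(system, xs2))
  m2 <- sum((f2[-1] + f2[-length(f2)]) / 2 * diff(xs2))
  if (abs(m2 - masses[bmax]) / tot > 1e-4)
    warning("grid too coarse: bin mass changes by more than 1e-4 on refinement")
  structure(list(edges = edges, masses = masses / tot),
            class = "density_grid_1d")
}

#' @export
print.density_grid_1d <- function(x, ...) {
  cat(sprintf("<density_grid_1d> %d bins on [%g, %g]\n",
              length(x$masses), x$edges[1], x$edges[length(x$edges)]))
  invisible(x)
}

#' i.i.d. equilibrium position samples
#'
#' For 1D systems, draws i.i.d. samples from `pi_x` by inverse-CDF lookup on
#' a fine quadrature grid (exact up to quadrature error). For n-D systems,
#' delegates to a Metropolized GHMC chain (exact stationary distribution)
#' and thins it; a first-half/second-half mean diagnostic guards against an
#' unequilibrated chain.
#'
#' @param system a [langevin_system()].
#' @param n number of samples.
#' @param seed optional integer seed.
#' @param grid_points inverse-CDF grid resolution (1D).
#' @param ... for n-D systems, arguments passed to [run_ghmc_chain()]
#'   (`splitting`, `dt`, `gamma`, `steps_per_proposal`).
#' @return numeric vector (1D) or `n x dimension` matrix of positions.
#' @export
sample_equilibrium_positions <- function(system, n, seed = NULL,
                                         grid_points = 200001L, ...) {
  stopifnot(n >= 1)
  if (system$dimension == 1L) {
    dom <- default_domain_1d(system)
    xs <- seq(dom[1], dom[2], length.out = grid_points)
    f <- exp(-(u_grid_1d(system, xs) - min(u_grid_1d(system, xs))))
    inc <- (f[-1] + f[-length(f)]) / 2 * diff(xs)
    cdf <- c(0, cumsum(inc)) / sum(inc)
    # collapse duplicated CDF values in the far tails for interpolation
    keep <- c(TRUE, diff(cdf) > 0)
    with_seed(seed, {
      u <- runif(n)
      approx(cdf[keep], xs[keep], xout = u, rule = 2)$y
    })
  } else {
    with_seed(seed, sample_equilibrium_positions_nd(system, n, ...))
  }
}

sample_equilibrium_positions_nd <- function(system, n, splitting = "OVRVO",
                                            dt = 0.05, gamma = 1,
                                            steps_per_proposal = 10L) {
  cfg <- integrator_config(splitting, dt = dt, gamma = gamma)
  thin <- max(1L, as.integer(ceiling(10 * (1 / gamma) / dt /
                                       steps_per_proposal)))
  burn <- 50L * thin
  chain <- run_ghmc_chain(system, cfg,
                          steps_per_proposal = steps_per_proposal,
                          n_iterations = burn + n * thin, thin = 1L)
  pos <- chain$positions[seq(burn + thin, burn + n * thin, by = thin), ,
                         drop = FALSE]
  # equilibration diagnostic on the first coordinate
  half <- nrow(pos) %/% 2
  if (half >= 10) {
    a <- pos[seq_len(half), 1]
    b <- pos[seq(half + 1, nrow(pos)), 1]
    se <- sqrt(sd(a)^2 / length(a) + sd(b)^2 / length(b))
    if (se > 0 && abs(mean(a) - mean(b)) > 3 * se)
      stop("equilibrium chain failed to equilibrate ",
           "(first/second-half mean discrepancy > 3 SE)")
  }
  pos
}

#' i.i.d. Maxwell-Boltzmann velocity samples
#'
#' Each component is Normal with mean 0 and variance `1 / (beta m_i)`; for
#' unconstrained systems the velocity distribution is independent of the
#' position.
#'
#' @inheritParams sample_equilibrium_positions
#' @return numeric vector (1D) or `n x dimension` matrix of velocities.
#' @export
sample_velocities <- function(system, n, seed = NULL) {
  stopifnot(n >= 1)
  d <- system$dimension
  sds <- 1 / sqrt(system$beta * system$masses)
  with_seed(seed, {
    m <- matrix(rnorm(n * d), n, d) * rep(sds, each = n)
    if (d == 1L) drop(m) else m
  })
}
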