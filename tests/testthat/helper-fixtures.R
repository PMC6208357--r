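# Shared fixtures, built in code.

dw <- langevin_system("double_well")            # beta = 1, gamma-study m = 10
qt <- langevin_system("quartic")                # beta = 1, m = 1

# flat potential with a declared bounded support: "equilibrium" positions
# are uniform on [-2, 2]; shadow work is identically zero
free_particle <- langevin_system(
  "custom", dimension = 1L, masses = 1, beta = 1,
  potential = function(x) 0, gradient = function(x) 0 * x,
  domain = c(-2, 2))

# absolute-scale comparison for quantities that can be legitimately ~ 0
expect_close <- function(a, b, tol) {
  expect_lt(abs(a - b), tol * max(1, abs(b)))
}

# Central finite-difference force oracle (independent of force()).
fd_force <- function(system, x, h = 1e-5) {
  d <- length(x)
  vapply(seq_len(d), function(i) {
    e <- replace(numeric(d), i, h)
    -(potential_energy(system, x + e) - potential_energy(system, x - e)) /
      (2 * h) / system$beta
  }, numeric(1))
}

# Shadow work of one recorded single-cycle trajectory from the explicit
# energy bookkeeping: delta_h minus the kinetic-energy change across every
# O substep, all read off the per-substep states.
bookkeeping_work <- function(system, run, letters) {
  X <- run$states$x; V <- run$states$v
  n <- nrow(X)
  u <- function(i) potential_energy(system, X[i, ])
  t <- function(i) kinetic_energy(system, V[i, ])
  dh <- (u(n) + t(n)) - (u(1) + t(1))
  dq <- 0
  for (s in seq_along(letters)) {
    if (letters[s] == "O") dq <- dq + (t(s + 1) - t(s))
  }
  dh - dq
}

# Histogram of 1D samples on fixed edges (out-of-range samples dropped).
hist1d <- function(x, edges) {
  x <- x[x >= edges[1] & x <= edges[length(edges)]]
  make_histogram(tabulate(findInterval(x, edges, all.inside = TRUE),
                          length(edges) - 1), list(edges))
}
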