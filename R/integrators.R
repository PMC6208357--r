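# Splitting-string parsing, the R/V/O substeps, trajectory execution and
# exact shadow-work accounting.
#
# A splitting string such as "OVRVO" names a symmetric (Strang) Trotter
# factorization of the Langevin propagator.  Each occurrence of a letter L
# receives the time fraction 1/count(L) of the timestep, so that per cycle
# every letter advances its sub-propagator by a total of dt:
#   "OVRVO" -> (O,1/2) (V,1/2) (R,1) (V,1/2) (O,1/2)
#   "VRORV" -> (V,1/2) (R,1/2) (O,1) (R,1/2) (V,1/2)
#
# For symmetric splittings the shadow work of a trajectory is
#   w = delta_h - delta_q,
# the total change in reduced Hamiltonian minus the reduced heat exchanged
# across the O substeps.  Non-palindromic strings are rejected: their work
# accounting requires a different path-probability ratio.

.letter_codes <- c(R = 0L, V = 1L, O = 2L)

#' Parse a splitting string into an ordered substep sequence
#'
#' @param spec character string over the letters R, V, O (case-insensitive),
#'   e.g. `"OVRVO"`, `"VRORV"`, `"RVOVR"`, `"ORVRO"`.
#' @return object of class `splitting_scheme` with fields `letters`
#'   (character vector) and `fractions` (per-substep fraction of the
#'   timestep; the fractions of each letter sum to 1).
#' @examples
#' parse_splitting("OVRVO")
#' @export
parse_splitting <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1, nzchar(spec))
  letters <- strsplit(toupper(spec), "")[[1]]
  bad <- setdiff(letters, names(.letter_codes))
  if (length(bad))
    stop("illegal character(s) in splitting string: ",
         paste(unique(bad), collapse = ", "))
  if (!identical(letters, rev(letters)))
    stop("non-palindromic splitting '", spec, "' is not supported: ",
         "shadow-work accounting here assumes a symmetric splitting")
  counts <- table(letters)
  fractions <- 1 / as.numeric(counts[letters])
  structure(list(string = paste(letters, collapse = ""),
                 letters = letters, fractions = fractions),
            class = "splitting_scheme")
}

#' @export
print.splitting_scheme <- function(x, ...) {
  cat(sprintf("<splitting_scheme> %s: %s\n", x$string,
              paste(sprintf("(%s,%s)", x$letters,
                            format(x$fractions)), collapse = " ")))
  invisible(x)
}

#' Integrator configuration
#'
#' @param splitting a splitting string or a [parse_splitting()] result.
#' @param dt timestep (reduced time units), > 0.
#' @param gamma collision rate (inverse reduced time), >= 0.
#' @return object of class `integrator_config`.
#' @export
integrator_config <- function(splitting, dt, gamma) {
  scheme <- if (inherits(splitting, "splitting_scheme")) splitting
            else parse_splitting(splitting)
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0,
            is.numeric(gamma), length(gamma) == 1, gamma >= 0)
  structure(list(scheme = scheme, dt = as.numeric(dt),
                 gamma = as.numeric(gamma)),
            class = "integrator_config")
}

#' @export
print.integrator_config <- function(x, ...) {
  cat(sprintf("<integrator_config> %s, dt = %g, gamma = %g\n",
              x$scheme$string, x$dt, x$gamma))
  invisible(x)
}

#' Config from a list block
#'
#' Accepts `list(splitting = "OVRVO", dt = 0.5, gamma = 10)` as parsed from
#' a JSON/TOML-style config.
#' @param config list with fields `splitting`, `dt`, `gamma`.
#' @return an [integrator_config()].
#' @export
config_from_list <- function(config) {
  integrator_config(config$splitting, dt = config$dt, gamma = config$gamma)
}

#' R substep: position drift
#'
#' `x' = x + v tau`, velocity unchanged.
#'
#' @param system a [langevin_system()].
#' @param x,v phase point.
#' @param tau substep duration, >= 0.
#' @return list with updated `x` and `v`.
#' @export
substep_R <- function(system, x, v, tau) {
  stopifnot(tau >= 0)
  list(x = x + v * tau, v = v)
}

#' V substep: velocity kick by the force
#'
#' `v' = v - M^{-1} grad U(x) tau`, position unchanged.
#'
#' @inheritParams substep_R
#' @return list with updated `x` and `v`.
#' @export
substep_V <- function(system, x, v, tau) {
  stopifnot(tau >= 0)
  list(x = x, v = v + force(system, x) / system$masses * tau)
}

#' O substep: Ornstein-Uhlenbeck partial velocity randomization
#'
#' `v' = a v + sqrt(1 - a^2) (beta M)^{-1/2} xi` with `a = exp(-gamma tau)`.
#' The reduced heat exchanged, `t(v') - t(v)`, is returned alongside the
#' state.
#'
#' @inheritParams substep_R
#' @param gamma collision rate.
#' @param xi standard-normal vector of the system's dimension (drawn
#'   internally if missing).
#' @return list with `x`, `v` and the reduced heat increment `heat`.
#' @export
substep_O <- function(system, x, v, tau, gamma, xi = NULL) {
  stopifnot(tau >= 0, gamma >= 0)
  if (is.null(xi)) xi <- rnorm(system$dimension)
  a <- exp(-gamma * tau)
  v2 <- a * v + sqrt(1 - a^2) / sqrt(system$beta * system$masses) * xi
  list(x = x, v = v2,
       heat = kinetic_energy(system, v2) - kinetic_energy(system, v))
}

#' Run integrator cycles with exact shadow-work accounting
#'
#' Executes `n_steps` full cycles of the configured splitting, each substep
#' advancing by `fraction * dt`, with one fresh standard-normal draw per
#' degree of freedom per O substep and one force evaluation per V substep.
#' The returned work ledger satisfies `shadow_work = delta_h - delta_q`
#' exactly as computed.
#'
#' @param system a [langevin_system()].
#' @param config an [integrator_config()].
#' @param x0,v0 initial phase point.
#' @param n_steps number of cycles, >= 0.
#' @param seed optional integer seed (bitwise-reproducible trajectories).
#' @param record_substeps if TRUE, also return the phase point after every
#'   substep (diagnostic; keep `n_steps` small).
#' @param thin if > 0, record the state after every `thin`-th cycle.
#' @return list with `x`, `v` (final state), `ledger` (class `work_ledger`:
#'   `delta_h`, `delta_q`, `shadow_work`), and optionally `states`
#'   (per-substep phase points) and `trajectory` (thinned states).
#'   Signals an error of class `splitkl_instability` (carrying the step
#'   index) if the state becomes non-finite or `|x| > 1e6`.
#' @export
run_steps <- function(system, config, x0, v0, n_steps, seed = NULL,
                      record_substeps = FALSE, thin = 0) {
  stopifnot(n_steps >= 0)
  x0 <- check_position(system, x0)
  v0 <- as.numeric(v0)
  if (length(v0) != system$dimension) stop("v0 has the wrong dimension")
  if (n_steps == 0) {
    return(list(x = x0, v = v0,
                ledger = work_ledger(0, 0)))
  }
  res <- with_seed(seed,
    cpp_run_cycles(system$code, system$params, system$beta, system$masses,
                   .letter_codes[config$scheme$letters],
                   config$scheme$fractions, config$dt, config$gamma,
                   x0, v0, as.integer(n_steps),
                   record_states = record_substeps, thin = as.integer(thin),
                   pfun = system$potential_fn, gfun = system$gradient_fn))
  if (!res$stable) stop_instability(res$failed_step, "run_steps")
  out <- list(x = res$x, v = res$v,
              ledger = work_ledger(res$delta_h, res$delta_q))
  if (record_substeps)
    out$states <- list(x = res$states_x, v = res$states_v,
                       letters = config$scheme$letters)
  if (thin > 0)
    out$trajectory <- list(x = res$traj_x, v = res$traj_v)
  out
}

#' Work ledger of a trajectory
#'
#' @param delta_h total change in reduced Hamiltonian over the trajectory.
#' @param delta_q total reduced heat exchanged across O substeps.
#' @return object of class `work_ledger` with `shadow_work = delta_h -
#'   delta_q` (computed, not stored independently).
#' @export
work_ledger <- function(delta_h, delta_q) {
  structure(list(delta_h = delta_h, delta_q = delta_q,
                 shadow_work = delta_h - delta_q),
            class = "work_ledger")
}

#' @export
print.work_ledger <- function(x, ...) {
  cat(sprintf("<work_ledger> delta_h = %g, delta_q = %g, shadow work = %g\n",
              x$delta_h, x$delta_q, x$shadow_work))
  invisible(x)
}

#' Shadow work of a finalized ledger
#'
#' @param ledger a `work_ledger`.
#' @return `delta_h - delta_q`, the reduced shadow work.
#' @export
shadow_work <- function(ledger) {
  ledger$delta_h - ledger$delta_q
}

# Batched trajectories from many starts (internal): returns per-trajectory
# shadow work, final states and stability flags.
work_batch <- function(system, config, X0, V0, n_steps) {
  X0 <- as_matrix_nd(X0, system$dimension)
  V0 <- as_matrix_nd(V0, system$dimension)
  cpp_work_batch(system$code, system$params, system$beta, system$masses,
                 .letter_codes[config$scheme$letters],
                 config$scheme$fractions, config$dt, config$gamma,
                 X0, V0, as.integer(n_steps),
                 pfun = system$potential_fn, gfun = system$gradient_fn)
}

as_matrix_nd <- function(x, d) {
  if (is.matrix(x)) x else matrix(x, ncol = d)
}
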