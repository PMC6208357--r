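# Metropolization of splitting integrators: generalized hybrid Monte Carlo
# (GHMC).  A proposal is one or more integrator cycles; it is accepted with
# probability alpha = min{1, e^{-w_shad}}.  The resulting chain samples the
# canonical density exactly, at the cost of a momentum flip on rejection.

#' GHMC acceptance rate from equilibrium starts
#'
#' For each proposal, draws `(x0, v0) ~ pi`, runs `steps_per_proposal`
#' integrator cycles, and evaluates `alpha = min(1, e^{-w_shad})`.  The
#' returned rate is the sample mean of `alpha` (fresh equilibrium starts
#' isolate the rate from chain autocorrelation; no momentum flipping is
#' involved).  An unstable proposal counts as `alpha = 0`.
#'
#' @param system a [langevin_system()].
#' @param config an [integrator_config()].
#' @param steps_per_proposal integrator cycles per proposal (default 1).
#' @param n_proposals number of proposals.
#' @param seed optional integer seed.
#' @return object of class `acceptance_report` with `acceptance_rate`,
#'   `rejection_rate`, `n_proposals`, `se` and `n_unstable`.
#' @export
ghmc_acceptance_rate <- function(system, config, steps_per_proposal = 1L,
                                 n_proposals = 10000L, seed = NULL) {
  stopifnot(n_proposals >= 1, steps_per_proposal >= 1)
  with_seed(seed, {
    X0 <- as_matrix_nd(sample_equilibrium_positions(system, n_proposals),
                       system$dimension)
    V0 <- as_matrix_nd(sample_velocities(system, n_proposals),
                       system$dimension)
    run <- work_batch(system, config, X0, V0, steps_per_proposal)
    alpha <- ifelse(run$stable, pmin(1, exp(-run$work)), 0)
    acceptance_report(mean(alpha), n_proposals,
                      se = sd(alpha) / sqrt(n_proposals),
                      n_unstable = sum(!run$stable))
  })
}

#' Acceptance report container
#'
#' @param acceptance_rate mean acceptance probability in `[0, 1]`.
#' @param n_proposals number of proposals.
#' @param se standard error of the rate.
#' @param n_unstable proposals that diverged (counted as rejected).
#' @return object of class `acceptance_report`.
#' @export
acceptance_report <- function(acceptance_rate, n_proposals, se,
                              n_unstable = 0L) {
  stopifnot(acceptance_rate >= 0, acceptance_rate <= 1)
  structure(list(acceptance_rate = acceptance_rate,
                 rejection_rate = 1 - acceptance_rate,
                 n_proposals = n_proposals, se = se,
                 n_unstable = n_unstable),
            class = "acceptance_report")
}

#' @export
print.acceptance_report <- function(x, ...) {
  cat(sprintf(
    "<acceptance_report> acceptance %.4f +/- %.4f (n = %s proposals)\n",
    x$acceptance_rate, x$se, format(x$n_proposals, big.mark = ",")))
  invisible(x)
}

#' Run a GHMC chain (exact canonical sampler)
#'
#' A full Markov chain whose stationary distribution is exactly the
#' canonical density: each iteration proposes `steps_per_proposal` cycles of
#' the configured Langevin integrator (the O substeps inside the proposal
#' supply the velocity randomization), applies the Metropolis test on the
#' accumulated shadow work, and negates the momentum on rejection, as
#' detailed balance requires.  Used as the n-D equilibrium sampler by
#' [sample_equilibrium_positions()].
#'
#' @inheritParams ghmc_acceptance_rate
#' @param n_iterations chain length (>= 1).
#' @param thin record positions every `thin` iterations (default 1).
#' @param x0,v0 optional initial state; defaults to an equilibrium draw for
#'   1D systems and the origin plus a Maxwell-Boltzmann velocity otherwise.
#' @return list with `positions` (matrix, one recorded state per row),
#'   `report` (an [acceptance_report()]) and the final `x`, `v`.  Warns if
#'   the acceptance rate falls below 1%.
#' @export
run_ghmc_chain <- function(system, config, steps_per_proposal = 1L,
                           n_iterations = 10000L, seed = NULL, thin = 1L,
                           x0 = NULL, v0 = NULL) {
  stopifnot(n_iterations >= 1, thin >= 1)
  with_seed(seed, {
    if (is.null(x0)) {
      x0 <- if (system$dimension == 1L)
        sample_equilibrium_positions(system, 1)
      else numeric(system$dimension)
    }
    if (is.null(v0)) v0 <- as.numeric(sample_velocities(system, 1))
    res <- cpp_ghmc_chain(system$code, system$params, system$beta,
                          system$masses,
                          .letter_codes[config$scheme$letters],
                          config$scheme$fractions, config$dt, config$gamma,
                          as.numeric(x0), as.numeric(v0),
                          as.integer(steps_per_proposal),
                          as.integer(n_iterations), as.integer(thin),
                          pfun = system$potential_fn,
                          gfun = system$gradient_fn)
    rate <- res$n_accept / res$n_proposals
    if (rate < 0.01)
      warning(sprintf("GHMC chain nearly frozen: acceptance %.2f%%",
                      100 * rate))
    list(positions = res$positions,
         report = acceptance_report(
           rate, res$n_proposals,
           se = sqrt(rate * (1 - rate) / res$n_proposals)),
         x = res$x, v = res$v)
  })
}
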