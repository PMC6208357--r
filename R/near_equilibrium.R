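# The length-2T near-equilibrium protocol and the halved-difference-of-work-
# averages KL estimators.
#
# One protocol sample: draw (x0, v0) ~ pi, run T integrator steps
# accumulating shadow work w_first (the endpoint is then approximately a
# draw from the integrator's steady state rho); in phase mode continue
# directly for T more steps accumulating w_second; in configuration mode
# first replace the midpoint velocities with a fresh Maxwell-Boltzmann draw
# (turning the rho draw into an omega = rho_x * pi(v|x) draw) -- the
# velocity randomization itself does no work.  Then
#   D_KL(rho || pi)    ~ (  <w>_pi - <w>_rho   ) / 2   (phase mode)
#   D_KL(rho_x||pi_x)  ~ (  <w>_pi - <w>_omega ) / 2   (configuration mode)

#' Protocol specification for the near-equilibrium estimator
#'
#' @param n_steps_T steps per protocol half; `NULL` selects the default
#'   [default_protocol_length()] (two collision times).
#' @param mode `"phase"` for the full phase-space divergence, or
#'   `"configuration"` for the configuration-marginal divergence.
#' @param n_samples number of protocol samples (>= 2).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_steps_T = NULL,
                          mode = c("phase", "configuration"),
                          n_samples = 10000L) {
  mode <- match.arg(mode)
  if (!is.null(n_steps_T)) stopifnot(n_steps_T >= 1)
  stopifnot(n_samples >= 2)
  structure(list(n_steps_T = n_steps_T, mode = mode,
                 n_samples = as.integer(n_samples)),
            class = "protocol_spec")
}

#' Default protocol half-length: two collision times
#'
#' `T = ceiling((2 / gamma) / dt)`, at least 1 step.  Validate with
#' [check_protocol_length()] for the system at hand.
#'
#' @param config an [integrator_config()].
#' @return integer number of steps.
#' @export
default_protocol_length <- function(config) {
  if (config$gamma <= 0) stop("protocol length default needs gamma > 0")
  max(1L, as.integer(ceiling((2 / config$gamma) / config$dt)))
}

#' Relaxation-time estimate for protocol sizing
#'
#' The protocol must span the slowest relaxation that shapes the
#' integrator's steady state.  Velocities decorrelate on the collision time
#' `1/gamma`; for a heavy particle at high friction the configuration
#' relaxes more slowly, on `gamma m / k` with `k` the (thermally averaged)
#' curvature of the potential.  This returns `2/gamma + gamma m / k_eff`
#' with `k_eff = <U''>_pi` computed by quadrature (1D systems; for n-D
#' systems only the collision-time term is used).
#'
#' @param system a [langevin_system()].
#' @param config an [integrator_config()] (supplies `gamma`).
#' @return relaxation time in reduced time units.
#' @export
relaxation_time <- function(system, config) {
  if (config$gamma <= 0) stop("relaxation time needs gamma > 0")
  tau_v <- 2 / config$gamma
  if (system$dimension != 1L) return(tau_v)
  dom <- default_domain_1d(system)
  xs <- seq(dom[1], dom[2], length.out = 20001)
  u <- u_grid_1d(system, xs)
  w <- exp(-(u - min(u))); w <- w / sum(w)
  h <- xs[2] - xs[1]
  upp <- c(NA, diff(u, differences = 2) / h^2, NA) / system$beta
  k_eff <- sum(w[-c(1, length(w))] * upp[-c(1, length(upp))]) /
    sum(w[-c(1, length(w))])
  if (!is.finite(k_eff) || k_eff <= 0) return(tau_v)
  tau_v + config$gamma * system$masses[1] / k_eff
}

#' Protocol length spanning the configurational relaxation
#'
#' `T = ceiling(n_relax * relaxation_time / dt)`, floored at
#' [default_protocol_length()].  This is the protocol length the package
#' uses for validation-grade runs ([sandwich_validation()]); confirm it
#' with [check_protocol_length()] or [auto_protocol_length()] for new
#' systems.
#'
#' @inheritParams relaxation_time
#' @param n_relax relaxation times to span (default 2).
#' @return integer number of steps.
#' @export
suggest_protocol_length <- function(system, config, n_relax = 2) {
  max(default_protocol_length(config),
      as.integer(ceiling(n_relax * relaxation_time(system, config) /
                           config$dt)))
}

#' Select a protocol length by T-vs-2T concordance
#'
#' Starting from `start` (default [default_protocol_length()]), doubles the
#' protocol length until two successive doublings are concordant (the
#' [check_protocol_length()] criterion, |difference| < 2 combined SE), and
#' returns the first length of the concordant pair.
#'
#' @inheritParams run_protocol_samples
#' @param n_samples protocol samples per probe.
#' @param start initial protocol length.
#' @param max_doublings probe budget.
#' @param mode `"phase"` or `"configuration"`.
#' @return integer protocol length.
#' @export
auto_protocol_length <- function(system, config,
                                 mode = c("phase", "configuration"),
                                 n_samples = 20000L, seed = NULL,
                                 start = NULL, max_doublings = 8L) {
  mode <- match.arg(mode)
  T_cur <- if (is.null(start)) default_protocol_length(config)
           else as.integer(start)
  streak <- 0L
  first_ok <- T_cur
  for (k in seq_len(max_doublings)) {
    chk <- check_protocol_length(system, config,
                                 protocol_spec(T_cur, mode, n_samples),
                                 seed = child_seed(seed, k))
    if (chk$concordant) {
      if (streak == 0L) first_ok <- T_cur
      streak <- streak + 1L
      if (streak >= 2L) return(first_ok)
    } else streak <- 0L
    T_cur <- 2L * T_cur
  }
  warning("no concordant protocol length found within the doubling budget")
  T_cur
}

#' Draw near-equilibrium protocol samples
#'
#' Runs `spec$n_samples` independent length-2T protocols and returns the
#' paired shadow works of the two halves.
#'
#' @param system a [langevin_system()].
#' @param config an [integrator_config()].
#' @param spec a [protocol_spec()].
#' @param seed optional integer seed.
#' @return data.frame of class `protocol_samples` with columns `w_first`
#'   (equilibrium start) and `w_second` (steady-state / omega start), plus
#'   attributes recording the configuration.
#' @export
run_protocol_samples <- function(system, config, spec, seed = NULL) {
  T_steps <- if (is.null(spec$n_steps_T)) default_protocol_length(config)
             else as.integer(spec$n_steps_T)
  n <- spec$n_samples
  with_seed(seed, {
    X0 <- as_matrix_nd(sample_equilibrium_positions(system, n),
                       system$dimension)
    V0 <- as_matrix_nd(sample_velocities(system, n), system$dimension)
    first <- work_batch(system, config, X0, V0, T_steps)
    if (!all(first$stable))
      stop_instability(which(!first$stable)[1], "protocol first half")
    Vmid <- if (spec$mode == "configuration")
      as_matrix_nd(sample_velocities(system, n), system$dimension)
    else first$v_end
    second <- work_batch(system, config, first$x_end, Vmid, T_steps)
    if (!all(second$stable))
      stop_instability(which(!second$stable)[1], "protocol second half")
    out <- data.frame(w_first = first$work, w_second = second$work)
    class(out) <- c("protocol_samples", "data.frame")
    attr(out, "meta") <- list(system = system$name,
                              splitting = config$scheme$string,
                              dt = config$dt, gamma = config$gamma,
                              mode = spec$mode, T = T_steps)
    out
  })
}

#' Draw a single protocol sample
#'
#' @inheritParams run_protocol_samples
#' @return list with `w_first` and `w_second`.
#' @export
run_protocol_sample <- function(system, config, spec, seed = NULL) {
  spec1 <- spec
  spec1$n_samples <- 2L   # spec requires >= 2; we use the first row
  s <- run_protocol_samples(system, config, spec1, seed = seed)
  list(w_first = s$w_first[1], w_second = s$w_second[1])
}

#' KL estimate container
#'
#' @param value point estimate (nats).
#' @param ci_low,ci_high 95% confidence bounds (nats); widened to include
#'   the point estimate if a resampling interval falls beside it.
#' @param estimator estimator tag.
#' @param n sample-size metadata.
#' @param meta optional configuration echo.
#' @return object of class `kl_estimate`.
#' @export
kl_estimate <- function(value, ci_low, ci_high, estimator, n, meta = NULL) {
  ci_low <- min(ci_low, value)
  ci_high <- max(ci_high, value)
  structure(list(value = value, ci_low = ci_low, ci_high = ci_high,
                 estimator = estimator, n = n, meta = meta),
            class = "kl_estimate")
}

#' @export
print.kl_estimate <- function(x, ...) {
  cat(sprintf("<kl_estimate> %s: %.6g nats  [95%% CI %.6g, %.6g]  (n = %s)\n",
              x$estimator, x$value, x$ci_low, x$ci_high,
              format(x$n, big.mark = ",")))
  invisible(x)
}

#' Near-equilibrium KL estimate from protocol samples
#'
#' The halved difference of the two work averages,
#' `(mean(w_first) - mean(w_second)) / 2`, with a 95% CI from the paired
#' per-sample differences `d_i = (w_first_i - w_second_i) / 2` (the two
#' halves of one protocol are correlated; pairing uses that structure).
#' Negative point estimates are reported as-is.
#'
#' @param samples a `protocol_samples` data.frame (>= 2 rows).
#' @return a [kl_estimate()].
#' @export
estimate_kl_near_eq <- function(samples) {
  n <- nrow(samples)
  if (is.null(n) || n < 2) stop("need at least 2 protocol samples")
  d <- (samples$w_first - samples$w_second) / 2
  value <- mean(d)
  se <- sd(d) / sqrt(n)
  kl_estimate(value, value - 1.96 * se, value + 1.96 * se,
              estimator = paste0("near_equilibrium/",
                                 attr(samples, "meta")$mode %||% "phase"),
              n = n, meta = attr(samples, "meta"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Protocol-length concordance check
#'
#' Repeats the near-equilibrium estimate at protocol lengths T and 2T with
#' equal sample counts and reports whether the two estimates agree within
#' twice their combined standard error.  Discordance flags an under-length
#' protocol; it is not an error.
#'
#' @inheritParams run_protocol_samples
#' @return list with both estimates, their `difference`, `combined_se` and
#'   the logical `concordant`.
#' @export
check_protocol_length <- function(system, config, spec, seed = NULL) {
  T_steps <- if (is.null(spec$n_steps_T)) default_protocol_length(config)
             else as.integer(spec$n_steps_T)
  spec_T <- protocol_spec(T_steps, spec$mode, spec$n_samples)
  spec_2T <- protocol_spec(2L * T_steps, spec$mode, spec$n_samples)
  est_T <- estimate_kl_near_eq(
    run_protocol_samples(system, config, spec_T, seed = seed))
  est_2T <- estimate_kl_near_eq(
    run_protocol_samples(system, config, spec_2T,
                         seed = child_seed(seed, 1)))
  se_T <- (est_T$ci_high - est_T$ci_low) / (2 * 1.96)
  se_2T <- (est_2T$ci_high - est_2T$ci_low) / (2 * 1.96)
  combined <- sqrt(se_T^2 + se_2T^2)
  diff <- est_2T$value - est_T$value
  list(T = T_steps, estimate_T = est_T, estimate_2T = est_2T,
       difference = diff, combined_se = combined,
       concordant = abs(diff) < 2 * combined)
}
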