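# Asymptotically exact reference estimators for the KL divergence:
#   * nested Monte Carlo with adaptive inner-loop variance control
#     (a finite-sample UNDER-estimate),
#   * the Jensen-inequality exponential-average upper bound,
#   * exact histogram/quadrature KL for 1D systems,
#   * the two-level ("jagged") bootstrap for confidence intervals.

#' Adaptive inner-loop controller
#'
#' The nested estimator must converge one exponential average
#' `ln <e^{-w}>` per outer sample.  Inner samples are drawn in batches until
#' the first-order Taylor estimate of the standard deviation of that
#' log-mean, `sd(e^{-w}) / (mean(e^{-w}) sqrt(M))`, falls below
#' `sigma_threshold`, or the budget is hit.
#'
#' @param sigma_threshold target standard deviation of the inner log-mean
#'   (default 0.01).
#' @param budget maximum inner samples per outer sample (default 5e4).
#' @param batch samples drawn between convergence checks (default 100).
#' @param min_inner minimum inner samples before any stop decision
#'   (default 50).
#' @return object of class `inner_loop_controller`.
#' @export
inner_loop_controller <- function(sigma_threshold = 0.01, budget = 5e4,
                                  batch = 100L, min_inner = 50L) {
  stopifnot(sigma_threshold > 0, budget >= batch, batch >= 1, min_inner >= 2)
  structure(list(sigma_threshold = sigma_threshold,
                 budget = as.integer(budget), batch = as.integer(batch),
                 min_inner = as.integer(min_inner)),
            class = "inner_loop_controller")
}

#' Draw an approximate steady-state (or omega) start
#'
#' Draws `(x, v) ~ pi` and runs `decorrelation_steps` integrator steps so
#' the endpoint is approximately a draw from the integrator's steady state
#' rho.  In configuration mode the velocities are then replaced by a fresh
#' Maxwell-Boltzmann draw, yielding an approximate draw from
#' `omega(x, v) = rho_x(x) pi(v|x)`.
#'
#' @param system a [langevin_system()].
#' @param config an [integrator_config()].
#' @param mode `"phase"` or `"configuration"`.
#' @param decorrelation_steps integrator steps from the equilibrium start;
#'   default `ceiling((2 / gamma) / dt)` (two collision times).
#' @param seed optional integer seed.
#' @param n number of independent starts.
#' @return list with matrices `x` and `v` (`n` rows).
#' @export
sample_steady_state_start <- function(system, config,
                                      mode = c("phase", "configuration"),
                                      decorrelation_steps = NULL,
                                      seed = NULL, n = 1L) {
  mode <- match.arg(mode)
  if (is.null(decorrelation_steps))
    decorrelation_steps <- default_protocol_length(config)
  with_seed(seed, {
    X0 <- as_matrix_nd(sample_equilibrium_positions(system, n),
                       system$dimension)
    V0 <- as_matrix_nd(sample_velocities(system, n), system$dimension)
    if (decorrelation_steps > 0) {
      run <- work_batch(system, config, X0, V0, decorrelation_steps)
      if (!all(run$stable))
        stop_instability(which(!run$stable)[1], "steady-state decorrelation")
      X0 <- run$x_end; V0 <- run$v_end
    }
    if (mode == "configuration")
      V0 <- as_matrix_nd(sample_velocities(system, n), system$dimension)
    list(x = X0, v = V0)
  })
}

#' Inner-loop work collection from a fixed start
#'
#' Repeatedly runs the T-step protocol from the SAME fixed phase point, each
#' realization with fresh noise, recording the shadow work, until the
#' controller's convergence criterion is met or its budget is exhausted
#' (the row is then retained but flagged unconverged).
#'
#' @inheritParams sample_steady_state_start
#' @param start list with `x` and `v` (one phase point).
#' @param T_steps protocol length in integrator steps (>= 1).
#' @param controller an [inner_loop_controller()].
#' @return list with `work` (vector), `sigma_inner` and `converged`.
#' @export
collect_inner_work <- function(system, config, start, T_steps,
                               controller = inner_loop_controller(),
                               seed = NULL) {
  stopifnot(T_steps >= 1)
  x0 <- as.numeric(start$x); v0 <- as.numeric(start$v)
  with_seed(seed, {
    works <- numeric(0)
    sigma <- Inf
    repeat {
      m <- if (length(works) == 0)
        max(controller$min_inner, controller$batch)
      else min(controller$batch, controller$budget - length(works))
      res <- cpp_inner_work(system$code, system$params, system$beta,
                            system$masses,
                            .letter_codes[config$scheme$letters],
                            config$scheme$fractions, config$dt, config$gamma,
                            x0, v0, as.integer(T_steps), as.integer(m),
                            pfun = system$potential_fn,
                            gfun = system$gradient_fn)
      if (!all(res$stable))
        stop_instability(which(!res$stable)[1], "inner-loop protocol")
      works <- c(works, res$work)
      ew <- exp(-works)
      sigma <- sd(ew) / (mean(ew) * sqrt(length(works)))
      if (is.na(sigma)) sigma <- 0   # degenerate constant sample
      if (sigma <= controller$sigma_threshold ||
          length(works) >= controller$budget) break
    }
    list(work = works, sigma_inner = sigma,
         converged = sigma <= controller$sigma_threshold)
  })
}

#' Collect the jagged work array for the nested estimator
#'
#' Draws `n_outer` independent steady-state (or omega) starts and runs the
#' adaptive inner loop from each, producing the jagged array of work values
#' the nested Monte Carlo estimator consumes.
#'
#' @inheritParams sample_steady_state_start
#' @param n_outer number of outer-loop samples (>= 2).
#' @param T_steps protocol length; default [default_protocol_length()].
#' @param controller an [inner_loop_controller()].
#' @return object of class `jagged_work_samples`: list with `rows` (list of
#'   work vectors) and `row_meta` (data.frame: `inner_count`, `sigma_inner`,
#'   `converged`).
#' @export
collect_jagged_works <- function(system, config,
                                 mode = c("phase", "configuration"),
                                 n_outer = 200L, T_steps = NULL,
                                 decorrelation_steps = NULL,
                                 controller = inner_loop_controller(),
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_outer >= 2)
  if (is.null(T_steps)) T_steps <- default_protocol_length(config)
  with_seed(seed, {
    starts <- sample_steady_state_start(system, config, mode,
                                        decorrelation_steps, n = n_outer)
    rows <- vector("list", n_outer)
    meta <- data.frame(inner_count = integer(n_outer),
                       sigma_inner = numeric(n_outer),
                       converged = logical(n_outer))
    for (i in seq_len(n_outer)) {
      r <- collect_inner_work(system, config,
                              list(x = starts$x[i, ], v = starts$v[i, ]),
                              T_steps, controller)
      rows[[i]] <- r$work
      meta$inner_count[i] <- length(r$work)
      meta$sigma_inner[i] <- r$sigma_inner
      meta$converged[i] <- r$converged
    }
    jagged_work_samples(rows, meta,
                        meta_info = list(system = system$name,
                                         splitting = config$scheme$string,
                                         dt = config$dt,
                                         gamma = config$gamma,
                                         mode = mode, T = T_steps))
  })
}

#' Jagged work-sample container
#'
#' @param rows list of non-empty numeric vectors of finite reduced works;
#'   each row is one outer-loop sample.
#' @param row_meta optional per-row metadata data.frame.
#' @param meta_info optional configuration echo.
#' @return object of class `jagged_work_samples`.
#' @export
jagged_work_samples <- function(rows, row_meta = NULL, meta_info = NULL) {
  stopifnot(is.list(rows), length(rows) >= 1)
  for (r in rows) {
    if (length(r) == 0) stop("every row must be non-empty")
    if (!all(is.finite(r))) stop("all work values must be finite")
  }
  structure(list(rows = rows, row_meta = row_meta, meta = meta_info),
            class = "jagged_work_samples")
}

#' @export
print.jagged_work_samples <- function(x, ...) {
  counts <- lengths(x$rows)
  cat(sprintf(
    "<jagged_work_samples> %d outer rows, inner counts %d-%d (total %d)\n",
    length(x$rows), min(counts), max(counts), sum(counts)))
  invisible(x)
}

nested_point <- function(rows)
  mean(vapply(rows, function(w) log(mean(exp(-w))), numeric(1)))

# ln of the equally-weighted mean of per-row exponential averages: each
# outer (steady-state) draw contributes once, regardless of how many inner
# samples its adaptive loop used.  Pooling the raw works instead would
# length-weight the rows — and the adaptive inner counts correlate with the
# row's work distribution, which both biases the outer average and breaks
# the algebraic dominance over the nested estimate.
jensen_point <- function(rows) {
  log(mean(vapply(rows, function(w) mean(exp(-w)), numeric(1))))
}

#' Nested Monte Carlo KL estimate
#'
#' `(1/N) sum_i ln[ (1/M_i) sum_j e^{-w_ij} ]` over the jagged work array;
#' asymptotically exact as both loops grow, a finite-sample under-estimate
#' (the inner log of a mean is biased low, to leading order by
#' `sigma_inner^2 / 2M`).  The 95% CI comes from the two-level
#' [bootstrap_jagged()].
#'
#' @param jagged a [jagged_work_samples()] with >= 2 rows.
#' @param n_boot bootstrap resamples for the CI (default 100).
#' @param seed optional integer seed for the bootstrap.
#' @return a [kl_estimate()].
#' @export
nested_mc_kl <- function(jagged, n_boot = 100L, seed = NULL) {
  if (length(jagged$rows) < 2) stop("need >= 2 outer rows")
  value <- nested_point(jagged$rows)
  ci <- bootstrap_jagged(jagged, "nested", n_boot = n_boot, seed = seed)
  kl_estimate(value, ci[1], ci[2], estimator = "nested_mc",
              n = sum(lengths(jagged$rows)),
              meta = c(jagged$meta,
                       list(n_outer = length(jagged$rows),
                            bias_direction = "under-estimate")))
}

#' Jensen-inequality upper bound on the KL divergence
#'
#' `ln` of the mean exponentiated negative work over the collected samples
#' (each outer draw weighted equally), an upper bound by `<ln x> <= ln <x>`;
#' always >= the nested estimate on the same data, deterministically.
#' The CI comes from the same two-level [bootstrap_jagged()] as the nested
#' estimate: work values within a row share a start point, so a pooled
#' i.i.d. bootstrap would understate the uncertainty.
#'
#' @inheritParams nested_mc_kl
#' @return a [kl_estimate()].
#' @export
jensen_upper_bound <- function(jagged, n_boot = 100L, seed = NULL) {
  pooled <- unlist(jagged$rows, use.names = FALSE)
  if (length(pooled) < 1) stop("need at least one work value")
  value <- jensen_point(jagged$rows)
  ci <- if (length(jagged$rows) >= 2)
    bootstrap_jagged(jagged, "jensen", n_boot = n_boot, seed = seed)
  else c(value, value)
  kl_estimate(value, ci[1], ci[2], estimator = "jensen_upper_bound",
              n = length(pooled), meta = jagged$meta)
}

#' Two-level jagged bootstrap
#'
#' Resamples outer rows uniformly with replacement, then, within each
#' resampled row, the columns uniformly with replacement, recomputing the
#' statistic each time; returns the percentile 2.5/97.5 interval.
#'
#' @param jagged a [jagged_work_samples()].
#' @param statistic `"nested"` or `"jensen"`.
#' @param n_boot number of resamples (>= 2; default 100).
#' @param seed optional integer seed.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
bootstrap_jagged <- function(jagged, statistic = c("nested", "jensen"),
                             n_boot = 100L, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_boot >= 2)
  fn <- if (statistic == "nested") nested_point else jensen_point
  rows <- jagged$rows
  N <- length(rows)
  bs <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    picked <- rows[sample.int(N, N, replace = TRUE)]
    picked <- lapply(picked, function(w)
      w[sample.int(length(w), length(w), replace = TRUE)])
    fn(picked)
  }, numeric(1)))
  quantile(bs, c(0.025, 0.975), names = FALSE, type = 6)
}

# ---- histograms -----------------------------------------------------------

#' Histogram container
#'
#' @param masses numeric vector (1D) or matrix (2D) of non-negative bin
#'   masses; normalized to sum to 1.
#' @param edges list of per-dimension bin edge vectors (or a single numeric
#'   vector for 1D).
#' @return object of class `splitkl_histogram`.
#' @export
make_histogram <- function(masses, edges) {
  if (is.numeric(edges)) edges <- list(edges)
  dims <- if (is.matrix(masses)) dim(masses) else length(masses)
  if (length(edges) != length(dims))
    stop("edges must match the histogram dimensionality")
  for (k in seq_along(edges)) {
    if (length(edges[[k]]) != dims[k] + 1L)
      stop("edge vector ", k, " must have one more entry than bins")
    if (any(diff(edges[[k]]) <= 0))
      stop("edges must be strictly increasing")
  }
  if (any(masses < 0)) stop("negative bin mass")
  tot <- sum(masses)
  if (tot <= 0) stop("empty histogram")
  structure(list(masses = masses / tot, edges = edges),
            class = "splitkl_histogram")
}

#' @export
print.splitkl_histogram <- function(x, ...) {
  d <- if (is.matrix(x$masses)) paste(dim(x$masses), collapse = " x ")
       else length(x$masses)
  cat(sprintf("<splitkl_histogram> %s bins\n", d))
  invisible(x)
}

hist_masses <- function(h) {
  if (inherits(h, "splitkl_histogram")) h$masses
  else if (inherits(h, "density_grid_1d")) h$masses
  else h
}

hist_edges <- function(h) {
  if (inherits(h, "splitkl_histogram")) h$edges
  else if (inherits(h, "density_grid_1d")) list(h$edges)
  else NULL
}

#' Exact KL divergence between two histograms
#'
#' `sum_bins p ln(p / q)` with the convention `0 ln(0/q) = 0`.  Bin edges,
#' when carried by both inputs, must match; a bin with `p > 0` and `q = 0`
#' makes the divergence infinite and raises an error naming the offending
#' bins.
#'
#' @param sample_hist histogram of the sampled density (a
#'   [make_histogram()] object, a [equilibrium_density_1d()] grid, or a raw
#'   mass vector/matrix).
#' @param reference histogram of the reference density, same binning.
#' @return KL divergence in nats (non-negative).
#' @export
histogram_kl <- function(sample_hist, reference) {
  p <- hist_masses(sample_hist)
  q <- hist_masses(reference)
  ep <- hist_edges(sample_hist); eq <- hist_edges(reference)
  if (!is.null(ep) && !is.null(eq)) {
    if (length(ep) != length(eq) ||
        !all(mapply(function(a, b) isTRUE(all.equal(a, b)), ep, eq)))
      stop("sample and reference histograms have different bin edges")
  }
  if (length(p) != length(q)) stop("histograms have different shapes")
  p <- p / sum(p); q <- q / sum(q)
  bad <- which(p > 0 & q == 0)
  if (length(bad))
    stop("infinite divergence: sample mass where reference mass is zero ",
         "(bins ", paste(head(bad, 10), collapse = ", "), ")")
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Histogram edges from a trial run at the largest timestep
#'
#' Runs a trial trajectory at the sweep's largest timestep and returns
#' 100-bin (by default) edges spanning its bounding box, for use across all
#' conditions of a sweep so divergences are comparable.
#'
#' @param system a 1D [langevin_system()].
#' @param config an [integrator_config()] at the largest timestep.
#' @param n_steps trial-run length (default 1e4).
#' @param n_bins bins per dimension (default 100).
#' @param seed optional integer seed.
#' @return list with `x` and `v` edge vectors.
#' @export
histogram_edges_from_trial <- function(system, config, n_steps = 1e4,
                                       n_bins = 100L, seed = NULL) {
  if (system$dimension != 1L) stop("requires a 1D system")
  with_seed(seed, {
    x0 <- sample_equilibrium_positions(system, 1)
    v0 <- sample_velocities(system, 1)
    bb <- cpp_bounding_box(system$code, system$params, system$beta,
                           system$masses,
                           .letter_codes[config$scheme$letters],
                           config$scheme$fractions, config$dt, config$gamma,
                           x0, v0, as.integer(n_steps),
                           pfun = system$potential_fn,
                           gfun = system$gradient_fn)
    if (!bb$stable)
      stop_instability(bb$failed_step, "trial run for histogram edges")
    list(x = seq(bb$xmin[1], bb$xmax[1], length.out = n_bins + 1L),
         v = seq(bb$vmin[1], bb$vmax[1], length.out = n_bins + 1L))
  })
}

#' Empirical steady-state histogram of an integrator (1D)
#'
#' Runs one long trajectory, discards `n_burn` steps, and bins the cycle
#' endpoints on the supplied edges.  Phase mode returns the joint (x, v)
#' histogram; configuration mode its x-marginal.
#'
#' @inheritParams sample_steady_state_start
#' @param edges list with `x` and `v` edge vectors (see
#'   [histogram_edges_from_trial()]).
#' @param n_steps recorded steps (default 1e6).
#' @param n_burn burn-in steps (default 1e4).
#' @return a [make_histogram()] object (2D for phase, 1D for
#'   configuration), with attribute `n_out` counting out-of-box points.
#' @export
steady_state_histogram <- function(system, config, edges,
                                   mode = c("phase", "configuration"),
                                   n_steps = 1e6, n_burn = 1e4,
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (system$dimension != 1L) stop("requires a 1D system")
  with_seed(seed, {
    x0 <- sample_equilibrium_positions(system, 1)
    v0 <- sample_velocities(system, 1)
    res <- cpp_phase_histogram(system$code, system$params, system$beta,
                               system$masses,
                               .letter_codes[config$scheme$letters],
                               config$scheme$fractions, config$dt,
                               config$gamma, x0, v0,
                               as.integer(n_burn), as.integer(n_steps),
                               edges$x, edges$v,
                               pfun = system$potential_fn,
                               gfun = system$gradient_fn)
    if (!res$stable)
      stop_instability(res$failed_step, "steady-state histogram")
    h <- if (mode == "phase")
      make_histogram(res$counts, list(edges$x, edges$v))
    else
      make_histogram(rowSums(res$counts), list(edges$x))
    attr(h, "n_out") <- res$n_out
    h
  })
}

#' Quadrature equilibrium histogram on given edges (1D)
#'
#' Position bin masses by trapezoidal quadrature of `e^{-beta U}`; velocity
#' bin masses from the exact Maxwell-Boltzmann normal CDF.  Masses are
#' normalized over the supplied box (the same support as the empirical
#' histograms they are compared to).
#'
#' @param system a 1D [langevin_system()].
#' @param edges list with `x` and (for phase mode) `v` edge vectors.
#' @param mode `"phase"` or `"configuration"`.
#' @return a [make_histogram()] object.
#' @export
equilibrium_histogram <- function(system, edges,
                                  mode = c("phase", "configuration")) {
  mode <- match.arg(mode)
  dx <- equilibrium_density_1d(system, edges$x)
  if (mode == "configuration")
    return(make_histogram(dx$masses, list(edges$x)))
  sdv <- 1 / sqrt(system$beta * system$masses[1])
  pv <- diff(pnorm(edges$v, sd = sdv))
  make_histogram(outer(dx$masses, pv), list(edges$x, edges$v))
}
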