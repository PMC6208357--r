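# Experiment drivers: timestep sweeps, collision-rate sweeps, sandwich
# validation of the three KL estimators against each other (and against the
# exact histogram reference in 1D), and timestep stability scans.
# All drivers return plain data.frames that round-trip through
# write_results_csv()/read_results_csv().

#' Sweep configuration
#'
#' @param system a [langevin_system()] (or built-in system name).
#' @param splittings character vector of splitting strings.
#' @param dt_grid strictly increasing timesteps.
#' @param gamma_grid strictly increasing collision rates.
#' @param modes subset of `c("phase", "configuration")`.
#' @param estimator `"histogram"` (1D only; exact, with replicate-trajectory
#'   CIs) or `"near_eq"`.
#' @param n_steps steps per histogram trajectory (histogram estimator).
#' @param n_burn burn-in steps (histogram estimator).
#' @param n_reps replicate trajectories for histogram CIs.
#' @param n_samples protocol samples per condition (near_eq estimator).
#' @param seed integer seed.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(system, splittings, dt_grid, gamma_grid = 10,
                         modes = c("phase", "configuration"),
                         estimator = c("histogram", "near_eq"),
                         n_steps = 1e6, n_burn = 1e4, n_reps = 5L,
                         n_samples = 1e4, seed = 1L) {
  if (is.character(system)) system <- langevin_system(system)
  estimator <- match.arg(estimator)
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(length(dt_grid) >= 1, !is.unsorted(dt_grid, strictly = TRUE),
            length(gamma_grid) >= 1,
            !is.unsorted(gamma_grid, strictly = TRUE))
  structure(list(system = system, splittings = splittings,
                 dt_grid = dt_grid, gamma_grid = gamma_grid, modes = modes,
                 estimator = estimator, n_steps = n_steps, n_burn = n_burn,
                 n_reps = as.integer(n_reps), n_samples = n_samples,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

# Histogram KL with a CI from independent replicate trajectories.
histogram_kl_ci <- function(system, config, edges, mode, n_steps, n_burn,
                            n_reps, seed) {
  ref <- equilibrium_histogram(system, edges, mode)
  kls <- vapply(seq_len(n_reps), function(r) {
    h <- steady_state_histogram(system, config, edges, mode,
                                n_steps = n_steps, n_burn = n_burn,
                                seed = child_seed(seed, r))
    histogram_kl(h, ref)
  }, numeric(1))
  value <- mean(kls)
  se <- if (n_reps > 1) sd(kls) / sqrt(n_reps) else 0
  kl_estimate(value, value - 1.96 * se, value + 1.96 * se,
              estimator = paste0("histogram/", mode),
              n = n_reps * n_steps)
}

# One KL estimate for a single (splitting, dt, gamma, mode) condition.
condition_estimate <- function(cfg, splitting, dt, gamma, mode, edges,
                               seed) {
  config <- integrator_config(splitting, dt = dt, gamma = gamma)
  if (cfg$estimator == "histogram") {
    histogram_kl_ci(cfg$system, config, edges, mode,
                    n_steps = cfg$n_steps, n_burn = cfg$n_burn,
                    n_reps = cfg$n_reps, seed = seed)
  } else {
    samples <- run_protocol_samples(
      cfg$system, config,
      protocol_spec(mode = mode, n_samples = cfg$n_samples), seed = seed)
    estimate_kl_near_eq(samples)
  }
}

sweep_grid <- function(cfg, dt_values, gamma_values) {
  expand.grid(splitting = cfg$splittings, dt = dt_values,
              gamma = gamma_values, mode = cfg$modes,
              stringsAsFactors = FALSE)
}

run_sweep <- function(cfg, dt_values, gamma_values) {
  grid <- sweep_grid(cfg, dt_values, gamma_values)
  # shared histogram edges: union of trial-run bounding boxes across
  # splittings at the largest timestep where every splitting's trial run
  # stays finite (timesteps above that only yield instability-flagged rows)
  edges <- NULL
  if (cfg$estimator == "histogram") {
    for (dt_try in sort(dt_values, decreasing = TRUE)) {
      boxes <- tryCatch(
        lapply(seq_along(cfg$splittings), function(i)
          histogram_edges_from_trial(
            cfg$system,
            integrator_config(cfg$splittings[i], dt = dt_try,
                              gamma = max(gamma_values)),
            seed = child_seed(cfg$seed, 1000 + i))),
        splitkl_instability = function(e) NULL)
      if (!is.null(boxes)) break
    }
    if (!is.null(boxes)) {
      nb <- length(boxes[[1]]$x) - 1L
      edges <- list(
        x = seq(min(vapply(boxes, function(b) b$x[1], numeric(1))),
                max(vapply(boxes, function(b) tail(b$x, 1), numeric(1))),
                length.out = nb + 1L),
        v = seq(min(vapply(boxes, function(b) b$v[1], numeric(1))),
                max(vapply(boxes, function(b) tail(b$v, 1), numeric(1))),
                length.out = nb + 1L))
    }
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    est <- if (cfg$estimator == "histogram" && is.null(edges)) NULL
    else tryCatch(
      condition_estimate(cfg, g$splitting, g$dt, g$gamma, g$mode, edges,
                         seed = child_seed(cfg$seed, i)),
      splitkl_instability = function(e) e)
    if (inherits(est, "kl_estimate")) {
      data.frame(system = cfg$system$name, splitting = g$splitting,
                 dt = g$dt, gamma = g$gamma, mode = g$mode,
                 estimator = cfg$estimator, dkl = est$value,
                 ci_low = est$ci_low, ci_high = est$ci_high,
                 unstable = FALSE, seed = cfg$seed)
    } else {
      data.frame(system = cfg$system$name, splitting = g$splitting,
                 dt = g$dt, gamma = g$gamma, mode = g$mode,
                 estimator = cfg$estimator, dkl = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_,
                 unstable = TRUE, seed = cfg$seed)
    }
  })
  do.call(rbind, rows)
}

#' Timestep sweep
#'
#' One row per (splitting, dt, mode) at the config's first collision rate,
#' with the KL estimate and CI from the selected estimator.  Unstable
#' conditions are flagged, never dropped.
#'
#' @param cfg a [sweep_config()].
#' @return results data.frame.
#' @export
sweep_timesteps <- function(cfg) {
  run_sweep(cfg, cfg$dt_grid, cfg$gamma_grid[1])
}

#' Collision-rate sweep
#'
#' One row per (splitting, gamma, mode) at the config's first timestep.
#'
#' @param cfg a [sweep_config()].
#' @return results data.frame.
#' @export
sweep_collision_rates <- function(cfg) {
  run_sweep(cfg, cfg$dt_grid[1], cfg$gamma_grid)
}

#' Log-log scaling exponent of KL vs timestep
#'
#' Fits `ln(dkl) ~ ln(dt)` on the rows of a sweep table for one splitting
#' and mode; the slope estimates the order of the timestep-induced error.
#'
#' @param table a [sweep_timesteps()] result.
#' @param splitting,mode condition selectors.
#' @return the fitted slope.
#' @export
kl_scaling_exponent <- function(table, splitting, mode = "phase") {
  rows <- table[table$splitting == splitting & table$mode == mode &
                  !table$unstable & table$dkl > 0, ]
  if (nrow(rows) < 2) stop("need >= 2 positive, stable KL values")
  unname(coef(lm(log(rows$dkl) ~ log(rows$dt)))[2])
}

#' Sandwich validation of the three estimators (1D)
#'
#' Per condition, computes the nested Monte Carlo estimate (a likely
#' under-estimate), the near-equilibrium estimate, the Jensen upper bound
#' and the exact histogram reference, and checks the sandwich
#' `nested <= near-eq <= Jensen` within the 95% CIs, plus whether the
#' histogram truth lies inside the nested-to-Jensen bracket.
#'
#' All three estimators share one protocol length per condition, by default
#' [suggest_protocol_length()] (two relaxation times), which also sets the
#' steady-state decorrelation of the nested estimator's outer starts.
#'
#' @param cfg a [sweep_config()] (1D system; `n_samples` is used for the
#'   near-equilibrium estimate).
#' @param n_outer outer-loop samples for the nested estimator.
#' @param controller an [inner_loop_controller()].
#' @param T_steps protocol length override (default: suggested per
#'   condition).
#' @param hist_steps,hist_burn histogram reference trajectory lengths.
#' @return comparison data.frame with one row per (splitting, dt, mode).
#' @export
sandwich_validation <- function(cfg, n_outer = 200L,
                                controller = inner_loop_controller(),
                                T_steps = NULL,
                                hist_steps = 1e6, hist_burn = 1e4) {
  if (cfg$system$dimension != 1L)
    stop("sandwich validation needs a 1D system (histogram ground truth)")
  grid <- sweep_grid(cfg, cfg$dt_grid, cfg$gamma_grid[1])
  dt_max <- max(cfg$dt_grid)
  edges <- histogram_edges_from_trial(
    cfg$system,
    integrator_config(cfg$splittings[1], dt = dt_max,
                      gamma = cfg$gamma_grid[1]),
    seed = child_seed(cfg$seed, 999))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    config <- integrator_config(g$splitting, dt = g$dt, gamma = g$gamma)
    T_i <- if (is.null(T_steps)) suggest_protocol_length(cfg$system, config)
           else as.integer(T_steps)
    sd1 <- child_seed(cfg$seed, 4L * i)
    jag <- collect_jagged_works(cfg$system, config, mode = g$mode,
                                n_outer = n_outer, T_steps = T_i,
                                decorrelation_steps = T_i,
                                controller = controller, seed = sd1)
    nested <- nested_mc_kl(jag, seed = child_seed(cfg$seed, 4L * i + 1L))
    jensen <- jensen_upper_bound(jag,
                                 seed = child_seed(cfg$seed, 4L * i + 1L))
    neareq <- estimate_kl_near_eq(run_protocol_samples(
      cfg$system, config,
      protocol_spec(T_i, mode = g$mode, n_samples = cfg$n_samples),
      seed = child_seed(cfg$seed, 4L * i + 2L)))
    truth <- histogram_kl(
      steady_state_histogram(cfg$system, config, edges, g$mode,
                             n_steps = hist_steps, n_burn = hist_burn,
                             seed = child_seed(cfg$seed, 4L * i + 3L)),
      equilibrium_histogram(cfg$system, edges, g$mode))
    data.frame(
      system = cfg$system$name, splitting = g$splitting, dt = g$dt,
      gamma = g$gamma, mode = g$mode, T = T_i,
      nested = nested$value, nested_lo = nested$ci_low,
      nested_hi = nested$ci_high,
      neareq = neareq$value, neareq_lo = neareq$ci_low,
      neareq_hi = neareq$ci_high,
      jensen = jensen$value, jensen_lo = jensen$ci_low,
      jensen_hi = jensen$ci_high,
      hist_truth = truth,
      n_unconverged = sum(!jag$row_meta$converged),
      sandwiched = (nested$ci_low <= neareq$ci_high) &&
        (neareq$ci_low <= jensen$ci_high),
      truth_bracketed = (truth >= nested$ci_low) &&
        (truth <= jensen$ci_high),
      seed = cfg$seed)
  })
  do.call(rbind, rows)
}

#' Timestep stability scan
#'
#' A timestep is declared stable when ALL of `n_trajectories` independent
#' trajectories of `n_steps` integrator cycles from equilibrium starts stay
#' finite with `|x| < 1e6`.  Returns the largest stable grid point.
#'
#' @param system a [langevin_system()] (or built-in name).
#' @param splitting splitting string.
#' @param dt_grid increasing timesteps to probe.
#' @param gamma collision rate.
#' @param n_trajectories replicate trajectories per timestep (default 10).
#' @param n_steps cycles per trajectory (default 1e4).
#' @param seed integer seed.
#' @return list with `max_stable_dt` and the per-timestep `table`
#'   (`dt`, `n_unstable`, `stable`).
#' @export
stability_scan <- function(system, splitting, dt_grid, gamma = 10,
                           n_trajectories = 10L, n_steps = 1e4, seed = NULL) {
  if (is.character(system)) system <- langevin_system(system)
  stopifnot(!is.unsorted(dt_grid, strictly = TRUE))
  tab <- do.call(rbind, lapply(seq_along(dt_grid), function(i) {
    config <- integrator_config(splitting, dt = dt_grid[i], gamma = gamma)
    res <- with_seed(child_seed(seed, i) %||% NULL, {
      X0 <- as_matrix_nd(
        sample_equilibrium_positions(system, n_trajectories),
        system$dimension)
      V0 <- as_matrix_nd(sample_velocities(system, n_trajectories),
                         system$dimension)
      work_batch(system, config, X0, V0, n_steps)
    })
    data.frame(dt = dt_grid[i], n_unstable = sum(!res$stable),
               stable = all(res$stable))
  }))
  if (!any(tab$stable)) stop("no stable timestep on the supplied grid")
  list(max_stable_dt = max(tab$dt[tab$stable]), table = tab)
}
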