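fake_samples <- function(w1, w2) {
  s <- data.frame(w_first = w1, w_second = w2)
  class(s) <- c("protocol_samples", "data.frame")
  s
}

test_that("near-equilibrium estimator arithmetic", {
  s <- fake_samples(c(1, 1, 1), c(1, 1, 1))
  est <- estimate_kl_near_eq(s)
  expect_equal(est$value, 0)
  expect_equal(est$ci_high - est$ci_low, 0)
  # w_first = 2c, w_second = 0 -> estimate c
  est <- estimate_kl_near_eq(fake_samples(rep(0.8, 10), rep(0, 10)))
  expect_equal(est$value, 0.4)
  expect_error(estimate_kl_near_eq(fake_samples(1, 0)), "2")
})

test_that("kl_estimate enforces CI ordering", {
  e <- kl_estimate(0.5, 0.4, 0.6, "x", 10)
  expect_true(e$ci_low <= e$value && e$value <= e$ci_high)
  e <- kl_estimate(0.5, 0.6, 0.7, "x", 10)  # interval beside the point
  expect_true(e$ci_low <= e$value && e$value <= e$ci_high)
})

test_that("protocol sampling is reproducible and resets at the midpoint", {
  cfg <- integrator_config("OVRVO", dt = 0.5, gamma = 10)
  sp <- protocol_spec(3, "phase", 50)
  a <- run_protocol_samples(dw, cfg, sp, seed = 8)
  b <- run_protocol_samples(dw, cfg, sp, seed = 8)
  expect_identical(a$w_first, b$w_first)
  expect_identical(a$w_second, b$w_second)
  one <- run_protocol_sample(dw, cfg, sp, seed = 8)
  two <- run_protocol_sample(dw, cfg, sp, seed = 8)
  expect_identical(one, two)
  pair <- run_protocol_samples(dw, cfg, protocol_spec(3, "phase", 2),
                               seed = 8)
  expect_identical(one$w_first, pair$w_first[1])
  expect_identical(one$w_second, pair$w_second[1])
})

test_that("both work averages vanish at tiny timestep", {
  cfg <- integrator_config("OVRVO", dt = 0.01, gamma = 10)
  s <- run_protocol_samples(dw, cfg, protocol_spec(40, "phase", 4000),
                            seed = 2)
  expect_lt(abs(mean(s$w_first)), 4 * sd(s$w_first) / sqrt(nrow(s)) + 1e-4)
  expect_lt(abs(mean(s$w_second)), 4 * sd(s$w_second) / sqrt(nrow(s)) + 1e-4)
  est <- estimate_kl_near_eq(s)
  expect_lt(abs(est$value), 1e-3)
})

test_that("at high friction the midpoint velocity redraw is a no-op in
          distribution for splittings ending in O", {
  # OVRVO at gamma*tau >> 1: the trailing O substep leaves the midpoint
  # velocity an exact Maxwell-Boltzmann draw, so phase and configuration
  # modes coincide in distribution
  cfg <- integrator_config("OVRVO", dt = 0.4, gamma = 1000)
  T_steps <- 10
  ph <- estimate_kl_near_eq(run_protocol_samples(
    dw, cfg, protocol_spec(T_steps, "phase", 2e4), seed = 3))
  cf <- estimate_kl_near_eq(run_protocol_samples(
    dw, cfg, protocol_spec(T_steps, "configuration", 2e4), seed = 4))
  se_p <- (ph$ci_high - ph$ci_low) / (2 * 1.96)
  se_c <- (cf$ci_high - cf$ci_low) / (2 * 1.96)
  expect_lt(abs(ph$value - cf$value), 3 * sqrt(se_p^2 + se_c^2))
})

test_that("default and suggested protocol lengths reflect the relaxations", {
  cfg <- integrator_config("OVRVO", dt = 0.5, gamma = 10)
  expect_equal(default_protocol_length(cfg), 1L)  # ceil((2/10)/0.5)
  expect_equal(default_protocol_length(integrator_config("OVRVO", 0.05, 10)),
               4L)
  # configurational relaxation (gamma m / <U''> ~ 2.4 time units) dominates
  expect_gt(relaxation_time(dw, cfg), 2)
  expect_lt(relaxation_time(dw, cfg), 3)
  expect_gte(suggest_protocol_length(dw, cfg), 10L)
})

test_that("near-equilibrium estimate approaches the exact histogram KL", {
  cfg <- integrator_config("OVRVO", dt = 0.5, gamma = 10)
  T_steps <- suggest_protocol_length(dw, cfg)
  est <- estimate_kl_near_eq(run_protocol_samples(
    dw, cfg, protocol_spec(T_steps, "phase", 5e4), seed = 5))
  edges <- histogram_edges_from_trial(
    dw, integrator_config("OVRVO", 0.6, 10), seed = 6)
  truth <- histogram_kl(
    steady_state_histogram(dw, cfg, edges, "phase", n_steps = 2e6,
                           seed = 7),
    equilibrium_histogram(dw, edges, "phase"))
  se <- (est$ci_high - est$ci_low) / (2 * 1.96)
  # agreement to the resolution the estimator is designed for (~0.01 nats)
  expect_lt(abs(est$value - truth), 0.01 + 2 * se)
})

test_that("protocol-length concordance check flags under-length protocols", {
  cfg <- integrator_config("OVRVO", dt = 0.01, gamma = 10)
  chk <- check_protocol_length(dw, cfg, protocol_spec(20, "phase", 2000),
                               seed = 9)
  # tiny dt: concordant, or both already zero to the 0.01-nat resolution
  expect_true(chk$concordant || abs(chk$difference) < 0.01)
  expect_lt(abs(chk$estimate_T$value), 1e-3)
  expect_lt(abs(chk$estimate_2T$value), 1e-3)
  # T = 1 step at a large timestep under-reaches the steady state
  cfg6 <- integrator_config("OVRVO", dt = 0.6, gamma = 10)
  chk1 <- check_protocol_length(dw, cfg6, protocol_spec(1, "phase", 5e4),
                                seed = 10)
  expect_false(chk1$concordant)
  # a protocol spanning the configurational relaxation is concordant
  Tok <- suggest_protocol_length(dw, cfg6)
  chk2 <- check_protocol_length(dw, cfg6, protocol_spec(Tok, "phase", 5e4),
                                seed = 11)
  # concordant, or the drift is below the estimator's target resolution
  expect_true(chk2$concordant || abs(chk2$difference) < 0.01)
})

test_that("configuration-marginal estimate is bounded by the phase estimate", {
  for (split in c("OVRVO", "VRORV")) {
    cfg <- integrator_config(split, dt = 0.5, gamma = 10)
    T_steps <- suggest_protocol_length(dw, cfg)
    ph <- estimate_kl_near_eq(run_protocol_samples(
      dw, cfg, protocol_spec(T_steps, "phase", 2e4), seed = 12))
    cf <- estimate_kl_near_eq(run_protocol_samples(
      dw, cfg, protocol_spec(T_steps, "configuration", 2e4), seed = 13))
    se_p <- (ph$ci_high - ph$ci_low) / (2 * 1.96)
    se_c <- (cf$ci_high - cf$ci_low) / (2 * 1.96)
    expect_lt(cf$value, ph$value + 2 * sqrt(se_p^2 + se_c^2))
  }
})

test_that("phase-space error scales as a high power of the timestep", {
  dts <- c(0.3, 0.4, 0.5, 0.6)
  kl <- vapply(seq_along(dts), function(i) {
    cfg <- integrator_config("OVRVO", dt = dts[i], gamma = 10)
    estimate_kl_near_eq(run_protocol_samples(
      dw, cfg,
      protocol_spec(suggest_protocol_length(dw, cfg), "phase", 1e5),
      seed = 20 + i))$value
  }, numeric(1))
  expect_true(all(kl > 0))
  slope <- unname(coef(lm(log(kl) ~ log(dts)))[2])
  expect_gt(slope, 3)
  expect_lt(slope, 5)
})

test_that("VRORV shows the superconvergent configuration marginal", {
  T6 <- function(s) {
    cfg <- integrator_config(s, dt = 0.6, gamma = 10)
    estimate_kl_near_eq(run_protocol_samples(
      dw, cfg,
      protocol_spec(suggest_protocol_length(dw, cfg), "configuration", 2e4),
      seed = 30))
  }
  vrorv <- T6("VRORV"); ovrvo <- T6("OVRVO")
  expect_lt(vrorv$value, ovrvo$value)
  expect_lt(vrorv$ci_high, ovrvo$ci_low)   # the gap exceeds the CIs
})
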