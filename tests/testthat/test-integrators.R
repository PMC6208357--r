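test_that("splitting strings parse to the published substep sequences", {
  s <- parse_splitting("OVRVO")
  expect_equal(s$letters, c("O", "V", "R", "V", "O"))
  expect_equal(s$fractions, c(1/2, 1/2, 1, 1/2, 1/2))
  s <- parse_splitting("VRORV")
  expect_equal(s$letters, c("V", "R", "O", "R", "V"))
  expect_equal(s$fractions, c(1/2, 1/2, 1, 1/2, 1/2))
  s <- parse_splitting("R")
  expect_equal(s$letters, "R")
  expect_equal(s$fractions, 1)
  expect_equal(parse_splitting("ovrvo")$string, "OVRVO")
})

test_that("per-letter time fractions always sum to one", {
  for (spec in c("OVRVO", "VRORV", "RVOVR", "ORVRO", "OVRVRVO", "VROOORV")) {
    s <- parse_splitting(spec)
    for (L in unique(s$letters)) {
      expect_equal(sum(s$fractions[s$letters == L]), 1)
      # equal occurrences receive equal fractions
      expect_equal(length(unique(s$fractions[s$letters == L])), 1L)
    }
  }
})

test_that("illegal and non-palindromic splittings are rejected", {
  expect_error(parse_splitting("OVXVO"), "illegal")
  expect_error(parse_splitting("OVRV"), "palindrom")
  expect_error(parse_splitting("RVO"), "palindrom")
  expect_error(parse_splitting(""), "nzchar")
})

test_that("substeps implement the published update rules", {
  r <- substep_R(qt, x = 0, v = 1, tau = 0.5)
  expect_equal(r$x, 0.5)
  expect_equal(r$v, 1)
  expect_equal(substep_R(qt, 0.3, -2, 0), list(x = 0.3, v = -2))
  # V kick: grad U = 4 x^3 -> v' = v - 0.4 at x = 1, m = 1, tau = 0.1
  v <- substep_V(qt, x = 1, v = 0.25, tau = 0.1)
  expect_equal(v$v, 0.25 - 0.4)
  expect_equal(v$x, 1)
  expect_equal(substep_V(qt, 0, 0.25, 0.1)$v, 0.25)  # zero force at minimum
  # O with a = 1/2 (tau = ln 2 / gamma), beta m = 1, xi = 0
  o <- substep_O(qt, x = 0, v = 1, tau = log(2), gamma = 1, xi = 0)
  expect_equal(o$v, 0.5)
  expect_equal(o$heat, 0.5 * 0.5^2 - 0.5)            # t(0.5) - t(1) = -0.375
  # gamma = 0: no coupling
  o0 <- substep_O(qt, 0, 1, tau = 1, gamma = 0, xi = 1.7)
  expect_equal(o0$v, 1)
  expect_equal(o0$heat, 0)
  # full-randomization limit: a = 0, v' = (beta m)^(-1/2) xi
  oinf <- substep_O(dw, 0, 5, tau = 1e6, gamma = 10, xi = 1.3)
  expect_equal(oinf$v, 1.3 / sqrt(10))
})

test_that("ledger shadow work equals the explicit energy bookkeeping", {
  # 1000 random single OVRVO cycles: w must equal the four-term expansion
  # [u(x5)-u(x0)] + [t(v5)-t(v0)] - [t(v1)-t(v0)] - [t(v5)-t(v4)]
  cfg <- integrator_config("OVRVO", dt = 0.4, gamma = 10)
  set.seed(11)
  for (rep in 1:1000) {
    x0 <- runif(1, -1.2, 1.2); v0 <- rnorm(1, sd = sqrt(0.1))
    run <- run_steps(dw, cfg, x0, v0, n_steps = 1, record_substeps = TRUE)
    w_ledger <- shadow_work(run$ledger)
    X <- run$states$x[, 1]; V <- run$states$v[, 1]
    u <- function(x) potential_energy(dw, x)
    tk <- function(v) kinetic_energy(dw, v)
    w64 <- (u(X[6]) - u(X[1])) + (tk(V[6]) - tk(V[1])) -
      (tk(V[2]) - tk(V[1])) - (tk(V[6]) - tk(V[5]))
    expect_close(w_ledger, w64, 1e-12)
  }
})

test_that("generic substep bookkeeping matches the ledger for all splittings", {
  set.seed(12)
  for (spec in c("VRORV", "RVOVR", "ORVRO", "OVRVRVO")) {
    cfg <- integrator_config(spec, dt = 0.3, gamma = 10)
    for (rep in 1:25) {
      x0 <- runif(1, -1.2, 1.2); v0 <- rnorm(1, sd = sqrt(0.1))
      run <- run_steps(dw, cfg, x0, v0, n_steps = 1,
                       record_substeps = TRUE)
      expect_close(shadow_work(run$ledger),
                   bookkeeping_work(dw, run, parse_splitting(spec)$letters),
                   1e-12)
    }
  }
})

test_that("gamma = 0 gives zero heat and w = delta_h", {
  cfg <- integrator_config("OVRVO", dt = 0.1, gamma = 0)
  run <- run_steps(dw, cfg, 0.5, -0.3, 200, seed = 1)
  expect_identical(run$ledger$delta_q, 0)
  expect_identical(run$ledger$shadow_work, run$ledger$delta_h)
})

test_that("work ledger arithmetic and zero-step runs", {
  led <- work_ledger(1.0, 0.3)
  expect_equal(shadow_work(led), 0.7)
  expect_equal(shadow_work(work_ledger(0.4, 0.4)), 0)
  run0 <- run_steps(dw, integrator_config("OVRVO", 0.5, 10), 0.2, 0.1, 0)
  expect_equal(run0$ledger$delta_h, 0)
  expect_equal(run0$ledger$delta_q, 0)
  expect_equal(run0$x, 0.2)
  expect_equal(run0$v, 0.1)
})

test_that("velocity Verlet (VRV, gamma = 0) is time-reversible", {
  cfg <- integrator_config("VRV", dt = 0.1, gamma = 0)
  run <- run_steps(dw, cfg, 0.4, -0.2, 10)
  back <- run_steps(dw, cfg, run$x, -run$v, 10)
  expect_equal(back$x, 0.4, tolerance = 1e-10)
  expect_equal(back$v, 0.2, tolerance = 1e-10)
})

test_that("trajectories are bitwise reproducible given a seed", {
  cfg <- integrator_config("VRORV", dt = 0.5, gamma = 10)
  a <- run_steps(dw, cfg, 0.1, 0.2, 500, seed = 99)
  b <- run_steps(dw, cfg, 0.1, 0.2, 500, seed = 99)
  expect_identical(a$x, b$x)
  expect_identical(a$ledger$shadow_work, b$ledger$shadow_work)
  c <- run_steps(dw, cfg, 0.1, 0.2, 500, seed = 100)
  expect_false(identical(a$x, c$x))
})

test_that("double-well trajectories at dt = 0.1 stay finite for 1e6 steps", {
  cfg <- integrator_config("OVRVO", dt = 0.1, gamma = 10)
  run <- run_steps(dw, cfg, -0.4, 0, 1e6, seed = 4)
  expect_true(all(is.finite(c(run$x, run$v))))
})

test_that("instability raises a classed error carrying the step index", {
  cfg <- integrator_config("OVRVO", dt = 5, gamma = 10)
  err <- tryCatch(run_steps(dw, cfg, 1, 1, 1000, seed = 1),
                  splitkl_instability = function(e) e)
  expect_s3_class(err, "splitkl_instability")
  expect_true(is.numeric(err$step) && err$step >= 1)
})

test_that("integrator configs validate and build from list blocks", {
  expect_error(integrator_config("OVRVO", dt = -0.1, gamma = 10))
  expect_error(integrator_config("OVRVO", dt = 0.1, gamma = -1))
  cfg <- config_from_list(list(splitting = "VRORV", dt = 0.25, gamma = 2))
  expect_equal(cfg$scheme$string, "VRORV")
  expect_equal(cfg$dt, 0.25)
})
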