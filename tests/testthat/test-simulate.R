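test_that("single cell fed by the reservoir follows 1 - exp(-kt)", {
  k <- 12.5
  sys <- new_compartment_system(
    A = matrix(-k), b = k, volumes = 1e-6, kinds = "ECF", phase = "filling",
    sym_weights = 1)
  ts <- seq(0.05, 1, length.out = 10)
  exact <- 1 - exp(-k * ts)
  for (m in c("stiff", "rk", "expm")) {
    traj <- run_filling(sys, solver_settings(method = m), times = ts)
    got <- traj$states[-1, 1]
    expect_lt(max(abs(got - exact) / exact), 1e-6, label = paste("method", m))
  }
})

test_that("well-mixed compartment with a sink decays exponentially", {
  toy <- single_sink(Q = 1.96e-5, V = 2.6e-6, c0 = 3)
  ts <- seq(0, 1.2, by = 0.1)
  traj <- run_voiding(toy$system, initial = toy$initial, times = ts)
  exact <- toy$closed_form(ts)
  expect_lt(max(abs(traj$states[, 1] - exact) / exact), 1e-6)
})

test_that("equilibrium is a fixed point of the zero-clearance washout", {
  g <- small_fascicle()
  p <- anesthetic_params("lidocaine", "physiological")
  sys <- build_system(g, p, capillary_params(open_fraction = 0),
                      phase = "voiding")
  traj <- run_voiding(sys, t_end = 100, times = seq(0, 100, by = 10))
  drift <- max(abs(sweep(traj$states, 2, traj$states[1, ])))
  expect_lt(drift / max(traj$states[1, ]), 1e-8)
  # and duration is undefined: the criterion is never met
  expect_true(is.na(duration_of_action(traj)))
})

test_that("integrate_oracle is the identity at t = 0 and refuses large systems", {
  toy <- two_compartment_exchange(2e-3, 5e-4, 1e-6, 3e-6)
  expect_identical(integrate_oracle(toy$system, 0, c(1, 0)), c(1, 0))
  big <- chain_1d(501, 700, 2)
  expect_error(integrate_oracle(big$system, 1, numeric(501)), "n <= 500")
})

test_that("integrators agree with the dense matrix-exponential oracle", {
  toy <- chain_1d(12, 749, 1.874)
  ts <- c(0, 0.001, 0.005, 0.02)
  for (m in c("stiff", "rk", "expm")) {
    # hop rates are ~430/s, so the explicit path needs a small step here
    st <- if (m == "rk") solver_settings(m, max_step = 1e-5) else solver_settings(m)
    traj <- run_filling(toy$system, st, times = ts)
    for (j in seq_along(ts)) {
      ref <- integrate_oracle(toy$system, ts[j], numeric(12))
      expect_lt(max(abs(traj$states[j, ] - ref)), 1e-5 * max(ref, 1e-6),
                label = sprintf("method %s, t = %g", m, ts[j]))
    }
  }
})

test_that("independent subsystems integrate the same jointly and separately", {
  k1 <- 3; k2 <- 40
  joint <- new_compartment_system(
    A = diag(c(-k1, -k2)), b = c(k1, k2), volumes = c(1e-6, 1e-6),
    kinds = c("ECF", "ECF"), phase = "filling", sym_weights = c(1, 1))
  sep1 <- new_compartment_system(matrix(-k1), k1, 1e-6, "ECF", "filling",
                                 sym_weights = 1)
  sep2 <- new_compartment_system(matrix(-k2), k2, 1e-6, "ECF", "filling",
                                 sym_weights = 1)
  ts <- c(0, 0.01, 0.1, 0.5)
  j <- run_filling(joint, times = ts)$states
  s1 <- run_filling(sep1, times = ts)$states
  s2 <- run_filling(sep2, times = ts)$states
  expect_equal(j, cbind(s1, s2), tolerance = 1e-6)
})

test_that("solver paths agree on toy systems", {
  toy <- two_compartment_exchange(9.147e-3, 2.152e-4, 1e-6, 4.5e-6,
                                  initial = c(1, 0))
  ts <- seq(0, 0.02, length.out = 21)
  ref <- run_voiding(toy$system, solver_settings("expm"),
                     initial = c(1, 0), times = ts)$states
  for (m in c("stiff", "rk")) {
    # exchange rates reach ~9000/s: the explicit path needs a stable step
    st <- if (m == "rk") solver_settings(m, max_step = 1e-5) else solver_settings(m)
    got <- run_voiding(toy$system, st, initial = c(1, 0), times = ts)$states
    expect_lt(max(abs(got - ref)) / max(ref), 1e-4, label = m)
  }
})

test_that("states stay nonnegative within solver tolerance", {
  g <- small_fascicle()
  p <- anesthetic_params("bupivacaine", "physiological")
  settings <- solver_settings()
  trajf <- run_filling(build_system(g, p, phase = "filling"), settings,
                       t_end = 5)
  expect_gt(min(trajf$states), -10 * settings$abs_tol)
  trajv <- run_voiding(build_system(g, p, phase = "voiding"), settings,
                       t_end = 200, times = seq(0, 200, by = 5))
  expect_gt(min(trajv$states), -10 * settings$abs_tol)
})

test_that("washout mass loss equals the integrated capillary clearance", {
  g <- small_fascicle()
  p <- anesthetic_params("lidocaine", "physiological")
  sys <- build_system(g, p, phase = "voiding")
  # fine sampling: the capillary cells relax fast at the start of washout,
  # and the trapezoid integral has to resolve that transient
  traj <- run_voiding(sys, t_end = 20, times = seq(0, 20, by = 0.002))
  mb <- mass_balance(traj)
  lost <- mb$mass[1] - mb$mass[nrow(mb)]
  dt <- diff(mb$time)
  cleared <- sum((utils::head(mb$clearance_rate, -1) +
                  utils::tail(mb$clearance_rate, -1)) / 2 * dt)
  expect_equal(lost, cleared, tolerance = 1e-4)
})

test_that("filling auto-detects steady state when no horizon is given", {
  g <- small_fascicle()
  p <- anesthetic_params("lidocaine", "acidosis")
  sys <- build_system(g, p, phase = "filling", clearance_in_filling = FALSE)
  traj <- run_filling(sys)
  y_end <- traj$states[nrow(traj$states), ]
  dcdt <- as.vector(sys$A %*% y_end + sys$b)
  expect_lt(max(abs(dcdt)), 1e-6 * max(y_end))
  expect_equal(y_end, equilibrium_state(sys), tolerance = 1e-4)
})

test_that("explicit method enforces the 1 ms step bound", {
  expect_error(solver_settings("rk", max_step = 0.002), "0.001")
  expect_silent(solver_settings("rk", max_step = 0.001))
})
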