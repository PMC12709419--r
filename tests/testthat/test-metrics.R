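test_that("onset is zero when the initial state already exceeds threshold", {
  tr <- fake_trajectory(times = c(0, 1, 2),
                        states = matrix(0.9, 3, 4),
                        kinds = rep("FIBER", 4), phase = "filling")
  expect_identical(onset_time(tr, reference = "external"), 0)
})

test_that("fraction series and mean handle trivial states", {
  tr0 <- fake_trajectory(times = 0:3, states = matrix(0, 4, 5),
                         kinds = c("ECF", rep("FIBER", 4)), phase = "filling")
  expect_true(all(fraction_above(tr0, 0.5)$fraction == 0))
  tru <- fake_trajectory(times = 0:3, states = matrix(5, 4, 5),
                         kinds = c("ECF", rep("FIBER", 4)), phase = "voiding")
  expect_true(all(mean_fiber_concentration(tru)$mean_concentration == 5))
  expect_error(fraction_above(tr0, c(0.5, 0.5)), "4 fiber")
})

test_that("phase mismatches are rejected", {
  trf <- fake_trajectory(0:2, matrix(1, 3, 2), c("FIBER", "ECF"), "filling")
  trv <- fake_trajectory(0:2, matrix(1, 3, 2), c("FIBER", "ECF"), "voiding")
  expect_error(onset_time(trv), "filling")
  expect_error(duration_of_action(trf), "voiding")
  # voiding must start from the stated equilibrium
  expect_error(duration_of_action(trv, initial_equilibrium = c(9, 9)),
               "initial equilibrium")
})

test_that("interpolated crossing lies within one sample of the discrete one", {
  toy <- chain_1d(10, 749, 1.874)
  sys <- toy$system
  sys$kinds <- rep(c("ECF", "FIBER"), 5)  # kinds only affect metrics
  dt <- 0.005
  traj <- run_filling(sys, times = seq(0, 0.6, by = dt))
  on <- onset_time(traj, reference = "external")
  fr <- fraction_above(traj, 0.5)
  discrete <- traj$times[which(fr$fraction > 0.5)[1]]
  expect_true(on <= discrete && on >= discrete - dt)
})

test_that("onset decreases monotonically with the diffusion coefficient", {
  onset_for <- function(D) {
    toy <- chain_1d(14, D, 1.874)
    sys <- toy$system
    sys$kinds <- rep(c("ECF", "FIBER"), 7)
    traj <- run_filling(sys, times = seq(0, 2, by = 0.002))
    onset_time(traj, reference = "external")
  }
  ons <- vapply(c(300, 749, 1500), onset_for, numeric(1))
  expect_false(anyNA(ons))
  expect_true(all(diff(ons) < 0))
})

test_that("onset and duration are invariant under relabeling and rescaling", {
  toy <- chain_1d(10, 749, 1.874)
  sys <- toy$system
  sys$kinds <- rep(c("ECF", "FIBER"), 5)
  traj <- run_filling(sys, times = seq(0, 0.6, by = 0.005))
  on <- onset_time(traj, reference = "external")

  perm <- c(3, 1, 2, 7, 10, 4, 5, 9, 6, 8)
  traj_p <- traj
  traj_p$states <- traj$states[, perm]
  traj_p$kinds <- traj$kinds[perm]
  traj_p$equilibrium <- traj$equilibrium[perm]
  expect_identical(onset_time(traj_p, reference = "external"), on)

  # uniform rescaling of concentrations together with thresholds
  traj_s <- traj
  traj_s$states <- traj$states * 7
  expect_identical(onset_time(traj_s, reference = "external",
                              threshold = 0.5 * 7), on)
})

test_that("washout half-time tracks the mean-concentration half-time", {
  res <- reference_scenario("lidocaine", "physiological")
  mv <- res$metrics$voiding
  dur <- mv$duration
  ms <- mv$mean_fiber_series
  half_mean <- crossing_time(ms$time, -ms$mean_concentration,
                             -0.5 * ms$mean_concentration[1])
  expect_lt(abs(dur - half_mean) / dur, 0.10)
})

test_that("metric summaries tidy into the documented shapes", {
  res <- reference_scenario("lidocaine", "physiological")
  gl <- glance(res$metrics$filling)
  expect_identical(gl$phase, "filling")
  expect_identical(gl$drug, "lidocaine")
  td <- tidy(res$metrics$voiding)
  expect_setequal(unique(td$series), c("fraction_above", "mean_fiber"))
  expect_true(all(td$value[td$series == "fraction_above"] >= 0 &
                  td$value[td$series == "fraction_above"] <= 1))
})

test_that("filling fraction series is non-decreasing from the zero state", {
  res <- reference_scenario("lidocaine", "physiological")
  fr <- res$metrics$filling$fraction_series$fraction
  expect_true(all(diff(fr) > -1e-12))
  mean_f <- res$metrics$filling$mean_fiber_series$mean_concentration
  expect_true(all(diff(mean_f) > -1e-9 * max(mean_f)))
})
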