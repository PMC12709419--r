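test_that("two-cell aqueous toy assembles the minimal exchange matrix", {
  g2 <- mini_fascicle(c("ECF", "ECF"), pitch = 2)
  p <- anesthetic_params("lidocaine", "physiological")
  sys <- build_system(g2, p, capillary_params(open_fraction = 0),
                      phase = "voiding", edge_rate_convention = "per_edge")
  k <- 2 * p$D / g2$pitch^2
  expect_equal(as.matrix(sys$A), rbind(c(-k, k), c(k, -k)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(sys$b, c(0, 0))
})

test_that("filling source sits exactly on the aqueous boundary ring", {
  g <- default_fascicle()
  p <- anesthetic_params("lidocaine", "physiological")
  sys <- build_system(g, p, phase = "filling")
  ring <- boundary_ring(g)
  aqueous_ring <- ring[g$compartments$kind[ring] != "FIBER"]
  expect_identical(sort(which(sys$b != 0)), sort(aqueous_ring))
  # voiding has no source anywhere
  sysv <- build_system(g, p, phase = "voiding")
  expect_true(all(sysv$b == 0))
  expect_error(new_compartment_system(matrix(-1), b = 1, volumes = 1,
                                      kinds = "ECF", phase = "voiding"),
               "zero-flux")
})

test_that("exchange conserves volume-weighted mass exactly", {
  g <- default_fascicle()
  p <- anesthetic_params("bupivacaine", "acidosis")
  sys <- build_system(g, p, capillary_params(open_fraction = 0),
                      phase = "voiding")
  V <- sys$volumes
  set.seed(42)
  for (i in 1:5) {
    c0 <- runif(sys$n, 0, 10)
    flux <- V * as.vector(sys$A %*% c0)
    scale <- sum(pmax(flux, 0))  # total exchanged mass rate
    expect_lt(abs(sum(flux)) / scale, 1e-12)
  }
})

test_that("sign structure of the rate matrix is admissible", {
  g <- small_fascicle()
  p <- anesthetic_params("lidocaine", "acidosis")
  sys <- build_system(g, p, phase = "filling")
  A <- as.matrix(sys$A)
  expect_true(all(diag(A) <= 0))
  diag(A) <- 0
  expect_true(all(A >= 0))
})

test_that("analytic equilibrium is a fixed point of the clearance-free system", {
  g <- default_fascicle()
  for (drug in c("lidocaine", "bupivacaine")) {
    for (cond in c("physiological", "acidosis")) {
      p <- anesthetic_params(drug, cond)
      sys <- build_system(g, p, phase = "filling", clearance_in_filling = FALSE)
      ceq <- equilibrium_state(sys)
      resid <- max(abs(as.vector(sys$A %*% ceq + sys$b)))
      scale <- max(abs(sys$A)) * max(ceq)
      expect_lt(resid, 1e-9 * scale)
      # fiber level matches the membrane conductance ratio to 4 s.f.
      expect_equal(max(ceq), equilibrium_ratio(p), tolerance = 1e-4)
      expect_equal(min(ceq), 1)
    }
  }
})

test_that("fiber edges satisfy detailed balance at the conductance ratio", {
  g <- small_fascicle()
  p <- anesthetic_params("bupivacaine", "physiological")
  sys <- build_system(g, p, phase = "voiding")
  A <- as.matrix(sys$A)
  V <- sys$volumes
  fib <- which(sys$kinds == "FIBER")
  ecf <- which(sys$kinds != "FIBER")
  found <- 0L
  for (N in fib) for (E in ecf) {
    if (A[N, E] > 0) {
      found <- found + 1L
      expect_equal((A[N, E] * V[N]) / (A[E, N] * V[E]),
                   equilibrium_ratio(p), tolerance = 1e-4)
    }
  }
  expect_gt(found, 0L)
})

test_that("relabeling compartments permutes trajectories consistently", {
  g <- small_fascicle()
  p <- anesthetic_params("lidocaine", "physiological")
  sys <- build_system(g, p, phase = "filling")
  set.seed(7)
  perm <- sample(sys$n)
  P <- Matrix::sparseMatrix(i = seq_len(sys$n), j = perm, x = 1)
  sys_p <- new_compartment_system(
    A = P %*% sys$A %*% Matrix::t(P), b = as.vector(P %*% sys$b),
    volumes = sys$volumes[perm], kinds = sys$kinds[perm], phase = "filling",
    equilibrium = sys$equilibrium[perm], sym_weights = sys$sym_weights[perm])
  t1 <- run_filling(sys, t_end = 2, times = c(0, 0.5, 1, 2))
  t2 <- run_filling(sys_p, t_end = 2, times = c(0, 0.5, 1, 2))
  # unpermute: column i of t2 corresponds to original compartment perm[i]
  expect_equal(t1$states, t2$states[, order(perm)], tolerance = 1e-8)
})

test_that("clamped-boundary variant pins rim cells at unit concentration", {
  g <- small_fascicle()
  p <- anesthetic_params("lidocaine", "physiological")
  sys <- build_system(g, p, phase = "filling", boundary = "clamp")
  expect_gt(length(sys$clamp_ids), 0)
  traj <- run_filling(sys, t_end = 1, times = c(0, 0.5, 1))
  expect_true(all(traj$states[, sys$clamp_ids] == 1))
  expect_true(all(traj$states[-1, ] > 0))
})

test_that("system export writes a readable sparse matrix and sidecar", {
  g <- small_fascicle()
  sys <- build_system(g, anesthetic_params("lidocaine", "physiological"),
                      phase = "voiding")
  dir <- withr::local_tempdir()
  export_system(sys, dir)
  M <- Matrix::readMM(file.path(dir, "system.mtx"))
  expect_equal(dim(M), c(sys$n, sys$n))
  side <- jsonlite::fromJSON(file.path(dir, "system.json"))
  expect_identical(side$phase, "voiding")
  expect_equal(side$volumes, sys$volumes, tolerance = 1e-12)
})
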