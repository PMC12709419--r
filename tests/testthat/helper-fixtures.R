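# Shared lazily-computed fixtures. test_dir() runs all test files in one
# process, so expensive objects (the full fascicle, the reference scenario
# runs) are built once and reused.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_fascicle <- function() cached("fascicle_140", hex_fascicle())

small_fascicle <- function() {
  # ~230-cell disc sharing the standard pitch; small enough for dense oracles
  cached("fascicle_30",
         hex_fascicle(diameter = 30, target_total = NULL, target_fibers = NULL))
}

reference_scenario <- function(drug, condition) {
  key <- paste0("scenario_", drug, "_", condition)
  cached(key, {
    res <- run_scenario(scenario_config(drug = drug, condition = condition),
                        write_snapshots = FALSE)
    # keep full trajectories only for the calibration scenario; the metric
    # series live in res$metrics, so the big state matrices can be dropped
    if (!(drug == "lidocaine" && condition == "physiological")) {
      res$trajectories <- lapply(res$trajectories, function(tr) {
        tr$states <- tr$states[c(1, nrow(tr$states)), , drop = FALSE]
        tr
      })
    }
    gc()
    res
  })
}

# minimal hand-built geometry for assembly unit tests
mini_fascicle <- function(kinds, pitch = 2, slab_depth = 100) {
  n <- length(kinds)
  area <- sqrt(3) / 2 * pitch^2
  comp <- tibble::tibble(
    id = seq_len(n), kind = kinds,
    q = seq_len(n) - 1L, r = 0L,
    x = (seq_len(n) - 1) * pitch, y = 0,
    area = area, volume = area * slab_depth * 1e-9)
  adj <- tibble::tibble(id_a = seq_len(n - 1), id_b = 2:n,
                        x1 = pitch / 2, x2 = pitch / 2)
  structure(list(compartments = comp, adjacency = adj, pitch = pitch,
                 diameter = n * pitch + pitch, slab_depth = slab_depth,
                 fiber_volume_scale = 1, coordination = 6L,
                 boundary_ids = c(1L, n), counts = table(kinds)),
            class = "fascicle")
}

# trajectory object built directly from states (for metric edge cases)
fake_trajectory <- function(times, states, kinds, phase,
                            equilibrium = rep(1, length(kinds)),
                            volumes = rep(1e-6, length(kinds))) {
  structure(list(times = times, states = states, phase = phase,
                 kinds = kinds, volumes = volumes, equilibrium = equilibrium,
                 clearance_ids = integer(0), clearance_Q = 0,
                 settings = solver_settings(), meta = list()),
            class = "trajectory")
}

# first time a sampled series crosses a level, linearly interpolated
crossing_time <- function(times, series, level = 0.5) {
  i <- which(series > level)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  times[i - 1] + (level - series[i - 1]) /
    (series[i] - series[i - 1]) * (times[i] - times[i - 1])
}
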