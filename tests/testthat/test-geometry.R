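test_that("default preset reproduces the reference compartment counts", {
  g <- default_fascicle()
  expect_identical(unname(g$counts[c("n_fiber", "n_capillary", "n_ecf")]),
                   c(1254L, 7L, 3799L))
  expect_identical(nrow(g$compartments), 5060L)
  rep <- validate_geometry(g)
  expect_true(all(rep$pass), info = paste(rep$check[!rep$pass], collapse = ", "))
})

test_that("adjacency is stored once per touching pair at pitch distance", {
  g <- default_fascicle()
  comp <- g$compartments
  adj <- g$adjacency
  key <- paste(pmin(adj$id_a, adj$id_b), pmax(adj$id_a, adj$id_b))
  expect_false(anyDuplicated(key) > 0)
  expect_false(any(adj$id_a == adj$id_b))
  da <- comp[match(adj$id_a, comp$id), ]
  db <- comp[match(adj$id_b, comp$id), ]
  d <- sqrt((da$x - db$x)^2 + (da$y - db$y)^2)
  expect_lt(max(abs(d - g$pitch)), 1e-9)
  expect_equal(adj$x1 + adj$x2, d, tolerance = 1e-12)

  deg <- tabulate(c(adj$id_a, adj$id_b), nrow(comp))
  expect_lte(max(deg), 6L)
  interior <- sqrt(comp$x^2 + comp$y^2) < g$diameter / 2 - 2 * g$pitch
  expect_true(all(deg[interior] == 6L))
})

test_that("compartment volumes follow the area-depth convention", {
  g <- default_fascicle()
  comp <- g$compartments
  expect_true(all(comp$volume > 0))
  expect_equal(comp$volume, comp$area * g$slab_depth * 1e-9, tolerance = 1e-14)
  # fiber:ECF total cross-section honours 3:2
  ratio <- sum(comp$area[comp$kind == "FIBER"]) /
    sum(comp$area[comp$kind == "ECF"])
  expect_equal(ratio, 1.5, tolerance = 1e-12)
})

test_that("boundary ring is the set of cells with missing neighbours", {
  g <- default_fascicle()
  ring <- boundary_ring(g)
  expect_gt(length(ring), 0)
  expect_identical(ring, sort(ring))
  comp <- g$compartments
  rad <- sqrt(comp$x[ring]^2 + comp$y[ring]^2)
  expect_true(all(rad > g$diameter / 2 - 2 * g$pitch))

  # tiny disc: center cell has all six neighbours, the outer six are the rim
  g7 <- hex_fascicle(diameter = 2.5 * pitch_for_cells(),
                     target_total = NULL, target_fibers = NULL,
                     capillary_layout = matrix(integer(0), ncol = 2))
  expect_identical(nrow(g7$compartments), 7L)
  ring7 <- boundary_ring(g7)
  center <- which(g7$compartments$q == 0 & g7$compartments$r == 0)
  expect_identical(sort(setdiff(g7$compartments$id, ring7)), center)
})

test_that("untrimmed lattice is six-fold symmetric in kinds and rim", {
  g0 <- hex_fascicle(target_total = NULL, target_fibers = NULL)
  comp <- g0$compartments
  key <- paste(comp$q, comp$r)
  rot_key <- paste(-comp$r, comp$q + comp$r)  # 60-degree lattice rotation
  idx <- match(rot_key, key)
  expect_false(anyNA(idx))                    # the site set maps onto itself
  expect_identical(comp$kind[idx], comp$kind) # kinds invariant
  ring <- boundary_ring(g0)
  on_ring <- comp$id %in% ring
  expect_identical(on_ring[idx], on_ring)     # rim invariant as a set
})

test_that("degenerate and invalid inputs are rejected with clear errors", {
  expect_error(hex_fascicle(capillary_layout = rbind(c(0L, 0L), c(200L, 0L))),
               "q = 200")
  expect_error(hex_fascicle(capillary_layout = rbind(c(0L, 0L), c(0L, 0L))),
               "distinct")
  expect_error(hex_fascicle(diameter = 3 * pitch_for_cells(),
                            fiber_pattern = "none",
                            target_total = NULL, target_fibers = NULL,
                            capillary_layout = matrix(integer(0), ncol = 2)),
               "zero fiber")
})

test_that("validate_geometry flags injected faults without mutating input", {
  g <- small_fascicle()
  broken <- g
  broken$adjacency <- dplyr::bind_rows(broken$adjacency, broken$adjacency[1, ])
  rep <- validate_geometry(broken)
  expect_false(rep$pass[rep$check == "adjacency_unique"])

  broken2 <- g
  broken2$adjacency$x1[1] <- broken2$adjacency$x1[1] * 2
  rep2 <- validate_geometry(broken2)
  expect_false(rep2$pass[rep2$check == "interface_distances"])

  # original untouched and still valid
  expect_true(all(validate_geometry(g)$pass))
})

test_that("geometry CSV round-trips through write_fascicle", {
  g <- small_fascicle()
  dir <- withr::local_tempdir()
  write_fascicle(g, dir)
  comp <- utils::read.csv(file.path(dir, "compartments.csv"))
  adj <- utils::read.csv(file.path(dir, "adjacency.csv"))
  expect_identical(nrow(comp), nrow(g$compartments))
  expect_identical(nrow(adj), nrow(g$adjacency))
  expect_equal(comp$volume_uL, g$compartments$volume, tolerance = 1e-12)
})
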