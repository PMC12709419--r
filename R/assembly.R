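#' Low-level compartment system constructor
#'
#' Wraps an assembled linear ODE system `dc/dt = A c + b` in the class used by
#' the integrators and metrics. Normally produced by [build_system()]; exposed
#' so that small analytic toy systems can be built directly.
#'
#' @param A Sparse (or dense) square rate matrix, 1/s entries.
#' @param b Source vector (concentration/s); zero everywhere in voiding.
#' @param volumes Compartment volumes, uL.
#' @param kinds Character vector of compartment kinds
#'   (`"FIBER"`, `"ECF"`, `"CAPILLARY"`).
#' @param phase `"filling"` or `"voiding"`.
#' @param equilibrium Optional analytic equilibrium state; defaults to 1 for
#'   all compartments.
#' @param clearance_ids Integer ids of compartments with a clearance sink.
#' @param clearance_Q Clearance per capillary, uL/s.
#' @param sym_weights Optional detailed-balance weights making
#'   `diag(sqrt(w)) A diag(1/sqrt(w))` symmetric (enables the `expm` solver).
#' @param clamp_ids Compartments held at concentration 1 during filling under
#'   the clamped-boundary variant.
#' @param meta Optional named list of provenance fields.
#' @return An object of class `compartment_system`.
#' @export
new_compartment_system <- function(A, b, volumes, kinds, phase,
                                   equilibrium = NULL,
                                   clearance_ids = integer(0),
                                   clearance_Q = 0,
                                   sym_weights = NULL,
                                   clamp_ids = integer(0),
                                   meta = list()) {
  n <- length(volumes)
  A <- Matrix::Matrix(A, sparse = TRUE)
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(A) == n, ncol(A) == n, length(b) == n, length(kinds) == n)
  phase <- match.arg(phase, c("filling", "voiding"))
  if (phase == "voiding" && any(b != 0)) {
    stop("voiding phase has a zero-flux boundary: source vector must be zero")
  }
  if (is.null(equilibrium)) equilibrium <- rep(1, n)
  structure(list(n = n, A = A, b = b, volumes = volumes, kinds = kinds,
                 phase = phase, equilibrium = equilibrium,
                 clearance_ids = clearance_ids, clearance_Q = clearance_Q,
                 sym_weights = sym_weights, clamp_ids = clamp_ids,
                 meta = meta),
            class = "compartment_system")
}

#' @export
print.compartment_system <- function(x, ...) {
  cat(sprintf("<compartment_system> %d compartments, phase %s\n", x$n, x$phase))
  if (length(x$meta)) {
    cat("  ", paste(names(x$meta), unlist(lapply(x$meta, format)),
                    sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("  %d clearance sinks (Q = %g uL/s), %d source entries\n",
              length(x$clearance_ids), x$clearance_Q, sum(x$b != 0)))
  invisible(x)
}

#' Assemble the phase-specific linear ODE system for a fascicle
#'
#' Converts geometry plus kinetic parameters into `dc/dt = A c + b`.
#' Exchange terms by kind pair:
#' \itemize{
#'   \item ECF-ECF and ECF-CAPILLARY: first-order hop at the
#'     mean-first-passage rate \eqn{2D/x^2} over the center-to-center
#'     distance, applied to the donor concentration with donor-volume
#'     weighting (mass-conserving for unequal volumes).
#'   \item ECF-FIBER: directional membrane conductances `k_EN` (into the
#'     fiber) and `k_NE` (out of it), each lumped with the two intra-
#'     compartment diffusion legs via [lumped_rate()].
#'   \item FIBER-FIBER: no direct exchange (fibers are never adjacent under
#'     the default 1-in-4 pattern; the rule is a safety net).
#' }
#' Under the default `"per_compartment"` convention every tabulated rate
#' constant is treated as a whole-compartment quantity shared across the
#' lattice coordination number (6 for the hexagonal lattice): each edge
#' carries 1/6 of the hop rate and of the membrane conductances. The
#' `"per_edge"` alternative applies the full constants on every edge.
#'
#' Capillary compartments receive an extra diagonal clearance term
#' `-Q / V_cap`. In the filling phase the non-fiber rim compartments exchange
#' with a fixed external reservoir at unit concentration through one hop-rate
#' term per missing lattice neighbour (Dirichlet boundary via ghost
#' reservoir); alternatively `boundary = "clamp"` pins the rim cells at 1.
#' The voiding phase has a zero-flux (Neumann) outer boundary: no reservoir
#' terms at all.
#'
#' @param g A [hex_fascicle()] geometry.
#' @param p An [anesthetic_params()] object.
#' @param cap A [capillary_params()] object.
#' @param phase `"filling"` or `"voiding"`.
#' @param clearance_in_filling Keep capillary clearance active during filling
#'   (default TRUE; its effect on onset is negligible, the flag exposes the
#'   choice).
#' @param edge_rate_convention `"per_compartment"` (default) or `"per_edge"`;
#'   see Details.
#' @param boundary `"reservoir"` (ghost reservoir coupled to the rim) or
#'   `"clamp"` (rim cells held at 1).
#' @return A [new_compartment_system()] object.
#' @export
#' @examples
#' g <- hex_fascicle()
#' sys <- build_system(g, anesthetic_params("lidocaine", "physiological"))
build_system <- function(g, p, cap = capillary_params(),
                         phase = c("filling", "voiding"),
                         clearance_in_filling = TRUE,
                         edge_rate_convention = c("per_compartment", "per_edge"),
                         boundary = c("reservoir", "clamp")) {
  stopifnot(inherits(g, "fascicle"), inherits(p, "anesthetic_params"))
  phase <- match.arg(phase)
  edge_rate_convention <- match.arg(edge_rate_convention)
  boundary <- match.arg(boundary)

  comp <- g$compartments
  n <- nrow(comp)
  V <- comp$volume
  kinds <- comp$kind
  div <- if (edge_rate_convention == "per_compartment") g$coordination else 1L

  adj <- g$adjacency
  ia <- adj$id_a
  ib <- adj$id_b
  ka <- kinds[ia]
  kb <- kinds[ib]
  known <- c("FIBER", "ECF", "CAPILLARY")
  if (!all(ka %in% known & kb %in% known)) stop("unknown compartment kind in adjacency")
  if (any(ka == "FIBER" & kb == "FIBER")) {
    stop("direct fiber-fiber adjacency is not modeled")
  }

  ecfish <- function(k) k %in% c("ECF", "CAPILLARY")
  x_cc <- adj$x1 + adj$x2  # center-to-center distance

  trip_i <- trip_j <- integer(0)
  trip_x <- numeric(0)
  add <- function(i, j, rate) {
    trip_i <<- c(trip_i, i); trip_j <<- c(trip_j, j)
    trip_x <<- c(trip_x, rep_len(rate, length(i)))
  }

  # aqueous hops (ECF-ECF, ECF-CAPILLARY): flux = k * c_donor * V_donor
  m <- ecfish(ka) & ecfish(kb)
  k_hop <- mfpt_rate(p$D, x_cc[m]) / div
  add(ia[m], ib[m],  k_hop * V[ib[m]] / V[ia[m]])
  add(ia[m], ia[m], -k_hop)
  add(ib[m], ia[m],  k_hop * V[ia[m]] / V[ib[m]])
  add(ib[m], ib[m], -k_hop)

  # membrane exchange (ECF-FIBER), lumped with the diffusion legs
  m1 <- ecfish(ka) & kb == "FIBER"
  m2 <- ka == "FIBER" & ecfish(kb)
  E <- c(ia[m1], ib[m2])
  N <- c(ib[m1], ia[m2])
  xs1 <- c(adj$x1[m1], adj$x2[m2])
  xs2 <- c(adj$x2[m1], adj$x1[m2])
  lump <- function(k_mem) 2 * p$D * k_mem / ((xs1^2 + xs2^2) * k_mem + 2 * p$D)
  k_EN_edge <- lump(p$k_EN) / div
  k_NE_edge <- lump(p$k_NE) / div
  add(N, E,  k_EN_edge / V[N])
  add(E, E, -k_EN_edge / V[E])
  add(E, N,  k_NE_edge / V[E])
  add(N, N, -k_NE_edge / V[N])

  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x, dims = c(n, n))
  b <- numeric(n)

  # capillary clearance sink
  Q <- capillary_clearance(cap)
  cap_ids <- which(kinds == "CAPILLARY")
  clearance_on <- phase == "voiding" || clearance_in_filling
  if (clearance_on && length(cap_ids) > 0 && Q > 0) {
    A <- A + Matrix::sparseMatrix(i = cap_ids, j = cap_ids,
                                  x = -Q / V[cap_ids], dims = c(n, n))
  }

  clamp_ids <- integer(0)
  if (phase == "filling") {
    deg <- tabulate(c(ia, ib), n)
    rim <- which(deg < g$coordination & kinds != "FIBER")
    n_miss <- g$coordination - deg[rim]
    k_res <- mfpt_rate(p$D, g$pitch) / div
    if (boundary == "reservoir") {
      # ghost reservoir at concentration 1, one hop term per missing neighbour
      A <- A + Matrix::sparseMatrix(i = rim, j = rim, x = -k_res * n_miss,
                                    dims = c(n, n))
      b[rim] <- k_res * n_miss
    } else {
      # clamp: rim cells are held at 1 (rows zeroed; initial state sets them)
      A[rim, ] <- 0
      clamp_ids <- rim
    }
  }

  # lumped membrane ratio is the exact fixed-point fiber concentration
  lump_ratio <- lumped_rate(p$D, p$k_EN, g$pitch / 2, g$pitch / 2)$k_star /
    lumped_rate(p$D, p$k_NE, g$pitch / 2, g$pitch / 2)$k_star
  equilibrium <- ifelse(kinds == "FIBER", lump_ratio, 1)

  # detailed-balance weights (volumes uniform within each kind)
  V_E <- V[match("ECF", kinds)]
  V_N <- V[match("FIBER", kinds)]
  kEN_l <- lumped_rate(p$D, p$k_EN, g$pitch / 2, g$pitch / 2)$k_star
  kNE_l <- lumped_rate(p$D, p$k_NE, g$pitch / 2, g$pitch / 2)$k_star
  # w_j/w_i = A_ij/A_ji on every fiber-ECF edge makes diag(sqrt(w)) A diag(1/sqrt(w)) symmetric
  w <- rep(1, n)
  w[kinds == "FIBER"] <- (kNE_l * V_N) / (kEN_l * V_E)
  if (boundary == "clamp" && phase == "filling") w <- NULL  # zeroed rows break symmetry

  new_compartment_system(
    A = A, b = b, volumes = V, kinds = kinds, phase = phase,
    equilibrium = equilibrium, clearance_ids = cap_ids,
    clearance_Q = if (clearance_on) Q else 0,
    sym_weights = w, clamp_ids = clamp_ids,
    meta = list(drug = p$name, condition = p$condition, D = p$D,
                k_EN = p$k_EN, k_NE = p$k_NE, pitch = g$pitch,
                slab_depth = g$slab_depth,
                edge_rate_convention = edge_rate_convention,
                boundary = boundary,
                clearance_in_filling = clearance_in_filling))
}

#' Analytic no-clearance equilibrium state
#'
#' The fixed point of the exchange network under a unit external
#' concentration with clearance disabled: 1 in every aqueous (ECF/capillary)
#' compartment and the lumped membrane conductance ratio (numerically
#' `k_EN / k_NE` to four significant figures) in every fiber compartment.
#' Used as the initial condition of the voiding phase.
#'
#' @param sys A [build_system()] result (or any `compartment_system` carrying
#'   an `equilibrium` element).
#' @return Numeric state vector.
#' @export
equilibrium_state <- function(sys) {
  stopifnot(inherits(sys, "compartment_system"))
  sys$equilibrium
}

#' Export a compartment system for external verification
#'
#' Writes the rate matrix in Matrix Market format (`system.mtx`) plus a JSON
#' sidecar (`system.json`) with the phase, source vector, volumes and
#' clearance ids.
#'
#' @param sys A `compartment_system`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
export_system <- function(sys, dir) {
  stopifnot(inherits(sys, "compartment_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "system.mtx")
  p2 <- file.path(dir, "system.json")
  Matrix::writeMM(sys$A, p1)
  jsonlite::write_json(
    list(phase = sys$phase, b = sys$b, volumes = sys$volumes,
         kinds = sys$kinds, clearance_ids = sys$clearance_ids,
         clearance_Q = sys$clearance_Q, meta = sys$meta),
    p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
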