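#' Lattice pitch that tiles a disc with a target number of hexagonal cells
#'
#' The hexagonal cell area is \eqn{(\sqrt{3}/2)\,p^2} for pitch \eqn{p}
#' (center-to-center distance). Equating `n_cells` such cells with the area of
#' a disc of the given diameter yields the pitch used by the default fascicle
#' preset.
#'
#' @param diameter Fascicle diameter in micrometers.
#' @param n_cells Number of lattice cells the disc should hold.
#' @return Pitch in micrometers.
#' @export
#' @examples
#' pitch_for_cells(140, 5060)
pitch_for_cells <- function(diameter = 140, n_cells = 5060) {
  cell_area <- pi * (diameter / 2)^2 / n_cells
  sqrt(2 * cell_area / sqrt(3))
}

#' Default capillary layout: one central capillary plus a symmetric ring of six
#'
#' Returns axial hex coordinates for seven capillaries: the origin and the
#' lattice sites nearest to radius `diameter/3` at 60-degree spacing. The six
#' ring sites are generated by exact 60-degree lattice rotation of the first,
#' so the layout is six-fold symmetric.
#'
#' @param diameter Fascicle diameter (micrometers).
#' @param pitch Lattice pitch (micrometers).
#' @return Integer matrix with columns `q`, `r`.
#' @export
default_capillary_layout <- function(diameter = 140, pitch = pitch_for_cells(diameter)) {
  target <- c(diameter / 3, 0)
  # nearest axial site to the target point
  r0 <- round(target[2] / (pitch * sqrt(3) / 2))
  q0 <- round(target[1] / pitch - r0 / 2)
  # refine over a small neighbourhood
  cand <- expand.grid(q = q0 + (-1:1), r = r0 + (-1:1))
  cx <- pitch * (cand$q + cand$r / 2)
  cy <- pitch * sqrt(3) / 2 * cand$r
  i <- which.min((cx - target[1])^2 + (cy - target[2])^2)
  qr <- c(cand$q[i], cand$r[i])
  out <- matrix(c(0L, 0L), ncol = 2)
  for (k in 1:6) {
    out <- rbind(out, qr)
    qr <- hex_rotate60(qr)
  }
  out <- unique(out)
  dimnames(out) <- list(NULL, c("q", "r"))
  out
}

# 60-degree rotation in axial hex coordinates (pointy-top)
hex_rotate60 <- function(qr) c(-qr[2], qr[1] + qr[2])

# axial -> cartesian (pointy-top, origin at fascicle center)
hex_xy <- function(q, r, pitch) {
  list(x = pitch * (q + r / 2), y = pitch * sqrt(3) / 2 * r)
}

#' Build the hexagonal-lattice fascicle cross-section
#'
#' Constructs the 2D compartment geometry of a nerve fascicle: a pointy-top
#' hexagonal lattice clipped to a disc, with each site typed as a nerve
#' `FIBER`, extracellular fluid (`ECF`) or `CAPILLARY` compartment. Fibers
#' occupy the 1-in-4 sublattice (`q` and `r` both even); capillaries are
#' placed at explicit axial coordinates (by default one central plus six at
#' radius `diameter/3`).
#'
#' With the default arguments the build reproduces the reference fascicle:
#' 1254 fiber, 7 capillary and 3799 ECF compartments in a 140-micrometer disc.
#' Because hex-site counts inside a disc only change in symmetry-orbit jumps,
#' exact counts are reached by deterministic adjustment: surplus outermost ECF
#' sites are trimmed (largest radius first, ties by lowest id) and surplus
#' outermost fibers are demoted to ECF one complete 60-degree rotation orbit
#' at a time. Set `target_total`/`target_fibers` to `NULL` to keep the raw
#' clipped lattice.
#'
#' Compartment volume is `area * slab_depth * 1e-9` microliters, where
#' `slab_depth` is the axial thickness assigned to the 2D slice; fiber
#' compartments are additionally scaled by `fiber_volume_scale` so that the
#' fiber:ECF total cross-section can honour the anatomical 3:2 ratio (the
#' default, `NULL`, computes `1.5 * n_ecf / n_fiber`).
#'
#' @param diameter Fascicle diameter, micrometers.
#' @param pitch Lattice pitch, micrometers; `NULL` uses the reference lattice
#'   constant [pitch_for_cells()]`(140, 5060)` (about 1.874), so smaller test
#'   discs share the standard cell size.
#' @param slab_depth Axial slab thickness, micrometers, used to convert cell
#'   areas to volumes. The default is the package calibration (see
#'   [default_slab_depth()]).
#' @param fiber_pattern `"sublattice"` places fibers on the q,r-even 1-in-4
#'   sublattice; `"none"` requests no fibers (always an error, kept to make
#'   the degenerate case explicit).
#' @param capillary_layout Integer matrix of axial `(q, r)` coordinates, or
#'   `NULL` for [default_capillary_layout()]. Use a 0-row matrix for no
#'   capillaries.
#' @param fiber_volume_scale Numeric multiplier for fiber volumes relative to
#'   ECF volumes, or `NULL` for the 3:2 total-area convention.
#' @param target_total,target_fibers Exact compartment counts to enforce
#'   (default 5060 total / 1254 fibers for the 140-micrometer preset);
#'   `NULL` disables the adjustment.
#' @return An object of class `fascicle` with elements `compartments`
#'   (tibble: id, kind, q, r, x, y, area, volume), `adjacency` (tibble: id_a,
#'   id_b, x1, x2), `pitch`, `diameter`, `slab_depth`, `fiber_volume_scale`,
#'   `coordination`, `boundary_ids` and `counts`.
#' @export
#' @examples
#' g <- hex_fascicle()
#' g$counts
hex_fascicle <- function(diameter = 140,
                         pitch = NULL,
                         slab_depth = default_slab_depth(),
                         fiber_pattern = c("sublattice", "none"),
                         capillary_layout = NULL,
                         fiber_volume_scale = NULL,
                         target_total = if (diameter == 140) 5060L else NULL,
                         target_fibers = if (diameter == 140) 1254L else NULL) {
  fiber_pattern <- match.arg(fiber_pattern)
  if (is.null(pitch)) {
    pitch <- if (is.null(target_total)) pitch_for_cells(140, 5060)
             else pitch_for_cells(diameter, target_total)
  }
  stopifnot(pitch > 0, diameter > 2 * pitch, slab_depth > 0)
  radius <- diameter / 2

  # all lattice sites with center inside the disc
  rmax <- ceiling(2 * radius / (pitch * sqrt(3))) + 2
  qmax <- ceiling(radius / pitch) + rmax
  grid <- expand.grid(q = -qmax:qmax, r = -rmax:rmax)
  xy <- hex_xy(grid$q, grid$r, pitch)
  keep <- xy$x^2 + xy$y^2 <= radius^2 + 1e-12
  d <- data.frame(q = grid$q[keep], r = grid$r[keep],
                  x = xy$x[keep], y = xy$y[keep])
  d <- d[order(d$r, d$q), , drop = FALSE]  # row-major (r, then q) id order
  rownames(d) <- NULL
  d$radius <- sqrt(d$x^2 + d$y^2)

  # capillaries
  if (is.null(capillary_layout)) {
    capillary_layout <- default_capillary_layout(diameter, pitch)
  }
  capillary_layout <- matrix(as.integer(capillary_layout), ncol = 2,
                             dimnames = list(NULL, c("q", "r")))
  if (anyDuplicated(capillary_layout)) {
    stop("capillary coordinates must be distinct")
  }
  if (nrow(capillary_layout) > 0) {
    cxy <- hex_xy(capillary_layout[, 1], capillary_layout[, 2], pitch)
    out <- cxy$x^2 + cxy$y^2 > radius^2 + 1e-12
    if (any(out)) {
      bad <- capillary_layout[which(out)[1], ]
      stop(sprintf("capillary coordinate (q = %d, r = %d) lies outside the fascicle disc",
                   bad[1], bad[2]))
    }
  }
  cap_key <- paste(capillary_layout[, 1], capillary_layout[, 2])
  site_key <- paste(d$q, d$r)

  on_sublattice <- d$q %% 2 == 0 & d$r %% 2 == 0
  kind <- ifelse(site_key %in% cap_key, "CAPILLARY",
                 ifelse(fiber_pattern == "sublattice" & on_sublattice,
                        "FIBER", "ECF"))
  d$kind <- kind

  # exact-count adjustment: trim surplus rim ECF, demote surplus rim fibers
  if (!is.null(target_total)) {
    surplus <- nrow(d) - target_total
    if (surplus < 0) {
      stop(sprintf("lattice holds only %d sites; cannot reach %d compartments",
                   nrow(d), target_total))
    }
    if (surplus > 0) {
      ord <- order(-d$radius, seq_len(nrow(d)))
      drop <- ord[d$kind[ord] == "ECF"][seq_len(surplus)]
      d <- d[-drop, , drop = FALSE]
      rownames(d) <- NULL
    }
  }
  if (!is.null(target_fibers)) {
    n_fib <- sum(d$kind == "FIBER")
    if (n_fib < target_fibers) {
      stop(sprintf("pattern yields %d fibers, fewer than the %d required",
                   n_fib, target_fibers))
    }
    if (n_fib > target_fibers) {
      # demote outermost fibers, whole 60-degree orbits at a time, so the
      # fiber arrangement keeps the lattice six-fold symmetry when possible
      key_map <- stats::setNames(seq_len(nrow(d)), paste(d$q, d$r))
      fiber_order <- order(-d$radius, seq_len(nrow(d)))
      fiber_order <- fiber_order[d$kind[fiber_order] == "FIBER"]
      demoted <- integer(0)
      while (length(demoted) < n_fib - target_fibers) {
        cand <- fiber_order[!(fiber_order %in% demoted)][1]
        qr <- c(d$q[cand], d$r[cand])
        orbit <- integer(0)
        for (k in 1:6) {
          orbit <- c(orbit, key_map[[paste(qr[1], qr[2])]])
          qr <- hex_rotate60(qr)
        }
        demoted <- c(demoted, unique(orbit))
      }
      d$kind[demoted[seq_len(n_fib - target_fibers)]] <- "ECF"
    }
  }
  if (!any(d$kind == "FIBER")) {
    stop("fiber pattern produced zero fiber compartments")
  }

  d$id <- seq_len(nrow(d))
  cell_area <- sqrt(3) / 2 * pitch^2
  if (is.null(fiber_volume_scale)) {
    fiber_volume_scale <- 1.5 * sum(d$kind == "ECF") / sum(d$kind == "FIBER")
  }
  d$area <- cell_area * ifelse(d$kind == "FIBER", fiber_volume_scale, 1)
  d$volume <- d$area * slab_depth * 1e-9  # um^3 -> uL

  adjacency <- hex_adjacency(d, pitch)
  deg <- tabulate(c(adjacency$id_a, adjacency$id_b), nrow(d))
  boundary_ids <- d$id[deg < 6L]

  counts <- c(n_fiber = sum(d$kind == "FIBER"),
              n_capillary = sum(d$kind == "CAPILLARY"),
              n_ecf = sum(d$kind == "ECF"))

  structure(list(
    compartments = tibble::as_tibble(
      d[, c("id", "kind", "q", "r", "x", "y", "area", "volume")]),
    adjacency = adjacency,
    pitch = pitch,
    diameter = diameter,
    slab_depth = slab_depth,
    fiber_volume_scale = fiber_volume_scale,
    coordination = 6L,
    boundary_ids = boundary_ids,
    counts = counts
  ), class = "fascicle")
}

# unordered adjacency of touching hex cells; x1/x2 are the center-to-interface
# distances (pitch/2 each for equal cells)
hex_adjacency <- function(d, pitch) {
  key_map <- stats::setNames(seq_len(nrow(d)), paste(d$q, d$r))
  offsets <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 1L))  # 3 of 6: each pair once
  pairs <- lapply(seq_len(nrow(offsets)), function(k) {
    nb_key <- paste(d$q + offsets[k, 1], d$r + offsets[k, 2])
    nb <- unname(key_map[nb_key])
    ok <- !is.na(nb)
    cbind(a = seq_len(nrow(d))[ok], b = nb[ok])
  })
  pairs <- do.call(rbind, pairs)
  tibble::tibble(id_a = as.integer(pairs[, "a"]),
                 id_b = as.integer(pairs[, "b"]),
                 x1 = pitch / 2, x2 = pitch / 2)
}

#' @export
print.fascicle <- function(x, ...) {
  cat(sprintf("<fascicle> diameter %g um, pitch %.4f um, slab depth %g um\n",
              x$diameter, x$pitch, x$slab_depth))
  cat(sprintf("  %d compartments: %d fiber, %d capillary, %d ECF\n",
              nrow(x$compartments), x$counts[["n_fiber"]],
              x$counts[["n_capillary"]], x$counts[["n_ecf"]]))
  cat(sprintf("  fiber volume scale %.3f, %d boundary cells\n",
              x$fiber_volume_scale, length(x$boundary_ids)))
  invisible(x)
}

#' Identify the outer rim of the fascicle
#'
#' Returns the ids of compartments with fewer than six lattice neighbours
#' inside the disc, ordered by id. During the filling phase the non-fiber rim
#' cells exchange with the external anesthetic reservoir.
#'
#' @param g A [hex_fascicle()] geometry.
#' @return Integer vector of compartment ids (non-empty, increasing).
#' @export
boundary_ring <- function(g) {
  stopifnot(inherits(g, "fascicle"))
  sort(g$boundary_ids)
}

#' Check the structural invariants of a fascicle geometry
#'
#' Report-only validation: adjacency symmetry and uniqueness, the six-neighbour
#' cap, positive volumes, centers inside the disc, and (for the default
#' preset) the exact compartment counts. Never modifies its input.
#'
#' @param g A [hex_fascicle()] geometry.
#' @param expected_counts Optional named vector (`n_fiber`, `n_capillary`,
#'   `n_ecf`) to check counts against; defaults to the reference counts when
#'   the geometry has 5060 compartments.
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
validate_geometry <- function(g, expected_counts = NULL) {
  stopifnot(inherits(g, "fascicle"))
  comp <- g$compartments
  adj <- g$adjacency
  n <- nrow(comp)
  checks <- list()
  note <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail)
  }

  key <- paste(pmin(adj$id_a, adj$id_b), pmax(adj$id_a, adj$id_b))
  note("adjacency_unique", !anyDuplicated(key) && !any(adj$id_a == adj$id_b),
       "each touching pair stored exactly once, no self-pairs")

  # symmetry: every stored pair corresponds to two cells at lattice contact
  da <- comp[match(adj$id_a, comp$id), ]
  db <- comp[match(adj$id_b, comp$id), ]
  dist <- sqrt((da$x - db$x)^2 + (da$y - db$y)^2)
  note("adjacency_contact", all(abs(dist - g$pitch) < 1e-9),
       "all pair center distances equal the pitch")
  note("interface_distances", all(abs(adj$x1 + adj$x2 - g$pitch) < 1e-12),
       "x1 + x2 equals the center-to-center distance")

  deg <- tabulate(c(adj$id_a, adj$id_b), n)
  note("neighbor_cap", all(deg <= 6L), sprintf("max degree %d", max(deg)))
  note("positive_volumes", all(comp$volume > 0), "")
  note("centers_in_disc",
       all(comp$x^2 + comp$y^2 <= (g$diameter / 2)^2 + 1e-9), "")
  note("kinds_known", all(comp$kind %in% c("FIBER", "ECF", "CAPILLARY")), "")

  if (is.null(expected_counts) && n == 5060L) {
    expected_counts <- c(n_fiber = 1254L, n_capillary = 7L, n_ecf = 3799L)
  }
  if (!is.null(expected_counts)) {
    note("counts",
         all(g$counts[names(expected_counts)] == expected_counts),
         paste(sprintf("%s=%d", names(g$counts), g$counts), collapse = ", "))
  }
  note("counts_sum", sum(g$counts) == n, "")
  dplyr::bind_rows(checks)
}

#' Write a fascicle geometry to CSV files
#'
#' Writes `compartments.csv` (id, kind, q, r, x_um, y_um, area_um2,
#' volume_uL) and `adjacency.csv` (id_a, id_b, x1_um, x2_um) into `dir`.
#'
#' @param g A [hex_fascicle()] geometry.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_fascicle <- function(g, dir) {
  stopifnot(inherits(g, "fascicle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- g$compartments
  names(comp) <- c("id", "kind", "q", "r", "x_um", "y_um", "area_um2", "volume_uL")
  adj <- g$adjacency
  names(adj) <- c("id_a", "id_b", "x1_um", "x2_um")
  p1 <- file.path(dir, "compartments.csv")
  p2 <- file.path(dir, "adjacency.csv")
  utils::write.csv(comp, p1, row.names = FALSE)
  utils::write.csv(adj, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fascicle geometry into its compartment table
#'
#' @param x A `fascicle`.
#' @param ... Unused.
#' @return The compartment tibble (one row per compartment).
#' @export
tidy.fascicle <- function(x, ...) x$compartments

#' One-row summary of a fascicle geometry
#'
#' @param x A `fascicle`.
#' @param ... Unused.
#' @return A one-row tibble with counts and lattice parameters.
#' @export
glance.fascicle <- function(x, ...) {
  tibble::tibble(
    diameter = x$diameter, pitch = x$pitch, slab_depth = x$slab_depth,
    n_fiber = x$counts[["n_fiber"]], n_capillary = x$counts[["n_capillary"]],
    n_ecf = x$counts[["n_ecf"]], n_total = nrow(x$compartments),
    fiber_volume_scale = x$fiber_volume_scale)
}

#' Plot a fascicle cross-section
#'
#' Draws each compartment at its true position, coloured by kind (or by a
#' supplied per-compartment value).
#'
#' @param object A `fascicle`.
#' @param fill Optional numeric vector (length = number of compartments) to
#'   colour by instead of kind.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fascicle <- function(object, fill = NULL, ...) {
  comp <- object$compartments
  size <- object$pitch * 1.9
  if (is.null(fill)) {
    ggplot2::ggplot(comp, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$kind)) +
      ggplot2::geom_point(size = size / 2) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "kind") +
      ggplot2::theme_minimal()
  } else {
    comp$value <- fill
    ggplot2::ggplot(comp, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$value)) +
      ggplot2::geom_point(size = size / 2) +
      ggplot2::scale_colour_viridis_c() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "conc.") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
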