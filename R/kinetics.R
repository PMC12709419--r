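#' Mean-first-passage-time rate constant for diffusion over a distance
#'
#' For one-dimensional diffusive travel over distance `x` with diffusion
#' coefficient `D`, the mean first passage time is \eqn{x^2 / 2D}; the
#' corresponding first-order rate constant is its inverse, \eqn{k = 2D/x^2}.
#' This is the elementary hop rate between adjacent extracellular compartments.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param x Travel distance, um.
#' @return Rate constant, 1/s.
#' @export
#' @examples
#' mfpt_rate(749, 1.874)  # lidocaine across one lattice pitch
mfpt_rate <- function(D, x) {
  stopifnot(all(D > 0))
  if (any(x <= 0)) stop("distance x must be positive (x = 0 gives an infinite rate)")
  2 * D / x^2
}

#' Pharmacological lumping of a membrane crossing with its diffusion legs
#'
#' Transfer between the centers of two adjacent compartments separated by a
#' membrane proceeds in three serial steps: diffusion over `x1` to the
#' membrane, membrane crossing at rate `k_mem`, and diffusion over `x2` to the
#' second center. The serial (lumped) substitute rate is
#' \deqn{k^* = \frac{2 D\, k}{(x_1^2 + x_2^2)\,k + 2D},}
#' equivalently \eqn{1/k^* = (x_1^2 + x_2^2)/2D + 1/k}: reciprocal addition of
#' the three component rates \eqn{2D/x_1^2}, \eqn{k}, \eqn{2D/x_2^2} with the
#' two diffusion legs combined.
#'
#' Inputs follow the printed-unit convention of the parameter table: `D` in
#' um^2/s, distances in um, and `k_mem` as transcribed; with the tabulated
#' magnitudes the diffusion correction is below 0.01%, so lumped membrane
#' rates retain the tabulated forward/backward ratio to four significant
#' figures.
#'
#' @param D Diffusion coefficient, um^2/s.
#' @param k_mem Membrane crossing rate constant (tabulated units).
#' @param x1,x2 Center-to-membrane distances of the two compartments, um.
#' @return An object of class `lumped_rate`: list with `k_star` and
#'   `components` (named vector `k1`, `k2`, `k3`).
#' @export
#' @examples
#' lumped_rate(749, 9.147e-3, 0.937, 0.937)$k_star
lumped_rate <- function(D, k_mem, x1, x2) {
  stopifnot(D > 0, k_mem > 0, x1 > 0, x2 > 0)
  k_star <- 2 * D * k_mem / ((x1^2 + x2^2) * k_mem + 2 * D)
  structure(list(
    k_star = k_star,
    components = c(k1 = 2 * D / x1^2, k2 = k_mem, k3 = 2 * D / x2^2)
  ), class = "lumped_rate")
}

#' @export
print.lumped_rate <- function(x, ...) {
  cat(sprintf("<lumped_rate> k* = %.6g (k1 = %.4g, k2 = %.4g, k3 = %.4g)\n",
              x$k_star, x$components[1], x$components[2], x$components[3]))
  invisible(x)
}

#' Capillary hemodynamic parameters
#'
#' Blood velocity, capillary cross-section and the fraction of capillaries
#' open at any moment (vasomotion transiently closes about 25%).
#'
#' @param blood_velocity Capillary blood velocity, mm/s.
#' @param cross_section Capillary cross-sectional area, um^2.
#' @param open_fraction Fraction of capillaries open, in `[0, 1]`.
#' @return An object of class `capillary_params`.
#' @export
#' @examples
#' capillary_clearance(capillary_params())  # 1.96e-5 uL/s
capillary_params <- function(blood_velocity = 0.79, cross_section = 33,
                             open_fraction = 0.75) {
  if (blood_velocity < 0 || cross_section < 0) {
    stop("blood velocity and cross-section must be non-negative")
  }
  stopifnot(open_fraction >= 0, open_fraction <= 1)
  structure(list(blood_velocity = blood_velocity,
                 cross_section = cross_section,
                 open_fraction = open_fraction),
            class = "capillary_params")
}

#' Perfusion-limited capillary clearance
#'
#' Clearance is equated to the local blood flow through one capillary:
#' velocity times cross-section times the open fraction, converted from
#' um^3/s to uL/s.
#'
#' @param p A [capillary_params()] object.
#' @return Clearance Q in uL/s.
#' @export
capillary_clearance <- function(p = capillary_params()) {
  stopifnot(inherits(p, "capillary_params"))
  # mm/s -> um/s (x1000); um^3/s -> uL/s (x1e-9)
  p$blood_velocity * 1000 * p$cross_section * p$open_fraction * 1e-9
}

# cached preset table
the_presets <- new.env(parent = emptyenv())

#' Anesthetic kinetic parameter presets
#'
#' The transcribed parameter table: diffusion coefficient and the two
#' membrane rate constants (extracellular-to-fiber `k_EN`, fiber-to-
#' extracellular `k_NE`) for lidocaine and bupivacaine under physiological
#' and acidotic pH. Shipped as a versioned JSON resource inside the package;
#' `path` can point at an override file with the same structure.
#'
#' @param path Optional path to an alternative presets JSON file.
#' @return A tibble with columns `drug`, `condition`, `D_m2_s` (as printed,
#'   m^2/s), `D` (um^2/s), `k_EN`, `k_NE` (uL/s).
#' @export
#' @examples
#' anesthetic_presets()
anesthetic_presets <- function(path = NULL) {
  if (is.null(path) && !is.null(the_presets$table)) return(the_presets$table)
  if (is.null(path)) {
    path <- system.file("extdata", "anesthetic_presets.json",
                        package = "fasciclesim", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path)
  tab <- tibble::as_tibble(raw$presets)
  tab$D <- tab$D_m2_s * 1e12  # m^2/s -> um^2/s
  if (is.null(raw$version)) stop("presets file lacks a version field")
  attr(tab, "version") <- raw$version
  if (is.null(match.call()$path)) the_presets$table <- tab
  tab
}

#' Kinetic parameters for one anesthetic under one condition
#'
#' @param drug `"lidocaine"` or `"bupivacaine"` (or a drug named in a custom
#'   presets file).
#' @param condition `"physiological"` or `"acidosis"`.
#' @param presets Preset table from [anesthetic_presets()].
#' @return An object of class `anesthetic_params`: list with `name`,
#'   `condition`, `D` (um^2/s), `k_EN`, `k_NE` (uL/s).
#' @export
#' @examples
#' anesthetic_params("lidocaine", "physiological")
anesthetic_params <- function(drug, condition = c("physiological", "acidosis"),
                              presets = anesthetic_presets()) {
  condition <- match.arg(condition, unique(presets$condition))
  row <- presets[presets$drug == drug & presets$condition == condition, ]
  if (nrow(row) != 1) {
    valid <- paste(sprintf("%s/%s", presets$drug, presets$condition),
                   collapse = ", ")
    stop(sprintf("unknown preset '%s'/'%s'; valid presets: %s",
                 drug, condition, valid))
  }
  structure(list(name = row$drug, condition = row$condition,
                 D = row$D, k_EN = row$k_EN, k_NE = row$k_NE),
            class = "anesthetic_params")
}

#' @export
print.anesthetic_params <- function(x, ...) {
  cat(sprintf("<anesthetic_params> %s (%s): D = %g um2/s, k_EN = %g, k_NE = %g uL/s\n",
              x$name, x$condition, x$D, x$k_EN, x$k_NE))
  invisible(x)
}

#' Fiber-to-extracellular equilibrium concentration ratio
#'
#' At equilibrium the pairwise fiber/ECF exchange balances, so the fiber
#' concentration relative to the surrounding extracellular fluid equals
#' `k_EN / k_NE`. Under a unit external bolus this is also the absolute fiber
#' concentration at the no-clearance steady state.
#'
#' @param p An [anesthetic_params()] object.
#' @return Dimensionless concentration ratio.
#' @export
#' @examples
#' equilibrium_ratio(anesthetic_params("bupivacaine", "physiological"))  # 345.3
equilibrium_ratio <- function(p) {
  stopifnot(inherits(p, "anesthetic_params"))
  p$k_EN / p$k_NE
}
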