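#' Two-compartment exchange toy with closed-form solution
#'
#' Two well-mixed compartments exchanging through directional conductances
#' `k_fwd` (1 to 2) and `k_rev` (2 to 1), in uL/s:
#' \deqn{V_1 c_1' = -k_{fwd} c_1 + k_{rev} c_2, \quad
#'       V_2 c_2' = k_{fwd} c_1 - k_{rev} c_2.}
#' The solution is a single exponential relaxation toward the equilibrium
#' ratio \eqn{c_2/c_1 = k_{fwd}/k_{rev}} at rate
#' \eqn{\lambda = k_{fwd}/V_1 + k_{rev}/V_2}; the closed form is attached for
#' oracle comparisons.
#'
#' @param k_fwd,k_rev Exchange conductances, uL/s.
#' @param V1,V2 Volumes, uL.
#' @param initial Initial concentrations (length 2).
#' @return A list of class `toy_model` with elements `system` (a
#'   `compartment_system`, voiding phase, no clearance), `closed_form`
#'   (function of time returning the 2-vector state) and `name`.
#' @export
#' @examples
#' toy <- two_compartment_exchange(1e-3, 1e-3, 1e-6, 1e-6)
#' toy$closed_form(0.01)
two_compartment_exchange <- function(k_fwd, k_rev, V1, V2,
                                     initial = c(1, 0)) {
  stopifnot(k_fwd > 0, k_rev > 0, V1 > 0, V2 > 0, length(initial) == 2)
  A <- rbind(c(-k_fwd / V1,  k_rev / V1),
             c( k_fwd / V2, -k_rev / V2))
  sys <- new_compartment_system(
    A = A, b = c(0, 0), volumes = c(V1, V2), kinds = c("ECF", "FIBER"),
    phase = "voiding",
    equilibrium = c(1, k_fwd / k_rev),
    sym_weights = c(1, (k_rev * V2) / (k_fwd * V1)),
    meta = list(toy = "two_compartment_exchange"))
  lambda <- k_fwd / V1 + k_rev / V2
  # conserved mass m = V1 c1 + V2 c2; equilibrium shares from k ratios
  m <- V1 * initial[1] + V2 * initial[2]
  c1_inf <- m / (V1 + V2 * k_fwd / k_rev)
  c2_inf <- c1_inf * k_fwd / k_rev
  closed_form <- function(t) {
    decay <- exp(-lambda * t)
    c(c1_inf + (initial[1] - c1_inf) * decay,
      c2_inf + (initial[2] - c2_inf) * decay)
  }
  structure(list(system = sys, closed_form = closed_form, initial = initial,
                 name = "two_compartment_exchange"),
            class = "toy_model")
}

#' One-dimensional diffusion chain toy
#'
#' A chain of `n_cells` identical aqueous compartments with nearest-neighbour
#' hops at the mean-first-passage rate `2D/pitch^2`, fed by a ghost reservoir
#' at unit concentration at cell 1 (filling phase). The time for the far cell
#' to reach half the reservoir concentration scales diffusively with chain
#' length (Fick scaling).
#'
#' @param n_cells Number of chain cells (>= 3).
#' @param D Diffusion coefficient, um^2/s.
#' @param pitch Cell spacing, um.
#' @param slab_volume Volume per cell, uL (cosmetic; hop dynamics are
#'   volume-independent for equal cells).
#' @return A `toy_model` list with the filling-phase `system` and `name`.
#' @export
chain_1d <- function(n_cells, D, pitch, slab_volume = 1e-6) {
  stopifnot(n_cells >= 3, D > 0, pitch > 0)
  k <- mfpt_rate(D, pitch)
  n <- n_cells
  i <- c(seq_len(n - 1), 2:n, seq_len(n), 1)
  j <- c(2:n, seq_len(n - 1), seq_len(n), 1)
  deg <- c(1, rep(2, n - 2), 1)  # interior cells have two neighbours
  x <- c(rep(k, 2 * (n - 1)), -k * deg, -k)  # last -k: reservoir coupling at cell 1
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  b <- c(k, rep(0, n - 1))
  sys <- new_compartment_system(
    A = A, b = b, volumes = rep(slab_volume, n), kinds = rep("ECF", n),
    phase = "filling", equilibrium = rep(1, n), sym_weights = rep(1, n),
    meta = list(toy = "chain_1d", n_cells = n, D = D, pitch = pitch))
  structure(list(system = sys, closed_form = NULL, name = "chain_1d"),
            class = "toy_model")
}

#' Single well-mixed compartment with a clearance sink
#'
#' One compartment of volume `V` drained at `Q` uL/s:
#' \eqn{c(t) = c_0 e^{-Qt/V}}. Exact decay oracle for the clearance term.
#'
#' @param Q Clearance, uL/s.
#' @param V Volume, uL.
#' @param c0 Initial concentration.
#' @return A `toy_model` with the voiding-phase `system` and `closed_form`.
#' @export
single_sink <- function(Q, V, c0 = 1) {
  stopifnot(Q >= 0, V > 0)
  A <- matrix(-Q / V, 1, 1)
  sys <- new_compartment_system(
    A = A, b = 0, volumes = V, kinds = "CAPILLARY", phase = "voiding",
    equilibrium = c0, clearance_ids = 1L, clearance_Q = Q,
    sym_weights = 1, meta = list(toy = "single_sink"))
  structure(list(system = sys,
                 closed_form = function(t) c0 * exp(-Q * t / V),
                 initial = c0, name = "single_sink"),
            class = "toy_model")
}

#' @export
print.toy_model <- function(x, ...) {
  cat(sprintf("<toy_model> %s (%d compartments)\n", x$name, x$system$n))
  invisible(x)
}
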