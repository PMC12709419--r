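# linear interpolation of the first threshold crossing of a sampled series
interp_crossing <- function(times, series, level, strict = TRUE) {
  hit <- if (strict) series > level else series >= level
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  s0 <- series[i - 1]; s1 <- series[i]
  if (s1 == s0) return(t1)
  t0 + (level - s0) / (s1 - s0) * (t1 - t0)
}

fiber_threshold <- function(traj, reference, threshold) {
  fib <- traj$kinds == "FIBER"
  switch(reference,
         external = rep(threshold, sum(fib)),
         equilibrium = threshold * traj$equilibrium[fib])
}

#' Fraction of fiber compartments above a concentration threshold
#'
#' For each sample time, the fraction of fiber compartments whose
#' concentration strictly exceeds their threshold. The threshold may be a
#' scalar or a per-fiber vector (e.g. half of each fiber's own equilibrium
#' value).
#'
#' @param traj A `trajectory`.
#' @param threshold Scalar or per-fiber numeric vector; defaults to half of
#'   each fiber's equilibrium concentration.
#' @return Tibble with `time` and `fraction`.
#' @export
fraction_above <- function(traj, threshold = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  fib <- which(traj$kinds == "FIBER")
  if (is.null(threshold)) threshold <- 0.5 * traj$equilibrium[fib]
  if (length(threshold) == 1) threshold <- rep(threshold, length(fib))
  if (length(threshold) != length(fib)) {
    stop(sprintf("threshold vector has length %d but there are %d fiber compartments",
                 length(threshold), length(fib)))
  }
  above <- sweep(traj$states[, fib, drop = FALSE], 2, threshold, ">")
  tibble::tibble(time = traj$times, fraction = rowMeans(above))
}

#' Mean concentration over fiber compartments
#'
#' @param traj A `trajectory`.
#' @param volume_weighted Weight by compartment volume (default unweighted;
#'   fiber compartments share one volume under the standard presets).
#' @return Tibble with `time` and `mean_concentration`.
#' @export
mean_fiber_concentration <- function(traj, volume_weighted = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  fib <- which(traj$kinds == "FIBER")
  sub <- traj$states[, fib, drop = FALSE]
  m <- if (volume_weighted) {
    as.vector(sub %*% traj$volumes[fib]) / sum(traj$volumes[fib])
  } else {
    rowMeans(sub)
  }
  tibble::tibble(time = traj$times, mean_concentration = m)
}

#' Onset time of anesthetic effect
#'
#' The effect is counted as present when more than `fiber_fraction` (default
#' 50%) of fiber compartments exceed `threshold` (default 50%) of the
#' reference concentration; onset is the earliest such time, refined by
#' linear interpolation of the fraction series between bracketing samples.
#'
#' The default reference is each fiber's own equilibrium concentration
#' (`"equilibrium"`), the convention under which the model reproduces the
#' reported onset times; `"external"` counts against the external unit
#' concentration instead.
#'
#' @param traj A filling-phase `trajectory`.
#' @param reference `"equilibrium"` or `"external"`.
#' @param threshold Concentration threshold as a fraction of the reference.
#' @param fiber_fraction Required fraction of fiber compartments.
#' @return Onset time in seconds, or `NA` if never reached within the run.
#' @export
onset_time <- function(traj, reference = c("equilibrium", "external"),
                       threshold = 0.5, fiber_fraction = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$phase != "filling") stop("onset is defined on a filling trajectory")
  reference <- match.arg(reference)
  thr <- fiber_threshold(traj, reference, threshold)
  fr <- fraction_above(traj, thr)
  interp_crossing(fr$time, fr$fraction, fiber_fraction, strict = TRUE)
}

#' Duration of anesthetic action (washout half-time)
#'
#' Starting from equilibrium, the earliest time at which at least
#' `fiber_fraction` of fiber compartments have fallen below `threshold` of
#' their own initial equilibrium concentration, linearly interpolated between
#' samples.
#'
#' @param traj A voiding-phase `trajectory`.
#' @param initial_equilibrium Initial state the washout started from; defaults
#'   to the trajectory's stored equilibrium. The trajectory's first sample
#'   must match it.
#' @param threshold Fraction of the initial value (default 0.5).
#' @param fiber_fraction Required fraction of fiber compartments (default 0.5).
#' @return Duration in seconds, or `NA` if the criterion is never met.
#' @export
duration_of_action <- function(traj, initial_equilibrium = NULL,
                               threshold = 0.5, fiber_fraction = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$phase != "voiding") stop("duration is defined on a voiding trajectory")
  if (is.null(initial_equilibrium)) initial_equilibrium <- traj$equilibrium
  if (max(abs(traj$states[1, ] - initial_equilibrium)) >
      1e-6 * max(initial_equilibrium)) {
    stop("trajectory does not start at the supplied initial equilibrium")
  }
  fib <- which(traj$kinds == "FIBER")
  thr <- threshold * initial_equilibrium[fib]
  below <- sweep(traj$states[, fib, drop = FALSE], 2, thr, "<")
  frac_below <- rowMeans(below)
  interp_crossing(traj$times, frac_below, fiber_fraction, strict = FALSE)
}

#' Full metric set for one phase
#'
#' Bundles onset or duration with the fraction-above-threshold and mean fiber
#' concentration series.
#'
#' @param traj A `trajectory`.
#' @param reference Threshold reference for the filling phase, see
#'   [onset_time()].
#' @param threshold,fiber_fraction Metric thresholds (both default 0.5).
#' @return An object of class `phase_metrics` with fields `phase`,
#'   `onset_time` or `duration`, `fraction_series`, `mean_fiber_series`,
#'   `thresholds`, `reference` and run metadata.
#' @export
phase_metrics <- function(traj, reference = c("equilibrium", "external"),
                          threshold = 0.5, fiber_fraction = 0.5) {
  stopifnot(inherits(traj, "trajectory"))
  reference <- match.arg(reference)
  if (traj$phase == "filling") {
    onset <- onset_time(traj, reference, threshold, fiber_fraction)
    duration <- NA_real_
    thr <- fiber_threshold(traj, reference, threshold)
    fr <- fraction_above(traj, thr)
  } else {
    onset <- NA_real_
    duration <- duration_of_action(traj, threshold = threshold,
                                   fiber_fraction = fiber_fraction)
    fib <- which(traj$kinds == "FIBER")
    thr <- threshold * traj$equilibrium[fib]
    fr <- fraction_above(traj, thr)
  }
  structure(list(phase = traj$phase,
                 onset_time = onset,
                 duration = duration,
                 fraction_series = fr,
                 mean_fiber_series = mean_fiber_concentration(traj),
                 thresholds = c(fiber_fraction = fiber_fraction,
                                concentration_fraction = threshold),
                 reference = reference,
                 meta = traj$meta),
            class = "phase_metrics")
}

#' @export
print.phase_metrics <- function(x, ...) {
  cat(sprintf("<phase_metrics> %s phase", x$phase))
  if (!is.na(x$onset_time)) cat(sprintf(": onset %.3g s", x$onset_time))
  if (!is.na(x$duration)) cat(sprintf(": duration %.4g s", x$duration))
  cat(sprintf(" (reference %s, thresholds %g/%g)\n", x$reference,
              x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

#' Tidy the metric series of a phase
#'
#' @param x A `phase_metrics` object.
#' @param ... Unused.
#' @return Long tibble with `time`, `series` (`"fraction_above"` or
#'   `"mean_fiber"`), `value`.
#' @export
tidy.phase_metrics <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(time = x$fraction_series$time, series = "fraction_above",
                   value = x$fraction_series$fraction),
    tibble::tibble(time = x$mean_fiber_series$time, series = "mean_fiber",
                   value = x$mean_fiber_series$mean_concentration))
}

#' One-row summary of a phase's metrics
#'
#' @param x A `phase_metrics` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.phase_metrics <- function(x, ...) {
  tibble::tibble(
    drug = x$meta$drug %||% NA_character_,
    condition = x$meta$condition %||% NA_character_,
    phase = x$phase,
    onset_s = x$onset_time,
    duration_s = x$duration,
    reference = x$reference,
    fiber_fraction = x$thresholds[["fiber_fraction"]],
    concentration_fraction = x$thresholds[["concentration_fraction"]])
}

#' @export
autoplot.phase_metrics <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$series, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
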