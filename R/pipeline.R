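#' Fully resolved run configuration
#'
#' Collects every knob of a single drug/condition simulation into one
#' explicit list. Re-resolving a resolved configuration is the identity.
#'
#' @param drug,condition Anesthetic preset selectors (see
#'   [anesthetic_params()]).
#' @param phases Character subset of `c("filling", "voiding")`.
#' @param diameter,pitch,slab_depth,fiber_volume_scale Geometry parameters
#'   (see [hex_fascicle()]).
#' @param method,rel_tol,abs_tol,max_step Solver parameters (see
#'   [solver_settings()]).
#' @param reference Onset threshold reference (see [onset_time()]).
#' @param clearance_in_filling,edge_rate_convention,boundary Assembly flags
#'   (see [build_system()]).
#' @param blood_velocity,cross_section,open_fraction Capillary parameters
#'   (see [capillary_params()]).
#' @param filling_t_end,voiding_t_end Phase horizons in seconds; `NULL` means
#'   automatic (steady-state detection for filling, a multiple of the
#'   well-mixed washout half-life for voiding).
#' @return A list of class `run_config`.
#' @export
scenario_config <- function(drug = "lidocaine",
                            condition = "physiological",
                            phases = c("filling", "voiding"),
                            diameter = 140,
                            pitch = NULL,
                            slab_depth = default_slab_depth(),
                            fiber_volume_scale = NULL,
                            method = "stiff",
                            rel_tol = 1e-8,
                            abs_tol = 1e-12,
                            max_step = 0.001,
                            reference = "equilibrium",
                            clearance_in_filling = TRUE,
                            edge_rate_convention = "per_compartment",
                            boundary = "reservoir",
                            blood_velocity = 0.79,
                            cross_section = 33,
                            open_fraction = 0.75,
                            filling_t_end = NULL,
                            voiding_t_end = NULL) {
  cfg <- as.list(environment())
  cfg$phases <- match.arg(phases, c("filling", "voiding"), several.ok = TRUE)
  # fail early on an unknown preset
  invisible(anesthetic_params(cfg$drug, cfg$condition))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' Unknown keys are an error; missing keys take the [scenario_config()]
#' defaults.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return A resolved `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(scenario_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  }
  do.call(scenario_config, raw)
}

config_geometry <- function(cfg) {
  hex_fascicle(diameter = cfg$diameter, pitch = cfg$pitch,
               slab_depth = cfg$slab_depth,
               fiber_volume_scale = cfg$fiber_volume_scale)
}

config_settings <- function(cfg) {
  solver_settings(method = cfg$method, rel_tol = cfg$rel_tol,
                  abs_tol = cfg$abs_tol, max_step = cfg$max_step)
}

# snapshot times mirroring the reported concentration-map panels
default_snapshot_times <- function(drug, phase) {
  if (phase == "filling") {
    if (drug == "bupivacaine") c(0, 2, 10, 20) else c(0, 1, 5, 10)
  } else {
    if (drug == "bupivacaine") c(0, 100, 500, 1000) else c(0, 10, 50, 100)
  }
}

#' Run one drug/condition scenario end to end
#'
#' Builds the geometry, assembles the phase systems, integrates the requested
#' phases, and computes onset/duration metrics. With `output_dir` set, also
#' writes the geometry CSVs, thinned long-format trajectory CSVs, a metrics
#' JSON, snapshot heatmaps (PNG) at the standard panel times, the fully
#' resolved configuration, and a plain-text log of all resolved parameters;
#' a `FAILED` marker file is left behind if the run errors after starting.
#'
#' @param config A [scenario_config()] or [read_run_config()] result.
#' @param output_dir Optional output directory.
#' @param geometry Optional pre-built [hex_fascicle()] (must match the
#'   configuration; passing one avoids rebuilding in sweeps).
#' @param write_snapshots Write PNG snapshots when `output_dir` is set.
#' @return A list of class `scenario_result`: `config`, `geometry`,
#'   `trajectories` (named list), `metrics` (named list of `phase_metrics`)
#'   and `summary` (one-row tibble).
#' @export
run_scenario <- function(config = scenario_config(), output_dir = NULL,
                         geometry = NULL, write_snapshots = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  marker <- if (!is.null(output_dir)) file.path(output_dir, "FAILED") else NULL

  run <- function() {
    p <- anesthetic_params(config$drug, config$condition)
    cap <- capillary_params(config$blood_velocity, config$cross_section,
                            config$open_fraction)
    g <- if (is.null(geometry)) config_geometry(config) else geometry
    settings <- config_settings(config)

    trajectories <- list()
    metrics <- list()
    if ("filling" %in% config$phases) {
      sys_f <- build_system(g, p, cap, phase = "filling",
                            clearance_in_filling = config$clearance_in_filling,
                            edge_rate_convention = config$edge_rate_convention,
                            boundary = config$boundary)
      trajectories$filling <- run_filling(sys_f, settings,
                                          t_end = config$filling_t_end)
      metrics$filling <- phase_metrics(trajectories$filling,
                                       reference = config$reference)
    }
    if ("voiding" %in% config$phases) {
      sys_v <- build_system(g, p, cap, phase = "voiding",
                            edge_rate_convention = config$edge_rate_convention)
      trajectories$voiding <- run_voiding(sys_v, settings,
                                          t_end = config$voiding_t_end)
      metrics$voiding <- phase_metrics(trajectories$voiding)
    }

    summary <- tibble::tibble(
      drug = config$drug, condition = config$condition,
      onset_s = if (!is.null(metrics$filling)) metrics$filling$onset_time else NA_real_,
      duration_s = if (!is.null(metrics$voiding)) metrics$voiding$duration else NA_real_,
      equilibrium_ratio = equilibrium_ratio(p),
      slab_depth = g$slab_depth,
      fiber_volume_scale = g$fiber_volume_scale)

    res <- structure(list(config = config, geometry = g,
                          trajectories = trajectories, metrics = metrics,
                          summary = summary),
                     class = "scenario_result")
    if (!is.null(output_dir)) {
      write_scenario_outputs(res, output_dir, write_snapshots)
    }
    res
  }

  if (is.null(marker)) return(run())
  tryCatch(run(), error = function(e) {
    writeLines(conditionMessage(e), marker)
    stop(e)
  })
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s / %s\n", x$config$drug, x$config$condition))
  print(x$summary)
  invisible(x)
}

write_scenario_outputs <- function(res, dir, write_snapshots) {
  cfg <- res$config
  write_fascicle(res$geometry, dir)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  for (phase in names(res$trajectories)) {
    traj <- res$trajectories[[phase]]
    thin <- max(1L, floor(length(traj$times) / 200))
    utils::write.csv(tidy(traj, every = thin),
                     file.path(dir, paste0(phase, "_trajectory.csv")),
                     row.names = FALSE)
    m <- res$metrics[[phase]]
    utils::write.csv(tidy(m), file.path(dir, paste0(phase, "_curves.csv")),
                     row.names = FALSE)
    if (write_snapshots) {
      st <- default_snapshot_times(cfg$drug, phase)
      st <- st[st <= max(traj$times)]
      render_snapshots(traj, res$geometry, st, dir = dir,
                       prefix = paste0(phase, "_"))
    }
  }

  metrics_json <- list(
    drug = cfg$drug, condition = cfg$condition,
    onset_s = res$summary$onset_s, duration_s = res$summary$duration_s,
    equilibrium_ratio = res$summary$equilibrium_ratio,
    reference = cfg$reference,
    thresholds = list(fiber_fraction = 0.5, concentration_fraction = 0.5),
    calibration = list(slab_depth = res$geometry$slab_depth,
                       fiber_volume_scale = res$geometry$fiber_volume_scale,
                       pitch = res$geometry$pitch),
    solver = list(method = cfg$method, rel_tol = cfg$rel_tol,
                  abs_tol = cfg$abs_tol),
    package_version = as.character(utils::packageVersion("fasciclesim")))
  jsonlite::write_json(metrics_json, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  log_lines <- c(
    sprintf("fasciclesim %s", utils::packageVersion("fasciclesim")),
    sprintf("%s = %s", names(unclass(cfg)),
            vapply(unclass(cfg), function(v)
              if (is.null(v)) "auto" else paste(format(v, digits = 6),
                                                collapse = ","),
              character(1))),
    sprintf("onset_s = %.6e", res$summary$onset_s),
    sprintf("duration_s = %.6e", res$summary$duration_s))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Concentration snapshot maps at selected times
#'
#' One hex-map raster per requested time, with a single colour scale shared
#' across the whole series so panels are directly comparable. Requested times
#' must lie inside the trajectory range (the nearest sample is drawn).
#'
#' @param traj A `trajectory`.
#' @param geometry The [hex_fascicle()] the trajectory was computed on.
#' @param times Times (s) to render.
#' @param dir Optional directory: plots are written as PNG files.
#' @param prefix File-name prefix when writing.
#' @return Invisibly, a named list of ggplot objects; each carries the shared
#'   scale in `attr(, "fill_limits")`.
#' @export
render_snapshots <- function(traj, geometry, times, dir = NULL, prefix = "") {
  stopifnot(inherits(traj, "trajectory"), inherits(geometry, "fascicle"))
  if (any(times < min(traj$times) - 1e-9 | times > max(traj$times) + 1e-9)) {
    stop(sprintf("snapshot time outside the trajectory range [%g, %g]",
                 min(traj$times), max(traj$times)))
  }
  idx <- vapply(times, function(t) which.min(abs(traj$times - t)), integer(1))
  limits <- range(traj$states[idx, ])
  plots <- list()
  for (k in seq_along(idx)) {
    val <- traj$states[idx[k], ]
    pl <- autoplot(geometry, fill = val) +
      ggplot2::scale_colour_viridis_c(limits = limits) +
      ggplot2::ggtitle(sprintf("%s, t = %g s", traj$phase, times[k]))
    attr(pl, "fill_limits") <- limits
    nm <- sprintf("%st%g", prefix, times[k])
    plots[[nm]] <- pl
    if (!is.null(dir)) {
      ggplot2::ggsave(file.path(dir, paste0(nm, ".png")), pl,
                      width = 5, height = 4.5, dpi = 120)
    }
  }
  invisible(plots)
}

#' Run the full drug-by-condition grid
#'
#' Runs every combination of `drugs` and `conditions` with a shared geometry
#' and returns the comparison table: onset, duration, equilibrium ratio, plus
#' the standard fold-changes (acidosis/physiological onset and duration per
#' drug, and onset prolongation across drugs per condition).
#'
#' @param drugs,conditions Character vectors.
#' @param config Base configuration (drug/condition fields are overridden).
#' @param output_dir Optional root directory; each scenario writes into a
#'   `drug_condition` subdirectory and the comparison table is written as
#'   `comparison.csv`.
#' @return A tibble with one row per scenario; fold-changes are attached as
#'   `attr(, "fold_changes")` and included in the written CSV.
#' @export
run_grid <- function(drugs = c("lidocaine", "bupivacaine"),
                     conditions = c("physiological", "acidosis"),
                     config = scenario_config(),
                     output_dir = NULL) {
  g <- config_geometry(config)
  rows <- list()
  for (d in drugs) for (cond in conditions) {
    cfg <- config
    cfg$drug <- d
    cfg$condition <- cond
    sub <- if (!is.null(output_dir)) file.path(output_dir, paste(d, cond, sep = "_"))
    res <- run_scenario(cfg, output_dir = sub, geometry = g)
    rows[[paste(d, cond)]] <- res$summary
  }
  out <- dplyr::bind_rows(rows)

  folds <- list()
  for (d in intersect(drugs, out$drug)) {
    sub <- out[out$drug == d, ]
    if (all(c("physiological", "acidosis") %in% sub$condition)) {
      phys <- sub[sub$condition == "physiological", ]
      acid <- sub[sub$condition == "acidosis", ]
      folds[[length(folds) + 1]] <- tibble::tibble(
        comparison = c(sprintf("%s onset physiological/acidosis", d),
                       sprintf("%s duration physiological/acidosis", d)),
        fold = c(phys$onset_s / acid$onset_s,
                 phys$duration_s / acid$duration_s))
    }
  }
  if (all(c("lidocaine", "bupivacaine") %in% out$drug)) {
    for (cond in unique(out$condition)) {
      li <- out[out$drug == "lidocaine" & out$condition == cond, ]
      bu <- out[out$drug == "bupivacaine" & out$condition == cond, ]
      if (nrow(li) == 1 && nrow(bu) == 1) {
        folds[[length(folds) + 1]] <- tibble::tibble(
          comparison = sprintf("onset prolongation bupivacaine/lidocaine (%s)", cond),
          fold = bu$onset_s / li$onset_s)
      }
    }
  }
  fold_tab <- dplyr::bind_rows(folds)
  attr(out, "fold_changes") <- fold_tab
  if (!is.null(output_dir)) {
    utils::write.csv(out, file.path(output_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(fold_tab, file.path(output_dir, "fold_changes.csv"),
                     row.names = FALSE)
  }
  out
}

#' Calibrate the slab depth against a target onset time
#'
#' Finds the axial slab depth at which the simulated onset time of one
#' reference scenario (lidocaine, physiological pH by default) equals
#' `target_onset`, by monotone root finding. The fitted value is meant to be
#' frozen (see [default_slab_depth()]) and reused unchanged for every other
#' scenario.
#'
#' @param target_onset Target onset time, seconds.
#' @param drug,condition Reference scenario.
#' @param interval Search interval for the depth, micrometers.
#' @param tol Root tolerance on the depth, micrometers.
#' @param config Base configuration for everything except the depth.
#' @param lockfile Optional path: the fitted value is written as JSON.
#' @return List with `slab_depth`, `achieved_onset`, `target_onset` and the
#'   `uniroot` diagnostics.
#' @export
calibrate_slab_depth <- function(target_onset = 8.69,
                                 drug = "lidocaine",
                                 condition = "physiological",
                                 interval = c(120, 320),
                                 tol = 0.05,
                                 config = scenario_config(),
                                 lockfile = NULL) {
  config$drug <- drug
  config$condition <- condition
  config$phases <- "filling"
  config$filling_t_end <- max(4 * target_onset, 20)
  onset_at <- function(depth) {
    cfg <- config
    cfg$slab_depth <- depth
    res <- run_scenario(cfg)
    on <- res$summary$onset_s
    if (is.na(on)) stop(sprintf("no onset within the horizon at depth %g", depth))
    on
  }
  root <- stats::uniroot(function(d) onset_at(d) - target_onset,
                         interval = interval, tol = tol)
  fit <- list(slab_depth = root$root,
              achieved_onset = root$f.root + target_onset,
              target_onset = target_onset,
              iterations = root$iter,
              drug = drug, condition = condition)
  if (!is.null(lockfile)) {
    jsonlite::write_json(fit, lockfile, auto_unbox = TRUE, digits = NA)
  }
  fit
}
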