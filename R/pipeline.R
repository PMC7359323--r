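# End-to-end pipeline driver: (DEM | synthetic curves) -> psi series ->
# ARIMA T_end -> surrogate, with a manifest recording seeds and file hashes.

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]: `material`, `process` and
#' `geometry` blocks (merged into [material_process_params()] /
#' [vessel_geometry()]), `numerics` (time step safety, snapshot interval,
#' durations), stage toggles, the uniform-mixing `cutoff_psi` and one explicit
#' seed per stochastic stage. Readable from / writable to YAML.
#'
#' @return nested configuration list
#' @export
default_pipeline_config <- function() {
  list(
    stages = list(dem = FALSE, synth_curves = TRUE, forecast = TRUE,
                  surrogate = TRUE),
    material = list(particle_radius = 3e-3, density = 1100, restitution = 0.6,
                    cohesion = 1e4, friction = 0.1, youngs_modulus = 5e6),
    process = list(n_particles = 2000, rpm = 60, cake_height = 0.09),
    geometry = list(vessel_radius = 0.05, blade_count = 2,
                    blade_height = 0.025),
    numerics = list(dt_safety = 0.2, duration_s = 2, snapshot_interval_s = 0.02,
                    settle_time = 0.4, n_regions = 3, contact_tolerance = 1e-3),
    cutoff_psi = 1.1,
    synth = list(n_runs = 40, noise_sd = 0.01, n_points = 150),
    surrogate = list(methods = c("rf", "svr", "plsr", "elastic_net")),
    seeds = list(dem = 1, synth = 2, surrogate = 3))
}

#' Read / write a pipeline configuration as YAML
#' @param file YAML path
#' @param config configuration list
#' @return the configuration (read) or `file` invisibly (write)
#' @export
read_pipeline_config <- function(file) {
  cfg <- utils::modifyList(default_pipeline_config(), yaml::read_yaml(file))
  if (!is.null(cfg$cutoff_psi) && cfg$cutoff_psi <= 1)
    stop("cutoff_psi must exceed 1", call. = FALSE)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}

config_params <- function(cfg) {
  do.call(material_process_params, c(cfg$material, cfg$process))
}

#' Run the integrated mixing pipeline
#'
#' Executes the enabled stages in order and writes each stage's standard files
#' under `out_dir`:
#' * `dem`: one DEM run at the configured parameters ->
#'   `trajectory.csv`, `series_dem.csv`;
#' * `synth_curves`: `n_runs` synthetic mixing curves over a sampled design ->
#'   `series_###.csv`;
#' * `forecast`: [forecast_to_cutoff()] per series -> `endpoint_###.json`;
#' * `surrogate`: feature table + [fit_and_crossvalidate()] +
#'   [permutation_importance()] -> `table.csv`, `surrogate_report.json`.
#'
#' A `manifest.json` records package version, seeds, stage wall-clocks and an
#' md5 hash of every output file. A stage failure halts the pipeline with the
#' prior stages' outputs (and the manifest) intact on disk.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML file path
#' @param out_dir output directory (created if missing)
#' @return list with elements `manifest`, and per executed stage its main
#'   in-memory artifact (`series`, `estimates`, `table`, `report`)
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("granumix_run_")) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    utils::modifyList(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "granumix",
                   version = as.character(utils::packageVersion("granumix")),
                   r_version = R.version.string, seeds = cfg$seeds,
                   cutoff_psi = cfg$cutoff_psi, stages = list(), files = list())
  result <- list()
  flush_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", wall_clock_s = proc.time()[["elapsed"]] - t0)
    flush_manifest()
    r
  }

  series_files <- character()
  series_meta <- list()

  if (isTRUE(cfg$stages$dem)) {
    result$dem <- run_stage("dem", function() {
      params <- config_params(cfg)
      geom <- do.call(vessel_geometry, cfg$geometry)
      contact <- contact_model_params(params, dt_safety = cfg$numerics$dt_safety)
      traj <- run_simulation(params, geom, contact,
                             duration_s = cfg$numerics$duration_s,
                             snapshot_interval_s = cfg$numerics$snapshot_interval_s,
                             seed = cfg$seeds$dem,
                             settle_time = cfg$numerics$settle_time)
      tf <- file.path(out_dir, "trajectory.csv")
      write_trajectory(traj, tf); add_file(tf)
      ser <- series_from_trajectory(traj, n_regions = cfg$numerics$n_regions,
                                    tolerance = cfg$numerics$contact_tolerance)
      sf <- file.path(out_dir, "series_dem.csv")
      write_segregation_series(ser, sf); add_file(sf)
      series_files <<- c(series_files, sf)
      series_meta <<- c(series_meta, list(list(params = params,
                                               provenance = "dem+arima")))
      list(trajectory = traj, series = ser)
    })
  }

  if (isTRUE(cfg$stages$synth_curves)) {
    result$synth <- run_stage("synth_curves", function() {
      design <- synthetic_design_table(n_rows = cfg$synth$n_runs,
                                       response = "noise", noise_sd = 0,
                                       seed = cfg$seeds$synth)
      out <- vector("list", nrow(design))
      for (i in seq_len(nrow(design))) {
        row <- design[i, ]
        # decay rate tied to the descriptors: deeper cakes and larger
        # particles mix in more revolutions
        rate_k <- 0.9 * (0.04 / row$cake_height) * (3e-3 / row$particle_radius)^0.3
        ser <- generate_mixing_curve(psi0 = 1.9, rate_k = rate_k, rpm = row$rpm,
                                     noise_sd = cfg$synth$noise_sd,
                                     n_points = cfg$synth$n_points,
                                     seed = cfg$seeds$synth + i,
                                     cutoff = cfg$cutoff_psi)
        sf <- file.path(out_dir, sprintf("series_%03d.csv", i))
        write_segregation_series(ser, sf); add_file(sf)
        series_files <<- c(series_files, sf)
        params <- do.call(material_process_params,
                          as.list(row[descriptor_names()]))
        series_meta <<- c(series_meta, list(list(params = params,
                                                 provenance = "synthetic")))
        out[[i]] <- ser
      }
      out
    })
  }

  if (isTRUE(cfg$stages$forecast)) {
    result$estimates <- run_stage("forecast", function() {
      lapply(seq_along(series_files), function(i) {
        ser <- read_segregation_series(series_files[i])
        est <- forecast_to_cutoff(ser, cutoff = cfg$cutoff_psi)
        ef <- file.path(out_dir, sprintf("endpoint_%03d.json", i))
        write_endpoint_report(est, ef); add_file(ef)
        est
      })
    })
  }

  if (isTRUE(cfg$stages$surrogate)) {
    if (is.null(result$estimates))
      stop("surrogate stage needs the forecast stage", call. = FALSE)
    result$table <- run_stage("surrogate_table", function() {
      runs <- lapply(seq_along(result$estimates), function(i)
        list(params = series_meta[[i]]$params, estimate = result$estimates[[i]],
             provenance = series_meta[[i]]$provenance))
      tab <- assemble_table(runs)
      tf <- file.path(out_dir, "table.csv")
      write_feature_table(tab, tf); add_file(tf)
      tab
    })
    result$report <- run_stage("surrogate", function() {
      rep <- fit_and_crossvalidate(result$table,
                                   methods = cfg$surrogate$methods,
                                   seed = cfg$seeds$surrogate)
      rep$importances <- permutation_importance(result$table,
                                                seed = cfg$seeds$surrogate)
      rf <- file.path(out_dir, "surrogate_report.json")
      write_surrogate_report(rep, rf); add_file(rf)
      rep
    })
  }

  flush_manifest()
  add_file(file.path(out_dir, "manifest.json"))
  result$manifest <- manifest
  result$out_dir <- out_dir
  result
}
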