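RUN_CONFIG_KEYS <- c("preset", "seed", "paths", "grid", "deselect",
                     "imaging", "segmentation", "packing", "oxygen",
                     "kinetics", "events", "chamber_area_cm2")

#' Build and validate a run configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]: file paths,
#' grid dimensions, stage thresholds and seeds, on top of a scenario
#' preset. Unknown keys are rejected before any stage runs.
#'
#' @param preset Scenario preset name (see [scenario_preset()]).
#' @param paths List with `stage_csv`, `tiles_dir`, `sensor_csv`,
#'   `classifier_json`, `packing_json`, `out_dir`.
#' @param ... Overrides for the remaining keys (`grid`, `deselect`,
#'   `imaging`, `segmentation`, `packing`, `oxygen`, `kinetics`, `events`,
#'   `chamber_area_cm2`, `seed`).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(preset = "cho_culture", paths = list(), ...) {
  cfg <- list(
    preset = preset, seed = 1L, paths = paths,
    grid = list(rows = 6, cols = 5),
    deselect = list(indices = NULL, zones = NULL),
    imaging = list(um_per_px = 1.8, refine = FALSE),
    segmentation = list(min_object_area = 30, max_hole_area = 100),
    packing = list(monolayer_warn_threshold = 0.85),
    oxygen = list(Q_uL_h = 300, c_air_uM = 200, phi0_deg = 55,
                  phi_air_deg = 25, despike_k = 5, smooth_window = 5,
                  outlet_delay_min = 15),
    kinetics = list(window_h = 15, r2_min = 0.95, plateau_min_density = 5e4),
    events = list(min_shift_uM = 10, min_slope_uM_per_h = 10,
                  refractory_h = 2),
    chamber_area_cm2 = 0.8
  )
  over <- list(...)
  bad <- setdiff(names(over), RUN_CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys rejected: ",
                        paste(bad, collapse = ", "))
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(cfg[[k]])) {
      badk <- setdiff(names(over[[k]]), names(cfg[[k]]))
      if (length(badk)) stop(sprintf("unknown config keys rejected: %s$%s",
                                     k, paste(badk, collapse = ", ")))
      cfg[[k]][names(over[[k]])] <- over[[k]]
    } else cfg[[k]] <- over[[k]]
  }
  structure(cfg, class = "run_config")
}

#' Write a complete synthetic fixture set to disk
#'
#' Renders image tiles at the imaging cadence, simulates the three DO
#' channels at the sensor cadence, and writes tiles, stage sheet,
#' ground-truth masks, sensor CSV (with phases), truth CSV and the
#' configuration YAML — everything [run_pipeline()] needs, with known
#' ground truth.
#'
#' @param preset_name Scenario preset name.
#' @param out_dir Output directory.
#' @param seed Master seed for the generator.
#' @param n_image_times Number of imaging time points (spread over the
#'   scenario span).
#' @param geometry A [tile_geometry()].
#' @param culture,sensors,duration_h Optional overrides of the preset's
#'   culture configuration, sensor configuration and simulated span.
#' @return List with paths, the ground truth, and the per-time rendered
#'   truth table.
#' @export
simulate_fixture_set <- function(preset_name = "cho_culture", out_dir,
                                 seed = 1L, n_image_times = 12,
                                 geometry = tile_geometry(),
                                 culture = NULL, sensors = NULL,
                                 duration_h = NULL) {
  ps <- scenario_preset(preset_name, seed = seed)
  if (!is.null(culture)) ps$culture <- culture
  if (!is.null(sensors)) ps$sensors <- sensors
  if (!is.null(duration_h)) ps$duration_h <- duration_h
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cal <- default_calibration()

  img_times <- seq(0, ps$duration_h, length.out = n_image_times)
  truth <- simulate_growth(ps$culture, img_times)
  stage_all <- NULL; render_truth <- NULL
  for (i in seq_along(img_times)) {
    rt <- render_tiles(truth, t_index = i, geometry = geometry)
    st <- write_tile_set(rt, out_dir, prefix = sprintf("t%03d", i))
    stage_all <- rbind(stage_all, st)
    render_truth <- rbind(render_truth, data.frame(
      t_h = img_times[i], n_cells = rt$truth$n_cells,
      confluency = rt$truth$confluency,
      packing_factor = rt$truth$packing_factor,
      density = rt$truth$density))
  }
  write_stage_csv(stage_all, file.path(out_dir, "stage.csv"))

  do_sim <- if (is.null(ps$protocol)) {
    sens_times <- seq(0, ps$duration_h,
                      by = ps$sensors$do_sample_interval_min / 60)
    truth_fine <- simulate_growth(ps$culture, sens_times)
    simulate_do_series(truth_fine, ps$sensors, seed = seed)
  } else {
    simulate_respiratory_assay(ps$protocol, ps$culture, ps$sensors,
                               seed = seed, duration_h = ps$duration_h)
  }
  write_sensor_csv(do_sim, file.path(out_dir, "sensors.csv"), cal)
  write_ground_truth_csv(truth, file.path(out_dir, "truth.csv"))
  yaml::write_yaml(list(preset = preset_name, seed = seed,
                        n_image_times = n_image_times,
                        tile_px = geometry$tile_px,
                        um_per_px = geometry$um_per_px),
                   file.path(out_dir, "config.yaml"))
  list(dir = out_dir, stage = stage_all, truth = truth,
       render_truth = render_truth, do_sim = do_sim, calibration = cal,
       geometry = geometry)
}

#' Run the full analysis pipeline
#'
#' Executes segmentation, density conversion, oxygen calibration and
#' uptake computation, growth kinetics and event detection in order, and
#' writes stage CSVs plus a versioned JSON report. Any missing input stops
#' the run with a message naming the path; partial outputs written before
#' a failing stage are preserved.
#'
#' @param config A [run_config()].
#' @return The report, invisibly also written to
#'   `paths$out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$paths
  for (k in c("stage_csv", "sensor_csv", "classifier_json", "packing_json"))
    if (is.null(p[[k]]) || !file.exists(p[[k]]))
      stop("missing input file for '", k, "': ",
           if (is.null(p[[k]])) "<unset>" else p[[k]])
  dir.create(p$out_dir, recursive = TRUE, showWarnings = FALSE)

  clf <- load_classifier(p$classifier_json)
  pkm <- load_packing_model(p$packing_json)
  stage <- utils::read.csv(p$stage_csv, stringsAsFactors = FALSE)

  # --- segmentation + density, per imaging time point
  density_df <- NULL
  for (t in sort(unique(stage$t_h))) {
    st <- stage[stage$t_h == t, , drop = FALSE]
    tiles <- read_tiles(st, p$tiles_dir)
    img <- stitch(tiles, st, um_per_px = config$imaging$um_per_px,
                  refine = config$imaging$refine)
    mask <- segment(as.matrix(img), clf,
                    min_object_area = config$segmentation$min_object_area,
                    max_hole_area = config$segmentation$max_hole_area)
    grid <- build_grid(dim(mask), config$grid$rows, config$grid$cols)
    grid <- tryCatch(
      deselect_regions(grid, config$deselect$indices, config$deselect$zones),
      error = function(e) stop("region deselection failed: ",
                               conditionMessage(e)))
    cr <- region_confluency(mask, grid)
    pcc <- packing_corrected_confluency(cr$culture_mean, pkm)
    dens <- density_from_pcc(
      pcc, pkm, chamber_area_cm2 = config$chamber_area_cm2,
      raw_confluency = cr$culture_mean,
      monolayer_warn_threshold = config$packing$monolayer_warn_threshold)
    density_df <- rbind(density_df, data.frame(
      t_h = t, confluency = cr$culture_mean, pcc = pcc,
      density_cells_cm2 = dens$density, cell_count = dens$cell_count,
      qc_monolayer = dens$qc_monolayer))
  }
  utils::write.csv(density_df, file.path(p$out_dir, "density.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- oxygen: calibrate, despike, uptake
  cal <- do_calibration(config$oxygen$phi0_deg, config$oxygen$phi_air_deg,
                        config$oxygen$c_air_uM)
  do_wide <- read_sensor_csv(p$sensor_csv, cal, use_phase = TRUE)
  spikes <- despike(do_wide$inlet, do_wide$outlet, k = config$oxygen$despike_k)
  our_raw <- compute_our(config$oxygen$Q_uL_h, do_wide$inlet, do_wide$outlet)
  our_raw <- compensate_outlet_delay(do_wide$time_h, our_raw,
                                     config$oxygen$outlet_delay_min)
  our_s <- smooth_our(our_raw, window = config$oxygen$smooth_window,
                      exclude = spikes)
  dd <- data.frame(t_h = density_df$t_h,
                   density = density_df$density_cells_cm2,
                   cell_count = density_df$cell_count)
  joined <- align_series(
    data.frame(time_h = do_wide$time_h, inlet = do_wide$inlet,
               outlet = do_wide$outlet, insitu = do_wide$insitu,
               our_mol_s = our_s, qc_spike = spikes), dd)
  sour <- compute_sour(joined$our_mol_s, pmax(joined$cell_count, 1))
  sour_df <- cbind(joined[, c("time_h", "density", "cell_count", "qc_spike")],
                   sour)
  utils::write.csv(sour_df, file.path(p$out_dir, "sour.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(time_h = do_wide$time_h, inlet_uM = do_wide$inlet,
               outlet_uM = do_wide$outlet, insitu_uM = do_wide$insitu,
               qc_spike = spikes),
    file.path(p$out_dir, "do_calibrated.csv"), row.names = FALSE, quote = FALSE)

  # --- kinetics + events
  kin <- windowed_mu(data.frame(t_h = density_df$t_h,
                                density = density_df$density_cells_cm2),
                     window_h = config$kinetics$window_h,
                     r2_min = config$kinetics$r2_min)
  svd_curve <- tryCatch(
    sour_vs_density(sour_df,
                    plateau_min_density = config$kinetics$plateau_min_density),
    error = function(e) list(curve = NULL, plateau = NA_real_))
  events <- detect_events(
    data.frame(time_h = do_wide$time_h, conc_uM = do_wide$insitu),
    min_shift_uM = config$events$min_shift_uM,
    min_slope_uM_per_h = config$events$min_slope_uM_per_h,
    refractory_h = config$events$refractory_h)
  utils::write.csv(events, file.path(p$out_dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mu_max_per_h = kin$mu_max, doubling_time_h = kin$g_h,
         lag_h = kin$lag_h, windows = kin$mu_t),
    file.path(p$out_dir, "kinetics.json"), auto_unbox = TRUE, digits = NA)

  report <- list(
    schema_version = "1",
    package_version = as.character(utils::packageVersion("sourflow")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    preset = config$preset,
    inputs_md5 = as.list(tools::md5sum(c(p$stage_csv, p$sensor_csv))),
    n_timepoints = nrow(density_df),
    mu_max_per_h = kin$mu_max,
    doubling_time_h = kin$g_h,
    lag_h = kin$lag_h,
    sour_plateau_amol_cell_s = svd_curve$plateau,
    n_events = nrow(events),
    events = events,
    qc = list(n_spikes_flagged = sum(spikes),
              n_negative_sour = sum(sour_df$negative_flag),
              n_monolayer_flags = sum(density_df$qc_monolayer),
              final_confluency = density_df$confluency[nrow(density_df)])
  )
  jsonlite::write_json(report, file.path(p$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
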