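# File round-tripping: TIFF tiles/masks, CSV tables, JSON models/reports,
# YAML run configuration. All tabular files are RFC-4180 CSV with a header
# row and SI units in the column names.

#' Write a rendered tile set (plus truth) to disk
#'
#' Writes per-tile TIFFs, a stage-position sheet, the ground-truth mask
#' (0/255 TIFF) and the realised truth as CSV for one time point.
#'
#' @param rendered Output of [render_tiles()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, typically encoding the time point.
#' @return Invisibly, the stage data frame with a `file` column added.
#' @export
write_tile_set <- function(rendered, dir, prefix = "t000") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stage <- rendered$stage
  stage$file <- sprintf("%s_%s.tif", prefix, stage$tile_id)
  for (k in seq_along(rendered$tiles))
    tiff::writeTIFF(rendered$tiles[[k]], file.path(dir, stage$file[k]),
                    bits.per.sample = 16)
  tiff::writeTIFF(rendered$mask / 1, file.path(dir, sprintf("%s_mask.tif", prefix)))
  invisible(stage)
}

#' Read tiles listed in a stage-position sheet
#'
#' @param stage Data frame with `file`, `x_um`, `y_um`, `t_h` columns.
#' @param dir Directory holding the TIFF tiles.
#' @return List of intensity matrices in stage order.
#' @export
read_tiles <- function(stage, dir) {
  lapply(stage$file, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing tile file: ", p)
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  })
}

#' @export
write_stage_csv <- function(stage, path) {
  utils::write.csv(stage, path, row.names = FALSE, quote = FALSE)
}

#' Write simulated sensor traces as a sensor CSV
#'
#' Long format `time_h, channel, phase_deg, conc_uM`; the phase column is
#' the reading a sensor calibrated as `cal` would have produced
#' ([phase_from_concentration()]), so the analysis side can exercise its
#' full phase-to-concentration path.
#'
#' @param do_sim A `do_sim` data frame.
#' @param path Output CSV path.
#' @param cal A `do_calibration` used to back-compute phases.
#' @export
write_sensor_csv <- function(do_sim, path, cal) {
  conc <- pmin(SENSOR_MAX_UM, pmax(0, do_sim$conc_uM))
  out <- data.frame(time_h = do_sim$time_h, channel = do_sim$channel,
                    phase_deg = phase_from_concentration(conc, cal),
                    conc_uM = do_sim$conc_uM)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a sensor CSV into per-channel concentration series
#'
#' Accepts either pre-calibrated files (a `conc_uM` column) or raw phase
#' files (`phase_deg`), in which case the calibration is applied.
#'
#' @param path Sensor CSV path.
#' @param cal A `do_calibration` (required when only phases are present).
#' @param use_phase If `TRUE`, convert the `phase_deg` column even when a
#'   `conc_uM` column exists.
#' @return Wide data frame: `time_h`, `inlet`, `outlet`, `insitu` (uM).
#' @export
read_sensor_csv <- function(path, cal = NULL, use_phase = FALSE) {
  if (!file.exists(path)) stop("missing sensor CSV: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (use_phase || !"conc_uM" %in% names(df)) {
    if (is.null(cal)) stop("phase-only sensor file requires a calibration")
    df$conc_uM <- as.numeric(phase_to_do(df$phase_deg, cal))
  }
  wide <- stats::reshape(df[, c("time_h", "channel", "conc_uM")],
                         idvar = "time_h", timevar = "channel",
                         direction = "wide")
  names(wide) <- sub("^conc_uM\\.", "", names(wide))
  wide <- wide[order(wide$time_h), , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

#' @export
write_ground_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE, quote = FALSE)
}

#' Serialise / load a pixel classifier (versioned JSON bundle)
#' @param clf A `pixel_classifier`.
#' @param path JSON path.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "pixel_classifier"))
  jsonlite::write_json(unclass(clf), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  if (!file.exists(path)) stop("missing classifier file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- x$feature_names
  x$center <- stats::setNames(unlist(x$center), nm)
  x$scale <- stats::setNames(unlist(x$scale), nm)
  x$weights <- stats::setNames(unlist(x$weights), nm)
  structure(x, class = "pixel_classifier")
}

#' Serialise / load a packing model as JSON
#' @param model A `packing_model`.
#' @param path JSON path.
#' @export
save_packing_model <- function(model, path) {
  stopifnot(inherits(model, "packing_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname save_packing_model
#' @export
load_packing_model <- function(path) {
  if (!file.exists(path)) stop("missing packing model file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  packing_model(x$mean_cell_footprint_um2, unlist(x$knots_confluency),
                unlist(x$knots_packing), x$provenance)
}
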