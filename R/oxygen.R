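#' Check phase-reading stability for calibration
#'
#' A calibration point may be recorded only once the optical phase reading
#' is stable: variations must not exceed +/- 0.05 degrees (max - min of at
#' most 0.1 degrees) over the trailing 3-minute window.
#'
#' @param time_min Sample times in minutes.
#' @param phase_deg Phase readings in degrees.
#' @param window_min Trailing window length (minutes, default 3).
#' @param band_deg Allowed max - min excursion (degrees, default 0.1).
#' @return `TRUE` iff the trailing window is stable.
#' @export
check_stability <- function(time_min, phase_deg, window_min = 3,
                            band_deg = 0.1) {
  stopifnot(length(time_min) == length(phase_deg))
  if (diff(range(time_min)) < window_min)
    stop(sprintf("window shorter than %g minutes", window_min))
  sel <- time_min >= max(time_min) - window_min
  diff(range(phase_deg[sel])) <= band_deg
}

#' Two-point Stern-Volmer calibration of an optical oxygen sensor
#'
#' Anchors the phase-to-concentration transfer at zero oxygen (sodium
#' sulfite solution, phase `phi0`) and at air saturation (`phi_air`,
#' concentration `c_air_uM`), using the tan-phase Stern-Volmer form for
#' phase-fluorimetric sensors: `tan(phi0) / tan(phi) = 1 + Ksv * C`. Both
#' calibration streams must pass [check_stability()].
#'
#' @param phi0_stream,phi_air_stream Data frames with `time_min`,
#'   `phase_deg` covering at least 3 minutes.
#' @param c_air_uM Dissolved-oxygen concentration at air saturation, uM.
#' @param channel Channel identifier stored with the calibration.
#' @return A `do_calibration`: `phi0_deg`, `phi_air_deg`, `c_air_uM`, `ksv`.
#' @export
two_point_calibrate <- function(phi0_stream, phi_air_stream, c_air_uM = 200,
                                channel = "unknown") {
  if (!check_stability(phi0_stream$time_min, phi0_stream$phase_deg))
    stop("zero-oxygen calibration stream is unstable")
  if (!check_stability(phi_air_stream$time_min, phi_air_stream$phase_deg))
    stop("air-saturation calibration stream is unstable")
  sel0 <- phi0_stream$time_min >= max(phi0_stream$time_min) - 3
  sela <- phi_air_stream$time_min >= max(phi_air_stream$time_min) - 3
  phi0 <- stats::median(phi0_stream$phase_deg[sel0])
  phi_air <- stats::median(phi_air_stream$phase_deg[sela])
  do_calibration(phi0, phi_air, c_air_uM, channel)
}

#' @rdname two_point_calibrate
#' @param phi0_deg,phi_air_deg Calibration anchor phases, degrees;
#'   `phi0 > phi_air` (quenching lowers the phase).
#' @export
do_calibration <- function(phi0_deg, phi_air_deg, c_air_uM = 200,
                           channel = "unknown") {
  check_finite(c(phi0_deg, phi_air_deg, c_air_uM), "calibration anchors")
  if (phi_air_deg >= phi0_deg)
    stop("non-physical calibration: phi_air must be below phi0")
  if (phi0_deg <= 0 || phi0_deg >= 90 || phi_air_deg <= 0)
    stop("phases must lie in (0, 90) degrees")
  if (c_air_uM <= 0) stop("c_air_uM must be positive")
  ksv <- (tan(phi0_deg * pi / 180) / tan(phi_air_deg * pi / 180) - 1) / c_air_uM
  structure(list(phi0_deg = phi0_deg, phi_air_deg = phi_air_deg,
                 c_air_uM = c_air_uM, ksv = ksv, channel = channel,
                 calibrated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "do_calibration")
}

#' Convert sensor phase readings to dissolved-oxygen concentration
#'
#' Inverts the tan-phase Stern-Volmer relation:
#' `C = (tan(phi0)/tan(phi) - 1) / Ksv`, clipped to the sensor range
#' \[0, 1406.25\] uM (0-45 mg/L). Non-finite phases yield `NA` (flagged),
#' not an error.
#'
#' @param phase_deg Phase readings, degrees, in (0, 90).
#' @param cal A `do_calibration`.
#' @return Concentrations in uM, with logical attribute `clipped`.
#' @export
phase_to_do <- function(phase_deg, cal) {
  stopifnot(inherits(cal, "do_calibration"))
  conc <- rep(NA_real_, length(phase_deg))
  ok <- is.finite(phase_deg) & phase_deg > 0 & phase_deg < 90
  conc[ok] <- (tan(cal$phi0_deg * pi / 180) / tan(phase_deg[ok] * pi / 180) - 1) /
    cal$ksv
  clipped <- !is.na(conc) & (conc < 0 | conc > SENSOR_MAX_UM)
  conc <- pmin(SENSOR_MAX_UM, pmax(0, conc))
  structure(conc, clipped = clipped)
}

#' Convert a concentration to the phase a calibrated sensor would read
#'
#' Exact inverse of [phase_to_do()] under the same calibration; used by the
#' simulator to exercise the full phase-to-concentration path.
#'
#' @param conc_uM Concentrations, uM, within the sensor range.
#' @param cal A `do_calibration`.
#' @return Phase in degrees.
#' @export
phase_from_concentration <- function(conc_uM, cal) {
  stopifnot(inherits(cal, "do_calibration"))
  if (any(conc_uM < 0)) stop("concentration must be >= 0")
  if (any(conc_uM > SENSOR_MAX_UM))
    stop(sprintf("concentration above sensor range (%.2f uM)", SENSOR_MAX_UM))
  atan(tan(cal$phi0_deg * pi / 180) / (1 + cal$ksv * conc_uM)) * 180 / pi
}

#' Flag common-mode spike artifacts on the inlet/outlet pair
#'
#' Samples where BOTH channels deviate from their rolling median by more
#' than `k` times the robust residual scale at the same timestamp are
#' flagged as common-mode spikes. Because such spikes hit both sensors
#' identically they cancel in the inlet-outlet differential; flagged
#' samples are excluded from uptake-rate smoothing but the raw differential
#' is retained.
#'
#' @param inlet_uM,outlet_uM Concentration series on common timestamps.
#' @param k Threshold multiplier (default 5).
#' @param window Rolling-median window, samples (odd).
#' @return Logical vector of spike flags.
#' @export
despike <- function(inlet_uM, outlet_uM, k = 5, window = 9) {
  stopifnot(length(inlet_uM) == length(outlet_uM))
  n <- length(inlet_uM)
  if (n < window) window <- max(3, 2 * floor((n - 1) / 2) - 1)
  if (n < 3) return(rep(FALSE, n))
  r_in <- inlet_uM - stats::runmed(inlet_uM, window, endrule = "median")
  r_out <- outlet_uM - stats::runmed(outlet_uM, window, endrule = "median")
  s_in <- max(stats::mad(r_in), 0.05)
  s_out <- max(stats::mad(r_out), 0.05)
  abs(r_in) > k * s_in & abs(r_out) > k * s_out
}

#' Compensate the outlet transport delay
#'
#' An outlet flow-through sensor reads the chamber concentration of
#' `delay_min` minutes earlier (tubing dead volume / flow rate), which
#' biases uptake low while the culture grows. Advancing the series by the
#' known delay removes that bias. Apply it to the inlet-outlet
#' differential (or the uptake rate derived from it), not to the outlet
#' alone: common-mode spike artifacts cancel in the differential at their
#' shared timestamp and must cancel before any re-indexing. Linear
#' interpolation; trailing samples reuse the last value.
#'
#' @param time_h Timestamps, hours.
#' @param x Series to advance (differential or uptake rate).
#' @param delay_min Transport delay, minutes (device geometry).
#' @return The series re-indexed to chamber time.
#' @export
compensate_outlet_delay <- function(time_h, x, delay_min) {
  if (delay_min <= 0) return(x)
  stats::approx(time_h, x, time_h + delay_min / 60, rule = 2)$y
}

#' Bulk oxygen uptake rate from the perfusion mass balance
#'
#' `OUR = Q * (O2_in - O2_out)` with Q converted from uL/h to L/s and
#' concentrations from uM to mol/L. Negative values (outlet above inlet,
#' i.e. noise exceeding the true differential) are propagated so that QC
#' can flag them downstream.
#'
#' @param Q_uL_h Volumetric flow rate, uL h^-1 (> 0).
#' @param inlet_uM,outlet_uM Concentrations, uM.
#' @return OUR in mol s^-1.
#' @export
compute_our <- function(Q_uL_h, inlet_uM, outlet_uM) {
  if (Q_uL_h <= 0) stop("Q must be > 0")
  flow_L_s(Q_uL_h) * (inlet_uM - outlet_uM) * 1e-6
}

#' Specific oxygen uptake rate
#'
#' `sOUR = OUR / X`, reported in amol cell^-1 s^-1. Negative values are
#' kept in the data with `negative_flag = TRUE` (they are measurement
#' artifacts of instrument noise, excluded from default plots but kept
#' auditable).
#'
#' @param our_mol_s Bulk uptake, mol s^-1.
#' @param X Cell count (> 0).
#' @return Data frame: `sour_amol_cell_s`, `negative_flag`, `X_at_t`.
#' @export
compute_sour <- function(our_mol_s, X) {
  if (any(X <= 0)) stop("X must be > 0")
  sour <- our_mol_s / X * AMOL_PER_MOL
  data.frame(sour_amol_cell_s = sour, negative_flag = sour < 0, X_at_t = X)
}

# Centered rolling median of OUR that skips flagged samples.
smooth_our <- function(our, window = 5, exclude = NULL) {
  n <- length(our)
  if (is.null(exclude)) exclude <- rep(FALSE, n)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - half):min(n, i + half)
    idx <- idx[!exclude[idx]]
    out[i] <- if (length(idx)) stats::median(our[idx]) else our[i]
  }
  out
}

#' Join oxygen and density series onto the sensor time grid
#'
#' Density (imaged every 30 min) is linearly interpolated onto the DO
#' timestamps (every 15 min). No extrapolation: DO samples before the first
#' or after the last image are dropped (with a message).
#'
#' @param do_df Data frame with `time_h` plus oxygen columns.
#' @param density_df Data frame with `t_h` and `density` (and optionally
#'   `cell_count`).
#' @return `do_df` restricted to the overlap, with interpolated `density`
#'   (and `cell_count` if present) columns appended.
#' @export
align_series <- function(do_df, density_df) {
  t0 <- min(density_df$t_h); t1 <- max(density_df$t_h)
  keep <- do_df$time_h >= t0 & do_df$time_h <= t1
  if (!any(keep)) stop("disjoint time spans: no overlap between DO and imaging")
  if (any(!keep))
    message(sum(!keep), " DO samples outside the imaging span dropped")
  out <- do_df[keep, , drop = FALSE]
  out$density <- stats::approx(density_df$t_h, density_df$density,
                               out$time_h)$y
  if ("cell_count" %in% names(density_df))
    out$cell_count <- stats::approx(density_df$t_h, density_df$cell_count,
                                    out$time_h)$y
  rownames(out) <- NULL
  out
}
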