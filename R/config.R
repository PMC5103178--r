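#' Culture simulation configuration
#'
#' Defines a simulated adherent culture in the perfused chamber: seeding
#' density, lag and maximal growth rate, geometry of the chamber, perfusion
#' rate, the cells' projected footprint, and the true specific oxygen uptake
#' rate (sOUR) profile that the simulator will impose. These parameters are
#' the ground truth that downstream image and oxygen analysis must recover.
#'
#' @param seeding_density Initial cell density, cells cm^-2 (> 0).
#' @param lag_h Lag-phase duration in hours; density stays at the seeding
#'   value until `lag_h`, then grows exponentially at `mu_max`.
#' @param mu_max Maximal specific growth rate, h^-1 (>= 0).
#' @param saturation_confluency Confluency at which growth saturates,
#'   fraction in (0, 1]. The exponential is smoothly capped so that
#'   confluency never exceeds this value.
#' @param cell_footprint_um2 Length-2 numeric `c(mean, sd)` of the projected
#'   single-cell area in um^2.
#' @param colony_mode Logical; if `TRUE` cells cluster into colonies and the
#'   packing factor rises with confluency, if `FALSE` cells stay isolated
#'   (packing factor 1).
#' @param packing_onset,packing_slope Parameters of the analytic packing
#'   curve used in colony mode: packing(c) = 1 + slope * max(0, c - onset).
#' @param chamber_area_cm2 Growth area of the culture chamber, cm^2.
#' @param chamber_volume_uL Chamber working volume, uL.
#' @param flow_rate_uL_h Perfusion flow rate Q, uL h^-1.
#' @param true_sour_profile Function of time (hours) returning the true sOUR
#'   in amol cell^-1 s^-1 (vectorised).
#' @param rng_seed Integer seed governing all stochastic draws of the
#'   generator; sub-streams are derived per component.
#' @return A validated list of class `culture_sim_config`.
#' @export
culture_sim_config <- function(seeding_density = 3e4,
                               lag_h = 0,
                               mu_max = 0.041,
                               saturation_confluency = 0.95,
                               cell_footprint_um2 = c(mean = 500, sd = 100),
                               colony_mode = FALSE,
                               packing_onset = 0.3,
                               packing_slope = 1.5,
                               chamber_area_cm2 = 0.8,
                               chamber_volume_uL = 25,
                               flow_rate_uL_h = 300,
                               true_sour_profile = function(t) rep(20, length(t)),
                               rng_seed = 1L) {
  num <- c(seeding_density = seeding_density, lag_h = lag_h, mu_max = mu_max,
           saturation_confluency = saturation_confluency,
           chamber_area_cm2 = chamber_area_cm2,
           chamber_volume_uL = chamber_volume_uL,
           flow_rate_uL_h = flow_rate_uL_h,
           packing_onset = packing_onset, packing_slope = packing_slope)
  check_finite(num, "culture_sim_config numeric fields")
  check_finite(cell_footprint_um2, "cell_footprint_um2")
  if (seeding_density <= 0) stop("seeding_density must be > 0")
  if (mu_max < 0) stop("mu_max must be >= 0")
  if (lag_h < 0) stop("lag_h must be >= 0")
  if (saturation_confluency <= 0 || saturation_confluency > 1)
    stop("saturation_confluency must be in (0, 1]")
  if (flow_rate_uL_h <= 0) stop("flow_rate_uL_h must be > 0")
  if (chamber_volume_uL <= 0) stop("chamber_volume_uL must be > 0")
  if (chamber_area_cm2 <= 0) stop("chamber_area_cm2 must be > 0")
  if (length(cell_footprint_um2) != 2 || cell_footprint_um2[1] <= 0)
    stop("cell_footprint_um2 must be c(mean, sd) with mean > 0")
  if (!is.function(true_sour_profile)) stop("true_sour_profile must be a function")
  structure(list(
    seeding_density = seeding_density, lag_h = lag_h, mu_max = mu_max,
    saturation_confluency = saturation_confluency,
    cell_footprint_um2 = c(mean = unname(cell_footprint_um2[1]),
                           sd = unname(cell_footprint_um2[2])),
    colony_mode = isTRUE(colony_mode),
    packing_onset = packing_onset,
    packing_slope = if (isTRUE(colony_mode)) packing_slope else 0,
    chamber_area_cm2 = chamber_area_cm2,
    chamber_volume_uL = chamber_volume_uL,
    flow_rate_uL_h = flow_rate_uL_h,
    true_sour_profile = true_sour_profile,
    rng_seed = as.integer(rng_seed)
  ), class = "culture_sim_config")
}

#' Oxygen sensor simulation configuration
#'
#' Noise, artifact and dynamic-response parameters for the three optical
#' dissolved-oxygen channels (inlet and outlet flow-through cells, in-situ
#' planar sensor).
#'
#' @param noise_sd_uM Gaussian read noise SD per channel, uM.
#' @param spike_rate_per_h Rate of common-mode spike artifacts (events that
#'   hit inlet and outlet simultaneously and identically), events h^-1.
#' @param spike_amplitude_uM Typical spike amplitude, uM.
#' @param insitu_overgrowth_bias Function mapping confluency to the uM
#'   depletion seen by the in-situ sensor due to cells overgrowing it;
#'   `NULL` installs a linear ramp reaching full depletion of
#'   `inlet_setpoint_uM` at `bias_full_confluency`.
#' @param bias_full_confluency Confluency at which the default overgrowth
#'   bias fully depletes the in-situ reading.
#' @param sensor_lag_min First-order sensor response time constant, minutes.
#' @param outlet_transport_delay_min Pure transport delay from chamber to the
#'   outlet flow-through cell, minutes.
#' @param do_sample_interval_min Sensor interrogation interval (default 15).
#' @param image_interval_min Imaging interval (default 30).
#' @param inlet_setpoint_uM Dissolved oxygen of the perfused medium, uM;
#'   must lie within the sensor range 0-1406.25 uM (0-45 mg/L).
#' @return A validated list of class `sensor_sim_config`.
#' @export
sensor_sim_config <- function(noise_sd_uM = 1.5,
                              spike_rate_per_h = 0,
                              spike_amplitude_uM = 30,
                              insitu_overgrowth_bias = NULL,
                              bias_full_confluency = 1.5,
                              sensor_lag_min = 10,
                              outlet_transport_delay_min = 15,
                              do_sample_interval_min = 15,
                              image_interval_min = 30,
                              inlet_setpoint_uM = 215) {
  num <- c(noise_sd_uM, spike_rate_per_h, spike_amplitude_uM, sensor_lag_min,
           outlet_transport_delay_min, do_sample_interval_min,
           image_interval_min, inlet_setpoint_uM, bias_full_confluency)
  check_finite(num, "sensor_sim_config numeric fields")
  if (noise_sd_uM < 0) stop("noise_sd_uM must be >= 0")
  if (do_sample_interval_min <= 0 || image_interval_min <= 0)
    stop("sample intervals must be > 0")
  if (inlet_setpoint_uM < 0 || inlet_setpoint_uM > SENSOR_MAX_UM)
    stop(sprintf("inlet_setpoint_uM must be within the sensor range [0, %.2f] uM",
                 SENSOR_MAX_UM))
  if (is.null(insitu_overgrowth_bias)) {
    setpoint <- inlet_setpoint_uM
    cfull <- bias_full_confluency
    insitu_overgrowth_bias <- function(confluency)
      setpoint * pmin(1, pmax(0, confluency) / cfull)
  }
  if (!is.function(insitu_overgrowth_bias))
    stop("insitu_overgrowth_bias must be a function or NULL")
  structure(list(
    noise_sd_uM = noise_sd_uM, spike_rate_per_h = spike_rate_per_h,
    spike_amplitude_uM = spike_amplitude_uM,
    insitu_overgrowth_bias = insitu_overgrowth_bias,
    bias_full_confluency = bias_full_confluency,
    sensor_lag_min = sensor_lag_min,
    outlet_transport_delay_min = outlet_transport_delay_min,
    do_sample_interval_min = do_sample_interval_min,
    image_interval_min = image_interval_min,
    inlet_setpoint_uM = inlet_setpoint_uM
  ), class = "sensor_sim_config")
}

#' Respiratory assay protocol
#'
#' Ordered medium-switch schedule for a mitochondrial respiration assay:
#' each segment starts at `start_h` and multiplies the culture's baseline
#' sOUR by `sour_multiplier` (e.g. an ATP-synthase inhibitor such as
#' oligomycin gives a multiplier < 1, an uncoupler such as FCCP > 1).
#'
#' @param start_h Strictly increasing segment start times, hours.
#' @param sour_multiplier Positive multiplier applied to the baseline sOUR
#'   within each segment.
#' @param label Per-segment compound name.
#' @return A data frame of class `respiratory_protocol`.
#' @export
respiratory_protocol <- function(start_h = c(0, 2.5, 6),
                                 sour_multiplier = c(1, 0.2, 3),
                                 label = c("baseline", "oligomycin", "FCCP")) {
  if (length(start_h) != length(sour_multiplier) ||
      length(start_h) != length(label))
    stop("start_h, sour_multiplier and label must have equal length")
  check_finite(c(start_h, sour_multiplier), "protocol values")
  if (any(diff(start_h) <= 0))
    stop("segment start times must be strictly increasing (overlap rejected)")
  if (any(sour_multiplier <= 0)) stop("sour_multiplier values must be > 0")
  structure(
    data.frame(start_h = start_h, sour_multiplier = sour_multiplier,
               label = label, stringsAsFactors = FALSE),
    class = c("respiratory_protocol", "data.frame"))
}

protocol_multiplier <- function(protocol, t_h) {
  idx <- findInterval(t_h, protocol$start_h)
  m <- rep(1, length(t_h))
  m[idx > 0] <- protocol$sour_multiplier[idx[idx > 0]]
  m
}
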