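#' Scenario presets
#'
#' Bundled culture/sensor/protocol parameter sets for the three study
#' scenarios:
#' \describe{
#'   \item{cho_culture}{CHO cells seeded at 3e4 cells cm^-2, no lag,
#'     mu_max 0.041 h^-1, isolated-cell morphology, constant true sOUR of
#'     20 amol cell^-1 s^-1, 40 h span.}
#'   \item{mesc_culture}{mouse embryonic stem cells seeded at 5e4 cells
#'     cm^-2, 72 h lag, mu_max 0.035 h^-1, clustered colonies with a steep
#'     packing curve (the monolayer assumption degrades late in these
#'     cultures), true sOUR 10 amol cell^-1 s^-1, 144 h span.}
#'   \item{respiratory_assay}{mESC seeded dense at 5e5 cells cm^-2, no
#'     growth over the 13 h assay, baseline sOUR 6 amol cell^-1 s^-1,
#'     oligomycin (x0.2) at 2.5 h and FCCP (x3) at 6 h.}
#' }
#' Perfusion is 300 uL/h into a ~25 uL chamber in every scenario.
#'
#' @param name Preset name.
#' @param seed Seed stored in the culture config.
#' @return List with elements `culture`, `sensors`, `duration_h`,
#'   `protocol` (assay only).
#' @export
scenario_preset <- function(name = c("cho_culture", "mesc_culture",
                                     "respiratory_assay"),
                            seed = 1L) {
  name <- match.arg(name)
  sensors <- sensor_sim_config(spike_rate_per_h = 0.05)
  switch(name,
    cho_culture = list(
      culture = culture_sim_config(
        seeding_density = 3e4, lag_h = 0, mu_max = 0.041,
        colony_mode = FALSE,
        true_sour_profile = function(t) rep(20, length(t)),
        rng_seed = seed),
      sensors = sensors, duration_h = 40, protocol = NULL),
    mesc_culture = list(
      culture = culture_sim_config(
        seeding_density = 5e4, lag_h = 72, mu_max = 0.035,
        saturation_confluency = 0.9,
        colony_mode = TRUE, packing_onset = 0.3, packing_slope = 7.8,
        true_sour_profile = function(t) rep(10, length(t)),
        rng_seed = seed),
      sensors = sensors, duration_h = 144, protocol = NULL),
    respiratory_assay = list(
      culture = culture_sim_config(
        seeding_density = 5e5, lag_h = 0, mu_max = 0,
        saturation_confluency = 0.9,
        colony_mode = TRUE, packing_onset = 0.3, packing_slope = 7.8,
        true_sour_profile = function(t) rep(6, length(t)),
        rng_seed = seed),
      sensors = sensors, duration_h = 13,
      protocol = respiratory_protocol())
  )
}

#' Default two-point calibration anchors used by the simulator
#'
#' Phase 55 degrees at zero oxygen, 25 degrees at air saturation
#' (200 uM at 37 C, configurable).
#'
#' @param c_air_uM Air-saturation concentration, uM.
#' @param channel Channel id.
#' @export
default_calibration <- function(c_air_uM = 200, channel = "inlet") {
  do_calibration(55, 25, c_air_uM, channel)
}
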