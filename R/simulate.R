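#' Simulate culture growth with known ground truth
#'
#' Generates the true time course of an adherent culture: lag phase at the
#' seeding density, exponential expansion at `mu_max` afterwards, and a
#' smooth cap so that confluency never exceeds the saturation value. The
#' confluency corresponding to a density solves
#' `confluency * packing(confluency) = density * footprint`, with the
#' analytic packing curve of the configuration (identity unless
#' `colony_mode`).
#'
#' @param config A [culture_sim_config()].
#' @param times Sorted, non-negative time points in hours.
#' @return A data frame of class `ground_truth_culture` with columns
#'   `times_h`, `cell_count`, `density` (cells cm^-2), `confluency`,
#'   `packing_factor` and `sour_true` (amol cell^-1 s^-1). The configuration
#'   is attached as attribute `config`.
#' @export
simulate_growth <- function(config, times) {
  stopifnot(inherits(config, "culture_sim_config"))
  check_finite(times, "times")
  if (any(times < 0)) stop("times must be non-negative")
  if (is.unsorted(times)) stop("times must be sorted")

  f_cm2 <- config$cell_footprint_um2[["mean"]] * 1e-8
  grow <- ifelse(times <= config$lag_h, 0, times - config$lag_h)
  dens_exp <- config$seeding_density * exp(config$mu_max * grow)

  conf_unc <- confluency_from_density(dens_exp, config)
  conf <- cap_confluency(conf_unc, config$saturation_confluency)
  pk <- packing_curve_analytic(conf, config)
  density <- conf * pk / f_cm2
  # below the cap the round trip is exact; keep the exponential value there
  # to avoid accumulating solver round-off
  uncapped <- conf_unc <= 0.9 * config$saturation_confluency
  density[uncapped] <- dens_exp[uncapped]

  out <- data.frame(
    times_h = times,
    cell_count = density * config$chamber_area_cm2,
    density = density,
    confluency = conf,
    packing_factor = pk,
    sour_true = config$true_sour_profile(times)
  )
  structure(out, class = c("ground_truth_culture", "data.frame"),
            config = config)
}

packing_curve_analytic <- function(confluency, config) {
  1 + config$packing_slope * pmax(0, confluency - config$packing_onset)
}

# Solve c * (1 + s*max(0, c - c0)) = density * footprint for c (monotone).
confluency_from_density <- function(density, config) {
  A <- density * config$cell_footprint_um2[["mean"]] * 1e-8
  s <- config$packing_slope
  c0 <- config$packing_onset
  if (s == 0) return(A)
  low <- A <= c0
  out <- A
  if (any(!low)) {
    b <- 1 - s * c0
    out[!low] <- (-b + sqrt(b^2 + 4 * s * A[!low])) / (2 * s)
  }
  out
}

# Identity below 0.9*sat, then a C1 monotone exponential approach to sat.
cap_confluency <- function(u, sat) {
  u0 <- 0.9 * sat
  ifelse(u <= u0, u, sat - (sat - u0) * exp(-(u - u0) / (sat - u0)))
}

#' Simulate inlet, outlet and in-situ dissolved-oxygen traces
#'
#' Applies the quasi-steady oxygen mass balance of a perfused chamber: the
#' noise-free outlet concentration is the inlet setpoint minus the uptake
#' differential `sOUR * X / Q` (unit-reconciled, clipped at 0 uM). The
#' outlet additionally sees a pure transport delay and a first-order sensor
#' lag; the in-situ channel sees the undelayed chamber concentration minus
#' an overgrowth bias that grows with confluency. Gaussian read noise is
#' added per channel and spike artifacts are injected at identical
#' timestamps, with identical amplitude, on inlet AND outlet (common mode).
#'
#' @param truth A `ground_truth_culture` from [simulate_growth()].
#' @param sensors A [sensor_sim_config()].
#' @param seed Integer seed for noise and spike draws; defaults to the
#'   culture config seed.
#' @param sour_override Optional vector of true sOUR values on the sensor
#'   time grid (used by the respiratory assay simulator).
#' @param times_h Optional explicit sensor time grid; defaults to the span
#'   of `truth` at `do_sample_interval_min`.
#' @return A long data frame of class `do_sim` with columns `time_h`,
#'   `channel` (inlet/outlet/insitu), `conc_uM`; attributes `spike_times_h`,
#'   `truth_grid` (X, confluency and true sOUR on the sensor grid),
#'   `clipped_events`, and the configs.
#' @export
simulate_do_series <- function(truth, sensors, seed = NULL,
                               sour_override = NULL, times_h = NULL) {
  stopifnot(inherits(truth, "ground_truth_culture"),
            inherits(sensors, "sensor_sim_config"))
  config <- attr(truth, "config")
  if (is.null(seed)) seed <- config$rng_seed
  if (is.null(times_h)) {
    times_h <- seq(min(truth$times_h), max(truth$times_h),
                   by = sensors$do_sample_interval_min / 60)
  }
  X <- stats::approx(truth$times_h, truth$cell_count, times_h, rule = 2)$y
  conf <- stats::approx(truth$times_h, truth$confluency, times_h, rule = 2)$y
  sour <- if (is.null(sour_override))
    stats::approx(truth$times_h, truth$sour_true, times_h, rule = 2)$y
  else sour_override
  stopifnot(length(sour) == length(times_h))

  inlet0 <- rep(sensors$inlet_setpoint_uM, length(times_h))
  delta <- sour_delta_uM(sour, X, config$flow_rate_uL_h)
  chamber <- pmax(0, sensors$inlet_setpoint_uM - delta)
  n_clip_outlet <- sum(sensors$inlet_setpoint_uM - delta < 0)

  # transport delay then first-order sensor response
  delay_h <- sensors$outlet_transport_delay_min / 60
  outlet0 <- stats::approx(times_h + delay_h, chamber, times_h, rule = 2)$y
  outlet0 <- first_order_filter(outlet0, times_h, sensors$sensor_lag_min)

  bias <- sensors$insitu_overgrowth_bias(conf)
  insitu0 <- pmax(0, chamber - bias)
  n_clip_insitu <- sum(chamber - bias < 0)
  insitu0 <- first_order_filter(insitu0, times_h, sensors$sensor_lag_min)

  sim <- with_seed(substream_seed(seed, "sensors"), {
    n <- length(times_h)
    noise <- function() if (sensors$noise_sd_uM > 0)
      stats::rnorm(n, 0, sensors$noise_sd_uM) else numeric(n)
    inlet <- inlet0 + noise()
    outlet <- outlet0 + noise()
    insitu <- insitu0 + noise()
    span_h <- diff(range(times_h))
    n_spikes <- if (sensors$spike_rate_per_h > 0)
      stats::rpois(1, sensors$spike_rate_per_h * span_h) else 0L
    spike_idx <- integer(0)
    if (n_spikes > 0) {
      spike_idx <- sort(sample(seq_len(n), min(n_spikes, n)))
      amp <- sensors$spike_amplitude_uM * stats::runif(length(spike_idx), 0.5, 1.5)
      inlet[spike_idx] <- inlet[spike_idx] + amp
      outlet[spike_idx] <- outlet[spike_idx] + amp
    }
    list(inlet = inlet, outlet = outlet, insitu = insitu, spike_idx = spike_idx)
  })

  out <- data.frame(
    time_h = rep(times_h, 3),
    channel = rep(c("inlet", "outlet", "insitu"), each = length(times_h)),
    conc_uM = c(sim$inlet, sim$outlet, sim$insitu),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("do_sim", "data.frame"),
            spike_times_h = times_h[sim$spike_idx],
            truth_grid = data.frame(time_h = times_h, X = X,
                                    confluency = conf, sour_true = sour),
            clipped_events = c(outlet = n_clip_outlet, insitu = n_clip_insitu),
            culture_config = config, sensor_config = sensors)
}

#' Simulate a respiratory (mitochondrial inhibitor/uncoupler) assay
#'
#' Runs the DO simulator with the culture's baseline sOUR multiplied per
#' protocol segment. A multiplier < 1 (respiration inhibited) makes the
#' in-situ oxygen rise towards a plateau; a multiplier > 1 (uncoupled,
#' maximal respiration) makes it fall. Transitions are smoothed by the
#' sensor time constant.
#'
#' @inheritParams simulate_do_series
#' @param protocol A [respiratory_protocol()].
#' @param config A [culture_sim_config()] for the assayed culture.
#' @return A `do_sim` data frame (see [simulate_do_series()]) with attribute
#'   `true_event_times_h`: the medium-switch times after the first segment.
#' @export
simulate_respiratory_assay <- function(protocol, config, sensors, seed = NULL,
                                       duration_h = 13) {
  stopifnot(inherits(protocol, "respiratory_protocol"),
            inherits(config, "culture_sim_config"))
  if (max(protocol$start_h) >= duration_h)
    stop("protocol segments must start within the simulated span")
  times <- seq(0, duration_h, by = sensors$do_sample_interval_min / 60)
  truth <- simulate_growth(config, times)
  mult <- protocol_multiplier(protocol, times)
  sim <- simulate_do_series(truth, sensors, seed = seed,
                            sour_override = truth$sour_true * mult,
                            times_h = times)
  attr(sim, "true_event_times_h") <- protocol$start_h[-1]
  attr(sim, "protocol") <- protocol
  sim
}
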