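test_that("growth simulation matches the closed-form exponential", {
  cfg <- culture_sim_config(seeding_density = 3e4, lag_h = 0, mu_max = 0.041,
                            saturation_confluency = 1)
  tr <- simulate_growth(cfg, c(0, 40))
  expect_equal(tr$density[2], 3e4 * exp(0.041 * 40), tolerance = 1e-9)
  expect_equal(tr$density[2], 1.547e5, tolerance = 1e-3)

  # zero growth rate: density constant at the seeding value
  tr0 <- simulate_growth(culture_sim_config(mu_max = 0), c(0, 10, 100))
  expect_true(all(tr0$density == 3e4))

  # lag definition: density at t = lag equals the seeding density
  trl <- simulate_growth(
    culture_sim_config(seeding_density = 5e4, lag_h = 72, mu_max = 0.035),
    c(0, 36, 72, 73))
  expect_equal(trl$density[3], 5e4)
  expect_gt(trl$density[4], 5e4)
})

test_that("growth is capped so confluency never exceeds saturation", {
  cfg <- culture_sim_config(seeding_density = 3e4, mu_max = 0.05,
                            saturation_confluency = 0.8)
  tr <- simulate_growth(cfg, seq(0, 200, by = 5))
  expect_true(all(tr$confluency <= 0.8 + 1e-12))
  expect_true(all(diff(tr$density) >= -1e-9))  # monotone during growth
})

test_that("invalid culture configurations are rejected with messages", {
  expect_error(culture_sim_config(seeding_density = -1), "seeding_density")
  expect_error(culture_sim_config(mu_max = NaN), "finite")
  expect_error(culture_sim_config(saturation_confluency = 1.2),
               "saturation_confluency")
  expect_error(culture_sim_config(flow_rate_uL_h = 0), "flow_rate")
  expect_error(simulate_growth(culture_sim_config(), c(3, 1)), "sorted")
})

test_that("rendered masks hit the requested confluency and stay consistent", {
  # zero confluency renders pure background
  r0 <- sf_render(0, 1)
  expect_equal(sum(r0$mask), 0)

  # painted-pixel count defines mask confluency
  r <- sf_render(0.3, 42)
  expect_equal(r$truth$confluency, sum(r$mask) / length(r$mask))
  expect_lt(abs(r$truth$confluency - 0.3), 0.02)

  # overlapping strips of neighbouring tiles show identical content
  g <- tile_geometry(tile_px = 128, n_tiles = c(1, 2), overlap = 0.1)
  rr <- sf_render(0.25, 5, geometry = g)
  ov <- g$tile_px - g$step_px
  left_strip <- rr$tiles[[1]][, (g$tile_px - ov + 1):g$tile_px]
  right_strip <- rr$tiles[[2]][, 1:ov]
  expect_identical(left_strip, right_strip)

  # unachievable confluency errors, naming the maximum
  cfg <- culture_sim_config(seeding_density = 0.95 / (500 * 1e-8), mu_max = 0,
                            saturation_confluency = 1)
  expect_error(render_tiles(simulate_growth(cfg, 0), 1), "0.92")
})

test_that("mask confluency tracks the request across seeds (property)", {
  set.seed(321)
  for (seed in 1:20) {
    conf <- stats::runif(1, 0.05, 0.8)  # seed-independent of renderer stream
    r <- sf_render(conf, 1000 + seed)
    expect_lt(abs(r$truth$confluency - conf), 0.02)
  }
})

test_that("colony mode clusters cells and raises the packing factor", {
  # same cell density in both modes: clustered cells overlap, so the same
  # count paints less area (higher packing factor, lower confluency)
  ri <- sf_render(0.4, 11, colony = FALSE)
  rc <- sf_render(0.4, 11, colony = TRUE)
  expect_equal(rc$truth$n_cells, ri$truth$n_cells)
  expect_gt(rc$truth$packing_factor, ri$truth$packing_factor)
  expect_lt(rc$truth$confluency, ri$truth$confluency)
})

test_that("rendering is deterministic for identical config and seed", {
  a <- sf_render(0.35, 99)
  b <- sf_render(0.35, 99)
  expect_identical(a$canvas, b$canvas)
  expect_identical(a$mask, b$mask)
})

test_that("quasi-steady mass balance sets the outlet concentration", {
  # 20 amol/cell/s at X = 8.333e4 cells and Q = 300 uL/h depletes 20 uM
  cfg <- sf_steady_culture(X = 8.3333e4, sour = 20)
  sens <- sensor_sim_config(noise_sd_uM = 0, spike_rate_per_h = 0)
  tr <- simulate_growth(cfg, seq(0, 5, by = 0.25))
  w <- sf_wide(simulate_do_series(tr, sens))
  expect_equal(w$inlet, rep(215, nrow(w)))
  expect_equal(w$outlet, rep(195, nrow(w)), tolerance = 1e-6)

  # no cells: outlet equals inlet
  cfg0 <- culture_sim_config(seeding_density = 1e-9, mu_max = 0,
                             true_sour_profile = function(t) rep(0, length(t)))
  w0 <- sf_wide(simulate_do_series(simulate_growth(cfg0, seq(0, 5, 0.25)), sens))
  expect_equal(w0$outlet, w0$inlet, tolerance = 1e-9)
})

test_that("mass conservation holds in noise-free traces", {
  sens <- sensor_sim_config(noise_sd_uM = 0, spike_rate_per_h = 0)
  for (sour in c(5, 60, 500)) {
    cfg <- culture_sim_config(seeding_density = 3e4, mu_max = 0.041,
                              saturation_confluency = 1,
                              true_sour_profile = function(t)
                                rep(sour, length(t)))
    w <- sf_wide(simulate_do_series(simulate_growth(cfg, seq(0, 40, 0.25)),
                                    sens))
    expect_true(all(w$outlet <= w$inlet + 1e-9))
    expect_true(all(w$outlet >= 0))
    expect_true(all(w$insitu >= 0))
  }
})

test_that("spikes are common mode: the differential is untouched", {
  cfg <- sf_steady_culture(sour = 20, seed = 4)
  tr <- simulate_growth(cfg, seq(0, 20, 0.25))
  spiky <- sensor_sim_config(noise_sd_uM = 1, spike_rate_per_h = 0.5)
  quiet <- sensor_sim_config(noise_sd_uM = 1, spike_rate_per_h = 0)
  w1 <- sf_wide(simulate_do_series(tr, spiky, seed = 8))
  w0 <- sf_wide(simulate_do_series(tr, quiet, seed = 8))
  expect_gt(length(attr(simulate_do_series(tr, spiky, seed = 8),
                        "spike_times_h")), 0)
  expect_equal(w1$inlet - w1$outlet, w0$inlet - w0$outlet, tolerance = 1e-12)
})

test_that("DO simulation is bit-identical under identical config and seed", {
  cfg <- sf_steady_culture(seed = 2)
  tr <- simulate_growth(cfg, seq(0, 10, 0.25))
  sens <- sensor_sim_config(spike_rate_per_h = 0.2)
  a <- simulate_do_series(tr, sens, seed = 77)
  b <- simulate_do_series(tr, sens, seed = 77)
  expect_identical(a$conc_uM, b$conc_uM)
})

test_that("respiratory assay reduces to the plain simulation at multiplier 1", {
  ps <- scenario_preset("respiratory_assay", seed = 6)
  flat <- respiratory_protocol(0, 1, "baseline")
  sim <- simulate_respiratory_assay(flat, ps$culture, ps$sensors, seed = 6)
  times <- seq(0, 13, by = 0.25)
  tr <- simulate_growth(ps$culture, times)
  ref <- simulate_do_series(tr, ps$sensors, seed = 6, times_h = times)
  expect_equal(sim$conc_uM, ref$conc_uM, tolerance = 1e-12)
})

test_that("inhibitor and uncoupler move the in-situ oxygen as mass balance demands", {
  ps <- scenario_preset("respiratory_assay", seed = 9)
  sens0 <- sensor_sim_config(noise_sd_uM = 0, spike_rate_per_h = 0)
  sim <- simulate_respiratory_assay(respiratory_protocol(), ps$culture,
                                    sens0, seed = 9)
  w <- sf_wide(sim)
  oligo <- w$time_h > 2.5 & w$time_h <= 3.5
  fccp <- w$time_h > 6 & w$time_h <= 7
  expect_true(all(diff(w$insitu[oligo]) > 0))  # reduced uptake -> O2 rises
  expect_true(all(diff(w$insitu[fccp]) < 0))   # uncoupled uptake -> O2 falls
  expect_error(respiratory_protocol(c(0, 2.5, 2.5), c(1, 0.2, 3),
                                    c("a", "b", "c")),
               "strictly increasing")
})

test_that("phase and concentration are exact inverses under one calibration", {
  cal <- default_calibration()
  expect_equal(phase_from_concentration(0, cal), cal$phi0_deg)
  expect_equal(as.numeric(phase_to_do(cal$phi0_deg, cal)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(phase_to_do(cal$phi_air_deg, cal)), cal$c_air_uM,
               tolerance = 1e-9)
  conc <- c(0, 5, 80, 200, 900)
  expect_equal(as.numeric(phase_to_do(phase_from_concentration(conc, cal), cal)),
               conc, tolerance = 1e-9)
  expect_error(phase_from_concentration(2000, cal), "sensor range")
  expect_error(phase_from_concentration(-1, cal), ">= 0")
})
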