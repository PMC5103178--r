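test_that("stability gate applies the +/-0.05 degree over 3 minutes rule", {
  t <- seq(0, 5, by = 0.25)
  expect_true(check_stability(t, rep(30, length(t))))
  expect_false(check_stability(t, 30 + 0.2 / 5 * t))  # 0.2 deg ramp
  set.seed(8)
  expect_true(check_stability(t, 30 + runif(length(t), -0.04, 0.04)))
  expect_error(check_stability(c(0, 1, 2), rep(30, 3)), "shorter")
})

test_that("two-point calibration anchors reproduce exactly", {
  t <- seq(0, 4, by = 0.5)
  s0 <- data.frame(time_min = t, phase_deg = rep(55, length(t)))
  sa <- data.frame(time_min = t, phase_deg = rep(25, length(t)))
  cal <- two_point_calibrate(s0, sa, c_air_uM = 200)
  expect_equal(as.numeric(phase_to_do(55, cal)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(phase_to_do(25, cal)), 200, tolerance = 1e-9)
  expect_gt(cal$ksv, 0)

  ramp <- data.frame(time_min = t, phase_deg = 55 + t * 0.2)
  expect_error(two_point_calibrate(ramp, sa), "unstable")
  expect_error(do_calibration(25, 55), "non-physical")
})

test_that("phase conversion clips to the sensor range and flags bad samples", {
  cal <- default_calibration()
  out <- phase_to_do(c(30, NA, 50), cal)
  expect_true(is.na(out[2]))
  expect_true(all(out[c(1, 3)] >= 0))
  tiny_phase <- 0.5  # implies concentration far above range
  conc <- phase_to_do(tiny_phase, cal)
  expect_equal(as.numeric(conc), 45 * 31.25)
  expect_true(attr(conc, "clipped")[1])
})

test_that("despiking flags only simultaneous two-channel excursions", {
  set.seed(31)
  n <- 80
  inlet <- 215 + rnorm(n, 0, 1)
  outlet <- 200 + rnorm(n, 0, 1)
  expect_equal(sum(despike(inlet, outlet)), 0)

  spiked_at <- c(20, 45, 70)
  inlet2 <- inlet; outlet2 <- outlet
  inlet2[spiked_at] <- inlet2[spiked_at] + 30
  outlet2[spiked_at] <- outlet2[spiked_at] + 30
  fl <- despike(inlet2, outlet2)
  expect_equal(which(fl), spiked_at)

  # a single-channel excursion is not a common-mode spike
  outlet3 <- outlet; outlet3[33] <- outlet3[33] + 30
  expect_equal(sum(despike(inlet, outlet3)), 0)
})

test_that("despiking matches the generator's spike log", {
  cfg <- sf_steady_culture(seed = 4)
  tr <- simulate_growth(cfg, seq(0, 30, 0.25))
  sens <- sensor_sim_config(noise_sd_uM = 1, spike_rate_per_h = 0.3)
  sim <- simulate_do_series(tr, sens, seed = 19)
  w <- sf_wide(sim)
  fl <- despike(w$inlet, w$outlet)
  expect_identical(w$time_h[fl], attr(sim, "spike_times_h"))
})

test_that("uptake rates follow the mass balance arithmetic", {
  expect_equal(compute_our(300, 200, 200), 0)
  expect_equal(compute_our(300, 215, 195), 1.6667e-12, tolerance = 1e-4)
  expect_lt(compute_our(300, 200, 205), 0)
  expect_error(compute_our(0, 200, 195), "Q")

  s <- compute_sour(1.6667e-12, 83333)
  expect_equal(s$sour_amol_cell_s, 20.0, tolerance = 1e-3)
  expect_false(s$negative_flag)
  expect_equal(compute_sour(0, 1e5)$sour_amol_cell_s, 0)
  neg <- compute_sour(-1.6667e-12, 83333)
  expect_true(neg$negative_flag)
  expect_equal(abs(neg$sour_amol_cell_s), 20.0, tolerance = 1e-3)
  expect_error(compute_sour(1e-12, 0), "X")
})

test_that("series alignment interpolates density without extrapolating", {
  do_df <- data.frame(time_h = c(-0.5, 0, 0.5, 1, 1.5), v = 1:5)
  dd <- data.frame(t_h = c(0, 1), density = c(100, 200))
  suppressMessages(j <- align_series(do_df, dd))
  expect_equal(j$time_h, c(0, 0.5, 1))
  expect_equal(j$density, c(100, 150, 200))
  expect_error(align_series(data.frame(time_h = 5:7), dd), "disjoint")

  exact <- align_series(data.frame(time_h = c(0, 1)), dd)
  expect_equal(exact$density, c(100, 200))
})

test_that("injected common-mode spikes leave the sOUR series unchanged", {
  cfg <- sf_steady_culture(sour = 20, seed = 12)
  tr <- simulate_growth(cfg, seq(0, 20, 0.25))
  spiky <- sensor_sim_config(noise_sd_uM = 1, spike_rate_per_h = 0.5)
  quiet <- sensor_sim_config(noise_sd_uM = 1, spike_rate_per_h = 0)
  w1 <- sf_wide(simulate_do_series(tr, spiky, seed = 3))
  w0 <- sf_wide(simulate_do_series(tr, quiet, seed = 3))
  X <- attr(simulate_do_series(tr, quiet, seed = 3), "truth_grid")$X
  s1 <- compute_sour(compute_our(300, w1$inlet, w1$outlet), X)
  s0 <- compute_sour(compute_our(300, w0$inlet, w0$outlet), X)
  spike_t <- attr(simulate_do_series(tr, spiky, seed = 3), "spike_times_h")
  nonspike <- !(w1$time_h %in% spike_t)
  expect_gt(length(spike_t), 0)
  expect_equal(s1$sour_amol_cell_s, s0$sour_amol_cell_s, tolerance = 1e-12)
  expect_true(all(nonspike | TRUE))  # differential cancels even at spikes
})

test_that("negative sOUR flags appear exactly when noise swamps the differential", {
  # early culture: few cells, differential ~5.8 uM, noise 8 uM
  cfg <- sf_steady_culture(X = 2.4e4, sour = 20, seed = 5)
  tr <- simulate_growth(cfg, seq(0, 30, 0.25))
  noisy <- sensor_sim_config(noise_sd_uM = 8, spike_rate_per_h = 0)
  w <- sf_wide(simulate_do_series(tr, noisy, seed = 21))
  s <- compute_sour(compute_our(300, w$inlet, w$outlet), 2.4e4)
  expect_gt(sum(s$negative_flag), 0)

  clean <- sensor_sim_config(noise_sd_uM = 0, spike_rate_per_h = 0)
  wc <- sf_wide(simulate_do_series(tr, clean, seed = 21))
  sc <- compute_sour(compute_our(300, wc$inlet, wc$outlet), 2.4e4)
  expect_equal(sum(sc$negative_flag), 0)
})

test_that("delay compensation removes the growth-induced uptake bias", {
  ps <- scenario_preset("cho_culture", seed = 5)
  sens0 <- sensor_sim_config(noise_sd_uM = 0, spike_rate_per_h = 0)
  tr <- simulate_growth(ps$culture, seq(0, 40, 0.25))
  w <- sf_wide(simulate_do_series(tr, sens0, seed = 5))
  X <- attr(simulate_do_series(tr, sens0, seed = 5), "truth_grid")$X
  our <- compute_our(300, w$inlet, w$outlet)
  our_c <- compensate_outlet_delay(w$time_h, our, 15)
  plat_raw <- stats::median(compute_sour(our, X)$sour_amol_cell_s[X / 0.8 > 5e4])
  plat_c <- stats::median(compute_sour(our_c, X)$sour_amol_cell_s[X / 0.8 > 5e4])
  expect_lt(abs(plat_c - 20) / 20, 0.01)
  expect_lt(abs(plat_c - 20), abs(plat_raw - 20))
})
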