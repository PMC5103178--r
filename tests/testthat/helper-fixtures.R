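# Shared fixtures, memoized so expensive renders/training run once per suite.
.sf_cache <- new.env(parent = emptyenv())

# single-time render at a requested confluency (isolated cells by default)
sf_render <- function(confluency, seed, colony = FALSE,
                      geometry = tile_geometry()) {
  cfg <- culture_sim_config(
    seeding_density = max(confluency, 1e-9) / (500 * 1e-8), mu_max = 0,
    saturation_confluency = 1, colony_mode = colony,
    packing_slope = if (colony) 3 else 0, rng_seed = seed)
  render_tiles(simulate_growth(cfg, 0), t_index = 1,
               geometry = geometry, seed = seed)
}

# five labelled training renders spanning the confluency range
sf_training_set <- function() {
  if (is.null(.sf_cache$train)) {
    confs <- c(0.05, 0.2, 0.4, 0.6, 0.8)
    .sf_cache$train <- lapply(seq_along(confs),
                              function(i) sf_render(confs[i], 200 + i))
  }
  .sf_cache$train
}

sf_classifier <- function() {
  if (is.null(.sf_cache$clf)) {
    tr <- sf_training_set()
    .sf_cache$clf <- train_pixel_classifier(
      lapply(tr, `[[`, "canvas"), lapply(tr, `[[`, "mask"), seed = 7)
  }
  .sf_cache$clf
}

sf_packing_fixtures <- function() {
  if (is.null(.sf_cache$pkfix)) {
    confs <- c(0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.7, 0.8)
    area <- prod(tile_geometry()$canvas_px) * 1.8^2 * 1e-8
    .sf_cache$pkfix <- lapply(seq_along(confs), function(i) {
      r <- sf_render(confs[i], 300 + i)
      list(mask = r$mask, n_cells = r$truth$n_cells, area_cm2 = area)
    })
  }
  .sf_cache$pkfix
}

sf_packing_model <- function() {
  if (is.null(.sf_cache$pkm)) {
    .sf_cache$pkm <- calibrate_packing(sf_packing_fixtures())
  }
  .sf_cache$pkm
}

# long do_sim -> wide channels
sf_wide <- function(do) {
  d <- as.data.frame(do)
  data.frame(time_h = unique(d$time_h),
             inlet = d$conc_uM[d$channel == "inlet"],
             outlet = d$conc_uM[d$channel == "outlet"],
             insitu = d$conc_uM[d$channel == "insitu"])
}

# steady-state culture producing a fixed cell count X and constant sOUR
sf_steady_culture <- function(X = 8.3333e4, sour = 20, area = 0.8, seed = 1) {
  culture_sim_config(seeding_density = X / area, mu_max = 0,
                     saturation_confluency = 1,
                     chamber_area_cm2 = area,
                     true_sour_profile = function(t) rep(sour, length(t)),
                     rng_seed = seed)
}
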