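test_that("stitching places tiles exactly from stage coordinates", {
  # a single tile stitches to itself
  tl <- matrix(runif(64 * 64), 64, 64)
  st <- data.frame(tile_id = "t1", x_um = 0, y_um = 0, t_h = 0)
  expect_equal(unclass(stitch(list(tl), st))[, ], tl, ignore_attr = TRUE)

  # two tiles with exact 10% overlap: placement error 0, identical content
  g <- tile_geometry(tile_px = 64, n_tiles = c(1, 2), overlap = 0.1)
  rr <- sf_render(0.3, 21, geometry = g)
  out <- stitch(rr$tiles, rr$stage, um_per_px = g$um_per_px)
  expect_equal(dim(out), as.integer(g$canvas_px))
  expect_equal(unclass(out)[, ], rr$canvas, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cross-correlation refinement recovers jittered stage positions", {
  g <- tile_geometry(tile_px = 96, n_tiles = c(2, 2), overlap = 0.15)
  rr <- sf_render(0.4, 33, geometry = g)
  jit <- rr$stage
  set.seed(14)
  dx <- sample(-3:3, nrow(jit), replace = TRUE)
  dy <- sample(-3:3, nrow(jit), replace = TRUE)
  dx[1] <- dy[1] <- 0  # anchor tile
  jit$x_um <- jit$x_um + dx * g$um_per_px
  jit$y_um <- jit$y_um + dy * g$um_per_px
  out <- stitch(rr$tiles, jit, um_per_px = g$um_per_px,
                refine = TRUE, search_px = 4)
  off <- attr(out, "offsets_px")
  true_off <- attr(stitch(rr$tiles, rr$stage, um_per_px = g$um_per_px),
                   "offsets_px")
  resid <- abs((off$row0 - off$row0[1]) - (true_off$row0 - true_off$row0[1])) +
    abs((off$col0 - off$col0[1]) - (true_off$col0 - true_off$col0[1]))
  expect_true(all(resid <= 1))
})

test_that("non-overlapping tile sets leave flagged gaps", {
  tl <- matrix(0.5, 32, 32)
  st <- data.frame(tile_id = c("a", "b"), x_um = c(0, 100 * 1.8),
                   y_um = c(0, 0), t_h = 0)
  expect_warning(out <- stitch(list(tl, tl), st), "gap")
  expect_true(anyNA(out))
})

test_that("the analysis grid partitions the image", {
  g <- build_grid(c(6800, 15300), rows = 47, cols = 15)
  expect_equal(g$rows * g$cols, 705)

  g1 <- build_grid(c(100, 100), 1, 1)
  expect_equal(diff(g1$row_breaks), 100)

  g2 <- build_grid(c(100, 100), 2, 2)
  expect_equal(diff(g2$row_breaks), c(50, 50))
  expect_equal(diff(g2$col_breaks), c(50, 50))

  # partition property: disjoint regions whose union is the image
  g3 <- build_grid(c(97, 53), 7, 5)
  covered <- matrix(0L, 97, 53)
  for (r in seq_len(7)) for (cc in seq_len(5)) {
    rows <- (g3$row_breaks[r] + 1):g3$row_breaks[r + 1]
    cols <- (g3$col_breaks[cc] + 1):g3$col_breaks[cc + 1]
    covered[rows, cols] <- covered[rows, cols] + 1L
  }
  expect_true(all(covered == 1L))
  expect_error(build_grid(c(4, 4), 5, 5), "more regions")
  expect_error(build_grid(c(100, 3), 2, 5), "exceed")
})

test_that("region deselection updates retained counts and guards emptiness", {
  g <- build_grid(c(6800, 15300), 47, 15)
  des <- read.csv(system.file("extdata", "chamber_deselection_synthetic_47x15.csv",
                              package = "sourflow"))
  g2 <- deselect_regions(g, indices = des$region_index)
  expect_equal(sum(!g2$retained), 198)
  expect_equal(sum(g2$retained), 507)

  expect_equal(sum(deselect_regions(g, indices = NULL)$retained), 705)
  g3 <- deselect_regions(g, indices = 2:705)
  expect_equal(sum(g3$retained), 1)
  expect_error(deselect_regions(g, indices = 1:705), "no analyzable area")
  expect_error(deselect_regions(g, indices = 706), "out of range")

  # geometric exclusion zones discard intersecting regions
  gz <- deselect_regions(build_grid(c(100, 100), 2, 2),
                         zones = list(c(1, 10, 1, 10)))
  expect_equal(sum(gz$retained), 3)
})

test_that("feature stack behaves on degenerate and structured inputs", {
  const <- matrix(0.5, 40, 40)
  fs <- extract_features(const)
  expect_true(all(fs[, , "sd_s2"] == 0))
  expect_true(all(fs[, , "sd_s5"] == 0))
  expect_true(all(fs[, , "grad_mag"] == 0))
  expect_true(all(abs(fs[, , "log"]) < 1e-12))
  expect_true(all(is.finite(fs)))

  # step edge: gradient magnitude peaks on the edge line
  step <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  fstep <- extract_features(step)
  gm <- fstep[, , "grad_mag"]
  expect_true(all(gm[, 20] >= apply(gm[, -c(20, 21)], 1, max)))

  # halo rim carries a stronger LoG response than background
  r <- sf_render(0.2, 55)
  fr <- extract_features(r$canvas)
  rim <- sourflow:::dilate_binary(r$mask > 0, 2) & !(r$mask > 0)
  expect_gt(stats::median(abs(fr[, , "log"][rim])),
            stats::median(abs(fr[, , "log"][!rim & !(r$mask > 0)])))
})

test_that("classifier training is deterministic and honest about chance", {
  # linearly separable toy problem reaches perfect training accuracy
  set.seed(5)
  img <- matrix(rep(c(0.2, 0.8), each = 200), 20, 20)
  lab <- matrix(rep(c(1, 0), each = 200), 20, 20)
  clf <- train_pixel_classifier(img, lab, seed = 3, n_per_class = 150)
  expect_equal(clf$holdout_accuracy, 1)

  # permuted labels score at chance over 10 seeds
  tr <- sf_training_set()[[3]]
  accs <- sapply(1:10, function(s) {
    set.seed(s)
    perm <- matrix(sample(tr$mask), nrow(tr$mask), ncol(tr$mask))
    suppressWarnings(
      train_pixel_classifier(tr$canvas, perm, seed = s,
                             n_per_class = 1500))$holdout_accuracy
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)

  # generator fixtures: held-out pixel accuracy at least 0.9
  expect_gte(sf_classifier()$holdout_accuracy, 0.9)

  # single-class labels are rejected
  expect_error(train_pixel_classifier(img, matrix(0, 20, 20), seed = 1),
               "both classes")

  # determinism
  a <- train_pixel_classifier(img, lab, seed = 3, n_per_class = 150)
  expect_identical(a$weights, clf$weights)
})

test_that("segmentation recovers confluency and is deterministic", {
  clf <- sf_classifier()

  blank <- sf_render(0, 2)
  expect_equal(sum(segment(blank$canvas, clf)), 0)

  r <- sf_render(0.3, 77)
  m <- segment(r$canvas, clf)
  expect_lt(abs(mean(m) - mean(r$mask)), 0.05)
  expect_identical(segment(r$canvas, clf), m)
})

test_that("confluency error stays within 5% from sparse to packed layers", {
  clf <- sf_classifier()
  for (conf in c(0.05, 0.4, 0.8)) {
    r <- sf_render(conf, round(conf * 1000) + 3)
    m <- segment(r$canvas, clf)
    expect_lt(abs(mean(m) - mean(r$mask)), 0.05)
  }
})

test_that("stitch-then-segment equals segment-then-stitch away from seams", {
  clf <- sf_classifier()
  g <- tile_geometry(tile_px = 96, n_tiles = c(1, 2), overlap = 0.1)
  rr <- sf_render(0.3, 61, geometry = g)
  whole <- segment(rr$canvas, clf, min_object_area = 0, max_hole_area = 0)
  parts <- lapply(rr$tiles, segment, clf = clf,
                  min_object_area = 0, max_hole_area = 0)
  stitched_mask <- stitch(lapply(parts, function(m) unclass(m) * 1), rr$stage,
                          um_per_px = g$um_per_px, method = "max")
  # compare interior pixels at least 8 px from any tile edge
  interior <- matrix(FALSE, g$canvas_px[1], g$canvas_px[2])
  interior[9:(g$canvas_px[1] - 8),
           c(9:(g$step_px - 8), (g$tile_px + 9):(g$canvas_px[2] - 8))] <- TRUE
  expect_equal(unclass(stitched_mask)[interior], as.numeric(whole[interior]))
})
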