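#' Tile geometry for the synthetic chamber canvas
#'
#' @param tile_px Square tile side in pixels.
#' @param n_tiles Integer `c(ny, nx)` tiles covering the chamber canvas.
#' @param overlap Fractional overlap between neighbouring tiles.
#' @param um_per_px Microscope calibration, micrometres per pixel.
#' @export
tile_geometry <- function(tile_px = 128, n_tiles = c(2, 2), overlap = 0.1,
                          um_per_px = 1.8) {
  stopifnot(tile_px >= 16, length(n_tiles) == 2, all(n_tiles >= 1),
            overlap >= 0, overlap < 0.5, um_per_px > 0)
  step <- round(tile_px * (1 - overlap))
  structure(list(tile_px = as.integer(tile_px),
                 n_tiles = as.integer(n_tiles),
                 overlap = overlap, um_per_px = um_per_px,
                 step_px = as.integer(step),
                 canvas_px = as.integer(step * (n_tiles - 1) + tile_px)),
            class = "tile_geometry")
}

canvas_area_cm2 <- function(geometry) {
  prod(geometry$canvas_px) * geometry$um_per_px^2 * 1e-8
}

# Paint a rotated ellipse into logical matrix M; returns updated M.
paint_ellipse <- function(M, cy, cx, a, b, theta) {
  H <- nrow(M); W <- ncol(M)
  r <- ceiling(max(a, b))
  rows <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  cols <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(rows) || !length(cols)) return(M)
  dy <- rows - cy; dx <- cols - cx
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(y, x) (x * ct + y * st) / a)
  v <- outer(dy, dx, function(y, x) (-x * st + y * ct) / b)
  M[rows, cols] <- M[rows, cols] | (u^2 + v^2 <= 1)
  M
}

MAX_RENDER_CONFLUENCY <- 0.92

#' Render phase contrast-like tiles with ground-truth masks
#'
#' Draws the culture at one time point as dark textured ellipses with a
#' bright halo rim on a noisy background (stylised phase-contrast
#' appearance, not physics-based optics), returning the per-pixel
#' ground-truth mask alongside the tiles and their stage metadata. The cell
#' count equals the true density times the canvas area; cell areas are then
#' rescaled (a few bisection passes) so the painted fraction matches the
#' true confluency to within 2% absolute. In colony mode new cells are
#' preferentially placed in contact with existing ones.
#'
#' @param truth A `ground_truth_culture` from [simulate_growth()].
#' @param t_index Row of `truth` to render.
#' @param geometry A [tile_geometry()].
#' @param seed Integer seed; default derives from the culture seed and
#'   `t_index` so each time point gets an independent sub-stream.
#' @return List with `tiles` (list of intensity matrices in \[0,1\]),
#'   `stage` (data frame: tile_id, x_um, y_um, t_h), `mask` (canvas-sized
#'   0/1 ground truth), `canvas` (stitched-truth intensity image), `truth`
#'   (realised n_cells, confluency, packing_factor, density) and `geometry`.
#' @export
render_tiles <- function(truth, t_index = 1, geometry = tile_geometry(),
                         seed = NULL) {
  stopifnot(inherits(truth, "ground_truth_culture"),
            inherits(geometry, "tile_geometry"))
  config <- attr(truth, "config")
  row <- truth[t_index, ]
  conf_target <- row$confluency
  if (conf_target < 0 || conf_target > 1)
    stop("requested confluency must be in [0, 1]")
  if (conf_target > MAX_RENDER_CONFLUENCY)
    stop(sprintf(
      "requested confluency %.3f exceeds the maximum achievable %.2f given the cell footprint",
      conf_target, MAX_RENDER_CONFLUENCY))
  if (is.null(seed)) seed <- config$rng_seed + 101L * t_index
  H <- geometry$canvas_px[1]; W <- geometry$canvas_px[2]
  n_cells <- round(row$density * canvas_area_cm2(geometry))

  res <- with_seed(substream_seed(seed, "render"), {
    mask <- matrix(FALSE, H, W)
    cells <- NULL
    if (n_cells > 0) {
      f_px <- config$cell_footprint_um2[["mean"]] / geometry$um_per_px^2
      sd_px <- config$cell_footprint_um2[["sd"]] / geometry$um_per_px^2
      areas <- pmax(0.25 * f_px, stats::rnorm(n_cells, f_px, sd_px))
      aspect <- stats::runif(n_cells, 0.6, 1)
      theta <- stats::runif(n_cells, 0, pi)
      cy <- numeric(n_cells); cx <- numeric(n_cells)
      reff <- sqrt(areas / pi)
      target_painted <- conf_target * H * W
      painted <- 0
      for (i in seq_len(n_cells)) {
        cluster <- config$colony_mode && i > 1 &&
          painted > target_painted * (i - 1) / n_cells
        if (cluster) {
          j <- sample.int(i - 1, 1)
          d <- stats::runif(1, 0.5, 1.0) * (reff[i] + reff[j])
          ang <- stats::runif(1, 0, 2 * pi)
          cy[i] <- min(max(cy[j] + d * sin(ang), 1), H)
          cx[i] <- min(max(cx[j] + d * cos(ang), 1), W)
        } else {
          best <- c(stats::runif(1, 1, H), stats::runif(1, 1, W)); best_d <- -1
          for (try in seq_len(60)) {
            py <- stats::runif(1, 1, H); px <- stats::runif(1, 1, W)
            dmin <- if (i == 1) Inf else
              min(sqrt((cy[1:(i - 1)] - py)^2 + (cx[1:(i - 1)] - px)^2) -
                    (reff[1:(i - 1)] + reff[i]))
            if (dmin > best_d) { best <- c(py, px); best_d <- dmin }
            if (dmin > 2) break
          }
          cy[i] <- best[1]; cx[i] <- best[2]
        }
        a <- sqrt(areas[i] / (pi * aspect[i])); b <- aspect[i] * a
        mask <- paint_ellipse(mask, cy[i], cx[i], a, b, theta[i])
        painted <- sum(mask)
      }
      # rescale cell areas so painted fraction matches the true confluency
      scale_lo <- 0.5; scale_hi <- 2; s <- 1
      repaint <- function(s) {
        m <- matrix(FALSE, H, W)
        for (i in seq_len(n_cells)) {
          a <- sqrt(s * areas[i] / (pi * aspect[i])); b <- aspect[i] * a
          m <- paint_ellipse(m, cy[i], cx[i], a, b, theta[i])
        }
        m
      }
      # tight tolerance: the realised footprint (painted / count) must stay
      # consistent across the confluency range for density calibration
      tol <- max(0.002, 0.004 * conf_target)
      for (pass in seq_len(12)) {
        frac <- sum(mask) / (H * W)
        if (abs(frac - conf_target) <= tol) break
        if (frac < conf_target) scale_lo <- s else scale_hi <- s
        s <- (scale_lo + scale_hi) / 2
        mask <- repaint(s)
      }
      cells <- data.frame(cy = cy, cx = cx, area_px = s * areas,
                          aspect = aspect, theta = theta)
    }
    # stylised PCM appearance: bright halo rim just outside the dark body
    rim <- dilate_binary(mask, 2) & !mask
    img <- matrix(0.55, H, W) + matrix(stats::rnorm(H * W, 0, 0.05), H, W)
    img[rim] <- 0.82 + stats::rnorm(sum(rim), 0, 0.04)
    img[mask] <- 0.33 + stats::rnorm(sum(mask), 0, 0.06)
    img <- matrix(pmin(1, pmax(0, as.numeric(EBImage::gblur(img, sigma = 0.7)))),
                  H, W)
    list(mask = mask, img = img, cells = cells)
  })

  mask <- res$mask
  conf_real <- sum(mask) / (H * W)
  mean_area <- if (n_cells > 0) mean(res$cells$area_px) else NA_real_
  packing_real <- if (n_cells > 0 && conf_real > 0)
    max(1, n_cells * mean_area / sum(mask)) else 1

  # cut tiles from the canvas (overlap strips therefore render identically)
  tiles <- list(); stage <- NULL
  k <- 0
  for (iy in seq_len(geometry$n_tiles[1])) {
    for (ix in seq_len(geometry$n_tiles[2])) {
      k <- k + 1
      r0 <- (iy - 1) * geometry$step_px
      c0 <- (ix - 1) * geometry$step_px
      tiles[[k]] <- res$img[r0 + seq_len(geometry$tile_px),
                            c0 + seq_len(geometry$tile_px)]
      stage <- rbind(stage, data.frame(
        tile_id = sprintf("t%03d", k),
        x_um = c0 * geometry$um_per_px,
        y_um = r0 * geometry$um_per_px,
        t_h = row$times_h))
    }
  }
  list(tiles = tiles, stage = stage,
       mask = matrix(as.integer(mask), H, W),
       canvas = res$img,
       truth = list(n_cells = n_cells, confluency = conf_real,
                    packing_factor = packing_real,
                    density = n_cells / canvas_area_cm2(geometry)),
       geometry = geometry)
}

# binary dilation by a square structuring element of half-width r (shift-OR)
dilate_binary <- function(m, r = 1) {
  out <- m
  for (dr in -r:r) for (dc in -r:r) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_edge(m, dr, dc)
  }
  out
}

# shift with edge replication
shift_edge <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dr, 1), H)
  ci <- pmin(pmax(seq_len(W) - dc, 1), W)
  m[ri, ci, drop = FALSE]
}
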