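#' Stitch tiles into a chamber image using stage coordinates
#'
#' Places each tile by translating its calibrated stage position into image
#' space (row-major, origin top-left, 0-based micrometre offsets divided by
#' the um-per-pixel scalar). Overlapping pixels are resolved by feathered
#' averaging (weights taper towards tile edges) or, for binary masks, by
#' taking the maximum. An optional cross-correlation refinement searches a
#' small window around the nominal placement of each tile against the
#' mosaic built so far.
#'
#' @param tiles List of intensity matrices sharing one acquisition time.
#' @param stage Data frame with `x_um`, `y_um` per tile (same order).
#' @param um_per_px Stage-to-image calibration scalar.
#' @param flip_y If `TRUE` the stage y axis points opposite to image rows.
#' @param refine If `TRUE`, refine each tile placement by maximising the
#'   Pearson correlation with the current mosaic within `search_px`.
#' @param search_px Half-width of the refinement search window, pixels.
#' @param method `"feather"` (weighted average, for intensities) or
#'   `"max"` (for masks).
#' @return The stitched matrix. Gap pixels not covered by any tile are `NA`
#'   (a warning is emitted). Attribute `offsets_px` holds the final placement
#'   (1-based top-left row/col) per tile.
#' @export
stitch <- function(tiles, stage, um_per_px = 1.8, flip_y = FALSE,
                   refine = FALSE, search_px = 3,
                   method = c("feather", "max")) {
  method <- match.arg(method)
  stopifnot(is.list(tiles), length(tiles) >= 1, nrow(stage) == length(tiles))
  check_finite(um_per_px, "um_per_px")
  if ("t_h" %in% names(stage) && length(unique(stage$t_h)) > 1)
    stop("all tiles must share the same acquisition time")

  col0 <- round(stage$x_um / um_per_px)
  row0 <- round(stage$y_um / um_per_px)
  if (flip_y) row0 <- -row0
  row0 <- row0 - min(row0); col0 <- col0 - min(col0)

  hs <- vapply(tiles, nrow, 1L); ws <- vapply(tiles, ncol, 1L)
  H <- max(row0 + hs); W <- max(col0 + ws)
  pad <- if (refine) search_px else 0
  H <- H + 2 * pad; W <- W + 2 * pad
  num <- matrix(0, H, W); den <- matrix(0, H, W)
  offs <- data.frame(row0 = integer(length(tiles)), col0 = integer(length(tiles)))

  for (k in seq_along(tiles)) {
    tl <- tiles[[k]]
    h <- nrow(tl); w <- ncol(tl)
    r <- row0[k] + pad; cc <- col0[k] + pad
    if (refine && k > 1) {
      adj <- refine_offset(num, den, tl, r, cc, search_px)
      r <- r + adj[1]; cc <- cc + adj[2]
    }
    wgt <- if (method == "feather")
      outer(pmin(seq_len(h), rev(seq_len(h))), pmin(seq_len(w), rev(seq_len(w))), pmin)
    else matrix(1, h, w)
    rows <- r + seq_len(h); cols <- cc + seq_len(w)
    keep <- rows >= 1 & rows <= H
    keepc <- cols >= 1 & cols <= W
    if (method == "max") {
      num[rows[keep], cols[keepc]] <- pmax(num[rows[keep], cols[keepc]],
                                           tl[keep, keepc])
      den[rows[keep], cols[keepc]] <- 1
    } else {
      num[rows[keep], cols[keepc]] <- num[rows[keep], cols[keepc]] +
        tl[keep, keepc] * wgt[keep, keepc]
      den[rows[keep], cols[keepc]] <- den[rows[keep], cols[keepc]] +
        wgt[keep, keepc]
    }
    offs$row0[k] <- r; offs$col0[k] <- cc
  }
  out <- num / den
  out[den == 0] <- NA_real_
  # trim refinement padding rows/cols that stayed empty
  cover_r <- which(rowSums(den) > 0); cover_c <- which(colSums(den) > 0)
  out <- out[min(cover_r):max(cover_r), min(cover_c):max(cover_c), drop = FALSE]
  offs$row0 <- offs$row0 - min(cover_r) + 1
  offs$col0 <- offs$col0 - min(cover_c) + 1
  if (anyNA(out)) warning("stitched image contains gap pixels (flagged as NA)")
  structure(out, offsets_px = offs)
}

# best (dr, dc) within +-search maximising correlation over the overlap
refine_offset <- function(num, den, tile, r, cc, search_px) {
  H <- nrow(num); W <- ncol(num)
  mosaic <- num / ifelse(den > 0, den, NA)
  best <- c(0L, 0L); best_cor <- -Inf
  h <- nrow(tile); w <- ncol(tile)
  for (dr in -search_px:search_px) for (dc in -search_px:search_px) {
    rows <- r + dr + seq_len(h); cols <- cc + dc + seq_len(w)
    ok_r <- rows >= 1 & rows <= H; ok_c <- cols >= 1 & cols <= W
    if (sum(ok_r) < 4 || sum(ok_c) < 4) next
    sub <- mosaic[rows[ok_r], cols[ok_c]]
    tsub <- tile[ok_r, ok_c]
    idx <- !is.na(sub)
    if (sum(idx) < 50) next
    cr <- suppressWarnings(stats::cor(sub[idx], tsub[idx]))
    if (is.finite(cr) && cr > best_cor) { best_cor <- cr; best <- c(dr, dc) }
  }
  best
}

#' Partition an image into a rectangular analysis grid
#'
#' Divides the stitched chamber image into `rows` x `cols` contiguous
#' regions of interest (the culture-wide default mirrors a 47 x 15 grid);
#' remainder pixels are absorbed by edge regions. Regions are indexed
#' row-major.
#'
#' @param image Matrix, or integer `c(H, W)` image dimension.
#' @param rows,cols Grid dimensions (>= 1).
#' @return A `region_grid`: rows, cols, pixel break vectors, image dim, and
#'   a `retained` logical per region (all `TRUE` initially).
#' @export
build_grid <- function(image, rows = 47, cols = 15) {
  dm <- if (is.matrix(image)) dim(image) else as.integer(image)
  stopifnot(length(dm) == 2, rows >= 1, cols >= 1)
  if (rows * cols > prod(dm))
    stop("grid has more regions than the image has pixels")
  if (rows > dm[1] || cols > dm[2])
    stop("grid dimensions exceed image dimensions")
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    row_breaks = round(seq(0, dm[1], length.out = rows + 1)),
    col_breaks = round(seq(0, dm[2], length.out = cols + 1)),
    dim = dm,
    retained = rep(TRUE, rows * cols)
  ), class = "region_grid")
}

#' @export
print.region_grid <- function(x, ...) {
  cat(sprintf("region_grid: %d x %d = %d regions (%d retained, %d discarded) on %d x %d px\n",
              x$rows, x$cols, x$rows * x$cols, sum(x$retained),
              sum(!x$retained), x$dim[1], x$dim[2]))
  invisible(x)
}

n_regions <- function(grid) grid$rows * grid$cols

#' De-select analysis regions
#'
#' Marks regions as discarded, either by row-major index or by geometric
#' exclusion zones (pixel rectangles, e.g. the in-situ oxygen sensor
#' location or uneven chamber edges). A region intersecting any zone is
#' discarded.
#'
#' @param grid A [build_grid()] result.
#' @param indices Integer region indices (row-major) to discard.
#' @param zones List of `c(row_min, row_max, col_min, col_max)` pixel
#'   rectangles.
#' @return The grid with updated `retained` flags.
#' @export
deselect_regions <- function(grid, indices = NULL, zones = NULL) {
  stopifnot(inherits(grid, "region_grid"))
  idx <- integer(0)
  if (!is.null(indices)) {
    indices <- as.integer(indices)
    if (any(indices < 1 | indices > n_regions(grid)))
      stop("region indices out of range")
    idx <- c(idx, indices)
  }
  if (!is.null(zones)) {
    for (z in zones) {
      stopifnot(length(z) == 4)
      for (r in seq_len(grid$rows)) for (cc in seq_len(grid$cols)) {
        rr <- c(grid$row_breaks[r] + 1, grid$row_breaks[r + 1])
        cr <- c(grid$col_breaks[cc] + 1, grid$col_breaks[cc + 1])
        if (rr[1] <= z[2] && rr[2] >= z[1] && cr[1] <= z[4] && cr[2] >= z[3])
          idx <- c(idx, (r - 1) * grid$cols + cc)
      }
    }
  }
  grid$retained[unique(idx)] <- FALSE
  if (!any(grid$retained)) stop("no analyzable area: all regions discarded")
  grid
}
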