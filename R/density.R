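#' Per-region and culture-wide confluency from a segmentation mask
#'
#' Confluency of a region is the ratio of cell pixels to total pixels; the
#' culture-wide value is the unweighted arithmetic mean over retained
#' regions (discarded regions are excluded).
#'
#' @param mask 0/1 segmentation mask congruent with the grid's image.
#' @param grid A [build_grid()] region grid (with retained flags).
#' @return List of class `confluency_record`: `per_region` (row-major
#'   fractions, `NA` for discarded regions), `culture_mean`, `retained`.
#' @export
region_confluency <- function(mask, grid) {
  stopifnot(inherits(grid, "region_grid"))
  mask <- unclass(mask)
  if (!all(dim(mask) == grid$dim))
    stop("mask and grid are not congruent")
  per <- numeric(n_regions(grid))
  k <- 0
  for (r in seq_len(grid$rows)) {
    rows <- (grid$row_breaks[r] + 1):grid$row_breaks[r + 1]
    for (cc in seq_len(grid$cols)) {
      k <- k + 1
      cols <- (grid$col_breaks[cc] + 1):grid$col_breaks[cc + 1]
      npx <- length(rows) * length(cols)
      if (npx == 0) stop("grid contains a zero-pixel region")
      per[k] <- sum(mask[rows, cols]) / npx
    }
  }
  res <- per
  res[!grid$retained] <- NA_real_
  structure(list(per_region = res,
                 culture_mean = mean(per[grid$retained]),
                 retained = grid$retained),
            class = "confluency_record")
}

#' Construct a packing model
#'
#' Maps confluency to a packing factor (>= 1, monotone non-decreasing): how
#' much denser than isolated cells the cells pack inside clusters. Together
#' with the mean single-cell footprint this converts confluency into cell
#' density.
#'
#' @param mean_cell_footprint_um2 Mean projected single-cell area, um^2.
#' @param knots_confluency,knots_packing Monotone piecewise-linear packing
#'   curve (at most 5 knots); constant extrapolation beyond the knots.
#' @param provenance Free-form calibration metadata.
#' @export
packing_model <- function(mean_cell_footprint_um2,
                          knots_confluency = c(0, 1),
                          knots_packing = c(1, 1),
                          provenance = list()) {
  if (!is.finite(mean_cell_footprint_um2) || mean_cell_footprint_um2 <= 0)
    stop("mean cell footprint must be positive")
  stopifnot(length(knots_confluency) == length(knots_packing),
            length(knots_confluency) >= 2, length(knots_confluency) <= 5)
  if (is.unsorted(knots_confluency, strictly = TRUE))
    stop("confluency knots must be strictly increasing")
  if (any(knots_packing < 1) || is.unsorted(knots_packing))
    stop("packing factors must be >= 1 and monotone non-decreasing")
  structure(list(mean_cell_footprint_um2 = mean_cell_footprint_um2,
                 knots_confluency = knots_confluency,
                 knots_packing = knots_packing,
                 provenance = provenance),
            class = "packing_model")
}

packing_factor <- function(model, confluency) {
  stats::approx(model$knots_confluency, model$knots_packing, confluency,
                rule = 2)$y
}

#' Packing-corrected confluency (PCC)
#'
#' `PCC = confluency * packing(confluency)`; equal to the raw confluency in
#' the isolated-cell regime where the packing factor is 1.
#'
#' @param mask A 0/1 segmentation mask, or a numeric confluency fraction.
#' @param model A calibrated [packing_model()].
#' @return PCC fraction(s).
#' @export
packing_corrected_confluency <- function(mask, model) {
  if (!inherits(model, "packing_model")) stop("model is not calibrated")
  conf <- if (is.matrix(mask)) sum(unclass(mask) > 0) / length(mask)
          else as.numeric(mask)
  conf * packing_factor(model, conf)
}

#' Cell density from packing-corrected confluency
#'
#' `density = PCC / footprint` (cells cm^-2); cell count is density times
#' the chamber growth area. When the raw confluency exceeds
#' `monolayer_warn_threshold` the record is flagged: the monolayer
#' assumption underlying the PCC conversion is then unreliable (dense,
#' 3-D-like colonies).
#'
#' @param pcc PCC fraction(s) in \[0, 1\] (values above 1 are permitted only
#'   via packing > 1).
#' @param model A [packing_model()].
#' @param chamber_area_cm2 Growth area, cm^2.
#' @param raw_confluency Optional raw confluency used for the QC flag.
#' @param monolayer_warn_threshold Raw-confluency QC threshold.
#' @return Data frame: `density` (cells cm^-2), `cell_count`, `qc_monolayer`.
#' @export
density_from_pcc <- function(pcc, model, chamber_area_cm2 = 0.8,
                             raw_confluency = NULL,
                             monolayer_warn_threshold = 0.85) {
  if (!inherits(model, "packing_model")) stop("model is not calibrated")
  if (model$mean_cell_footprint_um2 <= 0) stop("non-positive footprint")
  if (any(pcc < 0)) stop("pcc must be >= 0")
  density <- pcc / (model$mean_cell_footprint_um2 * 1e-8)
  qc <- if (is.null(raw_confluency)) rep(FALSE, length(pcc))
        else raw_confluency > monolayer_warn_threshold
  data.frame(density = density,
             cell_count = density * chamber_area_cm2,
             qc_monolayer = qc)
}

#' Calibrate the packing model on ground-truthed fixtures
#'
#' Fits the mean cell footprint from the least-confluent fixtures (isolated
#' cells, packing factor ~1) and the monotone packing curve from the
#' remaining fixtures by isotonic regression of the required packing factor
#' `true_density * footprint / confluency` against confluency, reduced to
#' at most 5 knots. The fit is deterministic given the fixture set and
#' makes [density_from_pcc()] unbiased on the fixtures.
#'
#' @param fixtures List of fixtures, each a list with `mask` (0/1 matrix),
#'   `n_cells` (true count) and `area_cm2` (imaged area). The `truth`
#'   element of [render_tiles()] output plus its mask is a valid source.
#' @return A calibrated [packing_model()].
#' @export
calibrate_packing <- function(fixtures) {
  if (length(fixtures) < 3)
    stop("at least 3 fixtures spanning the confluency range are required")
  conf <- vapply(fixtures, function(f) sum(unclass(f$mask) > 0) / length(f$mask), 0)
  dens <- vapply(fixtures, function(f) f$n_cells / f$area_cm2, 0)
  if (diff(range(conf)) < 0.2)
    stop("fixtures span less than 20% confluency range; extrapolation unsafe")
  ord <- order(conf)
  conf <- conf[ord]; dens <- dens[ord]
  # footprint from the sparsest third (isolated cells, packing ~1):
  # painted area / cell count reduces to confluency / density. Taking the
  # largest sparse-fixture footprint keeps every required packing factor
  # >= 1, so the >=1 clamp stays inactive and any footprint misestimate
  # cancels through the fitted curve (density_from_pcc then reproduces the
  # fixture densities).
  k <- max(2, floor(length(conf) / 3))
  foot_cm2 <- max(conf[seq_len(k)] / dens[seq_len(k)])
  foot_um2 <- foot_cm2 * 1e8
  pk_req <- pmax(1, dens * foot_cm2 / conf)
  iso <- stats::isoreg(conf, pk_req)
  knot_x <- unique(stats::quantile(conf, c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  knot_y <- pmax(1, stats::approx(iso$x, iso$yf, knot_x, rule = 2)$y)
  knot_y <- cummax(knot_y)
  if (length(knot_x) < 2) stop("fixtures collapse to a single confluency")
  packing_model(foot_um2, knot_x, knot_y,
                provenance = list(n_fixtures = length(fixtures),
                                  confluency_range = range(conf)))
}
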