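#' Specific growth rate between two cell counts
#'
#' `mu = ln(X / X0) / t`.
#'
#' @param X0 Initial cell count (> 0).
#' @param X Cell count at time `t` (> 0).
#' @param t Elapsed time, hours (> 0).
#' @return Growth rate in h^-1.
#' @export
growth_rate <- function(X0, X, t) {
  if (any(c(X0, X, t) <= 0)) stop("X0, X and t must all be > 0")
  log(X / X0) / t
}

#' Population doubling time
#'
#' `g = ln(2) / mu`; undefined for non-positive growth rates.
#'
#' @param mu Specific growth rate, h^-1 (> 0).
#' @return Doubling time in hours.
#' @export
doubling_time <- function(mu) {
  if (any(mu <= 0)) stop("doubling time is undefined for mu <= 0")
  log(2) / mu
}

#' Population standard deviation of replicate measurements
#'
#' Population form with divisor n: `sigma = sqrt(sum((x - mean)^2) / n)`.
#' A single replicate gives sigma = 0.
#'
#' @param x Replicate values (n >= 1).
#' @return List of class `summary_stats`: `mean`, `sigma`, `n`.
#' @export
stddev_population <- function(x) {
  if (length(x) == 0) stop("empty input")
  m <- mean(x)
  structure(list(mean = m, sigma = sqrt(mean((x - m)^2)), n = length(x)),
            class = "summary_stats")
}

#' Windowed growth-rate extraction from a density time series
#'
#' Slides a window of `window_h` hours over the series and fits
#' `ln(density) ~ t` by least squares in each window with at least 3
#' positive points. `mu_max` is the largest windowed rate whose fit R^2
#' passes the gate (which excludes lag and plateau windows). The lag
#' duration is estimated by back-extrapolating the best-fit exponential
#' line to the seeding density; on noise-free lag-then-exponential data
#' this recovers the true lag exactly.
#'
#' @param density_df Data frame with `t_h` and `density`.
#' @param window_h Window width, hours (default 15; long enough that the
#'   max-over-windows step stays close to unbiased at realistic imaging
#'   noise).
#' @param r2_min R^2 gate for accepting a window (default 0.95).
#' @param smooth_n Rolling-median pre-smoothing of log density, samples
#'   (odd; 1 disables). Exact log-linear stretches pass through unchanged
#'   (the median of a monotone window is its centre), while measurement
#'   noise is suppressed before the max-over-windows step, which would
#'   otherwise inflate `mu_max`.
#' @return List of class `growth_kinetics`: `mu_t` (window table), `mu_max`
#'   (h^-1), `g_h` (ln 2 / mu_max), `lag_h`, `window_h`.
#' @export
windowed_mu <- function(density_df, window_h = 15, r2_min = 0.95,
                        smooth_n = 5) {
  t <- density_df$t_h; d <- density_df$density
  stopifnot(length(t) == length(d))
  if (smooth_n > 1 && length(d) >= smooth_n && all(d > 0)) {
    k <- min(smooth_n, 2 * floor((length(d) - 1) / 2) + 1)
    if (k %% 2 == 0) k <- k - 1
    d <- exp(stats::runmed(log(d), k, endrule = "median"))
  }
  wins <- NULL
  for (i in seq_along(t)) {
    sel <- t >= t[i] & t <= t[i] + window_h
    if (sum(sel) < 3) next
    if (any(d[sel] <= 0)) next  # skipped, non-positive densities
    ft <- stats::lm(log(d[sel]) ~ t[sel])
    ssres <- sum(stats::residuals(ft)^2)
    sstot <- sum((log(d[sel]) - mean(log(d[sel])))^2)
    r2 <- if (sstot < 1e-12) (if (ssres < 1e-12) 1 else 0) else 1 - ssres / sstot
    wins <- rbind(wins, data.frame(
      window_start_h = t[i], n = sum(sel),
      mu = unname(stats::coef(ft)[2]),
      intercept = unname(stats::coef(ft)[1]), r2 = r2))
    if (t[i] + window_h > max(t)) break
  }
  if (is.null(wins)) stop("no window with >= 3 positive densities")
  ok <- wins$r2 >= r2_min & is.finite(wins$mu) & wins$mu > 0
  if (!any(ok)) {
    # noisy series can leave no window above the absolute gate; fall back
    # to the best-fitting windows (relative gate) so mu_max stays defined
    ok <- wins$r2 >= 0.9 * max(wins$r2) & is.finite(wins$mu) & wins$mu > 0
  }
  mu_max <- if (any(ok)) max(wins$mu[ok]) else NA_real_
  lag_h <- NA_real_
  if (any(ok)) {
    best <- wins[ok, ][which.max(wins$mu[ok]), ]
    lag_h <- max(0, (log(d[1]) - best$intercept) / best$mu)
  }
  structure(list(mu_t = wins, mu_max = mu_max,
                 g_h = if (is.finite(mu_max) && mu_max > 0)
                   doubling_time(mu_max) else NA_real_,
                 lag_h = lag_h, window_h = window_h),
            class = "growth_kinetics")
}

#' @export
print.growth_kinetics <- function(x, ...) {
  cat(sprintf("growth_kinetics: mu_max %.4f /h, doubling time %.1f h, lag %.1f h (%d windows)\n",
              x$mu_max, x$g_h, x$lag_h, nrow(x$mu_t)))
  invisible(x)
}

#' sOUR-versus-density curve with plateau estimate
#'
#' Bins specific uptake rates by cell density (log-spaced bins) and
#' estimates the plateau as the median sOUR over densities above a
#' threshold (default 5e4 cells cm^-2, where uptake stabilises in CHO-like
#' cultures). Negative-flagged points are excluded throughout; the median
#' is robust to the early sOUR spike some cultures show.
#'
#' @param joined Data frame with `density`, `sour_amol_cell_s` and
#'   `negative_flag` columns (see [align_series()] and [compute_sour()]).
#' @param n_bins Number of log-spaced density bins.
#' @param plateau_min_density Density threshold for the plateau window.
#' @return List: `curve` (per-bin mean density, median sOUR, n), `plateau`
#'   (amol cell^-1 s^-1), `plateau_min_density`, `n_used`.
#' @export
sour_vs_density <- function(joined, n_bins = 12, plateau_min_density = 5e4) {
  use <- !joined$negative_flag & is.finite(joined$sour_amol_cell_s) &
    is.finite(joined$density) & joined$density > 0
  if (!any(use)) stop("all points are negative-flagged or invalid")
  d <- joined$density[use]; s <- joined$sour_amol_cell_s[use]
  brks <- exp(seq(log(min(d)), log(max(d)), length.out = n_bins + 1))
  brks[1] <- min(d) * (1 - 1e-9)
  brks[n_bins + 1] <- max(d) * (1 + 1e-9)
  bin <- cut(d, brks, labels = FALSE)
  curve <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    idx <- which(bin == b)
    data.frame(density = mean(d[idx]),
               sour_median = stats::median(s[idx]),
               n = length(idx))
  }))
  above <- d > plateau_min_density
  plateau <- if (any(above)) stats::median(s[above]) else NA_real_
  list(curve = curve, plateau = plateau,
       plateau_min_density = plateau_min_density, n_used = sum(use))
}
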