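#' Detect respiratory events from the in-situ oxygen channel
#'
#' Scans a cleaned in-situ dissolved-oxygen series for change-points where
#' the rolling slope exceeds `min_slope_uM_per_h` and the subsequent level
#' shift exceeds `min_shift_uM` in the same direction. A rise of in-situ
#' oxygen means the cells' uptake fell (e.g. ATP-synthase inhibition); a
#' fall means uptake rose (e.g. uncoupler-stimulated respiration). Events
#' are separated by a refractory window. The in-situ channel is treated as
#' qualitative (timing and direction only); it is never converted to an
#' uptake rate because cell overgrowth biases its absolute level.
#'
#' @param insitu_df Data frame with `time_h` and `conc_uM` (spike-flagged
#'   samples already removed or interpolated).
#' @param min_shift_uM Minimum level shift (mean of following minus mean of
#'   preceding samples), uM.
#' @param min_slope_uM_per_h Minimum rolling slope magnitude, uM/h.
#' @param refractory_h Dead time after a detection, hours.
#' @param side_n Samples averaged on each side for the level shift.
#' @param true_event_times_h Optional true switch times; if given, each
#'   event gets a `latency_min` (detection time minus nearest true switch).
#' @return Data frame of events: `t_detect_h`, `direction`
#'   (`uptake_decrease`/`uptake_increase`), `magnitude_uM`, `latency_min`.
#'   Zero rows when nothing is detected.
#' @export
detect_events <- function(insitu_df, min_shift_uM = 10,
                          min_slope_uM_per_h = 10, refractory_h = 2,
                          side_n = 4, true_event_times_h = NULL) {
  t <- insitu_df$time_h; x <- insitu_df$conc_uM
  n <- length(t)
  empty <- data.frame(t_detect_h = numeric(0), direction = character(0),
                      magnitude_uM = numeric(0), latency_min = numeric(0))
  if (n < 2 * side_n + 3) return(empty)
  events <- empty
  last_detect <- -Inf
  for (i in (side_n + 2):(n - side_n - 1)) {
    if (t[i] - last_detect < refractory_h) next
    # backward slope: the change must already have started at sample i,
    # so an event is never dated before its true onset
    slope <- (x[i] - x[i - 1]) / (t[i] - t[i - 1])
    if (abs(slope) < min_slope_uM_per_h) next
    pre <- mean(x[(i - side_n):(i - 1)])
    post <- mean(x[(i + 1):(i + side_n)])
    shift <- post - pre
    if (abs(shift) < min_shift_uM) next
    if (sign(shift) != sign(slope)) next
    latency <- NA_real_
    if (!is.null(true_event_times_h) && length(true_event_times_h))
      latency <- (t[i] - true_event_times_h[
        which.min(abs(true_event_times_h - t[i]))]) * 60
    events <- rbind(events, data.frame(
      t_detect_h = t[i],
      direction = if (slope > 0) "uptake_decrease" else "uptake_increase",
      magnitude_uM = abs(shift), latency_min = latency))
    last_detect <- t[i]
  }
  events
}
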