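#' Growth-curve plot
#' @param density_df Data frame with `t_h` and `density_cells_cm2`.
#' @return A ggplot object.
#' @export
plot_growth_curve <- function(density_df) {
  ggplot2::ggplot(density_df,
                  ggplot2::aes(x = .data$t_h, y = .data$density_cells_cm2)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = expression(cells~cm^-2)) +
    ggplot2::theme_minimal()
}

#' Dissolved-oxygen triptych (inlet / outlet / in-situ)
#' @param do_df Data frame with `time_h`, `inlet_uM`, `outlet_uM`,
#'   `insitu_uM`.
#' @return A ggplot object.
#' @export
plot_do_profiles <- function(do_df) {
  long <- data.frame(
    time_h = rep(do_df$time_h, 3),
    channel = rep(c("inlet", "outlet", "in-situ"), each = nrow(do_df)),
    conc_uM = c(do_df$inlet_uM, do_df$outlet_uM, do_df$insitu_uM))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$conc_uM,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = expression(DO~(mu*M))) +
    ggplot2::theme_minimal()
}

#' sOUR-versus-density plot with plateau annotation
#' @param svd Output of [sour_vs_density()].
#' @return A ggplot object.
#' @export
plot_sour_vs_density <- function(svd) {
  ggplot2::ggplot(svd$curve, ggplot2::aes(x = .data$density,
                                          y = .data$sour_median)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = svd$plateau, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(cells~cm^-2),
                  y = expression(sOUR~(amol~cell^-1~s^-1))) +
    ggplot2::theme_minimal()
}
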