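#' Spaghetti plot of distance trajectories
#'
#' One line per `(subject, condition)` trajectory, faceted by subject, the
#' standard view of per-individual perturbation-and-recovery behaviour.
#'
#' @param trajectories Long trajectory tibble.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories) {
  check_trajectories(trajectories)
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(.data$time_h, .data$distance,
                               colour = .data$condition,
                               group = interaction(.data$subject_id, .data$condition))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$subject_id)) +
    ggplot2::labs(x = "Time (h)", y = "Aitchison distance from baseline",
                  colour = "Condition")
}

#' Mean trajectory with standard-error ribbon per group
#'
#' @param trajectories Long trajectory tibble.
#' @param by Grouping column (default `"condition"`).
#' @return A ggplot object.
#' @export
plot_group_mean <- function(trajectories, by = "condition") {
  s <- group_mean_se(trajectories, by = by)
  ggplot2::ggplot(s, ggplot2::aes(.data$time_h, .data$mean_distance,
                                  colour = .data[[by]], fill = .data[[by]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_distance - .data$se,
                                      ymax = .data$mean_distance + .data$se),
                         alpha = 0.2, colour = NA, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "Mean Aitchison distance from baseline")
}

#' @exportS3Method ggplot2::autoplot
autoplot.mbr_fpca <- function(object, n_sd = 2, ...) {
  K <- object$K
  df <- purrr::map_dfr(seq_len(K), function(k) {
    tibble::tibble(
      component = sprintf("FPCA%d (%.0f%%)", k, 100 * object$explained_fraction[k]),
      time_h = rep(object$grid, 3),
      curve = rep(c("mean", "plus", "minus"), each = length(object$grid)),
      value = c(object$mean_curve,
                object$mean_curve + n_sd * sqrt(object$lambda[k]) * object$phi[, k],
                object$mean_curve - n_sd * sqrt(object$lambda[k]) * object$phi[, k])
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$value,
                                   linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$component)) +
    ggplot2::scale_linetype_manual(values = c(mean = "solid", plus = "dashed",
                                              minus = "dotted")) +
    ggplot2::labs(x = "Time (h)", y = "Distance from baseline",
                  linetype = NULL,
                  title = sprintf("Modes of variation (mean %s %d sd)",
                                  "±", n_sd))
}

#' @exportS3Method ggplot2::autoplot
autoplot.mbr_bagplot <- function(object, ...) {
  pts <- tidy.mbr_bagplot(object)
  hull_df <- function(h, what) {
    tibble::tibble(x = h[, 1], y = h[, 2], what = what)
  }
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_polygon(data = hull_df(object$fence_hull, "fence"),
                          fill = "steelblue", alpha = 0.1) +
    ggplot2::geom_polygon(data = hull_df(object$bag_hull, "bag"),
                          fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::annotate("point", x = object$depth_median[1],
                      y = object$depth_median[2], shape = 3, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = "FPCA1", y = "FPCA2", colour = "Outlier")
}
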