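#' Plot per-strain R0 estimates
#'
#' Point estimates with bootstrap confidence intervals, strains ordered by
#' R0.  The dashed line marks the persistence threshold `R0 = 1`.
#'
#' @param object An [infer_r0()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.r0_fit <- function(object, ...) {
  est <- object$estimates
  est$strain <- stats::reorder(est$strain, est$r0)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$strain, y = .data$r0)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = expression(R[0]),
                  title = "Aggregate reproduction number by strain") +
    ggplot2::theme_minimal()
}

#' Plot a moment trajectory
#'
#' @param object An [integrate_moments()] trajectory.
#' @param ... Unused.
#' @return A ggplot object with one panel per moment.
#' @export
autoplot.npm_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t", "s", "U", "M")],
    cols = c("s", "U", "M"), names_to = "moment", values_to = "value")
  long$moment <- factor(long$moment, levels = c("s", "U", "M"),
                        labels = c("soluble s", "fiber number U",
                                   "aggregated mass M"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~moment, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot propagon recovery time courses
#'
#' Box plots of per-cell propagon counts at each sample time, one facet
#' per strain — the standard display of the curing/recovery assay.
#'
#' @param data Propagon table with columns `time_min`, `propagons` and
#'   optionally `strain`.
#' @return A ggplot object.
#' @export
plot_propagon_timecourse <- function(data) {
  check_columns(data, c("time_min", "propagons"), "propagon table")
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = factor(.data$time_min),
                                    y = .data$propagons)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "time after release (min)", y = "propagons per cell") +
    ggplot2::theme_minimal()
  if ("strain" %in% names(data))
    p <- p + ggplot2::facet_wrap(~strain)
  p
}
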