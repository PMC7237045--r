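#' Plot the AUC distribution of a selectivity table
#'
#' Gaussian-kernel-smoothed density of per-neuron AUC values (kernel width
#' 0.02, about the bootstrap SE of a single AUC estimate), split by cell
#' type, with the mean significance bounds marked.
#'
#' @param object a `selectivity_table`.
#' @param bw kernel width.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.selectivity_table <- function(object, bw = 0.02, ...) {
  df <- dplyr::bind_rows(lapply(split(object$auc, object$type), function(a) {
    d <- stats::density(a, bw = bw, from = 0, to = 1, n = 256)
    tibble::tibble(auc = d$x, density = d$y)
  }), .id = "type")
  ggplot2::ggplot(df, ggplot2::aes(.data$auc, .data$density,
                                   colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(mean(object$lo), mean(object$hi)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(exc = "#2166ac",
                                            inh = "#b2182b")) +
    ggplot2::labs(x = "AUC", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot decoding accuracy over the stimulus window
#'
#' @param object a `population_decoder`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.population_decoder <- function(object, ...) {
  df <- object$accuracy_by_time
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$accuracy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$accuracy - .data$sd,
                                      ymax = .data$accuracy + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::geom_point(data = df[object$fit_bin, ], colour = "black",
                        shape = 1, size = 3) +
    ggplot2::labs(x = "time (tau)", y = "test accuracy (%)",
                  title = paste0("group: ", object$group)) +
    ggplot2::theme_minimal()
}

#' Plot the calibration surface and the chosen iso-rate contour
#'
#' @param object an `amplitude_calibration`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.amplitude_calibration <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$freq, .data$alpha,
                               fill = .data$mean_rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_path(data = object$contour,
                       ggplot2::aes(.data$freq, .data$alpha),
                       inherit.aes = FALSE, colour = "white") +
    ggplot2::geom_point(data = object$alphas,
                        ggplot2::aes(.data$freq, .data$alpha),
                        inherit.aes = FALSE, colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "pulse frequency (per tau)", y = "amplitude alpha",
                  fill = "mean rate") +
    ggplot2::theme_minimal()
}

#' Plot normalized eigenvalue density maps
#'
#' @param object an `eigen_density` tibble.
#' @param which one of `"all"`, `"sig"`, `"ratio"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eigen_density <- function(object, which = c("all", "sig", "ratio"),
                                   ...) {
  which <- match.arg(which)
  col <- switch(which, all = "density_all", sig = "density_sig",
                ratio = "ratio")
  ggplot2::ggplot(object, ggplot2::aes(.data$re, .data$im,
                                       fill = .data[[col]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "Re(lambda) / a", y = "Im(lambda) / a", fill = which) +
    ggplot2::theme_minimal()
}

#' Plot task-transfer selectivity (AUC vs AUC)
#'
#' @param object a `transfer_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.transfer_report <- function(object, ...) {
  ggplot2::ggplot(object$neurons,
                  ggplot2::aes(.data$auc_1, .data$auc_2,
                               colour = .data$changed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#d6604d")) +
    ggplot2::labs(x = "AUC, task 1", y = "AUC, task 2",
                  colour = "status changed") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}
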