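#' Plot excitations and activations of a redundancy solution
#'
#' One facet per muscle over the gait cycle, excitation and activation as
#' lines; optionally overlays (scaled) EMG envelopes.
#'
#' @param object A `gaitmet_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gaitmet_solution
#' @export
autoplot.gaitmet_solution <- function(object, ...) {
  df <- object$states |>
    dplyr::mutate(pct = 100 * .data$time / max(.data$time)) |>
    tidyr::pivot_longer(c("excitation", "activation"),
                        names_to = "signal", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$pct, .data$value,
                                   color = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "Gait cycle (%)", y = "Excitation / activation",
                  color = NULL,
                  title = sprintf("Muscle controls (workflow %s)", object$workflow)) +
    ggplot2::theme_minimal()
}

#' Plot per-muscle metabolic rate trajectories
#'
#' @param object A `metabolic_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metabolic_trajectory
#' @export
autoplot.metabolic_trajectory <- function(object, ...) {
  df <- object |>
    dplyr::mutate(pct = 100 * .data$time / max(.data$time))
  ggplot2::ggplot(df, ggplot2::aes(.data$pct, .data$e_dot)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~muscle, scales = "free_y") +
    ggplot2::labs(x = "Gait cycle (%)", y = "Metabolic rate (W)",
                  title = sprintf("Metabolic rate (%s)", object$model[1])) +
    ggplot2::theme_minimal()
}

#' Plot the pointwise statistic and threshold of a 1-D permutation test
#'
#' @param x A `gaitmet_snpm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_snpm <- function(x, ...) {
  K <- length(x$t)
  df <- tibble::tibble(pct = 100 * (seq_len(K) - 1) / (K - 1), t = x$t)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$pct, .data$t)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * x$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Gait cycle (%)", y = "Paired t statistic") +
    ggplot2::theme_minimal()
  if (nrow(x$clusters) > 0) {
    p <- p + ggplot2::geom_rect(
      data = x$clusters,
      ggplot2::aes(xmin = .data$start_pct, xmax = .data$end_pct,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15
    )
  }
  p
}

#' Plot muscle-group metabolic rate series
#'
#' @param group_result Output of [muscle_group_rates()].
#' @return A ggplot object.
#' @export
plot_group_rates <- function(group_result) {
  df <- group_result$series |>
    dplyr::mutate(pct = 100 * .data$time / max(.data$time))
  ggplot2::ggplot(df, ggplot2::aes(.data$pct, .data$e_dot, color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Gait cycle (%)", y = "Metabolic rate (W)", color = NULL) +
    ggplot2::theme_minimal()
}
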