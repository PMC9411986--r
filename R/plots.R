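#' Plot an SRR series with detected exponential phases
#'
#' Points on a log rate axis with the fitted log-linear segments overlaid.
#'
#' @param data SRR data as in [detect_exponential_phases()].
#' @param phases Optional result of [detect_exponential_phases()]; detected
#'   automatically when NULL.
#' @return A ggplot object.
#' @export
plot_srr_phases <- function(data, phases = NULL) {
  df <- srr_series(data)
  if (is.null(phases)) phases <- detect_exponential_phases(data)
  p <- ggplot2::ggplot(df[df$rate > 0, ],
                       ggplot2::aes(x = .data$time_h, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)",
                  y = expression(SRR ~ (nmol ~ cm^-3 ~ d^-1)))
  if (nrow(phases)) {
    seg <- purrr::map_dfr(seq_len(nrow(phases)), function(i) {
      fit <- fit_exponential_phase(df, phases$t_start[i], phases$t_end[i])
      tt <- seq(phases$t_start[i], phases$t_end[i], length.out = 20)
      tibble::tibble(t = tt, rate = exp(fit$intercept + fit$mu * tt),
                     phase = factor(phases$phase[i]))
    })
    p <- p + ggplot2::geom_line(
      data = seg,
      ggplot2::aes(x = .data$t, y = .data$rate, color = .data$phase))
  }
  p
}

#' Plot concentration time series per analyte
#'
#' @param conc Concentration table with `time_h`, `analyte`, `mean_mM` and
#'   optionally `sd_mM`.
#' @return A ggplot object.
#' @export
plot_concentrations <- function(conc) {
  p <- ggplot2::ggplot(conc, ggplot2::aes(x = .data$time_h,
                                          y = .data$mean_mM,
                                          color = .data$analyte)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mM)")
  if ("sd_mM" %in% names(conc)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_mM - .data$sd_mM,
                   ymax = .data$mean_mM + .data$sd_mM), width = 2)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Ordination biplot of a PCoA result
#'
#' @param object A [pcoa_ordination()].
#' @param metadata Optional tibble with `library_id` plus columns to map to
#'   color (`treatment`) and label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_ordination <- function(object, metadata = NULL, ...) {
  df <- object$coordinates
  if (!is.null(metadata)) df <- dplyr::left_join(df, metadata,
                                                 by = "library_id")
  aes <- if ("treatment" %in% names(df)) {
    ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                 color = .data$treatment)
  } else {
    ggplot2::aes(x = .data$Axis1, y = .data$Axis2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$relative_inertia[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$relative_inertia[2]))
}

#' Heatmap of logarithmically normalized metabolite profiles
#'
#' @param normalized Output of [normalize_fractional()].
#' @return A ggplot object.
#' @export
plot_metabolite_heatmap <- function(normalized) {
  ggplot2::ggplot(normalized,
                  ggplot2::aes(x = factor(.data$timepoint_h),
                               y = .data$metabolite,
                               fill = .data$log_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "Time (h)", y = NULL,
                  fill = "log10 fractional\nabundance")
}
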