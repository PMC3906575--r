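# Plotting: exon-vs-intron rate scatter for a scan and the power curve of a
# simulation study.

#' Plot exonic versus intronic difference rates
#'
#' Each point is one exon/intron pair; exons called significantly accelerated
#' (q-value at or below the scan cutoff with D_e > D_i) are circled. The
#' dashed diagonal marks D_e = D_i.
#'
#' @param object an `accel_scan`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot accel_scan
#' @importFrom ggplot2 autoplot
autoplot.accel_scan <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$testable, , drop = FALSE]
  sig <- df[df$exon_id %in% object$significant$exon_id, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$D_i, y = .data$D_e)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::geom_point(data = sig, shape = 1, size = 4,
                        colour = "firebrick", stroke = 1) +
    ggplot2::labs(
      x = expression(D[i] ~ "(intronic differences per bp)"),
      y = expression(D[e] ~ "(exonic differences per bp)"),
      title = "Exonic vs intronic difference rates",
      subtitle = sprintf("%d pairs; %d significant at q <= %.3g",
                         nrow(df), nrow(sig), object$config$q_cut)
    ) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' Plot rejection rates from a power study
#'
#' @param power tibble from [run_power_study()].
#' @return A ggplot object.
#' @export
plot_power <- function(power) {
  ggplot2::ggplot(power,
                  ggplot2::aes(x = .data$copy_number, y = .data$rejection_rate,
                               colour = factor(.data$factor),
                               group = factor(.data$factor))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = unique(power$copy_number)) +
    ggplot2::labs(x = "gene copy number", y = "rejection rate",
                  colour = "exon rate factor",
                  title = "Detection power by copy number") +
    ggplot2::theme_minimal()
}
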