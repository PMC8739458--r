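# ggplot2 renderings of the view objects. Each autoplot() draws exactly the
# numbers its view computed; no statistics are recomputed at plot time.

#' @exportS3Method ggplot2::autoplot
autoplot.histogram_view <- function(object, ...) {
  b <- object$bins
  p <- ggplot2::ggplot(b) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$left, xmax = .data$right,
                                    ymin = 0, ymax = .data$count),
                       fill = "grey60", colour = "white", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = object$border, colour = "steelblue",
                        linetype = "dashed") +
    ggplot2::labs(x = object$parameter, y = "count",
                  title = sprintf("Distribution of %s", object$parameter),
                  subtitle = sprintf("dashed: bottom-%g%% border%s",
                                     100 * object$level,
                                     if (!is.na(object$cutoff)) "; solid: configured cutoff" else ""))
  if (!is.na(object$cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = object$cutoff, colour = "firebrick")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.trend_view <- function(object, ...) {
  pts <- object$points
  if (identical(object$grouping, "by_injection_order")) {
    p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$injection_time,
                                           y = .data$value,
                                           colour = .data$sample_type)) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "injection time", y = object$parameter,
                    title = sprintf("%s across batch %s", object$parameter,
                                    object$batch_name))
    if (!is.null(object$cutoff) && !is.na(object$cutoff)) {
      p <- p + ggplot2::geom_hline(yintercept = object$cutoff,
                                   colour = "firebrick", linetype = "dashed")
    }
    return(p)
  }
  pts$group <- factor(pts$group, levels = pts$group)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$group, y = .data$mean, group = 1)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$grouping, y = paste("mean", object$parameter),
                  title = sprintf("%s by %s", object$parameter,
                                  sub("^by_", "", object$grouping))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.std_a_signal_view <- function(object, ...) {
  pts <- object$points
  pts$xml_file_name <- factor(pts$xml_file_name, levels = unique(pts$xml_file_name))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$xml_file_name,
                                    y = .data$peak_area,
                                    colour = .data$status)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~compound, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(pass = "darkgreen",
                                            fail = "firebrick",
                                            not_evaluable = "grey50")) +
    ggplot2::labs(x = "batch", y = "Std-A peak area",
                  title = "First-calibrator signal, batch to batch") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rt_view <- function(object, ...) {
  d <- object$deviations
  d$xml_file_name <- factor(d$xml_file_name, levels = unique(d$xml_file_name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xml_file_name,
                                  y = .data$deviation,
                                  colour = .data$compound, group = .data$compound)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "batch", y = "RT deviation from monthly mean (min)",
                  title = "Absolute RT vs monthly average") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}
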