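#' Plot a time budget
#'
#' Bar chart of percent of observation time per behavior; several budgets
#' (e.g. manual vs automated methods) can be compared side by side.
#'
#' @param ... One or more [time_budget()]s, optionally named
#'   (`manual = b1, model = b2`).
#' @return A ggplot object.
#' @export
plot_time_budget <- function(...) {
  budgets <- list(...)
  nm <- names(budgets) %||% paste0("method", seq_along(budgets))
  nm[!nzchar(nm)] <- paste0("method", which(!nzchar(nm)))
  d <- do.call(rbind, Map(function(b, n)
    data.frame(method = n, behavior = b$behavior, percent = b$percent),
    budgets, nm))
  d$behavior <- factor(d$behavior, levels = unique(d$behavior))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$behavior, y = .data$percent,
                                  fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of observation time", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot cumulative behavior curves
#'
#' One line per behavior: cumulative seconds against time of night.
#'
#' @param curves Matrix from [cumulative_curves()].
#' @return A ggplot object.
#' @export
plot_cumulative_curves <- function(curves) {
  n <- nrow(curves)
  d <- data.frame(
    second = rep(seq_len(n), ncol(curves)),
    behavior = rep(colnames(curves), each = n),
    cumulative_s = as.vector(curves))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$second / 3600,
                                  y = .data$cumulative_s,
                                  color = .data$behavior)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "hours since start of observation",
                  y = "cumulative seconds", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cumulative sway trace
#'
#' Cumulative bodypart displacement over the night with detected bouts
#' shaded, optionally alongside the cumulative manually scored sway time on
#' a second axis — steep increases in the displacement trace co-occur with
#' observed swaying.
#'
#' @param trace A [sway_trace()].
#' @param manual_seq Optional second-resolution [behavior_sequence()] of
#'   manual scoring containing a `"Swaying"` label.
#' @param sway_label Label counted from `manual_seq`.
#' @return A ggplot object.
#' @export
plot_sway_trace <- function(trace, manual_seq = NULL,
                            sway_label = "Swaying") {
  nf <- length(trace$steps)
  d <- data.frame(hour = (seq_len(nf) - 1L) / trace$fps / 3600,
                  cumulative_px = trace$cumulative)
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$hour,
                                       y = .data$cumulative_px))
  if (nrow(trace$bouts))
    g <- g + ggplot2::geom_rect(
      data = data.frame(xmin = trace$bouts$start_s / 3600,
                        xmax = trace$bouts$end_s / 3600),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85")
  g <- g + ggplot2::geom_line(color = "firebrick")
  if (!is.null(manual_seq)) {
    scale <- max(trace$cumulative, 1) /
      max(cumsum(manual_seq$labels == sway_label), 1)
    dm <- data.frame(hour = seq_along(manual_seq$labels) / 3600,
                     scaled = cumsum(manual_seq$labels == sway_label) * scale)
    g <- g +
      ggplot2::geom_line(data = dm,
                         ggplot2::aes(x = .data$hour, y = .data$scaled),
                         color = "purple") +
      ggplot2::scale_y_continuous(
        sec.axis = ggplot2::sec_axis(~ . / scale,
                                     name = "cumulative sway (s, manual)"))
  }
  g + ggplot2::labs(x = "hours since start of observation",
                    y = "cumulative displacement (px)") +
    ggplot2::theme_minimal()
}
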