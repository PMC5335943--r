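#' Plot a multichannel EEG recording
#'
#' Stacked channel traces on a shared time axis.
#'
#' @param recording An `eeg_recording`.
#' @param channels Channels to show (default: all).
#' @param max_seconds Truncate the display after this many seconds.
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, channels = NULL, max_seconds = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- sampling_rate(recording)
  df <- tibble::as_tibble(as.data.frame(recording))
  if (!is.null(channels)) df <- df[, channels, drop = FALSE]
  df$time_s <- (seq_len(nrow(df)) - 1) / fs
  if (!is.null(max_seconds)) df <- df[df$time_s <= max_seconds, ]
  long <- tidyr::pivot_longer(df, -"time_s",
    names_to = "channel", values_to = "amplitude"
  )
  long$channel <- factor(long$channel, levels = setdiff(names(df), "time_s"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' Confusion-matrix heatmap for a CV report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      title = sprintf(
        "%d-fold CV (%s): mean accuracy %.3f",
        object$n_folds, object$method, object$mean_accuracy
      ),
      x = "predicted", y = "truth"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mutual-information feature ranking
#'
#' @param ranking Tibble from [mi_rank()].
#' @param top_n Number of leading features to display (default 20).
#' @return A ggplot object.
#' @export
plot_mi_ranking <- function(ranking, top_n = 20) {
  df <- utils::head(ranking, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$mi, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mutual information with label (bits)", y = NULL) +
    ggplot2::theme_minimal()
}
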