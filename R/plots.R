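# Plotting is best-effort presentation of the evaluation tibbles; nothing
# downstream depends on it.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_raster labs scale_fill_viridis_c facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot spatial tuning curves
#'
#' One line per STN set: total activity against stimulus azimuth.
#'
#' @param object a [tuning_curves()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.tuning_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$stim_azimuth, y = .data$response,
                     colour = factor(.data$stn_theta))) +
    geom_line() + geom_point() +
    labs(x = "stimulus azimuth (deg)", y = "total activity",
         colour = "STN azimuth (deg)") +
    theme_minimal()
}

#' Plot per-channel tuning before/after the DiffMask operation
#'
#' @param object a [diffmask_tuning()] tibble.
#' @param ... unused.
#' @return a ggplot object faceted by processing stage.
#' @export
autoplot.diffmask_tuning <- function(object, ...) {
  ggplot(object, aes(x = .data$stim_azimuth, y = .data$response,
                     group = .data$channel,
                     colour = log10(.data$center_freq))) +
    geom_line(alpha = 0.6) +
    facet_wrap(~stage) +
    labs(x = "stimulus azimuth (deg)", y = "per-channel response",
         colour = "log10 f (Hz)") +
    theme_minimal()
}

#' Plot a parameter-sweep surface
#'
#' @param object a [parameter_sweep()] tibble.
#' @param ... unused.
#' @return a ggplot tile plot of mean STOI over the grid.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot(object, aes(x = factor(1000 * .data$tau_h), y = factor(.data$a),
                     fill = .data$mean_stoi)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "kernel tau_h (ms)", y = "DiffMask a", fill = "mean STOI") +
    theme_minimal()
}

#' Spike raster plot
#'
#' @param events a [spike_events()] tibble.
#' @param ... unused.
#' @return a ggplot raster of spike times by frequency channel, faceted by
#'   STN azimuth if more than one is present.
#' @export
plot_raster <- function(events, ...) {
  p <- ggplot(events, aes(x = .data$time_s, y = .data$channel_index)) +
    geom_point(shape = ".", alpha = 0.6) +
    labs(x = "time (s)", y = "frequency channel") +
    theme_minimal()
  if (length(unique(events$theta_deg)) > 1L) {
    p <- p + facet_wrap(~theta_deg, labeller = "label_both")
  }
  p
}

#' Time-frequency mask image
#'
#' @param mask a `tf_mask`.
#' @param stride plot every `stride`-th sample (default 32).
#' @return a ggplot raster image.
#' @export
plot_mask <- function(mask, stride = 32L) {
  stopifnot(inherits(mask, "tf_mask"))
  idx <- seq(1L, nrow(mask$values), by = stride)
  df <- expand.grid(time_s = (idx - 1L) / mask$fs,
                    channel = seq_len(ncol(mask$values)))
  df$value <- as.vector(mask$values[idx, ])
  ggplot(df, aes(x = .data$time_s, y = .data$channel, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency channel",
         fill = mask$kind) +
    theme_minimal()
}
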