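# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_col
#'   geom_path geom_point scale_fill_viridis_c labs theme_minimal facet_wrap
NULL

#' Plot a spectrogram
#'
#' @param object A `spectrogram`.
#' @param trans Power transform for display: `"log10"` (default) or
#'   `"identity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrogram <- function(object, trans = "log10", ...) {
  df <- tidy(object)
  if (trans == "log10") df$power <- log10(df$power + 1e-12)
  ggplot(df, aes(x = .data$t_s, y = .data$freq_hz, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c(name = if (trans == "log10") "log10 power"
                         else "power") +
    labs(x = "time (s)", y = "frequency (Hz)") +
    theme_minimal()
}

#' Plot a phase-amplitude coupling profile
#'
#' The 40-bin profile is shown over two theta cycles (0-720 degrees), the
#' field's usual display.
#'
#' @param object A `pac_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pac_profile <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::mutate(df,
                                            phase_deg = .data$phase_deg + 360))
  ggplot(df2, aes(x = .data$phase_deg, y = .data$amplitude)) +
    geom_col(width = 9, fill = "grey40") +
    labs(x = "theta phase (deg)", y = "gamma power",
         title = sprintf("MI = %.4f, preferred phase = %.0f deg",
                         object$mi, object$preferred_phase_deg)) +
    theme_minimal()
}

#' Plot a comodulogram
#'
#' @param object A `comodulogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.comodulogram <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$theta_hz, y = .data$gamma_hz, fill = .data$mi)) +
    geom_raster() +
    scale_fill_viridis_c(name = "MI") +
    labs(x = "theta frequency (Hz)", y = "gamma frequency (Hz)") +
    theme_minimal()
}

#' Plot a CSD map
#'
#' @param object A `csd_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csd_map <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$t_s, y = .data$depth_um, fill = .data$csd)) +
    geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(name = "CSD", low = "blue", mid = "white",
                                  high = "red") +
    labs(x = "time (s)", y = "depth (um)") +
    theme_minimal()
}

#' Plot theta-sorted gamma power
#'
#' Per-theta-power-bin mean gamma power (ascending normalized theta).
#'
#' @param object A `theta_sorted`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.theta_sorted <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$theta_mid, y = .data$mean_gamma)) +
    geom_line() + geom_point() +
    labs(x = "normalized theta power (z)", y = "mean gamma power") +
    theme_minimal()
}

#' Plot a behaviour track
#'
#' @param object A `behavior_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.behavior_track <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$body_x_cm, y = .data$body_y_cm)) +
    geom_path(alpha = 0.5) +
    ggplot2::coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
  lm <- attr(object, "landmarks")
  if (length(lm)) {
    df <- tibble::tibble(name = names(lm),
                         x = vapply(lm, `[`, numeric(1), 1),
                         y = vapply(lm, `[`, numeric(1), 2))
    p <- p + geom_point(data = df, aes(x = .data$x, y = .data$y),
                        colour = "red", size = 3) +
      ggplot2::geom_text(data = df,
                         aes(x = .data$x, y = .data$y, label = .data$name),
                         vjust = -1)
  }
  p
}
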