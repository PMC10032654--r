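#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot midline snapshots
#'
#' @param object A [midline_track()].
#' @param every Plot every `every`-th frame.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.midline_track <- function(object, every = 5, ...) {
  frames <- sort(unique(object$frame))
  keep <- frames[seq(1, length(frames), by = every)]
  d <- object[object$frame %in% keep, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x_m, .data$y_m,
                                  group = .data$frame,
                                  colour = .data$time_s)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", colour = "time (s)",
                  title = "Midline snapshots")
}

#' Plot a lateral amplitude envelope
#'
#' @param object An [amplitude_profile()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.amplitude_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$s_bl, .data$amplitude_m)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "arclength (BL)", y = "amplitude (m)",
                  title = "Lateral amplitude envelope")
}

#' Plot a reconstructed pressure field
#'
#' @param object A [pressure_field()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pressure_field <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_m, .data$y_m, fill = .data$p_pa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "p (Pa)",
                  title = "Reconstructed pressure field")
}

#' Quiver-style plot of one velocity frame
#'
#' @param seq A [vf_seq()].
#' @param frame Frame index.
#' @param every Subsample factor for arrows.
#' @param remove_mean Subtract the mean flow first (vortex visualisation).
#' @return A ggplot.
#' @export
plot_velocity_frame <- function(seq, frame = 1, every = 4,
                                remove_mean = FALSE) {
  if (remove_mean) seq <- subtract_mean_flow(seq)
  xi <- seq(1, length(seq$x), by = every)
  yi <- seq(1, length(seq$y), by = every)
  d <- expand.grid(i = xi, j = yi)
  sc <- 0.4 * every * grid_step(seq) /
    max(sqrt(seq$u[, , frame]^2 + seq$v[, , frame]^2), 1e-12)
  d <- tibble::tibble(
    x = seq$x[d$i], y = seq$y[d$j],
    u = seq$u[cbind(d$i, d$j, frame)], v = seq$v[cbind(d$i, d$j, frame)])
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + sc * .data$u,
                                       yend = .data$y + sc * .data$v),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm")),
                          linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", title = "Velocity field")
}

#' Plot the phase-difference-versus-distance relationship
#'
#' @param phases Tibble from [follower_phases()].
#' @param fit Optional [linear_fit()] to overlay.
#' @return A ggplot.
#' @export
plot_phase_distance <- function(phases, fit = NULL) {
  g <- ggplot2::ggplot(phases, ggplot2::aes(.data$distance_m,
                                            .data$phase_rad)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gap distance (m)", y = "phase difference (rad)",
                  title = "Foil-fish phase difference vs distance")
  if (!is.null(fit)) {
    g <- g + ggplot2::geom_abline(slope = fit$slope,
                                  intercept = fit$intercept,
                                  linetype = 2)
  }
  g
}
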