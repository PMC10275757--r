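# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @export
tidy.pressure_field <- function(x, ...) {
  g <- x$grid
  coords <- expand.grid(x = g$x, y = g$y, z = g$z, KEEP.OUT.ATTRS = FALSE)
  tibble(
    x = coords$x, y = coords$y, z = coords$z,
    pressure = as.vector(x$pressure)
  )
}

#' @export
glance.pressure_field <- function(x, ...) beam_metrics(x)

#' @export
tidy.axisym_field <- function(x, ...) {
  coords <- expand.grid(r = x$r, z = x$z, KEEP.OUT.ATTRS = FALSE)
  tibble(r = coords$r, z = coords$z, pressure = as.vector(x$pressure))
}

#' @export
tidy.temperature_field <- function(x, ...) x$trace

#' @export
glance.temperature_field <- function(x, ...) {
  i <- which.max(x$trace$max_rise)
  tibble(
    peak_rise = x$trace$max_rise[i],
    time_of_peak = x$trace$time[i],
    duration = max(x$trace$time)
  )
}

#' @export
tidy.activation_map <- function(x, ...) x$nodes

#' @export
glance.activation_map <- function(x, ...) {
  tibble(
    activated_area = x$activated_area,
    total_area = x$total_area,
    centre_x = x$centre$x,
    centre_y = x$centre$y,
    threshold = x$threshold,
    n_active = sum(x$nodes$active)
  )
}

#' @export
tidy.lick_session <- function(x, ...) {
  tibble(
    trial = seq_along(x$onsets),
    onset = x$onsets,
    success = trial_success(x$onsets, x$licks, x$reward_delay)
  )
}

#' @export
glance.lick_session <- function(x, ...) session_metrics(x)

#' Plot a pressure field slice
#'
#' Renders the amplitude over the two sampled axes of a planar field (or
#' the profile for a line grid).
#'
#' @param object A `pressure_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pressure_field <- function(object, ...) {
  df <- tidy(object)
  n <- c(x = length(object$grid$x), y = length(object$grid$y),
         z = length(object$grid$z))
  axes <- names(n)[n > 1]
  if (length(axes) >= 2) {
    ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1]]] * 1e3,
                                     .data[[axes[2]]] * 1e3,
                                     fill = .data$pressure)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(name = "|p| (Pa)") +
      ggplot2::labs(x = paste(axes[1], "(mm)"), y = paste(axes[2], "(mm)")) +
      ggplot2::coord_equal()
  } else {
    ax <- if (length(axes)) axes[1] else "z"
    ggplot2::ggplot(df, ggplot2::aes(.data[[ax]] * 1e3, .data$pressure)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = paste(ax, "(mm)"), y = "|p| (Pa)")
  }
}

#' Plot the maximum temperature-rise time course
#'
#' @param object A `temperature_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.temperature_field <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$time, .data$max_rise)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "max temperature rise (°C)")
}

#' Plot an activation map
#'
#' Electrode amplitudes with the activation threshold encoded as point
#' shape and the response centre marked.
#'
#' @param object An `activation_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activation_map <- function(object, ...) {
  p <- ggplot2::ggplot(object$nodes,
                       ggplot2::aes(.data$x, .data$y,
                                    colour = .data$amplitude,
                                    shape = .data$active)) +
    ggplot2::geom_point(size = 4) +
    ggplot2::scale_colour_viridis_c(name = "amplitude") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
  if (is.finite(object$centre$x)) {
    p <- p + ggplot2::annotate("point", x = object$centre$x,
                               y = object$centre$y, shape = 3, size = 5)
  }
  p
}

#' Plot a spike density function
#'
#' @param sdf A tibble from [spike_density_function()].
#' @param onset Optional stimulus onset marker (s).
#' @return A ggplot.
#' @export
plot_sdf <- function(sdf, onset = NULL) {
  p <- ggplot2::ggplot(sdf, ggplot2::aes(.data$time * 1e3, .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "rate (Hz)")
  if (!is.null(onset)) {
    p <- p + ggplot2::geom_vline(xintercept = onset * 1e3, linetype = 2)
  }
  p
}
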