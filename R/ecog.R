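#' Trial-averaged evoked potentials and N1 amplitudes
#'
#' Averages trial-aligned voltage traces per channel and extracts the N1
#' amplitude: the magnitude (in the trace's voltage unit) of the most
#' negative deflection of the mean trace inside the post-onset search
#' window. The per-channel noise s.d. is estimated from the pre-onset
#' baseline of the raw (single-trial) signal, pooled across trials; the
#' activation threshold convention (2 x s.d. of the signal) refers to this
#' raw-signal value.
#'
#' @param traces Tibble with columns `channel`, `trial`, `time` (s,
#'   relative to stimulus onset) and `voltage`.
#' @param n1_window Post-onset search window (s), default 0 to 100 ms.
#' @param baseline_window Pre-onset baseline extent (s), default 200 ms
#'   (i.e. times in `[-0.2, 0)`).
#' @return A list with `potentials` (tibble `channel`, `time`,
#'   `mean_voltage`) and `n1` (tibble `channel`, `n1_amplitude`,
#'   `noise_sd`).
#' @export
evoked_potential <- function(traces, n1_window = c(0, 0.1),
                             baseline_window = 0.2) {
  stopifnot(all(c("channel", "trial", "time", "voltage") %in% names(traces)))
  pot <- traces |>
    dplyr::group_by(.data$channel, .data$time) |>
    dplyr::summarise(mean_voltage = mean(.data$voltage), .groups = "drop")
  noise <- traces |>
    dplyr::filter(.data$time >= -baseline_window, .data$time < 0) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(noise_sd = sd(.data$voltage), .groups = "drop")
  n1 <- pot |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      n1_amplitude = {
        w <- .data$time >= n1_window[1] & .data$time <= n1_window[2]
        max(0, -min(.data$mean_voltage[w]))
      },
      .groups = "drop"
    ) |>
    dplyr::left_join(noise, by = "channel")
  list(potentials = pot, n1 = n1)
}

# --- piecewise-linear interpolation machinery ---------------------------

# Triangulate electrodes that sit on a (possibly incomplete) regular grid:
# each unit cell with all 4 corners present contributes two triangles;
# cells with exactly 3 present corners contribute that single triangle.
# Returns an integer matrix, one row of 3 node indices per triangle.
grid_triangulation <- function(x, y) {
  xs <- sort(unique(round(x, 9)))
  ys <- sort(unique(round(y, 9)))
  idx <- matrix(NA_integer_, length(xs), length(ys))
  for (i in seq_along(x)) {
    idx[match(round(x[i], 9), xs), match(round(y[i], 9), ys)] <- i
  }
  tris <- list()
  for (cx in seq_len(length(xs) - 1)) {
    for (cy in seq_len(length(ys) - 1)) {
      corners <- c(idx[cx, cy], idx[cx + 1, cy], idx[cx + 1, cy + 1],
                   idx[cx, cy + 1])
      pres <- !is.na(corners)
      if (sum(pres) == 4) {
        tris[[length(tris) + 1]] <- corners[c(1, 2, 3)]
        tris[[length(tris) + 1]] <- corners[c(1, 3, 4)]
      } else if (sum(pres) == 3) {
        tris[[length(tris) + 1]] <- corners[pres]
      }
    }
  }
  if (!length(tris)) abort("electrode layout has no complete grid cell")
  do.call(rbind, tris)
}

tri_area <- function(px, py) {
  abs((px[2] - px[1]) * (py[3] - py[1]) -
        (px[3] - px[1]) * (py[2] - py[1])) / 2
}

# Exact area of {linear interpolant > lev} inside one triangle: clip the
# triangle with the half-plane defined by the linear function.
tri_suprathreshold_area <- function(px, py, v, lev) {
  above <- v > lev
  if (all(above)) return(tri_area(px, py))
  if (!any(above)) return(0)
  poly_x <- numeric(0)
  poly_y <- numeric(0)
  for (i in 1:3) {
    j <- i %% 3 + 1
    if (above[i]) {
      poly_x <- c(poly_x, px[i]); poly_y <- c(poly_y, py[i])
    }
    if (xor(above[i], above[j])) {
      tfrac <- (lev - v[i]) / (v[j] - v[i])
      poly_x <- c(poly_x, px[i] + tfrac * (px[j] - px[i]))
      poly_y <- c(poly_y, py[i] + tfrac * (py[j] - py[i]))
    }
  }
  n <- length(poly_x)
  abs(sum(poly_x * poly_y[c(2:n, 1)] - poly_x[c(2:n, 1)] * poly_y)) / 2
}

#' Activation map from per-electrode response amplitudes
#'
#' Builds the piecewise-linear (triangulated) interpolation of per-electrode
#' response amplitudes (N1 peak depolarization, or peak firing rate) over
#' the electrode layout and reports: the activated area, i.e. the exact
#' area over which the interpolant exceeds the background-noise threshold
#' `2 * noise_sd` (computed by clipping each triangle against the threshold
#' plane, no rasterization); and the response centre, the amplitude-weighted
#' centroid of the suprathreshold electrodes. Layouts must lie on a
#' (possibly incomplete) regular grid, or a precomputed triangulation can
#' be supplied.
#'
#' @param amplitudes Tibble with `x`, `y` (mm) and `amplitude` per
#'   electrode.
#' @param noise_sd Background noise standard deviation (same unit as
#'   `amplitude`); the activation threshold is `2 * noise_sd`.
#' @param triangulation Optional integer matrix (rows of 3 node indices);
#'   default from [grid_triangulation()] on the layout.
#' @return An `activation_map`: `nodes` tibble (with `active` flag),
#'   `activated_area` (mm^2), `total_area` (mm^2 of the triangulated hull),
#'   `centre` (one-row tibble or `NA` when nothing is active),
#'   `threshold`.
#' @export
ecog_activation_map <- function(amplitudes, noise_sd, triangulation = NULL) {
  if (!"amplitude" %in% names(amplitudes) &&
      "n1_amplitude" %in% names(amplitudes)) {
    amplitudes$amplitude <- amplitudes$n1_amplitude
  }
  stopifnot(all(c("x", "y", "amplitude") %in% names(amplitudes)))
  assert_nonneg_scalar(noise_sd, "noise_sd")
  if (nrow(amplitudes) < 3) abort("need at least 3 electrodes")
  tri <- triangulation %||% grid_triangulation(amplitudes$x, amplitudes$y)
  lev <- 2 * noise_sd
  act_area <- 0
  tot_area <- 0
  for (r in seq_len(nrow(tri))) {
    px <- amplitudes$x[tri[r, ]]
    py <- amplitudes$y[tri[r, ]]
    v <- amplitudes$amplitude[tri[r, ]]
    tot_area <- tot_area + tri_area(px, py)
    act_area <- act_area + tri_suprathreshold_area(px, py, v, lev)
  }
  nodes <- amplitudes |>
    dplyr::mutate(active = .data$amplitude > lev)
  centre <- if (any(nodes$active)) {
    response_centre(nodes[nodes$active, ])
  } else {
    tibble(x = NA_real_, y = NA_real_)
  }
  structure(
    list(
      nodes = nodes,
      triangulation = tri,
      activated_area = act_area,
      total_area = tot_area,
      centre = centre,
      threshold = lev
    ),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> %d electrodes, activated %.3g / %.3g mm^2, centre (%.3g, %.3g)\n",
    nrow(x$nodes), x$activated_area, x$total_area, x$centre$x, x$centre$y
  ))
  invisible(x)
}
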