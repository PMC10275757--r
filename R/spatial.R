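#' Rate-weighted spatial dispersion of activated cells
#'
#' Mean pairwise Euclidean distance between responding cells, weighted by
#' the product of their (population-normalized) maximum firing rates:
#' \deqn{D = \sum_{i<j} w_i w_j d_{ij} / \sum_{i<j} w_i w_j,\quad
#'       w_i = r_i / \max_k r_k.}
#' The paper-style phrasing ("distance weighted according to the maximum
#' firing rate") admits alternatives; `method = "unweighted"` gives the
#' plain mean pairwise distance for comparison.
#'
#' @param cells Data frame with columns `x`, `y` (spatial coordinates, any
#'   consistent unit) and, for the weighted method, `max_rate` (Hz).
#' @param method `"pairwise_product"` (default) or `"unweighted"`.
#' @return Dispersion in the coordinate unit; 0 for a single cell.
#' @export
spatial_dispersion <- function(cells, method = c("pairwise_product",
                                                 "unweighted")) {
  method <- match.arg(method)
  n <- nrow(cells)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  w <- if (method == "pairwise_product") {
    r <- cells$max_rate
    if (max(r) <= 0) abort("all weights are zero")
    r / max(r)
  } else {
    rep(1, n)
  }
  W <- outer(w, w)
  iu <- upper.tri(d)
  sum(W[iu] * d[iu]) / sum(W[iu])
}

#' Centre of response
#'
#' Amplitude-weighted centroid of the responding units (cells weighted by
#' maximum firing rate, or electrodes weighted by peak depolarization):
#' \eqn{\bar x = \sum w_i x_i / \sum w_i}. This is the variant of the
#' "rate weighted by distance" estimator that is symmetric under
#' relabelling and recovers pure translations of the activity footprint.
#' `method = "unweighted"` returns the plain centroid.
#'
#' @param units Data frame with `x`, `y` and a weight column (`max_rate` or
#'   `amplitude`; the first present is used).
#' @param method `"weighted_centroid"` (default) or `"unweighted"`.
#' @return A one-row tibble with `x` and `y`.
#' @export
response_centre <- function(units, method = c("weighted_centroid",
                                              "unweighted")) {
  method <- match.arg(method)
  if (nrow(units) < 1) abort("need at least one active unit")
  w <- if (method == "unweighted") {
    rep(1, nrow(units))
  } else if ("max_rate" %in% names(units)) {
    units$max_rate
  } else if ("amplitude" %in% names(units)) {
    units$amplitude
  } else {
    abort("`units` needs a `max_rate` or `amplitude` column")
  }
  if (sum(w) <= 0) abort("weights must sum to a positive value")
  tibble(x = sum(w * units$x) / sum(w), y = sum(w * units$y) / sum(w))
}

#' Displacement between two response centres
#'
#' Euclidean distance between two centre-of-response positions.
#'
#' @param centre_a,centre_b One-row data frames with `x`, `y` (as returned
#'   by [response_centre()]) or length-2 numeric vectors.
#' @return Distance in the coordinate unit.
#' @export
centre_displacement <- function(centre_a, centre_b) {
  xy <- function(p) if (is.data.frame(p)) c(p$x[1], p$y[1]) else p[1:2]
  sqrt(sum((xy(centre_a) - xy(centre_b))^2))
}

#' Density of activated cells per stimulated area
#'
#' Ratio of the number of activated cells to the stimulated area: the
#' ultrasound focal-spot area for frequencies of 2.25 MHz and above, and
#' the recording-array area below that (where the focal spot exceeds the
#' array).
#'
#' @param n_responding Number of activated cells.
#' @param frequency Stimulus frequency (Hz).
#' @param focal_area Focal-spot area (mm^2), e.g. `pi * (fwhm/2)^2`.
#' @param mea_area Recording-array area (mm^2).
#' @return Density (cells per mm^2).
#' @export
activated_density <- function(n_responding, frequency, focal_area, mea_area) {
  assert_positive_scalar(focal_area, "focal_area")
  assert_positive_scalar(mea_area, "mea_area")
  n_responding / if (frequency >= 2.25e6) focal_area else mea_area
}
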