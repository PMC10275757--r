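#' Acoustic exposure intensity metrics
#'
#' Computes the non-derated plane-wave exposure intensities used in
#' ultrasound safety reporting from a pulsed stimulus:
#' \describe{
#'   \item{Isppa}{spatial-peak pulse-average intensity
#'     \eqn{p^2 / (2 \rho c)}, cycle-averaged over the on-portion of each
#'     pulse.}
#'   \item{Isptp}{spatial-peak temporal-peak intensity, evaluated with the
#'     same \eqn{p^2 / (2 \rho c)} convention but its own sound speed
#'     (safety-report back-calculation convention).}
#'   \item{Ispta}{spatial-peak temporal-average intensity,
#'     `isppa * duty_cycle * burst_duration / time_base`.}
#' }
#' The two sound speeds are deliberately separate explicit parameters: the
#' conventional Isppa tabulations use soft-tissue c = 1540 m/s while the
#' Isptp back-calculation uses water c = 1500 m/s; neither is hard-coded
#' elsewhere. The Ispta averaging window (`time_base`) defaults to the
#' stimulus repetition period `burst_duration + inter_stimulus_interval`.
#'
#' @param stimulus A [us_stimulus()].
#' @param density Medium density (kg/m3).
#' @param c_isppa Sound speed used for Isppa/Ispta (m/s).
#' @param c_isptp Sound speed used for Isptp (m/s).
#' @param time_base Averaging window for Ispta (s); must be positive.
#' @return A one-row tibble with `isppa`, `ispta`, `isptp` in W cm^-2.
#' @examples
#' s <- us_stimulus(1.27e6, burst_duration = 0.1)
#' exposure_metrics(s) # Isppa 52.37 W/cm2
#' @export
exposure_metrics <- function(stimulus, density = 1000,
                             c_isppa = 1540, c_isptp = 1500,
                             time_base = NULL) {
  stopifnot(inherits(stimulus, "us_stimulus"))
  assert_positive_scalar(density, "density")
  assert_positive_scalar(c_isppa, "c_isppa")
  assert_positive_scalar(c_isptp, "c_isptp")
  time_base <- time_base %||%
    (stimulus$burst_duration + stimulus$inter_stimulus_interval)
  if (!is.numeric(time_base) || time_base <= 0) {
    abort("`time_base` (repetition period) must be positive")
  }
  p <- stimulus$peak_pressure
  w_per_m2_to_w_per_cm2 <- 1e-4
  isppa <- p^2 / (2 * density * c_isppa) * w_per_m2_to_w_per_cm2
  isptp <- p^2 / (2 * density * c_isptp) * w_per_m2_to_w_per_cm2
  ispta <- isppa * stimulus$duty_cycle * stimulus$burst_duration / time_base
  tibble(isppa = isppa, ispta = ispta, isptp = isptp)
}
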