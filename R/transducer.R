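#' Spherical-cap focused transducer specification
#'
#' Describes a single-element concave (spherical-cap) focused transducer by
#' its centre frequency, aperture diameter and radius of curvature (the
#' geometric focus), plus the uniform equivalent surface pressure of the
#' source. All quantities are SI: Hz, m, Pa.
#'
#' The axial origin convention used throughout the acoustic module places
#' `z = 0` at the apex (deepest point) of the concave surface, with `z`
#' increasing along the beam axis towards the focus, so the geometric focus
#' sits at `z = radius_of_curvature`.
#'
#' @param center_frequency Centre frequency (Hz).
#' @param aperture_diameter Active aperture diameter (m). Must be smaller
#'   than twice the radius of curvature.
#' @param radius_of_curvature Radius of curvature of the cap (m); the
#'   geometric focal distance measured from the apex.
#' @param source_amplitude Equivalent surface pressure \eqn{p_0 = \rho c u_0}
#'   (Pa) for a uniform normal-velocity source. The radiated field is linear
#'   in this amplitude.
#'
#' @return An object of class `transducer_spec`.
#' @examples
#' transducer_spec(15e6, 12.7e-3, 25.4e-3)
#' @export
transducer_spec <- function(center_frequency, aperture_diameter,
                            radius_of_curvature, source_amplitude = 1) {
  assert_positive_scalar(center_frequency, "center_frequency")
  assert_positive_scalar(aperture_diameter, "aperture_diameter")
  assert_positive_scalar(radius_of_curvature, "radius_of_curvature")
  assert_nonneg_scalar(source_amplitude, "source_amplitude")
  if (aperture_diameter >= 2 * radius_of_curvature) {
    abort("`aperture_diameter` must be < 2 * `radius_of_curvature`")
  }
  structure(
    list(
      center_frequency = center_frequency,
      aperture_diameter = aperture_diameter,
      radius_of_curvature = radius_of_curvature,
      source_amplitude = source_amplitude
    ),
    class = "transducer_spec"
  )
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf(
    "<transducer_spec> %.2f MHz, aperture %.2f mm, ROC %.2f mm, p0 %.3g Pa\n",
    x$center_frequency / 1e6, x$aperture_diameter * 1e3,
    x$radius_of_curvature * 1e3, x$source_amplitude
  ))
  invisible(x)
}

#' Acoustic propagation medium
#'
#' Linear acoustic properties of the propagation medium. Attenuation follows
#' a frequency power law \eqn{\alpha = \alpha_0 (f/\mathrm{MHz})^y} with
#' \eqn{\alpha_0} in dB cm\eqn{^{-1}} MHz\eqn{^{-y}}. The nonlinearity
#' parameter B/A is stored for reference only; no operation in this package
#' uses it (all propagation is linear).
#'
#' Defaults are degassed water: c = 1500 m/s, rho = 1000 kg/m3,
#' alpha0 = 2.2e-3 dB/cm/MHz^y with y = 2, B/A = 5.
#'
#' @param sound_speed Sound speed c (m/s).
#' @param density Volumetric mass rho (kg/m3).
#' @param attenuation_prefactor Attenuation prefactor (dB cm^-1 MHz^-y).
#' @param attenuation_exponent Frequency power-law exponent y.
#' @param nonlinearity_BA Nonlinearity parameter B/A (stored only).
#'
#' @return An object of class `acoustic_medium`.
#' @examples
#' water <- acoustic_medium()
#' brain <- acoustic_medium(attenuation_prefactor = 0.21, attenuation_exponent = 1.18)
#' @export
acoustic_medium <- function(sound_speed = 1500, density = 1000,
                            attenuation_prefactor = 2.2e-3,
                            attenuation_exponent = 2,
                            nonlinearity_BA = 5) {
  assert_positive_scalar(sound_speed, "sound_speed")
  assert_positive_scalar(density, "density")
  assert_nonneg_scalar(attenuation_prefactor, "attenuation_prefactor")
  assert_positive_scalar(attenuation_exponent, "attenuation_exponent")
  assert_positive_scalar(nonlinearity_BA, "nonlinearity_BA")
  structure(
    list(
      sound_speed = sound_speed,
      density = density,
      attenuation_prefactor = attenuation_prefactor,
      attenuation_exponent = attenuation_exponent,
      nonlinearity_BA = nonlinearity_BA
    ),
    class = "acoustic_medium"
  )
}

#' Ultrasound stimulus (burst timing and pressure)
#'
#' A pulsed ultrasound stimulus: bursts of `burst_duration` seconds of
#' carrier gated at `pulse_repetition_frequency` with on-fraction
#' `duty_cycle`, repeated either every `inter_stimulus_interval` seconds of
#' silence or at `repetition_frequency` (period = 1/repetition_frequency,
#' which must exceed the burst duration).
#'
#' @param peak_pressure Peak (rarefactional/compressional) pressure at the
#'   focus (Pa).
#' @param pulse_repetition_frequency Intra-burst pulse repetition frequency
#'   (Hz). Use 0 for continuous (unpulsed) bursts.
#' @param duty_cycle On-fraction of each pulse period, in (0, 1].
#' @param burst_duration Sonication duration of one burst (s).
#' @param inter_stimulus_interval Silence between bursts (s).
#' @param repetition_frequency Optional stimulus repetition rate (Hz);
#'   overrides `inter_stimulus_interval` when given.
#' @param n_repeats Number of bursts in the sequence.
#'
#' @return An object of class `us_stimulus`.
#' @examples
#' us_stimulus(1.27e6, burst_duration = 0.02, repetition_frequency = 13)
#' @export
us_stimulus <- function(peak_pressure, pulse_repetition_frequency = 1000,
                        duty_cycle = 0.5, burst_duration = 0.05,
                        inter_stimulus_interval = 0.5,
                        repetition_frequency = NULL, n_repeats = 1) {
  assert_nonneg_scalar(peak_pressure, "peak_pressure")
  assert_nonneg_scalar(pulse_repetition_frequency, "pulse_repetition_frequency")
  if (!is.numeric(duty_cycle) || duty_cycle <= 0 || duty_cycle > 1) {
    abort("`duty_cycle` must be in (0, 1]")
  }
  assert_positive_scalar(burst_duration, "burst_duration")
  if (pulse_repetition_frequency > 0 &&
      burst_duration < 1 / pulse_repetition_frequency) {
    abort("`burst_duration` must cover at least one pulse repetition period")
  }
  if (!is.null(repetition_frequency)) {
    assert_positive_scalar(repetition_frequency, "repetition_frequency")
    if (1 / repetition_frequency <= burst_duration) {
      abort("repetition period must exceed `burst_duration`")
    }
    inter_stimulus_interval <- 1 / repetition_frequency - burst_duration
  }
  assert_nonneg_scalar(inter_stimulus_interval, "inter_stimulus_interval")
  structure(
    list(
      peak_pressure = peak_pressure,
      pulse_repetition_frequency = pulse_repetition_frequency,
      duty_cycle = duty_cycle,
      burst_duration = burst_duration,
      inter_stimulus_interval = inter_stimulus_interval,
      repetition_frequency = 1 / (burst_duration + inter_stimulus_interval),
      n_repeats = n_repeats
    ),
    class = "us_stimulus"
  )
}

#' Built-in transducer presets
#'
#' The three spherical-cap geometries used throughout the package examples:
#' \describe{
#'   \item{"0.5MHz"}{25.4 mm aperture, 31.75 mm radius of curvature.}
#'   \item{"2.25MHz"}{12.7 mm aperture, 25.4 mm radius of curvature.}
#'   \item{"15MHz"}{12.7 mm aperture, 25.4 mm radius of curvature.}
#' }
#' All presets pair the transducer with a degassed-water medium.
#'
#' @param name Preset name: `"0.5MHz"`, `"2.25MHz"` or `"15MHz"`.
#' @return A list with elements `transducer` and `medium`.
#' @examples
#' us_preset("15MHz")
#' @export
us_preset <- function(name = c("0.5MHz", "2.25MHz", "15MHz")) {
  name <- match.arg(name)
  geom <- switch(name,
    "0.5MHz"  = list(f = 0.5e6,  d = 25.4e-3, roc = 31.75e-3),
    "2.25MHz" = list(f = 2.25e6, d = 12.7e-3, roc = 25.4e-3),
    "15MHz"   = list(f = 15e6,   d = 12.7e-3, roc = 25.4e-3)
  )
  list(
    transducer = transducer_spec(geom$f, geom$d, geom$roc),
    medium = acoustic_medium()
  )
}
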