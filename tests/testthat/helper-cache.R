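# Shared fixtures, memoized across test files (beam characterizations and
# the 15 MHz focal field are expensive; each is computed at most once per
# test run).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

cached_beam <- function(preset) {
  cached(paste0("beam_", preset), {
    pre <- us_preset(preset)
    characterize_beam(pre$transducer, pre$medium)
  })
}

# Calibrated 15 MHz axisymmetric focal field (1.27 MPa at the focus).
cached_focal_field15 <- function() {
  cached("focal15", {
    pre <- us_preset("15MHz")
    focal_pressure_map(pre$transducer, pre$medium,
                       target_focal_pressure = 1.27e6)
  })
}

# A small uniform-pressure field for scalar source-term checks.
uniform_pressure_field <- function(p, n = 5L, spacing = 1e-4) {
  ax <- seq(0, by = spacing, length.out = n)
  g <- field_grid(x = ax, y = ax, z = ax + 1e-3)
  structure(
    list(grid = g, pressure = array(p, c(n, n, n)),
         amplitude = array(complex(real = p), c(n, n, n)), frequency = 15e6),
    class = "pressure_field"
  )
}

# Gaussian pressure ball |p|(r) = p0 exp(-r^2 / (2 sigma^2)) on a cube.
gaussian_pressure_field <- function(p0 = 1e6, sigma = 5e-4, n = 41L,
                                    halfwidth = 2e-3) {
  ax <- seq(-halfwidth, halfwidth, length.out = n)
  d2 <- as.matrix(expand.grid(ax, ax, ax)^2) %*% c(1, 1, 1)
  g <- field_grid(x = ax, y = ax, z = ax)
  structure(
    list(grid = g, pressure = array(p0 * exp(-d2 / (2 * sigma^2)), c(n, n, n)),
         frequency = 15e6),
    class = "pressure_field"
  )
}

# Continuous (single-segment) stimulus helper for solver closed-form tests.
continuous_stimulus <- function(p = 1e6, duration = 0.1) {
  us_stimulus(p, pulse_repetition_frequency = 0, duty_cycle = 1,
              burst_duration = duration, inter_stimulus_interval = duration)
}
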