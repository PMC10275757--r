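# Frozen oracle values (computed before the build with an independent
# brute-force Rayleigh quadrature of the cap integral at lambda/32 arc
# discretization, trapezoid rule; and by hand unit conversion):
#   15 MHz geometry (12.7 mm aperture, 25.4 mm ROC, attenuating water):
#     on-axis argmax depth = 25.268 mm
#   0.5 MHz geometry (25.4 mm aperture, 31.75 mm ROC): argmax = 24.780 mm
#   attenuation: (2.2e-3 dB/cm/MHz^2, y = 2, 0.5 MHz) -> 0.00633211 Np/m

test_that("attenuation conversion reproduces hand-converted values", {
  expect_equal(attenuation_np(0.21, 1.18, 15e6), 59.0463, tolerance = 1e-5)
  expect_equal(attenuation_np(2.2e-3, 2, 0.5e6), 0.00633211,
               tolerance = 1e-5)
  # at 1 MHz only the dB/cm -> Np/m conversion remains
  for (x in c(0.1, 0.5, 2)) {
    expect_equal(attenuation_np(x, 1.7, 1e6), x * 100 * log(10) / 20)
  }
})

test_that("on-axis closed form matches an independent Rayleigh quadrature", {
  # independent oracle: direct theta quadrature of the cap integral
  onaxis_oracle <- function(z, f, a, A, c = 1500, alpha = 0) {
    k <- complex(real = 2 * pi * f / c, imaginary = alpha)
    thmax <- asin(a / A)
    th <- seq(0, thmax, length.out = 20001)
    vapply(z, function(zz) {
      R <- sqrt((zz - A * (1 - cos(th)))^2 + (A * sin(th))^2)
      integ <- sin(th) * exp(1i * k * R) / R
      Mod((2 * pi * f / c) * A^2 *
            (sum(integ) - 0.5 * integ[1] - 0.5 * integ[length(th)]) *
            diff(th)[1])
    }, numeric(1))
  }
  tx <- transducer_spec(15e6, 12.7e-3, 25.4e-3)
  med <- acoustic_medium()
  al <- attenuation_np(2.2e-3, 2, 15e6)
  z <- c(20e-3, 23e-3, 25.268e-3, 27e-3)
  expect_equal(onaxis_pressure(tx, med, z),
               onaxis_oracle(z, 15e6, 6.35e-3, 25.4e-3, alpha = al),
               tolerance = 1e-4)
  # frozen argmax depths from the pre-build oracle
  zg <- seq(20e-3, 28e-3, by = 2e-6)
  expect_equal(zg[which.max(onaxis_pressure(tx, med, zg))] * 1e3, 25.268,
               tolerance = 1e-3)
  tx05 <- transducer_spec(0.5e6, 25.4e-3, 31.75e-3)
  zg <- seq(5e-3, 55e-3, by = 1e-5)
  expect_equal(zg[which.max(onaxis_pressure(tx05, med, zg))] * 1e3, 24.780,
               tolerance = 1e-3)
})

test_that("on-axis pressure is linear in source amplitude with exact focal limit", {
  med <- acoustic_medium(attenuation_prefactor = 0) # lossless
  tx1 <- transducer_spec(0.5e6, 25.4e-3, 31.75e-3, source_amplitude = 1)
  tx2 <- transducer_spec(0.5e6, 25.4e-3, 31.75e-3, source_amplitude = 2)
  z <- c(10e-3, 25e-3, 31.75e-3, 40e-3)
  expect_equal(onaxis_pressure(tx2, med, z), 2 * onaxis_pressure(tx1, med, z))
  # geometric-focus singularity resolves to the closed-form limit p0 * k * h
  k <- 2 * pi * 0.5e6 / 1500
  h <- 31.75e-3 - sqrt(31.75e-3^2 - 12.7e-3^2)
  expect_equal(onaxis_pressure(tx1, med, 31.75e-3), k * h, tolerance = 1e-10)
})

test_that("Rayleigh surface integral matches the closed form on axis", {
  med0 <- acoustic_medium(attenuation_prefactor = 0)
  for (preset in c("0.5MHz", "2.25MHz")) {
    pre <- us_preset(preset)
    tx <- pre$transducer
    A <- tx$radius_of_curvature
    z <- seq(0.2 * A, 1.5 * A, length.out = 24)
    z <- z[abs(z - A) > 1e-4]
    g <- field_grid(z = z)
    lam <- 1500 / tx$center_frequency
    fld <- rayleigh_field(tx, med0, g, max_pitch = lam / 12)
    ref <- onaxis_pressure(tx, med0, z)
    expect_lt(max(abs(as.vector(fld$pressure) / ref - 1)), 0.01)
  }
})

test_that("transverse profile through the focus is radially symmetric", {
  pre <- us_preset("2.25MHz")
  xs <- seq(-1.5e-3, 1.5e-3, by = 1e-4)
  g <- field_grid(x = xs, z = 21.7e-3)
  fld <- rayleigh_field(pre$transducer, pre$medium, g)
  p <- as.vector(fld$pressure)
  expect_equal(p, rev(p), tolerance = 1e-6)
  gy <- field_grid(y = xs, z = 21.7e-3)
  fy <- rayleigh_field(pre$transducer, pre$medium, gy)
  expect_equal(as.vector(fy$pressure), p, tolerance = 1e-6)
})

test_that("beam FWHM narrows with frequency; axial exceeds lateral; focus approached at high ka", {
  b05 <- cached_beam("0.5MHz")
  b225 <- cached_beam("2.25MHz")
  b15 <- cached_beam("15MHz")
  expect_gt(b05$lateral_fwhm, b225$lateral_fwhm)
  expect_gt(b225$lateral_fwhm, b15$lateral_fwhm)
  for (b in list(b05, b225, b15)) {
    expect_gt(b$axial_fwhm, b$lateral_fwhm)
  }
  expect_lte(b05$peak_depth, 31.75e-3)
  expect_lte(b225$peak_depth, 25.4e-3)
  # high-gain limit: peak depth within 1% of the geometric focus at 15 MHz
  expect_equal(b15$peak_depth, 25.4e-3, tolerance = 0.01)
  # low-gain geometry peaks proximal to the focus
  expect_lt(b05$peak_depth, 31.75e-3 * 0.99)
})

test_that("beam metrics recover the closed form on a synthetic Gaussian field", {
  sigma <- 0.8e-3
  ax <- seq(-4e-3, 4e-3, by = 5e-5)
  zax <- seq(10e-3, 40e-3, by = 2e-4)
  pz <- exp(-(zax - 25e-3)^2 / (2 * (3 * sigma)^2))
  px <- exp(-ax^2 / (2 * sigma^2))
  arr <- array(outer(px, pz), c(length(ax), 1, length(zax)))
  fld <- structure(
    list(grid = field_grid(x = ax, z = zax), pressure = arr,
         frequency = 1e6),
    class = "pressure_field"
  )
  bm <- beam_metrics(fld)
  expect_equal(bm$lateral_fwhm, 2 * sigma * sqrt(2 * log(2)),
               tolerance = 1e-3)
  expect_equal(bm$axial_fwhm, 2 * 3 * sigma * sqrt(2 * log(2)),
               tolerance = 1e-3)
  expect_equal(bm$peak_depth, 25e-3, tolerance = 1e-2)
  # peak on the grid boundary is refused
  bad <- fld
  bad$pressure[1, 1, ] <- 2 * max(bad$pressure)
  expect_error(beam_metrics(bad), "boundary")
})

test_that("beam metrics converge under grid refinement (< 0.5% change)", {
  pre <- us_preset("2.25MHz")
  # transverse metrics on an explicit grid at two samplings
  mk <- function(dx) {
    g <- field_grid(x = seq(-2.2e-3, 2.2e-3, by = dx), z = 21.7e-3)
    beam_metrics(rayleigh_field(pre$transducer, pre$medium, g))
  }
  coarse <- mk(8e-5)
  fine <- mk(4e-5)
  for (col in c("lateral_fwhm", "peak_pressure")) {
    expect_lt(abs(coarse[[col]] / fine[[col]] - 1), 0.005)
  }
  # axial metrics from the closed-form profile at two samplings
  lam <- 1500 / 2.25e6
  ca <- characterize_beam(pre$transducer, pre$medium, dz = lam / 16)
  fa <- characterize_beam(pre$transducer, pre$medium, dz = lam / 32)
  expect_lt(abs(ca$axial_fwhm / fa$axial_fwhm - 1), 0.005)
  expect_lt(abs(ca$peak_depth / fa$peak_depth - 1), 0.005)
})

test_that("amplitude calibration is an exact linear rescale", {
  pre <- us_preset("15MHz")
  expect_equal(calibrate_amplitude(pre$transducer, pre$medium, 0), 0)
  a1 <- calibrate_amplitude(pre$transducer, pre$medium, 1.27e6)
  a2 <- calibrate_amplitude(pre$transducer, pre$medium, 2 * 1.27e6)
  expect_equal(a2, 2 * a1)
  tx <- pre$transducer
  tx$source_amplitude <- a1
  z <- seq(20e-3, 28e-3, by = 1e-5)
  expect_equal(max(onaxis_pressure(tx, pre$medium, z)), 1.27e6,
               tolerance = 1e-6)
})

test_that("field simulation refuses invalid inputs", {
  pre <- us_preset("2.25MHz")
  g <- field_grid(z = c(20e-3, 22e-3))
  lam <- 1500 / 2.25e6
  expect_error(rayleigh_field(pre$transducer, pre$medium, g,
                              max_pitch = lam * 0.6), "refuse")
  expect_error(field_grid(z = c(2e-3, 1e-3)), "increasing")
  expect_error(transducer_spec(1e6, 30e-3, 10e-3), "radius_of_curvature")
  # a node behind the concave surface is flagged invalid, not evaluated
  gin <- field_grid(x = c(0, 2.54e-3), z = c(1e-5, 20e-3))
  fld <- rayleigh_field(pre$transducer, pre$medium, gin)
  expect_true(is.na(fld$pressure[2, 1, 1]))
  expect_equal(fld$n_invalid, 1)
})
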