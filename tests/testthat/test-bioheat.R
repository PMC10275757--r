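test_that("heating source term is the absorbed-intensity formula", {
  par <- tissue_thermal_params() # absorption 59.0463 Np/m at 15 MHz
  st <- us_stimulus(1.27e6, burst_duration = 0.02)
  fld <- uniform_pressure_field(1.27e6)
  src <- build_heat_source(fld, par, st, duty_as_factor = FALSE)
  # scalar arithmetic oracle, written out independently
  q_expected <- attenuation_np(0.21, 1.18, 15e6) * (1.27e6)^2 / (1046 * 1546)
  expect_equal(src$q_us[2, 2, 2], q_expected, tolerance = 1e-12)
  # duty cycle as a multiplicative source factor
  src_d <- build_heat_source(fld, par, st)
  expect_equal(src_d$q_us, 0.5 * src$q_us)
  # quadratic pressure scaling and the zero field
  src_h <- build_heat_source(uniform_pressure_field(1.27e6 / 2), par, st,
                             duty_as_factor = FALSE)
  expect_equal(src_h$q_us, src$q_us / 4)
  src_0 <- build_heat_source(uniform_pressure_field(0), par, st)
  expect_true(all(src_0$q_us == 0))
})

test_that("Pennes solver reproduces the adiabatic and perfusion-balance closed forms", {
  # K_t = 0 decouples the nodes; interior nodes follow the 0-d closed forms
  par_ad <- tissue_thermal_params(thermal_conductivity = 0,
                                  perfusion_coefficient = 0,
                                  metabolic_heat = 0)
  fld <- uniform_pressure_field(1e6)
  st <- continuous_stimulus(1e6, duration = 2)
  src <- build_heat_source(fld, par_ad, st, duty_as_factor = FALSE)
  sol <- solve_pennes(src, par_ad, duration = 2, time_step = 0.01,
                      snapshot_times = c(1, 2))
  rhoC <- 1046 * 3630
  q <- src$q_us[2, 2, 2]
  # T(t) = T0 + q t / (rho C), exact (4+ significant figures)
  expect_equal(sol$snapshots[[1]][3, 3, 3] - 37, q * 1 / rhoC,
               tolerance = 1e-10)
  expect_equal(sol$snapshots[[2]][3, 3, 3] - 37, q * 2 / rhoC,
               tolerance = 1e-10)
  # with perfusion: theta(t) = (q/(rho_bl C_bl P)) (1 - exp(-pe t))
  par_pf <- tissue_thermal_params(thermal_conductivity = 0,
                                  metabolic_heat = 0)
  src_long <- build_heat_source(fld, par_pf, continuous_stimulus(1e6, 600),
                                duty_as_factor = FALSE)
  sol_pf <- solve_pennes(src_long, par_pf, duration = 600, time_step = 0.05,
                         snapshot_times = c(300, 600))
  steady <- q / (1050 * 3617 * 9.7e-3)
  pe <- 1050 * 3617 * 9.7e-3 / rhoC
  expect_equal(sol_pf$snapshots[[1]][3, 3, 3] - 37,
               steady * (1 - exp(-pe * 300)), tolerance = 1e-9)
  expect_equal(sol_pf$snapshots[[2]][3, 3, 3] - 37, steady,
               tolerance = 1e-4 * steady)
})

test_that("a source-free field at arterial temperature stays exactly arterial", {
  par <- tissue_thermal_params(metabolic_heat = 0)
  src <- build_heat_source(uniform_pressure_field(0), par,
                           continuous_stimulus(0, 0.1))
  sol <- solve_pennes(src, par, duration = 0.1, snapshot_times = 0.1)
  expect_true(all(sol$snapshots[[1]] == 37))
  expect_equal(max(sol$trace$max_rise), 0)
})

test_that("explicit stability violations are refused with the admissible step", {
  par <- tissue_thermal_params()
  src <- build_heat_source(gaussian_pressure_field(n = 21L), par,
                           continuous_stimulus(1e6, 0.1))
  d <- 4e-3 / 20
  dt_adm <- 1 / (2 * (0.51 / (1046 * 3630)) * 3 / d^2)
  expect_error(solve_pennes(src, par, 0.1, time_step = 2 * dt_adm),
               "stability")
  expect_error(solve_pennes(src, par, 0.1, time_step = 2 * dt_adm),
               sprintf("%.3g", dt_adm))
})

test_that("FD and spectral solvers agree with the Green's-function oracle", {
  par <- tissue_thermal_params()
  st <- continuous_stimulus(1e6, 0.1)
  fld <- gaussian_pressure_field(p0 = 1e6, sigma = 5e-4, n = 41L)
  src <- build_heat_source(fld, par, st)
  fd <- pennes_rise(src, par, duration = 0.1)
  sp <- solve_pennes_spectral(src, par, duration = 0.1)
  # independent oracle: continuous heating of a Gaussian ball, spatial
  # Green's function integrated in closed form, 1-d time quadrature
  rhoC <- 1046 * 3630
  kap <- 0.51 / rhoC
  pe <- 1050 * 3617 * 9.7e-3 / rhoC
  s0 <- max(src$q_us) / rhoC
  sigq <- 5e-4 / sqrt(2) # q ~ p^2 halves the Gaussian variance
  oracle <- s0 * stats::integrate(function(tau) {
    (sigq^2 / (sigq^2 + 2 * kap * tau))^1.5 * exp(-pe * tau)
  }, 0, 0.1, rel.tol = 1e-10)$value
  expect_equal(max(sp$trace$max_rise), oracle, tolerance = 1e-4)
  expect_equal(max(fd$trace$max_rise), oracle, tolerance = 0.02)
  expect_equal(max(fd$trace$max_rise), max(sp$trace$max_rise),
               tolerance = 0.02)
  # node tracking equals the full-field spatial maximum
  spf <- solve_pennes_spectral(src, par, duration = 0.1, track = "full")
  expect_equal(max(sp$trace$max_rise), max(spf$trace$max_rise),
               tolerance = 1e-9)
})

test_that("the US-induced rise is linear in q_us and equals the two-run difference", {
  par <- tissue_thermal_params() # metabolic heat on
  st <- continuous_stimulus(1e6, 0.05)
  fld <- gaussian_pressure_field(n = 21L)
  src <- build_heat_source(fld, par, st)
  snap <- c(0.025, 0.05)
  with_us <- solve_pennes(src, par, 0.05, snapshot_times = snap)
  src0 <- build_heat_source(gaussian_pressure_field(p0 = 0, n = 21L), par, st)
  without <- solve_pennes(src0, par, 0.05, snapshot_times = snap)
  two_run <- us_temperature_rise(with_us, without)
  direct <- pennes_rise(src, par, 0.05, snapshot_times = snap)
  expect_equal(two_run, max(direct$trace$max_rise), tolerance = 1e-12)
  # metabolic baseline genuinely evolves yet cancels in the difference
  expect_gt(max(without$trace$max_rise), 0)
  # rise scales linearly with q_us (quadratically with pressure)
  fld2 <- gaussian_pressure_field(p0 = 1e6 * sqrt(2), n = 21L)
  src2 <- build_heat_source(fld2, par, st)
  direct2 <- pennes_rise(src2, par, 0.05)
  expect_equal(max(direct2$trace$max_rise), 2 * max(direct$trace$max_rise),
               tolerance = 1e-9)
})

test_that("mismatched grids and schedules are refused", {
  par <- tissue_thermal_params()
  st <- continuous_stimulus(1e6, 0.05)
  fld <- gaussian_pressure_field(n = 21L)
  src <- build_heat_source(fld, par, st)
  a <- solve_pennes(src, par, 0.05, snapshot_times = 0.05)
  b <- solve_pennes(src, par, 0.05, snapshot_times = 0.025)
  expect_error(us_temperature_rise(a, b), "snapshot")
  other <- build_heat_source(gaussian_pressure_field(n = 11L), par, st)
  expect_error(build_heat_source(fld, par, st,
                                 grid = other$grid), "grid")
})

test_that("repeated-burst peak rise is non-decreasing in repetition frequency", {
  par <- tissue_thermal_params()
  fld <- gaussian_pressure_field(p0 = 1e6, sigma = 4e-4, n = 33L,
                                 halfwidth = 3.2e-3)
  peaks <- vapply(c(2, 5, 13), function(fr) {
    st <- us_stimulus(1e6, burst_duration = 0.02, repetition_frequency = fr)
    src <- build_heat_source(fld, par, st)
    repeated_burst_rise(src, par, min_time = 2, max_time = 3)$peak_rise
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})
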