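test_that("spike density function conserves kernel mass", {
  # single spike: unit-mass kernel centred on it
  sdf <- spike_density_function(0.05, c(-0.2, 0.3), dt = 1e-3)
  expect_equal(sum(sdf$rate) * 1e-3, 1, tolerance = 1e-6)
  expect_equal(sdf$time[which.max(sdf$rate)], 0.05, tolerance = 1e-3)
  # two kernel widths, equal integrals
  sp <- c(0.01, 0.013, 0.05, 0.09)
  s1 <- spike_density_function(sp, c(-0.2, 0.3), sigma = 2e-3)
  s2 <- spike_density_function(sp, c(-0.2, 0.3), sigma = 8e-3)
  expect_equal(sum(s1$rate), sum(s2$rate), tolerance = 1e-4)
  # pooling over trials normalizes to per-trial rate
  df <- tibble::tibble(time = rep(sp, 5), trial = rep(1:5, each = 4))
  s5 <- spike_density_function(df, c(-0.2, 0.3))
  expect_equal(sum(s5$rate) * 1e-3, 4, tolerance = 1e-5)
  # empty train: zero trace
  s0 <- spike_density_function(numeric(0), c(0, 0.1))
  expect_true(all(s0$rate == 0))
})

test_that("SDF recovers a homogeneous Poisson rate", {
  set.seed(11)
  r <- 30
  sp <- cumsum(rexp(600, r))
  sp <- sp[sp < 10]
  sdf <- spike_density_function(sp, c(0.5, 9.5))
  expect_equal(mean(sdf$rate), r, tolerance = 0.1)
})

test_that("latency is the post-onset derivative maximum, shift-equivariant", {
  set.seed(21)
  mk_spikes <- function(delay, onset = 0, n_trials = 30) {
    unlist(lapply(seq_len(n_trials), function(i) {
      c(runif(3, -0.2, 0.25),                         # baseline
        onset + delay + sort(runif(12, 0, 0.08)))     # burst
    }))
  }
  sp <- mk_spikes(0.012)
  sdf <- spike_density_function(sp, c(-0.2, 0.25), n_trials = 30)
  lat <- response_latency(sdf, onset = 0)
  expect_lt(abs(lat - 12), 3)  # within one kernel width (sigma = 3 ms)
  # long-latency case classified beyond the 45 ms threshold
  sp50 <- mk_spikes(0.050)
  lat50 <- response_latency(
    spike_density_function(sp50, c(-0.2, 0.25), n_trials = 30), 0
  )
  expect_gt(lat50, 45)
  expect_lt(abs(lat50 - 50), 3)
  # shifting spikes and onset together leaves the latency unchanged
  sdf_sh <- spike_density_function(sp + 0.1, c(-0.1, 0.35), n_trials = 30)
  expect_equal(response_latency(sdf_sh, onset = 0.1), lat, tolerance = 1e-9)
  # flat trace: undefined
  flat <- tibble::tibble(time = seq(0, 0.1, 1e-3), rate = 5)
  expect_true(is.na(response_latency(flat, 0)))
})

test_that("A/e duration matches closed forms and is scale invariant", {
  tt <- seq(-0.1, 0.4, by = 1e-4)
  sig <- 0.02
  gaus <- tibble::tibble(time = tt, rate = 80 * exp(-(tt - 0.1)^2 / (2 * sig^2)))
  d <- response_duration(gaus)
  expect_equal(d, 2 * sqrt(2) * sig * 1e3, tolerance = 1e-3,
               ignore_attr = TRUE)
  # scaling the trace leaves the duration unchanged
  gaus2 <- gaus
  gaus2$rate <- gaus2$rate * 7.3
  expect_equal(response_duration(gaus2), d)
  # rectangular response of length L, narrow-kernel smoothed: ~L
  set.seed(31)
  L <- 0.1
  sp <- unlist(lapply(1:40, function(i) sort(runif(40, 0, L))))
  sdf <- spike_density_function(sp, c(-0.1, 0.3), sigma = 2e-3, n_trials = 40)
  expect_equal(as.numeric(response_duration(sdf)), L * 1e3, tolerance = 0.1)
  # censoring: trace still above A/e at the window edge
  cens <- tibble::tibble(time = seq(0, 0.05, 1e-3),
                         rate = 10 + seq(0, 0.05, 1e-3))
  expect_true(is.na(response_duration(cens)))
  expect_true(attr(response_duration(cens), "censored"))
})

test_that("Fano factor: Poisson near 1, deterministic 0, hand arithmetic", {
  expect_equal(fano_factor(c(2, 4, 6, 8)), (20 / 3) / 5) # var 20/3, mean 5
  expect_equal(fano_factor(rep(7, 20)), 0)
  set.seed(41)
  expect_lt(abs(fano_factor(rpois(2000, 4)) - 1), 0.1)
  expect_true(is.na(fano_factor(c(0, 0, 0))))
  expect_error(fano_factor(3), "2 trials")
})

test_that("weighted dispersion behaves on degenerate and synthetic footprints", {
  one <- tibble::tibble(x = c(1, 1, 1), y = c(2, 2, 2),
                        max_rate = c(5, 1, 3))
  expect_equal(spatial_dispersion(one), 0)
  two <- tibble::tibble(x = c(0, 3), y = c(0, 4), max_rate = c(10, 10))
  expect_equal(spatial_dispersion(two), 5)
  # dispersion grows monotonically with the footprint width
  set.seed(51)
  disp <- vapply(c(0.1, 0.3, 0.6), function(s) {
    cells <- tibble::tibble(x = rnorm(200, 0, s), y = rnorm(200, 0, s),
                            max_rate = runif(200, 10, 60))
    spatial_dispersion(cells)
  }, numeric(1))
  expect_true(all(diff(disp) > 0))
  # down-weighted distant cells shrink the dispersion
  mix <- tibble::tibble(x = c(0, 0.1, 5), y = 0, max_rate = c(50, 50, 1))
  expect_lt(spatial_dispersion(mix),
            spatial_dispersion(dplyr::mutate(mix, max_rate = 50)))
})

test_that("response centre is the weighted centroid with exact recovery", {
  sym <- tibble::tibble(x = c(-1, 1, 0, 0) + 2, y = c(0, 0, -1, 1) + 3,
                        max_rate = rep(8, 4))
  expect_equal(unlist(response_centre(sym)), c(x = 2, y = 3))
  single <- tibble::tibble(x = 1.2, y = 3.4, max_rate = 5)
  expect_equal(unlist(response_centre(single)), c(x = 1.2, y = 3.4))
  shifted <- dplyr::mutate(sym, x = x + 0.4)
  expect_equal(centre_displacement(response_centre(sym),
                                   response_centre(shifted)), 0.4)
  expect_equal(centre_displacement(c(0, 0), c(3, 4)), 5)
  # electrode amplitudes work through the same estimator
  amps <- tibble::tibble(x = c(0, 1), y = c(0, 0), amplitude = c(1, 3))
  expect_equal(response_centre(amps)$x, 0.75)
})

test_that("activated density selects the right normalizing area", {
  expect_equal(activated_density(10, 15e6, focal_area = 1, mea_area = 9), 10)
  expect_equal(activated_density(0, 15e6, 1, 9), 0)
  expect_equal(activated_density(12, 0.5e6, 1, 9), 12 / 9)
  expect_equal(activated_density(12, 2.25e6, 2, 9), 6)
  # focal disc area from a beam FWHM
  fw <- 0.276
  expect_equal(activated_density(5, 15e6, pi * (fw / 2)^2, 9),
               5 / (pi * 0.138^2))
})

test_that("response dominance index spans ON to OFF", {
  expect_equal(response_dominance_index(30, 0), 1)
  expect_equal(response_dominance_index(0, 30), -1)
  expect_equal(response_dominance_index(20, 20), 0)
  expect_equal(response_dominance_index(30, 10), 0.5)
  expect_true(is.na(response_dominance_index(0, 0)))
})

test_that("per-cell metrics classify SL/LL exhaustively at 45 ms", {
  cfg <- generator_config(seed = 13)
  mea <- gen_retina_mea(cfg, n_trials = 15)
  cr <- cell_responses(mea$spikes, mea$events)
  expect_true(all(cr$latency_class %in% c("SL", "LL")))
  with_lat <- cr[!is.na(cr$latency), ]
  expect_true(all((with_lat$latency < 45) == (with_lat$latency_class == "SL")))
  # responsive cells are overwhelmingly true responders
  truth <- mea$cells
  joined <- dplyr::inner_join(cr, truth, by = "cell")
  expect_gt(mean(joined$responding[joined$responsive]), 0.6)
  # strong responders are almost all detected
  strong <- joined[joined$responding & joined$peak_rate > 30, ]
  expect_gt(mean(strong$responsive), 0.8)
})
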