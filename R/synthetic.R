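# Run code with a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rtruncnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Synthetic-data generator configuration
#'
#' Parameters of the synthetic retinal MEA, micro-ECoG and behavioural
#' generators. Defaults encode the study conditions the analysis targets:
#' short-latency (direct, mechanosensitive-channel) responses at
#' 12.2 +/- 2.5 ms and long-latency (network) responses at 50.4 +/- 4.2 ms;
#' a 16 x 16, 200 um-pitch MEA; a 32-channel, 300 um-pitch surface array
#' (6 x 6 grid minus corners); beam footprints of 4.36, 1.61 and 0.276 mm
#' FWHM at 0.5, 2.25 and 15 MHz; 35-trial behavioural sessions with
#' 10-30 s inter-trial intervals, a 500 ms reward delay and anticipatory
#' lick latencies of 187.1 +/- 37.3 ms (US) / 265.9 +/- 46.5 ms (light).
#' The response-probability and success-probability pressure dependences
#' are logistic (a modelling choice; the data constrain only
#' monotonicity).
#'
#' @param seed Integer seed; every generator is deterministic given the
#'   seed (each derives an independent stream offset from it).
#' @param ... Named overrides of any default listed above (see the
#'   returned object for field names).
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # retinal MEA geometry
    mea_pitch = 0.2, mea_nx = 16L, mea_ny = 16L,           # mm, electrodes
    n_cells = 800L,                # RGCs scattered over the array
    response_spread = 0.25,        # mm, biological spread added to the beam
    transfected_fraction = 0.5,
    footprint_fwhm = c("0.5" = 4.36, "2.25" = 1.61, "15" = 0.276), # mm
    sl_latency_mean = 12.2e-3, sl_latency_sd = 2.5e-3,     # s
    ll_latency_mean = 50.4e-3, ll_latency_sd = 4.2e-3,     # s
    baseline_rate = 2,                                     # Hz
    peak_rate_max = 60,                                    # Hz
    pressure_p50 = 0.35, pressure_slope = 0.35,            # MPa, logistic
    ll_response_scale = 0.4,       # LL response probability multiplier
    # ECoG
    ecog_pitch = 0.3, ecog_n = 6L,                         # mm, grid minus corners
    ecog_footprint_fwhm = 1.2,                             # mm, cortical spread
    n1_amplitude = 15, n1_latency = 0.02, n1_width = 5e-3, # uV, s, s
    ecog_noise_sd = 3, ecog_fs = 1000,                     # uV, Hz
    # behaviour
    n_trials = 35L, iti_range = c(10, 30), reward_delay = 0.5,
    spontaneous_lick_rate = 1,                             # Hz
    compulsive_lick_rate = 6,                              # Hz
    lick_latency_us = c(mean = 187.1e-3, sd = 37.3e-3),    # s
    lick_latency_light = c(mean = 265.9e-3, sd = 46.5e-3), # s
    success_p50 = 0.35, success_slope = 0.35, success_max = 0.75
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown generator parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "generator_config")
}

footprint_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Synthetic retinal MEA recording
#'
#' Generates inhomogeneous-Poisson spike trains for a population of retinal
#' ganglion cells on the MEA grid under repeated focused-ultrasound
#' stimulation. Cells respond with probability proportional to the
#' Gaussian beam footprint at their position times a logistic
#' pressure-sensitivity term; short-latency responses occur only in
#' "transfected" cells, long-latency (network) responses in any cell.
#' Responding cells fire at an elevated rate from onset + latency to
#' stimulus offset + latency, on top of baseline activity.
#'
#' @param config A [generator_config()].
#' @param pressure Peak pressure (MPa).
#' @param frequency Stimulus frequency (Hz); selects the beam footprint.
#' @param duration Stimulus duration (s).
#' @param n_trials Number of stimulus repetitions (0.5 Hz repetition).
#' @param centre Beam centre (mm, length 2); default the array centre.
#' @return A list: `spikes` (tibble `cell`, `trial`, `time` in s, absolute),
#'   `events` (tibble `trial`, `onset`, `duration`, `pressure`,
#'   `frequency`), `cells` ground truth (position, transfected, responding,
#'   class, latency, peak rate), `centre`.
#' @export
gen_retina_mea <- function(config, pressure = 1.27, frequency = 15e6,
                           duration = 0.1, n_trials = 20L, centre = NULL) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 101L, {
    pitch <- config$mea_pitch
    lim_x <- (config$mea_nx - 1) * pitch
    lim_y <- (config$mea_ny - 1) * pitch
    n_cells <- config$n_cells
    xy <- tibble(x = runif(n_cells, 0, lim_x), y = runif(n_cells, 0, lim_y))
    centre <- centre %||% c(lim_x / 2, lim_y / 2)
    fw <- config$footprint_fwhm[[sprintf("%g", frequency / 1e6)]]
    if (is.null(fw)) abort("no footprint FWHM configured for this frequency")
    # response footprint: beam width convolved with a biological spread
    sig <- sqrt(footprint_sigma(fw)^2 + config$response_spread^2)
    d2 <- (xy$x - centre[1])^2 + (xy$y - centre[2])^2
    w <- exp(-d2 / (2 * sig^2))
    sens <- stats::plogis((pressure - config$pressure_p50) /
                            config$pressure_slope)
    transfected <- runif(n_cells) < config$transfected_fraction
    p_sl <- w * sens * transfected
    p_ll <- w * sens * config$ll_response_scale
    responds_sl <- runif(n_cells) < p_sl
    responds_ll <- !responds_sl & runif(n_cells) < p_ll
    responding <- responds_sl | responds_ll
    latency <- rep(NA_real_, n_cells)
    latency[responds_sl] <- rtruncnorm_pos(sum(responds_sl),
                                           config$sl_latency_mean,
                                           config$sl_latency_sd)
    latency[responds_ll] <- rtruncnorm_pos(sum(responds_ll),
                                           config$ll_latency_mean,
                                           config$ll_latency_sd)
    peak_rate <- ifelse(responding,
                        config$peak_rate_max * (0.3 + 0.7 * w) * sens, 0)
    period <- 2
    events <- tibble(
      trial = seq_len(n_trials),
      onset = (seq_len(n_trials) - 1) * period + 0.5,
      duration = duration, pressure = pressure, frequency = frequency
    )
    total_time <- n_trials * period
    spikes <- purrr::map_dfr(seq_len(n_cells), function(ic) {
      # baseline homogeneous Poisson over the whole recording
      nb <- rpois(1, config$baseline_rate * total_time)
      tt <- sort(runif(nb, 0, total_time))
      if (responding[ic]) {
        for (ie in seq_len(n_trials)) {
          t0 <- events$onset[ie] + latency[ic]
          resp_len <- duration
          nr <- rpois(1, peak_rate[ic] * resp_len)
          tt <- c(tt, runif(nr, t0, t0 + resp_len))
        }
      }
      if (!length(tt)) return(NULL)
      tibble(cell = ic, time = sort(tt))
    })
    # assign trials by containing window (for alignment convenience)
    spikes$trial <- findInterval(spikes$time, events$onset - 0.5)
    cells <- tibble(
      cell = seq_len(n_cells), x = xy$x, y = xy$y,
      transfected = transfected, responding = responding,
      latency_class = dplyr::case_when(responds_sl ~ "SL",
                                       responds_ll ~ "LL",
                                       TRUE ~ NA_character_),
      latency = latency, peak_rate = peak_rate, footprint = w
    )
    list(spikes = spikes, events = events, cells = cells, centre = centre)
  })
}

#' Synthetic micro-ECoG recording
#'
#' Per-channel evoked traces: a negative N1 deflection (Gaussian time
#' course) whose amplitude follows the Gaussian beam footprint over the
#' electrode layout, plus white noise, repeated over trials.
#'
#' @param config A [generator_config()].
#' @param pressure Peak pressure (MPa); scales the N1 amplitude through the
#'   logistic sensitivity.
#' @param centre_offset Beam-centre offset from the array centre (mm).
#' @param n_trials Number of trials.
#' @return A list: `traces` (tibble `channel`, `trial`, `time` s relative
#'   to onset, `voltage` uV), `layout` (tibble `channel`, `x`, `y` mm),
#'   `truth` (per-channel noiseless N1 amplitude and the true centre).
#' @export
gen_ecog <- function(config, pressure = 1.27, centre_offset = c(0, 0),
                     n_trials = 50L) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 202L, {
    n <- config$ecog_n
    pitch <- config$ecog_pitch
    grid <- expand.grid(ix = seq_len(n), iy = seq_len(n))
    corner <- (grid$ix %in% c(1, n)) & (grid$iy %in% c(1, n))
    grid <- grid[!corner, ]
    layout <- tibble(
      channel = seq_len(nrow(grid)),
      x = (grid$ix - 1) * pitch, y = (grid$iy - 1) * pitch
    )
    centre <- c(mean(layout$x), mean(layout$y)) + centre_offset
    sig <- footprint_sigma(config$ecog_footprint_fwhm)
    d2 <- (layout$x - centre[1])^2 + (layout$y - centre[2])^2
    sens <- stats::plogis((pressure - config$pressure_p50) /
                            config$pressure_slope)
    amp <- config$n1_amplitude * sens * exp(-d2 / (2 * sig^2))
    tt <- seq(-0.2, 0.3, by = 1 / config$ecog_fs)
    template <- exp(-(tt - config$n1_latency)^2 / (2 * config$n1_width^2))
    traces <- purrr::map_dfr(layout$channel, function(ch) {
      purrr::map_dfr(seq_len(n_trials), function(tr) {
        tibble(
          channel = ch, trial = tr, time = tt,
          voltage = -amp[ch] * template +
            rnorm(length(tt), 0, config$ecog_noise_sd)
        )
      })
    })
    list(
      traces = traces, layout = layout,
      truth = tibble(channel = layout$channel, x = layout$x, y = layout$y,
                     n1_amplitude = amp),
      centre = centre
    )
  })
}

#' Synthetic behavioural lick sessions
#'
#' Generates `lick_session` objects: spontaneous Poisson licking at the
#' configured rate (or the compulsive rate), plus, on success trials
#' (Bernoulli with logistic pressure dependence, capped at `success_max`),
#' an anticipatory lick at the configured latency and a short consummatory
#' lick burst after the reward.
#'
#' @param config A [generator_config()].
#' @param pressures Pressure (MPa) of each session to generate (`NA` for a
#'   light session).
#' @param compulsive Logical, recycled over sessions: replace the
#'   spontaneous rate by the compulsive rate.
#' @return A list: `sessions` (list of [lick_session()]),
#'   `truth` (tibble: per-session success probability, spontaneous rate,
#'   latency parameters, compulsive flag).
#' @export
gen_licks <- function(config, pressures = c(0.2, 0.7, 1.2),
                      compulsive = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  compulsive <- rep_len(compulsive, length(pressures))
  with_seed(config$seed + 303L, {
    out <- purrr::map(seq_along(pressures), function(i) {
      pr <- pressures[i]
      light <- is.na(pr)
      p_succ <- if (light) {
        config$success_max
      } else {
        config$success_max *
          stats::plogis((pr - config$success_p50) / config$success_slope)
      }
      lat <- if (light) config$lick_latency_light else config$lick_latency_us
      iti <- runif(config$n_trials, config$iti_range[1], config$iti_range[2])
      onsets <- cumsum(iti)
      t_end <- onsets[length(onsets)] + 5
      sp_rate <- if (compulsive[i]) config$compulsive_lick_rate else
        config$spontaneous_lick_rate
      licks <- sort(runif(rpois(1, sp_rate * t_end), 0, t_end))
      succ <- runif(config$n_trials) < p_succ
      ant <- onsets[succ] + pmin(
        pmax(rnorm(sum(succ), lat[["mean"]], lat[["sd"]]), 0.02),
        config$reward_delay - 1e-3
      )
      cons <- unlist(lapply(onsets[succ], function(o) {
        o + config$reward_delay + sort(runif(4, 0, 1))
      }))
      session <- lick_session(
        onsets, c(licks, ant, cons),
        reward_delay = config$reward_delay,
        stimulus = if (light) "light" else "US",
        pressure = pr
      )
      truth <- tibble(
        session = i, pressure = pr, success_prob = p_succ,
        spontaneous_rate = sp_rate,
        latency_mean = lat[["mean"]], latency_sd = lat[["sd"]],
        compulsive = compulsive[i]
      )
      list(session = session, truth = truth)
    })
    list(
      sessions = purrr::map(out, "session"),
      truth = purrr::map_dfr(out, "truth")
    )
  })
}
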