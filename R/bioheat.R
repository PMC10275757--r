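#' Tissue thermal parameters for the Pennes bioheat model
#'
#' Thermal and perfusion constants of brain tissue and blood. Defaults are
#' the standard literature values for grey matter: brain density
#' 1046 kg/m3, specific heat 3630 J/kg/degC, thermal conductivity
#' 0.51 W/m/degC, blood density 1050 kg/m3, blood specific heat
#' 3617 J/kg/degC, perfusion coefficient 9.7e-3 1/s, arterial temperature
#' 37 degC, metabolic heat generation 11.37 W/kg. The brain sound speed
#' default is 1546 m/s. `absorption_np` is the acoustic amplitude
#' absorption of the tissue at the insonation frequency (Np/m), e.g.
#' `attenuation_np(0.21, 1.18, 15e6)` = 59.04 Np/m for brain at 15 MHz.
#'
#' @param brain_density,brain_sound_speed,brain_specific_heat Brain rho
#'   (kg/m3), c (m/s) and C (J/kg/degC).
#' @param thermal_conductivity K_t (W/m/degC).
#' @param blood_density,blood_specific_heat Blood rho and C.
#' @param perfusion_coefficient P_blood (1/s).
#' @param arterial_temperature T_a (degC).
#' @param metabolic_heat gamma_brain (W/kg).
#' @param absorption_np Acoustic absorption alpha_np (Np/m).
#' @return An object of class `tissue_thermal_params`.
#' @export
tissue_thermal_params <- function(brain_density = 1046,
                                  brain_sound_speed = 1546,
                                  brain_specific_heat = 3630,
                                  thermal_conductivity = 0.51,
                                  blood_density = 1050,
                                  blood_specific_heat = 3617,
                                  perfusion_coefficient = 9.7e-3,
                                  arterial_temperature = 37,
                                  metabolic_heat = 11.37,
                                  absorption_np = attenuation_np(0.21, 1.18, 15e6)) {
  for (nm in c("brain_density", "brain_sound_speed", "brain_specific_heat",
               "thermal_conductivity", "blood_density", "blood_specific_heat",
               "perfusion_coefficient", "metabolic_heat", "absorption_np")) {
    assert_nonneg_scalar(get(nm), nm)
  }
  structure(
    list(
      brain_density = brain_density,
      brain_sound_speed = brain_sound_speed,
      brain_specific_heat = brain_specific_heat,
      thermal_conductivity = thermal_conductivity,
      blood_density = blood_density,
      blood_specific_heat = blood_specific_heat,
      perfusion_coefficient = perfusion_coefficient,
      arterial_temperature = arterial_temperature,
      metabolic_heat = metabolic_heat,
      absorption_np = absorption_np
    ),
    class = "tissue_thermal_params"
  )
}

#' Axisymmetric focal pressure map
#'
#' Evaluates the Rayleigh integral on an (r, z) half-plane around the focus,
#' exploiting the axisymmetry of the spherical-cap source. This is the
#' economical representation of the focal field used to build 3-D heating
#' source terms. The cap pitch defaults to lambda/2, which is accurate to
#' better than 0.1% in the focal region (verified against lambda/6) because
#' focal points see nearly equal path lengths from all cap elements.
#'
#' @param transducer A [transducer_spec()].
#' @param medium An [acoustic_medium()].
#' @param target_focal_pressure If not `NULL`, rescale the map so its
#'   spatial peak equals this pressure (Pa).
#' @param r_max,dr Radial extent and step (m).
#' @param z_halfwidth,dz Axial half-extent about the radius of curvature and
#'   step (m).
#' @param max_pitch Cap element pitch; default lambda/2.
#' @return An `axisym_field`: radial axis `r`, axial axis `z`, pressure
#'   matrix (`length(r)` x `length(z)`, Pa), frequency.
#' @export
focal_pressure_map <- function(transducer, medium,
                               target_focal_pressure = NULL,
                               r_max = 1.2e-3, dr = 1.25e-5,
                               z_halfwidth = 8e-3, dz = 1.25e-4,
                               max_pitch = NULL) {
  lam <- medium$sound_speed / transducer$center_frequency
  max_pitch <- max_pitch %||% (lam / 2)
  elems <- cap_elements(transducer, lam, max_pitch)
  k <- complex_wavenumber(transducer, medium)
  A <- transducer$radius_of_curvature
  r <- seq(0, r_max, by = dr)
  z <- seq(A - z_halfwidth, A + z_halfwidth, by = dz)
  P <- matrix(0, length(r), length(z))
  for (iz in seq_along(z)) {
    P[, iz] <- Mod(rayleigh_eval(cbind(r, 0, z[iz]), elems, k, Re(k),
                                 transducer$source_amplitude))
  }
  if (!is.null(target_focal_pressure)) {
    P <- P / max(P) * target_focal_pressure
  }
  structure(
    list(r = r, z = z, pressure = P, frequency = transducer$center_frequency),
    class = "axisym_field"
  )
}

# Interpolate an axisymmetric pressure map onto a 3-D rectilinear grid.
axisym_to_grid <- function(field, grid) {
  rv <- sqrt(outer(grid$x^2, grid$y^2, "+"))
  p3 <- array(0, c(length(grid$x), length(grid$y), length(grid$z)))
  for (iz in seq_along(grid$z)) {
    zq <- grid$z[iz]
    if (zq < field$z[1] || zq > field$z[length(field$z)]) next
    izlo <- min(max(findInterval(zq, field$z), 1L), length(field$z) - 1L)
    w <- (zq - field$z[izlo]) / (field$z[izlo + 1] - field$z[izlo])
    pr <- field$pressure[, izlo] * (1 - w) + field$pressure[, izlo + 1] * w
    pv <- approx(field$r, pr, as.vector(rv), rule = 2)$y
    pv[as.vector(rv) > max(field$r)] <- 0
    p3[, , iz] <- pv
  }
  p3
}

#' Build the ultrasound heating source term
#'
#' Converts a maximum-pressure field into the volumetric heating rate
#' \deqn{Q_{US} = \alpha_{np}\, p_{max}^2 / (\rho_b c_b)} (W/m3) and attaches
#' the stimulus burst schedule. By default the kilohertz intra-burst pulsing
#' is not time-resolved: its duty cycle multiplies the source during bursts
#' (`duty_as_factor = TRUE`), which is accurate because thermal time
#' constants far exceed the millisecond pulse period; set it to `FALSE` to
#' resolve the pulsing explicitly in the solver (validation only).
#'
#' @param field An `axisym_field` from [focal_pressure_map()] or a
#'   `pressure_field` from [rayleigh_field()].
#' @param params A [tissue_thermal_params()]; supplies `absorption_np`,
#'   brain density and sound speed.
#' @param stimulus A [us_stimulus()]; supplies duty cycle and burst timing.
#' @param grid A [field_grid()] for the thermal simulation. Required for
#'   axisymmetric input; for a `pressure_field`, defaults to the field's own
#'   grid (a different grid is an error -- regrid the field instead).
#' @return A `heat_source_field`: grid, `q_us` array (W/m3, duty-scaled if
#'   requested), the stimulus, and flags.
#' @export
build_heat_source <- function(field, params, stimulus, grid = NULL,
                              duty_as_factor = TRUE) {
  stopifnot(inherits(params, "tissue_thermal_params"),
            inherits(stimulus, "us_stimulus"))
  if (inherits(field, "axisym_field")) {
    if (is.null(grid)) abort("`grid` is required for an axisymmetric field")
    p3 <- axisym_to_grid(field, grid)
  } else if (inherits(field, "pressure_field")) {
    if (!is.null(grid) && !identical(grid, field$grid)) {
      abort("`grid` does not match the field's grid")
    }
    grid <- field$grid
    p3 <- field$pressure
    p3[is.na(p3)] <- 0
  } else {
    abort("`field` must be an `axisym_field` or `pressure_field`")
  }
  q <- params$absorption_np * p3^2 /
    (params$brain_density * params$brain_sound_speed)
  if (duty_as_factor) q <- q * stimulus$duty_cycle
  structure(
    list(
      grid = grid, q_us = q, stimulus = stimulus,
      duty_as_factor = duty_as_factor
    ),
    class = "heat_source_field"
  )
}

# On/off source schedule (relative factor) over [0, duration].
# Rows: start, end, factor. With duty_as_factor the factor is 1 during
# bursts; otherwise the kHz pulsing is resolved explicitly.
source_schedule <- function(source, duration) {
  st <- source$stimulus
  period <- st$burst_duration + st$inter_stimulus_interval
  segs <- list()
  t0 <- 0
  rep_i <- 0L
  while (t0 < duration && rep_i < st$n_repeats) {
    b_end <- min(t0 + st$burst_duration, duration)
    if (source$duty_as_factor || st$pulse_repetition_frequency == 0) {
      segs[[length(segs) + 1L]] <- c(t0, b_end, 1)
    } else {
      pp <- 1 / st$pulse_repetition_frequency
      tt <- t0
      while (tt < b_end) {
        on_end <- min(tt + pp * st$duty_cycle, b_end)
        segs[[length(segs) + 1L]] <- c(tt, on_end, 1)
        tt <- tt + pp
      }
    }
    if (b_end < min(t0 + period, duration)) {
      segs[[length(segs) + 1L]] <- c(b_end, min(t0 + period, duration), 0)
    }
    t0 <- t0 + period
    rep_i <- rep_i + 1L
  }
  if (t0 < duration) segs[[length(segs) + 1L]] <- c(t0, duration, 0)
  m <- do.call(rbind, segs)
  # merge/normalize into contiguous intervals
  out <- list()
  tcur <- 0
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] > tcur + 1e-12) out[[length(out) + 1L]] <- c(tcur, m[i, 1], 0)
    out[[length(out) + 1L]] <- m[i, ]
    tcur <- m[i, 2]
  }
  do.call(rbind, out)
}

grid_spacing <- function(grid) {
  sp <- function(ax) if (length(ax) > 1) diff(ax)[1] else Inf
  d <- c(sp(grid$x), sp(grid$y), sp(grid$z))
  for (ax in list(grid$x, grid$y, grid$z)) {
    if (length(ax) > 1 && diff(range(diff(ax))) > 1e-9 * diff(ax)[1]) {
      abort("thermal grids must be uniformly spaced along each axis")
    }
  }
  d
}

# 7-point Laplacian with Dirichlet (value pinned at faces) boundaries.
laplacian3 <- function(Tm, d) {
  L <- array(0, dim(Tm))
  n <- dim(Tm)
  if (n[1] > 2) {
    L[2:(n[1] - 1), , ] <- (Tm[1:(n[1] - 2), , ] + Tm[3:n[1], , ] -
                              2 * Tm[2:(n[1] - 1), , ]) / d[1]^2
  }
  if (n[2] > 2) {
    L[, 2:(n[2] - 1), ] <- L[, 2:(n[2] - 1), ] +
      (Tm[, 1:(n[2] - 2), ] + Tm[, 3:n[2], ] - 2 * Tm[, 2:(n[2] - 1), ]) / d[2]^2
  }
  if (n[3] > 2) {
    L[, , 2:(n[3] - 1)] <- L[, , 2:(n[3] - 1)] +
      (Tm[, , 1:(n[3] - 2)] + Tm[, , 3:n[3]] - 2 * Tm[, , 2:(n[3] - 1)]) / d[3]^2
  }
  L
}

zero_faces <- function(Tm) {
  n <- dim(Tm)
  if (n[1] > 1) { Tm[1, , ] <- 0; Tm[n[1], , ] <- 0 }
  if (n[2] > 1) { Tm[, 1, ] <- 0; Tm[, n[2], ] <- 0 }
  if (n[3] > 1) { Tm[, , 1] <- 0; Tm[, , n[3]] <- 0 }
  Tm
}

#' Solve the Pennes bioheat equation (explicit finite differences)
#'
#' Integrates
#' \deqn{\rho_b C_b \frac{\partial T}{\partial t} =
#'   \nabla\cdot(K_t \nabla T) - \rho_{bl} C_{bl} P_{bl} (T - T_a) + Q,}
#' with \eqn{Q = Q_{US}(x)\,s(t) + \rho_b \gamma_b}, Dirichlet
#' \eqn{T = T_a} boundaries, initial condition \eqn{T_0} (default
#' \eqn{T_a}). Diffusion is advanced with an explicit 7-point stencil;
#' the perfusion/source reaction is advanced exactly (exponential update),
#' so the adiabatic (`K_t = 0`, `P = 0`) and perfusion-balance (`K_t = 0`)
#' closed forms are reproduced to machine precision. A requested time step
#' above the diffusion stability limit
#' \eqn{\Delta t \le 1/(2\kappa(\Delta x^{-2}+\Delta y^{-2}+\Delta z^{-2}))}
#' is refused with the admissible value.
#'
#' @param source A `heat_source_field` from [build_heat_source()].
#' @param params A [tissue_thermal_params()].
#' @param duration Simulated time (s).
#' @param time_step Time step (s); default half the stability limit (and no
#'   coarser than 1 ms during source-on intervals).
#' @param snapshot_times Times (s) at which to store the full temperature
#'   array (memory permitting).
#' @param include_metabolic Include the metabolic volumetric source. The
#'   US-induced rise is a difference of two runs, so the metabolic term
#'   cancels; disable it to solve for the rise directly (see
#'   [pennes_rise()]).
#' @param T0 Initial temperature (degC); default arterial.
#' @return A `temperature_field`: grid, trace tibble (`time`,
#'   `max_temperature`, `max_rise` = max over space of T - T_a), snapshots,
#'   schedule, params.
#' @export
solve_pennes <- function(source, params, duration, time_step = NULL,
                         snapshot_times = numeric(0),
                         include_metabolic = TRUE, T0 = NULL) {
  stopifnot(inherits(source, "heat_source_field"),
            inherits(params, "tissue_thermal_params"))
  assert_positive_scalar(duration, "duration")
  g <- source$grid
  d <- grid_spacing(g)
  rhoC <- params$brain_density * params$brain_specific_heat
  kap <- params$thermal_conductivity / rhoC
  pe <- params$blood_density * params$blood_specific_heat *
    params$perfusion_coefficient / rhoC
  dt_stab <- if (kap > 0 && any(is.finite(d))) {
    1 / (2 * kap * sum(1 / d[is.finite(d)]^2))
  } else {
    Inf
  }
  if (!is.null(time_step) && time_step > dt_stab) {
    abort(sprintf(
      "time step %.3g s violates the explicit stability limit; use <= %.3g s",
      time_step, dt_stab
    ))
  }
  dt0 <- time_step %||% min(dt_stab / 2, 1e-3)
  sched <- source_schedule(source, duration)
  s_us <- source$q_us / rhoC                       # degC/s
  s_met <- if (include_metabolic) params$metabolic_heat / params$brain_specific_heat else 0
  Ta <- params$arterial_temperature
  theta <- array((T0 %||% Ta) - Ta, dim(s_us))     # rise above arterial
  theta <- zero_faces(theta)
  times <- 0
  max_trace <- max(theta)
  snaps <- list()
  snapshot_times <- sort(snapshot_times)
  record_snap <- function(tnow, theta) {
    due <- snapshot_times[abs(snapshot_times - tnow) < 1e-9]
    if (length(due)) snaps[[sprintf("%.9f", due[1])]] <<- theta + Ta
    snaps
  }
  snaps <- record_snap(0, theta)
  tnow <- 0
  for (i in seq_len(nrow(sched))) {
    seg_len <- sched[i, 2] - sched[i, 1]
    if (seg_len <= 0) next
    # land exactly on snapshot times inside the segment
    brk <- snapshot_times[snapshot_times > sched[i, 1] + 1e-12 &
                            snapshot_times < sched[i, 2] - 1e-12]
    bounds <- unique(c(sched[i, 1], brk, sched[i, 2]))
    for (b in seq_len(length(bounds) - 1L)) {
      span <- bounds[b + 1] - bounds[b]
      nst <- max(1L, ceiling(span / dt0))
      dt <- span / nst
      sfield_on <- sched[i, 3] > 0
      for (stp in seq_len(nst)) {
        theta <- theta + dt * kap * laplacian3(theta, d)
        s_tot <- s_met + if (sfield_on) sched[i, 3] * s_us else 0
        if (pe > 0) {
          ef <- exp(-pe * dt)
          theta <- theta * ef + s_tot / pe * (1 - ef)
        } else {
          theta <- theta + dt * s_tot
        }
        theta <- zero_faces(theta)
        tnow <- tnow + dt
      }
      if (anyNA(theta)) abort("NaN detected in temperature field; aborting")
      times <- c(times, tnow)
      max_trace <- c(max_trace, max(theta))
      snaps <- record_snap(tnow, theta)
    }
  }
  structure(
    list(
      grid = g,
      trace = tibble(time = times, max_rise = max_trace,
                     max_temperature = max_trace + Ta),
      snapshots = snaps,
      schedule = sched,
      params = params,
      include_metabolic = include_metabolic,
      final = theta + Ta
    ),
    class = "temperature_field"
  )
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf(
    "<temperature_field> %d trace points to %.3g s, peak rise %.4g degC\n",
    nrow(x$trace), max(x$trace$time), max(x$trace$max_rise)
  ))
  invisible(x)
}

#' Ultrasound-induced temperature rise
#'
#' The maximum over space and recorded times of the pointwise difference
#' between a simulation with the ultrasound source and its source-free
#' baseline. Metabolic and perfusion baselines cancel by construction. Both
#' fields must have been solved on the same grid with the same snapshot
#' times and parameters.
#'
#' @param with_us,without_us `temperature_field` objects from
#'   [solve_pennes()] with matching snapshots.
#' @return Maximum rise (degC).
#' @seealso [pennes_rise()] for the direct (single-run) equivalent.
#' @export
us_temperature_rise <- function(with_us, without_us) {
  stopifnot(inherits(with_us, "temperature_field"),
            inherits(without_us, "temperature_field"))
  if (!identical(with_us$grid, without_us$grid)) {
    abort("temperature fields were solved on different grids")
  }
  if (!identical(names(with_us$snapshots), names(without_us$snapshots)) ||
      length(with_us$snapshots) == 0) {
    abort("temperature fields need matching, non-empty snapshot schedules")
  }
  max(vapply(
    names(with_us$snapshots),
    function(nm) max(with_us$snapshots[[nm]] - without_us$snapshots[[nm]]),
    numeric(1)
  ))
}

#' US-induced rise solved directly (linear superposition)
#'
#' Because the Pennes operator is linear with identical boundaries, the
#' difference between the with-US and without-US solutions satisfies the
#' same equation with only the `q_us` source, zero initial rise and zero
#' Dirichlet boundary. This solves that rise equation in one run; it equals
#' `us_temperature_rise(solve_pennes(source, ...), solve_pennes(zero, ...))`
#' exactly and is the economical route for large grids.
#'
#' @inheritParams solve_pennes
#' @return A `temperature_field` whose trace/snapshots hold the rise
#'   (`max_temperature` is reported relative to arterial + rise).
#' @export
pennes_rise <- function(source, params, duration, time_step = NULL,
                        snapshot_times = numeric(0)) {
  solve_pennes(source, params, duration, time_step = time_step,
               snapshot_times = snapshot_times,
               include_metabolic = FALSE, T0 = NULL)
}

#' Spectral (k-space) Pennes propagator
#'
#' Solves the same rise equation as [pennes_rise()] on a periodic domain by
#' exact per-mode exponential integration: each Fourier mode obeys
#' \eqn{\dot{\hat\theta} = -(\kappa k^2 + P_e)\hat\theta + \hat s\, s(t)},
#' integrated in closed form over each on/off interval of the source
#' schedule. Time integration is exact for piecewise-constant envelopes, so
#' arbitrarily long burst sequences cost one array update per interval.
#' Used as the independent cross-check of the finite-difference solver and
#' as the engine for long repeated-stimulation runs. The domain must be
#' large enough that periodic images do not reach the focal region over the
#' simulated time (diffusion length \eqn{\sqrt{4\kappa t}} small compared
#' with the half-domain).
#'
#' @inheritParams solve_pennes
#' @param sample_times Times at which the rise is recorded (the source
#'   schedule's interval boundaries are always used as integration
#'   breakpoints).
#' @param track `"node"` records the rise at the source-peak node by a
#'   single-point inverse transform (the spatial maximum sits there for a
#'   centre-peaked source); `"full"` inverse-transforms the whole field at
#'   every sample time and records the true spatial maximum.
#' @return A `temperature_field` (rise values) with a trace at
#'   `sample_times`.
#' @export
solve_pennes_spectral <- function(source, params, duration,
                                  sample_times = NULL,
                                  track = c("node", "full")) {
  track <- match.arg(track)
  stopifnot(inherits(source, "heat_source_field"),
            inherits(params, "tissue_thermal_params"))
  g <- source$grid
  d <- grid_spacing(g)
  n <- dim(source$q_us)
  if (any(!is.finite(d[n > 1]))) abort("spectral solver needs uniform axes")
  rhoC <- params$brain_density * params$brain_specific_heat
  kap <- params$thermal_conductivity / rhoC
  pe <- params$blood_density * params$blood_specific_heat *
    params$perfusion_coefficient / rhoC
  kax <- function(nn, dd) {
    if (nn == 1) return(0)
    2 * pi * c(0:floor(nn / 2), -(ceiling(nn / 2) - 1):-1)[1:nn] / (nn * dd)
  }
  K2 <- outer(outer(kax(n[1], d[1])^2, kax(n[2], d[2])^2, "+"),
              kax(n[3], d[3])^2, "+")
  lamk <- kap * K2 + pe
  Sh <- fft(source$q_us / rhoC)
  Th <- array(0 + 0i, dim = n)
  sched <- source_schedule(source, duration)
  sample_times <- sort(unique(sample_times %||% sched[, 2]))
  times <- numeric(0)
  max_trace <- numeric(0)
  # single-point inverse DFT at the source-peak node
  i0 <- arrayInd(which.max(source$q_us), n)
  ph <- lapply(1:3, function(d) {
    exp(2i * pi * (i0[d] - 1) * (seq_len(n[d]) - 1) / n[d])
  })
  node_value <- function(Th) {
    acc <- 0 + 0i
    for (kz in seq_len(n[3])) {
      acc <- acc + pz_k[kz] * drop(crossprod(ph[[1]], Th[, , kz] %*% ph[[2]]))
    }
    Re(acc) / prod(n)
  }
  pz_k <- ph[[3]]
  for (i in seq_len(nrow(sched))) {
    brk <- sample_times[sample_times > sched[i, 1] + 1e-12 &
                          sample_times < sched[i, 2] - 1e-12]
    bounds <- unique(c(sched[i, 1], brk, sched[i, 2]))
    for (b in seq_len(length(bounds) - 1L)) {
      span <- bounds[b + 1] - bounds[b]
      ef <- exp(-lamk * span)
      Th <- Th * ef
      if (sched[i, 3] > 0) {
        # forced response: span * (1 - e^{-lam*span})/(lam*span), safe at lam ~ 0
        xg <- lamk * span
        gf <- span * ifelse(xg < 1e-8, 1 - xg / 2, (1 - ef) / pmax(xg, 1e-300))
        Th <- Th + sched[i, 3] * Sh * gf
      }
      tend <- bounds[b + 1]
      if (any(abs(sample_times - tend) < 1e-9) ||
          i == nrow(sched) && b == length(bounds) - 1L) {
        times <- c(times, tend)
        max_trace <- c(max_trace, if (track == "node") {
          node_value(Th)
        } else {
          max(Re(fft(Th, inverse = TRUE)) / prod(n))
        })
      }
    }
  }
  structure(
    list(
      grid = g,
      trace = tibble(time = times, max_rise = max_trace,
                     max_temperature = max_trace + params$arterial_temperature),
      snapshots = list(),
      schedule = sched,
      params = params,
      include_metabolic = FALSE,
      final = Re(fft(Th, inverse = TRUE)) / prod(n) +
        params$arterial_temperature
    ),
    class = "temperature_field"
  )
}

#' Repeated-burst temperature rise to plateau
#'
#' Integrates the US-induced rise for a burst train (e.g. 20 ms bursts at
#' 13 Hz) with the spectral propagator until the peak cumulative rise
#' plateaus: at least `min_time` seconds simulated and the relative slope of
#' the peak-rise envelope below `plateau_slope` per second (measured across
#' the trailing second), or until `max_time`. The spatial maximum is
#' recorded at every burst end, where the transient peaks.
#'
#' @param source A `heat_source_field` whose stimulus carries the burst
#'   duration and repetition rate ([us_stimulus()] with
#'   `repetition_frequency` and `n_repeats = Inf` semantics -- bursts repeat
#'   for the whole run).
#' @param params A [tissue_thermal_params()].
#' @param min_time,max_time Minimum/maximum simulated time (s).
#' @param plateau_slope Relative slope threshold (fraction per second).
#' @return A list: `peak_rise` (degC), `plateau_reached`, `plateau_time`,
#'   `slope` (relative, per second), and the burst-end `trace` tibble.
#' @export
repeated_burst_rise <- function(source, params, min_time = 10, max_time = 30,
                                plateau_slope = 0.01) {
  st <- source$stimulus
  period <- st$burst_duration + st$inter_stimulus_interval
  src <- source
  src$stimulus$n_repeats <- ceiling(max_time / period)
  burst_ends <- seq_len(src$stimulus$n_repeats) * period - st$inter_stimulus_interval
  sol <- solve_pennes_spectral(src, params, duration = max_time,
                               sample_times = burst_ends)
  is_end <- vapply(sol$trace$time, function(t) {
    any(abs(burst_ends - t) < 1e-6)
  }, logical(1))
  tr <- sol$trace[is_end, ]
  per_sec <- max(1L, round(1 / period))
  peak <- NA_real_
  plateau_time <- NA_real_
  slope <- NA_real_
  for (i in seq_len(nrow(tr))) {
    if (tr$time[i] < min_time || i <= per_sec) next
    slope_i <- (tr$max_rise[i] - tr$max_rise[i - per_sec]) /
      (tr$time[i] - tr$time[i - per_sec]) / tr$max_rise[i]
    if (slope_i < plateau_slope) {
      peak <- tr$max_rise[i]
      plateau_time <- tr$time[i]
      slope <- slope_i
      break
    }
  }
  reached <- is.finite(peak)
  if (!reached) {
    n <- nrow(tr)
    slope <- (tr$max_rise[n] - tr$max_rise[n - per_sec]) /
      (tr$time[n] - tr$time[n - per_sec]) / tr$max_rise[n]
    peak <- tr$max_rise[n]
    plateau_time <- tr$time[n]
  }
  list(peak_rise = peak, plateau_reached = reached,
       plateau_time = plateau_time, slope = slope, trace = tr)
}
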