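---
title: "Models and methods in sonosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sonosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sonosim)
```

sonosim models the physics and the analysis chain of focused-ultrasound
neurostimulation experiments: the radiated pressure field of spherical-cap
transducers, the acoustic exposure and tissue-heating consequences of a
pulsed stimulus, and the electrophysiological and behavioural response
metrics used to quantify ultrasound-evoked activity. This vignette explains
the models, their assumptions, the tunable parameters, and the numerical
and design choices, in the order a study would use them.

## Linear acoustic field of a spherical-cap transducer

A single-element focused transducer is described by its centre frequency,
aperture diameter and radius of curvature (ROC); the uniform normal
velocity of the surface is expressed as an equivalent surface pressure
`source_amplitude` (Pa). Two routes evaluate the monochromatic field in a
lossy medium:

* `onaxis_pressure()` — the closed-form axial solution for a focusing
  bowl (the classical uniformly-driven spherical-cap result),
  `p(z) = p0 * A/|A - z| * |exp(ikR_b) - exp(ikz)|`, with the complex
  wavenumber `k = omega/c + i*alpha_np` carrying the amplitude attenuation
  and the removable singularity at the geometric focus replaced by its
  limit `p0 * k * h` (cap depth `h`).
* `rayleigh_field()` — the Rayleigh surface integral with the cap
  discretized into ring-sectioned elements. The default element pitch is
  lambda/6; a pitch above lambda/2 is refused as aliased. Grid nodes lying
  behind the concave surface are flagged invalid rather than evaluated.

The two routes agree on axis to better than 1% near the focus (this is a
test), which is why `characterize_beam()` mixes them for speed: the axial
profile (peak depth, axial FWHM) from the closed form, the transverse
profile through the axial peak (lateral FWHM) from the surface integral.
FWHM crossings are located by linear interpolation between samples,
resolving plateau ties to the outermost crossing.

Axial positions are referenced to the *apex* of the concave surface, so
the geometric focus sits at `z = ROC`. For weakly focused geometries the
axial amplitude profile is extremely flat — for the 0.5 MHz geometry the
profile varies by less than 0.5% over more than 2 mm around its maximum —
so the reported peak depth of such a transducer is an ill-conditioned
argmax: small modelling differences (full-wave versus integral solutions,
source discretization) legitimately move it by a millimetre while agreeing
everywhere in amplitude to a fraction of a percent. The strongly focused
15 MHz geometry does not suffer from this and its peak depth is a sharp,
reproducible number.

Attenuation follows the power law `alpha0 * (f/MHz)^y` (dB/cm), converted
by `attenuation_np()` to Np/m (`* 100 * ln(10)/20`). Water defaults are
`alpha0 = 2.2e-3, y = 2`; brain uses `alpha0 = 0.21, y = 1.18`, giving
59.04 Np/m at 15 MHz. The stored nonlinearity parameter B/A is
deliberately unused: every operation here is linear, which is adequate
because at the pressures considered the second harmonic carries about 1%
of the energy.

`calibrate_amplitude()` exploits the linearity of the field in the source
amplitude: matching a target focal pressure is an exact rescale, no
iteration.

## Exposure metrics

`exposure_metrics()` reports the plane-wave intensities used in safety
tables, in W/cm2: Isppa = `p^2/(2 rho c)` averaged over the on-portion of
each pulse; Ispta = Isppa × duty cycle × burst/time-base; Isptp evaluated
with the same `p^2/(2 rho c)` form. Two sound speeds are deliberately
separate explicit arguments (`c_isppa = 1540`, `c_isptp = 1500`): safety
tabulations conventionally back-calculate Isppa with soft-tissue sound
speed but Isptp with water, and the package mirrors that convention
instead of silently unifying it. The Ispta time base is a required notion
rather than a hidden constant because the averaging window (repetition
period versus a fixed 1 s window) is a reporting convention; the default
averages over the stimulus repetition period
(`burst_duration + inter_stimulus_interval`).

## Ultrasound heating and the Pennes bioheat equation

`build_heat_source()` converts a maximum-pressure field into the
volumetric heating rate `Q_US = alpha_np * p_max^2 / (rho_b * c_b)`
(W/m3). The kilohertz intra-burst pulsing is not time-resolved by default:
its duty cycle multiplies the source during bursts
(`duty_as_factor = TRUE`). This is accurate because tissue thermal time
constants (tens of milliseconds and longer) far exceed the 1 ms pulse
period; the exact envelope remains available (`duty_as_factor = FALSE`)
for validation on small problems.

`solve_pennes()` integrates
`rho_b C_b dT/dt = div(K_t grad T) - rho_bl C_bl P_bl (T - T_a) + Q`
with `Q = Q_US * s(t) + rho_b * gamma_b`, Dirichlet `T = T_a` boundaries
and initial condition 37 degC. Defaults are the standard grey-matter and
blood constants (rho_b 1046 kg/m3, C_b 3630 J/kg/degC, K_t 0.51 W/m/degC,
rho_bl 1050, C_bl 3617, P_bl 9.7e-3 1/s, gamma_b 11.37 W/kg). The brain
sound speed default is 1546 m/s — source tabulations of this constant are
inconsistent and occasionally corrupted in print, so the value is an
explicit, overridable parameter rather than a buried constant.

Numerically the solver splits each step: diffusion by an explicit 7-point
stencil (a step above the stability limit
`1/(2 kappa (dx^-2 + dy^-2 + dz^-2))` is refused with the admissible
value), and the perfusion/source reaction advanced *exactly* by its
exponential update. The split keeps the adiabatic and perfusion-balance
closed forms exact to machine precision, which the tests assert at four
significant figures and better.

Because the operator is linear with fixed boundaries, the ultrasound-induced
rise equals the difference of a with-US and a without-US run, and that
difference itself solves the same equation with only the `Q_US` source and
zero boundary/initial rise. `pennes_rise()` solves the rise directly in one
run; `us_temperature_rise()` takes the explicit two-run difference (they
agree to machine precision; also a test).

`solve_pennes_spectral()` is a second, independent integrator of the same
rise equation on a periodic domain: each Fourier mode has the exact
solution `theta_k(t+dt) = theta_k e^{-(kappa k^2 + P_e) dt} + forced
response`, integrated in closed form over each on/off interval of the
envelope. It is exact in time for piecewise-constant envelopes, so a
multi-second 13 Hz burst train costs two array updates per period. It
serves two roles: the independent oracle for the finite-difference solver
(they agree within 2% on a resolved Gaussian-source problem, and the
spectral route itself matches an analytic Green's-function quadrature to
seven digits), and the engine for long repeated-stimulation runs where
explicit stepping would be needlessly slow. The periodic domain must stay
large relative to the diffusion length `sqrt(4 kappa t)` of the run; the
default repeated-burst domain (12 x 12 x 16 mm for a 0.276 mm focal spot,
20 s horizon, diffusion length 3.3 mm) respects this.

`repeated_burst_rise()` integrates a burst train until the peak rise
plateaus: at least 10 s simulated and a trailing-second relative slope
below 1%/s. The burst-end values are recorded at the source-peak node via
a single-point inverse transform; for a centre-peaked source the spatial
maximum sits there (asserted against the full-field maximum in tests).

Problem sizes used by the shipped analyses: the single-burst run uses a
6 x 6 x 12 mm Dirichlet subdomain at 50 um lateral / 100 um axial spacing
(1.8M nodes, 0.5 ms steps), chosen so that grid refinement moves the peak
rise by well under 5% and doubling the domain changes it by under 1%; the
repeated-burst run uses a 12 x 12 x 16 mm periodic domain at 75/125 um.
The focal pressure map that feeds both is evaluated axisymmetrically out
to r = 1.2 mm (beyond which `Q_US` is negligible at 15 MHz) with a
lambda/2 cap pitch, verified against lambda/6 to better than 0.1% in the
focal region — focal points see nearly equal path lengths from the whole
cap, which relaxes the pitch requirement there.

## Spike-train response metrics

`spike_density_function()` convolves spike times with a unit-mass
Gaussian kernel and divides by the number of pooled trials, so the trace
integrates to the mean per-trial spike count. The default kernel
(sigma = 3 ms) resolves ~10 ms latencies while smoothing millisecond bin
noise; latency estimates should be quoted to within one kernel width, and
that is the tolerance the parameter-recovery tests use.

* Latency (`response_latency()`): time from onset to the maximum of the
  discrete SDF derivative after onset; a flat post-onset trace returns
  `NA`. The short/long-latency partition is exhaustive and exclusive at
  45 ms (strictly below = SL).
* Duration (`response_duration()`): the interval between the outermost
  linearly-interpolated crossings of `A/e` around the SDF peak `A`;
  right/left-censored windows return `NA` with a `censored` attribute.
  For a Gaussian SDF this equals `2*sqrt(2)*sigma` exactly.
* `fano_factor()`: sample variance over mean of per-trial counts.
* Responsiveness (the paper-style criterion is unstated, so the package
  states one): mean response-window rate (stimulus duration + 50 ms)
  above the across-trial baseline mean by more than three baseline
  standard deviations.

Spatial statistics over responding cells: `spatial_dispersion()` is the
pairwise distance average weighted by products of population-normalized
maximum rates; `response_centre()` is the rate- (or amplitude-) weighted
centroid. The phrasing "rate weighted by distance from other cells"
admits several estimators; the centroid is the only candidate that is
symmetric under relabelling, returns a single unit's own position, and
recovers pure translations of the footprint exactly, which is why it is
the default (both functions expose an unweighted variant as a strategy
switch). `activated_density()` normalizes the responding-cell count by the
focal-spot area at 2.25 MHz and above and by the array area at 0.5 MHz,
where the focal spot exceeds the array. The response dominance index is
implemented as `(ON - OFF)/(ON + OFF)`; its exact published form lives in
an external reference, so this standard contrast form is an explicit
assumption of the package.

## Micro-ECoG evoked potentials and activation maps

`evoked_potential()` averages trial-aligned traces per channel; N1 is the
magnitude of the most negative deflection of the mean trace in a 0–100 ms
post-onset window. The noise standard deviation is estimated from the
raw single-trial pre-onset baseline (200 ms), pooled across trials: the
"2 x s.d. of the signal" activation threshold refers to the signal, not
to the n-fold-averaged trace, and using the averaged-trace s.d. would let
the extreme-value bias of the windowed minimum create false activations.

`ecog_activation_map()` interpolates electrode amplitudes piecewise
linearly over a triangulation of the layout and reports the activated
area — the area where the interpolant exceeds `2 * noise_sd` — computed
*exactly* by clipping each triangle against the threshold plane (no
rasterization, hence no resolution parameter). Layouts on a possibly
incomplete regular grid are triangulated automatically (each complete
cell split into two triangles, three-cornered edge cells kept); scattered
layouts require an explicit triangulation, a documented limitation. The
map centre is the amplitude-weighted centroid of suprathreshold
electrodes; an all-subthreshold map has zero area and an undefined
centre.

## Behavioural licking metrics

A trial succeeds when at least one lick falls in the anticipatory window
`[onset, onset + 0.5 s)`. The session anticipatory rate is the mean
anticipatory-window rate minus the spontaneous rate (mean count in the
second before each onset), multiplied by the success rate *as a fraction*
— the multiplication is a down-weighting of unreliable sessions and the
fraction form keeps the result in Hz (the percent form would change
units). The first-lick latency averages successful trials only.

Compulsive-licking sessions are excluded by `rout_exclude()`: robust
z-scores from the median and scaled MAD of the per-session spontaneous
rates, converted to two-sided normal tails and thresholded by
Benjamini–Hochberg at Q = 1%. The reference procedure is a
proprietary-software method (robust regression + outlier FDR); for the
constant model used here this analog preserves its intent — a bounded
false discovery rate among excluded sessions — and the tests check both a
direct-computation oracle and a ≤ ~1% false-exclusion rate on clean
Gaussian samples. It is an analog, not a re-implementation.
`retention_filter()` keeps animals at or above 60% success on training
day 4.

## Synthetic data generators

The generators exist so that every analysis stage is testable against
known ground truth without any recorded data. They emulate the
*statistical structure* the analyses assume, not the biophysics:

* `gen_retina_mea()` — retinal ganglion cells scattered uniformly over a
  16 x 16, 200 um-pitch array; response probability follows a Gaussian
  beam footprint (FWHM 4.36 / 1.61 / 0.276 mm at 0.5 / 2.25 / 15 MHz)
  times a logistic pressure sensitivity; short-latency responses
  (12.2 ± 2.5 ms, truncated positive) only in "transfected" cells,
  long-latency network responses (50.4 ± 4.2 ms) in any cell; spiking is
  piecewise-homogeneous Poisson (baseline plus a latency-shifted
  response plateau). The response footprint adds a 0.25 mm biological
  spread in quadrature to the beam width: real activation spreads beyond
  a 0.276 mm spot through cell size and lateral connectivity, and
  without it a 200 um-pitch array would see almost no cells under the
  15 MHz beam. The logistic pressure curve is a modelling choice; the
  emulated data constrain only monotonicity.
* `gen_ecog()` — 32 channels on a 6 x 6-minus-corners, 300 um grid (the
  exact commercial layout is not published; the layout is overridable);
  traces are a footprint-scaled negative Gaussian N1 template plus white
  noise. The default N1 scale (15 uV) and cortical footprint (1.2 mm
  FWHM) put the default activated area near 1.4 mm2 at 1.27 MPa.
* `gen_licks()` — 35-trial sessions with 10–30 s inter-trial intervals;
  spontaneous Poisson licking (1 Hz; 6 Hz for compulsive sessions), a
  Bernoulli success draw with logistic pressure dependence, an
  anticipatory lick at 187.1 ± 37.3 ms (ultrasound) or 265.9 ± 46.5 ms
  (light), and a consummatory burst after reward.

All generators are deterministic under the configuration seed (each
derives a fixed stream offset; the caller's RNG state is saved and
restored), and each returns a ground-truth sidecar table against which
the tests run parameter recovery. What passing these tests shows is that
the *estimators* are correct and adequately powered at realistic effect
sizes; it does not validate the generators against real recordings —
white ECoG noise, Poisson spiking and stationary baselines are idealized.

## Pipeline and file formats

`load_run_config()` / `save_run_config()` read and write YAML run
configurations (unknown keys and stages rejected with all problems listed
at once; lossless round trip), and `run_pipeline()` executes the
configured generate-and-analyze stages, writing CSV tables and a JSON
manifest with MD5 hashes so identical configuration and seed reproduce
identical outputs. Tables are plain CSV and configuration YAML throughout;
SI units in files (metres, seconds, Pa), with millimetre/MPa appearing
only at reporting surfaces.

## Known limitations

* Propagation is linear and monochromatic: no harmonics, cavitation,
  mechanical index, standing waves or skull aberration.
* The Rayleigh integral treats the curved source with the plane-baffle
  Green's function — standard, and accurate at these geometries, but one
  reason weakly-focused argmax positions are not sharp.
* Thermal parameters are constant (no temperature dependence, no CEM43
  dose), and the repeated-burst engine assumes an effectively unbounded
  homogeneous medium.
* The ROUT analog and the response dominance index are stated analogs of
  procedures whose exact published forms are external.
* Activation maps require a (near-)grid electrode layout unless a
  triangulation is supplied.
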