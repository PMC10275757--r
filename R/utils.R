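# Internal numeric helpers shared across modules.

# Full width at half maximum of a sampled 1-d profile.
#
# Crossings are located by walking outward from the global maximum to the
# first sample below half maximum on each side and linearly interpolating
# between the bracketing samples. Plateaus at exactly half maximum resolve
# to the outermost crossing. Errors if either half-maximum crossing lies
# outside the sampled range (profile too narrow a window).
profile_fwhm <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ipk <- which.max(y)
  half <- y[ipk] / 2
  iL <- ipk
  while (iL > 1 && y[iL] >= half) iL <- iL - 1
  iR <- ipk
  while (iR < length(y) && y[iR] >= half) iR <- iR + 1
  if (y[iL] >= half || y[iR] >= half) {
    abort("profile does not fall below half maximum inside the sampled range")
  }
  xl <- x[iL] + (half - y[iL]) / (y[iL + 1] - y[iL]) * (x[iL + 1] - x[iL])
  xr <- x[iR - 1] + (half - y[iR - 1]) / (y[iR] - y[iR - 1]) * (x[iR] - x[iR - 1])
  xr - xl
}

# Outermost crossings of `y` with level `lev` around the global peak,
# linearly interpolated; returns c(left, right) or NA for a censored side.
level_crossings <- function(x, y, lev) {
  ipk <- which.max(y)
  left <- NA_real_
  if (ipk >= 2L) {
    for (i in seq.int(ipk, 2L, by = -1L)) {
      if (y[i - 1] < lev && y[i] >= lev) {
        left <- x[i - 1] + (lev - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (ipk <= length(y) - 1L) {
    for (i in seq.int(ipk, length(y) - 1L)) {
      if (y[i + 1] < lev && y[i] >= lev) {
        right <- x[i] + (lev - y[i]) / (y[i + 1] - y[i]) * (x[i + 1] - x[i])
        break
      }
    }
  }
  c(left, right)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

assert_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative finite number", name))
  }
  invisible(x)
}
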