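#' A lick-detection behavioural session
#'
#' One session of the associative go/no-go licking task: stimulus (light or
#' ultrasound) onsets, lick timestamps, and the delay between stimulus
#' onset and reward-valve opening (anticipatory licks are those between the
#' two).
#'
#' @param onsets Trial stimulus onsets (s), sorted.
#' @param licks Lick timestamps (s).
#' @param reward_delay Delay from onset to water valve (s), default 0.5.
#' @param stimulus `"US"` or `"light"`.
#' @param pressure Ultrasound pressure (MPa), `NA` for light.
#' @param animal,day Optional identifiers.
#' @return An object of class `lick_session`.
#' @export
lick_session <- function(onsets, licks, reward_delay = 0.5,
                         stimulus = c("US", "light"), pressure = NA_real_,
                         animal = NA_character_, day = NA_integer_) {
  stimulus <- match.arg(stimulus)
  if (is.unsorted(onsets)) abort("`onsets` must be sorted")
  assert_positive_scalar(reward_delay, "reward_delay")
  structure(
    list(
      onsets = as.numeric(onsets), licks = sort(as.numeric(licks)),
      reward_delay = reward_delay, stimulus = stimulus,
      pressure = pressure, animal = animal, day = day
    ),
    class = "lick_session"
  )
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf(
    "<lick_session> %s%s, %d trials, %d licks\n", x$stimulus,
    if (is.na(x$pressure)) "" else sprintf(" %.2g MPa", x$pressure),
    length(x$onsets), length(x$licks)
  ))
  invisible(x)
}

#' Per-trial success flags
#'
#' A trial is successful when the animal performs at least one anticipatory
#' lick, i.e. a lick in `[onset, onset + reward_delay)`.
#'
#' @param onsets Trial onsets (s), vectorized.
#' @param licks Lick timestamps (s).
#' @param reward_delay Onset-to-valve delay (s).
#' @return Logical vector, one flag per trial.
#' @export
trial_success <- function(onsets, licks, reward_delay = 0.5) {
  vapply(onsets, function(o) {
    any(licks >= o & licks < o + reward_delay)
  }, logical(1))
}

#' Session success rate (percent)
#'
#' `100 * successful trials / trials`.
#'
#' @param session A [lick_session()].
#' @return Percentage in `[0, 100]`.
#' @export
success_rate <- function(session) {
  stopifnot(inherits(session, "lick_session"))
  100 * mean(trial_success(session$onsets, session$licks,
                           session$reward_delay))
}

#' Spontaneous lick rate (Hz)
#'
#' Mean lick count over the 1 s windows immediately preceding each
#' stimulus onset.
#'
#' @param session A [lick_session()].
#' @return Rate in Hz.
#' @export
spontaneous_rate <- function(session) {
  stopifnot(inherits(session, "lick_session"))
  mean(vapply(session$onsets, function(o) {
    sum(session$licks >= o - 1 & session$licks < o)
  }, numeric(1)))
}

#' Session anticipatory lick rate (Hz)
#'
#' The mean anticipatory-window lick rate (licks in
#' `[onset, onset + reward_delay)` scaled to Hz), minus the spontaneous
#' lick rate, multiplied by the success rate expressed as a fraction so the
#' result stays in Hz.
#'
#' @param session A [lick_session()].
#' @return Baseline-corrected, success-scaled anticipatory rate (Hz).
#' @export
anticipatory_rate <- function(session) {
  stopifnot(inherits(session, "lick_session"))
  win <- session$reward_delay
  per_trial <- vapply(session$onsets, function(o) {
    sum(session$licks >= o & session$licks < o + win) / win
  }, numeric(1))
  (mean(per_trial) - spontaneous_rate(session)) * success_rate(session) / 100
}

#' Mean time to first anticipatory lick (ms)
#'
#' Mean, over successful trials, of the time from stimulus onset to the
#' first anticipatory lick.
#'
#' @param session A [lick_session()].
#' @return Latency in ms; `NA` when no trial was successful.
#' @export
first_lick_latency <- function(session) {
  stopifnot(inherits(session, "lick_session"))
  lat <- vapply(session$onsets, function(o) {
    w <- session$licks[session$licks >= o &
                         session$licks < o + session$reward_delay]
    if (length(w)) w[1] - o else NA_real_
  }, numeric(1))
  if (all(is.na(lat))) return(NA_real_)
  mean(lat, na.rm = TRUE) * 1e3
}

#' Robust outlier exclusion of compulsive-licking sessions
#'
#' One-dimensional analog of the ROUT procedure for a constant model:
#' per-session spontaneous lick rates are converted to robust z-scores
#' using the median and the scaled MAD (1.4826 * MAD), z-scores to
#' two-sided normal tail probabilities, and sessions are excluded by
#' Benjamini-Hochberg FDR control at `q`. This reproduces the intent of
#' the proprietary method (maximum false discovery rate Q among excluded
#' sessions); it is an analog, not a clone.
#'
#' @param rates Per-session spontaneous lick rates (Hz).
#' @param q Maximum false discovery rate (default 0.01, i.e. Q = 1%).
#' @return Logical exclusion flags, one per session.
#' @export
rout_exclude <- function(rates, q = 0.01) {
  n <- length(rates)
  if (n < 4) {
    warn("fewer than 4 sessions; no outlier exclusion performed")
    return(rep(FALSE, n))
  }
  med <- median(rates)
  scale <- mad(rates) # already scaled by 1.4826
  z <- if (scale > 0) {
    (rates - med) / scale
  } else {
    ifelse(rates == med, 0, Inf * sign(rates - med))
  }
  p <- 2 * pnorm(-abs(z))
  p.adjust(p, method = "BH") < q
}

#' Task-retention filter
#'
#' Keeps animals whose light-stimulation success rate on the fourth
#' training day is at least the retention criterion (60%).
#'
#' @param day4_success Success rates (percent) on training day 4.
#' @param criterion Retention threshold (percent).
#' @return Logical keep flags.
#' @export
retention_filter <- function(day4_success, criterion = 60) {
  day4_success >= criterion
}

#' Summary metrics for one or more sessions
#'
#' Computes the full per-session metric set and, when several sessions are
#' given, flags compulsive-licking outliers with [rout_exclude()] on the
#' spontaneous rates.
#'
#' @param sessions A [lick_session()] or a list of them.
#' @param q FDR level for the outlier exclusion.
#' @return A tibble with one row per session: identifiers, `n_trials`,
#'   `success_rate` (%), `spontaneous_rate` (Hz), `anticipatory_rate` (Hz),
#'   `first_lick_latency` (ms), `excluded`.
#' @export
session_metrics <- function(sessions, q = 0.01) {
  if (inherits(sessions, "lick_session")) sessions <- list(sessions)
  out <- purrr::map_dfr(sessions, function(s) {
    tibble(
      animal = s$animal, day = s$day, stimulus = s$stimulus,
      pressure = s$pressure, n_trials = length(s$onsets),
      success_rate = success_rate(s),
      spontaneous_rate = spontaneous_rate(s),
      anticipatory_rate = anticipatory_rate(s),
      first_lick_latency = first_lick_latency(s)
    )
  })
  out$excluded <- if (nrow(out) >= 4) {
    rout_exclude(out$spontaneous_rate, q = q)
  } else {
    rep(FALSE, nrow(out))
  }
  out
}
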