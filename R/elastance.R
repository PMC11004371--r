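## Time-varying elastance waveforms and the pacing clock.  The R functions
## here mirror the compiled right-hand side exactly; they are the reference
## implementation used by the analysis layer and the tests.

#' Right-atrial pacing schedule
#'
#' Beat onsets at exact multiples of the pacing period `60/heart_rate`,
#' covering `[0, duration]` (the onset at or just beyond `duration` is
#' included so every instant of the trajectory falls inside a beat window).
#'
#' @param heart_rate bpm, within [30, 220].
#' @param duration schedule span, s.
#' @return list of class `cv_pacing` with `heart_rate`, `beat_period` (s) and
#'   `beat_onsets` (s, strictly increasing, spacing exactly the period).
#' @examples
#' pacing_schedule(60, 10)$beat_onsets   # 0, 1, ..., 10
#' @export
pacing_schedule <- function(heart_rate, duration) {
  if (heart_rate < 30 || heart_rate > 220)
    stop("heart_rate must be within [30, 220] bpm")
  if (duration <= 0) stop("duration must be > 0")
  period <- 60 / heart_rate
  onsets <- seq(0L, floor(duration * heart_rate / 60 + 1e-9)) * period
  structure(list(heart_rate = heart_rate, beat_period = period,
                 beat_onsets = onsets), class = "cv_pacing")
}

## Systolic duration for a given period: Bazett-like sqrt scaling with a hard
## cap so diastole survives rapid pacing.
.systole_duration <- function(period, sys_k = 0.7, max_fraction = 0.66) {
  min(sys_k * sqrt(period), max_fraction * period)
}

#' Normalized activation waveform
#'
#' Shape of the periodic activation driving chamber elastance, as a function
#' of phase within the beat.  The waveform has three segments: a fast
#' raised-cosine rise to `rise1_level` over the first 15% of the rise window
#' (the short isovolumic-contraction burst that sets dP/dt_max), a linear
#' climb to 1 at `peak_fraction` of systole (sustained ejection), and a
#' raised-cosine relaxation back to 0 at the end of systole.  It is 0
#' throughout diastole.
#'
#' @param phase position in the cycle, dimensionless in [0, 1); values
#'   outside are wrapped modulo 1 with a warning.
#' @param period beat period, s (needed because the systolic fraction of the
#'   cycle depends on the heart rate).
#' @param sys_k,max_fraction systole-duration rule, see [model_config()].
#' @param peak_fraction,rise1_level waveform shape parameters.
#' @return activation in [0, 1], same length as `phase`.
#' @export
normalized_activation <- function(phase, period = 0.75, sys_k = 0.7,
                                  max_fraction = 0.66, peak_fraction = 0.78,
                                  rise1_level = 0.30) {
  if (any(phase < 0 | phase >= 1)) {
    warning("phase outside [0,1); wrapping modulo 1")
    phase <- phase %% 1
  }
  d <- .systole_duration(period, sys_k, max_fraction)
  tau <- phase * period
  tp <- peak_fraction * d
  t1 <- 0.15 * tp
  a1 <- rise1_level
  out <- numeric(length(tau))
  i1 <- tau < t1
  i2 <- !i1 & tau < tp
  i3 <- !i1 & !i2 & tau < d
  out[i1] <- a1 * 0.5 * (1 - cos(pi * tau[i1] / t1))
  out[i2] <- a1 + (1 - a1) * (tau[i2] - t1) / (tp - t1)
  out[i3] <- 0.5 * (1 + cos(pi * (tau[i3] - tp) / (d - tp)))
  out
}

#' Chamber elastance at a time point
#'
#' `E(t) = E_min + (E_max - E_min) * activation(phase)`, periodic with the
#' pacing period.  For the ventricles `E_max` carries the force-frequency
#' gain applied by the simulator; this function takes the chamber parameters
#' as given.
#'
#' @param t time, s (vectorized).
#' @param chamber one row of the `chambers` data frame of a `cv_config`
#'   (fields `E_max`, `E_min`, `onset_advance_s`, `sysk_scale`), or a list
#'   with those fields.
#' @param schedule a `cv_pacing` from [pacing_schedule()].
#' @param sys_k,max_fraction,peak_fraction,rise1_level waveform parameters,
#'   defaulting to the packaged activation settings.
#' @return elastance in mmHg/ml, bounded by `[E_min, E_max]`.
#' @export
chamber_elastance <- function(t, chamber, schedule, sys_k = 0.7,
                              max_fraction = 0.66, peak_fraction = 0.78,
                              rise1_level = 0.30) {
  period <- schedule$beat_period
  adv <- if (!is.null(chamber$onset_advance_s)) chamber$onset_advance_s else 0
  scl <- if (!is.null(chamber$sysk_scale)) chamber$sysk_scale else 1
  phase <- ((t + adv) %% period) / period
  act <- normalized_activation(phase, period, sys_k * scl, max_fraction,
                               peak_fraction, rise1_level)
  chamber$E_min + (chamber$E_max - chamber$E_min) * act
}

#' Chamber pressure from the elastance relation
#'
#' `P = E(t) * (V - V0)`.  During deep preload reduction the linear relation
#' can go negative; pressures are clamped at a floor (default -5 mmHg), the
#' same rule the simulator applies.
#'
#' @param volume chamber volume, ml.
#' @param E_t instantaneous elastance, mmHg/ml (> 0).
#' @param V0_chamber unstressed volume, ml.
#' @param p_floor clamp floor, mmHg.
#' @return pressure, mmHg.
#' @examples
#' chamber_pressure(60, 2, 10)   # 100
#' @export
chamber_pressure <- function(volume, E_t, V0_chamber, p_floor = -5) {
  if (any(E_t <= 0)) stop("E_t must be > 0")
  pmax(E_t * (volume - V0_chamber), p_floor)
}
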