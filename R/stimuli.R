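#' Declarative stimulus description
#'
#' A stimulus is a pulse *rate* (s^-1) presented to the excitatory population
#' of the target node(s); being a rate it must be non-negative everywhere.
#' Wave stimuli are a constant carrier pulse rate amplitude-modulated by a
#' sine in one of the standard frequency bands, made positive either by
#' half-wave rectification (the positive lobes of the sine) or full-wave
#' rectification (its absolute value, whose fundamental sits at twice the
#' modulation frequency).
#'
#' @param kind one of `"half_wave"`, `"full_wave"`, `"burst"`,
#'   `"pulse_function"`, `"none"`.
#' @param carrier_amp peak pulse rate (s^-1), default 200.
#' @param f_mod modulation frequency (Hz); required for wave kinds.
#' @param onset stimulus start (s), default 0.
#' @param duration active duration (s); for `"burst"` the duration of one
#'   burst (default 0.1 s); for `"pulse_function"` the sampled support
#'   (default 0.3 s, ~75 time constants, beyond which the tail is negligible).
#' @param targets character vector of target node names (empty = all nodes).
#' @param burst_count number of bursts (`"burst"` only).
#' @param burst_gap gap between burst onsets (s); alternatively supply
#'   explicit `burst_onsets` (e.g. from [phase_aligned_onsets()]).
#' @param burst_onsets explicit burst onset times (s), overrides `onset` and
#'   `burst_gap`.
#' @param bias for `"full_wave"`: `"rectified"` (default, `|sin|`) or
#'   `"offset"` (sine raised to be non-negative, `(1+sin)/2`); only the
#'   rectified form doubles the effective frequency.
#' @param tau_pulse time constant of the monophasic pulse function (s),
#'   default 0.004.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("half_wave", "full_wave", "burst",
                                   "pulse_function", "none"),
                          carrier_amp = 200, f_mod = NULL, onset = 0,
                          duration = NULL, targets = character(),
                          burst_count = 1L, burst_gap = NULL,
                          burst_onsets = NULL,
                          bias = c("rectified", "offset"),
                          tau_pulse = 0.004) {
  kind <- match.arg(kind)
  bias <- match.arg(bias)
  if (is.null(duration))
    duration <- switch(kind, burst = 0.1, pulse_function = 0.3,
                       stop("'duration' is required for kind ", kind,
                            call. = FALSE))
  if (onset < 0) stop("onset must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (carrier_amp <= 0) stop("carrier_amp must be positive", call. = FALSE)
  if (kind %in% c("half_wave", "full_wave", "burst")) {
    if (is.null(f_mod) || f_mod <= 0)
      stop("f_mod must be a positive modulation frequency (Hz)", call. = FALSE)
  }
  if (tau_pulse <= 0) stop("tau_pulse must be positive", call. = FALSE)
  structure(list(kind = kind, carrier_amp = carrier_amp, f_mod = f_mod,
                 onset = onset, duration = duration, targets = targets,
                 burst_count = as.integer(burst_count), burst_gap = burst_gap,
                 burst_onsets = burst_onsets, bias = bias,
                 tau_pulse = tau_pulse),
            class = "stimulus_spec")
}

new_stimulus_trace <- function(t0, dt, values, targets) {
  if (any(values < 0)) stop("stimulus trace must be non-negative", call. = FALSE)
  structure(list(t0 = t0, dt = dt, values = values, targets = targets),
            class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf(
    "<stimulus_trace> t0=%g s  dt=%g s  %d samples  peak=%.3g s^-1  targets: %s\n",
    x$t0, x$dt, length(x$values), max(x$values),
    if (length(x$targets)) paste(x$targets, collapse = ", ") else "(all)"))
  invisible(x)
}

#' Sample a stimulus specification on a time grid
#'
#' Dispatches on `spec$kind` to [half_wave()], [full_wave()], [gamma_burst()]
#' or [pulse_function()].
#'
#' @param spec a [stimulus_spec()].
#' @param dt sample step (s).
#' @return a `stimulus_trace` (fields `t0`, `dt`, `values`, `targets`).
#' @export
sample_stimulus <- function(spec, dt) {
  stopifnot(inherits(spec, "stimulus_spec"))
  switch(spec$kind,
         half_wave = half_wave(spec, dt),
         full_wave = full_wave(spec, dt),
         burst = gamma_burst(spec, dt),
         pulse_function = pulse_function(spec, dt),
         none = new_stimulus_trace(spec$onset, dt, numeric(0), spec$targets))
}

.rel_times <- function(spec, dt) (seq_len(round(spec$duration / dt)) - 1) * dt

#' Half-wave rectified sinusoidally modulated pulse train
#'
#' `carrier_amp * max(0, sin(2 pi f_mod (t - onset)))` inside the active
#' window; zero outside.  Mean over whole periods is `carrier_amp / pi`.
#'
#' @inheritParams sample_stimulus
#' @return a `stimulus_trace` starting at `spec$onset`.
#' @export
half_wave <- function(spec, dt) {
  if (is.null(spec$f_mod) || spec$f_mod <= 0)
    stop("f_mod must be positive", call. = FALSE)
  tr <- .rel_times(spec, dt)
  v <- spec$carrier_amp * pmax(0, sin(2 * pi * spec$f_mod * tr))
  new_stimulus_trace(spec$onset, dt, v, spec$targets)
}

#' Full-wave rectified sinusoidally modulated pulse train
#'
#' Default (`bias = "rectified"`): `carrier_amp * |sin(2 pi f_mod (t-onset))|`,
#' whose fundamental is at `2 * f_mod` and whose whole-period mean is
#' `2 * carrier_amp / pi`.  The `"offset"` bias instead raises the sine,
#' `carrier_amp * (1 + sin)/2`, keeping the fundamental at `f_mod`.
#'
#' @inheritParams sample_stimulus
#' @return a `stimulus_trace` starting at `spec$onset`.
#' @export
full_wave <- function(spec, dt) {
  if (is.null(spec$f_mod) || spec$f_mod <= 0)
    stop("f_mod must be positive", call. = FALSE)
  tr <- .rel_times(spec, dt)
  s <- sin(2 * pi * spec$f_mod * tr)
  v <- if (spec$bias == "rectified") spec$carrier_amp * abs(s)
       else spec$carrier_amp * (1 + s) / 2
  new_stimulus_trace(spec$onset, dt, v, spec$targets)
}

#' Gamma burst train
#'
#' One or more brief (default 100 ms) full-wave gamma-modulated segments.
#' At 32.1 Hz modulation, a 100-ms rectified burst contains up to six
#' positive peaks (the rectified waveform oscillates at 64.2 Hz).  Burst
#' onsets come from `burst_onsets` (e.g. phase-aligned to an ongoing
#' oscillation), or from `onset` plus multiples of `burst_gap`.
#'
#' @inheritParams sample_stimulus
#' @return a `stimulus_trace` covering first onset to last burst end, zero
#'   between bursts.
#' @export
gamma_burst <- function(spec, dt) {
  if (is.null(spec$f_mod) || spec$f_mod <= 0)
    stop("f_mod must be positive", call. = FALSE)
  onsets <- spec$burst_onsets
  if (is.null(onsets)) {
    gap <- if (!is.null(spec$burst_gap)) spec$burst_gap else spec$duration
    onsets <- spec$onset + (seq_len(spec$burst_count) - 1) * gap
  }
  onsets <- sort(onsets)
  if (any(diff(onsets) < spec$duration - 1e-12))
    stop("bursts overlap: onsets closer than one burst duration", call. = FALSE)
  t0 <- onsets[1]
  n <- round((max(onsets) + spec$duration - t0) / dt)
  v <- numeric(n)
  seg <- full_wave(stimulus_spec("full_wave", carrier_amp = spec$carrier_amp,
                                 f_mod = spec$f_mod, onset = 0,
                                 duration = spec$duration, bias = spec$bias),
                   dt)$values
  for (on in onsets) {
    i0 <- round((on - t0) / dt)
    v[i0 + seq_along(seg)] <- seg
  }
  new_stimulus_trace(t0, dt, v, spec$targets)
}

#' Monophasic exponential pulse function
#'
#' The classic pulse-density stimulus `t^7 exp(-t/tau)` (time relative to
#' onset, `tau` default 4 ms), scaled so its maximum — reached at `t = 7 tau`,
#' 28 ms after onset for the default — equals `carrier_amp`.  Its analytic
#' time integral is `carrier_amp * tau * 7! * e^7 / 7^7` (about 5.37 Hz s for
#' a 200 s^-1 peak), the "unit pulse" energy content of a single pulse.
#'
#' @inheritParams sample_stimulus
#' @return a `stimulus_trace` starting at `spec$onset`.
#' @export
pulse_function <- function(spec, dt) {
  tau <- spec$tau_pulse
  tr <- .rel_times(spec, dt)
  cc <- spec$carrier_amp / ((7 * tau)^7 * exp(-7))
  v <- cc * tr^7 * exp(-tr / tau)
  new_stimulus_trace(spec$onset, dt, v, spec$targets)
}

#' Unit-pulse energy of a stimulus trace
#'
#' Trapezoidal time-integral of the rate waveform (Hz s, dimensionless),
#' used as a proxy for the energy a stimulus delivers.  A 16-s half-wave
#' 200 s^-1 stimulus delivers about 1000 unit pulses; the standard pulse
#' function about 5.4.
#'
#' @param trace a `stimulus_trace`, or a numeric rate vector.
#' @param dt sample step (s); taken from the trace when omitted.
#' @return energy (Hz s).
#' @export
unit_pulse_energy <- function(trace, dt = NULL) {
  if (inherits(trace, "stimulus_trace")) {
    if (is.null(dt)) dt <- trace$dt
    trace <- trace$values
  }
  if (is.null(dt)) stop("'dt' required for a bare numeric trace", call. = FALSE)
  if (length(trace) < 2) return(0)
  pracma::trapz(seq_along(trace) * dt, trace)
}

#' Burst onsets phase-aligned to an ongoing oscillation
#'
#' Brief bursts transfer energy efficiently only when they coincide with the
#' positive (excitatory) half-cycles of the underlying oscillation.  Given a
#' reference trace (typically the excitatory potential `ye` of the responding
#' node), this returns onset times at consecutive zero-up-crossings of the
#' mean-subtracted reference so that each burst lies inside a positive
#' half-cycle.
#'
#' @param reference numeric reference trace (mV).
#' @param fs sampling rate of the reference (Hz).
#' @param n_bursts number of onsets required.
#' @param burst_duration burst length (s); must fit inside a positive
#'   half-cycle (a 20% overhang is tolerated, as for a 100-ms burst on a
#'   5.3 Hz rhythm whose positive half-cycle is 94 ms).
#' @param f_base base oscillation frequency (Hz); when given, the reference
#'   is smoothed with a moving average of about a sixth of the base period
#'   before crossing detection, and the half-cycle length used in the fit
#'   check is `1/(2*f_base)` rather than the (noise-sensitive) measured
#'   crossing spacing.
#' @param t0 time of the first reference sample (s), added to the returned
#'   onsets.
#' @return numeric vector of `n_bursts` onset times (s).
#' @export
phase_aligned_onsets <- function(reference, fs, n_bursts, burst_duration,
                                 f_base = NULL, t0 = 0) {
  x <- reference - mean(reference)
  if (!is.null(f_base)) {
    k <- max(1L, round(fs / (6 * f_base)))
    xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    # nearest-value padding keeps sample alignment without edge artefacts
    ok <- which(!is.na(xs))
    xs[seq_len(ok[1] - 1)] <- xs[ok[1]]
    xs[seq(ok[length(ok)] + 1, length.out = length(xs) - ok[length(ok)])] <-
      xs[ok[length(ok)]]
    x <- xs
  }
  s <- sign(x)
  up <- which(s[-1] > 0 & s[-length(s)] <= 0)
  down <- which(s[-1] <= 0 & s[-length(s)] > 0)
  if (length(up) == 0 || length(down) == 0)
    stop("reference has no sign change; cannot phase-align", call. = FALSE)
  half <- if (!is.null(f_base)) 1 / (2 * f_base)
  else median(diff(sort(c(up, down)))) / fs
  if (burst_duration > 1.2 * half)
    stop(sprintf(
      "burst (%.3f s) does not fit inside a positive half-cycle (%.3f s)",
      burst_duration, half), call. = FALSE)
  # one onset per base cycle: drop crossings closer than ~a base period
  # (fast intra-cycle structure can produce extra zero crossings)
  min_gap <- if (!is.null(f_base)) 0.8 / f_base else burst_duration
  keep <- c()
  last <- -Inf
  for (i in up) {
    if ((i - last) / fs >= min_gap) { keep <- c(keep, i); last <- i }
  }
  up <- keep
  if (length(up) < n_bursts)
    stop("too few positive half-cycles (", length(up), ") for ", n_bursts,
         " bursts", call. = FALSE)
  t0 + up[seq_len(n_bursts)] / fs
}
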