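#' Band-power summary of an LFP trace
#'
#' Single-taper (Hann-windowed) periodogram of the mean-subtracted trace,
#' with power integrated over the standard bands theta (4-8 Hz), alpha
#' (8-12 Hz), beta (12-30 Hz) and gamma (30-100 Hz).  Band edges are closed
#' on the left and open on the right (power exactly at 8 Hz counts as
#' alpha).  Fractions are normalised by total 4-100 Hz power, so they sum to
#' 1 over the four bands; `out_of_band` carries the remainder of the total
#' spectrum.  Spectral peaks are local maxima above a prominence threshold.
#'
#' @param x numeric trace (post-transient; remove transients before calling).
#' @param fs sampling rate (Hz).
#' @param bands named list of `c(lo, hi)` band edges (Hz).
#' @param window taper: `"hann"` (default) or `"rect"`.
#' @param peak_prominence minimum peak prominence as a fraction of the
#'   largest spectral value, default 0.05.
#' @param max_peaks maximum number of peaks reported.
#' @return an object of class `band_power_summary`: `fractions` (per band),
#'   `power` (absolute, per band), `total_power` (whole spectrum),
#'   `in_band_power`, `out_of_band`, `peak_frequency` (dominant in-band
#'   peak, Hz), and `peaks` (data frame `freq`, `height`).
#' @export
band_power <- function(x, fs,
                       bands = list(theta = c(4, 8), alpha = c(8, 12),
                                    beta = c(12, 30), gamma = c(30, 100)),
                       window = c("hann", "rect"),
                       peak_prominence = 0.05, max_peaks = 10L) {
  window <- match.arg(window)
  n <- length(x)
  if (n < 2 * fs) stop("trace too short: need at least 2 s of samples",
                       call. = FALSE)
  x <- x - mean(x)
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))) else rep(1, n)
  X <- fft(x * w)
  half <- seq_len(floor(n / 2) + 1)
  pwr <- (Mod(X[half])^2) / sum(w^2) / n
  # one-sided spectrum: double every bin that has a negative-frequency twin
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(half)] <- 1
  pwr <- pwr * dbl
  freq <- (half - 1) * fs / n

  band_pow <- vapply(bands, function(b)
    sum(pwr[freq >= b[1] & freq < b[2]]), numeric(1))
  lo <- min(vapply(bands, `[`, numeric(1), 1))
  hi <- max(vapply(bands, `[`, numeric(1), 2))
  in_band <- sum(pwr[freq >= lo & freq < hi])
  total <- sum(pwr)
  fractions <- if (in_band > 0) band_pow / in_band else band_pow * 0

  pk <- pracma::findpeaks(pwr, minpeakheight = peak_prominence * max(pwr),
                          sortstr = TRUE)
  peaks <- if (is.null(pk)) data.frame(freq = numeric(), height = numeric())
  else data.frame(freq = freq[pk[, 2]], height = pk[, 1])[
    seq_len(min(nrow(pk), max_peaks)), ]
  inb <- peaks$freq >= lo & peaks$freq < hi
  peak_frequency <- if (any(inb)) peaks$freq[inb][1] else NA_real_

  structure(list(fractions = fractions, power = band_pow,
                 total_power = total, in_band_power = in_band,
                 out_of_band = total - in_band,
                 peak_frequency = peak_frequency, peaks = peaks,
                 freq = freq, spectrum = pwr),
            class = "band_power_summary")
}

#' @export
print.band_power_summary <- function(x, ...) {
  fr <- paste(sprintf("%s %.1f%%", names(x$fractions), 100 * x$fractions),
              collapse = "  ")
  cat("<band_power_summary> ", fr, "\n", sep = "")
  if (is.finite(x$peak_frequency))
    cat(sprintf("  dominant in-band peak at %.2f Hz\n", x$peak_frequency))
  invisible(x)
}

#' Sliding amplitude envelope
#'
#' Root-mean-square of the mean-subtracted trace in a centred sliding window
#' (edges padded with the nearest valid value).
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param window window length (s), default 0.5.
#' @return envelope, same length as `x`.
#' @export
amplitude_envelope <- function(x, fs, window = 0.5) {
  k <- max(3L, round(window * fs))
  if (k %% 2 == 0) k <- k + 1L
  x <- x - mean(x)
  e2 <- stats::filter(x^2, rep(1 / k, k), sides = 2)
  e2 <- as.numeric(e2)
  # pad the half-window edges with the nearest computed value
  first <- which(!is.na(e2))[1]
  last <- tail(which(!is.na(e2)), 1)
  e2[seq_len(first - 1)] <- e2[first]
  if (last < length(e2)) e2[(last + 1):length(e2)] <- e2[last]
  sqrt(pmax(e2, 0))
}

#' Detect a sustained amplitude transition in an LFP trace
#'
#' A stimulus-induced dynamical transition shows as a sustained change of the
#' LFP amplitude envelope.  The envelope (sliding-window RMS, default 0.5 s)
#' is compared with its pre-stimulus baseline level; the transition time is
#' the first instant the envelope leaves the baseline band by more than
#' `threshold` (fractional, default 0.3) and stays out for at least `dwell`
#' seconds.  A symmetric test after the transition detects spontaneous
#' reversion to baseline.
#'
#' @param x numeric LFP trace (mV), full run including baseline.
#' @param fs sampling rate (Hz).
#' @param baseline `c(start, end)` (s) of the pre-stimulus baseline window.
#' @param onset stimulus onset (s); transition search starts here.  Defaults
#'   to the end of the baseline window.
#' @param window envelope window (s), default 0.5.
#' @param threshold fractional envelope departure defining a transition,
#'   default 0.3.
#' @param dwell minimum time outside (or back inside) the baseline band
#'   (s), default 1.
#' @param t0 time of the first sample (s), default 0.
#' @return an object of class `transition_report`: `detected`,
#'   `transition_time` (absolute, s), `transition_after_onset`,
#'   `pre_envelope`, `post_envelope`, `reverted`, `reversion_time`,
#'   `direction` (`"up"`/`"down"`).
#' @export
detect_transition <- function(x, fs, baseline, onset = NULL, window = 0.5,
                              threshold = 0.3, dwell = 1, t0 = 0) {
  tt <- t0 + (seq_along(x) - 1) / fs
  if (is.null(onset)) onset <- baseline[2]
  base_idx <- tt >= baseline[1] & tt < baseline[2]
  if (!any(base_idx)) stop("baseline window is empty", call. = FALSE)
  if (baseline[2] > onset + 1e-9)
    stop("baseline window must precede the stimulus onset", call. = FALSE)
  env <- amplitude_envelope(x, fs, window)
  base <- mean(env[base_idx])
  dev <- abs(env - base) / base
  out <- dev > threshold
  ndwell <- max(1L, round(dwell * fs))
  search <- which(tt >= onset)

  run_start <- function(flag, idx) {
    # first index in idx where flag stays TRUE for ndwell samples
    r <- rle(flag[idx])
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= ndwell)
    if (!length(hit)) return(NA_integer_)
    idx[ends[hit[1]] - r$lengths[hit[1]] + 1]
  }

  i_tr <- run_start(out, search)
  if (is.na(i_tr))
    return(structure(list(detected = FALSE, transition_time = NA_real_,
                          transition_after_onset = NA_real_,
                          pre_envelope = base, post_envelope = NA_real_,
                          reverted = FALSE, reversion_time = NA_real_,
                          direction = NA_character_, envelope = env,
                          baseline_envelope = base),
                     class = "transition_report"))
  t_tr <- tt[i_tr]
  post_win <- tt > t_tr & tt <= t_tr + dwell
  post <- mean(env[post_win])
  i_rev <- run_start(!out, which(tt > t_tr + dwell))
  structure(list(detected = TRUE, transition_time = t_tr,
                 transition_after_onset = t_tr - onset,
                 pre_envelope = base, post_envelope = post,
                 reverted = !is.na(i_rev),
                 reversion_time = if (!is.na(i_rev)) tt[i_rev] else NA_real_,
                 direction = if (post < base) "down" else "up",
                 envelope = env, baseline_envelope = base),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  if (!x$detected) {
    cat("<transition_report> no transition detected\n")
  } else {
    cat(sprintf(
      "<transition_report> %s transition at %.2f s (%.2f s after onset)%s\n",
      x$direction, x$transition_time, x$transition_after_onset,
      if (x$reverted) sprintf(", reverted at %.2f s", x$reversion_time) else ""))
  }
  invisible(x)
}

#' Dominant repeat period of an amplitude envelope
#'
#' Slow beating or ramped repetition of an oscillatory state shows as a
#' periodic amplitude envelope.  The envelope autocorrelation is scanned for
#' its highest local maximum above a significance floor; the corresponding
#' lag is the repeat period.  For a two-tone beat at `f1` and `f2` the
#' period is `1 / |f1 - f2|`.
#'
#' @param x numeric trace.
#' @param fs sampling rate (Hz).
#' @param env_window envelope window (s), default 0.5.
#' @param min_period shortest period considered (s), default 1.
#' @param max_period longest period considered (s), default half the trace.
#' @param floor minimum autocorrelation height for a significant peak,
#'   default 0.25.
#' @return repeat period (s), or `NA` when no significant envelope
#'   periodicity exists.
#' @export
repeat_period <- function(x, fs, env_window = 0.5, min_period = 1,
                          max_period = NULL, floor = 0.25) {
  if (is.null(max_period)) max_period <- length(x) / fs / 2
  if (max_period <= min_period) stop("trace too short for the period range",
                                     call. = FALSE)
  env <- amplitude_envelope(x, fs, env_window)
  # an essentially unmodulated envelope carries no repeat structure
  if (mean(env) <= 0 || sd(env) < 0.02 * mean(env)) return(NA_real_)
  env <- env - mean(env)
  lag_max <- round(max_period * fs)
  ac <- acf(env, lag.max = lag_max, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1
  ok <- lags >= round(min_period * fs)
  pk <- pracma::findpeaks(ac[ok], minpeakheight = floor, sortstr = TRUE)
  if (is.null(pk)) return(NA_real_)
  (lags[ok][pk[1, 2]]) / fs
}

#' Spectral and transition report for a whole simulation
#'
#' Convenience wrapper: per-node and cluster-mean band power on the
#' post-transient segment, plus (when `onset` is given) a transition report
#' per node and the cluster.
#'
#' @param sim an `nm_simulation`.
#' @param onset stimulus onset (s) or `NULL` for a resting run.
#' @param downsample analysis sampling-rate divisor, default 10 (1 kHz at
#'   the default dt; the spectral content of interest is below 100 Hz).
#' @param ... passed to [detect_transition()].
#' @return a list with `nodes` (per-node summaries), `cluster`, and the
#'   analysis sampling rate `fs`.
#' @export
analyze_simulation <- function(sim, onset = NULL, downsample = 10L, ...) {
  idx <- seq(1, length(sim$t), by = downsample)
  fs <- sim$fs / downsample
  cut <- sim$config$transient_cut
  one <- function(tr) {
    post <- tr[sim$t[idx] >= cut]
    res <- list(band_power = band_power(post, fs))
    if (!is.null(onset)) {
      res$transition <- detect_transition(
        tr, fs, baseline = c(cut, onset), onset = onset,
        t0 = sim$t[idx][1], ...)
      res$repeat_period <- repeat_period(tr[sim$t[idx] >= onset], fs)
    }
    res
  }
  nodes <- lapply(seq_along(sim$names), function(k) one(sim$lfp[k, idx]))
  names(nodes) <- sim$names
  list(nodes = nodes, cluster = one(sim$cluster_lfp[idx]), fs = fs)
}
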