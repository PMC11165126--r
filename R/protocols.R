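#' Default band stimulation frequencies
#'
#' Modulation frequencies per band, matched to the fundamental resonances of
#' the six-node preset (theta 5.3, alpha 9.9, beta 16.0, gamma 32.1 Hz).
#' Override per protocol call when working with other networks.
#'
#' @return named numeric vector.
#' @export
band_frequencies <- function() c(theta = 5.3, alpha = 9.9, beta = 16.0,
                                 gamma = 32.1)

#' Names of the registered stimulation protocols
#'
#' @return character vector of protocol names accepted by [run_protocol()].
#' @export
protocol_registry <- function() c(
  "resting", "band_stim_theta", "band_stim_alpha", "band_stim_beta",
  "band_stim_gamma", "beta_then_burst", "theta_then_gamma_wave",
  "repeated_aligned_bursts")

# stimulus blocks + horizon for each protocol; onsets follow the standard
# timeline: primary stimulus at 4 s, any second stimulus at 10 s
.protocol_def <- function(name, freqs, t_end) {
  pair <- c("A32V", "A11")   # in-hub + in-connector: the responsive pair
  band_stim <- function(band, t_end) list(
    t_end = t_end,
    stimuli = list(list(kind = "half_wave", carrier_amp = 200,
                        f_mod = unname(freqs[band]), onset = 4,
                        duration = t_end - 4, targets = pair)))
  switch(name,
    resting = list(t_end = t_end %||% 20, stimuli = list()),
    band_stim_theta = band_stim("theta", t_end %||% 20),
    band_stim_alpha = band_stim("alpha", t_end %||% 20),
    band_stim_beta = band_stim("beta", t_end %||% 20),
    band_stim_gamma = band_stim("gamma", t_end %||% 20),
    beta_then_burst = {
      te <- t_end %||% 20
      list(t_end = te, stimuli = list(
        list(kind = "half_wave", carrier_amp = 200,
             f_mod = unname(freqs["beta"]), onset = 4, duration = te - 4,
             targets = pair),
        list(kind = "burst", carrier_amp = 200,
             f_mod = unname(freqs["gamma"]), onset = 10, duration = 0.1,
             targets = character())))
    },
    theta_then_gamma_wave = {
      # the theta-induced state persists well past 17 s: extend the horizon
      te <- t_end %||% 30
      list(t_end = te, stimuli = list(
        list(kind = "half_wave", carrier_amp = 200,
             f_mod = unname(freqs["theta"]), onset = 4, duration = te - 4,
             targets = pair),
        list(kind = "half_wave", carrier_amp = 200,
             f_mod = unname(freqs["gamma"]), onset = 10, duration = te - 10,
             targets = character())))
    },
    repeated_aligned_bursts = {
      te <- t_end %||% 30
      list(t_end = te, two_pass = TRUE, stimuli = list(
        list(kind = "half_wave", carrier_amp = 200,
             f_mod = unname(freqs["theta"]), onset = 4, duration = te - 4,
             targets = pair)))
    },
    stop("unknown protocol '", name, "'; registry: ",
         paste(protocol_registry(), collapse = ", "), call. = FALSE))
}

#' Run a named stimulation protocol
#'
#' Reproducible presets for the cluster experiments: `resting` (noise only),
#' `band_stim_<band>` (a 200 s^-1 half-wave stimulus in the given band
#' applied to A32V and A11 at 4 s), `beta_then_burst` (beta wave at 4 s, a
#' 100-ms gamma burst to all nodes at 10 s), `theta_then_gamma_wave` (theta
#' wave at 4 s, a continuous gamma wave to all nodes at 10 s; 30-s horizon so
#' late responses are not censored) and `repeated_aligned_bursts` (theta wave
#' at 4 s, then three 100-ms gamma bursts phase-aligned to the positive
#' half-cycles of A32V's excitatory potential after 10 s; two simulation
#' passes, the first providing the alignment reference).
#'
#' Each run writes the LFP traces (CSV), an analysis report with band powers
#' and transition detections per node (JSON), and a sidecar echoing the full
#' configuration, then returns everything invisibly.
#'
#' @param name protocol name, see [protocol_registry()].
#' @param config a [run_config()]; its `stimuli` are replaced by the
#'   protocol's definition.
#' @param freqs band stimulation frequencies, default [band_frequencies()].
#' @param t_end optional horizon override (s).
#' @param write whether to write output files, default TRUE.
#' @param quiet suppress log messages.
#' @return invisibly, a list with `sim` (`nm_simulation`), `analysis`,
#'   `stimuli` (sampled traces), and `files`.
#' @export
run_protocol <- function(name, config = run_config(),
                         freqs = band_frequencies(), t_end = NULL,
                         write = TRUE, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  def <- .protocol_def(name, freqs, t_end)
  log_ <- function(...) if (!quiet) message(sprintf(...))
  inp <- .resolve_inputs(config)
  cfg <- config$sim
  cfg$t_end <- def$t_end
  specs <- lapply(def$stimuli, function(b) do.call(stimulus_spec, b))
  traces <- lapply(specs, sample_stimulus, dt = cfg$dt)

  log_("protocol '%s': %d nodes, %g s at dt = %g s, seed %d", name,
       length(inp$net$names), cfg$t_end, cfg$dt, cfg$seed)
  sim <- simulate_cluster(inp$net, inp$params, traces, cfg)

  if (isTRUE(def$two_pass)) {
    # phase-align three 100-ms gamma bursts to positive half-cycles of the
    # theta oscillation of A32V's excitatory potential, from 10 s onwards
    ye <- sim$states$ye["A32V", sim$t >= 10]
    onsets <- phase_aligned_onsets(ye, fs = 1 / cfg$dt, n_bursts = 3,
                                   burst_duration = 0.1,
                                   f_base = unname(freqs["theta"]), t0 = 10)
    log_("phase-aligned burst onsets: %s s",
         paste(sprintf("%.3f", onsets), collapse = ", "))
    burst <- stimulus_spec("burst", carrier_amp = 200,
                           f_mod = unname(freqs["gamma"]), duration = 0.1,
                           burst_onsets = onsets, targets = character())
    specs <- c(specs, list(burst))
    traces <- c(traces, list(sample_stimulus(burst, cfg$dt)))
    sim <- simulate_cluster(inp$net, inp$params, traces, cfg)
  }

  onset <- if (length(specs)) min(vapply(traces, `[[`, numeric(1), "t0"))
  else NULL
  an <- analyze_simulation(sim, onset = onset)

  files <- character()
  if (write) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    stem <- file.path(config$output_dir, name)
    csv <- paste0(stem, "_lfp.csv")
    side <- paste0(stem, "_run.json")
    rep_file <- paste0(stem, "_report.json")
    write_simulation(sim, csv, side,
                     extra = list(protocol = name,
                                  stimuli = lapply(specs, unclass),
                                  network = config$network))
    report <- list(
      protocol = name,
      cluster = .report_entry(an$cluster),
      nodes = lapply(an$nodes, .report_entry))
    jsonlite::write_json(report, rep_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <- c(lfp = csv, sidecar = side, report = rep_file)
    log_("wrote %s", paste(files, collapse = ", "))
  }
  invisible(list(sim = sim, analysis = an, stimuli = traces, files = files))
}

.report_entry <- function(x) {
  out <- list(band_fractions = as.list(x$band_power$fractions),
              peak_frequency = x$band_power$peak_frequency)
  if (!is.null(x$transition)) {
    tr <- x$transition
    out$transition <- list(detected = tr$detected,
                           time = tr$transition_time,
                           after_onset = tr$transition_after_onset,
                           direction = tr$direction,
                           reverted = tr$reverted,
                           reversion_time = tr$reversion_time)
    out$repeat_period <- x$repeat_period
  }
  out
}
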