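#' Per-node neural mass parameters
#'
#' Constants of one three-population neural mass.  Written as a driven
#' critically damped oscillator, each population obeys
#' \deqn{y'' + (2/\tau) y' + y/\tau^2 = F(t),}
#' so a node has no self-sustained rhythm; its characteristic response
#' frequency is of order \eqn{1/(2\pi\tau_e)}.
#'
#' @param name node label.
#' @param band frequency-band label (`"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`); metadata only, never used by the dynamics.
#' @param C base feedback constant; the four feedback gains are
#'   `C1..C4 = C * c_ratios`.
#' @param c_ratios multipliers for C1..C4; default the Jansen-Rit ratios
#'   `(1, 0.8, 0.25, 0.25)`.
#' @param A excitatory synaptic gain (mV), default 3.25.
#' @param B inhibitory synaptic gain (mV), default 22.
#' @param tau_e,tau_i excitatory / inhibitory time constants (s), in (0, 0.1].
#' @param r,w_av,q_m,v0 parameters of the internal voltage-to-rate transform
#'   (see [transfer_params()]).
#' @param w_av_out average synaptic weight of the *output* transform applied to
#'   this node's LFP as seen by linked nodes; defaults to `w_av` (a single
#'   average weight per node), but in- and out-link averages may differ.
#' @param variant,arg_form passed to [transfer_params()].
#' @param f_nominal nominal emergent frequency (Hz), metadata.
#' @return an object of class `node_params` with elements `transfer_internal`
#'   and `transfer_output`.
#' @export
node_params <- function(name, band = c("theta", "alpha", "beta", "gamma"),
                        C, c_ratios = c(1, 0.8, 0.25, 0.25),
                        A = 3.25, B = 22,
                        tau_e, tau_i,
                        r = 0.5, w_av = 3, q_m = 2.5, v0 = 6,
                        w_av_out = w_av,
                        variant = "erfc", arg_form = "v_over_v0",
                        f_nominal = NA_real_) {
  band <- match.arg(band)
  stopifnot(is.character(name), length(name) == 1L)
  if (!(tau_e > 0 && tau_e <= 0.1) || !(tau_i > 0 && tau_i <= 0.1))
    stop("tau_e and tau_i must lie in (0, 0.1] s", call. = FALSE)
  if (A <= 0 || B <= 0 || C <= 0) stop("A, B, C must be positive", call. = FALSE)
  if (length(c_ratios) != 4L || any(c_ratios <= 0))
    stop("c_ratios must be four positive multipliers", call. = FALSE)
  ti <- transfer_params(q_m = q_m, v0 = v0, r = r, w_av = w_av,
                        variant = variant, arg_form = arg_form)
  to <- transfer_params(q_m = q_m, v0 = v0, r = r, w_av = w_av_out,
                        variant = variant, arg_form = arg_form)
  structure(list(name = name, band = band,
                 A = A, B = B, C = C, c_ratios = c_ratios,
                 C1 = C * c_ratios[1], C2 = C * c_ratios[2],
                 C3 = C * c_ratios[3], C4 = C * c_ratios[4],
                 tau_e = tau_e, tau_i = tau_i,
                 transfer_internal = ti, transfer_output = to,
                 f_nominal = f_nominal),
            class = "node_params")
}

#' @export
print.node_params <- function(x, ...) {
  cat(sprintf(
    "<node_params> %s [%s]  C=%g  tau_e=%g ms  tau_i=%g ms  w_av=%g  r=%g\n",
    x$name, x$band, x$C, 1000 * x$tau_e, 1000 * x$tau_i,
    x$transfer_internal$w_av, x$transfer_internal$r))
  invisible(x)
}

#' Parameter set of the six-node prefrontal cluster
#'
#' The heterogeneous per-node constants that tune the six cluster areas to
#' characteristic frequency bands: A10 to gamma, A32V and A46D to theta, A32
#' and A11 to beta, A9 to alpha.  Time constants span 5-25 ms; the steepness
#' `r = 0.5` is common to all nodes, and heterogeneity enters through `C`,
#' `w_av`, and the time constants.
#'
#' The preset uses the ratio argument form of the erfc transform
#' (`arg_form = "v0_over_v"`) with a common threshold `v0 = 8` mV: this is
#' the form the synaptic-weight-distribution derivation gives directly, it
#' is continuous at rest, and under drive it produces limit cycles whose
#' frequencies closely match the nominal per-node values (32, ~5.5, 16,
#' ~9.5, ~6, 16 Hz).  The package vignette documents this calibration.
#'
#' @param ... overrides applied to every node (e.g. `variant = "sigmoid"`
#'   or `arg_form = "v_over_v0"`), passed to [node_params()].
#' @return a named list of six [node_params()] objects, in the node order
#'   (A10, A32V, A32, A9, A46D, A11) used throughout the package.
#' @export
#' @examples
#' pars <- pfc_node_params()
#' sapply(pars, function(p) p$band)
pfc_node_params <- function(...) {
  spec <- list(
    list(name = "A10",  band = "gamma", C = 220, w_av = 3,   tau_e = 0.005,
         tau_i = 0.005, f_nominal = 32.1),
    list(name = "A32V", band = "theta", C = 200, w_av = 5,   tau_e = 0.025,
         tau_i = 0.025, f_nominal = 5.3),
    list(name = "A32",  band = "beta",  C = 250, w_av = 3,   tau_e = 0.010,
         tau_i = 0.010, f_nominal = 16.0),
    list(name = "A9",   band = "alpha", C = 220, w_av = 1.5, tau_e = 0.016,
         tau_i = 0.017, f_nominal = 9.9),
    list(name = "A46D", band = "theta", C = 200, w_av = 3.5, tau_e = 0.025,
         tau_i = 0.025, f_nominal = 5.9),
    list(name = "A11",  band = "beta",  C = 250, w_av = 3,   tau_e = 0.010,
         tau_i = 0.010, f_nominal = 16.1))
  dots <- list(...)
  defaults <- list(arg_form = "v0_over_v", v0 = 8)
  defaults <- defaults[setdiff(names(defaults), names(dots))]
  out <- lapply(spec, function(s) do.call(node_params, c(s, defaults, dots)))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# flatten a list of node_params into parallel numeric vectors for the C++ core
.params_arrays <- function(params) {
  g <- function(f) vapply(params, f, numeric(1))
  tr <- function(which, field)
    vapply(params, function(p) p[[which]][[field]], numeric(1))
  code <- function(which, map, field)
    vapply(params, function(p) map[[p[[which]][[field]]]], integer(1))
  list(A = g(function(p) p$A), B = g(function(p) p$B),
       C1 = g(function(p) p$C1), C2 = g(function(p) p$C2),
       C3 = g(function(p) p$C3), C4 = g(function(p) p$C4),
       tau_e = g(function(p) p$tau_e), tau_i = g(function(p) p$tau_i),
       int_variant = code("transfer_internal", .variant_code, "variant"),
       int_argform = code("transfer_internal", .argform_code, "arg_form"),
       int_qm = tr("transfer_internal", "q_m"),
       int_v0 = tr("transfer_internal", "v0"),
       int_r = tr("transfer_internal", "r"),
       int_wav = tr("transfer_internal", "w_av"),
       out_variant = code("transfer_output", .variant_code, "variant"),
       out_argform = code("transfer_output", .argform_code, "arg_form"),
       out_qm = tr("transfer_output", "q_m"),
       out_v0 = tr("transfer_output", "v0"),
       out_r = tr("transfer_output", "r"),
       out_wav = tr("transfer_output", "w_av"))
}
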