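# run-configuration schema: building, validation, loading, description

.allowed_keys <- list(
  top = c("network", "nodes", "sim", "stimuli", "output_dir", "protocol"),
  network = c("fixture_seed", "edges", "coords", "distances", "velocity"),
  sim = c("dt", "t_end", "transient_cut", "seed", "noise_scale", "noise_kind",
          "coupling_scaling", "coupling_gain"),
  stimulus = c("kind", "carrier_amp", "f_mod", "onset", "duration", "targets",
               "burst_count", "burst_gap", "burst_onsets", "bias", "tau_pulse"),
  node = c("name", "band", "C", "c_ratios", "A", "B", "tau_e", "tau_i", "r",
           "w_av", "q_m", "v0", "w_av_out", "variant", "arg_form", "f_nominal"))

.check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key: ", path, "$", bad[1], call. = FALSE)
  invisible(TRUE)
}

#' Build a validated run configuration
#'
#' A run configuration bundles the network source, per-node parameters,
#' simulation settings and stimulus blocks.  Unknown keys anywhere in the
#' structure are rejected with the offending field path, so typos never pass
#' silently.
#'
#' @param network list: either `fixture_seed` (synthetic cluster) or file
#'   paths `edges` plus `coords`/`distances`, with optional `velocity`.
#' @param nodes `"pfc"` (default, the six-node preset) or a list of per-node
#'   parameter lists accepted by [node_params()].
#' @param sim list of [sim_config()] overrides.
#' @param stimuli list of stimulus blocks accepted by [stimulus_spec()].
#' @param output_dir where protocol outputs are written.
#' @return an object of class `run_config` with every default resolved.
#' @export
run_config <- function(network = list(fixture_seed = 1), nodes = "pfc",
                       sim = list(), stimuli = list(),
                       output_dir = "nmsim-out") {
  .check_keys(network, .allowed_keys$network, "network")
  .check_keys(sim, .allowed_keys$sim, "sim")
  for (i in seq_along(stimuli))
    .check_keys(stimuli[[i]], .allowed_keys$stimulus,
                sprintf("stimuli[[%d]]", i))
  if (is.list(nodes))
    for (i in seq_along(nodes))
      .check_keys(nodes[[i]], .allowed_keys$node, sprintf("nodes[[%d]]", i))
  cfg <- do.call(sim_config, sim)
  structure(list(network = network, nodes = nodes, sim = cfg,
                 stimuli = stimuli, output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` or
#'   `.json`).
#' @return a validated `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  .check_keys(raw, .allowed_keys$top, "config")
  raw$protocol <- NULL
  do.call(run_config, raw)
}

# materialise the network and node parameters described by a run_config
.resolve_inputs <- function(rc) {
  nw <- rc$network
  net <- if (!is.null(nw$fixture_seed)) {
    make_pfc_fixture(nw$fixture_seed,
                     velocity = if (is.null(nw$velocity)) 1 else nw$velocity)
  } else {
    load_edge_list(nw$edges, coords = nw$coords, distances = nw$distances,
                   velocity = if (is.null(nw$velocity)) 1 else nw$velocity)
  }
  params <- if (identical(rc$nodes, "pfc")) pfc_node_params()
  else lapply(rc$nodes, function(nd) do.call(node_params, nd))
  if (length(params) != length(net$names))
    stop("node parameter count does not match the network", call. = FALSE)
  list(net = net, params = params)
}

#' Print a fully resolved configuration
#'
#' Echoes every resolved default (integration step, horizon, noise, coupling,
#' network source, node parameters, stimuli) so that runs are
#' self-documenting.
#'
#' @param rc a [run_config()].
#' @return `rc`, invisibly.
#' @export
describe_config <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  s <- rc$sim
  cat("run configuration\n")
  if (!is.null(rc$network$fixture_seed))
    cat(sprintf("  network: synthetic pFC fixture, seed %d\n",
                rc$network$fixture_seed))
  else
    cat(sprintf("  network: files %s / %s\n", rc$network$edges,
                paste(c(rc$network$coords, rc$network$distances),
                      collapse = "")))
  cat(sprintf("  sim: dt=%g s  t_end=%g s  transient_cut=%g s  seed=%d\n",
              s$dt, s$t_end, s$transient_cut, s$seed))
  cat(sprintf("  noise: %s, scale %g s^-1\n", s$noise_kind, s$noise_scale))
  cat(sprintf("  coupling: %s, gain %g\n", s$coupling_scaling,
              s$coupling_gain))
  nodes <- if (identical(rc$nodes, "pfc")) "pfc preset (6 nodes)"
  else sprintf("%d custom nodes", length(rc$nodes))
  cat("  nodes:", nodes, "\n")
  if (length(rc$stimuli)) {
    for (st in rc$stimuli)
      cat(sprintf("  stimulus: %s f=%s Hz amp=%s onset=%s s targets=%s\n",
                  st$kind, st$f_mod %||% "-",
                  st$carrier_amp %||% 200, st$onset %||% 0,
                  paste(st$targets %||% "(all)", collapse = ",")))
  } else cat("  stimuli: none (resting)\n")
  cat("  output_dir:", rc$output_dir, "\n")
  invisible(rc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
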