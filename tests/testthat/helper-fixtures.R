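# shared helpers for the test suite

# a single isolated node embedded in the cluster machinery
one_node_net <- function(name = "N1") {
  cluster_network(name, matrix(0, 1, 1), matrix(0, 1, 1))
}

# constant-rate stimulus trace (tonic drive) for a set of targets
tonic_stimulus <- function(rate, t_end, dt, targets) {
  structure(list(t0 = 0, dt = dt, values = rep(rate, round(t_end / dt)),
                 targets = targets),
            class = "stimulus_trace")
}

# random state inside the rest basin: potentials a few tenths of a mV on the
# e/i populations, micro-volt scale on the pyramidal population (whose
# feedback argument is amplified by C1 ~ 200)
basin_state <- function(n_nodes) {
  as.vector(rbind(runif(n_nodes, -1, 1) * 1e-3,
                  runif(n_nodes, -1, 1) * 1e-3,
                  runif(n_nodes, -1, 1) * 0.3,
                  runif(n_nodes, -1, 1) * 0.3,
                  runif(n_nodes, -1, 1) * 0.3,
                  runif(n_nodes, -1, 1) * 0.3))
}

# dominant nonzero-frequency spectral peak of a trace
dominant_freq <- function(x, fs) {
  sp <- Mod(fft(x - mean(x))[seq_len(length(x) %/% 2)])^2
  fr <- (seq_along(sp) - 1) * fs / length(x)
  fr[fr > 1][which.max(sp[fr > 1])]
}

band_edges <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
                   gamma = c(30, 100))
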