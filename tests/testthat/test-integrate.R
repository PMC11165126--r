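test_that("zero noise, zero stimulus, zero state stays exactly at rest", {
  net <- make_pfc_fixture(1)
  cfg <- sim_config(t_end = 1, transient_cut = 0.5, noise_kind = "none")
  sim <- simulate_cluster(net, pfc_node_params(), cfg = cfg)
  expect_identical(max(abs(sim$lfp)), 0)
  expect_identical(max(abs(sim$states$y0)), 0)
})

test_that("runs are bit-identical for a fixed seed", {
  net <- make_pfc_fixture(2)
  cfg <- sim_config(t_end = 1.5, transient_cut = 1, seed = 7)
  a <- simulate_cluster(net, pfc_node_params(), cfg = cfg)
  b <- simulate_cluster(net, pfc_node_params(), cfg = cfg)
  expect_identical(a$lfp, b$lfp)
  expect_identical(a$states, b$states)
})

test_that("noise 'none' equals gaussian noise with zero scale", {
  net <- make_pfc_fixture(1)
  a <- simulate_cluster(net, pfc_node_params(),
                        cfg = sim_config(t_end = 1, transient_cut = 0.5,
                                         noise_kind = "none"))
  b <- simulate_cluster(net, pfc_node_params(),
                        cfg = sim_config(t_end = 1, transient_cut = 0.5,
                                         noise_scale = 0))
  expect_identical(a$lfp, b$lfp)
})

test_that("uncoupled linear node matches the critically damped closed form", {
  lin <- node_params("L", "beta", C = 250, tau_e = 0.01, tau_i = 0.01,
                     variant = "none")
  cfg <- sim_config(t_end = 0.2, transient_cut = 0.1, noise_kind = "none")
  sim <- simulate_cluster(one_node_net("L"), list(lin), cfg = cfg,
                          state0 = c(0, 0, 1, 0, 0, 0))
  tt <- sim$t
  ref <- (1 + tt / 0.01) * exp(-tt / 0.01)   # ye(0)=1, ye'(0)=0
  rel <- abs(sim$states$ye[1, ] - ref) / pmax(abs(ref), 1e-12)
  expect_lt(max(rel), 1e-6)
})

test_that("compiled nonlinear node agrees with an independent deSolve solution", {
  skip_if_not_installed("deSolve")
  p <- pfc_node_params()$A32
  cfg <- sim_config(t_end = 0.5, transient_cut = 0.1, noise_kind = "none")
  drive <- 40
  stim <- tonic_stimulus(drive, 0.5, cfg$dt, "A32")
  sim <- simulate_cluster(one_node_net("A32"), list(p), list(stim), cfg)
  S <- function(v) rate_transform(v, p$transfer_internal)
  rhs <- function(t, y, parms) {
    ae <- p$A / p$tau_e; bi <- p$B / p$tau_i
    list(c(y[2], ae * S(y[3] - y[5]) - 2 / p$tau_e * y[2] - y[1] / p$tau_e^2,
           y[4], ae * p$C2 * S(p$C1 * y[1]) + ae * drive -
             2 / p$tau_e * y[4] - y[3] / p$tau_e^2,
           y[6], bi * p$C4 * S(p$C3 * y[1]) - 2 / p$tau_i * y[6] -
             y[5] / p$tau_i^2))
  }
  ref <- deSolve::ode(numeric(6), times = seq(0, 0.5, 1e-3), func = rhs,
                      parms = NULL, method = "ode45", rtol = 1e-10,
                      atol = 1e-12)
  ours <- sim$lfp[1, match(round(ref[, 1], 6), round(sim$t, 6))]
  theirs <- ref[, 4] - ref[, 6]
  expect_lt(max(abs(ours - theirs)), 1e-5 * max(1, max(abs(theirs))))
})

test_that("compiled delay coupling matches a plain R reference loop", {
  # 2-node delayed system, short horizon, deterministic tonic drive
  W <- matrix(c(0, 800, 600, 0), 2, byrow = TRUE)
  D <- matrix(c(0, 2, 2, 0), 2)
  net <- cluster_network(c("a", "b"), W, D)
  params <- list(pfc_node_params()$A32, pfc_node_params()$A32V)
  params[[1]]$name <- "a"; params[[2]]$name <- "b"
  cfg <- sim_config(t_end = 0.3, transient_cut = 0.1, noise_kind = "none",
                    coupling_scaling = "raw", coupling_gain = 0.04)
  stim <- tonic_stimulus(50, 0.3, cfg$dt, c("a", "b"))
  sim <- simulate_cluster(net, params, list(stim), cfg)

  # independent R implementation of the same scheme
  dt <- cfg$dt; nst <- round(0.3 / dt)
  Wbar <- coupling_matrix(net, "raw", 0.04)
  ds <- delay_steps(net, dt)
  y <- matrix(0, 6, 2)  # columns = nodes
  dyh <- matrix(0, 2, nst + 1)
  lfp <- matrix(0, 2, nst + 1)
  Sint <- lapply(params, function(p) function(v)
    rate_transform(v, p$transfer_internal))
  Sout <- lapply(params, function(p) function(v)
    rate_transform(v, p$transfer_output))
  deriv <- function(y, drv) {
    out <- y * 0
    for (k in 1:2) {
      p <- params[[k]]; ae <- p$A / p$tau_e; bi <- p$B / p$tau_i
      s <- y[, k]
      out[, k] <- c(s[2],
                    ae * Sint[[k]](s[3] - s[5]) - 2 / p$tau_e * s[2] -
                      s[1] / p$tau_e^2,
                    s[4],
                    ae * p$C2 * Sint[[k]](p$C1 * s[1]) + drv[k] -
                      2 / p$tau_e * s[4] - s[3] / p$tau_e^2,
                    s[6],
                    bi * p$C4 * Sint[[k]](p$C3 * s[1]) - 2 / p$tau_i * s[6] -
                      s[5] / p$tau_i^2)
    }
    out
  }
  for (i in 1:nst) {
    drv <- numeric(2)
    for (k in 1:2) {
      coup <- 0
      for (j in 1:2) {
        if (Wbar[k, j] == 0) next
        m <- i - 1 - ds[k, j]
        dyj <- if (m >= 0) dyh[j, m + 1] else 0
        coup <- coup + Wbar[k, j] * Sout[[j]](dyj)
      }
      p <- params[[k]]
      drv[k] <- p$A / p$tau_e * (50 + coup)
    }
    k1 <- deriv(y, drv); k2 <- deriv(y + dt / 2 * k1, drv)
    k3 <- deriv(y + dt / 2 * k2, drv); k4 <- deriv(y + dt * k3, drv)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    dyh[, i + 1] <- y[3, ] - y[5, ]
    lfp[, i + 1] <- y[3, ] - y[5, ]
  }
  expect_equal(sim$lfp, lfp, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("delayed path at infinite velocity equals a delay-free network", {
  net <- make_pfc_fixture(1)
  netI <- cluster_network(net$names, net$W, net$D, velocity = Inf,
                          coords = net$coords)
  netF <- cluster_network(net$names, net$W, net$D, velocity = 1e9,
                          coords = net$coords)
  cfg <- sim_config(t_end = 1.5, transient_cut = 1, seed = 3)
  a <- simulate_cluster(netI, pfc_node_params(), cfg = cfg)
  b <- simulate_cluster(netF, pfc_node_params(), cfg = cfg)
  expect_identical(a$lfp, b$lfp)
})

test_that("RK4 convergence order is close to four on a smooth probe", {
  co <- convergence_order()
  expect_gte(co$order, 3.5)
  expect_error(convergence_order(dts = c(1e-3, 5e-4)), "3 step sizes")
})

test_that("state blow-up is reported with step and node", {
  p <- node_params("X", "beta", C = 250, tau_e = 0.01, tau_i = 0.01,
                   A = 1e154, variant = "none")
  cfg <- sim_config(t_end = 0.1, transient_cut = 0.05, noise_kind = "none")
  stim <- tonic_stimulus(1e200, 0.1, cfg$dt, "X")
  expect_error(simulate_cluster(one_node_net("X"), list(p), list(stim), cfg),
               "blow-up.*node")
})

test_that("unknown stimulus targets are rejected", {
  net <- make_pfc_fixture(1)
  st <- stimulus_spec("half_wave", f_mod = 10, duration = 1,
                      targets = "nope")
  expect_error(simulate_cluster(net, pfc_node_params(), list(st),
                                sim_config(t_end = 1, transient_cut = 0)),
               "unknown stimulus target")
})

test_that("simulation result invariants hold", {
  net <- make_pfc_fixture(1)
  cfg <- sim_config(t_end = 1, transient_cut = 0.5, seed = 2)
  sim <- simulate_cluster(net, pfc_node_params(), cfg = cfg)
  expect_equal(sim$cluster_lfp, colMeans(sim$lfp))
  expect_equal(sim$lfp, sim$states$ye - sim$states$yi)
  expect_length(sim$t, round(1 / cfg$dt) + 1)
})
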