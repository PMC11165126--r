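#' Generic fixed-step RK4 integrator (pure R)
#'
#' Classic fourth-order Runge-Kutta with stage evaluations at `t`, `t+dt/2`
#' and `t+dt`.  Used as the reference path for convergence and closed-form
#' checks of the compiled cluster integrator, and for smooth probe systems.
#'
#' @param f derivative function `f(t, y)` returning `dy/dt`.
#' @param y0 initial state (numeric vector).
#' @param t0 initial time (s).
#' @param dt step size (s).
#' @param nsteps number of steps.
#' @return matrix with `nsteps + 1` rows (states) and attribute `"t"`.
#' @export
rk4_integrate <- function(f, y0, t0 = 0, dt, nsteps) {
  y <- as.numeric(y0)
  out <- matrix(NA_real_, nsteps + 1, length(y))
  out[1, ] <- y
  t <- t0
  for (i in seq_len(nsteps)) {
    k1 <- f(t, y)
    k2 <- f(t + dt / 2, y + dt / 2 * k1)
    k3 <- f(t + dt / 2, y + dt / 2 * k2)
    k4 <- f(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
    out[i + 1, ] <- y
  }
  attr(out, "t") <- t0 + dt * (0:nsteps)
  out
}

#' Observed convergence order of the RK4 scheme
#'
#' Integrates a smooth, delay-free probe system at each step size in `dts`,
#' measures the end-state error against a fine-step reference (the same
#' scheme at `min(dts)/16`), and estimates the global order from successive
#' error ratios (a Richardson-type estimate).  The classic scheme should show
#' order close to 4.
#'
#' @param f probe derivative function `f(t, y)`; default a critically damped
#'   node (`tau` 10 ms) driven by a smooth sinusoidal force.
#' @param y0 initial state; default `c(1, 0)`.
#' @param t_end integration horizon (s).
#' @param dts decreasing sequence of at least 3 step sizes (s).
#' @return list with `orders` (pairwise estimates), `order` (their median)
#'   and `errors`.
#' @export
convergence_order <- function(f = NULL, y0 = c(1, 0), t_end = 0.1,
                              dts = c(4e-3, 2e-3, 1e-3, 5e-4)) {
  if (length(dts) < 3) stop("need at least 3 step sizes", call. = FALSE)
  dts <- sort(dts, decreasing = TRUE)
  if (is.null(f)) {
    tau <- 0.01
    f <- function(t, y) c(y[2],
                          50 * sin(2 * pi * 20 * t) - 2 / tau * y[2] -
                            y[1] / tau^2)
  }
  dt_ref <- min(dts) / 16
  ref <- rk4_integrate(f, y0, 0, dt_ref, round(t_end / dt_ref))
  yref <- ref[nrow(ref), ]
  errors <- vapply(dts, function(dt) {
    sol <- rk4_integrate(f, y0, 0, dt, round(t_end / dt))
    sqrt(sum((sol[nrow(sol), ] - yref)^2))
  }, numeric(1))
  orders <- log2(errors[-length(errors)] / errors[-1]) /
    log2(dts[-length(dts)] / dts[-1])
  list(order = median(orders), orders = orders, errors = errors, dts = dts)
}
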