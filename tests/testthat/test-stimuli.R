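dt <- 1e-4

test_that("half-wave stimulus: amplitude, rectified mean, silence before onset", {
  sp <- stimulus_spec("half_wave", f_mod = 16, onset = 1, duration = 2)
  tr <- half_wave(sp, dt)
  expect_equal(tr$t0, 1)
  expect_equal(max(tr$values), 200, tolerance = 1e-4)
  expect_equal(min(tr$values), 0)
  # mean of a rectified sine over whole periods is amp/pi
  expect_equal(mean(tr$values), 200 / pi, tolerance = 1e-3)
  expect_length(tr$values, round(2 / dt))  # nothing sampled before onset
})

test_that("full-wave stimulus doubles the effective frequency", {
  sp <- stimulus_spec("full_wave", f_mod = 32.1, duration = 4)
  tr <- full_wave(sp, dt)
  expect_equal(mean(tr$values), 2 * 200 / pi, tolerance = 1e-3)
  expect_equal(dominant_freq(tr$values, 1 / dt), 64.2, tolerance = 0.01)
  # agrees with the half wave wherever sin >= 0
  hw <- half_wave(stimulus_spec("half_wave", f_mod = 32.1, duration = 4), dt)
  pos <- hw$values > 0
  expect_equal(tr$values[pos], hw$values[pos])
  # half-wave fundamental stays at f_mod
  expect_equal(dominant_freq(hw$values, 1 / dt), 32.1, tolerance = 0.01)
})

test_that("offset-biased full wave keeps the fundamental at f_mod", {
  sp <- stimulus_spec("full_wave", f_mod = 16, duration = 4, bias = "offset")
  tr <- full_wave(sp, dt)
  expect_true(all(tr$values >= 0))
  expect_equal(dominant_freq(tr$values, 1 / dt), 16, tolerance = 0.01)
})

test_that("a 100-ms gamma burst carries at most six positive peaks", {
  sp <- stimulus_spec("burst", f_mod = 32.1, duration = 0.1)
  tr <- gamma_burst(sp, dt)
  pk <- pracma::findpeaks(tr$values, minpeakheight = 1e-9)
  expect_lte(nrow(pk), 6)
  expect_gte(nrow(pk), 5)
})

test_that("burst trains: disjoint actives, linear energy, overlap rejected", {
  sp3 <- stimulus_spec("burst", f_mod = 32.1, duration = 0.1,
                       burst_count = 3L, burst_gap = 0.3)
  tr3 <- gamma_burst(sp3, dt)
  expect_equal(sum(tr3$values > 1e-9) * dt, 0.3, tolerance = 0.01)
  spx2 <- stimulus_spec("burst", f_mod = 32.1, duration = 0.1,
                        burst_count = 3L, burst_gap = 0.3, carrier_amp = 400)
  expect_equal(unit_pulse_energy(gamma_burst(spx2, dt)),
               2 * unit_pulse_energy(tr3), tolerance = 1e-10)
  bad <- stimulus_spec("burst", f_mod = 32.1, duration = 0.1,
                       burst_count = 2L, burst_gap = 0.05)
  expect_error(gamma_burst(bad, dt), "overlap")
})

test_that("pulse function peaks at 7 tau with the requested amplitude", {
  sp <- stimulus_spec("pulse_function", onset = 0.05)
  tr <- pulse_function(sp, dt)
  ipk <- which.max(tr$values)
  expect_equal(max(tr$values), 200, tolerance = 1e-6)
  expect_equal((ipk - 1) * dt, 7 * 0.004, tolerance = 1e-3)  # 28 ms after onset
})

test_that("pulse-function energy matches the closed form and a quadrature oracle", {
  sp <- stimulus_spec("pulse_function")
  e <- unit_pulse_energy(pulse_function(sp, dt))
  closed <- 200 * 0.004 * factorial(7) * exp(7) / 7^7
  expect_equal(closed, 5.3689, tolerance = 1e-4)
  expect_equal(e, closed, tolerance = 1e-3)
  # independent quadrature of the scaled density
  orac <- integrate(function(t) 200 / ((7 * 0.004)^7 * exp(-7)) *
                      t^7 * exp(-t / 0.004), 0, 0.3)$value
  expect_equal(e, orac, tolerance = 1e-4)
})

test_that("unit-pulse energy: 16-s half wave ~ 1000, degenerate cases", {
  sp <- stimulus_spec("half_wave", f_mod = 16, duration = 16)
  e <- unit_pulse_energy(half_wave(sp, dt))
  expect_equal(e, 200 * 16 / pi, tolerance = 1e-3)   # ~1018.6
  expect_equal(unit_pulse_energy(numeric(0), dt = dt), 0)
  expect_equal(unit_pulse_energy(rep(200, round(1 / dt) + 1), dt = dt), 200,
               tolerance = 1e-6)
})

test_that("every generated trace is non-negative over random specifications", {
  set.seed(21)
  for (i in 1:40) {
    kind <- sample(c("half_wave", "full_wave", "burst", "pulse_function"), 1)
    sp <- stimulus_spec(kind, carrier_amp = runif(1, 1, 500),
                        f_mod = runif(1, 1, 80), onset = runif(1, 0, 2),
                        duration = runif(1, 0.05, 1),
                        bias = sample(c("rectified", "offset"), 1))
    expect_true(all(sample_stimulus(sp, 5e-4)$values >= 0))
  }
})

test_that("energy is linear in amplitude and duration over whole periods", {
  e1 <- unit_pulse_energy(half_wave(
    stimulus_spec("half_wave", f_mod = 10, duration = 1), dt))
  e2 <- unit_pulse_energy(half_wave(
    stimulus_spec("half_wave", f_mod = 10, duration = 2), dt))
  e3 <- unit_pulse_energy(half_wave(
    stimulus_spec("half_wave", f_mod = 10, duration = 1, carrier_amp = 400),
    dt))
  expect_equal(e2, 2 * e1, tolerance = 1e-6)
  expect_equal(e3, 2 * e1, tolerance = 1e-10)
})

test_that("phase-aligned onsets land on successive positive half-cycles", {
  fs <- 2000
  tt <- seq(0, 2, 1 / fs)
  ref <- sin(2 * pi * 5.3 * tt)
  on <- phase_aligned_onsets(ref, fs, n_bursts = 3, burst_duration = 0.1,
                             f_base = 5.3)
  expect_equal(diff(on), rep(1 / 5.3, 2), tolerance = 0.01)  # ~188.7 ms
  # each burst lies inside a positive half-cycle of the reference
  for (o in on)
    expect_true(all(sin(2 * pi * 5.3 * (o + c(0.01, 0.05))) > 0))
  expect_error(phase_aligned_onsets(ref, fs, 3, 0.3, f_base = 5.3),
               "does not fit")
  expect_error(phase_aligned_onsets(rep(1, 100) + 1e-9 * (1:100), fs, 1, 0.1),
               "no sign change")
  expect_error(phase_aligned_onsets(ref[1:2001], fs, 30, 0.05, f_base = 5.3),
               "too few")
})

test_that("stimulus specifications validate their fields", {
  expect_error(stimulus_spec("half_wave", f_mod = -1, duration = 1), "f_mod")
  expect_error(stimulus_spec("half_wave", duration = 1), "f_mod")
  expect_error(stimulus_spec("half_wave", f_mod = 5, duration = -1),
               "duration")
  expect_error(stimulus_spec("half_wave", f_mod = 5), "duration")
  # burst and pulse_function have sensible default durations
  expect_equal(stimulus_spec("burst", f_mod = 32.1)$duration, 0.1)
  expect_equal(stimulus_spec("pulse_function")$duration, 0.3)
})
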