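fs <- 500

test_that("single tones land their power in the correct band", {
  tt <- seq(0, 10, 1 / fs)
  bp <- band_power(sin(2 * pi * 10 * tt), fs)
  expect_gt(bp$fractions[["alpha"]], 0.99)
  expect_lt(max(bp$fractions[c("theta", "beta", "gamma")]), 0.01)
  expect_equal(bp$peak_frequency, 10, tolerance = 0.05)
})

test_that("two equal-power tones split band power evenly", {
  tt <- seq(0, 20, 1 / fs)
  x <- sin(2 * pi * 5 * tt) + sin(2 * pi * 16 * tt)
  bp <- band_power(x, fs)
  expect_equal(bp$fractions[["theta"]], 0.5, tolerance = 0.02)
  expect_equal(bp$fractions[["beta"]], 0.5, tolerance = 0.02)
})

test_that("white noise spreads power in proportion to band width", {
  set.seed(5)
  x <- rnorm(fs * 120)
  bp <- band_power(x, fs, window = "rect")
  widths <- c(theta = 4, alpha = 4, beta = 18, gamma = 70) / 96
  expect_equal(unname(bp$fractions), unname(widths), tolerance = 0.05)
})

test_that("band powers are Parseval-consistent with the total spectrum", {
  set.seed(6)
  tt <- seq(0, 12, 1 / fs)
  x <- sin(2 * pi * 7 * tt) + 0.5 * rnorm(length(tt))
  bp <- band_power(x, fs)
  expect_equal(bp$in_band_power + bp$out_of_band, bp$total_power,
               tolerance = 1e-6)
  expect_equal(sum(bp$fractions), 1, tolerance = 1e-9)
  # windowed periodogram total equals windowed signal power (Parseval)
  n <- length(x); w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  xc <- x - mean(x)
  expect_equal(bp$total_power, sum((xc * w)^2) / sum(w^2),
               tolerance = 0.01)   # one-sided folding of the Nyquist bins
  expect_error(band_power(x[1:100], fs), "too short")
})

test_that("band edges are closed on the left: 8 Hz counts as alpha", {
  # grid chosen so 8 Hz falls exactly on a frequency bin
  tt <- seq(0, 16 - 1 / fs, 1 / fs)
  bp <- band_power(sin(2 * pi * 8 * tt), fs)
  expect_gt(bp$fractions[["alpha"]], 0.6)
  expect_gt(bp$fractions[["alpha"]], bp$fractions[["theta"]])
})

test_that("a constant-amplitude oscillation yields no transition", {
  tt <- seq(0, 20, 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  tr <- detect_transition(x, fs, baseline = c(1, 3), onset = 4)
  expect_false(tr$detected)
})

test_that("a planted amplitude drop is located within one envelope window", {
  tt <- seq(0, 25, 1 / fs)
  amp <- ifelse(tt < 12.5, 1, 0.5)
  x <- amp * sin(2 * pi * 10 * tt)
  tr <- detect_transition(x, fs, baseline = c(1, 3), onset = 4)
  expect_true(tr$detected)
  expect_equal(tr$transition_time, 12.5, tolerance = 0.5)
  expect_equal(tr$direction, "down")
  expect_false(tr$reverted)
})

test_that("recovery after a drop sets the reversion flag and time", {
  tt <- seq(0, 25, 1 / fs)
  amp <- ifelse(tt < 10, 1, ifelse(tt < 17, 0.5, 1))
  x <- amp * sin(2 * pi * 10 * tt)
  tr <- detect_transition(x, fs, baseline = c(1, 3), onset = 4)
  expect_true(tr$detected)
  expect_true(tr$reverted)
  expect_equal(tr$reversion_time, 17, tolerance = 0.5)
})

test_that("detector outcomes are invariant to trace scaling", {
  tt <- seq(0, 25, 1 / fs)
  amp <- ifelse(tt < 12.5, 1, 0.45)
  x <- amp * sin(2 * pi * 10 * tt)
  t1 <- detect_transition(x, fs, baseline = c(1, 3), onset = 4)
  t2 <- detect_transition(1000 * x, fs, baseline = c(1, 3), onset = 4)
  expect_equal(t1$transition_time, t2$transition_time)
  expect_equal(repeat_period(x * (1 + 0.5 * sin(2 * pi * tt / 6.6)), fs),
               repeat_period(1000 * x * (1 + 0.5 * sin(2 * pi * tt / 6.6)),
                             fs))
  expect_error(detect_transition(x, fs, baseline = c(30, 31), onset = 31),
               "empty")
  expect_error(detect_transition(x, fs, baseline = c(1, 6), onset = 4),
               "precede")
})

test_that("repeat period recovers a planted envelope modulation", {
  tt <- seq(0, 30, 1 / fs)
  x <- (1 + 0.5 * sin(2 * pi * tt / 6.6)) * sin(2 * pi * 16 * tt)
  expect_equal(repeat_period(x, fs), 6.6, tolerance = 0.2)
  expect_true(is.na(repeat_period(sin(2 * pi * 16 * tt), fs)))
})

test_that("two-tone beats repeat at the reciprocal frequency difference", {
  tt <- seq(0, 30, 1 / fs)
  x <- sin(2 * pi * 16 * tt) + sin(2 * pi * 16.15 * tt)
  expect_equal(repeat_period(x, fs), 1 / 0.15, tolerance = 0.3)
})

test_that("detector calibration: planted change points across 100 seeds", {
  fs2 <- 250
  hits <- 0
  for (seed in 1:100) {
    set.seed(seed)
    t_true <- runif(1, 8, 20)
    drop <- runif(1, 0.3, 0.6)
    tt <- seq(0, 25, 1 / fs2)
    amp <- ifelse(tt < t_true, 1, drop)
    x <- amp * sin(2 * pi * 10 * tt) + 0.03 * rnorm(length(tt))
    tr <- detect_transition(x, fs2, baseline = c(1, 3), onset = 4)
    if (tr$detected && abs(tr$transition_time - t_true) <= 0.5)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})
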