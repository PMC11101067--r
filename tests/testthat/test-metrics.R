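test_that("zero-phase filtering preserves DC, passband and peak timing", {
  fs <- 800e3
  expect_equal(lowpass_zerophase(rep(2.5, 500), fs, 10e3), rep(2.5, 500),
               tolerance = 1e-9)
  # 1 kHz tone far below a 10 kHz cut-off is attenuated by < 0.1%
  t <- (0:3999) / fs
  x <- sin(2 * pi * 1e3 * t)
  y <- lowpass_zerophase(x, fs, 10e3)
  mid <- 1000:3000
  expect_lt(abs(max(abs(y[mid])) - 1), 1e-3)
  # symmetric pulse away from the record edges keeps its peak position
  p <- pulse_half_sine(start = 0.3e-3)$force
  expect_equal(which.max(lowpass_zerophase(p, fs, 10e3)), which.max(p))
  # a pulse touching the record start may shift by at most one sample
  p0 <- pulse_half_sine()$force
  expect_lte(abs(which.max(lowpass_zerophase(p0, fs, 10e3)) -
                   which.max(p0)), 1)
  # linear operator
  a <- rnorm(300)
  b <- rnorm(300)
  expect_equal(lowpass_zerophase(2 * a + 3 * b, fs, 15e3),
               2 * lowpass_zerophase(a, fs, 15e3) +
                 3 * lowpass_zerophase(b, fs, 15e3), tolerance = 1e-10)
  expect_error(lowpass_zerophase(a, fs, 400e3), "Nyquist")
})

test_that("repeated filtering attenuates at least as much at every tone", {
  fs <- 800e3
  t <- (0:3999) / fs
  for (f0 in c(5e3, 10e3, 20e3, 40e3)) {
    x <- sin(2 * pi * f0 * t)
    once <- lowpass_zerophase(x, fs, 10e3)
    twice <- lowpass_zerophase(once, fs, 10e3)
    mid <- 1000:3000
    expect_lte(max(abs(twice[mid])), max(abs(once[mid])) * (1 + 1e-9))
  }
})

test_that("normalization is a scale-invariant division by the mallet peak", {
  x <- c(0, 3219, 1000)
  expect_equal(normalize_to_mallet(x, 9247)[2], 0.348, tolerance = 1e-3)
  expect_equal(normalize_to_mallet(rep(0, 5), 9247), rep(0, 5))
  expect_equal(normalize_to_mallet(7 * x, 7 * 9247),
               normalize_to_mallet(x, 9247))
  expect_error(normalize_to_mallet(x, 0), "positive")
})

test_that("feature extraction reads peaks, period and delay", {
  fs <- 800e3
  t <- seq(0, 1e-3, by = 1 / fs)
  x <- sin(2 * pi * 5e3 * t)
  ft <- signal_features(x, fs)
  expect_equal(ft$period, 1 / 5e3, tolerance = 1 / fs / (1 / 5e3))
  expect_equal(ft$first_peak, 1, tolerance = 1e-3)
  # single lobe: no period, first peak defined
  lone <- signal_features(pulse_half_sine()$force, fs, mallet_peak = 9247,
                          mallet_peak_time = 0)
  expect_equal(lone$first_peak, 1)
  expect_true(is.na(lone$period))
  expect_equal(lone$delay, 0.070e-3)
  expect_error(signal_features(rep(0, 100), fs), "no positive peak")
})

test_that("windowed RMSE matches its closed forms", {
  fs <- 800e3
  base <- reference_sim()$data$force_stem / 9247
  expect_equal(rmse_window(base, base, fs), 0)
  expect_equal(rmse_window(base + 0.02, base, fs), 2.0, tolerance = 1e-9)
  # quarter-period-shifted unit sines: RMSE = 100% over whole periods
  t <- seq(0, 3 / 1e3, by = 1 / fs)
  s <- sin(2 * pi * 1e3 * t)
  cs <- cos(2 * pi * 1e3 * t)
  expect_equal(rmse_window(cs, s, fs), 100, tolerance = 1)
  # near-symmetry when both signals carry the same window structure
  a <- base + 0.001
  expect_equal(rmse_window(a, base, fs), rmse_window(base, a, fs),
               tolerance = 0.05)
  lone <- pulse_half_sine()$force / 9247
  expect_error(rmse_window(lone, lone, fs), "two identifiable")
})

test_that("dominant frequency finds the spectral peak", {
  fs <- 800e3
  t <- seq(0, 2e-3, by = 1 / fs)
  x <- 0.4 + sin(2 * pi * 3.5e3 * t) + 0.2 * sin(2 * pi * 30e3 * t)
  expect_equal(dominant_frequency(x, fs), 3.5e3, tolerance = 0.05)
})
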