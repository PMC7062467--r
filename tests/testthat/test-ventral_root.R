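# square-envelope bursts in the generator's world: broadband noise whose
# envelope steps between a baseline gain and baseline + burst gain
make_square_bursts <- function(on_s = 1, off_s = 3, total_s = 60, fs = 1000,
                               burst_gain = 4, baseline_gain = 1) {
  n <- total_s * fs
  t <- (seq_len(n) - 1) / fs
  period <- on_s + off_s
  env <- as.numeric(t %% period < on_s)
  set.seed(99)
  timeseries(rnorm(n) * (baseline_gain + burst_gain * env), fs,
             units = "a.u.")
}

test_that("leaky integrator matches the RC step response", {
  fs <- 1000
  ts <- timeseries(c(rep(0, 100), rep(1, 400)), fs)
  y <- rectify_integrate(ts, 0.05)
  # after k samples of ON input the discrete response is 1 - exp(-k dt / tau)
  expect_equal(y$values[100 + 50], 1 - exp(-1), tolerance = 1e-3)
  expect_equal(y$values[100 + 150], 1 - exp(-3), tolerance = 1e-3)
  # zero input stays identically zero
  z <- rectify_integrate(timeseries(rep(0, 100), fs), 0.05)
  expect_true(all(z$values == 0))
  # |sin| of a fast carrier integrates to its mean 2/pi (sampled densely so
  # the discrete mean of |sin| approximates the continuous one)
  fs2 <- 20000
  tt <- (0:(2 * fs2 - 1)) / fs2
  s <- rectify_integrate(timeseries(sin(2 * pi * 100 * tt), fs2), 0.05)
  expect_equal(mean(s$values[fs2:(2 * fs2)]), 2 / pi, tolerance = 0.01)
  expect_error(rectify_integrate(timeseries(c(0, 1), 10), 0.05),
               "below one sample")
})

test_that("square-envelope bursts are recovered with correct timing", {
  raw <- make_square_bursts(on_s = 1, off_s = 3, total_s = 60)
  b <- detect_bursts(rectify_integrate(raw),
                     burst_detection_params(min_duration_s = 0.3))
  expect_identical(nrow(b), 15L)
  expect_equal(mean(diff(b$onset_s)), 4.0, tolerance = 0.05 / 4)
  expect_true(all(abs(b$duration_s - 1.0) < 0.1))
})

test_that("noise-only and flat traces yield empty tables", {
  set.seed(1)
  noise <- timeseries(rnorm(20000), 1000)
  b <- detect_bursts(rectify_integrate(noise),
                     burst_detection_params(threshold_k = 5))
  expect_identical(nrow(b), 0L)
  expect_warning(bf <- detect_bursts(timeseries(rep(1, 100), 100)), "flat")
  expect_identical(nrow(bf), 0L)
})

test_that("events closer than merge_gap_s are merged", {
  fs <- 1000
  env <- numeric(10 * fs)
  env[2000:2500] <- 1   # 0.5 s event
  env[2551:3050] <- 1   # second event 50 ms later
  ts <- timeseries(env, fs)
  ts$integrator_tau_s <- NULL  # raw envelope, no lag compensation wanted
  b1 <- detect_bursts(ts, burst_detection_params(merge_gap_s = 0.1))
  expect_identical(nrow(b1), 1L)
  b2 <- detect_bursts(ts, burst_detection_params(merge_gap_s = 0.01))
  expect_identical(nrow(b2), 2L)
})

test_that("burst metrics follow their definitions", {
  fs <- 1000
  x <- numeric(12 * fs)
  onsets <- c(0, 4, 8)
  for (o in onsets) x[(o * fs + 1):(o * fs + fs)] <- 2  # |raw| = 2 inside
  raw <- timeseries(x, fs)
  bursts <- data.frame(onset_s = onsets, offset_s = onsets + 1,
                       duration_s = 1, amplitude = NA, cycle_index = 1:3)
  bm <- burst_metrics(bursts, raw)
  expect_equal(bm$frequency_hz, 0.25)
  expect_equal(bm$bursts$amplitude, rep(2, 3), tolerance = 1e-6)
  expect_equal(bm$mean_duration_s, 1)
  one <- burst_metrics(bursts[1, ], raw)
  expect_false(one$frequency_defined)
  expect_true(is.na(one$frequency_hz))
})

test_that("detection is gain-invariant; amplitudes scale linearly", {
  cfg <- scenario_config(seed = 21, duration_s = 120)
  g <- gen_ventral_root(cfg)
  b1 <- detect_bursts(rectify_integrate(g$raw))
  m1 <- burst_metrics(b1, g$raw)
  scaled <- timeseries(g$raw$values * 7.3, g$raw$sampling_rate_hz)
  b2 <- detect_bursts(rectify_integrate(scaled))
  m2 <- burst_metrics(b2, scaled)
  expect_equal(b2$onset_s, b1$onset_s, tolerance = 1e-9)
  expect_equal(b2$duration_s, b1$duration_s, tolerance = 1e-9)
  expect_equal(m2$bursts$amplitude, 7.3 * m1$bursts$amplitude,
               tolerance = 1e-6)
})

test_that("burst recovery holds across SNR levels", {
  for (snr in c(5, 10, 20)) {
    cfg <- scenario_config(seed = 31, duration_s = 300,
                           vr = list(burst_gain = snr / 5))
    g <- gen_ventral_root(cfg)
    b <- detect_bursts(rectify_integrate(g$raw))
    bm <- burst_metrics(b, g$raw)
    tr <- g$truth$bursts
    f_true <- (nrow(tr) - 1) / diff(range(tr$onset_s))
    expect_equal(bm$frequency_hz, f_true, tolerance = 0.05)
    expect_equal(bm$mean_duration_s, mean(tr$duration_s), tolerance = 0.05)
  }
})

test_that("time-course normalization hits 100% in the pre-control window", {
  ms <- data.frame(time_s = seq(5, 1195, by = 10), value = 3)
  tc <- timecourse_normalize(ms, epoch("pre", 0, 600))
  expect_true(all(abs(tc$metric_pct - 100) < 1e-9))
  # doubling after the pre-control period gives 200% bins
  ms2 <- ms
  ms2$value[ms2$time_s >= 600] <- 6
  tc2 <- timecourse_normalize(ms2, epoch("pre", 0, 600))
  expect_true(all(abs(tc2$metric_pct[tc2$bin_start_s >= 600] - 200) < 1e-9))
  # a bin with no bursts is NA, not zero
  ms3 <- ms[ms$time_s < 300 | ms$time_s >= 400, ]
  tc3 <- timecourse_normalize(ms3, epoch("pre", 0, 600))
  gap <- tc3$bin_start_s >= 300 & tc3$bin_start_s < 390
  expect_true(all(is.na(tc3$metric_pct[gap])))
  expect_error(timecourse_normalize(
    data.frame(time_s = 1, value = 0), epoch("pre", 0, 600)), "zero")
})

test_that("epoch comparison averages the final window and names offenders", {
  ms <- data.frame(time_s = seq(0.5, 1799.5, by = 1), value = 1)
  ms$value[ms$time_s >= 600 & ms$time_s < 1200] <- 0.893
  eps <- list(epoch("control", 0, 600), epoch("drug", 600, 1200),
              epoch("washout", 1200, 1800))
  em <- epoch_compare(ms, eps)
  expect_equal(em$mean_value[2] / em$mean_value[1], 0.893, tolerance = 1e-9)
  expect_equal(em$mean_value[3] / em$mean_value[1], 1, tolerance = 1e-9)
  expect_error(epoch_compare(ms, list(epoch("short", 0, 100))), "short")
})
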