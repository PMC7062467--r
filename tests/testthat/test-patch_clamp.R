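# build a current-clamp trace with parametric triangular spikes: linear rise
# (slope well above the 10 mV/ms criterion) and linear fall, so onset voltage
# and width-at-half-amplitude are exact by construction
tri_spike_trace <- function(peaks_s, fs = 10000, rest = -60, amp = 60,
                            rise_ms = 0.8, fall_ms = 1.2, total_s = 1) {
  n <- total_s * fs
  v <- rep(rest, n)
  up <- round(rise_ms / 1000 * fs); dn <- round(fall_ms / 1000 * fs)
  shape <- c(seq(0, amp, length.out = up + 1), seq(amp, 0,
             length.out = dn + 1)[-1])
  for (p in peaks_s) {
    i_on <- round(p * fs) + 1 - up
    seg <- i_on:min(n, i_on + length(shape) - 1)
    v[seg] <- v[seg] + shape[seq_along(seg)]
  }
  timeseries(v, fs, units = "mV")
}

test_that("spike peaks are detected with a refractory rule", {
  peaks <- c(0.1, 0.25, 0.4, 0.6, 0.9)
  v <- tri_spike_trace(peaks)
  ev <- detect_spikes(v)
  expect_length(ev$times_s, 5L)
  expect_true(all(abs(ev$times_s - peaks) <= 1 / v$sampling_rate_hz + 1e-12))
  sub <- timeseries(rep(-60, 1000) + rnorm(1000, 0, 0.2), 10000, units = "mV")
  expect_length(detect_spikes(sub)$times_s, 0L)
  # two peaks 0.4 ms apart collapse to one event
  twin <- tri_spike_trace(c(0.5, 0.5004), rise_ms = 0.1, fall_ms = 0.1)
  expect_length(detect_spikes(twin)$times_s, 1L)
})

test_that("dV/dt onset criterion finds the start of the final fast run", {
  fs <- 10000
  # linear rise at 20 mV/ms beginning at exactly 50 ms
  n <- fs %/% 10
  v <- rep(-60, n)
  i0 <- fs * 0.05
  ramp <- seq(0, 50, by = 20 / 10)  # 20 mV/ms at 10 kHz = 2 mV/sample
  v[(i0 + 1):(i0 + length(ramp))] <- -60 + ramp
  ts <- timeseries(v, fs, units = "mV")
  pk <- (i0 + length(ramp) - 1) / fs
  on <- spike_onset(ts, pk)
  expect_equal(on$onset_s, i0 / fs, tolerance = 1.5 / fs)
  expect_equal(on$onset_mV, -60, tolerance = 0.5)
  # a 5 mV/ms rise never meets the criterion
  slow <- rep(-60, n)
  ramp2 <- seq(0, 50, by = 5 / 10)
  slow[(i0 + 1):(i0 + length(ramp2))] <- -60 + ramp2
  on2 <- spike_onset(timeseries(slow, fs, units = "mV"),
                     (i0 + length(ramp2) - 1) / fs)
  expect_true(is.na(on2$onset_s))
})

test_that("Gaussian spike onset matches the analytic derivative root", {
  fs <- 100000
  sigma <- 0.0005; A <- 70; tp <- 0.05
  tt <- (seq_len(fs %/% 10) - 1) / fs
  v <- -65 + A * exp(-(tt - tp)^2 / (2 * sigma^2))
  ts <- timeseries(v, fs, units = "mV")
  # dV/dt = -A (t-tp)/sigma^2 exp(...) = 10 mV/ms has its earliest
  # (sustained-run) root on the rising limb; solve numerically as the oracle
  f <- function(t) -A * (t - tp) / sigma^2 * exp(-(t - tp)^2 / (2 * sigma^2)) -
    10000
  lo <- tp - 6 * sigma; hi <- tp - sigma
  root <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  on <- spike_onset(ts, tp)
  expect_lt(abs(on$onset_s - root), 2 / fs)
})

test_that("half-width is exact for parametric spikes and FWHM for Gaussians", {
  for (hw_ms in c(0.5, 1.0, 2.0)) {
    v <- tri_spike_trace(0.5, rise_ms = 0.8 * hw_ms, fall_ms = 1.2 * hw_ms)
    sf <- spike_features(v)
    expect_equal(sf$half_width_ms, hw_ms, tolerance = 0.1 + 1e-9)
  }
  # Gaussian spike measured from baseline: FWHM = 2.355 sigma
  fs <- 100000
  sigma <- 0.0005
  tt <- (0:(fs %/% 10) - 1) / fs
  v <- -65 + 80 * exp(-(tt - 0.05)^2 / (2 * sigma^2))
  ts <- timeseries(v, fs, units = "mV")
  hw <- half_width(ts, list(onset_s = 0.048, onset_mV = -65),
                   list(peak_s = 0.05, peak_mV = 15))
  expect_equal(hw, 2.355 * sigma * 1000, tolerance = 1000 / fs + 0.002)
})

test_that("half-width is invariant to offset and time shift", {
  v <- tri_spike_trace(0.5)
  hw0 <- spike_features(v)$half_width_ms
  shifted <- timeseries(v$values + 17.3, v$sampling_rate_hz,
                        start_time_s = 2.25, units = "mV")
  expect_equal(spike_features(shifted)$half_width_ms, hw0, tolerance = 1e-9)
})

test_that("mAHP averages usable sweeps and references pre-pulse rest", {
  cfg <- scenario_config(seed = 9)
  bp <- gen_patch_sweeps(cfg, "brief_pulse")
  m <- mAHP_amplitude(bp$sweeps)
  expect_equal(m$mAHP_mV, bp$truth$mAHP_mV, tolerance = 0.5)
  expect_identical(m$n_used, 15L)
  expect_false(m$flagged)
  expect_warning(m5 <- mAHP_amplitude(bp$sweeps[1:5]), "usable sweeps")
  expect_equal(m5$mAHP_mV, bp$truth$mAHP_mV, tolerance = 0.5)
})

test_that("inter-spike AHP uses the last five intervals, with fallback", {
  cfg <- scenario_config(seed = 10)
  ps <- gen_patch_sweeps(cfg, "step")
  counts <- vapply(ps$sweeps, function(sw)
    length(detect_spikes(sw$response)$times_s), integer(1))
  best <- ps$sweeps[[which.max(counts)]]
  ia <- interspike_ahp(best)
  expect_equal(ia$interspike_ahp_mV, ps$truth$interspike_ahp_mV,
               tolerance = 0.5)
  expect_identical(ia$n_intervals, 5L)
  # a 4-spike sweep: only 3 intervals, warn but compute
  cmd4 <- timeseries(c(rep(0, 1000), rep(200, 10000), rep(0, 1000)), 10000,
                     units = "pA")
  four <- patch_sweep(cmd4, tri_spike_trace(c(0.3, 0.5, 0.7, 0.9),
                                            total_s = 1.2), "step")
  expect_warning(ia4 <- interspike_ahp(four), "using all")
  expect_identical(ia4$n_intervals, 3L)
})

test_that("rheobase picks the first firing step; censoring is explicit", {
  sr <- data.frame(current_pA = c(10, 60, 110, 160),
                   spike_count = c(0, 0, 3, 8))
  expect_equal(rheobase(sr)$rheobase_pA, 110)
  expect_equal(rheobase(data.frame(current_pA = 10, spike_count = 2))$rheobase_pA,
               10)
  cens <- rheobase(data.frame(current_pA = c(10, 60), spike_count = c(0, 0)))
  expect_true(cens$censored)
  expect_true(is.na(cens$rheobase_pA))
})

test_that("depolarizing block needs repetitive firing then >= 100 ms silence", {
  fs <- 10000
  mk <- function(spikes_s, I) {
    cmd <- timeseries(c(rep(0, fs %/% 10), rep(I, fs), rep(0, fs %/% 10)),
                      fs, units = "pA")
    patch_sweep(cmd, tri_spike_trace(spikes_s, total_s = 1.2), "step")
  }
  # 5 rapid spikes in 300 ms then silence: block
  blocked <- mk(0.15 + (0:4) * 0.05, 510)
  # 90 ms pause mid-train: not block (and firing continues to step end)
  paused <- mk(c(0.15 + (0:4) * 0.05, 0.44 + (0:11) * 0.055), 460)
  tonic <- mk(seq(0.15, 1.05, by = 0.04), 410)
  res <- depolarizing_block(list(tonic, paused, blocked))
  expect_equal(res$block_pA, 510)
  expect_false(res$censored)
  res2 <- depolarizing_block(list(tonic, paused))
  expect_true(res2$censored)
})

test_that("max firing rate comes from inter-spike span; ties to lower current", {
  sr <- data.frame(current_pA = c(110, 160, 210, 260),
                   rate_hz = c(5, 20, 12, 20))
  mf <- max_firing(sr)
  expect_equal(mf$max_rate_hz, 20)
  expect_equal(mf$at_current_pA, 160)
  expect_error(max_firing(data.frame(current_pA = 1, rate_hz = NA_real_)),
               "no step")
})

test_that("input resistance recovers R and is order-invariant", {
  cfg <- scenario_config(seed = 11)
  vc <- gen_patch_sweeps(cfg, "vc_steps")
  ir <- input_resistance(vc$sweeps)
  expect_equal(ir$input_resistance_MOhm, 100, tolerance = 5)
  expect_gt(ir$r_squared, 0.99)
  ir2 <- input_resistance(rev(vc$sweeps))
  expect_equal(ir2$input_resistance_MOhm, ir$input_resistance_MOhm,
               tolerance = 1e-9)
  expect_error(input_resistance(vc$sweeps[1:2]), "at least 3")
})

test_that("holding-current change recovers injected drug effects", {
  cfg <- scenario_config(seed = 13)
  hc <- gen_holding_current(cfg, delta_pA = -37)
  d <- holding_current_change(hc$trace, hc$truth$drug_onset_s)
  expect_equal(d$delta_pA, -37, tolerance = 3)
  # plateau arithmetic: baseline -50, plateau -152 -> delta -102
  flat <- timeseries(c(rep(-50, 3000), rep(-152, 3000)), 100, units = "pA")
  d2 <- holding_current_change(flat, 30)
  expect_equal(d2$delta_pA, -102, tolerance = 0.5)
  expect_error(holding_current_change(flat, 100), "outside")
})

test_that("ramp threshold reads the first spike's onset voltage", {
  cfg <- scenario_config(seed = 14)
  rp <- gen_patch_sweeps(cfg, "ramp")
  rt <- ramp_threshold(rp$sweeps[[1]])
  expect_equal(rt$threshold_mV, rp$truth$threshold_mV, tolerance = 1)
  # subthreshold ramp errors
  cfg2 <- scenario_config(seed = 14, cell = list(threshold_mV = 100))
  rp2 <- gen_patch_sweeps(cfg2, "ramp")
  expect_error(ramp_threshold(rp2$sweeps[[1]]), "no spike")
})

test_that("spontaneous rate is count over window, offset-invariant", {
  v <- tri_spike_trace(seq(0.25, 5.75, by = 0.5), total_s = 6)
  expect_equal(spontaneous_rate(v), 2.0)
  shifted <- timeseries(v$values + 5, v$sampling_rate_hz, units = "mV")
  expect_equal(spontaneous_rate(shifted), 2.0)
  quiet <- timeseries(rep(-60, 60000), 10000, units = "mV")
  expect_equal(spontaneous_rate(quiet), 0)
})

test_that("C-bouton-style parameter shifts give sign-correct feature changes", {
  for (seed in c(2, 5, 8)) {
    off_cfg <- scenario_config(seed = seed)
    on_cfg <- scenario_config(
      seed = seed,
      cell = list(spike = list(half_width_ms = 0.9,
                               interspike_ahp_mV = 10),
                  fI = list(block_pA = 610)))
    feats <- lapply(list(off = off_cfg, on = on_cfg), function(cf) {
      ps <- gen_patch_sweeps(cf, "step")
      ex <- excitability_summary(ps$sweeps)
      best <- ps$sweeps[[which.max(ex$fI_curve$spike_count)]]
      list(block = ex$block_pA, rate = ex$max_rate_hz,
           hw = median(spike_features(best$response)$half_width_ms,
                       na.rm = TRUE),
           ahp = suppressWarnings(interspike_ahp(best)$interspike_ahp_mV))
    })
    expect_lt(feats$on$hw, feats$off$hw)       # narrower spikes
    expect_gt(feats$on$ahp, feats$off$ahp)     # deeper inter-spike AHP
    expect_gt(feats$on$block, feats$off$block) # higher block current
    expect_gt(feats$on$rate, feats$off$rate)   # higher max firing
  }
})
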