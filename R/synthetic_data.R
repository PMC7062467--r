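#' Scenario configuration for the synthetic generators
#'
#' Defaults describe the recording conditions the analysis chain was built
#' for: ventral-root bursting at ~0.23 Hz with ~2 s bursts, GCaMP imaging at
#' 5 Hz with transients phase-locked to the locomotor cycle in a stated
#' fraction of cells, and 10 kHz current-clamp sweeps with parametric spikes.
#' Every generated quantity is recorded as ground truth for recovery tests.
#'
#' @param seed Integer RNG seed; generators are pure functions of
#'   (config, seed).
#' @param duration_s Recording length for the ventral-root trace, seconds.
#' @param vr,ca,cell Named lists overriding the modality defaults (see the
#'   function body for fields and values).
#' @param epochs Optional list of lists with `name`, `start_s`, `end_s`,
#'   `amplitude_multiplier`, `rate_multiplier`, `duration_multiplier`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, duration_s = 600, vr = list(),
                            ca = list(), cell = list(), epochs = NULL) {
  vr_def <- list(burst_rate_hz = 0.23, burst_duration_s = 2.0,
                 carrier_noise_sd = 1.0, burst_gain = 4.0, baseline_gain = 1.0,
                 sampling_rate_hz = 2000, jitter_shape = 10,
                 burst_duration_cv = 0.15, edge_s = 0.05)
  ca_def <- list(n_cells = 10L, coupled_fraction = 0.65, kappa = 3,
                 preferred_phase_rad = NULL, transients_per_cycle_prob = 0.8,
                 kernel_rise_s = 0.2, kernel_decay_s = 1.5,
                 amplitude_dff_pct = c(30, 100), noise_sd_pct = 5,
                 bleach_tau_s = Inf, frame_rate_hz = 5, f0_au = 100,
                 duration_s = 300)
  cell_def <- list(rest_mV = -60, threshold_mV = -45, R_MOhm = 100,
                   sampling_rate_hz = 10000, noise_sd_mV = 0.15,
                   spike = list(amplitude_mV = 60, half_width_ms = 1.0,
                                ahp_mV = 5, interspike_ahp_mV = 8),
                   fI = list(gain_hz_per_pA = 0.08, rheobase_pA = 110,
                             block_pA = 510, base_rate_hz = 5),
                   step = list(start_pA = 10, increment_pA = 50,
                               duration_s = 1, n_steps = 17L))
  merge_cfg <- function(def, user) {
    for (k in names(user)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(user[[k]]))
        merge_cfg(def[[k]], user[[k]]) else user[[k]]
    }
    def
  }
  structure(list(seed = as.integer(seed), duration_s = duration_s,
                 vr = merge_cfg(vr_def, vr), ca = merge_cfg(ca_def, ca),
                 cell = merge_cfg(cell_def, cell), epochs = epochs),
            class = "scenario_config")
}

epoch_multiplier <- function(epochs, t, field) {
  if (is.null(epochs)) return(1)
  for (ep in epochs) {
    if (t >= ep$start_s && t < ep$end_s && !is.null(ep[[field]]))
      return(ep[[field]])
  }
  1
}

#' Generate a synthetic ventral-root recording
#'
#' Broadband zero-mean noise whose envelope is
#' `baseline_gain + burst_gain * (smoothed burst train)`. Inter-onset
#' intervals are Gamma-distributed (shape `jitter_shape`) around
#' `1 / burst_rate_hz`; epoch multipliers scale the burst gain, rate and
#' duration from the onset's epoch.
#'
#' @param cfg A [scenario_config()].
#' @return List `raw` ([timeseries()], a.u.) and `truth` (list with the true
#'   burst table and the epoch definition).
#' @export
gen_ventral_root <- function(cfg) {
  set.seed(cfg$seed)
  vr <- cfg$vr
  fs <- vr$sampling_rate_hz
  n <- round(cfg$duration_s * fs)
  onsets <- numeric(0); durs <- numeric(0); gains <- numeric(0)
  t <- stats::rgamma(1, shape = vr$jitter_shape,
                     rate = vr$jitter_shape * vr$burst_rate_hz) / 2
  while (t < cfg$duration_s) {
    rate <- vr$burst_rate_hz * epoch_multiplier(cfg$epochs, t, "rate_multiplier")
    dur <- vr$burst_duration_s *
      epoch_multiplier(cfg$epochs, t, "duration_multiplier")
    # cycle-to-cycle duration variability (locomotor bursts are not clocked)
    if (vr$burst_duration_cv > 0) {
      sh <- 1 / vr$burst_duration_cv^2
      dur <- dur * stats::rgamma(1, shape = sh, rate = sh)
    }
    gain <- vr$burst_gain *
      epoch_multiplier(cfg$epochs, t, "amplitude_multiplier")
    if (t + dur < cfg$duration_s) {
      onsets <- c(onsets, t); durs <- c(durs, dur); gains <- c(gains, gain)
    }
    ioi <- stats::rgamma(1, shape = vr$jitter_shape,
                         rate = vr$jitter_shape * rate)
    # keep >= 1 s of quiescence between bursts so distinct locomotor cycles
    # stay resolvable (gaps below the detector's default merge window would
    # not be biologically meaningful at these rhythm frequencies)
    t <- t + max(ioi, dur + 1.0)
  }
  env <- numeric(n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L
    i1 <- min(round((onsets[i] + durs[i]) * fs), n)
    env[i0:i1] <- gains[i] / vr$burst_gain  # relative gain; scaled below
  }
  # soften edges with a short moving average so onsets are not step artifacts
  ke <- max(1L, round(vr$edge_s * fs))
  if (ke > 1L)
    env <- stats::filter(env, rep(1 / ke, ke), sides = 2)
  env[is.na(env)] <- 0
  sigma <- vr$baseline_gain + vr$burst_gain * env
  raw <- stats::rnorm(n, 0, vr$carrier_noise_sd) * sigma
  truth_bursts <- data.frame(onset_s = onsets, offset_s = onsets + durs,
                             duration_s = durs,
                             amplitude = gains * sqrt(2 / pi) *
                               vr$carrier_noise_sd,
                             cycle_index = seq_along(onsets))
  list(raw = timeseries(raw, fs, 0, units = "a.u.", channel_id = "vr"),
       truth = list(bursts = truth_bursts, epochs = cfg$epochs,
                    burst_gains = gains))
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` gives the circular uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2L] > 0 || log(c0 / u[2L]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3L] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Generate synthetic GCaMP ROI traces phase-locked to locomotor cycles
#'
#' Coupled cells emit at most one transient per cycle (probability
#' `transients_per_cycle_prob`) at a von Mises phase around their preferred
#' phase; uncoupled cells emit a rate-matched Poisson stream. Events are
#' convolved with a rise/decay kernel, scaled to the configured dF/F0
#' amplitude on an `f0_au` baseline, multiplied by an exponential bleach
#' decay, and sampled at `frame_rate_hz` with additive Gaussian noise.
#'
#' @param cfg A [scenario_config()].
#' @param truth_bursts Burst table whose onsets define the cycles (>= 2).
#' @return List `traces` (list of [timeseries()], names = ROI ids) and
#'   `truth` (per-cell coupling flags, preferred phases, event times).
#' @export
gen_calcium_cells <- function(cfg, truth_bursts) {
  if (nrow(truth_bursts) < 2L) stop("need >= 2 true bursts to define cycles")
  set.seed(cfg$seed + 1L)
  ca <- cfg$ca
  onsets <- truth_bursts$onset_s
  span <- c(onsets[1L], onsets[length(onsets)])
  dur <- min(ca$duration_s, span[2L])
  n_cells <- ca$n_cells
  n_coup <- round(ca$coupled_fraction * n_cells)
  mu <- if (is.null(ca$preferred_phase_rad))
    stats::runif(n_cells, 0, 2 * pi) else rep_len(ca$preferred_phase_rad,
                                                  n_cells)
  fs <- ca$frame_rate_hz
  nf <- round(dur * fs)
  tt <- (seq_len(nf) - 1) / fs
  # kernel: (1 - exp(-t/rise)) * exp(-t/decay), normalized to unit peak
  ker_t <- seq(0, ca$kernel_decay_s * 6, by = 1 / fs)
  ker <- (1 - exp(-ker_t / ca$kernel_rise_s)) * exp(-ker_t / ca$kernel_decay_s)
  ker <- ker / max(ker)
  cyc_per_s <- (length(onsets) - 1) / diff(range(onsets))
  traces <- list(); truth <- list()
  for (cidx in seq_len(n_cells)) {
    coupled <- cidx <= n_coup
    if (coupled) {
      ev <- numeric(0)
      for (i in seq_len(length(onsets) - 1L)) {
        if (onsets[i] >= dur) break
        if (stats::runif(1) < ca$transients_per_cycle_prob) {
          th <- rvonmises(1L, mu[cidx], ca$kappa)
          ev <- c(ev, onsets[i] + th / (2 * pi) * (onsets[i + 1L] - onsets[i]))
        }
      }
    } else {
      n_ev <- stats::rpois(1, ca$transients_per_cycle_prob * cyc_per_s * dur)
      ev <- sort(stats::runif(n_ev, 0, dur))
    }
    ev <- ev[ev < dur - 1 / fs]
    amp <- stats::runif(length(ev), ca$amplitude_dff_pct[1L],
                        ca$amplitude_dff_pct[2L])
    f <- rep(0, nf)
    for (j in seq_along(ev)) {
      i0 <- floor(ev[j] * fs) + 1L
      seg <- i0:min(nf, i0 + length(ker) - 1L)
      f[seg] <- f[seg] + amp[j] / 100 * ca$f0_au * ker[seq_along(seg)]
    }
    f <- (ca$f0_au + f)
    if (is.finite(ca$bleach_tau_s)) f <- f * exp(-tt / ca$bleach_tau_s)
    f <- f + stats::rnorm(nf, 0, ca$noise_sd_pct / 100 * ca$f0_au)
    f <- pmax(f, 1e-3)  # intensities are physically non-negative
    roi <- sprintf("roi%03d", cidx)
    traces[[roi]] <- timeseries(f, fs, 0, units = "a.u.", channel_id = roi)
    truth[[roi]] <- list(coupled = coupled, preferred_phase_rad = mu[cidx],
                         event_times_s = ev, amplitudes_dff_pct = amp)
  }
  list(traces = traces, truth = truth)
}

# ---- patch-clamp sweep synthesis -------------------------------------------

# piecewise-linear spike core: rise over 0.8*hw, fall over 1.2*hw, so the
# width at half amplitude (with linear interpolation) is exactly hw
spike_core_shape <- function(fs, amp_mV, hw_ms) {
  up <- max(2L, round(0.8 * hw_ms / 1000 * fs))
  dn <- max(2L, round(1.2 * hw_ms / 1000 * fs))
  c(seq(0, amp_mV, length.out = up + 1L),
    seq(amp_mV, 0, length.out = dn + 1L)[-1L])
}

add_spike <- function(v, i_on, shape) {
  seg <- i_on:min(length(v), i_on + length(shape) - 1L)
  v[seg] <- v[seg] + shape[seq_along(seg)]
  v
}

# symmetric V-shaped trough of given depth centered mid-interval
add_trough <- function(v, i0, i1, depth_mV) {
  if (i1 - i0 < 4L) return(v)
  mid <- (i0 + i1) %/% 2L
  down <- seq(0, -depth_mV, length.out = mid - i0 + 1L)
  up <- seq(-depth_mV, 0, length.out = i1 - mid + 1L)[-1L]
  v[i0:i1] <- v[i0:i1] + c(down, up)
  v
}

#' Generate a family of synthetic patch-clamp sweeps
#'
#' Renders current-clamp step families, brief supramaximal pulses, ramps,
#' voltage-clamp step families and gap-free traces from a parametric cell
#' model: firing rate `base_rate + gain * (I - rheobase)` clipped at zero and
#' capped at the last pre-block step; above `block_pA` the cell fires an
#' initial burst then falls silent (>= 100 ms) — a phenomenological
#' depolarizing block. Spikes are piecewise-linear cores with exact
#' half-width, plus alpha-function mAHP / V-shaped inter-spike troughs, so
#' every feature is an exact function of the configuration.
#'
#' @param cfg A [scenario_config()].
#' @param protocol One of `"step"`, `"brief_pulse"`, `"ramp"`, `"vc_steps"`,
#'   `"gapfree"`.
#' @param n_sweeps Sweeps for the brief_pulse protocol (default 15).
#' @return List `sweeps` (list of [patch_sweep()]) and `truth`.
#' @export
gen_patch_sweeps <- function(cfg, protocol = c("step", "brief_pulse", "ramp",
                                               "vc_steps", "gapfree"),
                             n_sweeps = 15L) {
  protocol <- match.arg(protocol)
  set.seed(cfg$seed + 2L)
  cl <- cfg$cell
  fs <- cl$sampling_rate_hz
  switch(protocol,
         step = gen_steps(cl, fs),
         brief_pulse = gen_brief_pulses(cl, fs, n_sweeps),
         ramp = gen_ramp(cl, fs),
         vc_steps = gen_vc_steps(cl, fs),
         gapfree = gen_gapfree(cl, fs))
}

gen_steps <- function(cl, fs) {
  st <- cl$step
  pre <- round(0.1 * fs); dur <- round(st$duration_s * fs)
  post <- round(0.1 * fs)
  n <- pre + dur + post
  currents <- st$start_pA + st$increment_pA * (seq_len(st$n_steps) - 1L)
  shape <- spike_core_shape(fs, cl$spike$amplitude_mV, cl$spike$half_width_ms)
  fI <- cl$fI
  cap_I <- max(fI$rheobase_pA,
               max(c(currents[currents < fI$block_pA], fI$rheobase_pA)))
  sweeps <- list(); truth_spikes <- list()
  for (I in currents) {
    cmd <- c(rep(0, pre), rep(I, dur), rep(0, post))
    v <- rep(cl$rest_mV, n)
    spk <- numeric(0)
    if (I >= fI$rheobase_pA) {
      rate <- fI$base_rate_hz + fI$gain_hz_per_pA *
        (min(I, cap_I) - fI$rheobase_pA)
      blocked <- I >= fI$block_pA
      t0 <- 0.02
      if (blocked) {
        n_spk <- 3L
      } else {
        n_spk <- max(1L, floor((st$duration_s - 2 * t0) * rate) + 1L)
      }
      spk <- t0 + (seq_len(n_spk) - 1L) / rate
      spk <- spk[spk < st$duration_s - 0.005]
      # depolarized plateau at threshold during the step
      v[(pre + 1L):(pre + dur)] <- cl$threshold_mV
      idx <- pre + round(spk * fs) + 1L
      for (ii in idx) v <- add_spike(v, ii, shape)
      if (length(idx) > 1L) {
        for (j in seq_len(length(idx) - 1L)) {
          i0 <- idx[j] + length(shape); i1 <- idx[j + 1L] - 1L
          v <- add_trough(v, i0, i1, cl$spike$interspike_ahp_mV)
        }
      }
      spk_abs <- (idx - 1L) / fs  # onset times; peaks sit one rise later
    } else {
      # subthreshold RC charge toward I*R, capped below threshold
      tau <- 0.02
      tstep <- (seq_len(dur) - 1) / fs
      vss <- min(cl$rest_mV + I * cl$R_MOhm * 1e-3, cl$threshold_mV - 2)
      v[(pre + 1L):(pre + dur)] <-
        cl$rest_mV + (vss - cl$rest_mV) * (1 - exp(-tstep / tau))
    }
    v <- v + stats::rnorm(n, 0, cl$noise_sd_mV)
    cmd_ts <- timeseries(cmd, fs, 0, units = "pA", channel_id = "cmd")
    v_ts <- timeseries(v, fs, 0, units = "mV", channel_id = "vm")
    key <- sprintf("I%g", I)
    sweeps[[key]] <- patch_sweep(cmd_ts, v_ts, "step")
    truth_spikes[[key]] <- spk + 0.1  # absolute onset times within the sweep
  }
  rates <- vapply(truth_spikes, function(s)
    if (length(s) >= 2L) (length(s) - 1) / (s[length(s)] - s[1L])
    else NA_real_, numeric(1))
  truth <- list(
    currents_pA = currents,
    spike_times = truth_spikes,
    rheobase_pA = currents[currents >= cl$fI$rheobase_pA][1L],
    block_pA = if (any(currents >= cl$fI$block_pA))
      currents[currents >= cl$fI$block_pA][1L] else NA_real_,
    max_rate_hz = if (any(is.finite(rates))) max(rates, na.rm = TRUE)
      else NA_real_,
    half_width_ms = cl$spike$half_width_ms,
    interspike_ahp_mV = cl$spike$interspike_ahp_mV,
    threshold_mV = cl$threshold_mV)
  list(sweeps = sweeps, truth = truth)
}

gen_brief_pulses <- function(cl, fs, n_sweeps) {
  pre <- round(0.1 * fs)
  n <- round(0.5 * fs)
  pulse <- round(0.01 * fs)
  shape <- spike_core_shape(fs, cl$spike$amplitude_mV, cl$spike$half_width_ms)
  # mAHP: negative alpha function, unit peak at tau_a (on-grid)
  tau_a <- 0.02
  at <- seq(0, 0.2, by = 1 / fs)
  alpha <- (at / tau_a) * exp(1 - at / tau_a)
  sweeps <- vector("list", n_sweeps)
  for (s in seq_len(n_sweeps)) {
    cmd <- rep(0, n); cmd[(pre + 1L):(pre + pulse)] <- 2000
    v <- rep(cl$rest_mV, n)
    i_on <- pre + round(0.002 * fs)
    v <- add_spike(v, i_on, shape)
    i_a <- i_on + length(shape)
    seg <- i_a:min(n, i_a + length(alpha) - 1L)
    v[seg] <- v[seg] - cl$spike$ahp_mV * alpha[seq_along(seg)]
    v <- v + stats::rnorm(n, 0, cl$noise_sd_mV)
    sweeps[[s]] <- patch_sweep(
      timeseries(cmd, fs, 0, units = "pA", channel_id = "cmd"),
      timeseries(v, fs, 0, units = "mV", channel_id = "vm"), "brief_pulse")
  }
  list(sweeps = sweeps,
       truth = list(mAHP_mV = cl$spike$ahp_mV, v_rest_mV = cl$rest_mV,
                    half_width_ms = cl$spike$half_width_ms))
}

gen_ramp <- function(cl, fs) {
  pre <- round(0.1 * fs)
  dur <- round(1 * fs)
  n <- pre + dur + round(0.1 * fs)
  I_max <- 2.5 * cl$fI$rheobase_pA
  cmd <- c(rep(0, pre), seq(0, I_max, length.out = dur), rep(0, n - pre - dur))
  v <- cl$rest_mV + cmd * cl$R_MOhm * 1e-3
  v <- pmin(v, cl$threshold_mV)
  i_th <- which(v >= cl$threshold_mV)[1L]
  shape <- spike_core_shape(fs, cl$spike$amplitude_mV, cl$spike$half_width_ms)
  spk_onsets <- integer(0)
  if (!is.na(i_th)) {
    isi <- round(0.08 * fs)
    spk_onsets <- seq(i_th, min(n - length(shape), pre + dur), by = isi)
    for (ii in spk_onsets) v <- add_spike(v, ii, shape)
  }
  v <- v + stats::rnorm(n, 0, cl$noise_sd_mV)
  list(sweeps = list(patch_sweep(
         timeseries(cmd, fs, 0, units = "pA", channel_id = "cmd"),
         timeseries(v, fs, 0, units = "mV", channel_id = "vm"), "ramp")),
       truth = list(threshold_mV = cl$threshold_mV,
                    first_spike_onset_s = (spk_onsets[1L] - 1L) / fs))
}

gen_vc_steps <- function(cl, fs, noise_sd_pA = 2) {
  levels <- seq(-75, -52.5, by = 2.5)
  pre <- round(0.05 * fs); dur <- round(0.2 * fs)
  n <- pre + dur
  tau <- 0.005
  sweeps <- lapply(levels, function(V) {
    cmd <- c(rep(cl$rest_mV, pre), rep(V, dur))
    i_ss <- (V - cl$rest_mV) / cl$R_MOhm * 1000  # pA
    tstep <- (seq_len(dur) - 1) / fs
    resp <- c(rep(0, pre), i_ss * (1 - exp(-tstep / tau)))
    resp <- resp + stats::rnorm(n, 0, noise_sd_pA)
    patch_sweep(timeseries(cmd, fs, 0, units = "mV", channel_id = "cmd"),
          timeseries(resp, fs, 0, units = "pA", channel_id = "im"),
          "vc_steps")
  })
  list(sweeps = sweeps,
       truth = list(R_MOhm = cl$R_MOhm, levels_mV = levels))
}

gen_gapfree <- function(cl, fs, rate_hz = 2, duration_s = 10) {
  n <- round(duration_s * fs)
  v <- rep(cl$rest_mV, n)
  n_spk <- stats::rpois(1, rate_hz * duration_s)
  onsets <- sort(stats::runif(n_spk, 0.05, duration_s - 0.05))
  # enforce a biological minimum ISI of 10 ms
  if (length(onsets) > 1L) onsets <- onsets[c(TRUE, diff(onsets) > 0.01)]
  shape <- spike_core_shape(fs, cl$spike$amplitude_mV, cl$spike$half_width_ms)
  for (o in onsets) v <- add_spike(v, round(o * fs) + 1L, shape)
  v <- v + stats::rnorm(n, 0, cl$noise_sd_mV)
  cmd <- timeseries(rep(0, n), fs, 0, units = "pA", channel_id = "cmd")
  list(sweeps = list(patch_sweep(cmd,
         timeseries(v, fs, 0, units = "mV", channel_id = "vm"), "gapfree")),
       truth = list(spike_times_s = onsets, rate_hz = length(onsets) /
                      duration_s))
}

#' Generate a holding-current trace with a drug-induced shift
#'
#' @param cfg A [scenario_config()].
#' @param delta_pA Drug-induced change (negative = inward).
#' @param drug_onset_s Perfusion onset, seconds.
#' @param duration_s Total length, seconds.
#' @param baseline_pA Pre-drug holding current.
#' @param noise_sd_pA Additive noise SD.
#' @param fs Sampling rate, Hz.
#' @return List `trace` ([timeseries()], pA) and `truth`.
#' @export
gen_holding_current <- function(cfg, delta_pA = -37, drug_onset_s = 60,
                                duration_s = 180, baseline_pA = -50,
                                noise_sd_pA = 4, fs = 100) {
  set.seed(cfg$seed + 3L)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  drift <- delta_pA / (1 + exp(-(t - drug_onset_s - 15) / 5))
  x <- baseline_pA + drift + stats::rnorm(n, 0, noise_sd_pA)
  list(trace = timeseries(x, fs, 0, units = "pA", channel_id = "ihold"),
       truth = list(delta_pA = delta_pA, baseline_pA = baseline_pA,
                    drug_onset_s = drug_onset_s))
}

#' Generate a full multimodal scenario and optionally write it to disk
#'
#' One call produces the ventral-root trace, the calcium ROI set locked to
#' its true bursts, and a patch-clamp step family, with all ground truth;
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Optional directory; when given, traces are written as HDF5
#'   (`vr.h5`, `calcium.h5`), ground-truth tables as CSV, and the resolved
#'   configuration as YAML.
#' @return List `vr`, `calcium`, `patch`, `config`, and (if written) `paths`.
#' @export
gen_full_scenario <- function(cfg, out_dir = NULL) {
  vr <- gen_ventral_root(cfg)
  ca <- gen_calcium_cells(cfg, vr$truth$bursts)
  pc <- gen_patch_sweeps(cfg, "step")
  out <- list(vr = vr, calcium = ca, patch = pc, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p_vr <- file.path(out_dir, "vr.h5")
    if (file.exists(p_vr)) file.remove(p_vr)
    write_timeseries(vr$raw, p_vr)
    p_ca <- file.path(out_dir, "calcium.h5")
    if (file.exists(p_ca)) file.remove(p_ca)
    for (tr in ca$traces) write_timeseries(tr, p_ca)
    write_table(vr$truth$bursts, file.path(out_dir, "true_bursts.csv"))
    truth_cells <- do.call(rbind, lapply(names(ca$truth), function(r)
      data.frame(roi_id = r, coupled = ca$truth[[r]]$coupled,
                 preferred_phase_rad = ca$truth[[r]]$preferred_phase_rad,
                 n_events = length(ca$truth[[r]]$event_times_s))))
    write_table(truth_cells, file.path(out_dir, "true_cells.csv"))
    cfg_plain <- unclass(cfg)
    cfg_plain$ca$bleach_tau_s <-
      if (is.finite(cfg$ca$bleach_tau_s)) cfg$ca$bleach_tau_s else "Inf"
    yaml::write_yaml(cfg_plain, file.path(out_dir, "scenario.yaml"))
    out$paths <- list(vr = p_vr, calcium = p_ca,
                      true_bursts = file.path(out_dir, "true_bursts.csv"),
                      true_cells = file.path(out_dir, "true_cells.csv"),
                      config = file.path(out_dir, "scenario.yaml"))
  }
  out
}
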