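#' A stimulus/response sweep pair
#'
#' @param command Command [timeseries()] (pA in current clamp, mV in voltage
#'   clamp).
#' @param response Response [timeseries()] (mV or pA); must share rate and
#'   span with the command.
#' @param protocol_tag One of `gapfree`, `step`, `brief_pulse`, `ramp`,
#'   `vc_steps`.
#' @return An object of class `sweep`.
#' @export
patch_sweep <- function(command, response,
                        protocol_tag = c("gapfree", "step", "brief_pulse",
                                         "ramp", "vc_steps")) {
  protocol_tag <- match.arg(protocol_tag)
  stopifnot(inherits(command, "timeseries"), inherits(response, "timeseries"))
  if (length(command$values) != length(response$values) ||
      command$sampling_rate_hz != response$sampling_rate_hz)
    stop("command and response must share rate and span")
  structure(list(command = command, response = response,
                 protocol_tag = protocol_tag), class = "sweep")
}

#' Detect action-potential peaks
#'
#' A spike is a local maximum above `peak_threshold_mV`, with at least
#' `refractory_ms` between successive peaks (larger peak wins within the
#' refractory window).
#'
#' @param v Membrane-potential [timeseries()] (mV).
#' @param peak_threshold_mV Peak threshold (default -10 mV).
#' @param refractory_ms Minimum peak separation (default 1 ms).
#' @return An [event_series()] of peak times.
#' @export
detect_spikes <- function(v, peak_threshold_mV = -10, refractory_ms = 1) {
  x <- v$values
  n <- length(x)
  if (n < 3L) return(event_series(numeric(0)))
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] &
                      x[2:(n - 1)] >= x[3:n], FALSE) & x > peak_threshold_mV
  idx <- which(is_peak)
  if (!length(idx)) return(event_series(numeric(0)))
  min_gap <- refractory_ms / 1000 * v$sampling_rate_hz
  keep <- idx[1L]
  for (i in idx[-1L]) {
    last <- keep[length(keep)]
    if (i - last >= min_gap) keep <- c(keep, i)
    else if (x[i] > x[last]) keep[length(keep)] <- i
  }
  t <- ts_times(v)
  event_series(t[keep])
}

#' Spike onset by the dV/dt criterion
#'
#' dV/dt is computed by central differences on the raw trace. Walking back
#' from the peak, the onset is the earliest sample of the final contiguous run
#' in which dV/dt >= `dvdt_mV_per_ms`. Spikes whose upstroke never reaches the
#' criterion are flagged (`NA` onset).
#'
#' @param v Membrane-potential [timeseries()] (mV).
#' @param peak_s Peak time of a detected spike (s).
#' @param dvdt_mV_per_ms Slope criterion (default 10 mV/ms).
#' @return List `onset_s`, `onset_mV` (both `NA` if the criterion is unmet).
#' @export
spike_onset <- function(v, peak_s, dvdt_mV_per_ms = 10) {
  x <- v$values
  n <- length(x)
  fs <- v$sampling_rate_hz
  pk <- round((peak_s - v$start_time_s) * fs) + 1L
  pk <- min(max(pk, 2L), n - 1L)
  # central-difference slope in mV/ms
  slope <- function(i) (x[i + 1L] - x[i - 1L]) * fs / 2 / 1000
  i <- pk
  found <- FALSE
  while (i >= 2L) {
    if (slope(i) >= dvdt_mV_per_ms) { found <- TRUE; break }
    i <- i - 1L
    if (pk - i > 0.05 * fs) break  # search at most 50 ms before the peak
  }
  if (!found) return(list(onset_s = NA_real_, onset_mV = NA_real_))
  while (i > 2L && slope(i - 1L) >= dvdt_mV_per_ms) i <- i - 1L
  t <- ts_times(v)
  list(onset_s = t[i], onset_mV = x[i])
}

#' Spike half-width
#'
#' Amplitude is `peak_mV - onset_mV`; the half-width is the time between the
#' rising and falling crossings of `onset_mV + amplitude / 2`, with linear
#' interpolation between samples.
#'
#' @param v Membrane-potential [timeseries()] (mV).
#' @param onset List/row with `onset_s`, `onset_mV` (from [spike_onset()]).
#' @param peak List/row with `peak_s`, `peak_mV`.
#' @return Half-width in ms, or `NA` (flagged) if the falling crossing is
#'   missing (truncated sweep).
#' @export
half_width <- function(v, onset, peak) {
  if (!is.finite(onset$onset_s)) return(NA_real_)
  stopifnot(onset$onset_s < peak$peak_s)
  half <- onset$onset_mV + (peak$peak_mV - onset$onset_mV) / 2
  fs <- v$sampling_rate_hz
  x <- v$values
  t <- ts_times(v)
  i_on <- round((onset$onset_s - v$start_time_s) * fs) + 1L
  i_pk <- round((peak$peak_s - v$start_time_s) * fs) + 1L
  cross_up <- NA_real_
  for (i in i_on:(i_pk - 1L)) {
    if (x[i] <= half && x[i + 1L] > half) {
      cross_up <- t[i] + (half - x[i]) / (x[i + 1L] - x[i]) / fs
      break
    }
  }
  if (!is.finite(cross_up) && x[i_on] > half) cross_up <- t[i_on]
  cross_dn <- NA_real_
  i <- i_pk
  while (i < length(x)) {
    if (x[i] >= half && x[i + 1L] < half) {
      cross_dn <- t[i] + (x[i] - half) / (x[i] - x[i + 1L]) / fs
      break
    }
    i <- i + 1L
  }
  if (!is.finite(cross_up) || !is.finite(cross_dn)) return(NA_real_)
  (cross_dn - cross_up) * 1000
}

#' Per-spike waveform features for a sweep
#'
#' Combines [detect_spikes()], [spike_onset()] and [half_width()].
#'
#' @param v Membrane-potential [timeseries()] (mV).
#' @param peak_threshold_mV Passed to [detect_spikes()].
#' @param dvdt_mV_per_ms Passed to [spike_onset()].
#' @return data.frame `peak_s`, `peak_mV`, `onset_s`, `onset_mV`,
#'   `half_width_ms` (rows with unmet dV/dt criterion have `NA` onset and
#'   half-width and are excluded from half-width statistics downstream).
#' @export
spike_features <- function(v, peak_threshold_mV = -10, dvdt_mV_per_ms = 10) {
  ev <- detect_spikes(v, peak_threshold_mV)
  fs <- v$sampling_rate_hz
  rows <- lapply(ev$times_s, function(pt) {
    pk_i <- round((pt - v$start_time_s) * fs) + 1L
    on <- spike_onset(v, pt, dvdt_mV_per_ms)
    hw <- if (is.finite(on$onset_s))
      half_width(v, on, list(peak_s = pt, peak_mV = v$values[pk_i]))
      else NA_real_
    data.frame(peak_s = pt, peak_mV = v$values[pk_i],
               onset_s = on$onset_s, onset_mV = on$onset_mV,
               half_width_ms = hw)
  })
  if (!length(rows))
    return(data.frame(peak_s = numeric(0), peak_mV = numeric(0),
                      onset_s = numeric(0), onset_mV = numeric(0),
                      half_width_ms = numeric(0)))
  do.call(rbind, rows)
}

#' mAHP amplitude from brief-pulse sweeps
#'
#' Sweeps with zero or multiple spikes are excluded; the remainder are
#' averaged (aligned on their common time base), and the mAHP is the
#' pre-pulse resting voltage minus the minimum in the 5-200 ms post-spike
#' window, reported positive for a hyperpolarization.
#'
#' @param sweeps List of [patch_sweep()] objects (brief_pulse protocol).
#' @param n_avg Number of sweeps to average (default 15).
#' @param window_ms Post-spike search window (default `c(5, 200)`).
#' @return List `mAHP_mV`, `v_rest_mV`, `n_used`, `flagged` (TRUE when no
#'   post-spike dip below rest exists).
#' @export
mAHP_amplitude <- function(sweeps, n_avg = 15L, window_ms = c(5, 200)) {
  usable <- Filter(function(sw)
    length(detect_spikes(sw$response)$times_s) == 1L, sweeps)
  if (!length(usable)) stop("no usable sweeps (need exactly one spike each)")
  if (length(usable) < n_avg)
    warning("only ", length(usable), " usable sweeps (< ", n_avg, ")")
  usable <- usable[seq_len(min(length(usable), n_avg))]
  vmat <- sapply(usable, function(sw) sw$response$values)
  avg <- rowMeans(vmat)
  ref <- usable[[1L]]$response
  avg_ts <- timeseries(avg, ref$sampling_rate_hz, ref$start_time_s,
                       units = "mV", channel_id = ref$channel_id)
  # pulse onset from the command trace of the first sweep
  cmd <- usable[[1L]]$command$values
  pulse_i <- which(abs(cmd - cmd[1L]) > 1e-9)[1L]
  fs <- ref$sampling_rate_hz
  if (is.na(pulse_i)) stop("command trace has no pulse")
  v_rest <- mean(avg[seq_len(pulse_i - 1L)])
  pk <- detect_spikes(avg_ts)$times_s[1L]
  i0 <- round((pk - ref$start_time_s + window_ms[1L] / 1000) * fs) + 1L
  i1 <- round((pk - ref$start_time_s + window_ms[2L] / 1000) * fs) + 1L
  i1 <- min(i1, length(avg))
  trough <- min(avg[i0:i1])
  m <- v_rest - trough
  list(mAHP_mV = m, v_rest_mV = v_rest, n_used = length(usable),
       flagged = m <= 0)
}

#' Inter-spike AHP from the maximum-rate step
#'
#' For each of the last `k_last` inter-spike intervals of the given sweep, the
#' AHP is the preceding spike's onset voltage minus the trough between the two
#' spikes; the mean over intervals is returned. The onset voltage reference
#' makes the measure robust to DC offset.
#'
#' @param sw The [patch_sweep()] with the highest spike count.
#' @param k_last Number of trailing intervals to use (default 5).
#' @return List `interspike_ahp_mV`, `n_intervals`.
#' @export
interspike_ahp <- function(sw, k_last = 5L) {
  v <- sw$response
  feats <- spike_features(v)
  ns <- nrow(feats)
  if (ns < 2L) stop("need at least 2 spikes for inter-spike AHP")
  n_int <- ns - 1L
  if (n_int < k_last)
    warning("only ", n_int, " inter-spike intervals available (< ", k_last,
            "); using all")
  use <- seq.int(max(1L, n_int - k_last + 1L), n_int)
  fs <- v$sampling_rate_hz
  x <- v$values
  ahp <- vapply(use, function(i) {
    i0 <- round((feats$peak_s[i] - v$start_time_s) * fs) + 1L
    i1 <- round((feats$peak_s[i + 1L] - v$start_time_s) * fs) + 1L
    trough <- min(x[i0:i1])
    feats$onset_mV[i] - trough
  }, numeric(1))
  list(interspike_ahp_mV = mean(ahp), n_intervals = length(use))
}

#' Rheobase from a step family's spike counts
#'
#' @param step_results data.frame with `current_pA`, `spike_count`, ordered
#'   (or orderable) by current.
#' @return List `rheobase_pA` (`NA` when censored), `censored`.
#' @export
rheobase <- function(step_results) {
  sr <- step_results[order(step_results$current_pA), , drop = FALSE]
  i <- which(sr$spike_count >= 1L)[1L]
  if (is.na(i)) return(list(rheobase_pA = NA_real_, censored = TRUE))
  list(rheobase_pA = sr$current_pA[i], censored = FALSE)
}

#' Depolarizing-block current from a step family
#'
#' The block current is the lowest-current step in which, after repetitive
#' firing is established (>= `min_spikes` spikes with inter-spike intervals
#' < 100 ms), a spike-free period of at least 100 ms occurs before step end.
#'
#' @param step_sweeps List of [patch_sweep()] objects (1 s steps), any order.
#' @param silent_ms Silent-period criterion (default 100 ms).
#' @param min_spikes Spikes required to establish repetitive firing
#'   (default 2).
#' @return List `block_pA` (`NA` when censored), `censored`.
#' @export
depolarizing_block <- function(step_sweeps, silent_ms = 100, min_spikes = 2L) {
  amp <- vapply(step_sweeps, step_current, numeric(1))
  for (sw in step_sweeps[order(amp)]) {
    st <- detect_spikes(sw$response)$times_s
    if (length(st) < min_spikes) next
    isi <- diff(st)
    rep_established <- which(isi < 0.1)
    if (length(rep_established) < min_spikes - 1L) next
    # step end: last time the command is away from holding
    cmd <- sw$command$values
    tc <- ts_times(sw$command)
    on_idx <- which(abs(cmd - cmd[1L]) > 1e-9)
    step_end <- if (length(on_idx)) tc[on_idx[length(on_idx)]] else max(tc)
    # silent period after >= min_spikes rapid spikes
    k0 <- rep_established[min_spikes - 1L] + 1L  # index of spike completing it
    gaps <- c(diff(st), step_end - st[length(st)])
    if (any(gaps[k0:length(gaps)] >= silent_ms / 1000))
      return(list(block_pA = step_current(sw), censored = FALSE))
  }
  list(block_pA = NA_real_, censored = TRUE)
}

step_current <- function(sw) {
  cmd <- sw$command$values
  dev <- cmd - cmd[1L]
  i <- which.max(abs(dev))
  cmd[i]
}

#' Maximum firing rate across a step family
#'
#' Rate per step is `(n_spikes - 1) / (last - first spike time)`; ties go to
#' the lower current.
#'
#' @param step_results data.frame with `current_pA`, `rate_hz` (or a list of
#'   sweeps, from which both are computed).
#' @return List `max_rate_hz`, `at_current_pA`.
#' @export
max_firing <- function(step_results) {
  if (!is.data.frame(step_results))
    step_results <- do.call(rbind, lapply(step_results, function(sw) {
      st <- detect_spikes(sw$response)$times_s
      data.frame(current_pA = step_current(sw),
                 rate_hz = if (length(st) >= 2L)
                   (length(st) - 1) / (st[length(st)] - st[1L]) else NA_real_)
    }))
  sr <- step_results[order(step_results$current_pA), , drop = FALSE]
  sr <- sr[is.finite(sr$rate_hz), , drop = FALSE]
  if (!nrow(sr)) stop("no step with >= 2 spikes; maximum rate undefined")
  i <- which.max(sr$rate_hz)  # which.max returns the first (lowest current)
  list(max_rate_hz = sr$rate_hz[i], at_current_pA = sr$current_pA[i])
}

#' Input resistance from a voltage-clamp step family
#'
#' Least-squares slope of command voltage over steady-state current (mean of
#' the last 20% of each step), in megaohms.
#'
#' @param vc_sweeps List of [patch_sweep()] objects (vc_steps protocol), >= 3
#'   levels.
#' @param steady_frac Final fraction of the step used as steady state.
#' @return List `input_resistance_MOhm`, `r_squared`; warns when r^2 < 0.9.
#' @export
input_resistance <- function(vc_sweeps, steady_frac = 0.2) {
  if (length(vc_sweeps) < 3L) stop("need at least 3 voltage levels")
  lv <- t(vapply(vc_sweeps, function(sw) {
    cmd <- sw$command$values
    on_idx <- which(abs(cmd - cmd[1L]) > 1e-9)
    if (!length(on_idx)) on_idx <- seq_along(cmd)
    n_on <- length(on_idx)
    ss <- on_idx[ceiling(n_on * (1 - steady_frac)):n_on]
    c(v = mean(cmd[ss]), i = mean(sw$response$values[ss]))
  }, numeric(2)))
  fit <- stats::lm(lv[, "v"] ~ lv[, "i"])
  r2 <- summary(fit)$r.squared
  # mV / pA = 1e-3 V / 1e-12 A = 1e9 Ohm = 1e3 MOhm
  R <- unname(stats::coef(fit)[2L]) * 1e3
  if (r2 < 0.9)
    warning(sprintf("I-V relation poorly linear (r^2 = %.3f)", r2))
  list(input_resistance_MOhm = R, r_squared = r2)
}

#' Drug-induced holding-current change
#'
#' Baseline is the median over the 30 s before `drug_onset_s`; the change is
#' the extremum of the 1 s median-filtered trace after onset minus baseline.
#' Inward currents are negative.
#'
#' @param i_trace Holding-current [timeseries()] (pA, voltage clamp).
#' @param drug_onset_s Perfusion onset (s), within the recording span.
#' @param direction `"auto"` (largest excursion), `"inward"`, or `"outward"`.
#' @param baseline_s Baseline window before onset (default 30 s).
#' @return List `delta_pA`, `baseline_pA`.
#' @export
holding_current_change <- function(i_trace, drug_onset_s,
                                   direction = c("auto", "inward", "outward"),
                                   baseline_s = 30) {
  direction <- match.arg(direction)
  t <- ts_times(i_trace)
  if (drug_onset_s <= t[1L] || drug_onset_s >= ts_end(i_trace))
    stop("drug_onset_s outside recording span")
  x <- i_trace$values
  base <- stats::median(x[t >= drug_onset_s - baseline_s & t < drug_onset_s])
  fs <- i_trace$sampling_rate_hz
  k <- max(3L, round(fs))  # ~1 s median filter
  if (k %% 2L == 0L) k <- k + 1L
  post <- x[t >= drug_onset_s]
  sm <- stats::runmed(post, k)
  delta <- switch(direction,
    inward  = min(sm) - base,
    outward = max(sm) - base,
    auto    = { d <- c(min(sm), max(sm)) - base; d[which.max(abs(d))] })
  list(delta_pA = delta, baseline_pA = base)
}

#' Action-potential voltage threshold from a current ramp
#'
#' Onset voltage (dV/dt criterion) of the first spike elicited by a 1 s
#' depolarizing ramp.
#'
#' @param ramp_sweep A [patch_sweep()] with `protocol_tag = "ramp"`.
#' @param dvdt_mV_per_ms Slope criterion (default 10 mV/ms).
#' @return List `threshold_mV`, `at_time_s`.
#' @export
ramp_threshold <- function(ramp_sweep, dvdt_mV_per_ms = 10) {
  v <- ramp_sweep$response
  st <- detect_spikes(v)$times_s
  if (!length(st)) stop("no spike on the ramp; threshold undefined")
  on <- spike_onset(v, st[1L], dvdt_mV_per_ms)
  if (!is.finite(on$onset_mV)) stop("dV/dt criterion unmet on first spike")
  list(threshold_mV = on$onset_mV, at_time_s = on$onset_s)
}

#' Spontaneous firing rate in a window
#'
#' @param v Gap-free membrane-potential [timeseries()].
#' @param window An [epoch()]; defaults to the whole recording.
#' @return Rate in Hz (spike count / window duration).
#' @export
spontaneous_rate <- function(v, window = NULL) {
  if (is.null(window)) window <- epoch("all", v$start_time_s, ts_end(v))
  st <- detect_spikes(v)$times_s
  n <- sum(st >= window$start_s & st < window$end_s)
  n / (window$end_s - window$start_s)
}

#' Excitability summary for one cell's step family
#'
#' @param step_sweeps List of [patch_sweep()] objects (step protocol).
#' @return List `rheobase_pA`, `rheobase_censored`, `block_pA`,
#'   `block_censored`, `max_rate_hz`, `at_current_pA`, `fI_curve`
#'   (data.frame `current_pA`, `rate_hz`, `spike_count`).
#' @export
excitability_summary <- function(step_sweeps) {
  fI <- do.call(rbind, lapply(step_sweeps, function(sw) {
    st <- detect_spikes(sw$response)$times_s
    data.frame(current_pA = step_current(sw), spike_count = length(st),
               rate_hz = if (length(st) >= 2L)
                 (length(st) - 1) / (st[length(st)] - st[1L]) else NA_real_)
  }))
  fI <- fI[order(fI$current_pA), , drop = FALSE]
  rh <- rheobase(fI)
  bl <- depolarizing_block(step_sweeps)
  mf <- if (any(is.finite(fI$rate_hz))) max_firing(fI)
        else list(max_rate_hz = NA_real_, at_current_pA = NA_real_)
  list(rheobase_pA = rh$rheobase_pA, rheobase_censored = rh$censored,
       block_pA = bl$block_pA, block_censored = bl$censored,
       max_rate_hz = mf$max_rate_hz, at_current_pA = mf$at_current_pA,
       fI_curve = fI)
}
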