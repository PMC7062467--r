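#' Baseline fluorescence (f0) from a quiet window
#'
#' Automates the manual "period of low-level activity": f0 is the minimum,
#' over all 10-consecutive-frame windows within the first 60 s, of the window
#' mean intensity.
#'
#' @param trace ROI intensity [timeseries()] (a.u., strictly positive),
#'   at least 60 s long.
#' @param window_len_frames Window length in frames (default 10).
#' @return List `f0`, `window_start_s`, `window_len_frames`.
#' @export
estimate_baseline <- function(trace, window_len_frames = 10L) {
  stopifnot(inherits(trace, "timeseries"))
  t <- ts_times(trace)
  first_min <- which(t - trace$start_time_s < 60)
  if (ts_end(trace) - trace$start_time_s < 60)
    stop("recording shorter than 60 s; cannot pick a baseline window")
  if (length(first_min) < window_len_frames)
    stop("fewer than ", window_len_frames, " frames in the first minute")
  x <- trace$values[first_min]
  k <- window_len_frames
  csum <- cumsum(c(0, x))
  means <- (csum[(k + 1):length(csum)] - csum[1:(length(csum) - k)]) / k
  i <- which.min(means)
  f0 <- means[i]
  if (f0 <= 0) stop("baseline f0 <= 0; intensities must be positive")
  list(f0 = f0, window_start_s = t[i], window_len_frames = k)
}

#' Convert a fluorescence trace to dF/F0 in percent
#'
#' `dff[i] = 100 * (f[i] - f0) / f0`.
#'
#' @param trace ROI intensity [timeseries()].
#' @param baseline Result of [estimate_baseline()] (or a list with `f0`).
#' @return A [timeseries()] in `%dF/F0` units.
#' @export
compute_dff <- function(trace, baseline) {
  stopifnot(inherits(trace, "timeseries"), baseline$f0 > 0)
  timeseries(100 * (trace$values - baseline$f0) / baseline$f0,
             trace$sampling_rate_hz, trace$start_time_s,
             units = "%dF/F0", channel_id = trace$channel_id)
}

#' Correct slow photobleaching by exponential-envelope division
#'
#' Fits a mono-exponential plus offset, `a * exp(-t / tau) + c`, to the
#' rolling 10th-percentile envelope of the trace (which tracks baseline, not
#' transients), divides the trace by the fitted decay renormalized to its
#' first-minute level, and returns the input unchanged when the fitted decay
#' is below 1% per minute or the fit fails.
#'
#' @param trace ROI intensity [timeseries()], at least 60 s long.
#' @param envelope_s Rolling-percentile window, seconds (default 30).
#' @return A [timeseries()], bleach-corrected (or unchanged).
#' @export
correct_bleach <- function(trace, envelope_s = 30) {
  stopifnot(inherits(trace, "timeseries"))
  t <- ts_times(trace) - trace$start_time_s
  if (max(t) < 60) stop("recording shorter than 60 s")
  x <- trace$values
  k <- max(3L, round(envelope_s * trace$sampling_rate_hz))
  n <- length(x)
  centers <- seq(1L, n, by = max(1L, k %/% 2L))
  env <- vapply(centers, function(i) {
    lo <- max(1L, i - k %/% 2L); hi <- min(n, i + k %/% 2L)
    stats::quantile(x[lo:hi], 0.10, names = FALSE)
  }, numeric(1))
  te <- t[centers]
  # cheap pre-screen: if the envelope's linear trend loses < 1% of its level
  # per minute there is nothing to correct and the trace passes through
  lin <- stats::lm.fit(cbind(1, te), env)$coefficients
  if (!is.finite(lin[2L]) ||
      -lin[2L] * 60 < 0.01 * max(env[te < 60])) return(trace)
  fit <- tryCatch(
    stats::nls(env ~ a * exp(-te / tau) + c0,
               start = list(a = max(env) - min(env) + 1e-9,
                            tau = max(t) / 2, c0 = min(env)),
               control = stats::nls.control(warnOnly = FALSE),
               lower = c(0, 1, 0), algorithm = "port"),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("bleach fit did not converge; returning trace unchanged")
    return(trace)
  }
  cf <- stats::coef(fit)
  decay_fun <- function(tt) cf[["a"]] * exp(-tt / cf[["tau"]]) + cf[["c0"]]
  # fractional loss of the fitted envelope over the first minute, per minute
  loss_per_min <- (decay_fun(0) - decay_fun(60)) / decay_fun(0)
  if (!is.finite(loss_per_min) || loss_per_min < 0.01) return(trace)
  g <- decay_fun(t)
  ref <- mean(g[t < 60])  # renormalize so the first-minute baseline is kept
  timeseries(x * ref / g, trace$sampling_rate_hz, trace$start_time_s,
             units = trace$units, channel_id = trace$channel_id)
}

#' Detect Ca2+ transients on a dF/F0 trace
#'
#' Onset is an upward threshold crossing sustained for at least
#' `sustain_frames` frames; the peak is the local maximum before the trace
#' falls back below half the threshold; events closer than
#' `min_separation_s` are merged, keeping the larger peak.
#'
#' @param dff A [timeseries()] in percent dF/F0.
#' @param threshold_pct Detection threshold, % dF/F0 (default 20, > 0).
#' @param min_separation_s Minimum event separation, seconds (default 1).
#' @param sustain_frames Frames the crossing must be sustained (default 2).
#' @param roi_id Label copied into the output.
#' @return data.frame `roi_id`, `onset_s`, `peak_s`, `amplitude_dff_pct`.
#' @export
detect_transients <- function(dff, threshold_pct = 20, min_separation_s = 1,
                              sustain_frames = 2L, roi_id = dff$channel_id) {
  stopifnot(inherits(dff, "timeseries"))
  if (!(threshold_pct > 0)) stop("threshold_pct must be > 0")
  raw <- dff$values
  n <- length(raw)
  # centered 3-frame mean: suppresses single-frame noise re-crossings of the
  # threshold during slow decays without biasing onset times
  x <- if (n >= 3L)
    stats::filter(raw, rep(1 / 3, 3), sides = 2) else raw
  x[is.na(x)] <- raw[is.na(x)]
  x <- as.numeric(x)
  t <- ts_times(dff)
  above <- x > threshold_pct
  d <- diff(c(FALSE, above))
  starts <- which(d == 1L)
  out <- list()
  for (s in starts) {
    run_end <- s
    while (run_end < n && above[run_end + 1L]) run_end <- run_end + 1L
    if (run_end - s + 1L < sustain_frames) next
    # prominence gate: a genuine transient rises at least threshold/2 above
    # its immediately preceding local level; noise re-crossings during the
    # decay of an earlier event do not
    pre_min <- min(x[max(1L, s - 3L):s])
    if (max(x[s:run_end]) - pre_min < threshold_pct / 2) next
    # peak: local max before the trace falls back below threshold/2
    e <- run_end
    while (e < n && x[e + 1L] > threshold_pct / 2) e <- e + 1L
    pk <- s - 1L + which.max(raw[s:e])
    out[[length(out) + 1L]] <- c(onset = t[s], peak = t[pk], amp = raw[pk])
  }
  # stacked events: a transient arriving before its predecessor has decayed
  # below threshold produces no crossing, only a local minimum followed by a
  # fresh rise of at least threshold/2 while still above threshold
  if (n >= 5L) {
    for (m in which(c(FALSE, diff(sign(diff(x))) > 0, FALSE))) {
      if (x[m] <= threshold_pct) next
      hi <- min(n, m + 5L)
      rise <- max(x[m:hi]) - x[m]
      if (rise < threshold_pct / 2) next
      s <- m + 1L
      e <- m - 1L + which.max(x[m:hi])
      pk <- m - 1L + which.max(raw[m:hi])
      out[[length(out) + 1L]] <- c(onset = t[s], peak = t[pk], amp = raw[pk])
    }
  }
  if (!length(out))
    return(data.frame(roi_id = character(0), onset_s = numeric(0),
                      peak_s = numeric(0), amplitude_dff_pct = numeric(0)))
  m <- do.call(rbind, out)
  ev <- data.frame(onset_s = m[, "onset"], peak_s = m[, "peak"],
                   amplitude_dff_pct = m[, "amp"])
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  # merge events closer than min_separation_s, keep the larger peak
  if (nrow(ev) > 1L && min_separation_s > 0) {
    keep <- rep(TRUE, nrow(ev))
    cur <- 1L
    for (i in 2:nrow(ev)) {
      if (ev$onset_s[i] - ev$onset_s[cur] < min_separation_s) {
        if (ev$amplitude_dff_pct[i] > ev$amplitude_dff_pct[cur]) {
          keep[cur] <- FALSE; cur <- i
        } else keep[i] <- FALSE
      } else cur <- i
    }
    ev <- ev[keep, , drop = FALSE]
  }
  data.frame(roi_id = roi_id, ev, row.names = NULL)
}

#' Full per-ROI fluorescence-to-transients chain
#'
#' Bleach correction, baseline estimation, dF/F0 conversion and transient
#' detection in one call.
#'
#' @param trace ROI intensity [timeseries()].
#' @param threshold_pct,min_separation_s Passed to [detect_transients()].
#' @param bleach_correct Apply [correct_bleach()] first (default TRUE).
#' @return List `dff` ([timeseries()]), `baseline`, `transients` (data.frame).
#' @export
roi_to_transients <- function(trace, threshold_pct = 20,
                              min_separation_s = 1, bleach_correct = TRUE) {
  if (bleach_correct) trace <- correct_bleach(trace)
  bl <- estimate_baseline(trace)
  dff <- compute_dff(trace, bl)
  list(dff = dff, baseline = bl,
       transients = detect_transients(dff, threshold_pct, min_separation_s))
}
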