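#' Ventral-root study: burst detection, time courses and epoch statistics
#'
#' Runs the full ventral-root chain per preparation (rectify/integrate,
#' detect bursts, per-burst metrics), bins each metric into 0.5-min
#' time-course bins normalized to the pre-control epoch, averages the final
#' `window_s` of each epoch, and compares epochs across preparations with the
#' normality-gated repeated-measures machinery.
#'
#' @param raw_list List of raw ventral-root [timeseries()], one per
#'   preparation.
#' @param epochs List of [epoch()] objects shared by all preparations; the
#'   first is treated as the pre-control/normalization epoch.
#' @param params A [burst_detection_params()].
#' @param tau_s Integrator time constant (default 0.05 s).
#' @param window_s Epoch comparison window (default 300 s).
#' @param bin_s Time-course bin (default 30 s).
#' @return List `per_prep` (burst tables and metrics), `timecourses`,
#'   `epoch_means` (long data.frame: prep, metric, epoch, value),
#'   `effects_pct` (per-metric mean percent change, epoch 2 vs epoch 1),
#'   `stats` (per-metric `test_report`).
#' @export
run_vr_study <- function(raw_list, epochs, params = burst_detection_params(),
                         tau_s = 0.05, window_s = 300, bin_s = 30) {
  check_epochs(epochs)
  per_prep <- list(); rows <- list(); tcs <- list()
  for (pi in seq_along(raw_list)) {
    raw <- raw_list[[pi]]
    integ <- rectify_integrate(raw, tau_s)
    bursts <- detect_bursts(integ, params)
    bm <- burst_metrics(bursts, raw)
    b <- bm$bursts
    series <- list(
      frequency = data.frame(
        time_s = b$onset_s[-1L],
        value = 1 / diff(b$onset_s)),
      duration = data.frame(time_s = b$onset_s, value = b$duration_s),
      amplitude = data.frame(time_s = b$onset_s, value = b$amplitude))
    tcs[[pi]] <- lapply(series, timecourse_normalize, pre_control = epochs[[1L]],
                        bin_s = bin_s)
    for (metric in names(series)) {
      em <- epoch_compare(series[[metric]], epochs, window_s)
      rows[[length(rows) + 1L]] <- data.frame(
        prep = pi, metric = metric, epoch = em$epoch, value = em$mean_value)
    }
    per_prep[[pi]] <- list(bursts = b, metrics = bm)
  }
  epoch_means <- do.call(rbind, rows)
  stats_out <- list(); effects <- list()
  ep_names <- vapply(epochs, `[[`, character(1), "name")
  for (metric in unique(epoch_means$metric)) {
    sub <- epoch_means[epoch_means$metric == metric, ]
    long <- data.frame(unit_id = sub$prep, condition = sub$epoch,
                       value = sub$value)
    stats_out[[metric]] <- if (length(ep_names) >= 3L)
      repeated_compare(long) else paired_compare(long)
    w <- long_to_wide(long)[, ep_names, drop = FALSE]
    effects[[metric]] <- 100 * mean(w[[2L]] / w[[1L]] - 1)
  }
  list(per_prep = per_prep, timecourses = tcs, epoch_means = epoch_means,
       effects_pct = unlist(effects), stats = stats_out)
}

#' Phase study: per-cell circular statistics and coupled fractions
#'
#' @param bursts Burst table defining locomotor cycles (>= 2 bursts).
#' @param transients data.frame with `roi_id` and `onset_s` (and optionally
#'   `peak_s`) — e.g. stacked outputs of [detect_transients()].
#' @param regions Optional named character vector mapping roi_id to region;
#'   unmapped cells get `"other"`.
#' @param alpha Significance level for the coupling call.
#' @param use `"onset"` (default) or `"peak"` event times.
#' @return List `cells` (stacked [cell_phase_result()] rows), `fractions`
#'   (per-region coupled fractions), `n_excluded` (out-of-cycle events).
#' @export
run_phase_study <- function(bursts, transients, regions = NULL, alpha = 0.05,
                            use = c("onset", "peak")) {
  use <- match.arg(use)
  cycles <- define_cycles(bursts)
  tcol <- if (use == "onset") "onset_s" else "peak_s"
  cells <- list(); n_excl <- 0L
  for (roi in unique(transients$roi_id)) {
    tt <- transients[[tcol]][transients$roi_id == roi]
    ph <- assign_phase(tt, cycles, roi_id = roi)
    n_excl <- n_excl + attr(ph, "n_excluded")
    region <- if (!is.null(regions) && roi %in% names(regions))
      regions[[roi]] else "other"
    cells[[roi]] <- cell_phase_result(ph, roi_id = roi, region = region,
                                      alpha = alpha)
  }
  cells <- if (length(cells)) do.call(rbind, c(cells, make.row.names = FALSE))
           else data.frame(roi_id = character(0), region = character(0),
                           n = integer(0), mean_direction_rad = numeric(0),
                           vector_length_r = numeric(0),
                           rayleigh_Z = numeric(0), p_value = numeric(0),
                           coupled = logical(0))
  fractions <- if (nrow(cells)) coupled_fraction(cells, alpha) else
    data.frame(region = character(0), n_cells = integer(0),
               n_coupled = integer(0), fraction = numeric(0))
  list(cells = cells, fractions = fractions, n_excluded = n_excl)
}

#' Patch study: per-cell features and paired condition comparisons
#'
#' @param cells Named list; each element is one cell with elements named by
#'   condition (e.g. `control`, `drug`), each holding a list of step
#'   [sweep()]s.
#' @return List `features` (long data.frame: cell, condition, rheobase_pA,
#'   block_pA, max_rate_hz, half_width_ms, interspike_ahp_mV) and `stats`
#'   (per-feature paired `test_report` across the two conditions).
#' @export
run_patch_study <- function(cells) {
  rows <- list()
  for (cn in names(cells)) {
    for (cond in names(cells[[cn]])) {
      sweeps <- cells[[cn]][[cond]]
      ex <- excitability_summary(sweeps)
      best <- which.max(ex$fI_curve$spike_count)
      best_sw <- sweeps[[order(vapply(sweeps, step_current, numeric(1)))[best]]]
      ia <- tryCatch(
        suppressWarnings(interspike_ahp(best_sw)$interspike_ahp_mV),
        error = function(e) NA_real_)
      sf <- spike_features(best_sw$response)
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cn, condition = cond,
        rheobase_pA = ex$rheobase_pA, block_pA = ex$block_pA,
        max_rate_hz = ex$max_rate_hz,
        half_width_ms = stats::median(sf$half_width_ms, na.rm = TRUE),
        interspike_ahp_mV = ia)
    }
  }
  features <- do.call(rbind, rows)
  stats_out <- list()
  conds <- unique(features$condition)
  if (length(conds) == 2L) {
    for (f in c("rheobase_pA", "block_pA", "max_rate_hz", "half_width_ms",
                "interspike_ahp_mV")) {
      a <- features[[f]][features$condition == conds[1L]]
      b <- features[[f]][features$condition == conds[2L]]
      ok <- is.finite(a) & is.finite(b)
      stats_out[[f]] <- tryCatch(paired_compare(a[ok], b[ok]),
                                 error = function(e) NULL)
    }
  }
  list(features = features, stats = stats_out)
}

#' Run manifest for provenance
#'
#' @param config Arbitrary configuration object (stored as-is).
#' @param inputs Character vector of input file paths (hashed by size+mtime
#'   when present).
#' @param outputs Character vector of output paths.
#' @param seed Seed used for any randomness.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = character(0),
                         outputs = character(0), seed = NA_integer_) {
  hash1 <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    sprintf("size=%d", file.info(p)$size)
  }
  structure(list(
    config = config,
    inputs = stats::setNames(vapply(inputs, hash1, character(1)),
                             inputs),
    outputs = outputs,
    seed = seed,
    package_version = as.character(utils::packageVersion("fictloc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' Write a manifest as JSON
#' @param manifest A [run_manifest()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       force = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
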