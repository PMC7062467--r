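#' Locomotor cycles from detected bursts
#'
#' Cycle i is the half-open interval between consecutive flexor-related burst
#' onsets, `[onset[i], onset[i+1])`; phase 0 is the burst onset.
#'
#' @param bursts A burst table (from [detect_bursts()]) or numeric onset
#'   vector; at least 2 onsets, strictly increasing.
#' @return An object of class `locomotor_cycles` with field `onset_s`.
#' @export
define_cycles <- function(bursts) {
  onsets <- if (is.data.frame(bursts)) bursts$onset_s else as.numeric(bursts)
  if (length(onsets) < 2L) stop("need at least 2 burst onsets to form cycles")
  if (any(diff(onsets) <= 0)) stop("burst onsets must be strictly increasing")
  structure(list(onset_s = onsets), class = "locomotor_cycles")
}

#' Map event times onto locomotor-cycle phase
#'
#' An event at time t in cycle `[o_i, o_{i+1})` gets phase
#' `2*pi*(t - o_i)/(o_{i+1} - o_i)`. Events before the first onset or at/after
#' the last onset are excluded and counted.
#'
#' @param events An [event_series()] or numeric vector of event times.
#' @param cycles A [define_cycles()] result.
#' @param roi_id Label attached to the samples.
#' @return data.frame `phase_rad` (in `[0, 2*pi)`), `cycle_index`, `roi_id`,
#'   with attribute `n_excluded`.
#' @export
assign_phase <- function(events, cycles, roi_id = "roi") {
  times <- if (inherits(events, "event_series")) events$times_s
           else as.numeric(events)
  o <- cycles$onset_s
  idx <- findInterval(times, o)
  inside <- idx >= 1L & times < o[length(o)]
  n_excluded <- sum(!inside)
  times <- times[inside]; idx <- idx[inside]
  phase <- 2 * pi * (times - o[idx]) / (o[idx + 1L] - o[idx])
  phase[phase >= 2 * pi] <- 0  # guard exact-boundary rounding
  out <- data.frame(phase_rad = phase, cycle_index = idx,
                    roi_id = rep_len(roi_id, length(phase)))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Circular mean direction and resultant vector length
#'
#' `r = |sum(exp(i*theta))| / n`; the direction is the argument of the sum,
#' mapped to `[0, 2*pi)`. With r numerically zero the direction is undefined
#' and returned as `NA`.
#'
#' @param phases Numeric vector of phases in radians, or a data.frame with a
#'   `phase_rad` column.
#' @return List `mean_direction_rad`, `vector_length_r`, `n`.
#' @export
circular_mean <- function(phases) {
  th <- if (is.data.frame(phases)) phases$phase_rad else as.numeric(phases)
  n <- length(th)
  if (n < 1L) stop("need at least one phase")
  C <- sum(cos(th)); S <- sum(sin(th))
  r <- sqrt(C^2 + S^2) / n
  dir <- if (r < 1e-12) NA_real_ else atan2(S, C) %% (2 * pi)
  list(mean_direction_rad = dir, vector_length_r = r, n = n)
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * r^2`; the p-value uses the standard series approximation
#' `p ~ exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)]`,
#' clipped to (0, 1]. Samples with fewer than `min_n` events are flagged
#' underpowered and given p = 1.
#'
#' @param phases Numeric vector of phases (radians) or data.frame with
#'   `phase_rad`.
#' @param min_n Minimum sample size for a meaningful test (default 4).
#' @return List `Z`, `p_value`, `n`, `r`, `underpowered`.
#' @export
rayleigh_test <- function(phases, min_n = 4L) {
  th <- if (is.data.frame(phases)) phases$phase_rad else as.numeric(phases)
  n <- length(th)
  cm <- circular_mean(th)
  r <- cm$vector_length_r
  Z <- n * r^2
  if (n < min_n)
    return(list(Z = Z, p_value = 1, n = n, r = r, underpowered = TRUE))
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                  (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(Z = Z, p_value = p, n = n, r = r, underpowered = FALSE)
}

#' Per-cell circular summary with coupling call
#'
#' Pools a cell's transient phases across all cycles into one circular sample
#' and applies [rayleigh_test()]; the cell is "coupled" when p < alpha.
#'
#' @param phases data.frame from [assign_phase()] (one cell), or numeric.
#' @param roi_id Cell label.
#' @param region Region label (e.g. `"L1-3"`, `"L4-6"`).
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame: `roi_id`, `region`, `n`,
#'   `mean_direction_rad`, `vector_length_r`, `rayleigh_Z`, `p_value`,
#'   `coupled`.
#' @export
cell_phase_result <- function(phases, roi_id = "roi", region = "other",
                              alpha = 0.05) {
  th <- if (is.data.frame(phases)) phases$phase_rad else as.numeric(phases)
  if (!length(th))
    return(data.frame(roi_id = roi_id, region = region, n = 0L,
                      mean_direction_rad = NA_real_, vector_length_r = NA_real_,
                      rayleigh_Z = NA_real_, p_value = 1, coupled = FALSE))
  cm <- circular_mean(th)
  rt <- rayleigh_test(th)
  data.frame(roi_id = roi_id, region = region, n = cm$n,
             mean_direction_rad = cm$mean_direction_rad,
             vector_length_r = cm$vector_length_r,
             rayleigh_Z = rt$Z, p_value = rt$p_value,
             coupled = rt$p_value < alpha)
}

#' Fraction of phase-coupled cells, per region
#'
#' No multiplicity correction is applied across cells (each cell's Rayleigh
#' test stands alone).
#'
#' @param results data.frame of stacked [cell_phase_result()] rows.
#' @param alpha Significance level (default 0.05).
#' @param group_by Column to group by (default `"region"`); `NULL` pools all.
#' @return data.frame `region`, `n_cells`, `n_coupled`, `fraction`.
#' @export
coupled_fraction <- function(results, alpha = 0.05, group_by = "region") {
  stopifnot(is.data.frame(results), "p_value" %in% names(results))
  grp <- if (is.null(group_by)) rep("all", nrow(results))
         else as.character(results[[group_by]])
  split_res <- split(results$p_value, grp)
  out <- lapply(names(split_res), function(g) {
    p <- split_res[[g]]
    data.frame(region = g, n_cells = length(p),
               n_coupled = sum(p < alpha),
               fraction = if (length(p)) sum(p < alpha) / length(p)
                          else NA_real_)
  })
  do.call(rbind, out)
}
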