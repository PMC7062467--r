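#' Uniformly sampled time series
#'
#' The universal carrier for all three recording modalities: extracellular
#' ventral-root voltage, ROI fluorescence, and intracellular voltage/current
#' sweeps. Sample `i` (1-based in R) sits at
#' `start_time_s + (i - 1) / sampling_rate_hz`.
#'
#' @param values Numeric vector of samples; all finite, length >= 1.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param start_time_s Time of the first sample, seconds.
#' @param units Signal units, e.g. `"mV"`, `"pA"`, `"a.u."`.
#' @param channel_id Channel label.
#' @return An object of class `timeseries`.
#' @export
timeseries <- function(values, sampling_rate_hz, start_time_s = 0,
                       units = "a.u.", channel_id = "ch0") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("timeseries needs at least one sample")
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be > 0")
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite samples at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  structure(
    list(values = values, sampling_rate_hz = as.numeric(sampling_rate_hz),
         start_time_s = as.numeric(start_time_s), units = as.character(units),
         channel_id = as.character(channel_id)),
    class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries '%s'> %d samples @ %g Hz, t0=%g s, units=%s\n",
              x$channel_id, length(x$values), x$sampling_rate_hz,
              x$start_time_s, x$units))
  invisible(x)
}

#' @export
length.timeseries <- function(x) length(x$values)

#' Sample times of a time series
#'
#' @param ts A [timeseries()].
#' @return Numeric vector of sample times in seconds.
#' @export
ts_times <- function(ts) {
  ts$start_time_s + (seq_along(ts$values) - 1) / ts$sampling_rate_hz
}

#' End of the recording span (time just past the last sample)
#' @param ts A [timeseries()].
#' @return Numeric scalar, seconds.
#' @export
ts_end <- function(ts) {
  ts$start_time_s + length(ts$values) / ts$sampling_rate_hz
}

#' Sorted event times with optional labels
#'
#' @param times_s Numeric vector, non-decreasing.
#' @param labels Optional character vector of per-event tags.
#' @return An object of class `event_series`.
#' @export
event_series <- function(times_s, labels = NULL) {
  times_s <- as.numeric(times_s)
  if (is.unsorted(times_s)) stop("event times must be non-decreasing")
  if (!is.null(labels) && length(labels) != length(times_s))
    stop("labels must match times in length")
  structure(list(times_s = times_s, labels = labels), class = "event_series")
}

#' Named analysis window
#'
#' Epochs (e.g. control / drug / washout) partition a recording; within one
#' recording they must not overlap.
#'
#' @param name Epoch label.
#' @param start_s,end_s Bounds in seconds, `end_s > start_s`.
#' @return An object of class `epoch`.
#' @export
epoch <- function(name, start_s, end_s) {
  if (!(end_s > start_s)) stop("epoch '", name, "': end_s must exceed start_s")
  structure(list(name = as.character(name), start_s = as.numeric(start_s),
                 end_s = as.numeric(end_s)), class = "epoch")
}

#' Validate a list of epochs for overlap
#' @param epochs List of [epoch()] objects.
#' @return The list, invisibly; errors on overlap.
#' @export
check_epochs <- function(epochs) {
  if (length(epochs) < 2L) return(invisible(epochs))
  o <- order(vapply(epochs, `[[`, numeric(1), "start_s"))
  epochs <- epochs[o]
  for (i in seq_len(length(epochs) - 1L)) {
    if (epochs[[i]]$end_s > epochs[[i + 1L]]$start_s + 1e-12)
      stop("epochs '", epochs[[i]]$name, "' and '", epochs[[i + 1L]]$name,
           "' overlap")
  }
  invisible(epochs)
}

#' Read a time series from CSV or HDF5
#'
#' CSV layout: metadata comment lines `# key=value` (must include
#' `sampling_rate_hz`; optional `start_time_s`, `units`, `channel_id`)
#' followed by a header `value` (or `time_s,value`) and one sample per row.
#' HDF5 layout: one group per channel holding a dataset `values` with
#' attributes `sampling_rate_hz`, `start_time_s`, `units`.
#'
#' @param path File path.
#' @param format `"csv"` or `"hdf5"`; default inferred from the extension.
#' @param channel Channel (HDF5 group) name; for CSV, recorded as the label.
#' @return A [timeseries()].
#' @export
read_timeseries <- function(path, format = c("auto", "csv", "hdf5"),
                            channel = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) "hdf5"
              else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_timeseries_csv(path, channel)
  else read_timeseries_h5(path, channel)
}

read_timeseries_csv <- function(path, channel) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", l)
    if (grepl("=", kv, fixed = TRUE)) {
      k <- trimws(sub("=.*$", "", kv)); v <- trimws(sub("^[^=]*=", "", kv))
      meta[[k]] <- v
    }
  }
  if (is.null(meta$sampling_rate_hz))
    stop("CSV is missing required metadata 'sampling_rate_hz': ", path)
  body <- lines[setdiff(seq_along(lines), meta_idx)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  col <- if ("value" %in% names(df)) "value" else names(df)[ncol(df)]
  vals <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("non-finite samples in ", path, " at data rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  timeseries(vals,
             sampling_rate_hz = as.numeric(meta$sampling_rate_hz),
             start_time_s = as.numeric(meta$start_time_s %||% 0),
             units = meta$units %||% "a.u.",
             channel_id = channel %||% (meta$channel_id %||% "ch0"))
}

read_timeseries_h5 <- function(path, channel) {
  if (is.null(channel)) {
    contents <- rhdf5::h5ls(path)
    groups <- contents$name[contents$group == "/" & contents$otype == "H5I_GROUP"]
    if (length(groups) != 1L)
      stop("HDF5 file has ", length(groups),
           " channel groups; pass `channel` explicitly")
    channel <- groups[[1L]]
  }
  grp <- paste0("/", channel)
  vals <- as.numeric(rhdf5::h5read(path, paste0(grp, "/values")))
  at <- rhdf5::h5readAttributes(path, grp)
  if (is.null(at$sampling_rate_hz))
    stop("HDF5 group ", grp, " is missing attribute 'sampling_rate_hz'")
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop("non-finite samples in ", path, ":", grp, " at indices: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  timeseries(vals, sampling_rate_hz = as.numeric(at$sampling_rate_hz),
             start_time_s = as.numeric(at$start_time_s %||% 0),
             units = as.character(at$units %||% "a.u."),
             channel_id = channel)
}

#' Write a time series to CSV or HDF5
#'
#' @param ts A [timeseries()].
#' @param path Destination; `.h5`/`.hdf5` extension selects HDF5.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) rhdf5::h5createFile(path)
    grp <- ts$channel_id
    h5 <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(h5), add = TRUE)
    if (!rhdf5::H5Lexists(h5, grp)) rhdf5::h5createGroup(h5, grp)
    rhdf5::h5write(ts$values, h5, paste0(grp, "/values"))
    gid <- rhdf5::H5Gopen(h5, grp)
    rhdf5::h5writeAttribute(ts$sampling_rate_hz, gid, "sampling_rate_hz")
    rhdf5::h5writeAttribute(ts$start_time_s, gid, "start_time_s")
    rhdf5::h5writeAttribute(ts$units, gid, "units")
    rhdf5::H5Gclose(gid)
  } else {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(
      sprintf("# sampling_rate_hz=%.17g", ts$sampling_rate_hz),
      sprintf("# start_time_s=%.17g", ts$start_time_s),
      sprintf("# units=%s", ts$units),
      sprintf("# channel_id=%s", ts$channel_id),
      "value",
      sprintf("%.17g", ts$values)), con)
  }
  invisible(path)
}

#' Extract a half-open time window [start_s, end_s) from a time series
#'
#' The returned `start_time_s` is the time of the first retained sample, so
#' slicing is idempotent: re-slicing with the same bounds is a no-op.
#'
#' @param ts A [timeseries()].
#' @param start_s,end_s Window bounds in seconds.
#' @return A [timeseries()] covering the overlap.
#' @export
slice_window <- function(ts, start_s, end_s) {
  if (!(end_s > start_s)) stop("end_s must exceed start_s")
  t <- ts_times(ts)
  keep <- which(t >= start_s - 1e-12 & t < end_s - 1e-12)
  if (!length(keep))
    stop(sprintf("window [%g, %g) does not overlap recording span [%g, %g)",
                 start_s, end_s, ts$start_time_s, ts_end(ts)))
  timeseries(ts$values[keep], ts$sampling_rate_hz, start_time_s = t[keep[1L]],
             units = ts$units, channel_id = ts$channel_id)
}

#' Write a tabular result to CSV with stable column order
#'
#' @param rows A data.frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (is.null(rows)) stop("rows must be non-null")
  rows <- as.data.frame(rows)
  ok <- tryCatch({
    utils::write.csv(format(rows, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
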