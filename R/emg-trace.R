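#' Stimulus-locked EMG trace
#'
#' Container for a single sampled surface-EMG sweep together with its
#' sampling rate and the sample index of the first pulse of the stimulus
#' train. The reflex detector ([detect_reflex()]) requires at least 60 ms of
#' pre-stimulus signal (the baseline window) and at least 150 ms at and
#' after the onset (covering the 90--150 ms response window).
#'
#' @param samples Numeric vector of EMG amplitudes in mV, uniformly sampled.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param onset_index 1-based sample index of stimulus-train onset.
#' @return An object of class `emg_trace`.
#' @examples
#' tr <- emg_trace(rnorm(600, sd = 0.01), sampling_rate = 2000, onset_index = 201)
#' print(tr)
#' @export
emg_trace <- function(samples, sampling_rate, onset_index) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("`samples` must be a numeric vector with at least 2 elements")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` must be finite and non-missing")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive number (Hz)")
  onset_index <- as.integer(onset_index)
  if (length(onset_index) != 1L || is.na(onset_index) ||
      onset_index < 1L || onset_index > length(samples))
    stop("`onset_index` must be a sample index inside the trace")
  x <- structure(
    list(samples = as.numeric(samples),
         sampling_rate = as.numeric(sampling_rate),
         onset_index = onset_index),
    class = "emg_trace")
  validate_emg_trace(x)
  x
}

#' Validate an EMG trace against the detector's requirements
#'
#' Checks that the trace holds at least 60 ms of samples before the stimulus
#' onset, at least 150 ms at/after it, and that both detection windows
#' contain at least two samples at the trace's sampling rate.
#'
#' @param x An `emg_trace`.
#' @return `x`, invisibly; errors otherwise.
#' @export
validate_emg_trace <- function(x) {
  stopifnot(inherits(x, "emg_trace"))
  fs <- x$sampling_rate
  pre_ms  <- (x$onset_index - 1L) / fs * 1000
  post_ms <- (length(x$samples) - x$onset_index + 1L) / fs * 1000
  if (pre_ms < 60)
    stop(sprintf("insufficient pre-stimulus data: %.1f ms available, 60 ms required", pre_ms))
  if (post_ms < 150)
    stop(sprintf("insufficient post-stimulus data: %.1f ms available, 150 ms required", post_ms))
  # both detection windows (baseline and response) span 60 ms
  if (floor(60 * fs / 1000) < 2)
    stop("sampling rate too low: fewer than 2 samples per detection window")
  invisible(x)
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %d samples @ %g Hz, onset at sample %d (%.1f ms pre / %.1f ms post)\n",
              length(x$samples), x$sampling_rate, x$onset_index,
              (x$onset_index - 1L) / x$sampling_rate * 1000,
              (length(x$samples) - x$onset_index + 1L) / x$sampling_rate * 1000))
  invisible(x)
}

#' Read an EMG trace from CSV plus JSON sidecar
#'
#' The trace file is a CSV with header `time_s,emg_mV`, one row per sample
#' with uniform spacing; the sidecar is JSON holding `sampling_rate_hz`,
#' `onset_index` (1-based) and `units`. Sample spacing is validated against
#' the declared sampling rate to 1e-9 s.
#'
#' @param csv_path Path to the trace CSV.
#' @param meta_path Path to the JSON sidecar.
#' @return An [emg_trace()].
#' @export
read_trace <- function(csv_path, meta_path) {
  dat <- utils::read.csv(csv_path)
  if (!all(c("time_s", "emg_mV") %in% names(dat)))
    stop("trace CSV must have columns `time_s` and `emg_mV`")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (k in c("sampling_rate_hz", "onset_index"))
    if (is.null(meta[[k]])) stop(sprintf("sidecar missing `%s`", k))
  fs <- as.numeric(meta$sampling_rate_hz)
  if (nrow(dat) >= 2L) {
    dt <- diff(dat$time_s)
    if (any(abs(dt - 1 / fs) > 1e-9))
      stop("trace CSV sample spacing is not uniform at the declared sampling rate")
  }
  emg_trace(dat$emg_mV, sampling_rate = fs,
            onset_index = as.integer(meta$onset_index))
}

#' Write an EMG trace as CSV plus JSON sidecar
#'
#' @param trace An [emg_trace()].
#' @param csv_path,meta_path Output paths.
#' @return Invisibly, the trace.
#' @export
write_trace <- function(trace, csv_path, meta_path) {
  validate_emg_trace(trace)
  t0 <- (seq_along(trace$samples) - 1L) / trace$sampling_rate
  utils::write.csv(data.frame(time_s = t0, emg_mV = trace$samples),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = trace$sampling_rate,
         onset_index = trace$onset_index, units = "mV"),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(trace)
}
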