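#' Reflex-detection configuration
#'
#' Parameters of the windowed Z-score response criterion: the peak amplitude
#' in a post-stimulus response window is compared against the mean and
#' standard deviation of a pre-stimulus baseline window, and a reflex is
#' declared when the Z-score reaches the criterion.
#'
#' @param response_window_ms Length-2 numeric, ms relative to stimulus onset
#'   (default `c(90, 150)`).
#' @param baseline_window_ms Length-2 numeric, ms relative to onset
#'   (default `c(-60, 0)`).
#' @param z_criterion Response criterion (default 12).
#' @param rectify Rectify (absolute value) the signal before windowing?
#'   Default `FALSE`: the criterion is applied to the raw peak amplitude.
#' @param sd_divisor `"n-1"` (sample SD, default) or `"n"` (population SD)
#'   for the baseline standard deviation.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(response_window_ms = c(90, 150),
                             baseline_window_ms = c(-60, 0),
                             z_criterion = 12,
                             rectify = FALSE,
                             sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  stopifnot(length(response_window_ms) == 2L, length(baseline_window_ms) == 2L)
  if (response_window_ms[1] >= response_window_ms[2] ||
      baseline_window_ms[1] >= baseline_window_ms[2])
    stop("window start must be strictly before window end")
  if (!is.numeric(z_criterion) || z_criterion <= 0)
    stop("`z_criterion` must be positive")
  structure(list(response_window_ms = as.numeric(response_window_ms),
                 baseline_window_ms = as.numeric(baseline_window_ms),
                 z_criterion = as.numeric(z_criterion),
                 rectify = isTRUE(rectify),
                 sd_divisor = sd_divisor),
            class = "detection_config")
}

#' Extract a millisecond window from a trace
#'
#' Windows are specified in ms relative to the stimulus onset and converted
#' to sample indices with `floor(t * fs / 1000)`; the extracted span is the
#' half-open index interval `[floor(start*fs/1000), floor(end*fs/1000))`
#' shifted by the onset index. At 1000 Hz with onset at sample 101, the
#' baseline window (-60, 0) maps to samples 41..100.
#'
#' @param trace An [emg_trace()].
#' @param window_ms Length-2 numeric, ms relative to onset.
#' @return Numeric vector of the windowed samples (length >= 2).
#' @export
extract_window <- function(trace, window_ms) {
  validate_emg_trace(trace)
  stopifnot(is.numeric(window_ms), length(window_ms) == 2L,
            window_ms[1] < window_ms[2])
  fs <- trace$sampling_rate
  # offsets relative to the onset sample; half-open [lo, hi)
  lo <- floor(window_ms[1] * fs / 1000)
  hi <- floor(window_ms[2] * fs / 1000)
  idx_lo <- trace$onset_index + lo
  idx_hi <- trace$onset_index + hi - 1L
  n <- length(trace$samples)
  if (idx_lo < 1L || idx_hi > n)
    stop(sprintf(
      "window [%g, %g) ms maps to samples %d..%d, outside the trace (1..%d)",
      window_ms[1], window_ms[2], idx_lo, idx_hi, n))
  if (idx_hi - idx_lo + 1L < 2L)
    stop("window contains fewer than 2 samples at this sampling rate")
  trace$samples[idx_lo:idx_hi]
}

#' Detect a nociceptive withdrawal reflex in a single trace
#'
#' Computes the Z-score criterion: the maximum amplitude in the response
#' window (default 90--150 ms post onset) minus the baseline mean (default
#' -60--0 ms), divided by the baseline standard deviation. A Z-score at or
#' above the criterion (default 12) is a reflex response.
#'
#' A flat baseline (SD = 0) leaves the Z-score undefined and is a hard
#' error; callers must not interpret it as "no response".
#'
#' @param trace An [emg_trace()].
#' @param config A [detection_config()].
#' @return An object of class `detection_result` with fields
#'   `peak_amplitude`, `baseline_mean`, `baseline_sd`, `z_score`,
#'   `is_response`.
#' @examples
#' set.seed(1)
#' x <- rnorm(600, sd = 0.01)
#' x[441] <- 0.3  # burst peak 120 ms after onset at sample 201 (2000 Hz)
#' detect_reflex(emg_trace(x, 2000, 201))
#' @export
detect_reflex <- function(trace, config = detection_config()) {
  stopifnot(inherits(config, "detection_config"))
  if (config$rectify) trace$samples <- abs(trace$samples)
  resp <- extract_window(trace, config$response_window_ms)
  base <- extract_window(trace, config$baseline_window_ms)
  peak <- max(resp)
  bmean <- mean(base)
  bsd <- stats::sd(base)
  if (config$sd_divisor == "n")
    bsd <- bsd * sqrt((length(base) - 1) / length(base))
  if (bsd == 0)
    stop("degenerate baseline: standard deviation is zero, Z-score undefined")
  z <- (peak - bmean) / bsd
  structure(list(peak_amplitude = peak,
                 baseline_mean = bmean,
                 baseline_sd = bsd,
                 z_score = z,
                 is_response = classify_response(z, config$z_criterion)),
            class = "detection_result")
}

#' @rdname detect_reflex
#' @export
compute_z_score <- detect_reflex

#' Classify a Z-score against the response criterion
#'
#' The criterion boundary is inclusive: a Z-score exactly equal to the
#' criterion counts as a response.
#'
#' @param z_score Finite numeric Z-score.
#' @param z_criterion Positive criterion (default 12).
#' @return Logical.
#' @export
classify_response <- function(z_score, z_criterion = 12) {
  if (!is.numeric(z_score) || length(z_score) != 1L || !is.finite(z_score))
    stop("`z_score` must be a single finite number")
  z_score >= z_criterion
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> peak %.4g mV, baseline %.4g +/- %.4g mV, Z = %.2f -> %s\n",
    x$peak_amplitude, x$baseline_mean, x$baseline_sd, x$z_score,
    if (x$is_response) "RESPONSE" else "no response"))
  invisible(x)
}
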