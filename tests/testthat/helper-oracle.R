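# Independent brute-force transcription of the staircase narrative, written
# straight-line with plain mA arithmetic (rounded to 0.1 mA per step to keep
# the comparison honest about representation). Shares no code with the
# package's state machine.
#
# Narrative: intensity rises in 2 mA steps from 1 mA until a reflex; then
# falls in 1 mA steps until the reflex disappears; rises in 0.5 mA steps
# until a second reflex; falls in 0.5 mA steps until it disappears; rises in
# 0.5 mA steps until a third reflex. Threshold = mean of the three success
# intensities. Stops at 30 mA without a response, or on request.
oracle_staircase <- function(respond_fn, max_mA = 30) {
  delivered <- numeric(0)
  successes <- numeric(0)
  deliver <- function(i) {
    delivered[length(delivered) + 1] <<- i
    respond_fn(i)
  }
  # phase 1: coarse ascent from 1 mA in 2 mA steps
  i <- 1
  repeat {
    hit <- deliver(i)
    if (hit) { successes <- c(successes, i); break }
    if (i >= max_mA) return(list(status = "CAP_REACHED", threshold = NA_real_,
                                 delivered = delivered, successes = successes))
    i <- round(min(i + 2, max_mA), 1)
  }
  # descend in 1 mA steps until the response disappears (floor 0 counts as
  # a guaranteed miss without delivery)
  i <- round(i - 1, 1)
  while (i > 0 && deliver(i)) i <- round(i - 1, 1)
  # ascend in 0.5 mA steps until the second response
  i <- round(i + 0.5, 1)
  repeat {
    hit <- deliver(i)
    if (hit) { successes <- c(successes, i); break }
    if (i >= max_mA) return(list(status = "CAP_REACHED", threshold = NA_real_,
                                 delivered = delivered, successes = successes))
    i <- round(min(i + 0.5, max_mA), 1)
  }
  # descend in 0.5 mA steps until the response disappears
  i <- round(i - 0.5, 1)
  while (i > 0 && deliver(i)) i <- round(i - 0.5, 1)
  # ascend in 0.5 mA steps until the third response
  i <- round(i + 0.5, 1)
  repeat {
    hit <- deliver(i)
    if (hit) { successes <- c(successes, i); break }
    if (i >= max_mA) return(list(status = "CAP_REACHED", threshold = NA_real_,
                                 delivered = delivered, successes = successes))
    i <- round(min(i + 0.5, max_mA), 1)
  }
  list(status = "OK", threshold = mean(successes),
       delivered = delivered, successes = successes)
}

# naive two-pass Z-score reference: explicit loops, no shared code with
# detect_reflex
oracle_z_score <- function(samples, fs, onset, response_ms = c(90, 150),
                           baseline_ms = c(-60, 0)) {
  idx <- function(w) {
    lo <- onset + floor(w[1] * fs / 1000)
    hi <- onset + floor(w[2] * fs / 1000) - 1
    lo:hi
  }
  base <- samples[idx(baseline_ms)]
  m <- 0
  for (v in base) m <- m + v
  m <- m / length(base)
  ss <- 0
  for (v in base) ss <- ss + (v - m)^2
  s <- sqrt(ss / (length(base) - 1))
  peak <- -Inf
  for (v in samples[idx(response_ms)]) if (v > peak) peak <- v
  (peak - m) / s
}

# deterministic test trace with a flat baseline alternation and an optional
# spike in the response window
make_pulse_trace <- function(peak_mV = 13, fs = 2000) {
  n_pre <- 0.1 * fs
  x <- c(rep(c(-1, 1), length.out = n_pre), rep(0, 0.2 * fs))
  onset <- n_pre + 1
  spike_at <- onset + floor(120 * fs / 1000)  # 120 ms post onset
  x[spike_at] <- peak_mV
  emg_trace(x, sampling_rate = fs, onset_index = onset)
}
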