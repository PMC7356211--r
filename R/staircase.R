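#' Staircase configuration
#'
#' Schedule of the adaptive threshold staircase: a coarse ascent in 2 mA
#' steps from 1 mA until the first reflex, a 1 mA descent until the reflex
#' disappears, then 0.5 mA fine ascents/descents until the second and third
#' reflexes; the threshold is the mean of the three phase-terminating
#' success intensities. The run stops early when the intensity cap (30 mA)
#' is reached without a response, or when the subject aborts.
#'
#' All intensities are represented internally in integer tenths of mA so
#' that repeated +/-0.5, +/-1 and +/-2 mA steps cannot accumulate
#' floating-point drift.
#'
#' @param start_mA First stimulus intensity (default 1).
#' @param coarse_up_mA Ascending step before the first success (default 2).
#' @param first_down_mA Descending step after the first success (default 1).
#' @param fine_step_mA Fine step for later phases (default 0.5).
#' @param max_mA Intensity cap (default 30).
#' @param min_mA Intensity floor (default 0); the floor counts as a
#'   guaranteed non-response without a stimulus being delivered.
#' @param required_successes Successes defining the threshold (default 3).
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_mA = 1, coarse_up_mA = 2, first_down_mA = 1,
                             fine_step_mA = 0.5, max_mA = 30, min_mA = 0,
                             required_successes = 3L) {
  if (!(fine_step_mA > 0 && fine_step_mA <= first_down_mA &&
        first_down_mA <= coarse_up_mA))
    stop("need 0 < fine_step_mA <= first_down_mA <= coarse_up_mA")
  if (start_mA > max_mA) stop("start_mA must not exceed max_mA")
  if (min_mA < 0 || min_mA >= start_mA) stop("need 0 <= min_mA < start_mA")
  steps <- c(start_mA, coarse_up_mA, first_down_mA, fine_step_mA, max_mA, min_mA)
  if (any(abs(steps * 10 - round(steps * 10)) > 1e-9))
    stop("all intensities and steps must be multiples of 0.1 mA")
  structure(list(start_mA = start_mA, coarse_up_mA = coarse_up_mA,
                 first_down_mA = first_down_mA, fine_step_mA = fine_step_mA,
                 max_mA = max_mA, min_mA = min_mA,
                 required_successes = as.integer(required_successes)),
            class = "staircase_config")
}

# phase labels; terminal ones carry no current intensity
.sc_phases <- c("ASCEND_COARSE", "DESCEND_1", "ASCEND_FINE_2", "DESCEND_FINE",
                "ASCEND_FINE_3", "DONE", "FAILED", "ABORTED")

#' Initial staircase state
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_state`: phase, current intensity,
#'   stimulus history and recorded success intensities (all intensities in
#'   integer tenths of mA internally; accessors return mA).
#' @export
staircase_init <- function(config = staircase_config()) {
  structure(list(phase = "ASCEND_COARSE",
                 current_dmA = as.integer(round(config$start_mA * 10)),
                 at_max = config$start_mA >= config$max_mA,
                 history = list(),
                 success_dmA = integer(0)),
            class = "staircase_state")
}

#' Current stimulus intensity of a staircase state, in mA
#' @param state A `staircase_state`.
#' @return Numeric mA, or `NA` for terminal states.
#' @export
current_intensity <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  if (state$phase %in% c("DONE", "FAILED", "ABORTED")) return(NA_real_)
  state$current_dmA / 10
}

#' Is the staircase finished?
#' @param state A `staircase_state`.
#' @return Logical.
#' @export
is_terminal <- function(state) {
  stopifnot(inherits(state, "staircase_state"))
  state$phase %in% c("DONE", "FAILED", "ABORTED")
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("<staircase_state> phase %s, current %s mA, %d stimuli, successes: %s\n",
              x$phase,
              if (is_terminal(x)) "-" else format(x$current_dmA / 10),
              length(x$history),
              if (length(x$success_dmA)) paste(x$success_dmA / 10, collapse = ", ")
              else "none"))
  invisible(x)
}

# move to an ascending intensity, clamping at the cap; `dmA` is the
# unclamped requirement in tenths
.sc_ascend_to <- function(state, dmA, phase, config) {
  cap <- as.integer(round(config$max_mA * 10))
  state$phase <- phase
  if (dmA >= cap) {
    state$current_dmA <- cap
    state$at_max <- TRUE
  } else {
    state$current_dmA <- as.integer(dmA)
    state$at_max <- FALSE
  }
  state
}

# move to a descending intensity; a requirement at/below the floor counts
# as a guaranteed non-response without stimulus delivery, so the state
# skips straight to the next ascending phase at floor + fine step
.sc_descend_to <- function(state, dmA, phase, config) {
  floor_dmA <- as.integer(round(config$min_mA * 10))
  fine <- as.integer(round(config$fine_step_mA * 10))
  if (dmA <= floor_dmA) {
    next_phase <- if (phase == "DESCEND_1") "ASCEND_FINE_2" else "ASCEND_FINE_3"
    return(.sc_ascend_to(state, floor_dmA + fine, next_phase, config))
  }
  state$phase <- phase
  state$current_dmA <- as.integer(dmA)
  state$at_max <- FALSE
  state
}

#' Advance the staircase by one observed stimulus outcome
#'
#' Pure state transition. `last_response` is the detector's verdict for a
#' stimulus just delivered at `current_intensity(state)`. Ascending phases
#' step up after a miss and record a success (moving to the next descending
#' phase) after a hit; descending phases keep stepping down while the
#' response persists and hand over to the next fine ascent once it
#' disappears. The third recorded success terminates the staircase
#' (`DONE`). An ascent clamped at the cap that still fails terminates with
#' `FAILED`; a descent that would cross the floor treats the floor as a
#' guaranteed non-response and skips to the next ascending phase.
#'
#' @param state A non-terminal `staircase_state`.
#' @param last_response Logical: did the stimulus evoke a reflex?
#' @param config A [staircase_config()].
#' @return The next `staircase_state`.
#' @export
staircase_advance <- function(state, last_response, config = staircase_config()) {
  stopifnot(inherits(state, "staircase_state"), inherits(config, "staircase_config"))
  if (is_terminal(state))
    stop("illegal transition: staircase already in terminal phase ", state$phase)
  stopifnot(is.logical(last_response), length(last_response) == 1L,
            !is.na(last_response))
  cur <- state$current_dmA
  coarse <- as.integer(round(config$coarse_up_mA * 10))
  down1 <- as.integer(round(config$first_down_mA * 10))
  fine <- as.integer(round(config$fine_step_mA * 10))

  record_success <- function(state) {
    state$success_dmA <- c(state$success_dmA, cur)
    state
  }

  switch(state$phase,
    ASCEND_COARSE = {
      if (last_response) {
        state <- record_success(state)
        .sc_descend_to(state, cur - down1, "DESCEND_1", config)
      } else if (state$at_max) {
        state$phase <- "FAILED"; state
      } else .sc_ascend_to(state, cur + coarse, "ASCEND_COARSE", config)
    },
    DESCEND_1 = {
      if (last_response) .sc_descend_to(state, cur - down1, "DESCEND_1", config)
      else .sc_ascend_to(state, cur + fine, "ASCEND_FINE_2", config)
    },
    ASCEND_FINE_2 = {
      if (last_response) {
        state <- record_success(state)
        .sc_descend_to(state, cur - fine, "DESCEND_FINE", config)
      } else if (state$at_max) {
        state$phase <- "FAILED"; state
      } else .sc_ascend_to(state, cur + fine, "ASCEND_FINE_2", config)
    },
    DESCEND_FINE = {
      if (last_response) .sc_descend_to(state, cur - fine, "DESCEND_FINE", config)
      else .sc_ascend_to(state, cur + fine, "ASCEND_FINE_3", config)
    },
    ASCEND_FINE_3 = {
      if (last_response) {
        state <- record_success(state)
        if (length(state$success_dmA) >= config$required_successes)
          state$phase <- "DONE"
        else  # required_successes > 3: reuse the final fine cycle
          state <- .sc_descend_to(state, cur - fine, "DESCEND_FINE", config)
        state
      } else if (state$at_max) {
        state$phase <- "FAILED"; state
      } else .sc_ascend_to(state, cur + fine, "ASCEND_FINE_3", config)
    },
    stop("unknown phase ", state$phase))
}

#' Signal that the subject aborted the session
#'
#' Responder callbacks passed to [run_staircase()] call this to model the
#' subject asking to stop; the staircase terminates with status `ABORTED`.
#'
#' @param message Optional message.
#' @export
abort_session <- function(message = "subject requested stop") {
  cond <- structure(class = c("nwr_abort", "condition"),
                    list(message = message, call = sys.call(-1)))
  stop(cond)
}

#' Run a complete staircase against a responder
#'
#' Iterates [staircase_advance()] until a terminal phase, delivering each
#' scheduled intensity to `responder`. The responder maps an intensity in mA
#' to either a logical (reflex present?) or a list with elements `response`
#' (logical) and optionally `rating` (0--10) and `z_score`; it may call
#' [abort_session()].
#'
#' @param responder Function of one argument (intensity in mA).
#' @param config A [staircase_config()].
#' @return An object of class `threshold_result`: `threshold_mA` (mean of
#'   the success intensities, or `NA`), `status` (`"OK"`, `"CAP_REACHED"`
#'   or `"ABORTED"`), `success_intensities_mA`, `n_stimuli`, and `history`
#'   (data frame: intensity_mA, is_response, rating, z_score).
#' @examples
#' run_staircase(function(i) i >= 10.2)  # threshold 10.667 mA
#' @export
run_staircase <- function(responder, config = staircase_config()) {
  stopifnot(is.function(responder))
  state <- staircase_init(config)
  aborted <- FALSE
  while (!is_terminal(state)) {
    i_mA <- current_intensity(state)
    out <- tryCatch(responder(i_mA),
                    nwr_abort = function(cond) cond)
    if (inherits(out, "nwr_abort")) { aborted <- TRUE; break }
    if (is.logical(out)) out <- list(response = out)
    stopifnot(is.logical(out$response), length(out$response) == 1L)
    state$history[[length(state$history) + 1L]] <-
      list(intensity_mA = i_mA,
           is_response = out$response,
           rating = if (is.null(out$rating)) NA_real_ else as.numeric(out$rating),
           z_score = if (is.null(out$z_score)) NA_real_ else as.numeric(out$z_score))
    state <- staircase_advance(state, out$response, config)
  }
  history <- do.call(rbind, lapply(state$history, as.data.frame))
  if (is.null(history))
    history <- data.frame(intensity_mA = numeric(0), is_response = logical(0),
                          rating = numeric(0), z_score = numeric(0))
  status <- if (aborted) "ABORTED"
            else if (state$phase == "DONE") "OK"
            else "CAP_REACHED"
  successes <- state$success_dmA / 10
  structure(list(
    threshold_mA = if (status == "OK") compute_threshold(successes, config)
                   else NA_real_,
    status = status,
    success_intensities_mA = successes,
    n_stimuli = nrow(history),
    history = history),
    class = "threshold_result")
}

#' Reflex threshold from the staircase's success intensities
#'
#' The threshold is the arithmetic mean of the phase-terminating success
#' intensities; exactly `required_successes` values are required.
#'
#' @param success_intensities_mA Numeric vector of success intensities.
#' @param config A [staircase_config()] (supplies `required_successes`).
#' @return Threshold in mA.
#' @examples
#' compute_threshold(c(11, 10.5, 10.5))  # 10.6667
#' @export
compute_threshold <- function(success_intensities_mA, config = staircase_config()) {
  if (length(success_intensities_mA) != config$required_successes)
    stop(sprintf("need exactly %d success intensities, got %d",
                 config$required_successes, length(success_intensities_mA)))
  mean(success_intensities_mA)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> status %s, threshold %s mA (%d stimuli; successes: %s)\n",
              x$status,
              if (is.na(x$threshold_mA)) "-" else format(round(x$threshold_mA, 4)),
              x$n_stimuli,
              if (length(x$success_intensities_mA))
                paste(x$success_intensities_mA, collapse = ", ") else "none"))
  invisible(x)
}
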