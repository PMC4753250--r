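#' Stimulus trace
#'
#' A frame-indexed binary LED record for one session. Frames are 0-based and
#' contiguous; `led_state` is 0 (OFF) or 1 (ON). The stimulus shares the
#' acquisition clock of the behavioural tracks of the same session.
#'
#' @param led_state Integer/logical vector of per-frame LED states (0/1).
#' @param frame_rate_hz Acquisition rate in Hz.
#' @param frame Optional explicit frame indices; must be contiguous and start
#'   anywhere (normally 0). Defaults to `0:(length(led_state)-1)`.
#'
#' @return A data.frame of class `stimulus_trace` with columns `frame`,
#'   `led_state` and attribute `frame_rate_hz`.
#' @export
stimulus_trace <- function(led_state, frame_rate_hz = 4, frame = NULL) {
  led_state <- as.integer(led_state)
  if (any(is.na(led_state)) || !all(led_state %in% c(0L, 1L)))
    stop("`led_state` must be binary (0 = OFF, 1 = ON)", call. = FALSE)
  n <- length(led_state)
  if (n < 1L) stop("stimulus trace must have at least one frame", call. = FALSE)
  if (is.null(frame)) frame <- seq.int(0L, n - 1L)
  frame <- as.integer(frame)
  if (length(frame) != n) stop("`frame` length mismatch", call. = FALSE)
  if (n > 1L && any(diff(frame) != 1L))
    stop("frame index must be contiguous (no gaps, no duplicates)",
         call. = FALSE)
  structure(data.frame(frame = frame, led_state = led_state),
            frame_rate_hz = frame_rate_hz,
            class = c("stimulus_trace", "data.frame"))
}

#' @export
print.stimulus_trace <- function(x, ...) {
  n <- nrow(x)
  fr <- attr(x, "frame_rate_hz")
  cat(sprintf("Stimulus trace: %d frames at %g Hz (%.1f s), %.1f%% ON\n",
              n, fr, n / fr, 100 * mean(x$led_state)))
  invisible(x)
}

#' Frame rate of a stimulus trace
#' @param x A `stimulus_trace`.
#' @return Frame rate in Hz.
#' @export
frame_rate <- function(x) attr(x, "frame_rate_hz")

#' Encode a stimulus trace as a +/-1 signal
#'
#' The reverse-correlation convention: LED ON is encoded as +1 and LED OFF
#' as -1. This is the signal that is averaged over pre-event windows.
#'
#' @param trace A `stimulus_trace`.
#' @return A numeric vector in \{-1, +1\}, one value per frame.
#' @examples
#' encode_stimulus(stimulus_trace(c(1, 0, 1)))  # +1 -1 +1
#' @export
encode_stimulus <- function(trace) {
  stopifnot(inherits(trace, "stimulus_trace"))
  2 * trace$led_state - 1
}

#' Generate a Bernoulli (white) flicker stimulus
#'
#' Each frame is ON independently with probability `bernoulli_p` — the
#' simplest white process, with a flat power spectrum. Under this stimulus
#' the event-triggered average is an unbiased filter estimate.
#'
#' @param spec A [simulation_spec()] with `stimulus_kind = "bernoulli"`.
#' @param config An [acq_config()]; supplies the frame rate.
#' @return A `stimulus_trace`.
#' @export
generate_bernoulli_stimulus <- function(spec, config = acq_config()) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$stimulus_kind != "bernoulli")
    stop("spec$stimulus_kind must be \"bernoulli\"", call. = FALSE)
  p <- spec$bernoulli_p
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("`bernoulli_p` must lie strictly inside (0, 1)", call. = FALSE)
  n <- n_frames(spec, config)
  set.seed(spec$seed)
  stimulus_trace(stats::rbinom(n, 1L, p), frame_rate_hz = config$frame_rate_hz)
}

#' Generate a step stimulus (light OFF to light ON)
#'
#' OFF for every frame before the onset, ON from the onset frame to the end:
#' exactly one OFF-to-ON transition (none if the onset is frame 0).
#'
#' @param spec A [simulation_spec()] with `stimulus_kind = "step"`; the onset
#'   time is `spec$step_onset_s`.
#' @param config An [acq_config()].
#' @return A `stimulus_trace`.
#' @export
generate_step_stimulus <- function(spec, config = acq_config()) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$stimulus_kind != "step")
    stop("spec$stimulus_kind must be \"step\"", call. = FALSE)
  if (spec$step_onset_s < 0 || spec$step_onset_s >= spec$duration_s)
    stop("`step_onset_s` must lie in [0, duration_s)", call. = FALSE)
  n <- n_frames(spec, config)
  onset <- as.integer(round(spec$step_onset_s * config$frame_rate_hz))
  led <- c(rep(0L, onset), rep(1L, n - onset))
  stimulus_trace(led, frame_rate_hz = config$frame_rate_hz)
}

#' Generate a constant stimulus
#'
#' All frames share one LED state; used for controls and degenerate-input
#' tests.
#'
#' @param spec A [simulation_spec()] with `stimulus_kind = "constant"`.
#' @param config An [acq_config()].
#' @param on Logical; if `TRUE` all frames are ON, otherwise all OFF.
#' @return A `stimulus_trace`.
#' @export
generate_constant_stimulus <- function(spec, config = acq_config(), on = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  n <- n_frames(spec, config)
  stimulus_trace(rep(as.integer(on), n), frame_rate_hz = config$frame_rate_hz)
}

n_frames <- function(spec, config) {
  n <- as.integer(round(spec$duration_s * config$frame_rate_hz))
  if (n < 1L) stop("duration shorter than one frame", call. = FALSE)
  n
}
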