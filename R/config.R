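#' Acquisition configuration
#'
#' Bundles the timing constants of a behavioural / imaging session: the
#' behavioural frame rate (the camera and LED flicker share one clock), the
#' imaging frame period, the bin width for step-response probabilities, and
#' the pre-event window for triggered averages.
#'
#' @param frame_rate_hz Behavioural acquisition rate in Hz. Default 4.
#' @param frame_period_ms Imaging frame period in milliseconds. Default 85.
#' @param step_bin_s Bin width for step-response transition probabilities in
#'   seconds; must be an integer multiple of one frame period. Default 0.25.
#' @param ta_window_s Length of the pre-event stimulus window used for
#'   triggered averages, in seconds. Default 20.
#' @param seed Non-negative integer seed recorded with the configuration.
#'
#' @return An object of class `acq_config` (a named list).
#' @examples
#' cfg <- acq_config()
#' cfg$frame_rate_hz
#' @export
acq_config <- function(frame_rate_hz = 4, frame_period_ms = 85,
                       step_bin_s = 0.25, ta_window_s = 20, seed = 0L) {
  stopifnot(is.numeric(frame_rate_hz), length(frame_rate_hz) == 1L,
            is.finite(frame_rate_hz), frame_rate_hz > 0)
  stopifnot(is.numeric(frame_period_ms), length(frame_period_ms) == 1L,
            is.finite(frame_period_ms), frame_period_ms > 0)
  stopifnot(is.numeric(step_bin_s), length(step_bin_s) == 1L,
            is.finite(step_bin_s), step_bin_s > 0)
  stopifnot(is.numeric(ta_window_s), length(ta_window_s) == 1L,
            is.finite(ta_window_s), ta_window_s > 0)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  nf <- step_bin_s * frame_rate_hz
  if (abs(nf - round(nf)) > 1e-8) {
    stop("`step_bin_s` must be an integer multiple of one frame period (1/",
         frame_rate_hz, " s)", call. = FALSE)
  }
  structure(list(frame_rate_hz = frame_rate_hz,
                 frame_period_ms = frame_period_ms,
                 step_bin_s = step_bin_s,
                 ta_window_s = ta_window_s,
                 seed = as.integer(seed)),
            class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Acquisition configuration\n")
  cat(sprintf("  frame rate      : %g Hz (behaviour)\n", x$frame_rate_hz))
  cat(sprintf("  frame period    : %g ms (imaging)\n", x$frame_period_ms))
  cat(sprintf("  step bin        : %g s\n", x$step_bin_s))
  cat(sprintf("  TA window       : %g s\n", x$ta_window_s))
  cat(sprintf("  seed            : %d\n", x$seed))
  invisible(x)
}

#' Read an acquisition configuration from a YAML file
#'
#' The file holds top-level keys matching the arguments of [acq_config()];
#' unknown keys are ignored so module-specific parameters can live in the
#' same file.
#'
#' @param path Path to a YAML configuration file.
#' @return An `acq_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw),
                    c("frame_rate_hz", "frame_period_ms", "step_bin_s",
                      "ta_window_s", "seed"))
  do.call(acq_config, raw[keep])
}
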