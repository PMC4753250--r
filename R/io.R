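#' @name io
#' @title Delimited-text readers and writers
#'
#' @description
#' All session artefacts are tab-separated text with a one-line header, so
#' fixtures are inspectable and diffable:
#' \itemize{
#'   \item tracks: `animal_id, frame, state, valid`
#'   \item stimulus: `frame, led_state`
#'   \item traces: `roi_id, frame, intensity`
#'   \item choice: `assay_id, n_stimulus_side, n_control_side, n_neutral`
#'     (optional `group`)
#' }
#' Readers validate schema and integrity; writers emit a canonical layout so
#' a write/read/write cycle is byte-identical.
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

write_tsv_canonical <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read behavioural tracks
#'
#' @param path TSV with columns `animal_id`, `frame`, `state` and optionally
#'   `valid` (assumed `TRUE` when absent).
#' @param config An [acq_config()] (currently unused beyond provenance; the
#'   tracks carry no clock of their own).
#' @return A [behavior_tracks()] object.
#' @export
read_tracks <- function(path, config = acq_config()) {
  df <- read_tsv_checked(path, c("animal_id", "frame", "state"), "tracks")
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else NULL
  behavior_tracks(df$animal_id, df$frame, df$state, valid)
}

#' Write behavioural tracks
#' @param tracks A `behavior_tracks` object.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "behavior_tracks"))
  df <- as.data.frame(tracks)
  df$valid <- ifelse(df$valid, "TRUE", "FALSE")
  write_tsv_canonical(df, path)
}

#' Read a stimulus log
#'
#' @param path TSV with columns `frame`, `led_state` (0/1).
#' @param config An [acq_config()]; supplies the frame rate.
#' @return A [stimulus_trace()].
#' @export
read_stimulus <- function(path, config = acq_config()) {
  df <- read_tsv_checked(path, c("frame", "led_state"), "stimulus")
  frame <- as.integer(df$frame)
  o <- order(frame)
  frame <- frame[o]
  led <- df$led_state[o]
  if (length(frame) > 1L && any(diff(frame) != 1L))
    stop("stimulus log has a gap or duplicate in `frame`", call. = FALSE)
  stimulus_trace(led, frame_rate_hz = config$frame_rate_hz, frame = frame)
}

#' Write a stimulus log
#' @param trace A `stimulus_trace`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_stimulus <- function(trace, path) {
  stopifnot(inherits(trace, "stimulus_trace"))
  write_tsv_canonical(as.data.frame(trace), path)
}

#' Read fluorescence traces
#'
#' @param path TSV with columns `roi_id`, `frame`, `intensity`; frames of
#'   each ROI must be 0..(n-1).
#' @param n_pre_frames,n_stim_frames Window annotations applied to every ROI
#'   (pre-stimulus wash, stimulation); the remainder of each trace is the
#'   post-stimulus wash.
#' @param frame_period_ms Imaging frame period in milliseconds.
#' @return A named list of [fluorescence_trace()] objects, one per ROI.
#' @export
read_traces <- function(path, n_pre_frames = 100, n_stim_frames = 200,
                        frame_period_ms = 85) {
  df <- read_tsv_checked(path, c("roi_id", "frame", "intensity"), "traces")
  out <- lapply(split(df, df$roi_id), function(d) {
    d <- d[order(d$frame), ]
    if (!identical(as.integer(d$frame), seq.int(0L, nrow(d) - 1L)))
      stop("trace frames for ROI ", d$roi_id[1],
           " are not contiguous from 0", call. = FALSE)
    fluorescence_trace(d$intensity, roi_id = d$roi_id[1],
                       frame_period_ms = frame_period_ms,
                       n_pre_frames = n_pre_frames,
                       n_stim_frames = n_stim_frames,
                       n_post_frames = nrow(d) - n_pre_frames - n_stim_frames)
  })
  out[order(names(out))]
}

#' Write fluorescence traces
#' @param traces A list of `fluorescence_trace` objects (or a single one).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(roi_id = attr(tr, "roi_id"),
               frame = seq.int(0L, length(tr$intensity) - 1L),
               intensity = tr$intensity)
  }))
  write_tsv_canonical(df, path)
}

#' Read two-choice assay counts
#'
#' @param path TSV with columns `assay_id`, `n_stimulus_side`,
#'   `n_control_side`, `n_neutral` and optionally `group`.
#' @return A data.frame with those columns (counts as integers).
#' @export
read_choice <- function(path) {
  df <- read_tsv_checked(path, c("assay_id", "n_stimulus_side",
                                 "n_control_side", "n_neutral"), "choice")
  for (col in c("n_stimulus_side", "n_control_side", "n_neutral")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(is.na(df[[col]])) || any(df[[col]] < 0L))
      stop("column ", col, " must hold non-negative integer counts",
           call. = FALSE)
  }
  df
}

#' Write two-choice assay counts
#' @param counts A data.frame as returned by [read_choice()] or
#'   [simulate_two_choice()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_choice <- function(counts, path) {
  write_tsv_canonical(as.data.frame(counts), path)
}
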