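.states <- c("RUN", "TURN")

#' Behavioural tracks
#'
#' Frame-indexed RUN/TURN state labels for a population of larvae, one row
#' per (animal, frame). Larvae navigate by alternating two states: runs
#' (forward peristaltic crawling) and turns (head-sweeping reorientation).
#' `valid` marks frames where the tracker held the animal; the state label is
#' meaningful only where `valid` is `TRUE`. Frames are 0-based on the same
#' clock as the session's [stimulus_trace()].
#'
#' @param animal_id Character vector of animal identifiers.
#' @param frame Integer frame indices.
#' @param state Character vector of `"RUN"` / `"TURN"` labels (may be `NA`
#'   where `valid` is `FALSE`).
#' @param valid Logical vector; defaults to all `TRUE`.
#'
#' @return A data.frame of class `behavior_tracks`, sorted by animal then
#'   frame.
#' @export
behavior_tracks <- function(animal_id, frame, state, valid = NULL) {
  animal_id <- as.character(animal_id)
  frame <- as.integer(frame)
  state <- as.character(state)
  n <- length(frame)
  if (length(animal_id) == 1L) animal_id <- rep(animal_id, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- as.logical(valid)
  stopifnot(length(animal_id) == n, length(state) == n, length(valid) == n)
  bad <- valid & !(state %in% .states)
  if (any(bad))
    stop("unknown state label(s): ",
         paste(unique(state[bad]), collapse = ", "),
         " (allowed: RUN, TURN)", call. = FALSE)
  if (anyDuplicated(paste(animal_id, frame)))
    stop("duplicate (animal_id, frame) rows", call. = FALSE)
  df <- data.frame(animal_id = animal_id, frame = frame, state = state,
                   valid = valid, stringsAsFactors = FALSE)
  df <- df[order(df$animal_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("behavior_tracks", "data.frame")
  df
}

#' @export
print.behavior_tracks <- function(x, ...) {
  ids <- unique(x$animal_id)
  cat(sprintf("Behavioural tracks: %d animals, %d frames total, %.1f%% valid\n",
              length(ids), nrow(x), 100 * mean(x$valid)))
  st <- table(factor(x$state[x$valid], levels = .states))
  cat(sprintf("  valid frames: %d RUN, %d TURN\n", st[["RUN"]], st[["TURN"]]))
  invisible(x)
}

#' Number of animals in a track set
#' @param tracks A `behavior_tracks` object.
#' @return Integer count of distinct animals.
#' @export
n_animals <- function(tracks) {
  stopifnot(inherits(tracks, "behavior_tracks"))
  length(unique(tracks$animal_id))
}
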