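.kinds <- c("RUN_TO_TURN", "TURN_TO_RUN")

#' Detect run/turn transition events
#'
#' A transition event is recorded at the first frame of the new state,
#' whenever two consecutive frames (frame difference exactly 1) of the same
#' animal are both valid and carry different states. State changes that span
#' an invalid gap (tracking loss) are discarded: the initiation frame is then
#' unknown.
#'
#' @param tracks A [behavior_tracks()] object.
#' @return A data.frame of class `transition_events` with columns
#'   `animal_id`, `frame` (first frame of the new state) and `kind`
#'   (`"RUN_TO_TURN"` or `"TURN_TO_RUN"`).
#' @export
detect_transitions <- function(tracks) {
  stopifnot(inherits(tracks, "behavior_tracks"))
  n <- nrow(tracks)
  if (n < 2L) return(empty_events())
  a <- tracks$animal_id; f <- tracks$frame
  st <- tracks$state; v <- tracks$valid
  i <- seq_len(n - 1L)                    # row i -> row i+1
  ok <- a[i] == a[i + 1L] & (f[i + 1L] - f[i]) == 1L & v[i] & v[i + 1L] &
    st[i] != st[i + 1L]
  ok[is.na(ok)] <- FALSE
  j <- which(ok) + 1L                     # rows holding the new state
  ev <- data.frame(animal_id = a[j], frame = f[j],
                   kind = ifelse(st[j] == "TURN", "RUN_TO_TURN",
                                 "TURN_TO_RUN"),
                   stringsAsFactors = FALSE)
  class(ev) <- c("transition_events", "data.frame")
  ev
}

empty_events <- function() {
  ev <- data.frame(animal_id = character(0), frame = integer(0),
                   kind = character(0), stringsAsFactors = FALSE)
  class(ev) <- c("transition_events", "data.frame")
  ev
}

#' @export
print.transition_events <- function(x, ...) {
  tab <- table(factor(x$kind, levels = .kinds))
  cat(sprintf("Transition events: %d run-to-turn, %d turn-to-run (%d animals)\n",
              tab[["RUN_TO_TURN"]], tab[["TURN_TO_RUN"]],
              length(unique(x$animal_id))))
  invisible(x)
}

#' Event-triggered stimulus average
#'
#' Reverse correlation of the +/-1 encoded stimulus against transition
#' events: the mean stimulus over the `window_s` seconds preceding (and
#' including) the initiation frame of each event of the requested kind.
#' Lag 0 is the first frame of the new state itself. Events whose full
#' pre-event window falls outside the session are excluded (not zero-padded)
#' and counted in `n_excluded`.
#'
#' The per-lag standard error is a sample SD over events divided by
#' `sqrt(n_events)`, computed cluster-robustly: events from different animals
#' that fall on the same frame reuse the same stimulus value, so those
#' repeats are grouped by frame before the variance is formed
#' (`sem_method = "frame_cluster"`, the default). When every contributing
#' frame is distinct this reduces exactly to the naive per-event formula,
#' which is also available as `sem_method = "event"`.
#'
#' @param stimulus A [stimulus_trace()].
#' @param events A `transition_events` data.frame from [detect_transitions()].
#' @param kind `"RUN_TO_TURN"` or `"TURN_TO_RUN"`.
#' @param window_s Pre-event window length in seconds (default from config).
#' @param config An [acq_config()].
#' @param sem_method `"frame_cluster"` (default) or `"event"`.
#' @return An object of class `triggered_average`: list with `kind`,
#'   `lags_s` (non-positive grid, `-window_s..0`), `mean`, `sem`,
#'   `n_events`, `n_excluded`, `sem_method`.
#' @export
triggered_average <- function(stimulus, events, kind = "RUN_TO_TURN",
                              window_s = NULL, config = acq_config(),
                              sem_method = c("frame_cluster", "event")) {
  stopifnot(inherits(stimulus, "stimulus_trace"))
  kind <- match.arg(kind, .kinds)
  sem_method <- match.arg(sem_method)
  if (is.null(window_s)) window_s <- config$ta_window_s
  fr <- frame_rate(stimulus)
  W <- as.integer(round(window_s * fr))
  if (W < 0L) stop("`window_s` must be non-negative", call. = FALSE)

  s <- encode_stimulus(stimulus)
  f0 <- stimulus$frame[1L]
  ev <- events$frame[events$kind == kind] - f0   # 0-based within session
  usable <- ev >= W & ev < length(s)
  n_excluded <- sum(!usable)
  ev <- ev[usable]
  n <- length(ev)
  if (n == 0L)
    stop("no usable ", kind, " events: cannot form a triggered average",
         call. = FALSE)

  lags <- (-W):0L
  idx <- outer(ev, lags, "+") + 1L          # n x (W+1), 1-based into s
  vals <- matrix(s[idx], nrow = n)
  mu <- colMeans(vals)

  sem <- numeric(W + 1L)
  if (n > 1L) {
    if (sem_method == "event") {
      sem <- apply(vals, 2L, stats::sd) / sqrt(n)
    } else {
      for (j in seq_len(W + 1L)) {
        cl <- rowsum(vals[, j] - mu[j], idx[, j])  # per-frame residual sums
        sem[j] <- sqrt(sum(cl^2) / (n - 1)) / sqrt(n)
      }
    }
  }
  structure(list(kind = kind, lags_s = lags / fr, mean = mu, sem = sem,
                 n_events = n, n_excluded = n_excluded,
                 sem_method = sem_method),
            class = "triggered_average")
}

#' @export
print.triggered_average <- function(x, ...) {
  cat(sprintf("Triggered average (%s): %d events (%d excluded), window %g s\n",
              x$kind, x$n_events, x$n_excluded, -x$lags_s[1]))
  cat(sprintf("  mean at lag 0: %+.3f (sem %.3f, %s)\n",
              x$mean[length(x$mean)], x$sem[length(x$sem)], x$sem_method))
  invisible(x)
}

#' @export
as.data.frame.triggered_average <- function(x, ...) {
  data.frame(kind = x$kind, lag_s = x$lags_s, mean = x$mean, sem = x$sem,
             n_events = x$n_events, stringsAsFactors = FALSE)
}

#' Binned step-response transition probabilities
#'
#' For a light-step session, the probability that an animal initiates a
#' transition of the given kind in each time bin: the number of animals with
#' an initiation in the bin divided by the number of animals in the arena
#' (animals with at least one valid frame in the bin). The peak post-step bin
#' is compared against the mean pre-step bin probability with a one-sample
#' z-test (normal approximation to the binomial), and the approximation's
#' validity is flagged by the rule `n*p >= 5` and `n*(1-p) >= 5` at the peak.
#'
#' @param tracks A [behavior_tracks()] object.
#' @param stimulus A [stimulus_trace()] with exactly one OFF-to-ON step.
#' @param kind Transition kind, default `"RUN_TO_TURN"`.
#' @param config An [acq_config()]; `step_bin_s` sets the bin width.
#' @param baseline_window_s Length of the pre-step window used for the
#'   baseline; `NULL` (default) uses all pre-step bins.
#' @param alternative `"greater"` (one-sided increase, default) or
#'   `"two.sided"`.
#' @return An object of class `step_response`: a per-bin data.frame
#'   (`bin_start_s`, `probability`, `n_at_risk`, `n_events`) with attributes
#'   `baseline_probability`, `peak_bin_start_s`, `peak_probability`,
#'   `peak_n`, `z_stat`, `p_value`, `valid`, `alternative`, `onset_s`.
#' @export
step_transition_probability <- function(tracks, stimulus,
                                        kind = "RUN_TO_TURN",
                                        config = acq_config(),
                                        baseline_window_s = NULL,
                                        alternative = c("greater",
                                                        "two.sided")) {
  stopifnot(inherits(tracks, "behavior_tracks"),
            inherits(stimulus, "stimulus_trace"))
  kind <- match.arg(kind, .kinds)
  alternative <- match.arg(alternative)
  if (n_animals(tracks) < 1L) stop("no animals in the track set",
                                   call. = FALSE)
  led <- stimulus$led_state
  d <- diff(led)
  if (sum(d == 1L) != 1L || any(d == -1L) || led[1L] != 0L)
    stop("stimulus is not a single OFF-to-ON step", call. = FALSE)
  fr <- frame_rate(stimulus)
  b <- as.integer(round(config$step_bin_s * fr))
  f0 <- stimulus$frame[1L]
  onset <- stimulus$frame[which(d == 1L) + 1L] - f0   # 0-based onset frame
  n_frames_total <- nrow(stimulus)
  n_bins <- n_frames_total %/% b
  if (n_bins < 1L) stop("session shorter than one bin", call. = FALSE)

  bin_of <- function(fr_idx) fr_idx %/% b              # 0-based bin index
  events <- detect_transitions(tracks)
  ev <- events[events$kind == kind, , drop = FALSE]
  ev_bin <- bin_of(ev$frame - f0)
  ev_bin <- ev_bin[ev_bin >= 0L & ev_bin < n_bins]

  # animals at risk: at least one valid frame in the bin
  tv <- tracks[tracks$valid, c("animal_id", "frame")]
  tb <- bin_of(tv$frame - f0)
  keep <- tb >= 0L & tb < n_bins
  if (any(keep)) {
    aid <- as.integer(factor(tv$animal_id[keep]))
    pair <- unique(as.numeric(tb[keep]) * (max(aid) + 1) + aid)
    n_at_risk <- tabulate(floor(pair / (max(aid) + 1)) + 1L, nbins = n_bins)
  } else {
    n_at_risk <- integer(n_bins)
  }

  n_events_bin <- tabulate(ev_bin + 1L, nbins = n_bins)
  prob <- ifelse(n_at_risk > 0L, n_events_bin / n_at_risk, NA_real_)

  bin_start_s <- (seq_len(n_bins) - 1L) * b / fr
  onset_s <- onset / fr
  pre <- which(bin_start_s + b / fr <= onset_s)        # bins fully pre-step
  if (length(pre) == 0L)
    stop("no pre-step bins: cannot form a baseline", call. = FALSE)
  if (!is.null(baseline_window_s)) {
    nb <- as.integer(round(baseline_window_s * fr / b))
    pre <- utils::tail(pre, nb)
  }
  baseline <- mean(prob[pre], na.rm = TRUE)

  post <- which(bin_start_s >= onset_s)
  if (length(post) == 0L) stop("no post-step bins", call. = FALSE)
  peak <- post[which.max(prob[post])]
  p_hat <- prob[peak]
  n_peak <- n_at_risk[peak]

  if (!is.na(p_hat) && baseline > 0 && baseline < 1 && n_peak > 0L) {
    z <- (p_hat - baseline) / sqrt(baseline * (1 - baseline) / n_peak)
    p_value <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
               else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  } else {
    z <- NA_real_; p_value <- NA_real_
  }
  valid <- !is.na(p_hat) && n_peak * p_hat >= 5 && n_peak * (1 - p_hat) >= 5

  out <- data.frame(bin_start_s = bin_start_s, probability = prob,
                    n_at_risk = n_at_risk, n_events = n_events_bin)
  structure(out, class = c("step_response", "data.frame"),
            kind = kind, baseline_probability = baseline,
            peak_bin_start_s = bin_start_s[peak], peak_probability = p_hat,
            peak_n = n_peak, z_stat = z, p_value = p_value, valid = valid,
            alternative = alternative, onset_s = onset_s,
            baseline_bins = length(pre))
}

#' @export
print.step_response <- function(x, ...) {
  cat(sprintf("Step response (%s): onset %g s, %d bins of %g s\n",
              attr(x, "kind"), attr(x, "onset_s"), nrow(x),
              x$bin_start_s[2] - x$bin_start_s[1]))
  cat(sprintf("  baseline p = %.4f (%d pre-step bins)\n",
              attr(x, "baseline_probability"), attr(x, "baseline_bins")))
  cat(sprintf("  peak p = %.4f at %g s (n = %d), z = %.2f, p = %.3g, %s\n",
              attr(x, "peak_probability"), attr(x, "peak_bin_start_s"),
              attr(x, "peak_n"), attr(x, "z_stat"), attr(x, "p_value"),
              if (isTRUE(attr(x, "valid"))) "normal approx. valid (np>=5)"
              else "normal approx. NOT valid"))
  invisible(x)
}

#' Full reverse-correlation report for one session
#'
#' Computes both triggered averages (run-to-turn and turn-to-run), the event
#' and exclusion counts, and — when the stimulus is a single OFF-to-ON step —
#' the binned step response. With `out_dir` set, writes the TA table, the
#' step table and a JSON count/exclusion log.
#'
#' @param tracks A [behavior_tracks()] object.
#' @param stimulus A [stimulus_trace()].
#' @param config An [acq_config()].
#' @param out_dir Optional output directory.
#' @return A list with elements `ta` (named list of `triggered_average`),
#'   `step` (a `step_response` or `NULL`), `counts` (event/exclusion log).
#' @export
revcorr_report <- function(tracks, stimulus, config = acq_config(),
                           out_dir = NULL) {
  events <- detect_transitions(tracks)
  ta <- list()
  counts <- list(n_animals = n_animals(tracks))
  for (k in .kinds) {
    n_k <- sum(events$kind == k)
    counts[[paste0("n_", tolower(k))]] <- n_k
    ta[[k]] <- if (n_k > 0L)
      tryCatch(triggered_average(stimulus, events, kind = k, config = config),
               error = function(e) NULL)
    if (!is.null(ta[[k]]))
      counts[[paste0("n_excluded_", tolower(k))]] <- ta[[k]]$n_excluded
  }
  led <- stimulus$led_state
  is_step <- led[1L] == 0L && sum(diff(led) == 1L) == 1L &&
    !any(diff(led) == -1L)
  step <- if (is_step)
    step_transition_probability(tracks, stimulus, config = config) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ta_df <- do.call(rbind, lapply(ta[!vapply(ta, is.null, logical(1))],
                                   as.data.frame))
    if (!is.null(ta_df))
      write_tsv_canonical(ta_df, file.path(out_dir, "triggered_average.tsv"))
    if (!is.null(step)) {
      sdf <- as.data.frame(step)
      sdf$baseline <- attr(step, "baseline_probability")
      sdf$z <- attr(step, "z_stat")
      sdf$p <- attr(step, "p_value")
      sdf$valid <- attr(step, "valid")
      write_tsv_canonical(sdf, file.path(out_dir, "step_response.tsv"))
    }
    jsonlite::write_json(counts, file.path(out_dir, "revcorr_counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ta = ta, step = step, counts = counts)
}
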