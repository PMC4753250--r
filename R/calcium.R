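#' Fluorescence trace
#'
#' A single-ROI intensity time series under the wash/stimulation/wash
#' protocol: `n_pre_frames` of washing substance (water), `n_stim_frames` of
#' tastant stimulation, then at least `n_post_frames` of wash again, at
#' `frame_period_ms` per frame.
#'
#' @param intensity Non-negative numeric vector, one value per frame.
#' @param roi_id Identifier of the region of interest / neuron.
#' @param frame_period_ms Frame period in milliseconds (default 85).
#' @param n_pre_frames,n_stim_frames,n_post_frames Window lengths in frames
#'   (defaults 100 / 200 / 100); their sum must equal the trace length.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(intensity, roi_id = "roi1",
                               frame_period_ms = 85, n_pre_frames = 100,
                               n_stim_frames = 200, n_post_frames = 100) {
  intensity <- as.numeric(intensity)
  if (any(!is.finite(intensity)))
    stop("intensities must be finite", call. = FALSE)
  n <- n_pre_frames + n_stim_frames + n_post_frames
  if (length(intensity) != n)
    stop(sprintf(paste0("trace length (%d) does not match the annotated ",
                        "windows (%d pre + %d stim + %d post = %d)"),
                 length(intensity), n_pre_frames, n_stim_frames,
                 n_post_frames, n), call. = FALSE)
  structure(list(intensity = intensity),
            roi_id = as.character(roi_id),
            frame_period_ms = frame_period_ms,
            n_pre_frames = as.integer(n_pre_frames),
            n_stim_frames = as.integer(n_stim_frames),
            n_post_frames = as.integer(n_post_frames),
            class = "fluorescence_trace")
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "Fluorescence trace %s: %d frames (%d pre / %d stim / %d post), %g ms/frame\n",
    attr(x, "roi_id"), length(x$intensity), attr(x, "n_pre_frames"),
    attr(x, "n_stim_frames"), attr(x, "n_post_frames"),
    attr(x, "frame_period_ms")))
  invisible(x)
}

#' Compute the relative fluorescence change (delta F / F, %)
#'
#' `F0` is the mean of five designated frames of the unstimulated (water)
#' phase — by default the five frames immediately preceding stimulation
#' onset, the choice that minimises the bleaching bias in the baseline.
#' `F_peak` is the raw maximum intensity during the stimulation window, and
#' \deqn{\Delta F/F\,(\%) = 100\,(F_{peak} - F_0)/F_0.}
#' An optional moving-average pre-filter is available for the peak search
#' (off by default: single-frame maxima are what the formula describes).
#'
#' @param trace A [fluorescence_trace()].
#' @param f0_frames Integer vector of 0-based frame indices used for `F0`;
#'   default the last five pre-stimulus frames.
#' @param smooth_frames Width of a centred moving average applied before the
#'   peak search; 1 (default) means no smoothing.
#' @return A data.frame of class `dff_result` with one row: `roi_id`, `f0`,
#'   `f_peak`, `dff_percent`, `peak_frame` (0-based).
#' @export
compute_dff <- function(trace, f0_frames = NULL, smooth_frames = 1L) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  y <- trace$intensity
  n_pre <- attr(trace, "n_pre_frames")
  n_stim <- attr(trace, "n_stim_frames")
  if (is.null(f0_frames)) f0_frames <- (n_pre - 5L):(n_pre - 1L)
  f0_frames <- as.integer(f0_frames)
  if (any(f0_frames < 0L) || any(f0_frames >= n_pre))
    stop("`f0_frames` must lie inside the pre-stimulus window", call. = FALSE)
  f0 <- mean(y[f0_frames + 1L])
  if (!is.finite(f0) || f0 <= 0)
    stop("F0 is not positive; delta F / F is undefined", call. = FALSE)
  stim <- y[(n_pre + 1L):(n_pre + n_stim)]
  if (smooth_frames > 1L)
    stim <- as.numeric(stats::filter(stim, rep(1 / smooth_frames,
                                               smooth_frames), sides = 2))
  peak_rel <- which.max(stim)
  f_peak <- stim[peak_rel]
  out <- data.frame(roi_id = attr(trace, "roi_id"), f0 = f0, f_peak = f_peak,
                    dff_percent = 100 * (f_peak - f0) / f0,
                    peak_frame = n_pre + peak_rel - 1L,
                    stringsAsFactors = FALSE)
  class(out) <- c("dff_result", "data.frame")
  out
}

#' Delta F / F for a collection of traces
#'
#' @param traces A list of [fluorescence_trace()] objects (as returned by
#'   [read_traces()]).
#' @param ... Passed to [compute_dff()].
#' @return A `dff_result` data.frame, one row per ROI.
#' @export
compute_dff_table <- function(traces, ...) {
  out <- do.call(rbind, lapply(traces, compute_dff, ...))
  rownames(out) <- NULL
  out
}

#' Water-only baseline distribution
#'
#' Each neuron class gets an individual baseline: the delta F / F values
#' measured when only water was applied, kept as a distribution (not reduced
#' to a scalar) to absorb bleaching and other biological variability in the
#' downstream response test.
#'
#' @param water_dff Numeric vector of water-only delta F / F values (>= 3).
#' @return An object of class `water_baseline`: list with the `sample`, `n`,
#'   `median` and `mad`.
#' @export
water_baseline <- function(water_dff) {
  stopifnot(is.numeric(water_dff))
  water_dff <- water_dff[is.finite(water_dff)]  # keeps animal-id names
  if (length(water_dff) < 3L)
    stop("need at least 3 water-only measurements for a baseline",
         call. = FALSE)
  structure(list(sample = water_dff, n = length(water_dff),
                 median = stats::median(water_dff),
                 mad = stats::mad(water_dff)),
            class = "water_baseline")
}

#' @export
print.water_baseline <- function(x, ...) {
  cat(sprintf("Water-only baseline: n = %d, median dF/F = %.2f%% (MAD %.2f)\n",
              x$n, x$median, x$mad))
  invisible(x)
}

#' Significance stars
#'
#' The three conventional levels: `*` for p < 0.05, `**` for p < 0.01,
#' `***` for p < 0.001, empty otherwise.
#'
#' @param p A p-value (vectorised).
#' @return Character vector of star strings.
#' @export
signif_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Test a tastant response against the water baseline
#'
#' Wilcoxon signed-rank test on paired differences when the two samples can
#' be paired (matching `names()` on both vectors, i.e. measurements from the
#' same animals); otherwise a Wilcoxon rank-sum test with a warning, since
#' unpaired samples cannot support a signed-rank analysis.
#'
#' @param tastant_dff Numeric vector of tastant delta F / F values; names are
#'   animal ids when available.
#' @param water_dff Numeric vector (or [water_baseline()]) of water-only
#'   values; names are animal ids when available.
#' @param alternative Passed to [stats::wilcox.test()] (default two-sided).
#' @param exact Logical or `NULL`; `NULL` uses an exact distribution for
#'   n < 25 (without ties) and the normal approximation otherwise.
#' @return A list of class `response_test`: `statistic`, `p_value`, `method`
#'   (`"signed-rank"` or `"rank-sum"`), `n`, `stars`.
#' @export
test_response <- function(tastant_dff, water_dff,
                          alternative = "two.sided", exact = NULL) {
  if (inherits(water_dff, "water_baseline")) water_dff <- water_dff$sample
  tastant_dff <- tastant_dff[is.finite(tastant_dff)]
  water_dff <- water_dff[is.finite(water_dff)]
  paired <- !is.null(names(tastant_dff)) && !is.null(names(water_dff)) &&
    length(intersect(names(tastant_dff), names(water_dff))) >= 3L
  if (paired) {
    ids <- intersect(names(tastant_dff), names(water_dff))
    x <- tastant_dff[ids]; y <- water_dff[ids]
    n <- length(ids)
    if (is.null(exact)) exact <- n < 25
    if (all(x == y)) {
      # every paired difference is zero: no evidence of any shift
      ht <- list(statistic = c(V = 0), p.value = 1)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                                alternative = alternative,
                                                exact = exact))
    }
    method <- "signed-rank"
  } else {
    if (length(tastant_dff) < 3L || length(water_dff) < 3L)
      stop("need at least 3 measurements per sample", call. = FALSE)
    warning("samples cannot be paired by animal id; ",
            "falling back to the rank-sum test", call. = FALSE)
    n <- min(length(tastant_dff), length(water_dff))
    if (is.null(exact)) exact <- n < 25
    ht <- suppressWarnings(stats::wilcox.test(tastant_dff, water_dff,
                                              paired = FALSE,
                                              alternative = alternative,
                                              exact = exact))
    method <- "rank-sum"
  }
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = method, n = n, stars = signif_stars(ht$p.value)),
            class = "response_test")
}

#' @export
print.response_test <- function(x, ...) {
  cat(sprintf("Wilcoxon %s test vs water baseline: V/W = %g, n = %d, p = %.4g %s\n",
              x$method, x$statistic, x$n, x$p_value, x$stars))
  invisible(x)
}
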