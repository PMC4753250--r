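#' Two-choice preference index
#'
#' The standard larval two-choice index,
#' \deqn{PI = (N_{stim} - N_{ctrl}) / (N_{stim} + N_{ctrl}),}
#' counting only larvae that left the neutral midline zone. An alternative
#' denominator including neutral animals is available.
#'
#' @param n_stimulus_side,n_control_side,n_neutral Non-negative counts
#'   (vectorised).
#' @param denominator `"sides"` (default: neutral larvae excluded) or
#'   `"total"`.
#' @return Numeric PI in `[-1, 1]`.
#' @examples
#' compute_pi(10, 20, 5)   # -1/3
#' @export
compute_pi <- function(n_stimulus_side, n_control_side, n_neutral = 0,
                       denominator = c("sides", "total")) {
  denominator <- match.arg(denominator)
  if (any(n_stimulus_side < 0) || any(n_control_side < 0) ||
      any(n_neutral < 0))
    stop("counts must be non-negative", call. = FALSE)
  sides <- n_stimulus_side + n_control_side
  if (any(sides == 0))
    stop("PI is undefined when no larva chose either side", call. = FALSE)
  den <- if (denominator == "sides") sides else sides + n_neutral
  (n_stimulus_side - n_control_side) / den
}

#' Per-assay preference indices
#'
#' @param counts A data.frame of two-choice counts ([read_choice()] /
#'   [simulate_two_choice()] schema).
#' @param ... Passed to [compute_pi()].
#' @return The input with columns `n_total` and `pi` appended.
#' @export
pi_table <- function(counts, ...) {
  counts$n_total <- counts$n_stimulus_side + counts$n_control_side +
    counts$n_neutral
  counts$pi <- compute_pi(counts$n_stimulus_side, counts$n_control_side,
                          counts$n_neutral, ...)
  counts
}

#' Compare two groups of preference indices
#'
#' Wilcoxon rank-sum test for independent groups, or signed-rank for paired
#' designs. P-values are exact for n < 25 per group (normal approximation
#' with continuity correction otherwise, and whenever ties preclude the
#' exact distribution).
#'
#' @param pis_a,pis_b Numeric samples of per-assay PIs (each n >= 3).
#' @param paired Logical, default `FALSE`.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A list of class `group_comparison`: `statistic`, `p_value`,
#'   `method`, `n_a`, `n_b`, `stars`.
#' @export
compare_groups <- function(pis_a, pis_b, paired = FALSE,
                           alternative = "two.sided") {
  pis_a <- pis_a[is.finite(pis_a)]; pis_b <- pis_b[is.finite(pis_b)]
  if (length(pis_a) < 3L || length(pis_b) < 3L)
    stop("need at least 3 assays per group", call. = FALSE)
  if (paired && length(pis_a) != length(pis_b))
    stop("paired comparison needs equal-length samples", call. = FALSE)
  exact <- max(length(pis_a), length(pis_b)) < 25
  ht <- suppressWarnings(stats::wilcox.test(pis_a, pis_b, paired = paired,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = if (paired) "signed-rank" else "rank-sum",
                 n_a = length(pis_a), n_b = length(pis_b),
                 stars = signif_stars(ht$p.value)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon %s test: W/V = %g (n = %d vs %d), p = %.4g %s\n",
              x$method, x$statistic, x$n_a, x$n_b, x$p_value, x$stars))
  invisible(x)
}

#' Pairwise group comparisons
#'
#' All pairwise Wilcoxon rank-sum comparisons between groups of assays, one
#' row per pair — the layout used for multi-genotype designs (control,
#' driver-only, effector-only, ablated).
#'
#' @param counts A counts data.frame with a `group` column.
#' @param ... Passed to [compare_groups()].
#' @return A data.frame with columns `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `stars`.
#' @export
compare_all_groups <- function(counts, ...) {
  counts <- pi_table(counts)
  groups <- sort(unique(counts$group))
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(groups, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    cmp <- compare_groups(counts$pi[counts$group == ga],
                          counts$pi[counts$group == gb], ...)
    data.frame(group_a = ga, group_b = gb, n_a = cmp$n_a, n_b = cmp$n_b,
               statistic = cmp$statistic, p_value = cmp$p_value,
               stars = cmp$stars, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate two-choice assay counts
#'
#' Each assay draws `n_larvae` animals from a multinomial over (neutral,
#' stimulus side, control side) with probabilities
#' `(p_neutral, (1 - p_neutral) * p, (1 - p_neutral) * (1 - p))`.
#'
#' @param true_p_stimulus_side Probability that a non-neutral larva ends on
#'   the stimulus side.
#' @param n_larvae Larvae per assay (default 30).
#' @param n_assays Number of assays.
#' @param p_neutral Probability of staying in the neutral zone (default 0.1).
#' @param seed Non-negative integer seed.
#' @param group Optional group label attached to every row.
#' @return A data.frame with columns `assay_id`, `n_stimulus_side`,
#'   `n_control_side`, `n_neutral` (and `group` when given).
#' @export
simulate_two_choice <- function(true_p_stimulus_side, n_larvae = 30,
                                n_assays = 15, p_neutral = 0.1, seed = 0L,
                                group = NULL) {
  p <- true_p_stimulus_side
  stopifnot(p >= 0, p <= 1, p_neutral >= 0, p_neutral < 1, n_larvae >= 1,
            n_assays >= 1)
  set.seed(seed)
  draws <- stats::rmultinom(n_assays, n_larvae,
                            c(p_neutral, (1 - p_neutral) * p,
                              (1 - p_neutral) * (1 - p)))
  out <- data.frame(assay_id = sprintf("assay%03d", seq_len(n_assays)),
                    n_stimulus_side = draws[2L, ],
                    n_control_side = draws[3L, ],
                    n_neutral = draws[1L, ],
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group
  out
}
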