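#' Simulation specification
#'
#' Study-scale parameters for a simulated optogenetic session: population
#' size, duration, and the stimulus program. The defaults mirror a typical
#' flicker experiment — on the order of 120 animals tracked at 4 Hz under a
#' fair Bernoulli flicker.
#'
#' @param n_animals Number of larvae (default 120).
#' @param duration_s Session length in seconds (default 600).
#' @param stimulus_kind One of `"bernoulli"`, `"step"`, `"constant"`.
#' @param bernoulli_p Per-frame ON probability for the Bernoulli flicker.
#' @param step_onset_s Light-ON time for the step stimulus, in seconds.
#' @param seed Non-negative integer seed; every generator in this package is
#'   a pure function of its parameters and this seed.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_animals = 120, duration_s = 600,
                            stimulus_kind = c("bernoulli", "step", "constant"),
                            bernoulli_p = 0.5, step_onset_s = 30, seed = 0L) {
  stimulus_kind <- match.arg(stimulus_kind)
  stopifnot(is.numeric(n_animals), n_animals >= 1,
            is.numeric(duration_s), duration_s > 0,
            is.numeric(bernoulli_p), is.numeric(step_onset_s),
            is.numeric(seed), seed >= 0)
  if (stimulus_kind == "bernoulli" && (bernoulli_p <= 0 || bernoulli_p >= 1))
    stop("`bernoulli_p` must lie strictly inside (0, 1)", call. = FALSE)
  structure(list(n_animals = as.integer(n_animals), duration_s = duration_s,
                 stimulus_kind = stimulus_kind, bernoulli_p = bernoulli_p,
                 step_onset_s = step_onset_s, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Linear-nonlinear hazard model parameters
#'
#' The generative model of the run/turn switch: each animal is a two-state
#' chain whose per-frame transition probability is a baseline hazard scaled
#' by an exponential nonlinearity of the linearly filtered (+/-1 encoded)
#' stimulus,
#' \deqn{P(\mathrm{run \to turn\ at\ } t) =
#'   \min\!\big(1-\epsilon,\ \lambda_{rt}\,\Delta t\,
#'   \exp\!\big(\textstyle\sum_l k_l\, s_{t-l}\big)\big),}
#' and analogously for turn-to-run with the kernel scaled by
#' `turn_filter_sign`. Under a Bernoulli stimulus the triggered average at
#' lag \eqn{-l} equals \eqn{\tanh(k_l)}, so filter recovery by reverse
#' correlation is exact up to that saturating distortion.
#'
#' @param baseline_run_to_turn_hazard Baseline run-to-turn rate, per second.
#'   Default 0.1 (10 s mean runs).
#' @param baseline_turn_to_run_hazard Baseline turn-to-run rate, per second.
#'   Default 0.5 (2 s mean turns).
#' @param filter_kernel Numeric vector of log-hazard gains over lags
#'   `0..L` frames (units: log-hazard per unit +/-1 stimulus). Default: the
#'   aversive kernel [exp_decay_kernel()].
#' @param nonlinearity Only `"exponential"` is implemented.
#' @param turn_filter_sign Multiplier applied to the kernel for the
#'   turn-to-run hazard; the default -1 makes light that promotes turn
#'   initiation also prolong turns, mirroring opposing run/turn trends.
#' @return An object of class `lnp_params`.
#' @export
lnp_params <- function(baseline_run_to_turn_hazard = 0.1,
                       baseline_turn_to_run_hazard = 0.5,
                       filter_kernel = exp_decay_kernel(),
                       nonlinearity = "exponential",
                       turn_filter_sign = -1) {
  nonlinearity <- match.arg(nonlinearity, "exponential")
  if (!is.numeric(filter_kernel) || length(filter_kernel) < 1L ||
      any(!is.finite(filter_kernel)))
    stop("`filter_kernel` must be a finite numeric vector of length >= 1",
         call. = FALSE)
  stopifnot(is.numeric(baseline_run_to_turn_hazard),
            baseline_run_to_turn_hazard >= 0,
            is.numeric(baseline_turn_to_run_hazard),
            baseline_turn_to_run_hazard >= 0,
            is.numeric(turn_filter_sign), length(turn_filter_sign) == 1L)
  structure(list(baseline_run_to_turn_hazard = baseline_run_to_turn_hazard,
                 baseline_turn_to_run_hazard = baseline_turn_to_run_hazard,
                 filter_kernel = as.numeric(filter_kernel),
                 nonlinearity = nonlinearity,
                 turn_filter_sign = turn_filter_sign),
            class = "lnp_params")
}

#' Decaying-exponential stimulus kernel
#'
#' The default "aversive" ground-truth filter: positive log-hazard gain that
#' decays exponentially with lag, so recent light drives turn initiation.
#'
#' @param amplitude Gain at lag 0 (log-hazard per unit stimulus). Default 0.4.
#' @param tau_s Decay time constant in seconds. Default 1.
#' @param length_s Kernel support in seconds. Default 5.
#' @param frame_rate_hz Frame rate used to discretise the lags. Default 4.
#' @return Numeric vector of kernel values over lags `0..length_s*frame_rate_hz`.
#' @export
exp_decay_kernel <- function(amplitude = 0.4, tau_s = 1, length_s = 5,
                             frame_rate_hz = 4) {
  lags <- seq.int(0L, as.integer(round(length_s * frame_rate_hz)))
  amplitude * exp(-(lags / frame_rate_hz) / tau_s)
}

#' Filtered stimulus drive
#'
#' Causal convolution of the +/-1 encoded stimulus with the kernel,
#' `drive[t] = sum_l k[l] * s[t - l]`, with pre-session history imputed as
#' OFF (-1): animals are dark-reared before stimulation.
#'
#' @param signal Encoded +/-1 stimulus vector.
#' @param kernel Kernel over lags `0..L`.
#' @param history Value imputed for frames before the session (default -1).
#' @return Numeric vector, same length as `signal`.
#' @export
filter_drive <- function(signal, kernel, history = -1) {
  L <- length(kernel) - 1L
  padded <- c(rep(history, L), signal)
  out <- stats::filter(padded, kernel, method = "convolution", sides = 1)
  as.numeric(out[(L + 1L):length(padded)])
}

# trusted fast path: rows already sorted/validated
new_behavior_tracks <- function(animal_id, frame, state, valid) {
  df <- data.frame(animal_id = animal_id, frame = frame, state = state,
                   valid = valid, stringsAsFactors = FALSE)
  class(df) <- c("behavior_tracks", "data.frame")
  df
}

#' Simulate a larval population under a stimulus
#'
#' Forward-simulates independent two-state (run/turn) chains under the
#' linear-nonlinear hazard model of [lnp_params()]. All animals share the
#' session stimulus (one arena, one LED panel) and start in the RUN state.
#' Per-frame transition probabilities exceeding 1 are clipped at
#' \eqn{1 - 10^{-6}}; if more than 1% of frame probabilities needed
#' clipping a warning reports the fraction.
#'
#' @param params An [lnp_params()] object.
#' @param spec A [simulation_spec()]; supplies `n_animals` and `seed`.
#' @param stimulus A [stimulus_trace()] covering the session.
#' @param config An [acq_config()]; must match the stimulus frame rate.
#' @return A [behavior_tracks()] object, all frames valid, with attribute
#'   `clip_fraction` (fraction of frame hazards clipped).
#' @export
simulate_population <- function(params, spec, stimulus,
                                config = acq_config()) {
  stopifnot(inherits(params, "lnp_params"), inherits(spec, "simulation_spec"),
            inherits(stimulus, "stimulus_trace"))
  fr <- config$frame_rate_hz
  if (!isTRUE(all.equal(fr, frame_rate(stimulus))))
    stop("stimulus frame rate does not match the configuration", call. = FALSE)
  dt <- 1 / fr
  n_t <- nrow(stimulus)
  n_a <- spec$n_animals
  s <- encode_stimulus(stimulus)
  drive <- filter_drive(s, params$filter_kernel)

  p_rt_raw <- params$baseline_run_to_turn_hazard * dt * exp(drive)
  p_tr_raw <- params$baseline_turn_to_run_hazard * dt *
    exp(params$turn_filter_sign * drive)
  eps <- 1e-6
  clip_frac <- mean(c(p_rt_raw >= 1, p_tr_raw >= 1))
  if (clip_frac > 0.01)
    warning(sprintf(
      "%.1f%% of per-frame hazards exceeded 1 and were clipped at 1 - 1e-6",
      100 * clip_frac), call. = FALSE)
  p_rt <- pmin(p_rt_raw, 1 - eps)
  p_tr <- pmin(p_tr_raw, 1 - eps)

  set.seed(spec$seed)
  run <- matrix(NA, nrow = n_a, ncol = n_t)  # TRUE = RUN
  cur <- rep(TRUE, n_a)
  run[, 1L] <- cur
  if (n_t > 1L) {
    for (t in 2:n_t) {
      u <- stats::runif(n_a)
      flip <- (cur & u < p_rt[t]) | (!cur & u < p_tr[t])
      cur <- xor(cur, flip)
      run[, t] <- cur
    }
  }

  ids <- sprintf("a%03d", seq_len(n_a))
  run_by_animal <- as.vector(t(run))  # frames within animal 1, then animal 2, ...
  out <- new_behavior_tracks(
    animal_id = rep(ids, each = n_t),
    frame = rep(stimulus$frame, times = n_a),
    state = c("TURN", "RUN")[run_by_animal + 1L],
    valid = rep(TRUE, n_a * n_t))
  attr(out, "clip_fraction") <- clip_frac
  out
}

#' Write the ground truth of a simulated session
#'
#' Emits a JSON sidecar with the kernel, hazards and seed so that filter
#' recovery can be checked against what generated the data.
#'
#' @param params An [lnp_params()].
#' @param spec A [simulation_spec()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(params, spec, path) {
  jsonlite::write_json(
    list(baseline_run_to_turn_hazard = params$baseline_run_to_turn_hazard,
         baseline_turn_to_run_hazard = params$baseline_turn_to_run_hazard,
         filter_kernel = params$filter_kernel,
         nonlinearity = params$nonlinearity,
         turn_filter_sign = params$turn_filter_sign,
         n_animals = spec$n_animals, duration_s = spec$duration_s,
         stimulus_kind = spec$stimulus_kind,
         bernoulli_p = spec$bernoulli_p, step_onset_s = spec$step_onset_s,
         seed = spec$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
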