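#' Calcium-trace simulation parameters
#'
#' Generative model for synthetic fluorescence traces under the
#' wash/stimulation/wash protocol:
#' \deqn{F_t = F_0\,\beta^t + F_0\,A\,h(t - t_{on}) + \varepsilon_t,}
#' with multiplicative per-frame bleaching \eqn{\beta}, a double-exponential
#' stimulus-locked transient \eqn{h} (normalised to continuous-time peak 1)
#' present only in responders, and i.i.d. Gaussian noise.
#'
#' @param f0_level Baseline intensity, arbitrary units (default 100).
#' @param response_amplitude Transient peak as a fraction of `f0_level`
#'   (default 0.5, i.e. a 50% delta F / F response).
#' @param bleach_rate Per-frame multiplicative decay (default 0.9995;
#'   roughly 18% loss over a 400-frame measurement).
#' @param noise_sd Gaussian noise SD in intensity units (default 2).
#' @param n_pre_frames,n_stim_frames,n_post_frames Protocol windows
#'   (defaults 100 / 200 / 100 frames at 85 ms per frame).
#' @param rise_tau_frames,decay_tau_frames Transient time constants in
#'   frames (defaults 3 and 25, i.e. ~0.26 s rise and ~2.1 s decay — a slow
#'   genetically encoded indicator under sustained tastant stimulation).
#' @return An object of class `calcium_sim_params`.
#' @export
calcium_sim_params <- function(f0_level = 100, response_amplitude = 0.5,
                               bleach_rate = 0.9995, noise_sd = 2,
                               n_pre_frames = 100, n_stim_frames = 200,
                               n_post_frames = 100, rise_tau_frames = 3,
                               decay_tau_frames = 25) {
  stopifnot(f0_level > 0, bleach_rate > 0, bleach_rate <= 1, noise_sd >= 0,
            rise_tau_frames > 0, decay_tau_frames > rise_tau_frames,
            n_pre_frames >= 5, n_stim_frames >= 1, n_post_frames >= 0)
  structure(list(f0_level = f0_level,
                 response_amplitude = response_amplitude,
                 bleach_rate = bleach_rate, noise_sd = noise_sd,
                 n_pre_frames = as.integer(n_pre_frames),
                 n_stim_frames = as.integer(n_stim_frames),
                 n_post_frames = as.integer(n_post_frames),
                 rise_tau_frames = rise_tau_frames,
                 decay_tau_frames = decay_tau_frames),
            class = "calcium_sim_params")
}

#' Normalised double-exponential transient
#'
#' `h(d) = (exp(-d/tau_decay) - exp(-d/tau_rise)) / peak` for `d >= 0`
#' (0 before onset), normalised so the continuous-time peak equals 1.
#'
#' @param d Frames since stimulation onset (may be negative).
#' @param rise_tau_frames,decay_tau_frames Time constants in frames.
#' @return Transient values, same length as `d`.
#' @export
calcium_transient <- function(d, rise_tau_frames, decay_tau_frames) {
  tr <- rise_tau_frames; td <- decay_tau_frames
  t_star <- log(td / tr) * tr * td / (td - tr)
  peak <- exp(-t_star / td) - exp(-t_star / tr)
  ifelse(d >= 0, (exp(-d / td) - exp(-d / tr)) / peak, 0)
}

#' Simulate a fluorescence trace
#'
#' @param params A [calcium_sim_params()].
#' @param responder Logical; if `TRUE` the trace carries a stimulus-locked
#'   transient of amplitude `response_amplitude`.
#' @param seed Non-negative integer seed.
#' @param roi_id Identifier for the trace.
#' @return A [fluorescence_trace()].
#' @export
simulate_calcium_trace <- function(params, responder = TRUE, seed = 0L,
                                   roi_id = "roi1") {
  stopifnot(inherits(params, "calcium_sim_params"))
  if (responder && params$response_amplitude < 0)
    stop("a responder needs a non-negative `response_amplitude`",
         call. = FALSE)
  n <- params$n_pre_frames + params$n_stim_frames + params$n_post_frames
  t <- seq.int(0L, n - 1L)
  set.seed(seed)
  y <- params$f0_level * params$bleach_rate^t
  if (responder && params$response_amplitude > 0) {
    d <- t - params$n_pre_frames
    y <- y + params$f0_level * params$response_amplitude *
      calcium_transient(d, params$rise_tau_frames, params$decay_tau_frames)
  }
  if (params$noise_sd > 0) y <- y + stats::rnorm(n, 0, params$noise_sd)
  fluorescence_trace(pmax(y, 0), roi_id = roi_id,
                     n_pre_frames = params$n_pre_frames,
                     n_stim_frames = params$n_stim_frames,
                     n_post_frames = params$n_post_frames)
}
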