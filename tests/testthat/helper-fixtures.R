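# Shared fixtures and independent oracles.

make_tracks_df <- function() {
  data.frame(
    animal_id = rep(c("a1", "a2"), each = 8),
    frame = rep(0:7, 2),
    state = c("RUN", "RUN", "RUN", "TURN", "TURN", "RUN", "RUN", "RUN",
              "TURN", "TURN", "RUN", "RUN", "RUN", "RUN", "TURN", "TURN"),
    valid = TRUE, stringsAsFactors = FALSE)
}

write_fixture_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

# Independent brute-force triggered average: explicit per-event, per-lag
# loops, with the per-frame duplicate grouping done by hand.
ta_oracle <- function(stimulus, events, kind, window_s, config) {
  fr <- attr(stimulus, "frame_rate_hz")
  W <- as.integer(round(window_s * fr))
  s <- ifelse(stimulus$led_state == 1, 1, -1)
  f0 <- stimulus$frame[1]
  ev <- events$frame[events$kind == kind] - f0
  ev <- ev[ev >= W & ev < length(s)]
  n <- length(ev)
  lags <- (-W):0
  mu <- sem <- numeric(length(lags))
  for (j in seq_along(lags)) {
    acc <- 0
    for (e in ev) acc <- acc + s[e + lags[j] + 1]
    mu[j] <- acc / n
    if (n > 1) {
      frames <- ev + lags[j]
      ss <- 0
      for (f in sort(unique(frames))) {
        cl <- 0
        for (e in ev) if (e + lags[j] == f) cl <- cl + (s[f + 1] - mu[j])
        ss <- ss + cl^2
      }
      sem[j] <- sqrt(ss / (n - 1)) / sqrt(n)
    }
  }
  list(lags_s = lags / fr, mean = mu, sem = sem, n_events = n)
}

# Random stimulus + random event fixture for oracle-equivalence tests.
random_ta_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(80:300, 1)
  stim <- stimulus_trace(rbinom(n, 1, runif(1, 0.2, 0.8)))
  n_ev <- sample(5:50, 1)
  ev <- data.frame(animal_id = sprintf("a%02d", sample(1:8, n_ev, TRUE)),
                   frame = sample(0:(n - 1), n_ev, replace = TRUE),
                   kind = sample(c("RUN_TO_TURN", "TURN_TO_RUN"), n_ev, TRUE),
                   stringsAsFactors = FALSE)
  class(ev) <- c("transition_events", "data.frame")
  list(stimulus = stim, events = ev,
       window_s = sample(2:6, 1) / attr(stim, "frame_rate_hz") * 2)
}

# Simulate one full flicker session and return its pieces.
simulate_session <- function(seed, params = lnp_params(),
                             n_animals = 120, duration_s = 600,
                             config = acq_config()) {
  spec <- simulation_spec(n_animals = n_animals, duration_s = duration_s,
                          seed = seed)
  stim <- generate_bernoulli_stimulus(spec, config)
  tracks <- simulate_population(params, spec, stim, config)
  list(spec = spec, stimulus = stim, tracks = tracks,
       events = detect_transitions(tracks))
}

water_dff_sample <- function(n, seed_base, params = calcium_sim_params()) {
  x <- vapply(seq_len(n), function(j) {
    compute_dff(simulate_calcium_trace(params, responder = FALSE,
                                       seed = seed_base + j))$dff_percent
  }, numeric(1))
  names(x) <- paste0("an", seq_len(n))
  x
}
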