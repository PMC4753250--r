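cfg <- acq_config()

test_that("Bernoulli stimulus is a fair white process", {
  spec <- simulation_spec(duration_s = 25000, seed = 11)  # 1e5 frames at 4 Hz
  stim <- generate_bernoulli_stimulus(spec, cfg)
  s <- encode_stimulus(stim)
  n <- length(s)
  expect_equal(n, 1e5)
  expect_true(all(s %in% c(-1, 1)))
  # binomial CI on the mean at n = 1e5
  expect_lt(abs(mean(s)), 0.01)
  # lag-1 autocorrelation of a white process
  r1 <- cor(s[-n], s[-1])
  expect_lt(abs(r1), 3 / sqrt(n))
  # chi-square goodness of fit for P(ON) = 1/2
  expect_gt(chisq.test(table(stim$led_state), p = c(0.5, 0.5))$p.value, 0.001)
})

test_that("Bernoulli stimulus respects its probability parameter", {
  spec <- simulation_spec(duration_s = 250, bernoulli_p = 0.999, seed = 2)
  stim <- generate_bernoulli_stimulus(spec, cfg)
  expect_gt(mean(stim$led_state), 0.98)
  expect_error(generate_bernoulli_stimulus(
    simulation_spec(bernoulli_p = 0.5, seed = 1), cfg), NA)
  expect_error(simulation_spec(bernoulli_p = 1), "bernoulli_p")
  expect_error(simulation_spec(bernoulli_p = 0), "bernoulli_p")
})

test_that("step stimulus has exactly one OFF-to-ON transition", {
  spec <- simulation_spec(duration_s = 60, stimulus_kind = "step",
                          step_onset_s = 30, seed = 1)
  stim <- generate_step_stimulus(spec, cfg)
  expect_equal(stim$led_state[1:120], rep(0L, 120))
  expect_equal(stim$led_state[121:240], rep(1L, 120))
  expect_equal(sum(diff(encode_stimulus(stim)) != 0), 1)

  all_on <- generate_step_stimulus(
    simulation_spec(duration_s = 10, stimulus_kind = "step",
                    step_onset_s = 0, seed = 1), cfg)
  expect_true(all(all_on$led_state == 1L))
  expect_error(generate_step_stimulus(
    simulation_spec(duration_s = 10, stimulus_kind = "step",
                    step_onset_s = 10, seed = 1), cfg), "onset")
})

test_that("population simulator reproduces its baseline hazard", {
  params <- lnp_params(baseline_run_to_turn_hazard = 0.1,
                       filter_kernel = 0)
  ses <- simulate_session(5, params)
  ev <- ses$events
  run_frames <- sum(ses$tracks$state == "RUN")
  rate <- sum(ev$kind == "RUN_TO_TURN") / (run_frames / cfg$frame_rate_hz)
  n_rt <- sum(ev$kind == "RUN_TO_TURN")
  se <- rate / sqrt(n_rt)  # Poisson-rate standard error
  expect_lt(abs(rate - 0.1), 3 * se)
})

test_that("zero baseline hazard means no run-to-turn transitions", {
  params <- lnp_params(baseline_run_to_turn_hazard = 0, filter_kernel = 0)
  ses <- simulate_session(3, params, n_animals = 20, duration_s = 120)
  expect_equal(sum(ses$events$kind == "RUN_TO_TURN"), 0)
  expect_true(all(ses$tracks$state == "RUN"))
})

test_that("simulators are pure functions of parameters and seed", {
  s1 <- simulate_session(9, n_animals = 10, duration_s = 60)
  s2 <- simulate_session(9, n_animals = 10, duration_s = 60)
  expect_identical(s1$stimulus, s2$stimulus)
  expect_identical(s1$tracks, s2$tracks)
  t1 <- simulate_calcium_trace(calcium_sim_params(), TRUE, seed = 4)
  t2 <- simulate_calcium_trace(calcium_sim_params(), TRUE, seed = 4)
  expect_identical(t1$intensity, t2$intensity)
  expect_identical(simulate_two_choice(0.6, n_assays = 5, seed = 8),
                   simulate_two_choice(0.6, n_assays = 5, seed = 8))
})

test_that("run lengths under a flat hazard are exponential with mean 1/rate", {
  lambda <- 0.1
  params <- lnp_params(baseline_run_to_turn_hazard = lambda,
                       baseline_turn_to_run_hazard = 2, filter_kernel = 0)
  ses <- simulate_session(21, params, n_animals = 400, duration_s = 400)
  ev <- ses$events
  # run lengths: frames between a TURN_TO_RUN and the next RUN_TO_TURN
  # restrict to runs starting >100 s before session end: completion is then
  # near-certain (P(censored) < e^-10) and the sample is selection-free
  runs <- unlist(lapply(split(ev, ev$animal_id), function(e) {
    e <- e[order(e$frame), ]
    starts <- e$frame[e$kind == "TURN_TO_RUN"]
    starts <- starts[starts < (400 - 100) * 4]
    ends <- e$frame[e$kind == "RUN_TO_TURN"]
    lens <- vapply(starts, function(s) {
      nxt <- ends[ends > s]
      if (length(nxt)) nxt[1] - s else NA_integer_
    }, numeric(1))
    lens[!is.na(lens)]
  }))
  expect_gt(length(runs), 1e4)
  expect_lt(abs(mean(runs) / 4 - 1 / lambda),
            3 * sd(runs) / 4 / sqrt(length(runs)))
  # the per-frame chain gives geometric run lengths with per-frame
  # probability lambda*dt; reconstruct continuous event times (uniform
  # within-frame jitter) and KS-test the exponential shape at the exactly
  # corresponding continuous rate -fr*log(1 - lambda*dt)
  set.seed(1)
  t_cont <- (runs - runif(length(runs))) / 4
  ks <- suppressWarnings(ks.test(t_cont, "pexp", -4 * log(1 - lambda / 4)))
  expect_gt(ks$p.value, 0.01)
})

test_that("hazard clipping is reported when the nonlinearity saturates", {
  params <- lnp_params(baseline_run_to_turn_hazard = 10,
                       filter_kernel = c(3, 2))
  spec <- simulation_spec(n_animals = 5, duration_s = 30, seed = 1)
  stim <- generate_bernoulli_stimulus(spec, cfg)
  expect_warning(simulate_population(params, spec, stim, cfg), "clipped")
  expect_error(lnp_params(filter_kernel = c(0.1, NaN)), "finite")
})

test_that("synthetic calcium traces follow their generative closed form", {
  cp <- calcium_sim_params(noise_sd = 0, bleach_rate = 1)
  flat <- simulate_calcium_trace(cp, responder = FALSE, seed = 1)
  expect_equal(flat$intensity, rep(100, 400))
  resp <- simulate_calcium_trace(cp, responder = TRUE, seed = 1)
  d <- seq_along(resp$intensity) - 1 - 100
  expect_equal(resp$intensity,
               100 + 100 * 0.5 * calcium_transient(d, 3, 25))
})

test_that("two-choice counts are multinomial draws that conserve larvae", {
  counts <- simulate_two_choice(0.7, n_larvae = 30, n_assays = 50,
                                p_neutral = 0.2, seed = 6)
  expect_true(all(counts$n_stimulus_side + counts$n_control_side +
                    counts$n_neutral == 30))
  sure <- simulate_two_choice(1, n_larvae = 30, n_assays = 10,
                              p_neutral = 0, seed = 7)
  expect_true(all(pi_table(sure)$pi == 1))
  # symmetric case: mean PI near 0 over many assays
  sym <- pi_table(simulate_two_choice(0.5, n_larvae = 30, n_assays = 1e4,
                                      p_neutral = 0, seed = 8))
  se <- sd(sym$pi) / sqrt(nrow(sym))
  expect_lt(abs(mean(sym$pi)), 3 * se)
})
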