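test_that("delta F / F follows its defining arithmetic", {
  const <- fluorescence_trace(rep(200, 400))
  expect_equal(compute_dff(const)$dff_percent, 0)

  y <- rep(100, 400); y[150] <- 150
  r <- compute_dff(fluorescence_trace(y))
  expect_equal(r$f0, 100)
  expect_equal(r$f_peak, 150)
  expect_equal(r$dff_percent, 50)
  expect_equal(r$peak_frame, 149)  # 0-based

  # F0 uses the five frames immediately preceding stimulation by default
  y2 <- c(rep(50, 95), rep(100, 5), rep(120, 200), rep(50, 100))
  expect_equal(compute_dff(fluorescence_trace(y2))$f0, 100)
  expect_equal(compute_dff(fluorescence_trace(y2),
                           f0_frames = 0:4)$f0, 50)
  expect_error(compute_dff(fluorescence_trace(y2), f0_frames = 100:104),
               "pre-stimulus")

  # the peak is searched only inside the stimulation window
  y3 <- rep(100, 400); y3[350] <- 500
  expect_equal(compute_dff(fluorescence_trace(y3))$dff_percent, 0)

  expect_error(fluorescence_trace(rep(1, 300)), "length")
  expect_error(compute_dff(fluorescence_trace(rep(0, 400))), "F0")
})

test_that("noise-free synthetic responders match the transient closed form", {
  for (amp in c(0.2, 0.5, 1)) {
    cp <- calcium_sim_params(noise_sd = 0, bleach_rate = 1,
                             response_amplitude = amp)
    r <- compute_dff(simulate_calcium_trace(cp, TRUE, seed = 1))
    peak_disc <- max(calcium_transient(0:199, cp$rise_tau_frames,
                                       cp$decay_tau_frames))
    expect_equal(r$dff_percent, 100 * amp * peak_disc)
  }
})

test_that("delta F / F is gain-invariant but not offset-invariant", {
  cp <- calcium_sim_params()
  for (seed in 1:100) {
    tr <- simulate_calcium_trace(cp, responder = seed %% 2 == 0, seed = seed)
    gain <- exp(runif(1, -2, 2))
    scaled <- fluorescence_trace(tr$intensity * gain)
    expect_equal(compute_dff(scaled)$dff_percent,
                 compute_dff(tr)$dff_percent)
  }
  # additive offset k rescales dff by f0 / (f0 + k)
  y <- rep(100, 400); y[150] <- 150
  base <- compute_dff(fluorescence_trace(y))$dff_percent
  shifted <- compute_dff(fluorescence_trace(y + 100))$dff_percent
  expect_equal(shifted, base * 100 / 200)
})

test_that("water baseline keeps the distribution and reflects bleaching", {
  wb <- water_baseline(c(1, -2, 3))
  expect_equal(wb$sample, c(1, -2, 3))
  expect_equal(wb$median, 1)
  expect_equal(water_baseline(c(0, 0, 0))$median, 0)
  expect_error(water_baseline(c(1, 2)), "at least 3")

  # bleaching-only traces: water dff centred on the bleach closed form
  b <- 0.999
  cp <- calcium_sim_params(noise_sd = 0, bleach_rate = b)
  d <- compute_dff(simulate_calcium_trace(cp, FALSE, seed = 1))$dff_percent
  f0 <- mean(100 * b^(95:99))
  expect_equal(d, 100 * (100 * b^100 - f0) / f0)
})

test_that("response test pairs by animal id and maps p-values to stars", {
  x <- c(an1 = 10, an2 = 12, an3 = 9, an4 = 11, an5 = 10.5)
  expect_gt(test_response(x, x)$p_value, 0.9)
  expect_equal(test_response(x, x)$stars, "")
  expect_equal(test_response(x, x)$method, "signed-rank")

  # unpaired samples fall back to the rank-sum test with a warning
  expect_warning(
    res <- test_response(unname(x), unname(x + 1)), "rank-sum")
  expect_equal(res$method, "rank-sum")

  expect_equal(signif_stars(c(0.2, 0.04, 0.004, 0.0004, 0.03)),
               c("", "*", "**", "***", "*"))
})

test_that("water-vs-water signed-rank test holds its nominal size", {
  cp <- calcium_sim_params()
  n_rep <- 1000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    w1 <- water_dff_sample(10, 40000 + 20 * i, cp)
    w2 <- water_dff_sample(10, 40000 + 20 * i + 10, cp)
    if (test_response(w1, water_baseline(w2))$p_value < 0.05)
      rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("moderate responders are detected against the water baseline", {
  resp_params <- calcium_sim_params(response_amplitude = 0.3)
  null_params <- calcium_sim_params()
  n_rep <- 100
  hits <- 0L
  for (i in seq_len(n_rep)) {
    r <- vapply(1:8, function(j) {
      compute_dff(simulate_calcium_trace(resp_params, TRUE,
                                         seed = 90000 + 16 * i + j))$dff_percent
    }, numeric(1))
    names(r) <- paste0("an", 1:8)
    w <- water_dff_sample(8, 90000 + 16 * i + 8, null_params)
    if (test_response(r, w)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})
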