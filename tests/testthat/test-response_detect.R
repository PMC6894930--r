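test_that("a flat noiseless trace is never called a response", {
  flat <- rep(0, 300)
  act <- detect_activation(flat, 100, 200)
  expect_false(act$responded)
  expect_true(act$degenerate)     # zero baseline SD is flagged
  inh <- detect_inhibition(flat, 100, 200)
  expect_false(inh$responded)
})

test_that("activation calls match a brute-force evaluation on noisy steps", {
  set.seed(71)
  for (rep in 1:25) {
    x <- rnorm(300, sd = 0.05)
    onset <- sample(105:180, 1)
    x[(onset + 1):300] <- x[(onset + 1):300] + 10 * 0.05   # 10 sigma step
    sm <- smooth_trace(x)
    got <- detect_activation(sm, 100, 200)
    want <- oracle_detect_activation(sm, 100, 200)
    expect_true(got$responded)
    expect_identical(got$onset_frame, as.integer(want$onset_frame))
    # the 13-frame forward-looking magnitude window lets a call fire up
    # to act_window frames ahead of a strong step (a lenient 1 SD noise
    # derivative then suffices), never later than the step itself
    expect_gte(got$onset_frame, onset - 13)
    expect_lte(got$onset_frame, onset)
    expect_equal(got$latency_s, (got$onset_frame - 100) / 10)
  }
})

test_that("inhibition calls match brute force on declining scaled traces", {
  set.seed(72)
  for (rep in 1:25) {
    x <- 1 + rnorm(300, sd = 0.03)
    decline_at <- sample(100:150, 1)
    idx <- (decline_at + 1):300
    x[idx] <- x[idx] - pmin((seq_along(idx)) / 30, 1) * 1
    sc <- minmax_scale(smooth_trace(x))
    got <- detect_inhibition(sc, 100, 200)
    want <- oracle_detect_inhibition(sc$scaled, 100, 200)
    expect_true(got$responded)
    expect_identical(got$onset_frame, as.integer(want$onset_frame))
    # the 11-frame mean criterion needs a few frames of slow decline
    # before it clears the 2 SD threshold, and can anticipate it by a
    # few frames through the forward-looking window
    expect_lte(abs(got$onset_frame - decline_at), 12)
  }
})

test_that("raising a threshold multiplier never creates or advances a call", {
  set.seed(73)
  for (rep in 1:15) {
    x <- smooth_trace(rnorm(300, sd = 0.05) +
                        c(rep(0, 130), rep(runif(1, 0, 0.4), 170)))
    base <- detect_activation(x, 100, 200,
                              detection_params(act_mag_mult = 1.5,
                                               act_deriv_mult = 0.5))
    for (pars in list(detection_params(act_mag_mult = 2.5,
                                       act_deriv_mult = 0.5),
                      detection_params(act_mag_mult = 1.5,
                                       act_deriv_mult = 1.5))) {
      strict <- detect_activation(x, 100, 200, pars)
      if (!base$responded) expect_false(strict$responded)
      if (strict$responded) expect_gte(strict$onset_frame, base$onset_frame)
    }
  }
})

test_that("onsets whose look-ahead window would leave the trace are ineligible", {
  # strong step right at the end of the pulse: the 13-frame mean window
  # may dangle past stim_offset but never past the trace end
  x <- c(rep(0, 205), rep(5, 5))
  ens_call <- detect_activation(x + rnorm(210, sd = 1e-3), 100, 210,
                                detection_params(prestim_window = 100))
  if (ens_call$responded)
    expect_lte(ens_call$onset_frame + 12, 209)
})

test_that("threshold sweeps are monotone and plateau at the responder fraction", {
  cfg <- synthetic_config(n_traces = 40, responder_fraction = 0.5,
                          peak_amplitude = 1.5, noise_sd = 0.05, seed = 99)
  ens <- generate_ensemble(cfg)$ensemble
  mag_grid <- c(0.5, 1, 1.5, 2, 2.5, 3, 4)
  sweep <- threshold_sweep(ens, mag_grid, c(0, 0.5, 1), "activation")
  # stricter magnitude thresholds cannot add responses
  for (j in seq_len(ncol(sweep)))
    expect_true(all(diff(sweep[, j]) <= 0))
  # counts plateau near the true responder count over a wide band
  truth_n <- sum(generate_ensemble(cfg)$truth$responder)
  mid <- sweep[mag_grid >= 1.5 & mag_grid <= 3, ]
  expect_true(all(abs(mid - truth_n) <= 0.1 * n_traces(ens)))
  # at the default magnitude threshold the counts are derivative-insensitive
  at2 <- sweep[mag_grid == 2, ]
  expect_lte(max(at2) - min(at2), 2)

  null_ens <- generate_null_buffer(synthetic_config(n_traces = 40, seed = 98))
  nsweep <- threshold_sweep(null_ens, mag_grid, c(0, 1), "activation")
  for (j in seq_len(ncol(nsweep)))
    expect_true(all(diff(nsweep[, j]) <= 0))
  expect_error(threshold_sweep(ens, numeric(0), 1), "non-empty")
})

test_that("ensemble detection skips excluded traces and fills magnitudes", {
  cfg <- synthetic_config(n_traces = 10, responder_fraction = 1,
                          noise_sd = 0.02, seed = 55)
  g <- generate_ensemble(cfg)
  tr <- g$ensemble$traces
  tr[4, 17] <- NaN
  ens <- tiny_ensemble(tr, meta = g$ensemble$meta)
  calls <- detect_ensemble(ens, "activation")
  expect_true(is.na(calls$responded[4]))
  expect_true(all(calls$responded[-4]))
  expect_true(all(calls$magnitude[-4] > 0.5))
  expect_true(all(calls$rise_time_s[which(calls$responded)] >= 0))
})
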