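# The synthetic dyad generator: ground-truth coupling, envelopes,
# determinism and the kappa -> PLV dial.

test_that("speech envelope has the right length, support and rhythm", {
  env <- generate_speech_envelope(90, 250, 5, seed = 1)
  expect_length(env, 22500L)
  expect_true(all(env >= 0))
  # dominant fluctuation in the syllabic (theta) range
  pk <- peak_freq(as.numeric(env), 250, lo = 0.5, hi = 12)
  expect_gte(pk, 4); expect_lte(pk, 8)
  # a slower delta-range component is present: power at ~2 Hz well above
  # the spectral floor at ~9 Hz
  sp <- stats::spec.pgram(stats::ts(env - mean(env), frequency = 250),
                          taper = 0, spans = 21, plot = FALSE)
  p_at <- function(f) mean(sp$spec[abs(sp$freq - f) < 0.4])
  expect_gt(p_at(2), 5 * p_at(9))
  # determinism
  expect_identical(as.numeric(env), as.numeric(generate_speech_envelope(90, 250, 5, seed = 1)))
  expect_false(identical(as.numeric(env), as.numeric(generate_speech_envelope(90, 250, 5, seed = 2))))
  expect_error(generate_speech_envelope(-1, 250), "positive")
  expect_error(generate_speech_envelope(10, 250, syllable_rate = 12), "syllable_rate")
})

test_that("a session has 11 epochs per participant with the right roles", {
  cfg <- tiny_cfg(n_topics = 5)
  ses <- generate_dyad_session(cfg, 1)
  for (p in c("A", "B")) {
    expect_length(ses$epochs[[p]]$epochs, 11L)
    roles <- vapply(ses$epochs[[p]]$epochs, `[[`, character(1), "role")
    expect_equal(sum(roles == "speak"), 5L)
    expect_equal(sum(roles == "listen"), 5L)
    expect_equal(sum(roles == "rest"), 1L)
  }
  expect_length(ses$envelopes, 10L)  # one per speaking turn
})

test_that("sessions are bit-identical under a fixed config and seed", {
  cfg <- tiny_cfg(coupling = data.frame(listener = 1, speaker = 2,
                                        band = "alpha", kappa = 0.5))
  s1 <- generate_dyad_session(cfg, 2)
  s2 <- generate_dyad_session(cfg, 2)
  expect_identical(s1$epochs$A$epochs, s2$epochs$A$epochs)
  expect_identical(s1$envelopes, s2$envelopes)
  # different dyads differ
  s3 <- generate_dyad_session(cfg, 1)
  expect_false(identical(s1$epochs$A$epochs[[1]]$data, s3$epochs$A$epochs[[1]]$data))
})

test_that("full coupling with no noise produces near-perfect phase locking", {
  cfg <- synth_config(n_dyads = 1, n_channels = 2, epoch_len = 20, n_topics = 2,
                      bands = tiny_bands(), noise_sd = 0, phase_noise_sd = 0,
                      coupling = data.frame(listener = 1, speaker = 2,
                                            band = "alpha", kappa = 1),
                      seed = 3)
  ses <- generate_dyad_session(cfg, 1)
  tens <- interbrain_plv(ses$epochs$B, ses$epochs$A, tiny_bands(), trim = 250)
  expect_gt(min(tens[1, 2, "alpha", c("topic1", "topic2")]), 0.95)
  # rest epochs carry no cross-participant coupling
  expect_lt(tens[1, 2, "alpha", "rest"], 0.95)
})

test_that("mean PLV of coupled pairs is non-decreasing in kappa", {
  kappas <- c(0, 0.25, 0.5, 1)
  means <- vapply(kappas, function(k) {
    cfg <- synth_config(n_dyads = 10, n_channels = 2, epoch_len = 10, n_topics = 2,
                        bands = tiny_bands(),
                        coupling = if (k > 0) data.frame(listener = 1, speaker = 2,
                                                         band = "alpha", kappa = k),
                        seed = 99)
    vals <- vapply(1:10, function(d) {
      ses <- generate_dyad_session(cfg, d)
      tens <- interbrain_plv(ses$epochs$B, ses$epochs$A, tiny_bands()[2], trim = 100)
      mean(tens[1, 2, 1, c("topic1", "topic2")])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_lt(means[1], 0.3)   # uncoupled oscillators decohere
  expect_gt(means[4], 0.8)   # strong coupling locks
})

test_that("config validation rejects malformed coupling tables", {
  expect_error(tiny_cfg(coupling = data.frame(listener = 1, speaker = 2,
                                              band = "alpha", kappa = 1.2)), "kappa")
  expect_error(tiny_cfg(coupling = data.frame(listener = 9, speaker = 2,
                                              band = "alpha", kappa = 0.5)), "range")
  expect_error(tiny_cfg(coupling = data.frame(listener = 1, speaker = 2,
                                              band = "gamma", kappa = 0.5)), "band")
  expect_error(tiny_cfg(env_coupling = data.frame(role = "shout", channel = 1,
                                                  band = "alpha", kappa = 0.5)), "role")
  expect_error(synth_config(rate = 250, epoch_len = 0.3002), "integer")
  # ground truth mirrors the positive-kappa entries
  cfg <- tiny_cfg(coupling = data.frame(listener = c(1, 2), speaker = c(2, 3),
                                        band = "alpha", kappa = c(0.5, 0)))
  ses <- generate_dyad_session(cfg, 1)
  expect_equal(nrow(ses$truth$coupled_pairs), 1L)
})
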