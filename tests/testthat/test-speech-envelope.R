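# Amplitude-envelope extraction and brain-to-envelope PLV with the
# intra-brain correction.

test_that("envelope of an AM tone peaks at the modulation rate", {
  fs <- 8000
  t <- (0:(10 * fs - 1)) / fs
  audio <- (1 + 1 * sin(2 * pi * 4 * t)) * sin(2 * pi * 1000 * t)
  env <- amplitude_envelope(audio, fs)
  expect_length(env, 2500L)
  expect_true(all(env >= 0))
  pk <- peak_freq(as.numeric(env[100:2400]), 250, lo = 0.5, hi = 12)
  expect_lt(abs(pk - 4), 0.25)
})

test_that("degenerate audio is handled: silence, constant tone, polarity", {
  fs <- 8000
  expect_warning(env0 <- amplitude_envelope(numeric(fs), fs), "all-zero")
  expect_true(all(env0 == 0))
  t <- (0:(4 * fs - 1)) / fs
  tone <- sin(2 * pi * 1000 * t)
  env <- amplitude_envelope(tone, fs)
  mid <- 100:(length(env) - 100)
  expect_lt(sd(env[mid]) / mean(env[mid]), 0.05)
  # polarity flip leaves the envelope unchanged
  expect_equal(as.numeric(amplitude_envelope(-tone, fs)), as.numeric(env), tolerance = 1e-12)
  expect_error(amplitude_envelope(tone, 4000), "8 kHz")
})

test_that("an EEG channel that copies the envelope has PLV 1 in every band", {
  env <- generate_speech_envelope(8, 250, 5, seed = 2)
  # EEG channels carry the envelope's fluctuation exactly
  flc <- as.numeric(env) - mean(env)
  mats <- list(topic1 = rbind(flc, flc))
  rest <- matrix(rnorm(2 * 2000), 2)
  es <- make_es(mats, rest)
  out <- brain_envelope_plv(es, list(topic1 = as.numeric(env)), tiny_bands(),
                            role = "listen", trim = 100)
  expect_equal(unname(as.vector(out)), rep(1, 4), tolerance = 1e-9)
  expect_false(attr(out, "corrected"))
})

test_that("an entrained synthetic channel shows strong envelope PLV, noise does not", {
  cfg <- synth_config(n_dyads = 1, n_channels = 2, epoch_len = 20, n_topics = 2,
                      bands = tiny_bands(), noise_sd = 0.2,
                      env_coupling = data.frame(role = "speak", channel = 1,
                                                band = "theta", kappa = 1),
                      seed = 4)
  ses <- generate_dyad_session(cfg, 1)
  envs <- list(topic1 = as.numeric(ses$envelopes[["topic1.A"]]$values),
               topic2 = as.numeric(ses$envelopes[["topic2.A"]]$values))
  out <- brain_envelope_plv(ses$epochs$A, envs, tiny_bands(), role = "speak", trim = 250)
  expect_gt(out[1, "theta"], 0.8)
  # channel 2 is independent background: below the random-phase null's
  # 95th percentile (Monte-Carlo oracle)
  T_eff <- 20 * 250 - 2 * 250
  null95 <- quantile(replicate(300, plv(runif(T_eff, -pi, pi), runif(T_eff, -pi, pi))), 0.95)
  expect_lt(out[2, "alpha"], null95 * 3 + 0.05)
})

test_that("intra-brain correction subtracts the per-band mean sensor-pair PLV", {
  set.seed(6)
  mats <- list(topic1 = matrix(rnorm(3 * 2000), 3), topic2 = matrix(rnorm(3 * 2000), 3))
  rest <- matrix(rnorm(3 * 2000), 3)
  es <- make_es(mats, rest)
  env <- lapply(mats, function(m) abs(rnorm(2000)) + 0.1)
  raw <- brain_envelope_plv(es, env, tiny_bands(), role = "listen", trim = 100)
  cor1 <- intrabrain_correction(raw, es, tiny_bands(), role = "listen", trim = 100)
  expect_true(attr(cor1, "corrected"))
  expect_error(intrabrain_correction(cor1, es, tiny_bands()), "already corrected")
  # brute-force oracle: per-topic mean over the 3 distinct sensor pairs,
  # on phases from the same multi-band filter geometry
  bands <- tiny_bands()
  for (b in seq_along(bands)) {
    ims <- vapply(names(mats), function(tp) {
      ph <- Arg(dyadsync:::band_phasors(mats[[tp]], bands, 250, trim = 100,
                                        unit = FALSE)[[b]])
      mean(c(plv_loop(ph[, 1], ph[, 2]), plv_loop(ph[, 1], ph[, 3]),
             plv_loop(ph[, 2], ph[, 3])))
    }, numeric(1))
    expect_equal(unname(cor1[, b]), unname(raw[, b] - mean(ims)), tolerance = 1e-10)
  }
  # correction is a per-band constant shift: channel differences preserved
  expect_equal(diff(cor1[, 1]), diff(raw[, 1]), tolerance = 1e-12)
  # identical signals on all channels + env PLV 1 -> corrected 0
  env2 <- generate_speech_envelope(8, 250, 5, seed = 9)
  flc2 <- as.numeric(env2) - mean(env2)
  same <- rbind(flc2, flc2, flc2)
  es2 <- make_es(list(topic1 = same), rest)
  r2 <- brain_envelope_plv(es2, list(topic1 = as.numeric(env2)), tiny_bands(),
                           role = "listen", trim = 100)
  c2 <- intrabrain_correction(r2, es2, tiny_bands(), role = "listen", trim = 100)
  expect_equal(max(abs(c2)), 0, tolerance = 1e-9)
})
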