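# Preprocessing: re-referencing, zero-phase FIR filtering, epoch extraction.

test_that("high-pass removes DC and re-referencing zeros the reference channel", {
  set.seed(1)
  x <- matrix(c(10, 7, 0), nrow = 3, ncol = 2500)   # constant offsets (uV)
  raw <- raw_recording(x, 250, c("C3", "C4", "A2"))
  out <- preprocess_recording(raw, highpass = 1, lowpass = NULL)
  # after high-pass, per-channel mean is essentially zero
  expect_lt(max(abs(rowMeans(out$samples))), 1e-5 * 10)
  # re-reference alone: x - x = 0 on the reference channel
  x[3, ] <- rnorm(2500)
  raw2 <- raw_recording(x, 250, c("C3", "C4", "A2"))
  reref <- preprocess_recording(raw2, highpass = NULL, lowpass = NULL, new_reference = "A2")
  expect_identical(reref$reference, "A2")
  expect_equal(max(abs(reref$samples["A2", ])), 0)
  expect_equal(reref$samples["C3", ], 10 - x[3, ], ignore_attr = TRUE)
})

test_that("low-pass attenuation of an out-of-band tone matches the designed response", {
  t <- (0:4999) / 250
  x <- matrix(sin(2 * pi * 30 * t), nrow = 1)
  raw <- raw_recording(x, 250)
  out <- preprocess_recording(raw, highpass = NULL, lowpass = 20)
  mid <- 1000:4000
  ratio <- sqrt(mean(out$samples[1, mid]^2)) / sqrt(mean(x[1, mid]^2))
  # oracle: squared magnitude of the designed FIR at 30 Hz
  b <- fir_design("low", 20, 250)
  H <- Mod(sum(b * exp(-2i * pi * 30 / 250 * (seq_along(b) - 1))))^2
  expect_lt(ratio, 0.05)
  expect_equal(ratio, H, tolerance = 0.25)
})

test_that("zero-phase filtering is linear and lag-free", {
  set.seed(2)
  x <- rnorm(3000)
  b <- fir_design("pass", c(4, 8), 250)
  y1 <- fir_filtfilt(x, b)
  y3 <- fir_filtfilt(3 * x, b)
  expect_equal(y3, 3 * y1, tolerance = 1e-12)
  # cross-correlation peak between band-limited input and its filtered
  # version is at lag 0
  s <- fir_filtfilt(rnorm(3000), b)    # band-limited test signal
  sf <- fir_filtfilt(s, b)
  cc <- ccf(s[500:2500], sf[500:2500], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("analytic signal matches the textbook Hilbert construction", {
  set.seed(3)
  x <- rnorm(2048)
  z <- analytic_signal(x)
  ref <- hilbert_ref(x)
  expect_equal(z, ref, tolerance = 1e-10)
  expect_equal(Re(z), x, tolerance = 1e-10)
})

test_that("filter design rejects cutoffs at or above Nyquist and missing references", {
  raw <- raw_recording(matrix(rnorm(500), 1), 250)
  expect_error(preprocess_recording(raw, highpass = 125), "Nyquist")
  expect_error(preprocess_recording(raw, new_reference = "nope"), "not present")
  expect_error(fir_design("pass", c(8, 4), 250), "lo < hi")
})

test_that("epoch extraction yields 11 labelled epochs and is a lossless relabelling", {
  cfg <- tiny_cfg(n_topics = 5)
  ses <- generate_dyad_session(cfg, 1)
  raw <- session_to_recording(ses, "A", gap_s = 1)
  es <- extract_epochs(raw, epoch_len = cfg$epoch_len)
  expect_length(es$epochs, 11L)
  roles <- table(vapply(es$epochs, `[[`, character(1), "role"))
  expect_equal(as.vector(roles[c("speak", "listen", "rest")]), c(5L, 5L, 1L))
  expect_equal(es$T, cfg$epoch_len * cfg$rate)
  # extracted samples reproduce the original segments exactly
  for (k in c(1L, 6L, 11L)) {
    m <- raw$markers[k, ]
    seg <- raw$samples[, (m$sample + 1):(m$sample + es$T)]
    expect_identical(es$epochs[[k]]$data, seg)
  }
})

test_that("the bad-channel screen flags flatlines and variance outliers", {
  set.seed(9)
  x <- matrix(rnorm(6 * 2000), 6)
  x[2, ] <- 0                      # flatline
  x[5, ] <- rnorm(2000, sd = 500)  # variance outlier
  raw <- raw_recording(x, 250)
  out <- screen_bad_channels(raw)
  expect_setequal(attr(out, "bad_channels"), c("ch02", "ch05"))
  expect_identical(out$samples, raw$samples)   # flag-only by default
  fixed <- screen_bad_channels(raw, interpolate = TRUE)
  good <- colMeans(x[c(1, 3, 4, 6), ])
  expect_equal(fixed$samples[2, ], good, ignore_attr = TRUE)
  # clean recording: nothing flagged
  expect_length(attr(screen_bad_channels(raw_recording(matrix(rnorm(8000), 4), 250)),
                     "bad_channels"), 0L)
})

test_that("epoch extraction errors on truncated epochs and warns on missing rest", {
  raw <- raw_recording(matrix(rnorm(2000), 2), 250,
                       markers = data.frame(sample = 900, role = "speak", topic = "t1"))
  expect_error(extract_epochs(raw, epoch_len = 2), "truncated")
  raw2 <- raw_recording(matrix(rnorm(2000), 2), 250,
                        markers = data.frame(sample = 0, role = "speak", topic = "t1"))
  expect_warning(es <- extract_epochs(raw2, epoch_len = 2), "rest")
  expect_length(es$epochs, 1L)
})
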