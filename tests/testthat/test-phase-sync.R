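# Instantaneous phase, the PLV and the interbrain tensor.

test_that("PLV identities hold exactly", {
  set.seed(1)
  ph <- runif(5000, -pi, pi)
  expect_identical(plv(ph, ph), 1)
  # exactly cancelling differences
  psi <- ph - rep(c(0, pi), length.out = 5000)
  expect_lt(plv(ph, psi), 1e-12)
  # symmetry and offset invariance
  psi2 <- runif(5000, -pi, pi)
  expect_equal(plv(ph, psi2), plv(psi2, ph), tolerance = 1e-14)
  expect_equal(plv(ph + 1.234, psi2), plv(ph, psi2), tolerance = 1e-12)
  # range
  for (i in 1:10) {
    v <- plv(runif(200, -pi, pi), runif(200, -pi, pi))
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(plv(ph, ph[-1]), "equal length")
})

test_that("PLV of independent uniform phases sits at the 1/sqrt(T) floor", {
  set.seed(7)
  T <- 22500
  reps <- 200
  vals <- replicate(reps, plv(runif(T, -pi, pi), runif(T, -pi, pi)))
  # E[PLV] ~ sqrt(pi / (4 T)) = 0.0059 at T = 22500
  expect_gt(mean(vals), 0.004)
  expect_lt(mean(vals), 0.008)
  expect_lt(unname(quantile(vals, 0.95)), 0.015)
})

test_that("instantaneous phase of a sinusoid advances linearly at its frequency", {
  t <- (0:22499) / 250
  ph <- instantaneous_phase(sin(2 * pi * 10 * t), band_spec("alpha", 9, 12), 250)
  expect_length(ph, 22500 - 2 * 250)   # trim = 1 s per edge
  expect_true(all(ph > -pi & ph <= pi))
  up <- signal::unwrap(ph)
  slope <- unname(coef(lm(up ~ seq_along(up)))[2]) * 250 / (2 * pi)
  expect_lt(abs(slope - 10) / 10, 0.01)
})

test_that("quadrature signals show a constant pi/2 phase difference", {
  t <- (0:9999) / 250
  b <- band_spec("alpha", 9, 12)
  ph_sin <- instantaneous_phase(sin(2 * pi * 10 * t), b, 250)
  ph_cos <- instantaneous_phase(cos(2 * pi * 10 * t), b, 250)
  d <- (ph_cos - ph_sin) %% (2 * pi)
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  # circular SD
  R <- Mod(mean(exp(1i * d)))
  expect_lt(sqrt(-2 * log(R)), 0.05)
})

test_that("interbrain tensor matches the scalar PLV loop and shape contract", {
  cfg <- tiny_cfg()
  ses <- generate_dyad_session(cfg, 1)
  bands <- tiny_bands()
  trim <- 100L
  tens <- interbrain_plv(ses$epochs$B, ses$epochs$A, bands, trim = trim)
  expect_equal(dim(tens), c(3L, 3L, 2L, 3L))
  expect_equal(dimnames(tens)$trial, c("topic1", "topic2", "rest"))
  expect_true(all(tens >= 0 & tens <= 1))
  # scalar-loop oracle over every pair of one trial, on the same phases
  # the tensor path uses (same band set, hence same filter geometry)
  li <- ses$epochs$B$epochs[[which(vapply(ses$epochs$B$epochs, `[[`, character(1), "role") == "listen")[1]]]
  sp <- ses$epochs$A$epochs[[which(vapply(ses$epochs$A$epochs, `[[`, character(1), "role") == "speak")[1]]]
  stopifnot(li$topic == sp$topic)
  zl <- dyadsync:::band_phasors(li$data, bands, cfg$rate, trim = trim, unit = FALSE)
  zs <- dyadsync:::band_phasors(sp$data, bands, cfg$rate, trim = trim, unit = FALSE)
  for (b in seq_along(bands)) {
    phl <- Arg(zl[[b]])   # time x channel
    phs <- Arg(zs[[b]])
    for (l in 1:3) for (s in 1:3) {
      expect_equal(tens[l, s, b, li$topic], plv_loop(phl[, l], phs[, s]),
                   tolerance = 1e-12)
    }
  }
})

test_that("identical listener and speaker signals give a unit diagonal", {
  set.seed(5)
  mats <- list(topic1 = matrix(rnorm(3 * 2000), 3), topic2 = matrix(rnorm(3 * 2000), 3))
  rest <- matrix(rnorm(3 * 2000), 3)
  li <- make_es(mats, rest, role = "listen")
  sp <- make_es(mats, rest, role = "speak")
  tens <- interbrain_plv(li, sp, tiny_bands(), trim = 100)
  for (k in 1:3) expect_equal(unname(diag(tens[, , 1, k])), rep(1, 3), tolerance = 1e-12)
})

test_that("rest subtraction and topic collapse behave as an average of differences", {
  dn <- list(listener = paste0("l", 1:2), speaker = paste0("s", 1:2),
             band = c("b1", "b2"), trial = c("t1", "t2", "rest"))
  tens <- array(runif(2 * 2 * 2 * 3), dim = c(2, 2, 2, 3), dimnames = dn)
  # all topics equal rest -> zeros
  t0 <- tens
  t0[, , , 1] <- t0[, , , 3]; t0[, , , 2] <- t0[, , , 3]
  expect_equal(max(abs(rest_subtract_and_collapse(t0))), 0)
  # constant shift
  t1 <- tens
  t1[, , , 1] <- t1[, , , 3] + 0.2; t1[, , , 2] <- t1[, , , 3] + 0.2
  expect_equal(unname(as.vector(rest_subtract_and_collapse(t1))),
               rep(0.2, 8), tolerance = 1e-14)
  # random tensor against the naive triple loop
  got <- rest_subtract_and_collapse(tens)
  for (l in 1:2) for (s in 1:2) for (b in 1:2) {
    want <- mean(c(tens[l, s, b, 1] - tens[l, s, b, 3],
                   tens[l, s, b, 2] - tens[l, s, b, 3]))
    expect_equal(got[l, s, b], want, tolerance = 1e-14)
  }
  expect_error(rest_subtract_and_collapse(tens[, , , 1:2, drop = FALSE]), "rest")
})
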