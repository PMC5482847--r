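# Mediation regression (full + partial models) and the exclusion mask.

test_that("a perfectly mediated response gives r2 = 1 in the partial model", {
  set.seed(1)
  x1 <- rnorm(30)
  fit <- fit_mediation(x1, x1, model = "listener_only")
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$flagged)
})

test_that("OLS fits match the normal-equations closed form to 1e-8", {
  set.seed(2)
  for (i in 1:10) {
    x1 <- rnorm(30); x2 <- rnorm(30)
    y <- 0.1 + 0.5 * x1 - 0.3 * x2 + 0.2 * x1 * x2 + rnorm(30, 0, 0.5)
    fit <- fit_mediation(y, x1, x2, model = "full")
    want <- ols_oracle(cbind(1, x1, x2, x1 * x2), y)
    expect_equal(unname(fit$beta), unname(want$beta), tolerance = 1e-8)
    expect_equal(fit$r2, want$r2, tolerance = 1e-8)
    expect_equal(fit$F, want$F, tolerance = 1e-8)
    expect_equal(fit$p, want$p, tolerance = 1e-8)
    expect_equal(c(fit$df1, fit$df2), c(3, 26))
  }
})

test_that("known coefficients are recovered within 3 standard errors", {
  set.seed(3)
  x1 <- rnorm(30); x2 <- rnorm(30)
  beta <- c(0.1, 0.5, -0.3, 0.2)
  X <- cbind(1, x1, x2, x1 * x2)
  y <- drop(X %*% beta) + rnorm(30, 0, 0.01)
  fit <- fit_mediation(y, x1, x2, model = "full")
  sigma2 <- sum((y - X %*% solve(crossprod(X), crossprod(X, y)))^2) / 26
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  expect_true(all(abs(fit$beta - beta) <= 3 * se))
})

test_that("under the null, r2 has mean ~ k/(n-1) and p is roughly uniform", {
  set.seed(4)
  n <- 30
  r2s <- ps <- numeric(300)
  for (i in seq_len(300)) {
    fit <- fit_mediation(rnorm(n), rnorm(n), rnorm(n), model = "full")
    r2s[i] <- fit$r2; ps[i] <- fit$p
  }
  expect_lt(abs(mean(r2s) - 3 / (n - 1)), 0.025)
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("the full model never has lower r2 than either partial model", {
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(30); x1 <- rnorm(30); x2 <- rnorm(30)
    rf <- fit_mediation(y, x1, x2, "full")$r2
    expect_gte(rf, fit_mediation(y, x1, x2, "listener_only")$r2 - 1e-12)
    expect_gte(rf, fit_mediation(y, x1, x2, "speaker_only")$r2 - 1e-12)
  }
})

test_that("degenerate designs are flagged rather than fitted", {
  x <- rnorm(30)
  f1 <- fit_mediation(rnorm(30), rep(1, 30), x, model = "full")   # constant predictor
  expect_true(f1$flagged); expect_true(is.na(f1$p))
  f2 <- fit_mediation(rep(2, 30), x, x, model = "full")           # constant response
  expect_true(f2$flagged)
  expect_error(fit_mediation(c(1, NA, rnorm(28)), x, x, "full"), "finite")
})

test_that("the scan fits all three models for every pair and band", {
  set.seed(6)
  n <- 12
  bb <- array(rnorm(n * 4 * 3 * 2), c(n, 4, 3, 2),
              dimnames = list(NULL, paste0("l", 1:4), paste0("s", 1:3), c("x", "y")))
  env_l <- array(rnorm(n * 4 * 2), c(n, 4, 2), dimnames = list(NULL, paste0("l", 1:4), c("x", "y")))
  env_s <- array(rnorm(n * 3 * 2), c(n, 3, 2), dimnames = list(NULL, paste0("s", 1:3), c("x", "y")))
  scan <- mediation_scan(bb, env_l, env_s)
  expect_equal(nrow(scan), 4 * 3 * 2 * 3)
  expect_setequal(unique(scan$model), c("full", "listener_only", "speaker_only"))
  # one cell cross-checked against fit_mediation
  one <- scan[scan$listener == "l2" & scan$speaker == "s3" & scan$band == "y" &
                scan$model == "full", ]
  want <- fit_mediation(bb[, 2, 3, 2], env_l[, 2, 2], env_s[, 3, 2], "full")
  expect_equal(one$r2, want$r2, tolerance = 1e-12)
  expect_equal(one$p, want$p, tolerance = 1e-12)
  expect_error(mediation_scan(bb[1:10, , , , drop = FALSE], env_l, env_s), "case")
})

test_that("the exclusion mask applies both removal criteria in order", {
  dn <- list(paste0("l", 1:3), paste0("s", 1:3), "alpha")
  bb_sig <- array(TRUE, c(3, 3, 1), dimnames = dn)
  bb_sig[3, 3, 1] <- FALSE
  med <- data.frame(listener = "l1", speaker = "s1", band = "alpha",
                    model = "full", significant = TRUE)
  env_l <- matrix(c(FALSE, TRUE, FALSE), 3, 1, dimnames = list(dn[[1]], "alpha"))
  env_s <- matrix(c(FALSE, FALSE, TRUE), 3, 1, dimnames = list(dn[[2]], "alpha"))
  out <- exclusion_mask(bb_sig, med, env_l, env_s)
  # set-arithmetic oracle: start from bb_sig, drop (l1,s1) by mediation,
  # drop any pair with l2 (listener) or s3 (speaker)
  want <- bb_sig
  want[1, 1, 1] <- FALSE
  want[2, , 1] <- FALSE
  want[, 3, 1] <- FALSE
  expect_identical(out$mask, want)
  pr <- out$provenance
  expect_equal(pr$status[pr$listener == "l1" & pr$speaker == "s1"], "mediation")
  expect_true(all(pr$status[pr$listener == "l2"] == "envelope_channel"))
  # survivors subset of the significant set
  expect_true(all(which(out$mask) %in% which(bb_sig)))
  # all channels envelope-involved -> empty survivors
  all_env <- matrix(TRUE, 3, 1, dimnames = list(dn[[1]], "alpha"))
  out2 <- exclusion_mask(bb_sig, med[0, ], all_env, all_env)
  expect_equal(sum(out2$mask), 0L)
  # nothing to remove -> unchanged
  no_env <- matrix(FALSE, 3, 1, dimnames = list(dn[[1]], "alpha"))
  out3 <- exclusion_mask(bb_sig, med[0, ], no_env, no_env)
  expect_identical(out3$mask, bb_sig)
})
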