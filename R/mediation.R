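# Regression-based mediation: does the coupling of each brain to the
# shared speech envelope statistically explain the interbrain coupling?
# The full model is Y = b0 + b1*x1 + b2*x2 + b12*x1*x2 + e, where Y is
# the interbrain coupling of a (listener channel, speaker channel) pair,
# x1 the listener's envelope coupling at that listener channel, and x2
# the speaker's envelope coupling at that speaker channel. Two partial
# (single-predictor) models complement it.

mediation_models <- c("full", "listener_only", "speaker_only")

#' Fit one mediation regression
#'
#' Ordinary least squares for the full interaction model or one of the
#' single-predictor partial models, with the overall-model F test.
#'
#' @param y Response: interbrain coupling across cases.
#' @param x1,x2 Predictors: listener / speaker envelope coupling.
#' @param model `"full"`, `"listener_only"` or `"speaker_only"`.
#' @return A `mediation_fit` list: `model`, `beta` (named coefficients),
#'   `r2`, `F`, `df1`, `df2`, `p`, `flagged` (TRUE when the design is
#'   rank-deficient or the response constant, in which case `p` is `NA`).
#' @export
fit_mediation <- function(y, x1, x2 = NULL, model = c("full", "listener_only", "speaker_only")) {
  model <- match.arg(model)
  n <- length(y)
  if (model != "listener_only" && is.null(x2)) stop("x2 is required for this model")
  X <- switch(model,
    full          = cbind(b0 = 1, b1 = x1, b2 = x2, b12 = x1 * x2),
    listener_only = cbind(b0 = 1, b1 = x1),
    speaker_only  = cbind(b0 = 1, b2 = x2)
  )
  if (any(!is.finite(y)) || any(!is.finite(X))) stop("inputs must be finite")
  if (n != nrow(X) || (!is.null(x2) && length(x2) != n && model != "listener_only")) {
    stop("y, x1 and x2 must have equal length")
  }
  k <- ncol(X) - 1L
  if (n < k + 2L) stop("need at least ", k + 2L, " cases for the ", model, " model")
  beta <- c(beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_, beta12 = NA_real_)
  fit <- stats::lm.fit(X, y)
  tss <- sum((y - mean(y))^2)
  flagged <- fit$rank < ncol(X) || tss == 0
  if (flagged) {
    return(structure(list(model = model, beta = beta, r2 = NA_real_, F = NA_real_,
                          df1 = k, df2 = n - k - 1L, p = NA_real_, flagged = TRUE),
                     class = "mediation_fit"))
  }
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / tss
  df1 <- k; df2 <- n - k - 1L
  Fstat <- (tss - rss) / df1 / (rss / df2)
  cf <- fit$coefficients
  beta["beta0"] <- cf[["b0"]]
  if ("b1" %in% names(cf)) beta["beta1"] <- cf[["b1"]]
  if ("b2" %in% names(cf)) beta["beta2"] <- cf[["b2"]]
  if ("b12" %in% names(cf)) beta["beta12"] <- cf[["b12"]]
  structure(list(model = model, beta = beta, r2 = r2, F = Fstat, df1 = df1,
                 df2 = df2, p = pf(Fstat, df1, df2, lower.tail = FALSE),
                 flagged = FALSE),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit:%s> r2 = %.3f, F(%d, %d) = %.2f, p = %.4g%s\n",
              x$model, x$r2, x$df1, x$df2, x$F, x$p,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Mediation regression scan over all channel pairs
#'
#' Fits the full and both partial models for every (listener channel,
#' speaker channel) pair within every band: 729 fits per model per band
#' for the 27-channel montage.
#'
#' @param bb Array `case x listener x speaker x band` of interbrain
#'   coupling values.
#' @param env_l,env_s Arrays `case x channel x band` of corrected
#'   envelope coupling for the listener / speaker role.
#' @param alpha Uncorrected significance level for each overall-model F
#'   test (default 0.05).
#' @return `data.frame(listener, speaker, band, model, r2, F, df1, df2,
#'   p, significant)`.
#' @export
mediation_scan <- function(bb, env_l, env_s, alpha = 0.05) {
  stopifnot(length(dim(bb)) == 4L, length(dim(env_l)) == 3L, length(dim(env_s)) == 3L)
  n <- dim(bb)[1L]
  if (dim(env_l)[1L] != n || dim(env_s)[1L] != n) stop("case sets must match across inputs")
  if (dim(env_l)[2L] != dim(bb)[2L] || dim(env_s)[2L] != dim(bb)[3L] ||
      dim(env_l)[3L] != dim(bb)[4L] || dim(env_s)[3L] != dim(bb)[4L]) {
    stop("channel/band dimensions of bb and envelope arrays are inconsistent")
  }
  dn <- dimnames(bb)
  lch <- dn[[2L]] %||% sprintf("l%02d", seq_len(dim(bb)[2L]))
  sch <- dn[[3L]] %||% sprintf("s%02d", seq_len(dim(bb)[3L]))
  bnd <- dn[[4L]] %||% sprintf("band%d", seq_len(dim(bb)[4L]))
  rows <- vector("list", length(lch) * length(sch) * length(bnd) * 3L)
  r <- 0L
  for (b in seq_along(bnd)) {
    for (l in seq_along(lch)) {
      x1 <- env_l[, l, b]
      for (s in seq_along(sch)) {
        x2 <- env_s[, s, b]
        y <- bb[, l, s, b]
        for (m in mediation_models) {
          fit <- fit_mediation(y, x1, x2, model = m)
          r <- r + 1L
          rows[[r]] <- data.frame(
            listener = lch[l], speaker = sch[s], band = bnd[b], model = m,
            r2 = fit$r2, F = fit$F, df1 = fit$df1, df2 = fit$df2, p = fit$p,
            significant = !is.na(fit$p) && fit$p < alpha
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' Exclusion mask: interbrain coupling not explained by speech
#'
#' Starting from the significant interbrain pairs, removes (i) any pair
#' for which any of the three mediation models is significant and (ii)
#' any pair containing a channel with significant envelope entrainment
#' for its role, leaving the "pure" interbrain coupling set.
#'
#' @param bb_sig Logical `listener x speaker x band` array of significant
#'   interbrain enhancement.
#' @param med Output of [mediation_scan()].
#' @param env_sig_l,env_sig_s Logical `channel x band` matrices of
#'   significant envelope entrainment for the listener / speaker role.
#' @return `list(mask, provenance)`: `mask` is the surviving logical
#'   array; `provenance` records, per initially-significant pair, which
#'   criterion removed it (`"mediation"`, `"envelope_channel"`) or
#'   `"surviving"`.
#' @export
exclusion_mask <- function(bb_sig, med, env_sig_l, env_sig_s) {
  stopifnot(is.array(bb_sig), length(dim(bb_sig)) == 3L)
  if (is.null(dimnames(bb_sig))) {
    dimnames(bb_sig) <- list(sprintf("l%02d", seq_len(dim(bb_sig)[1L])),
                             sprintf("s%02d", seq_len(dim(bb_sig)[2L])),
                             sprintf("band%d", seq_len(dim(bb_sig)[3L])))
  }
  dn <- dimnames(bb_sig)
  lch <- dn[[1L]]; sch <- dn[[2L]]; bnd <- dn[[3L]]
  med_any <- array(FALSE, dim = dim(bb_sig), dimnames = dn)
  sig_rows <- med[med$significant, , drop = FALSE]
  if (nrow(sig_rows) > 0L) {
    li <- match(sig_rows$listener, lch)
    si <- match(sig_rows$speaker, sch)
    bi <- match(sig_rows$band, bnd)
    med_any[cbind(li, si, bi)] <- TRUE
  }
  mask <- bb_sig
  prov <- NULL
  for (b in seq_along(bnd)) {
    for (l in seq_along(lch)) {
      for (s in seq_along(sch)) {
        if (!bb_sig[l, s, b]) next
        status <- "surviving"
        if (med_any[l, s, b]) {
          status <- "mediation"
        } else if (env_sig_l[l, b] || env_sig_s[s, b]) {
          status <- "envelope_channel"
        }
        if (status != "surviving") mask[l, s, b] <- FALSE
        prov <- rbind(prov, data.frame(listener = lch[l], speaker = sch[s],
                                       band = bnd[b], status = status))
      }
    }
  }
  list(mask = mask, provenance = prov %||%
         data.frame(listener = character(0), speaker = character(0),
                    band = character(0), status = character(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
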