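# Group-level inference: real-vs-surrogate contrasts via a nonparametric
# centered-difference bootstrap t-test, Benjamini-Hochberg FDR control,
# and z-score difference maps for topographic summaries.

#' Nonparametric bootstrap paired t-test
#'
#' For each feature the paired differences `d = real - surrogate` give an
#' observed t statistic `mean(d) / (sd(d) / sqrt(n))`. The null is built
#' by resampling the mean-centered differences with replacement `n_boot`
#' times; the two-sided p value is `(1 + #{|t*| >= |t_obs|}) / (n_boot + 1)`.
#'
#' @param real,surrogate Cases-by-features numeric matrices of equal shape.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed; feature-level resampling streams are derived
#'   from it, so results are reproducible.
#' @return `data.frame(feature, mean_diff, t, df, p_raw)`; features whose
#'   differences have zero variance get `p_raw = 1` with a warning.
#' @export
bootstrap_paired_test <- function(real, surrogate, n_boot = 10000, seed = 1) {
  real <- as.matrix(real); surrogate <- as.matrix(surrogate)
  if (!identical(dim(real), dim(surrogate))) stop("real and surrogate must have matching shapes")
  n <- nrow(real)
  if (n < 2L) stop("need at least two cases")
  d <- real - surrogate
  nf <- ncol(d)
  feats <- colnames(d)
  if (is.null(feats)) feats <- sprintf("f%04d", seq_len(nf))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nf)
  res <- cpp_boot_t(d, as.integer(n_boot), seeds)
  p <- res[, 2L]; tval <- res[, 1L]
  if (anyNA(p)) {
    warning(sum(is.na(p)), " feature(s) with zero-variance differences; p set to 1")
    tval[is.na(tval)] <- 0
    p[is.na(p)] <- 1
  }
  data.frame(feature = feats, mean_diff = colMeans(d), t = tval,
             df = n - 1L, p_raw = p, row.names = NULL)
}

#' Benjamini-Hochberg FDR correction
#'
#' Monotone step-up adjusted p values and the significance mask at level
#' `q`, applied jointly to all supplied p values.
#'
#' @param p_raw Numeric vector of p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return `list(p_fdr, significant)`; empty input gives empty output.
#' @export
fdr_correct <- function(p_raw, q = 0.05) {
  if (length(p_raw) == 0L) return(list(p_fdr = numeric(0), significant = logical(0)))
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  p_fdr <- p.adjust(p_raw, method = "BH")
  list(p_fdr = p_fdr, significant = p_fdr < q)
}

#' Real-vs-surrogate group test with FDR correction
#'
#' Convenience wrapper: [bootstrap_paired_test()] followed by
#' [fdr_correct()] across all features jointly, with effect direction.
#'
#' @inheritParams bootstrap_paired_test
#' @param q FDR level (default 0.05).
#' @return `data.frame(feature, mean_diff, t, df, p_raw, p_fdr,
#'   significant, direction)` where `direction` is the sign of the mean
#'   real-surrogate difference.
#' @export
group_test <- function(real, surrogate, n_boot = 10000, q = 0.05, seed = 1) {
  res <- bootstrap_paired_test(real, surrogate, n_boot = n_boot, seed = seed)
  fdr <- fdr_correct(res$p_raw, q = q)
  res$p_fdr <- fdr$p_fdr
  res$significant <- fdr$significant
  res$direction <- sign(res$mean_diff)
  attr(res, "q") <- q
  res
}

#' Mean real-minus-surrogate z-score map
#'
#' Within each case, PLVs are z-scored across features within each band;
#' the map is the mean over cases of the real minus surrogate z scores
#' (the topographic summary used for head plots).
#'
#' @param real,surrogate Cases-by-features matrices.
#' @param band Factor (length = number of features) giving each feature's
#'   band; z-scoring is performed within band.
#' @return Numeric vector (one value per feature); features in a band
#'   with zero variance for some case are flagged `NA` with a warning.
#' @export
zscore_map <- function(real, surrogate, band = NULL) {
  real <- as.matrix(real); surrogate <- as.matrix(surrogate)
  if (!identical(dim(real), dim(surrogate))) stop("real and surrogate must have matching shapes")
  if (is.null(band)) band <- factor(rep("all", ncol(real)))
  band <- as.factor(band)
  stopifnot(length(band) == ncol(real))
  zrow <- function(x) {
    out <- numeric(length(x))
    for (g in levels(band)) {
      i <- band == g
      s <- sd(x[i])
      out[i] <- if (is.na(s) || s == 0) NA_real_ else (x[i] - mean(x[i])) / s
    }
    out
  }
  zr <- t(apply(real, 1L, zrow))
  zs <- t(apply(surrogate, 1L, zrow))
  if (anyNA(zr) || anyNA(zs)) warning("zero feature variance within a band for some case; NA returned")
  out <- colMeans(zr - zs)
  names(out) <- colnames(real)
  out
}
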