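# Zero-phase FIR filtering and analytic-signal extraction.
#
# All filtering uses Hamming windowed-sinc FIR designs (signal::fir1)
# applied forward-backward, i.e. with the squared magnitude response
# |B(f)|^2 and exactly zero phase. The application is done in the
# frequency domain (FFTW) on reflect-padded signals, which is equivalent
# to forward-backward time-domain filtering away from the padded edges.

# smallest 5-smooth integer >= n (efficient FFT length)
next_fast_len <- function(n) {
  n <- as.integer(n)
  if (n <= 2L) return(2L)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Design a windowed-sinc FIR filter
#'
#' Hamming windowed-sinc design via [signal::fir1()]. The default order is
#' at least three cycles of the lowest cutoff frequency (rounded up to an
#' even number), a standard choice for EEG band filters.
#'
#' @param type `"low"`, `"high"` or `"pass"`.
#' @param cutoff Cutoff frequency in Hz (length 2 for `"pass"`).
#' @param rate Sampling rate in Hz.
#' @param order Filter order; defaults to `3 * rate / min(cutoff)` rounded
#'   up to even.
#' @return Numeric vector of filter coefficients with attributes
#'   `order`, `type`, `cutoff`, `rate`.
#' @export
fir_design <- function(type = c("pass", "low", "high"), cutoff, rate, order = NULL) {
  type <- match.arg(type)
  nyq <- rate / 2
  if (any(!is.finite(cutoff)) || any(cutoff <= 0) || any(cutoff >= nyq)) {
    stop("cutoff frequencies must lie strictly between 0 and the Nyquist frequency")
  }
  if (type == "pass" && (length(cutoff) != 2L || diff(cutoff) <= 0)) {
    stop("bandpass design needs cutoff = c(lo, hi) with lo < hi")
  }
  if (is.null(order)) order <- ceiling(3 * rate / min(cutoff))
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  if (type == "high") {
    # spectral inversion of a DC-normalised low-pass: exact null at DC
    lp <- as.numeric(signal::fir1(order, cutoff / nyq, "low"))
    lp <- lp / sum(lp)
    b <- -lp
    b[order %/% 2L + 1L] <- b[order %/% 2L + 1L] + 1
  } else {
    b <- as.numeric(signal::fir1(order, cutoff / nyq, type))
  }
  structure(b, order = order, type = type, cutoff = cutoff, rate = rate)
}

# |B(f)|^2 gain vector for frequency-domain zero-phase application
fir_gain <- function(b, nfft) {
  Mod(stats::fft(c(b, numeric(nfft - length(b)))))[seq_len(nfft %/% 2 + 1)]^2
}

# padding / fft length bookkeeping shared by the filtering entry points
fir_geometry <- function(T, ntaps) {
  pad <- min(ntaps, T - 1L)
  nfft <- next_fast_len(T + 2L * pad)
  list(pad = as.integer(pad), nfft = nfft)
}

#' Zero-phase FIR filtering
#'
#' Applies an FIR filter forward-backward (squared magnitude response,
#' exactly zero phase) to a signal vector or to each row of a
#' channels-by-time matrix.
#'
#' @param x Numeric vector, or matrix with channels in rows.
#' @param b Filter coefficients from [fir_design()].
#' @return Filtered data with the shape of `x`.
#' @export
fir_filtfilt <- function(x, b) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else t(x)
  g <- fir_geometry(nrow(X), length(b))
  out <- cpp_fir_zerophase(X, fir_gain(b, g$nfft), g$nfft, g$pad)
  if (vec) drop(out) else {
    res <- t(out)
    dimnames(res) <- dimnames(x)
    res
  }
}

# design + gain caches (filters are redesigned thousands of times in the
# replicated pipelines; the designs depend only on band, rate and nfft)
.fir_cache <- new.env(parent = emptyenv())

cached_band_design <- function(band, rate) {
  key <- paste("d", band$name, band$lo, band$hi, rate, sep = "|")
  d <- .fir_cache[[key]]
  if (is.null(d)) {
    if (band$hi >= rate / 2) {
      stop("band '", band$name, "' extends to or beyond the Nyquist frequency")
    }
    d <- fir_design("pass", c(band$lo, band$hi), rate)
    .fir_cache[[key]] <- d
  }
  d
}

cached_band_gains <- function(bands, rate, nfft) {
  key <- paste("g", paste(vapply(bands, `[[`, character(1), "name"), collapse = ","),
               rate, nfft, sep = "|")
  g <- .fir_cache[[key]]
  if (is.null(g)) {
    designs <- lapply(bands, cached_band_design, rate = rate)
    g <- vapply(designs, fir_gain, numeric(nfft %/% 2 + 1), nfft = nfft)
    .fir_cache[[key]] <- g
  }
  g
}

# Band-limited analytic signal (unit phasors or raw analytic values) for
# each row of a channels x time matrix, for each band. Returns a named
# list (by band) of time x channel complex matrices, edge-trimmed.
band_phasors <- function(x, bands, rate, trim = 0L, unit = TRUE) {
  bands <- as_band_list(bands)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  T <- ncol(x)
  if (2L * trim >= T) stop("2 * trim must be smaller than the epoch length")
  ntaps <- max(vapply(bands, function(b) {
    attr(cached_band_design(b, rate), "order") + 1L
  }, integer(1)))
  g <- fir_geometry(T, ntaps)
  gains <- cached_band_gains(bands, rate, g$nfft)
  ph <- cpp_band_phasors(t(x), gains, g$nfft, g$pad, as.integer(trim), unit)
  names(ph) <- names(bands)
  ph
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length whose argument is the
#'   instantaneous phase and modulus the instantaneous amplitude.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  n <- length(x)
  gain <- rep(1, n %/% 2 + 1)
  z <- cpp_band_phasors(matrix(x, ncol = 1L), matrix(gain, ncol = 1L), n, 0L, 0L, FALSE)[[1L]]
  drop(z)
}
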