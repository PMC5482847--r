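# Instantaneous phase and the single-trial phase-locking value (PLV)
# between all listener x speaker channel pairs.

#' Band-limited instantaneous phase
#'
#' Band-pass filters each channel with a zero-phase FIR filter and takes
#' the angle of the analytic signal (Hilbert transform). `trim` samples
#' are dropped from each edge to suppress filter transients.
#'
#' @param x Channels-by-time numeric matrix (or a single-channel vector).
#' @param band A [band_spec()].
#' @param rate Sampling rate in Hz.
#' @param trim Samples removed from each edge (default 1 s).
#' @return Channels-by-time matrix of phases wrapped to `(-pi, pi]`, with
#'   attributes `band` and `trim`.
#' @export
instantaneous_phase <- function(x, band, rate, trim = round(rate)) {
  stopifnot(inherits(band, "band_spec"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  z <- band_phasors(x, list(band), rate, trim = as.integer(trim), unit = FALSE)[[1L]]
  ph <- t(Arg(z))
  # Arg() returns [-pi, pi]; map -pi to pi for a half-open wrap
  ph[ph <= -pi] <- pi
  rownames(ph) <- rownames(x)
  out <- if (vec) drop(ph) else ph
  attr(out, "band") <- band
  attr(out, "trim") <- as.integer(trim)
  out
}

#' Phase-locking value of two phase sequences
#'
#' The modulus of the time-averaged unit phasor of the phase difference:
#' `PLV = |sum(exp(1i * (phi - psi))) / T|`. Equal to 1 for a constant
#' phase lag and near 0 for independent phases.
#'
#' @param phi,psi Numeric phase sequences (radians) of equal length.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' ph <- runif(1000, -pi, pi)
#' plv(ph, ph)        # 1: identical phases
#' plv(ph, ph + 1.2)  # 1: constant lag
plv <- function(phi, psi) {
  if (length(phi) != length(psi)) stop("phase sequences must have equal length")
  if (length(phi) < 2L) stop("need at least two time points")
  Mod(mean(exp(1i * (phi - psi))))
}

# match listener/speaker epoch sets trial-for-trial (topics, then rest)
align_trials <- function(listener, speaker) {
  li <- epochs_by_role(listener, "listen")
  sp <- epochs_by_role(speaker, "speak")
  lt <- vapply(listener$epochs[li], `[[`, character(1), "topic")
  st <- vapply(speaker$epochs[sp], `[[`, character(1), "topic")
  if (length(li) != length(sp) || !identical(lt, st)) {
    stop("listener and speaker trial sets are misaligned (topics must match)")
  }
  list(listener = li, speaker = sp, topics = lt,
       listener_rest = rest_epoch(listener), speaker_rest = rest_epoch(speaker))
}

#' Interbrain PLV tensor
#'
#' Computes the single-trial PLV between every listener channel and every
#' speaker channel, per frequency band and per trial (topics plus rest).
#' For the canonical 27-channel montage this yields 729 pairs per band and
#' a `27 x 27 x 4 x 6` tensor.
#'
#' @param listener,speaker [epoch_set()] objects with matching rate and
#'   epoch length, trial-aligned topic-for-topic.
#' @param bands List of [band_spec()] (default [canonical_bands()]).
#' @param trim Edge samples dropped before the PLV (default 1 s).
#' @return A 4-d array `listener x speaker x band x trial` with a `"rest"`
#'   trial slice when both sets contain a rest epoch.
#' @export
interbrain_plv <- function(listener, speaker, bands = canonical_bands(),
                           trim = round(listener$rate)) {
  stopifnot(inherits(listener, "epoch_set"), inherits(speaker, "epoch_set"))
  if (listener$rate != speaker$rate || listener$T != speaker$T) {
    stop("listener and speaker epoch sets must share rate and epoch length")
  }
  bands <- as_band_list(bands)
  al <- align_trials(listener, speaker)
  trials <- al$topics
  has_rest <- !is.null(al$listener_rest) && !is.null(al$speaker_rest)
  if (has_rest) trials <- c(trials, "rest")
  L <- length(listener$channels); S <- length(speaker$channels)
  out <- array(NA_real_, dim = c(L, S, length(bands), length(trials)),
               dimnames = list(listener = listener$channels,
                               speaker = speaker$channels,
                               band = names(bands), trial = trials))
  li_data <- c(lapply(al$listener, function(i) listener$epochs[[i]]$data),
               if (has_rest) list(al$listener_rest$data))
  sp_data <- c(lapply(al$speaker, function(i) speaker$epochs[[i]]$data),
               if (has_rest) list(al$speaker_rest$data))
  for (k in seq_along(trials)) {
    pl <- band_phasors(li_data[[k]], bands, listener$rate, trim = trim)
    ps <- band_phasors(sp_data[[k]], bands, speaker$rate, trim = trim)
    for (b in seq_along(bands)) out[, , b, k] <- cpp_plv_cross(pl[[b]], ps[[b]])
  }
  attr(out, "trim") <- as.integer(trim)
  out
}

#' Rest-baseline subtraction and topic collapse
#'
#' Subtracts the resting-condition PLV from each topic's PLV and averages
#' the differences across topics, yielding one coupling map per case.
#'
#' @param tensor A `listener x speaker x band x trial` PLV array with a
#'   `"rest"` trial slice (see [interbrain_plv()]).
#' @return A `listener x speaker x band` array of rest-corrected,
#'   topic-averaged PLV differences (values in `[-1, 1]`).
#' @export
rest_subtract_and_collapse <- function(tensor) {
  stopifnot(is.array(tensor), length(dim(tensor)) == 4L)
  trials <- dimnames(tensor)[[4L]]
  if (!"rest" %in% trials) stop("tensor has no rest slice; cannot baseline-subtract")
  topics <- setdiff(trials, "rest")
  if (length(topics) == 0L) stop("tensor has no topic slices")
  rest <- tensor[, , , "rest", drop = FALSE][, , , 1L, drop = FALSE]
  dim(rest) <- dim(tensor)[1:3]
  acc <- array(0, dim = dim(tensor)[1:3], dimnames = dimnames(tensor)[1:3])
  for (tp in topics) {
    sl <- tensor[, , , tp, drop = FALSE]
    dim(sl) <- dim(tensor)[1:3]
    acc <- acc + (sl - rest)
  }
  acc / length(topics)
}
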