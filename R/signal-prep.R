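# Raw dual-EEG recordings and their reduction to role-labelled epochs.

#' Construct a raw EEG recording
#'
#' @param samples Channels-by-time numeric matrix (amplitudes in microvolts).
#' @param rate Sampling rate in Hz.
#' @param channel_names Character vector of unique channel names; defaults
#'   to `ch01`, `ch02`, ...
#' @param reference Name of the current reference channel, or `"none"`.
#' @param markers Optional `data.frame(sample, role, topic)` with 0-based
#'   sample indices marking the first sample of each turn.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(samples, rate, channel_names = NULL,
                          reference = "none", markers = NULL) {
  stopifnot(is.matrix(samples), is.numeric(samples), rate > 0)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples) || anyDuplicated(channel_names)) {
    stop("channel_names must be unique and match the number of rows")
  }
  if (!is.null(markers)) {
    stopifnot(is.data.frame(markers), all(c("sample", "role", "topic") %in% names(markers)))
    if (any(markers$sample < 0 | markers$sample >= ncol(samples))) {
      stop("marker sample indices out of range")
    }
  }
  rownames(samples) <- channel_names
  structure(
    list(samples = samples, rate = rate, channel_names = channel_names,
         reference = reference, markers = markers),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (ref: %s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, x$reference))
  invisible(x)
}

#' Re-reference and band-filter a raw recording
#'
#' Re-references to a named channel (or the channel average), then applies
#' a zero-phase FIR high-pass followed by a zero-phase FIR low-pass.
#' Filter parameters are recorded in the `provenance` attribute.
#'
#' @param raw A [raw_recording()].
#' @param highpass,lowpass Cutoffs in Hz (`NULL` skips the stage).
#' @param new_reference Channel name, `"average"`, or `NULL` to keep the
#'   current reference.
#' @param highpass_order,lowpass_order Optional FIR orders; see
#'   [fir_design()] for the defaults.
#' @return A filtered `raw_recording`.
#' @export
preprocess_recording <- function(raw, highpass = 1, lowpass = 20,
                                 new_reference = NULL,
                                 highpass_order = NULL, lowpass_order = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  nyq <- raw$rate / 2
  for (f in c(highpass, lowpass)) {
    if (!is.null(f) && f >= nyq) stop("filter cutoff must be below the Nyquist frequency")
  }
  x <- raw$samples
  if (!is.null(new_reference)) {
    if (identical(new_reference, "average")) {
      x <- sweep(x, 2L, colMeans(x))
    } else {
      if (!new_reference %in% raw$channel_names) {
        stop("reference channel '", new_reference, "' not present in the recording")
      }
      x <- sweep(x, 2L, x[new_reference, ])
    }
    raw$reference <- new_reference
  }
  prov <- list(reference = raw$reference)
  if (!is.null(highpass)) {
    b <- fir_design("high", highpass, raw$rate, highpass_order)
    x <- fir_filtfilt(x, b)
    prov$highpass <- list(cutoff = highpass, order = attr(b, "order"),
                          window = "hamming", application = "forward-backward")
  }
  if (!is.null(lowpass)) {
    b <- fir_design("low", lowpass, raw$rate, lowpass_order)
    x <- fir_filtfilt(x, b)
    prov$lowpass <- list(cutoff = lowpass, order = attr(b, "order"),
                         window = "hamming", application = "forward-backward")
  }
  raw$samples <- x
  attr(raw, "provenance") <- prov
  raw
}

#' Screen for bad channels
#'
#' Simple variance/flatline screen: flags channels that are (nearly)
#' constant or whose log-variance deviates from the montage median by
#' more than `z` robust standard deviations. Optionally replaces flagged
#' channels by the average of the remaining channels. Off by default in
#' the pipeline (synthetic data needs none; real recordings are expected
#' to arrive cleaned).
#'
#' @param raw A [raw_recording()].
#' @param z Robust z threshold on log channel variance (default 4).
#' @param flat_tol Channels with SD below this are flagged as flat.
#' @param interpolate Replace flagged channels by the mean of the
#'   remaining channels (default `FALSE`: flag only).
#' @return `raw` with attribute `bad_channels` (character vector);
#'   flagged channels replaced when `interpolate = TRUE`.
#' @export
screen_bad_channels <- function(raw, z = 4, flat_tol = 1e-10, interpolate = FALSE) {
  stopifnot(inherits(raw, "raw_recording"))
  v <- apply(raw$samples, 1L, stats::var)
  flat <- v < flat_tol^2
  lv <- log(pmax(v, flat_tol^2))
  dev <- abs(lv - stats::median(lv)) / max(stats::mad(lv), 1e-12)
  bad <- flat | dev > z
  if (any(bad) && !all(bad) && interpolate) {
    fill <- colMeans(raw$samples[!bad, , drop = FALSE])
    for (i in which(bad)) raw$samples[i, ] <- fill
  }
  attr(raw, "bad_channels") <- raw$channel_names[bad]
  raw
}

#' Construct an epoch set
#'
#' @param epochs List of epochs, each `list(role, topic, data)` with `data`
#'   a channels-by-time matrix; roles are `"speak"`, `"listen"` or `"rest"`.
#' @param rate Sampling rate in Hz.
#' @param channels Channel names common to all epochs.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(epochs, rate, channels) {
  stopifnot(is.list(epochs), length(epochs) >= 1L, rate > 0)
  T <- ncol(epochs[[1L]]$data)
  for (e in epochs) {
    stopifnot(is.matrix(e$data))
    if (nrow(e$data) != length(channels) || ncol(e$data) != T) {
      stop("all epochs must share the channel count and epoch length")
    }
    if (!e$role %in% c("speak", "listen", "rest")) stop("unknown epoch role: ", e$role)
  }
  structure(list(epochs = epochs, rate = rate, channels = channels, T = T),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  roles <- table(vapply(x$epochs, `[[`, character(1), "role"))
  cat(sprintf("<epoch_set> %d epochs (%s), %d channels x %d samples @ %g Hz\n",
              length(x$epochs),
              paste(sprintf("%s: %d", names(roles), roles), collapse = ", "),
              length(x$channels), x$T, x$rate))
  invisible(x)
}

# epochs of one role, ordered by topic; falls back to all non-rest epochs
# when the requested role is absent (e.g. ad-hoc sets built for testing)
epochs_by_role <- function(es, role) {
  roles <- vapply(es$epochs, `[[`, character(1), "role")
  idx <- which(roles == role)
  if (length(idx) == 0L && role != "rest") idx <- which(roles != "rest")
  topics <- vapply(es$epochs[idx], `[[`, character(1), "topic")
  idx[order(topics)]
}

rest_epoch <- function(es) {
  roles <- vapply(es$epochs, `[[`, character(1), "role")
  idx <- which(roles == "rest")
  if (length(idx) == 0L) return(NULL)
  es$epochs[[idx[1L]]]
}

#' Extract role-labelled epochs from a continuous recording
#'
#' Slices fixed-length epochs starting at each marker; intervals are
#' half-open `[start, start + T)` with 0-based marker indices.
#'
#' @param raw A [raw_recording()] with markers, or a separate `manifest`.
#' @param manifest Optional `data.frame(sample, role, topic)` overriding
#'   `raw$markers`.
#' @param epoch_len Epoch length in seconds; `epoch_len * rate` must be an
#'   integer.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(raw, manifest = NULL, epoch_len = 90) {
  stopifnot(inherits(raw, "raw_recording"))
  if (is.null(manifest)) manifest <- raw$markers
  if (is.null(manifest)) stop("no markers available for epoch extraction")
  T <- epoch_len * raw$rate
  if (abs(T - round(T)) > 1e-9) stop("epoch_len * rate must be an integer sample count")
  T <- as.integer(round(T))
  n_avail <- ncol(raw$samples)
  epochs <- lapply(seq_len(nrow(manifest)), function(i) {
    s0 <- manifest$sample[i]
    if (s0 + T > n_avail) {
      stop(sprintf("epoch at marker %d (sample %d, %s/%s) is truncated: needs %d samples, %d available",
                   i, s0, manifest$role[i], manifest$topic[i], T, n_avail - s0))
    }
    list(role = manifest$role[i], topic = manifest$topic[i],
         data = raw$samples[, seq.int(s0 + 1L, s0 + T), drop = FALSE])
  })
  if (!any(manifest$role == "rest")) {
    warning("no rest epoch in the manifest; rest-baseline subtraction will be unavailable")
  }
  epoch_set(epochs, raw$rate, raw$channel_names)
}
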