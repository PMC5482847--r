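# Speech amplitude envelope extraction and brain-to-envelope PLV with
# intra-brain correction.

#' Speech amplitude envelope from audio
#'
#' Computes a short-time power spectrogram, sums the power over an
#' acoustic band, takes the square root (amplitude) and resamples the
#' frame series to the EEG rate. Defaults: Hamming window 25 ms, hop 4 ms
#' (a 250 Hz frame rate), acoustic band 100-4000 Hz.
#'
#' @param audio Numeric waveform.
#' @param rate Audio sampling rate in Hz (>= 8 kHz).
#' @param win,hop Spectrogram window and hop in seconds.
#' @param band Acoustic band limits in Hz over which power is summed.
#' @param out_rate Output (EEG) rate in Hz.
#' @return Non-negative numeric envelope of length
#'   `round(length(audio) / rate * out_rate)`, with attribute `rate`.
#' @export
amplitude_envelope <- function(audio, rate, win = 0.025, hop = 0.004,
                               band = c(100, 4000), out_rate = 250) {
  stopifnot(is.numeric(audio), length(audio) > 0)
  if (rate < 8000) stop("audio rate must be at least 8 kHz")
  n_out <- round(length(audio) / rate * out_rate)
  if (all(audio == 0)) {
    warning("all-zero audio: returning an all-zero envelope")
    return(structure(numeric(n_out), rate = out_rate))
  }
  n <- round(win * rate)
  h <- max(1L, round(hop * rate))
  sg <- signal::specgram(audio, n = n, Fs = rate, overlap = n - h)
  pw <- Mod(sg$S)^2
  sel <- sg$f >= band[1] & sg$f <= min(band[2], rate / 2)
  if (!any(sel)) stop("acoustic band selects no spectrogram bins")
  amp <- sqrt(colSums(pw[sel, , drop = FALSE]))
  t_out <- (seq_len(n_out) - 1) / out_rate
  env <- approx(sg$t, amp, xout = t_out, rule = 2)$y
  env[env < 0] <- 0
  structure(env, rate = out_rate)
}

# per-topic brain-to-envelope PLV from precomputed unit phasors
# eeg_ph, env_ph: lists band -> list topic -> (T x ch) / (T x 1)
env_plv_from_phasors <- function(eeg_ph, env_ph, channels, bands, topics) {
  out <- array(NA_real_, dim = c(length(channels), length(bands), length(topics)),
               dimnames = list(channel = channels, band = bands, topic = topics))
  for (b in seq_along(bands)) {
    for (k in seq_along(topics)) {
      out[, b, k] <- drop(cpp_plv_cross(eeg_ph[[b]][[k]], env_ph[[b]][[k]]))
    }
  }
  out
}

# mean PLV over all distinct within-subject sensor pairs, per band x topic
intra_mean_from_phasors <- function(eeg_ph, bands, topics) {
  out <- matrix(NA_real_, length(bands), length(topics),
                dimnames = list(band = bands, topic = topics))
  for (b in seq_along(bands)) {
    for (k in seq_along(topics)) {
      pm <- cpp_plv_cross(eeg_ph[[b]][[k]], eeg_ph[[b]][[k]])
      out[b, k] <- mean(pm[upper.tri(pm)])
    }
  }
  out
}

#' Brain-to-envelope phase synchronization
#'
#' PLV between each band-filtered EEG channel and the band-filtered speech
#' amplitude envelope, per topic, collapsed across topics by averaging.
#'
#' @param epochs An [epoch_set()]; epochs of one role (the role whose
#'   entrainment is being measured), one per topic.
#' @param envelopes Amplitude envelope(s) at the EEG rate: a numeric
#'   vector (single epoch) or a list named by topic.
#' @param bands List of [band_spec()].
#' @param role Which role's epochs to use: `"listen"`, `"speak"`, or
#'   `"any"` (all non-rest epochs).
#' @param trim Edge samples dropped before the PLV.
#' @return A channels-by-band matrix of uncorrected envelope PLVs with
#'   attributes `per_topic` (3-d array) and `corrected = FALSE`.
#' @export
brain_envelope_plv <- function(epochs, envelopes, bands = canonical_bands(),
                               role = "any", trim = round(epochs$rate)) {
  stopifnot(inherits(epochs, "epoch_set"))
  bands <- as_band_list(bands)
  idx <- if (role == "any") epochs_by_role(epochs, "none") else epochs_by_role(epochs, role)
  topics <- vapply(epochs$epochs[idx], `[[`, character(1), "topic")
  if (is.numeric(envelopes)) {
    if (length(idx) != 1L) stop("a single envelope requires a single matching epoch")
    envelopes <- setNames(list(envelopes), topics)
  }
  if (!all(topics %in% names(envelopes))) stop("missing envelope for topic(s): ",
                                               paste(setdiff(topics, names(envelopes)), collapse = ", "))
  eeg_ph <- env_ph <- rep(list(vector("list", length(topics))), length(bands))
  for (k in seq_along(topics)) {
    ep <- epochs$epochs[[idx[k]]]$data
    env <- envelopes[[topics[k]]]
    if (length(env) != ncol(ep)) stop("envelope and epoch lengths differ for topic ", topics[k])
    pe <- band_phasors(ep, bands, epochs$rate, trim = trim)
    pv <- band_phasors(env - mean(env), bands, epochs$rate, trim = trim)
    for (b in seq_along(bands)) {
      eeg_ph[[b]][[k]] <- pe[[b]]
      env_ph[[b]][[k]] <- pv[[b]]
    }
  }
  per_topic <- env_plv_from_phasors(eeg_ph, env_ph, epochs$channels, names(bands), topics)
  out <- apply(per_topic, c(1, 2), mean)
  attr(out, "per_topic") <- per_topic
  attr(out, "corrected") <- FALSE
  out
}

#' Intra-brain PLV correction of envelope synchronization
#'
#' For each band, the mean PLV over all distinct within-subject sensor
#' pairs (computed per topic on the same epochs, then averaged across
#' topics) is subtracted from every channel's brain-envelope PLV. This
#' removes the subject's global within-brain synchrony level from the
#' envelope coupling estimate.
#'
#' @param env_plv Uncorrected output of [brain_envelope_plv()].
#' @param epochs,bands,role,trim As passed to [brain_envelope_plv()].
#' @return The corrected channels-by-band matrix (`corrected = TRUE`),
#'   with the per-band correction stored in attribute `intra_mean`.
#' @export
intrabrain_correction <- function(env_plv, epochs, bands = canonical_bands(),
                                  role = "any", trim = round(epochs$rate)) {
  if (isTRUE(attr(env_plv, "corrected"))) stop("envelope PLV is already corrected")
  bands <- as_band_list(bands)
  idx <- if (role == "any") epochs_by_role(epochs, "none") else epochs_by_role(epochs, role)
  topics <- vapply(epochs$epochs[idx], `[[`, character(1), "topic")
  eeg_ph <- rep(list(vector("list", length(topics))), length(bands))
  for (k in seq_along(topics)) {
    pe <- band_phasors(epochs$epochs[[idx[k]]]$data, bands, epochs$rate, trim = trim)
    for (b in seq_along(bands)) eeg_ph[[b]][[k]] <- pe[[b]]
  }
  im <- intra_mean_from_phasors(eeg_ph, names(bands), topics)
  correction <- rowMeans(im)
  out <- sweep(unclass(env_plv), 2L, correction)
  attr(out, "per_topic") <- NULL
  attr(out, "corrected") <- TRUE
  attr(out, "intra_mean") <- correction
  out
}
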