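# Role-preserving, non-time-corresponding surrogate datasets: the null
# hypothesis keeps each participant's role and signal statistics but
# pairs signals (or envelopes) from different topics, destroying genuine
# moment-to-moment coupling.

#' Enumerate trial-shuffled surrogate pairings
#'
#' All ordered pairs of unequal topic indices. With 5 topics this yields
#' the 20 surrogate combinations.
#'
#' @param n_topics Number of topic trials (>= 2).
#' @return `data.frame(listener_trial, speaker_trial)` with
#'   `n_topics * (n_topics - 1)` rows.
#' @export
enumerate_surrogate_pairings <- function(n_topics) {
  if (!is.numeric(n_topics) || n_topics < 2) stop("n_topics must be at least 2")
  n_topics <- as.integer(n_topics)
  g <- expand.grid(listener_trial = seq_len(n_topics), speaker_trial = seq_len(n_topics))
  g <- g[g$listener_trial != g$speaker_trial, , drop = FALSE]
  rownames(g) <- NULL
  g
}

# shared kernel: surrogate coupling map from per-band, per-trial phasors.
# li_ph/sp_ph: band -> list over topics of T x ch phasor matrices;
# rest_map: L x S x band rest PLV (subtracted from every pairing).
surrogate_map_from_phasors <- function(li_ph, sp_ph, rest_map, pairings, dn) {
  acc <- array(0, dim = dim(rest_map), dimnames = dn)
  for (r in seq_len(nrow(pairings))) {
    i <- pairings$listener_trial[r]; j <- pairings$speaker_trial[r]
    for (b in seq_along(li_ph)) {
      acc[, , b] <- acc[, , b] + (cpp_plv_cross(li_ph[[b]][[i]], sp_ph[[b]][[j]]) - rest_map[, , b])
    }
  }
  acc / nrow(pairings)
}

#' Surrogate interbrain coupling map
#'
#' Interbrain PLV computed for every non-matching topic pairing of
#' listener and speaker epochs (roles preserved), with the same rest
#' subtraction applied to each pairing, averaged over all pairings.
#'
#' @inheritParams interbrain_plv
#' @return A `listener x speaker x band` surrogate coupling map,
#'   deterministic given the epochs (all pairings are enumerated).
#' @export
surrogate_interbrain <- function(listener, speaker, bands = canonical_bands(),
                                 trim = round(listener$rate)) {
  stopifnot(inherits(listener, "epoch_set"), inherits(speaker, "epoch_set"))
  bands <- as_band_list(bands)
  al <- align_trials(listener, speaker)
  if (is.null(al$listener_rest) || is.null(al$speaker_rest)) {
    stop("both participants need a rest epoch for the surrogate map")
  }
  n_topics <- length(al$topics)
  pairings <- enumerate_surrogate_pairings(n_topics)
  li_ph <- sp_ph <- rep(list(vector("list", n_topics)), length(bands))
  for (k in seq_len(n_topics)) {
    pl <- band_phasors(listener$epochs[[al$listener[k]]]$data, bands, listener$rate, trim = trim)
    ps <- band_phasors(speaker$epochs[[al$speaker[k]]]$data, bands, speaker$rate, trim = trim)
    for (b in seq_along(bands)) {
      li_ph[[b]][[k]] <- pl[[b]]
      sp_ph[[b]][[k]] <- ps[[b]]
    }
  }
  rl <- band_phasors(al$listener_rest$data, bands, listener$rate, trim = trim)
  rs <- band_phasors(al$speaker_rest$data, bands, speaker$rate, trim = trim)
  L <- length(listener$channels); S <- length(speaker$channels)
  dn <- list(listener = listener$channels, speaker = speaker$channels, band = names(bands))
  rest_map <- array(NA_real_, dim = c(L, S, length(bands)), dimnames = dn)
  for (b in seq_along(bands)) rest_map[, , b] <- cpp_plv_cross(rl[[b]], rs[[b]])
  surrogate_map_from_phasors(li_ph, sp_ph, rest_map, pairings, dn)
}

#' Surrogate brain-to-envelope synchronization
#'
#' Brain-envelope PLV for every non-matching envelope/EEG topic pairing
#' (with the intra-brain correction applied exactly as for real data),
#' averaged over all pairings.
#'
#' @inheritParams brain_envelope_plv
#' @return A corrected channels-by-band surrogate envelope PLV matrix.
#' @export
surrogate_envelope <- function(epochs, envelopes, bands = canonical_bands(),
                               role = "any", trim = round(epochs$rate)) {
  stopifnot(inherits(epochs, "epoch_set"))
  bands <- as_band_list(bands)
  idx <- if (role == "any") epochs_by_role(epochs, "none") else epochs_by_role(epochs, role)
  topics <- vapply(epochs$epochs[idx], `[[`, character(1), "topic")
  if (!all(topics %in% names(envelopes))) stop("missing envelope for topic(s): ",
                                               paste(setdiff(topics, names(envelopes)), collapse = ", "))
  n_topics <- length(topics)
  pairings <- enumerate_surrogate_pairings(n_topics)
  eeg_ph <- env_ph <- rep(list(vector("list", n_topics)), length(bands))
  for (k in seq_len(n_topics)) {
    pe <- band_phasors(epochs$epochs[[idx[k]]]$data, bands, epochs$rate, trim = trim)
    env <- envelopes[[topics[k]]]
    pv <- band_phasors(env - mean(env), bands, epochs$rate, trim = trim)
    for (b in seq_along(bands)) {
      eeg_ph[[b]][[k]] <- pe[[b]]
      env_ph[[b]][[k]] <- pv[[b]]
    }
  }
  im <- intra_mean_from_phasors(eeg_ph, names(bands), topics)
  acc <- matrix(0, length(epochs$channels), length(bands),
                dimnames = list(channel = epochs$channels, band = names(bands)))
  for (r in seq_len(nrow(pairings))) {
    i <- pairings$listener_trial[r]   # envelope topic
    j <- pairings$speaker_trial[r]    # EEG topic
    for (b in seq_along(bands)) {
      acc[, b] <- acc[, b] + (drop(cpp_plv_cross(eeg_ph[[b]][[j]], env_ph[[b]][[i]])) - im[b, j])
    }
  }
  out <- acc / nrow(pairings)
  attr(out, "corrected") <- TRUE
  out
}
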