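# Synthetic dyad sessions with known ground truth. Channels are 1/f
# noise plus one band-limited stochastic phase oscillator per analysis
# band. Interbrain coupling is produced by attracting the listener's and
# the speaker's oscillator toward a shared trial-unique driver phase;
# envelope entrainment by attracting an oscillator toward the phase of
# the band-filtered speech envelope. Coupling strength kappa in [0, 1]
# scales the attraction and maps monotonically onto the PLV.

#' Standard 27-channel 10-20 montage
#'
#' @param n Number of channels; for `n = 27` the standard 10-20 labels
#'   are used, otherwise generic `ch01..chNN` names.
#' @return Character vector of channel names.
#' @export
montage_channels <- function(n = 27) {
  if (n == 27) {
    c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "FC1", "FC2", "FC5", "FC6",
      "C3", "C4", "T7", "T8", "CP1", "CP2", "CP5", "CP6", "P3", "P4",
      "P7", "P8", "O1", "O2", "Fz", "Cz", "Pz")
  } else {
    sprintf("ch%02d", seq_len(n))
  }
}

#' Configuration for synthetic dyad generation
#'
#' Defaults mirror the study design being emulated: 15 dyads, 27 channels
#' at 250 Hz, 90-second epochs, 5 conversation topics (plus rest), a 5 Hz
#' syllable rate, and the four canonical bands.
#'
#' @param n_dyads,n_channels,rate,epoch_len,n_topics Study geometry.
#' @param bands List of [band_spec()].
#' @param coupling `data.frame(listener, speaker, band, kappa)` giving
#'   interbrain coupled channel pairs (channel names or indices); kappa in
#'   `[0, 1]`. A channel-band may appear in at most one entry per side.
#' @param env_coupling `data.frame(role, channel, band, kappa)` giving
#'   envelope-entrained channels per role (`"speak"`/`"listen"`).
#' @param syllable_rate Syllabic rhythm of the generated envelopes (Hz).
#' @param noise_exponent Spectral slope of the 1/f background noise.
#' @param noise_sd Background noise SD relative to oscillator amplitude.
#' @param osc_amp Amplitude of each band oscillator.
#' @param phase_noise_sd Oscillator phase-noise SD (rad/sample); drives
#'   decoherence of uncoupled oscillators.
#' @param noise_substep Samples per phase-noise innovation (innovations
#'   are held constant within each block and scaled to keep the random
#'   walk variance `phase_noise_sd^2` per sample; the default, 5 samples
#'   = 50 Hz at the 250 Hz rate, is far above every analysis band).
#' @param attraction_gain Attraction toward the driver at kappa = 1
#'   (rad/sample).
#' @param driver_noise_sd Driver phase-noise SD (rad/sample).
#' @param detune_sd Per-oscillator frequency detuning SD (Hz).
#' @param case_scale_range Range of the per-case multiplier applied to
#'   envelope-coupling kappas (induces across-case variability used by
#'   mediation analyses); default `c(1, 1)` = no variability.
#' @param channels Channel names; default [montage_channels()].
#' @param seed Master seed; per-dyad substreams are derived from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_dyads = 15, n_channels = 27, rate = 250,
                         epoch_len = 90, n_topics = 5,
                         bands = canonical_bands(), coupling = NULL,
                         env_coupling = NULL, syllable_rate = 5,
                         noise_exponent = 1, noise_sd = 1, osc_amp = 1,
                         phase_noise_sd = 0.1, noise_substep = 5,
                         attraction_gain = 0.25,
                         driver_noise_sd = 0.05, detune_sd = 0.1,
                         case_scale_range = c(1, 1), channels = NULL,
                         seed = 1) {
  stopifnot(n_dyads >= 1, n_channels >= 1, rate > 0, epoch_len > 0, n_topics >= 2)
  T <- rate * epoch_len
  if (abs(T - round(T)) > 1e-9) stop("rate * epoch_len must be an integer sample count")
  if (!(syllable_rate > 0.5 && syllable_rate < 10)) {
    stop("syllable_rate must lie in (0.5, 10) Hz")
  }
  bands <- as_band_list(bands)
  if (is.null(channels)) channels <- montage_channels(n_channels)
  stopifnot(length(channels) == n_channels)
  norm_chan <- function(x) {
    if (is.numeric(x)) {
      if (any(x < 1 | x > n_channels)) stop("coupling channel index out of range")
      channels[x]
    } else {
      if (!all(x %in% channels)) stop("unknown coupling channel name(s)")
      as.character(x)
    }
  }
  if (!is.null(coupling)) {
    stopifnot(is.data.frame(coupling),
              all(c("listener", "speaker", "band", "kappa") %in% names(coupling)))
    if (any(coupling$kappa < 0 | coupling$kappa > 1)) stop("kappa must lie in [0, 1]")
    if (!all(coupling$band %in% names(bands))) stop("coupling references unknown band(s)")
    coupling$listener <- norm_chan(coupling$listener)
    coupling$speaker <- norm_chan(coupling$speaker)
    if (anyDuplicated(coupling[c("listener", "band")]) ||
        anyDuplicated(coupling[c("speaker", "band")])) {
      stop("a channel-band may appear in at most one coupling entry per side")
    }
  }
  if (!is.null(env_coupling)) {
    stopifnot(is.data.frame(env_coupling),
              all(c("role", "channel", "band", "kappa") %in% names(env_coupling)))
    if (any(env_coupling$kappa < 0 | env_coupling$kappa > 1)) stop("kappa must lie in [0, 1]")
    if (!all(env_coupling$band %in% names(bands))) stop("env_coupling references unknown band(s)")
    if (!all(env_coupling$role %in% c("speak", "listen"))) stop("env_coupling roles must be speak/listen")
    env_coupling$channel <- norm_chan(env_coupling$channel)
    if (anyDuplicated(env_coupling[c("role", "channel", "band")])) {
      stop("duplicate env_coupling entries")
    }
  }
  structure(list(
    n_dyads = n_dyads, n_channels = n_channels, rate = rate,
    epoch_len = epoch_len, n_topics = n_topics, bands = bands,
    coupling = coupling, env_coupling = env_coupling,
    syllable_rate = syllable_rate, noise_exponent = noise_exponent,
    noise_sd = noise_sd, osc_amp = osc_amp,
    phase_noise_sd = phase_noise_sd, noise_substep = as.integer(noise_substep),
    attraction_gain = attraction_gain,
    driver_noise_sd = driver_noise_sd, detune_sd = detune_sd,
    case_scale_range = case_scale_range, channels = channels,
    T = as.integer(round(T)), seed = as.integer(seed)
  ), class = "synth_config")
}

#' Generate a quasi-rhythmic speech amplitude envelope
#'
#' Product of a syllabic (`syllable_rate`, theta-range) and a slower
#' phrasal (~2 Hz, delta-range) rectified modulator, each a noisy phase
#' oscillator, so the fluctuation spectrum carries a dominant syllabic
#' peak plus a delta component — the quasi-rhythms of connected speech.
#'
#' @param duration Epoch duration in seconds (> 0).
#' @param rate Sampling rate in Hz.
#' @param syllable_rate Syllable rate in Hz, in (0.5, 10).
#' @param seed Integer seed (reproducible output).
#' @return Non-negative numeric vector of length `duration * rate` with
#'   attribute `rate`.
#' @export
generate_speech_envelope <- function(duration, rate = 250, syllable_rate = 5, seed = 1) {
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (!is.numeric(rate) || rate <= 0) stop("rate must be positive")
  if (!(syllable_rate > 0.5 && syllable_rate < 10)) stop("syllable_rate must lie in (0.5, 10) Hz")
  T <- as.integer(round(duration * rate))
  set.seed(seed)
  th_s <- runif(1, -pi, pi) + cumsum(2 * pi * syllable_rate / rate + rnorm(T, 0, 0.03))
  th_d <- runif(1, -pi, pi) + cumsum(2 * pi * 2 / rate + rnorm(T, 0, 0.02))
  syl <- (1 + sin(th_s)) / 2
  slow <- (1 + sin(th_d)) / 2
  env <- (0.3 + 0.7 * syl) * (0.5 + 0.5 * slow)
  structure(env, rate = rate)
}

# per-bin spectral amplitudes for 1/f^exponent noise, cached per (T, exponent)
.pink_cache <- new.env(parent = emptyenv())
pink_amp <- function(T, exponent) {
  key <- paste(T, exponent, sep = "|")
  a <- .pink_cache[[key]]
  if (is.null(a)) {
    a <- c(0, seq_len(T %/% 2)^(-exponent / 2))
    .pink_cache[[key]] <- a
  }
  a
}

# one synthetic epoch: channels x T matrix of oscillators + 1/f noise.
# coup: data.frame(channel, band, kappa, driver) rows active here;
# drv: T x K driver phases; ent: data.frame(channel, band, kappa);
# env_phase: T x B matrix of envelope band phases (or NULL).
synth_epoch <- function(cfg, coup, drv, ent, env_phase, seed) {
  T <- cfg$T; nch <- cfg$n_channels; B <- length(cfg$bands)
  fb <- vapply(cfg$bands, function(b) (b$lo + b$hi) / 2, numeric(1))
  n <- nch * B
  ch_i <- rep(seq_len(nch), each = B)
  bd_i <- rep(seq_len(B), times = nch)
  set.seed(seed)
  omega <- 2 * pi * fb[bd_i] / cfg$rate + rnorm(n, 0, 2 * pi * cfg$detune_sd / cfg$rate)
  theta0 <- runif(n, -pi, pi)
  kap1 <- numeric(n); idx1 <- rep(1L, n)
  if (!is.null(coup) && nrow(coup) > 0L) {
    oi <- (match(coup$channel, cfg$channels) - 1L) * B + match(coup$band, names(cfg$bands))
    kap1[oi] <- coup$kappa
    idx1[oi] <- coup$driver
  }
  kap2 <- numeric(n); idx2 <- rep(1L, n)
  if (!is.null(ent) && nrow(ent) > 0L && !is.null(env_phase)) {
    oi <- (match(ent$channel, cfg$channels) - 1L) * B + match(ent$band, names(cfg$bands))
    kap2[oi] <- ent$kappa
    idx2[oi] <- match(ent$band, names(cfg$bands))
  }
  if (is.null(drv)) drv <- matrix(0, T, 1L)
  if (is.null(env_phase)) env_phase <- matrix(0, T, 1L)
  sub <- cfg$noise_substep
  n_inn <- (T + sub - 1L) %/% sub
  noise <- if (cfg$phase_noise_sd > 0) matrix(rnorm(n_inn * n), n_inn, n) else matrix(0, n_inn, n)
  # innovation held constant within each substep block: scaling by
  # 1/sqrt(sub) keeps the random-walk variance sigma^2 * t per sample
  osc <- cpp_osc_bank(T, nch, ch_i, rep(cfg$osc_amp, n), omega,
                      rep(cfg$phase_noise_sd / sqrt(sub), n), theta0, kap1, idx1, drv,
                      kap2, idx2, env_phase, cfg$attraction_gain, noise, sub, FALSE)
  x <- osc$signal
  if (cfg$noise_sd > 0) {
    nf <- T %/% 2L + 1L
    white <- matrix(rnorm(2L * nf * nch), 2L * nf, nch)
    x <- x + cfg$noise_sd * cpp_pink_noise(T, pink_amp(T, cfg$noise_exponent), white)
  }
  t(x)
}

# driver phases for the interbrain coupling entries of one turn
synth_drivers <- function(cfg, seed) {
  K <- if (is.null(cfg$coupling)) 0L else nrow(cfg$coupling)
  if (K == 0L) return(NULL)
  set.seed(seed)
  fb <- vapply(cfg$bands, function(b) (b$lo + b$hi) / 2, numeric(1))
  f <- fb[match(cfg$coupling$band, names(cfg$bands))]
  drv <- matrix(0, cfg$T, K)
  for (k in seq_len(K)) {
    drv[, k] <- runif(1, -pi, pi) +
      cumsum(2 * pi * f[k] / cfg$rate + rnorm(cfg$T, 0, cfg$driver_noise_sd))
  }
  drv
}

# envelope band phases used as entrainment drivers (no trim)
envelope_band_phase <- function(env, bands, rate) {
  ph <- band_phasors(env - mean(env), bands, rate, trim = 0L, unit = FALSE)
  do.call(cbind, lapply(ph, function(z) Arg(z[, 1L])))
}

#' Generate one synthetic dyad session
#'
#' Produces, per participant, 11 role-labelled epochs (5 speak, 5 listen,
#' 1 rest) plus one speech envelope per speaking turn, with interbrain
#' coupling and envelope entrainment injected per the configuration.
#' Rest epochs contain no cross-participant coupling.
#'
#' @param config A [synth_config()].
#' @param dyad Dyad index in `1..n_dyads`; each dyad has its own
#'   deterministic substream of the master seed.
#' @return A `dyad_session` list: `epochs` (named list of [epoch_set()]
#'   for participants `"A"` and `"B"`), `envelopes` (one per speaking
#'   turn, named `"<topic>.<speaker>"`), `topics`, `truth` (ground-truth
#'   coupled pairs, entrained channels and per-case envelope scale).
#' @export
generate_dyad_session <- function(config, dyad = 1) {
  stopifnot(inherits(config, "synth_config"), dyad >= 1, dyad <= config$n_dyads)
  cfg <- config
  set.seed(cfg$seed)
  dyad_seed <- sample.int(2^31 - 2, cfg$n_dyads)[dyad]
  set.seed(dyad_seed)
  u <- runif(2, cfg$case_scale_range[1L], cfg$case_scale_range[2L])
  names(u) <- c("A", "B")
  n_units <- cfg$n_topics * 2L * 4L + 2L
  useed <- sample.int(.Machine$integer.max, n_units)
  topics <- sprintf("topic%d", seq_len(cfg$n_topics))
  epochs <- list(A = list(), B = list())
  envelopes <- list()
  ent_for <- function(role, scale) {
    ec <- cfg$env_coupling
    if (is.null(ec)) return(NULL)
    ec <- ec[ec$role == role, , drop = FALSE]
    if (nrow(ec) == 0L) return(NULL)
    ec$kappa <- pmin(1, ec$kappa * scale)
    ec
  }
  coup_for <- function(side) {
    cc <- cfg$coupling
    if (is.null(cc)) return(NULL)
    data.frame(channel = cc[[side]], band = cc$band, kappa = cc$kappa,
               driver = seq_len(nrow(cc)))
  }
  s <- 0L
  for (ti in seq_len(cfg$n_topics)) {
    for (speaker in c("A", "B")) {
      listener <- if (speaker == "A") "B" else "A"
      env_seed <- useed[s + 1L]; drv_seed <- useed[s + 2L]
      sp_seed <- useed[s + 3L]; li_seed <- useed[s + 4L]
      s <- s + 4L
      env <- generate_speech_envelope(cfg$epoch_len, cfg$rate, cfg$syllable_rate, env_seed)
      env_phase <- envelope_band_phase(env, cfg$bands, cfg$rate)
      drv <- synth_drivers(cfg, drv_seed)
      sp_data <- synth_epoch(cfg, coup_for("speaker"), drv,
                             ent_for("speak", u[[speaker]]), env_phase, sp_seed)
      li_data <- synth_epoch(cfg, coup_for("listener"), drv,
                             ent_for("listen", u[[speaker]]), env_phase, li_seed)
      rownames(sp_data) <- rownames(li_data) <- cfg$channels
      epochs[[speaker]] <- c(epochs[[speaker]],
                             list(list(role = "speak", topic = topics[ti], data = sp_data)))
      epochs[[listener]] <- c(epochs[[listener]],
                              list(list(role = "listen", topic = topics[ti], data = li_data)))
      envelopes[[paste(topics[ti], speaker, sep = ".")]] <-
        list(topic = topics[ti], speaker = speaker, values = env)
    }
  }
  for (p in c("A", "B")) {
    rest <- synth_epoch(cfg, NULL, NULL, NULL, NULL, useed[s + 1L])
    s <- s + 1L
    rownames(rest) <- cfg$channels
    epochs[[p]] <- c(epochs[[p]], list(list(role = "rest", topic = "rest", data = rest)))
  }
  truth <- list(
    coupled_pairs = if (is.null(cfg$coupling)) NULL else
      cfg$coupling[cfg$coupling$kappa > 0, , drop = FALSE],
    entrained = if (is.null(cfg$env_coupling)) NULL else
      cfg$env_coupling[cfg$env_coupling$kappa > 0, , drop = FALSE],
    case_scale = u
  )
  structure(list(
    dyad = dyad, rate = cfg$rate, channels = cfg$channels, topics = topics,
    participants = c("A", "B"),
    epochs = list(A = epoch_set(epochs$A, cfg$rate, cfg$channels),
                  B = epoch_set(epochs$B, cfg$rate, cfg$channels)),
    envelopes = envelopes, truth = truth
  ), class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf("<dyad_session %d> %d channels, topics: %s; %d envelopes\n",
              x$dyad, length(x$channels), paste(x$topics, collapse = ", "),
              length(x$envelopes)))
  invisible(x)
}

#' Flatten a session participant into a continuous recording
#'
#' Concatenates the participant's epochs (in recorded order) with silent
#' gaps and builds the marker table, for exercising the continuous
#' preprocessing/extraction path.
#'
#' @param session A [generate_dyad_session()] result.
#' @param participant `"A"` or `"B"`.
#' @param gap_s Gap between epochs in seconds.
#' @return A [raw_recording()] with markers.
#' @export
session_to_recording <- function(session, participant = "A", gap_s = 2) {
  es <- session$epochs[[participant]]
  gap <- matrix(0, length(es$channels), round(gap_s * es$rate))
  pieces <- list()
  markers <- NULL
  pos <- 0L
  for (e in es$epochs) {
    markers <- rbind(markers, data.frame(sample = pos, role = e$role, topic = e$topic))
    pieces <- c(pieces, list(e$data, gap))
    pos <- pos + ncol(e$data) + ncol(gap)
  }
  samples <- do.call(cbind, pieces)
  raw_recording(samples, es$rate, es$channels, markers = markers)
}

#' Synthesize turn audio from an envelope
#'
#' Amplitude-modulated broadband noise carrier whose amplitude envelope
#' is the supplied one; used to produce WAV fixtures whose
#' [amplitude_envelope()] approximately recovers the original.
#'
#' @param env Envelope at the EEG rate (attribute `rate`).
#' @param audio_rate Audio sampling rate (>= 8 kHz).
#' @param seed Integer seed for the noise carrier.
#' @return Numeric waveform in `[-1, 1]` with attribute `rate`.
#' @export
synth_turn_audio <- function(env, audio_rate = 8000, seed = 1) {
  env_rate <- attr(env, "rate") %||% 250
  n_out <- round(length(env) / env_rate * audio_rate)
  t_env <- (seq_along(env) - 1) / env_rate
  t_out <- (seq_len(n_out) - 1) / audio_rate
  env_up <- approx(t_env, as.numeric(env), xout = t_out, rule = 2)$y
  set.seed(seed)
  x <- env_up * rnorm(n_out)
  structure(x / max(abs(x)) * 0.9, rate = audio_rate)
}
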