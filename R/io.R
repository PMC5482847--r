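# Plain-format I/O: mono PCM16 WAV audio and the session fixture format
# (JSON sidecar manifest + raw float64 binary matrices). No R package in
# scope reads WAV, so a minimal RIFF reader/writer is provided.

#' Write a mono 16-bit PCM WAV file
#'
#' @param x Numeric waveform in `[-1, 1]` (clipped otherwise).
#' @param path Output path.
#' @param rate Sampling rate in Hz (default from attribute `rate`).
#' @export
write_wav <- function(x, path, rate = attr(x, "rate") %||% 8000) {
  x <- pmax(-1, pmin(1, as.numeric(x)))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' @param path WAV file path.
#' @return Numeric waveform in `[-1, 1]` with attribute `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), 1, size = 4, endian = "little")
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file: ", path)
  rate <- NULL; bits <- NULL; channels <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, integer(), 1, size = 2, endian = "little")
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      channels <- fmt[2]
      if (fmt[1] != 1L || bits != 16L) stop("only 16-bit PCM WAV is supported: ", path)
      if (sz > 16) readBin(con, raw(), sz - 16)
    } else if (id == "data") {
      data <- readBin(con, integer(), sz / 2, size = 2, endian = "little", signed = TRUE)
      break
    } else {
      readBin(con, raw(), sz)
    }
  }
  if (is.null(data) || is.null(rate)) stop("corrupt or incomplete WAV file: ", path)
  if (channels > 1) data <- data[seq(1, length(data), by = channels)]
  structure(data / 32767, rate = rate)
}

#' Write a dyad session in the fixture format
#'
#' One JSON manifest plus one raw little-endian float64 binary per
#' participant (channels fastest-varying) and one envelope binary per
#' speaking turn.
#'
#' @param session A `dyad_session`.
#' @param dir Output directory (created if needed).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    rate = session$rate, channels = session$channels, topics = session$topics,
    participants = session$participants, dyad = session$dyad,
    epochs = lapply(session$participants, function(p) {
      lapply(session$epochs[[p]]$epochs, function(e) list(role = e$role, topic = e$topic))
    }),
    envelopes = lapply(session$envelopes, function(e)
      list(topic = e$topic, speaker = e$speaker, length = length(e$values)))
  )
  names(manifest$epochs) <- session$participants
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (p in session$participants) {
    con <- file(file.path(dir, paste0("eeg_", p, ".bin")), "wb")
    for (e in session$epochs[[p]]$epochs) {
      writeBin(as.numeric(e$data), con, size = 8, endian = "little")
    }
    close(con)
  }
  for (nm in names(session$envelopes)) {
    con <- file(file.path(dir, paste0("env_", nm, ".bin")), "wb")
    writeBin(as.numeric(session$envelopes[[nm]]$values), con, size = 8, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Read a dyad session from the fixture format
#'
#' @param dir Directory written by [write_session()].
#' @return A `dyad_session` (without ground truth).
#' @export
read_session <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  rate <- mf$rate
  channels <- mf$channels
  nch <- length(channels)
  epochs <- list()
  for (p in mf$participants) {
    path <- file.path(dir, paste0("eeg_", p, ".bin"))
    if (!file.exists(path)) stop("missing EEG data file: ", path)
    labels <- mf$epochs[[p]]
    con <- file(path, "rb")
    eps <- lapply(seq_len(nrow(labels)), function(i) {
      sz <- file.size(path) / 8 / nrow(labels) / nch
      m <- matrix(readBin(con, numeric(), nch * sz, size = 8, endian = "little"), nrow = nch)
      rownames(m) <- channels
      list(role = labels$role[i], topic = labels$topic[i], data = m)
    })
    close(con)
    epochs[[p]] <- epoch_set(eps, rate, channels)
  }
  envelopes <- list()
  for (nm in names(mf$envelopes)) {
    path <- file.path(dir, paste0("env_", nm, ".bin"))
    if (!file.exists(path)) stop("missing envelope file: ", path)
    v <- readBin(path, numeric(), mf$envelopes[[nm]]$length, size = 8, endian = "little")
    envelopes[[nm]] <- list(topic = mf$envelopes[[nm]]$topic,
                            speaker = mf$envelopes[[nm]]$speaker,
                            values = structure(v, rate = rate))
  }
  structure(list(dyad = mf$dyad, rate = rate, channels = channels,
                 topics = mf$topics, participants = mf$participants,
                 epochs = epochs, envelopes = envelopes, truth = NULL),
            class = "dyad_session")
}
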