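#' Define a frequency band
#'
#' @param name Band label (e.g. `"alpha"`).
#' @param lo,hi Band edges in Hz; `0 < lo < hi` required.
#' @return A `band_spec` list with fields `name`, `lo`, `hi`.
#' @export
#' @examples
#' band_spec("alpha", 9, 12)
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.finite(lo) && is.finite(hi) && lo > 0 && lo < hi)) {
    stop("band edges must satisfy 0 < lo < hi")
  }
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' Canonical EEG analysis bands
#'
#' The four bands used throughout the interbrain analyses: delta 1-3 Hz,
#' theta 4-8 Hz, alpha 9-12 Hz and beta 15-20 Hz.
#'
#' @return A list of [band_spec()] objects.
#' @export
canonical_bands <- function() {
  list(
    band_spec("delta", 1, 3),
    band_spec("theta", 4, 8),
    band_spec("alpha", 9, 12),
    band_spec("beta", 15, 20)
  )
}

# normalise a bands argument: list of band_spec (or a single one)
as_band_list <- function(bands) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  if (!is.list(bands) || !all(vapply(bands, inherits, logical(1), "band_spec"))) {
    stop("`bands` must be a band_spec or a list of band_spec objects")
  }
  nm <- vapply(bands, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("band names must be unique")
  names(bands) <- nm
  bands
}

band_names <- function(bands) vapply(as_band_list(bands), `[[`, character(1), "name")
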