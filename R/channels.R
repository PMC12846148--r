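#' Canonical 14-channel EEG montage
#'
#' The fixed channel set of the 14-electrode 10-20 headset used throughout
#' the package. Every matrix and feature table is indexed in this order, so
#' readers reorder their input to it and downstream code never has to guess.
#'
#' @return Character vector of the 14 channel labels in canonical order.
#' @export
#' @examples
#' eeg_channels()
eeg_channels <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Hemisphere of each canonical channel
#'
#' @return Named character vector mapping each channel label to
#'   `"left"` or `"right"`.
#' @export
channel_hemisphere <- function() {
  ch <- eeg_channels()
  side <- ifelse(ch %in% c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1"),
                 "left", "right")
  stats::setNames(side, ch)
}

#' Canonical EEG frequency bands
#'
#' The five conventional bands used for relative-power features: delta
#' 0.5-3 Hz, theta 4-7 Hz, alpha 8-13 Hz, beta 14-30 Hz, gamma 31-55 Hz.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(0.5, 4, 8, 14, 31),
    hi   = c(3, 7, 13, 30, 55)
  )
}

#' @return Character vector of band names in canonical (low to high) order.
#' @rdname eeg_bands
#' @export
band_names <- function() eeg_bands()$band

# Resolve a band name to its (lo, hi) edges; errors on unknown names.
band_edges <- function(band) {
  bands <- eeg_bands()
  i <- match(band, bands$band)
  if (is.na(i)) {
    stop("unknown frequency band: '", band, "' (expected one of ",
         paste(bands$band, collapse = ", "), ")", call. = FALSE)
  }
  c(lo = bands$lo[i], hi = bands$hi[i])
}

# Canonical names of the 70 band x channel features, band-major:
# delta.AF3 ... delta.AF4, theta.AF3, ..., gamma.AF4.
feature_names <- function() {
  as.vector(t(outer(band_names(), eeg_channels(), paste, sep = ".")))
}
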