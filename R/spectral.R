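#' Extract pre-report epochs from a recording
#'
#' For every SWB report, takes the closed window of `round(window_s * fs) + 1`
#' samples ending exactly at the report-time sample (1281 samples for a 10 s
#' window at 128 Hz). Reports given before one full window has elapsed, or
#' past the end of the recording, are skipped with a warning rather than
#' failing the whole recording.
#'
#' @param rec An [swb_recording()].
#' @param window_s Window length in seconds (default 10).
#' @return A tibble of class `swb_epochs` with columns `participant_id`,
#'   `report_index`, `swb` and a list-column `samples` of 14 x L matrices.
#'   The number of skipped reports is attached as attribute `n_skipped`.
#' @export
extract_epochs <- function(rec, window_s = 10) {
  stopifnot_msg(inherits(rec, "swb_recording"), "rec must be an swb_recording")
  stopifnot_msg(window_s > 0, "window_s must be positive")
  L <- round(window_s * rec$fs) + 1L
  n_samp <- ncol(rec$samples)
  rows <- vector("list", length(rec$swb))
  skipped <- 0L
  for (i in seq_along(rec$swb)) {
    end0 <- round(rec$report_times[i] * rec$fs)  # 0-based sample index
    start0 <- end0 - L + 1L
    if (start0 < 0L || end0 > n_samp - 1L) {
      skipped <- skipped + 1L
      warning(sprintf("participant %s: report %d at t=%.3fs outside usable range; skipped",
                      rec$participant_id, i, rec$report_times[i]),
              call. = FALSE)
      next
    }
    rows[[i]] <- tibble::tibble(
      participant_id = rec$participant_id,
      report_index = i,
      swb = rec$swb[i],
      samples = list(rec$samples[, (start0 + 1L):(end0 + 1L), drop = FALSE])
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(participant_id = character(), report_index = integer(),
                          swb = integer(), samples = list())
  }
  attr(out, "fs") <- rec$fs
  attr(out, "n_skipped") <- skipped
  class(out) <- c("swb_epochs", class(out))
  out
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero phase), preserving length and epoch alignment.
#'
#' @param x Numeric signal (one channel).
#' @param band Band name (see [eeg_bands()]) or a numeric `c(lo, hi)` in Hz.
#' @param fs Sampling rate in Hz; must exceed twice the band's upper edge.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, band, fs) {
  edges <- if (is.character(band)) band_edges(band) else as.numeric(band)
  lo <- edges[1]; hi <- edges[2]
  stopifnot_msg(lo > 0 && lo < hi, "band edges must satisfy 0 < lo < hi")
  if (fs <= 2 * hi) {
    stop("sampling rate ", fs, " Hz too low for a band reaching ", hi, " Hz",
         call. = FALSE)
  }
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Welch PSD for a channels-in-columns matrix. Hann segments of seg_s seconds
# with 50% overlap, one-sided density scaling. Returns list(freq, psd) with
# psd of dim (n_freq x n_channels).
welch_psd_ <- function(xmat, fs, seg_s = 2) {
  xmat <- as.matrix(xmat)
  n <- nrow(xmat)
  nseg <- round(seg_s * fs)
  if (nseg > n) {
    stop("signal shorter than one Welch segment (", nseg, " samples)",
         call. = FALSE)
  }
  step <- floor(nseg / 2)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  u <- sum(w^2)
  nch <- ncol(xmat)
  # all segments of all channels side by side, one FFT call
  segs <- matrix(0, nseg, length(starts) * nch)
  for (s in seq_along(starts)) {
    block <- xmat[starts[s]:(starts[s] + nseg - 1L), , drop = FALSE]
    segs[, ((s - 1L) * nch + 1L):(s * nch)] <- block * w
  }
  spec <- stats::mvfft(segs)
  nfreq <- floor(nseg / 2) + 1L
  pow <- (Mod(spec[seq_len(nfreq), , drop = FALSE])^2) / (fs * u)
  one_sided <- c(1, rep(2, nfreq - 2L), if (nseg %% 2 == 0) 1 else 2)
  pow <- pow * one_sided
  # average across segments per channel
  psd <- matrix(0, nfreq, nch)
  for (s in seq_along(starts)) {
    psd <- psd + pow[, ((s - 1L) * nch + 1L):(s * nch), drop = FALSE]
  }
  psd <- psd / length(starts)
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = psd)
}

# Trapezoidal integral of PSD columns over [lo, min(hi, fs/2)].
band_integral_ <- function(freq, psd, lo, hi, fs) {
  hi_eff <- min(hi, fs / 2)
  sel <- which(freq >= lo & freq <= hi_eff)
  if (length(sel) < 2) return(colSums(psd[sel, , drop = FALSE]) * 0)
  df <- diff(freq[sel])
  p <- psd[sel, , drop = FALSE]
  colSums((p[-1, , drop = FALSE] + p[-length(sel), , drop = FALSE]) *
            df / 2)
}

#' Band power of a signal
#'
#' Welch power spectral density (2 s Hann segments, 50% overlap) integrated
#' over the band with the trapezoidal rule. Bands reaching above the Nyquist
#' frequency are truncated at `fs / 2`.
#'
#' @inheritParams bandpass
#' @param seg_s Welch segment length in seconds (default 2).
#' @return Band power in microvolt^2 (non-negative scalar).
#' @export
band_power <- function(x, band, fs, seg_s = 2) {
  edges <- if (is.character(band)) band_edges(band) else as.numeric(band)
  res <- welch_psd_(matrix(as.numeric(x), ncol = 1), fs, seg_s)
  as.numeric(band_integral_(res$freq, res$psd, edges[1], edges[2], fs))
}

# 5 x 14 band-power matrix for one epoch (channels in rows).
band_power_matrix_ <- function(epoch, fs, seg_s = 2) {
  res <- welch_psd_(t(epoch), fs, seg_s)
  bands <- eeg_bands()
  out <- matrix(0, nrow(bands), ncol(res$psd),
                dimnames = list(bands$band, rownames(epoch)))
  for (b in seq_len(nrow(bands))) {
    out[b, ] <- band_integral_(res$freq, res$psd, bands$lo[b], bands$hi[b], fs)
  }
  out
}

#' Relative band power of one epoch
#'
#' For each channel, the power of each of the five bands divided by the sum
#' of the five band powers at that channel, so every channel's relative
#' powers add to exactly 1. The normaliser is the five-band total (not the
#' broadband 0..Nyquist power), which keeps the feature independent of the
#' recording bandwidth.
#'
#' @param epoch A 14 x L sample matrix (rows in canonical channel order).
#' @param fs Sampling rate in Hz.
#' @return A 5 x 14 matrix with entries in `[0, 1]`; columns sum to 1.
#' @export
relative_power <- function(epoch, fs) {
  bp <- band_power_matrix_(epoch, fs)
  tot <- colSums(bp)
  bad <- which(tot <= 0 | !is.finite(tot))
  if (length(bad) > 0) {
    stop("degenerate (all-zero) signal on channel ",
         paste(eeg_channels()[bad], collapse = ", "), call. = FALSE)
  }
  sweep(bp, 2, tot, "/")
}

#' Frontal alpha asymmetry of one epoch
#'
#' The natural-log difference of alpha-band power between the right and left
#' most-frontal sensors: `ln(alpha power at AF4) - ln(alpha power at AF3)`,
#' with alpha power measured by [band_power()] on the alpha-filtered signal.
#' Antisymmetric under swapping the two channels and invariant to common
#' scaling.
#'
#' @inheritParams relative_power
#' @return A single dimensionless FAA value.
#' @export
compute_faa <- function(epoch, fs) {
  ch <- rownames(epoch)
  if (is.null(ch)) ch <- eeg_channels()
  i_l <- match("AF3", ch); i_r <- match("AF4", ch)
  if (is.na(i_l) || is.na(i_r)) {
    stop("epoch must contain channels AF3 and AF4", call. = FALSE)
  }
  p_l <- band_power(bandpass(epoch[i_l, ], "alpha", fs), "alpha", fs)
  p_r <- band_power(bandpass(epoch[i_r, ], "alpha", fs), "alpha", fs)
  if (p_l <= 0 || p_r <= 0) {
    stop("degenerate signal: zero alpha power on AF3 or AF4", call. = FALSE)
  }
  log(p_r) - log(p_l)
}

#' Long-format relative-power features for a set of epochs
#'
#' @param epochs An `swb_epochs` tibble from [extract_epochs()], or a list of
#'   them (e.g. one per participant).
#' @param fs Sampling rate; taken from the epochs attribute when present.
#' @return A tibble with columns `participant_id`, `report_index`, `swb`,
#'   `band`, `channel`, `rel_power` (70 rows per epoch).
#' @export
epoch_features <- function(epochs, fs = attr(epochs, "fs")) {
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  bands <- band_names(); chans <- eeg_channels()
  purrr::pmap_dfr(
    list(epochs$participant_id, epochs$report_index, epochs$swb, epochs$samples),
    function(pid, idx, swb, mat) {
      rp <- relative_power(mat, fs)
      tibble::tibble(
        participant_id = pid, report_index = idx, swb = swb,
        band = rep(bands, each = length(chans)),
        channel = rep(chans, times = length(bands)),
        rel_power = as.vector(t(rp))
      )
    }
  )
}

#' Frontal alpha asymmetry features for a set of epochs
#'
#' @inheritParams epoch_features
#' @return A tibble with columns `participant_id`, `report_index`, `swb`,
#'   `faa` (one row per epoch).
#' @export
faa_features <- function(epochs, fs = attr(epochs, "fs")) {
  if (is.null(fs)) stop("fs is required", call. = FALSE)
  purrr::pmap_dfr(
    list(epochs$participant_id, epochs$report_index, epochs$swb, epochs$samples),
    function(pid, idx, swb, mat) {
      tibble::tibble(participant_id = pid, report_index = idx, swb = swb,
                     faa = compute_faa(mat, fs))
    }
  )
}

#' Widen long-format features into an epochs x 70 matrix
#'
#' Columns are ordered band-major (`delta.AF3` ... `gamma.AF4`), matching
#' the canonical band and channel orders.
#'
#' @param features Long feature tibble from [epoch_features()], typically for
#'   one participant.
#' @return List with `x` (n_epochs x 70 numeric matrix, rownames = report
#'   index) and `swb` (integer labels).
#' @export
feature_matrix <- function(features) {
  key <- paste(features$band, features$channel, sep = ".")
  cols <- feature_names()
  wide <- tidyr::pivot_wider(
    dplyr::mutate(features, .feature = factor(key, levels = cols)),
    id_cols = c("report_index", "swb"),
    names_from = ".feature", values_from = "rel_power"
  )
  wide <- dplyr::arrange(wide, .data$report_index)
  x <- as.matrix(wide[, cols, drop = FALSE])
  rownames(x) <- wide$report_index
  list(x = x, swb = as.integer(wide$swb))
}
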