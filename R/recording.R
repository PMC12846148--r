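#' Construct a validated EEG recording with SWB reports
#'
#' A recording couples a 14 x T sample matrix (microvolts, rows in canonical
#' channel order) with the time-stamped subjective well-being reports given
#' during the session: strictly increasing report times (seconds from
#' recording start) and one integer SWB rating in 1..10 per report.
#'
#' @param samples Numeric matrix, 14 rows (channels) by T columns (samples).
#'   Rows may carry channel names in any order; they are reordered to
#'   [eeg_channels()].
#' @param fs Sampling rate in Hz.
#' @param report_times Report times in seconds, strictly increasing.
#' @param swb Integer SWB ratings in 1..10, one per report time.
#' @param participant_id Participant identifier.
#' @param handedness `"right"` or `"left"`. Stored for reporting only; no
#'   computation branches on it.
#' @return An object of class `swb_recording`.
#' @export
swb_recording <- function(samples, fs, report_times, swb,
                          participant_id = "P01", handedness = "right") {
  samples <- as.matrix(samples)
  canon <- eeg_channels()
  if (nrow(samples) != length(canon)) {
    stop("samples must have ", length(canon), " rows (channels), got ",
         nrow(samples), call. = FALSE)
  }
  if (!is.null(rownames(samples))) {
    missing_ch <- setdiff(canon, rownames(samples))
    extra_ch <- setdiff(rownames(samples), canon)
    if (length(missing_ch) > 0 || length(extra_ch) > 0) {
      stop("channel label mismatch: missing [",
           paste(missing_ch, collapse = ", "), "], unexpected [",
           paste(extra_ch, collapse = ", "), "]", call. = FALSE)
    }
    samples <- samples[canon, , drop = FALSE]
  } else {
    rownames(samples) <- canon
  }
  stopifnot_msg(length(fs) == 1 && is.finite(fs) && fs > 0,
                "fs must be a positive sampling rate in Hz")
  if (length(report_times) != length(swb)) {
    stop("report_times and swb must have equal length", call. = FALSE)
  }
  if (length(report_times) > 1 && any(diff(report_times) <= 0)) {
    stop("report times must be strictly increasing", call. = FALSE)
  }
  if (anyNA(swb) || any(swb != round(swb)) || any(swb < 1) || any(swb > 10)) {
    stop("swb values must be integers in 1..10", call. = FALSE)
  }
  handedness <- match.arg(handedness, c("right", "left"))
  structure(
    list(participant_id = as.character(participant_id),
         handedness = handedness,
         fs = as.numeric(fs),
         samples = samples,
         report_times = as.numeric(report_times),
         swb = as.integer(swb)),
    class = "swb_recording"
  )
}

#' @export
print.swb_recording <- function(x, ...) {
  cat(sprintf(
    "<swb_recording> %s (%s-handed): 14 x %d samples @ %g Hz, %d reports\n",
    x$participant_id, x$handedness, ncol(x$samples), x$fs, length(x$swb)))
  invisible(x)
}

#' Read a recording from a wide channel CSV plus a reports CSV
#'
#' The EEG file is a wide CSV with one column per channel (header = the 14
#' canonical labels, any order) and one row per sample; an optional leading
#' comment line `# fs: <Hz>` carries the sampling rate. The reports file is a
#' CSV with columns `time_s` and `swb`.
#'
#' @param eeg_path Path to the wide EEG CSV.
#' @param reports_path Path to the reports CSV.
#' @param fs Sampling rate in Hz; only needed when the EEG file has no
#'   `# fs:` metadata line.
#' @param participant_id,handedness Passed through to [swb_recording()].
#' @return An `swb_recording` with channels in canonical order.
#' @export
read_recording <- function(eeg_path, reports_path, fs = NULL,
                           participant_id = "P01", handedness = "right") {
  first <- readLines(eeg_path, n = 1L)
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("fs[:= ]+([0-9.]+)", first))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
  }
  if (is.null(fs)) {
    stop("sampling rate not found: provide fs= or a '# fs: <Hz>' header line",
         call. = FALSE)
  }
  eeg <- readr::read_csv(eeg_path, comment = "#", show_col_types = FALSE)
  canon <- eeg_channels()
  missing_ch <- setdiff(canon, names(eeg))
  extra_ch <- setdiff(names(eeg), canon)
  if (length(missing_ch) > 0 || length(extra_ch) > 0) {
    stop("channel label mismatch in ", eeg_path, ": missing [",
         paste(missing_ch, collapse = ", "), "], unexpected [",
         paste(extra_ch, collapse = ", "), "]", call. = FALSE)
  }
  samples <- t(as.matrix(eeg[, canon]))
  reports <- readr::read_csv(reports_path, show_col_types = FALSE)
  if (!all(c("time_s", "swb") %in% names(reports))) {
    stop("reports file must have columns time_s and swb", call. = FALSE)
  }
  swb_recording(samples, fs, reports$time_s, reports$swb,
                participant_id = participant_id, handedness = handedness)
}

#' Write a recording to the paired CSV format
#'
#' @param rec An `swb_recording`.
#' @param eeg_path,reports_path Output paths; see [read_recording()] for the
#'   format.
#' @return `rec`, invisibly.
#' @export
write_recording <- function(rec, eeg_path, reports_path) {
  stopifnot_msg(inherits(rec, "swb_recording"), "rec must be an swb_recording")
  writeLines(sprintf("# fs: %.10g", rec$fs), eeg_path)
  wide <- tibble::as_tibble(t(rec$samples))
  readr::write_csv(wide, eeg_path, append = TRUE, col_names = TRUE)
  readr::write_csv(tibble::tibble(time_s = rec$report_times, swb = rec$swb),
                   reports_path)
  invisible(rec)
}

#' Write / read a labelled square distance matrix as CSV
#'
#' The CSV carries participant ids as both the header row and the first
#' column, so the file round-trips bit-identically through the paired reader
#' (`readr` writes doubles at full round-trip precision).
#'
#' @param M Square numeric matrix. Row order matches `ids`.
#' @param path Output path.
#' @param ids Participant ids; defaults to `rownames(M)`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(M, path, ids = rownames(M)) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) {
    stop("matrix must be square, got ", nrow(M), " x ", ncol(M),
         call. = FALSE)
  }
  if (is.null(ids)) stop("ids are required (or set rownames on M)",
                         call. = FALSE)
  if (length(ids) == 0) stop("empty id list: nothing to write", call. = FALSE)
  if (length(ids) != nrow(M)) {
    stop("ids length (", length(ids), ") does not match matrix dimension (",
         nrow(M), ")", call. = FALSE)
  }
  out <- tibble::as_tibble(M, .name_repair = ~as.character(ids))
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids)), out)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @return `read_distance_matrix()` returns the labelled square matrix.
#' @export
read_distance_matrix <- function(path) {
  # base read.csv: strtod parsing is correctly rounded, so values written at
  # shortest round-trip precision come back bit-identical
  tab <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(tab$id)
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M)) {
    stop("file does not contain a square matrix", call. = FALSE)
  }
  dimnames(M) <- list(ids, ids)
  M
}
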