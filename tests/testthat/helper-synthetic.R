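# Shared fixtures, generated in code. All use compressed sessions
# (reports every 10.5 s) since the properties under test do not depend on
# the reporting interval; this keeps simulated sample counts manageable.

quiet_cfg <- function(...) analysis_config(min_epochs = 10, ...)

tiny_cohort <- function(band = "gamma", strength = 0.4, n = 1, reports = 12,
                        seed = 7) {
  generate_cohort(coupled_cohort_spec(band, strength, n_participants = n,
                                      n_reports = reports,
                                      report_interval_s = 10.5, seed = seed))
}

# epoch with a given waveform on every channel (14 x length(w))
flat_epoch <- function(w) {
  m <- matrix(rep(w, each = 14), 14, length(w), byrow = FALSE)
  rownames(m) <- eeg_channels()
  m
}

sinus <- function(f, fs = 128, n = 1281) sin(2 * pi * f * (0:(n - 1)) / fs)

# brute-force DTW over all monotone warping paths (short series only);
# squared local costs with a final square root, as in dtw_distance()
dtw_brute <- function(x, y) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  nx <- ncol(x); ny <- ncol(y)
  lc <- function(i, j) sum((x[, i] - y[, j])^2)
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(lc(1, 1))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    lc(i, j) + best
  }
  sqrt(rec(nx, ny))
}

# explicit-loop silhouette oracle
silhouette_brute <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i] & seq_len(n) != i)
    if (length(same) == 0) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(d[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(s), per_sample = s)
}
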