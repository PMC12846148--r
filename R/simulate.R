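#' Coupling between the latent comfort process and EEG band amplitudes
#'
#' Defines how a participant's band amplitudes respond to the latent comfort
#' level z(t): the amplitude of band b at channel c is
#' `base_amp[b] * (1 + beta[b, c] * z(t))`, so `beta` is a dimensionless
#' modulation slope and must stay inside (-1, 1) to keep amplitudes positive.
#'
#' @param beta 5 x 14 matrix of coupling slopes (bands x channels), or a
#'   single number recycled to the full matrix. Default 0 (no coupling).
#' @param base_amp Baseline band amplitudes in microvolts, one per band.
#'   Defaults follow the usual 1/f-like decline of resting EEG.
#' @param noise_sd Broadband measurement noise amplitude (microvolts).
#' @return A `swb_coupling` list.
#' @export
coupling_spec <- function(beta = 0,
                          base_amp = c(delta = 20, theta = 10, alpha = 15,
                                       beta = 5, gamma = 3),
                          noise_sd = 2) {
  nb <- length(band_names())
  nc <- length(eeg_channels())
  if (length(beta) == 1) beta <- matrix(beta, nb, nc)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(nb, nc))) {
    stop("beta must be a ", nb, " x ", nc, " matrix (bands x channels)",
         call. = FALSE)
  }
  if (any(abs(beta) >= 1)) {
    stop("all |beta| must be < 1 so band amplitudes stay positive",
         call. = FALSE)
  }
  stopifnot_msg(length(base_amp) == nb && all(base_amp > 0),
                "base_amp must be 5 strictly positive amplitudes")
  stopifnot_msg(length(noise_sd) == 1 && noise_sd >= 0,
                "noise_sd must be a single non-negative number")
  dimnames(beta) <- list(band_names(), eeg_channels())
  structure(list(beta = beta, base_amp = stats::setNames(base_amp, band_names()),
                 noise_sd = noise_sd),
            class = "swb_coupling")
}

#' Cohort design for the synthetic comfort-coupled EEG generator
#'
#' Describes a cohort of participants organised in coupling clusters: every
#' participant in a cluster shares that cluster's [coupling_spec()] up to a
#' small per-participant jitter, while latent comfort trajectories and noise
#' are independent across participants.
#'
#' @param n_clusters Number of planted coupling clusters.
#' @param participants_per_cluster Participants per cluster.
#' @param cluster_couplings List of one [coupling_spec()] per cluster.
#' @param session_length_s Session length in seconds. The default, 2100 s,
#'   yields 70 reports at the 30 s reporting interval, matching the size of a
#'   typical recorded session set.
#' @param report_interval_s Seconds between SWB reports (default 30).
#' @param fs Sampling rate in Hz (default 128).
#' @param latent_tau Time constant (s) of the Ornstein-Uhlenbeck comfort
#'   process (default 60: comfort drifts slowly relative to the 10 s
#'   feature window).
#' @param report_bias Logistic compression of the report mapping; larger
#'   values concentrate ratings on the middle of the 1..10 scale, emulating
#'   the mid-heavy report histograms of real participants. 0 disables the
#'   squashing.
#' @param beta_jitter_sd Per-participant coupling jitter, as a fraction of
#'   the cluster slope (default 0.1).
#' @param seed Master seed of the cohort.
#' @return A `swb_cohort_spec` list.
#' @export
cohort_spec <- function(n_clusters = 1,
                        participants_per_cluster = 4,
                        cluster_couplings = list(coupling_spec()),
                        session_length_s = 2100,
                        report_interval_s = 30,
                        fs = 128,
                        latent_tau = 60,
                        report_bias = 1,
                        beta_jitter_sd = 0.1,
                        seed = 1L) {
  if (length(cluster_couplings) != n_clusters) {
    stop("need exactly one coupling_spec per cluster", call. = FALSE)
  }
  ok <- vapply(cluster_couplings, inherits, logical(1), "swb_coupling")
  stopifnot_msg(all(ok), "cluster_couplings must be coupling_spec() objects")
  stopifnot_msg(n_clusters >= 1 && participants_per_cluster >= 1,
                "cluster counts must be >= 1")
  stopifnot_msg(session_length_s > 0 && report_interval_s > 0 && fs > 0,
                "session_length_s, report_interval_s and fs must be positive")
  stopifnot_msg(session_length_s >= report_interval_s,
                "session must be at least one reporting interval long")
  structure(list(n_clusters = as.integer(n_clusters),
                 participants_per_cluster = as.integer(participants_per_cluster),
                 cluster_couplings = cluster_couplings,
                 session_length_s = session_length_s,
                 report_interval_s = report_interval_s,
                 fs = fs,
                 latent_tau = latent_tau,
                 report_bias = report_bias,
                 beta_jitter_sd = beta_jitter_sd,
                 seed = as.integer(seed)),
            class = "swb_cohort_spec")
}

#' Simulate a standardized latent comfort trajectory
#'
#' The latent comfort level is a stationary Ornstein-Uhlenbeck process
#' sampled on the report grid: an AR(1) series with autoregression
#' `exp(-dt / tau)` and standard-normal stationary distribution, so its mean
#' tends to 0 and its variance to 1 as the session grows. `tau = Inf` with
#' zero innovation degenerates to a constant level.
#'
#' @param length_s Trajectory length in seconds.
#' @param fs_report Sampling rate of the report grid in Hz (e.g. 1/30 for a
#'   30 s reporting interval).
#' @param tau OU time constant in seconds.
#' @param seed Integer seed.
#' @return Numeric vector `z` with one value per report slot.
#' @export
simulate_latent <- function(length_s, fs_report, tau, seed = 1L) {
  if (!is.finite(tau) && !is.infinite(tau)) stop("tau must be numeric",
                                                 call. = FALSE)
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  n <- floor(length_s * fs_report + 1e-9)
  stopifnot_msg(n >= 1, "length_s * fs_report must yield at least one step")
  dt <- 1 / fs_report
  phi <- exp(-dt / tau)
  withr::with_seed(as.integer(seed), {
    innov <- stats::rnorm(n)
    z <- numeric(n)
    z[1] <- innov[1]
    s <- sqrt(1 - phi^2)
    if (n > 1) {
      for (i in 2:n) z[i] <- phi * z[i - 1] + s * innov[i]
    }
    z
  })
}

#' Map a latent comfort level to integer SWB reports
#'
#' Monotone mapping of the latent level through a logistic-type squashing
#' `tanh(report_bias * z) / report_bias` (identity when `report_bias = 0`)
#' followed by the affine map `5.5 + 1.5 * u`, rounded half-up and clipped to
#' the 1..10 rating scale. Larger `report_bias` compresses the tails and
#' yields the mid-heavy rating histograms seen in practice; z = 0 always maps
#' to a rating of 6.
#'
#' @param z Latent comfort values.
#' @param report_bias Non-negative compression parameter.
#' @return Integer vector of SWB ratings in 1..10.
#' @export
latent_to_swb <- function(z, report_bias = 1) {
  stopifnot_msg(length(report_bias) == 1 && report_bias >= 0,
                "report_bias must be a single non-negative number")
  u <- if (report_bias == 0) z else tanh(report_bias * z) / report_bias
  raw <- floor(5.5 + 1.5 * u + 0.5)  # round half up
  as.integer(pmin(10, pmax(1, raw)))
}

# Band-limited unit-variance Gaussian noise for all channels at once.
# The spectrum of each channel's band component is drawn directly as complex
# Gaussian coefficients on the in-band bins (Hermitian-symmetric so the
# inverse transform is real), which is distributionally identical to
# band-passing white Gaussian noise with a brick-wall filter; disjoint bands
# are independent by construction.
band_noise_matrix_ <- function(n, fs, n_channels) {
  n_fft <- stats::nextn(n, c(2, 3, 5))
  freq <- (seq_len(n_fft) - 1) * fs / n_fft
  folded <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  half <- which(freq > 0 & freq <= fs / 2 + 1e-12)
  bands <- eeg_bands()
  out <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    hi <- min(bands$hi[b], fs / 2)
    sel <- half[folded[half] >= bands$lo[b] & folded[half] <= hi]
    m <- length(sel)
    re <- matrix(stats::rnorm(m * n_channels), m, n_channels)
    im <- matrix(stats::rnorm(m * n_channels), m, n_channels)
    spec <- matrix(0 + 0i, n_fft, n_channels)
    spec[sel, ] <- complex(real = re, imaginary = im)
    mirror <- n_fft - sel + 2L
    okm <- mirror >= 1 & mirror <= n_fft & mirror != sel
    spec[mirror[okm], ] <- Conj(spec[sel[okm], , drop = FALSE])
    y <- Re(stats::mvfft(spec, inverse = TRUE)) / sqrt(n_fft)
    y <- y[seq_len(n), , drop = FALSE]
    sds <- sqrt(colMeans(y^2))
    out[[b]] <- y / rep(sds, each = n)
  }
  names(out) <- bands$band
  out
}

#' Synthesize comfort-coupled multichannel EEG
#'
#' Builds `samples[c, t] = sum_b base_amp[b] * (1 + beta[b, c] * z(t)) *
#' n_bc(t) + noise_sd * e(t)`, where each `n_bc` is independent unit-variance
#' noise band-limited to band b, and the latent level z (given on the report
#' grid) is held piecewise-constant at sample resolution. The recording
#' carries one extra trailing sample so the last report window is complete.
#'
#' @param z Latent comfort values, one per report slot.
#' @param coupling A [coupling_spec()].
#' @param session_length_s Session length in seconds; must equal
#'   `length(z)` reporting intervals.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return Numeric 14 x (session_length_s * fs + 1) sample matrix.
#' @export
synthesize_eeg <- function(z, coupling, session_length_s, fs, seed = 1L) {
  stopifnot_msg(inherits(coupling, "swb_coupling"),
                "coupling must be a coupling_spec()")
  n_rep <- length(z)
  stopifnot_msg(n_rep >= 1, "z must contain at least one report slot")
  n <- round(session_length_s * fs) + 1L
  seg <- round(session_length_s * fs / n_rep)
  idx <- pmin(floor((seq_len(n) - 1) / seg) + 1L, n_rep)
  z_t <- z[idx]
  nc <- length(eeg_channels())
  withr::with_seed(as.integer(seed), {
    noise_bands <- band_noise_matrix_(n, fs, nc)
    samples <- matrix(0, nc, n)
    for (b in seq_along(noise_bands)) {
      if (all(coupling$beta[b, ] == 0)) {
        samples <- samples + coupling$base_amp[b] * t(noise_bands[[b]])
      } else {
        amp <- coupling$base_amp[b] * (1 + outer(coupling$beta[b, ], z_t))
        samples <- samples + amp * t(noise_bands[[b]])
      }
    }
    if (coupling$noise_sd > 0) {
      samples <- samples + coupling$noise_sd * matrix(stats::rnorm(nc * n), nc, n)
    }
    rownames(samples) <- eeg_channels()
    samples
  })
}

#' Generate a synthetic comfort-coupled cohort with ground truth
#'
#' Produces one recording per participant. Participants inherit their
#' cluster's coupling with additive Gaussian jitter (SD = `beta_jitter_sd`
#' times the cluster slope, elementwise), and get independent latent comfort
#' trajectories and noise. The returned tibble carries the ground truth
#' needed by recovery tests: the cluster label, the realised coupling matrix
#' and the latent trajectory of every participant.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `swb_cohort` with one row per participant and
#'   columns `participant_id`, `cluster` (0-based), `recording` (list of
#'   [swb_recording()]), `beta` (list of 5 x 14 matrices) and `latent`
#'   (list of numeric vectors).
#' @export
generate_cohort <- function(spec) {
  stopifnot_msg(inherits(spec, "swb_cohort_spec"), "spec must be a cohort_spec()")
  n_total <- spec$n_clusters * spec$participants_per_cluster
  seeds <- withr::with_seed(spec$seed,
                            sample.int(.Machine$integer.max - 1L, 3L * n_total))
  n_rep <- floor(spec$session_length_s / spec$report_interval_s + 1e-9)
  stopifnot_msg(n_rep >= 1, "session too short for a single report")
  rows <- vector("list", n_total)
  p <- 0L
  for (cl in seq_len(spec$n_clusters)) {
    base <- spec$cluster_couplings[[cl]]
    for (j in seq_len(spec$participants_per_cluster)) {
      p <- p + 1L
      sd_jit <- spec$beta_jitter_sd * abs(base$beta)
      beta_i <- withr::with_seed(seeds[3L * p - 2L],
                                 base$beta + stats::rnorm(length(base$beta)) * sd_jit)
      beta_i <- pmin(pmax(beta_i, -0.99), 0.99)
      dim(beta_i) <- dim(base$beta)
      dimnames(beta_i) <- dimnames(base$beta)
      coup_i <- coupling_spec(beta_i, base$base_amp, base$noise_sd)
      z <- simulate_latent(n_rep * spec$report_interval_s,
                           1 / spec$report_interval_s,
                           spec$latent_tau, seed = seeds[3L * p - 1L])
      swb <- latent_to_swb(z, spec$report_bias)
      samples <- synthesize_eeg(z, coup_i,
                                n_rep * spec$report_interval_s,
                                spec$fs, seed = seeds[3L * p])
      rec <- swb_recording(samples, spec$fs,
                           report_times = spec$report_interval_s * seq_len(n_rep),
                           swb = swb,
                           participant_id = sprintf("P%02d", p))
      rows[[p]] <- tibble::tibble(
        participant_id = rec$participant_id,
        cluster = cl - 1L,
        recording = list(rec),
        beta = list(beta_i),
        latent = list(z)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("swb_cohort", class(out))
  out
}
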