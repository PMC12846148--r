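#' Per-participant data bundle for the transfer analyses
#'
#' Computes, for every participant of a cohort, the pre-report epochs, the
#' long-format relative-power features, the wide feature matrix and the FAA
#' values, plus the usability flag: a participant is usable when at least
#' `min_epochs` epochs remain and at least two distinct SWB values survive
#' singleton removal (a participant who always reports the same value can
#' never be classified or regressed).
#'
#' @param cohort An `swb_cohort` tibble from [generate_cohort()], or a list
#'   of [swb_recording()] objects.
#' @param config An [analysis_config()].
#' @param compute_faa Also compute FAA features (needed by the
#'   `faa_linreg` method; skipping them saves time for the other methods).
#' @return Tibble with one row per participant: `participant_id`, `usable`,
#'   `exclusion_reason`, and list-columns `epochs`, `features` (wide matrix
#'   list as returned by [feature_matrix()]) and `faa`.
#' @export
prepare_participants <- function(cohort, config = analysis_config(),
                                 compute_faa = FALSE) {
  recs <- if (inherits(cohort, "swb_cohort")) cohort$recording else cohort
  rows <- purrr::map(recs, function(rec) {
    ep <- extract_epochs(rec, config$window_s)
    fm <- participant_feature_matrix_(rec, config$window_s)
    faa <- if (compute_faa) faa_features(ep, fs = rec$fs) else NULL
    usable <- TRUE; reason <- NA_character_
    if (nrow(ep) < config$min_epochs) {
      usable <- FALSE; reason <- "fewer epochs than min_epochs"
    } else {
      keep <- tryCatch(drop_singleton_labels(fm$swb), error = function(e) integer(0))
      if (length(unique(fm$swb[keep])) < 2) {
        usable <- FALSE
        reason <- "fewer than 2 SWB classes after singleton removal"
      }
    }
    tibble::tibble(participant_id = rec$participant_id,
                   handedness = rec$handedness,
                   usable = usable, exclusion_reason = reason,
                   epochs = list(ep), features = list(fm),
                   faa = list(faa), fs = rec$fs)
  })
  dplyr::bind_rows(rows)
}

# Epochs x 70 feature matrix straight from a recording (no intermediate
# long tibble); column order matches feature_names(). The Welch segments of
# all epochs and channels go through a single FFT call, and the trapezoidal
# band integrals are applied as one linear map; numerically identical to
# relative_power() per epoch.
participant_feature_matrix_ <- function(rec, window_s = 10) {
  fs <- rec$fs
  L <- round(window_s * fs) + 1L
  n_samp <- ncol(rec$samples)
  ends0 <- round(rec$report_times * fs)
  ok <- which(ends0 - L + 1L >= 0L & ends0 <= n_samp - 1L)
  n_ep <- length(ok)
  nch <- nrow(rec$samples)
  nseg <- round(2 * fs)
  step <- floor(nseg / 2)
  starts <- seq(1L, L - nseg + 1L, by = step)
  nwin <- length(starts)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  u <- sum(w^2)
  segs <- matrix(0, nseg, n_ep * nwin * nch)
  for (r in seq_len(n_ep)) {
    a0 <- ends0[ok[r]] - L + 2L  # 1-based epoch start
    for (s in seq_len(nwin)) {
      block <- t(rec$samples[, (a0 + starts[s] - 1L):(a0 + starts[s] + nseg - 2L),
                             drop = FALSE])
      segs[, ((r - 1L) * nwin + s - 1L) * nch + seq_len(nch)] <- block * w
    }
  }
  spec <- stats::mvfft(segs)
  nfreq <- floor(nseg / 2) + 1L
  pow <- (Mod(spec[seq_len(nfreq), , drop = FALSE])^2) / (fs * u)
  one_sided <- c(1, rep(2, nfreq - 2L), if (nseg %% 2 == 0) 1 else 2)
  pow <- pow * one_sided
  # trapezoidal band integrals as a 5 x nfreq weight matrix
  freq <- (seq_len(nfreq) - 1L) * fs / nseg
  bands <- eeg_bands()
  wmat <- matrix(0, nrow(bands), nfreq)
  for (b in seq_len(nrow(bands))) {
    sel <- which(freq >= bands$lo[b] & freq <= min(bands$hi[b], fs / 2))
    if (length(sel) < 2) next
    df <- diff(freq[sel])
    wmat[b, sel] <- c(df / 2, 0) + c(0, df / 2)
  }
  bp <- wmat %*% pow  # 5 x (n_ep * nwin * nch)
  x <- matrix(0, n_ep, length(feature_names()),
              dimnames = list(ok, feature_names()))
  for (r in seq_len(n_ep)) {
    cols <- ((r - 1L) * nwin * nch + 1L):(r * nwin * nch)
    arr <- array(bp[, cols], c(nrow(bands), nch, nwin))
    bpm <- rowMeans(arr, dims = 2)  # 5 x nch, averaged over segments
    tot <- colSums(bpm)
    bad <- which(tot <= 0 | !is.finite(tot))
    if (length(bad) > 0) {
      stop("degenerate (all-zero) signal on channel ",
           paste(eeg_channels()[bad], collapse = ", "), call. = FALSE)
    }
    x[r, ] <- as.vector(t(bpm / rep(tot, each = nrow(bands))))
  }
  list(x = x, swb = rec$swb[ok], report_index = ok)
}

#' Train one participant's SWB transfer model
#'
#' Four model families are supported, matching the transfer analyses:
#' `faa_linreg` (seed-averaged SMOTE-balanced line of SWB on FAA),
#' `rp_knn` (1-NN on the relative power of the participant's own best
#' band/channel combination), `rp_linreg_fixed` (seed-averaged line of SWB on
#' relative alpha power at T7, the feature with the lowest group-level
#' p-value) and `ts_knn` (1-NN on the band-filtered series of the best
#' band/channel combination).
#'
#' @param pdata One row of [prepare_participants()] (as a list).
#' @param method One of `"faa_linreg"`, `"rp_knn"`, `"rp_linreg_fixed"`,
#'   `"ts_knn"`.
#' @param config An [analysis_config()].
#' @return An object of class `swb_transfer_model`.
#' @export
train_transfer_model <- function(pdata,
                                 method = c("rp_knn", "faa_linreg",
                                            "rp_linreg_fixed", "ts_knn"),
                                 config = analysis_config()) {
  method <- match.arg(method)
  if (!isTRUE(pdata$usable)) {
    stop("participant ", pdata$participant_id, " excluded: ",
         pdata$exclusion_reason, call. = FALSE)
  }
  fm <- pdata$features[[1]] %||% pdata$features
  model <- switch(
    method,
    faa_linreg = {
      faa <- pdata$faa[[1]] %||% pdata$faa
      if (is.null(faa)) stop("FAA features missing; rerun prepare_participants(compute_faa = TRUE)",
                             call. = FALSE)
      fit <- participant_mean_slope(faa$faa, faa$swb, config$smote_seeds,
                                    config$smote_k)
      list(band = "alpha", channel = "AF3/AF4",
           slope = fit$slope, intercept = fit$intercept)
    },
    rp_linreg_fixed = {
      xcol <- fm$x[, "alpha.T7"]
      fit <- participant_mean_slope(xcol, fm$swb, config$smote_seeds,
                                    config$smote_k)
      list(band = "alpha", channel = "T7",
           slope = fit$slope, intercept = fit$intercept)
    },
    rp_knn = {
      scan <- rp_scan_fast_(fm$x, fm$swb)
      best <- best_combination(scan)$winners[1, ]
      keep <- drop_singleton_labels(fm$swb)
      list(band = best$band, channel = best$channel,
           train_x = fm$x[keep, paste(best$band, best$channel, sep = "."),
                          drop = FALSE],
           train_y = fm$swb[keep])
    },
    ts_knn = {
      ep <- pdata$epochs[[1]] %||% pdata$epochs
      fs <- pdata$fs %||% attr(ep, "fs")
      scan <- ts_knn_scan_(ep, fs)
      best <- scan[which.min(scan$mse), ]
      keep <- drop_singleton_labels(ep$swb)
      series <- purrr::map(ep$samples[keep], function(mat) {
        matrix(bandpass(mat[best$channel, ], best$band, fs), nrow = 1)
      })
      list(band = best$band, channel = best$channel,
           train_series = series, train_y = ep$swb[keep], fs = fs)
    }
  )
  structure(c(list(owner_id = pdata$participant_id, method = method), model),
            class = "swb_transfer_model")
}

# Scheme-1 scan over band x channel filtered series (the clustering stage
# only uses single filtered series, so this avoids the generic scheme
# machinery's repeated filtering).
ts_knn_scan_ <- function(ep, fs) {
  keep <- drop_singleton_labels(ep$swb)
  labels <- ep$swb[keep]
  combos <- tidyr::expand_grid(band = band_names(), channel = eeg_channels())
  res <- purrr::pmap_dfr(combos, function(band, channel) {
    series <- purrr::map(ep$samples[keep], function(mat) {
      bandpass(mat[channel, ], band, fs)
    })
    x <- do.call(rbind, series)
    pred <- loo_1nn(x, labels, metric = "euclidean")
    tibble::tibble(band = band, channel = channel, mse = mse(labels, pred))
  })
  res
}

#' Predict a target participant's SWB with another participant's model
#'
#' Linear models predict `slope * feature + intercept`, clipped to the 1..10
#' scale but left real-valued; 1-NN models return the label of the nearest
#' training instance of the model owner (ties to the lowest owner index).
#' All of the target's epochs are predicted.
#'
#' @param model An [train_transfer_model()] result.
#' @param pdata The target participant's row of [prepare_participants()].
#' @return Tibble with `owner_id`, `target_id`, `swb_true`, `swb_pred`.
#' @export
predict_swb <- function(model, pdata) {
  stopifnot_msg(inherits(model, "swb_transfer_model"),
                "model must be an swb_transfer_model")
  fm <- pdata$features[[1]] %||% pdata$features
  pred <- switch(
    model$method,
    faa_linreg = {
      faa <- pdata$faa[[1]] %||% pdata$faa
      if (is.null(faa)) stop("FAA features missing for target", call. = FALSE)
      pmin(10, pmax(1, model$slope * faa$faa + model$intercept))
    },
    rp_linreg_fixed = {
      pmin(10, pmax(1, model$slope * fm$x[, "alpha.T7"] + model$intercept))
    },
    rp_knn = {
      key <- paste(model$band, model$channel, sep = ".")
      if (!key %in% colnames(fm$x)) stop("feature mismatch: ", key,
                                         call. = FALSE)
      xt <- fm$x[, key]
      d <- abs(outer(xt, as.numeric(model$train_x), "-"))
      model$train_y[apply(d, 1L, which.min)]
    },
    ts_knn = {
      ep <- pdata$epochs[[1]] %||% pdata$epochs
      fs <- model$fs
      train <- do.call(rbind, purrr::map(model$train_series, as.numeric))
      purrr::map_int(ep$samples, function(mat) {
        xs <- bandpass(mat[model$channel, ], model$band, fs)
        d2 <- rowSums(sweep(train, 2, xs)^2)
        as.integer(model$train_y[which.min(d2)])
      })
    }
  )
  truth <- switch(model$method,
                  faa_linreg = (pdata$faa[[1]] %||% pdata$faa)$swb,
                  rp_linreg_fixed = fm$swb,
                  rp_knn = fm$swb,
                  ts_knn = (pdata$epochs[[1]] %||% pdata$epochs)$swb)
  tibble::tibble(owner_id = model$owner_id,
                 target_id = pdata$participant_id,
                 swb_true = as.numeric(truth),
                 swb_pred = as.numeric(pred))
}

#' Normalized transfer distance between true and predicted SWB
#'
#' The mean absolute prediction error divided by the number of distinct true
#' SWB values, which makes distances comparable across participants whose
#' rating ranges (and hence maximum possible errors) differ.
#'
#' @param swb_true Recorded SWB values of the target participant.
#' @param swb_pred Predictions from the owner's model.
#' @return Non-negative scalar distance (not a metric; the triangle
#'   inequality is not guaranteed).
#' @export
transfer_distance <- function(swb_true, swb_pred) {
  if (length(swb_true) == 0) stop("empty input", call. = FALSE)
  if (length(swb_true) != length(swb_pred)) {
    stop("swb_true and swb_pred must have equal length", call. = FALSE)
  }
  mean(abs(swb_true - swb_pred)) / length(unique(swb_true))
}

#' Build the cross-participant transfer-distance matrix
#'
#' Trains one model per usable participant, applies every model to every
#' other usable participant, and assembles the raw asymmetric distance matrix
#' `D[A, B]` together with its min-symmetrized form
#' `D_sym[A, B] = min(D[A, B], D[B, A])`. Diagonals are 0 by convention.
#'
#' @param participants Output of [prepare_participants()].
#' @param method Transfer model family, see [train_transfer_model()].
#' @param config An [analysis_config()].
#' @return Object of class `swb_distance_matrix`: list with `ids`, `D`,
#'   `D_sym`, `method` and `excluded` (tibble of excluded participants with
#'   reasons).
#' @export
build_distance_matrix <- function(participants, method = "rp_knn",
                                  config = analysis_config()) {
  usable <- participants[participants$usable, , drop = FALSE]
  excluded <- participants[!participants$usable,
                           c("participant_id", "exclusion_reason")]
  n <- nrow(usable)
  if (n < 3) stop("need at least 3 usable participants", call. = FALSE)
  ids <- usable$participant_id
  models <- purrr::map(seq_len(n), function(i) {
    train_transfer_model(usable[i, ], method = method, config = config)
  })
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      pr <- predict_swb(models[[a]], usable[b, ])
      D[a, b] <- transfer_distance(pr$swb_true, pr$swb_pred)
    }
  }
  structure(list(ids = ids, D = D, D_sym = pmin(D, t(D)),
                 method = method, excluded = excluded),
            class = "swb_distance_matrix")
}

#' @export
print.swb_distance_matrix <- function(x, ...) {
  cat(sprintf("<swb_distance_matrix> %s: %d participants (%d excluded)\n",
              x$method, length(x$ids), nrow(x$excluded)))
  invisible(x)
}
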