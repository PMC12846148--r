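#' Drop SWB labels that occur only once
#'
#' Leave-one-out evaluation of a 1-NN classifier can never predict a label
#' whose only exemplar is the left-out instance, so instances whose SWB was
#' reported a single time are removed before evaluation. Order is preserved.
#'
#' @param labels Integer label vector.
#' @return Integer vector of kept (original) positions.
#' @export
drop_singleton_labels <- function(labels) {
  if (length(labels) == 0) stop("empty instance list", call. = FALSE)
  counts <- table(labels)
  keep <- which(labels %in% as.integer(names(counts)[counts >= 2]))
  if (length(keep) == 0) {
    stop("all labels are singletons: no usable instances remain",
         call. = FALSE)
  }
  keep
}

#' Mean squared error between true and predicted labels
#'
#' Squared error respects the ordinal structure of the SWB scale: predicting
#' 4 for a true 3 costs far less than predicting 9.
#'
#' @param true,pred Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(true, pred) {
  if (length(true) != length(pred)) {
    stop("true and pred must have equal length", call. = FALSE)
  }
  stopifnot_msg(length(true) >= 1, "mse needs at least one pair")
  mean((as.numeric(true) - as.numeric(pred))^2)
}

#' Leave-one-out 1-nearest-neighbour prediction
#'
#' Each instance is predicted as the label of its nearest other instance.
#' Distance ties are broken by the smallest instance index, making the
#' evaluation deterministic and order-stable.
#'
#' @param x Numeric matrix (instances in rows) for the Euclidean metric, or a
#'   list of channel x time matrices for the time-series metrics.
#' @param labels Integer labels, one per instance.
#' @param metric `"euclidean"` or `"dtw"` (dynamic time warping; time-series
#'   input only).
#' @return Integer vector of predicted labels.
#' @export
loo_1nn <- function(x, labels, metric = c("euclidean", "dtw")) {
  metric <- match.arg(metric)
  n <- length(labels)
  if (n < 2) stop("leave-one-out needs at least 2 instances", call. = FALSE)
  if (is.list(x)) {
    stopifnot_msg(length(x) == n, "one instance per label required")
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- if (metric == "dtw") {
          dtw_distance(x[[i]], x[[j]])
        } else {
          sqrt(sum((x[[i]] - x[[j]])^2))
        }
      }
    }
  } else {
    x <- as.matrix(x)
    stopifnot_msg(nrow(x) == n, "one instance per label required")
    if (metric == "dtw") stop("dtw metric needs time-series input",
                              call. = FALSE)
    sq <- rowSums(x^2)
    d <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    d[d < 0] <- 0
  }
  diag(d) <- Inf
  labels[max.col(-d, ties.method = "first")]  # ties -> lowest index
}

# A classifier over a single class is vacuous; mirrors the exclusion of
# participants who always reported the same SWB value.
check_label_variety_ <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("fewer than 2 distinct SWB classes remain: participant cannot be evaluated",
         call. = FALSE)
  }
  invisible(labels)
}

# Scheme-1 scan over all 70 band x channel relative-power features without
# per-combination tibble overhead; same predictions as evaluate_scheme().
rp_scan_fast_ <- function(x70, swb) {
  keep <- drop_singleton_labels(swb)
  check_label_variety_(swb[keep])
  x70 <- x70[keep, , drop = FALSE]
  labels <- swb[keep]
  combos <- feature_names()
  mses <- vapply(combos, function(cn) {
    xv <- x70[, cn]
    d <- abs(outer(xv, xv, "-"))
    diag(d) <- Inf
    pred <- labels[max.col(-d, ties.method = "first")]
    mean((labels - pred)^2)
  }, numeric(1))
  nm <- strsplit(combos, ".", fixed = TRUE)
  tibble::tibble(band = vapply(nm, `[`, "", 1),
                 channel = vapply(nm, `[`, "", 2),
                 mse = unname(mses), n_used = length(keep))
}

#' Dynamic time warping distance
#'
#' Classic unconstrained dynamic-programming DTW for (multi)channel series,
#' in the squared-cost convention: the local cost at aligned time points is
#' the squared Euclidean distance across channels (dependent-multivariate
#' variant), and the distance is the square root of the minimal cumulative
#' cost over all monotone warping paths. Symmetric, zero exactly for
#' identical inputs, and never larger than the Euclidean distance for
#' equal-length series (the identity path is admissible).
#'
#' @param x,y Numeric vectors, or channel x time matrices with matching
#'   channel counts.
#' @return Non-negative DTW distance.
#' @export
dtw_distance <- function(x, y) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.vector(y)) y <- matrix(y, nrow = 1)
  if (nrow(x) != nrow(y)) {
    stop("series must have the same channel count", call. = FALSE)
  }
  nx <- ncol(x); ny <- ncol(y)
  stopifnot_msg(nx >= 1 && ny >= 1, "series must be non-empty")
  # squared local cost matrix
  cx <- colSums(x^2); cy <- colSums(y^2)
  lc <- pmax(outer(cx, cy, "+") - 2 * crossprod(x, y), 0)
  acc <- matrix(Inf, nx + 1, ny + 1)
  acc[1, 1] <- 0
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      acc[i + 1, j + 1] <- lc[i, j] +
        min(acc[i, j + 1], acc[i + 1, j], acc[i, j])
    }
  }
  sqrt(acc[nx + 1, ny + 1])
}

#' Evaluate one 1-NN input scheme for one participant
#'
#' Runs singleton removal, leave-one-out 1-NN and MSE scoring for one of the
#' three input schemes: scheme 1 uses a single band x channel feature (or one
#' filtered series), scheme 2 all 14 channels of one band, scheme 3 all 70
#' band x channel combinations.
#'
#' @param data For `source = "rp"`, the output of [feature_matrix()] (or a
#'   long feature tibble for one participant). For `source = "ts"`, an
#'   `swb_epochs` tibble for one participant.
#' @param scheme 1, 2 or 3.
#' @param band Band name (schemes 1 and 2).
#' @param channel Channel label (scheme 1 only).
#' @param source `"rp"` (relative power features) or `"ts"` (band-filtered
#'   time series).
#' @param metric Distance metric for the 1-NN search.
#' @param fs Sampling rate (time-series source only).
#' @return An object of class `swb_knn_eval` with the scheme description,
#'   the MSE, the number of instances used and the per-instance predictions.
#' @export
evaluate_scheme <- function(data, scheme, band = NULL, channel = NULL,
                            source = c("rp", "ts"),
                            metric = c("euclidean", "dtw"), fs = NULL) {
  source <- match.arg(source)
  metric <- match.arg(metric)
  scheme <- as.integer(scheme)
  stopifnot_msg(scheme %in% 1:3, "scheme must be 1, 2 or 3")
  if (scheme <= 2 && is.null(band)) stop("schemes 1 and 2 need a band",
                                         call. = FALSE)
  if (scheme == 1 && is.null(channel)) stop("scheme 1 needs a channel",
                                            call. = FALSE)
  pid <- if (is.data.frame(data) && "participant_id" %in% names(data)) {
    data$participant_id[1]
  } else {
    NA_character_
  }
  if (source == "rp") {
    if (is.data.frame(data)) data <- feature_matrix(data)
    labels <- data$swb
    cols <- switch(scheme,
                   paste(band, channel, sep = "."),
                   paste(band, eeg_channels(), sep = "."),
                   feature_names())
    x <- data$x[, cols, drop = FALSE]
    keep <- drop_singleton_labels(labels)
    check_label_variety_(labels[keep])
    pred <- loo_1nn(x[keep, , drop = FALSE], labels[keep], metric = "euclidean")
  } else {
    if (is.null(fs)) fs <- attr(data, "fs")
    if (is.null(fs)) stop("fs is required for the time-series source",
                          call. = FALSE)
    labels <- data$swb
    series <- purrr::map(data$samples, function(mat) {
      rows <- switch(scheme, match(channel, rownames(mat)),
                     seq_len(nrow(mat)), seq_len(nrow(mat)))
      bands_used <- if (scheme == 3) band_names() else band
      filt <- lapply(bands_used, function(b) {
        if (is.na(b) || identical(b, "none")) {
          mat[rows, , drop = FALSE]
        } else {
          t(apply(mat[rows, , drop = FALSE], 1, bandpass, band = b, fs = fs))
        }
      })
      do.call(rbind, filt)
    })
    keep <- drop_singleton_labels(labels)
    check_label_variety_(labels[keep])
    pred <- loo_1nn(series[keep], labels[keep], metric = metric)
  }
  structure(
    list(participant_id = pid,
         scheme = scheme, band = band,
         channel = if (scheme == 1) channel else NA_character_,
         source = source, metric = metric,
         mse = mse(labels[keep], pred), n_used = length(keep),
         predictions = tibble::tibble(swb_true = labels[keep],
                                      swb_pred = pred)),
    class = "swb_knn_eval"
  )
}

#' @export
print.swb_knn_eval <- function(x, ...) {
  cat(sprintf("<swb_knn_eval> scheme %d (%s%s), %s: MSE = %.4f on %d instances\n",
              x$scheme, x$band %||% "all bands",
              if (!is.na(x$channel %||% NA)) paste0("/", x$channel) else "",
              x$source, x$mse, x$n_used))
  invisible(x)
}

#' Scan every band (x channel) combination with 1-NN for one participant
#'
#' @inheritParams evaluate_scheme
#' @param scheme 1 (each band at each channel) or 2 (each band, all
#'   channels).
#' @return Tibble with one row per combination: `band`, `channel` (scheme 1),
#'   `mse`, `n_used`.
#' @export
knn_scan <- function(data, scheme = 1, source = "rp", metric = "euclidean",
                     fs = NULL) {
  scheme <- as.integer(scheme)
  stopifnot_msg(scheme %in% 1:2, "knn_scan covers schemes 1 and 2")
  if (identical(source, "rp") && is.data.frame(data)) data <- feature_matrix(data)
  combos <- if (scheme == 1) {
    tidyr::expand_grid(band = band_names(), channel = eeg_channels())
  } else {
    tibble::tibble(band = band_names(), channel = NA_character_)
  }
  res <- purrr::pmap_dfr(combos, function(band, channel) {
    ev <- evaluate_scheme(data, scheme, band = band,
                          channel = if (scheme == 1) channel else NULL,
                          source = source, metric = metric, fs = fs)
    tibble::tibble(band = band, channel = channel %||% NA_character_,
                   mse = ev$mse, n_used = ev$n_used)
  })
  res
}

#' Best band/channel combinations of a scan
#'
#' Returns every combination achieving the minimal MSE together with a
#' uniqueness flag; downstream winner tallies only count unique winners,
#' since a tie has no single "best" combination.
#'
#' @param evals Tibble from [knn_scan()] (columns `band`, `channel`, `mse`).
#' @param tol Absolute tolerance for treating two MSEs as tied.
#' @return List with `winners` (tibble of argmin rows) and `is_unique`.
#' @export
best_combination <- function(evals, tol = 1e-12) {
  if (is.null(evals) || nrow(evals) == 0) stop("no evaluations supplied",
                                               call. = FALSE)
  m <- min(evals$mse)
  winners <- evals[evals$mse <= m + tol, , drop = FALSE]
  list(winners = winners, is_unique = nrow(winners) == 1)
}

#' Rescale per-band minimal MSEs to the (0, 1] range
#'
#' Divides each participant's per-band minimal MSE by the largest of them, so
#' the worst band maps to exactly 1 and results become comparable across
#' participants with different SWB ranges.
#'
#' @param x Non-negative MSE values.
#' @return `x / max(x)`.
#' @export
rescale_mse <- function(x) {
  stopifnot_msg(length(x) >= 1 && all(x >= 0), "need non-negative values")
  m <- max(x)
  if (m == 0) stop("all values are zero: rescaling is degenerate",
                   call. = FALSE)
  x / m
}

#' Tally winning categories across participants
#'
#' Counts, per category (e.g. band), how many participants have that
#' category as their unique minimal-MSE winner. Participants whose minimum
#' is tied between several categories have no single "best" combination and
#' are excluded from the tally (and reported).
#'
#' @param scans Tibble of per-participant scan results with columns
#'   `participant_id`, a category column named by `by`, and `mse`.
#' @param by Category column to tally (default `"band"`).
#' @return List with `counts` (named integer vector over the categories
#'   present) and `tied` (ids of excluded participants).
#' @export
winner_tally <- function(scans, by = "band") {
  split_scans <- split(scans, scans$participant_id)
  winners <- character(0); tied <- character(0)
  for (pid in names(split_scans)) {
    bc <- best_combination(split_scans[[pid]])
    cats <- unique(bc$winners[[by]])
    if (bc$is_unique || length(cats) == 1) {
      winners <- c(winners, cats[1])
    } else {
      tied <- c(tied, pid)
    }
  }
  list(counts = table(winners), tied = tied)
}

#' Chi-squared goodness-of-fit test on winner tallies
#'
#' Tests observed per-category winner counts against the uniform expectation
#' `total / n_categories`, reporting the statistic, its upper-tail p-value
#' with `n_categories - 1` degrees of freedom and the standardized Pearson
#' residuals `(O - E) / sqrt(E)`.
#'
#' @param counts Named or unnamed non-negative integer counts.
#' @return An object of class `swb_count_test`.
#' @export
chi_squared_gof <- function(counts) {
  counts <- as.numeric(counts0 <- counts)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("counts must be non-negative with positive total", call. = FALSE)
  }
  k <- length(counts)
  ht <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / k, k)))
  structure(
    list(counts = counts,
         category = names(counts0) %||% as.character(seq_len(k)),
         expected = as.numeric(ht$expected),
         statistic = unname(ht$statistic),
         df = unname(ht$parameter),
         p_value = ht$p.value,
         residuals = as.numeric(ht$residuals)),
    class = "swb_count_test"
  )
}

#' @export
print.swb_count_test <- function(x, ...) {
  cat(sprintf("<swb_count_test> chi^2(%d) = %.3f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Binomial test on the dominant winner count
#'
#' Exact binomial test of whether one category wins more often than the
#' chance rate `p0`. The one-sided upper-tail p-value is the headline result
#' (the hypothesis is an excess of wins); the two-sided value is also kept.
#'
#' @param k_wins Wins of the category of interest.
#' @param n Total number of participants tallied.
#' @param p0 Chance win probability (default `1/n_categories` of the tally).
#' @return List with `p_one_sided`, `p_two_sided`, `k_wins`, `n`, `p0`.
#' @export
binomial_winner_test <- function(k_wins, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)",
                               call. = FALSE)
  stopifnot_msg(k_wins >= 0 && k_wins <= n, "need 0 <= k_wins <= n")
  list(
    p_one_sided = stats::binom.test(k_wins, n, p0, alternative = "greater")$p.value,
    p_two_sided = stats::binom.test(k_wins, n, p0, alternative = "two.sided")$p.value,
    k_wins = k_wins, n = n, p0 = p0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
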