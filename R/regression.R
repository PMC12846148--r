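#' SMOTE class balancing
#'
#' Oversamples every minority SWB class up to the majority count by adding
#' convex combinations `x_i + lambda * (x_nn - x_i)` with `lambda ~ U(0, 1)`
#' and `x_nn` drawn among the `k_neighbors` nearest same-class members.
#' `k_neighbors` is shrunk to `class size - 1` for small classes. With a
#' fixed seed the augmented set is bit-identical across runs.
#'
#' @param x Numeric feature vector (or single-column matrix).
#' @param y Integer class labels; every class must have at least 2 members
#'   (remove singletons first, see [drop_singleton_labels()]).
#' @param k_neighbors Neighbour count (default 5).
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y` and `synthetic` (original rows
#'   first, in input order).
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  cls <- split(seq_along(y), y)
  sizes <- lengths(cls)
  if (any(sizes < 2)) {
    stop("every class needs >= 2 members before SMOTE (singletons present)",
         call. = FALSE)
  }
  target <- max(sizes)
  synth_x <- numeric(0); synth_y <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (ci in seq_along(cls)) {
      idx <- cls[[ci]]
      m <- length(idx)
      need <- target - m
      if (need == 0) next
      xv <- x[idx]
      k <- min(k_neighbors, m - 1)
      base <- sample.int(m, need, replace = TRUE)
      lam <- stats::runif(need)
      choice <- sample.int(k, need, replace = TRUE)
      nn_pick <- integer(need)
      for (d in seq_len(need)) {
        ord <- order(abs(xv - xv[base[d]]))
        ord <- ord[ord != base[d]]
        nn_pick[d] <- ord[choice[d]]
      }
      synth_x <- c(synth_x, xv[base] + lam * (xv[nn_pick] - xv[base]))
      synth_y <- c(synth_y, rep(as.integer(names(cls)[ci]), need))
    }
  })
  out_x <- c(x, synth_x)
  out_y <- c(as.integer(y), synth_y)
  flag <- c(rep(FALSE, length(x)), rep(TRUE, length(synth_x)))
  tibble::tibble(x = out_x, y = out_y, synthetic = flag)
}

#' Ordinary least-squares line fit
#'
#' @param x Predictor values (at least two distinct).
#' @param y Response values.
#' @return List with `slope` and `intercept` minimising the residual sum of
#'   squares.
#' @export
fit_line <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("need equal-length x and y with at least 2 points", call. = FALSE)
  }
  if (max(x) - min(x) == 0) {
    stop("degenerate design: x is constant", call. = FALSE)
  }
  co <- stats::.lm.fit(cbind(1, as.numeric(x)), as.numeric(y))$coefficients
  list(slope = co[2], intercept = co[1])
}

#' Seed-averaged SMOTE-balanced regression slope for one participant
#'
#' For each seed the feature is SMOTE-balanced against the SWB labels and an
#' OLS line of SWB on the feature is fitted; the participant's slope (and
#' intercept) is the arithmetic mean over the seeds. Labels reported only
#' once are removed first.
#'
#' @param x Feature values (one per epoch).
#' @param y SWB labels.
#' @param seeds Integer SMOTE seeds (default 1..10).
#' @param k_neighbors SMOTE neighbour count.
#' @return List with `slope`, `intercept` (seed means) and `n_used`.
#' @export
participant_mean_slope <- function(x, y, seeds = 1:10, k_neighbors = 5) {
  keep <- drop_singleton_labels(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(y)) < 2) {
    stop("participant has fewer than 2 SWB classes after singleton removal",
         call. = FALSE)
  }
  fits <- purrr::map(seeds, function(s) {
    bal <- smote_balance(x, y, k_neighbors = k_neighbors, seed = s)
    fit_line(bal$x, bal$y)
  })
  list(slope = mean(purrr::map_dbl(fits, "slope")),
       intercept = mean(purrr::map_dbl(fits, "intercept")),
       n_used = length(keep))
}

#' One-sample t-test on per-participant slopes
#'
#' Two-sided test of zero mean slope across participants, with the sample
#' standard deviation (denominator n - 1), Cohen's d = mean / sd and the
#' 95% confidence interval `mean +- t(0.975, df) * sd / sqrt(n)`.
#'
#' @param slopes One mean slope per participant (at least 3).
#' @return An object of class `swb_slope_test`.
#' @export
group_slope_test <- function(slopes) {
  slopes <- as.numeric(slopes)
  if (length(slopes) < 3) stop("need at least 3 slopes", call. = FALSE)
  s <- stats::sd(slopes)
  if (s == 0) stop("degenerate input: slopes have zero variance",
                   call. = FALSE)
  ht <- stats::t.test(slopes, mu = 0, conf.level = 0.95)
  structure(
    list(mean_slope = mean(slopes), sd_slope = s,
         cohens_d = mean(slopes) / s,
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value,
         ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
         n = length(slopes)),
    class = "swb_slope_test"
  )
}

#' @export
print.swb_slope_test <- function(x, ...) {
  cat(sprintf("<swb_slope_test> mean %.4f (sd %.4f), d = %.3f, t(%d) = %.3f, p = %.4g\n",
              x$mean_slope, x$sd_slope, x$cohens_d, x$df, x$t, x$p))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment over a fixed test family
#'
#' Step-up adjustment with the family size `m_total` fixed independently of
#' how many p-values are supplied: unlisted tests are treated as p = 1, which
#' leaves the adjustment of the listed ones unchanged. This allows adjusting
#' a table of only the nominally significant results against the full
#' 5 band x 14 channel family of 70 tests.
#'
#' @param pvals Uncorrected p-values in `[0, 1]`.
#' @param m_total Size of the test family (default `length(pvals)`).
#' @param q FDR level for the rejection flags (default 0.05).
#' @return Tibble with columns `p`, `p_adj`, `reject`.
#' @export
bh_fdr <- function(pvals, m_total = length(pvals), q = 0.05) {
  pvals <- as.numeric(pvals)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]",
                                       call. = FALSE)
  if (m_total < length(pvals)) {
    stop("m_total must be at least length(pvals)", call. = FALSE)
  }
  adj <- stats::p.adjust(pvals, method = "BH", n = m_total)
  tibble::tibble(p = pvals, p_adj = adj, reject = adj <= q)
}

#' Group-level regression table over all band x channel features
#'
#' For every band x channel relative-power feature: the seed-averaged
#' SMOTE-balanced slope of each participant, a two-sided one-sample t-test of
#' zero mean slope across participants, Cohen's d, the 95% CI and the
#' Benjamini-Hochberg adjustment over the full family of 70 tests.
#'
#' @param features Long feature tibble from [epoch_features()] covering all
#'   participants to include (apply any usability exclusions beforehand).
#' @param config An [analysis_config()].
#' @return Tibble with one row per band x channel: `band`, `channel`,
#'   `mean_slope`, `sd_slope`, `cohens_d`, `t`, `df`, `p`, `p_corr`,
#'   `ci_low`, `ci_high`, `reject`.
#' @export
regress_cohort <- function(features, config = analysis_config()) {
  mats <- features |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_map(~feature_matrix(.x))
  slopes <- purrr::map(mats, function(fm) {
    mean_slopes_all_(fm$x, fm$swb, config$smote_seeds, config$smote_k)
  })
  slope_mat <- do.call(rbind, slopes)  # participants x 70
  res <- purrr::map_dfr(seq_len(ncol(slope_mat)), function(j) {
    st <- group_slope_test(slope_mat[, j])
    nm <- strsplit(feature_names()[j], ".", fixed = TRUE)[[1]]
    tibble::tibble(band = nm[1], channel = nm[2],
                   mean_slope = st$mean_slope, sd_slope = st$sd_slope,
                   cohens_d = st$cohens_d, t = st$t, df = st$df, p = st$p,
                   ci_low = st$ci_low, ci_high = st$ci_high)
  })
  adj <- bh_fdr(res$p, m_total = nrow(res), q = config$fdr_q)
  res$p_corr <- adj$p_adj
  res$reject <- adj$reject
  res[, c("band", "channel", "mean_slope", "sd_slope", "cohens_d", "t",
          "df", "p", "p_corr", "ci_low", "ci_high", "reject")]
}

# Lean hot path: seed-averaged SMOTE slopes for every column of an
# epochs x features matrix. Identical sampling scheme (and RNG stream) to
# smote_balance() + fit_line(); avoids per-call tibble construction and
# re-sorting for the large simulation suites. The nearest-neighbour tables
# per class depend only on the feature values, so they are computed once per
# feature and reused across seeds.
mean_slopes_all_ <- function(x_mat, y, seeds = 1:10, k_neighbors = 5) {
  keep <- drop_singleton_labels(y)
  x_mat <- x_mat[keep, , drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2) {
    stop("fewer than 2 SWB classes after singleton removal", call. = FALSE)
  }
  cls <- split(seq_along(y), y)
  sizes <- lengths(cls)
  target <- max(sizes)
  p <- ncol(x_mat)
  y_num <- as.numeric(y)
  cls_y <- as.numeric(names(cls))
  n_synth <- sum(target - sizes)
  y_full <- c(y_num, unlist(purrr::map2(cls_y, target - sizes, rep)))
  n_full <- length(y_full)
  sum_y <- sum(y_full); mean_y <- sum_y / n_full
  out <- numeric(p)
  withr::with_preserve_seed({
    for (j in seq_len(p)) {
      xj <- x_mat[, j]
      nn_tab <- lapply(cls, function(idx) {
        m <- length(idx); k <- min(k_neighbors, m - 1)
        xv <- xj[idx]
        v <- vapply(seq_len(m), function(i) {
          ord <- order(abs(xv - xv[i]))
          ord[ord != i][seq_len(k)]
        }, integer(k))
        if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
      })
      slope_sum <- 0
      for (s in seeds) {
        set.seed(as.integer(s))
        synth_x <- numeric(0)
        for (ci in seq_along(cls)) {
          m <- sizes[ci]
          need <- target - m
          if (need == 0) next
          xv <- xj[cls[[ci]]]
          k <- min(k_neighbors, m - 1)
          base <- sample.int(m, need, replace = TRUE)
          lam <- stats::runif(need)
          choice <- sample.int(k, need, replace = TRUE)
          nn_pick <- nn_tab[[ci]][cbind(base, choice)]
          synth_x <- c(synth_x, xv[base] + lam * (xv[nn_pick] - xv[base]))
        }
        x_full <- c(xj, synth_x)
        mean_x <- sum(x_full) / n_full
        sxx <- sum(x_full * x_full) - n_full * mean_x^2
        if (sxx == 0) stop("degenerate design: x is constant", call. = FALSE)
        slope_sum <- slope_sum +
          (sum(x_full * y_full) - n_full * mean_x * mean_y) / sxx
      }
      out[j] <- slope_sum / length(seeds)
    }
  })
  out
}
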