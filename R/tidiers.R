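#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidiers for package result objects
#'
#' `tidy()` returns the per-element detail of a result as a tibble;
#' `glance()` returns its one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name swb_tidiers
NULL

#' @rdname swb_tidiers
#' @export
tidy.swb_count_test <- function(x, ...) {
  tibble::tibble(category = x$category, observed = x$counts,
                 expected = x$expected, residual = x$residuals)
}

#' @rdname swb_tidiers
#' @export
glance.swb_count_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @rdname swb_tidiers
#' @export
tidy.swb_knn_eval <- function(x, ...) {
  dplyr::mutate(x$predictions,
                participant_id = x$participant_id,
                scheme = x$scheme, .before = 1)
}

#' @rdname swb_tidiers
#' @export
glance.swb_knn_eval <- function(x, ...) {
  tibble::tibble(participant_id = x$participant_id, scheme = x$scheme,
                 band = x$band %||% NA_character_,
                 channel = x$channel %||% NA_character_,
                 mse = x$mse, n_used = x$n_used)
}

#' @rdname swb_tidiers
#' @export
glance.swb_slope_test <- function(x, ...) {
  tibble::tibble(mean_slope = x$mean_slope, sd_slope = x$sd_slope,
                 cohens_d = x$cohens_d, t = x$t, df = x$df, p = x$p,
                 ci_low = x$ci_low, ci_high = x$ci_high, n = x$n)
}

#' @rdname swb_tidiers
#' @export
tidy.swb_distance_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$D_sym), .name_repair = ~c("from", "to", "distance"))
}

#' @rdname swb_tidiers
#' @export
tidy.swb_embedding <- function(x, ...) {
  tibble::tibble(id = x$ids,
                 dim1 = x$coords[, 1],
                 dim2 = if (ncol(x$coords) >= 2) x$coords[, 2] else 0)
}

#' @rdname swb_tidiers
#' @export
tidy.swb_partition <- function(x, ...) {
  tibble::tibble(id = x$ids, k = x$k, label = x$labels,
                 silhouette = x$silhouette)
}

#' @rdname swb_tidiers
#' @export
glance.swb_partition <- function(x, ...) {
  tibble::tibble(k = x$k, silhouette_mean = x$silhouette_mean,
                 tot_withinss = x$tot_withinss)
}

#' Plot an Isomap embedding, optionally coloured by a partition
#'
#' @param object An [isomap_embed()] result.
#' @param partition Optional [kmeans_partition()] result on the same ids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swb_embedding <- function(object, partition = NULL, ...) {
  df <- tidy(object)
  if (!is.null(partition)) {
    df$cluster <- factor(partition$labels[match(df$id, partition$ids)])
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$cluster))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "component 1", y = "component 2",
                  title = "Isomap embedding of transfer distances") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.swb_embedding
#' @export
autoplot.swb_partition <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(df$label, -df$silhouette), ]
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos, .data$silhouette,
                                   fill = factor(.data$label))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "silhouette", fill = "cluster",
                  title = sprintf("Silhouette profile, k = %d (mean %.3f)",
                                  object$k, object$silhouette_mean)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.swb_embedding
#' @export
autoplot.swb_count_test <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$category, .data$observed)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expected[1]),
                        linetype = 2) +
    ggplot2::labs(y = "winner count",
                  title = sprintf("Winner tallies vs chance (chi^2(%d) = %.3f)",
                                  object$df, object$statistic)) +
    ggplot2::theme_minimal()
}

#' Rescaled-MSE overview across participants and bands
#'
#' Bar chart of each participant's per-band minimal MSE divided by the
#' largest of their band MSEs, so the worst band is 1 for everyone and
#' participants with different rating ranges become comparable.
#'
#' @param scan_results Tibble with columns `participant_id`, `band`, `mse`
#'   (minimal MSE per band per participant).
#' @return A ggplot object.
#' @export
plot_rescaled_mse <- function(scan_results) {
  df <- scan_results |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(rescaled = rescale_mse(.data$mse)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$participant_id, .data$rescaled,
                                   fill = .data$band)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "participant", y = "rescaled MSE", fill = "band") +
    ggplot2::theme_minimal()
}
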