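#' Group regression table straight from prepared participants
#'
#' Same computation as [regress_cohort()] but starting from the wide
#' per-participant feature matrices of [prepare_participants()], which is the
#' efficient entry point for simulation studies that generate many cohorts.
#' Only usable participants enter the group tests.
#'
#' @param participants Output of [prepare_participants()].
#' @param config An [analysis_config()].
#' @param include_left_handed Keep left-handed participants in the group
#'   tests. Default `FALSE`: their slopes tend to run opposite to the
#'   right-handed majority, and with so few of them the group test is
#'   reported for the right-handed cohort (they are still summarised
#'   separately in the source analyses).
#' @return Tibble as in [regress_cohort()].
#' @export
regress_participants <- function(participants, config = analysis_config(),
                                 include_left_handed = FALSE) {
  if (!include_left_handed && "handedness" %in% names(participants)) {
    participants <- participants[participants$handedness == "right", ,
                                 drop = FALSE]
  }
  usable <- participants[participants$usable, , drop = FALSE]
  if (nrow(usable) < 3) stop("need at least 3 usable participants",
                             call. = FALSE)
  slope_mat <- do.call(rbind, purrr::map(usable$features, function(fm) {
    mean_slopes_all_(fm$x, fm$swb, config$smote_seeds, config$smote_k)
  }))
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

#' Planted-cluster recovery through the full transfer pipeline
#'
#' Generates (or accepts) a cohort with planted coupling clusters, runs the
#' full chain — features, per-participant transfer models, min-symmetrized
#' distance matrix, Isomap embedding, k-means — and scores the recovered
#' partition against the planted cluster labels with the adjusted Rand index.
#'
#' @param cohort An `swb_cohort` from [generate_cohort()] (must carry the
#'   ground-truth `cluster` column).
#' @param config An [analysis_config()].
#' @param method Transfer model family (default `"rp_knn"`).
#' @param k Number of clusters to recover (default: the number planted).
#' @return List with `ari`, `partition`, `distance`, `truth`.
#' @export
cluster_recovery <- function(cohort, config = analysis_config(),
                             method = "rp_knn", k = NULL) {
  stopifnot_msg(inherits(cohort, "swb_cohort"),
                "cohort must come from generate_cohort()")
  if (is.null(k)) k <- length(unique(cohort$cluster))
  parts <- prepare_participants(cohort, config,
                                compute_faa = identical(method, "faa_linreg"))
  dm <- build_distance_matrix(parts, method = method, config = config)
  emb <- isomap_embed(dm, n_neighbors = config$isomap_neighbors,
                      n_components = config$embed_dims)
  part <- kmeans_partition(emb, k, restarts = config$kmeans_restarts,
                           seed = config$master_seed)
  truth <- cohort$cluster[match(part$ids, cohort$participant_id)]
  list(ari = adjusted_rand(part$labels, truth),
       partition = part, distance = dm, truth = truth)
}

#' Two-cluster cohort with opposite-sign gamma coupling
#'
#' Convenience constructor for the planted-subgroup validation studies: two
#' clusters whose gamma-band amplitudes are coupled to the latent comfort
#' level with opposite signs (+/- `strength` on every channel).
#'
#' @param participants_per_cluster Participants per cluster.
#' @param strength Absolute gamma coupling slope (default 0.5, a strong
#'   coupling).
#' @param n_reports Reports per participant.
#' @param report_interval_s Seconds between reports.
#' @param seed Cohort seed.
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A `swb_cohort_spec`.
#' @export
two_cluster_spec <- function(participants_per_cluster = 4, strength = 0.5,
                             n_reports = 60, report_interval_s = 30,
                             seed = 1L, ...) {
  beta_pos <- matrix(0, 5, 14); beta_pos[5, ] <- strength
  beta_neg <- -beta_pos
  cohort_spec(
    n_clusters = 2,
    participants_per_cluster = participants_per_cluster,
    cluster_couplings = list(coupling_spec(beta_pos), coupling_spec(beta_neg)),
    session_length_s = n_reports * report_interval_s,
    report_interval_s = report_interval_s,
    seed = seed, ...
  )
}

#' Single-participant cohort with coupling on one band
#'
#' @param band Coupled band name.
#' @param strength Coupling slope on that band (all channels).
#' @param n_participants Number of participants.
#' @param n_reports Reports per participant.
#' @param report_interval_s Seconds between reports.
#' @param seed Cohort seed.
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A `swb_cohort_spec`.
#' @export
coupled_cohort_spec <- function(band = "gamma", strength = 0.5,
                                n_participants = 1, n_reports = 60,
                                report_interval_s = 30, seed = 1L, ...) {
  beta <- matrix(0, 5, 14)
  beta[match(band, band_names()), ] <- strength
  cohort_spec(
    n_clusters = 1,
    participants_per_cluster = n_participants,
    cluster_couplings = list(coupling_spec(beta)),
    session_length_s = n_reports * report_interval_s,
    report_interval_s = report_interval_s,
    seed = seed, ...
  )
}
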