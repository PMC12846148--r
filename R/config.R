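#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with validated defaults: the
#' pre-report window length, the neighbour count of the SWB classifier, the
#' SMOTE settings and seeds, the FDR level, the candidate cluster counts,
#' the Isomap neighbourhood and embedding dimension, the usability filter
#' and the master seed.
#'
#' @param window_s Pre-report window length in seconds (default 10).
#' @param knn_k Neighbour count of the SWB classifier; the pipeline uses 1
#'   because the report distributions are heavily imbalanced.
#' @param smote_k SMOTE neighbour count (shrunk per class when a class is
#'   smaller than `smote_k + 1`).
#' @param smote_seeds Integer seeds for the repeated SMOTE draws; the slope
#'   reported per participant is the mean over these seeds.
#' @param fdr_q False discovery rate level for the Benjamini-Hochberg step-up.
#' @param cluster_ks Candidate numbers of clusters for the k-means stage.
#' @param isomap_neighbors Neighbourhood size of the Isomap graph.
#' @param embed_dims Embedding dimension of the Isomap output.
#' @param min_epochs Minimum usable reports for a participant to enter the
#'   cross-participant analyses.
#' @param kmeans_restarts Random restarts per k-means fit.
#' @param master_seed Seed from which all internal randomness is derived.
#' @return A validated `swb_config` list.
#' @export
#' @examples
#' analysis_config()
analysis_config <- function(window_s = 10,
                            knn_k = 1L,
                            smote_k = 5L,
                            smote_seeds = 1:10,
                            fdr_q = 0.05,
                            cluster_ks = 2:6,
                            isomap_neighbors = 1L,
                            embed_dims = 2L,
                            min_epochs = 20L,
                            kmeans_restarts = 50L,
                            master_seed = 1L) {
  cfg <- list(
    window_s = as.numeric(window_s),
    knn_k = as.integer(knn_k),
    smote_k = as.integer(smote_k),
    smote_seeds = as.integer(smote_seeds),
    fdr_q = as.numeric(fdr_q),
    cluster_ks = as.integer(cluster_ks),
    isomap_neighbors = as.integer(isomap_neighbors),
    embed_dims = as.integer(embed_dims),
    min_epochs = as.integer(min_epochs),
    kmeans_restarts = as.integer(kmeans_restarts),
    master_seed = as.integer(master_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "swb_config")
}

validate_config <- function(cfg) {
  stopifnot_msg(length(cfg$window_s) == 1 && is.finite(cfg$window_s) &&
                  cfg$window_s > 0, "window_s must be a positive number")
  stopifnot_msg(cfg$knn_k >= 1L, "knn_k must be >= 1")
  stopifnot_msg(cfg$smote_k >= 1L, "smote_k must be >= 1")
  stopifnot_msg(length(cfg$smote_seeds) >= 1 && !anyNA(cfg$smote_seeds),
                "smote_seeds must be a non-empty integer vector")
  stopifnot_msg(cfg$fdr_q > 0 && cfg$fdr_q < 1, "fdr_q must lie in (0, 1)")
  stopifnot_msg(all(cfg$cluster_ks >= 2L), "all cluster_ks must be >= 2")
  stopifnot_msg(cfg$isomap_neighbors >= 1L, "isomap_neighbors must be >= 1")
  stopifnot_msg(cfg$embed_dims >= 1L, "embed_dims must be >= 1")
  stopifnot_msg(cfg$min_epochs >= 1L, "min_epochs must be >= 1")
  stopifnot_msg(cfg$kmeans_restarts >= 1L, "kmeans_restarts must be >= 1")
  invisible(cfg)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Load an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their defaults; keys that are not part of
#' [analysis_config()] are rejected so typos never silently alter a run. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a YAML key/value file.
#' @param quiet Suppress the echo of the resolved configuration.
#' @return A validated `swb_config` list.
#' @export
load_config <- function(path, quiet = TRUE) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain key: value pairs",
                           call. = FALSE)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in names(vals)) {
    if (!is.numeric(vals[[key]])) {
      stop("config key '", key, "' must be numeric", call. = FALSE)
    }
  }
  cfg <- do.call(analysis_config, vals)
  if (!quiet) print(cfg)
  cfg
}

#' @export
print.swb_config <- function(x, ...) {
  cat("<swb_config>\n")
  for (key in names(x)) {
    cat(sprintf("  %-17s %s\n", key, paste(x[[key]], collapse = " ")))
  }
  invisible(x)
}
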