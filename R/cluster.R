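#' Isomap embedding of a symmetrized distance matrix
#'
#' Builds the symmetric k-nearest-neighbour graph of the precomputed
#' distances (ties to the lowest index), repairs a disconnected graph by
#' adding minimum-weight bridging edges between components (so the stated
#' neighbourhood size is kept everywhere else), computes geodesic distances
#' as shortest paths, and embeds them with classical multidimensional scaling
#' (double-centred squared-geodesic eigendecomposition).
#'
#' @param D Symmetric, zero-diagonal distance matrix (or an
#'   [build_distance_matrix()] result, whose `D_sym` is used).
#' @param n_neighbors Neighbourhood size of the graph (default 1).
#' @param n_components Embedding dimension (default 2).
#' @return Object of class `swb_embedding`: `ids`, `coords`
#'   (n x n_components), `n_neighbors`, `connectivity_repair`, `geodesics`.
#' @export
isomap_embed <- function(D, n_neighbors = 1, n_components = 2) {
  if (inherits(D, "swb_distance_matrix")) D <- D$D_sym
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 4) stop("need at least 4 points to embed", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12))) {
    stop("distance matrix must be symmetric (use the min-symmetrized form)",
         call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  }
  ids <- rownames(D) %||% as.character(seq_len(n))
  edges <- NULL
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])[seq_len(min(n_neighbors, n - 1))]
    nb <- seq_len(n)[-i][ord]
    edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = "first")
  igraph::E(g)$weight <- D[igraph::as_edgelist(g, names = FALSE)]
  repaired <- FALSE
  repeat {
    comp <- igraph::components(g)
    if (comp$no == 1) break
    repaired <- TRUE
    # minimum-weight edge bridging any two components
    cross <- outer(comp$membership, comp$membership, "!=")
    Dx <- D; Dx[!cross] <- Inf
    pos <- which(Dx == min(Dx), arr.ind = TRUE)[1, ]
    g <- igraph::add_edges(g, c(pos[1], pos[2]), weight = D[pos[1], pos[2]])
  }
  geo <- igraph::distances(g, weights = igraph::E(g)$weight)
  mds <- stats::cmdscale(stats::as.dist(geo), k = n_components)
  if (ncol(mds) < n_components) {
    mds <- cbind(mds, matrix(0, n, n_components - ncol(mds)))
  }
  rownames(mds) <- ids
  structure(list(ids = ids, coords = mds, n_neighbors = n_neighbors,
                 connectivity_repair = repaired, geodesics = geo),
            class = "swb_embedding")
}

#' @export
print.swb_embedding <- function(x, ...) {
  cat(sprintf("<swb_embedding> %d points in %d dims (neighbors = %d%s)\n",
              nrow(x$coords), ncol(x$coords), x$n_neighbors,
              if (x$connectivity_repair) ", graph repaired" else ""))
  invisible(x)
}

#' Partition an embedding with k-means
#'
#' Best of `restarts` random-start k-means fits by within-cluster sum of
#' squares, deterministic under a fixed seed. Cluster labels are renumbered
#' 0..k-1 in order of first appearance so reruns are comparable. The
#' silhouette of the partition (Euclidean distances in the embedding space)
#' is attached.
#'
#' @param embedding An [isomap_embed()] result (or a coordinate matrix).
#' @param k Number of clusters (2 <= k <= number of points).
#' @param restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @return Object of class `swb_partition`: `ids`, `k`, `labels` (0-based),
#'   `silhouette_mean`, `silhouette`, `coords`.
#' @export
kmeans_partition <- function(embedding, k, restarts = 50, seed = 1L) {
  coords <- if (inherits(embedding, "swb_embedding")) embedding$coords else as.matrix(embedding)
  ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  n <- nrow(coords)
  if (k > n) stop("k must not exceed the number of points", call. = FALSE)
  stopifnot_msg(k >= 1, "k must be >= 1")
  if (k == n) {
    # every point is its own cluster centre; WCSS is exactly 0
    km <- list(cluster = seq_len(n), tot.withinss = 0)
  } else {
    km <- withr::with_seed(as.integer(seed),
                           stats::kmeans(coords, centers = k, nstart = restarts,
                                         iter.max = 100))
  }
  raw <- km$cluster
  labels <- as.integer(factor(raw, levels = unique(raw))) - 1L
  sil <- if (k >= 2) silhouette_score(coords, labels) else
    list(mean = NA_real_, per_sample = rep(NA_real_, n))
  structure(list(ids = ids, k = as.integer(k), labels = labels,
                 silhouette_mean = sil$mean, silhouette = sil$per_sample,
                 coords = coords, tot_withinss = km$tot.withinss),
            class = "swb_partition")
}

#' @export
print.swb_partition <- function(x, ...) {
  cat(sprintf("<swb_partition> k = %d, mean silhouette = %.4f\n",
              x$k, x$silhouette_mean))
  invisible(x)
}

#' Silhouette coefficient of a partition
#'
#' For each sample, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' the other members of its own cluster and `b` the smallest mean distance to
#' the members of any other cluster. Samples in singleton clusters get
#' `s = 0` (standard convention).
#'
#' @param x Coordinate matrix (rows = samples; Euclidean distances are used)
#'   or a precomputed symmetric distance matrix (set `is_dist = TRUE`).
#' @param labels Cluster labels, one per sample; at least two clusters.
#' @param is_dist Interpret `x` as a distance matrix.
#' @return List with `mean` and `per_sample`.
#' @export
silhouette_score <- function(x, labels, is_dist = FALSE) {
  labels <- as.vector(labels)
  n <- length(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least 2 clusters", call. = FALSE)
  }
  d <- if (is_dist) as.matrix(x) else as.matrix(stats::dist(x))
  stopifnot_msg(nrow(d) == n, "one label per sample required")
  lev <- unique(labels)
  # mean distance from every sample to every cluster
  md <- sapply(lev, function(cl) {
    members <- labels == cl
    rowSums(d[, members, drop = FALSE]) / sum(members)
  })
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], lev)
    m <- sum(labels == labels[i])
    if (m == 1) { s[i] <- 0; next }
    a <- md[i, ci] * m / (m - 1)  # exclude self from own-cluster mean
    b <- min(md[i, -ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  list(mean = mean(s), per_sample = s)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table: 1 for identical partitions, about 0 for independent ones; invariant
#' to label renaming.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Adjusted Rand index (<= 1).
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  e <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - e
  if (denom == 0) return(0)
  (sum_ij - e) / denom
}

#' Pairwise partition-consistency table
#'
#' Adjusted Rand index for every unordered pair of methods at every cluster
#' count, assessing whether different distance constructions partition the
#' participants the same way.
#'
#' @param partitions Tibble with columns `method`, `k`, `id`, `label`
#'   (e.g. stacked [tidy()][generics::tidy] output of [kmeans_partition()]
#'   results).
#' @return Tibble with `method_a`, `method_b`, `k`, `ari`.
#' @export
consistency_table <- function(partitions) {
  methods <- unique(partitions$method)
  ks <- sort(unique(partitions$k))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(ks, function(k) {
      pa <- partitions[partitions$method == pr[1] & partitions$k == k, ]
      pb <- partitions[partitions$method == pr[2] & partitions$k == k, ]
      pa <- pa[order(pa$id), ]; pb <- pb[order(pb$id), ]
      if (!identical(pa$id, pb$id)) {
        stop("partitions of methods ", pr[1], " and ", pr[2],
             " cover different participants", call. = FALSE)
      }
      tibble::tibble(method_a = pr[1], method_b = pr[2], k = k,
                     ari = adjusted_rand(pa$label, pb$label))
    })
  })
}

#' Embed, partition and score one distance matrix across cluster counts
#'
#' Convenience wrapper chaining [isomap_embed()], [kmeans_partition()] for
#' every requested k and the silhouette summary.
#'
#' @param D Symmetrized distance matrix or [build_distance_matrix()] result.
#' @param config An [analysis_config()].
#' @return List with `embedding`, `partitions` (list by k) and `summary`
#'   tibble (`k`, `silhouette`).
#' @export
cluster_distance_matrix <- function(D, config = analysis_config()) {
  emb <- isomap_embed(D, n_neighbors = config$isomap_neighbors,
                      n_components = config$embed_dims)
  parts <- purrr::map(config$cluster_ks, function(k) {
    kmeans_partition(emb, k, restarts = config$kmeans_restarts,
                     seed = config$master_seed + k)
  })
  names(parts) <- paste0("k", config$cluster_ks)
  list(embedding = emb,
       partitions = parts,
       summary = tibble::tibble(
         k = config$cluster_ks,
         silhouette = purrr::map_dbl(parts, "silhouette_mean")))
}
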