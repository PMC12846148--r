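test_that("Isomap reproduces geodesics on a path graph", {
  D <- abs(outer(0:3, 0:3, "-")) * 1.0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  emb <- isomap_embed(D, n_neighbors = 1, n_components = 2)
  ed <- as.matrix(stats::dist(emb$coords))
  expect_equal(unname(ed), unname(emb$geodesics), tolerance = 1e-6)
  expect_equal(unname(emb$geodesics[1, ]), c(0, 1, 2, 3), tolerance = 1e-9)
})

test_that("Isomap on a complete graph is classical MDS (Procrustes exact)", {
  withr::with_seed(31, {
    pts <- matrix(rnorm(12), 6, 2)
    D <- as.matrix(stats::dist(pts))
    emb <- isomap_embed(D, n_neighbors = 5, n_components = 2)
    expect_false(emb$connectivity_repair)
    expect_equal(unname(as.matrix(stats::dist(emb$coords))), unname(D),
                 tolerance = 1e-6)
  })
})

test_that("disconnected 1-NN graphs are repaired, not fatal", {
  # two tight pairs far apart: 1-NN graph has two components
  D <- as.matrix(stats::dist(c(0, 0.1, 10, 10.1)))
  emb <- isomap_embed(D, n_neighbors = 1)
  expect_true(emb$connectivity_repair)
  expect_true(all(is.finite(emb$coords)))
  expect_error(isomap_embed(D[, c(2, 1, 3, 4)]), "symmetric")
  D2 <- D; diag(D2) <- 1
  expect_error(isomap_embed(D2), "diagonal")
})

test_that("k-means partitions are deterministic and recover separated clouds", {
  withr::with_seed(32, {
    coords <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
                    matrix(rnorm(10, 5, 0.1), 5, 2))
  })
  rownames(coords) <- paste0("p", 1:10)
  part <- kmeans_partition(coords, 2, restarts = 10, seed = 5)
  expect_equal(part$labels, rep(0:1, each = 5))
  part2 <- kmeans_partition(coords, 2, restarts = 10, seed = 5)
  expect_identical(part$labels, part2$labels)
  # k = n: every point its own cluster, zero within-cluster scatter
  pn <- kmeans_partition(coords, 10, restarts = 2, seed = 1)
  expect_equal(sort(unique(pn$labels)), 0:9)
  expect_equal(pn$tot_withinss, 0, tolerance = 1e-12)
  expect_error(kmeans_partition(coords, 11, seed = 1), "exceed")
})

test_that("silhouette matches the hand case and the explicit-loop oracle", {
  # clusters {0,1} and {10,11}: outer points have a = 1, b = 10.5 and the
  # inner points a = 1, b = 9.5
  coords <- matrix(c(0, 1, 10, 11), ncol = 1)
  s <- silhouette_score(coords, c(0, 0, 1, 1))
  expect_equal(s$per_sample,
               c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5),
               tolerance = 1e-12)
  expect_equal(s$mean, (9.5 / 10.5 + 8.5 / 9.5) / 2, tolerance = 1e-12)

  # a = 0, b > 0 gives s = 1; singleton clusters get s = 0
  s2 <- silhouette_score(matrix(c(0, 0, 5), ncol = 1), c(0, 0, 1))
  expect_equal(s2$per_sample, c(1, 1, 0))
  expect_error(silhouette_score(coords, rep(1, 4)), "2 clusters")

  withr::with_seed(33, {
    for (rep in 1:5) {
      n <- sample(8:30, 1)
      x <- matrix(rnorm(2 * n), n, 2)
      lab <- sample(0:2, n, replace = TRUE)
      if (length(unique(lab)) < 2) next
      got <- silhouette_score(x, lab)
      ora <- silhouette_brute(stats::dist(x), lab)
      expect_equal(got$per_sample, ora$per_sample, tolerance = 1e-12)
    }
  })
})

test_that("adjusted Rand matches hand case, oracle and invariances", {
  expect_equal(adjusted_rand(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_equal(adjusted_rand(1:6, rep(1, 6)), 0)
  expect_error(adjusted_rand(1:3, 1:4), "equal length")
  withr::with_seed(34, {
    for (rep in 1:10) {
      a <- sample(1:4, 25, TRUE); b <- sample(1:3, 25, TRUE)
      expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
      expect_equal(adjusted_rand(a, b), adjusted_rand(b, a), tolerance = 1e-12)
    }
  })
})

test_that("independent random partitions score at chance level", {
  withr::with_seed(35, {
    aris <- vapply(1:1000, function(i) {
      adjusted_rand(sample(0:2, 27, TRUE), sample(0:2, 27, TRUE))
    }, 1)
  })
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("consistency table compares methods pairwise per k", {
  parts <- tidyr::expand_grid(method = c("faa", "rp"), k = 2:3,
                              id = paste0("p", 1:6))
  parts$label <- rep(c(0, 0, 0, 1, 1, 1), 4)
  ct <- consistency_table(parts)
  expect_equal(nrow(ct), 2)
  expect_true(all(ct$ari == 1))
  bad <- parts
  bad$id[bad$method == "rp"] <- paste0("q", 1:6)
  expect_error(consistency_table(bad), "different participants")
})

test_that("cluster summary selects k by silhouette on planted cohorts", {
  co <- generate_cohort(two_cluster_spec(participants_per_cluster = 3,
                                         strength = 0.5, n_reports = 20,
                                         report_interval_s = 10.5, seed = 91))
  res <- cluster_recovery(co, quiet_cfg())
  expect_gte(res$ari, 0.8)
  cl <- cluster_distance_matrix(res$distance, quiet_cfg())
  expect_equal(cl$summary$k, 2:6)
  expect_true(all(cl$summary$silhouette >= -1 & cl$summary$silhouette <= 1))
})
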