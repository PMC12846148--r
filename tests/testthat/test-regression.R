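test_that("SMOTE balances classes with convex in-class interpolation", {
  x <- c(0, 1, 10, 11, 12, 13)
  y <- c(2L, 2L, 7L, 7L, 7L, 7L)
  bal <- smote_balance(x, y, seed = 3)
  expect_equal(as.vector(table(bal$y)), c(4L, 4L))
  synth <- bal$x[bal$synthetic]
  expect_true(all(synth >= 0 & synth <= 1))  # convex hull of class 2

  # already balanced input is untouched
  bal2 <- smote_balance(c(1, 2, 3, 4), c(1L, 1L, 2L, 2L), seed = 1)
  expect_equal(nrow(bal2), 4)
  expect_false(any(bal2$synthetic))

  # determinism per seed
  b1 <- smote_balance(x, y, seed = 42)
  expect_identical(b1, smote_balance(x, y, seed = 42))
  expect_false(identical(b1$x, smote_balance(x, y, seed = 43)$x))

  expect_error(smote_balance(x, c(2L, 2L, 7L, 7L, 7L, 8L)), "2 members")
  expect_error(smote_balance(numeric(0), integer(0)), "empty")
})

test_that("line fit matches the normal-equations solution", {
  f <- fit_line(c(0, 1), c(1, 3))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(fit_line(c(1, 2, 3), c(4, 4, 4))$slope, 0)
  f3 <- fit_line(c(0, 1, 2), c(0, 1, 0))
  expect_equal(f3$slope, 0, tolerance = 1e-12)
  expect_equal(f3$intercept, 1 / 3, tolerance = 1e-12)
  expect_error(fit_line(c(2, 2, 2), 1:3), "constant")

  withr::with_seed(19, {
    for (rep in 1:5) {
      x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x))
      f <- fit_line(x, y)
      X <- cbind(1, x)
      beta <- solve(t(X) %*% X, t(X) %*% y)
      expect_equal(unname(c(f$intercept, f$slope)), c(beta), tolerance = 1e-10)
    }
  })
})

test_that("seed-averaged slope recovers a noiseless line exactly", {
  y <- rep(c(4L, 5L, 6L, 7L), each = c(3L))
  x <- (y - 1) / 3
  fit <- participant_mean_slope(x, y, seeds = 1:10)
  expect_equal(fit$slope, 3, tolerance = 1e-9)
  expect_identical(fit$slope,
                   participant_mean_slope(x, y, seeds = 1:10)$slope)
})

test_that("group slope test matches hand computation", {
  st <- group_slope_test(c(2, 4, 6))
  expect_equal(st$mean_slope, 4)
  expect_equal(st$sd_slope, 2)
  expect_equal(st$cohens_d, 2)
  expect_equal(st$t, 4 / (2 / sqrt(3)), tolerance = 1e-9)
  expect_equal(st$df, 2)
  st0 <- group_slope_test(c(-1, 0, 1))
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)
  expect_lt(st0$ci_low, st0$ci_high)
  expect_error(group_slope_test(c(1, 1, 1)), "zero variance")
  expect_error(group_slope_test(c(1, 2)), "at least 3")
  expect_named(glance(st), c("mean_slope", "sd_slope", "cohens_d", "t", "df",
                             "p", "ci_low", "ci_high", "n"))
})

test_that("BH adjustment is a step-up over the full test family", {
  # equal p-values: the step-up minimum sits at j = m, so p_adj = p
  res <- bh_fdr(rep(0.001, 10), m_total = 10)
  expect_equal(res$p_adj, rep(0.001, 10))
  expect_true(all(res$reject))
  expect_equal(bh_fdr(0.5, 1)$p_adj, 0.5)
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
  expect_error(bh_fdr(c(0.2, 0.3), m_total = 1), "m_total")
  # monotone non-decreasing in sorted order
  withr::with_seed(23, {
    p <- runif(15)
    adj <- bh_fdr(p, m_total = 40)$p_adj
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  })
})

test_that("fast all-features slope path equals the public per-feature path", {
  co <- tiny_cohort("beta", 0.4, reports = 16, seed = 71)
  fm <- prepare_participants(co, quiet_cfg())$features[[1]]
  keepable <- drop_singleton_labels(fm$swb)
  fast <- swbeeg:::mean_slopes_all_(fm$x, fm$swb, seeds = 1:10)
  for (j in c(1, 23, 70)) {
    ref <- participant_mean_slope(fm$x[, j], fm$swb, seeds = 1:10)$slope
    expect_equal(fast[j], ref, tolerance = 1e-9)
  }
})

test_that("cohort regression table has the full 70-feature family", {
  co <- generate_cohort(two_cluster_spec(participants_per_cluster = 2,
                                         strength = 0.5, n_reports = 14,
                                         report_interval_s = 10.5, seed = 72))
  parts <- prepare_participants(co, quiet_cfg())
  tab <- regress_participants(parts, quiet_cfg())
  expect_equal(nrow(tab), 70)
  expect_equal(tab$df, rep(nrow(co) - 1, 70))
  expect_equal(tab$cohens_d, tab$mean_slope / tab$sd_slope, tolerance = 1e-9)
  expect_true(all(tab$p_corr >= tab$p - 1e-12))

  # tidy interface produces the same table from long features
  feats <- dplyr::bind_rows(purrr::map(co$recording, function(r) {
    epoch_features(extract_epochs(r, 10), fs = r$fs)
  }))
  tab2 <- regress_cohort(feats, quiet_cfg())
  expect_equal(tab2$mean_slope, tab$mean_slope, tolerance = 1e-9)
  expect_equal(tab2$p, tab$p, tolerance = 1e-9)
})

test_that("left-handed participants are excluded from group tests by default", {
  co <- generate_cohort(two_cluster_spec(participants_per_cluster = 2,
                                         strength = 0.5, n_reports = 14,
                                         report_interval_s = 10.5, seed = 73))
  co$recording[[1]]$handedness <- "left"
  parts <- prepare_participants(co, quiet_cfg())
  tab_r <- regress_participants(parts, quiet_cfg())
  tab_all <- regress_participants(parts, quiet_cfg(),
                                  include_left_handed = TRUE)
  expect_equal(unique(tab_r$df), 2)     # 3 right-handed participants
  expect_equal(unique(tab_all$df), 3)   # all 4 participants
})
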