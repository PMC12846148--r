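test_that("singleton labels are removed, order preserved", {
  expect_equal(drop_singleton_labels(c(5, 5, 6, 6, 9)), 1:4)
  expect_equal(drop_singleton_labels(c(7, 7, 7)), 1:3)
  expect_error(drop_singleton_labels(c(1, 2, 3)), "singleton")
  expect_error(drop_singleton_labels(integer(0)), "empty")
  keep <- drop_singleton_labels(c(9, 5, 6, 5, 6))
  expect_equal(keep, 2:5)
})

test_that("leave-one-out 1-NN predicts nearest other label with index ties", {
  x <- matrix(c(0, 1, 2), ncol = 1)
  pred <- loo_1nn(x, c(3L, 7L, 3L))
  expect_equal(pred, c(7L, 3L, 7L))
  expect_equal(mse(c(3, 7, 3), pred), 16)

  # perfect separation -> zero error
  x2 <- matrix(c(0, 0, 100, 100), ncol = 1)
  expect_equal(mse(c(2, 2, 9, 9), loo_1nn(x2, c(2L, 2L, 9L, 9L))), 0)

  # equidistant neighbours: lowest index wins
  x3 <- matrix(c(0, 2, 1), ncol = 1)
  expect_equal(loo_1nn(x3, c(4L, 8L, 5L))[3], 4L)
  expect_error(loo_1nn(matrix(1), 3L), "at least 2")
})

test_that("1-NN LOO matches a brute-force all-pairs scan", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      p <- sample(c(1, 5, 14), 1)
      x <- matrix(rnorm(n * p), n, p)
      labels <- sample(3:8, n, replace = TRUE)
      pred <- loo_1nn(x, labels)
      brute <- vapply(seq_len(n), function(i) {
        d <- vapply(seq_len(n), function(j) {
          if (i == j) Inf else sqrt(sum((x[i, ] - x[j, ])^2))
        }, 1)
        labels[which.min(d)]
      }, 1L)
      expect_identical(pred, brute)
    }
  })
})

test_that("MSE handles hand cases and is permutation invariant", {
  expect_equal(mse(c(3, 5), c(4, 9)), 8.5)
  expect_equal(mse(3, 9), 36)
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_error(mse(1:3, 1:2), "equal length")
  withr::with_seed(8, {
    a <- rnorm(20); b <- rnorm(20); o <- sample(20)
    expect_equal(mse(a, b), mse(a[o], b[o]))
  })
})

test_that("DTW equals exhaustive search over monotone paths", {
  expect_equal(dtw_distance(c(0, 0, 1), c(0, 1, 1)), 0)
  expect_equal(dtw_distance(1:5, 1:5), 0)
  expect_error(dtw_distance(matrix(1:4, 2), matrix(1:3, 3)), "channel")
  withr::with_seed(55, {
    for (rep in 1:8) {
      nx <- sample(2:6, 1); ny <- sample(2:6, 1)
      ch <- sample(1:3, 1)
      x <- matrix(rnorm(ch * nx), ch); y <- matrix(rnorm(ch * ny), ch)
      expect_equal(dtw_distance(x, y), dtw_brute(x, y), tolerance = 1e-12)
      expect_equal(dtw_distance(x, y), dtw_distance(y, x), tolerance = 1e-12)
    }
    # identity path bound for equal lengths
    a <- rnorm(6); b <- rnorm(6)
    expect_lte(dtw_distance(a, b), sqrt(sum((a - b)^2)) + 1e-12)
  })
})

test_that("input schemes expose 1, 14 and 70 features", {
  co <- tiny_cohort("gamma", 0.5, reports = 14, seed = 61)
  fm <- prepare_participants(co, quiet_cfg())$features[[1]]
  expect_equal(ncol(fm$x), 70)
  ev1 <- evaluate_scheme(fm, 1, band = "gamma", channel = "T7")
  ev2 <- evaluate_scheme(fm, 2, band = "gamma")
  ev3 <- evaluate_scheme(fm, 3)
  expect_true(all(c(ev1$mse, ev2$mse, ev3$mse) >= 0))
  expect_equal(ev3$n_used, length(drop_singleton_labels(fm$swb)))

  # the coupled band carries more signal than an uncoupled one
  evd <- evaluate_scheme(fm, 2, band = "delta")
  expect_lt(ev2$mse, evd$mse)

  # constant-SWB participants cannot be evaluated
  fm_const <- fm; fm_const$swb <- rep(6L, length(fm$swb))
  expect_error(evaluate_scheme(fm_const, 2, band = "gamma"), "distinct")
})

test_that("time-series scheme matches feature scheme plumbing", {
  co <- tiny_cohort("gamma", 0.5, reports = 10, seed = 62)
  ep <- extract_epochs(co$recording[[1]], 10)
  ev <- evaluate_scheme(ep, 1, band = "alpha", channel = "AF3", source = "ts",
                        fs = 128)
  expect_gte(ev$mse, 0)
  expect_equal(nrow(ev$predictions), ev$n_used)
})

test_that("best combinations and rescaled MSE behave as argmin/max-normalise", {
  evals <- tibble::tibble(band = c("a", "b"), channel = c("c1", "c2"),
                          mse = c(1, 2))
  bc <- best_combination(evals)
  expect_true(bc$is_unique)
  expect_equal(bc$winners$band, "a")
  evals$mse <- c(1, 1)
  expect_false(best_combination(evals)$is_unique)
  expect_error(best_combination(evals[0, ]), "no evaluations")

  expect_equal(rescale_mse(c(2, 4)), c(0.5, 1))
  expect_equal(rescale_mse(5), 1)
  expect_equal(rescale_mse(c(1, 1, 1)), c(1, 1, 1))
  expect_error(rescale_mse(c(0, 0)), "zero")
})

test_that("goodness-of-fit test is order invariant with Pearson residuals", {
  ct <- chi_squared_gof(c(5, 5, 5, 5, 5))
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 1)
  ct2 <- chi_squared_gof(c(2, 3, 3, 5, 16))
  ct3 <- chi_squared_gof(c(16, 5, 3, 3, 2))
  expect_equal(ct2$statistic, ct3$statistic)
  expect_equal(ct2$df, 4)
  expect_equal(ct2$residuals, (ct2$counts - ct2$expected) / sqrt(ct2$expected))
  expect_error(chi_squared_gof(c(0, 0)), "total")
  expect_s3_class(tidy(ct2), "tbl_df")
  expect_named(glance(ct2), c("statistic", "df", "p_value"))
})

test_that("binomial winner test is exact", {
  bt <- binomial_winner_test(3, 4, 0.5)
  expect_equal(bt$p_two_sided, 0.625)
  # at the expected count the upper tail includes the mode
  bt2 <- binomial_winner_test(4, 20, 0.2)
  expect_gte(bt2$p_one_sided, 0.5)
  expect_error(binomial_winner_test(2, 4, 1.2), "p0")
})

test_that("winner tallies count unique winners and report ties", {
  scans <- dplyr::bind_rows(
    tibble::tibble(participant_id = "a", band = band_names(),
                   channel = "T7", mse = c(3, 2, 1, 2, 3)),
    tibble::tibble(participant_id = "b", band = band_names(),
                   channel = "T7", mse = c(1, 1, 2, 2, 2)),
    tibble::tibble(participant_id = "c", band = band_names(),
                   channel = "T7", mse = c(5, 4, 3, 2, 1))
  )
  wt <- winner_tally(scans)
  expect_equal(as.vector(wt$counts[c("alpha", "gamma")]), c(1L, 1L))
  expect_equal(wt$tied, "b")
})
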