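test_that("transfer distance implements the normalized mean absolute error", {
  expect_equal(transfer_distance(c(2, 4, 4, 6), c(2, 4, 4, 6)), 0)
  expect_equal(transfer_distance(c(2, 4, 4, 6), c(3, 4, 5, 6)), (2 / 4) / 3,
               tolerance = 1e-12)
  expect_equal(transfer_distance(c(5, 5), c(7, 7)), 2)
  expect_error(transfer_distance(numeric(0), numeric(0)), "empty")
  expect_error(transfer_distance(1:3, 1:2), "equal length")
  # bounded by the max absolute error over the unique count
  withr::with_seed(3, {
    tr <- sample(1:10, 30, TRUE); pr <- sample(1:10, 30, TRUE)
    expect_lte(transfer_distance(tr, pr),
               max(abs(tr - pr)) / length(unique(tr)))
  })
})

test_that("transfer models store their selection and predict in range", {
  co <- tiny_cohort("gamma", 0.5, n = 3, reports = 16, seed = 81)
  parts <- prepare_participants(co, quiet_cfg(), compute_faa = TRUE)
  m_rp <- train_transfer_model(parts[1, ], "rp_knn", quiet_cfg())
  expect_s3_class(m_rp, "swb_transfer_model")
  expect_true(m_rp$band %in% band_names())
  expect_true(m_rp$channel %in% eeg_channels())

  m_t7 <- train_transfer_model(parts[1, ], "rp_linreg_fixed", quiet_cfg())
  expect_equal(m_t7$band, "alpha")
  expect_equal(m_t7$channel, "T7")

  # self-prediction with 1-NN on the training set is perfect
  pr_self <- predict_swb(m_rp, parts[1, ])
  keep <- drop_singleton_labels(parts$features[[1]]$swb)
  expect_equal(pr_self$swb_pred[keep], pr_self$swb_true[keep])

  # linear predictions stay clipped to the rating scale
  m_big <- m_t7
  m_big$slope <- 0; m_big$intercept <- 12.3
  pr <- predict_swb(m_big, parts[2, ])
  expect_true(all(pr$swb_pred == 10))
  m_big$intercept <- 6
  expect_true(all(predict_swb(m_big, parts[2, ])$swb_pred == 6))

  m_faa <- train_transfer_model(parts[1, ], "faa_linreg", quiet_cfg())
  pf <- predict_swb(m_faa, parts[2, ])
  expect_true(all(pf$swb_pred >= 1 & pf$swb_pred <= 10))
})

test_that("unusable participants are excluded with a reason", {
  co <- tiny_cohort("gamma", 0.5, n = 4, reports = 16, seed = 82)
  rec <- co$recording[[1]]
  rec$swb <- rep(6L, length(rec$swb))  # constant reporter
  co$recording[[1]] <- rec
  parts <- prepare_participants(co, quiet_cfg())
  expect_false(parts$usable[1])
  expect_match(parts$exclusion_reason[1], "2 SWB classes")
  expect_error(train_transfer_model(parts[1, ], "rp_knn", quiet_cfg()),
               "excluded")
  dm <- build_distance_matrix(parts, "rp_knn", quiet_cfg())
  expect_equal(dim(dm$D), c(3, 3))
  expect_equal(dm$excluded$participant_id, parts$participant_id[1])

  # min_epochs filter
  parts2 <- prepare_participants(co[2:4, ], analysis_config(min_epochs = 50))
  expect_true(all(!parts2$usable))
})

test_that("distance matrix is zero-diagonal and min-symmetrized", {
  co <- generate_cohort(two_cluster_spec(participants_per_cluster = 2,
                                         strength = 0.5, n_reports = 16,
                                         report_interval_s = 10.5, seed = 83))
  parts <- prepare_participants(co, quiet_cfg())
  dm <- build_distance_matrix(parts, "rp_knn", quiet_cfg())
  expect_equal(unname(diag(dm$D)), rep(0, 4))
  expect_true(all(dm$D >= 0))
  expect_identical(dm$D_sym, pmin(dm$D, t(dm$D)))
  expect_equal(dm$D_sym, t(dm$D_sym))
  # explicit min rule
  D <- matrix(c(0, 0.4, 0.2, 0), 2, byrow = TRUE)
  expect_equal(pmin(D, t(D))[1, 2], 0.2)
  expect_equal(pmin(D, t(D))[2, 1], 0.2)
})
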