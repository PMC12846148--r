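test_that("epochs are the closed 10 s window ending at the report sample", {
  co <- tiny_cohort(reports = 18, seed = 41)
  ep <- extract_epochs(co$recording[[1]], 10)
  expect_equal(nrow(ep), 18)
  expect_true(all(vapply(ep$samples, ncol, 1L) == 1281))
  expect_equal(ep$report_index, 1:18)

  # a report before one full window is skipped with a warning, not an error
  rec <- co$recording[[1]]
  rec$report_times[1] <- 5
  rec$report_times <- sort(rec$report_times)
  expect_warning(ep2 <- extract_epochs(rec, 10), "skipped")
  expect_equal(nrow(ep2) + attr(ep2, "n_skipped"), length(rec$swb))
  expect_equal(nrow(ep2), 17)
})

test_that("band-pass filter passes in-band and rejects out-of-band tones", {
  x10 <- sinus(10)
  y <- bandpass(x10, "alpha", 128)
  core <- 200:1080  # away from filter edge transients
  expect_gte(max(abs(y[core])), 0.9)
  y40 <- bandpass(sinus(40), "alpha", 128)
  expect_lte(max(abs(y40[core])), 0.1)
  expect_equal(bandpass(rep(0, 1281), "alpha", 128), rep(0, 1281))
  expect_length(y, 1281)
  expect_error(bandpass(x10, "gamma", 100), "too low")
})

test_that("band power concentrates, scales quadratically and tracks bandwidth", {
  x <- sinus(10)
  p <- vapply(band_names(), function(b) band_power(x, b, 128), 1)
  expect_gte(p[["alpha"]] / sum(p), 0.95)
  expect_equal(band_power(2 * x, "alpha", 128) / band_power(x, "alpha", 128),
               4, tolerance = 1e-6)
  expect_error(band_power(rnorm(100), "alpha", 128), "segment")

  # flat-spectrum oracle: white-noise band power ~ bandwidth
  bands <- eeg_bands()
  acc <- rep(0, 5)
  withr::with_seed(77, {
    for (i in 1:100) {
      w <- rnorm(1281)
      acc <- acc + vapply(band_names(), function(b) band_power(w, b, 128), 1)
    }
  })
  dens <- (acc / 100) / (bands$hi - bands$lo)
  expect_lt(max(dens) / min(dens), 1.15 / 0.85)
})

test_that("relative power normalises, is scale invariant and flags dead channels", {
  ep <- flat_epoch(sinus(10))
  rp <- relative_power(ep, 128)
  expect_true(all(rp["alpha", ] >= 0.9))
  expect_equal(unname(colSums(rp)), rep(1, 14), tolerance = 1e-9)

  # two-line spectrum splits between delta and beta
  ep2 <- flat_epoch(sinus(2) + sinus(20))
  rp2 <- relative_power(ep2, 128)
  expect_equal(unname(rp2["delta", 1]), 0.5, tolerance = 0.05)
  expect_equal(unname(rp2["beta", 1]), 0.5, tolerance = 0.05)
  expect_true(all(rp2[c("theta", "alpha", "gamma"), ] <= 0.05))

  noise <- matrix(rnorm(14 * 1281), 14)
  rpn <- relative_power(noise, 128)
  expect_equal(unname(colSums(rpn)), rep(1, 14), tolerance = 1e-9)
  expect_true(all(rpn >= 0))
  expect_equal(relative_power(noise * 3.7, 128), rpn, tolerance = 1e-9)

  dead <- noise; dead[3, ] <- 0
  expect_error(relative_power(dead, 128), "F3")
})

test_that("FAA is the log power ratio of AF4 to AF3", {
  w <- sinus(10) + 0.1 * withr::with_seed(5, rnorm(1281))
  ep <- flat_epoch(w)
  expect_equal(compute_faa(ep, 128), 0, tolerance = 1e-12)

  ep2 <- ep; ep2["AF4", ] <- 2 * w
  expect_equal(compute_faa(ep2, 128), log(4), tolerance = 1e-6)

  # antisymmetry under swapping the two frontal channels
  ep3 <- ep2; ep3["AF3", ] <- ep2["AF4", ]; ep3["AF4", ] <- ep2["AF3", ]
  expect_equal(compute_faa(ep3, 128), -compute_faa(ep2, 128), tolerance = 1e-12)
  # invariance to common scaling
  expect_equal(compute_faa(ep2 * 5, 128), compute_faa(ep2, 128),
               tolerance = 1e-9)
})

test_that("fast feature-matrix path equals the per-epoch reference path", {
  co <- tiny_cohort("alpha", 0.3, reports = 6, seed = 43)
  rec <- co$recording[[1]]
  fast <- swbeeg:::participant_feature_matrix_(rec, 10)
  ref <- feature_matrix(epoch_features(extract_epochs(rec, 10), fs = rec$fs))
  expect_equal(unname(fast$x), unname(ref$x), tolerance = 1e-12)
  expect_identical(fast$swb, ref$swb)
})
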