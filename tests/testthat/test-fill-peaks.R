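test_that("a flat spectrum passes through every stage unchanged", {
  y <- rep(5, 200)
  fit <- fill_peaks(y, hwi = 3, lambda = 4, bins = 20, it = 5)
  expect_equal(fit$smoothed[1, ], y, tolerance = 1e-10)
  expect_equal(fit$subsampled[1, ], rep(5, 20), tolerance = 1e-10)
  expect_equal(fit$suppressed[1, ], rep(5, 20), tolerance = 1e-10)
  expect_equal(fit$baseline[1, ], y, tolerance = 1e-10)
  corrected <- subtract_baseline(spectra_set(y), fit)
  expect_equal(corrected$intensities[1, ], rep(0, 200), tolerance = 1e-10)
})

test_that("a linear baseline under isolated narrow peaks is recovered", {
  n <- 1000
  truth <- 10 + 0.02 * (seq_len(n) - 1)
  spec <- synthetic_spec(
    n, "linear", c(10, 0.02 * (n - 1)),
    peaks = data.frame(centre = c(200, 500, 800), height = c(50, 80, 30), sigma = c(4, 5, 3)),
    noise_sigma = 0, seed = 1
  )
  g <- generate_spectra(spec)
  expect_equal(g$truth, truth, tolerance = 1e-12)
  fit <- fill_peaks(g$spectra, hwi = 2, lambda = NA, bins = 100, it = 10)
  # worst case is the constant end extension plus the half-bucket minimum
  # bias: slope * (bucket width - 1) = 0.18
  expect_lt(max(abs(fit$baseline[1, g$peak_free] - truth[g$peak_free])), 0.2)
})

test_that("the no-smoothing sentinel leaves the raw spectrum untouched", {
  set.seed(8)
  y <- rexp(300, 0.1)
  fit <- fill_peaks(y, hwi = 2, lambda = NA, bins = 30, it = 3)
  expect_identical(fit$smoothed[1, ], y)
  sch <- make_bins(300, 30)
  manual <- stretch(suppress(subsample_min(y, sch), window_schedule(2, 3)), sch)
  expect_identical(fit$baseline[1, ], manual)
})

test_that("suppression never exceeds the subsampled values and anchors the baseline", {
  set.seed(9)
  m <- rbind(rnorm(400, 50, 5), 30 + cumsum(rnorm(400)))
  fit <- fill_peaks(m, hwi = 4, lambda = 2, bins = 40, it = 6)
  expect_true(all(fit$suppressed <= fit$subsampled + 1e-12))
  for (i in 1:2) {
    at_centres <- stretch(fit$suppressed[i, ], fit$scheme, at = fit$scheme$centre)
    expect_identical(at_centres, fit$suppressed[i, ])
    expect_equal(
      stretch(fit$suppressed[i, ], fit$scheme),
      fit$baseline[i, ]
    )
  }
})

test_that("subtraction is exact, preserves negatives, and validates shapes", {
  set.seed(10)
  s <- spectra_set(rbind(rnorm(120, 10), rnorm(120, 10)))
  fit <- fill_peaks(s, hwi = 2, lambda = 3, bins = 12, it = 4)
  corr <- subtract_baseline(s, fit)
  expect_equal(corr$intensities, s$intensities - fit$baseline, tolerance = 0)
  expect_true(any(corr$intensities < 0))
  expect_error(subtract_baseline(spectra_set(rnorm(100)), fit), "mismatch")
})

test_that("data-frame and vector inputs give the same fit as a spectra_set", {
  set.seed(12)
  y <- rnorm(150, 20)
  base <- fill_peaks(spectra_set(y), hwi = 2, lambda = 2, bins = 15, it = 3)
  via_vec <- fill_peaks(y, hwi = 2, lambda = 2, bins = 15, it = 3)
  df <- tibble::tibble(axis = seq_len(150), intensity = y)
  via_df <- fill_peaks(df, hwi = 2, lambda = 2, bins = 15, it = 3)
  expect_identical(base$baseline, via_vec$baseline)
  expect_identical(base$baseline, via_df$baseline)
})

test_that("tidiers and autoplot expose the fit in standard forms", {
  set.seed(13)
  fit <- fill_peaks(rbind(rnorm(100, 5), rnorm(100, 7)), hwi = 2, lambda = 2, bins = 10, it = 3)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 200L)
  expect_named(td, c("spectrum", "channel", "axis", "intensity", "smoothed", "baseline", "corrected"))
  expect_equal(td$corrected, td$intensity - td$baseline)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_bins, 10L)
  expect_equal(gl$final_halfwidth, 1L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("spectra shorter than twice the bin count are rejected", {
  expect_error(fill_peaks(rnorm(30), hwi = 2, bins = 20, it = 2), "bins")
  expect_error(fill_peaks(rnorm(100), bins = 10, it = 2), "hwi")
})

test_that("baseline_rmse scores against a stored truth with a mask", {
  est <- c(1, 2, 3, 4)
  truth <- c(1, 2, 5, 4)
  expect_equal(baseline_rmse(est, truth), 1)
  expect_equal(baseline_rmse(est, truth, mask = c(TRUE, TRUE, FALSE, TRUE)), 0)
  expect_error(baseline_rmse(est, truth[1:3]), "lengths")
})
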