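test_that("without peaks or noise the spectrum equals the truth baseline", {
  spec <- synthetic_spec(500, "exponential-decay", c(100, 3, 10), noise_sigma = 0, seed = 1)
  g <- generate_spectra(spec)
  expect_identical(g$spectra$intensities[1, ], g$truth)
  expect_true(all(g$peak_free))
})

test_that("identical seeds reproduce byte-identical spectra; seeds matter", {
  spec <- maldi_like_preset(seed = 99L)
  g1 <- generate_spectra(spec)
  g2 <- generate_spectra(spec)
  expect_identical(g1$spectra$intensities, g2$spectra$intensities)
  g3 <- generate_spectra(maldi_like_preset(seed = 100L))
  expect_false(identical(g1$spectra$intensities, g3$spectra$intensities))
  # generation does not disturb the session RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_spectra(spec)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the MALDI-like preset matches its documented shape", {
  spec <- maldi_like_preset()
  expect_equal(spec$n_channels, 4000L)
  expect_equal(spec$baseline_kind, "exponential-decay")
  expect_equal(nrow(spec$peaks), 20L)
  g <- generate_spectra(spec)
  expect_gt(mean(g$peak_free), 0.5)
  expect_length(g$truth, 4000L)
  expect_true(all(is.finite(g$truth)))
  expect_true(all(diff(g$truth) < 0)) # decaying baseline
})

test_that("the LIBS-like truth baseline has two dips and a ridge", {
  g <- generate_spectra(libs_like_preset())
  d <- diff(g$truth)
  sign_flips <- diff(sign(d[abs(d) > 1e-6]))
  # local minima (dips): derivative flips - to +; ridge top flips + to -
  expect_gte(sum(sign_flips > 0), 2)
  expect_gte(sum(sign_flips < 0), 1)
  expect_length(g$truth, 1500L)
  # the tuned edges cover the preset exactly
  edges <- libs_like_edges()
  sch <- make_bins(1500, edges)
  expect_equal(sch$end[nrow(sch)], 1500L)
  expect_error(libs_like_edges(1000), "1500")
})

test_that("invalid synthetic specifications are rejected", {
  expect_error(
    synthetic_spec(100, "linear", c(0, 1),
                   peaks = data.frame(centre = 200, height = 1, sigma = 2)),
    "centres"
  )
  expect_error(
    synthetic_spec(100, "linear", c(0, 1),
                   peaks = data.frame(centre = 50, height = -1, sigma = 2)),
    "height"
  )
  expect_error(
    synthetic_spec(100, "linear", c(0, 1),
                   peaks = data.frame(centre = 50, height = 1, sigma = 0)),
    "sigma"
  )
  expect_error(synthetic_spec(100, "linear", c(0, 1), noise_sigma = -1), "noise_sigma")
  expect_error(synthetic_spec(100, "linear", c(0, NA)), "finite")
})

test_that("generate-to-file writes spectrum, truth, and metadata that round-trip", {
  g <- generate_spectra(synthetic_spec(
    200, "polynomial", c(5, 2, -1),
    peaks = data.frame(centre = 100, height = 40, sigma = 5),
    noise_sigma = 0.5, seed = 77
  ))
  prefix <- file.path(withr::local_tempdir(), "synth")
  paths <- write_synthetic(g, prefix)
  expect_true(all(file.exists(paths)))
  back <- read_spectra(paths[1])
  expect_equal(back$intensities, g$spectra$intensities, tolerance = 1e-14)
  truth_back <- read_spectra(paths[2])
  expect_equal(truth_back$intensities[1, ], g$truth, tolerance = 1e-14)
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(meta$seed, 77L)
  expect_equal(meta$n_channels, 200L)
  expect_equal(meta$noise_sigma, 0.5)
})
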