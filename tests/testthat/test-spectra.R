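test_that("spectrum construction enforces grid, finiteness and band ranges", {
  expect_s3_class(spectrum(seq(500, 1000, 5), rep(1, 101), "visnir"),
                  "ewdrs_spectrum")
  expect_error(spectrum(c(500, 500, 600), 1:3, "visnir"), class = "ewdrs_invalid_grid")
  expect_error(spectrum(c(500, 600), c(1, NA), "visnir"), class = "ewdrs_invalid_values")
  expect_error(spectrum(c(500, 600), 1:2, "swir"), class = "ewdrs_band_range")
  expect_error(spectrum(c(1100, 1200), 1:2, "visnir"), class = "ewdrs_band_range")
  expect_error(spectrum(c(500, 600), 1, "visnir"), class = "ewdrs_grid_mismatch")
})

test_that("referencing computes (Mraw-Bg)/(Mstd-Bg) and validates the triplet", {
  g <- seq(500, 1000, 10)
  bg <- spectrum(g, rep(0.1, length(g)), "visnir")
  mstd <- spectrum(g, rep(0.9, length(g)), "visnir")

  # identity: Mraw = Mstd, Bg = 0
  tri <- reference_triplet(mstd, spectrum(g, rep(0, length(g)), "visnir"), mstd)
  expect_equal(reference_spectrum(tri)$values, rep(1, length(g)))

  # zero: Mraw = Bg
  tri0 <- reference_triplet(bg, bg, mstd)
  expect_equal(reference_spectrum(tri0)$values, rep(0, length(g)))

  # direct arithmetic: (0.5-0.1)/(0.9-0.1) = 0.5
  mraw <- spectrum(g, rep(0.5, length(g)), "visnir")
  expect_equal(reference_spectrum(reference_triplet(mraw, bg, mstd))$values[1L], 0.5)

  # scale invariance in the standard
  k <- 3.7
  tri_k <- reference_triplet(
    spectrum(g, 0.1 + k * (mraw$values - 0.1), "visnir"), bg,
    spectrum(g, 0.1 + k * (mstd$values - 0.1), "visnir"))
  expect_equal(reference_spectrum(tri_k)$values,
               reference_spectrum(reference_triplet(mraw, bg, mstd))$values)

  # invalid triplets
  expect_error(reference_triplet(mraw, bg, bg), class = "ewdrs_invalid_reference")
  g2 <- seq(505, 1000, 10)
  expect_error(
    reference_triplet(mraw, bg, spectrum(g2, rep(0.9, length(g2)), "visnir")),
    class = "ewdrs_grid_mismatch")
})

test_that("Savitzky-Golay reproduces polynomials and suppresses noise", {
  g <- seq(500, 1000, 2)
  quad <- 2 + 0.004 * (g - 700) + 3e-5 * (g - 700)^2
  s <- spectrum(g, quad, "visnir")
  expect_equal(savitzky_golay(s, 2, 41)$values, quad, tolerance = 1e-12)

  const <- spectrum(g, rep(5, length(g)), "visnir")
  expect_equal(savitzky_golay(const, 2, 41)$values, rep(5, length(g)))

  noisy <- with_seed(42, spectrum(g, quad + rnorm(length(g), 0, 0.05), "visnir"))
  rms_in <- sqrt(mean((noisy$values - quad)^2))
  rms_out <- sqrt(mean((savitzky_golay(noisy, 2, 41)$values - quad)^2))
  expect_lt(rms_out, rms_in)

  expect_error(savitzky_golay(s, 2, 40), class = "ewdrs_parameter")
  expect_error(savitzky_golay(s, 3, 3), class = "ewdrs_parameter")
  expect_error(savitzky_golay(smooth_spectrum(seq(500, 520, 5)), 2, 41),
               class = "ewdrs_parameter")
})

test_that("matching factor is the VIS/NIR-to-SWIR intensity ratio at 1000 nm", {
  gv <- seq(500, 1000, 5)
  gs <- seq(1000, 1500, 5)
  vis <- spectrum(gv, rep(0.8, length(gv)), "visnir")
  swir <- spectrum(gs, rep(0.4, length(gs)), "swir")
  m <- matching_factor(vis, swir)
  expect_equal(m$factor, 2)
  expect_equal(m$factor, m$i_visnir / m$i_swir)

  equal <- matching_factor(vis, spectrum(gs, rep(0.8, length(gs)), "swir"))
  expect_equal(equal$factor, 1)

  expect_error(matching_factor(vis, spectrum(gs, rep(0, length(gs)), "swir")),
               class = "ewdrs_degenerate_match")
})

test_that("merged spectra are continuous at the junction and tagged merged", {
  gv <- seq(500, 1000, 5)
  gs <- seq(1000, 1500, 5)
  vis <- spectrum(gv, rep(2, length(gv)), "visnir")
  swir <- spectrum(gs, rep(1, length(gs)), "swir")
  merged <- merge_bands(vis, swir)
  expect_equal(merged$band, "merged")
  expect_equal(merged$values, rep(2, length(merged$values)))

  # arbitrary positive inputs: zero junction discontinuity
  vis2 <- with_seed(7, spectrum(gv, runif(length(gv), 0.5, 2), "visnir"))
  swir2 <- with_seed(8, spectrum(gs, runif(length(gs), 0.2, 1), "swir"))
  m <- matching_factor(vis2, swir2)
  merged2 <- merge_bands(vis2, swir2, m)
  junction <- spectrum_value_at(merged2, 1000)
  expect_equal(junction, m$factor * m$i_swir, tolerance = 1e-12)
  expect_equal(junction, m$i_visnir, tolerance = 1e-12)

  expect_error(merge_bands(swir2, swir2), class = "ewdrs_parameter")
})

test_that("resample interpolates linearly and refuses extrapolation", {
  g <- seq(500, 1000, 10)
  ramp <- spectrum(g, g / 100, "visnir")
  expect_equal(resample(ramp, g)$values, ramp$values)
  mids <- g[-length(g)] + 5
  expect_equal(resample(ramp, mids)$values, mids / 100)
  expect_error(resample(ramp, c(499, 600)), class = "ewdrs_range")
})

test_that("spectrum CSV round-trips values and band tag", {
  s <- smooth_spectrum()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$band, "visnir")
  expect_equal(back$wavelengths_nm, s$wavelengths_nm)
  expect_equal(back$values, s$values, tolerance = 1e-9)
})
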