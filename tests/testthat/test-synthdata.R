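test_that("preset properties carry the designed spectral features", {
  nm <- make_properties("nm_phantom")
  mm <- make_properties("mm_phantom")
  g <- nm$wavelengths_nm

  win <- g >= 1150 & g <= 1300
  expect_equal(g[win][which.max(nm$mu_a[win])], 1210)
  win_v <- g >= 550 & g <= 700
  expect_equal(g[win_v][which.max(mm$mu_a[win_v])], 630)
  # nerve-mimicking layer carries no blood pigment; muscle phantom has
  # weaker lipid than the nerve phantom
  expect_false("pseudo_blood" %in% names(phantom_recipe("nm_phantom")$weights))
  expect_false("pseudo_heme_dye" %in% names(phantom_recipe("nm_phantom")$weights))
  expect_lt(phantom_recipe("mm_phantom")$weights[["pseudo_lipid"]],
            phantom_recipe("nm_phantom")$weights[["pseudo_lipid"]])

  for (p in c("nm_phantom", "mm_phantom", "nerve", "muscle", "skin",
              "vessel", "nvb", "connective")) {
    props <- make_properties(p)
    expect_true(all(diff(props$mu_s_prime) < 0))
    expect_true(all(props$mu_a >= 0))
    expect_equal(c(props$g, props$n), c(0.9, 1.34))
  }
  expect_error(phantom_recipe("granite"), class = "ewdrs_unknown_key")
})

test_that("measurement triplets round-trip exactly at zero noise", {
  truth <- spectrum(seq(500, 1500, 10), 0.5 + 0.3 * sin(seq(500, 1500, 10) / 130),
                    "merged")
  quiet <- noise_model(gain_sd = 0, additive_sd_frac = 0, seed = 3)
  tri <- make_measurement_triplet(truth, quiet, repeat_index = 1L)
  expect_equal(reference_spectrum(tri)$values, truth$values, tolerance = 1e-14)

  # substream contract: raw varies with repeat index, standard does not
  noisy <- noise_model(seed = 3)
  t1 <- make_measurement_triplet(truth, noisy, 1L)
  t2 <- make_measurement_triplet(truth, noisy, 2L)
  expect_identical(t1$m_std$values, t2$m_std$values)
  expect_identical(t1$bg$values, t2$bg$values)
  expect_false(identical(t1$m_raw$values, t2$m_raw$values))
})

test_that("repeat noise lands near the configured gain jitter", {
  truth <- spectrum(seq(500, 1500, 10), rep(1, 101), "merged")
  noisy <- noise_model(gain_sd = 0.02, additive_sd_frac = 0, seed = 12)
  reps <- lapply(1:20, function(r)
    reference_spectrum(make_measurement_triplet(truth, noisy, r)))
  vals <- vapply(reps, function(s) s$values[50L], 0)
  expect_gt(sd(vals) / mean(vals), 0.01)
  expect_lt(sd(vals) / mean(vals), 0.04)
})

test_that("labeled datasets honor the counting contract and class structure", {
  ds <- make_labeled_dataset(classes = c("nerve", "muscle"), n_per_class = 3L,
                             grid_nm = seq(600, 1400, 100), n_photons = 2000,
                             seed = 5)
  expect_equal(nrow(ds$data$x), 6L)
  expect_equal(nlevels(ds$data$labels), 2L)
  expect_equal(as.vector(table(ds$data$labels)), c(3L, 3L))

  quiet <- noise_model(gain_sd = 0, additive_sd_frac = 0, seed = 1)
  ds0 <- make_labeled_dataset(classes = c("nerve", "muscle"), n_per_class = 2L,
                              grid_nm = seq(600, 1400, 200), n_photons = 1000,
                              noise = quiet, seed = 5)
  expect_equal(ds0$data$x[1L, ], ds0$data$x[2L, ], tolerance = 1e-13,
               ignore_attr = TRUE)
})

test_that("nerve presets show a deeper lipid dip than muscle in generated data", {
  ds <- make_labeled_dataset(classes = c("nerve", "muscle"), n_per_class = 2L,
                             grid_nm = seq(1150, 1320, 10), n_photons = 20000,
                             seed = 7)
  swir_of <- function(i) peak_ratio_swir(ds$spectra[[i]])
  nerve_r <- mean(vapply(which(ds$labels == "nerve"), swir_of, 0))
  muscle_r <- mean(vapply(which(ds$labels == "muscle"), swir_of, 0))
  expect_lt(nerve_r, muscle_r)
})

test_that("the tissue study design reproduces the published margins", {
  d <- tissue_study_design()
  expect_equal(sum(d$n_spectra), 85L)
  expect_equal(sum(d$n_spectra[d$group == "nerve_nvb"]), 25L)
  expect_equal(sum(d$n_spectra[d$group == "other"]), 60L)
  expect_setequal(d$class, c("nerve", "nvb", "skin", "muscle", "vessel",
                             "connective"))
})
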