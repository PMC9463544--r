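test_that("transport kernels match their closed forms", {
  expect_equal(sample_free_path(2, exp(-1)), 0.5)
  expect_lt(sample_free_path(1, 1 - 1e-12), 1e-9)
  expect_error(sample_free_path(0, 0.5), class = "ewdrs_parameter")

  expect_equal(sample_hg_deflection(0, 0.75), 0.5)
  expect_equal(sample_hg_deflection(0.9, 0.5), 0.98550, tolerance = 1e-5)
  u <- with_seed(2, runif(1e6))
  expect_lt(abs(mean(sample_free_path(1, u)) - 1), 0.005)
  expect_lt(abs(mean(sample_hg_deflection(0.9, u)) - 0.9), 0.003)
  expect_true(all(abs(sample_hg_deflection(0.9, u)) <= 1))

  expect_equal(fresnel_unpolarized(1.34, 1.34, 0.7), 0)
  expect_equal(fresnel_unpolarized(1.34, 1, 1), (0.34 / 2.34)^2, tolerance = 1e-6)
  cos_tir <- sqrt(1 - (1 / 1.34)^2) * 0.9  # beyond the critical angle
  expect_equal(fresnel_unpolarized(1.34, 1, cos_tir), 1)
})

test_that("probe geometry validates NA and fiber spacing", {
  expect_s3_class(probe_geometry(), "ewdrs_probe")
  expect_error(probe_geometry(na = 1.2), class = "ewdrs_parameter")
  expect_error(probe_geometry(spacing_mm = 0.5), class = "ewdrs_parameter")
})

test_that("weight ledger closes and results are deterministic in the seed", {
  mat <- flat_material(mu_a = 0.05, mu_s_prime = 1.5)
  mod <- build_two_layer(flat_material(mu_a = 0.01, n = 1.4), 1, mat, 10)
  r1 <- simulate_detected_reflectance(mod, quick_probe(), 800, 5000, seed = 42)
  r2 <- simulate_detected_reflectance(mod, quick_probe(), 800, 5000, seed = 42)
  expect_identical(r1$detector_fractions, r2$detector_fractions)
  expect_identical(r1$diffuse_reflectance, r2$diffuse_reflectance)
  r3 <- simulate_detected_reflectance(mod, quick_probe(), 800, 5000, seed = 43)
  expect_false(identical(r1$diffuse_reflectance, r3$diffuse_reflectance))
  expect_ledger_closed(r1)
  expect_lte(sum(r1$detector_fractions), r1$diffuse_reflectance)
})

test_that("opaque media absorb essentially all launched weight", {
  opaque <- flat_material(mu_a = 1000, mu_s_prime = 1, n = 1.34)
  r <- simulate_detected_reflectance(build_homogeneous(opaque), quick_probe(),
                                     800, 20000, seed = 1)
  expect_lt(abs(r$absorbed + r$specular - 1), 1e-3)
  expect_ledger_closed(r)
})

test_that("two-layer model with identical materials reproduces the homogeneous run", {
  mat <- flat_material(mu_a = 0.05, mu_s_prime = 1.5)
  hom <- build_homogeneous(mat)
  two <- layered_model(list(layer(mat, 1), layer(mat, Inf)))
  g <- seq(600, 1400, 200)
  s_hom <- simulate_spectrum(hom, quick_probe(), g, 4000, seed = 9)
  s_two <- simulate_spectrum(two, quick_probe(), g, 4000, seed = 9)
  expect_equal(s_two$spectrum$values, s_hom$spectrum$values)
})

test_that("wavelength-constant properties give a flat spectrum within error bars", {
  mod <- build_homogeneous(flat_material(mu_a = 0.1, mu_s_prime = 2))
  g <- seq(600, 1400, 100)
  sim <- simulate_spectrum(mod, quick_probe(), g, 20000, seed = 4)
  tot <- sim$spectrum$values
  se_tot <- sqrt(rowSums(sim$per_detector_se^2))
  expect_true(all(abs(tot - mean(tot)) < 4 * se_tot))
})

test_that("simulate_spectrum refuses wavelengths outside the property grids", {
  mat <- optical_properties(seq(600, 900, 10), rep(0.1, 31), rep(1, 31))
  expect_error(
    simulate_spectrum(build_homogeneous(mat), quick_probe(),
                      c(500, 700), 100, seed = 1),
    class = "ewdrs_range")
})

test_that("voxel and layered engines agree on an equivalent medium", {
  mat <- flat_material(mu_a = 0.2, mu_s_prime = 2)
  lay <- build_two_layer(flat_material(mu_a = 0.05, mu_s_prime = 2), 1, mat, 9)
  vox <- voxelize(lay, voxel_mm = 0.1, lateral_mm = 16, depth_mm = 10)
  rl <- simulate_detected_reflectance(lay, quick_probe(), 800, 30000, seed = 6)
  rv <- simulate_detected_reflectance(vox, quick_probe(), 800, 30000, seed = 6)
  expect_ledger_closed(rv)
  dl <- sum(rl$detector_fractions)
  dv <- sum(rv$detector_fractions)
  se <- sqrt(sum(rl$detector_se^2) + sum(rv$detector_se^2))
  expect_lt(abs(dl - dv), 4 * se)
})

test_that("single-packet traces report a coherent terminal event", {
  mod <- build_homogeneous(flat_material(mu_a = 0.1, mu_s_prime = 2))
  events <- vapply(1:50, function(s)
    trace_photon(mod, quick_probe(), 800, seed = s)$event, "")
  expect_true(all(events %in% c("detected", "escaped_undetected",
                                "transmitted", "roulette")))
  expect_gt(mean(events == "escaped_undetected"), 0.2)
  tr <- trace_photon(mod, quick_probe(), 800, seed = 7)
  expect_lt(abs(ledger_total(tr$weights) - 1), 1e-6)
})

test_that("diffusion oracle is monotone in distance and absorption", {
  rho <- seq(1, 4, 0.25)
  r1 <- diffusion_reflectance_oracle(0.01, 1, 1.34, rho)
  expect_true(all(diff(r1) < 0))
  r2 <- diffusion_reflectance_oracle(0.02, 1, 1.34, rho)
  expect_true(all(r2 < r1))
  expect_warning(diffusion_reflectance_oracle(0.5, 1, 1.34, 1),
                 "diffusive regime")
})
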