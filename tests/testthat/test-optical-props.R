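test_that("scattering-decay fit recovers parameters from clean and noisy data", {
  g <- seq(500, 1500, 10)
  truth <- list(a = 50, b = 600, c = 0.2)
  y <- truth$a * exp(-g / truth$b) + truth$c
  fit <- fit_scattering_decay(g, y)
  expect_equal(fit$a, truth$a, tolerance = 1e-6)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
  expect_equal(fit$c, truth$c, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
  expect_equal(eval_scattering_decay(fit, g), y, tolerance = 1e-6)

  y_noisy <- with_seed(5, y + rnorm(length(g), 0, 0.01))
  fitn <- fit_scattering_decay(g, y_noisy)
  expect_lt(abs(fitn$a / truth$a - 1), 0.05)
  expect_lt(abs(fitn$b / truth$b - 1), 0.05)
  expect_lt(abs(fitn$c / truth$c - 1), 0.05)

  # degenerate constant input: a -> 0 branch, c = mean
  flat <- fit_scattering_decay(g, rep(1.5, length(g)))
  expect_true(flat$degenerate)
  expect_equal(flat$a, 0)
  expect_equal(flat$c, 1.5)

  expect_error(fit_scattering_decay(g[1:3], y[1:3]), class = "ewdrs_parameter")
  expect_error(fit_scattering_decay(g, -y), class = "ewdrs_parameter")
})

test_that("absorption smoothing preserves quadratics, clamps at zero, reduces roughness", {
  g <- 500:1500
  quad <- 0.5 + 1e-6 * (g - 1000)^2
  props <- optical_properties(g, quad, rep(1, length(g)))
  sm <- smooth_absorption(props)
  expect_equal(sm$mu_a, quad, tolerance = 1e-10)
  expect_equal(sm$mu_s_prime, props$mu_s_prime)
  expect_equal(c(sm$g, sm$n), c(0.9, 1.34))

  noisy <- with_seed(3, pmax(quad + rnorm(length(g), 0, 0.05), 0))
  props_n <- optical_properties(g, noisy, rep(1, length(g)))
  sm_n <- smooth_absorption(props_n)
  expect_true(all(sm_n$mu_a >= 0))
  roughness <- function(v) mean(diff(v, differences = 2)^2)
  expect_lt(roughness(sm_n$mu_a), roughness(noisy))

  # near-zero noise floors undershoot after smoothing; the clamp holds at 0
  low <- optical_properties(g, pmax(with_seed(9, rnorm(length(g), 0, 1e-4)), 0),
                            rep(1, length(g)))
  sm_low <- smooth_absorption(low)
  expect_true(all(sm_low$mu_a >= 0))
  expect_true(any(sm_low$mu_a == 0))
})

test_that("chromophore basis has the stated feature wavelengths with unit maxima", {
  basis <- chromophore_basis()
  g <- 500:1500
  for (b in basis) {
    v <- b(g)
    expect_true(all(v >= 0))
    expect_equal(max(v), 1, tolerance = 1e-9)
  }
  win <- 1150:1300
  expect_equal(win[which.max(basis$pseudo_lipid(win))], 1210)
  # 1180 shoulder: locally concave bump
  d2 <- diff(basis$pseudo_lipid(1170:1190), differences = 2)
  expect_lt(d2[10], 0)
  expect_equal(c(550:700)[which.max(basis$pseudo_heme_dye(550:700))], 630)
  blood <- basis$pseudo_blood(540:650)
  expect_equal(c(540:650)[which.max(blood)], 575)
  # dual doublet: 610 is a second local maximum
  expect_gt(basis$pseudo_blood(610), basis$pseudo_blood(595))
  expect_gt(basis$pseudo_blood(610), basis$pseudo_blood(640))
  expect_gt(basis$pseudo_water(1450), basis$pseudo_water(1200))
})

test_that("synth_mu_a is linear, homogeneous and guards unknown names", {
  g <- seq(500, 1500, 5)
  expect_equal(synth_mu_a(c(pseudo_lipid = 0), g), rep(0, length(g)))
  lip <- synth_mu_a(c(pseudo_lipid = 1), g)
  wat <- synth_mu_a(c(pseudo_water = 1), g)
  both <- synth_mu_a(c(pseudo_lipid = 1, pseudo_water = 1), g)
  expect_equal(both, lip + wat)
  expect_equal(synth_mu_a(c(pseudo_lipid = 2.5), g), 2.5 * lip)
  win <- g[g >= 1150 & g <= 1300]
  expect_equal(win[which.max(synth_mu_a(c(pseudo_lipid = 1), win))], 1210)
  expect_error(synth_mu_a(c(nope = 1), g), class = "ewdrs_unknown_key")
  expect_error(synth_mu_a(c(pseudo_lipid = -1), g), class = "ewdrs_parameter")
})

test_that("mu_s recovery applies the similarity relation", {
  expect_equal(mu_s_from_reduced(1, 0), 1)
  expect_equal(mu_s_from_reduced(1, 0.9), 10)
  expect_error(mu_s_from_reduced(1, 1), class = "ewdrs_parameter")
})

test_that("properties CSV round-trips including g and n comments", {
  props <- make_properties("nerve")
  path <- withr::local_tempfile(fileext = ".csv")
  write_properties_csv(props, path)
  back <- read_properties_csv(path)
  expect_equal(back$mu_a, props$mu_a, tolerance = 1e-9)
  expect_equal(back$mu_s_prime, props$mu_s_prime, tolerance = 1e-9)
  expect_equal(back$g, 0.9)
  expect_equal(back$n, 1.34)
  expect_equal(back$name, "nerve")
})
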