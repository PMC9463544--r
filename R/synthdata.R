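#' Repeat-measurement noise model
#'
#' Instrument noise applied when generating synthetic measurement repeats:
#' a multiplicative gain jitter per repeat and additive detector noise per
#' wavelength. The published study reports five repeats per location but no
#' noise characterization, so the defaults (2% gain SD, additive SD 0.5% of
#' the signal median) are documented, non-canonical choices.
#'
#' @param gain_sd Multiplicative gain jitter SD per repeat (`>= 0`).
#' @param additive_sd_frac Additive noise SD as a fraction of the median
#'   raw signal (`>= 0`).
#' @param seed Master seed for all repeats drawn under this model.
#' @return An `ewdrs_noise_model`.
#' @export
noise_model <- function(gain_sd = 0.02, additive_sd_frac = 0.005, seed = 1) {
  stopifnot(gain_sd >= 0, additive_sd_frac >= 0)
  structure(list(gain_sd = gain_sd, additive_sd_frac = additive_sd_frac,
                 seed = seed),
            class = "ewdrs_noise_model")
}

# Preset table: chromophore weights (mm^-1 at each chromophore's peak),
# exponential scattering-decay parameters, and a flat baseline absorption.
# Weights were chosen once so that the preset family reproduces the
# qualitative feature set of the study samples: a lipid-rich, pigment-free
# nerve-mimicking phantom; a heme-dye muscle phantom with its 630-nm band
# and weak lipid features; and six dissected-tissue classes with the dual
# 575/610-nm blood doublet (except muscle), SWIR lipid dips, and 1450-nm
# water. Nerve and connective deliberately share every sub-1000-nm
# contribution and differ only in SWIR lipid, so the VIS/NIR band alone
# cannot separate them.
preset_table <- function() {
  list(
    nm_phantom = list(weights = c(pseudo_lipid = 0.15, pseudo_water = 0.15),
                      scatter = c(a = 3.0, b = 700, c = 0.25), baseline = 0.03),
    mm_phantom = list(weights = c(pseudo_lipid = 0.03, pseudo_water = 0.20,
                                  pseudo_heme_dye = 0.90),
                      scatter = c(a = 2.5, b = 700, c = 0.25), baseline = 0.03),
    nerve      = list(weights = c(pseudo_lipid = 0.30, pseudo_water = 0.35,
                                  pseudo_blood = 0.12),
                      scatter = c(a = 4.0, b = 700, c = 0.30), baseline = 0.03),
    muscle     = list(weights = c(pseudo_lipid = 0.05, pseudo_water = 0.45,
                                  pseudo_heme_dye = 0.40, pseudo_blood = 0.05),
                      scatter = c(a = 2.5, b = 800, c = 0.25), baseline = 0.03),
    skin       = list(weights = c(pseudo_lipid = 0.45, pseudo_water = 0.30,
                                  pseudo_blood = 0.20),
                      scatter = c(a = 5.0, b = 600, c = 0.40), baseline = 0.03),
    vessel     = list(weights = c(pseudo_lipid = 0.08, pseudo_water = 0.40,
                                  pseudo_blood = 0.60),
                      scatter = c(a = 3.0, b = 700, c = 0.30), baseline = 0.03),
    nvb        = list(weights = c(pseudo_lipid = 0.40, pseudo_water = 0.35,
                                  pseudo_blood = 0.25),
                      scatter = c(a = 3.0, b = 800, c = 0.25), baseline = 0.03),
    connective = list(weights = c(pseudo_lipid = 0.60, pseudo_water = 0.35,
                                  pseudo_blood = 0.12),
                      scatter = c(a = 4.0, b = 700, c = 0.30), baseline = 0.03)
  )
}

#' Phantom / tissue recipe presets
#'
#' Named synthetic recipes for the two phantom layers (`nm_phantom`,
#' `mm_phantom`) and the six dissected-tissue classes (`nerve`, `muscle`,
#' `skin`, `vessel`, `nvb`, `connective`). The nerve-mimicking phantom
#' carries no blood-simulating pigment; the muscle-mimicking phantom
#' carries the 630-nm heme-dye band and only weak lipid.
#'
#' @param preset Preset name.
#' @return An `ewdrs_recipe` with `name`, `weights`, `scatter` (a, b, c) and
#'   `baseline`.
#' @export
phantom_recipe <- function(preset) {
  tab <- preset_table()
  if (!preset %in% names(tab))
    stop_ewdrs(paste0("unknown preset '", preset, "'; available: ",
                      paste(names(tab), collapse = ", ")),
               "ewdrs_unknown_key")
  structure(c(list(name = preset), tab[[preset]]), class = "ewdrs_recipe")
}

#' Optical properties from a recipe
#'
#' Absorption is the recipe's baseline plus the weighted
#' [chromophore_basis()] combination; reduced scattering follows the
#' recipe's first-order exponential decay `a*exp(-lambda/b) + c`. Anisotropy
#' 0.9 and refractive index 1.34 throughout. Properties live on a 1-nm
#' master grid from 500 to 1500 nm; simulations subsample it.
#'
#' @param recipe An [phantom_recipe()] or a preset name.
#' @param grid Wavelength grid (nm, default `500:1500`).
#' @return An [optical_properties()] record.
#' @export
make_properties <- function(recipe, grid = 500:1500) {
  if (is.character(recipe)) recipe <- phantom_recipe(recipe)
  stopifnot(inherits(recipe, "ewdrs_recipe"))
  mu_a <- recipe$baseline + synth_mu_a(recipe$weights, grid)
  sc <- recipe$scatter
  mu_sp <- sc[["a"]] * exp(-grid / sc[["b"]]) + sc[["c"]]
  optical_properties(grid, mu_a, mu_sp, g = 0.9, n = 1.34, name = recipe$name)
}

#' Generate a synthetic measurement triplet
#'
#' Constructs raw, background and standard spectra such that referencing
#' the noiseless triplet recovers the true spectrum exactly: a smooth
#' lamp-and-detector response `L(lambda)` and a flat background are
#' synthesized, the standard is `Bg + L`, and the raw measurement is
#' `Bg + S*L` plus noise. Gain jitter and additive noise are drawn from a
#' substream derived from `(noise$seed, repeat_index)`, so the standard and
#' background are identical across repeats while the raw measurement
#' varies.
#'
#' @param true_spectrum Positive-valued [spectrum()].
#' @param noise An [noise_model()].
#' @param repeat_index Repeat number (1-based) selecting the substream.
#' @return A [reference_triplet()].
#' @export
make_measurement_triplet <- function(true_spectrum, noise = noise_model(),
                                     repeat_index = 1L) {
  stopifnot(is_spectrum(true_spectrum), inherits(noise, "ewdrs_noise_model"))
  grid <- true_spectrum$wavelengths_nm
  lamp <- 0.2 + exp(-((grid - 1050) / 400)^2)   # broadband source-like shape
  bg <- rep(0.05, length(grid))
  raw_clean <- true_spectrum$values * lamp
  raw <- with_seed(derive_seed(noise$seed, repeat_index), {
    gain <- 1 + rnorm(1L, 0, noise$gain_sd)
    eps <- rnorm(length(grid), 0, noise$additive_sd_frac * median(raw_clean))
    raw_clean * gain + eps
  })
  band <- true_spectrum$band
  reference_triplet(spectrum(grid, bg + raw, band),
                    spectrum(grid, bg, band),
                    spectrum(grid, bg + lamp, band))
}

#' Simulate the phantom study workflow
#'
#' Reproduces the phantom measurement bookkeeping: two one-layer phantoms
#' (homogeneous nerve-mimicking and muscle-mimicking) plus three two-layer
#' phantoms (nerve-mimicking cover of 1, 2, 3 mm over the muscle-mimicking
#' base), each measured `n_repeats` times (default 5), for 25 spectra in
#' the default configuration. Each phantom's spectrum is Monte Carlo
#' simulated once, then noisy repeats are emitted through the synthetic
#' triplet + referencing path.
#'
#' @param seed Master seed.
#' @param probe A [probe_geometry()].
#' @param grid_nm Simulation wavelengths.
#' @param n_photons Photons per wavelength.
#' @param n_repeats Repeats per phantom (default 5).
#' @param noise An [noise_model()] (its seed is derived from `seed`).
#' @return List with `spectra` (list of referenced repeat spectra),
#'   `manifest` (data frame: phantom, nm_thickness_mm, repeat), and
#'   `true_spectra` (one noiseless simulated spectrum per phantom).
#' @export
make_phantom_study <- function(seed, probe = probe_geometry(),
                               grid_nm = seq(500, 1500, by = 20),
                               n_photons = 10000, n_repeats = 5L,
                               noise = noise_model(seed = derive_seed(seed, 9001))) {
  nm <- make_properties("nm_phantom")
  mm <- make_properties("mm_phantom")
  configs <- list(
    list(id = "nm_1layer", model = build_homogeneous(nm), th = NA_real_),
    list(id = "mm_1layer", model = build_homogeneous(mm), th = NA_real_),
    list(id = "two_layer_1mm", model = build_two_layer(nm, 1, mm), th = 1),
    list(id = "two_layer_2mm", model = build_two_layer(nm, 2, mm), th = 2),
    list(id = "two_layer_3mm", model = build_two_layer(nm, 3, mm), th = 3))
  spectra <- list()
  manifest <- list()
  true_spectra <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    sim <- simulate_spectrum(cfg$model, probe, grid_nm, n_photons, seed = seed)
    true_spectra[[cfg$id]] <- sim$spectrum
    for (r in seq_len(n_repeats)) {
      tri <- make_measurement_triplet(sim$spectrum, noise,
                                      repeat_index = (ci - 1L) * n_repeats + r)
      spectra[[length(spectra) + 1L]] <- reference_spectrum(tri)
      manifest[[length(manifest) + 1L]] <-
        data.frame(phantom = cfg$id, nm_thickness_mm = cfg$th, repeat_idx = r)
    }
  }
  list(spectra = spectra, manifest = do.call(rbind, manifest),
       true_spectra = true_spectra)
}

#' Design table of the dissected-tissue study
#'
#' Sample counts per dissected-tissue class (five repeats per measurement
#' location), grouped into the classification margin `nerve_nvb` (nerve and
#' neurovascular bundle) versus `other`. The margins are 25 and 60 spectra,
#' 85 in total.
#'
#' @return Data frame with columns `class`, `group`, `n_spectra`.
#' @export
tissue_study_design <- function() {
  data.frame(
    class = c("nerve", "nvb", "skin", "muscle", "vessel", "connective"),
    group = c("nerve_nvb", "nerve_nvb", "other", "other", "other", "other"),
    n_spectra = c(15L, 10L, 15L, 15L, 15L, 15L))
}

#' Generate a labeled multi-class spectral dataset
#'
#' Simulates one spectrum per class preset (homogeneous models, common
#' per-wavelength random-number substreams across classes so that classes
#' with identical optical properties in a band produce identical simulated
#' values there), then emits `n_per_class` noisy measurement repeats per
#' class through the triplet + referencing path.
#'
#' @param classes Character vector of preset names (default the six
#'   dissected-tissue classes).
#' @param n_per_class Repeats per class (default 5, the study's repeat
#'   count).
#' @param probe A [probe_geometry()].
#' @param grid_nm Simulation wavelengths.
#' @param n_photons Photons per wavelength.
#' @param noise An [noise_model()] (its seed is derived from `seed`).
#' @param seed Master seed.
#' @return List with `data` (an [labeled_spectra()] on `grid_nm`),
#'   `spectra` (the individual repeat spectra), and `true_spectra` (one
#'   noiseless simulated spectrum per class).
#' @export
make_labeled_dataset <- function(classes = c("nerve", "nvb", "skin", "muscle",
                                             "vessel", "connective"),
                                 n_per_class = 5L, probe = probe_geometry(),
                                 grid_nm = seq(500, 1500, by = 25),
                                 n_photons = 20000, noise = NULL, seed = 1) {
  stopifnot(n_per_class >= 2L)
  if (is.null(noise)) noise <- noise_model(seed = derive_seed(seed, 9002))
  spectra <- list()
  labels <- character(0)
  true_spectra <- list()
  for (ci in seq_along(classes)) {
    props <- make_properties(classes[ci])
    sim <- simulate_spectrum(build_homogeneous(props), probe, grid_nm,
                             n_photons, seed = seed)  # common substreams
    true_spectra[[classes[ci]]] <- sim$spectrum
    for (r in seq_len(n_per_class)) {
      tri <- make_measurement_triplet(sim$spectrum, noise,
                                      repeat_index = (ci - 1L) * n_per_class + r)
      spectra[[length(spectra) + 1L]] <- reference_spectrum(tri)
      labels <- c(labels, classes[ci])
    }
  }
  feats <- t(vapply(spectra, function(s) s$values,
                    numeric(length(grid_nm))))
  list(data = labeled_spectra(feats, labels, grid_nm),
       spectra = spectra, labels = labels, true_spectra = true_spectra)
}
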