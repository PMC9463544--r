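# ewdrs

Model-based characterization of **extended-wavelength diffuse reflectance
spectroscopy** (EWDRS): fiber-optic probe measurements spanning the VIS/NIR
(500–1000 nm) and SWIR (1000–1500 nm) bands, used for intraoperative
identification of nerves and neurovascular bundles against muscle, skin,
vessels and connective tissue.

The package is aimed at biomedical-optics researchers who want to study
probe designs, layered phantoms and buried-structure scenarios in
simulation before (or alongside) hardware experiments. It provides:

* a **Monte Carlo photon-transport engine** (C++ core) for layered and
  voxelized tissue models under a seven-fiber contact probe (600-µm cores,
  NA 0.39, six detectors on a hexagon around the source), with weighted
  packets, Henyey–Greenstein scattering, Fresnel boundaries, Russian
  roulette, NA-gated per-fiber detection and an exact weight ledger;
* the **dual-band preprocessing chain**: referencing against a reflectance
  standard, `S_ref = (M_raw − Bg) / (M_std − Bg)`; Savitzky–Golay smoothing
  (order 2, window 41); and band merging at 1000 nm via the matching factor
  `M = I_VISNIR(1000) / I_SWIR(1000)`;
* **agreement analysis**: area-under-curve normalization, 95% confidence
  bands (mean ± 1.96 SD of repeats), difference spectra with out-of-band
  intervals, and the diagnostic peak ratios 575/610 nm (blood) and
  1210/1270 nm (lipid);
* **sparse multinomial logistic regression** (L1 prior, coordinate-wise
  bound optimization) with leave-one-out cross-validation and
  confusion/accuracy summaries;
* a **synthetic-data module** generating phantom and tissue stand-ins —
  optical-property presets built from Gaussian pseudo-chromophores at the
  documented feature wavelengths, measurement triplets with repeat noise,
  and labeled multi-class datasets.

## Worked example

Simulate the two-layer phantom study — a nerve-mimicking (NM) cover over a
muscle-mimicking (MM) base whose dye absorbs at 630 nm — and watch the
diagnostic ratios track the cover thickness:

```r
library(ewdrs)

probe <- probe_geometry()            # 0.3 mm cores, NA 0.39, 0.66 mm spacing
nm <- make_properties("nm_phantom")  # lipid-rich, no blood pigment
mm <- make_properties("mm_phantom")  # 630-nm heme-mimicking dye

grid <- seq(500, 1500, 20)
sims <- lapply(c(1, 2, 3), function(th)
  simulate_spectrum(build_two_layer(nm, th, mm), probe, grid,
                    n_photons_per_wavelength = 1e5, seed = 17))

round(sapply(sims, function(s) c(swir = peak_ratio_swir(s$spectrum),
                                 vis  = peak_ratio_phantom_vis(s$spectrum))), 3)
#>       [,1]  [,2]  [,3]     # NM cover: 1 mm, 2 mm, 3 mm
#> swir 0.767 0.728 0.722
#> vis  0.969 1.041 1.064
```

The SWIR (lipid) ratio falls toward the pure-NM value as the lipid-rich
cover thickens, while the VIS ratio rises toward 1 as the buried dye's
630-nm dip fades — at 3 mm the dip is smaller than the Monte Carlo noise
floor of the simulation itself. Every run is bit-reproducible: results are
a pure function of (model, probe, photons, seed).

A single-wavelength run exposes the full physics ledger:

```r
r <- simulate_detected_reflectance(build_homogeneous(nm), probe,
                                   wavelength_nm = 800,
                                   n_photons = 1e5, seed = 7)
print(r)
#> <detection result> 100000 photons, seed 7
#>   detected (6 fibers): 9.826e-03 total
#>   specular 0.0212 | diffuse 0.4971 | transmitted 0.0000 | absorbed 0.4817
```

`ledger_total(r)` is 1 to within 1e-6 on every run. A classification
round-trip on the synthetic six-tissue dataset:

```r
ds <- make_labeled_dataset(seed = 29)            # 6 classes x 5 repeats
feats <- prepare_features(ds$spectra, ds$labels, band = "full")
confusion_and_accuracy(feats$labels, loocv(feats, prior_scale = 0.1))
```

A thin command-line front end over the same functions is installed at
`inst/cli/ewdrs.R` (subcommands `preprocess`, `merge`, `props`, `simulate`,
`synth`, `compare`, `classify`, `run`).

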