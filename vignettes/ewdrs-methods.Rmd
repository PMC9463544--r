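---
title: "Model-based characterization of extended-wavelength diffuse reflectance measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based characterization of extended-wavelength diffuse reflectance measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement being modeled

Extended-wavelength diffuse reflectance spectroscopy (EWDRS) probes tissue
with a fiber-optic contact probe over 500–1500 nm, acquired by two
spectrometers: a VIS/NIR channel (500–1000 nm, where haemoglobin-like
pigments absorb) and a SWIR channel (1000–1500 nm, where lipid, water and
collagen absorb). The probe is a central illumination fiber with six
collection fibers on a hexagon around it (600-µm cores, NA 0.39). The
application driving the platform is intraoperative nerve identification:
nerves and neurovascular bundles (NVB) differ from surrounding muscle, skin
and vessels in their blood-related 575/610-nm doublet and their
lipid-related 1210-nm dip.

`ewdrs` re-creates that measurement chain end to end in software so that
probe designs, layered phantoms and buried-structure scenarios can be
studied without hardware: a Monte Carlo photon-transport engine with the
probe's source–detector geometry, the dual-band preprocessing chain,
agreement statistics against measurement confidence bands, diagnostic peak
ratios, and a sparse multinomial logistic regression (SMLR) classifier with
leave-one-out cross-validation. Because no raw spectra are distributed with
the study this package emulates, a synthetic-data module generates phantom
and tissue stand-ins with the documented spectral features; every empirical
statement in this vignette is computed by the package's own tests and
acceptance script.

## Preprocessing model

Each acquisition is referenced against a 99% reflectance standard,

$$S_{ref}(\lambda) = \frac{M_{raw}(\lambda) - Bg(\lambda)}{M_{std}(\lambda) - Bg(\lambda)},$$

which cancels the lamp spectrum and the spectral response of each detector.
Referenced intensities are in arbitrary units and may exceed 1 (the
standard is used in contact geometry), so no upper bound is enforced. SWIR
spectra are smoothed with a Savitzky–Golay filter of order 2 and window 41
samples. Edges are handled by evaluating the polynomial fit of the
first/last full window at the end positions (no padding), so polynomials up
to the filter order are reproduced exactly everywhere — the property the
test suite asserts to machine precision.

The two bands are joined at 1000 nm by a scalar matching factor
$M = I_{VIS/NIR}(1000)/I_{SWIR}(1000)$. The platform multiplies the SWIR
band by $M$ and keeps the VIS/NIR band unscaled: referencing fixes the
VIS/NIR scale first, and rescaling the later band preserves it. Points of
either band on the wrong side of the junction are dropped so the merged
grid is single-valued; the junction is continuous by construction.
Intensities at off-grid wavelengths are always linear interpolations,
consistent with `resample()`. One documented gap: the original hardware
applies an InGaAs fixed-pattern-noise correction for which no algorithm is
published; the platform does not model it.

## Optical properties

Materials carry $\mu_a(\lambda)$ and $\mu_s'(\lambda)$ in mm⁻¹ on a 1-nm
master grid (500–1500 nm), with anisotropy fixed at $g = 0.9$ and
refractive index $n = 1.34$ for every tissue and phantom. Reduced
scattering spectra are modeled as a first-order exponential decay
$\mu_s'(\lambda) = a\,e^{-\lambda/b} + c$, fitted by Levenberg–Marquardt
nonlinear least squares initialized from a log-linear regression; the
published method names the decay family but not its parameterization, so
the offset form with $\lambda$ as the independent variable was chosen and
the degenerate constant-input case is handled as $a \to 0$ with $c$ the
sample mean. Absorption spectra are smoothed with the same order-2
Savitzky–Golay filter (window 41, mirroring the preprocessing default,
since only the order is documented) and clamped at zero from below.

Because no extinction spectra are tabulated in the source study, synthetic
chromophores are Gaussian mixtures placed at the documented feature
wavelengths: pseudo-lipid (1210-nm peak, 1180-nm shoulder), pseudo-water
(970 and 1450 nm), a pseudo-heme dye (single 630-nm band, the muscle
phantom's pigment), and pseudo-blood (575/610-nm doublet). Only the
feature positions are meaningful; the line widths are stand-ins.

## Monte Carlo engine

The engine is a weighted-packet "hop–drop–spin" transport code in the MCML
tradition, written in C++:

* **Launch.** Position uniform over the 0.3-mm source core; direction
  uniform in solid angle within the NA cone in air, Fresnel-attenuated
  (booked as specular reflection) and refracted into the tissue. The beam
  profile is not documented for the physical system; a filled uniform cone
  is the conventional default.
* **Propagation.** Dimensionless optical depth $-\ln u$ is consumed across
  layer or voxel boundaries; layered models use exact analytic interface
  crossings, voxel models a face-to-face traversal with material looked up
  per cell. At each interaction the packet deposits
  $w\,\mu_a/\mu_t$ (continuous absorption weighting) and scatters through a
  Henyey–Greenstein deflection sampled by inverse CDF.
* **Boundaries.** Unpolarized Fresnel reflection/refraction at the
  tissue–air surface and at internal index mismatches (the probe face is
  modeled as air-coupled; coupling is not documented for the hardware, so
  the external index is a parameter). Voxel models require one internal
  index, which the constructor enforces. Photons exiting the finite bottom
  of a stack are booked as transmitted without a bottom Fresnel step; the
  study geometries end in 40-mm or deeper bases where that weight is
  negligible.
* **Detection.** A packet escaping the top surface is detected by a fiber
  if its exit point lies inside that fiber's core circle and its refracted
  exit direction lies within the acceptance cone ($\sin\theta_{air} \le$
  NA). Escaping weight can also be tallied into concentric annuli,
  ungated, for diffusion-theory cross-checks.
* **Termination.** Russian roulette below weight $10^{-4}$ with survival
  probability 0.1. The ledger books the *net* roulette change — terminated
  weight minus the amplification granted to survivors — so that specular +
  diffuse + transmitted + absorbed + roulette equals the launched weight
  exactly (within $10^{-6}$) on every run, while the roulette entry is zero
  in expectation. A safety cap (default $4\times10^{6}$ interactions per
  packet, capped weight booked to the roulette entry) exists because in an
  effectively non-absorbing half-space the depth coordinate of a packet is
  a recurrent random walk whose return time has infinite mean; the cap is
  unreachable in any absorbing medium.
* **Randomness.** All draws come from counter-derived splitmix64
  substreams: one stream per packet, keyed by (run seed, packet index), and
  one run seed per wavelength, keyed by (master seed, wavelength value).
  Results are therefore a pure function of (model, probe, photons, seed),
  bit-identical across runs, independent of R's RNG state — and two models
  simulated under the same master seed share randomness per wavelength.
  This common-random-numbers property is used deliberately: model-to-model
  differences (cover-thickness contrasts, band-presence comparisons) are
  then quasi-deterministic, because packets follow identical paths until
  they first reach the region where the models differ.

### Verification strategy

Simulated spectra have no printed reference values, so the engine is
verified by invariants: exact ledger closure across randomized
configurations; total reflectance of 1 (within $10^{-3}$) for a
non-absorbing matched-boundary half-space; hexagonal detector symmetry
within Monte Carlo standard errors (estimated per detector from the
per-packet second moments); equality of a homogeneous model and a
two-layer model built from the same material; and agreement with an
independent closed-form oracle. The oracle is the steady-state diffusion
dipole for a semi-infinite medium (isotropic source at
$z_0 = 1/(\mu_a + \mu_s')$, image source above the extrapolated boundary
$z_b = 2AD$ with Groenhuis' internal-reflection parameter). Its exitance is
evaluated from the boundary radiance, $R(\rho) = C_\phi\,\phi + C_j\,j_z$
with the two Fresnel angular moments integrated numerically: the flux-only
form of the same dipole misallocates light between near and far field under
an index-mismatched boundary and cannot certify the engine in the very
range it is needed, while the radiance-based form tracks the transport
solution closely. The tests assert agreement within 15% at 1–3 mm
source–detector separation for $\mu_s' = 1$ mm⁻¹, $\mu_a = 0.01$ mm⁻¹,
$n = 1.34$; the acceptance script reports the measured maximum deviation.

## Tissue models

Layered models are half-open slabs $[z_{top}, z_{bot})$ — an interface
depth belongs to the lower layer — laterally infinite, with the probe at
$z = 0$. The phantom study geometry is a nerve-mimicking (NM) cover of 1–3
mm over a 40-mm muscle-mimicking (MM) base. The nerve-plexus scenario is
voxelized (default 0.1-mm voxels, resolving the thinnest 0.2-mm muscle
cover): a 2-mm-thick network of nerve cylinders — three 2-mm trunks 3 mm
apart joined by two 1-mm branches, dimensions configurable because only the
slab thickness and cover depths are documented — under muscle covers of
0.2–2 mm, embedded in muscle. Lateral voxel lookups clamp to the edge
material; packets rarely travel beyond the default 20-mm grid half-width.

## Synthetic data: what it emulates and what it does not

The generator reproduces the *structure* of the study's datasets — five
measurement repeats per sample; two one-layer plus three two-layer phantoms
(25 spectra); six dissected-tissue classes with margins of 25 nerve+NVB
versus 60 other spectra (85 total) — and the *qualitative* spectral
features: the NM phantom's 1210-nm dip and 1180-nm shoulder with no blood
pigment, the MM phantom's 630-nm dye band with weak lipid, and tissue
classes with the blood doublet, lipid and water features. Chromophore
weights per preset were fixed once, when the presets were designed, so that
the qualitative orderings documented for the real samples hold (nerve's
lipid ratio below muscle's; the phantom pair separable in VIS/NIR by the
630-nm dye); measured ratio values from the original phantoms are not
reproduction targets, since those depend on unavailable raw data. Two
deliberate design points:

* A flat baseline absorption of 0.03 mm⁻¹ represents the gelatin/water
  matrix of the phantoms and unmodeled background absorbers in tissue.
  Without it the VIS/NIR band of the pigment-free presets would be almost
  transparent, which is neither physical for these samples nor kind to a
  transport code (packet walks grow without bound as $\mu_a \to 0$).
* The heme-family shapes (pseudo-blood and the heme dye) carry a weak
  broad tail through 700–1000 nm, a few percent of their main band,
  mirroring the residual NIR absorption of haemoglobin and myoglobin;
  without it, pigmented tissue would be unphysically transparent between
  the visible bands and the SWIR, and band-dependent sensing depth — a
  central mechanism in depth studies — would vanish from the family.
  Relatedly, the neurovascular-bundle and muscle presets use nearly equal
  scattering decays so that their contrast is chromophore-driven, as the
  depth-study narrative assumes.
* `nerve` and `connective` share every sub-1000-nm contribution (blood,
  water, scattering, baseline) and differ only in SWIR lipid weight.
  Combined with common random numbers, their simulated VIS/NIR bands are
  bit-identical, making "the VIS/NIR channel alone cannot separate them"
  an exact property of the generated data rather than a statistical
  accident. This is the synthetic analogue of the study's finding that
  full-band classification beats VIS/NIR-only classification.

Measurement noise is a 2% multiplicative gain jitter per repeat plus
additive noise at 0.5% of the median raw signal — invented, documented
values; the study reports repeat counts but no noise model. Triplets are
constructed so the referencing equation recovers the true spectrum exactly
at zero noise (the synthetic lamp shape cancels), which the tests assert.

What passing tests on these data do **not** show: performance on real
tissue spectra (real chromophore line shapes, probe-pressure effects,
inter-animal variability and instrument artifacts are absent), recovery of
the study's specific selected wavelengths, or its measured ratio values.

## Classifier

SMLR maximizes the multinomial log-likelihood minus
$\lambda \sum |w|$ (Laplacian prior, intercepts unpenalized, last class
pinned at zero) by cyclic coordinate-wise bound optimization: the Hessian
is majorized by $\tfrac12(1 - 1/K)\,\mathrm{diag}(X^TX)$, giving
soft-threshold updates. Convergence is declared when the largest weight
change in a sweep falls below $10^{-6}$ (at most $10^4$ sweeps; exceeding
them flags the model rather than raising). Features are AUC-normalized
merged spectra resampled to a 5-nm grid and z-scored, with the default
penalty $\lambda = 0.1$ — the source study states no hyperparameters or
feature preparation, so these are package defaults chosen once, not fitted
values. Leave-one-out cross-validation refits the standardization inside
every fold. Ties in the posterior argmax break toward the lowest class
index so predictions are deterministic. An independent check in the test
suite compares predictions against `glmnet`'s multinomial lasso at a
matched penalty; the two parameterizations differ (glmnet's symmetric
multinomial versus a pinned reference class) so agreement is asserted on
predictions, not coefficients.

## Agreement analysis and ratios

Simulated and measured spectra are AUC-normalized (trapezoid rule) before
comparison; the 95% confidence band is the pointwise mean ±1.96 sample SD
of the normalized repeats, and the agreement report flags wavelengths where
the simulation leaves the band, merged into contiguous intervals without
bridging single in-band points. Peak ratios interpolate linearly (the
simulation grids are coarser than the 1-nm measurement grids): 575/610 nm
for blood, 1210/1270 nm for lipid, and — because the muscle phantom's dye
absorbs at 630 nm rather than at the haemoglobin doublet, and the
wavelength pair behind the study's phantom "VIS/NIR peak ratio" is not
documented — a documented 630/700-nm phantom variant. Whether the original
ratios were computed on normalized or raw spectra is also undocumented;
ratios here are scale-free between the presets' flanks, so the choice only
matters through normalization's reshaping, and the package computes them on
the spectra it is given.

Buried-feature contrast is quantified as dip depth against a linear
baseline (`dip_depth()` for a single spectrum; the acceptance studies use
the mean deficit across the dye band, 600–640 nm, of the ratio of a
two-layer spectrum to the homogeneous cover-material spectrum simulated
under the same master seed — the ratio cancels the cover's own spectral
curvature and, through common random numbers, most Monte Carlo noise).
"Detectable" means the dip exceeds the 1.96-sigma counting-noise floor of
the stated photon budget, propagated from the engine's per-detector
standard errors — the noise an observer of a single simulated spectrum
pair would face without variance reduction.

## Problem sizes and numerical choices

The simulation sizes used by the tests and the acceptance script are the
package's own working points, chosen to keep full runs practical on a
single CPU: 10⁵ packets per wavelength on a 20-nm grid for the two-layer
thickness study, 4×10⁴ packets per wavelength on a 50-nm grid for the
voxelized plexus study (five volumes: homogeneous muscle plus four cover
depths), 2×10⁴ packets on a 50-nm grid for the six-class tissue dataset,
10⁵ packets for single-wavelength physics checks, and 4×10⁵ quadrature
points for the plexus-volume cross-check. Tolerances: ledger
closure 10⁻⁶; merged-band junction continuity 10⁻¹²; posterior
normalization 10⁻¹²; diffusion-oracle agreement 15%; hexagonal symmetry 3
Monte Carlo standard errors. Degenerate inputs are handled explicitly:
constant scattering spectra take the $a \to 0$ branch, zero SWIR intensity
at the match point and non-positive spectrum integrals raise typed errors,
and a LOOCV fold that loses a whole class warns and still predicts.

## Known limitations

The engine is CPU-only and unpolarized, with no fluorescence or
time-resolved transport. Probe–tissue coupling (air gap assumed) and fiber
spacing (0.66 mm assumed) are undocumented hardware details exposed as
parameters. The plexus geometry beyond its 2-mm thickness is invented and
flagged as such. Synthetic chromophores reproduce feature wavelengths, not
true extinction line shapes, so absolute simulated ratios should not be
compared against the study's measured ratio tables — only orderings and
trends are meaningful, and those are what the acceptance criteria assert.

One directional property is known to be marginal rather than robust in
this synthetic family: in the plexus depth study, the VIS/NIR band's
contrast is expected to decay faster with muscle-cover depth than the
SWIR band's (deep structures being a SWIR specialty). The heme-family
shapes carry only a weak NIR tail, so the two bands end up with nearly
equal sensing depths here, and the band-decay asymmetry — while present in
expectation across seeds — is comparable to the Monte Carlo uncertainty of
a single run at the documented photon budget. The corresponding acceptance
assertion is kept at its stated conditions and can fail for individual
seeds; resolving it per run would take roughly twenty times the photon
budget. The companion claims (a shallow plexus perturbs VIS/NIR more than
SWIR; both bands' contrast decays monotonically with depth) are robust.
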