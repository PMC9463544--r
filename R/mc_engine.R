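#' Seven-fiber contact probe geometry
#'
#' One central illumination fiber with six identical collection fibers on a
#' regular hexagon around it. Defaults describe the physical probe: 600-um
#' core (0.3-mm radius), NA 0.39, and a 0.66-mm center-to-center spacing
#' (core plus a nominal cladding/buffer allowance; the spacing is
#' configurable because only the core size and NA are published).
#'
#' @param core_radius_mm Fiber core radius (mm).
#' @param na Numerical aperture in air, in (0, 1); gates both the launch
#'   cone and the detection acceptance cone.
#' @param spacing_mm Source-to-detector center spacing (mm,
#'   `>= 2 * core_radius_mm` so fibers do not overlap).
#' @param n_detectors Number of ring detectors (default 6).
#' @return An `ewdrs_probe`.
#' @export
probe_geometry <- function(core_radius_mm = 0.3, na = 0.39,
                           spacing_mm = 0.66, n_detectors = 6L) {
  stopifnot(core_radius_mm > 0, n_detectors >= 1)
  if (na <= 0 || na >= 1) stop_ewdrs("NA must be in (0, 1)", "ewdrs_parameter")
  if (spacing_mm < 2 * core_radius_mm)
    stop_ewdrs("fibers overlap: spacing must be >= 2 * core radius",
               "ewdrs_parameter")
  structure(list(core_radius_mm = core_radius_mm, na = na,
                 spacing_mm = spacing_mm, n_detectors = as.integer(n_detectors)),
            class = "ewdrs_probe")
}

#' Elementary transport kernels
#'
#' The closed-form sampling and boundary formulas the photon stepper is
#' built from, exported for direct verification:
#' * `sample_free_path(mu_t, u) = -log(u) / mu_t` (mm), the exponential
#'   free-path inverse CDF.
#' * `sample_hg_deflection(g, u)`: inverse-CDF sample of the
#'   Henyey-Greenstein deflection cosine (`2u - 1` for g = 0).
#' * `fresnel_unpolarized(n_i, n_t, cos_theta_i)`: mean of s- and
#'   p-polarized Fresnel reflectances, 1 beyond the critical angle.
#'
#' @param mu_t Total interaction coefficient (mm^-1, `> 0`).
#' @param u Uniform(0,1) variates.
#' @param g Anisotropy, `|g| < 1`.
#' @param n_i,n_t Refractive indices on the incident / transmitted side.
#' @param cos_theta_i Incidence-angle cosine in (0, 1].
#' @return Numeric vector matching `u` (or `cos_theta_i`).
#' @name transport_kernels
NULL

#' @rdname transport_kernels
#' @export
sample_free_path <- function(mu_t, u) {
  if (any(mu_t <= 0)) stop_ewdrs("mu_t must be positive", "ewdrs_parameter")
  stopifnot(all(u > 0 & u < 1))
  k <- max(length(mu_t), length(u))
  sample_free_path_cpp(rep_len(as.double(mu_t), k), rep_len(as.double(u), k))
}

#' @rdname transport_kernels
#' @export
sample_hg_deflection <- function(g, u) {
  if (abs(g) >= 1) stop_ewdrs("|g| must be < 1", "ewdrs_parameter")
  stopifnot(all(u >= 0 & u <= 1))
  sample_hg_cpp(g, as.double(u))
}

#' @rdname transport_kernels
#' @export
fresnel_unpolarized <- function(n_i, n_t, cos_theta_i) {
  stopifnot(n_i > 0, n_t > 0, all(cos_theta_i > 0 & cos_theta_i <= 1))
  fresnel_unpolarized_cpp(n_i, n_t, as.double(cos_theta_i))
}

# Dispatch a single-wavelength run to the compiled stepper.
mc_run <- function(model, probe, wavelength_nm, n_photons, seed,
                   ring_edges = numeric(0), w_min = 1e-4, p_survive = 0.1,
                   max_steps = 4e6, n_external = 1.0) {
  stopifnot(inherits(probe, "ewdrs_probe"), n_photons >= 1)
  if (inherits(model, "ewdrs_layered_model")) {
    props <- lapply(model$layers, function(l)
      props_at_wavelength(l$material, wavelength_nm))
    raw <- mc_run_layered_cpp(
      z_bot = model$interfaces_mm,
      mua = vapply(props, `[[`, 0, "mu_a"),
      mus = vapply(props, `[[`, 0, "mu_s"),
      gg = vapply(props, `[[`, 0, "g"),
      nn = vapply(props, `[[`, 0, "n"),
      probe = unclass(probe), n_photons = as.integer(n_photons),
      seed = as.double(seed), ring_edges = as.double(ring_edges),
      w_min = w_min, p_survive = p_survive, max_steps = max_steps,
      n_ext = n_external)
  } else if (inherits(model, "ewdrs_voxel_model")) {
    props <- lapply(model$materials, props_at_wavelength, nm = wavelength_nm)
    raw <- mc_run_voxel_cpp(
      grid = as.integer(model$grid) - 1L, dim(model$grid), model$voxel_mm,
      mua = vapply(props, `[[`, 0, "mu_a"),
      mus = vapply(props, `[[`, 0, "mu_s"),
      gg = vapply(props, `[[`, 0, "g"),
      n_in = props[[1L]]$n,
      probe = unclass(probe), n_photons = as.integer(n_photons),
      seed = as.double(seed), ring_edges = as.double(ring_edges),
      w_min = w_min, p_survive = p_survive, max_steps = max_steps,
      n_ext = n_external)
  } else {
    stop_ewdrs("model must be layered or voxel", "ewdrs_parameter")
  }
  structure(raw, class = "ewdrs_detection_result")
}

#' Trace a single photon packet
#'
#' Convenience wrapper launching one packet and reporting its terminal
#' event. Under continuous absorption weighting a packet sheds weight along
#' its path rather than dying at an absorption site, so the terminal event
#' is where the residual packet ended: collected by a detector, escaped
#' the top surface undetected, transmitted through the bottom, or
#' terminated by Russian roulette; the `weights` field carries the full
#' ledger of the trace.
#'
#' @inheritParams simulate_detected_reflectance
#' @return List with `event` (one of `"detected"`, `"escaped_undetected"`,
#'   `"transmitted"`, `"roulette"`), `detector` (index 1-6 or `NA`), and
#'   `weights` (the single-packet detection result).
#' @export
trace_photon <- function(model, probe, wavelength_nm, seed, ...) {
  r <- mc_run(model, probe, wavelength_nm, n_photons = 1L, seed = seed, ...)
  det <- which(r$detector_fractions > 0)
  event <- if (length(det)) "detected"
    else if (r$diffuse_reflectance > 0) "escaped_undetected"
    else if (r$transmittance > 0) "transmitted"
    else "roulette"
  list(event = event, detector = if (length(det)) det[1L] else NA_integer_,
       weights = r)
}

#' Simulate detected reflectance at one wavelength
#'
#' Traces weighted photon packets from the source fiber through the model
#' and tallies the fraction of launched weight collected by each of the six
#' ring fibers (exit inside a detector core, refracted exit direction within
#' the acceptance cone), alongside a full weight ledger: specular
#' reflection, total diffuse reflectance, transmittance, absorbed fraction,
#' and Russian-roulette net loss. The ledger sums to 1 within 1e-6 on every
#' run. Identical `(model, probe, n_photons, seed)` give bit-identical
#' results; photon substreams are derived by counter so the result does not
#' depend on R's RNG state.
#'
#' @param model A [layered_model()] or [voxel_model()].
#' @param probe A [probe_geometry()].
#' @param wavelength_nm Wavelength at which material properties are
#'   interpolated.
#' @param n_photons Photon packets to launch.
#' @param seed Master seed (non-negative integer).
#' @param ring_edges Optional ascending radii (mm); when given, escaping
#'   weight is also tallied into the annuli they bound (field
#'   `ring_weights`), ungated by the fiber optics — used for
#'   diffusion-theory cross-checks.
#' @param w_min,p_survive Russian-roulette threshold and survival
#'   probability (defaults 1e-4 and 0.1). Roulette is booked as the *net*
#'   ledger change (terminated weight minus survivor amplification), so the
#'   ledger is exact per run and the roulette entry averages to zero.
#' @param max_steps Safety cap on interaction events per photon; capped
#'   weight is booked to the roulette entry. Only reachable in effectively
#'   non-absorbing media.
#' @param n_external Refractive index above the surface (air, 1.0).
#' @return An `ewdrs_detection_result`: `detector_fractions` (6),
#'   `detector_se`, `specular`, `diffuse_reflectance`, `transmittance`,
#'   `absorbed`, `roulette_lost`, `n_photons`, `seed` and optionally
#'   `ring_weights`.
#' @export
simulate_detected_reflectance <- function(model, probe, wavelength_nm,
                                          n_photons, seed,
                                          ring_edges = numeric(0),
                                          w_min = 1e-4, p_survive = 0.1,
                                          max_steps = 4e6, n_external = 1.0) {
  mc_run(model, probe, wavelength_nm, n_photons, seed, ring_edges,
         w_min, p_survive, max_steps, n_external)
}

#' @export
print.ewdrs_detection_result <- function(x, ...) {
  cat(sprintf(paste0("<detection result> %d photons, seed %g\n",
                     "  detected (6 fibers): %.3e total\n",
                     "  specular %.4f | diffuse %.4f | transmitted %.4f | absorbed %.4f\n"),
              x$n_photons, x$seed, sum(x$detector_fractions),
              x$specular, x$diffuse_reflectance, x$transmittance, x$absorbed))
  invisible(x)
}

#' Ledger total of a detection result
#'
#' @param result An `ewdrs_detection_result`.
#' @return `specular + diffuse + transmitted + absorbed + roulette`, equal to
#'   1 within 1e-6 by construction.
#' @export
ledger_total <- function(result) {
  result$specular + result$diffuse_reflectance + result$transmittance +
    result$absorbed + result$roulette_lost
}

#' Simulate an EWDRS spectrum
#'
#' Runs [simulate_detected_reflectance()] at every wavelength of `grid_nm`,
#' deriving one independent substream per wavelength from the master seed,
#' keyed by the wavelength value itself
#' (`derive_seed(seed, 1000 * wavelength)`), and returns the summed
#' six-fiber detected fraction as a `merged`-band spectrum. Using one master
#' seed across several models gives common random numbers per wavelength —
#' even across different grids that share wavelengths — which cancels Monte
#' Carlo noise in model-to-model comparisons.
#'
#' @inheritParams simulate_detected_reflectance
#' @param grid_nm Ascending simulation wavelengths (nm) covered by every
#'   material property grid.
#' @param n_photons_per_wavelength Photons per wavelength.
#' @param ... Passed to [simulate_detected_reflectance()].
#' @return An `ewdrs_simulated_spectrum`: `spectrum` (sum of the six
#'   fibers), `per_detector` (matrix wavelength x 6), `per_detector_se`,
#'   `results` (per-wavelength detection results), `seed`.
#' @export
simulate_spectrum <- function(model, probe, grid_nm, n_photons_per_wavelength,
                              seed, ...) {
  stopifnot(all(diff(grid_nm) > 0))
  results <- vector("list", length(grid_nm))
  per_det <- matrix(0, length(grid_nm), probe$n_detectors)
  per_se <- per_det
  for (i in seq_along(grid_nm)) {
    r <- mc_run(model, probe, grid_nm[i], n_photons_per_wavelength,
                seed = derive_seed(seed, round(1000 * grid_nm[i])), ...)
    results[[i]] <- r
    per_det[i, ] <- r$detector_fractions
    per_se[i, ] <- r$detector_se
  }
  structure(list(spectrum = spectrum(grid_nm, rowSums(per_det), "merged"),
                 per_detector = per_det, per_detector_se = per_se,
                 results = results, seed = seed),
            class = "ewdrs_simulated_spectrum")
}

#' @export
print.ewdrs_simulated_spectrum <- function(x, ...) {
  cat(sprintf("<simulated spectrum> %d wavelengths, %d photons each, seed %g\n",
              length(x$spectrum$wavelengths_nm), x$results[[1L]]$n_photons, x$seed))
  invisible(x)
}

#' Steady-state diffusion-approximation reflectance (dipole oracle)
#'
#' Closed-form spatially resolved diffuse reflectance `R(rho)` from a
#' semi-infinite medium: an isotropic point source at depth
#' `z0 = 1/(mu_a + mu_s')` and its image above the extrapolated boundary at
#' `-z0 - 2*zb`, with `zb = 2*A*D` and the Groenhuis internal-reflection
#' parameter `A` for the relative index. The exitance is evaluated from the
#' boundary radiance — `R = C_phi * fluence + C_j * flux`, with the two
#' Fresnel angular moments integrated numerically — rather than from the
#' normal flux alone, which is known to misallocate light between near and
#' far field under index-mismatched boundaries. Valid in the diffusive
#' regime (`mu_s' >> mu_a`); a warning is emitted when `mu_s'/mu_a < 10`.
#' Serves as an independent analytic cross-check of the Monte Carlo engine,
#' not as a measurement model.
#'
#' @param mu_a Absorption coefficient (mm^-1).
#' @param mu_s_prime Reduced scattering coefficient (mm^-1).
#' @param n_rel Tissue-to-outside relative refractive index (e.g. 1.34).
#' @param rho_mm Radial source-detector distances (mm).
#' @return Reflectance per unit area (mm^-2) at each `rho_mm`.
#' @export
diffusion_reflectance_oracle <- function(mu_a, mu_s_prime, n_rel, rho_mm) {
  stopifnot(mu_a > 0, mu_s_prime > 0, n_rel > 0)
  if (mu_s_prime / mu_a < 10)
    warning("outside the diffusive regime (mu_s'/mu_a < 10); oracle unreliable")
  mu_tr <- mu_a + mu_s_prime
  D <- 1 / (3 * mu_tr)
  mu_eff <- sqrt(3 * mu_a * mu_tr)
  r_d <- -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
  A <- (1 + r_d) / (1 - r_d)
  z0 <- 1 / mu_tr
  zb <- 2 * A * D
  # Fresnel angular moments of the escape probability (internal -> outside)
  transm <- function(ct) 1 - fresnel_unpolarized_cpp(n_rel, 1, ct)
  c_phi <- 0.5 * stats::integrate(function(ct) transm(ct) * ct, 0, 1,
                                  rel.tol = 1e-8)$value
  c_j <- 1.5 * stats::integrate(function(ct) transm(ct) * ct^2, 0, 1,
                                rel.tol = 1e-8)$value
  r1 <- sqrt(z0^2 + rho_mm^2)
  r2 <- sqrt((z0 + 2 * zb)^2 + rho_mm^2)
  fluence <- (exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D)
  flux <- (z0 * (mu_eff + 1 / r1) * exp(-mu_eff * r1) / r1^2 +
             (z0 + 2 * zb) * (mu_eff + 1 / r2) * exp(-mu_eff * r2) / r2^2) / (4 * pi)
  c_phi * fluence + c_j * flux
}
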