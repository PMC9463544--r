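#' Area-under-the-curve normalization
#'
#' Rescales a spectrum so its trapezoid-rule integral over the wavelength
#' grid equals 1. Both simulated and measured spectra are normalized this
#' way before comparison, removing the arbitrary scale difference between
#' simulation units and referenced measurement units.
#'
#' @param s An [spectrum()].
#' @return The normalized spectrum (same grid and band).
#' @export
auc_normalize <- function(s) {
  stopifnot(is_spectrum(s))
  area <- trapz(s$wavelengths_nm, s$values)
  if (!(area > 0))
    stop_ewdrs("spectrum integral must be positive", "ewdrs_normalization")
  spectrum(s$wavelengths_nm, s$values / area, s$band)
}

#' Pointwise confidence band of repeated measurements
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) of
#' repeat spectra on a common grid, with band `mean -/+ z * SD`; z = 1.96
#' gives the 95% interval used to judge simulation agreement.
#'
#' @param repeats List of at least two spectra on one common grid (resample
#'   first if needed).
#' @param z Band half-width in SD units (default 1.96).
#' @return An `ewdrs_confidence_band` with `wavelengths_nm`, `mean`, `sd`,
#'   `lower`, `upper`, `z`, `n_repeats`.
#' @export
confidence_band <- function(repeats, z = 1.96) {
  stopifnot(all(vapply(repeats, is_spectrum, TRUE)), z >= 0)
  if (length(repeats) < 2L)
    stop_ewdrs("need at least two repeats", "ewdrs_insufficient_data")
  grid <- repeats[[1L]]$wavelengths_nm
  for (r in repeats[-1L])
    if (!identical(r$wavelengths_nm, grid))
      stop_ewdrs("repeats must share one grid; resample first",
                 "ewdrs_grid_mismatch")
  m <- vapply(repeats, function(r) r$values, grid)
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, sd)
  structure(list(wavelengths_nm = grid, mean = mu, sd = sdev,
                 lower = mu - z * sdev, upper = mu + z * sdev,
                 z = z, n_repeats = length(repeats)),
            class = "ewdrs_confidence_band")
}

#' Simulation-versus-measurement agreement report
#'
#' Difference spectrum (simulation minus measurement mean), a pointwise
#' out-of-band mask where the simulated value leaves the confidence band,
#' and the contiguous out-of-band wavelength intervals. Gaps of a single
#' in-band grid point are not bridged: intervals are maximal runs of the
#' mask.
#'
#' @param simulated Simulated spectrum on the band's grid (both AUC
#'   normalized upstream).
#' @param band An [confidence_band()].
#' @return An `ewdrs_agreement`: `difference` spectrum, logical
#'   `out_of_band` mask, and `intervals` (two-column matrix of nm start/end).
#' @export
agreement <- function(simulated, band) {
  stopifnot(is_spectrum(simulated), inherits(band, "ewdrs_confidence_band"))
  if (!identical(simulated$wavelengths_nm, band$wavelengths_nm))
    stop_ewdrs("simulated spectrum must be on the band grid; resample first",
               "ewdrs_resample_required")
  diff_vals <- simulated$values - band$mean
  mask <- simulated$values < band$lower | simulated$values > band$upper
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  intervals <- cbind(start_nm = band$wavelengths_nm[starts[keep]],
                     end_nm = band$wavelengths_nm[ends[keep]])
  structure(list(difference = spectrum(simulated$wavelengths_nm, diff_vals,
                                       simulated$band),
                 out_of_band = mask, intervals = intervals),
            class = "ewdrs_agreement")
}

#' Diagnostic peak ratios
#'
#' Ratio of linearly interpolated intensities at two wavelengths. The
#' platform's presets are the blood-related VIS/NIR ratio (575/610 nm), the
#' lipid-related SWIR ratio (1210/1270 nm), and a phantom variant
#' (630/700 nm) for the muscle phantom whose heme-mimicking dye absorbs at
#' 630 nm rather than at the haemoglobin doublet.
#'
#' @param s An [spectrum()] spanning both wavelengths.
#' @param numerator_nm,denominator_nm Wavelengths (nm).
#' @return A scalar ratio.
#' @export
peak_ratio <- function(s, numerator_nm, denominator_nm) {
  num <- spectrum_value_at(s, numerator_nm)
  den <- spectrum_value_at(s, denominator_nm)
  if (den <= 0)
    stop_ewdrs("denominator intensity must be positive", "ewdrs_ratio")
  num / den
}

#' @rdname peak_ratio
#' @export
peak_ratio_visnir <- function(s) peak_ratio(s, 575, 610)

#' @rdname peak_ratio
#' @export
peak_ratio_swir <- function(s) peak_ratio(s, 1210, 1270)

#' @rdname peak_ratio
#' @export
peak_ratio_phantom_vis <- function(s) peak_ratio(s, 630, 700)

#' Trend of a ratio across layer thicknesses
#'
#' Reports the sign of the Spearman rank trend of ratio versus thickness
#' and whether the sequence is strictly monotone.
#'
#' @param ratios_by_thickness Named numeric vector; names are thicknesses
#'   (mm), at least 3 points.
#' @return List with `direction` (`"positive"`, `"negative"`, or `"flat"`)
#'   and `is_monotonic`.
#' @export
ratio_trend <- function(ratios_by_thickness) {
  stopifnot(length(ratios_by_thickness) >= 3L)
  th <- as.numeric(names(ratios_by_thickness))
  stopifnot(!any(is.na(th)))
  o <- order(th)
  r <- ratios_by_thickness[o]
  rho <- suppressWarnings(stats::cor(th[o], r, method = "spearman"))
  d <- diff(r)
  list(direction = if (is.na(rho) || rho == 0) "flat"
                   else if (rho > 0) "positive" else "negative",
       is_monotonic = all(d > 0) || all(d < 0))
}

#' Depth of a spectral dip against a linear baseline
#'
#' Interpolates a straight baseline between two flanking wavelengths and
#' returns baseline minus spectrum at the dip center (positive values mean
#' an absorption dip). Used, e.g., to quantify how much of a buried layer's
#' 630-nm feature survives a given cover thickness.
#'
#' @param s An [spectrum()].
#' @param center_nm Dip wavelength.
#' @param left_nm,right_nm Flanking baseline wavelengths.
#' @return Scalar dip depth in the spectrum's intensity units.
#' @export
dip_depth <- function(s, center_nm, left_nm, right_nm) {
  stopifnot(left_nm < center_nm, center_nm < right_nm)
  yl <- spectrum_value_at(s, left_nm)
  yr <- spectrum_value_at(s, right_nm)
  base <- yl + (yr - yl) * (center_nm - left_nm) / (right_nm - left_nm)
  base - spectrum_value_at(s, center_nm)
}
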