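#' Construct a spectrum
#'
#' A spectrum is an intensity trace on a strictly ascending wavelength grid
#' with a band tag. The platform acquires two bands with separate
#' spectrometers — VIS/NIR (500 to 1000 nm) and SWIR (1000 to 1500 nm) — and
#' joins them into a `merged` spectrum spanning 500 to 1500 nm.
#'
#' @param wavelengths_nm Strictly increasing numeric wavelength grid (nm).
#' @param values Numeric intensities, one per wavelength (arbitrary units).
#' @param band One of `"visnir"`, `"swir"`, `"merged"`. The grid must lie
#'   within the band's nominal range (VIS/NIR 500-1000 nm, SWIR 1000-1500 nm,
#'   merged 500-1500 nm).
#' @return An object of class `ewdrs_spectrum` with fields `wavelengths_nm`,
#'   `values`, and `band`.
#' @examples
#' s <- spectrum(seq(500, 1000, 5), rep(1, 101), "visnir")
#' print(s)
#' @export
spectrum <- function(wavelengths_nm, values, band = c("merged", "visnir", "swir")) {
  band <- match.arg(band)
  wavelengths_nm <- as.double(wavelengths_nm)
  values <- as.double(values)
  if (length(wavelengths_nm) < 1L || length(values) != length(wavelengths_nm))
    stop_ewdrs("values must have the same length as the wavelength grid",
               "ewdrs_grid_mismatch")
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0))
    stop_ewdrs("wavelength grid must be finite and strictly increasing",
               "ewdrs_invalid_grid")
  if (any(!is.finite(values)))
    stop_ewdrs("all spectrum values must be finite", "ewdrs_invalid_values")
  rng <- switch(band, visnir = c(500, 1000), swir = c(1000, 1500),
                merged = c(500, 1500))
  if (wavelengths_nm[1L] < rng[1L] || wavelengths_nm[length(wavelengths_nm)] > rng[2L])
    stop_ewdrs(sprintf("band '%s' grid must lie within [%g, %g] nm",
                       band, rng[1L], rng[2L]), "ewdrs_band_range")
  structure(list(wavelengths_nm = wavelengths_nm, values = values, band = band),
            class = "ewdrs_spectrum")
}

#' @export
print.ewdrs_spectrum <- function(x, ...) {
  cat(sprintf("<ewdrs spectrum> band=%s, %d points, %g-%g nm\n",
              x$band, length(x$wavelengths_nm),
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' @export
as.data.frame.ewdrs_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, value = x$values)
}

is_spectrum <- function(x) inherits(x, "ewdrs_spectrum")

#' Linear interpolation of a spectrum at arbitrary wavelengths
#'
#' @param s An [spectrum()].
#' @param nm Wavelengths (nm) inside the grid span.
#' @return Interpolated intensities.
#' @export
spectrum_value_at <- function(s, nm) {
  stopifnot(is_spectrum(s))
  if (any(nm < s$wavelengths_nm[1L] | nm > max(s$wavelengths_nm)))
    stop_ewdrs("requested wavelength outside the spectrum span", "ewdrs_range")
  approx(s$wavelengths_nm, s$values, xout = nm)$y
}

#' Bundle a raw measurement with its background and reflectance standard
#'
#' Each acquisition set consists of the raw sample measurement `Mraw`, a
#' shuttered background `Bg`, and a measurement of a 99% reflectance standard
#' `Mstd`, all on one spectrometer grid. Referencing divides the
#' background-subtracted sample signal by the background-subtracted standard
#' signal, cancelling the lamp spectrum and the spectrometer response.
#'
#' @param m_raw,bg,m_std Spectra on an identical grid with an identical band
#'   tag.
#' @return An `ewdrs_triplet`.
#' @export
reference_triplet <- function(m_raw, bg, m_std) {
  stopifnot(is_spectrum(m_raw), is_spectrum(bg), is_spectrum(m_std))
  if (!identical(m_raw$wavelengths_nm, bg$wavelengths_nm) ||
      !identical(m_raw$wavelengths_nm, m_std$wavelengths_nm) ||
      m_raw$band != bg$band || m_raw$band != m_std$band)
    stop_ewdrs("triplet members must share one wavelength grid and band",
               "ewdrs_grid_mismatch")
  if (any(m_std$values - bg$values <= 0))
    stop_ewdrs("reflectance standard must exceed background everywhere",
               "ewdrs_invalid_reference")
  structure(list(m_raw = m_raw, bg = bg, m_std = m_std),
            class = "ewdrs_triplet")
}

#' Reference a measurement against the reflectance standard
#'
#' Computes `(Mraw - Bg) / (Mstd - Bg)` pointwise. The result is in arbitrary
#' units and may legitimately exceed 1 because the standard is used in a
#' contact-probe geometry rather than a calibrated non-contact one.
#'
#' @param triplet A [reference_triplet()].
#' @return The referenced spectrum on the same grid and band.
#' @export
reference_spectrum <- function(triplet) {
  stopifnot(inherits(triplet, "ewdrs_triplet"))
  denom <- triplet$m_std$values - triplet$bg$values
  vals <- (triplet$m_raw$values - triplet$bg$values) / denom
  spectrum(triplet$m_raw$wavelengths_nm, vals, triplet$m_raw$band)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing; the platform default (order 2,
#' window 41) is applied to SWIR spectra to suppress detector noise. Edge
#' points are handled by evaluating the polynomial fit of the first/last full
#' window at the edge positions, so polynomials up to `poly_order` are
#' reproduced exactly everywhere, including the spectrum ends.
#'
#' @param s An [spectrum()].
#' @param poly_order Polynomial order (default 2).
#' @param window Odd window length, `> poly_order` and no longer than the
#'   grid (default 41).
#' @return A smoothed spectrum on the same grid.
#' @export
savitzky_golay <- function(s, poly_order = 2L, window = 41L) {
  stopifnot(is_spectrum(s))
  if (window %% 2 == 0 || window <= poly_order)
    stop_ewdrs("window must be odd and greater than poly_order",
               "ewdrs_parameter")
  if (window > length(s$values))
    stop_ewdrs("window longer than the spectrum", "ewdrs_parameter")
  vals <- as.numeric(signal::sgolayfilt(s$values, p = poly_order, n = window))
  spectrum(s$wavelengths_nm, vals, s$band)
}

#' Matching factor between the two spectrometer bands
#'
#' The two spectrometers meet at 1000 nm; the scalar matching factor
#' `M = I_VIS/NIR(1000) / I_SWIR(1000)` rescales one band so the merged
#' spectrum is continuous at the junction. Intensities at non-grid match
#' points are obtained by linear interpolation.
#'
#' @param visnir,swir Spectra whose grids both cover `match_nm`.
#' @param match_nm Junction wavelength (default 1000 nm).
#' @return An `ewdrs_match` with fields `factor`, `i_visnir`, `i_swir`,
#'   `match_nm`.
#' @export
matching_factor <- function(visnir, swir, match_nm = 1000) {
  i_vis <- spectrum_value_at(visnir, match_nm)
  i_swir <- spectrum_value_at(swir, match_nm)
  if (i_swir <= 0)
    stop_ewdrs("SWIR intensity at the match point must be positive",
               "ewdrs_degenerate_match")
  structure(list(factor = i_vis / i_swir, i_visnir = i_vis, i_swir = i_swir,
                 match_nm = match_nm),
            class = "ewdrs_match")
}

#' Merge the VIS/NIR and SWIR bands into one spectrum
#'
#' Keeps the VIS/NIR points below the match point unscaled, multiplies the
#' SWIR band by the matching factor, and concatenates. Overlapping points
#' (VIS/NIR at or above the junction, SWIR below it) are dropped so the
#' merged grid is single-valued; by construction the two sides agree at the
#' junction to within floating-point round-off.
#'
#' @param visnir Spectrum tagged `visnir`.
#' @param swir Spectrum tagged `swir`.
#' @param match Optional [matching_factor()] result; computed from the inputs
#'   when omitted.
#' @return A `merged` spectrum covering both bands.
#' @export
merge_bands <- function(visnir, swir, match = NULL) {
  stopifnot(is_spectrum(visnir), is_spectrum(swir))
  if (visnir$band != "visnir" || swir$band != "swir")
    stop_ewdrs("merge_bands expects a visnir and a swir spectrum",
               "ewdrs_parameter")
  if (is.null(match)) match <- matching_factor(visnir, swir)
  keep_v <- visnir$wavelengths_nm < match$match_nm
  keep_s <- swir$wavelengths_nm >= match$match_nm
  spectrum(c(visnir$wavelengths_nm[keep_v], swir$wavelengths_nm[keep_s]),
           c(visnir$values[keep_v], match$factor * swir$values[keep_s]),
           "merged")
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; extrapolation beyond the original span is refused.
#'
#' @param s An [spectrum()].
#' @param new_grid Ascending wavelengths inside the span of `s`.
#' @return The resampled spectrum (same band tag).
#' @export
resample <- function(s, new_grid) {
  stopifnot(is_spectrum(s))
  spectrum(new_grid, spectrum_value_at(s, new_grid), s$band)
}

#' Read / write the two-column spectrum CSV dialect
#'
#' Plain CSV with header `wavelength_nm,value` and an optional
#' `# band=visnir|swir|merged` comment line.
#'
#' @param path File path.
#' @param band Band tag used when the file carries no band comment.
#' @return [read_spectrum_csv()] returns a spectrum; [write_spectrum_csv()]
#'   returns the path invisibly.
#' @export
read_spectrum_csv <- function(path, band = "merged") {
  lines <- readLines(path)
  band_line <- grep("^#\\s*band=", lines, value = TRUE)
  if (length(band_line))
    band <- sub("^#\\s*band=", "", band_line[1L])
  d <- read.csv(text = lines[!startsWith(lines, "#")])
  spectrum(d$wavelength_nm, d$value, band)
}

#' @rdname read_spectrum_csv
#' @param s Spectrum to write.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# band=%s", s$band), "wavelength_nm,value",
               sprintf("%.10g,%.10g", s$wavelengths_nm, s$values)),
             con, sep = "\n")
  invisible(path)
}
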