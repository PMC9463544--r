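#' Optical properties of a material across the platform wavelength range
#'
#' Per-wavelength absorption and reduced scattering coefficients plus scalar
#' anisotropy and refractive index. Defaults g = 0.9 and n = 1.34 are used
#' for every tissue and phantom material unless overridden.
#'
#' @param wavelengths_nm Ascending wavelength grid (nm).
#' @param mu_a Absorption coefficient per wavelength (mm^-1, `>= 0`).
#' @param mu_s_prime Reduced scattering coefficient per wavelength
#'   (mm^-1, `> 0`).
#' @param g Scattering anisotropy, in (-1, 1).
#' @param n Refractive index, `>= 1`.
#' @param name Optional material name used in printing and model manifests.
#' @return An `ewdrs_optical_properties` object.
#' @export
optical_properties <- function(wavelengths_nm, mu_a, mu_s_prime,
                               g = 0.9, n = 1.34, name = "material") {
  wavelengths_nm <- as.double(wavelengths_nm)
  stopifnot(length(mu_a) == length(wavelengths_nm),
            length(mu_s_prime) == length(wavelengths_nm),
            all(diff(wavelengths_nm) > 0))
  if (any(mu_a < 0)) stop_ewdrs("mu_a must be >= 0", "ewdrs_parameter")
  if (any(mu_s_prime <= 0)) stop_ewdrs("mu_s_prime must be > 0", "ewdrs_parameter")
  if (abs(g) >= 1) stop_ewdrs("anisotropy g must be in (-1, 1)", "ewdrs_parameter")
  if (n < 1) stop_ewdrs("refractive index must be at least 1", "ewdrs_parameter")
  structure(list(wavelengths_nm = wavelengths_nm, mu_a = as.double(mu_a),
                 mu_s_prime = as.double(mu_s_prime), g = g, n = n, name = name),
            class = "ewdrs_optical_properties")
}

#' @export
print.ewdrs_optical_properties <- function(x, ...) {
  cat(sprintf("<optical properties '%s'> %d wavelengths %g-%g nm, g=%g, n=%g\n",
              x$name, length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$g, x$n))
  invisible(x)
}

is_optical_properties <- function(x) inherits(x, "ewdrs_optical_properties")

#' Fit a first-order exponential decay to a reduced scattering spectrum
#'
#' Models `mu_s'(lambda) = a * exp(-lambda / b) + c` by nonlinear least
#' squares, initialized from a log-linear regression of the offset-subtracted
#' samples. Constant input is handled as the degenerate `a -> 0` branch with
#' `c` equal to the sample mean.
#'
#' @param wavelengths_nm Wavelengths (nm), at least 4 points.
#' @param mu_s_prime_samples Positive reduced scattering samples (mm^-1).
#' @return An `ewdrs_scatter_fit` with fields `a` (mm^-1), `b` (nm), `c`
#'   (mm^-1), and `residual_rms` (mm^-1).
#' @export
fit_scattering_decay <- function(wavelengths_nm, mu_s_prime_samples) {
  x <- as.double(wavelengths_nm)
  y <- as.double(mu_s_prime_samples)
  stopifnot(length(x) == length(y))
  if (length(x) < 4L) stop_ewdrs("need at least 4 samples", "ewdrs_parameter")
  if (any(y <= 0)) stop_ewdrs("mu_s_prime samples must be positive", "ewdrs_parameter")

  if (diff(range(y)) < 1e-12 * max(y)) {
    return(structure(list(a = 0, b = Inf, c = mean(y), residual_rms = sd(y) %||% 0,
                          degenerate = TRUE),
                     class = "ewdrs_scatter_fit"))
  }
  # log-linear start: log(y - c0) ~ log(a) - x/b
  c0 <- max(0, min(y) * 0.9)
  yl <- log(pmax(y - c0, 1e-8))
  lf <- stats::lm(yl ~ x)
  b0 <- -1 / coef(lf)[[2L]]
  if (!is.finite(b0) || b0 <= 0) b0 <- diff(range(x))
  a0 <- exp(coef(lf)[[1L]])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-x / b) + c,
                      start = list(a = a0, b = b0, c = c0),
                      lower = c(1e-12, 1e-6, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    stop_ewdrs("exponential-decay fit failed to converge", "ewdrs_fit_failure")
  p <- coef(fit)
  res <- y - (p[["a"]] * exp(-x / p[["b"]]) + p[["c"]])
  structure(list(a = p[["a"]], b = p[["b"]], c = p[["c"]],
                 residual_rms = sqrt(mean(res^2)), degenerate = FALSE),
            class = "ewdrs_scatter_fit")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Evaluate a fitted scattering-decay model
#'
#' @param fit An [fit_scattering_decay()] result (or any list with `a`, `b`,
#'   `c`).
#' @param wavelengths_nm Wavelengths (nm).
#' @return `a * exp(-lambda/b) + c` (mm^-1).
#' @export
eval_scattering_decay <- function(fit, wavelengths_nm) {
  if (is.infinite(fit$b)) return(rep(fit$c, length(wavelengths_nm)))
  fit$a * exp(-wavelengths_nm / fit$b) + fit$c
}

#' Smooth the absorption spectrum of a material
#'
#' Applies the order-2 Savitzky-Golay filter to `mu_a` only, clamping any
#' negative excursions of the smoothed curve at zero. Scattering, anisotropy
#' and refractive index are untouched.
#'
#' @param props An [optical_properties()] object.
#' @param window,poly_order Filter settings (defaults 41 and 2).
#' @return New `ewdrs_optical_properties` with smoothed `mu_a`.
#' @export
smooth_absorption <- function(props, window = 41L, poly_order = 2L) {
  stopifnot(is_optical_properties(props))
  s <- spectrum(props$wavelengths_nm, props$mu_a, "merged")
  sm <- savitzky_golay(s, poly_order = poly_order, window = window)
  optical_properties(props$wavelengths_nm, pmax(sm$values, 0),
                     props$mu_s_prime, props$g, props$n, props$name)
}

#' Synthetic chromophore basis
#'
#' Unit-amplitude absorption shape functions over 500-1500 nm built from
#' Gaussian mixtures placed at the characteristic feature wavelengths of the
#' tissue chromophores the platform emulates:
#' \describe{
#'   \item{pseudo_lipid}{dip complex peaking at 1210 nm with an 1180-nm
#'     shoulder (fat in nerve, skin, and connective tissue).}
#'   \item{pseudo_water}{broad bands near 970 and 1450 nm.}
#'   \item{pseudo_heme_dye}{a single 630-nm band mimicking heme pigments /
#'     myoglobin-like absorbers and the red-green dye of the muscle phantom.}
#'   \item{pseudo_blood}{the dual 575/610-nm haemoglobin-like doublet.}
#' }
#' Both heme-family shapes carry a weak broad tail through 700-1000 nm
#' (a few percent of the main band), reflecting the residual absorption of
#' haemoglobin and myoglobin across the NIR window; without it,
#' pigment-bearing tissue would be unphysically transparent between the
#' visible bands and the SWIR.
#' These are stand-in line shapes, not measured extinction spectra: only the
#' feature wavelengths carry meaning.
#'
#' @return Named list of vectorized functions of wavelength (nm), each
#'   non-negative with unit maximum over 500-1500 nm.
#' @export
chromophore_basis <- function() {
  gmix <- function(centers, sigmas, amps) {
    grid <- 500:1500
    raw <- function(nm) {
      v <- 0
      for (i in seq_along(centers))
        v <- v + amps[i] * exp(-((nm - centers[i]) / sigmas[i])^2 / 2)
      v
    }
    peak <- max(raw(grid))
    function(nm) raw(nm) / peak
  }
  list(
    pseudo_lipid   = gmix(c(1210, 1180), c(14, 9), c(1, 0.5)),
    pseudo_water   = gmix(c(970, 1450), c(45, 60), c(0.35, 1)),
    pseudo_heme_dye = gmix(c(630, 830), c(28, 150), c(1, 0.07)),
    pseudo_blood   = gmix(c(575, 610, 830), c(12, 11, 150), c(1, 0.85, 0.07))
  )
}

#' Build an absorption spectrum from chromophore weights
#'
#' Non-negative linear combination of the [chromophore_basis()] shapes.
#'
#' @param concentrations Named non-negative weights (mm^-1 at each
#'   chromophore's unit-maximum wavelength); names must exist in `basis`.
#' @param grid Wavelength grid (nm).
#' @param basis Chromophore basis (default [chromophore_basis()]).
#' @return Numeric `mu_a` (mm^-1) on `grid`.
#' @export
synth_mu_a <- function(concentrations, grid, basis = chromophore_basis()) {
  if (any(concentrations < 0))
    stop_ewdrs("chromophore weights must be >= 0", "ewdrs_parameter")
  unknown <- setdiff(names(concentrations), names(basis))
  if (length(unknown))
    stop_ewdrs(paste("unknown chromophore:", paste(unknown, collapse = ", ")),
               "ewdrs_unknown_key")
  mu_a <- rep(0, length(grid))
  for (nm in names(concentrations))
    mu_a <- mu_a + concentrations[[nm]] * basis[[nm]](grid)
  mu_a
}

#' Recover the scattering coefficient from its reduced form
#'
#' The similarity relation `mu_s = mu_s' / (1 - g)` converts the reduced
#' scattering coefficient (what integrating-sphere inversions report) into
#' the scattering coefficient the transport engine steps with.
#'
#' @param mu_s_prime Reduced scattering coefficient (mm^-1).
#' @param g Anisotropy, `< 1`.
#' @return `mu_s` (mm^-1).
#' @export
mu_s_from_reduced <- function(mu_s_prime, g) {
  if (any(g >= 1)) stop_ewdrs("anisotropy must be < 1", "ewdrs_parameter")
  mu_s_prime / (1 - g)
}

#' Read / write the optical-properties CSV dialect
#'
#' Columns `wavelength_nm,mu_a_mm-1,mu_s_prime_mm-1` with `# g=` and `# n=`
#' comment lines.
#'
#' @param path File path.
#' @return [read_properties_csv()] returns an [optical_properties()] object.
#' @export
read_properties_csv <- function(path) {
  lines <- readLines(path)
  get_scalar <- function(key, default) {
    ln <- grep(sprintf("^#\\s*%s=", key), lines, value = TRUE)
    if (length(ln)) as.numeric(sub(sprintf("^#\\s*%s=", key), "", ln[1L])) else default
  }
  nm_line <- grep("^#\\s*name=", lines, value = TRUE)
  d <- read.csv(text = lines[!startsWith(lines, "#")], check.names = FALSE)
  optical_properties(d[["wavelength_nm"]], d[["mu_a_mm-1"]], d[["mu_s_prime_mm-1"]],
                     g = get_scalar("g", 0.9), n = get_scalar("n", 1.34),
                     name = if (length(nm_line)) sub("^#\\s*name=", "", nm_line[1L])
                            else "material")
}

#' @rdname read_properties_csv
#' @param props Properties to write.
#' @export
write_properties_csv <- function(props, path) {
  stopifnot(is_optical_properties(props))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# name=%s", props$name),
               sprintf("# g=%g", props$g), sprintf("# n=%g", props$n),
               "wavelength_nm,mu_a_mm-1,mu_s_prime_mm-1",
               sprintf("%.10g,%.10g,%.10g", props$wavelengths_nm,
                       props$mu_a, props$mu_s_prime)),
             con, sep = "\n")
  invisible(path)
}

# Interpolate a material's transport coefficients at one wavelength.
props_at_wavelength <- function(material, nm) {
  stopifnot(is_optical_properties(material))
  if (nm < material$wavelengths_nm[1L] || nm > max(material$wavelengths_nm))
    stop_ewdrs("wavelength outside the material's property grid", "ewdrs_range")
  mu_a <- approx(material$wavelengths_nm, material$mu_a, xout = nm)$y
  mu_sp <- approx(material$wavelengths_nm, material$mu_s_prime, xout = nm)$y
  list(mu_a = mu_a, mu_s = mu_s_from_reduced(mu_sp, material$g),
       g = material$g, n = material$n)
}
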