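#' Construct an infrared spectrum
#'
#' The canonical in-memory representation: a uniform ascending wavenumber
#' grid (at most 600--4000 cm\eqn{^{-1}}) paired with an absorbance vector.
#'
#' @param wavenumbers ascending, uniformly spaced grid in cm\eqn{^{-1}}.
#' @param absorbance absorbance values, same length as `wavenumbers`.
#' @return an object of class `ir_spectrum` (list with `wavenumbers`,
#'   `absorbance`, `resolution`).
#' @export
ir_spectrum <- function(wavenumbers, absorbance) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) < 2) stop("a spectrum needs at least two points")
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance differ in length")
  d <- diff(wavenumbers)
  if (any(d <= 0)) stop("wavenumber grid must be strictly ascending")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("wavenumber grid must be uniform")
  if (min(wavenumbers) < 600 - 1e-9 || max(wavenumbers) > 4000 + 1e-9)
    stop("grid must lie within 600-4000 cm^-1")
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 resolution = mean(d)),
            class = "ir_spectrum")
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("IR spectrum: %d points, %.0f-%.0f cm^-1 at %.3g cm^-1 resolution\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
              x$resolution))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    all(abs(a$wavenumbers - b$wavenumbers) < 1e-9)
}

#' Define an absorption band
#'
#' @param center band centre in cm\eqn{^{-1}}.
#' @param fwhm full width at half maximum in cm\eqn{^{-1}} (> 0).
#' @param amplitude peak absorbance (>= 0).
#' @param shape Lorentzian fraction of the pseudo-Voigt profile in `[0, 1]`
#'   (0 = pure Gaussian, 1 = pure Lorentzian).
#' @param assignment free-text assignment label.
#' @return an object of class `ir_band`.
#' @export
band <- function(center, fwhm, amplitude, shape = 0.5, assignment = "") {
  if (fwhm <= 0) stop_domain("fwhm must be positive")
  if (amplitude < 0) stop_domain("amplitude must be non-negative")
  if (shape < 0 || shape > 1) stop_domain("shape must lie in [0, 1]")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 shape = shape, assignment = assignment),
            class = "ir_band")
}

# unit-height pseudo-Voigt profile
pseudo_voigt <- function(nu, center, fwhm, shape) {
  z <- (nu - center) / fwhm
  gauss <- exp(-4 * log(2) * z^2)
  lorentz <- 1 / (1 + 4 * z^2)
  shape * lorentz + (1 - shape) * gauss
}

#' Evaluate a set of bands on a wavenumber grid
#'
#' @param bands a list of [band()] objects.
#' @param wavenumbers grid in cm\eqn{^{-1}}.
#' @param weights optional per-band amplitude multipliers (default all 1).
#' @return an `ir_spectrum`.
#' @export
bands_to_spectrum <- function(bands, wavenumbers, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(bands))
  a <- numeric(length(wavenumbers))
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    a <- a + weights[i] * b$amplitude *
      pseudo_voigt(wavenumbers, b$center, b$fwhm, b$shape)
  }
  ir_spectrum(wavenumbers, a)
}

#' Spectral mixing residual
#'
#' The difference between a mixture spectrum and the mole-fraction-weighted
#' combination of the pure-component spectra,
#' \eqn{\Delta A_{mix}(\nu) = A_{mix}(\nu) - [x_A A_A(\nu) + (1-x_A) A_B(\nu)]}.
#' Non-zero residuals flag intermolecular interactions absent from the
#' pure liquids.
#'
#' @param mix,pure_a,pure_b `ir_spectrum` objects on an identical grid
#'   (grids are never silently resampled).
#' @param x_a mole fraction of component A in the mixture.
#' @return an `ir_spectrum` holding \eqn{\Delta A_{mix}}.
#' @export
mixing_residual <- function(mix, pure_a, pure_b, x_a) {
  if (x_a < 0 || x_a > 1) stop_domain("x_a must lie in [0, 1]")
  if (!same_grid(mix, pure_a) || !same_grid(mix, pure_b))
    stop("spectra are on different wavenumber grids; resample explicitly first")
  ir_spectrum(mix$wavenumbers,
              mix$absorbance - (x_a * pure_a$absorbance +
                                (1 - x_a) * pure_b$absorbance))
}

#' Baseline-corrected band intensity in a window
#'
#' Subtracts a straight-line local baseline anchored at the window edges
#' and reports the maximum remaining absorbance (peak height). Peak height
#' rather than integrated area is the default because band positions and
#' intensities, not areas, are what composition trends are read from;
#' `method = "area"` integrates the baseline-corrected signal instead.
#'
#' @param spec an `ir_spectrum`.
#' @param window numeric `c(lo, hi)` in cm\eqn{^{-1}}, inside the grid.
#' @param method `"height"` (default) or `"area"` (trapezoidal).
#' @return the band intensity (absorbance, or absorbance·cm\eqn{^{-1}} for
#'   area).
#' @export
band_intensity <- function(spec, window, method = c("height", "area")) {
  method <- match.arg(method)
  if (length(window) != 2 || window[1] >= window[2])
    stop_domain("window must be c(lo, hi) with lo < hi")
  idx <- which(spec$wavenumbers >= window[1] & spec$wavenumbers <= window[2])
  if (length(idx) < 2) stop("window is empty on this grid")
  nu <- spec$wavenumbers[idx]
  a <- spec$absorbance[idx]
  n <- length(idx)
  baseline <- a[1] + (a[n] - a[1]) * (nu - nu[1]) / (nu[n] - nu[1])
  corrected <- a - baseline
  switch(method,
         height = max(corrected),
         area = sum(diff(nu) * (corrected[-1] + corrected[-n]) / 2))
}

#' Composition-normalised (relative) absorbance
#'
#' Band intensity divided by the mole fraction of the species carrying the
#' band; under Beer-Lambert behaviour with no speciation change this is
#' constant in composition, so departures trace association equilibria.
#'
#' @param intensity band intensity (absorbance).
#' @param fraction mole fraction (> 0).
#' @return `intensity / fraction`.
#' @export
relative_absorbance <- function(intensity, fraction) {
  if (any(fraction <= 0)) stop_domain("fraction must be positive")
  intensity / fraction
}
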