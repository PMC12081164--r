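## Compact compiled tabulation of hemoglobin molar extinction coefficients
## (oxy- and deoxy-hemoglobin, cm^-1 M^-1), after the widely used
## Gratzer/Prahl compilation, sampled at coarse wavelengths over the fNIRS
## window and linearly interpolated. Values are converted to cm^-1 uM^-1 at
## the user interface.
.extinctionTable <- matrix(c(
  # nm    HbO2      Hb
  650,   368.0,  3750.12,
  660,   319.6,  3226.56,
  680,   277.6,  2407.92,
  690,   276.0,  2051.96,
  700,   290.0,  1794.28,
  710,   316.8,  1540.48,
  730,   390.0,  1102.20,
  740,   446.0,  1115.88,
  750,   518.0,  1405.24,
  760,   586.0,  1548.52,
  770,   650.0,  1311.88,
  780,   710.0,  1075.44,
  790,   774.0,   903.60,
  800,   816.0,   761.72,
  810,   864.0,   717.08,
  820,   916.0,   693.76,
  830,   974.0,   693.04,
  840,  1022.0,   692.36,
  850,  1058.0,   691.32,
  860,  1092.0,   696.08,
  880,  1154.0,   726.44,
  900,  1198.0,   761.84
), ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("nm", "hbo", "hbr")))

#' Hemoglobin extinction coefficients
#'
#' Linear interpolation of the bundled extinction tabulation.
#'
#' @param wavelengths wavelengths in nm (within 650-900).
#' @return matrix with columns \code{hbo}, \code{hbr} in cm^-1 uM^-1.
#' @export
extinctionCoefficients <- function(wavelengths) {
  tab <- .extinctionTable
  if (any(wavelengths < min(tab[, 1]) | wavelengths > max(tab[, 1])))
    stop("wavelength outside the tabulated range 650-900 nm")
  out <- cbind(
    hbo = stats::approx(tab[, 1], tab[, 2], wavelengths)$y,
    hbr = stats::approx(tab[, 1], tab[, 3], wavelengths)$y
  ) / 1e6
  rownames(out) <- as.character(wavelengths)
  out
}

#' Differential pathlength factor
#'
#' \code{dpfScholkmann} implements the general age- and wavelength-dependent
#' DPF formula (valid roughly 690-830 nm); \code{dpfDuncan} interpolates the
#' four wavelength-specific age formulas of the Duncan adult-head fits.
#'
#' @param wavelengths wavelengths (nm).
#' @param age subject age (years).
#' @return numeric DPF per wavelength (unitless).
#' @export
dpfScholkmann <- function(wavelengths, age = 25) {
  223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wavelengths^3 +
    0.001245 * wavelengths^2 - 0.9025 * wavelengths
}

#' @rdname dpfScholkmann
#' @export
dpfDuncan <- function(wavelengths, age = 25) {
  ref <- cbind(nm = c(690, 744, 807, 832),
               a = c(5.38, 5.11, 4.99, 4.67),
               b = c(0.049, 0.106, 0.067, 0.062),
               c = c(0.877, 0.723, 0.814, 0.819))
  wl <- pmin(pmax(wavelengths, min(ref[, "nm"])), max(ref[, "nm"]))
  a <- stats::approx(ref[, "nm"], ref[, "a"], wl)$y
  b <- stats::approx(ref[, "nm"], ref[, "b"], wl)$y
  cc <- stats::approx(ref[, "nm"], ref[, "c"], wl)$y
  a + b * age^cc
}

#' Parameters of the modified Beer-Lambert conversion
#'
#' Bundles the extinction coefficients, differential pathlength factors and
#' partial volume factor used by \code{\link{mbll}}. DPF values can come
#' from the Scholkmann formula (default), the Duncan fits, or be supplied
#' directly.
#'
#' @param wavelengths the two wavelengths (nm).
#' @param dpf either a numeric vector (one per wavelength), or one of
#'   \code{"scholkmann"}, \code{"duncan"}.
#' @param pvf partial volume factor (default 50).
#' @param age subject age in years for the DPF formulas.
#' @param extinction optional 2 x 2 matrix (rows = wavelengths, columns
#'   \code{hbo}, \code{hbr}, cm^-1 uM^-1) overriding the bundled table.
#' @return a list of class \code{BeerLambertParams}.
#' @export
beerLambertParams <- function(wavelengths, dpf = "scholkmann", pvf = 50,
                              age = 25, extinction = NULL) {
  if (length(wavelengths) != 2L)
    stop("exactly 2 wavelengths are required")
  if (is.character(dpf))
    dpf <- switch(match.arg(dpf, c("scholkmann", "duncan")),
                  scholkmann = dpfScholkmann(wavelengths, age),
                  duncan = dpfDuncan(wavelengths, age))
  if (any(dpf < 1 | dpf > 20))
    stop("dpf outside the plausible range [1, 20]")
  if (is.null(extinction)) extinction <- extinctionCoefficients(wavelengths)
  E <- as.matrix(extinction)
  if (!identical(dim(E), c(2L, 2L)))
    stop("extinction must be a 2 x 2 matrix")
  if (rcond(E) < 1e-12)
    stop("singular extinction matrix for wavelengths ",
         paste(wavelengths, collapse = ", "))
  structure(list(wavelengths = wavelengths, extinction = E,
                 dpf = dpf, pvf = pvf, age = age),
            class = "BeerLambertParams")
}

#' Effective optical pathlength
#'
#' \code{deff = d * DPF / PVF}, with the source-detector distance \code{d}
#' in cm.
#'
#' @param distanceCm source-detector distance in cm.
#' @param dpf differential pathlength factor.
#' @param pvf partial volume factor.
#' @return effective pathlength in cm.
#' @export
effectivePathlength <- function(distanceCm, dpf, pvf = 50) {
  distanceCm * dpf / pvf
}
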