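#' Construct a Spectrum
#'
#' @param wavelengthsNm strictly increasing wavelength grid, nm.
#' @param values one value per grid point. For `kind = "absorbance"`,
#'   negative values (instrument baseline noise) are clipped to zero with a
#'   warning.
#' @param kind `"emission"`, `"absorbance"` or `"synchronous"`.
#' @param label free-text label.
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(285:450, gaussianBand(285:450, 340, 15, 1000))
#' peakPosition(s)
#' @export
Spectrum <- function(wavelengthsNm, values,
                     kind = c("emission", "absorbance", "synchronous"),
                     label = "") {
  kind <- match.arg(kind)
  wavelengthsNm <- as.numeric(wavelengthsNm)
  values <- as.numeric(values)
  if (kind == "absorbance" && any(values < 0, na.rm = TRUE)) {
    warning(sprintf("%d negative absorbance value(s) clipped to 0",
                    sum(values < 0, na.rm = TRUE)))
    values <- pmax(values, 0)
  }
  new("Spectrum", kind = kind, wavelengthsNm = wavelengthsNm,
      values = values, label = as.character(label))
}

#' Gaussian band profile
#'
#' Convenience for building synthetic spectra:
#' `amplitude * exp(-(x - centerNm)^2 / (2 * widthNm^2))`.
#'
#' @param x wavelengths, nm.
#' @param centerNm band center, nm.
#' @param widthNm Gaussian sigma, nm.
#' @param amplitude peak height.
#' @return numeric vector of band values.
#' @export
gaussianBand <- function(x, centerNm, widthNm, amplitude = 1) {
  amplitude * exp(-(x - centerNm)^2 / (2 * widthNm^2))
}

#' @describeIn Spectrum wavelength grid in nm.
#' @param x a `Spectrum`.
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengthsNm)

#' Intensity values of a Spectrum
#' @param x a [Spectrum-class].
#' @return numeric vector of stored values.
#' @export
intensities <- function(x) {
  stopifnot(is(x, "Spectrum"))
  x@values
}

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum [%s] %d points, %.6g-%.6g nm%s\n",
              object@kind, length(object@wavelengthsNm),
              min(object@wavelengthsNm), max(object@wavelengthsNm),
              if (nzchar(object@label)) paste0(" <", object@label, ">") else ""))
})

#' Interpolated value of a spectrum at a wavelength
#'
#' Piecewise-linear interpolation between the bracketing grid points; exact
#' at grid points. Querying outside the grid range is an error (no
#' extrapolation).
#'
#' @param x a [Spectrum-class] or [TitrationSeries-class]. For a series the
#'   value is returned for every concentration column.
#' @param lambdaNm query wavelength, nm.
#' @return a single value (`Spectrum`) or one value per concentration
#'   (`TitrationSeries`, named by concentration in M).
#' @export
setMethod("intensityAt", "Spectrum", function(x, lambdaNm) {
  .interpAt(x@wavelengthsNm, x@values, lambdaNm)
})

.interpAt <- function(w, v, lambdaNm) {
  stopifnot(length(lambdaNm) == 1L, is.finite(lambdaNm))
  if (lambdaNm < w[1L] || lambdaNm > w[length(w)])
    stop(sprintf("wavelength %.6g nm outside grid range [%.6g, %.6g]",
                 lambdaNm, w[1L], w[length(w)]))
  approx(w, v, xout = lambdaNm, method = "linear", ties = "ordered")$y
}

#' Peak wavelength of a spectrum
#'
#' Wavelength of the maximum value within a window. Ties are broken toward
#' the shorter wavelength, so a flat trace reports the window's lower edge.
#'
#' @param x a [Spectrum-class].
#' @param windowNm `c(lo, hi)` window in nm; default spans the whole grid.
#' @return peak wavelength, nm.
#' @export
setMethod("peakPosition", "Spectrum", function(x, windowNm = NULL) {
  w <- x@wavelengthsNm
  if (is.null(windowNm)) windowNm <- range(w)
  stopifnot(length(windowNm) == 2L, windowNm[1L] <= windowNm[2L])
  sel <- w >= windowNm[1L] & w <= windowNm[2L]
  if (!any(sel))
    stop("window does not overlap the wavelength grid")
  ws <- w[sel]
  vs <- x@values[sel]
  ws[which.max(vs)] # which.max returns the first = shortest wavelength
})

#' Subtract a background spectrum
#'
#' Pointwise subtraction of a background trace (e.g. the intrinsic ligand
#' absorbance) from a sample trace. When the grids differ, the background
#' is linearly interpolated onto the sample grid; sample points outside the
#' background's range are an error (extrapolation is forbidden). For
#' absorbance spectra, negative differences are clipped to zero with a
#' warning (baseline noise).
#'
#' @param sample a [Spectrum-class].
#' @param background a [Spectrum-class] of the same kind.
#' @return a [Spectrum-class] with the background removed; kind preserved.
#' @export
subtractBackground <- function(sample, background) {
  stopifnot(is(sample, "Spectrum"), is(background, "Spectrum"))
  ws <- sample@wavelengthsNm
  wb <- background@wavelengthsNm
  if (ws[1L] < wb[1L] || ws[length(ws)] > wb[length(wb)])
    stop("background does not cover the sample wavelength range; ",
         "extrapolation is forbidden")
  bg <- if (identical(ws, wb)) background@values
        else approx(wb, background@values, xout = ws,
                    method = "linear", ties = "ordered")$y
  Spectrum(ws, sample@values - bg, kind = sample@kind,
           label = sample@label)
}
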