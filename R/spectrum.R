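#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed nonnegative function: a reflectance,
#' an illuminant irradiance, or a receptor spectral sensitivity.
#'
#' @param wavelengths_nm Strictly increasing numeric vector of wavelengths
#'   in nanometres.
#' @param values Nonnegative numeric vector, same length as
#'   `wavelengths_nm`.
#' @param kind One of `"reflectance"`, `"irradiance"`, `"sensitivity"`.
#' @param allow_above_one Reflectance values above 1 are rejected unless this
#'   is `TRUE` (measurements scaled against a non-ideal white standard can
#'   legitimately exceed 1).
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelengths_nm`, `values` and `kind`.
#' @examples
#' s <- spectrum(400:700, rep(0.5, 301), "reflectance")
#' @export
spectrum <- function(wavelengths_nm, values,
                     kind = c("reflectance", "irradiance", "sensitivity"),
                     allow_above_one = FALSE) {
  kind <- match.arg(kind)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (length(wavelengths_nm) < 1) {
    stop("a spectrum needs at least one wavelength", call. = FALSE)
  }
  if (any(!is.finite(wavelengths_nm)) || any(!is.finite(values))) {
    stop("spectrum contains non-finite entries", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("spectrum values must be nonnegative", call. = FALSE)
  }
  if (kind == "reflectance" && !allow_above_one && any(values > 1 + 1e-12)) {
    stop("reflectance above 1; pass allow_above_one = TRUE if white-standard scaled",
         call. = FALSE)
  }
  structure(list(wavelengths_nm = wavelengths_nm, values = values, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s, %d points, %g-%g nm>\n", x$kind,
              length(x$values), min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; extrapolation outside the measured support is
#' refused because reflectance and sensitivity curves carry no information
#' there.
#'
#' @param s A [spectrum()].
#' @param grid Numeric vector of target wavelengths (nm), within the
#'   support of `s`.
#' @return A [spectrum()] of the same kind on `grid`.
#' @export
resample_spectrum <- function(s, grid) {
  stopifnot(inherits(s, "spectrum"))
  grid <- as.numeric(grid)
  tol <- 1e-9
  if (min(grid) < min(s$wavelengths_nm) - tol ||
      max(grid) > max(s$wavelengths_nm) + tol) {
    stop("grid extends outside the spectrum's wavelength support", call. = FALSE)
  }
  v <- stats::approx(s$wavelengths_nm, s$values, xout = grid, rule = 2)$y
  spectrum(grid, pmax(v, 0), s$kind, allow_above_one = TRUE)
}

#' Read a spectrum from CSV
#'
#' Expects a header `wavelength_nm,value`.
#'
#' @param path CSV file path.
#' @inheritParams spectrum
#' @return A [spectrum()].
#' @export
read_spectrum_csv <- function(path, kind = "reflectance",
                              allow_above_one = FALSE) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    stop("spectrum CSV must have columns wavelength_nm,value", call. = FALSE)
  }
  spectrum(d$wavelength_nm, d$value, kind, allow_above_one = allow_above_one)
}

#' Write a spectrum to CSV
#'
#' @param s A [spectrum()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelengths_nm, value = s$values),
    path, row.names = FALSE)
  invisible(path)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Common integration grid for several spectra: 1-nm steps over the shared
# support (coarser spectra are linearly interpolated onto it).
common_grid <- function(..., step = 1) {
  specs <- list(...)
  lo <- max(vapply(specs, function(s) min(s$wavelengths_nm), 0))
  hi <- min(vapply(specs, function(s) max(s$wavelengths_nm), 0))
  if (hi - lo < step) {
    stop("spectra share no overlapping wavelength support", call. = FALSE)
  }
  seq(lo, hi, by = step)
}
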