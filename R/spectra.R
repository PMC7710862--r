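#' Construct a spectrum
#'
#' A spectrum is a sampled function of wavelength: reflectance (as a
#' fraction) or radiance (relative photon flux). Wavelengths must be strictly
#' increasing and values non-negative.
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing.
#' @param value Numeric vector of the same length, all values >= 0.
#' @return An object of class `"spectrum"`, a list with elements
#'   `wavelength` and `value`.
#' @export
#' @examples
#' s <- spectrum(seq(300, 650, by = 10), rep(0.2, 36))
spectrum <- function(wavelength, value) {
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value))
    stop("wavelength and value must have the same length")
  if (length(wavelength) < 2L)
    stop("a spectrum needs at least two samples")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(value)) || any(value < 0))
    stop("spectral values must be finite and non-negative")
  structure(list(wavelength = wavelength, value = value), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d samples, %g-%g nm, values %.4g-%.4g>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$value), max(x$value)))
  invisible(x)
}

#' The standard 10 nm analysis grid
#'
#' Wavelength grid used throughout: 300 to 650 nm in 10 nm steps, covering
#' the spectral range of hymenopteran trichromatic vision.
#'
#' @return Numeric vector `seq(300, 650, by = 10)`.
#' @export
hex_grid <- function() seq(300, 650, by = 10)

#' Resample a spectrum by shape-preserving cubic interpolation
#'
#' Interpolates spectral values onto a new wavelength grid using the
#' piecewise cubic Hermite interpolating polynomial (PCHIP). PCHIP is
#' shape-preserving: monotone segments of the input remain monotone and the
#' interpolant never overshoots local extrema, which matters for reflectance
#' curves that must stay within physically meaningful bounds.
#'
#' @param spec A [spectrum()].
#' @param grid Target wavelength grid (nm), strictly increasing. Defaults to
#'   [hex_grid()].
#' @return A [spectrum()] sampled on `grid`.
#' @export
resample_spectrum <- function(spec, grid = hex_grid()) {
  stopifnot(inherits(spec, "spectrum"))
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  rng <- range(spec$wavelength)
  if (min(grid) < rng[1] || max(grid) > rng[2])
    stop(sprintf(
      "grid [%g, %g] extends beyond the measured range [%g, %g]: refusing to extrapolate",
      min(grid), max(grid), rng[1], rng[2]))
  v <- pracma::pchip(spec$wavelength, spec$value, grid)
  # numerical noise can push non-negative data a hair below zero
  v[v < 0 & v > -1e-12] <- 0
  spectrum(grid, v)
}

#' Read spectra from a CSV file
#'
#' Expected layout: header row; first column `wavelength_nm`; each remaining
#' column one spectrum, with sample IDs as column headers.
#'
#' @param path Path to a CSV file.
#' @return Named list of [spectrum()] objects, one per sample column.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("first column must be named 'wavelength_nm'")
  wl <- df[[1]]
  if (any(diff(wl) <= 0)) stop("wavelengths in file must be strictly increasing")
  out <- lapply(df[-1], function(v) spectrum(wl, v))
  out
}

#' Write spectra to a CSV file
#'
#' Inverse of [read_spectra_csv()]. All spectra must share one wavelength grid.
#'
#' @param spectra Named list of [spectrum()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1, !is.null(names(spectra)))
  wl <- spectra[[1]]$wavelength
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelength, wl)))
      stop("all spectra must share the same wavelength grid")
  df <- data.frame(wavelength_nm = wl)
  for (nm in names(spectra)) df[[nm]] <- spectra[[nm]]$value
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
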