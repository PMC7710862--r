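# Hexagon color space for hymenopteran trichromatic vision: receptor quantum
# catches under von Kries adaptation to a background, saturating transduction
# E = P/(P+1), and projection of the three excitations onto a 2D hexagon.

#' Rhodopsin absorbance template sensitivity
#'
#' Generates a photoreceptor spectral-sensitivity curve from the A1 visual
#' pigment absorbance template of Govardovskii et al. (alpha band plus beta
#' band), parameterized only by the peak wavelength.
#'
#' @param lambda_max Peak sensitivity wavelength (nm).
#' @param grid Wavelength grid (nm), default [hex_grid()].
#' @return A [spectrum()] with values normalized to peak 1.
#' @export
receptor_template <- function(lambda_max, grid = hex_grid()) {
  stopifnot(lambda_max > 250, lambda_max < 700)
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  lm_beta <- 189 + 0.315 * lambda_max
  b_beta <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lm_beta) / b_beta)^2)
  s <- alpha + beta
  spectrum(grid, s / max(s))
}

#' Standard daylight illuminant as photon flux
#'
#' A smooth daylight-class spectral power distribution: black-body radiance
#' at the stated correlated color temperature, converted from energy to
#' relative photon-flux units (multiplied by wavelength) and normalized to 1
#' at 540 nm. The normalization is arbitrary: it cancels in von Kries
#' adaptation.
#'
#' @param grid Wavelength grid (nm), default [hex_grid()].
#' @param cct Correlated color temperature in kelvin (default 6500).
#' @return A [spectrum()] in relative photon-flux units.
#' @export
daylight_illuminant <- function(grid = hex_grid(), cct = 6500) {
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kb <- 1.380649e-23
  lam <- grid * 1e-9
  energy <- 1 / (lam^5 * (exp(h * c0 / (lam * kb * cct)) - 1))
  photons <- energy * lam                # E = hc/lambda per photon
  ref <- stats::approx(grid, photons, xout = 540, rule = 2)$y
  spectrum(grid, photons / ref)
}

#' Average green-leaf adaptation background
#'
#' A smooth synthetic green-leaf reflectance: about 5% in the UV, rising to a
#' chlorophyll-window peak near 15% at 550 nm and declining toward 5% at
#' 650 nm. Only its relative shape matters, since it defines the von Kries
#' adaptation state.
#'
#' @param grid Wavelength grid (nm), default [hex_grid()].
#' @return A [spectrum()] of reflectance fractions.
#' @export
green_leaf_background <- function(grid = hex_grid()) {
  base <- 0.05
  peak <- 0.10 * exp(-((grid - 550) / 55)^2)
  spectrum(grid, base + peak)
}

#' Honeybee visual system
#'
#' Bundles the three receptor sensitivities (UV, blue, green), the illuminant
#' and the adaptation background needed to compute hexagon color loci.
#' Defaults use template sensitivities with peaks at 344, 436 and 544 nm
#' (honeybee UV, B and G receptor classes), a daylight photon-flux
#' illuminant, and a green-leaf background.
#'
#' @param sensitivities Named list of three [spectrum()] objects
#'   (`uv`, `blue`, `green`).
#' @param illuminant A [spectrum()] in photon-flux units.
#' @param background A [spectrum()] of background reflectance, strictly
#'   positive over the grid.
#' @param grid Common wavelength grid; every spectrum is resampled onto it.
#' @return An object of class `"visual_system"`.
#' @export
visual_system <- function(sensitivities = NULL,
                          illuminant = daylight_illuminant(grid),
                          background = green_leaf_background(grid),
                          grid = hex_grid()) {
  if (is.null(sensitivities)) {
    sensitivities <- list(uv = receptor_template(344, grid),
                          blue = receptor_template(436, grid),
                          green = receptor_template(544, grid))
  }
  if (length(sensitivities) != 3L ||
      !setequal(names(sensitivities), c("uv", "blue", "green")))
    stop("sensitivities must be a named list: uv, blue, green")
  sens <- lapply(sensitivities[c("uv", "blue", "green")],
                 resample_spectrum, grid = grid)
  ill <- resample_spectrum(illuminant, grid)
  bg <- resample_spectrum(background, grid)
  if (any(ill$value <= 0)) stop("illuminant must be strictly positive on the grid")
  if (any(bg$value <= 0)) stop("background must be strictly positive on the grid")
  structure(list(sensitivities = sens, illuminant = ill, background = bg,
                 grid = grid),
            class = "visual_system")
}

#' @export
print.visual_system <- function(x, ...) {
  cat(sprintf("<visual_system: trichromat, grid %g-%g nm by %g>\n",
              min(x$grid), max(x$grid), x$grid[2] - x$grid[1]))
  invisible(x)
}

#' Receptor quantum catches and excitations for a stimulus
#'
#' Computes, for each receptor class i, the quantum catch
#' \deqn{P_i = R_i \sum_\lambda I_S(\lambda) S_i(\lambda) D(\lambda)}
#' with the von Kries adaptation factor
#' \eqn{R_i = 1 / \sum_\lambda I_B(\lambda) S_i(\lambda) D(\lambda)}, where
#' \eqn{I_S} is the stimulus reflectance, \eqn{I_B} the background
#' reflectance, \eqn{D} the photon-flux illuminant and \eqn{S_i} the receptor
#' sensitivity. Sums are left-rectangle integrals on the common 10 nm grid
#' (the grid width cancels in the ratio). Excitation follows the saturating
#' transduction \eqn{E_i = P_i / (P_i + 1)}, so a stimulus identical to the
#' background gives \eqn{P_i = 1}, \eqn{E_i = 0.5} in every receptor.
#'
#' @param reflectance A [spectrum()] of stimulus reflectance.
#' @param vs A [visual_system()].
#' @return An object of class `"excitation"`: list with numeric triplets `P`
#'   and `E`, each named (`uv`, `blue`, `green`).
#' @export
receptor_excitations <- function(reflectance, vs) {
  stopifnot(inherits(vs, "visual_system"))
  refl <- resample_spectrum(reflectance, vs$grid)
  ill <- vs$illuminant$value
  bg <- vs$background$value
  P <- vapply(vs$sensitivities, function(s) {
    denom <- sum(bg * s$value * ill)
    if (denom <= 0)
      stop("background has zero overlap with a receptor sensitivity: von Kries factor undefined")
    sum(refl$value * s$value * ill) / denom
  }, numeric(1))
  E <- P / (P + 1)
  structure(list(P = P, E = E), class = "excitation")
}

#' @export
print.excitation <- function(x, ...) {
  cat(sprintf("<excitation: E = (%.3f, %.3f, %.3f)>\n",
              x$E[["uv"]], x$E[["blue"]], x$E[["green"]]))
  invisible(x)
}

#' Project receptor excitations onto the hexagon
#'
#' The hexagon chromaticity coordinates of a trichromat:
#' \deqn{x = \frac{\sqrt{3}}{2}(E_G - E_{UV}), \qquad
#'       y = E_B - \frac{E_{UV} + E_G}{2}.}
#' Distances between loci are expressed in hexagon units (Hu).
#'
#' @param e An `"excitation"` from [receptor_excitations()], or a numeric
#'   triplet `c(uv, blue, green)` of excitations in `[0, 1]`.
#' @return A `"color_locus"`: list with `x`, `y` and the excitations used.
#' @export
hexagon_locus <- function(e) {
  if (inherits(e, "excitation")) ev <- e$E
  else {
    ev <- as.numeric(e)
    if (length(ev) != 3) stop("need three excitation values (uv, blue, green)")
    names(ev) <- c("uv", "blue", "green")
  }
  if (any(ev < 0) || any(ev > 1)) stop("excitations must lie in [0, 1]")
  color_locus(x = sqrt(3) / 2 * (ev[["green"]] - ev[["uv"]]),
              y = ev[["blue"]] - (ev[["uv"]] + ev[["green"]]) / 2,
              excitations = ev)
}

#' Construct a color locus directly
#'
#' A point in the hexagon (or any translated) coordinate frame. Loci given
#' directly — e.g. reconstructed from published bivariate color PDFs that
#' live in a translated positive frame — carry no excitation triplet.
#'
#' @param x,y Coordinates in hexagon units.
#' @param excitations Optional named excitation triplet.
#' @return An object of class `"color_locus"`.
#' @export
color_locus <- function(x, y, excitations = NULL) {
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 excitations = excitations),
            class = "color_locus")
}

#' @export
print.color_locus <- function(x, ...) {
  cat(sprintf("<color_locus: (%.4f, %.4f) Hu>\n", x$x, x$y))
  invisible(x)
}

#' Translate a locus (or matrix of loci) by a constant offset
#'
#' Translation does not change any pairwise distance, so analyses based on
#' color distance are identical in the native hexagon frame and in any
#' shifted positive frame.
#'
#' @param loci A `"color_locus"`, or a two-column matrix/data.frame of x, y.
#' @param dx,dy Offsets in hexagon units.
#' @return Same shape as the input, shifted.
#' @export
translate_loci <- function(loci, dx = 0, dy = 0) {
  if (inherits(loci, "color_locus"))
    return(color_locus(loci$x + dx, loci$y + dy))
  m <- as.matrix(loci)
  stopifnot(ncol(m) == 2)
  m[, 1] <- m[, 1] + dx
  m[, 2] <- m[, 2] + dy
  m
}

#' Euclidean color distance in hexagon units
#'
#' @param a,b `"color_locus"` objects (or anything with `$x`, `$y`).
#' @return Distance in Hu.
#' @export
color_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Convert spectra to hexagon loci
#'
#' Convenience wrapper: resample each reflectance spectrum, compute receptor
#' excitations and project into the hexagon.
#'
#' @param spectra Named list of reflectance [spectrum()] objects.
#' @param vs A [visual_system()].
#' @return data.frame with columns `sample_id`, `x`, `y`.
#' @export
spectra_to_loci <- function(spectra, vs = visual_system()) {
  stopifnot(length(spectra) >= 1)
  ids <- names(spectra)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_along(spectra))
  rows <- lapply(seq_along(spectra), function(i) {
    loc <- hexagon_locus(receptor_excitations(spectra[[i]], vs))
    data.frame(sample_id = ids[i], x = loc$x, y = loc$y)
  })
  do.call(rbind, rows)
}
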