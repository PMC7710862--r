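# Bivariate probability density functions for intraspecific floral color
# variability: two marginal distributions (one per hexagon coordinate)
# coupled by a copula. Joint density by Sklar's theorem:
#   f(x, y) = f_x(x) f_y(y) c(F_x(x), F_y(y)).

#' Construct a bivariate color PDF
#'
#' @param margin_x,margin_y [marginal_model()]s for the two coordinates.
#' @param copula A [copula_model()] describing their dependence.
#' @return An object of class `"bivariate_pdf"`.
#' @export
bivariate_pdf <- function(margin_x, margin_y, copula = copula_model("independence")) {
  stopifnot(inherits(margin_x, "marginal_model"),
            inherits(margin_y, "marginal_model"),
            inherits(copula, "copula_model"))
  structure(list(margin_x = margin_x, margin_y = margin_y, copula = copula),
            class = "bivariate_pdf")
}

#' @export
print.bivariate_pdf <- function(x, ...) {
  cat("<bivariate_pdf>\n  x: "); print(x$margin_x)
  cat("  y: "); print(x$margin_y)
  cat("  dependence: "); print(x$copula)
  invisible(x)
}

#' Joint density of a bivariate color PDF
#'
#' Marginal CDF values are clipped to `[1e-12, 1 - 1e-12]` before copula
#' evaluation to avoid log(0) in extreme tails. Points outside a margin's
#' support return density 0.
#'
#' @param pdf A [bivariate_pdf()].
#' @param x,y Coordinate vectors (hexagon units, any translated frame).
#' @return Density values `d`.
#' @export
pdf_density <- function(pdf, x, y) {
  stopifnot(inherits(pdf, "bivariate_pdf"))
  fx <- marginal_density(pdf$margin_x, x)
  fy <- marginal_density(pdf$margin_y, y)
  out <- numeric(length(fx))
  ok <- fx > 0 & fy > 0
  if (any(ok)) {
    u <- .clip01(marginal_cdf(pdf$margin_x, x[ok]))
    v <- .clip01(marginal_cdf(pdf$margin_y, y[ok]))
    out[ok] <- fx[ok] * fy[ok] * copula_density(pdf$copula, u, v)
  }
  out
}

#' Sample color loci from a bivariate PDF
#'
#' Draws `(u, v)` pairs from the copula by conditional inversion and maps
#' them through the marginal quantile functions.
#'
#' @param pdf A [bivariate_pdf()].
#' @param n Number of loci.
#' @param seed Optional integer seed.
#' @return `n` x 2 matrix with columns `x`, `y`.
#' @export
pdf_sample <- function(pdf, n, seed = NULL) {
  stopifnot(inherits(pdf, "bivariate_pdf"), n >= 0)
  uv <- copula_sample(pdf$copula, n, seed = seed)
  cbind(x = marginal_quantile(pdf$margin_x, uv[, 1]),
        y = marginal_quantile(pdf$margin_y, uv[, 2]))
}

marginal_to_list <- function(m)
  list(family = m$family, params = m$parameters,
       se = if (is.null(m$se)) NULL else as.list(m$se))

marginal_from_list <- function(l)
  marginal_model(l$family, unlist(l$params),
                 se = if (is.null(l$se)) NULL else unlist(l$se))

#' Serialize a bivariate PDF to JSON
#'
#' Layout: `{margin_x: {family, params, se}, margin_y: {...},
#' copula: {family, rotation, par1, par2, se}}`.
#'
#' @param pdf A [bivariate_pdf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdf_json <- function(pdf, path) {
  stopifnot(inherits(pdf, "bivariate_pdf"))
  cop <- pdf$copula
  jsonlite::write_json(
    list(margin_x = marginal_to_list(pdf$margin_x),
         margin_y = marginal_to_list(pdf$margin_y),
         copula = list(family = cop$family, rotation = cop$rotation,
                       par1 = cop$par1, par2 = cop$par2,
                       se = if (is.null(cop$se)) NULL else as.list(cop$se))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a bivariate PDF from JSON
#'
#' @param path Path written by [write_pdf_json()].
#' @return A [bivariate_pdf()].
#' @export
read_pdf_json <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  cop <- copula_model(l$copula$family, l$copula$rotation,
                      par1 = l$copula$par1 %||% NA_real_,
                      par2 = l$copula$par2 %||% NA_real_,
                      se = if (is.null(l$copula$se)) NULL else unlist(l$copula$se))
  bivariate_pdf(marginal_from_list(l$margin_x), marginal_from_list(l$margin_y),
                cop)
}
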