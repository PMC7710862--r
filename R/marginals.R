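# Marginal distribution models for color-locus coordinates.
# Parameter conventions follow the usual reporting style for fitted floral
# color PDFs: gamma by shape/rate, weibull by shape/scale, normal by
# mean/std (the ML, 1/n, standard deviation).

#' Construct a marginal distribution model
#'
#' @param family `"normal"`, `"gamma"` or `"weibull"`.
#' @param parameters Named numeric vector: normal `mean`, `std`; gamma
#'   `shape`, `rate`; weibull `shape`, `scale`.
#' @param se Optional named standard errors.
#' @return An object of class `"marginal_model"`.
#' @export
marginal_model <- function(family = c("normal", "gamma", "weibull"),
                           parameters, se = NULL) {
  family <- match.arg(family)
  need <- switch(family, normal = c("mean", "std"),
                 gamma = c("shape", "rate"), weibull = c("shape", "scale"))
  if (!all(need %in% names(parameters)))
    stop(sprintf("%s needs parameters: %s", family, paste(need, collapse = ", ")))
  p <- as.list(parameters[need])
  scale_par <- p[[need[2]]]
  if (scale_par <= 0) stop(sprintf("%s must be positive", need[2]))
  if (family != "normal" && p$shape <= 0) stop("shape must be positive")
  structure(list(family = family, parameters = p, se = se),
            class = "marginal_model")
}

#' @export
print.marginal_model <- function(x, ...) {
  cat(sprintf("<marginal_model: %s(%s)>\n", x$family,
              paste(sprintf("%s=%.4g", names(x$parameters),
                            unlist(x$parameters)), collapse = ", ")))
  invisible(x)
}

#' Marginal density, CDF, quantile and sampling
#'
#' Thin dispatchers over the base distribution functions for the model's
#' family and parameters.
#'
#' @param m A [marginal_model()].
#' @param x,q,p,n Usual distribution-function arguments.
#' @return Numeric vector.
#' @export
marginal_density <- function(m, x) {
  p <- m$parameters
  switch(m$family,
         normal = stats::dnorm(x, p$mean, p$std),
         gamma = stats::dgamma(x, shape = p$shape, rate = p$rate),
         weibull = stats::dweibull(x, shape = p$shape, scale = p$scale))
}

#' @rdname marginal_density
#' @export
marginal_cdf <- function(m, q) {
  p <- m$parameters
  switch(m$family,
         normal = stats::pnorm(q, p$mean, p$std),
         gamma = stats::pgamma(q, shape = p$shape, rate = p$rate),
         weibull = stats::pweibull(q, shape = p$shape, scale = p$scale))
}

#' @rdname marginal_density
#' @export
marginal_quantile <- function(m, p) {
  pp <- m$parameters
  switch(m$family,
         normal = stats::qnorm(p, pp$mean, pp$std),
         gamma = stats::qgamma(p, shape = pp$shape, rate = pp$rate),
         weibull = stats::qweibull(p, shape = pp$shape, scale = pp$scale))
}

#' @rdname marginal_density
#' @export
marginal_sample <- function(m, n) {
  p <- m$parameters
  switch(m$family,
         normal = stats::rnorm(n, p$mean, p$std),
         gamma = stats::rgamma(n, shape = p$shape, rate = p$rate),
         weibull = stats::rweibull(n, shape = p$shape, scale = p$scale))
}

#' Fit a marginal distribution by maximum likelihood
#'
#' ML estimation with asymptotic standard errors via `fitdistrplus`. For the
#' normal family the estimates are the sample mean and the ML (1/n) standard
#' deviation.
#'
#' @param samples Numeric vector, n >= 5; strictly positive for gamma and
#'   weibull.
#' @param family `"normal"`, `"gamma"` or `"weibull"`.
#' @return A [marginal_model()] with standard errors.
#' @export
fit_marginal <- function(samples, family = c("normal", "gamma", "weibull")) {
  family <- match.arg(family)
  samples <- as.numeric(samples)
  if (length(samples) < 5) stop("need at least 5 samples")
  if (stats::sd(samples) == 0) stop("degenerate (constant) data")
  if (family != "normal" && any(samples <= 0))
    stop(sprintf("%s requires strictly positive samples", family))
  if (family == "normal") {
    # closed-form ML; SEs from the Fisher information
    n <- length(samples)
    mu <- mean(samples)
    sd_ml <- sqrt(mean((samples - mu)^2))
    return(marginal_model("normal", c(mean = mu, std = sd_ml),
                          se = c(mean = sd_ml / sqrt(n),
                                 std = sd_ml / sqrt(2 * n))))
  }
  fit <- fitdistrplus::fitdist(samples, family, method = "mle")
  est <- fit$estimate
  se <- fit$sd
  marginal_model(family, est, se = se)
}

# Asymptotic CDF of the Anderson-Darling statistic (Marsaglia & Marsaglia
# 2004 short-series approximation; adequate over the p-values of interest).
ad_asymptotic_cdf <- function(z) {
  vapply(z, function(zi) {
    if (zi <= 0) return(0)
    if (zi < 2) {
      zi^-0.5 * exp(-1.2337141 / zi) *
        (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
          (0.011672 - 0.00168691 * zi) * zi) * zi) * zi) * zi)
    } else {
      exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
        (0.008056 - 0.0003146 * zi) * zi) * zi) * zi) * zi))
    }
  }, numeric(1))
}

#' Anderson-Darling goodness-of-fit test against a specified marginal
#'
#' Computes the A-squared statistic of the samples against the fully
#' specified CDF of `marginal` and an asymptotic p-value. Because the null
#' distribution here is completely specified (no parameters re-estimated
#' from the tested sample), the standard asymptotic law of A-squared applies.
#'
#' @param samples Numeric vector.
#' @param marginal A [marginal_model()].
#' @return List with `statistic` (A-squared) and `p_value`.
#' @export
ad_gof_test <- function(samples, marginal) {
  stopifnot(inherits(marginal, "marginal_model"))
  x <- sort(as.numeric(samples))
  n <- length(x)
  if (n < 1) stop("samples must be non-empty")
  u <- marginal_cdf(marginal, x)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  list(statistic = a2, p_value = 1 - ad_asymptotic_cdf(a2))
}
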