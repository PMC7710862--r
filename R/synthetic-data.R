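# Synthetic inputs for exercising every pipeline stage without any external
# download: smooth floral reflectance spectra, binomial choice data from a
# known discrimination function, and the published-parameter model fixtures.

#' Generate a synthetic floral reflectance spectrum
#'
#' Baseline plus Gaussian reflectance components plus optional Gaussian
#' noise, clipped to [0, 1], on the 10 nm analysis grid. The default
#' component layout imitates a UV-blue floral profile.
#'
#' @param baseline Baseline reflectance fraction.
#' @param components data.frame with columns `center` (nm), `width` (nm),
#'   `amplitude`; components must lie within 300-650 nm plus/minus 100 nm.
#' @param noise_sd Gaussian noise SD (reflectance fraction).
#' @param seed Optional integer seed.
#' @param grid Wavelength grid, default [hex_grid()].
#' @return A [spectrum()].
#' @export
make_spectrum <- function(baseline = 0.05,
                          components = data.frame(center = c(350, 440),
                                                  width = c(40, 50),
                                                  amplitude = c(0.25, 0.35)),
                          noise_sd = 0, seed = NULL, grid = hex_grid()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(baseline >= 0)
  v <- rep(baseline, length(grid))
  if (nrow(components) > 0) {
    if (any(components$center < 200 | components$center > 750))
      stop("component centers must lie within [300, 650] nm plus/minus 100 nm")
    for (i in seq_len(nrow(components)))
      v <- v + components$amplitude[i] *
        exp(-((grid - components$center[i]) / components$width[i])^2)
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(grid), sd = noise_sd)
  spectrum(grid, pmin(pmax(v, 0), 1))
}

#' Generate synthetic behavioral choice data
#'
#' Emulates per-bee proportion-correct data: for each subject the named
#' coefficient of the generating discrimination function is perturbed by a
#' Gaussian draw, the perturbed curve is evaluated at every color-distance
#' level, and binomial counts are drawn. Perturbations that produce an
#' invalid coefficient set are resampled (at most 100 attempts).
#'
#' @param fn Generating [discrimination_function()].
#' @param dc_levels Color-distance levels (Hu), at least 3.
#' @param n_subjects Number of subjects.
#' @param subject_sd SD of the per-subject deviation.
#' @param random_param Name of the perturbed coefficient.
#' @param n_trials Trials per subject x level.
#' @param seed Optional integer seed.
#' @return A [choice_dataset()].
#' @export
make_choice_data <- function(fn, dc_levels, n_subjects = 5, subject_sd = 0,
                             random_param = names(fn$coefficients)[2],
                             n_trials = 100, seed = NULL) {
  stopifnot(inherits(fn, "discrimination_function"))
  if (length(unique(dc_levels)) < 3) stop("need at least 3 distinct color-distance levels")
  if (!random_param %in% names(fn$coefficients))
    stop(sprintf("unknown coefficient '%s'", random_param))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(s) {
    cf <- unlist(fn$coefficients)
    if (subject_sd > 0) {
      ok <- FALSE
      for (attempt in 1:100) {
        cf_try <- cf
        cf_try[random_param] <- cf[random_param] + stats::rnorm(1, sd = subject_sd)
        fn_try <- tryCatch(discrimination_function(fn$form, cf_try),
                           error = function(e) NULL)
        if (!is.null(fn_try)) { ok <- TRUE; break }
      }
      if (!ok) {
        warning("could not find a valid perturbation; using unperturbed coefficients")
        fn_try <- fn
      }
    } else fn_try <- fn
    p <- eval_discrimination(fn_try, dc_levels, clamp = FALSE)
    p <- pmin(pmax(p, 0), 1)
    k <- stats::rbinom(length(dc_levels), size = n_trials, prob = p)
    data.frame(subject_id = sprintf("bee%02d", s), delta_c_hu = dc_levels,
               n_correct = k, n_trials = n_trials)
  })
  choice_dataset(do.call(rbind, rows))
}

#' Published-parameter model fixtures
#'
#' The fitted model objects of the Eulophia zeyheriana / Wahlenbergia
#' cuspidata mimicry system, reconstructed from their published parameter
#' estimates and validated on construction:
#'
#' * `successive_blue`, `successive_yellow`: 3-parameter logistic
#'   discrimination functions for successive viewing of blue / yellow
#'   stimuli (blue: K = 0.990, r = 53.8, Mo = 0.528; yellow: K = 0.951,
#'   r = 47.2, Mo = 0.555).
#' * `absolute`: 4-parameter logistic for absolute conditioning
#'   (K = 0.842, Mo = 0.441, xmid = 0.081, scal = 0.009).
#' * `pdfs`: four bivariate color PDFs in the translated positive (x', y')
#'   frame — `wc_petal`, `wc_pollen` (W. cuspidata petal and pollen
#'   presenter) and `ez_lateral_petal`, `ez_labellum` (E. zeyheriana) —
#'   each as marginals plus a rotated copula.
#'
#' Published confidence intervals / standard errors are attached as metadata
#' and are not propagated through the Monte-Carlo analysis.
#'
#' @return Named list with elements `successive_blue`, `successive_yellow`,
#'   `absolute`, `pdfs`.
#' @export
bee_fixtures <- function() {
  succ_blue <- discrimination_function(
    "logistic3", c(K = 0.990, r = 53.8, Mo = 0.528),
    ci95 = list(K = c(0.969, 1.01), r = c(45.3, 66.3), Mo = c(0.474, 0.571)))
  succ_yellow <- discrimination_function(
    "logistic3", c(K = 0.951, r = 47.2, Mo = 0.555),
    ci95 = list(K = c(0.913, 0.989), r = c(35.7, 69.5), Mo = c(0.420, 0.651)))
  absolute <- discrimination_function(
    "logistic4", c(K = 0.842, Mo = 0.441, xmid = 0.081, scal = 0.009),
    ci95 = list(K = c(0.766, 0.919), Mo = c(0.377, 0.505),
                xmid = c(0.076, 0.086), scal = c(0.004, 0.015)))
  pdfs <- list(
    wc_petal = bivariate_pdf(
      marginal_model("gamma", c(shape = 491, rate = 659),
                     se = c(shape = 136, rate = 183)),
      marginal_model("gamma", c(shape = 1270, rate = 1150),
                     se = c(shape = 353, rate = 320)),
      copula_model("tawn2", 270, par1 = -9.13, par2 = 0.244,
                   se = c(par1 = 4.75, par2 = 0.030))),
    wc_pollen = bivariate_pdf(
      marginal_model("gamma", c(shape = 182, rate = 159),
                     se = c(shape = 54.9, rate = 48.0)),
      marginal_model("weibull", c(shape = 22.8, scale = 1.26),
                     se = c(shape = 3.86, scale = 0.012)),
      copula_model("tawn2", 180, par1 = 3.61, par2 = 0.490,
                   se = c(par1 = 0.846, par2 = 0.110))),
    ez_lateral_petal = bivariate_pdf(
      marginal_model("normal", c(mean = 0.761, std = 0.027),
                     se = c(mean = 0.006, std = 0.004)),
      marginal_model("normal", c(mean = 1.08, std = 0.012),
                     se = c(mean = 0.002, std = 0.002)),
      copula_model("joe", 90, par1 = -2.15, se = c(par1 = 0.552))),
    ez_labellum = bivariate_pdf(
      marginal_model("normal", c(mean = 1.22, std = 0.070),
                     se = c(mean = 0.015, std = 0.011)),
      marginal_model("gamma", c(shape = 1370, rate = 1100),
                     se = c(shape = 423, rate = 339)),
      copula_model("gumbel", 180, par1 = 4.19, se = c(par1 = 0.764))))
  list(successive_blue = succ_blue, successive_yellow = succ_yellow,
       absolute = absolute, pdfs = pdfs)
}
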