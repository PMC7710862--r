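# Experience-dependent psychometric color-discrimination functions.
#
# Two closed forms are used, keyed by parameter count:
#   logistic3 (successive viewing):  pi = Mo*K / (Mo + (K - Mo) exp(-r dC))
#   logistic4 (absolute conditioning): pi = Mo + (K - Mo) / (1 + exp((xmid - dC)/scal))
# In the 3-parameter form K is the upper limit, Mo the value at dC = 0, r the
# increment rate (per Hu). In the 4-parameter form K and Mo are upper and
# lower asymptotes, xmid the inflection distance (Hu) and scal the rate scale
# (Hu). Reported probabilities are clamped at 0.5, the chance level of a
# two-alternative choice.

#' Construct a discrimination function
#'
#' @param form `"logistic3"` or `"logistic4"`.
#' @param coefficients Named numeric vector: `K, r, Mo` for logistic3;
#'   `K, Mo, xmid, scal` for logistic4.
#' @param clamp_floor Chance floor used when clamping (default 0.5).
#' @param ci95 Optional named list of length-2 confidence intervals.
#' @param loglik Optional fitted log-likelihood (set by [fit_discrimination()]).
#' @param n_obs Optional number of observations behind `loglik`.
#' @return An object of class `"discrimination_function"`.
#' @export
discrimination_function <- function(form = c("logistic3", "logistic4"),
                                    coefficients, clamp_floor = 0.5,
                                    ci95 = NULL, loglik = NA_real_,
                                    n_obs = NA_integer_) {
  form <- match.arg(form)
  need <- if (form == "logistic3") c("K", "r", "Mo") else c("K", "Mo", "xmid", "scal")
  if (!all(need %in% names(coefficients)))
    stop(sprintf("%s needs coefficients: %s", form, paste(need, collapse = ", ")))
  cf <- as.list(coefficients[need])
  if (form == "logistic3") {
    if (cf$r <= 0) stop("r must be positive")
    if (cf$Mo <= 0 || cf$K < cf$Mo) stop("need 0 < Mo <= K")
  } else {
    if (cf$scal <= 0) stop("scal must be positive")
    if (cf$xmid < 0) stop("xmid must be non-negative")
    if (cf$K < cf$Mo) stop("need Mo <= K")
  }
  structure(list(form = form, coefficients = cf, clamp_floor = clamp_floor,
                 ci95 = ci95, loglik = loglik, n_obs = n_obs),
            class = "discrimination_function")
}

#' @export
print.discrimination_function <- function(x, ...) {
  cat(sprintf("<discrimination_function: %s; %s>\n", x$form,
              paste(sprintf("%s=%.4g", names(x$coefficients),
                            unlist(x$coefficients)), collapse = ", ")))
  invisible(x)
}

#' Predicted probability of accurate discrimination
#'
#' Evaluates the psychometric function at color distance(s) `dC` (Hu). With
#' `clamp = TRUE` (the default) values below the chance floor of a
#' two-alternative task are reported as the floor (0.5).
#'
#' @param fn A [discrimination_function()].
#' @param dC Color distance(s) in hexagon units, all >= 0.
#' @param clamp Apply the chance floor?
#' @return Probability vector, same length as `dC`.
#' @export
eval_discrimination <- function(fn, dC, clamp = TRUE) {
  stopifnot(inherits(fn, "discrimination_function"))
  dC <- as.numeric(dC)
  if (any(dC < 0)) stop("color distances must be non-negative")
  cf <- fn$coefficients
  p <- if (fn$form == "logistic3") {
    cf$Mo * cf$K / (cf$Mo + (cf$K - cf$Mo) * exp(-cf$r * dC))
  } else {
    cf$Mo + (cf$K - cf$Mo) / (1 + exp((cf$xmid - dC) / cf$scal))
  }
  if (clamp) p <- pmax(p, fn$clamp_floor)
  p
}

#' Color distance at a target accuracy
#'
#' Solves \eqn{\pi(\Delta C) = target} for the unique distance by monotone
#' root finding (absolute tolerance 1e-8 Hu). The target must lie strictly
#' between the function's effective floor and its upper asymptote K.
#'
#' @param fn A [discrimination_function()].
#' @param target Probability, e.g. 0.75 for the pi75 threshold.
#' @return Distance in Hu.
#' @export
threshold_distance <- function(fn, target = 0.75) {
  stopifnot(inherits(fn, "discrimination_function"))
  cf <- fn$coefficients
  if (target >= cf$K)
    stop(sprintf("target %.3f is at or above the upper asymptote K = %.3f: no solution",
                 target, cf$K))
  floor_val <- max(fn$clamp_floor, eval_discrimination(fn, 0, clamp = FALSE))
  if (target <= floor_val)
    stop(sprintf("target %.3f is at or below the function floor %.3f: no solution",
                 target, floor_val))
  upper <- 1
  while (eval_discrimination(fn, upper, clamp = FALSE) < target && upper < 1e6)
    upper <- upper * 2
  stats::uniroot(function(d) eval_discrimination(fn, d, clamp = FALSE) - target,
                 interval = c(0, upper), tol = 1e-10)$root
}

#' Construct a behavioral choice dataset
#'
#' Per-subject proportion-correct data over a set of color distances. Either
#' counts (`n_correct`, `n_trials`) or a `proportion` column may be given.
#'
#' @param df data.frame with columns `subject_id`, `delta_c_hu` and either
#'   `n_correct` + `n_trials` or `proportion`.
#' @return The validated data.frame with a computed `proportion` column,
#'   class `"choice_dataset"`.
#' @export
choice_dataset <- function(df) {
  stopifnot(is.data.frame(df), all(c("subject_id", "delta_c_hu") %in% names(df)))
  if (!"proportion" %in% names(df)) {
    stopifnot(all(c("n_correct", "n_trials") %in% names(df)))
    if (any(df$n_correct < 0) || any(df$n_correct > df$n_trials))
      stop("n_correct must lie in [0, n_trials]")
    df$proportion <- df$n_correct / df$n_trials
  }
  if (any(df$delta_c_hu < 0)) stop("color distances must be non-negative")
  if (any(df$proportion < 0 | df$proportion > 1))
    stop("proportions must lie in [0, 1]")
  class(df) <- c("choice_dataset", "data.frame")
  df
}

#' Read a choice dataset from CSV
#'
#' Columns: `subject_id, delta_c_hu, n_correct, n_trials` (or `proportion`).
#'
#' @param path CSV path.
#' @return A [choice_dataset()].
#' @export
read_choice_csv <- function(path) choice_dataset(utils::read.csv(path))

self_start_logistic3 <- function(dC, prop) {
  K <- min(max(prop), 0.999)
  Mo <- max(min(prop), 0.501)
  if (Mo >= K) { Mo <- K - 0.05 }
  # rate from the steepest observed rise of the mean curve
  mu <- tapply(prop, dC, mean)
  xs <- as.numeric(names(mu))
  slopes <- diff(mu) / diff(xs)
  r <- max(4 * max(slopes, na.rm = TRUE) / max(K - Mo, 0.05), 1)
  c(K = K, r = min(r, 500), Mo = Mo)
}

self_start_logistic4 <- function(dC, prop) {
  K <- min(max(prop), 0.999)
  Mo <- max(min(prop), 1e-3)
  mu <- tapply(prop, dC, mean)
  xs <- as.numeric(names(mu))
  mid <- (K + Mo) / 2
  xmid <- xs[which.min(abs(mu - mid))]
  slopes <- diff(mu) / diff(xs)
  scal <- max(K - Mo, 0.05) / max(4 * max(slopes, na.rm = TRUE), 1)
  c(K = K, Mo = Mo, xmid = max(xmid, 1e-3), scal = max(scal, 1e-4))
}

#' Fit a discrimination function to choice data
#'
#' Fixed-effect coefficients are estimated by nonlinear least squares on the
#' proportions (Gaussian residuals, Levenberg-Marquardt). When
#' `random_param` names a coefficient and the data contain at least two
#' subjects, a per-subject Gaussian deviation on that single coefficient is
#' estimated with a nonlinear mixed-effects model (subject as the grouping
#' factor); if the mixed fit fails to converge the fixed-effects fit is
#' returned with a warning.
#'
#' @param data A [choice_dataset()] (or a data.frame accepted by it).
#' @param form `"logistic3"` or `"logistic4"`.
#' @param random_param Coefficient name to carry the per-subject random
#'   deviation, or `"none"`.
#' @return A [discrimination_function()] with 95% CIs (t-based; the
#'   coefficient carrying the random term uses containment degrees of
#'   freedom, subjects minus one) and the fitted log-likelihood.
#' @export
fit_discrimination <- function(data, form = c("logistic3", "logistic4"),
                               random_param = "none") {
  form <- match.arg(form)
  data <- choice_dataset(as.data.frame(data))
  n_levels <- length(unique(data$delta_c_hu))
  n_par <- if (form == "logistic3") 3L else 4L
  if (n_levels < n_par)
    stop(sprintf("%s requires at least %d distinct color-distance levels, got %d",
                 form, n_par, n_levels))
  par_names <- if (form == "logistic3") c("K", "r", "Mo") else c("K", "Mo", "xmid", "scal")
  if (random_param != "none") {
    if (!random_param %in% par_names)
      stop(sprintf("random_param must be one of: %s", paste(par_names, collapse = ", ")))
    if (length(unique(data$subject_id)) < 2)
      stop("a random term requires at least two subjects")
  }
  df <- data.frame(dC = data$delta_c_hu, prop = data$proportion,
                   subject = factor(data$subject_id))
  if (form == "logistic3") {
    start <- self_start_logistic3(df$dC, df$prop)
    model <- prop ~ Mo * K / (Mo + (K - Mo) * exp(-r * dC))
    lower <- c(K = 0.5, r = 1e-3, Mo = 0.3)
    upper <- c(K = 1.2, r = 2000, Mo = 1.1)
  } else {
    start <- self_start_logistic4(df$dC, df$prop)
    model <- prop ~ Mo + (K - Mo) / (1 + exp((xmid - dC) / scal))
    lower <- c(K = 0.5, Mo = 0, xmid = 0, scal = 1e-5)
    upper <- c(K = 1.2, Mo = 1, xmid = 2, scal = 2)
  }
  fit <- minpack.lm::nlsLM(model, data = df, start = as.list(start),
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  ll <- as.numeric(stats::logLik(fit))
  crit <- stats::setNames(rep(stats::qt(0.975, nrow(df) - n_par), n_par),
                          names(est))
  if (random_param != "none") {
    mixed <- tryCatch({
      fixed_fml <- stats::as.formula(paste(paste(par_names, collapse = " + "), "~ 1"))
      random_fml <- stats::as.formula(paste(random_param, "~ 1 | subject"))
      m <- nlme::nlme(model, data = df, fixed = fixed_fml, random = random_fml,
                      start = est[par_names],
                      control = nlme::nlmeControl(maxIter = 200, pnlsMaxIter = 20,
                                                  returnObject = TRUE))
      list(est = nlme::fixef(m),
           se = sqrt(diag(m$varFix)),
           ll = as.numeric(stats::logLik(m)),
           df = m$fixDF$X,
           n_groups = length(unique(df$subject)))
    }, error = function(e) NULL)
    if (is.null(mixed)) {
      warning("mixed-effects fit did not converge; returning fixed-effects fit")
    } else {
      est <- mixed$est; se <- mixed$se; ll <- mixed$ll
      crit <- stats::qt(0.975, mixed$df[names(est)])
      names(crit) <- names(est)
      # containment df for the coefficient carrying the random term: its
      # between-subject information comes from n_groups subjects only
      crit[random_param] <- stats::qt(0.975, max(mixed$n_groups - 1, 1))
    }
  }
  est <- est[par_names]
  se <- se[par_names]
  crit <- crit[par_names]
  ci <- stats::setNames(lapply(seq_along(est), function(i)
    est[[i]] + c(-1, 1) * crit[[i]] * se[[i]]), par_names)
  discrimination_function(form, est, ci95 = ci, loglik = ll,
                          n_obs = nrow(df))
}

#' Likelihood-ratio comparison of nested discrimination fits
#'
#' Compares a smaller against a larger nested fit on the same data:
#' chi-square = 2 (ll_large - ll_small), df = difference in parameter count,
#' p from the chi-square distribution. Following standard model-selection
#' practice the simpler form is preferred when p >= 0.05.
#'
#' @param fit_small,fit_large Fitted [discrimination_function()]s from
#'   [fit_discrimination()], `fit_small` with fewer parameters, both fit to
#'   the same observations.
#' @return List with `chi_sq`, `df`, `p_value`, `preferred`.
#' @export
lrt_compare <- function(fit_small, fit_large) {
  stopifnot(inherits(fit_small, "discrimination_function"),
            inherits(fit_large, "discrimination_function"))
  k_small <- length(fit_small$coefficients)
  k_large <- length(fit_large$coefficients)
  if (k_large <= k_small)
    stop("fit_large must have more parameters than fit_small")
  if (is.na(fit_small$loglik) || is.na(fit_large$loglik))
    stop("both fits need log-likelihoods (use fit_discrimination)")
  if (!is.na(fit_small$n_obs) && !is.na(fit_large$n_obs) &&
      fit_small$n_obs != fit_large$n_obs)
    stop("fits were not made on the same data")
  chi_sq <- 2 * (fit_large$loglik - fit_small$loglik)
  if (chi_sq < -1e-6)
    warning("larger model has lower likelihood: check convergence")
  chi_sq <- max(chi_sq, 0)
  df <- k_large - k_small
  p <- stats::pchisq(chi_sq, df = df, lower.tail = FALSE)
  list(chi_sq = chi_sq, df = df, p_value = p,
       preferred = if (p >= 0.05) fit_small$form else fit_large$form)
}

#' Studentized bootstrap test for equality of means
#'
#' Two-sample bootstrap test of H0: equal means. Both samples are recentered
#' to the pooled mean before resampling, the studentized difference of means
#' \eqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}} is computed on
#' each resample, and the two-sided p-value is the fraction of resampled
#' |t*| at least as large as the observed |t|.
#'
#' @param a,b Numeric vectors (e.g. predicted accuracies on a common grid).
#' @param n_resamples Number of bootstrap resamples (default 100000).
#' @param seed Integer seed for reproducibility.
#' @return List with `t_Ho` (observed studentized statistic), `p_value`,
#'   `n_resamples`.
#' @export
bootstrap_mean_equality <- function(a, b, n_resamples = 100000, seed = 1) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  va <- stats::var(a); vb <- stats::var(b)
  if (is.na(va) || is.na(vb) || (va == 0 && vb == 0))
    stop("degenerate (zero-variance) inputs")
  na <- length(a); nb <- length(b)
  t_stat <- function(x, y)
    (mean(x) - mean(y)) / sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  t_obs <- t_stat(a, b)
  pooled <- mean(c(a, b))
  a0 <- a - mean(a) + pooled
  b0 <- b - mean(b) + pooled
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # vectorized over resamples: matrix of resampled indices
  am <- matrix(a0[sample.int(na, na * n_resamples, replace = TRUE)], nrow = na)
  bm <- matrix(b0[sample.int(nb, nb * n_resamples, replace = TRUE)], nrow = nb)
  ma <- colMeans(am); mb <- colMeans(bm)
  va_s <- (colSums(am^2) - na * ma^2) / (na - 1)
  vb_s <- (colSums(bm^2) - nb * mb^2) / (nb - 1)
  tstar <- (ma - mb) / sqrt(va_s / na + vb_s / nb)
  p <- mean(abs(tstar) >= abs(t_obs))
  list(t_Ho = t_obs, p_value = p, n_resamples = n_resamples)
}

#' Serialize a discrimination function to JSON
#'
#' @param fn A [discrimination_function()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discrimination_json <- function(fn, path) {
  stopifnot(inherits(fn, "discrimination_function"))
  jsonlite::write_json(
    list(form = fn$form, coefficients = fn$coefficients, ci95 = fn$ci95,
         clamp_floor = fn$clamp_floor, loglik = fn$loglik),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a discrimination function from JSON
#'
#' @param path Path written by [write_discrimination_json()] (or hand-written
#'   with the same fields, e.g. externally published simultaneous-viewing
#'   coefficients).
#' @return A [discrimination_function()].
#' @export
read_discrimination_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  discrimination_function(x$form, unlist(x$coefficients),
                          clamp_floor = x$clamp_floor %||% 0.5,
                          ci95 = x$ci95,
                          loglik = x$loglik %||% NA_real_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
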