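# Bivariate copulas for modelling the dependence structure of color-locus
# clouds: Gumbel and Tawn type II (both extreme-value copulas, implemented
# through their Pickands dependence functions), Joe (Archimedean), and the
# independence copula. Rotations by 90/180/270 degrees are true rotations of
# the density on the unit square — 90: c(u,v) = c0(v, 1-u); 180 ("survival"):
# c0(1-u, 1-v); 270: c0(1-v, u) — the convention of the vine-copula
# literature. For exchangeable families a 90/270 rotation coincides with the
# simpler argument reflection c0(1-u, v) / c0(u, 1-v); they differ only for
# the asymmetric Tawn family. Printed negative dependence parameters for
# 90/270-degree rotations mean: the base family uses |par1| and the rotation
# supplies the negative association.
#
# Conventions fixed here (documented in the methods vignette):
#  - Extreme-value form: C(u,v) = exp(ln(uv) * A(t)), t = ln(u)/ln(uv).
#  - Tawn type II Pickands function:
#      A(t) = (1 - psi) t + ((1-t)^theta + (psi t)^theta)^(1/theta),
#    theta >= 1, psi in [0,1]; psi = 1 recovers Gumbel. The asymmetry weight
#    attaches to the first argument's share of ln(uv).

UV_EPS <- 1e-12

.clip01 <- function(x) pmin(pmax(x, UV_EPS), 1 - UV_EPS)

#' Construct a copula model
#'
#' @param family `"gumbel"`, `"joe"`, `"tawn2"` or `"independence"`.
#' @param rotation Rotation of the density in degrees: 0, 90, 180 or 270.
#'   180 is the survival copula; 90 and 270 produce negative dependence from
#'   a positive-dependence base family.
#' @param par1 Dependence parameter theta as conventionally printed: for 90
#'   and 270 degree rotations a negative value whose magnitude is the
#'   base-family parameter.
#' @param par2 Asymmetry weight psi in `[0, 1]` (tawn2 only).
#' @param se Optional named standard errors.
#' @return An object of class `"copula_model"`.
#' @export
copula_model <- function(family = c("gumbel", "joe", "tawn2", "independence"),
                         rotation = 0, par1 = NA_real_, par2 = NA_real_,
                         se = NULL) {
  family <- match.arg(family)
  if (!rotation %in% c(0, 90, 180, 270))
    stop("rotation must be one of 0, 90, 180, 270")
  if (family == "independence") {
    rotation <- 0; par1 <- NA_real_; par2 <- NA_real_
  } else {
    if (is.na(par1)) stop("par1 is required for this family")
    if (rotation %in% c(90, 270)) {
      if (par1 > 0)
        warning("positive par1 with a 90/270 rotation: interpreting magnitude")
    }
    theta <- abs(par1)
    if (theta < 1)
      stop(sprintf("|par1| = %.3f outside the admissible range [1, Inf) for %s",
                   theta, family))
    if (family == "tawn2") {
      if (is.na(par2) || par2 < 0 || par2 > 1)
        stop("tawn2 needs par2 (asymmetry weight) in [0, 1]")
    } else par2 <- NA_real_
  }
  structure(list(family = family, rotation = rotation,
                 par1 = par1, par2 = par2, se = se),
            class = "copula_model")
}

#' @export
print.copula_model <- function(x, ...) {
  if (x$family == "independence") cat("<copula_model: independence>\n")
  else cat(sprintf("<copula_model: %s %d deg, par1=%.4g%s>\n", x$family,
                   x$rotation, x$par1,
                   if (!is.na(x$par2)) sprintf(", par2=%.4g", x$par2) else ""))
  invisible(x)
}

# ---- Pickands dependence functions (extreme-value families) --------------

pickands <- function(family, t, theta, psi) {
  if (family == "gumbel")
    (t^theta + (1 - t)^theta)^(1 / theta)
  else                                     # tawn2
    (1 - psi) * t + ((1 - t)^theta + (psi * t)^theta)^(1 / theta)
}

pickands_d1 <- function(family, t, theta, psi) {
  if (family == "gumbel") {
    B <- t^theta + (1 - t)^theta
    B^(1 / theta - 1) * (t^(theta - 1) - (1 - t)^(theta - 1))
  } else {
    B <- (1 - t)^theta + (psi * t)^theta
    (1 - psi) + B^(1 / theta - 1) * (psi^theta * t^(theta - 1) - (1 - t)^(theta - 1))
  }
}

pickands_d2 <- function(family, t, theta, psi) {
  if (family == "gumbel") {
    B <- t^theta + (1 - t)^theta
    Bp <- t^(theta - 1) - (1 - t)^(theta - 1)
    (theta - 1) * B^(1 / theta - 2) *
      (B * (t^(theta - 2) + (1 - t)^(theta - 2)) - Bp^2)
  } else {
    B <- (1 - t)^theta + (psi * t)^theta
    Bp <- psi^theta * t^(theta - 1) - (1 - t)^(theta - 1)
    (theta - 1) * B^(1 / theta - 2) *
      (B * (psi^theta * t^(theta - 2) + (1 - t)^(theta - 2)) - Bp^2)
  }
}

# ---- Base-family CDF, partial derivatives (h-functions) and density ------

base_fns <- function(family, theta, psi) {
  if (family == "independence") {
    return(list(
      cdf = function(u, v) u * v,
      du = function(u, v) v,
      dv = function(u, v) u,
      dens = function(u, v) rep(1, max(length(u), length(v)))))
  }
  if (family %in% c("gumbel", "tawn2")) {
    list(
      cdf = function(u, v) {
        s <- log(u) + log(v); t <- log(u) / s
        exp(s * pickands(family, t, theta, psi))
      },
      du = function(u, v) {
        s <- log(u) + log(v); t <- log(u) / s
        A <- pickands(family, t, theta, psi)
        A1 <- pickands_d1(family, t, theta, psi)
        exp(s * A) * (A + (1 - t) * A1) / u
      },
      dv = function(u, v) {
        s <- log(u) + log(v); t <- log(u) / s
        A <- pickands(family, t, theta, psi)
        A1 <- pickands_d1(family, t, theta, psi)
        exp(s * A) * (A - t * A1) / v
      },
      dens = function(u, v) {
        s <- log(u) + log(v); t <- log(u) / s
        A <- pickands(family, t, theta, psi)
        A1 <- pickands_d1(family, t, theta, psi)
        A2 <- pickands_d2(family, t, theta, psi)
        exp(s * A) / (u * v) *
          ((A - t * A1) * (A + (1 - t) * A1) - t * (1 - t) * A2 / s)
      })
  } else {                                  # joe
    list(
      cdf = function(u, v) {
        a <- (1 - u)^theta; b <- (1 - v)^theta
        1 - (a + b - a * b)^(1 / theta)
      },
      du = function(u, v) {
        a <- (1 - u)^theta; b <- (1 - v)^theta
        (1 - u)^(theta - 1) * (1 - b) * (a + b - a * b)^(1 / theta - 1)
      },
      dv = function(u, v) {
        a <- (1 - u)^theta; b <- (1 - v)^theta
        (1 - v)^(theta - 1) * (1 - a) * (a + b - a * b)^(1 / theta - 1)
      },
      dens = function(u, v) {
        a <- (1 - u)^theta; b <- (1 - v)^theta
        Tt <- a + b - a * b
        Tt^(1 / theta - 2) * (1 - u)^(theta - 1) * (1 - v)^(theta - 1) *
          (theta - 1 + Tt)
      })
  }
}

cop_fns <- function(cop) {
  stopifnot(inherits(cop, "copula_model"))
  theta <- if (is.na(cop$par1)) NA_real_ else abs(cop$par1)
  f0 <- base_fns(cop$family, theta, cop$par2)
  rot <- cop$rotation
  if (rot == 0) return(f0)
  if (rot == 90) {
    # (U, V) = (1 - V0, U0): C(u,v) = v - C0(v, 1-u)
    list(cdf = function(u, v) v - f0$cdf(v, 1 - u),
         du = function(u, v) f0$dv(v, 1 - u),
         dv = function(u, v) 1 - f0$du(v, 1 - u),
         dens = function(u, v) f0$dens(v, 1 - u))
  } else if (rot == 180) {
    # (U, V) = (1 - U0, 1 - V0): survival copula
    list(cdf = function(u, v) u + v - 1 + f0$cdf(1 - u, 1 - v),
         du = function(u, v) 1 - f0$du(1 - u, 1 - v),
         dv = function(u, v) 1 - f0$dv(1 - u, 1 - v),
         dens = function(u, v) f0$dens(1 - u, 1 - v))
  } else {
    # (U, V) = (V0, 1 - U0): C(u,v) = u - C0(1-v, u)
    list(cdf = function(u, v) u - f0$cdf(1 - v, u),
         du = function(u, v) 1 - f0$dv(1 - v, u),
         dv = function(u, v) f0$du(1 - v, u),
         dens = function(u, v) f0$dens(1 - v, u))
  }
}

#' Copula density
#'
#' Evaluates the copula density c(u, v) with the model's rotation applied.
#'
#' @param cop A [copula_model()].
#' @param u,v Numeric vectors in (0, 1).
#' @return Density values.
#' @export
copula_density <- function(cop, u, v) {
  if (any(u <= 0 | u >= 1) || any(v <= 0 | v >= 1))
    stop("u and v must lie strictly inside (0, 1)")
  cop_fns(cop)$dens(u, v)
}

#' Copula CDF
#'
#' @param cop A [copula_model()].
#' @param u,v Numeric vectors in (0, 1).
#' @return C(u, v).
#' @export
copula_cdf <- function(cop, u, v) {
  if (any(u <= 0 | u >= 1) || any(v <= 0 | v >= 1))
    stop("u and v must lie strictly inside (0, 1)")
  cop_fns(cop)$cdf(u, v)
}

#' Conditional distribution (h-function) of a copula
#'
#' `h(v | u) = dC(u, v)/du`, the conditional CDF of V given U = u. Monotone
#' increasing in `v`; the basis of conditional-inversion sampling.
#'
#' @param cop A [copula_model()].
#' @param u,v Numeric vectors in (0, 1).
#' @return Conditional probabilities.
#' @export
copula_hfun <- function(cop, u, v) {
  if (any(u <= 0 | u >= 1) || any(v <= 0 | v >= 1))
    stop("u and v must lie strictly inside (0, 1)")
  cop_fns(cop)$du(u, v)
}

#' Sample from a copula by conditional inversion
#'
#' Draws `(u, w)` uniform and solves `h(v | u) = w` for `v` by bisection
#' (vectorized over samples, absolute tolerance 1e-10). Works for every
#' supported family and rotation because only the h-function is needed.
#'
#' @param cop A [copula_model()].
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return Two-column matrix of `(u, v)` pairs.
#' @export
copula_sample <- function(cop, n, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(matrix(numeric(0), ncol = 2,
                            dimnames = list(NULL, c("u", "v"))))
  u <- .clip01(stats::runif(n))
  w <- stats::runif(n)
  if (cop$family == "independence")
    return(cbind(u = u, v = .clip01(w)))
  fns <- cop_fns(cop)
  lo <- rep(UV_EPS, n)
  hi <- rep(1 - UV_EPS, n)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- fns$du(u, mid) < w
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-10) break
  }
  cbind(u = u, v = (lo + hi) / 2)
}

#' Kendall's tau of a copula by numeric integration
#'
#' Computes \eqn{\tau = 1 - 4 \int\!\!\int \partial_u C \,\partial_v C
#' \,du\,dv} by tensor-product Gauss-Legendre quadrature on the unit square,
#' using the analytic partial derivatives. Serves as the deterministic
#' reference against which empirical tau of samples is checked.
#'
#' @param cop A [copula_model()].
#' @param n_nodes Quadrature nodes per axis (default 96).
#' @return Kendall's tau.
#' @export
copula_tau <- function(cop, n_nodes = 96) {
  if (cop$family == "independence") return(0)
  gl <- pracma::gaussLegendre(n_nodes, UV_EPS, 1 - UV_EPS)
  fns <- cop_fns(cop)
  U <- rep(gl$x, times = n_nodes)
  V <- rep(gl$x, each = n_nodes)
  W <- rep(gl$w, times = n_nodes) * rep(gl$w, each = n_nodes)
  integral <- sum(W * fns$du(U, V) * fns$dv(U, V))
  1 - 4 * integral
}

#' Fast empirical Kendall's tau
#'
#' O(n log n) inversion-counting estimate of Kendall's tau for continuous
#' (tie-free) data; ties are broken by jittering ranks infinitesimally via
#' stable ordering.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Empirical tau.
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  yy <- y[order(x, y)]
  count_inv <- function(v) {
    n <- length(v)
    if (n < 2) return(list(inv = 0, sorted = v))
    half <- n %/% 2
    L <- count_inv(v[1:half])
    R <- count_inv(v[(half + 1):n])
    # pairs (l in L, r in R) with l > r
    cross <- sum(length(L$sorted) - findInterval(R$sorted, L$sorted))
    list(inv = L$inv + R$inv + cross,
         sorted = sort(c(L$sorted, R$sorted)))
  }
  disc <- count_inv(yy)$inv
  1 - 4 * disc / (n * (n - 1))
}

#' Fit a copula to pseudo-observations by maximum likelihood
#'
#' Fits every candidate family/rotation combination by ML (L-BFGS-B on the
#' log-density) and selects the winner by AIC. Standard errors come from the
#' numeric Hessian at the optimum. Printed `par1` follows the sign
#' convention: negative for 90/270-degree rotations.
#'
#' @param uv Two-column matrix of (u, v) pseudo-observations in (0, 1).
#' @param candidate_families Character vector of families to try (default
#'   all four supported).
#' @param rotations Rotations to try for each non-independence family.
#' @return The winning [copula_model()] with an `aic` attribute.
#' @export
fit_copula <- function(uv, candidate_families = c("gumbel", "joe", "tawn2",
                                                  "independence"),
                       rotations = c(0, 90, 180, 270)) {
  uv <- as.matrix(uv)
  stopifnot(ncol(uv) == 2)
  if (nrow(uv) < 20) stop("need at least 20 pseudo-observations")
  if (any(uv <= 0 | uv >= 1)) stop("pseudo-observations must lie in (0, 1)")
  u <- .clip01(uv[, 1]); v <- .clip01(uv[, 2])
  best <- NULL
  for (fam in candidate_families) {
    if (fam == "independence") {
      cand <- list(model = copula_model("independence"), aic = 0, ll = 0)
      if (is.null(best) || cand$aic < best$aic) best <- cand
      next
    }
    rots <- rotations
    for (rot in rots) {
      nll <- function(p) {
        th <- p[1]; ps <- if (fam == "tawn2") p[2] else NA_real_
        m <- copula_model(fam, rot,
                          par1 = if (rot %in% c(90, 270)) -th else th,
                          par2 = ps)
        d <- tryCatch(copula_density(m, u, v), error = function(e) NULL)
        if (is.null(d) || any(!is.finite(d)) || any(d <= 0)) return(1e10)
        -sum(log(d))
      }
      p0 <- if (fam == "tawn2") c(2, 0.5) else 2
      lower <- if (fam == "tawn2") c(1 + 1e-6, 1e-6) else 1 + 1e-6
      upper <- if (fam == "tawn2") c(50, 1 - 1e-6) else 50
      opt <- tryCatch(
        stats::optim(p0, nll, method = "L-BFGS-B", lower = lower,
                     upper = upper, hessian = TRUE),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) next
      k <- length(p0)
      aic <- 2 * opt$value + 2 * k
      se <- tryCatch({
        vc <- solve(opt$hessian)
        sq <- sqrt(pmax(diag(vc), 0))
        stats::setNames(sq, c("par1", "par2")[seq_len(k)])
      }, error = function(e) NULL)
      th <- opt$par[1]
      model <- copula_model(fam, rot,
                            par1 = if (rot %in% c(90, 270)) -th else th,
                            par2 = if (fam == "tawn2") opt$par[2] else NA_real_,
                            se = se)
      cand <- list(model = model, aic = aic, ll = -opt$value)
      if (is.null(best) || cand$aic < best$aic) best <- cand
    }
  }
  if (is.null(best)) stop("no candidate copula converged")
  out <- best$model
  attr(out, "aic") <- best$aic
  attr(out, "loglik") <- best$ll
  out
}
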