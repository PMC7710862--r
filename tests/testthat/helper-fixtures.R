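# Shared fixtures and small independent oracles used across test files.

fx <- bee_fixtures()

# independent bisection oracle for threshold distances: halves an interval on
# the raw closed form without using threshold_distance()
oracle_threshold <- function(fn, target, lo = 0, hi = 1, iter = 60) {
  f <- function(d) {
    cf <- fn$coefficients
    if (fn$form == "logistic3")
      cf$Mo * cf$K / (cf$Mo + (cf$K - cf$Mo) * exp(-cf$r * d))
    else
      cf$Mo + (cf$K - cf$Mo) / (1 + exp((cf$xmid - d) / cf$scal))
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Gauss-Legendre double integral of a function over (0,1)^2
unit_square_integral <- function(f, n = 96) {
  gl <- pracma::gaussLegendre(n, 1e-9, 1 - 1e-9)
  U <- rep(gl$x, times = n); V <- rep(gl$x, each = n)
  W <- rep(gl$w, times = n) * rep(gl$w, each = n)
  sum(W * f(U, V))
}

# finite-difference mixed partial of the copula CDF (independent density oracle)
fd_copula_density <- function(cop, u, v, h = 1e-5) {
  (copula_cdf(cop, u + h, v + h) - copula_cdf(cop, u - h, v + h) -
     copula_cdf(cop, u + h, v - h) + copula_cdf(cop, u - h, v - h)) / (4 * h^2)
}

# the four published copula models, for parameterized copula tests
fixture_copulas <- function() {
  list(wc_petal = fx$pdfs$wc_petal$copula,
       wc_pollen = fx$pdfs$wc_pollen$copula,
       ez_lateral_petal = fx$pdfs$ez_lateral_petal$copula,
       ez_labellum = fx$pdfs$ez_labellum$copula)
}
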