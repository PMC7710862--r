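test_that("copula parameter validation enforces admissible ranges", {
  expect_error(copula_model("gumbel", 0, par1 = 0.5), "admissible")
  expect_error(copula_model("tawn2", 0, par1 = 3), "par2")
  expect_error(copula_model("tawn2", 0, par1 = 3, par2 = 1.4), "par2")
  expect_error(copula_model("gumbel", 45, par1 = 2), "rotation")
  expect_error(copula_density(copula_model("gumbel", 0, par1 = 2),
                              c(0.5, 1.2), c(0.5, 0.5)), "inside")
})

test_that("gumbel reduces to independence at theta = 1 and is exchangeable", {
  ind <- copula_model("gumbel", 0, par1 = 1)
  set.seed(41)
  u <- runif(20, 0.02, 0.98); v <- runif(20, 0.02, 0.98)
  expect_equal(copula_density(ind, u, v), rep(1, 20), tolerance = 1e-9)
  g2 <- copula_model("gumbel", 0, par1 = 2)
  expect_equal(copula_density(g2, u, v), copula_density(g2, v, u),
               tolerance = 1e-12)
})

test_that("analytic densities match the finite-difference mixed partial of the CDF", {
  set.seed(42)
  u <- runif(8, 0.05, 0.95); v <- runif(8, 0.05, 0.95)
  for (cop in c(fixture_copulas(),
                list(copula_model("tawn2", 90, par1 = -3, par2 = 0.6),
                     copula_model("joe", 270, par1 = -2.5)))) {
    expect_equal(copula_density(cop, u, v), fd_copula_density(cop, u, v),
                 tolerance = 1e-4)
  }
})

test_that("h-functions are the u-derivative of the CDF and monotone in v", {
  set.seed(43)
  u <- runif(8, 0.05, 0.95); v <- runif(8, 0.05, 0.95)
  for (cop in fixture_copulas()) {
    hfd <- (copula_cdf(cop, u + 1e-6, v) - copula_cdf(cop, u - 1e-6, v)) / 2e-6
    expect_equal(copula_hfun(cop, u, v), hfd, tolerance = 1e-5)
    vv <- seq(0.01, 0.99, by = 0.01)
    expect_true(all(diff(copula_hfun(cop, rep(0.37, length(vv)), vv)) > 0))
  }
})

test_that("copula densities integrate to one and have uniform sample margins", {
  i <- 0
  for (cop in fixture_copulas()) {
    i <- i + 1
    total <- unit_square_integral(function(u, v) copula_density(cop, u, v))
    expect_equal(total, 1, tolerance = 1e-3)
    # the inverted (conditional) coordinate must come out uniform
    uv <- copula_sample(cop, 5000, seed = 440 + i)
    expect_gt(stats::ks.test(uv[, 2], "punif")$p.value, 0.01)
  }
})

test_that("empirical Kendall tau of samples matches the numeric-integration oracle", {
  # the four published dependence models
  for (cop in fixture_copulas()) {
    uv <- copula_sample(cop, 30000, seed = 45)
    expect_lt(abs(kendall_tau(uv[, 1], uv[, 2]) - copula_tau(cop)), 0.02)
  }
  # closed-form anchors: gumbel tau = 1 - 1/theta, independence tau = 0
  expect_equal(copula_tau(copula_model("gumbel", 0, par1 = 2)), 0.5,
               tolerance = 1e-4)
  expect_equal(copula_tau(copula_model("gumbel", 180, par1 = 4.19)),
               1 - 1 / 4.19, tolerance = 1e-4)
  uv0 <- copula_sample(copula_model("gumbel", 0, par1 = 1), 50000, seed = 46)
  expect_lt(abs(kendall_tau(uv0[, 1], uv0[, 2])), 0.01)
  uvg <- copula_sample(copula_model("gumbel", 0, par1 = 2), 50000, seed = 47)
  expect_equal(kendall_tau(uvg[, 1], uvg[, 2]), 0.5, tolerance = 0.01)
  # 90-degree rotated joe with printed negative parameter: negative dependence
  joe90 <- copula_model("joe", 90, par1 = -2.15)
  uvj <- copula_sample(joe90, 30000, seed = 48)
  tj <- kendall_tau(uvj[, 1], uvj[, 2])
  expect_lt(tj, 0)
  expect_lt(abs(tj - copula_tau(joe90)), 0.02)
})

test_that("kendall_tau agrees with cor(method = 'kendall') on small samples", {
  set.seed(49)
  x <- rnorm(300); y <- 0.5 * x + rnorm(300)
  expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"),
               tolerance = 1e-10)
})

test_that("rotating twice by 180 degrees reproduces the base density", {
  set.seed(50)
  u <- runif(10, 0.05, 0.95); v <- runif(10, 0.05, 0.95)
  base <- copula_model("tawn2", 0, par1 = 3.61, par2 = 0.49)
  surv <- copula_model("tawn2", 180, par1 = 3.61, par2 = 0.49)
  expect_equal(copula_density(base, u, v),
               copula_density(surv, 1 - u, 1 - v), tolerance = 1e-12)
})

test_that("ML copula fitting recovers parameters and identifies independence", {
  uv <- copula_sample(copula_model("gumbel", 0, par1 = 3), 5000, seed = 51)
  fit <- fit_copula(uv, candidate_families = "gumbel", rotations = 0)
  expect_gte(fit$par1, 2.8); expect_lte(fit$par1, 3.2)
  expect_true(!is.null(fit$se))
  set.seed(52)
  ind <- cbind(runif(2000), runif(2000))
  best <- fit_copula(ind)
  expect_lt(abs(copula_tau(best)), 0.03)
  expect_error(fit_copula(cbind(runif(10), runif(10))), "at least 20")
})
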