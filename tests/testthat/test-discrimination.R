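test_that("discrimination functions evaluate to their published predictions", {
  # at zero distance the 3-parameter form reduces to Mo
  expect_equal(eval_discrimination(fx$successive_blue, 0, clamp = FALSE), 0.528)
  expect_equal(eval_discrimination(fx$successive_blue, 0.056), 0.949,
               tolerance = 0.005 / 0.949)
  expect_equal(eval_discrimination(fx$absolute, 0.138), 0.841,
               tolerance = 0.005 / 0.841)
  # raw values below chance floor to 0.5 when clamped
  expect_equal(eval_discrimination(fx$absolute, 0.01), 0.5)
  expect_lt(eval_discrimination(fx$absolute, 0.01, clamp = FALSE), 0.5)
  expect_error(eval_discrimination(fx$absolute, -0.1), "non-negative")
})

test_that("threshold solving matches an independent bisection oracle", {
  d75_abs <- threshold_distance(fx$absolute, 0.75)
  expect_equal(d75_abs, oracle_threshold(fx$absolute, 0.75), tolerance = 1e-7)
  expect_equal(d75_abs, 0.092, tolerance = 0.005 / 0.092)
  d75_blue <- threshold_distance(fx$successive_blue, 0.75)
  expect_equal(d75_blue, oracle_threshold(fx$successive_blue, 0.75),
               tolerance = 1e-7)
  expect_equal(d75_blue, 0.0187, tolerance = 1e-3)
  expect_error(threshold_distance(fx$successive_blue, 0.999), "no solution")
  expect_error(threshold_distance(fx$successive_blue, 0.4), "no solution")
})

test_that("fitted and fixture functions are monotone with the right asymptotes", {
  fns <- list(fx$successive_blue, fx$successive_yellow, fx$absolute)
  grid <- seq(0, 1, by = 1e-3)
  for (fn in fns) {
    p <- eval_discrimination(fn, grid, clamp = FALSE)
    expect_true(all(diff(p) >= -1e-12))
    expect_equal(eval_discrimination(fn, 10, clamp = FALSE),
                 fn$coefficients$K, tolerance = 1e-6)
  }
  expect_equal(eval_discrimination(fx$absolute, 0, clamp = FALSE),
               fx$absolute$coefficients$Mo, tolerance = 1e-3)
})

test_that("threshold_distance inverts eval_discrimination on its domain", {
  for (fn in list(fx$successive_blue, fx$absolute)) {
    floor_val <- eval_discrimination(fn, 0, clamp = FALSE)
    targets <- seq(max(floor_val, 0.5) + 0.02, fn$coefficients$K - 0.02,
                   length.out = 7)
    for (tg in targets) {
      d <- threshold_distance(fn, tg)
      expect_equal(eval_discrimination(fn, d, clamp = FALSE), tg,
                   tolerance = 1e-6)
    }
  }
})

test_that("simulated choice data recover the generating coefficients", {
  # successive-type generator: 10 distance levels, 5 bees, subject variation
  # on the rate (the second-listed coefficient), binomial n = 100 per level
  lv <- seq(0.005, 0.12, length.out = 10)
  truth3 <- unlist(fx$successive_blue$coefficients)
  hits <- 0; total <- 0
  for (i in 1:50) {
    d <- make_choice_data(fx$successive_blue, lv, n_subjects = 5,
                          subject_sd = 5, random_param = "r",
                          n_trials = 100, seed = 100 + i)
    f <- suppressWarnings(fit_discrimination(d, "logistic3", random_param = "r"))
    for (nm in names(truth3)) {
      hits <- hits + (truth3[nm] >= f$ci95[[nm]][1] && truth3[nm] <= f$ci95[[nm]][2])
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.90)
})

test_that("logistic4 fits recover absolute-conditioning coefficients", {
  # stimulus levels concentrated around the steep transition, as in a
  # threshold-focused psychophysical design
  lv4 <- c(0.02, 0.05, 0.065, 0.075, 0.085, 0.095, 0.11, 0.14, 0.2)
  truth4 <- unlist(fx$absolute$coefficients)
  hits <- 0; total <- 0
  for (i in 1:50) {
    d <- make_choice_data(fx$absolute, lv4, n_subjects = 9, subject_sd = 0,
                          n_trials = 100, seed = 200 + i)
    f <- fit_discrimination(d, "logistic4")
    for (nm in names(truth4)) {
      hits <- hits + (truth4[nm] >= f$ci95[[nm]][1] && truth4[nm] <= f$ci95[[nm]][2])
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.90)
})

test_that("under-determined choice data are rejected", {
  d <- data.frame(subject_id = "b1", delta_c_hu = 0.05, n_correct = 80,
                  n_trials = 100)
  expect_error(fit_discrimination(d, "logistic3"), "levels")
  d3 <- data.frame(subject_id = "b1", delta_c_hu = c(0.02, 0.05, 0.08),
                   n_correct = c(55, 70, 90), n_trials = 100)
  expect_error(fit_discrimination(d3, "logistic4"), "levels")
})

test_that("likelihood-ratio comparison behaves at identity and detects a true lower asymptote", {
  lv4 <- c(0.02, 0.05, 0.065, 0.075, 0.085, 0.095, 0.11, 0.14, 0.2)
  d <- make_choice_data(fx$absolute, lv4, n_subjects = 9, n_trials = 100,
                        seed = 301)
  f3 <- fit_discrimination(d, "logistic3")
  f4 <- fit_discrimination(d, "logistic4")
  cmp <- lrt_compare(f3, f4)
  expect_gte(cmp$chi_sq, -1e-6)
  expect_equal(cmp$df, 1)
  # identical model refit against itself: reuse f3 loglik in a mock larger fit
  f3b <- f3; f3b$coefficients$extra <- 0
  cmp0 <- lrt_compare(f3, f3b)
  expect_equal(cmp0$chi_sq, 0, tolerance = 1e-8)
  expect_equal(cmp0$p_value, 1, tolerance = 1e-8)
  expect_equal(cmp0$preferred, "logistic3")
  # power: data truly flat at a non-chance floor before a steep rise should
  # prefer the 4-parameter form in a majority of replicates
  wins <- 0
  for (i in 1:30) {
    di <- make_choice_data(fx$absolute, lv4, n_subjects = 9, n_trials = 100,
                           seed = 400 + i)
    ci <- lrt_compare(fit_discrimination(di, "logistic3"),
                      fit_discrimination(di, "logistic4"))
    wins <- wins + (ci$preferred == "logistic4")
  }
  expect_gt(wins / 30, 0.5)
})

test_that("bootstrap equality test is exact at identity, powerful at separation, calibrated under the null", {
  a <- c(0.5, 0.6, 0.7, 0.8)
  r0 <- bootstrap_mean_equality(a, a, n_resamples = 2000, seed = 3)
  expect_equal(r0$t_Ho, 0)
  expect_gt(r0$p_value, 0.95)
  set.seed(11)
  r1 <- bootstrap_mean_equality(rnorm(200, 0.5, 0.01), rnorm(200, 0.9, 0.01),
                                n_resamples = 5000, seed = 4)
  expect_lt(r1$p_value, 0.001)
  expect_error(bootstrap_mean_equality(rep(0.5, 5), rep(0.5, 5)), "degenerate")
  # type-I calibration at alpha = 0.05
  set.seed(21)
  rej <- 0
  for (i in 1:500) {
    x <- rnorm(30, 0.7, 0.05); y <- rnorm(30, 0.7, 0.05)
    rej <- rej + (bootstrap_mean_equality(x, y, n_resamples = 999,
                                          seed = 1000 + i)$p_value < 0.05)
  }
  expect_gte(rej / 500, 0.03)
  expect_lte(rej / 500, 0.07)
})

test_that("successive and absolute fixture predictions differ on a common grid", {
  grid <- seq(0.01, 0.25, by = 0.01)
  pa <- eval_discrimination(fx$absolute, grid)
  ps <- eval_discrimination(fx$successive_blue, grid)
  r <- bootstrap_mean_equality(pa, ps, n_resamples = 10000, seed = 5)
  expect_lt(r$p_value, 0.001)
  expect_lt(r$t_Ho, 0)   # absolute conditioning is the poorer discriminator
})

test_that("discrimination functions serialize to JSON and back", {
  path <- tempfile(fileext = ".json")
  write_discrimination_json(fx$absolute, path)
  back <- read_discrimination_json(path)
  expect_equal(back$form, "logistic4")
  expect_equal(unlist(back$coefficients), unlist(fx$absolute$coefficients))
  expect_equal(eval_discrimination(back, 0.138), eval_discrimination(fx$absolute, 0.138))
})
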