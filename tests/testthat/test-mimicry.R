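test_that("frequency classification produces 10% bands by construction", {
  cl <- classify_frequency(fx$pdfs$ez_lateral_petal, n = 20000, seed = 71)
  tab <- table(cl$class) / nrow(cl)
  for (band in c("typical", "less_frequent", "rare"))
    expect_equal(unname(tab[band]), 0.10, tolerance = 0.01 / 0.10)
  # determinism under a fixed seed
  cl2 <- classify_frequency(fx$pdfs$ez_lateral_petal, n = 20000, seed = 71)
  expect_identical(cl$class, cl2$class)
  expect_error(classify_frequency(fx$pdfs$ez_lateral_petal, n = 500), "10000")
})

test_that("for a circular normal cloud, typical loci sit inside rare loci", {
  circ <- bivariate_pdf(marginal_model("normal", c(mean = 0, std = 1)),
                        marginal_model("normal", c(mean = 0, std = 1)))
  cl <- classify_frequency(circ, n = 20000, seed = 72)
  r <- sqrt(cl$x^2 + cl$y^2)
  expect_lt(max(r[cl$class == "typical"]), min(r[cl$class == "rare"]))
})

test_that("within-species class distances of the orchid petal match the published table", {
  cl <- classify_frequency(fx$pdfs$ez_lateral_petal, n = 100000, seed = 73)
  tl <- class_pair_distances(cl, c("typical", "less_frequent"), seed = 74)
  expect_equal(tl$mean_dc, 0.025, tolerance = 0.005 / 0.025)
  tr <- class_pair_distances(cl, c("typical", "rare"), seed = 75)
  expect_equal(tr$mean_dc, 0.035, tolerance = 0.005 / 0.035)
  # rare pairs are farther apart than less-frequent pairs from typical
  expect_gt(tr$mean_dc, tl$mean_dc)
  expect_named(tl$d_bands, c("typical", "less_frequent"))
})

test_that("a near-degenerate PDF collapses all class distances to zero", {
  tiny <- bivariate_pdf(
    marginal_model("normal", c(mean = 0.761, std = 0.027e-6)),
    marginal_model("normal", c(mean = 1.08, std = 0.012e-6)),
    copula_model("joe", 90, par1 = -2.15))
  cl <- classify_frequency(tiny, n = 10000, seed = 76)
  d <- class_pair_distances(cl, c("typical", "rare"), seed = 77)
  expect_lt(d$mean_dc, 1e-4)
})

test_that("cross-species distances are zero for identical seeded draws and stable in n", {
  p <- fx$pdfs$wc_petal
  d_same <- cross_species_distances(p, p, 10000, seed = c(78, 78))
  expect_true(all(d_same == 0))
  d1 <- cross_species_distances(fx$pdfs$ez_lateral_petal, fx$pdfs$wc_petal,
                                20000, seed = 79)
  d2 <- cross_species_distances(fx$pdfs$ez_lateral_petal, fx$pdfs$wc_petal,
                                40000, seed = 79)
  mc_se <- sd(d1) / sqrt(length(d1))
  expect_lt(abs(median(d1) - median(d2)), 4 * mc_se)
})

test_that("report medians and ranges are translation invariant", {
  shift <- function(p, dx, dy) {
    q <- p
    if (q$margin_x$family == "normal")
      q$margin_x$parameters$mean <- q$margin_x$parameters$mean + dx
    if (q$margin_y$family == "normal")
      q$margin_y$parameters$mean <- q$margin_y$parameters$mean + dy
    q
  }
  a <- fx$pdfs$ez_lateral_petal
  b <- bivariate_pdf(marginal_model("normal", c(mean = 0.745, std = 0.034)),
                     marginal_model("normal", c(mean = 1.104, std = 0.031)))
  d0 <- cross_species_distances(a, b, 10000, seed = 80)
  d1 <- cross_species_distances(shift(a, 5, -2), shift(b, 5, -2), 10000,
                                seed = 80)
  expect_equal(as.numeric(d0), as.numeric(d1), tolerance = 1e-12)
})

test_that("percent below threshold equals percent below the threshold distance exactly", {
  dc <- cross_species_distances(fx$pdfs$ez_lateral_petal, fx$pdfs$wc_petal,
                                20000, seed = 81)
  fns <- list(absolute = fx$absolute, successive = fx$successive_blue)
  rep <- discrimination_report(dc, fns)
  for (nm in names(fns)) {
    d75 <- threshold_distance(fns[[nm]], 0.75)
    pct_dist <- 100 * mean(dc < d75)
    pct_pi <- 100 * mean(eval_discrimination(fns[[nm]], dc, clamp = FALSE) < 0.75)
    expect_equal(pct_dist, pct_pi)
    expect_equal(rep$pct_below[rep$condition == nm], pct_dist)
  }
  # experience ordering: inexperienced bees are confused more often
  expect_gte(rep$pct_below[rep$condition == "absolute"],
             rep$pct_below[rep$condition == "successive"])
})

test_that("degenerate and low-asymptote report cases follow the stated conventions", {
  fns <- list(absolute = fx$absolute, successive = fx$successive_blue)
  rep0 <- discrimination_report(rep(0, 100), fns)
  expect_true(all(rep0$pct_below == 100))
  # at zero distance each function sits at its own floor (Mo, or chance)
  expect_equal(rep0$pi_median[rep0$condition == "absolute"], 0.5)
  expect_equal(rep0$pi_median[rep0$condition == "successive"], 0.528)
  weak <- discrimination_function("logistic3", c(K = 0.7, r = 50, Mo = 0.52))
  rep1 <- discrimination_report(seq(0, 0.3, length.out = 50),
                                c(fns, list(weak = weak)))
  expect_true(rep1$flag_low_K[rep1$condition == "weak"])
  expect_equal(rep1$pct_below[rep1$condition == "weak"], 100)
})

test_that("the simultaneous column appears only when a function is supplied", {
  dc <- seq(0.01, 0.2, length.out = 500)
  fns <- list(absolute = fx$absolute, successive = fx$successive_blue)
  rep2 <- discrimination_report(dc, fns)
  expect_false("simultaneous" %in% rep2$condition)
  simul <- discrimination_function("logistic3", c(K = 0.999, r = 90, Mo = 0.55))
  rep3 <- discrimination_report(dc, c(fns, list(simultaneous = simul)))
  expect_true("simultaneous" %in% rep3$condition)
  expect_error(discrimination_report(dc, list(absolute = fx$absolute)),
               "successive")
})

test_that("mimicry_report drives multiple region pairs end to end", {
  pairs <- list(petals = list(pdf_a = fx$pdfs$ez_lateral_petal,
                              pdf_b = fx$pdfs$wc_petal),
                labellum_pollen = list(pdf_a = fx$pdfs$ez_labellum,
                                       pdf_b = fx$pdfs$wc_pollen))
  out <- mimicry_report(pairs,
                        list(absolute = fx$absolute,
                             successive = fx$successive_blue),
                        n_pairs = 10000, seed = 82)
  expect_equal(nrow(out), 4)
  expect_true(all(out$pct_below >= 0 & out$pct_below <= 100))
  expect_true(all(out$pi_median >= 0.5 & out$pi_median <= 1))
  expect_true(all(out$min_dc <= out$median_dc & out$median_dc <= out$max_dc))
})
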