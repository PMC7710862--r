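# Monte-Carlo confusion-region analysis: classify typical / less-frequent /
# rare colors of a species from the density of sampled loci, measure within-
# and cross-species color distances, and score them against discrimination
# functions for different bee viewing conditions.

#' Classify sampled loci by color frequency
#'
#' Draws `n` loci from the species' bivariate color PDF, evaluates the joint
#' density at each locus, and classifies loci by empirical density quantiles:
#' typical above the 0.90 quantile, less frequent in (0.45, 0.55], rare in
#' (0.15, 0.25]. Loci outside the three bands are labelled `"unclassified"`.
#'
#' @param pdf A [bivariate_pdf()].
#' @param n Number of Monte-Carlo loci (default 100000, minimum 10000).
#' @param seed Optional integer seed.
#' @return data.frame with columns `x`, `y`, `density`, `class` plus an
#'   attribute `quantiles` holding the density quantiles used.
#' @export
classify_frequency <- function(pdf, n = 100000, seed = NULL) {
  stopifnot(inherits(pdf, "bivariate_pdf"))
  if (n < 10000) stop("n must be at least 10000 for stable density quantiles")
  xy <- pdf_sample(pdf, n, seed = seed)
  d <- pdf_density(pdf, xy[, 1], xy[, 2])
  if (stats::sd(d) == 0) stop("degenerate PDF: constant density over samples")
  q <- stats::quantile(d, c(0.15, 0.25, 0.45, 0.55, 0.90), names = FALSE)
  cls <- rep("unclassified", n)
  cls[d > q[5]] <- "typical"
  cls[d > q[3] & d <= q[4]] <- "less_frequent"
  cls[d > q[1] & d <= q[2]] <- "rare"
  out <- data.frame(x = xy[, 1], y = xy[, 2], density = d, class = cls)
  attr(out, "quantiles") <- stats::setNames(
    q, c("q15", "q25", "q45", "q55", "q90"))
  out
}

#' Mean color distance between two frequency classes
#'
#' Samples up to `cap` random cross-pairs (one locus from each class) and
#' returns their mean Euclidean distance together with the density band of
#' each class.
#'
#' @param classed Output of [classify_frequency()].
#' @param pair Character vector of two class labels, e.g.
#'   `c("typical", "rare")`.
#' @param cap Maximum number of random cross-pairs (default 100000).
#' @param seed Optional integer seed for the pair draw.
#' @return List with `mean_dc`, `n_pairs`, and `d_bands` (density range per
#'   class).
#' @export
class_pair_distances <- function(classed, pair, cap = 100000, seed = NULL) {
  stopifnot(is.data.frame(classed), length(pair) == 2)
  if (!is.null(seed)) set.seed(seed)
  ia <- which(classed$class == pair[1])
  ib <- which(classed$class == pair[2])
  if (!length(ia) || !length(ib))
    stop(sprintf("empty class: %s", pair[which(c(length(ia), length(ib)) == 0)[1]]))
  k <- min(cap, length(ia) * length(ib))
  sa <- ia[sample.int(length(ia), k, replace = TRUE)]
  sb <- ib[sample.int(length(ib), k, replace = TRUE)]
  dc <- sqrt((classed$x[sa] - classed$x[sb])^2 +
               (classed$y[sa] - classed$y[sb])^2)
  bands <- lapply(list(ia, ib), function(i) range(classed$density[i]))
  names(bands) <- pair
  list(mean_dc = mean(dc), n_pairs = k, d_bands = bands)
}

#' Cross-species color-distance sample
#'
#' Draws `n_pairs` loci from each species' PDF (independent streams), pairs
#' them elementwise and returns the Euclidean distances. This emulates a bee
#' encountering one flower of each species at random.
#'
#' @param pdf_a,pdf_b [bivariate_pdf()]s of the two species/regions.
#' @param n_pairs Number of paired draws (default 100000, minimum 10000).
#' @param seed Optional integer seed. A scalar seeds two independent
#'   sub-streams (`seed` and `seed + 1`); a length-2 vector seeds each
#'   species' stream explicitly (identical stream seeds with identical PDFs
#'   give identical paired draws).
#' @return Numeric vector of distances with attribute `summary`
#'   (median, min, max).
#' @export
cross_species_distances <- function(pdf_a, pdf_b, n_pairs = 100000,
                                    seed = NULL) {
  if (n_pairs < 10000) stop("n_pairs must be at least 10000")
  seeds <- if (is.null(seed)) list(NULL, NULL)
           else if (length(seed) == 1) list(seed, seed + 1)
           else list(seed[1], seed[2])
  a <- pdf_sample(pdf_a, n_pairs, seed = seeds[[1]])
  b <- pdf_sample(pdf_b, n_pairs, seed = seeds[[2]])
  dc <- sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  attr(dc, "summary") <- c(median = stats::median(dc),
                           min = min(dc), max = max(dc))
  dc
}

#' Discrimination report over a color-distance sample
#'
#' For each supplied discrimination function (named for its viewing
#' condition, e.g. `absolute`, `successive`, `simultaneous`), reports the
#' predicted accuracy at the median distance, the accuracy range over the
#' whole sample (clamped at chance), and the percentage of pairs whose
#' accuracy falls below `threshold` — equivalently, whose distance falls
#' below that function's threshold distance. A simultaneous-viewing column
#' appears only when a simultaneous function is supplied.
#'
#' @param distances Numeric vector of color distances (Hu).
#' @param fns Named list of [discrimination_function()]s; must include at
#'   least `absolute` and `successive`.
#' @param threshold Accuracy threshold (default 0.75).
#' @return data.frame with one row per condition: `condition`, `median_dc`,
#'   `min_dc`, `max_dc`, `pi_median`, `pi_min`, `pi_max`, `pct_below`,
#'   `flag_low_K`.
#' @export
discrimination_report <- function(distances, fns, threshold = 0.75) {
  distances <- as.numeric(distances)
  stopifnot(length(distances) >= 1, is.list(fns))
  if (!all(c("absolute", "successive") %in% names(fns)))
    stop("fns must include at least 'absolute' and 'successive'")
  med <- stats::median(distances)
  rows <- lapply(names(fns), function(nm) {
    fn <- fns[[nm]]
    stopifnot(inherits(fn, "discrimination_function"))
    low_K <- fn$coefficients$K < threshold
    if (low_K) {
      pct <- 100
    } else {
      d75 <- threshold_distance(fn, threshold)
      pct <- 100 * mean(distances < d75)
    }
    pi_all_range <- range(eval_discrimination(fn, range(distances)))
    data.frame(condition = nm,
               median_dc = med, min_dc = min(distances),
               max_dc = max(distances),
               pi_median = eval_discrimination(fn, med),
               pi_min = pi_all_range[1], pi_max = pi_all_range[2],
               pct_below = pct, flag_low_K = low_K)
  })
  do.call(rbind, rows)
}

#' Full mimic-vs-model confusion analysis
#'
#' Convenience driver combining [cross_species_distances()] and
#' [discrimination_report()] for a set of flower-region pairs.
#'
#' @param pairs Named list; each element a list with `pdf_a`, `pdf_b`.
#' @param fns Named list of discrimination functions (see
#'   [discrimination_report()]).
#' @param n_pairs Monte-Carlo pairs per region pair.
#' @param threshold Accuracy threshold.
#' @param seed Integer seed; sub-seeds are derived per region pair.
#' @return data.frame, one row per region pair x condition.
#' @export
mimicry_report <- function(pairs, fns, n_pairs = 100000, threshold = 0.75,
                           seed = 1) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    dc <- cross_species_distances(p$pdf_a, p$pdf_b, n_pairs,
                                  seed = seed + i - 1)
    rep <- discrimination_report(dc, fns, threshold)
    cbind(pair = names(pairs)[i], rep)
  })
  do.call(rbind, rows)
}
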