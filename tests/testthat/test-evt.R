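test_that("block maxima are per-block maxima with empty blocks skipped", {
  s <- block_maxima(list(c(3, 9, 4), c(7, 7), c(1, 2, 10)))
  expect_equal(s$values, c(9, 7, 10))
  expect_equal(s$m, 3)
  expect_equal(s$mean_block_size, 8 / 3)

  expect_equal(block_maxima(list(c(2, 5)))$values, 5)

  with_empty <- block_maxima(list(c(1, 2), numeric(0), c(4)))
  expect_equal(with_empty$values, c(2, 4))
  expect_equal(with_empty$skipped, 1L)
  expect_error(block_maxima(list(numeric(0), numeric(0))), "empty")

  # maxima of blocks of 30 exponentials follow F^30
  set.seed(2)
  blocks <- replicate(1e4, stats::rexp(30), simplify = FALSE)
  mx <- block_maxima(blocks)
  expect_equal(mx$mean_block_size, 30)
  d <- ks_distance(mx$values,
                   function(x) max_distribution_cdf(stats::pexp, 30, x))
  expect_lt(d, 0.02)
})

test_that("normalized histogram sums to one over right-open bins", {
  h <- normalized_histogram(c(1, 1, 2), bin_width = 1)
  expect_equal(h$masses, c(2 / 3, 1 / 3))
  expect_equal(h$bin_edges, c(1, 2, 3))

  # right-open: a value on an interior edge belongs to the bin above
  h2 <- normalized_histogram(c(1.0, 2.0), bin_width = 1)
  expect_equal(h2$masses, c(0.5, 0.5))

  set.seed(3)
  for (i in 1:5) {
    vals <- stats::rlnorm(200, meanlog = i)
    hh <- normalized_histogram(vals, bin_width = 0.5 * i)
    expect_equal(sum(hh$masses), 1, tolerance = 1e-12)
    expect_true(all(hh$masses >= 0))
    expect_equal(length(hh$masses), length(hh$bin_edges) - 1)
    expect_lte(hh$bin_edges[1], min(vals))
    expect_gt(max(hh$bin_edges), max(vals))
  }
  expect_error(normalized_histogram(numeric(0)), "nonempty")

  # bin masses agree with analytic CDF differences (4 standard errors)
  u <- stream_uniform(make_stream(21), 1e5)
  g <- qgumbel(u)
  hg <- normalized_histogram(g, bin_width = 0.1)
  p_true <- diff(pgumbel(hg$bin_edges))
  se <- sqrt(p_true * (1 - p_true) / 1e5)
  check <- p_true > 1e-4
  expect_true(all(abs(hg$masses[check] - p_true[check]) < 4 * se[check]))
})

test_that("r_squared matches hand-computed values and guards input", {
  obs <- c(0.2, 0.5, 0.3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(0.25, 0.45, 0.3)),
               1 - 0.005 / (sum((obs - mean(obs))^2)))
  expect_equal(r_squared(obs, c(0.25, 0.45, 0.3)), 0.892857, tolerance = 1e-6)
  expect_error(r_squared(c(1, 2), c(1, 2)), "3 points")
  expect_error(r_squared(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("ks_distance is the sup distance to the reference CDF", {
  expect_equal(ks_distance(0, pgumbel), 1 - pgumbel(0))
  expect_equal(ks_distance(qgumbel(0.5), pgumbel), 0.5)
  # whole sample below the support of a Frechet: total mismatch
  expect_equal(ks_distance(c(-3, -2, -1), function(x) pfrechet(x, 2)), 1)

  u <- stream_uniform(make_stream(31), 1e5)
  expect_lt(ks_distance(qgumbel(u, 40, 5),
                        function(x) pgumbel(x, 40, 5)),
            1.95 / sqrt(1e5))
})

test_that("least-squares fit of an exactly-Gumbel histogram is perfect", {
  centers <- seq(10.25, 149.75, by = 0.5)
  masses <- dgumbel(centers, 40, 5) * 0.5
  h <- structure(list(bin_edges = c(centers - 0.25, max(centers) + 0.25),
                      masses = masses / sum(masses), bin_width = 0.5),
                 class = "normalized_histogram")
  fit <- fit_extreme(h, family = "gumbel", method = "histogram_ls")
  expect_gt(fit$r_squared, 1 - 1e-6)
  expect_equal(fit$location, 40, tolerance = 1e-3)
  expect_equal(fit$scale, 5, tolerance = 1e-3)
})

test_that("maximum likelihood recovers Gumbel and Frechet parameters", {
  u <- stream_uniform(make_stream(41), 2e4)
  g <- qgumbel(u, 40, 5)
  fit <- fit_extreme(g, family = "gumbel", method = "mle")
  expect_lt(abs(fit$location - 40), 0.1)
  expect_lt(abs(fit$scale - 5), 0.1)
  expect_lt(fit$ks, 1.95 / sqrt(2e4))

  uf <- stream_uniform(make_stream(42), 1e5)
  fr <- qfrechet(uf, shape = 20, location = 0, scale = 28)
  fitf <- fit_extreme(fr, family = "frechet", method = "mle")
  expect_lt(abs(fitf$shape_alpha - 20) / 20, 0.10)
  expect_lt(abs(fitf$scale - 28) / 28, 0.10)
})

test_that("fit_extreme validates its inputs", {
  expect_error(fit_extreme(rep(5, 100), "gumbel"), "degenerate")
  h <- normalized_histogram(c(1, 2, 3, 4), 1)
  expect_error(fit_extreme(h, "gumbel", method = "mle"), "raw maxima")
  expect_error(fit_extreme("not data", "gumbel"), "must be")
  expect_error(fit_extreme(c(1, 2), "gumbel"), "too few")
})

test_that("fits are stable under sub-bin shifts of the histogram origin", {
  u <- stream_uniform(make_stream(4), 2e4)
  g <- qgumbel(u, 40, 5)
  f1 <- fit_extreme(normalized_histogram(g, 1), "gumbel")
  f2 <- fit_extreme(normalized_histogram(g, 1, origin = floor(min(g)) - 0.4),
                    "gumbel")
  expect_lt(abs(f1$location - f2$location), 0.05)
  expect_lt(abs(f1$scale - f2$scale) / f1$scale, 0.01)
})
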