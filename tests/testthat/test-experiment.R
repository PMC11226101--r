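test_that("experiment configuration enforces its invariants", {
  expect_error(experiment_config(trials_m = 50), "at least 100")
  expect_error(
    experiment_config(tc = time_constant_model("pareto", 20, 20),
                      fit_family = "gumbel"),
    "does not match")
  cfg <- experiment_config(tc = time_constant_model("pareto", 20, 20),
                           fit_family = "gumbel",
                           allow_family_mismatch = TRUE)
  expect_equal(cfg$fit_family, "gumbel")
  # automatic family selection
  expect_equal(experiment_config(
    tc = time_constant_model("exponential", 20, 5))$fit_family, "gumbel")
  expect_equal(experiment_config(
    tc = time_constant_model("pareto", 20, 20))$fit_family, "frechet")
})

test_that("experiments are byte-reproducible from the master seed", {
  cfg <- experiment_config(tc = time_constant_model("exponential", 20, 5),
                           trials_m = 500, master_seed = 7)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$maxima$values, r2$maxima$values)
  expect_identical(r1$fit$location, r2$fit$location)
  expect_identical(r1$histogram$masses, r2$histogram$masses)

  r3 <- run_experiment(experiment_config(
    tc = time_constant_model("exponential", 20, 5),
    trials_m = 500, master_seed = 8))
  expect_false(identical(r1$maxima$values, r3$maxima$values))

  # trial i runs on substream i: prefix of a longer run is identical
  cfg_long <- experiment_config(tc = time_constant_model("exponential", 20, 5),
                                trials_m = 600, master_seed = 7)
  r_long <- run_experiment(cfg_long)
  expect_identical(r_long$maxima$values[1:500], r1$maxima$values)
})

test_that("closed-form maxima parameters cover the exponential family", {
  tc <- time_constant_model("exponential", mu = 20, sigma = 5)
  th <- theoretical_max_params(tc, 30)
  expect_equal(th$location, 20 + log(30) / 5)
  expect_equal(th$location, 20.680, tolerance = 1e-4)
  expect_equal(th$scale, 0.2)
  # single-draw anchor
  th1 <- theoretical_max_params(tc, 1)
  expect_equal(th1$location, 20)
  tc_scale <- time_constant_model("exponential", 20, 5, convention = "scale")
  expect_equal(theoretical_max_params(tc_scale, 30)$scale, 5)
  expect_error(theoretical_max_params(time_constant_model("pareto", 20, 20),
                                      30), "exponential")
})

test_that("degenerate (fixed-xi) experiments refuse to fit", {
  cfg <- experiment_config(tc = time_constant_model("fixed", mu = 20),
                           trials_m = 100, master_seed = 1)
  expect_error(run_experiment(cfg), "degenerate")
})

test_that("mostly-silent configurations abort with a diagnostic", {
  cfg <- experiment_config(
    lif = lif_parameters(theta = -50, i_ext = 1),
    tc = time_constant_model("exponential", 20, 5),
    mode = "ode", trials_m = 100, master_seed = 1)
  expect_error(run_experiment(cfg), "no spikes")
})

test_that("a mis-specified family fits visibly worse on the same maxima", {
  cfg <- experiment_config(tc = time_constant_model("pareto", 20, 7.5),
                           trials_m = 5000, master_seed = 2)
  res <- run_experiment(cfg)
  wrong <- fit_extreme(res$maxima, "gumbel", "histogram_ls")
  expect_lt(wrong$r_squared, res$fit$r_squared)
  expect_gt(wrong$ks, res$fit$ks)
})

test_that("Frechet shape estimates approach the Pareto tail index with m", {
  fit_at <- function(m) {
    cfg <- experiment_config(tc = time_constant_model("pareto", 20, 20),
                             trials_m = m, master_seed = 6,
                             fit_method = "mle")
    run_experiment(cfg)$fit$shape_alpha
  }
  a_small <- fit_at(5000)
  a_large <- fit_at(50000)
  expect_lt(abs(a_large - 20), abs(a_small - 20))
  expect_lt(abs(a_large - 20) / 20, 0.25)
})

test_that("reproduce_reference wires the named configurations", {
  res <- reproduce_reference("fig3", scale_factor = 0.01, master_seed = 3)
  expect_s3_class(res, "experiment_result")
  expect_equal(res$config$trials_m, 1000L)
  expect_equal(res$config$tc$family, "exponential")
  expect_equal(res$fit$family, "gumbel")
  expect_equal(sum(res$histogram$masses), 1, tolerance = 1e-12)

  res75 <- reproduce_reference("fig4_sigma7p5", scale_factor = 0.01,
                           master_seed = 3)
  expect_equal(res75$config$trials_m, 10000L)
  expect_equal(res75$config$tc$sigma, 7.5)
  # heavy-tailed maxima: the fitted tail index tracks the Pareto sigma
  expect_lt(abs(res75$fit$shape_alpha - 7.5) / 7.5, 0.25)
  expect_error(reproduce_reference("fig5"), "arg")
})

test_that("ode-mode experiments run the same pipeline end to end", {
  cfg <- experiment_config(tc = time_constant_model("exponential", 20, 5),
                           mode = "ode", trials_m = 300, master_seed = 4)
  res <- run_experiment(cfg)
  expect_equal(res$maxima$m, 300)
  # ode intervals are about xi * log 6 for each drawn xi, so maxima sit
  # near 20 * log 6 ~ 36 ms and above
  expect_gt(min(res$maxima$values), 30)
  expect_true(is.finite(res$fit$r_squared))
})
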