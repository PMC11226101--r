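test_that("euler_step implements the forward-Euler contract", {
  p <- lif_parameters()
  expect_equal(euler_step(-65, xi = 20, p), -64.4)
  # asymptote v_rest + r*i_ext = -53 is a fixed point
  expect_equal(euler_step(-53, xi = 20, p), -53)
  expect_error(euler_step(-65, xi = 0, p), "positive")

  # iterates increase monotonically toward -53 without overshoot, and stay
  # above the continuous solution V(t) = -53 + (V0 + 53) exp(-t/xi)
  v <- -65
  for (k in 1:200) {
    v_new <- euler_step(v, 20, p)
    expect_gt(v_new, v)
    expect_lte(v_new, -53)
    expect_gte(v_new, -53 + (-65 + 53) * exp(-k * p$dt / 20))
    v <- v_new
  }
})

test_that("analytic first-passage time matches the closed form", {
  p <- lif_parameters()
  expect_equal(analytic_first_spike_time(20, p), 20 * log(6))
  expect_equal(analytic_first_spike_time(1, p), log(6))
  # threshold at rest fires immediately
  expect_equal(analytic_first_spike_time(20, lif_parameters(theta = -65)), 0)
  expect_error(
    analytic_first_spike_time(20, lif_parameters(theta = -50, i_ext = 1)),
    "silent")
})

test_that("synapse current decays exponentially from i_s0 through omega", {
  syn <- synapse_model(tau_s = 2, i_s0 = 3)
  expect_equal(synapse_current(syn, 0), 3)
  expect_equal(synapse_current(syn, 2), 3 * exp(-1))
  expect_equal(synapse_current(syn, 2), syn$omega)
  expect_error(synapse_current(syn, -1), "non-negative")
  t <- seq(0, 20, by = 0.5)
  expect_true(all(diff(synapse_current(syn, t)) < 0))
  expect_lt(synapse_current(syn, 100), 1e-10)
})

test_that("extract_intervals uses the from-zero convention and validates", {
  expect_equal(extract_intervals(c(36, 72, 108)), c(36, 36, 36))
  expect_equal(extract_intervals(20), 20)
  expect_equal(extract_intervals(c(10, 15, 40)), c(10, 5, 25))
  expect_equal(extract_intervals(c(10, 15, 40), from_zero = FALSE), c(5, 25))
  expect_error(extract_intervals(c(10, 5)), "strictly increasing")
  expect_error(extract_intervals(c(10, 10)), "strictly increasing")
  expect_identical(extract_intervals(numeric(0)), numeric(0))
})

test_that("ode mode with fixed xi reproduces the discrete recurrence exactly", {
  p <- lif_parameters()
  tc <- time_constant_model("fixed", mu = 20)
  tr <- simulate_trial(p, tc, synapse_model(enabled = FALSE), make_stream(1),
                       mode = "ode")
  expect_identical(tr$spike_times, recurrence_spike_times(20, p))
  expect_true(length(unique(tr$intervals)) == 1)
  expect_equal(tr$intervals[1], recurrence_period(20, p))
})

test_that("ode-mode intervals are the deterministic crossing map of each xi", {
  p <- lif_parameters()
  tc <- time_constant_model("exponential", mu = 20, sigma = 5)
  tr <- simulate_trial(p, tc, synapse_model(), make_stream(42), mode = "ode")
  expect_gt(length(tr$spike_times), 10)
  expected <- vapply(tr$xi_draws, recurrence_period, numeric(1), p = p)
  expect_equal(tr$intervals, expected)
})

test_that("spike trains respect the trial window and grid invariants", {
  p <- lif_parameters()
  tc <- time_constant_model("exponential", mu = 20, sigma = 5)
  for (mode in c("ode", "direct")) {
    tr <- simulate_trial(p, tc, synapse_model(), make_stream(3), mode = mode)
    expect_true(all(diff(tr$spike_times) > 0))
    expect_lte(max(tr$spike_times), p$n_steps * p$dt)
    expect_true(all(tr$intervals > 0))
    expect_equal(length(tr$intervals), length(tr$spike_times))
  }
  tr_ode <- simulate_trial(p, tc, synapse_model(), make_stream(3), "ode")
  expect_true(all(tr_ode$spike_times %% p$dt == 0))
})

test_that("fast synapse decay leaves spike times unchanged", {
  p <- lif_parameters()
  tc <- time_constant_model("exponential", mu = 20, sigma = 5)
  gated <- simulate_trial(p, tc, synapse_model(tau_s = 0.5), make_stream(9),
                          mode = "ode")
  ungated <- simulate_trial(p, tc, synapse_model(enabled = FALSE),
                            make_stream(9), mode = "ode")
  expect_identical(gated$spike_times, ungated$spike_times)
})

test_that("silent configurations give empty trains with a warning", {
  p_silent <- lif_parameters(theta = -50, i_ext = 1) # asymptote -64 mV
  expect_false(p_silent$can_spike)
  expect_warning(
    tr <- simulate_trial(p_silent, time_constant_model("fixed", 20),
                         synapse_model(), make_stream(1), "ode"),
    "silent")
  expect_length(tr$spike_times, 0)

  # direct mode: location beyond the trial window
  expect_warning(
    tr2 <- simulate_trial(lif_parameters(n_steps = 10),
                          time_constant_model("exponential", 20, 5),
                          synapse_model(), make_stream(1), "direct"),
    "no spikes")
  expect_length(tr2$spike_times, 0)
})

test_that("direct-mode intervals follow the configured interval law", {
  cfg <- experiment_config(tc = time_constant_model("exponential", 20, 5),
                           trials_m = 2000, master_seed = 5)
  res <- run_experiment(cfg, keep_trains = TRUE)
  pooled <- unlist(lapply(res$trains, function(t) t$intervals))
  expect_gt(length(pooled), 9e4)
  expect_lt(ks_distance(pooled, function(q) stats::pexp(q - 20, rate = 5)),
            0.01)
})
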